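# Shared fixtures: all built in code, nothing on disk.

# fully random tiny MLP (every layer nonzero) for gradient/aggregation tests
rand_net <- function(seed, d = 2L, h = 3L, c = 2L) {
  withr::with_seed(seed, structure(list(
    W1 = matrix(stats::rnorm(d * h, sd = 0.5), d, h),
    b1 = stats::rnorm(h, sd = 0.2),
    W2 = matrix(stats::rnorm(h * h, sd = 0.5), h, h),
    b2 = stats::rnorm(h, sd = 0.2),
    W3 = matrix(stats::rnorm(h * c, sd = 0.5), h, c),
    b3 = stats::rnorm(c, sd = 0.2)), class = "model_params"))
}

# a net whose first-class probability on scalar input x is
# exp(x) / (exp(x) + 1) for any sign of x: the hidden layers carry
# (relu(x), relu(-x)) so the output logits are (x, 0)
prob_dial_net <- function() {
  structure(list(
    W1 = matrix(c(1, -1), 1, 2), b1 = c(0, 0),
    W2 = diag(2), b2 = c(0, 0),
    W3 = matrix(c(1, -1, 0, 0), 2, 2), b3 = c(0, 0)),
    class = "model_params")
}

# central finite differences of local_loss — the independent gradient oracle
fd_gradients <- function(params, x, y, h = 1e-5) {
  g <- lapply(params, function(tensor) tensor * 0)
  for (nm in names(params)) {
    for (i in seq_along(params[[nm]])) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      g[[nm]][i] <- (local_loss(pp, x, y) - local_loss(pm, x, y)) / (2 * h)
    }
  }
  g
}

param_max_abs_diff <- function(p, q) {
  max(vapply(names(p), function(nm) max(abs(p[[nm]] - q[[nm]])),
             numeric(1)))
}

# tiny labelled dataset of random 8-bit images
toy_dataset <- function(n, h = 4L, w = 4L, seed = 1L,
                        labels = rep(c("normal", "pneumonia"),
                                     length.out = n)) {
  imgs <- withr::with_seed(seed, lapply(seq_len(n), function(i) {
    array(sample(0:255, h * w, replace = TRUE), dim = c(h, w, 1L))
  }))
  labelled_dataset(imgs, labels, class_names = c("normal", "pneumonia"))
}

# linearly separable flattened tensors: class decided by mean input shift
separable_tensors <- function(n, d = 8L, shift = 2, seed = 1L) {
  withr::with_seed(seed, {
    y_lab <- rep(c("a", "b"), length.out = n)[sample.int(n)]
    x <- matrix(stats::rnorm(n * d), n, d)
    x[y_lab == "b", ] <- x[y_lab == "b", ] + shift
    list(x = x, y = one_hot_encode(y_lab, c("a", "b")))
  })
}

# standard small synthetic study dataset used across orchestration tests
study_split <- function(n = 200L, seed = 7L) {
  ds <- generate_dataset(synth_spec(n_images = n, seed = seed))
  split_train_test(normalize_pixels(ds), ratio = 0.9, seed = 42L)
}
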