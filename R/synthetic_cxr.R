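#' Specification for the synthetic chest-X-ray-like generator
#'
#' The generator replaces downloaded radiographs with a controllable
#' two-class fixture: both classes share a fixed vignette background
#' (darker borders, brighter centre, loosely mimicking the lung field of a
#' frontal radiograph), and the positive "pneumonia" class additionally
#' carries one bright elliptical opacity with a Gaussian-feathered edge — a
#' crude analogue of a consolidation. Because the classes differ only by
#' the patch, a one-parameter mean-pixel threshold classifier is a valid
#' independent baseline, which the test-suite exploits.
#'
#' @param n_images number of images to generate (>= 2).
#' @param image_size integer `(height, width)` in pixels.
#' @param channels 1 (native) or 3 (the single channel is replicated).
#' @param prevalence fraction of positive-class images in \[0, 1\].
#' @param opacity_intensity added brightness of the patch plateau on the
#'   0--255 scale.
#' @param opacity_radius_px patch semi-major axis in pixels; must be below
#'   half the smaller image dimension.
#' @param noise_sd per-pixel Gaussian noise SD on the 0--255 scale.
#' @param seed RNG seed; the same spec (seed included) yields
#'   byte-identical images.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_images = 600L, image_size = c(28L, 28L),
                       channels = 1L, prevalence = 0.5,
                       opacity_intensity = 120, opacity_radius_px = 6,
                       noise_sd = 20, seed = 7L) {
  if (!(is.numeric(n_images) && n_images >= 2)) {
    stop("invalid `n_images`: need at least 2, got ", n_images)
  }
  stopifnot(length(image_size) == 2L, all(image_size >= 4L))
  if (!channels %in% c(1L, 3L)) stop("invalid `channels`: must be 1 or 3")
  if (!(is.numeric(prevalence) && prevalence >= 0 && prevalence <= 1)) {
    stop("invalid `prevalence`: must lie in [0, 1], got ", prevalence)
  }
  if (!(opacity_intensity >= 0 && opacity_intensity <= 255)) {
    stop("invalid `opacity_intensity`: must lie in [0, 255]")
  }
  if (!(opacity_radius_px > 0 && opacity_radius_px < min(image_size) / 2)) {
    stop("invalid `opacity_radius_px`: must be positive and below ",
         "min(image_size)/2 = ", min(image_size) / 2)
  }
  if (!(noise_sd >= 0)) stop("invalid `noise_sd`: must be non-negative")
  structure(
    list(n_images = as.integer(n_images),
         image_size = as.integer(image_size),
         channels = as.integer(channels),
         prevalence = prevalence,
         opacity_intensity = opacity_intensity,
         opacity_radius_px = opacity_radius_px,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# shared vignette background: dark borders, brighter centre
synth_background <- function(h, w) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  d2 <- ((yy - cy) / (h / 2))^2 + ((xx - cx) / (w / 2))^2
  30 + 70 * exp(-d2 / 0.9)
}

# additive elliptical opacity with a Gaussian-feathered edge;
# plateau value `intensity`, feather scale 20% of the radius
synth_patch <- function(h, w, cy, cx, ry, rx, intensity) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  r <- sqrt(((yy - cy) / ry)^2 + ((xx - cx) / rx)^2)
  feather <- 0.2
  mask <- ifelse(r <= 1, 1, exp(-((r - 1) / feather)^2 / 2))
  intensity * mask
}

#' Generate a synthetic two-class image dataset
#'
#' Draws `round(prevalence * n_images)` positive ("pneumonia") and the
#' remaining negative ("normal") images according to a [synth_spec()],
#' shuffles their order, and returns 8-bit pixels (integers in
#' \[0, 255\]) ready for [normalize_pixels()]. Each positive image carries
#' one opacity centred uniformly at random within the central half of the
#' frame (the "lung field"), with mild random eccentricity; negatives are
#' background plus noise only.
#'
#' @param spec a [synth_spec()].
#' @return a [labelled_dataset()] with classes `normal` / `pneumonia`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  n <- spec$n_images
  n_pos <- round(spec$prevalence * n)
  bg <- synth_background(h, w)
  withr::with_seed(spec$seed, {
    labels <- c(rep("pneumonia", n_pos), rep("normal", n - n_pos))
    labels <- labels[sample.int(n)]
    images <- vector("list", n)
    for (i in seq_len(n)) {
      im <- bg
      if (labels[i] == "pneumonia") {
        # centre uniform in the central half of each dimension
        cy <- stats::runif(1, 0.25 * h, 0.75 * h)
        cx <- stats::runif(1, 0.25 * w, 0.75 * w)
        ecc <- stats::runif(1, 0.6, 1)   # mild eccentricity
        im <- im + synth_patch(h, w, cy, cx,
                               ry = spec$opacity_radius_px * ecc,
                               rx = spec$opacity_radius_px,
                               intensity = spec$opacity_intensity)
      }
      if (spec$noise_sd > 0) {
        im <- im + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
      }
      im <- round(pmin(pmax(im, 0), 255))
      if (spec$channels == 3L) {
        im <- array(rep(im, 3L), dim = c(h, w, 3L))
      } else {
        dim(im) <- c(h, w, 1L)
      }
      images[[i]] <- im
    }
    labelled_dataset(images, labels,
                     class_names = c("normal", "pneumonia"))
  })
}

#' Write a dataset as a PNG image tree
#'
#' Writes one 8-bit PNG per image under per-class subdirectories named by
#' the upper-cased class (`NORMAL/`, `PNEUMONIA/`), the layout of the
#' public Kaggle chest X-ray collections. Loading the tree back with
#' [load_image_dir()] reproduces pixels and labels exactly.
#'
#' @param dataset a non-empty [labelled_dataset()] on the 0--255 scale.
#' @param root_path output directory (created if missing).
#' @return the root path, invisibly.
#' @export
write_image_dir <- function(dataset, root_path) {
  stopifnot(inherits(dataset, "labelled_dataset"))
  if (length(dataset) == 0L) stop("refusing to write an empty dataset")
  dir.create(root_path, showWarnings = FALSE, recursive = TRUE)
  for (cls in dataset$class_names) {
    dir.create(file.path(root_path, toupper(cls)), showWarnings = FALSE)
  }
  for (i in seq_along(dataset$images)) {
    im <- dataset$images[[i]]
    if (any(im < 0 | im > 255 | im != floor(im))) {
      stop("image ", i, " is not 8-bit (integers in [0, 255]); ",
           "write before normalization")
    }
    out <- if (dim(im)[3L] == 1L) im[, , 1L] else im
    png::writePNG(out / 255,
                  file.path(root_path, toupper(dataset$labels[i]),
                            sprintf("img_%05d.png", i)))
  }
  invisible(root_path)
}

#' Mean-pixel threshold baseline
#'
#' Fits the one-parameter classifier "positive if the image mean exceeds
#' t", choosing t to maximize training accuracy over the sorted candidate
#' midpoints. This is deliberately the simplest possible detector of the
#' synthetic opacity and serves as an independent yardstick for the
#' separability of generated data; it touches none of the MLP code.
#'
#' @param train,test [labelled_dataset()]s (either pixel scale).
#' @param positive_class label counted as positive; default `"pneumonia"`.
#' @return list with `threshold`, `train_accuracy`, `test_accuracy`.
#' @export
threshold_baseline <- function(train, test, positive_class = "pneumonia") {
  mean_of <- function(ds) vapply(ds$images, mean, numeric(1))
  m_tr <- mean_of(train); y_tr <- train$labels == positive_class
  ord <- order(m_tr)
  m_s <- m_tr[ord]; y_s <- y_tr[ord]
  cand <- c(m_s[1L] - 1, (m_s[-1L] + m_s[-length(m_s)]) / 2,
            m_s[length(m_s)] + 1)
  acc <- vapply(cand, function(t) mean((m_tr > t) == y_tr), numeric(1))
  thr <- cand[which.max(acc)]
  m_te <- mean_of(test); y_te <- test$labels == positive_class
  list(threshold = thr,
       train_accuracy = max(acc),
       test_accuracy = mean((m_te > thr) == y_te))
}
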