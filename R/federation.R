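#' Partition the training set into client shards
#'
#' Simulates the cross-silo setting: the pooled training data is shuffled
#' under `seed` and sliced contiguously into `n_clients` IID shards named
#' `clients_1 ... clients_N`. Shard sizes differ by at most one; the first
#' `n %% n_clients` shards receive the extra image. In a real federation
#' each hospital owns its data — this partition exists only so the whole
#' loop can be exercised on one machine.
#'
#' @param train a [labelled_dataset()] (the training portion).
#' @param n_clients number of participating clients (>= 1).
#' @param seed shuffle seed.
#' @return list of `client_shard` objects, each with `client_id` and
#'   `data`.
#' @export
create_shards <- function(train, n_clients, seed = 42L) {
  stopifnot(inherits(train, "labelled_dataset"))
  n <- length(train)
  if (!(n_clients >= 1)) stop("`n_clients` must be >= 1")
  if (n_clients > n) {
    stop("more clients (", n_clients, ") than training images (", n, ")")
  }
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  base <- n %/% n_clients
  extra <- n %% n_clients
  sizes <- rep(base, n_clients) + c(rep(1L, extra),
                                    rep(0L, n_clients - extra))
  stops <- cumsum(sizes)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  lapply(seq_len(n_clients), function(i) {
    structure(
      list(client_id = sprintf("clients_%d", i),
           data = dataset_subset(train, perm[starts[i]:stops[i]])),
      class = "client_shard"
    )
  })
}

#' Construct a client shard directly
#'
#' Normally shards come from [create_shards()]; this constructor exists
#' for audits and for composing federations whose clients hold
#' pre-existing (e.g. genuinely private, unequal) datasets.
#'
#' @param client_id client name, e.g. `"clients_1"`.
#' @param data the client's [labelled_dataset()].
#' @return a `client_shard` object.
#' @export
client_shard <- function(client_id, data) {
  stopifnot(is.character(client_id), length(client_id) == 1L,
            inherits(data, "labelled_dataset"))
  structure(list(client_id = client_id, data = data),
            class = "client_shard")
}

#' @export
print.client_shard <- function(x, ...) {
  cat("<client_shard> ", x$client_id, ": ", length(x$data), " images\n",
      sep = "")
  invisible(x)
}

#' Data-proportional weight scaling factor of one client
#'
#' The fraction of all shard data held by `client_id`:
#' `|D_k| / sum_j |D_j|`. These factors weight each client's parameters in
#' the federated average and sum to one over the participating clients;
#' for the equal IID shards of [create_shards()] they reduce to
#' `1/n_clients`.
#'
#' @param shards list of shards from [create_shards()].
#' @param client_id the client's name.
#' @return object of class `scaling_factor` with `client_id` and `factor`.
#' @export
weight_scaling_factor <- function(shards, client_id) {
  ids <- vapply(shards, `[[`, character(1), "client_id")
  k <- match(client_id, ids)
  if (is.na(k)) stop("unknown client_id: '", client_id, "'")
  sizes <- vapply(shards, function(s) length(s$data), numeric(1))
  structure(list(client_id = client_id, factor = sizes[k] / sum(sizes)),
            class = "scaling_factor")
}

#' Scaling factors for all clients
#'
#' @param shards list of shards from [create_shards()].
#' @return named numeric vector of factors, summing to 1, in shard order.
#' @export
scaling_factors <- function(shards) {
  sizes <- vapply(shards, function(s) length(s$data), numeric(1))
  stats::setNames(sizes / sum(sizes),
                  vapply(shards, `[[`, character(1), "client_id"))
}

#' Scale every parameter tensor of a model
#'
#' Elementwise multiplication of all weight and bias tensors by one
#' scalar — the per-client step of FedAvg before summation.
#'
#' @param params a `model_params` object ([init_mlp()]).
#' @param factor scalar in (0, 1\].
#' @return the scaled `model_params`.
#' @export
scale_model <- function(params, factor) {
  if (inherits(factor, "scaling_factor")) factor <- factor$factor
  if (!(is.numeric(factor) && length(factor) == 1L && is.finite(factor))) {
    stop("`factor` must be a single finite number")
  }
  if (factor <= 0 || factor > 1) stop("`factor` must lie in (0, 1]")
  params[] <- lapply(params, function(tensor) tensor * factor)
  params
}

#' Federated averaging of pre-scaled client models
#'
#' Tensor-wise summation of the already-scaled client parameter lists.
#' Because the scaling factors sum to one, the result is the
#' data-size-weighted average of the client models; with equal shards it is
#' their plain mean. Summation runs in list (client-id) order so the
#' aggregate is bit-reproducible.
#'
#' @param scaled_params_list non-empty list of shape-compatible
#'   `model_params`, each already multiplied by its client's factor via
#'   [scale_model()].
#' @return the aggregated `model_params`.
#' @export
fedavg <- function(scaled_params_list) {
  if (length(scaled_params_list) == 0L) stop("no client models to average")
  ref <- scaled_params_list[[1L]]
  for (j in seq_along(scaled_params_list)[-1L]) {
    p <- scaled_params_list[[j]]
    for (nm in names(ref)) {
      if (!identical(dim0(ref[[nm]]), dim0(p[[nm]]))) {
        stop("shape mismatch in tensor '", nm, "' of client model ", j)
      }
    }
  }
  out <- ref
  for (j in seq_along(scaled_params_list)[-1L]) {
    p <- scaled_params_list[[j]]
    for (nm in names(out)) out[[nm]] <- out[[nm]] + p[[nm]]
  }
  out
}

# dim() that also covers plain vectors
dim0 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Write a shard audit manifest
#'
#' @param shards list of shards from [create_shards()].
#' @param path CSV output path; columns `client_id,index,class`.
#' @return the path, invisibly.
#' @export
write_shard_manifest <- function(shards, path) {
  df <- do.call(rbind, lapply(shards, function(s) {
    data.frame(client_id = s$client_id,
               index = seq_along(s$data$labels),
               class = s$data$labels)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
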