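#' Evaluate a global model on the central test set
#'
#' Accuracy is the fraction of test images whose argmax-probability
#' prediction matches the label, with ties broken toward the earlier class
#' index (so a freshly initialized model, which emits exactly uniform
#' probabilities, predicts the first vocabulary class everywhere and
#' scores the base rate of that class — 0.5 on a balanced set, with loss
#' exactly `log(2)`). Loss is the mean categorical cross-entropy.
#'
#' @param params `model_params`.
#' @param test a non-empty [labelled_dataset()] or pre-flattened
#'   `list(x, y)`.
#' @return list with `accuracy` and `loss`.
#' @export
evaluate_global <- function(params, test) {
  tensors <- shard_tensors(test)
  if (nrow(tensors$x) == 0L) stop("empty test set")
  p <- mlp_forward(params, tensors$x)
  pred <- max.col(p, ties.method = "first")
  truth <- max.col(tensors$y, ties.method = "first")
  list(accuracy = mean(pred == truth),
       loss = cross_entropy(p, tensors$y))
}

#' Deterministic per-client, per-round seed stream
#'
#' Clients must be decorrelated across rounds yet fully reproducible, so
#' each (round, client) pair gets its own seed derived arithmetically from
#' the master seed. Exported as part of the reproducibility contract: an
#' independent re-execution of any single client's local update only needs
#' this derivation.
#'
#' @param seed master seed from the config.
#' @param round communication round, 1-based.
#' @param client client index, 1-based.
#' @return an integer seed below 2^31.
#' @export
client_round_seed <- function(seed, round, client) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(round) +
                10007 * as.numeric(client)) %% 2147483647)
}

#' Run the federated training loop
#'
#' The server-side algorithm. The training data is sharded once across
#' `cfg$n_clients` clients; then for each of `cfg$rounds` rounds every
#' client downloads the current global parameters, runs a [local_update()]
#' on its private shard, and returns its best local model; the server
#' scales each returned model by the client's data-proportional factor,
#' sums them (FedAvg), evaluates the new global model on the central test
#' set, and logs a round record (accuracy, loss, wall time). After the
#' last round the optimal model `w_star` is the round with minimal global
#' loss ([select_optimal()]). Clients run sequentially in client-id order;
#' the aggregate is order-independent up to floating-point summation.
#' Per-round client models are released as soon as they are aggregated, so
#' at most `n_clients + 2` parameter sets are alive at any time; round
#' snapshots are kept only under `keep_round_params = TRUE`.
#'
#' @param train,test [labelled_dataset()]s, already normalized.
#' @param cfg a [fed_config()].
#' @param stop_at_accuracy optional early-stop threshold: the loop ends
#'   after the first round whose global accuracy reaches it (earlier
#'   rounds are unaffected).
#' @param keep_round_params keep every round's global parameters (memory
#'   heavy; for diagnostics only).
#' @param verbose print a line per round.
#' @return object of class `federated_result`: `history` (data frame with
#'   columns `round, global_accuracy, global_loss, wall_time_s`), `w_star`
#'   (`model_params`), `best_round`, `best_loss`, `cfg`, and optionally
#'   `round_params`.
#' @export
run_federated_training <- function(train, test, cfg,
                                   stop_at_accuracy = NULL,
                                   keep_round_params = FALSE,
                                   verbose = FALSE) {
  stopifnot(inherits(cfg, "fed_config"))
  shards <- create_shards(train, cfg$n_clients, seed = cfg$seed)
  factors <- scaling_factors(shards)
  shard_data <- lapply(shards, function(s) dataset_tensors(s$data))
  test_data <- shard_tensors(test)
  input_dim <- ncol(shard_data[[1L]]$x)
  n_classes <- ncol(shard_data[[1L]]$y)
  global <- init_mlp(input_dim, hidden = cfg$hidden,
                     n_classes = n_classes, seed = cfg$seed)
  history <- data.frame(round = integer(0), global_accuracy = numeric(0),
                        global_loss = numeric(0), wall_time_s = numeric(0))
  round_params <- if (keep_round_params) list() else NULL
  w_star <- global; best_loss <- Inf; best_round <- NA_integer_
  for (r in seq_len(cfg$rounds)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      scaled <- vector("list", cfg$n_clients)
      for (k in seq_len(cfg$n_clients)) {
        upd <- local_update(global, shard_data[[k]], cfg,
                            seed = client_round_seed(cfg$seed, r, k))
        scaled[[k]] <- scale_model(upd$params, factors[[k]])
        upd <- NULL   # release the unscaled client model
      }
      new_global <- fedavg(scaled)
      scaled <- NULL  # release per-round transients
      ev <- evaluate_global(new_global, test_data)
      list(global = new_global, ev = ev)
    }, error = function(e) {
      stop("federated round ", r, " failed: ", conditionMessage(e),
           call. = FALSE)
    })
    global <- res$global
    history[nrow(history) + 1L, ] <-
      list(r, res$ev$accuracy, res$ev$loss,
           proc.time()[["elapsed"]] - t0)
    if (res$ev$loss < best_loss) {
      best_loss <- res$ev$loss; best_round <- r; w_star <- global
    }
    if (keep_round_params) round_params[[r]] <- global
    if (verbose) {
      cat(sprintf("round %3d  accuracy %.4f  loss %.6f\n",
                  r, res$ev$accuracy, res$ev$loss))
    }
    if (!is.null(stop_at_accuracy) &&
        res$ev$accuracy >= stop_at_accuracy) break
  }
  out <- list(history = history, w_star = w_star,
              best_round = best_round, best_loss = best_loss, cfg = cfg)
  if (keep_round_params) out$round_params <- round_params
  structure(out, class = "federated_result")
}

#' @export
print.federated_result <- function(x, ...) {
  n <- nrow(x$history)
  cat("<federated_result> ", n, " rounds, ", x$cfg$n_clients,
      " clients\n  best round ", x$best_round, ": loss ",
      format(x$best_loss, digits = 6), ", accuracy ",
      format(x$history$global_accuracy[x$best_round], digits = 4),
      "\n  final round ", n, ": accuracy ",
      format(x$history$global_accuracy[n], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Select the optimal round by minimum global loss
#'
#' The argmin rule applied to the recorded history: the optimal global
#' model is the one from the round with the smallest test-set loss,
#' earliest round on ties.
#'
#' @param history data frame with columns `round` and `global_loss` (the
#'   `history` of a [run_federated_training()] result, or any injected
#'   record sequence).
#' @return the `round` value of the loss-minimizing record.
#' @export
select_optimal <- function(history) {
  if (is.null(nrow(history)) || nrow(history) == 0L) {
    stop("empty round history")
  }
  history$round[which.min(history$global_loss)]
}

#' Write round metrics to CSV
#'
#' Writes the full per-round table and a companion summary at every tenth
#' round (`<path stem>_summary.csv`), the granularity at which federated
#' runs are customarily reported.
#'
#' @param history non-empty round history data frame.
#' @param path output CSV with header
#'   `round,global_accuracy,global_loss,wall_time_s`.
#' @return the main path, invisibly.
#' @export
write_metrics <- function(history, path) {
  if (is.null(nrow(history)) || nrow(history) == 0L) {
    stop("empty round history")
  }
  cols <- c("round", "global_accuracy", "global_loss", "wall_time_s")
  stopifnot(all(cols %in% names(history)))
  utils::write.csv(format(history[cols], digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  every10 <- history[history$round %% 10L == 0L, cols]
  utils::write.csv(format(every10, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   sub("\\.csv$", "_summary.csv", path),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
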