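#' Federated learning configuration
#'
#' Defaults follow the study setting: 50 global rounds of 5 local epochs.
#'
#' @param n_rounds Global aggregation rounds.
#' @param local_epochs Client epochs per round.
#' @param seed Seed for global model initialization and per-client training
#'   streams.
#' @return An `fl_config` object.
#' @export
fl_config <- function(n_rounds = 50L, local_epochs = 5L, seed = 1L) {
  stopifnot(n_rounds >= 0L, local_epochs >= 1L)
  structure(list(n_rounds = as.integer(n_rounds),
                 local_epochs = as.integer(local_epochs),
                 seed = as.integer(seed)),
            class = "fl_config")
}

#' One client's contribution to an aggregation round
#'
#' @param client_id Client label.
#' @param params The client's trained `parameter_vector`.
#' @param n_samples Local training sample count (must be positive when
#'   `success`).
#' @param success Whether local training completed.
#' @return A `client_update` object.
#' @export
client_update <- function(client_id, params, n_samples, success = TRUE) {
  if (success && n_samples <= 0L) {
    stop("successful update requires a positive sample count", call. = FALSE)
  }
  structure(list(client_id = client_id, params = params,
                 n_samples = as.integer(n_samples), success = isTRUE(success)),
            class = "client_update")
}

#' Fault-tolerant federated averaging
#'
#' Element-wise weighted mean of the successful clients' parameter vectors,
#' weighted by local sample count; failed clients are excluded and the
#' weights renormalized over the survivors. Batch-norm running statistics
#' are averaged like weights.
#'
#' @param updates List of [client_update()]s.
#' @return The aggregated `parameter_vector`.
#' @export
fedavg_aggregate <- function(updates) {
  ok <- Filter(function(u) isTRUE(u$success), updates)
  if (length(ok) == 0L) {
    stop("aggregation failure: no successful client updates", call. = FALSE)
  }
  w <- vapply(ok, function(u) u$n_samples, numeric(1))
  w <- w / sum(w)
  ref <- unclass(ok[[1L]]$params)
  agg <- lapply(ref, function(a) a * w[1L])
  for (k in seq_along(ok)[-1L]) {
    pk <- unclass(ok[[k]]$params)
    if (!identical(names(pk), names(ref))) {
      stop("client parameter vectors are not aligned", call. = FALSE)
    }
    for (nm in names(agg)) agg[[nm]] <- agg[[nm]] + pk[[nm]] * w[k]
  }
  structure(agg, class = "parameter_vector")
}

client_train_seed <- function(seed, i) as.integer((seed + 7919 * i) %% 2147483629)

#' Run a federated training simulation
#'
#' Implements the client-server loop: each round the current global
#' parameters are broadcast to every client, each client trains
#' `local_epochs` epochs on its own data (Adam, cross entropy; optimizer
#' state is client-local and reset each round), updates are collected and
#' aggregated by [fedavg_aggregate()]. A client whose local training raises
#' an error contributes a failed update (fault tolerance); a round with no
#' surviving update aborts the run. Clients run sequentially in-process;
#' results are independent of client order.
#'
#' @param spec A [model_spec()].
#' @param clients List of clients, each a list with `data` (a
#'   `ceph_dataset`), optional `id` and optional `seed` (defaults derive
#'   deterministically from `cfg$seed` and the client index).
#' @param cfg An [fl_config()].
#' @param train A [train_config()] for the local steps (its `epochs` and
#'   `seed` are overridden per round/client).
#' @param eval_data Optional `ceph_dataset` evaluated with the aggregated
#'   model every `eval_every` rounds (accuracy logged).
#' @param eval_every Evaluation cadence in rounds (0 disables).
#' @param init_params Optional starting `parameter_vector` (defaults to a
#'   fresh [build_model()] with `cfg$seed`).
#' @return An `fl_result`: list with `params` (final global
#'   `parameter_vector`), `model`, `rounds` (one tibble row per completed
#'   round), `spec`, `cfg`.
#' @export
run_federated <- function(spec, clients, cfg = fl_config(),
                          train = train_config(), eval_data = NULL,
                          eval_every = 1L, init_params = NULL) {
  if (length(clients) == 0L) stop("at least one client required", call. = FALSE)
  for (cl in clients) {
    if (is.null(cl$data) || length(cl$data$y) == 0L) {
      stop("every client needs nonempty data", call. = FALSE)
    }
  }
  global_model <- build_model(spec, seed = cfg$seed)
  if (!is.null(init_params)) global_model <- set_parameters(global_model, init_params)
  logs <- list()
  for (r in seq_len(cfg$n_rounds)) {
    gparams <- get_parameters(global_model)
    updates <- vector("list", length(clients))
    losses <- rep(NA_real_, length(clients))
    for (i in seq_along(clients)) {
      cl <- clients[[i]]
      cid <- cl$id %||% paste0("client", i)
      tc <- train
      tc$epochs <- cfg$local_epochs
      tc$seed <- cl$seed %||% client_train_seed(cfg$seed, i)
      res <- tryCatch(
        train_model(set_parameters(global_model, gparams), cl$data, tc,
                    epoch_offset = (r - 1L) * cfg$local_epochs),
        error = function(e) e)
      if (inherits(res, "error")) {
        updates[[i]] <- client_update(cid, NULL, 0L, success = FALSE)
      } else {
        updates[[i]] <- client_update(cid, get_parameters(res$model),
                                      length(cl$data$y))
        losses[i] <- utils::tail(res$history$loss, 1L)
      }
    }
    agg <- fedavg_aggregate(updates)
    global_model <- set_parameters(global_model, agg)
    acc <- NA_real_
    if (!is.null(eval_data) && eval_every > 0L &&
        (r %% eval_every == 0L || r == cfg$n_rounds)) {
      acc <- evaluate_model(global_model, eval_data)$accuracy
    }
    logs[[r]] <- tibble::tibble(
      round = r,
      client_id = vapply(seq_along(clients), function(i)
        clients[[i]]$id %||% paste0("client", i), character(1)),
      train_loss = losses,
      success = vapply(updates, function(u) u$success, logical(1)),
      global_accuracy = acc)
  }
  structure(list(params = get_parameters(global_model), model = global_model,
                 rounds = if (length(logs)) dplyr::bind_rows(logs)
                          else tibble::tibble(round = integer(), client_id = character(),
                                              train_loss = numeric(), success = logical(),
                                              global_accuracy = numeric()),
                 spec = spec, cfg = cfg),
            class = "fl_result")
}

#' @export
print.fl_result <- function(x, ...) {
  cat(sprintf("<fl_result> %d round(s), %d client(s), head=%s\n",
              x$cfg$n_rounds, length(unique(x$rounds$client_id)), x$spec$head))
  if (nrow(x$rounds)) {
    last <- x$rounds[x$rounds$round == max(x$rounds$round), ]
    if (any(is.finite(last$global_accuracy))) {
      cat(sprintf("  final global accuracy: %.4f\n", last$global_accuracy[1L]))
    }
  }
  invisible(x)
}

#' Write a federated round log as JSON lines
#'
#' One JSON record per round with per-client training losses and the
#' logged global accuracy.
#'
#' @param result An `fl_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_round_log <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in unique(result$rounds$round)) {
    block <- result$rounds[result$rounds$round == r, ]
    rec <- list(round = r,
                train_loss = stats::setNames(as.list(block$train_loss),
                                             block$client_id),
                global_accuracy = block$global_accuracy[1L])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
  invisible(path)
}
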