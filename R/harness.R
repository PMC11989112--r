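#' Configuration of a comparison setting
#'
#' Three settings compare how two imaging sites can share knowledge:
#'
#' * `"ll"` (local learning): each client trains its own model on its own
#'   training data; every model is evaluated on the merged test pool.
#' * `"cl"` (centralized learning): one model trains on the merged training
#'   pools and is evaluated on the merged test pool.
#' * `"fl"` (federated learning): [run_federated()] rounds over the clients;
#'   the global model is evaluated on the merged test pool (per-client test
#'   breakdowns are also reported).
#'
#' @param setting `"ll"`, `"cl"` or `"fl"`.
#' @param spec A [model_spec()].
#' @param epochs Local/centralized training epochs (default 100; ignored
#'   for `"fl"`, which uses `fl$n_rounds * fl$local_epochs`).
#' @param train A [train_config()] template (its `epochs`/`seed` fields are
#'   managed by the harness).
#' @param fl An [fl_config()] (federated setting only).
#' @param seed Master seed.
#' @return A `setting_config`.
#' @export
setting_config <- function(setting = c("ll", "cl", "fl"), spec = model_spec(),
                           epochs = 100L, train = train_config(),
                           fl = fl_config(), seed = 1L) {
  setting <- match.arg(setting)
  structure(list(setting = setting, spec = spec, epochs = as.integer(epochs),
                 train = train, fl = fl, seed = as.integer(seed)),
            class = "setting_config")
}

#' Run one comparison setting on a two-client dataset
#'
#' @param cfg A [setting_config()].
#' @param data Named list of clients, each a list with `train` and `test`
#'   `ceph_dataset`s (any number of clients; the study scenario uses two).
#' @return A `setting_result`: list with `setting`, `reports` (named list of
#'   `metrics_report`s -- one per client for `"ll"`, one `"merged"` report for
#'   `"cl"`/`"fl"`), `per_client_test` (federated breakdown), `models`, and
#'   for `"fl"` the underlying `fl_result`.
#' @export
run_setting <- function(cfg, data) {
  stopifnot(inherits(cfg, "setting_config"))
  if (length(data) == 0L) stop("no clients supplied", call. = FALSE)
  for (cl in data) {
    if (is.null(cl$train) || is.null(cl$test) ||
        length(cl$train$y) == 0L || length(cl$test$y) == 0L) {
      stop("every client needs nonempty train and test splits", call. = FALSE)
    }
  }
  ids <- names(data) %||% paste0("client", seq_along(data))
  merged_test <- merge_datasets(lapply(data, `[[`, "test"))
  out <- list(setting = cfg$setting)

  if (cfg$setting == "ll") {
    reports <- list()
    models <- list()
    for (i in seq_along(data)) {
      tc <- cfg$train
      tc$epochs <- cfg$epochs
      tc$seed <- client_train_seed(cfg$seed, i)
      model <- build_model(cfg$spec, seed = cfg$seed)
      if (cfg$epochs > 0L) model <- train_model(model, data[[i]]$train, tc)$model
      reports[[ids[i]]] <- evaluate_model(model, merged_test)
      models[[ids[i]]] <- model
    }
    out$reports <- reports
    out$models <- models
  } else if (cfg$setting == "cl") {
    tc <- cfg$train
    tc$epochs <- cfg$epochs
    tc$seed <- cfg$seed
    merged_train <- merge_datasets(lapply(data, `[[`, "train"))
    model <- build_model(cfg$spec, seed = cfg$seed)
    if (cfg$epochs > 0L) model <- train_model(model, merged_train, tc)$model
    out$reports <- list(merged = evaluate_model(model, merged_test))
    out$models <- list(merged = model)
  } else {
    clients <- lapply(seq_along(data), function(i)
      list(id = ids[i], data = data[[i]]$train))
    fl_cfg <- cfg$fl
    fl_cfg$seed <- cfg$seed
    fl <- run_federated(cfg$spec, clients, fl_cfg, train = cfg$train,
                        eval_data = merged_test, eval_every = 1L)
    out$reports <- list(merged = evaluate_model(fl$model, merged_test))
    out$per_client_test <- stats::setNames(
      lapply(data, function(cl) evaluate_model(fl$model, cl$test)), ids)
    out$models <- list(merged = fl$model)
    out$fl <- fl
  }
  structure(out, class = "setting_result")
}

#' @export
print.setting_result <- function(x, ...) {
  cat(sprintf("<setting_result: %s>\n", toupper(x$setting)))
  for (nm in names(x$reports)) {
    cat(sprintf("  %s: accuracy %.4f\n", nm, x$reports[[nm]]$accuracy))
  }
  invisible(x)
}

#' Federated contribution/sacrifice deltas
#'
#' Builds the accuracy-delta table comparing federated learning with local
#' and centralized learning: `FL - LL` per client (the contribution of
#' federation to that site) and `CL - FL` on the merged test set (the
#' sacrifice of federation versus pooling the data; negative means FL beat
#' CL). All deltas are plain differences on the \[0, 1\] accuracy scale.
#'
#' @param ll Named numeric vector of per-client LL accuracies.
#' @param cl CL accuracy (merged).
#' @param fl FL accuracy (merged).
#' @param model Optional model label carried into the output.
#' @return Tibble with columns `model`, `comparison`, `client`, `delta`.
#' @examples
#' contribution_table(ll = c(dicle = 0.7084, isbi = 0.5935),
#'                    cl = 0.7345, fl = 0.7457)
#' @export
contribution_table <- function(ll, cl, fl, model = NA_character_) {
  stopifnot(all(ll >= 0 & ll <= 1), cl >= 0, cl <= 1, fl >= 0, fl <= 1)
  clients <- names(ll) %||% paste0("client", seq_along(ll))
  dplyr::bind_rows(
    tibble::tibble(model = model, comparison = "fl_vs_ll", client = clients,
                   delta = unname(fl - ll)),
    tibble::tibble(model = model, comparison = "cl_vs_fl", client = "merged",
                   delta = cl - fl))
}

#' Plot federated round convergence
#'
#' @param object An `fl_result` with logged global accuracies.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fl_result
#' @export
autoplot.fl_result <- function(object, ...) {
  df <- unique(object$rounds[, c("round", "global_accuracy")])
  df <- df[is.finite(df$global_accuracy), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$round, y = .data$global_accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Federated round", y = "Global accuracy") +
    ggplot2::theme_minimal()
}

#' Tidy / summarize a federated run
#'
#' @param x An `fl_result`.
#' @param ... Unused.
#' @return `tidy()`: the per-round, per-client log tibble; `glance()`: a
#'   one-row summary.
#' @method tidy fl_result
#' @export
tidy.fl_result <- function(x, ...) x$rounds

#' @rdname tidy.fl_result
#' @method glance fl_result
#' @export
glance.fl_result <- function(x, ...) {
  acc <- x$rounds$global_accuracy[is.finite(x$rounds$global_accuracy)]
  tibble::tibble(n_rounds = x$cfg$n_rounds,
                 local_epochs = x$cfg$local_epochs,
                 final_accuracy = if (length(acc)) utils::tail(acc, 1L) else NA_real_,
                 best_accuracy = if (length(acc)) max(acc) else NA_real_)
}
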