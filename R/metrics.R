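#' Multiclass evaluation metrics
#'
#' Computes the evaluation panel for one model evaluation: accuracy,
#' support-weighted one-vs-rest precision/recall/F1, Cohen's kappa, the
#' unweighted mean of the per-class one-vs-rest AUCs (ties counted 1/2,
#' i.e. the Mann-Whitney ranking probability), and the confusion matrix
#' (rows = true classes).
#'
#' A class absent from `y_true` has no defined AUC and is excluded from the
#' AUC mean with a warning. If expected chance agreement equals 1, kappa is
#' defined as 1 for perfect agreement and 0 otherwise, with a warning.
#'
#' @param y_true True classes: 0-based indices, 1-based codes are not
#'   accepted; roman labels `"I"/"II"/"III"` are.
#' @param y_score Numeric matrix `n x k` of per-class scores (higher =
#'   more confident); predictions are the row-wise argmax.
#' @param n_classes Number of classes (default: columns of `y_score`).
#' @return A `metrics_report`: list with `accuracy`, `precision`, `recall`,
#'   `f1`, `kappa`, `auc`, `confusion`, `per_class` (tibble), `n`.
#' @export
compute_metrics <- function(y_true, y_score, n_classes = ncol(y_score)) {
  if (is.character(y_true) || is.factor(y_true)) {
    y_true <- class_target_index(as.character(y_true))
  }
  y_true <- as.integer(y_true)
  if (is.null(dim(y_score))) y_score <- matrix(y_score, nrow = length(y_score))
  n <- length(y_true)
  stopifnot(n >= 1L, nrow(y_score) == n, all(is.finite(y_score)),
            all(y_true >= 0L & y_true < n_classes))
  pred <- max.col(y_score, ties.method = "first") - 1L

  k <- n_classes
  confusion <- matrix(0L, k, k,
                      dimnames = list(true = as.character(seq_len(k) - 1L),
                                      pred = as.character(seq_len(k) - 1L)))
  for (i in seq_len(n)) {
    confusion[y_true[i] + 1L, pred[i] + 1L] <- confusion[y_true[i] + 1L, pred[i] + 1L] + 1L
  }
  support <- rowSums(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- support - tp
  prec_k <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec_k <- ifelse(support > 0, tp / (tp + fn), 0)
  f1_k <- ifelse(prec_k + rec_k > 0, 2 * prec_k * rec_k / (prec_k + rec_k), 0)
  wts <- support / n
  accuracy <- sum(tp) / n

  # Cohen's kappa with chance agreement from marginal products
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe >= 1) {
    warning("chance agreement is 1; kappa set to ", if (accuracy == 1) 1 else 0)
    kappa <- if (accuracy == 1) 1 else 0
  } else {
    kappa <- (accuracy - pe) / (1 - pe)
  }

  auc_k <- rep(NA_real_, k)
  for (c in seq_len(k)) {
    pos <- y_true == c - 1L
    n1 <- sum(pos); n0 <- n - n1
    if (n1 == 0L || n0 == 0L) next
    r <- rank(y_score[, c], ties.method = "average")
    auc_k[c] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  if (anyNA(auc_k)) {
    warning(sprintf("one-vs-rest AUC undefined for class(es) %s (absent); excluded from mean",
                    paste(which(is.na(auc_k)) - 1L, collapse = ", ")))
  }

  structure(list(
    accuracy = accuracy,
    precision = sum(wts * prec_k),
    recall = sum(wts * rec_k),
    f1 = sum(wts * f1_k),
    kappa = kappa,
    auc = mean(auc_k, na.rm = TRUE),
    confusion = confusion,
    per_class = tibble::tibble(class = class_label(seq_len(k) - 1L, from = "index"),
                               support = as.integer(support),
                               precision = prec_k, recall = rec_k, f1 = f1_k,
                               auc = auc_k),
    n = n), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n=%d  acc=%.4f  P=%.4f  R=%.4f  F1=%.4f  kappa=%.4f  AUC=%.4f\n",
    x$n, x$accuracy, x$precision, x$recall, x$f1, x$kappa, x$auc))
  print(x$confusion)
  invisible(x)
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return `tidy()`: the per-class tibble; `glance()`: a one-row tibble of
#'   the summary metrics.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @rdname tidy.metrics_report
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, precision = x$precision,
                 recall = x$recall, f1 = x$f1, kappa = x$kappa,
                 auc = x$auc, n = x$n)
}

#' Write a metrics report as JSON (confusion matrix also as CSV)
#'
#' @param report A `metrics_report`.
#' @param path JSON output path; the confusion matrix goes to the same path
#'   with extension `.confusion.csv`.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(
    list(accuracy = report$accuracy, precision = report$precision,
         recall = report$recall, f1 = report$f1, kappa = report$kappa,
         auc = report$auc, n = report$n,
         confusion = unname(apply(report$confusion, 1L, as.list, simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(report$confusion),
                   sub("\\.json$", ".confusion.csv", path))
  invisible(path)
}

#' Plot a metrics report as a confusion-matrix heatmap
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "pred", "n")
  df$true <- class_label(as.integer(as.character(df$true)), from = "index")
  df$pred <- class_label(as.integer(as.character(df$pred)), from = "index")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(skeletal_levels())) +
    ggplot2::labs(x = "Predicted class", y = "True class",
                  title = sprintf("Accuracy %.3f, kappa %.3f",
                                  object$accuracy, object$kappa)) +
    ggplot2::theme_minimal()
}
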