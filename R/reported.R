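# Bundled benchmark tables from the published two-clinic cephalometric
# study (Dicle and ISBI sites): best-run accuracies of the six DenseNet121
# variants under the centralized (cl), local (ll) and federated (fl)
# settings, and the printed contribution/sacrifice deltas. They serve as a
# regression fixture for the delta arithmetic and for the augmented-model
# gain bounds.

#' Published benchmark accuracies and contribution deltas
#'
#' `reported_accuracies()` returns the bundled accuracy table of the
#' two-clinic benchmark (columns `model`, `setting` in cl/ll/fl, `dataset`
#' in dicle/isbi/merged, `accuracy`). `reported_contribution_cells()`
#' returns the deltas as printed in the benchmark's contribution table.
#' `reported_contributions()` recomputes the deltas from the accuracies via
#' [contribution_table()].
#'
#' @return A tibble.
#' @export
reported_accuracies <- function() {
  path <- system.file("extdata", "reported_accuracies.csv", package = "fedceph",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname reported_accuracies
#' @export
reported_contribution_cells <- function() {
  path <- system.file("extdata", "reported_contributions.csv", package = "fedceph",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname reported_accuracies
#' @export
reported_contributions <- function() {
  acc <- reported_accuracies()
  dplyr::bind_rows(lapply(unique(acc$model), function(m) {
    a <- acc[acc$model == m, ]
    ll <- stats::setNames(a$accuracy[a$setting == "ll"], a$dataset[a$setting == "ll"])
    contribution_table(ll = ll,
                       cl = a$accuracy[a$setting == "cl"],
                       fl = a$accuracy[a$setting == "fl"],
                       model = m)
  }))
}

#' Minimum accuracy gain of the augmented models over the baseline
#'
#' For a given setting, the smallest accuracy improvement of any augmented
#' DenseNet121 variant over the plain DenseNet121 baseline, in percentage
#' points, computed from the bundled benchmark accuracies.
#'
#' @param setting `"fl"` or `"cl"`.
#' @return A single number (percentage points).
#' @export
reported_min_augmented_gain <- function(setting = c("fl", "cl")) {
  setting <- match.arg(setting)
  acc <- reported_accuracies()
  a <- acc[acc$setting == setting, ]
  base <- a$accuracy[a$model == "densenet121"]
  aug <- a$accuracy[a$model != "densenet121"]
  100 * min(aug - base)
}
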