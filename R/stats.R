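#' Paired t test on cross-validation results
#'
#' Two-sided paired Student t test on the element-wise differences
#' `a - b` (e.g. per-fold accuracies of two settings). Degenerate inputs are
#' flagged rather than erroring: all-zero differences give `t = 0, p = 1`;
#' zero-variance nonzero-mean differences give a divergent t (signed `Inf`)
#' with `p = 0` and `degenerate = TRUE`.
#'
#' @param a,b Paired numeric samples of equal length `n >= 2`.
#' @return One-row tibble: `mean_diff`, `t`, `df`, `p_value`, `degenerate`.
#' @examples
#' paired_ttest(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  d <- a - b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble::tibble(mean_diff = 0, t = 0, df = n - 1L, p_value = 1,
                            degenerate = TRUE))
    }
    return(tibble::tibble(mean_diff = mean(d), t = sign(mean(d)) * Inf,
                          df = n - 1L, p_value = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(mean_diff = unname(ht$estimate), t = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 degenerate = FALSE)
}

#' Shapiro-Wilk normality test
#'
#' Standard W statistic and p value (Royston's approximation, via
#' `stats::shapiro.test()`). Constant samples have undefined W and are
#' returned with `degenerate = TRUE` and `NA` statistics.
#'
#' @param x Numeric sample, `3 <= n <= 5000`.
#' @return One-row tibble: `W`, `p_value`, `n`, `degenerate`.
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3L || n > 5000L) {
    stop(sprintf("sample size %d unsupported (need 3 <= n <= 5000)", n),
         call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    return(tibble::tibble(W = NA_real_, p_value = NA_real_, n = n,
                          degenerate = TRUE))
  }
  ht <- stats::shapiro.test(x)
  tibble::tibble(W = unname(ht$statistic), p_value = ht$p.value, n = n,
                 degenerate = FALSE)
}

#' Stratified k-fold split of a labeled manifest
#'
#' Partitions rows into `k` folds with per-class proportions within one
#' sample of the global proportions, deterministically for a given seed.
#'
#' @param manifest Data frame with a class column.
#' @param k Number of folds.
#' @param class_col Name of the class column.
#' @param seed Shuffle seed.
#' @return The manifest with an integer `fold` column in `1..k`.
#' @export
kfold_split <- function(manifest, k = 5L, class_col = "class", seed = 1L) {
  cls <- manifest[[class_col]]
  if (is.null(cls)) stop(sprintf("no '%s' column", class_col), call. = FALSE)
  tab <- table(cls)
  small <- names(tab)[tab < k]
  if (length(small)) {
    stop(sprintf("class(es) %s have fewer than k=%d members; cannot stratify",
                 paste(small, collapse = ", "), k), call. = FALSE)
  }
  fold <- integer(nrow(manifest))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(cls == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  manifest$fold <- fold
  manifest
}
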