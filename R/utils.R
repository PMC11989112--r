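sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Validate a channels x height x width feature map.
check_feature_map <- function(F, arg = "F") {
  if (!is.array(F) || length(dim(F)) != 3L) {
    stop(sprintf("`%s` must be a 3-d array (channels x height x width)", arg),
         call. = FALSE)
  }
  if (any(dim(F) < 1L) || any(!is.finite(F))) {
    stop(sprintf("`%s` must have positive dimensions and finite entries", arg),
         call. = FALSE)
  }
  invisible(F)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
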