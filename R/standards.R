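#' ANB-angle threshold standards
#'
#' A threshold standard maps the ANB angle (degrees) to a skeletal class.
#' The Class I band `[class1_low, class1_high]` is closed at both ends;
#' angles strictly above the band are Class II, strictly below are Class III.
#'
#' Two standards are bundled: `"steiner"` (Class I band 3.2--5.7 degrees,
#' conventionally used for the ISBI cephalogram dataset) and `"kim"`
#' (Class I band 0--4 degrees, used for the Dicle dataset).
#'
#' @param name Label for the standard (e.g. `"steiner"`, `"kim"`).
#' @param class1_low,class1_high Closed Class I band endpoints in degrees;
#'   `class1_low < class1_high` is required.
#' @return A `threshold_standard` object.
#' @examples
#' threshold_standard("kim", 0, 4)
#' lookup_standard("steiner")
#' @export
threshold_standard <- function(name, class1_low, class1_high) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(class1_low), is.numeric(class1_high),
            is.finite(class1_low), is.finite(class1_high))
  if (!(class1_low < class1_high)) {
    stop("`class1_low` must be strictly less than `class1_high`", call. = FALSE)
  }
  structure(
    list(name = name, class1_low = as.numeric(class1_low),
         class1_high = as.numeric(class1_high)),
    class = "threshold_standard"
  )
}

#' @export
print.threshold_standard <- function(x, ...) {
  cat(sprintf("<threshold_standard: %s>  Class I: [%g, %g] deg; II > %g; III < %g\n",
              x$name, x$class1_low, x$class1_high, x$class1_high, x$class1_low))
  invisible(x)
}

#' @rdname threshold_standard
#' @export
lookup_standard <- function(name) {
  switch(tolower(name),
    steiner = threshold_standard("steiner", 3.2, 5.7),
    kim     = threshold_standard("kim", 0, 4),
    stop(sprintf("unknown threshold standard '%s' (bundled: 'steiner', 'kim')", name),
         call. = FALSE)
  )
}

# Coerce a standard given as object or bundled name.
as_standard <- function(standard) {
  if (inherits(standard, "threshold_standard")) return(standard)
  if (is.character(standard) && length(standard) == 1L) return(lookup_standard(standard))
  stop("`standard` must be a threshold_standard or a bundled standard name",
       call. = FALSE)
}

#' Skeletal class labels and codes
#'
#' Skeletal classes use roman labels `"I"`, `"II"`, `"III"` with stable
#' integer codes 1/2/3 and zero-based model-target indices 0/1/2.
#'
#' @param x A vector of roman labels, integer codes, or target indices.
#' @return `skeletal_levels()` returns the ordered labels;
#'   `class_code()` integer codes; `class_target_index()` 0-based indices;
#'   `class_label()` roman labels from either coding.
#' @examples
#' class_code(c("I", "III"))
#' class_label(c(0, 2), from = "index")
#' @export
skeletal_levels <- function() c("I", "II", "III")

#' @rdname skeletal_levels
#' @export
class_code <- function(x) {
  i <- match(as.character(x), skeletal_levels())
  if (anyNA(i) && !anyNA(x)) stop("invalid skeletal class label", call. = FALSE)
  i
}

#' @rdname skeletal_levels
#' @export
class_target_index <- function(x) class_code(x) - 1L

#' @rdname skeletal_levels
#' @param from Either `"code"` (1/2/3) or `"index"` (0/1/2).
#' @export
class_label <- function(x, from = c("code", "index")) {
  from <- match.arg(from)
  i <- as.integer(x) + if (from == "index") 1L else 0L
  if (any(!is.na(i) & (i < 1L | i > 3L))) stop("invalid skeletal class code", call. = FALSE)
  skeletal_levels()[i]
}

#' Classify an ANB angle into skeletal class I/II/III
#'
#' Total on finite angles: Class I iff the angle lies in the closed band
#' `[class1_low, class1_high]`, Class II iff strictly above, Class III iff
#' strictly below.
#'
#' @param angle Numeric vector of ANB angles in degrees.
#' @param standard A [threshold_standard()] or bundled name (`"kim"`,
#'   `"steiner"`).
#' @return Character vector of `"I"`, `"II"`, `"III"`.
#' @examples
#' classify_skeletal(5.6, "kim")      # "II"
#' classify_skeletal(3.2, "steiner")  # "I" (band endpoints included)
#' @export
classify_skeletal <- function(angle, standard) {
  standard <- as_standard(standard)
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("`angle` must be finite numeric", call. = FALSE)
  }
  out <- rep("I", length(angle))
  out[angle > standard$class1_high] <- "II"
  out[angle < standard$class1_low] <- "III"
  out
}
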