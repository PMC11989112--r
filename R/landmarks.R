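#' Parse a landmark annotation file
#'
#' Annotation files hold one point per line as `"x,y"` (whitespace separators
#' are tolerated). In the 19-landmark layout used by the ISBI cephalogram
#' annotations, A-point, nasion and B-point are the 5th, 2nd and 6th lines;
#' in the compact 3-point layout the order is fixed as A, N, B. Lines after
#' the first `expected_n` are ignored.
#'
#' @param file Path to an annotation file, a single string of file content,
#'   or a character vector of lines.
#' @param expected_n Number of landmarks to read (3 or 19, typically).
#' @return A `landmark_set`: a tibble with columns `x`, `y` and
#'   `expected_n` rows, in file order.
#' @examples
#' parse_landmark_file("10,20\n30,40\n50,60", expected_n = 3)
#' @export
parse_landmark_file <- function(file, expected_n = 19L) {
  stopifnot(is.character(file), length(file) >= 1L)
  lines <- if (length(file) == 1L) {
    if (!grepl("[\n,]", file) && file.exists(file)) readLines(file, warn = FALSE)
    else strsplit(file, "\n", fixed = TRUE)[[1L]]
  } else file
  expected_n <- as.integer(expected_n)
  lines <- lines[seq_len(min(length(lines), expected_n))]
  nonblank <- trimws(lines)
  if (length(lines) < expected_n) {
    stop(sprintf("landmark file truncated: %d parseable line(s), expected %d",
                 length(lines), expected_n), call. = FALSE)
  }
  xs <- ys <- numeric(expected_n)
  for (i in seq_len(expected_n)) {
    fields <- strsplit(nonblank[i], "[,[:space:]]+")[[1L]]
    fields <- fields[nzchar(fields)]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || anyNA(vals[1:2]) || !all(is.finite(vals[1:2]))) {
      stop(sprintf("malformed coordinate at line %d: '%s'", i, lines[i]),
           call. = FALSE)
    }
    xs[i] <- vals[1L]; ys[i] <- vals[2L]
  }
  structure(tibble::tibble(x = xs, y = ys),
            class = c("landmark_set", class(tibble::tibble())))
}

# Landmark slots of the 19-point ISBI layout.
ANB_SLOTS_19 <- c(A = 5L, N = 2L, B = 6L)

#' Extract the A, N and B points from a landmark set
#'
#' @param lms A `landmark_set` (see [parse_landmark_file()]), or any
#'   data frame with `x`, `y` columns and 3 or 19 rows.
#' @return Named list of numeric `c(x, y)` pairs `A`, `N`, `B`.
#' @export
anb_points <- function(lms) {
  n <- nrow(lms)
  idx <- if (n >= 19L) ANB_SLOTS_19 else if (n == 3L) c(A = 1L, N = 2L, B = 3L)
         else stop(sprintf("landmark set has %d points; need 3 or 19", n), call. = FALSE)
  lapply(as.list(idx), function(i) c(x = lms$x[i], y = lms$y[i]))
}

#' Signed ANB angle at nasion
#'
#' Returns the signed angle, in degrees, from ray N->B to ray N->A,
#' counter-clockwise positive in an x-right/y-up frame. With
#' `y_axis = "down"` (the image pixel convention, the default) the y
#' components are negated before the computation. The magnitude equals the
#' unsigned angle at N; the sign is positive when A is anterior to B
#' (maxilla ahead of mandible) for a facing-right lateral view, so Class III
#' subjects yield negative angles.
#'
#' @param A,N,B Numeric length-2 points `c(x, y)` (A-point, nasion, B-point).
#' @param y_axis `"down"` for pixel coordinates (default) or `"up"`.
#' @return Angle in degrees, in (-180, 180].
#' @examples
#' compute_anb_angle(c(0, 1), c(0, 0), c(1, 0), y_axis = "up")  # +90
#' @export
compute_anb_angle <- function(A, N, B, y_axis = c("down", "up")) {
  y_axis <- match.arg(y_axis)
  A <- as.numeric(A); N <- as.numeric(N); B <- as.numeric(B)
  stopifnot(length(A) == 2L, length(N) == 2L, length(B) == 2L,
            all(is.finite(c(A, N, B))))
  if (y_axis == "down") {
    A[2L] <- -A[2L]; N[2L] <- -N[2L]; B[2L] <- -B[2L]
  }
  u <- A - N  # ray N->A
  v <- B - N  # ray N->B
  if (all(u == 0) || all(v == 0)) {
    stop("degenerate geometry: A or B coincides with N", call. = FALSE)
  }
  ang <- atan2(v[1L] * u[2L] - v[2L] * u[1L], sum(u * v)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Read or write a dataset manifest
#'
#' Manifests are CSV files with header
#' `image_path,landmark_path,client_id,class`; the `class` column is optional
#' before labeling. Extra columns (e.g. `split`, `anb`) round-trip.
#'
#' @param path CSV path.
#' @param manifest A manifest tibble.
#' @return `read_manifest()` returns a tibble; `write_manifest()` its input,
#'   invisibly.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = FALSE)
  required <- c("image_path", "landmark_path", "client_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("manifest missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$client_id <- as.character(df$client_id)
  tibble::as_tibble(df)
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  lead <- intersect(c("image_path", "landmark_path", "client_id", "class"),
                    names(manifest))
  manifest <- manifest[, c(lead, setdiff(names(manifest), lead))]
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

resolve_anb <- function(record, landmark_root = NULL) {
  cols <- c("a_x", "a_y", "n_x", "n_y", "b_x", "b_y")
  if (all(cols %in% names(record)) && all(is.finite(unlist(record[cols])))) {
    return(list(A = c(record$a_x, record$a_y),
                N = c(record$n_x, record$n_y),
                B = c(record$b_x, record$b_y)))
  }
  lp <- record$landmark_path
  if (is.null(lp) || is.na(lp) || !nzchar(lp)) {
    stop("record has neither inline A/N/B coordinates nor a landmark_path",
         call. = FALSE)
  }
  if (!is.null(landmark_root) && !file.exists(lp)) lp <- file.path(landmark_root, lp)
  n_lines <- length(readLines(lp, warn = FALSE))
  lms <- parse_landmark_file(lp, expected_n = if (n_lines >= 19L) 19L else 3L)
  anb_points(lms)
}

#' Label a manifest by ANB angle under per-client standards
#'
#' Resolves A/N/B for every record (inline `a_x ... b_y` columns or the
#' landmark file), computes the signed ANB angle in pixel (y-down)
#' coordinates, and assigns the skeletal class under that record's client
#' standard. Records whose landmarks cannot be resolved get `NA` class and
#' are collected into an error report; the run continues.
#'
#' @param manifest Manifest tibble (see [read_manifest()]).
#' @param standards Named list/character vector mapping every `client_id` to
#'   a [threshold_standard()] or bundled standard name.
#' @param landmark_root Optional directory prefixed to relative landmark
#'   paths.
#' @return The manifest with `anb` and `class` columns filled; failures (if
#'   any) in `attr(, "errors")`, a tibble with `row` and `message`.
#' @seealso [label_counts()] for the per-client count/proportion table.
#' @export
label_manifest <- function(manifest, standards, landmark_root = NULL) {
  if (nrow(manifest) == 0L) {
    manifest$anb <- numeric(0)
    manifest$class <- character(0)
    attr(manifest, "errors") <- tibble::tibble(row = integer(), message = character())
    return(manifest)
  }
  missing_std <- setdiff(unique(manifest$client_id), names(standards))
  if (length(missing_std)) {
    stop("no threshold standard for client(s): ",
         paste(missing_std, collapse = ", "), call. = FALSE)
  }
  stds <- lapply(standards, as_standard)
  anb <- rep(NA_real_, nrow(manifest))
  cls <- rep(NA_character_, nrow(manifest))
  errs <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    res <- tryCatch({
      pts <- resolve_anb(rec, landmark_root)
      a <- compute_anb_angle(pts$A, pts$N, pts$B, y_axis = "down")
      list(anb = a, class = classify_skeletal(a, stds[[rec$client_id]]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- tibble::tibble(row = i, message = conditionMessage(res))
    } else {
      anb[i] <- res$anb
      cls[i] <- res$class
    }
  }
  manifest$anb <- anb
  manifest$class <- cls
  attr(manifest, "errors") <-
    if (length(errs)) dplyr::bind_rows(errs)
    else tibble::tibble(row = integer(), message = character())
  manifest
}

#' Class counts and proportions of a labeled manifest
#'
#' @param manifest A labeled manifest (with a `class` column).
#' @param by_client Also include per-client rows (default `TRUE`).
#' @return Tibble with columns `client_id` (`"overall"` for the pooled row),
#'   `class`, `n`, `proportion`. Proportions are exact fractions; rounding is
#'   left to presentation.
#' @export
label_counts <- function(manifest, by_client = TRUE) {
  if (nrow(manifest) == 0L) {
    return(tibble::tibble(client_id = character(), class = character(),
                          n = integer(), proportion = numeric()))
  }
  count_block <- function(df, id) {
    n <- vapply(skeletal_levels(), function(k) sum(df$class == k, na.rm = TRUE),
                integer(1), USE.NAMES = FALSE)
    tibble::tibble(client_id = id, class = skeletal_levels(),
                   n = n, proportion = n / nrow(df))
  }
  out <- count_block(manifest, "overall")
  if (by_client) {
    per <- lapply(sort(unique(manifest$client_id)),
                  function(cid) count_block(manifest[manifest$client_id == cid, ], cid))
    out <- dplyr::bind_rows(dplyr::bind_rows(per), out)
  }
  out
}

#' Write a JSON labeling report
#'
#' Per-class counts and proportions per client and overall, as produced by
#' [label_counts()].
#'
#' @inheritParams label_counts
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_label_report <- function(manifest, path) {
  counts <- label_counts(manifest)
  errs <- attr(manifest, "errors")
  report <- list(
    total = nrow(manifest),
    clients = lapply(split(counts, counts$client_id), function(df) {
      list(n = sum(df$n),
           counts = stats::setNames(as.list(df$n), df$class),
           proportions = stats::setNames(as.list(df$proportion), df$class))
    }),
    n_errors = if (is.null(errs)) 0L else nrow(errs)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
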