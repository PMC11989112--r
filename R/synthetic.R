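#' Synthetic two-clinic cephalogram dataset configuration
#'
#' The generator emulates the structure of the two-site study scenario:
#' client "dicle" (856 images, class ratios 0.46/0.33/0.21, Kim labeling
#' standard) and client "isbi" (400 images, ratios 0.2/0.22/0.58, Steiner
#' standard). Generation is angle-first: a class-consistent ANB angle is
#' drawn, the A/N/B landmarks are solved to realize it exactly, and a
#' stylized lateral-cephalogram-like image is rendered in which the
#' mandibular contour's anterior position is a monotone function of the
#' angle, so the class is visually learnable.
#'
#' @param clients Named list; each client is a list with `n` (image count),
#'   `ratios` (length-3 class proportions summing to 1) and `standard`
#'   (a [threshold_standard()] or bundled name).
#' @param image_size Image side length in pixels (64 for desk-scale work,
#'   up to 224).
#' @param angle_jitter Pixel-scale placement noise of the landmarks (the
#'   realized angle is preserved exactly by re-solving A).
#' @param angle_clip Maximum |ANB| in degrees.
#' @param margin Degrees trimmed from each class-band boundary so placement
#'   jitter cannot cross classes.
#' @param render_noise Background noise amplitude in \[0, 1\].
#' @param test_fraction Held-out fraction of the stratified train/test split.
#' @param seed Master seed; identical configs generate identical datasets.
#' @return A `synth_config` object.
#' @export
synth_config <- function(clients = list(
                           dicle = list(n = 856L, ratios = c(0.46, 0.33, 0.21),
                                        standard = "kim"),
                           isbi = list(n = 400L, ratios = c(0.2, 0.22, 0.58),
                                       standard = "steiner")),
                         image_size = 64L, angle_jitter = 2,
                         angle_clip = 15, margin = 0.1,
                         render_noise = 0.05, test_fraction = 0.2,
                         seed = 1L) {
  stopifnot(length(clients) >= 1L, !is.null(names(clients)))
  for (nm in names(clients)) {
    cl <- clients[[nm]]
    stopifnot(cl$n >= 1L, length(cl$ratios) == 3L,
              abs(sum(cl$ratios) - 1) < 1e-8, all(cl$ratios >= 0))
    std <- as_standard(cl$standard)
    if (angle_clip <= max(abs(std$class1_low), abs(std$class1_high))) {
      stop("`angle_clip` must exceed the outer band thresholds of every standard",
           call. = FALSE)
    }
  }
  structure(list(clients = clients, image_size = as.integer(image_size),
                 angle_jitter = angle_jitter, angle_clip = angle_clip,
                 margin = margin, render_noise = render_noise,
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "synth_config")
}

#' Deterministic largest-remainder apportionment of class counts
#'
#' @param n Total count.
#' @param ratios Class proportions summing to 1.
#' @return Integer vector summing to `n` (ties broken by class order).
#' @examples
#' apportion_counts(100, c(0.46, 0.33, 0.21))  # 46 33 21
#' @export
apportion_counts <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- exact - base
    give <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

# Class band intersected with [-clip, clip], trimmed by `margin` at each
# class boundary.
class_band <- function(cls, standard, clip, margin = 0.1) {
  standard <- as_standard(standard)
  band <- switch(cls,
    I = c(standard$class1_low + margin, standard$class1_high - margin),
    II = c(standard$class1_high + margin, clip),
    III = c(-clip, standard$class1_low - margin),
    stop("unknown class ", cls, call. = FALSE))
  if (band[1L] >= band[2L]) {
    stop(sprintf("empty angle band for class %s under '%s' with clip %g",
                 cls, standard$name, clip), call. = FALSE)
  }
  band
}

#' Draw a class-consistent ANB angle
#'
#' Uniform draw from the class's angle band under the given standard,
#' intersected with `[-clip, clip]` and shrunk by `margin` degrees at each
#' boundary. Uses the current RNG stream.
#'
#' @param cls `"I"`, `"II"` or `"III"`.
#' @param standard A [threshold_standard()] or bundled name.
#' @param clip Maximum |angle| in degrees.
#' @param margin Boundary trim in degrees.
#' @return Angle in degrees.
#' @export
sample_angle <- function(cls, standard, clip = 15, margin = 0.1) {
  band <- class_band(cls, standard, clip, margin)
  stats::runif(1L, band[1L], band[2L])
}

#' Solve A/N/B landmark positions realizing an ANB angle
#'
#' Nasion is anchored in the upper-anterior region, B below it; A is placed
#' on the ray from N rotated by the requested angle from the N->B direction
#' (in the y-up frame), so that [compute_anb_angle()] with `y_axis = "down"`
#' reproduces the request to within 1e-9. Jitter perturbs N and B; A is
#' re-solved, preserving the angle exactly. Placement is retried (up to 100
#' times) until all points are at least 2 px inside the image.
#'
#' @param angle Requested signed ANB angle in degrees.
#' @param image_size Image side length in pixels.
#' @param jitter Gaussian placement noise (pixels).
#' @return List of pixel-coordinate points `A`, `N`, `B` (y down).
#' @export
place_landmarks <- function(angle, image_size, jitter = 2) {
  stopifnot(is.finite(angle))
  S <- image_size
  for (attempt in seq_len(100L)) {
    N <- c(0.62 * S + jitter * stats::rnorm(1L),
           0.28 * S + jitter * stats::rnorm(1L))
    L <- 0.45 * S * (1 + 0.05 * jitter / 2 * stats::rnorm(1L))
    phi <- -0.08 + 0.02 * jitter * stats::rnorm(1L)  # slight posterior lean
    B <- N + L * c(sin(phi), cos(phi))
    # y-up frame: direction N->B, rotated CCW by the requested angle
    v <- c(B[1L] - N[1L], -(B[2L] - N[2L]))
    v <- v / sqrt(sum(v^2))
    th <- angle * pi / 180
    vr <- c(cos(th) * v[1L] - sin(th) * v[2L],
            sin(th) * v[1L] + cos(th) * v[2L])
    r <- 0.38 * L
    A_up <- c(N[1L], -N[2L]) + r * vr
    A <- c(A_up[1L], -A_up[2L])
    pts <- rbind(A, N, B)
    if (all(pts >= 2) && all(pts <= S - 1)) {
      return(list(A = unname(A), N = unname(N), B = unname(B)))
    }
  }
  stop(sprintf("could not place landmarks inside a %dpx image for angle %.2f",
               image_size, angle), call. = FALSE)
}

# Quadratic Bezier points.
bezier_points <- function(p0, p1, p2, n = 80L) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1L] + 2 * (1 - t) * t * p1[1L] + t^2 * p2[1L],
        (1 - t)^2 * p0[2L] + 2 * (1 - t) * t * p1[2L] + t^2 * p2[2L])
}

# Stamp a polyline onto the canvas (2x2 pixel footprint, max blend).
draw_polyline <- function(canvas, pts, value) {
  S <- nrow(canvas)
  # densify segments to ~0.5 px steps
  dens <- list()
  for (i in seq_len(nrow(pts) - 1L)) {
    d <- sqrt(sum((pts[i + 1L, ] - pts[i, ])^2))
    k <- max(2L, ceiling(d * 2))
    t <- seq(0, 1, length.out = k)
    dens[[i]] <- cbind(pts[i, 1L] + t * (pts[i + 1L, 1L] - pts[i, 1L]),
                       pts[i, 2L] + t * (pts[i + 1L, 2L] - pts[i, 2L]))
  }
  p <- do.call(rbind, dens)
  for (off in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    r <- round(p[, 2L]) + off[2L]  # canvas row = y
    c <- round(p[, 1L]) + off[1L]
    keep <- r >= 1 & r <= S & c >= 1 & c <= S
    idx <- cbind(r[keep], c[keep])
    canvas[idx] <- pmax(canvas[idx], value)
  }
  canvas
}

#' Render a stylized cephalogram-like image
#'
#' Draws a bright cranial dome, a maxillary ridge through A, and a
#' mandibular contour through B whose chin point is displaced anteriorly in
#' proportion to minus the ANB angle (a protruded mandible for negative,
#' Class III angles), plus additive uniform background noise. Deterministic
#' under the current RNG stream.
#'
#' @param geom Landmark list from [place_landmarks()].
#' @param angle Realized ANB angle in degrees (drives the mandible shape).
#' @param image_size Side length in pixels.
#' @param noise Background noise amplitude (0 disables).
#' @param elements Subset of `c("cranium", "maxilla", "mandible")` to draw;
#'   empty with `noise = 0` yields a blank image.
#' @return Numeric `image_size x image_size` matrix in \[0, 1\].
#' @export
render_image <- function(geom, angle, image_size, noise = 0.05,
                         elements = c("cranium", "maxilla", "mandible")) {
  S <- image_size
  canvas <- matrix(0, S, S)
  if (noise > 0) canvas <- canvas + noise * matrix(stats::runif(S * S), S, S)
  if ("cranium" %in% elements) {
    t <- seq(3.3, 6.1, length.out = 120L)
    pts <- cbind(0.45 * S + 0.38 * S * cos(t), 0.34 * S + 0.30 * S * sin(t))
    canvas <- draw_polyline(canvas, pts, 0.9)
  }
  if ("maxilla" %in% elements) {
    A <- geom$A
    pts <- bezier_points(c(A[1L] - 0.12 * S, A[2L] + 0.02 * S),
                         c(A[1L], A[2L] - 0.02 * S),
                         c(A[1L] + 0.05 * S, A[2L]))
    canvas <- draw_polyline(canvas, pts, 0.75)
  }
  if ("mandible" %in% elements) {
    B <- geom$B
    chin <- c(B[1L] + S * (0.02 - 0.012 * angle), B[2L] + 0.16 * S)
    pts1 <- bezier_points(B, c(B[1L] + 0.02 * S, B[2L] + 0.10 * S), chin)
    pts2 <- rbind(chin, c(chin[1L] - 0.30 * S, chin[2L] + 0.01 * S))
    canvas <- draw_polyline(canvas, pts1, 0.85)
    canvas <- draw_polyline(canvas, pts2, 0.85)
  }
  pmin(pmax(canvas, 0), 1)
}

# 19-slot landmark file content with A/N/B at lines 5/2/6 and in-bounds
# filler points elsewhere (fillers carry no anatomical meaning).
landmark_file_lines <- function(geom, image_size) {
  S <- image_size
  fill <- function() c(stats::runif(1L, 0.05 * S, 0.35 * S),
                       stats::runif(1L, 0.55 * S, 0.95 * S))
  pts <- lapply(seq_len(19L), function(i) fill())
  pts[[ANB_SLOTS_19[["A"]]]] <- geom$A
  pts[[ANB_SLOTS_19[["N"]]]] <- geom$N
  pts[[ANB_SLOTS_19[["B"]]]] <- geom$B
  vapply(pts, function(p) sprintf("%.4f,%.4f", p[1L], p[2L]), character(1))
}

#' Generate a labeled synthetic two-client dataset
#'
#' Writes per-image PNGs and 19-slot landmark annotation files (A/N/B on
#' lines 5/2/6, so the full ISBI-style parsing path is exercised), plus a
#' manifest CSV and the configuration as JSON. Class counts per client are
#' the deterministic largest-remainder apportionment of `n` by the class
#' ratios; an 80/20 stratified train/test split is recorded in the `split`
#' column. By construction, relabeling any record under its client's
#' standard reproduces its intended class.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @param write_files Write images/landmarks to disk (`TRUE`) or return the
#'   manifest with in-memory images in `attr(, "images")` (`FALSE`).
#' @return Manifest tibble with columns `image_path`, `landmark_path`,
#'   `client_id`, `class`, `anb`, `split`.
#' @export
generate_dataset <- function(cfg = synth_config(), dir = tempfile("synthceph"),
                             write_files = TRUE) {
  stopifnot(inherits(cfg, "synth_config"))
  if (write_files) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "landmarks"), recursive = TRUE, showWarnings = FALSE)
  }
  S <- cfg$image_size
  rows <- list()
  images <- list()
  with_seed(cfg$seed, {
    for (cid in names(cfg$clients)) {
      cl <- cfg$clients[[cid]]
      std <- as_standard(cl$standard)
      counts <- apportion_counts(cl$n, cl$ratios)
      classes <- rep(skeletal_levels(), counts)
      classes <- classes[sample.int(length(classes))]
      # stratified split: last round(n_k * fraction) of each class's
      # (already shuffled) occurrences go to test
      split <- rep("train", length(classes))
      for (k in skeletal_levels()) {
        idx <- which(classes == k)
        n_test <- round(length(idx) * cfg$test_fraction)
        if (n_test > 0L) split[utils::tail(idx, n_test)] <- "test"
      }
      for (i in seq_along(classes)) {
        cls <- classes[i]
        ang <- sample_angle(cls, std, cfg$angle_clip, cfg$margin)
        geom <- place_landmarks(ang, S, cfg$angle_jitter)
        img <- render_image(geom, ang, S, cfg$render_noise)
        ip <- file.path("images", sprintf("%s_%04d.png", cid, i))
        lp <- file.path("landmarks", sprintf("%s_%04d.txt", cid, i))
        if (write_files) {
          write_image(img, file.path(dir, ip))
          writeLines(landmark_file_lines(geom, S), file.path(dir, lp))
        } else {
          images[[length(images) + 1L]] <- img
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          image_path = ip, landmark_path = lp, client_id = cid,
          class = cls, anb = ang, split = split[i])
      }
    }
  })
  manifest <- dplyr::bind_rows(rows)
  if (write_files) {
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    jsonlite::write_json(
      list(clients = cfg$clients, image_size = cfg$image_size,
           angle_jitter = cfg$angle_jitter, angle_clip = cfg$angle_clip,
           margin = cfg$margin, render_noise = cfg$render_noise,
           test_fraction = cfg$test_fraction, seed = cfg$seed),
      file.path(dir, "synth_config.json"), auto_unbox = TRUE, digits = NA)
    attr(manifest, "dir") <- dir
  } else {
    attr(manifest, "images") <- images
  }
  manifest
}

#' Load a generated dataset into per-client train/test arrays
#'
#' Convenience wrapper around [load_dataset()] for the harness: returns the
#' named per-client list of `train`/`test` datasets that [run_setting()]
#' consumes.
#'
#' @param manifest Manifest from [generate_dataset()] (files on disk).
#' @param dir Dataset directory (defaults to the manifest's recorded one).
#' @param input_size Model input size (images are resized if needed).
#' @param normalize Normalization constants for [identity_transform()].
#' @return Named list: per client, a list with `train` and `test`
#'   `ceph_dataset`s.
#' @export
load_client_splits <- function(manifest, dir = attr(manifest, "dir"),
                               input_size = NULL,
                               normalize = list(mean = 0.5, sd = 0.25)) {
  if (is.null(dir)) stop("dataset directory unknown; pass `dir`", call. = FALSE)
  input_size <- input_size %||% 64L
  tf <- identity_transform(input_size, normalize)
  out <- list()
  for (cid in unique(manifest$client_id)) {
    m <- manifest[manifest$client_id == cid, ]
    out[[cid]] <- list(
      train = load_dataset(m[m$split == "train", ], input_size, tf, image_root = dir),
      test = load_dataset(m[m$split == "test", ], input_size, tf, image_root = dir))
  }
  out
}
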