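# Image IO, transforms, and in-memory datasets.

#' Read a grayscale image
#'
#' PNG files are read natively; a multi-channel image is averaged to one
#' channel. Values are in \[0, 1\].
#'
#' @param path Image path.
#' @return Numeric H x W matrix.
#' @export
read_image <- function(path) {
  if (!grepl("\\.png$", path, ignore.case = TRUE)) {
    stop(sprintf("unsupported image format for '%s' (PNG expected)", path),
         call. = FALSE)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3L, dim(img)[3L])),
                                               drop = FALSE], c(1L, 2L), mean)
  img
}

#' Write a grayscale image as PNG
#'
#' @param img Numeric H x W matrix; values clipped to \[0, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Bilinear image resize
#'
#' @param img Numeric H x W matrix.
#' @param out_h,out_w Output dimensions.
#' @return Resized matrix.
#' @export
resize_image <- function(img, out_h, out_w = out_h) {
  H <- nrow(img); W <- ncol(img)
  if (H == out_h && W == out_w) return(img)
  # align-corners = FALSE convention
  ys <- pmin(pmax((seq_len(out_h) - 0.5) * H / out_h + 0.5, 1), H)
  xs <- pmin(pmax((seq_len(out_w) - 0.5) * W / out_w + 0.5, 1), W)
  y0 <- pmin(floor(ys), H - 1L); y1 <- y0 + 1L; wy <- ys - y0
  x0 <- pmin(floor(xs), W - 1L); x1 <- x0 + 1L; wx <- xs - x0
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  top <- a + sweep(b - a, 2L, wx, "*")
  bot <- c + sweep(d - c, 2L, wx, "*")
  top + sweep(bot - top, 1L, wy, "*")
}

center_crop <- function(img, size) {
  H <- nrow(img); W <- ncol(img)
  y0 <- max(0L, (H - size) %/% 2L); x0 <- max(0L, (W - size) %/% 2L)
  img[y0 + seq_len(min(size, H)), x0 + seq_len(min(size, W)), drop = FALSE]
}

#' Transform pipelines
#'
#' `train_transform()` follows the study recipe: random resized crop to the
#' input size, optional random horizontal flip, then normalization.
#' `eval_transform()` resizes to `8/7` of the input size, center-crops, and
#' normalizes. Horizontal flip mirrors a lateral cephalogram's facing
#' direction, which inverts the sign convention of the ANB angle; it is kept
#' as the default for fidelity to the recipe but can be disabled with
#' `hflip = FALSE`.
#'
#' @param input_size Target side length in pixels.
#' @param hflip Enable random horizontal flips.
#' @param crop_scale Area range of the random crop, relative to the image.
#' @param crop_ratio Aspect-ratio range of the random crop.
#' @param normalize List with `mean` and `sd`, or `NULL` to skip.
#' @return A function `(img_matrix, rng_unused) -> matrix` applied per image.
#' @export
train_transform <- function(input_size, hflip = TRUE, crop_scale = c(0.6, 1),
                            crop_ratio = c(3 / 4, 4 / 3),
                            normalize = list(mean = 0.5, sd = 0.25)) {
  force(input_size)
  function(img) {
    H <- nrow(img); W <- ncol(img)
    area <- H * W * stats::runif(1L, crop_scale[1L], crop_scale[2L])
    ratio <- exp(stats::runif(1L, log(crop_ratio[1L]), log(crop_ratio[2L])))
    ch <- min(H, max(1L, round(sqrt(area / ratio))))
    cw <- min(W, max(1L, round(sqrt(area * ratio))))
    y0 <- sample.int(H - ch + 1L, 1L) - 1L
    x0 <- sample.int(W - cw + 1L, 1L) - 1L
    img <- img[y0 + seq_len(ch), x0 + seq_len(cw), drop = FALSE]
    img <- resize_image(img, input_size, input_size)
    if (hflip && stats::runif(1L) < 0.5) img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    if (!is.null(normalize)) img <- (img - normalize$mean) / normalize$sd
    img
  }
}

#' @rdname train_transform
#' @export
eval_transform <- function(input_size, normalize = list(mean = 0.5, sd = 0.25)) {
  force(input_size)
  resize_to <- as.integer(round(input_size * 8 / 7))
  function(img) {
    img <- resize_image(img, resize_to, resize_to)
    img <- center_crop(img, input_size)
    if (!is.null(normalize)) img <- (img - normalize$mean) / normalize$sd
    img
  }
}

#' @rdname train_transform
#' @export
identity_transform <- function(input_size, normalize = list(mean = 0.5, sd = 0.25)) {
  force(input_size)
  function(img) {
    if (nrow(img) != input_size || ncol(img) != input_size) {
      img <- resize_image(img, input_size, input_size)
    }
    if (!is.null(normalize)) img <- (img - normalize$mean) / normalize$sd
    img
  }
}

#' Load an image dataset from a labeled manifest
#'
#' Materializes images into an `N x C x H x W` array plus 0-based integer
#' targets, applying `transform` per image (default: resize + normalize
#' only). Records with `NA` class are dropped.
#'
#' @param manifest Labeled manifest tibble.
#' @param input_size Side length images are brought to.
#' @param transform A transform function (see [train_transform()]); the
#'   default is [identity_transform()].
#' @param image_root Optional directory prefixed to relative image paths.
#' @return A `ceph_dataset`: list with `x` (array), `y` (0-based integers),
#'   `manifest`.
#' @export
load_dataset <- function(manifest, input_size = 64L, transform = NULL,
                         image_root = NULL) {
  manifest <- manifest[!is.na(manifest$class), , drop = FALSE]
  n <- nrow(manifest)
  if (n == 0L) stop("manifest has no labeled records", call. = FALSE)
  if (is.null(transform)) transform <- identity_transform(input_size)
  x <- array(0, dim = c(n, 1L, input_size, input_size))
  for (i in seq_len(n)) {
    p <- manifest$image_path[i]
    if (!is.null(image_root) && !file.exists(p)) p <- file.path(image_root, p)
    x[i, 1L, , ] <- transform(read_image(p))
  }
  structure(list(x = x, y = class_target_index(manifest$class), manifest = manifest),
            class = "ceph_dataset")
}

#' Assemble a dataset from in-memory images
#'
#' @param images List of H x W matrices or an `N x H x W` array.
#' @param classes Character vector of skeletal classes (`"I"`/`"II"`/`"III"`).
#' @param normalize List with `mean` and `sd`, or `NULL`.
#' @return A `ceph_dataset`.
#' @export
as_ceph_dataset <- function(images, classes, normalize = list(mean = 0.5, sd = 0.25)) {
  if (is.array(images) && length(dim(images)) == 3L) {
    images <- lapply(seq_len(dim(images)[1L]), function(i) images[i, , ])
  }
  n <- length(images)
  stopifnot(n == length(classes))
  size <- nrow(images[[1L]])
  x <- array(0, dim = c(n, 1L, size, size))
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (!is.null(normalize)) img <- (img - normalize$mean) / normalize$sd
    x[i, 1L, , ] <- img
  }
  structure(list(x = x, y = class_target_index(classes), manifest = NULL),
            class = "ceph_dataset")
}

#' @export
print.ceph_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<ceph_dataset> %d images %dx%d, classes: %s\n", d[1L], d[3L], d[4L],
              paste(sprintf("%s=%d", skeletal_levels(), tabulate(x$y + 1L, 3L)),
                    collapse = " ")))
  invisible(x)
}

# Concatenate datasets (merged training / test pools).
merge_datasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && is.list(ds[[1L]]) && !inherits(ds[[1L]], "ceph_dataset")) {
    ds <- ds[[1L]]
  }
  x <- do.call(abind_first, list(lapply(ds, function(d) d$x)))
  y <- unlist(lapply(ds, function(d) d$y), use.names = FALSE)
  structure(list(x = x, y = y, manifest = NULL), class = "ceph_dataset")
}

abind_first <- function(arrs) {
  d <- dim(arrs[[1L]])
  n <- sum(vapply(arrs, function(a) dim(a)[1L], integer(1)))
  out <- array(0, dim = c(n, d[2L], d[3L], d[4L]))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[1L]
    out[at + seq_len(k), , , ] <- a
    at <- at + k
  }
  out
}

subset_dataset <- function(data, idx) {
  structure(list(x = data$x[idx, , , , drop = FALSE], y = data$y[idx],
                 manifest = if (!is.null(data$manifest)) data$manifest[idx, ]),
            class = "ceph_dataset")
}
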