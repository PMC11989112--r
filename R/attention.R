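#' Attention and pooling blocks on feature maps
#'
#' Feature maps are plain 3-d arrays with dimensions channels x height x
#' width (C x H x W). Four augmentation blocks operate on them:
#'
#' * **Channel attention (CA)**: per-channel gates
#'   `sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))`, where both pools collapse
#'   the spatial plane to one value per channel and the one-hidden-layer MLP
#'   (ReLU hidden activation) is shared between the two descriptors.
#' * **Spatial attention (SA)**: a per-position gate
#'   `sigmoid(conv7x7([mean_c(F); max_c(F)]))` from the channel-wise mean and
#'   max maps, convolved with a 7x7 kernel at stride 1 and zero padding 3 so
#'   the H x W extent is preserved.
#' * **Squeeze-and-excitation (SE)**: squeeze is global average pooling to a
#'   channel descriptor `z`; excitation is `sigmoid(fc2(relu(fc1(z))))`.
#' * **Spatial pyramid pooling (SPP)**: adaptive average pooling to each grid
#'   size in `sizes`, flattened and concatenated to a fixed-length vector
#'   whose length does not depend on H or W.
#'
#' Attention gates are applied multiplicatively by [apply_block()]: CA/SE
#' broadcast over positions, SA broadcasts over channels.
#'
#' @name attention_blocks
NULL

reduced_width <- function(C, r) max(1L, C %/% as.integer(r))

#' Parameters for the attention blocks
#'
#' Constructors for block parameter sets. With `zero = TRUE` all weights and
#' biases are zero (every gate is then exactly 0.5); otherwise weights are
#' He-normal initialized from `seed`.
#'
#' @param C Number of feature-map channels.
#' @param r Reduction ratio of the bottleneck MLP (hidden width `C %/% r`,
#'   clamped to be at least 1). Default 16.
#' @param seed Integer seed for random initialization.
#' @param zero If `TRUE`, all-zero parameters.
#' @return A parameter list of the matching class.
#' @export
ca_params <- function(C, r = 16L, seed = 1L, zero = FALSE) {
  h <- reduced_width(C, r)
  p <- with_seed(seed, list(
    w1 = matrix(stats::rnorm(h * C, sd = sqrt(2 / C)), h, C),
    b1 = numeric(h),
    w2 = matrix(stats::rnorm(C * h, sd = sqrt(2 / h)), C, h),
    b2 = numeric(C)
  ))
  if (zero) p <- lapply(p, function(a) a * 0)
  structure(c(p, list(C = as.integer(C), r = as.integer(r))),
            class = "ca_params")
}

#' @rdname ca_params
#' @export
sa_params <- function(seed = 1L, zero = FALSE) {
  k <- with_seed(seed, array(stats::rnorm(7 * 7 * 2, sd = sqrt(2 / (49 * 2))),
                             dim = c(7, 7, 2)))
  if (zero) k[] <- 0
  structure(list(kernel = k, bias = 0), class = "sa_params")
}

#' @rdname ca_params
#' @export
se_params <- function(C, r = 16L, seed = 1L, zero = FALSE) {
  h <- reduced_width(C, r)
  p <- with_seed(seed, list(
    w1 = matrix(stats::rnorm(h * C, sd = sqrt(2 / C)), h, C),
    b1 = numeric(h),
    w2 = matrix(stats::rnorm(C * h, sd = sqrt(2 / h)), C, h),
    b2 = numeric(C)
  ))
  if (zero) p <- lapply(p, function(a) a * 0)
  structure(c(p, list(C = as.integer(C), r = as.integer(r))),
            class = "se_params")
}

bottleneck_mlp <- function(v, p) {
  drop(p$w2 %*% relu(drop(p$w1 %*% v) + p$b1)) + p$b2
}

#' @describeIn attention_blocks Per-channel attention weights, length C,
#'   each strictly in (0, 1).
#' @param F A C x H x W feature-map array.
#' @param p Block parameters ([ca_params()], [sa_params()], [se_params()]).
#' @export
channel_attention <- function(F, p) {
  check_feature_map(F)
  C <- dim(F)[1L]
  if (!inherits(p, "ca_params") || p$C != C) {
    stop(sprintf("channel-attention parameters expect %s channels, feature map has %d",
                 if (inherits(p, "ca_params")) p$C else "?", C), call. = FALSE)
  }
  avg <- apply(F, 1L, mean)
  mx <- apply(F, 1L, max)
  sigmoid(bottleneck_mlp(avg, p) + bottleneck_mlp(mx, p))
}

# 2-d convolution of a (kh x kw x Cin) kernel over a Cin x H x W array,
# stride 1, zero padding preserving H x W. Returns an H x W matrix.
conv2d_same <- function(x, kernel, bias = 0) {
  kh <- dim(kernel)[1L]; kw <- dim(kernel)[2L]; cin <- dim(kernel)[3L]
  H <- dim(x)[2L]; W <- dim(x)[3L]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  out <- matrix(bias, H, W)
  pad <- array(0, dim = c(cin, H + 2 * ph, W + 2 * pw))
  pad[, ph + seq_len(H), pw + seq_len(W)] <- x
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      block <- pad[, i:(i + H - 1L), j:(j + W - 1L), drop = FALSE]
      for (c in seq_len(cin)) {
        out <- out + kernel[i, j, c] * matrix(block[c, , ], H, W)
      }
    }
  }
  out
}

#' @describeIn attention_blocks Spatial attention map, H x W, entries
#'   strictly in (0, 1).
#' @export
spatial_attention <- function(F, p) {
  check_feature_map(F)
  if (!inherits(p, "sa_params")) stop("`p` must be sa_params", call. = FALSE)
  stopifnot(all(dim(p$kernel) == c(7, 7, 2)))
  H <- dim(F)[2L]; W <- dim(F)[3L]
  desc <- array(0, dim = c(2L, H, W))
  desc[1L, , ] <- apply(F, c(2L, 3L), mean)
  desc[2L, , ] <- apply(F, c(2L, 3L), max)
  sigmoid(conv2d_same(desc, p$kernel, p$bias))
}

#' @describeIn attention_blocks Squeeze step: channel descriptor `z`,
#'   the spatial mean of each channel (length C).
#' @export
se_squeeze <- function(F) {
  check_feature_map(F)
  apply(F, 1L, mean)
}

#' @describeIn attention_blocks Excitation step: channel scales
#'   `sigmoid(fc2(relu(fc1(z))))`, length C, each strictly in (0, 1).
#' @param z Channel descriptor (length C), from [se_squeeze()].
#' @export
se_excite <- function(z, p) {
  if (!inherits(p, "se_params") || p$C != length(z)) {
    stop("squeeze-excitation parameters incompatible with descriptor length",
         call. = FALSE)
  }
  sigmoid(bottleneck_mlp(z, p))
}

#' Apply an attention block to a feature map
#'
#' Scales the feature map element-wise by the block's attention values:
#' channel gates (CA, SE) broadcast over positions, the spatial gate (SA)
#' broadcasts over channels. `"SA_SE"` composes SA first, then SE on the
#' SA output.
#'
#' @param F A C x H x W feature-map array.
#' @param block One of `"CA"`, `"SA"`, `"SE"`, `"SA_SE"`.
#' @param params Named list carrying the needed parameter sets in elements
#'   `ca`, `sa`, `se`.
#' @return A feature map of the same shape.
#' @export
apply_block <- function(F, block = c("CA", "SA", "SE", "SA_SE"), params) {
  block <- match.arg(block)
  check_feature_map(F)
  need <- switch(block, CA = "ca", SA = "sa", SE = "se", SA_SE = c("sa", "se"))
  if (missing(params) || !all(need %in% names(params))) {
    stop(sprintf("block '%s' needs initialized params element(s): %s",
                 block, paste(need, collapse = ", ")), call. = FALSE)
  }
  scale_channels <- function(F, s) F * array(s, dim = dim(F))  # channel fastest
  scale_spatial <- function(F, m) {
    C <- dim(F)[1L]
    F * aperm(array(m, dim = c(dim(F)[2L], dim(F)[3L], C)), c(3L, 1L, 2L))
  }
  switch(block,
    CA = scale_channels(F, channel_attention(F, params$ca)),
    SA = scale_spatial(F, spatial_attention(F, params$sa)),
    SE = scale_channels(F, se_excite(se_squeeze(F), params$se)),
    SA_SE = {
      G <- scale_spatial(F, spatial_attention(F, params$sa))
      scale_channels(G, se_excite(se_squeeze(G), params$se))
    }
  )
}

#' Spatial pyramid pooling configuration
#'
#' @param sizes Strictly increasing positive integers; default `c(4, 8, 16)`.
#' @return An `spp_config` object.
#' @export
spp_config <- function(sizes = c(4L, 8L, 16L)) {
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L || any(sizes < 1L) || is.unsorted(sizes, strictly = TRUE)) {
    stop("`sizes` must be a nonempty strictly increasing vector of positive integers",
         call. = FALSE)
  }
  structure(list(sizes = sizes), class = "spp_config")
}

# Half-open adaptive-average-pooling bin boundaries: 0-based bin b over n
# cells spans floor(b*n/s) .. ceil((b+1)*n/s) - 1. Bins repeat cells when
# n < s. Returns a list of 1-based index vectors.
adaptive_bins <- function(n, s) {
  lapply(seq_len(s) - 1L, function(b) {
    lo <- floor(b * n / s)
    hi <- ceiling((b + 1) * n / s)
    seq.int(lo + 1L, hi)
  })
}

# Adaptive average pooling of a C x H x W array to an s x s grid.
# Returns an array (s, s, C): bin-row, bin-col, channel.
adaptive_avg_pool3 <- function(F, s) {
  C <- dim(F)[1L]; H <- dim(F)[2L]; W <- dim(F)[3L]
  rb <- adaptive_bins(H, s); cb <- adaptive_bins(W, s)
  out <- array(0, dim = c(s, s, C))
  for (i in seq_len(s)) {
    for (j in seq_len(s)) {
      block <- F[, rb[[i]], cb[[j]], drop = FALSE]
      out[i, j, ] <- apply(block, 1L, mean)
    }
  }
  out
}

#' Spatial pyramid pooling to a fixed-length vector
#'
#' Adaptive average pooling of the feature map to each grid size, flattened
#' (spatial bins within each channel, channels concatenated) and joined in
#' configuration order. The output length is `C * sum(sizes^2)` regardless
#' of H and W.
#'
#' @param F A C x H x W feature-map array.
#' @param cfg An [spp_config()] (or a plain size vector).
#' @return Numeric vector of length `C * sum(sizes^2)`.
#' @export
spp_pool <- function(F, cfg = spp_config()) {
  if (!inherits(cfg, "spp_config")) cfg <- spp_config(cfg)
  check_feature_map(F)
  unlist(lapply(cfg$sizes, function(s) {
    p <- adaptive_avg_pool3(F, s)       # (s, s, C)
    as.vector(aperm(p, c(2L, 1L, 3L)))  # row-major bins within channel
  }), use.names = FALSE)
}

#' Fully-connected input width after spatial pyramid pooling
#'
#' @param final_channels Channels of the final feature map.
#' @param spp_sizes Pyramid grid sizes.
#' @return `final_channels * sum(spp_sizes^2)`.
#' @examples
#' fc_input_size(1024, c(4, 8, 16))  # 344064
#' @export
fc_input_size <- function(final_channels, spp_sizes = c(4L, 8L, 16L)) {
  if (length(spp_sizes) == 0L) stop("`spp_sizes` must be nonempty", call. = FALSE)
  stopifnot(final_channels >= 1L, all(spp_sizes >= 1L))
  as.integer(final_channels) * sum(as.integer(spp_sizes)^2L)
}
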