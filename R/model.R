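#' Backbone configuration for the dense convolutional classifier
#'
#' The backbone is a DenseNet-style network: a 7x7 stride-2 stem convolution
#' with batch norm and a 3x3 stride-2 max pool, dense blocks whose
#' convolution layers (1x1 bottleneck to `bottleneck * growth_rate` channels,
#' then 3x3 to `growth_rate` channels, each preceded by batch norm and ReLU)
#' concatenate their outputs onto the running feature map, and transition
#' layers (1x1 convolution compressing channels by `compression`, then 2x2
#' stride-2 average pooling) between blocks. A final batch norm + ReLU yields
#' the feature map the classification heads consume.
#'
#' The default layout `c(6, 12, 24, 16)` with growth 32 is the canonical
#' 121-layer configuration (final feature map 1024 channels at 224 input);
#' [tiny_backbone()] is a reduced preset (`c(2, 2)` blocks, growth 8,
#' grayscale 64x64 input) for CPU-scale experiments.
#'
#' @param block_layout Integer vector of dense-block sizes.
#' @param growth_rate Channels added per dense layer.
#' @param in_channels Input image channels (1 grayscale, 3 RGB).
#' @param input_size Input image side length in pixels.
#' @param bottleneck Bottleneck width multiplier (1x1 conv outputs
#'   `bottleneck * growth_rate` channels).
#' @param compression Transition channel compression factor.
#' @return A `backbone_config` object.
#' @export
backbone_config <- function(block_layout = c(6L, 12L, 24L, 16L),
                            growth_rate = 32L,
                            in_channels = 3L,
                            input_size = 224L,
                            bottleneck = 4L,
                            compression = 0.5) {
  stopifnot(length(block_layout) >= 1L, all(block_layout >= 1L),
            growth_rate >= 1L, in_channels >= 1L, input_size >= 1L)
  structure(list(block_layout = as.integer(block_layout),
                 growth_rate = as.integer(growth_rate),
                 stem_channels = 2L * as.integer(growth_rate),
                 in_channels = as.integer(in_channels),
                 input_size = as.integer(input_size),
                 bottleneck = as.integer(bottleneck),
                 compression = compression),
            class = "backbone_config")
}

#' @rdname backbone_config
#' @export
tiny_backbone <- function() {
  backbone_config(block_layout = c(2L, 2L), growth_rate = 8L,
                  in_channels = 1L, input_size = 64L)
}

#' @rdname backbone_config
#' @export
densenet121_backbone <- function(in_channels = 3L, input_size = 224L) {
  backbone_config(in_channels = in_channels, input_size = input_size)
}

MODEL_HEADS <- c("plain", "CA", "SA", "SE", "SA_SE", "SPP")

#' Model specification
#'
#' Combines a backbone with one of six classification heads: `"plain"`
#' (global average pooling + fully connected layer), the four attention
#' variants `"CA"`, `"SA"`, `"SE"`, `"SA_SE"` (the attention gate is applied
#' to the final feature map, then adaptive average pooling to 1x1 and the
#' fully connected layer), and `"SPP"` (spatial pyramid pooling replaces the
#' global pooling; the fully connected input width follows
#' [fc_input_size()]).
#'
#' @param backbone A [backbone_config()].
#' @param head One of `"plain"`, `"CA"`, `"SA"`, `"SE"`, `"SA_SE"`, `"SPP"`.
#' @param n_classes Number of output classes (default 3).
#' @param spp_sizes Pyramid sizes for the SPP head.
#' @param reduction_ratio Bottleneck reduction of the CA/SE gates.
#' @return A `model_spec` object.
#' @export
model_spec <- function(backbone = tiny_backbone(), head = "plain",
                       n_classes = 3L, spp_sizes = c(4L, 8L, 16L),
                       reduction_ratio = 16L) {
  head <- match.arg(head, MODEL_HEADS)
  spec <- structure(list(backbone = backbone, head = head,
                         n_classes = as.integer(n_classes),
                         spp_sizes = as.integer(spp_sizes),
                         reduction_ratio = as.integer(reduction_ratio)),
                    class = "model_spec")
  spec$arch <- arch_plan(spec)  # validates geometry
  spec
}

# Static channel/spatial bookkeeping for a spec; configuration errors are
# raised here (e.g. input too small for the stem + pooling pyramid).
arch_plan <- function(spec) {
  bb <- spec$backbone
  H <- bb$input_size
  if (H < 2L * 7L) {
    stop(sprintf("input size %d is smaller than the stem's receptive footprint", H),
         call. = FALSE)
  }
  Hs <- conv_out_dim(H, 7L, 2L, 3L)
  Hp <- conv_out_dim(Hs, 3L, 2L, 1L)
  C <- bb$stem_channels
  S <- Hp
  blocks <- list()
  block_out_channels <- integer(0)
  nb <- length(bb$block_layout)
  for (b in seq_len(nb)) {
    layers <- list()
    for (l in seq_len(bb$block_layout[b])) {
      layers[[l]] <- list(cin = C, mid = bb$bottleneck * bb$growth_rate,
                          gout = bb$growth_rate)
      C <- C + bb$growth_rate
    }
    blk <- list(layers = layers, out_channels = C, spatial = S)
    block_out_channels[b] <- C
    if (b < nb) {
      ct <- as.integer(floor(C * bb$compression))
      blk$transition <- list(cin = C, cout = ct)
      C <- ct
      S <- S %/% 2L
      if (S < 1L) stop("spatial size collapses below 1 in transition", call. = FALSE)
    }
    blocks[[b]] <- blk
  }
  fc_in <- if (spec$head == "SPP") fc_input_size(C, spec$spp_sizes) else C
  list(stem_spatial = Hs, pool_spatial = Hp, blocks = blocks,
       block_out_channels = block_out_channels,
       final_channels = C, final_spatial = S, fc_in = fc_in)
}

# Deterministic per-tensor seed so that a tensor shared between two variants
# (e.g. the fully connected head) initializes identically for the same seed.
param_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 1e5 * 20011 + h) %% 2147483629) + 1L
}

init_conv <- function(seed, name, kh, kw, cin, cout) {
  with_seed(param_seed(seed, name),
            array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
                  dim = c(kh, kw, cin, cout)))
}

init_fc <- function(seed, name, d_in, d_out) {
  bound <- 1 / sqrt(d_in)
  with_seed(param_seed(seed, name),
            list(W = matrix(stats::runif(d_in * d_out, -bound, bound), d_in, d_out),
                 b = stats::runif(d_out, -bound, bound)))
}

bn_param_set <- function(prefix, C) {
  stats::setNames(
    list(rep(1, C), rep(0, C), rep(0, C), rep(1, C)),
    paste0(prefix, c(".gamma", ".beta", ".running_mean", ".running_var")))
}

#' Build a classifier model
#'
#' Instantiates all parameters of a [model_spec()] deterministically from a
#' seed: identical spec + seed give bit-identical parameters, and tensors
#' shared between head variants (backbone, fully connected layer) initialize
#' identically across variants for the same seed.
#'
#' @param spec A [model_spec()].
#' @param seed Integer initialization seed.
#' @return A `fedceph_model` (callable through [predict.fedceph_model()]).
#' @export
build_model <- function(spec, seed = 1L) {
  if (!inherits(spec, "model_spec")) stop("`spec` must be a model_spec", call. = FALSE)
  ap <- spec$arch
  bb <- spec$backbone
  params <- list()
  add <- function(x) params <<- c(params, x)

  add(stats::setNames(list(init_conv(seed, "stem.conv", 7L, 7L, bb$in_channels,
                                     bb$stem_channels)), "stem.conv.kernel"))
  add(bn_param_set("stem.bn", bb$stem_channels))

  for (b in seq_along(ap$blocks)) {
    blk <- ap$blocks[[b]]
    for (l in seq_along(blk$layers)) {
      ly <- blk$layers[[l]]
      pre <- sprintf("db%d.l%d", b, l)
      add(bn_param_set(paste0(pre, ".bn1"), ly$cin))
      add(stats::setNames(list(init_conv(seed, paste0(pre, ".conv1"), 1L, 1L,
                                         ly$cin, ly$mid)),
                          paste0(pre, ".conv1.kernel")))
      add(bn_param_set(paste0(pre, ".bn2"), ly$mid))
      add(stats::setNames(list(init_conv(seed, paste0(pre, ".conv2"), 3L, 3L,
                                         ly$mid, ly$gout)),
                          paste0(pre, ".conv2.kernel")))
    }
    if (!is.null(blk$transition)) {
      tr <- blk$transition
      pre <- sprintf("tr%d", b)
      add(bn_param_set(paste0(pre, ".bn"), tr$cin))
      add(stats::setNames(list(init_conv(seed, paste0(pre, ".conv"), 1L, 1L,
                                         tr$cin, tr$cout)),
                          paste0(pre, ".conv.kernel")))
    }
  }
  Cf <- ap$final_channels
  add(bn_param_set("final.bn", Cf))

  hr <- reduced_width(Cf, spec$reduction_ratio)
  he_mat <- function(name, nr, nc) {
    with_seed(param_seed(seed, name),
              matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nc)), nr, nc))
  }
  if (spec$head %in% c("CA")) {
    add(list("head.ca.w1" = he_mat("head.ca.w1", hr, Cf), "head.ca.b1" = numeric(hr),
             "head.ca.w2" = he_mat("head.ca.w2", Cf, hr), "head.ca.b2" = numeric(Cf)))
  }
  if (spec$head %in% c("SA", "SA_SE")) {
    add(list("head.sa.kernel" = init_conv(seed, "head.sa.kernel", 7L, 7L, 2L, 1L),
             "head.sa.bias" = 0))
  }
  if (spec$head %in% c("SE", "SA_SE")) {
    add(list("head.se.w1" = he_mat("head.se.w1", hr, Cf), "head.se.b1" = numeric(hr),
             "head.se.w2" = he_mat("head.se.w2", Cf, hr), "head.se.b2" = numeric(Cf)))
  }
  fc <- init_fc(seed, "fc", ap$fc_in, spec$n_classes)
  add(list("fc.weight" = fc$W, "fc.bias" = fc$b))

  structure(list(spec = spec, params = params,
                 plan_cache = new.env(parent = emptyenv())),
            class = "fedceph_model")
}

#' @export
print.fedceph_model <- function(x, ...) {
  ap <- x$spec$arch
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<fedceph_model> head=%s layout=[%s] growth=%d input=%dpx\n",
              x$spec$head,
              paste(x$spec$backbone$block_layout, collapse = ","),
              x$spec$backbone$growth_rate, x$spec$backbone$input_size))
  cat(sprintf("  final feature map: %d x %d x %d; fc input %d; %s values\n",
              ap$final_channels, ap$final_spatial, ap$final_spatial, ap$fc_in,
              format(n_par, big.mark = ",")))
  invisible(x)
}

# ---- forward / backward ----

# Forward pass. Returns logits, a backward closure (if need_grad) producing
# the named gradient list, and updated batch-norm buffers (if training).
model_forward <- function(model, x, training = FALSE, need_grad = training,
                          return_features = FALSE) {
  spec <- model$spec
  ap <- spec$arch
  params <- model$params
  pc <- model$plan_cache
  if (length(dim(x)) == 3L) x <- array(x, c(1L, dim(x)))
  stopifnot(length(dim(x)) == 4L, dim(x)[2L] == spec$backbone$in_channels,
            dim(x)[3L] == spec$backbone$input_size,
            dim(x)[4L] == spec$backbone$input_size)
  N <- dim(x)[1L]
  X <- nchw_to_rows(x)

  backs <- list()
  gr <- new.env(parent = emptyenv()); gr$g <- list()
  bufs <- list()
  addg <- function(nm, g) {
    cur <- gr$g[[nm]]
    gr$g[[nm]] <- if (is.null(cur)) g else cur + g
  }
  push <- function(f) backs[[length(backs) + 1L]] <<- f

  run_conv <- function(X, nm, kh, stride, pad, H, W, N) {
    kern <- params[[paste0(nm, ".kernel")]]
    r <- if (kh == 1L) op_conv1x1(X, kern)
         else op_conv(X, kern, get_plan(pc, H, W, kh, kh, stride, pad, N))
    list(out = r$out, back = function(g) {
      b <- r$backward(g)
      addg(paste0(nm, ".kernel"), b$gkernel)
      b$gx
    })
  }
  run_bn <- function(X, nm) {
    r <- op_bn(X, params[[paste0(nm, ".gamma")]], params[[paste0(nm, ".beta")]],
               params[[paste0(nm, ".running_mean")]], params[[paste0(nm, ".running_var")]],
               training = training)
    if (training) {
      bufs[[paste0(nm, ".running_mean")]] <<- r$running_mean
      bufs[[paste0(nm, ".running_var")]] <<- r$running_var
    }
    list(out = r$out, back = function(g) {
      b <- r$backward(g)
      addg(paste0(nm, ".gamma"), b$ggamma)
      addg(paste0(nm, ".beta"), b$gbeta)
      b$gx
    })
  }

  H <- spec$backbone$input_size; W <- H

  # stem
  r <- run_conv(X, "stem.conv", 7L, 2L, 3L, H, W, N); if (need_grad) push(r$back)
  X <- r$out; H <- ap$stem_spatial; W <- H
  r <- run_bn(X, "stem.bn"); if (need_grad) push(r$back); X <- r$out
  r <- op_relu(X); if (need_grad) push(r$backward); X <- r$out
  r <- op_maxpool(X, get_plan(pc, H, W, 3L, 3L, 2L, 1L, N))
  if (need_grad) push(r$backward)
  X <- r$out; H <- ap$pool_spatial; W <- H

  # dense blocks
  for (b in seq_along(ap$blocks)) {
    blk <- ap$blocks[[b]]
    for (l in seq_along(blk$layers)) {
      ly <- blk$layers[[l]]
      pre <- sprintf("db%d.l%d", b, l)
      s <- list()
      r1 <- run_bn(X, paste0(pre, ".bn1")); s <- c(s, list(r1$back))
      r2 <- op_relu(r1$out);                s <- c(s, list(r2$backward))
      r3 <- run_conv(r2$out, paste0(pre, ".conv1"), 1L, 1L, 0L, H, W, N)
      s <- c(s, list(r3$back))
      r4 <- run_bn(r3$out, paste0(pre, ".bn2")); s <- c(s, list(r4$back))
      r5 <- op_relu(r4$out);                s <- c(s, list(r5$backward))
      r6 <- run_conv(r5$out, paste0(pre, ".conv2"), 3L, 1L, 1L, H, W, N)
      s <- c(s, list(r6$back))
      cin <- ly$cin
      if (need_grad) {
        local({
          sub_backs <- s; cin_l <- cin
          push(function(g) {
            gx_direct <- g[, seq_len(cin_l), drop = FALSE]
            gt <- g[, -seq_len(cin_l), drop = FALSE]
            for (f in rev(sub_backs)) gt <- f(gt)
            gx_direct + gt
          })
        })
      }
      X <- cbind(X, r6$out)
    }
    if (!is.null(blk$transition)) {
      pre <- sprintf("tr%d", b)
      r <- run_bn(X, paste0(pre, ".bn")); if (need_grad) push(r$back); X <- r$out
      r <- op_relu(X); if (need_grad) push(r$backward); X <- r$out
      r <- run_conv(X, paste0(pre, ".conv"), 1L, 1L, 0L, H, W, N)
      if (need_grad) push(r$back); X <- r$out
      r <- op_avgpool(X, get_plan(pc, H, W, 2L, 2L, 2L, 0L, N))
      if (need_grad) push(r$backward)
      X <- r$out; H <- H %/% 2L; W <- W %/% 2L
    }
  }

  r <- run_bn(X, "final.bn"); if (need_grad) push(r$back); X <- r$out
  r <- op_relu(X); if (need_grad) push(r$backward); X <- r$out

  if (isTRUE(return_features)) {
    return(list(features = X, H = H, W = W, N = N))
  }

  HW <- H * W
  Cf <- ap$final_channels

  # head gates
  if (spec$head %in% c("SA", "SA_SE")) {
    r <- head_sa_gate(X, params, N, H, W, pc, addg, need_grad)
    if (need_grad) push(r$back); X <- r$out
  }
  if (spec$head == "CA") {
    r <- head_channel_gate(X, params, "head.ca", N, HW, use_max = TRUE,
                           addg = addg, need_grad = need_grad)
    if (need_grad) push(r$back); X <- r$out
  }
  if (spec$head %in% c("SE", "SA_SE")) {
    r <- head_channel_gate(X, params, "head.se", N, HW, use_max = FALSE,
                           addg = addg, need_grad = need_grad)
    if (need_grad) push(r$back); X <- r$out
  }

  # pooling to the fully connected layer
  if (spec$head == "SPP") {
    r <- op_spp(X, N, H, W, spec$spp_sizes)
  } else {
    r <- op_gap(X, N, HW)
  }
  if (need_grad) push(r$backward)
  X <- r$out

  r <- op_fc(X, params[["fc.weight"]], params[["fc.bias"]])
  if (need_grad) {
    push(function(g) {
      b <- r$backward(g)
      addg("fc.weight", b$gW); addg("fc.bias", b$gb)
      b$gx
    })
  }
  logits <- r$out

  back <- NULL
  if (need_grad) {
    back <- function(glogits) {
      g <- glogits
      for (f in rev(backs)) g <- f(g)
      gr$g
    }
  }
  list(logits = logits, back = back, buffers = bufs)
}

# Channel gate (CA with avg+max descriptors, SE with avg only), batched.
head_channel_gate <- function(X, params, prefix, N, HW, use_max, addg, need_grad) {
  w1 <- params[[paste0(prefix, ".w1")]]; b1 <- params[[paste0(prefix, ".b1")]]
  w2 <- params[[paste0(prefix, ".w2")]]; b2 <- params[[paste0(prefix, ".b2")]]
  C <- ncol(X)
  grp <- rep(seq_len(N), each = HW)
  A <- rowsum(X, grp, reorder = FALSE) / HW
  mlp_fwd <- function(V) {
    pre1 <- V %*% t(w1) + rep(b1, each = N)
    H1 <- pre1 * (pre1 > 0)
    list(out = H1 %*% t(w2) + rep(b2, each = N), pre1 = pre1, H1 = H1, V = V)
  }
  fa <- mlp_fwd(A)
  z <- fa$out
  if (use_max) {
    arr <- array(X, dim = c(HW, N, C))
    Mx <- apply(arr, c(2L, 3L), max)
    argpos <- apply(arr, c(2L, 3L), which.max)
    fm <- mlp_fwd(Mx)
    z <- z + fm$out
  }
  S <- sigmoid(z)
  out <- X * S[grp, , drop = FALSE]
  back <- function(g) {
    gX <- g * S[grp, , drop = FALSE]
    gS <- rowsum(g * X, grp, reorder = FALSE)
    gpre <- gS * S * (1 - S)
    mlp_bwd <- function(f) {
      gH <- (gpre %*% w2) * (f$pre1 > 0)
      addg(paste0(prefix, ".w2"), t(crossprod(f$H1, gpre)))
      addg(paste0(prefix, ".b2"), colSums(gpre))
      addg(paste0(prefix, ".w1"), t(crossprod(f$V, gH)))
      addg(paste0(prefix, ".b1"), colSums(gH))
      gH %*% w1
    }
    gA <- mlp_bwd(fa)
    gX <- gX + gA[grp, , drop = FALSE] / HW
    if (use_max) {
      gM <- mlp_bwd(fm)
      rowoff <- (seq_len(N) - 1L) * HW
      flat <- rep((seq_len(C) - 1L) * (N * HW), each = N) +
        rep(rowoff, times = C) + as.vector(argpos)
      gX[flat] <- gX[flat] + as.vector(gM)
    }
    gX
  }
  list(out = out, back = if (need_grad) back else NULL)
}

# Spatial gate: sigmoid(conv7x7([mean_c; max_c])), batched.
head_sa_gate <- function(X, params, N, H, W, pc, addg, need_grad) {
  C <- ncol(X)
  n <- nrow(X)
  mn <- rowMeans(X)
  mx <- X[, 1L]
  argc <- rep(1L, n)
  for (c in seq_len(C)[-1L]) {
    m <- X[, c] > mx
    mx[m] <- X[m, c]
    argc[m] <- c
  }
  desc <- cbind(mn, mx)
  plan <- get_plan(pc, H, W, 7L, 7L, 1L, 3L, N)
  cr <- op_conv(desc, params[["head.sa.kernel"]], plan, bias = params[["head.sa.bias"]])
  S <- sigmoid(cr$out)  # n x 1
  Sv <- as.vector(S)
  out <- X * Sv
  back <- function(g) {
    gX <- g * Sv
    gSv <- rowSums(g * X)
    gpre <- matrix(gSv * Sv * (1 - Sv), ncol = 1L)
    cb <- cr$backward(gpre)
    addg("head.sa.kernel", cb$gkernel)
    addg("head.sa.bias", cb$gbias)
    gdesc <- cb$gx
    gX <- gX + gdesc[, 1L] / C      # mean path: recycles down columns
    flat <- (argc - 1L) * n + seq_len(n)
    gX[flat] <- gX[flat] + gdesc[, 2L]
    gX
  }
  list(out = out, back = if (need_grad) back else NULL)
}

#' Predict with a model
#'
#' Evaluation-mode forward pass (batch-norm running statistics, no
#' stochasticity): deterministic for fixed parameters and input.
#'
#' @param object A `fedceph_model`.
#' @param x Image array, `N x C x H x W` (or a single `C x H x W` image).
#' @param type `"logits"`, `"prob"` (softmax), or `"class"` (0-based index).
#' @param ... Unused.
#' @return Matrix `N x n_classes`, or integer vector for `type = "class"`.
#' @export
predict.fedceph_model <- function(object, x, type = c("logits", "prob", "class"), ...) {
  type <- match.arg(type)
  logits <- model_forward(object, x, training = FALSE, need_grad = FALSE)$logits
  switch(type,
         logits = logits,
         prob = softmax_rows(logits),
         class = max.col(logits, ties.method = "first") - 1L)
}

#' Extract or replace the full parameter vector of a model
#'
#' The parameter vector is the ordered, named list of every array in the
#' model state -- trainable weights and batch-norm running statistics -- in a
#' deterministic order identical across models built from the same spec.
#'
#' @param model A `fedceph_model`.
#' @return `get_parameters()`: a `parameter_vector` (named list of arrays).
#' @export
get_parameters <- function(model) {
  structure(model$params, class = "parameter_vector")
}

#' @rdname get_parameters
#' @param params A `parameter_vector` (or plain named list) shape-compatible
#'   with the model.
#' @export
set_parameters <- function(model, params) {
  params <- unclass(params)
  cur <- model$params
  if (!identical(names(params), names(cur))) {
    k <- min(length(params), length(cur))
    bad <- which(names(params)[seq_len(k)] != names(cur)[seq_len(k)])[1L]
    if (is.na(bad) || length(bad) == 0L) bad <- k + 1L
    stop(sprintf("incompatible parameter vector: name mismatch at entry %d ('%s' vs '%s')",
                 bad,
                 if (bad <= length(params)) names(params)[bad] else "<missing>",
                 if (bad <= length(cur)) names(cur)[bad] else "<missing>"),
         call. = FALSE)
  }
  for (nm in names(cur)) {
    if (!identical(dim(params[[nm]]) %||% length(params[[nm]]),
                   dim(cur[[nm]]) %||% length(cur[[nm]]))) {
      stop(sprintf("incompatible parameter vector: shape mismatch for '%s'", nm),
           call. = FALSE)
    }
  }
  model$params <- params
  model
}

#' Number of values in a parameter vector
#' @param params A `parameter_vector`.
#' @return Total count of scalar values.
#' @export
n_parameters <- function(params) sum(vapply(params, length, numeric(1)))

#' Save or load a model checkpoint
#'
#' @param model A `fedceph_model`.
#' @param path Checkpoint path (an RDS archive holding the spec and the
#'   parameter vector).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(spec = model$spec, params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  m <- build_model(obj$spec, seed = 0L)
  set_parameters(m, obj$params)
}

# Final backbone feature map (after the last batch norm + ReLU) of a single
# image, as a C x H x W array; eval mode.
final_feature_map <- function(model, x) {
  r <- model_forward(model, x, training = FALSE, need_grad = FALSE,
                     return_features = TRUE)
  stopifnot(r$N == 1L)
  rows_to_chw(r$features, r$H, r$W)
}

# Force every attention gate of a model to scale ~1 (sigmoid saturation);
# used to check that augmented heads preserve the backbone.
saturate_gates <- function(model, bias = 50) {
  p <- model$params
  for (nm in grep("^head\\.(ca|se)\\.(w1|w2)$", names(p), value = TRUE)) p[[nm]][] <- 0
  for (nm in grep("^head\\.(ca|se)\\.b2$", names(p), value = TRUE)) p[[nm]][] <- bias
  if ("head.sa.kernel" %in% names(p)) {
    p[["head.sa.kernel"]][] <- 0
    p[["head.sa.bias"]] <- bias
  }
  model$params <- p
  model
}
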