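# Numerics core for the convolutional models.
#
# Feature tensors are stored as dense matrices with N*H*W rows and C columns;
# rows are ordered image-slowest, then row, then column fastest
# (row index = ((n-1)*H + h-1)*W + w). Convolutions gather rows through
# precomputed index plans (im2col) and run as BLAS matrix products; each
# primitive returns its output together with a backward closure, so a forward
# pass accumulates a tape that is replayed in reverse for gradients.

nchw_to_rows <- function(x) {
  d <- dim(x)  # N C H W
  matrix(aperm(x, c(4L, 3L, 1L, 2L)), nrow = d[1L] * d[3L] * d[4L], ncol = d[2L])
}

rows_to_chw <- function(X, H, W) {
  # single image rows (H*W x C) -> C x H x W array
  C <- ncol(X)
  aperm(array(X, dim = c(W, H, C)), c(3L, 2L, 1L))
}

conv_out_dim <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# Index plan for a k_h x k_w window over an H x W grid, batched over N images.
# For each kernel offset, a row-index vector into the (N*H*W + 1)-row
# augmented matrix whose last row stands in for out-of-padding positions.
conv_plan <- function(H, W, kh, kw, stride, pad, N) {
  Ho <- conv_out_dim(H, kh, stride, pad)
  Wo <- conv_out_dim(W, kw, stride, pad)
  stopifnot(Ho >= 1L, Wo >= 1L)
  HW <- H * W
  dummy <- N * HW + 1L
  base_ho <- rep(seq_len(Ho), each = Wo)
  base_wo <- rep(seq_len(Wo), times = Ho)
  img_off <- (seq_len(N) - 1L) * HW
  rows <- vector("list", kh * kw)
  o <- 0L
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      o <- o + 1L
      h <- (base_ho - 1L) * stride + i - pad
      w <- (base_wo - 1L) * stride + j - pad
      invalid <- h < 1L | h > H | w < 1L | w > W
      pos <- (pmin(pmax(h, 1L), H) - 1L) * W + pmin(pmax(w, 1L), W)
      r <- as.vector(outer(pos, img_off, "+"))
      r[rep(invalid, times = N)] <- dummy
      rows[[o]] <- r
    }
  }
  list(Ho = Ho, Wo = Wo, rows = rows, dummy = dummy, n_out = N * Ho * Wo)
}

# Cached plan lookup (plans depend on layer geometry and batch size).
get_plan <- function(cache, H, W, kh, kw, stride, pad, N) {
  key <- paste(H, W, kh, kw, stride, pad, N, sep = "_")
  p <- cache[[key]]
  if (is.null(p)) {
    p <- conv_plan(H, W, kh, kw, stride, pad, N)
    cache[[key]] <- p
  }
  p
}

# Kernel array (kh, kw, Cin, Cout) <-> column-weight matrix whose row order
# matches the im2col column order (channel fastest, then kw, then kh).
kernel_to_mat <- function(k) {
  d <- dim(k)
  matrix(aperm(k, c(3L, 2L, 1L, 4L)), nrow = d[1L] * d[2L] * d[3L], ncol = d[4L])
}

mat_to_kernel <- function(m, kh, kw, cin, cout) {
  aperm(array(m, dim = c(cin, kw, kh, cout)), c(3L, 2L, 1L, 4L))
}

# General conv: X (N*H*W x Cin) -> (N*Ho*Wo x Cout). Returns out + backward.
op_conv <- function(X, kernel, plan, bias = NULL) {
  d <- dim(kernel)
  Wc <- kernel_to_mat(kernel)
  Xa <- rbind(X, 0)
  cols <- do.call(cbind, lapply(plan$rows, function(r) Xa[r, , drop = FALSE]))
  out <- cols %*% Wc
  if (!is.null(bias)) out <- out + rep(bias, each = nrow(out))
  backward <- function(gout) {
    gWc <- crossprod(cols, gout)
    gcols <- gout %*% t(Wc)
    gX <- matrix(0, nrow(X) + 1L, d[3L])
    cin <- d[3L]
    for (o in seq_along(plan$rows)) {
      idx <- ((o - 1L) * cin + 1L):(o * cin)
      r <- plan$rows[[o]]
      gX[r, ] <- gX[r, ] + gcols[, idx, drop = FALSE]
    }
    list(gx = gX[seq_len(nrow(X)), , drop = FALSE],
         gkernel = mat_to_kernel(gWc, d[1L], d[2L], d[3L], d[4L]),
         gbias = if (is.null(bias)) NULL else colSums(gout))
  }
  list(out = out, backward = backward)
}

# Pointwise (1x1, stride 1) conv fast path.
op_conv1x1 <- function(X, kernel) {
  d <- dim(kernel)
  Wm <- matrix(kernel, d[3L], d[4L])
  out <- X %*% Wm
  backward <- function(gout) {
    list(gx = gout %*% t(Wm),
         gkernel = array(crossprod(X, gout), dim = d))
  }
  list(out = out, backward = backward)
}

# column-broadcast helpers (avoid sweep()'s aperm overhead)
col_sub <- function(X, v) X - rep(v, each = nrow(X))
col_mul <- function(X, v) X * rep(v, each = nrow(X))
col_axpb <- function(X, a, b) X * rep(a, each = nrow(X)) + rep(b, each = nrow(X))

op_bn <- function(X, gamma, beta, running_mean, running_var,
                  training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    M <- nrow(X)
    mu <- colMeans(X)
    xc <- col_sub(X, mu)
    v <- colMeans(xc * xc)
    invstd <- 1 / sqrt(v + eps)
    xhat <- col_mul(xc, invstd)
    out <- col_axpb(xhat, gamma, beta)
    unbiased <- if (M > 1L) v * M / (M - 1L) else v
    new_rm <- (1 - momentum) * running_mean + momentum * mu
    new_rv <- (1 - momentum) * running_var + momentum * unbiased
    backward <- function(gout) {
      ggamma <- colSums(gout * xhat)
      gbeta <- colSums(gout)
      t1 <- col_sub(gout, colMeans(gout))
      t2 <- col_mul(xhat, colMeans(gout * xhat))
      list(gx = col_mul(t1 - t2, gamma * invstd),
           ggamma = ggamma, gbeta = gbeta)
    }
    list(out = out, backward = backward, running_mean = new_rm, running_var = new_rv)
  } else {
    invstd <- 1 / sqrt(running_var + eps)
    xhat <- col_mul(col_sub(X, running_mean), invstd)
    out <- col_axpb(xhat, gamma, beta)
    backward <- function(gout) {
      list(gx = col_mul(gout, gamma * invstd),
           ggamma = colSums(gout * xhat), gbeta = colSums(gout))
    }
    list(out = out, backward = backward,
         running_mean = running_mean, running_var = running_var)
  }
}

op_relu <- function(X) {
  mask <- X > 0
  list(out = X * mask, backward = function(gout) gout * mask)
}

op_maxpool <- function(X, plan) {
  Xa <- rbind(X, -Inf)
  cur <- Xa[plan$rows[[1L]], , drop = FALSE]
  arg <- matrix(1L, nrow(cur), ncol(cur))
  for (o in seq_along(plan$rows)[-1L]) {
    g <- Xa[plan$rows[[o]], , drop = FALSE]
    m <- g > cur
    cur[m] <- g[m]
    arg[m] <- o
  }
  backward <- function(gout) {
    gX <- matrix(0, nrow(X) + 1L, ncol(X))
    for (o in seq_along(plan$rows)) {
      m <- arg == o
      if (!any(m)) next
      contrib <- gout * m
      r <- plan$rows[[o]]
      gX[r, ] <- gX[r, ] + contrib
    }
    gX[seq_len(nrow(X)), , drop = FALSE]
  }
  list(out = cur, backward = backward)
}

op_avgpool <- function(X, plan) {
  k <- length(plan$rows)
  Xa <- rbind(X, 0)
  acc <- Xa[plan$rows[[1L]], , drop = FALSE]
  for (o in seq_along(plan$rows)[-1L]) acc <- acc + Xa[plan$rows[[o]], , drop = FALSE]
  out <- acc / k
  backward <- function(gout) {
    gX <- matrix(0, nrow(X) + 1L, ncol(X))
    gk <- gout / k
    for (o in seq_along(plan$rows)) {
      r <- plan$rows[[o]]
      gX[r, ] <- gX[r, ] + gk
    }
    gX[seq_len(nrow(X)), , drop = FALSE]
  }
  list(out = out, backward = backward)
}

# Global average pooling over the spatial plane: (N*HW x C) -> (N x C).
op_gap <- function(X, N, HW) {
  grp <- rep(seq_len(N), each = HW)
  out <- rowsum(X, grp, reorder = FALSE) / HW
  backward <- function(gout) gout[grp, , drop = FALSE] / HW
  list(out = out, backward = backward)
}

# Dense (s^2 x HW) averaging matrix for adaptive average pooling; bins in
# row-major order (bin row slow, bin column fast).
adaptive_pool_matrix <- function(H, W, s) {
  rb <- adaptive_bins(H, s)
  cb <- adaptive_bins(W, s)
  P <- matrix(0, s * s, H * W)
  k <- 0L
  for (i in seq_len(s)) {
    for (j in seq_len(s)) {
      k <- k + 1L
      cells <- as.vector(outer(cb[[j]], (rb[[i]] - 1L) * W, "+"))
      P[k, cells] <- P[k, cells] + 1 / (length(rb[[i]]) * length(cb[[j]]))
    }
  }
  P
}

# Batched spatial pyramid pooling: (N*HW x C) -> (N x C*sum(s^2)); per image
# the layout matches spp_pool(): bins fastest within channel, channels next,
# sizes concatenated in order.
op_spp <- function(X, N, H, W, sizes) {
  HW <- H * W
  C <- ncol(X)
  Ps <- lapply(sizes, function(s) adaptive_pool_matrix(H, W, s))
  pieces <- vector("list", length(sizes))
  for (k in seq_along(sizes)) {
    P <- Ps[[k]]
    s2 <- nrow(P)
    pooled <- matrix(0, N * s2, C)
    for (n in seq_len(N)) {
      pooled[(n - 1L) * s2 + seq_len(s2), ] <-
        P %*% X[(n - 1L) * HW + seq_len(HW), , drop = FALSE]
    }
    # (N*s2 x C) -> N x (s2*C), bins fastest within channel
    a <- array(pooled, dim = c(s2, N, C))
    pieces[[k]] <- t(matrix(aperm(a, c(1L, 3L, 2L)), nrow = s2 * C, ncol = N))
  }
  out <- do.call(cbind, pieces)
  backward <- function(gout) {
    gX <- matrix(0, nrow(X), C)
    col0 <- 0L
    for (k in seq_along(sizes)) {
      P <- Ps[[k]]
      s2 <- nrow(P)
      block <- gout[, col0 + seq_len(s2 * C), drop = FALSE]
      col0 <- col0 + s2 * C
      for (n in seq_len(N)) {
        gp <- matrix(block[n, ], s2, C)  # bins fastest -> s2 x C
        gX[(n - 1L) * HW + seq_len(HW), ] <-
          gX[(n - 1L) * HW + seq_len(HW), ] + crossprod(P, gp)
      }
    }
    gX
  }
  list(out = out, backward = backward)
}

op_fc <- function(X, W, b) {
  out <- X %*% W + rep(b, each = nrow(X))
  backward <- function(gout) {
    list(gx = gout %*% t(W), gW = crossprod(X, gout), gb = colSums(gout))
  }
  list(out = out, backward = backward)
}

softmax_rows <- function(z) {
  m <- apply(z, 1L, max)
  e <- exp(z - m)
  e / rowSums(e)
}

# Mean cross-entropy over the batch; gradient w.r.t. logits.
ce_loss <- function(logits, targets) {
  N <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(N), targets + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / N)
}

# ---- Adam optimizer ----

adam_init <- function(param_names) {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e$names <- param_names
  e
}

adam_step <- function(opt, params, grads, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in intersect(names(grads), opt$names)) {
    g <- grads[[nm]]
    m <- opt$m[[nm]]; if (is.null(m)) m <- g * 0
    v <- opt$v[[nm]]; if (is.null(v)) v <- g * 0
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    opt$m[[nm]] <- m
    opt$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  params
}
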