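# Independent brute-force oracles used across test files. These deliberately
# use plain loops and scalar arithmetic, not the package's vectorized paths.

rand_fmap <- function(C, H, W) array(rnorm(C * H * W), dim = c(C, H, W))

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# Channel attention by explicit loops over channels and matrix rows.
oracle_channel_attention <- function(F, p) {
  C <- dim(F)[1]
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) {
    avg[c] <- mean(F[c, , ])
    mx[c] <- max(F[c, , ])
  }
  mlp <- function(v) {
    h <- numeric(nrow(p$w1))
    for (i in seq_len(nrow(p$w1))) h[i] <- max(0, sum(p$w1[i, ] * v) + p$b1[i])
    o <- numeric(nrow(p$w2))
    for (i in seq_len(nrow(p$w2))) o[i] <- sum(p$w2[i, ] * h) + p$b2[i]
    o
  }
  oracle_sigmoid(mlp(avg) + mlp(mx))
}

# Spatial attention through a sliding-window double loop.
oracle_spatial_attention <- function(F, p) {
  C <- dim(F)[1]; H <- dim(F)[2]; W <- dim(F)[3]
  d1 <- matrix(0, H, W); d2 <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    d1[i, j] <- mean(F[, i, j])
    d2[i, j] <- max(F[, i, j])
  }
  desc <- list(d1, d2)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- p$bias
    for (di in 1:7) for (dj in 1:7) {
      ii <- i + di - 4; jj <- j + dj - 4
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        for (ch in 1:2) acc <- acc + p$kernel[di, dj, ch] * desc[[ch]][ii, jj]
      }
    }
    out[i, j] <- oracle_sigmoid(acc)
  }
  out
}

oracle_se_excite <- function(z, p) {
  h <- numeric(nrow(p$w1))
  for (i in seq_len(nrow(p$w1))) h[i] <- max(0, sum(p$w1[i, ] * z) + p$b1[i])
  o <- numeric(nrow(p$w2))
  for (i in seq_len(nrow(p$w2))) o[i] <- sum(p$w2[i, ] * h) + p$b2[i]
  oracle_sigmoid(o)
}

# Adaptive-average-pooling bins by explicit floor/ceil arithmetic.
oracle_spp <- function(F, sizes) {
  C <- dim(F)[1]; H <- dim(F)[2]; W <- dim(F)[3]
  out <- c()
  for (s in sizes) {
    for (c in seq_len(C)) {
      for (bi in 0:(s - 1)) {
        for (bj in 0:(s - 1)) {
          r0 <- floor(bi * H / s) + 1; r1 <- ceiling((bi + 1) * H / s)
          c0 <- floor(bj * W / s) + 1; c1 <- ceiling((bj + 1) * W / s)
          out <- c(out, mean(F[c, r0:r1, c0:c1]))
        }
      }
    }
  }
  out
}

# spp_pool flattens bins-within-channel per size; reorder the oracle (which
# is channel-major already) to match: it is the same layout.
oracle_spp_matching <- function(F, sizes) oracle_spp(F, sizes)

# Hand-looped sample-weighted mean of parameter vectors.
oracle_fedavg <- function(vecs, ns) {
  w <- ns / sum(ns)
  out <- numeric(length(vecs[[1]]))
  for (j in seq_along(out)) {
    acc <- 0
    for (k in seq_along(vecs)) acc <- acc + w[k] * vecs[[k]][j]
    out[j] <- acc
  }
  out
}

# One-vs-rest AUC by all-pairs counting with ties worth 1/2.
oracle_auc <- function(pos_scores, neg_scores) {
  tot <- 0
  for (a in pos_scores) for (b in neg_scores) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos_scores) * length(neg_scores))
}

# Signed angle between rays by atan2 of cross and dot products (y-up frame).
oracle_signed_angle <- function(A, N, B) {
  u <- A - N; v <- B - N
  atan2(v[1] * u[2] - v[2] * u[1], sum(u * v)) * 180 / pi
}

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}
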