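test_that("channel attention: zero params gate 0.5, pooling identity, loop oracle", {
  set.seed(1)
  F <- rand_fmap(4, 5, 6)
  p0 <- ca_params(4, r = 2, zero = TRUE)
  expect_equal(channel_attention(F, p0), rep(0.5, 4))

  # channel-constant map: avg pool equals max pool -> sigmoid(2*MLP(v))
  v <- c(-1, 0.5, 2, 7)
  Fc <- array(rep(v, 5 * 6), dim = c(4, 5, 6))
  p <- ca_params(4, r = 2, seed = 3)
  mlp <- function(x) drop(p$w2 %*% pmax(drop(p$w1 %*% x) + p$b1, 0)) + p$b2
  expect_equal(channel_attention(Fc, p), 1 / (1 + exp(-2 * mlp(v))),
               tolerance = 1e-12)

  for (i in 1:100) {
    C <- sample(2:6, 1)
    F <- rand_fmap(C, sample(1:8, 1), sample(1:8, 1))
    p <- ca_params(C, r = 1, seed = i)
    got <- channel_attention(F, p)
    expect_equal(got, oracle_channel_attention(F, p), tolerance = 1e-6)
    expect_true(all(got > 0 & got < 1))
    # invariant to any spatial permutation
    Fp <- F
    perm <- sample(dim(F)[2] * dim(F)[3])
    for (c in seq_len(C)) Fp[c, , ] <- matrix(as.vector(F[c, , ])[perm], dim(F)[2], dim(F)[3])
    expect_equal(channel_attention(Fp, p), got, tolerance = 1e-12)
  }
})

test_that("spatial attention: zero kernel gives flat 0.5, preserves H x W, matches conv oracle", {
  F <- rand_fmap(3, 9, 7)
  expect_equal(spatial_attention(F, sa_params(zero = TRUE)),
               matrix(0.5, 9, 7))
  set.seed(2)
  for (i in 1:100) {
    C <- sample(1:4, 1); H <- sample(7:12, 1); W <- sample(7:12, 1)
    F <- rand_fmap(C, H, W)
    p <- sa_params(seed = i)
    p$bias <- rnorm(1)
    got <- spatial_attention(F, p)
    expect_equal(dim(got), c(H, W))
    expect_equal(got, oracle_spatial_attention(F, p), tolerance = 1e-6)
    expect_true(all(got > 0 & got < 1))
  }
})

test_that("squeeze is the exact spatial mean; excitation matches its oracle", {
  Fc <- array(7, dim = c(3, 4, 5))
  expect_equal(se_squeeze(Fc), rep(7, 3))
  F1 <- array(0, dim = c(1, 2, 2)); F1[1, , ] <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(se_squeeze(F1), 2.5)
  set.seed(4)
  F <- rand_fmap(5, 6, 7)
  z_loop <- vapply(1:5, function(c) {
    acc <- 0
    for (i in 1:6) for (j in 1:7) acc <- acc + F[c, i, j]
    acc / 42
  }, numeric(1))
  expect_identical(se_squeeze(F), apply(F, 1, mean))
  expect_equal(se_squeeze(F), z_loop, tolerance = 1e-12)

  expect_equal(se_excite(rnorm(4), se_params(4, zero = TRUE)), rep(0.5, 4))
  # identity weights at r = 1, z = 0 -> 0.5
  pid <- se_params(3, r = 1, zero = TRUE)
  pid$w1 <- diag(3); pid$w2 <- diag(3)
  expect_equal(se_excite(rep(0, 3), pid), rep(0.5, 3))
  for (i in 1:100) {
    C <- sample(2:6, 1)
    z <- rnorm(C)
    p <- se_params(C, r = 1, seed = i)
    got <- se_excite(z, p)
    expect_equal(got, oracle_se_excite(z, p), tolerance = 1e-6)
    expect_true(all(got > 0 & got < 1))
  }
})

test_that("apply_block broadcasts multiplicatively and composes SA then SE", {
  set.seed(5)
  F <- rand_fmap(4, 6, 6)
  # zero params -> every gate 0.5 -> output is 0.5 * F
  prm <- list(ca = ca_params(4, zero = TRUE), sa = sa_params(zero = TRUE),
              se = se_params(4, zero = TRUE))
  for (blk in c("CA", "SA", "SE")) {
    expect_equal(apply_block(F, blk, prm), 0.5 * F, tolerance = 1e-12)
  }
  # saturated SE gate -> identity in the limit
  psat <- se_params(4, zero = TRUE); psat$b2[] <- 60
  expect_equal(apply_block(F, "SE", list(se = psat)), F, tolerance = 1e-8)

  # SA_SE equals the standalone composition
  prm2 <- list(sa = sa_params(seed = 9), se = se_params(4, r = 2, seed = 10))
  G <- apply_block(F, "SA", prm2)
  expect_equal(apply_block(F, "SA_SE", prm2), apply_block(G, "SE", prm2),
               tolerance = 1e-12)

  # broadcast axes: CA scales whole channels, SA scales whole positions
  a <- channel_attention(F, ca_params(4, r = 2, seed = 1))
  got <- apply_block(F, "CA", list(ca = ca_params(4, r = 2, seed = 1)))
  for (c in 1:4) expect_equal(got[c, , ], F[c, , ] * a[c], tolerance = 1e-12)

  expect_error(apply_block(F, "SA", list()), "initialized")
})

test_that("spatial pyramid pooling is fixed-length and matches the bin oracle", {
  Fc <- array(7, dim = c(2, 5, 9))
  expect_equal(spp_pool(Fc, spp_config(c(2L, 3L))), rep(7, 2 * 13))
  expect_equal(fc_input_size(1024, c(4, 8, 16)), 344064L)
  expect_equal(fc_input_size(1, 1), 1L)
  expect_equal(fc_input_size(32, c(2, 3)), 416L)
  expect_error(fc_input_size(8, integer(0)), "nonempty")
  expect_error(spp_config(c(4, 4)), "strictly increasing")

  set.seed(6)
  a <- spp_pool(rand_fmap(2, 10, 10))
  b <- spp_pool(rand_fmap(2, 13, 7))
  expect_equal(length(a), length(b))
  expect_equal(length(a), 2L * (16L + 64L + 256L))

  for (i in 1:100) {
    C <- sample(1:3, 1); H <- sample(1:64, 1); W <- sample(1:64, 1)
    F <- rand_fmap(C, H, W)
    sizes <- sort(sample(1:6, 2))
    got <- spp_pool(F, spp_config(sizes))
    expect_equal(length(got), C * sum(sizes^2))
    expect_equal(got, oracle_spp_matching(F, sizes), tolerance = 1e-6)
  }
})
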