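pv <- function(x) structure(list(w = x), class = "parameter_vector")

test_that("federated averaging is the sample-weighted mean with fault tolerance", {
  u1 <- client_update("a", pv(2.0), 1)
  u2 <- client_update("b", pv(4.0), 3)
  expect_equal(fedavg_aggregate(list(u1, u2))$w, 3.5)

  # identical parameters aggregate to themselves exactly
  same <- pv(c(0.25, -1, 3))
  agg <- fedavg_aggregate(list(client_update("a", same, 10),
                               client_update("b", same, 3)))
  expect_identical(agg$w, same$w)

  # a failed client is excluded and weights renormalized
  agg2 <- fedavg_aggregate(list(client_update("a", pv(7), 5),
                                client_update("b", NULL, 0, success = FALSE)))
  expect_equal(agg2$w, 7)
  expect_error(fedavg_aggregate(list(client_update("b", NULL, 0, success = FALSE))),
               "aggregation failure")
  expect_error(client_update("a", pv(1), 0, success = TRUE), "positive sample count")
})

test_that("aggregation matches a hand-looped weighted mean and its algebraic properties", {
  set.seed(3)
  for (rep in 1:25) {
    k <- sample(2:3, 1)
    d <- sample(1:10, 1)
    vecs <- lapply(seq_len(k), function(i) rnorm(d))
    ns <- sample(1:50, k)
    ups <- lapply(seq_len(k), function(i) client_update(i, pv(vecs[[i]]), ns[i]))
    got <- fedavg_aggregate(ups)$w
    expect_equal(got, oracle_fedavg(vecs, ns), tolerance = 1e-12)

    # permutation invariance in client order
    perm <- sample(k)
    expect_equal(fedavg_aggregate(ups[perm])$w, got, tolerance = 1e-12)

    # homogeneity: scaling every client's params scales the aggregate
    ups_s <- lapply(seq_len(k), function(i) client_update(i, pv(3 * vecs[[i]]), ns[i]))
    expect_equal(fedavg_aggregate(ups_s)$w, 3 * got, tolerance = 1e-12)

    # convexity: aggregate stays inside the element-wise envelope
    lo <- do.call(pmin, vecs); hi <- do.call(pmax, vecs)
    expect_true(all(got >= lo - 1e-12 & got <= hi + 1e-12))
  }
})

fed_spec <- model_spec(backbone_config(c(1L, 1L), 4L, 1L, input_size = 16L))

fed_dataset <- function(n, seed) {
  withr::with_seed(seed, {
    x <- array(rnorm(n * 16 * 16), c(n, 1, 16, 16))
    y <- sample(0:2, n, replace = TRUE)
    for (i in seq_len(n)) x[i, 1, , ] <- x[i, 1, , ] + (y[i] - 1) * 0.5
    structure(list(x = x, y = y), class = "ceph_dataset")
  })
}

test_that("zero rounds return the initial parameters and an empty log", {
  ds <- fed_dataset(8, 1)
  res <- run_federated(fed_spec, list(list(data = ds)), fl_config(n_rounds = 0L, seed = 4))
  expect_identical(unclass(res$params), build_model(fed_spec, seed = 4)$params)
  expect_equal(nrow(res$rounds), 0L)
})

test_that("single-client federation equals sequential local training, bit for bit", {
  ds <- fed_dataset(12, 2)
  cfg <- fl_config(n_rounds = 3L, local_epochs = 2L, seed = 11)
  tc <- train_config(batch_size = 8)
  res <- run_federated(fed_spec, list(list(data = ds)), cfg, train = tc)

  # oracle: chain train_model() round by round with the same seed stream
  m <- build_model(fed_spec, seed = cfg$seed)
  tco <- tc
  tco$epochs <- cfg$local_epochs
  tco$seed <- fedceph:::client_train_seed(cfg$seed, 1L)
  for (r in seq_len(cfg$n_rounds)) {
    m <- train_model(m, ds, tco, epoch_offset = (r - 1L) * cfg$local_epochs)$model
  }
  expect_identical(unclass(res$params), m$params)
})

test_that("identical clients with identical seeds leave the aggregate at either update", {
  ds <- fed_dataset(10, 3)
  cfg <- fl_config(n_rounds = 2L, local_epochs = 1L, seed = 5)
  tc <- train_config(batch_size = 8)
  cl <- list(data = ds, seed = 99L)
  res2 <- run_federated(fed_spec, list(cl, cl), cfg, train = tc)
  res1 <- run_federated(fed_spec, list(cl), cfg, train = tc)
  expect_equal(unclass(res2$params), unclass(res1$params), tolerance = 1e-14)
})

test_that("zero learning rate freezes every trainable parameter across rounds", {
  ds <- fed_dataset(10, 4)
  cfg <- fl_config(n_rounds = 2L, local_epochs = 2L, seed = 8)
  res <- run_federated(fed_spec, list(list(data = ds)), cfg,
                       train = train_config(lr = 0, batch_size = 8))
  init <- build_model(fed_spec, seed = 8)$params
  trainable <- grep("running_", names(init), invert = TRUE, value = TRUE)
  expect_identical(unclass(res$params)[trainable], init[trainable])
  # batch-norm running statistics do move (they ride along the vector)
  expect_false(identical(unclass(res$params), init))
})

test_that("a client that errors mid-round is excluded; survivors carry the round", {
  ds <- fed_dataset(10, 5)
  # images of the wrong size pass the nonempty precheck but fail in training
  bad <- structure(list(x = array(0, c(4, 1, 8, 8)), y = rep(0L, 4)),
                   class = "ceph_dataset")
  cfg <- fl_config(n_rounds = 1L, local_epochs = 1L, seed = 2)
  res <- run_federated(fed_spec, list(list(id = "ok", data = ds),
                                      list(id = "broken", data = bad)),
                       cfg, train = train_config(batch_size = 8))
  expect_equal(res$rounds$success, c(TRUE, FALSE))
  # all clients failing aborts the round
  expect_error(run_federated(fed_spec, list(list(data = bad)), cfg),
               "aggregation failure")
})
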