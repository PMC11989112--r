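test_that("angle sampling stays inside the trimmed class bands", {
  set.seed(1)
  for (i in 1:200) {
    a1 <- sample_angle("I", "kim", clip = 15)
    expect_true(a1 >= 0.1 && a1 <= 3.9)
    a3 <- sample_angle("III", "steiner", clip = 15)
    expect_true(a3 < 3.1 && a3 >= -15)
    a2 <- sample_angle("II", "steiner", clip = 15)
    expect_true(a2 > 5.7)
  }
  expect_error(sample_angle("II", "steiner", clip = 5), "empty angle band")
  # uniformity over the band
  x <- withr::with_seed(2, replicate(1e4, sample_angle("I", "kim", 15)))
  ks <- suppressWarnings(stats::ks.test(x, "punif", 0.1, 3.9))
  expect_gt(ks$p.value, 0.01)
})

test_that("landmark placement realizes the requested angle to 1e-9", {
  set.seed(3)
  expect_silent(g0 <- place_landmarks(0, 64, jitter = 0))
  # zero angle: A lies on ray N -> B
  v <- g0$B - g0$N; u <- g0$A - g0$N
  expect_equal(v[1] * u[2] - v[2] * u[1], 0, tolerance = 1e-9)
  expect_gt(sum(u * v), 0)

  for (i in 1:1000) {
    ang <- runif(1, -10, 10)
    g <- place_landmarks(ang, 64, jitter = 2)
    expect_equal(compute_anb_angle(g$A, g$N, g$B, y_axis = "down"), ang,
                 tolerance = 1e-9)
    pts <- rbind(g$A, g$N, g$B)
    expect_true(all(pts >= 2 & pts <= 63))
  }
})

test_that("rendering is deterministic, angle-sensitive, and can be blanked", {
  g <- withr::with_seed(4, place_landmarks(5, 64, jitter = 0))
  i1 <- withr::with_seed(9, render_image(g, 5, 64, noise = 0.1))
  i2 <- withr::with_seed(9, render_image(g, 5, 64, noise = 0.1))
  expect_identical(i1, i2)

  # mandibular contour centroid shifts anteriorly with the angle
  gp <- withr::with_seed(5, place_landmarks(10, 64, jitter = 0))
  gm <- withr::with_seed(5, place_landmarks(-10, 64, jitter = 0))
  ip <- render_image(gp, 10, 64, noise = 0, elements = "mandible")
  im <- render_image(gm, -10, 64, noise = 0, elements = "mandible")
  cx <- function(img) mean(which(img > 0, arr.ind = TRUE)[, 2])
  expect_gt(abs(cx(ip) - cx(im)), 2)

  blank <- render_image(g, 5, 64, noise = 0, elements = character(0))
  expect_equal(blank, matrix(0, 64, 64))
  expect_true(all(i1 >= 0 & i1 <= 1))
})

test_that("class counts follow largest-remainder apportionment exactly", {
  expect_equal(apportion_counts(100, c(0.46, 0.33, 0.21)), c(46L, 33L, 21L))
  expect_equal(apportion_counts(400, c(0.2, 0.22, 0.58)), c(80L, 88L, 232L))
  set.seed(6)
  for (i in 1:50) {
    r <- runif(3); r <- r / sum(r)
    n <- sample(1:500, 1)
    cnt <- apportion_counts(n, r)
    expect_equal(sum(cnt), n)
    expect_true(all(abs(cnt - n * r) < 1))
  }
})

test_that("generated datasets are self-consistent, stratified, and reproducible", {
  cfg <- synth_config(clients = list(
    a = list(n = 40L, ratios = c(0.46, 0.33, 0.21), standard = "kim"),
    b = list(n = 30L, ratios = c(0.2, 0.22, 0.58), standard = "steiner")),
    seed = 21L)
  dir1 <- withr::local_tempdir()
  man <- generate_dataset(cfg, dir1)
  expect_equal(nrow(man), 70L)
  expect_equal(unname(table(man$class[man$client_id == "a"])[skeletal_levels()]),
               apportion_counts(40, c(0.46, 0.33, 0.21)), ignore_attr = TRUE)

  # intended class always equals the label recomputed from the files on disk
  lab <- label_manifest(man[, c("image_path", "landmark_path", "client_id")],
                        standards = list(a = "kim", b = "steiner"),
                        landmark_root = dir1)
  expect_equal(lab$class, man$class)

  # split is stratified within one sample per class
  for (cid in c("a", "b")) {
    m <- man[man$client_id == cid, ]
    for (k in skeletal_levels()) {
      n_k <- sum(m$class == k)
      n_test <- sum(m$class == k & m$split == "test")
      expect_lte(abs(n_test - 0.2 * n_k), 1)
    }
  }

  # identical config regenerates identical files
  dir2 <- withr::local_tempdir()
  man2 <- generate_dataset(cfg, dir2)
  expect_equal(man2$anb, man$anb)
  expect_identical(man2$class, man$class)
  sums1 <- tools::md5sum(list.files(dir1, recursive = TRUE, full.names = TRUE))
  sums2 <- tools::md5sum(list.files(dir2, recursive = TRUE, full.names = TRUE))
  expect_identical(unname(sums1), unname(sums2))

  # landmark files exercise the 19-slot layout
  lms <- parse_landmark_file(file.path(dir1, man$landmark_path[1]), expected_n = 19)
  expect_equal(nrow(lms), 19L)
})

test_that("cross-standard disagreement records are produced on request", {
  # angles in (4, 5.7] are Class II under Kim but Class I under Steiner
  set.seed(30)
  for (i in 1:50) {
    ang <- sample_angle("II", "kim", clip = 5.6)
    expect_true(ang > 4 && ang <= 5.7)
    expect_equal(classify_skeletal(ang, "kim"), "II")
    expect_equal(classify_skeletal(ang, "steiner"), "I")
  }
})

test_that("in-memory generation skips disk but keeps the same structure", {
  cfg <- synth_config(clients = list(a = list(n = 10L, ratios = c(0.4, 0.3, 0.3),
                                              standard = "kim")), seed = 8L)
  man <- generate_dataset(cfg, write_files = FALSE)
  imgs <- attr(man, "images")
  expect_equal(length(imgs), 10L)
  expect_equal(dim(imgs[[1]]), c(64L, 64L))
  expect_equal(classify_skeletal(man$anb, "kim"), man$class)
})
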