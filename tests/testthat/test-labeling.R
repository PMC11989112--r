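test_that("landmark files parse in order, tolerating dialects and trailing lines", {
  lms <- parse_landmark_file("10,20\n30,40\n50,60", expected_n = 3)
  expect_equal(lms$x, c(10, 30, 50))
  expect_equal(lms$y, c(20, 40, 60))

  # 19-line file: A/N/B are slots 5/2/6
  lines <- sprintf("%d,%d", 100 + seq_len(21), 200 + seq_len(21))  # 2 trailing
  lms19 <- parse_landmark_file(paste(lines, collapse = "\n"), expected_n = 19)
  expect_equal(nrow(lms19), 19L)
  pts <- anb_points(lms19)
  expect_equal(pts$A, c(x = 105, y = 205))
  expect_equal(pts$N, c(x = 102, y = 202))
  expect_equal(pts$B, c(x = 106, y = 206))

  # whitespace dialect and reals
  lms_ws <- parse_landmark_file("1.5 2.5\n3 4", expected_n = 2)
  expect_equal(lms_ws$x, c(1.5, 3))

  expect_error(parse_landmark_file("10,20\nabc,40", expected_n = 2), "line 2")
  expect_error(parse_landmark_file("10,20", expected_n = 3), "truncated")
})

test_that("signed ANB angle matches its geometric definition and oracle", {
  expect_equal(compute_anb_angle(c(1, 0), c(0, 0), c(2, 0), y_axis = "up"), 0)
  expect_equal(compute_anb_angle(c(0, 1), c(0, 0), c(1, 0), y_axis = "up"), 90)
  expect_equal(compute_anb_angle(c(3, 4), c(0, 0), c(5, 0), y_axis = "up"),
               53.130102, tolerance = 1e-6)
  expect_error(compute_anb_angle(c(0, 0), c(0, 0), c(1, 0)), "degenerate")

  set.seed(11)
  for (i in 1:1000) {
    A <- runif(2, -10, 10); N <- runif(2, -10, 10); B <- runif(2, -10, 10)
    if (all(A == N) || all(B == N)) next
    ang <- compute_anb_angle(A, N, B, y_axis = "up")
    expect_equal(ang, oracle_signed_angle(A, N, B), tolerance = 1e-9)
    # rigid rotation + uniform scaling invariance
    R <- rot2(runif(1, -180, 180)); s <- runif(1, 0.1, 5)
    tr <- function(p) as.vector(s * R %*% p + c(1, -2))
    expect_equal(compute_anb_angle(tr(A), tr(N), tr(B), y_axis = "up"), ang,
                 tolerance = 1e-6)
    # reflection negates
    fl <- function(p) c(-p[1], p[2])
    expect_equal(compute_anb_angle(fl(A), fl(N), fl(B), y_axis = "up"), -ang,
                 tolerance = 1e-9)
    # pixel convention: y down on (x, y) == y up on (x, -y), exactly
    ng <- function(p) c(p[1], -p[2])
    expect_identical(compute_anb_angle(ng(A), ng(N), ng(B), y_axis = "down"), ang)
  }
})

test_that("threshold classification is exhaustive, exclusive, and matches the standards", {
  expect_equal(classify_skeletal(5.6, "kim"), "II")      # Dicle worked example
  expect_equal(classify_skeletal(3.2, "steiner"), "I")   # closed band endpoint
  expect_equal(classify_skeletal(5.7, "steiner"), "I")
  expect_equal(classify_skeletal(-2.0, "kim"), "III")
  expect_equal(classify_skeletal(5.8, "steiner"), "II")
  expect_equal(classify_skeletal(c(0, 4), "kim"), c("I", "I"))

  for (std in list(lookup_standard("kim"), lookup_standard("steiner"))) {
    grid <- sort(c(seq(-20, 20, by = 0.05), std$class1_low, std$class1_high))
    cls <- classify_skeletal(grid, std)
    expect_true(all(cls %in% skeletal_levels()))  # exactly one class each
    expect_equal(cls == "I", grid >= std$class1_low & grid <= std$class1_high)
    expect_equal(cls == "II", grid > std$class1_high)
    expect_equal(cls == "III", grid < std$class1_low)
  }
  expect_error(threshold_standard("bad", 5, 3), "strictly less")
})

test_that("class labels, codes and target indices are a bijection", {
  expect_equal(class_code(c("I", "II", "III")), 1:3)
  expect_equal(class_target_index(c("I", "II", "III")), 0:2)
  expect_equal(class_label(1:3), c("I", "II", "III"))
  expect_equal(class_label(0:2, from = "index"), c("I", "II", "III"))
  expect_error(class_code("IV"), "invalid")
})

test_that("manifest labeling assigns classes, collects errors, and is idempotent", {
  dir <- withr::local_tempdir()
  # three inline records with known angles under kim: 1 -> I, 5 -> II, -1 -> III
  mk <- function(angle) {
    g <- place_landmarks(angle, 64, jitter = 0)
    tibble::tibble(a_x = g$A[1], a_y = g$A[2], n_x = g$N[1], n_y = g$N[2],
                   b_x = g$B[1], b_y = g$B[2])
  }
  set.seed(2)
  recs <- dplyr::bind_rows(lapply(c(1, 5, -1), mk))
  man <- dplyr::bind_cols(
    tibble::tibble(image_path = paste0("img", 1:3, ".png"),
                   landmark_path = NA_character_, client_id = "dicle"),
    recs)
  lab <- label_manifest(man, standards = list(dicle = "kim"))
  expect_equal(lab$class, c("I", "II", "III"))
  counts <- label_counts(lab)
  expect_equal(sum(counts$n[counts$client_id == "overall"]), 3L)
  expect_equal(counts$n[counts$client_id == "overall"], c(1L, 1L, 1L))

  # relabeling with the same standard is idempotent
  lab2 <- label_manifest(lab, standards = list(dicle = "kim"))
  expect_equal(lab2$class, lab$class)
  expect_equal(lab2$anb, lab$anb)

  # empty manifest: empty table, no error
  empty <- label_manifest(man[0, ], standards = list(dicle = "kim"))
  expect_equal(nrow(empty), 0L)
  expect_equal(nrow(label_counts(empty)), 0L)

  # a bad record is reported, the rest proceed
  bad <- man
  bad$a_x[2] <- NA_real_
  labb <- label_manifest(bad, standards = list(dicle = "kim"))
  expect_equal(labb$class[c(1, 3)], c("I", "III"))
  expect_true(is.na(labb$class[2]))
  expect_equal(attr(labb, "errors")$row, 2L)

  # missing standard for a client errors up front
  expect_error(label_manifest(man, standards = list(other = "kim")), "dicle")
})

test_that("label counts reproduce the two-site distribution proportions", {
  # per-class totals of the larger site in the benchmark scenario
  cnt <- c(399L, 284L, 180L)
  man <- tibble::tibble(
    image_path = sprintf("i%d.png", seq_len(sum(cnt))), landmark_path = NA_character_,
    client_id = "dicle", class = rep(c("I", "II", "III"), cnt))
  counts <- label_counts(man, by_client = FALSE)
  expect_equal(counts$n, cnt)
  expect_equal(counts$proportion, cnt / sum(cnt), tolerance = 1e-12)
  expect_equal(sum(counts$proportion), 1)
  expect_equal(round(counts$proportion, 2), c(0.46, 0.33, 0.21))
})

test_that("manifests and label reports round-trip through disk", {
  dir <- withr::local_tempdir()
  man <- tibble::tibble(image_path = "a.png", landmark_path = "a.txt",
                        client_id = "c1", class = "II", anb = 5.6)
  p <- file.path(dir, "m.csv")
  write_manifest(man, p)
  back <- read_manifest(p)
  expect_equal(back$class, "II")
  expect_equal(back$anb, 5.6)

  jp <- file.path(dir, "report.json")
  write_label_report(man, jp)
  rep <- jsonlite::read_json(jp)
  expect_equal(rep$total, 1L)
  expect_equal(rep$clients$c1$counts$II, 1L)
})
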