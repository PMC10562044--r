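test_that("Otsu threshold separates a two-level image and is shift-stable", {
  img <- matrix(c(rep(0, 50), rep(100, 50)), 10)
  thr <- otsu_threshold(img)
  expect_gt(thr, 0)
  expect_lt(thr, 100)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "constant")
  # shift invariance of the induced partition (up to binning)
  set.seed(4)
  x <- matrix(sample(0:255, 400, replace = TRUE), 20)
  t0 <- otsu_threshold(x)
  t7 <- otsu_threshold(x + 7)
  expect_identical(x > t0, (x + 7) > t7)
})

test_that("Otsu equals an exhaustive between-class-variance search", {
  # oracle: maximise w0 w1 (mu0 - mu1)^2 over every candidate split value
  otsu_oracle <- function(x) {
    x <- as.vector(x)
    cand <- sort(unique(x))
    best <- -Inf; thr <- NA
    for (t in cand[-length(cand)]) {
      lo <- x[x <= t]; hi <- x[x > t]
      w0 <- length(lo) / length(x); w1 <- 1 - w0
      v <- w0 * w1 * (mean(lo) - mean(hi))^2
      if (v > best) { best <- v; thr <- t }
    }
    thr
  }
  set.seed(5)
  for (i in 1:50) {
    img <- matrix(sample(0:255, 256, replace = TRUE,
                         prob = runif(256)^2), 16)
    if (length(unique(as.vector(img))) < 2) next
    thr <- otsu_threshold(img)
    orc <- otsu_oracle(img)
    # same foreground partition
    expect_identical(img > thr, img > orc)
  }
})

test_that("roi_summary reproduces hand-computed statistics", {
  img <- matrix(0, 4, 4)
  img[1, 1:4] <- c(1, 2, 3, 4)
  m <- matrix(FALSE, 4, 4); m[1, 1:4] <- TRUE
  roi <- roi_mask(m, "toy")
  s <- roi_summary(img, roi)
  expect_equal(unname(s["mean"]), 2.5)
  expect_equal(unname(s["sd"]), sd(1:4))
  expect_equal(round(unname(s["sd"]), 4), 1.2910)
  expect_equal(unname(s["n"]), 4)
  cimg <- matrix(7, 4, 4)
  expect_equal(unname(roi_summary(cimg, roi)), c(7, 0, 4))
  expect_error(roi_mask(matrix(FALSE, 2, 2), "empty"), "fewer than 2")
})

test_that("pooled t-test matches direct numeric integration of the t density", {
  x <- c(5.1, 4.8, 5.6, 5.0, 4.7, 5.3, 5.2)
  y <- c(4.2, 4.6, 4.1, 4.9, 4.4, 4.0)
  tt <- two_sample_ttest(x, y)
  # oracle: pooled t statistic and two-sided p by integrating the t density
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t_ref <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  dens <- function(u) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + u^2 / df)^(-(df + 1) / 2)
  p_ref <- 2 * integrate(dens, abs(t_ref), Inf, rel.tol = 1e-10)$value
  expect_equal(unname(tt["t"]), t_ref, tolerance = 1e-12)
  expect_equal(unname(tt["df"]), df)
  expect_equal(unname(tt["p"]), p_ref, tolerance = 1e-6)
  # symmetry and degenerate conventions
  rev <- two_sample_ttest(y, x)
  expect_equal(unname(rev["t"]), -t_ref, tolerance = 1e-12)
  expect_equal(unname(rev["p"]), unname(tt["p"]))
  same <- two_sample_ttest(c(2, 2, 2), c(2, 2))
  expect_equal(unname(same[c("t", "p")]), c(0, 1))
  w <- two_sample_ttest(x, y, welch = TRUE)
  expect_equal(unname(w["p"]), t.test(x, y)$p.value)
})

test_that("percent difference reproduces the published rod comparisons", {
  expect_equal(percent_difference(57.96, 55.32), 4.55)
  expect_equal(percent_difference(74.95, 70.82), 5.51)
  expect_equal(percent_difference(57.96, 56.47), 2.57)
  expect_equal(percent_difference(74.95, 72.25), 3.60)
  expect_equal(percent_difference(10, 10), 0)
  expect_error(percent_difference(0, 5), "positive")
})

test_that("rod ROIs are disjoint, sized with diameter, and Otsu-derived", {
  dz <- make_derenzo(rod_spec())
  sc <- scanner_model(matrix = c(192L, 192L))
  expected <- project_expected(dz$phantom, sc, "anterior")
  full <- sample_counts(expected, seed = 9)
  proj <- project_labels(dz$labels, dz$phantom, sc, "anterior")
  rois <- rod_rois(full, proj)
  expect_length(rois, 6L)
  areas <- vapply(rois, `[[`, 1L, "n")
  expect_true(all(diff(areas) > 0))   # monotone with rod diameter
  total <- Reduce(`+`, lapply(rois, `[[`, "mask"))
  expect_true(all(total <= 1))        # pairwise disjoint
})

test_that("organ ROIs cover the expected anatomy", {
  to <- make_anthropomorphic(shape = c(84L, 56L, 90L), voxel_size = 4.4)
  sc <- scanner_model(matrix = c(96L, 96L), pixel_size = 4.4)
  rois <- organ_rois(to$labels, to$phantom, sc, "anterior")
  expect_length(rois, 4L)
  expect_gt(rois$liver$n, rois$right_kidney$n)
  expect_gt(rois$liver$n, rois$left_kidney$n)
})

test_that("significance_table flags thinned images and clears the reference", {
  set.seed(6)
  e <- expected_image(matrix(80, 24, 24), "anterior", 2.2, 300)
  full <- sample_counts(e, seed = 6)
  m <- matrix(FALSE, 24, 24); m[5:20, 5:20] <- TRUE
  roi <- roi_mask(m, "core")
  st <- significance_table(full, list(full = full,
                                      thin = thin_counts(full, 0.1, seed = 2)),
                           list(roi))
  expect_equal(nrow(st), 2L)
  expect_equal(st$p[st$image_id == "full"], 1)
  expect_false(st$significant[st$image_id == "full"])
  expect_true(st$significant[st$image_id == "thin"])
  expect_lt(abs(st$mean[st$image_id == "thin"] - 8) / 8, 0.2)
})
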