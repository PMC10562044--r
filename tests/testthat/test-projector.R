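test_that("system resolution follows the collimator model and calibration", {
  sc <- scanner_model()
  expect_equal(system_fwhm(100, sc), 9.4)
  expect_error(system_fwhm(-1, sc), "non-negative")
  d <- seq(0, 300, by = 10)
  expect_true(all(diff(system_fwhm(d, sc)) >= 0))
  # closed form at depth 0 from the calibrated intrinsic term
  r_coll_ref <- 3.0 * (58 + 100) / 58
  r_int <- sqrt(9.4^2 - r_coll_ref^2)
  expect_equal(system_fwhm(0, sc), sqrt(r_int^2 + 3.0^2))
})

test_that("projector conserves counts for a point source in air", {
  sc <- desk_scanner(c(64L, 64L))
  for (depth in c(3L, 10L, 18L)) {
    ph <- point_phantom(c(48L, 20L, 48L), depth_index = depth, activity = 2)
    img <- project_expected(ph, sc, "anterior")
    expect_equal(sum(img$values), 2 * 65 * 300, tolerance = 1e-9)
    expect_true(all(img$values >= 0))
  }
  # zero activity -> all-zero image
  z <- voxel_phantom(array(0, c(8, 8, 8)), array(0, c(8, 8, 8)), 2.2)
  expect_true(all(project_expected(z, sc)$values == 0))
})

test_that("attenuation reduces a point source by exp(-mu d)", {
  sc <- desk_scanner(c(64L, 64L))
  shape <- c(48L, 20L, 48L)
  act <- array(0, shape)
  act[24, 15, 24] <- 1
  # water only in front of the source along the anterior path
  mu <- array(0, shape)
  mu[, 1:10, ] <- MU_WATER_208KEV
  ph <- voxel_phantom(act, mu, 2.2, "shielded")
  img <- project_expected(ph, sc, "anterior")
  d_mm <- 10 * 2.2
  expect_equal(sum(img$values), 65 * 300 * exp(-MU_WATER_208KEV * d_mm),
               tolerance = 1e-6)
  # posterior path is unshielded
  img_p <- project_expected(ph, sc, "posterior")
  expect_equal(sum(img_p$values), 65 * 300, tolerance = 1e-9)
})

test_that("projector is linear in the activity map", {
  sc <- desk_scanner(c(48L, 48L))
  shape <- c(32L, 10L, 32L)
  mu <- array(MU_WATER_208KEV, shape)
  set.seed(3)
  a1 <- array(runif(prod(shape)), shape)
  a2 <- array(runif(prod(shape)), shape)
  p1 <- project_expected(voxel_phantom(a1, mu, 2.2), sc)$values
  p2 <- project_expected(voxel_phantom(a2, mu, 2.2), sc)$values
  p12 <- project_expected(voxel_phantom(2 * a1 + 3 * a2, mu, 2.2), sc)$values
  expect_equal(p12, 2 * p1 + 3 * p2, tolerance = 1e-9)
})

test_that("a projected point source recovers the calibrated system FWHM", {
  sc <- scanner_model(matrix = c(96L, 96L))
  depth_idx <- 46L  # slab centre at (46 - 0.5) * 2.2 = 100.1 mm
  ph <- point_phantom(c(64L, 50L, 64L), depth_index = depth_idx, activity = 1)
  img <- project_expected(ph, sc, "anterior")$values
  # second-moment width of the projected point-spread function
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  win <- 14L
  ii <- (pk[1] - win):(pk[1] + win)
  prof <- img[ii, pk[2]]
  mu <- sum(prof * ii) / sum(prof)
  sd_px <- sqrt(sum(prof * (ii - mu)^2) / sum(prof))
  fwhm_mm <- sd_px * 2 * sqrt(2 * log(2)) * sc$pixel_size
  expect_lt(abs(fwhm_mm - 9.4), 0.2)
})

test_that("Poisson sampling has the right mean and variance behaviour", {
  e <- expected_image(matrix(1e4, 3, 3), "anterior", 2.2, 300)
  ci <- sample_counts(e, seed = 1)
  expect_true(all(abs(ci$counts - 1e4) < 4 * 100))
  expect_equal(ci$fraction, 1)
  z <- sample_counts(expected_image(matrix(0, 4, 4), "anterior", 2.2, 300))
  expect_true(all(z$counts == 0))
  # variance/mean over repeated draws of one pixel
  set.seed(42)
  draws <- rpois(1e4, 50)
  expect_gt(var(draws) / mean(draws), 0.9)
  expect_lt(var(draws) / mean(draws), 1.1)
})

test_that("thinning is binomial, nested, and conserves counts in expectation", {
  e <- expected_image(matrix(200, 16, 16), "anterior", 2.2, 300)
  full <- sample_counts(e, seed = 2)
  same <- thin_counts(full, 1)
  expect_identical(same$counts, full$counts)
  expect_error(thin_counts(thin_counts(full, 0.5, seed = 1), 0.8),
               "cannot be created")
  set.seed(11)
  t30 <- thin_counts(full, 0.3)
  expect_true(all(t30$counts <= full$counts))
  expect_equal(t30$duration, 90)
  # empirical total over many seeds within 3 sigma of the binomial prediction
  n_tot <- sum(full$counts)
  set.seed(12)
  tots <- replicate(300, sum(thin_counts(full, 0.3)$counts))
  se <- sqrt(n_tot * 0.3 * 0.7 / 300)
  expect_lt(abs(mean(tots) - 0.3 * n_tot), 3 * se)
})

test_that("thinned Poisson counts remain Poisson with scaled mean", {
  # chi-square goodness of fit of thin(Poisson(10), 0.5) against Poisson(5)
  set.seed(123)
  n <- 1e4
  x <- rbinom(n, rpois(n, 10), 0.5)
  kmax <- 14
  obs <- tabulate(pmin(x, kmax) + 1L, kmax + 1L)
  p <- dpois(0:(kmax - 1), 5)
  p <- c(p, 1 - sum(p))
  gof <- chisq.test(obs, p = p)
  expect_gt(gof$p.value, 0.001)
})

test_that("simulate_scan produces nested fraction chains per view", {
  ph <- make_brain_like(c(32L, 32L, 24L), seed = 4L, total_activity = 5)
  sc <- desk_scanner(c(48L, 48L))
  fr <- c(0.3, 0.5, 0.9)
  scan <- simulate_scan(ph, sc, fr, seed = 7L)
  expect_setequal(names(scan), c("anterior", "posterior"))
  expect_setequal(names(scan$anterior), c("full", "0.9", "0.5", "0.3"))
  a <- scan$anterior
  expect_true(all(a[["0.3"]]$counts <= a[["0.5"]]$counts))
  expect_true(all(a[["0.5"]]$counts <= a[["0.9"]]$counts))
  expect_true(all(a[["0.9"]]$counts <= a$full$counts))
  # reproducible under the same seed
  scan2 <- simulate_scan(ph, sc, fr, seed = 7L)
  expect_identical(scan2$anterior[["0.3"]]$counts, a[["0.3"]]$counts)
  # total counts at fraction f within 4 sigma of f * full total
  n_f <- sum(a$full$counts)
  for (f in fr) {
    tol <- 4 * sqrt(n_f * f * (1 - f))
    expect_lt(abs(sum(a[[sprintf("%g", f)]]$counts) - f * n_f), tol)
  }
})

test_that("organ counts scale across time points as the retention ratios", {
  sc <- scanner_model(matrix = c(96L, 96L), pixel_size = 4.4)
  shape <- c(84L, 56L, 90L)
  t24 <- make_anthropomorphic(time_h = 24, shape = shape, voxel_size = 4.4)
  t96 <- make_anthropomorphic(time_h = 96, shape = shape, voxel_size = 4.4)
  s24 <- sample_counts(project_expected(t24$phantom, sc, "anterior"), seed = 8)
  s96 <- sample_counts(project_expected(t96$phantom, sc, "anterior"), seed = 9)
  rois <- organ_rois(t24$labels, t24$phantom, sc, "anterior")
  for (roi in rois) {
    n24 <- sum(s24$counts[roi$mask])
    n96 <- sum(s96$counts[roi$mask])
    expect_gt(n24 + n96, 1e4)
    # conditional on the total, the 96 h counts are binomial with
    # p = 0.6 / 1.6 under the configured 1.0 : 0.6 retention ratio
    bt <- binom.test(n96, n24 + n96, p = 0.6 / 1.6)
    expect_gt(bt$p.value, 1e-4)
  }
})

test_that("count image TIFF round trip preserves counts and metadata", {
  e <- expected_image(matrix(runif(64, 0, 500), 8, 8), "anterior", 2.2, 300)
  ci <- sample_counts(e, seed = 5)
  ci$fraction <- 0.4
  pre <- file.path(tempdir(), "img")
  write_count_image(ci, pre)
  back <- read_count_image(pre)
  expect_identical(back$counts, ci$counts)
  expect_equal(back$fraction, 0.4)
  expect_equal(back$view, "anterior")
})
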