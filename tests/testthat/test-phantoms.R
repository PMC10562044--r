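test_that("Shepp-Logan phantom has the standard structure", {
  expect_error(make_shepp_logan(c(-1, 10, 10)), "positive")
  ph <- make_shepp_logan(c(64L, 64L, 48L))
  expect_s3_class(ph, "voxel_phantom")
  expect_true(all(ph$activity >= 0))
  expect_equal(nrow(luscint:::shepp_logan_table()), 10L)
  # voxels outside the outer ellipsoid are exactly zero: evaluate analytic
  # membership over the full grid
  g <- luscint:::norm_grid(c(64L, 64L, 48L))
  outside <- !luscint:::ellipsoid_mask(g[[1]], g[[2]], g[[3]],
                                       0.69, 0.92, 0.81, 0, 0, 0)
  expect_true(all(ph$activity[outside] == 0))
  expect_true(all(ph$attenuation[outside] == 0))
  expect_true(all(ph$attenuation[!outside] %in% c(0, MU_WATER_208KEV)))
  # linearity of the total under scaling
  ph2 <- make_shepp_logan(c(64L, 64L, 48L), total_activity = 3 * total_activity(ph))
  expect_equal(total_activity(ph2), 3 * total_activity(ph))
})

test_that("brain-like phantom is seeded, ratio-exact, and plausibly sized", {
  a <- make_brain_like(c(48L, 48L, 40L), seed = 5L)
  b <- make_brain_like(c(48L, 48L, 40L), seed = 5L)
  expect_identical(a$activity, b$activity)
  c_ <- make_brain_like(c(48L, 48L, 40L), seed = 6L)
  expect_false(identical(a$activity, c_$activity))
  grey <- a$grey_mask
  white <- a$support & !grey
  ratio <- mean(a$activity[grey]) / mean(a$activity[white])
  expect_lt(abs(ratio - 4) / 4, 0.05)
  frac <- mean(a$support)
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.8)
})

test_that("Derenzo activity bookkeeping matches the nominal volumes", {
  dz <- make_derenzo(rod_spec(tbr = 5))
  expect_equal(total_activity(dz$phantom), 15.44, tolerance = 1e-10)
  dz20 <- make_derenzo(rod_spec(tbr = 20))
  expect_equal(total_activity(dz20$phantom), 5.21, tolerance = 1e-10)
  # exact cylinder volumes sum to 178.6 cm^3 (closed form)
  v <- derenzo_rod_volumes(rod_spec())
  expect_equal(sum(v), sum(pi * (c(10, 13, 17, 22, 28, 33) / 2)^2 * 78) / 1000)
  expect_equal(round(sum(v), 1), 178.6)
  # per-rod booking: 6 labelled rods, each with activity conc * nominal volume
  labs <- dz$labels$labels
  expect_setequal(unique(as.vector(labs)), 0:6)
  rod1 <- sum(dz$phantom$activity[labs == 1L])
  expect_equal(rod1, 10 * v[1] * 180 / sum(v) / 1000, tolerance = 1e-10)
  # overlapping rods are rejected
  expect_error(make_derenzo(rod_spec(diameters = c(200, 200))), "overlap|fit")
})

test_that("anthropomorphic phantom books organ activity from the curve", {
  tac <- default_tac()
  to <- make_anthropomorphic(tac, time_h = 24, shape = c(84L, 56L, 90L),
                             voxel_size = 4.4)
  expect_setequal(unname(to$labels$organ_names),
                  c("liver", "spleen", "right_kidney", "left_kidney"))
  expected <- sum(vapply(names(tac$values), function(o)
    tac_percent_ia(tac, o, 24) / 100 * tac$injected_activity, 1.0))
  expect_equal(total_activity(to$phantom), expected, tolerance = 1e-10)
  # organ totals scale as the configured 1.0 : 0.6 : 0.4 across time points
  to96 <- make_anthropomorphic(tac, time_h = 96, shape = c(84L, 56L, 90L),
                               voxel_size = 4.4)
  to168 <- make_anthropomorphic(tac, time_h = 168, shape = c(84L, 56L, 90L),
                                voxel_size = 4.4)
  expect_equal(total_activity(to96$phantom) / total_activity(to$phantom), 0.6,
               tolerance = 1e-10)
  expect_equal(total_activity(to168$phantom) / total_activity(to$phantom), 0.4,
               tolerance = 1e-10)
  # zero injected activity -> all-zero map
  tac0 <- time_activity_curve(tac$times, tac$values, 0)
  to0 <- make_anthropomorphic(tac0, time_h = 24, shape = c(84L, 56L, 90L),
                              voxel_size = 4.4)
  expect_true(all(to0$phantom$activity == 0))
  # time outside the curve support errors without the extrapolation flag
  expect_error(make_anthropomorphic(tac, time_h = 300, shape = c(84L, 56L, 90L),
                                    voxel_size = 4.4), "support")
  expect_silent(make_anthropomorphic(tac, time_h = 300, shape = c(84L, 56L, 90L),
                                     voxel_size = 4.4, extrapolate = TRUE))
})

test_that("training corpus has the documented size and structure", {
  spec <- training_corpus_spec(n_slices = 4L, n_duplicates = 5L, matrix = 32L)
  corpus <- make_training_corpus(spec, seed = 2L)
  expect_length(corpus, 8L)   # 2 * n_slices
  for (p in corpus) {
    expect_identical(dim(p$activity), c(32L, 5L, 32L))
    # duplicated slices are identical along the projection axis
    for (d in 2:5) expect_identical(p$activity[, d, ], p$activity[, 1, ])
  }
  acts <- vapply(corpus, total_activity, 1.0)
  # concentration mode: the brightest set hits the top of each range
  expect_equal(max(acts[1:4]), 20.6, tolerance = 1e-9)
  expect_equal(max(acts[5:8]), 31, tolerance = 1e-9)
  expect_true(all(acts > 0))
  # quoting the ranges at a larger reference grid shrinks totals by the
  # head-area ratio
  spec2 <- training_corpus_spec(n_slices = 4L, n_duplicates = 5L,
                                matrix = 32L, reference_matrix = 64L)
  acts2 <- vapply(make_training_corpus(spec2, seed = 2L), total_activity, 1.0)
  expect_equal(max(acts2[1:4]), 20.6 / 4, tolerance = 1e-9)
  # fixed concentration: a voxel with the same base intensity in every
  # slice (the head centre) carries the same activity in every set
  centre <- vapply(corpus[1:4], function(p) p$activity[16, 1, 16], 1.0)
  expect_true(all(centre > 0))
  expect_lt(diff(range(centre)) / mean(centre), 1e-9)
  # deterministic under a fixed seed
  corpus2 <- make_training_corpus(spec, seed = 2L)
  expect_identical(corpus[[6]]$activity, corpus2[[6]]$activity)
})

test_that("linear activity assignment spans the printed range endpoints", {
  spec <- training_corpus_spec(n_slices = 4L, n_duplicates = 3L, matrix = 32L,
                               reference_matrix = 32L)
  corpus <- make_training_corpus(spec, seed = 2L, activity_mode = "linear")
  acts <- vapply(corpus, total_activity, 1.0)
  expect_equal(min(acts[1:4]), 2.88, tolerance = 1e-9)
  expect_equal(max(acts[1:4]), 20.6, tolerance = 1e-9)
  expect_equal(min(acts[5:8]), 1.36, tolerance = 1e-9)
  expect_equal(max(acts[5:8]), 31, tolerance = 1e-9)
})

test_that("total_activity is additive and zero on empty phantoms", {
  z <- voxel_phantom(array(0, c(4, 4, 4)), array(0, c(4, 4, 4)), 1)
  expect_equal(total_activity(z), 0)
  a <- array(runif(64), c(4, 4, 4))
  m <- array(0, c(4, 4, 4))
  mask <- array(rep(c(TRUE, FALSE), 32), c(4, 4, 4))
  p1 <- voxel_phantom(a * mask, m, 1)
  p2 <- voxel_phantom(a * !mask, m, 1)
  expect_equal(total_activity(p1) + total_activity(p2),
               total_activity(voxel_phantom(a, m, 1)))
})

test_that("phantom NIfTI round trip preserves grids and labels", {
  dz <- make_derenzo(rod_spec(), shape = c(80L, 20L, 80L), voxel_size = 4.4)
  pre <- file.path(tempdir(), "dz")
  write_phantom(dz$phantom, pre, dz$labels)
  back <- read_phantom(pre)
  expect_equal(back$phantom$activity, dz$phantom$activity, tolerance = 1e-6)
  expect_equal(back$phantom$voxel_size, dz$phantom$voxel_size)
  expect_identical(back$labels$labels, dz$labels$labels)
})
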