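test_that("patch extraction follows the stride grid and foreground rule", {
  img <- matrix(1, 256, 256)
  ds <- extract_patches(img, img, offset = c(0L, 0L))
  expect_equal(ncol(ds$input), 100L)           # 10 tiles per axis
  expect_equal(ds$size, 25L)
  # all-zero label image yields nothing
  ds0 <- extract_patches(img, matrix(0, 256, 256), offset = c(0L, 0L))
  expect_equal(ncol(ds0$input), 0L)
  # exactly one pair from a minimal image
  one <- extract_patches(matrix(2, 25, 25), matrix(3, 25, 25))
  expect_equal(ncol(one$input), 1L)
  expect_error(extract_patches(matrix(1, 30, 30), matrix(1, 25, 25)), "shape")
  expect_error(extract_patches(matrix(1, 10, 10), matrix(1, 10, 10)), "size")
  # mixed foreground: only tiles with nonzero label survive
  lab <- matrix(0, 50, 50); lab[1:25, 1:25] <- 5
  mix <- extract_patches(matrix(1, 50, 50), lab, offset = c(0L, 0L))
  expect_equal(ncol(mix$input), 1L)
  b <- bind_patches(ds, one)
  expect_equal(ncol(b$input), 101L)
})

test_that("network construction matches the published layer accounting", {
  paper <- network_spec(n_blocks = 8, convs_per_block = 8, growth = 16,
                        low_level_filters = 16, bottleneck_filters = 256)
  expect_equal(n_weighted_layers(paper), 69L)
  desk <- network_spec()
  expect_equal(n_weighted_layers(desk),
               length(build_model(desk, 1)$weights))
  # dense connectivity: channels entering in-block layer j equal
  # block-input channels plus (j - 1) * growth
  m <- build_model(desk, 1)
  plan <- m$plan
  lidx <- 1L
  block_in <- desk$low_level_filters
  for (b in seq_len(desk$n_blocks)) {
    for (j in seq_len(desk$convs_per_block)) {
      lidx <- lidx + 1L
      cin <- luscint:::plan_in_channels(plan, lidx)
      expect_equal(cin, block_in + (j - 1L) * desk$growth)
    }
    block_in <- block_in + desk$convs_per_block * desk$growth
  }
  # bottleneck sees every preceding feature map
  expect_equal(luscint:::plan_in_channels(plan, lidx + 1L), block_in)
  # MSRA initialisation is seed-deterministic with zero biases
  m2 <- build_model(desk, 1)
  expect_identical(m$weights, m2$weights)
  expect_true(all(vapply(m$biases, function(b) all(b == 0), TRUE)))
  m3 <- build_model(desk, 2)
  expect_false(identical(m$weights, m3$weights))
})

test_that("compiled forward pass matches the pure-R reference oracle", {
  spec <- network_spec(n_blocks = 2, convs_per_block = 2, growth = 3,
                       low_level_filters = 4, bottleneck_filters = 5)
  m <- build_model(spec, 3)
  set.seed(7)
  H <- 9L; W <- 8L; N <- 2L
  x <- runif(H * W * N)
  got <- luscint:::cpp_net_forward(m$plan$layers, m$weights, m$biases,
                                   x, H, W, N)
  want <- ref_net_forward(m$plan$layers, m$weights, m$biases, x, H, W, N)
  expect_equal(got, as.vector(want), tolerance = 1e-5)
})

test_that("analytic gradients agree with double-precision finite differences", {
  spec <- network_spec(n_blocks = 1, convs_per_block = 2, growth = 3,
                       low_level_filters = 4, bottleneck_filters = 4)
  m <- build_model(spec, 11)
  set.seed(8)
  H <- 7L; W <- 7L; N <- 2L
  x <- runif(H * W * N); y <- runif(H * W * N)
  g <- luscint:::cpp_net_loss_grad(m$plan$layers, m$weights, m$biases,
                                   x, y, H, W, N)
  ref_loss <- function(wts) {
    out <- ref_net_forward(m$plan$layers, wts, m$biases, x, H, W, N)
    sqrt(mean((as.vector(out) - y)^2))
  }
  expect_equal(g$loss, ref_loss(m$weights), tolerance = 1e-6)
  eps <- 1e-5
  for (l in seq_along(m$weights)) {
    for (i in sample(length(m$weights[[l]]), 3)) {
      wp <- m$weights; wp[[l]][i] <- wp[[l]][i] + eps
      wm <- m$weights; wm[[l]][i] <- wm[[l]][i] - eps
      num <- (ref_loss(wp) - ref_loss(wm)) / (2 * eps)
      expect_equal(g$dW[[l]][i], num, tolerance = 5e-3)
    }
  }
})

test_that("training is deterministic, respects lr = 0, and learns identity", {
  set.seed(20)
  n <- 64L
  base <- matrix(rpois(625 * n, 30), 625, n)
  ds <- structure(list(input = base, label = base, size = 25L,
                       provenance = data.frame()), class = "patch_dataset")
  spec <- network_spec(n_blocks = 2, convs_per_block = 2, growth = 4,
                       low_level_filters = 4, bottleneck_filters = 8)
  # zero learning rate leaves the initial weights untouched
  m0 <- build_model(spec, 5)
  cfg0 <- train_config(iterations = 5L, learning_rate = 1e-30, seed = 5)
  t0 <- train_denoiser(m0, ds, cfg0)
  expect_equal(t0$weights, m0$weights, tolerance = 1e-12)
  expect_length(t0$loss_history, 5L)
  # identical seeds give identical loss histories
  cfg <- train_config(iterations = 40L, batch_size = 8L, seed = 9)
  r1 <- denoiser(ds, spec, cfg)
  r2 <- denoiser(ds, spec, cfg)
  expect_identical(r1$loss_history, r2$loss_history)
  # the identity task trains: loss after 500 iterations is below the
  # loss after 10 on the same toy architecture
  cfg500 <- train_config(iterations = 500L, batch_size = 8L, seed = 9)
  r500 <- denoiser(ds, spec, cfg500)
  late <- mean(tail(r500$loss_history, 20))
  early <- mean(r500$loss_history[1:10])
  expect_lt(late, early)
})

test_that("denoised output keeps shape, is non-negative, and round-trips", {
  set.seed(21)
  n <- 48L
  lab <- matrix(rpois(625 * n, 40), 625, n)
  inp <- matrix(rbinom(625 * n, lab, 0.4), 625, n)
  ds <- structure(list(input = inp, label = lab, size = 25L,
                       provenance = data.frame()), class = "patch_dataset")
  spec <- network_spec(n_blocks = 1, convs_per_block = 2, growth = 4,
                       low_level_filters = 4, bottleneck_filters = 8)
  m <- denoiser(ds, spec, train_config(iterations = 60L, batch_size = 8L, seed = 3))
  img <- count_image(matrix(rpois(31 * 37, 15), 31, 37), "anterior", 2.2, 300,
                     fraction = 0.4)
  out <- predict(m, img)
  expect_identical(dim(out$counts), dim(img$counts))
  expect_true(all(out$counts >= 0))
  expect_true(out$denoised)
  expect_error(predict(build_model(spec, 1), img), "not been trained")
  # checkpoint round trip reproduces predictions exactly
  path <- file.path(tempdir(), "model.json")
  write_denoiser(m, path)
  m2 <- read_denoiser(path)
  expect_equal(predict(m2, img)$counts, out$counts)
  expect_equal(m2$norm_const, m$norm_const)
})
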