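#' Desk-scale denoising experiment
#'
#' The reduced-size counterpart of the full training study, sized for a
#' single CPU core: simulates 30 training scenes (96 x 96 slab phantoms
#' from the two-family corpus), trains the default 2-block network for
#' `iterations` mini-batches on sub-image pairs at all nine count
#' fractions, then denoises fresh-noise scans of 20 held-out scenes and
#' reports the PSNR improvement at 30% retained counts and the mean RMSE
#' against the full-count reference across {10, 30, 50, 70, 90}%.
#'
#' @param seed integer seed driving simulation noise and training.
#' @param iterations training iterations.
#' @param spec a [network_spec()].
#' @param matrix scene matrix size.
#' @param n_train,n_holdout scenes per corpus family for training /
#'   held-out evaluation.
#' @param eval_fractions count fractions evaluated.
#' @param model optional pre-trained model (skips training).
#' @return list with `model`, `dpsnr30` (per held-out image), `rmse`
#'   (image x fraction matrix), `mean_rmse`, `monotone`, and
#'   `gain_ratio` (mean total-count ratio output/reference by fraction).
#' @export
desk_denoising_experiment <- function(seed = 1L, iterations = 2000L,
                                      spec = network_spec(), matrix = 96L,
                                      n_train = 15L, n_holdout = 10L,
                                      eval_fractions = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                      model = NULL) {
  scanner <- scanner_model(matrix = c(matrix, matrix))
  if (is.null(model)) {
    corpus <- make_training_corpus(
      training_corpus_spec(n_slices = n_train, n_duplicates = 30L,
                           matrix = matrix), seed = 1L)
    patches <- corpus_patches(corpus, scanner, seq(0.1, 0.9, by = 0.1),
                              seed = seed)
    model <- denoiser(patches, spec,
                      train_config(iterations = iterations, seed = seed))
  }
  holdout <- make_training_corpus(
    training_corpus_spec(n_slices = n_holdout, n_duplicates = 30L,
                         matrix = matrix), seed = 1L)
  nf <- length(eval_fractions)
  rmse_m <- matrix(NA_real_, length(holdout), nf,
                   dimnames = list(NULL, sprintf("%g", eval_fractions)))
  ratio_m <- rmse_m
  dpsnr30 <- numeric(length(holdout))
  for (i in seq_along(holdout)) {
    scan <- simulate_scan(holdout[[i]], scanner, eval_fractions,
                          seed = seed + 5000L + i, views = "anterior")
    full <- scan$anterior$full
    for (j in seq_len(nf)) {
      f <- eval_fractions[j]
      inp <- scan$anterior[[sprintf("%g", f)]]
      out <- predict(model, inp)
      rmse_m[i, j] <- rmse(full, out)
      ratio_m[i, j] <- sum(out$counts) / sum(full$counts)
      if (f == 0.3)
        dpsnr30[i] <- psnr(full, out) - psnr(full, inp)
    }
  }
  mean_rmse <- colMeans(rmse_m)
  list(model = model, dpsnr30 = dpsnr30, rmse = rmse_m,
       mean_rmse = mean_rmse,
       monotone = all(diff(mean_rmse) <= 1e-9),
       gain_ratio = colMeans(ratio_m))
}

#' Activity-recovery experiment
#'
#' Noise-free conjugate-view quantification of a uniform source layer
#' embedded in water slabs of several thicknesses: projects the slab
#' anterior and posterior, forms the geometric-mean estimate with the
#' analytic transmission and self-attenuation corrections, and reports
#' the relative recovery error.
#'
#' @param thicknesses_mm water slab thicknesses to test.
#' @param activity true source activity, MBq.
#' @param source_thickness_mm thickness of the uniform source layer.
#' @return data frame with columns `thickness_mm`, `recovered_mbq`,
#'   `error_pct`.
#' @export
activity_recovery_experiment <- function(thicknesses_mm = c(50, 100, 150, 200),
                                         activity = 5,
                                         source_thickness_mm = 22) {
  sc <- scanner_model(matrix = c(64L, 64L))
  mu <- MU_WATER_208KEV
  voxel <- 2.2
  rows <- lapply(thicknesses_mm, function(thick) {
    ny <- as.integer(round(thick / voxel))
    ns <- max(1L, as.integer(round(source_thickness_mm / voxel)))
    shape <- c(48L, ny, 48L)
    act <- array(0, shape)
    j0 <- (ny - ns) %/% 2 + 1L
    sl <- 9:40
    act[sl, j0:(j0 + ns - 1L), sl] <- activity / (length(sl)^2 * ns)
    ph <- voxel_phantom(act, array(mu, shape), voxel, "slab")
    ia <- sum(project_expected(ph, sc, "anterior")$values) / sc$scan_time
    ip <- sum(project_expected(ph, sc, "posterior")$values) / sc$scan_time
    m <- conjugate_view_measurement(
      ia, ip, t_factor = exp(-mu * ny * voxel), c_cal = sc$sensitivity,
      f_corr = self_attenuation_factor(mu, ns * voxel))
    a_hat <- conjugate_view_activity(m)
    data.frame(thickness_mm = thick, recovered_mbq = a_hat,
               error_pct = 100 * (a_hat - activity) / activity)
  })
  do.call(rbind, rows)
}
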