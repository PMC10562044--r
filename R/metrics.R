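#' Root-mean-square error between two images
#'
#' `sqrt(sum((ref - test)^2) / V)` over all `V` pixels.
#'
#' @param ref,test numeric matrices (or [count_image()]s) of equal shape.
#' @return RMSE in count units.
#' @export
rmse <- function(ref, test) {
  a <- as_count_matrix(ref); b <- as_count_matrix(test)
  if (!identical(dim(a), dim(b))) stop("images must share shape")
  sqrt(mean((a - b)^2))
}

#' Peak signal-to-noise ratio
#'
#' `20 log10(i_max / rmse)` in dB; `i_max` defaults to the maximum of the
#' reference image.  Identical images yield `Inf`.
#'
#' @inheritParams rmse
#' @param i_max peak intensity; defaults to `max(ref)`.
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, i_max = NULL) {
  a <- as_count_matrix(ref)
  if (is.null(i_max)) i_max <- max(a)
  r <- rmse(ref, test)
  if (r == 0) return(Inf)
  20 * log10(i_max / r)
}

#' Global structural similarity index
#'
#' Single-window SSIM computed from whole-image means, standard
#' deviations and covariance:
#' `(2 mu_x mu_y + C1)(2 s_xy + C2) / ((mu_x^2 + mu_y^2 + C1)(s_x^2 + s_y^2 + C2))`.
#' The stabilising constants default to `(0.01 L)^2` and `(0.03 L)^2`
#' with `L = max(ref)`.  A windowed mean (8x8 tiles) is available behind
#' `windowed = TRUE` for cross-checks.
#'
#' @inheritParams rmse
#' @param c1,c2 stabilising constants; `NULL` for the defaults.
#' @param L dynamic range used for the default constants.
#' @param windowed average local SSIM over non-overlapping 8x8 tiles
#'   instead of the global statistic.
#' @return SSIM in \[-1, 1\].
#' @export
ssim_global <- function(ref, test, c1 = NULL, c2 = NULL, L = NULL,
                        windowed = FALSE) {
  a <- as_count_matrix(ref); b <- as_count_matrix(test)
  if (!identical(dim(a), dim(b))) stop("images must share shape")
  if (is.null(L)) L <- max(a)
  if (is.null(c1)) c1 <- (0.01 * L)^2
  if (is.null(c2)) c2 <- (0.03 * L)^2
  one <- function(x, y) {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- sum((x - mx)^2) / (n - 1)
    vy <- sum((y - my)^2) / (n - 1)
    cxy <- sum((x - mx) * (y - my)) / (n - 1)
    (2 * mx * my + c1) * (2 * cxy + c2) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }
  if (!windowed) return(one(as.vector(a), as.vector(b)))
  w <- 8L
  vals <- c()
  for (i in seq(1L, nrow(a) - w + 1L, by = w))
    for (j in seq(1L, ncol(a) - w + 1L, by = w)) {
      ii <- i:(i + w - 1L); jj <- j:(j + w - 1L)
      vals <- c(vals, one(as.vector(a[ii, jj]), as.vector(b[ii, jj])))
    }
  mean(vals)
}

#' Whole-image fidelity report
#'
#' One row of RMSE / PSNR / SSIM per test image against a common
#' reference, ordered by count fraction.
#'
#' @param ref reference image ([count_image()] or matrix).
#' @param tests named list of test images; [count_image()] entries supply
#'   their own `fraction`, otherwise names are parsed as fractions.
#' @param i_max peak intensity for PSNR (default `max(ref)`).
#' @return data frame with columns `image_id`, `fraction`, `rmse`,
#'   `psnr_db`, `ssim`.
#' @export
metric_report <- function(ref, tests, i_max = NULL) {
  if (inherits(tests, "count_image")) tests <- list(tests)
  ids <- names(tests)
  if (is.null(ids)) ids <- sprintf("image_%d", seq_along(tests))
  fr <- vapply(seq_along(tests), function(i) {
    t <- tests[[i]]
    if (inherits(t, "count_image")) t$fraction
    else suppressWarnings(as.numeric(ids[i]))
  }, 1.0)
  out <- data.frame(image_id = ids, fraction = fr,
                    rmse = vapply(tests, function(t) rmse(ref, t), 1.0),
                    psnr_db = vapply(tests, function(t) psnr(ref, t, i_max), 1.0),
                    ssim = vapply(tests, function(t) ssim_global(ref, t), 1.0))
  out[order(out$fraction, na.last = TRUE), , drop = FALSE]
}
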