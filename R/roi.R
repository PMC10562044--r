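#' Otsu threshold of an image
#'
#' Maximises the between-class variance over a 256-bin histogram spanning
#' the image range; the returned threshold is the upper edge of the
#' optimal background bin, so `image > threshold` is the foreground.
#'
#' @param image numeric matrix or [count_image()], at least two distinct
#'   values.
#' @param n_bins histogram bins.
#' @return threshold value.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  x <- as.vector(as_count_matrix(image))
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("constant image has no Otsu threshold")
  bin <- pmin(floor((x - lo) / (hi - lo) * n_bins), n_bins - 1L)
  h <- tabulate(bin + 1L, n_bins)
  n <- length(x)
  sums <- numeric(n_bins)
  agg <- rowsum(x, bin)
  sums[as.integer(rownames(agg)) + 1L] <- agg
  w0 <- cumsum(h) / n
  s0 <- cumsum(sums) / n
  mu_t <- s0[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sb2 <- rep(-Inf, n_bins)
  sb2[valid] <- (mu_t * w0[valid] - s0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sb2)
  lo + k * (hi - lo) / n_bins
}

#' ROI mask
#'
#' @param mask logical matrix.
#' @param name label (rod diameter or organ name).
#' @return object of class `roi_mask` with pixel count `n`.
#' @export
roi_mask <- function(mask, name) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  n <- sum(mask)
  if (n <= 1L) stop("ROI '", name, "' has fewer than 2 pixels")
  structure(list(mask = mask, name = name, n = n), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI '%s': %d pixels\n", x$name, x$n))
  invisible(x)
}

#' Projected thickness maps of labelled structures
#'
#' Projects an [organ_label_map()] along the view axis onto the detector
#' grid: for each label, the summed voxel path length (mm) per pixel.
#' Uses the same voxel-to-pixel binning and posterior mirroring as
#' [project_expected()].
#'
#' @param labels an [organ_label_map()].
#' @param phantom the matching [voxel_phantom()] (for voxel size).
#' @param scanner a [scanner_model()].
#' @param view projection view.
#' @return named list of thickness matrices (mm).
#' @export
project_labels <- function(labels, phantom, scanner = scanner_model(),
                           view = c("anterior", "posterior")) {
  view <- match.arg(view)
  stopifnot(inherits(labels, "organ_label_map"),
            inherits(phantom, "voxel_phantom"))
  lab <- labels$labels
  vs <- phantom$voxel_size
  d <- dim(lab)
  px <- scanner$pixel_size
  nu <- scanner$matrix[1]; nv <- scanner$matrix[2]
  ui <- floor((seq_len(d[1]) - (d[1] + 1) / 2) * vs[1] / px + nu / 2) + 1L
  vi <- floor((seq_len(d[3]) - (d[3] + 1) / 2) * vs[3] / px + nv / 2) + 1L
  u_ok <- ui >= 1L & ui <= nu; v_ok <- vi >= 1L & vi <= nv
  lin <- outer(ui[u_ok], (vi[v_ok] - 1L) * nu, `+`)
  ids <- sort(unique(as.vector(lab))); ids <- ids[ids != 0]
  out <- list()
  for (id in ids) {
    cnt <- apply(lab[u_ok, , v_ok, drop = FALSE] == id, c(1, 3), sum)
    Tm <- matrix(0, nu, nv)
    nz <- which(cnt > 0)
    if (length(nz)) {
      agg <- rowsum(cnt[nz] * vs[2], lin[nz])
      Tm[as.integer(rownames(agg))] <- agg
    }
    if (view == "posterior") Tm <- Tm[nu:1, , drop = FALSE]
    out[[labels$organ_names[[as.character(id)]]]] <- Tm
  }
  out
}

#' Rod ROIs from the full-count image
#'
#' For each rod, applies the Otsu threshold to the full-count image
#' restricted to the rod's neighbourhood (the projected rod disc dilated
#' by `margin_mm`).  Masks are defined once on the full-count image and
#' are meant to be reused unchanged for every reduced-count and denoised
#' image, keeping the comparison paired.
#'
#' @param full_count_image the full-count [count_image()].
#' @param rod_projection named list of rod thickness maps from
#'   [project_labels()].
#' @param margin_mm dilation of the rod footprint defining the
#'   neighbourhood searched.
#' @return list of [roi_mask()]s, one per rod.
#' @export
rod_rois <- function(full_count_image, rod_projection, margin_mm = 10) {
  img <- as_count_matrix(full_count_image)
  px <- if (inherits(full_count_image, "count_image"))
    full_count_image$pixel_size else 1
  margin_px <- ceiling(margin_mm / px)
  out <- list()
  for (nm in names(rod_projection)) {
    fp <- rod_projection[[nm]] > 0
    if (!any(fp)) stop("empty projected footprint for ", nm)
    hood <- dilate_mask(fp, margin_px)
    thr <- otsu_threshold(img[hood])
    mask <- hood & img > thr
    if (!any(mask)) stop("empty Otsu mask for ", nm)
    out[[nm]] <- roi_mask(mask, nm)
  }
  out
}

# square-structuring-element binary dilation
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (di in -r:r) for (dj in -r:r) {
    ii <- idx[, 1] + di; jj <- idx[, 2] + dj
    ok <- ii >= 1 & ii <= nrow(mask) & jj >= 1 & jj <= ncol(mask)
    out[cbind(ii[ok], jj[ok])] <- TRUE
  }
  out
}

#' Organ ROIs from projected label thickness
#'
#' Replaces manually drawn organ ROIs: each organ's mask is the set of
#' pixels where its projected thickness exceeds `thickness_fraction` of
#' the organ's maximum projected thickness.
#'
#' @param labels an [organ_label_map()].
#' @param phantom the matching [voxel_phantom()].
#' @param scanner a [scanner_model()].
#' @param view projection view.
#' @param thickness_fraction threshold as a fraction of the maximum
#'   projected thickness.
#' @return list of [roi_mask()]s, one per organ.
#' @export
organ_rois <- function(labels, phantom, scanner = scanner_model(),
                       view = "anterior", thickness_fraction = 0.5) {
  th <- project_labels(labels, phantom, scanner, view)
  out <- list()
  for (nm in names(th)) {
    m <- th[[nm]] >= thickness_fraction * max(th[[nm]])
    out[[nm]] <- roi_mask(m, nm)
  }
  out
}

#' Mean, SD and pixel count within an ROI
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of the
#' pixel values inside the mask.
#'
#' @param image matrix or [count_image()].
#' @param roi a [roi_mask()].
#' @return named numeric vector `(mean, sd, n)`.
#' @export
roi_summary <- function(image, roi) {
  stopifnot(inherits(roi, "roi_mask"))
  x <- as_count_matrix(image)[roi$mask]
  c(mean = mean(x), sd = stats::sd(x), n = length(x))
}

#' Two-sample t-test on pixel intensities
#'
#' Pooled-variance Student t-test by default (Welch behind a flag),
#' two-sided.  Degenerate samples with zero pooled variance and equal
#' means return `t = 0, p = 1`.
#'
#' @param x_pixels,y_pixels numeric vectors (n >= 2 each).
#' @param welch use the Welch (unequal-variance) variant.
#' @return named vector `(t, df, p)`.
#' @export
two_sample_ttest <- function(x_pixels, y_pixels, welch = FALSE) {
  if (length(x_pixels) < 2 || length(y_pixels) < 2)
    stop("both samples need at least 2 values")
  if (stats::sd(x_pixels) == 0 && stats::sd(y_pixels) == 0) {
    if (mean(x_pixels) == mean(y_pixels))
      return(c(t = 0, df = length(x_pixels) + length(y_pixels) - 2, p = 1))
    return(c(t = Inf * sign(mean(x_pixels) - mean(y_pixels)),
             df = length(x_pixels) + length(y_pixels) - 2, p = 0))
  }
  ht <- stats::t.test(x_pixels, y_pixels, var.equal = !welch)
  c(t = unname(ht$statistic), df = unname(ht$parameter),
    p = unname(ht$p.value))
}

#' Percent difference between ROI means
#'
#' `100 |ref - test| / ref`, reported to two decimals.
#'
#' @param ref_mean reference ROI mean (> 0).
#' @param test_mean test ROI mean.
#' @return percent difference, rounded to 2 decimals.
#' @export
percent_difference <- function(ref_mean, test_mean) {
  if (any(ref_mean <= 0)) stop("reference mean must be positive")
  round(100 * abs(ref_mean - test_mean) / ref_mean, 2)
}

#' ROI significance table
#'
#' For every ROI x test image: the ROI mean and SD, and a two-sample
#' t-test of the test pixels against the reference pixels within the same
#' (fixed) ROI.
#'
#' @param ref_image reference (full-count) image.
#' @param test_images named list of images sharing the reference's shape.
#' @param rois list of [roi_mask()]s.
#' @param alpha significance level.
#' @param welch passed to [two_sample_ttest()].
#' @return data frame with one row per image x ROI: `image_id`,
#'   `fraction`, `roi`, `mean`, `sd`, `n`, `t`, `df`, `p`, `significant`.
#' @export
significance_table <- function(ref_image, test_images, rois, alpha = 0.01,
                               welch = FALSE) {
  if (inherits(test_images, "count_image")) test_images <- list(test_images)
  ids <- names(test_images)
  if (is.null(ids)) ids <- sprintf("image_%d", seq_along(test_images))
  ref <- as_count_matrix(ref_image)
  rows <- list()
  for (i in seq_along(test_images)) {
    timg <- test_images[[i]]
    tm <- as_count_matrix(timg)
    if (!identical(dim(tm), dim(ref))) stop("image shapes differ")
    frac <- if (inherits(timg, "count_image")) timg$fraction else NA_real_
    for (roi in rois) {
      xs <- tm[roi$mask]; ys <- ref[roi$mask]
      tt <- two_sample_ttest(xs, ys, welch)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = ids[i], fraction = frac, roi = roi$name,
        mean = mean(xs), sd = stats::sd(xs), n = roi$n,
        t = tt["t"], df = tt["df"], p = tt["p"],
        significant = tt["p"] < alpha, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
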