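#' Gamma-camera acquisition model
#'
#' All acquisition constants of the modelled dual-head system (medium
#' energy general purpose parallel-hole collimator): 256 x 256 matrix at
#' 2.2 mm pixels, 65 cps/MBq system sensitivity, 9.4 mm system FWHM at the
#' reference depth, 5 min scan, MEGP collimator with 3.0 mm holes, 1.05 mm
#' septa, 58 mm hole length, 540 x 400 mm useful field of view.  Scatter,
#' septal penetration and energy-window physics are folded into the
#' sensitivity constant; the depth-dependent point-spread function is
#' Gaussian.
#'
#' @param pixel_size detector pixel size, mm.
#' @param matrix length-2 integer detector matrix.
#' @param sensitivity system sensitivity, counts/s per MBq.
#' @param system_fwhm_ref system resolution FWHM (mm) at `ref_depth`.
#' @param ref_depth calibration depth for the system resolution, mm.
#' @param hole_diameter,septal_thickness,hole_length collimator geometry, mm.
#' @param scan_time acquisition duration, s.
#' @param ufov useful field of view (transaxial, axial), mm.
#' @param hole_shape_factor multiplier on the effective hole diameter
#'   (hexagonal-hole correction; 1 = none).
#' @return an object of class `scanner_model`.
#' @export
scanner_model <- function(pixel_size = 2.2, matrix = c(256L, 256L),
                          sensitivity = 65, system_fwhm_ref = 9.4,
                          ref_depth = 100, hole_diameter = 3.0,
                          septal_thickness = 1.05, hole_length = 58,
                          scan_time = 300, ufov = c(540, 400),
                          hole_shape_factor = 1) {
  stopifnot(pixel_size > 0, all(matrix > 0), sensitivity > 0,
            system_fwhm_ref > 0, ref_depth >= 0, hole_diameter > 0,
            hole_length > 0, scan_time > 0)
  if (any(matrix * pixel_size > max(ufov) * 1.1))
    stop("matrix extent exceeds the useful field of view")
  d_eff <- hole_diameter * hole_shape_factor
  l_eff <- hole_length
  r_coll_ref <- d_eff * (l_eff + ref_depth) / l_eff
  if (r_coll_ref >= system_fwhm_ref)
    stop("collimator resolution at the reference depth exceeds the system FWHM")
  intrinsic_fwhm <- sqrt(system_fwhm_ref^2 - r_coll_ref^2)
  structure(list(pixel_size = pixel_size, matrix = as.integer(matrix),
                 sensitivity = sensitivity, system_fwhm_ref = system_fwhm_ref,
                 ref_depth = ref_depth, hole_diameter = hole_diameter,
                 septal_thickness = septal_thickness, hole_length = hole_length,
                 scan_time = scan_time, ufov = ufov, d_eff = d_eff,
                 l_eff = l_eff, intrinsic_fwhm = intrinsic_fwhm),
            class = "scanner_model")
}

#' @export
print.scanner_model <- function(x, ...) {
  cat(sprintf("Gamma camera: %dx%d @ %.2f mm, %.0f cps/MBq, %.0f s scan\n",
              x$matrix[1], x$matrix[2], x$pixel_size, x$sensitivity,
              x$scan_time))
  cat(sprintf("  FWHM %.2f mm at %.0f mm depth (intrinsic %.2f mm)\n",
              x$system_fwhm_ref, x$ref_depth, x$intrinsic_fwhm))
  invisible(x)
}

#' System resolution at depth
#'
#' FWHM of the system point-spread function at source-to-collimator
#' distance `depth_mm`: `R(z) = sqrt(R_int^2 + R_coll(z)^2)` with the
#' parallel-hole collimator term `R_coll(z) = d_eff (l_eff + z) / l_eff`.
#' The intrinsic term is calibrated once so that `R(ref_depth)` equals the
#' quoted system resolution.
#'
#' @param depth_mm source depth(s) in mm, >= 0.
#' @param scanner a [scanner_model()].
#' @return FWHM in mm (vectorised over `depth_mm`).
#' @export
system_fwhm <- function(depth_mm, scanner = scanner_model()) {
  if (any(depth_mm < 0)) stop("depth must be non-negative")
  r_coll <- scanner$d_eff * (scanner$l_eff + depth_mm) / scanner$l_eff
  sqrt(scanner$intrinsic_fwhm^2 + r_coll^2)
}

#' Expected-count and count images
#'
#' `expected_image` holds real-valued expected counts from the analytic
#' projector; `count_image` holds an integer Poisson realisation (or a
#' real-valued denoised image flagged `denoised`).
#'
#' @param values,counts 2D numeric matrix.
#' @param view `"anterior"` or `"posterior"`.
#' @param pixel_size pixel size, mm.
#' @param duration acquisition duration, s.
#' @param fraction retained count fraction (1 for a full scan).
#' @return classed list.
#' @export
expected_image <- function(values, view, pixel_size, duration) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("expected counts must be finite and non-negative")
  structure(list(values = values, view = match.arg(view, c("anterior", "posterior")),
                 pixel_size = pixel_size, duration = duration),
            class = "expected_image")
}

#' @rdname expected_image
#' @param denoised logical flag for real-valued network output.
#' @export
count_image <- function(counts, view, pixel_size, duration, fraction = 1,
                        denoised = FALSE) {
  counts <- as.matrix(counts)
  if (!denoised && any(counts != round(counts)))
    stop("counts must be integers")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  structure(list(counts = counts, view = match.arg(view, c("anterior", "posterior")),
                 pixel_size = pixel_size, duration = duration,
                 fraction = fraction, denoised = denoised),
            class = "count_image")
}

#' @export
print.count_image <- function(x, ...) {
  cat(sprintf("%s count image %dx%d @ %.2f mm, fraction %.2f, %.4g counts%s\n",
              x$view, nrow(x$counts), ncol(x$counts), x$pixel_size, x$fraction,
              sum(x$counts), if (isTRUE(x$denoised)) " (denoised)" else ""))
  invisible(x)
}

#' @export
print.expected_image <- function(x, ...) {
  cat(sprintf("%s expected image %dx%d @ %.2f mm, %.4g expected counts\n",
              x$view, nrow(x$values), ncol(x$values), x$pixel_size,
              sum(x$values)))
  invisible(x)
}

# pull the pixel matrix out of any image representation
as_count_matrix <- function(x) {
  if (inherits(x, "count_image")) x$counts
  else if (inherits(x, "expected_image")) x$values
  else as.matrix(x)
}

# column-normalised 1D Gaussian convolution matrix (counts conserving)
gauss_mat <- function(n, sigma_px) {
  if (sigma_px < 1e-6) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), `-`)
  g <- exp(-d^2 / (2 * sigma_px^2))
  sweep(g, 2, colSums(g), `/`)
}

#' Analytic planar projection
#'
#' Surrogate for full photon-transport simulation: phantom voxels are
#' binned onto the detector grid (activity-conserving), each depth slab is
#' attenuated by the accumulated `exp(-sum mu dl)` from the slab centre to
#' the camera face, blurred with a Gaussian of FWHM [system_fwhm()] at the
#' slab depth, and accumulated; the result is scaled by sensitivity times
#' scan time.  Anterior and posterior views accumulate in opposite
#' directions; the posterior image is mirrored left-right to the display
#' convention.
#'
#' @param phantom a [voxel_phantom()].
#' @param scanner a [scanner_model()].
#' @param view `"anterior"` or `"posterior"`.
#' @param face_distance distance from the collimator face to the nearest
#'   phantom face, mm.
#' @param crop allow activity outside the field of view to be dropped
#'   instead of raising an error.
#' @return an [expected_image()] (matrix indexed transaxial x axial).
#' @export
project_expected <- function(phantom, scanner = scanner_model(),
                             view = c("anterior", "posterior"),
                             face_distance = 0, crop = FALSE) {
  view <- match.arg(view)
  stopifnot(inherits(phantom, "voxel_phantom"),
            inherits(scanner, "scanner_model"))
  act <- phantom$activity; mu <- phantom$attenuation
  vs <- phantom$voxel_size
  d <- dim(act)
  px <- scanner$pixel_size
  nu <- scanner$matrix[1]; nv <- scanner$matrix[2]
  # voxel centre -> detector pixel (phantom centred on the detector axis)
  ui <- floor((seq_len(d[1]) - (d[1] + 1) / 2) * vs[1] / px + nu / 2) + 1L
  vi <- floor((seq_len(d[3]) - (d[3] + 1) / 2) * vs[3] / px + nv / 2) + 1L
  u_ok <- ui >= 1L & ui <= nu
  v_ok <- vi >= 1L & vi <= nv
  if (!crop && (any(!u_ok & rowSums(act, dims = 1) > 0) ||
                any(!v_ok & apply(act, 3, sum) > 0)))
    stop("phantom activity falls outside the field of view (set crop = TRUE)")
  dy <- vs[2]
  jseq <- if (view == "anterior") seq_len(d[2]) else rev(seq_len(d[2]))
  expected <- matrix(0, nu, nv)
  cum_mu <- matrix(0, nu, nv)      # integral of mu (per mm) * dy, on pixels
  # group index arrays built once
  ug <- ui[u_ok]; vg <- vi[v_ok]
  lin <- outer(ug, (vg - 1L) * nu, `+`)     # pixel linear index per voxel
  depth0 <- face_distance
  blur_cache <- new.env(parent = emptyenv())
  for (s in seq_along(jseq)) {
    j <- jseq[s]
    a_sl <- act[u_ok, j, v_ok, drop = FALSE][, 1, ]
    m_sl <- mu[u_ok, j, v_ok, drop = FALSE][, 1, ]
    dim(a_sl) <- dim(lin); dim(m_sl) <- dim(lin)
    # scatter activity / gather attenuation onto the pixel grid
    A <- matrix(0, nu, nv)
    M <- matrix(0, nu, nv)
    nzi <- which(a_sl > 0 | m_sl > 0)
    if (length(nzi)) {
      agg_a <- rowsum(a_sl[nzi], lin[nzi])
      keys <- as.integer(rownames(agg_a))
      A[keys] <- agg_a
      agg_m <- rowsum(m_sl[nzi], lin[nzi])
      cnt <- rowsum(rep(1, length(nzi)), lin[nzi])
      M[keys] <- agg_m / cnt
    }
    atten <- exp(-(cum_mu + M * dy / 2))
    contrib <- A * atten
    if (any(contrib > 0)) {
      depth <- depth0 + (s - 0.5) * dy
      sigma <- system_fwhm(depth, scanner) / (2 * sqrt(2 * log(2))) / px
      key <- sprintf("%.6f", sigma)
      if (is.null(blur_cache[[key]]))
        blur_cache[[key]] <- list(gu = gauss_mat(nu, sigma),
                                  gv = gauss_mat(nv, sigma))
      bl <- blur_cache[[key]]
      expected <- expected + bl$gu %*% contrib %*% t(bl$gv)
    }
    cum_mu <- cum_mu + M * dy
  }
  expected <- expected * scanner$sensitivity * scanner$scan_time
  if (view == "posterior") expected <- expected[nu:1, , drop = FALSE]
  expected_image(expected, view, px, scanner$scan_time)
}

#' Poisson realisation of an expected image
#'
#' Independent Poisson draw per pixel.
#'
#' @param expected an [expected_image()].
#' @param seed optional integer seed.
#' @return a [count_image()] with `fraction = 1`.
#' @export
sample_counts <- function(expected, seed = NULL) {
  stopifnot(inherits(expected, "expected_image"))
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(stats::rpois(length(expected$values), expected$values),
                   nrow(expected$values), ncol(expected$values))
  count_image(counts, expected$view, expected$pixel_size, expected$duration,
              fraction = 1)
}

#' Binomial count thinning
#'
#' Retains each detected photon independently with probability
#' `fraction / counts$fraction`; statistically equivalent to a scan of
#' duration scaled by `fraction`.
#'
#' @param counts a [count_image()].
#' @param fraction target retained fraction of the *full* scan, must not
#'   exceed the image's current fraction.
#' @param seed optional integer seed.
#' @return a [count_image()] with the new `fraction`.
#' @export
thin_counts <- function(counts, fraction, seed = NULL) {
  stopifnot(inherits(counts, "count_image"))
  if (isTRUE(counts$denoised)) stop("cannot thin a denoised (real-valued) image")
  if (fraction <= 0 || fraction > counts$fraction)
    stop("fraction must be in (0, current fraction]; counts cannot be created")
  if (!is.null(seed)) set.seed(seed)
  p <- fraction / counts$fraction
  thinned <- matrix(stats::rbinom(length(counts$counts), counts$counts, p),
                    nrow(counts$counts), ncol(counts$counts))
  count_image(thinned, counts$view, counts$pixel_size,
              counts$duration * p, fraction = fraction)
}

#' Simulate a full scan with nested reduced-count versions
#'
#' One full-count Poisson realisation per view plus a nested thinning
#' chain: each reduced-count image is thinned from the next-larger
#' fraction, so count sets are pixelwise monotone (the list-mode
#' subsampling interpretation of scan-time reduction).
#'
#' @param phantom a [voxel_phantom()].
#' @param scanner a [scanner_model()].
#' @param fractions count fractions in (0, 1).
#' @param seed integer seed; each view consumes an independent stream.
#' @param views character vector of views to simulate.
#' @param face_distance passed to [project_expected()].
#' @return nested list `views -> c("full", fractions)` of
#'   [count_image()]s, with the [expected_image()]s attached as attribute
#'   `"expected"`.
#' @export
simulate_scan <- function(phantom, scanner = scanner_model(),
                          fractions = seq(0.1, 0.9, by = 0.1), seed = 1L,
                          views = c("anterior", "posterior"),
                          face_distance = 0) {
  if (any(fractions <= 0 | fractions >= 1)) stop("fractions must lie in (0, 1)")
  fractions <- sort(unique(fractions), decreasing = TRUE)
  out <- list()
  expected <- list()
  for (k in seq_along(views)) {
    v <- views[k]
    exp_img <- project_expected(phantom, scanner, v, face_distance)
    expected[[v]] <- exp_img
    set.seed(seed + (k - 1L))
    imgs <- list(full = sample_counts(exp_img))
    prev <- imgs$full
    for (f in fractions) {
      prev <- thin_counts(prev, f)
      imgs[[sprintf("%g", f)]] <- prev
    }
    out[[v]] <- imgs
  }
  attr(out, "expected") <- expected
  out
}
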