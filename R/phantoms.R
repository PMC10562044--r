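#' Linear attenuation coefficient of water at 208 keV
#'
#' Default used for all water-equivalent attenuation maps, in 1/mm
#' (NIST-interpolated value for the 208 keV Lu-177 gamma line).
#' @export
MU_WATER_208KEV <- 0.0136

#' Voxel phantom container
#'
#' Co-registered activity (MBq per voxel) and linear-attenuation (1/mm)
#' grids on a common voxel lattice.  Axes are (x, y, z) with z axial;
#' planar projections are taken along y (anterior camera on the -y side).
#'
#' @param activity 3D non-negative array, MBq per voxel.
#' @param attenuation 3D non-negative array, 1/mm, same shape.
#' @param voxel_size length-3 numeric (dx, dy, dz) in mm.
#' @param name label.
#' @return an object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(activity, attenuation, voxel_size, name = "phantom") {
  activity <- as.array(activity); attenuation <- as.array(attenuation)
  if (!identical(dim(activity), dim(attenuation)))
    stop("activity and attenuation grids must share shape")
  if (length(dim(activity)) != 3L) stop("phantom grids must be 3D")
  if (any(activity < 0)) stop("activity must be non-negative")
  if (any(attenuation < 0)) stop("attenuation must be non-negative")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(activity = activity, attenuation = attenuation,
                 voxel_size = voxel_size, name = name),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf("Voxel phantom '%s': %d x %d x %d voxels of %.2f x %.2f x %.2f mm\n",
              x$name, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  total activity %.4g MBq\n", total_activity(x)))
  invisible(x)
}

#' Total activity of a phantom
#' @param phantom a [voxel_phantom()].
#' @return total activity in MBq.
#' @export
total_activity <- function(phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  sum(phantom$activity)
}

#' Organ / rod label map
#'
#' @param labels 3D integer array (0 = background) matching its phantom.
#' @param organ_names named character vector mapping label id to name,
#'   e.g. `c("1" = "liver")`.
#' @return an object of class `organ_label_map`.
#' @export
organ_label_map <- function(labels, organ_names) {
  labels <- as.array(labels)
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids != 0]
  if (!all(as.character(ids) %in% names(organ_names)))
    stop("every nonzero label needs a name")
  structure(list(labels = labels, organ_names = organ_names),
            class = "organ_label_map")
}

# normalised grid coordinates in [-1, 1] along each axis
norm_grid <- function(shape) {
  lapply(seq_along(shape), function(a)
    (seq_len(shape[a]) - (shape[a] + 1) / 2) * 2 / shape[a])
}

# 3D Shepp-Logan ellipsoid table ("modified" intensities); columns:
# a, b, c, x0, y0, z0, phi (deg, about z), A
shepp_logan_table <- function() {
  matrix(c(
    0.6900, 0.9200, 0.810,  0.00,  0.0000,  0.00,   0,  1.00,
    0.6624, 0.8740, 0.780,  0.00, -0.0184,  0.00,   0, -0.80,
    0.1100, 0.3100, 0.220,  0.22,  0.0000,  0.00, -18, -0.20,
    0.1600, 0.4100, 0.280, -0.22,  0.0000,  0.00,  18, -0.20,
    0.2100, 0.2500, 0.410,  0.00,  0.3500, -0.15,   0,  0.10,
    0.0460, 0.0460, 0.050,  0.00,  0.1000,  0.25,   0,  0.10,
    0.0460, 0.0460, 0.050,  0.00, -0.1000,  0.25,   0,  0.10,
    0.0460, 0.0230, 0.050, -0.08, -0.6050,  0.00,   0,  0.10,
    0.0230, 0.0230, 0.020,  0.00, -0.6060,  0.00,   0,  0.10,
    0.0230, 0.0460, 0.020,  0.06, -0.6050,  0.00,   0,  0.10),
    ncol = 8, byrow = TRUE,
    dimnames = list(NULL, c("a", "b", "c", "x0", "y0", "z0", "phi", "A")))
}

ellipsoid_mask <- function(gx, gy, gz, a, b, c_, x0, y0, z0, phi_deg = 0) {
  phi <- phi_deg * pi / 180
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  X <- array(rep(gx, times = ny * nz), c(nx, ny, nz)) - x0
  Y <- array(rep(rep(gy, each = nx), times = nz), c(nx, ny, nz)) - y0
  Z <- array(rep(gz, each = nx * ny), c(nx, ny, nz)) - z0
  xr <- X * cos(phi) + Y * sin(phi)
  yr <- -X * sin(phi) + Y * cos(phi)
  (xr / a)^2 + (yr / b)^2 + (Z / c_)^2 <= 1
}

#' Shepp-Logan head phantom
#'
#' Standard 10-ellipsoid 3D Shepp-Logan phantom with the modified
#' (non-negative) intensity set mapped to activity; the attenuation map is
#' water inside the outer head ellipsoid and zero outside.
#'
#' @param shape length-3 integer grid shape.
#' @param voxel_size voxel size in mm (scalar or length 3); the head is
#'   scaled to fill the grid.
#' @param total_activity optional total activity (MBq) to scale to.
#' @param mu_water water attenuation coefficient, 1/mm.
#' @param z_extent fraction of the normalised z range covered by the grid
#'   (values < 1 crop to central, non-empty slices).
#' @return a [voxel_phantom()].
#' @export
make_shepp_logan <- function(shape = c(128L, 128L, 96L), voxel_size = 2.2,
                             total_activity = NULL,
                             mu_water = MU_WATER_208KEV, z_extent = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0)) stop("shape must be 3 positive integers")
  g <- norm_grid(shape)
  g[[3]] <- g[[3]] * z_extent
  tab <- shepp_logan_table()
  act <- array(0, shape)
  for (e in seq_len(nrow(tab))) {
    m <- ellipsoid_mask(g[[1]], g[[2]], g[[3]], tab[e, "a"], tab[e, "b"],
                        tab[e, "c"], tab[e, "x0"], tab[e, "y0"], tab[e, "z0"],
                        tab[e, "phi"])
    act[m] <- act[m] + tab[e, "A"]
  }
  act[act < 0] <- 0
  head <- ellipsoid_mask(g[[1]], g[[2]], g[[3]], tab[1, "a"], tab[1, "b"],
                         tab[1, "c"], tab[1, "x0"], tab[1, "y0"], tab[1, "z0"])
  if (!is.null(total_activity) && sum(act) > 0)
    act <- act * (total_activity / sum(act))
  voxel_phantom(act, ifelse(head, mu_water, 0), voxel_size, "shepp_logan")
}

#' Parametric brain-like phantom
#'
#' Synthetic stand-in for a licensed brain phantom: a head-shaped support
#' containing folded high-activity ("grey") and low-activity ("white")
#' compartments generated from a seeded band-limited random field.  The
#' grey:white activity ratio is exact by construction.
#'
#' @param shape length-3 integer grid shape.
#' @param seed integer seed; the same seed reproduces the same phantom.
#' @param ratio grey:white activity concentration ratio.
#' @param n_waves number of random cosine components in the folding field.
#' @inheritParams make_shepp_logan
#' @return a [voxel_phantom()].
#' @export
make_brain_like <- function(shape = c(128L, 128L, 96L), seed = 1L,
                            voxel_size = 2.2, ratio = 4,
                            total_activity = NULL,
                            mu_water = MU_WATER_208KEV, n_waves = 30L,
                            z_extent = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0)) stop("shape must be 3 positive integers")
  set.seed(seed)
  g <- norm_grid(shape)
  g[[3]] <- g[[3]] * z_extent
  support <- ellipsoid_mask(g[[1]], g[[2]], g[[3]], 0.85, 0.90, 0.80, 0, 0, 0)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  X <- array(rep(g[[1]], times = ny * nz), shape)
  Y <- array(rep(rep(g[[2]], each = nx), times = nz), shape)
  Z <- array(rep(g[[3]], each = nx * ny), shape)
  field <- array(0, shape)
  for (k in seq_len(n_waves)) {
    f <- stats::runif(3, 1.5, 5)
    s <- sample(c(-1, 1), 3, replace = TRUE)
    ph <- stats::runif(1, 0, 2 * pi)
    field <- field + cos(pi * (s[1] * f[1] * X + s[2] * f[2] * Y +
                               s[3] * f[3] * Z) + ph)
  }
  thr <- stats::median(field[support])
  grey <- support & field > thr
  act <- array(0, shape)
  act[support] <- 1
  act[grey] <- ratio
  if (!is.null(total_activity) && sum(act) > 0)
    act <- act * (total_activity / sum(act))
  ph <- voxel_phantom(act, ifelse(support, mu_water, 0), voxel_size, "brain_like")
  ph$grey_mask <- grey
  ph$support <- support
  ph
}

#' Derenzo rod specification
#'
#' @param diameters rod diameters in mm (one rod per diameter).
#' @param height rod height in mm.
#' @param phantom_diameter cylinder diameter of the phantom body, mm.
#' @param rod_concentration rod activity concentration, MBq/kg.
#' @param tbr target-to-background concentration ratio (>= 1).
#' @return an object of class `rod_spec`.
#' @export
rod_spec <- function(diameters = c(10, 13, 17, 22, 28, 33), height = 78,
                     phantom_diameter = 340, rod_concentration = 10, tbr = 5) {
  stopifnot(all(diameters > 0), height > 0, phantom_diameter > 0,
            rod_concentration >= 0, tbr >= 1)
  structure(list(diameters = diameters, height = height,
                 phantom_diameter = phantom_diameter,
                 rod_concentration = rod_concentration, tbr = tbr),
            class = "rod_spec")
}

#' Exact cylinder volumes of the Derenzo rods
#' @param spec a [rod_spec()].
#' @return numeric vector of rod volumes in cm^3.
#' @export
derenzo_rod_volumes <- function(spec = rod_spec()) {
  pi * (spec$diameters / 2)^2 * spec$height / 1000
}

#' Derenzo hot-rod phantom
#'
#' Flat cylindrical phantom imaged face-on: the cylinder axis (and the
#' rods) run along the anteroposterior projection axis, so the planar
#' view shows the rod pattern.  One rod per diameter, placed on a ring.
#' Activity is booked by nominal volumes (water density 1 g/cm^3): the
#' rods share `rod_total_volume` cm^3 at `rod_concentration` MBq/kg,
#' pro-rated by their exact cylinder volumes, and the background holds
#' `(phantom_volume - rod_total_volume)` cm^3 at `rod_concentration/tbr`,
#' so the phantom total is independent of voxelisation.  With the default
#' nominal volumes (180 and 7000 cm^3) the totals are 15.44 MBq at 5:1
#' and 5.21 MBq at 20:1 target-to-background ratio.
#'
#' @param spec a [rod_spec()].
#' @param shape length-3 integer grid shape.
#' @param voxel_size voxel size in mm.
#' @param rod_total_volume nominal total rod volume, cm^3.
#' @param phantom_volume nominal phantom volume, cm^3.
#' @param ring_radius radius of the rod-centre ring, mm.
#' @param mu_water water attenuation, 1/mm.
#' @return list with elements `phantom` ([voxel_phantom()]) and
#'   `labels` ([organ_label_map()]; rod k labelled k).
#' @export
make_derenzo <- function(spec = rod_spec(), shape = c(160L, 36L, 160L),
                         voxel_size = 2.2, rod_total_volume = 180,
                         phantom_volume = 7000, ring_radius = NULL,
                         mu_water = MU_WATER_208KEV) {
  shape <- as.integer(shape)
  voxel_size <- if (length(voxel_size) == 1L) rep(voxel_size, 3L) else voxel_size
  R <- spec$phantom_diameter / 2
  nrod <- length(spec$diameters)
  if (is.null(ring_radius)) ring_radius <- 0.56 * R
  ang <- (seq_len(nrod) - 1) * 2 * pi / nrod
  cx <- ring_radius * cos(ang); cy <- ring_radius * sin(ang)
  radii <- spec$diameters / 2
  if (any(ring_radius + radii > R))
    stop("rods do not fit inside the phantom diameter")
  for (i in seq_len(nrod - 1)) for (j in (i + 1):nrod) {
    d <- sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2)
    if (d < radii[i] + radii[j]) stop("overlapping rods")
  }
  gx <- (seq_len(shape[1]) - (shape[1] + 1) / 2) * voxel_size[1]
  gy <- (seq_len(shape[2]) - (shape[2] + 1) / 2) * voxel_size[2]
  gz <- (seq_len(shape[3]) - (shape[3] + 1) / 2) * voxel_size[3]
  if (2 * R > shape[1] * voxel_size[1] || 2 * R > shape[3] * voxel_size[3] ||
      spec$height > shape[2] * voxel_size[2])
    stop("grid too small for the phantom; increase shape or voxel_size")
  nx <- shape[1]; ny <- shape[2]
  # cylinder axis along y (the projection axis); rod pattern in (x, z)
  inside_xz <- outer(gx^2, gz^2, `+`) <= R^2
  iny <- abs(gy) <= spec$height / 2
  body <- aperm(array(rep(inside_xz, ny), c(nx, shape[3], ny)), c(1, 3, 2)) &
    rep(rep(iny, each = nx), times = shape[3])
  lab2d <- matrix(0L, nx, shape[3])
  for (k in seq_len(nrod)) {
    d2 <- outer((gx - cx[k])^2, (gz - cy[k])^2, `+`)
    lab2d[d2 <= radii[k]^2] <- k
  }
  labels <- aperm(array(rep(lab2d, ny), c(nx, shape[3], ny)), c(1, 3, 2))
  labels[!body] <- 0L
  v_exact <- derenzo_rod_volumes(spec)
  v_nom <- v_exact * rod_total_volume / sum(v_exact)       # cm^3, booked
  rod_act <- spec$rod_concentration * v_nom / 1000          # MBq (1 g/cm^3)
  bkg_act <- spec$rod_concentration / spec$tbr *
    (phantom_volume - rod_total_volume) / 1000
  act <- array(0, shape)
  nbkg <- sum(body & labels == 0L)
  act[body & labels == 0L] <- bkg_act / nbkg
  for (k in seq_len(nrod)) {
    vox <- labels == k
    if (!any(vox)) stop("rod ", k, " has no voxels; refine the grid")
    act[vox] <- rod_act[k] / sum(vox)
  }
  phantom <- voxel_phantom(act, ifelse(body, mu_water, 0), voxel_size,
                           sprintf("derenzo_tbr%g", spec$tbr))
  nm <- stats::setNames(sprintf("rod_%gmm", spec$diameters),
                        as.character(seq_len(nrod)))
  list(phantom = phantom, labels = organ_label_map(labels, nm))
}

#' Organ time-activity curves
#'
#' Percent-injected-activity retention curves per organ.
#'
#' @param times sampling times post injection, hours, strictly increasing.
#' @param values named list (or matrix with organ rownames) of %IA values
#'   per organ at `times`.
#' @param injected_activity injected activity, MBq.
#' @return an object of class `time_activity_curve`.
#' @export
time_activity_curve <- function(times, values, injected_activity) {
  stopifnot(all(diff(times) > 0), injected_activity >= 0)
  if (is.matrix(values)) values <- as.list(as.data.frame(t(values)))
  stopifnot(all(vapply(values, length, 1L) == length(times)))
  v <- do.call(rbind, values)
  if (any(v < 0) || any(v > 100)) stop("%IA values must lie in [0, 100]")
  structure(list(times = times, values = values,
                 injected_activity = injected_activity),
            class = "time_activity_curve")
}

#' Default torso time-activity curves
#'
#' Liver, spleen and kidney retention sampled at 24/96/168 h with every
#' organ decaying in the proportion 1.0 : 0.6 : 0.4 across the three time
#' points, so that the 96 h full-count scan carries 60% and the 168 h scan
#' 40% of the 24 h counts.  The 24 h retention values are calibrated so
#' that a 5-min planar scan of the default torso yields organ ROI count
#' levels in the regime typical of post-therapy Lu-177 imaging
#' (roughly 60-120 counts per pixel).
#'
#' @param injected_activity injected activity, MBq.
#' @return a [time_activity_curve()].
#' @export
default_tac <- function(injected_activity = 7400) {
  r <- c(1, 0.6, 0.4)
  time_activity_curve(
    times = c(24, 96, 168),
    values = list(liver = 0.57 * r, spleen = 0.18 * r,
                  right_kidney = 0.27 * r, left_kidney = 0.25 * r),
    injected_activity = injected_activity)
}

#' Percent injected activity at a time point
#'
#' Linear interpolation within the observed support of the curve.
#'
#' @param tac a [time_activity_curve()].
#' @param organ organ name.
#' @param time_h time post injection, hours.
#' @param extrapolate allow constant extrapolation outside the support.
#' @return %IA value.
#' @export
tac_percent_ia <- function(tac, organ, time_h, extrapolate = FALSE) {
  stopifnot(inherits(tac, "time_activity_curve"))
  v <- tac$values[[organ]]
  if (is.null(v)) stop("unknown organ: ", organ)
  if (!extrapolate &&
      (time_h < min(tac$times) - 1e-9 || time_h > max(tac$times) + 1e-9))
    stop("time outside the curve support (set extrapolate = TRUE to clamp)")
  stats::approx(tac$times, v, xout = time_h, rule = 2)$y
}

# Organ ellipsoids (mm): centres and semi-axes chosen so that the four
# source organs project onto the anterior view without mutual overlap,
# as manual planar-dosimetry ROIs assume.
default_organ_params <- function() {
  data.frame(
    name = c("liver", "spleen", "right_kidney", "left_kidney"),
    cx = c(-55, 95, -55, 55), cy = c(-10, 20, 52, 52),
    cz = c(58, 64, -42, -42),
    ax = c(78, 30, 25, 25), ay = c(58, 25, 20, 20), az = c(48, 40, 42, 42))
}

#' Parametric anthropomorphic torso phantom
#'
#' Synthetic stand-in for a licensed anthropomorphic phantom: an
#' elliptical-cylinder body with ellipsoidal liver, spleen and kidneys.
#' Each organ's activity is its time-activity-curve value at `time_h`
#' times the injected activity, distributed uniformly over the organ;
#' soft tissue is approximated as water.
#'
#' @param tac a [time_activity_curve()].
#' @param time_h imaging time post injection, hours.
#' @param shape length-3 integer grid shape.
#' @param voxel_size voxel size in mm.
#' @param organ_params data frame of organ ellipsoids (name, centre
#'   cx/cy/cz and semi-axes ax/ay/az in mm); overlaps resolve to the
#'   earlier row.
#' @param extrapolate passed to [tac_percent_ia()].
#' @param mu_water water attenuation, 1/mm.
#' @return list with elements `phantom` and `labels`.
#' @export
make_anthropomorphic <- function(tac = default_tac(), time_h = 24,
                                 shape = c(168L, 110L, 180L), voxel_size = 2.2,
                                 organ_params = default_organ_params(),
                                 extrapolate = FALSE,
                                 mu_water = MU_WATER_208KEV) {
  shape <- as.integer(shape)
  voxel_size <- if (length(voxel_size) == 1L) rep(voxel_size, 3L) else voxel_size
  gx <- (seq_len(shape[1]) - (shape[1] + 1) / 2) * voxel_size[1]
  gy <- (seq_len(shape[2]) - (shape[2] + 1) / 2) * voxel_size[2]
  gz <- (seq_len(shape[3]) - (shape[3] + 1) / 2) * voxel_size[3]
  a <- 0.92 * shape[1] * voxel_size[1] / 2
  b <- 0.92 * shape[2] * voxel_size[2] / 2
  nx <- shape[1]; ny <- shape[2]
  body_xy <- outer((gx / a)^2, (gy / b)^2, `+`) <= 1
  body <- array(body_xy, shape)
  labels <- array(0L, shape)
  X <- array(rep(gx, times = ny * shape[3]), shape)
  Y <- array(rep(rep(gy, each = nx), times = shape[3]), shape)
  Z <- array(rep(gz, each = nx * ny), shape)
  for (k in seq_len(nrow(organ_params))) {
    p <- organ_params[k, ]
    m <- ((X - p$cx) / p$ax)^2 + ((Y - p$cy) / p$ay)^2 +
      ((Z - p$cz) / p$az)^2 <= 1
    labels[m & body & labels == 0L] <- k
  }
  act <- array(0, shape)
  for (k in seq_len(nrow(organ_params))) {
    pia <- tac_percent_ia(tac, organ_params$name[k], time_h, extrapolate)
    a_org <- pia / 100 * tac$injected_activity
    vox <- labels == k
    if (!any(vox)) stop("organ ", organ_params$name[k], " has no voxels")
    act[vox] <- a_org / sum(vox)
  }
  phantom <- voxel_phantom(act, ifelse(body, mu_water, 0), voxel_size,
                           sprintf("torso_%gh", time_h))
  nm <- stats::setNames(organ_params$name,
                        as.character(seq_len(nrow(organ_params))))
  list(phantom = phantom, labels = organ_label_map(labels, nm))
}

#' Training-corpus specification
#'
#' @param n_slices axial slices taken per base phantom.
#' @param n_duplicates copies per slice forming one slab set.
#' @param matrix in-plane matrix size.
#' @param activity_range_a (min, max) total activity in MBq for the
#'   Shepp-Logan family, quoted at `reference_matrix` resolution.
#' @param activity_range_b (min, max) total activity for the brain-like
#'   family, quoted at `reference_matrix` resolution.
#' @param reference_matrix matrix size at which the activity ranges are
#'   quoted (defaults to `matrix`).  When `matrix` differs, assigned
#'   totals are rescaled by the head-area ratio
#'   `(matrix / reference_matrix)^2`, which preserves per-pixel count
#'   statistics when shrinking the grid.
#' @return an object of class `training_corpus_spec`.
#' @export
training_corpus_spec <- function(n_slices = 150L, n_duplicates = 30L,
                                 matrix = 256L,
                                 activity_range_a = c(2.88, 20.6),
                                 activity_range_b = c(1.36, 31),
                                 reference_matrix = matrix) {
  stopifnot(n_slices >= 1, n_duplicates >= 1, matrix >= 1,
            all(activity_range_a > 0), all(activity_range_b > 0),
            reference_matrix >= 1)
  structure(list(n_slices = as.integer(n_slices),
                 n_duplicates = as.integer(n_duplicates),
                 matrix = as.integer(matrix),
                 activity_range_a = activity_range_a,
                 activity_range_b = activity_range_b,
                 reference_matrix = as.integer(reference_matrix)),
            class = "training_corpus_spec")
}

#' Generate the training corpus of slab phantoms
#'
#' From each base phantom (Shepp-Logan and the parametric brain), takes
#' `n_slices` central axial slices and duplicates each `n_duplicates`
#' times along the projection (anteroposterior) axis to form one
#' `matrix` x `n_duplicates` x `matrix` slab phantom per slice
#' (`2 * n_slices` sets in total).
#'
#' Per-set total activity is assigned in one of two modes.  The default,
#' `"concentration"`, fills every slice at one fixed activity
#' concentration per family, scaled so the brightest set equals the top
#' of the family's activity range: totals then vary with slice content
#' (dim edge slices, bright central slices), which keeps the full-count
#' brightness per tissue voxel constant across the corpus — the property
#' that makes the retained count fraction of a reduced-count image
#' inferable from its brightness.  `"linear"` instead spaces the totals
#' evenly over the range, decoupling brightness from content.
#'
#' @param spec a [training_corpus_spec()].
#' @param seed seed for the brain-like base phantom.
#' @param voxel_size voxel size in mm.
#' @param activity_mode `"concentration"` (default) or `"linear"`.
#' @return list of [voxel_phantom()] objects with attribute
#'   `assigned_activity`.
#' @export
make_training_corpus <- function(spec = training_corpus_spec(), seed = 1L,
                                 voxel_size = 2.2,
                                 activity_mode = c("concentration", "linear")) {
  activity_mode <- match.arg(activity_mode)
  nz_big <- as.integer(ceiling(spec$n_slices * 1.15)) + 2L
  base <- list(
    a = make_shepp_logan(c(spec$matrix, spec$matrix, nz_big), voxel_size),
    b = make_brain_like(c(spec$matrix, spec$matrix, nz_big), seed, voxel_size))
  area_scale <- (spec$matrix / spec$reference_matrix)^2
  ranges <- list(a = spec$activity_range_a * area_scale,
                 b = spec$activity_range_b * area_scale)
  out <- list()
  for (fam in c("a", "b")) {
    ph <- base[[fam]]
    z0 <- floor((nz_big - spec$n_slices) / 2)
    sums <- vapply(seq_len(spec$n_slices),
                   function(s) sum(ph$activity[, , z0 + s]), 1.0)
    acts <- if (activity_mode == "linear") {
      if (spec$n_slices == 1L) ranges[[fam]][1] else
        seq(ranges[[fam]][1], ranges[[fam]][2], length.out = spec$n_slices)
    } else {
      sums * ranges[[fam]][2] / max(sums)
    }
    for (s in seq_len(spec$n_slices)) {
      sl_a <- ph$activity[, , z0 + s]
      sl_m <- ph$attenuation[, , z0 + s]
      tot <- sum(sl_a)
      scale <- if (tot > 0) acts[s] / (tot * spec$n_duplicates) else 0
      act <- aperm(array(sl_a * scale,
                         c(spec$matrix, spec$matrix, spec$n_duplicates)),
                   c(1, 3, 2))
      mu <- aperm(array(sl_m, c(spec$matrix, spec$matrix, spec$n_duplicates)),
                  c(1, 3, 2))
      p <- voxel_phantom(act, mu, voxel_size,
                         sprintf("corpus_%s_%03d", fam, s))
      attr(p, "assigned_activity") <- acts[s]
      out[[length(out) + 1L]] <- p
    }
  }
  out
}
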