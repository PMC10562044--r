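# Shared fixtures, built once per test run.

desk_scanner <- function(matrix = c(96L, 96L)) scanner_model(matrix = matrix)

# small slab phantom with a single hot voxel
point_phantom <- function(shape = c(64L, 20L, 64L), voxel = 2.2,
                          depth_index = 10L, activity = 2) {
  act <- array(0, shape)
  act[shape[1] %/% 2, depth_index, shape[3] %/% 2] <- activity
  voxel_phantom(act, array(0, shape), voxel, "point")
}

# uniform water slab with an embedded uniform source layer
slab_phantom <- function(total_thickness_mm, source_thickness_mm,
                         activity = 5, voxel = 2.2,
                         nx = 48L, nz = 48L, mu = MU_WATER_208KEV) {
  ny <- as.integer(round(total_thickness_mm / voxel))
  act <- array(0, c(nx, ny, nz))
  ns <- max(1L, as.integer(round(source_thickness_mm / voxel)))
  j0 <- (ny - ns) %/% 2 + 1L
  sl <- 9:(nx - 8)
  nvox <- length(sl)^2 * ns
  act[sl, j0:(j0 + ns - 1L), sl] <- activity / nvox
  voxel_phantom(act, array(mu, c(nx, ny, nz)), voxel, "slab")
}
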