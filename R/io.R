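#' Write / read a voxel phantom as NIfTI plus JSON sidecar
#'
#' Writes `<prefix>_activity.nii.gz`, `<prefix>_attenuation.nii.gz` and
#' `<prefix>.json` (name, voxel size, optional organ label dictionary;
#' labels go to `<prefix>_labels.nii.gz`).
#'
#' @param phantom a [voxel_phantom()].
#' @param prefix path prefix without extension.
#' @param labels optional [organ_label_map()].
#' @return `write_phantom` returns `prefix` invisibly; `read_phantom`
#'   returns a list with `phantom` and (possibly `NULL`) `labels`.
#' @export
write_phantom <- function(phantom, prefix, labels = NULL) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  wr <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- phantom$voxel_size
    RNifti::writeNifti(img, path)
  }
  wr(phantom$activity, paste0(prefix, "_activity.nii.gz"))
  wr(phantom$attenuation, paste0(prefix, "_attenuation.nii.gz"))
  side <- list(name = phantom$name, voxel_size = phantom$voxel_size)
  if (!is.null(labels)) {
    wr(labels$labels, paste0(prefix, "_labels.nii.gz"))
    side$organ_names <- as.list(labels$organ_names)
  }
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  rd <- function(path) {
    img <- RNifti::readNifti(path)
    array(as.vector(img), dim = dim(img))
  }
  act <- rd(paste0(prefix, "_activity.nii.gz"))
  mu <- rd(paste0(prefix, "_attenuation.nii.gz"))
  ph <- voxel_phantom(act, mu, side$voxel_size, side$name)
  labels <- NULL
  lab_path <- paste0(prefix, "_labels.nii.gz")
  if (file.exists(lab_path)) {
    lab <- rd(lab_path)
    storage.mode(lab) <- "integer"
    labels <- organ_label_map(lab, unlist(side$organ_names))
  }
  list(phantom = ph, labels = labels)
}

#' Write / read a count image as 32-bit float TIFF plus JSON sidecar
#'
#' Counts are stored scaled to \[0, 1\] with the scale recorded in the
#' sidecar (view, fraction, duration, pixel size, denoised flag).
#'
#' @param image a [count_image()] or [expected_image()].
#' @param prefix path prefix without extension.
#' @return `write_count_image` returns `prefix` invisibly;
#'   `read_count_image` returns the image.
#' @export
write_count_image <- function(image, prefix) {
  m <- as_count_matrix(image)
  scale <- max(m, 1)
  tiff::writeTIFF(m / scale, paste0(prefix, ".tif"), bits.per.sample = 32L)
  side <- list(type = class(image)[1], view = image$view,
               pixel_size = image$pixel_size, duration = image$duration,
               scale = scale)
  if (inherits(image, "count_image")) {
    side$fraction <- image$fraction
    side$denoised <- isTRUE(image$denoised)
  }
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_count_image
#' @export
read_count_image <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(paste0(prefix, ".tif")) * side$scale
  if (identical(side$type, "expected_image"))
    return(expected_image(m, side$view, side$pixel_size, side$duration))
  if (!isTRUE(side$denoised)) {
    m <- round(m)
    storage.mode(m) <- "integer"
  }
  count_image(m, side$view, side$pixel_size, side$duration,
              fraction = side$fraction, denoised = isTRUE(side$denoised))
}

#' Write detected events as a list-mode CSV
#'
#' Expands a count image into one row per detected photon (time uniform
#' over the acquisition, energy fixed at the photopeak) with detector
#' coordinates; provided for interface completeness with list-mode
#' toolchains.
#'
#' @param image a [count_image()].
#' @param path output CSV path.
#' @param energy_kev photopeak energy recorded per event.
#' @param seed seed for the event time jitter.
#' @return `path` invisibly.
#' @export
write_list_mode <- function(image, path, energy_kev = 208, seed = 1L) {
  stopifnot(inherits(image, "count_image"), !isTRUE(image$denoised))
  set.seed(seed)
  idx <- which(image$counts > 0, arr.ind = TRUE)
  n <- image$counts[idx]
  u <- rep((idx[, 1] - 0.5) * image$pixel_size, n)
  v <- rep((idx[, 2] - 0.5) * image$pixel_size, n)
  ev <- data.frame(time_s = sort(stats::runif(sum(n), 0, image$duration)),
                   energy_kev = energy_kev, u_mm = u, v_mm = v)
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}
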