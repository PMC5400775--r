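#' @useDynLib hyprpvc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm sd
NULL

#' Single 3D image volume
#'
#' Container for one 3D scalar grid in activity-concentration units
#' (kBq mL^-1) together with its voxel spacing and origin. Axis order is
#' (x, y, z) in R's column-major array layout; the grid shape is fixed at
#' construction and arithmetic between volumes requires matching shape and
#' voxel size.
#'
#' @param data numeric 3D array of voxel values.
#' @param voxel_size numeric length-3 vector of voxel edge lengths in mm,
#'   all strictly positive.
#' @param origin numeric length-3 vector, position of the first voxel centre
#'   in mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  storage.mode(data) <- "double"
  voxel_size <- as.numeric(voxel_size)
  origin <- as.numeric(origin)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three strictly positive values (mm)",
         call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  structure(list(data = data, voxel_size = voxel_size, origin = origin),
            class = "image_volume")
}

is_image_volume <- function(x) inherits(x, "image_volume")

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("image volumes have different grid shapes", call. = FALSE)
  if (!isTRUE(all.equal(a$voxel_size, b$voxel_size)))
    stop("image volumes have different voxel sizes", call. = FALSE)
  invisible(TRUE)
}

#' @export
Ops.image_volume <- function(e1, e2) {
  if (missing(e2)) {
    e1$data <- get(.Generic)(e1$data)
    return(e1)
  }
  if (is_image_volume(e1) && is_image_volume(e2)) {
    check_same_grid(e1, e2)
    e1$data <- get(.Generic)(e1$data, e2$data)
    return(e1)
  }
  if (is_image_volume(e1)) {
    e1$data <- get(.Generic)(e1$data, e2)
    return(e1)
  }
  e2$data <- get(.Generic)(e1, e2$data)
  e2
}

#' Dynamic (4D) image series
#'
#' An ordered list of [image_volume()] frames sharing one grid, plus frame
#' start times and durations in seconds. Frame durations must be positive and
#' start times non-decreasing.
#'
#' @param frames list of `image_volume` objects, or a 4D array (frames on the
#'   4th axis) combined with `voxel_size`.
#' @param frame_start numeric vector of frame start times (s).
#' @param frame_duration numeric vector of frame durations (s).
#' @param voxel_size voxel size in mm, used only when `frames` is a 4D array.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(frames, frame_start, frame_duration,
                          voxel_size = c(1, 1, 1)) {
  if (is.array(frames) && length(dim(frames)) == 4L) {
    nf <- dim(frames)[4]
    frames <- lapply(seq_len(nf), function(i)
      image_volume(frames[, , , i, drop = TRUE], voxel_size = voxel_size))
  }
  if (!is.list(frames) || length(frames) == 0L ||
      !all(vapply(frames, is_image_volume, logical(1))))
    stop("`frames` must be a non-empty list of image_volume objects",
         call. = FALSE)
  frame_start <- as.numeric(frame_start)
  frame_duration <- as.numeric(frame_duration)
  nf <- length(frames)
  if (length(frame_start) != nf || length(frame_duration) != nf)
    stop("frame timing vectors must match the number of frames",
         call. = FALSE)
  if (any(!is.finite(frame_duration)) || any(frame_duration <= 0))
    stop("all frame durations must be positive", call. = FALSE)
  if (is.unsorted(frame_start))
    stop("frame start times must be non-decreasing", call. = FALSE)
  for (i in seq_len(nf)[-1]) check_same_grid(frames[[1]], frames[[i]])
  structure(list(frames = frames, frame_start = frame_start,
                 frame_duration = frame_duration),
            class = "dynamic_image")
}

is_dynamic_image <- function(x) inherits(x, "dynamic_image")

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$frames[[1]]$data)
  cat(sprintf("<dynamic_image> %d frames of %d x %d x %d voxels, %.4g s total\n",
              length(x$frames), d[1], d[2], d[3], sum(x$frame_duration)))
  invisible(x)
}

#' @export
length.dynamic_image <- function(x) length(x$frames)

#' Frame midpoint times of a dynamic series
#' @param dyn a [dynamic_image()].
#' @return numeric vector of frame midpoints in seconds.
#' @export
frame_mid_times <- function(dyn) {
  stopifnot(is_dynamic_image(dyn))
  dyn$frame_start + dyn$frame_duration / 2
}

#' Isotropic Gaussian point spread function model
#'
#' The scanner resolution is modelled as an isotropic Gaussian kernel
#' parameterised by its full width at half maximum (FWHM) in mm. The sampled
#' kernel is truncated at +/- 4 sigma and renormalised to unit mass.
#'
#' @param fwhm_mm FWHM of the Gaussian in mm, > 0. Default 6.75 mm, a typical
#'   post-reconstruction brain PET resolution.
#' @return An object of class `psf_model` with fields `fwhm_mm` and
#'   `sigma_mm`.
#' @export
psf_model <- function(fwhm_mm = 6.75) {
  structure(list(fwhm_mm = fwhm_mm, sigma_mm = fwhm_to_sigma(fwhm_mm),
                 kind = "isotropic-gaussian"),
            class = "psf_model")
}

#' Convert Gaussian FWHM to standard deviation
#'
#' @param fwhm_mm full width at half maximum, > 0 (mm).
#' @return `fwhm_mm / (2 * sqrt(2 * log(2)))` (mm).
#' @export
fwhm_to_sigma <- function(fwhm_mm) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) ||
      fwhm_mm <= 0)
    stop("`fwhm_mm` must be a single positive number", call. = FALSE)
  fwhm_mm / (2 * sqrt(2 * log(2)))
}

# sampled, truncated, unit-mass 1D Gaussian kernel; sigma in voxel units
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox < 1e-8) return(1.0)
  radius <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- dnorm(seq(-radius, radius), sd = sigma_vox)
  k / sum(k)
}

# internal: blur a plain 3D array; sigma_mm scalar, voxel_size length-3
blur_array <- function(arr, sigma_mm, voxel_size, boundary) {
  bnd <- match.arg(boundary, c("reflect", "periodic"))
  kernels <- lapply(1:3, function(ax)
    gaussian_kernel_1d(sigma_mm / voxel_size[ax]))
  cpp_conv_separable(arr, dim(arr), kernels,
                     if (bnd == "periodic") 1L else 0L)
}

#' Gaussian smoothing of an image volume
#'
#' Convolves the volume with a separable sampled Gaussian of the PSF's FWHM.
#' The per-axis standard deviation is expressed in voxel units through the
#' volume's voxel size, so anisotropic voxels are handled correctly.
#'
#' @param img an [image_volume()].
#' @param psf a [psf_model()] (or a single FWHM in mm).
#' @param boundary `"reflect"` (mirror padding, default) or `"periodic"`
#'   (circular wrap, under which the discrete convolution matches the FFT
#'   product exactly).
#' @return The blurred `image_volume` (same shape and metadata).
#' @export
gaussian_blur <- function(img, psf, boundary = "reflect") {
  stopifnot(is_image_volume(img))
  if (is.numeric(psf)) psf <- psf_model(psf)
  stopifnot(inherits(psf, "psf_model"))
  if (anyNA(img$data) || any(!is.finite(img$data)))
    stop("input volume contains NaN/Inf", call. = FALSE)
  img$data <- blur_array(img$data, psf$sigma_mm, img$voxel_size, boundary)
  img
}

#' Duration-weighted average of dynamic frames
#'
#' Computes `sum_i I_i * dt_i / sum_i dt_i` over a subset of frames: the
#' composite image used by HYPR, normalised by total duration so that it
#' stays in concentration units.
#'
#' @param dyn a [dynamic_image()].
#' @param frame_subset integer indices of the frames to combine (default all).
#' @return An [image_volume()].
#' @export
duration_weighted_sum <- function(dyn, frame_subset = seq_along(dyn$frames)) {
  stopifnot(is_dynamic_image(dyn))
  frame_subset <- as.integer(frame_subset)
  if (length(frame_subset) == 0L)
    stop("`frame_subset` must be non-empty", call. = FALSE)
  if (any(frame_subset < 1L) || any(frame_subset > length(dyn$frames)))
    stop("`frame_subset` out of range", call. = FALSE)
  dt <- dyn$frame_duration[frame_subset]
  acc <- dyn$frames[[frame_subset[1]]]$data * dt[1]
  for (j in seq_along(frame_subset)[-1])
    acc <- acc + dyn$frames[[frame_subset[j]]]$data * dt[j]
  out <- dyn$frames[[frame_subset[1]]]
  out$data <- acc / sum(dt)
  out
}
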