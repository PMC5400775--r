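#' Read a 3D NIfTI-1 volume
#'
#' @param path path to a `.nii` / `.nii.gz` file holding a 3D volume.
#' @return An [image_volume()] with voxel size taken from the header.
#' @export
read_image_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume: ", path, call. = FALSE)
  vs <- RNifti::pixdim(nii)[1:3]
  org <- -RNifti::worldToVoxel(c(0, 0, 0), nii)[1:3] * vs
  image_volume(arr, voxel_size = vs, origin = org)
}

#' Write a 3D volume as NIfTI-1
#'
#' @param img an [image_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_image_nifti <- function(img, path) {
  stopifnot(is_image_volume(img))
  arr <- img$data
  attr(arr, "pixdim") <- img$voxel_size
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

#' Read frame timing from a sidecar file
#'
#' Accepts either a JSON sidecar with fields `FrameTimesStart` and
#' `FrameDuration` (seconds), or a two-column whitespace/CSV text file of
#' frame start and duration.
#'
#' @param path path to the timing file.
#' @return list with numeric `frame_start` and `frame_duration` (s).
#' @export
read_frame_timing <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^\\s*\\{", first)) {
    j <- jsonlite::fromJSON(path)
    if (is.null(j$FrameTimesStart) || is.null(j$FrameDuration))
      stop("timing JSON must contain FrameTimesStart and FrameDuration",
           call. = FALSE)
    return(list(frame_start = as.numeric(j$FrameTimesStart),
                frame_duration = as.numeric(j$FrameDuration)))
  }
  tab <- utils::read.table(path, header = FALSE,
                           sep = if (grepl(",", first)) "," else "")
  if (ncol(tab) < 2L)
    stop("timing text file must have two columns: start, duration (s)",
         call. = FALSE)
  list(frame_start = as.numeric(tab[[1]]), frame_duration = as.numeric(tab[[2]]))
}

#' Write a JSON frame-timing sidecar
#'
#' @param dyn a [dynamic_image()] (or a list with `frame_start`,
#'   `frame_duration`).
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_frame_timing <- function(dyn, path) {
  jsonlite::write_json(list(FrameTimesStart = dyn$frame_start,
                            FrameDuration = dyn$frame_duration),
                       path, digits = NA)
  invisible(path)
}

#' Read a 4D dynamic NIfTI series with frame timing
#'
#' @param path path to a 4D NIfTI file, frames on the 4th axis.
#' @param timing_path path to the timing sidecar (see [read_frame_timing()]).
#' @return A [dynamic_image()].
#' @export
read_dynamic_nifti <- function(path, timing_path) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D NIfTI series: ", path, call. = FALSE)
  tm <- read_frame_timing(timing_path)
  if (length(tm$frame_duration) != dim(arr)[4])
    stop("timing sidecar length does not match the number of frames",
         call. = FALSE)
  dynamic_image(arr, tm$frame_start, tm$frame_duration,
                voxel_size = RNifti::pixdim(nii)[1:3])
}

#' Write a dynamic series as 4D NIfTI plus timing sidecar
#'
#' @param dyn a [dynamic_image()].
#' @param path output NIfTI path.
#' @param timing_path output JSON sidecar path (default: `path` with a
#'   `.json` extension).
#' @return `path`, invisibly.
#' @export
write_dynamic_nifti <- function(dyn, path,
                                timing_path = sub("\\.nii(\\.gz)?$", ".json",
                                                  path)) {
  stopifnot(is_dynamic_image(dyn))
  d <- dim(dyn$frames[[1]]$data)
  arr <- array(0, c(d, length(dyn$frames)))
  for (i in seq_along(dyn$frames)) arr[, , , i] <- dyn$frames[[i]]$data
  attr(arr, "pixdim") <- c(dyn$frames[[1]]$voxel_size, 1)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  write_frame_timing(dyn, timing_path)
  invisible(path)
}
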