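# run code with a locally-set RNG seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of the digital brain phantom
#'
#' Describes a Hoffman-style grey/white-matter brain phantom: an ellipsoidal
#' brain envelope with a folded cortical grey-matter rib pattern (2-4 voxels
#' thick) over a white-matter interior. The single-fill physical phantom
#' realises an apparent grey:white activity ratio of about 4:1, which is the
#' default here.
#'
#' @param shape grid size in voxels (default `c(128, 128, 90)`).
#' @param voxel_size voxel size in mm (default 2 mm isotropic).
#' @param gm_activity grey-matter activity in kBq mL^-1 (default 25).
#' @param gm_wm_ratio grey:white activity ratio, >= 1 (default 4).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 90L),
                         voxel_size = c(2, 2, 2),
                         gm_activity = 25,
                         gm_wm_ratio = 4) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be three positive integers", call. = FALSE)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive lengths (mm)", call. = FALSE)
  if (!is.numeric(gm_activity) || gm_activity <= 0)
    stop("`gm_activity` must be positive", call. = FALSE)
  if (!is.numeric(gm_wm_ratio) || gm_wm_ratio < 1)
    stop("`gm_wm_ratio` must be >= 1", call. = FALSE)
  structure(list(shape = shape, voxel_size = voxel_size,
                 gm_activity = gm_activity, gm_wm_ratio = gm_wm_ratio,
                 labels = c(background = 0L, WM = 1L, GM = 2L,
                            WM_core = 3L)),
            class = "phantom_spec")
}

#' Integer label mask over an image grid
#'
#' @param labels an [image_volume()] (or 3D array) of integer region labels.
#' @param names named integer vector mapping region names to label values.
#' @param voxel_size voxel size, used when `labels` is a plain array.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(labels,
                     names = c(background = 0L, WM = 1L, GM = 2L,
                               WM_core = 3L),
                     voxel_size = c(1, 1, 1)) {
  if (!is_image_volume(labels))
    labels <- image_volume(labels, voxel_size = voxel_size)
  if (any(labels$data != round(labels$data)))
    stop("labels must be integers", call. = FALSE)
  structure(list(labels = labels, names = names), class = "voi_mask")
}

# resolve a label given by name or value to its integer value
resolve_label <- function(mask, label) {
  stopifnot(inherits(mask, "voi_mask"))
  if (is.character(label)) {
    if (!label %in% names(mask$names))
      stop("unknown region name: ", label, call. = FALSE)
    return(as.integer(mask$names[[label]]))
  }
  as.integer(label)
}

#' Build the digital brain phantom
#'
#' Procedurally generates a deterministic label map on the requested grid: an
#' ellipsoidal brain envelope (background outside), a continuous cortical
#' grey-matter shell, and folded grey-matter ribs reaching into the
#' white-matter interior (band thickness about 2-4 voxels at the default
#' 2-mm grid). A ~2.5 cc sphere of uniform deep white matter at the centre
#' is labelled separately (`WM_core`) as the noise VOI, mirroring a
#' centrum-semiovale region where measured activity is nearly uniform. The
#' true-activity volume carries `gm_activity` in grey matter,
#' `gm_activity / gm_wm_ratio` in all white matter and 0 outside.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `mask` (a [voi_mask()]) and `activity`
#'   (an [image_volume()] of true concentrations).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$shape
  vs <- spec$voxel_size
  half <- n * vs / 2
  semi <- c(0.72, 0.85, 0.80) * half   # brain-like ellipsoid semi-axes (mm)
  if (any(semi < 6 * vs))
    stop("grid too small to contain the brain envelope", call. = FALSE)

  cx <- (seq_len(n[1]) - (n[1] + 1) / 2) * vs[1]
  cy <- (seq_len(n[2]) - (n[2] + 1) / 2) * vs[2]
  cz <- (seq_len(n[3]) - (n[3] + 1) / 2) * vs[3]
  x <- array(cx, n)
  y <- array(rep(cy, each = n[1]), n)
  z <- array(rep(cz, each = n[1] * n[2]), n)

  r2 <- (x / semi[1])^2 + (y / semi[2])^2 + (z / semi[3])^2
  inside <- r2 <= 1

  # folded cortical ribs: wavy sinusoidal bands through the interior
  period <- 28   # mm between rib repetitions
  u <- x / period + 0.35 * sin(2 * pi * z / 90) + 0.25 * sin(2 * pi * y / 70)
  ribs <- abs(sin(2 * pi * u)) >= 0.78

  labels <- array(0L, n)
  labels[inside] <- 1L                              # WM interior
  labels[inside & r2 > 0.82] <- 2L                  # cortical GM shell
  labels[inside & r2 <= 0.82 & r2 > 0.20 & ribs] <- 2L  # folded GM ribs
  # r2 <= 0.20 deep core stays WM (centrum-semiovale-like uniform region);
  # a ~2.5 cc sphere inside it is the uniform deep-WM noise VOI
  core_r <- (3 * 2500 / (4 * pi))^(1 / 3)   # mm, 2.5 cc
  core <- x^2 + y^2 + z^2 <= core_r^2
  labels[core & labels == 1L] <- 3L

  act <- array(0, n)
  act[labels == 1L | labels == 3L] <- spec$gm_activity / spec$gm_wm_ratio
  act[labels == 2L] <- spec$gm_activity

  list(mask = voi_mask(labels, names = spec$labels, voxel_size = vs),
       activity = image_volume(act, voxel_size = vs))
}

#' Dynamic framing scheme
#'
#' @param durations ordered frame durations in seconds, all positive.
#' @return An object of class `framing_scheme` with `frame_start` (cumulative
#'   from 0) and `frame_duration`.
#' @export
framing_scheme <- function(durations) {
  durations <- as.numeric(durations)
  if (length(durations) == 0L || any(!is.finite(durations)) ||
      any(durations <= 0))
    stop("all frame durations must be positive", call. = FALSE)
  structure(list(frame_start = cumsum(c(0, durations[-length(durations)])),
                 frame_duration = durations),
            class = "framing_scheme")
}

#' Named framing presets
#'
#' `"hoffman18"`: 18 frames over 30 min (6 x 5, 3 x 10, 4 x 60, 5 x 300 s),
#' the dynamic brain protocol used for the phantom experiments.
#' `"pib"`: 90-min amyloid protocol (1 x 15, 3 x 5, 3 x 10, 2 x 30, 3 x 60,
#' 2 x 150, 2 x 300, 7 x 600 s). `"fmz"`: 60-min flumazenil protocol
#' (4 x 15, 4 x 60, 2 x 150, 2 x 300, 4 x 600 s).
#'
#' @param name one of `"hoffman18"`, `"pib"`, `"fmz"`.
#' @return A [framing_scheme()].
#' @export
framing_preset <- function(name = c("hoffman18", "pib", "fmz")) {
  name <- match.arg(name)
  durations <- switch(name,
    hoffman18 = c(rep(5, 6), rep(10, 3), rep(60, 4), rep(300, 5)),
    pib = c(15, rep(5, 3), rep(10, 3), rep(30, 2), rep(60, 3),
            rep(150, 2), rep(300, 2), rep(600, 7)),
    fmz = c(rep(15, 4), rep(60, 4), rep(150, 2), rep(300, 2), rep(600, 4)))
  framing_scheme(durations)
}

#' Image-space Poisson noise model
#'
#' Expected counts per voxel and frame are
#' `concentration * duration * sensitivity`; the observed frame is a Poisson
#' draw divided back by `duration * sensitivity`, so voxel noise scales as
#' `1/sqrt(duration)`. The default sensitivity of 0.09 counts per
#' (kBq mL^-1 s voxel) puts the grey-matter coefficient of variation of a
#' 5-s frame near 30%, a realistic low-statistics frame.
#'
#' @param sensitivity expected counts per (kBq mL^-1 s voxel), > 0.
#' @param seed RNG seed; identical seeds give identical realisations.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sensitivity = 0.09, seed = 20170421L) {
  if (!is.numeric(sensitivity) || sensitivity <= 0)
    stop("`sensitivity` must be positive", call. = FALSE)
  structure(list(sensitivity = sensitivity, seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate a dynamic PET acquisition of a known activity map
#'
#' Each frame is the PSF-blurred true image; with a [noise_model()], frames
#' are Poisson realisations whose expected counts scale with frame duration,
#' returned in concentration units. With `noise = NULL` every frame equals
#' the blurred truth exactly.
#'
#' @param true_img non-negative true-activity [image_volume()].
#' @param psf a [psf_model()].
#' @param framing a [framing_scheme()].
#' @param noise a [noise_model()] or `NULL` for noise-free frames.
#' @param boundary convolution boundary for the PSF blur.
#' @return A [dynamic_image()].
#' @export
simulate_dynamic <- function(true_img, psf = psf_model(6.75),
                             framing = framing_preset("hoffman18"),
                             noise = noise_model(),
                             boundary = "reflect") {
  stopifnot(is_image_volume(true_img), inherits(framing, "framing_scheme"))
  if (any(true_img$data < 0))
    stop("true activity must be non-negative", call. = FALSE)
  blurred <- gaussian_blur(true_img, psf, boundary = boundary)
  blurred$data[blurred$data < 0] <- 0
  nf <- length(framing$frame_duration)
  frames <- vector("list", nf)
  if (is.null(noise)) {
    for (i in seq_len(nf)) frames[[i]] <- blurred
  } else {
    stopifnot(inherits(noise, "noise_model"))
    with_preserved_seed(noise$seed, {
      for (i in seq_len(nf)) {
        scale <- framing$frame_duration[i] * noise$sensitivity
        lambda <- blurred$data * scale
        fr <- blurred
        fr$data <- array(stats::rpois(length(lambda), lambda) / scale,
                         dim(lambda))
        frames[[i]] <- fr
      }
    })
  }
  dynamic_image(frames, framing$frame_start, framing$frame_duration)
}

#' Percent bias of the measured grey-matter concentration
#'
#' `100 * (mean over GM voxels - true GM value) / true GM value`. On a
#' blurred hot-GM phantom this is negative (spill-out dominates).
#'
#' @param measured measured [image_volume()].
#' @param mask a [voi_mask()] sharing the grid.
#' @param true_activity true GM concentration (scalar), or a true-activity
#'   [image_volume()] whose GM mean is used.
#' @param label GM label name or value (default `"GM"`).
#' @return Percent bias (scalar).
#' @export
gm_bias <- function(measured, mask, true_activity, label = "GM") {
  stopifnot(is_image_volume(measured), inherits(mask, "voi_mask"))
  lab <- resolve_label(mask, label)
  sel <- mask$labels$data == lab
  if (!any(sel)) stop("empty grey-matter mask", call. = FALSE)
  truth <- if (is_image_volume(true_activity)) mean(true_activity$data[sel])
           else as.numeric(true_activity)
  if (!is.finite(truth) || truth <= 0)
    stop("true GM activity must be positive", call. = FALSE)
  100 * (mean(measured$data[sel]) - truth) / truth
}

#' Simulate a dynamic acquisition from per-region time-activity curves
#'
#' Builds a dynamic truth whose voxel time courses follow one TAC per label
#' region, blurs every frame with the PSF, and optionally adds
#' duration-scaled Poisson noise as in [simulate_dynamic()]. Used for
#' kinetic phantoms where regional time courses (not a static fill) define
#' the truth.
#'
#' @param mask a [voi_mask()] defining the regions.
#' @param tacs named list of [time_activity_curve()] objects, one per region
#'   name present in `mask$names`; all sharing the same framing. Unlisted
#'   regions stay at 0.
#' @param psf a [psf_model()].
#' @param noise a [noise_model()] or `NULL`.
#' @param boundary convolution boundary for the PSF blur.
#' @return A [dynamic_image()].
#' @export
simulate_dynamic_from_tacs <- function(mask, tacs, psf = psf_model(6.75),
                                       noise = NULL, boundary = "reflect") {
  stopifnot(inherits(mask, "voi_mask"), is.list(tacs), length(tacs) > 0)
  if (is.null(names(tacs)) || !all(names(tacs) %in% names(mask$names)))
    stop("`tacs` must be named after regions of the mask", call. = FALSE)
  ref <- tacs[[1]]
  nf <- length(ref$values)
  for (tc in tacs) {
    stopifnot(inherits(tc, "tac"))
    if (length(tc$values) != nf ||
        !isTRUE(all.equal(tc$frame_mid_times, ref$frame_mid_times)))
      stop("all TACs must share one framing", call. = FALSE)
    if (any(tc$values < 0))
      stop("true activity must be non-negative", call. = FALSE)
  }
  vs <- mask$labels$voxel_size
  d <- dim(mask$labels$data)
  sel <- lapply(names(tacs), function(nm)
    mask$labels$data == mask$names[[nm]])
  sig <- psf$sigma_mm
  frames <- vector("list", nf)
  fd <- ref$frame_durations
  fs <- ref$frame_mid_times - fd / 2
  build <- function() {
    for (i in seq_len(nf)) {
      truth <- array(0, d)
      for (j in seq_along(tacs)) truth[sel[[j]]] <- tacs[[j]]$values[i]
      bl <- blur_array(truth, sig, vs, boundary)
      bl[bl < 0] <- 0
      if (!is.null(noise)) {
        scale <- fd[i] * noise$sensitivity
        bl <- array(stats::rpois(length(bl), bl * scale) / scale, d)
      }
      frames[[i]] <<- image_volume(bl, voxel_size = vs)
    }
  }
  if (is.null(noise)) build()
  else {
    stopifnot(inherits(noise, "noise_model"))
    with_preserved_seed(noise$seed, build())
  }
  dynamic_image(frames, fs, fd)
}
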