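#' Partial-volume-correction pipeline configuration
#'
#' Selects the composition order of iterative deconvolution (IDM, applied
#' frame by frame) and HYPR denoising (applied to the whole series):
#' `"none"`, `"idm"`, `"idm_hypr"`, `"hypr_idm"` or `"hypr_idm_hypr"` (the
#' recommended order: denoise, deconvolve, denoise again).
#'
#' @param order the composition order.
#' @param deconv a [deconv_config()] for the IDM stage.
#' @param hypr a [hypr_config()] for the HYPR stage(s); ignored when
#'   `order = "idm"` or `"none"`.
#' @return An object of class `pvc_config`.
#' @export
pvc_config <- function(order = c("hypr_idm_hypr", "none", "idm", "idm_hypr",
                                 "hypr_idm"),
                       deconv = deconv_config(),
                       hypr = hypr_config()) {
  order <- match.arg(order)
  stopifnot(inherits(deconv, "deconv_config"), inherits(hypr, "hypr_config"))
  structure(list(order = order, deconv = deconv, hypr = hypr),
            class = "pvc_config")
}

#' Run the configured PVC pipeline on a dynamic series
#'
#' Applies the stages of `cfg$order` left to right. IDM stages deconvolve
#' each frame independently (all temporal regularisation lives in HYPR);
#' HYPR stages recompute their composite from the stage input. Frame timing
#' is preserved and the result is deterministic for fixed inputs.
#'
#' @param dyn a [dynamic_image()].
#' @param cfg a [pvc_config()].
#' @return The corrected [dynamic_image()].
#' @export
run_pvc <- function(dyn, cfg) {
  stopifnot(is_dynamic_image(dyn), inherits(cfg, "pvc_config"))
  if (cfg$order == "none") return(dyn)
  stages <- strsplit(cfg$order, "_", fixed = TRUE)[[1]]
  if ("hypr" %in% stages && length(dyn$frames) < 2L)
    stop("HYPR requires a multi-frame series", call. = FALSE)
  for (stage in stages) {
    if (stage == "hypr") {
      dyn <- hypr_denoise(dyn, cfg$hypr)
    } else {
      for (i in seq_along(dyn$frames))
        dyn$frames[[i]] <- deconvolve(dyn$frames[[i]], cfg$deconv)
    }
  }
  dyn
}

#' Coefficient of variation within a labelled region
#'
#' `100 * SD / mean` over the region's voxels, with the population SD
#' convention (divide by N) as a descriptive image-noise metric.
#'
#' @param img an [image_volume()].
#' @param mask a [voi_mask()] on the same grid.
#' @param label region name or integer label.
#' @return CoV in percent.
#' @export
voi_cov <- function(img, mask, label) {
  stopifnot(is_image_volume(img), inherits(mask, "voi_mask"))
  sel <- mask$labels$data == resolve_label(mask, label)
  if (!any(sel)) stop("empty region", call. = FALSE)
  x <- img$data[sel]
  m <- mean(x)
  if (m <= 0) stop("region mean is non-positive", call. = FALSE)
  100 * sqrt(mean((x - m)^2)) / m
}

#' Extract a regional time-activity curve
#'
#' Per-frame mean over the region's voxels, with frame timing attached.
#'
#' @param dyn a [dynamic_image()].
#' @param mask a [voi_mask()] on the same grid.
#' @param label region name or integer label.
#' @return A [time_activity_curve()].
#' @export
extract_tac <- function(dyn, mask, label) {
  stopifnot(is_dynamic_image(dyn), inherits(mask, "voi_mask"))
  sel <- mask$labels$data == resolve_label(mask, label)
  if (!any(sel)) stop("empty region", call. = FALSE)
  vals <- vapply(dyn$frames, function(fr) mean(fr$data[sel]), numeric(1))
  time_activity_curve(frame_mid_times(dyn), vals, dyn$frame_duration)
}

# serialisable echo of a (nested) config object
config_echo <- function(x) {
  if (inherits(x, "psf_model")) return(list(fwhm_mm = x$fwhm_mm))
  if (is.list(x)) {
    out <- lapply(unclass(x), config_echo)
    if (length(class(x)) && class(x)[1] != "list") out$class <- class(x)[1]
    return(out)
  }
  x
}

#' Phantom evaluation of a set of PVC methods
#'
#' Generates the digital phantom and one noisy dynamic acquisition (fixed
#' seed from the noise model), runs every configured method on it, and
#' tabulates per-frame grey-matter bias and white-matter CoV plus summary
#' means over the low-statistics (duration <= 10 s) and high-statistics
#' (>= 300 s) frame classes.
#'
#' @param spec a [phantom_spec()].
#' @param framing a [framing_scheme()].
#' @param noise a [noise_model()] or `NULL` for a noise-free series.
#' @param methods named list of [pvc_config()] objects.
#' @param psf acquisition [psf_model()] (the blur the simulation applies).
#' @param low_stat_max,high_stat_min frame-class thresholds in seconds.
#' @return An object of class `evaluation_report`: list with `per_frame` and
#'   `summary` data frames, the config echo, and the seed.
#' @export
evaluate_phantom_experiment <- function(spec = phantom_spec(),
                                        framing = framing_preset("hoffman18"),
                                        noise = noise_model(),
                                        methods,
                                        psf = psf_model(6.75),
                                        low_stat_max = 10,
                                        high_stat_min = 300) {
  if (!is.list(methods) || length(methods) == 0L ||
      !all(vapply(methods, inherits, logical(1), "pvc_config")))
    stop("`methods` must be a non-empty list of pvc_config objects",
         call. = FALSE)
  if (is.null(names(methods)) || any(names(methods) == ""))
    names(methods) <- paste0("method", seq_along(methods))
  ph <- make_phantom(spec)
  dyn <- simulate_dynamic(ph$activity, psf, framing, noise)
  frame_class <- ifelse(framing$frame_duration <= low_stat_max, "low",
                 ifelse(framing$frame_duration >= high_stat_min, "high",
                        "mid"))
  per_frame <- NULL
  for (mn in names(methods)) {
    corrected <- tryCatch(run_pvc(dyn, methods[[mn]]),
                          error = function(e)
                            stop("method '", mn, "': ", conditionMessage(e),
                                 call. = FALSE))
    bias <- vapply(corrected$frames, gm_bias, numeric(1),
                   mask = ph$mask, true_activity = spec$gm_activity)
    wm_label <- if ("WM_core" %in% names(ph$mask$names)) "WM_core" else "WM"
    wmcov <- vapply(corrected$frames, voi_cov, numeric(1),
                    mask = ph$mask, label = wm_label)
    per_frame <- rbind(per_frame, data.frame(
      method = mn, frame = seq_along(corrected$frames),
      mid_time_s = frame_mid_times(dyn),
      duration_s = framing$frame_duration, class = frame_class,
      gm_bias_pct = bias, wm_cov_pct = wmcov))
  }
  keep <- per_frame$class != "mid"
  summary <- stats::aggregate(
    cbind(gm_bias_pct, wm_cov_pct) ~ method + class,
    data = per_frame[keep, , drop = FALSE], FUN = mean)
  structure(list(per_frame = per_frame, summary = summary,
                 config = lapply(methods, config_echo),
                 seed = if (is.null(noise)) NA_integer_ else noise$seed,
                 sd_convention = "population"),
            class = "evaluation_report")
}

#' Write / read an evaluation report
#'
#' JSON for lossless machine round-trips; optionally CSV tables alongside.
#'
#' @param report an `evaluation_report`.
#' @param path output `.json` path.
#' @param csv_dir optional directory for `per_frame.csv` / `summary.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, csv_dir = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  if (!is.null(csv_dir)) {
    dir.create(csv_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report$per_frame, file.path(csv_dir, "per_frame.csv"),
                     row.names = FALSE)
    utils::write.csv(report$summary, file.path(csv_dir, "summary.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  j$per_frame <- as.data.frame(j$per_frame)
  j$summary <- as.data.frame(j$summary)
  structure(j, class = "evaluation_report")
}
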