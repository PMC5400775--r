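#' Arterial plasma input function
#'
#' Metabolite-corrected plasma concentration on a dense time grid.
#'
#' @param times seconds, strictly increasing, starting at 0.
#' @param concentration kBq mL^-1, non-negative.
#' @return An object of class `plasma_input`.
#' @export
plasma_input <- function(times, concentration) {
  times <- as.numeric(times)
  concentration <- as.numeric(concentration)
  if (length(times) != length(concentration) || length(times) < 2L)
    stop("times and concentration must be equal-length vectors (>= 2)",
         call. = FALSE)
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing from 0", call. = FALSE)
  if (any(concentration < 0) || any(!is.finite(concentration)))
    stop("concentration must be finite and non-negative", call. = FALSE)
  structure(list(times = times, concentration = concentration),
            class = "plasma_input")
}

#' Synthetic bolus plasma input
#'
#' A bolus surrogate for a measured arterial input: linear rise from 0 to the
#' peak, then a multi-exponential decay. With all decay rates zero the curve
#' plateaus at the peak value.
#'
#' @param peak_time time of the peak (s), > 0.
#' @param peak_value peak concentration (kBq mL^-1), > 0.
#' @param decay_rates exponential decay rates after the peak (s^-1), >= 0.
#' @param fractions mixing fractions of the decay terms (normalised to 1).
#' @param duration end of the curve (s).
#' @param dt grid spacing (s).
#' @return A [plasma_input()].
#' @export
synth_plasma_input <- function(peak_time = 30, peak_value = 50,
                               decay_rates = c(0.02, 0.003, 2e-4),
                               fractions = c(0.7, 0.2, 0.1),
                               duration = 3600, dt = 0.5) {
  if (peak_time <= 0 || peak_value <= 0 || duration <= peak_time || dt <= 0)
    stop("plasma input parameters must be positive with duration > peak_time",
         call. = FALSE)
  if (length(decay_rates) != length(fractions) || any(decay_rates < 0) ||
      any(fractions < 0) || sum(fractions) == 0)
    stop("decay_rates/fractions must be non-negative and matched in length",
         call. = FALSE)
  fractions <- fractions / sum(fractions)
  times <- seq(0, duration, by = dt)
  conc <- ifelse(times <= peak_time,
                 peak_value * times / peak_time,
                 peak_value * colSums(fractions *
                   exp(-outer(decay_rates, pmax(times - peak_time, 0)))))
  plasma_input(times, conc)
}

#' Read / write a two-column plasma input text file
#'
#' Whitespace- or comma-separated columns: time (s), concentration
#' (kBq mL^-1).
#'
#' @param path file path.
#' @return [read_plasma_input()]: a [plasma_input()].
#' @export
read_plasma_input <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  tab <- utils::read.table(path, header = grepl("[A-Za-z]", first),
                           sep = if (grepl(",", first)) "," else "")
  plasma_input(tab[[1]], tab[[2]])
}

#' @rdname read_plasma_input
#' @param input a [plasma_input()] to write.
#' @export
write_plasma_input <- function(input, path) {
  utils::write.table(data.frame(time_s = input$times,
                                concentration = input$concentration),
                     path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' Reversible two-tissue-compartment parameters
#'
#' Rate constants in the field's units: `K1` in mL cm^-3 min^-1, `k2`-`k4`
#' in min^-1, `Vb` a unitless fractional blood volume. The total distribution
#' volume is `VT = (K1/k2) (1 + k3/k4)` for `k4 > 0` and `K1/k2` when
#' `k3 = 0`.
#'
#' @param K1,k2,k3,k4 rate constants, all >= 0, `k2 > 0`.
#' @param Vb fractional blood volume in `[0, 1)` (default 0).
#' @return An object of class `two_tissue_params`.
#' @export
two_tissue_params <- function(K1, k2, k3 = 0, k4 = 0, Vb = 0) {
  vals <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4, Vb = Vb)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all kinetic parameters must be finite and non-negative",
         call. = FALSE)
  if (k2 <= 0) stop("`k2` must be positive", call. = FALSE)
  if (Vb >= 1) stop("`Vb` must be below 1", call. = FALSE)
  structure(as.list(vals), class = "two_tissue_params")
}

#' Distribution volume of a two-tissue parameter set
#' @param p a [two_tissue_params()].
#' @return `VT` (unitless).
#' @export
vt_2tcm <- function(p) {
  stopifnot(inherits(p, "two_tissue_params"))
  if (p$k3 == 0) return(p$K1 / p$k2)
  if (p$k4 <= 0)
    stop("VT is undefined for irreversible binding (k3 > 0, k4 = 0)",
         call. = FALSE)
  (p$K1 / p$k2) * (1 + p$k3 / p$k4)
}

#' Regional time-activity curve
#'
#' @param frame_mid_times frame midpoint times (s).
#' @param values regional mean concentrations (kBq mL^-1).
#' @param frame_durations frame durations (s), all positive.
#' @return An object of class `tac`.
#' @export
time_activity_curve <- function(frame_mid_times, values, frame_durations) {
  frame_mid_times <- as.numeric(frame_mid_times)
  values <- as.numeric(values)
  frame_durations <- as.numeric(frame_durations)
  if (length(frame_mid_times) != length(values) ||
      length(values) != length(frame_durations))
    stop("TAC fields must have equal length", call. = FALSE)
  if (any(frame_durations <= 0))
    stop("frame durations must be positive", call. = FALSE)
  structure(list(frame_mid_times = frame_mid_times, values = values,
                 frame_durations = frame_durations), class = "tac")
}

#' Write a TAC as CSV
#' @param tac a [time_activity_curve()].
#' @param path output path.
#' @export
write_tac_csv <- function(tac, path) {
  start <- tac$frame_mid_times - tac$frame_durations / 2
  utils::write.csv(data.frame(frame_start_s = start,
                              frame_duration_s = tac$frame_durations,
                              frame_mid_s = tac$frame_mid_times,
                              value = tac$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# exact convolution of a piecewise-linear sampled curve with exp(-a t)
# on a uniform grid; returns the sampled convolution (same length)
conv_exp_linear <- function(cp, dt, a) {
  n <- length(cp)
  if (n < 2L) return(numeric(n))
  c0 <- cp[-n]
  c1 <- cp[-1]
  if (a * dt < 1e-12) {
    inc <- dt * (c0 + c1) / 2
    e <- 1
  } else {
    e <- exp(-a * dt)
    inc <- c0 * (1 - e) / a + (c1 - c0) * (1 / a - (1 - e) / (a^2 * dt))
  }
  c(0, stats::filter(inc, e, method = "recursive"))
}

# resample a plasma input onto a uniform grid [0, t_end]
plasma_uniform <- function(input, t_end, dt = NULL) {
  if (is.null(dt)) dt <- min(0.5, min(diff(input$times)))
  times <- seq(0, t_end, by = dt)
  conc <- stats::approx(input$times, input$concentration, xout = times,
                        rule = 2)$y
  list(times = times, conc = conc, dt = dt)
}

#' Simulate a two-tissue-compartment time-activity curve
#'
#' Solves `dC1/dt = K1 Cp - (k2 + k3) C1 + k4 C2`,
#' `dC2/dt = k3 C1 - k4 C2` by the closed-form bi-exponential impulse
#' response convolved exactly with the piecewise-linear plasma curve, then
#' frame-averages `(1 - Vb) (C1 + C2) + Vb Cp` with duration-weighted
#' integrals.
#'
#' @param p a [two_tissue_params()] (rates per minute).
#' @param input a [plasma_input()] covering the scan duration (times in s).
#' @param framing a [framing_scheme()].
#' @return A [time_activity_curve()].
#' @export
simulate_2tcm <- function(p, input, framing) {
  stopifnot(inherits(p, "two_tissue_params"),
            inherits(input, "plasma_input"),
            inherits(framing, "framing_scheme"))
  t_end <- max(framing$frame_start + framing$frame_duration)
  if (max(input$times) < t_end)
    stop("plasma input does not cover the scan duration", call. = FALSE)
  pu <- plasma_uniform(input, t_end)
  # rates are per minute, the time grid per second
  K1 <- p$K1 / 60; k2 <- p$k2 / 60; k3 <- p$k3 / 60; k4 <- p$k4 / 60
  s <- k2 + k3 + k4
  disc <- sqrt(max(s^2 - 4 * k2 * k4, 0))
  a1 <- (s - disc) / 2
  a2 <- (s + disc) / 2
  if (a2 - a1 < 1e-15) a2 <- a1 + 1e-12   # repeated-root guard
  phi1 <- K1 * (k3 + k4 - a1) / (a2 - a1)
  phi2 <- K1 * (a2 - k3 - k4) / (a2 - a1)
  tissue <- phi1 * conv_exp_linear(pu$conc, pu$dt, a1) +
            phi2 * conv_exp_linear(pu$conc, pu$dt, a2)
  total <- (1 - p$Vb) * tissue + p$Vb * pu$conc
  # duration-weighted frame averages via the cumulative integral
  n <- length(total)
  cum <- c(0, cumsum(pu$dt * (total[-n] + total[-1]) / 2))
  cum_at <- function(t) stats::approx(pu$times, cum, xout = t, rule = 2)$y
  fs <- framing$frame_start
  fd <- framing$frame_duration
  vals <- (cum_at(fs + fd) - cum_at(fs)) / fd
  time_activity_curve(fs + fd / 2, vals, fd)
}

# cumulative plasma integral evaluated at arbitrary times
plasma_cum_integral <- function(input, at_times) {
  tt <- input$times
  cc <- input$concentration
  n <- length(tt)
  cum <- c(0, cumsum(diff(tt) * (cc[-n] + cc[-1]) / 2))
  stats::approx(tt, cum, xout = at_times, rule = 2)$y
}

#' Logan graphical analysis of a regional TAC
#'
#' Linearises the reversible-tracer kinetics: for frames after `t_star`,
#' regresses `Y(t) = int_0^t C_T / C_T(t)` on
#' `X(t) = int_0^t C_p / C_T(t)`; the slope estimates the distribution
#' volume VT. Tissue integrals use the trapezoid rule on the frame grid
#' (starting from 0 at time 0); plasma integrals use the dense input grid.
#' Note the slope is negatively biased by TAC noise.
#'
#' @param tac a [time_activity_curve()].
#' @param input a [plasma_input()].
#' @param t_star start of the linear phase (s), or `"auto"` to pick the
#'   earliest frame from which every included point deviates from the
#'   fitted line by less than 10% of the fitted value.
#' @return list with `vt` (slope), `intercept`, and `diagnostics`
#'   (`n_points`, `r_squared`, `max_rel_residual`, `t_star`).
#' @export
logan_vt <- function(tac, input, t_star) {
  stopifnot(inherits(tac, "tac"), inherits(input, "plasma_input"))
  mid <- tac$frame_mid_times
  ct <- tac$values
  n <- length(mid)
  cum_ct <- c(0, cumsum(diff(c(0, mid)) * (c(0, ct)[-(n + 1)] + ct) / 2))[-1]
  cum_cp <- plasma_cum_integral(input, mid)

  fit_from <- function(use) {
    if (sum(use) < 3L)
      stop("Logan fit needs at least 3 frames after t_star", call. = FALSE)
    if (any(ct[use] <= 0))
      stop("non-positive TAC values after t_star", call. = FALSE)
    x <- cum_cp[use] / ct[use]
    y <- cum_ct[use] / ct[use]
    f <- stats::lm.fit(cbind(1, x), y)
    res <- f$residuals
    list(vt = unname(f$coefficients[2]), intercept = unname(f$coefficients[1]),
         diagnostics = list(
           n_points = sum(use),
           r_squared = 1 - sum(res^2) / max(sum((y - mean(y))^2),
                                            .Machine$double.eps),
           max_rel_residual = max(abs(res)) / max(abs(y)),
           t_star = min(mid[use])))
  }

  if (identical(t_star, "auto")) {
    for (k in seq_len(n - 2L)) {
      use <- seq_len(n) >= k
      f <- tryCatch(fit_from(use), error = function(e) NULL)
      if (is.null(f)) next
      fitted <- f$intercept + f$vt * cum_cp[use] / ct[use]
      if (all(abs(cum_ct[use] / ct[use] - fitted) < 0.10 * abs(fitted)))
        return(f)
    }
    stop("no t_star satisfies the 10% linearity rule", call. = FALSE)
  }
  fit_from(mid >= t_star)
}

#' Voxelwise Logan parametric VT image
#'
#' Applies [logan_vt()] independently to every voxel time course. Voxels
#' with fewer than 3 usable frames or non-positive values after `t_star`
#' are set to 0; their count is attached as attribute `n_failed`.
#'
#' @param dyn a [dynamic_image()].
#' @param input a [plasma_input()].
#' @param t_star start of the linear phase (s).
#' @return An [image_volume()] of VT values with attribute `n_failed`.
#' @export
logan_parametric_image <- function(dyn, input, t_star) {
  stopifnot(is_dynamic_image(dyn), inherits(input, "plasma_input"))
  mid <- frame_mid_times(dyn)
  nf <- length(mid)
  use <- mid >= t_star
  if (sum(use) < 3L)
    stop("Logan fit needs at least 3 frames after t_star", call. = FALSE)
  d <- dim(dyn$frames[[1]]$data)
  nvox <- prod(d)
  V <- matrix(0, nvox, nf)
  for (j in seq_len(nf)) V[, j] <- as.numeric(dyn$frames[[j]]$data)

  # per-voxel trapezoid cumulative integral of the TAC from time 0
  tt <- c(0, mid)
  cum <- matrix(0, nvox, nf)
  prev_val <- numeric(nvox)
  acc <- numeric(nvox)
  for (j in seq_len(nf)) {
    acc <- acc + (tt[j + 1] - tt[j]) * (prev_val + V[, j]) / 2
    cum[, j] <- acc
    prev_val <- V[, j]
  }
  cum_cp <- plasma_cum_integral(input, mid)

  ok <- rowSums(V[, use, drop = FALSE] > 0) == sum(use)
  X <- sweep(1 / V[, use, drop = FALSE], 2, cum_cp[use], "*")
  Y <- cum[, use, drop = FALSE] / V[, use, drop = FALSE]
  m <- sum(use)
  sx <- rowSums(X); sy <- rowSums(Y)
  sxx <- rowSums(X^2); sxy <- rowSums(X * Y)
  denom <- sxx - sx^2 / m
  slope <- ifelse(ok & denom > 0, (sxy - sx * sy / m) / denom, 0)
  slope[!is.finite(slope)] <- 0

  out <- dyn$frames[[1]]
  out$data <- array(slope, d)
  attr(out, "n_failed") <- sum(!ok)
  out
}

#' Non-linear regression fit of the two-tissue model
#'
#' Weighted least squares of [simulate_2tcm()] against a measured TAC via
#' Levenberg-Marquardt with non-negativity bounds, multistarted from a small
#' deterministic grid of initial parameter sets. Weights default to frame
#' durations. A fit is flagged non-identifiable when the VT standard error
#' (delta method on the Jacobian) exceeds the estimate itself.
#'
#' @param tac a [time_activity_curve()].
#' @param input a [plasma_input()].
#' @param init optional [two_tissue_params()] used as an additional start.
#' @param weights `"duration"` (w_i proportional to frame duration, default)
#'   or `"uniform"`, or a numeric vector.
#' @param fit_k4 if `FALSE`, `k3`/`k4` are fixed at 0 (one-tissue model).
#' @return list with `params` ([two_tissue_params()]), `vt`, `sse`,
#'   `identifiable`, `n_starts_converged`.
#' @export
nlr_fit_2tcm <- function(tac, input, init = NULL,
                         weights = c("duration", "uniform"), fit_k4 = TRUE) {
  stopifnot(inherits(tac, "tac"), inherits(input, "plasma_input"))
  if (mean(tac$values) <= 0)
    stop("TAC has non-positive mean: kinetic fit is not identifiable",
         call. = FALSE)
  if (is.character(weights)) {
    weights <- match.arg(weights)
    w <- if (weights == "duration") tac$frame_durations
         else rep(1, length(tac$values))
  } else w <- as.numeric(weights)
  w <- w / sum(w)
  framing <- framing_scheme(tac$frame_durations)

  make_p <- function(th) {
    if (fit_k4) two_tissue_params(th[1], th[2], th[3], th[4])
    else two_tissue_params(th[1], th[2], 0, 0)
  }
  resid_fn <- function(th) {
    th <- pmax(th, c(1e-6, 1e-6, 0, 0)[seq_along(th)])
    pred <- simulate_2tcm(make_p(th), input, framing)$values
    sqrt(w) * (pred - tac$values)
  }
  starts <- list(c(0.1, 0.05, 0.01, 0.005),
                 c(0.3, 0.15, 0.05, 0.025),
                 c(0.5, 0.30, 0.10, 0.050),
                 c(0.05, 0.02, 0.002, 0.001))
  if (!is.null(init))
    starts <- c(list(c(init$K1, init$k2, init$k3, init$k4)), starts)
  npar <- if (fit_k4) 4L else 2L
  starts <- lapply(starts, function(s) s[seq_len(npar)])

  best <- NULL
  n_conv <- 0L
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         lower = rep(0, npar),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$par))) next
    n_conv <- n_conv + 1L
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("2TCM fit did not converge from any start", call. = FALSE)

  th <- pmax(best$par, c(1e-6, 1e-6, 0, 0)[seq_len(npar)])
  p <- make_p(th)
  vt <- tryCatch(vt_2tcm(p), error = function(e) NA_real_)

  identifiable <- is.finite(vt)
  if (identifiable) {
    se_vt <- tryCatch({
      J <- best$hessian                 # J'J from nls.lm
      dof <- max(length(tac$values) - npar, 1L)
      sigma2 <- best$deviance / dof
      covm <- sigma2 * solve(J)
      h <- 1e-4
      grad <- vapply(seq_len(npar), function(i) {
        thp <- th; thp[i] <- thp[i] + h
        thm <- th; thm[i] <- max(thm[i] - h, 0)
        (tryCatch(vt_2tcm(make_p(thp)), error = function(e) NA_real_) -
         tryCatch(vt_2tcm(make_p(thm)), error = function(e) NA_real_)) /
          (thp[i] - thm[i])
      }, numeric(1))
      sqrt(max(drop(t(grad) %*% covm %*% grad), 0))
    }, error = function(e) Inf)
    if (!is.finite(se_vt) || se_vt > abs(vt)) identifiable <- FALSE
  }
  list(params = p, vt = vt, sse = best$deviance,
       identifiable = identifiable, n_starts_converged = n_conv)
}
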