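test_that("synthetic plasma input rises to a single peak and scales linearly", {
  flat <- synth_plasma_input(peak_time = 30, peak_value = 40,
                             decay_rates = c(0, 0, 0))
  expect_equal(max(flat$concentration), 40)
  expect_equal(flat$concentration[flat$times >= 30],
               rep(40, sum(flat$times >= 30)))

  p1 <- synth_plasma_input(peak_value = 50)
  p2 <- synth_plasma_input(peak_value = 100)
  expect_equal(p2$concentration, 2 * p1$concentration, tolerance = 1e-12)

  # unimodal: one sign change of the finite difference
  d <- diff(p1$concentration)
  expect_equal(sum(diff(sign(d[d != 0])) != 0), 1)
  expect_error(synth_plasma_input(peak_value = -1), "positive")
})

test_that("two-tissue parameter container derives VT by the closed form", {
  expect_equal(vt_2tcm(two_tissue_params(0.3, 0.15, 0.05, 0.025)), 6)
  expect_equal(vt_2tcm(two_tissue_params(0.1, 0.05)), 2)
  expect_error(vt_2tcm(two_tissue_params(0.1, 0.05, 0.01, 0)),
               "irreversible")
  expect_error(two_tissue_params(0.1, 0), "k2")
  expect_error(two_tissue_params(-0.1, 0.05), "non-negative")
})

test_that("compartment simulation matches an independent ODE solver", {
  skip_if_not_installed("deSolve")
  input <- synth_plasma_input()
  framing <- framing_preset("fmz")
  p <- two_tissue_params(0.3, 0.15, 0.05, 0.025, Vb = 0.05)
  tac <- simulate_2tcm(p, input, framing)

  cp_fun <- stats::approxfun(input$times, input$concentration, rule = 2)
  deriv <- function(t, y, parms) {
    cp <- cp_fun(t)
    with(as.list(parms), list(c(
      K1 * cp - (k2 + k3) * y[1] + k4 * y[2],
      k3 * y[1] - k4 * y[2])))
  }
  parms <- c(K1 = p$K1 / 60, k2 = p$k2 / 60, k3 = p$k3 / 60, k4 = p$k4 / 60)
  times <- seq(0, 3600, by = 1)
  sol <- deSolve::lsoda(c(0, 0), times, deriv, parms,
                        rtol = 1e-10, atol = 1e-10)
  tissue <- (1 - p$Vb) * (sol[, 2] + sol[, 3]) + p$Vb * cp_fun(times)
  cum <- c(0, cumsum(diff(times) * (tissue[-length(tissue)] +
                                      tissue[-1]) / 2))
  fs <- framing$frame_start; fd <- framing$frame_duration
  at <- function(t) approx(times, cum, xout = t, rule = 2)$y
  expected <- (at(fs + fd) - at(fs)) / fd
  expect_equal(tac$values, expected, tolerance = 1e-4)
})

test_that("limiting cases of the compartment model behave analytically", {
  input <- synth_plasma_input()
  framing <- framing_preset("fmz")
  zero <- simulate_2tcm(two_tissue_params(0, 0.15), input, framing)
  expect_equal(zero$values, rep(0, length(zero$values)))

  # constant plasma: 1-tissue equilibrium at K1/k2
  const <- plasma_input(seq(0, 3600, 1), rep(10, 3601))
  one_t <- simulate_2tcm(two_tissue_params(0.1, 0.2), const, framing)
  expect_equal(one_t$values[length(one_t$values)] / 10, 0.1 / 0.2,
               tolerance = 0.01)

  # constant infusion: late TAC / Cp approaches VT for fast 2TCM kinetics
  p <- two_tissue_params(0.3, 0.4, 0.2, 0.2)
  two_t <- simulate_2tcm(p, const, framing)
  expect_equal(two_t$values[length(two_t$values)] / 10, vt_2tcm(p),
               tolerance = 0.01)
})

test_that("Logan slope recovers VT on noise-free curves", {
  input <- synth_plasma_input()
  framing <- framing_preset("fmz")
  tac1 <- simulate_2tcm(two_tissue_params(0.1, 0.05), input, framing)
  fit1 <- logan_vt(tac1, input, t_star = 1200)
  expect_equal(fit1$vt, 2.0, tolerance = 0.02)

  # slow reversible kinetics need the long protocol to linearise
  input90 <- synth_plasma_input(duration = 5400)
  framing90 <- framing_preset("pib")
  tac2 <- simulate_2tcm(two_tissue_params(0.3, 0.15, 0.05, 0.025),
                        input90, framing90)
  fit2 <- logan_vt(tac2, input90, t_star = 3000)
  expect_equal(fit2$vt, 6.0, tolerance = 0.05)

  auto <- logan_vt(tac2, input90, t_star = "auto")
  expect_gt(auto$diagnostics$t_star, 1000)
  expect_equal(auto$vt, 6.0, tolerance = 0.10)

  expect_error(logan_vt(tac1, input, t_star = 3500), "at least 3")
  bad <- tac2; bad$values[length(bad$values)] <- -1
  expect_error(logan_vt(bad, input90, t_star = 3000), "non-positive")
})

test_that("TAC noise biases the Logan slope downward, monotonically in noise", {
  input <- synth_plasma_input()
  framing <- framing_preset("fmz")
  tac <- simulate_2tcm(two_tissue_params(0.3, 0.15, 0.05, 0.025),
                       input, framing)
  vt0 <- logan_vt(tac, input, t_star = 1200)$vt
  mean_vt <- function(cov, reps) {
    vts <- vapply(seq_len(reps), function(r) {
      noisy <- tac
      noisy$values <- tac$values * (1 + cov * rnorm(length(tac$values)))
      tryCatch(logan_vt(noisy, input, t_star = 1200)$vt,
               error = function(e) NA_real_)
    }, numeric(1))
    mean(vts, na.rm = TRUE)
  }
  set.seed(31)
  ladder <- vapply(c(0.05, 0.10, 0.20), mean_vt, numeric(1), reps = 100)
  expect_true(all(ladder < vt0))
  expect_true(all(diff(c(vt0, ladder)) < 0))
})

test_that("parametric Logan maps agree with regional fits and zero out background", {
  input <- synth_plasma_input(duration = 5400)
  framing <- framing_preset("pib")
  gm <- simulate_2tcm(two_tissue_params(0.3, 0.15, 0.05, 0.025),
                      input, framing)
  wm <- simulate_2tcm(two_tissue_params(0.1, 0.05), input, framing)
  ph <- shared_small_phantom()
  # no blur: regions keep their exact time courses
  dyn <- simulate_dynamic_from_tacs(ph$mask,
                                    list(GM = gm, WM = wm, WM_core = wm),
                                    psf_model(0.01))
  vt_map <- logan_parametric_image(dyn, input, t_star = 3000)
  lab <- ph$mask$labels$data
  expect_equal(mean(vt_map$data[lab == 2]), 6.0, tolerance = 0.05)
  expect_equal(mean(vt_map$data[lab == 1]), 2.0, tolerance = 0.05)
  expect_equal(unique(vt_map$data[lab == 0]), 0)
  expect_equal(attr(vt_map, "n_failed"), sum(lab == 0))
  # regional fit and voxel fit coincide for uniform regions
  expect_equal(mean(vt_map$data[lab == 2]),
               logan_vt(gm, input, t_star = 3000)$vt, tolerance = 1e-6)
})

test_that("NLR fitting recovers parameters and flags degenerate input", {
  input <- synth_plasma_input()
  framing <- framing_preset("fmz")
  truth <- two_tissue_params(0.3, 0.15, 0.05, 0.025)
  tac <- simulate_2tcm(truth, input, framing)
  fit <- nlr_fit_2tcm(tac, input)
  expect_equal(fit$vt, 6.0, tolerance = 0.01)
  expect_true(fit$identifiable)

  one_t <- simulate_2tcm(two_tissue_params(0.1, 0.05), input, framing)
  fit1 <- nlr_fit_2tcm(one_t, input, fit_k4 = FALSE)
  expect_equal(fit1$params$K1 / fit1$params$k2, 2.0, tolerance = 0.01)

  set.seed(17)
  junk <- time_activity_curve(tac$frame_mid_times,
                              rnorm(length(tac$values), 0, 1),
                              tac$frame_durations)
  res <- tryCatch(nlr_fit_2tcm(junk, input), error = function(e) e)
  expect_true(inherits(res, "error") || !res$identifiable)
})
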