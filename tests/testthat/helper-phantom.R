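# small phantom + cached full-size simulation shared by the heavier tests

small_spec <- function(...) phantom_spec(shape = c(48, 48, 36), ...)

# lazily-computed shared objects (built once per test run)
.shared <- new.env(parent = emptyenv())

shared_hoffman_sim <- function() {
  if (is.null(.shared$sim)) {
    ph <- make_phantom(phantom_spec())
    dyn <- simulate_dynamic(ph$activity, psf_model(6.75),
                            framing_preset("hoffman18"), noise_model())
    .shared$sim <- list(ph = ph, dyn = dyn,
                        low = which(dyn$frame_duration <= 10),
                        high = which(dyn$frame_duration >= 300))
  }
  .shared$sim
}

shared_small_phantom <- function() {
  if (is.null(.shared$small)) .shared$small <- make_phantom(small_spec())
  .shared$small
}

# noise in the white-matter measurement: population SD over the uniform
# deep-WM noise VOI
wm_sd <- function(img, mask) {
  x <- img$data[mask$labels$data == 3]
  sqrt(mean((x - mean(x))^2))
}

# hot-GM kinetic phantom: regional 2TCM time courses on the small phantom
kinetic_phantom <- function(noise = NULL) {
  ph <- shared_small_phantom()
  input <- synth_plasma_input()
  framing <- framing_preset("fmz")
  gm_tac <- simulate_2tcm(two_tissue_params(0.3, 0.15, 0.05, 0.025),
                          input, framing)
  wm_tac <- simulate_2tcm(two_tissue_params(0.15, 0.075), input, framing)
  dyn <- simulate_dynamic_from_tacs(
    ph$mask, list(GM = gm_tac, WM = wm_tac, WM_core = wm_tac),
    psf_model(6.75), noise = noise)
  list(ph = ph, dyn = dyn, input = input,
       vt_gm_true = vt_2tcm(two_tissue_params(0.3, 0.15, 0.05, 0.025)),
       vt_wm_true = vt_2tcm(two_tissue_params(0.15, 0.075)))
}
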