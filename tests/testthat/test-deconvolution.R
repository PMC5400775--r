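test_that("config validation rejects bad iteration counts and weights", {
  expect_error(deconv_config(n_iterations = -1), "non-negative")
  expect_error(deconv_config(prior_weight = 1.2), "\\[0, 1\\]")
  expect_error(deconv_config(algorithm = "unsharp"))
  # non-negativity default: on for Lucy-Richardson, off for Van Cittert
  expect_false(deconv_config("vc_classic")$enforce_nonnegativity)
  expect_true(deconv_config("lucy_richardson")$enforce_nonnegativity)
})

test_that("all algorithms leave a uniform volume unchanged and n = 0 is the identity", {
  u <- image_volume(array(4.2, c(16, 16, 16)), c(2, 2, 2))
  for (alg in c("vc_paper", "vc_classic", "vc_reblurred")) {
    out <- vc_iterate(u, deconv_config(alg, n_iterations = 8,
                                       prior_type = "none", prior_weight = 0))
    expect_equal(out$data, u$data, tolerance = 1e-10)
  }
  out <- lucy_richardson(u, deconv_config("lucy_richardson",
                                          n_iterations = 8,
                                          prior_type = "none",
                                          prior_weight = 0))
  expect_equal(out$data, u$data, tolerance = 1e-8)

  x <- random_volume(16)
  for (alg in c("vc_classic", "lucy_richardson")) {
    out <- deconvolve(x, deconv_config(alg, n_iterations = 0))
    expect_identical(out$data, x$data)
  }
})

test_that("the current-estimate recursion matches the (2 - H)^n spectrum oracle", {
  x <- random_volume(32, seed = 11)
  for (n in c(1, 2, 4, 8)) {
    cfg <- deconv_config("vc_paper", n_iterations = n, prior_type = "none",
                         prior_weight = 0, boundary = "periodic")
    out <- vc_iterate(x, cfg)
    expected <- fft_vc_paper(x$data, 6.75, c(2, 2, 2), n)
    expect_lt(rel_err(out$data, expected), 1e-6)
  }
})

test_that("classic Van Cittert restores regional activity monotonically", {
  ph <- shared_small_phantom()
  g <- gaussian_blur(ph$activity, psf_model(6.75))
  biases <- vapply(c(0, 2, 4, 8, 16), function(n) {
    cfg <- deconv_config("vc_classic", n_iterations = n,
                         prior_type = "none", prior_weight = 0)
    gm_bias(vc_iterate(g, cfg), ph$mask, 25)
  }, numeric(1))
  # spill-out bias is negative and shrinks monotonically with iterations
  expect_true(all(biases < 0))
  expect_true(all(diff(biases) > 0))
  expect_lt(abs(biases[5]), abs(biases[1]) / 2)
})

test_that("Lucy-Richardson conserves flux and sharpens a blurred impulse", {
  x <- random_volume(32, seed = 3)
  cfg <- deconv_config("lucy_richardson", n_iterations = 50,
                       prior_type = "none", prior_weight = 0,
                       boundary = "periodic")
  out <- lucy_richardson(x, cfg)
  expect_lt(abs(sum(out$data) - sum(x$data)) / sum(x$data), 1e-8)

  arr <- array(0, c(33, 33, 33)); arr[17, 17, 17] <- 1000
  g <- gaussian_blur(image_volume(arr, c(2, 2, 2)), psf_model(6.75),
                     boundary = "periodic")
  peaks <- vapply(c(5, 15, 50), function(n) {
    cfg <- deconv_config("lucy_richardson", n_iterations = n,
                         prior_type = "none", prior_weight = 0,
                         boundary = "periodic")
    max(lucy_richardson(g, cfg)$data)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
  # multiplicative update recovers a point source faster than the additive
  # classic Van Cittert at equal iteration count
  vc <- vc_iterate(g, deconv_config("vc_classic", n_iterations = 50,
                                    prior_type = "none", prior_weight = 0,
                                    boundary = "periodic"))
  expect_gt(peaks[3], max(vc$data))

  neg <- x; neg$data[1] <- -1
  expect_error(lucy_richardson(neg, cfg), "non-negative")
})

test_that("spatial priors act as declared on spikes, constants and weight 0", {
  x <- random_volume(12, seed = 5)
  expect_identical(apply_prior(x, "median", 0)$data, x$data)
  expect_identical(apply_prior(x, "none", 0.5)$data, x$data)
  u <- image_volume(array(3.3, c(12, 12, 12)), c(2, 2, 2))
  expect_equal(apply_prior(u, "median", 0.7)$data, u$data, tolerance = 1e-12)
  expect_equal(apply_prior(u, "gibbs", 0.7)$data, u$data, tolerance = 1e-12)

  spike <- array(0, c(9, 9, 9)); spike[5, 5, 5] <- 10
  sv <- image_volume(spike, c(2, 2, 2))
  # 27-voxel neighbourhood median of the spike voxel is 0
  expect_equal(apply_prior(sv, "median", 1)$data[5, 5, 5], 0)
  # Gibbs local mean: spike pulled to 10/27
  expect_equal(apply_prior(sv, "gibbs", 1)$data[5, 5, 5], 10 / 27,
               tolerance = 1e-12)
  expect_error(apply_prior(x, "median", 1.5), "\\[0, 1\\]")
})

test_that("unregularised sharpening amplifies noise monotonically with iterations", {
  set.seed(99)
  noisy <- image_volume(array(rpois(32^3, 100), c(32, 32, 32)), c(2, 2, 2))
  sds <- vapply(0:10, function(n) {
    cfg <- deconv_config("vc_paper", n_iterations = n, prior_type = "none",
                         prior_weight = 0)
    sd(vc_iterate(noisy, cfg)$data)
  }, numeric(1))
  expect_true(all(diff(sds) >= 0))
})

test_that("deconvolution increases grey/white contrast on the blurred phantom", {
  ph <- shared_small_phantom()
  g <- gaussian_blur(ph$activity, psf_model(6.75))
  lab <- ph$mask$labels$data
  contrast <- function(img)
    mean(img$data[lab == 2]) / mean(img$data[lab == 1 | lab == 3])
  out <- vc_iterate(g, deconv_config(n_iterations = 8))
  expect_gt(contrast(out), contrast(g))
})

test_that("non-finite blow-ups raise a divergence error naming the iteration", {
  x <- random_volume(8)
  x$data <- x$data * 1e308
  cfg <- deconv_config("vc_paper", n_iterations = 30, prior_type = "none",
                       prior_weight = 0)
  expect_error(vc_iterate(x, cfg), "iteration [0-9]+")
})
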