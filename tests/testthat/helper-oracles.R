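# independent frequency-domain oracles for the periodic-boundary operators

# 1D DFT of a centred kernel embedded circularly in length n
kernel_transfer_1d <- function(k, n) {
  r <- (length(k) - 1) / 2
  v <- numeric(n)
  idx <- ((-r:r) %% n) + 1
  v[idx] <- v[idx] + k
  fft(v)
}

# 3D transfer function of a separable kernel set on an n1 x n2 x n3 grid
transfer_3d <- function(kernels, dims) {
  h1 <- kernel_transfer_1d(kernels[[1]], dims[1])
  h2 <- kernel_transfer_1d(kernels[[2]], dims[2])
  h3 <- kernel_transfer_1d(kernels[[3]], dims[3])
  outer(outer(h1, h2), h3)
}

# sampled unit-mass Gaussian kernel, as the package constructs it
oracle_kernel <- function(fwhm_mm, voxel_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# circular convolution via FFT
fft_blur <- function(arr, fwhm_mm, voxel_mm) {
  ks <- lapply(voxel_mm, function(v) oracle_kernel(fwhm_mm, v))
  H <- transfer_3d(ks, dim(arr))
  Re(fft(fft(arr) * H, inverse = TRUE)) / length(arr)
}

# closed-form spectrum of n iterations of the current-estimate Van Cittert
# recursion under periodic boundary: multiply by (2 - H)^n
fft_vc_paper <- function(arr, fwhm_mm, voxel_mm, n) {
  ks <- lapply(voxel_mm, function(v) oracle_kernel(fwhm_mm, v))
  H <- transfer_3d(ks, dim(arr))
  Re(fft(fft(arr) * (2 - H)^n, inverse = TRUE)) / length(arr)
}

rel_err <- function(a, b) max(abs(a - b)) / max(abs(b))

random_volume <- function(n = 32, voxel = c(2, 2, 2), seed = 42) {
  set.seed(seed)
  image_volume(array(runif(n^3, 0, 10), c(n, n, n)), voxel_size = voxel)
}
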