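#' Discrete 1-D Gaussian kernel
#'
#' Kernel weights sampled at integer voxel offsets, truncated at
#' `radius_sigmas` standard deviations and normalized to sum to one.
#'
#' @param sigma_vox Standard deviation in voxel units (> 0).
#' @param radius_sigmas Truncation radius in multiples of sigma.
#' @return Numeric vector of length `2*ceiling(radius_sigmas*sigma_vox) + 1`.
#' @export
gaussian_kernel_1d <- function(sigma_vox, radius_sigmas = 3) {
  stopifnot(is.numeric(sigma_vox), length(sigma_vox) == 1L, sigma_vox > 0)
  r <- ceiling(radius_sigmas * sigma_vox)
  x <- seq.int(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Band matrix applying a symmetric FIR kernel along one dimension with
# zero padding outside the array (a map that is 0 outside the head).
.conv_band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  B <- matrix(0, n, n)
  for (off in seq.int(-r, r)) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= n
    B[cbind(i[ok], j[ok])] <- kernel[off + r + 1L]
  }
  B
}

#' Separable 3-D Gaussian smoothing with zero padding
#'
#' Convolves a 3-D array with a truncated, normalized Gaussian kernel,
#' axis by axis. The FWHM is given in millimetres and converted per axis
#' using the voxel size, so anisotropic voxels are handled correctly
#' (sigma_vox = FWHM / 2.3548 / voxel_size per axis). Values outside the
#' array are treated as zero.
#'
#' @param arr 3-D numeric array.
#' @param fwhm_mm Full width at half maximum of the kernel, mm.
#' @param voxel_size_mm Voxel edge lengths, mm; recycled to length 3.
#' @param radius_sigmas Kernel truncation radius in sigmas.
#' @return Smoothed array of the same shape.
#' @export
smooth_gaussian_3d <- function(arr, fwhm_mm, voxel_size_mm,
                               radius_sigmas = 3) {
  stopifnot(length(dim(arr)) == 3L, fwhm_mm >= 0)
  if (fwhm_mm == 0) return(arr)
  vs <- rep_len(voxel_size_mm, 3L)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  out <- arr
  for (ax in 1:3) {
    k <- gaussian_kernel_1d(sigma_vox[ax], radius_sigmas)
    if (length(k) == 1L) next
    out <- .apply_kernel_axis(out, k, ax)
  }
  out
}

.apply_kernel_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  B <- .conv_band_matrix(dp[1L], kernel)
  y <- B %*% matrix(x, nrow = dp[1L])
  dim(y) <- dp
  aperm(y, order(perm))
}
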