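# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

default_spec <- function() fixture("spec", phantom_spec)
default_labels <- function() fixture("labels", function() build_phantom(default_spec()))
default_truth <- function() fixture("truth", kinetic_truth)
default_cp <- function() fixture("cp", simulate_input_function)
default_sched <- function() fixture("sched", default_frame_schedule)
default_fbwm <- function() fixture("fbwm", function() make_fbwm_series(default_labels()))
default_cs <- function() fixture("cs", function() cs_analogue_mask(default_labels(), default_spec()))
default_gm_rois <- function() fixture("gm_rois", function() merge_gm_rois(default_labels()))

# a coarse phantom (3 mm voxels, 64^3) for tests that only need geometry
small_spec <- function() fixture("small_spec", function()
  phantom_spec(grid_shape = c(64L, 64L, 64L), voxel_size_mm = 3))
small_labels <- function() fixture("small_labels", function() build_phantom(small_spec()))

# dense numeric convolution of the one-tissue model (independent oracle)
onetcm_oracle <- function(K1, k2, cp, schedule, dt = 0.002) {
  t_max <- max(schedule$frame_end_min)
  tt <- seq(0, t_max, by = dt)
  cpv <- eval_input(cp, tt)
  # C(t_i) on the dense grid by trapezoidal convolution with exp(-k2 u)
  ker <- exp(-k2 * tt)
  n <- length(tt)
  conv <- stats::convolve(cpv, rev(ker), type = "open")[seq_len(n)] * dt
  # trapezoid end-correction
  conv <- conv - dt * (cpv * ker[1] + cpv[1] * ker) / 2
  C <- K1 * conv
  vapply(seq_len(nrow(schedule)), function(i) {
    sel <- which(tt >= schedule$frame_start_min[i] - dt / 2 &
                   tt <= schedule$frame_end_min[i] + dt / 2)
    # trapezoidal time-average of C over the frame
    h <- diff(tt[sel])
    sum(h * (C[sel[-1]] + C[sel[-length(sel)]]) / 2) /
      (tt[sel[length(sel)]] - tt[sel[1]])
  }, numeric(1))
}

# direct (triple-loop) 3-D Gaussian convolution, zero padding
smooth_bruteforce <- function(arr, fwhm_mm, voxel_size_mm, radius_sigmas = 3) {
  vs <- rep_len(voxel_size_mm, 3L)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  ks <- lapply(sig, function(s) {
    r <- ceiling(radius_sigmas * s)
    x <- seq(-r, r)
    k <- exp(-x^2 / (2 * s^2))
    k / sum(k)
  })
  k3 <- outer(outer(ks[[1]], ks[[2]]), ks[[3]])
  r <- (dim(k3) - 1) / 2
  d <- dim(arr)
  out <- array(0, d)
  # direct (non-separable) convolution with the full 3-D kernel,
  # accumulated offset by offset with zero padding
  rng <- function(n, off) pmax(1, 1 - off):pmin(n, n - off)
  for (di in -r[1]:r[1]) for (dj in -r[2]:r[2]) for (dk in -r[3]:r[3]) {
    w <- k3[di + r[1] + 1, dj + r[2] + 1, dk + r[3] + 1]
    ix <- rng(d[1], di); jx <- rng(d[2], dj); kx <- rng(d[3], dk)
    out[ix, jx, kx] <- out[ix, jx, kx] +
      w * arr[ix + di, jx + dj, kx + dk]
  }
  out
}
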