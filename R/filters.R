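# Separable 3D image filters used by the native extraction engine:
# undecimated single-level Haar wavelet subbands and Laplacian-of-Gaussian
# responses. All filtering uses replicate (nearest-edge) padding so output
# grids keep the input shape.

# Shift a 3D array by one voxel along `axis` (direction +1), replicating the
# far edge.
shift_replicate <- function(a, axis) {
  dm <- dim(a)
  n <- dm[axis]
  idx <- rep(list(quote(expr = )), 3L)
  idx[[axis]] <- c(seq(2L, n), n)
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# One undecimated Haar step along `axis`: returns list(L, H) with
# L = (x_i + x_{i+1})/sqrt(2), H = (x_i - x_{i+1})/sqrt(2).
haar_step <- function(a, axis) {
  nxt <- shift_replicate(a, axis)
  s <- sqrt(2)
  list(L = (a + nxt) / s, H = (a - nxt) / s)
}

# All 8 single-level Haar subbands, named by the filter applied along
# (x, y, z): "LLH" = lowpass in x and y, highpass in z.
haar_subbands <- function(a) {
  sx <- haar_step(a, 1L)
  out <- list()
  for (fx in c("L", "H")) {
    sy <- haar_step(sx[[fx]], 2L)
    for (fy in c("L", "H")) {
      sz <- haar_step(sy[[fy]], 3L)
      for (fz in c("L", "H"))
        out[[paste0(fx, fy, fz)]] <- sz[[fz]]
    }
  }
  out
}

# Convolve along one axis with an odd symmetric kernel, replicate padding.
convolve_axis <- function(a, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  stopifnot(r == floor(r), r >= 0)
  if (r == 0L) return(a * kernel)
  ord <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, ord)
  dm <- dim(ap)
  m <- matrix(ap, dm[1], dm[2] * dm[3])
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
              m[rep(dm[1], r), , drop = FALSE])
  f <- stats::filter(mp, kernel, method = "convolution", sides = 2)
  f <- as.matrix(f)[(r + 1L):(r + dm[1]), , drop = FALSE]
  back <- array(f, dm)
  aperm(back, order(ord))
}

# Normalized 1D Gaussian kernel, sigma in voxels, truncated at 4 sigma.
gaussian_kernel <- function(sigma_vox, truncate = 4) {
  r <- max(1L, ceiling(truncate * sigma_vox))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Gaussian smoothing with physical sigma (mm), anisotropy-aware.
gaussian_smooth <- function(a, sigma_mm, spacing_mm) {
  for (axis in 1:3)
    a <- convolve_axis(a, gaussian_kernel(sigma_mm / spacing_mm[axis]), axis)
  a
}

# Laplacian of Gaussian: smooth at sigma_mm, then the discrete Laplacian
# (second central differences scaled by spacing^2, summed over axes).
log_filter <- function(a, sigma_mm, spacing_mm) {
  g <- gaussian_smooth(a, sigma_mm, spacing_mm)
  out <- array(0, dim(a))
  for (axis in 1:3)
    out <- out + convolve_axis(g, c(1, -2, 1), axis) / spacing_mm[axis]^2
  out
}
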