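# Image restoration: frequency-domain low-pass denoising and
# Richardson-Lucy deconvolution, applied per view before segmentation.

# 2D FFT helpers (base stats::fft; images are matrices [row = y, col = x])
fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

# DFT frequency axis in cycles/pixel, matching stats::fft ordering
fft_freqs <- function(n) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / n
}

# reflect-pad a matrix by (py, px) on each side
pad_reflect <- function(img, py, px) {
  h <- nrow(img); w <- ncol(img)
  if (py >= h || px >= w)
    stop("padding exceeds image size")
  ridx <- c(rev(seq_len(py) + 1L), seq_len(h), h - seq_len(py))
  cidx <- c(rev(seq_len(px) + 1L), seq_len(w), w - seq_len(px))
  img[ridx, cidx, drop = FALSE]
}

# circular 'same' convolution of img with a small centred kernel, via FFT
conv2_circular <- function(img, kernel) {
  h <- nrow(img); w <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  cy <- (kh - 1L) %/% 2L; cx <- (kw - 1L) %/% 2L
  kp <- matrix(0, h, w)
  ry <- ((seq_len(kh) - 1L - cy) %% h) + 1L
  rx <- ((seq_len(kw) - 1L - cx) %% w) + 1L
  kp[ry, rx] <- kernel
  ifft2(fft2(img) * fft2(kp))
}

# 'same' convolution with reflective border handling
conv2_reflect <- function(img, kernel) {
  py <- (nrow(kernel) - 1L) %/% 2L + 1L
  px <- (ncol(kernel) - 1L) %/% 2L + 1L
  padded <- pad_reflect(img, py, px)
  out <- conv2_circular(padded, kernel)
  out[py + seq_len(nrow(img)), px + seq_len(ncol(img)), drop = FALSE]
}

#' Normalised 2D Gaussian convolution kernel
#'
#' @param sigma_px Gaussian sd in pixels, > 0.
#' @param radius_px Kernel half-width; default `ceiling(4 * sigma_px)`.
#' @return Odd-sized square matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma_px, radius_px = ceiling(4 * sigma_px)) {
  stopifnot(sigma_px > 0, radius_px >= 1)
  ax <- seq(-radius_px, radius_px)
  g <- exp(-ax^2 / (2 * sigma_px^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Low-pass denoise an image in the frequency domain
#'
#' Attenuates spatial frequencies above a cutoff using a Gaussian transfer
#' function `H(f) = exp(-2 (f/f_c)^2)` with `f_c = cutoff * Nyquist`
#' (so `H(f_c) = e^-2 ~ 0.14` and frequencies 1.5x the cutoff are suppressed
#' ~90-fold). A Gaussian response is used rather than an ideal brick-wall
#' filter to avoid ringing around bright particles. Output is clipped at 0.
#'
#' @param img Numeric matrix.
#' @param cutoff Cutoff frequency in cycles/pixel, in (0, 0.5];
#'   `cutoff = 0.5` is the Nyquist frequency. Default 0.3.
#' @return Filtered image, same shape, non-negative.
#' @export
lowpass_denoise <- function(img, cutoff = 0.3) {
  if (!is.matrix(img) || !is.numeric(img)) stop("'img' must be a numeric matrix")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 ||
      cutoff > 0.5)
    stop("'cutoff' must lie in (0, 0.5] (fraction of sampling frequency)")
  fy <- fft_freqs(nrow(img))
  fx <- fft_freqs(ncol(img))
  f2 <- outer(fy^2, fx^2, `+`)
  H <- exp(-2 * f2 / cutoff^2)
  out <- ifft2(fft2(img) * H)
  out[out < 0] <- 0
  out
}

#' Richardson-Lucy deconvolution
#'
#' Iterative maximum-likelihood restoration under Poisson noise:
#' `e_{k+1} = e_k * (psf~ (*) (img / (psf (*) e_k)))`, starting from
#' `e_0 = img`, where `psf~` is the mirrored PSF. Convolutions use
#' reflective border padding; the ratio is guarded by a small epsilon
#' (default 1e-12) against division by zero. Iteration stops early when the
#' mean relative change drops below `tol`.
#'
#' @param img Non-negative numeric matrix.
#' @param psf_kernel Non-negative kernel summing to 1 (within 1e-6), e.g.
#'   from [gaussian_kernel()].
#' @param n_iter Maximum iterations, >= 1. Default 10.
#' @param tol Early-stopping threshold on mean relative change. Default 1e-4.
#' @param eps Guard added to the denominator. Default 1e-12.
#' @return Deconvolved image; non-negative, same shape.
#' @export
deconvolve_rl <- function(img, psf_kernel, n_iter = 10L, tol = 1e-4,
                          eps = 1e-12) {
  if (!is.matrix(img)) stop("'img' must be a non-negative matrix")
  # tolerate FFT round-off from upstream filtering, reject real negatives
  if (any(img < -1e-8 * max(abs(img), 1)))
    stop("'img' must be a non-negative matrix")
  img[img < 0] <- 0
  if (!is.matrix(psf_kernel) || any(psf_kernel < 0))
    stop("'psf_kernel' must be a non-negative matrix")
  s <- sum(psf_kernel)
  if (s <= 0 || abs(s - 1) > 1e-6)
    stop("'psf_kernel' must have entries summing to 1")
  if (n_iter < 1L) stop("'n_iter' must be >= 1")
  psf_m <- psf_kernel[rev(seq_len(nrow(psf_kernel))),
                      rev(seq_len(ncol(psf_kernel))), drop = FALSE]
  e <- img
  for (it in seq_len(n_iter)) {
    blurred <- conv2_reflect(e, psf_kernel)
    ratio <- img / (blurred + eps)
    e_new <- e * conv2_reflect(ratio, psf_m)
    e_new[e_new < 0] <- 0
    delta <- mean(abs(e_new - e)) / (mean(abs(e)) + eps)
    e <- e_new
    if (delta < tol) break
  }
  e
}
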