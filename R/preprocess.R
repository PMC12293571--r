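# Frequency-domain convolution with a centred small kernel, circular
# boundary. The kernel FFT is cached by callers that convolve repeatedly
# (Richardson-Lucy re-uses one PSF for every iteration).

kernel_fft <- function(kernel, dims) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (kh > dims[1] || kw > dims[2]) {
    # crop an oversized kernel centrally, preserving its normalisation
    # (unit sum for smoothing kernels, zero sum for derivative kernels)
    s0 <- sum(kernel)
    rr <- (dims[1] - 1L) %/% 2L; rc <- (dims[2] - 1L) %/% 2L
    cr <- (kh + 1L) %/% 2L; cc <- (kw + 1L) %/% 2L
    rows <- max(1L, cr - rr):min(kh, cr + rr)
    cols <- max(1L, cc - rc):min(kw, cc + rc)
    kernel <- kernel[rows, cols, drop = FALSE]
    if (abs(s0) < 1e-8) {
      kernel <- kernel - mean(kernel)
    } else if (sum(kernel) != 0) {
      kernel <- kernel * (s0 / sum(kernel))
    }
    kh <- nrow(kernel); kw <- ncol(kernel)
  }
  pad <- matrix(0, dims[1], dims[2])
  pad[seq_len(kh), seq_len(kw)] <- kernel
  # rotate so the kernel centre sits at (1,1): circular shift by centre-1
  cr <- (kh + 1L) %/% 2L; cc <- (kw + 1L) %/% 2L
  pad <- pad[c(cr:dims[1], seq_len(cr - 1L)), c(cc:dims[2], seq_len(cc - 1L)),
             drop = FALSE]
  stats::fft(pad)
}

fft_convolve <- function(image, kfft) {
  Re(stats::fft(stats::fft(image) * kfft, inverse = TRUE)) / length(image)
}

# Normalised isotropic Gaussian kernel, truncated at 4 sigma.
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Scale-normalised Laplacian-of-Gaussian kernel (sigma^2 * LoG), adjusted
# to exact zero sum so the response is invariant to additive offsets.
# Positive response at the centre of DARK blobs of matching scale.
log_kernel <- function(sigma) {
  r <- max(2L, ceiling(4 * sigma))
  x <- -r:r
  xs <- outer(x^2, rep(1, length(x))); ys <- t(xs)
  r2 <- xs + ys
  g <- exp(-r2 / (2 * sigma^2)) / (2 * pi * sigma^2)
  k <- (r2 - 2 * sigma^2) / sigma^4 * g       # analytic Laplacian of G
  k <- k - mean(k)                            # enforce zero DC response
  k * sigma^2                                 # scale normalisation
}

#' Richardson-Lucy deconvolution with a Gaussian point-spread function
#'
#' Sharpens a channel before segmentation using the standard
#' Richardson-Lucy multiplicative update with a normalised isotropic
#' Gaussian PSF. The update conserves total flux and keeps the estimate
#' non-negative. With `iterations = 0` or `psf_sigma_px = 0` the input is
#' returned unchanged. Intensity measurements downstream are always taken
#' on the original channel; this enhancement only feeds segmentation.
#'
#' @param image Non-negative numeric matrix (one channel).
#' @param psf_sigma_px Gaussian PSF sigma in pixels (>= 0; default 1.5).
#' @param iterations Number of RL iterations (>= 0; default 10).
#' @return Enhanced channel, same dimensions, non-negative.
#' @export
enhance_richardson_lucy <- function(image, psf_sigma_px = 1.5,
                                    iterations = 10L) {
  if (any(image < 0)) stop("image must be non-negative", call. = FALSE)
  if (psf_sigma_px < 0) stop("psf_sigma_px must be >= 0", call. = FALSE)
  if (iterations < 0) stop("iterations must be >= 0", call. = FALSE)
  if (iterations == 0 || psf_sigma_px == 0) return(image)
  dims <- dim(image)
  kfft <- kernel_fft(gaussian_kernel(psf_sigma_px), dims)
  eps <- 1e-12
  est <- image
  for (i in seq_len(iterations)) {
    blurred <- fft_convolve(est, kfft)
    ratio <- image / pmax(blurred, eps)
    # Gaussian PSF is symmetric: correlation equals convolution
    est <- est * fft_convolve(ratio, kfft)
    est[est < 0] <- 0
  }
  est
}

#' Enhance dark spheroidal structures (nucleoli) in a nucleoplasmic channel
#'
#' Nucleoli appear as dark round holes in RNA polymerase II staining. This
#' operation turns them into bright local maxima: a multi-scale
#' scale-normalised Laplacian-of-Gaussian bank (5 logarithmically spaced
#' scales spanning the requested diameter band, `sigma = diameter/(2*sqrt(2))`
#' at the band edges) responds positively at dark-blob centres; a guard
#' scale at 2.5 times the upper band edge is subtracted so that structures
#' larger than the band (and step edges, whose scale-normalised response
#' grows with sigma) are suppressed rather than merely down-weighted. The
#' result is clamped at zero and scaled by `sensitivity / 1000`.
#'
#' The response is invariant to additive intensity offsets (zero-sum
#' kernels) and translation-equivariant away from the image border.
#'
#' @param image Numeric matrix, typically the RNA Pol II channel.
#' @param size_min_um,size_max_um Diameter band in micrometres
#'   (0 < min < max; defaults 3 and 15).
#' @param sensitivity Linear gain on the response; 1000 = unit gain
#'   (default 1133, the reference configuration).
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param n_scales Number of scales across the band (default 5).
#' @return Non-negative response map, same dimensions as `image`.
#' @export
enhance_dark_spheres <- function(image, size_min_um = 3, size_max_um = 15,
                                 sensitivity = 1133, pixel_size_um = 0.173,
                                 n_scales = 5L) {
  if (size_min_um <= 0 || size_min_um >= size_max_um) {
    stop("require 0 < size_min_um < size_max_um", call. = FALSE)
  }
  sig_lo <- length_um_to_px(size_min_um, pixel_size_um) / (2 * sqrt(2))
  sig_hi <- length_um_to_px(size_max_um, pixel_size_um) / (2 * sqrt(2))
  sigmas <- exp(seq(log(sig_lo), log(sig_hi), length.out = n_scales))
  dims <- dim(image)
  resp <- matrix(-Inf, dims[1], dims[2])
  for (s in sigmas) {
    r <- fft_convolve(image, kernel_fft(log_kernel(s), dims))
    resp <- pmax(resp, r)
  }
  guard <- fft_convolve(image, kernel_fft(log_kernel(2.5 * sig_hi), dims))
  out <- resp - pmax(guard, 0)
  out[out < 0] <- 0
  out * (sensitivity / 1000)
}

# Response for small BRIGHT blobs (marker foci). Foci ride on locally
# bright pedestals (the nucleolus itself), whose boundaries would leak
# into any plain band-pass response; a white top-hat with a square
# element of half-width 0.75x the blob diameter first removes every
# structure wider than ~1.5 blob diameters (pedestal and its edges),
# then a matched-scale negated LoG localises the remaining peaks. Light
# pre-smoothing keeps single-pixel shot noise out of the top-hat.
bright_blob_response <- function(image, diameter_px, presmooth_sigma = 1) {
  sigma <- diameter_px / (2 * sqrt(2))
  dims <- dim(image)
  sm <- if (presmooth_sigma > 0) {
    fft_convolve(image, kernel_fft(gaussian_kernel(presmooth_sigma), dims))
  } else image
  r_se <- max(2L, as.integer(round(0.75 * diameter_px)))
  th <- sm - grey_open(sm, r_se)
  out <- -fft_convolve(th, kernel_fft(log_kernel(sigma), dims))
  # robust noise scale of the response, taken before clamping (the
  # unclamped response is zero-median over signal-free regions; blobs
  # occupy too few pixels to move the MAD)
  noise <- stats::mad(out)
  out[out < 0] <- 0
  attr(out, "noise_scale") <- noise
  out
}

# greyscale morphology with a (2r+1)^2 square structuring element,
# computed as r iterations of a 3x3 min/max filter; the image border is
# treated as non-constraining
grey_erode <- function(m, r) iterate_minmax(m, r, pmin, Inf)
grey_dilate <- function(m, r) iterate_minmax(m, r, pmax, -Inf)
grey_open <- function(m, r) grey_dilate(grey_erode(m, r), r)

iterate_minmax <- function(m, r, op, fill) {
  for (k in seq_len(r)) {
    acc <- m
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      acc <- op(acc, shift_matrix(m, dr, dc, fill = fill))
    }
    m <- acc
  }
  m
}
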