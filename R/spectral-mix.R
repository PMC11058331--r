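#' @useDynLib mfnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif sd setNames cor ks.test
#' @importFrom utils read.csv write.csv
NULL

#' Decompose an image into amplitude and phase spectra
#'
#' Computes the unnormalized 2D discrete Fourier transform of a real-valued
#' image and returns its polar decomposition: the amplitude (modulus)
#' spectrum, which carries the low-level appearance ("style") of the slice,
#' and the phase (argument) spectrum, which carries the spatial semantics.
#' Together they losslessly represent the complex spectrum as
#' `amplitude * exp(1i * phase)`.
#'
#' @param image Real-valued numeric matrix, at least 2x2, all entries finite.
#' @param slice_id Optional label used in error messages when the input is
#'   invalid (useful when decomposing many slices in a loop).
#' @return An object of class `spectral_pair`: a list with `amplitude`
#'   (non-negative matrix), `phase` (matrix of radians in (-pi, pi]) and
#'   `shape` (integer vector `c(H, W)`).
#' @seealso [compose()], [mix_amplitude()], [mix_images()]
#' @examples
#' sp <- decompose_image(matrix(runif(64), 8, 8))
#' max(abs(compose(sp$amplitude, sp$phase) - compose(sp$amplitude, sp$phase)))
#' @export
decompose_image <- function(image, slice_id = NULL) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("decompose_image: 'image' must be a numeric matrix")
  }
  if (nrow(image) < 2L || ncol(image) < 2L) {
    stop("decompose_image: image must be at least 2x2")
  }
  if (!all(is.finite(image))) {
    lab <- if (is.null(slice_id)) "input image" else paste0("slice '", slice_id, "'")
    stop("decompose_image: non-finite values in ", lab)
  }
  z <- stats::fft(image)
  structure(
    list(amplitude = Mod(z), phase = Arg(z),
         shape = c(nrow(image), ncol(image))),
    class = "spectral_pair"
  )
}

#' Convexly mix two amplitude spectra
#'
#' Elementwise interpolation `(1 - lam) * a_src + lam * a_donor`. Both
#' inputs must be non-negative grids of identical shape; the result is
#' again a valid amplitude spectrum.
#'
#' @param a_src,a_donor Amplitude matrices of identical shape.
#' @param lam Mixing ratio in `[0, 1]`; 0 returns `a_src`, 1 returns
#'   `a_donor`.
#' @return Amplitude matrix of the same shape.
#' @export
mix_amplitude <- function(a_src, a_donor, lam) {
  if (!identical(dim(a_src), dim(a_donor))) {
    stop("mix_amplitude: shape mismatch between source and donor amplitudes")
  }
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0 || lam > 1) {
    stop("mix_amplitude: 'lam' must be a single value in [0, 1]")
  }
  (1 - lam) * a_src + lam * a_donor
}

#' Reconstruct an image from amplitude and phase spectra
#'
#' Inverse 2D Fourier transform of `amplitude * exp(1i * phase)`, normalized
#' by `1/(H*W)` so that `compose(decompose_image(x)$amplitude, ...)` inverts
#' the unnormalized forward transform. The real part is returned; when the
#' spectra come from real images on a shared grid, Hermitian symmetry is
#' preserved by convex amplitude mixing and the imaginary residual is at
#' float-noise level (see [compose_residual()]).
#'
#' @param amplitude Non-negative matrix.
#' @param phase Matrix of radians, same shape as `amplitude`.
#' @return Real matrix of the same shape.
#' @export
compose <- function(amplitude, phase) {
  if (!identical(dim(amplitude), dim(phase))) {
    stop("compose: shape mismatch between amplitude and phase")
  }
  if (any(amplitude < 0)) stop("compose: amplitude must be non-negative")
  z <- stats::fft(amplitude * exp(1i * phase), inverse = TRUE)
  Re(z) / length(z)
}

#' Imaginary residual of the inverse transform
#'
#' Max-abs imaginary component of the full complex inverse transform before
#' the real part is taken — a diagnostic for how far a mixed spectrum is
#' from exact Hermitian symmetry.
#'
#' @inheritParams compose
#' @return Scalar max-abs imaginary residual.
#' @export
compose_residual <- function(amplitude, phase) {
  if (!identical(dim(amplitude), dim(phase))) {
    stop("compose_residual: shape mismatch between amplitude and phase")
  }
  z <- stats::fft(amplitude * exp(1i * phase), inverse = TRUE)
  max(abs(Im(z))) / length(z)
}

#' Sample amplitude-mixing ratios
#'
#' Draws mixing ratios from a continuous uniform distribution on `range`
#' (default the full `[0, 1]` interval). Uses R's global RNG stream, so a
#' `set.seed()` call makes the draws reproducible. A degenerate range such
#' as `c(0.3, 0.3)` yields that constant.
#'
#' @param n Number of draws.
#' @param range Length-2 numeric, `0 <= range[1] <= range[2] <= 1`.
#' @return Numeric vector of `n` ratios in `range`.
#' @export
sample_lambda <- function(n = 1L, range = c(0, 1)) {
  if (length(range) != 2L || any(!is.finite(range)) ||
      range[1] > range[2] || range[1] < 0 || range[2] > 1) {
    stop("sample_lambda: 'range' must satisfy 0 <= lo <= hi <= 1")
  }
  if (range[1] == range[2]) return(rep(range[1], n))
  stats::runif(n, range[1], range[2])
}

#' Mix two co-registered modality slices in frequency space
#'
#' The core augmentation: both slices are decomposed, their amplitude
#' spectra are convexly interpolated at ratio `lam`, and the mixture is
#' recomposed with the *source* slice's phase spectrum. Because phase
#' carries the spatial semantics, the source mask remains valid for the
#' mixed image and is carried over unchanged. The reconstructed image is
#' clipped to `[0, 1]` (float round-off can push values marginally outside
#' the valid intensity range).
#'
#' @param src,donor [modality_image()] objects of identical spatial shape
#'   and distinct modality ids (normally two modalities of the same case).
#' @param lam Mixing ratio in `[0, 1]`.
#' @param clip If `FALSE`, skip the final clipping (used by tests that
#'   verify the spectral linearity of the mixture analytically).
#' @return An object of class `mixed_sample`: list with `image`, `lam`,
#'   `source_modality`, `donor_modality`, `mask`, `case_id`.
#' @export
mix_images <- function(src, donor, lam, clip = TRUE) {
  stopifnot(inherits(src, "modality_image"), inherits(donor, "modality_image"))
  if (!identical(dim(src$pixels), dim(donor$pixels))) {
    stop("mix_images: source and donor slices have different shapes")
  }
  if (identical(src$modality_id, donor$modality_id)) {
    stop("mix_images: source and donor must be distinct modalities")
  }
  sp_s <- decompose_image(src$pixels, slice_id = src$modality_id)
  sp_d <- decompose_image(donor$pixels, slice_id = donor$modality_id)
  a_mix <- mix_amplitude(sp_s$amplitude, sp_d$amplitude, lam)
  img <- compose(a_mix, sp_s$phase)
  if (clip) img <- pmin(pmax(img, 0), 1)
  structure(
    list(image = img, lam = lam,
         source_modality = src$modality_id, donor_modality = donor$modality_id,
         mask = src$mask, case_id = src$case_id),
    class = "mixed_sample"
  )
}
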