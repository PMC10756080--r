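# Discrete spectral phasor transform and polar (phase/modulation) maps.
#
# For a spectrum I(lambda) on [lambda_min, lambda_max] the first-harmonic
# spectral phasor is
#   G = int I(l) cos(2*pi*n*(l - lmin)/(lmax - lmin)) dl / int I(l) dl
#   S = int I(l) sin(2*pi*n*(l - lmin)/(lmax - lmin)) dl / int I(l) dl
# Discretely the integrals become rectangle-rule sums over channel centres.
# Every (G, S) of a nonnegative spectrum is a convex combination of points
# on the unit circle, hence lies in the closed unit disc.

new_phasor_field <- function(G, S, total, valid, harmonic, axis, threshold) {
  structure(
    list(
      G = G, S = S, total_intensity = total, valid_mask = valid,
      harmonic = as.integer(harmonic), axis = axis,
      intensity_threshold = threshold
    ),
    class = "phasor_field"
  )
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf(
    "<phasor_field> %d x %d pixels, harmonic %d, %d/%d valid (threshold %g)\n",
    nrow(x$G), ncol(x$G), x$harmonic, sum(x$valid_mask), length(x$valid_mask),
    x$intensity_threshold
  ))
  invisible(x)
}

#' @export
dim.phasor_field <- function(x) dim(x$G)

# Default intensity threshold: 3x the modal total count, read as the modal
# background level of a slide with dark (glass) regions. Stacks without a
# dark background should pass an explicit threshold.
default_intensity_threshold <- function(total) {
  tt <- tabulate(as.integer(round(total)) + 1L)
  3 * (which.max(tt) - 1L)
}

#' Per-pixel spectral phasor transform of a lambda stack
#'
#' Computes, for every pixel, the normalized first-harmonic (or higher)
#' Fourier coefficients of its emission spectrum:
#' `G = sum_k I_k cos(2 pi n x_k) / sum_k I_k` and the sine analogue `S`,
#' with `x_k = (centre_k - lambda_min) / (lambda_max - lambda_min)`.
#' Pixels whose total intensity falls below `intensity_threshold` (or is
#' zero) are marked invalid and excluded from all downstream statistics; an
#' all-zero stack therefore yields an all-invalid field, not an error.
#'
#' Because the transform normalizes by total intensity, two spectra that
#' differ only by a positive scale factor map to the same (G, S); the phasor
#' encodes spectral shape only.
#'
#' @param stack An [hsi_stack()].
#' @param harmonic Fourier harmonic `n >= 1` (default 1).
#' @param intensity_threshold Minimum total counts for a pixel to be valid.
#'   Default `NULL` uses 3x the modal total count of the stack (a background
#'   estimate for slides with dark regions).
#' @return A `"phasor_field"`: matrices `G`, `S`, `total_intensity`, logical
#'   `valid_mask`, plus `harmonic`, `axis` and the threshold used. `G`/`S`
#'   are `NA` at invalid pixels.
#' @examples
#' ax <- spectral_axis(423, 723, 30)
#' I <- array(0, dim = c(2, 2, 30)); I[, , 8] <- 100 # delta at 498 nm
#' pf <- phasor_transform(hsi_stack(I, ax), intensity_threshold = 1)
#' phase_modulation(pf)$phase[1, 1] # 90 degrees
#' @export
phasor_transform <- function(stack, harmonic = 1L, intensity_threshold = NULL) {
  stopifnot(inherits(stack, "hsi_stack"))
  harmonic <- as.integer(harmonic)
  if (is.na(harmonic) || harmonic < 1L) {
    stop("`harmonic` must be a positive integer", call. = FALSE)
  }
  axis <- stack$axis
  d <- dim(stack$intensities)
  x <- (axis$channel_centers - axis$lambda_min) /
    (axis$lambda_max - axis$lambda_min)
  ang <- 2 * pi * harmonic * x

  im <- matrix(stack$intensities, nrow = d[1L] * d[2L], ncol = d[3L])
  total <- rowSums(im)
  if (is.null(intensity_threshold)) {
    intensity_threshold <- default_intensity_threshold(total)
  }
  valid <- total > 0 & total >= intensity_threshold

  G <- S <- rep(NA_real_, length(total))
  if (any(valid)) {
    G[valid] <- (im[valid, , drop = FALSE] %*% cos(ang)) / total[valid]
    S[valid] <- (im[valid, , drop = FALSE] %*% sin(ang)) / total[valid]
  }
  new_phasor_field(
    G = matrix(G, d[1L], d[2L]), S = matrix(S, d[1L], d[2L]),
    total = matrix(total, d[1L], d[2L]), valid = matrix(valid, d[1L], d[2L]),
    harmonic = harmonic, axis = axis, threshold = intensity_threshold
  )
}

#' Spectral phasor of a single spectrum
#'
#' `spectrum_phasor()` applies the discrete transform to one intensity
#' vector sampled at the channel centres of `axis`. `phasor_quadrature()`
#' evaluates the same normalized Fourier integrals by trapezoidal quadrature
#' on an arbitrary (typically dense) wavelength grid, which makes it the
#' continuous reference for the discrete transform and the natural tool for
#' near-delta calibration spectra.
#'
#' @param intensity Nonnegative intensity vector.
#' @param axis A [spectral_axis()]; `length(intensity)` must equal
#'   `axis$n_channels`.
#' @param wavelength Increasing wavelength grid (nm) for the quadrature form.
#' @param lambda_min,lambda_max Window defining the phasor period for the
#'   quadrature form.
#' @param harmonic Fourier harmonic, default 1.
#' @return A list with `G`, `S`, `phase` (degrees in `[0, 360)`),
#'   `modulation` and `total`. Zero-total input yields `NA` coordinates.
#' @examples
#' ax <- spectral_axis(423, 723, 30)
#' sp <- numeric(30); sp[8] <- 1
#' spectrum_phasor(sp, ax)$phase # 90
#' @export
spectrum_phasor <- function(intensity, axis, harmonic = 1L) {
  stopifnot(inherits(axis, "spectral_axis"), is.numeric(intensity))
  if (length(intensity) != axis$n_channels) {
    stop(sprintf(
      "channel mismatch: spectrum has %d values, axis has %d channels",
      length(intensity), axis$n_channels
    ), call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensity must be nonnegative", call. = FALSE)
  x <- (axis$channel_centers - axis$lambda_min) /
    (axis$lambda_max - axis$lambda_min)
  phasor_from_sums(
    num_g = sum(intensity * cos(2 * pi * harmonic * x)),
    num_s = sum(intensity * sin(2 * pi * harmonic * x)),
    total = sum(intensity)
  )
}

#' @rdname spectrum_phasor
#' @export
phasor_quadrature <- function(wavelength, intensity, lambda_min, lambda_max,
                              harmonic = 1L) {
  stopifnot(
    is.numeric(wavelength), is.numeric(intensity),
    length(wavelength) == length(intensity), length(wavelength) >= 2L,
    lambda_max > lambda_min
  )
  if (any(intensity < 0)) stop("intensity must be nonnegative", call. = FALSE)
  if (is.unsorted(wavelength, strictly = TRUE)) {
    stop("`wavelength` must be strictly increasing", call. = FALSE)
  }
  ang <- 2 * pi * harmonic * (wavelength - lambda_min) /
    (lambda_max - lambda_min)
  phasor_from_sums(
    num_g = pracma::trapz(wavelength, intensity * cos(ang)),
    num_s = pracma::trapz(wavelength, intensity * sin(ang)),
    total = pracma::trapz(wavelength, intensity)
  )
}

phasor_from_sums <- function(num_g, num_s, total) {
  if (total <= 0) {
    return(list(
      G = NA_real_, S = NA_real_, phase = NA_real_,
      modulation = NA_real_, total = total
    ))
  }
  G <- num_g / total
  S <- num_s / total
  list(
    G = G, S = S,
    phase = (atan2(S, G) * 180 / pi) %% 360,
    modulation = sqrt(G^2 + S^2),
    total = total
  )
}

#' Phase and modulation maps of a phasor field
#'
#' Converts per-pixel Cartesian phasor coordinates to polar form:
#' `phase = atan2(S, G)` mapped to degrees in `[0, 360)` and
#' `modulation = sqrt(G^2 + S^2)`. Phase tracks the spectral centre of mass
#' (redder emission, larger phase at harmonic 1); modulation tracks spectral
#' width (narrower spectrum, modulation closer to 1; a flat spectrum sits at
#' the origin). Pixels at the origin (`G = S = 0`, e.g. a spectrally flat
#' spectrum) have undefined phase and are flagged invalid rather than
#' silently assigned 0.
#'
#' @param field A `"phasor_field"` from [phasor_transform()].
#' @return A list of class `"phase_modulation_map"` with matrices `phase`
#'   (degrees), `modulation`, and logical `valid` (the field's mask with
#'   undefined-phase pixels removed).
#' @export
phase_modulation <- function(field) {
  stopifnot(inherits(field, "phasor_field"))
  modulation <- sqrt(field$G^2 + field$S^2)
  undefined <- field$valid_mask & !is.na(modulation) & modulation < 1e-12
  valid <- field$valid_mask & !undefined
  phase <- (atan2(field$S, field$G) * 180 / pi) %% 360
  phase[!valid] <- NA_real_
  modulation[!valid] <- NA_real_
  structure(
    list(phase = phase, modulation = modulation, valid = valid),
    class = "phase_modulation_map"
  )
}
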