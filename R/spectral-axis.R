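# Uniform wavelength grid shared by stacks, phasor fields and fingerprints.

#' Define a uniform spectral axis
#'
#' A spectral axis describes the wavelength grid of a lambda stack: a
#' detection window `[lambda_min, lambda_max]` (nm) divided into
#' `n_channels` equal bins. Channel centres follow the mid-bin convention,
#' `centre[k] = lambda_min + (k - 0.5) * delta` with
#' `delta = (lambda_max - lambda_min) / n_channels`. Mid-bin centres make a
#' spectrally flat spectrum map exactly to the phasor origin (the sampled
#' first-harmonic cosine and sine sum to zero by symmetry) and keep the
#' continuous phase/wavelength calibration consistent with the discrete
#' transform.
#'
#' @param lambda_min,lambda_max Window edges in nm, `lambda_max > lambda_min`.
#' @param n_channels Number of spectral channels (positive integer).
#' @return An object of class `"spectral_axis"` with fields `lambda_min`,
#'   `lambda_max`, `n_channels`, `channel_width` and `channel_centers`.
#' @examples
#' ax <- spectral_axis(423, 723, 30)
#' channel_centers(ax)[c(1, 8, 30)] # 428, 498, 718 nm
#' @export
spectral_axis <- function(lambda_min, lambda_max, n_channels) {
  stopifnot(
    is.numeric(lambda_min), is.numeric(lambda_max), length(lambda_min) == 1L,
    length(lambda_max) == 1L, is.finite(lambda_min), is.finite(lambda_max)
  )
  if (lambda_max <= lambda_min) {
    stop("`lambda_max` must be greater than `lambda_min`", call. = FALSE)
  }
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1L) {
    stop("`n_channels` must be a positive integer", call. = FALSE)
  }
  delta <- (lambda_max - lambda_min) / n_channels
  structure(
    list(
      lambda_min = as.numeric(lambda_min),
      lambda_max = as.numeric(lambda_max),
      n_channels = n_channels,
      channel_width = delta,
      channel_centers = lambda_min + (seq_len(n_channels) - 0.5) * delta
    ),
    class = "spectral_axis"
  )
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf(
    "<spectral_axis> %g-%g nm, %d channels of %g nm (centres %g..%g nm)\n",
    x$lambda_min, x$lambda_max, x$n_channels, x$channel_width,
    x$channel_centers[1L], x$channel_centers[x$n_channels]
  ))
  invisible(x)
}

#' Channel centre wavelengths of a spectral axis
#'
#' @param axis A [spectral_axis()].
#' @return Numeric vector of channel-centre wavelengths in nm.
#' @export
channel_centers <- function(axis) {
  stopifnot(inherits(axis, "spectral_axis"))
  axis$channel_centers
}

assert_same_axis <- function(a, b) {
  ok <- inherits(a, "spectral_axis") && inherits(b, "spectral_axis") &&
    isTRUE(all.equal(a$lambda_min, b$lambda_min)) &&
    isTRUE(all.equal(a$lambda_max, b$lambda_max)) &&
    a$n_channels == b$n_channels
  if (!ok) stop("spectral axes differ", call. = FALSE)
  invisible(TRUE)
}

#' Convert between phasor phase and wavelength
#'
#' At the first harmonic the phasor phase of a monochromatic (near-delta)
#' emission is proportional to its position in the spectral window:
#' `lambda = lambda_min + (lambda_max - lambda_min) * phase / 360`. This is
#' the calibration used to annotate phasor plots with wavelengths (on the
#' 423-723 nm axis, 90 degrees corresponds to 498 nm and 180 degrees to
#' 573 nm). The mapping is one-to-one only at harmonic 1; higher harmonics
#' wrap several times around the circle and are rejected.
#'
#' @param phase Phase angle(s) in degrees; values outside `[0, 360)` are
#'   wrapped with a warning.
#' @param wavelength Wavelength(s) in nm inside `[lambda_min, lambda_max]`.
#' @param axis A [spectral_axis()].
#' @param harmonic Transform harmonic; must be 1.
#' @return `phase_to_wavelength()` returns wavelengths in nm;
#'   `wavelength_to_phase()` returns phases in degrees in `[0, 360)`.
#' @examples
#' ax <- spectral_axis(423, 723, 30)
#' phase_to_wavelength(90, ax)   # 498
#' wavelength_to_phase(573, ax)  # 180
#' @export
phase_to_wavelength <- function(phase, axis, harmonic = 1L) {
  stopifnot(inherits(axis, "spectral_axis"), is.numeric(phase))
  if (harmonic != 1L) {
    stop("phase/wavelength calibration is one-to-one only at harmonic 1",
      call. = FALSE
    )
  }
  if (any(phase < 0 | phase >= 360, na.rm = TRUE)) {
    warning("phase outside [0, 360) wrapped modulo 360", call. = FALSE)
    phase <- phase %% 360
  }
  axis$lambda_min + (axis$lambda_max - axis$lambda_min) * phase / 360
}

#' @rdname phase_to_wavelength
#' @export
wavelength_to_phase <- function(wavelength, axis, harmonic = 1L) {
  stopifnot(inherits(axis, "spectral_axis"), is.numeric(wavelength))
  if (harmonic != 1L) {
    stop("phase/wavelength calibration is one-to-one only at harmonic 1",
      call. = FALSE
    )
  }
  if (any(wavelength < axis$lambda_min | wavelength > axis$lambda_max,
    na.rm = TRUE
  )) {
    stop("wavelength outside the spectral axis window", call. = FALSE)
  }
  360 * (wavelength - axis$lambda_min) / (axis$lambda_max - axis$lambda_min)
}
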