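# Independent oracles and small fixtures used across the suite.

# Dense-grid Riemann-sum reference for the normalized phasor integrals,
# deliberately written with plain sums (independent of the package's
# transform and quadrature code paths).
oracle_phasor <- function(f, lambda_min, lambda_max, n = 10000L) {
  wl <- seq(lambda_min, lambda_max, length.out = n)
  intens <- f(wl)
  ang <- 2 * pi * (wl - lambda_min) / (lambda_max - lambda_min)
  G <- sum(intens * cos(ang)) / sum(intens)
  S <- sum(intens * sin(ang)) / sum(intens)
  list(
    G = G, S = S,
    phase = (atan2(S, G) * 180 / pi) %% 360,
    modulation = sqrt(G^2 + S^2)
  )
}

gaussian_emission <- function(peak, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  function(wl) exp(-(wl - peak)^2 / (2 * sigma^2))
}

paper_axis <- function() spectral_axis(423, 723, 30)

# Stack in which every pixel carries the same spectrum.
uniform_stack <- function(spectrum, nrow = 4L, ncol = 4L,
                          axis = paper_axis()) {
  arr <- array(rep(spectrum, each = nrow * ncol),
    dim = c(nrow, ncol, length(spectrum))
  )
  hsi_stack(arr, axis)
}

# Two-material phantom on a custom pair of narrow emitters placed at the
# given calibration phases; left half material A, right half material B.
two_material_phantom <- function(phase_a = 60, phase_b = 120, fwhm = 30,
                                 side = 20L, mean_counts = 1000,
                                 noise = FALSE, seed = 1L,
                                 axis = paper_axis()) {
  comps <- list(
    mat_a = component_spec("mat_a", phase_to_wavelength(phase_a, axis), fwhm),
    mat_b = component_spec("mat_b", phase_to_wavelength(phase_b, axis), fwhm)
  )
  layout <- matrix("left", side, side)
  layout[, (side %/% 2 + 1L):side] <- "right"
  cfg <- phantom_config(
    width = side, height = side,
    regions = list(
      left = list(weights = c(mat_a = 1), brightness = 1),
      right = list(weights = c(mat_b = 1), brightness = 1)
    ),
    layout = layout, components = comps, axis = axis,
    mean_counts = mean_counts, bit_depth = 16L, noise = noise, seed = seed
  )
  make_tissue_phantom(cfg)
}

# Phasor field built directly from explicit G/S matrices (bypasses the
# transform; for polar-conversion and group-statistics fixtures).
field_from_gs <- function(G, S, axis = paper_axis()) {
  specphasor:::new_phasor_field(
    G = G, S = S, total = matrix(1000, nrow(G), ncol(G)),
    valid = !is.na(G), harmonic = 1L, axis = axis, threshold = 0
  )
}
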