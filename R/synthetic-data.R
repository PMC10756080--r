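# Synthetic tissue phantoms: seeded lambda stacks built as Poisson-noised
# linear mixtures of endogenous-fluorophore emission spectra arranged in
# tissue-like regions, with ground truth carried alongside so every pipeline
# stage can be tested without external data.

#' Describe a fluorophore emission spectrum
#'
#' Components are modelled as (optionally skewed) Gaussian emission bands:
#' `peak` is the emission maximum in nm, `fwhm` the full width at half
#' maximum in nm, and `skew` a skew-normal shape parameter (0 = symmetric,
#' positive = red-tailed, as most tissue fluorophores are). `brightness` is
#' a relative emitted-intensity scale used when components are mixed.
#'
#' @param name Component name.
#' @param peak Emission peak, nm.
#' @param fwhm Full width at half maximum, nm (> 0).
#' @param skew Skew-normal shape parameter (default 0).
#' @param brightness Relative brightness (default 1).
#' @return An object of class `"component_spec"`.
#' @export
component_spec <- function(name, peak, fwhm, skew = 0, brightness = 1) {
  stopifnot(is.character(name), length(name) == 1L, is.numeric(peak),
            is.numeric(fwhm), is.numeric(skew), is.numeric(brightness))
  if (fwhm <= 0) stop("`fwhm` must be positive", call. = FALSE)
  if (brightness < 0) stop("`brightness` must be nonnegative", call. = FALSE)
  structure(
    list(name = name, peak = peak, fwhm = fwhm, skew = skew,
         brightness = brightness),
    class = "component_spec"
  )
}

#' Default endogenous-fluorophore component library
#'
#' Literature-plausible stand-in emission bands for the autofluorophores
#' relevant to label-free skin imaging under 405 nm excitation: the four
#' collagen types and elastin in the blue-green, NADH blue, FAD green, and
#' a broad red-shifted melanin band. Peak positions preserve the expected
#' blue (structural proteins, NADH) to red (FAD, melanin) ordering; they
#' are configuration entries, not measured reference spectra.
#'
#' @return Named list of [component_spec()] objects: collagen_I..IV,
#'   elastin, NADH, FAD, melanin.
#' @export
default_components <- function() {
  specs <- list(
    component_spec("collagen_I", peak = 445, fwhm = 70, skew = 2),
    component_spec("collagen_II", peak = 450, fwhm = 72, skew = 2),
    component_spec("collagen_III", peak = 460, fwhm = 75, skew = 2),
    component_spec("collagen_IV", peak = 470, fwhm = 78, skew = 2),
    component_spec("elastin", peak = 490, fwhm = 85, skew = 2),
    component_spec("NADH", peak = 462, fwhm = 70, skew = 1),
    component_spec("FAD", peak = 532, fwhm = 80, skew = 2),
    component_spec("melanin", peak = 600, fwhm = 130, skew = 1)
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1L), "name"))
}

#' Sample a component spectrum on a spectral axis
#'
#' Evaluates the component's (skew-)Gaussian emission density at the
#' channel centres and scales by channel width and brightness, so a band
#' fully inside the window integrates (sums) to `brightness` and a band
#' outside the window yields a near-zero vector.
#'
#' @param spec A [component_spec()].
#' @param axis A [spectral_axis()].
#' @return Nonnegative intensity vector of length `axis$n_channels`.
#' @export
make_spectrum <- function(spec, axis) {
  stopifnot(inherits(spec, "component_spec"), inherits(axis, "spectral_axis"))
  sigma <- spec$fwhm / (2 * sqrt(2 * log(2)))
  z <- (axis$channel_centers - spec$peak) / sigma
  dens <- stats::dnorm(z) / sigma
  if (spec$skew != 0) {
    dens <- 2 * dens * stats::pnorm(spec$skew * z)
  }
  spec$brightness * axis$channel_width * dens
}

default_region_profiles <- function() {
  list(
    background = list(
      weights = c(elastin = 1), brightness = 0.01
    ),
    epidermis = list(
      weights = c(NADH = 0.4, FAD = 0.2, melanin = 0.2, elastin = 0.2),
      brightness = 1
    ),
    dermis = list(
      weights = c(collagen_I = 0.35, collagen_III = 0.25,
                  collagen_IV = 0.10, elastin = 0.30),
      brightness = 1
    ),
    lesion = list(
      weights = c(NADH = 0.35, elastin = 0.25, collagen_I = 0.20,
                  collagen_III = 0.10, FAD = 0.05, melanin = 0.05),
      brightness = 1
    )
  )
}

#' Default nevus-like and melanoma-like lesion mixtures
#'
#' Lesion-nest composition profiles used by [make_cohort()]: the
#' nevus-like profile is dominated by NADH, elastin and collagen (bluer
#' emission), the melanoma-like profile by FAD and melanin (redder
#' emission). Values are intensity weights over [default_components()] and
#' sum to 1.
#'
#' @return Named list with elements `nevus` and `melanoma`.
#' @export
default_lesion_profiles <- function() {
  list(
    nevus = c(NADH = 0.35, elastin = 0.25, collagen_I = 0.20,
              collagen_III = 0.10, FAD = 0.05, melanin = 0.05),
    melanoma = c(FAD = 0.40, melanin = 0.40, NADH = 0.10,
                 elastin = 0.05, collagen_I = 0.05)
  )
}

# Default tissue-like layout: dark border frame (glass background), an
# epidermis band along the top, one melanocytic nest disc in the dermis.
default_layout <- function(height, width) {
  lab <- matrix("dermis", height, width)
  fr <- max(2L, round(0.05 * min(height, width)))
  lab[c(seq_len(fr), height - seq_len(fr) + 1L), ] <- "background"
  lab[, c(seq_len(fr), width - seq_len(fr) + 1L)] <- "background"
  epi <- (fr + 1L):max(fr + 1L, round(0.18 * height))
  lab[epi, (fr + 1L):(width - fr)] <- "epidermis"
  cy <- round(0.60 * height); cx <- round(0.50 * width)
  r <- 0.18 * min(height, width)
  ix <- which(
    (row(lab) - cy)^2 + (col(lab) - cx)^2 <= r^2
  )
  lab[ix] <- "lesion"
  lab
}

#' Configure a synthetic tissue phantom
#'
#' Collects the geometry, per-region composition, photon budget and seed
#' that fully determine one phantom. Regions are given as a named list of
#' `list(weights = <named weights over components, summing to 1>,
#' brightness = <relative mean-count multiplier>)`; the layout is a
#' character matrix of region names (default: a dark background frame, an
#' epidermis band, a dermis, and one lesion-nest disc).
#'
#' @param width,height Image size in pixels (default 96 x 96).
#' @param regions Named list of region profiles; default
#'   `default_region_profiles()`.
#' @param layout Character matrix of region names matching `height` x
#'   `width`; default tissue-like layout.
#' @param components Named list of [component_spec()]s the weights refer
#'   to.
#' @param axis [spectral_axis()] of the acquisition (default 423-723 nm,
#'   30 channels).
#' @param mean_counts Mean total photon count per pixel in a
#'   brightness-1 region (default 1000).
#' @param bit_depth Quantization depth (default 8; values clip at
#'   `2^bit_depth - 1`).
#' @param noise Apply Poisson noise (default `TRUE`).
#' @param tile_grid `NULL` for a single stack, or `c(rows, cols)` to also
#'   emit overlapping tiles.
#' @param tile_size Tile size in pixels (required with `tile_grid`; the
#'   full image size is then derived from grid, tile size and overlap).
#' @param overlap Tile overlap fraction (default 0.05).
#' @param seed RNG seed; the seed fully determines the phantom.
#' @return An object of class `"phantom_config"`.
#' @export
phantom_config <- function(width = 96L, height = 96L,
                           regions = default_region_profiles(),
                           layout = NULL,
                           components = default_components(),
                           axis = spectral_axis(423, 723, 30),
                           mean_counts = 1000, bit_depth = 8L,
                           noise = TRUE, tile_grid = NULL,
                           tile_size = NULL, overlap = 0.05, seed = 1L) {
  if (!is.null(tile_grid)) {
    if (is.null(tile_size)) {
      stop("`tile_size` is required when `tile_grid` is given", call. = FALSE)
    }
    ov <- round(overlap * tile_size)
    height <- tile_size * tile_grid[1L] - ov * (tile_grid[1L] - 1L)
    width <- tile_size * tile_grid[2L] - ov * (tile_grid[2L] - 1L)
  }
  if (is.null(layout)) layout <- default_layout(height, width)
  stopifnot(is.matrix(layout), nrow(layout) == height, ncol(layout) == width)
  used <- unique(as.vector(layout))
  missing_regions <- setdiff(used, names(regions))
  if (length(missing_regions) > 0L) {
    stop(sprintf(
      "layout uses regions with no profile: %s",
      paste(missing_regions, collapse = ", ")
    ), call. = FALSE)
  }
  for (rn in used) {
    w <- regions[[rn]]$weights
    if (is.null(names(w)) || !all(names(w) %in% names(components))) {
      stop(sprintf("region '%s': weights must name known components", rn),
        call. = FALSE
      )
    }
    if (abs(sum(w) - 1) > 1e-8) {
      stop(sprintf("region '%s': mixture weights must sum to 1", rn),
        call. = FALSE
      )
    }
  }
  structure(
    list(
      width = as.integer(width), height = as.integer(height),
      regions = regions, layout = layout, components = components,
      axis = axis, mean_counts = mean_counts,
      bit_depth = as.integer(bit_depth), noise = isTRUE(noise),
      tile_grid = tile_grid, tile_size = tile_size, overlap = overlap,
      seed = as.integer(seed)
    ),
    class = "phantom_config"
  )
}

# Expected (noiseless, unquantized) spectrum of one region: the weighted
# component mixture rescaled so its total equals mean_counts * brightness.
region_expected_spectrum <- function(config, region_name) {
  prof <- config$regions[[region_name]]
  mix <- numeric(config$axis$n_channels)
  for (cn in names(prof$weights)) {
    sp <- make_spectrum(config$components[[cn]], config$axis)
    tot <- sum(sp)
    if (tot > 0) mix <- mix + prof$weights[[cn]] * sp / tot
  }
  mix * config$mean_counts * prof$brightness
}

#' Generate a synthetic tissue phantom
#'
#' Builds the lambda stack whose pixels are Poisson realizations of
#' region-wise expected spectra (component mixtures scaled to the photon
#' budget), quantized by clipping at `2^bit_depth - 1`. Ground truth is
#' returned alongside: the region label image, the noiseless expected
#' stack, and each region's exact phasor coordinates (from the expected
#' spectrum). The same seed always yields a bit-identical stack.
#'
#' @param config A [phantom_config()].
#' @return A list of class `"tissue_phantom"`: `stack` ([hsi_stack()]),
#'   `labels` (character matrix), `truth` (data frame: region, G, S,
#'   phase, modulation, expected_counts), `expected` (noiseless
#'   [hsi_stack()]), `config`, and — when `config$tile_grid` is set —
#'   `tiles` (a [tile_set()] carved from the noisy stack).
#' @export
make_tissue_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  used <- unique(as.vector(config$layout))
  nch <- config$axis$n_channels
  expected <- array(0, dim = c(config$height, config$width, nch))
  truth <- list()
  flat_labels <- as.vector(config$layout)
  for (rn in used) {
    sp <- region_expected_spectrum(config, rn)
    ix <- which(flat_labels == rn)
    for (k in seq_len(nch)) {
      plane <- expected[, , k]
      plane[ix] <- sp[k]
      expected[, , k] <- plane
    }
    ph <- spectrum_phasor(sp, config$axis)
    truth[[rn]] <- data.frame(
      region = rn, G = ph$G, S = ph$S, phase = ph$phase,
      modulation = ph$modulation, expected_counts = sum(sp),
      stringsAsFactors = FALSE
    )
  }
  noisy <- if (config$noise) {
    array(stats::rpois(length(expected), expected), dim = dim(expected))
  } else {
    round(expected)
  }
  maxval <- 2^config$bit_depth - 1
  noisy[noisy > maxval] <- maxval
  out <- list(
    stack = hsi_stack(noisy, config$axis, bit_depth = config$bit_depth),
    labels = config$layout,
    truth = do.call(rbind, c(unname(truth), list(make.row.names = FALSE))),
    expected = hsi_stack(expected, config$axis,
      bit_depth = config$bit_depth
    ),
    config = config
  )
  if (!is.null(config$tile_grid)) {
    out$tiles <- carve_tiles(out$stack, config$tile_grid, config$tile_size,
      config$overlap
    )
  }
  structure(out, class = "tissue_phantom")
}

# Cut a stack into an overlapping tile grid (inverse of stitch_tiles up to
# the averaging at seams, which is exact here because shared pixels are
# copied, not re-acquired).
carve_tiles <- function(stack, grid, tile_size, overlap) {
  ov <- round(overlap * tile_size)
  step <- tile_size - ov
  tiles <- list()
  pos <- NULL
  for (r in seq_len(grid[1L])) {
    for (cc in seq_len(grid[2L])) {
      rows <- (r - 1L) * step + seq_len(tile_size)
      cols <- (cc - 1L) * step + seq_len(tile_size)
      tiles[[length(tiles) + 1L]] <- hsi_stack(
        stack$intensities[rows, cols, , drop = FALSE],
        stack$axis, bit_depth = stack$bit_depth
      )
      pos <- rbind(pos, c(r, cc))
    }
  }
  tile_set(tiles, pos, overlap_fraction = overlap)
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf(
    "<tissue_phantom> %d x %d px, regions: %s; seed %d\n",
    x$config$height, x$config$width,
    paste(unique(as.vector(x$labels)), collapse = ", "), x$config$seed
  ))
  invisible(x)
}

# Multiplicative lognormal jitter on mixture weights, renormalized: keeps
# weights positive and models between-sample compositional variability.
jitter_weights <- function(weights, sd) {
  w <- weights * exp(stats::rnorm(length(weights), 0, sd))
  w / sum(w)
}

#' Generate a synthetic two-group cohort
#'
#' Emulates a benign-versus-malignant cohort: each sample is a small
#' tissue phantom whose lesion-nest mixture is the group profile with
#' multiplicative lognormal weight jitter (between-sample variability),
#' surrounded by a common dermis and a dark background frame. The
#' ground-truth per-sample phase/modulation centres of mass (phasor of the
#' noiseless lesion spectrum) are recorded so downstream group comparison
#' can be checked as a parameter-recovery problem.
#'
#' @param n_nevus,n_melanoma Samples per group (each >= 2; the group
#'   t-test needs at least 2).
#' @param nevus_profile,melanoma_profile Named lesion mixture weights over
#'   `components`, summing to 1; defaults [default_lesion_profiles()].
#' @param jitter_sd Lognormal sigma of the between-sample weight jitter
#'   (default 0.05; 0 gives identical lesions up to photon noise).
#' @param size Phantom side length in pixels (default 48).
#' @param mean_counts Mean photon count per pixel (default 1000).
#' @param bit_depth Quantization depth (default 16 so the photon budget is
#'   not clipped).
#' @param components Component library (default [default_components()]).
#' @param axis [spectral_axis()] (default 423-723 nm, 30 channels).
#' @param seed RNG seed; fully determines the cohort.
#' @return A list of class `"synthetic_cohort"` of samples; each sample is
#'   a list with `id`, `label`, `stack`, `mask` (lesion ROI), `truth_phase`
#'   and `truth_modulation`.
#' @export
make_cohort <- function(n_nevus = 5L, n_melanoma = 5L,
                        nevus_profile = default_lesion_profiles()$nevus,
                        melanoma_profile = default_lesion_profiles()$melanoma,
                        jitter_sd = 0.05, size = 48L, mean_counts = 1000,
                        bit_depth = 16L,
                        components = default_components(),
                        axis = spectral_axis(423, 723, 30), seed = 1L) {
  if (n_nevus < 2L || n_melanoma < 2L) {
    stop("need at least 2 samples per group for the group t-test",
      call. = FALSE
    )
  }
  set.seed(seed)
  labels <- c(rep("nevus", n_nevus), rep("melanoma", n_melanoma))
  profiles <- list(nevus = nevus_profile, melanoma = melanoma_profile)
  for (p in profiles) {
    if (abs(sum(p) - 1) > 1e-8) {
      stop("lesion profiles must sum to 1", call. = FALSE)
    }
  }
  samples <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    lb <- labels[i]
    w <- jitter_weights(profiles[[lb]], jitter_sd)
    regions <- default_region_profiles()
    regions$lesion$weights <- w
    cfg <- phantom_config(
      width = size, height = size, regions = regions,
      components = components, axis = axis, mean_counts = mean_counts,
      bit_depth = bit_depth, noise = TRUE,
      seed = sample.int(.Machine$integer.max, 1L)
    )
    ph <- make_tissue_phantom(cfg)
    tr <- ph$truth[ph$truth$region == "lesion", ]
    samples[[i]] <- list(
      id = sprintf("%s_%02d", lb, sum(labels[seq_len(i)] == lb)),
      label = lb, stack = ph$stack, mask = ph$labels == "lesion",
      truth_phase = tr$phase, truth_modulation = tr$modulation
    )
  }
  structure(samples, class = "synthetic_cohort")
}

#' Transform a synthetic cohort into comparison-ready samples
#'
#' Convenience bridge from [make_cohort()] to [cohort_compare()]: applies
#' the phasor transform (and optionally phasor-space median filtering) to
#' every sample's stack and pairs the resulting field with its lesion
#' mask.
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param harmonic Transform harmonic (default 1).
#' @param intensity_threshold Validity threshold in counts; the default
#'   (a quarter of the nominal photon budget is a sensible choice for
#'   these phantoms) is `NULL`, i.e. the transform's modal-background
#'   default.
#' @param filter_kernel,filter_repeats Median-filter settings;
#'   `filter_repeats = 0` (default) skips filtering.
#' @return List of samples suitable for [cohort_compare()].
#' @export
cohort_fields <- function(cohort, harmonic = 1L, intensity_threshold = NULL,
                          filter_kernel = 3L, filter_repeats = 0L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  lapply(cohort, function(s) {
    f <- phasor_transform(s$stack, harmonic = harmonic,
      intensity_threshold = intensity_threshold
    )
    if (filter_repeats > 0L) {
      f <- median_filter_phasor(f, kernel = filter_kernel,
        repeats = filter_repeats
      )
    }
    list(id = s$id, label = s$label, field = f, mask = s$mask)
  })
}
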