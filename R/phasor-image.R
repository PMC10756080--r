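# Phasor-space tools: denoising, 2-D histograms, pseudocolor phase maps,
# cursors and the reciprocity between phasor space and image space.

#' Median-filter a phasor field
#'
#' Applies an invalid-pixel-aware median filter to the G and S planes
#' independently; total intensity and the valid mask are unchanged. Median
#' filtering in phasor space tightens the phasor cluster of a homogeneous
#' material without mixing spectra the way spatial smoothing of the raw
#' stack would: a constant region is left exactly in place.
#'
#' @param field A `"phasor_field"`.
#' @param kernel Odd window size `>= 3` (default 3).
#' @param repeats Number of filter passes (default 1); 0 returns the field
#'   unchanged.
#' @return The filtered `"phasor_field"`.
#' @export
median_filter_phasor <- function(field, kernel = 3L, repeats = 1L) {
  stopifnot(inherits(field, "phasor_field"))
  kernel <- as.integer(kernel)
  if (is.na(kernel) || kernel < 3L || kernel %% 2L == 0L) {
    stop("`kernel` must be an odd integer >= 3", call. = FALSE)
  }
  repeats <- as.integer(repeats)
  for (i in seq_len(repeats)) {
    field$G <- neighborhood_median(field$G, field$valid_mask, kernel)
    field$S <- neighborhood_median(field$S, field$valid_mask, kernel)
  }
  field
}

# Median over the kernel x kernel neighbourhood, ignoring invalid (NA)
# neighbours; edges use the available part of the window.
neighborhood_median <- function(m, valid, kernel) {
  h <- nrow(m); w <- ncol(m)
  r <- (kernel - 1L) %/% 2L
  m[!valid] <- NA_real_
  pad <- matrix(NA_real_, h + 2L * r, w + 2L * r)
  pad[r + seq_len(h), r + seq_len(w)] <- m
  shifts <- matrix(NA_real_, h * w, kernel^2)
  k <- 0L
  for (dc in -r:r) {
    for (dr in -r:r) {
      k <- k + 1L
      shifts[, k] <- pad[r + dr + seq_len(h), r + dc + seq_len(w)]
    }
  }
  out <- matrix(apply(shifts, 1L, stats::median, na.rm = TRUE), h, w)
  out[!valid] <- NA_real_
  out[is.nan(out)] <- NA_real_
  out
}

#' 2-D phasor histogram
#'
#' Counts valid pixels on a square bin grid over the phasor unit square
#' `[-1, 1] x [-1, 1]`. The total count equals the number of valid pixels;
#' any log scaling for display is presentation only.
#'
#' @param field A `"phasor_field"`.
#' @param bins Bins per axis (default 128).
#' @return An object of class `"phasor_histogram"` with `counts`
#'   (`bins x bins`, G along rows, S along columns), `breaks` and `mids`.
#' @export
phasor_histogram <- function(field, bins = 128L) {
  stopifnot(inherits(field, "phasor_field"))
  bins <- as.integer(bins)
  stopifnot(bins >= 1L)
  breaks <- seq(-1, 1, length.out = bins + 1L)
  g <- field$G[field$valid_mask]
  s <- field$S[field$valid_mask]
  counts <- matrix(0L, bins, bins)
  if (length(g) > 0L) {
    gi <- findInterval(g, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    si <- findInterval(s, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- matrix(
      tabulate(gi + bins * (si - 1L), nbins = bins^2), bins, bins
    )
  }
  structure(
    list(counts = counts, breaks = breaks,
         mids = (breaks[-1L] + breaks[-(bins + 1L)]) / 2, bins = bins),
    class = "phasor_histogram"
  )
}

#' @export
print.phasor_histogram <- function(x, ...) {
  cat(sprintf(
    "<phasor_histogram> %d x %d bins over [-1,1]^2, %d pixels\n",
    x$bins, x$bins, sum(x$counts)
  ))
  invisible(x)
}

#' Plot a phasor histogram
#'
#' Log1p-scaled density image of the (G, S) plane with the unit circle
#' drawn; optionally overlays fingerprint markers via
#' [overlay_fingerprints()].
#'
#' @param x A `"phasor_histogram"`.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.phasor_histogram <- function(x, main = "Spectral phasor", ...) {
  cols <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(
    x = x$mids, y = x$mids, z = log1p(x$counts),
    col = cols, xlab = "G", ylab = "S", main = main, asp = 1,
    xlim = c(-1, 1), ylim = c(-1, 1), useRaster = TRUE, ...
  )
  th <- seq(0, 2 * pi, length.out = 361)
  graphics::lines(cos(th), sin(th), col = "grey40")
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Pseudocolor phase map
#'
#' Renders each valid pixel with a hue that maps its phasor phase linearly
#' from `phase_range[1]` (red) to `phase_range[2]` (violet); phases outside
#' the range are clamped to the endpoint colors and invalid pixels are
#' black. At harmonic 1 the phase encodes the spectral centre of mass, so
#' the map is a false-color "spectral position" image of the tissue.
#'
#' @param field A `"phasor_field"`.
#' @param phase_range Length-2 numeric, degrees within `[0, 360)`,
#'   `lo < hi`; default `c(45, 180)`.
#' @param value Brightness in `[0, 1]` for valid pixels, or `"intensity"`
#'   to modulate brightness by total intensity.
#' @return An `rows x cols x 3` RGB array in `[0, 1]`.
#' @export
pseudocolor_phase <- function(field, phase_range = c(45, 180), value = 1) {
  stopifnot(inherits(field, "phasor_field"), length(phase_range) == 2L)
  lo <- phase_range[1L]; hi <- phase_range[2L]
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop("`phase_range` must satisfy lo < hi", call. = FALSE)
  }
  pm <- phase_modulation(field)
  h <- nrow(pm$phase); w <- ncol(pm$phase)
  frac <- (pm$phase - lo) / (hi - lo)
  frac[frac < 0] <- 0
  frac[frac > 1] <- 1
  hue <- 0.75 * frac # HSV hue 0 = red ... 0.75 = violet
  if (identical(value, "intensity")) {
    v <- field$total_intensity / max(field$total_intensity, 1)
  } else {
    v <- matrix(value, h, w)
  }
  rgb <- array(0, dim = c(h, w, 3L))
  ok <- pm$valid
  if (any(ok)) {
    cols <- grDevices::col2rgb(grDevices::hsv(hue[ok], 1, v[ok])) / 255
    for (ch in 1:3) {
      plane <- matrix(0, h, w)
      plane[ok] <- cols[ch, ]
      rgb[, , ch] <- plane
    }
  }
  rgb
}

#' Write an RGB array as PNG
#'
#' @param rgb `rows x cols x 3` array in `[0, 1]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}

#' Phasor-space cursors
#'
#' Cursors are scriptable geometric selectors in the (G, S) plane used to
#' segment the image through the reciprocity principle: pixels whose phasor
#' falls inside the cursor are highlighted back in image space. Three
#' shapes are supported: a circle, a polygon, and a phase/modulation wedge
#' (an annular sector in polar phasor coordinates). Cursor membership is
#' boundary-inclusive.
#'
#' @param g,s Circle centre or polygon vertex coordinates.
#' @param radius Circle radius (> 0).
#' @param phase_lo,phase_hi Wedge phase bounds in degrees,
#'   `0 <= phase_lo < phase_hi < 360`.
#' @param mod_lo,mod_hi Wedge modulation bounds, `0 <= mod_lo < mod_hi`.
#' @return An object of class `"phasor_cursor"`.
#' @examples
#' cursor_circle(0.2, 0.5, 0.1)
#' cursor_wedge(90, 180)
#' @export
cursor_circle <- function(g, s, radius) {
  stopifnot(is.numeric(g), is.numeric(s), length(g) == 1L, length(s) == 1L)
  if (!is.numeric(radius) || radius <= 0) {
    stop("`radius` must be positive", call. = FALSE)
  }
  structure(
    list(shape = "circle", g = g, s = s, radius = radius),
    class = "phasor_cursor"
  )
}

#' @rdname cursor_circle
#' @export
cursor_polygon <- function(g, s) {
  stopifnot(is.numeric(g), is.numeric(s), length(g) == length(s))
  if (length(g) < 3L) {
    stop("a polygon cursor needs at least 3 vertices", call. = FALSE)
  }
  structure(
    list(shape = "polygon", g = g, s = s),
    class = "phasor_cursor"
  )
}

#' @rdname cursor_circle
#' @export
cursor_wedge <- function(phase_lo, phase_hi, mod_lo = 0, mod_hi = 1) {
  if (phase_lo >= phase_hi) {
    stop("`phase_lo` must be smaller than `phase_hi`", call. = FALSE)
  }
  if (phase_lo < 0 || phase_hi >= 360) {
    stop("wedge phases must lie in [0, 360)", call. = FALSE)
  }
  if (mod_lo >= mod_hi || mod_lo < 0) {
    stop("`mod_lo` must be smaller than `mod_hi` and nonnegative",
      call. = FALSE
    )
  }
  structure(
    list(shape = "phase_wedge", phase_lo = phase_lo, phase_hi = phase_hi,
         mod_lo = mod_lo, mod_hi = mod_hi),
    class = "phasor_cursor"
  )
}

#' @export
print.phasor_cursor <- function(x, ...) {
  desc <- switch(x$shape,
    circle = sprintf("circle centre (%.3g, %.3g) radius %.3g",
                     x$g, x$s, x$radius),
    polygon = sprintf("polygon with %d vertices", length(x$g)),
    phase_wedge = sprintf("wedge phase [%g, %g] deg, modulation [%g, %g]",
                          x$phase_lo, x$phase_hi, x$mod_lo, x$mod_hi)
  )
  cat("<phasor_cursor>", desc, "\n")
  invisible(x)
}

#' Select image pixels by a phasor-space cursor
#'
#' Implements the image-space half of the reciprocity principle: the
#' returned mask is `TRUE` exactly at valid pixels whose (G, S) lies inside
#' (or on the boundary of) the cursor.
#'
#' @param field A `"phasor_field"`.
#' @param cursor A [cursor_circle()], [cursor_polygon()] or
#'   [cursor_wedge()].
#' @return Logical matrix of the field's dimensions, with attribute
#'   `provenance = "cursor"`.
#' @export
select_by_cursor <- function(field, cursor) {
  stopifnot(inherits(field, "phasor_field"), inherits(cursor, "phasor_cursor"))
  inside <- switch(cursor$shape,
    circle = {
      (field$G - cursor$g)^2 + (field$S - cursor$s)^2 <= cursor$radius^2
    },
    polygon = {
      m <- matrix(FALSE, nrow(field$G), ncol(field$G))
      ok <- field$valid_mask
      if (any(ok)) {
        m[ok] <- pracma::inpolygon(
          field$G[ok], field$S[ok], cursor$g, cursor$s, boundary = TRUE
        )
      }
      m
    },
    phase_wedge = {
      pm <- phase_modulation(field)
      pm$phase >= cursor$phase_lo & pm$phase <= cursor$phase_hi &
        pm$modulation >= cursor$mod_lo & pm$modulation <= cursor$mod_hi
    }
  )
  inside[is.na(inside)] <- FALSE
  mask <- inside & field$valid_mask
  attr(mask, "provenance") <- "cursor"
  mask
}

#' Restrict a phasor field to a region of interest
#'
#' Implements the phasor-space half of the reciprocity principle: the
#' secondary phasor of an image region. The returned field keeps only
#' pixels that are valid in the input and inside the mask.
#'
#' @param field A `"phasor_field"`.
#' @param mask Logical matrix of the field's dimensions (hand-drawn or from
#'   [select_by_cursor()]).
#' @return A `"phasor_field"` whose valid mask is `valid & mask`.
#' @export
phasor_of_roi <- function(field, mask) {
  stopifnot(inherits(field, "phasor_field"))
  if (!is.logical(mask) || !identical(dim(mask), dim(field$G))) {
    stop("`mask` must be a logical matrix matching the field dimensions",
      call. = FALSE
    )
  }
  keep <- field$valid_mask & mask
  field$valid_mask <- keep
  field$G[!keep] <- NA_real_
  field$S[!keep] <- NA_real_
  field
}
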