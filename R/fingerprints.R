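# Pure-component phasor fingerprints and linear-combination unmixing.
#
# The phasor of a mixture of emitters lies at the intensity-weighted
# barycentre of the pure emitters' phasors, so a two-component mixture sits
# on the segment joining the pure positions and a three-component mixture
# inside their triangle. The recovered fractions are intensity (emitted
# photon) fractions, not molar fractions.

#' Create a component fingerprint
#'
#' A fingerprint is the named phasor position of a pure fluorophore
#' (collagen, elastin, NADH, FAD, melanin, ...) optionally carrying the
#' emission spectrum it was computed from.
#'
#' @param name Component name.
#' @param G,S Phasor coordinates; must lie in the closed unit disc.
#' @param source_spectrum Optional intensity vector on `axis`.
#' @param axis Optional [spectral_axis()] for `source_spectrum`.
#' @return An object of class `"component_fingerprint"`.
#' @export
component_fingerprint <- function(name, G, S, source_spectrum = NULL,
                                  axis = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(G), is.numeric(S))
  if (G^2 + S^2 > 1 + 1e-9) {
    stop("fingerprint centroid must lie inside the unit disc", call. = FALSE)
  }
  structure(
    list(name = name, G = G, S = S,
         source_spectrum = source_spectrum, axis = axis),
    class = "component_fingerprint"
  )
}

#' @export
print.component_fingerprint <- function(x, ...) {
  cat(sprintf("<component_fingerprint> %s at (G = %.4f, S = %.4f)\n",
              x$name, x$G, x$S))
  invisible(x)
}

as_gs <- function(p) {
  if (inherits(p, "component_fingerprint")) c(p$G, p$S)
  else {
    stopifnot(is.numeric(p), length(p) == 2L)
    as.numeric(p)
  }
}

#' Phasor-cluster centroids by k-means
#'
#' Runs k-means over the valid (G, S) pixels of a field and returns the
#' cluster centroids, ordered by increasing phase angle for
#' reproducibility. With `k = 1` this is the arithmetic mean phasor of the
#' cluster (the centroid minimizing the inertia of the whole distribution);
#' larger `k` resolves multi-modal phasor clouds. The random-number state
#' is seeded locally and restored, so calls are reproducible and leave the
#' session RNG untouched.
#'
#' @param field A `"phasor_field"`.
#' @param k Number of centroids; at most the number of valid pixels.
#' @param seed RNG seed for k-means initialization (default 0).
#' @param nstart Random restarts (default 10).
#' @return A `k x 2` matrix with columns `G`, `S`.
#' @export
component_centroid <- function(field, k, seed = 0L, nstart = 10L) {
  stopifnot(inherits(field, "phasor_field"))
  k <- as.integer(k)
  pts <- cbind(field$G[field$valid_mask], field$S[field$valid_mask])
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (nrow(pts) < k) {
    stop(sprintf("k = %d exceeds the %d valid pixels", k, nrow(pts)),
      call. = FALSE
    )
  }
  distinct <- unique(pts)
  if (k == 1L) {
    ctr <- matrix(colMeans(pts), 1L, 2L)
  } else if (nrow(distinct) == k) {
    # exactly k distinct phasors (e.g. a noiseless phantom): they are the
    # optimal centroids, and random k-means starts would stumble over the
    # duplicated rows
    ctr <- distinct
  } else if (nrow(distinct) < k) {
    stop(sprintf("k = %d exceeds the %d distinct phasors", k, nrow(distinct)),
      call. = FALSE
    )
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(
      if (!is.null(old_seed)) {
        assign(".Random.seed", old_seed, envir = globalenv())
      },
      add = TRUE
    )
    set.seed(seed)
    # jitter-free data with duplicated points can make kmeans complain about
    # empty clusters; unique starting rows avoid that for exact clusters
    km <- suppressWarnings(
      stats::kmeans(pts, centers = k, nstart = nstart, iter.max = 100L)
    )
    ctr <- km$centers
  }
  ctr <- ctr[order(atan2(ctr[, 2L], ctr[, 1L]) %% (2 * pi)), , drop = FALSE]
  dimnames(ctr) <- list(NULL, c("G", "S"))
  ctr
}

#' Two-component linear unmixing on the phasor segment
#'
#' Projects a phasor orthogonally onto the segment joining two pure
#' component fingerprints. The position along the segment gives the
#' intensity fraction of component `a`; the perpendicular distance left
#' over is reported as the residual (a measure of how well the two-emitter
#' model explains the pixel). Fractions are clamped to `[0, 1]`.
#'
#' @param p Phasor to unmix: `c(G, S)` or a [component_fingerprint()].
#' @param a,b Pure-component fingerprints (or `c(G, S)` pairs); must be
#'   distinct.
#' @return A list with `fraction_a`, `fraction_b = 1 - fraction_a` and
#'   `residual` (distance from `p` to its projection on the segment).
#' @examples
#' unmix_two(c(0.5, 0.5), c(1, 0), c(0, 1))$fraction_a # 0.5
#' @export
unmix_two <- function(p, a, b) {
  p <- as_gs(p); a <- as_gs(a); b <- as_gs(b)
  ab <- a - b
  len2 <- sum(ab^2)
  if (len2 < 1e-18) {
    stop("degenerate pair: the two fingerprints coincide", call. = FALSE)
  }
  t <- sum((p - b) * ab) / len2
  t <- min(max(t, 0), 1)
  proj <- b + t * ab
  list(
    fraction_a = t,
    fraction_b = 1 - t,
    residual = sqrt(sum((p - proj)^2))
  )
}

#' Three-component barycentric unmixing in the phasor triangle
#'
#' Solves the 2x2 barycentric system for the intensity fractions of three
#' non-collinear pure components. A phasor outside the triangle yields a
#' negative coordinate: the result is flagged (`outside = TRUE`), negative
#' fractions are clamped to zero and the remainder renormalized to sum
#' to 1.
#'
#' @param p Phasor to unmix: `c(G, S)` or a [component_fingerprint()].
#' @param a,b,c Pure-component fingerprints (or `c(G, S)` pairs), not
#'   collinear.
#' @return A list with `fractions` (length 3, sums to 1, order a, b, c) and
#'   logical `outside`.
#' @export
unmix_three <- function(p, a, b, c) {
  p <- as_gs(p); a <- as_gs(a); b <- as_gs(b); c <- as_gs(c)
  M <- cbind(a - c, b - c)
  if (abs(det(M)) < 1e-12) {
    stop("collinear fingerprints: use unmix_two() for a two-component model",
      call. = FALSE
    )
  }
  fab <- solve(M, p - c)
  f <- c(fab, 1 - sum(fab))
  outside <- any(f < -1e-12)
  if (outside) {
    f[f < 0] <- 0
    f <- f / sum(f)
  }
  names(f) <- c("a", "b", "c")
  list(fractions = f, outside = outside)
}

#' Build a fingerprint library from component spectra
#'
#' Transforms each component's emission spectrum (see
#' [default_components()] and [make_spectrum()]) on the given axis and
#' tabulates the resulting pure-component phasor positions. The shipped
#' defaults are synthetic literature-plausible spectra — configurable
#' stand-ins, not measured reference spectra.
#'
#' @param components Named list of [component_spec()] objects.
#' @param axis A [spectral_axis()].
#' @param harmonic Transform harmonic (default 1).
#' @return A data frame with columns `name`, `G`, `S`, `lambda_min`,
#'   `lambda_max`, `n_channels`, `harmonic`.
#' @export
fingerprint_library <- function(components = default_components(),
                                axis = spectral_axis(423, 723, 30),
                                harmonic = 1L) {
  rows <- lapply(components, function(cs) {
    ph <- spectrum_phasor(make_spectrum(cs, axis), axis, harmonic = harmonic)
    data.frame(
      name = cs$name, G = ph$G, S = ph$S,
      lambda_min = axis$lambda_min, lambda_max = axis$lambda_max,
      n_channels = axis$n_channels, harmonic = as.integer(harmonic),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read or write a fingerprint library CSV
#'
#' The CSV carries columns `name, G, S, lambda_min, lambda_max, n_channels,
#' harmonic` so a library is always tied to the axis it was computed on.
#'
#' @param library Data frame as returned by [fingerprint_library()].
#' @param path CSV path.
#' @return `read_fingerprints()` returns the library data frame;
#'   `write_fingerprints()` returns `path` invisibly.
#' @export
write_fingerprints <- function(library, path) {
  utils::write.csv(library, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "G", "S", "lambda_min", "lambda_max", "n_channels",
            "harmonic")
  if (!all(need %in% names(df))) {
    stop(sprintf(
      "fingerprint CSV must have columns: %s", paste(need, collapse = ", ")
    ), call. = FALSE)
  }
  df
}

#' Overlay fingerprint centroids on a phasor histogram
#'
#' Draws the 2-D phasor histogram and marks each library component's
#' centroid with a labeled point, the standard way to read which molecular
#' species a tissue phasor cloud overlaps.
#'
#' @param histogram A [phasor_histogram()].
#' @param library Fingerprint library data frame (may have zero rows for a
#'   bare histogram).
#' @param file Optional PNG path; when given the figure is written there.
#' @param main Plot title.
#' @return The library, invisibly.
#' @export
overlay_fingerprints <- function(histogram, library, file = NULL,
                                 main = "Spectral phasor") {
  stopifnot(inherits(histogram, "phasor_histogram"), is.data.frame(library))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900, res = 150)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  plot(histogram, main = main)
  if (nrow(library) > 0L) {
    graphics::points(library$G, library$S, pch = 21, bg = "white",
                     col = "black", cex = 1.2)
    graphics::text(library$G, library$S, labels = library$name,
                   pos = 3, cex = 0.7)
  }
  invisible(library)
}
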