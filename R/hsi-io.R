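# Lambda-stack TIFF input/output and mosaic stitching of tiled acquisitions.

#' Read and write lambda stacks as multi-page TIFF
#'
#' A lambda stack is stored as one TIFF page per spectral channel, pages
#' ordered by ascending wavelength. `write_stack()` scales counts by
#' `2^bit_depth - 1` as the TIFF container requires; `read_stack()` reads
#' raw integer sample values back, so a quantized stack round-trips
#' bit-identically.
#'
#' @param stack An [hsi_stack()]; values must not exceed
#'   `2^bit_depth - 1` (they are clipped with a warning otherwise).
#' @param path TIFF file path.
#' @param axis The [spectral_axis()] the file is expected to match; a
#'   page-count mismatch is an error naming both counts.
#' @param bit_depth Bit depth used for encoding/decoding (8 or 16).
#' @return `read_stack()` returns an [hsi_stack()]; `write_stack()` returns
#'   `path` invisibly.
#' @export
read_stack <- function(path, axis, bit_depth = 8L) {
  stopifnot(inherits(axis, "spectral_axis"))
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != axis$n_channels) {
    stop(sprintf(
      "channel mismatch: '%s' has %d pages, axis has %d channels",
      path, length(pages), axis$n_channels
    ), call. = FALSE)
  }
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1L)))) {
    stop("each TIFF page must be a single-channel (grayscale) image",
      call. = FALSE
    )
  }
  d <- dim(pages[[1L]])
  arr <- array(0, dim = c(d[1L], d[2L], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  hsi_stack(arr, axis, bit_depth = bit_depth)
}

#' @rdname read_stack
#' @export
write_stack <- function(stack, path, bit_depth = stack$bit_depth) {
  stopifnot(inherits(stack, "hsi_stack"))
  maxval <- 2^bit_depth - 1
  arr <- stack$intensities
  if (any(arr > maxval)) {
    warning(sprintf("intensities above %d clipped on write", maxval),
      call. = FALSE
    )
    arr[arr > maxval] <- maxval
  }
  pages <- lapply(seq_len(dim(arr)[3L]), function(k) {
    round(arr[, , k]) / maxval
  })
  tiff::writeTIFF(pages, path,
    bits.per.sample = as.integer(bit_depth),
    compression = "none"
  )
  invisible(path)
}

#' Assemble a set of overlapping tiles
#'
#' Whole-slide acquisitions are collected as a rectangular grid of tiles
#' with a small fractional overlap (5% in the acquisition geometry this
#' package targets) so that the field borders are sampled in two tiles.
#'
#' @param tiles List of [hsi_stack()] objects sharing one axis and pixel
#'   dimensions.
#' @param grid_positions Integer matrix or two-column data frame of
#'   (row, col) grid positions, one per tile, 1-based.
#' @param overlap_fraction Fraction of the tile extent shared between
#'   neighbours, in `[0, 0.5)`; default 0.05.
#' @return An object of class `"tile_set"`.
#' @export
tile_set <- function(tiles, grid_positions, overlap_fraction = 0.05) {
  stopifnot(is.list(tiles), length(tiles) >= 1L)
  if (!all(vapply(tiles, inherits, logical(1L), "hsi_stack"))) {
    stop("all tiles must be hsi_stack objects", call. = FALSE)
  }
  pos <- as.matrix(grid_positions)
  storage.mode(pos) <- "integer"
  if (nrow(pos) != length(tiles) || ncol(pos) != 2L) {
    stop("`grid_positions` must give one (row, col) pair per tile",
      call. = FALSE
    )
  }
  if (overlap_fraction < 0 || overlap_fraction >= 0.5) {
    stop("`overlap_fraction` must lie in [0, 0.5)", call. = FALSE)
  }
  d1 <- dim(tiles[[1L]]$intensities)
  for (t in tiles[-1L]) {
    assert_same_axis(t$axis, tiles[[1L]]$axis)
    if (!identical(dim(t$intensities), d1)) {
      stop("inconsistent tile shapes", call. = FALSE)
    }
  }
  nr <- max(pos[, 1L]); nc <- max(pos[, 2L])
  want <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  have <- paste(pos[, 1L], pos[, 2L])
  gaps <- setdiff(paste(want$row, want$col), have)
  if (length(gaps) > 0L) {
    stop(sprintf(
      "missing grid positions: %s",
      paste(sprintf("(%s)", sub(" ", ",", gaps)), collapse = " ")
    ), call. = FALSE)
  }
  if (anyDuplicated(have)) stop("duplicated grid positions", call. = FALSE)
  structure(
    list(
      tiles = tiles, grid_positions = pos,
      overlap_fraction = overlap_fraction,
      grid = c(rows = nr, cols = nc)
    ),
    class = "tile_set"
  )
}

#' @export
print.tile_set <- function(x, ...) {
  d <- dim(x$tiles[[1L]]$intensities)
  cat(sprintf(
    "<tile_set> %d x %d grid of %d x %d px tiles, overlap %.1f%%\n",
    x$grid["rows"], x$grid["cols"], d[1L], d[2L], 100 * x$overlap_fraction
  ))
  invisible(x)
}

#' Stitch a tile set into one mosaic stack
#'
#' Tiles are placed on the grid with an overlap of
#' `round(overlap_fraction * tile_extent)` pixels between neighbours;
#' pixels covered by more than one tile are averaged channel-wise. Because
#' the phasor transform normalizes each pixel by its total intensity, the
#' blending rule only matters at seams; a plain mean keeps stitching
#' commutative with the transform away from the overlap strips.
#'
#' @param tileset A [tile_set()].
#' @return An [hsi_stack()] covering the full mosaic,
#'   `tile_extent * grid - overlap strips` in each dimension.
#' @export
stitch_tiles <- function(tileset) {
  stopifnot(inherits(tileset, "tile_set"))
  d <- dim(tileset$tiles[[1L]]$intensities)
  th <- d[1L]; tw <- d[2L]; nch <- d[3L]
  ov_r <- round(tileset$overlap_fraction * th)
  ov_c <- round(tileset$overlap_fraction * tw)
  nr <- unname(tileset$grid["rows"]); nc <- unname(tileset$grid["cols"])
  H <- th * nr - ov_r * (nr - 1L)
  W <- tw * nc - ov_c * (nc - 1L)
  acc <- array(0, dim = c(H, W, nch))
  cnt <- matrix(0, H, W)
  for (i in seq_along(tileset$tiles)) {
    r0 <- (tileset$grid_positions[i, 1L] - 1L) * (th - ov_r)
    c0 <- (tileset$grid_positions[i, 2L] - 1L) * (tw - ov_c)
    rows <- r0 + seq_len(th)
    cols <- c0 + seq_len(tw)
    acc[rows, cols, ] <- acc[rows, cols, ] + tileset$tiles[[i]]$intensities
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  mosaic <- acc / as.vector(cnt) # cnt recycles over channels
  hsi_stack(mosaic, tileset$tiles[[1L]]$axis,
    bit_depth = tileset$tiles[[1L]]$bit_depth
  )
}

#' Serialize a phasor field as TIFF plus JSON sidecar
#'
#' The field is written as a 4-page 32-bit float TIFF — `(G + 1) / 2`,
#' `(S + 1) / 2`, total intensity scaled to its maximum, and the valid mask —
#' with a JSON sidecar recording the axis, harmonic, threshold and the
#' scale factors needed to invert the encoding.
#'
#' @param field A `"phasor_field"`.
#' @param path_prefix Output prefix; writes `<prefix>.tif` and
#'   `<prefix>.json`.
#' @return `write_phasor_field()` returns the prefix invisibly;
#'   `read_phasor_field()` returns the restored `"phasor_field"`.
#' @export
write_phasor_field <- function(field, path_prefix) {
  stopifnot(inherits(field, "phasor_field"))
  imax <- max(field$total_intensity, 1)
  g <- (field$G + 1) / 2
  s <- (field$S + 1) / 2
  g[!field$valid_mask] <- 0
  s[!field$valid_mask] <- 0
  pages <- list(
    g, s, field$total_intensity / imax,
    matrix(as.numeric(field$valid_mask), nrow(field$G), ncol(field$G))
  )
  tiff::writeTIFF(pages, paste0(path_prefix, ".tif"),
    bits.per.sample = 32L, compression = "none"
  )
  jsonlite::write_json(
    list(
      axis = list(
        lambda_min = field$axis$lambda_min,
        lambda_max = field$axis$lambda_max,
        n_channels = field$axis$n_channels
      ),
      harmonic = field$harmonic,
      intensity_threshold = field$intensity_threshold,
      intensity_max = imax,
      encoding = "pages: (G+1)/2, (S+1)/2, intensity/intensity_max, valid"
    ),
    paste0(path_prefix, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path_prefix)
}

#' @rdname write_phasor_field
#' @export
read_phasor_field <- function(path_prefix) {
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"),
    simplifyVector = TRUE
  )
  pages <- tiff::readTIFF(paste0(path_prefix, ".tif"), all = TRUE)
  valid <- pages[[4L]] > 0.5
  G <- pages[[1L]] * 2 - 1
  S <- pages[[2L]] * 2 - 1
  G[!valid] <- NA_real_
  S[!valid] <- NA_real_
  new_phasor_field(
    G = G, S = S,
    total = pages[[3L]] * meta$intensity_max,
    valid = valid,
    harmonic = meta$harmonic,
    axis = spectral_axis(
      meta$axis$lambda_min, meta$axis$lambda_max, meta$axis$n_channels
    ),
    threshold = meta$intensity_threshold
  )
}

#' Read and write region-of-interest masks as 8-bit TIFF
#'
#' Masks use the 0/255 convention: foreground (lesion) pixels are 255.
#'
#' @param mask Logical matrix.
#' @param path TIFF file path.
#' @return `read_roi_mask()` returns a logical matrix; `write_roi_mask()`
#'   returns `path` invisibly.
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  tiff::writeTIFF(ifelse(mask, 1, 0), path,
    bits.per.sample = 8L, compression = "none"
  )
  invisible(path)
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  tiff::readTIFF(path) > 0.5
}
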