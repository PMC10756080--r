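# Container for a lambda stack: per-pixel nonnegative intensity spectra.

#' Create a hyperspectral lambda stack
#'
#' An `hsi_stack` holds a rows x cols x channels array of nonnegative
#' intensities (detector counts) together with the [spectral_axis()] that
#' labels the channel dimension and the acquisition bit depth.
#'
#' @param intensities 3-D numeric array, `rows x cols x n_channels`,
#'   nonnegative; the third dimension must match `axis$n_channels`.
#' @param axis A [spectral_axis()].
#' @param bit_depth Acquisition bit depth (8 or 16 typical); recorded for
#'   input/output, not enforced on values.
#' @return An object of class `"hsi_stack"`.
#' @examples
#' ax <- spectral_axis(423, 723, 30)
#' st <- hsi_stack(array(1, dim = c(4, 4, 30)), ax)
#' @export
hsi_stack <- function(intensities, axis, bit_depth = 8L) {
  stopifnot(inherits(axis, "spectral_axis"))
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop("`intensities` must be a 3-D array (rows x cols x channels)",
      call. = FALSE
    )
  }
  if (dim(intensities)[3L] != axis$n_channels) {
    stop(sprintf(
      "channel mismatch: stack has %d channels, axis has %d",
      dim(intensities)[3L], axis$n_channels
    ), call. = FALSE)
  }
  if (anyNA(intensities) || any(intensities < 0)) {
    stop("intensities must be finite and nonnegative", call. = FALSE)
  }
  structure(
    list(
      intensities = intensities,
      axis = axis,
      bit_depth = as.integer(bit_depth)
    ),
    class = "hsi_stack"
  )
}

#' @export
print.hsi_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<hsi_stack> %d x %d pixels, %d channels (%g-%g nm), %d-bit\n",
    d[1L], d[2L], d[3L], x$axis$lambda_min, x$axis$lambda_max, x$bit_depth
  ))
  invisible(x)
}

#' @export
dim.hsi_stack <- function(x) dim(x$intensities)
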