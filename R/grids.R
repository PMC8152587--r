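#' Bin grid for spectral standardization
#'
#' A grid of contiguous half-open bins \code{[low + i*width, low + (i+1)*width)},
#' \code{i = 0, ..., n_bins - 1}, onto which a raw spectrum is discretised.
#' The abscissa unit is wavenumber (cm^-1) for FTIR grids and m/z for mass
#' spectra.
#'
#' @param low lower edge of the first bin.
#' @param high upper edge of the grid; the number of bins is
#'   \code{ceiling((high - low) / width)}.
#' @param width bin width in abscissa units.
#' @return An object of class \code{bin_grid} with fields \code{low},
#'   \code{high}, \code{width} and \code{n_bins}.
#' @seealso [default_ftir_grid()], [default_ms_grid()], [bin_centers()]
#' @export
bin_grid <- function(low, high, width) {
  stopifnot(is.numeric(low), is.numeric(high), is.numeric(width),
            length(low) == 1L, length(high) == 1L, length(width) == 1L)
  if (!is.finite(low) || !is.finite(high) || !is.finite(width))
    stop("bin_grid: low, high and width must be finite")
  if (width <= 0) stop("bin_grid: width must be positive")
  if (high <= low) stop("bin_grid: high must exceed low")
  structure(
    list(low = low, high = high, width = width,
         n_bins = as.integer(ceiling((high - low) / width))),
    class = "bin_grid")
}

#' Default FTIR grid: 400-4000 cm^-1 at 4 cm^-1 resolution (900 bins)
#'
#' Covers the mid-infrared region recorded by routine bench-top FTIR
#' instruments; 4 cm^-1 matches common instrument resolution.
#' @return a [bin_grid()].
#' @export
default_ftir_grid <- function() bin_grid(400, 4000, 4)

#' Default EI-MS grid: unit-mass bins covering m/z 1-650
#'
#' One bin per integer m/z value, suitable for unit-resolution electron
#' ionisation spectra of small molecules.
#' @return a [bin_grid()].
#' @export
default_ms_grid <- function() bin_grid(1, 651, 1)

#' Bin centers of a grid
#' @param grid a [bin_grid()].
#' @return numeric vector of length \code{grid$n_bins}.
#' @export
bin_centers <- function(grid) {
  stopifnot(inherits(grid, "bin_grid"))
  grid$low + (seq_len(grid$n_bins) - 0.5) * grid$width
}

# 0-based index of the bin containing x, or NA outside the grid
bin_index <- function(grid, x) {
  i <- floor((x - grid$low) / grid$width)
  i[i < 0 | i >= grid$n_bins] <- NA_integer_
  as.integer(i)
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> [%g, %g) width %g: %d bins\n",
              x$low, x$high, x$width, x$n_bins))
  invisible(x)
}
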