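#' Raw spectrum container
#'
#' Holds the (x, y) pairs of one spectrum as parsed from a JCAMP-DX record
#' (or produced by the synthetic generator), before any standardization.
#' On construction the points are sorted by abscissa and duplicate abscissa
#' values collapsed to their mean, so that \code{x} is strictly increasing.
#'
#' @param compound_id opaque identifier string.
#' @param technique \code{"FTIR"} or \code{"MS"}.
#' @param x abscissa values: wavenumber (cm^-1) for FTIR, m/z for MS.
#' @param y ordinate values: transmittance or absorbance for FTIR, relative
#'   abundance for MS. Must be finite.
#' @param y_unit one of \code{"TRANSMITTANCE"}, \code{"ABSORBANCE"},
#'   \code{"ABUNDANCE"}.
#' @return object of class \code{raw_spectrum}.
#' @export
raw_spectrum <- function(compound_id, technique = c("FTIR", "MS"),
                         x, y,
                         y_unit = c("TRANSMITTANCE", "ABSORBANCE", "ABUNDANCE")) {
  technique <- match.arg(technique)
  y_unit <- match.arg(y_unit)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("raw_spectrum: x and y lengths differ (", length(x), " vs ", length(y), ")")
  if (length(x) == 0L) stop("raw_spectrum: empty spectrum")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("raw_spectrum: non-finite values in spectrum '", compound_id, "'")
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (anyDuplicated(x)) {
    y <- as.numeric(tapply(y, x, mean))
    x <- sort(unique(x))
  }
  structure(list(compound_id = as.character(compound_id), technique = technique,
                 x = x, y = y, y_unit = y_unit),
            class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("<raw_spectrum> %s [%s, %s] %d points, x in [%g, %g]\n",
              x$compound_id, x$technique, x$y_unit, length(x$x),
              min(x$x), max(x$x)))
  invisible(x)
}

new_standard_spectrum <- function(compound_id, technique, grid, values,
                                  interpolated_mask) {
  structure(list(compound_id = compound_id, technique = technique,
                 grid = grid, values = values,
                 interpolated_mask = interpolated_mask),
            class = "standard_spectrum")
}

#' @export
print.standard_spectrum <- function(x, ...) {
  cat(sprintf("<standard_spectrum> %s [%s] %d bins, %d interpolated\n",
              x$compound_id, x$technique, x$grid$n_bins,
              sum(x$interpolated_mask)))
  invisible(x)
}

#' Standardize an FTIR spectrum onto a bin grid
#'
#' Converts absorbance to transmittance (\code{T = 10^-A}) if necessary,
#' averages the in-bin ordinates of every bin covered by data, min-max
#' normalizes the covered bin means to [0, 1], and fills bins that lie inside
#' the recorded range but received no datum by a cubic interpolating spline
#' through the covered bins, evaluated at the bin centers and clipped to
#' [0, 1]. Bins outside the recorded range are set to the full-transmittance
#' baseline 1.0. Normalizing the binned means (rather than the raw ordinates)
#' makes standardization idempotent bin-for-bin.
#'
#' When fewer than 4 bins carry data the spline is ill-posed and linear
#' interpolation is used instead (with a warning). A constant spectrum maps
#' to 1.0 in every covered bin (the max == min normalization convention).
#'
#' @param s a [raw_spectrum()] with \code{technique == "FTIR"}.
#' @param grid a [bin_grid()]; defaults to [default_ftir_grid()].
#' @return a \code{standard_spectrum}: \code{values} of length
#'   \code{grid$n_bins} in [0, 1], with \code{interpolated_mask} flagging the
#'   spline-filled bins.
#' @export
standardize_ftir <- function(s, grid = default_ftir_grid()) {
  stopifnot(inherits(s, "raw_spectrum"), inherits(grid, "bin_grid"))
  if (s$technique != "FTIR")
    stop("standardize_ftir: spectrum technique is ", s$technique, ", not FTIR")
  y <- s$y
  if (s$y_unit == "ABSORBANCE") y <- 10^(-y)

  idx <- bin_index(grid, s$x)          # 0-based; NA outside grid
  keep <- !is.na(idx)
  if (sum(keep) == 0L || length(unique(idx[keep])) < 2L)
    stop("standardize_ftir: spectrum '", s$compound_id,
         "' covers fewer than 2 bins of the grid")
  tab <- tapply(y[keep], idx[keep], mean)
  means <- as.numeric(tab)
  covered <- as.integer(names(tab)) + 1L   # 1-based bin numbers
  # min-max normalization of the bin means; flat spectra map to baseline 1.0
  rng <- range(means)
  if (rng[2] > rng[1]) means <- (means - rng[1]) / (rng[2] - rng[1])
  else means <- rep(1, length(means))
  values <- rep(1.0, grid$n_bins)
  mask <- rep(FALSE, grid$n_bins)
  values[covered] <- means

  centers <- bin_centers(grid)
  lo <- min(covered); hi <- max(covered)
  missing <- setdiff(seq.int(lo, hi), covered)
  if (length(missing)) {
    if (length(covered) >= 4L) {
      f <- stats::splinefun(centers[covered], values[covered], method = "natural")
      fill <- f(centers[missing])
    } else {
      warning("standardize_ftir: fewer than 4 support bins for '",
              s$compound_id, "'; falling back to linear interpolation")
      fill <- stats::approx(centers[covered], values[covered],
                            xout = centers[missing])$y
    }
    values[missing] <- pmin(pmax(fill, 0), 1)
    mask[missing] <- TRUE
  }
  values <- pmin(pmax(values, 0), 1)
  new_standard_spectrum(s$compound_id, "FTIR", grid, values, mask)
}

#' Standardize an EI mass spectrum onto unit-mass bins
#'
#' Sums peak abundances into integer m/z bins (floor convention for
#' fractional m/z), scales so the base peak equals 1.0, and leaves absent
#' bins at 0. No interpolation is performed. Peaks beyond the grid are
#' dropped with a message reporting the count.
#'
#' @param s a [raw_spectrum()] with \code{technique == "MS"}.
#' @param grid a [bin_grid()] of unit width; defaults to [default_ms_grid()].
#' @return a \code{standard_spectrum}; \code{interpolated_mask} is all FALSE.
#' @export
standardize_ms <- function(s, grid = default_ms_grid()) {
  stopifnot(inherits(s, "raw_spectrum"), inherits(grid, "bin_grid"))
  if (s$technique != "MS")
    stop("standardize_ms: spectrum technique is ", s$technique, ", not MS")
  if (grid$width != 1)
    stop("standardize_ms: MS grid must have unit (1 m/z) bin width")
  idx <- bin_index(grid, s$x)
  dropped <- sum(is.na(idx))
  if (dropped > 0L)
    message("standardize_ms: dropped ", dropped, " peak(s) outside the grid for '",
            s$compound_id, "'")
  keep <- !is.na(idx)
  if (!any(keep) || all(s$y[keep] == 0))
    stop("standardize_ms: spectrum '", s$compound_id,
         "' has no base peak (all-zero abundances on the grid)")
  sums <- tapply(s$y[keep], idx[keep], sum)
  values <- numeric(grid$n_bins)
  values[as.integer(names(sums)) + 1L] <- as.numeric(sums)
  values <- values / max(values)
  new_standard_spectrum(s$compound_id, "MS", grid, values,
                        rep(FALSE, grid$n_bins))
}

#' Standardize a raw spectrum, dispatching on technique
#' @param s a [raw_spectrum()].
#' @param grid a [bin_grid()]; defaults depend on technique.
#' @return a \code{standard_spectrum}.
#' @export
standardize_spectrum <- function(s, grid = NULL) {
  stopifnot(inherits(s, "raw_spectrum"))
  if (s$technique == "FTIR")
    standardize_ftir(s, grid %||% default_ftir_grid())
  else
    standardize_ms(s, grid %||% default_ms_grid())
}

#' Convert a standardized spectrum back to a raw spectrum
#'
#' The resulting raw spectrum samples every bin center of the grid, so
#' re-standardizing it reproduces the standardized values exactly
#' (standardization is idempotent).
#'
#' @param s a \code{standard_spectrum}.
#' @return a [raw_spectrum()].
#' @export
as_raw <- function(s) {
  stopifnot(inherits(s, "standard_spectrum"))
  raw_spectrum(s$compound_id, s$technique, bin_centers(s$grid), s$values,
               if (s$technique == "MS") "ABUNDANCE" else "TRANSMITTANCE")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write standardized spectra as a columnar CSV
#'
#' One row per compound, one column per bin; the header row carries the bin
#' centers (prefixed by the technique), the first column the compound ids.
#'
#' @param spectra list of \code{standard_spectrum} objects on a shared grid.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, logical(1), "standard_spectrum")))
  g0 <- spectra[[1]]$grid
  for (s in spectra)
    if (!identical(unclass(s$grid), unclass(g0)))
      stop("write_spectra_csv: spectra use different grids")
  m <- do.call(rbind, lapply(spectra, `[[`, "values"))
  df <- data.frame(compound_id = vapply(spectra, `[[`, character(1),
                                        "compound_id"), m,
                   check.names = FALSE)
  names(df)[-1] <- sprintf("%s_%g", tolower(spectra[[1]]$technique),
                           bin_centers(g0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
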