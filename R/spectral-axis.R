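#' Calibrated wavenumber axis for a hyperspectral SRS stack
#'
#' The C-H stretch region of liver tissue is scanned at a fixed wavenumber
#' step; each channel of a hyperspectral stack corresponds to one point on
#' this axis. The default covers 2800 cm^-1 upward in 40 channels of
#' 5 cm^-1, which spans the lipid (2850 cm^-1), protein (2930 cm^-1) and
#' DNA (2960 cm^-1) Raman clusters.
#'
#' @param start_wavenumber First channel position in cm^-1.
#' @param step Channel spacing in cm^-1; must be positive.
#' @param n_channels Number of spectral channels; at least 2.
#' @return An object of class `spectral_axis` with fields
#'   `start_wavenumber`, `step`, `n_channels`.
#' @examples
#' ax <- spectral_axis()
#' axis_values(ax)[1:5]
#' @export
spectral_axis <- function(start_wavenumber = 2800, step = 5, n_channels = 40) {
  stopifnot(is.numeric(start_wavenumber), length(start_wavenumber) == 1L)
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("`step` must be a single positive number (cm^-1)")
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 2L)
    stop("`n_channels` must be an integer >= 2")
  structure(
    list(start_wavenumber = as.numeric(start_wavenumber),
         step = as.numeric(step),
         n_channels = n_channels),
    class = "spectral_axis"
  )
}

#' Wavenumber values of a spectral axis
#'
#' @param axis A [spectral_axis()].
#' @return Numeric vector of length `n_channels`, strictly increasing.
#' @export
axis_values <- function(axis) {
  stopifnot(inherits(axis, "spectral_axis"))
  axis$start_wavenumber + axis$step * (seq_len(axis$n_channels) - 1)
}

#' @export
print.spectral_axis <- function(x, ...) {
  v <- axis_values(x)
  cat(sprintf("<spectral_axis> %d channels, %g to %g cm^-1 (step %g)\n",
              x$n_channels, v[1], v[length(v)], x$step))
  invisible(x)
}
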