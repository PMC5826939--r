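#' Reference Raman spectra for the three tissue classes
#'
#' Builds Gaussian-mixture reference spectra for the spectral clusters of
#' liver tissue in the C-H stretch region: lipid (dominant CH2 stretch at
#' 2850 cm^-1 with a minor 2930 cm^-1 shoulder), protein (CH3 stretch at
#' 2930 cm^-1) and DNA (2960 cm^-1 with a minor 2930 cm^-1 shoulder).
#' Each spectrum is evaluated on `axis` and peak-normalized to 1; the
#' minor shoulders create the partial spectral overlap seen in tissue
#' phasor plots while keeping each class argmax at its cluster center.
#'
#' @param axis A [spectral_axis()]; must cover all requested peak centers.
#' @return Named list of three `reference_spectrum` objects
#'   (`lipid`, `protein`, `dna`), each with fields `class_label`,
#'   `peak_centers`, `peak_widths`, `peak_weights`, and `values`
#'   (the spectrum sampled on `axis`, max 1).
#' @examples
#' refs <- make_reference_spectra(spectral_axis())
#' axis_values(spectral_axis())[which.max(refs$lipid$values)]  # 2850
#' @export
make_reference_spectra <- function(axis = spectral_axis()) {
  stopifnot(inherits(axis, "spectral_axis"))
  specs <- list(
    lipid   = list(centers = c(2850, 2930), widths = c(12, 18), weights = c(1, 0.25)),
    protein = list(centers = 2930,          widths = 18,        weights = 1),
    dna     = list(centers = c(2960, 2930), widths = c(12, 16), weights = c(1, 0.30))
  )
  out <- lapply(names(specs), function(lbl) {
    p <- specs[[lbl]]
    reference_spectrum(lbl, p$centers, p$widths, p$weights, axis)
  })
  names(out) <- names(specs)
  out
}

#' Construct a reference spectrum as a Gaussian mixture
#'
#' @param class_label One of `"lipid"`, `"protein"`, `"dna"`.
#' @param peak_centers Peak positions, cm^-1, within 2700-3100.
#' @param peak_widths Gaussian sigmas, cm^-1, positive.
#' @param peak_weights Relative amplitudes, nonnegative, not all zero.
#' @param axis A [spectral_axis()] the spectrum is sampled on; every center
#'   must fall inside the axis range.
#' @return A `reference_spectrum` object; `values` is peak-normalized to 1.
#' @export
reference_spectrum <- function(class_label, peak_centers, peak_widths,
                               peak_weights, axis = spectral_axis()) {
  class_label <- match.arg(class_label, c("lipid", "protein", "dna"))
  stopifnot(length(peak_centers) == length(peak_widths),
            length(peak_centers) == length(peak_weights))
  if (any(peak_weights < 0) || all(peak_weights == 0))
    stop("peak weights must be nonnegative and not all zero")
  if (any(peak_centers < 2700 | peak_centers > 3100))
    stop("peak centers must lie within [2700, 3100] cm^-1")
  if (any(peak_widths <= 0))
    stop("peak widths (sigma) must be positive")
  wn <- axis_values(axis)
  bad <- peak_centers < min(wn) | peak_centers > max(wn)
  if (any(bad))
    stop(sprintf("axis (%g-%g cm^-1) does not cover peak center(s): %s",
                 min(wn), max(wn), paste(peak_centers[bad], collapse = ", ")))
  v <- eval_gaussian_mixture(wn, peak_centers, peak_widths, peak_weights)
  structure(
    list(class_label = class_label,
         peak_centers = as.numeric(peak_centers),
         peak_widths = as.numeric(peak_widths),
         peak_weights = as.numeric(peak_weights),
         axis = axis,
         values = v / max(v)),
    class = "reference_spectrum"
  )
}

# Sum of Gaussians evaluated at x; no normalization.
eval_gaussian_mixture <- function(x, centers, sigmas, weights) {
  v <- numeric(length(x))
  for (i in seq_along(centers))
    v <- v + weights[i] * exp(-(x - centers[i])^2 / (2 * sigmas[i]^2))
  v
}

#' @export
print.reference_spectrum <- function(x, ...) {
  cat(sprintf("<reference_spectrum> %s: peaks at %s cm^-1\n",
              x$class_label, paste(x$peak_centers, collapse = ", ")))
  invisible(x)
}
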