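#' Spectral phasor transform of a hyperspectral stack
#'
#' Maps each pixel's spectrum to its normalized first-harmonic Fourier
#' coefficients
#' \deqn{g = \sum_k I_k \cos(2\pi h k/N) / \sum_k I_k, \qquad
#'       s = \sum_k I_k \sin(2\pi h k/N) / \sum_k I_k,}
#' with channel index \eqn{k = 0, \dots, N-1} and harmonic \eqn{h}.
#' Spectrally similar pixels cluster in the (g, s) plane, so chemical
#' classes can be gated geometrically. Any nonnegative spectrum maps into
#' the closed unit disc, and the transform is invariant to global scaling
#' of a pixel's spectrum.
#'
#' @param stack A `hyperspectral_stack` (see [hyperspectral_stack()]).
#' @param harmonic Harmonic number, integer >= 1 (default 1).
#' @return A `phasor_field`: matrices `g`, `s`, `total_intensity` (per-pixel
#'   channel sum), logical matrix `flagged` (pixels with total <= 0, which
#'   get g = s = 0), and `harmonic`.
#' @examples
#' ph <- generate_phantom(tissue_phantom_spec("normal", seed = 1,
#'                                            height_px = 32, width_px = 32))
#' pf <- phasor_transform(ph$stack)
#' range(pf$g^2 + pf$s^2)
#' @export
phasor_transform <- function(stack, harmonic = 1L) {
  stopifnot(inherits(stack, "hyperspectral_stack"))
  harmonic <- as.integer(harmonic)
  if (is.na(harmonic) || harmonic < 1L) stop("`harmonic` must be an integer >= 1")
  d <- dim(stack$data)
  n <- d[3]
  if (n < 2L) stop("phasor transform needs at least 2 spectral channels")
  if (!all(is.finite(stack$data))) {
    bad <- sum(!is.finite(apply(stack$data, c(1, 2), sum)))
    stop(sprintf("stack contains non-finite values in %d pixel(s)", bad))
  }
  x <- matrix(stack$data, nrow = d[1] * d[2], ncol = n)
  k <- 0:(n - 1)
  cosv <- cos(2 * pi * harmonic * k / n)
  sinv <- sin(2 * pi * harmonic * k / n)
  total <- rowSums(x)
  flagged <- total <= 0
  denom <- ifelse(flagged, 1, total)
  g <- as.vector(x %*% cosv) / denom
  s <- as.vector(x %*% sinv) / denom
  g[flagged] <- 0; s[flagged] <- 0
  structure(
    list(g = matrix(g, d[1], d[2]),
         s = matrix(s, d[1], d[2]),
         total_intensity = matrix(total, d[1], d[2]),
         flagged = matrix(flagged, d[1], d[2]),
         harmonic = harmonic),
    class = "phasor_field"
  )
}

#' Phasor coordinates of a single spectrum
#'
#' Convenience wrapper: the phasor point of one spectrum (e.g. a reference
#' spectrum) under the same convention as [phasor_transform()].
#'
#' @param intensity Numeric vector, one value per channel.
#' @param harmonic Harmonic number (default 1).
#' @return Named numeric vector `c(g =, s =)`.
#' @export
spectrum_phasor <- function(intensity, harmonic = 1L) {
  n <- length(intensity)
  stopifnot(n >= 2L)
  total <- sum(intensity)
  if (total <= 0) return(c(g = 0, s = 0))
  k <- 0:(n - 1)
  c(g = sum(intensity * cos(2 * pi * harmonic * k / n)) / total,
    s = sum(intensity * sin(2 * pi * harmonic * k / n)) / total)
}

#' 2D phasor density histogram
#'
#' Histogram of (g, s) over the square [-1, 1]^2; the phasor-plot density
#' used to locate chemical clusters before gating. Flagged (zero-intensity)
#' pixels are excluded; counts sum to the number of unflagged pixels.
#'
#' @param field A `phasor_field`.
#' @param bins Number of bins per axis, >= 8.
#' @return List with `counts` (bins x bins matrix, g on rows, s on
#'   columns) and `breaks` (common bin edges).
#' @export
phasor_density <- function(field, bins = 128L) {
  stopifnot(inherits(field, "phasor_field"))
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 8L) stop("`bins` must be an integer >= 8")
  breaks <- seq(-1, 1, length.out = bins + 1L)
  keep <- !field$flagged
  g <- pmin(pmax(field$g[keep], -1), 1)
  s <- pmin(pmax(field$s[keep], -1), 1)
  gi <- pmin(pmax(findInterval(g, breaks, rightmost.closed = TRUE), 1L), bins)
  si <- pmin(pmax(findInterval(s, breaks, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  if (length(gi)) {
    t2 <- table(factor(gi, levels = seq_len(bins)),
                factor(si, levels = seq_len(bins)))
    counts <- matrix(as.integer(t2), bins, bins)
  }
  list(counts = counts, breaks = breaks)
}
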