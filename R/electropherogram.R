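#' Specification of a synthetic cIEF electropherogram
#'
#' Describes one capillary isoelectric focusing trace of a protein and its
#' PTM isoforms on a pH 5-8 gradient. Isoform pI shifts follow the cIEF
#' conventions: phospho- and acetyl-isoforms shift to lower pI than the
#' unmodified isoform (acetyl much farther), glycosyl-isoforms shift to
#' higher pI.
#'
#' @param unmodified_pI pI of the unmodified isoform.
#' @param isoforms Data frame with columns `ptm` (one of `"unmodified"`,
#'   `"phospho"`, `"acetyl"`, `"glycosyl"`), `pI_shift` (pH units,
#'   relative to `unmodified_pI`; 0 for unmodified), `concentration`
#'   (relative, nonnegative, summing to 1), `sigma` (Gaussian peak width,
#'   pH units). See [default_isoforms()].
#' @param pI_range Axis limits, pH units (default 5-8 separation gradient).
#' @param n_points Number of axis samples.
#' @param baseline_level Constant baseline as a fraction of the tallest
#'   noiseless peak.
#' @param noise_sigma Additive Gaussian noise SD as a fraction of the
#'   tallest noiseless peak.
#' @param seed Integer seed.
#' @return An `electropherogram_spec` object.
#' @export
electropherogram_spec <- function(unmodified_pI = 6.5,
                                  isoforms = default_isoforms(),
                                  pI_range = c(5, 8),
                                  n_points = 601L,
                                  baseline_level = 0.02,
                                  noise_sigma = 0.01,
                                  seed = 1L) {
  stopifnot(is.data.frame(isoforms),
            all(c("ptm", "pI_shift", "concentration", "sigma") %in%
                  names(isoforms)))
  if (!all(isoforms$ptm %in% c("unmodified", "phospho", "acetyl", "glycosyl")))
    stop("isoform `ptm` must be unmodified/phospho/acetyl/glycosyl")
  if (any(isoforms$concentration < 0))
    stop("isoform concentrations must be nonnegative")
  if (abs(sum(isoforms$concentration) - 1) > 1e-9)
    stop("isoform concentrations must sum to 1")
  if (any(isoforms$pI_shift[isoforms$ptm == "phospho"] >= 0))
    stop("phospho shifts must be negative (toward lower pI)")
  if (any(isoforms$pI_shift[isoforms$ptm == "acetyl"] >= 0))
    stop("acetyl shifts must be negative (toward lower pI)")
  if (nrow(isoforms[isoforms$ptm == "acetyl", ]) &&
      nrow(isoforms[isoforms$ptm == "phospho", ]) &&
      min(isoforms$pI_shift[isoforms$ptm == "acetyl"]) >=
        min(isoforms$pI_shift[isoforms$ptm == "phospho"]))
    stop("acetyl shifts must be more negative than phospho shifts")
  if (any(isoforms$pI_shift[isoforms$ptm == "glycosyl"] <= 0))
    stop("glycosyl shifts must be positive (toward higher pI)")
  if (any(isoforms$sigma <= 0)) stop("peak sigmas must be positive")
  centers <- unmodified_pI + isoforms$pI_shift
  outside <- centers < pI_range[1] | centers > pI_range[2]
  if (any(outside))
    stop(sprintf("isoform center(s) %s outside the pI axis [%g, %g]",
                 paste(round(centers[outside], 2), collapse = ", "),
                 pI_range[1], pI_range[2]))
  structure(
    list(unmodified_pI = unmodified_pI, isoforms = isoforms,
         pI_range = as.numeric(pI_range), n_points = as.integer(n_points),
         baseline_level = baseline_level, noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "electropherogram_spec"
  )
}

#' Default isoform composition
#'
#' A three-isoform mixture (unmodified 0.5, phospho 0.3, acetyl 0.2) with
#' the standard pI-shift directions and default peak width 0.05 pH units.
#'
#' @param unmodified,phospho,acetyl,glycosyl Relative concentrations;
#'   must sum to 1. Isoforms at 0 are dropped.
#' @param phospho_shift,acetyl_shift,glycosyl_shift pI shifts (pH units).
#' @param sigma Common Gaussian peak width (pH units).
#' @return Isoform data frame for [electropherogram_spec()].
#' @export
default_isoforms <- function(unmodified = 0.5, phospho = 0.3, acetyl = 0.2,
                             glycosyl = 0,
                             phospho_shift = -0.15, acetyl_shift = -0.5,
                             glycosyl_shift = 0.3, sigma = 0.05) {
  df <- data.frame(
    ptm = c("unmodified", "phospho", "acetyl", "glycosyl"),
    pI_shift = c(0, phospho_shift, acetyl_shift, glycosyl_shift),
    concentration = c(unmodified, phospho, acetyl, glycosyl),
    sigma = sigma
  )
  df[df$concentration > 0, , drop = FALSE]
}

#' Generate a synthetic electropherogram with ground truth
#'
#' trace = baseline + sum over isoforms of a Gaussian centered at
#' `unmodified_pI + pI_shift` whose area is proportional to the isoform's
#' relative concentration, plus Gaussian noise.
#'
#' @param spec An [electropherogram_spec()].
#' @return List with `trace` (an `electropherogram`: data frame columns
#'   `pI`, `intensity`) and `truth` (named vector of ground-truth relative
#'   concentrations by PTM).
#' @examples
#' e <- generate_electropherogram(electropherogram_spec(seed = 3))
#' e$truth
#' @export
generate_electropherogram <- function(spec) {
  stopifnot(inherits(spec, "electropherogram_spec"))
  set.seed(spec$seed)
  pI <- seq(spec$pI_range[1], spec$pI_range[2], length.out = spec$n_points)
  iso <- spec$isoforms
  clean <- numeric(length(pI))
  for (i in seq_len(nrow(iso))) {
    center <- spec$unmodified_pI + iso$pI_shift[i]
    # unit-concentration Gaussian has unit area
    clean <- clean + iso$concentration[i] *
      stats::dnorm(pI, mean = center, sd = iso$sigma[i])
  }
  peak <- max(clean)
  if (peak <= 0) stop("spec produces an empty trace")
  intensity <- clean + spec$baseline_level * peak
  if (spec$noise_sigma > 0)
    intensity <- intensity + stats::rnorm(length(pI), sd = spec$noise_sigma * peak)
  truth <- tapply(iso$concentration, iso$ptm, sum)
  list(
    trace = electropherogram(pI, intensity),
    truth = truth[order(names(truth))]
  )
}

#' Simulate lambda-phosphatase treatment of a sample
#'
#' Returns a spec in which phospho-isoform concentration has been
#' transferred to the unmodified isoform (dephosphorylation restores the
#' unmodified charge state); acetyl and glycosyl isoforms are untouched
#' and total concentration is conserved. Complete dephosphorylation by
#' default; `efficiency` scales the transferred fraction.
#'
#' @param spec An [electropherogram_spec()].
#' @param efficiency Fraction of phospho concentration removed, in [0, 1].
#' @return A new `electropherogram_spec`.
#' @examples
#' sp <- electropherogram_spec(isoforms = default_isoforms(0.6, 0.4, 0))
#' apply_phosphatase(sp)$isoforms
#' @export
apply_phosphatase <- function(spec, efficiency = 1) {
  stopifnot(inherits(spec, "electropherogram_spec"))
  if (efficiency < 0 || efficiency > 1) stop("`efficiency` must be in [0, 1]")
  iso <- spec$isoforms
  is_p <- iso$ptm == "phospho"
  moved <- sum(iso$concentration[is_p]) * efficiency
  if (moved > 0) {
    iso$concentration[is_p] <- iso$concentration[is_p] * (1 - efficiency)
    if (any(iso$ptm == "unmodified")) {
      iso$concentration[iso$ptm == "unmodified"][1] <-
        iso$concentration[iso$ptm == "unmodified"][1] + moved
    } else {
      iso <- rbind(iso, data.frame(ptm = "unmodified", pI_shift = 0,
                                   concentration = moved,
                                   sigma = iso$sigma[1]))
    }
  }
  out <- spec
  out$isoforms <- iso
  out
}

#' Construct an electropherogram
#'
#' @param pI Strictly increasing pI axis (pH units).
#' @param intensity Chemiluminescence intensity, same length as `pI`.
#' @return An `electropherogram` (data frame with class attribute).
#' @export
electropherogram <- function(pI, intensity) {
  if (length(pI) != length(intensity))
    stop("`pI` and `intensity` must have equal length")
  if (any(diff(pI) <= 0)) stop("`pI` axis must be strictly increasing")
  structure(data.frame(pI = pI, intensity = intensity),
            class = c("electropherogram", "data.frame"))
}
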