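#' Normalize an electropherogram to unit peak intensity
#'
#' Peak intensities of cIEF electropherograms are normalized to 1 before
#' quantification, so relative concentrations are comparable across
#' capillaries and exposure settings.
#'
#' @param e An `electropherogram`.
#' @return An `electropherogram` whose maximum intensity is 1.
#' @export
normalize_trace <- function(e) {
  stopifnot(inherits(e, "electropherogram"))
  m <- max(e$intensity)
  if (!is.finite(m) || m <= 0)
    stop("trace maximum must be positive to normalize")
  electropherogram(e$pI, e$intensity / m)
}

#' Subtract the baseline from an electropherogram
#'
#' `"rolling_min"` (default) estimates the baseline as a centered rolling
#' minimum (window wide relative to peak widths) smoothed by a rolling
#' mean; `"linear"` fits a straight line through the lower envelope
#' (points below the median). Output is clipped at zero.
#'
#' @param e An `electropherogram`.
#' @param method `"rolling_min"` or `"linear"`.
#' @param window Rolling window width in axis points (default ~1/6 of the
#'   trace); must not exceed the trace length.
#' @return Baseline-subtracted `electropherogram` (nonnegative).
#' @export
subtract_baseline <- function(e, method = c("rolling_min", "linear"),
                              window = NULL) {
  stopifnot(inherits(e, "electropherogram"))
  method <- match.arg(method)
  n <- nrow(e)
  if (is.null(window)) window <- max(11L, 2L * (n %/% 12L) + 1L)
  window <- as.integer(window)
  if (window > n) stop("baseline `window` larger than the trace")
  if (method == "rolling_min") {
    base <- zoo::rollapply(e$intensity, width = window, FUN = min,
                           partial = TRUE, align = "center")
    base <- zoo::rollapply(base, width = window, FUN = mean,
                           partial = TRUE, align = "center")
  } else {
    low <- e$intensity <= stats::median(e$intensity)
    fit <- stats::lm(intensity ~ pI, data = e[low, , drop = FALSE])
    base <- stats::predict(fit, newdata = data.frame(pI = e$pI))
  }
  electropherogram(e$pI, pmax(e$intensity - base, 0))
}

#' Detect and fit isoform peaks as a Gaussian mixture
#'
#' Candidate peaks come from prominence-based detection on the
#' baseline-subtracted trace; a Gaussian mixture (one component per
#' candidate) is then refined by nonlinear least squares. Components whose
#' fitted amplitude falls below the prominence threshold are dropped.
#'
#' @param e Baseline-subtracted `electropherogram`.
#' @param max_peaks Maximum number of components (default 6).
#' @param prominence Minimum peak prominence as a fraction of the trace
#'   maximum (default 0.05).
#' @param init_sigma Initial peak width guess, pH units.
#' @return Data frame of peaks sorted by center: `center`, `sigma`, `auc`
#'   (fitted Gaussian area), `height`; attribute `residual_rms` carries
#'   the fit residual. Zero rows when nothing exceeds the threshold.
#' @examples
#' sp <- electropherogram_spec(noise_sigma = 0, baseline_level = 0)
#' pk <- fit_peaks(generate_electropherogram(sp)$trace)
#' pk$center
#' @export
fit_peaks <- function(e, max_peaks = 6L, prominence = 0.05,
                      init_sigma = 0.05) {
  stopifnot(inherits(e, "electropherogram"))
  x <- e$pI; y <- e$intensity
  m <- max(y)
  empty <- data.frame(center = numeric(0), sigma = numeric(0),
                      auc = numeric(0), height = numeric(0))
  if (m <= 0) return(empty)
  # moving-average smoothing for detection only; shoulders of partially
  # overlapped peaks have small valley prominence, easily lost to noise
  half <- max(1L, length(y) %/% 300L)
  ys <- as.numeric(stats::filter(y, rep(1, 2L * half + 1L) / (2L * half + 1L)))
  ys[is.na(ys)] <- y[is.na(ys)]
  found <- pracma::findpeaks(ys, minpeakheight = prominence * m,
                             minpeakdistance = max(3L, length(y) %/% 200L),
                             npeaks = as.integer(max_peaks), sortstr = TRUE)
  if (is.null(found)) return(empty)

  k <- nrow(found)
  start <- list()
  for (i in seq_len(k)) {
    start[[paste0("h", i)]] <- found[i, 1]
    start[[paste0("c", i)]] <- x[found[i, 2]]
    start[[paste0("w", i)]] <- init_sigma
  }
  model <- function(par) {
    yhat <- numeric(length(x))
    for (i in seq_len(k))
      yhat <- yhat + par[[paste0("h", i)]] *
        exp(-(x - par[[paste0("c", i)]])^2 / (2 * par[[paste0("w", i)]]^2))
    yhat
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start,
      fn = function(par) y - model(par),
      lower = rep(c(0, min(x), 1e-4), times = k),
      upper = rep(c(2 * m, max(x), diff(range(x))), times = k),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(err) NULL)
  if (is.null(fit)) {
    # fall back to detection-based estimates
    pars <- data.frame(center = x[found[, 2]], sigma = init_sigma,
                       height = found[, 1])
  } else {
    p <- fit$par
    pars <- data.frame(
      center = vapply(seq_len(k), function(i) p[[paste0("c", i)]], numeric(1)),
      sigma = vapply(seq_len(k), function(i) abs(p[[paste0("w", i)]]), numeric(1)),
      height = vapply(seq_len(k), function(i) p[[paste0("h", i)]], numeric(1)))
  }
  pars <- pars[pars$height >= prominence * m, , drop = FALSE]
  if (nrow(pars) == 0) return(empty)
  pars$auc <- pars$height * pars$sigma * sqrt(2 * pi)
  pars <- pars[order(pars$center), c("center", "sigma", "auc", "height")]
  rownames(pars) <- NULL
  if (!is.null(fit)) {
    yhat <- model(fit$par)
    attr(pars, "residual_rms") <- sqrt(mean((y - yhat)^2))
  }
  pars
}

#' Assign PTM identities to fitted peaks by pI shift
#'
#' Labels each fitted peak by its shift from the unmodified pI, following
#' the cIEF shift conventions: phospho- and acetyl-isoforms sit at lower
#' pI (acetyl much farther), glycosyl-isoforms at higher pI. When
#' `unmodified_pI` is not supplied it is inferred as the highest-pI peak
#' whose height is at least `major_fraction` of the tallest peak (supply
#' the protein's nominal pI when strong glycosyl peaks are expected).
#'
#' @param peaks Data frame from [fit_peaks()].
#' @param unmodified_pI Known unmodified pI; if `NULL`, inferred from the
#'   peaks as described above.
#' @param phospho_min Minimum |shift| to call a modification (pH units).
#' @param acetyl_cut |shift| beyond which a lower-pI peak is acetyl rather
#'   than phospho.
#' @param glyco_min Minimum positive shift to call glycosyl.
#' @param major_fraction Height fraction defining "major" peaks for
#'   unmodified-peak inference.
#' @return `peaks` with columns `assignment` and `ambiguous` (TRUE for
#'   peaks within `phospho_min` of a class boundary).
#' @export
assign_isoforms <- function(peaks, unmodified_pI = NULL,
                            phospho_min = 0.05, acetyl_cut = 0.35,
                            glyco_min = 0.05, major_fraction = 0.25) {
  if (!nrow(peaks)) {
    peaks$assignment <- character(0)
    peaks$ambiguous <- logical(0)
    return(peaks)
  }
  if (is.null(unmodified_pI)) {
    major <- peaks[peaks$height >= major_fraction * max(peaks$height), ]
    unmodified_pI <- max(major$center)
  }
  shift <- peaks$center - unmodified_pI
  assignment <- ifelse(abs(shift) < phospho_min, "unmodified",
                ifelse(shift >= glyco_min, "glycosyl",
                ifelse(shift <= -acetyl_cut, "acetyl", "phospho")))
  boundary <- pmin(abs(abs(shift) - phospho_min),
                   abs(-shift - acetyl_cut))
  peaks$assignment <- assignment
  peaks$ambiguous <- boundary < phospho_min / 2
  peaks
}

#' Relative isoform concentrations from fitted peaks
#'
#' The relative concentration of each PTM class is the summed AUC of its
#' assigned peaks divided by the total AUC of all isoform peaks.
#'
#' @param peaks Data frame from [assign_isoforms()] (needs `auc` and
#'   `assignment`).
#' @param protein Optional protein name to record.
#' @return An `isoform_profile`: `protein`, `peaks`, and named
#'   `relative_concentration` (sums to 1).
#' @export
relative_concentrations <- function(peaks, protein = NA_character_) {
  if (!nrow(peaks)) stop("no peaks to quantify")
  total <- sum(peaks$auc)
  if (total <= 0) stop("total AUC is zero; cannot form relative concentrations")
  rc <- tapply(peaks$auc, peaks$assignment, sum) / total
  rc <- rc[order(names(rc))]
  structure(
    list(protein = protein, peaks = peaks,
         relative_concentration = rc),
    class = "isoform_profile"
  )
}

#' Full cIEF quantification pipeline for one trace
#'
#' normalize -> baseline subtraction -> Gaussian-mixture peak fit -> PTM
#' assignment by pI shift -> AUC-ratio relative concentrations.
#'
#' @param e An `electropherogram` (raw).
#' @param protein Optional protein name.
#' @param unmodified_pI Known unmodified pI, or `NULL` to infer.
#' @param ... Passed to [fit_peaks()] and [assign_isoforms()] (matched by
#'   name).
#' @return An `isoform_profile`.
#' @examples
#' e <- generate_electropherogram(electropherogram_spec(seed = 5))$trace
#' quantify_cief(e, unmodified_pI = 6.5)$relative_concentration
#' @export
quantify_cief <- function(e, protein = NA_character_, unmodified_pI = NULL,
                          ...) {
  dots <- list(...)
  take <- function(f) dots[names(dots) %in% names(formals(f))]
  e2 <- subtract_baseline(normalize_trace(e))
  peaks <- do.call(fit_peaks, c(list(e2), take(fit_peaks)))
  peaks <- do.call(assign_isoforms,
                   c(list(peaks, unmodified_pI = unmodified_pI),
                     take(assign_isoforms)))
  relative_concentrations(peaks, protein = protein)
}

#' Phosphatase sensitivity score
#'
#' The phospho relative concentration lost between a sample and its
#' lambda-phosphatase-treated counterpart, clipped to [0, 1]. A protein is
#' called phosphatase-sensitive when the score reaches `threshold`
#' (default 0.1): its phospho peaks collapse into the unmodified peak on
#' treatment.
#'
#' @param before,after `isoform_profile`s of the same protein, untreated
#'   and treated.
#' @param threshold Sensitivity call threshold.
#' @return List `score` (in [0, 1]) and `sensitive` (logical).
#' @export
phosphatase_sensitivity <- function(before, after, threshold = 0.1) {
  get_p <- function(pr) {
    rc <- pr$relative_concentration
    if ("phospho" %in% names(rc)) unname(rc[["phospho"]]) else 0
  }
  score <- min(max(get_p(before) - get_p(after), 0), 1)
  list(score = score, sensitive = score >= threshold)
}

#' Coefficient of variation of an isoform across replicates
#'
#' SD/mean of one isoform's relative concentration over replicate
#' profiles; replicate fidelity is adequate at CV <= 0.1.
#'
#' @param profiles List of >= 2 `isoform_profile`s (replicates).
#' @param isoform PTM class name (default `"phospho"`).
#' @return List `cv` (NA with `undefined = TRUE` when the mean is 0),
#'   `mean`, `sd`, `undefined`.
#' @export
replicate_cv <- function(profiles, isoform = "phospho") {
  if (length(profiles) < 2L) stop("need at least 2 replicates")
  vals <- vapply(profiles, function(pr) {
    rc <- pr$relative_concentration
    if (isoform %in% names(rc)) unname(rc[[isoform]]) else 0
  }, numeric(1))
  m <- mean(vals); s <- stats::sd(vals)
  if (m == 0) return(list(cv = NA_real_, mean = m, sd = s, undefined = TRUE))
  list(cv = s / m, mean = m, sd = s, undefined = FALSE)
}
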