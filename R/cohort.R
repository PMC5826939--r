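#' Default six-protein cIEF panel
#'
#' Synthetic stand-ins for the six liver proteins whose isoform profiles
#' separate NASH from normal livers: Akt (phospho-isoforms higher in
#' NASH), 4EBP1, BID, HMGCS2 and FABP1 (phospho-isoforms lower in NASH),
#' and FABP5 (mainly acetylated in NASH, phosphatase-insensitive). The
#' nominal pI values and compositions are synthetic choices with the
#' observed effect directions; no measured pI positions are reproduced.
#'
#' @return Named list; per protein: `nominal_pI`, and `normal` / `nash`
#'   isoform data frames (see [default_isoforms()]).
#' @export
default_protein_panel <- function() {
  mk <- function(u, p, a) default_isoforms(unmodified = u, phospho = p,
                                           acetyl = a)
  list(
    AKT    = list(nominal_pI = 6.3, normal = mk(0.70, 0.30, 0),
                  nash = mk(0.45, 0.55, 0)),
    EIF4EBP1 = list(nominal_pI = 6.6, normal = mk(0.40, 0.60, 0),
                    nash = mk(0.75, 0.25, 0)),
    BID    = list(nominal_pI = 6.2, normal = mk(0.60, 0.40, 0),
                  nash = mk(0.85, 0.15, 0)),
    HMGCS2 = list(nominal_pI = 6.9, normal = mk(0.50, 0.50, 0),
                  nash = mk(0.80, 0.20, 0)),
    FABP1  = list(nominal_pI = 7.2, normal = mk(0.55, 0.45, 0),
                  nash = mk(0.80, 0.20, 0)),
    FABP5  = list(nominal_pI = 6.8, normal = mk(0.70, 0, 0.30),
                  nash = mk(0.30, 0, 0.70))
  )
}

#' Generate a synthetic liver cohort on disk
#'
#' Writes, for each sample, hyperspectral SRS frames (multi-page TIFF +
#' sidecar JSON) and per-protein replicate electropherograms (CSV), plus
#' a JSON manifest recording groups, seeds, file paths and ground truth.
#' Defaults mirror the study design: 9 normal + 9 NASH livers, at least
#' nine 400 x 400 px frames per sample (scaled via `frames_per_sample` /
#' `frame_px`), four cIEF replicates per protein per sample.
#'
#' Per-sample biology is varied around the cohort means: the target lipid
#' fraction is jittered (SD `lipid_fraction_sd`, clamped to [0.01, 0.9])
#' and isoform compositions are jittered on the log scale
#' (SD `isoform_jitter`) then renormalized. Reruns with the same
#' `base_seed` are byte-identical.
#'
#' @param n_normal,n_nash Number of samples per group (>= 1).
#' @param base_seed Base integer seed; all per-sample/frame/replicate
#'   seeds derive from it.
#' @param out_dir Output directory (created if needed).
#' @param frames_per_sample Frames (independent phantoms) per sample.
#' @param frame_px Frame side length in pixels.
#' @param replicates cIEF replicates per protein per sample.
#' @param panel Protein panel, see [default_protein_panel()].
#' @param lipid_fraction_sd Between-sample SD of the target lipid
#'   fraction.
#' @param isoform_jitter Between-sample log-scale SD of isoform
#'   concentrations.
#' @param noise_sigma Phantom noise level (see [tissue_phantom_spec()]).
#' @return The manifest (list), invisibly; also written to
#'   `<out_dir>/manifest.json`.
#' @export
generate_cohort <- function(n_normal = 9L, n_nash = 9L, base_seed = 0L,
                            out_dir, frames_per_sample = 3L, frame_px = 200L,
                            replicates = 4L, panel = default_protein_panel(),
                            lipid_fraction_sd = 0.02, isoform_jitter = 0.15,
                            noise_sigma = 0.05) {
  if (n_normal < 1L || n_nash < 1L) stop("both group counts must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create output dir '%s'", out_dir))

  groups <- c(rep("normal", n_normal), rep("nash", n_nash))
  samples <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    mode <- groups[i]
    sample_seed <- base_seed + 7919L * i
    sample_id <- sprintf("%s_%02d", toupper(mode), i)
    sdir <- file.path(out_dir, sample_id)
    dir.create(sdir, showWarnings = FALSE)

    set.seed(sample_seed)
    target <- phantom_mode_defaults(mode)$lipid_fraction +
      stats::rnorm(1, sd = lipid_fraction_sd)
    target <- min(max(target, 0.01), 0.9)

    stack_files <- character(frames_per_sample)
    true_fracs <- numeric(frames_per_sample)
    for (j in seq_len(frames_per_sample)) {
      spec <- tissue_phantom_spec(mode, height_px = frame_px,
                                  width_px = frame_px,
                                  target_lipid_fraction = target,
                                  noise_sigma = noise_sigma,
                                  seed = sample_seed + j)
      ph <- generate_phantom(spec)
      stack_files[j] <- file.path(sample_id, sprintf("frame_%02d.tif", j))
      write_stack(ph$stack, file.path(out_dir, stack_files[j]))
      true_fracs[j] <- ph$truth$true_lipid_fraction
    }

    traces <- list()
    for (pn in seq_along(panel)) {
      prot <- names(panel)[pn]
      iso0 <- panel[[prot]][[mode]]
      set.seed(sample_seed + 500L + pn)
      conc <- iso0$concentration *
        exp(stats::rnorm(nrow(iso0), sd = isoform_jitter))
      iso <- iso0
      iso$concentration <- conc / sum(conc)
      files <- character(replicates)
      for (r in seq_len(replicates)) {
        spec <- electropherogram_spec(
          unmodified_pI = panel[[prot]]$nominal_pI, isoforms = iso,
          seed = sample_seed + 500L + pn * 10L + r)
        files[r] <- file.path(sample_id,
                              sprintf("%s_rep%d.csv", prot, r))
        write_trace(generate_electropherogram(spec)$trace,
                    file.path(out_dir, files[r]))
      }
      traces[[prot]] <- list(
        nominal_pI = panel[[prot]]$nominal_pI,
        true_concentration = as.list(
          tapply(iso$concentration, iso$ptm, sum)),
        files = files)
    }

    samples[[i]] <- list(
      sample_id = sample_id, group = mode, mode = mode,
      seed = sample_seed,
      target_lipid_fraction = target,
      true_lipid_fraction_per_frame = true_fracs,
      stacks = stack_files, traces = traces)
  }

  manifest <- list(base_seed = base_seed,
                   n_normal = n_normal, n_nash = n_nash,
                   frames_per_sample = frames_per_sample,
                   frame_px = frame_px, replicates = replicates,
                   samples = samples)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
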