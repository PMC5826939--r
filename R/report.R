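#' Assemble per-sample isoform profiles into a cohort table
#'
#' Rows are protein x isoform, columns are samples (manifest order);
#' cells are relative concentrations, so the cells of one protein in one
#' sample column sum to 1. Proteins are ordered alphabetically and
#' isoforms in the fixed order unmodified, phospho, acetyl, glycosyl, so
#' the table is canonical regardless of input order.
#'
#' @param profiles Nested list: `profiles[[sample_id]][[protein]]` is an
#'   `isoform_profile`.
#' @param sample_ids Sample ordering (manifest order).
#' @param groups Character vector of group labels (`"normal"`/`"nash"`),
#'   one per sample.
#' @return A `cohort_table`: numeric matrix `values` (rows named
#'   `protein:isoform`), `groups`, `proteins`, `isoforms`.
#' @export
build_cohort_table <- function(profiles, sample_ids = names(profiles),
                               groups) {
  if (length(groups) != length(sample_ids))
    stop("`groups` must have one label per sample")
  proteins <- sort(unique(unlist(lapply(profiles, names))))
  iso_order <- c("unmodified", "phospho", "acetyl", "glycosyl")
  for (sid in sample_ids) {
    missing <- setdiff(proteins, names(profiles[[sid]]))
    if (length(missing))
      stop(sprintf("sample '%s' lacks profile(s) for protein(s): %s",
                   sid, paste(missing, collapse = ", ")))
  }
  present <- unique(unlist(lapply(profiles, function(s)
    lapply(names(s), function(p)
      paste(p, names(s[[p]]$relative_concentration), sep = ":")))))
  rows <- unlist(lapply(proteins, function(p)
    paste(p, iso_order[paste(p, iso_order, sep = ":") %in% present],
          sep = ":")))
  values <- matrix(0, length(rows), length(sample_ids),
                   dimnames = list(rows, sample_ids))
  for (sid in sample_ids) for (p in proteins) {
    rc <- profiles[[sid]][[p]]$relative_concentration
    for (iso in names(rc))
      values[paste(p, iso, sep = ":"), sid] <- rc[[iso]]
  }
  structure(list(values = values, groups = groups, proteins = proteins,
                 isoforms = iso_order[iso_order %in%
                   sub("^[^:]+:", "", rows)]),
            class = "cohort_table")
}

#' Differential isoform analysis between NASH and normal groups
#'
#' Per protein x isoform row: group means and SDs, the NASH/normal ratio
#' of means, and a two-tailed paired Student's t-test p-value (pairing by
#' sample index within each group); significance at p <= 0.05. No
#' multiple-testing correction by default (`adjust = "BH"` applies
#' Benjamini-Hochberg to the significance calls). `paired = FALSE` uses
#' Welch's unpaired test instead.
#'
#' @param table A `cohort_table`.
#' @param paired Paired t-test (default TRUE); requires equal group sizes.
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame (`differential_table`): `protein`, `isoform`,
#'   `normal_mean`, `normal_sd`, `nash_mean`, `nash_sd`, `ratio`
#'   (NA + `ratio_undefined` when the normal mean is 0), `t`, `p`
#'   (NA + `p_degenerate` for zero-variance differences), `significant`.
#' @export
differential_analysis <- function(table, paired = TRUE, alpha = 0.05,
                                  adjust = c("none", "BH")) {
  stopifnot(inherits(table, "cohort_table"))
  adjust <- match.arg(adjust)
  is_normal <- table$groups == "normal"
  is_nash <- table$groups == "nash"
  if (!any(is_normal) || !any(is_nash))
    stop("both groups must be non-empty")
  if (paired && sum(is_normal) != sum(is_nash))
    stop("paired analysis requires equal group sizes (pairing by index)")
  rows <- rownames(table$values)
  out <- do.call(rbind, lapply(rows, function(rn) {
    x <- table$values[rn, is_normal]   # normal
    y <- table$values[rn, is_nash]     # nash
    ratio_ok <- mean(x) != 0
    res <- data.frame(
      protein = sub(":.*$", "", rn), isoform = sub("^[^:]+:", "", rn),
      normal_mean = mean(x), normal_sd = stats::sd(x),
      nash_mean = mean(y), nash_sd = stats::sd(y),
      ratio = if (ratio_ok) mean(y) / mean(x) else NA_real_,
      ratio_undefined = !ratio_ok,
      t = NA_real_, p = NA_real_, p_degenerate = FALSE)
    if (paired) {
      d <- y - x
      if (length(d) < 2 || stats::sd(d) == 0) {
        res$p_degenerate <- TRUE; return(res)
      }
      tt <- stats::t.test(y, x, paired = TRUE)
    } else {
      if (length(x) < 2 || length(y) < 2 ||
          (stats::sd(x) == 0 && stats::sd(y) == 0)) {
        res$p_degenerate <- TRUE; return(res)
      }
      tt <- stats::t.test(y, x, var.equal = FALSE)
    }
    res$t <- unname(tt$statistic); res$p <- tt$p.value
    res
  }))
  padj <- if (adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out$significant <- !is.na(padj) & padj <= alpha
  rownames(out) <- rows
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Render cohort heat maps with lossless CSV twins
#'
#' Two heat maps for rapid assessment: per-sample relative concentrations
#' (0-1 scale, green/yellow/red) and the NASH/normal differential
#' (log2 of the ratio of group means, symmetric cyan/blue/red scale;
#' undefined ratios drawn as NA cells). CSV twins carry the exact
#' numbers; figures are written only when a graphics device is usable.
#'
#' @param table A `cohort_table`.
#' @param differential A `differential_table`.
#' @param out_dir Output directory.
#' @return Named list of written file paths, invisibly.
#' @export
render_heatmaps <- function(table, differential, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  conc_csv <- file.path(out_dir, "concentration_matrix.csv")
  utils::write.csv(as.data.frame(table$values), conc_csv, row.names = TRUE)
  diff_csv <- file.path(out_dir, "differential_table.csv")
  utils::write.csv(as.data.frame(differential), diff_csv, row.names = FALSE)

  files <- list(concentration_csv = conc_csv, differential_csv = diff_csv)
  conc_png <- file.path(out_dir, "concentration_heatmap.png")
  ratio_png <- file.path(out_dir, "ratio_heatmap.png")
  ok <- tryCatch({
    grDevices::png(conc_png, width = 1200, height = 800, res = 120)
    pheatmap::pheatmap(
      table$values, cluster_rows = FALSE, cluster_cols = FALSE,
      breaks = seq(0, 1, length.out = 101),
      color = grDevices::colorRampPalette(c("darkgreen", "yellow", "red"))(100),
      main = "Isoform relative concentrations")
    grDevices::dev.off()

    l2 <- log2(differential$ratio)
    l2[!is.finite(l2)] <- NA
    lim <- max(abs(l2), na.rm = TRUE)
    if (!is.finite(lim) || lim == 0) lim <- 1
    m <- matrix(l2, ncol = 1,
                dimnames = list(rownames(differential), "log2 NASH/normal"))
    grDevices::png(ratio_png, width = 500, height = 800, res = 120)
    pheatmap::pheatmap(
      m, cluster_rows = FALSE, cluster_cols = FALSE,
      breaks = seq(-lim, lim, length.out = 101),
      color = grDevices::colorRampPalette(c("cyan", "blue", "red"))(100),
      na_col = "grey85", main = "Differential (log2 ratio)")
    grDevices::dev.off()
    TRUE
  }, error = function(err) { try(grDevices::dev.off(), silent = TRUE); FALSE })
  if (ok) files <- c(files, list(concentration_png = conc_png,
                                 ratio_png = ratio_png))
  invisible(files)
}

#' Full cohort report: imaging plus proteomics
#'
#' Runs the complete analysis over a simulated (or compatible) cohort
#' directory: per-sample phasor segmentation, percentage steatosis and
#' droplet morphometry on every frame; per-sample cIEF quantification of
#' every replicate trace; group comparisons; differential table and heat
#' maps. Results are written as a deterministic JSON report (fixed
#' ordering and full-precision numbers, so reruns are byte-identical).
#'
#' @param manifest Manifest list from [generate_cohort()], or the path of
#'   a `manifest.json`.
#' @param cohort_dir Directory holding the cohort files (defaults to the
#'   manifest's directory when `manifest` is a path).
#' @param out_dir Report output directory.
#' @param gates Phasor gates (default [default_gates()]).
#' @return The report (list), invisibly; written to
#'   `<out_dir>/report.json` alongside the heat maps.
#' @export
full_report <- function(manifest, cohort_dir = NULL, out_dir,
                        gates = default_gates()) {
  if (is.character(manifest)) {
    if (is.null(cohort_dir)) cohort_dir <- dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  }
  if (is.null(cohort_dir))
    stop("`cohort_dir` is required when `manifest` is not a path")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  missing <- unlist(lapply(manifest$samples, function(s)
    Filter(function(f) !file.exists(file.path(cohort_dir, f)),
           c(unlist(s$stacks),
             unlist(lapply(s$traces, function(tr) unlist(tr$files)))))))
  if (length(missing))
    stop(sprintf("cohort is incomplete; missing: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))

  summaries <- list()
  profiles <- list()
  for (s in manifest$samples) {
    frames <- lapply(unlist(s$stacks), function(f) {
      stack <- read_stack(file.path(cohort_dir, f))
      seg <- segment_by_gates(phasor_transform(stack), gates)
      list(composition = percentage_steatosis(seg),
           droplets = detect_droplets(seg, stack$pixel_size))
    })
    summaries[[s$sample_id]] <- summarize_sample(frames, s$sample_id)
    profiles[[s$sample_id]] <- lapply(s$traces, function(tr) {
      reps <- lapply(unlist(tr$files), function(f)
        quantify_cief(read_trace(file.path(cohort_dir, f)),
                      unmodified_pI = tr$nominal_pI))
      # replicate-mean profile, renormalized
      isos <- sort(unique(unlist(lapply(reps, function(p)
        names(p$relative_concentration)))))
      m <- vapply(isos, function(iso) mean(vapply(reps, function(p) {
        rc <- p$relative_concentration
        if (iso %in% names(rc)) unname(rc[[iso]]) else 0
      }, numeric(1))), numeric(1))
      structure(list(protein = NA_character_, peaks = NULL,
                     relative_concentration = m / sum(m)),
                class = "isoform_profile")
    })
  }

  groups <- vapply(manifest$samples, function(s) s$group, "")
  ids <- vapply(manifest$samples, function(s) s$sample_id, "")
  normal <- summaries[ids[groups == "normal"]]
  nash <- summaries[ids[groups == "nash"]]
  comparison <- compare_groups(normal, nash,
                               paired = length(normal) == length(nash))

  table <- build_cohort_table(profiles, ids, groups)
  differential <- differential_analysis(
    table, paired = length(normal) == length(nash))
  figures <- render_heatmaps(table, differential, out_dir)

  report <- list(
    samples = lapply(ids, function(sid) {
      ss <- summaries[[sid]]
      list(sample_id = ss$sample_id, group = groups[ids == sid],
           n_frames = ss$n_frames,
           mean_percent_steatosis = ss$mean_percent_steatosis,
           sd_percent_steatosis = ss$sd_percent_steatosis,
           droplet_count = ss$droplet_count,
           mean_droplet_diameter_um = ss$mean_droplet_diameter_um)
    }),
    group_comparison = unclass(comparison),
    differential = as.data.frame(differential),
    # paths relative to the report directory, so reruns are byte-identical
    files = lapply(figures, basename)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(report)
}
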