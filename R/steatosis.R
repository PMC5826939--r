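#' Percentage steatosis from a segmentation map
#'
#' The lipid SRS signal as a percentage of the combined lipid, DNA and
#' protein SRS signals. Intensity-weighted by default (sums of SRS signal
#' over member pixels, which is proportional to chemical concentration);
#' a pixel-count-weighted variant is available via `weighting`.
#' Unassigned signal is excluded from the denominator.
#'
#' @param seg A `segmentation_map` from [segment_by_gates()].
#' @param weighting `"intensity"` (default) or `"pixel"`.
#' @return A `composition_summary`: `lipid_signal`, `protein_signal`,
#'   `dna_signal`, `percent_steatosis` (in [0, 100]).
#' @examples
#' seg <- structure(list(labels = matrix("lipid", 2, 2),
#'                       class_signal = c(lipid = 30, protein = 60,
#'                                        dna = 10, unassigned = 0)),
#'                  class = "segmentation_map")
#' percentage_steatosis(seg)$percent_steatosis  # 30
#' @export
percentage_steatosis <- function(seg, weighting = c("intensity", "pixel")) {
  stopifnot(inherits(seg, "segmentation_map"))
  weighting <- match.arg(weighting)
  need <- c("lipid", "protein", "dna")
  if (!all(need %in% names(seg$class_signal)))
    stop("segmentation map lacks class signals for lipid/protein/dna")
  if (weighting == "intensity") {
    sig <- seg$class_signal[need]
  } else {
    tab <- table(factor(seg$labels, levels = c(need, "unassigned")))
    sig <- as.numeric(tab[need]); names(sig) <- need
  }
  denom <- sum(sig)
  if (denom <= 0) stop("all class signals are zero: empty tissue")
  structure(
    list(lipid_signal = unname(sig[["lipid"]]),
         protein_signal = unname(sig[["protein"]]),
         dna_signal = unname(sig[["dna"]]),
         percent_steatosis = 100 * unname(sig[["lipid"]]) / denom),
    class = "composition_summary"
  )
}

#' Detect lipid droplets in a segmentation map
#'
#' 8-connected components of the lipid mask with at least `min_area_px`
#' pixels. Each component's equivalent circular diameter is
#' `pixel_size * 2 * sqrt(area / pi)`; droplets below 1 um equivalent
#' diameter are flagged microvesicular (`"micro"`), the rest
#' macrovesicular (`"macro"`). Droplets touching the frame border are
#' kept.
#'
#' @param seg A `segmentation_map`.
#' @param pixel_size Pixel size, um/px.
#' @param min_area_px Minimum component area in pixels (default 1).
#' @return Data frame with one row per droplet: `centroid_row`,
#'   `centroid_col` (px), `area_px`, `equivalent_diameter_um`, `class`.
#' @examples
#' lab <- matrix("protein", 8, 8); lab[3:5, 3:5] <- "lipid"
#' seg <- structure(list(labels = lab, class_signal = c(lipid = 1,
#'   protein = 1, dna = 0, unassigned = 0)), class = "segmentation_map")
#' detect_droplets(seg, pixel_size = 0.5)
#' @export
detect_droplets <- function(seg, pixel_size, min_area_px = 1L) {
  stopifnot(inherits(seg, "segmentation_map"))
  if (pixel_size <= 0) stop("`pixel_size` must be positive (um/px)")
  mask <- seg$labels == "lipid"
  empty <- data.frame(centroid_row = numeric(0), centroid_col = numeric(0),
                      area_px = integer(0), equivalent_diameter_um = numeric(0),
                      class = character(0))
  if (!any(mask)) return(empty)
  comp <- label_components_8(mask)
  tab <- tabulate(comp$labels)
  keep <- which(tab >= min_area_px)
  if (!length(keep)) return(empty)
  rows <- comp$rows; cols <- comp$cols; lab <- comp$labels
  cr <- vapply(split(rows, lab), mean, numeric(1))[as.character(keep)]
  cc <- vapply(split(cols, lab), mean, numeric(1))[as.character(keep)]
  area <- tab[keep]
  diam <- pixel_size * 2 * sqrt(area / pi)
  out <- data.frame(centroid_row = unname(cr), centroid_col = unname(cc),
                    area_px = area, equivalent_diameter_um = diam,
                    class = ifelse(diam < 1, "micro", "macro"))
  out[order(out$centroid_row, out$centroid_col), , drop = FALSE]
}

# 8-connected component labeling of a logical matrix via the pixel
# adjacency graph (edges to E, S, SE, SW neighbors; components found in C
# by igraph). Returns per-foreground-pixel rows, cols, and component ids.
label_components_8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)                      # column-major linear indices
  if (!length(idx)) return(list(rows = integer(0), cols = integer(0),
                                labels = integer(0)))
  pos <- match(seq_len(h * w), idx)       # linear index -> vertex id
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  edge_to <- function(dr, dc) {
    ok <- rows + dr >= 1L & rows + dr <= h & cols + dc >= 1L & cols + dc <= w
    nb <- (cols[ok] + dc - 1L) * h + (rows[ok] + dr)
    v2 <- pos[nb]
    cbind(which(ok)[!is.na(v2)], v2[!is.na(v2)])
  }
  edges <- rbind(edge_to(1L, 0L), edge_to(0L, 1L), edge_to(1L, 1L),
                 edge_to(-1L, 1L))
  if (nrow(edges) == 0L) {
    memb <- seq_along(idx)
  } else {
    g <- igraph::make_graph(edges = as.vector(t(edges)), n = length(idx),
                            directed = FALSE)
    memb <- igraph::components(g)$membership
  }
  list(rows = rows, cols = cols, labels = as.integer(memb))
}

#' Summarize per-frame results for one sample
#'
#' Mean and standard deviation of percentage steatosis across a sample's
#' frames (steatosis error bars are SDs across the stacked hyperspectral
#' images of each liver), with droplet statistics pooled over frames.
#'
#' @param frames List; each element has `composition` (a
#'   `composition_summary`) and `droplets` (a droplet data frame).
#' @param sample_id Sample identifier.
#' @return A `sample_summary`: `sample_id`, `n_frames`,
#'   `mean_percent_steatosis`, `sd_percent_steatosis` (0 for one frame),
#'   `droplet_count`, `mean_droplet_diameter_um` (NA when no droplets).
#' @export
summarize_sample <- function(frames, sample_id) {
  if (!length(frames)) stop("`frames` must contain at least one frame")
  pct <- vapply(frames, function(f) f$composition$percent_steatosis, numeric(1))
  diam <- unlist(lapply(frames, function(f) f$droplets$equivalent_diameter_um))
  structure(
    list(sample_id = as.character(sample_id),
         n_frames = length(frames),
         mean_percent_steatosis = mean(pct),
         sd_percent_steatosis = if (length(pct) > 1) stats::sd(pct) else 0,
         droplet_count = length(diam),
         mean_droplet_diameter_um = if (length(diam)) mean(diam) else NA_real_),
    class = "sample_summary"
  )
}

#' Compare steatosis metrics between normal and NASH groups
#'
#' Paired two-tailed Student's t-tests (pairing by sample index, matching
#' the study's paired design) on percentage steatosis and mean droplet
#' diameter, plus NASH/normal ratios of the group means. Significance is
#' declared at p <= 0.05. An unpaired Welch alternative is available via
#' `paired = FALSE`.
#'
#' @param normal,nash Lists of `sample_summary` objects; equal lengths
#'   when `paired = TRUE`.
#' @param paired Use the paired t-test (default TRUE).
#' @param alpha Significance level (default 0.05).
#' @return A `group_comparison`: for each metric (`percent_steatosis`,
#'   `droplet_diameter`, `droplet_count`) the group means, NASH/normal
#'   ratio, `t`, `p`, `significant`, and `degenerate` (TRUE when the
#'   paired differences have zero variance, in which case t and p are NA).
#' @export
compare_groups <- function(normal, nash, paired = TRUE, alpha = 0.05) {
  if (paired && length(normal) != length(nash))
    stop(paste("paired comparison requires equal group sizes",
               "(samples are paired by index)"))
  if (!length(normal) || !length(nash)) stop("both groups must be non-empty")
  pull <- function(group, field) vapply(group, function(s) s[[field]], numeric(1))
  metric <- function(field) {
    x <- pull(normal, field); y <- pull(nash, field)
    paired_metric(x, y, paired, alpha)
  }
  structure(
    list(percent_steatosis = metric("mean_percent_steatosis"),
         droplet_diameter = metric("mean_droplet_diameter_um"),
         droplet_count = metric("droplet_count"),
         paired = paired, alpha = alpha),
    class = "group_comparison"
  )
}

paired_metric <- function(normal, nash, paired, alpha) {
  out <- list(normal_mean = mean(normal), nash_mean = mean(nash),
              ratio = if (mean(normal) != 0) mean(nash) / mean(normal) else NA_real_,
              t = NA_real_, p = NA_real_, significant = FALSE,
              degenerate = FALSE)
  if (paired) {
    d <- nash - normal
    if (length(d) < 2 || stats::sd(d) == 0) {
      out$degenerate <- TRUE
      return(out)
    }
    tt <- stats::t.test(nash, normal, paired = TRUE)
  } else {
    if (length(normal) < 2 || length(nash) < 2 ||
        (stats::sd(normal) == 0 && stats::sd(nash) == 0)) {
      out$degenerate <- TRUE
      return(out)
    }
    tt <- stats::t.test(nash, normal, var.equal = FALSE)
  }
  out$t <- unname(tt$statistic)
  out$p <- tt$p.value
  out$significant <- tt$p.value <= alpha
  out
}
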