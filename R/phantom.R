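#' Specification of a synthetic liver tissue phantom
#'
#' Describes one frame of synthetic liver tissue for hyperspectral SRS
#' imaging. Two modes emulate the two steatosis phenotypes: `"normal"`
#' livers carry microvesicular steatosis (sub-micrometer lipid droplets),
#' `"nash"` livers carry macrovesicular steatosis (droplets from
#' sub-micrometer up to 50 um). Hepatocyte cytoplasm is protein-class,
#' nuclei are DNA-class discs, droplets are lipid-class discs.
#'
#' `target_lipid_fraction` is the ground-truth share of the total
#' (noiseless) SRS signal carried by lipid pixels; its default is the
#' cohort mean for the mode (0.09 normal, 0.28 NASH).
#'
#' @param mode `"normal"` or `"nash"`; selects the droplet-diameter law
#'   and the default lipid fraction.
#' @param height_px,width_px Frame size in pixels.
#' @param pixel_size Pixel size, um/px.
#' @param target_lipid_fraction Lipid share of total SRS signal, in [0, 1).
#' @param droplet_median,droplet_sigma Log-normal diameter law (median in
#'   um, sigma on the log scale); defaults depend on `mode`.
#' @param droplet_max Truncation diameter, um (<= 50).
#' @param nucleus_density Expected nuclei per 100x100 px tile.
#' @param noise_sigma Additive Gaussian noise SD as a fraction of the mean
#'   noiseless signal.
#' @param seed Integer seed; identical specs give bit-identical phantoms.
#' @return A `tissue_phantom_spec` object.
#' @export
tissue_phantom_spec <- function(mode = c("normal", "nash"),
                                height_px = 200, width_px = 200,
                                pixel_size = 0.5,
                                target_lipid_fraction = NULL,
                                droplet_median = NULL,
                                droplet_sigma = NULL,
                                droplet_max = NULL,
                                nucleus_density = 2,
                                noise_sigma = 0.05,
                                seed = 1L) {
  mode <- match.arg(mode)
  defaults <- phantom_mode_defaults(mode)
  if (is.null(target_lipid_fraction)) target_lipid_fraction <- defaults$lipid_fraction
  if (is.null(droplet_median)) droplet_median <- defaults$droplet_median
  if (is.null(droplet_sigma)) droplet_sigma <- defaults$droplet_sigma
  if (is.null(droplet_max)) droplet_max <- defaults$droplet_max
  if (!is.numeric(target_lipid_fraction) || target_lipid_fraction < 0 ||
      target_lipid_fraction >= 1)
    stop("`target_lipid_fraction` must lie in [0, 1)")
  if (droplet_max > 50) stop("`droplet_max` must be <= 50 um")
  if (pixel_size <= 0) stop("`pixel_size` must be positive (um/px)")
  structure(
    list(mode = mode,
         height_px = as.integer(height_px), width_px = as.integer(width_px),
         pixel_size = pixel_size,
         target_lipid_fraction = target_lipid_fraction,
         droplet_median = droplet_median, droplet_sigma = droplet_sigma,
         droplet_max = droplet_max,
         nucleus_density = nucleus_density,
         noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "tissue_phantom_spec"
  )
}

# Mode-dependent defaults. The droplet-diameter laws realize the two
# steatosis phenotypes: sub-micrometer droplets in normal livers,
# sub-micrometer-to-50-um droplets in NASH livers, with a roughly
# two-fold NASH/normal mean detected diameter. Lipid fractions are the
# cohort means (28% NASH, 9% normal).
phantom_mode_defaults <- function(mode) {
  switch(mode,
    normal = list(lipid_fraction = 0.09, droplet_median = 0.6,
                  droplet_sigma = 0.40, droplet_max = 2),
    nash   = list(lipid_fraction = 0.28, droplet_median = 0.9,
                  droplet_sigma = 0.80, droplet_max = 50)
  )
}

# Relative SRS signal amplitude per class (lipid CH2 is the strongest
# band in tissue); the lipid amplitude is rescaled per phantom so the
# realized lipid signal fraction equals the target exactly.
.class_amplitudes <- c(lipid = 2.0, protein = 1.0, dna = 1.3)

#' Generate a synthetic hyperspectral liver frame with ground truth
#'
#' Builds the label image by placing lipid droplets (discs with diameters
#' drawn from the spec's truncated log-normal law) on a protein-class
#' cytoplasm background, then DNA-class nuclei in lipid-free locations
#' (nuclei are displaced by large droplets, as in macrovesicular
#' steatosis). Droplets are added until the lipid share of total signal
#' reaches the target; the lipid amplitude is then solved analytically so
#' the realized noiseless signal fraction equals `target_lipid_fraction`
#' exactly. Each pixel's noiseless spectrum is its class amplitude times
#' the class reference spectrum; Gaussian noise is added per voxel.
#'
#' @param spec A [tissue_phantom_spec()].
#' @param axis A [spectral_axis()].
#' @param references Reference spectra from [make_reference_spectra()].
#' @param max_droplets Bound on placement iterations before erroring out.
#' @return List with `stack` (a `hyperspectral_stack`: `data` H x W x C
#'   array, `axis`, `pixel_size`) and `truth` (a `phantom_ground_truth`:
#'   `label_image` (character matrix), `droplets` (data.frame of centers
#'   in px and true diameters in um), `true_lipid_fraction`).
#' @examples
#' ph <- generate_phantom(tissue_phantom_spec("nash", seed = 1))
#' ph$truth$true_lipid_fraction
#' @export
generate_phantom <- function(spec, axis = spectral_axis(),
                             references = make_reference_spectra(axis),
                             max_droplets = 100000L) {
  stopifnot(inherits(spec, "tissue_phantom_spec"))
  h <- spec$height_px; w <- spec$width_px
  set.seed(spec$seed)

  ref_mat <- rbind(lipid = references$lipid$values,
                   protein = references$protein$values,
                   dna = references$dna$values)
  channel_sum <- rowSums(ref_mat)        # per-class spectrum integral
  amp <- .class_amplitudes

  label <- matrix("protein", h, w)
  droplets <- place_droplets(spec, label, amp, channel_sum, max_droplets)
  label <- droplets$label
  label <- place_nuclei(spec, label)

  n_class <- c(lipid = sum(label == "lipid"),
               protein = sum(label == "protein"),
               dna = sum(label == "dna"))

  # Solve the lipid amplitude so the realized signal fraction is exact.
  f <- spec$target_lipid_fraction
  if (f > 0) {
    if (n_class[["lipid"]] == 0)
      stop("no lipid pixels placed; target lipid fraction unreachable")
    other <- amp[["protein"]] * channel_sum[["protein"]] * n_class[["protein"]] +
             amp[["dna"]] * channel_sum[["dna"]] * n_class[["dna"]]
    amp[["lipid"]] <- f * other / ((1 - f) * channel_sum[["lipid"]] * n_class[["lipid"]])
  }

  class_idx <- match(label, rownames(ref_mat))
  clean <- amp[class_idx] * ref_mat[class_idx, , drop = FALSE]  # n_px x C
  lipid_signal <- sum(clean[class_idx == 1L, ])
  total_signal <- sum(clean)
  true_fraction <- if (total_signal > 0) lipid_signal / total_signal else 0

  if (spec$noise_sigma > 0) {
    noisy <- clean + stats::rnorm(length(clean), sd = spec$noise_sigma * mean(clean))
  } else noisy <- clean
  stack <- array(noisy, dim = c(h, w, ncol(ref_mat)))

  list(
    stack = hyperspectral_stack(stack, axis, spec$pixel_size),
    truth = structure(
      list(label_image = label,
           droplets = droplets$table,
           true_lipid_fraction = true_fraction),
      class = "phantom_ground_truth")
  )
}

# Sequentially rasterize droplets until the lipid signal share (at the
# default amplitudes) reaches the target. Returns the updated label
# image and the as-drawn droplet table.
place_droplets <- function(spec, label, amp, channel_sum, max_droplets) {
  h <- nrow(label); w <- ncol(label)
  f <- spec$target_lipid_fraction
  tab <- data.frame(center_row = numeric(0), center_col = numeric(0),
                    diameter_um = numeric(0))
  if (f <= 0) return(list(label = label, table = tab))

  n_total <- h * w
  frac_now <- function() {
    n <- c(lipid = sum(label == "lipid"), protein = n_total - sum(label == "lipid"))
    sl <- amp[["lipid"]] * channel_sum[["lipid"]] * n[["lipid"]]
    sl / (sl + amp[["protein"]] * channel_sum[["protein"]] * n[["protein"]])
  }

  k <- 0L
  rows <- cols <- diams <- numeric(0)
  while (frac_now() < f) {
    k <- k + 1L
    if (k > max_droplets)
      stop(sprintf("target lipid fraction %.3g unreachable after %d droplets",
                   f, max_droplets))
    d <- draw_truncated_lognormal(1, spec$droplet_median, spec$droplet_sigma,
                                  spec$droplet_max)
    cr <- stats::runif(1, 0.5, h + 0.5)
    cc <- stats::runif(1, 0.5, w + 0.5)
    label[disc_pixels(cr, cc, d / (2 * spec$pixel_size), h, w)] <- "lipid"
    rows <- c(rows, cr); cols <- c(cols, cc); diams <- c(diams, d)
  }
  list(label = label,
       table = data.frame(center_row = rows, center_col = cols,
                          diameter_um = diams))
}

# DNA-class nuclei discs, rejected from lipid-occupied locations (bounded
# retries per nucleus; a crowded NASH frame simply gets fewer nuclei).
place_nuclei <- function(spec, label) {
  h <- nrow(label); w <- ncol(label)
  n_nuclei <- round(spec$nucleus_density * h * w / 1e4)
  if (n_nuclei < 1) return(label)
  for (i in seq_len(n_nuclei)) {
    for (try in 1:50) {
      d <- min(max(stats::rnorm(1, 8, 1), 5), 11)   # hepatocyte nucleus, um
      cr <- stats::runif(1, 0.5, h + 0.5)
      cc <- stats::runif(1, 0.5, w + 0.5)
      px <- disc_pixels(cr, cc, d / (2 * spec$pixel_size), h, w)
      if (!any(label[px] == "lipid")) { label[px] <- "dna"; break }
    }
  }
  label
}

# Linear indices of pixels whose centers fall within radius_px of
# (center_row, center_col); always at least the nearest in-bounds pixel,
# so sub-pixel droplets are representable.
disc_pixels <- function(center_row, center_col, radius_px, h, w) {
  r0 <- max(1L, floor(center_row - radius_px)); r1 <- min(h, ceiling(center_row + radius_px))
  c0 <- max(1L, floor(center_col - radius_px)); c1 <- min(w, ceiling(center_col + radius_px))
  rr <- r0:r1; cc <- c0:c1
  dist2 <- outer((rr - center_row)^2, (cc - center_col)^2, `+`)
  inside <- which(dist2 <= radius_px^2, arr.ind = TRUE)
  if (nrow(inside) == 0) {
    nr <- min(max(round(center_row), 1L), h)
    nc <- min(max(round(center_col), 1L), w)
    return((nc - 1L) * h + nr)
  }
  (cc[inside[, 2]] - 1L) * h + rr[inside[, 1]]
}

# Log-normal diameters truncated at `maximum` by resampling.
draw_truncated_lognormal <- function(n, median, sigma, maximum) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rlnorm(n - length(out), meanlog = log(median), sdlog = sigma)
    out <- c(out, d[d <= maximum])
  }
  out
}

#' Construct a hyperspectral stack object
#'
#' @param data H x W x C numeric array (C = number of spectral channels).
#' @param axis A [spectral_axis()] with `n_channels` equal to `dim(data)[3]`.
#' @param pixel_size Pixel size, um/px.
#' @return A `hyperspectral_stack` object.
#' @export
hyperspectral_stack <- function(data, axis, pixel_size) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  stopifnot(inherits(axis, "spectral_axis"))
  if (dim(data)[3] != axis$n_channels)
    stop("stack channel count does not match the spectral axis")
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  structure(list(data = data, axis = axis, pixel_size = pixel_size),
            class = "hyperspectral_stack")
}

#' @export
print.hyperspectral_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyperspectral_stack> %d x %d px, %d channels, %g um/px\n",
              d[1], d[2], d[3], x$pixel_size))
  invisible(x)
}
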