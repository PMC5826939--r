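#' Write a hyperspectral stack as a multi-page TIFF with sidecar JSON
#'
#' Page k of the TIFF is spectral channel k (float32). Axis calibration
#' and pixel size go to `<path>.json`.
#'
#' @param stack A `hyperspectral_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "hyperspectral_stack"))
  d <- dim(stack$data)
  # TIFF stores [0, 1] samples; keep the affine intensity calibration in
  # the sidecar so arbitrary-unit SRS intensities round-trip
  lo <- min(stack$data)
  rng <- max(stack$data) - lo
  if (rng == 0) rng <- 1
  pages <- lapply(seq_len(d[3]),
                  function(k) (stack$data[, , k] - lo) / rng)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(start_wavenumber = stack$axis$start_wavenumber,
               step = stack$axis$step,
               n_channels = stack$axis$n_channels,
               pixel_size = stack$pixel_size,
               intensity_offset = lo, intensity_range = rng)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a hyperspectral stack written by [write_stack()]
#'
#' @param path TIFF path; `<path>.json` must exist alongside.
#' @return A `hyperspectral_stack`.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  axis <- spectral_axis(meta$start_wavenumber, meta$step, meta$n_channels)
  data <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  if (!is.null(meta$intensity_range))
    data <- data * meta$intensity_range + meta$intensity_offset
  hyperspectral_stack(data, axis, meta$pixel_size)
}

#' Write / read an electropherogram as a two-column CSV
#'
#' Columns `pI`, `intensity`.
#'
#' @param e An `electropherogram`.
#' @param path CSV path.
#' @return `path` invisibly (write); an `electropherogram` (read).
#' @export
write_trace <- function(e, path) {
  stopifnot(inherits(e, "electropherogram"))
  utils::write.csv(as.data.frame(e)[, c("pI", "intensity")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  electropherogram(df$pI, df$intensity)
}

#' Write / read phasor gates as labeled polygons in JSON
#'
#' @param gates List of `phasor_gate` objects.
#' @param path JSON path.
#' @return `path` invisibly (write); a list of gates (read).
#' @export
write_gates <- function(gates, path) {
  out <- lapply(gates, function(g)
    list(label = g$label,
         polygon = list(g = g$polygon[, 1], s = g$polygon[, 2])))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gates
#' @export
read_gates <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(raw)), function(i)
    phasor_gate(raw$label[i],
                cbind(raw$polygon$g[[i]], raw$polygon$s[[i]])))
}

#' Write a segmentation map as an indexed TIFF plus a class-signal CSV
#'
#' The TIFF stores class indices scaled into [0, 1] gray levels
#' (unassigned 0, then gate classes in `class_order`); the CSV twin
#' carries the labels and summed class signals.
#'
#' @param seg A `segmentation_map`.
#' @param path Output TIFF path; the CSV goes to `<path>.csv`.
#' @param class_order Label order used for the integer encoding.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path,
                               class_order = c("lipid", "protein", "dna")) {
  stopifnot(inherits(seg, "segmentation_map"))
  idx <- match(seg$labels, class_order, nomatch = 0L)
  tiff::writeTIFF(matrix(idx / length(class_order), nrow(seg$labels)),
                  path, bits.per.sample = 8L)
  df <- data.frame(class = names(seg$class_signal),
                   signal = as.numeric(seg$class_signal))
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
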