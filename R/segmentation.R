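#' Phasor-domain gates
#'
#' A gate is a simple polygon in the (g, s) plane; pixels whose phasor
#' coordinates fall inside a gate are assigned that gate's chemical class.
#' Mirrors the manual cluster gating of phasor plots, kept identical
#' across images of a study.
#'
#' @param label Class name (e.g. `"lipid"`).
#' @param polygon Two-column numeric matrix of (g, s) vertices, >= 3 rows,
#'   forming a simple (non-self-intersecting) polygon.
#' @return A `phasor_gate` object.
#' @export
phasor_gate <- function(label, polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("`polygon` must be a >= 3 x 2 matrix of (g, s) vertices")
  if (!all(is.finite(polygon))) stop("gate vertices must be finite")
  if (!is_simple_polygon(polygon))
    stop(sprintf("gate '%s' polygon is self-intersecting", label))
  structure(list(label = as.character(label), polygon = unname(polygon)),
            class = "phasor_gate")
}

#' Automatic gates around reference phasor points
#'
#' Places a regular-hexagon gate (circumradius `radius`) around the phasor
#' point of each reference spectrum. Automates, deterministically, the
#' manual cluster gating of a phasor plot; hand-drawn polygon gates can be
#' used instead via [phasor_gate()] / [read_gates()].
#'
#' @param axis A [spectral_axis()].
#' @param references Reference spectra from [make_reference_spectra()].
#' @param radius Hexagon circumradius in phasor units (default 0.12).
#' @return List of `phasor_gate` objects, one per reference.
#' @examples
#' gates <- default_gates()
#' vapply(gates, function(g) g$label, "")
#' @export
default_gates <- function(axis = spectral_axis(),
                          references = make_reference_spectra(axis),
                          radius = 0.12) {
  centers <- t(vapply(references, function(r) spectrum_phasor(r$values),
                      numeric(2)))
  dmin <- min(stats::dist(centers))
  if (dmin <= 2 * radius)
    stop(sprintf(paste0(
      "reference phasor points are closer (%.3f) than twice the gate ",
      "radius (%.3f); supply manual gates or reduce `radius`"),
      dmin, radius))
  ang <- seq(0, 2 * pi, length.out = 7L)[-7L]
  lapply(seq_along(references), function(i) {
    hexagon <- cbind(centers[i, 1] + radius * cos(ang),
                     centers[i, 2] + radius * sin(ang))
    phasor_gate(references[[i]]$class_label, hexagon)
  })
}

#' Segment a phasor field by gates
#'
#' Assigns each pixel the label of the gate containing its (g, s) point
#' (even-odd rule; boundary points count as inside); pixels outside all
#' gates, and flagged zero-intensity pixels, are `"unassigned"`. Class
#' signals accumulate the per-pixel total SRS intensity, so the class
#' signal sums (plus unassigned) partition the total stack intensity.
#'
#' @param field A `phasor_field` from [phasor_transform()].
#' @param gates List of pairwise-disjoint `phasor_gate` objects.
#' @return A `segmentation_map`: character matrix `labels` and named
#'   numeric `class_signal` (one entry per gate label plus `unassigned`).
#' @export
segment_by_gates <- function(field, gates) {
  stopifnot(inherits(field, "phasor_field"))
  if (!length(gates) || !all(vapply(gates, inherits, TRUE, "phasor_gate")))
    stop("`gates` must be a non-empty list of phasor_gate objects")
  labs <- vapply(gates, function(g) g$label, "")
  if (anyDuplicated(labs)) stop("gate labels must be unique")
  check_gates_disjoint(gates)

  g <- as.vector(field$g); s <- as.vector(field$s)
  label <- rep("unassigned", length(g))
  for (gate in gates) {
    inside <- points_in_polygon(g, s, gate$polygon)
    label[inside & label == "unassigned"] <- gate$label
  }
  label[as.vector(field$flagged)] <- "unassigned"

  total <- as.vector(field$total_intensity)
  class_signal <- vapply(c(labs, "unassigned"),
                         function(l) sum(total[label == l]), numeric(1))
  structure(
    list(labels = matrix(label, nrow(field$g), ncol(field$g)),
         class_signal = class_signal),
    class = "segmentation_map"
  )
}

#' @export
print.segmentation_map <- function(x, ...) {
  tab <- table(x$labels)
  cat("<segmentation_map>\n")
  for (l in names(x$class_signal))
    cat(sprintf("  %-10s %8d px, signal %.4g\n", l,
                if (l %in% names(tab)) tab[[l]] else 0L, x$class_signal[[l]]))
  invisible(x)
}

# Even-odd ray casting, vectorized over points; points on an edge are
# treated as inside (checked explicitly to avoid crossing-parity edge
# cases on boundaries).
points_in_polygon <- function(x, y, polygon) {
  px <- polygon[, 1]; py <- polygon[, 2]
  n <- length(px)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    # collinear and within the segment's bounding box
    d <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    on_edge <- on_edge | (abs(d) < 1e-12 &
                            x >= pmin(xi, xj) - 1e-12 & x <= pmax(xi, xj) + 1e-12 &
                            y >= pmin(yi, yj) - 1e-12 & y <= pmax(yi, yj) + 1e-12)
    j <- i
  }
  inside | on_edge
}

# Disjointness test on a fine grid of each polygon's vertices plus
# pairwise vertex-in-polygon and edge-intersection checks.
check_gates_disjoint <- function(gates) {
  n <- length(gates)
  if (n < 2L) return(invisible(TRUE))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- gates[[i]]$polygon; b <- gates[[j]]$polygon
    if (any(points_in_polygon(a[, 1], a[, 2], b)) ||
        any(points_in_polygon(b[, 1], b[, 2], a)) ||
        polygons_edges_intersect(a, b))
      stop(sprintf("gates '%s' and '%s' overlap; gates must be pairwise disjoint",
                   gates[[i]]$label, gates[[j]]$label))
  }
  invisible(TRUE)
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
     ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

polygons_edges_intersect <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (segments_intersect(a[i, ], a[if (i == na) 1L else i + 1L, ],
                           b[j, ], b[if (j == nb) 1L else j + 1L, ]))
      return(TRUE)
  }
  FALSE
}

is_simple_polygon <- function(p) {
  n <- nrow(p)
  if (n == 3L) return(TRUE)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    # skip shared-vertex edge pairs
    if (abs(i - j) <= 1L || (i == 1L && j == n) || (j == 1L && i == n)) next
    if (segments_intersect(p[i, ], p[if (i == n) 1L else i + 1L, ],
                           p[j, ], p[if (j == n) 1L else j + 1L, ]))
      return(FALSE)
  }
  TRUE
}

#' Mean spectrum of pixels assigned to one class
#'
#' Averages the raw spectra of all pixels carrying `label` in a
#' segmentation map; used to verify that gated clusters have the expected
#' Raman band (e.g. the lipid cluster peaks at 2850 cm^-1).
#'
#' @param stack The `hyperspectral_stack` the segmentation came from.
#' @param seg A `segmentation_map`.
#' @param label Class label to average over.
#' @return Numeric vector of length `n_channels` (NA if no pixel has the
#'   label).
#' @export
class_mean_spectrum <- function(stack, seg, label) {
  stopifnot(inherits(stack, "hyperspectral_stack"),
            inherits(seg, "segmentation_map"))
  d <- dim(stack$data)
  x <- matrix(stack$data, d[1] * d[2], d[3])
  keep <- as.vector(seg$labels == label)
  if (!any(keep)) return(rep(NA_real_, d[3]))
  colMeans(x[keep, , drop = FALSE])
}
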