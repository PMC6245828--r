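#' Measurement configuration
#'
#' Bundles every tunable parameter of the geometry and extraction pipeline.
#' Defaults are sensible for fundus-scale vasculature (vessels tens to
#' hundreds of pixels long, a few pixels wide).
#'
#' @param spacing Arc-length resampling step for derivative curvature, px.
#' @param sigma Gaussian coordinate-smoothing scale for derivative
#'   curvature, px.
#' @param zero_tol Curvature magnitude treated as flat when partitioning,
#'   1/px.
#' @param min_run Minimum constant-sign run length, points.
#' @param p Exponent of the curvature-integral metric (strictly positive
#'   integer).
#' @param chain_k Chain-code curvature neighborhood half-width, points.
#' @param min_points Vessels with fewer traced points are excluded from tree
#'   totals.
#' @param scales Ridge-detection scales, px.
#' @param rho Structure-tensor regularization scale for ridge detection, px.
#' @param threshold Ridge binarization threshold; `NULL` selects Otsu's
#'   threshold on the nonzero responses.
#' @param spur_len Maximum skeleton spur length pruned before tracing, px.
#' @param smooth_window Moving-average window applied to traced centerlines,
#'   points.
#' @return A list of class `retinotort_config`.
#' @export
retinotort_config <- function(spacing = 1, sigma = 2, zero_tol = 1e-4,
                              min_run = 5, p = 1, chain_k = 8,
                              min_points = 10, scales = c(1.5, 2, 3), rho = 1,
                              threshold = NULL, spur_len = 8,
                              smooth_window = 9) {
  if (p < 1 || p != round(p)) stop_invalid("p must be a strictly positive integer")
  structure(list(spacing = spacing, sigma = sigma, zero_tol = zero_tol,
                 min_run = min_run, p = as.integer(p), chain_k = chain_k,
                 min_points = min_points, scales = scales, rho = rho,
                 threshold = threshold, spur_len = spur_len,
                 smooth_window = smooth_window),
            class = "retinotort_config")
}

#' Tortuosity by constant-sign curvature subdivision (tortuosity density)
#'
#' Subdivides the vessel into `n` subsegments of constant-sign curvature and
#' combines their arc-to-chord excesses with the subdivision count:
#' \deqn{\tau = \frac{n-1}{L_c} \sum_{i=1}^{n}
#'   \left[\frac{L_{csi}}{L_{xsi}} - 1\right]}
#' where `L_c` is the vessel arc length and `L_csi`, `L_xsi` are the arc and
#' chord lengths of subsegment `i`. A vessel with a single convexity (n = 1)
#' scores 0. The value has units 1/pixel and scales as `1/s` under uniform
#' scaling by `s`, so it behaves as a tortuosity density.
#'
#' @inheritParams arc_length
#' @inheritParams signed_curvature
#' @inheritParams partition_constant_sign
#' @return Tortuosity density, 1/pixel.
#' @export
grisan_tortuosity <- function(polyline, sigma = 2, spacing = 1,
                              min_run = 5, zero_tol = 1e-4) {
  prof <- signed_curvature(polyline, sigma = sigma, spacing = spacing)
  part <- partition_constant_sign(prof, min_run = min_run, zero_tol = zero_tol)
  if (part$n == 1L) return(0)
  if (any(part$chord_lengths <= .Machine$double.eps^0.5)) {
    stop_degenerate("a constant-sign subsegment has zero chord length")
  }
  lc <- arc_length(prof$points)
  (part$n - 1) / lc * sum(part$arc_lengths / part$chord_lengths - 1)
}

#' Integrated-curvature tortuosity
#'
#' A measure depending only on the skeleton curvature:
#' \deqn{\tau = \left(\sum_j |k(j)|^p\right)^{1/p}}
#' summed over the interior points of the arc-length-resampled vessel
#' (boundary points, whose curvature is not estimable by central
#' differences, are excluded). `p` is a strictly positive integer; `p = 1`
#' accumulates total absolute curvature.
#'
#' @inheritParams grisan_tortuosity
#' @param p Strictly positive integer exponent.
#' @return Non-negative curvature aggregate.
#' @export
trucco_tortuosity <- function(polyline, p = 1, sigma = 2, spacing = 1) {
  if (!is.numeric(p) || p < 1 || p != round(p)) {
    stop_invalid("p must be a strictly positive integer")
  }
  prof <- signed_curvature(polyline, sigma = sigma, spacing = spacing)
  n <- length(prof$values)
  interior <- prof$values[3:(n - 2L)]
  sum(abs(interior)^p)^(1 / p)
}

#' Chain-code tortuosity density
#'
#' Combines the number of sign changes of the chain-code curvature with the
#' accumulated curvature magnitude:
#' \deqn{\tau = \frac{n-1}{n} \cdot \frac{1}{L_c} \sum_i |K(p_i, k)|}
#' where `n` is the number of constant-sign subsegments of the chain-code
#' curvature profile, `L_c` the arc length of the rasterized chain, and the
#' sum runs over all chain points. Magnitudes are summed because signed
#' contributions of opposite-convexity arcs cancel, which would null the
#' measure on balanced S-curves. A vessel with no sign change (n = 1)
#' scores 0. Units 1/pixel.
#'
#' The subsegment count `n` is taken from [partition_constant_sign()] on the
#' chain-code profile with chain-specific defaults: the flatness tolerance
#' `zero_tol` reflects the quantization floor of the 8-direction code after
#' smoothing, and `min_run` scales with the smoothing window `k` so that
#' residual staircase wiggles do not masquerade as inflections.
#'
#' @inheritParams arc_length
#' @inheritParams chain_code_curvature
#' @inheritParams partition_constant_sign
#' @return Tortuosity density, 1/pixel.
#' @export
onkaew_tortuosity <- function(polyline, k = 8, min_run = 2 * k, zero_tol = 0.02) {
  prof <- chain_code_curvature(polyline, k = k)
  part <- partition_constant_sign(prof, min_run = min_run, zero_tol = zero_tol)
  if (part$n == 1L) return(0)
  lc <- arc_length(prof$points)
  (part$n - 1) / part$n * sum(abs(prof$values)) / lc
}

#' Arc-length-weighted integration over a vessel tree
#'
#' Combines per-vessel tortuosity values into a single score for the whole
#' retina using weighted additivity:
#' \deqn{\tau = \frac{\sum_i L_{ci}\,\tau_{ci}}{\sum_i L_{ci}}}
#' The result always lies within the range of the constituent per-vessel
#' values.
#'
#' @param values Per-vessel metric values.
#' @param lengths Per-vessel arc lengths, pixels (all > 0).
#' @return The integrated tortuosity value.
#' @export
integrate_tree <- function(values, lengths) {
  if (length(values) == 0L) stop_empty_tree()
  if (length(values) != length(lengths)) {
    stop_invalid("values and lengths must have the same length")
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop_invalid("all arc lengths must be positive")
  }
  sum(lengths * values) / sum(lengths)
}

#' All four tortuosity metrics for one vessel
#'
#' @inheritParams arc_length
#' @param config A [retinotort_config()].
#' @return A one-row data.frame: `vessel_id`, `length_px`, `hart`, `grisan`,
#'   `trucco`, `onkaew`.
#' @export
vessel_tortuosity <- function(polyline, config = retinotort_config()) {
  polyline <- as_polyline(polyline)
  data.frame(
    vessel_id = polyline$id,
    length_px = arc_length(polyline),
    hart = hart_tortuosity(polyline),
    grisan = grisan_tortuosity(polyline, sigma = config$sigma,
                               spacing = config$spacing,
                               min_run = config$min_run,
                               zero_tol = config$zero_tol),
    trucco = trucco_tortuosity(polyline, p = config$p, sigma = config$sigma,
                               spacing = config$spacing),
    onkaew = onkaew_tortuosity(polyline, k = config$chain_k),
    stringsAsFactors = FALSE)
}

#' Tortuosity of a vessel tree
#'
#' Measures every segment and integrates each metric over the tree with
#' [integrate_tree()]. Segments shorter than `config$min_points` points are
#' excluded from the totals (and reported in the `dropped` element).
#'
#' @param tree A `vessel_tree` or list of [polyline]s.
#' @inheritParams vessel_tortuosity
#' @return A `tree_tortuosity`: list with `per_vessel` (data.frame),
#'   `totals` (named vector, one value per metric), `weights` (per-vessel
#'   arc lengths) and `dropped` (ids of excluded segments).
#' @export
tree_tortuosity <- function(tree, config = retinotort_config()) {
  segments <- if (inherits(tree, "vessel_tree")) tree$segments else tree
  segments <- lapply(segments, as_polyline)
  npts <- vapply(segments, function(p) nrow(p$points), integer(1))
  dropped <- vapply(segments[npts < config$min_points], function(p) p$id, character(1))
  segments <- segments[npts >= config$min_points]
  if (length(segments) == 0L) stop_empty_tree()
  per <- do.call(rbind, lapply(segments, vessel_tortuosity, config = config))
  rownames(per) <- NULL
  metrics <- c("hart", "grisan", "trucco", "onkaew")
  totals <- vapply(metrics, function(m) integrate_tree(per[[m]], per$length_px),
                   numeric(1))
  structure(list(per_vessel = per, totals = totals,
                 weights = stats::setNames(per$length_px, per$vessel_id),
                 dropped = dropped),
            class = "tree_tortuosity")
}

#' @export
print.tree_tortuosity <- function(x, ...) {
  cat(sprintf("<tree_tortuosity: %d vessels (%d dropped)>\n",
              nrow(x$per_vessel), length(x$dropped)))
  cat("totals:\n")
  print(signif(x$totals, 6))
  invisible(x)
}

#' Write a tortuosity report as CSV
#'
#' Per-vessel rows plus one `TOTAL` row holding the integrated values.
#'
#' @param report A `tree_tortuosity`.
#' @param path Output CSV path.
#' @export
write_tortuosity_report <- function(report, path) {
  df <- report$per_vessel
  total <- data.frame(vessel_id = "TOTAL", length_px = sum(df$length_px),
                      hart = report$totals[["hart"]],
                      grisan = report$totals[["grisan"]],
                      trucco = report$totals[["trucco"]],
                      onkaew = report$totals[["onkaew"]],
                      stringsAsFactors = FALSE)
  utils::write.csv(rbind(df, total), path, row.names = FALSE)
  invisible(path)
}
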