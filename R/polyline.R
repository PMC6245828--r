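#' Vessel centerline polylines
#'
#' A `polyline` is an ordered sequence of 2-D points (sub-pixel coordinates
#' allowed) describing one vessel centerline. Coordinates follow the image
#' convention: x grows rightwards, y grows downwards, 0-based pixel indices.
#'
#' @param x Numeric vector of x coordinates, or a two-column matrix/data.frame
#'   of (x, y) points.
#' @param y Numeric vector of y coordinates (ignored when `x` is two-column).
#' @param id Optional vessel identifier (coerced to character).
#' @return An object of class `polyline`: a list with elements `points`
#'   (n x 2 numeric matrix with columns `x`, `y`) and `id`.
#' @examples
#' p <- polyline(c(0, 1, 2), c(0, 1, 0))
#' arc_length(p)
#' chord_length(p)
#' hart_tortuosity(p)
#' @export
polyline <- function(x, y = NULL, id = NULL) {
  if (is.null(y)) {
    pts <- as.matrix(x)
    if (ncol(pts) != 2L) stop_invalid("expected a two-column matrix of (x, y) points")
  } else {
    if (length(x) != length(y)) stop_invalid("x and y must have the same length")
    pts <- cbind(x, y)
  }
  storage.mode(pts) <- "double"
  colnames(pts) <- c("x", "y")
  if (nrow(pts) < 2L) stop_invalid("a polyline needs at least 2 points")
  if (any(!is.finite(pts))) stop_invalid("polyline coordinates must be finite")
  step <- sqrt(rowSums(diff(pts)^2))
  if (any(step == 0)) stop_invalid("consecutive polyline points must be distinct")
  structure(list(points = pts, id = if (is.null(id)) NA_character_ else as.character(id)),
            class = "polyline")
}

#' @export
print.polyline <- function(x, ...) {
  cat(sprintf("<polyline '%s': %d points, arc %.2f px, chord %.2f px>\n",
              x$id, nrow(x$points), arc_length(x), chord_length(x)))
  invisible(x)
}

as_polyline <- function(x, id = NULL) {
  if (inherits(x, "polyline")) return(x)
  polyline(x, id = id)
}

#' Arc length of a polyline
#'
#' Total length along the curve: the sum of Euclidean step lengths between
#' consecutive points (the curve length obtained by following all points of
#' the vessel).
#'
#' @param polyline A [polyline].
#' @return Arc length in pixels (strictly positive).
#' @export
arc_length <- function(polyline) {
  polyline <- as_polyline(polyline)
  sum(sqrt(rowSums(diff(polyline$points)^2)))
}

#' Chord length of a polyline
#'
#' Euclidean distance between the two end points of the vessel.
#'
#' @inheritParams arc_length
#' @return Chord length in pixels (zero for a closed curve).
#' @export
chord_length <- function(polyline) {
  polyline <- as_polyline(polyline)
  pts <- polyline$points
  sqrt(sum((pts[nrow(pts), ] - pts[1L, ])^2))
}

#' Arc-to-chord tortuosity (distance metric)
#'
#' The classical distance-based tortuosity: how long the curve is relative to
#' its chord, `L_c / L_x - 1`. Dimensionless, zero for a straight vessel, and
#' invariant under rotation, translation and uniform scaling.
#'
#' @inheritParams arc_length
#' @return Non-negative dimensionless tortuosity.
#' @export
hart_tortuosity <- function(polyline) {
  polyline <- as_polyline(polyline)
  lx <- chord_length(polyline)
  if (lx <= .Machine$double.eps^0.5) {
    stop_degenerate("zero chord length (closed curve): arc-to-chord tortuosity undefined")
  }
  arc_length(polyline) / lx - 1
}

#' Resample a polyline to uniform arc-length spacing
#'
#' Linear interpolation of the coordinates against cumulative arc length.
#' The first and last points of the input are always retained.
#'
#' @inheritParams arc_length
#' @param spacing Target spacing between consecutive samples, pixels.
#' @return A [polyline] with (approximately) uniform step length.
#' @export
resample_polyline <- function(polyline, spacing = 1) {
  polyline <- as_polyline(polyline)
  if (!is.numeric(spacing) || spacing <= 0) stop_invalid("spacing must be positive")
  pts <- polyline$points
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  total <- s[length(s)]
  targets <- seq(0, total, by = spacing)
  if (total - targets[length(targets)] > 1e-9 * max(total, 1)) targets <- c(targets, total)
  if (length(targets) < 2L) targets <- c(0, total)
  xi <- stats::approx(s, pts[, 1L], xout = targets, ties = "ordered")$y
  yi <- stats::approx(s, pts[, 2L], xout = targets, ties = "ordered")$y
  keep <- c(TRUE, sqrt(diff(xi)^2 + diff(yi)^2) > 1e-12)
  polyline(xi[keep], yi[keep], id = polyline$id)
}

#' Locally smooth a polyline
#'
#' Centered moving average of the coordinates, used to attenuate the discrete
#' staircase effect of the pixel representation. Endpoints are preserved
#' exactly; near the ends the window shrinks symmetrically so the filter
#' passes straight uniformly-sampled lines unchanged.
#'
#' @inheritParams arc_length
#' @param window Odd window width in points (>= 1). `window = 1` is the
#'   identity.
#' @return A smoothed [polyline].
#' @export
smooth_polyline <- function(polyline, window = 5) {
  polyline <- as_polyline(polyline)
  if (!is.numeric(window) || window < 1) stop_invalid("window must be >= 1")
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  pts <- polyline$points
  n <- nrow(pts)
  if (n < window) stop_invalid("polyline has fewer points than the smoothing window")
  if (window == 1L) return(polyline)
  h <- (window - 1L) %/% 2L
  out <- pts
  for (d in 1:2) {
    cs <- c(0, cumsum(pts[, d]))
    j <- seq_len(n)
    half <- pmin(h, j - 1L, n - j)
    out[, d] <- (cs[j + half + 1L] - cs[j - half]) / (2 * half + 1)
  }
  # moving average can collapse consecutive points on degenerate zigzags
  keep <- c(TRUE, sqrt(rowSums(diff(out)^2)) > 1e-12)
  polyline(out[keep, , drop = FALSE], id = polyline$id)
}

#' Read and write centerline tables
#'
#' Centerlines are exchanged as long tables with columns `vessel_id`,
#' `point_index`, `x`, `y` (CSV with header, or JSON holding the same
#' records).
#'
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @return `read_centerlines()` returns a list of [polyline]s;
#'   `write_centerlines()` returns `path` invisibly.
#' @export
read_centerlines <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  req <- c("vessel_id", "point_index", "x", "y")
  if (!all(req %in% names(df))) {
    stop_invalid(paste("centerline table must have columns:", paste(req, collapse = ", ")))
  }
  out <- lapply(split(df, df$vessel_id), function(d) {
    d <- d[order(d$point_index), , drop = FALSE]
    polyline(d$x, d$y, id = d$vessel_id[1L])
  })
  out[order(names(out))]
}

#' @rdname read_centerlines
#' @param segments A list of [polyline]s (or a `vessel_tree`).
#' @export
write_centerlines <- function(segments, path) {
  if (inherits(segments, "vessel_tree")) segments <- segments$segments
  rows <- lapply(segments, function(p) {
    p <- as_polyline(p)
    data.frame(vessel_id = p$id, point_index = seq_len(nrow(p$points)) - 1L,
               x = p$points[, 1L], y = p$points[, 2L])
  })
  df <- do.call(rbind, rows)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
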