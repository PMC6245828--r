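#' Signed curvature along a centerline
#'
#' Estimates the signed curvature
#' \deqn{k(j) = \frac{x'(j)\,y''(j) - x''(j)\,y'(j)}{[x'(j)^2 + y'(j)^2]^{3/2}}}
#' at each point of the vessel, i.e. the rate of change of the tangent
#' direction. The polyline is first resampled to uniform arc-length spacing,
#' its coordinates are low-pass filtered with a Gaussian of standard
#' deviation `sigma` (reflective padding, so straight lines stay exactly
#' straight), and the derivatives are taken by central finite differences.
#' The first and last two samples are assigned curvature 0 and treated as
#' boundary points by downstream sums.
#'
#' @inheritParams arc_length
#' @param sigma Gaussian smoothing scale for the coordinates, pixels.
#' @param spacing Arc-length resampling step, pixels.
#' @return A `curvature_profile`: list with `values` (signed curvature,
#'   1/pixel, one per resampled point), `points` (the smoothed resampled
#'   [polyline] the values refer to), `method = "derivative"`, `window`
#'   (sigma) and `spacing`.
#' @export
signed_curvature <- function(polyline, sigma = 2, spacing = 1) {
  polyline <- as_polyline(polyline)
  if (!is.numeric(sigma) || sigma < 0) stop_invalid("sigma must be non-negative")
  rp <- resample_polyline(polyline, spacing)
  pts <- rp$points
  n <- nrow(pts)
  if (n < 5L) stop_invalid("need at least 5 points after resampling to estimate curvature")
  if (sigma > 0) pts <- gauss_smooth_coords(pts, sigma / spacing)
  h <- spacing
  idx <- 2:(n - 1L)
  d1 <- (pts[idx + 1L, , drop = FALSE] - pts[idx - 1L, , drop = FALSE]) / (2 * h)
  d2 <- (pts[idx + 1L, , drop = FALSE] - 2 * pts[idx, , drop = FALSE] +
           pts[idx - 1L, , drop = FALSE]) / h^2
  num <- d1[, 1L] * d2[, 2L] - d2[, 1L] * d1[, 2L]
  den <- (d1[, 1L]^2 + d1[, 2L]^2)^1.5
  k <- numeric(n)
  k[idx] <- ifelse(den > 0, num / den, 0)
  k[c(1L, 2L, n - 1L, n)] <- 0
  sm <- polyline(pts, id = rp$id)
  structure(list(values = k, points = sm, method = "derivative",
                 window = sigma, spacing = spacing),
            class = "curvature_profile")
}

# Gaussian filter of the coordinate columns with point-reflection padding
# (the curve is extrapolated linearly through each endpoint), so that the
# filter is exact on straight lines and does not drag endpoints inwards.
gauss_smooth_coords <- function(pts, sigma_samples) {
  if (sigma_samples <= 0) return(pts)
  r <- max(1L, ceiling(3 * sigma_samples))
  w <- stats::dnorm(seq(-r, r), sd = sigma_samples)
  w <- w / sum(w)
  n <- nrow(pts)
  r <- min(r, n - 1L)
  w <- stats::dnorm(seq(-r, r), sd = sigma_samples)
  w <- w / sum(w)
  out <- pts
  for (d in 1:2) {
    v <- pts[, d]
    head_pad <- 2 * v[1L] - v[(r + 1L):2L]
    tail_pad <- 2 * v[n] - v[(n - 1L):(n - r)]
    vp <- c(head_pad, v, tail_pad)
    out[, d] <- as.numeric(stats::filter(vp, w, sides = 2))[(r + 1L):(r + n)]
  }
  out
}

#' Chain-code curvature along a centerline
#'
#' Discrete curvature without differentiation: the polyline is rasterized to
#' an 8-connected pixel chain and each step is labelled by its direction
#' code (the 8 neighbourhood directions, multiples of 45 degrees,
#' counter-clockwise from east). The code angles are unwrapped to a
#' continuous direction sequence, low-pass filtered with two passes of a
#' width-`k` moving average (a triangular kernel, which exactly cancels the
#' alternating one-code staircase oscillation of rasterized oblique lines
#' when `k` is even), and the curvature at a point is the per-step change of
#' the smoothed direction, in radians per point. `k = 1` applies no
#' smoothing, so a right-angle corner scores exactly pi/2 at the corner
#' pixel. Straight 8-connected runs score exactly zero; the two chain
#' endpoints are assigned 0.
#'
#' @inheritParams arc_length
#' @param k Smoothing window in points (>= 1).
#' @return A `curvature_profile` with `method = "chain_code"`; its `points`
#'   element is the rasterized integer chain.
#' @export
chain_code_curvature <- function(polyline, k = 8) {
  polyline <- as_polyline(polyline)
  if (!is.numeric(k) || k < 1 || k != round(k)) stop_invalid("k must be a positive integer")
  k <- as.integer(k)
  chain <- rasterize_polyline(polyline$points)
  m <- nrow(chain)
  if (m < 3L) stop_invalid("rasterized chain too short for curvature estimation")
  if (k > m / 2) stop_invalid("k exceeds half the chain length")
  ang <- atan2(diff(chain[, 2L]), diff(chain[, 1L]))  # m - 1 step angles
  turn <- diff(ang)
  turn <- ((turn + pi) %% (2 * pi)) - pi               # wrap to (-pi, pi]
  turn[turn == -pi] <- pi
  a_u <- ang[1L] + c(0, cumsum(turn))                  # unwrapped code angles
  a_s <- boxcar(boxcar(a_u, k), k)
  vals <- numeric(m)
  vals[2:(m - 1L)] <- diff(a_s)[1:(m - 2L)]
  structure(list(values = vals, points = polyline(chain, id = polyline$id),
                 method = "chain_code", window = k, spacing = NA_real_),
            class = "curvature_profile")
}

# centered moving average of width w (window truncated at the ends)
boxcar <- function(v, w) {
  if (w <= 1) return(v)
  n <- length(v)
  cs <- c(0, cumsum(v))
  j <- seq_len(n)
  h <- (w - 1) / 2
  lo <- pmax(ceiling(j - h), 1L)
  hi <- pmin(floor(j + h), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Round the polyline to the pixel grid and join consecutive pixels with
# Bresenham segments, yielding an ordered 8-connected chain without
# consecutive duplicates.
rasterize_polyline <- function(pts) {
  rp <- round(pts)
  keep <- c(TRUE, rowSums(abs(diff(rp))) > 0)
  rp <- rp[keep, , drop = FALSE]
  if (nrow(rp) < 2L) stop_invalid("polyline collapses to a single pixel")
  out_x <- integer(0)
  out_y <- integer(0)
  for (i in seq_len(nrow(rp) - 1L)) {
    seg <- bresenham(rp[i, 1L], rp[i, 2L], rp[i + 1L, 1L], rp[i + 1L, 2L])
    if (i > 1L) seg <- seg[-1L, , drop = FALSE]
    out_x <- c(out_x, seg[, 1L])
    out_y <- c(out_y, seg[, 2L])
  }
  cbind(x = out_x, y = out_y)
}

bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- sign(x1 - x0); sy <- sign(y1 - y0)
  n <- max(dx, dy) + 1L
  xs <- integer(n); ys <- integer(n)
  err <- dx - dy
  x <- x0; y <- y0
  for (i in seq_len(n)) {
    xs[i] <- x; ys[i] <- y
    if (x == x1 && y == y1) { xs <- xs[1:i]; ys <- ys[1:i]; break }
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx)  { err <- err + dx; y <- y + sy }
  }
  cbind(xs, ys)
}

#' Partition a curvature profile into constant-sign subsegments
#'
#' Splits the vessel into maximal runs over which the signed curvature does
#' not change sign. Near-zero values (|k| < `zero_tol`) inherit the sign of
#' the current run; an all-zero vessel is a single subsegment. Runs shorter
#' than `min_run` points are merged into their longer neighbour to suppress
#' noise-driven inflections.
#'
#' @param profile A `curvature_profile` from [signed_curvature()] or
#'   [chain_code_curvature()].
#' @param min_run Minimum run length in points before merging.
#' @param zero_tol Curvature magnitude below which a point counts as flat,
#'   1/pixel.
#' @return A `subsegment_partition`: list with `ranges` (two-column matrix of
#'   start/end indices, contiguous and covering the profile), `n` (number of
#'   subsegments), `arc_lengths` (`L_csi`) and `chord_lengths` (`L_xsi`) in
#'   pixels, and `signs`.
#' @export
partition_constant_sign <- function(profile, min_run = 5, zero_tol = 1e-4) {
  if (!inherits(profile, "curvature_profile")) stop_invalid("expected a curvature_profile")
  if (min_run < 1) stop_invalid("min_run must be >= 1")
  k <- profile$values
  n_pts <- length(k)
  s <- sign(k)
  s[abs(k) < zero_tol] <- 0
  # collapse to signed runs, zeros absorbed into the running sign
  cur <- 0
  run_sign <- integer(0)
  run_len <- integer(0)
  for (j in seq_len(n_pts)) {
    sj <- s[j]
    if (sj != 0 && sj != cur) {
      if (cur == 0 && length(run_len) > 0L) {
        # leading flat stretch joins the first signed run
        run_sign[length(run_sign)] <- sj
        cur <- sj
        run_len[length(run_len)] <- run_len[length(run_len)] + 1L
        next
      }
      run_sign <- c(run_sign, sj)
      run_len <- c(run_len, 1L)
      cur <- sj
    } else {
      if (length(run_len) == 0L) {
        run_sign <- 0L
        run_len <- 0L
      }
      run_len[length(run_len)] <- run_len[length(run_len)] + 1L
    }
  }
  # merge short runs into the longer neighbour until stable
  while (length(run_len) > 1L && any(run_len < min_run)) {
    i <- which.min(run_len)
    if (i == 1L) j <- 2L
    else if (i == length(run_len)) j <- i - 1L
    else j <- if (run_len[i - 1L] >= run_len[i + 1L]) i - 1L else i + 1L
    run_len[j] <- run_len[j] + run_len[i]
    run_len <- run_len[-i]
    run_sign <- run_sign[-i]
  }
  ends <- cumsum(run_len)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  pts <- profile$points$points
  arcs <- numeric(length(starts))
  chords <- numeric(length(starts))
  for (i in seq_along(starts)) {
    rng <- starts[i]:ends[i]
    sub <- pts[rng, , drop = FALSE]
    arcs[i] <- if (nrow(sub) > 1L) sum(sqrt(rowSums(diff(sub)^2))) else 0
    chords[i] <- sqrt(sum((sub[nrow(sub), ] - sub[1L, ])^2))
  }
  structure(list(ranges = cbind(start = starts, end = ends),
                 n = length(starts), signs = run_sign,
                 arc_lengths = arcs, chord_lengths = chords),
            class = "subsegment_partition")
}
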