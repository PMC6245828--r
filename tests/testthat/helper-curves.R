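# Curve constructors and independent brute-force oracles used across tests.

semicircle_polyline <- function(r = 1, n = 2000) {
  th <- seq(-pi / 2, pi / 2, length.out = n)
  polyline(r * sin(th), r * (1 - cos(th)))
}

circle_polyline <- function(r = 1, n = 500, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  polyline(center[1] + r * cos(th), center[2] + r * sin(th))
}

# two semicircles of radius r joined with a continuous tangent (one inflection)
s_curve_polyline <- function(r = 40, n_half = 900) {
  t1 <- seq(0, pi, length.out = n_half)
  t2 <- t1[-1]
  polyline(c(r * sin(t1), -r * sin(t2)),
           c(r * (1 - cos(t1)), 2 * r + r * (1 - cos(t2))))
}

sinusoid_polyline <- function(length = 200, amplitude = 15, half_waves = 2,
                              n = 400) {
  make_vessel(vessel_spec("sinusoid", length = length, amplitude = amplitude,
                          half_waves = half_waves, n_points = n))
}

rigid_motion <- function(pl, angle = 0, shift = c(0, 0)) {
  p <- pl$points
  ca <- cos(angle); sa <- sin(angle)
  polyline(ca * p[, 1] - sa * p[, 2] + shift[1],
           sa * p[, 1] + ca * p[, 2] + shift[2], id = pl$id)
}

reverse_polyline <- function(pl) {
  p <- pl$points
  polyline(rev(p[, 1]), rev(p[, 2]), id = pl$id)
}

# mean distance from each point of `seg` to the densely sampled curve `gt`
mean_dev_to_truth <- function(seg, gt, spacing = 0.25) {
  g <- resample_polyline(gt, spacing)$points
  d2 <- outer(seg$points[, 1], g[, 1], "-")^2 +
        outer(seg$points[, 2], g[, 2], "-")^2
  mean(sqrt(apply(d2, 1, min)))
}

# brute-force Cohen kappa from an explicitly built confusion matrix
kappa_from_confusion <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  cm <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(a)) {
    cm[as.character(a[i]), as.character(b[i])] <- cm[as.character(a[i]), as.character(b[i])] + 1
  }
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum((rowSums(cm) / n) * (colSums(cm) / n))
  (po - pe) / (1 - pe)
}

# naive, loop-based re-derivation of the chain-code tortuosity: same
# definition as the package (rounding + Bresenham chain, unwrapped angles,
# double moving average of width k, per-step difference, sign partition with
# zero tolerance and shortest-run merging), coded with explicit loops.
naive_onkaew <- function(pl, k = 8, min_run = 2 * k, zero_tol = 0.02) {
  rp <- round(pl$points)
  keep <- c(TRUE, rowSums(abs(diff(rp))) > 0)
  rp <- rp[keep, , drop = FALSE]
  pts <- rp[1, , drop = FALSE]
  for (i in seq_len(nrow(rp) - 1)) {
    x0 <- rp[i, 1]; y0 <- rp[i, 2]; x1 <- rp[i + 1, 1]; y1 <- rp[i + 1, 2]
    dx <- abs(x1 - x0); dy <- abs(y1 - y0)
    sx <- sign(x1 - x0); sy <- sign(y1 - y0); err <- dx - dy
    x <- x0; y <- y0
    while (!(x == x1 && y == y1)) {
      e2 <- 2 * err
      if (e2 > -dy) { err <- err - dy; x <- x + sx }
      if (e2 < dx)  { err <- err + dx; y <- y + sy }
      pts <- rbind(pts, c(x, y))
    }
  }
  m <- nrow(pts)
  ang <- numeric(m - 1)
  for (i in seq_len(m - 1)) ang[i] <- atan2(pts[i + 1, 2] - pts[i, 2], pts[i + 1, 1] - pts[i, 1])
  au <- numeric(m - 1); au[1] <- ang[1]
  for (i in 2:(m - 1)) {
    d <- ang[i] - ang[i - 1]
    while (d <= -pi) d <- d + 2 * pi
    while (d > pi) d <- d - 2 * pi
    au[i] <- au[i - 1] + d
  }
  box1 <- function(v, w) {
    n <- length(v); out <- numeric(n); h <- (w - 1) / 2
    for (j in seq_len(n)) {
      lo <- max(ceiling(j - h), 1); hi <- min(floor(j + h), n)
      out[j] <- mean(v[lo:hi])
    }
    out
  }
  as <- box1(box1(au, k), k)
  K <- numeric(m)
  for (i in 2:(m - 1)) K[i] <- as[i] - as[i - 1]
  # sign partition with zero absorption and shortest-run merging
  s <- sign(K); s[abs(K) < zero_tol] <- 0
  runs_sign <- c(); runs_len <- c(); cur <- 0
  for (j in seq_len(m)) {
    if (s[j] != 0 && s[j] != cur) {
      if (cur == 0 && length(runs_len) > 0) {
        runs_sign[length(runs_sign)] <- s[j]
        runs_len[length(runs_len)] <- runs_len[length(runs_len)] + 1
        cur <- s[j]
      } else {
        runs_sign <- c(runs_sign, s[j]); runs_len <- c(runs_len, 1); cur <- s[j]
      }
    } else {
      if (length(runs_len) == 0) { runs_sign <- 0; runs_len <- 0 }
      runs_len[length(runs_len)] <- runs_len[length(runs_len)] + 1
    }
  }
  while (length(runs_len) > 1 && any(runs_len < min_run)) {
    i <- which.min(runs_len)
    j <- if (i == 1) 2 else if (i == length(runs_len)) i - 1 else {
      if (runs_len[i - 1] >= runs_len[i + 1]) i - 1 else i + 1
    }
    runs_len[j] <- runs_len[j] + runs_len[i]
    runs_len <- runs_len[-i]; runs_sign <- runs_sign[-i]
  }
  n_seg <- length(runs_len)
  if (n_seg == 1) return(0)
  lc <- 0
  for (i in seq_len(m - 1)) lc <- lc + sqrt(sum((pts[i + 1, ] - pts[i, ])^2))
  (n_seg - 1) / n_seg * sum(abs(K)) / lc
}
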