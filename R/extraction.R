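#' Read a fundus-style image
#'
#' Reads PNG (or TIFF when the tiff package is available) into a numeric
#' intensity matrix in [0, 1], rows indexing y (downwards) and columns x.
#' RGB images are reduced to the green channel, where vessel contrast is
#' highest in fundus photography.
#'
#' @param path Image file path.
#' @return Numeric matrix of intensities.
#' @export
read_fundus <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop_invalid("reading TIFF requires the 'tiff' package")
    }
    img <- tiff::readTIFF(path)
  } else {
    img <- png::readPNG(path)
  }
  as_intensity(img)
}

as_intensity <- function(img) {
  if (length(dim(img)) == 3L) img <- img[, , 2L]  # green channel
  img <- as.matrix(img)
  if (any(!is.finite(img))) stop_invalid("image intensities must be finite")
  if (nrow(img) < 32L || ncol(img) < 32L) stop_invalid("image must be at least 32x32")
  img
}

# ---- low-level raster helpers -------------------------------------------

# shift a matrix by (dy, dx), replicating the border
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dx, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# separable Gaussian blur with replicated borders
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  w <- w / sum(w)
  out <- matrix(0, nrow(m), ncol(m))
  for (t in seq(-r, r)) out <- out + w[t + r + 1L] * shift_mat(m, t, 0L)
  m2 <- matrix(0, nrow(m), ncol(m))
  for (t in seq(-r, r)) m2 <- m2 + w[t + r + 1L] * shift_mat(out, 0L, t)
  m2
}

# Otsu's threshold on the given values, 256-bin histogram
otsu_threshold <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0L || diff(range(v)) == 0) return(Inf)
  nb <- 256L
  br <- seq(min(v), max(v), length.out = nb + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1L] + br[-(nb + 1L)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Multiscale ridge detection
#'
#' Detects dark tubular structures (vessels) as intensity valleys using a
#' multiscale, structure-tensor-regularized second-order operator. At each
#' scale the image is Gaussian-smoothed, the Hessian is estimated by finite
#' differences and its entries are regularized with a Gaussian of scale
#' `rho` before eigen-analysis; the valley response is the positive part of
#' the largest Hessian eigenvalue, scale-normalized by sigma^2. The final
#' map is the pointwise maximum over scales. Constant images yield an
#' all-zero map.
#'
#' @param image Numeric intensity matrix (see [read_fundus()]), or an array
#'   whose green channel is used.
#' @param scales Detection scales (Gaussian sigmas), pixels.
#' @param rho Tensor regularization scale, pixels.
#' @return A `ridge_map`: list with `strength` (matrix >= 0) and `scales`.
#' @export
detect_ridges <- function(image, scales = c(2, 3, 4), rho = 1) {
  img <- as_intensity(image)
  best <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    g <- gauss_blur(img, s)
    # central-difference Hessian of the smoothed image
    gx  <- (shift_mat(g, 0L, -1L) - shift_mat(g, 0L, 1L)) / 2
    gy  <- (shift_mat(g, -1L, 0L) - shift_mat(g, 1L, 0L)) / 2
    hxx <- shift_mat(g, 0L, -1L) - 2 * g + shift_mat(g, 0L, 1L)
    hyy <- shift_mat(g, -1L, 0L) - 2 * g + shift_mat(g, 1L, 0L)
    hxy <- (shift_mat(gx, -1L, 0L) - shift_mat(gx, 1L, 0L)) / 2
    if (rho > 0) {
      hxx <- gauss_blur(hxx, rho); hyy <- gauss_blur(hyy, rho)
      hxy <- gauss_blur(hxy, rho)
    }
    tr <- hxx + hyy
    disc <- sqrt(pmax((hxx - hyy)^2 + 4 * hxy^2, 0))
    lam_max <- (tr + disc) / 2      # > 0 across a dark (valley) vessel
    resp <- s^2 * pmax(lam_max, 0)
    best <- pmax(best, resp)
  }
  structure(list(strength = best, scales = scales), class = "ridge_map")
}

#' Binarize a ridge map and thin it to a 1-px skeleton
#'
#' Thresholds the ridge response (Otsu's threshold on the nonzero responses
#' when `threshold` is `NULL`) and applies topology-preserving thinning
#' until every centerline is at most one pixel wide (no 2x2 block of
#' skeleton pixels remains).
#'
#' @param ridges A `ridge_map` from [detect_ridges()], or a numeric matrix.
#' @param threshold Binarization threshold (>= 0), or `NULL` for Otsu.
#' @return A `skeleton`: list with logical matrix `mask`.
#' @export
binarize_and_skeletonize <- function(ridges, threshold = NULL) {
  strength <- if (inherits(ridges, "ridge_map")) ridges$strength else as.matrix(ridges)
  if (is.null(threshold)) {
    nz <- strength[strength > 0]
    threshold <- if (length(nz) == 0L) Inf else otsu_threshold(nz)
  }
  if (threshold < 0) stop_invalid("threshold must be >= 0")
  mask <- strength > threshold
  mask[is.na(mask)] <- FALSE
  structure(list(mask = thin_mask(mask)), class = "skeleton")
}

# Zhang-Suen thinning, vectorized over the whole mask, followed by removal
# of any residual 2x2 blocks via simple-point deletion.
thin_mask <- function(mask) {
  m <- mask
  storage.mode(m) <- "integer"
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9: N, NE, E, SE, S, SW, W, NW
      p2 <- shift_mat(m, -1L,  0L); p3 <- shift_mat(m, -1L,  1L)
      p4 <- shift_mat(m,  0L,  1L); p5 <- shift_mat(m,  1L,  1L)
      p6 <- shift_mat(m,  1L,  0L); p7 <- shift_mat(m,  1L, -1L)
      p8 <- shift_mat(m,  0L, -1L); p9 <- shift_mat(m, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (step == 1L) {
        cond <- m == 1L & b >= 2L & b <= 6L & a == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- m == 1L & b >= 2L & b <= 6L & a == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m <- remove_2x2(m)
  m == 1L
}

# delete simple pixels participating in 2x2 all-on blocks
remove_2x2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    blk <- m[-nr, -nc] & m[-1L, -nc] & m[-nr, -1L] & m[-1L, -1L]
    idx <- which(blk, arr.ind = TRUE)
    if (nrow(idx) == 0L) break
    removed_any <- FALSE
    for (r in seq_len(nrow(idx))) {
      cand <- rbind(idx[r, ], idx[r, ] + c(1L, 0L), idx[r, ] + c(0L, 1L), idx[r, ] + c(1L, 1L))
      for (q in seq_len(4L)) {
        i <- cand[q, 1L]; j <- cand[q, 2L]
        if (m[i, j] == 1L && is_simple_pixel(m, i, j)) {
          m[i, j] <- 0L
          removed_any <- TRUE
          break
        }
      }
    }
    if (!removed_any) break  # all candidates essential; give up (pathological)
  }
  m
}

# connectivity-preserving deletability: the 8-neighbourhood minus the pixel
# stays a single 8-connected set and the pixel is not an isolated endpoint
is_simple_pixel <- function(m, i, j) {
  nr <- nrow(m); nc <- ncol(m)
  nb <- matrix(0L, 3L, 3L)
  ri <- (i - 1L):(i + 1L); ci <- (j - 1L):(j + 1L)
  ok_r <- ri >= 1L & ri <= nr; ok_c <- ci >= 1L & ci <= nc
  nb[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
  nb[2L, 2L] <- 0L
  on <- which(nb == 1L)
  if (length(on) <= 1L) return(FALSE)
  # count connected components among neighbours (8-connectivity in 3x3 ring)
  coords <- arrayInd(on, c(3L, 3L))
  seen <- logical(length(on))
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue) > 0L) {
    cur <- queue[1L]; queue <- queue[-1L]
    d <- abs(coords[, 1L] - coords[cur, 1L]) <= 1L &
         abs(coords[, 2L] - coords[cur, 2L]) <= 1L
    newly <- which(d & !seen)
    seen[newly] <- TRUE
    queue <- c(queue, newly)
  }
  all(seen)
}

# transition count (crossing number): number of 0->1 transitions in the
# circular 8-neighbour sequence; 1 at endpoints, 2 on path pixels, >= 3 at
# branch points. Robust to 4-connected staircase pixels, whose plain
# neighbour count exceeds 2.
transition_count <- function(m) {
  p2 <- shift_mat(m, -1L,  0L); p3 <- shift_mat(m, -1L,  1L)
  p4 <- shift_mat(m,  0L,  1L); p5 <- shift_mat(m,  1L,  1L)
  p6 <- shift_mat(m,  1L,  0L); p7 <- shift_mat(m,  1L, -1L)
  p8 <- shift_mat(m,  0L, -1L); p9 <- shift_mat(m, -1L, -1L)
  (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
  (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
  (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
  (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
}

#' Prune short skeleton spurs
#'
#' Thinning a curved ribbon leaves short side branches. Pruning walks from
#' every skeleton endpoint; a branch that reaches a junction pixel within
#' `len` steps is deleted (the junction itself is kept). Repeated until
#' stable so nested spurs are removed.
#'
#' @param skeleton A `skeleton` or logical matrix.
#' @param len Maximum spur length, pixels.
#' @return A `skeleton`.
#' @export
prune_skeleton <- function(skeleton, len = 8) {
  mask <- if (inherits(skeleton, "skeleton")) skeleton$mask else as.matrix(skeleton)
  mode(mask) <- "logical"
  m <- mask
  storage.mode(m) <- "integer"
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    a <- transition_count(m)
    ends <- which(m == 1L & a == 1L, arr.ind = TRUE)
    if (nrow(ends) == 0L) break
    removed <- FALSE
    for (e in seq_len(nrow(ends))) {
      path <- matrix(ends[e, ], 1L, 2L)
      if (m[path[1L, 1L], path[1L, 2L]] == 0L) next
      hit_junction <- FALSE
      repeat {
        cur <- path[nrow(path), ]
        ri <- cur[1L] + offs[, 1L]; ci <- cur[2L] + offs[, 2L]
        ok <- ri >= 1L & ri <= nr & ci >= 1L & ci <= nc
        nbs <- cbind(ri[ok], ci[ok])
        nbs <- nbs[m[nbs] == 1L, , drop = FALSE]
        if (nrow(path) > 1L) {
          prev <- path[nrow(path) - 1L, ]
          nbs <- nbs[!(nbs[, 1L] == prev[1L] & nbs[, 2L] == prev[2L]), , drop = FALSE]
        }
        if (nrow(nbs) == 0L) break
        if (any(a[nbs] >= 3L)) { hit_junction <- TRUE; break }
        if (nrow(nbs) > 1L) break            # ambiguous: not a simple spur
        path <- rbind(path, nbs[1L, ])
        if (nrow(path) > len) break
      }
      if (hit_junction && nrow(path) <= len) {
        m[path] <- 0L
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  structure(list(mask = m == 1L), class = "skeleton")
}

#' Trace a skeleton into ordered vessel segments
#'
#' Decomposes the centerline skeleton into its constituent vessels.
#' Junctions are skeleton pixels whose crossing number (0->1 transitions
#' around the 8-neighbourhood) is three or more; removing them splits the
#' skeleton into simple paths, each returned as an ordered [polyline].
#' Tracing starts from the lexicographically smallest (y, x) endpoint of
#' each path, which makes the decomposition deterministic.
#'
#' @param skeleton A `skeleton` from [binarize_and_skeletonize()], or a
#'   logical matrix.
#' @return A `vessel_tree`: list with `segments` (list of [polyline]s, ids
#'   "V1", "V2", ... in trace order) and `junctions` (two-column matrix of
#'   0-based (x, y) junction coordinates).
#' @export
trace_segments <- function(skeleton) {
  mask <- if (inherits(skeleton, "skeleton")) skeleton$mask else as.matrix(skeleton)
  mode(mask) <- "logical"
  nr <- nrow(mask); nc <- ncol(mask)
  if (!any(mask)) {
    return(structure(list(segments = list(),
                          junctions = matrix(numeric(0), 0L, 2L,
                                             dimnames = list(NULL, c("x", "y")))),
                     class = "vessel_tree"))
  }
  m <- mask
  storage.mode(m) <- "integer"
  ncount <- function(mm) {
    shift_mat(mm, -1L, 0L) + shift_mat(mm, 1L, 0L) + shift_mat(mm, 0L, -1L) +
    shift_mat(mm, 0L, 1L) + shift_mat(mm, -1L, -1L) + shift_mat(mm, -1L, 1L) +
    shift_mat(mm, 1L, -1L) + shift_mat(mm, 1L, 1L)
  }
  junction <- m == 1L & transition_count(m) >= 3L
  body <- m
  body[junction] <- 0L
  # splitting can expose further internal branch pixels; iterate until every
  # remaining pixel is a path or end pixel
  repeat {
    extra <- body == 1L & transition_count(body) >= 3L
    if (!any(extra)) break
    junction <- junction | extra
    body[extra] <- 0L
  }
  jidx <- which(junction, arr.ind = TRUE)
  segs <- list()
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  visited <- matrix(FALSE, nr, nc)
  # order candidate pixels lexicographically by (y, x) = (row, col)
  px <- which(body == 1L, arr.ind = TRUE)
  px <- px[order(px[, 1L], px[, 2L]), , drop = FALSE]
  neighbours_of <- function(i, j, mm) {
    ri <- i + offs$dy; ci <- j + offs$dx
    ok <- ri >= 1L & ri <= nr & ci >= 1L & ci <= nc
    ri <- ri[ok]; ci <- ci[ok]
    keep <- mm[cbind(ri, ci)] == 1L
    cbind(ri[keep], ci[keep])
  }
  deg <- ncount(body)
  for (r in seq_len(nrow(px))) {
    i0 <- px[r, 1L]; j0 <- px[r, 2L]
    if (visited[i0, j0]) next
    # find the component and its endpoints by flood fill
    comp <- matrix(c(i0, j0), 1L, 2L)
    visited[i0, j0] <- TRUE
    queue <- 1L
    while (length(queue) > 0L) {
      cur <- queue[1L]; queue <- queue[-1L]
      nbs <- neighbours_of(comp[cur, 1L], comp[cur, 2L], body)
      if (nrow(nbs) > 0L) {
        new <- nbs[!visited[nbs], , drop = FALSE]
        if (nrow(new) > 0L) {
          visited[new] <- TRUE
          queue <- c(queue, nrow(comp) + seq_len(nrow(new)))
          comp <- rbind(comp, new)
        }
      }
    }
    degs <- deg[comp]
    ends <- comp[degs <= 1L, , drop = FALSE]
    start <- if (nrow(ends) > 0L) {
      ends[order(ends[, 1L], ends[, 2L]), , drop = FALSE][1L, ]
    } else {
      comp[order(comp[, 1L], comp[, 2L]), , drop = FALSE][1L, ]  # cycle
    }
    # walk the path
    inpath <- matrix(FALSE, nr, nc)
    path <- matrix(start, 1L, 2L)
    inpath[start[1L], start[2L]] <- TRUE
    repeat {
      tail_px <- path[nrow(path), ]
      nbs <- neighbours_of(tail_px[1L], tail_px[2L], body)
      nbs <- nbs[!inpath[nbs], , drop = FALSE]
      if (nrow(nbs) == 0L) break
      # prefer 4-connected continuation, then lexicographic, for determinism
      d4 <- (abs(nbs[, 1L] - tail_px[1L]) + abs(nbs[, 2L] - tail_px[2L])) == 1L
      ordn <- order(!d4, nbs[, 1L], nbs[, 2L])
      nxt <- nbs[ordn[1L], ]
      path <- rbind(path, nxt)
      inpath[nxt[1L], nxt[2L]] <- TRUE
    }
    # attach an adjacent junction pixel at each free end, so segments meet
    if (nrow(jidx) > 0L) {
      for (endside in c("head", "tail")) {
        e <- if (endside == "head") path[1L, ] else path[nrow(path), ]
        dj <- abs(jidx[, 1L] - e[1L]) <= 1L & abs(jidx[, 2L] - e[2L]) <= 1L
        if (any(dj)) {
          jpt <- jidx[which(dj)[1L], ]
          path <- if (endside == "head") rbind(jpt, path) else rbind(path, jpt)
        }
      }
    }
    if (nrow(path) >= 2L) {
      segs[[length(segs) + 1L]] <- polyline(path[, 2L] - 1, path[, 1L] - 1,
                                            id = paste0("V", length(segs) + 1L))
    }
  }
  junc_xy <- if (nrow(jidx) > 0L) {
    cbind(x = jidx[, 2L] - 1, y = jidx[, 1L] - 1)
  } else matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("x", "y")))
  structure(list(segments = segs, junctions = junc_xy), class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree: %d segments, %d junctions>\n",
              length(x$segments), nrow(x$junctions)))
  invisible(x)
}

#' Extract the vessel tree from a fundus-style image
#'
#' Full extraction pipeline: multiscale ridge detection, binarization and
#' thinning to a 1-px skeleton, decomposition into segments at junctions,
#' and local smoothing of each traced centerline. Segments shorter than
#' `config$min_points` are dropped.
#'
#' @inheritParams detect_ridges
#' @param config A [retinotort_config()].
#' @return A `vessel_tree`.
#' @export
extract_tree <- function(image, config = retinotort_config()) {
  ridges <- detect_ridges(image, scales = config$scales, rho = config$rho)
  skel <- binarize_and_skeletonize(ridges, threshold = config$threshold)
  skel <- prune_skeleton(skel, len = config$spur_len)
  tree <- trace_segments(skel)
  keep <- vapply(tree$segments, function(p) nrow(p$points) >= config$min_points,
                 logical(1))
  segs <- lapply(tree$segments[keep], function(p) {
    if (nrow(p$points) >= config$smooth_window) {
      smooth_polyline(p, config$smooth_window)
    } else p
  })
  structure(list(segments = segs, junctions = tree$junctions),
            class = "vessel_tree")
}

#' Measure the total tortuosity of an image
#'
#' Extracts the vessel tree, measures the four tortuosity metrics on every
#' vessel and integrates them into per-retina totals.
#'
#' @inheritParams extract_tree
#' @return A `tree_tortuosity` (see [tree_tortuosity()]).
#' @export
measure_image <- function(image, config = retinotort_config()) {
  tree <- extract_tree(image, config)
  if (length(tree$segments) == 0L) stop_empty_tree("no vessels extracted from image")
  tree_tortuosity(tree, config)
}
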