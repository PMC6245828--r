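#' Parametric vessel specification
#'
#' Describes one synthetic vessel centerline from a family with analytic
#' tortuosity: `"line"` (straight), `"arc"` (circular arc of angle `theta`),
#' `"sinusoid"` (sine wave of `half_waves` half-periods over a straight
#' chord) or `"multi_inflection"` (piecewise sine half-waves, optionally
#' with per-half-wave amplitudes).
#'
#' @param family Curve family.
#' @param length Chord extent along the main axis (line, sinusoid,
#'   multi_inflection), pixels.
#' @param radius Arc radius, pixels.
#' @param theta Arc opening angle, radians.
#' @param amplitude Sine amplitude, pixels (scalar, or one value per
#'   half-wave for `multi_inflection`).
#' @param half_waves Number of sine half-periods.
#' @param n_points Number of samples.
#' @param origin Start point (x, y).
#' @param angle Orientation of the main axis, radians (0 = x direction).
#' @return A `vessel_spec`.
#' @export
vessel_spec <- function(family = c("line", "arc", "sinusoid", "multi_inflection"),
                        length = 100, radius = 50, theta = pi, amplitude = 10,
                        half_waves = 2, n_points = 200, origin = c(0, 0),
                        angle = 0) {
  family <- match.arg(family)
  if (n_points < 2) stop_invalid("n_points must be >= 2")
  if (family %in% c("line", "sinusoid", "multi_inflection") && length <= 0) {
    stop_invalid("length must be positive")
  }
  if (family == "arc" && (radius <= 0 || theta <= 0 || theta > 2 * pi)) {
    stop_invalid("arc needs radius > 0 and theta in (0, 2*pi]")
  }
  if (family %in% c("sinusoid", "multi_inflection")) {
    if (any(amplitude < 0)) stop_invalid("amplitude must be non-negative")
    if (half_waves < 1 || half_waves != round(half_waves)) {
      stop_invalid("half_waves must be a positive integer")
    }
    if (family == "multi_inflection" && !(length(amplitude) %in% c(1L, half_waves))) {
      stop_invalid("amplitude must be scalar or one per half-wave")
    }
  }
  structure(list(family = family, length = length, radius = radius,
                 theta = theta, amplitude = amplitude,
                 half_waves = as.integer(half_waves),
                 n_points = as.integer(n_points),
                 origin = origin, angle = angle),
            class = "vessel_spec")
}

#' Sample a synthetic vessel with its analytic tortuosity
#'
#' Returns the sampled centerline annotated with the closed-form (line,
#' arc) or quadrature (sinusoid) arc-to-chord tortuosity of the generating
#' curve and its interior inflection count. For an arc of angle
#' \eqn{\theta} the annotation is \eqn{\theta / (2 \sin(\theta/2)) - 1}.
#'
#' @param spec A [vessel_spec()].
#' @param id Vessel identifier.
#' @return A [polyline] with attributes `hart_true` (analytic arc-to-chord
#'   tortuosity), `inflections` (interior inflection count) and `family`.
#' @export
make_vessel <- function(spec, id = NULL) {
  if (!inherits(spec, "vessel_spec")) stop_invalid("expected a vessel_spec")
  n <- spec$n_points
  if (spec$family == "line") {
    t <- seq(0, spec$length, length.out = n)
    xy <- cbind(t, 0)
    hart <- 0
    infl <- 0L
  } else if (spec$family == "arc") {
    th <- seq(-spec$theta / 2, spec$theta / 2, length.out = n)
    xy <- cbind(spec$radius * sin(th), spec$radius * (1 - cos(th)))
    hart <- spec$theta / (2 * sin(spec$theta / 2)) - 1
    infl <- 0L
  } else {
    h <- spec$half_waves
    amps <- rep(spec$amplitude, length.out = h)
    t <- seq(0, spec$length, length.out = n)
    yfun <- function(tt) {
      pc <- pmin(floor(tt / spec$length * h), h - 1)
      amps[pc + 1] * (-1)^pc * abs(sin(h * pi * tt / spec$length))
    }
    xy <- cbind(t, yfun(t))
    dy <- function(tt) {
      pc <- pmin(floor(tt / spec$length * h), h - 1)
      w <- h * pi / spec$length
      amps[pc + 1] * (-1)^pc * sign(sin(w * tt)) * w * cos(w * tt) *
        ifelse(abs(sin(w * tt)) < 1e-12, 0, 1)
    }
    arc <- stats::integrate(function(tt) sqrt(1 + dy(tt)^2), 0, spec$length,
                            subdivisions = 2000L, rel.tol = 1e-9,
                            stop.on.error = FALSE)$value
    hart <- arc / spec$length - 1
    infl <- h - 1L
  }
  # rigid placement
  ca <- cos(spec$angle); sa <- sin(spec$angle)
  rot <- cbind(c(ca, sa), c(-sa, ca))
  xy <- xy %*% t(rot)
  xy[, 1] <- xy[, 1] + spec$origin[1]
  xy[, 2] <- xy[, 2] + spec$origin[2]
  out <- polyline(xy, id = id)
  attr(out, "hart_true") <- hart
  attr(out, "inflections") <- infl
  attr(out, "family") <- spec$family
  out
}

#' Render a phantom fundus image with ground-truth centerlines
#'
#' Draws dark vessels of constant width on a bright background by
#' distance-to-centerline thresholding (round end caps), then adds optional
#' Gaussian noise. Bit-exact reproducible for a given seed.
#'
#' @param specs List of [vessel_spec()]s (their origins/angles place them on
#'   the canvas).
#' @param shape Canvas (rows, cols) = (height, width), pixels.
#' @param width Vessel width, pixels (>= 1).
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units).
#' @param seed Integer seed for the noise stream.
#' @param background,foreground Background and vessel intensities.
#' @param allow_crossing Permit vessels closer than twice the width.
#' @return A `phantom_image`: list with `raster` (matrix), `centerlines`
#'   (list of annotated [polyline]s), `width`, `noise_sd`.
#' @export
render_phantom <- function(specs, shape = c(200, 200), width = 3,
                           noise_sd = 0, seed = 1, background = 0.85,
                           foreground = 0.2, allow_crossing = FALSE) {
  if (width < 1) stop_invalid("width must be >= 1")
  centerlines <- lapply(seq_along(specs), function(i) {
    make_vessel(specs[[i]], id = paste0("GT", i))
  })
  dense <- lapply(centerlines, function(p) resample_polyline(p, 0.25)$points)
  for (p in dense) {
    if (any(p[, 1] < 0 | p[, 1] > shape[2] - 1 | p[, 2] < 0 | p[, 2] > shape[1] - 1)) {
      stop_layout("a ground-truth centerline leaves the canvas")
    }
  }
  if (!allow_crossing && length(dense) > 1L) {
    for (i in seq_along(dense)) {
      for (j in seq_len(i - 1L)) {
        d2 <- outer(dense[[i]][, 1], dense[[j]][, 1], "-")^2 +
              outer(dense[[i]][, 2], dense[[j]][, 2], "-")^2
        if (min(d2) < (2 * width)^2) {
          stop_layout(sprintf("vessels %d and %d are closer than twice the width", i, j))
        }
      }
    }
  }
  raster <- matrix(background, shape[1], shape[2])
  r <- width / 2
  rc <- ceiling(r)
  offs <- expand.grid(dx = -rc:rc, dy = -rc:rc)
  for (p in dense) {
    px0 <- round(p[, 1]); py0 <- round(p[, 2])
    for (o in seq_len(nrow(offs))) {
      px <- px0 + offs$dx[o]; py <- py0 + offs$dy[o]
      d2 <- (px - p[, 1])^2 + (py - p[, 2])^2
      ok <- d2 <= r^2 & px >= 0 & px <= shape[2] - 1 & py >= 0 & py <= shape[1] - 1
      if (any(ok)) raster[cbind(py[ok] + 1L, px[ok] + 1L)] <- foreground
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    raster <- raster + matrix(stats::rnorm(length(raster), sd = noise_sd),
                              nrow(raster), ncol(raster))
    raster <- pmin(pmax(raster, 0), 1)
  }
  structure(list(raster = raster, centerlines = centerlines, width = width,
                 noise_sd = noise_sd), class = "phantom_image")
}

#' Write a phantom raster as PNG
#'
#' @param phantom A `phantom_image` (or plain matrix).
#' @param path Output path.
#' @export
write_phantom_png <- function(phantom, path) {
  m <- if (inherits(phantom, "phantom_image")) phantom$raster else phantom
  png::writePNG(pmin(pmax(m, 0), 1), path)
  invisible(path)
}

#' Rater model and panel specification
#'
#' A rater is modelled by a row-stochastic confusion matrix: the probability
#' of each reported grade given the true grade. `rater_model()` builds one
#' with a given probability of reporting the true grade, the remainder
#' spread over adjacent grades (ordinal errors).
#'
#' @param accuracy Probability of reporting the true grade.
#' @param n_grades Number of grades (default 4).
#' @return Row-stochastic matrix (true x reported).
#' @export
rater_model <- function(accuracy = 0.8, n_grades = 4L) {
  if (accuracy < 0 || accuracy > 1) stop_invalid("accuracy must be in [0, 1]")
  m <- matrix(0, n_grades, n_grades)
  for (g in seq_len(n_grades)) {
    m[g, g] <- accuracy
    nb <- c(g - 1L, g + 1L)
    nb <- nb[nb >= 1L & nb <= n_grades]
    m[g, nb] <- (1 - accuracy) / length(nb)
  }
  m / rowSums(m)
}

#' Panel specification
#'
#' @param n_images Number of rated images.
#' @param prior Probability vector over the true grades (default uniform
#'   over the four tortuosity grades, mirroring a balanced study design).
#' @param raters Named list of confusion matrices (one per rater).
#' @param rounds Round labels; each rater reports independently per round.
#' @param seed Integer seed.
#' @return A `panel_spec`.
#' @export
panel_spec <- function(n_images = 60, prior = rep(0.25, 4),
                       raters = stats::setNames(replicate(5, rater_model(), simplify = FALSE),
                                                paste0("E", 1:5)),
                       rounds = c("R1", "R2"), seed = 1) {
  if (abs(sum(prior) - 1) > 1e-9) stop_invalid("prior must sum to 1")
  if (length(raters) < 2L) stop_invalid("need at least 2 raters")
  for (m in raters) {
    m <- as.matrix(m)
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9)) {
      stop_invalid("rater confusion matrices must be row-stochastic")
    }
  }
  if (is.null(names(raters))) names(raters) <- paste0("E", seq_along(raters))
  structure(list(n_images = as.integer(n_images), prior = prior,
                 raters = raters, rounds = rounds, seed = as.integer(seed)),
            class = "panel_spec")
}

#' Simulate a multi-rater ordinal rating panel
#'
#' Draws true grades from the prior, then each rater's report for each
#' round independently from their confusion row. Reproducible for a fixed
#' seed; the truth and rating streams are split so changing the number of
#' raters does not perturb the true grades.
#'
#' @param spec A [panel_spec()].
#' @return List with `panel` (long data.frame `image_id`, `rater_id`,
#'   `round`, `grade`), `truth` (data.frame `image_id`, `grade`), `tables`
#'   (one `rating_table` per round).
#' @export
simulate_panel <- function(spec) {
  if (!inherits(spec, "panel_spec")) stop_invalid("expected a panel_spec")
  n_grades <- length(spec$prior)
  set.seed(spec$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  set.seed(sub_seeds[1L])
  truth <- sample.int(n_grades, spec$n_images, replace = TRUE, prob = spec$prior) - 1L
  ids <- sprintf("img%03d", seq_len(spec$n_images))
  set.seed(sub_seeds[2L])
  rows <- list()
  for (rd in spec$rounds) {
    for (ra in names(spec$raters)) {
      conf <- as.matrix(spec$raters[[ra]])
      rep_grade <- vapply(truth, function(g) {
        sample.int(n_grades, 1L, prob = conf[g + 1L, ]) - 1L
      }, integer(1))
      rows[[paste(rd, ra)]] <- data.frame(image_id = ids, rater_id = ra,
                                          round = rd, grade = rep_grade,
                                          stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  tables <- lapply(stats::setNames(spec$rounds, spec$rounds), function(rd) {
    sub <- panel[panel$round == rd, ]
    rating_table(sub$image_id, sub$rater_id, sub$grade, round = rd,
                 scale = seq_len(n_grades) - 1L)
  })
  list(panel = panel, truth = data.frame(image_id = ids, grade = truth,
                                         stringsAsFactors = FALSE),
       tables = tables)
}
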