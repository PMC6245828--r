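phantom_one_vessel <- function(spec, shape = c(120, 220), ...) {
  render_phantom(list(spec), shape = shape, width = 3, noise_sd = 0, seed = 1, ...)
}

test_that("ridge detection responds on centerlines and is silent on flat images", {
  flat <- matrix(0.5, 64, 64)
  expect_true(all(detect_ridges(flat)$strength == 0))
  # one dark horizontal vessel: per-column argmax row within +-1 px of truth
  ph <- phantom_one_vessel(vessel_spec("line", length = 180, origin = c(20, 60),
                                       n_points = 200))
  rm_ <- detect_ridges(ph$raster)
  rows <- apply(rm_$strength[, 40:180], 2, which.max)
  expect_true(all(abs(rows - 61) <= 1))
  # two crossing vessels: response above threshold on >= 95% of truth pixels
  cross <- render_phantom(list(
    vessel_spec("line", length = 180, origin = c(20, 40), angle = 0.35, n_points = 200),
    vessel_spec("line", length = 180, origin = c(20, 100), angle = -0.35, n_points = 200)),
    shape = c(140, 220), width = 3, noise_sd = 0, seed = 1, allow_crossing = TRUE)
  rm2 <- detect_ridges(cross$raster)
  thr <- quantile(rm2$strength[rm2$strength > 0], 0.5)
  hit <- 0; tot <- 0
  for (ctr in cross$centerlines) {
    g <- resample_polyline(ctr, 1)$points
    ij <- cbind(round(g[, 2]) + 1, round(g[, 1]) + 1)
    hit <- hit + sum(rm2$strength[ij] > thr)
    tot <- tot + nrow(ij)
  }
  expect_gte(hit / tot, 0.95)
})

test_that("binarization and thinning give 1-px-wide skeletons of the right extent", {
  # bar of width 5 reduces to a single 1-px line
  bar <- matrix(0, 60, 80)
  bar[28:32, 10:70] <- 1
  sk <- binarize_and_skeletonize(bar, threshold = 0.5)
  expect_true(sum(sk$mask) <= 63 && sum(sk$mask) >= 55)
  expect_equal(sum(sk$mask & row(sk$mask) != 30), 0)
  # all below threshold: empty skeleton
  expect_equal(sum(binarize_and_skeletonize(bar, threshold = 2)$mask), 0)
  # phantom sinusoid: skeleton pixel count within 10% of true length
  ph <- phantom_one_vessel(vessel_spec("sinusoid", length = 180, amplitude = 10,
                                       half_waves = 3, origin = c(20, 60), n_points = 300))
  sk2 <- binarize_and_skeletonize(detect_ridges(ph$raster))
  true_len <- arc_length(ph$centerlines[[1]])
  expect_equal(sum(sk2$mask), true_len, tolerance = 0.10)
})

test_that("skeletons never contain a 2x2 block of on-pixels", {
  shapes <- list(
    phantom_one_vessel(vessel_spec("sinusoid", length = 180, amplitude = 12,
                                   half_waves = 4, origin = c(20, 60), n_points = 300)),
    phantom_one_vessel(vessel_spec("arc", radius = 90, theta = 1.4,
                                   origin = c(110, 60), n_points = 300)))
  for (ph in shapes) {
    m <- binarize_and_skeletonize(detect_ridges(ph$raster))$mask
    blocks <- m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] & m[-nrow(m), -1] & m[-1, -1]
    expect_false(any(blocks))
  }
})

test_that("tracing decomposes skeletons at junctions deterministically", {
  # empty skeleton
  empty <- matrix(FALSE, 40, 40)
  expect_length(trace_segments(empty)$segments, 0)
  # single open curve: one segment containing every pixel
  m <- matrix(FALSE, 40, 60)
  for (x in 5:55) m[round(20 + 8 * sin((x - 5) / 8)), x] <- TRUE
  tr <- trace_segments(m)
  expect_length(tr$segments, 1)
  expect_equal(nrow(tr$segments[[1]]$points), sum(m))
  # Y shape: three arms meeting at one pixel
  y <- matrix(FALSE, 20, 20)
  y[cbind(9:13, rep(9, 5))] <- TRUE            # stem
  y[cbind(8:4, 8:4)] <- TRUE                   # upper-left arm
  y[cbind(8:4, 10:14)] <- TRUE                 # upper-right arm
  ty <- trace_segments(y)
  expect_length(ty$segments, 3)
  expect_equal(nrow(ty$junctions), 1)
  # segment cores partition the skeleton minus junctions
  core <- lapply(ty$segments, function(s) {
    pts <- cbind(s$points[, 2] + 1, s$points[, 1] + 1)
    pts[!(pts[, 1] %in% (ty$junctions[, 2] + 1) & pts[, 2] %in% (ty$junctions[, 1] + 1)), , drop = FALSE]
  })
  all_core <- do.call(rbind, core)
  expect_equal(nrow(all_core), nrow(unique(all_core)))
  expect_equal(nrow(all_core), sum(y) - nrow(ty$junctions))
  # retracing the same mask is identical
  ty2 <- trace_segments(y)
  expect_identical(lapply(ty$segments, `[[`, "points"),
                   lapply(ty2$segments, `[[`, "points"))
})

test_that("full extraction recovers phantom centerlines and their tortuosity", {
  blank <- matrix(0.85, 100, 100)
  expect_length(extract_tree(blank)$segments, 0)
  expect_error(measure_image(blank), class = "retinotort_empty_tree")
  # single vessel: one segment, sub-pixel mean deviation
  ph <- phantom_one_vessel(vessel_spec("sinusoid", length = 180, amplitude = 10,
                                       half_waves = 3, origin = c(20, 60), n_points = 300))
  tree <- extract_tree(ph$raster)
  expect_length(tree$segments, 1)
  expect_lt(mean_dev_to_truth(tree$segments[[1]], ph$centerlines[[1]]), 1)
  # five separated vessels recovered as five segments
  fam <- list(
    vessel_spec("line", length = 170, origin = c(20, 25), n_points = 200),
    vessel_spec("sinusoid", length = 160, amplitude = 10, half_waves = 3,
                origin = c(20, 65), n_points = 300),
    vessel_spec("sinusoid", length = 160, amplitude = 8, half_waves = 2,
                origin = c(20, 115), n_points = 300),
    vessel_spec("sinusoid", length = 160, amplitude = 9, half_waves = 4,
                origin = c(20, 165), n_points = 300),
    vessel_spec("line", length = 170, angle = 0.1, origin = c(20, 205), n_points = 200))
  ph5 <- render_phantom(fam, shape = c(240, 210), width = 3, noise_sd = 0, seed = 2)
  tree5 <- extract_tree(ph5$raster)
  expect_length(tree5$segments, 5)
})

test_that("image measurement integrates per-vessel metrics deterministically", {
  two <- render_phantom(list(
    vessel_spec("line", length = 150, origin = c(20, 40), n_points = 200),
    vessel_spec("line", length = 150, origin = c(20, 90), n_points = 200)),
    shape = c(130, 190), width = 3, noise_sd = 0, seed = 1)
  rep_two <- measure_image(two$raster)
  expect_lt(rep_two$totals[["hart"]], 0.01)
  expect_lt(rep_two$totals[["grisan"]], 0.01)
  expect_lt(rep_two$totals[["onkaew"]], 0.01)
  # straight + sinusoid: the integrated value lies strictly between the two
  mix <- render_phantom(list(
    vessel_spec("line", length = 150, origin = c(20, 40), n_points = 200),
    vessel_spec("sinusoid", length = 150, amplitude = 12, half_waves = 3,
                origin = c(20, 100), n_points = 300)),
    shape = c(150, 190), width = 3, noise_sd = 0, seed = 1)
  rep_mix <- measure_image(mix$raster)
  harts <- sort(rep_mix$per_vessel$hart)
  expect_gt(rep_mix$totals[["hart"]], harts[1])
  expect_lt(rep_mix$totals[["hart"]], harts[2])
  # determinism: identical input, identical report
  expect_identical(measure_image(mix$raster), rep_mix)
})
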