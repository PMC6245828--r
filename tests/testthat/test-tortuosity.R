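test_that("subdivision tortuosity matches the two-semicircle closed form and vanishes at n = 1", {
  # any single-convexity arc scores 0 (prefactor n - 1)
  expect_equal(grisan_tortuosity(semicircle_polyline(r = 40, n = 800)), 0)
  # S-curve of two radius-r semicircles: r * tau = (pi - 2) / (2 pi)
  r <- 40
  g <- grisan_tortuosity(s_curve_polyline(r = r))
  expect_lt(abs(r * g - (pi - 2) / (2 * pi)), 1e-2)
  # straight vessels score 0
  expect_equal(grisan_tortuosity(polyline(seq(0, 200), rep(3, 201))), 0)
})

test_that("subdivision tortuosity scales as 1/s (tortuosity density)", {
  v <- sinusoid_polyline(length = 200, amplitude = 12, half_waves = 3, n = 500)
  g1 <- grisan_tortuosity(v)
  for (s in c(2, 5)) {
    scaled <- polyline(v$points * s)
    gs <- grisan_tortuosity(scaled, sigma = 2 * s, spacing = s)
    expect_equal(gs, g1 / s, tolerance = 1e-3)
  }
})

test_that("curvature-integral tortuosity matches circle closed forms", {
  line <- polyline(seq(0, 100), 0.25 * seq(0, 100))
  expect_equal(trucco_tortuosity(line), 0)
  # unit-radius quarter circle with 100 interior samples: each |k| ~ 1
  th <- seq(0, pi / 2, length.out = 500)
  qc <- polyline(cos(th), sin(th))
  sp <- (pi / 2) / 103
  expect_equal(trucco_tortuosity(qc, p = 1, sigma = 3 * sp, spacing = sp), 100,
               tolerance = 0.03)
  expect_equal(trucco_tortuosity(qc, p = 2, sigma = 3 * sp, spacing = sp), 10,
               tolerance = 0.03)
  expect_error(trucco_tortuosity(line, p = 0), class = "retinotort_invalid_input")
  expect_error(trucco_tortuosity(line, p = 1.5), class = "retinotort_invalid_input")
})

test_that("chain-code tortuosity vanishes on straight and single-convexity vessels", {
  expect_equal(onkaew_tortuosity(polyline(0:150, rep(0, 151))), 0)
  expect_equal(onkaew_tortuosity(polyline(0:150, 0:150)), 0)
  # oblique line: small quantization floor, far below tortuous values
  obl <- make_vessel(vessel_spec("line", length = 200, angle = 0.3, n_points = 300))
  expect_lt(onkaew_tortuosity(obl), 0.02)
  arc <- make_vessel(vessel_spec("arc", radius = 40, theta = 2, origin = c(60, 60),
                                 n_points = 300))
  expect_equal(onkaew_tortuosity(arc), 0)
})

test_that("subdivision metrics strictly increase with inflection count at fixed span", {
  gr <- on <- numeric(0)
  for (h in c(2, 4, 6)) {
    v <- sinusoid_polyline(length = 200, amplitude = 15, half_waves = h, n = 400)
    gr <- c(gr, grisan_tortuosity(v))
    on <- c(on, onkaew_tortuosity(v))
  }
  expect_true(all(diff(gr) > 0))
  expect_true(all(diff(on) > 0))
})

test_that("chain-code tortuosity matches an independently coded brute-force oracle", {
  for (h in c(2, 4, 6)) {
    v <- sinusoid_polyline(length = 200, amplitude = 15, half_waves = h, n = 400)
    expect_equal(onkaew_tortuosity(v), naive_onkaew(v), tolerance = 1e-9)
  }
})

test_that("all four metrics are invariant under rigid motion", {
  v <- sinusoid_polyline(length = 200, amplitude = 12, half_waves = 3, n = 500)
  base <- c(hart_tortuosity(v), grisan_tortuosity(v), trucco_tortuosity(v))
  moved <- rigid_motion(v, angle = 0.71, shift = c(31.2, -7.9))
  got <- c(hart_tortuosity(moved), grisan_tortuosity(moved), trucco_tortuosity(moved))
  expect_equal(got, base, tolerance = 1e-6)
  # the chain-code metric lives on the pixel grid: invariant under
  # grid-preserving motions (quarter-turns, integer shifts)
  o0 <- onkaew_tortuosity(v)
  turned <- rigid_motion(v, angle = pi / 2, shift = c(250, 17))
  expect_equal(onkaew_tortuosity(turned), o0, tolerance = 1e-9)
})

test_that("all four metrics are unchanged when the point order is reversed", {
  v <- sinusoid_polyline(length = 200, amplitude = 12, half_waves = 4, n = 500)
  rv <- reverse_polyline(v)
  expect_equal(hart_tortuosity(rv), hart_tortuosity(v), tolerance = 1e-12)
  expect_equal(grisan_tortuosity(rv), grisan_tortuosity(v), tolerance = 1e-9)
  expect_equal(trucco_tortuosity(rv), trucco_tortuosity(v), tolerance = 1e-9)
  expect_equal(onkaew_tortuosity(rv), onkaew_tortuosity(v), tolerance = 1e-9)
})

test_that("tree integration is the arc-length-weighted mean with its range property", {
  expect_equal(integrate_tree(0.42, 10), 0.42)
  expect_equal(integrate_tree(c(0.2, 0.4), c(7, 7)), 0.3)
  expect_equal(integrate_tree(c(0.2, 0.6), c(1, 3)), 0.5)
  expect_error(integrate_tree(numeric(0), numeric(0)), class = "retinotort_empty_tree")
  expect_error(integrate_tree(c(0.1, 0.2), c(1, -1)), class = "retinotort_invalid_input")
  expect_error(integrate_tree(c(0.1, 0.2), 1), class = "retinotort_invalid_input")
  set.seed(42)
  for (i in 1:25) {
    vals <- runif(sample(2:8, 1))
    lens <- runif(length(vals), 1, 100)
    tot <- integrate_tree(vals, lens)
    expect_gte(tot, min(vals))
    expect_lte(tot, max(vals))
  }
  expect_equal(integrate_tree(rep(0.37, 5), runif(5, 1, 9)), 0.37)
})

test_that("per-vessel and tree reports carry all metrics and drop short vessels", {
  segs <- list(make_vessel(vessel_spec("line", length = 120, n_points = 150), id = "straight"),
               sinusoid_polyline(length = 150, amplitude = 12, half_waves = 3, n = 300))
  segs[[2]]$id <- "bendy"
  short <- polyline(c(0, 1, 2), c(0, 0.5, 0))
  short$id <- "crumb"
  tt <- tree_tortuosity(c(segs, list(short)))
  expect_equal(nrow(tt$per_vessel), 2)
  expect_equal(tt$dropped, "crumb")
  expect_named(tt$totals, c("hart", "grisan", "trucco", "onkaew"))
  for (m in names(tt$totals)) {
    expect_gte(tt$totals[[m]], min(tt$per_vessel[[m]]))
    expect_lte(tt$totals[[m]], max(tt$per_vessel[[m]]))
  }
  expect_error(tree_tortuosity(list(short)), class = "retinotort_empty_tree")
  f <- withr::local_tempfile(fileext = ".csv")
  write_tortuosity_report(tt, f)
  back <- utils::read.csv(f)
  expect_equal(back$vessel_id, c("straight", "bendy", "TOTAL"))
  expect_equal(back$hart[3], unname(tt$totals[["hart"]]), tolerance = 1e-9)
})
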