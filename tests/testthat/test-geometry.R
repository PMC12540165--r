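test_that("straight tube has constant radius and the right area profile", {
  g <- make_straight_tube(1.0, 10, 100)
  expect_true(all(g$radius_mm == 1.0))
  expect_equal(diff(range(g$axial_mm)), 10)
  expect_equal(pi * g$radius_mm^2, rep(pi, 100), tolerance = 1e-12)
  expect_error(make_straight_tube(1.0, 10, 49), "at least 50")
  expect_error(make_straight_tube(-1, 10), "positive")
  expect_error(make_straight_tube(1, 0), "positive")
})

test_that("vessel_geometry enforces its invariants", {
  expect_error(vessel_geometry(1:60, c(rep(1, 59), -1)), "positive")
  expect_error(vessel_geometry(c(1:30, 30:59), rep(1, 60)), "increasing")
  expect_error(vessel_geometry(1:49, rep(1, 49)), "50 axial samples")
})

test_that("stenotic vessel hits the requested minimal lumen diameter", {
  spec <- stenosis_spec(2.5, 2.5, 1.0, 4)
  g <- make_stenotic_vessel(spec, 800)
  expect_equal(min(2 * g$radius_mm), 1.0, tolerance = 0.005)
  # profile equals the base taper outside the lesion window
  x1 <- spec$stenosis_center - 2; x2 <- spec$stenosis_center + 2
  outside <- g$axial_mm < x1 | g$axial_mm > x2
  expect_true(all(abs(g$radius_mm[outside] - 1.25) < 1e-12))
  expect_error(stenosis_spec(2.5, 2.5, 2.5, 4), "MLD")
  expect_error(stenosis_spec(2.5, 2.5, 0, 4), "MLD")
  expect_error(
    make_stenotic_vessel(stenosis_spec(2.5, 2.5, 1, 4, stenosis_center = 1)),
    "lesion window")
})

test_that("representative lesion measures 62% diameter stenosis", {
  g <- make_stenotic_vessel(representative_spec(), 600)
  m <- measure_morphology(g)
  expect_equal(m$diameter_stenosis_pct, 62, tolerance = 1 / 62)
})

test_that("modality perturbation is seeded, attenuated, and identity at zero noise", {
  g <- make_stenotic_vessel(stenosis_spec(2.2, 2.0, 0.9, 4), 400)
  g0 <- perturb_modality(g, 0, seed = 5)
  expect_identical(g0$radius_mm, g$radius_mm)
  ga <- perturb_modality(g, 0.05, smoothing_window = 1, seed = 11)
  gb <- perturb_modality(g, 0.05, smoothing_window = 1, seed = 11)
  expect_identical(ga$radius_mm, gb$radius_mm)
  gc <- perturb_modality(g, 0.05, smoothing_window = 1, seed = 12)
  expect_false(identical(ga$radius_mm, gc$radius_mm))
  # half-normal mean of |delta r| at sd 0.05, no smoothing, 1e4 samples
  big <- make_straight_tube(2, 100, 1e4)
  gp <- perturb_modality(big, 0.05, smoothing_window = 0, seed = 3)
  expect_equal(mean(abs(gp$radius_mm - big$radius_mm)),
               0.05 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("perturbation does not disturb the caller's RNG stream", {
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(perturb_modality(make_straight_tube(1, 10), 0.01, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("STL export has the expected triangle count and round-trips", {
  g <- make_straight_tube(1, 10, 60)
  path <- tempfile(fileext = ".stl")
  ntri <- export_surface_stl(g, path, circumferential_samples = 64)
  expect_equal(ntri, 2 * 64 * (60 - 1))
  v <- read_surface_stl(path)
  r_back <- sqrt(v[, 2]^2 + v[, 3]^2)
  expect_lt(max(abs(r_back - 1)), 1e-6)
  expect_error(export_surface_stl(g, path, circumferential_samples = 8),
               "at least 16")
})

test_that("radius profile CSV round-trips losslessly and validates input", {
  g <- make_stenotic_vessel(stenosis_spec(2.4, 2.1, 1.1, 5), 200)
  path <- tempfile(fileext = ".csv")
  write_radius_profile_csv(g, path)
  g2 <- read_radius_profile_csv(path)
  expect_lt(max(abs(g2$radius_mm - g$radius_mm)), 1e-9)
  expect_lt(max(abs(g2$axial_mm - g$axial_mm)), 1e-9)

  bad <- data.frame(axial_mm = c(0, 1, 2, 1.5, 4:60),
                    radius_mm = rep(1, 61))
  bp <- tempfile(fileext = ".csv")
  write.csv(bad, bp, row.names = FALSE)
  expect_error(read_radius_profile_csv(bp), "row 4")
  bad2 <- data.frame(axial_mm = 0:60, radius_mm = c(rep(1, 30), 0, rep(1, 30)))
  write.csv(bad2, bp, row.names = FALSE)
  expect_error(read_radius_profile_csv(bp), "row 31")
})

test_that("morphometry recovers generating spec parameters within 2%", {
  set.seed(42)
  for (rep in 1:12) {
    prox <- runif(1, 1.8, 4.0)
    dist <- prox * runif(1, 0.8, 1.05)
    ds <- runif(1, 30, 80)
    mld <- prox * (1 - ds / 100)
    if (mld >= 0.95 * min(prox, dist)) next
    len <- runif(1, 2.5, 9)
    spec <- stenosis_spec(prox, dist, mld, len)
    m <- measure_morphology(make_stenotic_vessel(spec, 900))
    expect_equal(m$minimal_lumen_diameter, mld, tolerance = 0.02)
    expect_equal(m$proximal_diameter, prox, tolerance = 0.02)
    expect_equal(m$distal_diameter, dist, tolerance = 0.02)
    expect_equal(m$stenosis_length, len, tolerance = 0.02)
  }
})

test_that("paired perturbations yield diameter differences with SD sqrt(2) sigma", {
  g <- make_straight_tube(1.5, 60, 4000)
  sigma <- 0.04
  i0 <- 2000L  # fixed interior station
  d <- vapply(1:400, function(k) {
    a <- perturb_modality(g, sigma, 0, seed = 2 * k)
    b <- perturb_modality(g, sigma, 0, seed = 2 * k + 1)
    2 * (a$radius_mm[i0] - b$radius_mm[i0])
  }, numeric(1))
  expect_equal(sd(d), sqrt(2) * 2 * sigma, tolerance = 0.10)
})
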