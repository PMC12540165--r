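# shared solved fields for the metric tests (straight tube with a developed
# 10 mm measurement window, and a creeping-flow stenosis)
tube_field <- local({
  case <- tube_case(radius = 1, window = 10, ext = 20, flow = 1)
  solve_steady(build_mesh(case$geometry, 1), case)
})
tube_planes <- measurement_planes(20, 30, c(24, 28), c(15, 19))

test_that("PR follows the Poiseuille oracle on a straight tube", {
  pp <- pressure_profile(tube_field)
  pr <- pressure_ratio(pp, tube_planes, reference_inlet_pressure = 13332)
  # drop across the window is ~89.13 Pa against a 13332 Pa reference
  expected <- 1 - poiseuille_reference(1, 10, 1)$pressure_drop_pa / 13332
  expect_equal(pr, expected, tolerance = 3e-4)
  expect_true(pr > 0 && pr <= 1)
})

test_that("PR equals one exactly at zero flow", {
  case <- tube_case(flow = 0)
  field <- solve_steady(build_mesh(case$geometry, 0), case)
  pp <- pressure_profile(field)
  pr <- pressure_ratio(pp, tube_planes)
  expect_identical(pr, 1)
})

test_that("PR preconditions are enforced", {
  pp <- pressure_profile(tube_field)
  expect_error(pressure_ratio(pp, tube_planes, reference_inlet_pressure = 100),
               "gauge pressure drop")
  far <- measurement_planes(-5, 30, c(10, 20), c(-4, -1))
  expect_error(pressure_ratio(pp, far), "outside the solved domain")
})

test_that("WSSR is unity on a straight tube and pressure-reference free", {
  wp <- wall_shear_stress(tube_field)
  expect_equal(wssr(wp, tube_planes), 1, tolerance = 0.02)
})

test_that("WSSR approximates the cube of the radius ratio at creeping flow", {
  spec <- stenosis_spec(2, 2, 1.5, 10, inlet_extension = 15,
                        outlet_extension = 15)
  g <- make_stenotic_vessel(spec, 600)
  q <- 0.003
  case <- case_definition(g, fixed_inlet_flow(q, 2 * g$radius_mm[1]),
                          modality = "DSA")
  field <- solve_steady(build_mesh(g, 1), case)
  planes <- measurement_planes(12, 32, c(19.3, 20.7), c(8, 12))
  w <- wssr(wall_shear_stress(field), planes)
  expect_equal(w, (1 / 0.75)^3, tolerance = 0.10)
  # doubling the flow leaves WSSR unchanged in the Stokes regime
  case2 <- case_definition(g, fixed_inlet_flow(2 * q, 2 * g$radius_mm[1]),
                           modality = "DSA")
  f2 <- solve_steady(build_mesh(g, 1), case2)
  expect_equal(wssr(wall_shear_stress(f2), planes), w, tolerance = 0.01)
})

test_that("high-WSS area matches the full window at WSS above threshold", {
  wp <- wall_shear_stress(tube_field)
  # WSS ~ 4.456 Pa > 3 Pa: the 10 mm window contributes 2 pi R L
  a <- high_wss_area(wp, threshold = 3, window = c(20, 30))
  expect_equal(a, 2 * pi * 1 * 10, tolerance = 0.02)
  # below-threshold flow exposes no area
  low_case <- tube_case(radius = 1, window = 10, ext = 20,
                        flow = 1 * 2 / 4.456338)
  low <- solve_steady(build_mesh(low_case$geometry, 1), low_case)
  expect_equal(high_wss_area(wall_shear_stress(low), 3, window = c(20, 30)), 0)
  # area is non-increasing in the threshold
  a_seq <- vapply(c(1, 2, 3, 4, 5), function(tau)
    high_wss_area(wp, tau), numeric(1))
  expect_true(all(diff(a_seq) <= 0))
  expect_error(high_wss_area(wp, threshold = 0), "positive")
})

test_that("metrics refuse unconverged fields", {
  f <- tube_field
  f$converged <- FALSE
  expect_error(wall_shear_stress(f), "converged")
  expect_error(pressure_profile(f), "converged")
})

test_that("CTA- and CMD-labelled cases with identical inputs give identical metrics", {
  g <- make_stenotic_vessel(stenosis_spec(2.3, 2.1, 1.2, 4.5), 300)
  d_in <- 2 * g$radius_mm[1]
  q <- 0.9
  cta <- case_definition(g, tcd_inlet_flow(q * 1000 / (10 * pi * d_in^2 / 4), d_in),
                         modality = "CTA")
  cmd <- compose_cmd(cta, timi_inlet_flow(40, 40 * 6 / (1000 * q / (pi * d_in^2 / 4)),
                                          6, d_in))
  # equalize the flows exactly, then the two labelled cases must match
  cmd$inlet$flow_rate_ml_s <- cta$inlet$flow_rate_ml_s
  mesh <- build_mesh(g, 0)
  m1 <- compute_hemodynamics(solve_steady(mesh, cta))
  m2 <- compute_hemodynamics(solve_steady(mesh, cmd))
  expect_identical(m1$pressure_ratio, m2$pressure_ratio)
  expect_identical(m1$wssr, m2$wssr)
  expect_identical(m1$high_wss_area_mm2, m2$high_wss_area_mm2)
})
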