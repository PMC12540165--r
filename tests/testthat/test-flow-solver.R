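test_that("mesh construction scales with level and stays body-fitted", {
  g <- make_stenotic_vessel(representative_spec(), 300)
  m0 <- build_mesh(g, 0)
  m1 <- build_mesh(g, 1)
  expect_equal(m1$n_axial, round(1.5 * m0$n_axial))
  expect_equal(m1$n_radial, round(1.5 * m0$n_radial))
  expect_error(build_mesh(g, 5), "0..4")
  # outermost node follows the wall; straight tube exactly at the radius
  tg <- make_straight_tube(1.3, 20, 100)
  mt <- build_mesh(tg, 0)
  expect_lt(max(abs(mt$Rn[, mt$n_radial + 1] - 1.3)), 1e-12)
  # positive mapping Jacobian: all cell volumes positive
  cg <- stenocfd:::cell_geometry(m1)
  expect_true(all(cg$vol > 0))
  # near-wall radial spacing at most half the uniform spacing
  dr <- diff(m0$Rn[1, ])
  expect_lte(dr[length(dr)], 0.5 * m0$Rn[1, m0$n_radial + 1] / m0$n_radial)
})

test_that("solver reproduces Poiseuille flow in a straight tube", {
  case <- tube_case(radius = 1, window = 10, ext = 20, flow = 1)
  mesh <- build_mesh(case$geometry, 1)
  field <- solve_steady(mesh, case)
  expect_true(field$converged)
  ref <- poiseuille_reference(1, 10, 1)
  pp <- pressure_profile(field)
  dp <- approx(pp$x_mm, pp$pressure_pa, 20)$y - approx(pp$x_mm, pp$pressure_pa, 30)$y
  expect_equal(dp, ref$pressure_drop_pa, tolerance = 0.02)
  wp <- wall_shear_stress(field)
  win <- wp$x_mm >= 20 & wp$x_mm <= 30
  expect_equal(mean(wp$wss_pa[win]), ref$wss_pa, tolerance = 0.02)
  # centreline velocity reaches twice the mean in the developed region
  u_mean <- 1e-6 / (pi * 1e-6)
  i <- which.min(abs(field$cell_x[, 1] - 30e-3))
  expect_equal(field$u[i, 1], 2 * u_mean, tolerance = 0.01)
  # pressure is monotone non-increasing and ~0 at the outlet station
  expect_true(all(diff(pp$pressure_pa) <= 1e-10))
  expect_lt(abs(pp$pressure_pa[nrow(pp)]), 0.02 * ref$pressure_drop_pa)
  # mass conservation at every axial station
  expect_lt(max(abs(field$station_flux / 1e-6 - 1)), 1e-6)
})

test_that("zero-flow case returns the null solution", {
  case <- tube_case(flow = 0)
  field <- solve_steady(build_mesh(case$geometry, 0), case)
  expect_true(field$converged)
  expect_true(all(field$u == 0) && all(field$v == 0) && all(field$p == 0))
  wp <- wall_shear_stress(field)
  expect_true(all(wp$wss_pa == 0))
})

test_that("inlet Reynolds numbers at or above 2000 are refused", {
  geom <- make_straight_tube(2, 40, 100)
  case <- case_definition(geom, fixed_inlet_flow(25, 4), modality = "DSA")
  expect_error(solve_steady(build_mesh(geom, 0), case), "Reynolds")
})

test_that("creeping-flow pressure drop matches the lubrication integral", {
  # gentle stenosis: |dR/dx| < 0.1, Re < 1
  spec <- stenosis_spec(2, 2, 1.5, 10, inlet_extension = 15, outlet_extension = 15)
  g <- make_stenotic_vessel(spec, 600)
  q <- 0.003
  case <- case_definition(g, fixed_inlet_flow(q, 2 * g$radius_mm[1]),
                          modality = "DSA")
  mesh <- build_mesh(g, 1)
  field <- solve_steady(mesh, case)
  expect_lt(field$reynolds_inlet, 1)
  pp <- pressure_profile(field)
  x_from <- 3; x_to <- max(g$axial_mm) - 3
  dp_num <- approx(pp$x_mm, pp$pressure_pa, x_from)$y -
    approx(pp$x_mm, pp$pressure_pa, x_to)$y
  dp_lub <- lubrication_drop(g, q, from = x_from, to = x_to)
  expect_equal(dp_num, dp_lub, tolerance = 0.05)
  # pressure non-increasing upstream of the throat
  up <- pp$x_mm <= 20
  expect_true(all(diff(pp$pressure_pa[up]) <= 1e-10))

  # Stokes linearity: doubling the flow doubles WSS within 1%
  case2 <- case_definition(g, fixed_inlet_flow(2 * q, 2 * g$radius_mm[1]),
                           modality = "DSA")
  f2 <- solve_steady(mesh, case2)
  w1 <- wall_shear_stress(field); w2 <- wall_shear_stress(f2)
  mid <- w1$x_mm > 5 & w1$x_mm < max(g$axial_mm) - 5
  expect_equal(w2$wss_pa[mid] / w1$wss_pa[mid], rep(2, sum(mid)),
               tolerance = 0.01)
})

test_that("grid convergence of the developed-region pressure drop is ~2nd order", {
  case <- tube_case(radius = 1, window = 15, ext = 7.5, flow = 0.2,
                    n_samples = 200)
  an <- poiseuille_reference(1, 15, 0.2)$pressure_drop_pa
  err <- vapply(0:3, function(lev) {
    field <- solve_steady(build_mesh(case$geometry, lev), case)
    pp <- pressure_profile(field)
    dp <- approx(pp$x_mm, pp$pressure_pa, 10)$y -
      approx(pp$x_mm, pp$pressure_pa, 25)$y
    abs(dp - an)
  }, numeric(1))
  orders <- log(err[-4] / err[-1]) / log(1.5)
  expect_true(all(orders >= 1.8))
})

test_that("the solver is deterministic: identical inputs, identical fields", {
  g <- make_stenotic_vessel(representative_spec(), 300)
  case <- case_definition(g, fixed_inlet_flow(1.0, 2 * g$radius_mm[1]),
                          modality = "DSA")
  mesh <- build_mesh(g, 0)
  f1 <- solve_steady(mesh, case)
  f2 <- solve_steady(mesh, case)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$p, f2$p)
  expect_identical(f1$residual_history, f2$residual_history)
})

test_that("non-convergence raises a condition carrying the residual history", {
  g <- make_stenotic_vessel(representative_spec(), 300)
  case <- case_definition(g, fixed_inlet_flow(1.3, 2 * g$radius_mm[1]),
                          modality = "DSA")
  err <- tryCatch(solve_steady(build_mesh(g, 0), case, max_iterations = 70),
                  stenocfd_no_convergence = function(e) e)
  expect_s3_class(err, "stenocfd_no_convergence")
  expect_true(is.matrix(err$residual_history))
})

test_that("mesh independence study picks the coarsest level on a straight tube", {
  case <- tube_case(radius = 1.1, window = 10, ext = 11, flow = 0.4)
  planes <- measurement_planes(8, 24, c(14, 18), c(9, 13))
  out <- mesh_independence_study(case$geometry, case, levels = 0:1,
                                 planes = planes)
  expect_equal(out$chosen_level, 0)
  expect_lt(out$table$rel_change[1], 0.02)
  # a zero criterion can never be met in floating point
  expect_error(
    mesh_independence_study(case$geometry, case, levels = 0:1,
                            criterion = 0, planes = planes),
    class = "stenocfd_no_independence")
})

test_that("poiseuille_reference matches closed-form arithmetic", {
  ref <- poiseuille_reference(1, 10, 1, 0.0035)
  expect_equal(ref$pressure_drop_pa, 8 * 0.0035 * 0.01 * 1e-6 / (pi * 1e-12))
  expect_equal(ref$wss_pa, 4 * 0.0035 * 1e-6 / (pi * 1e-9))
  expect_equal(unlist(poiseuille_reference(1, 10, 0)), c(0, 0),
               ignore_attr = TRUE)
  # R^-3 scaling of WSS
  expect_equal(poiseuille_reference(2, 10, 1)$wss_pa, ref$wss_pa / 8)
})

test_that("field export writes valid VTK and residual CSV", {
  case <- tube_case(flow = 0.2, n_samples = 120)
  field <- solve_steady(build_mesh(case$geometry, 0), case)
  vtk <- tempfile(fileext = ".vtk")
  export_vtk(field, vtk)
  lines <- readLines(vtk, n = 6)
  expect_match(lines[1], "vtk DataFile")
  expect_match(lines[5], "DIMENSIONS")
  csv <- tempfile(fileext = ".csv")
  write_residual_history(field, csv)
  rh <- read.csv(csv)
  expect_named(rh, c("iteration", "continuity", "x_momentum", "r_momentum"))
  expect_lt(tail(rh$continuity, 1), 1e-5)
})
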