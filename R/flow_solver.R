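#' Body-fitted axisymmetric structured mesh
#'
#' Builds a structured mesh of the lumen half-plane: uniform axial stations
#' and radial lines following the (spline-interpolated) radius profile,
#' with smooth tanh grading that clusters cells toward the wall (near-wall
#' spacing below half the uniform spacing, standing in for near-wall prism
#' layers). Cell counts scale by 1.5x per refinement level in each
#' direction.
#'
#' @param geom a [vessel_geometry].
#' @param refinement_level integer in 0..4.
#' @param base_axial,base_radial level-0 cell counts (>= 100 axial, >= 8
#'   radial).
#' @param wall_clustering tanh grading strength (larger = stronger
#'   clustering at the wall).
#' @return An object of class `vessel_mesh` with node matrices `Xn`, `Rn`
#'   (mm; rows = axial index, cols = radial index), cell counts and the
#'   refinement level.
#' @export
build_mesh <- function(geom, refinement_level = 0L, base_axial = 120L,
                       base_radial = 10L, wall_clustering = 2) {
  stopifnot(inherits(geom, "vessel_geometry"))
  if (refinement_level < 0 || refinement_level > 4)
    stop("refinement_level must be in 0..4", call. = FALSE)
  if (base_axial < 100L || base_radial < 8L)
    stop("level-0 cell counts must be >= 100 axial and >= 8 radial", call. = FALSE)
  nx <- as.integer(round(base_axial * 1.5^refinement_level))
  ny <- as.integer(round(base_radial * 1.5^refinement_level))
  rfun <- stats::splinefun(geom$axial_mm, geom$radius_mm, method = "natural")
  x <- seq(min(geom$axial_mm), max(geom$axial_mm), length.out = nx + 1L)
  rw <- rfun(x)
  if (any(rw <= 0)) stop("interpolated radius non-positive", call. = FALSE)
  xi <- seq(0, 1, length.out = ny + 1L)
  eta <- tanh(wall_clustering * xi) / tanh(wall_clustering)
  structure(list(Xn = matrix(x, nx + 1L, ny + 1L),
                 Rn = outer(rw, eta),
                 n_axial = nx, n_radial = ny,
                 refinement_level = as.integer(refinement_level),
                 geometry = geom),
            class = "vessel_mesh")
}

#' @export
print.vessel_mesh <- function(x, ...) {
  cat(sprintf("<vessel_mesh> %d x %d cells (level %d), span %.1f mm\n",
              x$n_axial, x$n_radial, x$refinement_level,
              diff(range(x$Xn[, 1]))))
  invisible(x)
}

#' Solve steady incompressible flow with SIMPLE
#'
#' Finite-volume solution of the steady incompressible Newtonian
#' Navier-Stokes equations in the axisymmetric lumen: SIMPLE
#' pressure-velocity coupling with Rhie-Chow mass fluxes on a colocated
#' body-fitted grid, first-order upwind convection with a deferred
#' second-order-upwind correction active at convergence, uniform ("plug")
#' velocity inlet matching the case flow rate, no-slip rigid wall, symmetry
#' axis, and a zero-gauge-pressure outlet with zero-gradient velocity.
#' Convergence requires the normalized continuity and both momentum
#' residuals to fall below `tolerance` (residual norms are L1 imbalances
#' normalized by their value at outer iteration 10).
#'
#' The laminar model is only accepted for inlet Reynolds numbers below
#' 2000.
#'
#' @param mesh a [build_mesh] result.
#' @param case a [case_definition].
#' @param tolerance normalized residual target (default 1e-5).
#' @param max_iterations outer iteration cap.
#' @param relax_velocity,relax_pressure under-relaxation factors.
#' @param first_order_iterations iterations before the second-order
#'   deferred correction is activated.
#' @return An object of class `flow_field`: cell-centred `u`, `v` (m/s) and
#'   `p` (Pa gauge) matrices (axial x radial), cell centroids and volumes,
#'   `station_flux` (m^3/s through every axial station), normalized
#'   `residual_history`, `converged`, `reynolds_inlet`, plus the mesh and
#'   case. Non-convergence raises a condition of class
#'   `stenocfd_no_convergence` carrying the residual history.
#' @export
solve_steady <- function(mesh, case, tolerance = 1e-5, max_iterations = 6000L,
                         relax_velocity = 0.7, relax_pressure = 0.3,
                         first_order_iterations = 50L) {
  stopifnot(inherits(mesh, "vessel_mesh"), inherits(case, "case_definition"))
  fl <- case$fluid
  q_m3_s <- case$inlet$flow_rate_ml_s * 1e-6
  r_in_m <- mesh$Rn[1, ncol(mesh$Rn)] * 1e-3
  u_in <- q_m3_s / (pi * r_in_m^2)
  re <- fl$density * u_in * 2 * r_in_m / fl$dynamic_viscosity
  if (re >= 2000)
    stop(sprintf(paste0("inlet Reynolds number %.0f >= 2000: the steady ",
                        "laminar model is not valid for this case"), re),
         call. = FALSE)
  if (q_m3_s == 0) {
    nx <- mesh$n_axial; ny <- mesh$n_radial
    zero <- matrix(0, nx, ny)
    cellgeo <- cell_geometry(mesh)
    out <- structure(list(u = zero, v = zero, p = zero,
                          cell_x = cellgeo$cx, cell_r = cellgeo$cr,
                          cell_volume = cellgeo$vol,
                          station_flux = rep(0, nx + 1L),
                          residual_history = matrix(0, 1, 3,
                            dimnames = list(NULL, c("continuity", "x_momentum", "r_momentum"))),
                          iterations = 0L, converged = TRUE,
                          reynolds_inlet = 0, mesh = mesh, case = case),
                     class = "flow_field")
    return(out)
  }
  res <- .simple_solve_cpp(mesh$Xn * 1e-3, mesh$Rn * 1e-3,
                           fl$density, fl$dynamic_viscosity, u_in,
                           tolerance, as.integer(max_iterations),
                           relax_velocity, relax_pressure,
                           as.integer(first_order_iterations),
                           5L, 1e-7, 2000L)
  colnames(res$residual_history) <- c("continuity", "x_momentum", "r_momentum")
  if (!res$converged) {
    cond <- errorCondition(
      sprintf("SIMPLE did not converge within %d iterations (final residuals: %s)",
              max_iterations,
              paste(signif(utils::tail(res$residual_history, 1), 3), collapse = ", ")),
      class = "stenocfd_no_convergence",
      residual_history = res$residual_history)
    stop(cond)
  }
  structure(c(res, list(reynolds_inlet = re, mesh = mesh, case = case)),
            class = "flow_field")
}

# cell centroids/volumes (mm-based mesh -> metres), used for the zero-flow
# shortcut; mirrors the C++ computation
cell_geometry <- function(mesh) {
  Xn <- mesh$Xn * 1e-3; Rn <- mesh$Rn * 1e-3
  nx <- mesh$n_axial; ny <- mesh$n_radial
  cx <- matrix(0, nx, ny); cr <- matrix(0, nx, ny); vol <- matrix(0, nx, ny)
  for (j in seq_len(ny)) {
    x4 <- cbind(Xn[-(nx + 1L), j], Xn[-1L, j], Xn[-1L, j + 1L], Xn[-(nx + 1L), j + 1L])
    r4 <- cbind(Rn[-(nx + 1L), j], Rn[-1L, j], Rn[-1L, j + 1L], Rn[-(nx + 1L), j + 1L])
    a1 <- 0.5 * ((x4[, 2] - x4[, 1]) * (r4[, 3] - r4[, 1]) -
                   (x4[, 3] - x4[, 1]) * (r4[, 2] - r4[, 1]))
    a2 <- 0.5 * ((x4[, 3] - x4[, 1]) * (r4[, 4] - r4[, 1]) -
                   (x4[, 4] - x4[, 1]) * (r4[, 3] - r4[, 1]))
    cx[, j] <- (a1 * (x4[, 1] + x4[, 2] + x4[, 3]) + a2 * (x4[, 1] + x4[, 3] + x4[, 4])) /
      (3 * (a1 + a2))
    cr[, j] <- (a1 * (r4[, 1] + r4[, 2] + r4[, 3]) + a2 * (r4[, 1] + r4[, 3] + r4[, 4])) /
      (3 * (a1 + a2))
    vol[, j] <- a1 * (r4[, 1] + r4[, 2] + r4[, 3]) / 3 +
      a2 * (r4[, 1] + r4[, 3] + r4[, 4]) / 3
  }
  list(cx = cx, cr = cr, vol = vol)
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "<flow_field> %d x %d cells, Re_inlet %.0f, %d iterations, %s\n",
    nrow(x$u), ncol(x$u), x$reynolds_inlet, x$iterations,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Wall shear stress profile
#'
#' Extracts the wall shear stress magnitude `mu * |du_t/dn|` at every axial
#' wall segment using a one-sided second-order difference along the
#' body-fitted wall normal (quadratic through the wall and the two
#' wall-adjacent cell rows).
#'
#' @param field a converged [solve_steady] flow field.
#' @return An object of class `wall_shear_profile`: data frame with
#'   `arc_mm` (wall arc length), `x_mm`, `radius_mm` and `wss_pa`.
#' @export
wall_shear_stress <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  if (!isTRUE(field$converged))
    stop("wall shear stress requires a converged flow field", call. = FALSE)
  mesh <- field$mesh
  mu <- field$case$fluid$dynamic_viscosity
  nx <- mesh$n_axial; ny <- mesh$n_radial
  Xw <- mesh$Xn[, ny + 1L] * 1e-3; Rw <- mesh$Rn[, ny + 1L] * 1e-3
  ax <- diff(Xw); ar <- diff(Rw)
  len <- sqrt(ax^2 + ar^2)
  tx <- ax / len; tr <- ar / len
  ninx <- ar / len; ninr <- -ax / len           # inward normal
  mx <- (Xw[-1L] + Xw[-(nx + 1L)]) / 2
  mr <- (Rw[-1L] + Rw[-(nx + 1L)]) / 2
  if (all(field$u == 0)) {
    wss <- rep(0, nx)
  } else {
    d1 <- (field$cell_x[, ny] - mx) * ninx + (field$cell_r[, ny] - mr) * ninr
    d2 <- (field$cell_x[, ny - 1L] - mx) * ninx + (field$cell_r[, ny - 1L] - mr) * ninr
    u1 <- field$u[, ny] * tx + field$v[, ny] * tr
    u2 <- field$u[, ny - 1L] * tx + field$v[, ny - 1L] * tr
    wss <- mu * abs((u1 * d2^2 - u2 * d1^2) / (d1 * d2 * (d2 - d1)))
  }
  out <- data.frame(arc_mm = (cumsum(len) - len / 2) * 1e3,
                    x_mm = mx * 1e3, radius_mm = mr * 1e3, wss_pa = wss)
  class(out) <- c("wall_shear_profile", "data.frame")
  out
}

#' Axial profile of area-averaged gauge pressure
#'
#' Cross-section (volume-weighted) mean gauge pressure at every axial cell
#' station.
#'
#' @param field a converged [solve_steady] flow field.
#' @return Data frame with `x_mm` and `pressure_pa` (gauge), class
#'   `pressure_profile`.
#' @export
pressure_profile <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  if (!isTRUE(field$converged))
    stop("pressure profile requires a converged flow field", call. = FALSE)
  pbar <- rowSums(field$p * field$cell_volume) / rowSums(field$cell_volume)
  out <- data.frame(x_mm = field$cell_x[, 1] * 1e3, pressure_pa = pbar)
  class(out) <- c("pressure_profile", "data.frame")
  out
}

#' Hagen-Poiseuille analytic reference
#'
#' Closed-form developed-flow pressure drop and wall shear stress for a
#' straight tube: `dP = 8 mu L Q / (pi R^4)` and `WSS = 4 mu Q / (pi R^3)`.
#'
#' @param radius tube radius, mm.
#' @param length tube length, mm.
#' @param flow volumetric flow, mL/s.
#' @param viscosity dynamic viscosity, Pa.s.
#' @return List with `pressure_drop_pa` and `wss_pa`.
#' @export
poiseuille_reference <- function(radius, length, flow, viscosity = 0.0035) {
  if (any(c(radius, length, viscosity) <= 0) || flow < 0)
    stop("radius, length, viscosity must be positive and flow >= 0", call. = FALSE)
  R <- radius * 1e-3; L <- length * 1e-3; Q <- flow * 1e-6
  list(pressure_drop_pa = 8 * viscosity * L * Q / (pi * R^4),
       wss_pa = 4 * viscosity * Q / (pi * R^3))
}

#' Mesh-independence study monitored on PR
#'
#' Solves the case at successive refinement levels and monitors the
#' translesional pressure ratio (PR); the solution is deemed
#' mesh-independent at the first level whose PR differs from the next finer
#' level by less than `criterion` (default 2\% relative).
#'
#' @param geom a [vessel_geometry].
#' @param case a [case_definition] (its geometry is ignored in favour of
#'   `geom`).
#' @param levels increasing refinement levels to run (>= 2).
#' @param criterion relative PR-change threshold (default 0.02).
#' @param planes a [measurement_planes]; default derived from the measured
#'   morphology via [default_planes].
#' @param ... passed to [solve_steady].
#' @return List with `chosen_level` and a data frame `table` (`level`,
#'   `n_cells`, `pr`, `rel_change` vs the next finer level). If no level
#'   meets the criterion an error of class `stenocfd_no_independence`
#'   carrying the table is raised.
#' @export
mesh_independence_study <- function(geom, case, levels = 0:3, criterion = 0.02,
                                    planes = NULL, ...) {
  stopifnot(inherits(geom, "vessel_geometry"))
  if (length(levels) < 2L) stop("at least two levels are required", call. = FALSE)
  levels <- sort(as.integer(levels))
  if (is.null(planes)) planes <- default_planes(geom)
  pr <- numeric(length(levels)); ncells <- integer(length(levels))
  for (k in seq_along(levels)) {
    mesh <- build_mesh(geom, levels[k])
    field <- solve_steady(mesh, case, ...)
    pr[k] <- pressure_ratio(pressure_profile(field), planes)
    ncells[k] <- mesh$n_axial * mesh$n_radial
  }
  rel <- c(abs(diff(pr)) / abs(pr[-length(pr)]), NA_real_)
  tab <- data.frame(level = levels, n_cells = ncells, pr = pr, rel_change = rel)
  ok <- which(rel < criterion)
  if (!length(ok)) {
    cond <- errorCondition(
      sprintf("PR mesh-independence criterion %.3g never met", criterion),
      class = "stenocfd_no_independence", table = tab)
    stop(cond)
  }
  list(chosen_level = levels[ok[1]], table = tab)
}

#' Export a flow field as legacy VTK (structured grid)
#'
#' ASCII legacy VTK with the mesh nodes as a structured grid and
#' cell-centred velocity vectors and pressure scalars.
#'
#' @param field a [solve_steady] flow field.
#' @param path output `.vtk` path.
#' @return The path, invisibly.
#' @export
export_vtk <- function(field, path) {
  stopifnot(inherits(field, "flow_field"))
  mesh <- field$mesh
  nx <- mesh$n_axial; ny <- mesh$n_radial
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("# vtk DataFile Version 3.0",
               "stenocfd axisymmetric flow field (x, r, 0), SI units",
               "ASCII", "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", nx + 1L, ny + 1L),
               sprintf("POINTS %d double", (nx + 1L) * (ny + 1L))), con)
  for (j in seq_len(ny + 1L))
    writeLines(sprintf("%.9g %.9g 0", mesh$Xn[, j] * 1e-3, mesh$Rn[, j] * 1e-3), con)
  writeLines(c(sprintf("CELL_DATA %d", nx * ny),
               "VECTORS velocity double"), con)
  for (j in seq_len(ny))
    writeLines(sprintf("%.9g %.9g 0", field$u[, j], field$v[, j]), con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  for (j in seq_len(ny))
    writeLines(sprintf("%.9g", field$p[, j]), con)
  invisible(path)
}

#' Write the residual history as CSV
#'
#' @param field a [solve_steady] flow field.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_residual_history <- function(field, path) {
  stopifnot(inherits(field, "flow_field"))
  df <- as.data.frame(field$residual_history)
  df <- cbind(iteration = seq_len(nrow(df)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
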