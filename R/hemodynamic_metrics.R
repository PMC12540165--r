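#' Measurement planes and windows for hemodynamic metrics
#'
#' Axial locations where PR and WSSR are sampled: a proximal plane, a
#' distal plane, the stenotic throat window and the proximal reference
#' window.
#'
#' @param proximal_plane,distal_plane axial positions, mm.
#' @param throat_window,proximal_reference_window axial intervals
#'   `c(start, end)`, mm.
#' @return An object of class `measurement_planes`.
#' @export
measurement_planes <- function(proximal_plane, distal_plane, throat_window,
                               proximal_reference_window) {
  stopifnot(length(throat_window) == 2L, length(proximal_reference_window) == 2L)
  if (!(proximal_plane < throat_window[1] && throat_window[2] < distal_plane))
    stop("planes must be ordered proximal < throat window < distal", call. = FALSE)
  if (proximal_reference_window[2] > throat_window[1])
    stop("proximal reference window must lie upstream of the throat window",
         call. = FALSE)
  structure(list(proximal_plane = proximal_plane, distal_plane = distal_plane,
                 throat_window = throat_window,
                 proximal_reference_window = proximal_reference_window),
            class = "measurement_planes")
}

#' Default plane placement around a detected lesion
#'
#' Places the proximal plane one proximal diameter upstream of the lesion
#' window (with the proximal reference window of one diameter width centred
#' there), the distal plane three diameters downstream (past desk-scale
#' reattachment), and the throat window as the central third of the lesion
#' window. All positions are clamped inside the geometry span.
#'
#' @param geom a [vessel_geometry].
#' @param morph optional precomputed [measure_morphology] result.
#' @return A [measurement_planes].
#' @export
default_planes <- function(geom, morph = NULL) {
  stopifnot(inherits(geom, "vessel_geometry"))
  if (is.null(morph)) morph <- measure_morphology(geom)
  if (morph$no_lesion)
    stop("no lesion detected; supply measurement_planes explicitly", call. = FALSE)
  d <- morph$proximal_diameter
  x1 <- morph$lesion_window[1]; x2 <- morph$lesion_window[2]
  span <- range(geom$axial_mm)
  clamp <- function(x) pmin(pmax(x, span[1] + 1e-6), span[2] - 1e-6)
  third <- (x2 - x1) / 3
  measurement_planes(
    proximal_plane = clamp(x1 - d),
    distal_plane = clamp(x2 + 3 * d),
    throat_window = clamp(c(x1 + third, x2 - third)),
    proximal_reference_window = clamp(c(x1 - 1.5 * d, x1 - 0.5 * d)))
}

#' Translesional pressure ratio (PR)
#'
#' The ratio of mean pressure distal to the stenosis to mean pressure
#' proximal to it, `PR = P_distal / P_proximal`, on absolute pressures.
#' Gauge CFD pressures are shifted so that the inlet-station mean equals
#' `reference_inlet_pressure` (default 13332 Pa, i.e. 100 mmHg), which
#' makes the ratio well defined and reproducible.
#'
#' @param profile a [pressure_profile].
#' @param planes a [measurement_planes].
#' @param reference_inlet_pressure absolute inlet pressure, Pa; must exceed
#'   the maximum gauge pressure drop.
#' @return PR (unitless, in (0, 1] for positive flow).
#' @export
pressure_ratio <- function(profile, planes, reference_inlet_pressure = 13332) {
  stopifnot(inherits(profile, "pressure_profile"),
            inherits(planes, "measurement_planes"))
  rng <- range(profile$x_mm)
  if (planes$proximal_plane < rng[1] || planes$distal_plane > rng[2])
    stop("measurement planes fall outside the solved domain", call. = FALSE)
  if (reference_inlet_pressure <= diff(range(profile$pressure_pa)))
    stop("reference_inlet_pressure must exceed the maximum gauge pressure drop",
         call. = FALSE)
  shift <- reference_inlet_pressure - profile$pressure_pa[1]
  pa <- profile$pressure_pa + shift
  p_prox <- stats::approx(profile$x_mm, pa, planes$proximal_plane)$y
  p_dist <- stats::approx(profile$x_mm, pa, planes$distal_plane)$y
  p_dist / p_prox
}

#' Wall shear stress ratio (WSSR)
#'
#' Arc-length-weighted mean wall shear stress over the stenotic throat
#' window divided by the same over the proximal reference segment,
#' `WSSR = WSS_stenosis / WSS_proximal`.
#'
#' @param wall_profile a [wall_shear_stress] profile.
#' @param planes a [measurement_planes].
#' @return WSSR (unitless).
#' @export
wssr <- function(wall_profile, planes) {
  stopifnot(inherits(wall_profile, "wall_shear_profile"),
            inherits(planes, "measurement_planes"))
  m_throat <- window_mean(wall_profile, planes$throat_window)
  m_prox <- window_mean(wall_profile, planes$proximal_reference_window)
  if (!is.finite(m_prox) || m_prox == 0)
    stop("proximal reference WSS is zero; WSSR undefined", call. = FALSE)
  m_throat / m_prox
}

# trapezoidal arc-weighted mean of wss over an axial window
window_mean <- function(wp, window) {
  sel <- wp$x_mm >= window[1] & wp$x_mm <= window[2]
  if (sum(sel) < 2L)
    stop("measurement window contains fewer than 2 wall samples", call. = FALSE)
  s <- wp$arc_mm[sel]; w <- wp$wss_pa[sel]
  sum(diff(s) * (w[-1] + w[-sum(sel)]) / 2) / (s[sum(sel)] - s[1])
}

#' Luminal area exposed to high wall shear stress
#'
#' Surface-of-revolution area where WSS exceeds the threshold:
#' `integral of 2 pi R(s) [WSS(s) > tau] ds` over the wall, trapezoidal in
#' arc length. The default threshold of 3.0 Pa marks abnormally elevated
#' shear in intracranial and carotid arteries.
#'
#' @param wall_profile a [wall_shear_stress] profile.
#' @param threshold WSS threshold, Pa (> 0).
#' @param window optional axial window `c(start, end)` in mm restricting the
#'   integration (default: the whole wall).
#' @return High-WSS area, mm^2.
#' @export
high_wss_area <- function(wall_profile, threshold = 3, window = NULL) {
  stopifnot(inherits(wall_profile, "wall_shear_profile"))
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  wp <- wall_profile
  if (!is.null(window)) {
    # clip at the exact window ends: interpolate wall samples there so the
    # bounding half-segments are not dropped
    sel <- wp$x_mm > window[1] & wp$x_mm < window[2]
    ends <- lapply(window, function(x0) {
      if (x0 < min(wp$x_mm) || x0 > max(wp$x_mm)) return(NULL)
      data.frame(arc_mm = stats::approx(wp$x_mm, wp$arc_mm, x0)$y,
                 x_mm = x0,
                 radius_mm = stats::approx(wp$x_mm, wp$radius_mm, x0)$y,
                 wss_pa = stats::approx(wp$x_mm, wp$wss_pa, x0)$y)
    })
    wp <- rbind(ends[[1]], as.data.frame(wp)[sel, ], ends[[2]])
  }
  f <- 2 * pi * wp$radius_mm * (wp$wss_pa > threshold)
  s <- wp$arc_mm
  sum(diff(s) * (f[-1] + f[-length(f)]) / 2)
}

#' All four hemodynamic parameters for one case
#'
#' Convenience wrapper computing flow rate, PR, WSSR and high-WSS area from
#' a converged flow field.
#'
#' @param field a [solve_steady] flow field.
#' @param planes optional [measurement_planes]; default [default_planes] of
#'   the case geometry.
#' @param threshold high-WSS threshold, Pa.
#' @param reference_inlet_pressure absolute inlet pressure, Pa.
#' @return An object of class `hemodynamic_metrics`: list with
#'   `pressure_ratio`, `wssr`, `high_wss_area_mm2`, `flow_rate_ml_s`,
#'   `reference_inlet_pressure`.
#' @export
compute_hemodynamics <- function(field, planes = NULL, threshold = 3,
                                 reference_inlet_pressure = 13332) {
  stopifnot(inherits(field, "flow_field"))
  if (is.null(planes)) planes <- default_planes(field$case$geometry)
  wp <- wall_shear_stress(field)
  pp <- pressure_profile(field)
  out <- list(pressure_ratio = pressure_ratio(pp, planes, reference_inlet_pressure),
              wssr = wssr(wp, planes),
              high_wss_area_mm2 = high_wss_area(wp, threshold),
              flow_rate_ml_s = field$case$inlet$flow_rate_ml_s,
              reference_inlet_pressure = reference_inlet_pressure)
  class(out) <- "hemodynamic_metrics"
  out
}

#' @export
print.hemodynamic_metrics <- function(x, ...) {
  cat(sprintf(
    "<hemodynamics> Q %.3f mL/s, PR %.4f, WSSR %.2f, high-WSS area %.1f mm^2\n",
    x$flow_rate_ml_s, x$pressure_ratio, x$wssr, x$high_wss_area_mm2))
  invisible(x)
}
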