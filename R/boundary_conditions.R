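#' Blood fluid properties
#'
#' Blood is modelled as an incompressible Newtonian fluid; defaults are the
#' standard haemodynamic values density 1060 kg/m^3 and dynamic viscosity
#' 0.0035 Pa.s.
#'
#' @param density kg/m^3.
#' @param dynamic_viscosity Pa.s.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1060, dynamic_viscosity = 0.0035) {
  if (density <= 0 || dynamic_viscosity <= 0)
    stop("density and viscosity must be positive", call. = FALSE)
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

new_inlet_flow <- function(flow_rate_ml_s, inlet_diameter_mm, source) {
  area_mm2 <- pi * inlet_diameter_mm^2 / 4
  structure(list(flow_rate_ml_s = flow_rate_ml_s,
                 mean_velocity_mm_s = 1000 * flow_rate_ml_s / area_mm2,
                 inlet_diameter_mm = inlet_diameter_mm,
                 source = source),
            class = "inlet_flow")
}

#' Inlet flow from a TIMI frame count
#'
#' Converts a contrast-transit frame count measured on DSA into a mean
#' inlet velocity and flow rate: `velocity = path_length / (frame_count /
#' frame_rate)` and `Q = velocity * pi * d^2 / 4`. The DSA acquisition rate
#' defaults to 6 frames/s.
#'
#' @param path_length centreline contrast path length, mm.
#' @param frame_count TIMI frame count (may be fractional).
#' @param frame_rate acquisition rate, frames/s.
#' @param inlet_diameter inlet diameter, mm.
#' @return An `inlet_flow` with source `"TIMI"`; flow rate in mL/s.
#' @export
timi_inlet_flow <- function(path_length, frame_count, frame_rate = 6,
                            inlet_diameter) {
  if (any(c(path_length, frame_count, frame_rate, inlet_diameter) <= 0))
    stop("all TIMI inputs must be positive", call. = FALSE)
  v_mm_s <- path_length / (frame_count / frame_rate)
  q_ml_s <- v_mm_s * pi * inlet_diameter^2 / 4 / 1000
  new_inlet_flow(q_ml_s, inlet_diameter, "TIMI")
}

#' Inlet flow from a TCD mean velocity
#'
#' Converts a transcranial Doppler mean velocity (cm/s) into an inlet flow
#' rate through a circular inlet of the given diameter.
#'
#' @param mean_velocity TCD mean velocity, cm/s.
#' @param inlet_diameter inlet diameter, mm.
#' @return An `inlet_flow` with source `"TCD"`; flow rate in mL/s.
#' @export
tcd_inlet_flow <- function(mean_velocity, inlet_diameter) {
  if (any(c(mean_velocity, inlet_diameter) <= 0))
    stop("velocity and diameter must be positive", call. = FALSE)
  v_mm_s <- mean_velocity * 10
  q_ml_s <- v_mm_s * pi * inlet_diameter^2 / 4 / 1000
  new_inlet_flow(q_ml_s, inlet_diameter, "TCD")
}

#' Fixed inlet flow rate
#'
#' Prescribes the inlet volumetric flow rate directly (used for analytic
#' oracles and fixed-flow sweeps).
#'
#' @param flow_rate mL/s.
#' @param inlet_diameter inlet diameter, mm.
#' @return An `inlet_flow` with source `"fixed"`.
#' @export
fixed_inlet_flow <- function(flow_rate, inlet_diameter) {
  if (flow_rate < 0 || inlet_diameter <= 0)
    stop("flow_rate must be >= 0 and diameter positive", call. = FALSE)
  new_inlet_flow(flow_rate, inlet_diameter, "fixed")
}

#' @export
print.inlet_flow <- function(x, ...) {
  cat(sprintf("<inlet_flow> %.4f mL/s (%.1f mm/s through %.2f mm, %s)\n",
              x$flow_rate_ml_s, x$mean_velocity_mm_s, x$inlet_diameter_mm,
              x$source))
  invisible(x)
}

#' Murray cube-law outlet flow split
#'
#' Allocates outlet flow fractions proportional to the cube of the outlet
#' diameters: `fraction_i = d_i^3 / sum(d_j^3)`.
#'
#' @param outlet_diameters outlet diameters, mm (all positive).
#' @return An object of class `outlet_split` with `outlet_diameters` and
#'   `fractions` (summing to 1).
#' @export
murray_outlet_split <- function(outlet_diameters) {
  if (length(outlet_diameters) < 1L)
    stop("at least one outlet diameter is required", call. = FALSE)
  if (any(!is.finite(outlet_diameters)) || any(outlet_diameters <= 0))
    stop("outlet diameters must be positive", call. = FALSE)
  f <- outlet_diameters^3 / sum(outlet_diameters^3)
  structure(list(outlet_diameters = outlet_diameters, fractions = f),
            class = "outlet_split")
}

#' Case definition: geometry + boundary conditions + modality
#'
#' Bundles everything one steady simulation needs: the lumen geometry, the
#' inlet flow, the outlet split, the fluid constants and the imaging
#' modality label. A `CMD` case must carry a TIMI-sourced inlet (the hybrid
#' model is CTA geometry driven by the DSA-derived flow).
#'
#' @param geometry a [vessel_geometry].
#' @param inlet an `inlet_flow`.
#' @param split an [murray_outlet_split] result, or `NULL` for a single
#'   outlet.
#' @param fluid a [fluid_properties].
#' @param modality `"DSA"`, `"CTA"` or `"CMD"`.
#' @return An object of class `case_definition`.
#' @export
case_definition <- function(geometry, inlet, split = NULL,
                            fluid = fluid_properties(),
                            modality = c("DSA", "CTA", "CMD")) {
  modality <- match.arg(modality)
  stopifnot(inherits(geometry, "vessel_geometry"), inherits(inlet, "inlet_flow"),
            inherits(fluid, "fluid_properties"))
  if (!is.null(split)) stopifnot(inherits(split, "outlet_split"))
  if (modality == "CMD" && inlet$source != "TIMI")
    stop("a CMD case requires a TIMI-sourced (DSA-derived) inlet flow",
         call. = FALSE)
  structure(list(geometry = geometry, inlet = inlet, split = split,
                 fluid = fluid, modality = modality),
            class = "case_definition")
}

#' Compose the hybrid CMD case
#'
#' The CMD model uses the same geometry and outlet conditions as the CTA
#' case but replaces the inlet flow rate by the DSA-derived TIMI frame
#' count value. The inlet velocity is recomputed for the CTA inlet area so
#' the prescribed volumetric flow is the DSA one.
#'
#' @param cta_case a `case_definition` with modality `"CTA"`.
#' @param dsa_inlet an `inlet_flow` with source `"TIMI"`.
#' @return A `case_definition` with modality `"CMD"`.
#' @export
compose_cmd <- function(cta_case, dsa_inlet) {
  stopifnot(inherits(cta_case, "case_definition"), inherits(dsa_inlet, "inlet_flow"))
  if (dsa_inlet$source != "TIMI")
    stop("CMD requires a TIMI-sourced inlet; got source '", dsa_inlet$source,
         "'", call. = FALSE)
  inlet <- new_inlet_flow(dsa_inlet$flow_rate_ml_s,
                          cta_case$inlet$inlet_diameter_mm, "TIMI")
  case_definition(cta_case$geometry, inlet, cta_case$split, cta_case$fluid,
                  modality = "CMD")
}
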