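#' Configuration of the synthetic ICAS cohort
#'
#' Defines the virtual cohort the pipeline is exercised on: territory
#' strata sizes and per-territory diameter and inlet-velocity
#' distributions (anchored to published ICAS cohort morphology), the
#' stenosis-severity and lesion-length distributions, and the
#' inter-modality measurement-noise model (radial segmentation noise per
#' modality, and a coefficient of variation on the measured inlet
#' velocity).
#'
#' Distributions are truncated normals. Severity is truncated to 10-85\%
#' diameter stenosis: the generator's validity envelope for the steady
#' laminar solver.
#'
#' @param n_per_territory named counts for MCA/ICA/VA (default 31/6/3).
#' @param territory_params data frame with columns `territory`,
#'   `prox_mean`, `prox_sd`, `dist_mean`, `dist_sd`, `vel_mean`, `vel_sd`
#'   (diameters mm, velocities cm/s).
#' @param ds_pct mean and SD of diameter stenosis, \%.
#' @param ds_range truncation range for DS\%.
#' @param lesion_length mean and SD, mm.
#' @param lesion_length_range truncation range, mm.
#' @param modality_radial_noise_sd per-sample radial segmentation noise SD,
#'   mm.
#' @param smoothing_window_mm smoothing window applied to the radial noise.
#' @param flow_measurement_noise_cv coefficient of variation of the
#'   measured (TIMI / TCD) velocity around the true velocity.
#' @param seed integer master seed.
#' @param n_geometry_samples axial samples per generated lumen.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(
    n_per_territory = c(MCA = 31L, ICA = 6L, VA = 3L),
    territory_params = data.frame(
      territory = c("MCA", "ICA", "VA"),
      prox_mean = c(2.19, 3.26, 3.95), prox_sd = c(0.48, 0.87, 0.89),
      dist_mean = c(2.00, 2.78, 3.46), dist_sd = c(0.55, 0.74, 0.49),
      vel_mean = c(34, 28, 11), vel_sd = c(15, 10, 4)),
    ds_pct = c(mean = 58.95, sd = 19.84),
    ds_range = c(10, 85),
    lesion_length = c(mean = 4.28, sd = 2.18),
    lesion_length_range = c(1.5, 12),
    modality_radial_noise_sd = 0.05,
    smoothing_window_mm = 1.0,
    flow_measurement_noise_cv = 0.10,
    seed = 1L,
    n_geometry_samples = 400L) {
  stopifnot(all(c("MCA", "ICA", "VA") %in% names(n_per_territory)),
            all(n_per_territory >= 0),
            all(c("territory", "prox_mean", "prox_sd", "dist_mean", "dist_sd",
                  "vel_mean", "vel_sd") %in% names(territory_params)),
            ds_pct[["sd"]] >= 0, lesion_length[["sd"]] >= 0,
            modality_radial_noise_sd >= 0, flow_measurement_noise_cv >= 0)
  if (ds_range[1] <= 0 || ds_range[2] >= 95)
    stop("ds_range must lie within (0, 95)", call. = FALSE)
  structure(list(n_per_territory = n_per_territory,
                 territory_params = territory_params,
                 ds_pct = ds_pct, ds_range = ds_range,
                 lesion_length = lesion_length,
                 lesion_length_range = lesion_length_range,
                 modality_radial_noise_sd = modality_radial_noise_sd,
                 smoothing_window_mm = smoothing_window_mm,
                 flow_measurement_noise_cv = flow_measurement_noise_cv,
                 seed = as.integer(seed),
                 n_geometry_samples = as.integer(n_geometry_samples)),
            class = "cohort_config")
}

# crude translesional pressure-drop estimate (Pa) for generator feasibility:
# lubrication integral over the cosine lesion plus a Borda-Carnot expansion
# loss; diameters/length mm, velocity cm/s through the proximal section
estimate_drop_pa <- function(prox, dist, mld, len, vel_cm_s) {
  mu <- 0.0035; rho <- 1060
  q <- vel_cm_s * 10 * pi * prox^2 / 4 / 1000 * 1e-6       # m^3/s
  xs <- seq(-0.5, 0.5, length.out = 101)
  rbase <- (prox + (dist - prox) * (xs + 0.5)) / 2
  rmid <- (prox + dist) / 4
  delta <- rmid - mld / 2
  r_m <- pmax(rbase - delta * (1 + cos(2 * pi * xs)) / 2, mld / 4) * 1e-3
  visc <- 8 * mu * q / pi * sum((len * 1e-3 / 100) / r_m^4)
  v_throat <- q / (pi * (mld / 2 * 1e-3)^2)
  v_dist <- q / (pi * (dist / 2 * 1e-3)^2)
  visc + rho / 2 * (v_throat - v_dist)^2
}

# truncated-normal draw by rejection; sd = 0 degenerates to the mean
rtruncnorm1 <- function(mean, sd, lower, upper, max_attempts = 100L) {
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate draw outside truncation range", call. = FALSE)
    return(mean)
  }
  for (i in seq_len(max_attempts)) {
    x <- rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  stop("truncated-normal sampling failed after 100 attempts", call. = FALSE)
}

#' Sample the lesion truths of a synthetic cohort
#'
#' Seeded, reproducible draws of one lesion specification per case:
#' territory, proximal/distal reference diameters, diameter stenosis,
#' minimal lumen diameter, lesion length, true inlet velocity, and the
#' contrast path length used by the TIMI converter (80\% of the generated
#' vessel span). DS\% draws that would make the MLD reach the distal
#' reference diameter are resampled (up to 100 attempts).
#'
#' @param config a [cohort_config].
#' @return Data frame of class `cohort_truth` (one row per case) with
#'   attribute `"config"`.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  tp <- config$territory_params
  territories <- rep(names(config$n_per_territory), config$n_per_territory)
  n <- length(territories)
  with_local_seed(config$seed, {
    rows <- lapply(seq_len(n), function(i) {
      terr <- territories[i]
      p <- tp[tp$territory == terr, ]
      prox <- rtruncnorm1(p$prox_mean, p$prox_sd, 1.0, 6.0)
      # distal reference additionally bounded to an anatomical taper ratio
      dist <- NA_real_
      for (att in seq_len(100L)) {
        cand <- rtruncnorm1(p$dist_mean, p$dist_sd, 0.8, 6.0)
        if (cand >= 0.55 * prox && cand <= 1.1 * prox) { dist <- cand; break }
      }
      if (is.na(dist)) stop("could not sample a feasible distal diameter",
                            call. = FALSE)
      # severity, length and velocity are drawn jointly: a lesion is accepted
      # only if some velocity in its truncation range keeps the estimated
      # translesional drop physiologically representable (flow through a
      # severe stenosis is limited by the available perfusion pressure);
      # the estimate carries headroom for the configured noise
      cv <- config$flow_measurement_noise_cv
      ds <- NA_real_; len <- NA_real_; vel <- NA_real_
      for (att in seq_len(100L)) {
        ds_c <- rtruncnorm1(config$ds_pct[["mean"]], config$ds_pct[["sd"]],
                            config$ds_range[1], config$ds_range[2])
        if (prox * (1 - ds_c / 100) >= 0.98 * min(prox, dist)) next
        len_c <- rtruncnorm1(config$lesion_length[["mean"]],
                             config$lesion_length[["sd"]],
                             config$lesion_length_range[1],
                             config$lesion_length_range[2])
        mld <- prox * (1 - ds_c / 100)
        span <- 10 * prox + len_c + 10 * prox
        dx <- span / (config$n_geometry_samples - 1)
        sd_att <- config$modality_radial_noise_sd /
          sqrt(max(1, config$smoothing_window_mm / dx))
        mld_eff <- max(mld - 4 * sd_att, 0.25 * mld)
        for (vatt in seq_len(10L)) {
          vel_c <- rtruncnorm1(p$vel_mean, p$vel_sd, max(3, 0.2 * p$vel_mean),
                               3 * p$vel_mean)
          drop <- estimate_drop_pa(prox, dist, mld_eff, len_c,
                                   vel_c * (1 + 2.5 * cv))
          if (drop < 8000) { vel <- vel_c; break }
        }
        if (!is.na(vel)) { ds <- ds_c; len <- len_c; break }
      }
      if (is.na(vel))
        stop("could not sample a feasible lesion after 100 attempts",
             call. = FALSE)
      data.frame(case_id = sprintf("case%03d", i), territory = terr,
                 proximal_diameter = prox, distal_diameter = dist,
                 ds_pct_true = ds,
                 minimal_lumen_diameter = prox * (1 - ds / 100),
                 stenosis_length = len,
                 velocity_cm_s = vel,
                 path_length_mm = 0.8 * span,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "config") <- config
    class(out) <- c("cohort_truth", "data.frame")
    out
  })
}

truth_spec <- function(row) {
  stenosis_spec(proximal_diameter = row$proximal_diameter,
                distal_diameter = row$distal_diameter,
                minimal_lumen_diameter = row$minimal_lumen_diameter,
                stenosis_length = row$stenosis_length,
                territory = row$territory)
}

#' Realize the three modality cases of one lesion
#'
#' From one lesion truth: perturbs the true lumen independently per imaging
#' modality, derives the DSA inlet from a (noisy) TIMI frame count at 6
#' frames/s, the CTA inlet from a (noisy) TCD velocity, and composes the
#' hybrid CMD case (CTA geometry + DSA inlet).
#'
#' @param row one row of a [sample_cohort] data frame.
#' @param config the [cohort_config].
#' @param case_index integer used to derive per-case noise seeds.
#' @return List with elements `DSA`, `CTA`, `CMD` (each a
#'   [case_definition]) and `true_geometry`.
#' @export
realize_modalities <- function(row, config, case_index = 1L) {
  spec <- truth_spec(row)
  geom <- make_stenotic_vessel(spec, config$n_geometry_samples)
  base <- config$seed + 1000L * case_index
  g_dsa <- perturb_modality(geom, config$modality_radial_noise_sd,
                            config$smoothing_window_mm, seed = base + 1L,
                            provenance = "perturbed-DSA")
  g_cta <- perturb_modality(geom, config$modality_radial_noise_sd,
                            config$smoothing_window_mm, seed = base + 2L,
                            provenance = "perturbed-CTA")
  v_true <- row$velocity_cm_s * 10  # mm/s
  cv <- config$flow_measurement_noise_cv
  eps <- if (cv > 0) with_local_seed(base + 3L, rnorm(2, 0, cv)) else c(0, 0)
  v_dsa <- v_true * max(1 + eps[1], 0.2)
  v_cta <- v_true * max(1 + eps[2], 0.2)
  frame_rate <- 6
  frame_count <- row$path_length_mm * frame_rate / v_dsa
  d_in_dsa <- 2 * g_dsa$radius_mm[1]
  d_in_cta <- 2 * g_cta$radius_mm[1]
  inlet_dsa <- timi_inlet_flow(row$path_length_mm, frame_count, frame_rate,
                               d_in_dsa)
  inlet_cta <- tcd_inlet_flow(v_cta / 10, d_in_cta)
  case_dsa <- case_definition(g_dsa, inlet_dsa,
                              murray_outlet_split(2 * g_dsa$radius_mm[length(g_dsa$radius_mm)]),
                              modality = "DSA")
  case_cta <- case_definition(g_cta, inlet_cta,
                              murray_outlet_split(2 * g_cta$radius_mm[length(g_cta$radius_mm)]),
                              modality = "CTA")
  case_cmd <- compose_cmd(case_cta, inlet_dsa)
  list(DSA = case_dsa, CTA = case_cta, CMD = case_cmd, true_geometry = geom)
}

case_cache_key <- function(case) {
  r <- case$geometry$radius_mm; x <- case$geometry$axial_mm
  # full-precision fingerprint of (geometry, flow, fluid); identical cases --
  # and only those, for all practical purposes -- share a key
  paste(format(c(length(r), sum(r), sum(r^2), sum(r^3), sum(x * r), min(r),
                 which.min(r), case$inlet$flow_rate_ml_s, case$fluid$density,
                 case$fluid$dynamic_viscosity), digits = 17),
        collapse = "|")
}

#' Run the full pipeline over a synthetic cohort
#'
#' For every case and modality: measures morphology on the
#' modality-specific lumen, solves the steady flow and derives the
#' hemodynamic metrics. Identical (geometry, flow) pairs are solved once
#' (memoised); the solver is deterministic so this is exact. Solver
#' failures are flagged per row, never dropped silently.
#'
#' @param cohort a [sample_cohort] data frame.
#' @param refinement_level mesh refinement level used for every case.
#' @param tolerance,max_iterations passed to [solve_steady].
#' @param cache memoise identical (geometry, flow) solves.
#' @param quiet suppress progress output.
#' @return Data frame of class `cohort_metrics`: one row per
#'   (case, modality) with morphology and hemodynamic columns and a
#'   `converged` flag.
#' @export
run_cohort <- function(cohort, refinement_level = 1L, tolerance = 1e-5,
                       max_iterations = 8000L, cache = TRUE, quiet = TRUE) {
  stopifnot(inherits(cohort, "cohort_truth"))
  config <- attr(cohort, "config")
  memo <- new.env(parent = emptyenv())
  memo$store <- list()
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort[i, ]
    cases <- realize_modalities(rec, config, case_index = i)
    for (mod in c("DSA", "CTA", "CMD")) {
      case <- cases[[mod]]
      morph <- measure_morphology(case$geometry)
      key <- case_cache_key(case)
      hemo <- if (cache && !is.null(memo$store[[key]])) {
        memo$store[[key]]
      } else {
        h <- tryCatch({
          mesh <- build_mesh(case$geometry, refinement_level)
          planes <- default_planes(case$geometry, morph)
          field <- tryCatch(
            solve_steady(mesh, case, tolerance = tolerance,
                         max_iterations = max_iterations),
            # one retry with stronger under-relaxation for stiff cases
            stenocfd_no_convergence = function(e)
              solve_steady(mesh, case, tolerance = tolerance,
                           max_iterations = 2L * max_iterations,
                           relax_velocity = 0.4, relax_pressure = 0.15))
          compute_hemodynamics(field, planes)
        }, stenocfd_no_convergence = function(e) conditionMessage(e),
           error = function(e) conditionMessage(e))
        if (cache) memo$store[[key]] <- h
        h
      }
      ok <- inherits(hemo, "hemodynamic_metrics")
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = rec$case_id, modality = mod, territory = rec$territory,
        converged = ok,
        flow_rate_ml_s = case$inlet$flow_rate_ml_s,
        PR = if (ok) hemo$pressure_ratio else NA_real_,
        WSSR = if (ok) hemo$wssr else NA_real_,
        high_wss_area_mm2 = if (ok) hemo$high_wss_area_mm2 else NA_real_,
        ds_pct = morph$diameter_stenosis_pct,
        as_pct = morph$area_stenosis_pct,
        proximal_diameter = morph$proximal_diameter,
        distal_diameter = morph$distal_diameter,
        minimal_lumen_diameter = morph$minimal_lumen_diameter,
        stenosis_length = morph$stenosis_length,
        note = if (ok) "" else as.character(hemo),
        stringsAsFactors = FALSE)
      if (!quiet) message(rec$case_id, " ", mod, if (!ok) " [failed]")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_metrics", "data.frame")
  out
}

morph_params <- c("ds_pct", "as_pct", "proximal_diameter", "distal_diameter",
                  "minimal_lumen_diameter", "stenosis_length")
hemo_params <- c("flow_rate_ml_s", "PR", "WSSR", "high_wss_area_mm2")

pick <- function(metrics, mod, param) {
  m <- metrics[metrics$modality == mod & metrics$converged, ]
  stats::setNames(m[[param]], m$case_id)
}

paired_values <- function(metrics, mod_a, mod_b, param) {
  a <- pick(metrics, mod_a, param)
  b <- pick(metrics, mod_b, param)
  ids <- intersect(names(a), names(b))
  list(a = unname(a[ids]), b = unname(b[ids]), n = length(ids))
}

#' Modality-comparison tables and agreement outputs
#'
#' Reduces a cohort metrics table to the modality-comparison structure of
#' the analysis: morphology comparison DSA vs CTA (summaries + paired
#' tests), per-territory subgroup tables with Kruskal-Wallis p-values for
#' both morphology and hemodynamics, pairwise agreement (Bland-Altman +
#' ICC(2,1)) for the hemodynamic parameters across DSA/CTA/CMD, and
#' Bland-Altman plot data.
#'
#' @param metrics a [run_cohort] result.
#' @param alpha normality-gate level.
#' @return List with elements `table1` (morphology DSA vs CTA), `table2`
#'   (morphology by territory), `table3` (hemodynamics by territory),
#'   `agreement` (one row per parameter and modality pair) and `figdata`
#'   (named list of Bland-Altman data frames).
#' @export
reproduce_tables <- function(metrics, alpha = 0.05) {
  stopifnot(inherits(metrics, "cohort_metrics"))
  terrs <- c("MCA", "ICA", "VA")

  table1 <- do.call(rbind, lapply(morph_params, function(param) {
    pv <- paired_values(metrics, "DSA", "CTA", param)
    p <- if (pv$n >= 3) paired_compare(pv$a, pv$b, alpha)$p_value else NA_real_
    data.frame(parameter = param,
               DSA = summarize_distribution(pv$a, alpha),
               CTA = summarize_distribution(pv$b, alpha),
               p_value = p, stringsAsFactors = FALSE)
  }))

  subgroup_table <- function(params, mods) {
    rows <- lapply(params, function(param) {
      lapply(mods, function(mod) {
        vals <- metrics[metrics$modality == mod & metrics$converged, ]
        groups <- lapply(terrs, function(tt) vals[[param]][vals$territory == tt])
        groups <- groups[lengths(groups) > 0]
        kw <- if (length(groups) >= 2 && sum(lengths(groups)) >= 5)
          kruskal_wallis(groups)$p else NA_real_
        cells <- vapply(terrs, function(tt) {
          v <- vals[[param]][vals$territory == tt]
          if (length(v) >= 3) summarize_distribution(v, alpha)
          else if (length(v) > 0) sprintf("%.4g (n=%d)", mean(v), length(v))
          else "not computable"
        }, character(1))
        data.frame(parameter = param, source = mod,
                   MCA = cells[1], ICA = cells[2], VA = cells[3],
                   p_value = kw, stringsAsFactors = FALSE)
      })
    })
    out <- do.call(rbind, unlist(rows, recursive = FALSE))
    rownames(out) <- NULL
    out
  }
  table2 <- subgroup_table(morph_params, c("DSA", "CTA"))
  table3 <- rbind(
    subgroup_table("flow_rate_ml_s", c("DSA", "CTA")),
    subgroup_table(c("PR", "WSSR", "high_wss_area_mm2"),
                   c("DSA", "CTA", "CMD")))

  pairs <- list(c("DSA", "CTA"), c("DSA", "CMD"), c("CTA", "CMD"))
  agreement <- list(); figdata <- list()
  for (param in morph_params) {
    pv <- paired_values(metrics, "DSA", "CTA", param)
    if (pv$n >= 3) {
      agreement[[length(agreement) + 1L]] <-
        cbind(agreement_summary(pv$a, pv$b, param, alpha),
              comparison = "DSA vs CTA")
      ba <- bland_altman(pv$a, pv$b)
      figdata[[paste0(param, "_DSA_CTA")]] <-
        data.frame(mean = ba$means, difference = ba$differences)
    }
  }
  for (param in c("PR", "WSSR", "high_wss_area_mm2")) {
    for (pr in pairs) {
      pv <- paired_values(metrics, pr[1], pr[2], param)
      if (pv$n >= 3) {
        agreement[[length(agreement) + 1L]] <-
          cbind(agreement_summary(pv$a, pv$b, param, alpha),
                comparison = paste(pr[1], "vs", pr[2]))
        ba <- bland_altman(pv$a, pv$b)
        figdata[[paste(param, pr[1], pr[2], sep = "_")]] <-
          data.frame(mean = ba$means, difference = ba$differences)
      }
    }
  }
  pv <- paired_values(metrics, "DSA", "CTA", "flow_rate_ml_s")
  if (pv$n >= 3) {
    agreement[[length(agreement) + 1L]] <-
      cbind(agreement_summary(pv$a, pv$b, "flow_rate_ml_s", alpha),
            comparison = "DSA vs CTA")
    ba <- bland_altman(pv$a, pv$b)
    figdata[["flow_rate_ml_s_DSA_CTA"]] <-
      data.frame(mean = ba$means, difference = ba$differences)
  }
  list(table1 = table1, table2 = table2, table3 = table3,
       agreement = do.call(rbind, agreement), figdata = figdata)
}
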