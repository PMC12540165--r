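zero_noise_config <- function(n = c(MCA = 2L, ICA = 1L, VA = 0L), seed = 7L)
  cohort_config(n_per_territory = n, modality_radial_noise_sd = 0,
                flow_measurement_noise_cv = 0, seed = seed)

test_that("cohort sampling is seeded and respects territory counts", {
  cfg <- cohort_config(seed = 11L)
  co1 <- sample_cohort(cfg)
  co2 <- sample_cohort(cfg)
  expect_identical(as.data.frame(co1), as.data.frame(co2))
  expect_equal(unname(table(co1$territory)[c("MCA", "ICA", "VA")]),
               c(31L, 6L, 3L), ignore_attr = TRUE)
  expect_equal(nrow(co1), 40L)
  # different seed, different cohort
  co3 <- sample_cohort(cohort_config(seed = 12L))
  expect_false(identical(co1$proximal_diameter, co3$proximal_diameter))
  # all sampled lesions satisfy the spec invariants
  expect_true(all(co1$minimal_lumen_diameter > 0))
  expect_true(all(co1$minimal_lumen_diameter <
                    pmin(co1$proximal_diameter, co1$distal_diameter)))
  expect_true(all(co1$ds_pct_true > 0 & co1$ds_pct_true < 95))
})

test_that("zero-SD distributions degenerate to their means", {
  cfg <- cohort_config(
    n_per_territory = c(MCA = 3L, ICA = 0L, VA = 0L),
    territory_params = data.frame(territory = "MCA", prox_mean = 2.2,
                                  prox_sd = 0, dist_mean = 2.0, dist_sd = 0,
                                  vel_mean = 30, vel_sd = 0),
    ds_pct = c(mean = 60, sd = 0), lesion_length = c(mean = 4, sd = 0),
    seed = 1L)
  co <- sample_cohort(cfg)
  expect_true(all(co$proximal_diameter == 2.2))
  expect_true(all(co$distal_diameter == 2.0))
  expect_true(all(co$ds_pct_true == 60))
  expect_true(all(co$velocity_cm_s == 30))
})

test_that("zero-noise modalities share geometry and the DSA/CMD inlet", {
  cfg <- zero_noise_config()
  co <- sample_cohort(cfg)
  cases <- realize_modalities(co[1, ], cfg, 1L)
  expect_identical(cases$DSA$geometry$radius_mm, cases$CTA$geometry$radius_mm)
  expect_identical(cases$CMD$geometry$radius_mm, cases$CTA$geometry$radius_mm)
  expect_identical(cases$CMD$inlet$flow_rate_ml_s, cases$DSA$inlet$flow_rate_ml_s)
  expect_equal(cases$DSA$inlet$flow_rate_ml_s, cases$CTA$inlet$flow_rate_ml_s,
               tolerance = 1e-12)
  expect_equal(cases$DSA$inlet$source, "TIMI")
  expect_equal(cases$CTA$inlet$source, "TCD")
  expect_equal(cases$CMD$modality, "CMD")
})

test_that("CMD geometry always hashes equal to CTA geometry, also under noise", {
  cfg <- cohort_config(n_per_territory = c(MCA = 2L, ICA = 0L, VA = 0L),
                       seed = 3L)
  co <- sample_cohort(cfg)
  for (i in 1:2) {
    cases <- realize_modalities(co[i, ], cfg, i)
    expect_identical(cases$CMD$geometry$radius_mm, cases$CTA$geometry$radius_mm)
    expect_false(identical(cases$DSA$geometry$radius_mm,
                           cases$CTA$geometry$radius_mm))
    # DSA and CMD differ only through geometry, not inlet flow
    expect_identical(cases$CMD$inlet$flow_rate_ml_s,
                     cases$DSA$inlet$flow_rate_ml_s)
  }
})

test_that("measured flow noise has the configured coefficient of variation", {
  cfg <- cohort_config(n_per_territory = c(MCA = 1L, ICA = 0L, VA = 0L),
                       modality_radial_noise_sd = 0,
                       flow_measurement_noise_cv = 0.10, seed = 21L)
  co <- sample_cohort(cfg)
  q_true <- tcd_inlet_flow(co$velocity_cm_s[1],
                           co$proximal_diameter[1])$flow_rate_ml_s
  ratio <- vapply(1:500, function(k) {
    cases <- realize_modalities(co[1, ], cfg, case_index = k)
    cases$DSA$inlet$flow_rate_ml_s / q_true
  }, numeric(1))
  expect_equal(sd(ratio), 0.10, tolerance = 0.02 / 0.10)
})

test_that("reproduce_tables mirrors the comparison structure", {
  # metrics-level fixture: no solves needed to test the table layer
  set.seed(5)
  n <- 12
  ids <- sprintf("case%03d", 1:n)
  terr <- rep(c("MCA", "ICA", "VA"), c(8, 2, 2))
  base <- data.frame(case_id = ids, territory = terr, converged = TRUE,
                     stringsAsFactors = FALSE)
  mk <- function(mod, jitter) {
    cbind(base, modality = mod,
          flow_rate_ml_s = 1.5 + 0.2 * seq_len(n) + jitter * rnorm(n, 0, 0.05),
          PR = 0.9 - 0.03 * seq_len(n) + jitter * rnorm(n, 0, 0.01),
          WSSR = 5 + seq_len(n) + jitter * rnorm(n, 0, 0.3),
          high_wss_area_mm2 = 10 + seq_len(n) + jitter * rnorm(n, 0, 0.5),
          ds_pct = 40 + seq_len(n), as_pct = 60 + seq_len(n),
          proximal_diameter = 2 + 0.05 * seq_len(n),
          distal_diameter = 1.9 + 0.05 * seq_len(n),
          minimal_lumen_diameter = 1 + 0.02 * seq_len(n),
          stenosis_length = 4 + 0.1 * seq_len(n))
  }
  metrics <- rbind(mk("DSA", 1), mk("CTA", 1), mk("CMD", 1))
  class(metrics) <- c("cohort_metrics", "data.frame")
  tabs <- reproduce_tables(metrics)
  expect_equal(nrow(tabs$table1), 6)
  expect_named(tabs$table1, c("parameter", "DSA", "CTA", "p_value"))
  expect_equal(nrow(tabs$table2), 12)          # 6 params x 2 modalities
  expect_equal(nrow(tabs$table3), 2 + 3 * 3)   # flow x2, 3 params x 3 modalities
  expect_true(all(c("mean_diff", "loa_lower", "loa_upper", "icc", "p",
                    "comparison") %in% names(tabs$agreement)))
  expect_true(length(tabs$figdata) >= 10)
  # hemodynamic parameters are compared across all three modality pairs
  pr_rows <- tabs$agreement[tabs$agreement$parameter == "PR", ]
  expect_equal(sort(pr_rows$comparison),
               sort(c("DSA vs CTA", "DSA vs CMD", "CTA vs CMD")))
})

test_that("run_cohort flags rather than drops failing cases", {
  cfg <- zero_noise_config(n = c(MCA = 1L, ICA = 0L, VA = 0L), seed = 2L)
  co <- sample_cohort(cfg)
  # starve the solver so the case cannot converge
  mx <- run_cohort(co, refinement_level = 0, max_iterations = 80)
  expect_equal(nrow(mx), 3L)
  expect_true(all(!mx$converged))
  expect_true(all(is.na(mx$PR)))
  expect_true(all(nzchar(mx$note)))
})
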