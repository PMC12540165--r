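# Independent oracles and fixture builders used across the suite.

# lubrication-theory pressure drop (Pa) for a slowly varying axisymmetric
# lumen at creeping flow: integral of 8 mu Q / (pi R(x)^4) dx
lubrication_drop <- function(geom, flow_ml_s, viscosity = 0.0035,
                             from = NULL, to = NULL) {
  x <- geom$axial_mm * 1e-3
  r <- geom$radius_mm * 1e-3
  q <- flow_ml_s * 1e-6
  f <- 8 * viscosity * q / (pi * r^4)
  sel <- rep(TRUE, length(x))
  if (!is.null(from)) sel <- sel & geom$axial_mm >= from
  if (!is.null(to)) sel <- sel & geom$axial_mm <= to
  xs <- x[sel]; fs <- f[sel]
  sum(diff(xs) * (fs[-1] + fs[-length(fs)]) / 2)
}

# brute-force two-way ANOVA ICC(2,1): direct sums, no shared code with the
# package implementation
icc21_brute <- function(a, b) {
  x <- cbind(a, b)
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  msr <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    sse <- sse + (x[i, j] - rowMeans(x)[i] - colMeans(x)[j] + grand)^2
  mse <- sse / ((n - 1) * (k - 1))
  unname((msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n))
}

# exact two-sided sign-flip enumeration of the Wilcoxon signed-rank p-value
# (no zeros, no ties)
wilcoxon_exact_brute <- function(d) {
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% rk
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

# Kruskal-Wallis H by direct rank formula (no ties)
kw_brute <- function(groups) {
  pooled <- unlist(groups)
  n <- length(pooled)
  rk <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  rs <- tapply(rk, idx, sum)
  12 / (n * (n + 1)) * sum(rs^2 / lengths(groups)) - 3 * (n + 1)
}

# straight-tube case with development extensions: measurement window
# [ext, ext + window] sits in developed flow
tube_case <- function(radius = 1, window = 10, ext = 20, flow = 1,
                      n_samples = 300) {
  geom <- make_straight_tube(radius, window + 2 * ext, n_samples)
  case_definition(geom, fixed_inlet_flow(flow, 2 * radius), modality = "DSA")
}

# representative 62% diameter-stenosis MCA-like lesion
representative_spec <- function() {
  stenosis_spec(2.2, 2.0, 0.84, 4.1, territory = "MCA")
}

area_pressure <- function(field) pressure_profile(field)
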