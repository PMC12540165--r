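#' Axisymmetric vessel lumen geometry
#'
#' A `vessel_geometry` is an axial profile of lumen radius: the package's
#' stand-in for a segmented DSA or CTA lumen. The lumen is a surface of
#' revolution about the vessel axis, so every quantity the pipeline derives
#' (pressure ratio, wall shear stress along the wall, luminal areas) is
#' well defined while analytic oracles remain available.
#'
#' @param axial_mm strictly increasing axial sample coordinates, mm.
#' @param radius_mm lumen radius at each axial sample, mm; all positive.
#' @param provenance one of `"synthetic"`, `"perturbed-DSA"`,
#'   `"perturbed-CTA"`, `"file"`.
#' @return An object of class `vessel_geometry`.
#' @export
vessel_geometry <- function(axial_mm, radius_mm,
                            provenance = c("synthetic", "perturbed-DSA",
                                           "perturbed-CTA", "file")) {
  provenance <- match.arg(provenance)
  axial_mm <- as.numeric(axial_mm)
  radius_mm <- as.numeric(radius_mm)
  if (length(axial_mm) != length(radius_mm))
    stop("axial_mm and radius_mm must have equal length", call. = FALSE)
  if (length(axial_mm) < 50L)
    stop("a vessel_geometry needs at least 50 axial samples", call. = FALSE)
  if (any(diff(axial_mm) <= 0))
    stop("axial coordinates must be strictly increasing", call. = FALSE)
  if (any(!is.finite(radius_mm)) || any(radius_mm <= 0))
    stop("all radii must be positive and finite", call. = FALSE)
  structure(list(axial_mm = axial_mm, radius_mm = radius_mm,
                 provenance = provenance),
            class = "vessel_geometry")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf(
    "<vessel_geometry> %d samples, span %.2f mm, radius %.3f-%.3f mm (%s)\n",
    length(x$axial_mm), diff(range(x$axial_mm)),
    min(x$radius_mm), max(x$radius_mm), x$provenance))
  invisible(x)
}

#' Parametric stenotic lesion specification
#'
#' Houses the six anatomical parameters of the morphological assessment
#' (proximal/distal reference diameters, minimal lumen diameter, lesion
#' length) together with the arterial territory and the straight parent
#' segments retained up- and downstream of the lesion. Inlet and outlet
#' extensions default to 10 proximal diameters so that measurement planes
#' sit in developed flow.
#'
#' @param proximal_diameter,distal_diameter reference diameters, mm.
#' @param minimal_lumen_diameter MLD, mm; must be smaller than both
#'   reference diameters.
#' @param stenosis_length axial extent of the lesion window, mm.
#' @param territory arterial territory label: `"MCA"`, `"ICA"` or `"VA"`.
#' @param inlet_extension,outlet_extension straight parent-vessel lengths
#'   retained before/after the lesion window, mm. Default 10 proximal
#'   diameters.
#' @param stenosis_center axial position of the lesion centre, mm. Default
#'   `inlet_extension + stenosis_length / 2`.
#' @return An object of class `stenosis_spec`.
#' @export
stenosis_spec <- function(proximal_diameter, distal_diameter,
                          minimal_lumen_diameter, stenosis_length,
                          territory = c("MCA", "ICA", "VA"),
                          inlet_extension = 10 * proximal_diameter,
                          outlet_extension = 10 * proximal_diameter,
                          stenosis_center = inlet_extension + stenosis_length / 2) {
  territory <- match.arg(territory)
  stopifnot(is.numeric(proximal_diameter), is.numeric(distal_diameter),
            is.numeric(minimal_lumen_diameter), is.numeric(stenosis_length))
  if (proximal_diameter <= 0 || distal_diameter <= 0)
    stop("reference diameters must be positive", call. = FALSE)
  if (minimal_lumen_diameter <= 0 ||
      minimal_lumen_diameter >= min(proximal_diameter, distal_diameter))
    stop("minimal_lumen_diameter must satisfy 0 < MLD < min(proximal, distal)",
         call. = FALSE)
  if (stenosis_length <= 0) stop("stenosis_length must be positive", call. = FALSE)
  if (inlet_extension < 0 || outlet_extension < 0)
    stop("extensions must be non-negative", call. = FALSE)
  structure(list(proximal_diameter = proximal_diameter,
                 distal_diameter = distal_diameter,
                 minimal_lumen_diameter = minimal_lumen_diameter,
                 stenosis_length = stenosis_length,
                 stenosis_center = stenosis_center,
                 territory = territory,
                 inlet_extension = inlet_extension,
                 outlet_extension = outlet_extension),
            class = "stenosis_spec")
}

#' Straight cylindrical tube geometry
#'
#' Analytic-oracle geometry: a constant-radius tube for which the
#' Hagen-Poiseuille closed forms apply in the developed region.
#'
#' @param radius lumen radius, mm.
#' @param length axial length, mm.
#' @param n_samples number of axial samples (>= 50).
#' @return A [vessel_geometry].
#' @export
make_straight_tube <- function(radius, length, n_samples = 200L) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive", call. = FALSE)
  if (!is.numeric(length) || length <= 0) stop("length must be positive", call. = FALSE)
  if (n_samples < 50L) stop("n_samples must be at least 50", call. = FALSE)
  vessel_geometry(seq(0, length, length.out = n_samples),
                  rep(radius, n_samples), provenance = "synthetic")
}

#' Cosine-constriction stenotic vessel
#'
#' Builds an axisymmetric lumen with a smooth cosine (Young-Tsai style)
#' constriction:
#' \deqn{R(x) = R_{base}(x) - \delta \, (1 + \cos(2\pi (x - x_c)/L_s))/2}
#' inside the lesion window, where \eqn{R_{base}} tapers linearly from the
#' proximal to the distal reference radius across the lesion window and is
#' constant elsewhere, and \eqn{\delta} is chosen so the minimum lumen
#' diameter equals `spec$minimal_lumen_diameter`.
#'
#' @param spec a [stenosis_spec].
#' @param n_samples number of axial samples (>= 50).
#' @return A [vessel_geometry].
#' @export
make_stenotic_vessel <- function(spec, n_samples = 400L) {
  stopifnot(inherits(spec, "stenosis_spec"))
  if (n_samples < 50L) stop("n_samples must be at least 50", call. = FALSE)
  x1 <- spec$stenosis_center - spec$stenosis_length / 2
  x2 <- spec$stenosis_center + spec$stenosis_length / 2
  if (x1 < 0)
    stop("lesion window exceeds the axial span (stenosis_center too small)",
         call. = FALSE)
  L <- x2 + spec$outlet_extension
  x <- seq(0, L, length.out = n_samples)
  rp <- spec$proximal_diameter / 2
  rd <- spec$distal_diameter / 2
  rbase <- ifelse(x <= x1, rp,
                  ifelse(x >= x2, rd, rp + (rd - rp) * (x - x1) / (x2 - x1)))
  w <- numeric(n_samples)
  inside <- x > x1 & x < x2
  w[inside] <- (1 + cos(2 * pi * (x[inside] - spec$stenosis_center) /
                          spec$stenosis_length)) / 2
  target <- spec$minimal_lumen_diameter / 2
  # delta such that min(rbase - delta * w) == target; monotone in delta
  f <- function(d) min(rbase - d * w) - target
  delta <- stats::uniroot(f, lower = 0, upper = rp, tol = 1e-12)$root
  vessel_geometry(x, rbase - delta * w, provenance = "synthetic")
}

#' Emulate inter-modality segmentation differences
#'
#' Adds seeded Gaussian radial noise to a lumen profile, optionally smoothed
#' by a moving average, emulating the small differences between DSA- and
#' CTA-derived segmentations of the same lesion. Smoothing over a window of
#' `k` samples attenuates the per-sample noise SD by a factor of
#' approximately `1/sqrt(k)`; the applied factor is returned in the
#' `"attenuation"` attribute.
#'
#' @param geom a [vessel_geometry].
#' @param radial_noise_sd per-sample radial noise SD, mm (>= 0).
#' @param smoothing_window moving-average window, mm (0 = no smoothing).
#' @param seed integer seed; identical seeds give identical output.
#' @param provenance provenance label for the perturbed geometry.
#' @return A new [vessel_geometry]; attribute `"attenuation"` holds the
#'   noise-SD attenuation factor of the smoothing.
#' @export
perturb_modality <- function(geom, radial_noise_sd, smoothing_window = 0,
                             seed = 1L,
                             provenance = c("perturbed-DSA", "perturbed-CTA")) {
  stopifnot(inherits(geom, "vessel_geometry"))
  provenance <- match.arg(provenance)
  if (radial_noise_sd < 0) stop("radial_noise_sd must be >= 0", call. = FALSE)
  if (radial_noise_sd == 0) {
    out <- vessel_geometry(geom$axial_mm, geom$radius_mm, provenance)
    attr(out, "attenuation") <- 1
    return(out)
  }
  n <- length(geom$radius_mm)
  noise <- with_local_seed(seed, rnorm(n, 0, radial_noise_sd))
  k <- smoothing_samples(geom, smoothing_window)
  if (k > 1L) noise <- moving_average(noise, k)
  r <- pmax(geom$radius_mm + noise, 0.05 * min(geom$radius_mm))
  out <- vessel_geometry(geom$axial_mm, r, provenance)
  attr(out, "attenuation") <- 1 / sqrt(k)
  out
}

#' Noise attenuation factor of the perturbation smoothing
#'
#' @param geom a [vessel_geometry].
#' @param smoothing_window moving-average window, mm.
#' @return The factor by which smoothing attenuates the per-sample radial
#'   noise SD (1 when no smoothing applies).
#' @export
perturbation_attenuation <- function(geom, smoothing_window) {
  1 / sqrt(smoothing_samples(geom, smoothing_window))
}

smoothing_samples <- function(geom, smoothing_window) {
  if (smoothing_window <= 0) return(1L)
  dx <- mean(diff(geom$axial_mm))
  k <- max(1L, round(smoothing_window / dx))
  if (k %% 2L == 0L) k <- k + 1L
  as.integer(k)
}

moving_average <- function(x, k) {
  h <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(h + 1L):(h + length(x))]
}

# run expr under a temporary RNG state so callers' streams are untouched
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Export a lumen as a binary STL surface of revolution
#'
#' Writes the tube wall as a triangulated binary STL (units mm). End caps
#' are optional and flagged in the STL header.
#'
#' @param geom a [vessel_geometry].
#' @param path output file path.
#' @param circumferential_samples number of points around the circumference
#'   (>= 16).
#' @param end_caps close the tube ends with triangle fans.
#' @return Invisibly, the number of triangles written.
#' @export
export_surface_stl <- function(geom, path, circumferential_samples = 64L,
                               end_caps = FALSE) {
  stopifnot(inherits(geom, "vessel_geometry"))
  if (circumferential_samples < 16L)
    stop("circumferential_samples must be at least 16", call. = FALSE)
  nc <- as.integer(circumferential_samples)
  na <- length(geom$axial_mm)
  theta <- 2 * pi * (seq_len(nc) - 1L) / nc
  # vertex ring per axial station
  vx <- function(i) {
    r <- geom$radius_mm[i]
    cbind(geom$axial_mm[i], r * cos(theta), r * sin(theta))
  }
  tris <- vector("list", na - 1L)
  for (i in seq_len(na - 1L)) {
    a <- vx(i); b <- vx(i + 1L)
    jn <- c(seq_len(nc)[-1L], 1L)  # next circumferential index
    # two triangles per quad, outward-facing
    t1 <- cbind(a, b, a[jn, , drop = FALSE])
    t2 <- cbind(b, b[jn, , drop = FALSE], a[jn, , drop = FALSE])
    tris[[i]] <- rbind(t1, t2)
  }
  tri <- do.call(rbind, tris)
  if (end_caps) {
    for (i in c(1L, na)) {
      ring <- vx(i)
      centre <- c(geom$axial_mm[i], 0, 0)
      jn <- c(seq_len(nc)[-1L], 1L)
      cap <- cbind(matrix(centre, nc, 3, byrow = TRUE), ring, ring[jn, , drop = FALSE])
      tri <- rbind(tri, cap)
    }
  }
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- sprintf("stenocfd surface of revolution; caps=%d", as.integer(end_caps))
  hdr <- charToRaw(formatC(hdr, width = -80))
  writeBin(hdr[1:80], con)
  writeBin(as.integer(nrow(tri)), con, size = 4, endian = "little")
  for (t in seq_len(nrow(tri))) {
    p1 <- tri[t, 1:3]; p2 <- tri[t, 4:6]; p3 <- tri[t, 7:9]
    nrm <- c((p2 - p1)[2] * (p3 - p1)[3] - (p2 - p1)[3] * (p3 - p1)[2],
             (p2 - p1)[3] * (p3 - p1)[1] - (p2 - p1)[1] * (p3 - p1)[3],
             (p2 - p1)[1] * (p3 - p1)[2] - (p2 - p1)[2] * (p3 - p1)[1])
    nn <- sqrt(sum(nrm^2))
    if (nn > 0) nrm <- nrm / nn
    writeBin(as.numeric(c(nrm, p1, p2, p3)), con, size = 4, endian = "little")
    writeBin(as.integer(0L), con, size = 2, endian = "little")
  }
  invisible(nrow(tri))
}

#' Read vertices back from a binary STL file
#'
#' Round-trip helper: returns the triangle vertices of a binary STL as a
#' matrix with columns x, y, z (mm).
#'
#' @param path STL file path.
#' @return A numeric matrix of vertices (3 rows per triangle).
#' @export
read_surface_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  invisible(readBin(con, "raw", 80))
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  out <- matrix(NA_real_, 3L * ntri, 3L)
  for (t in seq_len(ntri)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    out[(3L * t - 2L):(3L * t), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    invisible(readBin(con, "raw", 2))
  }
  out
}

#' Read / write an axial radius profile as CSV
#'
#' Two-column CSV (`axial_mm`, `radius_mm`) with a header; the round trip
#' is lossless to well below 1e-9 mm.
#'
#' @param path CSV file path.
#' @return `read_radius_profile_csv` returns a [vessel_geometry];
#'   `write_radius_profile_csv` returns the path invisibly.
#' @export
read_radius_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("axial_mm", "radius_mm") %in% names(df)))
    stop("radius profile CSV must have columns axial_mm, radius_mm", call. = FALSE)
  bad <- which(!is.finite(df$radius_mm) | df$radius_mm <= 0)
  if (length(bad))
    stop(sprintf("non-positive or missing radius at row %d", bad[1]), call. = FALSE)
  ns <- which(diff(df$axial_mm) <= 0)
  if (length(ns))
    stop(sprintf("axial column not strictly increasing at row %d", ns[1] + 1L),
         call. = FALSE)
  vessel_geometry(df$axial_mm, df$radius_mm, provenance = "file")
}

#' @rdname read_radius_profile_csv
#' @param geom a [vessel_geometry].
#' @export
write_radius_profile_csv <- function(geom, path) {
  stopifnot(inherits(geom, "vessel_geometry"))
  df <- data.frame(axial_mm = geom$axial_mm, radius_mm = geom$radius_mm)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
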