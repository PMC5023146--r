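# Evaluate expr with a temporary RNG state (internal)
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic ventricle specification
#'
#' A truncated half-ellipsoid (base plane at the equator, slices toward the
#' apex), emulating a short-axis CMR contour stack. Default dimensions give
#' cavity volumes on the scale of a dilated right ventricle (roughly 250
#' cm^3).
#'
#' @param a,b,c ellipsoid semi-axes (cm): short-axis a, b; long-axis c.
#' @param wall wall thickness offset (cm), must be < min(a, b).
#' @param n_slices slice count (default 13, the 12-14 CMR range).
#' @param n_points points per contour (default 100).
#' @param noise_sd relative radial contour noise SD (default 0).
#' @param apex_frac covered fraction of the long axis (default 0.9; the apical
#'   cap is not sliced).
#' @param seed RNG seed for the noise.
#' @return object of class \code{synthetic_ventricle_spec}.
#' @export
synthetic_ventricle_spec <- function(a = 4, b = 4, c = 8, wall = 0.45,
                                     n_slices = 13, n_points = 100,
                                     noise_sd = 0, apex_frac = 0.9,
                                     seed = 1) {
  if (wall >= min(a, b)) stop("wall thickness must be below the inner radius")
  stopifnot(a > 0, b > 0, c > 0, wall > 0, n_slices >= 3, n_points >= 8,
            noise_sd >= 0, apex_frac > 0, apex_frac < 1)
  structure(list(a = a, b = b, c = c, wall = wall, n_slices = n_slices,
                 n_points = n_points, noise_sd = noise_sd,
                 apex_frac = apex_frac, seed = seed),
            class = "synthetic_ventricle_spec")
}

#' Generate a synthetic ventricle contour stack
#'
#' Slices are placed at the midpoints of equal z bins from the equatorial
#' base plane toward the apex; the inner border is the ellipsoid cross
#' section, the outer border the cross section of the wall-offset ellipsoid
#' (semi-axes + wall). Optional multiplicative Gaussian radial noise per
#' point. Deterministic given the spec's seed.
#'
#' @param spec a \code{\link{synthetic_ventricle_spec}}.
#' @return a \code{\link{contour_stack}}.
#' @export
generate_ventricle <- function(spec = synthetic_ventricle_spec()) {
  stopifnot(inherits(spec, "synthetic_ventricle_spec"))
  with_seed(spec$seed, {
    zmax <- spec$apex_frac * spec$c
    dz <- zmax / spec$n_slices
    zs <- (seq_len(spec$n_slices) - 0.5) * dz
    th <- 2 * pi * (seq_len(spec$n_points) - 1) / spec$n_points
    mk <- function(sa, sb, sc, z) {
      f <- sqrt(max(1 - (z / sc)^2, 0))
      r <- cbind(sa * f * cos(th), sb * f * sin(th))
      if (spec$noise_sd > 0)
        r <- r * (1 + stats::rnorm(spec$n_points, 0, spec$noise_sd))
      contour(r)
    }
    slices <- lapply(zs, function(z)
      ventricle_slice(mk(spec$a, spec$b, spec$c, z),
                      mk(spec$a + spec$wall, spec$b + spec$wall,
                         spec$c + spec$wall, z),
                      z))
    contour_stack(slices, spacing = dz, label = "synthetic")
  })
}

#' Analytic cavity volume of a synthetic ventricle spec
#'
#' The exact volume of the sliced region
#' \eqn{\int_0^{z_{max}} \pi a b (1 - z^2/c^2)\,dz}, for oracle comparisons
#' with the disk-summation stack volume.
#'
#' @param spec a \code{\link{synthetic_ventricle_spec}}.
#' @param surface \code{"inner"} or \code{"outer"}.
#' @return volume (cm^3).
#' @export
ellipsoid_volume <- function(spec, surface = c("inner", "outer")) {
  surface <- match.arg(surface)
  a <- spec$a; b <- spec$b; c <- spec$c
  if (surface == "outer") { a <- a + spec$wall; b <- b + spec$wall
    c <- c + spec$wall }
  zmax <- spec$apex_frac * spec$c
  pi * a * b * (zmax - zmax^3 / (3 * c^2))
}

#' Synthetic cohort specification
#'
#' Emulates the structure of the 16-patient begin-ejection cohort table: two
#' outcome groups whose wall stress differs by a specified ratio, an EF
#' change (\code{delta_ef}) constructed as a noisy decreasing linear function
#' of stress with a target correlation, and group-independent geometry
#' columns. Defaults reproduce the printed cohort's group stress means/SDs
#' (82.9 +/- 27.5 vs 133.9 +/- 31.4 kPa, ratio 1.615) and the reported
#' stress-outcome correlation of about -0.6. The linear-with-Gaussian-noise
#' EF model is a test instrument, not a physiological claim.
#'
#' @param n_per_group patients per outcome group (default 8).
#' @param stress_mean Group-1 mean begin-ejection stress (kPa).
#' @param stress_ratio Group-2 / Group-1 mean stress ratio (default 1.615).
#' @param stress_sds per-group stress SDs (kPa).
#' @param def_corr target population correlation of delta_ef with stress
#'   (in (-1, 1)).
#' @param def_sd target SD of delta_ef (%).
#' @param seed RNG seed.
#' @return object of class \code{synthetic_cohort_spec}.
#' @export
synthetic_cohort_spec <- function(n_per_group = 8, stress_mean = 82.9,
                                  stress_ratio = 1.615,
                                  stress_sds = c(27.5, 31.4),
                                  def_corr = -0.6, def_sd = 7.6, seed = 1) {
  if (abs(def_corr) >= 1) stop("infeasible correlation target")
  stopifnot(n_per_group >= 2, stress_mean > 0, stress_ratio > 0,
            all(stress_sds >= 0), def_sd >= 0)
  structure(list(n_per_group = n_per_group, stress_mean = stress_mean,
                 stress_ratio = stress_ratio, stress_sds = stress_sds,
                 def_corr = def_corr, def_sd = def_sd, seed = seed),
            class = "synthetic_cohort_spec")
}

#' Generate a synthetic outcome cohort
#'
#' Per-group Gaussian begin-ejection stress draws (truncated at a small
#' positive floor), delta_ef linear in stress with Gaussian noise calibrated
#' to the spec's correlation and SD targets, phase stresses (BF/EF/EE) tied
#' to the begin-ejection value by the cohort-mean phase ratios with lognormal
#' jitter, and group-independent geometry columns (WT, curvatures, EDV,
#' strain) on the printed cohort's scale. Deterministic given the seed.
#'
#' @param spec a \code{\link{synthetic_cohort_spec}}.
#' @return data.frame with columns patient, group, delta_ef, wt, ccur, lcur,
#'   edv, stress, strain and stress_2g_bf/ef/be/ee.
#' @export
generate_cohort <- function(spec = synthetic_cohort_spec()) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_per_group
    group <- rep(1:2, each = n)
    mu <- spec$stress_mean * c(1, spec$stress_ratio)[group]
    sd <- spec$stress_sds[group]
    stress <- pmax(stats::rnorm(2 * n, mu, sd), 1)
    # population pooled stress variance: within + between-group
    m1 <- spec$stress_mean; m2 <- spec$stress_mean * spec$stress_ratio
    var_s <- mean(spec$stress_sds^2) + ((m2 - m1) / 2)^2
    beta <- spec$def_corr * spec$def_sd / sqrt(var_s)
    sd_eps <- spec$def_sd * sqrt(1 - spec$def_corr^2)
    alpha <- -4.9 - beta * mean(c(m1, m2))
    delta_ef <- alpha + beta * stress + stats::rnorm(2 * n, 0, sd_eps)
    jit <- function() exp(stats::rnorm(2 * n, 0, 0.1))
    data.frame(
      patient = seq_len(2 * n), group = group, delta_ef = delta_ef,
      wt = pmax(stats::rnorm(2 * n, 0.49, 0.12), 0.15),
      ccur = pmax(stats::rnorm(2 * n, 0.52, 0.2), 0.1),
      lcur = pmax(stats::rnorm(2 * n, 1.27, 0.45), 0.2),
      edv = pmax(stats::rnorm(2 * n, 345, 130), 80),
      stress = stress,
      strain = pmax(stats::rnorm(2 * n, 0.6, 0.12), 0.05),
      stress_2g_bf = 0.066 * stress * jit(),
      stress_2g_ef = 0.398 * stress * jit(),
      stress_2g_be = stress,
      stress_2g_ee = 0.266 * stress * jit())
  })
}
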