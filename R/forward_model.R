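#' Four-point pressure schedule
#'
#' The imposed right-ventricular pressure over one cycle, reduced to its four
#' landmark values: Pmin (begin-filling), Pdia (end-filling), Pmax
#' (begin-ejection) and Psys (end-ejection). The two isovolumic phases are
#' omitted, so the schedule jumps Pdia -> Pmax and Psys -> Pmin between
#' phases. Default values are package configuration placeholders on a
#' physiological RV scale, not measured profiles.
#'
#' @param Pmin,Pdia,Pmax,Psys pressures (kPa); \code{Pmin < Pdia <= Pmax},
#'   \code{Psys} in \code{(Pmin, Pmax)}.
#' @param fill_frac fraction of the cycle spent in filling (default 0.6).
#' @param samples_per_phase time samples per phase (default 9).
#' @return object of class \code{pressure_schedule}.
#' @export
pressure_schedule <- function(Pmin = 0.3, Pdia = 1.3, Pmax = 8.7, Psys = 2.7,
                              fill_frac = 0.6, samples_per_phase = 9) {
  stopifnot(Pmin < Pdia, Pdia <= Pmax, Psys > Pmin, Psys < Pmax,
            fill_frac > 0, fill_frac < 1, samples_per_phase >= 2)
  structure(list(Pmin = Pmin, Pdia = Pdia, Pmax = Pmax, Psys = Psys,
                 fill_frac = fill_frac,
                 samples_per_phase = as.integer(samples_per_phase)),
            class = "pressure_schedule")
}

#' Volume-equivalent spherical chamber
#'
#' Reduces a contour stack to the incompressible thick-walled sphere with the
#' same cavity and wall volumes. This chamber is the package's forward-model
#' stand-in for a full 3D finite-element solve: it preserves the
#' pressure-volume relation and transmural mean stress/strain that the
#' downstream analysis consumes, with closed-form kinematics.
#'
#' @param s a \code{\link{contour_stack}}.
#' @return object of class \code{equivalent_chamber} with zero-load inner and
#'   outer radii \code{Ri}, \code{Ro} (cm) and the source label.
#' @export
to_equivalent_chamber <- function(s) {
  vi <- stack_volume(s, "inner")
  vo <- stack_volume(s, "outer")
  if (vo - vi <= 1e-8 * vo) stop("zero wall volume")
  Ri <- (3 * vi / (4 * pi))^(1 / 3)
  Ro <- (3 * vo / (4 * pi))^(1 / 3)
  structure(list(Ri = Ri, Ro = Ro, source_label = s$label),
            class = "equivalent_chamber")
}

#' Construct an equivalent chamber from radii
#' @param Ri,Ro zero-load inner and outer radii (cm), \code{0 < Ri < Ro}.
#' @return object of class \code{equivalent_chamber}.
#' @export
equivalent_chamber <- function(Ri, Ro) {
  stopifnot(Ri > 0, Ro > Ri)
  structure(list(Ri = Ri, Ro = Ro, source_label = "direct"),
            class = "equivalent_chamber")
}

# d/d(lambda) of the reduced equibiaxial strain energy w(lambda) =
# W(lambda, lambda, lambda^-2) with the fiber in-plane (I4 = lambda^2).
# Vectorized over lambda. (internal)
wprime_equibiaxial <- function(p, lam) {
  if (inherits(p, "fung_params")) {
    Ef <- (lam^2 - 1) / 2
    Er <- (lam^-4 - 1) / 2
    Q <- p$b1 * Ef^2 + p$b2 * (Ef^2 + Er^2)
    dQ <- 2 * p$b1 * Ef * lam + 2 * p$b2 * (Ef * lam - 2 * Er * lam^-5)
    (p$C_f / 2) * exp(Q) * dQ
  } else {
    I1 <- 2 * lam^2 + lam^-4
    I2 <- lam^4 + 2 * lam^-2
    I4 <- lam^2
    dw <- mr_energy_derivs(p, I1, I2, I4)
    dw$W1 * (4 * lam - 4 * lam^-5) + dw$W2 * (4 * lam^3 - 4 * lam^-3) +
      dw$W4 * 2 * lam
  }
}

# Luminal pressure supported at deformed inner radius ri (internal):
# p = int_{Ri}^{Ro} lambda w'(lambda) R^2 / r^3 dR,  r^3 = R^3 + ri^3 - Ri^3
chamber_pressure <- function(ch, p_mat, ri, rel.tol = 1e-8) {
  dv <- ri^3 - ch$Ri^3
  f <- function(R) {
    r3 <- R^3 + dv
    r <- r3^(1 / 3)
    lam <- r / R
    lam * wprime_equibiaxial(p_mat, lam) * R^2 / r3
  }
  stats::integrate(f, ch$Ri, ch$Ro, rel.tol = rel.tol,
                   subdivisions = 200L)$value
}

#' Inflate an equivalent chamber
#'
#' Quasi-static inflation of the incompressible thick-walled sphere: the
#' deformed inner radius solves
#' \deqn{p = \int_{r_i}^{r_o} \frac{2(\sigma_{\theta\theta}-\sigma_{rr})}{r}\,dr}
#' with \eqn{\sigma_{\theta\theta}-\sigma_{rr} = \frac{\lambda}{2} w'(\lambda)}
#' from the equibiaxial reduced energy and the closed-form kinematics
#' \eqn{r^3 = R^3 + r_i^3 - R_i^3}. Radial stress satisfies
#' \eqn{\sigma_{rr}(r_i) = -p}, \eqn{\sigma_{rr}(r_o) = 0}.
#'
#' @param ch an \code{\link{equivalent_chamber}}.
#' @param material material parameters (Mooney-Rivlin family or Fung).
#' @param p luminal pressure (kPa), >= 0.
#' @param n_profile radial profile sample count (default 21).
#' @param rel.tol quadrature relative tolerance (default 1e-8).
#' @return object of class \code{transmural_state}: pressure, deformed radii,
#'   cavity \code{volume} (cm^3), radial \code{profile} data.frame
#'   (R, r, lambda, sigma_rr, sigma_tt, E_tt, E_rr), and the volume-weighted
#'   wall averages \code{stress_p1} (max principal Cauchy, kPa) and
#'   \code{strain_p1} (max principal Green-Lagrange).
#' @export
inflate <- function(ch, material, p, n_profile = 21, rel.tol = 1e-8) {
  stopifnot(inherits(ch, "equivalent_chamber"), p >= 0)
  if (p == 0) {
    ri <- ch$Ri
  } else {
    # bracket: pressure is strictly increasing in ri for stiffening laws
    hi <- ch$Ri * 1.05
    p_hi <- chamber_pressure(ch, material, hi, rel.tol)
    it <- 0
    while (p_hi < p && it < 60) {
      hi <- hi * 1.15
      p_hi <- tryCatch(chamber_pressure(ch, material, hi, rel.tol),
                       error = function(e) Inf)
      if (!is.finite(p_hi)) { p_hi <- Inf; break }
      it <- it + 1
    }
    if (!is.finite(p_hi) && it == 0)
      stop("inflation non-convergence: pressure above supportable range")
    if (is.finite(p_hi) && p_hi < p)
      stop("inflation non-convergence: pressure above supportable range")
    ri <- stats::uniroot(function(x)
      chamber_pressure(ch, material, x, rel.tol) - p,
      c(ch$Ri, hi), tol = ch$Ri * 1e-10)$root
  }
  dv <- ri^3 - ch$Ri^3
  Rg <- seq(ch$Ri, ch$Ro, length.out = n_profile)
  rg <- (Rg^3 + dv)^(1 / 3)
  lam <- rg / Rg
  dstress <- lam * wprime_equibiaxial(material, lam) / 2  # sigma_tt - sigma_rr
  # sigma_rr by cumulative quadrature of 2*dstress/r dr from the inner wall
  srr <- numeric(n_profile)
  srr[1] <- -p
  for (k in 2:n_profile) {
    srr[k] <- srr[k - 1] + stats::integrate(function(R) {
      r3 <- R^3 + dv
      r <- r3^(1 / 3)
      l <- r / R
      l * wprime_equibiaxial(material, l) * R^2 / r3
    }, Rg[k - 1], Rg[k], rel.tol = rel.tol)$value
  }
  stt <- srr + dstress
  Ett <- (lam^2 - 1) / 2
  Err <- (lam^-4 - 1) / 2
  wgt <- Rg^2 / sum(Rg^2)                 # volume weighting (d vol = 4 pi R^2 dR)
  structure(list(
    pressure = p, ri = ri, ro = (ch$Ro^3 + dv)^(1 / 3),
    volume = 4 / 3 * pi * ri^3,
    profile = data.frame(R = Rg, r = rg, lambda = lam,
                         sigma_rr = srr, sigma_tt = stt,
                         E_tt = Ett, E_rr = Err),
    stress_p1 = sum(wgt * stt), strain_p1 = sum(wgt * Ett),
    chamber = ch), class = "transmural_state")
}

# Resolve a geometry argument to an equivalent chamber (internal)
as_chamber <- function(g) {
  if (inherits(g, "equivalent_chamber")) g
  else if (inherits(g, "contour_stack")) to_equivalent_chamber(g)
  else if (inherits(g, "preshrink_result")) to_equivalent_chamber(g$zero_load)
  else stop("cannot interpret geometry argument")
}

# One phase of the cycle: pressures p0 -> p1 on a fixed chamber (internal)
run_phase <- function(ch, material, p0, p1, t0, t1, n, phase_tag) {
  pg <- seq(p0, p1, length.out = n)
  tg <- seq(t0, t1, length.out = n)
  states <- lapply(pg, function(p) inflate(ch, material, p))
  df <- data.frame(
    t = tg, phase = phase_tag, p_kpa = pg,
    vol_cm3 = vapply(states, function(s) s$volume, 0),
    stress_p1_kpa = vapply(states, function(s) s$stress_p1, 0),
    strain_p1 = vapply(states, function(s) s$strain_p1, 0))
  list(df = df, states = states)
}

#' Simulate a two-geometry (2G) cardiac cycle
#'
#' The filling phase inflates the diastole zero-load chamber from Pmin to
#' Pdia; the model then switches instantaneously to the systole zero-load
#' chamber at begin-ejection (pressure Pmax) and deflates it to Psys; the
#' cycle closes by switching back to the diastole chamber at Pmin. The two
#' isovolumic phases are omitted, so stress and strain are discontinuous at
#' the end-filling -> begin-ejection and end-ejection -> begin-filling
#' transitions while (for calibrated geometries) volume is continuous.
#'
#' @param dia,sys diastole/systole zero-load geometries
#'   (\code{preshrink_result}, \code{contour_stack} or
#'   \code{equivalent_chamber}).
#' @param materials list with elements \code{diastole} and \code{systole}.
#' @param sched a \code{\link{pressure_schedule}}.
#' @return object of class \code{cycle_result}: data.frame \code{series}
#'   (t, phase, p_kpa, vol_cm3, stress_p1_kpa, strain_p1) plus the four
#'   landmark \code{transmural_state}s in \code{landmarks} (BF, EF, BE, EE)
#'   and the chambers/materials used.
#' @export
simulate_cycle_2G <- function(dia, sys, materials, sched = pressure_schedule()) {
  stopifnot(inherits(sched, "pressure_schedule"),
            all(c("diastole", "systole") %in% names(materials)))
  ch_d <- as_chamber(dia)
  ch_s <- as_chamber(sys)
  n <- sched$samples_per_phase
  fill <- run_phase(ch_d, materials$diastole, sched$Pmin, sched$Pdia,
                    0, sched$fill_frac, n, "filling")
  eject <- run_phase(ch_s, materials$systole, sched$Pmax, sched$Psys,
                     sched$fill_frac, 1, n, "ejection")
  series <- rbind(fill$df, eject$df)
  structure(list(
    series = series,
    landmarks = list(BF = fill$states[[1]], EF = fill$states[[n]],
                     BE = eject$states[[1]], EE = eject$states[[n]]),
    chambers = list(diastole = ch_d, systole = ch_s),
    materials = materials, schedule = sched, model = "2G"),
    class = "cycle_result")
}

#' Simulate a one-geometry (1G) cycle
#'
#' A single zero-load geometry and material carried through both phases, with
#' the filling phase ending at Pmax and the ejection phase returning to Pmin:
#' the degenerate 2G cycle, with no stress/strain discontinuities.
#'
#' @param geom zero-load geometry (as in \code{\link{simulate_cycle_2G}}).
#' @param material material parameters.
#' @param sched a \code{\link{pressure_schedule}}; its Pmax/Pmin are used as
#'   the phase end pressures.
#' @return a \code{cycle_result} with \code{model = "1G"}.
#' @export
simulate_cycle_1G <- function(geom, material, sched = pressure_schedule()) {
  s1 <- pressure_schedule(sched$Pmin, sched$Pmax, sched$Pmax,
                          Psys = sched$Pmin + 1e-9 * (sched$Pmax - sched$Pmin),
                          fill_frac = sched$fill_frac,
                          samples_per_phase = sched$samples_per_phase)
  # exactly the 2G code path with coincident geometries/materials/end pressures
  s1$Psys <- sched$Pmin
  out <- simulate_cycle_2G(geom, geom,
                           list(diastole = material, systole = material), s1)
  out$model <- "1G"
  out
}

#' @export
print.cycle_result <- function(x, ...) {
  lm <- x$landmarks
  cat(x$model, "cycle:", nrow(x$series), "samples\n")
  for (nm in names(lm))
    cat(sprintf("  %s: p=%.2f kPa  V=%.1f cm^3  Stress-P1=%.2f kPa  Strain-P1=%.3f\n",
                nm, lm[[nm]]$pressure, lm[[nm]]$volume,
                lm[[nm]]$stress_p1, lm[[nm]]$strain_p1))
  invisible(x)
}

# Deform a zero-load stack to a target cavity volume (internal): inner
# contours and z scale isotropically by k = (V/V0)^(1/3) about per-slice
# inner centroids; the outer contour is set per slice so the 3D wall volume
# is conserved (incompressible wall).
map_stack_to_volume <- function(s, V) {
  v0 <- stack_volume(s, "inner")
  k <- (V / v0)^(1 / 3)
  slices <- lapply(s$slices, function(sl) {
    ctr <- polygon_centroid(sl$inner)
    inner <- sweep(unclass(sl$inner), 2, ctr)
    outer <- sweep(unclass(sl$outer), 2, ctr)
    Ai <- polygon_area(sl$inner)
    Ao <- polygon_area(sl$outer)
    so <- sqrt((k^2 * Ai + (Ao - Ai) / k) / Ao)
    ventricle_slice(contour(sweep(inner * k, 2, ctr, "+")),
                    contour(sweep(outer * so, 2, ctr, "+")),
                    sl$z * k)
  })
  contour_stack(slices, s$spacing * k, s$label)
}

#' Phase-landmark geometric and mechanical metrics
#'
#' Maps the deformed cavity volume at each landmark (BF, EF, BE, EE) back to
#' the phase's zero-load contour stack (inner surface scaled isotropically,
#' outer surface by wall-volume conservation) and evaluates wall thickness,
#' circumferential and longitudinal curvature on the deformed stack.
#'
#' @param r a \code{cycle_result}.
#' @param stack_map list with \code{diastole} and \code{systole} zero-load
#'   \code{\link{contour_stack}}s (the geometries the cycle was built from).
#' @return data.frame with one row per landmark: phase, p_kpa, vol_cm3,
#'   stress_p1_kpa, strain_p1, wt_cm, ccur_1cm, lcur_1cm.
#' @export
extract_phase_metrics <- function(r, stack_map) {
  stopifnot(inherits(r, "cycle_result"),
            all(c("diastole", "systole") %in% names(stack_map)))
  phase_of <- c(BF = "diastole", EF = "diastole",
                BE = "systole", EE = "systole")
  rows <- lapply(names(r$landmarks), function(nm) {
    st <- r$landmarks[[nm]]
    src <- stack_map[[phase_of[[nm]]]]
    def <- map_stack_to_volume(src, st$volume)
    wt <- mean(vapply(def$slices, function(sl) wall_thickness(sl)$mean, 0))
    cc <- mean(vapply(def$slices, function(sl)
      circumferential_curvature(resample_contour(sl$inner))$mean, 0))
    lc <- longitudinal_curvature(def)$mean
    data.frame(state = nm, p_kpa = st$pressure, vol_cm3 = st$volume,
               stress_p1_kpa = st$stress_p1, strain_p1 = st$strain_p1,
               wt_cm = wt, ccur_1cm = cc, lcur_1cm = lc)
  })
  do.call(rbind, rows)
}
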