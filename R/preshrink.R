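#' Shrink a contour stack toward its zero-load configuration
#'
#' Each slice is shrunk about its inner-contour centroid: the inner
#' (endocardial) contour by the factor \code{1 - inner_rate}, the outer
#' contour by the smaller factor that conserves the wall cross-sectional area
#' of the slice (for an annulus with radii Ri < Ro the new outer radius is
#' \code{sqrt(Ro^2 - Ri^2 + ((1-inner_rate) Ri)^2)}). Slice spacing and z are
#' reduced by \code{1 - axial_rate}.
#'
#' @param s a \code{\link{contour_stack}}.
#' @param inner_rate inner-contour shrink fraction, in [0, 0.5].
#' @param axial_rate long-axis shrink fraction, in [0, 0.5].
#' @return shrunk \code{contour_stack}; attribute \code{outer_rates} records
#'   the derived per-slice outer shrink fractions.
#' @export
shrink_stack <- function(s, inner_rate, axial_rate = inner_rate) {
  stopifnot(inner_rate >= 0, inner_rate <= 0.5,
            axial_rate >= 0, axial_rate <= 0.5)
  ki <- 1 - inner_rate
  kz <- 1 - axial_rate
  outer_rates <- numeric(length(s$slices))
  slices <- lapply(seq_along(s$slices), function(i) {
    sl <- s$slices[[i]]
    Ai <- polygon_area(sl$inner)
    Ao <- polygon_area(sl$outer)
    so2 <- (Ao - Ai + Ai * ki^2) / Ao
    if (so2 <= 0) stop("wall-area conservation has no real solution") # guarded
    so <- sqrt(so2)
    outer_rates[i] <<- 1 - so
    ctr <- polygon_centroid(sl$inner)
    inner <- sweep(sweep(unclass(sl$inner), 2, ctr) * ki, 2, ctr, "+")
    outer <- sweep(sweep(unclass(sl$outer), 2, ctr) * so, 2, ctr, "+")
    ventricle_slice(contour(inner), contour(outer), sl$z * kz)
  })
  out <- contour_stack(slices, s$spacing * kz, s$label)
  attr(out, "outer_rates") <- outer_rates
  out
}

#' Recover a zero-load geometry by iterative pre-shrink
#'
#' Iterates the inner shrink rate (secant method with bisection fallback;
#' the inflated volume is strictly decreasing in the rate) until the shrunk
#' geometry, pressurized to the phase's landmark pressure through the
#' equivalent-chamber forward model, reproduces the imaged target volume.
#' The diastole phase starts from a 2\% shrinkage and uses the minimum
#' (begin-filling) pressure; the systole phase starts from 15\% (reflecting
#' an assumed 10-15\% sarcomere shortening) and uses the end-systole
#' pressure.
#'
#' @param s_in_vivo in-vivo minimum-volume \code{\link{contour_stack}}.
#' @param material material parameters for the phase.
#' @param pressure landmark pressure (kPa), > 0 (0 allowed for the trivial
#'   identity case).
#' @param target_volume imaged cavity volume to match (cm^3).
#' @param phase \code{"diastole"} or \code{"systole"} (sets the starting
#'   rate).
#' @param tol relative volume tolerance (default 0.005).
#' @param axial_ratio axial_rate / inner_rate coupling (default 1).
#' @param max_iter iteration cap (default 50).
#' @return object of class \code{preshrink_result}: \code{zero_load} stack,
#'   \code{iterations}, \code{inner_rate}, \code{volume_error} (relative),
#'   \code{phase} and the iteration \code{trace} data.frame.
#' @export
find_zero_load <- function(s_in_vivo, material, pressure, target_volume,
                           phase = c("diastole", "systole"), tol = 0.005,
                           axial_ratio = 1, max_iter = 50) {
  phase <- match.arg(phase)
  stopifnot(pressure >= 0, target_volume > 0)
  trace <- data.frame(iter = integer(), rate = numeric(), volume = numeric())
  vol_at <- function(rate) {
    st <- shrink_stack(s_in_vivo, rate, min(rate * axial_ratio, 0.5))
    inflate(to_equivalent_chamber(st), material, pressure)$volume
  }
  eval_g <- function(rate, it) {
    v <- vol_at(rate)
    trace[nrow(trace) + 1L, ] <<- list(it, rate, v)
    v - target_volume
  }
  done <- function(g) abs(g) / target_volume < tol
  result <- function(rate, g, it) {
    structure(list(
      zero_load = shrink_stack(s_in_vivo, rate,
                               min(rate * axial_ratio, 0.5)),
      iterations = it, inner_rate = rate,
      volume_error = abs(g) / target_volume, phase = phase, trace = trace),
      class = "preshrink_result")
  }
  # trivial identity: unshrunk geometry already matches
  g0 <- eval_g(0, 1L)
  if (done(g0)) return(result(0, g0, 1L))
  r0 <- 0; r1 <- if (phase == "diastole") 0.02 else 0.15
  g1 <- eval_g(r1, 2L)
  if (done(g1)) return(result(r1, g1, 2L))
  # volume is decreasing in rate: maintain a sign-change bracket when seen
  lo <- hi <- NA_real_
  upd <- function(r, g) {
    if (g > 0 && (is.na(lo) || r > lo)) lo <<- r
    if (g < 0 && (is.na(hi) || r < hi)) hi <<- r
  }
  upd(r0, g0); upd(r1, g1)
  for (it in 3:max_iter) {
    if (g1 == g0) stop("pre-shrink non-convergence: flat objective")
    r2 <- r1 - g1 * (r1 - r0) / (g1 - g0)
    if (r2 < 0) r2 <- 0
    if (r2 > 0.5) r2 <- 0.5
    if (!is.na(lo) && !is.na(hi) && (r2 <= min(lo, hi) || r2 >= max(lo, hi)))
      r2 <- (lo + hi) / 2                   # bisection fallback
    g2 <- eval_g(r2, it)
    if (done(g2)) return(result(r2, g2, it))
    upd(r2, g2)
    r0 <- r1; g0 <- g1; r1 <- r2; g1 <- g2
  }
  stop("pre-shrink non-convergence after ", max_iter,
       " iterations; best relative error ",
       signif(min(abs(trace$volume - target_volume)) / target_volume, 3))
}

#' @export
print.preshrink_result <- function(x, ...) {
  cat(sprintf(
    "preshrink_result (%s): inner_rate=%.4f, %d iterations, volume error %.3g%%\n",
    x$phase, x$inner_rate, x$iterations, 100 * x$volume_error))
  invisible(x)
}

#' Calibrate one phase: zero-load geometry plus material stiffness
#'
#' A phase of the two-geometry cycle must satisfy two imaged volumes: the
#' minimum volume at the phase's low-pressure landmark (matched by the
#' pre-shrink rate) and the maximum volume at its high-pressure landmark
#' (matched by a stiffness scale factor). The two one-dimensional solves are
#' alternated until both volumes agree with their targets.
#'
#' Diastole: Vmin at Pmin, Vmax at Pdia. Systole: Vmin at Psys, Vmax at Pmax.
#'
#' @param s_in_vivo in-vivo minimum-volume \code{\link{contour_stack}}.
#' @param material starting material parameters.
#' @param sched a \code{\link{pressure_schedule}}.
#' @param v_min,v_max imaged minimum and maximum cavity volumes (cm^3).
#' @param phase \code{"diastole"} or \code{"systole"}.
#' @param tol relative volume tolerance on both landmarks (default 0.005).
#' @param max_outer alternation cap (default 10).
#' @return list: \code{preshrink} (a \code{preshrink_result}),
#'   \code{material} (scaled), \code{stiffness_factor}, landmark volume
#'   errors \code{err_min}, \code{err_max}.
#' @export
calibrate_phase <- function(s_in_vivo, material, sched, v_min, v_max,
                            phase = c("diastole", "systole"), tol = 0.005,
                            max_outer = 10) {
  phase <- match.arg(phase)
  p_lo <- if (phase == "diastole") sched$Pmin else sched$Psys
  p_hi <- if (phase == "diastole") sched$Pdia else sched$Pmax
  mat <- material
  fac <- 1
  ps <- NULL
  for (k in seq_len(max_outer)) {
    ps <- find_zero_load(s_in_vivo, mat, p_lo, v_min, phase, tol = tol / 2)
    ch <- to_equivalent_chamber(ps$zero_load)
    v_hi <- inflate(ch, mat, p_hi)$volume
    err_max <- abs(v_hi - v_max) / v_max
    if (err_max < tol) break
    sc <- scale_stiffness_to_volume(mat, ch, p_hi, v_max, tol = tol / 2)
    mat <- sc$params
    fac <- fac * sc$factor
  }
  ch <- to_equivalent_chamber(ps$zero_load)
  err_min <- abs(inflate(ch, mat, p_lo)$volume - v_min) / v_min
  err_max <- abs(inflate(ch, mat, p_hi)$volume - v_max) / v_max
  list(preshrink = ps, material = mat, stiffness_factor = fac,
       err_min = err_min, err_max = err_max)
}

#' Calibrate and simulate a full 2G patient model
#'
#' Convenience pipeline: calibrates the diastole and systole phases of an
#' in-vivo minimum-volume geometry against an imaged (Vmin, Vmax) pair and
#' runs the two-geometry cycle.
#'
#' @param s_in_vivo in-vivo minimum-volume \code{\link{contour_stack}}.
#' @param materials list with \code{diastole} and \code{systole} starting
#'   parameters (default \code{\link{default_material}} sets).
#' @param sched a \code{\link{pressure_schedule}}.
#' @param v_min,v_max imaged minimum and maximum cavity volumes (cm^3).
#' @param tol relative landmark-volume tolerance (default 0.005).
#' @return list: \code{cycle} (a \code{cycle_result}), \code{diastole},
#'   \code{systole} (calibration results), \code{stack_map} (zero-load
#'   stacks, for \code{\link{extract_phase_metrics}}).
#' @export
build_2g_model <- function(s_in_vivo, v_min, v_max,
                           materials = list(
                             diastole = default_material("ventricle_diastole"),
                             systole = default_material("ventricle_systole")),
                           sched = pressure_schedule(), tol = 0.005) {
  cal_d <- calibrate_phase(s_in_vivo, materials$diastole, sched,
                           v_min, v_max, "diastole", tol)
  cal_s <- calibrate_phase(s_in_vivo, materials$systole, sched,
                           v_min, v_max, "systole", tol)
  cyc <- simulate_cycle_2G(cal_d$preshrink, cal_s$preshrink,
                           list(diastole = cal_d$material,
                                systole = cal_s$material), sched)
  list(cycle = cyc, diastole = cal_d, systole = cal_s,
       stack_map = list(diastole = cal_d$preshrink$zero_load,
                        systole = cal_s$preshrink$zero_load))
}
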