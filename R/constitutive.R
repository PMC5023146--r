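#' Deformation state
#'
#' Bundles a deformation gradient \eqn{F} with the derived right Cauchy-Green
#' tensor \eqn{C = F^T F}, the Green-Lagrange strain \eqn{E = (C - I)/2} and a
#' reference-configuration fiber direction. All constitutive evaluations in the
#' package consume this object.
#'
#' @param F 3x3 deformation gradient, \code{det F > 0}.
#' @param fiber_dir unit fiber direction in the reference configuration
#'   (normalized internally).
#' @return An object of class \code{deformation_state} with elements
#'   \code{F}, \code{C}, \code{E}, \code{fiber_dir}.
#' @export
deformation_state <- function(F, fiber_dir = c(1, 0, 0)) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3L, 3L)) || any(!is.finite(F)))
    stop("invalid-deformation: F must be a finite 3x3 matrix")
  if (det(F) <= 0)
    stop("invalid-deformation: det F must be positive")
  fiber_dir <- as.numeric(fiber_dir)
  nf <- sqrt(sum(fiber_dir^2))
  if (length(fiber_dir) != 3L || nf == 0)
    stop("fiber_dir must be a non-zero length-3 vector")
  C <- crossprod(F)                      # F^T F
  C <- (C + t(C)) / 2                    # symmetrize against round-off
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("invalid-deformation: C not positive definite")
  structure(list(F = F, C = C, E = (C - diag(3)) / 2,
                 fiber_dir = fiber_dir / nf),
            class = "deformation_state")
}

#' Isotropic modified Mooney-Rivlin parameters
#'
#' Strain-energy density
#' \deqn{W = c_1(I_1-3) + c_2(I_2-3) + D_1[\exp(D_2(I_1-3)) - 1].}
#' The printed form of this law groups the exponential as
#' \eqn{\exp(D_2(I_1-3)-1)}, which gives non-zero energy and stress at the
#' identity deformation; the zero-at-reference grouping above is the package
#' default and the literal grouping is available via \code{literal_grouping}.
#'
#' @param c1,c2 stress-like coefficients (kPa).
#' @param D1 stress-like coefficient (kPa).
#' @param D2 dimensionless exponent.
#' @param literal_grouping use the literal printed exponent grouping
#'   (compatibility flag, default \code{FALSE}).
#' @return object of class \code{iso_mr_params}.
#' @export
iso_mr_params <- function(c1, c2 = 0, D1 = 0, D2 = 0, literal_grouping = FALSE) {
  stopifnot(c1 >= 0, D1 >= 0, D2 >= 0)
  structure(list(c1 = c1, c2 = c2, D1 = D1, D2 = D2,
                 literal_grouping = isTRUE(literal_grouping)),
            class = "iso_mr_params")
}

#' Anisotropic (transversely isotropic) modified Mooney-Rivlin parameters
#'
#' Adds the fiber-reinforcement term
#' \eqn{\frac{K_1}{2K_2}[\exp(K_2(I_4-1)^2) - 1]} to the isotropic law, with
#' \eqn{I_4 = C_{ij} (n_f)_i (n_f)_j} the squared fiber stretch. The
#' \eqn{K_2 \to 0} limit \eqn{(K_1/2)(I_4-1)^2} is handled explicitly.
#'
#' @param iso \code{iso_mr_params} object.
#' @param K1 stress-like fiber stiffness (kPa), \code{K1 >= 0}.
#' @param K2 dimensionless exponent, \code{K2 >= 0} (0 means quadratic limit).
#' @return object of class \code{aniso_mr_params}.
#' @export
aniso_mr_params <- function(iso, K1, K2) {
  stopifnot(inherits(iso, "iso_mr_params"), K1 >= 0, K2 >= 0)
  structure(list(iso = iso, K1 = K1, K2 = K2), class = "aniso_mr_params")
}

#' Fung-type transversely isotropic parameters
#'
#' \deqn{W = \frac{C_f}{2}(e^Q - 1),\quad
#'  Q = b_1 E_{ff}^2 + b_2(E_{cc}^2+E_{rr}^2+E_{cr}^2+E_{rc}^2)
#'        + b_3(E_{fc}^2+E_{cf}^2+E_{fr}^2+E_{rf}^2),}
#' with strains expressed in local fiber / cross-fiber / radial axes.
#'
#' @param C_f stress-like scale (kPa), \code{C_f >= 0}.
#' @param b1,b2,b3 dimensionless exponents.
#' @return object of class \code{fung_params}.
#' @export
fung_params <- function(C_f, b1, b2, b3) {
  stopifnot(C_f >= 0)
  structure(list(C_f = C_f, b1 = b1, b2 = b2, b3 = b3),
            class = "fung_params")
}

#' Strain invariants of a deformation state
#'
#' @param state a \code{\link{deformation_state}}.
#' @return list with \code{I1 = tr C}, \code{I2 = (I1^2 - tr(C C))/2} and the
#'   fiber invariant \code{I4 = n_f' C n_f}.
#' @export
strain_invariants <- function(state) {
  stopifnot(inherits(state, "deformation_state"))
  C <- state$C
  I1 <- sum(diag(C))
  I2 <- (I1^2 - sum(C * C)) / 2
  n <- state$fiber_dir
  I4 <- drop(n %*% C %*% n)
  list(I1 = I1, I2 = I2, I4 = I4)
}

#' Isotropic Mooney-Rivlin strain-energy density
#'
#' @param p \code{iso_mr_params}.
#' @param I1,I2 first and second strain invariants.
#' @return energy density (kPa).
#' @export
energy_iso <- function(p, I1, I2) {
  stopifnot(inherits(p, "iso_mr_params"))
  ex <- if (p$literal_grouping) exp(p$D2 * (I1 - 3) - 1) else
    exp(p$D2 * (I1 - 3)) - 1
  if (any(!is.finite(ex)))
    stop("parameter/stretch-range error: exponential overflow in energy_iso")
  p$c1 * (I1 - 3) + p$c2 * (I2 - 3) + p$D1 * ex
}

#' Anisotropic Mooney-Rivlin strain-energy density
#'
#' @param p \code{aniso_mr_params}.
#' @param I1,I2,I4 strain invariants (\code{I4 > 0}).
#' @return energy density (kPa).
#' @export
energy_aniso <- function(p, I1, I2, I4) {
  stopifnot(inherits(p, "aniso_mr_params"), all(I4 > 0))
  w_iso <- energy_iso(p$iso, I1, I2)
  d <- I4 - 1
  w_f <- if (p$K2 == 0) {
    (p$K1 / 2) * d^2                      # K2 -> 0 limit
  } else if (p$iso$literal_grouping) {
    (p$K1 / (2 * p$K2)) * exp(p$K2 * d^2 - 1)
  } else {
    (p$K1 / (2 * p$K2)) * (exp(p$K2 * d^2) - 1)
  }
  if (any(!is.finite(w_f)))
    stop("parameter/stretch-range error: exponential overflow in energy_aniso")
  w_iso + w_f
}

#' Fung-type strain-energy density
#'
#' @param p \code{fung_params}.
#' @param E 3x3 Green-Lagrange strain in local (fiber, cross-fiber, radial)
#'   axes.
#' @return energy density (kPa).
#' @export
energy_fung <- function(p, E) {
  stopifnot(inherits(p, "fung_params"))
  E <- as.matrix(E)
  Q <- p$b1 * E[1, 1]^2 +
    p$b2 * (E[2, 2]^2 + E[3, 3]^2 + E[2, 3]^2 + E[3, 2]^2) +
    p$b3 * (E[1, 2]^2 + E[2, 1]^2 + E[1, 3]^2 + E[3, 1]^2)
  w <- (p$C_f / 2) * (exp(Q) - 1)
  if (!is.finite(w))
    stop("parameter/stretch-range error: exponential overflow in energy_fung")
  w
}

# dW/dI1, dW/dI2, dW/dI4 for the Mooney-Rivlin family (internal)
mr_energy_derivs <- function(p, I1, I2, I4) {
  if (inherits(p, "iso_mr_params")) p <- aniso_mr_params(p, 0, 0)
  iso <- p$iso
  W1 <- iso$c1 + if (iso$literal_grouping)
    iso$D1 * iso$D2 * exp(iso$D2 * (I1 - 3) - 1) else
      iso$D1 * iso$D2 * exp(iso$D2 * (I1 - 3))
  d <- I4 - 1
  W4 <- if (p$K2 == 0) p$K1 * d else if (iso$literal_grouping)
    p$K1 * d * exp(p$K2 * d^2 - 1) else p$K1 * d * exp(p$K2 * d^2)
  list(W1 = W1, W2 = iso$c2, W4 = W4)
}

# Total strain energy as a function of the deformation state (internal;
# used by the finite-difference stress oracle as well).
energy_of_state <- function(p, state) {
  if (inherits(p, "fung_params")) {
    R <- fiber_basis(state$fiber_dir)
    energy_fung(p, t(R) %*% state$E %*% R)
  } else if (inherits(p, "aniso_mr_params")) {
    iv <- strain_invariants(state)
    energy_aniso(p, iv$I1, iv$I2, iv$I4)
  } else if (inherits(p, "iso_mr_params")) {
    iv <- strain_invariants(state)
    energy_iso(p, iv$I1, iv$I2)
  } else stop("unknown material parameter class")
}

# Orthonormal basis with first column = f (internal). The Fung exponent Q is
# invariant under rotations of the cross-fiber/radial pair, so the completion
# is arbitrary.
fiber_basis <- function(f) {
  f <- f / sqrt(sum(f^2))
  a <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  c2 <- a - sum(a * f) * f
  c2 <- c2 / sqrt(sum(c2^2))
  c3 <- c(f[2] * c2[3] - f[3] * c2[2],
          f[3] * c2[1] - f[1] * c2[3],
          f[1] * c2[2] - f[2] * c2[1])
  cbind(f, c2, c3, deparse.level = 0)
}

#' Cauchy stress of an incompressible hyperelastic state
#'
#' Evaluates the Cauchy stress tensor for the Mooney-Rivlin family
#' (\eqn{\sigma = 2(W_1 + I_1 W_2)B - 2W_2 B^2 + 2W_4\, Fn_f \otimes Fn_f - pI})
#' or the Fung law (second Piola-Kirchhoff from \eqn{\partial W/\partial E}
#' pushed forward). Incompressibility is enforced exactly: the Lagrange
#' pressure \eqn{p} is fixed by a traction-free direction whose normal stress
#' vanishes.
#'
#' @param p material parameters (\code{iso_mr_params}, \code{aniso_mr_params}
#'   or \code{fung_params}).
#' @param state a \code{\link{deformation_state}} with \code{det F = 1}
#'   (within 1e-8).
#' @param traction_free index 1..3 of the spatial axis, or a length-3 spatial
#'   direction vector, whose normal stress is zero. Default 3 (radial).
#' @return symmetric 3x3 Cauchy stress (kPa).
#' @export
cauchy_stress <- function(p, state, traction_free = 3) {
  stopifnot(inherits(state, "deformation_state"))
  J <- det(state$F)
  if (abs(J - 1) > 1e-8)
    stop("invalid-deformation: cauchy_stress requires det F = 1 (incompressible)")
  if (inherits(p, "fung_params")) {
    R <- fiber_basis(state$fiber_dir)
    Et <- t(R) %*% state$E %*% R
    Q <- p$b1 * Et[1, 1]^2 +
      p$b2 * (Et[2, 2]^2 + Et[3, 3]^2 + Et[2, 3]^2 + Et[3, 2]^2) +
      p$b3 * (Et[1, 2]^2 + Et[2, 1]^2 + Et[1, 3]^2 + Et[3, 1]^2)
    wts <- matrix(c(p$b1, p$b3, p$b3,
                    p$b3, p$b2, p$b2,
                    p$b3, p$b2, p$b2), 3, 3, byrow = TRUE)
    St <- p$C_f * exp(Q) * (wts * Et)      # dW/dE in fiber axes
    S <- R %*% St %*% t(R)
    sig <- state$F %*% S %*% t(state$F)
  } else {
    iv <- strain_invariants(state)
    dw <- mr_energy_derivs(p, iv$I1, iv$I2, iv$I4)
    B <- tcrossprod(state$F)               # F F^T
    fn <- drop(state$F %*% state$fiber_dir)
    sig <- 2 * (dw$W1 + iv$I1 * dw$W2) * B - 2 * dw$W2 * (B %*% B) +
      2 * dw$W4 * tcrossprod(fn)
  }
  if (length(traction_free) == 1L) {
    k <- as.integer(traction_free)
    pr <- sig[k, k]
  } else {
    d <- traction_free / sqrt(sum(traction_free^2))
    pr <- drop(d %*% sig %*% d)
  }
  sig <- sig - pr * diag(3)
  (sig + t(sig)) / 2
}

# Deformation state for a named loading mode at stretch lam (internal).
# Fiber along x. For uniaxial-crossfiber, the two lateral stretches are
# solved so both lateral normal stresses vanish.
mode_state <- function(p, lam, mode) {
  if (mode == "equibiaxial") {
    deformation_state(diag(c(lam, lam, lam^-2)))
  } else if (mode == "uniaxial-fiber") {
    deformation_state(diag(c(lam, lam^-0.5, lam^-0.5)))
  } else if (mode == "uniaxial-crossfiber") {
    if (abs(lam - 1) < 1e-12) return(deformation_state(diag(3)))
    resid <- function(m1) {
      st <- deformation_state(diag(c(m1, lam, 1 / (lam * m1))))
      cauchy_stress(p, st, traction_free = 3)[1, 1]
    }
    m1 <- tryCatch(
      stats::uniroot(resid, c(0.2, 3), tol = 1e-12)$root,
      error = function(e) lam^-0.5)
    deformation_state(diag(c(m1, lam, 1 / (lam * m1))))
  } else stop("unknown mode: ", mode)
}

#' Stress-stretch curve
#'
#' Fiber-direction (\code{T_ff}) and cross-fiber (\code{T_cc}) Cauchy stresses
#' over a stretch grid, in a named loading mode, with the radial direction
#' traction-free.
#'
#' @param p material parameters.
#' @param mode one of \code{"equibiaxial"}, \code{"uniaxial-fiber"},
#'   \code{"uniaxial-crossfiber"}.
#' @param lambda ascending stretch grid with \code{lambda >= 1}.
#' @return data.frame with columns \code{lambda}, \code{T_ff}, \code{T_cc}
#'   and attribute \code{mode}; class \code{stress_stretch_curve}.
#' @export
stress_stretch_curve <- function(p, mode = "equibiaxial", lambda) {
  mode <- match.arg(mode,
                    c("equibiaxial", "uniaxial-fiber", "uniaxial-crossfiber"))
  lambda <- as.numeric(lambda)
  if (any(lambda < 1) || is.unsorted(lambda, strictly = FALSE))
    stop("lambda grid must be ascending and >= 1")
  tf <- tc <- numeric(length(lambda))
  for (i in seq_along(lambda)) {
    st <- mode_state(p, lambda[i], mode)
    sg <- cauchy_stress(p, st, traction_free = 3)
    tf[i] <- sg[1, 1]
    tc[i] <- sg[2, 2]
  }
  out <- data.frame(lambda = lambda, T_ff = tf, T_cc = tc)
  attr(out, "mode") <- mode
  class(out) <- c("stress_stretch_curve", "data.frame")
  out
}

#' Fit the anisotropic Mooney-Rivlin law to Fung-law stress curves
#'
#' Bounded least squares (3 fixed multi-starts unless \code{start} is given)
#' on the summed squared \code{T_ff}/\code{T_cc} differences over the given
#' modes and stretch range.
#'
#' @param f target law: \code{fung_params} (the usual case) or any
#'   Mooney-Rivlin parameter object (useful for self-fit checks).
#' @param lambda_max upper end of the stretch range (default 1.3).
#' @param n_grid number of grid points (default 25).
#' @param modes loading modes to match (default equibiaxial).
#' @param start optional numeric start \code{c(c1, c2, D1, D2, K1, K2)}.
#' @return list with \code{params} (\code{aniso_mr_params}), \code{rms}
#'   (kPa, over all matched stresses), \code{converged}.
#' @export
fit_aniso_to_fung <- function(f, lambda_max = 1.3, n_grid = 25,
                              modes = "equibiaxial", start = NULL) {
  stopifnot(inherits(f, c("fung_params", "aniso_mr_params", "iso_mr_params")))
  lam <- seq(1, lambda_max, length.out = n_grid)
  targets <- lapply(modes, function(m) stress_stretch_curve(f, m, lam))
  n_obs <- 2L * n_grid * length(modes)
  ssq <- function(th) {
    pp <- aniso_mr_params(iso_mr_params(th[1], th[2], th[3], th[4]),
                          th[5], max(th[6], 1e-8))
    s <- 0
    for (k in seq_along(modes)) {
      cur <- tryCatch(stress_stretch_curve(pp, modes[k], lam),
                      error = function(e) NULL)
      if (is.null(cur)) return(1e12)
      s <- s + sum((cur$T_ff - targets[[k]]$T_ff)^2 +
                     (cur$T_cc - targets[[k]]$T_cc)^2)
    }
    s
  }
  starts <- if (!is.null(start)) list(as.numeric(start)) else
    list(c(1, 0.1, 0.5, 1, 1, 1),
         c(5, 0.5, 0.1, 3, 5, 3),
         c(0.2, 0.01, 1, 0.5, 0.5, 0.5))
  best <- NULL
  for (s0 in starts) {
    op <- tryCatch(
      stats::optim(s0, ssq, method = "L-BFGS-B",
                   lower = c(0, -5, 0, 0, 0, 1e-6),
                   upper = rep(1e3, 6),
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) stop("optimizer failed on all starts")
  th <- best$par
  list(params = aniso_mr_params(iso_mr_params(th[1], th[2], th[3], th[4]),
                                th[5], max(th[6], 1e-8)),
       rms = sqrt(best$value / n_obs),
       converged = best$convergence == 0)
}

# Multiply all stress-like parameters by a factor (internal)
scale_material <- function(p, factor) {
  if (inherits(p, "fung_params")) {
    fung_params(p$C_f * factor, p$b1, p$b2, p$b3)
  } else if (inherits(p, "aniso_mr_params")) {
    aniso_mr_params(scale_material(p$iso, factor), p$K1 * factor, p$K2)
  } else if (inherits(p, "iso_mr_params")) {
    iso_mr_params(p$c1 * factor, p$c2 * factor, p$D1 * factor, p$D2,
                  p$literal_grouping)
  } else stop("unknown material parameter class")
}

#' Scale material stiffness to match an inflated volume
#'
#' Finds a single multiplicative factor on all stress-like parameters
#' (c1, c2, D1, K1 — or C_f for the Fung law) so that inflating the chamber at
#' the given pressure reproduces the target cavity volume. The inflated volume
#' is strictly decreasing in the factor, so a bracketed root search on
#' log10(factor) in [-3, 3] is used.
#'
#' @param p material parameters.
#' @param chamber an \code{\link{equivalent_chamber}}.
#' @param pressure inflation pressure (kPa), > 0.
#' @param target_volume target cavity volume (cm^3).
#' @param tol relative volume tolerance (default 0.005).
#' @return list with \code{params} (scaled), \code{factor},
#'   \code{volume_error} (relative).
#' @export
scale_stiffness_to_volume <- function(p, chamber, pressure, target_volume,
                                      tol = 0.005) {
  stopifnot(pressure >= 0, target_volume > 0)
  vol_at <- function(lf) {
    inflate(chamber, scale_material(p, 10^lf), pressure)$volume
  }
  err <- function(lf) vol_at(lf) - target_volume
  e0 <- err(0)
  if (abs(e0) / target_volume < tol)
    return(list(params = p, factor = 1, volume_error = abs(e0) / target_volume))
  lo <- -3; hi <- 3
  e_lo <- tryCatch(err(lo), error = function(e) NA_real_)
  e_hi <- tryCatch(err(hi), error = function(e) NA_real_)
  if (!is.finite(e_lo) || !is.finite(e_hi) || e_lo * e_hi > 0)
    stop("calibration-failure: target volume unreachable within factor bounds")
  r <- stats::uniroot(err, c(lo, hi), tol = 1e-10)
  fac <- 10^r$root
  v <- vol_at(r$root)
  verr <- abs(v - target_volume) / target_volume
  if (verr > tol)
    stop("calibration-failure: residual volume error ", signif(verr, 3))
  list(params = scale_material(p, fac), factor = fac, volume_error = verr)
}

#' Default material parameter sets
#'
#' Named configuration defaults for four tissue types: ventricle wall in the
#' diastole and systole phases (anisotropic law; systole stiffer, standing in
#' for the contracted sarcomere state), and isotropic patch and scar. The
#' numeric values are package configuration defaults on the physiological
#' stiffness scale; per-patient models rescale them against measured volumes
#' with \code{\link{scale_stiffness_to_volume}}.
#'
#' @param name one of \code{"ventricle_diastole"}, \code{"ventricle_systole"},
#'   \code{"patch"}, \code{"scar"}.
#' @return material parameter object.
#' @export
default_material <- function(name = c("ventricle_diastole", "ventricle_systole",
                                      "patch", "scar")) {
  name <- match.arg(name)
  switch(name,
         ventricle_diastole = aniso_mr_params(
           iso_mr_params(c1 = 1, c2 = 0, D1 = 0.25, D2 = 1), K1 = 2, K2 = 1),
         ventricle_systole = aniso_mr_params(
           iso_mr_params(c1 = 8, c2 = 0, D1 = 2, D2 = 1), K1 = 16, K2 = 1),
         patch = iso_mr_params(c1 = 100, c2 = 0, D1 = 20, D2 = 2),
         scar = iso_mr_params(c1 = 50, c2 = 0, D1 = 10, D2 = 2))
}

#' Read/write material parameter sets as JSON
#'
#' JSON format: an object of named parameter sets, each with a \code{law}
#' field (\code{"iso_mr"}, \code{"aniso_mr"}, \code{"fung"}) and the law's
#' named parameters.
#'
#' @param path file path.
#' @return named list of material parameter objects.
#' @export
read_materials_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(m) {
    switch(m$law,
           iso_mr = iso_mr_params(m$c1, m$c2 %||% 0, m$D1 %||% 0, m$D2 %||% 0),
           aniso_mr = aniso_mr_params(
             iso_mr_params(m$c1, m$c2 %||% 0, m$D1 %||% 0, m$D2 %||% 0),
             m$K1, m$K2),
           fung = fung_params(m$C_f, m$b1, m$b2, m$b3),
           stop("unknown law: ", m$law))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
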