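# Shared fixture builders (all geometry is generated in code)

circle_pts <- function(r = 1, n = 100, center = c(0, 0), phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

ellipse_pts <- function(a, b, n = 100, center = c(0, 0), rot = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  x <- a * cos(th); y <- b * sin(th)
  cbind(center[1] + x * cos(rot) - y * sin(rot),
        center[2] + x * sin(rot) + y * cos(rot))
}

# Stack of circular slices sampling a sphere of radius R (both poles
# truncated at zfrac), wall thickness `wall`
sphere_stack <- function(R = 3, wall = 0.4, n_slices = 25, zfrac = 0.9,
                         n = 100) {
  zs <- seq(-zfrac * R, zfrac * R, length.out = n_slices)
  slices <- lapply(zs, function(z)
    ventricle_slice(contour(circle_pts(sqrt(R^2 - z^2), n)),
                    contour(circle_pts(sqrt((R + wall)^2 - z^2), n)),
                    z))
  contour_stack(slices, spacing = diff(zs)[1], label = "sphere")
}

# Stack of identical annular slices (cylinder)
cylinder_stack <- function(r = 2, wall = 0.5, h = 5, n_slices = 10, n = 100) {
  dz <- h / n_slices
  zs <- (seq_len(n_slices) - 0.5) * dz
  slices <- lapply(zs, function(z)
    ventricle_slice(contour(circle_pts(r, n)),
                    contour(circle_pts(r + wall, n)), z))
  contour_stack(slices, spacing = dz, label = "cylinder")
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Random incompressible deformation gradient near the identity
random_incompressible_F <- function(scale = 0.15) {
  F <- diag(3) + matrix(rnorm(9, sd = scale), 3)
  F / det(F)^(1 / 3)
}

# Finite-difference Cauchy stress oracle: sigma = (dW/dF) F^T - pr I with the
# Lagrange pressure fixed by the same traction-free direction
fd_cauchy_stress <- function(p, F, fiber, traction_free = 3, h = 1e-6) {
  P <- matrix(0, 3, 3)
  wof <- function(Fx) {
    C <- crossprod(Fx)
    st <- structure(list(F = Fx, C = C, E = (C - diag(3)) / 2,
                         fiber_dir = fiber / sqrt(sum(fiber^2))),
                    class = "deformation_state")
    rv2g:::energy_of_state(p, st)
  }
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (wof(Fp) - wof(Fm)) / (2 * h)
  }
  sig <- P %*% t(F) / det(F)
  sig <- (sig + t(sig)) / 2
  pr <- if (length(traction_free) == 1L) sig[traction_free, traction_free]
  else {
    d <- traction_free / sqrt(sum(traction_free^2))
    drop(d %*% sig %*% d)
  }
  sig - pr * diag(3)
}

# O(n^2) pairwise AUC oracle, ties counted 1/2
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}
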