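test_that("strain invariants: identity, equibiaxial closed form, brute-force contraction", {
  expect_equal(unlist(strain_invariants(deformation_state(diag(3)))),
               c(I1 = 3, I2 = 3, I4 = 1))

  lam <- 1.25
  st <- deformation_state(diag(c(lam, lam, lam^-2)), fiber_dir = c(1, 0, 0))
  iv <- strain_invariants(st)
  expect_equal(iv$I1, 2 * lam^2 + lam^-4)
  expect_equal(iv$I4, lam^2)

  set.seed(11)
  for (rep in 1:5) {
    F <- random_incompressible_F(0.3)
    nf <- rnorm(3); nf <- nf / sqrt(sum(nf^2))
    st <- deformation_state(F, nf)
    C <- crossprod(F)
    # explicit index-summation oracle
    I1o <- sum(diag(C))
    I2o <- 0
    for (i in 1:3) for (j in 1:3) I2o <- I2o + C[i, j] * C[i, j]
    I2o <- (I1o^2 - I2o) / 2
    I4o <- 0
    for (i in 1:3) for (j in 1:3) I4o <- I4o + C[i, j] * nf[i] * nf[j]
    iv <- strain_invariants(st)
    expect_equal(iv$I1, I1o, tolerance = 1e-12)
    expect_equal(iv$I2, I2o, tolerance = 1e-12)
    expect_equal(iv$I4, I4o, tolerance = 1e-12)
  }

  expect_error(deformation_state(diag(c(1, 1, -1))), "invalid-deformation")
})

test_that("strain-energy laws: reference state, direct values, symmetries", {
  # all laws vanish at the identity deformation
  expect_equal(energy_iso(iso_mr_params(1.3, 0.4, 2, 3), 3, 3), 0)
  expect_equal(energy_aniso(aniso_mr_params(iso_mr_params(1, 1, 1, 1), 2, 2),
                            3, 3, 1), 0)
  expect_equal(energy_fung(fung_params(2, 10, 5, 3), matrix(0, 3, 3)), 0)

  # direct-evaluation oracles
  expect_equal(energy_iso(iso_mr_params(1, 0, 0, 0), 4, 3), 1)
  expect_equal(energy_iso(iso_mr_params(0, 0, 2, 3), 3.1, 3),
               2 * (exp(0.3) - 1))
  p_an <- aniso_mr_params(iso_mr_params(0, 0, 0, 0), 2, 1)
  expect_equal(energy_aniso(p_an, 3, 3, 2), exp(1) - 1)
  E <- matrix(0, 3, 3); E[1, 1] <- 1
  expect_equal(energy_fung(fung_params(2, 1, 0, 0), E), exp(1) - 1)

  # anisotropic term symmetric in I4 about 1
  expect_equal(energy_aniso(p_an, 3, 3, 1.3), energy_aniso(p_an, 3, 3, 0.7))

  # K2 -> 0 limit is the quadratic law, not a crash
  p0 <- aniso_mr_params(iso_mr_params(0, 0, 0, 0), 3, 0)
  expect_equal(energy_aniso(p0, 3, 3, 1.4), (3 / 2) * 0.4^2)

  # Fung exponent invariant under swapping the shear pair within a b-group
  E1 <- matrix(0, 3, 3); E1[2, 3] <- 0.2
  E2 <- matrix(0, 3, 3); E2[3, 2] <- 0.2
  f <- fung_params(1, 2, 3, 4)
  expect_equal(energy_fung(f, E1), energy_fung(f, E2))

  # the literal printed exponent grouping is available and is non-zero at rest
  plit <- iso_mr_params(0, 0, 2, 3, literal_grouping = TRUE)
  expect_equal(energy_iso(plit, 3, 3), 2 * (exp(-1)))
})

test_that("cauchy stress: stress-free reference, neo-Hookean closed form, FD oracle", {
  mats <- list(
    aniso = aniso_mr_params(iso_mr_params(1.2, 0.3, 0.5, 2), 3, 1.5),
    fung = fung_params(1.1, 8, 4, 2))
  for (m in mats)
    expect_equal(cauchy_stress(m, deformation_state(diag(3))),
                 matrix(0, 3, 3), tolerance = 1e-12)

  # incompressible neo-Hookean uniaxial: sigma_axial = 2 c1 (lam^2 - 1/lam)
  lam <- 1.35
  nh <- aniso_mr_params(iso_mr_params(2.5, 0, 0, 0), 0, 1)
  st <- deformation_state(diag(c(lam, lam^-0.5, lam^-0.5)))
  sig <- cauchy_stress(nh, st, traction_free = 3)
  expect_equal(sig[1, 1], 2 * 2.5 * (lam^2 - 1 / lam), tolerance = 1e-10)
  expect_equal(sig[2, 2], 0, tolerance = 1e-10)

  # finite-difference energy-gradient oracle on random incompressible states
  set.seed(42)
  for (rep in 1:4) {
    F <- random_incompressible_F()
    nf <- rnorm(3); nf <- nf / sqrt(sum(nf^2))
    for (m in mats) {
      sig <- cauchy_stress(m, deformation_state(F, nf), traction_free = 2)
      sfd <- fd_cauchy_stress(m, F, nf, traction_free = 2)
      expect_lt(max(abs(sig - sfd)) / max(abs(sig), 1e-8), 1e-5)
    }
  }
})

test_that("energy is frame-indifferent under superposed rotations", {
  set.seed(7)
  for (rep in 1:5) {
    F <- random_incompressible_F()
    Q <- random_rotation()
    nf <- c(1, 0, 0)
    for (m in list(aniso_mr_params(iso_mr_params(1, 0.2, 0.3, 1.5), 2, 1),
                   fung_params(0.9, 6, 3, 2))) {
      w1 <- rv2g:::energy_of_state(m, deformation_state(F, nf))
      w2 <- rv2g:::energy_of_state(m, deformation_state(Q %*% F, nf))
      expect_equal(w1, w2, tolerance = 1e-12)
    }
  }
})

test_that("stress-stretch curves: zero at rest, fiber/cross-fiber ordering", {
  p <- aniso_mr_params(iso_mr_params(1, 0, 0.3, 1), 3, 1)
  c0 <- stress_stretch_curve(p, "equibiaxial", 1)
  expect_equal(c0$T_ff, 0, tolerance = 1e-12)
  expect_equal(c0$T_cc, 0, tolerance = 1e-12)

  lam <- seq(1, 1.3, length.out = 12)
  cv <- stress_stretch_curve(p, "equibiaxial", lam)
  expect_true(all(cv$T_ff[-1] > cv$T_cc[-1]))     # K1 > 0
  expect_true(all(diff(cv$T_ff) > 0))

  iso <- aniso_mr_params(iso_mr_params(1, 0, 0.3, 1), 0, 1)
  ci <- stress_stretch_curve(iso, "equibiaxial", lam)
  expect_equal(ci$T_ff, ci$T_cc, tolerance = 1e-10)

  expect_error(stress_stretch_curve(p, "equibiaxial", c(1.2, 1.1)),
               "ascending")
  # uniaxial cross-fiber mode solves both lateral tractions to zero
  st <- rv2g:::mode_state(p, 1.2, "uniaxial-crossfiber")
  sg <- cauchy_stress(p, st, traction_free = 3)
  expect_lt(abs(sg[1, 1]), 1e-7)
})

test_that("anisotropic MR fit to Fung targets: self-fit, round-trip, null target", {
  lam <- seq(1, 1.3, length.out = 25)

  # idempotence on a self-generated target (started at the truth)
  truth <- aniso_mr_params(iso_mr_params(1.5, 0.2, 0.4, 1.2), 2.5, 1.8)
  fit_self <- fit_aniso_to_fung(truth,
                                start = c(1.5, 0.2, 0.4, 1.2, 2.5, 1.8))
  expect_lt(fit_self$rms, 1e-6)
  tgt_self <- stress_stretch_curve(truth, "equibiaxial", lam)
  got_self <- stress_stretch_curve(fit_self$params, "equibiaxial", lam)
  expect_equal(got_self$T_ff, tgt_self$T_ff, tolerance = 1e-6)

  # round-trip: fit the MR law to a Fung target, curves agree within 5% RMS
  f <- fung_params(0.6, 10, 4, 2)
  ft <- fit_aniso_to_fung(f, lambda_max = 1.3, n_grid = 25)
  tgt <- stress_stretch_curve(f, "equibiaxial", lam)
  got <- stress_stretch_curve(ft$params, "equibiaxial", lam)
  rms <- sqrt(mean(c(got$T_ff - tgt$T_ff, got$T_cc - tgt$T_cc)^2))
  expect_lt(rms / max(abs(c(tgt$T_ff, tgt$T_cc))), 0.05)

  # zero-stiffness target fits to identically zero stress
  f0 <- fung_params(0, 10, 4, 2)
  ft0 <- fit_aniso_to_fung(f0, lambda_max = 1.2, n_grid = 10)
  got0 <- stress_stretch_curve(ft0$params, "equibiaxial", seq(1, 1.2, 0.05))
  expect_lt(max(abs(c(got0$T_ff, got0$T_cc))), 1e-4)
})

test_that("single stiffness factor calibrates inflated volume to target", {
  ch <- equivalent_chamber(3.2, 3.65)
  m <- default_material("ventricle_diastole")
  v1 <- inflate(ch, m, 1.0)$volume

  # already matched -> factor 1
  sc1 <- scale_stiffness_to_volume(m, ch, 1.0, v1)
  expect_equal(sc1$factor, 1)

  # smaller target at the same pressure -> stiffer (factor > 1), round trip
  v_small <- (v1 + 4 / 3 * pi * ch$Ri^3) / 2
  sc2 <- scale_stiffness_to_volume(m, ch, 1.0, v_small, tol = 0.005)
  expect_gt(sc2$factor, 1)
  expect_lt(abs(inflate(ch, sc2$params, 1.0)$volume - v_small) / v_small,
            0.005)
})
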