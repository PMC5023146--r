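test_that("equivalent chamber preserves cavity and wall volumes", {
  sph <- sphere_stack(R = 3, wall = 0.4, n_slices = 60, zfrac = 0.999)
  ch <- to_equivalent_chamber(sph)
  expect_lt(abs(ch$Ri - 3) / 3, 0.01)
  expect_lt(abs(ch$Ro - 3.4) / 3.4, 0.01)
  wall_stack <- stack_volume(sph, "outer") - stack_volume(sph, "inner")
  wall_ch <- 4 / 3 * pi * (ch$Ro^3 - ch$Ri^3)
  expect_lt(abs(wall_ch - wall_stack) / wall_stack, 0.001)

  # invariance under rigid in-plane motion of every slice
  moved <- contour_stack(lapply(sph$slices, function(sl)
    ventricle_slice(contour(sweep(unclass(sl$inner), 2, c(2, -1), "+")),
                    contour(sweep(unclass(sl$outer), 2, c(2, -1), "+")),
                    sl$z)), spacing = sph$spacing)
  ch2 <- to_equivalent_chamber(moved)
  expect_equal(ch2$Ri, ch$Ri, tolerance = 1e-12)

  expect_error(to_equivalent_chamber(
    contour_stack(lapply(sph$slices, function(sl)
      ventricle_slice(sl$inner, contour(unclass(sl$inner) * 1.000000001),
                      sl$z)), spacing = sph$spacing)), "wall")
})

test_that("inflation: zero-pressure state, wall boundary conditions, incompressibility", {
  ch <- equivalent_chamber(3.2, 3.7)
  mat <- default_material("ventricle_diastole")

  s0 <- inflate(ch, mat, 0)
  expect_equal(s0$volume, 4 / 3 * pi * ch$Ri^3, tolerance = 1e-10)
  expect_lt(max(abs(s0$profile$sigma_tt)), 1e-10)

  for (p in c(0.5, 2, 8)) {
    st <- inflate(ch, mat, p)
    expect_equal(st$profile$sigma_rr[1], -p, tolerance = 1e-9)
    expect_lt(abs(st$profile$sigma_rr[nrow(st$profile)]), 1e-3 * p)
    expect_gt(st$stress_p1, 0)
    # wall material volume conserved through the deformation
    wall0 <- ch$Ro^3 - ch$Ri^3
    expect_lt(abs((st$ro^3 - st$ri^3) - wall0) / wall0, 1e-10)
  }

  # volume strictly increasing in pressure
  vols <- vapply(c(0.3, 1, 3, 6), function(p) inflate(ch, mat, p)$volume, 0)
  expect_true(all(diff(vols) > 0))

  # quadrature refinement changes the answer below 1e-6 relative
  v1 <- inflate(ch, mat, 2, rel.tol = 1e-8)$volume
  v2 <- inflate(ch, mat, 2, rel.tol = 1e-11)$volume
  expect_lt(abs(v1 - v2) / v2, 1e-6)
})

test_that("thin-wall limit reproduces the Laplace membrane stress within 3%", {
  ch <- equivalent_chamber(5, 5.05)
  st <- inflate(ch, iso_mr_params(30), 0.4)
  laplace <- 0.4 * st$ri / (2 * (st$ro - st$ri))
  expect_lt(abs(st$stress_p1 - laplace) / laplace, 0.03)
})

test_that("degenerate 2G cycle equals 1G and is free of discontinuities", {
  ch <- equivalent_chamber(3.4, 3.85)
  mat <- default_material("ventricle_diastole")
  sched <- pressure_schedule(Pmin = 0.3, Pdia = 5, Pmax = 5, Psys = 0.3000001,
                             samples_per_phase = 5)
  cyc2 <- simulate_cycle_2G(ch, ch, list(diastole = mat, systole = mat), sched)
  cyc1 <- simulate_cycle_1G(ch, mat,
                            pressure_schedule(Pmin = 0.3, Pdia = 5, Pmax = 5,
                                              Psys = 2, samples_per_phase = 5))
  expect_equal(cyc1$series$vol_cm3, cyc2$series$vol_cm3, tolerance = 1e-6)
  expect_equal(cyc1$series$stress_p1_kpa, cyc2$series$stress_p1_kpa,
               tolerance = 1e-5)
  # continuity at the phase transition
  n <- 5
  expect_equal(cyc2$series$stress_p1_kpa[n], cyc2$series$stress_p1_kpa[n + 1],
               tolerance = 1e-6)
  # constant-pressure schedule gives a constant state
  flat <- simulate_cycle_2G(ch, ch, list(diastole = mat, systole = mat),
                            pressure_schedule(1, 1.0000001, 1.0000002,
                                              1.0000001,
                                              samples_per_phase = 3))
  expect_lt(diff(range(flat$series$vol_cm3)) / flat$series$vol_cm3[1], 1e-6)
})

test_that("calibrated 2G cycle: stress orderings, volume closure, discontinuities", {
  stk <- generate_ventricle(synthetic_ventricle_spec(n_slices = 9))
  vmin <- stack_volume(stk, "inner")
  vmax <- 1.6 * vmin
  sched <- pressure_schedule(samples_per_phase = 3)
  mdl <- build_2g_model(stk, vmin, vmax, sched = sched)
  lm <- mdl$cycle$landmarks

  # Table-2-style orderings: BE > EF and EE > BF in stress
  expect_gt(lm$BE$stress_p1, lm$EF$stress_p1)
  expect_gt(lm$EE$stress_p1, lm$BF$stress_p1)
  # 2G-specific stress discontinuities at the phase switches
  expect_gt(abs(lm$BE$stress_p1 - lm$EF$stress_p1) / lm$EF$stress_p1, 0.05)

  # calibration closure: volumes match across the switches within 2%
  expect_lt(abs(lm$EF$volume - lm$BE$volume) / lm$BE$volume, 0.02)
  expect_lt(abs(lm$BF$volume - lm$EE$volume) / lm$EE$volume, 0.02)
  # and match the imaged trace
  expect_lt(abs(lm$BF$volume - vmin) / vmin, 0.02)
  expect_lt(abs(lm$EF$volume - vmax) / vmax, 0.02)

  # 1G begin-filling state is close to the 2G one (same diastole geometry)
  cyc1 <- simulate_cycle_1G(mdl$diastole$preshrink, mdl$diastole$material,
                            sched)
  expect_lt(abs(cyc1$landmarks$BF$stress_p1 - lm$BF$stress_p1) /
              max(lm$BF$stress_p1, 1e-9), 0.05)
})

test_that("phase metrics on the deformed stack: WT and C-cur respond to inflation", {
  stk <- generate_ventricle(synthetic_ventricle_spec(n_slices = 9))
  vmin <- stack_volume(stk, "inner")
  mdl <- build_2g_model(stk, vmin, 1.6 * vmin,
                        sched = pressure_schedule(samples_per_phase = 3))
  pm <- extract_phase_metrics(mdl$cycle, mdl$stack_map)
  expect_setequal(pm$state, c("BF", "EF", "BE", "EE"))
  bf <- pm[pm$state == "BF", ]; ef <- pm[pm$state == "EF", ]
  expect_gt(ef$vol_cm3, bf$vol_cm3)
  expect_lt(ef$wt_cm, bf$wt_cm)            # incompressible wall thins
  expect_lt(ef$ccur_1cm, bf$ccur_1cm)      # radius grows, curvature drops

  # zero pressure maps back to the zero-load stack metrics
  zl <- mdl$stack_map$diastole
  cyc0 <- simulate_cycle_2G(zl, mdl$stack_map$systole,
                            list(diastole = mdl$diastole$material,
                                 systole = mdl$systole$material),
                            pressure_schedule(Pmin = 1e-9, Pdia = 1,
                                              Pmax = 1.5, Psys = 1e-8,
                                              samples_per_phase = 2))
  pm0 <- extract_phase_metrics(cyc0, mdl$stack_map)
  wt_zl <- mean(vapply(zl$slices, function(sl) wall_thickness(sl)$mean, 0))
  expect_equal(pm0$wt_cm[pm0$state == "BF"], wt_zl, tolerance = 1e-3)
})
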