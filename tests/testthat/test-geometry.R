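test_that("contour resampling: circle, idempotence, perimeter preservation", {
  cc <- resample_contour(contour(circle_pts(2, 5000, phase = 0.3)), 100)
  r <- sqrt(rowSums(unclass(cc)^2))
  expect_true(all(abs(r - 2) < 1e-6))
  d <- sqrt(rowSums((unclass(cc)[c(2:100, 1), ] - unclass(cc))^2))
  expect_equal(d, rep(mean(d), 100), tolerance = 1e-6)  # equal spacing
  # spacing is the 100-gon chord of the target arc spacing 2 pi r / n
  expect_equal(mean(d), 2 * 2 * sin(pi / 100), tolerance = 1e-6)
  expect_lt(abs(polygon_perimeter(cc) - 2 * pi * 2) / (2 * pi * 2), 0.001)

  # resampling an equal-spaced polygon with the same n is idempotent
  c1 <- resample_contour(contour(circle_pts(1.5, 64, phase = 1)), 64)
  c2 <- resample_contour(c1, 64)
  expect_equal(unclass(c2), unclass(c1), tolerance = 1e-6)

  # ellipse perimeter vs dense-polygon quadrature oracle within 0.1%
  e <- resample_contour(contour(ellipse_pts(3, 2, 500)), 100)
  per_oracle <- polygon_perimeter(ellipse_pts(3, 2, 20000))
  expect_lt(abs(polygon_perimeter(e) - per_oracle) / per_oracle, 0.001)

  expect_error(resample_contour(contour(matrix(0, 9, 2) + 1e-16)),
               "degenerate")
})

test_that("disk-summation volume: cylinder, hemisphere, cubic scaling", {
  cyl <- cylinder_stack(r = 2, wall = 0.5, h = 5, n_slices = 10)
  expect_equal(stack_volume(cyl, "inner"), 20 * pi, tolerance = 1e-3)

  # hemisphere sampled at 50 mid-point slices vs (2/3) pi R^3
  R <- 3
  dz <- R / 50
  zs <- (seq_len(50) - 0.5) * dz
  slices <- lapply(zs, function(z)
    ventricle_slice(contour(circle_pts(sqrt(R^2 - z^2), 100)),
                    contour(circle_pts(sqrt(R^2 - z^2) + 0.3, 100)), z))
  hemi <- contour_stack(slices, spacing = dz)
  expect_lt(abs(stack_volume(hemi, "inner") - 2 / 3 * pi * R^3) /
              (2 / 3 * pi * R^3), 0.02)

  # similarity: volume scales as k^3
  k <- 1.7
  scaled <- contour_stack(lapply(cyl$slices, function(sl)
    ventricle_slice(contour(unclass(sl$inner) * k),
                    contour(unclass(sl$outer) * k), sl$z * k)),
    spacing = cyl$spacing * k)
  expect_equal(stack_volume(scaled, "inner"),
               k^3 * stack_volume(cyl, "inner"), tolerance = 1e-10)
})

test_that("wall thickness: annulus, ellipse brute force, rotation invariance", {
  sl <- ventricle_slice(contour(circle_pts(2, 100)),
                        contour(circle_pts(2.5, 100)), 0)
  wt <- wall_thickness(sl)
  expect_true(all(abs(wt$per_point - 0.5) < 1e-3))
  expect_false(any(wt$fallback))

  # concentric similar low-eccentricity ellipses vs dense nearest-distance
  sl2 <- ventricle_slice(contour(ellipse_pts(3, 2.7, 200)),
                         contour(ellipse_pts(3 * 1.15, 2.7 * 1.15, 200)), 0)
  wt2 <- wall_thickness(sl2)
  inner <- unclass(resample_contour(sl2$inner, 100))
  dense_outer <- ellipse_pts(3 * 1.15, 2.7 * 1.15, 20000)
  brute <- vapply(seq_len(100), function(i)
    sqrt(min((dense_outer[, 1] - inner[i, 1])^2 +
               (dense_outer[, 2] - inner[i, 2])^2)), 0)
  expect_lt(max(abs(wt2$per_point - brute) / brute), 0.01)

  # isometry: thickness invariant under rigid rotation + translation
  th <- 0.7; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  sl3 <- ventricle_slice(
    contour(sweep(unclass(sl2$inner) %*% t(Rm), 2, c(1, -2), "+")),
    contour(sweep(unclass(sl2$outer) %*% t(Rm), 2, c(1, -2), "+")), 0)
  expect_equal(wall_thickness(sl3)$mean, wt2$mean, tolerance = 1e-5)
})

test_that("circumferential curvature: circle, collinear window, ellipse analytic", {
  cc <- circumferential_curvature(resample_contour(contour(circle_pts(2, 100))))
  expect_true(all(abs(cc$per_point - 0.5) < 1e-6))

  expect_equal(rv2g:::circle_fit_curvature(1:7, rep(2, 7)), 0)

  # analytic ellipse curvature kappa(t) = a b / (a^2 sin^2 t + b^2 cos^2 t)^(3/2)
  a <- 3; b <- 2; n <- 100
  th <- 2 * pi * (seq_len(n) - 1) / n
  e <- contour(cbind(a * cos(th), b * sin(th)))
  kap <- circumferential_curvature(e)$per_point
  kan <- a * b / (a^2 * sin(th)^2 + b^2 * cos(th)^2)^1.5
  expect_lt(max(abs(kap - kan) / kan), 0.02)
})

test_that("longitudinal curvature: sphere, cylinder, translation invariance", {
  sph <- sphere_stack(R = 3, wall = 0.4, n_slices = 25, zfrac = 0.85)
  lc <- longitudinal_curvature(sph)
  interior <- lc$per_point[5:21, ]
  expect_lt(max(abs(interior - 1 / 3)) * 3, 0.02)

  cyl <- cylinder_stack(n_slices = 8)
  expect_lt(longitudinal_curvature(cyl)$mean, 1e-8)

  shifted <- contour_stack(lapply(sph$slices, function(sl)
    ventricle_slice(sl$inner, sl$outer, sl$z + 4)), spacing = sph$spacing)
  expect_equal(longitudinal_curvature(shifted)$mean, lc$mean,
               tolerance = 1e-10)

  expect_error(longitudinal_curvature(cylinder_stack(n_slices = 2)),
               ">= 3 slices")
})

test_that("quarter partition: equal arcs, disjoint cover, brute-force boundaries", {
  sl <- ventricle_slice(contour(circle_pts(2, 100)),
                        contour(circle_pts(2.5, 100)), 0)
  q <- quarter_partition(sl)
  expect_equal(lengths(q), rep(25L, 4))
  expect_setequal(unlist(q), 1:100)

  # elongated ellipse: boundaries match cumulative-arc-length search
  sl2 <- ventricle_slice(contour(ellipse_pts(4, 1.5, 300)),
                         contour(ellipse_pts(4.4, 1.9, 300)), 0)
  q2 <- quarter_partition(sl2)
  expect_setequal(unlist(q2), 1:100)
  inner <- unclass(resample_contour(sl2$inner, 100))
  seg <- sqrt(rowSums((inner[c(2:100, 1), ] - inner)^2))
  spos <- c(0, cumsum(seg))[1:100]
  L <- sum(seg)
  brute <- lapply(1:4, function(k)
    which(spos >= (k - 1) * L / 4 & spos < k * L / 4))
  expect_identical(q2, brute)
  # arc length of each quarter within half a point-spacing of L/4
  arcs <- vapply(q2, function(ix) sum(seg[ix]), 0)
  expect_lt(max(abs(arcs - L / 4)), L / 100 / 2 + 1e-9)
})

test_that("two-layer fibers: limiting angles, unit norm, orthogonal to transmural normal", {
  stk <- generate_ventricle(synthetic_ventricle_spec(n_slices = 5))
  fb0 <- assign_fibers(stk, fiber_layer_spec(epi_angle = 0, endo_angle = 0))
  fb90 <- assign_fibers(stk, fiber_layer_spec(epi_angle = 90, endo_angle = 90))
  for (i in seq_along(fb0)) {
    expect_equal(fb0[[i]]$endo[, 3], rep(0, 100))       # circumferential
    expect_equal(fb90[[i]]$endo[, 3], rep(1, 100))      # longitudinal
  }

  stk2 <- generate_ventricle(synthetic_ventricle_spec(a = 3.5, b = 2.8,
                                                      noise_sd = 0.01,
                                                      seed = 5, n_slices = 6))
  fb <- assign_fibers(stk2, fiber_layer_spec())
  for (sl in fb) {
    for (lay in c("endo", "epi")) {
      v <- sl[[lay]]
      expect_equal(rowSums(v^2), rep(1, 100), tolerance = 1e-10)
      expect_lt(max(abs(rowSums(v * sl$normal))), 1e-10)
    }
  }
})

test_that("contour stack JSON and CSV round-trips preserve geometry", {
  stk <- generate_ventricle(synthetic_ventricle_spec(n_slices = 4,
                                                     noise_sd = 0.01,
                                                     seed = 9))
  f <- tempfile(fileext = ".json")
  write_contour_stack(stk, f)
  back <- read_contour_stack(f)
  expect_equal(stack_volume(back, "inner"), stack_volume(stk, "inner"),
               tolerance = 1e-9)
  expect_equal(length(back$slices), length(stk$slices))

  # CSV round trip
  rows <- do.call(rbind, lapply(seq_along(stk$slices), function(i) {
    sl <- stk$slices[[i]]
    rbind(data.frame(slice = i, z = sl$z, surface = "inner",
                     x = unclass(sl$inner)[, 1], y = unclass(sl$inner)[, 2]),
          data.frame(slice = i, z = sl$z, surface = "outer",
                     x = unclass(sl$outer)[, 1], y = unclass(sl$outer)[, 2]))
  }))
  fcsv <- tempfile(fileext = ".csv")
  write.csv(rows, fcsv, row.names = FALSE)
  back2 <- read_contour_stack_csv(fcsv, spacing = stk$spacing)
  expect_equal(stack_volume(back2, "outer"), stack_volume(stk, "outer"),
               tolerance = 1e-9)
})
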