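test_that("curvature of spheres is uniform at 337.5/R everywhere", {
  g <- test_grid()
  for (R in c(7.0, 7.8, 8.6)) {
    cm <- gaussian_curvature_map(sphere_map(g, R), "anterior")
    expect_lt(max(abs(map_flat(cm) - 337.5 / R)), 0.05)
  }
})

test_that("curvature of a tilted plane is zero", {
  g <- test_grid()
  pl <- map_from_function(g, function(nt) 0.08 * nt$x + 0.01, "elevation")
  expect_lt(max(abs(map_flat(gaussian_curvature_map(pl)))), 1e-6)
})

test_that("conicoid apex curvature equals the apical radius power", {
  g <- test_grid()
  con <- asphotoric_elevation(g, 7.8, 7.8, 0, Q = -0.2)
  cm <- gaussian_curvature_map(con)
  expect_equal(map_flat(cm)[1], 337.5 / 7.8, tolerance = 0.05 / 43)
})

test_that("axial principal meridians recover spheres, torics, conicoids", {
  g <- test_grid()
  am <- axial_principal_meridians(sphere_map(g, 7.8))
  expect_equal(am$r_flat, 7.8, tolerance = 1e-3)
  expect_equal(am$r_steep, 7.8, tolerance = 1e-3)
  expect_equal(am$axis, 0)

  tor <- asphotoric_elevation(g, 7.9, 7.6, 10, Q = 0)
  am <- axial_principal_meridians(tor)
  expect_equal(am$r_flat, 7.9, tolerance = 0.02)
  expect_equal(am$r_steep, 7.6, tolerance = 0.02)
  expect_equal(am$axis, 10, tolerance = 1)

  con <- asphotoric_elevation(g, 7.7, 7.7, 0, Q = -0.2)
  am <- axial_principal_meridians(con)
  expect_equal(am$r_flat, am$r_steep, tolerance = 1e-6)
  expect_gt(am$r_flat, 7.7)  # prolate: axial radius grows off-axis
})

test_that("flat surfaces propagate a degenerate-fit error through k_avg", {
  g <- test_grid()
  pl <- map_from_function(g, function(nt) rep(0, length(nt$r)),
                          "elevation")
  expect_error(k_avg(pl), "degenerate")
})

test_that("k_avg matches the analytic keratometric conversion", {
  g <- test_grid()
  expect_equal(k_avg(sphere_map(g, 7.5)), 45, tolerance = 0.1)
  tor <- asphotoric_elevation(g, 7.9, 7.6, 25, Q = 0)
  expect_equal(k_avg(tor), (337.5 / 7.9 + 337.5 / 7.6) / 2,
               tolerance = 0.1)
})

test_that("Zernike fit recovers pure basis surfaces exactly", {
  g <- test_grid()
  z20 <- map_from_function(g, function(nt)
    zernike_mode(2, 0, nt$r / 4, nt$theta * pi / 180) / 1000, "elevation")
  sp <- fit_zernike(z20, 8, 4)
  expect_equal(unname(sp$coefficients["Z2_0"]), 1, tolerance = 1e-6)
  expect_lt(max(abs(sp$coefficients[names(sp$coefficients) != "Z2_0"])),
            1e-6)
  expect_equal(length(sp$coefficients), (8 + 1) * (8 + 2) / 2)
})

test_that("a plane fits entirely into piston and tilt", {
  g <- test_grid()
  pl <- map_from_function(g, function(nt) (0.05 * nt$x - 0.01) / 1,
                          "elevation")
  sp <- fit_zernike(pl, 6, 4)
  hi <- zernike_indices(6)$n > 1
  expect_lt(max(abs(sp$coefficients[hi])), 1e-9)
})

test_that("reconstruction error decreases with Zernike order", {
  g <- test_grid()
  surf <- map_from_function(g, function(nt)
    0.002 * sin(nt$x) * cos(1.3 * nt$y) + 0.001 * nt$x^2, "elevation")
  rms_err <- vapply(c(4L, 6L, 8L), function(k) {
    sp <- fit_zernike(surf, k, 4)
    rec <- zernike_reconstruct(sp, g)
    sqrt(mean((map_flat(surf) - map_flat(rec))^2))
  }, numeric(1))
  expect_true(all(diff(rms_err) < 0))
})

test_that("Zernike fit + reconstruct is a projection", {
  g <- test_grid()
  surf <- generate_cornea("Abn", seed = 5L)$anterior_elevation
  sp1 <- fit_zernike(surf, 6, 4)
  rec <- zernike_reconstruct(sp1, g)
  sp2 <- fit_zernike(rec, 6, 4)
  expect_equal(sp2$coefficients, sp1$coefficients, tolerance = 1e-8)
})

test_that("aspho-toric self-fit recovers exact model parameters", {
  g <- test_grid()
  el <- asphotoric_elevation(g, 7.8, 7.6, 95, Q = -0.2)
  f <- fit_reference_asphotoric(el, Q = -0.2)
  expect_equal(f$r_flat, 7.8, tolerance = 1e-3)
  expect_equal(f$r_steep, 7.6, tolerance = 1e-3)
  expect_equal(f$axis, 95, tolerance = 0.5)
  expect_lt(f$fit_rms_residual, 1e-3)
  expect_gte(f$r_flat, f$r_steep)
})

test_that("sphere fitted with prolate Q leaves the analytic residual gap", {
  g <- test_grid()
  sph <- asphotoric_elevation(g, 7.8, 7.8, 0, Q = 0)
  f <- fit_reference_asphotoric(sph, Q = -0.2)
  expect_equal(f$r_flat, f$r_steep, tolerance = 1e-6)
  # the conicoid family with Q != 0 cannot represent a sphere exactly:
  # a strictly positive but sub-micron best-fit residual remains
  expect_gt(f$fit_rms_residual, 0.5)
  expect_lt(f$fit_rms_residual, 5)
})

test_that("refitting a fitted reference surface is idempotent", {
  g <- test_grid()
  el <- generate_cornea("Normal", seed = 9L)$anterior_elevation
  f1 <- fit_reference_asphotoric(el, Q = -0.2)
  model <- map_from_function(g, function(nt)
    kcscreen:::reference_elevation_flat(f1, nt), "elevation")
  f2 <- fit_reference_asphotoric(model, Q = -0.2)
  expect_equal(f2$r_flat, f1$r_flat, tolerance = 1e-9)
  expect_equal(f2$r_steep, f1$r_steep, tolerance = 1e-9)
  expect_equal(f2$axis, f1$axis, tolerance = 1e-6)
})

test_that("deviation maps vanish on the reference and localize bumps", {
  g <- test_grid()
  el <- asphotoric_elevation(g, 7.8, 7.7, 40, Q = -0.2)
  f <- fit_reference_asphotoric(el, Q = -0.2)
  dev0 <- deviation_map(el, f)
  expect_lt(max(abs(map_flat(dev0))), 1e-6)
  # add a 5 um Gaussian bump at a known spot
  nt <- node_table(g)
  bump <- 5e-3 * exp(-((nt$x - 1)^2 + (nt$y + 1.5)^2) / (2 * 0.5^2))
  el2 <- flat_to_map(g, map_flat(el) + bump, "elevation")
  dev2 <- deviation_map(el2, f)
  dz <- dz_max(dev2)
  expect_equal(dz$value, 5, tolerance = 0.3)
  expect_lt(sqrt(sum((dz$location - c(1, -1.5))^2)), 0.3)
})

test_that("keratoconic surfaces fit worse than their matched normals", {
  pair <- kcn_normal_pair(seed = 21L)
  f_k <- fit_reference_asphotoric(pair$kcn$anterior_elevation, Q = -0.2)
  f_n <- fit_reference_asphotoric(pair$normal$anterior_elevation, Q = -0.2)
  expect_gt(f_k$fit_rms_residual, f_n$fit_rms_residual)
  dev_k <- deviation_map(pair$kcn$anterior_elevation, f_k)
  dev_n <- deviation_map(pair$normal$anterior_elevation, f_n)
  expect_gt(max(abs(map_flat(dev_k))), max(abs(map_flat(dev_n))))
})

test_that("rotation-invariant geometry survives meridian relabeling", {
  g <- test_grid()
  s <- generate_cornea("Kcn", seed = 31L)
  rot <- function(m, k) {
    m$values <- m$values[, c((k + 1):ncol(m$values), 1:k)]
    m
  }
  el <- s$anterior_elevation
  el_r <- rot(el, 16L)
  expect_equal(rms_vs_reference(deviation_map(
    el_r, fit_reference_asphotoric(el_r, -0.2))),
    rms_vs_reference(deviation_map(
      el, fit_reference_asphotoric(el, -0.2))),
    tolerance = 1e-6)
  expect_equal(k_max(gaussian_curvature_map(el_r))$value,
               k_max(gaussian_curvature_map(el))$value, tolerance = 1e-9)
})
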