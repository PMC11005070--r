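test_that("symmetry indexes vanish on rotationally symmetric maps", {
  g <- test_grid()
  radial <- map_from_function(g, function(nt) 43 + 0.3 * nt$r^2,
                              "curvature")
  expect_equal(symmetry_index(radial, "OD"), 0, tolerance = 1e-9)
  expect_equal(symmetry_index(radial, "OS"), 0, tolerance = 1e-9)
})

test_that("inferior steepening gives positive SI and negative SI_THK", {
  pair <- kcn_normal_pair(seed = 11L)
  curv <- gaussian_curvature_map(pair$kcn$anterior_elevation)
  expect_gt(symmetry_index(curv, "OD"), 0)
  expect_lt(thickness_symmetry_index(pair$kcn$corneal_thickness, "OD"), 0)
})

test_that("SI is equivariant under the laterality mirror", {
  s <- generate_cornea("Kcn", seed = 13L)
  m <- mirror_scan(s)
  curv <- gaussian_curvature_map(s$anterior_elevation)
  curv_m <- gaussian_curvature_map(m$anterior_elevation)
  expect_equal(symmetry_index(curv_m, m$laterality),
               symmetry_index(curv, s$laterality), tolerance = 1e-9)
  expect_equal(thickness_symmetry_index(m$corneal_thickness, m$laterality),
               thickness_symmetry_index(s$corneal_thickness,
                                        s$laterality), tolerance = 1e-9)
})

test_that("CSI matches the analytic polar moments of a quadratic map", {
  g <- test_grid()
  b <- 0.8
  m <- map_from_function(g, function(nt) 46 - b * nt$r^2, "curvature")
  # E[r^2] = 1.125 over the 1.5 mm disc and 5.625 over the 1.5-3 annulus
  expect_equal(center_surrounding_index(m), b * (5.625 - 1.125),
               tolerance = 0.15)
  expect_gt(center_surrounding_index(m), 0)
  const <- map_from_function(g, function(nt) rep(44, length(nt$r)),
                             "curvature")
  expect_equal(center_surrounding_index(const), 0)
})

test_that("central cones raise CSI above the matched normal", {
  pk <- default_phenotype_params("Kcn")
  pk$cone_center_r <- 0.2
  pair_k <- generate_cornea("Kcn", pk, seed = 15L)
  pn <- pk
  pn$cone_height <- 0; pn$cone_coma <- 0; pn$corneal_thinning_depth <- 0
  pn$epi_thinning_depth <- 0; pn$epi_annulus_gain <- 0
  pair_n <- generate_cornea("Normal", pn, seed = 15L)
  expect_gt(
    center_surrounding_index(gaussian_curvature_map(
      pair_k$anterior_elevation)),
    center_surrounding_index(gaussian_curvature_map(
      pair_n$anterior_elevation)))
})

test_that("RMS of deviation maps follows closed forms", {
  g <- test_grid()
  zero <- flat_to_map(g, rep(0, 1 + g$n_rings * g$n_meridians),
                      "deviation")
  expect_equal(rms_vs_reference(zero), 0)
  const <- flat_to_map(g, rep(4, 1 + g$n_rings * g$n_meridians),
                       "deviation")
  expect_equal(rms_vs_reference(const), 4)
  h <- 6
  sine <- map_from_function(g, function(nt)
    h * sin(2 * nt$theta * pi / 180), "deviation")
  expect_equal(rms_vs_reference(sine), h / sqrt(2), tolerance = 1e-6)
})

test_that("extremum locations honour the construction and tie-breaks", {
  g <- test_grid()
  base <- map_from_function(g, function(nt) rep(540, length(nt$r)),
                            "thickness")
  nt <- node_table(g)
  crater <- 540 - 80 * exp(-((nt$x - 0.8)^2 + (nt$y + 0.6)^2) /
                             (2 * 0.3^2))
  m <- flat_to_map(g, crater, "thickness")
  tm <- thickness_min(m)
  expect_equal(tm$value, min(crater))
  expect_lt(sqrt(sum((tm$location - c(0.8, -0.6))^2)), 0.2)
  # uniform map: tie-break lands on the vertex
  tm0 <- thickness_min(base)
  expect_equal(tm0$value, 540)
  expect_equal(unname(tm0$location), c(0, 0))
  expect_equal(unname(dz_max(flat_to_map(
    g, rep(0, 1 + g$n_rings * g$n_meridians), "deviation"))$location),
    c(0, 0))
})

test_that("corneal minimum is never below the stromal minimum", {
  for (seed in 1:4) {
    s <- generate_cornea("Kcn", sample_phenotype_params("Kcn", seed),
                         seed = seed)
    expect_gte(thickness_min(s$corneal_thickness)$value,
               thickness_min(s$stromal_thickness)$value)
  }
})

test_that("k_max finds constructed cone apices", {
  g <- test_grid()
  const <- map_from_function(g, function(nt) rep(43, length(nt$r)),
                             "curvature")
  expect_equal(k_max(const)$value, 43)
  nt <- node_table(g)
  spike <- 43 + 12 * exp(-((nt$x - 1)^2 + (nt$y + 1)^2) / (2 * 0.4^2))
  km <- k_max(flat_to_map(g, spike, "curvature"))
  expect_equal(km$value, max(spike))
  expect_lt(sqrt(sum((km$location - c(1, -1))^2)), 0.2)
})

test_that("thickness-increase profile is zero for uniform maps and
           analytic for paraboloids", {
  g <- test_grid()
  unif <- map_from_function(g, function(nt) rep(540, length(nt$r)),
                            "thickness")
  pr <- pct_thickness_increase_profile(unif)
  expect_equal(max(abs(pr$pti)), 0)
  expect_false(pr$truncated)
  a <- 12; tmin <- 480
  par <- map_from_function(g, function(nt) tmin + a * nt$r^2, "thickness")
  pr2 <- pct_thickness_increase_profile(par)
  # the innermost annuli can be empty on the default grid (filled by
  # interpolation), so strict growth is asserted away from the center
  expect_true(all(diff(pr2$pti) >= 0))
  expect_true(all(diff(pr2$pti[pr2$d >= 0.3]) > 0))
  # annulus-averaged d^2 at the outermost annulus ~ d_max^2
  expect_equal(pr2$pti[length(pr2$pti)], 100 * a * 2.95^2 / tmin,
               tolerance = 0.05)
})

test_that("pti_index compares subject and normative profiles", {
  g <- test_grid()
  par <- map_from_function(g, function(nt) 480 + 10 * nt$r^2, "thickness")
  pr <- pct_thickness_increase_profile(par)
  expect_equal(pti_index(pr, list(d = pr$d, pti = pr$pti)), 0)
  expect_equal(pti_index(pr, list(d = pr$d, pti = pr$pti + 3)), -3)
  expect_error(pti_index(pr, list(d = pr$d[-1], pti = pr$pti[-1])),
               "distance grids")
  expect_equal(pti_index(pr, NULL), max(pr$pti))
})

test_that("keratoconic profiles rise faster than matched normals", {
  pair <- kcn_normal_pair(seed = 17L)
  pk <- pct_thickness_increase_profile(pair$kcn$corneal_thickness)
  pn <- pct_thickness_increase_profile(pair$normal$corneal_thickness)
  sel <- pk$d >= 0.3 & pk$d <= 2   # innermost annuli are noise-dominated
  expect_true(all(pk$pti[sel] >= pn$pti[sel]))
})

test_that("notable-point spread follows hand arithmetic and isometry", {
  pts <- rbind(matrix(0, 4, 2), matrix(rep(c(1.4, 0), each = 3), 3, 2))
  expect_equal(nps_spread(pts), (4 * 0.6 + 3 * 0.8) / 7)
  expect_equal(nps_spread(pts), 0.6857, tolerance = 1e-4)
  # translation and rotation invariance
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts2 <- sweep(pts %*% Rm, 2, c(3, -2), "+")
  expect_equal(nps_spread(pts2), nps_spread(pts), tolerance = 1e-12)
  expect_equal(nps_spread(matrix(1, 7, 2)), 0)
  expect_error(nps_spread(matrix(0, 6, 2)), "7 x 2")
})

test_that("ectatic index is the advertised functional of the spectrum", {
  s <- generate_cornea("Kcn", seed = 19L)
  sp <- fit_zernike(s$anterior_elevation)
  idx <- zernike_indices(8)
  nm <- idx$name[idx$n >= 2]
  zero_w <- structure(list(alpha1 = stats::setNames(numeric(length(nm)),
                                                    nm),
                           alpha2 = stats::setNames(numeric(length(nm)),
                                                    nm),
                           side = "anterior", n_train = 0L),
                      class = "ei_weights")
  expect_equal(ectatic_index(sp, zero_w), 0)
  sel_w <- zero_w
  sel_w$alpha1["Z2_0"] <- 1
  expect_equal(ectatic_index(sp, sel_w),
               unname(sp$coefficients["Z2_0"]))
  sel_w$alpha2["Z4_0"] <- 2
  expect_equal(ectatic_index(sp, sel_w),
               unname(sp$coefficients["Z2_0"] +
                        2 * sp$coefficients["Z4_0"]^2))
})

test_that("trained EI weights separate the classes they were fitted on", {
  set.seed(101)
  scans <- c(lapply(1:15, function(i)
    generate_cornea("Kcn", sample_phenotype_params("Kcn", i), seed = i)),
    lapply(16:30, function(i)
      generate_cornea("Normal", sample_phenotype_params("Normal", i),
                      seed = i)))
  labels <- rep(c("Kcn", "Normal"), each = 15)
  spectra <- lapply(scans, function(s) fit_zernike(s$anterior_elevation))
  w <- train_ei_weights(spectra, labels, side = "anterior")
  ei <- vapply(spectra, ectatic_index, numeric(1), w = w)
  auc_ei <- empirical_auc(ei, labels == "Kcn")$auc
  expect_gte(auc_ei, 0.95)
  # EI at least matches the best single coefficient on training data
  best_single <- max(vapply(names(w$alpha1), function(nm)
    empirical_auc(vapply(spectra, function(s) s$coefficients[[nm]],
                         numeric(1)), labels == "Kcn")$auc, numeric(1)))
  expect_gte(auc_ei + 1e-9, best_single)
  # duplicating every sample leaves the optimum unchanged
  w2 <- train_ei_weights(c(spectra, spectra), c(labels, labels),
                         side = "anterior")
  expect_equal(w2$alpha1, w$alpha1, tolerance = 1e-6)
  expect_error(train_ei_weights(spectra, rep("Kcn", 30)), "both classes")
})

test_that("label-shuffled EI training yields chance-level discrimination", {
  set.seed(202)
  scans <- c(lapply(1:12, function(i)
    generate_cornea("Kcn", sample_phenotype_params("Kcn", i + 40),
                    seed = i + 40)),
    lapply(13:24, function(i)
      generate_cornea("Normal", sample_phenotype_params("Normal", i + 40),
                      seed = i + 40)))
  spectra <- lapply(scans, function(s) fit_zernike(s$anterior_elevation))
  true_labels <- rep(c("Kcn", "Normal"), each = 12)
  aucs <- vapply(1:8, function(rep) {
    sh <- sample(true_labels)
    w <- train_ei_weights(spectra, sh, side = "anterior", lambda = 1)
    ho <- vapply(spectra, ectatic_index, numeric(1), w = w)
    empirical_auc(ho, true_labels == "Kcn")$auc_raw
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("index vectors are deterministic, complete and ordered", {
  s <- generate_cornea("SKcn", seed = 23L)
  v1 <- compute_index_vector(s)
  v2 <- compute_index_vector(s)
  expect_identical(as.numeric(v1), as.numeric(v2))
  expect_equal(names(v1), INDEX_NAMES)
  expect_true(all(is.finite(v1)))
  expect_gt(v1[["Thk_Min"]], 0)
  pts <- attr(v1, "notable_points")
  expect_equal(dim(pts), c(7L, 2L))
  expect_true(all(sqrt(rowSums(pts^2)) <= 4 + 1e-9))
})

test_that("the full index vector is laterality-equivariant", {
  s <- generate_cornea("Kcn", seed = 29L)
  m <- mirror_scan(s)
  expect_equal(as.numeric(compute_index_vector(m)),
               as.numeric(compute_index_vector(s)), tolerance = 1e-9)
})

test_that("a keratoconic eye is more extreme than its matched normal on
           most indexes", {
  pair <- kcn_normal_pair(seed = 37L)
  vk <- compute_index_vector(pair$kcn)
  vn <- compute_index_vector(pair$normal)
  # documented abnormal directions (EI left out: untrained weights give 0)
  higher <- c("SI_F", "SI_B", "CSI_F", "CSI_B", "RMS_F", "RMS_B", "pTI",
              "pEpiTI", "KMax_F", "KMax_B", "DZMax_F", "DZMax_B",
              "KAvg_F", "KAvg_B")
  lower <- c("SI_THK", "Thk_Min", "NPtsR")
  n_extreme <- sum(vk[higher] > vn[higher]) + sum(vk[lower] < vn[lower])
  expect_gte(n_extreme, 15)
})

test_that("near-normal conicoid eyes have near-zero asymmetry indexes", {
  p <- default_phenotype_params("Normal")
  p$toricity <- 0; p$noise_sd <- 0
  s <- generate_cornea("Normal", p, seed = 31L)
  v <- compute_index_vector(s)
  expect_lt(abs(v[["SI_F"]]), 0.05)
  expect_lt(abs(v[["SI_THK"]]), 0.05)
  expect_lt(v[["RMS_F"]], 0.5)
  expect_lt(abs(v[["DZMax_F"]]), 1)
  expect_equal(v[["Thk_Min"]], p$central_thickness, tolerance = 0.1)
})
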