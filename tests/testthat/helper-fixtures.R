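# Shared fixtures: everything is generated in code at test time.

# default grid used throughout (operators are cached per grid, so sharing
# one instance keeps the suite fast)
test_grid <- function() polar_grid()

# small grid for cheap I/O and container tests
small_grid <- function() polar_grid(n_rings = 16L, n_meridians = 32L,
                                    max_radius = 4.0)

sphere_map <- function(grid, R) {
  map_from_function(grid, function(nt) -(R - sqrt(R^2 - nt$r^2)),
                    "elevation")
}

# a well-behaved synthetic scan with uniform layer structure on any grid
flat_layer_scan <- function(grid = small_grid(), epi = 50, stroma = 490,
                            R = 7.8, laterality = "OD", scan_id = "flat") {
  el_a <- sphere_map(grid, R)
  el_p <- sphere_map(grid, R * 0.82)
  const_map <- function(v) flat_to_map(grid, rep(v, 1 + grid$n_rings *
                                                   grid$n_meridians),
                                       "thickness")
  corneal_scan(el_a, el_p, const_map(epi + stroma), const_map(epi),
               const_map(stroma), laterality = laterality,
               scan_id = scan_id)
}

# matched keratoconus / normal pair sharing base geometry
kcn_normal_pair <- function(seed = 42L, grid = test_grid()) {
  pk <- default_phenotype_params("Kcn")
  pn <- pk
  pn$cone_height <- 0; pn$cone_coma <- 0; pn$corneal_thinning_depth <- 0
  pn$epi_thinning_depth <- 0; pn$epi_annulus_gain <- 0
  list(kcn = generate_cornea("Kcn", pk, grid = grid, seed = seed),
       normal = generate_cornea("Normal", pn, grid = grid, seed = seed))
}

# memoised full-scale study (500 eyes/class, one training configuration)
# shared by the end-to-end acceptance checks
acceptance_study <- function() {
  if (is.null(.fixture_env$acc_study)) {
    cfg <- default_run_config(
      n_per_class = c(Abn = 500, Kcn = 500, MyPO = 500, Normal = 500,
                      SKcn = 500),
      seed = 101L,
      mlp_grid = list(list(hidden = 15L, learning_rate = 0.05,
                           momentum = 0.9, sigma = 1,
                           max_epochs = 3000L)))
    .fixture_env$acc_study <- run_screening_study(cfg, verbose = FALSE)
  }
  .fixture_env$acc_study
}

# memoised tiny end-to-end study shared by pipeline tests
.fixture_env <- new.env()
tiny_study <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- default_run_config(
      n_per_class = c(Abn = 12, Kcn = 12, MyPO = 12, Normal = 12,
                      SKcn = 12),
      seed = 7L,
      mlp_grid = list(list(hidden = 10L, learning_rate = 0.05,
                           momentum = 0.9, sigma = 1,
                           max_epochs = 800L)))
    .fixture_env$study <- run_screening_study(cfg, verbose = FALSE)
  }
  .fixture_env$study
}
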