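# Synthetic corneal phenotype generator.
#
# Five phenotypes are emulated on top of a shared aspho-toric optical base:
#   Normal  - aspho-toric surfaces, physiologic pachymetry, measurement noise
#   Kcn     - an inferiorly decentered Gaussian cone on both surfaces
#             (posterior amplified), a co-located corneal thinning crater,
#             focal epithelial thinning over the cone with a compensatory
#             thickened annulus around it
#   SKcn    - the same mechanism at roughly half the keratoconic effect sizes
#   MyPO    - a Munnerlyn-like central ablation (flattening + tissue removal)
#   Abn     - band-limited random surface irregularity (scars etc.)
# All maps receive Gaussian measurement noise; stromal thickness is defined
# as corneal minus epithelial thickness so the additivity invariant is exact.

#' Default phenotype parameters for a diagnostic class
#'
#' Central values (no sampling) of the generator parameters for each
#' phenotype; [sample_phenotype_params()] draws around these.
#'
#' @param cls Diagnostic class label.
#' @return Named list of generator parameters (`phenotype_params`).
#' @export
default_phenotype_params <- function(cls = "Normal") {
  base <- list(
    base_radius_ant = 7.8,    # mm
    base_radius_post = 6.4,   # mm
    q_ant = -0.2, q_post = -0.3,
    toricity = 0.8,           # D, anterior principal-meridian power difference
    toricity_post_ratio = 0.35,
    axis = 90,                # deg, flat meridian
    central_thickness = 545,  # um
    peripheral_increase = 70, # um added at the map edge
    epithelial_thickness = 53,   # um central
    epithelial_peripheral_drop = 2,  # um thinner at the edge
    cone_height = 0,          # um, anterior cone amplitude
    cone_coma = 0,            # um, coma-like inferior steepening component
    cone_width_sigma = 1.1,   # mm
    cone_center_r = 0,        # mm
    cone_center_theta = 270,  # deg (inferior)
    posterior_cone_ratio = 1.3,
    corneal_thinning_depth = 0,  # um, crater co-located with the cone
    epi_thinning_depth = 0,   # um over the cone apex
    epi_annulus_gain = 0,     # um, compensatory annular thickening
    ablation_depth = 0,       # um (MyPO)
    ablation_sigma = 2.2,     # mm, Gaussian ablation profile width
    irregularity_rms = 0,     # um (Abn)
    noise_sd = 1.5)           # um on thickness maps (elevation gets 10%)
  tweak <- switch(as.character(cls),
    Normal = list(),
    Kcn = list(base_radius_ant = 7.2, base_radius_post = 5.9, q_ant = -0.4,
               central_thickness = 500, cone_height = 26, cone_coma = 16,
               cone_center_r = 0.9, corneal_thinning_depth = 70,
               epi_thinning_depth = 13, epi_annulus_gain = 5,
               toricity = 1.5),
    SKcn = list(base_radius_ant = 7.5, base_radius_post = 6.15,
                q_ant = -0.3, central_thickness = 522, cone_height = 13,
                cone_coma = 8, cone_center_r = 0.9,
                corneal_thinning_depth = 35,
                epi_thinning_depth = 6.5, epi_annulus_gain = 2.5,
                toricity = 1.0),
    MyPO = list(ablation_depth = 55),
    Abn = list(irregularity_rms = 5),
    stop("unknown diagnostic class: ", cls))
  base[names(tweak)] <- tweak
  base
}

validate_phenotype_params <- function(p) {
  chk <- function(ok, msg) if (!ok) stop("invalid phenotype params: ", msg)
  chk(p$base_radius_ant >= 6.5 && p$base_radius_ant <= 9.5,
      "anterior radius outside [6.5, 9.5] mm")
  chk(p$base_radius_post >= 4.5 && p$base_radius_post <= 8.5,
      "posterior radius outside [4.5, 8.5] mm")
  chk(p$central_thickness >= 380 && p$central_thickness <= 650,
      "central thickness outside [380, 650] um")
  chk(p$epithelial_thickness >= 35 && p$epithelial_thickness <= 75,
      "epithelial thickness outside [35, 75] um")
  chk(p$cone_height >= 0 && p$cone_width_sigma > 0 && p$cone_center_r >= 0,
      "cone parameters must be non-negative")
  chk(p$corneal_thinning_depth >= 0 && p$epi_thinning_depth >= 0 &&
        p$epi_annulus_gain >= 0, "thinning parameters must be non-negative")
  chk(p$ablation_depth >= 0 && p$irregularity_rms >= 0 && p$noise_sd >= 0,
      "depth/noise parameters must be non-negative")
  invisible(p)
}

#' Generate one synthetic corneal scan
#'
#' Builds the five maps of a [corneal_scan()] for the given phenotype
#' parameters: aspho-toric anterior/posterior elevations plus (depending on
#' the class) the Gaussian cone protrusion with posterior amplification, the
#' co-located thinning crater and epithelial remodeling ring, the central
#' ablation profile, or band-limited irregularity; then measurement noise.
#' Deterministic given (`params`, `seed`).
#'
#' @param cls Diagnostic class label (drives which features are active via
#'   the parameters; the label itself is returned as ground truth by the
#'   cohort generator).
#' @param params Parameter list from [default_phenotype_params()] or
#'   [sample_phenotype_params()].
#' @param grid A [polar_grid()].
#' @param seed Integer seed for the measurement noise and irregularity.
#' @param laterality `"OD"` or `"OS"`.
#' @param scan_id Scan identifier.
#' @return A [corneal_scan()].
#' @export
generate_cornea <- function(cls, params = default_phenotype_params(cls),
                            grid = polar_grid(), seed = 1L,
                            laterality = "OD", scan_id = NULL) {
  p <- validate_phenotype_params(params)
  if (is.null(scan_id)) scan_id <- paste0(cls, "-", seed)
  nt <- node_table(grid)
  n <- length(nt$r)
  # principal radii from flat radius + toricity (diopters)
  c_flat_a <- 1 / p$base_radius_ant
  c_steep_a <- c_flat_a + p$toricity / KERATOMETRIC_INDEX
  c_flat_p <- 1 / p$base_radius_post
  c_steep_p <- c_flat_p + p$toricity * p$toricity_post_ratio /
    KERATOMETRIC_INDEX
  ant <- asphotoric_elevation_values(nt$r, nt$theta, 1 / c_flat_a,
                                     1 / c_steep_a, p$axis, p$q_ant)
  post <- asphotoric_elevation_values(nt$r, nt$theta, 1 / c_flat_p,
                                      1 / c_steep_p, p$axis, p$q_post)
  # cone: radial Gaussian protrusion toward the instrument
  thr <- p$cone_center_theta * pi / 180
  cx <- p$cone_center_r * cos(thr); cy <- p$cone_center_r * sin(thr)
  d2 <- (nt$x - cx)^2 + (nt$y - cy)^2
  bump <- exp(-d2 / (2 * p$cone_width_sigma^2))
  if (p$cone_height > 0) {
    ant <- ant + p$cone_height / 1000 * bump
    post <- post + p$posterior_cone_ratio * p$cone_height / 1000 * bump
  }
  # coma-like asymmetric steepening along the cone meridian: ectasia steepens
  # the whole inferior cornea, not just the focal bump
  if (p$cone_coma > 0) {
    rho <- nt$r / grid$max_radius
    com <- (3 * rho^3 - 2 * rho) * cos((nt$theta - p$cone_center_theta) *
                                         pi / 180)
    ant <- ant - p$cone_coma / 1000 * com
    post <- post - p$posterior_cone_ratio * p$cone_coma / 1000 * com
  }
  # myopic ablation: Gaussian-profiled central flattening, tissue removed
  abl <- if (p$ablation_depth > 0)
    p$ablation_depth * exp(-(nt$r / p$ablation_sigma)^2) else 0
  ant <- ant - abl / 1000
  # band-limited irregularity (random Zernike modes of order 3..6)
  irr <- 0
  if (p$irregularity_rms > 0) {
    idx <- zernike_indices(6L)
    hi <- which(idx$n >= 3L)
    cf <- local_seed(seed + 211L, stats::rnorm(length(hi)))
    cf <- cf / sqrt(sum(cf^2)) * p$irregularity_rms
    rho <- nt$r / grid$max_radius; tha <- nt$theta * pi / 180
    irr <- numeric(n)
    for (i in seq_along(hi))
      irr <- irr + cf[i] * zernike_mode(idx$n[hi[i]], idx$m[hi[i]], rho, tha)
    ant <- ant + irr / 1000
    post <- post + 0.5 * irr / 1000
  }
  # pachymetry: central value + quadratic peripheral increase - crater
  thk <- p$central_thickness +
    p$peripheral_increase * (nt$r / grid$max_radius)^2 -
    p$corneal_thinning_depth * bump - abl
  # epithelium: base profile - focal thinning + compensatory annulus
  ring <- exp(-(sqrt(d2) - 2 * p$cone_width_sigma)^2 /
                (2 * (0.75 * p$cone_width_sigma)^2))
  epi <- p$epithelial_thickness -
    p$epithelial_peripheral_drop * (nt$r / grid$max_radius)^2 -
    p$epi_thinning_depth * bump + p$epi_annulus_gain * ring
  if (p$irregularity_rms > 0) epi <- epi + 0.3 * irr
  # measurement noise; stroma = cornea - epithelium keeps additivity exact
  noise <- local_seed(seed, list(
    ant = stats::rnorm(n, 0, 0.1 * p$noise_sd / 1000),
    post = stats::rnorm(n, 0, 0.1 * p$noise_sd / 1000),
    thk = stats::rnorm(n, 0, p$noise_sd),
    epi = stats::rnorm(n, 0, 0.5 * p$noise_sd)))
  ant <- ant + noise$ant - noise$ant[1L]    # elevation stays 0 at the apex
  post <- post + noise$post - noise$post[1L]
  thk <- thk + noise$thk
  epi <- epi + noise$epi
  stro <- thk - epi
  mk <- function(v, kind) flat_to_map(grid, v, kind)
  # generated in right-eye coordinates; left eyes are the mirror image
  scan <- corneal_scan(mk(ant, "elevation"), mk(post, "elevation"),
                       mk(thk, "thickness"), mk(epi, "thickness"),
                       mk(stro, "thickness"),
                       laterality = "OD", scan_id = scan_id)
  if (laterality == "OS") scan <- mirror_scan(scan)
  scan
}

# truncated-normal / clamped draws for the cohort priors
rnorm_clamped <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Draw phenotype parameters from the class priors
#'
#' Samples one parameter set for the given class around the
#' [default_phenotype_params()] central values: base geometry and
#' pachymetry vary like a healthy/ectatic population, keratoconic effect
#' sizes (cone height, crater depth, epithelial remodeling) span mild to
#' advanced disease, and the suspect class draws the same effect sizes
#' scaled to 50% +/- 10% of the keratoconus means.
#'
#' @param cls Diagnostic class label.
#' @param rng_seed Integer seed.
#' @return A `phenotype_params` list.
#' @export
sample_phenotype_params <- function(cls, rng_seed = 1L) {
  p <- default_phenotype_params(cls)
  kcn_means <- default_phenotype_params("Kcn")
  local_seed(rng_seed, {
    p$axis <- stats::runif(1, 0, 180)
    p$toricity <- abs(stats::rnorm(1, p$toricity, 0.5))
    p$central_thickness <- rnorm_clamped(1, p$central_thickness, 28, 420,
                                         630)
    p$peripheral_increase <- rnorm_clamped(1, 70, 10, 40, 100)
    p$epithelial_thickness <- rnorm_clamped(1, 53, 2.5, 45, 62)
    if (cls %in% c("Normal", "MyPO", "Abn")) {
      p$base_radius_ant <- rnorm_clamped(1, 7.8, 0.22, 7.1, 8.5)
      p$q_ant <- rnorm_clamped(1, -0.2, 0.08, -0.45, 0.05)
    }
    p$base_radius_post <- p$base_radius_ant * rnorm_clamped(1, 0.82, 0.012,
                                                            0.78, 0.86)
    p$q_post <- rnorm_clamped(1, -0.3, 0.08, -0.55, -0.05)
    if (cls == "Kcn") {
      p$base_radius_ant <- rnorm_clamped(1, 7.2, 0.3, 6.5, 7.9)
      p$base_radius_post <- p$base_radius_ant * rnorm_clamped(1, 0.82,
                                                              0.012, 0.78,
                                                              0.86)
      p$q_ant <- rnorm_clamped(1, -0.4, 0.12, -0.8, -0.1)
      p$cone_height <- stats::runif(1, 12, 40)
      p$cone_coma <- stats::runif(1, 8, 24)
      p$cone_width_sigma <- stats::runif(1, 0.9, 1.4)
      p$cone_center_r <- stats::runif(1, 0.3, 1.5)
      p$cone_center_theta <- stats::rnorm(1, 270, 20)
      p$corneal_thinning_depth <- stats::runif(1, 40, 100)
      p$epi_thinning_depth <- stats::runif(1, 8, 18)
      p$epi_annulus_gain <- stats::runif(1, 3, 7)
      p$toricity <- abs(stats::rnorm(1, 1.5, 1.0))
    } else if (cls == "SKcn") {
      p$base_radius_ant <- rnorm_clamped(1, 7.5, 0.27, 6.8, 8.2)
      p$base_radius_post <- p$base_radius_ant * rnorm_clamped(1, 0.82,
                                                              0.012, 0.78,
                                                              0.86)
      p$q_ant <- rnorm_clamped(1, -0.3, 0.11, -0.65, 0.0)
      att <- stats::runif(1, 0.4, 0.6)    # 50% +/- 10% of the Kcn means
      p$cone_height <- att * kcn_means$cone_height
      p$cone_coma <- att * kcn_means$cone_coma
      p$epi_thinning_depth <- att * kcn_means$epi_thinning_depth
      p$corneal_thinning_depth <- att * kcn_means$corneal_thinning_depth
      p$epi_annulus_gain <- att * kcn_means$epi_annulus_gain
      p$cone_width_sigma <- stats::runif(1, 0.9, 1.4)
      p$cone_center_r <- stats::runif(1, 0.3, 1.5)
      p$cone_center_theta <- stats::rnorm(1, 270, 20)
    } else if (cls == "MyPO") {
      p$ablation_depth <- stats::runif(1, 25, 85)
      p$central_thickness <- rnorm_clamped(1, 545, 28, 460, 630)
    } else if (cls == "Abn") {
      p$irregularity_rms <- stats::runif(1, 2.5, 8)
    }
  })
  p
}

#' Class mix of the emulated screening population
#'
#' Proportions of the five diagnostic classes in a heterogeneous screening
#' population (normal 39.9%, keratoconus 24.2%, suspect 3.1%, myopic
#' post-operative 22.7%, abnormal 10.0%).
#'
#' @param n_total Total number of eyes.
#' @return Named integer vector of per-class counts summing to `n_total`.
#' @export
default_class_mix <- function(n_total) {
  w <- c(Abn = 669, Kcn = 1616, MyPO = 1519, Normal = 2663, SKcn = 210)
  raw <- w / sum(w) * n_total
  n <- floor(raw)
  rem <- n_total - sum(n)
  if (rem > 0) {
    extra <- order(raw - n, decreasing = TRUE)[seq_len(rem)]
    n[extra] <- n[extra] + 1L
  }
  stats::setNames(as.integer(n), names(w))
}

# per-scan metadata (class, seed, laterality) for a cohort; the single
# cohort seed determines everything downstream
cohort_plan <- function(n_per_class, seed) {
  cls <- rep(names(n_per_class), times = as.integer(n_per_class))
  n <- length(cls)
  lat <- local_seed(seed + 101L, sample(c("OD", "OS"), n, replace = TRUE))
  data.frame(class = cls,
             scan_seed = seed + 1000L + seq_len(n) * 7L,
             laterality = lat,
             scan_id = sprintf("%s-%04d", cls, seq_len(n)),
             stringsAsFactors = FALSE)
}

#' Generate a labelled synthetic cohort
#'
#' Draws per-eye phenotype parameters from the class priors and generates
#' one scan per eye. The whole cohort is determined by the single seed.
#'
#' @param n_per_class Named integer vector of eyes per class (e.g.
#'   `c(Normal = 10, Kcn = 10)`); see [default_class_mix()] for the
#'   population mix.
#' @param grid A [polar_grid()].
#' @param seed Integer seed.
#' @return List with `scans` (list of [corneal_scan()]), `labels` (factor in
#'   diagnostic-class order) and `plan` (per-scan metadata).
#' @export
generate_cohort <- function(n_per_class, grid = polar_grid(), seed = 1L) {
  plan <- cohort_plan(n_per_class, seed)
  scans <- lapply(seq_len(nrow(plan)), function(i)
    generate_cornea(plan$class[i],
                    sample_phenotype_params(plan$class[i],
                                            plan$scan_seed[i]),
                    grid = grid, seed = plan$scan_seed[i],
                    laterality = plan$laterality[i],
                    scan_id = plan$scan_id[i]))
  list(scans = scans,
       labels = factor(plan$class,
                       levels = intersect(DIAGNOSTIC_CLASSES,
                                          unique(plan$class))),
       plan = plan)
}

#' Inferior-superior keratometric difference (I-S value)
#'
#' Mean curvature at the five inferior ring points minus the five superior
#' ring points, on the 3 mm-radius ring at 30-degree spacing (inferior
#' 210..330 degrees, superior 30..150 degrees); values above 1.4 D are the
#' classic keratoconus screening criterion. The point set is mirror
#' symmetric, so the value is laterality-equivariant as-is.
#'
#' @param curv Curvature [scalar_map()] (D).
#' @param laterality `"OD"` or `"OS"` (kept for interface symmetry).
#' @param ring_radius Ring radius in mm (default 3).
#' @return I-S difference in D.
#' @export
is_value <- function(curv, laterality = c("OD", "OS"), ring_radius = 3.0) {
  laterality <- match.arg(laterality)
  inf_th <- seq(210, 330, by = 30) * pi / 180
  sup_th <- seq(30, 150, by = 30) * pi / 180
  inf <- mean(map_interp(curv, ring_radius * cos(inf_th),
                         ring_radius * sin(inf_th)))
  sup <- mean(map_interp(curv, ring_radius * cos(sup_th),
                         ring_radius * sin(sup_th)))
  inf - sup
}

#' Rule-based keratoconus label from the clinical screening criteria
#'
#' Evaluates the quantitative keratoconus criteria on one scan: 3-mm I-S
#' difference > 1.4 D; central keratometry > 47.2 D; focal corneal thinning
#' (minimum below the normal 5th percentile with the thinnest point off the
#' vertex or co-located with the curvature maximum); and focal epithelial
#' thinning over the cone apex. The scan is labelled keratoconus when at
#' least two criteria fire.
#'
#' @param scan A [corneal_scan()].
#' @param thk_p5 Normal-cohort 5th percentile of minimum corneal thickness
#'   (um).
#' @param epi_p5 Normal-cohort 5th percentile of minimum epithelial
#'   thickness (um).
#' @return List with `label` (`"Kcn"` or `"not-Kcn"`) and `criteria`
#'   (named logical vector).
#' @export
rule_based_label <- function(scan, thk_p5 = 495, epi_p5 = 48) {
  s <- if (scan$laterality == "OS") mirror_scan(scan) else scan
  curv <- gaussian_curvature_map(s$anterior_elevation, "anterior")
  is_d <- is_value(curv, s$laterality)
  k_central <- k_avg(s$anterior_elevation)
  thk <- thickness_min(s$corneal_thickness)
  km <- k_max(curv)
  epi <- thickness_min(s$epithelial_thickness)
  dist <- function(a, b) sqrt(sum((a - b)^2))
  criteria <- c(
    is_gt_1.4 = is_d > 1.4,
    central_k_gt_47.2 = k_central > 47.2,
    focal_corneal_thinning = thk$value < thk_p5 &&
      (dist(thk$location, c(0, 0)) > 0.5 ||
         dist(thk$location, km$location) < 1.0),
    focal_epithelial_thinning = epi$value < epi_p5 &&
      dist(epi$location, km$location) <= 1.0)
  list(label = if (sum(criteria) >= 2L) "Kcn" else "not-Kcn",
       criteria = criteria)
}
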