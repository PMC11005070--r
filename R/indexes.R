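# The 19 scalar screening indexes, their helper operations, and the
# per-scan orchestration that assembles the index vector.

#' Names of the 19 screening indexes, in fixed order
#'
#' Curvature-type indexes are in keratometric diopters, elevation/thickness
#' indexes in micrometres, `NPtsR` in mm, `EI_F`/`EI_B` dimensionless and
#' `pTI`/`pEpiTI` in percent.
#' @export
INDEX_NAMES <- c("SI_F", "SI_B", "CSI_F", "CSI_B", "EI_F", "EI_B",
                 "RMS_F", "RMS_B", "SI_THK", "pTI", "pEpiTI", "Thk_Min",
                 "KMax_F", "KMax_B", "DZMax_F", "DZMax_B", "NPtsR",
                 "KAvg_F", "KAvg_B")

# Hemispheric zone centers (x, y) for the symmetry indexes.
# Right eyes use the 81/261 degree axis, left eyes its mirror image 99/279;
# the inferior zone is the one with negative y (261 or 279 degrees).
si_zone_centers <- function(laterality, center_dist = 3.0) {
  ax <- if (laterality == "OD") 81 else 99
  sup <- ax * pi / 180
  inf <- (ax + 180) * pi / 180
  list(inferior = center_dist * c(cos(inf), sin(inf)),
       superior = center_dist * c(cos(sup), sin(sup)))
}

#' Hemispheric symmetry index of a curvature or thickness map
#'
#' Difference between the area-weighted means of two circular zones of
#' radius 1.5 mm whose centers sit 3 mm from the vertex on the 81/261 degree
#' axis (right eyes) or its mirror image 99/279 (left eyes): inferior-zone
#' mean minus superior-zone mean. The zones graze the edge of the 8 mm
#' support and are clipped to it.
#'
#' On curvature maps this is the symmetry index (positive when the inferior
#' cornea is steeper, as in keratoconus); on corneal thickness maps it is the
#' thickness symmetry index (negative when the inferior cornea is thinner).
#'
#' @param map Curvature or thickness [scalar_map()].
#' @param laterality `"OD"` or `"OS"`.
#' @param zone_radius Zone radius in mm (default 1.5).
#' @param center_dist Distance of the zone centers from the vertex (mm,
#'   default 3).
#' @return Inferior minus superior zone mean.
#' @export
symmetry_index <- function(map, laterality = c("OD", "OS"),
                           zone_radius = 1.5, center_dist = 3.0) {
  laterality <- match.arg(laterality)
  ctr <- si_zone_centers(laterality, center_dist)
  sample_zone_mean(map, ctr$inferior, zone_radius, clip = TRUE) -
    sample_zone_mean(map, ctr$superior, zone_radius, clip = TRUE)
}

#' @rdname symmetry_index
#' @export
thickness_symmetry_index <- function(map, laterality = c("OD", "OS"),
                                     zone_radius = 1.5, center_dist = 3.0) {
  symmetry_index(map, laterality, zone_radius, center_dist)
}

#' Center-surrounding index of a curvature map
#'
#' Mean curvature of the central disc of radius 1.5 mm minus the mean over
#' the concentric 1.5-3 mm annulus: positive when the center is steeper than
#' its surround (central ectasia), negative for centrally flattened corneas
#' (myopic ablation profile).
#'
#' @param curv Curvature [scalar_map()] (D).
#' @param r_center Central zone radius (mm).
#' @param r_outer Annulus outer radius (mm).
#' @return Central mean minus annulus mean (D).
#' @export
center_surrounding_index <- function(curv, r_center = 1.5, r_outer = 3.0) {
  sample_zone_mean(curv, c(0, 0), r_center) -
    sample_annulus_mean(curv, r_center, r_outer)
}

#' Area-weighted RMS of a deviation map
#'
#' Root-mean-square of the deviation from the reference surface over the
#' full fitted zone, in micrometres.
#'
#' @param dev Deviation [scalar_map()] (um) from [deviation_map()].
#' @return RMS in um.
#' @export
rms_vs_reference <- function(dev) {
  stopifnot(inherits(dev, "scalar_map"))
  nt <- node_table(dev$grid)
  v <- map_flat(dev)
  sqrt(sum(nt$w * v^2) / sum(nt$w))
}

# Shared extremum helper: canonical order (apex, then ring-major) makes
# which.min/which.max implement the documented tie-break (smallest radius,
# then smallest meridian index).
map_extremum <- function(map, which = c("max", "min")) {
  which <- match.arg(which)
  v <- map_flat(map)
  i <- if (which == "max") which.max(v) else which.min(v)
  nt <- node_table(map$grid)
  list(value = v[i], location = c(x = nt$x[i], y = nt$y[i]), index = i)
}

#' Signed maximum of a deviation map and its location
#'
#' The highest point of the elevation relative to the best-fit reference
#' surface (signed maximum, not maximum absolute value), with its Cartesian
#' location; ties resolve to the smallest radius then smallest meridian.
#'
#' @param dev Deviation [scalar_map()] (um).
#' @return List with `value` (um) and `location` (mm).
#' @export
dz_max <- function(dev) map_extremum(dev, "max")[c("value", "location")]

#' Minimum of a thickness map and its location
#'
#' @param thk Thickness [scalar_map()] (um).
#' @return List with `value` (um) and `location` (mm).
#' @export
thickness_min <- function(thk) map_extremum(thk, "min")[c("value", "location")]

#' Maximum of a curvature map and its location
#'
#' @param curv Curvature [scalar_map()] (D).
#' @return List with `value` (D) and `location` (mm).
#' @export
k_max <- function(curv) map_extremum(curv, "max")[c("value", "location")]

#' Average keratometry over the central 3 mm zone
#'
#' Mean keratometric power of the two principal meridians,
#' `337.5 * (1/Rf + 1/Rs) / 2`, where `Rf`, `Rs` are the per-meridian mean
#' axial radii from [axial_principal_meridians()].
#'
#' @param elevation Elevation [scalar_map()] (mm).
#' @param zone_diameter Central zone diameter (mm, default 3).
#' @return Average keratometry in D.
#' @export
k_avg <- function(elevation, zone_diameter = 3.0) {
  pm <- axial_principal_meridians(elevation, zone_diameter)
  KERATOMETRIC_INDEX * (1 / pm$r_flat + 1 / pm$r_steep) / 2
}

#' Percentage thickness-increase profile around the thinnest point
#'
#' Centered on the thinnest point of the map, computes the area-weighted
#' mean thickness `CT(d)` over annuli of width 0.1 mm out to 3 mm and
#' returns the percentage increase profile
#' `PTI(d) = 100 * (CT(d) - CT_min) / CT_min`, where `CT_min` is the
#' thickness at the thinnest point. Annuli are clipped to the map support;
#' a thinnest point closer than 0.5 mm to the rim flags the profile as
#' truncated.
#'
#' @param thk Thickness [scalar_map()] (um).
#' @param d_max Outermost annulus distance (mm).
#' @param step Annulus width (mm).
#' @return List with `d` (annulus outer distances, mm), `pti` (percent),
#'   `ct_min` (um), `center` (mm) and `truncated` (logical).
#' @export
pct_thickness_increase_profile <- function(thk, d_max = 3.0, step = 0.1) {
  tm <- thickness_min(thk)
  ctr <- tm$location
  nt <- node_table(thk$grid)
  dist <- sqrt((nt$x - ctr[1])^2 + (nt$y - ctr[2])^2)
  v <- map_flat(thk)
  d <- seq(step, d_max, by = step)
  pti <- numeric(length(d))
  for (i in seq_along(d)) {
    inside <- dist > d[i] - step + 1e-9 & dist <= d[i] + 1e-9
    if (!any(inside)) { pti[i] <- NA_real_; next }
    w <- nt$w[inside]
    ct <- if (sum(w) > 0) sum(w * v[inside]) / sum(w) else mean(v[inside])
    pti[i] <- 100 * (ct - tm$value) / tm$value
  }
  # interpolate over any empty annuli (possible only at very coarse grids)
  if (anyNA(pti)) pti <- stats::approx(d[!is.na(pti)], pti[!is.na(pti)],
                                       xout = d, rule = 2)$y
  truncated <- sqrt(sum(ctr^2)) > thk$grid$max_radius - 0.5
  list(d = d, pti = pti, ct_min = tm$value, center = ctr,
       truncated = truncated)
}

#' Maximum excess of a thickness-increase profile over a normative profile
#'
#' The screening index is the maximum, over annulus distances, of the
#' subject's percentage thickness-increase profile minus the normative 95th
#' percentile profile; positive values mean the thickness rises abnormally
#' fast away from the thinnest point.
#'
#' @param profile Subject profile from [pct_thickness_increase_profile()].
#' @param normative_p95 Normative profile: list with `d` and `pti` on the
#'   same distance grid (or `NULL` for a zero baseline).
#' @return Index value in percent.
#' @export
pti_index <- function(profile, normative_p95 = NULL) {
  if (is.null(normative_p95)) return(max(profile$pti))
  if (length(normative_p95$d) != length(profile$d) ||
      max(abs(normative_p95$d - profile$d)) > 1e-9)
    stop("profile and normative profile are on different distance grids")
  max(profile$pti - normative_p95$pti)
}

#' @describeIn pti_index Convenience wrapper applying the same machinery to
#'   an epithelial thickness map (profile centered on the epithelial
#'   thinnest point).
#' @param epi_thk Epithelial thickness [scalar_map()] (um).
#' @export
epi_pti_index <- function(epi_thk, normative_p95 = NULL) {
  pti_index(pct_thickness_increase_profile(epi_thk), normative_p95)
}

#' Spread of the notable points
#'
#' Mean Euclidean distance of the seven notable points (thinnest corneal,
#' epithelial and stromal points, anterior/posterior curvature maxima,
#' anterior/posterior deviation maxima) from their barycenter. A small
#' spread with extreme index values indicates a spatially coherent cone.
#'
#' @param points A 7 x 2 numeric matrix of Cartesian locations (mm).
#' @return Mean distance from the barycenter (mm).
#' @export
nps_spread <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) != 7L || ncol(points) != 2L)
    stop("points must be a 7 x 2 matrix")
  ctr <- colMeans(points)
  mean(sqrt((points[, 1] - ctr[1])^2 + (points[, 2] - ctr[2])^2))
}

#' Ectatic index: weighted multi-quadratic Zernike functional
#'
#' Evaluates `sum_k sum_nm alpha_nmk * c_nm^k` for k in {1, 2}: a
#' linear-plus-quadratic functional of the Zernike coefficients whose
#' weights are trained to separate normal from keratoconic surfaces
#' ([train_ei_weights()]).
#'
#' @param spec A `zernike_spectrum`.
#' @param w An `ei_weights` object.
#' @return The scalar ectatic index (dimensionless).
#' @export
ectatic_index <- function(spec, w) {
  stopifnot(inherits(spec, "zernike_spectrum"), inherits(w, "ei_weights"))
  cs <- spec$coefficients[names(w$alpha1)]
  if (anyNA(cs))
    stop("spectrum does not cover the (n, m) support of the weights")
  sum(w$alpha1 * cs) + sum(w$alpha2 * cs^2)
}

#' Train ectatic-index weights on labelled Zernike spectra
#'
#' Fits the per-coefficient weights of the ectatic index by ridge-regularized
#' logistic discrimination of keratoconus versus normal surfaces on the
#' feature vector `(c_nm, c_nm^2)` (piston and tilt excluded). The fitted
#' linear predictor, without its intercept, is the ectatic index.
#'
#' @param spectra List of `zernike_spectrum` objects.
#' @param labels Factor/character vector: `"Kcn"` is the positive class,
#'   anything else negative. Both classes must be present.
#' @param side `"anterior"` or `"posterior"` (recorded).
#' @param lambda Ridge penalty passed to [glmnet::glmnet()].
#' @return Object of class `ei_weights` with named `alpha1` and `alpha2`
#'   weight vectors.
#' @export
train_ei_weights <- function(spectra, labels, side = c("anterior",
                                                       "posterior"),
                             lambda = 0.05) {
  side <- match.arg(side)
  y <- as.integer(as.character(labels) == "Kcn")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (length(spectra) != length(y)) stop("spectra and labels length mismatch")
  idx <- zernike_indices(spectra[[1L]]$max_order)
  keep <- idx$n >= 2L
  nm <- idx$name[keep]
  C <- t(vapply(spectra, function(s) s$coefficients[nm],
                numeric(length(nm))))
  X <- cbind(C, C^2)
  colnames(X) <- c(paste0(nm, "_k1"), paste0(nm, "_k2"))
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  beta <- as.numeric(fit$beta)
  w <- list(alpha1 = stats::setNames(beta[seq_along(nm)], nm),
            alpha2 = stats::setNames(beta[seq_along(nm) + length(nm)], nm),
            side = side, intercept = as.numeric(fit$a0), lambda = lambda,
            n_train = length(y))
  class(w) <- "ei_weights"
  w
}

#' @export
print.ei_weights <- function(x, ...) {
  cat(sprintf("ei_weights (%s): %d Zernike modes, trained on %d surfaces\n",
              x$side, length(x$alpha1), x$n_train))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Per-scan feature extraction and index assembly.
#
# Everything except the ectatic indexes and the thickness-increase excesses
# is a fixed function of the scan; those two need trained weights and a
# normative profile. compute_scan_features() extracts once; the pipeline
# calls it per scan and assembles the vector after the training-only models
# are frozen. Scans are canonicalized to right-eye orientation first, which
# makes every index exactly invariant under mirroring + laterality flip.

compute_scan_features <- function(scan) {
  stopifnot(inherits(scan, "corneal_scan"))
  if (scan$laterality == "OS") scan <- mirror_scan(scan)
  curv_f <- gaussian_curvature_map(scan$anterior_elevation, "anterior")
  curv_b <- gaussian_curvature_map(scan$posterior_elevation, "posterior")
  ref_f <- fit_reference_asphotoric(scan$anterior_elevation, Q = -0.2)
  ref_b <- fit_reference_asphotoric(scan$posterior_elevation, Q = -0.3)
  dev_f <- deviation_map(scan$anterior_elevation, ref_f)
  dev_b <- deviation_map(scan$posterior_elevation, ref_b)
  dzf <- dz_max(dev_f); dzb <- dz_max(dev_b)
  kmf <- k_max(curv_f); kmb <- k_max(curv_b)
  thk <- thickness_min(scan$corneal_thickness)
  epi <- thickness_min(scan$epithelial_thickness)
  str <- thickness_min(scan$stromal_thickness)
  pts <- rbind(epi$location, str$location, thk$location, kmf$location,
               kmb$location, dzf$location, dzb$location)
  rownames(pts) <- c("PEpiThkMin", "PStrThkMin", "PThkMin", "PKmaxF",
                     "PKmaxB", "PDZMaxF", "PDZMaxB")
  list(
    scan_id = scan$scan_id,
    indexes = c(
      SI_F = symmetry_index(curv_f, scan$laterality),
      SI_B = symmetry_index(curv_b, scan$laterality),
      CSI_F = center_surrounding_index(curv_f),
      CSI_B = center_surrounding_index(curv_b),
      RMS_F = rms_vs_reference(dev_f),
      RMS_B = rms_vs_reference(dev_b),
      SI_THK = thickness_symmetry_index(scan$corneal_thickness,
                                        scan$laterality),
      Thk_Min = thk$value,
      KMax_F = kmf$value,
      KMax_B = kmb$value,
      DZMax_F = dzf$value,
      DZMax_B = dzb$value,
      NPtsR = nps_spread(pts),
      KAvg_F = k_avg(scan$anterior_elevation),
      KAvg_B = k_avg(scan$posterior_elevation)),
    spec_f = fit_zernike(scan$anterior_elevation),
    spec_b = fit_zernike(scan$posterior_elevation),
    pti_profile = pct_thickness_increase_profile(scan$corneal_thickness),
    epi_profile = pct_thickness_increase_profile(scan$epithelial_thickness),
    notable_points = pts)
}

assemble_index_vector <- function(features, ei_w_f = NULL, ei_w_b = NULL,
                                  normative = NULL) {
  v <- stats::setNames(numeric(length(INDEX_NAMES)), INDEX_NAMES)
  v[names(features$indexes)] <- features$indexes
  v["EI_F"] <- if (is.null(ei_w_f)) 0 else
    ectatic_index(features$spec_f, ei_w_f)
  v["EI_B"] <- if (is.null(ei_w_b)) 0 else
    ectatic_index(features$spec_b, ei_w_b)
  v["pTI"] <- pti_index(features$pti_profile,
                        if (is.null(normative)) NULL else normative$pti_p95)
  v["pEpiTI"] <- pti_index(features$epi_profile,
                           if (is.null(normative)) NULL else
                             normative$epi_pti_p95)
  attr(v, "notable_points") <- features$notable_points
  attr(v, "scan_id") <- features$scan_id
  v
}

#' Compute the 19-element screening index vector for one eye
#'
#' Orchestrates the full geometry chain — curvature maps, best-fit
#' aspho-toric reference surfaces, deviation maps, Zernike decomposition,
#' thickness profiles and notable points — and assembles the 19 screening
#' indexes in their fixed order. Left-eye scans are mirrored to right-eye
#' orientation first, so mirrored fellow scans yield identical vectors.
#'
#' @param scan A [corneal_scan()].
#' @param ei_w_f,ei_w_b Trained [train_ei_weights()] for the anterior and
#'   posterior surfaces; `NULL` yields `EI_F = EI_B = 0`.
#' @param normative A [normative_percentiles()] model supplying the
#'   thickness-increase 95th-percentile profiles; `NULL` compares against a
#'   zero baseline.
#' @return Named numeric vector of length 19 (see [INDEX_NAMES]), with the
#'   notable-point locations attached as attribute `notable_points`.
#' @export
compute_index_vector <- function(scan, ei_w_f = NULL, ei_w_b = NULL,
                                 normative = NULL) {
  tryCatch(
    assemble_index_vector(compute_scan_features(scan), ei_w_f, ei_w_b,
                          normative),
    error = function(e) stop("index computation failed for scan '",
                             scan$scan_id, "': ", conditionMessage(e)))
}

#' Compute the index table for a list of scans
#'
#' @param scans List of [corneal_scan()]s.
#' @inheritParams compute_index_vector
#' @return Data frame: `scan_id`, `laterality`, then the 19 index columns.
#' @export
compute_index_table <- function(scans, ei_w_f = NULL, ei_w_b = NULL,
                                normative = NULL) {
  rows <- lapply(scans, compute_index_vector, ei_w_f = ei_w_f,
                 ei_w_b = ei_w_b, normative = normative)
  out <- as.data.frame(do.call(rbind, rows))
  data.frame(scan_id = vapply(scans, function(s) s$scan_id, ""),
             laterality = vapply(scans, function(s) s$laterality, ""),
             out, stringsAsFactors = FALSE)
}
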