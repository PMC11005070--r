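# Best-fit aspho-toric reference surfaces and deviation maps.
#
# The reference family is a conicoid sagitta with fixed asphericity Q and a
# meridionally varying apical curvature
#   c(theta) = c_flat + (c_steep - c_flat) * sin^2(theta - axis),
# equivalently c(theta) = a0 + ac cos 2theta + as sin 2theta, the
# parametrization actually optimized (smooth, no axis wrap-around).
# Elevation is positive toward the instrument, so the model surface is the
# negated sagitta.

# Conicoid sagitta (mm) for apical curvature c (1/mm) and asphericity Q.
conic_sagitta <- function(r, curv, Q) {
  disc <- pmax(1 - (1 + Q) * curv^2 * r^2, 1e-9)
  curv * r^2 / (1 + sqrt(disc))
}

# Aspho-toric elevation model on flat node vectors (r, theta deg).
asphotoric_elevation_values <- function(r, theta_deg, r_flat, r_steep,
                                        axis_deg, Q) {
  th <- (theta_deg - axis_deg) * pi / 180
  curv <- 1 / r_flat + (1 / r_steep - 1 / r_flat) * sin(th)^2
  -conic_sagitta(r, curv, Q)
}

#' Aspho-toric elevation map
#'
#' Builds the elevation map (mm, positive toward the instrument, apex at 0)
#' of an aspho-toric surface: conicoid meridians of fixed asphericity `Q`
#' whose apical curvature varies sinusoidally between the flat and steep
#' principal meridians.
#'
#' @param grid A [polar_grid()].
#' @param r_flat,r_steep Apical radii of the flat and steep meridians (mm).
#' @param axis Flat-meridian axis in degrees.
#' @param Q Asphericity (Q = 0 sphere, Q < 0 prolate).
#' @return An elevation [scalar_map()].
#' @export
asphotoric_elevation <- function(grid, r_flat, r_steep = r_flat, axis = 0,
                                 Q = -0.2) {
  map_from_function(grid, function(nt)
    asphotoric_elevation_values(nt$r, nt$theta, r_flat, r_steep, axis, Q),
    kind = "elevation")
}

#' Best-fit aspho-toric reference surface
#'
#' Fits the aspho-toric family (asphericity fixed, never fitted) to an
#' elevation map over a centred circular zone by area-weighted least squares.
#' The optimizer is Levenberg-Marquardt on the smooth curvature
#' parametrization `(a0, ac, as)`, started from the closed-form paraxial
#' spherical fit, and is deterministic.
#'
#' @param elevation Elevation [scalar_map()] (mm).
#' @param Q Fixed asphericity: -0.2 for the anterior surface, -0.3 for the
#'   posterior surface (physiological averages).
#' @param zone_diameter Fit zone diameter in mm (default 8).
#' @return Object of class `reference_surface` with `r_flat`, `r_steep`
#'   (mm, flat >= steep), `axis` (deg, flat meridian, `[0, 180)`), `Q`,
#'   `fit_zone_diameter`, `fit_rms_residual` (um) and the raw curvature
#'   coefficients `curv_coefs`.
#' @export
fit_reference_asphotoric <- function(elevation, Q = -0.2,
                                     zone_diameter = 8.0) {
  stopifnot(inherits(elevation, "scalar_map"))
  g <- elevation$grid
  zr <- zone_diameter / 2
  if (zr > g$max_radius + 1e-6) stop("fit zone outside map support")
  nt <- node_table(g)
  inside <- nt$r <= zr + 1e-9
  r <- nt$r[inside]; thr <- nt$theta[inside] * pi / 180
  z <- map_flat(elevation)[inside]
  sw <- sqrt(nt$w[inside])
  # paraxial spherical initialization: z ~ -c r^2 / 2
  c0 <- -2 * sum(nt$w[inside] * z * r^2) / sum(nt$w[inside] * r^4)
  model <- function(p) {
    curv <- p[1] + p[2] * cos(2 * thr) + p[3] * sin(2 * thr)
    -conic_sagitta(r, curv, Q)
  }
  resid_fn <- function(p) sw * (z - model(p))
  fit <- minpack.lm::nls.lm(par = c(c0, 0, 0), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  if (fit$info == 0 || fit$info == 9)
    stop(sprintf("aspho-toric fit did not converge (residual %.3g um)",
                 1000 * sqrt(fit$deviance / sum(nt$w[inside]))))
  p <- fit$par
  amp <- sqrt(p[2]^2 + p[3]^2)
  c_flat <- p[1] - amp
  c_steep <- p[1] + amp
  axis <- if (amp < 1e-12) 0 else
    ((atan2(-p[3], -p[2]) / 2) * 180 / pi) %% 180  # curvature minimum
  if (c_flat <= 0)
    stop("aspho-toric fit produced non-positive flat curvature")
  rms <- 1000 * sqrt(sum((sw * (z - model(p)))^2) / sum(nt$w[inside]))
  out <- list(r_flat = 1 / c_flat, r_steep = 1 / c_steep, axis = axis,
              Q = Q, fit_zone_diameter = zone_diameter,
              fit_rms_residual = rms, curv_coefs = p)
  class(out) <- "reference_surface"
  out
}

#' @export
print.reference_surface <- function(x, ...) {
  cat(sprintf(paste0("reference_surface: R %.3f/%.3f mm @ %.1f deg, Q = %.2f",
                     " (fixed), RMS residual %.3g um\n"),
              x$r_flat, x$r_steep, x$axis, x$Q, x$fit_rms_residual))
  invisible(x)
}

# Evaluate a fitted reference surface on a grid (elevation mm).
reference_elevation_flat <- function(ref, nt) {
  p <- ref$curv_coefs
  thr <- nt$theta * pi / 180
  curv <- p[1] + p[2] * cos(2 * thr) + p[3] * sin(2 * thr)
  -conic_sagitta(nt$r, curv, ref$Q)
}

#' Deviation of an elevation map from its reference surface
#'
#' Node-wise elevation minus reference-surface elevation, in micrometres.
#' Positive values are forward protrusions relative to the best-fit
#' aspho-toric shape (the signature of an ectatic cone).
#'
#' @param elevation Elevation [scalar_map()] (mm).
#' @param ref A [fit_reference_asphotoric()] result for the same surface.
#' @return A deviation [scalar_map()] (um).
#' @export
deviation_map <- function(elevation, ref) {
  stopifnot(inherits(elevation, "scalar_map"),
            inherits(ref, "reference_surface"))
  nt <- node_table(elevation$grid)
  dev <- (map_flat(elevation) - reference_elevation_flat(ref, nt)) * 1000
  flat_to_map(elevation$grid, dev, kind = "deviation")
}
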