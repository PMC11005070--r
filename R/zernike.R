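# Zernike decomposition of elevation maps over a circular pupil.
#
# Orthonormal (unit-variance over the unit disc) basis; OSA/ANSI (n, m)
# ordering with signed azimuthal frequency m: m < 0 are sine terms,
# m >= 0 cosine terms. Coefficients are in micrometres.

#' Zernike mode table for a maximum radial order
#'
#' @param max_order Maximum radial order n.
#' @return Data frame with columns `n`, `m` (signed azimuthal frequency) and
#'   `name` (e.g. `"Z4_-2"`), one row per mode, `(max_order+1)(max_order+2)/2`
#'   rows in OSA order.
#' @export
zernike_indices <- function(max_order) {
  n <- rep(0:max_order, times = 0:max_order + 1L)
  m <- unlist(lapply(0:max_order, function(k) seq(-k, k, by = 2L)))
  data.frame(n = n, m = m, name = paste0("Z", n, "_", m),
             stringsAsFactors = FALSE)
}

# Radial polynomial R_n^|m|(rho) by the explicit factorial sum.
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  out <- 0
  for (s in 0:((n - m) / 2)) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) *
         factorial((n - m) / 2 - s)) * rho^(n - 2 * s)
  }
  out
}

# One orthonormal mode evaluated at polar points (rho in [0,1], theta rad).
zernike_mode <- function(n, m, rho, theta) {
  norm <- sqrt(2 * (n + 1) / (1 + (m == 0)))
  ang <- if (m >= 0) cos(m * theta) else sin(-m * theta)
  norm * zernike_radial(n, m, rho) * ang
}

# Design matrix (+ weights + qr) for a grid/pupil/order combination, cached.
zernike_design <- function(grid, max_order, pupil_radius) {
  key <- paste0("zern|", grid_signature(grid), "|", max_order, "|",
                format(pupil_radius, digits = 12))
  hit <- .kcs_cache[[key]]
  if (!is.null(hit)) return(hit)
  nt <- node_table(grid)
  inside <- nt$r <= pupil_radius + 1e-9
  rho <- nt$r[inside] / pupil_radius
  theta <- nt$theta[inside] * pi / 180
  idx <- zernike_indices(max_order)
  Z <- matrix(0, sum(inside), nrow(idx))
  for (i in seq_len(nrow(idx)))
    Z[, i] <- zernike_mode(idx$n[i], idx$m[i], rho, theta)
  sw <- sqrt(pmax(nt$w[inside], 1e-8))  # area weights; tiny weight keeps apex
  qrz <- qr(Z * sw)
  if (qrz$rank < ncol(Z))
    stop("Zernike design is rank deficient for this grid; lower max_order")
  out <- list(inside = inside, sw = sw, Z = Z, qr = qrz, idx = idx)
  .kcs_cache[[key]] <- out
  out
}

#' Least-squares Zernike decomposition of an elevation map
#'
#' Fits the orthonormal Zernike basis up to `max_order` to the elevation over
#' the disc of `pupil_radius`, by area-weighted least squares. Coefficients
#' are returned in micrometres.
#'
#' @param elevation Elevation [scalar_map()] (mm).
#' @param max_order Maximum radial order (default 8; >= 4).
#' @param pupil_radius Fit zone radius in mm (defaults to the full map
#'   support).
#' @return Object of class `zernike_spectrum`: named coefficient vector
#'   (`Zn_m`, um), plus `max_order`, `pupil_radius`, `normalization`.
#' @export
fit_zernike <- function(elevation, max_order = 8L, pupil_radius = NULL) {
  stopifnot(inherits(elevation, "scalar_map"))
  g <- elevation$grid
  if (is.null(pupil_radius)) pupil_radius <- g$max_radius
  if (pupil_radius > g$max_radius + 1e-9)
    stop("pupil_radius exceeds map support")
  if (max_order < 4L) stop("max_order must be >= 4")
  des <- zernike_design(g, max_order, pupil_radius)
  z_um <- map_flat(elevation)[des$inside] * 1000
  coef <- qr.coef(des$qr, z_um * des$sw)
  spec <- list(coefficients = stats::setNames(as.numeric(coef), des$idx$name),
               max_order = as.integer(max_order),
               pupil_radius = pupil_radius,
               normalization = "orthonormal-unit-disc")
  class(spec) <- "zernike_spectrum"
  spec
}

#' @export
print.zernike_spectrum <- function(x, ...) {
  cat(sprintf("zernike_spectrum: order <= %d over %.3g mm pupil, RMS %.3g um\n",
              x$max_order, x$pupil_radius,
              sqrt(sum(x$coefficients[-1]^2))))
  invisible(x)
}

#' Reconstruct the fitted Zernike component of a surface
#'
#' Evaluates a [fit_zernike()] spectrum back onto a grid, as an elevation
#' map in mm. Applying [fit_zernike()] to the reconstruction returns the
#' same spectrum (the fit is a projection).
#'
#' @param spec A `zernike_spectrum`.
#' @param grid Target [polar_grid()].
#' @return An elevation [scalar_map()] (mm); nodes outside the pupil are
#'   extrapolated from the polynomial basis.
#' @export
zernike_reconstruct <- function(spec, grid) {
  nt <- node_table(grid)
  rho <- nt$r / spec$pupil_radius
  theta <- nt$theta * pi / 180
  idx <- zernike_indices(spec$max_order)
  z <- numeric(length(rho))
  for (i in seq_len(nrow(idx)))
    z <- z + spec$coefficients[i] * zernike_mode(idx$n[i], idx$m[i], rho,
                                                 theta)
  flat_to_map(grid, z / 1000, kind = "elevation")
}
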