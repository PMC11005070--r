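# Polar sampling grid and scalar maps shared by all tomography code.
#
# Maps live on a ring/meridian lattice with one extra apex sample at r = 0.
# The canonical node order everywhere in the package is: apex first, then
# ring-major (ring 1 meridian 1, ring 1 meridian 2, ..., ring 2 meridian 1, ...).
# Extremum tie-breaks (smallest radius, then smallest meridian index) fall out
# of that order for free.

#' Polar sampling grid for corneal maps
#'
#' Defines the lattice on which all corneal maps are sampled: `n_rings`
#' concentric rings of `n_meridians` equally spaced meridians, covering a disc
#' of radius `max_radius` millimetres, plus a single apex sample at the
#' corneal vertex. Ring `k` sits at radius `k * max_radius / n_rings` and
#' meridian `j` at angle `(j - 1) * 360 / n_meridians` degrees,
#' counterclockwise from the nasal (+x, right-eye convention) axis.
#'
#' @param n_rings Number of radial samples (>= 16).
#' @param n_meridians Number of angular samples (>= 32, divisible by 4).
#' @param max_radius Radius of coverage in mm; the default 4 mm gives the
#'   8 mm diameter zone over which all indexes are defined.
#' @return An object of class `polar_grid`.
#' @examples
#' g <- polar_grid()
#' g$n_rings
#' @export
polar_grid <- function(n_rings = 31L, n_meridians = 256L, max_radius = 4.0) {
  n_rings <- as.integer(n_rings)
  n_meridians <- as.integer(n_meridians)
  if (n_rings < 16L) stop("n_rings must be >= 16")
  if (n_meridians < 32L || n_meridians %% 4L != 0L)
    stop("n_meridians must be >= 32 and divisible by 4")
  if (!is.finite(max_radius) || max_radius <= 0) stop("max_radius must be > 0")
  g <- list(n_rings = n_rings, n_meridians = n_meridians,
            max_radius = as.numeric(max_radius))
  class(g) <- "polar_grid"
  g
}

#' @export
print.polar_grid <- function(x, ...) {
  cat(sprintf("polar_grid: %d rings x %d meridians, radius %.3g mm (+ apex)\n",
              x$n_rings, x$n_meridians, x$max_radius))
  invisible(x)
}

grid_signature <- function(grid) {
  paste(grid$n_rings, grid$n_meridians, format(grid$max_radius, digits = 15),
        sep = "|")
}

grid_same <- function(a, b) identical(grid_signature(a), grid_signature(b))

#' Ring radii of a polar grid (mm), excluding the apex
#' @param grid A [polar_grid()].
#' @return Numeric vector of length `n_rings`.
#' @keywords internal
grid_radii <- function(grid) {
  seq_len(grid$n_rings) * grid$max_radius / grid$n_rings
}

#' Meridian angles of a polar grid (degrees)
#' @param grid A [polar_grid()].
#' @return Numeric vector of length `n_meridians`.
#' @keywords internal
grid_angles <- function(grid) {
  (seq_len(grid$n_meridians) - 1) * 360 / grid$n_meridians
}

# Per-node geometry in canonical order: apex + ring-major lattice.
# Columns: r, theta (deg), x, y, w (area weight, proportional to r; apex 0).
# Cached per grid because every index touches it.
.kcs_cache <- new.env(parent = emptyenv())

node_table <- function(grid) {
  key <- paste0("nodes|", grid_signature(grid))
  hit <- .kcs_cache[[key]]
  if (!is.null(hit)) return(hit)
  r_rings <- grid_radii(grid)
  th <- grid_angles(grid)
  r <- c(0, rep(r_rings, each = grid$n_meridians))
  theta <- c(0, rep(th, times = grid$n_rings))
  rad <- theta * pi / 180
  out <- list(r = r, theta = theta, x = r * cos(rad), y = r * sin(rad), w = r)
  .kcs_cache[[key]] <- out
  out
}

#' Scalar map on a polar grid
#'
#' A single-valued field (elevation, thickness, curvature or deviation)
#' sampled on a [polar_grid()]. Values are stored as an apex scalar plus an
#' `n_rings x n_meridians` matrix (rows = rings, columns = meridians).
#'
#' Units by kind: elevation maps are millimetres (positive toward the
#' instrument, apex at zero); thickness and deviation maps are micrometres;
#' curvature maps are keratometric diopters.
#'
#' @param grid A [polar_grid()].
#' @param apex Value at the vertex (r = 0).
#' @param values Numeric `n_rings x n_meridians` matrix.
#' @param kind One of `"elevation"`, `"thickness"`, `"curvature"`,
#'   `"deviation"`.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(grid, apex, values,
                       kind = c("elevation", "thickness", "curvature",
                                "deviation")) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "polar_grid"))
  values <- as.matrix(values)
  if (!identical(dim(values), c(grid$n_rings, grid$n_meridians)))
    stop(sprintf("values must be a %d x %d matrix", grid$n_rings,
                 grid$n_meridians))
  if (length(apex) != 1L || !is.finite(apex))
    stop("apex must be a single finite value")
  if (any(!is.finite(values)))
    stop("scalar_map values must be finite (no missing values inside support)")
  if (kind == "thickness" && (apex <= 0 || any(values <= 0)))
    stop("thickness values must be > 0")
  m <- list(grid = grid, apex = as.numeric(apex),
            values = matrix(as.numeric(values), grid$n_rings,
                            grid$n_meridians),
            kind = kind)
  class(m) <- "scalar_map"
  m
}

#' @export
print.scalar_map <- function(x, ...) {
  fl <- map_flat(x)
  cat(sprintf("scalar_map (%s): %d rings x %d meridians, range [%.4g, %.4g]\n",
              x$kind, x$grid$n_rings, x$grid$n_meridians, min(fl), max(fl)))
  invisible(x)
}

# Canonical flattening: apex first, then ring-major.
map_flat <- function(map) c(map$apex, as.vector(t(map$values)))

flat_to_map <- function(grid, flat, kind) {
  scalar_map(grid, flat[1L],
             matrix(flat[-1L], grid$n_rings, grid$n_meridians, byrow = TRUE),
             kind = kind)
}

# Build a scalar_map by evaluating f(nodes) on the canonical node table;
# f receives the node_table list and returns a flat vector.
map_from_function <- function(grid, f, kind) {
  flat_to_map(grid, f(node_table(grid)), kind)
}

#' Bilinear interpolation of a scalar map at arbitrary points
#'
#' Interpolates linearly in radius (between adjacent rings, or between the
#' apex and ring 1) and in angle (between adjacent meridians, periodic).
#'
#' @param map A [scalar_map()].
#' @param x,y Cartesian coordinates in mm (vectors of equal length).
#' @return Numeric vector of interpolated values.
#' @export
map_interp <- function(map, x, y) {
  g <- map$grid
  r <- sqrt(x^2 + y^2)
  if (any(r > g$max_radius + 1e-9))
    stop("interpolation point outside map support")
  r <- pmin(r, g$max_radius)
  theta <- (atan2(y, x) * 180 / pi) %% 360
  dr <- g$max_radius / g$n_rings
  dth <- 360 / g$n_meridians
  # radial cell: ring index below (0 = apex)
  k0 <- pmin(floor(r / dr), g$n_rings - 1L)
  tr <- r / dr - k0
  j0 <- floor(theta / dth)            # 0-based meridian below
  tt <- theta / dth - j0
  j0 <- j0 %% g$n_meridians
  j1 <- (j0 + 1L) %% g$n_meridians
  val_at <- function(k, j) {
    # k: ring (0 = apex), j: 0-based meridian
    out <- numeric(length(k))
    at_apex <- k == 0L
    out[at_apex] <- map$apex
    idx <- !at_apex
    if (any(idx)) out[idx] <- map$values[cbind(k[idx], j[idx] + 1L)]
    out
  }
  v00 <- val_at(k0, j0); v01 <- val_at(k0, j1)
  v10 <- val_at(k0 + 1L, j0); v11 <- val_at(k0 + 1L, j1)
  (1 - tr) * ((1 - tt) * v00 + tt * v01) + tr * ((1 - tt) * v10 + tt * v11)
}

#' Area-weighted mean of a map over a circular zone
#'
#' Averages map values over all nodes inside the disc of given center and
#' radius, with weights proportional to the node area element `r dr dtheta`.
#'
#' @param map A [scalar_map()].
#' @param center Length-2 numeric, Cartesian zone center in mm.
#' @param radius Zone radius in mm.
#' @param clip If `FALSE` (default) a zone extending beyond the grid support
#'   is an error; if `TRUE` the zone is intersected with the support (used by
#'   the hemispheric symmetry zones, which graze the map edge).
#' @return The weighted mean (same units as the map).
#' @export
sample_zone_mean <- function(map, center, radius, clip = FALSE) {
  stopifnot(inherits(map, "scalar_map"), length(center) == 2L, radius > 0)
  g <- map$grid
  if (!clip && sqrt(sum(center^2)) + radius > g$max_radius + 1e-6)
    stop("zone extends beyond map support")
  nt <- node_table(g)
  d2 <- (nt$x - center[1])^2 + (nt$y - center[2])^2
  inside <- d2 <= (radius + 1e-9)^2
  if (!any(inside)) stop("zone contains no grid nodes")
  v <- map_flat(map)[inside]
  w <- nt$w[inside]
  if (sum(w) <= 0) return(mean(v))  # apex-only zone
  sum(w * v) / sum(w)
}

#' Area-weighted mean of a map over a concentric annulus
#'
#' @param map A [scalar_map()].
#' @param r_inner,r_outer Annulus radii in mm, `0 <= r_inner < r_outer <=
#'   max_radius`; nodes with `r_inner < r <= r_outer` contribute.
#' @return The weighted mean.
#' @export
sample_annulus_mean <- function(map, r_inner, r_outer) {
  stopifnot(inherits(map, "scalar_map"))
  g <- map$grid
  if (!(r_inner >= 0 && r_inner < r_outer))
    stop("require 0 <= r_inner < r_outer")
  if (r_outer > g$max_radius + 1e-6)
    stop("annulus extends beyond map support")
  nt <- node_table(g)
  inside <- nt$r > r_inner + 1e-9 & nt$r <= r_outer + 1e-9
  if (!any(inside)) stop("annulus contains no grid nodes")
  v <- map_flat(map)[inside]
  w <- nt$w[inside]
  sum(w * v) / sum(w)
}

# Mirror a map about the vertical (y) axis: theta -> 180 - theta.
# Exact node permutation because n_meridians is even.
map_mirror <- function(map) {
  g <- map$grid
  nm <- g$n_meridians
  half <- nm %/% 2L
  # meridian j (1-based, angle (j-1)*dth) maps to angle 180 - (j-1)*dth,
  # i.e. 1-based index ((half - (j-1)) %% nm) + 1
  j <- seq_len(nm)
  jm <- ((half - (j - 1L)) %% nm) + 1L
  scalar_map(g, map$apex, map$values[, jm, drop = FALSE], kind = map$kind)
}
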