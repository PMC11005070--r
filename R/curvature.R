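# Curvature maps and axial-power analysis of elevation height fields.
#
# Derivatives are estimated by local weighted biquadratic fits over a 5x5
# ring/meridian neighbourhood. The fit is performed in a frame rotated to the
# node's own radial/tangential directions: the neighbourhood geometry is then
# identical for every meridian of a ring, so one 6-parameter least-squares
# operator per ring serves all meridians, and the Gaussian curvature (a
# rotation invariant) is unaffected by the frame choice.

KERATOMETRIC_INDEX <- 337.5  # (n - 1) * 1000 with n = 1.3375, D per mm^-1

# Per-ring derivative operators for a grid, cached.
# For ring k the operator maps neighbourhood values (rows) to
# (zu, zv, zuu, zuv, zvv) where u = radial, v = tangential at the node.
curvature_operators <- function(grid) {
  key <- paste0("curvops|", grid_signature(grid))
  hit <- .kcs_cache[[key]]
  if (!is.null(hit)) return(hit)
  nr <- grid$n_rings; nm <- grid$n_meridians
  rr <- grid_radii(grid)
  dr <- grid$max_radius / nr
  dth <- 2 * pi / nm
  ops <- vector("list", nr)
  for (k in seq_len(nr)) {
    # meridian stride chosen so the tangential span of the window matches
    # the radial span; otherwise the tangential second derivative is
    # estimated from a sliver of arc and amplifies measurement noise
    step <- max(1L, min(as.integer(round(dr / (rr[k] * dth))), nm %/% 12L))
    djs <- step * (-2:2)
    # near the apex a narrower radial window suffices (the apex sample and
    # the wide angular stride supply the information) and cuts truncation
    half <- if (k <= 3L) 2L else 3L
    k_lo <- min(max(1L, k - half), nr - 2L * half)
    ks <- k_lo:(k_lo + 2L * half)
    use_apex <- k <= 3L
    # local coords of neighbour (ring k2, meridian offset dj) relative to
    # the node, in the radial(u)/tangential(v) frame:
    # u = r' cos(dj*dth) - r_k, v = r' sin(dj*dth)
    kk <- rep(ks, each = length(djs))
    dd <- rep(djs, times = length(ks))
    u <- rr[kk] * cos(dd * dth) - rr[k]
    v <- rr[kk] * sin(dd * dth)
    if (use_apex) { u <- c(u, -rr[k]); v <- c(v, 0) }
    # biquadratic basis extended with all cubic terms and the radial quartic:
    # ring arcs couple u and v (u ~ -v^2/2r along an arc), so the cubic cross
    # terms, and the wide radial span, otherwise bias the second derivatives
    A <- cbind(1, u, v, u^2, u * v, v^2, u^3, u^2 * v, u * v^2, v^3, u^4)
    # the quartic cross term matters at large radii where ring arcs couple
    # u and v strongly; near the apex it only destabilizes the small window
    if (k > 3L) A <- cbind(A, u^2 * v^2)
    # the quintic radial term helps only where the window is two-sided
    # (the apex sample makes the innermost windows effectively two-sided);
    # on the one-sided rim windows it just amplifies noise
    if (k <= nr - 3L) A <- cbind(A, u^5)
    sc <- sqrt(colSums(A^2))
    As <- sweep(A, 2L, sc, "/")
    M <- sweep(solve(crossprod(As), t(As)), 1L, sc, "/")
    # rows: zu = M[2,], zv = M[3,], zuu = 2*M[4,], zuv = M[5,], zvv = 2*M[6,]
    D <- rbind(M[2, ], M[3, ], 2 * M[4, ], M[5, ], 2 * M[6, ])
    # neighbour flat-vector indices for each meridian j (cols of a matrix):
    # node index of (ring k2, meridian j+dj) = 1 + (k2-1)*nm + ((j-1+dj) mod nm)
    nb <- matrix(0L, nrow = length(u), ncol = nm)
    row <- 1L
    for (k2 in ks) for (dj in djs) {
      nb[row, ] <- 1L + (k2 - 1L) * nm + ((seq_len(nm) - 1L + dj) %% nm) + 1L
      row <- row + 1L
    }
    if (use_apex) nb[row, ] <- 1L
    ops[[k]] <- list(D = D, nb = nb)
  }
  # apex operator: global x/y frame, apex + rings 1..2, all meridians
  th <- grid_angles(grid) * pi / 180
  ra2 <- rep(rr[1:2], each = nm)
  tha <- rep(th, 2L)
  xa <- c(0, ra2 * cos(tha))
  ya <- c(0, ra2 * sin(tha))
  Aa <- cbind(1, xa, ya, xa^2, xa * ya, ya^2)
  Ma <- solve(crossprod(Aa), t(Aa))
  Da <- rbind(Ma[2, ], Ma[3, ], 2 * Ma[4, ], Ma[5, ], 2 * Ma[6, ])
  nb_a <- c(1L, 1L + as.vector(outer(seq_len(nm), 0:1,
                                     function(j, k2) k2 * nm + j)))
  out <- list(rings = ops, apex = list(D = Da, nb = nb_a))
  .kcs_cache[[key]] <- out
  out
}

# Derivative fields of an elevation map: list of flat vectors
# (zu, zv, zuu, zuv, zvv) in the local radial/tangential frame
# (global x/y at the apex).
elevation_derivatives <- function(elevation) {
  g <- elevation$grid
  ops <- curvature_operators(g)
  z <- map_flat(elevation)
  n <- length(z)
  out <- lapply(1:5, function(i) numeric(n))
  da <- ops$apex$D %*% z[ops$apex$nb]
  for (i in 1:5) out[[i]][1L] <- da[i]
  nm <- g$n_meridians
  for (k in seq_len(g$n_rings)) {
    op <- ops$rings[[k]]
    zw <- matrix(z[op$nb], nrow = nrow(op$nb))
    dd <- op$D %*% zw                       # 5 x nm
    idx <- 1L + (k - 1L) * nm + seq_len(nm)
    for (i in 1:5) out[[i]][idx] <- dd[i, ]
  }
  names(out) <- c("zu", "zv", "zuu", "zuv", "zvv")
  out
}

#' Gaussian curvature map of a corneal surface in keratometric diopters
#'
#' Computes, at every node of an elevation height field, the principal
#' curvatures from the first and second fundamental forms (derivatives by
#' local biquadratic fits over 5x5 node neighbourhoods) and converts the
#' root of their product — the root-Gaussian curvature, a mean-like curvature
#' in mm^-1 — to keratometric diopters as `337.5 * sqrt(k1 * k2)`. Saddle
#' regions (negative Gaussian curvature) are given the signed root
#' `-337.5 * sqrt(-k1 * k2)` so the map stays continuous.
#'
#' A sphere of radius R mm maps to the uniform value `337.5 / R` D.
#'
#' @param elevation Elevation [scalar_map()] in mm.
#' @param side `"anterior"` or `"posterior"` (recorded on the result).
#' @return A curvature [scalar_map()] (diopters) with attribute `side`.
#' @export
gaussian_curvature_map <- function(elevation,
                                   side = c("anterior", "posterior")) {
  side <- match.arg(side)
  stopifnot(inherits(elevation, "scalar_map"))
  d <- elevation_derivatives(elevation)
  num <- d$zuu * d$zvv - d$zuv^2
  den <- (1 + d$zu^2 + d$zv^2)^2
  K <- num / den
  if (any(!is.finite(K)))
    stop("non-finite curvature at node ", which(!is.finite(K))[1L])
  D <- KERATOMETRIC_INDEX * sign(K) * sqrt(abs(K))
  m <- flat_to_map(elevation$grid, D, kind = "curvature")
  attr(m, "side") <- side
  m
}

#' Mean axial radii of the two principal meridians
#'
#' For each meridian, fits a polynomial profile through the apex and the
#' meridian's elevation samples, converts the slope to the axial radius
#' (distance along the surface normal to the optical axis,
#' `Ra = r * sqrt(1 + z'^2) / |z'|`), and averages it over the central zone.
#' A sinusoidal `a + b cos 2theta + c sin 2theta` model across meridians then
#' yields the flat/steep mean radii and the flat axis.
#'
#' @param elevation Elevation [scalar_map()] (mm).
#' @param zone_diameter Averaging zone diameter in mm (default 3).
#' @return List with `r_flat`, `r_steep` (mm, `r_flat >= r_steep`) and
#'   `axis` (degrees in `[0, 180)`, flat meridian; 0 by convention when the
#'   surface is rotationally symmetric).
#' @export
axial_principal_meridians <- function(elevation, zone_diameter = 3.0) {
  stopifnot(inherits(elevation, "scalar_map"))
  g <- elevation$grid
  zone_r <- zone_diameter / 2
  if (zone_r > g$max_radius + 1e-9) stop("zone outside map support")
  rr <- grid_radii(g)
  fit_r <- max(2.5, min(zone_r + 1.0, g$max_radius))
  kfit <- which(rr <= fit_r + 1e-9)
  kavg <- which(rr <= zone_r + 1e-9)
  if (length(kavg) < 3L) stop("zone too small for the grid")
  # degree-5 polynomial in r through the apex, shared design for all meridians
  key <- paste0("axproj|", grid_signature(g), "|", fit_r)
  P <- .kcs_cache[[key]]
  if (is.null(P)) {
    rv <- c(0, rr[kfit])
    A <- outer(rv, 0:5, `^`)
    P <- solve(crossprod(A), t(A))
    .kcs_cache[[key]] <- P
  }
  Z <- rbind(elevation$apex,
             elevation$values[kfit, , drop = FALSE])   # (1+|kfit|) x nm
  coef <- P %*% Z                                      # 6 x nm
  # slope z'(r) at the averaging radii
  ra <- rr[kavg]
  dA <- outer(ra, 0:5, function(r, p) ifelse(p == 0, 0, p * r^(p - 1)))
  slope <- dA %*% coef                                 # |kavg| x nm
  # averaging is done in the power domain (1/Ra): locally axis-parallel
  # patches (slope ~ 0, e.g. atop a decentered cone) have zero axial power
  # but infinite axial radius, and would otherwise dominate the mean
  pw <- abs(slope) / (ra * sqrt(1 + slope^2))          # 1/Ra per node
  m <- colMeans(pw)                                    # mean power per meridian
  if (any(!is.finite(m)) || mean(m) < 1e-6)
    stop("degenerate meridian fit: surface has no axial curvature")
  th2 <- 2 * grid_angles(g) * pi / 180
  X <- cbind(1, cos(th2), sin(th2))
  cf <- solve(crossprod(X), crossprod(X, m))
  amp <- sqrt(cf[2]^2 + cf[3]^2)
  p_flat <- cf[1] - amp                                # flat = least power
  p_steep <- cf[1] + amp
  if (p_flat < 1e-6) stop("degenerate meridian fit: flat meridian has no power")
  if (amp < 1e-9 * cf[1])
    return(list(r_flat = 1 / cf[1], r_steep = 1 / cf[1], axis = 0))
  phi <- atan2(cf[3], cf[2])
  axis <- (((phi + pi) / 2) * 180 / pi) %% 180  # power minimum = flat meridian
  list(r_flat = 1 / p_flat, r_steep = 1 / p_steep, axis = axis)
}
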