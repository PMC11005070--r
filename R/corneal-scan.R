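# The per-eye scan container and its on-disk text format.

DIAGNOSTIC_CLASSES <- c("Abn", "Kcn", "MyPO", "Normal", "SKcn")

#' Diagnostic class factor
#'
#' The five diagnostic classes in their fixed (alphabetical, confusion-matrix)
#' order: `Abn` (abnormal cornea), `Kcn` (keratoconus), `MyPO` (myopic
#' post-operative), `Normal`, `SKcn` (keratoconus suspect).
#'
#' @param x Character vector of class labels.
#' @return A factor with the five fixed levels.
#' @export
diagnostic_class <- function(x) {
  f <- factor(as.character(x), levels = DIAGNOSTIC_CLASSES)
  if (anyNA(f)) stop("unknown diagnostic class label; valid labels: ",
                     paste(DIAGNOSTIC_CLASSES, collapse = ", "))
  f
}

#' Corneal tomography scan for one eye
#'
#' Bundles the five maps describing one eye on a common polar grid: anterior
#' and posterior elevation (mm, positive toward the instrument, zero at each
#' surface's vertex) and corneal, epithelial and stromal thickness (um).
#' Corneal thickness must equal epithelial + stromal thickness within 1 um at
#' every node (well below the device-scale axial resolution).
#'
#' @param anterior_elevation,posterior_elevation Elevation [scalar_map()]s (mm).
#' @param corneal_thickness,epithelial_thickness,stromal_thickness Thickness
#'   [scalar_map()]s (um).
#' @param laterality `"OD"` (right) or `"OS"` (left).
#' @param scan_id Free-text identifier.
#' @return An object of class `corneal_scan`.
#' @export
corneal_scan <- function(anterior_elevation, posterior_elevation,
                         corneal_thickness, epithelial_thickness,
                         stromal_thickness, laterality = c("OD", "OS"),
                         scan_id = "scan") {
  laterality <- match.arg(laterality)
  maps <- list(anterior_elevation = anterior_elevation,
               posterior_elevation = posterior_elevation,
               corneal_thickness = corneal_thickness,
               epithelial_thickness = epithelial_thickness,
               stromal_thickness = stromal_thickness)
  for (nm in names(maps))
    if (!inherits(maps[[nm]], "scalar_map"))
      stop(nm, " must be a scalar_map")
  g <- anterior_elevation$grid
  for (nm in names(maps))
    if (!grid_same(maps[[nm]]$grid, g))
      stop("grid mismatch between maps: ", nm)
  add_err <- abs(map_flat(corneal_thickness) -
                 map_flat(epithelial_thickness) - map_flat(stromal_thickness))
  if (max(add_err) > 1.0)
    stop(sprintf(paste0("corneal thickness differs from epithelial + stromal ",
                        "by up to %.3g um (tolerance 1 um)"), max(add_err)))
  s <- c(maps, list(laterality = laterality, scan_id = as.character(scan_id)))
  class(s) <- "corneal_scan"
  s
}

#' @export
print.corneal_scan <- function(x, ...) {
  g <- x$anterior_elevation$grid
  cat(sprintf("corneal_scan '%s' (%s): %d rings x %d meridians over %.3g mm\n",
              x$scan_id, x$laterality, g$n_rings, g$n_meridians,
              g$max_radius))
  cat(sprintf("  central corneal / epithelial thickness: %.1f / %.1f um\n",
              x$corneal_thickness$apex, x$epithelial_thickness$apex))
  invisible(x)
}

SCAN_SECTIONS <- c(anterior_elevation = "ANTERIOR_ELEVATION_MM",
                   posterior_elevation = "POSTERIOR_ELEVATION_MM",
                   corneal_thickness = "CORNEAL_THICKNESS_UM",
                   epithelial_thickness = "EPITHELIAL_THICKNESS_UM",
                   stromal_thickness = "STROMAL_THICKNESS_UM")

#' Write a corneal scan to the sectioned text format
#'
#' The scan dialect is a UTF-8 text file: a `[META]` section with
#' `key = value` lines (`scan_id`, `laterality`, `n_rings`, `n_meridians`,
#' `max_radius_mm`), then one section per map (`[ANTERIOR_ELEVATION_MM]`,
#' `[POSTERIOR_ELEVATION_MM]`, `[CORNEAL_THICKNESS_UM]`,
#' `[EPITHELIAL_THICKNESS_UM]`, `[STROMAL_THICKNESS_UM]`), each holding one
#' apex-value line followed by an `n_rings x n_meridians` CSV block
#' (row = ring, column = meridian), written with 9 significant digits.
#'
#' @param scan A [corneal_scan()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_scan()]
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "corneal_scan"))
  g <- scan$anterior_elevation$grid
  fmt <- function(x) formatC(x, digits = 9, format = "g")
  lines <- c("[META]",
             paste0("scan_id = ", scan$scan_id),
             paste0("laterality = ", scan$laterality),
             paste0("n_rings = ", g$n_rings),
             paste0("n_meridians = ", g$n_meridians),
             paste0("max_radius_mm = ", fmt(g$max_radius)))
  for (nm in names(SCAN_SECTIONS)) {
    m <- scan[[nm]]
    lines <- c(lines, paste0("[", SCAN_SECTIONS[[nm]], "]"), fmt(m$apex),
               apply(m$values, 1L, function(row) paste(fmt(row),
                                                       collapse = ",")))
  }
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing: ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a corneal scan from the sectioned text format
#'
#' Reads a file produced by [write_scan()] (or any writer of the documented
#' dialect) and validates all container invariants: one value per grid node,
#' a shared grid across the five maps, and corneal = epithelial + stromal
#' thickness within 1 um.
#'
#' @param path File path.
#' @return A [corneal_scan()].
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) stop("scan file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  sec_starts <- grep("^\\[.+\\]$", lines)
  sec_names <- gsub("^\\[|\\]$", "", lines[sec_starts])
  sec_end <- c(sec_starts[-1L] - 1L, length(lines))
  get_section <- function(name) {
    i <- match(name, sec_names)
    if (is.na(i)) stop("scan format error: missing section [", name, "]")
    body <- lines[seq(sec_starts[i] + 1L, sec_end[i])]
    body[nzchar(body)]
  }
  meta_lines <- get_section("META")
  kv <- strsplit(meta_lines, "=", fixed = TRUE)
  meta <- stats::setNames(trimws(vapply(kv, `[`, "", 2L)),
                          trimws(vapply(kv, `[`, "", 1L)))
  for (k in c("scan_id", "laterality", "n_rings", "n_meridians",
              "max_radius_mm"))
    if (is.na(meta[k])) stop("scan format error: META lacks '", k, "'")
  grid <- polar_grid(as.integer(meta["n_rings"]),
                     as.integer(meta["n_meridians"]),
                     as.numeric(meta["max_radius_mm"]))
  read_map <- function(section, kind) {
    body <- get_section(section)
    if (length(body) != grid$n_rings + 1L)
      stop("scan format error: section [", section, "] has ",
           length(body) - 1L, " rows, expected ", grid$n_rings)
    apex <- as.numeric(body[1L])
    rows <- lapply(body[-1L],
                   function(l) as.numeric(strsplit(l, ",", fixed = TRUE)[[1L]]))
    if (any(lengths(rows) != grid$n_meridians))
      stop("scan format error: section [", section,
           "] row length != n_meridians")
    scalar_map(grid, apex, do.call(rbind, rows), kind = kind)
  }
  kinds <- c(anterior_elevation = "elevation", posterior_elevation = "elevation",
             corneal_thickness = "thickness", epithelial_thickness = "thickness",
             stromal_thickness = "thickness")
  maps <- lapply(names(SCAN_SECTIONS),
                 function(nm) read_map(SCAN_SECTIONS[[nm]], kinds[[nm]]))
  names(maps) <- names(SCAN_SECTIONS)
  corneal_scan(maps$anterior_elevation, maps$posterior_elevation,
               maps$corneal_thickness, maps$epithelial_thickness,
               maps$stromal_thickness,
               laterality = as.character(meta["laterality"]),
               scan_id = as.character(meta["scan_id"]))
}

#' Mirror a scan about the vertical axis
#'
#' Reflects every map left-right (nasal/temporal flip) and toggles the
#' laterality, producing the enantiomorphic fellow-eye scan. All
#' rotation-invariant quantities and the full index vector are unchanged by
#' this operation.
#'
#' @param scan A [corneal_scan()].
#' @return The mirrored [corneal_scan()].
#' @export
mirror_scan <- function(scan) {
  corneal_scan(map_mirror(scan$anterior_elevation),
               map_mirror(scan$posterior_elevation),
               map_mirror(scan$corneal_thickness),
               map_mirror(scan$epithelial_thickness),
               map_mirror(scan$stromal_thickness),
               laterality = if (scan$laterality == "OD") "OS" else "OD",
               scan_id = scan$scan_id)
}
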