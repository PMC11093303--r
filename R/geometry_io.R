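#' Export the plexus geometry as WKT polygons
#'
#' One closed `POLYGON` string per region (cord, five roots, three trunks),
#' in model coordinates (mm).
#'
#' @param geom A `plexus_geometry`.
#' @return Named character vector of WKT `POLYGON` strings.
#' @export
geometry_wkt <- function(geom) {
  stopifnot(inherits(geom, "plexus_geometry"))
  polys <- geometry_polygons(geom)
  vapply(polys, function(q) {
    ring <- rbind(q, q[1, , drop = FALSE])
    sprintf("POLYGON ((%s))",
            paste(sprintf("%.9g %.9g", ring[, 1], ring[, 2]), collapse = ", "))
  }, character(1))
}

geometry_polygons <- function(geom) {
  polys <- list(cord = cord_quad(geom$cord))
  for (r in ROOT_IDS) polys[[paste0("root_", r)]] <- root_quad(geom$roots[[r]])
  for (tr in TRUNK_IDS) polys[[paste0("trunk_", tr)]] <- trunk_quad(geom$trunks[[tr]])
  polys
}

#' Write the plexus geometry outline as WKT or SVG
#'
#' @param geom A `plexus_geometry`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_geometry_wkt <- function(geom, path) {
  w <- geometry_wkt(geom)
  writeLines(paste0(names(w), "\t", w), path)
  invisible(path)
}

#' @rdname write_geometry_wkt
#' @export
write_geometry_svg <- function(geom, path) {
  polys <- geometry_polygons(geom)
  all_pts <- do.call(rbind, polys)
  pad <- 2
  x0 <- min(all_pts[, 1]) - pad; x1 <- max(all_pts[, 1]) + pad
  y0 <- min(all_pts[, 2]) - pad; y1 <- max(all_pts[, 2]) + pad
  hdr <- sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" viewBox="%.3f %.3f %.3f %.3f" width="%dmm" height="%dmm">',
    x0, y0, x1 - x0, y1 - y0, round(x1 - x0), round(y1 - y0))
  body <- vapply(names(polys), function(nm) {
    q <- polys[[nm]]
    sprintf('<polygon id="%s" points="%s" fill="none" stroke="black" stroke-width="0.15"/>',
            nm, paste(sprintf("%.4f,%.4f", q[, 1], q[, 2]), collapse = " "))
  }, character(1))
  writeLines(c(hdr, body, "</svg>"), path)
  invisible(path)
}

#' Read and write the plexus model configuration
#'
#' The model configuration is a hierarchical YAML file holding the root
#' dimension table, cord parameters, root angles, trunk lengths, load cases
#' and mesh sizes. The bundled default file
#' (`system.file("extdata", "baseline_plexus.yaml", package = "plexusfem")`)
#' reproduces the baseline model.
#'
#' @param path Path to a YAML configuration file.
#' @return `read_plexus_config()` returns a `plexus_config` list with
#'   elements `dims`, `cord`, `angles`, `trunk_lengths`, `middle_trunk_kink`,
#'   `load_cases`,
#'   `mesh` (list with `h_max`, `h_min`) and `seed`.
#' @export
read_plexus_config <- function(path = default_config_path()) {
  raw <- yaml::read_yaml(path)
  dims <- as.data.frame(raw$root_dimensions, stringsAsFactors = FALSE)
  dims$len_drg_to_foramen <- as.numeric(dims$len_drg_to_foramen)
  validate_root_dimensions(dims)
  cord <- bp_cord_parameters(
    width = raw$cord$width,
    attachment_y = unlist(raw$cord$attachment_y)[ROOT_IDS],
    length = raw$cord$length)
  angles <- unlist(raw$angles)[ROOT_IDS]
  trunk_lengths <- unlist(raw$trunk_lengths)[TRUNK_IDS]
  structure(list(
    dims = dims, cord = cord, angles = angles, trunk_lengths = trunk_lengths,
    middle_trunk_kink = raw$middle_trunk_kink %||% bp_middle_trunk_kink(),
    load_cases = raw$load_cases %||% c("case1", "case2"),
    mesh = list(h_max = raw$mesh$h_max %||% 2, h_min = raw$mesh$h_min %||% 0.2),
    seed = raw$seed %||% 20240514L
  ), class = "plexus_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_plexus_config
#' @param config A `plexus_config` list.
#' @export
write_plexus_config <- function(config, path) {
  raw <- list(
    root_dimensions = as.list(config$dims),
    cord = list(width = config$cord$width,
                attachment_y = as.list(config$cord$attachment_y),
                length = config$cord$length),
    angles = as.list(config$angles),
    trunk_lengths = as.list(config$trunk_lengths),
    middle_trunk_kink = config$middle_trunk_kink,
    load_cases = config$load_cases,
    mesh = config$mesh,
    seed = config$seed
  )
  yaml::write_yaml(raw, path)
  invisible(path)
}

default_config_path <- function() {
  system.file("extdata", "baseline_plexus.yaml", package = "plexusfem")
}

#' Default model configuration
#'
#' In-memory equivalent of the bundled YAML configuration.
#' @return A `plexus_config` list.
#' @export
default_plexus_config <- function() {
  structure(list(
    dims = bp_root_dimensions(),
    cord = bp_cord_parameters(),
    angles = bp_default_angles(),
    trunk_lengths = bp_trunk_lengths(),
    middle_trunk_kink = bp_middle_trunk_kink(),
    load_cases = c("case1", "case2"),
    mesh = list(h_max = 2, h_min = 0.2),
    seed = 20240514L
  ), class = "plexus_config")
}

#' Build geometry from a configuration
#' @param config A `plexus_config`.
#' @return A `plexus_geometry`.
#' @export
geometry_from_config <- function(config = default_plexus_config()) {
  build_plexus_geometry(config$dims, config$cord, config$angles,
                        config$trunk_lengths, config$middle_trunk_kink)
}
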