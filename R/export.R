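#' Export a mesh as an Abaqus INP deck
#'
#' Writes nodes, CPS4 (or CPS4R) element cards grouped by region, element
#' sets per region and node sets for each named edge set. Triangular
#' elements, if present, are written as CPS3.
#'
#' @param mesh A `plexus_mesh`.
#' @param path Output file.
#' @param element_type Quad element code, `"CPS4"` or `"CPS4R"`.
#' @return The path, invisibly.
#' @export
write_mesh_inp <- function(mesh, path, element_type = c("CPS4", "CPS4R")) {
  element_type <- match.arg(element_type)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("*HEADING", "plexusfem 2D plane-stress mesh (mm)")
  wl("*NODE")
  wl(sprintf("%d, %.10g, %.10g", seq_len(nrow(mesh$nodes)),
             mesh$nodes[, 1], mesh$nodes[, 2]))
  quads <- which(!is.na(mesh$elems[, 4]))
  tris <- which(is.na(mesh$elems[, 4]))
  if (length(quads)) {
    for (rg in unique(mesh$region[quads])) {
      sel <- quads[mesh$region[quads] == rg]
      wl(sprintf("*ELEMENT, TYPE=%s, ELSET=%s", element_type, rg))
      wl(sprintf("%d, %d, %d, %d, %d", sel, mesh$elems[sel, 1],
                 mesh$elems[sel, 2], mesh$elems[sel, 3], mesh$elems[sel, 4]))
    }
  }
  if (length(tris)) {
    for (rg in unique(mesh$region[tris])) {
      sel <- tris[mesh$region[tris] == rg]
      wl(sprintf("*ELEMENT, TYPE=CPS3, ELSET=%s_tri", rg))
      wl(sprintf("%d, %d, %d, %d", sel, mesh$elems[sel, 1],
                 mesh$elems[sel, 2], mesh$elems[sel, 3]))
    }
  }
  for (es in names(mesh$edge_sets)) {
    nodes <- edge_set_nodes(mesh, es)
    wl(sprintf("*NSET, NSET=%s", es))
    wl(paste(tapply(nodes, ceiling(seq_along(nodes) / 12),
                    paste, collapse = ", "), collapse = ",\n"))
  }
  invisible(path)
}

#' Export a mesh (optionally with results) as legacy ASCII VTK
#'
#' Writes an unstructured grid; if a solution is supplied, nodal
#' displacements are written as point data and centroid stresses plus von
#' Mises as cell data.
#'
#' @param mesh A `plexus_mesh`.
#' @param path Output file.
#' @param sol Optional `fe_solution`.
#' @return The path, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, sol = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  wl("# vtk DataFile Version 3.0", "plexusfem mesh", "ASCII",
     "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n))
  wl(sprintf("%.10g %.10g 0", mesh$nodes[, 1], mesh$nodes[, 2]))
  sizes <- ifelse(is.na(mesh$elems[, 4]), 3L, 4L)
  wl(sprintf("CELLS %d %d", ne, sum(sizes + 1L)))
  for (e in seq_len(ne)) {
    en <- mesh$elems[e, ]; en <- en[!is.na(en)]
    wl(paste(c(length(en), en - 1L), collapse = " "))
  }
  wl(sprintf("CELL_TYPES %d", ne))
  wl(as.character(ifelse(sizes == 4L, 9L, 5L)))
  if (!is.null(sol)) {
    wl(sprintf("POINT_DATA %d", n), "VECTORS displacement double")
    wl(sprintf("%.10g %.10g 0", sol$u[, 1], sol$u[, 2]))
    wl(sprintf("CELL_DATA %d", ne), "SCALARS von_mises double 1",
       "LOOKUP_TABLE default")
    wl(sprintf("%.10g", sol$stress$vm))
    wl("TENSORS stress double")
    wl(sprintf("%.10g %.10g 0 %.10g %.10g 0 0 0 0",
               sol$stress$sxx, sol$stress$txy, sol$stress$txy, sol$stress$syy))
  }
  invisible(path)
}

#' Write per-element von Mises stresses as CSV
#'
#' @param stress A `stress_field`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_stress_csv <- function(stress, path) {
  utils::write.csv(as.data.frame(stress), path, row.names = FALSE)
  invisible(path)
}
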