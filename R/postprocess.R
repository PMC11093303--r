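#' Maximum von Mises stress at a root-cord junction
#'
#' Returns the maximum element von Mises stress over the elements adjacent to
#' the root's junction edge set (elements sharing at least one node with the
#' root-cord interface). By default only elements of the root's own region
#' are considered — the reported quantity is the stress in the proximal nerve
#' root, not in the adjoining cord; `side = "both"` includes cord elements
#' too. Element stress is the centroid value by default; `measure = "max_gp"`
#' uses the maximum integration-point value instead.
#'
#' @param stress A `stress_field` (from an `fe_solution`).
#' @param mesh The `plexus_mesh` the stresses were computed on.
#' @param root_id One of `"C5"`..`"T1"`, or an edge-set name.
#' @param measure `"centroid"` or `"max_gp"`.
#' @param side `"root"` (default) or `"both"`.
#' @return Stress in MPa.
#' @export
max_junction_stress <- function(stress, mesh, root_id,
                                measure = c("centroid", "max_gp"),
                                side = c("root", "both")) {
  measure <- match.arg(measure)
  side <- match.arg(side)
  set_name <- if (root_id %in% ROOT_IDS) paste0("junction_", root_id) else root_id
  if (is.null(mesh$edge_sets[[set_name]]) ||
      nrow(mesh$edge_sets[[set_name]]) == 0) {
    stop(sprintf("junction edge set '%s' is empty or missing", set_name))
  }
  jn <- edge_set_nodes(mesh, set_name)
  adj <- which(apply(matrix(mesh$elems %in% jn, nrow(mesh$elems), 4), 1, any))
  if (side == "root" && root_id %in% ROOT_IDS) {
    in_root <- adj[mesh$region[adj] == paste0("root_", root_id)]
    if (length(in_root)) adj <- in_root
  }
  vals <- if (measure == "centroid") stress$vm[adj] else stress$vm_max_gp[adj]
  max(vals)
}

#' Mean displacement magnitude of a distal trunk face
#'
#' Magnitude of the mean displacement vector over the nodes of the trunk's
#' distal edge set.
#'
#' @param sol An `fe_solution`.
#' @param mesh The `plexus_mesh`.
#' @param trunk `"upper"`, `"middle"` or `"lower"`, or an edge-set name.
#' @return Displacement in mm.
#' @export
distal_displacement <- function(sol, mesh, trunk) {
  set_name <- if (trunk %in% TRUNK_IDS) paste0("distal_", trunk) else trunk
  if (is.null(mesh$edge_sets[[set_name]]) ||
      nrow(mesh$edge_sets[[set_name]]) == 0) {
    stop(sprintf("distal edge set '%s' is empty or missing", set_name))
  }
  nd <- edge_set_nodes(mesh, set_name)
  sqrt(sum(colMeans(sol$u[nd, , drop = FALSE])^2))
}

#' Engineering strain from displacement and original length
#'
#' `100 * u / L0`, in percent.
#'
#' @param u Displacement (mm).
#' @param L0 Original segment length (mm), > 0.
#' @return Strain in percent. Vectorised.
#' @examples
#' engineering_strain(7.3, 41.4)  # 17.63...%, 17.6% at one decimal
#' @export
engineering_strain <- function(u, L0) {
  if (any(L0 <= 0)) stop("engineering_strain(): L0 must be > 0")
  100 * u / L0
}

#' Percent change of a variant value against a baseline
#'
#' `100 * (variant - baseline) / baseline`, rounded to the nearest integer.
#' Use [format_percent_change()] for the sign-prefixed printed form.
#'
#' @param variant,baseline Values in the same units; `baseline` must be > 0.
#' @return Integer percent change. Vectorised.
#' @examples
#' percent_change(0.137, 0.246)  # -44
#' percent_change(0.286, 0.171)  # +67
#' @export
percent_change <- function(variant, baseline) {
  if (any(baseline <= 0)) stop("percent_change(): baseline must be > 0")
  round(100 * (variant - baseline) / baseline)
}

#' @rdname percent_change
#' @param pc Integer percent change.
#' @export
format_percent_change <- function(pc) {
  sprintf("%+d%%", as.integer(pc))
}

#' Summarise one solved case into the reported quantities
#'
#' Per-root maximum junction von Mises stress, per-trunk distal displacement,
#' and per-trunk engineering strain relative to the original path length.
#'
#' @param sol An `fe_solution`.
#' @param mesh The `plexus_mesh`.
#' @param geom The `plexus_geometry` (for original path lengths).
#' @param case_id Label recorded in the output.
#' @return A list of class `study_result` with data.frames `junction_stress`
#'   (root, vm_MPa) and `trunk_response` (trunk, length0_mm,
#'   displacement_mm, strain_pct).
#' @export
summarise_case <- function(sol, mesh, geom, case_id = "case1") {
  js <- data.frame(
    root = ROOT_IDS,
    vm_MPa = vapply(ROOT_IDS, function(r)
      max_junction_stress(sol$stress, mesh, r), numeric(1)),
    row.names = NULL
  )
  L0 <- vapply(TRUNK_IDS, function(tr) path_length(geom, tr), numeric(1))
  u <- vapply(TRUNK_IDS, function(tr) distal_displacement(sol, mesh, tr),
              numeric(1))
  tr <- data.frame(
    trunk = TRUNK_IDS, length0_mm = unname(L0), displacement_mm = unname(u),
    strain_pct = unname(engineering_strain(u, L0)), row.names = NULL
  )
  structure(list(case_id = case_id, junction_stress = js, trunk_response = tr),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result %s>\n", x$case_id))
  cat("  max junction von Mises stress [MPa]:\n")
  s <- x$junction_stress
  cat(sprintf("    %s\n", paste(sprintf("%s %.3f", s$root, s$vm_MPa),
                                collapse = "  ")))
  t <- x$trunk_response
  for (k in seq_len(nrow(t))) {
    cat(sprintf("  %s trunk: L0 %.1f mm, u %.1f mm, strain %.1f%%\n",
                t$trunk[k], t$length0_mm[k], t$displacement_mm[k],
                t$strain_pct[k]))
  }
  invisible(x)
}
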