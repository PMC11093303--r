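#' Phase-one validation run: both loading cases on the baseline model
#'
#' Builds the baseline geometry, meshes it once, and solves both loading
#' cases on the identical mesh. Because the model is linear elastic with
#' zero-valued displacement constraints, the two stress fields differ only by
#' the applied-pressure ratio; this is verified internally.
#'
#' @param config A `plexus_config` ([default_plexus_config()]).
#' @return A list of class `validation_result` with elements `case1`, `case2`
#'   (each a `study_result`), `mesh`, `geom`, `stress_ratio` (per-root
#'   case2/case1 junction-stress ratios) and `pressure_ratio`.
#' @export
run_validation <- function(config = default_plexus_config()) {
  geom <- geometry_from_config(config)
  mesh <- generate_mesh(geom, config$mesh$h_max, config$mesh$h_min)
  res <- list()
  sols <- list()
  for (cs in c("case1", "case2")) {
    sols[[cs]] <- solve_plexus_case(mesh, cs)
    res[[cs]] <- summarise_case(sols[[cs]], mesh, geom, cs)
  }
  p1 <- bp_load_case("case1")$applied_pressure
  p2 <- bp_load_case("case2")$applied_pressure
  ratio <- res$case2$junction_stress$vm_MPa / res$case1$junction_stress$vm_MPa
  if (max(abs(ratio / (p2 / p1) - 1)) > 1e-6) {
    warning("case2/case1 stress ratio deviates from the pressure ratio; check linearity")
  }
  structure(list(case1 = res$case1, case2 = res$case2, mesh = mesh,
                 geom = geom, solutions = sols,
                 stress_ratio = stats::setNames(ratio, ROOT_IDS),
                 pressure_ratio = p2 / p1),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("Baseline validation (both loading cases, identical mesh)\n")
  print(x$case1); print(x$case2)
  cat(sprintf("  case2/case1 junction-stress ratio: %.4f (pressure ratio %.4f)\n",
              mean(x$stress_ratio), x$pressure_ratio))
  invisible(x)
}

#' Phase-two nerve-root angle sweep
#'
#' Rebuilds and remeshes the model for each angle delta (all five root angles
#' perturbed simultaneously by the same amount, the default reading of the
#' variation study; `mode = "single"` perturbs one root at a time instead and
#' returns one sweep per root), solves the chosen loading case, and reports
#' per-root junction stresses with percent changes against the delta-0
#' baseline. Infeasible perturbed geometries are recorded as failed cells and
#' the sweep continues.
#'
#' @param config A `plexus_config`.
#' @param deltas Angle deltas in degrees; must include 0 when percent changes
#'   are requested.
#' @param case Loading case id.
#' @param mode `"simultaneous"` (default) or `"single"`.
#' @return An object of class `sweep_result`: data.frame `stress` with
#'   columns `delta`, `root`, `vm_MPa`, `pct_change` (NA for delta 0 and for
#'   failed cells), and attributes.
#' @export
run_angle_sweep <- function(config = default_plexus_config(),
                            deltas = c(-6, -3, 0, 3, 6), case = "case1",
                            mode = c("simultaneous", "single")) {
  mode <- match.arg(mode)
  if (!0 %in% deltas) stop("deltas must include 0 (the baseline) for percent changes")
  geom0 <- geometry_from_config(config)
  one_run <- function(geom) {
    mesh <- generate_mesh(geom, config$mesh$h_max, config$mesh$h_min)
    sol <- solve_plexus_case(mesh, case)
    vapply(ROOT_IDS, function(r) max_junction_stress(sol$stress, mesh, r),
           numeric(1))
  }
  rows <- list()
  if (mode == "simultaneous") {
    for (d in sort(deltas)) {
      vm <- tryCatch(
        one_run(if (d == 0) geom0 else perturb_root_angles(geom0, d)),
        error = function(e) rep(NA_real_, 5))
      rows[[length(rows) + 1L]] <- data.frame(
        delta = d, root = ROOT_IDS, vm_MPa = unname(vm), row.names = NULL)
    }
  } else {
    for (d in sort(deltas)) {
      for (r in ROOT_IDS) {
        dv <- stats::setNames(numeric(5), ROOT_IDS); dv[r] <- d
        vm <- tryCatch(
          one_run(if (d == 0) geom0 else perturb_root_angles(geom0, dv)),
          error = function(e) rep(NA_real_, 5))
        rows[[length(rows) + 1L]] <- data.frame(
          delta = d, perturbed = r, root = ROOT_IDS, vm_MPa = unname(vm),
          row.names = NULL)
      }
    }
  }
  stress <- do.call(rbind, rows)
  base <- stress[stress$delta == 0, ]
  if (mode == "simultaneous") {
    base_map <- stats::setNames(base$vm_MPa, base$root)
    stress$pct_change <- ifelse(
      stress$delta == 0 | is.na(stress$vm_MPa), NA_real_,
      percent_change(stress$vm_MPa, base_map[stress$root]))
  } else {
    key <- paste(stress$perturbed, stress$root)
    bkey <- paste(base$perturbed, base$root)
    base_map <- stats::setNames(base$vm_MPa, bkey)
    stress$pct_change <- ifelse(
      stress$delta == 0 | is.na(stress$vm_MPa), NA_real_,
      percent_change(stress$vm_MPa, base_map[key]))
  }
  structure(list(stress = stress, case = case, mode = mode, deltas = sort(deltas)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Angle sweep (%s, %s): max junction von Mises stress [MPa]\n",
              x$case, x$mode))
  if (x$mode == "simultaneous") {
    wide <- stats::reshape(x$stress[, c("delta", "root", "vm_MPa")],
                           idvar = "root", timevar = "delta",
                           direction = "wide")
    print(wide, row.names = FALSE)
  } else {
    print(utils::head(x$stress, 10))
  }
  invisible(x)
}

#' Mesh-convergence study
#'
#' Re-runs a solve at uniformly refined mesh sizes and reports the tracked
#' quantity at each level with its relative change between successive levels.
#'
#' @param factors Refinement factors relative to the base mesh parameters.
#' @param base Base [mesh_params()].
#' @param quantity Function `(sol, mesh) -> numeric(1)` to track; the default
#'   tracks the maximum C5 junction stress on the plexus model.
#' @param geom Geometry to mesh (default baseline).
#' @param case Loading case.
#' @return data.frame with `factor`, `h_max`, `h_min`, `n_elements`, `value`,
#'   `rel_change`.
#' @export
run_convergence <- function(factors = c(1, 2, 4), base = mesh_params(2, 0.2),
                            quantity = NULL, geom = build_plexus_geometry(),
                            case = "case1") {
  if (is.null(quantity)) {
    quantity <- function(sol, mesh) max_junction_stress(sol$stress, mesh, "C5")
  }
  rows <- lapply(factors, function(fc) {
    mp <- refine_mesh_params(base, fc)
    mesh <- generate_mesh(geom, mp$h_max, mp$h_min)
    sol <- solve_plexus_case(mesh, case)
    data.frame(factor = fc, h_max = mp$h_max, h_min = mp$h_min,
               n_elements = nrow(mesh$elems), value = quantity(sol, mesh))
  })
  out <- do.call(rbind, rows)
  out$rel_change <- c(NA, abs(diff(out$value)) / utils::head(out$value, -1))
  out
}

#' Write study outputs as CSV or JSON
#'
#' Writes the junction-stress, trunk-response and (for sweeps) percent-change
#' tables in the layout of the published result tables.
#'
#' @param x A `validation_result` or `sweep_result`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"json"`.
#' @return Paths of the files written, invisibly.
#' @export
write_study_outputs <- function(x, dir, format = c("csv", "json")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, paste0(name, ".", format))
    if (format == "csv") utils::write.csv(df, p, row.names = FALSE)
    else jsonlite::write_json(df, p, dataframe = "rows", digits = NA,
                              pretty = TRUE)
    paths <<- c(paths, p)
  }
  if (inherits(x, "validation_result")) {
    js <- merge(x$case1$junction_stress, x$case2$junction_stress,
                by = "root", suffixes = c("_case1", "_case2"))
    js <- js[match(ROOT_IDS, js$root), ]
    emit(js, "junction_stress")
    tr <- rbind(cbind(case = "case1", x$case1$trunk_response),
                cbind(case = "case2", x$case2$trunk_response))
    emit(tr, "trunk_response")
  } else if (inherits(x, "sweep_result")) {
    emit(x$stress, "angle_sweep")
  } else stop("unsupported result object")
  invisible(paths)
}
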