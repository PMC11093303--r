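#' Elliptical cross-sectional area of a nerve root
#'
#' Nerve-root cross sections are modelled as ellipses with major and minor
#' axes equal to the cranial-caudal and transverse diameters, so the area is
#' `pi/4 * d_cc * d_t`.
#'
#' @param d_cc Cranial-caudal diameter (mm), the in-plane strip width.
#' @param d_t Transverse diameter (mm).
#' @return Area in mm^2. Vectorised over both arguments.
#' @examples
#' ellipse_area(3.0, 1.1)
#' sum(ellipse_area(bp_root_dimensions()$d_cranial_caudal,
#'                  bp_root_dimensions()$d_transverse))  # 16.25 mm^2
#' @export
ellipse_area <- function(d_cc, d_t) {
  if (any(!is.finite(d_cc)) || any(!is.finite(d_t)) ||
      any(d_cc <= 0) || any(d_t <= 0)) {
    stop("ellipse_area(): both diameters must be finite and > 0")
  }
  pi / 4 * d_cc * d_t
}

#' Per-root elliptical areas
#'
#' @param dims Root dimension table as from [bp_root_dimensions()].
#' @return Named numeric vector of root areas (mm^2).
#' @export
root_areas <- function(dims = bp_root_dimensions()) {
  validate_root_dimensions(dims)
  stats::setNames(ellipse_area(dims$d_cranial_caudal, dims$d_transverse),
                  dims$root)
}

#' Trunk cross-sectional areas by tissue-area conservation
#'
#' Cross-sectional area is assumed conserved as roots combine into trunks,
#' so each trunk area is the sum of its member root areas: upper = C5 + C6,
#' middle = C7, lower = C8 + T1. The three trunk areas therefore sum exactly
#' to the five root areas.
#'
#' @inheritParams root_areas
#' @return Named numeric vector (mm^2) for trunks `upper`, `middle`, `lower`.
#' @export
trunk_areas <- function(dims = bp_root_dimensions()) {
  a <- root_areas(dims)
  members <- trunk_members()
  vapply(members, function(m) sum(a[m]), numeric(1))
}

#' Applied distal-trunk pressure from composite-theory load partition
#'
#' The total tensile force (load multiplier times the single-root rupture
#' load) is divided between the trunks in proportion to their cross-sectional
#' areas (composite theory with a common Young's modulus). Because the same
#' areas convert each trunk's force share back to a pressure, the applied
#' pressure is identical for all three trunks:
#' `p = multiplier * F_fail / sum(root areas)`.
#'
#' @param case A `bp_load_case` (or its id as a string).
#' @inheritParams root_areas
#' @return Pressure in MPa (a single number applied to all trunks).
#' @examples
#' applied_pressure(bp_load_case("case1"))  # ~0.332 MPa
#' applied_pressure(bp_load_case("case2"))  # ~0.652 MPa (published: 0.653)
#' @export
applied_pressure <- function(case, dims = bp_root_dimensions()) {
  if (is.character(case)) case <- bp_load_case(case)
  stopifnot(inherits(case, "bp_load_case"))
  total <- sum(root_areas(dims))
  if (total <= 0) stop("applied_pressure(): total root area must be > 0")
  case$load_multiplier * case$rupture_load / total
}

#' Force carried by one trunk under a uniform pressure
#'
#' With the model's unit plane-stress thickness, a pressure `p` over a trunk
#' of cross-sectional area `A` carries force `p * A`; summed over trunks this
#' recovers the total applied tensile force.
#'
#' @param p Pressure (MPa).
#' @param trunk_area Trunk cross-sectional area (mm^2).
#' @return Force in N. Vectorised.
#' @export
trunk_force <- function(p, trunk_area) {
  if (any(p < 0) || any(trunk_area <= 0)) {
    stop("trunk_force(): pressure must be >= 0 and area > 0")
  }
  p * trunk_area
}

#' Load partition report
#'
#' Tabulates, for one loading case, the trunk areas, the force share of each
#' trunk, and the (common) applied pressure — both the published value and
#' the value recomputed from the root areas.
#'
#' @inheritParams applied_pressure
#' @return A `data.frame` with one row per trunk.
#' @export
load_partition <- function(case, dims = bp_root_dimensions()) {
  if (is.character(case)) case <- bp_load_case(case)
  areas <- trunk_areas(dims)
  p_computed <- applied_pressure(case, dims)
  data.frame(
    trunk = names(areas),
    area_mm2 = unname(areas),
    pressure_published_MPa = case$applied_pressure,
    pressure_computed_MPa = p_computed,
    force_N = unname(trunk_force(p_computed, areas)),
    row.names = NULL
  )
}
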