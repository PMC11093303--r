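#' @importFrom stats setNames
NULL

ROOT_IDS <- c("C5", "C6", "C7", "C8", "T1")
TRUNK_IDS <- c("upper", "middle", "lower")

#' Average infant brachial plexus root dimensions
#'
#' Bundled average dimensions of the five brachial plexus nerve roots (C5-T1)
#' of human neonates, measured during primary reconstructive surgery and
#' averaged over 23 infants. All values are in millimetres. The cranial-caudal
#' diameter is the in-plane strip width of each root in the 2D model; the
#' transverse diameter is the out-of-plane axis used (together with the
#' cranial-caudal one) to estimate elliptical cross-sectional areas. The three
#' length columns are consecutive segments along each root: spinal cord to
#' dorsal root ganglion (DRG), DRG to end of the bony foramen, and foramen to
#' trunk formation. T1 has no DRG-to-foramen segment (recorded as `NA`).
#'
#' @return A `data.frame` with one row per root and columns `root`,
#'   `d_cranial_caudal`, `d_transverse`, `len_spinal_to_drg`,
#'   `len_drg_to_foramen`, `len_foramen_to_trunk` (all mm).
#' @examples
#' dims <- bp_root_dimensions()
#' root_path_lengths(dims)  # C5 = 30.5 mm, ... T1 = 13.5 mm
#' @export
bp_root_dimensions <- function() {
  data.frame(
    root = ROOT_IDS,
    d_cranial_caudal = c(3.0, 3.1, 3.8, 2.7, 2.5),
    d_transverse = c(1.1, 1.3, 1.6, 1.4, 1.4),
    len_spinal_to_drg = c(7.5, 7.5, 7.5, 7.5, 7.5),
    len_drg_to_foramen = c(9.0, 8.0, 7.0, 5.5, NA_real_),
    len_foramen_to_trunk = c(14.0, 15.5, 19.0, 7.0, 6.0),
    stringsAsFactors = FALSE
  )
}

#' Total root path lengths (cord surface to trunk formation)
#'
#' Sums the consecutive segment lengths of each root; missing segments (the
#' T1 DRG-to-foramen entry) contribute zero.
#'
#' @param dims Root dimension table as from [bp_root_dimensions()].
#' @return Named numeric vector of per-root path lengths in mm.
#' @export
root_path_lengths <- function(dims = bp_root_dimensions()) {
  validate_root_dimensions(dims)
  len <- rowSums(cbind(dims$len_spinal_to_drg, dims$len_drg_to_foramen,
                       dims$len_foramen_to_trunk), na.rm = TRUE)
  setNames(len, dims$root)
}

validate_root_dimensions <- function(dims) {
  stopifnot(is.data.frame(dims))
  need <- c("root", "d_cranial_caudal", "d_transverse", "len_spinal_to_drg",
            "len_drg_to_foramen", "len_foramen_to_trunk")
  missing_cols <- setdiff(need, names(dims))
  if (length(missing_cols)) {
    stop("root dimension table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!identical(dims$root, ROOT_IDS)) {
    stop("root dimension table must have rows C5, C6, C7, C8, T1 in order")
  }
  num <- as.matrix(dims[, setdiff(need, "root")])
  if (any(!is.na(num) & num <= 0)) {
    stop("all root dimensions and segment lengths must be strictly positive")
  }
  invisible(dims)
}

#' Loading-rate material and load cases
#'
#' The two bundled loading cases for the plexus model: a quasistatic stretch
#' (case 1, 0.01 mm/s) and a dynamic stretch (case 2, 10 mm/s). Each case
#' carries the loading rate, the experimentally measured single-root rupture
#' load, the load multiplier (the applied tensile force is 5x the rupture
#' load), the loading-rate-dependent Young's modulus and Poisson's ratio from
#' neonatal piglet tests, and the resulting uniform pressure applied to the
#' distal face of each trunk. `applied_pressure` stores the published applied
#' value; [applied_pressure()] recomputes it from the root areas as a
#' cross-check (agreement within 0.2%).
#'
#' @param case `"case1"` or `"case2"`.
#' @return An object of class `bp_load_case`: a list with fields `case_id`,
#'   `loading_rate` (mm/s), `rupture_load` (N), `load_multiplier`,
#'   `youngs_modulus` (MPa), `poisson_ratio`, `applied_pressure` (MPa).
#' @examples
#' bp_load_case("case1")$applied_pressure  # 0.332 MPa
#' @export
bp_load_case <- function(case = c("case1", "case2")) {
  case <- match.arg(case)
  tab <- list(
    case1 = list(case_id = "case1", loading_rate = 0.01, rupture_load = 1.08,
                 load_multiplier = 5, youngs_modulus = 1.48,
                 poisson_ratio = 0.4, applied_pressure = 0.332),
    case2 = list(case_id = "case2", loading_rate = 10, rupture_load = 2.12,
                 load_multiplier = 5, youngs_modulus = 2.02,
                 poisson_ratio = 0.4, applied_pressure = 0.653)
  )
  structure(tab[[case]], class = "bp_load_case")
}

#' @export
print.bp_load_case <- function(x, ...) {
  cat(sprintf(
    "<bp_load_case %s> rate %g mm/s, rupture load %g N (x%g), E = %g MPa, nu = %g, p = %g MPa\n",
    x$case_id, x$loading_rate, x$rupture_load, x$load_multiplier,
    x$youngs_modulus, x$poisson_ratio, x$applied_pressure))
  invisible(x)
}

#' Default trunk lengths (trunk formation to distal face)
#'
#' Trunk segment lengths consistent with the published total path lengths
#' (cord surface to distal trunk face: upper 41.4, middle 38.3, lower 30.8 mm)
#' minus the per-root path sums, measured along the representative member
#' root of each trunk (C5 for the upper trunk, C7 middle, C8 lower):
#' upper 41.4 - 30.5 = 10.9, middle 38.3 - 33.5 = 4.8,
#' lower 30.8 - 20.0 = 10.8 mm.
#'
#' @return Named numeric vector (mm) for trunks `upper`, `middle`, `lower`.
#' @export
bp_trunk_lengths <- function() {
  c(upper = 10.9, middle = 4.8, lower = 10.8)
}

#' Representative member root of each trunk
#'
#' The member root along which trunk path lengths and strains are reported:
#' C5 for the upper trunk, C7 for the middle, C8 for the lower.
#'
#' @return Named character vector keyed by trunk.
#' @export
trunk_representative_root <- function() {
  c(upper = "C5", middle = "C7", lower = "C8")
}

trunk_members <- function() {
  list(upper = c("C5", "C6"), middle = "C7", lower = c("C8", "T1"))
}

#' Default caudal kink of the middle trunk
#'
#' Angle (degrees) between the middle trunk's axis and the C7 root direction.
#' Like the baseline root angles, this is a reconstructed calibration value
#' (the bend of the middle trunk toward the confluence of the plexus is
#' visible in the source anatomy but its angle is not printed).
#'
#' @return A single angle in degrees.
#' @export
bp_middle_trunk_kink <- function() 31
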