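# Geometry conventions: consistent mm/N/MPa unit system. The spinal cord axis
# is the y axis with +y pointing caudally (so C5 attaches at the smallest y);
# roots extend laterally in +x. A root angle theta_i is measured between the
# root centerline and the caudal cord direction (+y): theta = 90 deg is
# perpendicular to the cord, theta < 90 slopes caudally.

deg2rad <- function(d) d * pi / 180

root_direction <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  c(sin(t), cos(t))
}

direction_angle <- function(v) {
  # angle (deg) between a direction and the caudal cord axis (+y)
  atan2(v[1], v[2]) * 180 / pi
}

vec_norm <- function(v) sqrt(sum(v^2))

#' Spinal cord parameters for the 2D plexus model
#'
#' The cord is modelled as a vertical strip of tissue with the five nerve
#' roots attached along its lateral (x = 0) edge. The source anatomy tables
#' do not include cord dimensions, so the width and the C5-T1 attachment
#' spacing are model assumptions recorded here (and in the bundled config):
#' a 7 mm wide cord with root attachment centres spaced over about 20 mm.
#' Attachment positions are axial coordinates (mm, increasing cranial to
#' caudal, i.e. C5 to T1).
#'
#' @param width Cord strip width (mm).
#' @param attachment_y Named numeric vector of root attachment centres (mm),
#'   strictly increasing from C5 to T1, all positive.
#' @param length Total cord length (mm); must exceed the caudal-most
#'   attachment.
#' @return A list of class `bp_cord_parameters`.
#' @export
bp_cord_parameters <- function(width = 7,
                               attachment_y = c(C5 = 4.3, C6 = 8.8, C7 = 13.5,
                                                C8 = 19.6, T1 = 26.2),
                               length = 30.2) {
  stopifnot(width > 0, length > 0)
  if (!identical(names(attachment_y), ROOT_IDS)) {
    stop("attachment_y must be named C5..T1 in order")
  }
  if (any(attachment_y <= 0) || any(diff(attachment_y) <= 0)) {
    stop("attachment positions must be positive and strictly increasing from C5 to T1")
  }
  if (max(attachment_y) >= length) {
    stop("cord length must exceed the caudal-most attachment position")
  }
  structure(list(width = width, attachment_y = attachment_y, length = length),
            class = "bp_cord_parameters")
}

#' Bundled default nerve-root angles
#'
#' Baseline angles (degrees, between each root centerline and the caudal cord
#' direction; 90 is perpendicular to the cord) are not published for the
#' source anatomy. These defaults were reconstructed during model calibration
#' so that (a) the published total path lengths from cord surface to distal
#' trunk face hold exactly (they do for any angles, since segment lengths are
#' preserved) and (b) the baseline quasistatic junction-stress profile
#' approximates the published one (C5 about 0.246 MPa, highest stresses at
#' C5/C6). They are calibration artifacts, not measurements.
#'
#' @return Named numeric vector of angles in degrees (C5..T1).
#' @export
bp_default_angles <- function() {
  c(C5 = 73.85, C6 = 77.4, C7 = 50, C8 = 37.5, T1 = 49)
}

#' Nominal trunk strip widths under area conservation
#'
#' Tissue cross-sectional area is conserved as roots combine into trunks; the
#' trunk's elliptical area equals the summed member areas and its transverse
#' diameter is taken as the mean member transverse diameter, so the in-plane
#' trunk width is `sum(member areas) / (pi/4 * mean(member d_t))`. When the
#' members share a transverse diameter this reduces exactly to the sum of the
#' member cranial-caudal widths (middle trunk 3.8 mm, lower 5.2 mm); the
#' upper trunk comes to 6.108 mm.
#'
#' @inheritParams root_areas
#' @return Named numeric vector of trunk widths (mm).
#' @export
trunk_widths <- function(dims = bp_root_dimensions()) {
  a <- root_areas(dims)
  dt <- stats::setNames(dims$d_transverse, dims$root)
  vapply(trunk_members(), function(m) sum(a[m]) / (pi / 4 * mean(dt[m])),
         numeric(1))
}

# Nominal per-member share of a trunk's proximal face, proportional to the
# member cranial-caudal widths.
member_subwidths <- function(dims = bp_root_dimensions()) {
  w <- trunk_widths(dims)
  dcc <- stats::setNames(dims$d_cranial_caudal, dims$root)
  members <- trunk_members()
  out <- list()
  for (tr in names(members)) {
    m <- members[[tr]]
    out[[tr]] <- stats::setNames(w[[tr]] * dcc[m] / sum(dcc[m]), m)
  }
  out
}

#' Build the baseline 2D plexus geometry
#'
#' Constructs the planar model: a rectangular cord strip, five straight root
#' strips leaving the cord's lateral edge at the given angles with in-plane
#' width equal to each root's cranial-caudal diameter and centerline length
#' equal to its summed segment lengths, and three straight trunk strips
#' (upper = C5+C6, middle = C7, lower = C8+T1). Each trunk's proximal face is
#' the straight segment through its member-root endpoints, split between
#' members in proportion to their widths; the trunk extends perpendicular to
#' that face by the given trunk length. Total path length from the cord
#' surface to the distal trunk face along the representative root therefore
#' equals root path length + trunk length by construction.
#'
#' @param dims Root dimension table ([bp_root_dimensions()]).
#' @param cord Cord parameters ([bp_cord_parameters()]).
#' @param angles Named numeric vector of root angles in degrees, in
#'   (0, 180) exclusive ([bp_default_angles()]).
#' @param trunk_lengths Named numeric vector of trunk lengths in mm
#'   ([bp_trunk_lengths()]).
#' @param middle_trunk_kink Angle (degrees) by which the middle trunk's axis
#'   deviates caudally from the C7 direction, representing the bend of the
#'   trunk toward the confluence of the plexus. The two-root trunks get their
#'   axes from their member endpoints instead.
#' @return An object of class `plexus_geometry`.
#' @examples
#' geom <- build_plexus_geometry()
#' path_length(geom, "upper")  # 41.4 mm
#' @export
build_plexus_geometry <- function(dims = bp_root_dimensions(),
                                  cord = bp_cord_parameters(),
                                  angles = bp_default_angles(),
                                  trunk_lengths = bp_trunk_lengths(),
                                  middle_trunk_kink = bp_middle_trunk_kink()) {
  validate_root_dimensions(dims)
  if (!inherits(cord, "bp_cord_parameters")) cord <- do.call(bp_cord_parameters, cord)
  if (!identical(names(angles), ROOT_IDS)) {
    stop("angles must be a named vector C5..T1 in order")
  }
  if (any(angles <= 0 | angles >= 180)) {
    stop("root angles must lie strictly between 0 and 180 degrees")
  }
  if (!identical(names(trunk_lengths), TRUNK_IDS) || any(trunk_lengths <= 0)) {
    stop("trunk_lengths must be positive and named upper, middle, lower")
  }

  lens <- root_path_lengths(dims)
  dcc <- stats::setNames(dims$d_cranial_caudal, dims$root)
  subw <- member_subwidths(dims)
  members <- trunk_members()

  roots <- list()
  for (r in ROOT_IDS) {
    A <- c(0, cord$attachment_y[[r]])
    d <- root_direction(angles[[r]])
    hh <- dcc[[r]] / (2 * sin(deg2rad(angles[[r]])))
    roots[[r]] <- list(
      root = r, A = A, theta = angles[[r]], length = lens[[r]],
      width = dcc[[r]], E = A + lens[[r]] * d,
      prox = rbind(cranial = c(0, A[2] - hh), caudal = c(0, A[2] + hh)),
      half_height = hh
    )
  }

  # feasibility: proximal intervals inside the cord edge and pairwise disjoint
  iv <- t(vapply(roots, function(rt) rt$prox[, 2], numeric(2)))
  if (any(iv[, 1] <= 0) || any(iv[, 2] >= cord$length)) {
    stop("geometry infeasible: a root footprint extends beyond the cord ends")
  }
  for (k in seq_len(nrow(iv) - 1)) {
    if (iv[k + 1, 1] <= iv[k, 2]) {
      stop(sprintf(
        "geometry infeasible: root strips %s and %s overlap on the cord edge",
        ROOT_IDS[k], ROOT_IDS[k + 1]))
    }
  }

  trunks <- list()
  for (tr in TRUNK_IDS) {
    mem <- members[[tr]]
    s <- subw[[tr]]
    if (length(mem) == 2) {
      Ec <- roots[[mem[1]]]$E
      Ek <- roots[[mem[2]]]$E
      D <- vec_norm(Ec - Ek)
      if (D < 1e-9) {
        stop(sprintf("geometry infeasible: %s trunk member endpoints coincide", tr))
      }
      m <- (Ec - Ek) / D                      # points toward the cranial member
      Fc <- Ec + (s[[1]] / 2) * m
      Fk <- Ek - (s[[2]] / 2) * m
      W <- vec_norm(Fc - Fk)
      split <- Fc - (W * s[[1]] / sum(s)) * m
      faces <- list(rbind(Fc, split), rbind(split, Fk))
      names(faces) <- mem
      mid_face <- (Fc + Fk) / 2
      mid_A <- (roots[[mem[1]]]$A + roots[[mem[2]]]$A) / 2
      t1 <- c(m[2], -m[1])
      axis <- if (sum(t1 * (mid_face - mid_A)) > 0) t1 else -t1
      dist <- rbind(cranial = Fc + trunk_lengths[[tr]] * axis,
                    caudal = Fk + trunk_lengths[[tr]] * axis)
    } else {
      rt <- roots[[mem]]
      d <- root_direction(rt$theta)
      m <- c(d[2], -d[1])                     # cranial perpendicular
      Fc <- rt$E + (s[[1]] / 2) * m
      Fk <- rt$E - (s[[1]] / 2) * m
      W <- vec_norm(Fc - Fk)
      faces <- stats::setNames(list(rbind(Fc, Fk)), mem)
      # the middle trunk bends caudally toward the confluence of the plexus;
      # its axis deviates from the C7 direction by a configurable kink, and
      # its distal face is perpendicular to the trunk axis (the applied load
      # acts normal to that face), so its distal width is the projection of
      # the proximal face onto the trunk cross-section
      axis <- root_direction(rt$theta + middle_trunk_kink)
      if (abs(middle_trunk_kink) >= 90) {
        stop("geometry infeasible: middle trunk kink must be below 90 degrees")
      }
      mt <- c(axis[2], -axis[1])
      if (sum((Fc - Fk) * mt) < 0) mt <- -mt
      Wd <- W * cos(deg2rad(middle_trunk_kink))
      mid_dist <- rt$E + trunk_lengths[[tr]] * axis
      dist <- rbind(cranial = mid_dist + (Wd / 2) * mt,
                    caudal = mid_dist - (Wd / 2) * mt)
    }
    Lt <- trunk_lengths[[tr]]
    trunks[[tr]] <- list(
      trunk = tr, members = mem, width = W, length = Lt,
      face = rbind(cranial = Fc, caudal = Fk),
      member_faces = faces, axis = axis,
      dist = dist,
      representative = trunk_representative_root()[[tr]]
    )
    for (mm in mem) roots[[mm]]$dist <- faces[[mm]]
    for (mm in mem) roots[[mm]]$trunk <- tr
  }

  geom <- structure(list(
    dims = dims, cord = cord, angles = angles, trunk_lengths = trunk_lengths,
    middle_trunk_kink = middle_trunk_kink, roots = roots, trunks = trunks
  ), class = "plexus_geometry")
  validate_plexus_geometry(geom)
  geom
}

root_quad <- function(rt) {
  # corner order: prox cranial, dist cranial, dist caudal, prox caudal
  rbind(rt$prox["cranial", ], rt$dist[1, ], rt$dist[2, ], rt$prox["caudal", ])
}

trunk_quad <- function(tk) {
  rbind(tk$face["cranial", ], tk$dist["cranial", ],
        tk$dist["caudal", ], tk$face["caudal", ])
}

cord_quad <- function(cord) {
  rbind(c(-cord$width, 0), c(0, 0), c(0, cord$length), c(-cord$width, cord$length))
}

quad_signed_area <- function(q) {
  x <- q[, 1]; y <- q[, 2]
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

quad_is_convex <- function(q) {
  cr <- numeric(4)
  for (i in 1:4) {
    a <- q[i, ]; b <- q[i %% 4 + 1, ]; c <- q[(i + 1) %% 4 + 1, ]
    cr[i] <- (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
  }
  all(cr > 0) || all(cr < 0)
}

validate_plexus_geometry <- function(geom) {
  for (r in ROOT_IDS) {
    q <- root_quad(geom$roots[[r]])
    if (!quad_is_convex(q) || abs(quad_signed_area(q)) < 1e-9) {
      stop(sprintf("geometry infeasible: root %s strip is degenerate or non-convex", r))
    }
  }
  for (tr in TRUNK_IDS) {
    q <- trunk_quad(geom$trunks[[tr]])
    if (!quad_is_convex(q) || abs(quad_signed_area(q)) < 1e-9) {
      stop(sprintf("geometry infeasible: %s trunk strip is degenerate or non-convex", tr))
    }
  }
  invisible(geom)
}

#' Perturb all nerve-root angles by a fixed delta
#'
#' Rotates every root centerline about its cord junction by `delta` degrees
#' (positive opens the angle toward the caudal axis convention used here:
#' theta + delta), preserving every root's centerline length exactly, and
#' re-attaches the trunks to the displaced root endpoints (the trunk proximal
#' face follows the member endpoints, so the trunk width varies slightly with
#' the perturbation while its length is preserved).
#'
#' @param geom A `plexus_geometry`.
#' @param delta Angle change in degrees; either a single number applied to
#'   all five roots or a named per-root vector. Must lie within
#'   `max_delta` in absolute value.
#' @param max_delta Safe perturbation range (degrees, default 10).
#' @return A new `plexus_geometry`.
#' @export
perturb_root_angles <- function(geom, delta, max_delta = 10) {
  stopifnot(inherits(geom, "plexus_geometry"))
  if (length(delta) == 1 && is.null(names(delta))) {
    delta <- stats::setNames(rep(delta, 5), ROOT_IDS)
  }
  if (!all(ROOT_IDS %in% names(delta))) {
    stop("delta must be a scalar or named per-root (C5..T1)")
  }
  delta <- delta[ROOT_IDS]
  if (any(abs(delta) > max_delta)) {
    stop(sprintf("angle perturbation exceeds the safe range of +/-%g degrees", max_delta))
  }
  build_plexus_geometry(geom$dims, geom$cord, geom$angles + delta,
                        geom$trunk_lengths, geom$middle_trunk_kink)
}

#' Path length from cord surface to distal trunk face
#'
#' Arc length of the representative centerline (C5 for the upper trunk, C7
#' middle, C8 lower): the member root centerline from its cord junction to
#' its endpoint plus the trunk segment to the distal face, measured from the
#' stored coordinates.
#'
#' @param geom A `plexus_geometry`.
#' @param trunk `"upper"`, `"middle"` or `"lower"`.
#' @return Length in mm.
#' @examples
#' g <- build_plexus_geometry()
#' c(path_length(g, "upper"), path_length(g, "middle"), path_length(g, "lower"))
#' @export
path_length <- function(geom, trunk = TRUNK_IDS) {
  stopifnot(inherits(geom, "plexus_geometry"))
  trunk <- match.arg(trunk)
  tk <- geom$trunks[[trunk]]
  rt <- geom$roots[[tk$representative]]
  root_len <- vec_norm(rt$E - rt$A)
  trunk_len <- vec_norm((tk$dist["cranial", ] + tk$dist["caudal", ]) / 2 -
                        (tk$face["cranial", ] + tk$face["caudal", ]) / 2)
  root_len + trunk_len
}

#' @export
print.plexus_geometry <- function(x, ...) {
  cat("<plexus_geometry>\n")
  cat(sprintf("  cord: %g x %g mm; roots C5..T1 at y = %s mm\n",
              x$cord$width, x$cord$length,
              paste(signif(x$cord$attachment_y, 4), collapse = ", ")))
  cat(sprintf("  root angles (deg): %s\n",
              paste(sprintf("%s=%.2f", ROOT_IDS, x$angles), collapse = ", ")))
  for (tr in TRUNK_IDS) {
    cat(sprintf("  %s trunk: width %.3f mm, length %.1f mm, path %.1f mm\n",
                tr, x$trunks[[tr]]$width, x$trunks[[tr]]$length,
                path_length(x, tr)))
  }
  invisible(x)
}

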