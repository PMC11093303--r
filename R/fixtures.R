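# Analytic verification fixtures: every pipeline stage is testable with no
# external input. Each fixture bundles mesh + material + boundary conditions
# with the closed-form fields it must reproduce.

#' Uniform-bar tension fixture
#'
#' Rectangular bar `[0, L] x [0, W]` under a uniform end traction `p` on the
#' right edge. With `clamped = FALSE` the left edge is an axial roller
#' (`ux = 0`, one corner pinned in y), for which the exact solution is a
#' uniform uniaxial stress state for any Poisson ratio:
#' `sxx = p`, `syy = txy = 0`, end displacement `p * L / E`.
#' With `clamped = TRUE` the left edge is fully clamped, which for `nu > 0`
#' constrains lateral contraction and makes the problem non-polynomial —
#' used for mesh-convergence checks.
#'
#' @param L,W Bar dimensions (mm).
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @param p End traction (MPa).
#' @param h Element size (mm).
#' @param clamped Clamp the left edge instead of the axial roller.
#' @return An `analytic_fixture`: list with `mesh`, `material`, `bcs`,
#'   `expected` (list `sxx`, `syy`, `txy`, `u_end`) and `tol`.
#' @examples
#' fx <- make_bar_fixture()
#' fx$expected$u_end  # p * L / E
#' @export
make_bar_fixture <- function(L = 41.4, W = 3, E = 1.48, nu = 0, p = 0.332,
                             h = 1, clamped = FALSE) {
  stopifnot(L > 0, W > 0, h > 0)
  mesh <- rect_mesh(L, W, h = h)
  left_nodes <- edge_set_nodes(mesh, "left")
  corner <- left_nodes[which.min(mesh$nodes[left_nodes, 2])]
  fixed <- if (clamped) {
    list(list(nodes = left_nodes, ux = 0, uy = 0))
  } else {
    list(list(nodes = left_nodes, ux = 0, uy = NA),
         list(nodes = corner, ux = NA, uy = 0))
  }
  bcs <- boundary_conditions(
    fixed = fixed,
    tractions = list(list(edges = mesh$edge_sets$right, pressure = p))
  )
  structure(list(
    mesh = mesh, material = material(E, nu), bcs = bcs,
    expected = list(sxx = p, syy = 0, txy = 0, u_end = p * L / E),
    tol = 1e-8, clamped = clamped
  ), class = "analytic_fixture")
}

#' Distorted-patch constant-stress fixture
#'
#' The classic patch test: a unit square split into five quadrilaterals by an
#' interior quadrilateral whose corners are randomly perturbed (seeded), with
#' a linear displacement field `u = a + G x` prescribed on the boundary
#' nodes. A correct element passes the solve with the interior nodes matching
#' the linear field and a constant stress `D * strain(G)` in every element.
#'
#' @param seed Integer seed for the interior-node distortion.
#' @param mat Material.
#' @param grad 2 x 2 displacement-gradient matrix of the imposed field
#'   (default a mixed stretch + shear).
#' @return An `analytic_fixture` with `expected$stress` (sxx, syy, txy),
#'   `expected$u_fun(x, y)` and `tol`.
#' @export
make_patch_fixture <- function(seed = 1, mat = material(1.48, 0.4),
                               grad = matrix(c(2e-3, 5e-4, 8e-4, -1e-3), 2, 2)) {
  set.seed(seed)
  outer4 <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  inner0 <- rbind(c(0.3, 0.3), c(0.7, 0.25), c(0.75, 0.7), c(0.25, 0.75))
  inner <- inner0 + matrix(stats::runif(8, -0.05, 0.05), 4, 2)
  nodes <- rbind(outer4, inner)
  elems <- rbind(
    c(1L, 2L, 6L, 5L),
    c(2L, 3L, 7L, 6L),
    c(3L, 4L, 8L, 7L),
    c(4L, 1L, 5L, 8L),
    c(5L, 6L, 7L, 8L)
  )
  for (e in seq_len(nrow(elems))) {
    q <- nodes[elems[e, ], ]
    if (quad_signed_area(q) < 0) elems[e, ] <- elems[e, c(1, 4, 3, 2)]
  }
  mesh <- structure(list(nodes = nodes, elems = elems,
                         region = rep("patch", nrow(elems)),
                         edge_sets = list(), root_axes = NULL,
                         h_max = 1, h_min = 0.25),
                    class = "plexus_mesh")
  u_fun <- function(x, y) cbind(grad[1, 1] * x + grad[1, 2] * y,
                                grad[2, 1] * x + grad[2, 2] * y)
  ub <- u_fun(nodes[1:4, 1], nodes[1:4, 2])
  bcs <- boundary_conditions(fixed = list(
    list(nodes = 1:4, ux = ub[, 1], uy = ub[, 2])
  ))
  eps <- c(grad[1, 1], grad[2, 2], grad[1, 2] + grad[2, 1])
  sig <- as.numeric(plane_stress_D(mat$E, mat$nu) %*% eps)
  structure(list(
    mesh = mesh, material = mat, bcs = bcs,
    expected = list(stress = stats::setNames(sig, c("sxx", "syy", "txy")),
                    u_fun = u_fun, interior = 5:8),
    tol = 1e-10
  ), class = "analytic_fixture")
}

#' Randomised plexus geometry for property tests
#'
#' Draws a feasible plexus geometry by jittering the baseline root angles and
#' segment-sum lengths. Deterministic for a fixed seed; infeasible draws are
#' resampled (up to `max_tries`). Jitters are test instruments emulating
#' anatomical variability, not population models.
#'
#' @param seed Integer seed.
#' @param angle_jitter Half-width of the uniform angle jitter (degrees).
#' @param length_jitter_fraction Half-width of the uniform relative jitter on
#'   root path lengths.
#' @param config Base configuration.
#' @param max_tries Resampling attempts before failing.
#' @return A `plexus_geometry`.
#' @export
random_plexus <- function(seed, angle_jitter = 6, length_jitter_fraction = 0,
                          config = default_plexus_config(), max_tries = 25) {
  set.seed(seed)
  for (k in seq_len(max_tries)) {
    angles <- config$angles + stats::runif(5, -angle_jitter, angle_jitter)
    dims <- config$dims
    if (length_jitter_fraction > 0) {
      fac <- 1 + stats::runif(5, -length_jitter_fraction, length_jitter_fraction)
      for (col in c("len_spinal_to_drg", "len_drg_to_foramen",
                    "len_foramen_to_trunk")) {
        dims[[col]] <- dims[[col]] * fac
      }
    }
    g <- tryCatch(
      build_plexus_geometry(dims, config$cord, angles, config$trunk_lengths),
      error = function(e) NULL)
    if (!is.null(g)) return(g)
  }
  stop(sprintf("random_plexus(): no feasible geometry after %d draws", max_tries))
}

#' Solve an analytic fixture
#'
#' @param fx An `analytic_fixture`.
#' @param scheme Quad integration scheme.
#' @return An `fe_solution`.
#' @export
solve_fixture <- function(fx, scheme = "full_2x2") {
  solve_elasticity(fx$mesh, fx$material, fx$bcs, scheme = scheme)
}
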