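# Plane-stress linear elasticity on bilinear quadrilaterals (Q4) and
# constant-strain triangles (T3). Consistent units: mm, N, MPa; default
# unit thickness so edge pressures (MPa) become line tractions (N/mm).

#' Plane-stress material
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio (0 <= nu < 0.5).
#' @param thickness Plane-stress thickness (mm), default 1.
#' @return A `material` list.
#' @export
material <- function(E, nu, thickness = 1) {
  stopifnot(E > 0, nu >= 0, nu < 0.5, thickness > 0)
  structure(list(E = E, nu = nu, thickness = thickness), class = "material")
}

#' @rdname material
#' @param case A `bp_load_case`.
#' @export
case_material <- function(case) {
  if (is.character(case)) case <- bp_load_case(case)
  material(case$youngs_modulus, case$poisson_ratio)
}

plane_stress_D <- function(E, nu) {
  E / (1 - nu^2) * matrix(c(1, nu, 0,
                            nu, 1, 0,
                            0, 0, (1 - nu) / 2), 3, 3, byrow = TRUE)
}

# bilinear shape function derivatives and Jacobian at (xi, eta)
quad_jacobian <- function(xy, xi, eta) {
  dN <- matrix(c(-(1 - eta), -(1 - xi),
                  (1 - eta), -(1 + xi),
                  (1 + eta),  (1 + xi),
                 -(1 + eta),  (1 - xi)) / 4, 4, 2, byrow = TRUE)
  J <- t(dN) %*% xy
  detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  list(dN = dN, J = J, detJ = detJ)
}

quad_B <- function(xy, xi, eta) {
  jac <- quad_jacobian(xy, xi, eta)
  if (jac$detJ <= 0) stop("degenerate quadrilateral (non-positive Jacobian)")
  dNxy <- jac$dN %*% solve(t(jac$J))  # 4 x 2: dN/dx, dN/dy
  B <- matrix(0, 3, 8)
  B[1, seq(1, 8, 2)] <- dNxy[, 1]
  B[2, seq(2, 8, 2)] <- dNxy[, 2]
  B[3, seq(1, 8, 2)] <- dNxy[, 2]
  B[3, seq(2, 8, 2)] <- dNxy[, 1]
  list(B = B, detJ = jac$detJ)
}

#' Element stiffness of a 4-node plane-stress quadrilateral
#'
#' Bilinear isoparametric element. `full_2x2` uses 2 x 2 Gauss quadrature
#' (three rigid-body zero-energy modes). `reduced_1pt` uses single-point
#' quadrature plus stiffness-type hourglass stabilisation of the two
#' zero-energy hourglass modes; the stabilisation coefficient `hg_coef`
#' scales a rank-2 correction built from the hourglass base vector.
#'
#' @param xy 4 x 2 matrix of corner coordinates (counter-clockwise).
#' @param mat A [material()].
#' @param scheme `"full_2x2"` or `"reduced_1pt"`.
#' @param hg_coef Hourglass stabilisation coefficient (reduced scheme only).
#' @return 8 x 8 symmetric stiffness matrix (N/mm), dofs ordered
#'   (u1, v1, ..., u4, v4).
#' @export
element_stiffness_quad <- function(xy, mat, scheme = c("full_2x2", "reduced_1pt"),
                                   hg_coef = 0.05) {
  scheme <- match.arg(scheme)
  D <- plane_stress_D(mat$E, mat$nu)
  K <- matrix(0, 8, 8)
  if (scheme == "full_2x2") {
    g <- 1 / sqrt(3)
    for (xi in c(-g, g)) for (eta in c(-g, g)) {
      b <- quad_B(xy, xi, eta)
      K <- K + t(b$B) %*% D %*% b$B * b$detJ * mat$thickness
    }
  } else {
    b <- quad_B(xy, 0, 0)
    K <- t(b$B) %*% D %*% b$B * (4 * b$detJ) * mat$thickness
    # hourglass stabilisation (Flanagan-Belytschko, stiffness form)
    h <- c(1, -1, 1, -1)
    dNxy <- quad_jacobian(xy, 0, 0)$dN %*% solve(t(quad_jacobian(xy, 0, 0)$J))
    gam <- h - dNxy %*% (t(xy) %*% h)  # hourglass shape vector (4)
    gam <- as.numeric(gam)
    A <- 4 * b$detJ
    k_hg <- hg_coef * mat$E * mat$thickness * A * sum(dNxy^2)
    Ghg <- matrix(0, 8, 8)
    Ghg[seq(1, 8, 2), seq(1, 8, 2)] <- gam %o% gam
    Ghg[seq(2, 8, 2), seq(2, 8, 2)] <- gam %o% gam
    K <- K + k_hg * Ghg
  }
  (K + t(K)) / 2
}

#' Element stiffness of a 3-node constant-strain triangle
#'
#' @param xy 3 x 2 matrix of corner coordinates (counter-clockwise).
#' @inheritParams element_stiffness_quad
#' @return 6 x 6 symmetric stiffness matrix (N/mm).
#' @export
element_stiffness_tri <- function(xy, mat) {
  A <- triangle_area(xy)
  if (A <= 0) stop("degenerate triangle (non-positive area)")
  b <- tri_B(xy)
  D <- plane_stress_D(mat$E, mat$nu)
  K <- t(b) %*% D %*% b * A * mat$thickness
  (K + t(K)) / 2
}

tri_B <- function(xy) {
  A2 <- 2 * triangle_area(xy)
  x <- xy[, 1]; y <- xy[, 2]
  bvec <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2]) / A2
  cvec <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1]) / A2
  B <- matrix(0, 3, 6)
  B[1, seq(1, 6, 2)] <- bvec
  B[2, seq(2, 6, 2)] <- cvec
  B[3, seq(1, 6, 2)] <- cvec
  B[3, seq(2, 6, 2)] <- bvec
  B
}

#' Von Mises equivalent stress in plane stress
#'
#' `sqrt(sxx^2 - sxx*syy + syy^2 + 3*txy^2)`; non-negative by construction.
#'
#' @param sxx,syy,txy In-plane stress components (MPa). Vectorised.
#' @return Equivalent stress (MPa).
#' @examples
#' von_mises_plane_stress(1, -1, 0)  # sqrt(3)
#' @export
von_mises_plane_stress <- function(sxx, syy, txy) {
  stopifnot(all(is.finite(sxx)), all(is.finite(syy)), all(is.finite(txy)))
  sqrt(pmax(0, sxx^2 - sxx * syy + syy^2 + 3 * txy^2))
}

#' Boundary conditions for a plane-stress solve
#'
#' Three constraint kinds: `fixed` node sets with prescribed displacement
#' components (`NA` leaves a component free, so a fully clamped edge uses
#' `ux = 0, uy = 0`), `guided` node sets constrained to move only along a
#' given axial direction (the transverse component is fixed; used for the
#' symmetry-type supports on the outer nerve edges), and `tractions`: edge
#' sets loaded by a uniform pressure acting along the outward normal
#' (positive = pulling outward).
#'
#' @param fixed List of `list(nodes =, ux =, uy =)` entries; `ux`/`uy` may be
#'   scalars, per-node vectors, or `NA`.
#' @param guided List of `list(nodes =, axis =)` entries; `axis` is the unit
#'   direction left free.
#' @param tractions List of `list(edges =, pressure =)` entries; `edges` is a
#'   k x 2 node-index matrix on the boundary.
#' @return A `boundary_conditions` object.
#' @export
boundary_conditions <- function(fixed = list(), guided = list(),
                                tractions = list()) {
  structure(list(fixed = fixed, guided = guided, tractions = tractions),
            class = "boundary_conditions")
}

#' Assemble the global stiffness matrix
#'
#' @param mesh A `plexus_mesh`.
#' @param mat A [material()].
#' @param scheme Integration scheme for quads, see [element_stiffness_quad()].
#' @return Sparse symmetric `dgCMatrix` of size (2n x 2n).
#' @export
assemble_stiffness <- function(mesh, mat, scheme = "full_2x2") {
  ne <- nrow(mesh$elems)
  ii <- vector("list", ne); jj <- vector("list", ne); xx <- vector("list", ne)
  for (e in seq_len(ne)) {
    en <- mesh$elems[e, ]
    tri <- is.na(en[4])
    en <- en[!is.na(en)]
    xy <- mesh$nodes[en, , drop = FALSE]
    Ke <- if (tri) element_stiffness_tri(xy, mat)
          else element_stiffness_quad(xy, mat, scheme)
    dofs <- as.vector(rbind(2L * en - 1L, 2L * en))
    nd <- length(dofs)
    ii[[e]] <- rep(dofs, times = nd)
    jj[[e]] <- rep(dofs, each = nd)
    xx[[e]] <- as.vector(Ke)
  }
  n2 <- 2L * nrow(mesh$nodes)
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n2, n2))
}

# consistent nodal loads for a uniform pressure on boundary edges, acting
# along each edge's outward normal (away from the adjacent element centroid),
# or along a fixed direction if one is given
traction_loads <- function(mesh, edges, pressure, thickness = 1,
                           direction = NULL) {
  f <- numeric(2L * nrow(mesh$nodes))
  centroids <- element_centroids(mesh)
  emap <- edge_element_map(mesh)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    key <- paste(min(a, b), max(a, b))
    eid <- emap[[key]]
    if (is.null(eid)) stop("traction edge is not an element edge")
    pa <- mesh$nodes[a, ]; pb <- mesh$nodes[b, ]
    ev <- pb - pa
    len <- sqrt(sum(ev^2))
    if (is.null(direction)) {
      nrm <- c(ev[2], -ev[1]) / len
      mid <- (pa + pb) / 2
      if (sum(nrm * (mid - centroids[eid[1], ])) < 0) nrm <- -nrm
    } else {
      nrm <- direction / sqrt(sum(direction^2))
    }
    fe <- pressure * thickness * len / 2 * nrm
    f[c(2 * a - 1, 2 * a)] <- f[c(2 * a - 1, 2 * a)] + fe
    f[c(2 * b - 1, 2 * b)] <- f[c(2 * b - 1, 2 * b)] + fe
  }
  f
}

element_centroids <- function(mesh) {
  t(vapply(seq_len(nrow(mesh$elems)), function(e) {
    en <- mesh$elems[e, ]; en <- en[!is.na(en)]
    colMeans(mesh$nodes[en, , drop = FALSE])
  }, numeric(2)))
}

edge_element_map <- function(mesh) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (e in seq_len(nrow(mesh$elems))) {
    en <- mesh$elems[e, ]; en <- en[!is.na(en)]
    pairs <- cbind(en, c(en[-1], en[1]))
    for (k in seq_len(nrow(pairs))) {
      key <- paste(min(pairs[k, ]), max(pairs[k, ]))
      env[[key]] <- c(env[[key]], e)
    }
  }
  env
}

#' Assemble and solve the constrained plane-stress problem
#'
#' Assembles the global stiffness and consistent traction loads, applies the
#' fixed and guided constraints exactly (guided nodes are rotated into local
#' axial/transverse coordinates so the transverse component becomes a plain
#' fixed dof), and solves with a sparse Cholesky factorisation. Prescribed
#' non-zero displacements are supported (used by the patch test).
#'
#' @param mesh A `plexus_mesh`.
#' @param mat A [material()].
#' @param bcs A [boundary_conditions()].
#' @param scheme Quad integration scheme.
#' @return A list of class `fe_solution` with `u` (n x 2 nodal displacements,
#'   mm), `reactions` (n x 2, N), `residual` (relative global equilibrium
#'   residual), `f_applied`, and `stress` — a `stress_field` data.frame with
#'   per-element centroid stresses `sxx`, `syy`, `txy`, `vm` and the maximum
#'   integration-point von Mises `vm_max_gp` (MPa), plus `region`.
#' @export
solve_elasticity <- function(mesh, mat, bcs, scheme = "full_2x2") {
  n <- nrow(mesh$nodes)
  n2 <- 2L * n
  K <- assemble_stiffness(mesh, mat, scheme)
  f <- numeric(n2)
  for (tr in bcs$tractions) {
    f <- f + traction_loads(mesh, tr$edges, tr$pressure, mat$thickness,
                            tr$direction)
  }

  fixed_nodes_all <- unlist(lapply(bcs$fixed, `[[`, "nodes"))
  guided_nodes_all <- unlist(lapply(bcs$guided, `[[`, "nodes"))
  if (length(intersect(fixed_nodes_all, guided_nodes_all))) {
    stop("a node cannot be both fixed and guided")
  }

  # transformation for guided (skew) supports
  guided_nodes <- integer(0)
  Ti <- 1:n2; Tj <- 1:n2; Tx <- rep(1, n2)
  for (g in bcs$guided) {
    ax <- g$axis / sqrt(sum(g$axis^2))
    tv <- c(-ax[2], ax[1])
    for (nd in g$nodes) {
      d1 <- 2L * nd - 1L; d2 <- 2L * nd
      sel <- Ti %in% c(d1, d2) & Ti == Tj
      Tx[sel] <- 0
      Ti <- c(Ti, d1, d2, d1, d2)
      Tj <- c(Tj, d1, d1, d2, d2)
      Tx <- c(Tx, ax[1], ax[2], tv[1], tv[2])
    }
    guided_nodes <- c(guided_nodes, g$nodes)
  }
  has_guided <- length(guided_nodes) > 0
  if (has_guided) {
    keep <- Tx != 0
    T <- Matrix::sparseMatrix(i = Ti[keep], j = Tj[keep], x = Tx[keep],
                              dims = c(n2, n2))
    Kt <- Matrix::t(T) %*% K %*% T
    ft <- as.numeric(Matrix::t(T) %*% f)
  } else {
    T <- NULL; Kt <- K; ft <- f
  }

  # constrained dofs and prescribed values (in transformed coordinates)
  cons_dof <- integer(0); cons_val <- numeric(0)
  for (fx in bcs$fixed) {
    nn <- fx$nodes
    ux <- rep_len(if (is.null(fx$ux)) NA_real_ else fx$ux, length(nn))
    uy <- rep_len(if (is.null(fx$uy)) NA_real_ else fx$uy, length(nn))
    if (any(!is.na(ux))) {
      cons_dof <- c(cons_dof, 2L * nn[!is.na(ux)] - 1L)
      cons_val <- c(cons_val, ux[!is.na(ux)])
    }
    if (any(!is.na(uy))) {
      cons_dof <- c(cons_dof, 2L * nn[!is.na(uy)])
      cons_val <- c(cons_val, uy[!is.na(uy)])
    }
  }
  cons_dof <- c(cons_dof, 2L * guided_nodes)  # transverse (2nd local) dof
  cons_val <- c(cons_val, rep(0, length(guided_nodes)))
  if (anyDuplicated(cons_dof)) {
    dup <- duplicated(cons_dof)
    agree <- tapply(cons_val, cons_dof, function(v) diff(range(v)) < 1e-12)
    if (!all(agree)) stop("conflicting prescribed values on a constrained dof")
    cons_val <- cons_val[!dup]
    cons_dof <- cons_dof[!dup]
  }
  if (length(cons_dof) < 3) stop("insufficient constraints: rigid-body modes remain")

  free <- setdiff(seq_len(n2), cons_dof)
  ut <- numeric(n2)
  ut[cons_dof] <- cons_val
  rhs <- ft[free] - as.numeric(Kt[free, cons_dof, drop = FALSE] %*% cons_val)
  Kff <- Matrix::forceSymmetric(Kt[free, free])
  sol <- tryCatch(Matrix::solve(Kff, rhs),
                  error = function(e) stop("singular stiffness system: ",
                                           conditionMessage(e)))
  ut[free] <- as.numeric(sol)
  u_flat <- if (has_guided) as.numeric(T %*% ut) else ut

  r_flat <- as.numeric(K %*% u_flat - f)
  # reaction forces live on the constrained dofs (both components of guided
  # nodes carry the transverse reaction in global coordinates)
  cons_glob <- unique(c(setdiff(cons_dof, 2L * guided_nodes),
                        2L * guided_nodes - 1L, 2L * guided_nodes))
  reac_mask <- logical(n2)
  reac_mask[cons_glob] <- TRUE
  r_reac <- ifelse(reac_mask, r_flat, 0)
  applied <- c(sum(f[seq(1, n2, 2)]), sum(f[seq(2, n2, 2)]))
  reac <- c(sum(r_reac[seq(1, n2, 2)]), sum(r_reac[seq(2, n2, 2)]))
  denom <- sqrt(sum(applied^2))
  residual <- if (denom > 1e-12) sqrt(sum((reac + applied)^2)) / denom
              else sqrt(sum(reac^2))

  stress <- recover_stress(mesh, mat, u_flat)
  structure(list(
    u = matrix(u_flat, ncol = 2, byrow = TRUE),
    reactions = matrix(r_flat, ncol = 2, byrow = TRUE),
    residual = residual, f_applied = f, stress = stress
  ), class = "fe_solution")
}

recover_stress <- function(mesh, mat, u_flat) {
  D <- plane_stress_D(mat$E, mat$nu)
  ne <- nrow(mesh$elems)
  out <- matrix(0, ne, 5)
  g <- 1 / sqrt(3)
  for (e in seq_len(ne)) {
    en <- mesh$elems[e, ]
    tri <- is.na(en[4])
    en <- en[!is.na(en)]
    xy <- mesh$nodes[en, , drop = FALSE]
    ue <- u_flat[as.vector(rbind(2L * en - 1L, 2L * en))]
    if (tri) {
      s <- as.numeric(D %*% (tri_B(xy) %*% ue))
      vmg <- von_mises_plane_stress(s[1], s[2], s[3])
      out[e, ] <- c(s, vmg, vmg)
    } else {
      sc <- as.numeric(D %*% (quad_B(xy, 0, 0)$B %*% ue))
      vm_gp <- 0
      for (xi in c(-g, g)) for (eta in c(-g, g)) {
        s <- as.numeric(D %*% (quad_B(xy, xi, eta)$B %*% ue))
        vm_gp <- max(vm_gp, von_mises_plane_stress(s[1], s[2], s[3]))
      }
      out[e, ] <- c(sc, von_mises_plane_stress(sc[1], sc[2], sc[3]), vm_gp)
    }
  }
  structure(data.frame(
    element = seq_len(ne), region = mesh$region,
    sxx = out[, 1], syy = out[, 2], txy = out[, 3],
    vm = out[, 4], vm_max_gp = out[, 5]
  ), class = c("stress_field", "data.frame"))
}

#' Standard plexus boundary conditions and loads
#'
#' The cord midline is fully clamped (encastre), and the given pressure acts
#' as a uniform outward traction on the three distal trunk faces. The
#' guided (symmetry-type) supports on the nerves — which fix the displacement
#' component transverse to the local nerve axis so a nerve can only stretch
#' along itself, in the plane of the model — come in three modes:
#' `"all_nerves"` (default) guides the superior and inferior side edges of
#' all five root strips, `"outer"` guides only the superior side of C5 and
#' the inferior side of T1 (the free outer boundary of the fan), and
#' `"none"` applies no guiding. Nodes shared between two differently-guided
#' sides (the trunk-face split points) are left unguided.
#'
#' @param mesh A `plexus_mesh` from [generate_mesh()].
#' @param pressure Distal-trunk pressure (MPa), identical for all trunks.
#' @param guided_mode `"all_nerves"`, `"outer"` or `"none"`.
#' @return A [boundary_conditions()] object.
#' @export
plexus_boundary_conditions <- function(mesh, pressure,
                                       guided_mode = c("all_nerves", "outer",
                                                       "none")) {
  guided_mode <- match.arg(guided_mode)
  side_sets <- switch(guided_mode,
    all_nerves = stats::setNames(
      lapply(ROOT_IDS, function(r) paste0("side_", r, c("_cranial", "_caudal"))),
      ROOT_IDS),
    outer = list(C5 = "side_C5_cranial", T1 = "side_T1_caudal"),
    none = list())
  all_side_nodes <- unlist(lapply(unlist(side_sets), function(s)
    edge_set_nodes(mesh, s)))
  shared <- unique(all_side_nodes[duplicated(all_side_nodes)])
  fixed_nodes <- edge_set_nodes(mesh, "cord_midline")
  guided <- list()
  for (r in names(side_sets)) {
    nodes <- setdiff(unique(unlist(lapply(side_sets[[r]], function(s)
      edge_set_nodes(mesh, s)))), c(shared, fixed_nodes))
    if (length(nodes)) {
      guided[[length(guided) + 1L]] <- list(nodes = nodes,
                                            axis = mesh$root_axes[[r]])
    }
  }
  boundary_conditions(
    fixed = list(list(nodes = fixed_nodes, ux = 0, uy = 0)),
    guided = guided,
    tractions = lapply(TRUNK_IDS, function(tr) {
      list(edges = mesh$edge_sets[[paste0("distal_", tr)]], pressure = pressure)
    })
  )
}

#' Solve one loading case on a plexus mesh
#'
#' Convenience wrapper: builds the case material, the standard boundary
#' conditions with the case's published distal-trunk pressure, and solves.
#'
#' @param mesh A `plexus_mesh`.
#' @param case A `bp_load_case` or its id.
#' @param pressure Applied pressure (MPa); defaults to the case's published
#'   value.
#' @param scheme Quad integration scheme.
#' @param guided_mode Guided-support mode, see [plexus_boundary_conditions()].
#' @return An `fe_solution`.
#' @export
solve_plexus_case <- function(mesh, case = "case1",
                              pressure = NULL, scheme = "full_2x2",
                              guided_mode = "all_nerves") {
  if (is.character(case)) case <- bp_load_case(case)
  if (is.null(pressure)) pressure <- case$applied_pressure
  solve_elasticity(mesh, case_material(case),
                   plexus_boundary_conditions(mesh, pressure, guided_mode),
                   scheme)
}
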