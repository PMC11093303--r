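# Structured quad-dominant meshing of the plexus strips. Each strip (root,
# trunk, cord) is meshed as a mapped grid; interface nodes (root-cord and
# root-trunk) are computed once and shared bitwise between the adjoining
# grids, so merging coincident nodes is exact and runs are bit-reproducible.

# n points from P to Q inclusive with exact endpoints
interp_points <- function(P, Q, n_div) {
  t <- seq_len(n_div - 1) / n_div
  pts <- rbind(P, outer(rep(1, n_div - 1), P) + t %o% (Q - P), Q)
  dimnames(pts) <- NULL
  pts
}

n_divisions <- function(len, h_max, h_min) {
  n <- ceiling(len / h_max - 1e-9)
  n <- min(n, max(1, floor(len / h_min + 1e-9)))
  max(1L, as.integer(n))
}

# mapped grid between two matching node columns; rows i = 0..n_len along the
# strip, j across. Returns nodes and 4-node quads (local indices).
column_grid <- function(prox, dist, n_len) {
  n_w <- nrow(prox) - 1L
  nodes <- matrix(0, (n_len + 1L) * (n_w + 1L), 2L)
  idx <- function(i, j) i * (n_w + 1L) + j + 1L
  for (j in 0:n_w) {
    col <- interp_points(prox[j + 1L, ], dist[j + 1L, ], n_len)
    nodes[idx(0:n_len, j), ] <- col
  }
  quads <- matrix(0L, n_len * n_w, 4L)
  k <- 0L
  for (i in seq_len(n_len) - 1L) {
    for (j in seq_len(n_w) - 1L) {
      k <- k + 1L
      quads[k, ] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
    }
  }
  list(nodes = nodes, quads = quads, idx = idx, n_len = n_len, n_w = n_w)
}

#' Mesh parameters and uniform refinement
#'
#' @param h_max Maximum global element size (mm).
#' @param h_min Minimum element size (mm).
#' @return A list with `h_max`, `h_min`.
#' @export
mesh_params <- function(h_max = 2, h_min = 0.2) {
  stopifnot(h_min > 0, h_min <= h_max)
  list(h_max = h_max, h_min = h_min)
}

#' @rdname mesh_params
#' @param params Mesh parameters.
#' @param factor Refinement factor (> 1 refines; 1 is the identity).
#' @export
refine_mesh_params <- function(params, factor) {
  stopifnot(factor >= 1)
  mesh_params(params$h_max / factor, params$h_min / factor)
}

#' Generate a structured quadrilateral mesh of the plexus geometry
#'
#' Meshes each strip (cord, five roots, three trunks) as a mapped grid of
#' bilinear quadrilaterals with target edge size `h_max` (edges never driven
#' below `h_min`). Grids conform exactly along the root-cord and root-trunk
#' interfaces. Named boundary edge sets are recorded for the cord midline,
#' the three distal trunk faces, the superior (cranial) side of C5, the
#' inferior (caudal) side of T1, and the five root-cord junctions.
#'
#' @param geom A `plexus_geometry`.
#' @param h_max,h_min Global mesh size bounds (mm); defaults follow the
#'   converged model (2 mm / 0.2 mm).
#' @return A `plexus_mesh`: list with `nodes` (n x 2 matrix, mm), `elems`
#'   (m x 4 integer matrix, counter-clockwise; triangles padded with `NA`),
#'   `region` (per-element tag), `edge_sets` (named list of k x 2 node-index
#'   matrices) and `root_axes` (per-root unit direction vectors).
#' @examples
#' mesh <- generate_mesh(build_plexus_geometry())
#' nrow(mesh$elems)
#' @export
generate_mesh <- function(geom, h_max = 2, h_min = 0.2) {
  stopifnot(inherits(geom, "plexus_geometry"), h_min > 0, h_min <= h_max)
  dims <- geom$dims
  dcc <- stats::setNames(dims$d_cranial_caudal, dims$root)

  grids <- list()     # per-region: nodes, quads, plus local edge records
  edge_records <- list()

  # --- trunk face nodes (computed once, shared with member roots) ----------
  face_nodes <- list()    # per trunk: full across-face node matrix
  member_slices <- list() # per root: its distal node matrix
  n_w_root <- stats::setNames(integer(5), ROOT_IDS)
  for (r in ROOT_IDS) n_w_root[[r]] <- n_divisions(dcc[[r]], h_max, h_min)

  for (tr in TRUNK_IDS) {
    tk <- geom$trunks[[tr]]
    pieces <- list()
    for (m in tk$members) {
      f <- tk$member_faces[[m]]
      pieces[[m]] <- interp_points(f[1, ], f[2, ], n_w_root[[m]])
      member_slices[[m]] <- pieces[[m]]
    }
    fn <- pieces[[1]]
    if (length(pieces) == 2) fn <- rbind(fn, pieces[[2]][-1, , drop = FALSE])
    face_nodes[[tr]] <- fn
  }

  # --- root strips ---------------------------------------------------------
  for (r in ROOT_IDS) {
    rt <- geom$roots[[r]]
    n_w <- n_w_root[[r]]
    prox <- interp_points(rt$prox["cranial", ], rt$prox["caudal", ], n_w)
    prox[, 1] <- 0  # exactly on the cord edge
    n_len <- n_divisions(rt$length, h_max, h_min)
    g <- column_grid(prox, member_slices[[r]], n_len)
    grids[[paste0("root_", r)]] <- g
    er <- list()
    er[[paste0("junction_", r)]] <- cbind(g$idx(0L, 0:(n_w - 1L)),
                                          g$idx(0L, 1:n_w))
    er[[paste0("side_", r, "_cranial")]] <- cbind(g$idx(0:(n_len - 1L), 0L),
                                                  g$idx(1:n_len, 0L))
    er[[paste0("side_", r, "_caudal")]] <- cbind(g$idx(0:(n_len - 1L), n_w),
                                                 g$idx(1:n_len, n_w))
    edge_records[[paste0("root_", r)]] <- er
  }

  # --- trunk strips --------------------------------------------------------
  for (tr in TRUNK_IDS) {
    tk <- geom$trunks[[tr]]
    fn <- face_nodes[[tr]]
    # distal row at the same normalised across-face positions as the
    # proximal face nodes (the distal face may be shorter, e.g. the kinked
    # middle trunk)
    seg <- sqrt(rowSums((fn[-1, , drop = FALSE] -
                         fn[-nrow(fn), , drop = FALSE])^2))
    pos <- c(0, cumsum(seg)) / sum(seg)
    dist <- outer(rep(1, nrow(fn)), tk$dist["cranial", ]) +
      pos %o% (tk$dist["caudal", ] - tk$dist["cranial", ])
    n_len <- n_divisions(tk$length, h_max, h_min)
    g <- column_grid(fn, dist, n_len)
    grids[[paste0("trunk_", tr)]] <- g
    n_w <- g$n_w
    edge_records[[paste0("trunk_", tr)]] <-
      stats::setNames(list(cbind(g$idx(n_len, 0:(n_w - 1L)),
                                 g$idx(n_len, 1:n_w))),
                      paste0("distal_", tr))
  }

  # --- cord strip ----------------------------------------------------------
  w <- geom$cord$width
  n_x <- 2L * max(1L, as.integer(ceiling(w / (2 * h_max) - 1e-9)))
  xs <- interp_points(c(-w, 0), c(0, 0), n_x)[, 1]
  xs[n_x / 2L + 1L] <- -w / 2  # exact midline station
  xs[n_x + 1L] <- 0

  iv_pts <- lapply(ROOT_IDS, function(r) {
    g <- grids[[paste0("root_", r)]]
    g$nodes[g$idx(0L, 0:g$n_w), 2]  # exact interface y stations
  })
  ys <- numeric(0)
  fill <- function(a, b) {
    n <- n_divisions(b - a, h_max, h_min)
    if (n <= 1L) return(numeric(0))
    interp_points(c(a, 0), c(b, 0), n)[2:n, 1]
  }
  prev <- 0
  for (k in seq_along(iv_pts)) {
    seg <- iv_pts[[k]]
    ys <- c(ys, fill(prev, seg[1]), seg)
    prev <- seg[length(seg)]
  }
  ys <- c(0, ys, fill(prev, geom$cord$length), geom$cord$length)
  n_y <- length(ys) - 1L

  cord_nodes <- cbind(rep(xs, each = n_y + 1L), rep(ys, n_x + 1L))
  cidx <- function(ix, iy) (ix) * (n_y + 1L) + iy + 1L  # ix, iy zero-based
  cquads <- matrix(0L, n_x * n_y, 4L)
  k <- 0L
  for (ix in seq_len(n_x) - 1L) {
    for (iy in seq_len(n_y) - 1L) {
      k <- k + 1L
      cquads[k, ] <- c(cidx(ix, iy), cidx(ix + 1L, iy),
                       cidx(ix + 1L, iy + 1L), cidx(ix, iy + 1L))
    }
  }
  grids[["cord"]] <- list(nodes = cord_nodes, quads = cquads)
  mid <- n_x / 2L
  edge_records[["cord"]] <- list(
    cord_midline = cbind(cidx(mid, 0:(n_y - 1L)), cidx(mid, 1:n_y)))

  # --- merge into a global mesh -------------------------------------------
  region_names <- names(grids)
  all_nodes <- do.call(rbind, lapply(grids, `[[`, "nodes"))
  keys <- paste(sprintf("%.17g", all_nodes[, 1]),
                sprintf("%.17g", all_nodes[, 2]))
  uniq <- !duplicated(keys)
  global_id <- match(keys, keys[uniq])
  nodes <- all_nodes[uniq, , drop = FALSE]

  offsets <- cumsum(c(0L, vapply(grids, function(g) nrow(g$nodes), integer(1))))
  names(offsets) <- c(region_names, "end")

  elems <- list(); region <- list()
  for (rn in region_names) {
    q <- grids[[rn]]$quads + offsets[[rn]]
    q[] <- global_id[q]
    elems[[rn]] <- q
    region[[rn]] <- rep(rn, nrow(q))
  }
  elems <- do.call(rbind, elems)
  region <- unlist(region, use.names = FALSE)

  edge_sets <- list()
  for (rn in names(edge_records)) {
    for (es in names(edge_records[[rn]])) {
      e <- edge_records[[rn]][[es]] + offsets[[rn]]
      e[] <- global_id[e]
      edge_sets[[es]] <- e
    }
  }
  # the outer free boundary of the nerve fan
  edge_sets[["superior_edge"]] <- edge_sets[["side_C5_cranial"]]
  edge_sets[["inferior_edge"]] <- edge_sets[["side_T1_caudal"]]

  # counter-clockwise orientation
  for (e in seq_len(nrow(elems))) {
    q <- nodes[elems[e, ], ]
    if (quad_signed_area(q) < 0) elems[e, ] <- elems[e, c(1, 4, 3, 2)]
  }

  structure(list(
    nodes = nodes, elems = elems, region = region, edge_sets = edge_sets,
    root_axes = lapply(stats::setNames(ROOT_IDS, ROOT_IDS),
                       function(r) root_direction(geom$roots[[r]]$theta)),
    h_max = h_max, h_min = h_min
  ), class = "plexus_mesh")
}

#' @export
print.plexus_mesh <- function(x, ...) {
  nq <- sum(!is.na(x$elems[, 4]))
  nt <- sum(is.na(x$elems[, 4]))
  cat(sprintf("<plexus_mesh> %d nodes, %d elements (%d quads, %d triangles), h = [%g, %g] mm\n",
              nrow(x$nodes), nrow(x$elems), nq, nt, x$h_min, x$h_max))
  invisible(x)
}

#' Structured rectangle mesh
#'
#' Axis-aligned rectangular domain `[0, L] x [0, W]` meshed with an
#' `nx x ny` grid of bilinear quads. Used by the analytic verification
#' fixtures (uniform bar, cantilever).
#'
#' @param L,W Rectangle dimensions (mm).
#' @param h Target element size (mm), or give `nx`, `ny` directly.
#' @param nx,ny Number of divisions along x and y.
#' @return A `plexus_mesh` with edge sets `left`, `right`, `bottom`, `top`.
#' @export
rect_mesh <- function(L, W, h = NULL, nx = NULL, ny = NULL) {
  if (is.null(nx)) nx <- max(1L, as.integer(ceiling(L / h - 1e-9)))
  if (is.null(ny)) ny <- max(1L, as.integer(ceiling(W / h - 1e-9)))
  left <- interp_points(c(0, 0), c(0, W), ny)
  right <- interp_points(c(L, 0), c(L, W), ny)
  g <- column_grid(left, right, nx)
  es <- list(
    left = cbind(g$idx(0L, 0:(ny - 1L)), g$idx(0L, 1:ny)),
    right = cbind(g$idx(nx, 0:(ny - 1L)), g$idx(nx, 1:ny)),
    bottom = cbind(g$idx(0:(nx - 1L), 0L), g$idx(1:nx, 0L)),
    top = cbind(g$idx(0:(nx - 1L), ny), g$idx(1:nx, ny))
  )
  elems <- g$quads
  for (e in seq_len(nrow(elems))) {
    q <- g$nodes[elems[e, ], ]
    if (quad_signed_area(q) < 0) elems[e, ] <- elems[e, c(1, 4, 3, 2)]
  }
  structure(list(nodes = g$nodes, elems = elems,
                 region = rep("rect", nrow(elems)), edge_sets = es,
                 root_axes = NULL, h_max = max(L / nx, W / ny),
                 h_min = min(L / nx, W / ny)),
            class = "plexus_mesh")
}

#' Element quality and mesh validity checks
#'
#' `element_jacobians()` returns the minimum Jacobian determinant of the
#' bilinear map over the 2 x 2 Gauss points of each quad (triangles: twice
#' the signed area). `mesh_edge_lengths()` returns all unique element edge
#' lengths. `mesh_connected()` checks that the element adjacency graph
#' (elements sharing nodes) has a single connected component.
#'
#' @param mesh A `plexus_mesh`.
#' @return See details.
#' @export
element_jacobians <- function(mesh) {
  gp <- 1 / sqrt(3) * c(-1, 1)
  vapply(seq_len(nrow(mesh$elems)), function(e) {
    en <- mesh$elems[e, ]
    if (is.na(en[4])) {
      xy <- mesh$nodes[en[1:3], ]
      return(2 * triangle_area(xy))
    }
    xy <- mesh$nodes[en, ]
    m <- Inf
    for (xi in gp) for (eta in gp) {
      m <- min(m, quad_jacobian(xy, xi, eta)$detJ)
    }
    m
  }, numeric(1))
}

#' @rdname element_jacobians
#' @export
mesh_edge_lengths <- function(mesh) {
  eds <- element_edges(mesh)
  p <- mesh$nodes[eds[, 1], , drop = FALSE] - mesh$nodes[eds[, 2], , drop = FALSE]
  sqrt(rowSums(p^2))
}

element_edges <- function(mesh) {
  out <- list()
  for (e in seq_len(nrow(mesh$elems))) {
    en <- mesh$elems[e, ]
    en <- en[!is.na(en)]
    out[[e]] <- cbind(en, c(en[-1], en[1]))
  }
  eds <- do.call(rbind, out)
  eds <- t(apply(eds, 1, sort))
  unique(eds)
}

#' @rdname element_jacobians
#' @export
mesh_connected <- function(mesh) {
  n <- nrow(mesh$nodes)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  for (e in seq_len(nrow(mesh$elems))) {
    en <- mesh$elems[e, ]; en <- en[!is.na(en)]
    r <- find(en[1])
    for (k in en[-1]) { rk <- find(k); if (rk != r) comp[rk] <- r }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  length(unique(roots)) == 1L
}

#' Nodes belonging to a named edge set
#' @param mesh A `plexus_mesh`.
#' @param name Edge set name.
#' @return Sorted vector of node indices.
#' @export
edge_set_nodes <- function(mesh, name) {
  es <- mesh$edge_sets[[name]]
  if (is.null(es)) stop(sprintf("mesh has no edge set '%s'", name))
  sort(unique(as.vector(es)))
}

triangle_area <- function(xy) {
  0.5 * ((xy[2, 1] - xy[1, 1]) * (xy[3, 2] - xy[1, 2]) -
         (xy[3, 1] - xy[1, 1]) * (xy[2, 2] - xy[1, 2]))
}
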