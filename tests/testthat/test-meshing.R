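test_that("structured rectangle meshing gives the counting-argument sizes", {
  m <- rect_mesh(10, 2, h = 1)
  expect_equal(nrow(m$nodes), 33)   # (10+1) * (2+1)
  expect_equal(nrow(m$elems), 20)   # 10 * 2
  expect_true(all(element_jacobians(m) > 0))
  expect_setequal(names(m$edge_sets), c("left", "right", "bottom", "top"))
})

test_that("mesh parameter refinement divides both size bounds", {
  mp <- mesh_params(2, 0.2)
  expect_equal(refine_mesh_params(mp, 2), list(h_max = 1, h_min = 0.1))
  expect_equal(refine_mesh_params(mp, 1), mp)
  expect_error(refine_mesh_params(mp, 0.5), "factor")
  # repeated refinement drives the largest element edge down monotonically
  g <- build_plexus_geometry()
  hmax <- vapply(c(1, 2, 4), function(fc) {
    p <- refine_mesh_params(mp, fc)
    max(mesh_edge_lengths(generate_mesh(g, p$h_max, p$h_min)))
  }, numeric(1))
  expect_true(all(diff(hmax) < 0))
})

test_that("baseline plexus mesh is valid, conforming and within size bounds", {
  mesh <- baseline_solution()$mesh
  ne <- nrow(mesh$elems)
  # same order of magnitude as the reference model's 212 elements
  expect_gt(ne, 212 / 3)
  expect_lt(ne, 212 * 3)
  expect_true(all(element_jacobians(mesh) > 0))
  el <- mesh_edge_lengths(mesh)
  expect_gte(min(el), 0.2 * 0.7)
  expect_lte(max(el), 2.0 * 1.3)
  expect_true(mesh_connected(mesh))
  # all-quad strip meshes: quad fraction at least 90%
  expect_gte(mean(!is.na(mesh$elems[, 4])), 0.9)
  # region tags cover every element exactly once
  expect_length(mesh$region, ne)
  expect_setequal(unique(mesh$region),
                  c("cord", paste0("root_", c("C5", "C6", "C7", "C8", "T1")),
                    paste0("trunk_", c("upper", "middle", "lower"))))
  # no duplicate nodes
  d <- as.matrix(stats::dist(mesh$nodes))
  diag(d) <- Inf
  expect_gt(min(d), 1e-9)
})

test_that("junction and boundary edge sets are placed correctly", {
  b <- baseline_solution()
  mesh <- b$mesh
  for (r in c("C5", "C6", "C7", "C8", "T1")) {
    jn <- edge_set_nodes(mesh, paste0("junction_", r))
    expect_gt(length(jn), 1)
    expect_true(all(abs(mesh$nodes[jn, 1]) < 1e-12))  # on the cord edge
  }
  mid <- edge_set_nodes(mesh, "cord_midline")
  expect_true(all(abs(mesh$nodes[mid, 1] + b$geom$cord$width / 2) < 1e-12))
  expect_error(edge_set_nodes(mesh, "nope"), "no edge set")
  # distal sets lie on the trunk distal faces
  for (tr in c("upper", "middle", "lower")) {
    dn <- edge_set_nodes(mesh, paste0("distal_", tr))
    tk <- b$geom$trunks[[tr]]
    seg <- tk$dist["caudal", ] - tk$dist["cranial", ]
    off <- sweep(mesh$nodes[dn, , drop = FALSE], 2, tk$dist["cranial", ])
    cross <- off[, 1] * seg[2] - off[, 2] * seg[1]
    expect_true(all(abs(cross) < 1e-8))
  }
})

test_that("mesh generation is deterministic", {
  g <- build_plexus_geometry()
  m1 <- generate_mesh(g, 2, 0.2)
  m2 <- generate_mesh(g, 2, 0.2)
  expect_identical(m1, m2)
})

test_that("meshes export to INP and VTK", {
  mesh <- rect_mesh(4, 2, h = 1)
  tmp <- tempfile(fileext = ".inp")
  write_mesh_inp(mesh, tmp)
  lines <- readLines(tmp)
  expect_true(any(grepl("^\\*NODE", lines)))
  expect_true(any(grepl("TYPE=CPS4", lines)))
  expect_true(any(grepl("NSET=left", lines)))
  tmp2 <- tempfile(fileext = ".vtk")
  sol <- solve_fixture(make_bar_fixture(L = 4, W = 2, h = 1))
  write_mesh_vtk(mesh, tmp2, sol)
  lines2 <- readLines(tmp2)
  expect_true(any(grepl("UNSTRUCTURED_GRID", lines2)))
  expect_true(any(grepl("von_mises", lines2)))
})
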