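test_that("quad stiffness is symmetric with exactly the rigid-body null space", {
  set.seed(7)
  for (k in 1:5) {
    xy <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)) +
      matrix(stats::runif(8, -0.15, 0.15), 4, 2)
    K <- element_stiffness_quad(xy, material(1.48, 0.4))
    expect_identical(max(abs(K - t(K))), 0)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-10), 3)  # 2 translations + 1 rotation
    # rigid translation produces no force
    expect_lt(max(abs(K %*% rep(c(1, 0), 4))), 1e-12)
    expect_lt(max(abs(K %*% rep(c(0, 1), 4))), 1e-12)
  }
})

test_that("reduced integration has hourglass modes; stabilisation removes them", {
  xy <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  K0 <- element_stiffness_quad(xy, material(1, 0.3), "reduced_1pt", hg_coef = 0)
  ev0 <- eigen(K0, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev0) < 1e-10), 5)  # 3 rigid + 2 hourglass
  K1 <- element_stiffness_quad(xy, material(1, 0.3), "reduced_1pt")
  ev1 <- eigen(K1, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev1) < 1e-10), 3)
})

test_that("full-integration stiffness matches a 4x4-point quadrature oracle", {
  mat <- material(1, 0)
  # affine elements: the integrand is polynomial, both quadratures exact
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(element_stiffness_quad(sq, mat),
               brute_force_quad_stiffness(sq, 1, 0), tolerance = 1e-13)
  par <- rbind(c(0, 0), c(2, 0.5), c(2.7, 1.9), c(0.7, 1.4))
  expect_equal(element_stiffness_quad(par, mat, "full_2x2"),
               brute_force_quad_stiffness(par, 1, 0), tolerance = 1e-12)
  mat2 <- material(1.48, 0.4)
  expect_equal(element_stiffness_quad(sq, mat2),
               brute_force_quad_stiffness(sq, 1.48, 0.4), tolerance = 1e-13)
  expect_error(element_stiffness_quad(sq[c(1, 4, 3, 2), ], mat), "Jacobian")
})

test_that("uniform bar reproduces the closed-form stretch for any Poisson ratio", {
  for (nu in c(0, 0.4)) {
    fx <- make_bar_fixture(L = 41.4, W = 3, E = 1.48, nu = nu, p = 0.332, h = 1)
    sol <- solve_fixture(fx)
    expect_lt(max(abs(sol$stress$sxx / fx$expected$sxx - 1)), 1e-8)
    expect_lt(max(abs(sol$stress$syy)), 1e-8)
    expect_lt(max(abs(sol$stress$txy)), 1e-8)
    expect_lt(max(abs(sol$stress$vm / fx$expected$sxx - 1)), 1e-8)
    right <- edge_set_nodes(fx$mesh, "right")
    expect_equal(mean(sol$u[right, 1]), fx$expected$u_end, tolerance = 1e-8)
    expect_lt(sol$residual, 1e-8)
  }
})

test_that("constant-strain triangles pass the uniform-stress bar test", {
  fx <- make_bar_fixture(L = 10, W = 2, E = 2.02, nu = 0.4, p = 0.653, h = 0.5)
  fx$mesh <- triangulate_mesh(fx$mesh)
  sol <- solve_fixture(fx)
  expect_lt(max(abs(sol$stress$sxx / fx$expected$sxx - 1)), 1e-8)
  expect_lt(max(abs(sol$stress$syy)), 1e-8)
  expect_lt(sol$residual, 1e-8)
})

test_that("distorted patch test is exact for arbitrary seeds", {
  for (seed in c(1, 2, 3, 11)) {
    fx <- make_patch_fixture(seed)
    sol <- solve_fixture(fx)
    ue <- fx$expected$u_fun(fx$mesh$nodes[, 1], fx$mesh$nodes[, 2])
    expect_lt(max(abs(sol$u - ue)), 1e-10)
    s <- as.matrix(sol$stress[, c("sxx", "syy", "txy")])
    expect_lt(max(abs(sweep(s, 2, fx$expected$stress))), 1e-10)
  }
  # a pure-rotation gradient has zero strain, hence zero stress
  fx0 <- make_patch_fixture(5, grad = matrix(c(0, 1e-3, -1e-3, 0), 2, 2))
  sol0 <- solve_fixture(fx0)
  expect_lt(max(abs(as.matrix(sol0$stress[, c("sxx", "syy", "txy")]))), 1e-12)
})

test_that("cantilever tip deflection matches beam theory within 5%", {
  L <- 10; W <- 1; E <- 1000; nu <- 0.3; P <- 0.5
  mesh <- rect_mesh(L, W, nx = 100, ny = 10)
  bcs <- boundary_conditions(
    fixed = list(list(nodes = edge_set_nodes(mesh, "left"), ux = 0, uy = 0)),
    tractions = list(list(edges = mesh$edge_sets$right, pressure = P / W,
                          direction = c(0, -1))))
  sol <- solve_elasticity(mesh, material(E, nu), bcs)
  tip <- mean(sol$u[edge_set_nodes(mesh, "right"), 2])
  expect_equal(tip, -beam_tip_deflection(P, L, E, nu, W), tolerance = 0.05)
})

test_that("solutions scale linearly with the applied pressure", {
  b <- baseline_solution()
  sol2 <- solve_plexus_case(b$mesh, "case1", pressure = 2 * 0.332)
  expect_equal(sol2$u, 2 * b$sol$u, tolerance = 1e-10)
  expect_equal(sol2$stress$vm, 2 * b$sol$stress$vm, tolerance = 1e-10)
})

test_that("solution is invariant under rigid translation of the geometry", {
  b <- baseline_solution()
  mesh2 <- b$mesh
  mesh2$nodes <- sweep(mesh2$nodes, 2, c(-3.7, 2.9))
  sol2 <- solve_plexus_case(mesh2, "case1")
  s1 <- max_junction_stress(b$sol$stress, b$mesh, "C5")
  s2 <- max_junction_stress(sol2$stress, mesh2, "C5")
  expect_equal(s2, s1, tolerance = 1e-6)
})

test_that("every plexus solve satisfies global equilibrium", {
  b <- baseline_solution()
  expect_lt(b$sol$residual, 1e-8)
  sol2 <- solve_plexus_case(b$mesh, "case2")
  expect_lt(sol2$residual, 1e-8)
  gp <- perturb_root_angles(b$geom, -6)
  mp <- generate_mesh(gp, 2, 0.2)
  expect_lt(solve_plexus_case(mp, "case1")$residual, 1e-8)
})

test_that("constraint handling rejects ill-posed problems", {
  mesh <- rect_mesh(4, 2, h = 1)
  # only tractions: rigid-body modes remain
  bcs <- boundary_conditions(
    tractions = list(list(edges = mesh$edge_sets$right, pressure = 1)))
  expect_error(solve_elasticity(mesh, material(1, 0.3), bcs), "constraints")
  # a node cannot be fixed and guided at once
  n1 <- edge_set_nodes(mesh, "left")
  bcs2 <- boundary_conditions(
    fixed = list(list(nodes = n1, ux = 0, uy = 0)),
    guided = list(list(nodes = n1[1], axis = c(1, 0))),
    tractions = list(list(edges = mesh$edge_sets$right, pressure = 1)))
  expect_error(solve_elasticity(mesh, material(1, 0.3), bcs2), "fixed and guided")
})

test_that("plane-stress von Mises formula handles the canonical states", {
  expect_identical(von_mises_plane_stress(0.332, 0, 0), 0.332)  # uniaxial
  expect_identical(von_mises_plane_stress(1.7, 1.7, 0), 1.7)    # equibiaxial
  expect_equal(von_mises_plane_stress(1, -1, 0), sqrt(3))
  expect_identical(von_mises_plane_stress(0, 0, 0), 0)
  expect_equal(von_mises_plane_stress(0, 0, 2), 2 * sqrt(3))    # pure shear
  expect_true(all(von_mises_plane_stress(stats::rnorm(50), stats::rnorm(50),
                                         stats::rnorm(50)) >= 0))
  expect_error(von_mises_plane_stress(NA, 0, 0))
})
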