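# Independent numerical oracles used across the suite.

# brute-force element stiffness by high-order (4x4) Gauss-Legendre
# quadrature, written independently of the element routines
brute_force_quad_stiffness <- function(xy, E, nu, thickness = 1) {
  gp <- c(-0.8611363115940526, -0.3399810435848563,
          0.3399810435848563, 0.8611363115940526)
  gw <- c(0.3478548451374538, 0.6521451548625461,
          0.6521451548625461, 0.3478548451374538)
  D <- E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
  K <- matrix(0, 8, 8)
  for (i in 1:4) for (j in 1:4) {
    xi <- gp[i]; eta <- gp[j]
    dN <- matrix(c(-(1 - eta), -(1 - xi),
                    (1 - eta), -(1 + xi),
                    (1 + eta),  (1 + xi),
                   -(1 + eta),  (1 - xi)) / 4, 4, 2, byrow = TRUE)
    J <- t(dN) %*% xy
    dNxy <- dN %*% solve(t(J))
    B <- matrix(0, 3, 8)
    B[1, seq(1, 8, 2)] <- dNxy[, 1]
    B[2, seq(2, 8, 2)] <- dNxy[, 2]
    B[3, seq(1, 8, 2)] <- dNxy[, 2]
    B[3, seq(2, 8, 2)] <- dNxy[, 1]
    K <- K + gw[i] * gw[j] * t(B) %*% D %*% B * det(J) * thickness
  }
  K
}

# split every quad of a mesh into two triangles (for T3 element checks)
triangulate_mesh <- function(mesh) {
  q <- mesh$elems
  tris <- rbind(cbind(q[, 1], q[, 2], q[, 3], NA),
                cbind(q[, 1], q[, 3], q[, 4], NA))
  mesh$elems <- tris
  mesh$region <- rep(mesh$region, 2)
  mesh
}

# Timoshenko cantilever tip deflection under an end shear load
beam_tip_deflection <- function(P, L, E, nu, W, thickness = 1) {
  I <- thickness * W^3 / 12
  G <- E / (2 * (1 + nu))
  A <- W * thickness
  P * L^3 / (3 * E * I) + P * L / (5 / 6 * G * A)
}

baseline_solution <- local({
  cache <- new.env()
  function(case = "case1") {
    key <- case
    if (is.null(cache[[key]])) {
      geom <- build_plexus_geometry()
      mesh <- generate_mesh(geom, 2, 0.2)
      cache[[key]] <- list(geom = geom, mesh = mesh,
                           sol = solve_plexus_case(mesh, case))
    }
    cache[[key]]
  }
})
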