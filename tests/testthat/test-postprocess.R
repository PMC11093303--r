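test_that("junction stress on a uniform bar returns the uniform stress", {
  fx <- make_bar_fixture(L = 10, W = 2, E = 1, nu = 0, p = 0.25, h = 0.5)
  sol <- solve_fixture(fx)
  # treat the loaded edge as the junction window
  expect_equal(max_junction_stress(sol$stress, fx$mesh, "right"), 0.25,
               tolerance = 1e-8)
  # doubling the pressure doubles the reported maximum
  fx2 <- make_bar_fixture(L = 10, W = 2, E = 1, nu = 0, p = 0.5, h = 0.5)
  sol2 <- solve_fixture(fx2)
  expect_equal(max_junction_stress(sol2$stress, fx2$mesh, "right"),
               2 * max_junction_stress(sol$stress, fx$mesh, "right"),
               tolerance = 1e-10)
  expect_error(max_junction_stress(sol$stress, fx$mesh, "junction_C5"),
               "empty or missing")
})

test_that("distal displacement matches the closed-form bar stretch", {
  fx <- make_bar_fixture(L = 41.4, W = 3, E = 1.48, nu = 0, p = 0.332, h = 1)
  sol <- solve_fixture(fx)
  expect_equal(distal_displacement(sol, fx$mesh, "right"),
               0.332 * 41.4 / 1.48, tolerance = 1e-8)
  fx0 <- make_bar_fixture(p = 0)
  sol0 <- solve_fixture(fx0)
  expect_equal(distal_displacement(sol0, fx0$mesh, "right"), 0)
  expect_error(distal_displacement(sol, fx$mesh, "distal_upper"),
               "empty or missing")
})

test_that("engineering strain reproduces the published worked examples", {
  pairs <- rbind(c(7.3, 41.4, 17.6), c(10.6, 41.4, 25.6), c(3.8, 38.3, 9.9),
                 c(5.3, 38.3, 13.8), c(5.8, 30.8, 18.8))
  for (k in seq_len(nrow(pairs))) {
    expect_equal(round(engineering_strain(pairs[k, 1], pairs[k, 2]), 1),
                 pairs[k, 3])
  }
  expect_identical(engineering_strain(0, 12.3), 0)
  expect_error(engineering_strain(1, 0), "L0")
})

test_that("percent change recovers the published parenthetical values", {
  expect_equal(percent_change(0.137, 0.246), -44)
  expect_equal(percent_change(0.286, 0.171), 67)
  expect_equal(percent_change(0.5, 0.5), 0)
  expect_identical(format_percent_change(percent_change(0.278, 0.246)), "+13%")
  expect_identical(format_percent_change(percent_change(0.137, 0.246)), "-44%")
  expect_error(percent_change(1, 0), "baseline")
})

test_that("per-element stresses export to CSV", {
  fx <- make_bar_fixture(L = 4, W = 2, h = 1)
  sol <- solve_fixture(fx)
  tmp <- tempfile(fileext = ".csv")
  write_stress_csv(sol$stress, tmp)
  df <- utils::read.csv(tmp)
  expect_equal(nrow(df), nrow(fx$mesh$elems))
  expect_true(all(c("sxx", "syy", "txy", "vm", "vm_max_gp") %in% names(df)))
})

test_that("case summary collects stresses, displacements and strains", {
  b <- baseline_solution()
  sr <- summarise_case(b$sol, b$mesh, b$geom, "case1")
  expect_s3_class(sr, "study_result")
  expect_equal(sr$junction_stress$root, c("C5", "C6", "C7", "C8", "T1"))
  expect_true(all(is.finite(sr$junction_stress$vm_MPa)))
  expect_equal(sr$trunk_response$length0_mm, c(41.4, 38.3, 30.8),
               tolerance = 1e-9)
  expect_equal(sr$trunk_response$strain_pct,
               100 * sr$trunk_response$displacement_mm /
                 sr$trunk_response$length0_mm)
})
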