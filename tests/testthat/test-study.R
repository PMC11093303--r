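test_that("validation run solves both cases on one mesh with linear scaling", {
  res <- run_validation()
  expect_s3_class(res, "validation_result")
  expect_equal(res$case1$junction_stress$root, c("C5", "C6", "C7", "C8", "T1"))
  expect_equal(nrow(res$case2$junction_stress), 5)
  # case2/case1 per-root stress ratio equals the pressure ratio everywhere
  expect_equal(unname(res$stress_ratio), rep(0.653 / 0.332, 5),
               tolerance = 1e-9)
  # upper roots carry the highest junction stresses
  vm <- stats::setNames(res$case1$junction_stress$vm_MPa,
                        res$case1$junction_stress$root)
  expect_gt(min(vm["C5"], vm["C6"]), max(vm["C8"], vm["T1"]))
  # Table-3 / Table-5 style outputs
  d <- tempfile()
  paths <- write_study_outputs(res, d, "csv")
  expect_true(all(file.exists(paths)))
  js <- utils::read.csv(file.path(d, "junction_stress.csv"))
  expect_equal(dim(js), c(5, 3))
  paths2 <- write_study_outputs(res, d, "json")
  expect_true(all(file.exists(paths2)))
})

test_that("angle sweep perturbs all roots and reports percent changes", {
  cfg <- default_plexus_config()
  sw <- run_angle_sweep(cfg, deltas = c(-6, -3, 0, 3, 6))
  expect_equal(nrow(sw$stress), 25)
  expect_equal(sum(!is.na(sw$stress$vm_MPa)), 25)
  expect_equal(sum(!is.na(sw$stress$pct_change)), 20)
  base <- sw$stress[sw$stress$delta == 0, ]
  expect_true(all(is.na(base$pct_change)))
  # the delta-0 column equals the validation baseline
  b <- baseline_solution()
  vm0 <- vapply(c("C5", "C6", "C7", "C8", "T1"), function(r)
    max_junction_stress(b$sol$stress, b$mesh, r), numeric(1))
  expect_equal(base$vm_MPa, unname(vm0), tolerance = 1e-12)
  # percent changes are integers computed against delta 0
  chk <- sw$stress[sw$stress$delta == 6 & sw$stress$root == "C5", ]
  expect_equal(chk$pct_change,
               percent_change(chk$vm_MPa, base$vm_MPa[base$root == "C5"]))
  expect_error(run_angle_sweep(cfg, deltas = c(-3, 3)), "include 0")
})

test_that("degenerate sweep equals the baseline and reruns are identical", {
  cfg <- default_plexus_config()
  sw0 <- run_angle_sweep(cfg, deltas = 0)
  expect_equal(nrow(sw0$stress), 5)
  expect_true(all(is.na(sw0$stress$pct_change)))
  sw1 <- run_angle_sweep(cfg, deltas = c(-3, 0, 3))
  sw2 <- run_angle_sweep(cfg, deltas = c(3, 0, -3))  # order-invariant
  expect_identical(sw1$stress, sw2$stress)
})

test_that("single-root perturbation mode isolates one root per run", {
  cfg <- default_plexus_config()
  sw <- run_angle_sweep(cfg, deltas = c(0, 6), mode = "single")
  expect_equal(nrow(sw$stress), 2 * 5 * 5)
  d6 <- sw$stress[sw$stress$delta == 6, ]
  expect_equal(nrow(d6), 25)
  expect_true(all(c("perturbed", "pct_change") %in% names(d6)))
})

test_that("convergence study reports sizes and relative changes", {
  cv <- run_convergence(factors = c(1, 2))
  expect_equal(names(cv), c("factor", "h_max", "h_min", "n_elements",
                            "value", "rel_change"))
  expect_true(is.na(cv$rel_change[1]))
  expect_gt(cv$n_elements[2], cv$n_elements[1])
})
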