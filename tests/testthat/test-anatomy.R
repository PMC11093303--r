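test_that("root path lengths equal the summed segment columns", {
  expect_equal(root_path_lengths(),
               c(C5 = 30.5, C6 = 31.0, C7 = 33.5, C8 = 20.0, T1 = 13.5))
  dims <- bp_root_dimensions()
  expect_true(all(dims$d_cranial_caudal >= dims$d_transverse))
  expect_true(is.na(dims$len_drg_to_foramen[dims$root == "T1"]))
  bad <- dims; bad$d_transverse[2] <- -1
  expect_error(validate_root_dimensions(bad), "positive")
})

test_that("default geometry reproduces the published trunk path lengths", {
  geom <- build_plexus_geometry()
  expect_equal(path_length(geom, "upper"), 41.4, tolerance = 1e-9)
  expect_equal(path_length(geom, "middle"), 38.3, tolerance = 1e-9)
  expect_equal(path_length(geom, "lower"), 30.8, tolerance = 1e-9)
})

test_that("geometry construction is deterministic", {
  g1 <- build_plexus_geometry()
  g2 <- build_plexus_geometry()
  expect_identical(g1, g2)
})

test_that("angle perturbation preserves lengths and inverts exactly", {
  g <- build_plexus_geometry()
  expect_identical(perturb_root_angles(g, 0), g)
  gp <- perturb_root_angles(g, 6)
  expect_equal(unname(gp$angles - g$angles), rep(6, 5))
  back <- perturb_root_angles(gp, -6)
  expect_equal(back$angles, g$angles, tolerance = 1e-9)
  # root centerline length invariant under rotation about the junction
  for (r in c("C5", "C8")) {
    rt <- gp$roots[[r]]
    expect_equal(sqrt(sum((rt$E - rt$A)^2)), root_path_lengths()[[r]],
                 tolerance = 1e-9)
  }
  # trunks re-attach to the displaced endpoints: C5's sub-face midpoint
  # tracks the displaced C5 endpoint (up to the small width re-split)
  mid <- (gp$trunks$upper$member_faces$C5[1, ] +
          gp$trunks$upper$member_faces$C5[2, ]) / 2
  expect_lt(sqrt(sum((mid - gp$roots$C5$E)^2)), 0.3)
  expect_error(perturb_root_angles(g, 11), "safe range")
  expect_error(perturb_root_angles(g, c(C5 = 1)), "scalar or named")
})

test_that("strip widths follow the cranial-caudal diameters", {
  g <- build_plexus_geometry()
  dims <- bp_root_dimensions()
  for (k in seq_along(ROOT_IDS <- dims$root)) {
    rt <- g$roots[[ROOT_IDS[k]]]
    # proximal cut on the cord edge: d_cc / sin(theta), exactly
    expect_equal(unname(diff(rt$prox[, 2])),
                 dims$d_cranial_caudal[k] / sin(rt$theta * pi / 180),
                 tolerance = 1e-12)
    # distal face close to the nominal width
    wd <- sqrt(sum((rt$dist[1, ] - rt$dist[2, ])^2))
    expect_lt(abs(wd / dims$d_cranial_caudal[k] - 1), 0.15)
  }
  tw <- trunk_widths()
  for (tr in names(tw)) {
    expect_lt(abs(g$trunks[[tr]]$width / tw[[tr]] - 1), 0.15)
  }
  expect_equal(g$trunks$middle$width, 3.8, tolerance = 1e-12)
})

test_that("infeasible configurations fail with informative errors", {
  cord <- bp_cord_parameters(attachment_y = c(C5 = 4.3, C6 = 6.0, C7 = 13.5,
                                              C8 = 19.6, T1 = 26.2))
  expect_error(build_plexus_geometry(cord = cord), "C5 and C6 overlap")
  expect_error(build_plexus_geometry(angles = c(C5 = 0, C6 = 77.4, C7 = 50,
                                                C8 = 37.5, T1 = 49)),
               "between 0 and 180")
  expect_error(bp_cord_parameters(attachment_y = c(C5 = 5, C6 = 4, C7 = 10,
                                                   C8 = 15, T1 = 20)),
               "increasing")
  expect_error(bp_cord_parameters(length = 10), "cord length")
})

test_that("geometry exports to WKT and SVG", {
  g <- build_plexus_geometry()
  w <- geometry_wkt(g)
  expect_length(w, 9)
  expect_true(all(grepl("^POLYGON \\(\\(", w)))
  # closed rings: first and last vertex identical
  for (s in w) {
    pts <- strsplit(sub("^POLYGON \\(\\((.*)\\)\\)$", "\\1", s), ", ")[[1]]
    expect_identical(pts[1], pts[length(pts)])
  }
  tmp <- tempfile(fileext = ".svg")
  write_geometry_svg(g, tmp)
  expect_true(any(grepl("<polygon", readLines(tmp))))
  tmp2 <- tempfile(fileext = ".wkt")
  write_geometry_wkt(g, tmp2)
  expect_length(readLines(tmp2), 9)
})

test_that("configuration round-trips through YAML", {
  cfg <- default_plexus_config()
  tmp <- tempfile(fileext = ".yaml")
  write_plexus_config(cfg, tmp)
  cfg2 <- read_plexus_config(tmp)
  expect_equal(cfg2$angles, cfg$angles)
  expect_equal(cfg2$dims, cfg$dims)
  expect_identical(geometry_from_config(cfg2), geometry_from_config(cfg))
  bundled <- read_plexus_config()
  expect_identical(geometry_from_config(bundled), build_plexus_geometry())
})
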