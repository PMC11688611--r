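# Five-parameter morphometry: analytic targets, oracles, invariances.

test_that("analytic circle gives inv_form_factor exactly 1", {
  R <- c(1, 5, 42.5)
  expect_equal(inv_form_factor(2 * pi * R, pi * R^2), rep(1, 3))
})

test_that("rasterized disk matches analytic circle values", {
  R <- 100
  f <- compute_cell_features(raster_disk_pair(R))
  expect_equal(nrow(f), 1L)
  expect_lt(abs(f$inv_form_factor - 1), 0.02)                 # P^2/(4*pi*A)
  expect_lt(abs(f$gyration_radius - R / sqrt(2)) / (R / sqrt(2)), 0.01)
  expect_lt(abs(f$area - pi * R^2) / (pi * R^2), 0.02)
  expect_lt(abs(f$perimeter - 2 * pi * R) / (2 * pi * R), 0.02)
  expect_equal(f$nuclear_displacement, 0, tolerance = 1e-9)   # centered
})

test_that("axis-aligned (2b, b) ellipse has elongation factor 2", {
  f <- compute_cell_features(raster_ellipse_pair(80, 40))
  expect_lt(abs(f$elongation_factor - 2) / 2, 0.02)
})

test_that("gyration radius and centroid agree with per-pixel oracle", {
  p <- generate_cell_mask(shape_params("polarized", body_radius = 8,
                                       jitter_sd = 0.08), 90, seed = 4)
  f <- compute_cell_features(p)
  o <- brute_gyration(p$cell_mask)
  expect_equal(f$gyration_radius, o$gyration, tolerance = 1e-9)
  expect_equal(f$cell_x, o$cx, tolerance = 1e-9)
  expect_equal(f$cell_y, o$cy, tolerance = 1e-9)
})

test_that("features are scale-equivariant within digitization tolerance", {
  f1 <- compute_cell_features(raster_ellipse_pair(50, 25, nucleus_dx = 10))
  f2 <- compute_cell_features(raster_ellipse_pair(100, 50, nucleus_dx = 20))
  expect_lt(abs(f2$area / f1$area - 4) / 4, 0.02)
  expect_lt(abs(f2$perimeter / f1$perimeter - 2) / 2, 0.02)
  expect_lt(abs(f2$gyration_radius / f1$gyration_radius - 2) / 2, 0.02)
  expect_lt(abs(f2$nuclear_displacement / f1$nuclear_displacement - 2) / 2,
            0.02)
  expect_lt(abs(f2$inv_form_factor / f1$inv_form_factor - 1), 0.05)
  expect_lt(abs(f2$elongation_factor / f1$elongation_factor - 1), 0.05)
})

test_that("features are invariant under 90-degree rotation", {
  p <- generate_cell_mask(shape_params("polarized", jitter_sd = 0.06),
                          150, seed = 9)
  rot90 <- function(m) t(m[nrow(m):1, ])
  pr <- labeled_image_pair(rot90(p$cell_mask), rot90(p$nucleus_mask))
  f <- compute_cell_features(p)
  fr <- compute_cell_features(pr)
  for (par in PARAMS)
    expect_equal(fr[[par]], f[[par]], tolerance = 1e-9)
})

test_that("features are stable under arbitrary rotation to 5%", {
  sp <- shape_params("elongated", elongation_target = 1.8, jitter_sd = 0)
  f0 <- compute_cell_features(generate_cell_mask(sp, 110, seed = 1,
                                                 orientation = 0))
  f1 <- compute_cell_features(generate_cell_mask(sp, 110, seed = 1,
                                                 orientation = 0.7))
  for (par in c("inv_form_factor", "area", "gyration_radius",
                "elongation_factor"))
    expect_lt(abs(f1[[par]] / f0[[par]] - 1), 0.05)
})

test_that("pixel size scales lengths and leaves shape indices alone", {
  pair <- raster_ellipse_pair(60, 30, nucleus_dx = 8)
  pair2 <- labeled_image_pair(pair$cell_mask, pair$nucleus_mask,
                              pixel_size = 0.65)
  f1 <- compute_cell_features(pair)
  f2 <- compute_cell_features(pair2)
  expect_equal(f2$area, f1$area * 0.65^2, tolerance = 1e-9)
  expect_equal(f2$gyration_radius, f1$gyration_radius * 0.65,
               tolerance = 1e-9)
  expect_equal(f2$nuclear_displacement, f1$nuclear_displacement * 0.65,
               tolerance = 1e-9)
  expect_equal(f2$inv_form_factor, f1$inv_form_factor, tolerance = 1e-9)
  expect_equal(f2$elongation_factor, f1$elongation_factor,
               tolerance = 1e-9)
})

test_that("border-touching cells are excluded, orphan nuclei warned", {
  pair <- raster_disk_pair(30, margin = 6)
  # shift the disk so it touches the top border: cell dropped silently
  cm <- pair$cell_mask
  cm2 <- rbind(cm[-(1:7), ], matrix(0L, 7, ncol(cm)))
  f <- compute_cell_features(labeled_image_pair(cm2, pair$nucleus_mask))
  expect_equal(nrow(f), 0L)
  f2 <- compute_cell_features(labeled_image_pair(cm2, pair$nucleus_mask),
                              exclude_border = FALSE)
  expect_equal(nrow(f2), 1L)
  # a nucleus with no enclosing cell is skipped with a warning
  nm <- matrix(0L, nrow(cm), ncol(cm))
  nm[2:4, 2:4] <- 1L   # far outside the disk
  expect_warning(f3 <- compute_cell_features(labeled_image_pair(cm, nm)),
                 "skipped")
  expect_equal(nrow(f3), 0L)
  expect_equal(attr(f3, "skipped_nuclei"), 1L)
  # empty masks give an empty record list
  empty <- labeled_image_pair(matrix(0L, 10, 10), matrix(0L, 10, 10))
  expect_equal(nrow(compute_cell_features(empty)), 0L)
})

test_that("normalized displacement divides by equivalent radius", {
  pair <- raster_disk_pair(50, nucleus_dx = 10)
  f <- compute_cell_features(pair)
  fn <- compute_cell_features(pair, normalize_displacement = TRUE)
  expect_equal(fn$nuclear_displacement,
               f$nuclear_displacement / sqrt(f$area / pi),
               tolerance = 1e-9)
})

test_that("well aggregation averages parameters and applies QC", {
  rec <- data.frame(cell_id = 1:2, area = c(100, 200), perimeter = c(40, 60),
                    inv_form_factor = c(1.2, 1.4),
                    nuclear_displacement = c(1, 3),
                    gyration_radius = c(5, 7),
                    elongation_factor = c(1.5, 2.5),
                    cell_x = 0, cell_y = 0, nucleus_x = 0, nucleus_y = 0)
  w <- aggregate_well(rec, min_cells = 50, well_id = "A01")
  expect_equal(w$area, 150)
  expect_equal(w$elongation_factor, 2)
  expect_false(w$qc_pass)           # 2 cells < min_cells = 50
  expect_equal(w$n_cells, 2L)
  # single cell: profile equals the record
  w1 <- aggregate_well(rec[1, ], min_cells = 1)
  for (p in PARAMS) expect_equal(w1[[p]], rec[1, p][[1]])
  expect_true(w1$qc_pass)
  expect_error(aggregate_well(rec[0, ]), "no cell records")
  # median aggregation available
  w2 <- aggregate_well(rec, min_cells = 1, fun = "median")
  expect_equal(w2$area, 150)
})
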