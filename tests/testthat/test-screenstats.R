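# Control normalization, plate Z-scores and the replicate hit rule.

make_wells <- function(values, treatments, plate = "P01", screen = 1) {
  n <- length(values)
  w <- data.frame(plate_id = plate,
                  well_id = sprintf("A%02d", seq_len(n)),
                  screen_id = screen, treatment = treatments,
                  n_cells = 50, qc_pass = TRUE)
  for (p in PARAMS) w[[p]] <- values
  w
}

test_that("ratio-to-control normalization anchors controls at 1", {
  w <- make_wells(c(2, 4, 3, 6, 9), c("control_siRNA", "control_siRNA",
                                      "g1", "g2", "g3"))
  norm <- normalize_plate(w)
  ctrl <- norm$treatment == "control_siRNA"
  for (p in PARAMS) {
    expect_equal(mean(norm[[p]][ctrl]), 1)
    expect_equal(norm[[p]][norm$treatment == "g2"], 2)  # 6 / mean(2,4)
  }
  # constant plate equal to the control mean -> everything 1
  wc <- make_wells(rep(3, 5), c("control_siRNA", "control_siRNA",
                                "g1", "g2", "g3"))
  nc <- normalize_plate(wc)
  for (p in PARAMS) expect_true(all(nc[[p]] == 1))
})

test_that("plates without usable controls are dropped with a warning", {
  w <- make_wells(1:5, paste0("g", 1:5))
  expect_error(expect_warning(normalize_plate(w), "no QC-passing control"),
               "no plate retained")
  w2 <- rbind(make_wells(1:5, c("control_siRNA", paste0("g", 1:4))),
              make_wells(1:5, paste0("h", 1:5), plate = "P02"))
  expect_warning(norm <- normalize_plate(w2), "P02")
  expect_setequal(unique(norm$plate_id), "P01")
})

test_that("hand-computed Z-scores: library {1,2,3}, sample SD", {
  w <- make_wells(c(1, 2, 3, 2), c("g1", "g2", "g3", "control_siRNA"))
  z <- zscore_plate(w, screen_config(normalization = "none"))
  z1 <- z[z$parameter == "area", ]
  expect_equal(z1$z[z1$gene == "g3"], 1)           # (3 - 2) / 1
  expect_equal(z1$z[z1$gene == "g2"], 0)           # the plate mean
  expect_equal(z1$center[1], 2)
  expect_equal(z1$scale[1], 1)
  # the control well is scored but not part of the statistics
  expect_equal(z1$z[z1$gene == "control_siRNA"], 0)
  # population SD variant
  zp <- zscore_plate(w, screen_config(sd_mode = "population"))
  expect_equal(zp$scale[1], sd(c(1, 2, 3)) * sqrt(2 / 3))
})

test_that("degenerate plates raise errors rather than silent zeros", {
  w <- make_wells(rep(2, 5), c("control_siRNA", paste0("g", 1:4)))
  expect_error(zscore_plate(w), "zero spread")
  expect_error(zscore_plate(w[1:3, ]), "fewer than 3 scored wells")
})

test_that("Z-scores standardize every plate/parameter/screen group", {
  scr <- small_screen(seed = 11)
  z <- score_wells(scr$wells)
  grp <- interaction(z$plate_id, z$screen_id, z$parameter, drop = TRUE)
  for (g in split(z[!z$is_control & z$qc_pass, ],
                  grp[!z$is_control & z$qc_pass])) {
    expect_lt(abs(mean(g$z)), 1e-9)
    expect_lt(abs(sd(g$z) - 1), 1e-9)
  }
})

test_that("classical Z is invariant to affine rescaling of a plate", {
  scr <- small_screen(n_genes = 88, seed = 13, cells_per_well = 20)
  cfg <- screen_config(normalization = "none")
  z1 <- zscore_plate(scr$wells, cfg)
  w2 <- scr$wells
  for (p in PARAMS) w2[[p]] <- 3.7 * w2[[p]] + 11
  z2 <- zscore_plate(w2, cfg)
  expect_equal(z2$z, z1$z, tolerance = 1e-9)
})

test_that("the 2-of-3 rule with sign consistency calls hits correctly", {
  cfg <- screen_config()
  h <- call_hits(mini_ztab(c(1.6, 1.7, 0.3)), cfg)
  expect_true(h$hit)
  expect_equal(h$dir_inv_form_factor, 1)
  expect_equal(h$phenotype_class, "increased_polarity")
  # mixed signs do not count when consistency is required
  h2 <- call_hits(mini_ztab(c(1.6, -1.7, 0.3)), cfg)
  expect_false(h2$hit)
  # ... but do without the consistency requirement
  h3 <- call_hits(mini_ztab(c(1.6, -1.7, 0.3)),
                  screen_config(require_sign_consistency = FALSE))
  expect_true(h3$hit)
  # one screen beyond threshold is never enough
  h4 <- call_hits(mini_ztab(c(4.0, 0.2, 0.1)), cfg)
  expect_false(h4$hit)
})

test_that("all-negative parameters give the talin-like phenotype class", {
  tabs <- do.call(rbind, lapply(PARAMS, function(p)
    mini_ztab(c(-2, -2.5, -1.8), parameter = p)))
  h <- call_hits(tabs)
  expect_true(h$hit)
  expect_equal(h$phenotype_class, "decreased_polarity")
  expect_equal(h$n_parameters_perturbed, 5L)
  expect_true(all(h[paste0("dir_", PARAMS)] == -1))
})

test_that("genes in fewer than min_screens screens are not evaluable", {
  expect_warning(h <- call_hits(mini_ztab(3)), "not evaluable")
  expect_false(h$evaluable)
  expect_false(h$hit)
  expect_true(is.na(h$phenotype_class))
})

test_that("raising the threshold never enlarges the hit set", {
  scr <- small_screen(seed = 19)
  z <- score_wells(scr$wells)
  prev <- NULL
  for (thr in c(1.0, 1.5, 2.0, 3.0)) {
    h <- call_hits(z, screen_config(z_threshold = thr))
    hits <- h$gene[h$hit]
    if (!is.null(prev)) expect_true(all(hits %in% prev))
    prev <- hits
  }
})

test_that("robust and classical hit sets agree on clean synthetic screens", {
  scr <- small_screen(seed = 23)
  z_c <- score_wells(scr$wells, screen_config())
  z_r <- score_wells(scr$wells, screen_config(z_variant = "robust"))
  hc <- call_hits(z_c, screen_config())
  hr <- call_hits(z_r, screen_config(z_variant = "robust"))
  a <- hc$gene[hc$hit]; b <- hr$gene[hr$hit]
  jac <- length(intersect(a, b)) / length(union(a, b))
  expect_gte(jac, 0.8)
})

test_that("screen summaries count hits consistently with the calls", {
  scr <- small_screen(seed = 29)
  h <- call_hits(score_wells(scr$wells))
  s <- summarize_screen(h)
  expect_equal(s$n_hits, sum(h$hit))
  expect_equal(s$n_decreased + s$n_increased + s$n_mixed, s$n_hits)
  expect_equal(s$fraction_hits, s$n_hits / s$n_evaluable)
  # counts agree with an independent confusion-matrix recomputation
  ev <- evaluate_against_truth(h, scr$sim$truth)
  expect_equal(ev$tp + ev$fn,
               sum(scr$sim$truth$class != "null"))
  expect_equal(ev$tp + ev$fp, s$n_hits)
  # trivial arithmetic case
  h10 <- data.frame(gene = paste0("g", 1:10), evaluable = TRUE,
                    hit = rep(c(TRUE, FALSE), c(2, 8)),
                    phenotype_class = c("decreased_polarity",
                                        "decreased_polarity",
                                        rep(NA, 8)),
                    n_parameters_perturbed = c(1, 1, rep(0, 8)))
  s10 <- summarize_screen(h10)
  expect_equal(s10$fraction_hits, 0.2)
  expect_equal(s10$n_decreased, 2L)
})
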