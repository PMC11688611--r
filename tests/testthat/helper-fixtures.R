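# Shared fixture builders: analytic raster shapes and small screens.

PARAMS <- c("inv_form_factor", "nuclear_displacement", "area",
            "gyration_radius", "elongation_factor")

# binary raster of an axis-aligned ellipse (semi-axes a, b) with an
# optional nucleus disk, as a labeled_image_pair
raster_ellipse_pair <- function(a, b, nucleus_r = max(2, round(b / 3)),
                                nucleus_dx = 0, margin = 6) {
  n <- 2 * ceiling(max(a, b)) + 2 * margin + 1
  c0 <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), each = n), n)
  ys <- matrix(rep(seq_len(n), times = n), n)
  cell <- (xs - c0)^2 / a^2 + (ys - c0)^2 / b^2 <= 1
  nuc <- (xs - c0 - nucleus_dx)^2 + (ys - c0)^2 <= nucleus_r^2
  labeled_image_pair(matrix(as.integer(cell), n),
                     matrix(as.integer(nuc), n))
}

raster_disk_pair <- function(R, ...) raster_ellipse_pair(R, R, ...)

# brute-force per-pixel centroid and gyration radius oracle
brute_gyration <- function(mask) {
  sx <- sy <- npx <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    if (mask[i, j] > 0) { sx <- sx + j; sy <- sy + i; npx <- npx + 1 }
  cx <- sx / npx; cy <- sy / npx
  ss <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    if (mask[i, j] > 0) ss <- ss + (j - cx)^2 + (i - cy)^2
  list(cx = cx, cy = cy, gyration = sqrt(ss / npx))
}

# small complete screen: layout + effects + simulated wells
small_screen <- function(n_genes = 176, seed = 11, cells_per_well = 50,
                         fraction_decrease = 0.1, fraction_increase = 0.1,
                         ...) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  lay <- plate_layout(genes)
  em <- effect_model(genes, fraction_hits_decrease = fraction_decrease,
                     fraction_hits_increase = fraction_increase,
                     seed = seed, ...)
  sim <- simulate_screens(lay, em, cells_per_well = cells_per_well,
                          seed = seed)
  wells <- aggregate_cells(sim$cells, layout = lay)
  list(layout = lay, effects = em, sim = sim, wells = wells)
}

# minimal hand-built Z-score table for hit-rule unit tests: one gene,
# one parameter, z values across 3 screens
mini_ztab <- function(z_by_screen, gene = "GENEX",
                      parameter = "inv_form_factor") {
  data.frame(plate_id = "P01", well_id = "A01", gene = gene,
             screen_id = seq_along(z_by_screen), parameter = parameter,
             value = NA_real_, z = z_by_screen, center = 0, scale = 1,
             is_control = FALSE, qc_pass = TRUE)
}

# all orderings of hclust leaves reachable by subtree flips, as a
# brute-force oracle for optimal leaf ordering (n <= 8)
tree_orderings <- function(hc) {
  expand <- function(id) {
    if (id < 0L) return(list(-id))
    a <- expand(hc$merge[id, 1]); b <- expand(hc$merge[id, 2])
    out <- list()
    for (x in a) for (y in b) {
      out[[length(out) + 1L]] <- c(x, y)
      out[[length(out) + 1L]] <- c(y, x)
    }
    out
  }
  expand(nrow(hc$merge))
}

adjacent_cost <- function(order, d) {
  dm <- as.matrix(d)
  sum(dm[cbind(order[-length(order)], order[-1])])
}
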