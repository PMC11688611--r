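# Synthetic screen generator: plate layouts with the study's control
# structure, a per-gene effect model, and two generation tiers (direct
# feature draws for fast statistics; label-mask images for testing the
# morphometry stage).

WELL_IDS_96 <- paste0(rep(LETTERS[1:8], each = 12),
                      sprintf("%02d", rep(1:12, times = 8)))

#' Build a plate layout for one or more 96-well siRNA plates
#'
#' Each plate carries one siRNA SMARTpool per library well plus the
#' control structure used throughout: 6 non-targeting `control_siRNA`
#' wells, one `TLN1` (talin-1) positive-control well and one
#' `polyL-lysine` reference well (non-polarized resting morphology).
#' The same physical layout is replicated across the requested screens,
#' so every gene occupies the same plate position in every screen.
#'
#' @param genes character vector of library gene identifiers; they are
#'   chunked onto plates of 88 library wells (96 - 8 control wells).
#' @param n_screens number of replicate screens (default 3).
#' @param n_control control_siRNA wells per plate (default 6).
#' @return data.frame with columns `plate_id`, `well_id`, `screen_id`,
#'   `treatment`, one row per well per screen.
#' @examples
#' lay <- plate_layout(sprintf("GENE%03d", 1:176))
#' table(lay$treatment == "control_siRNA", lay$plate_id, lay$screen_id)
#' @export
plate_layout <- function(genes, n_screens = 3, n_control = 6) {
  if (!length(genes) || anyDuplicated(genes))
    stopf("`genes` must be a non-empty vector of unique identifiers")
  if (any(genes %in% CONTROL_TREATMENTS))
    stopf("gene identifiers must not collide with control labels")
  n_screens <- check_count(n_screens, "n_screens")
  n_control <- check_count(n_control, "n_control")
  lib_per_plate <- 96L - n_control - 2L
  n_plates <- ceiling(length(genes) / lib_per_plate)
  # controls spread across the plate at fixed, evenly spaced positions
  ctrl_pos <- round(seq(2, 95, length.out = n_control + 2L))
  plates <- lapply(seq_len(n_plates), function(p) {
    treat <- rep(NA_character_, 96L)
    treat[ctrl_pos[seq_len(n_control)]] <- "control_siRNA"
    treat[ctrl_pos[n_control + 1L]] <- "TLN1"
    treat[ctrl_pos[n_control + 2L]] <- "polyL-lysine"
    g <- genes[seq.int((p - 1L) * lib_per_plate + 1L,
                       min(p * lib_per_plate, length(genes)))]
    treat[which(is.na(treat))[seq_along(g)]] <- g
    keep <- !is.na(treat)
    data.frame(plate_id = sprintf("P%02d", p),
               well_id = WELL_IDS_96[keep], treatment = treat[keep])
  })
  one <- do.call(rbind, plates)
  out <- do.call(rbind, lapply(seq_len(n_screens), function(s) {
    d <- one; d$screen_id <- s; d
  }))
  rownames(out) <- NULL
  out[, c("plate_id", "well_id", "screen_id", "treatment")]
}

# baseline well means of the five parameters for cells polarized on
# anti-LFA-1 (pixel units at 10x-like sampling)
default_baseline <- function() {
  c(inv_form_factor = 1.8, nuclear_displacement = 2.5, area = 250,
    gyration_radius = 7.5, elongation_factor = 1.7)
}

#' Per-gene effect model for the simulator
#'
#' Assigns each library gene a multiplicative effect vector over the
#' five morphology parameters (log-scale shifts applied to the
#' phenotype distribution mean). A fraction of genes is planted as
#' polarity-decreasing hits (negative shift on all five parameters, the
#' talin-like phenotype) and a fraction as polarity-increasing hits;
#' the remaining genes are null (all-zero effects). The `TLN1` positive
#' control gets twice the planted magnitude and the `polyL-lysine`
#' reference three times (resting, non-polarized cells), both negative
#' on all five parameters.
#'
#' @param genes library gene identifiers.
#' @param fraction_hits_decrease,fraction_hits_increase fractions of
#'   library genes planted as decreased/increased-polarity hits; their
#'   sum must be <= 1. Defaults 0.10 each, matching the ~8-11.5% hit
#'   rates typical of morphology screens of this design.
#' @param effect_magnitude absolute log-scale shift of a planted hit
#'   (default 0.25, i.e. ~28% change in the well mean).
#' @param sd_screen between-screen (replicate) noise SD on the log
#'   scale, per gene and screen (default 0.06).
#' @param sd_cell within-well cell-to-cell variability SD on the log
#'   scale (default 0.30).
#' @param affected_params which of the five parameters planted effects
#'   touch (default all five).
#' @param seed integer seed for the (deterministic) assignment of genes
#'   to effect classes.
#' @return object of class `effect_model`: the effect matrix (genes +
#'   controls by 5 parameters, log scale), the truth table, and the
#'   noise settings.
#' @export
effect_model <- function(genes,
                         fraction_hits_decrease = 0.10,
                         fraction_hits_increase = 0.10,
                         effect_magnitude = 0.25,
                         sd_screen = 0.06,
                         sd_cell = 0.30,
                         affected_params = PARAM_NAMES,
                         seed = 1L) {
  fd <- check_number(fraction_hits_decrease, "fraction_hits_decrease", 0, 1)
  fi <- check_number(fraction_hits_increase, "fraction_hits_increase", 0, 1)
  if (fd + fi > 1) stopf("hit fractions must sum to <= 1")
  effect_magnitude <- check_number(effect_magnitude, "effect_magnitude", 0)
  sd_screen <- check_number(sd_screen, "sd_screen", 0)
  sd_cell <- check_number(sd_cell, "sd_cell", 0)
  if (!all(affected_params %in% PARAM_NAMES))
    stopf("unknown parameter in `affected_params`")
  n <- length(genes)
  n_dec <- round(fd * n); n_inc <- round(fi * n)
  cls <- rep("null", n)
  picked <- with_seed(derive_seed(seed, 101L), sample.int(n, n_dec + n_inc))
  cls[picked[seq_len(n_dec)]] <- "decrease"
  if (n_inc > 0) cls[picked[n_dec + seq_len(n_inc)]] <- "increase"
  eff <- matrix(0, nrow = n + 3L, ncol = length(PARAM_NAMES),
                dimnames = list(c(genes, CONTROL_TREATMENTS), PARAM_NAMES))
  sgn <- ifelse(cls == "decrease", -1, ifelse(cls == "increase", 1, 0))
  eff[seq_len(n), affected_params] <-
    outer(sgn * effect_magnitude, rep(1, length(affected_params)))
  eff["TLN1", ] <- -2 * effect_magnitude
  eff["polyL-lysine", ] <- -3 * effect_magnitude
  eff["control_siRNA", ] <- 0
  truth <- data.frame(gene = genes, class = cls,
                      stringsAsFactors = FALSE)
  for (p in PARAM_NAMES)
    truth[[paste0("dir_", p)]] <- sign(eff[seq_len(n), p])
  structure(list(effects = eff, truth = truth,
                 effect_magnitude = effect_magnitude,
                 sd_screen = sd_screen, sd_cell = sd_cell),
            class = "effect_model")
}

#' Simulate triplicate screens as per-cell feature draws
#'
#' The fast generation tier: instead of rendering images, per-cell
#' parameter values are drawn directly from the phenotype
#' distributions. Each well's five parameters are lognormal around the
#' baseline mean shifted by the gene's effect vector plus a per-(gene,
#' screen) replicate noise term; individual cells add within-well
#' lognormal variability. Every well uses an RNG substream derived
#' deterministically from the master seed, so the dataset is a pure
#' function of (layout, effects, seed) and wells are independent.
#'
#' @param layout plate layout from [plate_layout()] covering all
#'   screens.
#' @param effects an [effect_model()] covering every gene in the
#'   layout.
#' @param cells_per_well cells drawn per well (default 50; the screens
#'   seeded thousands of cells per well, which is unnecessary for
#'   desk-scale statistics).
#' @param seed master integer seed.
#' @param baseline named baseline means of the five parameters.
#' @return list with `cells` (per-cell long table), `layout`, and
#'   `truth` (planted per-gene direction table).
#' @export
simulate_screens <- function(layout, effects, cells_per_well = 50,
                             seed = 1L, baseline = default_baseline()) {
  if (!inherits(effects, "effect_model"))
    stopf("`effects` must be an effect_model")
  cells_per_well <- check_count(cells_per_well, "cells_per_well")
  seed <- check_count(seed, "seed", lower = 0L)
  missing_genes <- setdiff(unique(layout$treatment),
                           rownames(effects$effects))
  if (length(missing_genes))
    stopf("gene(s) missing from effect model: %s",
          paste(utils::head(missing_genes, 5), collapse = ", "))
  if (!all(PARAM_NAMES %in% names(baseline)))
    stopf("`baseline` must name all five parameters")
  log_base <- log(baseline[PARAM_NAMES])
  plates <- sort(unique(layout$plate_id))
  n_par <- length(PARAM_NAMES)

  rows <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    trt <- layout$treatment[i]
    p_idx <- match(layout$plate_id[i], plates)
    w_idx <- match(layout$well_id[i], WELL_IDS_96)
    s_id <- layout$screen_id[i]
    e <- effects$effects[trt, ]
    vals <- with_seed(derive_seed(seed, 23L, p_idx, w_idx, s_id), {
      mu <- log_base + e + stats::rnorm(n_par, 0, effects$sd_screen)
      v <- exp(matrix(rep(mu, each = cells_per_well),
                      nrow = cells_per_well) +
               matrix(stats::rnorm(cells_per_well * n_par, 0,
                                   effects$sd_cell),
                      nrow = cells_per_well))
      colnames(v) <- PARAM_NAMES
      # digitized shapes cannot go below the circular bound
      v[, "inv_form_factor"] <- pmax(v[, "inv_form_factor"], 1)
      v[, "elongation_factor"] <- pmax(v[, "elongation_factor"], 1)
      v
    })
    d <- data.frame(plate_id = layout$plate_id[i],
                    well_id = layout$well_id[i],
                    screen_id = s_id, treatment = trt,
                    cell_id = seq_len(cells_per_well))
    rows[[i]] <- cbind(d, as.data.frame(vals))
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  list(cells = cells, layout = layout, truth = effects$truth)
}

# map a gene's effect vector to shape parameters for the image tier;
# qualitative: area drives body size, elongation its axis ratio,
# nuclear displacement the nucleus offset, and the form-factor /
# gyration effects the tail length
effect_to_shape <- function(e, base = shape_params("polarized")) {
  shape_params("polarized",
               body_radius = base$body_radius * exp(e[["area"]] / 2),
               elongation_target = max(1, base$elongation_target *
                                         exp(e[["elongation_factor"]])),
               tail_length_frac = min(2, max(0, base$tail_length_frac *
                 exp((e[["inv_form_factor"]] + e[["gyration_radius"]]) / 2))),
               nucleus_offset_frac = min(1, max(0, base$nucleus_offset_frac *
                 exp(e[["nuclear_displacement"]]))),
               jitter_sd = base$jitter_sd)
}

#' Simulate screen fields as label-mask TIFF images
#'
#' The image generation tier: renders each well as one or more imaged
#' fields of synthetic cells on a placement grid and writes paired
#' 16-bit label TIFFs named `<plate>_<well>_<field>_{cell,nuc}.tif`
#' inside one `screen_<k>/` directory per replicate screen, plus
#' `layout.csv` and `truth.csv`. Cell-to-cell variability enters
#' through lognormal jitter of the shape parameters; gene effects shift
#' the shape distribution as described in [effect_model()]. Intended
#' for desk-scale runs (a few wells) feeding [features_from_masks()].
#'
#' @inheritParams simulate_screens
#' @param out_dir directory for the TIFFs and CSVs.
#' @param n_fields imaged fields per well (default 8, the acquisition
#'   design of the screens).
#' @param cells_per_field cells rendered per field.
#' @param base_shape baseline [shape_params()] of an unperturbed
#'   polarized cell.
#' @param field_size field image side length in pixels.
#' @return invisibly, a data.frame listing the written mask files.
#' @export
simulate_fields <- function(layout, effects, out_dir, n_fields = 8,
                            cells_per_field = 6, seed = 1L,
                            base_shape = shape_params("polarized",
                                                      jitter_sd = 0.04),
                            field_size = 220) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_fields <- check_count(n_fields, "n_fields")
  cells_per_field <- check_count(cells_per_field, "cells_per_field")
  grid_n <- ceiling(sqrt(cells_per_field))
  tile <- floor(field_size / grid_n)
  plates <- sort(unique(layout$plate_id))
  files <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    trt <- layout$treatment[i]
    e <- effects$effects[trt, ]
    p_idx <- match(layout$plate_id[i], plates)
    w_idx <- match(layout$well_id[i], WELL_IDS_96)
    s_id <- layout$screen_id[i]
    scr_dir <- file.path(out_dir, sprintf("screen_%d", s_id))
    dir.create(scr_dir, showWarnings = FALSE)
    ff <- character(n_fields)
    for (f in seq_len(n_fields)) {
      fseed <- derive_seed(seed, 47L, p_idx, w_idx, s_id, f)
      cellm <- matrix(0L, field_size, field_size)
      nucm <- matrix(0L, field_size, field_size)
      with_seed(fseed, {
        for (k in seq_len(cells_per_field)) {
          sp <- effect_to_shape(e + stats::rnorm(5, 0, effects$sd_cell / 3),
                                base_shape)
          # shrink until the cell fits its grid tile
          while (2 * required_extent(sp) > tile - 4 && sp$body_radius > 3)
            sp$body_radius <- sp$body_radius * 0.9
          sub <- generate_cell_mask(sp, tile - 2L,
                                    seed = round(stats::runif(1) * 1e6))
          r0 <- ((k - 1L) %/% grid_n) * tile + 1L
          c0 <- ((k - 1L) %% grid_n) * tile + 1L
          rr <- r0 + seq_len(tile - 2L)
          cc <- c0 + seq_len(tile - 2L)
          cellm[rr, cc][sub$cell_mask > 0] <- k
          nucm[rr, cc][sub$nucleus_mask > 0] <- k
        }
      })
      base <- sprintf("%s_%s_%d", layout$plate_id[i], layout$well_id[i], f)
      write_label_tiff(cellm, file.path(scr_dir, paste0(base, "_cell.tif")))
      write_label_tiff(nucm, file.path(scr_dir, paste0(base, "_nuc.tif")))
      ff[f] <- file.path(sprintf("screen_%d", s_id), base)
    }
    files[[i]] <- data.frame(plate_id = layout$plate_id[i],
                             well_id = layout$well_id[i],
                             screen_id = s_id, field = seq_len(n_fields),
                             base = ff)
  }
  utils::write.csv(layout, file.path(out_dir, "layout.csv"),
                   row.names = FALSE)
  utils::write.csv(effects$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  invisible(do.call(rbind, files))
}
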