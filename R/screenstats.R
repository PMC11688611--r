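# Plate normalization, per-plate Z-scores and the replicate hit rule.

#' Configuration for screen scoring
#'
#' @param z_threshold absolute Z-score a parameter must reach to count
#'   as perturbed in one screen (default 1.5).
#' @param min_screens number of screens (out of `n_screens`) in which
#'   the threshold must be reached (default 2 of 3).
#' @param n_screens number of replicate screens (default 3).
#' @param sd_mode `"sample"` (n-1 denominator, default, the spreadsheet
#'   STDEV convention) or `"population"`.
#' @param z_variant `"classical"` (mean/SD, the printed formula;
#'   default) or `"robust"` (median and 1.4826*MAD).
#' @param normalization `"ratio_to_control"` (divide by the per-plate
#'   mean of the control_siRNA wells; default) or `"none"`.
#' @param require_sign_consistency when `TRUE` (default) the screens
#'   that pass the threshold must agree in sign for the parameter to be
#'   called; mixed-sign exceedances are not biologically coherent.
#' @param include_controls_in_stats when `TRUE` the plate mean/SD are
#'   computed over all wells; default `FALSE` (library wells only;
#'   controls are the normalization anchor and would shrink the SD).
#' @param min_cells QC threshold on cells per well.
#' @return object of class `screen_config`.
#' @export
screen_config <- function(z_threshold = 1.5, min_screens = 2, n_screens = 3,
                          sd_mode = c("sample", "population"),
                          z_variant = c("classical", "robust"),
                          normalization = c("ratio_to_control", "none"),
                          require_sign_consistency = TRUE,
                          include_controls_in_stats = FALSE,
                          min_cells = 20) {
  z_threshold <- check_number(z_threshold, "z_threshold")
  if (z_threshold <= 0) stopf("`z_threshold` must be > 0")
  n_screens <- check_count(n_screens, "n_screens")
  min_screens <- check_count(min_screens, "min_screens")
  if (min_screens > n_screens)
    stopf("`min_screens` cannot exceed `n_screens`")
  structure(list(z_threshold = z_threshold, min_screens = min_screens,
                 n_screens = n_screens, sd_mode = match.arg(sd_mode),
                 z_variant = match.arg(z_variant),
                 normalization = match.arg(normalization),
                 require_sign_consistency =
                   check_flag(require_sign_consistency,
                              "require_sign_consistency"),
                 include_controls_in_stats =
                   check_flag(include_controls_in_stats,
                              "include_controls_in_stats"),
                 min_cells = check_count(min_cells, "min_cells")),
            class = "screen_config")
}

check_wells <- function(wells) {
  need <- c("plate_id", "well_id", "screen_id", "treatment", "qc_pass",
            PARAM_NAMES)
  miss <- setdiff(need, names(wells))
  if (length(miss))
    stopf("well table is missing column(s): %s", paste(miss, collapse = ", "))
  wells
}

#' Normalize well profiles to per-plate controls
#'
#' Divides each parameter by the mean of that plate's (and screen's)
#' QC-passing `control_siRNA` wells, so control wells map to a
#' per-parameter mean of exactly 1 and library values are fold-changes
#' relative to the non-targeting control. Plates without a usable
#' control, or with a zero control mean, are dropped with a warning.
#'
#' @param wells well-profile data.frame (see [aggregate_cells()]).
#' @param config a [screen_config()]; with `normalization = "none"` the
#'   table is returned unchanged.
#' @return the well table with normalized parameter columns.
#' @export
normalize_plate <- function(wells, config = screen_config()) {
  check_wells(wells)
  if (config$normalization == "none") return(wells)
  key <- interaction(wells$plate_id, wells$screen_id, drop = TRUE)
  parts <- split(wells, key)
  out <- lapply(parts, function(d) {
    ctrl <- d$treatment == "control_siRNA" & d$qc_pass
    if (!any(ctrl)) {
      warnf("plate %s screen %s: no QC-passing control wells; plate dropped",
            d$plate_id[1], d$screen_id[1])
      return(NULL)
    }
    for (p in PARAM_NAMES) {
      cm <- mean(d[[p]][ctrl])
      if (!is.finite(cm) || cm == 0) {
        warnf("plate %s screen %s: control mean for %s is 0; plate dropped",
              d$plate_id[1], d$screen_id[1], p)
        return(NULL)
      }
      d[[p]] <- d[[p]] / cm
    }
    d
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res) || nrow(res) == 0L)
    stopf("no plate retained after control normalization")
  rownames(res) <- NULL
  res
}

#' Per-plate Z-scores for every parameter and screen
#'
#' Standardizes each (plate, screen, parameter) group to
#' \eqn{z = (x - mean) / STDEV}. By default the mean and SD are taken
#' over the plate's QC-passing library wells; control wells are scored
#' against that distribution but do not contribute to it. The robust
#' variant replaces mean/SD with median and 1.4826*MAD.
#'
#' @param wells normalized well profiles (see [normalize_plate()]).
#' @param config a [screen_config()].
#' @return long-format data.frame ("Z-score table"): one row per
#'   (plate, well, screen, parameter) with the normalized value, the
#'   plate centre/scale used and `z`; `is_control` flags control wells.
#' @export
zscore_plate <- function(wells, config = screen_config()) {
  check_wells(wells)
  key <- interaction(wells$plate_id, wells$screen_id, drop = TRUE)
  parts <- split(wells, key)
  out <- list()
  for (d in parts) {
    is_ctrl <- d$treatment %in% CONTROL_TREATMENTS
    scored <- d$qc_pass & (if (config$include_controls_in_stats) TRUE
                           else !is_ctrl)
    if (sum(scored) < 3L)
      stopf("plate %s screen %s: fewer than 3 scored wells",
            d$plate_id[1], d$screen_id[1])
    for (p in PARAM_NAMES) {
      x <- d[[p]]
      xs <- x[scored]
      if (config$z_variant == "classical") {
        ctr <- mean(xs)
        scl <- stats::sd(xs)
        if (config$sd_mode == "population")
          scl <- scl * sqrt((length(xs) - 1) / length(xs))
      } else {
        ctr <- stats::median(xs)
        scl <- stats::mad(xs)  # 1.4826 * MAD
      }
      if (!is.finite(scl) || scl == 0)
        stopf("plate %s screen %s: zero spread for %s, Z undefined",
              d$plate_id[1], d$screen_id[1], p)
      out[[length(out) + 1L]] <- data.frame(
        plate_id = d$plate_id, well_id = d$well_id,
        gene = d$treatment, screen_id = d$screen_id,
        parameter = p, value = x, z = (x - ctr) / scl,
        center = ctr, scale = scl,
        is_control = is_ctrl, qc_pass = d$qc_pass)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score a full multi-plate, multi-screen well table
#'
#' Convenience wrapper: [normalize_plate()] then [zscore_plate()].
#'
#' @inheritParams zscore_plate
#' @return the long-format Z-score table.
#' @export
score_wells <- function(wells, config = screen_config()) {
  zscore_plate(normalize_plate(wells, config), config)
}

#' Call hits with the replicate-consistency rule
#'
#' A parameter of a gene counts as perturbed when its |Z| reaches
#' `z_threshold` in at least `min_screens` of the replicate screens
#' (by default additionally with a consistent sign across those
#' screens). A gene is a hit when one or more of the five parameters
#' is perturbed. The phenotype class is `decreased_polarity` when all
#' perturbed parameters move down, `increased_polarity` when all move
#' up, and `mixed` otherwise. Genes with usable scores in fewer than
#' `min_screens` screens are reported as not evaluable (never as
#' non-hits).
#'
#' @param ztab Z-score table from [score_wells()] covering all screens.
#' @param config a [screen_config()].
#' @param include_controls also call control wells (default `FALSE`).
#' @return data.frame with one row per gene: `evaluable`, `hit`,
#'   `phenotype_class`, `n_parameters_perturbed`, and per-parameter
#'   `sig_*`, `dir_*`, `nsig_*` columns.
#' @export
call_hits <- function(ztab, config = screen_config(),
                      include_controls = FALSE) {
  need <- c("gene", "screen_id", "parameter", "z", "qc_pass")
  miss <- setdiff(need, names(ztab))
  if (length(miss))
    stopf("Z-score table missing column(s): %s", paste(miss, collapse = ", "))
  tab <- ztab[ztab$qc_pass, , drop = FALSE]
  if (!include_controls)
    tab <- tab[!(tab$gene %in% CONTROL_TREATMENTS), , drop = FALSE]
  genes <- sort(unique(tab$gene))
  thr <- config$z_threshold
  dropped <- 0L
  rows <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    gt <- tab[tab$gene == g, , drop = FALSE]
    row <- list(gene = g)
    n_usable <- length(unique(gt$screen_id))
    row$evaluable <- n_usable >= config$min_screens
    sig <- dir <- nsig <- stats::setNames(numeric(length(PARAM_NAMES)),
                                          PARAM_NAMES)
    for (p in PARAM_NAMES) {
      z <- gt$z[gt$parameter == p]
      z <- z[!is.na(z)]
      n_pos <- sum(z >= thr); n_neg <- sum(z <= -thr)
      if (config$require_sign_consistency) {
        hit_p <- max(n_pos, n_neg) >= config$min_screens
        d <- if (!hit_p) 0 else if (n_pos >= n_neg) 1 else -1
        ns <- max(n_pos, n_neg)
      } else {
        ns <- n_pos + n_neg
        hit_p <- ns >= config$min_screens
        d <- if (!hit_p) 0 else sign(sum(sign(z[abs(z) >= thr])))
        if (hit_p && d == 0) d <- sign(sum(z[abs(z) >= thr]))
      }
      sig[p] <- as.numeric(hit_p && row$evaluable)
      dir[p] <- if (sig[p] > 0) d else 0
      nsig[p] <- ns
    }
    if (!row$evaluable) dropped <- dropped + 1L
    row$hit <- row$evaluable && any(sig > 0)
    n_pert <- sum(sig > 0)
    dirs <- dir[sig > 0]
    row$phenotype_class <- if (!row$hit) NA_character_
      else if (all(dirs < 0)) "decreased_polarity"
      else if (all(dirs > 0)) "increased_polarity"
      else "mixed"
    row$n_parameters_perturbed <- n_pert
    for (p in PARAM_NAMES) {
      row[[paste0("sig_", p)]] <- sig[p] > 0
      row[[paste0("dir_", p)]] <- dir[p]
      row[[paste0("nsig_", p)]] <- nsig[p]
    }
    rows[[gi]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  if (dropped > 0)
    warnf("%d gene(s) scored in fewer than %d screens: not evaluable",
          dropped, config$min_screens)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Summarize a hit list
#'
#' @param hits output of [call_hits()].
#' @return list with library size, evaluable count, hit counts and
#'   fractions by phenotype class.
#' @export
summarize_screen <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) stopf("empty hit list")
  ev <- hits[hits$evaluable, , drop = FALSE]
  n <- nrow(ev)
  cls <- ev$phenotype_class[ev$hit]
  list(n_genes = nrow(hits),
       n_evaluable = n,
       n_hits = sum(ev$hit),
       n_decreased = sum(cls == "decreased_polarity"),
       n_increased = sum(cls == "increased_polarity"),
       n_mixed = sum(cls == "mixed"),
       fraction_hits = if (n) sum(ev$hit) / n else 0,
       fraction_decreased = if (n) sum(cls == "decreased_polarity") / n else 0,
       fraction_increased = if (n) sum(cls == "increased_polarity") / n else 0)
}

#' Compare hit calls against planted truth
#'
#' Confusion-matrix summary of a synthetic run: sensitivity (planted
#' hits recovered), specificity (planted nulls not called) and the
#' fraction of recovered hits whose phenotype class matches the planted
#' direction.
#'
#' @param hits output of [call_hits()].
#' @param truth truth table from the generator (`gene`, `class`).
#' @return list with `sensitivity`, `specificity`,
#'   `direction_accuracy`, and the underlying counts.
#' @export
evaluate_against_truth <- function(hits, truth) {
  m <- merge(hits[hits$evaluable, ], truth, by = "gene")
  planted <- m$class != "null"
  tp <- sum(planted & m$hit)
  fn <- sum(planted & !m$hit)
  tn <- sum(!planted & !m$hit)
  fp <- sum(!planted & m$hit)
  rec <- m[planted & m$hit, , drop = FALSE]
  dir_ok <- sum((rec$class == "decrease" &
                   rec$phenotype_class == "decreased_polarity") |
                (rec$class == "increase" &
                   rec$phenotype_class == "increased_polarity"))
  list(sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
       direction_accuracy = if (nrow(rec)) dir_ok / nrow(rec) else NA_real_,
       tp = tp, fn = fn, tn = tn, fp = fp, n_recovered = nrow(rec))
}
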