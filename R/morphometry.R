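# Per-cell morphometry from paired label masks: the five polarity
# read-outs, aggregated to well level.

#' Crofton perimeter of a binary mask
#'
#' Multi-directional boundary-length estimator based on the
#' Cauchy-Crofton formula: the number of intersections between the
#' object boundary and families of parallel test lines in four
#' directions (0, 45, 90, 135 degrees) is converted to a length. Unlike
#' a raw pixel-edge count (which converges to 8R, not 2*pi*R, for a
#' disk) this estimator is asymptotically unbiased for smooth shapes;
#' a rasterized disk of radius 100 px is measured to well within 2%.
#'
#' @param mask logical or 0/1 matrix, object = TRUE/1.
#' @return estimated boundary length in pixel units.
#' @export
crofton_perimeter <- function(mask) {
  m <- mask > 0
  if (!any(m)) return(0)
  # pad so boundary crossings at the image edge are counted
  mp <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  mp[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  nr <- nrow(mp); nc <- ncol(mp)
  n0   <- sum(mp[, -1L] != mp[, -nc])           # lines along rows
  n90  <- sum(mp[-1L, ] != mp[-nr, ])           # lines along columns
  n45  <- sum(mp[-nr, -nc] != mp[-1L, -1L])     # diagonal, spacing 1/sqrt(2)
  n135 <- sum(mp[-1L, -nc] != mp[-nr, -1L])
  (pi / 8) * (n0 + n90 + (n45 + n135) / sqrt(2))
}

# centroid, gyration radius and equivalent-ellipse axis ratio from
# pixel-centre coordinates of one labelled region
region_moments <- function(x, y) {
  cx <- mean(x); cy <- mean(y)
  dx <- x - cx; dy <- y - cy
  gyr <- sqrt(mean(dx^2 + dy^2))
  if (length(x) < 3L) {
    elong <- 1
  } else {
    mxx <- mean(dx^2); myy <- mean(dy^2); mxy <- mean(dx * dy)
    tr <- mxx + myy
    det <- mxx * myy - mxy^2
    disc <- sqrt(max(tr^2 / 4 - det, 0))
    l1 <- tr / 2 + disc
    l2 <- tr / 2 - disc
    elong <- if (l2 <= .Machine$double.eps * l1) Inf else sqrt(l1 / l2)
    if (!is.finite(elong) || elong < 1) elong <- max(elong, 1)
  }
  list(cx = cx, cy = cy, gyration = gyr, elongation = elong)
}

#' Compute the five morphology parameters per segmented cell
#'
#' For every cell label in the pair that has a matched nucleus and does
#' not touch the image border, computes:
#' \describe{
#'   \item{inv_form_factor}{\eqn{P^2/(4\pi A)}, a roundness index, 1 for
#'     a perfect circle, increasing with shape complexity; perimeter via
#'     [crofton_perimeter()].}
#'   \item{nuclear_displacement}{Euclidean distance between the nucleus
#'     centroid and the cell centroid (length units; optionally
#'     normalized by the cell's equivalent radius).}
#'   \item{area}{pixel count times `pixel_size^2`.}
#'   \item{gyration_radius}{root-mean-square distance of cell pixels
#'     from the cell centroid, a measure of cell spread.}
#'   \item{elongation_factor}{major/minor axis ratio of the
#'     moment-equivalent ellipse (cell length over width), >= 1.}
#' }
#' Nuclei are matched to the cell label covering the majority of their
#' pixels; nuclei with no enclosing cell are skipped and counted in the
#' `skipped_nuclei` attribute.
#'
#' @param pair a [labeled_image_pair()].
#' @param exclude_border drop cells touching the image border (their
#'   shape is truncated). Default `TRUE`.
#' @param normalize_displacement divide nuclear displacement by the
#'   cell's equivalent radius \eqn{\sqrt{A/\pi}}. Default `FALSE`
#'   (plain length units).
#' @return a data.frame with one row per measured cell: `cell_id`, the
#'   five parameters, centroids of cell and nucleus, `perimeter`.
#' @export
compute_cell_features <- function(pair, exclude_border = TRUE,
                                  normalize_displacement = FALSE) {
  if (!inherits(pair, "labeled_image_pair"))
    stopf("`pair` must be a labeled_image_pair")
  cm <- pair$cell_mask
  nm <- pair$nucleus_mask
  px <- pair$pixel_size
  empty <- data.frame(cell_id = integer(0), area = numeric(0),
                      perimeter = numeric(0), inv_form_factor = numeric(0),
                      nuclear_displacement = numeric(0),
                      gyration_radius = numeric(0),
                      elongation_factor = numeric(0),
                      cell_x = numeric(0), cell_y = numeric(0),
                      nucleus_x = numeric(0), nucleus_y = numeric(0))
  cell_ids <- sort(unique(cm[cm > 0]))
  if (!length(cell_ids)) return(empty)

  nr <- nrow(cm); ncl <- ncol(cm)
  idx <- which(cm > 0)
  row_i <- (idx - 1L) %% nr + 1L
  col_i <- (idx - 1L) %/% nr + 1L
  lab <- cm[idx]
  pix <- split(seq_along(idx), lab)

  # nucleus -> cell assignment by majority pixel overlap
  nuc_ids <- sort(unique(nm[nm > 0]))
  nuc_of_cell <- list()
  skipped <- 0L
  for (nid in nuc_ids) {
    nidx <- which(nm == nid)
    over <- cm[nidx]
    over <- over[over > 0]
    if (!length(over)) { skipped <- skipped + 1L; next }
    host <- as.integer(names(which.max(table(over))))
    nrow_i <- (nidx - 1L) %% nr + 1L
    ncol_i <- (nidx - 1L) %/% nr + 1L
    cand <- list(x = mean(ncol_i), y = mean(nrow_i))
    key <- as.character(host)
    # keep the largest nucleus if several claim the same cell
    if (is.null(nuc_of_cell[[key]]) ||
        length(nidx) > nuc_of_cell[[key]]$n) {
      nuc_of_cell[[key]] <- c(cand, n = length(nidx))
    }
  }

  out <- vector("list", length(cell_ids))
  for (k in seq_along(cell_ids)) {
    cid <- cell_ids[k]
    sel <- pix[[as.character(cid)]]
    ri <- row_i[sel]; ci <- col_i[sel]
    if (exclude_border &&
        (any(ri == 1L) || any(ri == nr) || any(ci == 1L) || any(ci == ncl)))
      next
    nuc <- nuc_of_cell[[as.character(cid)]]
    if (is.null(nuc)) next
    mom <- region_moments(ci, ri)
    sub <- matrix(FALSE, max(ri) - min(ri) + 1L, max(ci) - min(ci) + 1L)
    sub[cbind(ri - min(ri) + 1L, ci - min(ci) + 1L)] <- TRUE
    per <- crofton_perimeter(sub) * px
    area <- length(sel) * px^2
    ndisp <- sqrt((nuc$x - mom$cx)^2 + (nuc$y - mom$cy)^2) * px
    if (normalize_displacement) ndisp <- ndisp / sqrt(area / pi)
    out[[k]] <- data.frame(
      cell_id = cid, area = area, perimeter = per,
      inv_form_factor = inv_form_factor(per, area),
      nuclear_displacement = ndisp,
      gyration_radius = mom$gyration * px,
      elongation_factor = mom$elongation,
      cell_x = mom$cx * px, cell_y = mom$cy * px,
      nucleus_x = nuc$x * px, nucleus_y = nuc$y * px)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- empty
  if (skipped > 0)
    warnf("%d nucleus label(s) without an enclosing cell were skipped",
          skipped)
  attr(res, "skipped_nuclei") <- skipped
  res
}

#' Aggregate per-cell records to one well profile
#'
#' Arithmetic mean (or median) of each of the five parameters over all
#' cells measured in a well, pooled across that well's imaged fields.
#' QC fails when fewer than `min_cells` cells were measured.
#'
#' @param records data.frame of cell records from
#'   [compute_cell_features()], all from one well of one screen.
#' @param min_cells minimum cell count for `qc_pass` (default 20,
#'   matched to the synthetic desk scale).
#' @param fun aggregation: `"mean"` (default) or `"median"`.
#' @param well_id,plate_id,screen_id,treatment annotation carried into
#'   the profile.
#' @return one-row data.frame with `n_cells`, `qc_pass` and the mean of
#'   each of the five parameters.
#' @export
aggregate_well <- function(records, min_cells = 20, fun = c("mean", "median"),
                           well_id = NA, plate_id = NA, screen_id = NA,
                           treatment = NA) {
  fun <- match.arg(fun)
  if (is.null(records) || nrow(records) == 0L)
    stopf("no cell records to aggregate")
  min_cells <- check_count(min_cells, "min_cells", lower = 1L)
  f <- if (fun == "mean") mean else stats::median
  vals <- vapply(PARAM_NAMES, function(p) f(records[[p]]), numeric(1))
  out <- data.frame(plate_id = plate_id, well_id = well_id,
                    screen_id = screen_id, treatment = treatment,
                    n_cells = nrow(records),
                    qc_pass = nrow(records) >= min_cells)
  for (p in PARAM_NAMES) out[[p]] <- vals[[p]]
  out
}

#' Aggregate a full per-cell table to well profiles
#'
#' Convenience wrapper around [aggregate_well()] for a table carrying
#' `plate_id`, `well_id`, `screen_id` (and optionally `treatment`)
#' columns, as written by the simulator or by [features_from_masks()].
#'
#' @param cells per-cell data.frame.
#' @param layout optional plate layout (from [plate_layout()] or
#'   `layout.csv`) used to annotate treatments.
#' @inheritParams aggregate_well
#' @return data.frame of well profiles, one row per
#'   (plate, well, screen).
#' @export
aggregate_cells <- function(cells, layout = NULL, min_cells = 20,
                            fun = "mean") {
  key <- interaction(cells$plate_id, cells$well_id, cells$screen_id,
                     drop = TRUE)
  parts <- split(cells, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    aggregate_well(d, min_cells = min_cells, fun = fun,
                   well_id = d$well_id[1], plate_id = d$plate_id[1],
                   screen_id = d$screen_id[1],
                   treatment = if ("treatment" %in% names(d))
                     d$treatment[1] else NA)
  }))
  rownames(out) <- NULL
  if (!is.null(layout)) {
    m <- match(paste(out$plate_id, out$well_id, out$screen_id),
               paste(layout$plate_id, layout$well_id, layout$screen_id))
    out$treatment <- layout$treatment[m]
  }
  out
}

#' Read mask TIFFs and compute per-cell features for a whole run
#'
#' Scans a directory (recursively) for files named
#' `<plate>_<well>_<field>_cell.tif` / `..._nuc.tif` (as written by
#' [simulate_fields()]), pairs them, and runs
#' [compute_cell_features()] on each field. The replicate screen is
#' taken from an enclosing `screen_<k>` directory when present,
#' otherwise from the layout.
#'
#' @param mask_dir directory of 16-bit label TIFFs.
#' @param layout plate layout table mapping wells to treatments and
#'   screens (needs `plate_id`, `well_id`, `screen_id`, `treatment`).
#' @param pixel_size physical pixel side length.
#' @param ... passed to [compute_cell_features()].
#' @return per-cell data.frame with plate/well/screen/field annotation.
#' @export
features_from_masks <- function(mask_dir, layout, pixel_size = 1, ...) {
  files <- list.files(mask_dir, pattern = "_cell\\.tif$",
                      full.names = TRUE, recursive = TRUE)
  if (!length(files)) stopf("no *_cell.tif masks found in %s", mask_dir)
  out <- lapply(files, function(f) {
    base <- sub("_cell\\.tif$", "", basename(f))
    parts <- strsplit(base, "_", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stopf("mask file name %s does not follow <plate>_<well>_<field>", f)
    field <- parts[length(parts)]
    well <- parts[length(parts) - 1L]
    plate <- paste(parts[seq_len(length(parts) - 2L)], collapse = "_")
    nf <- file.path(dirname(f), paste0(base, "_nuc.tif"))
    if (!file.exists(nf)) stopf("missing nucleus mask %s", nf)
    sdir <- regmatches(basename(dirname(f)),
                       regexec("^screen_(\\d+)$", basename(dirname(f))))[[1]]
    m <- match(paste(plate, well), paste(layout$plate_id, layout$well_id))
    screen <- if (length(sdir)) as.integer(sdir[2])
              else if (any(!is.na(m))) layout$screen_id[m[1]] else NA
    pair <- labeled_image_pair(read_label_tiff(f), read_label_tiff(nf),
                               pixel_size = pixel_size, field_id = field,
                               well_id = well, plate_id = plate,
                               screen_id = screen)
    feats <- compute_cell_features(pair, ...)
    if (nrow(feats)) {
      feats$plate_id <- plate; feats$well_id <- well
      feats$screen_id <- screen; feats$field_id <- field
      if (any(!is.na(m))) feats$treatment <- layout$treatment[m[1]]
    }
    feats
  })
  out <- out[vapply(out, nrow, integer(1)) > 0L]
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read a 16-bit label TIFF
#'
#' Label images are stored as single-channel 16-bit TIFFs (labels up to
#' 65535), the interchange format between the simulator and the
#' morphometry stage.
#'
#' @param mask integer matrix of labels (background 0).
#' @param path output file.
#' @return `read_label_tiff` returns an integer matrix.
#' @export
write_label_tiff <- function(mask, path) {
  if (any(mask < 0) || any(mask > 65535))
    stopf("labels must fit in 16 bits")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  storage.mode(img) <- "integer"
  img
}
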