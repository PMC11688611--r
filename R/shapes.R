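# Synthetic cell silhouettes: parametric "round", "elongated" and
# polarized ("hand-mirror") shapes rasterized into label masks.

#' Shape parameters for one synthetic cell
#'
#' Describes the silhouette drawn by [generate_cell_mask()]. A resting
#' T cell is approximately circular; a cell polarized on immobilized
#' anti-LFA-1 adopts a hand-mirror outline: an elongated body with a
#' tapering trailing tail (uropod) and the nucleus displaced toward the
#' leading edge.
#'
#' @param phenotype_class one of `"round"`, `"elongated"`, `"polarized"`.
#' @param body_radius equivalent body radius in pixels (area of the body
#'   ellipse is kept at `pi * body_radius^2` whatever the elongation).
#' @param elongation_target major/minor axis ratio of the body ellipse
#'   (>= 1; 1 forces a circular body and is the only value allowed for
#'   the `"round"` class).
#' @param tail_length_frac tail length as a fraction of the body length
#'   (diameter along the major axis), in `[0, 2]`. Used only by the
#'   `"polarized"` class.
#' @param nucleus_offset_frac displacement of the nucleus centre toward
#'   the leading edge, as a fraction of `body_radius`, in `[0, 1]`.
#' @param jitter_sd relative amplitude of smooth radial boundary noise
#'   (>= 0; 0 gives the exact analytic outline).
#' @return an object of class `shape_params`.
#' @examples
#' shape_params("polarized", body_radius = 14, elongation_target = 1.8,
#'              tail_length_frac = 0.8, nucleus_offset_frac = 0.4)
#' @export
shape_params <- function(phenotype_class = c("round", "polarized", "elongated"),
                         body_radius = 12,
                         elongation_target = NULL,
                         tail_length_frac = 0.8,
                         nucleus_offset_frac = 0.35,
                         jitter_sd = 0) {
  phenotype_class <- match.arg(phenotype_class)
  if (is.null(elongation_target))
    elongation_target <- switch(phenotype_class,
                                round = 1, elongated = 2, polarized = 1.8)
  body_radius <- check_number(body_radius, "body_radius")
  if (body_radius <= 0) stopf("`body_radius` must be > 0")
  elongation_target <- check_number(elongation_target, "elongation_target",
                                    lower = 1)
  if (phenotype_class == "round" && elongation_target != 1)
    stopf("round cells must have elongation_target = 1")
  tail_length_frac <- check_number(tail_length_frac, "tail_length_frac",
                                   lower = 0, upper = 2)
  nucleus_offset_frac <- check_number(nucleus_offset_frac,
                                      "nucleus_offset_frac",
                                      lower = 0, upper = 1)
  jitter_sd <- check_number(jitter_sd, "jitter_sd", lower = 0)
  structure(list(phenotype_class = phenotype_class,
                 body_radius = body_radius,
                 elongation_target = elongation_target,
                 tail_length_frac = tail_length_frac,
                 nucleus_offset_frac = nucleus_offset_frac,
                 jitter_sd = jitter_sd),
            class = "shape_params")
}

#' Paired cell/nucleus label masks for one imaged field
#'
#' The morphometry input: two integer label images of identical size,
#' background 0, where nucleus label `k` belongs to cell label `k`.
#' Coordinates are pixel centres, origin top-left, `x` = column,
#' `y` = row.
#'
#' @param cell_mask,nucleus_mask integer matrices of equal dimensions.
#' @param pixel_size physical side length of one pixel (default 1, i.e.
#'   results in pixel units).
#' @param field_id,well_id,plate_id,screen_id identifiers carried along.
#' @return an object of class `labeled_image_pair`.
#' @export
labeled_image_pair <- function(cell_mask, nucleus_mask, pixel_size = 1,
                               field_id = NA, well_id = NA,
                               plate_id = NA, screen_id = NA) {
  if (!is.matrix(cell_mask) || !is.matrix(nucleus_mask))
    stopf("masks must be matrices")
  if (!identical(dim(cell_mask), dim(nucleus_mask)))
    stopf("cell and nucleus masks must share dimensions")
  if (any(cell_mask < 0) || any(nucleus_mask < 0))
    stopf("labels must be non-negative integers")
  pixel_size <- check_number(pixel_size, "pixel_size")
  if (pixel_size <= 0) stopf("`pixel_size` must be > 0")
  structure(list(cell_mask = cell_mask, nucleus_mask = nucleus_mask,
                 pixel_size = pixel_size, field_id = field_id,
                 well_id = well_id, plate_id = plate_id,
                 screen_id = screen_id),
            class = "labeled_image_pair")
}

# radial jitter profile: smooth low-order Fourier modulation of the
# boundary radius, deterministic for a given RNG state
sample_jitter_fun <- function(jitter_sd, orders = 2:5) {
  if (jitter_sd == 0) return(function(theta) rep(1, length(theta)))
  amp_c <- stats::rnorm(length(orders), 0, jitter_sd / sqrt(2 * length(orders)))
  amp_s <- stats::rnorm(length(orders), 0, jitter_sd / sqrt(2 * length(orders)))
  function(theta) {
    f <- rep(1, length(theta))
    for (i in seq_along(orders))
      f <- f + amp_c[i] * cos(orders[i] * theta) +
        amp_s[i] * sin(orders[i] * theta)
    pmax(f, 0.2)  # keep the outline star-shaped and connected
  }
}

# rasterize one cell into logical masks on an image_size x image_size
# grid; centre and orientation (phi, radians) given in pixel coords
rasterize_cell <- function(params, image_size, centre, phi, jitter_fun) {
  a <- params$body_radius * sqrt(params$elongation_target)
  b <- params$body_radius / sqrt(params$elongation_target)
  tail_len <- if (params$phenotype_class == "polarized")
    params$tail_length_frac * 2 * a else 0

  xs <- matrix(rep(seq_len(image_size), each = image_size),
               nrow = image_size)           # x = column index
  ys <- matrix(rep(seq_len(image_size), times = image_size),
               nrow = image_size)           # y = row index
  u <- (xs - centre[1]) * cos(phi) + (ys - centre[2]) * sin(phi)
  v <- -(xs - centre[1]) * sin(phi) + (ys - centre[2]) * cos(phi)

  # body: jittered ellipse, jitter applied on the normalized radius
  theta <- atan2(v / b, u / a)
  rad2 <- (u / a)^2 + (v / b)^2
  body <- rad2 <= jitter_fun(theta)^2

  cell <- body
  if (tail_len > 0) {
    # tapering tail along -u, overlapping the body rear so the union
    # stays a single connected component
    root <- -0.7 * a
    tip <- -(a + tail_len)
    wbase <- 0.55 * b
    frac <- (u - tip) / (root - tip)
    # floor of 0.7 px keeps the tapering tip connected after rasterization
    tail <- u >= tip & u <= root & abs(v) <= pmax(wbase * frac, 0.7)
    cell <- cell | tail
  }

  # nucleus: disk displaced toward the leading edge (+u), shrunk or
  # pulled back until strictly inside the cell mask
  rn <- 0.5 * b
  offset <- params$nucleus_offset_frac * params$body_radius
  offset <- min(offset, a - rn - 1)
  offset <- max(offset, 0)
  for (try in 1:25) {
    nuc <- (u - offset)^2 + v^2 <= rn^2
    if (any(nuc) && all(cell[nuc])) break
    if (offset > 0.5) offset <- offset * 0.8 else rn <- rn * 0.85
  }
  if (!any(nuc) || !all(cell[nuc]))
    stopf("could not place nucleus inside cell mask")
  list(cell = cell, nucleus = nuc)
}

required_extent <- function(params) {
  a <- params$body_radius * sqrt(params$elongation_target)
  tail_len <- if (params$phenotype_class == "polarized")
    params$tail_length_frac * 2 * a else 0
  (a + tail_len) * (1 + 4 * params$jitter_sd) + 2
}

#' Generate one synthetic cell as a label-mask pair
#'
#' Rasterizes a single cell of the requested phenotype class into a
#' square image: an elliptical body (circular for `"round"`), plus a
#' tapering tail and a nucleus displaced toward the leading edge for
#' `"polarized"`. The output is deterministic for fixed
#' `(params, seed)`; the cell is a single connected component and the
#' nucleus lies strictly inside it.
#'
#' @param params a [shape_params()] object.
#' @param image_size side length of the square image in pixels.
#' @param seed integer seed controlling orientation and boundary jitter.
#' @param orientation optional fixed orientation in radians; when `NULL`
#'   an orientation is drawn from the seed.
#' @return a [labeled_image_pair()] with one cell label and one nucleus
#'   label.
#' @examples
#' pair <- generate_cell_mask(shape_params("polarized"), 96, seed = 1)
#' table(pair$cell_mask)
#' @export
generate_cell_mask <- function(params, image_size, seed,
                               orientation = NULL) {
  if (!inherits(params, "shape_params")) stopf("`params` must be shape_params")
  image_size <- check_count(image_size, "image_size", lower = 8L)
  seed <- check_count(seed, "seed", lower = 0L)
  if (2 * required_extent(params) > image_size - 2)
    stopf("shape (extent %.1f px) exceeds image bounds (%d px)",
          2 * required_extent(params), image_size)
  masks <- with_seed(derive_seed(seed, 811L), {
    phi <- if (is.null(orientation)) stats::runif(1, 0, pi) else orientation
    jf <- sample_jitter_fun(params$jitter_sd)
    centre <- rep((image_size + 1) / 2, 2)
    # for polarized cells shift the centre so body + tail stay centred
    if (params$phenotype_class == "polarized") {
      a <- params$body_radius * sqrt(params$elongation_target)
      shift <- params$tail_length_frac * a / 2
      centre <- centre + shift * c(cos(phi), sin(phi))
    }
    rasterize_cell(params, image_size, centre, phi, jf)
  })
  stopifnot(n_components(masks$cell) == 1L)
  labeled_image_pair(cell_mask = matrix(as.integer(masks$cell),
                                        nrow = image_size),
                     nucleus_mask = matrix(as.integer(masks$nucleus),
                                           nrow = image_size))
}

# connected components of a logical matrix (8-connectivity), small
# flood-fill based labeller; also used to validate generated masks
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  nr <- nrow(mask)
  idx <- which(mask & lab == 0L)
  while (length(idx)) {
    nxt <- nxt + 1L
    queue <- idx[1]
    lab[queue] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      up_ok <- (cur - 1L) %% nr != 0L     # not in first row
      dn_ok <- cur %% nr != 0L            # not in last row
      for (spec in list(list(-1L, up_ok), list(1L, dn_ok),
                        list(-nr, TRUE), list(nr, TRUE),
                        list(-nr - 1L, up_ok), list(-nr + 1L, dn_ok),
                        list(nr - 1L, up_ok), list(nr + 1L, dn_ok))) {
        nb <- cur + spec[[1L]]
        ok <- nb >= 1L & nb <= length(mask) & spec[[2L]]
        nb <- nb[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        lab[nb] <- nxt
        queue <- c(queue, nb)
      }
      queue <- unique(queue)
    }
    idx <- which(mask & lab == 0L)
  }
  lab
}

n_components <- function(mask) max(label_components(mask))
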