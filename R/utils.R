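# Internal helpers: seed substreams, input checks, small numerics.

# The five morphology read-outs, in canonical order.
PARAM_NAMES <- c("inv_form_factor", "nuclear_displacement", "area",
                 "gyration_radius", "elongation_factor")

# Treatment labels reserved for controls on every plate.
CONTROL_TREATMENTS <- c("control_siRNA", "TLN1", "polyL-lysine")

#' Derive a reproducible integer sub-seed
#'
#' Wells, fields and cells each get an independent RNG substream derived
#' deterministically from one master seed by folding the key components
#' through a multiplicative integer hash (modulus 2147483629, a prime
#' below 2^31, so the result is always a valid R seed). Identical keys
#' always give identical substreams; distinct keys give streams that are
#' independent for practical purposes.
#'
#' @param master integer master seed.
#' @param ... additional integer key components (plate index, well index,
#'   screen id, a purpose code, ...).
#' @return a single integer in [1, 2147483628].
#' @keywords internal
derive_seed <- function(master, ...) {
  keys <- c(as.numeric(master), vapply(list(...), as.numeric, numeric(1)))
  m <- 2147483629
  h <- 17
  for (k in keys) {
    # keep the intermediate product under 2^53 so double arithmetic is exact
    h <- ((h * 48271) %% m + (abs(k) %% m) + 1) %% m
    h <- (h * 69621) %% m
  }
  as.integer(h + 1)
}

# run expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be TRUE or FALSE", name)
  x
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be a single number", name)
  if (x < lower || x > upper)
    stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  as.numeric(x)
}

check_count <- function(x, name, lower = 1L) {
  x <- check_number(x, name, lower = lower)
  if (x != round(x)) stopf("`%s` must be an integer", name)
  as.integer(x)
}

#' Inverse form factor from perimeter and area
#'
#' The roundness index \eqn{P^2 / (4 \pi A)}: exactly 1 for a perfect
#' circle and growing without bound as the outline becomes more complex
#' or elongated. Works on analytic values or on measurements from masks.
#'
#' @param perimeter boundary length (same length unit as `area`'s side).
#' @param area enclosed area.
#' @return the dimensionless roundness index.
#' @examples
#' inv_form_factor(perimeter = 2 * pi * 5, area = pi * 25)  # circle -> 1
#' @export
inv_form_factor <- function(perimeter, area) {
  if (any(area <= 0)) stopf("`area` must be positive")
  perimeter^2 / (4 * pi * area)
}
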