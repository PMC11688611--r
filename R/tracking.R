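# Live-cell motility metrics from time-stamped centroid tracks.

#' Motility metrics for one track
#'
#' From an ordered sequence of (t, x, y) positions computes the three
#' standard tracking read-outs:
#' \describe{
#'   \item{origin_of_distance}{straight-line distance from the starting
#'     point to the (final) object position.}
#'   \item{velocity}{net directional displacement divided by elapsed
#'     time.}
#'   \item{speed}{summed inter-point path length divided by elapsed
#'     time; always >= velocity.}
#' }
#'
#' @param t numeric times, strictly increasing (e.g. one frame every
#'   50 s).
#' @param x,y coordinates in length units.
#' @param per_frame when `TRUE` also return the per-frame
#'   origin-of-distance series.
#' @return list with `origin_of_distance`, `velocity`, `speed`,
#'   `path_length`, `duration` (and `origin_series` if requested).
#' @examples
#' track_metrics(t = c(0, 1, 2), x = c(0, 3, 3), y = c(0, 0, 4))
#' @export
track_metrics <- function(t, x, y, per_frame = FALSE) {
  if (length(t) < 2L) stopf("a track needs at least 2 points")
  if (length(x) != length(t) || length(y) != length(t))
    stopf("t, x, y must have equal length")
  if (any(!is.finite(t)) || any(!is.finite(x)) || any(!is.finite(y)))
    stopf("track coordinates must be finite")
  if (any(diff(t) <= 0)) stopf("times must be strictly increasing")
  elapsed <- t[length(t)] - t[1L]
  net <- sqrt((x[length(x)] - x[1L])^2 + (y[length(y)] - y[1L])^2)
  path <- sum(sqrt(diff(x)^2 + diff(y)^2))
  out <- list(origin_of_distance = net,
              velocity = net / elapsed,
              speed = path / elapsed,
              path_length = path,
              duration = elapsed)
  if (per_frame)
    out$origin_series <- sqrt((x - x[1L])^2 + (y - y[1L])^2)
  out
}

#' Motility metrics for a table of tracks
#'
#' @param tracks data.frame with columns `track_id`, `t`, `x`, `y` (as
#'   read from a tracking CSV).
#' @return data.frame of per-track metrics.
#' @export
track_metrics_table <- function(tracks) {
  need <- c("track_id", "t", "x", "y")
  miss <- setdiff(need, names(tracks))
  if (length(miss))
    stopf("track table missing column(s): %s", paste(miss, collapse = ", "))
  parts <- split(tracks, tracks$track_id)
  out <- do.call(rbind, lapply(parts, function(d) {
    d <- d[order(d$t), ]
    m <- track_metrics(d$t, d$x, d$y)
    data.frame(track_id = d$track_id[1L], n_points = nrow(d),
               duration = m$duration,
               origin_of_distance = m$origin_of_distance,
               velocity = m$velocity, speed = m$speed,
               path_length = m$path_length)
  }))
  rownames(out) <- NULL
  out
}

#' Population summary of track metrics
#'
#' Means and medians of the three metrics over tracks lasting at least
#' `min_duration`; shorter tracks are excluded from the summary (their
#' metrics are unstable).
#'
#' @param metrics output of [track_metrics_table()].
#' @param min_duration minimum track duration (same units as `t`).
#' @return one-row data.frame of summary statistics.
#' @export
summarize_tracks <- function(metrics, min_duration = 0) {
  keep <- metrics[metrics$duration >= min_duration, , drop = FALSE]
  if (!nrow(keep)) stopf("no track meets the minimum duration")
  data.frame(n_tracks = nrow(keep),
             mean_velocity = mean(keep$velocity),
             median_velocity = stats::median(keep$velocity),
             mean_origin_of_distance = mean(keep$origin_of_distance),
             median_origin_of_distance =
               stats::median(keep$origin_of_distance),
             mean_speed = mean(keep$speed),
             median_speed = stats::median(keep$speed))
}
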