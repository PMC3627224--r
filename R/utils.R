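# Interval utilities shared across modules. Intervals are data.frames with
# columns label, t_start, t_end; times in seconds throughout.

#' Build an interval table
#'
#' @param label character vector of labels.
#' @param t_start,t_end numeric vectors of interval bounds (seconds).
#' @return A data.frame with columns `label`, `t_start`, `t_end`.
#' @export
intervals_df <- function(label, t_start, t_end) {
  stopifnot(length(t_start) == length(t_end), all(t_end >= t_start))
  data.frame(label = as.character(label), t_start = as.numeric(t_start),
             t_end = as.numeric(t_end))
}

# logical: which times fall inside any interval (half-open [start, end))
in_intervals <- function(t, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(t)))
  iv <- intervals[order(intervals$t_start), , drop = FALSE]
  idx <- findInterval(t, iv$t_start)
  ok <- idx >= 1L
  ok[ok] <- t[ok] < iv$t_end[idx[ok]]
  ok
}

intervals_duration <- function(intervals) {
  if (nrow(intervals) == 0L) return(0)
  sum(intervals$t_end - intervals$t_start)
}

# restrict a sorted spike-time vector to an interval table
restrict_times <- function(t, intervals) t[in_intervals(t, intervals)]

#' Subset an interval table by label or pattern
#'
#' @param intervals interval table.
#' @param labels exact labels to keep.
#' @param pattern regex matched against labels.
#' @return the matching rows.
#' @export
intervals_for <- function(intervals, labels = NULL, pattern = NULL) {
  keep <- rep(TRUE, nrow(intervals))
  if (!is.null(labels)) keep <- keep & intervals$label %in% labels
  if (!is.null(pattern)) keep <- keep & grepl(pattern, intervals$label)
  intervals[keep, , drop = FALSE]
}

# linear interpolation of a position track at arbitrary times
interp_track <- function(position, t) {
  list(x = stats::approx(position$t, position$x, xout = t, rule = 2)$y,
       y = stats::approx(position$t, position$y, xout = t, rule = 2)$y)
}

#' Running speed from a position track
#'
#' Central finite differences on a uniformly sampled track.
#'
#' @param position data.frame with columns `t`, `x`, `y` (s, cm, cm).
#' @return data.frame with columns `t`, `speed` (cm/s).
#' @export
speed_series <- function(position) {
  n <- nrow(position)
  stopifnot(n >= 3L)
  dt <- diff(position$t)
  vx <- c(NA, diff(position$x)) / c(NA, dt)
  vy <- c(NA, diff(position$y)) / c(NA, dt)
  # centered: average of adjacent one-sided estimates
  sx <- (c(vx[-1], NA) + vx) / 2
  sy <- (c(vy[-1], NA) + vy) / 2
  sx[1] <- vx[2]; sy[1] <- vy[2]
  sx[n] <- vx[n]; sy[n] <- vy[n]
  data.frame(t = position$t, speed = sqrt(sx^2 + sy^2))
}

# deterministic sub-seed derivation (kept < 2^31)
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

# flag a value as undefined (NA with attribute), used where the spec asks for
# an explicit flag rather than a bare NaN
undefined_value <- function() structure(NA_real_, undefined = TRUE)

is_undefined <- function(x) isTRUE(attr(x, "undefined"))
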