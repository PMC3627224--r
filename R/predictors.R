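# Predictors of connection change: +/-20 ms pairing events during theta
# epochs of learning, their goal-area split, and Gaussian-kernel interneuron
# spike density at presynaptic spike times; plus the correlation /
# partial-correlation report relating predictors to transmission change.

#' Pairing events between a pyramidal cell and an interneuron
#'
#' For each presynaptic spike inside `epochs`, tests whether any
#' postsynaptic spike falls in the preceding `(t - window, t)` and the
#' following `(t, t + window)` open intervals (20 ms). Counts are per
#' presynaptic spike (binary, not deduplicated across multiple followers);
#' event locations are interpolated from the track and classified against
#' the goal areas.
#'
#' @param pre,post spike-time vectors.
#' @param epochs interval table (theta epochs of learning).
#' @param window pairing window (s; 0.02).
#' @param track position track (for event locations); optional.
#' @param goals,goal_radius goal coordinates and radius (cm) for the
#'   inside/outside split; optional.
#' @return list of class `pairing_summary`: `n_pre_window` (preceded),
#'   `n_post_window` (followed), `events` data.frame (`t`, `x`, `y`,
#'   `inside_goal`).
#' @export
pairing_events <- function(pre, post, epochs, window = 0.02, track = NULL,
                           goals = NULL, goal_radius = 20) {
  if (nrow(epochs) == 0L) stop("pairing epochs are empty")
  p <- sort(restrict_times(pre, epochs))
  q <- sort(post)
  eps <- 1e-12
  # open intervals: post strictly inside (t-window, t) / (t, t+window)
  preceded <- (findInterval(p - eps, q) - findInterval(p - window + eps, q)) > 0
  followed <- (findInterval(p + window - eps, q) - findInterval(p + eps, q)) > 0
  ev_t <- p[preceded | followed]
  events <- data.frame(t = ev_t, x = rep(NA_real_, length(ev_t)),
                       y = rep(NA_real_, length(ev_t)),
                       inside_goal = rep(NA, length(ev_t)))
  if (length(ev_t) && !is.null(track)) {
    trk <- interp_track(track, ev_t)
    events$x <- trk$x; events$y <- trk$y
    if (!is.null(goals) && nrow(goals)) {
      events$inside_goal <- vapply(seq_along(ev_t), function(i)
        any((goals$x - trk$x[i])^2 + (goals$y - trk$y[i])^2 <=
              goal_radius^2), logical(1))
    } else events$inside_goal <- FALSE
  }
  structure(list(n_pre_window = sum(preceded),
                 n_post_window = sum(followed),
                 n_pre_spikes = length(p), events = events),
            class = "pairing_summary")
}

#' Split pairing events by goal area
#'
#' @param summary a `pairing_summary` with located events.
#' @return named integer vector `c(n_inside, n_outside)`; totals conserved.
#' @export
goal_split <- function(summary) {
  ev <- summary$events
  ins <- sum(ev$inside_goal %in% TRUE)
  c(n_inside = ins, n_outside = nrow(ev) - ins)
}

#' Gaussian spike-density function
#'
#' Sum of unit-integral Gaussian kernels (sigma = 20 ms) centered on the
#' spikes; returns a function queryable at arbitrary times, evaluated by
#' exact kernel summation (kernels truncated at 10 sigma).
#'
#' @param spike_times spike times (s), sorted.
#' @param sigma kernel width (s; 0.02).
#' @return function `f(t)` returning density in Hz.
#' @export
spike_density <- function(spike_times, sigma = 0.02) {
  if (sigma <= 0) stop("sigma must be positive")
  st <- sort(spike_times)
  cut <- 10 * sigma
  function(t) {
    vapply(t, function(ti) {
      lo <- findInterval(ti - cut, st) + 1L
      hi <- findInterval(ti + cut, st)
      if (hi < lo) return(0)
      sum(stats::dnorm(ti, st[lo:hi], sigma))
    }, numeric(1))
  }
}

#' Interneuron spike density at presynaptic spike times
#'
#' Mean density (Hz) of the interneuron train, sampled at the presynaptic
#' pyramidal spikes, with its rate-normalized version (mean density divided
#' by the interneuron's mean rate; about 1 under independence) and the mean
#' running speed at those times (retained for partial-correlation control).
#'
#' @param post_spikes interneuron spike times.
#' @param pre_spikes presynaptic spike times (at least 10).
#' @param epochs interval table over which the interneuron mean rate is
#'   taken.
#' @param speed optional speed series (`t`, `speed`).
#' @param sigma kernel width (s; 0.02).
#' @return list of class `density_summary`: `mean_density`,
#'   `normalized_density`, `mean_speed`, `post_rate`.
#' @export
density_at_pre_spikes <- function(post_spikes, pre_spikes, epochs,
                                  speed = NULL, sigma = 0.02) {
  if (length(pre_spikes) < 10L) stop("need at least 10 presynaptic spikes")
  dens <- spike_density(post_spikes, sigma)
  d <- dens(pre_spikes)
  dur <- intervals_duration(epochs)
  rate <- length(restrict_times(post_spikes, epochs)) / dur
  norm <- if (rate > 0) mean(d) / rate else undefined_value()
  msp <- if (!is.null(speed))
    mean(stats::approx(speed$t, speed$speed, xout = pre_spikes,
                       rule = 2)$y) else NA_real_
  structure(list(mean_density = mean(d), normalized_density = norm,
                 mean_speed = msp, post_rate = rate),
            class = "density_summary")
}

# partial correlation by residualization: regress both on the controls,
# correlate residuals
partial_cor <- function(x, y, controls) {
  cm <- as.matrix(as.data.frame(controls))
  ok <- is.finite(x) & is.finite(y) & apply(is.finite(cm), 1, all)
  if (sum(ok) < 4L) return(NA_real_)
  rx <- stats::resid(stats::lm(x[ok] ~ cm[ok, , drop = FALSE]))
  ry <- stats::resid(stats::lm(y[ok] ~ cm[ok, , drop = FALSE]))
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

cor_or_na <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_))
  ct <- stats::cor.test(x[ok], y[ok])
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Relate predictors to transmission-probability change
#'
#' Per-pair Pearson correlations of the across-probe change in transmission
#' probability with (a) pairing counts before/after, (b) inside/outside goal
#' counts, (c) mean coincident spike density; partial correlations of the
#' density controlling for total pairing count and for running speed at
#' event times; and the density regression slope split by whether the
#' presynaptic cell is goal-centric.
#'
#' @param pairs data.frame with columns `d_transmission`, `n_pre_window`,
#'   `n_post_window`, and optionally `n_inside`, `n_outside`,
#'   `mean_density`, `mean_speed`, `goal_centric`.
#' @return list of class `predictor_report` of correlation results.
#' @export
predictor_analysis <- function(pairs) {
  if (nrow(pairs) < 10L) stop("need at least 10 pairs")
  d <- pairs$d_transmission
  out <- list(
    pairing_before = cor_or_na(pairs$n_pre_window, d),
    pairing_after = cor_or_na(pairs$n_post_window, d))
  if (!is.null(pairs$n_inside)) {
    out$inside <- cor_or_na(pairs$n_inside, d)
    out$outside <- cor_or_na(pairs$n_outside, d)
  }
  if (!is.null(pairs$mean_density)) {
    out$density <- cor_or_na(pairs$mean_density, d)
    total <- pairs$n_pre_window + pairs$n_post_window
    if (stats::sd(total) > 0)
      out$density_partial_pairing <-
        partial_cor(pairs$mean_density, d, list(pairing = total))
    if (!is.null(pairs$mean_speed) && stats::sd(pairs$mean_speed) > 0)
      out$density_partial_speed <-
        partial_cor(pairs$mean_density, d, list(speed = pairs$mean_speed))
  }
  if (!is.null(pairs$goal_centric) && !is.null(pairs$mean_density)) {
    slopes <- vapply(c(TRUE, FALSE), function(g) {
      sel <- pairs$goal_centric %in% g
      if (sum(sel) < 3L) return(NA_real_)
      stats::coef(stats::lm(d[sel] ~ pairs$mean_density[sel]))[2]
    }, numeric(1))
    out$density_slope_goal <- slopes[1]
    out$density_slope_nongoal <- slopes[2]
  }
  structure(out, class = "predictor_report")
}

#' @export
print.predictor_report <- function(x, ...) {
  cat("Predictors of transmission-probability change\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.list(v))
      cat(sprintf("  %-24s r = %+0.3f (p = %.3g)\n", nm, v$r, v$p))
    else cat(sprintf("  %-24s %+0.4f\n", nm, v))
  }
  invisible(x)
}
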