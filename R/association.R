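# Firing associations of single units to assembly expression: Pearson
# correlation of per-cycle instantaneous firing rate (IFR) with the
# expression score z, with logistic confirmation; rate-change indices and
# SWR-triggered rate histograms.

#' Instantaneous firing rate over oscillatory cycles
#'
#' @param spike_times spike times of one unit (s), sorted.
#' @param cycles cycle table (`t_start`, `t_end`).
#' @return numeric vector, one rate (Hz) per cycle.
#' @export
instantaneous_rates <- function(spike_times, cycles) {
  st <- sort(spike_times)
  cnt <- findInterval(cycles$t_end - 1e-12, st) -
    findInterval(cycles$t_start - 1e-12, st)
  cnt / (cycles$t_end - cycles$t_start)
}

#' Associate a unit's firing with assembly expression
#'
#' Pearson correlation between the IFR and the expression score z over valid
#' cycles in the classification window, classed `pInt` (r > 0, p < 0.05),
#' `nInt` (r < 0, p < 0.05) or `uInt`. A logistic regression of the new-map
#' indicator (z > 0) on the IFR is reported as confirmation (Wald statistic,
#' significant when |wald_z| > 1.960), not used for class assignment.
#'
#' @param ifr per-cycle rates from [instantaneous_rates()] (aligned with
#'   `expr` rows).
#' @param expr a `cycle_expression` data.frame.
#' @param window optional logical or index vector selecting cycles (e.g. the
#'   last 10 learning trials, the default classification window upstream).
#' @param min_cycles minimum valid paired cycles (30).
#' @param alpha significance level for the Pearson screen (0.05).
#' @return one-row data.frame: `r`, `p_value`, `class`, `wald_z`, `n_cycles`.
#' @export
associate <- function(ifr, expr, window = NULL, min_cycles = 30L,
                      alpha = 0.05) {
  stopifnot(length(ifr) == nrow(expr))
  sel <- expr$valid & !is.na(expr$z)
  if (!is.null(window)) {
    w <- rep(FALSE, nrow(expr))
    w[window] <- TRUE
    sel <- sel & w
  }
  x <- ifr[sel]; z <- expr$z[sel]
  n <- length(x)
  if (n < min_cycles)
    stop(sprintf("only %d valid paired cycles (need >= %d)", n, min_cycles))
  if (stats::sd(x) == 0) {
    return(data.frame(r = NA_real_, p_value = NA_real_, class = "uInt",
                      wald_z = NA_real_, n_cycles = n,
                      flag = "constant_ifr"))
  }
  ct <- stats::cor.test(x, z)
  cls <- if (ct$p.value < alpha && ct$estimate > 0) "pInt"
    else if (ct$p.value < alpha && ct$estimate < 0) "nInt" else "uInt"
  wald <- tryCatch({
    fit <- suppressWarnings(stats::glm((z > 0) ~ x, family = stats::binomial()))
    summary(fit)$coefficients["x", "z value"]
  }, error = function(e) NA_real_)
  data.frame(r = unname(ct$estimate), p_value = ct$p.value, class = cls,
             wald_z = wald, n_cycles = n, flag = "")
}

#' Rate-change index across learning
#'
#' `(last - first) / (last + first)` where `first` and `last` are the unit's
#' mean rates over the first and last `window` seconds (10 min) of the
#' learning interval. Positive means the rate increased.
#'
#' @param spike_times spike times of one unit.
#' @param learning numeric `c(t_start, t_end)` of the learning epoch; must
#'   span at least `2 * window`.
#' @param window duration of each end segment (s; 600).
#' @return one-row data.frame: `rate_first`, `rate_last`, `index` (an NA
#'   flagged row when both rates are zero).
#' @export
rate_change <- function(spike_times, learning, window = 600) {
  if (diff(learning) < 2 * window)
    stop("learning interval shorter than two rate windows")
  n1 <- sum(spike_times >= learning[1] & spike_times < learning[1] + window)
  n2 <- sum(spike_times >= learning[2] - window & spike_times < learning[2])
  r1 <- n1 / window; r2 <- n2 / window
  idx <- if (r1 + r2 == 0) NA_real_ else (r2 - r1) / (r2 + r1)
  data.frame(rate_first = r1, rate_last = r2, index = idx,
             flag = if (r1 + r2 == 0) "both_zero" else "")
}

#' SWR-triggered firing-rate histogram
#'
#' Event-triggered average rate in 20 ms bins centered on SWR power peaks.
#'
#' @param spike_times spike times of one unit.
#' @param swr_peaks SWR peak times (s); at least 10 events.
#' @param bin bin width (s; 0.02).
#' @param span half-window around each peak (s; 0.5).
#' @return data.frame with `lag` (bin centers, s) and `rate` (Hz).
#' @export
swr_rate_histogram <- function(spike_times, swr_peaks, bin = 0.02,
                               span = 0.5) {
  if (length(swr_peaks) < 10L) stop("need at least 10 SWR events")
  edges <- seq(-span, span, by = bin)
  st <- sort(spike_times)
  counts <- numeric(length(edges) - 1L)
  for (tp in swr_peaks) {
    d <- st[st >= tp - span & st < tp + span] - tp
    if (length(d))
      counts <- counts + tabulate(findInterval(d, edges),
                                  nbins = length(counts))
  }
  data.frame(lag = edges[-length(edges)] + bin / 2,
             rate = counts / (length(swr_peaks) * bin))
}
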