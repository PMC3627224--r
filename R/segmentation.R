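# Behavioral-state segmentation and oscillation detection from the LFP.
# All filters are zero-phase (forward-backward Butterworth) so that peak
# times are not shifted.

# sine-taper (Riedel-Sidorenko) multitaper power spectrum of one window;
# K = 5 tapers approximates a time-bandwidth product NW = 3
sine_multitaper_psd <- function(x, K = 5L) {
  N <- length(x)
  n <- seq_len(N)
  tap <- vapply(seq_len(K),
                function(k) sqrt(2 / (N + 1)) * sin(pi * k * n / (N + 1)),
                numeric(N))
  sp <- Mod(stats::mvfft(tap * x))^2
  rowMeans(sp)
}

zerophase_bandpass <- function(x, fs, band) {
  ny <- fs / 2
  if (band[2] >= ny) stop("band edge above Nyquist")
  bf <- signal::butter(3, band / ny, type = "pass")
  signal::filtfilt(bf, x)
}

#' Theta/delta power ratio time series
#'
#' Multitaper power ratio theta (5-12 Hz) over delta (2-4 Hz), measured in
#' 1600 ms windows stepped by 800 ms and timestamped at window centers.
#'
#' @param lfp numeric LFP trace.
#' @param fs sampling rate (Hz), at least 250.
#' @param t0 time of the first sample (s).
#' @param window,step analysis window and step (s).
#' @return data.frame with columns `t` (window center) and `ratio`.
#' @export
theta_delta_ratio <- function(lfp, fs, t0 = 0, window = 1.6, step = 0.8) {
  stopifnot(fs >= 250)
  N <- round(window * fs)
  if (length(lfp) < N) {
    warning("trace shorter than one analysis window; empty ratio series")
    return(data.frame(t = numeric(), ratio = numeric()))
  }
  starts <- seq(1L, length(lfp) - N + 1L, by = round(step * fs))
  freqs <- (seq_len(N) - 1) * fs / N
  th_idx <- which(freqs >= 5 & freqs <= 12)
  de_idx <- which(freqs >= 2 & freqs <= 4)
  ratio <- vapply(starts, function(s) {
    S <- sine_multitaper_psd(lfp[s:(s + N - 1L)])
    sum(S[th_idx]) / sum(S[de_idx])
  }, numeric(1))
  data.frame(t = t0 + (starts - 1L + N / 2) / fs, ratio = ratio)
}

#' Segment a session into exploration and rest
#'
#' Rest requires both speed < `speed_thresh` and theta/delta ratio <
#' `ratio_thresh` sustained for at least `min_rest` seconds; everything else
#' inside the series' coverage is exploration (transient immobility shorter
#' than `min_rest` is bridged). Gaps in the ratio series are reported as
#' `unlabeled` intervals, never silently filled.
#'
#' @param ratio data.frame from [theta_delta_ratio()].
#' @param speed data.frame with columns `t`, `speed` (from [speed_series()]).
#' @param speed_thresh,ratio_thresh,min_rest thresholds: 5 cm/s, ratio 2,
#'   2.4 s.
#' @return interval table with labels `exploration`, `rest`, `unlabeled`.
#' @export
segment_states <- function(ratio, speed, speed_thresh = 5, ratio_thresh = 2,
                           min_rest = 2.4) {
  if (nrow(ratio) == 0L)
    return(intervals_df(character(), numeric(), numeric()))
  step <- if (nrow(ratio) > 1L) stats::median(diff(ratio$t)) else 0.8
  sp <- stats::approx(speed$t, speed$speed, xout = ratio$t, rule = 2)$y
  restw <- sp < speed_thresh & ratio$ratio < ratio_thresh
  gap_after <- c(diff(ratio$t) > 1.5 * step, FALSE)
  # split the series at gaps; run-length encode within each block
  block <- cumsum(c(TRUE, gap_after[-length(gap_after)]))
  out <- list()
  need <- max(1L, ceiling(min_rest / step))
  for (b in unique(block)) {
    i <- which(block == b)
    r <- rle(restw[i])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    lab <- ifelse(r$values & r$lengths >= need, "rest", "exploration")
    # merge adjacent exploration runs (sub-threshold immobility bridged)
    t_lo <- ratio$t[i[starts]] - step / 2
    t_hi <- ratio$t[i[ends]] + step / 2
    df <- intervals_df(lab, t_lo, t_hi)
    keep <- c(TRUE, df$label[-1] != df$label[-nrow(df)])
    grp <- cumsum(keep)
    df <- do.call(rbind, lapply(split(df, grp), function(d)
      intervals_df(d$label[1], min(d$t_start), max(d$t_end))))
    out[[length(out) + 1L]] <- df
    if (b < max(block)) {
      j <- max(i)
      out[[length(out) + 1L]] <-
        intervals_df("unlabeled", ratio$t[j] + step / 2,
                     ratio$t[j + 1L] - step / 2)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# generic oscillatory-cycle detector: negative peaks of the band-passed
# trace delimit cycles; cycles with implied frequency outside valid_band
# are discarded
detect_cycles <- function(lfp, fs, intervals, band, valid_band, t0 = 0) {
  if (nrow(intervals) == 0L)
    return(data.frame(t_start = numeric(), t_end = numeric()))
  x <- zerophase_bandpass(lfp, fs, band)
  # degenerate input: negligible in-band energy (e.g. a pure out-of-band
  # tone) carries no genuine cycles, only filter residue
  if (stats::sd(x) < 0.02 * stats::sd(lfp))
    return(data.frame(t_start = numeric(), t_end = numeric()))
  d <- diff(x)
  minima <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  tmin <- t0 + (minima - 1L) / fs
  out <- list()
  for (i in seq_len(nrow(intervals))) {
    tm <- tmin[tmin >= intervals$t_start[i] & tmin <= intervals$t_end[i]]
    if (length(tm) < 2L) next
    st <- tm[-length(tm)]; en <- tm[-1]
    dur <- en - st
    ok <- dur >= 1 / valid_band[2] & dur <= 1 / valid_band[1]
    out[[length(out) + 1L]] <- data.frame(t_start = st[ok], t_end = en[ok])
  }
  if (!length(out)) return(data.frame(t_start = numeric(), t_end = numeric()))
  res <- do.call(rbind, out)
  res[order(res$t_start), , drop = FALSE]
}

#' Detect theta cycles
#'
#' Band-passes the LFP at 5-28 Hz (wide, so negative peaks are localized
#' sharply), delimits cycles by successive negative peaks within exploration
#' intervals, and keeps cycles whose implied frequency lies in 5-12 Hz.
#'
#' @param lfp,fs LFP trace and sampling rate.
#' @param intervals exploration intervals.
#' @param t0 time of the first LFP sample (s).
#' @return data.frame with `t_start`, `t_end` per cycle.
#' @export
detect_theta_cycles <- function(lfp, fs, intervals, t0 = 0)
  detect_cycles(lfp, fs, intervals, c(5, 28), c(5, 12), t0)

#' Detect gamma cycles
#'
#' As [detect_theta_cycles()] with a 30-80 Hz band and 30-80 Hz cycle
#' validity.
#'
#' @inheritParams detect_theta_cycles
#' @export
detect_gamma_cycles <- function(lfp, fs, intervals, t0 = 0)
  detect_cycles(lfp, fs, intervals, c(30, 80), c(30, 80), t0)

#' Detect sharp wave-ripple events
#'
#' Ripple-band (150-250 Hz) power summed across channels; events exceed the
#' background mean by `threshold_sd` SDs. The threshold is established on
#' the first rest interval and reused; background statistics are re-estimated
#' once after excluding detected events. Event boundaries extend to where
#' power falls back below mean + 2 SD; the peak is the power maximum.
#'
#' @param lfp numeric vector or matrix (columns = channels).
#' @param fs sampling rate (Hz).
#' @param rest_intervals interval table of rest epochs; the first row anchors
#'   the detection threshold.
#' @param threshold_sd detection threshold in background SDs (7).
#' @param ref optional reference channel (common-mode), subtracted from every
#'   channel before filtering.
#' @param t0 time of the first sample (s).
#' @return data.frame with `t_start`, `t_peak`, `t_end`, `peak_power`.
#' @export
detect_swr <- function(lfp, fs, rest_intervals, threshold_sd = 7,
                       ref = NULL, t0 = 0) {
  if (nrow(rest_intervals) == 0L)
    return(data.frame(t_start = numeric(), t_peak = numeric(),
                      t_end = numeric(), peak_power = numeric()))
  x <- if (is.matrix(lfp)) lfp else matrix(lfp, ncol = 1)
  if (all(apply(x, 2, stats::sd) == 0))
    stop("flat LFP: zero variance, SWR detection undefined")
  if (!is.null(ref)) x <- x - ref
  n <- nrow(x)
  t <- t0 + (seq_len(n) - 1L) / fs
  ksz <- max(1L, round(0.01 * fs))   # 10 ms RMS smoothing
  kern <- rep(1 / ksz, ksz)
  P <- rowSums(vapply(seq_len(ncol(x)), function(j) {
    f <- zerophase_bandpass(x[, j], fs, c(150, 250))
    sqrt(pmax(stats::filter(f^2, kern, sides = 2), 0))
  }, numeric(n)), na.rm = FALSE)
  P[is.na(P)] <- 0
  in_rest <- in_intervals(t, rest_intervals)
  first <- in_intervals(t, rest_intervals[1, , drop = FALSE])
  bg_stats <- function(excl) {
    sel <- first & !excl
    c(mean(P[sel]), stats::sd(P[sel]))
  }
  find_events <- function(thr, lo) {
    above <- in_rest & P > thr
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    idx <- which(r$values)
    ev <- lapply(idx, function(k) {
      s <- starts[k]; e <- ends[k]
      while (s > 1L && P[s - 1L] > lo && in_rest[s - 1L]) s <- s - 1L
      while (e < n && P[e + 1L] > lo && in_rest[e + 1L]) e <- e + 1L
      pk <- s - 1L + which.max(P[s:e])
      c(t[s], t[pk], t[e], P[pk])
    })
    if (!length(ev))
      return(data.frame(t_start = numeric(), t_peak = numeric(),
                        t_end = numeric(), peak_power = numeric()))
    m <- do.call(rbind, ev)
    # merge events sharing a boundary (from boundary extension)
    keep <- c(TRUE, m[-1, 1] > m[-nrow(m), 3])
    m <- m[keep, , drop = FALSE]
    data.frame(t_start = m[, 1], t_peak = m[, 2], t_end = m[, 3],
               peak_power = m[, 4])
  }
  st <- bg_stats(rep(FALSE, n))
  if (!is.finite(st[2]) || st[2] == 0)
    stop("ripple-band power has zero variance in the first rest interval")
  ev <- find_events(st[1] + threshold_sd * st[2], st[1] + 2 * st[2])
  excl <- rep(FALSE, n)
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev)))
      excl <- excl | (t >= ev$t_start[i] & t <= ev$t_end[i])
  }
  st <- bg_stats(excl)   # one re-estimation pass excluding events
  if (!is.finite(st[2]) || st[2] == 0)
    stop("ripple-band power has zero variance after event exclusion")
  find_events(st[1] + threshold_sd * st[2], st[1] + 2 * st[2])
}
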