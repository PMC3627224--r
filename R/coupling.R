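# Cross-correlogram detection of monosynaptic pyramidal->interneuron
# connections and tracking of spike-transmission probability and latency
# across epochs. CCGs use 0.5 ms bins over +/-50 ms so that the
# monosynaptic window (0.5-2.5 ms), the 5 ms control bin and the 30-50 ms
# chance bins are all addressable exactly. The reference train is always
# the pyramidal cell; probability is per reference spike.

#' Cross-correlogram of two spike trains
#'
#' Counts postsynaptic spike lags relative to each reference (presynaptic)
#' spike, restricted to `epoch`, normalized by the number of reference
#' spikes.
#'
#' @param pre,post sorted spike-time vectors (s); `pre` is the reference.
#' @param bin_width bin width (ms; 0.5).
#' @param window half-window (ms; 50).
#' @param epoch optional interval table restricting both trains.
#' @return object of class `ccg`: `lags` (bin centers, ms), `counts`,
#'   `prob` (counts / n_ref), `n_ref`, `bin_width`, `low_count` flag
#'   (n_ref < 100).
#' @export
build_ccg <- function(pre, post, bin_width = 0.5, window = 50,
                      epoch = NULL) {
  if (!is.null(epoch)) {
    pre <- restrict_times(pre, epoch)
    post <- restrict_times(post, epoch)
  }
  if (length(pre) == 0L || length(post) == 0L)
    stop("empty spike train in CCG construction")
  w <- window / 1000
  lo <- findInterval(pre - w, post)
  hi <- findInterval(pre + w, post)
  nper <- hi - lo
  lags_s <- post[sequence(nper, from = lo + 1L)] - rep(pre, nper)
  nbins <- as.integer(round(2 * window / bin_width))
  # tiny epsilon so lags landing exactly on a bin edge are not split by
  # floating-point noise (edge belongs to the upper, half-open bin)
  idx <- floor((lags_s * 1000 + window) / bin_width + 1e-6) + 1L
  idx[idx < 1L | idx > nbins] <- NA
  counts <- tabulate(idx[!is.na(idx)], nbins = nbins)
  edges <- seq(-window, window, by = bin_width)
  structure(list(lags = edges[-length(edges)] + bin_width / 2,
                 counts = counts, prob = counts / length(pre),
                 n_ref = length(pre), bin_width = bin_width,
                 window = window, low_count = length(pre) < 100L),
            class = "ccg")
}

#' @export
print.ccg <- function(x, ...) {
  cat(sprintf("ccg: %g ms bins over +/-%g ms, %d reference spikes%s\n",
              x$bin_width, x$window, x$n_ref,
              if (x$low_count) " (low count)" else ""))
  mono <- mono_bins(x)
  cat(sprintf("  peak prob %.4f at %.2f ms; mono-window mass %.4f\n",
              max(x$prob), x$lags[which.max(x$prob)],
              sum(x$prob[mono])))
  invisible(x)
}

# bin selectors: half-open bins [lower, upper)
mono_bins <- function(ccg, from = 0.5, to = 2.5) {
  lower <- ccg$lags - ccg$bin_width / 2
  upper <- ccg$lags + ccg$bin_width / 2
  which(lower >= from - 1e-9 & upper <= to + 1e-9)
}

baseline_bins <- function(ccg, from = 30, to = 50) {
  lower <- ccg$lags - ccg$bin_width / 2
  upper <- ccg$lags + ccg$bin_width / 2
  which((lower >= from - 1e-9 & upper <= to + 1e-9) |
          (lower >= -to - 1e-9 & upper <= -from + 1e-9))
}

control_5ms_bin <- function(ccg) {
  lower <- ccg$lags - ccg$bin_width / 2
  which(abs(lower - 5) < 1e-9)
}

#' Chance firing baseline of a CCG
#'
#' Mean and SD of per-bin probability over the 30-50 ms bins on both sides
#' of the histogram.
#'
#' @param ccg a `ccg`.
#' @param from,to baseline lag range (ms). The alternative dialect using the
#'   first and last 20 ms bins of the window corresponds to `from = 30,
#'   to = 50` on a +/-50 ms window and is the default.
#' @return list with `mean`, `sd`, `n_bins`.
#' @export
chance_baseline <- function(ccg, from = 30, to = 50) {
  bb <- baseline_bins(ccg, from, to)
  if (!length(bb)) stop("CCG window does not cover the baseline lags")
  list(mean = mean(ccg$prob[bb]), sd = stats::sd(ccg$prob[bb]),
       n_bins = length(bb))
}

#' Detect a monosynaptic peak
#'
#' Significant when the maximum per-bin probability in the 0.5-2.5 ms bins
#' exceeds the chance baseline mean by `n_sd` baseline SDs. Ties break
#' toward the earlier bin.
#'
#' @param ccg a `ccg`.
#' @param n_sd threshold in baseline SDs (3).
#' @return list: `significant`, `peak_bin` (index), `peak_lag` (ms),
#'   `peak_prob`, `baseline` (list), `insufficient` flag (zero-count CCG).
#' @export
detect_mono <- function(ccg, n_sd = 3) {
  base <- chance_baseline(ccg)
  mono <- mono_bins(ccg)
  pk <- mono[which.max(ccg$prob[mono])]   # which.max takes the first tie
  insufficient <- sum(ccg$counts) == 0L ||
    (!is.finite(base$sd)) || (base$sd == 0 && base$mean == 0)
  sig <- !insufficient && ccg$prob[pk] > base$mean + n_sd * base$sd
  list(significant = sig, peak_bin = pk, peak_lag = ccg$lags[pk],
       peak_prob = ccg$prob[pk], baseline = base,
       insufficient = insufficient)
}

#' Spike-transmission probability
#'
#' Baseline-subtracted probability mass over the monosynaptic bins:
#' `sum over 0.5-2.5 ms bins of (prob - baseline_mean)`. May be negative for
#' unconnected pairs. Control excesses at the 5 ms bin and over the 30-50 ms
#' bins are returned alongside.
#'
#' @param ccg a `ccg`.
#' @return list: `transmission`, `control_5ms`, `control_30_50`,
#'   `baseline_mean`.
#' @export
transmission <- function(ccg) {
  base <- chance_baseline(ccg)
  mono <- mono_bins(ccg)
  bb <- baseline_bins(ccg)
  c5 <- control_5ms_bin(ccg)
  list(transmission = sum(ccg$prob[mono] - base$mean),
       control_5ms = if (length(c5)) ccg$prob[c5] - base$mean else NA_real_,
       control_30_50 = mean(ccg$prob[bb]) - base$mean,
       baseline_mean = base$mean)
}

#' Monosynaptic transmission latency
#'
#' Count-weighted mean lag of the baseline-subtracted mass over the
#' monosynaptic bins (sub-bin precision via the center of mass). Defined
#' only for significant pairs; the peak-bin center is returned as an
#' alternative estimate.
#'
#' @param ccg a `ccg`.
#' @param detection optional result of [detect_mono()] (recomputed if
#'   missing).
#' @return list: `latency` (ms; NA flagged when not significant),
#'   `peak_latency` (ms).
#' @export
ccg_latency <- function(ccg, detection = NULL) {
  if (is.null(detection)) detection <- detect_mono(ccg)
  if (!isTRUE(detection$significant))
    return(list(latency = undefined_value(),
                peak_latency = detection$peak_lag))
  base <- chance_baseline(ccg)
  mono <- mono_bins(ccg)
  mass <- pmax(ccg$prob[mono] - base$mean, 0)
  if (sum(mass) == 0)
    return(list(latency = undefined_value(),
                peak_latency = detection$peak_lag))
  list(latency = sum(ccg$lags[mono] * mass) / sum(mass),
       peak_latency = detection$peak_lag)
}

#' Correlation coefficients of spike coincidence
#'
#' Rate-independent coupling measure: the binned spike-train covariance per
#' lag divided by the geometric mean of the two trains' bin-count standard
#' deviations (Pearson-style normalization), with pyramidal spikes as
#' reference (positive lags = interneuron after pyramidal cell).
#'
#' @param pre,post spike-time vectors; `pre` is the reference.
#' @param epoch optional restricting interval table.
#' @param bin_width bin width (ms; 0.5).
#' @param window half-window (ms; 50).
#' @return data.frame with `lag` (ms) and `coef`.
#' @export
coincidence_corrcoef <- function(pre, post, epoch = NULL, bin_width = 0.5,
                                 window = 50) {
  if (!length(pre) || !length(post)) stop("empty spike train")
  if (is.null(epoch)) {
    t0 <- min(pre[1], post[1]); t1 <- max(pre[length(pre)], post[length(post)])
    epoch <- intervals_df("all", t0, t1 + 1e-6)
  } else {
    pre <- restrict_times(pre, epoch)
    post <- restrict_times(post, epoch)
    if (!length(pre) || !length(post)) stop("empty spike train in epoch")
  }
  t0 <- min(epoch$t_start); t1 <- max(epoch$t_end)
  bw <- bin_width / 1000
  nb <- ceiling((t1 - t0) / bw)
  xb <- tabulate(pmin(floor((pre - t0) / bw) + 1L, nb), nbins = nb)
  yb <- tabulate(pmin(floor((post - t0) / bw) + 1L, nb), nbins = nb)
  if (stats::sd(xb) == 0 || stats::sd(yb) == 0)
    stop("zero-variance binned train; coincidence coefficient undefined")
  K <- as.integer(round(window / bin_width))
  xc <- xb - mean(xb); yc <- yb - mean(yb)
  # FFT cross-correlation; lag k > 0 pairs x_t with y_{t+k}
  nfft <- stats::nextn(nb + K, 2)
  fx <- stats::fft(c(xc, numeric(nfft - nb)))
  fy <- stats::fft(c(yc, numeric(nfft - nb)))
  cc <- Re(stats::fft(Conj(fx) * fy, inverse = TRUE)) / nfft
  pos <- cc[1:(K + 1L)]                    # lags 0..K
  neg <- cc[(nfft - K + 1L):nfft]          # lags -K..-1
  cov_k <- c(neg, pos) / nb
  data.frame(lag = (-K:K) * bin_width,
             coef = cov_k / (stats::sd(xb) * stats::sd(yb) * (nb - 1) / nb))
}

#' Track a pair's coupling across epochs
#'
#' Detection is decided on the full-day pooled CCG; per-epoch transmission
#' probability and latency are then computed for the same pair over the
#' preprobe, learning quartiles 1-4, postprobe, presleep and postsleep, with
#' deltas (quartile 4 - quartile 1, postprobe - preprobe, postsleep -
#' presleep) and the 5 ms / 30-50 ms control deltas. Epochs with fewer than
#' `min_ref` reference spikes are flagged and excluded from deltas.
#'
#' @param pre,post spike-time vectors (`pre` = pyramidal reference).
#' @param intervals session interval table (labels `preprobe`, `presleep`,
#'   `trialNN`, `postsleep`, `postprobe`).
#' @param min_ref minimum reference spikes per epoch (100).
#' @return object of class `mono_pair`: detection on the pooled CCG,
#'   per-epoch table, deltas.
#' @export
track_epochs <- function(pre, post, intervals, min_ref = 100L) {
  ep <- session_epochs(intervals)
  pooled <- build_ccg(pre, post, epoch = intervals)
  det <- detect_mono(pooled)
  trials <- ep$learning
  qsplit <- split(seq_len(nrow(trials)),
                  cut(seq_len(nrow(trials)), 4, labels = FALSE))
  epochs <- list(
    preprobe = intervals_for(intervals, "preprobe"),
    q1 = trials[qsplit[[1]], ], q2 = trials[qsplit[[2]], ],
    q3 = trials[qsplit[[3]], ], q4 = trials[qsplit[[4]], ],
    postprobe = intervals_for(intervals, "postprobe"),
    presleep = intervals_for(intervals, "presleep"),
    postsleep = intervals_for(intervals, "postsleep"))
  rows <- lapply(names(epochs), function(nm) {
    iv <- epochs[[nm]]
    pre_e <- restrict_times(pre, iv)
    if (length(pre_e) == 0L || length(restrict_times(post, iv)) == 0L)
      return(data.frame(epoch = nm, transmission = NA, latency = NA,
                        control_5ms = NA, control_30_50 = NA,
                        n_ref = length(pre_e), low_count = TRUE))
    cc <- build_ccg(pre, post, epoch = iv)
    tr <- transmission(cc)
    lat <- ccg_latency(cc, det)
    data.frame(epoch = nm, transmission = tr$transmission,
               latency = as.numeric(lat$latency),
               control_5ms = tr$control_5ms,
               control_30_50 = tr$control_30_50,
               n_ref = cc$n_ref, low_count = cc$low_count)
  })
  per_epoch <- do.call(rbind, rows)
  getv <- function(nm, col) {
    r <- per_epoch[per_epoch$epoch == nm, ]
    if (r$low_count) NA_real_ else r[[col]]
  }
  deltas <- data.frame(
    delta = c("q4_minus_q1", "postprobe_minus_preprobe",
              "postsleep_minus_presleep"),
    transmission = c(getv("q4", "transmission") - getv("q1", "transmission"),
                     getv("postprobe", "transmission") - getv("preprobe", "transmission"),
                     getv("postsleep", "transmission") - getv("presleep", "transmission")),
    latency = c(getv("q4", "latency") - getv("q1", "latency"),
                getv("postprobe", "latency") - getv("preprobe", "latency"),
                getv("postsleep", "latency") - getv("presleep", "latency")),
    control_5ms = c(getv("q4", "control_5ms") - getv("q1", "control_5ms"),
                    getv("postprobe", "control_5ms") - getv("preprobe", "control_5ms"),
                    getv("postsleep", "control_5ms") - getv("presleep", "control_5ms")),
    control_30_50 = c(getv("q4", "control_30_50") - getv("q1", "control_30_50"),
                      getv("postprobe", "control_30_50") - getv("preprobe", "control_30_50"),
                      getv("postsleep", "control_30_50") - getv("presleep", "control_30_50")))
  structure(list(detection = det, pooled = pooled, per_epoch = per_epoch,
                 deltas = deltas), class = "mono_pair")
}

#' @export
print.mono_pair <- function(x, ...) {
  d <- x$detection
  cat(sprintf("mono_pair: %s (peak prob %.4f at %.2f ms, baseline %.4f)\n",
              if (d$significant) "significant" else "not significant",
              d$peak_prob, d$peak_lag, d$baseline$mean))
  print(x$per_epoch, row.names = FALSE)
  invisible(x)
}
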