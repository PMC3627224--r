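# Synthetic five-session generator: latent per-theta-cycle map states, place
# fields in two maps, interneurons with state-dependent gain, and plastic
# monosynaptic pyramidal->interneuron connections (weights drift during
# learning only).

#' Homogeneous Poisson spike train over intervals
#'
#' @param rate rate (Hz), a scalar.
#' @param intervals interval table (see [intervals_df()]).
#' @return sorted numeric vector of spike times (s).
#' @export
poisson_train <- function(rate, intervals) {
  if (rate < 0) stop("rate must be nonnegative")
  if (nrow(intervals) == 0L || rate == 0) return(numeric())
  dur <- intervals$t_end - intervals$t_start
  n <- stats::rpois(length(dur), rate * dur)
  t <- rep(intervals$t_start, n) + stats::runif(sum(n)) * rep(dur, n)
  sort(t)
}

# piecewise-constant-rate Poisson train: one rate per segment
piecewise_poisson <- function(t0, t1, rate) {
  dur <- t1 - t0
  n <- stats::rpois(length(dur), pmax(rate, 0) * dur)
  tt <- rep(t0, n) + stats::runif(sum(n)) * rep(dur, n)
  sort(tt)
}

# connection weight at time t: w_start before learning, linear ramp across
# the learning span, w_end after (learning-restricted plasticity)
connection_weight <- function(t, w_start, w_end, learning_span) {
  u <- (t - learning_span[1]) / diff(learning_span)
  w_start + (w_end - w_start) * pmin(pmax(u, 0), 1)
}

# evoked interneuron spikes: each presynaptic spike at t elicits, with
# probability w(t), one spike at t + delay + N(0, jitter)
evoke_spikes <- function(pre, w, delay_ms, jitter_ms) {
  hit <- stats::runif(length(pre)) < w
  t <- pre[hit] + delay_ms / 1000 +
    stats::rnorm(sum(hit), 0, jitter_ms / 1000)
  list(times = sort(t), n_attempt = length(pre), n_evoked = sum(hit))
}

#' Simulate a monosynaptically coupled pyramidal-interneuron pair
#'
#' Minimal generator for coupling-level analyses: a Poisson presynaptic
#' train, a Poisson interneuron baseline, and evoked interneuron spikes at
#' `delay_ms + N(0, jitter_ms)` after each presynaptic spike with probability
#' `w(t)`. The weight ramps linearly from `w_start` to `w_end` across the
#' `learning` span and is constant outside it (constant at `w_start` when
#' `learning` is `NULL`).
#'
#' @param epochs interval table covering the simulated time.
#' @param pre_rate,post_rate presynaptic and baseline postsynaptic rates (Hz).
#' @param w_start,w_end connection weight (spike transmission probability).
#' @param learning optional `c(t_start, t_end)` of the learning span.
#' @param delay_ms,jitter_ms synaptic delay and Gaussian jitter SD (ms).
#' @param seed integer seed.
#' @return list with `pre`, `post` (sorted spike times), `evoked` (evoked
#'   spike times), `n_evoked`, `n_pre`, and `w_fun(t)`.
#' @export
simulate_coupled_pair <- function(epochs, pre_rate, post_rate,
                                  w_start, w_end = w_start, learning = NULL,
                                  delay_ms = 1.5, jitter_ms = 0.2,
                                  seed = 1L) {
  set.seed(as.integer(seed))
  pre <- poisson_train(pre_rate, epochs)
  base <- poisson_train(post_rate, epochs)
  w_fun <- if (is.null(learning)) {
    function(t) rep(w_start, length(t))
  } else {
    function(t) connection_weight(t, w_start, w_end, learning)
  }
  ev <- evoke_spikes(pre, w_fun(pre), delay_ms, jitter_ms)
  list(pre = pre, post = sort(c(base, ev$times)), evoked = ev$times,
       n_evoked = ev$n_evoked, n_pre = length(pre), w_fun = w_fun)
}

# default monosynaptic wiring consistent with the interneuron gain classes:
# pInt from remapped (new-assembly) cells with rising weights, nInt from
# stable cells with falling weights, uInt uncoupled
default_connections <- function(cfg, remapped) {
  rows <- list()
  new_cells <- which(remapped) - 1L
  old_cells <- which(!remapped) - 1L
  if (!length(old_cells)) old_cells <- new_cells
  if (!length(new_cells)) new_cells <- old_cells
  for (j in seq_len(cfg$n_int)) {
    g <- cfg$int_gain[j]
    if (g == 0) next
    pool <- if (g > 0) new_cells else old_cells
    pre <- sample(pool, min(2L, length(pool)))
    for (p in pre) {
      w <- if (g > 0) c(0.05, 0.15) else c(0.15, 0.05)
      rows[[length(rows) + 1L]] <- data.frame(
        pre = p, post = j - 1L, w_start = w[1], w_end = w[2],
        delay_ms = stats::runif(1, 1.0, 2.0), jitter_ms = 0.2)
    }
  }
  if (!length(rows))
    return(data.frame(pre = integer(), post = integer(),
                      w_start = numeric(), w_end = numeric(),
                      delay_ms = numeric(), jitter_ms = numeric()))
  do.call(rbind, rows)
}

session_intervals <- function(cfg) {
  labs <- c("preprobe", "presleep",
            sprintf("trial%02d", seq_len(cfg$n_trials)),
            "postsleep", "postprobe")
  dur <- c(cfg$probe_duration, cfg$rest_duration,
           rep(cfg$trial_duration, cfg$n_trials),
           cfg$rest_duration, cfg$probe_duration)
  t_end <- cumsum(dur)
  intervals_df(labs, c(0, t_end[-length(t_end)]), t_end)
}

#' Exploration / learning spans of a simulated day
#'
#' @param intervals the session interval table.
#' @return list with `exploration`, `rest`, `learning` interval tables and
#'   the `learning_span` (numeric length-2).
#' @export
session_epochs <- function(intervals) {
  expl <- intervals_for(intervals, pattern = "^(preprobe|postprobe|trial)")
  rest <- intervals_for(intervals, labels = c("presleep", "postsleep"))
  trials <- intervals_for(intervals, pattern = "^trial")
  list(exploration = expl, rest = rest, learning = trials,
       learning_span = c(min(trials$t_start), max(trials$t_end)))
}

#' Simulate a full five-session experiment
#'
#' Generates a complete synthetic recording day: trajectory, latent
#' per-theta-cycle map states (probability of the new map follows
#' `config$flicker_schedule` across learning trials; the preprobe is all-old
#' and the postprobe all-new), pyramidal spike trains from Gaussian place
#' fields under the active map (inhomogeneous Poisson, thinned on a 1 kHz
#' grid with sub-ms jitter), interneuron trains with state-dependent gain
#' plus evoked monosynaptic spikes, and an LFP with speed-modulated theta
#' during movement, a delta component during rest, and optional ripple
#' transients.
#'
#' @param config a [sim_config()].
#' @param generate_lfp generate the LFP trace (set `FALSE` to save time when
#'   only spikes are needed).
#' @param swr_rate rate of injected ripple transients during rest (Hz; 0
#'   disables).
#' @return An object of class `session_sim`: list with `bundle`
#'   (spikes, position, lfp, intervals, goals) and `truth`
#'   (cycles with latent states, field parameters, connection table with the
#'   learning span, interneuron classes).
#' @export
simulate_session <- function(config, generate_lfp = TRUE, swr_rate = 0.05) {
  cfg <- config
  intervals <- session_intervals(cfg)
  ep <- session_epochs(intervals)

  # ---- trajectory ------------------------------------------------------
  set.seed(derive_seed(cfg$seed, 1))
  pos_list <- list()
  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, ]
    if (iv$label %in% c("presleep", "postsleep")) {
      # animal resting near the arena edge; negligible movement
      n <- floor((iv$t_end - iv$t_start) * cfg$position_fs)
      pos_list[[i]] <- data.frame(
        t = iv$t_start + (seq_len(n) - 1) / cfg$position_fs,
        x = cfg$arena_radius * 0.95 + stats::rnorm(n, 0, 0.05),
        y = stats::rnorm(n, 0, 0.05))
    } else {
      g <- if (grepl("^trial", iv$label)) cfg$goals else NULL
      pos_list[[i]] <- generate_trajectory(
        cfg, c(iv$t_start, iv$t_end),
        seed = derive_seed(cfg$seed, 100 + i), goals = g)
    }
  }
  position <- do.call(rbind, pos_list)

  # ---- theta cycles and latent states ---------------------------------
  # global theta phase 2*pi*f*t; cycle boundaries at the negative peaks of
  # cos(phase), i.e. t = (k + 0.5) / f, kept when fully inside exploration
  set.seed(derive_seed(cfg$seed, 2))
  cyc_list <- list()
  trials <- ep$learning
  for (i in seq_len(nrow(ep$exploration))) {
    iv <- ep$exploration[i, ]
    k0 <- ceiling(iv$t_start * cfg$theta_freq - 0.5)
    k1 <- floor(iv$t_end * cfg$theta_freq - 0.5)
    if (k1 <= k0) next
    bounds <- (k0:k1 + 0.5) / cfg$theta_freq
    st <- bounds[-length(bounds)]; en <- bounds[-1]
    lab <- iv$label
    state <- if (lab == "preprobe") rep("old", length(st))
      else if (lab == "postprobe") rep("new", length(st))
      else {
        tr <- match(lab, trials$label)
        ifelse(stats::runif(length(st)) < cfg$flicker_schedule[tr],
               "new", "old")
      }
    cyc_list[[length(cyc_list) + 1L]] <- data.frame(
      t_start = st, t_end = en, state = state, session = lab,
      trial = if (grepl("^trial", lab)) match(lab, trials$label) else NA_integer_)
  }
  cycles <- do.call(rbind, cyc_list)
  cycles <- cycles[order(cycles$t_start), ]
  rownames(cycles) <- NULL

  # ---- place fields ----------------------------------------------------
  set.seed(derive_seed(cfg$seed, 3))
  draw_centers <- function(n) {
    r <- cfg$arena_radius * 0.85 * sqrt(stats::runif(n))
    a <- stats::runif(n, 0, 2 * pi)
    cbind(r * cos(a), r * sin(a))
  }
  old_c <- draw_centers(cfg$n_pyr)
  remapped <- rep(FALSE, cfg$n_pyr)
  remapped[sample.int(cfg$n_pyr, round(cfg$frac_remap * cfg$n_pyr))] <- TRUE
  new_c <- old_c
  # remapped fields move by at least 2 sigma (redraw until separated)
  for (u in which(remapped)) {
    repeat {
      cand <- draw_centers(1L)
      if (sum((cand - old_c[u, ])^2) >= (2 * cfg$sigma_field)^2) break
    }
    new_c[u, ] <- cand
  }
  fields <- data.frame(
    unit_id = seq_len(cfg$n_pyr) - 1L,
    old_x = old_c[, 1], old_y = old_c[, 2],
    new_x = new_c[, 1], new_y = new_c[, 2],
    sigma = cfg$sigma_field, peak = cfg$pyr_peak_rate,
    phi_pref = stats::runif(cfg$n_pyr, 0, 2 * pi),
    remapped = remapped)

  # ---- pyramidal spikes ------------------------------------------------
  # 1 kHz thinning grid over exploration, spike times jittered within the slot
  set.seed(derive_seed(cfg$seed, 4))
  grid_list <- lapply(seq_len(nrow(ep$exploration)), function(i) {
    iv <- ep$exploration[i, ]
    seq(iv$t_start, iv$t_end - 1e-3, by = 1e-3)
  })
  tt <- unlist(grid_list)
  trk <- interp_track(position, tt)
  phase <- 2 * pi * cfg$theta_freq * tt
  ci <- findInterval(tt, cycles$t_start)
  ok <- ci >= 1L
  ok[ok] <- tt[ok] < cycles$t_end[ci[ok]]
  is_new <- rep(FALSE, length(tt))
  is_new[ok] <- cycles$state[ci[ok]] == "new"
  spk <- vector("list", cfg$n_pyr + cfg$n_int)
  for (u in seq_len(cfg$n_pyr)) {
    fx <- ifelse(is_new, fields$new_x[u], fields$old_x[u])
    fy <- ifelse(is_new, fields$new_y[u], fields$old_y[u])
    d2 <- (trk$x - fx)^2 + (trk$y - fy)^2
    rate <- fields$peak[u] * exp(-d2 / (2 * fields$sigma[u]^2)) *
      (1 + cfg$theta_mod * cos(phase - fields$phi_pref[u]))
    sel <- stats::runif(length(tt)) < rate * 1e-3
    st <- tt[sel] + stats::runif(sum(sel), 0, 1e-3)
    st <- c(st, poisson_train(cfg$pyr_rest_rate, ep$rest))
    spk[[u]] <- sort(st)
  }

  # ---- interneuron baselines ------------------------------------------
  # piecewise-constant rate: base*(1 +/- gain) per exploration cycle, base
  # during rest and cycle-edge fragments
  set.seed(derive_seed(cfg$seed, 5))
  seg_t0 <- c(cycles$t_start, ep$rest$t_start)
  seg_t1 <- c(cycles$t_end, ep$rest$t_end)
  seg_s <- c(ifelse(cycles$state == "new", 1, -1), rep(0, nrow(ep$rest)))
  for (j in seq_len(cfg$n_int)) {
    g <- cfg$int_gain[j]
    rate <- cfg$int_base_rate * (1 + g * seg_s)
    spk[[cfg$n_pyr + j]] <- piecewise_poisson(seg_t0, seg_t1, rate)
  }

  # ---- monosynaptic connections ---------------------------------------
  set.seed(derive_seed(cfg$seed, 6))
  conn <- cfg$connection_table
  if (is.null(conn)) conn <- default_connections(cfg, remapped)
  if (nrow(conn)) {
    for (k in seq_len(nrow(conn))) {
      pre <- spk[[conn$pre[k] + 1L]]
      w <- connection_weight(pre, conn$w_start[k], conn$w_end[k],
                             ep$learning_span)
      ev <- evoke_spikes(pre, w, conn$delay_ms[k], conn$jitter_ms[k])
      post_i <- cfg$n_pyr + conn$post[k] + 1L
      spk[[post_i]] <- sort(c(spk[[post_i]], ev$times))
    }
  }

  spikes <- data.frame(
    unit_id = rep(seq_along(spk) - 1L, lengths(spk)),
    t = unlist(spk),
    unit_type = rep(rep(c("pyr", "int"), c(cfg$n_pyr, cfg$n_int)),
                    lengths(spk)))
  spikes <- spikes[order(spikes$unit_id, spikes$t), ]
  rownames(spikes) <- NULL

  # ---- LFP -------------------------------------------------------------
  lfp <- NULL
  if (generate_lfp) {
    set.seed(derive_seed(cfg$seed, 7))
    lfp <- synth_lfp(cfg, intervals, position, ep, swr_rate)
  }

  int_class <- ifelse(cfg$int_gain > 0, "pInt",
                      ifelse(cfg$int_gain < 0, "nInt", "uInt"))
  structure(list(
    bundle = list(spikes = spikes, position = position, lfp = lfp,
                  intervals = intervals, goals = cfg$goals),
    truth = list(cycles = cycles, fields = fields, connections = conn,
                 learning_span = ep$learning_span, int_class = int_class,
                 int_ids = cfg$n_pyr + seq_len(cfg$n_int) - 1L,
                 config = cfg)), class = "session_sim")
}

# LFP: speed-modulated 8 Hz theta + pink noise; rest adds a 3 Hz delta
# component; optional 200 Hz ripple transients in rest
synth_lfp <- function(cfg, intervals, position, ep, swr_rate) {
  fs <- cfg$lfp_fs
  t1 <- max(intervals$t_end)
  n <- floor(t1 * fs)
  t <- (seq_len(n) - 1) / fs
  sp <- stats::approx(position$t, speed_series(position)$speed, xout = t,
                      rule = 2)$y
  sp[is.na(sp)] <- 0
  theta_amp <- 40 * sp / (sp + 5)
  x <- theta_amp * cos(2 * pi * cfg$theta_freq * t)
  in_rest <- in_intervals(t, ep$rest)
  x[in_rest] <- x[in_rest] + 35 * sin(2 * pi * 3 * t[in_rest])
  # pink (1/f) noise by spectral shaping
  wn <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  pink <- Re(stats::fft(wn / sqrt(f), inverse = TRUE)) / n
  x <- x + 8 * pink / stats::sd(pink)
  if (swr_rate > 0 && nrow(ep$rest)) {
    ev <- poisson_train(swr_rate, ep$rest)
    for (te in ev) {
      idx <- which(t > te - 0.05 & t < te + 0.05)
      if (!length(idx)) next
      env <- exp(-(t[idx] - te)^2 / (2 * 0.01^2))
      x[idx] <- x[idx] + 25 * env * sin(2 * pi * 200 * (t[idx] - te))
    }
  }
  list(trace = x, fs = fs)
}

#' @export
print.session_sim <- function(x, ...) {
  b <- x$bundle
  cat("Synthetic session\n")
  cat(sprintf("  %d spikes from %d units over %.0f s\n", nrow(b$spikes),
              length(unique(b$spikes$unit_id)), max(b$intervals$t_end)))
  cat(sprintf("  %d theta cycles with latent states (%.1f%% new)\n",
              nrow(x$truth$cycles),
              100 * mean(x$truth$cycles$state == "new")))
  cat(sprintf("  %d monosynaptic connections; interneuron classes: %s\n",
              nrow(x$truth$connections),
              paste(sprintf("%s=%d", names(table(x$truth$int_class)),
                            table(x$truth$int_class)), collapse = " ")))
  invisible(x)
}
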