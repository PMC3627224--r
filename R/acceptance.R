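# Recovery benchmarks: simulation studies that measure how well every
# estimator recovers the generator's ground truth, at desk scale. Used by
# the acceptance script and the acceptance tests.

#' Run the full recovery-benchmark suite
#'
#' Simulates the study conditions and recomputes every recovery metric from
#' scratch: spike-transmission probability and latency recovery, detection
#' error rates, assembly-expression decoding, interneuron classification,
#' closed-form identities, oracle equivalences, and the ensemble directional
#' mirrors (probe-vs-sleep weight-change correlation, latency-probability
#' coupling, pairing-count recovery).
#'
#' @param seed integer master seed; all sub-simulations derive from it.
#' @param quiet suppress progress messages.
#' @return nested list of metrics (see the acceptance script for the flat
#'   summary written to JSON).
#' @export
recovery_benchmarks <- function(seed = 1L, quiet = TRUE) {
  seed <- as.integer(seed) %% 100000L
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- list()

  # ---- transmission + latency recovery --------------------------------
  say("transmission/latency recovery ...")
  iv600 <- intervals_df("e", 0, 600)
  w_levels <- c(0.05, 0.10, 0.20)
  tw <- do.call(rbind, lapply(seq_along(w_levels), function(i) {
    do.call(rbind, lapply(1:3, function(r) {
      p <- simulate_coupled_pair(iv600, pre_rate = 5, post_rate = 10,
                                 w_start = w_levels[i],
                                 seed = derive_seed(seed, 10 * i + r))
      cc <- build_ccg(p$pre, p$post)
      data.frame(w = w_levels[i], n_pre = p$n_pre,
                 est = transmission(cc)$transmission,
                 latency = as.numeric(ccg_latency(cc)$latency))
    }))
  }))
  est100 <- t(vapply(1:100, function(r) {
    p <- simulate_coupled_pair(iv600, pre_rate = 5, post_rate = 10,
                               w_start = 0.10,
                               seed = derive_seed(seed, 100 + r))
    cc <- build_ccg(p$pre, p$post)
    c(transmission(cc)$transmission,
      as.numeric(ccg_latency(cc)$latency))
  }, numeric(2)))
  out$transmission <- list(
    pairs = tw, max_abs_err = max(abs(tw$est - tw$w)),
    bias100 = mean(est100[, 1]) - 0.10,
    latency_rmse = sqrt(mean((est100[, 2] - 1.5)^2, na.rm = TRUE)))

  # latency shifts of +/-0.25 ms across two sessions, sign recovery
  say("latency shift recovery ...")
  ivA <- intervals_df("A", 0, 600)
  ivB <- intervals_df("B", 600, 1200)
  shift_sign <- vapply(1:60, function(r) {
    s <- if (r %% 2 == 0) 1 else -1
    pA <- simulate_coupled_pair(ivA, 5, 10, w_start = 0.10, delay_ms = 1.5,
                                seed = derive_seed(seed, 300 + r))
    pB <- simulate_coupled_pair(ivB, 5, 10, w_start = 0.10,
                                delay_ms = 1.5 + s * 0.25,
                                seed = derive_seed(seed, 400 + r))
    pre <- c(pA$pre, pB$pre); post <- sort(c(pA$post, pB$post))
    lA <- ccg_latency(build_ccg(pre, post, epoch = ivA))$latency
    lB <- ccg_latency(build_ccg(pre, post, epoch = ivB))$latency
    sign(lB - lA) == s
  }, logical(1))
  out$latency_shift <- list(sign_rate = mean(shift_sign), n = 60)

  # ---- detection error rates ------------------------------------------
  say("detection error rates ...")
  set.seed(derive_seed(seed, 500))
  fp <- vapply(1:500, function(i) {
    pre <- poisson_train(1, iv600)
    post <- poisson_train(10, iv600)
    detect_mono(build_ccg(pre, post))$significant
  }, logical(1))
  sens <- vapply(1:100, function(r) {
    p <- simulate_coupled_pair(iv600, pre_rate = 2, post_rate = 10,
                               w_start = 0.05,
                               seed = derive_seed(seed, 600 + r))
    detect_mono(build_ccg(p$pre, p$post))$significant
  }, logical(1))
  out$detection <- list(fpr = mean(fp), n_null = 500,
                        sensitivity = mean(sens), n_conn = 100)

  # ---- simulated day: decoding + classification -----------------------
  say("simulating the scaled five-session day ...")
  n_p <- 30L; n_n <- 30L; n_u <- 200L
  cfg <- sim_config(n_pyr = 40, n_int = n_p + n_n, n_trials = 20,
                    trial_duration = 60, probe_duration = 360,
                    rest_duration = 180,
                    int_gain = rep(c(0.3, -0.3), c(n_p, n_n)),
                    seed = derive_seed(seed, 700))
  sim <- simulate_session(cfg, generate_lfp = FALSE)
  b <- sim$bundle
  ep <- session_epochs(b$intervals)
  geom <- map_geometry(radius = cfg$arena_radius + 1, bin_size = 4)
  ids <- seq_len(cfg$n_pyr) - 1L
  maps <- lapply(c("preprobe", "postprobe"), function(s)
    lapply(ids, function(u)
      compute_rate_map(b$spikes$t[b$spikes$unit_id == u], b$position,
                       intervals_for(b$intervals, s), geometry = geom)))
  stack_pre <- build_stack(maps[[1]], ids)
  stack_post <- build_stack(maps[[2]], ids)
  learn <- sim$truth$cycles[!is.na(sim$truth$cycles$trial), ]
  expr <- expression_series(b$spikes, learn, stack_pre, stack_post,
                            b$position)
  sel <- expr$valid & expr$n_active >= 10
  out$decoding <- list(
    accuracy = mean((expr$z[sel] > 0) == (learn$state[sel] == "new")),
    n_cycles = sum(sel),
    accuracy_all = mean((expr$z[expr$valid] > 0) ==
                          (learn$state[expr$valid] == "new")))

  say("classifying interneurons ...")
  win <- learn$trial > max(learn$trial) - 10
  classify <- function(st) {
    ifr <- instantaneous_rates(st, learn)
    tryCatch(associate(ifr, expr, window = win)$class,
             error = function(e) "uInt")
  }
  cls_pn <- vapply(sim$truth$int_ids, function(u)
    classify(b$spikes$t[b$spikes$unit_id == u]), character(1))
  # uncoupled units: independent Poisson interneurons at the baseline rate
  set.seed(derive_seed(seed, 800))
  span <- ep$learning_span
  cls_u <- vapply(seq_len(n_u), function(i)
    classify(poisson_train(cfg$int_base_rate,
                           intervals_df("l", span[1], span[2]))),
    character(1))
  truth_cls <- sim$truth$int_class
  rc <- vapply(sim$truth$int_ids, function(u)
    rate_change(b$spikes$t[b$spikes$unit_id == u], span)$index, numeric(1))
  sign_p <- stats::binom.test(sum(rc[truth_cls == "pInt"] > 0),
                              sum(truth_cls == "pInt"),
                              alternative = "greater")$p.value
  sign_n <- stats::binom.test(sum(rc[truth_cls == "nInt"] < 0),
                              sum(truth_cls == "nInt"),
                              alternative = "greater")$p.value
  out$classification <- list(
    sens_pint = mean(cls_pn[truth_cls == "pInt"] == "pInt"),
    sens_nint = mean(cls_pn[truth_cls == "nInt"] == "nInt"),
    fpr_uint = mean(cls_u != "uInt"), n_uint = n_u,
    rc_mean_pint = mean(rc[truth_cls == "pInt"]),
    rc_mean_nint = mean(rc[truth_cls == "nInt"]),
    rc_sign_p_pint = sign_p, rc_sign_p_nint = sign_n)

  # ---- closed forms ---------------------------------------------------
  say("closed forms ...")
  N <- 100
  sp_err <- vapply(c(1 / N, 0.25, 1), function(f) {
    r <- matrix(0, 10, 10)
    r[seq_len(round(f * N))] <- 4.2
    m <- structure(list(rate = r, rate_unsmoothed = r,
                        occupancy = matrix(1, 10, 10),
                        visited = matrix(TRUE, 10, 10), bin_size = 4,
                        origin = c(0, 0), nx = 10, ny = 10),
                   class = "rate_map")
    abs(map_sparsity(m) - f)
  }, numeric(1))
  dens_err <- abs(spike_density(0, 0.02)(0) - 1 / (0.02 * sqrt(2 * pi)))
  set.seed(derive_seed(seed, 900))
  iv3k <- intervals_df("e", 0, 3000)
  pre <- poisson_train(2, iv3k); post <- poisson_train(10, iv3k)
  ps <- pairing_events(pre, post, iv3k)
  p_exp <- 1 - exp(-10 * 0.02)
  ci <- stats::qbinom(c(0.025, 0.975), ps$n_pre_spikes, p_exp) /
    ps$n_pre_spikes
  out$closed_forms <- list(
    sparsity_max_err = max(sp_err), density_err = dens_err,
    pairing_frac = ps$n_post_window / ps$n_pre_spikes,
    pairing_expected = p_exp, pairing_in_ci =
      ps$n_post_window / ps$n_pre_spikes >= ci[1] &&
      ps$n_post_window / ps$n_pre_spikes <= ci[2])

  # ---- oracle equivalence ---------------------------------------------
  say("oracle equivalences ...")
  set.seed(derive_seed(seed, 1000))
  oracle_pair <- all(vapply(1:5, function(r) {
    a <- sort(stats::runif(10, 0, 10)); c <- sort(stats::runif(10, 0, 10))
    ps <- pairing_events(a, c, intervals_df("e", 0, 10))
    brute <- c(sum(vapply(a, function(t)
      any(c > t - 0.02 & c < t), logical(1))),
      sum(vapply(a, function(t)
        any(c > t & c < t + 0.02), logical(1))))
    identical(c(ps$n_pre_window, ps$n_post_window), as.integer(brute))
  }, logical(1)))
  # leave-one-out equals explicit recomputation
  n <- 14
  mkstack <- function(vals, cid) {
    maps <- lapply(vals, function(v) structure(list(
      rate = matrix(v, 5, 5), rate_unsmoothed = matrix(v, 5, 5),
      occupancy = matrix(1, 5, 5), visited = matrix(TRUE, 5, 5),
      bin_size = 4, origin = c(0, 0), nx = 5, ny = 5),
      class = "rate_map"))
    suppressWarnings(build_stack(maps, cid))
  }
  vp <- stats::rnorm(n); vq <- stats::rnorm(n); vec <- abs(stats::rnorm(n))
  loo <- expression_score(vec, mkstack(vp, 0:(n - 1)),
                          mkstack(vq, 0:(n - 1)), c(1, 1),
                          exclude_cell = 4L)
  keep <- setdiff(0:(n - 1), 4L)
  brute <- expression_score(vec[keep + 1], mkstack(vp[keep + 1], keep),
                            mkstack(vq[keep + 1], keep), c(1, 1))
  oracle_loo <- isTRUE(all.equal(loo$z, brute$z, tolerance = 1e-12))
  pre_e <- seq(1, 100, by = 0.4)
  cc_e <- build_ccg(pre_e, pre_e + 0.0015)
  oracle_ccg <- cc_e$prob[abs(cc_e$lags - 1.75) < 1e-9] == 1 &&
    sum(cc_e$counts > 0) == 1
  out$oracles <- list(pairing = oracle_pair, leave_one_out = oracle_loo,
                      ccg_echo = oracle_ccg)

  # ---- ensemble directional mirrors -----------------------------------
  say("ensemble mirrors ...")
  iv_day <- intervals_df(
    c("preprobe", "presleep", sprintf("trial%02d", 1:4), "postsleep",
      "postprobe"),
    c(0, 300, 600, 750, 900, 1050, 1200, 1500),
    c(300, 600, 750, 900, 1050, 1200, 1500, 1800))
  span_day <- session_epochs(iv_day)$learning_span
  set.seed(derive_seed(seed, 1100))
  dw <- stats::runif(40, -0.05, 0.10)
  w0 <- stats::runif(40, 0.05, 0.12)
  deltas <- t(vapply(1:40, function(k) {
    p <- simulate_coupled_pair(iv_day, 4, 10, w_start = w0[k],
                               w_end = pmin(pmax(w0[k] + dw[k], 0), 1),
                               learning = span_day,
                               seed = derive_seed(seed, 1200 + k))
    mp <- track_epochs(p$pre, p$post, iv_day)
    d <- mp$deltas
    c(probe = d$transmission[d$delta == "postprobe_minus_preprobe"],
      sleep = d$transmission[d$delta == "postsleep_minus_presleep"])
  }, numeric(2)))
  r_ps <- stats::cor(deltas[, 1], deltas[, 2])

  # latency change coupled to weight change: larger dw -> shorter delay
  lat_prob <- t(vapply(1:30, function(k) {
    dwk <- stats::runif(1, 0, 0.12)
    w1 <- 0.06
    pA <- simulate_coupled_pair(intervals_df("A", 0, 600), 4, 10,
                                w_start = w1, delay_ms = 1.8,
                                seed = derive_seed(seed, 1300 + k))
    pB <- simulate_coupled_pair(intervals_df("B", 600, 1200), 4, 10,
                                w_start = w1 + dwk,
                                delay_ms = 1.8 - 4 * dwk,
                                seed = derive_seed(seed, 1400 + k))
    pre <- c(pA$pre, pB$pre); post <- sort(c(pA$post, pB$post))
    ccA <- build_ccg(pre, post, epoch = intervals_df("A", 0, 600))
    ccB <- build_ccg(pre, post, epoch = intervals_df("B", 600, 1200))
    c(d_tr = transmission(ccB)$transmission - transmission(ccA)$transmission,
      d_lat = as.numeric(ccg_latency(ccB)$latency) -
        as.numeric(ccg_latency(ccA)$latency))
  }, numeric(2)))
  ok_lp <- is.finite(lat_prob[, 2])
  r_lp <- stats::cor(lat_prob[ok_lp, 1], lat_prob[ok_lp, 2])

  # pairing-count-driven plasticity recovered by predictor_analysis: the
  # coincidences realized during learning set the weight change expressed
  # across the surrounding probes
  say("pairing-count recovery ...")
  # probe epochs sized so that each CCG rests on >= 2000 reference spikes
  # (same regime as the transmission-recovery benchmark): the probe
  # estimator's noise stays well below the planted weight-change spread
  n_pairs <- 50
  rates <- cbind(stats::runif(n_pairs, 4, 8), stats::runif(n_pairs, 6, 16))
  learn_iv <- intervals_df("learn", 600, 1200)
  pre_iv <- intervals_df("preprobe", 0, 600)
  post_iv <- intervals_df("postprobe", 1200, 1800)
  rec <- do.call(rbind, lapply(1:n_pairs, function(k) {
    pl <- simulate_coupled_pair(learn_iv, rates[k, 1], rates[k, 2],
                                w_start = 0.05,
                                seed = derive_seed(seed, 1500 + k))
    ps <- pairing_events(pl$pre, pl$post, learn_iv)
    dwk <- min(1e-4 * ps$n_post_window, 0.25)
    pa <- simulate_coupled_pair(pre_iv, rates[k, 1], rates[k, 2],
                                w_start = 0.05,
                                seed = derive_seed(seed, 1600 + k))
    pb <- simulate_coupled_pair(post_iv, rates[k, 1], rates[k, 2],
                                w_start = 0.05 + dwk,
                                seed = derive_seed(seed, 1700 + k))
    ccA <- build_ccg(pa$pre, pa$post)
    ccB <- build_ccg(pb$pre, pb$post)
    data.frame(d_transmission = transmission(ccB)$transmission -
                 transmission(ccA)$transmission,
               n_pre_window = ps$n_pre_window,
               n_post_window = ps$n_post_window)
  }))
  rep_rec <- predictor_analysis(rec)
  out$ensemble <- list(r_probe_sleep = r_ps,
                       r_latency_prob = r_lp,
                       r_pairing_recovery = rep_rec$pairing_after$r,
                       n_pairs = n_pairs)
  out
}
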