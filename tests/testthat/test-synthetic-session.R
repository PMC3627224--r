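# Generator contracts: confinement, determinism, speed calibration, the
# place-field forward model, evoked-spike fidelity and the flicker schedule.

test_that("trajectories are confined, deterministic and speed-calibrated", {
  cfg <- sim_config(arena_radius = 60, seed = 1)
  trk <- generate_trajectory(cfg, c(0, 300), seed = 11)
  expect_true(all(trk$x^2 + trk$y^2 <= 60^2 + 1e-9))
  trk2 <- generate_trajectory(cfg, c(0, 300), seed = 11)
  expect_identical(trk, trk2)
  sp <- speed_series(trk)$speed
  expect_lt(abs(mean(sp, na.rm = TRUE) - 15) / 15, 0.2)
  expect_error(generate_trajectory(cfg, c(5, 5), seed = 1), "duration")
})

test_that("learning-trial trajectories visit every goal", {
  cfg <- sim_config(seed = 2)
  for (s in 1:3) {
    trk <- generate_trajectory(cfg, c(0, 45), seed = s, goals = cfg$goals)
    dmin <- vapply(seq_len(nrow(cfg$goals)), function(i)
      min(sqrt((trk$x - cfg$goals$x[i])^2 + (trk$y - cfg$goals$y[i])^2)),
      numeric(1))
    expect_true(all(dmin < 5))
  }
})

test_that("place_rate follows the Gaussian x theta-modulation closed form", {
  f <- list(old = list(x = 0, y = 0, sigma = 10, peak = 10),
            new = list(x = 30, y = 0, sigma = 10, peak = 10),
            phi_pref = 0)
  expect_equal(place_rate(f, "old", 0, 0, m = 0), 10)
  expect_equal(place_rate(f, "old", 10, 0, m = 0), 10 * exp(-0.5),
               tolerance = 1e-12)
  expect_lt(place_rate(f, "old", 500, 0, m = 0), 1e-10)
  expect_equal(place_rate(f, "new", 30, 0, m = 0), 10)
  # theta modulation bounds and rejection
  expect_equal(place_rate(f, "old", 0, 0, theta_phase = 0, m = 0.5), 15)
  expect_error(place_rate(f, "old", 0, 0, m = 1.5), "m ")
  f$old$sigma <- 0
  expect_error(place_rate(f, "old", 0, 0), "sigma")
})

test_that("identical (config, seed) reproduces the session exactly", {
  cfg <- sim_config(n_pyr = 6, n_int = 3, n_trials = 4, trial_duration = 30,
                    probe_duration = 60, rest_duration = 40, seed = 5)
  a <- simulate_session(cfg, generate_lfp = TRUE)
  b <- simulate_session(cfg, generate_lfp = TRUE)
  expect_identical(a$bundle$spikes, b$bundle$spikes)
  expect_identical(a$bundle$position, b$bundle$position)
  expect_identical(a$bundle$lfp$trace, b$bundle$lfp$trace)
  expect_identical(a$truth$cycles, b$truth$cycles)
})

test_that("session bundle invariants hold", {
  sim <- small_session()
  b <- sim$bundle
  for (u in unique(b$spikes$unit_id)) {
    st <- b$spikes$t[b$spikes$unit_id == u]
    expect_true(all(diff(st) > 0))
  }
  expect_true(all(b$spikes$t >= 0 & b$spikes$t <= max(b$intervals$t_end)))
  expect_equal(stats::sd(diff(b$position$t[1:1000])), 0, tolerance = 1e-9)
  # every theta cycle lies inside an exploratory session
  tc <- sim$truth$cycles
  expl <- intervals_for(b$intervals, pattern = "probe|trial")
  expect_true(all(in_intervals_pub(tc$t_start, expl)))
})

test_that("evoked spikes follow the weight schedule", {
  # w = 1, tight jitter: nearly every presynaptic spike has a follower
  p1 <- simulate_coupled_pair(intervals_df("e", 0, 200), pre_rate = 5,
                              post_rate = 0, w_start = 1,
                              delay_ms = 1.5, jitter_ms = 0.1, seed = 8)
  follow <- vapply(p1$pre, function(t)
    any(p1$post > t + 0.0012 & p1$post < t + 0.0018), logical(1))
  expect_gt(mean(follow), 0.99)
  # w = 0: no monosynaptic excess in the CCG
  p0 <- simulate_coupled_pair(intervals_df("e", 0, 600), pre_rate = 5,
                              post_rate = 10, w_start = 0, seed = 9)
  expect_false(detect_mono(build_ccg(p0$pre, p0$post))$significant)
  # evoked fraction matches w within binomial 95% bounds
  w <- 0.3
  p <- simulate_coupled_pair(intervals_df("e", 0, 400), pre_rate = 5,
                             post_rate = 0, w_start = w, seed = 10)
  ci <- stats::qbinom(c(0.025, 0.975), p$n_pre, w) / p$n_pre
  expect_gte(p$n_evoked / p$n_pre, ci[1])
  expect_lte(p$n_evoked / p$n_pre, ci[2])
})

test_that("flicker schedule governs latent cycle states", {
  cfg0 <- sim_config(n_pyr = 4, n_int = 2, n_trials = 4, trial_duration = 30,
                     probe_duration = 60, rest_duration = 30,
                     flicker_schedule = rep(0, 4), seed = 6)
  s0 <- simulate_session(cfg0, generate_lfp = FALSE)
  learn0 <- s0$truth$cycles[!is.na(s0$truth$cycles$trial), ]
  expect_true(all(learn0$state == "old"))
  # per-trial fraction of new cycles within binomial 95% bounds
  sim <- small_session()
  tc <- sim$truth$cycles
  sched <- sim$truth$config$flicker_schedule
  # joint test over all trials: 99.9% per-trial bounds keep the familywise
  # error below ~1%
  for (tr in unique(stats::na.omit(tc$trial))) {
    st <- tc$state[tc$trial %in% tr]
    n <- length(st)
    ci <- stats::qbinom(c(0.0005, 0.9995), n, sched[tr]) / n
    expect_gte(mean(st == "new"), ci[1] - 1e-9)
    expect_lte(mean(st == "new"), ci[2] + 1e-9)
  }
})

test_that("place cells fire far more inside their field than outside", {
  sim <- small_session()
  b <- sim$bundle
  tf <- sim$truth$fields
  expl <- intervals_for(b$intervals, "postprobe")
  trk <- b$position
  in_rate <- out_rate <- numeric(0)
  for (u in head(tf$unit_id, 8)) {
    st <- b$spikes$t[b$spikes$unit_id == u]
    st <- st[in_intervals_pub(st, expl)]
    samp <- trk[in_intervals_pub(trk$t, expl), ]
    d_samp <- sqrt((samp$x - tf$new_x[u + 1])^2 + (samp$y - tf$new_y[u + 1])^2)
    sx <- stats::approx(trk$t, trk$x, st, rule = 2)$y
    sy <- stats::approx(trk$t, trk$y, st, rule = 2)$y
    d_spk <- sqrt((sx - tf$new_x[u + 1])^2 + (sy - tf$new_y[u + 1])^2)
    dt <- 1 / sim$truth$config$position_fs
    t_in <- sum(d_samp < tf$sigma[u + 1]) * dt
    t_out <- sum(d_samp >= tf$sigma[u + 1]) * dt
    if (t_in < 5 || t_out < 5) next
    in_rate <- c(in_rate, sum(d_spk < tf$sigma[u + 1]) / t_in)
    out_rate <- c(out_rate, sum(d_spk >= tf$sigma[u + 1]) / t_out)
  }
  expect_gt(mean(in_rate), 5 * mean(out_rate))
})

test_that("bundle round-trips through the on-disk format", {
  cfg <- sim_config(n_pyr = 3, n_int = 2, n_trials = 2, trial_duration = 20,
                    probe_duration = 30, rest_duration = 20, seed = 12)
  sim <- simulate_session(cfg, generate_lfp = TRUE)
  d <- tempfile("bundle")
  write_session_bundle(sim, d)
  back <- read_session_bundle(d)
  expect_equal(back$spikes$t, sim$bundle$spikes$t, tolerance = 1e-6)
  expect_equal(back$intervals, sim$bundle$intervals)
  expect_equal(back$lfp$fs, sim$bundle$lfp$fs)
  expect_equal(back$lfp$trace, sim$bundle$lfp$trace, tolerance = 1e-4)
  expect_equal(back$truth$int_class, sim$truth$int_class)
  unlink(d, recursive = TRUE)
})
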