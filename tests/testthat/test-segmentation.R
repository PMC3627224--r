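# State segmentation and oscillation detection: analytic sinusoid counts,
# threshold behavior, and recovery of the simulator's session structure.

fs <- 1250

test_that("theta/delta ratio separates pure band-limited signals", {
  t <- seq(0, 20 - 1 / fs, 1 / fs)
  set.seed(1)
  r_theta <- theta_delta_ratio(sin(2 * pi * 8 * t) + 0.01 * rnorm(length(t)), fs)
  expect_true(all(r_theta$ratio > 2))
  r_delta <- theta_delta_ratio(sin(2 * pi * 3 * t) + 0.01 * rnorm(length(t)), fs)
  expect_true(all(r_delta$ratio < 1))
  expect_warning(out <- theta_delta_ratio(rnorm(100), fs), "shorter")
  expect_equal(nrow(out), 0)
})

test_that("ratio windows are 1600 ms stepped by 800 ms at window centers", {
  t <- seq(0, 10 - 1 / fs, 1 / fs)
  r <- theta_delta_ratio(sin(2 * pi * 8 * t), fs)
  expect_equal(r$t[1], 0.8)
  expect_equal(unique(round(diff(r$t), 6)), 0.8)
})

test_that("segment_states applies the speed/ratio/2.4 s rule", {
  tt <- seq(0.8, 100, by = 0.8)
  ratio_hi <- data.frame(t = tt, ratio = rep(5, length(tt)))
  fast <- data.frame(t = tt, speed = rep(20, length(tt)))
  s1 <- segment_states(ratio_hi, fast)
  expect_equal(s1$label, "exploration")
  ratio_lo <- data.frame(t = tt, ratio = rep(1, length(tt)))
  still <- data.frame(t = tt, speed = rep(0, length(tt)))
  s2 <- segment_states(ratio_lo, still)
  expect_equal(s2$label, "rest")
  # sub-2.4 s immobility is bridged into exploration
  ratio_mix <- ratio_hi
  ratio_mix$ratio[50:51] <- 1
  speed_mix <- fast
  speed_mix$speed[50:51] <- 0
  s3 <- segment_states(ratio_mix, speed_mix)
  expect_equal(s3$label, "exploration")
  expect_equal(nrow(s3), 1)
})

test_that("segmentation matches simulator session labels almost everywhere", {
  sim <- small_session_lfp()
  b <- sim$bundle
  ratio <- theta_delta_ratio(b$lfp$trace, b$lfp$fs)
  states <- segment_states(ratio, speed_series(b$position))
  ep <- session_epochs(b$intervals)
  grid <- seq(1, max(b$intervals$t_end) - 1, by = 0.5)
  truth_rest <- in_intervals_pub(grid, ep$rest)
  est_rest <- in_intervals_pub(grid, intervals_for(states, "rest"))
  expect_gt(mean(truth_rest == est_rest), 0.95)
  # labeled intervals tile the covered span without overlap
  o <- states[order(states$t_start), ]
  expect_true(all(diff(o$t_start) > 0))
  expect_true(all(o$t_end[-nrow(o)] <= o$t_start[-1] + 1e-9))
})

test_that("cycle counts on pure sinusoids match f*T within one", {
  t10 <- seq(0, 10 - 1 / fs, 1 / fs)
  th <- detect_theta_cycles(sin(2 * pi * 8 * t10), fs, intervals_df("e", 0, 10))
  expect_true(abs(nrow(th) - 79) <= 1)
  expect_equal(median(th$t_end - th$t_start), 1 / 8, tolerance = 0.01)
  t1 <- seq(0, 1 - 1 / fs, 1 / fs)
  ga <- detect_gamma_cycles(sin(2 * pi * 50 * t1), fs, intervals_df("e", 0, 1))
  expect_true(abs(nrow(ga) - 49) <= 1)
  # 8 Hz carries no valid gamma cycles
  ga8 <- detect_gamma_cycles(sin(2 * pi * 8 * t10), fs, intervals_df("e", 0, 10))
  expect_equal(nrow(ga8), 0)
  expect_equal(nrow(detect_theta_cycles(sin(2 * pi * 8 * t10), fs,
                                        intervals_df(character(), numeric(),
                                                     numeric()))), 0)
})

test_that("white noise yields few valid theta cycles", {
  set.seed(3)
  x <- rnorm(10 * fs)
  th <- detect_theta_cycles(x, fs, intervals_df("e", 0, 10))
  expect_lt(nrow(th), 0.1 * 80)
})

test_that("theta cycle boundaries are local minima of the filtered trace", {
  sim <- small_session_lfp()
  b <- sim$bundle
  expl <- intervals_for(b$intervals, "preprobe")
  th <- detect_theta_cycles(b$lfp$trace, b$lfp$fs, expl)
  filt <- thetaflick:::zerophase_bandpass(b$lfp$trace, b$lfp$fs, c(5, 28))
  idx <- round(th$t_start[1:50] * b$lfp$fs) + 1
  expect_true(all(filt[idx] <= filt[idx - 1] & filt[idx] <= filt[idx + 1]))
})

test_that("gamma cycles nest inside theta cycles or none", {
  sim <- small_session_lfp()
  b <- sim$bundle
  expl <- intervals_for(b$intervals, "preprobe")
  th <- detect_theta_cycles(b$lfp$trace, b$lfp$fs, expl)
  ga <- detect_gamma_cycles(b$lfp$trace, b$lfp$fs, expl)
  expect_gt(nrow(ga), 0)
  # a gamma cycle fully contained in some theta cycle has exactly one
  # parent; the rest have none
  k <- findInterval(ga$t_start, th$t_start)
  contained <- k >= 1 & ga$t_end <= th$t_end[pmax(k, 1)] &
    ga$t_start >= th$t_start[pmax(k, 1)]
  expect_gt(sum(contained), 0)
  # parents are unambiguous: theta cycles are disjoint and ordered
  expect_true(all(diff(th$t_start) > 0))
  expect_true(all(th$t_end[-nrow(th)] <= th$t_start[-1] + 1e-9))
})

test_that("SWR detection finds injected ripples and little else", {
  set.seed(4)
  n <- 20 * fs
  tt <- (0:(n - 1)) / fs
  noise <- rnorm(n)
  burst <- 10 * exp(-(tt - 5)^2 / (2 * 0.01^2)) * sin(2 * pi * 200 * (tt - 5))
  ev <- detect_swr(noise + burst, fs, intervals_df("rest", 0, 20))
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$t_peak - 5), 0.02)
  # pure noise: fewer than one event per 10 s at 7 SD
  ev0 <- detect_swr(rnorm(n), fs, intervals_df("rest", 0, 20))
  expect_lt(nrow(ev0), 2)
  expect_equal(nrow(detect_swr(noise, fs,
                               intervals_df(character(), numeric(),
                                            numeric()))), 0)
  expect_error(detect_swr(rep(1, n), fs, intervals_df("rest", 0, 20)),
               "variance")
})
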