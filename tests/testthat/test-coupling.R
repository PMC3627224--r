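# Cross-correlogram construction, monosynaptic detection, transmission and
# latency estimation, the coincidence coefficient, and epoch tracking.

test_that("an echo train puts probability 1 in the bin containing +1.5 ms", {
  pre <- seq(1, 100, by = 0.4)
  post <- pre + 0.0015
  cc <- build_ccg(pre, post)
  k <- which(abs(cc$lags - 1.75) < 1e-9)   # bin [1.5, 2.0) holds lag 1.5
  expect_equal(cc$prob[k], 1)
  expect_equal(sum(cc$counts > 0), 1)
  expect_equal(sum(cc$counts), length(pre))
  expect_error(build_ccg(numeric(0), post), "empty")
})

test_that("CCG counts are symmetric under train swap with lag negation", {
  set.seed(1)
  pre <- sort(runif(300, 0, 100))
  post <- sort(runif(800, 0, 100))
  a <- build_ccg(pre, post)
  b <- build_ccg(post, pre)
  expect_equal(a$counts, rev(b$counts))
})

test_that("independent Poisson pair matches the analytic flat CCG", {
  set.seed(2)
  iv <- intervals_df("e", 0, 1000)
  pre <- poisson_train(1, iv)
  post <- poisson_train(10, iv)
  cc <- build_ccg(pre, post)
  expected <- 10 * 0.0005
  sd3 <- 3 * sqrt(expected / cc$n_ref)
  expect_true(all(abs(cc$prob - expected) < sd3 + 2e-3))
  base <- chance_baseline(cc)
  expect_equal(base$mean, expected, tolerance = 0.2)
  expect_equal(base$n_bins, 80)
})

test_that("chance baseline ignores the monosynaptic window", {
  pre <- seq(1, 200, by = 0.5)
  set.seed(3)
  post <- sort(c(pre + 0.0015, poisson_train(5, intervals_df("e", 0, 200))))
  cc <- build_ccg(pre, post)
  cc_null <- build_ccg(pre, sort(poisson_train(5, intervals_df("e", 0, 200))))
  b1 <- chance_baseline(cc)$mean
  b0 <- chance_baseline(cc_null)$mean
  expect_equal(b1, b0, tolerance = 0.3)
  # flat CCG: transmission exactly 0
  flat <- cc_null
  flat$prob <- rep(0.005, length(flat$prob))
  expect_equal(transmission(flat)$transmission, 0, tolerance = 1e-12)
  expect_lt(chance_baseline(flat)$sd, 1e-12)
})

test_that("detection respects the 0.5-2.5 ms window and 3 SD rule", {
  set.seed(4)
  # peak at 5 ms only: outside the monosynaptic window
  pre <- seq(1, 400, by = 0.5)
  post5 <- sort(c(pre + 0.0052, poisson_train(3, intervals_df("e", 0, 400))))
  cc5 <- build_ccg(pre, post5)
  expect_false(detect_mono(cc5)$significant)
  expect_gt(transmission(cc5)$control_5ms, 0.5)
  # simulated connected pair is detected
  p <- simulate_coupled_pair(intervals_df("e", 0, 500), pre_rate = 4,
                             post_rate = 10, w_start = 0.1, seed = 5)
  expect_true(detect_mono(build_ccg(p$pre, p$post))$significant)
})

test_that("transmission recovers the weight and nulls stay at zero", {
  p <- simulate_coupled_pair(intervals_df("e", 0, 600), pre_rate = 4,
                             post_rate = 10, w_start = 0.2, seed = 6)
  cc <- build_ccg(p$pre, p$post)
  tr <- transmission(cc)
  # oracle: brute-force count of evoked spikes actually emitted
  oracle <- p$n_evoked / p$n_pre
  expect_lt(abs(tr$transmission - oracle), 0.015)
  expect_lt(abs(tr$transmission - 0.2), 0.02)
  expect_lt(abs(tr$control_30_50), 1e-12)
  # w = 0 within 3 binomial SD of zero
  p0 <- simulate_coupled_pair(intervals_df("e", 0, 600), pre_rate = 4,
                              post_rate = 10, w_start = 0, seed = 7)
  tr0 <- transmission(build_ccg(p0$pre, p0$post))$transmission
  expect_lt(abs(tr0), 3 * sqrt(10 * 0.0005 * 4 / p0$n_pre))
})

test_that("latency is the baseline-subtracted center of mass", {
  # evoked mass in the bin centered at 1.75 ms over a sparse baseline
  set.seed(20)
  pre <- seq(1, 100, by = 0.4)
  bg <- poisson_train(1, intervals_df("e", 0, 100))
  cc <- build_ccg(pre, sort(c(pre + 0.0017, bg)))
  det <- detect_mono(cc)
  expect_true(det$significant)
  expect_equal(ccg_latency(cc, det)$latency, 1.75, tolerance = 0.01)
  # two equal masses at the 1.0-1.5 and 2.0-2.5 bins average to 1.75
  n <- length(pre)
  half <- seq_len(floor(n / 2))
  post2 <- sort(c(pre[half] + 0.0012, pre[-half] + 0.0022, bg))
  cc2 <- build_ccg(pre, post2)
  expect_equal(ccg_latency(cc2)$latency, (1.25 + 2.25) / 2, tolerance = 0.03)
  # ground-truth delay recovered within 0.2 ms
  p <- simulate_coupled_pair(intervals_df("e", 0, 600), pre_rate = 4,
                             post_rate = 10, w_start = 0.1, seed = 8)
  lat <- ccg_latency(build_ccg(p$pre, p$post))$latency
  expect_lt(abs(lat - 1.5), 0.2)
  # non-significant pair: flagged undefined
  p0 <- simulate_coupled_pair(intervals_df("e", 0, 300), pre_rate = 2,
                              post_rate = 10, w_start = 0, seed = 9)
  l0 <- ccg_latency(build_ccg(p0$pre, p0$post))
  expect_true(is.na(l0$latency))
})

test_that("coincidence coefficient is Pearson-normalized and rate-robust", {
  set.seed(10)
  tr <- sort(runif(400, 0, 200))
  cc <- coincidence_corrcoef(tr, tr, intervals_df("e", 0, 200))
  expect_equal(cc$coef[cc$lag == 0], 1, tolerance = 1e-9)
  # independent pair: coefficients near zero at all lags
  a <- poisson_train(5, intervals_df("e", 0, 400))
  b <- poisson_train(8, intervals_df("e", 0, 400))
  cc0 <- coincidence_corrcoef(a, b, intervals_df("e", 0, 400))
  expect_true(all(abs(cc0$coef) < 5 / sqrt(400 / 0.0005)))
  # thinning both trains preserves the coefficient scale, unlike raw prob
  p <- simulate_coupled_pair(intervals_df("e", 0, 600), pre_rate = 6,
                             post_rate = 12, w_start = 0.3, seed = 11)
  keep <- function(x) x[runif(length(x)) < 0.5]
  c_full <- coincidence_corrcoef(p$pre, p$post, intervals_df("e", 0, 600))
  c_thin <- coincidence_corrcoef(keep(p$pre), keep(p$post),
                                 intervals_df("e", 0, 600))
  peak_full <- max(c_full$coef[c_full$lag > 0 & c_full$lag <= 3])
  peak_thin <- max(c_thin$coef[c_thin$lag > 0 & c_thin$lag <= 3])
  expect_lt(abs(peak_thin / peak_full - 0.5), 0.25)  # ~ w scales with thinning
  expect_error(coincidence_corrcoef(numeric(0), b), "empty")
})

test_that("track_epochs recovers learning-restricted weight drift", {
  iv <- intervals_df(
    c("preprobe", "presleep", sprintf("trial%02d", 1:4), "postsleep",
      "postprobe"),
    c(0, 300, 600, 750, 900, 1050, 1200, 1500),
    c(300, 600, 750, 900, 1050, 1200, 1500, 1800))
  ep <- session_epochs(iv)
  p <- simulate_coupled_pair(iv, pre_rate = 4, post_rate = 10,
                             w_start = 0.05, w_end = 0.15,
                             learning = ep$learning_span, seed = 12)
  mp <- track_epochs(p$pre, p$post, iv)
  expect_true(mp$detection$significant)
  d <- mp$deltas
  probe_d <- d$transmission[d$delta == "postprobe_minus_preprobe"]
  expect_lt(abs(probe_d - 0.10), 0.03)
  sleep_d <- d$transmission[d$delta == "postsleep_minus_presleep"]
  expect_lt(abs(sleep_d - 0.10), 0.03)
  expect_lt(abs(d$control_5ms[2]), 0.02)
  # constant-w pair: deltas within noise of zero
  p0 <- simulate_coupled_pair(iv, pre_rate = 4, post_rate = 10,
                              w_start = 0.10, seed = 13)
  mp0 <- track_epochs(p0$pre, p0$post, iv)
  expect_lt(abs(mp0$deltas$transmission[2]), 0.03)
  expect_true(all(!mp0$per_epoch$low_count))
})
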