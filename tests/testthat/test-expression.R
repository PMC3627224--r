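# Assembly-expression scoring: stack construction, cycle vectors, the
# Fisher r-to-z score and its exact symmetries, and latent-state decoding.

test_that("stacks assemble and slice consistently", {
  r1 <- matrix(runif(100), 10, 10)
  maps <- lapply(1:14, function(i) manual_rate_map(r1 * i))
  st <- build_stack(maps, 0:13)
  expect_equal(dim(st$rates), c(10, 10, 14))
  expect_equal(st$rates[3, 7, ], vapply(maps, function(m) m$rate[3, 7],
                                        numeric(1)))
  expect_error(build_stack(maps[1]), "at least 2")
  expect_warning(build_stack(maps[1:5], 0:4), "14")
  # constant maps -> identical population vectors at every location
  cst <- lapply(1:14, function(i) manual_rate_map(matrix(i, 10, 10)))
  stc <- suppressWarnings(build_stack(cst, 0:13))
  expect_equal(stc$rates[1, 1, ], stc$rates[9, 4, ])
})

test_that("cycle vectors are counts over duration in stack order", {
  spikes <- data.frame(unit_id = c(0, 0, 1, 2), t = c(1.01, 1.05, 1.02, 2))
  v <- cycle_vector(spikes, c(1.0, 1.125), 0:2)
  expect_equal(unname(v), c(2, 1, 0) / 0.125)
  expect_equal(unname(v[1]), 16)
  expect_error(cycle_vector(spikes, c(1, 1), 0:2), "positive")
})

test_that("per-cycle vectors conserve trial spike counts", {
  sim <- small_session()
  ex <- small_expression()
  learn <- ex$learn
  tr1 <- learn[learn$trial %in% 1, ]
  cnt <- thetaflick:::cycle_count_matrix(sim$bundle$spikes, tr1, 0:4)
  for (u in 0:4) {
    st <- sim$bundle$spikes$t[sim$bundle$spikes$unit_id == u]
    direct <- sum(st >= min(tr1$t_start) & st < max(tr1$t_end))
    # cycles tile the trial up to half-cycle edges
    expect_lte(abs(sum(cnt[u + 1, ]) - direct), 5)
  }
})

test_that("expression score matches the Fisher r-to-z closed form", {
  # construct vectors with known correlations: n = 14
  set.seed(4)
  n <- 14
  stack_of <- function(vals) {
    maps <- lapply(vals, function(v) manual_rate_map(matrix(v, 5, 5)))
    suppressWarnings(build_stack(maps, seq_len(n) - 1))
  }
  base <- rnorm(n)
  vec <- base
  # orthogonalize: r_pre = 0 against x, r_post = 0.5 against y
  x <- residuals(lm(rnorm(n) ~ base))
  y <- 0.5 * scale(base)[, 1] + sqrt(1 - 0.25) * scale(x)[, 1]
  sp <- stack_of(x); sq <- stack_of(y)
  sc <- expression_score(vec, sp, sq, c(0, 0))
  expect_true(sc$valid)
  expect_equal(sc$r_pre, 0, tolerance = 1e-10)
  expect_equal(sc$r_post, 0.5, tolerance = 1e-10)
  expect_equal(sc$z, atanh(0.5) / sqrt(2 / 11), tolerance = 1e-10)
  expect_equal(sc$z, 1.288, tolerance = 1e-3)
  # identical stacks -> z = 0 exactly
  s0 <- expression_score(vec, sp, sp, c(0, 0))
  expect_identical(s0$z, 0)
  # antisymmetry: swapping stacks negates z exactly
  swapped <- expression_score(vec, sq, sp, c(0, 0))
  expect_identical(swapped$z, -sc$z)
  expect_error(expression_score(vec[1:3], stack_of(x[1:3]), stack_of(y[1:3]),
                                c(0, 0)))
})

test_that("scores are invariant under consistent cell permutation", {
  set.seed(5)
  n <- 14
  vals_p <- rnorm(n); vals_q <- rnorm(n); vec <- rnorm(n)
  mk <- function(vals, ids) {
    maps <- lapply(vals, function(v) manual_rate_map(matrix(v, 5, 5)))
    suppressWarnings(build_stack(maps, ids))
  }
  perm <- sample(n)
  a <- expression_score(vec, mk(vals_p, 0:(n - 1)), mk(vals_q, 0:(n - 1)),
                        c(1, 1))
  b <- expression_score(vec[perm], mk(vals_p[perm], perm - 1),
                        mk(vals_q[perm], perm - 1), c(1, 1))
  expect_equal(a$z, b$z, tolerance = 1e-12)
  expect_equal(a$r_pre, b$r_pre, tolerance = 1e-12)
})

test_that("leave-one-out equals brute-force recomputation", {
  set.seed(6)
  n <- 14
  vals_p <- rnorm(n); vals_q <- rnorm(n); vec <- abs(rnorm(n))
  mk <- function(vals, ids) {
    maps <- lapply(vals, function(v) manual_rate_map(matrix(v, 5, 5)))
    suppressWarnings(build_stack(maps, ids))
  }
  full_p <- mk(vals_p, 0:(n - 1)); full_q <- mk(vals_q, 0:(n - 1))
  for (drop_id in c(0, 7, 13)) {
    keep <- setdiff(0:(n - 1), drop_id)
    loo <- expression_score(vec, full_p, full_q, c(2, 2),
                            exclude_cell = drop_id)
    brute <- expression_score(vec[keep + 1], mk(vals_p[keep + 1], keep),
                              mk(vals_q[keep + 1], keep), c(2, 2))
    expect_equal(loo$z, brute$z, tolerance = 1e-12)
    expect_equal(loo$n_cells, n - 1)
  }
})

test_that("zero-spike cycles are scored invalid, not imputed", {
  ex <- small_expression()
  zero <- ex$expr$n_active == 0
  expect_true(all(!ex$expr$valid[zero]))
})

test_that("sign(z) decodes the latent map state on simulated cycles", {
  sim <- small_session()
  ex <- small_expression()
  sel <- ex$expr$valid
  acc <- mean((ex$expr$z[sel] > 0) == (ex$learn$state[sel] == "new"))
  expect_gt(acc, 0.85)
  expect_gt(median(ex$expr$z[sel & ex$learn$state == "new"]), 0)
  expect_lt(median(ex$expr$z[sel & ex$learn$state == "old"]), 0)
})

test_that("gamma-cycle scores agree with their containing theta cycle", {
  sim <- small_session()
  st <- small_stacks()
  ex <- small_expression()
  learn <- ex$learn
  # synthetic gamma cycles: split each theta cycle into thirds
  sub <- learn[seq_len(min(2000, nrow(learn))), ]
  g1 <- data.frame(t_start = sub$t_start,
                   t_end = sub$t_start + (sub$t_end - sub$t_start) / 3)
  g2 <- data.frame(t_start = g1$t_end,
                   t_end = sub$t_start + 2 * (sub$t_end - sub$t_start) / 3)
  gam <- rbind(g1, g2)
  gam <- gam[order(gam$t_start), ]
  exg <- expression_series(sim$bundle$spikes, gam, st$stack_pre,
                           st$stack_post, sim$bundle$position,
                           oscillation = "gamma", theta_cycles = sub)
  expect_true(all(!is.na(exg$theta_id)))
  both <- !is.na(exg$z) & !is.na(ex$expr$z[exg$theta_id])
  expect_gt(cor(exg$z[both], ex$expr$z[exg$theta_id][both]), 0)
})
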