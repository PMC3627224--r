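# Shared simulated fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memoize <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small simulated day shared by module tests (no LFP; spikes only)
small_session <- function() memoize("small_session", function() {
  cfg <- sim_config(n_pyr = 25, n_int = 9, n_trials = 12,
                    trial_duration = 45, probe_duration = 240,
                    rest_duration = 120, seed = 42L)
  simulate_session(cfg, generate_lfp = FALSE)
})

# same scaled day with LFP, for segmentation / pipeline tests
small_session_lfp <- function() memoize("small_session_lfp", function() {
  cfg <- sim_config(n_pyr = 20, n_int = 6, n_trials = 8,
                    trial_duration = 45, probe_duration = 180,
                    rest_duration = 120, seed = 43L)
  simulate_session(cfg, generate_lfp = TRUE, swr_rate = 0.1)
})

# probe rate maps and population-vector stacks for the small session
small_stacks <- function() memoize("small_stacks", function() {
  sim <- small_session()
  b <- sim$bundle
  geom <- map_geometry(radius = sim$truth$config$arena_radius + 1,
                       bin_size = 4)
  ids <- seq_len(sim$truth$config$n_pyr) - 1L
  pre <- lapply(ids, function(u)
    compute_rate_map(b$spikes$t[b$spikes$unit_id == u], b$position,
                     intervals_for(b$intervals, "preprobe"),
                     geometry = geom))
  post <- lapply(ids, function(u)
    compute_rate_map(b$spikes$t[b$spikes$unit_id == u], b$position,
                     intervals_for(b$intervals, "postprobe"),
                     geometry = geom))
  list(pre_maps = pre, post_maps = post,
       stack_pre = build_stack(pre, ids),
       stack_post = build_stack(post, ids), ids = ids)
})

# expression series over learning cycles of the small session
small_expression <- function() memoize("small_expression", function() {
  sim <- small_session()
  st <- small_stacks()
  learn <- sim$truth$cycles[!is.na(sim$truth$cycles$trial), ]
  list(learn = learn,
       expr = expression_series(sim$bundle$spikes, learn, st$stack_pre,
                                st$stack_post, sim$bundle$position))
})

# interval membership predicate usable from any test file
in_intervals_pub <- function(t, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(t)))
  iv <- iv[order(iv$t_start), ]
  idx <- findInterval(t, iv$t_start)
  ok <- idx >= 1
  ok[ok] <- t[ok] < iv$t_end[idx[ok]]
  ok
}

# hand-built rate_map with explicit fields (for closed-form statistics)
manual_rate_map <- function(rate, occupancy = NULL, bin_size = 4) {
  nx <- nrow(rate); ny <- ncol(rate)
  if (is.null(occupancy)) occupancy <- matrix(1, nx, ny)
  structure(list(rate = rate, rate_unsmoothed = rate,
                 occupancy = occupancy, visited = occupancy > 0,
                 spike_count = NA, bin_size = bin_size,
                 origin = c(0, 0), nx = nx, ny = ny),
            class = "rate_map")
}
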