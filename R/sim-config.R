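#' Configuration for a synthetic five-session experiment
#'
#' Defines a full simulated recording day on a circular cheeseboard arena:
#' preprobe, presleep, learning trials, postsleep, postprobe. Pyramidal cells
#' carry Gaussian place fields in two spatial maps ("old" and "new"); each
#' theta cycle of exploratory epochs expresses one latent map, with the
#' per-trial probability of the new map given by `flicker_schedule`.
#' Interneurons fire a baseline modulated by the latent map state
#' (`int_gain`) and receive monosynaptic input from pyramidal cells via
#' `connection_table`, whose weights may drift during learning only.
#'
#' @param arena_radius arena radius (cm).
#' @param n_pyr,n_int numbers of pyramidal cells and interneurons.
#' @param n_trials number of learning trials.
#' @param trial_duration,probe_duration,rest_duration epoch durations (s).
#' @param theta_freq theta frequency (Hz).
#' @param mean_speed target mean running speed (cm/s).
#' @param frac_remap fraction of pyramidal cells whose new-map field center
#'   is redrawn independently of the old-map center.
#' @param flicker_schedule per-trial probability that a theta cycle expresses
#'   the new map; length `n_trials`, nondecreasing, in `[0, 1]`.
#' @param goals matrix or data.frame of goal coordinates (x, y in cm); must
#'   lie inside the arena.
#' @param connection_table data.frame with columns `pre`, `post`, `w_start`,
#'   `w_end`, `delay_ms`, `jitter_ms`: monosynaptic pyramidal->interneuron
#'   connections; weight ramps linearly from `w_start` to `w_end` across
#'   learning and is constant outside it. `NULL` for the default wiring
#'   (see Details), `NA` to disable all connections.
#' @param int_base_rate interneuron baseline rate (Hz).
#' @param int_gain per-interneuron state gain in `[-1, 1]`: rate is
#'   `int_base_rate * (1 + gain)` on new-map cycles and
#'   `int_base_rate * (1 - gain)` on old-map cycles. Sign defines the ground
#'   truth class (positive = pInt, negative = nInt, zero = uInt). `NULL`
#'   splits interneurons into equal thirds (+0.3, -0.3, 0).
#' @param pyr_peak_rate in-field peak rate of place cells (Hz).
#' @param pyr_rest_rate pyramidal baseline rate during rest/sleep (Hz).
#' @param sigma_field Gaussian place-field width (cm).
#' @param theta_mod depth of theta rate modulation in `[0, 1]`.
#' @param position_fs position sampling rate (Hz).
#' @param lfp_fs LFP sampling rate (Hz).
#' @param seed integer seed; the generator is fully deterministic given
#'   (config, seed).
#'
#' @details
#' The default wiring gives every interneuron two presynaptic pyramidal
#' cells: pInt interneurons are driven by remapped ("new-assembly") cells
#' with weights rising 0.05 to 0.15 across learning, nInt by cells falling
#' 0.15 to 0.05, uInt by constant-weight 0.10 connections.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(arena_radius = 60,
                       n_pyr = 40,
                       n_int = 9,
                       n_trials = 40,
                       trial_duration = 45,
                       probe_duration = 1500,
                       rest_duration = 1500,
                       theta_freq = 8,
                       mean_speed = 15,
                       frac_remap = 0.8,
                       flicker_schedule = NULL,
                       goals = NULL,
                       connection_table = NULL,
                       int_base_rate = 15,
                       int_gain = NULL,
                       pyr_peak_rate = 12,
                       pyr_rest_rate = 1,
                       sigma_field = 12,
                       theta_mod = 0.5,
                       position_fs = 40,
                       lfp_fs = 1250,
                       seed = 1L) {
  if (is.null(flicker_schedule))
    flicker_schedule <- seq(0.1, 0.9, length.out = n_trials)
  stopifnot(length(flicker_schedule) == n_trials,
            all(flicker_schedule >= 0), all(flicker_schedule <= 1),
            all(diff(flicker_schedule) >= -1e-12))
  if (is.null(goals)) {
    ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
    goals <- data.frame(x = arena_radius / 2 * cos(ang),
                        y = arena_radius / 2 * sin(ang))
  }
  goals <- as.data.frame(goals)
  names(goals) <- c("x", "y")
  stopifnot(all(goals$x^2 + goals$y^2 <= arena_radius^2))
  if (is.null(int_gain)) {
    third <- ceiling(n_int / 3)
    int_gain <- rep(c(0.3, -0.3, 0), c(third, third, n_int - 2 * third))
    int_gain <- int_gain[seq_len(n_int)]
  }
  stopifnot(length(int_gain) == n_int, all(abs(int_gain) <= 1))
  stopifnot(frac_remap >= 0, frac_remap <= 1,
            theta_mod >= 0, theta_mod <= 1,
            trial_duration > 0, probe_duration > 0, rest_duration > 0)
  cfg <- structure(list(
    arena_radius = arena_radius, n_pyr = n_pyr, n_int = n_int,
    n_trials = n_trials, trial_duration = trial_duration,
    probe_duration = probe_duration, rest_duration = rest_duration,
    theta_freq = theta_freq, mean_speed = mean_speed,
    frac_remap = frac_remap, flicker_schedule = flicker_schedule,
    goals = goals, connection_table = connection_table,
    int_base_rate = int_base_rate, int_gain = int_gain,
    pyr_peak_rate = pyr_peak_rate, pyr_rest_rate = pyr_rest_rate,
    sigma_field = sigma_field, theta_mod = theta_mod,
    position_fs = position_fs, lfp_fs = lfp_fs,
    seed = as.integer(seed)), class = "sim_config")
  if (!is.null(cfg$connection_table) && !is.data.frame(cfg$connection_table) &&
      all(is.na(cfg$connection_table))) {
    cfg$connection_table <- data.frame(pre = integer(), post = integer(),
                                       w_start = numeric(), w_end = numeric(),
                                       delay_ms = numeric(), jitter_ms = numeric())
  }
  if (!is.null(cfg$connection_table)) validate_connections(cfg)
  cfg
}

validate_connections <- function(cfg) {
  ct <- cfg$connection_table
  stopifnot(is.data.frame(ct),
            all(c("pre", "post", "w_start", "w_end", "delay_ms",
                  "jitter_ms") %in% names(ct)))
  if (nrow(ct)) {
    stopifnot(all(ct$w_start >= 0), all(ct$w_start <= 1),
              all(ct$w_end >= 0), all(ct$w_end <= 1),
              all(ct$delay_ms > 0.5), all(ct$delay_ms < 2.5),
              all(ct$jitter_ms >= 0),
              all(ct$pre >= 0), all(ct$pre < cfg$n_pyr),
              all(ct$post >= 0), all(ct$post < cfg$n_int))
  }
  invisible(ct)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic session configuration\n")
  cat(sprintf("  arena radius %g cm, %d pyramidal cells, %d interneurons\n",
              x$arena_radius, x$n_pyr, x$n_int))
  cat(sprintf("  %d learning trials x %g s; probes %g s; rests %g s\n",
              x$n_trials, x$trial_duration, x$probe_duration, x$rest_duration))
  cat(sprintf("  theta %g Hz, mean speed %g cm/s, remap fraction %g\n",
              x$theta_freq, x$mean_speed, x$frac_remap))
  cat(sprintf("  p(new) %.2f -> %.2f across trials; seed %d\n",
              x$flicker_schedule[1], x$flicker_schedule[x$n_trials], x$seed))
  invisible(x)
}
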