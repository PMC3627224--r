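#' Generate a foraging trajectory on the circular arena
#'
#' Smoothed random walk (Ornstein-Uhlenbeck velocity) confined to the disc of
#' radius `config$arena_radius`, sampled at `config$position_fs`. When
#' `goals` are supplied (learning trials), the heading is biased toward the
#' next unvisited goal until all goals have been visited, after which the
#' animal forages freely; this guarantees at least one visit per goal for
#' trials long enough to reach them.
#'
#' @param config a [sim_config()].
#' @param interval numeric length-2 vector `c(t_start, t_end)` (s).
#' @param seed integer seed.
#' @param goals optional goal coordinates to visit (data.frame x, y).
#' @return data.frame with columns `t`, `x`, `y`.
#' @export
generate_trajectory <- function(config, interval, seed, goals = NULL) {
  dur <- diff(interval)
  if (!is.finite(dur) || dur <= 0)
    stop("trajectory interval must have positive duration")
  fs <- config$position_fs
  dt <- 1 / fs
  n <- floor(dur * fs)
  R <- config$arena_radius
  set.seed(as.integer(seed))
  # OU velocity: relaxation tau, stationary speed scale calibrated so that
  # the mean speed of the 2D OU process (Rayleigh mean sigma*sqrt(pi/2))
  # matches config$mean_speed
  tau <- 1.0
  sigma_v <- config$mean_speed / sqrt(pi / 2)
  x <- numeric(n); y <- numeric(n)
  xc <- stats::runif(1, -R / 2, R / 2); yc <- stats::runif(1, -R / 2, R / 2)
  vx <- stats::rnorm(1, 0, sigma_v); vy <- stats::rnorm(1, 0, sigma_v)
  gvec <- if (!is.null(goals) && nrow(goals)) as.matrix(goals[, c("x", "y")]) else NULL
  goal_i <- 1L
  tau_goal <- 0.5       # homing time constant while running to a goal
  noise <- sigma_v * sqrt(2 * dt / tau)
  for (i in seq_len(n)) {
    seeking <- !is.null(gvec) && goal_i <= nrow(gvec)
    if (seeking) {
      dx <- gvec[goal_i, 1] - xc; dy <- gvec[goal_i, 2] - yc
      d <- sqrt(dx^2 + dy^2)
      if (d < 5) { seeking <- FALSE; goal_i <- goal_i + 1L }
      else {
        # relax velocity toward a straight run at the goal
        ax <- (config$mean_speed * dx / d - vx) / tau_goal
        ay <- (config$mean_speed * dy / d - vy) / tau_goal
      }
    }
    if (!seeking) { ax <- -vx / tau; ay <- -vy / tau }
    vx <- vx + ax * dt + noise * stats::rnorm(1)
    vy <- vy + ay * dt + noise * stats::rnorm(1)
    xn <- xc + vx * dt; yn <- yc + vy * dt
    r2 <- xn^2 + yn^2
    if (r2 > R^2) {
      # reflect the radial velocity component at the wall
      r <- sqrt(r2); ux <- xn / r; uy <- yn / r
      vr <- vx * ux + vy * uy
      vx <- vx - 2 * vr * ux; vy <- vy - 2 * vr * uy
      xn <- xc + vx * dt; yn <- yc + vy * dt
      r2 <- xn^2 + yn^2
      if (r2 > R^2) { s <- R / sqrt(r2) * 0.999; xn <- xn * s; yn <- yn * s }
    }
    xc <- xn; yc <- yn
    x[i] <- xc; y[i] <- yc
  }
  data.frame(t = interval[1] + (seq_len(n) - 1) * dt, x = x, y = y)
}

#' Place-field firing rate under one map
#'
#' Gaussian spatial tuning with multiplicative theta modulation:
#' `rate = peak * exp(-d^2 / (2 sigma^2)) * (1 + m * cos(phase - phi_pref))`
#' where `d` is the distance to the active map's field center.
#'
#' @param cell_fields list with per-map field parameters: `old` and `new`,
#'   each a list/row with `x`, `y`, `sigma`, `peak`, and shared `phi_pref`.
#' @param map_state `"old"` or `"new"`.
#' @param x,y position (cm); vectors allowed.
#' @param theta_phase theta phase (radians), recycled against `x`.
#' @param m theta modulation depth in `[0, 1]`.
#' @return firing rate(s), Hz.
#' @export
place_rate <- function(cell_fields, map_state = c("old", "new"), x, y,
                       theta_phase = 0, m = 0) {
  map_state <- match.arg(map_state)
  f <- cell_fields[[map_state]]
  if (f$sigma <= 0) stop("sigma_field must be positive")
  if (m < 0 || m > 1) stop("theta modulation depth m must be in [0, 1]")
  d2 <- (x - f$x)^2 + (y - f$y)^2
  phi <- if (is.null(cell_fields$phi_pref)) 0 else cell_fields$phi_pref
  f$peak * exp(-d2 / (2 * f$sigma^2)) * (1 + m * cos(theta_phase - phi))
}
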