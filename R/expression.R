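# Per-cycle scoring of old- vs new-map assembly expression: population
# vectors of instantaneous rates correlated with the probe-session
# population-vector stacks, compared by Fisher's r-to-z. Positive z means
# the new (postprobe) map is expressed.

#' Stack per-cell rate maps into a population-vector array
#'
#' @param maps list of `rate_map`s (same geometry), one per screened
#'   pyramidal cell, in a fixed recorded order.
#' @param cell_ids unit ids matching `maps`.
#' @return object of class `pv_stack`: 3D array `(x, y, cell)`, `visited`
#'   mask (bins visited in the probe), `cell_ids`, geometry.
#' @export
build_stack <- function(maps, cell_ids = seq_along(maps) - 1L) {
  if (length(maps) < 2L) stop("need at least 2 cells to build a stack")
  g <- maps[[1]]
  for (m in maps[-1])
    if (m$nx != g$nx || m$ny != g$ny || any(m$origin != g$origin) ||
        m$bin_size != g$bin_size)
      stop("rate maps have different geometry")
  if (length(maps) < 14L)
    warning("fewer than 14 cells in the population-vector stack")
  arr <- array(NA_real_, c(g$nx, g$ny, length(maps)))
  visited <- maps[[1]]$visited
  for (k in seq_along(maps)) {
    arr[, , k] <- maps[[k]]$rate
    visited <- visited & maps[[k]]$visited
  }
  structure(list(rates = arr, visited = visited, cell_ids = cell_ids,
                 origin = g$origin, bin_size = g$bin_size,
                 nx = g$nx, ny = g$ny), class = "pv_stack")
}

#' @export
print.pv_stack <- function(x, ...) {
  cat(sprintf("pv_stack: %d cells on %dx%d bins (%d jointly visited)\n",
              length(x$cell_ids), x$nx, x$ny, sum(x$visited)))
  invisible(x)
}

#' Instantaneous-rate population vector for one cycle
#'
#' Per cell, spike count inside the cycle divided by cycle duration (Hz),
#' in stack cell order.
#'
#' @param spikes spike table (`unit_id`, `t`).
#' @param cycle numeric `c(t_start, t_end)`.
#' @param cell_ids cell order.
#' @return named numeric vector (Hz).
#' @export
cycle_vector <- function(spikes, cycle, cell_ids) {
  dur <- cycle[2] - cycle[1]
  if (dur <= 0) stop("cycle duration must be positive")
  v <- vapply(cell_ids, function(u) {
    st <- spikes$t[spikes$unit_id == u]
    sum(st >= cycle[1] & st < cycle[2])
  }, numeric(1)) / dur
  names(v) <- cell_ids
  v
}

# spike-count matrix (cells x cycles) via findInterval on sorted trains
cycle_count_matrix <- function(spikes, cycles, cell_ids) {
  m <- matrix(0, length(cell_ids), nrow(cycles))
  for (k in seq_along(cell_ids)) {
    st <- sort(spikes$t[spikes$unit_id == cell_ids[k]])
    if (!length(st)) next
    m[k, ] <- findInterval(cycles$t_end - 1e-12, st) -
      findInterval(cycles$t_start - 1e-12, st)
  }
  rownames(m) <- cell_ids
  m
}

#' Fisher r-to-z assembly-expression score for one cycle
#'
#' Correlates the cycle's population vector with the location's pre- and
#' postprobe population vectors and compares the two correlations:
#' `z = (atanh(r_post) - atanh(r_pre)) / sqrt(2 / (n - 3))`.
#'
#' @param vec cycle population vector (stack cell order).
#' @param stack_pre,stack_post `pv_stack`s with identical cell order.
#' @param bin integer `c(i, j)` location bin (0-based).
#' @param exclude_cell optional unit id left out (own-cell exclusion for
#'   membership scoring).
#' @return list with `r_pre`, `r_post`, `z`, `n_cells`, `valid`.
#' @export
expression_score <- function(vec, stack_pre, stack_post, bin,
                             exclude_cell = NULL) {
  if (!identical(stack_pre$cell_ids, stack_post$cell_ids))
    stop("stacks have different cell order")
  keep <- rep(TRUE, length(vec))
  if (!is.null(exclude_cell))
    keep <- stack_pre$cell_ids != exclude_cell
  n <- sum(keep)
  if (n <= 3L) stop("Fisher z undefined for 3 or fewer cells")
  i <- bin[1] + 1L; j <- bin[2] + 1L
  invalid <- list(r_pre = NA_real_, r_post = NA_real_, z = NA_real_,
                  n_cells = n, valid = FALSE)
  if (i < 1L || i > stack_pre$nx || j < 1L || j > stack_pre$ny ||
      !stack_pre$visited[i, j] || !stack_post$visited[i, j])
    return(invalid)
  a <- vec[keep]
  p1 <- stack_pre$rates[i, j, keep]
  p2 <- stack_post$rates[i, j, keep]
  if (n < 5L || stats::sd(a) == 0 || stats::sd(p1) == 0 ||
      stats::sd(p2) == 0)
    return(invalid)
  r_pre <- stats::cor(a, p1)
  r_post <- stats::cor(a, p2)
  if (abs(r_pre) >= 1 || abs(r_post) >= 1) {
    out <- invalid; out$r_pre <- r_pre; out$r_post <- r_post
    return(out)
  }
  z <- (atanh(r_post) - atanh(r_pre)) / sqrt(2 / (n - 3))
  list(r_pre = r_pre, r_post = r_post, z = z, n_cells = n, valid = TRUE)
}

#' Score assembly expression over a series of oscillatory cycles
#'
#' One score per cycle: the animal's location at the cycle midpoint selects
#' the probe population vectors; cycles at locations not visited in both
#' probes, or with degenerate vectors, are flagged invalid. For gamma
#' cycles, the containing theta cycle index is recorded.
#'
#' @param spikes spike table (`unit_id`, `t`).
#' @param cycles cycle table (`t_start`, `t_end`), theta or gamma.
#' @param stack_pre,stack_post probe `pv_stack`s.
#' @param position position track.
#' @param exclude_cell optional unit id excluded from every vector.
#' @param oscillation `"theta"` or `"gamma"`.
#' @param theta_cycles when scoring gamma cycles, the theta-cycle table used
#'   to assign each gamma cycle its containing theta cycle.
#' @return data.frame of class `cycle_expression`: per cycle `t_start`,
#'   `t_end`, `t_mid`, `bin_x`, `bin_y`, `r_pre`, `r_post`, `n_cells`, `z`,
#'   `n_active`, `valid`, `oscillation` (and `theta_id` for gamma).
#' @export
expression_series <- function(spikes, cycles, stack_pre, stack_post,
                              position, exclude_cell = NULL,
                              oscillation = c("theta", "gamma"),
                              theta_cycles = NULL) {
  oscillation <- match.arg(oscillation)
  cell_ids <- stack_pre$cell_ids
  keep <- rep(TRUE, length(cell_ids))
  if (!is.null(exclude_cell)) keep <- cell_ids != exclude_cell
  n <- sum(keep)
  if (n <= 3L) stop("Fisher z undefined for 3 or fewer cells")
  cnt <- cycle_count_matrix(spikes, cycles, cell_ids)
  dur <- cycles$t_end - cycles$t_start
  tm <- (cycles$t_start + cycles$t_end) / 2
  trk <- interp_track(position, tm)
  bx <- bin_index(trk$x, stack_pre$origin[1], stack_pre$bin_size, stack_pre$nx)
  by <- bin_index(trk$y, stack_pre$origin[2], stack_pre$bin_size, stack_pre$ny)
  nc <- nrow(cycles)
  r_pre <- r_post <- z <- rep(NA_real_, nc)
  valid <- rep(FALSE, nc)
  n_active <- colSums(cnt[keep, , drop = FALSE] > 0)
  for (c_i in seq_len(nc)) {
    if (is.na(bx[c_i]) || is.na(by[c_i])) next
    i <- bx[c_i] + 1L; j <- by[c_i] + 1L
    if (!stack_pre$visited[i, j] || !stack_post$visited[i, j]) next
    a <- cnt[keep, c_i] / dur[c_i]
    p1 <- stack_pre$rates[i, j, keep]
    p2 <- stack_post$rates[i, j, keep]
    if (n < 5L || stats::sd(a) == 0 || stats::sd(p1) == 0 ||
        stats::sd(p2) == 0) next
    rp <- stats::cor(a, p1); rq <- stats::cor(a, p2)
    r_pre[c_i] <- rp; r_post[c_i] <- rq
    if (abs(rp) >= 1 || abs(rq) >= 1) next
    z[c_i] <- (atanh(rq) - atanh(rp)) / sqrt(2 / (n - 3))
    valid[c_i] <- TRUE
  }
  out <- data.frame(t_start = cycles$t_start, t_end = cycles$t_end,
                    t_mid = tm, bin_x = bx, bin_y = by,
                    r_pre = r_pre, r_post = r_post, n_cells = n,
                    n_active = n_active, z = z, valid = valid,
                    oscillation = oscillation)
  if (oscillation == "gamma" && !is.null(theta_cycles)) {
    ti <- findInterval(tm, theta_cycles$t_start)
    inside <- ti >= 1L & tm <= theta_cycles$t_end[pmax(ti, 1L)]
    out$theta_id <- ifelse(inside, ti, NA_integer_)
  }
  class(out) <- c("cycle_expression", class(out))
  out
}
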