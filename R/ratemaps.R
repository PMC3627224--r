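# Occupancy-normalized place-field rate maps and spatial-tuning statistics.
# Bins are half-open: bin i covers [origin + i*bin_size, origin + (i+1)*bin_size),
# 0-based indices. Rate is defined only on visited bins.

#' Shared map geometry for a session
#'
#' @param position position track, or `NULL` when `radius` is given.
#' @param bin_size bin side (cm).
#' @param radius arena radius (cm); grid covers `[-radius, radius]`.
#' @return list with `origin`, `bin_size`, `nx`, `ny`.
#' @export
map_geometry <- function(position = NULL, bin_size = 4, radius = NULL) {
  if (!is.null(radius)) {
    origin <- c(-radius, -radius)
    n <- ceiling(2 * radius / bin_size)
    return(list(origin = origin, bin_size = bin_size, nx = n, ny = n))
  }
  stopifnot(!is.null(position))
  origin <- c(floor(min(position$x) / bin_size) * bin_size,
              floor(min(position$y) / bin_size) * bin_size)
  list(origin = origin, bin_size = bin_size,
       nx = ceiling((max(position$x) - origin[1]) / bin_size + 1e-9),
       ny = ceiling((max(position$y) - origin[2]) / bin_size + 1e-9))
}

bin_index <- function(v, origin, bin_size, n) {
  i <- floor((v - origin) / bin_size)
  i[i < 0 | i >= n] <- NA
  i
}

# separable 2D Gaussian smoothing on the grid, treating NA-outside as zero
smooth_grid <- function(m, sd_bins) {
  if (sd_bins <= 0) return(m)
  half <- max(1L, ceiling(3 * sd_bins))
  k <- stats::dnorm(-half:half, sd = sd_bins)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    out <- stats::filter(c(rep(0, half), v, rep(0, half)), k, sides = 2)
    out[(half + 1):(half + n)]
  }
  m2 <- apply(m, 2, pad_conv)
  t(apply(m2, 1, pad_conv))
}

#' Compute an occupancy-normalized rate map
#'
#' Spikes and occupancy are restricted to exploration intervals and samples
#' with running speed above `speed_thresh` (5 cm/s). Rate is the ratio of
#' Gaussian-smoothed spike counts to Gaussian-smoothed occupancy; bins never
#' visited are masked. The unsmoothed rate is retained for coherence.
#'
#' @param spike_times spike times of one unit (s).
#' @param position position track (`t`, `x`, `y`).
#' @param intervals exploration intervals.
#' @param geometry from [map_geometry()]; computed from `position` if `NULL`.
#' @param bin_size bin side (cm), used when `geometry` is `NULL`.
#' @param smoothing_sd Gaussian smoothing SD (cm); 0 disables.
#' @param speed_thresh minimum speed (cm/s).
#' @return object of class `rate_map`: `rate`, `rate_unsmoothed`,
#'   `occupancy` (s), `visited`, plus geometry fields.
#' @export
compute_rate_map <- function(spike_times, position, intervals,
                             geometry = NULL, bin_size = 4,
                             smoothing_sd = 4, speed_thresh = 5) {
  if (is.null(geometry)) geometry <- map_geometry(position, bin_size)
  sp <- speed_series(position)
  keep <- in_intervals(position$t, intervals) & sp$speed > speed_thresh
  pos <- position[keep, , drop = FALSE]
  if (nrow(pos) == 0L) stop("no position samples pass the speed/interval filter")
  dt <- stats::median(diff(position$t))
  ix <- bin_index(pos$x, geometry$origin[1], geometry$bin_size, geometry$nx)
  iy <- bin_index(pos$y, geometry$origin[2], geometry$bin_size, geometry$ny)
  ok <- !is.na(ix) & !is.na(iy)
  occ <- matrix(0, geometry$nx, geometry$ny)
  tb <- table(factor(ix[ok], levels = 0:(geometry$nx - 1)),
              factor(iy[ok], levels = 0:(geometry$ny - 1)))
  occ[] <- as.numeric(tb) * dt
  if (sum(occ) == 0) stop("zero total occupancy")
  # spikes kept when the nearest position sample passes the filter
  st <- spike_times[in_intervals(spike_times, intervals)]
  cnt <- matrix(0, geometry$nx, geometry$ny)
  if (length(st)) {
    near <- findInterval(st, position$t - dt / 2)
    near[near < 1L] <- 1L
    near[near > nrow(position)] <- nrow(position)
    stk <- keep[near]
    if (any(stk)) {
      trkk <- interp_track(position, st[stk])
      sx <- bin_index(trkk$x, geometry$origin[1], geometry$bin_size, geometry$nx)
      sy <- bin_index(trkk$y, geometry$origin[2], geometry$bin_size, geometry$ny)
      oks <- !is.na(sx) & !is.na(sy)
      tbs <- table(factor(sx[oks], levels = 0:(geometry$nx - 1)),
                   factor(sy[oks], levels = 0:(geometry$ny - 1)))
      cnt[] <- as.numeric(tbs)
    }
  }
  visited <- occ > 0
  raw <- matrix(NA_real_, geometry$nx, geometry$ny)
  raw[visited] <- cnt[visited] / occ[visited]
  sdb <- smoothing_sd / geometry$bin_size
  cs <- smooth_grid(cnt, sdb)
  os <- smooth_grid(occ, sdb)
  rate <- matrix(NA_real_, geometry$nx, geometry$ny)
  rate[visited] <- cs[visited] / os[visited]
  structure(list(rate = rate, rate_unsmoothed = raw, occupancy = occ,
                 visited = visited, spike_count = sum(cnt),
                 bin_size = geometry$bin_size, origin = geometry$origin,
                 nx = geometry$nx, ny = geometry$ny),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf(
    "rate_map: %dx%d bins of %g cm, %d visited, %.0f s occupancy, peak %.2f Hz\n",
    x$nx, x$ny, x$bin_size, sum(x$visited), sum(x$occupancy),
    suppressWarnings(max(x$rate, na.rm = TRUE))))
  invisible(x)
}

# mean of visited 8-neighbors per bin; returns matrix of means and counts
neighbor_mean <- function(rate, visited) {
  nx <- nrow(rate); ny <- ncol(rate)
  s <- matrix(0, nx, ny); cnt <- matrix(0L, nx, ny)
  v <- ifelse(visited, rate, 0)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    xd <- max(1, 1 - dx):min(nx, nx - dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    yd <- max(1, 1 - dy):min(ny, ny - dy)
    s[xd, yd] <- s[xd, yd] + v[xs, ys]
    cnt[xd, yd] <- cnt[xd, yd] + visited[xs, ys]
  }
  list(mean = ifelse(cnt > 0, s / cnt, NA), count = cnt)
}

#' Spatial coherence of a rate map
#'
#' Fisher z-transform of the Pearson correlation between each bin's firing
#' rate and the mean rate of its visited 8-neighbors, over visited bins with
#' at least `min_neighbors` visited neighbors. Computed on the unsmoothed
#' map by default (smoothing would inflate it).
#'
#' @param map a `rate_map`.
#' @param use_unsmoothed correlate unsmoothed rates (default `TRUE`).
#' @param min_neighbors minimum visited neighbors per qualifying bin.
#' @return coherence in z-units; an NA flagged `undefined` for constant maps.
#' @export
map_coherence <- function(map, use_unsmoothed = TRUE, min_neighbors = 4L) {
  r <- if (use_unsmoothed) map$rate_unsmoothed else map$rate
  nb <- neighbor_mean(r, map$visited)
  sel <- map$visited & nb$count >= min_neighbors
  if (sum(sel) < 10L)
    stop("fewer than 10 qualifying bins for coherence")
  a <- r[sel]; b <- nb$mean[sel]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(undefined_value())
  atanh(stats::cor(a, b))
}

#' Sparsity of a rate map
#'
#' `(sum(Pi*Ri))^2 / sum(Pi*Ri^2)` with `Pi` the occupancy probability of
#' bin i and `Ri` its firing rate, over visited bins. Lies in (0, 1]; small
#' values mean spatially concentrated firing.
#'
#' @param map a `rate_map`.
#' @return sparsity; an NA flagged `undefined` when the cell never fired.
#' @export
map_sparsity <- function(map) {
  sel <- map$visited
  if (sum(map$occupancy) <= 0) stop("zero total occupancy")
  P <- map$occupancy[sel] / sum(map$occupancy[sel])
  R <- map$rate[sel]
  if (all(R == 0)) return(undefined_value())
  sum(P * R)^2 / sum(P * R^2)
}

#' Similarity of two rate maps
#'
#' Pearson correlation of firing rates over bins visited in both maps.
#' Used with the remapping screen (similarity < 0.2 between probe sessions).
#'
#' @param map_a,map_b `rate_map`s on the same geometry.
#' @param min_bins minimum jointly visited bins (10).
#' @return correlation; an NA flagged `undefined` below `min_bins` or for
#'   constant maps.
#' @export
field_similarity <- function(map_a, map_b, min_bins = 10L) {
  if (map_a$nx != map_b$nx || map_a$ny != map_b$ny ||
      map_a$bin_size != map_b$bin_size ||
      any(map_a$origin != map_b$origin))
    stop("rate maps have different geometry")
  sel <- map_a$visited & map_b$visited
  if (sum(sel) < min_bins) return(undefined_value())
  a <- map_a$rate[sel]; b <- map_b$rate[sel]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(undefined_value())
  stats::cor(a, b)
}

map_peak <- function(map) {
  if (all(is.na(map$rate))) return(c(NA, NA))
  idx <- which(map$rate == max(map$rate, na.rm = TRUE), arr.ind = TRUE)[1, ]
  c(map$origin[1] + (idx[1] - 0.5) * map$bin_size,
    map$origin[2] + (idx[2] - 0.5) * map$bin_size)
}

#' Is the map's peak near a goal?
#'
#' @param map a `rate_map`.
#' @param goals goal coordinates (data.frame x, y).
#' @param radius goal-area radius (cm).
#' @return logical.
#' @export
is_goal_centric <- function(map, goals, radius = 20) {
  pk <- map_peak(map)
  if (any(is.na(pk))) stop("map has no defined peak")
  if (is.null(goals) || nrow(goals) == 0L) return(FALSE)
  any((goals$x - pk[1])^2 + (goals$y - pk[2])^2 <= radius^2)
}

#' Spatial-tuning statistics and screens for one map
#'
#' Applies the place-cell screen (coherence >= 0.6 z-units and sparsity <=
#' 0.3) and the goal-centric test.
#'
#' @param map a `rate_map`.
#' @param goals,goal_radius goal coordinates and radius for the goal test.
#' @param coherence_min,sparsity_max screen thresholds.
#' @return one-row data.frame: coherence, sparsity, peak_rate, peak_x,
#'   peak_y, is_place_cell, is_goal_centric.
#' @export
place_field_stats <- function(map, goals = NULL, goal_radius = 20,
                              coherence_min = 0.6, sparsity_max = 0.3) {
  coh <- tryCatch(map_coherence(map), error = function(e) undefined_value())
  spa <- map_sparsity(map)
  pk <- map_peak(map)
  data.frame(
    coherence = as.numeric(coh), sparsity = as.numeric(spa),
    peak_rate = suppressWarnings(max(map$rate, na.rm = TRUE)),
    peak_x = pk[1], peak_y = pk[2],
    is_place_cell = isTRUE(!is.na(coh) && !is.na(spa) &&
                             coh >= coherence_min && spa <= sparsity_max),
    is_goal_centric = if (!is.null(goals) && !any(is.na(pk)))
      is_goal_centric(map, goals, goal_radius) else NA)
}
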