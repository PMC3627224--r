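# End-to-end orchestration: simulate -> segment -> maps -> express ->
# associate -> couple -> predict, with per-stage TSV outputs stamped with
# the config hash and seed, and a ground-truth scorecard.

# stable content hash (djb2 over the deparsed config) for provenance stamps
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Aggregates every stage parameter with its standard default: speed
#' threshold 5 cm/s, theta/delta ratio 2, minimum rest 2.4 s, theta
#' detection band 5-28 Hz, gamma 30-80 Hz, ripple 150-250 Hz at 7 SD,
#' place-cell screen coherence 0.6 / sparsity 0.3, remapping similarity 0.2,
#' monosynaptic window 0.5-2.5 ms with 30-50 ms chance bins at 3 SD, pairing
#' window 20 ms, density kernel sigma 20 ms, classification over the last 10
#' learning trials at alpha 0.05 (logistic confirmation 1.960).
#'
#' @param sim a [sim_config()] (used when `simulate = TRUE`).
#' @param simulate generate the session (`TRUE`) or read it from
#'   `input_dir`.
#' @param input_dir bundle directory when `simulate = FALSE`.
#' @param bin_size,smoothing_sd rate-map bin (cm) and smoothing SD (cm).
#' @param goal_radius goal-area radius (cm).
#' @param speed_thresh,ratio_thresh,min_rest state-segmentation thresholds.
#' @param coherence_min,sparsity_max,similarity_max screening thresholds.
#' @param classify_trials number of final learning trials used for
#'   association (10).
#' @param alpha Pearson screen significance level.
#' @param pairing_window pairing window (s).
#' @param density_sigma spike-density kernel SD (s).
#' @param seed integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), simulate = TRUE,
                            input_dir = NULL, bin_size = 4,
                            smoothing_sd = 4, goal_radius = 20,
                            speed_thresh = 5, ratio_thresh = 2,
                            min_rest = 2.4, coherence_min = 0.6,
                            sparsity_max = 0.3, similarity_max = 0.2,
                            classify_trials = 10L, alpha = 0.05,
                            pairing_window = 0.02, density_sigma = 0.02,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' Serializes the full configuration (including the simulation config) to
#' JSON; reading it back yields an equivalent run.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- x$sim
  sim_args$goals <- as.data.frame(sim_args$goals)
  if (!is.null(sim_args$connection_table))
    sim_args$connection_table <- as.data.frame(sim_args$connection_table)
  sim <- do.call(sim_config, sim_args)
  x$sim <- NULL
  x$input_dir <- if (is.null(x$input_dir)) NULL else x$input_dir
  do.call(pipeline_config, c(list(sim = sim), x))
}

#' Run the full analysis pipeline
#'
#' Executes all stages in dependency order on a simulated (or loaded)
#' session and writes per-stage TSV outputs to `out_dir`, each stamped with
#' the configuration hash and seed. Undefined-statistic flags are propagated
#' into the output tables, never dropped.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (`NULL` for no file output).
#' @return list of class `pipeline_result` with elements `sim`, `states`,
#'   `theta_cycles`, `maps`, `stats`, `stacks`, `expression`,
#'   `associations`, `rate_changes`, `pairs`, `pair_epochs`, `predictors`,
#'   `report`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  cfg <- config
  prov <- list(hash = config_hash(cfg), seed = cfg$seed,
               time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  stamp <- function(df) { attr(df, "provenance") <- prov; df }

  # ---- stage 1: session -----------------------------------------------
  if (cfg$simulate) {
    sim <- simulate_session(cfg$sim)
  } else {
    if (is.null(cfg$input_dir)) stop("simulate stage: no input_dir given")
    raw <- read_session_bundle(cfg$input_dir)
    sim <- structure(list(bundle = raw, truth = raw$truth),
                     class = "session_sim")
  }
  b <- sim$bundle
  ep <- session_epochs(b$intervals)

  # ---- stage 2: state segmentation ------------------------------------
  if (is.null(b$lfp)) stop("segment stage: bundle has no LFP")
  ratio <- theta_delta_ratio(b$lfp$trace, b$lfp$fs)
  spd <- speed_series(b$position)
  states <- segment_states(ratio, spd, cfg$speed_thresh, cfg$ratio_thresh,
                           cfg$min_rest)
  expl <- intervals_for(states, "exploration")
  theta_cycles <- detect_theta_cycles(b$lfp$trace, b$lfp$fs, expl)

  # ---- stage 3: rate maps + screens -----------------------------------
  geom <- map_geometry(radius = max(abs(c(b$position$x, b$position$y))) + 1,
                       bin_size = cfg$bin_size)
  pyr_ids <- sort(unique(b$spikes$unit_id[b$spikes$unit_type == "pyr"]))
  int_ids <- sort(unique(b$spikes$unit_id[b$spikes$unit_type == "int"]))
  probe <- list(pre = intervals_for(b$intervals, "preprobe"),
                post = intervals_for(b$intervals, "postprobe"))
  maps <- list(pre = list(), post = list())
  stats_rows <- list()
  for (u in pyr_ids) {
    st <- b$spikes$t[b$spikes$unit_id == u]
    for (side in c("pre", "post")) {
      m <- compute_rate_map(st, b$position, probe[[side]], geometry = geom,
                            smoothing_sd = cfg$smoothing_sd,
                            speed_thresh = cfg$speed_thresh)
      maps[[side]][[as.character(u)]] <- m
      pf <- place_field_stats(m, b$goals, cfg$goal_radius,
                              cfg$coherence_min, cfg$sparsity_max)
      pf$unit_id <- u; pf$session <- paste0(side, "probe")
      stats_rows[[length(stats_rows) + 1L]] <- pf
    }
  }
  stats <- do.call(rbind, stats_rows)
  sim_tab <- data.frame(unit_id = pyr_ids, similarity = vapply(
    pyr_ids, function(u) as.numeric(field_similarity(
      maps$pre[[as.character(u)]], maps$post[[as.character(u)]])),
    numeric(1)))
  # screen: place cell in at least one probe session
  screened <- pyr_ids[vapply(pyr_ids, function(u)
    any(stats$is_place_cell[stats$unit_id == u]), logical(1))]
  if (length(screened) < 5L) screened <- pyr_ids

  # ---- stage 4: assembly expression -----------------------------------
  stack_pre <- build_stack(maps$pre[as.character(screened)], screened)
  stack_post <- build_stack(maps$post[as.character(screened)], screened)
  learn_cycles <- theta_cycles[
    in_intervals((theta_cycles$t_start + theta_cycles$t_end) / 2,
                 ep$learning), , drop = FALSE]
  expr <- expression_series(b$spikes, learn_cycles, stack_pre, stack_post,
                            b$position)

  # ---- stage 5: firing associations -----------------------------------
  ntr <- nrow(ep$learning)
  last_trials <- ep$learning[max(1L, ntr - cfg$classify_trials + 1L):ntr, ]
  win <- in_intervals(expr$t_mid, last_trials)
  assoc_rows <- list(); rc_rows <- list()
  for (u in int_ids) {
    st <- b$spikes$t[b$spikes$unit_id == u]
    ifr <- instantaneous_rates(st, learn_cycles)
    a <- tryCatch(associate(ifr, expr, window = win, alpha = cfg$alpha),
                  error = function(e)
                    data.frame(r = NA, p_value = NA, class = "uInt",
                               wald_z = NA, n_cycles = 0L,
                               flag = "too_few_cycles"))
    a$unit_id <- u
    assoc_rows[[length(assoc_rows) + 1L]] <- a
    rc <- tryCatch(rate_change(st, ep$learning_span),
                   error = function(e)
                     data.frame(rate_first = NA, rate_last = NA, index = NA,
                                flag = "short_learning"))
    rc$unit_id <- u
    rc_rows[[length(rc_rows) + 1L]] <- rc
  }
  associations <- do.call(rbind, assoc_rows)
  rate_changes <- do.call(rbind, rc_rows)

  # ---- stage 6: monosynaptic coupling ---------------------------------
  pair_rows <- list(); epoch_rows <- list(); tracked <- list()
  for (p_id in pyr_ids) {
    pre <- b$spikes$t[b$spikes$unit_id == p_id]
    if (length(pre) < 100L) next
    for (i_id in int_ids) {
      post <- b$spikes$t[b$spikes$unit_id == i_id]
      cc <- build_ccg(pre, post)
      det <- detect_mono(cc)
      tr <- transmission(cc)
      lat <- ccg_latency(cc, det)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        pre_id = p_id, post_id = i_id, significant = det$significant,
        peak_prob = det$peak_prob, baseline = det$baseline$mean,
        transmission = tr$transmission,
        latency = as.numeric(lat$latency))
      if (det$significant) {
        mp <- track_epochs(pre, post, b$intervals)
        key <- paste(p_id, i_id, sep = "-")
        tracked[[key]] <- mp
        pe <- mp$per_epoch
        pe$pre_id <- p_id; pe$post_id <- i_id
        epoch_rows[[length(epoch_rows) + 1L]] <- pe
      }
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else NULL
  pair_epochs <- if (length(epoch_rows)) do.call(rbind, epoch_rows) else NULL

  # ---- stage 7: predictors --------------------------------------------
  predictors <- NULL; report <- NULL
  sig <- pairs[pairs$significant, , drop = FALSE]
  if (!is.null(sig) && nrow(sig)) {
    theta_learning <- learn_cycles
    pr_rows <- list()
    for (k in seq_len(nrow(sig))) {
      pre <- b$spikes$t[b$spikes$unit_id == sig$pre_id[k]]
      post <- b$spikes$t[b$spikes$unit_id == sig$post_id[k]]
      ps <- pairing_events(pre, post,
                           intervals_df("theta", theta_learning$t_start,
                                        theta_learning$t_end),
                           cfg$pairing_window, b$position, b$goals,
                           cfg$goal_radius)
      gs <- goal_split(ps)
      prespk <- restrict_times(pre, ep$learning)
      ds <- if (length(prespk) >= 10L)
        density_at_pre_spikes(post, prespk, ep$learning, spd,
                              cfg$density_sigma)
      else list(mean_density = NA, normalized_density = NA, mean_speed = NA)
      mp <- tracked[[paste(sig$pre_id[k], sig$post_id[k], sep = "-")]]
      dtr <- mp$deltas$transmission[
        mp$deltas$delta == "postprobe_minus_preprobe"]
      gc <- stats$is_goal_centric[stats$unit_id == sig$pre_id[k] &
                                    stats$session == "postprobe"]
      pr_rows[[length(pr_rows) + 1L]] <- data.frame(
        pre_id = sig$pre_id[k], post_id = sig$post_id[k],
        d_transmission = dtr, n_pre_window = ps$n_pre_window,
        n_post_window = ps$n_post_window, n_inside = gs["n_inside"],
        n_outside = gs["n_outside"],
        mean_density = as.numeric(ds$mean_density),
        normalized_density = as.numeric(ds$normalized_density),
        mean_speed = as.numeric(ds$mean_speed),
        goal_centric = isTRUE(gc))
    }
    predictors <- do.call(rbind, pr_rows)
    rownames(predictors) <- NULL
    report <- tryCatch(predictor_analysis(predictors),
                       error = function(e) NULL)
  }

  res <- structure(list(
    sim = sim, states = stamp(states), theta_cycles = stamp(theta_cycles),
    maps = maps, stats = stamp(stats), similarity = stamp(sim_tab),
    screened = screened, stacks = list(pre = stack_pre, post = stack_post),
    expression = stamp(expr), associations = stamp(associations),
    rate_changes = stamp(rate_changes), pairs = stamp(pairs),
    pair_epochs = stamp(pair_epochs), predictors = stamp(predictors),
    report = report, provenance = prov), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) if (!is.null(df))
      utils::write.table(df, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wt(res$states, "states.tsv")
    wt(res$theta_cycles, "theta_cycles.tsv")
    wt(res$stats, "map_stats.tsv")
    wt(res$similarity, "similarity.tsv")
    wt(res$expression, "expression.tsv")
    wt(res$associations, "associations.tsv")
    wt(res$rate_changes, "rate_change.tsv")
    wt(res$pairs, "pairs.tsv")
    wt(res$pair_epochs, "pair_epochs.tsv")
    wt(res$predictors, "predictors.tsv")
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result (config", x$provenance$hash, ")\n")
  cat(sprintf("  states: %d intervals; theta cycles: %d\n",
              nrow(x$states), nrow(x$theta_cycles)))
  cat(sprintf("  screened place cells: %d; valid expression cycles: %d\n",
              length(x$screened), sum(x$expression$valid)))
  cat(sprintf("  interneuron classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$associations$class)),
                            table(x$associations$class)), collapse = " ")))
  if (!is.null(x$pairs))
    cat(sprintf("  monosynaptic pairs: %d significant of %d tested\n",
                sum(x$pairs$significant), nrow(x$pairs)))
  invisible(x)
}

#' Score pipeline results against simulator ground truth
#'
#' @param results a `pipeline_result` from a simulated session.
#' @param truth the simulator truth (defaults to `results$sim$truth`).
#' @param min_active minimum active cells per cycle for the decoding score.
#' @return list of class `truth_scorecard`: cycle-state decoding accuracy,
#'   per-connection transmission bias and RMSE, latency RMSE, interneuron
#'   class confusion matrix and sensitivities.
#' @export
validate_against_truth <- function(results, truth = NULL,
                                   min_active = 10L) {
  if (is.null(truth)) truth <- results$sim$truth
  if (is.null(truth)) stop("no ground truth available")
  expr <- results$expression
  tc <- truth$cycles
  mid <- expr$t_mid
  ti <- findInterval(mid, tc$t_start)
  ok <- ti >= 1L & mid <= tc$t_end[pmax(ti, 1L)]
  state <- rep(NA_character_, length(mid))
  state[ok] <- tc$state[ti[ok]]
  sel <- expr$valid & !is.na(state) & expr$n_active >= min_active
  acc <- if (any(sel))
    mean((expr$z[sel] > 0) == (state[sel] == "new")) else NA_real_

  conn <- truth$connections
  bias <- rmse <- lat_rmse <- NA_real_
  if (!is.null(conn) && nrow(conn) && !is.null(results$pair_epochs)) {
    pe <- results$pair_epochs
    conn$post_global <- truth$int_ids[conn$post + 1L]   # interneuron index -> unit id
    est <- merge(conn, pe[pe$epoch == "postprobe", ],
                 by.x = c("pre", "post_global"), by.y = c("pre_id", "post_id"))
    if (nrow(est)) {
      err <- est$transmission - est$w_end
      bias <- mean(err); rmse <- sqrt(mean(err^2))
      lerr <- est$latency - est$delay_ms
      lat_rmse <- sqrt(mean(lerr^2, na.rm = TRUE))
    }
  }

  confusion <- sens <- NULL
  if (!is.null(truth$int_class) && !is.null(results$associations)) {
    a <- results$associations
    idx <- match(a$unit_id, truth$int_ids)
    okc <- !is.na(idx)
    confusion <- table(truth = truth$int_class[idx[okc]],
                       called = a$class[okc])
    sens <- vapply(c("pInt", "nInt"), function(cl) {
      n <- sum(truth$int_class[idx[okc]] == cl)
      if (!n) return(NA_real_)
      sum(truth$int_class[idx[okc]] == cl & a$class[okc] == cl) / n
    }, numeric(1))
  }
  structure(list(decoding_accuracy = acc, transmission_bias = bias,
                 transmission_rmse = rmse, latency_rmse = lat_rmse,
                 confusion = confusion, sensitivity = sens),
            class = "truth_scorecard")
}

#' @export
print.truth_scorecard <- function(x, ...) {
  cat("Ground-truth scorecard\n")
  cat(sprintf("  cycle-state decoding accuracy: %.3f\n",
              x$decoding_accuracy))
  cat(sprintf("  transmission bias %.4f, RMSE %.4f; latency RMSE %.3f ms\n",
              x$transmission_bias, x$transmission_rmse, x$latency_rmse))
  if (!is.null(x$sensitivity))
    cat(sprintf("  class sensitivity: pInt %.2f, nInt %.2f\n",
                x$sensitivity["pInt"], x$sensitivity["nInt"]))
  if (!is.null(x$confusion)) print(x$confusion)
  invisible(x)
}
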