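# Session-bundle I/O. Layout: spikes.tsv (unit_id, t, unit_type),
# position.tsv (t, x, y), lfp.bin (float32 little-endian) + lfp.json
# (rate, n_samples), intervals.tsv (label, t_start, t_end), goals.tsv,
# ground_truth.json. Times in seconds, positions in cm, 0-based unit ids.

#' Write a session bundle to a directory
#'
#' @param sim a `session_sim` (or a bare bundle list) from
#'   [simulate_session()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(sim, dir) {
  bundle <- if (inherits(sim, "session_sim")) sim$bundle else sim
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, f)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wtsv(bundle$spikes, "spikes.tsv")
  wtsv(bundle$position, "position.tsv")
  wtsv(bundle$intervals, "intervals.tsv")
  wtsv(bundle$goals, "goals.tsv")
  if (!is.null(bundle$lfp)) {
    con <- file(file.path(dir, "lfp.bin"), "wb")
    writeBin(as.numeric(bundle$lfp$trace), con, size = 4, endian = "little")
    close(con)
    jsonlite::write_json(list(rate = bundle$lfp$fs,
                              n_samples = length(bundle$lfp$trace),
                              channels = 1L),
                         file.path(dir, "lfp.json"), auto_unbox = TRUE)
  }
  if (inherits(sim, "session_sim")) {
    tr <- sim$truth
    jsonlite::write_json(
      list(cycles = tr$cycles, fields = tr$fields,
           connections = tr$connections, learning_span = tr$learning_span,
           int_class = tr$int_class, int_ids = tr$int_ids,
           seed = tr$config$seed),
      file.path(dir, "ground_truth.json"), digits = NA)
  }
  invisible(dir)
}

#' Read a session bundle from a directory
#'
#' @param dir directory written by [write_session_bundle()].
#' @return list with `spikes`, `position`, `lfp`, `intervals`, `goals`, and
#'   `truth` when `ground_truth.json` is present.
#' @export
read_session_bundle <- function(dir) {
  rtsv <- function(f)
    utils::read.table(file.path(dir, f), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  out <- list(spikes = rtsv("spikes.tsv"), position = rtsv("position.tsv"),
              intervals = rtsv("intervals.tsv"), goals = rtsv("goals.tsv"),
              lfp = NULL, truth = NULL)
  jf <- file.path(dir, "lfp.json")
  if (file.exists(jf)) {
    meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
    con <- file(file.path(dir, "lfp.bin"), "rb")
    x <- readBin(con, numeric(), n = meta$n_samples, size = 4,
                 endian = "little")
    close(con)
    out$lfp <- list(trace = x, fs = meta$rate)
  }
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt))
    out$truth <- jsonlite::read_json(gt, simplifyVector = TRUE)
  out
}
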