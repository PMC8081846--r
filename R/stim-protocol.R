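#' Generate a homogeneous Poisson spike train
#'
#' ISIs are drawn i.i.d. exponential with the requested mean; spike times
#' accumulate from the first draw onward (there is no spike at time zero)
#' until the requested duration is exceeded. No refractory period is
#' imposed; draws are floored at 1 microsecond so that times remain
#' strictly increasing after 6-decimal rounding on export. The same seed
#' always yields the same train. A train with zero spikes (duration much
#' shorter than the mean ISI) is legal.
#'
#' @param mean_isi_s mean inter-spike interval in seconds (> 0); the
#'   reciprocal of the target mean firing rate.
#' @param duration_s length of the single continuous trial in seconds (> 0).
#' @param seed integer seed.
#' @param cell_id label; default records the generator parameters.
#' @return a [spike_train()] with `condition = "POISSON"`.
#' @export
#' @examples
#' st <- generate_poisson_train(1 / 5.52, duration_s = 200, seed = 1)
#' n_spikes(st) / total_duration(st)   # close to 5.52 Hz
generate_poisson_train <- function(mean_isi_s, duration_s, seed,
                                   cell_id = NULL) {
  if (!is.numeric(mean_isi_s) || mean_isi_s <= 0)
    stop("`mean_isi_s` must be > 0")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("`duration_s` must be > 0")
  if (is.null(cell_id))
    cell_id <- sprintf("poisson_isi%.6g_seed%d", mean_isi_s, as.integer(seed))
  times <- with_seed(as.integer(seed), {
    # draw in blocks until past duration
    acc <- numeric(0)
    t_end <- 0
    block <- max(64L, ceiling(1.2 * duration_s / mean_isi_s))
    while (t_end <= duration_s) {
      draws <- pmax(stats::rexp(block, rate = 1 / mean_isi_s), 1e-6)
      acc <- c(acc, draws)
      t_end <- sum(acc)
    }
    cumsum(acc)
  })
  times <- times[times < duration_s]
  spike_train(times, trial_durations = duration_s,
              cell_id = cell_id, condition = "POISSON")
}

#' Build a stimulation protocol from a spike train
#'
#' Trials are concatenated end-to-end into absolute pulse times from
#' protocol start. With `repeat_train = TRUE` the whole train is replayed
#' end-to-end until the protocol duration is filled — the standard way to
#' extend a 200-s recording into a 2-h stimulation — and the repetition is
#' recorded in the source descriptor. Pulses at or beyond `duration_s` are
#' truncated. Times are rounded to 1 microsecond; any collision created by
#' rounding is nudged forward by 1 microsecond to preserve strict
#' monotonicity.
#'
#' @param train a [spike_train()] with at least one spike.
#' @param duration_s protocol duration in seconds; default 7200 (2 h).
#' @param repeat_train replay the train end-to-end to fill the duration.
#' @param source source descriptor text; defaults to the cell id (plus a
#'   repetition note when repeating).
#' @return a `stim_protocol`: `pulse_times_s`, `duration_s`, `source`.
#' @export
as_protocol <- function(train, duration_s = 7200, repeat_train = FALSE,
                        source = NULL) {
  validate_spike_train(train)
  if (!n_spikes(train)) stop("cannot build a protocol from an empty train")
  if (duration_s <= 0) stop("`duration_s` must be > 0")
  abs_times <- train$trials$start_s[train$spikes$trial + 1L] + train$spikes$time_s
  train_span <- total_duration(train)
  if (repeat_train) {
    n_rep <- ceiling(duration_s / train_span)
    abs_times <- rep(abs_times, n_rep) +
      rep((seq_len(n_rep) - 1) * train_span, each = length(abs_times))
    if (is.null(source))
      source <- sprintf("%s (repeated x%d to %.0f s)", train$cell_id,
                        n_rep, duration_s)
  }
  if (is.null(source)) source <- train$cell_id
  pt <- round(abs_times[abs_times < duration_s], 6)
  while (any(diff(pt) <= 0)) {         # rounding collisions: nudge by 1 us
    i <- which(diff(pt) <= 0)
    pt[i + 1L] <- pt[i] + 1e-6
    pt <- round(pt, 6)
  }
  pt <- pt[pt < duration_s]
  if (!length(pt)) stop("no pulses fall inside the protocol duration")
  structure(list(pulse_times_s = pt, duration_s = duration_s,
                 source = source),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %d pulses over %.0f s (%.3f Hz) from %s\n",
              length(x$pulse_times_s), x$duration_s,
              length(x$pulse_times_s) / x$duration_s, x$source))
  invisible(x)
}

#' Export a stimulation protocol file
#'
#' Writes the text protocol format: a version line, `duration_s` and
#' `source` metadata, then one ascending pulse time per line with fixed
#' 6 decimal places. LF line endings are forced so output is bit-exact
#' across platforms; the same train and duration always produce a
#' byte-identical file.
#'
#' @param x a `stim_protocol` or a [spike_train()] (converted via
#'   [as_protocol()]).
#' @param path output file.
#' @param duration_s protocol duration when converting a train.
#' @param ... passed to [as_protocol()] when `x` is a train.
#' @return the `stim_protocol`, invisibly.
#' @export
export_protocol <- function(x, path, duration_s = 7200, ...) {
  proto <- if (inherits(x, "stim_protocol")) x
           else as_protocol(x, duration_s = duration_s, ...)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("# spikeburst-protocol v1",
               sprintf("# duration_s=%.6f", proto$duration_s),
               sprintf("# source=%s", proto$source),
               sprintf("%.6f", proto$pulse_times_s)),
             con, sep = "\n")
  invisible(proto)
}

#' Import a stimulation protocol file
#'
#' Round-trips [export_protocol()] output exactly (1 microsecond
#' resolution). The header must carry the format version line and a
#' `duration_s`; pulse times must be strictly increasing, inside
#' `[0, duration_s)`, and non-empty.
#'
#' @param path protocol file.
#' @return a `stim_protocol`.
#' @export
import_protocol <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# spikeburst-protocol v1", lines[1]))
    stop("not a spikeburst protocol file (missing version header)")
  meta <- parse_meta(grep("^#", lines, value = TRUE))
  if (is.null(meta$duration_s)) stop("protocol header lacks duration_s")
  duration_s <- as.numeric(meta$duration_s)
  body <- trimws(lines[!grepl("^#", lines)])
  body <- body[nzchar(body)]
  if (!length(body)) stop("protocol contains no pulses")
  pt <- suppressWarnings(as.numeric(body))
  if (anyNA(pt)) stop("malformed pulse time in protocol file")
  if (any(diff(pt) <= 0)) stop("pulse times must be strictly increasing")
  if (any(pt < 0) || any(pt >= duration_s))
    stop("pulse times must lie in [0, duration_s)")
  structure(list(pulse_times_s = pt, duration_s = duration_s,
                 source = meta$source %||% "unknown"),
            class = "stim_protocol")
}
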