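#' Two-stage mean-ISI burst threshold
#'
#' Computes the non-biased burst-detection threshold from the pooled ISIs of
#' a spike train. Stage 1 takes the arithmetic mean of all ISIs; every ISI
#' greater than or equal to that mean is removed. Stage 2 takes the mean of
#' the retained (sub-mean) ISIs, and this second mean is the burst
#' threshold. The procedure runs exactly once — there is no iteration to
#' convergence.
#'
#' Tie handling is deliberate and visible on degenerate data: stage-1
#' removal uses `>=`, so a train whose ISIs are all equal retains nothing
#' and the threshold is undefined (`NA`), which downstream yields zero
#' bursts rather than an error.
#'
#' For an exponential (Poisson-train) ISI distribution with mean `mu` the
#' threshold converges to `E[X | X < mu] = mu * (1 - 2/e) / (1 - 1/e)`,
#' about `0.418 * mu`.
#'
#' @param isis an `isi_sequence` from [compute_isis()], or a bare numeric
#'   vector of ISIs in seconds.
#' @return A `threshold_result` list: `stage1_mean_s`, `threshold_s`
#'   (`NA_real_` when undefined), `n_total`, `n_retained`.
#' @export
#' @examples
#' compute_burst_threshold(c(0.010, 0.010, 0.012, 0.300, 0.080,
#'                           0.090, 0.011, 0.012, 0.010, 0.400))
compute_burst_threshold <- function(isis) {
  x <- pooled_isis(isis)
  if (length(x) < 1)
    stop("insufficient data: at least one ISI is required")
  if (any(x <= 0)) stop("ISIs must be positive")
  stage1 <- mean(x)
  retained <- x[x < stage1]
  structure(
    list(stage1_mean_s = stage1,
         threshold_s = if (length(retained)) mean(retained) else NA_real_,
         n_total = length(x),
         n_retained = length(retained)),
    class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> stage-1 mean %.6f s; threshold %s (retained %d/%d ISIs)\n",
              x$stage1_mean_s,
              if (is.na(x$threshold_s)) "undefined"
              else sprintf("%.6f s", x$threshold_s),
              x$n_retained, x$n_total))
  invisible(x)
}

#' Segment a spike train's ISIs into bursts
#'
#' A burst is a maximal run of two or more consecutive ISIs each strictly
#' below the threshold ("fell below"); an isolated sub-threshold ISI is not
#' a burst, and ISIs exactly equal to the threshold are interburst. Runs
#' never cross trial boundaries. With an undefined threshold there are no
#' bursts and every ISI is interburst.
#'
#' @param isis an `isi_sequence` (or a numeric vector treated as one trial).
#' @param threshold a `threshold_result`, normally computed from the same
#'   ISIs by [compute_burst_threshold()].
#' @return A `burst_segmentation` list: `threshold`; `bursts`, a data frame
#'   with one row per burst (`trial`, `first_isi_index` — both 0-based —
#'   `n_isis`, `n_spikes`, `duration_s`); and `labels`, a per-trial list of
#'   `"intraburst"`/`"interburst"` flags aligned with the ISI sequence.
#' @export
segment_bursts <- function(isis, threshold) {
  if (!inherits(threshold, "threshold_result"))
    stop("`threshold` must come from compute_burst_threshold()")
  per_trial <- if (inherits(isis, "isi_sequence")) unclass(isis) else list(pooled_isis(isis))
  thr <- threshold$threshold_s

  bursts <- vector("list", length(per_trial))
  labels <- vector("list", length(per_trial))
  for (tr in seq_along(per_trial)) {
    x <- per_trial[[tr]]
    lab <- rep("interburst", length(x))
    if (length(x) && !is.na(thr)) {
      r <- rle(x < thr)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values & r$lengths >= 2L)
      if (length(keep)) {
        lab[sequence(r$lengths[keep], from = starts[keep])] <- "intraburst"
        cs <- c(0, cumsum(x))
        bursts[[tr]] <- data.frame(
          trial = tr - 1L,
          first_isi_index = starts[keep] - 1L,
          n_isis = r$lengths[keep],
          n_spikes = r$lengths[keep] + 1L,
          duration_s = cs[ends[keep] + 1L] - cs[starts[keep]])
      }
    }
    labels[[tr]] <- lab
  }
  bursts <- do.call(rbind, bursts)
  if (is.null(bursts))
    bursts <- data.frame(trial = integer(0), first_isi_index = integer(0),
                         n_isis = integer(0), n_spikes = integer(0),
                         duration_s = numeric(0))
  bursts <- bursts[order(bursts$trial, bursts$first_isi_index), , drop = FALSE]
  rownames(bursts) <- NULL
  structure(list(threshold = threshold, bursts = bursts, labels = labels),
            class = "burst_segmentation")
}

#' @export
print.burst_segmentation <- function(x, ...) {
  n_intra <- sum(x$bursts$n_isis)
  n_tot <- sum(lengths(x$labels))
  cat(sprintf("<burst_segmentation> %d burst(s); %d/%d ISIs intraburst\n",
              nrow(x$bursts), n_intra, n_tot))
  invisible(x)
}

#' Detect bursts in a spike train
#'
#' Convenience composition: compute ISIs, derive the two-stage mean-ISI
#' threshold from the ISIs pooled across all trials (one threshold per
#' train), then segment each trial. Deterministic: identical trains give
#' identical segmentations.
#'
#' @param train a [spike_train()] with at least one ISI.
#' @return a `burst_segmentation`; see [segment_bursts()].
#' @export
detect_bursts <- function(train) {
  isis <- compute_isis(train)
  segment_bursts(isis, compute_burst_threshold(isis))
}

#' Export a burst report as JSON
#'
#' Writes the threshold block and one record per burst with fields
#' `trial`, `first_isi_index`, `n_isis`, `duration_s`.
#'
#' @param seg a `burst_segmentation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_burst_report <- function(seg, path) {
  stopifnot(inherits(seg, "burst_segmentation"))
  thr <- seg$threshold
  report <- list(
    threshold = list(stage1_mean_s = thr$stage1_mean_s,
                     threshold_s = thr$threshold_s,
                     n_total = thr$n_total,
                     n_retained = thr$n_retained),
    bursts = seg$bursts[c("trial", "first_isi_index", "n_isis", "duration_s")])
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}
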