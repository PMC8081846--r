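#' Spike-train metric suite
#'
#' Computes the per-train burst and firing-rate statistics used to
#' characterise experience conditions:
#'
#' * `avg_firing_rate_hz` — spikes per second of total recorded time (sum
#'   of trial durations, so silent trials still count as recording time);
#' * `mean_n_intraburst_isis` — mean ISIs per burst, and
#'   `mean_burst_length_spikes` = that + 1 (a burst of k ISIs spans k + 1
#'   spikes);
#' * `mean_burst_duration_s` — mean over bursts of the sum of member ISIs;
#' * `mean_burst_freq_hz` — reciprocal of the mean pooled intraburst ISI
#'   (spike rate within bursts);
#' * `mean_nonburst_freq_hz` — reciprocal of the mean pooled interburst ISI
#'   (spike rate outside bursts);
#' * `burst_rate_hz` — bursts per second of recorded time;
#' * `fraction_isis_in_bursts` — number of ISIs inside bursts over total
#'   ISIs (the "fraction of spikes in bursts" of the field's tables is this
#'   ISI-count ratio);
#' * interior-gap statistics `mean_n_interburst_isis` and
#'   `mean_interburst_interval_s`, computed only over maximal interburst
#'   runs lying *between* two bursts of the same trial (leading and
#'   trailing non-burst spans are not gaps, though their ISIs still enter
#'   `mean_nonburst_freq_hz`).
#'
#' Burst-dependent fields are `NA` when no burst was detected; interior-gap
#' fields are `NA` when no trial contains two bursts.
#'
#' @param train a [spike_train()] with at least 2 spikes.
#' @param seg optional precomputed `burst_segmentation` for `train`;
#'   computed by [detect_bursts()] if missing.
#' @return a `train_metrics` object (named list, printable), including the
#'   counts `n_spikes`, `n_isis`, `n_bursts`.
#' @export
compute_metrics <- function(train, seg = NULL) {
  validate_spike_train(train)
  if (n_spikes(train) < 2)
    stop("insufficient data: at least 2 spikes are required")
  isis <- compute_isis(train)
  if (is.null(seg)) seg <- segment_bursts(isis, compute_burst_threshold(isis))

  dur <- total_duration(train)
  all_isis <- pooled_isis(isis)
  labels <- seg$labels
  intra <- unlist(Map(function(x, l) x[l == "intraburst"], unclass(isis), labels))
  inter <- unlist(Map(function(x, l) x[l == "interburst"], unclass(isis), labels))
  nb <- nrow(seg$bursts)

  gaps <- interior_gaps(isis, labels)

  metrics <- list(
    cell_id = train$cell_id,
    condition = train$condition,
    avg_firing_rate_hz = n_spikes(train) / dur,
    mean_n_intraburst_isis = if (nb) mean(seg$bursts$n_isis) else NA_real_,
    mean_burst_length_spikes = if (nb) mean(seg$bursts$n_isis) + 1 else NA_real_,
    mean_burst_duration_s = if (nb) mean(seg$bursts$duration_s) else NA_real_,
    mean_n_interburst_isis = if (length(gaps$n)) mean(gaps$n) else NA_real_,
    mean_interburst_interval_s = if (length(gaps$dur)) mean(gaps$dur) else NA_real_,
    mean_burst_freq_hz = if (length(intra)) 1 / mean(intra) else NA_real_,
    mean_nonburst_freq_hz = if (length(inter)) 1 / mean(inter) else NA_real_,
    burst_rate_hz = nb / dur,
    fraction_isis_in_bursts = if (length(all_isis)) sum(seg$bursts$n_isis) / length(all_isis) else NA_real_,
    n_spikes = n_spikes(train),
    n_isis = length(all_isis),
    n_bursts = nb)
  structure(metrics, class = "train_metrics")
}

# maximal interburst runs bounded by a burst on both sides, per trial
interior_gaps <- function(isis, labels) {
  per_trial <- lapply(seq_along(labels), function(tr) {
    lab <- labels[[tr]]
    x <- isis[[tr]]
    if (!length(lab) || !any(lab == "intraburst")) return(NULL)
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values == "interburst" &
                 seq_along(r$values) > 1L &
                 seq_along(r$values) < length(r$values))
    if (!length(k)) return(NULL)
    cs <- c(0, cumsum(x))
    list(n = r$lengths[k], dur = cs[ends[k] + 1L] - cs[starts[k]])
  })
  list(n = unlist(lapply(per_trial, `[[`, "n")),
       dur = unlist(lapply(per_trial, `[[`, "dur")))
}

#' @export
print.train_metrics <- function(x, ...) {
  cat(sprintf("<train_metrics> cell '%s' (%s)\n", x$cell_id, x$condition))
  num <- x[metric_fields()]
  for (f in names(num))
    cat(sprintf("  %-28s %s\n", f,
                if (is.na(num[[f]])) "undefined" else format(num[[f]], digits = 6)))
  cat(sprintf("  counts: %d spikes, %d ISIs, %d bursts\n",
              x$n_spikes, x$n_isis, x$n_bursts))
  invisible(x)
}

metric_fields <- function() c(
  "avg_firing_rate_hz", "mean_n_intraburst_isis", "mean_burst_length_spikes",
  "mean_burst_duration_s", "mean_n_interburst_isis",
  "mean_interburst_interval_s", "mean_burst_freq_hz",
  "mean_nonburst_freq_hz", "burst_rate_hz", "fraction_isis_in_bursts")

#' Per-cell metric table
#'
#' @param metrics a list of `train_metrics` objects.
#' @return data frame with one row per cell: `cell_id`, `condition`, the
#'   metric columns, and the counts.
#' @export
metrics_table <- function(metrics) {
  if (inherits(metrics, "train_metrics")) metrics <- list(metrics)
  cols <- c("cell_id", "condition", metric_fields(),
            "n_spikes", "n_isis", "n_bursts")
  do.call(rbind, lapply(metrics, function(m) {
    as.data.frame(m[cols], stringsAsFactors = FALSE)
  }))
}

#' Aggregate per-cell metrics into a group summary
#'
#' Reports mean and standard error of the mean (sample SD / sqrt(n)) per
#' metric, skipping cells where a metric is undefined; `n` is reported per
#' metric. SEM is `NA` when fewer than 2 cells define a metric.
#'
#' @param metrics list of `train_metrics` (one per cell).
#' @param condition group label.
#' @return a `group_summary`: `condition`, `summary` (metric, mean, sem, n)
#'   and `cells` (per-cell metric table).
#' @export
aggregate_group <- function(metrics, condition = NULL) {
  if (inherits(metrics, "train_metrics")) metrics <- list(metrics)
  if (!length(metrics)) stop("at least one cell is required")
  tab <- metrics_table(metrics)
  if (is.null(condition)) condition <- tab$condition[1]
  summ <- do.call(rbind, lapply(metric_fields(), function(f) {
    v <- tab[[f]][!is.na(tab[[f]])]
    data.frame(metric = f,
               mean = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  }))
  structure(list(condition = condition, summary = summ, cells = tab),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> condition %s, %d cell(s)\n",
              x$condition, nrow(x$cells)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Select the exemplar cell of a group
#'
#' The exemplar is the cell whose metric value (by default the average
#' firing rate) is closest to the group mean; its recorded pattern is the
#' natural stimulation template for the group. Ties are broken by the
#' lexicographically smallest `cell_id`.
#'
#' @param group a `group_summary` from [aggregate_group()].
#' @param metric metric name; default `"avg_firing_rate_hz"`.
#' @return the exemplar `cell_id` (character scalar), with the cell's
#'   metric value and the group mean attached as attributes.
#' @export
select_exemplar <- function(group, metric = "avg_firing_rate_hz") {
  stopifnot(inherits(group, "group_summary"))
  if (!metric %in% names(group$cells)) stop(sprintf("unknown metric '%s'", metric))
  v <- group$cells[[metric]]
  ok <- !is.na(v)
  if (!any(ok)) stop(sprintf("no cell has a defined value for '%s'", metric))
  m <- mean(v[ok])
  d <- abs(v - m)
  cand <- group$cells$cell_id[ok][d[ok] == min(d[ok])]
  id <- sort(cand)[1]
  structure(id, value = v[group$cells$cell_id == id][1], group_mean = m)
}

#' Write a per-cell metrics CSV
#'
#' One row per cell; columns are `cell_id`, `condition`, the metric field
#' names and the counts. Undefined metrics are written as empty fields.
#'
#' @param metrics list of `train_metrics` or a `group_summary`.
#' @param path output file.
#' @param header optional comment lines (without leading `#`).
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path, header = NULL) {
  tab <- if (inherits(metrics, "group_summary")) metrics$cells else metrics_table(metrics)
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con, sep = "\n")
  utils::write.table(tab, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
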