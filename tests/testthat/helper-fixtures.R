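# Shared fixtures and independent brute-force oracles.

# The 10-ISI worked train: two 3-ISI bursts around a long gap.
worked_isis <- function() {
  c(0.010, 0.010, 0.012, 0.300, 0.080, 0.090, 0.011, 0.012, 0.010, 0.400)
}

worked_train <- function() {
  spike_train(c(0, cumsum(worked_isis())), trial_durations = 0.935)
}

# Brute-force burst segmentation oracle: scan every index and grow runs
# explicitly, no rle/vectorisation shared with the implementation.
oracle_segment <- function(isis, thr) {
  n <- length(isis)
  lab <- rep("interburst", n)
  bursts <- list()
  if (!is.na(thr)) {
    i <- 1
    while (i <= n) {
      if (isis[i] < thr) {
        j <- i
        while (j < n && isis[j + 1] < thr) j <- j + 1
        if (j - i + 1 >= 2) {
          lab[i:j] <- "intraburst"
          bursts[[length(bursts) + 1]] <-
            c(first = i, n_isis = j - i + 1, duration = sum(isis[i:j]))
        }
        i <- j + 1
      } else i <- i + 1
    }
  }
  list(labels = lab, bursts = bursts)
}

# Brute-force two-stage threshold.
oracle_threshold <- function(isis) {
  m1 <- sum(isis) / length(isis)
  kept <- c()
  for (x in isis) if (x < m1) kept <- c(kept, x)
  list(stage1 = m1,
       thr = if (length(kept)) sum(kept) / length(kept) else NA_real_)
}

random_valid_train <- function(n_trials = 3, max_spikes = 20, trial_dur = 1) {
  spikes <- list()
  trial <- list()
  for (tr in seq_len(n_trials) - 1L) {
    k <- sample(0:max_spikes, 1)
    if (k > 0) {
      tt <- sort(runif(k, 0, trial_dur * 0.999))
      tt <- unique(round(tt, 6))
      spikes[[length(spikes) + 1]] <- tt
      trial[[length(trial) + 1]] <- rep(tr, length(tt))
    }
  }
  spike_train(unlist(spikes) %||% numeric(0),
              trial = unlist(trial) %||% integer(0),
              trial_durations = rep(trial_dur, n_trials))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
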