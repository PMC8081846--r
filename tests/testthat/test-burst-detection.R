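test_that("two-stage threshold matches the hand-derived worked example", {
  thr <- compute_burst_threshold(worked_isis())
  expect_equal(thr$stage1_mean_s, 0.0935)
  expect_equal(thr$n_total, 10L)
  expect_equal(thr$n_retained, 8L)           # 0.300 and 0.400 removed
  expect_equal(thr$threshold_s, 0.029375)

  # agrees with the brute-force oracle
  orc <- oracle_threshold(worked_isis())
  expect_equal(thr$stage1_mean_s, orc$stage1)
  expect_equal(thr$threshold_s, orc$thr)
})

test_that("all-equal ISIs leave the threshold undefined and yield no bursts", {
  thr <- compute_burst_threshold(rep(0.1, 5))
  expect_equal(thr$stage1_mean_s, 0.1)
  expect_equal(thr$n_retained, 0L)
  expect_true(is.na(thr$threshold_s))
  seg <- segment_bursts(rep(0.1, 5), thr)
  expect_equal(nrow(seg$bursts), 0)
  expect_true(all(unlist(seg$labels) == "interburst"))
})

test_that("threshold errors on empty input", {
  expect_error(compute_burst_threshold(numeric(0)), "insufficient")
})

test_that("exponential ISIs give the closed-form conditional-mean threshold", {
  # E[X | X < mu] = mu (1 - 2/e) / (1 - 1/e) ~ 0.41802 mu
  mu <- 0.5
  set.seed(7)
  x <- rexp(2e5, 1 / mu)
  thr <- compute_burst_threshold(x)
  expect_equal(thr$threshold_s / mu, (1 - 2 * exp(-1)) / (1 - exp(-1)),
               tolerance = 0.01)
})

test_that("segmentation reproduces the worked example and the minimum-two rule", {
  isis <- worked_isis()
  seg <- segment_bursts(isis, compute_burst_threshold(isis))
  expect_equal(nrow(seg$bursts), 2)
  expect_equal(seg$bursts$first_isi_index, c(0L, 6L))
  expect_equal(seg$bursts$n_isis, c(3L, 3L))
  expect_equal(seg$bursts$n_spikes, c(4L, 4L))
  expect_equal(seg$bursts$duration_s, c(0.032, 0.033))
  inter <- isis[unlist(seg$labels) == "interburst"]
  expect_setequal(inter, c(0.300, 0.080, 0.090, 0.400))

  # a lone sub-threshold ISI is not a burst
  thr <- structure(list(stage1_mean_s = 0.3367, threshold_s = 0.1,
                        n_total = 3L, n_retained = 1L),
                   class = "threshold_result")
  seg1 <- segment_bursts(c(0.5, 0.01, 0.5), thr)
  expect_equal(nrow(seg1$bursts), 0)

  # nothing below threshold: all interburst
  seg2 <- segment_bursts(c(0.5, 0.6, 0.7), thr)
  expect_equal(nrow(seg2$bursts), 0)
  expect_true(all(unlist(seg2$labels) == "interburst"))
})

test_that("detect_bursts composes the pipeline deterministically", {
  st <- spike_train(c(0, .010, .020, .032, .332, .412, .502, .513, .525,
                      .535, .935))
  seg <- detect_bursts(st)
  expect_equal(nrow(seg$bursts), 2)
  expect_equal(seg$threshold$threshold_s, 0.029375)

  # 2 spikes -> 1 ISI -> removed by stage 1 -> no threshold, no bursts
  seg2 <- detect_bursts(spike_train(c(0.1, 0.2), trial_durations = 1))
  expect_true(is.na(seg2$threshold$threshold_s))
  expect_equal(nrow(seg2$bursts), 0)

  expect_identical(detect_bursts(st)$bursts, seg$bursts)
})

test_that("intraburst and interburst counts conserve the ISI total", {
  set.seed(99)
  for (rep in 1:40) {
    st <- random_valid_train(n_trials = sample(1:4, 1))
    isis <- compute_isis(st)
    if (sum(lengths(isis)) < 1) next
    seg <- segment_bursts(isis, compute_burst_threshold(isis))
    labs <- unlist(seg$labels)
    expect_equal(sum(labs == "intraburst"), sum(seg$bursts$n_isis))
    expect_equal(length(labs), seg$threshold$n_total)
  }
})

test_that("segmentation is equivariant under rescaling of all ISIs", {
  set.seed(123)
  for (rep in 1:25) {
    isis <- rexp(sample(5:60, 1), rate = sample(c(1, 10, 50), 1))
    c_scale <- runif(1, 0.1, 20)
    thr1 <- compute_burst_threshold(isis)
    thr2 <- compute_burst_threshold(isis * c_scale)
    expect_equal(thr2$stage1_mean_s, thr1$stage1_mean_s * c_scale)
    expect_equal(thr2$threshold_s, thr1$threshold_s * c_scale)
    s1 <- segment_bursts(isis, thr1)
    s2 <- segment_bursts(isis * c_scale, thr2)
    expect_identical(s1$labels, s2$labels)
  }
})

test_that("segmentation equals brute-force maximal-run enumeration", {
  set.seed(2024)
  for (rep in 1:1000) {
    n <- sample(1:50, 1)
    isis <- switch(sample(3, 1),
                   rexp(n, 20),
                   runif(n, 0.001, 0.5),
                   round(runif(n, 0.01, 0.2), 2))  # ties likely
    thr <- compute_burst_threshold(isis)
    seg <- segment_bursts(isis, thr)
    orc <- oracle_segment(isis, thr$threshold_s)
    expect_identical(seg$labels[[1]], orc$labels)
    expect_equal(nrow(seg$bursts), length(orc$bursts))
    if (length(orc$bursts)) {
      om <- do.call(rbind, orc$bursts)
      expect_equal(seg$bursts$first_isi_index, as.integer(om[, "first"]) - 1L)
      expect_equal(seg$bursts$n_isis, as.integer(om[, "n_isis"]))
      expect_equal(seg$bursts$duration_s, unname(om[, "duration"]))
    }
  }
})

test_that("burst report JSON round-trips the segmentation fields", {
  seg <- detect_bursts(worked_train())
  path <- withr::local_tempfile(fileext = ".json")
  export_burst_report(seg, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$threshold$threshold_s, 0.029375)
  expect_equal(rep$threshold$n_retained, 8)
  expect_equal(rep$bursts$first_isi_index, c(0, 6))
  expect_equal(rep$bursts$n_isis, c(3, 3))
})
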