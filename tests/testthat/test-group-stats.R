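# Frozen reference values for the omnibus normality statistic were computed
# with an independent implementation of the same published approximations
# (D'Agostino 1970; Anscombe & Glynn 1983) on the fixed samples below.
normalish_20 <- c(6.0979, 7.3956, 7.92, 8.0822, 8.2814, 8.2939, 9.3675,
                  9.9001, 9.9664, 10.1321, 10.2557, 10.6094, 10.7375,
                  10.935, 11.5009, 11.5556, 11.7569, 11.7588, 11.8811,
                  12.2545)
expo_40 <- c(0.7075, 1.0252, 0.5685, 0.8951, 0.2065, 3.3836, 0.0098,
             2.8092, 0.5753, 0.3005, 0.5411, 0.3121, 0.8998, 1.0737,
             1.8843, 0.2221, 3.1447, 0.7359, 0.3484, 0.8836, 0.0751,
             0.06, 1.2236, 0.7729, 2.196, 0.4752, 0.5213, 1.1808,
             0.5265, 0.0222, 0.2933, 1.0143, 0.6347, 1.3966, 0.0083,
             0.9038, 0.2503, 0.3556, 3.0749, 1.4044)

test_that("normality omnibus matches frozen reference values", {
  r1 <- check_normality(normalish_20)
  expect_equal(r1$statistic, 1.6864987809, tolerance = 1e-8)
  expect_equal(r1$p_value, 0.4303100040, tolerance = 1e-8)
  expect_false(r1$significant)

  r2 <- check_normality(expo_40)
  expect_equal(r2$statistic, 15.9939408788, tolerance = 1e-8)
  expect_equal(r2$p_value, 0.0003364804733, tolerance = 1e-8)
  expect_true(r2$significant)
})

test_that("normality routing honours the sample-size precondition", {
  r <- check_normality(c(1, 2, 3, 4, 5, 6))
  expect_true(r$untestable)
  expect_true(is.na(r$p_value))
  expect_error(check_normality(c(1, 2)), "n >= 3")
})

test_that("normality test is calibrated under the null and rejects skew", {
  set.seed(77)
  ps <- replicate(100, check_normality(rnorm(5000))$p_value)
  expect_gte(mean(ps > 0.001), 0.99)
  set.seed(78)
  expect_true(check_normality(rexp(5000))$significant)
})

test_that("two-sample comparison routes and computes correctly", {
  r <- compare_two(c(1, 2, 3, 4), c(3, 4, 5, 6), route = "parametric")
  expect_equal(r$test_name, "unpaired_t")
  expect_equal(r$statistic, -2.1909, tolerance = 1e-4)
  expect_equal(r$df, 6)

  # identical samples: centred rank statistic 0, not significant
  r2 <- compare_two(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$statistic, 0)
  expect_false(r2$significant)

  # strong skew forces the non-parametric route under auto
  set.seed(3)
  skewed <- rexp(60)^2
  normal <- rnorm(60, mean = 1)
  r3 <- compare_two(skewed, normal)
  expect_equal(r3$test_name, "mann_whitney")

  expect_error(compare_two(rep(1, 5), rep(1, 5)), "degenerate")
  expect_error(compare_two(1, c(1, 2)), "n >= 2")
})

test_that("multi-group comparison: equal means give F = 0, p = 1", {
  r <- compare_multi(list(c(1, 3), c(2, 2), c(3, 1)), route = "parametric")
  expect_equal(r$test_name, "one_way_anova")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_null(r$posthoc)
  expect_false(is.null(r$extra$bartlett))
  expect_error(compare_multi(list(1:3, 1:3)), ">= 3 groups")
  expect_error(compare_multi(list(1:3, 1:3, 5)), "n >= 2")
})

test_that("a shifted group is flagged by SNK on exactly the right pairs", {
  set.seed(101)
  hits <- 0; wrong <- 0; n_rep <- 100
  for (i in 1:n_rep) {
    g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10, mean = 3))
    r <- compare_multi(g, route = "parametric")
    if (isTRUE(r$significant) && !is.null(r$posthoc)) {
      ph <- r$posthoc
      sig_pairs <- ph[ph$significant, c("group_a", "group_b")]
      involves_c <- apply(sig_pairs, 1, function(p) "c" %in% p)
      if (nrow(sig_pairs) > 0 && all(involves_c)) hits <- hits + 1
      if (any(!involves_c)) wrong <- wrong + 1
    }
  }
  expect_gte(hits / n_rep, 0.95)
  expect_lte(wrong / n_rep, 0.05)
})

test_that("non-parametric route uses Kruskal-Wallis with Dunn post-hoc", {
  set.seed(55)
  g <- list(a = rexp(25), b = rexp(25), c = rexp(25) + 3)
  r <- compare_multi(g)
  expect_equal(r$test_name, "kruskal_wallis")
  expect_true(r$significant)
  expect_false(is.null(r$posthoc))
  sig <- r$posthoc[r$posthoc$significant, ]
  expect_true(all(apply(sig[, c("group_a", "group_b")], 1,
                        function(p) "c" %in% p)))
})

test_that("post-hoc tests are gated by the omnibus result", {
  set.seed(60)
  for (i in 1:50) {
    g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8))
    r <- compare_multi(g, route = "parametric")
    if (!isTRUE(r$significant)) expect_null(r$posthoc)
    r2 <- compare_multi(g, route = "nonparametric")
    if (!isTRUE(r2$significant)) expect_null(r2$posthoc)
  }
})

test_that("KS comparison matches hand-enumerated D values and properties", {
  expect_equal(ks_compare(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_compare(c(1, 2), c(10, 11, 12))$statistic, 1)
  expect_equal(ks_compare(c(1, 2, 3, 4), c(2, 3, 4, 5))$statistic, 0.25)

  set.seed(4)
  a <- rnorm(30); b <- rnorm(40)
  d1 <- ks_compare(a, b)$statistic
  expect_equal(ks_compare(b, a)$statistic, d1)        # symmetric
  expect_equal(ks_compare(a + 5, b + 5)$statistic, d1) # shift-invariant
  expect_true(d1 >= 0 && d1 <= 1)
  expect_equal(ks_compare(a, b)$alpha, 0.001)

  expect_error(ks_compare(numeric(0), 1), "non-empty")
})

test_that("stat reports serialise to JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  res <- list(amp = compare_two(c(1, 2, 3, 4), c(3, 4, 5, 6),
                                route = "parametric"))
  export_stat_report(res, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$amp$test_name, "unpaired_t")
  expect_equal(back$amp$alpha, 0.05)
})
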