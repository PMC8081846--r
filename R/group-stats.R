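stat_result <- function(test_name, statistic, df = NA_real_, p_value,
                        alpha, posthoc = NULL, notes = "",
                        untestable = FALSE, extra = NULL) {
  structure(list(test_name = test_name,
                 statistic = unname(statistic),
                 df = unname(df),
                 p_value = unname(p_value),
                 alpha = alpha,
                 significant = if (is.na(p_value)) NA else p_value < alpha,
                 posthoc = posthoc,
                 notes = notes,
                 untestable = untestable,
                 extra = extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic %s, p %s (alpha %g)%s\n",
              x$test_name,
              if (is.na(x$statistic[1])) "NA" else
                paste(format(x$statistic, digits = 5), collapse = ", "),
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 4),
              x$alpha,
              if (isTRUE(x$significant)) " *" else ""))
  if (nzchar(x$notes)) cat("  ", x$notes, "\n", sep = "")
  if (!is.null(x$posthoc)) {
    cat("  post-hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' The K-squared omnibus statistic combines the transformed sample skewness
#' and kurtosis (each brought to approximate standard normality) as
#' `K2 = Z1^2 + Z2^2`, referred to a chi-squared distribution with 2
#' degrees of freedom. The kurtosis transformation requires `n >= 8`;
#' smaller samples return a result flagged untestable, which forces
#' non-parametric routing downstream.
#'
#' @param x numeric sample, `n >= 3`.
#' @param alpha significance level; default 0.05.
#' @return a `stat_result`; `$untestable` is `TRUE` when `n < 8`.
#' @export
check_normality <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("normality check requires n >= 3")
  if (n < 8)
    return(stat_result("dagostino_pearson", NA_real_, p_value = NA_real_,
                       alpha = alpha, untestable = TRUE,
                       notes = sprintf("n = %d < 8: omnibus test untestable; route non-parametric", n)))
  z1 <- skewness_z(x)
  z2 <- kurtosis_z(x)
  k2 <- z1^2 + z2^2
  stat_result("dagostino_pearson", k2, df = 2,
              p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
              alpha = alpha,
              notes = sprintf("skew z = %.4f, kurtosis z = %.4f", z1, z2))
}

# D'Agostino (1970) transformed skewness
skewness_z <- function(x) {
  n <- length(x)
  m <- x - mean(x)
  b1 <- (sum(m^3) / n) / (sum(m^2) / n)^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  a <- sqrt(2 / (w2 - 1))
  delta * log(y / a + sqrt((y / a)^2 + 1))
}

# Anscombe & Glynn (1983) transformed kurtosis
kurtosis_z <- function(x) {
  n <- length(x)
  m <- x - mean(x)
  b2 <- (sum(m^4) / n) / (sum(m^2) / n)^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  (1 - 2 / (9 * a) -
     ((1 - 2 / a) / (1 + xs * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
}

route_samples <- function(samples, alpha, route) {
  if (route != "auto")
    return(list(parametric = route == "parametric",
                why = sprintf("route forced %s", route)))
  checks <- lapply(samples, function(s) {
    if (length(s) < 3) stat_result("dagostino_pearson", NA_real_,
                                   p_value = NA_real_, alpha = alpha,
                                   untestable = TRUE, notes = "n < 3")
    else check_normality(s, alpha)
  })
  fails <- vapply(checks, function(cc) isTRUE(cc$untestable) ||
                    isTRUE(cc$significant), logical(1))
  list(parametric = !any(fails),
       why = if (any(fails))
         "normality rejected or untestable in at least one sample: non-parametric route"
       else "all samples pass normality: parametric route")
}

#' Compare two independent samples
#'
#' Routing follows normality: if both samples pass the
#' [check_normality()] omnibus test, an unpaired two-sample t-test with
#' equal-variance pooling is used; otherwise a Mann-Whitney rank-sum test.
#' The Mann-Whitney p-value is exact when sample sizes permit and tie-free,
#' and otherwise uses the tie-corrected normal approximation; the reported
#' statistic is the standardised (centred) U, so identical samples give 0.
#'
#' @param a,b numeric samples, each `n >= 2`.
#' @param alpha significance level; default 0.05.
#' @param route `"auto"` (normality-based), `"parametric"` or
#'   `"nonparametric"` override.
#' @return a `stat_result`; `$notes` records the routing decision.
#' @export
compare_two <- function(a, b, alpha = 0.05,
                        route = c("auto", "parametric", "nonparametric")) {
  route <- match.arg(route)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
    stop("degenerate data: both samples constant and equal")
  r <- route_samples(list(a, b), alpha, route)
  if (r$parametric) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    stat_result("unpaired_t", tt$statistic, df = tt$parameter,
                p_value = tt$p.value, alpha = alpha, notes = r$why)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    u <- wt$statistic                     # U for the first sample
    n1 <- length(a); n2 <- length(b)
    mu <- n1 * n2 / 2
    ties <- table(c(a, b))
    n <- n1 + n2
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
    z <- if (sigma > 0) (u - mu) / sigma else 0
    stat_result("mann_whitney", z, p_value = wt$p.value, alpha = alpha,
                notes = sprintf("%s; U = %g", r$why, u))
  }
}

#' Compare three or more independent groups
#'
#' Parametric route: one-way ANOVA, with Bartlett's variance-homogeneity
#' test reported alongside (in `$extra$bartlett`) and a
#' Student-Newman-Keuls stepwise post-hoc on the studentized-range
#' distribution (`posthoc = "tukey"` substitutes Tukey's HSD). The
#' non-parametric route is Kruskal-Wallis with Dunn's rank-based multiple
#' comparisons (Bonferroni-adjusted). Either post-hoc runs only when the
#' omnibus test is significant — a non-significant omnibus never yields
#' significant pairs.
#'
#' @param groups list of numeric samples (>= 3 groups, each `n >= 2`).
#' @param alpha significance level; default 0.05.
#' @param route `"auto"`, `"parametric"` or `"nonparametric"`.
#' @param posthoc `"snk"` (default) or `"tukey"` for the parametric route.
#' @return a `stat_result`; `$posthoc` is a data frame of pairwise results
#'   or `NULL` when the omnibus is non-significant.
#' @export
compare_multi <- function(groups, alpha = 0.05,
                          route = c("auto", "parametric", "nonparametric"),
                          posthoc = c("snk", "tukey")) {
  route <- match.arg(route)
  posthoc <- match.arg(posthoc)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 3) stop("compare_multi needs >= 3 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  r <- route_samples(groups, alpha, route)

  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))

  if (r$parametric) {
    fit <- stats::aov(x ~ g)
    tab <- summary(fit)[[1]]
    fstat <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
    dfs <- tab[["Df"]]
    bart <- stats::bartlett.test(x, g)
    ph <- if (!is.na(p) && p < alpha)
      snk_posthoc(groups, mse = tab[["Mean Sq"]][2], df_err = dfs[2],
                  alpha = alpha, method = posthoc) else NULL
    stat_result("one_way_anova", fstat, df = dfs,
                p_value = p, alpha = alpha, posthoc = ph,
                notes = sprintf("%s; Bartlett chi-sq = %.4f, p = %.4g",
                                r$why, bart$statistic, bart$p.value),
                extra = list(bartlett = bart))
  } else {
    kw <- stats::kruskal.test(x, g)
    ph <- if (kw$p.value < alpha) dunn_posthoc(groups, alpha) else NULL
    stat_result("kruskal_wallis", kw$statistic, df = kw$parameter,
                p_value = kw$p.value, alpha = alpha, posthoc = ph,
                notes = r$why)
  }
}

# Student-Newman-Keuls (or Tukey) pairwise comparisons on group means.
# SNK refers the studentized range of a p-step stretch of ordered means to
# q(p, df); stepwise gating declares every pair inside a non-significant
# stretch non-significant.
snk_posthoc <- function(groups, mse, df_err, alpha, method = "snk") {
  k <- length(groups)
  means <- vapply(groups, mean, 1)
  ns <- lengths(groups)
  ord <- order(means)
  means <- means[ord]; ns <- ns[ord]; nm <- names(groups)[ord]

  blocked <- matrix(FALSE, k, k)   # stretches declared non-significant
  rows <- list()
  for (span in k:2) {
    for (i in 1:(k - span + 1)) {
      j <- i + span - 1
      q <- abs(means[j] - means[i]) /
        sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
      stretch <- if (method == "snk") span else k
      p <- stats::ptukey(q, stretch, df_err, lower.tail = FALSE)
      sig <- !blocked[i, j] && p < alpha
      if (!sig) {
        # gate every sub-stretch
        for (a in i:j) for (b in a:j) blocked[a, b] <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = nm[i], group_b = nm[j], q = q, p = p, significant = sig)
    }
  }
  ph <- do.call(rbind, rows)
  rownames(ph) <- NULL
  ph
}

# Dunn's rank-based multiple comparisons after Kruskal-Wallis,
# tie-corrected z, Bonferroni-adjusted p-values.
dunn_posthoc <- function(groups, alpha) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  n <- length(x)
  rk <- rank(x)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(rk, g, mean)
  ns <- tapply(rk, g, length)
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(idx) {
    a <- pairs[1, idx]; b <- pairs[2, idx]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    p <- min(1, 2 * stats::pnorm(-abs(z)) * m)
    data.frame(group_a = a, group_b = b, z = z, p = p,
               significant = p < alpha)
  })
  ph <- do.call(rbind, rows)
  rownames(ph) <- NULL
  ph
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two empirical cumulative distributions via the supremum
#' distance D with the asymptotic p-value. The conventional cutoff for
#' cumulative mEPSC amplitude distributions is stringent (`alpha = 0.001`),
#' reflecting the large per-event sample sizes.
#'
#' @param a,b numeric samples, each `n >= 1`.
#' @param alpha significance level; default 0.001.
#' @return a `stat_result` with `statistic = D`.
#' @export
ks_compare <- function(a, b, alpha = 0.001) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  stat_result("kolmogorov_smirnov", kt$statistic, p_value = kt$p.value,
              alpha = alpha,
              notes = sprintf("two-sample D, asymptotic p, n = %d vs %d",
                              length(a), length(b)))
}

#' Write a set of comparison results as a JSON report
#'
#' @param results a `stat_result` or list of them (names become labels).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_stat_report <- function(results, path) {
  if (inherits(results, "stat_result")) results <- list(results)
  recs <- lapply(results, function(r) {
    r$extra <- NULL
    unclass(r)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows", force = TRUE)
  invisible(path)
}
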