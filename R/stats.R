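#' Statistical test result container
#'
#' Uniform return type for the cohort statistics: test name, statistic,
#' degrees of freedom (a number or a pair), p-value, and optionally a
#' data.frame of pairwise contrasts.
#'
#' @param test character test name
#' @param statistic numeric test statistic
#' @param df degrees of freedom (numeric scalar or length-2 vector)
#' @param p_value p-value in `[0, 1]`
#' @param pairwise optional data.frame with columns `contrast`,
#'   `statistic`, `p_value`
#' @return An object of class `stat_result`.
#' @export
stat_result <- function(test, statistic, df, p_value, pairwise = NULL) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p-value must lie in [0, 1]", call. = FALSE)
  structure(list(test = test, statistic = as.numeric(statistic),
                 df = as.numeric(df), p_value = as.numeric(p_value),
                 pairwise = pairwise),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(signif(x$df, 6), collapse = ", ")
  cat(sprintf("<stat_result> %s: statistic = %.4g, df = %s, p = %s\n",
              x$test, x$statistic, dfs, format_p3(x$p_value)))
  if (!is.null(x$pairwise)) {
    cat("  pairwise contrasts:\n")
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("    %s: p = %s\n", x$pairwise$contrast[i],
                  format_p3(x$pairwise$p_value[i])))
  }
  invisible(x)
}

#' Kolmogorov-Smirnov (Lilliefors) normality test
#'
#' One-sample KS test against a normal distribution with mean and SD
#' estimated from the sample.  Because the parameters are estimated,
#' Lilliefors critical values are used (the classic KS null distribution
#' would be anticonservative); the p-value is the Dallal-Wilkinson
#' approximation.
#'
#' @param x numeric sample (n >= 5; the Lilliefors p-value approximation
#'   is not defined below that)
#' @return A [stat_result()] with the D statistic (df is `NA`).
#' @export
ks_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5L)
    stop("Lilliefors normality test requires n >= 5", call. = FALSE)
  if (sd(x) == 0)
    stop("zero-variance sample: normality is undefined for a constant",
         call. = FALSE)
  lt <- nortest::lillie.test(x)
  stat_result("Kolmogorov-Smirnov (Lilliefors)", unname(lt$statistic),
              NA_real_, lt$p.value)
}

# Accept either a list of numeric vectors or (values, group) and return a
# named list of numeric vectors.
as_group_list <- function(groups, values = NULL) {
  if (!is.null(values)) groups <- split(values, groups)
  if (!is.list(groups) || length(groups) < 1L)
    stop("`groups` must be a list of numeric vectors", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  lapply(groups, function(g) as.numeric(g[is.finite(g)]))
}

#' Levene test for homogeneity of variance
#'
#' Brown-Forsythe/Levene test centered at the group means (the SPSS
#' default), as used to check the equal-variance assumption before
#' t-tests and ANOVA.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2)
#' @return A [stat_result()] with the W (F) statistic and
#'   `(df_between, df_within)`.
#' @export
levene_test <- function(groups) {
  gs <- as_group_list(groups)
  if (length(gs) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(gs) < 2L))
    stop("each group needs n >= 2", call. = FALSE)
  y <- unlist(gs, use.names = FALSE)
  f <- factor(rep(names(gs), lengths(gs)), levels = names(gs))
  lt <- car::leveneTest(y, f, center = mean)
  stat_result("Levene (center = mean)", lt[1, "F value"],
              c(lt[1, "Df"], lt[2, "Df"]), lt[1, "Pr(>F)"])
}

#' Independent two-sample t-test (pooled variance)
#'
#' Two-sided t-test with pooled variance, df = n_a + n_b - 2.  When the
#' pooled variance is zero the statistic degenerates: equal means give
#' t = 0, p = 1; unequal means have an infinite statistic and raise an
#' error.
#'
#' @param a,b numeric samples (each n >= 2)
#' @return A [stat_result()].
#' @export
t_test_independent <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs n >= 2", call. = FALSE)
  df <- length(a) + length(b) - 2
  pooled <- ((length(a) - 1) * stats::var(a) +
             (length(b) - 1) * stats::var(b)) / df
  if (pooled == 0) {
    if (mean(a) == mean(b))
      return(stat_result("independent t (pooled)", 0, df, 1))
    stop("zero pooled variance with unequal means: ",
         "t statistic is infinite", call. = FALSE)
  }
  tt <- t.test(a, b, var.equal = TRUE)
  stat_result("independent t (pooled)", unname(tt$statistic),
              unname(tt$parameter), tt$p.value)
}

#' One-way analysis of variance with pairwise contrasts
#'
#' Omnibus one-way ANOVA (equal-variance F test) across >= 2 groups.
#' Pairwise contrasts are appended as two-sided pooled-variance t-tests
#' between each pair of groups, uncorrected by default (mirroring the
#' P1/P2/P3 presentation of clinical tables); set `correction` to
#' `"bonferroni"` or `"holm"` for multiplicity adjustment.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2)
#' @param pairwise append pairwise contrasts?
#' @param correction p-value adjustment across the pairwise family:
#'   `"none"` (default), `"bonferroni"` or `"holm"`
#' @return A [stat_result()] with F, `(df_between, df_within)`, p, and a
#'   `pairwise` data.frame.
#' @export
one_way_anova <- function(groups, pairwise = TRUE,
                          correction = c("none", "bonferroni", "holm")) {
  correction <- match.arg(correction)
  gs <- as_group_list(groups)
  if (length(gs) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(gs) < 2L))
    stop("each group needs n >= 2", call. = FALSE)
  y <- unlist(gs, use.names = FALSE)
  f <- factor(rep(names(gs), lengths(gs)), levels = names(gs))
  fit <- anova(aov(y ~ f))
  Fv <- fit[1, "F value"]; p <- fit[1, "Pr(>F)"]
  if (fit[1, "Mean Sq"] == 0 && fit[2, "Mean Sq"] == 0) { Fv <- 0; p <- 1 }
  pw <- NULL
  if (pairwise) {
    nm <- names(gs)
    pairs <- utils::combn(length(gs), 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      r <- t_test_independent(gs[[i1]], gs[[i2]])
      data.frame(contrast = paste(nm[i1], "vs", nm[i2]),
                 statistic = r$statistic, p_value = r$p_value,
                 stringsAsFactors = FALSE)
    }))
    pw$p_value <- stats::p.adjust(pw$p_value, method = correction)
  }
  stat_result("one-way ANOVA", Fv, c(fit[1, "Df"], fit[2, "Df"]), p,
              pairwise = pw)
}

#' One-way ANOVA reconstructed from group summary statistics
#'
#' Computes the omnibus F test from printed group means, SDs and sizes:
#' between-group mean square `sum(n_i (m_i - m)^2) / (k - 1)` over
#' within-group mean square `sum((n_i - 1) s_i^2) / (N - k)`, with `m`
#' the grand (size-weighted) mean.  Agrees with [one_way_anova()] on raw
#' data to numerical precision, and lets published summary tables be
#' re-analyzed without the raw measurements.
#'
#' @param means,sds,ns numeric vectors of group means, SDs and sizes
#'   (equal length >= 2; `ns >= 2`, `sds > 0`)
#' @return A [stat_result()].
#' @examples
#' anova_from_summary(c(0.34, 0.29, 0.26), c(0.07, 0.07, 0.03),
#'                    c(21, 21, 21))
#' @export
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (length(sds) != k || length(ns) != k)
    stop("`means`, `sds` and `ns` must have equal length", call. = FALSE)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(ns < 2)) stop("all group sizes must be >= 2", call. = FALSE)
  if (any(sds <= 0)) stop("all SDs must be > 0", call. = FALSE)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ms_between <- sum(ns * (means - grand)^2) / (k - 1)
  ms_within <- sum((ns - 1) * sds^2) / (N - k)
  Fv <- ms_between / ms_within
  p <- pf(Fv, k - 1, N - k, lower.tail = FALSE)
  stat_result("one-way ANOVA (from summaries)", Fv, c(k - 1, N - k), p)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction,
#' df = (r - 1)(c - 1), for comparing categorical data (e.g. sex by
#' group) across groups.
#'
#' @param table 2D matrix of nonnegative integer counts with all row and
#'   column sums positive
#' @return A [stat_result()].
#' @export
chi_square <- function(table) {
  if (!is.matrix(table) || any(table < 0) ||
      any(table != round(table)))
    stop("`table` must be a matrix of nonnegative integer counts",
         call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all row and column marginals must be positive", call. = FALSE)
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  stat_result("Pearson chi-square", unname(ct$statistic),
              unname(ct$parameter), ct$p.value)
}

#' Exact power of the two-sided two-sample t-test
#'
#' Power computed from the noncentral t distribution with
#' noncentrality `delta / sigma * sqrt(n / 2)` and `2n - 2` degrees of
#' freedom, for `n` per group.
#'
#' @param n per-group sample size (>= 2)
#' @param delta true between-group mean difference (metric units)
#' @param sigma common SD (metric units)
#' @param alpha two-sided significance level
#' @return Power in `[0, 1]`.
#' @export
two_sample_t_power <- function(n, delta, sigma, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- delta / sigma * sqrt(n / 2)
  tc <- qt(1 - alpha / 2, df)
  pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
}

#' A-priori sample size for a two-sample t-test (exact noncentral t)
#'
#' Smallest integer per-group n whose exact noncentral-t power reaches
#' the requested power at the given two-sided level, expected maximum
#' between-group difference and common SD.  The exact computation is
#' what standard power software uses; with alpha 0.05, power 0.8,
#' difference 0.1 and SD 0.05 it returns 6 per group (a normal
#' approximation would understate the requirement).
#'
#' @param delta expected maximum between-group difference (> 0)
#' @param sigma common SD (> 0)
#' @param alpha two-sided significance level (default 0.05)
#' @param power target power (default 0.8)
#' @param n_max search cap
#' @return Integer n per group.
#' @examples
#' sample_size_two_sample_t(delta = 0.1, sigma = 0.05)  # 6
#' @export
sample_size_two_sample_t <- function(delta, sigma, alpha = 0.05,
                                     power = 0.8, n_max = 1e6L) {
  stopifnot_scalar_num(sigma, "sigma", positive = TRUE)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("`delta` = 0 admits no finite sample size; need delta > 0",
         call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("`alpha` and `power` must lie in (0, 1)", call. = FALSE)
  n <- 2L
  while (n <= n_max) {
    if (two_sample_t_power(n, delta, sigma, alpha) >= power)
      return(n)
    n <- n + 1L
  }
  stop("no n <= n_max reaches the requested power", call. = FALSE)
}
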