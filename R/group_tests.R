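#' Normality-gated two-group comparisons
#'
#' Compares every covariate between the two outcome groups. Continuous
#' variables are gated by a Shapiro-Wilk test in each group at
#' `alpha_normal`: if both groups are compatible with normality, an
#' independent-samples t-test (pooled variance) is used, otherwise a
#' Wilcoxon rank-sum test. Categorical variables use a chi-squared test on
#' the 2-way contingency table. All tests are two-sided. A variable constant
#' in both groups is flagged and not tested.
#'
#' @param table cohort data.frame with a two-level factor `outcome` column
#'   (see [simulate_cohort()]).
#' @param outcome name of the outcome column (default `"outcome"`).
#' @param alpha_normal significance level of the normality gate (default 0.05).
#' @return data.frame of class `group_tests`, one row per covariate:
#'   `variable`, `type`, `method` (`t-test`, `rank-sum`, `chi-squared` or
#'   `none`), `statistic`, `p_value`, and per-group summary strings
#'   (`mean +/- SD` or `count (%)` of the last level).
#' @export
compare_groups <- function(table, outcome = "outcome", alpha_normal = 0.05) {
  grp <- check_outcome(table, outcome)
  vars <- setdiff(names(table), outcome)
  rows <- lapply(vars, function(v) {
    x <- table[[v]]
    x1 <- x[grp == levels(grp)[1]]
    x2 <- x[grp == levels(grp)[2]]
    if (is.numeric(x)) {
      s1 <- sprintf("%.2f ± %.2f", mean(x1), stats::sd(x1))
      s2 <- sprintf("%.2f ± %.2f", mean(x2), stats::sd(x2))
      if (length(unique(x)) == 1L)
        return(data.frame(variable = v, type = "continuous", method = "none",
                          statistic = NA_real_, p_value = NA_real_,
                          summary1 = s1, summary2 = s2,
                          note = "constant in both groups"))
      normal <- shapiro_ok(x1, alpha_normal) && shapiro_ok(x2, alpha_normal)
      if (normal) {
        tt <- stats::t.test(x1, x2, var.equal = TRUE)
        data.frame(variable = v, type = "continuous", method = "t-test",
                   statistic = unname(tt$statistic), p_value = tt$p.value,
                   summary1 = s1, summary2 = s2, note = "")
      } else {
        wt <- suppressWarnings(stats::wilcox.test(x1, x2))
        data.frame(variable = v, type = "continuous", method = "rank-sum",
                   statistic = unname(wt$statistic), p_value = wt$p.value,
                   summary1 = s1, summary2 = s2, note = "")
      }
    } else {
      x <- as.factor(x)
      lev <- levels(x)[length(levels(x))]
      cnt <- function(xx) sprintf("%d (%.1f%%)", sum(xx == lev),
                                  100 * mean(xx == lev))
      if (length(unique(x)) == 1L)
        return(data.frame(variable = v, type = "categorical", method = "none",
                          statistic = NA_real_, p_value = NA_real_,
                          summary1 = cnt(x1), summary2 = cnt(x2),
                          note = "constant in both groups"))
      ct <- suppressWarnings(stats::chisq.test(base::table(x, grp)))
      data.frame(variable = v, type = "categorical", method = "chi-squared",
                 statistic = unname(ct$statistic), p_value = ct$p.value,
                 summary1 = cnt(x1), summary2 = cnt(x2), note = "")
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_tests", "data.frame")
  out
}

shapiro_ok <- function(x, alpha) {
  # shapiro.test requires 3..5000 values; outside that range, fall back to
  # treating the sample as non-normal (rank-sum is always valid)
  if (length(x) < 3L || length(x) > 5000L) return(FALSE)
  if (stats::sd(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value > alpha
}

check_outcome <- function(table, outcome) {
  if (!outcome %in% names(table)) stop("no column '", outcome, "' in table")
  grp <- as.factor(table[[outcome]])
  if (nlevels(grp) != 2L) stop("outcome must have exactly 2 levels")
  if (any(tabulate(grp, 2L) == 0L)) stop("both outcome groups must be non-empty")
  grp
}

#' Pool per-group summaries into an overall mean and SD
#'
#' Given per-group sample sizes, means and SDs, returns the mean and SD of
#' the pooled sample, exactly as if the raw samples had been concatenated:
#' the overall mean is the size-weighted mean of group means, and the overall
#' variance follows the law of total variance with the sample (n-1)
#' denominator.
#'
#' @param n integer vector of group sizes (all `>= 1`).
#' @param mean numeric vector of group means.
#' @param sd numeric vector of group SDs (groups of size 1 contribute 0
#'   within-group variance).
#' @return list with `n`, `mean`, `sd` of the pooled sample.
#' @export
pooled_summary <- function(n, mean, sd) {
  stopifnot(length(n) == length(mean), length(n) == length(sd), all(n >= 1))
  N <- sum(n)
  M <- sum(n * mean) / N
  sd0 <- ifelse(n > 1, sd, 0)
  ss <- sum((n - 1) * sd0^2) + sum(n * (mean - M)^2)
  list(n = N, mean = M, sd = if (N > 1) sqrt(ss / (N - 1)) else NA_real_)
}
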