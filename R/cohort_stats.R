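# Between-group baseline comparisons for the cohort table: pooled t-test,
# Pearson chi-square, Mann-Whitney U, Kruskal-Wallis, one-way ANOVA, and
# the normal/non-normal routing that assembles the full report.

.test_result <- function(test, statistic, df, p_value) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat("<test_result> ", x$test, ": statistic = ", signif(x$statistic, 4),
      if (!is.null(x$df) && !all(is.na(x$df))) paste0(", df = ", paste(x$df, collapse = ", ")),
      ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Pooled-variance two-sample t-test
#'
#' Two-sided independent-samples t-test with pooled variance, computable
#' either from raw values or from `(n, mean, sd)` group summaries (as
#' printed in a baseline characteristics table).
#'
#' @param a,b either numeric vectors of raw values, or named lists/vectors
#'   with elements `n`, `mean`, `sd`.
#' @return A `test_result` with the t statistic, degrees of freedom, and
#'   two-sided p value.
#' @export
ttest_pooled <- function(a, b) {
  summ <- function(x) {
    if (is.list(x) || !is.null(names(x))) {
      list(n = x[["n"]], mean = x[["mean"]], sd = x[["sd"]])
    } else {
      if (length(x) < 2) stop("each group needs n >= 2 raw values")
      list(n = length(x), mean = mean(x), sd = stats::sd(x))
    }
  }
  sa <- summ(a); sb <- summ(b)
  if (sa$n < 2 || sb$n < 2) stop("each group needs n >= 2")
  df <- sa$n + sb$n - 2
  sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / df
  if (sp2 <= 0) stop("zero pooled variance; t-test undefined")
  tval <- (sa$mean - sb$mean) / sqrt(sp2 * (1 / sa$n + 1 / sb$n))
  .test_result("pooled t-test", tval, df, 2 * stats::pt(-abs(tval), df))
}

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction), with
#' `df = (r - 1)(c - 1)`.
#'
#' @param tab an r x c matrix of counts.
#' @return A `test_result`.
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has a zero marginal")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  .test_result("Pearson chi-square", res$statistic, res$parameter, res$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test: exact enumeration when both groups are small
#' (n <= 20) and the data are tie-free, otherwise the normal approximation
#' with tie correction (no continuity correction, so the two-group case
#' matches the Kruskal-Wallis chi-square exactly).
#'
#' @param a,b numeric vectors of raw values.
#' @return A `test_result` with the U statistic.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both groups must be non-empty")
  ties <- any(duplicated(c(a, b)))
  exact <- length(a) <= 20 && length(b) <= 20 && !ties
  res <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                             correct = FALSE))
  .test_result(if (exact) "Mann-Whitney U (exact)"
               else "Mann-Whitney U (normal approximation)",
               res$statistic, NA, res$p.value)
}

#' Kruskal-Wallis rank test across groups
#'
#' Standard H statistic with tie correction against a chi-square reference
#' with k - 1 degrees of freedom.
#'
#' @param groups list of numeric vectors.
#' @return A `test_result`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2)
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1) stop("all values identical; H undefined")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- stats::kruskal.test(vals, g)
  .test_result("Kruskal-Wallis", res$statistic, res$parameter, res$p.value)
}

#' One-way analysis of variance
#'
#' Classical equal-variance F test, df (k - 1, N - k).
#'
#' @param groups list of numeric vectors, each with n >= 2.
#' @return A `test_result`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- stats::oneway.test(vals ~ g, var.equal = TRUE)
  .test_result("one-way ANOVA", res$statistic, res$parameter, res$p.value)
}

# Shapiro-Wilk normality gate used by the routing rule.
.both_normal <- function(a, b, alpha = 0.05) {
  ok <- function(x) {
    if (length(x) < 3 || length(unique(x)) == 1) return(FALSE)
    stats::shapiro.test(x)$p.value >= alpha
  }
  ok(a) && ok(b)
}

#' Baseline comparison table for a two-group cohort
#'
#' Routes each covariate of a cohort record table to the appropriate
#' between-group test: continuous variables passing a Shapiro-Wilk
#' normality gate (alpha = 0.05) in both groups go to the pooled t-test
#' and are summarised as mean (sd); other continuous variables go to the
#' Mann-Whitney U test and are summarised as median (IQR); categorical
#' variables go to the uncorrected Pearson chi-square on their
#' cross-tabulation. No multiple-testing adjustment is applied.
#'
#' @param records a cohort data.frame as returned by [generate_cohort()]
#'   (must contain a `label` column with both `"good"` and `"poor"`).
#' @param variables covariate columns to compare.
#' @param shapiro_alpha significance level of the normality gate.
#' @return Data.frame with one row per variable: the routed test, group
#'   summaries, test statistic, and p value.
#' @export
table1_report <- function(records,
                          variables = c("age", "sex", "nihss", "onset_bin",
                                        "artery", "toast", "treatment",
                                        "hemorrhagic_transformation"),
                          shapiro_alpha = 0.05) {
  stopifnot(all(c("good", "poor") %in% records$label))
  poor <- records[records$label == "poor", , drop = FALSE]
  good <- records[records$label == "good", , drop = FALSE]
  rows <- lapply(variables, function(v) {
    xp <- poor[[v]]; xg <- good[[v]]
    if (is.numeric(xp)) {
      if (.both_normal(xp, xg, shapiro_alpha)) {
        res <- ttest_pooled(xp, xg)
        sum_p <- sprintf("%.2f ± %.2f", mean(xp), stats::sd(xp))
        sum_g <- sprintf("%.2f ± %.2f", mean(xg), stats::sd(xg))
      } else {
        res <- mann_whitney(xp, xg)
        sum_p <- sprintf("%.1f (%.1f)", stats::median(xp), stats::IQR(xp))
        sum_g <- sprintf("%.1f (%.1f)", stats::median(xg), stats::IQR(xg))
      }
    } else {
      tab <- table(records$label, as.character(records[[v]]))
      res <- chi_square(tab)
      fmt <- function(x) paste(names(table(as.character(x))),
                               table(as.character(x)), sep = ":", collapse = " ")
      sum_p <- fmt(xp); sum_g <- fmt(xg)
    }
    data.frame(variable = v, test = res$test, poor = sum_p, good = sum_g,
               statistic = res$statistic, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' The printed baseline-table fixture
#'
#' Group counts and summary statistics of the reference 92-patient cohort
#' (42 poor / 50 good collateral circulation), as printed: contingency
#' tables for the categorical rows and `(n, mean, sd)` summaries for age.
#' Ships with the package for regression tests of the comparison
#' statistics.
#'
#' @return Named list: `gender`, `onset`, `treatment`, `artery`, `toast`,
#'   `hemorrhage` count matrices (rows poor, good) and `age` summaries.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "baseline_table_counts.json",
                      package = "collat4d")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw$tables, function(tb) {
    m <- as.matrix(tb$counts)  # rows as printed: poor, good
    dimnames(m) <- list(c("poor", "good"), tb$levels)
    m
  })
  out$age <- raw$age
  out
}
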