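# Contingency-table and summary-statistic comparisons for the clinical
# characteristics tables that accompany the imaging cohort (137 cases;
# abortion vs live-birth groups). Pearson chi-square and Fisher's exact
# test are delegated to the stats package; the Welch test is computed from
# summary statistics directly since no base function accepts them.

#' Pearson chi-square test for an r x c contingency table
#'
#' @param counts Matrix of nonnegative integer counts, at least 2x2, with
#'   no all-zero row or column.
#' @return List with `statistic` (Pearson X^2), `df`, `p`, `expected`
#'   (matrix of expected counts) and `low_expected` (`TRUE` when any
#'   expected count is below 5, where the asymptotic p-value is doubtful).
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("`counts` must be at least 2x2", call. = FALSE)
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("`counts` must be nonnegative and finite", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column total: expected counts undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected,
       low_expected = any(ct$expected < 5))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value from the conditional hypergeometric distribution (sum
#' of all tables with probability not exceeding the observed one), plus
#' the sample odds ratio `(a*d)/(b*c)`.
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @return List with `odds_ratio` (sample OR; `Inf` with
#'   `or_unbounded = TRUE` when an off-diagonal cell is zero) and `p`.
#' @export
fisher_exact_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("`counts` must be 2x2", call. = FALSE)
  if (any(counts < 0)) stop("`counts` must be nonnegative", call. = FALSE)
  p <- stats::fisher.test(counts)$p.value
  num <- counts[1, 1] * counts[2, 2]
  den <- counts[1, 2] * counts[2, 1]
  unbounded <- den == 0 && num > 0
  or <- if (den == 0) {
    if (num == 0) NaN else Inf
  } else num / den
  list(odds_ratio = or, p = p, or_unbounded = unbounded)
}

#' Group summary statistic
#'
#' @param mean Group mean.
#' @param sd Group standard deviation (> 0).
#' @param n Group size (>= 2).
#' @return List of class `summary_stat`.
#' @export
summary_stat <- function(mean, sd, n) {
  if (!is.numeric(sd) || sd <= 0) stop("`sd` must be > 0", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("`n` must be >= 2", call. = FALSE)
  structure(list(mean = mean, sd = sd, n = n), class = "summary_stat")
}

#' Welch two-sample t test from summary statistics
#'
#' `t = (mean_a - mean_b) / sqrt(sd_a^2/n_a + sd_b^2/n_b)` with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param a,b [summary_stat()] objects.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_from_summary <- function(a, b) {
  if (!inherits(a, "summary_stat") || !inherits(b, "summary_stat")) {
    stop("`a` and `b` must be summary_stat objects", call. = FALSE)
  }
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Load the packaged clinical tables
#'
#' The cohort characteristic tables are shipped verbatim as CSV files,
#' including their internal count inconsistencies — see
#' [validate_clinical_tables()], which flags rather than repairs them.
#'
#' @return List of data frames: `table1` (cohort characteristics),
#'   `table2` (histology subtypes per tumor group), `table3_counts`
#'   (abortion vs live-birth categorical comparisons with the printed
#'   p-values), `table3_summary` (tumor diameter summaries).
#' @export
load_clinical_tables <- function() {
  rd <- function(f) {
    path <- system.file("extdata", f, package = "ovatex", mustWork = TRUE)
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  list(table1 = rd("table1.csv"), table2 = rd("table2.csv"),
       table3_counts = rd("table3_counts.csv"),
       table3_summary = rd("table3_summary.csv"))
}

#' Validate the clinical table fixtures
#'
#' Cross-checks the shipped tables: every cohort characteristic must
#' partition the 137 cases, subtype counts must sum to their declared
#' group sizes, and the two-group table columns must sum to the group
#' sizes (32 abortion / 105 live birth). Known source inconsistencies are
#' reported in `flags` rather than corrected: the pregnancy-outcome
#' miscarriage count disagrees with the abortion group size, the
#' recomputed GA-of-detection chi-square p-value disagrees with the
#' printed one, and a printed p-value of "0" is interpreted as "< 0.001".
#'
#' @param tables Tables as returned by [load_clinical_tables()].
#' @return List with per-table check data frames (`table1_checks`,
#'   `table2_checks`, `table3_checks`), recomputed test results
#'   (`recomputed`), and a character vector `flags`.
#' @export
validate_clinical_tables <- function(tables = load_clinical_tables()) {
  t1 <- tables$table1
  total_cases <- sum(t1$count[t1$characteristic == t1$characteristic[1]])
  t1_checks <- do.call(rbind, lapply(split(t1, t1$characteristic), function(d) {
    data.frame(characteristic = d$characteristic[1], sum = sum(d$count),
               expected = total_cases, ok = sum(d$count) == total_cases)
  }))
  rownames(t1_checks) <- NULL

  t2 <- tables$table2
  t2_checks <- do.call(rbind, lapply(split(t2, t2$group), function(d) {
    data.frame(group = d$group[1], declared_n = d$group_n[1],
               subtype_sum = sum(d$count), ok = sum(d$count) == d$group_n[1])
  }))
  rownames(t2_checks) <- NULL

  t3 <- tables$table3_counts
  ts <- tables$table3_summary
  n_abortion <- ts$n[ts$group == "abortion"][1]
  n_live <- ts$n[ts$group == "live_birth"][1]
  t3_checks <- do.call(rbind, lapply(split(t3, t3$characteristic), function(d) {
    data.frame(characteristic = d$characteristic[1],
               abortion_sum = sum(d$abortion), live_birth_sum = sum(d$live_birth),
               ok = sum(d$abortion) == n_abortion && sum(d$live_birth) == n_live)
  }))
  rownames(t3_checks) <- NULL

  flags <- character(0)
  miscarriage <- t1$count[t1$characteristic == "Pregnancy outcome" &
                            t1$category == "Miscarriage"]
  if (length(miscarriage) == 1 && miscarriage != n_abortion) {
    flags <- c(flags, sprintf(
      paste0("table1 'Pregnancy outcome' miscarriage count (%d) disagrees ",
             "with the abortion group size (%d) used in table3"),
      miscarriage, n_abortion))
  }

  ga <- t3[t3$characteristic == "GA of detection", ]
  chi <- chi_square_test(cbind(ga$abortion, ga$live_birth))
  printed <- suppressWarnings(as.numeric(ga$p_printed[1]))
  if (is.finite(printed) && abs(chi$p - printed) > 0.005) {
    flags <- c(flags, sprintf(
      paste0("GA-of-detection: recomputed Pearson chi-square p = %.4f ",
             "(X^2 = %.3f, df = %d) differs from the printed p = %s"),
      chi$p, chi$statistic, chi$df, ga$p_printed[1]))
  }

  zero_p <- unique(t3$characteristic[t3$p_printed == "0"])
  for (ch in zero_p) {
    flags <- c(flags, sprintf(
      "'%s' prints p = 0; interpreted as p < 0.001, not an exact value", ch))
  }

  dia <- tables$table3_summary
  w <- welch_t_from_summary(
    summary_stat(dia$mean[1], dia$sd[1], dia$n[1]),
    summary_stat(dia$mean[2], dia$sd[2], dia$n[2]))

  list(table1_checks = t1_checks, table2_checks = t2_checks,
       table3_checks = t3_checks,
       recomputed = list(ga_detection_chi_square = chi,
                         tumor_diameter_welch = w),
       flags = flags)
}
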