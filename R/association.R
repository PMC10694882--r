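#' Case-control genotype contingency table
#'
#' Builds the 2 x 3 group-by-genotype table, rows (asthma, control), columns
#' (AA, AB, BB) in risk orientation.
#'
#' @param case,control `"genotype_counts"` for the asthma and control group at
#'   the same locus.
#' @return A numeric matrix with dimnames.
#' @export
genotype_table <- function(case, control) {
  stopifnot(inherits(case, "genotype_counts"), inherits(control, "genotype_counts"))
  if (case$locus$rs_id != control$locus$rs_id)
    stop("case and control counts are for different loci", call. = FALSE)
  risk <- case$locus$risk_allele
  other <- setdiff(c(case$locus$allele_1, case$locus$allele_2), risk)
  m <- rbind(asthma = count_vector(case), control = count_vector(control))
  colnames(m) <- c(paste0(risk, risk), paste0(risk, other), paste0(other, other))
  m
}

#' Case-control allele contingency table
#'
#' Builds the 2 x 2 group-by-allele table under one of two conventions.
#' `"two_n"` counts chromosomes: each group contributes `2 N_AA + N_AB` copies
#' of the risk allele out of `2 N` total — the statistically standard choice.
#' `"paper_n"` scales allele frequencies by the number of *individuals*
#' (`N_AA + N_AB/2` risk-allele units out of `N`), the convention many
#' published frequency tables implicitly use; its Pearson statistic is exactly
#' half the `two_n` statistic and the cells may be non-integral.
#'
#' @inheritParams genotype_table
#' @param convention `"two_n"` (default) or `"paper_n"`.
#' @return A numeric matrix with dimnames.
#' @export
allele_table <- function(case, control, convention = c("two_n", "paper_n")) {
  convention <- match.arg(convention)
  stopifnot(inherits(case, "genotype_counts"), inherits(control, "genotype_counts"))
  if (case$locus$rs_id != control$locus$rs_id)
    stop("case and control counts are for different loci", call. = FALSE)
  risk <- case$locus$risk_allele
  other <- setdiff(c(case$locus$allele_1, case$locus$allele_2), risk)
  row_of <- function(gc) {
    a <- gc$n_AA + gc$n_AB / 2
    b <- gc$n_BB + gc$n_AB / 2
    if (convention == "two_n") c(2 * a, 2 * b) else c(a, b)
  }
  m <- rbind(asthma = row_of(case), control = row_of(control))
  colnames(m) <- c(risk, other)
  if (any(colSums(m) == 0))
    attr(m, "untestable") <- "monomorphic locus: a zero allele column"
  m
}

#' Pearson chi-square test of independence
#'
#' The classical contingency-table test: statistic
#' \eqn{\sum (O - E)^2 / E} with expected counts from the row/column margins,
#' referred to the upper tail of the chi-square distribution with
#' \eqn{(r-1)(c-1)} degrees of freedom. Counts may be non-integral (the
#' `paper_n` allele convention produces half-integer cells). The Yates
#' continuity correction is available for 2 x 2 tables only.
#'
#' @param table Numeric matrix of counts, at least 2 x 2, all entries >= 0.
#' @param yates Apply the 0.5 continuity correction (2 x 2 tables only).
#' @return An object of class `"assoc_test"`: `statistic`, `df`, `p_value`,
#'   `method`.
#' @examples
#' pearson_chi2(rbind(c(29, 60, 12), c(16, 48, 28)))
#' @export
pearson_chi2 <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  check_table(table)
  if (yates && !all(dim(table) == c(2L, 2L)))
    stop("the Yates correction applies to 2 x 2 tables only", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(table, correct = yates))
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value),
                 method = if (yates) "pearson_yates" else "pearson",
                 expected = res$expected),
            class = "assoc_test")
}

check_table <- function(table) {
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  if (any(table < 0)) stop("negative cell count", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: a zero row or column margin", call. = FALSE)
  invisible(table)
}

#' Fisher exact test for a 2 x 2 table
#'
#' Two-tailed exact test: with the margins fixed, the p-value is the sum of
#' the hypergeometric probabilities of all tables no more probable than the
#' observed one. The `statistic` slot carries the observed table's
#' hypergeometric probability. Requires integer counts — `paper_n`-convention
#' allele tables are rejected with a pointer to the `two_n` convention.
#'
#' @param table 2 x 2 matrix of integer counts.
#' @return An `"assoc_test"` with `method = "fisher"` and `df = NA`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("Fisher exact test requires a 2 x 2 table", call. = FALSE)
  if (max(abs(table - round(table))) > 1e-8)
    stop("Fisher exact test requires integer counts; use the two_n allele ",
         "convention rather than paper_n", call. = FALSE)
  check_table(table)
  table <- round(table)
  res <- stats::fisher.test(table)
  p_obs <- stats::dhyper(table[1, 1], rowSums(table)[1], rowSums(table)[2],
                         colSums(table)[1])
  structure(list(statistic = unname(p_obs), df = NA_integer_,
                 p_value = unname(res$p.value), method = "fisher"),
            class = "assoc_test")
}

#' Automatic test choice for a contingency table
#'
#' The pipeline's selection rule: Fisher exact for 2 x 2 tables with any
#' expected count below 5, otherwise Pearson without continuity correction.
#'
#' @inheritParams pearson_chi2
#' @return An `"assoc_test"`.
#' @export
association_test <- function(table) {
  table <- as.matrix(table)
  check_table(table)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (all(dim(table) == c(2L, 2L)) && any(expected < 5) &&
      max(abs(table - round(table))) <= 1e-8)
    fisher_exact(table)
  else
    pearson_chi2(table)
}

#' @export
print.assoc_test <- function(x, ...) {
  if (x$method == "fisher")
    cat(sprintf("Fisher exact test: P = %.3g (observed-table probability %.3g)\n",
                x$p_value, x$statistic))
  else
    cat(sprintf("Pearson chi-square%s: X2 = %.4g, df = %d, P = %.3g\n",
                if (x$method == "pearson_yates") " (Yates)" else "",
                x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Odds ratio with Woolf confidence interval
#'
#' For a 2 x 2 table with case row (a, b) and control row (c, d), where the
#' first column is the exposed category, OR = (a d)/(b c) and the Woolf
#' interval is
#' \deqn{\exp(\ln OR \pm z_{1-\alpha/2} \sqrt{1/a + 1/b + 1/c + 1/d}).}
#' All four cells must be positive; with a zero cell the Haldane–Anscombe
#' correction (add 0.5 to every cell) can be requested explicitly.
#'
#' @param table 2 x 2 matrix: rows (case, control), columns
#'   (exposed, unexposed).
#' @param alpha Significance level for the `1 - alpha` interval.
#' @param haldane Add 0.5 to every cell (required when a cell is zero).
#' @return A list with `odds_ratio`, `ci_low`, `ci_high`, `alpha`.
#' @examples
#' odds_ratio_ci(rbind(c(45, 56), c(22, 70)))  # OR 2.56, CI 1.38-4.75
#' @export
odds_ratio_ci <- function(table, alpha = 0.05, haldane = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("odds ratio requires a 2 x 2 table", call. = FALSE)
  if (any(table < 0)) stop("negative cell count", call. = FALSE)
  if (any(table == 0) && !haldane)
    stop("zero cell: the Woolf interval is undefined; re-run with ",
         "haldane = TRUE to apply the +0.5 correction", call. = FALSE)
  if (haldane) table <- table + 0.5
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - alpha / 2)
  half <- z * sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(odds_ratio = or,
       ci_low = exp(log(or) - half),
       ci_high = exp(log(or) + half),
       alpha = alpha)
}

#' Summary statistics for a measured variable
#'
#' @param mean,sd,n Group mean, standard deviation and size.
#' @return A `"summary_stats"` list.
#' @export
summary_stats <- function(mean, sd, n) {
  stopifnot(sd >= 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "summary_stats")
}

#' Two-sample t test from summary statistics
#'
#' Student's t test computed from per-group mean, SD and n (published tables
#' report only these). The `pooled` variant uses the pooled variance
#' estimator with `n1 + n2 - 2` degrees of freedom; `welch` uses the
#' Satterthwaite approximation.
#'
#' @param a,b `"summary_stats"` for the two groups.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A list with `statistic`, `df`, `p_value`, `method`.
#' @examples
#' t_test_from_summary(summary_stats(6.48, 2.38, 101),
#'                     summary_stats(5.74, 3.70, 92))
#' @export
t_test_from_summary <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  if (a$sd <= 0 || b$sd <= 0) stop("summary SDs must be positive", call. = FALSE)
  if (variant == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- (a$mean - b$mean) / se
  list(statistic = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df),
       method = paste0(variant, "_t"))
}

#' Mann-Whitney rank-sum test (normal approximation)
#'
#' Utility counterpart to the t test for non-normal measurements: the
#' two-sample Wilcoxon rank-sum test with normal approximation and continuity
#' correction, on raw values.
#'
#' @param x,y Numeric vectors of raw measurements.
#' @return A list with `statistic` (W), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y) {
  res <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  list(statistic = unname(res$statistic), p_value = res$p.value,
       method = "rank_sum_normal_approx")
}
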