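#' Run the full case-control analysis
#'
#' Executes the whole pipeline on a cohort: demographics (sex chi-square and
#' age t test), per-locus genotype and allele association, risk
#' classification and the high/low-risk distribution comparison, and
#' assembles the four standard report tables plus a methods log that records
#' which test ran where.
#'
#' `paper_compat = TRUE` bundles the settings that reproduce published
#' summary statistics bit-for-bit: the `paper_n` allele-table convention
#' (allele frequencies scaled by individuals rather than chromosomes), the
#' fixed risk model, the pooled t test and no continuity correction. The
#' defaults are the statistically conventional choices (`two_n` chromosome
#' counting).
#'
#' @param x A `"cohort"`, or a path passed to [read_cohort()].
#' @param convention Allele-table convention, `"two_n"` or `"paper_n"`.
#' @param alpha Two-tailed significance level.
#' @param model `"fixed"` (the shipped classifier) or `"derive"` (re-derive
#'   from this cohort), or a `"risk_model"` object.
#' @param paper_compat Bundle the compatibility settings described above.
#' @param format,group_map Passed to [read_cohort()] when `x` is a path.
#' @return An object of class `"analysis_report"`.
#' @examples
#' rep <- run_analysis(fixture_cohort("han"), paper_compat = TRUE)
#' rep$loci$rs1042713$genotype_test$statistic  # 11.09
#' @export
run_analysis <- function(x, convention = c("two_n", "paper_n"), alpha = 0.05,
                         model = "fixed", paper_compat = FALSE,
                         format = "guess", group_map = NULL) {
  if (is.character(x))
    x <- read_cohort(x, format = format, group_map = group_map)
  stopifnot(inherits(x, "cohort"), alpha > 0, alpha < 1)
  if (paper_compat) convention <- "paper_n" else convention <- match.arg(convention)
  if (nrow(x) == 0L) stop("empty cohort", call. = FALSE)
  if (length(unique(x$group)) < 2L)
    stop("cohort must contain both an asthma and a control group", call. = FALSE)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  note("allele-table convention: %s", convention)
  note("alpha: %g (two-tailed)", alpha)

  ## demographics block
  demo <- demographics_block(x)
  note("sex comparison: %s", demo$sex_test$method)
  note("age comparison: %s", demo$age_test$method)

  ## per-locus association blocks
  loci_blocks <- list()
  for (rs in names(asthma_loci())) {
    case <- genotype_counts(x, "asthma", rs)
    ctrl <- genotype_counts(x, "control", rs)
    gt_tab <- genotype_table(case, ctrl)
    gt_test <- association_test(gt_tab)
    al_tab <- allele_table(case, ctrl, convention = convention)
    al_test <- if (is.null(attr(al_tab, "untestable")))
      association_test(al_tab) else NULL
    note("%s genotype test: %s; allele test: %s", rs, gt_test$method,
         if (is.null(al_test)) "untestable (monomorphic)" else al_test$method)
    loci_blocks[[rs]] <- list(
      locus = get_locus(rs),
      counts = list(asthma = case, control = ctrl),
      genotype_freq = list(asthma = genotype_frequencies(case),
                           control = genotype_frequencies(ctrl)),
      allele_freq = list(asthma = allele_frequencies(case),
                         control = allele_frequencies(ctrl)),
      genotype_table = gt_tab, genotype_test = gt_test,
      allele_table = al_tab, allele_test = al_test)
  }

  ## risk block
  if (inherits(model, "risk_model")) {
    risk_model <- model
  } else if (identical(model, "derive")) {
    risk_model <- derive_model(x, alpha = alpha)
  } else if (identical(model, "fixed")) {
    risk_model <- fixed_risk_model()
  } else stop("model must be 'fixed', 'derive' or a risk_model", call. = FALSE)
  risk <- risk_distribution_test(x, risk_model, alpha = alpha)
  note("risk model: %s; risk distribution test: %s",
       attr(risk_model, "provenance"), risk$test$method)

  structure(list(cohort_name = attr(x, "name"),
                 n = c(asthma = sum(x$group == "asthma"),
                       control = sum(x$group == "control")),
                 convention = convention, alpha = alpha,
                 demographics = demo, loci = loci_blocks,
                 risk_model = risk_model, risk = risk,
                 methods_log = log),
            class = "analysis_report")
}

demographics_block <- function(x) {
  sex_tab <- table(group = x$group, sex = factor(x$sex,
                                                 levels = c("male", "female")))
  sex_tab <- unclass(sex_tab[c("asthma", "control"), , drop = FALSE])
  sex_test <- tryCatch(pearson_chi2(sex_tab),
                       error = function(e) NULL)
  age_stats <- lapply(c(asthma = "asthma", control = "control"), function(g) {
    a <- x$age[x$group == g & !is.na(x$age)]
    if (length(a) >= 2 && stats::sd(a) > 0)
      summary_stats(mean(a), stats::sd(a), length(a)) else NULL
  })
  age_test <- if (!is.null(age_stats$asthma) && !is.null(age_stats$control))
    t_test_from_summary(age_stats$asthma, age_stats$control, "pooled")
  else list(statistic = NA, df = NA, p_value = NA, method = "not computed")
  list(sex_table = sex_tab, sex_test = sex_test,
       age = age_stats, age_test = age_test)
}

#' @export
print.analysis_report <- function(x, digits = 3, ...) {
  cat(sprintf("Four-locus asthma risk analysis: %s (n = %d asthma / %d control)\n",
              x$cohort_name, x$n[["asthma"]], x$n[["control"]]))
  cat(strrep("-", 72), "\n")
  cat("Demographics\n")
  print(x$demographics$sex_table)
  if (!is.null(x$demographics$sex_test))
    cat(sprintf("  sex: X2 = %.2f, P = %.3f\n",
                x$demographics$sex_test$statistic,
                x$demographics$sex_test$p_value))
  for (g in c("asthma", "control")) {
    s <- x$demographics$age[[g]]
    if (!is.null(s))
      cat(sprintf("  age %s: %.2f +/- %.2f (n = %d)\n", g, s$mean, s$sd, s$n))
  }
  if (!is.na(x$demographics$age_test$p_value))
    cat(sprintf("  age: t = %.2f, P = %.3f\n",
                x$demographics$age_test$statistic,
                x$demographics$age_test$p_value))
  cat(strrep("-", 72), "\n")
  for (rs in names(x$loci)) {
    b <- x$loci[[rs]]
    cat(sprintf("%s %s  (genotypes %s)\n", b$locus$gene, rs,
                paste(colnames(b$genotype_table), collapse = "/")))
    for (g in c("asthma", "control"))
      cat(sprintf("  %-8s %s\n", g, paste(b$genotype_freq[[g]]$percent,
                                          collapse = "  ")))
    cat(sprintf("  genotype: X2 = %.2f, P = %.3f [%s]\n",
                b$genotype_test$statistic, b$genotype_test$p_value,
                b$genotype_test$method))
    for (g in c("asthma", "control"))
      cat(sprintf("  %-8s allele %s/%s: %s\n", g,
                  b$locus$risk_allele,
                  setdiff(c(b$locus$allele_1, b$locus$allele_2),
                          b$locus$risk_allele),
                  paste(b$allele_freq[[g]]$percent, collapse = "  ")))
    if (!is.null(b$allele_test))
      cat(sprintf("  allele:   X2 = %.2f, P = %.3f [%s]\n",
                  b$allele_test$statistic, b$allele_test$p_value,
                  b$allele_test$method))
  }
  cat(strrep("-", 72), "\n")
  cat(sprintf("Risk-genotype distribution (%s model)\n",
              attr(x$risk_model, "provenance")))
  print(x$risk$table)
  cat(sprintf("  X2 = %.2f, P = %.3f; OR = %.2f (95%% CI %.2f-%.2f)\n",
              x$risk$test$statistic, x$risk$test$p_value,
              x$risk$or$odds_ratio, x$risk$or$ci_low, x$risk$or$ci_high))
  invisible(x)
}

#' Serialize an analysis report or risk model to JSON
#'
#' Reports serialize deterministically: the same cohort and configuration
#' give byte-identical JSON.
#'
#' @param x An `"analysis_report"` or `"risk_model"`.
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(x, path = NULL) {
  payload <- if (inherits(x, "analysis_report")) report_payload(x)
             else if (inherits(x, "risk_model")) model_payload(x)
             else stop("x must be an analysis_report or risk_model", call. = FALSE)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

test_payload <- function(t) {
  if (is.null(t)) return(NULL)
  list(method = t$method, statistic = t$statistic,
       df = if (is.na(t$df)) NULL else t$df, p_value = t$p_value)
}

report_payload <- function(x) {
  loci <- lapply(x$loci, function(b) {
    list(gene = b$locus$gene, rs_id = b$locus$rs_id,
         genotype_counts = lapply(b$counts, count_vector),
         genotype_freq = lapply(b$genotype_freq, function(f)
           c(f$freq_AA, f$freq_AB, f$freq_BB)),
         allele_freq = lapply(b$allele_freq, function(f) c(f$freq_A, f$freq_B)),
         genotype_test = test_payload(b$genotype_test),
         allele_table = unname(apply(b$allele_table, 1L, c, simplify = FALSE)),
         allele_test = test_payload(b$allele_test))
  })
  list(cohort = x$cohort_name, n = as.list(x$n), convention = x$convention,
       alpha = x$alpha,
       demographics = list(
         sex_table = unname(apply(x$demographics$sex_table, 1L, c,
                                  simplify = FALSE)),
         sex_test = test_payload(x$demographics$sex_test),
         age = lapply(x$demographics$age, function(s)
           if (is.null(s)) NULL else list(mean = s$mean, sd = s$sd, n = s$n)),
         age_test = test_payload(x$demographics$age_test)),
       loci = loci,
       risk = list(model = model_payload(x$risk_model),
                   table = unname(apply(x$risk$table, 1L, c, simplify = FALSE)),
                   test = test_payload(x$risk$test),
                   odds_ratio = x$risk$or$odds_ratio,
                   ci = c(x$risk$or$ci_low, x$risk$or$ci_high)),
       methods_log = x$methods_log)
}

model_payload <- function(m) {
  df <- as.data.frame(m)
  entries <- lapply(seq_len(nrow(df)), function(i) {
    e <- list(profile = profile_key(df[i, PROFILE_LOCI]),
              class = df$class[i])
    if ("observed" %in% names(df)) {
      e$observed <- df$observed[i]
      e$n_asthma <- df$n_asthma[i]
      e$n_control <- df$n_control[i]
      if (!is.na(df$p_value[i])) {
        e$odds_ratio <- df$odds_ratio[i]
        e$p_value <- df$p_value[i]
        e$method <- df$method[i]
      }
    }
    e
  })
  list(provenance = attr(m, "provenance"),
       alpha = if (is.na(attr(m, "alpha"))) NULL else attr(m, "alpha"),
       combinations = entries)
}
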