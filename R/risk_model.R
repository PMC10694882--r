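# Locus order used for risk profiles throughout: IL13 rs20541, IL4 rs2243250,
# ADRB2 rs1042713, FCER1B rs569108 (the order the model tables list them in).
PROFILE_LOCI <- c("rs20541", "rs2243250", "rs1042713", "rs569108")

#' Risk-homozygosity profile of a sample
#'
#' A sample's risk profile is one boolean per locus: whether the child is
#' homozygous for that locus's risk allele (IL13 GG, IL4 TT, ADRB2 AA,
#' FCER1B GG). There are 2^4 = 16 possible profiles; the all-false profile
#' ("no risk homozygotes") is the model's reference combination.
#'
#' @param sample One cohort row (a list or one-row data frame with the four
#'   genotype columns).
#' @return Named logical vector of length 4 (names `rs20541`, `rs2243250`,
#'   `rs1042713`, `rs569108`).
#' @export
risk_profile <- function(sample) {
  gts <- vapply(PROFILE_LOCI, function(rs) as.character(sample[[rs]]),
                character(1))
  if (anyNA(gts))
    stop("sample has a missing genotype and cannot be risk-classified",
         call. = FALSE)
  out <- vapply(PROFILE_LOCI, function(rs) {
    gts[[rs]] == risk_homozygote(get_locus(rs))
  }, logical(1))
  names(out) <- PROFILE_LOCI
  out
}

# The fixed high/low partition of the 16 risk-homozygosity combinations,
# enumerated literally: columns flag the risk homozygote at IL13, IL4, ADRB2,
# FCER1B. Low: the reference, every single homozygote, and the pairs
# {ADRB2, FCER1B} and {IL13, FCER1B}. High: the remaining four pairs, every
# triple, and the full combination.
fixed_partition <- function() {
  rows <- rbind(
    # low-risk combinations
    c(0, 0, 0, 0), # reference: no risk homozygotes
    c(0, 0, 0, 1), # FCER1B only
    c(0, 0, 1, 0), # ADRB2 only
    c(0, 1, 0, 0), # IL4 only
    c(1, 0, 0, 0), # IL13 only
    c(0, 0, 1, 1), # ADRB2 + FCER1B
    c(1, 0, 0, 1), # IL13 + FCER1B
    # high-risk combinations
    c(0, 1, 0, 1), # IL4 + FCER1B
    c(0, 1, 1, 0), # IL4 + ADRB2
    c(1, 0, 1, 0), # IL13 + ADRB2
    c(1, 1, 0, 0), # IL13 + IL4
    c(0, 1, 1, 1), # IL4 + ADRB2 + FCER1B
    c(1, 0, 1, 1), # IL13 + ADRB2 + FCER1B
    c(1, 1, 0, 1), # IL13 + IL4 + FCER1B
    c(1, 1, 1, 0), # IL13 + IL4 + ADRB2
    c(1, 1, 1, 1)) # all four
  df <- as.data.frame(rows == 1)
  names(df) <- PROFILE_LOCI
  df$class <- rep(c("low", "high"), c(7L, 9L))
  df
}

# vectorized risk profiles for a data frame of canonical genotype columns
profile_matrix <- function(df) {
  out <- vapply(PROFILE_LOCI, function(rs)
    df[[rs]] == risk_homozygote(get_locus(rs)), logical(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1L,
                                    dimnames = list(NULL, PROFILE_LOCI))
  out
}

profile_key <- function(profiles) {
  profiles <- as.matrix(profiles)
  apply(profiles, 1L, function(p) paste(as.integer(p), collapse = ""))
}

#' Classify risk profiles with the fixed model
#'
#' Looks each profile up in the fixed 16-combination partition.
#'
#' @param profile A logical vector of length 4 in profile order (IL13, IL4,
#'   ADRB2, FCER1B), or a logical matrix/data frame with one profile per row.
#' @return Character vector of `"high"`/`"low"`, one per profile.
#' @examples
#' classify_fixed(c(FALSE, FALSE, FALSE, FALSE))  # reference -> low
#' classify_fixed(c(TRUE, TRUE, TRUE, TRUE))      # all four -> high
#' @export
classify_fixed <- function(profile) {
  if (is.null(dim(profile))) profile <- matrix(profile, nrow = 1L)
  stopifnot(ncol(profile) == 4L)
  part <- fixed_partition()
  part$class[match(profile_key(profile), profile_key(part[PROFILE_LOCI]))]
}

#' The fixed four-locus risk model
#'
#' The canonical classifier shipped with the package: the fixed partition of
#' the 16 risk-homozygosity combinations, previously derived on an
#' independent Han cohort.
#'
#' @return An object of class `"risk_model"`: a data frame with one row per
#'   combination (logical columns `rs20541`, `rs2243250`, `rs1042713`,
#'   `rs569108`, plus `class`) and attributes `provenance = "fixed"` and
#'   `alpha = NA`.
#' @export
fixed_risk_model <- function() {
  structure(fixed_partition(), provenance = "fixed", alpha = NA_real_,
            class = c("risk_model", "data.frame"))
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> provenance: %s; %d/16 combinations high-risk\n",
              attr(x, "provenance"), sum(x$class == "high")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Derive a risk model from a case-control cohort
#'
#' Reproduces the construction rule of the fixed model on data: every
#' combination of risk-allele homozygotes is compared with the reference
#' combination (no risk homozygotes) in a 2 x 2 group-by-combination table;
#' a combination is classed high-risk when P < `alpha` and OR > 1 (strict
#' inequalities; ties are low). Fisher's exact test is used when any expected
#' count is below 5, Pearson's chi-square otherwise — combinations are sparse
#' by construction. No multiple-testing adjustment is applied. Combinations
#' with no carriers in the cohort cannot be tested; they inherit the fixed
#' model's class and are flagged `observed = FALSE` so the classifier stays
#' total.
#'
#' @param x A `"cohort"` containing both groups; samples with any missing
#'   genotype are excluded. The reference combination must be present in both
#'   groups.
#' @param alpha Significance level of the rule.
#' @return A `"risk_model"` whose rows additionally carry `n_asthma`,
#'   `n_control`, `odds_ratio`, `p_value`, `method` and `observed`.
#' @export
derive_model <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "cohort"), alpha > 0, alpha < 1)
  complete <- stats::complete.cases(as.data.frame(x)[, PROFILE_LOCI])
  df <- as.data.frame(x)[complete, ]
  keys <- profile_key(profile_matrix(df))
  model <- fixed_risk_model()
  model_keys <- profile_key(model[PROFILE_LOCI])
  tab <- table(factor(keys, levels = model_keys), df$group)
  n_case <- as.integer(tab[, "asthma"])
  n_ctrl <- as.integer(tab[, "control"])

  ref_row <- match(paste(rep(0L, 4L), collapse = ""), model_keys)
  if (n_case[ref_row] == 0L || n_ctrl[ref_row] == 0L)
    stop("reference combination (no risk homozygotes) absent from one group; ",
         "cannot derive a model", call. = FALSE)

  model$n_asthma <- n_case
  model$n_control <- n_ctrl
  model$odds_ratio <- NA_real_
  model$p_value <- NA_real_
  model$method <- NA_character_
  model$observed <- n_case + n_ctrl > 0L
  model$class[ref_row] <- "low"  # reference is low by definition

  for (i in setdiff(which(model$observed), ref_row)) {
    t22 <- rbind(asthma  = c(n_case[i], n_case[ref_row]),
                 control = c(n_ctrl[i], n_ctrl[ref_row]))
    res <- association_test(t22)
    or <- (t22[1, 1] * t22[2, 2]) / (t22[1, 2] * t22[2, 1])  # may be 0 or Inf
    model$odds_ratio[i] <- or
    model$p_value[i] <- res$p_value
    model$method[i] <- res$method
    model$class[i] <- if (res$p_value < alpha && !is.nan(or) && or > 1)
      "high" else "low"
  }
  # unobserved combinations keep the fixed class (model stays total)
  attr(model, "provenance") <- "derived"
  attr(model, "alpha") <- alpha
  model
}

#' Classify every sample of a cohort
#'
#' @param x A `"cohort"`.
#' @param model A `"risk_model"` (default: the fixed model).
#' @return Factor (`high`/`low`) of length `nrow(x)`; `NA` for samples with
#'   any missing genotype.
#' @export
classify_cohort <- function(x, model = fixed_risk_model()) {
  stopifnot(inherits(x, "cohort"), inherits(model, "risk_model"))
  df <- as.data.frame(x)
  out <- rep(NA_character_, nrow(df))
  complete <- stats::complete.cases(df[, PROFILE_LOCI])
  if (any(complete)) {
    keys <- profile_key(profile_matrix(df[complete, , drop = FALSE]))
    out[complete] <- model$class[match(keys, profile_key(model[PROFILE_LOCI]))]
  }
  factor(out, levels = c("high", "low"))
}

#' Compare the risk-class distribution between groups
#'
#' Counts classifiable samples per (group x risk class), tests independence
#' with Pearson's chi-square (no continuity correction) and reports the odds
#' ratio of asthma for the high-risk class with its Woolf 95% CI.
#'
#' @inheritParams classify_cohort
#' @param alpha Significance level for the confidence interval.
#' @return A list with `table` (2 x 2: rows asthma/control, columns
#'   high/low), `test` (an `"assoc_test"`) and `or` (from
#'   [odds_ratio_ci()]).
#' @export
risk_distribution_test <- function(x, model = fixed_risk_model(),
                                   alpha = 0.05) {
  cls <- classify_cohort(x, model)
  keep <- !is.na(cls)
  if (!any(keep & x$group == "asthma") || !any(keep & x$group == "control"))
    stop("need at least one classifiable sample per group", call. = FALSE)
  tab <- table(group = x$group[keep], class = cls[keep])
  tab <- unclass(tab[c("asthma", "control"), c("high", "low")])
  check_table(tab)
  list(table = tab,
       test = pearson_chi2(tab),
       or = odds_ratio_ci(tab, alpha = alpha))
}
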