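#' Bundled Han and Kazak cohort summary tables
#'
#' The package ships the summary data of the two Xinjiang case-control
#' cohorts on which the four-locus model was evaluated: per-group genotype
#' percentage distributions at the four SNPs, group sizes, demographic
#' summaries (sex counts and age mean +/- SD) and the high/low risk-genotype
#' counts. Genotype percentages are stored in risk orientation (risk
#' homozygote, heterozygote, non-risk homozygote).
#'
#' Group sizes: Han 101 asthma / 92 control; Kazak 80 asthma / 93 control.
#'
#' @param nationality `"han"` or `"kazak"`.
#' @return A list with elements `nationality`, `n` (named asthma/control),
#'   `genotype_pct` (data frame: group, rs_id, pct_AA, pct_AB, pct_BB),
#'   `demographics` (per group: male, female, age_mean, age_sd),
#'   `risk_counts` (2 x 2 matrix, rows asthma/control, columns high/low).
#' @examples
#' reference_tables("han")$n
#' @export
reference_tables <- function(nationality = c("han", "kazak")) {
  nationality <- match.arg(nationality)
  if (nationality == "han") {
    n <- c(asthma = 101L, control = 92L)
    pct <- rbind(
      c("asthma",  "rs1042713", 28.71, 59.41, 11.88),
      c("control", "rs1042713", 17.39, 52.17, 30.43),
      c("asthma",  "rs2243250", 70.30, 25.74,  3.96),
      c("control", "rs2243250", 50.00, 38.04, 11.96),
      c("asthma",  "rs569108",   4.95, 27.72, 67.33),
      c("control", "rs569108",   2.17, 21.74, 76.09),
      c("asthma",  "rs20541",   39.61, 48.51, 11.88),
      c("control", "rs20541",   20.65, 47.83, 31.52))
    demo <- list(asthma  = list(male = 66L, female = 35L,
                                age_mean = 6.48, age_sd = 2.38),
                 control = list(male = 48L, female = 44L,
                                age_mean = 5.74, age_sd = 3.70))
    risk <- rbind(asthma = c(high = 45L, low = 56L),
                  control = c(high = 22L, low = 70L))
  } else {
    n <- c(asthma = 80L, control = 93L)
    pct <- rbind(
      c("asthma",  "rs1042713", 21.25, 43.75, 35.00),
      c("control", "rs1042713", 17.20, 41.94, 40.86),
      c("asthma",  "rs2243250", 22.50, 55.00, 22.50),
      c("control", "rs2243250", 31.18, 51.61, 17.21),
      c("asthma",  "rs569108",   2.50, 16.25, 81.25),
      c("control", "rs569108",   1.07, 11.83, 87.10),
      c("asthma",  "rs20541",   45.00, 43.75, 11.25),
      c("control", "rs20541",   33.34, 53.76, 12.90))
    demo <- list(asthma  = list(male = 48L, female = 32L,
                                age_mean = 4.89, age_sd = 3.63),
                 control = list(male = 55L, female = 38L,
                                age_mean = 4.98, age_sd = 3.37))
    risk <- rbind(asthma = c(high = 15L, low = 65L),
                  control = c(high = 16L, low = 77L))
  }
  genotype_pct <- data.frame(group = pct[, 1], rs_id = pct[, 2],
                             pct_AA = as.numeric(pct[, 3]),
                             pct_AB = as.numeric(pct[, 4]),
                             pct_BB = as.numeric(pct[, 5]),
                             stringsAsFactors = FALSE)
  list(nationality = nationality, n = n, genotype_pct = genotype_pct,
       demographics = demo, risk_counts = risk)
}

#' Reconstructed integer genotype counts for a bundled cohort
#'
#' Applies [reconstruct_counts()] to every genotype percentage row of the
#' bundled summary tables. For both cohorts every row reconstructs to counts
#' summing exactly to the group size.
#'
#' @inheritParams reference_tables
#' @return Nested list: `$asthma` and `$control`, each a named list of
#'   `"genotype_counts"` per rs identifier (risk orientation).
#' @examples
#' count_vector <- function(gc) c(gc$n_AA, gc$n_AB, gc$n_BB)
#' reference_counts("han")$asthma$rs1042713  # 29 / 60 / 12
#' @export
reference_counts <- function(nationality = c("han", "kazak")) {
  ref <- reference_tables(match.arg(nationality))
  out <- list()
  for (grp in c("asthma", "control")) {
    rows <- ref$genotype_pct[ref$genotype_pct$group == grp, ]
    out[[grp]] <- lapply(stats::setNames(seq_len(nrow(rows)), rows$rs_id),
                         function(i) {
      as_genotype_counts(
        reconstruct_counts(as.numeric(rows[i, c("pct_AA", "pct_AB", "pct_BB")]),
                           ref$n[[grp]]),
        rows$rs_id[i])
    })
  }
  out
}

#' Deterministic fixture cohort for a bundled summary table
#'
#' Expands the reconstructed integer counts into an explicit per-child
#' cohort. The published data are summaries only — per-locus marginal counts
#' plus the high/low risk-class totals — so the per-child genotype
#' combinations are not determined by them. The fixture assigns genotypes so
#' that (a) every per-locus, per-group genotype count equals the
#' reconstructed count exactly, and (b) the number of high-risk children per
#' group under the fixed classifier equals the bundled risk-class count
#' exactly. Within those constraints the joint arrangement is found by a
#' seeded local search and is fully deterministic; it is one of many
#' arrangements consistent with the summaries, not the study's actual
#' per-child data. Sexes are assigned in block order to match the
#' demographic counts and ages are spread over deterministic normal quantiles
#' of the reported age distribution (truncated to 0-14 years).
#'
#' @inheritParams reference_tables
#' @return A `"cohort"`.
#' @export
fixture_cohort <- function(nationality = c("han", "kazak")) {
  nationality <- match.arg(nationality)
  ref <- reference_tables(nationality)
  counts <- reference_counts(nationality)
  loci <- asthma_loci()
  model <- fixed_risk_model()

  build_group <- function(grp) {
    n <- ref$n[[grp]]
    hom <- vapply(names(loci), function(rs) counts[[grp]][[rs]]$n_AA, integer(1))
    hom_mat <- arrange_risk_homozygotes(n, hom, ref$risk_counts[grp, "high"],
                                        model)
    df <- data.frame(sample_id = sprintf("%s_%s_%03d", nationality,
                                         substr(grp, 1, 4), seq_len(n)),
                     group = grp, stringsAsFactors = FALSE)
    demo <- ref$demographics[[grp]]
    df$sex <- rep(c("male", "female"), times = c(demo$male, demo$female))
    ages <- stats::qnorm((seq_len(n) - 0.5) / n, demo$age_mean, demo$age_sd)
    df$age <- round(pmin(pmax(ages, 0), 14), 2)
    for (rs in names(loci)) {
      loc <- loci[[rs]]
      other <- setdiff(c(loc$allele_1, loc$allele_2), loc$risk_allele)
      gt <- character(n)
      gt[hom_mat[, rs]] <- risk_homozygote(loc)
      rest <- which(!hom_mat[, rs])
      n_het <- counts[[grp]][[rs]]$n_AB
      gt[rest[seq_len(n_het)]] <- paste0(loc$allele_1, loc$allele_2)
      gt[rest[-seq_len(n_het)]] <- paste0(other, other)
      df[[rs]] <- gt
    }
    df
  }

  cohort(rbind(build_group("asthma"), build_group("control")),
         name = nationality)
}

# Find an n x 4 logical matrix (columns = loci) with given column sums whose
# number of high-risk rows under `model` equals `high_target`. Starts from a
# block assignment and runs a seeded swap search (sideways moves allowed so
# plateaus can be crossed); deterministic for fixed inputs.
arrange_risk_homozygotes <- function(n, hom_counts, high_target, model,
                                     max_iter = 50000L) {
  loci_ids <- names(asthma_loci())
  m <- matrix(FALSE, n, 4L, dimnames = list(NULL, loci_ids))
  for (j in seq_len(4L)) m[seq_len(hom_counts[j]), j] <- TRUE

  high_count <- function(mm) sum(classify_fixed(mm) == "high")
  cur <- high_count(m)
  if (cur == high_target) return(m)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(20120541L)
  for (iter in seq_len(max_iter)) {
    j <- sample.int(4L, 1L)
    from <- which(m[, j]); to <- which(!m[, j])
    if (length(from) == 0L || length(to) == 0L) next
    i1 <- from[sample.int(length(from), 1L)]
    i2 <- to[sample.int(length(to), 1L)]
    m2 <- m
    m2[i1, j] <- FALSE; m2[i2, j] <- TRUE
    delta <- sum(classify_fixed(m2[c(i1, i2), , drop = FALSE]) == "high") -
      sum(classify_fixed(m[c(i1, i2), , drop = FALSE]) == "high")
    cand <- cur + delta
    if (abs(cand - high_target) <= abs(cur - high_target)) {
      m <- m2; cur <- cand
      if (cur == high_target) return(m)
    }
  }
  stop(sprintf("could not arrange %d high-risk rows (reached %d of target %d)",
               n, cur, high_target), call. = FALSE)
}
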