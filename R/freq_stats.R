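#' Genotype counts at one locus, in risk-allele orientation
#'
#' Counts the three genotypes among the non-missing calls of one group at one
#' locus. Orientation is fixed so that allele "A" is the locus risk allele:
#' `n_AA` is the risk-homozygote count, `n_AB` the heterozygote count and
#' `n_BB` the non-risk homozygote count. Samples with a missing call at the
#' locus are excluded.
#'
#' @param x A `"cohort"`.
#' @param group `"asthma"` or `"control"`.
#' @param locus A `"locus"` object or an rs identifier.
#' @return An object of class `"genotype_counts"`.
#' @export
genotype_counts <- function(x, group = c("asthma", "control"), locus) {
  stopifnot(inherits(x, "cohort"))
  group <- match.arg(group)
  if (is.character(locus)) locus <- get_locus(locus)
  calls <- x[[locus$rs_id]][x$group == group]
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0L)
    stop(sprintf("no non-missing %s genotypes in the %s group",
                 locus$rs_id, group), call. = FALSE)
  risk <- locus$risk_allele
  other <- setdiff(c(locus$allele_1, locus$allele_2), risk)
  het <- paste0(locus$allele_1, locus$allele_2)  # canonical heterozygote
  as_genotype_counts(c(sum(calls == paste0(risk, risk)),
                       sum(calls == het),
                       sum(calls == paste0(other, other))),
                     locus)
}

#' @rdname genotype_counts
#' @param counts Length-3 integer vector `(n_AA, n_AB, n_BB)` in risk
#'   orientation, e.g. reconstructed from a printed table with
#'   [reconstruct_counts()].
#' @export
as_genotype_counts <- function(counts, locus) {
  if (is.character(locus)) locus <- get_locus(locus)
  stopifnot(inherits(locus, "locus"), length(counts) == 3L, all(counts >= 0))
  structure(list(locus = locus,
                 n_AA = as.integer(counts[1]),
                 n_AB = as.integer(counts[2]),
                 n_BB = as.integer(counts[3])),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  risk <- x$locus$risk_allele
  other <- setdiff(c(x$locus$allele_1, x$locus$allele_2), risk)
  cat(sprintf("<genotype_counts> %s %s: %s%s=%d %s%s=%d %s%s=%d (N=%d)\n",
              x$locus$gene, x$locus$rs_id,
              risk, risk, x$n_AA, risk, other, x$n_AB, other, other, x$n_BB,
              x$n_AA + x$n_AB + x$n_BB))
  invisible(x)
}

count_vector <- function(gc) c(gc$n_AA, gc$n_AB, gc$n_BB)

# 2-dp percentage string, rounding half away from zero as published
# frequency tables do (e.g. 0.43125 -> "43.13%", not the IEEE "43.12%")
format_percent <- function(p) {
  sprintf("%.2f%%", floor(p * 10000 + 0.5 + 1e-9) / 100)
}

#' Gene-counting allele frequencies
#'
#' Direct allele-frequency estimation from genotype counts: with genotype
#' counts N_AA, N_AB, N_BB and N their total,
#' \deqn{A = (N_{AA} + N_{AB}/2) / N, \qquad B = (N_{BB} + N_{AB}/2) / N.}
#' "A" is the risk allele under the package's risk orientation.
#'
#' @param counts A `"genotype_counts"` object.
#' @return A list with `locus`, `freq_A`, `freq_B` (proportions), `n`
#'   (individuals) and `percent` (2-dp percentage strings, as frequency
#'   tables print them).
#' @examples
#' allele_frequencies(as_genotype_counts(c(29, 60, 12), "rs1042713"))
#' @export
allele_frequencies <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  n <- counts$n_AA + counts$n_AB + counts$n_BB
  if (n == 0L) stop("empty group: no genotypes at locus", call. = FALSE)
  freq_a <- (counts$n_AA + counts$n_AB / 2) / n
  list(locus = counts$locus, freq_A = freq_a, freq_B = 1 - freq_a, n = n,
       percent = format_percent(c(A = freq_a, B = 1 - freq_a)))
}

#' Genotype frequencies
#'
#' Each genotype's frequency is its count over the total,
#' \eqn{AA = N_{AA}/N} etc.
#'
#' @inheritParams allele_frequencies
#' @return A list with `locus`, `freq_AA`, `freq_AB`, `freq_BB`, `n` and
#'   2-dp `percent` strings.
#' @export
genotype_frequencies <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  n <- counts$n_AA + counts$n_AB + counts$n_BB
  if (n == 0L) stop("empty group: no genotypes at locus", call. = FALSE)
  f <- count_vector(counts) / n
  list(locus = counts$locus, freq_AA = f[1], freq_AB = f[2], freq_BB = f[3],
       n = n, percent = format_percent(f))
}
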