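#' Define a biallelic SNP locus
#'
#' A locus is identified by its gene symbol and rs identifier and carries its
#' two alleles plus the designated asthma risk allele. Genotypes at a locus are
#' unordered allele pairs; the canonical ordering used throughout the package
#' puts `allele_1` before `allele_2` (so the canonical heterozygote at a locus
#' declared with alleles `A`, `G` is written `"AG"`).
#'
#' @param gene Gene symbol, e.g. `"IL13"`.
#' @param rs_id dbSNP identifier, e.g. `"rs20541"`.
#' @param allele_1,allele_2 The two single-character alleles. `allele_1` comes
#'   first in the canonical genotype ordering.
#' @param risk_allele The asthma-associated allele; must be one of the two.
#' @return An object of class `"locus"`.
#' @examples
#' locus("IL13", "rs20541", "A", "G", risk_allele = "G")
#' @export
locus <- function(gene, rs_id, allele_1, allele_2, risk_allele) {
  stopifnot(is.character(gene), is.character(rs_id))
  if (nchar(allele_1) != 1L || nchar(allele_2) != 1L)
    stop("alleles must be single characters", call. = FALSE)
  if (allele_1 == allele_2)
    stop("the two alleles of a locus must differ", call. = FALSE)
  if (!risk_allele %in% c(allele_1, allele_2))
    stop("risk_allele must be one of the locus alleles", call. = FALSE)
  structure(
    list(gene = gene, rs_id = rs_id,
         allele_1 = allele_1, allele_2 = allele_2,
         risk_allele = risk_allele),
    class = "locus"
  )
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("<locus> %s %s  alleles %s/%s  risk allele %s (risk homozygote %s)\n",
              x$gene, x$rs_id, x$allele_1, x$allele_2, x$risk_allele,
              risk_homozygote(x)))
  invisible(x)
}

#' The four model loci
#'
#' The four SNPs of the childhood-asthma gene model, in the order the model
#' tables list them: IL13 rs20541 (A/G, risk G), IL4 rs2243250 (T/C, risk T),
#' ADRB2 rs1042713 (A/G, risk A), FCER1B rs569108 (A/G, risk G). The list is
#' named by rs identifier.
#'
#' @return Named list of four `"locus"` objects.
#' @examples
#' names(asthma_loci())
#' @export
asthma_loci <- function() {
  loci <- list(
    locus("IL13",   "rs20541",   "A", "G", risk_allele = "G"),
    locus("IL4",    "rs2243250", "T", "C", risk_allele = "T"),
    locus("ADRB2",  "rs1042713", "A", "G", risk_allele = "A"),
    locus("FCER1B", "rs569108",  "A", "G", risk_allele = "G")
  )
  names(loci) <- vapply(loci, `[[`, "", "rs_id")
  loci
}

#' @rdname asthma_loci
#' @param rs_id rs identifier of one of the four model loci.
#' @export
get_locus <- function(rs_id) {
  loci <- asthma_loci()
  if (!rs_id %in% names(loci))
    stop(sprintf("unknown locus '%s'; built-in loci are %s",
                 rs_id, paste(names(loci), collapse = ", ")), call. = FALSE)
  loci[[rs_id]]
}

#' Risk homozygote genotype of a locus
#'
#' @param locus A `"locus"` object.
#' @return Canonical two-character genotype string of the risk homozygote
#'   (e.g. `"GG"` for IL13 rs20541).
#' @export
risk_homozygote <- function(locus) {
  paste0(locus$risk_allele, locus$risk_allele)
}

# tokens accepted as "missing genotype" in tabular input
MISSING_TOKENS <- c("NA", "./.", "", "--", ".")
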