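#' Canonicalize a raw genotype call
#'
#' Genotypes are unordered allele pairs, and source tables write heterozygotes
#' in either order ("GA" and "AG" denote the same genotype). This function
#' collapses a raw two-character call to the canonical ordering of the locus
#' (allele_1 before allele_2) and recognizes the usual missing-data tokens
#' (`"NA"`, `"./."`, `""`, `"--"`, `"."`).
#'
#' @param raw Raw genotype string, e.g. `"GA"`, or a missing token.
#' @param locus A `"locus"` object.
#' @param context Optional string (e.g. a sample id) used in error messages.
#' @return An object of class `"genotype"`: a list with `rs_id`, `alleles`
#'   (length-2 character, canonical order; `NA` if missing), `missing` flag
#'   and `risk_hom` flag (homozygous for the locus risk allele).
#' @examples
#' normalize_genotype("GA", get_locus("rs20541"))  # same as "AG"
#' @export
normalize_genotype <- function(raw, locus, context = NULL) {
  stopifnot(inherits(locus, "locus"))
  raw <- if (is.na(raw)) "NA" else trimws(as.character(raw))
  where <- if (is.null(context)) "" else sprintf(" (sample %s)", context)
  if (toupper(raw) %in% toupper(MISSING_TOKENS)) {
    return(structure(list(rs_id = locus$rs_id, alleles = c(NA_character_, NA_character_),
                          missing = TRUE, risk_hom = NA),
                     class = "genotype"))
  }
  # tolerate separator forms like "A/G" or "A|G"
  chars <- strsplit(gsub("[/|]", "", raw), "")[[1]]
  if (length(chars) != 2L)
    stop(sprintf("genotype '%s' at %s%s is not a two-allele call",
                 raw, locus$rs_id, where), call. = FALSE)
  chars <- toupper(chars)
  ok <- chars %in% c(locus$allele_1, locus$allele_2)
  if (!all(ok))
    stop(sprintf("allele '%s' in genotype '%s' is not a %s %s allele (%s/%s)%s",
                 chars[!ok][1], raw, locus$gene, locus$rs_id,
                 locus$allele_1, locus$allele_2, where), call. = FALSE)
  # canonical order: locus allele declaration order
  ord <- order(match(chars, c(locus$allele_1, locus$allele_2)))
  alleles <- chars[ord]
  structure(list(rs_id = locus$rs_id, alleles = alleles,
                 missing = FALSE,
                 risk_hom = all(alleles == locus$risk_allele)),
            class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat(sprintf("<genotype> %s %s%s\n", x$rs_id,
              if (x$missing) "missing" else paste(x$alleles, collapse = ""),
              if (isTRUE(x$risk_hom)) " [risk homozygote]" else ""))
  invisible(x)
}

#' @rdname normalize_genotype
#' @return `genotype_string()` returns the canonical two-character string, or
#'   `NA` for a missing genotype.
#' @param g A `"genotype"` object.
#' @export
genotype_string <- function(g) {
  if (g$missing) NA_character_ else paste(g$alleles, collapse = "")
}
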