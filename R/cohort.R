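#' Construct a four-locus case-control cohort
#'
#' A cohort is a data frame with one row per child and columns `sample_id`,
#' `group` (`"asthma"` or `"control"`), `sex` (`"male"`, `"female"`,
#' `"unknown"`), `age` (years, may be `NA`) and one canonical genotype column
#' per model locus (`rs20541`, `rs2243250`, `rs1042713`, `rs569108`; `NA`
#' marks a missing call). Construction validates and canonicalizes all fields.
#'
#' Group labels are matched case-insensitively: `"asthma"`/`"case"` map to the
#' asthma group, `"control"`/`"healthy"` to the control group; any other label
#' is an error rather than a third group.
#'
#' @param data A data frame with the columns above (raw genotype strings in
#'   either allele order are accepted).
#' @param name Cohort name, e.g. a nationality label.
#' @return An object of classes `"cohort"` and `"data.frame"`.
#' @export
cohort <- function(data, name = "cohort") {
  req <- c("sample_id", "group", "sex", "age", names(asthma_loci()))
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  data <- as.data.frame(data)[, req]
  data$sample_id <- as.character(data$sample_id)
  if (anyDuplicated(data$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(data$sample_id[duplicated(data$sample_id)]), collapse = ", "),
         call. = FALSE)
  data$group <- normalize_group(data$group)
  data$sex <- normalize_sex(data$sex)
  data$age <- suppressWarnings(as.numeric(data$age))
  if (any(!is.na(data$age) & data$age < 0))
    stop("negative age", call. = FALSE)
  for (rs in names(asthma_loci())) {
    loc <- get_locus(rs)
    # vectorized canonicalization over the common spellings; anything else
    # goes through normalize_genotype() for a precise validation error
    a1 <- loc$allele_1; a2 <- loc$allele_2
    canon <- c(stats::setNames(
      c(paste0(a1, a1), paste0(a1, a2), paste0(a1, a2), paste0(a2, a2)),
      c(paste0(a1, a1), paste0(a1, a2), paste0(a2, a1), paste0(a2, a2))),
      stats::setNames(rep(NA_character_, length(MISSING_TOKENS)),
                      MISSING_TOKENS))
    raw <- trimws(toupper(as.character(data[[rs]])))
    raw[is.na(raw)] <- "NA"
    canonical <- unname(canon[match(raw, names(canon))])
    for (i in which(is.na(canonical) & !raw %in% MISSING_TOKENS)) {
      # slow path: separator forms like "A/G", or a validation error
      canonical[i] <- genotype_string(
        normalize_genotype(data[[rs]][i], loc, context = data$sample_id[i]))
    }
    data[[rs]] <- canonical
  }
  structure(data, name = name, class = c("cohort", "data.frame"))
}

normalize_group <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- ifelse(x %in% c("asthma", "case"), "asthma",
                ifelse(x %in% c("control", "healthy"), "control", NA))
  if (anyNA(out))
    stop("unknown group label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         "; expected asthma/case or control/healthy", call. = FALSE)
  factor(out, levels = c("asthma", "control"))
}

normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == ""] <- "unknown"
  out <- ifelse(x %in% c("male", "m"), "male",
                ifelse(x %in% c("female", "f"), "female",
                       ifelse(x == "unknown", "unknown", NA)))
  if (anyNA(out))
    stop("unrecognized sex label(s): ", paste(unique(x[is.na(out)]), collapse = ", "),
         call. = FALSE)
  factor(out, levels = c("male", "female", "unknown"))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s: %d samples (%d asthma, %d control)\n",
              attr(x, "name"), nrow(x),
              sum(x$group == "asthma"), sum(x$group == "control")))
  NextMethod()
}

#' Read a cohort from TSV, CSV or VCF
#'
#' Tabular input must carry a header with columns `sample_id`, `group`, `sex`,
#' `age` and one genotype column per rs identifier. VCF input (VCF 4.x) is
#' matched on the `ID` column against the four model rs identifiers; `GT`
#' fields are decoded against `REF`/`ALT` and the phasing separator is
#' ignored. Because a VCF carries no phenotype, VCF input requires a
#' `group_map`: a two-column TSV (`sample_id`, `group`) or an equivalent data
#' frame.
#'
#' @param path Input file.
#' @param format One of `"tsv"`, `"csv"`, `"vcf"`. Guessed from the file
#'   extension by default.
#' @param group_map For VCF input: path to the sidecar group TSV or a data
#'   frame with columns `sample_id` and `group`.
#' @param name Cohort name; defaults to the file name.
#' @return A `"cohort"` object.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, format = c("guess", "tsv", "csv", "vcf"),
                        group_map = NULL, name = NULL) {
  format <- match.arg(format)
  if (format == "guess") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", vcf = "vcf", "tsv")
  }
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  if (format == "vcf")
    return(read_cohort_vcf(path, group_map, name))
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          na.strings = character(0), check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  cohort(df, name = name)
}

read_cohort_vcf <- function(path, group_map, name) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF input requires the VariantAnnotation package", call. = FALSE)
  if (is.null(group_map))
    stop("VCF input needs a group_map (sample_id, group)", call. = FALSE)
  if (is.character(group_map))
    group_map <- utils::read.table(group_map, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(group_map)))
    stop("group_map must have columns sample_id and group", call. = FALSE)

  vcf <- VariantAnnotation::readVcf(path)
  ids <- rownames(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(as.list(VariantAnnotation::alt(vcf)),
                function(a) as.character(a)[1], character(1))
  samples <- colnames(gt)
  loci <- asthma_loci()
  missing_sites <- setdiff(names(loci), ids)
  if (length(missing_sites) > 0L)
    stop("VCF lacks site(s): ", paste(missing_sites, collapse = ", "),
         call. = FALSE)

  decode <- function(rs) {
    i <- match(rs, ids)
    alleles <- c(ref[i], alt[i])
    vapply(gt[i, ], function(call) {
      if (is.na(call) || call %in% c("./.", ".|.", "."))
        return(NA_character_)
      idx <- as.integer(strsplit(call, "[/|]")[[1]]) + 1L
      if (length(idx) != 2L || anyNA(idx) || any(idx > length(alleles)))
        stop(sprintf("cannot decode GT '%s' at %s", call, rs), call. = FALSE)
      paste(alleles[idx], collapse = "")
    }, character(1))
  }

  df <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  m <- match(df$sample_id, as.character(group_map$sample_id))
  if (anyNA(m))
    stop("group_map lacks sample(s): ",
         paste(df$sample_id[is.na(m)], collapse = ", "), call. = FALSE)
  df$group <- as.character(group_map$group)[m]
  df$sex <- if ("sex" %in% names(group_map)) as.character(group_map$sex)[m] else "unknown"
  df$age <- if ("age" %in% names(group_map)) as.numeric(group_map$age)[m] else NA_real_
  for (rs in names(loci)) df[[rs]] <- decode(rs)
  cohort(df, name = name)
}

#' Write a cohort to TSV or CSV
#'
#' Writes the standard genotype table (header `sample_id`, `group`, `sex`,
#' `age`, `rs1042713`, `rs2243250`, `rs569108`, `rs20541`); missing genotypes
#' are written as `NA`. `write_cohort()` followed by [read_cohort()]
#' round-trips to an identical cohort.
#'
#' @param x A `"cohort"`.
#' @param path Output file.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "cohort"))
  out <- as.data.frame(x)[, c("sample_id", "group", "sex", "age",
                              "rs1042713", "rs2243250", "rs569108", "rs20541")]
  utils::write.table(out, path, sep = if (format == "csv") "," else "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Reconstruct integer counts from printed percentages
#'
#' Published frequency tables report genotype distributions as percentages
#' plus a group size; the underlying integer counts are recovered by rounding
#' `percent / 100 * n` to the nearest integer (half away from zero). When the
#' recovered counts do not sum to `n` a warning is issued — printed tables
#' contain occasional typos and must not halt the pipeline.
#'
#' @param percent Numeric vector of percentages (0–100 scale), one per
#'   category.
#' @param n Group size.
#' @return Integer vector of counts, same length as `percent`.
#' @examples
#' reconstruct_counts(c(28.71, 59.41, 11.88), 101)  # 29 60 12
#' @export
reconstruct_counts <- function(percent, n) {
  stopifnot(is.numeric(percent), all(percent >= 0), length(n) == 1L, n > 0)
  x <- percent / 100 * n
  counts <- as.integer(sign(x) * floor(abs(x) + 0.5))  # half away from zero
  if (sum(counts) != n)
    warning(sprintf("reconstructed counts sum to %d, not the group size %d",
                    sum(counts), as.integer(n)), call. = FALSE)
  counts
}
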