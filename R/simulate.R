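#' Specify a two-group four-locus cohort simulation
#'
#' A simulation spec states, per group, the sample size, the genotype
#' distribution at each locus (risk orientation: risk homozygote,
#' heterozygote, non-risk homozygote), the probability of male sex, and a
#' normal age model (years, truncated to 0-14 to match a paediatric cohort).
#' Loci are sampled independently within a group — published summaries
#' provide only marginal distributions — unless a joint case-group
#' distribution has been installed by [plant_risk_effect()].
#'
#' @param name Cohort name.
#' @param n Named integer vector `c(asthma = , control = )`.
#' @param genotype_probs Nested list `$asthma`/`$control`, each a named list
#'   (by rs id) of probability 3-vectors.
#' @param sex_prob Named numeric vector: probability of male per group.
#' @param age Nested list `$asthma`/`$control` with `mean` and `sd` (years).
#' @return An object of class `"simulation_spec"`.
#' @seealso [spec_from_counts()], [simulate_cohort()]
#' @export
simulation_spec <- function(name, n, genotype_probs,
                            sex_prob = c(asthma = 0.5, control = 0.5),
                            age = list(asthma = list(mean = 6, sd = 3),
                                       control = list(mean = 6, sd = 3))) {
  groups <- c("asthma", "control")
  stopifnot(all(groups %in% names(n)), all(n[groups] > 0),
            all(groups %in% names(genotype_probs)),
            all(groups %in% names(sex_prob)),
            all(sex_prob >= 0 & sex_prob <= 1))
  for (grp in groups) {
    probs <- genotype_probs[[grp]]
    if (!setequal(names(probs), names(asthma_loci())))
      stop("genotype_probs$", grp, " must cover exactly the four model loci",
           call. = FALSE)
    for (rs in names(probs)) {
      p <- probs[[rs]]
      if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-6)
        stop(sprintf("invalid genotype probability vector for %s (%s group)",
                     rs, grp), call. = FALSE)
    }
    if (age[[grp]]$sd < 0) stop("age sd must be non-negative", call. = FALSE)
  }
  structure(list(name = name, n = n[groups],
                 genotype_probs = genotype_probs[groups],
                 sex_prob = sex_prob[groups], age = age[groups],
                 joint_case = NULL),
            class = "simulation_spec")
}

#' Build a simulation spec from genotype counts
#'
#' Normalizes per-group, per-locus genotype counts into sampling
#' probabilities, so a spec can be built directly from reconstructed summary
#' tables.
#'
#' @param counts Nested list as returned by [reference_counts()]:
#'   `$asthma`/`$control`, each a named list of `"genotype_counts"`.
#' @param name Cohort name.
#' @param n Group sizes; defaults to the totals of `counts`.
#' @param demographics Optional per-group list with `male`, `female`,
#'   `age_mean`, `age_sd` (as in [reference_tables()]`$demographics`).
#' @return A `"simulation_spec"`.
#' @export
spec_from_counts <- function(counts, name = "simulated", n = NULL,
                             demographics = NULL) {
  groups <- c("asthma", "control")
  probs <- lapply(counts[groups], function(group_counts) {
    lapply(group_counts, function(gc) {
      v <- count_vector(gc)
      if (sum(v) == 0) stop("zero genotype total at a locus", call. = FALSE)
      v / sum(v)
    })
  })
  if (is.null(n))
    n <- vapply(counts[groups], function(gcs) sum(count_vector(gcs[[1]])),
                numeric(1))
  if (is.null(demographics)) {
    sex_prob <- c(asthma = 0.5, control = 0.5)
    age <- list(asthma = list(mean = 6, sd = 3),
                control = list(mean = 6, sd = 3))
  } else {
    sex_prob <- vapply(demographics[groups], function(d)
      d$male / (d$male + d$female), numeric(1))
    age <- lapply(demographics[groups], function(d)
      list(mean = d$age_mean, sd = d$age_sd))
  }
  simulation_spec(name, stats::setNames(as.integer(n), groups), probs,
                  sex_prob = sex_prob, age = age)
}

#' Ready-made specs for the bundled Han and Kazak summaries
#'
#' Convenience wrapper: [spec_from_counts()] applied to
#' [reference_counts()] with the bundled demographics, at the original group
#' sizes (Han 101/92, Kazak 80/93).
#'
#' @inheritParams reference_tables
#' @return A `"simulation_spec"`.
#' @export
reference_spec <- function(nationality = c("han", "kazak")) {
  nationality <- match.arg(nationality)
  ref <- reference_tables(nationality)
  spec_from_counts(reference_counts(nationality), name = nationality,
                   n = ref$n, demographics = ref$demographics)
}

# enumerate the 81 joint genotype combinations of a group's marginals
joint_distribution <- function(probs) {
  cats <- expand.grid(rs20541 = 1:3, rs2243250 = 1:3, rs1042713 = 1:3,
                      rs569108 = 1:3)
  p <- rep(1, nrow(cats))
  for (rs in names(cats)) p <- p * probs[[rs]][cats[[rs]]]
  cats$prob <- p
  cats
}

#' Plant a combination-level risk effect in the case group
#'
#' Rewrites the spec's case-group distribution as a joint distribution over
#' all 4-locus genotype combinations (the product of its marginals) and
#' multiplies the weight of every combination whose risk-homozygosity
#' profile is in `target` by `odds_ratio`, then renormalizes. The odds of
#' each target profile versus the reference profile (no risk homozygotes)
#' are thereby multiplied by exactly `odds_ratio`; the control group is
#' untouched. This is the package's only mechanism for inducing cross-locus
#' structure and exists to exercise the model-derivation rule.
#'
#' @param spec A `"simulation_spec"`.
#' @param target Logical matrix/data frame of risk profiles (columns
#'   `rs20541`, `rs2243250`, `rs1042713`, `rs569108`), or `"fixed_high"` for
#'   the fixed model's nine high-risk combinations. Must not include the
#'   reference profile.
#' @param odds_ratio Positive multiplier.
#' @return The modified `"simulation_spec"` (with a `joint_case` table).
#' @export
plant_risk_effect <- function(spec, target, odds_ratio) {
  stopifnot(inherits(spec, "simulation_spec"), odds_ratio > 0)
  if (identical(target, "fixed_high")) {
    fm <- fixed_risk_model()
    target <- fm[fm$class == "high", PROFILE_LOCI]
  }
  target <- as.matrix(target)
  if (!is.null(colnames(target)) && all(PROFILE_LOCI %in% colnames(target)))
    target <- target[, PROFILE_LOCI, drop = FALSE]
  if (nrow(target) > 0 && any(rowSums(target) == 0))
    stop("target must not include the reference combination", call. = FALSE)
  joint <- joint_distribution(spec$genotype_probs$asthma)
  if (nrow(target) > 0) {
    profile_keys <- profile_key(joint[, PROFILE_LOCI] == 1L)  # category 1 = risk hom
    hit <- profile_keys %in% profile_key(target)
    joint$prob[hit] <- joint$prob[hit] * odds_ratio
  }
  joint$prob <- joint$prob / sum(joint$prob)
  spec$joint_case <- joint
  spec
}

#' Read or write a simulation spec as JSON
#'
#' The on-disk form mirrors the arguments of [simulation_spec()]. A spec with
#' a planted joint case-group distribution round-trips as well.
#'
#' @param path JSON file.
#' @return `read_simulation_spec()` returns a `"simulation_spec"`;
#'   `write_simulation_spec()` returns `path` invisibly.
#' @export
read_simulation_spec <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("name", "n", "genotype_probs"))
    if (is.null(cfg[[f]]))
      stop("simulation spec lacks required field '", f, "'", call. = FALSE)
  gp <- lapply(cfg$genotype_probs, function(g) lapply(g, as.numeric))
  spec <- simulation_spec(cfg$name, unlist(cfg$n), gp,
                          sex_prob = if (is.null(cfg$sex_prob))
                            c(asthma = 0.5, control = 0.5) else unlist(cfg$sex_prob),
                          age = if (is.null(cfg$age))
                            list(asthma = list(mean = 6, sd = 3),
                                 control = list(mean = 6, sd = 3)) else cfg$age)
  if (!is.null(cfg$joint_case) && length(cfg$joint_case) > 0)
    spec$joint_case <- as.data.frame(cfg$joint_case)
  spec
}

#' @rdname read_simulation_spec
#' @param spec A `"simulation_spec"`.
#' @export
write_simulation_spec <- function(spec, path) {
  stopifnot(inherits(spec, "simulation_spec"))
  payload <- list(name = spec$name,
                  n = as.list(spec$n),                 # named objects, not
                  sex_prob = as.list(spec$sex_prob),   # bare JSON arrays
                  age = spec$age,
                  genotype_probs = spec$genotype_probs)
  if (!is.null(spec$joint_case)) payload$joint_case <- spec$joint_case
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

genotype_labels <- function(locus) {
  other <- setdiff(c(locus$allele_1, locus$allele_2), locus$risk_allele)
  c(risk_homozygote(locus),
    paste0(locus$allele_1, locus$allele_2),
    paste0(other, other))
}

#' Simulate a cohort from a spec
#'
#' Draws each sample's genotypes, sex and age from the spec's
#' distributions: genotypes per locus from the group's multinomial genotype
#' distribution (or, for the case group of a spec modified by
#' [plant_risk_effect()], from the joint combination distribution), sex
#' Bernoulli, age normal truncated to 0-14 years by rejection. Fully
#' reproducible: the same spec and seed give an identical cohort; the RNG
#' state of the session is left untouched. The seed is recorded in the
#' cohort's `"seed"` attribute.
#'
#' @param spec A `"simulation_spec"`.
#' @param seed Integer seed.
#' @param hwe Draw genotypes from Hardy-Weinberg proportions (p^2, 2pq, q^2
#'   of each distribution's gene-counting allele frequency) instead of the
#'   specified genotype distribution itself. The default `FALSE` keeps the
#'   simulated marginals faithful to the spec even where it deviates from
#'   HWE.
#' @return A `"cohort"`.
#' @examples
#' coh <- simulate_cohort(reference_spec("han"), seed = 1)
#' table(coh$group)
#' @export
simulate_cohort <- function(spec, seed, hwe = FALSE) {
  stopifnot(inherits(spec, "simulation_spec"), is.numeric(seed))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  loci <- asthma_loci()

  draw_group <- function(grp) {
    n <- spec$n[[grp]]
    df <- data.frame(sample_id = sprintf("%s_%s_%04d", spec$name,
                                         substr(grp, 1, 4), seq_len(n)),
                     group = grp, stringsAsFactors = FALSE)
    df$sex <- ifelse(stats::runif(n) < spec$sex_prob[[grp]], "male", "female")
    df$age <- round(rtrunc_norm(n, spec$age[[grp]]$mean, spec$age[[grp]]$sd,
                                0, 14), 2)
    if (grp == "asthma" && !is.null(spec$joint_case)) {
      rows <- sample.int(nrow(spec$joint_case), n, replace = TRUE,
                         prob = spec$joint_case$prob)
      for (rs in names(loci))
        df[[rs]] <- genotype_labels(loci[[rs]])[spec$joint_case[[rs]][rows]]
    } else {
      for (rs in names(loci)) {
        p <- spec$genotype_probs[[grp]][[rs]]
        if (hwe) {
          q <- p[1] + p[2] / 2  # gene-counting risk-allele frequency
          p <- c(q^2, 2 * q * (1 - q), (1 - q)^2)
        }
        cat_idx <- sample.int(3L, n, replace = TRUE, prob = p)
        df[[rs]] <- genotype_labels(loci[[rs]])[cat_idx]
      }
    }
    df
  }

  out <- cohort(rbind(draw_group("asthma"), draw_group("control")),
                name = spec$name)
  attr(out, "seed") <- as.integer(seed)
  out
}

# truncated-normal sampling by rejection; falls back to clamping for
# degenerate sd = 0
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}
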