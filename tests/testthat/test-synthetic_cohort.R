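test_that("simulation is deterministic in the seed and leaves the RNG alone", {
  spec <- reference_spec("han")
  set.seed(999)
  before <- .Random.seed
  c1 <- simulate_cohort(spec, seed = 7)
  expect_identical(.Random.seed, before)  # session RNG state untouched
  c2 <- simulate_cohort(spec, seed = 7)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(spec, seed = 8)
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
  expect_identical(attr(c1, "seed"), 7L)
  expect_identical(nrow(c1), 193L)
  expect_true(all(c1$age >= 0 & c1$age <= 14))
})

test_that("spec_from_counts normalizes counts into sampling probabilities", {
  spec <- reference_spec("han")
  expect_equal(spec$genotype_probs$asthma$rs1042713, c(29, 60, 12) / 101)
  kz <- reference_spec("kazak")
  # risk orientation: FCER1B risk homozygote GG first
  expect_equal(kz$genotype_probs$asthma$rs569108, c(2, 13, 65) / 80)
  expect_equal(kz$n, c(asthma = 80L, control = 93L))
  expect_equal(kz$sex_prob[["asthma"]], 48 / 80)

  degenerate <- spec_from_counts(list(
    asthma = lapply(stats::setNames(nm = names(asthma_loci())),
                    function(rs) as_genotype_counts(c(0, 0, 5), rs)),
    control = lapply(stats::setNames(nm = names(asthma_loci())),
                     function(rs) as_genotype_counts(c(0, 0, 5), rs))))
  expect_equal(degenerate$genotype_probs$asthma$rs20541, c(0, 0, 1))
  coh <- simulate_cohort(degenerate, seed = 1)
  expect_true(all(classify_cohort(coh) == "low"))  # nobody carries a risk hom

  expect_error(simulation_spec("bad", c(asthma = 10L, control = 10L),
                               list(asthma = lapply(stats::setNames(
                                 nm = names(asthma_loci())),
                                 function(rs) c(0.5, 0.6, 0.2)),
                                 control = degenerate$genotype_probs$control)),
               "invalid genotype probability")
})

test_that("empirical genotype frequencies converge to the spec probabilities", {
  spec <- reference_spec("han")
  # at the study's own sample sizes: within 99% binomial bounds per category
  coh <- simulate_cohort(spec, seed = 42)
  for (grp in c("asthma", "control")) {
    n <- spec$n[[grp]]
    for (rs in names(asthma_loci())) {
      p <- spec$genotype_probs[[grp]][[rs]]
      obs <- c(genotype_counts(coh, grp, rs)$n_AA,
               genotype_counts(coh, grp, rs)$n_AB,
               genotype_counts(coh, grp, rs)$n_BB)
      for (j in 1:3) {
        bounds <- qbinom(c(0.005, 0.995), n, p[j])
        expect_true(obs[j] >= bounds[1] && obs[j] <= bounds[2],
                    label = sprintf("%s %s category %d: %d in [%d, %d]",
                                    grp, rs, j, obs[j], bounds[1], bounds[2]))
      }
    }
  }
  # and tightly at n = 1e5
  big <- spec_from_counts(reference_counts("han"),
                          n = c(asthma = 1e5, control = 100))
  coh_big <- simulate_cohort(big, seed = 13)
  for (rs in names(asthma_loci())) {
    gf <- genotype_frequencies(genotype_counts(coh_big, "asthma", rs))
    expect_equal(c(gf$freq_AA, gf$freq_AB, gf$freq_BB),
                 big$genotype_probs$asthma[[rs]], tolerance = 0.01)
  }
})

test_that("hwe mode draws genotypes from Hardy-Weinberg proportions", {
  # a spec with zero heterozygotes is maximally far from HWE
  counts <- lapply(stats::setNames(nm = names(asthma_loci())),
                   function(rs) as_genotype_counts(c(50, 0, 50), rs))
  spec <- spec_from_counts(list(asthma = counts, control = counts),
                           n = c(asthma = 2e4, control = 100))
  coh <- simulate_cohort(spec, seed = 3, hwe = TRUE)
  gf <- genotype_frequencies(genotype_counts(coh, "asthma", "rs20541"))
  expect_equal(c(gf$freq_AA, gf$freq_AB, gf$freq_BB), c(0.25, 0.5, 0.25),
               tolerance = 0.02)  # p = q = 0.5 -> 1/4, 1/2, 1/4
})

test_that("plant_risk_effect rescales target-combination odds and nothing else", {
  probs <- lapply(stats::setNames(nm = names(asthma_loci())),
                  function(rs) c(0.3, 0.5, 0.2))
  spec <- simulation_spec("s", c(asthma = 100L, control = 100L),
                          list(asthma = probs, control = probs))

  # OR = 1 and an empty target both leave the joint distribution unchanged
  null1 <- plant_risk_effect(spec, "fixed_high", odds_ratio = 1)
  empty <- plant_risk_effect(spec, all_profiles()[0, ], odds_ratio = 5)
  expect_equal(null1$joint_case$prob, empty$joint_case$prob)
  expect_equal(sum(null1$joint_case$prob), 1)

  or5 <- plant_risk_effect(spec, "fixed_high", odds_ratio = 5)
  joint0 <- null1$joint_case
  joint5 <- or5$joint_case
  # odds of each high combination against the reference scale by exactly 5
  high <- classify_fixed(as.matrix(joint5[, colnames(all_profiles())] == 1L)) == "high"
  ref <- rowSums(joint5[, colnames(all_profiles())] == 1L) == 0
  odds0 <- joint0$prob[high] / sum(joint0$prob[ref])
  odds5 <- joint5$prob[high] / sum(joint5$prob[ref])
  expect_equal(odds5 / odds0, rep(5, sum(high)))
  # low-risk combinations keep their odds against the reference
  low <- !high & !ref
  expect_equal(joint5$prob[low] / sum(joint5$prob[ref]),
               joint0$prob[low] / sum(joint0$prob[ref]))

  expect_error(plant_risk_effect(spec, all_profiles()[1, , drop = FALSE], 5),
               "reference")
})

test_that("simulation specs round-trip through JSON", {
  spec <- reference_spec("kazak")
  path <- tempfile(fileext = ".json")
  write_simulation_spec(spec, path)
  back <- read_simulation_spec(path)
  expect_equal(back$genotype_probs, spec$genotype_probs)
  expect_equal(back$n, spec$n)
  expect_equal(back$sex_prob, spec$sex_prob)
  expect_identical(simulate_cohort(back, seed = 5),
                   simulate_cohort(spec, seed = 5))
})
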