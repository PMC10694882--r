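---
title: "The four-locus asthma risk-genotype model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The four-locus asthma risk-genotype model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourlocus)
```

## The model

Childhood asthma is polygenic, and its prevalence differs markedly between
ethnic groups living in the same region. One practical way to summarize a
child's genetic load is a small fixed panel of susceptibility SNPs. The panel
implemented here uses four biallelic loci:

| gene | rs id | alleles | risk allele | risk homozygote |
|------|-------|---------|-------------|-----------------|
| IL13 | rs20541 | A/G | G | GG |
| IL4 | rs2243250 | T/C | T | TT |
| ADRB2 | rs1042713 | A/G | A | AA |
| FCER1B | rs569108 | A/G | G | GG |

A child's **risk profile** is the vector of four booleans saying at which
loci they are homozygous for the risk allele. The 16 possible profiles are
partitioned into *high-* and *low-risk genotypes*. The fixed partition
shipped as `fixed_risk_model()` puts into the low class: the reference
profile (no risk homozygotes), every single risk homozygote, and the two
pairs {ADRB2, FCER1B} and {IL13, FCER1B}; the remaining four pairs, all four
triples and the full combination are high-risk. The test suite verifies that
this literal enumeration equals the closed-form rule "high iff at least three
risk homozygotes, or exactly two that are not one of those two exempt pairs"
over all 16 profiles.

The partition was originally *derived* by comparing each profile against the
reference profile in a case-control cohort: a profile is high-risk when its
asthma odds ratio versus the reference exceeds 1 with P < 0.05.
`derive_model()` reimplements this rule so it can be exercised on data.
Design choices it embodies:

* **Strict inequalities.** OR exactly 1 or P exactly alpha stays low; the
  rule is "P < 0.05 **and** OR > 1".
* **Test selection.** Fisher's exact test when any expected count of the
  2x2 (profile vs reference, asthma vs control) table is below 5, otherwise
  Pearson's chi-square. Profiles are sparse by construction, so Fisher does
  most of the work. No multiple-testing correction is applied — the rule is
  a fixed decision procedure, not a discovery screen.
* **Totality.** Profiles with no carriers cannot be tested; they inherit the
  fixed model's class and are flagged `observed = FALSE`, so a derived model
  always classifies every possible genotype.

## Gene-counting frequency estimation

With genotype counts $N_{AA}, N_{AB}, N_{BB}$ at a locus ($A$ denoting the
risk allele) and $N$ their sum,

$$A = \frac{N_{AA} + N_{AB}/2}{N}, \qquad B = \frac{N_{BB} + N_{AB}/2}{N},$$

and genotype frequencies are simple count proportions. All internal
computation is in full precision; the `percent` strings round half away from
zero to two decimals, since that is what published frequency tables do
(0.43125 prints as 43.13%, where IEEE half-even rounding would give 43.12%).

## Association statistics and the two allele-table conventions

Genotype association uses the 2x3 group-by-genotype Pearson chi-square.
For allele association there are two conventions, and the difference
matters when reproducing published tables:

* `two_n` (the default): each individual contributes two chromosomes, so the
  2x2 table holds $2N_{AA} + N_{AB}$ risk alleles out of $2N$. This is the
  statistically standard choice.
* `paper_n`: allele *frequencies* are scaled by the number of *individuals*,
  giving cells $N_{AA} + N_{AB}/2$ out of $N$ (possibly half-integral).
  Because the Pearson statistic scales linearly when all counts are
  multiplied by a constant, the `paper_n` statistic is exactly half the
  `two_n` one. Several published allele chi-squares (e.g. the bundled Han
  ADRB2 value 4.30, whose `two_n` counterpart is 8.60) are only reproduced
  under this convention, which is why `run_analysis(paper_compat = TRUE)`
  selects it. The scaling property itself is asserted in the test suite.

Fisher's exact test is the classical conditional test: the two-tailed
p-value sums hypergeometric probabilities of all tables no more probable
than the observed one. It requires integer counts and therefore refuses
`paper_n` tables rather than silently rounding them. The automatic selector
(`association_test()`) uses Fisher only for 2x2 tables with an expected
count below 5; agreement between Fisher and Pearson is only asymptotic —
near the expected-count-5 boundary their two-tailed p-values can differ by
about 0.1, which is why the sanity test of their agreement samples large
tables.

Odds ratios use the Woolf (log-normal) interval
$\exp(\ln \widehat{OR} \pm z_{1-\alpha/2}\sqrt{1/a+1/b+1/c+1/d})$, which
reproduces both bundled risk-table intervals to two decimals. A zero cell
makes the interval undefined; the Haldane–Anscombe +0.5 correction is an
explicit opt-in (`haldane = TRUE`), never silent.

Age comparisons use Student's t computed from summary statistics
(mean, SD, n), because that is all a published demographic table provides;
a Welch variant and a normal-approximation rank-sum utility are included
for raw data.

## Reconstructing counts from printed percentages

The bundled Han (101 asthma / 92 control) and Kazak (80 / 93) summary
tables store genotype distributions as percentages. `reconstruct_counts()`
recovers integers as `round(pct/100 * n)` with half-away-from-zero
rounding; for every one of the 16 genotype rows the result sums exactly to
the group size, which is the package's evidence that this rounding rule is
the right inverse of how the tables were produced. Inconsistencies are
warnings, not errors, because printed tables contain typos that must not
halt a pipeline.

Known discrepancies in the bundled tables, documented here and frozen in
the test suite rather than patched:

* Both FCER1B genotype chi-squares print values (2.16 Han, 1.38 Kazak) that
  no stated method reproduces from the same rows; Pearson on the
  reconstructed counts gives 2.23 and 1.28. The tables are sparse at this
  locus, so some unstated correction was likely applied.
* The Han IL4 and IL13 allele chi-squares (5.51, 7.17) sit slightly off the
  `paper_n` Pearson values (5.35, 7.23), consistent with intermediate
  rounding.
* The Han FCER1B allele percentages contradict gene counting applied to the
  same row's genotype percentages (printed 16.83/28.26 vs computed
  18.81/13.04); the genotype rows are treated as authoritative.
* The Han IL4 control allele cells sum to 90% (20.98 is presumably a typo
  for 30.98), and the Kazak high/low risk percentages (16.67/83.33) do not
  match their own counts (15/65 of 80); counts are authoritative because
  they reproduce the printed odds ratio.

## The synthetic cohort generator

`simulate_cohort()` draws each child independently: genotype per locus from
the group's multinomial genotype distribution, sex Bernoulli, age normal
truncated to 0–14 years (the paediatric inclusion window) by rejection
sampling. The generator's defaults, via `reference_spec()`, *are* the
bundled cohort summaries — group sizes, genotype distributions, sex ratios
and age moments — so a simulated cohort emulates the stated world rather
than a tunable one.

What the generator deliberately does **not** model: linkage disequilibrium
(IL13 and IL4 are both at 5q31 and are probably correlated in reality, but
only marginal distributions are published), family structure, admixture, or
genotyping error. Genotypes are drawn from the genotype distribution
directly rather than from allele frequencies, so marginals stay faithful to
the tables even where those deviate from Hardy–Weinberg equilibrium; an
`hwe = TRUE` mode substitutes the $p^2, 2pq, q^2$ proportions implied by
the gene-counting allele frequency. A green simulation test therefore
establishes correct marginal behaviour and seeded reproducibility, not
realism of the joint genotype structure.

`plant_risk_effect()` is the one mechanism that induces cross-locus
structure: it expands the case group into the full 81-combination joint
distribution (product of marginals), multiplies the weight of every
combination whose profile is in the target set by a constant, and
renormalizes — which multiplies each target profile's odds against the
reference profile by exactly that constant. The recovery test plants an
odds ratio of 5 on the nine high-risk profiles at n = 2000 per group. For
that test the base world uses symmetric genotype probabilities
(0.3/0.5/0.2 at every locus) rather than the bundled marginals: FCER1B risk
homozygotes are so rare in the real tables (~2%) that most FCER1B-involving
profiles would go unobserved even at n = 2000, leaving nothing to recover.
The symmetric world gives every profile an expected count above ~15 and was
fixed before any test was run.

## Deterministic fixtures

`fixture_cohort()` expands the reconstructed counts into an explicit
per-child cohort satisfying two exact constraints: every per-locus,
per-group genotype count, and the per-group high/low risk-class totals.
The published data determine only these summaries, not the per-child
combinations, so the fixture's joint arrangement — found by a seeded swap
search over risk-homozygote assignments — is one of many consistent
arrangements and is labelled synthetic. Ages are deterministic normal
quantiles of the reported mean/SD (so the fixture's age SD is slightly
shrunken relative to the printed value); sexes are block-assigned to match
the printed counts. Consequently the fixture reproduces every per-locus
statistic, the sex chi-square and the risk-class comparison exactly, while
its age t-test only approximates the printed one — the printed age
comparison is instead reproduced from the summary statistics directly by
`t_test_from_summary()`.

## Numerical and interface choices

* Heterozygotes are canonicalized to the locus's allele declaration order
  ("GA" and "AG" are the same genotype; the canonical form is "AG").
* Missing genotype calls exclude a sample from that locus's frequency and
  association computations, and from risk classification entirely (all four
  genotypes are required). How missing calls arose in the original data is
  unstated; this exclusion rule is the package's own robustness decision.
* Group labels accept case-insensitive synonyms ({asthma, case} and
  {control, healthy}); anything else is an error rather than a third group.
* VCF input decodes GT against REF/ALT, ignores the phasing separator
  (genotypes here are unphased unordered pairs), and requires a sidecar
  sample-to-group map because VCF carries no phenotype.
* Simulation specs serialize to JSON. YAML is not supported: no YAML parser
  is available in the package's dependency footprint, and JSON round-trips
  the spec (including a planted joint distribution) losslessly.
* Reports serialize deterministically; rerunning `run_analysis()` on the
  same cohort and configuration yields byte-identical JSON.
* The command-line wrapper (`inst/cli/fourlocus.R`) is a thin layer over
  the exported functions with exit codes 0 (success), 2 (validation or
  configuration error) and 3 (degenerate statistics).

## Limitations

The model is a fixed lookup over homozygosity indicators: no per-allele
dosages, no weighted score, no covariate adjustment, no interaction
estimation beyond the profile-level odds ratios the derivation rule needs.
The bundled summaries support reproduction of the published tables and
power the simulator's defaults, but per-child inference beyond the printed
summaries (for instance, the fixture's joint genotype arrangement) is
synthetic by construction.
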