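# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# Two-tailed Fisher p-value by brute-force enumeration of every 2x2 table
# with the observed margins: sum the hypergeometric probabilities of all
# tables no more probable than the observed one.
fisher_enumerate <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a) dhyper(a, r1, r2, c1), numeric(1))
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Closed-form counterpart of the fixed 16-combination partition: a profile is
# high-risk iff it carries >= 3 risk homozygotes, or exactly 2 that are not
# the pair {ADRB2, FCER1B} and not the pair {IL13, FCER1B}.
# Profile order: IL13, IL4, ADRB2, FCER1B.
closed_form_class <- function(profile) {
  k <- sum(profile)
  if (k >= 3) return("high")
  if (k == 2) {
    pair <- unname(which(profile))
    if (setequal(pair, c(3, 4)) || setequal(pair, c(1, 4)))
      return("low")
    return("high")
  }
  "low"
}

# all 16 risk profiles as a logical matrix (profile order above)
all_profiles <- function() {
  m <- as.matrix(expand.grid(c(FALSE, TRUE), c(FALSE, TRUE),
                             c(FALSE, TRUE), c(FALSE, TRUE)))
  colnames(m) <- c("rs20541", "rs2243250", "rs1042713", "rs569108")
  m
}

# small hand-written complete cohort used by IO and classification tests
mini_cohort_df <- function() {
  data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    group = c("asthma", "asthma", "control", "control"),
    sex = c("male", "female", "male", "female"),
    age = c(5.5, 7, 6, 8.25),
    rs20541 = c("GG", "GA", "AA", "AG"),
    rs2243250 = c("TT", "CT", "TC", "CC"),
    rs1042713 = c("AA", "AG", "GG", "GA"),
    rs569108 = c("GG", "AG", "AA", "GA"),
    stringsAsFactors = FALSE)
}
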