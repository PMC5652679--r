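# Independent brute-force oracles used to validate the package's
# implementations. These deliberately use direct, slow formulations.

# Exact HWE test by direct conditional probability: given n genotypes
# and n_rare copies of the rarer allele, P(n_het) follows the
# Levene-Haldane distribution computed here straight from factorials.
oracle_hwe <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  lprob <- vapply(hets, function(h) {
    n_aa <- (n_rare - h) / 2
    n_AA <- n - n_aa - h
    lfactorial(n) - lfactorial(n_AA) - lfactorial(h) - lfactorial(n_aa) +
      h * log(2) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
      lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(lprob)
  p_obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

# Kaplan-Meier survival by direct product over event times.
oracle_km <- function(times, events, at = sort(unique(times[events == 1]))) {
  vapply(at, function(t) {
    s <- 1
    for (u in sort(unique(times[events == 1 & times <= t]))) {
      d <- sum(times == u & events == 1)
      r <- sum(times >= u)
      s <- s * (1 - d / r)
    }
    s
  }, numeric(1))
}

# Two-group log-rank statistic by explicit risk-set enumeration.
oracle_logrank <- function(times, events, group) {
  group <- as.integer(factor(group)) - 1L
  o_minus_e <- 0; v <- 0
  for (u in sort(unique(times[events == 1]))) {
    at_risk <- times >= u
    d <- sum(times == u & events == 1)
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d1 <- sum(times == u & events == 1 & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- o_minus_e^2 / v
  list(chi_square = chi, p_value = pchisq(chi, 1, lower.tail = FALSE))
}

# Cox log partial likelihood (Breslow ties) for a single covariate,
# for grid-search maximization.
oracle_cox_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# AUC by enumeration of all case-control pairs.
oracle_auc <- function(scores, labels) {
  cases <- scores[labels == 1]; controls <- scores[labels == 0]
  total <- 0
  for (x in cases) for (y in controls)
    total <- total + (x > y) + 0.5 * (x == y)
  total / (length(cases) * length(controls))
}

# small deterministic genotype fixture
toy_genotypes <- function(counts, ids = NULL) {
  counts <- as.matrix(counts)
  nv <- ncol(counts)
  variants <- data.frame(
    variant_id = sprintf("v%02d", seq_len(nv)), chromosome = "1",
    position = seq_len(nv) * 100L,
    effect_allele = "A", other_allele = "G", gene = "",
    stringsAsFactors = FALSE)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(counts)))
  genotype_matrix(counts, variants, ids)
}

# minimal valid phenotype table builder
toy_phenotypes <- function(sample_id, bcr_event,
                           followup_months = rep(60, length(sample_id)),
                           gleason = rep(7, length(sample_id))) {
  data.frame(sample_id = sample_id, bcr_event = bcr_event,
             followup_months = followup_months,
             age_years = 66, psa_ng_ml = 8.3, prostate_volume_ml = 37,
             gleason = gleason, ece = 0, svi = 0, bni = 0, psm = 0,
             pt_stage = "pT2", stringsAsFactors = FALSE)
}
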