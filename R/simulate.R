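#' Default simulation variant panel
#'
#' The 16 published recurrence-associated SNPs (control-group MAFs as
#' population frequencies, ln of the published ORs as causal effects)
#' plus `n_null` non-causal filler SNPs at MAFs drawn once, with a
#' fixed internal seed, from Uniform(0.05, 0.5). The filler SNPs give
#' the p-value selection step both signal and noise to work on.
#'
#' @param n_null Number of null SNPs to append (default 84, for a
#'   100-SNP panel).
#' @return Data frame: variant annotation columns plus
#'   `population_maf` and `causal_ln_or`.
#' @export
default_variant_panel <- function(n_null = 84) {
  panel <- bcr_snp_panel()
  sig <- data.frame(panel[c("variant_id", "chromosome", "position",
                            "effect_allele", "other_allele", "gene")],
                    population_maf = panel$maf_controls,
                    causal_ln_or = log(panel$or_published),
                    stringsAsFactors = FALSE)
  if (n_null == 0) return(sig)
  # filler panel is part of the fixed study conditions, not of the
  # per-run randomness: use a private, constant stream
  rs <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(271828L)
    list(maf = stats::runif(n_null, 0.05, 0.5),
         chrom = sample(as.character(1:22), n_null, replace = TRUE))
  })
  nul <- data.frame(
    variant_id = sprintf("null%03d", seq_len(n_null)),
    chromosome = rs$chrom,
    position = 5000000L + 1000L * seq_len(n_null),
    effect_allele = "A", other_allele = "G", gene = "",
    population_maf = rs$maf, causal_ln_or = 0,
    stringsAsFactors = FALSE)
  rbind(sig, nul)
}

#' Cohort simulation configuration
#'
#' Defines the generative model for a synthetic radical-prostatectomy
#' cohort: Hardy-Weinberg genotypes at given population MAFs, a
#' logistic susceptibility model for biochemical recurrence with
#' per-allele log-odds `causal_ln_or`, clinical covariates drawn at
#' the reference cohort prevalences, and proportional-hazards
#' recurrence times sharing the SNP weights through one scale factor.
#'
#' @param n_samples Cohort size (default 912).
#' @param variant_specs Data frame as returned by
#'   [default_variant_panel()].
#' @param baseline_log_odds Intercept of the susceptibility model.
#'   `NULL` (default) calibrates it so the realized event rate matches
#'   `event_rate_target`.
#' @param clinical_log_odds Named vector of susceptibility log-odds for
#'   `age`, `psa`, `gleason_high`, `ece`, `svi`, `psm` (applied to
#'   centred covariates).
#' @param clinical_log_hazard Same names, log-hazard effects on the
#'   recurrence-time model.
#' @param grs_log_hazard Log-hazard per unit of the (centred) true
#'   genetic score; default `log(1.63)`.
#' @param event_rate_target Target marginal recurrence rate
#'   (default 0.232).
#' @param censoring_rate Probability that a would-be event is lost to
#'   follow-up instead (default 0).
#' @param missing_rate Per-genotype missing-call probability
#'   (default 1.3e-4, a 99.987% call rate).
#' @param followup_max_months Administrative censoring horizon
#'   (default 150).
#' @param median_event_months Median event time at the baseline hazard
#'   (default 36).
#' @param calibrate_marginal Pre-compensate the susceptibility weights
#'   so each SNP's *marginal* allelic OR matches `exp(causal_ln_or)`
#'   (default `TRUE`; see Details).
#' @param seed Integer seed; fully determines the cohort.
#'
#' @details A logistic model is non-collapsible: with 16 causal SNPs
#' and clinical effects in the predictor, the marginal (unadjusted,
#' allele-table) OR of each SNP is attenuated by roughly
#' `1/sqrt(1 + 0.35 * var(rest))` relative to its conditional effect.
#' Published allelic ORs are marginal quantities, so by default the
#' generator solves (by quadrature and root finding, deterministically)
#' for latent weights whose implied marginal ORs equal the requested
#' ones; `calibrate_marginal = FALSE` uses the weights as conditional
#' effects directly.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_samples = 912,
                              variant_specs = default_variant_panel(),
                              baseline_log_odds = NULL,
                              clinical_log_odds = c(
                                age = -0.005, psa = 0.02,
                                gleason_high = log(2.4), ece = log(3.1),
                                svi = log(2.6), psm = log(2.0)),
                              clinical_log_hazard = c(
                                age = -0.005, psa = 0.003,
                                gleason_high = log(2.428), ece = log(3.090),
                                svi = log(2.637), psm = log(1.972)),
                              grs_log_hazard = log(1.63),
                              event_rate_target = 0.232,
                              censoring_rate = 0,
                              missing_rate = 1.3e-4,
                              followup_max_months = 150,
                              median_event_months = 36,
                              calibrate_marginal = TRUE,
                              seed = 1L) {
  # population_maf is nominally a minor-allele frequency, but a group
  # frequency may sit slightly above 0.5 when the allele is minor only
  # in the combined cohort (one published SNP has control MAF 0.5121),
  # so the bound is < 1 rather than <= 0.5; 0 is allowed for tests
  stopifnot(n_samples >= 2,
            all(variant_specs$population_maf >= 0),
            all(variant_specs$population_maf < 1),
            event_rate_target > 0, event_rate_target < 1,
            censoring_rate >= 0, censoring_rate <= 1,
            missing_rate >= 0, missing_rate < 1)
  validate_variants(variant_specs[c("variant_id", "chromosome", "position",
                                    "effect_allele", "other_allele",
                                    "gene")])
  # covariate variances under the generative clinical distributions
  covar_var <- c(age = 6.63^2,
                 psa = (exp(0.75^2) - 1) * exp(2 * log(8.3) + 0.75^2),
                 gleason_high = 0.151 * 0.849, ece = 0.332 * 0.668,
                 svi = 0.103 * 0.897, psm = 0.307 * 0.693)
  lo <- clinical_log_odds[names(covar_var)]
  lo[is.na(lo)] <- 0
  clinical_var <- sum(lo^2 * covar_var)
  variant_specs$latent_ln_or <-
    if (calibrate_marginal)
      calibrate_causal_weights(variant_specs, clinical_var,
                               event_rate_target, baseline_log_odds)
    else variant_specs$causal_ln_or
  structure(list(n_samples = as.integer(n_samples),
                 variant_specs = variant_specs,
                 baseline_log_odds = baseline_log_odds,
                 clinical_log_odds = clinical_log_odds,
                 clinical_log_hazard = clinical_log_hazard,
                 grs_log_hazard = grs_log_hazard,
                 event_rate_target = event_rate_target,
                 censoring_rate = censoring_rate,
                 missing_rate = missing_rate,
                 followup_max_months = followup_max_months,
                 median_event_months = median_event_months,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# 32-node Gauss-Hermite quadrature of E[f(Z)], Z ~ N(0, 1)
gauss_hermite_mean <- function(f, nodes = 32) {
  # Golub-Welsch: eigen-decomposition of the Hermite Jacobi matrix
  i <- seq_len(nodes - 1)
  J <- matrix(0, nodes, nodes)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  x <- e$values * sqrt(2)                    # probabilists' nodes
  w <- e$vectors[1, ]^2                      # weights sum to 1
  sum(w * f(x))
}

# marginal allelic ln(OR) of one SNP with latent per-allele effect w,
# population MAF q, intercept b0, and an independent N(0, sigma2_rest)
# remainder in the linear predictor
marginal_allelic_lnor <- function(w, q, b0, sigma2_rest) {
  pg <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  s <- sqrt(max(sigma2_rest, 0))
  p_case <- vapply(0:2, function(g)
    gauss_hermite_mean(function(z)
      stats::plogis(b0 + w * (g - 2 * q) + s * z)), numeric(1))
  pr_case <- sum(pg * p_case)
  p1 <- sum((0:2) / 2 * pg * p_case) / pr_case
  p0 <- sum((0:2) / 2 * pg * (1 - p_case)) / (1 - pr_case)
  log((p1 / (1 - p1)) / (p0 / (1 - p0)))
}

# Pre-compensate the susceptibility weights so the *marginal* allelic
# odds ratio of each SNP matches its target: a logistic model is
# non-collapsible, so with many causal terms the marginal OR is
# attenuated relative to the conditional one. Deterministic
# (quadrature + root finding, no randomness).
calibrate_causal_weights <- function(variant_specs, clinical_var,
                                     event_rate_target,
                                     baseline_log_odds = NULL) {
  target <- variant_specs$causal_ln_or
  q <- variant_specs$population_maf
  w <- target
  active <- which(target != 0 & q > 0 & q < 1)
  if (!length(active)) return(target)
  for (iter in 1:4) {
    gvar <- w^2 * 2 * q * (1 - q)
    s2_tot <- sum(gvar) + clinical_var
    b0 <- if (is.null(baseline_log_odds)) {
      stats::uniroot(function(b)
        gauss_hermite_mean(function(z)
          stats::plogis(b + sqrt(s2_tot) * z)) - event_rate_target,
        c(-20, 20))$root
    } else baseline_log_odds
    for (j in active) {
      s2_rest <- s2_tot - gvar[j]
      w[j] <- stats::uniroot(function(ww)
        marginal_allelic_lnor(ww, q[j], b0, s2_rest) - target[j],
        interval = sort(c(0.2 * target[j], 3 * target[j])),
        extendInt = "yes")$root
    }
  }
  w
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Each variant's genotype is drawn independently with probabilities
#' `((1-q)^2, 2q(1-q), q^2)` at its `population_maf` q; missing calls
#' are then applied independently at `missing_rate`.
#'
#' @param config A [simulation_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  vs <- config$variant_specs
  counts <- vapply(vs$population_maf, function(q) {
    sample(0:2, n, replace = TRUE,
           prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
  }, integer(n))
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(counts)) < config$missing_rate,
                   nrow = n)
    counts[miss] <- NA_integer_
  }
  genotype_matrix(counts,
                  vs[c("variant_id", "chromosome", "position",
                       "effect_allele", "other_allele", "gene")],
                  sprintf("S%04d", seq_len(n)))
}

# centred genetic contribution to a linear predictor; missing calls
# contribute their expectation (0 after centring)
centred_genetic_eta <- function(genotypes, weights, mafs) {
  g <- sweep(genotypes$counts, 2, 2 * mafs)
  g[is.na(g)] <- 0
  as.numeric(g %*% weights)
}

#' Simulate recurrence outcomes and clinical covariates
#'
#' Clinical covariates are drawn at the reference cohort's marginal
#' distributions (age ~ N(66.2, 6.6); PSA log-normal with median 8.3;
#' ECE 33.2%, SVI 10.3%, BNI 4.4%, PSM 30.7%; Gleason 6/7/8/9 at
#' 6.8/78.1/4.6/10.5%; pT2/pT3/pT4 at 65.6/33.0/1.4%), independent of
#' genotype. Recurrence status is Bernoulli on the logistic linear
#' predictor (centred genetic + centred clinical terms + intercept);
#' event times are exponential with the shared proportional-hazards
#' predictor, censoring times uniform on (12, `followup_max_months`).
#'
#' @param genotypes Output of [simulate_genotypes()] under the same
#'   config.
#' @param config The same [simulation_config()].
#' @return A phenotype data frame (see [read_phenotypes()]).
#' @export
simulate_outcomes <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genotypes, "genotype_matrix"))
  if (!identical(genotypes$variants$variant_id,
                 config$variant_specs$variant_id))
    stop("genotypes do not match config variant panel", call. = FALSE)
  n <- length(genotypes$sample_ids)
  set.seed(config$seed + 1L)

  age <- stats::rnorm(n, 66.24, 6.63)
  psa <- stats::rlnorm(n, log(8.3), 0.75)
  volume <- pmax(stats::rnorm(n, 36.9, 16.0), 10)
  gleason <- sample(c(6L, 7L, 8L, 9L), n, replace = TRUE,
                    prob = c(0.068, 0.781, 0.046, 0.105))
  ece <- stats::rbinom(n, 1, 0.332)
  svi <- stats::rbinom(n, 1, 0.103)
  bni <- stats::rbinom(n, 1, 0.044)
  psm <- stats::rbinom(n, 1, 0.307)
  pt_stage <- sample(PT_STAGES, n, replace = TRUE,
                     prob = c(0.656, 0.330, 0.014))

  clin <- cbind(age = age - 66.24, psa = psa - exp(log(8.3) + 0.75^2 / 2),
                gleason_high = (gleason >= 8) - 0.151,
                ece = ece - 0.332, svi = svi - 0.103, psm = psm - 0.307)
  lo <- config$clinical_log_odds[colnames(clin)]
  lh <- config$clinical_log_hazard[colnames(clin)]
  lo[is.na(lo)] <- 0; lh[is.na(lh)] <- 0

  vs <- config$variant_specs
  eta_gen <- centred_genetic_eta(genotypes, vs$latent_ln_or,
                                 vs$population_maf)
  eta_x <- eta_gen + as.numeric(clin %*% lo)
  b0 <- config$baseline_log_odds
  if (is.null(b0)) {
    target <- config$event_rate_target
    b0 <- stats::uniroot(function(b)
      mean(stats::plogis(b + eta_x)) - target,
      interval = c(-20, 20))$root
  }
  p_event <- stats::plogis(b0 + eta_x)
  event <- stats::rbinom(n, 1, p_event)
  if (config$censoring_rate > 0)
    event <- event * stats::rbinom(n, 1, 1 - config$censoring_rate)

  # proportional-hazards predictor shares the SNP weights through one
  # scale factor: grs_log_hazard per unit of the causal score
  eta_h <- config$grs_log_hazard * eta_gen + as.numeric(clin %*% lh)
  lambda0 <- log(2) / config$median_event_months
  t_event <- stats::rexp(n, rate = lambda0 * exp(eta_h))
  t_cens <- stats::runif(n, 12, config$followup_max_months)
  followup <- ifelse(event == 1,
                     pmin(pmax(t_event, 0.5), config$followup_max_months),
                     t_cens)

  validate_phenotypes(data.frame(
    sample_id = genotypes$sample_ids, bcr_event = event,
    followup_months = followup, age_years = age, psa_ng_ml = psa,
    prostate_volume_ml = volume, gleason = gleason, ece = ece,
    svi = svi, bni = bni, psm = psm, pt_stage = pt_stage,
    stringsAsFactors = FALSE))
}

#' Simulate a full cohort
#'
#' @param config A [simulation_config()].
#' @return List: `genotypes` ([genotype_matrix()]), `phenotypes`
#'   (data frame), `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  genotypes <- simulate_genotypes(config)
  phenotypes <- simulate_outcomes(genotypes, config)
  list(genotypes = genotypes, phenotypes = phenotypes, config = config)
}
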