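#' Quality-control thresholds
#'
#' Defaults follow common exome-chip practice: markers are dropped when
#' monomorphic, when more than 5% of calls are missing, or when the
#' exact Hardy-Weinberg test gives p below 1e-6; samples are dropped
#' when their call rate is below 95%, when heterozygosity lies more
#' than 3 SD from the cohort mean, or when a pair shows cryptic
#' relatedness (identity-by-state excess above `relatedness_max_ibs_prop`).
#'
#' @param marker_max_missing Maximum per-marker missing-call fraction.
#' @param sample_min_call_rate Minimum per-sample call rate.
#' @param hwe_alpha Hardy-Weinberg exact-test significance level.
#' @param het_sd_limit Heterozygosity outlier limit in SD units.
#' @param relatedness_max_ibs_prop Ceiling on the pairwise relatedness
#'   coefficient (0 for unrelated pairs, 1 for duplicates).
#' @param drop_monomorphic Drop markers with no variation?
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(marker_max_missing = 0.05,
                          sample_min_call_rate = 0.95,
                          hwe_alpha = 1e-6,
                          het_sd_limit = 3.0,
                          relatedness_max_ibs_prop = 0.1875,
                          drop_monomorphic = TRUE) {
  stopifnot(marker_max_missing > 0, marker_max_missing < 1,
            sample_min_call_rate > 0, sample_min_call_rate < 1,
            hwe_alpha >= 0, hwe_alpha < 1, het_sd_limit > 0,
            relatedness_max_ibs_prop > 0)
  structure(list(marker_max_missing = marker_max_missing,
                 sample_min_call_rate = sample_min_call_rate,
                 hwe_alpha = hwe_alpha,
                 het_sd_limit = het_sd_limit,
                 relatedness_max_ibs_prop = relatedness_max_ibs_prop,
                 drop_monomorphic = drop_monomorphic),
            class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test for one biallelic marker: conditional on the
#' observed allele counts, the p-value sums the probabilities of all
#' heterozygote counts (same parity as observed) whose conditional
#' probability does not exceed that of the observed count. No mid-p
#' correction is applied.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (hom. reference,
#'   heterozygote, hom. alternate).
#' @return p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(1469, 138, 5)   # deficit of heterozygotes
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(length(n_hom_ref) == 1, length(n_het) == 1,
            length(n_hom_alt) == 1)
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be nonnegative integers", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("no genotypes observed", call. = FALSE)
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het   # rarer-allele count
  if (n_rare == 0) return(1)                        # monomorphic
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # log conditional probability of each attainable heterozygote count,
  # via the recurrence P(h+2)/P(h) = 4*n_aa(h)*n_AA(h) / ((h+2)*(h+1))
  lp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    n_aa <- (n_rare - h) / 2
    n_AA <- n - n_aa - h
    lp[k] <- lp[k - 1] + log(4 * n_aa * n_AA) - log((h + 2) * (h + 1))
  }
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  p_obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Per-marker summary statistics
#'
#' @param genotypes A [genotype_matrix()].
#' @return Data frame with one row per marker: `variant_id`,
#'   `call_rate`, `maf` (folded to the minor allele), `hwe_p`,
#'   `monomorphic`.
#' @export
marker_stats <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            length(genotypes$sample_ids) >= 1)
  g <- genotypes$counts
  n_obs <- colSums(!is.na(g))
  call_rate <- n_obs / nrow(g)
  eaf <- ifelse(n_obs > 0, colSums(g, na.rm = TRUE) / (2 * n_obs), NA_real_)
  maf <- pmin(eaf, 1 - eaf)
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    gj <- g[, j]
    gj <- gj[!is.na(gj)]
    if (!length(gj)) return(NA_real_)
    hwe_exact_test(sum(gj == 0), sum(gj == 1), sum(gj == 2))
  }, numeric(1))
  data.frame(variant_id = genotypes$variants$variant_id,
             call_rate = call_rate, maf = maf, hwe_p = hwe_p,
             monomorphic = !is.na(maf) & maf == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample summary statistics
#'
#' @param genotypes A [genotype_matrix()].
#' @return Data frame with one row per sample: `sample_id`,
#'   `call_rate`, `heterozygosity` (fraction of non-missing genotypes
#'   that are heterozygous; `NA` when all calls are missing).
#' @export
sample_stats <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            nrow(genotypes$variants) >= 1)
  g <- genotypes$counts
  n_obs <- rowSums(!is.na(g))
  data.frame(sample_id = genotypes$sample_ids,
             call_rate = n_obs / ncol(g),
             heterozygosity = ifelse(n_obs > 0,
                                     rowSums(g == 1, na.rm = TRUE) / n_obs,
                                     NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Pairwise relatedness as excess identity-by-state over its random-mating
# expectation, scaled so unrelated pairs sit near 0 and duplicates near 1.
# Returns pairs at or above the ceiling. Vectorized via genotype indicator
# matrices: |gi - gj| summed over markers is a sum of cross-products.
related_pairs <- function(genotypes, ceiling) {
  empty <- data.frame(sample_1 = character(), sample_2 = character(),
                      relatedness = numeric(), stringsAsFactors = FALSE)
  g <- genotypes$counts
  n <- nrow(g)
  if (n < 2 || ncol(g) < 1) return(empty)
  obs <- !is.na(g)
  ind <- lapply(0:2, function(v) {
    m <- (g == v) & obs
    storage.mode(m) <- "double"
    m
  })
  o <- obs; storage.mode(o) <- "double"
  n_obs <- tcrossprod(o)                       # co-observed markers
  absdiff <- tcrossprod(ind[[1]], ind[[2]]) + tcrossprod(ind[[2]], ind[[1]]) +
    tcrossprod(ind[[2]], ind[[3]]) + tcrossprod(ind[[3]], ind[[2]]) +
    2 * (tcrossprod(ind[[1]], ind[[3]]) + tcrossprod(ind[[3]], ind[[1]]))
  sim <- 1 - (absdiff / pmax(n_obs, 1)) / 2
  # expected IBS similarity per marker for an unrelated pair under HWE;
  # similarity weights: same genotype 1, one allele apart 0.5, opposite 0
  p <- colSums(g, na.rm = TRUE) / (2 * pmax(colSums(obs), 1))
  f0 <- (1 - p)^2; f1 <- 2 * p * (1 - p); f2 <- p^2
  e_sim <- f0^2 + f1^2 + f2^2 + (f0 * f1 + f1 * f2) * 2 * 0.5
  e_pair <- (o %*% (e_sim * t(o))) / pmax(n_obs, 1)
  r <- (sim - e_pair) / (1 - e_pair)
  r[n_obs == 0] <- NA
  # per-pair standard error of the similarity mean, so that a pair is
  # flagged only when its 3*SE lower bound clears the ceiling: with few
  # markers the estimator is noisy and only near-duplicates are callable
  cross02 <- tcrossprod(ind[[1]], ind[[3]]) + tcrossprod(ind[[3]], ind[[1]])
  sum_s2 <- n_obs - absdiff + (absdiff + 2 * cross02) / 4
  var_s <- pmax(sum_s2 / pmax(n_obs, 1) - sim^2, 0)
  se_r <- sqrt(var_s / pmax(n_obs, 1)) / (1 - e_pair)
  hit <- which(upper.tri(r) & !is.na(r) & (r - 3 * se_r) >= ceiling,
               arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  data.frame(sample_1 = genotypes$sample_ids[hit[, 1]],
             sample_2 = genotypes$sample_ids[hit[, 2]],
             relatedness = r[hit], stringsAsFactors = FALSE)
}

#' Apply marker and sample quality control
#'
#' Samples are screened first (call rate, heterozygosity outliers,
#' cryptic relatedness — the lower-call-rate member of each related
#' pair is dropped), then markers are screened on the surviving samples
#' (monomorphic, missingness, Hardy-Weinberg).
#'
#' @param genotypes A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return List of class `qc_result`: `genotypes` (filtered),
#'   `markers` and `samples` (per-unit stats with `kept` flag and
#'   `reason`), `summary` (before/after counts).
#' @export
apply_qc <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(thresholds, "qc_thresholds"))
  th <- thresholds

  ss <- sample_stats(genotypes)
  ss$reason <- ""
  low_cr <- ss$call_rate < th$sample_min_call_rate
  ss$reason[low_cr] <- "call_rate"
  het <- ss$heterozygosity
  mu <- mean(het, na.rm = TRUE); sdev <- stats::sd(het, na.rm = TRUE)
  if (!is.na(sdev) && sdev > 0) {
    out_het <- !is.na(het) & abs(het - mu) > th$het_sd_limit * sdev
    ss$reason[out_het & ss$reason == ""] <- "heterozygosity"
  }
  surv1 <- ss$reason == ""
  rel <- related_pairs(subset_genotypes(genotypes, samples = which(surv1)),
                       th$relatedness_max_ibs_prop)
  if (nrow(rel)) {
    for (k in seq_len(nrow(rel))) {
      pair <- c(rel$sample_1[k], rel$sample_2[k])
      i <- match(pair, ss$sample_id)
      if (any(ss$reason[i] != "")) next       # already gone
      drop <- i[which.min(ss$call_rate[i])]
      ss$reason[drop] <- "relatedness"
    }
  }
  ss$kept <- ss$reason == ""
  kept_samples <- which(ss$kept)
  if (!length(kept_samples))
    warning("all samples removed by QC", call. = FALSE)

  g2 <- subset_genotypes(genotypes, samples = kept_samples)
  ms <- marker_stats(g2)
  ms$reason <- ""
  if (th$drop_monomorphic)
    ms$reason[ms$monomorphic | is.na(ms$maf)] <- "monomorphic"
  cr_fail <- (1 - ms$call_rate) > th$marker_max_missing
  ms$reason[cr_fail & ms$reason == ""] <- "call_rate"
  hwe_fail <- !is.na(ms$hwe_p) & ms$hwe_p < th$hwe_alpha
  ms$reason[hwe_fail & ms$reason == ""] <- "hwe"
  ms$kept <- ms$reason == ""
  if (!any(ms$kept))
    warning("all markers removed by QC", call. = FALSE)

  out <- subset_genotypes(g2, variants = which(ms$kept))
  structure(list(
    genotypes = out,
    markers = ms[c("variant_id", "call_rate", "maf", "hwe_p",
                   "monomorphic", "kept", "reason")],
    samples = ss[c("sample_id", "call_rate", "heterozygosity",
                   "kept", "reason")],
    summary = list(n_samples_before = length(genotypes$sample_ids),
                   n_samples_after = length(out$sample_ids),
                   n_markers_before = nrow(genotypes$variants),
                   n_markers_after = nrow(out$variants))),
    class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  s <- x$summary
  cat("<qc_result> samples ", s$n_samples_before, " -> ", s$n_samples_after,
      "; markers ", s$n_markers_before, " -> ", s$n_markers_after, "\n",
      sep = "")
  invisible(x)
}
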