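#' Group-wise minor-allele frequencies
#'
#' Effect-allele frequency among non-missing genotypes within the
#' no-recurrence (control) and recurrence (case) groups. When the
#' effect allele is not the minor allele in the combined sample, the
#' orientation is flipped (counts reversed as 2 - g) and the flip
#' recorded, so downstream odds ratios always refer to the cohort
#' minor allele.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotypes Phenotype data frame (see [read_phenotypes()]).
#' @return Data frame per variant: `variant_id`, `maf_controls`,
#'   `maf_cases`, `flipped`, `n_controls`, `n_cases`,
#'   `empty_group` flag (a group with zero non-missing calls).
#' @export
group_maf <- function(genotypes, phenotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  phenotypes <- validate_phenotypes(phenotypes)
  m <- match(genotypes$sample_ids, phenotypes$sample_id)
  if (anyNA(m))
    stop("phenotypes missing for sample(s): ",
         paste(genotypes$sample_ids[is.na(m)], collapse = ", "),
         call. = FALSE)
  status <- phenotypes$bcr_event[m]
  if (!any(status == 1) || !any(status == 0))
    stop("need at least one case and one control", call. = FALSE)
  g <- genotypes$counts
  freq_in <- function(rows) {
    n_obs <- colSums(!is.na(g[rows, , drop = FALSE]))
    ifelse(n_obs > 0,
           colSums(g[rows, , drop = FALSE], na.rm = TRUE) / (2 * n_obs),
           NA_real_)
  }
  f_con <- freq_in(status == 0)
  f_cas <- freq_in(status == 1)
  n_obs_all <- colSums(!is.na(g))
  f_all <- ifelse(n_obs_all > 0, colSums(g, na.rm = TRUE) / (2 * n_obs_all),
                  NA_real_)
  flipped <- !is.na(f_all) & f_all > 0.5
  f_con[flipped] <- 1 - f_con[flipped]
  f_cas[flipped] <- 1 - f_cas[flipped]
  data.frame(variant_id = genotypes$variants$variant_id,
             maf_controls = f_con, maf_cases = f_cas, flipped = flipped,
             n_controls = sum(status == 0), n_cases = sum(status == 1),
             empty_group = is.na(f_con) | is.na(f_cas),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Allelic odds ratio from group minor-allele frequencies
#'
#' Odds ratio of carrying the effect allele in cases versus controls:
#' `OR = [p1/(1-p1)] / [p0/(1-p0)]`. The standard error of ln(OR) uses
#' the 2x2 allele table with allele counts reconstructed as
#' `round(2n * MAF)`; a 0.5 continuity correction is applied (and
#' flagged) when any cell is zero. The 95% CI is
#' `exp(lnOR +/- 1.96 SE)` and the p-value the two-sided normal tail
#' of `lnOR / SE`.
#'
#' @param maf_controls,maf_cases Effect-allele frequencies in the
#'   no-event and event groups.
#' @param n_controls,n_cases Group sample sizes (subjects, not alleles).
#' @return One-row data frame: `or_estimate`, `ln_or`, `se_ln_or`,
#'   `ci_low`, `ci_high`, `p_value`, `continuity_corrected`.
#' @export
#' @examples
#' allelic_or(0.05824, 0.1152, 700, 212)   # OR about 2.106
allelic_or <- function(maf_controls, maf_cases, n_controls, n_cases) {
  stopifnot(maf_controls >= 0, maf_controls <= 1,
            maf_cases >= 0, maf_cases <= 1,
            n_controls >= 1, n_cases >= 1)
  a <- round(2 * n_cases * maf_cases)        # effect alleles, cases
  b <- 2 * n_cases - a
  c <- round(2 * n_controls * maf_controls)  # effect alleles, controls
  d <- 2 * n_controls - c
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    or <- (a / b) / (c / d)
  } else {
    # point estimate straight from the frequencies (not re-rounded)
    or <- (maf_cases / (1 - maf_cases)) / (maf_controls / (1 - maf_controls))
  }
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ln_or <- log(or)
  z <- ln_or / se
  data.frame(or_estimate = or, ln_or = ln_or, se_ln_or = se,
             ci_low = exp(ln_or - 1.96 * se),
             ci_high = exp(ln_or + 1.96 * se),
             p_value = 2 * stats::pnorm(-abs(z)),
             continuity_corrected = corrected,
             stringsAsFactors = FALSE)
}

#' Logistic regression of a binary outcome on allele counts
#'
#' Additive-coding (0/1/2) maximum-likelihood logistic fit via
#' iteratively reweighted least squares, with Wald CI and p-value for
#' the allele-count coefficient. Complete separation is flagged rather
#' than returned as a silent estimate.
#'
#' @param counts Per-sample effect-allele counts (missing allowed;
#'   dropped casewise).
#' @param outcome Binary outcome vector.
#' @param covariates Optional data frame of numeric adjustment columns.
#' @return One-row data frame: `ln_or`, `se_ln_or`, `or_estimate`,
#'   `ci_low`, `ci_high`, `p_value`, `converged`.
#' @export
logistic_fit <- function(counts, outcome, covariates = NULL) {
  stopifnot(length(counts) == length(outcome))
  if (length(unique(stats::na.omit(outcome))) < 2)
    stop("outcome must take two values", call. = FALSE)
  if (length(unique(stats::na.omit(counts))) < 2)
    stop("allele count predictor is constant", call. = FALSE)
  dat <- data.frame(.y = outcome, .g = counts)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  cf <- summary(fit)$coefficients
  b <- cf[".g", "Estimate"]; se <- cf[".g", "Std. Error"]
  # separation: runaway coefficient or fitted probabilities at 0/1
  separated <- !fit$converged || abs(b) > 15 ||
    any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
  data.frame(ln_or = b, se_ln_or = se, or_estimate = exp(b),
             ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
             p_value = cf[".g", "Pr(>|z|)"],
             converged = fit$converged && !separated,
             stringsAsFactors = FALSE)
}

#' Per-SNP case-control association scan
#'
#' Runs the chosen association method for every marker against the
#' recurrence indicator and returns results sorted by p-value. Markers
#' that cannot be tested (monomorphic, empty group) are returned with
#' `flag` set and `NA` estimates; the scan never aborts on one marker.
#'
#' @param genotypes A [genotype_matrix()] (after QC).
#' @param phenotypes Phenotype data frame.
#' @param method `"allelic"` (2x2 allele-table odds ratio, default) or
#'   `"logistic"` (additive logistic regression).
#' @return Data frame of class `assoc_results`, one row per marker:
#'   variant annotation, `maf_controls`, `maf_cases`, `or_estimate`,
#'   `ci_low`, `ci_high`, `ln_or`, `se_ln_or`, `p_value`, `method`,
#'   `flag` ("" when clean), sorted by ascending `p_value`.
#' @export
run_association <- function(genotypes, phenotypes,
                            method = c("allelic", "logistic")) {
  method <- match.arg(method)
  phenotypes <- validate_phenotypes(phenotypes)
  gm <- group_maf(genotypes, phenotypes)
  m <- match(genotypes$sample_ids, phenotypes$sample_id)
  status <- phenotypes$bcr_event[m]
  res <- vector("list", nrow(gm))
  for (j in seq_len(nrow(gm))) {
    row <- c(genotypes$variants[j, , drop = FALSE],
             gm[j, c("maf_controls", "maf_cases", "flipped")])
    est <- data.frame(or_estimate = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, ln_or = NA_real_,
                      se_ln_or = NA_real_, p_value = NA_real_)
    flag <- ""
    if (gm$empty_group[j]) {
      flag <- "empty_group"
    } else if (min(gm$maf_controls[j], gm$maf_cases[j],
                   1 - gm$maf_controls[j], 1 - gm$maf_cases[j]) == 0 &&
               gm$maf_controls[j] == gm$maf_cases[j]) {
      flag <- "monomorphic"
    } else if (method == "allelic") {
      a <- allelic_or(gm$maf_controls[j], gm$maf_cases[j],
                      gm$n_controls[j], gm$n_cases[j])
      est <- a[c("or_estimate", "ci_low", "ci_high", "ln_or",
                 "se_ln_or", "p_value")]
      if (a$continuity_corrected) flag <- "continuity_corrected"
    } else {
      g <- genotypes$counts[, j]
      if (gm$flipped[j]) g <- 2L - g
      est <- tryCatch({
        f <- logistic_fit(g, status)
        if (!f$converged && flag == "") flag <- "non_converged"
        f[c("or_estimate", "ci_low", "ci_high", "ln_or",
            "se_ln_or", "p_value")]
      }, error = function(e) { flag <<- "fit_error"; est })
    }
    res[[j]] <- cbind(as.data.frame(row, stringsAsFactors = FALSE), est,
                      data.frame(method = method, flag = flag,
                                 stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$p_value, out$variant_id, na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("assoc_results", class(out))
  out
}

#' Select the GRS panel at a p-value threshold
#'
#' Keeps results with `p_value` strictly below `alpha`, ordered by
#' ascending p with ties broken by variant id. Bonferroni and
#' Benjamini-Hochberg adjusted p-values are attached for reporting
#' only; they play no role in selection.
#'
#' @param results An `assoc_results` data frame from
#'   [run_association()] (or any data frame with `variant_id` and
#'   `p_value`).
#' @param alpha Selection threshold (default 1e-3, strict `<`).
#' @return The selected subset, with `p_bonferroni` and `p_bh` columns.
#' @export
select_snps <- function(results, alpha = 1e-3) {
  stopifnot(nrow(results) >= 1, alpha > 0)
  results$p_bonferroni <- stats::p.adjust(results$p_value, "bonferroni")
  results$p_bh <- stats::p.adjust(results$p_value, "BH")
  keep <- !is.na(results$p_value) & results$p_value < alpha
  out <- results[keep, , drop = FALSE]
  out <- out[order(out$p_value, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) warning("no SNPs pass p < ", alpha, call. = FALSE)
  out
}

#' Write a Manhattan-ready table of per-SNP p-values
#'
#' @param results `assoc_results` data frame.
#' @param path Output TSV path (columns chrom, pos, variant_id, p).
#' @export
write_manhattan_tsv <- function(results, path) {
  tab <- data.frame(chrom = results$chromosome, pos = results$position,
                    variant_id = results$variant_id, p = results$p_value)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
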