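#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic: the probability
#' that a random case outranks a random control, ties counted one half.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcome (1 = case).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both outcome classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: for each case, the placement value
# against all controls (and vice versa). psi = 1, 1/2, 0.
delong_components <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  v10 <- vapply(x, function(xi)
    (sum(xi > y) + 0.5 * sum(xi == y)) / n, numeric(1))
  v01 <- vapply(y, function(yj)
    (sum(x > yj) + 0.5 * sum(x == yj)) / m, numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired comparison of two correlated AUCs
#'
#' Tests whether two risk scores computed on the same subjects have
#' equal AUC, using the structural-components (DeLong-type) estimate
#' of the variance of the AUC difference (`method = "delong"`), or a
#' subject-resampling bootstrap (`method = "bootstrap"`).
#'
#' @param scores_a,scores_b Risk scores for the same subjects.
#' @param labels Binary outcome (1 = case).
#' @param method `"delong"` or `"bootstrap"`.
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the bootstrap resampling.
#' @return List of class `roc_comparison`: `auc_a`, `auc_b`,
#'   `auc_diff` (b - a), `se_diff`, `ci_diff`, `p_value`, `n`,
#'   `method`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, labels,
                               method = c("delong", "bootstrap"),
                               n_boot = 2000, seed = 1L) {
  method <- match.arg(method)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must have equal length",
         call. = FALSE)
  stopifnot(all(labels %in% 0:1), sum(labels) > 0, sum(1 - labels) > 0)
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  auc_a <- ca$auc; auc_b <- cb$auc
  diff <- auc_b - auc_a
  if (identical(scores_a, scores_b) || all(scores_a == scores_b)) {
    out <- list(auc_a = auc_a, auc_b = auc_b, auc_diff = 0,
                se_diff = 0, ci_diff = c(0, 0), p_value = 1,
                n = length(labels), method = method)
    class(out) <- "roc_comparison"
    return(out)
  }
  if (method == "delong") {
    m <- length(ca$v10); n <- length(ca$v01)
    s10 <- stats::var(cbind(ca$v10, cb$v10))
    s01 <- stats::var(cbind(ca$v01, cb$v01))
    # var(diff) with contrast L = (-1, 1)
    L <- c(-1, 1)
    v <- as.numeric(t(L) %*% (s10 / m + s01 / n) %*% L)
    se <- sqrt(max(v, 0))
    z <- if (se > 0) diff / se else 0
    p <- if (se > 0) 2 * stats::pnorm(-abs(z)) else 1
    ci <- diff + c(-1.96, 1.96) * se
  } else {
    set.seed(seed)
    n_all <- length(labels)
    boots <- replicate(n_boot, {
      repeat {
        idx <- sample.int(n_all, replace = TRUE)
        if (any(labels[idx] == 1) && any(labels[idx] == 0)) break
      }
      roc_auc(scores_b[idx], labels[idx]) -
        roc_auc(scores_a[idx], labels[idx])
    })
    se <- stats::sd(boots)
    ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    z <- if (se > 0) diff / se else 0
    p <- if (se > 0) 2 * stats::pnorm(-abs(z)) else 1
  }
  out <- list(auc_a = auc_a, auc_b = auc_b, auc_diff = diff,
              se_diff = se, ci_diff = ci, p_value = min(1, p),
              n = length(labels), method = method)
  class(out) <- "roc_comparison"
  out
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf(
    "<roc_comparison> AUC %.4f vs %.4f (diff %+.4f, p = %.4g, %s, n = %d)\n",
    x$auc_a, x$auc_b, x$auc_diff, x$p_value, x$method, x$n))
  invisible(x)
}

#' In-sample predictions of the clinical and clinico-genetic logistic models
#'
#' Fits two nested logistic regressions of the recurrence indicator:
#' the clinical model (age, PSA, high-grade Gleason, ECE, SVI, PSM)
#' and the clinico-genetic model adding the GRS, and returns each
#' model's in-sample predicted probabilities for ROC analysis. No
#' cross-validation is performed (in-sample AUCs are optimistic; see
#' the vignette).
#'
#' @param phenotypes Phenotype data frame.
#' @param scores `grs_scores` data frame.
#' @param gleason_coding `"binary"` or `"ordinal"` (as in
#'   [fit_paper_models()]).
#' @return List: `prob_clinical`, `prob_genetic`, `labels`,
#'   `separation` flag, and the two `glm` fits.
#' @export
fit_evaluation_models <- function(phenotypes, scores,
                                  gleason_coding = c("binary", "ordinal")) {
  gleason_coding <- match.arg(gleason_coding)
  phenotypes <- validate_phenotypes(phenotypes)
  m <- match(phenotypes$sample_id, scores$sample_id)
  if (anyNA(m))
    stop("scores missing for sample(s): ",
         paste(phenotypes$sample_id[is.na(m)], collapse = ", "),
         call. = FALSE)
  gl <- if (gleason_coding == "binary") as.numeric(phenotypes$gleason >= 8)
        else phenotypes$gleason
  dat <- data.frame(y = phenotypes$bcr_event,
                    age = phenotypes$age_years, psa = phenotypes$psa_ng_ml,
                    gleason = gl, ece = phenotypes$ece,
                    svi = phenotypes$svi, psm = phenotypes$psm,
                    grs = scores$grs[m])
  fit_c <- suppressWarnings(
    stats::glm(y ~ age + psa + gleason + ece + svi + psm,
               data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  fit_g <- suppressWarnings(
    stats::glm(y ~ age + psa + gleason + ece + svi + psm + grs,
               data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  sep <- function(f) !f$converged || any(f$fitted.values > 1 - 1e-10) ||
    any(f$fitted.values < 1e-10)
  list(prob_clinical = stats::fitted(fit_c),
       prob_genetic = stats::fitted(fit_g),
       labels = dat$y,
       separation = sep(fit_c) || sep(fit_g),
       fit_clinical = fit_c, fit_genetic = fit_g)
}

#' Incremental-AUC evaluation of the GRS
#'
#' Convenience wrapper: fits both logistic models via
#' [fit_evaluation_models()] and compares their in-sample AUCs with
#' [compare_auc_paired()].
#'
#' @inheritParams fit_evaluation_models
#' @param method Passed to [compare_auc_paired()].
#' @return A `roc_comparison` (clinical = a, clinico-genetic = b) with
#'   an extra `separation` element.
#' @export
evaluate_grs_gain <- function(phenotypes, scores,
                              gleason_coding = "binary",
                              method = "delong") {
  fits <- fit_evaluation_models(phenotypes, scores, gleason_coding)
  cmp <- compare_auc_paired(fits$prob_clinical, fits$prob_genetic,
                            fits$labels, method = method)
  cmp$separation <- fits$separation
  cmp
}

#' Write ROC curve points as TSV
#'
#' @param scores,labels As in [roc_auc()].
#' @param path Output TSV (threshold, sensitivity, one_minus_specificity).
#' @export
write_roc_tsv <- function(scores, labels, path) {
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), numeric(1))
  utils::write.table(
    data.frame(threshold = thr, sensitivity = sens,
               one_minus_specificity = fpr),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
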