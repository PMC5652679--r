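#' Kaplan-Meier product-limit estimate
#'
#' @param times Positive follow-up times (months).
#' @param events Binary event indicator (1 = biochemical recurrence
#'   observed, 0 = censored).
#' @return Data frame of class `km_curve`, one row per distinct event
#'   time: `time`, `at_risk`, `events`, `survival`, `std_err`
#'   (Greenwood). Survival starts at 1 before the first event time.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1,
            all(times > 0), all(events %in% 0:1))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log")
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep], at_risk = fit$n.risk[keep],
                    events = fit$n.event[keep], survival = fit$surv[keep],
                    std_err = fit$std.err[keep] * fit$surv[keep])
  class(out) <- c("km_curve", class(out))
  out
}

#' Survival probability at a time point
#'
#' Right-continuous step-function lookup on a [km_estimate()] curve,
#' e.g. the 10-year recurrence-free rate at `t = 120` months.
#'
#' @param curve A `km_curve`.
#' @param t Time point(s).
#' @return Survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    past <- curve$time <= tt
    if (!any(past)) 1 else curve$survival[max(which(past))]
  }, numeric(1))
}

#' Log-rank test between survival curves
#'
#' Standard k-group log-rank statistic with hypergeometric variance;
#' p-value from the chi-square distribution with k-1 degrees of
#' freedom.
#'
#' @param times,events As in [km_estimate()].
#' @param groups Group labels (2 or more levels, each non-empty).
#' @return List: `chi_square`, `df`, `p_value`, `n_per_group`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- factor(groups)
  stopifnot(length(times) == length(events),
            length(times) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2 || any(tab == 0))
    stop("need >= 2 non-empty groups", call. = FALSE)
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(tab) - 1
  list(chi_square = fit$chisq, df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
       n_per_group = as.vector(tab))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization (Newton-Raphson via
#' `survival::coxph`) with Efron (default) or Breslow handling of tied
#' event times. Constant covariates are rejected and aliased
#' (collinear) covariates reported by name.
#'
#' @param covariates Data frame of numeric covariates.
#' @param times,events As in [km_estimate()].
#' @param ties_method `"efron"` or `"breslow"`.
#' @return List of class `cox_model`: `coefficients` data frame
#'   (`term`, `coef`, `hr`, `se`, `ci_low`, `ci_high`, `p_value`),
#'   `loglik`, `score_test` (chi-square), `converged`, `ties_method`,
#'   `n`, `n_events`, and the underlying `fit`.
#' @export
cox_fit <- function(covariates, times, events,
                    ties_method = c("efron", "breslow")) {
  ties_method <- match.arg(ties_method)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(times),
            length(times) == length(events), sum(events) >= 1)
  const <- vapply(covariates, function(x) length(unique(x[!is.na(x)])) < 2,
                  logical(1))
  if (any(const))
    stop("constant covariate(s): ",
         paste(names(covariates)[const], collapse = ", "), call. = FALSE)
  dat <- cbind(data.frame(.t = times, .e = events), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.t, .e) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties_method,
                         control = survival::coxph.control(
                           eps = 1e-9, iter.max = 100))
  if (anyNA(stats::coef(fit)))
    stop("collinear covariate(s) dropped by the fit: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  s <- summary(fit)
  cf <- s$coefficients
  mono <- any(abs(cf[, "coef"]) > 15)   # monotone likelihood escape
  coefs <- data.frame(term = gsub("`", "", rownames(cf)),
                      coef = cf[, "coef"], hr = exp(cf[, "coef"]),
                      se = cf[, "se(coef)"],
                      ci_low = exp(cf[, "coef"] - 1.96 * cf[, "se(coef)"]),
                      ci_high = exp(cf[, "coef"] + 1.96 * cf[, "se(coef)"]),
                      p_value = cf[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, loglik = fit$loglik[2],
                 score_test = as.numeric(s$sctest["test"]),
                 converged = fit$iter < 100 && !mono,
                 ties_method = ties_method, n = s$n, n_events = s$nevent,
                 fit = fit),
            class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat("<cox_model> n =", x$n, ", events =", x$n_events,
      ", ties =", x$ties_method, "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Fit the clinical and clinico-genetic Cox models
#'
#' The clinical model uses age, initial PSA, a high-grade Gleason
#' indicator (score >= 8 by default; ordinal coding optional),
#' extracapsular extension, seminal vesicle invasion and positive
#' surgical margin. The clinico-genetic model adds the GRS as a
#' continuous covariate (hazard ratio per score unit). Both models are
#' fit on identical samples.
#'
#' @param phenotypes Phenotype data frame.
#' @param scores `grs_scores` data frame aligned by `sample_id`.
#' @param gleason_coding `"binary"` (>= 8 indicator) or `"ordinal"`.
#' @param ties_method Passed to [cox_fit()].
#' @return List: `clinical` and `clinico_genetic` (`cox_model`
#'   objects), `data` (the assembled model frame).
#' @export
fit_paper_models <- function(phenotypes, scores,
                             gleason_coding = c("binary", "ordinal"),
                             ties_method = "efron") {
  gleason_coding <- match.arg(gleason_coding)
  phenotypes <- validate_phenotypes(phenotypes)
  m <- match(phenotypes$sample_id, scores$sample_id)
  if (anyNA(m))
    stop("scores missing for sample(s): ",
         paste(phenotypes$sample_id[is.na(m)], collapse = ", "),
         call. = FALSE)
  gl <- if (gleason_coding == "binary") as.numeric(phenotypes$gleason >= 8)
        else phenotypes$gleason
  covar <- data.frame(age = phenotypes$age_years,
                      psa = phenotypes$psa_ng_ml,
                      gleason = gl,
                      ece = phenotypes$ece, svi = phenotypes$svi,
                      psm = phenotypes$psm)
  grs <- scores$grs[m]
  clinical <- cox_fit(covar, phenotypes$followup_months,
                      phenotypes$bcr_event, ties_method)
  genetic <- cox_fit(cbind(covar, grs = grs), phenotypes$followup_months,
                     phenotypes$bcr_event, ties_method)
  list(clinical = clinical, clinico_genetic = genetic,
       data = cbind(covar, grs = grs,
                    followup_months = phenotypes$followup_months,
                    bcr_event = phenotypes$bcr_event))
}

#' Write a Kaplan-Meier curve or Cox summary as TSV
#'
#' @param x A `km_curve` or `cox_model`.
#' @param path Output path.
#' @export
write_survival_tsv <- function(x, path) {
  tab <- if (inherits(x, "cox_model")) x$coefficients else as.data.frame(x)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
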