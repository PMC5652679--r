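#' Build a weighted genetic risk score model
#'
#' One entry per selected SNP, weighted by the natural log of its odds
#' ratio. The effect allele stays the cohort minor allele for every
#' SNP, so protective SNPs (OR < 1) contribute negative weights; this
#' is what makes realistic scores mostly negative.
#'
#' @param selected Association results (rows of an `assoc_results`
#'   data frame, e.g. from [select_snps()]) with finite, non-unit
#'   `or_estimate` values.
#' @param alpha_used The selection threshold that produced `selected`
#'   (recorded in the model).
#' @return List of class `grs_model`: `entries` (data frame
#'   `variant_id`, `effect_allele`, `weight`), `alpha_used`,
#'   `provenance` (the input rows).
#' @export
build_model <- function(selected, alpha_used = NA_real_) {
  if (is.null(selected) || nrow(selected) == 0)
    stop("empty model: no SNPs selected", call. = FALSE)
  or <- selected$or_estimate
  if (any(!is.finite(or)) || any(or <= 0))
    stop("non-positive or non-finite OR for: ",
         paste(selected$variant_id[!is.finite(or) | or <= 0],
               collapse = ", "), call. = FALSE)
  if (any(or == 1))
    stop("OR exactly 1 (zero weight) for: ",
         paste(selected$variant_id[or == 1], collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(selected$variant_id))
    stop("duplicated variant ids in selection", call. = FALSE)
  entries <- data.frame(variant_id = selected$variant_id,
                        effect_allele = selected$effect_allele,
                        weight = log(or), stringsAsFactors = FALSE)
  structure(list(entries = entries, alpha_used = alpha_used,
                 provenance = selected),
            class = "grs_model")
}

#' @export
print.grs_model <- function(x, ...) {
  cat("<grs_model> ", nrow(x$entries), " SNPs; weight range [",
      round(min(x$entries$weight), 3), ", ",
      round(max(x$entries$weight), 3), "]\n", sep = "")
  invisible(x)
}

#' Theoretical score bounds of a GRS model
#'
#' @param model A [build_model()] result.
#' @return Named vector `lower`/`upper`: `2 * sum(min(0, w))` and
#'   `2 * sum(max(0, w))`.
#' @export
grs_bounds <- function(model) {
  w <- model$entries$weight
  c(lower = 2 * sum(pmin(0, w)), upper = 2 * sum(pmax(0, w)))
}

#' Score samples with a GRS model
#'
#' GRS = sum over model SNPs of (effect-allele count) x ln(OR).
#' Missing genotypes are imputed as twice the effect-allele frequency
#' among the scored samples at that SNP (`missing = "impute"`, the
#' default) or contribute nothing (`missing = "omit"`); the number of
#' imputed entries is reported per sample either way.
#'
#' @param genotypes A [genotype_matrix()] containing every model SNP.
#' @param model A [build_model()] result.
#' @param missing Missing-genotype policy, `"impute"` or `"omit"`.
#' @return Data frame of class `grs_scores`: `sample_id`, `grs`,
#'   `n_imputed`.
#' @export
score_samples <- function(genotypes, model,
                          missing = c("impute", "omit")) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(model, "grs_model"))
  missing <- match.arg(missing)
  idx <- match(model$entries$variant_id, genotypes$variants$variant_id)
  if (anyNA(idx))
    stop("model variants absent from genotypes: ",
         paste(model$entries$variant_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  vt <- genotypes$variants[idx, , drop = FALSE]
  ea <- model$entries$effect_allele
  mismatch <- ea != vt$effect_allele & ea != vt$other_allele
  if (any(mismatch))
    stop("effect-allele orientation mismatch for: ",
         paste(model$entries$variant_id[mismatch], collapse = ", "),
         call. = FALSE)
  g <- genotypes$counts[, idx, drop = FALSE]
  flip <- ea == vt$other_allele        # matrix counts the other allele
  g[, flip] <- 2L - g[, flip, drop = FALSE]
  n_imputed <- rowSums(is.na(g))
  # imputation value = 2 * effect-allele frequency = mean count
  fill <- if (missing == "impute") colMeans(g, na.rm = TRUE) else
    rep(0, ncol(g))
  gg <- g
  for (j in seq_len(ncol(gg))) gg[is.na(gg[, j]), j] <- fill[j]
  scores <- as.numeric(gg %*% model$entries$weight)
  out <- data.frame(sample_id = genotypes$sample_ids, grs = scores,
                    n_imputed = n_imputed, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("grs_scores", class(out))
  out
}

#' Dichotomize GRS into high and low groups
#'
#' @param scores A `grs_scores` data frame (or any with `grs`).
#' @param cutoff Threshold; scores at or above it are `"high"`
#'   (default -2.0; pass the sample median for a median split).
#' @return Input with a `group` factor column (`low`, `high`);
#'   attribute `group_counts` holds the split sizes.
#' @export
dichotomize <- function(scores, cutoff = -2.0) {
  stopifnot(nrow(scores) >= 1, is.finite(cutoff))
  scores$group <- factor(ifelse(scores$grs >= cutoff, "high", "low"),
                         levels = c("low", "high"))
  attr(scores, "cutoff") <- cutoff
  attr(scores, "group_counts") <- table(scores$group)
  scores
}

#' Write / read a GRS model as TSV
#'
#' @param model A `grs_model`.
#' @param path TSV path (columns variant_id, effect_allele, weight).
#' @export
write_grs_model <- function(model, path) {
  utils::write.table(model$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_grs_model
#' @export
read_grs_model <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "effect_allele", "weight") %in% names(tab)))
  structure(list(entries = tab[c("variant_id", "effect_allele", "weight")],
                 alpha_used = NA_real_, provenance = NULL),
            class = "grs_model")
}
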