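#' Pipeline run configuration
#'
#' Bundles every stage's options. Input is either a simulation config
#' (`sim`) or paths to existing genotype/phenotype files (`geno_path`
#' as VCF or genotype TSV, `pheno_path` as phenotype TSV).
#'
#' @param sim A [simulation_config()], or `NULL` when reading files.
#' @param geno_path,pheno_path Input files. Supplying them switches the
#'   input stage to file reading; combining them with an explicit `sim`
#'   is an error.
#' @param thresholds A [qc_thresholds()].
#' @param method Association method, `"allelic"` or `"logistic"`.
#' @param alpha Panel-selection p-value threshold.
#' @param grs_cutoff High/low GRS split (default -2.0; `"median"` uses
#'   the sample median).
#' @param gleason_coding `"binary"` or `"ordinal"`.
#' @param out_dir Output directory for stage artifacts (`NULL` for
#'   none).
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = simulation_config(), geno_path = NULL,
                       pheno_path = NULL, thresholds = qc_thresholds(),
                       method = "allelic", alpha = 1e-3,
                       grs_cutoff = -2.0, gleason_coding = "binary",
                       out_dir = NULL) {
  if (missing(sim) && !is.null(geno_path)) sim <- NULL
  if (is.null(sim) && (is.null(geno_path) || is.null(pheno_path)))
    stop("either a simulation config or both input paths are required",
         call. = FALSE)
  if (!is.null(sim) && !is.null(geno_path))
    stop("give either 'sim' or input paths, not both", call. = FALSE)
  structure(list(sim = sim, geno_path = geno_path,
                 pheno_path = pheno_path, thresholds = thresholds,
                 method = method, alpha = alpha, grs_cutoff = grs_cutoff,
                 gleason_coding = gleason_coding, out_dir = out_dir),
            class = "run_config")
}

#' Run the full GRS pipeline
#'
#' Stages, in order: cohort input (simulated or read), quality
#' control, per-SNP association, panel selection, GRS model and
#' scoring, Kaplan-Meier/log-rank by score group, clinical vs
#' clinico-genetic Cox models, and the incremental-AUC comparison.
#' When `out_dir` is set every stage's table is written as TSV (and
#' the simulated genotypes as VCF), so any stage can be rerun in
#' isolation. A stage failure stops the run with the stage name;
#' artifacts written so far are preserved.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage messages?
#' @return List of class `pipeline_result` with elements `cohort`,
#'   `qc`, `association`, `selected`, `model`, `scores`, `km`
#'   (per-group curves + log-rank), `cox` (both models), `auc`
#'   (`roc_comparison`), `config`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[grsurv] ", ...)
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out))
    dir.create(out, recursive = TRUE)
  emit <- function(tab, name) {
    if (!is.null(out))
      utils::write.table(tab, file.path(out, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("input", {
    if (!is.null(config$sim)) {
      co <- simulate_cohort(config$sim)
      if (!is.null(out)) {
        write_vcf(co$genotypes, file.path(out, "genotypes.vcf"))
        write_phenotypes(co$phenotypes, file.path(out, "phenotypes.tsv"))
      }
      co
    } else {
      geno <- if (grepl("\\.vcf(\\.gz)?$", config$geno_path))
        read_vcf(config$geno_path) else read_genotype_tsv(config$geno_path)
      list(genotypes = geno,
           phenotypes = read_phenotypes(config$pheno_path))
    }
  })
  say("input: ", length(cohort$genotypes$sample_ids), " samples, ",
      nrow(cohort$genotypes$variants), " variants")

  qc <- stage("qc", apply_qc(cohort$genotypes, config$thresholds))
  emit(qc$markers, "qc_markers.tsv"); emit(qc$samples, "qc_samples.tsv")
  say("qc: ", qc$summary$n_samples_after, " samples, ",
      qc$summary$n_markers_after, " markers kept")

  pheno <- cohort$phenotypes[
    cohort$phenotypes$sample_id %in% qc$genotypes$sample_ids, ,
    drop = FALSE]
  assoc <- stage("assoc",
                 run_association(qc$genotypes, pheno, config$method))
  emit(assoc, "association.tsv")
  if (!is.null(out)) write_manhattan_tsv(assoc, file.path(out,
                                                          "manhattan.tsv"))
  selected <- stage("select", select_snps(assoc, config$alpha))
  emit(selected, "selected.tsv")
  say("assoc: ", nrow(selected), " SNPs at p < ", config$alpha)

  model <- stage("score", build_model(selected, config$alpha))
  scores <- stage("score", score_samples(qc$genotypes, model))
  cutoff <- if (identical(config$grs_cutoff, "median"))
    stats::median(scores$grs) else config$grs_cutoff
  scores <- dichotomize(scores, cutoff)
  if (!is.null(out)) write_grs_model(model, file.path(out, "grs_model.tsv"))
  emit(scores, "grs_scores.tsv")

  m <- match(pheno$sample_id, scores$sample_id)
  km <- stage("survival", {
    grp <- scores$group[m]
    list(curves = lapply(split(seq_len(nrow(pheno)), grp), function(i)
           km_estimate(pheno$followup_months[i], pheno$bcr_event[i])),
         logrank = logrank_test(pheno$followup_months, pheno$bcr_event,
                                grp))
  })
  cox <- stage("survival",
               fit_paper_models(pheno, scores, config$gleason_coding))
  emit(cox$clinical$coefficients, "cox_clinical.tsv")
  emit(cox$clinico_genetic$coefficients, "cox_clinico_genetic.tsv")
  say("survival: log-rank chi2 = ",
      round(km$logrank$chi_square, 2), ", GRS HR = ",
      round(cox$clinico_genetic$coefficients[
        cox$clinico_genetic$coefficients$term == "grs", "hr"], 3))

  auc <- stage("evaluate",
               evaluate_grs_gain(pheno, scores, config$gleason_coding))
  emit(data.frame(auc_clinical = auc$auc_a, auc_genetic = auc$auc_b,
                  auc_diff = auc$auc_diff, p_value = auc$p_value),
       "auc_comparison.tsv")
  say("evaluate: AUC ", round(auc$auc_a, 3), " -> ", round(auc$auc_b, 3),
      " (p = ", signif(auc$p_value, 3), ")")

  structure(list(cohort = cohort, qc = qc, association = assoc,
                 selected = selected, model = model, scores = scores,
                 km = km, cox = cox, auc = auc, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n",
      "  samples after QC: ", x$qc$summary$n_samples_after, "\n",
      "  SNPs selected:    ", nrow(x$selected), "\n",
      "  log-rank p:       ", signif(x$km$logrank$p_value, 3), "\n",
      "  GRS HR (adj.):    ",
      round(x$cox$clinico_genetic$coefficients[
        x$cox$clinico_genetic$coefficients$term == "grs", "hr"], 3), "\n",
      "  AUC clinical vs clinico-genetic: ",
      round(x$auc$auc_a, 3), " vs ", round(x$auc$auc_b, 3),
      " (p = ", signif(x$auc$p_value, 3), ")\n", sep = "")
  invisible(x)
}
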