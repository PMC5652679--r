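#' Published 16-SNP biochemical-recurrence association panel
#'
#' The exome-chip panel of 16 SNPs reported as associated (p < 1e-3)
#' with biochemical recurrence (BCR) after radical prostatectomy in a
#' prospective cohort of 912 prostate-cancer patients, with the group
#' minor-allele frequencies (no-BCR vs BCR), allelic odds ratios, 95%
#' confidence intervals and p-values as published. The effect allele is
#' the cohort minor allele; twelve of the sixteen SNPs are protective
#' (OR < 1), which is why realistic GRS values are mostly negative.
#'
#' Genomic positions are synthetic placeholders (the published table
#' reports chromosome only); they matter only for writing well-formed
#' VCF and are flagged as such in the `position_synthetic` attribute.
#'
#' @return Data frame with columns `variant_id`, `chromosome`,
#'   `position`, `effect_allele`, `other_allele`, `gene`,
#'   `maf_controls` (no-BCR group), `maf_cases` (BCR group),
#'   `or_published`, `ci_low`, `ci_high`, `p_published`.
#' @export
#' @examples
#' panel <- bcr_snp_panel()
#' log(panel$or_published)   # the GRS weights
bcr_snp_panel <- function() {
  p <- data.frame(
    variant_id = c("rs4965121", "rs1128966", "rs1046404", "rs1046403",
                   "rs781831", "rs7009549", "rs12871532", "rs16964211",
                   "rs3133745", "rs2071286", "rs10853489", "rs7439186",
                   "rs2144425", "rs3935295", "rs4745571", "rs17168761"),
    chromosome = c("15", "17", "17", "17", "17", "8", "13", "15", "8",
                   "6", "18", "4", "6", "1", "9", "7"),
    other_allele  = c("G", "C", "C", "A", "T", "A", "C", "G", "C", "G",
                      "A", "C", "A", "G", "T", "T"),
    effect_allele = c("C", "G", "G", "G", "C", "G", "T", "A", "T", "A",
                      "G", "T", "G", "A", "C", "C"),
    gene = c("", "NT5C3B", "NT5C3B", "NT5C3B", "ZZEF1", "", "", "CYP19A1",
             "C8orf37-AS1", "NOTCH4", "", "AMBN", "OR12D3, OR5V1",
             "PTPN7", "PRUNE2", "AGMO"),
    maf_controls = c(0.05824, 0.1871, 0.1871, 0.1871, 0.3565, 0.5121,
                     0.3663, 0.2952, 0.2401, 0.1693, 0.4041, 0.1349,
                     0.3113, 0.1607, 0.1712, 0.3623),
    maf_cases = c(0.1152, 0.1083, 0.1083, 0.1088, 0.2593, 0.4124,
                  0.2742, 0.2097, 0.1613, 0.1019, 0.4954, 0.2005,
                  0.2281, 0.09677, 0.2419, 0.2765),
    or_published = c(2.106, 0.5278, 0.5278, 0.5306, 0.6317, 0.6689,
                     0.6536, 0.6335, 0.6088, 0.5565, 1.448, 1.607,
                     0.6539, 0.5594, 1.545, 0.6726),
    ci_low = c(1.455, 0.379, 0.379, 0.381, 0.4963, 0.5379, 0.5156,
               0.4895, 0.4585, 0.3955, 1.166, 1.214, 0.5087, 0.3948,
               1.192, 0.5307),
    ci_high = c(3.047, 0.735, 0.735, 0.7388, 0.804, 0.8316, 0.8285,
                0.82, 0.8083, 0.7831, 1.797, 2.127, 0.8406, 0.7927,
                2.004, 0.8523),
    p_published = c(5.75e-05, 0.000127, 0.000127, 0.000145, 0.000176,
                    0.000283, 0.000417, 0.000489, 0.000551, 0.000672,
                    7.73e-04, 0.000842, 0.000866, 0.000959, 0.000966,
                    0.000987),
    stringsAsFactors = FALSE
  )
  # deterministic synthetic coordinates, well separated per chromosome
  p$position <- 1000000L + 50000L * seq_len(nrow(p))
  attr(p, "position_synthetic") <- TRUE
  p[c("variant_id", "chromosome", "position", "effect_allele",
      "other_allele", "gene", "maf_controls", "maf_cases",
      "or_published", "ci_low", "ci_high", "p_published")]
}

#' Reference cohort and chip design constants
#'
#' Headline design numbers of the cohort the simulator emulates: 912
#' subjects after quality control of whom 212 experienced biochemical
#' recurrence, genotyped on an exome chip where 242,186 of 242,901
#' attempted markers were successfully genotyped.
#'
#' @return Named list: `n_total`, `n_events`, `n_controls`,
#'   `markers_attempted`, `markers_genotyped`.
#' @export
study_design <- function() {
  list(n_total = 912L, n_events = 212L, n_controls = 700L,
       markers_attempted = 242901L, markers_genotyped = 242186L)
}
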