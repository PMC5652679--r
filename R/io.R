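#' Read genotypes from a VCF file
#'
#' Reads a VCF (v4.x) containing biallelic SNP records with a GT format
#' field and returns effect-allele (ALT) counts per sample. Half calls
#' (e.g. `0/.`) and `./.` become missing. Multiallelic or non-SNP
#' records are rejected.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @return A [genotype_matrix()]; the effect allele is the ALT allele.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)     # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records", call. = FALSE)
  bad_multi <- grepl(",", fix$ALT, fixed = TRUE)
  bad_snp <- nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L |
    !(fix$REF %in% c("A", "C", "G", "T")) | !(fix$ALT %in% c("A", "C", "G", "T"))
  if (any(bad_multi | bad_snp))
    stop("non-biallelic-SNP records rejected: ",
         paste(fix$ID[bad_multi | bad_snp], collapse = ", "), call. = FALSE)
  if (anyDuplicated(fix$ID))
    stop("duplicated variant ids in VCF: ",
         paste(unique(fix$ID[duplicated(fix$ID)]), collapse = ", "),
         call. = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) == 0)
    stop("VCF has no genotype columns", call. = FALSE)
  if (colnames(gt)[1] == "FORMAT") {
    if (!all(startsWith(gt[, 1], "GT")))
      stop("VCF records lack a leading GT format field", call. = FALSE)
    gt <- gt[, -1, drop = FALSE]
  }
  # GT is the first colon-separated subfield
  gt[] <- sub(":.*$", "", gt)
  counts <- apply(gt, c(1, 2), gt_to_count)
  variants <- data.frame(
    variant_id = fix$ID, chromosome = fix$CHROM,
    position = as.integer(fix$POS),
    effect_allele = fix$ALT, other_allele = fix$REF,
    gene = "", stringsAsFactors = FALSE)
  genotype_matrix(t(counts), variants, colnames(gt))
}

# "0/1" or "0|1" -> ALT-allele count; any missing allele -> NA
gt_to_count <- function(gt) {
  if (is.na(gt)) return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (length(alleles) != 2L || any(alleles == "."))
    return(NA_integer_)
  a <- suppressWarnings(as.integer(alleles))
  if (anyNA(a) || any(!a %in% 0:1))
    stop("unsupported GT value: ", gt, call. = FALSE)
  sum(a)
}

#' Write genotypes as a minimal VCF
#'
#' Emits a plain-text VCF v4.2 with GT-only genotype columns; the
#' effect allele is written as ALT so [read_vcf()] round-trips.
#'
#' @param x A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  gt_strings <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "FORMAT", x$sample_ids), collapse = "\t")),
             con)
  v <- x$variants
  for (j in seq_len(nrow(v))) {
    g <- x$counts[, j]
    cells <- ifelse(is.na(g), "./.", gt_strings[as.character(g)])
    writeLines(paste(c(v$chromosome[j], v$position[j], v$variant_id[j],
                       v$other_allele[j], v$effect_allele[j], ".", "PASS",
                       "GT", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read or write the sample-by-variant genotype TSV dialect
#'
#' The TSV dialect has a header `sample_id` followed by variant ids and
#' body cells in {0,1,2,NA}. Variant annotation beyond the id is not
#' carried by this format; `read_genotype_tsv` reconstructs placeholder
#' annotation (`variants` argument overrides it), and
#' `write_genotype_tsv` drops it, so the pair round-trips counts,
#' sample ids and variant ids exactly.
#'
#' @param path File path.
#' @param variants Optional variant annotation data frame (as in
#'   [genotype_matrix()]) to attach on read, matched by `variant_id`.
#' @return `read_genotype_tsv`: a [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path, variants = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (names(tab)[1] != "sample_id")
    stop("first column must be 'sample_id', got '", names(tab)[1], "'",
         call. = FALSE)
  ids <- tab$sample_id
  body <- as.matrix(tab[-1])
  body[body == "NA" | body == ""] <- NA
  bad <- !is.na(body) & !(body %in% c("0", "1", "2"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid genotype cell '", body[bad][1], "' at sample '",
         ids[idx[1]], "', variant '", colnames(body)[idx[2]], "'",
         call. = FALSE)
  }
  counts <- matrix(as.integer(body), nrow = nrow(body),
                   ncol = ncol(body), dimnames = dimnames(body))
  vids <- colnames(tab)[-1]
  if (is.null(variants)) {
    variants <- data.frame(variant_id = vids, chromosome = "0",
                           position = seq_along(vids), effect_allele = "A",
                           other_allele = "C", gene = "",
                           stringsAsFactors = FALSE)
  } else {
    m <- match(vids, variants$variant_id)
    if (anyNA(m))
      stop("variants table lacks: ", paste(vids[is.na(m)], collapse = ", "),
           call. = FALSE)
    variants <- variants[m, , drop = FALSE]
  }
  genotype_matrix(counts, variants, ids)
}

#' @rdname read_genotype_tsv
#' @param x A [genotype_matrix()].
#' @return `write_genotype_tsv`: `path`, invisibly.
#' @export
write_genotype_tsv <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  tab <- data.frame(sample_id = x$sample_ids, x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

PT_STAGES <- c("pT2", "pT3", "pT4")

pheno_numeric_cols <- c("bcr_event", "followup_months", "age_years",
                        "psa_ng_ml", "prostate_volume_ml", "gleason",
                        "ece", "svi", "bni", "psm")

#' Read or write a phenotype/covariate table
#'
#' The phenotype TSV carries, per sample: the biochemical-recurrence
#' event indicator (`bcr_event`), follow-up in months, age, preoperative
#' PSA (ng/ml), prostate volume (ml, optional), pathological Gleason
#' score (6-10), the binary adverse-pathology indicators `ece`
#' (extracapsular extension), `svi` (seminal vesicle invasion), `bni`
#' (bladder-neck invasion), `psm` (positive surgical margin), and the
#' pathological T stage (`pT2`/`pT3`/`pT4`).
#'
#' @param path File path.
#' @return `read_phenotypes`: validated data frame with those columns.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_phenotypes(tab)
}

#' @rdname read_phenotypes
#' @param phenotypes A phenotype data frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  phenotypes <- validate_phenotypes(phenotypes)
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname read_phenotypes
#' @export
validate_phenotypes <- function(phenotypes) {
  tab <- as.data.frame(phenotypes, stringsAsFactors = FALSE)
  need <- c("sample_id", pheno_numeric_cols, "pt_stage")
  miss <- setdiff(setdiff(need, "prostate_volume_ml"), names(tab))
  if (length(miss))
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"prostate_volume_ml" %in% names(tab)) tab$prostate_volume_ml <- NA_real_
  tab$sample_id <- as.character(tab$sample_id)
  for (col in pheno_numeric_cols) tab[[col]] <- as.numeric(tab[[col]])
  if (anyNA(tab$bcr_event) || anyNA(tab$followup_months))
    stop("rows with missing bcr_event or followup_months: ",
         paste(tab$sample_id[is.na(tab$bcr_event) |
                             is.na(tab$followup_months)], collapse = ", "),
         call. = FALSE)
  checks <- list(
    bcr_event = tab$bcr_event %in% 0:1,
    followup_months = tab$followup_months > 0,
    gleason = is.na(tab$gleason) | tab$gleason %in% 6:10,
    ece = is.na(tab$ece) | tab$ece %in% 0:1,
    svi = is.na(tab$svi) | tab$svi %in% 0:1,
    bni = is.na(tab$bni) | tab$bni %in% 0:1,
    psm = is.na(tab$psm) | tab$psm %in% 0:1,
    pt_stage = is.na(tab$pt_stage) | tab$pt_stage %in% PT_STAGES)
  for (nm in names(checks)) {
    ok <- checks[[nm]]
    if (!all(ok))
      stop("invalid ", nm, " for sample(s): ",
           paste(tab$sample_id[!ok], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id))
    stop("duplicated sample ids: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
               collapse = ", "), call. = FALSE)
  rownames(tab) <- NULL
  tab[c("sample_id", "bcr_event", "followup_months", "age_years",
        "psa_ng_ml", "prostate_volume_ml", "gleason", "ece", "svi",
        "bni", "psm", "pt_stage")]
}
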