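#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds per-sample counts of the effect allele
#' (0, 1, 2 or `NA` for a missing call) for a set of biallelic SNPs,
#' together with the variant annotation table.
#'
#' @param counts Integer matrix, samples in rows, variants in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param variants Data frame with one row per column of `counts` and
#'   columns `variant_id`, `chromosome`, `position`, `effect_allele`,
#'   `other_allele`, `gene`. `gene` may be `""`.
#' @param sample_ids Character vector of unique sample identifiers, one
#'   per row of `counts`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `counts` (dimnames set to sample/variant ids), `variants` and
#'   `sample_ids`.
#' @export
genotype_matrix <- function(counts, variants, sample_ids) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  variants <- validate_variants(variants)
  sample_ids <- as.character(sample_ids)
  if (nrow(counts) != length(sample_ids))
    stop("counts has ", nrow(counts), " rows but ", length(sample_ids),
         " sample ids", call. = FALSE)
  if (ncol(counts) != nrow(variants))
    stop("counts has ", ncol(counts), " columns but ", nrow(variants),
         " variants", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  bad <- !is.na(counts) & !(counts %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("genotype count outside {0,1,2,NA} at sample '",
         sample_ids[idx[1]], "', variant '", variants$variant_id[idx[2]],
         "': ", counts[bad][1], call. = FALSE)
  }
  dimnames(counts) <- list(sample_ids, variants$variant_id)
  structure(list(counts = counts, variants = variants,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

validate_variants <- function(variants) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("variant_id", "chromosome", "position", "effect_allele",
            "other_allele", "gene")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variant table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  variants <- variants[need]
  variants$variant_id <- as.character(variants$variant_id)
  variants$chromosome <- as.character(variants$chromosome)
  variants$position <- as.integer(variants$position)
  variants$gene <- as.character(variants$gene)
  if (anyDuplicated(variants$variant_id))
    stop("duplicated variant ids: ",
         paste(unique(variants$variant_id[duplicated(variants$variant_id)]),
               collapse = ", "), call. = FALSE)
  bases <- c("A", "C", "G", "T")
  ok <- variants$effect_allele %in% bases & variants$other_allele %in% bases &
    variants$effect_allele != variants$other_allele
  if (nrow(variants) && any(!ok))
    stop("invalid alleles for variant(s): ",
         paste(variants$variant_id[!ok], collapse = ", "), call. = FALSE)
  rownames(variants) <- NULL
  variants
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$sample_ids), " samples x ",
      nrow(x$variants), " variants; ",
      sum(is.na(x$counts)), " missing calls\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param x A [genotype_matrix()].
#' @param samples,variants Index vectors (logical, integer or character)
#'   selecting rows (samples) and columns (variants); `NULL` keeps all.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(x$sample_ids) else samples
  vi <- if (is.null(variants)) seq_len(nrow(x$variants)) else variants
  if (is.character(vi)) vi <- match(vi, x$variants$variant_id)
  if (is.character(si)) si <- match(si, x$sample_ids)
  genotype_matrix(x$counts[si, vi, drop = FALSE],
                  x$variants[vi, , drop = FALSE],
                  x$sample_ids[si])
}
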