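panel_model <- function() {
  panel <- bcr_snp_panel()
  build_model(data.frame(variant_id = panel$variant_id,
                         effect_allele = panel$effect_allele,
                         or_estimate = panel$or_published,
                         stringsAsFactors = FALSE), alpha_used = 1e-3)
}

panel_genotypes <- function(counts) {
  panel <- bcr_snp_panel()
  genotype_matrix(counts,
                  panel[c("variant_id", "chromosome", "position",
                          "effect_allele", "other_allele", "gene")],
                  sprintf("s%02d", seq_len(nrow(counts))))
}

test_that("model weights are ln(OR) and invalid ORs are rejected", {
  model <- panel_model()
  expect_equal(nrow(model$entries), 16)
  w <- model$entries$weight[model$entries$variant_id == "rs4965121"]
  expect_equal(w, log(2.106), tolerance = 1e-12)
  expect_equal(sum(model$entries$weight < 0), 12)   # protective SNPs

  one <- data.frame(variant_id = "x", effect_allele = "A", or_estimate = 1)
  expect_error(build_model(one), "exactly 1")
  neg <- data.frame(variant_id = "x", effect_allele = "A", or_estimate = -2)
  expect_error(build_model(neg), "non-positive")
  expect_error(build_model(one[0, ]), "empty model")
  two <- data.frame(variant_id = c("a", "b"), effect_allele = "A",
                    or_estimate = c(2, 0.5))
  m2 <- build_model(two)
  expect_equal(m2$entries$weight, c(log(2), -log(2)))
})

test_that("scoring is the weighted allele-count sum", {
  model <- panel_model()
  counts <- matrix(0L, 3, 16)
  # sample 2: one risk allele at rs4965121 and two at rs1128966
  counts[2, 1] <- 1L; counts[2, 2] <- 2L
  # sample 3: homozygous for all 12 protective effect alleles
  counts[3, log(bcr_snp_panel()$or_published) < 0] <- 2L
  sc <- score_samples(panel_genotypes(counts), model)
  expect_equal(sc$grs[1], 0)                       # empty sum
  expect_equal(sc$grs[2], log(2.106) + 2 * log(0.5278), tolerance = 1e-12)
  expect_equal(sc$grs[2], -0.5333, tolerance = 1e-3)
  expect_equal(sc$grs[3], grs_bounds(model)[["lower"]], tolerance = 1e-12)
})

test_that("score bounds computed from the published weights contain the scores", {
  model <- panel_model()
  b <- grs_bounds(model)
  expect_equal(b[["upper"]], 4.0487, tolerance = 1e-3)
  expect_equal(b[["lower"]], -12.2794, tolerance = 1e-3)
  # the published observed range sits inside the theoretical bounds
  expect_lt(b[["lower"]], -7.19)
  expect_gt(b[["upper"]], 1.61)
  set.seed(9)
  counts <- matrix(sample(0:2, 50 * 16, TRUE), 50, 16)
  sc <- score_samples(panel_genotypes(counts), model)
  expect_true(all(sc$grs >= b[["lower"]] - 1e-12))
  expect_true(all(sc$grs <= b[["upper"]] + 1e-12))
})

test_that("missing genotypes are frequency-imputed and counted", {
  model <- panel_model()
  counts <- matrix(1L, 5, 16)
  counts[1, 3] <- NA
  sc <- score_samples(panel_genotypes(counts), model)
  expect_equal(sc$n_imputed, c(1, 0, 0, 0, 0))
  # frequency among the others is 1 copy -> imputed value 1 -> same score
  expect_equal(sc$grs[1], sc$grs[2])
  sc0 <- score_samples(panel_genotypes(counts), model, missing = "omit")
  w3 <- model$entries$weight[3]
  expect_equal(sc0$grs[1], sc0$grs[2] - w3)
  # model variant absent from the matrix is a named error
  g_sub <- panel_genotypes(counts)
  g_sub <- subset_genotypes(g_sub, variants = 1:15)
  expect_error(score_samples(g_sub, model), "rs17168761")
})

test_that("adding a tiny-weight SNP perturbs scores by at most 2x its weight", {
  model <- panel_model()
  counts <- matrix(sample(0:2, 20 * 16, TRUE), 20, 16)
  sc <- score_samples(panel_genotypes(counts), model)
  aug <- model$provenance
  aug <- rbind(aug, data.frame(variant_id = "tiny", effect_allele = "A",
                               or_estimate = exp(1e-4)))
  model2 <- build_model(aug)
  panel <- bcr_snp_panel()
  v2 <- rbind(panel[c("variant_id", "chromosome", "position",
                      "effect_allele", "other_allele", "gene")],
              data.frame(variant_id = "tiny", chromosome = "1",
                         position = 999L, effect_allele = "A",
                         other_allele = "G", gene = ""))
  g2 <- genotype_matrix(cbind(counts, sample(0:2, 20, TRUE)), v2,
                        sprintf("s%02d", 1:20))
  sc2 <- score_samples(g2, model2)
  expect_true(all(abs(sc2$grs - sc$grs) <= 2e-4 + 1e-12))
})

test_that("dichotomization sends ties to high and reports group sizes", {
  sc <- data.frame(sample_id = c("a", "b", "c"), grs = c(-2, -2.5, 0))
  d <- dichotomize(sc, -2)
  expect_equal(as.character(d$group), c("high", "low", "high"))
  expect_equal(as.vector(attr(d, "group_counts")), c(1, 2))
  d2 <- dichotomize(sc, -10)
  expect_true(all(d2$group == "high"))
  # median cutoff splits near-evenly without ties
  set.seed(2)
  sc3 <- data.frame(sample_id = sprintf("s%03d", 1:101),
                    grs = rnorm(101))
  d3 <- dichotomize(sc3, median(sc3$grs))
  expect_lte(abs(sum(d3$group == "high") - sum(d3$group == "low")), 1)
})

test_that("cases score higher than controls on the default simulated cohort", {
  res <- run_pipeline(run_config(sim = simulation_config(seed = 11)),
                      quiet = TRUE)
  ph <- res$cohort$phenotypes
  m <- match(res$scores$sample_id, ph$sample_id)
  grs_cases <- res$scores$grs[ph$bcr_event[m] == 1]
  grs_controls <- res$scores$grs[ph$bcr_event[m] == 0]
  expect_gt(mean(grs_cases), mean(grs_controls))
})

test_that("a GRS model round-trips through its TSV form", {
  model <- panel_model()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_grs_model(model, f)
  back <- read_grs_model(f)
  expect_equal(back$entries$weight, model$entries$weight, tolerance = 1e-12)
  expect_equal(back$entries$variant_id, model$entries$variant_id)
})
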