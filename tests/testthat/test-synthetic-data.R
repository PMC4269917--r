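test_that("cohort dimensions and metadata match the configured design", {
  co <- generate_cohort(cohort_config(n_female = 42, n_male = 84,
                                      tissues = c("sputum", "blood"),
                                      n_genes = 200, seed = 1))
  expect_named(co$expression, c("sputum", "blood"))
  for (ti in names(co$expression)) {
    expect_equal(ncol(co$expression[[ti]]), 126)
    md <- co$metadata[co$metadata$tissue == ti, ]
    expect_identical(colnames(co$expression[[ti]]), md$sample_id)
    expect_false(anyDuplicated(md$subject_id) > 0)
  }
  subj <- unique(co$metadata[, c("subject_id", "sex")])
  expect_equal(sum(subj$sex == "F"), 42)
  expect_equal(sum(subj$sex == "M"), 84)
  expect_equal(nrow(co$expression$sputum),
               length(co$gene_ids) + length(co$marker_genes))
})

test_that("identical seeds give bit-identical cohorts, different seeds differ", {
  cf <- cohort_config(n_female = 12, n_male = 12, n_genes = 50, seed = 7)
  expect_identical(generate_cohort(cf), generate_cohort(cf))
  cf2 <- cohort_config(n_female = 12, n_male = 12, n_genes = 50, seed = 8)
  expect_false(identical(generate_cohort(cf)$expression$sputum,
                         generate_cohort(cf2)$expression$sputum))
})

test_that("marker genes are bimodal and separate the sexes", {
  co <- generate_cohort(cohort_config(n_female = 15, n_male = 15,
                                      n_genes = 50, seed = 3))
  mk <- co$expression$sputum[co$marker_genes, ]
  sex <- co$metadata$sex[co$metadata$tissue == "sputum"]
  expect_true(all(colMeans(mk[, sex == "M"]) > colMeans(mk[, sex == "F"]) + 3))
})

test_that("null configuration yields uniform t-test and F-test p-values", {
  co <- generate_cohort(cohort_config(n_female = 20, n_male = 20,
                                      tissues = "sputum", n_genes = 5000,
                                      seed = 11))
  expr <- co$expression$sputum[co$gene_ids, ]
  md <- co$metadata
  tt <- differential_expression_ttest(expr, md)
  expect_gt(stats::ks.test(tt$p_value, "punif")$p.value, 0.01)
  ft <- differential_variance_ftest(expr, md)
  expect_gt(stats::ks.test(ft$p_value, "punif")$p.value, 0.01)
})

test_that("a planted mean shift is detected while null genes stay quiet", {
  # oracle: direct two-sample t-test + BH on the generated matrix
  co <- generate_cohort(cohort_config(n_female = 40, n_male = 40,
                                      tissues = "sputum", n_genes = 400,
                                      de_genes = c(G0001 = 2.0), seed = 5))
  expr <- co$expression$sputum[co$gene_ids, ]
  md <- co$metadata
  sexF <- md$sample_id[md$sex == "F"]
  sexM <- md$sample_id[md$sex == "M"]
  p_oracle <- vapply(seq_len(nrow(expr)), function(i)
    stats::t.test(expr[i, sexF], expr[i, sexM], var.equal = TRUE)$p.value,
    numeric(1))
  q_oracle <- stats::p.adjust(p_oracle, "BH")
  expect_lt(q_oracle[1], 0.01)
  expect_gte(mean(q_oracle[-1] > 0.1), 0.95)
  # package path agrees with the oracle
  tt <- differential_expression_ttest(expr, md)
  expect_equal(tt$p_value, p_oracle, tolerance = 1e-12)
})

test_that("planted variance inflation is detectable by the F-test", {
  dv <- stats::setNames(rep(4, 20), sprintf("G%04d", 1:20))
  hits <- vapply(1:5, function(s) {
    co <- generate_cohort(cohort_config(n_female = 42, n_male = 84,
                                        tissues = "sputum", n_genes = 300,
                                        dv_genes = dv, seed = 100 + s))
    ft <- differential_variance_ftest(co$expression$sputum[co$gene_ids, ],
                                      co$metadata)
    mean(ft$fdr_q[1:20] < 0.1)
  }, numeric(1))
  expect_gt(mean(hits), 0.8)
})

test_that("planted module co-expression is restricted to its sex and tissue", {
  sys <- make_planted_system(2, coupling = 1.0)
  mod <- sys$module
  md <- sys$cohort$metadata
  mean_cor <- function(tissue, sex) {
    sub <- sys$cohort$expression[[tissue]][
      mod$gene_ids, md$sample_id[md$tissue == tissue & md$sex == sex]]
    cc <- stats::cor(t(sub))
    mean(cc[upper.tri(cc)])
  }
  # oracle: correlation computed directly on the generated expression
  expect_gt(mean_cor("sputum", "F") - mean_cor("sputum", "M"), 0.2)
  expect_lt(abs(mean_cor("blood", "F")), 0.15)
  expect_lt(abs(mean_cor("sputum", "M")), 0.15)
})

test_that("cohort configuration errors are caught", {
  expect_error(cohort_config(n_female = 5), "at least 10")
  expect_error(
    cohort_config(modules = list(module_spec("F", "lung", "TF001", "G0001"))),
    "unknown tissue")
  expect_error(
    generate_cohort(cohort_config(n_genes = 10, de_genes = c(G9999 = 1))),
    "not in gene universe")
})

test_that("regulatory truth honours density, module forcing and set layout", {
  mod <- module_spec("F", "sputum", sprintf("TF%03d", 1:2),
                     sprintf("G%04d", 1:15))
  tr <- generate_regulatory_truth(truth_config(n_tf = 130, n_genes = 400,
                                               prior_density = 0.05,
                                               modules = list(mod), seed = 4))
  expect_equal(nrow(tr$motif_prior), 130)
  expect_true(all(tr$motif_prior[mod$tf_ids, mod$gene_ids] == 1))
  # density within binomial tolerance (4 sd)
  dens <- mean(tr$motif_prior)
  expect_lt(abs(dens - 0.05), 4 * sqrt(0.05 * 0.95 / (130 * 400)) + 30 / (130 * 400))
  expect_true(all(diag(tr$ppi) == 1))
  expect_identical(tr$ppi, t(tr$ppi))
  expect_true("MODULE_F_sputum_1" %in% names(tr$gene_sets))
  sizes <- lengths(tr$gene_sets)
  expect_true(all(sizes == 15))
  expect_true(all(unlist(tr$gene_sets) %in% tr$genes))
})

test_that("zero prior density with no modules gives an empty prior", {
  tr <- generate_regulatory_truth(truth_config(n_tf = 5, n_genes = 20,
                                               prior_density = 0, seed = 1))
  expect_true(all(tr$motif_prior == 0))
})

test_that("truth configuration rejects invalid densities and oversized modules", {
  expect_error(truth_config(prior_density = 1.2), "outside")
  expect_error(truth_config(prior_density = -0.1), "outside")
  expect_error(
    truth_config(n_tf = 2, n_genes = 5,
                 modules = list(module_spec("F", "sputum", "TF001",
                                            sprintf("G%04d", 1:10)))),
    "larger than the universe")
})

test_that("promoter fixtures have the configured records and planted sites", {
  fx <- generate_promoter_fixtures(seq_config(genes = 10, n_pwms = 3,
                                              planted_sites = 5, seed = 9))
  expect_length(fx$promoters, 10)
  expect_equal(nrow(fx$planted_sites), 5)
  expect_true(all(Biostrings::width(fx$promoters) == 1001))
  # planted consensus really sits at the recorded offset
  for (i in seq_len(nrow(fx$planted_sites))) {
    st <- fx$planted_sites[i, ]
    p <- fx$pwms[[st$tf]]
    found <- substr(as.character(fx$promoters[[st$gene]]),
                    751 + st$offset, 751 + st$offset + p$length - 1)
    expected <- pwm_consensus(p)
    if (st$strand == "-")
      expected <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(expected)))
    expect_identical(found, expected)
  }
  # determinism
  fx2 <- generate_promoter_fixtures(seq_config(genes = 10, n_pwms = 3,
                                               planted_sites = 5, seed = 9))
  expect_identical(as.character(fx$promoters), as.character(fx2$promoters))
})

test_that("promoter fixture errors are caught", {
  expect_error(seq_config(promoter_length = 500), ">= 1001")
  expect_error(seq_config(background = c(A = 0.5, C = 0.5, G = 0.5, T = 0.5)),
               "sum to 1")
  bad <- data.frame(gene = "G0001", tf = "PWM1", offset = 400L, strand = "+")
  expect_error(
    generate_promoter_fixtures(seq_config(genes = 2, planted_sites = bad)),
    "outside the promoter window")
})
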