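# Biomarker predicates and concordance verdicts.

# Small deterministic cohort shared across the tests below.
marker_cohort <- function(seed = 41, n = 40) {
  set.seed(seed)
  samples <- sprintf("S%02d", seq_len(n))
  genes <- c("SGA", "SGB", "SGC")
  mut <- matrix(rbinom(3 * n, 1, 0.3), 3, n,
                dimnames = list(genes, samples))
  calls <- mutation_calls(
    sample_id = samples[mut["SGB", ] == 1],
    gene = "SGB", consequence_class = "missense",
    protein_change = sample(c("V600E", "V600K", "G12D"),
                            sum(mut["SGB", ]), replace = TRUE))
  raw <- matrix(rexp(3 * n, 0.2), 3, n,
                dimnames = list(genes, samples))
  expr <- normalize_expression(raw, genes)
  ann <- sample_annotations(data.frame(
    sample_id = samples,
    tumor_site = rep(c("site_a", "site_b"), length.out = n),
    receptor_positive = rbinom(n, 1, 0.4) == 1,
    stringsAsFactors = FALSE))
  list(samples = samples, mut = mut, calls = calls, expr = expr,
       ann = ann)
}

test_that("build_marker_vector implements each rule type", {
  co <- marker_cohort()
  p_mut <- biomarker_predicate("m", "D", rule_mutation_in_genes("SGA"),
                               "marker_more_sensitive")
  v <- build_marker_vector(p_mut, mut = co$mut, ann = co$ann)
  expect_equal(unname(v), unname(co$mut["SGA", ] == 1))

  # wildtype is the elementwise complement of mutation_in_genes
  p_wt <- biomarker_predicate("w", "D", rule_wildtype_in_genes("SGA"),
                              "marker_more_resistant")
  expect_equal(build_marker_vector(p_wt, mut = co$mut, ann = co$ann), !v)

  # variant match keys on the protein change, not mere mutation status
  p_var <- biomarker_predicate("v", "D",
                               rule_variant_match("SGB", c("V600E", "V600K")),
                               "marker_more_sensitive")
  vv <- build_marker_vector(p_var, calls = co$calls, ann = co$ann)
  hit <- co$calls$sample_id[co$calls$protein_change %in% c("V600E", "V600K")]
  expect_equal(unname(vv), co$samples %in% hit)
  expect_true(sum(vv) < sum(co$mut["SGB", ]))  # G12D carriers excluded

  # median split on 4 distinct values marks exactly the top 2
  expr4 <- matrix(c(1, 2, 3, 4), 1, 4,
                  dimnames = list("SGX", paste0("Q", 1:4)))
  ann4 <- sample_annotations(data.frame(sample_id = paste0("Q", 1:4)))
  p_q <- biomarker_predicate("q", "D",
                             rule_expression_above_quantile("SGX", 0.5),
                             "marker_more_resistant")
  vq <- build_marker_vector(p_q, expr = expr4, ann = ann4)
  expect_equal(sum(vq), 2)
  expect_equal(unname(vq), c(FALSE, FALSE, TRUE, TRUE))

  p_flag <- biomarker_predicate("f", "D",
                                rule_annotation_flag("receptor_positive"),
                                "marker_more_sensitive")
  expect_equal(unname(build_marker_vector(p_flag, ann = co$ann)),
               co$ann$receptor_positive)
})

test_that("build_marker_vector validates genes, flags and cohort filters", {
  co <- marker_cohort()
  bad_gene <- biomarker_predicate("x", "D", rule_mutation_in_genes("NOPE"),
                                  "marker_more_sensitive")
  expect_error(build_marker_vector(bad_gene, mut = co$mut, ann = co$ann),
               "NOPE")
  bad_flag <- biomarker_predicate("x", "D", rule_annotation_flag("nope"),
                                  "marker_more_sensitive")
  expect_error(build_marker_vector(bad_flag, ann = co$ann), "nope")
  empty <- biomarker_predicate("x", "D", rule_mutation_in_genes("SGA"),
                               "marker_more_sensitive",
                               cohort_filter = "site_z")
  expect_error(build_marker_vector(empty, mut = co$mut, ann = co$ann),
               "0 samples")
})

test_that("cohort filtering commutes with marker evaluation", {
  co <- marker_cohort()
  pred_all <- biomarker_predicate("m", "D", rule_mutation_in_genes("SGA"),
                                  "marker_more_sensitive")
  pred_a <- biomarker_predicate("m", "D", rule_mutation_in_genes("SGA"),
                                "marker_more_sensitive",
                                cohort_filter = "site_a")
  v_all <- build_marker_vector(pred_all, mut = co$mut, ann = co$ann)
  v_a <- build_marker_vector(pred_a, mut = co$mut, ann = co$ann)
  in_a <- co$ann$sample_id[co$ann$tumor_site == "site_a"]
  expect_identical(v_a, v_all[in_a])
})

test_that("verdicts follow direction and p-value deterministically", {
  co <- marker_cohort(seed = 43, n = 60)
  marker <- co$mut["SGA", ] == 1
  set.seed(7)
  base <- rnorm(60, sd = 0.4)
  shifted <- base - 1 * marker     # marker-positive scored more sensitive
  scores <- rbind(DrugS = shifted)
  colnames(scores) <- co$samples

  p_sens <- biomarker_predicate("planted", "DrugS",
                                rule_mutation_in_genes("SGA"),
                                "marker_more_sensitive")
  rep1 <- evaluate_biomarkers(list(p_sens), scores, mut = co$mut,
                              ann = co$ann)
  expect_equal(rep1$verdict, "concordant")
  expect_lt(rep1$p, 0.05)

  # the same data with the opposite expectation is discordant
  p_res <- biomarker_predicate("planted", "DrugS",
                               rule_mutation_in_genes("SGA"),
                               "marker_more_resistant")
  expect_equal(evaluate_biomarkers(list(p_res), scores, mut = co$mut,
                                   ann = co$ann)$verdict, "discordant")

  # re-evaluation is deterministic
  rep2 <- evaluate_biomarkers(list(p_sens), scores, mut = co$mut,
                              ann = co$ann)
  expect_identical(rep1, rep2)
})

test_that("null shifts are non-significant at close to the nominal rate", {
  co <- marker_cohort(seed = 44, n = 60)
  marker_pred <- biomarker_predicate("null", "DrugN",
                                     rule_mutation_in_genes("SGA"),
                                     "marker_more_sensitive")
  hits <- 0
  n_rep <- 200
  set.seed(45)
  for (i in seq_len(n_rep)) {
    scores <- rbind(DrugN = rnorm(60))
    colnames(scores) <- co$samples
    r <- evaluate_biomarkers(list(marker_pred), scores, mut = co$mut,
                             ann = co$ann)
    if (r$verdict %in% c("concordant", "discordant")) hits <- hits + 1
  }
  # two-sided significance at 0.05 under the null: ~5% of replicates
  expect_gt(hits / n_rep, 0.01)
  expect_lt(hits / n_rep, 0.10)
})

test_that("the shipped example config loads into valid predicates", {
  cfg <- read_biomarker_config(
    system.file("extdata", "synthetic_biomarker_config.yaml",
                package = "pharmsig"))
  expect_length(cfg, 5)
  types <- vapply(cfg, function(p) p$rule$type, "")
  expect_setequal(types, c("mutation_in_genes", "variant_match",
                           "expression_above_quantile",
                           "wildtype_in_genes", "annotation_flag"))
  expect_equal(cfg[[2]]$cohort_filter, "site_a")
  expect_equal(cfg[[3]]$rule$q, 0.5)
})
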