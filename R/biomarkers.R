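# Machine-checkable biomarker-drug indications: each FDA-style indication
# becomes a predicate (rule + cohort filter + expected direction) whose
# marker vector is evaluated against the predicted sensitivity scores,
# yielding a concordance verdict per indication.

#' Construct a biomarker predicate
#'
#' @param name Human-readable indication name.
#' @param drug_id Drug whose scores are compared.
#' @param rule One of the `rule_*` constructors below.
#' @param expected_direction `"marker_more_sensitive"` or
#'   `"marker_more_resistant"`.
#' @param cohort_filter Character vector of `tumor_site` values restricting
#'   the cohort (empty = all samples).
#' @return List of class `biomarker_predicate`.
#' @export
biomarker_predicate <- function(name, drug_id, rule, expected_direction,
                                cohort_filter = character()) {
  expected_direction <- match.arg(expected_direction,
                                  c("marker_more_sensitive",
                                    "marker_more_resistant"))
  stopifnot(inherits(rule, "biomarker_rule"))
  structure(list(name = name, drug_id = drug_id, rule = rule,
                 expected_direction = expected_direction,
                 cohort_filter = as.character(cohort_filter)),
            class = "biomarker_predicate")
}

#' Biomarker rules
#'
#' * `rule_mutation_in_genes(genes)`: protein-altering mutation in any of
#'   the genes (e.g. an HRD gene set supplied by the user).
#' * `rule_wildtype_in_genes(genes)`: the elementwise complement.
#' * `rule_variant_match(gene, patterns)`: a specific protein change, e.g.
#'   `BRAF` with patterns `c("V600E", "V600K")`.
#' * `rule_expression_above_quantile(gene, q)`: sample's normalized
#'   expression strictly greater than the within-cohort-filter quantile
#'   `q` (ties fall in the negative group).
#' * `rule_annotation_flag(flag)`: a boolean annotation column (receptor
#'   status, promoter methylation, fusion calls consumed as flags).
#'
#' @param genes,gene Gene symbol(s).
#' @param patterns Protein-change strings (without the `p.` prefix).
#' @param q Quantile in (0, 1).
#' @param flag Annotation flag column name.
#' @return List of class `biomarker_rule`.
#' @name biomarker_rules
NULL

#' @rdname biomarker_rules
#' @export
rule_mutation_in_genes <- function(genes) {
  stopifnot(length(genes) > 0)
  structure(list(type = "mutation_in_genes", genes = toupper(genes)),
            class = "biomarker_rule")
}

#' @rdname biomarker_rules
#' @export
rule_wildtype_in_genes <- function(genes) {
  stopifnot(length(genes) > 0)
  structure(list(type = "wildtype_in_genes", genes = toupper(genes)),
            class = "biomarker_rule")
}

#' @rdname biomarker_rules
#' @export
rule_variant_match <- function(gene, patterns) {
  stopifnot(length(gene) == 1, length(patterns) > 0)
  structure(list(type = "variant_match", gene = toupper(gene),
                 patterns = sub("^p\\.", "", patterns)),
            class = "biomarker_rule")
}

#' @rdname biomarker_rules
#' @export
rule_expression_above_quantile <- function(gene, q) {
  stopifnot(length(gene) == 1, q > 0, q < 1)
  structure(list(type = "expression_above_quantile", gene = toupper(gene),
                 q = q),
            class = "biomarker_rule")
}

#' @rdname biomarker_rules
#' @export
rule_annotation_flag <- function(flag) {
  stopifnot(length(flag) == 1)
  structure(list(type = "annotation_flag", flag = flag),
            class = "biomarker_rule")
}

#' Load biomarker predicates from a YAML config
#'
#' Each entry supplies `name`, `drug`, `direction`, optional `cohort`
#' (tumor-site list) and a `rule` block with a `type` matching one of the
#' [biomarker_rules] plus its parameters.  See
#' `system.file("extdata", "biomarker_config.yaml", package = "pharmsig")`
#' for a worked example.
#'
#' @param path YAML file path.
#' @return List of [biomarker_predicate()] objects.
#' @export
read_biomarker_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(e) {
    r <- e$rule
    rule <- switch(r$type,
      mutation_in_genes = rule_mutation_in_genes(unlist(r$genes)),
      wildtype_in_genes = rule_wildtype_in_genes(unlist(r$genes)),
      variant_match = rule_variant_match(r$gene, unlist(r$patterns)),
      expression_above_quantile =
        rule_expression_above_quantile(r$gene, r$q),
      annotation_flag = rule_annotation_flag(r$flag),
      stop_fmt("read_biomarker_config: unknown rule type '%s'", r$type)
    )
    biomarker_predicate(e$name, e$drug, rule, e$direction,
                        cohort_filter = unlist(e$cohort) %||% character())
  })
}

#' Evaluate a predicate's marker vector over the cohort-filtered samples
#'
#' @param predicate A [biomarker_predicate()].
#' @param mut Genes-by-samples binary matrix ([binarize_mutations()]).
#' @param calls A [mutation_calls()] table (for `variant_match`).
#' @param expr Normalized expression matrix ([normalize_expression()]).
#' @param ann A [sample_annotations()] data frame (defines the cohort and
#'   tumor sites).
#' @return Named logical vector over the cohort-filtered samples.
#' @export
build_marker_vector <- function(predicate, mut = NULL, calls = NULL,
                                expr = NULL, ann = NULL) {
  stopifnot(inherits(predicate, "biomarker_predicate"))
  if (is.null(ann)) stop_fmt("build_marker_vector: annotations are required")
  samples <- ann$sample_id
  if (length(predicate$cohort_filter) > 0) {
    if (!"tumor_site" %in% names(ann))
      stop_fmt("build_marker_vector: cohort filter given but annotations lack 'tumor_site'")
    samples <- samples[ann$tumor_site %in% predicate$cohort_filter]
  }
  if (length(samples) == 0)
    stop_fmt("build_marker_vector: cohort filter '%s' selects 0 samples",
             paste(predicate$cohort_filter, collapse = ","))
  r <- predicate$rule
  out <- switch(r$type,
    mutation_in_genes = {
      miss <- setdiff(r$genes, rownames(mut))
      if (length(miss) > 0)
        stop_fmt("build_marker_vector: gene(s) absent from the mutation matrix: %s",
                 paste(miss, collapse = ", "))
      colSums(mut[r$genes, samples, drop = FALSE]) > 0
    },
    wildtype_in_genes = {
      miss <- setdiff(r$genes, rownames(mut))
      if (length(miss) > 0)
        stop_fmt("build_marker_vector: gene(s) absent from the mutation matrix: %s",
                 paste(miss, collapse = ", "))
      colSums(mut[r$genes, samples, drop = FALSE]) == 0
    },
    variant_match = {
      if (is.null(calls)) stop_fmt("build_marker_vector: variant_match needs the call table")
      hit <- calls$gene == r$gene &
        !is.na(calls$protein_change) &
        calls$protein_change %in% r$patterns
      stats::setNames(samples %in% calls$sample_id[hit], samples)
    },
    expression_above_quantile = {
      if (!r$gene %in% rownames(expr))
        stop_fmt("build_marker_vector: gene '%s' absent from the expression matrix",
                 r$gene)
      keep <- intersect(samples, colnames(expr))
      if (length(keep) < length(samples))
        stop_fmt("build_marker_vector: %d cohort sample(s) lack expression data",
                 length(samples) - length(keep))
      v <- expr[r$gene, samples]
      v > stats::quantile(v, r$q)     # strict: ties are marker-negative
    },
    annotation_flag = {
      if (!r$flag %in% attr(ann, "flags"))
        stop_fmt("build_marker_vector: unknown annotation flag '%s'", r$flag)
      stats::setNames(ann[[r$flag]][match(samples, ann$sample_id)], samples)
    }
  )
  stats::setNames(as.logical(out), samples)
}

#' Evaluate predicted-score concordance with biomarker indications
#'
#' For each predicate, compares the drug's predicted scores between
#' marker-positive and marker-negative samples (Welch test,
#' [two_sample_t()]) within the cohort filter, and derives a verdict:
#' `concordant` (p < `p_threshold`, observed direction matches the
#' expectation), `discordant` (p < `p_threshold`, direction opposite),
#' `borderline` (`p_threshold` <= p < `borderline_threshold`, direction
#' matches), otherwise `non_significant`.  Verdicts are a pure function of
#' (direction, p, thresholds).
#'
#' @param predicates List of [biomarker_predicate()] objects.
#' @param scores Drugs-by-samples score matrix.
#' @param mut,calls,expr,ann Cohort data passed to [build_marker_vector()].
#' @param p_threshold Significance threshold (default 0.05).
#' @param borderline_threshold Upper edge of the borderline band
#'   (default 0.10).
#' @return Data frame of class `concordance_report`: one row per predicate
#'   with the group-comparison fields and the verdict.
#' @export
evaluate_biomarkers <- function(predicates, scores, mut = NULL,
                                calls = NULL, expr = NULL, ann = NULL,
                                p_threshold = 0.05,
                                borderline_threshold = 0.10) {
  rows <- lapply(predicates, function(pr) {
    if (!pr$drug_id %in% rownames(scores))
      stop_fmt("evaluate_biomarkers: drug '%s' absent from the score matrix",
               pr$drug_id)
    marker <- build_marker_vector(pr, mut = mut, calls = calls,
                                  expr = expr, ann = ann)
    common <- intersect(names(marker), colnames(scores))
    cmp <- two_sample_t(scores[pr$drug_id, common], marker[common])
    match_dir <- cmp$direction == pr$expected_direction
    verdict <- if (cmp$p < p_threshold) {
      if (match_dir) "concordant" else "discordant"
    } else if (cmp$p < borderline_threshold && match_dir) {
      "borderline"
    } else {
      "non_significant"
    }
    data.frame(name = pr$name, drug_id = pr$drug_id,
               expected = pr$expected_direction, observed = cmp$direction,
               t = cmp$t, df = cmp$df, p = cmp$p,
               mean_pos = cmp$mean_pos, mean_neg = cmp$mean_neg,
               n_pos = cmp$n_pos, n_neg = cmp$n_neg, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("concordance_report", "data.frame")
  out
}

#' Export a concordance report as TSV
#' @param report A `concordance_report` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_concordance_report <- function(report, path) {
  write_tsv_file(as.data.frame(report), path)
}
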