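# Pan-cancer mutation-drug sensitivity scan: for every (drug, gene) pair
# passing the frequency and named-drug filters, an ordinary least-squares
# model of the drug's predicted score on mutation status with a tumor-site
# covariate; pairs are ranked by the mutation coefficient's t statistic
# (most negative = most sensitizing) and the top fraction selected.

#' Configuration for the mutation-drug scan
#'
#' @param min_mutation_freq Minimum pan-cancer mutation frequency for a
#'   gene to enter the scan (default 0.05; genes at frequency >=
#'   the threshold are kept).
#' @param top_fraction Fraction of ranked pairs selected for follow-up
#'   (default 0.01, "the top 1%").
#' @param drug_allowlist Optional character vector restricting the scan to
#'   named drugs further along the regulatory process; `NULL` = all drugs.
#' @param rank_by `"t"` (signed, ascending: sensitizing associations
#'   first) or `"abs_t"` (two-sided discovery).
#' @return List of class `scan_config`.
#' @export
scan_config <- function(min_mutation_freq = 0.05, top_fraction = 0.01,
                        drug_allowlist = NULL, rank_by = c("t", "abs_t")) {
  stopifnot(min_mutation_freq > 0, min_mutation_freq < 1,
            top_fraction > 0, top_fraction <= 1)
  structure(list(min_mutation_freq = min_mutation_freq,
                 top_fraction = top_fraction,
                 drug_allowlist = drug_allowlist,
                 rank_by = match.arg(rank_by)),
            class = "scan_config")
}

#' Scan for mutation-drug sensitivity associations
#'
#' For each eligible drug `d` and gene `g`, fits
#' `score_d ~ intercept + mutation_g + tumor_site` (the site entering as
#' one-hot columns against the lexicographically first reference level —
#' the mutation t statistic is invariant to that choice) and records the
#' mutation coefficient, its t statistic and two-sided p-value.  Pairs
#' whose design matrix is rank-deficient (e.g. a mutation confounded with
#' a site) are skipped with the reason recorded in
#' `attr(result, "skipped")`.  Results are sorted by t (ascending under
#' `rank_by = "t"`; ties broken lexicographically by drug then gene) and
#' assigned dense ranks 1..K.  BH-adjusted p-values are reported alongside
#' for context; the ranking itself uses the raw t.
#'
#' @param scores Drugs-by-samples score matrix.
#' @param mut Genes-by-samples binary mutation matrix.
#' @param ann A [sample_annotations()] data frame with `tumor_site`
#'   (>= 2 sites must be represented).
#' @param config A [scan_config()].
#' @return Data frame of class `association_results` with columns `rank`,
#'   `drug_id`, `gene`, `coefficient`, `t`, `p`, `fdr`, `freq`.
#' @export
mutation_drug_scan <- function(scores, mut, ann, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  if (!"tumor_site" %in% names(ann))
    stop_fmt("mutation_drug_scan: annotations lack 'tumor_site'")
  samples <- Reduce(intersect, list(colnames(scores), colnames(mut),
                                    ann$sample_id))
  if (length(samples) < 3)
    stop_fmt("mutation_drug_scan: only %d sample(s) shared across inputs",
             length(samples))
  site <- factor(ann$tumor_site[match(samples, ann$sample_id)])
  if (nlevels(droplevels(site)) < 2)
    stop_fmt("mutation_drug_scan: need >= 2 tumor sites represented")
  site <- droplevels(site)
  freq <- rowMeans(mut[, samples, drop = FALSE])
  genes <- rownames(mut)[freq >= config$min_mutation_freq]
  if (length(genes) == 0)
    stop_fmt("mutation_drug_scan: no gene reaches mutation frequency %g",
             config$min_mutation_freq)
  drugs <- rownames(scores)
  if (!is.null(config$drug_allowlist))
    drugs <- intersect(drugs, config$drug_allowlist)
  if (length(drugs) == 0)
    stop_fmt("mutation_drug_scan: no drug passes the allowlist")
  rows <- list()
  skipped <- character()
  for (d in drugs) {
    y <- scores[d, samples]
    for (g in genes) {
      mg <- as.numeric(mut[g, samples])
      fit <- stats::lm(y ~ mg + site)
      cf <- summary(fit)$coefficients
      if (anyNA(stats::coef(fit)) || !"mg" %in% rownames(cf)) {
        skipped[[paste(d, g, sep = "/")]] <-
          "rank-deficient design (mutation aliased with site)"
        next
      }
      rows[[paste(d, g, sep = "/")]] <-
        data.frame(drug_id = d, gene = g, coefficient = cf["mg", 1L],
                   t = cf["mg", 3L], p = cf["mg", 4L],
                   freq = unname(freq[g]), stringsAsFactors = FALSE)
    }
  }
  if (length(skipped) > 0)
    message(sprintf("mutation_drug_scan: skipped %d pair(s): %s",
                    length(skipped),
                    paste(names(skipped), collapse = ", ")))
  if (length(rows) == 0)
    stop_fmt("mutation_drug_scan: every (drug, gene) pair was skipped")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  key <- if (config$rank_by == "t") out$t else -abs(out$t)
  ord <- order(key, out$drug_id, out$gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$fdr <- bh_adjust(out$p)
  out <- out[, c("rank", "drug_id", "gene", "coefficient", "t", "p",
                 "fdr", "freq")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("association_results", "data.frame")
  out
}

#' Select the top fraction of ranked associations
#'
#' @param results Ranked `association_results` from
#'   [mutation_drug_scan()].
#' @param fraction Fraction of the K eligible pairs to keep; the count is
#'   `ceiling(fraction * K)`, so the output is never empty.
#' @return The first `ceiling(fraction * K)` rows by rank.
#' @export
top_fraction <- function(results, fraction = 0.01) {
  if (is.null(results) || nrow(results) == 0)
    stop_fmt("top_fraction: empty result set")
  stopifnot(fraction > 0, fraction <= 1)
  k <- ceiling(fraction * nrow(results))
  results[order(results$rank)[seq_len(k)], , drop = FALSE]
}

#' Export association results as TSV
#' @param results An `association_results` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_association_results <- function(results, path) {
  write_tsv_file(as.data.frame(results), path)
}
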