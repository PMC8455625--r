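# Validation statistics for locked signatures: per-drug Pearson
# correlation against external drug response (negative AUC) with
# Benjamini-Hochberg FDR; Welch two-sample comparisons of scores between
# biomarker groups; and the treatment-by-score logistic interaction test
# that distinguishes predictive from merely prognostic biomarkers.

#' Pearson correlation with p-value and Fisher-z confidence interval
#'
#' Standard product-moment correlation; the two-sided p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, and
#' the 95% confidence interval from the Fisher z transform.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @param conf_level Confidence level for the interval.
#' @return List with `r`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y))
    stop_fmt("pearson_with_p: length mismatch (%d vs %d)", length(x),
             length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_fmt("pearson_with_p: need n >= 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_fmt("pearson_with_p: constant input vector")
  ct <- stats::cor.test(x, y, method = "pearson",
                        conf.level = conf_level)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1L],
       ci_high = ct$conf.int[2L], p = ct$p.value, n = length(x))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Sorted ascending, `adj_i = min_(j >= i) (p_(j) * m / j)`, capped at 1,
#' returned in input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop_fmt("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Correlate predicted scores with external drug response
#'
#' For each drug present in both inputs, computes the Pearson correlation
#' between the predicted sensitivity score and the *negative* AUC over the
#' paired samples (higher AUC means lower IC50, so a well-calibrated score
#' correlates positively with -AUC), then adjusts the p-values across all
#' tested drugs by Benjamini-Hochberg.  Drugs with fewer than 3 paired
#' samples (or constant values) are skipped with a warning.
#'
#' @param scores Drugs-by-samples score matrix from [predict_scores()].
#' @param responses A [drug_response()] table; only `measure == "auc"`
#'   records are used.
#' @return Data frame of class `correlation_results` with columns
#'   `drug_id`, `n`, `r`, `ci_low`, `ci_high`, `p`, `fdr`.
#' @export
validate_against_response <- function(scores, responses) {
  auc <- responses[responses$measure == "auc", , drop = FALSE]
  drugs <- intersect(rownames(scores), unique(auc$drug_id))
  rows <- list()
  skipped <- character()
  for (d in drugs) {
    rd <- auc[auc$drug_id == d, , drop = FALSE]
    common <- intersect(colnames(scores), rd$sample_id)
    s <- scores[d, common]
    a <- stats::setNames(rd$value, rd$sample_id)[common]
    if (length(common) < 3 || stats::sd(s) == 0 || stats::sd(a) == 0) {
      skipped[[d]] <- sprintf("%d paired samples", length(common))
      next
    }
    pr <- pearson_with_p(s, -a)
    rows[[d]] <- data.frame(drug_id = d, n = pr$n, r = pr$r,
                            ci_low = pr$ci_low, ci_high = pr$ci_high,
                            p = pr$p, stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0)
    warn_fmt("validate_against_response: skipped %d drug(s): %s",
             length(skipped),
             paste(sprintf("%s (%s)", names(skipped), skipped),
                   collapse = "; "))
  if (length(rows) == 0)
    stop_fmt("validate_against_response: no drug has >= 3 paired samples")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- bh_adjust(out$p)
  class(out) <- c("correlation_results", "data.frame")
  out
}

#' Welch unpaired two-sample comparison of scores by marker status
#'
#' Welch t statistic with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value.  The direction flag is `"marker_more_sensitive"`
#' when the marker-positive group has the lower mean score (lower score =
#' predicted more sensitive).
#'
#' @param scores Numeric vector of per-sample scores.
#' @param marker Logical vector: `TRUE` = marker-positive.
#' @return List of class `group_comparison` with `t`, `df`, `p`,
#'   `mean_pos`, `mean_neg`, `n_pos`, `n_neg`, `direction`.
#' @export
two_sample_t <- function(scores, marker) {
  if (length(scores) != length(marker))
    stop_fmt("two_sample_t: length mismatch")
  ok <- !is.na(scores) & !is.na(marker)
  scores <- scores[ok]; marker <- as.logical(marker[ok])
  pos <- scores[marker]; neg <- scores[!marker]
  if (length(pos) < 2 || length(neg) < 2)
    stop_fmt("two_sample_t: each group needs >= 2 samples (got %d / %d)",
             length(pos), length(neg))
  if (stats::sd(pos) == 0 && stats::sd(neg) == 0) {
    if (mean(pos) == mean(neg)) {
      res <- list(t = 0, df = length(scores) - 2, p = 1)
    } else {
      stop_fmt("two_sample_t: both groups have zero variance")
    }
  } else {
    tt <- stats::t.test(pos, neg, var.equal = FALSE)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  structure(list(t = res$t, df = res$df, p = res$p,
                 mean_pos = mean(pos), mean_neg = mean(neg),
                 n_pos = length(pos), n_neg = length(neg),
                 direction = if (mean(pos) < mean(neg))
                   "marker_more_sensitive" else "marker_more_resistant"),
            class = "group_comparison")
}

#' Treatment-by-score logistic interaction test
#'
#' Fits the maximum-likelihood logistic model
#' `response ~ treatment + score + treatment:score` by iteratively
#' reweighted least squares (tolerance 1e-8, up to 100 iterations) and
#' reports Wald inference for each coefficient.  A significant interaction
#' establishes the score as a *predictive* biomarker (treatment-effect
#' modifier) rather than a merely prognostic one.  Non-convergence or
#' separation (any coefficient exceeding 15 in magnitude on the
#' standardized-score scale, or fitted probabilities collapsing to 0/1) is
#' a diagnostic error — no silent estimates.
#'
#' @param response Binary 0/1 outcome vector.
#' @param treatment Binary 0/1 treatment indicator.
#' @param score Numeric per-sample sensitivity score.
#' @param lr_test Also compute a likelihood-ratio p-value for the
#'   interaction term.
#' @return List of class `interaction_result`: `coefficients` (data frame
#'   with `term`, `estimate`, `se`, `z`, `p`), `interaction_p`,
#'   `converged`, `n`, and optionally `lr_p`.
#' @export
interaction_test <- function(response, treatment, score, lr_test = FALSE) {
  n <- length(response)
  if (length(treatment) != n || length(score) != n)
    stop_fmt("interaction_test: input length mismatch")
  response <- as.numeric(response); treatment <- as.numeric(treatment)
  if (!all(response %in% c(0, 1)) || !all(treatment %in% c(0, 1)))
    stop_fmt("interaction_test: response and treatment must be binary 0/1")
  if (length(unique(treatment)) < 2)
    stop_fmt("interaction_test: only one treatment arm present")
  if (length(unique(response)) < 2)
    stop_fmt("interaction_test: response is constant")
  if (n < 20)
    warn_fmt("interaction_test: n = %d (< 20); estimates may be unstable", n)
  fit <- suppressWarnings(
    stats::glm(response ~ treatment * score, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  if (!fit$converged)
    stop_fmt("interaction_test: IRLS did not converge within 100 iterations")
  cf <- stats::coef(fit)
  # coefficients re-expressed on the standardized-score scale (exact
  # reparametrization) for the separation diagnostic
  m <- mean(score); s <- stats::sd(score)
  cf_std <- c(cf[1L] + cf[3L] * m, cf[2L] + cf[4L] * m,
              cf[3L] * s, cf[4L] * s)
  mu <- stats::fitted(fit)
  if (any(abs(cf_std) > 15) || all(mu > 1 - 1e-8 | mu < 1e-8))
    stop_fmt("interaction_test: complete or quasi-separation detected (diverging coefficients)")
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = c("intercept", "treatment", "score",
                               "treatment:score"),
                      estimate = sm[, 1L], se = sm[, 2L], z = sm[, 3L],
                      p = sm[, 4L], row.names = NULL,
                      stringsAsFactors = FALSE)
  out <- list(coefficients = coefs,
              interaction_p = coefs$p[coefs$term == "treatment:score"],
              converged = TRUE, n = n)
  if (lr_test) {
    fit0 <- suppressWarnings(
      stats::glm(response ~ treatment + score, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100))
    )
    out$lr_p <- stats::pchisq(fit0$deviance - fit$deviance, df = 1,
                              lower.tail = FALSE)
  }
  structure(out, class = "interaction_result")
}

#' Export correlation results as a validation table
#' @param results A `correlation_results` data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_results <- function(results, path) {
  write_tsv_file(as.data.frame(results), path)
}
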