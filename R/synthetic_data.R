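# Synthetic pharmacogenomic cohorts with stored ground truth.  The
# generators emulate the statistical structure the pipeline assumes —
# sparse linear mutation/expression effects on a per-drug response,
# platform batch shifts neutralized by median centering, and a
# treatment-by-score interaction on a binary clinical endpoint — so every
# stage is testable without external downloads.  All generators are pure
# functions of (config, seed).

#' Configuration for a synthetic training cohort
#'
#' Per-gene parameters left `NULL` are drawn once, deterministically from
#' `seed`, inside the constructor: mutation rates uniform on
#' \[0.1, 0.4\], log2 expression means on \[2, 8\] and SDs on
#' \[0.5, 1.5\].  Per-drug truth (when `drug_truth` is `NULL`) plants
#' `n_causal` nonzero coefficients per drug with magnitudes uniform on
#' \[0.5, 1.5\] and random signs over the `<GENE>:expr` / `<GENE>:mut`
#' feature space, with residual noise `sigma`.
#'
#' @param n_samples Number of cell lines.
#' @param n_genes Panel size (symbols `SG001`, `SG002`, ...).
#' @param n_drugs Number of drugs (ids `DRUG01`, ...).
#' @param n_causal Nonzero coefficients planted per drug.
#' @param sigma Residual noise SD on the raw (pre-Z-scoring) response.
#' @param mutation_rates,expr_mean,expr_sd Optional per-gene vectors
#'   overriding the defaults.
#' @param drug_truth Optional named list per drug:
#'   `list(intercept =, coefficients = <named numeric>, sigma =)`.
#' @param seed Integer seed; the generators consume no other randomness.
#' @return List of class `training_cohort_config`.
#' @export
training_cohort_config <- function(n_samples = 500, n_genes = 60,
                                   n_drugs = 10, n_causal = 5,
                                   sigma = 0.5, mutation_rates = NULL,
                                   expr_mean = NULL, expr_sd = NULL,
                                   drug_truth = NULL, seed = 1) {
  stopifnot(n_samples >= 2, n_genes >= 1, sigma > 0)
  genes <- sprintf("SG%03d", seq_len(n_genes))
  cfg <- with_seed(seed, {
    pi_g <- mutation_rates %||% stats::runif(n_genes, 0.1, 0.4)
    mu_g <- expr_mean %||% stats::runif(n_genes, 2, 8)
    sd_g <- expr_sd %||% stats::runif(n_genes, 0.5, 1.5)
    if (any(pi_g < 0 | pi_g > 1))
      stop_fmt("training_cohort_config: mutation rates must lie in [0, 1]")
    if (any(sd_g <= 0))
      stop_fmt("training_cohort_config: expression SDs must be positive")
    feat_space <- c(paste0(genes, ":expr"), paste0(genes, ":mut"))
    truth <- drug_truth %||% {
      tr <- list()
      for (i in seq_len(n_drugs)) {
        picked <- sample(feat_space, n_causal)
        coefs <- stats::setNames(
          stats::runif(n_causal, 0.5, 1.5) * sample(c(-1, 1), n_causal,
                                                    replace = TRUE),
          picked)
        tr[[sprintf("DRUG%02d", i)]] <-
          list(intercept = stats::runif(1, -1, 1), coefficients = coefs,
               sigma = sigma)
      }
      tr
    }
    for (d in names(truth)) {
      bad <- setdiff(names(truth[[d]]$coefficients), feat_space)
      if (length(bad) > 0)
        stop_fmt("training_cohort_config: drug '%s' has coefficients outside the feature space: %s",
                 d, paste(bad, collapse = ", "))
      if (truth[[d]]$sigma <= 0)
        stop_fmt("training_cohort_config: drug '%s' has sigma <= 0", d)
    }
    list(mutation_rates = stats::setNames(pi_g, genes),
         expr_mean = stats::setNames(mu_g, genes),
         expr_sd = stats::setNames(sd_g, genes), drug_truth = truth)
  })
  structure(c(list(n_samples = as.integer(n_samples), genes = genes,
                   seed = as.integer(seed)), cfg),
            class = "training_cohort_config")
}

# Shared sampling of one cohort's raw data under a config.  Decoy silent
# and intronic calls are always emitted so downstream consequence
# filtering is exercised by default.
#' @noRd
sample_cohort <- function(config, sample_ids, mean_shift = 0) {
  genes <- config$genes
  n <- length(sample_ids)
  mu <- config$expr_mean + mean_shift
  fpkm <- matrix(0, nrow = length(genes), ncol = n,
                 dimnames = list(genes, sample_ids))
  for (g in seq_along(genes)) {
    fpkm[g, ] <- pmax(2^stats::rnorm(n, mu[g], config$expr_sd[g]) - 1, 0)
  }
  mut01 <- matrix(stats::rbinom(length(genes) * n, 1L,
                                rep(config$mutation_rates, times = n)),
                  nrow = length(genes), dimnames = list(genes, sample_ids))
  idx <- which(mut01 == 1L, arr.ind = TRUE)
  pos <- if (nrow(idx) > 0) sample(50:900, nrow(idx), replace = TRUE)
         else integer()
  call_df <- data.frame(
    sample_id = sample_ids[idx[, 2L]], gene = genes[idx[, 1L]],
    consequence_class = "missense",
    protein_change = if (nrow(idx) > 0)
      sprintf("A%dV", pos) else character(),
    stringsAsFactors = FALSE)
  # decoys: silent / intronic calls that must be ignored downstream
  decoy01 <- matrix(stats::rbinom(length(genes) * n, 1L, 0.08),
                    nrow = length(genes),
                    dimnames = list(genes, sample_ids))
  didx <- which(decoy01 == 1L, arr.ind = TRUE)
  decoy_df <- data.frame(
    sample_id = sample_ids[didx[, 2L]], gene = genes[didx[, 1L]],
    consequence_class = sample(c("silent", "intronic"), nrow(didx),
                               replace = TRUE),
    protein_change = NA_character_, stringsAsFactors = FALSE)
  all_calls <- rbind(call_df, decoy_df)
  calls <- mutation_calls(all_calls$sample_id, all_calls$gene,
                          all_calls$consequence_class,
                          all_calls$protein_change)
  list(fpkm = fpkm, calls = calls)
}

#' @noRd
cohort_features <- function(fpkm, calls, genes, sample_ids) {
  mutm <- binarize_mutations(calls, genes, sample_ids)
  exprm <- normalize_expression(fpkm, genes)
  assemble_features(exprm, mutm, genes)
}

#' @noRd
true_predictor <- function(config, features) {
  eta <- matrix(0, nrow = length(config$drug_truth), ncol = nrow(features),
                dimnames = list(names(config$drug_truth),
                                rownames(features)))
  for (d in names(config$drug_truth)) {
    tr <- config$drug_truth[[d]]
    f <- names(tr$coefficients)
    eta[d, ] <- tr$intercept +
      as.numeric(features[, f, drop = FALSE] %*% tr$coefficients)
  }
  eta
}

#' Generate a synthetic training cohort with stored truth
#'
#' Expression is `FPKM = max(2^N(mu_g, sd_g) - 1, 0)`; mutations are
#' per-gene Bernoulli draws emitted as missense calls (plus decoy silent
#' and intronic calls that downstream filtering must ignore); the response
#' for each drug is the planted sparse linear model over the features *as
#' the preprocessing module computes them*, plus Gaussian noise, then
#' Z-scored per drug across samples.
#'
#' @param config A [training_cohort_config()].
#' @return List with `expression` (FPKM matrix), `calls`
#'   ([mutation_calls()]), `response` ([drug_response()], `z_ic50`),
#'   `features` (the assembled feature matrix), and `truth` (the config
#'   plus, per drug, the raw linear predictor and the Z-scoring center and
#'   scale, so planted coefficients can be compared on the Z-score scale
#'   as `coefficients / z_scale`).
#' @export
gen_training_cohort <- function(config) {
  stopifnot(inherits(config, "training_cohort_config"))
  with_seed(config$seed + 1000L, {
    ids <- sprintf("CL%04d", seq_len(config$n_samples))
    raw <- sample_cohort(config, ids)
    features <- suppressMessages(
      cohort_features(raw$fpkm, raw$calls, config$genes, ids))
    eta <- true_predictor(config, features)
    rows <- list()
    truth_per_drug <- list()
    for (d in names(config$drug_truth)) {
      tr <- config$drug_truth[[d]]
      y_raw <- eta[d, ] + stats::rnorm(config$n_samples, 0, tr$sigma)
      ctr <- mean(y_raw); scl <- stats::sd(y_raw)
      y <- (y_raw - ctr) / scl
      rows[[d]] <- data.frame(drug_id = d, sample_id = ids,
                              measure = "z_ic50", value = unname(y),
                              stringsAsFactors = FALSE)
      truth_per_drug[[d]] <- list(eta = eta[d, ], z_center = ctr,
                                  z_scale = scl,
                                  coefficients = tr$coefficients,
                                  intercept = tr$intercept,
                                  sigma = tr$sigma)
    }
    resp <- do.call(rbind, rows)
    list(expression = raw$fpkm, calls = raw$calls,
         response = drug_response(resp$drug_id, resp$sample_id,
                                  resp$measure, resp$value),
         features = features,
         truth = list(config = config, drugs = truth_per_drug))
  })
}

#' Generate an external validation cohort sharing the training truth
#'
#' New samples from the same gene panel and truth, with per-gene platform
#' shifts added to the expression means before sampling (median centering
#' removes them downstream), and drug response reported as AUC: a monotone
#' *decreasing* transform of the true linear predictor plus noise, clipped
#' to \[0, 1\].  Under the linear transform with zero noise, -AUC
#' correlates with the true predictor at exactly r = 1.
#'
#' @param config The [training_cohort_config()] the truth is shared with.
#' @param n_samples External cohort size.
#' @param batch_shift Scalar or per-gene vector added to the log2
#'   expression means (the platform effect).
#' @param noise_sd SD of the AUC noise.
#' @param transform `"linear"` (range-mapped into \[0.05, 0.95\]) or
#'   `"logistic"` (`plogis(-eta)`).
#' @param seed Seed for this cohort (default `config$seed + 1`).
#' @return List with `expression`, `calls`, `response` (AUC), `features`,
#'   and `eta` (the true drugs-by-samples linear predictor).
#' @export
gen_external_cohort <- function(config, n_samples = 300, batch_shift = 0,
                                noise_sd = 0.02,
                                transform = c("linear", "logistic"),
                                seed = config$seed + 1L) {
  stopifnot(inherits(config, "training_cohort_config"))
  transform <- match.arg(transform)
  if (noise_sd < 0) stop_fmt("gen_external_cohort: noise_sd must be >= 0")
  with_seed(seed + 2000L, {
    ids <- sprintf("EXT%04d", seq_len(n_samples))
    raw <- sample_cohort(config, ids, mean_shift = batch_shift)
    features <- suppressMessages(
      cohort_features(raw$fpkm, raw$calls, config$genes, ids))
    eta <- true_predictor(config, features)
    rows <- list()
    for (d in rownames(eta)) {
      e <- eta[d, ]
      base <- if (transform == "linear") {
        if (max(e) > min(e))
          0.05 + 0.9 * (max(e) - e) / (max(e) - min(e))
        else rep(0.5, length(e))
      } else {
        stats::plogis(-e)
      }
      auc <- pmin(pmax(base + stats::rnorm(length(e), 0, noise_sd), 0), 1)
      rows[[d]] <- data.frame(drug_id = d, sample_id = ids,
                              measure = "auc", value = unname(auc),
                              stringsAsFactors = FALSE)
    }
    resp <- do.call(rbind, rows)
    list(expression = raw$fpkm, calls = raw$calls,
         response = drug_response(resp$drug_id, resp$sample_id,
                                  resp$measure, resp$value),
         features = features, eta = eta)
  })
}

#' Configuration for a synthetic clinical cohort
#'
#' Emulates a treated-versus-other clinical design with a binary response:
#' treatment is Bernoulli(`p_treat`), and response follows
#' `logit^-1(b0 + b_treatment*T + b_score*s + b_interaction*T*s)`.
#'
#' @param n_patients Cohort size.
#' @param p_treat Treatment assignment probability (1 allowed, to exercise
#'   the single-arm error path downstream).
#' @param b0,b_treatment,b_score,b_interaction Logistic coefficients.
#' @param tumor_sites Named probability vector over tumor sites.
#' @param seed Integer seed.
#' @return List of class `clinical_cohort_config`.
#' @export
clinical_cohort_config <- function(n_patients = 100, p_treat = 0.5,
                                   b0 = -0.25, b_treatment = 0,
                                   b_score = 0, b_interaction = -2,
                                   tumor_sites = c(prostate = 1),
                                   seed = 1) {
  stopifnot(n_patients >= 1, p_treat >= 0, p_treat <= 1,
            all(tumor_sites >= 0), sum(tumor_sites) > 0)
  structure(list(n_patients = as.integer(n_patients), p_treat = p_treat,
                 b0 = b0, b_treatment = b_treatment, b_score = b_score,
                 b_interaction = b_interaction,
                 tumor_sites = tumor_sites / sum(tumor_sites),
                 seed = as.integer(seed)),
            class = "clinical_cohort_config")
}

#' Generate a synthetic clinical cohort (treatment, response, score)
#'
#' The binary response is drawn from the logistic model in
#' [clinical_cohort_config()]; `response_pct` is emitted consistently with
#' the binary endpoint under the 50% threshold convention (responders
#' uniform on 51-100, non-responders on 0-50).
#'
#' @param config A [clinical_cohort_config()].
#' @param score Optional numeric score vector (length `n_patients`); drawn
#'   standard normal when `NULL`.
#' @return List with `annotations` (a [sample_annotations()] frame with
#'   `tumor_site`, `treatment`, `response_pct`, `response_binary`),
#'   `score`, `treatment` (0/1) and `response` (0/1).
#' @export
gen_clinical_cohort <- function(config, score = NULL) {
  stopifnot(inherits(config, "clinical_cohort_config"))
  with_seed(config$seed + 3000L, {
    n <- config$n_patients
    ids <- sprintf("PT%04d", seq_len(n))
    s <- score %||% stats::rnorm(n)
    if (length(s) != n)
      stop_fmt("gen_clinical_cohort: score length %d != n_patients %d",
               length(s), n)
    trt <- stats::rbinom(n, 1L, config$p_treat)
    pr <- stats::plogis(config$b0 + config$b_treatment * trt +
                          config$b_score * s +
                          config$b_interaction * trt * s)
    resp <- stats::rbinom(n, 1L, pr)
    pct <- ifelse(resp == 1L, stats::runif(n, 51, 100),
                  stats::runif(n, 0, 50))
    ann <- sample_annotations(
      data.frame(sample_id = ids,
                 tumor_site = sample(names(config$tumor_sites), n,
                                     replace = TRUE,
                                     prob = config$tumor_sites),
                 treatment = ifelse(trt == 1L, "treated", "other"),
                 response_pct = pct, response_binary = resp,
                 stringsAsFactors = FALSE),
      pct_threshold = 50)
    list(annotations = ann, score = s, treatment = trt, response = resp)
  })
}
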