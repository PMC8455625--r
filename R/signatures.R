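# Per-drug elastic-net response signatures: training with 10-fold
# cross-validated (alpha, lambda) selection, locking, serialization-ready
# coefficient tables, and cross-cohort prediction of Z-scored IC50
# sensitivity scores (lower = predicted more sensitive).
#
# The penalized objective is
#   (1/2n) * sum_i (y_i - b0 - x_i b)^2 + lambda * (alpha*||b||_1
#                                                   + (1-alpha)/2*||b||_2^2)
# with features standardized to zero mean / unit (population) variance
# internally and coefficients reported back on the original feature scale.
# Coordinate descent is delegated to glmnet; glmnet's gaussian solver
# internally rescales the response by its population standard deviation,
# which leaves the L1 penalty at the requested strength but inflates the
# ridge part by 1/sd(y).  Calls below compensate exactly by requesting
# (alpha/k, lambda*k) with k = alpha + (1-alpha)*sd(y), so the optimum
# returned is the objective stated above.

#' Training configuration for signature fitting
#'
#' @param alpha_grid L1-proportion grid searched by cross-validation;
#'   spans the lasso (1) to near-ridge (0.1) continuum.
#' @param lambda_path_size Number of log-spaced penalty values per alpha.
#' @param lambda_min_ratio Smallest path value as a fraction of the
#'   data-derived `lambda_max`.
#' @param n_folds Cross-validation folds.
#' @param seed Integer seed controlling fold assignment (and nothing else;
#'   the solver is deterministic).
#' @return List of class `sig_config`.
#' @export
sig_config <- function(alpha_grid = c(0.1, 0.325, 0.55, 0.775, 1.0),
                       lambda_path_size = 100, lambda_min_ratio = 1e-4,
                       n_folds = 10, seed = 1) {
  stopifnot(all(alpha_grid >= 0 & alpha_grid <= 1), length(alpha_grid) > 0,
            lambda_path_size >= 2, lambda_min_ratio > 0,
            lambda_min_ratio < 1, n_folds >= 2)
  structure(list(alpha_grid = sort(alpha_grid), lambda_path_size = lambda_path_size,
                 lambda_min_ratio = lambda_min_ratio,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "sig_config")
}

#' @noRd
pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

# Standardization bookkeeping: population (1/n) moments, constant columns
# excluded from the solve and restored with zero coefficients.
#' @noRd
std_stats <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2L, pop_sd)
  list(mean = m, sd = s, active = which(s > 0))
}

#' Data-derived penalty path
#'
#' `lambda_max = max_j |<x_j_std, y - mean(y)>| / (n * max(alpha, 0.001))`
#' followed by `size` log-spaced values down to `min_ratio * lambda_max`.
#' At `lambda >= lambda_max` (alpha > 0) every coefficient is exactly zero.
#'
#' @param x Feature matrix (original scale).
#' @param y Response vector.
#' @param alpha L1 proportion.
#' @param size,min_ratio Path length and lower end as fraction of the top.
#' @return Decreasing numeric vector of penalties.
#' @export
lambda_path <- function(x, y, alpha, size = 100, min_ratio = 1e-4) {
  st <- std_stats(x)
  yc <- y - mean(y)
  if (length(st$active) == 0)
    stop_fmt("lambda_path: all features are constant")
  xs <- sweep(sweep(x[, st$active, drop = FALSE], 2L, st$mean[st$active]),
              2L, st$sd[st$active], "/")
  lmax <- max(abs(crossprod(xs, yc))) / (nrow(x) * max(alpha, 0.001))
  if (lmax <= 0) lmax <- .Machine$double.eps
  exp(seq(log(lmax), log(min_ratio * lmax), length.out = size))
}

#' Elastic-net solution at fixed penalties (full path)
#'
#' Fits the stated objective at every value of `lambda` and returns
#' intercepts and coefficients on the original feature scale.  Constant
#' features get coefficient zero; a single-feature input is padded with a
#' zero column (whose coefficient is provably zero) to satisfy the solver.
#'
#' @param x Samples-by-features numeric matrix.
#' @param y Numeric response.
#' @param alpha L1 proportion in \[0, 1\].
#' @param lambda Decreasing vector of penalty strengths.
#' @return List with `intercept` (length = path) and `beta`
#'   (features x path matrix, original scale), plus `lambda`.
#' @export
enet_path_fit <- function(x, y, alpha, lambda) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(y) == n)
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  p <- ncol(x)
  st <- std_stats(x)
  beta <- matrix(0, nrow = p, ncol = length(lambda),
                 dimnames = list(colnames(x), NULL))
  if (length(st$active) == 0 || pop_sd(y) == 0) {
    return(list(intercept = rep(mean(y), length(lambda)), beta = beta,
                lambda = lambda))
  }
  xs <- sweep(sweep(x[, st$active, drop = FALSE], 2L, st$mean[st$active]),
              2L, st$sd[st$active], "/")
  padded <- FALSE
  if (ncol(xs) == 1L) {           # glmnet requires >= 2 columns
    xs <- cbind(xs, 0)
    padded <- TRUE
  }
  sy <- pop_sd(y)
  k <- alpha + (1 - alpha) * sy   # exact compensation for glmnet's
  alpha_g <- alpha / k            # internal response standardization
  fit <- glmnet::glmnet(xs, y, family = "gaussian", alpha = alpha_g,
                        lambda = lambda * k, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-12, maxit = 1e7)
  b_std <- as.matrix(fit$beta)
  a0 <- as.numeric(fit$a0)
  if (padded) b_std <- b_std[1L, , drop = FALSE]
  # back-transform from the standardized to the original feature scale
  b_orig <- b_std / st$sd[st$active]
  intercept <- a0 - as.numeric(crossprod(b_orig,
                                         st$mean[st$active]))
  beta[st$active, ] <- b_orig
  list(intercept = intercept, beta = beta, lambda = lambda)
}

#' Elastic-net solution at a single (alpha, lambda)
#'
#' @inheritParams enet_path_fit
#' @param lambda Single penalty strength.
#' @return List with scalar `intercept` and named `coefficients` on the
#'   original feature scale.
#' @export
enet_fit <- function(x, y, alpha, lambda) {
  # solve along a short descending path ending at the requested lambda;
  # warm starts make the endpoint more reliable than a one-point path
  path <- unique(sort(c(lambda * c(8, 4, 2), lambda), decreasing = TRUE))
  fit <- enet_path_fit(x, y, alpha, path)
  j <- which.min(abs(fit$lambda - lambda))
  list(intercept = fit$intercept[j],
       coefficients = stats::setNames(fit$beta[, j], colnames(x)))
}

#' Deterministic cross-validation fold assignment
#'
#' A seed-keyed shuffle of `1:n` split round-robin, so the assignment is a
#' pure function of `(seed, n)` and training is reproducible end to end.
#'
#' @param n Number of samples.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1:n_folds`.
#' @export
fold_assignment <- function(n, n_folds, seed) {
  perm <- with_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[perm] <- rep_len(seq_len(n_folds), n)
  folds
}

#' Construct a signature model
#'
#' @param drug_id Drug identifier.
#' @param intercept Model intercept.
#' @param coefficients Named numeric vector; names follow the
#'   `<GENE>:expr` / `<GENE>:mut` convention.
#' @param alpha,lambda Selected penalty mix and strength (`NA` for the
#'   degenerate constant-response model).
#' @param seed Seed used for fold assignment.
#' @param cv_summary Optional data frame of per-grid-point mean CV error.
#' @param locked Locked models are final: they are the only ones
#'   [predict_scores()] and [write_model_set()] accept, and must not be
#'   modified after training.
#' @return List of class `signature_model`.
#' @export
signature_model <- function(drug_id, intercept, coefficients, alpha, lambda,
                            seed, cv_summary = NULL, locked = FALSE) {
  if (length(coefficients) > 0) {
    bad <- names(coefficients)[!grepl(":(expr|mut)$", names(coefficients))]
    if (length(bad) > 0)
      stop_fmt("signature_model: coefficient name(s) outside the <GENE>:channel convention: %s",
               paste(sQuote(bad), collapse = ", "))
  }
  structure(list(drug_id = as.character(drug_id),
                 intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 alpha = as.numeric(alpha), lambda = as.numeric(lambda),
                 seed = as.numeric(seed), cv_summary = cv_summary,
                 locked = isTRUE(locked)),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("signature_model '%s': intercept %.4g, %d/%d nonzero coefficients, alpha=%s, lambda=%s%s\n",
              x$drug_id, x$intercept, nz, length(x$coefficients),
              format(x$alpha), format(x$lambda),
              if (x$locked) ", locked" else ""))
  invisible(x)
}

#' Bundle per-drug models sharing a feature namespace
#' @param models List of [signature_model()] objects.
#' @return Named list of class `signature_model_set` (names = drug ids).
#' @export
signature_model_set <- function(models) {
  stopifnot(all(vapply(models, inherits, TRUE, "signature_model")))
  ns <- lapply(models, function(m) names(m$coefficients))
  if (length(unique(vapply(ns, paste, "", collapse = "\r"))) > 1L)
    stop_fmt("signature_model_set: member models do not share a feature namespace")
  names(models) <- vapply(models, `[[`, "", "drug_id")
  structure(models, class = "signature_model_set")
}

#' Shared feature namespace of a model set
#' @param models A `signature_model_set`.
#' @return Character vector of feature names.
#' @export
model_set_features <- function(models) {
  names(models[[1L]]$coefficients)
}

#' Train one drug's elastic-net signature
#'
#' Selects (alpha, lambda) by `n_folds`-fold cross-validated mean squared
#' error over `alpha_grid` x a per-alpha [lambda_path()], ties broken
#' toward larger lambda then larger alpha (sparser models), refits on the
#' full data at the selected point, and returns a locked model with
#' coefficients on the original feature scale.
#'
#' @param features Samples-by-features matrix (see [assemble_features()]).
#' @param y Per-sample Z-scored IC50 response; either named by sample id or
#'   aligned with `rownames(features)`.  `NA` responses are dropped.
#' @param config A [sig_config()].
#' @return A locked [signature_model()] carrying `cv_summary`.
#' @export
fit_signature <- function(features, y, config = sig_config()) {
  stopifnot(inherits(config, "sig_config"))
  features <- as.matrix(features)
  if (!is.null(names(y))) {
    common <- intersect(rownames(features), names(y))
    y <- y[common]
    features <- features[common, , drop = FALSE]
  } else if (length(y) != nrow(features)) {
    stop_fmt("fit_signature: length(y) (%d) != nrow(features) (%d)",
             length(y), nrow(features))
  }
  ok <- !is.na(y)
  y <- as.numeric(y[ok])
  x <- features[ok, , drop = FALSE]
  n <- length(y)
  if (n < 2 * config$n_folds)
    stop_fmt("fit_signature: %d samples with non-missing response; need >= %d (2 x n_folds)",
             n, 2 * config$n_folds)
  empty_beta <- stats::setNames(numeric(ncol(x)), colnames(x))
  if (pop_sd(y) == 0) {
    warn_fmt("fit_signature: constant response; returning the intercept-only model")
    return(signature_model(drug_id = "", intercept = mean(y),
                           coefficients = empty_beta, alpha = NA_real_,
                           lambda = NA_real_, seed = config$seed,
                           locked = TRUE))
  }
  folds <- fold_assignment(n, config$n_folds, config$seed)
  grid <- list()
  for (a in config$alpha_grid) {
    path <- lambda_path(x, y, a, config$lambda_path_size,
                        config$lambda_min_ratio)
    sse <- numeric(length(path))
    for (f in seq_len(config$n_folds)) {
      tr <- folds != f
      fit <- enet_path_fit(x[tr, , drop = FALSE], y[tr], a, path)
      pred <- sweep(x[!tr, , drop = FALSE] %*% fit$beta, 2L,
                    fit$intercept, "+")
      sse <- sse + colSums((pred - y[!tr])^2)
    }
    grid[[as.character(a)]] <- data.frame(alpha = a, lambda = path,
                                          cv_mse = sse / n)
  }
  cv <- do.call(rbind, grid)
  rownames(cv) <- NULL
  # minimal CV error; ties -> larger lambda, then larger alpha
  ord <- order(cv$cv_mse, -cv$lambda, -cv$alpha)
  best <- cv[ord[1L], ]
  final <- enet_path_fit(x, y, best$alpha,
                         grid[[as.character(best$alpha)]]$lambda)
  j <- which.min(abs(final$lambda - best$lambda))
  signature_model(drug_id = "", intercept = final$intercept[j],
                  coefficients = stats::setNames(final$beta[, j],
                                                 colnames(x)),
                  alpha = best$alpha, lambda = best$lambda,
                  seed = config$seed, cv_summary = cv, locked = TRUE)
}

#' Train locked signatures for every eligible drug
#'
#' One model per drug holding Z-scored IC50 records in `responses`.  Drugs
#' whose fit fails its preconditions (too few samples, etc.) are reported
#' in a warning and in `attr(result, "failures")`, never silently dropped.
#' Output is deterministic given `config$seed`.
#'
#' @param features Samples-by-features matrix.
#' @param responses A [drug_response()] table; only `measure == "z_ic50"`
#'   records are used.
#' @param config A [sig_config()].
#' @return A [signature_model_set()].
#' @export
fit_all_drugs <- function(features, responses, config = sig_config()) {
  resp <- responses[responses$measure == "z_ic50", , drop = FALSE]
  drugs <- sort(unique(resp$drug_id))
  if (length(drugs) == 0)
    stop_fmt("fit_all_drugs: no z_ic50 records in the response table")
  models <- list()
  failures <- character()
  for (d in drugs) {
    rd <- resp[resp$drug_id == d, , drop = FALSE]
    y <- stats::setNames(rd$value, rd$sample_id)
    m <- tryCatch(fit_signature(features, y, config),
                  error = function(e) conditionMessage(e))
    if (is.character(m)) {
      failures[[d]] <- m
    } else {
      m$drug_id <- d
      models[[d]] <- m
    }
  }
  if (length(failures) > 0)
    warn_fmt("fit_all_drugs: %d drug(s) not fitted: %s",
             length(failures),
             paste(sprintf("%s (%s)", names(failures), failures),
                   collapse = "; "))
  if (length(models) == 0)
    stop_fmt("fit_all_drugs: no drug could be fitted")
  out <- signature_model_set(models)
  attr(out, "failures") <- failures
  out
}

#' Predict sensitivity scores with locked models
#'
#' `score(d, s) = intercept_d + sum_f beta_d[f] * x_s[f]`, aligned by
#' feature name, so column order of `features` is irrelevant.  Under
#' `missing_policy = "zero_fill"` (the cross-cohort default) features
#' absent from `features` contribute 0 — the cohort median for centered
#' expression, wild-type for mutation — and the per-drug count of filled
#' features is reported via `message()`.  Lower scores mean predicted more
#' sensitive.
#'
#' @param models A locked [signature_model_set()].
#' @param features Samples-by-features matrix.
#' @param missing_policy `"zero_fill"` or `"error"`.
#' @return Drugs-by-samples numeric score matrix.
#' @export
predict_scores <- function(models, features,
                           missing_policy = c("zero_fill", "error")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(models, "signature_model_set"))
  for (m in models) {
    if (!isTRUE(m$locked))
      stop_fmt("predict_scores: model for drug '%s' is not locked", m$drug_id)
  }
  features <- as.matrix(features)
  ns <- model_set_features(models)
  present <- intersect(ns, colnames(features))
  missing <- setdiff(ns, colnames(features))
  if (length(missing) > 0 && missing_policy == "error")
    stop_fmt("predict_scores: feature(s) missing from the cohort: %s",
             paste(missing, collapse = ", "))
  scores <- matrix(NA_real_, nrow = length(models), ncol = nrow(features),
                   dimnames = list(names(models), rownames(features)))
  for (d in names(models)) {
    m <- models[[d]]
    b <- m$coefficients[present]
    scores[d, ] <- m$intercept +
      as.numeric(features[, present, drop = FALSE] %*% b)
    n_fill <- sum(m$coefficients[missing] != 0)
    if (length(missing) > 0)
      message(sprintf("predict_scores: drug '%s': zero-filled %d absent feature(s) (%d with nonzero coefficient)",
                      d, length(missing), n_fill))
  }
  scores
}
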