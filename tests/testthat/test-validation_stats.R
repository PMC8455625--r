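# Validation statistics: Pearson with p/CI, BH step-up adjustment (checked
# against the published 18-drug validation table), Welch comparisons, and
# the logistic treatment-by-score interaction test.

test_that("pearson_with_p matches the product-moment definition", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_with_p(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_with_p(x, -x)$r, -1)

  y <- c(1, 3, 2, 4)
  # brute force: sum((x-xb)(y-yb)) / sqrt(sum((x-xb)^2) sum((y-yb)^2))
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r_brute, 0.8)
  res <- pearson_with_p(x, y)
  expect_equal(res$r, 0.8)
  # p from t = r * sqrt((n-2)/(1-r^2)) on n-2 df
  tstat <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(res$p, 2 * pt(tstat, 2, lower.tail = FALSE))
  expect_true(res$ci_low <= res$r && res$r <= res$ci_high)

  expect_error(pearson_with_p(x, c(1, 1, 1, 1)), "constant")
  expect_error(pearson_with_p(x, y[1:3]), "length mismatch")
  expect_error(pearson_with_p(x[1:2], y[1:2]), "n >= 3")
})

test_that("pearson_with_p is invariant under positive affine maps", {
  set.seed(31)
  x <- rnorm(30); y <- x + rnorm(30)
  base <- pearson_with_p(x, y)
  shifted <- pearson_with_p(3 * x + 2, y)
  expect_equal(shifted$r, base$r)
  expect_equal(shifted$p, base$p)
  neg <- pearson_with_p(-x, y)
  expect_equal(neg$r, -base$r)
  expect_equal(neg$p, base$p)
})

test_that("bh_adjust reproduces the published FDR column exactly", {
  tab <- read.delim(system.file("extdata", "ccle_published_correlations.tsv",
                                package = "pharmsig"))
  fdr <- bh_adjust(tab$p)
  # Nilotinib: rank 5 of 18 ascending -> p * 18 / 5
  nilo <- which(tab$drug == "Nilotinib")
  expect_equal(rank(tab$p)[nilo], 5)
  expect_equal(fdr[nilo], 5.95e-38 * 18 / 5)
  # the largest p is unchanged by the step-up adjustment
  palbo <- which(tab$drug == "Palbociclib")
  expect_equal(rank(tab$p)[palbo], 18)
  expect_equal(fdr[palbo], tab$p[palbo])
  # every adjusted value agrees with the printed column at its precision
  expect_equal(fdr, tab$fdr, tolerance = 5e-3)
  expect_true(all(fdr >= tab$p))
})

test_that("bh_adjust equals the brute-force step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  set.seed(32)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_lt(max(abs(bh_adjust(p) - bh_brute(p))), 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("validate_against_response pairs scores with negative AUC per drug", {
  set.seed(33)
  samples <- sprintf("S%02d", 1:30)
  auc <- runif(30, 0.2, 0.9)
  scores <- rbind(DrugX = -auc,                       # score == -AUC: r = 1
                  DrugY = rnorm(30))
  colnames(scores) <- samples
  resp <- drug_response(rep(c("DrugX", "DrugY"), each = 30),
                        rep(samples, 2), "auc", c(auc, auc))
  res <- validate_against_response(scores, resp)
  expect_equal(res$r[res$drug_id == "DrugX"], 1)
  expect_equal(res$fdr, bh_adjust(res$p))

  # a drug with < 3 paired samples is skipped with a warning
  resp2 <- drug_response(c(rep("DrugX", 30), "DrugY", "DrugY"),
                         c(samples, samples[1:2]), "auc",
                         c(auc, 0.5, 0.6))
  expect_warning(res2 <- validate_against_response(scores, resp2),
                 "skipped 1")
  expect_equal(res2$drug_id, "DrugX")
  expect_error(suppressWarnings(validate_against_response(
    scores, drug_response("DrugX", "S01", "auc", 0.5))), "no drug")
})

test_that("two_sample_t matches the Welch formulas computed by hand", {
  a <- c(0, 0, 1, 1); b <- c(1, 1, 2, 2)
  res <- two_sample_t(c(a, b), c(rep(TRUE, 4), rep(FALSE, 4)))
  # brute force: var = 1/3 each, se = sqrt(1/12 + 1/12), t = -1/se
  se <- sqrt(var(a) / 4 + var(b) / 4)
  expect_equal(res$t, -1 / se)
  expect_equal(res$t, -sqrt(6), tolerance = 1e-12)
  df <- (var(a) / 4 + var(b) / 4)^2 /
    ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  expect_equal(res$df, df)
  expect_equal(res$df, 6)
  expect_equal(res$p, 2 * pt(-abs(res$t), df))
  expect_equal(res$direction, "marker_more_sensitive")

  # identical groups: the zero-variance equal-mean edge gives t=0, p=1
  same <- two_sample_t(rep(1, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # scaling both groups leaves t and p unchanged
  scl <- two_sample_t(10 * c(a, b), c(rep(TRUE, 4), rep(FALSE, 4)))
  expect_equal(scl$t, res$t)
  expect_equal(scl$p, res$p)

  expect_error(two_sample_t(1:5, c(TRUE, rep(FALSE, 4))), ">= 2 samples")
  expect_error(two_sample_t(c(1, 1, 2, 2), c(TRUE, TRUE, FALSE, FALSE)),
               "zero variance")
})

test_that("interaction_test recovers a planted interaction and rejects bad input", {
  set.seed(34)
  n <- 400
  s <- rnorm(n)
  trt <- rbinom(n, 1, 0.5)
  pr <- plogis(-0.25 + 0.3 * trt + 0 * s - 2 * trt * s)
  resp <- rbinom(n, 1, pr)
  res <- interaction_test(resp, trt, s)
  expect_s3_class(res, "interaction_result")
  est <- res$coefficients$estimate[res$coefficients$term == "treatment:score"]
  expect_lt(est, -1)
  expect_lt(res$interaction_p, 0.05)
  expect_true(res$converged)

  # permuting the score destroys the planted interaction far more often
  # than not (single-draw sanity check; calibration is tested at scale)
  res_perm <- interaction_test(resp, trt, sample(s))
  expect_gt(res_perm$interaction_p, res$interaction_p)

  expect_error(interaction_test(rep(1, n), trt, s), "constant")
  expect_error(interaction_test(resp, rep(1, n), s), "one treatment arm")

  # complete separation is a diagnostic error, not a silent estimate
  s2 <- c(rnorm(50, -3), rnorm(50, 3))
  resp2 <- as.integer(s2 > 0)
  trt2 <- rep(c(0, 1), 50)
  expect_error(interaction_test(resp2, trt2, s2), "separation")

  expect_warning(interaction_test(c(0, 1, 0, 1, 0, 1, 0, 1, 1, 0),
                                  c(0, 1, 1, 0, 0, 1, 0, 1, 0, 1),
                                  rnorm(10)), "unstable")
})

test_that("interaction_test optionally reports a likelihood-ratio p-value", {
  set.seed(35)
  n <- 300
  s <- rnorm(n); trt <- rbinom(n, 1, 0.5)
  resp <- rbinom(n, 1, plogis(0.2 - 1.5 * trt * s))
  res <- interaction_test(resp, trt, s, lr_test = TRUE)
  expect_true(res$lr_p < 0.05)
  # Wald and LR agree on order of magnitude for a strong effect
  expect_equal(log10(res$lr_p), log10(res$interaction_p), tolerance = 1)
})
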