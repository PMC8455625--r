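# Fixture builders: everything is generated in code at test time.

write_lines_tmp <- function(lines, eol = "\n") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  con <- file(path, "wb")
  writeLines(lines, con, sep = eol)
  close(con)
  path
}

# Minimal well-formed mutation-call TSV (plain column names).
mutation_tsv_lines <- function() {
  c("sample_id\tgene\tconsequence_class\tprotein_change",
    "S1\tTP53\tMissense_Mutation\tp.R175H",
    "S1\tBRAF\tmissense\tV600E",
    "S2\tTP53\tSilent\tNA")
}

expression_tsv_lines <- function() {
  c("gene\tS1\tS2\tS3",
    "TP53\t0\t0\t0",
    "EGFR\t0\t0\t0")
}

# Small deterministic feature matrix + linear response for solver tests.
toy_regression <- function(n = 40, p = 6, seed = 42, sigma = 0.3) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%03d", 1:n),
                              paste0(sprintf("G%02d", 1:p),
                                     rep(c(":expr", ":mut"), length.out = p))))
  beta <- c(1.2, -0.8, rep(0, p - 2))
  y <- as.numeric(x %*% beta) + rnorm(n, 0, sigma)
  list(x = x, y = y, beta = beta)
}

# Population-sd standardization matching the solver's internal convention.
std_cols <- function(x) {
  sweep(sweep(x, 2, colMeans(x)), 2,
        apply(x, 2, function(c) sqrt(mean((c - mean(c))^2))), "/")
}

# Brute-force Benjamini-Hochberg straight from the step-up definition:
# sort ascending, adj_i = min_{j >= i} (p_(j) * m / j), cap at 1, return
# in input order.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  out <- numeric(m)
  for (i in seq_len(m)) {
    out[ord[i]] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out
}

# OLS t statistic for one coefficient via pseudo-inverse normal equations.
ols_t_brute <- function(y, design, col) {
  xtx_inv <- solve(crossprod(design))
  beta <- xtx_inv %*% crossprod(design, y)
  res <- y - design %*% beta
  df <- length(y) - ncol(design)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(xtx_inv))
  list(coef = beta[col, 1], t = beta[col, 1] / se[col], df = df,
       p = 2 * pt(abs(beta[col, 1] / se[col]), df, lower.tail = FALSE))
}
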