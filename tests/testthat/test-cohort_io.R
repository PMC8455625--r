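# Readers/writers: validation, synonym mapping, round trips, dialect
# tolerance (line endings, column order, MAF aliases).

test_that("mutation calls: ingest, synonym mapping, empty file", {
  path <- write_lines_tmp(mutation_tsv_lines())
  calls <- read_mutation_calls(path)
  expect_s3_class(calls, "mutation_calls")
  expect_equal(nrow(calls), 3)
  expect_equal(calls$consequence_class, c("missense", "missense", "silent"))
  expect_equal(calls$protein_change[1], "R175H")  # p. prefix stripped

  empty <- write_lines_tmp("sample_id\tgene\tconsequence_class")
  expect_equal(nrow(read_mutation_calls(empty)), 0)
})

test_that("mutation calls accept MAF-conventional aliases and CRLF", {
  lines <- c("Hugo_Symbol\tVariant_Classification\tTumor_Sample_Barcode\tHGVSp_Short",
             "braf\tMissense_Mutation\tS9\tp.V600E")
  for (eol in c("\n", "\r\n")) {
    path <- write_lines_tmp(lines, eol = eol)
    calls <- read_mutation_calls(path)
    expect_equal(calls$gene, "BRAF")        # case-normalized
    expect_equal(calls$sample_id, "S9")     # column order irrelevant
    expect_equal(calls$consequence_class, "missense")
    expect_equal(calls$protein_change, "V600E")
  }
})

test_that("mutation calls: format errors name the problem", {
  no_col <- write_lines_tmp(c("sample_id\tgene", "S1\tTP53"))
  expect_error(read_mutation_calls(no_col), "consequence_class")
  bad_cons <- write_lines_tmp(
    c("sample_id\tgene\tconsequence_class", "S1\tTP53\tweird_label"))
  expect_error(read_mutation_calls(bad_cons), "accepted synonyms")
})

test_that("expression reader validates and round-trips", {
  path <- write_lines_tmp(expression_tsv_lines())
  m <- read_expression_table(path)
  expect_equal(dim(m), c(2L, 3L))
  expect_true(all(m == 0))
  expect_equal(rownames(m), c("TP53", "EGFR"))

  dup <- write_lines_tmp(c("gene\tS1\tS2", "TP53\t1\t2", "tp53\t3\t4"))
  expect_error(read_expression_table(dup), "TP53")
  neg <- write_lines_tmp(c("gene\tS1\tS2", "TP53\t1\t-2"))
  expect_error(read_expression_table(neg), "negative FPKM")
  txt <- write_lines_tmp(c("gene\tS1\tS2", "TP53\t1\tabc"))
  expect_error(read_expression_table(txt), "non-numeric")

  set.seed(7)
  x <- matrix(round(runif(12, 0, 50), 6), 3, 4,
              dimnames = list(c("A1", "B2", "C3"), paste0("S", 1:4)))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(x, out)
  expect_equal(read_expression_table(out), x)
})

test_that("drug response table enforces its key and measure vocabulary", {
  lines <- c("drug\tsample\tmeasure\tvalue",
             sprintf("D%02d\tS1\tauc\t0.%d", 1:18, 1:18))
  tab <- read_drug_response(write_lines_tmp(lines))
  expect_equal(nrow(tab), 18)

  dup <- write_lines_tmp(c("drug\tsample\tmeasure\tvalue",
                           "D1\tS1\tauc\t0.5", "D1\tS1\tauc\t0.6"))
  expect_error(read_drug_response(dup), "duplicate")

  # same (drug, sample) under different measures is two distinct records
  mixed <- read_drug_response(write_lines_tmp(
    c("drug\tsample\tmeasure\tvalue",
      "D1\tS1\tz_ic50\t1.3", "D1\tS1\tauc\t0.5")))
  expect_equal(nrow(mixed), 2)

  expect_error(read_drug_response(write_lines_tmp(
    c("drug\tsample\tmeasure\tvalue", "D1\tS1\tic50\t2"))), "measure")
  expect_error(read_drug_response(write_lines_tmp(
    c("drug\tsample\tmeasure\tvalue", "D1\tS1\tauc\t42"))), "\\[0, 1\\]")
  pct <- read_drug_response(write_lines_tmp(
    c("drug\tsample\tmeasure\tvalue", "D1\tS1\tauc\t42")),
    auc_percent = TRUE)
  expect_equal(pct$value, 0.42)
})

test_that("gene panel reader dedups, orders, and rejects empty files", {
  p <- read_gene_panel(write_lines_tmp(c("TP53", "EGFR", "tp53")))
  expect_equal(p, c("TP53", "EGFR"))
  expect_error(read_gene_panel(write_lines_tmp(c("", "   ", "# c"))),
               "empty")
  with_comments <- read_gene_panel(write_lines_tmp(
    c("# panel v1", "KRAS  ", "BRAF # kinase")))
  expect_equal(with_comments, c("KRAS", "BRAF"))
})

test_that("annotations: typed columns, truthy flags, duplicate detection", {
  plain <- read_annotations(write_lines_tmp(
    c("sample_id\ttumor_site", sprintf("S%d\tlung", 1:5))))
  expect_equal(nrow(plain), 5)
  expect_equal(attr(plain, "flags"), character())

  flags <- read_annotations(write_lines_tmp(
    c("sample_id\ther2_pos", "S1\tyes", "S2\tNo", "S3\tTRUE", "S4\t0")))
  expect_equal(flags$her2_pos, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(attr(flags, "flags"), "her2_pos")

  expect_error(read_annotations(write_lines_tmp(
    c("sample_id\tflagged", "S1\tmaybe"))), "flagged")
  expect_error(read_annotations(write_lines_tmp(
    c("sample_id\ttumor_site", "S1\tlung", "S1\tcolon"))), "duplicated")

  # response_binary consistency under a declared threshold
  good <- c("sample_id\tresponse_pct\tresponse_binary",
            "S1\t80\t1", "S2\t10\t0")
  expect_silent(read_annotations(write_lines_tmp(good),
                                 pct_threshold = 50))
  bad <- c("sample_id\tresponse_pct\tresponse_binary",
           "S1\t80\t0")
  expect_error(read_annotations(write_lines_tmp(bad), pct_threshold = 50),
               "inconsistent")
})

test_that("model set serialization round-trips locked models exactly", {
  ns <- c("TP53:expr", "TP53:mut", "EGFR:expr")
  m1 <- signature_model("DrugA", intercept = 1 / 3,
                        coefficients = setNames(c(pi, 0, -1e-9), ns),
                        alpha = 0.325, lambda = 0.0123456789012345,
                        seed = 7, locked = TRUE)
  m2 <- signature_model("DrugB", intercept = -2.5,
                        coefficients = setNames(c(0, 0, 0), ns),
                        alpha = NA_real_, lambda = NA_real_,
                        seed = 7, locked = TRUE)
  set <- signature_model_set(list(m1, m2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model_set(set, path)
  back <- read_model_set(path)
  for (d in names(set)) {
    for (f in c("drug_id", "intercept", "coefficients", "alpha",
                "lambda", "seed")) {
      expect_identical(back[[d]][[f]], set[[d]][[f]], label = paste(d, f))
    }
    expect_true(back[[d]]$locked)
  }
  # zero coefficients are omitted from the file but restored on read
  lines <- readLines(path)
  expect_false(any(grepl("TP53:mut", grep("^[^#]", lines, value = TRUE))))
  expect_identical(back$DrugA$coefficients[["TP53:mut"]], 0)
})

test_that("model set reader rejects unknown term suffixes and unlocked input", {
  ns <- c("TP53:expr")
  m <- signature_model("D", 0, setNames(1, ns), 1, 0.1, 1, locked = FALSE)
  expect_error(write_model_set(signature_model_set(list(m)), tempfile()),
               "not locked")
  path <- write_lines_tmp(c("# pharmsig_model_set\tv1",
                            "# features\tTP53:expr",
                            "# model\tdrug=D\talpha=1\tlambda=0.1\tseed=1",
                            "drug\tterm\tcoefficient",
                            "D\t(Intercept)\t0",
                            "D\tTP53:protein\t1"))
  expect_error(read_model_set(path), "unknown term suffix")
})
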