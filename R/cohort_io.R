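# Readers, writers and validators for the cohort-level inputs: mutation
# call tables, FPKM expression matrices, drug-response tables, gene panels,
# sample annotations, and the locked signature-model table.
#
# All readers are tolerant of CRLF line endings and (where a header exists)
# column order, and reject files violating the type invariants with errors
# naming the offending row or column.

# ---- controlled vocabulary ------------------------------------------------

#' Consequence-class synonym table
#'
#' Maps the consequence strings accepted on input (MAF-style
#' `Variant_Classification` labels as well as plain lower-case labels) onto
#' the controlled vocabulary used throughout the package:
#' `missense`, `nonsense`, `frameshift`, `inframe_indel`, `splice_site`,
#' `silent`, `intronic`, `intergenic`, `UTR`, `other_noncoding`.
#' Matching is case-insensitive.  This is the single documented place where
#' the mapping lives.
#'
#' @return Named character vector: names are accepted synonyms (lower case),
#'   values are canonical classes.
#' @export
#' @examples
#' consequence_synonyms()[["missense_mutation"]]
consequence_synonyms <- function() {
  c(
    missense = "missense", missense_mutation = "missense",
    missense_variant = "missense",
    nonsense = "nonsense", nonsense_mutation = "nonsense",
    stop_gained = "nonsense", stop_lost = "nonsense",
    nonstop_mutation = "nonsense",
    frameshift = "frameshift", frame_shift_del = "frameshift",
    frame_shift_ins = "frameshift", frameshift_variant = "frameshift",
    inframe_indel = "inframe_indel", in_frame_del = "inframe_indel",
    in_frame_ins = "inframe_indel", inframe_deletion = "inframe_indel",
    inframe_insertion = "inframe_indel",
    splice_site = "splice_site", splice_site_variant = "splice_site",
    splice_region = "splice_site", splice_acceptor_variant = "splice_site",
    splice_donor_variant = "splice_site",
    silent = "silent", synonymous = "silent", synonymous_variant = "silent",
    intronic = "intronic", intron = "intronic", intron_variant = "intronic",
    intergenic = "intergenic", igr = "intergenic",
    intergenic_variant = "intergenic",
    utr = "UTR", `5'utr` = "UTR", `3'utr` = "UTR", `5'flank` = "UTR",
    `3'flank` = "UTR", five_prime_utr = "UTR", three_prime_utr = "UTR",
    other_noncoding = "other_noncoding", rna = "other_noncoding",
    lincrna = "other_noncoding",
    non_coding_transcript_exon = "other_noncoding"
  )
}

#' Consequence classes counted as protein-altering
#'
#' The binary mutation channel codes a gene/sample pair as mutated only when
#' at least one call falls in this set; silent, intronic, intergenic, UTR
#' and other non-coding calls are excluded.
#' @return Character vector of canonical classes.
#' @export
protein_altering_classes <- function() {
  c("missense", "nonsense", "frameshift", "inframe_indel", "splice_site")
}

#' @noRd
consequence_vocabulary <- function() {
  c("missense", "nonsense", "frameshift", "inframe_indel", "splice_site",
    "silent", "intronic", "intergenic", "UTR", "other_noncoding")
}

#' @noRd
map_consequence <- function(x) {
  syn <- consequence_synonyms()
  key <- tolower(trimws(x))
  out <- unname(syn[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop_fmt(
      "unknown consequence label(s): %s; accepted synonyms are: %s",
      paste(sQuote(bad), collapse = ", "),
      paste(sQuote(names(syn)), collapse = ", ")
    )
  }
  out
}

#' @noRd
pick_column <- function(df, aliases, what, path, required = TRUE) {
  hit <- intersect(aliases, names(df))
  if (length(hit) == 0) {
    if (!required) return(NULL)
    stop_fmt("'%s': missing required column '%s' (accepted names: %s)",
             path, aliases[[1L]], paste(aliases, collapse = ", "))
  }
  df[[hit[[1L]]]]
}

# ---- mutation calls -------------------------------------------------------

#' Construct and validate a mutation-call table
#'
#' @param sample_id,gene Character vectors (non-empty entries required).
#' @param consequence_class Canonical consequence classes (see
#'   [consequence_synonyms()]).
#' @param protein_change Optional protein-level change strings ("V600E");
#'   `NA` where unknown.
#' @return A `data.frame` of class `mutation_calls` with columns
#'   `sample_id`, `gene`, `consequence_class`, `protein_change`.  Gene
#'   symbols are upper-cased for cross-file matching.  Duplicate
#'   (sample, gene, change) rows are permitted; they collapse later in
#'   [binarize_mutations()].
#' @export
mutation_calls <- function(sample_id, gene, consequence_class,
                           protein_change = NA_character_) {
  protein_change <- rep_len(as.character(protein_change),
                            length(sample_id))
  df <- data.frame(sample_id = as.character(sample_id),
                   gene = toupper(as.character(gene)),
                   consequence_class = as.character(consequence_class),
                   protein_change = as.character(protein_change),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(is.na(df$sample_id) | df$sample_id == ""))
      stop_fmt("mutation calls: empty sample_id in row %d",
               which(is.na(df$sample_id) | df$sample_id == "")[1L])
    if (any(is.na(df$gene) | df$gene == ""))
      stop_fmt("mutation calls: empty gene in row %d",
               which(is.na(df$gene) | df$gene == "")[1L])
    bad <- setdiff(unique(df$consequence_class), consequence_vocabulary())
    if (length(bad) > 0)
      stop_fmt("mutation calls: consequence class(es) outside vocabulary: %s",
               paste(sQuote(bad), collapse = ", "))
  }
  class(df) <- c("mutation_calls", "data.frame")
  df
}

#' Read a mutation-call table from TSV
#'
#' Accepts plain column names (`sample_id`, `gene`, `consequence_class`,
#' `protein_change`) and their MAF-conventional aliases
#' (`Tumor_Sample_Barcode`, `Hugo_Symbol`, `Variant_Classification`,
#' `HGVSp_Short`).  Consequence strings are mapped to the controlled
#' vocabulary through [consequence_synonyms()]; an unknown string is an
#' error listing the accepted synonyms.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A [mutation_calls()] table (possibly zero rows).
#' @export
read_mutation_calls <- function(path) {
  df <- read_tsv_file(path)
  sample_id <- pick_column(df, c("sample_id", "sample",
                                 "Tumor_Sample_Barcode"), "sample_id", path)
  gene <- pick_column(df, c("gene", "Hugo_Symbol"), "gene", path)
  cons <- pick_column(df, c("consequence_class", "consequence",
                            "Variant_Classification"),
                      "consequence_class", path)
  pc <- pick_column(df, c("protein_change", "HGVSp_Short"),
                    "protein_change", path, required = FALSE)
  if (nrow(df) == 0) {
    return(mutation_calls(character(), character(), character(),
                          character()))
  }
  if (is.null(pc)) pc <- rep(NA_character_, nrow(df))
  # strip the HGVS "p." prefix so V600E and p.V600E compare equal
  pc <- sub("^p\\.", "", as.character(pc))
  mutation_calls(sample_id, gene, map_consequence(cons), pc)
}

#' Write a mutation-call table to TSV
#' @param calls A [mutation_calls()] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mutation_calls <- function(calls, path) {
  write_tsv_file(as.data.frame(calls), path)
}

# ---- expression -----------------------------------------------------------

#' Read a genes-by-samples FPKM expression matrix from TSV
#'
#' The first column holds gene symbols, the remaining columns one sample
#' each.  Values must be numeric and non-negative; duplicated gene symbols
#' (after upper-casing) are rejected.
#'
#' @param path Path to the tab-separated file.
#' @return Numeric matrix, genes in rows (upper-cased symbols), samples in
#'   columns.
#' @export
read_expression_table <- function(path) {
  df <- read_tsv_file(path)
  if (ncol(df) < 2)
    stop_fmt("'%s': expected a gene column plus at least one sample", path)
  genes <- toupper(as.character(df[[1L]]))
  if (any(is.na(genes) | genes == ""))
    stop_fmt("'%s': missing gene symbol in row %d", path,
             which(is.na(genes) | genes == "")[1L])
  if (anyDuplicated(genes))
    stop_fmt("'%s': duplicated gene symbol '%s'", path,
             genes[duplicated(genes)][1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num) && !all(is.na(vals) == is.na(num))) {
    idx <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1L, ]
    stop_fmt("'%s': non-numeric value '%s' at row %d (gene %s), column '%s'",
             path, vals[idx[1L], idx[2L]], idx[1L], genes[idx[1L]],
             colnames(vals)[idx[2L]])
  }
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop_fmt("'%s': missing value at row %d (gene %s), column '%s'",
             path, idx[1L], genes[idx[1L]], colnames(vals)[idx[2L]])
  }
  if (any(num < 0)) {
    idx <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop_fmt("'%s': negative FPKM %g at gene %s, sample '%s'",
             path, num[idx[1L], idx[2L]], genes[idx[1L]],
             colnames(num)[idx[2L]])
  }
  rownames(num) <- genes
  num
}

#' Write a genes-by-samples expression matrix to TSV
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output file path.
#' @param gene_col Name for the leading gene-symbol column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(mat, path, gene_col = "gene") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- gene_col
  write_tsv_file(df, path)
}

# ---- drug response --------------------------------------------------------

#' Construct and validate a drug-response table
#'
#' Holds both the Z-scored IC50 training target (`measure = "z_ic50"`) and
#' the AUC validation measure (`measure = "auc"`), keyed by
#' (drug, sample, measure).
#'
#' @param drug_id,sample_id Character vectors.
#' @param measure `"z_ic50"` or `"auc"` per record.
#' @param value Numeric response values; AUC values must lie in \[0, 1\].
#' @return A `data.frame` of class `drug_response`.
#' @export
drug_response <- function(drug_id, sample_id, measure, value) {
  df <- data.frame(drug_id = as.character(drug_id),
                   sample_id = as.character(sample_id),
                   measure = as.character(measure),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$measure), c("z_ic50", "auc"))
  if (length(bad) > 0)
    stop_fmt("drug response: unknown measure label(s): %s (use z_ic50 or auc)",
             paste(sQuote(bad), collapse = ", "))
  key <- paste(df$drug_id, df$sample_id, df$measure, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop_fmt("drug response: duplicate record for drug '%s', sample '%s', measure '%s'",
             d$drug_id, d$sample_id, d$measure)
  }
  isauc <- df$measure == "auc"
  if (any(isauc & (df$value < 0 | df$value > 1), na.rm = TRUE))
    stop_fmt("drug response: auc value outside [0, 1] for drug '%s', sample '%s' (use auc_percent = TRUE for a 0-100 scale)",
             df$drug_id[isauc & (df$value < 0 | df$value > 1)][1L],
             df$sample_id[isauc & (df$value < 0 | df$value > 1)][1L])
  if (anyNA(df$value))
    stop_fmt("drug response: non-numeric or missing value in row %d",
             which(is.na(df$value))[1L])
  class(df) <- c("drug_response", "data.frame")
  df
}

#' Read a drug-response table from TSV
#'
#' @param path TSV with columns `drug` (or `drug_id`), `sample` (or
#'   `sample_id`), `measure` (`z_ic50` / `auc`) and `value`.
#' @param auc_percent If `TRUE`, AUC values are given on a 0-100 scale and
#'   are divided by 100 on read.
#' @return A [drug_response()] table.
#' @export
read_drug_response <- function(path, auc_percent = FALSE) {
  df <- read_tsv_file(path)
  drug <- pick_column(df, c("drug", "drug_id"), "drug", path)
  sample <- pick_column(df, c("sample", "sample_id"), "sample", path)
  measure <- pick_column(df, "measure", "measure", path)
  value <- pick_column(df, "value", "value", path)
  value <- as.numeric(value)
  if (auc_percent) value[measure == "auc"] <- value[measure == "auc"] / 100
  drug_response(drug, sample, measure, value)
}

#' Write a drug-response table to TSV
#' @param resp A [drug_response()] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_drug_response <- function(resp, path) {
  df <- as.data.frame(resp)
  names(df)[names(df) == "drug_id"] <- "drug"
  names(df)[names(df) == "sample_id"] <- "sample"
  write_tsv_file(df, path)
}

# ---- gene panel -----------------------------------------------------------

#' Read a gene panel (one symbol per line)
#'
#' Lines starting with `#` are comments; blank lines are ignored.  Symbols
#' are upper-cased and de-duplicated preserving first-occurrence order.
#'
#' @param path Path to the panel file.
#' @return Character vector of unique, upper-cased gene symbols.
#' @export
read_gene_panel <- function(path) {
  if (!file.exists(path)) stop_fmt("file does not exist: '%s'", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[lines != ""]
  if (length(lines) == 0) stop_fmt("'%s': empty gene panel", path)
  unique(toupper(lines))
}

#' Write a gene panel
#' @param panel Character vector of gene symbols.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_panel <- function(panel, path) {
  writeLines(panel, path)
  invisible(path)
}

# ---- sample annotations ---------------------------------------------------

#' @noRd
truthy_map <- function() {
  c(`true` = TRUE, t = TRUE, yes = TRUE, y = TRUE, `1` = TRUE,
    `false` = FALSE, f = FALSE, no = FALSE, n = FALSE, `0` = FALSE)
}

#' Construct and validate per-sample annotations
#'
#' Column typing follows a header convention: `sample_id` (required,
#' unique), and the reserved optional columns `tumor_site` (categorical),
#' `treatment` (categorical), `response_pct` (numeric percent change) and
#' `response_binary` (0/1).  Every other column is treated as a boolean
#' biomarker flag and must be logical.
#'
#' @param df Data frame with the columns above.
#' @param pct_threshold Optional percent threshold; when given and both
#'   `response_pct` and `response_binary` are present, consistency
#'   (`response_binary == response_pct > pct_threshold`) is enforced.
#' @return The validated data frame, class `sample_annotations`, with the
#'   flag column names in `attr(, "flags")`.
#' @export
sample_annotations <- function(df, pct_threshold = NULL) {
  if (!"sample_id" %in% names(df))
    stop_fmt("annotations: missing required column 'sample_id'")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop_fmt("annotations: duplicated sample id '%s'",
             df$sample_id[duplicated(df$sample_id)][1L])
  reserved <- c("sample_id", "tumor_site", "treatment", "response_pct",
                "response_binary")
  flags <- setdiff(names(df), reserved)
  for (fc in flags) {
    if (!is.logical(df[[fc]]))
      stop_fmt("annotations: flag column '%s' is not boolean", fc)
  }
  if ("response_pct" %in% names(df))
    df$response_pct <- as.numeric(df$response_pct)
  if ("response_binary" %in% names(df)) {
    rb <- df$response_binary
    if (!all(rb %in% c(0L, 1L, NA)))
      stop_fmt("annotations: response_binary must be 0/1")
    df$response_binary <- as.integer(rb)
  }
  if (!is.null(pct_threshold) &&
      all(c("response_pct", "response_binary") %in% names(df))) {
    both <- !is.na(df$response_pct) & !is.na(df$response_binary)
    exp_bin <- as.integer(df$response_pct[both] > pct_threshold)
    if (any(exp_bin != df$response_binary[both]))
      stop_fmt("annotations: response_binary inconsistent with response_pct at threshold %g (sample '%s')",
               pct_threshold,
               df$sample_id[both][which(exp_bin != df$response_binary[both])[1L]])
  }
  attr(df, "flags") <- flags
  class(df) <- c("sample_annotations", "data.frame")
  df
}

#' Read per-sample annotations from TSV
#'
#' Flag columns (any column other than `sample_id`, `tumor_site`,
#' `treatment`, `response_pct`, `response_binary`) are parsed under the
#' truthy mapping `true/t/yes/y/1` and `false/f/no/n/0` (case-insensitive);
#' any other value in a flag column is an error naming the column.
#'
#' @inheritParams sample_annotations
#' @param path Path to the TSV file.
#' @return A [sample_annotations()] data frame.
#' @export
read_annotations <- function(path, pct_threshold = NULL) {
  df <- read_tsv_file(path)
  if (!"sample_id" %in% names(df)) {
    if ("sample" %in% names(df)) {
      names(df)[names(df) == "sample"] <- "sample_id"
    } else {
      stop_fmt("'%s': missing required column 'sample_id'", path)
    }
  }
  reserved <- c("sample_id", "tumor_site", "treatment", "response_pct",
                "response_binary")
  tm <- truthy_map()
  for (fc in setdiff(names(df), reserved)) {
    raw <- tolower(trimws(as.character(df[[fc]])))
    parsed <- unname(tm[raw])
    bad <- !is.na(raw) & raw != "na" & is.na(parsed)
    if (any(bad))
      stop_fmt("'%s': non-boolean value '%s' in flag column '%s' (row %d)",
               path, df[[fc]][bad][1L], fc, which(bad)[1L])
    df[[fc]] <- parsed
  }
  sample_annotations(df, pct_threshold = pct_threshold)
}

#' Write sample annotations to TSV
#' @param ann A [sample_annotations()] data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  write_tsv_file(as.data.frame(ann), path)
}

# ---- score matrix ---------------------------------------------------------

#' Write / read a drugs-by-samples score matrix
#'
#' Scores are serialized with 17 significant digits so that
#' `read_score_matrix(write_score_matrix(x))` reproduces `x` exactly.
#'
#' @param scores Numeric matrix, drugs in rows, samples in columns.
#' @param path File path.
#' @return `path` invisibly (writer); the numeric matrix (reader).
#' @export
write_score_matrix <- function(scores, path) {
  df <- data.frame(drug = rownames(scores),
                   apply(scores, 2L, format_full),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(scores) == 1L) names(df)[2L] <- colnames(scores)
  write_tsv_file(df, path)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(path) {
  df <- read_tsv_file(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  m <- matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m))
  rownames(m) <- as.character(df[[1L]])
  m
}

# ---- model set serialization ----------------------------------------------

#' Serialize a locked signature-model set to a long-format TSV
#'
#' The file has a comment header block carrying the shared feature
#' namespace and one metadata line per drug (alpha, lambda, seed), followed
#' by a long-format table `drug`, `term`, `coefficient` where `term` is
#' `"(Intercept)"` or a `<GENE>:expr` / `<GENE>:mut` feature name.
#' Coefficients that are exactly zero are omitted from the file and
#' restored as zero on read using the serialized namespace.  All floats are
#' written with 17 significant digits, so the write/read round trip is
#' exact.  The per-grid-point `cv_summary` is not serialized; the locked
#' linear model (intercept, coefficients, alpha, lambda, seed) is.
#'
#' @param models A [signature_model_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_set <- function(models, path) {
  stopifnot(inherits(models, "signature_model_set"))
  for (m in models) {
    if (!isTRUE(m$locked))
      stop_fmt("model for drug '%s' is not locked; refusing to serialize",
               m$drug_id)
  }
  ns <- model_set_features(models)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pharmsig_model_set\tv1", con)
  writeLines(paste(c("# features", ns), collapse = "\t"), con)
  for (m in models) {
    writeLines(paste0("# model\tdrug=", m$drug_id,
                      "\talpha=", format_full(m$alpha),
                      "\tlambda=", format_full(m$lambda),
                      "\tseed=", format_full(m$seed)), con)
  }
  writeLines("drug\tterm\tcoefficient", con)
  for (m in models) {
    writeLines(paste(m$drug_id, "(Intercept)", format_full(m$intercept),
                     sep = "\t"), con)
    keep <- which(m$coefficients != 0)
    for (j in keep) {
      writeLines(paste(m$drug_id, names(m$coefficients)[j],
                       format_full(m$coefficients[j]), sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a locked signature-model set written by [write_model_set()]
#'
#' @param path Path to the model TSV.
#' @return A [signature_model_set()]; every model is locked and carries the
#'   full coefficient vector over the serialized feature namespace (omitted
#'   terms restored as exact zeros).
#' @export
read_model_set <- function(path) {
  if (!file.exists(path)) stop_fmt("file does not exist: '%s'", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  feat_line <- hdr[startsWith(hdr, "# features")]
  if (length(feat_line) != 1L)
    stop_fmt("'%s': missing '# features' header line", path)
  ns <- strsplit(feat_line, "\t", fixed = TRUE)[[1L]][-1L]
  bad_ns <- ns[!grepl(":(expr|mut)$", ns)]
  if (length(bad_ns) > 0)
    stop_fmt("'%s': unknown term suffix in feature namespace: %s",
             path, paste(sQuote(bad_ns), collapse = ", "))
  meta_lines <- hdr[startsWith(hdr, "# model")]
  parse_meta <- function(line) {
    kv <- strsplit(line, "\t", fixed = TRUE)[[1L]][-1L]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    names(vals) <- keys
    vals
  }
  meta <- lapply(meta_lines, parse_meta)
  names(meta) <- vapply(meta, `[[`, "", "drug")
  parse_num <- function(s) if (s == "NA") NA_real_ else as.numeric(s)
  body <- body[body != ""]
  if (length(body) < 1L || !identical(strsplit(body[[1L]], "\t")[[1L]],
                                      c("drug", "term", "coefficient")))
    stop_fmt("'%s': expected header 'drug<TAB>term<TAB>coefficient'", path)
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  models <- list()
  for (r in rows) {
    drug <- r[[1L]]; term <- r[[2L]]; coefv <- as.numeric(r[[3L]])
    if (term != "(Intercept)") {
      if (!grepl(":(expr|mut)$", term))
        stop_fmt("'%s': unknown term suffix for term '%s' (drug '%s')",
                 path, term, drug)
      if (!term %in% ns)
        stop_fmt("'%s': term '%s' absent from the feature namespace", path,
                 term)
    }
    if (is.null(models[[drug]])) {
      coefs <- stats::setNames(numeric(length(ns)), ns)
      md <- meta[[drug]]
      if (is.null(md))
        stop_fmt("'%s': no '# model' metadata line for drug '%s'", path, drug)
      models[[drug]] <- list(drug_id = drug, intercept = 0,
                             coefficients = coefs,
                             alpha = parse_num(md[["alpha"]]),
                             lambda = parse_num(md[["lambda"]]),
                             seed = parse_num(md[["seed"]]))
    }
    if (term == "(Intercept)") {
      models[[drug]]$intercept <- coefv
    } else {
      models[[drug]]$coefficients[[term]] <- coefv
    }
  }
  out <- lapply(models, function(m) {
    signature_model(drug_id = m$drug_id, intercept = m$intercept,
                    coefficients = m$coefficients, alpha = m$alpha,
                    lambda = m$lambda, seed = m$seed, locked = TRUE)
  })
  signature_model_set(out)
}
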