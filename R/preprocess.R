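# Conversion of raw cohort inputs into the model-ready feature
# representation: a binary protein-coding mutation channel, a log2
# median-scaled expression channel, and their panel-restricted assembly
# into a samples x features matrix with "<GENE>:expr" / "<GENE>:mut"
# column names.

#' Binarize mutation calls into a genes-by-samples 0/1 matrix
#'
#' A gene/sample entry is 1 iff at least one call for that pair has a
#' protein-altering consequence ([protein_altering_classes()]); silent,
#' intronic, intergenic, UTR and other non-coding calls never set the bit.
#' Duplicate calls are collapsed (OR), so the result is invariant to call
#' multiplicity.  Samples with no calls at all yield all-zero columns
#' (wild-type coding), and calls for genes outside the panel are dropped
#' with a message reporting the count.
#'
#' @param calls A [mutation_calls()] table.
#' @param panel Character vector of panel gene symbols (rows of the result,
#'   in panel order).
#' @param samples Character vector of sample ids (columns of the result).
#' @return Binary integer matrix, `length(panel)` x `length(samples)`.
#' @export
binarize_mutations <- function(calls, panel, samples) {
  if (length(samples) == 0) stop_fmt("binarize_mutations: empty sample list")
  panel <- unique(toupper(panel))
  m <- matrix(0L, nrow = length(panel), ncol = length(samples),
              dimnames = list(panel, samples))
  if (nrow(calls) == 0) return(m)
  keep <- calls$consequence_class %in% protein_altering_classes() &
    calls$sample_id %in% samples
  off_panel <- sum(keep & !(calls$gene %in% panel))
  if (off_panel > 0)
    message(sprintf("binarize_mutations: dropped %d call(s) for genes outside the panel",
                    off_panel))
  keep <- keep & calls$gene %in% panel
  if (any(keep))
    m[cbind(calls$gene[keep], calls$sample_id[keep])] <- 1L
  m
}

#' Normalize FPKM expression: log2 transform and median scaling
#'
#' Computes `log2(FPKM + pseudo_count)` and subtracts the cohort median:
#' per gene by default (`mode = "per_gene"`, each gene's median across the
#' cohort's samples becomes 0), or a single cohort-wide median under
#' `mode = "global"` (provided for sensitivity analysis).  The result is
#' restricted to panel genes present in the input.
#'
#' @param raw Non-negative genes-by-samples FPKM matrix
#'   (see [read_expression_table()]).
#' @param panel Character vector of panel gene symbols.
#' @param pseudo_count Added before the log2 transform (FPKM may be zero).
#' @param mode `"per_gene"` (default) or `"global"` median centering.
#' @return Numeric genes-by-samples matrix; under `"per_gene"`, each row's
#'   median is 0.
#' @export
normalize_expression <- function(raw, panel, pseudo_count = 1,
                                 mode = c("per_gene", "global")) {
  mode <- match.arg(mode)
  if (ncol(raw) < 2)
    stop_fmt("normalize_expression: need >= 2 samples for median scaling (got %d)",
             ncol(raw))
  panel <- unique(toupper(panel))
  genes <- intersect(panel, rownames(raw))
  if (length(genes) == 0)
    stop_fmt("normalize_expression: no panel genes present in the expression table")
  x <- log2(raw[genes, , drop = FALSE] + pseudo_count)
  if (mode == "per_gene") {
    med <- apply(x, 1L, stats::median)
    x - med
  } else {
    x - stats::median(x)
  }
}

#' Assemble expression and mutation channels into a feature matrix
#'
#' Produces the samples-by-features matrix consumed by model training and
#' prediction.  Columns are ordered by the panel, expression channel before
#' mutation channel per gene, named `<GENE>:expr` and `<GENE>:mut`.  A gene
#' missing from one channel simply contributes no column for that channel.
#' The sample sets of the two channels are intersected (with a message when
#' rows are dropped).
#'
#' @param expr Genes-by-samples matrix from [normalize_expression()].
#' @param mut Genes-by-samples binary matrix from [binarize_mutations()].
#' @param panel Character vector fixing the gene order.
#' @return Numeric samples-by-features matrix.
#' @export
assemble_features <- function(expr, mut, panel) {
  panel <- unique(toupper(panel))
  samples <- intersect(colnames(expr), colnames(mut))
  if (length(samples) == 0)
    stop_fmt("assemble_features: expression and mutation data share no samples")
  dropped <- (ncol(expr) - length(samples)) + (ncol(mut) - length(samples))
  if (dropped > 0)
    message(sprintf("assemble_features: dropped %d sample column(s) absent from one channel",
                    dropped))
  cols <- list()
  for (g in panel) {
    if (g %in% rownames(expr))
      cols[[paste0(g, ":expr")]] <- expr[g, samples]
    if (g %in% rownames(mut))
      cols[[paste0(g, ":mut")]] <- as.numeric(mut[g, samples])
  }
  if (length(cols) == 0)
    stop_fmt("assemble_features: no panel genes present in either channel")
  out <- do.call(cbind, cols)
  rownames(out) <- samples
  out
}

#' Split feature-matrix column names back into gene and channel
#' @param features Feature matrix or character vector of column names.
#' @return Data frame with columns `feature`, `gene`, `channel`.
#' @export
feature_channels <- function(features) {
  nm <- if (is.character(features)) features else colnames(features)
  data.frame(feature = nm,
             gene = sub(":(expr|mut)$", "", nm),
             channel = sub("^.*:", "", nm),
             stringsAsFactors = FALSE)
}

#' Intersect gene panels across platforms
#'
#' Returns the genes present in every panel, ordered by the first panel
#' (the harmonized panel on which cross-cohort models are trained and
#' applied).
#'
#' @param panels List of character vectors (>= 1).
#' @return Character vector; error if the intersection is empty.
#' @export
harmonize_panel <- function(panels) {
  if (!is.list(panels) || length(panels) == 0)
    stop_fmt("harmonize_panel: need a non-empty list of panels")
  panels <- lapply(panels, function(p) unique(toupper(p)))
  common <- Reduce(intersect, panels)
  if (length(common) == 0)
    stop_fmt("harmonize_panel: the panels share no genes")
  panels[[1L]][panels[[1L]] %in% common]
}
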