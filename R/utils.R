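# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator with `seed`, runs `expr`, and restores whatever RNG
#' state was in place before, so package functions never perturb the user's
#' random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' @noRd
stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

# read.delim wrapper tolerant of CRLF line endings and arbitrary column
# order; returns character columns untouched.
#' @noRd
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop_fmt("file does not exist: '%s'", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    na.strings = c("NA", ""), quote = "")
}

#' @noRd
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Serialize doubles so that read(write(x)) is the identity.
#' @noRd
format_full <- function(x) sprintf("%.17g", x)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
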