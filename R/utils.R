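#' miRpair: integrative paired tumor/normal multi-omic analysis
#'
#' Paired SAM differential expression with sign-flip permutation FDR,
#' consensus miRNA target integration with inverse-association sets and
#' hypergeometric enrichment, aCGH loss/gain calling with minimal common
#' regions, net immunoscore analysis, and a seeded synthetic-cohort
#' generator with ground truth.
#'
#' @keywords internal
"_PACKAGE"

# Deterministic TSV writer: tab-separated, UTF-8, '#' reserved for comments,
# numbers rendered with full precision via format() so repeated writes of the
# same object are byte-identical.
write_tsv_file <- function(df, path) {
  stopifnot(is.data.frame(df))
  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x)) {
      format(x, digits = 17, trim = TRUE, scientific = FALSE)
    } else {
      as.character(x)
    }
  }
  out <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1L)
  lines <- c(
    paste(names(df), collapse = "\t"),
    apply(out, 1L, paste, collapse = "\t")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}
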