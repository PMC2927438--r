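# Readers and writers for the interchange formats: TSV everywhere
# (tab-separated, UTF-8, '#' comments) except miRNA loci, which travel as
# standard BED6 (0-based half-open).

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `case_id`, `tissue`
#'   (`tumor`/`normal`).
#' @return Validated data frame.
#' @export
read_samples <- function(path) {
  df <- read_tsv_file(path)
  need <- c("sample_id", "case_id", "tissue")
  if (!all(need %in% names(df)))
    stop("sample sheet needs columns sample_id, case_id, tissue: ", path)
  bad <- setdiff(unique(df$tissue), c("tumor", "normal"))
  if (length(bad))
    stop("tissue must be tumor/normal; offending values: ",
         paste(bad, collapse = ", "))
  df
}

pairing_from_samples <- function(samples) {
  split_cases <- split(samples, samples$case_id)
  bad <- names(split_cases)[vapply(split_cases, function(s) {
    sum(s$tissue == "tumor") != 1L || sum(s$tissue == "normal") != 1L
  }, logical(1))]
  if (length(bad))
    stop("each case needs exactly one tumor and one normal sample; offending case(s): ",
         paste(bad, collapse = ", "))
  data.frame(
    case_id = names(split_cases),
    tumor = vapply(split_cases, function(s) s$sample_id[s$tissue == "tumor"],
                   character(1)),
    normal = vapply(split_cases, function(s) s$sample_id[s$tissue == "normal"],
                    character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Read an expression matrix and its sample sheet into a paired cohort
#'
#' @param expr_path TSV: first column `feature`, one column per sample, log2
#'   values.
#' @param samples_path Sample sheet TSV (see [read_samples()]).
#' @param feature_kind `"mrna"` or `"mirna"`.
#' @return A [paired_cohort()].
#' @export
read_expression <- function(expr_path, samples_path,
                            feature_kind = c("mrna", "mirna")) {
  feature_kind <- match.arg(feature_kind)
  df <- read_tsv_file(expr_path)
  if (names(df)[1L] != "feature")
    stop("expression file must start with a 'feature' column: ", expr_path)
  dup <- df$feature[duplicated(df$feature)]
  if (length(dup))
    stop("duplicate feature ids in ", expr_path, ": ",
         paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", expr_path)
  rownames(m) <- df$feature
  samples <- read_samples(samples_path)
  missing <- setdiff(samples$sample_id, colnames(m))
  if (length(missing))
    stop("samples absent from expression matrix: ",
         paste(missing, collapse = ", "))
  paired_cohort(m[, samples$sample_id, drop = FALSE],
                pairing_from_samples(samples), feature_kind)
}

#' Read a predictor edge table
#'
#' @param path TSV with columns `mirna`, `gene`, `source` (`P1`/`P2`),
#'   `score`.
#' @return Validated data frame.
#' @export
read_predictions <- function(path) {
  df <- read_tsv_file(path)
  need <- c("mirna", "gene", "source")
  if (!all(need %in% names(df)))
    stop("predictor table needs columns mirna, gene, source: ", path)
  key <- paste(df$mirna, df$gene, df$source)
  if (anyDuplicated(key))
    stop("duplicate (mirna, gene, source) edges in ", path, ": ",
         paste(utils::head(unique(key[duplicated(key)]), 3L), collapse = "; "))
  df
}

#' Read aCGH probe tracks
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `log2ratio` and an
#'   optional leading `patient` column for multi-patient files.
#' @return Named list of per-patient probe data frames, each sorted and
#'   validated.
#' @export
read_probes <- function(path) {
  df <- read_tsv_file(path)
  if (!"patient" %in% names(df)) df$patient <- "patient1"
  need <- c("patient", "chrom", "start", "end", "log2ratio")
  if (!all(need %in% names(df)))
    stop("probe file needs columns chrom, start, end, log2ratio: ", path)
  out <- lapply(split(df[, c("chrom", "start", "end", "log2ratio")],
                      df$patient), function(p) {
    p <- p[order(p$chrom, p$start), , drop = FALSE]
    rownames(p) <- NULL
    validate_probe_track(p)
    p
  })
  out[order(names(out))]
}

#' Read miRNA loci from a BED file
#'
#' @param path BED (at least 4 columns) with 0-based half-open intervals.
#' @return Data frame `name`, `chrom`, `start`, `end`, `score`, `strand`
#'   with coordinates kept 0-based half-open.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    name = if (!is.null(gr$name)) gr$name else
      paste0("locus", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  if (any(df$start < 0)) stop("negative coordinates in ", path)
  if (any(df$end <= df$start)) stop("empty interval in ", path)
  df
}

#' Read an ordinal IHC score table
#'
#' @param path TSV with columns `case_id`, `marker`, `tumor_score`,
#'   `normal_score`.
#' @return Data frame.
#' @export
read_ihc <- function(path) {
  df <- read_tsv_file(path)
  need <- c("case_id", "marker", "tumor_score", "normal_score")
  if (!all(need %in% names(df)))
    stop("IHC table needs columns case_id, marker, tumor_score, normal_score: ",
         path)
  df
}

#' Write a data frame as canonical TSV
#'
#' Deterministic tab-separated output (same object, byte-identical file).
#' @param records Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(records, path) write_tsv_file(records, path)

#' Read a whole fixture directory back into a cohort bundle
#'
#' Inverse of [write_fixture()]: reads expression matrices, sample sheet,
#' predictor edges, probe tracks, miRNA loci and IHC scores.
#'
#' @param directory Directory written by [write_fixture()].
#' @return List with `mrna`, `mirna`, `predictions`, `probes`, `mirna_loci`,
#'   `ihc` (no ground truth: that never leaves the generator).
#' @export
read_cohort_dir <- function(directory) {
  f <- function(name) file.path(directory, name)
  list(mrna = read_expression(f("expression.tsv"), f("samples.tsv"), "mrna"),
       mirna = read_expression(f("mirna_expression.tsv"), f("samples.tsv"),
                               "mirna"),
       predictions = read_predictions(f("predictors.tsv")),
       probes = read_probes(f("probes.tsv")),
       mirna_loci = read_bed(f("mirna_loci.bed")),
       ihc = read_ihc(f("ihc.tsv")))
}
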