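#' Paired tumor/normal expression cohort
#'
#' Container for a log2 expression matrix (features x samples) together with
#' the sample pairing that links each tumor column to its patient-matched
#' normal column. All downstream differential analysis is paired: statistics
#' are computed on within-case tumor minus normal differences.
#'
#' @param values Numeric matrix of log2 expression, features in rows (unique
#'   rownames required), samples in columns (colnames required).
#' @param pairing Data frame with columns `case_id`, `tumor`, `normal` naming,
#'   for every case, its tumor and normal sample column in `values`.
#' @param feature_kind Either `"mrna"` or `"mirna"`.
#'
#' @return An object of class `paired_cohort`: a list with elements `values`,
#'   `pairing` and `feature_kind`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' p <- data.frame(case_id = c("c1", "c2"),
#'                 tumor = c("s1", "s3"), normal = c("s2", "s4"))
#' paired_cohort(m, p)
#' @export
paired_cohort <- function(values, pairing, feature_kind = c("mrna", "mirna")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have row (feature) and column (sample) names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate feature ids: ", paste(unique(dup), collapse = ", "))
  need <- c("case_id", "tumor", "normal")
  if (!all(need %in% names(pairing)))
    stop("'pairing' needs columns case_id, tumor, normal")
  pairing <- as.data.frame(pairing)[, need]
  pairing[] <- lapply(pairing, as.character)
  samp <- c(pairing$tumor, pairing$normal)
  missing <- setdiff(samp, colnames(values))
  if (length(missing))
    stop("pairing refers to samples absent from the matrix: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(samp))
    stop("a sample column is used by more than one pairing slot: ",
         paste(unique(samp[duplicated(samp)]), collapse = ", "))
  if (anyDuplicated(pairing$case_id))
    stop("duplicate case ids in pairing: ",
         paste(unique(pairing$case_id[duplicated(pairing$case_id)]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite values; missing values are not supported")
  structure(list(values = values, pairing = pairing,
                 feature_kind = feature_kind),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("paired_cohort (%s): %d features x %d samples, %d tumor/normal pairs\n",
              x$feature_kind, nrow(x$values), ncol(x$values), nrow(x$pairing)))
  invisible(x)
}

#' Per-case paired log2 differences (tumor minus normal)
#'
#' @param cohort A [paired_cohort()].
#' @return Numeric matrix, features x cases, of tumor - normal log2 values.
#' @export
paired_differences <- function(cohort) {
  stopifnot(inherits(cohort, "paired_cohort"))
  d <- cohort$values[, cohort$pairing$tumor, drop = FALSE] -
    cohort$values[, cohort$pairing$normal, drop = FALSE]
  colnames(d) <- cohort$pairing$case_id
  d
}

#' Median-center a cohort on its reference samples
#'
#' Subtracts from every feature row the median of that row over the reference
#' columns (the matched-normal samples by default), so that normal tissue sits
#' at log2 = 0 and tumor values read as relative abundance.
#'
#' @param cohort A [paired_cohort()].
#' @param reference `"normal"` (default) centers on the matched-normal
#'   columns; `"all"` centers on every sample.
#' @return A `paired_cohort` with centered values.
#' @export
median_center <- function(cohort, reference = c("normal", "all")) {
  stopifnot(inherits(cohort, "paired_cohort"))
  reference <- match.arg(reference)
  ref_cols <- if (reference == "normal") cohort$pairing$normal
              else colnames(cohort$values)
  med <- apply(cohort$values[, ref_cols, drop = FALSE], 1L, stats::median)
  cohort$values <- cohort$values - med
  cohort
}
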