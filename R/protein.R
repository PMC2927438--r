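#' Net immunoscores from paired tumor/normal ordinal IHC scores
#'
#' For each (case, marker) record the net value is the tumor immunoscore
#' minus the matched-normal immunoscore, the standard tissue-microarray
#' readout of protein gain or loss in tumor. Records missing either half are
#' dropped with a warning.
#'
#' @param table Data frame with columns `case_id`, `marker`, `tumor_score`,
#'   `normal_score`.
#' @param levels Integer ordinal scale size; scores must lie in
#'   `0 .. levels - 1` (default 5, i.e. a 0-4 scale).
#' @return List with `records` (the input rows plus `net`) and `summary`
#'   (per-marker `n`, `mean_net`, `se_net`); attribute `n_dropped`.
#' @export
net_scores <- function(table, levels = 5L) {
  need <- c("case_id", "marker", "tumor_score", "normal_score")
  stopifnot(is.data.frame(table), all(need %in% names(table)))
  tab <- as.data.frame(table)[, need]
  complete <- stats::complete.cases(tab[, c("tumor_score", "normal_score")])
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    warning(n_dropped, " record(s) missing a tissue score were dropped")
  tab <- tab[complete, , drop = FALSE]
  sc <- c(tab$tumor_score, tab$normal_score)
  if (any(sc < 0 | sc > levels - 1 | sc != round(sc)))
    stop("scores must be integers on the declared 0..", levels - 1, " scale")
  tab$net <- tab$tumor_score - tab$normal_score
  summ <- do.call(rbind, lapply(split(tab, tab$marker), function(m) {
    data.frame(marker = m$marker[1L], n = nrow(m), mean_net = mean(m$net),
               se_net = if (nrow(m) > 1L) stats::sd(m$net) / sqrt(nrow(m))
                        else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(records = tab, summary = summ), n_dropped = n_dropped)
}

#' Correlation of a marker's net immunoscores with a miRNA's tumor/normal
#' log2 ratios
#'
#' Joins the two inputs on case id and computes the correlation across the
#' shared cases — the protein-level analogue of the miRNA::mRNA inverse
#' correlation. Negative r indicates that higher miRNA levels in tumor go
#' with lower protein accumulation.
#'
#' @param nets Data frame for one marker with columns `case_id` and `net`
#'   (e.g. a subset of `net_scores()$records`).
#' @param mirna_ratios Named numeric vector of per-case tumor minus normal
#'   miRNA log2 values (names = case ids).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List of class `marker_correlation` with `r`, `n`, `undefined`.
#' @export
mirna_marker_correlation <- function(nets, mirna_ratios,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(nets), all(c("case_id", "net") %in% names(nets)),
            !is.null(names(mirna_ratios)))
  shared <- intersect(nets$case_id, names(mirna_ratios))
  if (length(shared) < 3L)
    stop("insufficient data: fewer than 3 shared cases between IHC and miRNA")
  x <- mirna_ratios[shared]
  y <- nets$net[match(shared, nets$case_id)]
  cr <- pair_correlation(x, y, method = method)
  structure(list(r = cr$r, n = cr$n, undefined = cr$undefined),
            class = "marker_correlation")
}
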