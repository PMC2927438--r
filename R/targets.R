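#' Consensus targets of a miRNA set across two predictors
#'
#' A gene is a consensus target of a miRNA set when it is predicted as a
#' target of at least one miRNA in the set by source P1 AND of at least one
#' miRNA in the set by source P2 (union over miRNAs, intersection over
#' prediction sources). This mirrors keeping only genes identified by both
#' prediction algorithms.
#'
#' @param tables Data frame of prediction edges with columns `mirna`, `gene`,
#'   `source` (values `"P1"`/`"P2"`) and optionally `score`.
#' @param mirnas Character vector of miRNA ids defining the set.
#' @return Sorted character vector of consensus target genes.
#' @export
consensus_targets <- function(tables, mirnas) {
  stopifnot(is.data.frame(tables),
            all(c("mirna", "gene", "source") %in% names(tables)))
  if (nrow(tables) == 0L) stop("empty prediction table")
  unknown <- setdiff(mirnas, unique(tables$mirna))
  if (length(unknown))
    warning("miRNA ids absent from prediction tables (ignored): ",
            paste(unknown, collapse = ", "))
  sel <- tables[tables$mirna %in% mirnas, , drop = FALSE]
  g1 <- unique(sel$gene[sel$source == "P1"])
  g2 <- unique(sel$gene[sel$source == "P2"])
  sort(intersect(g1, g2))
}

#' Direction-stratified inverse-association target sets
#'
#' Intersects consensus targets of up-regulated miRNAs with significantly
#' down-regulated genes (`inverse_up`) and consensus targets of
#' down-regulated miRNAs with significantly up-regulated genes
#' (`inverse_down`) — the inverse-association selection at the heart of
#' miRNA::mRNA integration. A gene landing in both inverse sets is kept in
#' both and listed in `flagged`.
#'
#' @param consensus_up,consensus_down Character vectors of consensus targets
#'   of the up- and down-regulated miRNA sets.
#' @param de A `sam_result` (or data frame with `feature` and `direction`)
#'   for the gene cohort.
#' @return List of class `target_consensus` with `targets_of_up`,
#'   `targets_of_down`, `inverse_up`, `inverse_down`, `flagged`.
#' @export
inverse_sets <- function(consensus_up, consensus_down, de) {
  stopifnot(is.data.frame(de), all(c("feature", "direction") %in% names(de)))
  genes_down <- de$feature[de$direction == "down"]
  genes_up <- de$feature[de$direction == "up"]
  inv_up <- sort(intersect(consensus_up, genes_down))
  inv_down <- sort(intersect(consensus_down, genes_up))
  structure(list(targets_of_up = sort(unique(consensus_up)),
                 targets_of_down = sort(unique(consensus_down)),
                 inverse_up = inv_up,
                 inverse_down = inv_down,
                 flagged = intersect(inv_up, inv_down)),
            class = "target_consensus")
}

#' Percentage of dysregulated genes explained by inverse-association sets
#'
#' @param tc A `target_consensus` from [inverse_sets()], or a list with
#'   `inverse_up` and `inverse_down` character vectors.
#' @param n_dysregulated Total count of significantly dysregulated genes.
#' @return `100 * |inverse_up U inverse_down| / n_dysregulated`.
#' @export
coverage_percent <- function(tc, n_dysregulated) {
  if (!is.numeric(n_dysregulated) || length(n_dysregulated) != 1L ||
      n_dysregulated <= 0)
    stop("n_dysregulated must be a positive count")
  100 * length(union(tc$inverse_up, tc$inverse_down)) / n_dysregulated
}

#' One-sided hypergeometric enrichment of a target set
#'
#' Tests whether `k` observed overlaps between an `n`-gene consensus target
#' set and the `K` dysregulated-in-direction genes out of a population of `N`
#' exceed chance: `p = P(X >= k)` for X hypergeometric(N, K, n). The tail is
#' summed in log space via `lchoose` for numerical stability.
#'
#' @param N Population gene count (the expression-matrix universe).
#' @param K Dysregulated-in-direction gene count.
#' @param n Consensus target set size.
#' @param k Observed overlap.
#' @return List of class `enrichment_result` with fields `N`, `K`, `n`, `k`,
#'   `p`.
#' @export
enrichment_test <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals < 0) || any(vals != round(vals)))
    stop("counts must be non-negative integers")
  if (K > N || n > N) stop("K and n cannot exceed N")
  if (k > min(K, n)) stop("overlap k cannot exceed min(K, n)")
  if (n > N - K + k) stop("overlap k too small: n - k exceeds N - K")
  imax <- min(K, n)
  if (k == 0) {
    p <- 1
  } else {
    i <- k:imax
    logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    m <- max(logp)
    p <- exp(m + log(sum(exp(logp - m))))
    p <- min(p, 1)
  }
  structure(list(N = N, K = K, n = n, k = k, p = p),
            class = "enrichment_result")
}

#' Pearson correlation of a miRNA profile and a gene profile across cases
#'
#' @param mirna_profile,gene_profile Numeric vectors over the same cases
#'   (length >= 3). Vector names, when present on both, are used to match
#'   cases.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List of class `correlation_record` with `r` (NA when undefined),
#'   `n`, and logical `undefined` (TRUE when either vector is constant).
#' @export
pair_correlation <- function(mirna_profile, gene_profile,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.null(names(mirna_profile)) && !is.null(names(gene_profile))) {
    shared <- intersect(names(mirna_profile), names(gene_profile))
    mirna_profile <- mirna_profile[shared]
    gene_profile <- gene_profile[shared]
  }
  if (length(mirna_profile) != length(gene_profile))
    stop("profile length mismatch")
  if (length(mirna_profile) < 3L)
    stop("need at least 3 cases for a correlation")
  if (any(!is.finite(mirna_profile)) || any(!is.finite(gene_profile)))
    stop("non-finite values in correlation input")
  undef <- stats::sd(mirna_profile) == 0 || stats::sd(gene_profile) == 0
  r <- if (undef) NA_real_
       else stats::cor(mirna_profile, gene_profile, method = method)
  structure(list(r = r, n = length(mirna_profile), undefined = undef),
            class = "correlation_record")
}

#' Five-number box-plot summary of a gene-set expression vector
#'
#' Minimum, lower quartile, median, upper quartile and maximum; quartiles by
#' linear interpolation of the order statistics (the convention of
#' `quantile(type = 7)`).
#'
#' @param values Numeric vector with at least one finite value.
#' @return List of class `box_summary` with `min`, `q1`, `median`, `q3`,
#'   `max`.
#' @export
box_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("box_summary needs at least one finite value")
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1),
                       names = FALSE, type = 7)
  structure(list(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5]),
            class = "box_summary")
}

#' Average-linkage clustering order under correlation distance
#'
#' Agglomerative hierarchical clustering of matrix rows (and columns) with
#' distance `1 - Pearson r`, average linkage — the classic expression
#' heat-map ordering. Constant rows, whose correlation with anything is
#' undefined, are assigned the maximal distance 2 to every other row.
#'
#' @param mat Numeric matrix, features x cases, with at least 2 rows.
#' @param cluster_columns Also order columns (default TRUE when >= 2
#'   columns).
#' @return List with `row_order`, `col_order` (integer permutations),
#'   `row_hclust`, `col_hclust`.
#' @export
cluster_order <- function(mat, cluster_columns = ncol(mat) >= 2L) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  corr_dist <- function(m) {
    sds <- apply(m, 1L, stats::sd)
    d <- matrix(2, nrow(m), nrow(m),
                dimnames = list(rownames(m), rownames(m)))
    ok <- which(sds > 0)
    if (length(ok) >= 2L) {
      cc <- stats::cor(t(m[ok, , drop = FALSE]))
      d[ok, ok] <- 1 - cc
    }
    diag(d) <- 0
    stats::as.dist(d)
  }
  hc_row <- stats::hclust(corr_dist(mat), method = "average")
  out <- list(row_order = hc_row$order, row_hclust = hc_row,
              col_order = seq_len(ncol(mat)), col_hclust = NULL)
  if (isTRUE(cluster_columns) && ncol(mat) >= 2L) {
    hc_col <- stats::hclust(corr_dist(t(mat)), method = "average")
    out$col_order <- hc_col$order
    out$col_hclust <- hc_col
  }
  out
}
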