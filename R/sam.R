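#' Settings for paired SAM differential expression
#'
#' @param fdr_target Target false discovery rate for the call set
#'   (default 0.05, the conventional 5% used for array filtering).
#' @param n_permutations `"exhaustive"` for all `2^n` sign-flip permutations
#'   of the per-case differences (allowed when `2^n_pairs <= 4096`), or an
#'   integer count of sampled sign flips.
#' @param s0_rule Rule for the exchangeability (fudge) factor s0 added to the
#'   per-feature standard error: `"tusher_cv"` (coefficient-of-variation
#'   search over s-percentile windows) or `"percentile:p"` (the p-th
#'   percentile of the s values, e.g. `"percentile:5"`).
#' @param delta_grid Optional numeric vector of Delta thresholds; by default
#'   50 evenly spaced quantiles of |d| are used.
#' @param seed Integer seed used only when permutations are sampled.
#' @return A list of class `sam_settings`.
#' @export
sam_settings <- function(fdr_target = 0.05, n_permutations = "exhaustive",
                         s0_rule = "tusher_cv", delta_grid = NULL,
                         seed = 1L) {
  if (!is.numeric(fdr_target) || length(fdr_target) != 1L ||
      fdr_target <= 0 || fdr_target >= 1)
    stop_config("fdr_target", "must be a single value in (0,1)")
  if (!(identical(n_permutations, "exhaustive") ||
        (is.numeric(n_permutations) && n_permutations >= 10)))
    stop_config("n_permutations", "must be \"exhaustive\" or a count >= 10")
  ok_rule <- identical(s0_rule, "tusher_cv") ||
    grepl("^percentile:[0-9.]+$", s0_rule)
  if (!ok_rule)
    stop_config("s0_rule", "must be \"tusher_cv\" or \"percentile:p\"")
  structure(list(fdr_target = fdr_target, n_permutations = n_permutations,
                 s0_rule = s0_rule, delta_grid = delta_grid,
                 seed = as.integer(seed)),
            class = "sam_settings")
}

# Tusher-style s0 search: pick the s-quantile s0 candidate that minimizes the
# coefficient of variation of the d-statistic spread across windows of s.
# Falls back to the 5th percentile of s when the CV search is degenerate.
sam_s0 <- function(dbar, s) {
  alphas <- seq(0, 1, by = 0.05)
  cand <- stats::quantile(s, alphas, names = FALSE, type = 7)
  qs <- stats::quantile(s, seq(0, 1, by = 0.01), names = FALSE, type = 7)
  grp <- cut(s, breaks = unique(c(-Inf, qs[-1], Inf)), labels = FALSE)
  cvs <- vapply(cand, function(s0c) {
    d <- dbar / (s + s0c)
    v <- tapply(d, grp, stats::mad)
    v <- v[is.finite(v)]
    if (length(v) < 2L || mean(v) == 0) return(NA_real_)
    stats::sd(v) / mean(v)
  }, numeric(1))
  if (all(is.na(cvs)))
    return(stats::quantile(s, 0.05, names = FALSE, type = 7))
  cand[which.min(cvs)]
}

sign_flip_matrix <- function(n, n_permutations, seed) {
  if (identical(n_permutations, "exhaustive")) {
    if (2^n > 4096)
      stop("exhaustive permutation requires 2^n_pairs <= 4096 (n_pairs <= 12)")
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n), KEEP.OUT.ATTRS = FALSE))
    dimnames(S) <- NULL
    t(S)
  } else {
    B <- as.integer(n_permutations)
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    matrix(sample(c(1, -1), n * B, replace = TRUE), nrow = n, ncol = B)
  }
}

sam_d <- function(dbar, s, s0) {
  denom <- s + s0
  d <- dbar / denom
  d[dbar == 0 & denom == 0] <- 0
  d
}

#' Paired SAM differential expression with permutation FDR
#'
#' Significance analysis of a paired tumor/normal cohort. For each feature the
#' per-case differences `z = tumor - normal` give `dbar = mean(z)`,
#' `s = sqrt(sum((z - dbar)^2) / (n (n - 1)))` and the moderated statistic
#' `d = dbar / (s + s0)`. The null distribution comes from sign-flip
#' permutations of the per-case differences (the paired-design permutation
#' group). For each threshold Delta the asymmetric cutoffs are read off the
#' sorted observed d against the permutation-expected order statistics, and
#' FDR is estimated as the median permutation count of d* beyond the cutoffs
#' divided by the observed call count (pi0 fixed at 1, conservative). The
#' call set is taken at the Delta maximizing calls subject to
#' `FDR <= fdr_target`.
#'
#' @param cohort A [paired_cohort()] with at least 3 pairs.
#' @param settings A [sam_settings()].
#' @return A data frame of class `sam_result` with columns `feature`, `dbar`,
#'   `s`, `d`, `q`, `direction` (`up`/`down`/`none`), sorted by `|d|`
#'   descending; attributes `s0`, `delta`, `cutlow`, `cutup`, `n_permutations`.
#' @export
paired_sam <- function(cohort, settings = sam_settings()) {
  stopifnot(inherits(cohort, "paired_cohort"))
  z <- paired_differences(cohort)
  n <- ncol(z)
  if (n < 3L)
    stop("insufficient data: paired SAM needs at least 3 tumor/normal pairs")
  if (any(!is.finite(z)))
    stop("non-finite paired differences")

  dbar <- rowMeans(z)
  ssq <- rowSums(z^2)
  ss <- pmax(ssq - n * dbar^2, 0)
  s <- sqrt(ss / (n * (n - 1)))

  s0 <- if (identical(settings$s0_rule, "tusher_cv")) {
    sam_s0(dbar, s)
  } else {
    p <- as.numeric(sub("^percentile:", "", settings$s0_rule))
    stats::quantile(s, p / 100, names = FALSE, type = 7)
  }
  if (s0 == 0 && any(s == 0 & dbar != 0))
    stop("degenerate scale: zero-variance feature with nonzero effect and s0 = 0")

  d <- sam_d(dbar, s, s0)

  S <- sign_flip_matrix(n, settings$n_permutations, settings$seed)
  B <- ncol(S)
  dbar_b <- (z %*% S) / n
  ss_b <- pmax(ssq - n * dbar_b^2, 0)
  s_b <- sqrt(ss_b / (n * (n - 1)))
  d_b <- sam_d(dbar_b, s_b, s0)

  ds <- sort(d)
  dbar_exp <- rowMeans(apply(d_b, 2L, sort))
  diff_os <- ds - dbar_exp

  grid <- settings$delta_grid
  if (is.null(grid)) {
    grid <- stats::quantile(abs(d), seq(0, 1, length.out = 50),
                            names = FALSE, type = 7)
    grid <- sort(unique(grid))
  } else {
    grid <- sort(unique(grid))
  }

  eval_delta <- function(delta) {
    up_ok <- diff_os >= delta & ds >= 0
    lo_ok <- diff_os <= -delta & ds <= 0
    cutup <- if (any(up_ok)) min(ds[up_ok]) else Inf
    cutlow <- if (any(lo_ok)) max(ds[lo_ok]) else -Inf
    called <- d >= cutup | d <= cutlow
    n_called <- sum(called)
    if (n_called == 0L) {
      list(fdr = 0, n_called = 0L, called = called,
           cutup = cutup, cutlow = cutlow)
    } else {
      false_b <- colSums(d_b >= cutup | d_b <= cutlow)
      fdr <- min(stats::median(false_b) / n_called, 1)
      list(fdr = fdr, n_called = n_called, called = called,
           cutup = cutup, cutlow = cutlow)
    }
  }

  evals <- lapply(grid, eval_delta)
  fdrs <- vapply(evals, `[[`, numeric(1), "fdr")
  ncalls <- vapply(evals, `[[`, integer(1), "n_called")

  ok <- fdrs <= settings$fdr_target
  if (any(ok)) {
    best <- which(ok)[which.max(ncalls[ok])]
  } else {
    best <- which.min(ncalls)  # most conservative Delta
  }
  chosen <- evals[[best]]
  called <- if (any(ok)) chosen$called else rep(FALSE, length(d))

  # per-feature q: smallest estimated FDR over grid thresholds at which the
  # feature enters the call set (1 when never called)
  q <- rep(1, length(d))
  for (i in seq_along(evals)) {
    ci <- evals[[i]]$called
    if (any(ci)) q[ci] <- pmin(q[ci], fdrs[i])
  }

  direction <- rep("none", length(d))
  direction[called & d > 0] <- "up"
  direction[called & d < 0] <- "down"

  out <- data.frame(feature = rownames(z), dbar = dbar, s = s, d = d, q = q,
                    direction = direction, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[order(-abs(out$d), out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "s0") <- s0
  attr(out, "delta") <- grid[best]
  attr(out, "cutup") <- chosen$cutup
  attr(out, "cutlow") <- chosen$cutlow
  attr(out, "n_permutations") <- B
  class(out) <- c("sam_result", "data.frame")
  out
}

#' Select the top-k up- and down-regulated miRNAs
#'
#' Picks the `k_up` called-up features with largest d and the `k_down`
#' called-down features with smallest (most negative) d, mirroring the
#' selection of the most highly dysregulated miRNAs for downstream target
#' analysis. Ties in d are broken by larger `|dbar|`, then lexicographic id.
#'
#' @param records A `sam_result` from [paired_sam()] on a miRNA cohort.
#' @param k_up,k_down Numbers of up/down features to select.
#' @return List with character vectors `up` and `down` and logical
#'   `incomplete` (TRUE when fewer called features were available than
#'   requested; a warning is also raised).
#' @export
top_k_mirnas <- function(records, k_up, k_down) {
  stopifnot(is.data.frame(records))
  pick <- function(df, k, decreasing) {
    if (k == 0L || nrow(df) == 0L) return(character(0))
    ord <- order(if (decreasing) -df$d else df$d, -abs(df$dbar), df$feature)
    df$feature[ord][seq_len(min(k, nrow(df)))]
  }
  ups <- records[records$direction == "up", , drop = FALSE]
  downs <- records[records$direction == "down", , drop = FALSE]
  up <- pick(ups, k_up, decreasing = TRUE)
  down <- pick(downs, k_down, decreasing = FALSE)
  incomplete <- length(up) < k_up || length(down) < k_down
  if (incomplete)
    warning(sprintf("fewer called miRNAs than requested (up %d/%d, down %d/%d)",
                    length(up), k_up, length(down), k_down))
  list(up = up, down = down, incomplete = incomplete)
}
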