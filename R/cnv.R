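#' Settings for aCGH segment calling
#'
#' The three calling criteria: a minimum run of consecutive probes pointing
#' in the same direction, a minimum average fold difference between test and
#' reference DNA, and a minimum aberration score (an ADM-style
#' `|mean log2| * sqrt(n) / sigma` statistic), plus the moving-average window
#' used to seed candidate regions.
#'
#' @param min_probes Minimum consecutive probes in a call (default 10).
#' @param min_fold Minimum average linear fold difference (default 1.5,
#'   i.e. `|mean log2| >= log2(1.5)`).
#' @param score_threshold Minimum aberration score (default 6.0).
#' @param window_bp Moving-average window in bp (default 1e6, 1 Mb).
#' @return List of class `cnv_settings`.
#' @export
cnv_settings <- function(min_probes = 10L, min_fold = 1.5,
                         score_threshold = 6.0, window_bp = 1e6) {
  if (min_probes < 2) stop_config("min_probes", "must be >= 2")
  if (min_fold <= 1) stop_config("min_fold", "must be > 1")
  if (window_bp <= 0) stop_config("window_bp", "must be positive")
  if (score_threshold <= 0) stop_config("score_threshold", "must be positive")
  structure(list(min_probes = as.integer(min_probes), min_fold = min_fold,
                 score_threshold = score_threshold, window_bp = window_bp),
            class = "cnv_settings")
}

validate_probe_track <- function(track) {
  need <- c("chrom", "start", "end", "log2ratio")
  if (!all(need %in% names(track)))
    stop("probe track needs columns chrom, start, end, log2ratio")
  if (any(track$start < 0)) stop("negative probe coordinates")
  if (any(track$end <= track$start)) stop("probe end must exceed start")
  for (ch in unique(track$chrom)) {
    p <- track[track$chrom == ch, , drop = FALSE]
    if (is.unsorted(p$start, strictly = TRUE))
      stop("probe track not sorted by (chrom, start): ", ch)
    if (nrow(p) > 1L && any(p$start[-1L] < p$end[-nrow(p)]))
      stop("overlapping probes on ", ch)
  }
  invisible(track)
}

#' Robust probe-level noise estimate for an aCGH track
#'
#' `sigma = 1.4826 * median(|first differences of log2 ratio|) / sqrt(2)`,
#' the MAD of lag-1 differences rescaled to the per-probe standard deviation.
#' Differences are taken within chromosomes only. Insensitive to the (sparse)
#' true aberration signal because a copy-number step contributes only two
#' large differences per segment.
#'
#' @param track Data frame with columns `chrom`, `start`, `end`,
#'   `log2ratio`, sorted by (chrom, start); at least 20 probes.
#' @return Positive noise estimate in log2 units.
#' @export
noise_sigma <- function(track) {
  validate_probe_track(track)
  if (nrow(track) < 20L) stop("noise_sigma needs at least 20 probes")
  d <- unlist(lapply(split(track$log2ratio, track$chrom), diff),
              use.names = FALSE)
  med <- stats::median(abs(d))
  if (med == 0)
    stop("degenerate noise: probe track is (locally) constant")
  1.4826 * med / sqrt(2)
}

# moving average of v over a centered bp window, two-pointer over sorted
# probe midpoints; returns means and window counts
moving_average_bp <- function(mid, v, window_bp) {
  n <- length(v)
  half <- window_bp / 2
  cs <- c(0, cumsum(v))
  lo <- findInterval(mid - half, mid, left.open = TRUE) + 1L
  hi <- findInterval(mid + half, mid)
  cnt <- hi - lo + 1L
  list(mean = (cs[hi + 1L] - cs[lo]) / cnt, count = cnt)
}

# contiguous sub-run maximizing the interval score |sum(v)| / sqrt(n): the
# aberration-score-optimal interval inside a candidate same-sign run. This
# pins segment boundaries at the true copy-number breakpoints: a probe is
# worth including only when its magnitude is about half the running mean or
# more, so weak noise probes at the run edges are shed.
max_score_subrun <- function(v) {
  n <- length(v)
  cs <- c(0, cumsum(abs(v)))
  best <- c(1L, n); best_score <- -Inf
  for (i in seq_len(n)) {
    w <- i:n
    sc <- (cs[w + 1L] - cs[i]) / sqrt(w - i + 1)
    j <- which.max(sc)
    if (sc[j] > best_score) {
      best_score <- sc[j]
      best <- c(i, w[j])
    }
  }
  best
}

segment_stats <- function(probes, sigma) {
  m <- mean(probes$log2ratio)
  n <- nrow(probes)
  list(n_probes = n, mean_log2 = m, score = abs(m) * sqrt(n) / sigma)
}

passes_criteria <- function(st, settings) {
  st$n_probes >= settings$min_probes &&
    abs(st$mean_log2) >= log2(settings$min_fold) &&
    st$score >= settings$score_threshold
}

#' Call copy-number loss/gain segments from an aCGH probe track
#'
#' Candidate regions are seeded where the moving average of the log2 ratio
#' over a `window_bp` window exceeds `2 sigma / sqrt(m)` (m probes in the
#' window), then grown to the maximal run of consecutive probes that share
#' the candidate's sign and are individually noise-significant
#' (`|log2 ratio| > 2 sigma`), then trimmed to the contiguous sub-run
#' maximizing the interval score `|sum| / sqrt(n)` so that boundaries land
#' on true breakpoints rather than stray noise probes.
#' A run is kept only when all three criteria
#' hold: at least `min_probes` consecutive probes, average fold
#' `|mean log2| >= log2(min_fold)`, and aberration score
#' `|mean| sqrt(n) / sigma >= score_threshold`. Kept runs of the same
#' direction separated by fewer than 2 probes are merged (and re-checked).
#'
#' @param track Sorted probe data frame (`chrom`, `start`, `end`,
#'   `log2ratio`).
#' @param settings A [cnv_settings()].
#' @param sigma Optional noise level; estimated by [noise_sigma()] when NULL.
#' @return Data frame of class `cnv_segments`: `chrom`, `start`, `end`,
#'   `direction` (`loss`/`gain`), `n_probes`, `mean_log2`, `score`, sorted by
#'   (chrom, start); attribute `sigma`.
#' @export
call_segments <- function(track, settings = cnv_settings(), sigma = NULL) {
  validate_probe_track(track)
  stopifnot(inherits(settings, "cnv_settings"))
  if (is.null(sigma)) sigma <- noise_sigma(track)

  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      n_probes = integer(0), mean_log2 = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  out <- list()

  for (ch in unique(track$chrom)) {
    p <- track[track$chrom == ch, , drop = FALSE]
    v <- p$log2ratio
    mid <- (p$start + p$end) / 2
    ma <- moving_average_bp(mid, v, settings$window_bp)
    seed_dir <- ifelse(abs(ma$mean) > 2 * sigma / sqrt(ma$count),
                       sign(ma$mean), 0)

    for (dir in c(-1, 1)) {
      qual <- sign(v) == dir & abs(v) > 2 * sigma
      r <- rle(qual)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      kept <- list()
      for (ri in runs) {
        i0 <- starts[ri]; i1 <- ends[ri]
        if (!any(seed_dir[i0:i1] == dir)) next
        sub <- max_score_subrun(v[i0:i1])
        i1 <- i0 + sub[2L] - 1L; i0 <- i0 + sub[1L] - 1L
        st <- segment_stats(p[i0:i1, , drop = FALSE], sigma)
        if (passes_criteria(st, settings))
          kept[[length(kept) + 1L]] <- c(i0 = i0, i1 = i1)
      }
      if (!length(kept)) next
      # merge kept runs separated by < 2 probes, re-check criteria
      merged <- list(kept[[1L]])
      for (kr in kept[-1L]) {
        last <- merged[[length(merged)]]
        if (kr["i0"] - last["i1"] - 1L < 2L) {
          cand <- c(i0 = unname(last["i0"]), i1 = unname(kr["i1"]))
          st <- segment_stats(p[cand["i0"]:cand["i1"], , drop = FALSE], sigma)
          if (passes_criteria(st, settings)) {
            merged[[length(merged)]] <- cand
            next
          }
        }
        merged[[length(merged) + 1L]] <- kr
      }
      for (mr in merged) {
        idx <- mr["i0"]:mr["i1"]
        st <- segment_stats(p[idx, , drop = FALSE], sigma)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = p$start[mr["i0"]], end = p$end[mr["i1"]],
          direction = if (dir < 0) "loss" else "gain",
          n_probes = st$n_probes, mean_log2 = st$mean_log2, score = st$score,
          stringsAsFactors = FALSE)
      }
    }
  }

  res <- if (length(out)) do.call(rbind, out) else empty
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "sigma") <- sigma
  class(res) <- c("cnv_segments", "data.frame")
  res
}

#' Annotate CNV segments with overlapping miRNA loci
#'
#' A miRNA is assigned to a segment when their intervals share at least one
#' base under 0-based half-open semantics.
#'
#' @param segments Data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param loci Data frame of miRNA loci with `name`, `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [read_bed()].
#' @return Character list, one element per segment row, of overlapping miRNA
#'   names (possibly empty).
#' @export
annotate_mirnas <- function(segments, loci) {
  stopifnot(all(c("chrom", "start", "end") %in% names(segments)),
            all(c("name", "chrom", "start", "end") %in% names(loci)))
  if (nrow(segments) == 0L) return(list())
  if (nrow(loci) == 0L) return(rep(list(character(0)), nrow(segments)))
  if (length(intersect(unique(segments$chrom), unique(loci$chrom))) == 0L)
    warning("no shared chromosome names; unmatched locus chroms: ",
            paste(sort(unique(loci$chrom)), collapse = ", "))
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom, IRanges::IRanges(segments$start + 1, segments$end))
  loc_gr <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(loci$start + 1, loci$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(seg_gr, loc_gr, minoverlap = 1L))
  res <- rep(list(character(0)), nrow(segments))
  for (qi in unique(S4Vectors::queryHits(hits))) {
    res[[qi]] <- sort(loci$name[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == qi]])
  }
  res
}

#' Minimal common regions of loss across patients
#'
#' Sweep-line computation of the maximal genomic intervals covered by loss
#' segments from at least `min_patients` distinct patients — the
#' deletion-overlap regions shared by multiple tumors.
#'
#' @param per_patient_segments Named list, one element per patient, each a
#'   segment data frame (`chrom`, `start`, `end`, optionally `direction`;
#'   when `direction` is present only `"loss"` rows are used).
#' @param min_patients Minimum number of patients required (>= 2 patients
#'   must be supplied).
#' @return Data frame `chrom`, `start`, `end`, `n_patients`, `patients`
#'   (comma-joined sorted ids of patients whose loss segments overlap the
#'   region), sorted and non-overlapping.
#' @export
common_regions <- function(per_patient_segments, min_patients = 2L) {
  stopifnot(is.list(per_patient_segments))
  if (length(per_patient_segments) < 2L)
    stop("common_regions needs segments from at least 2 patients")
  if (is.null(names(per_patient_segments)))
    names(per_patient_segments) <- paste0("patient", seq_along(per_patient_segments))

  # per patient: keep loss rows, merge that patient's own overlapping runs
  cov <- list()
  for (pid in names(per_patient_segments)) {
    seg <- per_patient_segments[[pid]]
    if (is.null(seg) || nrow(seg) == 0L) next
    if ("direction" %in% names(seg))
      seg <- seg[seg$direction == "loss", , drop = FALSE]
    if (nrow(seg) == 0L) next
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      seg$chrom, IRanges::IRanges(seg$start + 1, seg$end)))
    cov[[pid]] <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                             start = GenomicRanges::start(gr) - 1,
                             end = GenomicRanges::end(gr), patient = pid,
                             stringsAsFactors = FALSE)
  }
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_patients = integer(0),
                      patients = character(0), stringsAsFactors = FALSE)
  if (!length(cov)) return(empty)
  allseg <- do.call(rbind, cov)

  out <- list()
  for (ch in sort(unique(allseg$chrom))) {
    s <- allseg[allseg$chrom == ch, , drop = FALSE]
    bp <- sort(unique(c(s$start, s$end)))
    if (length(bp) < 2L) next
    keep_lo <- numeric(0); keep_hi <- numeric(0)
    for (i in seq_len(length(bp) - 1L)) {
      lo <- bp[i]; hi <- bp[i + 1L]
      n_cov <- length(unique(s$patient[s$start <= lo & s$end >= hi]))
      if (n_cov >= min_patients) {
        if (length(keep_lo) && keep_hi[length(keep_hi)] == lo) {
          keep_hi[length(keep_hi)] <- hi
        } else {
          keep_lo <- c(keep_lo, lo); keep_hi <- c(keep_hi, hi)
        }
      }
    }
    for (i in seq_along(keep_lo)) {
      pats <- sort(unique(s$patient[s$start < keep_hi[i] & s$end > keep_lo[i]]))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = keep_lo[i], end = keep_hi[i],
        n_patients = length(pats),
        patients = paste(pats, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
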