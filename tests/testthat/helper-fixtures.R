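# Shared builders and independent oracles used across the suite.

# paired cohort whose per-case differences equal the given matrix `z`
# (normal samples all zero, tumor samples = z)
diff_cohort <- function(z, feature_kind = "mrna") {
  n <- ncol(z)
  if (is.null(rownames(z))) rownames(z) <- sprintf("f%03d", seq_len(nrow(z)))
  cases <- sprintf("c%02d", seq_len(n))
  m <- cbind(z, matrix(0, nrow(z), n))
  colnames(m) <- c(paste0(cases, "_T"), paste0(cases, "_N"))
  pairing <- data.frame(case_id = cases, tumor = paste0(cases, "_T"),
                        normal = paste0(cases, "_N"),
                        stringsAsFactors = FALSE)
  paired_cohort(m, pairing, feature_kind)
}

# probe track from a vector of log2 ratios at fixed spacing
make_track <- function(values, spacing = 50000, chrom = "chr1", probe_len = 60) {
  start <- (seq_along(values) - 1) * spacing
  data.frame(chrom = chrom, start = start, end = start + probe_len,
             log2ratio = values, stringsAsFactors = FALSE)
}

# alternating +/-eps flank noise (deterministic, known noise_sigma)
alternating <- function(n, eps) rep(c(eps, -eps), length.out = n)

# exact hypergeometric upper tail by exhaustive enumeration of all
# n-subsets of a population of N labelled genes, K of them "special"
enum_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)  # genes 1..K are the special ones
  mean(overlaps >= k)
}

# brute-force all-pairs interval overlap (0-based half-open)
overlap_scan <- function(segments, loci) {
  lapply(seq_len(nrow(segments)), function(i) {
    hit <- loci$chrom == segments$chrom[i] &
      loci$start < segments$end[i] & loci$end > segments$start[i]
    sort(loci$name[hit])
  })
}

# brute-force per-coordinate coverage count for common regions
# (integer coordinates, small tracks only)
brute_common <- function(per_patient_segments, min_patients, max_bp) {
  chroms <- unique(unlist(lapply(per_patient_segments, function(s) s$chrom)))
  out <- list()
  for (ch in sort(chroms)) {
    cov <- matrix(FALSE, length(per_patient_segments), max_bp)
    for (pi in seq_along(per_patient_segments)) {
      s <- per_patient_segments[[pi]]
      if ("direction" %in% names(s)) s <- s[s$direction == "loss", , drop = FALSE]
      s <- s[s$chrom == ch, , drop = FALSE]
      for (ri in seq_len(nrow(s)))
        if (s$end[ri] > s$start[ri])
          cov[pi, (s$start[ri] + 1):s$end[ri]] <- TRUE
    }
    qual <- colSums(cov) >= min_patients
    r <- rle(qual)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (ri in which(r$values))
      out[[length(out) + 1]] <- data.frame(chrom = ch,
                                           start = starts[ri] - 1,
                                           end = ends[ri])
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  do.call(rbind, out)
}

# independent re-check of the three calling criteria on an emitted segment
segment_meets_criteria <- function(seg, track, sigma, settings) {
  p <- track[track$chrom == seg$chrom &
               track$start >= seg$start & track$end <= seg$end, , drop = FALSE]
  m <- mean(p$log2ratio)
  nrow(p) >= settings$min_probes &&
    abs(m) >= log2(settings$min_fold) &&
    abs(m) * sqrt(nrow(p)) / sigma >= settings$score_threshold &&
    all(sign(p$log2ratio) == sign(m))
}

# small, fast synthetic configuration for expression-level tests
small_synth <- function(seed, ...) {
  synth_config(n_pairs = 6L, n_genes = 300L, n_mirnas = 30L,
               n_up_mirnas = 3L, n_down_mirnas = 3L,
               targets_per_mirna = 8L, deletion_specs = list(),
               seed = seed, ...)
}
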