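test_that("noise estimate follows its closed form and concentrates", {
  tr <- make_track(alternating(100, 0.1))
  expect_equal(noise_sigma(tr), 1.4826 * 0.2 / sqrt(2), tolerance = 1e-12)
  set.seed(61)
  tr2 <- make_track(rnorm(10000, 0, 0.2))
  expect_lt(abs(noise_sigma(tr2) - 0.2) / 0.2, 0.05)
  expect_error(noise_sigma(make_track(rep(0.3, 50))), "degenerate")
  expect_error(noise_sigma(make_track(alternating(10, 0.1))), "at least 20")
  bad <- make_track(alternating(30, 0.1)); bad$start[2] <- 0
  expect_error(noise_sigma(bad), "sorted|overlap")
})

test_that("a 15-probe deletion passes all three criteria and is called exactly", {
  v <- c(alternating(30, 0.1), rep(-1, 15), alternating(30, 0.1))
  tr <- make_track(v)
  segs <- call_segments(tr)
  sigma <- attr(segs, "sigma")
  expect_equal(sigma, 1.4826 * 0.2 / sqrt(2), tolerance = 1e-12)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$direction, "loss")
  expect_identical(segs$n_probes, 15L)
  expect_equal(segs$mean_log2, -1)            # mean fold 2.0 >= 1.5
  expect_equal(segs$score, sqrt(15) / sigma)  # ~18.5 >> 6
  expect_equal(segs$start, 30 * 50000)        # exact probe boundaries
  expect_equal(segs$end, 44 * 50000 + 60)
})

test_that("sub-threshold events fail their respective criteria and are not called", {
  # 9 consecutive probes: fails the 10-probe rule
  tr9 <- make_track(c(alternating(30, 0.1), rep(-1, 9), alternating(30, 0.1)))
  expect_identical(nrow(call_segments(tr9)), 0L)
  # 12 probes at -0.3 (fold 1.23 < 1.5): fails the fold rule even though the
  # probe count and score criteria pass at this noise level
  tr12 <- make_track(c(alternating(30, 0.05), rep(-0.3, 12),
                       alternating(30, 0.05)))
  sig12 <- noise_sigma(tr12)
  expect_gt(0.3, 2 * sig12)                       # probes are significant
  expect_gt(0.3 * sqrt(12) / sig12, 6)            # score criterion passes
  expect_lt(0.3, log2(1.5))                       # fold criterion fails
  expect_identical(nrow(call_segments(tr12)), 0L)
  # an all-noise track yields nothing
  set.seed(77)
  expect_identical(nrow(call_segments(make_track(rnorm(200, 0, 0.1)))), 0L)
})

test_that("negating all log ratios swaps loss and gain and nothing else", {
  set.seed(83)
  v <- rnorm(300, 0, 0.1)
  v[100:119] <- v[100:119] - 1
  v[200:214] <- v[200:214] + 1
  tr <- make_track(v)
  s1 <- call_segments(tr)
  tr2 <- tr; tr2$log2ratio <- -tr2$log2ratio
  s2 <- call_segments(tr2)
  expect_identical(nrow(s1), 2L)
  expect_identical(s2$start, s1$start)
  expect_identical(s2$end, s1$end)
  expect_identical(s2$n_probes, s1$n_probes)
  expect_equal(s2$mean_log2, -s1$mean_log2)
  expect_equal(s2$score, s1$score)
  expect_identical(s2$direction, c("gain", "loss")[match(s1$direction,
                                                         c("loss", "gain"))])
})

test_that("embedded deletions are recovered within one probe spacing", {
  settings <- cnv_settings()
  for (seed in 1:10) {
    specs <- list(
      list(chrom = "chr1", start = 1e6, length_bp = 8e6, log2_ratio = -1,
           patients = 1L),
      list(chrom = "chr2", start = 5e6, length_bp = 1e6, log2_ratio = -1,
           patients = 1L),
      # sub-threshold: 9 probes at -1 and 20 probes at fold 1.2
      list(chrom = "chr3", start = 2e6, length_bp = 45e4, log2_ratio = -1,
           patients = 1L),
      list(chrom = "chr3", start = 10e6, length_bp = 1e6,
           log2_ratio = -log2(1.2), patients = 1L))
    co <- generate_cohort(synth_config(
      n_pairs = 1L, n_genes = 20L, n_mirnas = 6L, n_up_mirnas = 1L,
      n_down_mirnas = 1L, targets_per_mirna = 2L,
      deletion_specs = specs, seed = seed))
    tr <- co$probes$case01
    segs <- call_segments(tr, settings)
    sigma <- attr(segs, "sigma")
    # the two real deletions, and only those, are called
    expect_identical(nrow(segs), 2L)
    expect_identical(segs$direction, c("loss", "loss"))
    spacing <- 50000
    for (i in 1:2) {
      truth <- specs[[i]]
      expect_identical(segs$chrom[i], truth$chrom)
      expect_lte(abs(segs$start[i] - truth$start), spacing)
      expect_lte(abs(segs$end[i] - (truth$start + truth$length_bp)), spacing)
    }
    # independent post-hoc check: every emitted segment meets all criteria
    for (i in seq_len(nrow(segs)))
      expect_true(segment_meets_criteria(segs[i, ], tr, sigma, settings))
  }
})

test_that("miRNA loci annotate segments exactly as a brute-force scan", {
  segs <- data.frame(chrom = "chr1", start = 0, end = 1000)
  loci <- data.frame(name = c("miR-in", "miR-out"), chrom = "chr1",
                     start = c(100, 1000), end = c(200, 1100),
                     stringsAsFactors = FALSE)
  ann <- annotate_mirnas(segs, loci)
  expect_identical(ann[[1]], "miR-in")   # [1000,1100) misses [0,1000)

  set.seed(29)
  rs <- data.frame(chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                   start = sample.int(5000, 30))
  rs$end <- rs$start + sample.int(800, 30)
  rl <- data.frame(name = sprintf("miR-%03d", 1:100),
                   chrom = sample(c("chr1", "chr2"), 100, replace = TRUE),
                   start = sample.int(5500, 100), stringsAsFactors = FALSE)
  rl$end <- rl$start + sample.int(200, 100)
  expect_identical(annotate_mirnas(rs, rl), overlap_scan(rs, rl))

  other <- data.frame(name = "miR-x", chrom = "1", start = 10, end = 20)
  expect_warning(annotate_mirnas(segs, other), "chromosome")
})

test_that("common regions match the paper-style containment and a brute force", {
  # containment: one large loss and one fully contained loss share the
  # smaller interval (the 38.66 Mb / 7.09 Mb chr1 structure)
  segs <- list(X = data.frame(chrom = "chr1", start = 0, end = 38.66e6,
                              direction = "loss"),
               Y = data.frame(chrom = "chr1", start = 0, end = 7.09e6,
                              direction = "loss"))
  cr <- common_regions(segs, 2L)
  expect_identical(nrow(cr), 1L)
  expect_equal(cr$end - cr$start, 7.09e6)
  expect_identical(cr$patients, "X,Y")

  # disjoint segments share nothing
  dj <- list(a = data.frame(chrom = "chr1", start = 0, end = 100),
             b = data.frame(chrom = "chr1", start = 200, end = 300))
  expect_identical(nrow(common_regions(dj, 2L)), 0L)

  # three tiling patients, full agreement required
  t3 <- list(p1 = data.frame(chrom = "chr1", start = 0, end = 10),
             p2 = data.frame(chrom = "chr1", start = 5, end = 15),
             p3 = data.frame(chrom = "chr1", start = 8, end = 12))
  cr3 <- common_regions(t3, 3L)
  expect_equal(cr3[, c("start", "end")], data.frame(start = 8, end = 10))

  # random small tracks against a per-coordinate coverage count
  set.seed(47)
  for (rep in 1:5) {
    pats <- lapply(1:4, function(i) {
      k <- sample(1:4, 1)
      st <- sort(sample.int(9.5e4, k))
      data.frame(chrom = "chr1", start = st,
                 end = pmin(st + sample.int(2e4, k), 1e5),
                 direction = "loss")
    })
    names(pats) <- paste0("p", 1:4)
    for (mp in 2:3) {
      got <- common_regions(pats, mp)
      want <- brute_common(pats, mp, 1e5)
      expect_equal(got[, c("chrom", "start", "end")],
                   want, tolerance = 1e-12,
                   label = sprintf("rep %d min_patients %d", rep, mp))
    }
  }
  expect_error(common_regions(list(a = NULL), 2L), "at least 2")
})
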