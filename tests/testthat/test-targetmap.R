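test_that("consensus requires support from both prediction sources", {
  tab <- data.frame(mirna = c("m1", "m1", "m2"),
                    gene = c("gA", "gB", "gB"),
                    source = c("P1", "P1", "P2"), score = 1,
                    stringsAsFactors = FALSE)
  expect_identical(consensus_targets(tab[1, ], "m1"), character(0))
  expect_identical(consensus_targets(tab, c("m1", "m2")), "gB")
  expect_warning(consensus_targets(tab, c("m1", "mX")), "mX")
})

test_that("consensus precision beats either single predictor", {
  for (seed in c(2L, 12L, 22L)) {
    co <- generate_cohort(synth_config(seed = seed))
    up <- co$truth$up_mirnas
    truth <- unique(unlist(co$truth$true_targets[up]))
    sel <- co$predictions[co$predictions$mirna %in% up, ]
    g1 <- unique(sel$gene[sel$source == "P1"])
    g2 <- unique(sel$gene[sel$source == "P2"])
    cons <- consensus_targets(co$predictions, up)
    prec <- function(g) mean(g %in% truth)
    expect_gt(prec(cons), prec(g1))
    expect_gt(prec(cons), prec(g2))
  }
})

test_that("inverse sets intersect consensus targets with opposing calls", {
  de <- data.frame(feature = c("A", "B", "C", "D", "E"),
                   direction = c("up", "down", "down", "down", "up"),
                   stringsAsFactors = FALSE)
  tc <- inverse_sets(c("A", "B", "C"), c("E", "Z"), de)
  expect_identical(tc$inverse_up, c("B", "C"))
  expect_identical(tc$inverse_down, "E")
  # empty DE list leaves both inverse sets empty
  de0 <- de[0, ]
  tc0 <- inverse_sets(c("A", "B"), c("E"), de0)
  expect_length(tc0$inverse_up, 0)
  expect_length(tc0$inverse_down, 0)
  # a gene in both inverse sets is retained in both and flagged
  de2 <- data.frame(feature = c("X", "Y"), direction = c("up", "down"))
  tc2 <- inverse_sets(c("X", "Y"), c("X", "Y"), de2)
  expect_identical(tc2$inverse_up, "Y")
  expect_identical(tc2$inverse_down, "X")
})

test_that("repressed targets of up-miRNAs are recovered through the pipeline", {
  co <- generate_cohort(synth_config(seed = 4L))
  de_mir <- paired_sam(co$mirna)
  tk <- top_k_mirnas(de_mir, 5L, 5L)
  de <- paired_sam(co$mrna)
  tc <- inverse_sets(consensus_targets(co$predictions, tk$up),
                     consensus_targets(co$predictions, tk$down), de)
  truth_up <- unique(unlist(co$truth$true_targets[co$truth$up_mirnas]))
  # recovery is assessed on the targets the predictors can expose: a true
  # target absent from both predictor tables can never reach the inverse set
  reachable <- intersect(truth_up, consensus_targets(co$predictions, tk$up))
  expect_gte(mean(reachable %in% tc$inverse_up), 0.8)
  # and the predictors expose the expected share (~ sensitivity^2 or more)
  expect_gte(length(reachable) / length(truth_up), 0.45)
})

test_that("coverage percentage follows the union-over-dysregulated formula", {
  tc <- list(inverse_up = sprintf("d%03d", 1:249),
             inverse_down = sprintf("u%03d", 1:97))
  expect_equal(coverage_percent(tc, 2674), 100 * 346 / 2674)
  expect_identical(round(coverage_percent(tc, 2674)), 13)
  expect_equal(coverage_percent(list(inverse_up = character(0),
                                     inverse_down = character(0)), 10), 0)
  all_genes <- sprintf("g%02d", 1:50)
  expect_equal(coverage_percent(list(inverse_up = all_genes,
                                     inverse_down = character(0)), 50), 100)
  expect_error(coverage_percent(tc, 0), "positive")
  # invariant: equals (|A| + |B| - |A inter B|) / n * 100, relabeling-proof
  set.seed(5)
  for (i in 1:5) {
    A <- sample(letters, 8); B <- sample(letters, 6)
    got <- coverage_percent(list(inverse_up = A, inverse_down = B), 26)
    expect_equal(got, 100 * (length(A) + length(B) -
                               length(intersect(A, B))) / 26)
  }
})

test_that("hypergeometric tail matches exhaustive enumeration for N <= 12", {
  for (N in c(4L, 7L, 10L, 12L)) {
    for (K in 0:N) {
      for (n in 0:N) {
        ks <- max(0, n - (N - K)):min(K, n)
        for (k in ks) {
          got <- enrichment_test(N, K, n, k)$p
          expect_equal(got, enum_hyper_tail(N, K, n, k), tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
  expect_equal(enrichment_test(10, 5, 4, 4)$p, 5 / 210, tolerance = 1e-12)
  expect_equal(enrichment_test(100, 30, 10, 0)$p, 1)
  expect_equal(enrichment_test(20, 8, 20, 8)$p, 1)  # n = N forces k = K
  expect_error(enrichment_test(10, 5, 4, 5), "k")
  expect_error(enrichment_test(10, 12, 4, 2), "exceed")
  # cross-check the log-space sum against the distribution in stats
  expect_equal(enrichment_test(2000, 300, 150, 40)$p,
               phyper(39, 300, 1700, 150, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("enrichment p-values are super-uniform on null overlaps", {
  set.seed(73)
  N <- 2000; K <- 300; n <- 150
  p <- replicate(200, {
    k <- sum(sample.int(N, n) <= K)  # random target set vs fixed DE set
    enrichment_test(N, K, n, k)$p
  })
  expect_lte(mean(p <= 0.05), 0.075)
})

test_that("pair correlation matches hand arithmetic and its invariances", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pair_correlation(x, -x)$r, -1)
  expect_equal(pair_correlation(x, c(2, 1, 4, 3, 6))$r, 0.8220,
               tolerance = 1e-4)
  cc <- pair_correlation(x, rep(2, 5))
  expect_true(cc$undefined)
  expect_true(is.na(cc$r))
  expect_error(pair_correlation(x, 1:4), "mismatch")
  expect_error(pair_correlation(1:2, 2:1), "at least 3")
  # affine invariance and sign flip under negation
  set.seed(41)
  for (i in 1:5) {
    a <- rnorm(8); b <- rnorm(8)
    r0 <- pair_correlation(a, b)$r
    expect_equal(pair_correlation(2.5 * a + 7, b)$r, r0, tolerance = 1e-12)
    expect_equal(pair_correlation(a, 0.3 * b - 2)$r, r0, tolerance = 1e-12)
    expect_equal(pair_correlation(-a, b)$r, -r0, tolerance = 1e-12)
  }
})

test_that("box summaries give the five-number statistics", {
  b <- box_summary(c(1, 2, 3, 4, 5))
  expect_equal(unlist(b[c("min", "q1", "median", "q3", "max")]),
               c(min = 1, q1 = 2, median = 3, q3 = 4, max = 5))
  b1 <- box_summary(7.5)
  expect_true(all(unlist(b1) == 7.5))
  expect_error(box_summary(numeric(0)), "finite")
  set.seed(19)
  bn <- box_summary(rnorm(1000))
  expect_lt(abs(bn$median), 0.1)
  expect_true(bn$min <= bn$q1 && bn$q1 <= bn$median &&
                bn$median <= bn$q3 && bn$q3 <= bn$max)
})

test_that("correlation-distance clustering orders rows deterministically", {
  set.seed(55)
  base <- rnorm(10)
  m <- rbind(r1 = base + rnorm(10, sd = 0.01),
             r2 = rnorm(10), r3 = base + rnorm(10, sd = 0.01),
             r4 = rnorm(10))
  hc <- cluster_order(m, cluster_columns = FALSE)$row_hclust
  expect_equal(sort(abs(hc$merge[1, ])), c(1, 3))  # near-identical pair first

  # anticorrelated pair sits at distance 2; hand-computed 3-row linkage
  A <- c(-3, -1, 1, 3); C <- c(1, -1, -1, 1)
  m3 <- rbind(A = A, B = -A, C = C)
  hc3 <- cluster_order(m3, cluster_columns = FALSE)$row_hclust
  expect_equal(hc3$height, c(1, 1.5))  # cor(A,C)=0 -> d=1; avg(2,1)=1.5
  expect_true(3 %in% abs(hc3$merge[1, ]))  # C joins a zero-cor partner first

  # permuting input rows leaves the dendrogram topology unchanged
  mm <- rbind(m, r5 = base * -1 + rnorm(10, sd = 0.01))
  perm <- c(4, 2, 5, 1, 3)
  h1 <- cluster_order(mm, cluster_columns = FALSE)$row_hclust
  h2 <- cluster_order(mm[perm, ], cluster_columns = FALSE)$row_hclust
  d1 <- as.matrix(cophenetic(h1))
  d2 <- as.matrix(cophenetic(h2))[rownames(mm), rownames(mm)]
  expect_equal(d1, d2, tolerance = 1e-12)

  # constant rows are pushed to maximal distance
  mc <- rbind(k1 = rep(1, 6), k2 = rnorm(6), k3 = rnorm(6))
  hck <- cluster_order(mc, cluster_columns = FALSE)$row_hclust
  expect_equal(max(hck$height), 2)
})
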