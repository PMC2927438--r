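#' Configuration for the synthetic paired-cohort generator
#'
#' Defines the statistical structure of a simulated tumor/normal study:
#' matched expression matrices for genes and miRNAs with a small set of
#' truly shifted miRNAs whose predicted targets are repressed in tumor,
#' two imperfect target-prediction tables, per-patient aCGH probe tracks
#' with embedded deletions over miRNA loci, and ordinal IHC scores coupled
#' to marker-gene mRNA.
#'
#' Defaults describe the reference simulation used throughout the package:
#' 10 tumor/normal pairs, 2000 genes, 200 miRNAs, 5 up- and 5 down-shifted
#' miRNAs of mean |log2 shift| 2 with 10 disjoint true targets each (100
#' true differential genes, |shift| about 2), unit repression coupling,
#' log2 expression noise sd 0.5, predictors with sensitivity 0.8 and false
#' positive rate 0.01, 3 chromosomes of 500 probes at 50 kb spacing with
#' probe noise sd 0.1, heterozygous-deletion log2 ratio -1, and a 0-4
#' ordinal IHC scale.
#'
#' @param n_pairs Number of tumor/normal pairs.
#' @param n_genes,n_mirnas Feature counts.
#' @param n_up_mirnas,n_down_mirnas Counts of truly up-/down-shifted miRNAs.
#' @param mirna_effect Length-2 vector `c(mean, sd)` of the |log2 shift| of
#'   truly shifted miRNAs.
#' @param targets_per_mirna True targets per shifted miRNA (disjoint across
#'   miRNAs).
#' @param repression_beta Coupling: target log2 shift = `-beta * miRNA
#'   shift`.
#' @param noise_sd Gaussian log2 expression noise sd per sample.
#' @param predictor_sensitivity,predictor_fpr Per-source probability of
#'   reporting a true edge / a given false edge.
#' @param chroms Chromosome names of the synthetic genome.
#' @param n_probes_per_chrom,probe_spacing_bp aCGH track geometry.
#' @param probe_noise_sd Probe-level log2 ratio noise sd.
#' @param deletion_specs List of deletions, each
#'   `list(chrom, start, length_bp, log2_ratio, patients)` with `patients`
#'   a vector of case indices carrying the deletion.
#' @param n_markers Number of IHC markers (tied to true target genes).
#' @param ihc_levels Ordinal scale size (scores `0 .. ihc_levels - 1`).
#' @param seed Integer seed; the whole cohort derives from one stream.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_pairs = 10L, n_genes = 2000L, n_mirnas = 200L,
                         n_up_mirnas = 5L, n_down_mirnas = 5L,
                         mirna_effect = c(2, 0.25),
                         targets_per_mirna = 10L, repression_beta = 1,
                         noise_sd = 0.5,
                         predictor_sensitivity = 0.8, predictor_fpr = 0.01,
                         chroms = c("chr1", "chr2", "chr3"),
                         n_probes_per_chrom = 500L, probe_spacing_bp = 50000,
                         probe_noise_sd = 0.1,
                         deletion_specs = default_deletion_specs(),
                         n_markers = 4L, ihc_levels = 5L, seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs), n_genes = as.integer(n_genes),
              n_mirnas = as.integer(n_mirnas),
              n_up_mirnas = as.integer(n_up_mirnas),
              n_down_mirnas = as.integer(n_down_mirnas),
              mirna_effect = as.numeric(mirna_effect),
              targets_per_mirna = as.integer(targets_per_mirna),
              repression_beta = as.numeric(repression_beta),
              noise_sd = as.numeric(noise_sd),
              predictor_sensitivity = as.numeric(predictor_sensitivity),
              predictor_fpr = as.numeric(predictor_fpr),
              chroms = as.character(chroms),
              n_probes_per_chrom = as.integer(n_probes_per_chrom),
              probe_spacing_bp = as.numeric(probe_spacing_bp),
              probe_noise_sd = as.numeric(probe_noise_sd),
              deletion_specs = deletion_specs,
              n_markers = as.integer(n_markers),
              ihc_levels = as.integer(ihc_levels),
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

#' Default embedded deletions of the reference simulation
#'
#' Two overlapping chr1 deletions in different patients (a large one and a
#' contained smaller one, giving a known minimal common region) plus a
#' private chr2 deletion, all at heterozygous-loss log2 ratio -1.
#' @return List of deletion specs for [synth_config()].
#' @export
default_deletion_specs <- function() {
  list(
    list(chrom = "chr1", start = 1e6, length_bp = 8e6, log2_ratio = -1,
         patients = 1L),
    list(chrom = "chr1", start = 1e6, length_bp = 1.5e6, log2_ratio = -1,
         patients = 2L),
    list(chrom = "chr2", start = 5e6, length_bp = 1.5e6, log2_ratio = -1,
         patients = 3L)
  )
}

validate_synth_config <- function(cfg) {
  pos <- c("n_pairs", "n_genes", "n_mirnas", "targets_per_mirna",
           "n_probes_per_chrom", "probe_spacing_bp", "ihc_levels")
  for (f in pos) if (cfg[[f]] <= 0) stop_config(f, "must be a positive count")
  for (f in c("n_up_mirnas", "n_down_mirnas", "n_markers"))
    if (cfg[[f]] < 0) stop_config(f, "must be a non-negative count")
  if (cfg$n_up_mirnas + cfg$n_down_mirnas > cfg$n_mirnas)
    stop_config("n_up_mirnas", "shifted miRNAs exceed n_mirnas")
  if ((cfg$n_up_mirnas + cfg$n_down_mirnas) * cfg$targets_per_mirna >
      cfg$n_genes)
    stop_config("targets_per_mirna", "true targets exceed gene universe")
  if (length(cfg$mirna_effect) != 2L || cfg$mirna_effect[2] < 0)
    stop_config("mirna_effect", "must be c(mean, sd) with sd >= 0")
  if (cfg$noise_sd < 0) stop_config("noise_sd", "must be >= 0")
  if (cfg$probe_noise_sd < 0) stop_config("probe_noise_sd", "must be >= 0")
  for (f in c("predictor_sensitivity", "predictor_fpr")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_config(f, "must be a probability in [0,1]")
  }
  chrom_len <- cfg$n_probes_per_chrom * cfg$probe_spacing_bp
  for (ds in cfg$deletion_specs) {
    if (!all(c("chrom", "start", "length_bp", "log2_ratio", "patients") %in%
             names(ds)))
      stop_config("deletion_specs",
                  "each spec needs chrom, start, length_bp, log2_ratio, patients")
    if (!ds$chrom %in% cfg$chroms)
      stop_config("deletion_specs", paste0("unknown chrom ", ds$chrom))
    if (ds$start < 0 || ds$start + ds$length_bp > chrom_len)
      stop_config("deletion_specs", "deletion outside chromosome bounds")
    if (any(ds$patients < 1 | ds$patients > cfg$n_pairs))
      stop_config("deletion_specs", "patient index outside 1..n_pairs")
  }
  invisible(cfg)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic paired tumor/normal cohort with known ground truth
#'
#' Draws the full multi-omic bundle defined by a [synth_config()] from a
#' single seeded pseudo-random stream: paired log2 expression matrices for
#' genes and miRNAs (tumor values of true targets shifted by
#' `-beta * miRNA shift` before noise), two predictor edge tables, per-case
#' aCGH probe tracks with embedded deletions, miRNA genomic loci and ordinal
#' IHC scores, plus the generating ground truth. Identical configuration and
#' seed give bit-identical output; the caller's RNG state is untouched.
#'
#' @param config A [synth_config()].
#' @return List of class `synth_cohort`: `mrna`, `mirna` ([paired_cohort()]s),
#'   `predictions`, `probes` (named list of per-patient tracks),
#'   `mirna_loci`, `ihc`, `truth`, `config`.
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(config$seed)

  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  mirnas <- sprintf("miR-%03d", seq_len(config$n_mirnas))
  cases <- sprintf("case%02d", seq_len(config$n_pairs))
  tum <- paste0(cases, "_T"); nor <- paste0(cases, "_N")
  pairing <- data.frame(case_id = cases, tumor = tum, normal = nor,
                        stringsAsFactors = FALSE)

  # which miRNAs are truly shifted, and by how much
  n_shift <- config$n_up_mirnas + config$n_down_mirnas
  shifted <- if (n_shift > 0) sample(mirnas, n_shift) else character(0)
  up_mirnas <- shifted[seq_len(config$n_up_mirnas)]
  down_mirnas <- setdiff(shifted, up_mirnas)
  mags <- abs(stats::rnorm(n_shift, config$mirna_effect[1],
                           config$mirna_effect[2]))
  mirna_shift <- stats::setNames(rep(0, config$n_mirnas), mirnas)
  mirna_shift[up_mirnas] <- mags[seq_along(up_mirnas)]
  mirna_shift[down_mirnas] <- -mags[config$n_up_mirnas + seq_along(down_mirnas)]

  # disjoint true target sets and induced expected gene shifts
  pool <- sample(genes, n_shift * config$targets_per_mirna)
  true_targets <- list()
  gene_shift <- stats::setNames(rep(0, config$n_genes), genes)
  for (i in seq_along(shifted)) {
    tg <- pool[(i - 1L) * config$targets_per_mirna +
                 seq_len(config$targets_per_mirna)]
    true_targets[[shifted[i]]] <- tg
    gene_shift[tg] <- -config$repression_beta * mirna_shift[shifted[i]]
  }

  draw_matrix <- function(base, shift, n_feat, rownms) {
    # shift may be a per-feature vector or a feature x pair matrix
    noise_n <- matrix(stats::rnorm(n_feat * config$n_pairs, 0, config$noise_sd),
                      n_feat, config$n_pairs)
    noise_t <- matrix(stats::rnorm(n_feat * config$n_pairs, 0, config$noise_sd),
                      n_feat, config$n_pairs)
    normal <- base + noise_n
    tumor <- base + shift + noise_t
    m <- cbind(tumor, normal)
    dimnames(m) <- list(rownms, c(tum, nor))
    m
  }
  gene_base <- stats::rnorm(config$n_genes, 8, 1.5)
  mirna_base <- stats::rnorm(config$n_mirnas, 6, 1.5)
  mirna_mat <- draw_matrix(mirna_base, mirna_shift, config$n_mirnas, mirnas)

  # repression acts on the realized per-case miRNA abundance: each target's
  # tumor value is depressed by beta times its regulator's tumor deviation
  # from baseline (expectation -beta * shift), so miRNA::target and
  # miRNA::protein correlations carry true per-case signal
  gene_shift_mat <- matrix(0, config$n_genes, config$n_pairs,
                           dimnames = list(genes, NULL))
  for (m in shifted) {
    dev <- mirna_mat[m, tum] - mirna_base[match(m, mirnas)]
    gene_shift_mat[true_targets[[m]], ] <-
      matrix(-config$repression_beta * dev,
             length(true_targets[[m]]), config$n_pairs, byrow = TRUE)
  }
  mrna_mat <- draw_matrix(gene_base, gene_shift_mat, config$n_genes, genes)

  # predictor tables: true edges recalled per source, uniform false edges
  true_edges <- if (length(true_targets)) {
    data.frame(mirna = rep(names(true_targets),
                           lengths(true_targets)),
               gene = unlist(true_targets, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else data.frame(mirna = character(0), gene = character(0))
  true_key <- paste(true_edges$mirna, true_edges$gene)
  n_all_pairs <- config$n_mirnas * config$n_genes
  pred <- list()
  for (src in c("P1", "P2")) {
    keep <- stats::runif(nrow(true_edges)) < config$predictor_sensitivity
    te <- true_edges[keep, , drop = FALSE]
    n_false <- stats::rbinom(1L, n_all_pairs - nrow(true_edges),
                             config$predictor_fpr)
    fe <- data.frame(mirna = character(0), gene = character(0))
    if (n_false > 0) {
      idx <- sample.int(n_all_pairs, min(n_false * 2L + 50L, n_all_pairs))
      mi <- mirnas[(idx - 1L) %/% config$n_genes + 1L]
      gi <- genes[(idx - 1L) %% config$n_genes + 1L]
      ok <- !(paste(mi, gi) %in% true_key)
      fe <- data.frame(mirna = mi[ok], gene = gi[ok],
                       stringsAsFactors = FALSE)
      fe <- fe[seq_len(min(n_false, nrow(fe))), , drop = FALSE]
    }
    ed <- rbind(te, fe)
    ed$source <- src
    ed$score <- round(stats::runif(nrow(ed), 0.5, 1), 6)
    pred[[src]] <- ed
  }
  predictions <- do.call(rbind, pred)
  predictions <- predictions[order(predictions$source, predictions$mirna,
                                   predictions$gene), , drop = FALSE]
  rownames(predictions) <- NULL

  # miRNA genomic loci: laid out round-robin across chromosomes
  chrom_len <- config$n_probes_per_chrom * config$probe_spacing_bp
  n_chrom <- length(config$chroms)
  loc_chrom <- config$chroms[((seq_len(config$n_mirnas) - 1L) %% n_chrom) + 1L]
  loc_start <- (((seq_len(config$n_mirnas) - 1L) %/% n_chrom)) *
    (chrom_len %/% max(1L, ceiling(config$n_mirnas / n_chrom))) + 1000
  mirna_loci <- data.frame(name = mirnas, chrom = loc_chrom,
                           start = loc_start, end = loc_start + 80,
                           score = 0L, strand = "+",
                           stringsAsFactors = FALSE)

  # aCGH probe tracks per patient with embedded deletions
  probe_start <- rep((seq_len(config$n_probes_per_chrom) - 1L) *
                       config$probe_spacing_bp, n_chrom)
  probe_chrom <- rep(config$chroms, each = config$n_probes_per_chrom)
  probe_mid <- probe_start + 30
  probes <- list()
  true_deletions <- list()
  for (ci in seq_len(config$n_pairs)) {
    v <- stats::rnorm(length(probe_start), 0, config$probe_noise_sd)
    dels <- list()
    for (ds in config$deletion_specs) {
      if (!(ci %in% ds$patients)) next
      hit <- probe_chrom == ds$chrom & probe_mid >= ds$start &
        probe_mid < ds$start + ds$length_bp
      v[hit] <- v[hit] + ds$log2_ratio
      dels[[length(dels) + 1L]] <- data.frame(
        chrom = ds$chrom, start = ds$start, end = ds$start + ds$length_bp,
        log2_ratio = ds$log2_ratio, stringsAsFactors = FALSE)
    }
    probes[[cases[ci]]] <- data.frame(
      chrom = probe_chrom, start = probe_start, end = probe_start + 60,
      log2ratio = round(v, 6), stringsAsFactors = FALSE)
    true_deletions[[cases[ci]]] <-
      if (length(dels)) do.call(rbind, dels) else
        data.frame(chrom = character(0), start = numeric(0),
                   end = numeric(0), log2_ratio = numeric(0))
  }

  # IHC: markers are true targets of up-shifted miRNAs; the ordinal score is
  # a discretized linear readout of that gene's mRNA plus ordinal noise
  marker_pool <- unlist(true_targets[up_mirnas], use.names = FALSE)
  if (length(marker_pool) < config$n_markers)
    marker_pool <- c(marker_pool,
                     setdiff(genes, marker_pool)[seq_len(config$n_markers)])
  marker_genes <- marker_pool[seq_len(config$n_markers)]
  marker_mirna <- vapply(marker_genes, function(g) {
    hit <- names(true_targets)[vapply(true_targets, function(t) g %in% t,
                                      logical(1))]
    if (length(hit)) hit[1L] else NA_character_
  }, character(1))
  markers <- sprintf("marker%02d", seq_len(config$n_markers))
  top <- config$ihc_levels - 1L
  mid <- top / 2
  ihc <- list()
  for (mi in seq_along(markers)) {
    g <- marker_genes[mi]
    b <- gene_base[match(g, genes)]
    onoise <- function(n) sample(c(-1L, 0L, 1L), n, replace = TRUE,
                                 prob = c(0.15, 0.7, 0.15))
    tsc <- clamp(round(mid + (mrna_mat[g, tum] - b)) + onoise(config$n_pairs),
                 0L, top)
    nsc <- clamp(round(mid + (mrna_mat[g, nor] - b)) + onoise(config$n_pairs),
                 0L, top)
    ihc[[mi]] <- data.frame(case_id = cases, marker = markers[mi],
                            tumor_score = as.integer(tsc),
                            normal_score = as.integer(nsc),
                            stringsAsFactors = FALSE)
  }
  ihc <- do.call(rbind, ihc)
  rownames(ihc) <- NULL

  truth <- list(
    true_de_genes = data.frame(
      gene = names(gene_shift[gene_shift != 0]),
      shift = unname(gene_shift[gene_shift != 0]),
      direction = ifelse(gene_shift[gene_shift != 0] > 0, "up", "down"),
      stringsAsFactors = FALSE, row.names = NULL),
    true_mirna_shifts = mirna_shift[shifted],
    up_mirnas = up_mirnas, down_mirnas = down_mirnas,
    true_targets = true_targets,
    true_deletions = true_deletions,
    mirna_loci = mirna_loci,
    markers = data.frame(marker = markers, gene = marker_genes,
                         mirna = unname(marker_mirna),
                         stringsAsFactors = FALSE))

  structure(list(
    mrna = paired_cohort(mrna_mat, pairing, "mrna"),
    mirna = paired_cohort(mirna_mat, pairing, "mirna"),
    predictions = predictions, probes = probes,
    mirna_loci = mirna_loci, ihc = ihc,
    truth = truth, config = config), class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf(
    "synth_cohort: %d pairs, %d genes, %d miRNAs (%d up / %d down shifted), seed %d\n",
    x$config$n_pairs, x$config$n_genes, x$config$n_mirnas,
    x$config$n_up_mirnas, x$config$n_down_mirnas, x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to an interchange-format fixture directory
#'
#' Emits the cohort as TSV/BED files (expression matrices, sample sheet,
#' predictor edges, probe tracks, miRNA loci, IHC scores) plus a JSON
#' manifest recording the file list, seed and full configuration. Writing is
#' canonical: two writes of the same cohort are byte-identical, and the files
#' round-trip losslessly through the package readers.
#'
#' @param cohort A `synth_cohort` from [generate_cohort()].
#' @param directory Output directory (created if needed).
#' @return Character vector of written file names (the manifest content),
#'   invisibly.
#' @export
write_fixture <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synth_cohort"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", directory)
  probe_key <- file.access(directory, mode = 2)
  if (probe_key != 0) stop("directory not writable: ", directory)

  expr_df <- function(m) {
    cbind(data.frame(feature = rownames(m), stringsAsFactors = FALSE),
          as.data.frame(m, check.names = FALSE))
  }
  files <- character(0)
  wr <- function(df, name) {
    write_tsv_file(df, file.path(directory, name))
    files <<- c(files, name)
  }
  wr(expr_df(cohort$mrna$values), "expression.tsv")
  wr(expr_df(cohort$mirna$values), "mirna_expression.tsv")
  p <- cohort$mrna$pairing
  ids <- colnames(cohort$mrna$values)  # matrix column order, tumors first
  is_tum <- ids %in% p$tumor
  samples <- data.frame(
    sample_id = ids,
    case_id = ifelse(is_tum, p$case_id[match(ids, p$tumor)],
                     p$case_id[match(ids, p$normal)]),
    tissue = ifelse(is_tum, "tumor", "normal"),
    stringsAsFactors = FALSE)
  wr(samples, "samples.tsv")
  wr(cohort$predictions, "predictors.tsv")
  probes <- do.call(rbind, lapply(names(cohort$probes), function(pid) {
    cbind(data.frame(patient = pid, stringsAsFactors = FALSE),
          cohort$probes[[pid]])
  }))
  rownames(probes) <- NULL
  wr(probes, "probes.tsv")
  bed <- cohort$mirna_loci
  bed_lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", bed$chrom,
                       as.integer(bed$start), as.integer(bed$end), bed$name,
                       as.integer(bed$score), bed$strand)
  con <- file(file.path(directory, "mirna_loci.bed"), open = "wb")
  writeLines(bed_lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  files <- c(files, "mirna_loci.bed")
  wr(cohort$ihc, "ihc.tsv")

  manifest <- list(files = files, seed = cohort$config$seed,
                   config = unclass(cohort$config))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(files)
}
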