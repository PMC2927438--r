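# End-to-end orchestration: synthetic cohort -> paired SAM (mRNA and miRNA)
# -> top-k miRNA selection -> consensus targets / inverse sets / enrichment
# -> per-patient CNV calling and common loss regions with miRNA annotation
# -> net immunoscores and miRNA::protein correlations, summarized as one
# reproducible JSON-serializable record.

run_config_defaults <- function() {
  list(seed = 1L, k_up = 5L, k_down = 5L, min_patients = 2L,
       log_level = "info",
       synth = list(), sam = list(), cnv = list())
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown configuration key(s) in ", where, ": ",
         paste(extra, collapse = ", "))
}

#' Validate a run configuration
#'
#' A run configuration is a named list (typically from a YAML file, see
#' [read_config()]) with top-level keys `seed`, `k_up`, `k_down`,
#' `min_patients`, `log_level`, and nested blocks `synth`, `sam`, `cnv`
#' whose keys mirror [synth_config()], [sam_settings()] and
#' [cnv_settings()]. Unknown keys anywhere are rejected.
#'
#' @param config Named list of overrides (may be empty).
#' @return Fully populated, validated configuration list of class
#'   `run_config`.
#' @export
run_config <- function(config = list()) {
  def <- run_config_defaults()
  check_keys(config, names(def), "top level")
  cfg <- utils::modifyList(def, config)
  check_keys(cfg$synth, setdiff(names(formals(synth_config)), "seed"),
             "synth block")
  check_keys(cfg$sam, setdiff(names(formals(sam_settings)), "seed"),
             "sam block")
  check_keys(cfg$cnv, names(formals(cnv_settings)), "cnv block")
  cfg$seed <- as.integer(cfg$seed)
  for (f in c("k_up", "k_down", "min_patients"))
    if (cfg[[f]] < 0) stop_config(f, "must be a non-negative count")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file; keys as in [run_config()].
#' @return Validated `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  run_config(yaml::read_yaml(path) %||% list())
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full integrative pipeline on a synthetic cohort
#'
#' Generates the cohort defined by the configuration and chains every stage:
#' paired SAM differential expression for mRNA and miRNA, top-k miRNA
#' selection, consensus target integration with direction-stratified inverse
#' sets, coverage and hypergeometric enrichment, per-patient CNV segment
#' calling with minimal common loss regions and miRNA-locus annotation, and
#' net-immunoscore protein correlations. The returned summary records every
#' parameter that affects results; re-running with the same configuration
#' and seed reproduces it exactly.
#'
#' @param config A [run_config()] (or plain list of overrides).
#' @param out_dir Optional directory; when given, writes `summary.json`,
#'   the differential tables, segment table and correlation table there.
#' @return List with `summary` plus the full stage outputs (`cohort`,
#'   `de_mrna`, `de_mirna`, `top`, `targets`, `segments`, `common_regions`,
#'   `nets`, `correlations`).
#' @export
run_report <- function(config = run_config(), out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  seed <- config$seed

  cohort <- run_stage("synth", generate_cohort(
    do.call(synth_config, c(config$synth, list(seed = seed)))))

  n <- cohort$config$n_pairs
  sam_args <- config$sam
  if (is.null(sam_args$n_permutations))
    sam_args$n_permutations <- if (2^n <= 4096) "exhaustive" else 1000L
  settings <- do.call(sam_settings, c(sam_args, list(seed = seed)))

  de_mrna <- run_stage("diffexpr-mrna", paired_sam(cohort$mrna, settings))
  de_mirna <- run_stage("diffexpr-mirna", paired_sam(cohort$mirna, settings))
  top <- run_stage("top-k", suppressWarnings(
    top_k_mirnas(de_mirna, config$k_up, config$k_down)))

  cons_up <- run_stage("targetmap", suppressWarnings(
    if (length(top$up)) consensus_targets(cohort$predictions, top$up)
    else character(0)))
  cons_down <- run_stage("targetmap", suppressWarnings(
    if (length(top$down)) consensus_targets(cohort$predictions, top$down)
    else character(0)))
  tc <- run_stage("targetmap", inverse_sets(cons_up, cons_down, de_mrna))
  n_dys <- sum(de_mrna$direction != "none")
  coverage <- if (n_dys > 0) coverage_percent(tc, n_dys) else 0

  N <- nrow(cohort$mrna$values)
  n_down <- sum(de_mrna$direction == "down")
  n_up <- sum(de_mrna$direction == "up")
  enr_up <- run_stage("enrichment", enrichment_test(
    N, n_down, length(tc$targets_of_up), length(tc$inverse_up)))
  enr_down <- run_stage("enrichment", enrichment_test(
    N, n_up, length(tc$targets_of_down), length(tc$inverse_down)))

  cnv_set <- do.call(cnv_settings, config$cnv)
  segments <- run_stage("cnv", lapply(cohort$probes, call_segments,
                                      settings = cnv_set))
  seg_parts <- Filter(Negate(is.null), lapply(names(segments), function(pid) {
    s <- segments[[pid]]
    if (nrow(s) == 0L) return(NULL)
    cbind(data.frame(patient = pid, stringsAsFactors = FALSE),
          as.data.frame(s))
  }))
  seg_all <- if (length(seg_parts)) do.call(rbind, seg_parts) else NULL
  if (is.null(seg_all))
    seg_all <- data.frame(patient = character(0), chrom = character(0),
                          start = numeric(0), end = numeric(0),
                          direction = character(0), n_probes = integer(0),
                          mean_log2 = numeric(0), score = numeric(0))
  common <- run_stage("cnv", common_regions(segments, config$min_patients))
  loss <- seg_all[seg_all$direction == "loss", , drop = FALSE]
  mirnas_in_loss <- run_stage("cnv", if (nrow(loss))
    sort(unique(unlist(suppressWarnings(
      annotate_mirnas(loss, cohort$mirna_loci))))) else character(0))

  nets <- run_stage("protein", suppressWarnings(
    net_scores(cohort$ihc, levels = cohort$config$ihc_levels)))
  mir_diff <- paired_differences(cohort$mirna)
  corr <- do.call(rbind, lapply(seq_len(nrow(cohort$truth$markers)),
                                function(i) {
    mk <- cohort$truth$markers[i, ]
    if (is.na(mk$mirna)) return(NULL)
    rec <- run_stage("protein", mirna_marker_correlation(
      nets$records[nets$records$marker == mk$marker, , drop = FALSE],
      mir_diff[mk$mirna, ]))
    data.frame(marker = mk$marker, mirna = mk$mirna, r = rec$r, n = rec$n,
               stringsAsFactors = FALSE)
  }))
  if (is.null(corr))
    corr <- data.frame(marker = character(0), mirna = character(0),
                       r = numeric(0), n = integer(0))

  summary <- list(
    seed = seed,
    settings = list(
      sam = list(fdr_target = settings$fdr_target,
                 n_permutations = settings$n_permutations,
                 s0_rule = settings$s0_rule),
      cnv = unclass(cnv_set),
      k_up = config$k_up, k_down = config$k_down,
      min_patients = config$min_patients,
      synth = unclass(cohort$config)),
    n_mrna_up = n_up, n_mrna_down = n_down, n_mrna_dysregulated = n_dys,
    n_mirna_up = sum(de_mirna$direction == "up"),
    n_mirna_down = sum(de_mirna$direction == "down"),
    top_up_mirnas = top$up, top_down_mirnas = top$down,
    n_consensus_up = length(tc$targets_of_up),
    n_consensus_down = length(tc$targets_of_down),
    n_inverse_up = length(tc$inverse_up),
    n_inverse_down = length(tc$inverse_down),
    coverage_percent = coverage,
    enrichment_p_up_targets = enr_up$p,
    enrichment_p_down_targets = enr_down$p,
    n_segments = nrow(seg_all),
    n_loss_segments = nrow(loss),
    n_common_regions = nrow(common),
    n_mirnas_in_loss = length(mirnas_in_loss),
    marker_correlations = corr)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_tsv(as.data.frame(de_mrna), file.path(out_dir, "de_mrna.tsv"))
    write_tsv(as.data.frame(de_mirna), file.path(out_dir, "de_mirna.tsv"))
    write_tsv(seg_all, file.path(out_dir, "segments.tsv"))
    write_tsv(common, file.path(out_dir, "common_regions.tsv"))
    write_tsv(corr, file.path(out_dir, "protein_correlations.tsv"))
  }

  list(summary = summary, cohort = cohort, de_mrna = de_mrna,
       de_mirna = de_mirna, top = top, targets = tc,
       segments = segments, common_regions = common,
       nets = nets, correlations = corr)
}
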