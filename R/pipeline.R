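#' Pipeline run configuration
#'
#' Collects the input paths and stage parameters for one reproducible run.
#' All referenced files must exist when the pipeline starts.
#'
#' @param transcripts,genome,annotation,chromosome_map,peptides input paths
#'   (transcriptome FASTA, assembly FASTA, gene annotation GFF3,
#'   supercontig map TSV, peptide evidence TSV)
#' @param te_db primary TE database FASTA (metadata-tagged headers)
#' @param te_db_secondary optional second TE database FASTA for the
#'   concordance analysis
#' @param te_stats genome TE statistics TSV
#' @param tier_aedes,tier_culex,tier_drosophila,tier_fallback reference
#'   proteome FASTAs for the cascade (fallback optional)
#' @param viral_db optional viral protein FASTA
#' @param min_orf_nt ORF length cutoff (exclusive, nt)
#' @param min_peptides 1 or 2; the peptide-support filter echoed in the
#'   partition summaries
#' @param cascade [cascade_params()]
#' @param te_call [te_call_params()]
#' @param triage [triage_params()]
#' @param flank_nt gap-scan window flank
#' @param enrichment_reference reference category for enrichment ratios
#' @param scheme [scoring_scheme()]
#' @param seed integer seed (control sampling)
#' @param out_dir optional report directory
#' @return list of class `run_config`
#' @export
run_config <- function(transcripts, genome, annotation, chromosome_map,
                       peptides, te_db, te_stats,
                       tier_aedes, tier_culex, tier_drosophila,
                       tier_fallback = NULL, te_db_secondary = NULL,
                       viral_db = NULL, min_orf_nt = 200L,
                       min_peptides = 1L, cascade = cascade_params(),
                       te_call = te_call_params(), triage = triage_params(),
                       flank_nt = 5000L, enrichment_reference = "LTR",
                       scheme = scoring_scheme(), seed = 1L,
                       out_dir = NULL) {
  cfg <- as.list(environment())
  files <- c(transcripts, genome, annotation, chromosome_map, peptides,
             te_db, te_stats, tier_aedes, tier_culex, tier_drosophila,
             tier_fallback, te_db_secondary, viral_db)
  missing <- files[!file.exists(files)]
  if (length(missing)) abort("input file not found: %s", missing[1L])
  if (!min_peptides %in% c(1L, 2L)) abort("min_peptides must be 1 or 2")
  class(cfg) <- "run_config"
  cfg
}

#' Shortcut run configuration for a generated fixture bundle
#'
#' @param fx return value of [generate_fixtures()]
#' @param ... overrides passed to [run_config()]
#' @return `run_config`
#' @export
run_config_from_fixtures <- function(fx, ...) {
  p <- fx$paths
  run_config(transcripts = p$transcripts, genome = p$genome,
             annotation = p$annotation, chromosome_map = p$chromosome_map,
             peptides = p$peptides, te_db = p$te_db,
             te_db_secondary = p$te_db_secondary, te_stats = p$te_stats,
             tier_aedes = p$tier_aedes, tier_culex = p$tier_culex,
             tier_drosophila = p$tier_drosophila, viral_db = p$viral_db,
             ...)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes ORF extraction, peptide grouping, the tiered homology cascade,
#' TE-protein calling (with calibration curves, single-peptide quality
#' control, and optional dual-database concordance), enrichment
#' normalisation, the viral screen, and the genome-annotation evaluation
#' (transcript triage, sequencing-gap scan with a length-matched control
#' sample, chromosome and band enrichment). Deterministic given identical
#' inputs and seed.
#'
#' @param config a [run_config()]
#' @return list of class `pit_report` (see [write_report()] for the
#'   serialised layout); written to `config$out_dir` when set
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  scheme <- config$scheme

  transcripts <- .stage("read", read_dna_fasta(config$transcripts))
  genome <- .stage("read", read_dna_fasta(config$genome))
  annotation <- .stage("read", read_annotation(config$annotation))
  chr_map <- .stage("read", read_chromosome_map(config$chromosome_map))
  evidence <- .stage("read", read_peptide_evidence(config$peptides))
  tedb <- .stage("read", read_te_fasta(config$te_db))
  te_stats <- .stage("read", read_te_stats(config$te_stats))

  orfs <- .stage("orfs", extract_orfs(transcripts, config$min_orf_nt))
  groups <- .stage("grouping", group_peptides(evidence, orfs))
  reps <- .stage("grouping", group_representatives(groups, orfs))
  queries <- stats::setNames(reps$protein, reps$group_id)

  tiers <- .stage("cascade", {
    args <- list(AEDES = read_protein_fasta(config$tier_aedes),
                 CULEX = read_protein_fasta(config$tier_culex),
                 DROSOPHILA = read_protein_fasta(config$tier_drosophila))
    if (!is.null(config$tier_fallback))
      args$FALLBACK <- read_protein_fasta(config$tier_fallback)
    do.call(reference_tiers, args)
  })
  cascade <- .stage("cascade",
                    classify_proteins(queries, tiers, config$cascade, scheme))
  partition_all <- partition_summary(cascade, 1L, groups)
  partition_2pep <- partition_summary(cascade, 2L, groups)

  non_insect <- cascade$query_id[cascade$category == "NON_INSECT"]
  aedes_grp <- cascade$query_id[cascade$category == "AEDES"]
  non_aedes <- cascade$query_id[cascade$category == "NON_AEDES_INSECT"]

  calls <- .stage("te_calls",
                  call_tes(queries[non_insect], tedb, config$te_call, scheme))
  background_calls <- .stage("te_calls",
                             call_tes(queries[aedes_grp], tedb,
                                      config$te_call, scheme))
  calls_qc <- .stage("te_qc", qc_single_peptide(calls, groups, evidence))

  calib_cov <- .stage("calibration", coverage_calibration(
    queries[non_insect], queries[aedes_grp], tedb,
    identity_min_pct = config$te_call$identity_min_pct,
    evalue_max = config$te_call$evalue_max, scheme = scheme))
  calib_ident <- .stage("calibration", identity_calibration(
    queries[non_insect], queries[aedes_grp], tedb,
    coverage_min_pct = config$te_call$coverage_min_pct,
    evalue_max = config$te_call$evalue_max, scheme = scheme))
  selected_cutoff <- select_coverage_threshold(calib_cov)

  concordance <- NULL
  calls_secondary <- NULL
  if (!is.null(config$te_db_secondary)) {
    tedb2 <- .stage("read", read_te_fasta(config$te_db_secondary))
    calls_secondary <- .stage("te_calls",
                              call_tes(queries[non_insect], tedb2,
                                       config$te_call, scheme))
    concordance <- db_concordance(calls_qc, calls_secondary)
  }

  viral <- NULL
  if (!is.null(config$viral_db)) {
    vdb <- .stage("read", read_protein_fasta(config$viral_db))
    host_db <- stats::setNames(
      unlist(lapply(tiers, function(t) t$db), use.names = FALSE),
      unlist(lapply(tiers, function(t) names(t$db)), use.names = FALSE))
    viral <- .stage("viral", screen_viral(
      queries[non_insect], vdb,
      te_db = stats::setNames(tedb$protein, tedb$te_id),
      host_db = host_db, scheme = scheme))
  }

  # enrichment on the post-QC calls
  stats_order <- te_stats[te_stats$level == "ORDER", , drop = FALSE]
  stats_clade <- te_stats[te_stats$level == "CLADE", , drop = FALSE]
  counts_order <- count_calls(calls_qc, "order",
                              categories = stats_order$category)
  counts_clade <- count_calls(calls_qc, "clade",
                              categories = stats_clade$category)
  enr <- .stage("enrichment", {
    normalizers <- c("GENOME_PCT", "COPY_NUMBER", "DB_ENTRIES")
    out <- list()
    for (nm in normalizers) {
      out[[paste0("order_", tolower(nm))]] <-
        relative_enrichment(counts_order, stats_order, nm,
                            config$enrichment_reference)
    }
    out
  })
  breakdown <- orf_breakdown(calls_qc)

  # annotation evaluation: the non-Aedes-insect transcripts are the
  # candidates for new annotation; expressed host transcripts are the
  # control pool
  grp_tr <- stats::setNames(reps$transcript_id, reps$group_id)
  eval_tr <- unique(grp_tr[non_aedes])
  pool_tr <- unique(grp_tr[aedes_grp])
  hits <- .stage("align", align_transcripts(
    transcripts[c(eval_tr, pool_tr)], genome))
  tri <- .stage("triage", triage(hits, eval_tr, annotation, config$triage))
  new_tr <- tri$transcript_id[tri$category == "NEW_ANNOTATION"]
  gaps_new <- .stage("gap_scan", gap_scan(
    genome, tri[tri$category == "NEW_ANNOTATION", , drop = FALSE],
    config$flank_nt))
  # length-matched controls among host transcripts that aligned
  pool_hits <- hits[hits$transcript_id %in% pool_tr, , drop = FALSE]
  pool_best <- pool_hits[!duplicated(pool_hits$transcript_id), , drop = FALSE]
  controls <- NULL
  gaps_control <- NULL
  if (length(new_tr) && nrow(pool_best) >= length(new_tr)) {
    ctrl_ids <- matched_control_sample(
      stats::setNames(nchar(transcripts[new_tr]), new_tr),
      stats::setNames(nchar(transcripts[pool_best$transcript_id]),
                      pool_best$transcript_id),
      seed = config$seed)
    controls <- ctrl_ids
    gaps_control <- gap_scan(
      genome, pool_best[match(ctrl_ids, pool_best$transcript_id), ,
                        drop = FALSE],
      config$flank_nt)
  }
  # transcript length comparison: unmappable vs mapped candidates
  len_no_match <- nchar(transcripts[tri$transcript_id[
    tri$category == "NO_MATCH"]])
  len_mapped <- nchar(transcripts[tri$transcript_id[
    tri$category != "NO_MATCH"]])
  length_test <- if (length(len_no_match) >= 2L && length(len_mapped) >= 2L)
    ttest_equal_var(len_no_match, len_mapped) else NULL

  chrom <- .stage("hotspots", chromosome_enrichment(tri, chr_map))
  bands <- .stage("hotspots", band_hotspots(tri, chr_map))

  bundle <- list(
    n_orfs = nrow(orfs), n_groups = nrow(groups),
    n_groups_2pep = sum(groups$n_peptides >= 2L),
    cascade = cascade, partition_all = partition_all,
    partition_2pep = partition_2pep,
    te_calls = calls, te_calls_qc = calls_qc,
    te_calls_background = background_calls,
    te_calls_secondary = calls_secondary,
    concordance = concordance, viral = viral,
    calibration_coverage = calib_cov, calibration_identity = calib_ident,
    selected_coverage_cutoff = selected_cutoff,
    counts_order = counts_order, counts_clade = counts_clade,
    enrichment = enr, orf_breakdown = breakdown,
    triage = tri, gap_scan_new = gaps_new, gap_scan_control = gaps_control,
    controls = controls, length_test = length_test,
    chromosome_enrichment = chrom, band_hotspots = bands,
    manifest = list(
      package = "pitmobilome",
      version = as.character(utils::packageVersion("pitmobilome")),
      seed = config$seed,
      min_orf_nt = config$min_orf_nt,
      min_peptides = config$min_peptides,
      cascade = unclass(config$cascade),
      te_call = unclass(config$te_call),
      triage = unclass(config$triage),
      flank_nt = config$flank_nt,
      enrichment_reference = config$enrichment_reference,
      gap_penalties = c(open = config$scheme$gap_open,
                        extend = config$scheme$gap_extend),
      karlin_altschul = c(lambda = config$scheme$lambda,
                          K = config$scheme$K)))
  class(bundle) <- c("pit_report", "list")
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

#' Write a pipeline report
#'
#' Serialises every table of a [run_pipeline()] bundle as TSV, plus a JSON
#' summary (headline counts and percentages) and a JSON manifest echoing
#' every parameter actually applied. Rewriting the same bundle produces
#' byte-identical files.
#'
#' @param bundle `pit_report` from [run_pipeline()]
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  wt <- function(x, f) if (!is.null(x)) write_tsv_file(as.data.frame(x), p(f))
  wt(bundle$cascade, "cascade_results.tsv")
  wt(bundle$partition_all, "cascade_partition.tsv")
  wt(bundle$partition_2pep, "cascade_partition_2pep.tsv")
  wt(bundle$te_calls, "te_calls_raw.tsv")
  wt(bundle$te_calls_qc, "te_calls.tsv")
  wt(bundle$te_calls_background, "te_calls_background.tsv")
  wt(bundle$te_calls_secondary, "te_calls_secondary.tsv")
  wt(bundle$calibration_coverage, "calibration_coverage.tsv")
  wt(bundle$calibration_identity, "calibration_identity.tsv")
  for (nm in names(bundle$enrichment))
    wt(bundle$enrichment[[nm]], sprintf("enrichment_%s.tsv", nm))
  if (!is.null(bundle$orf_breakdown) && length(bundle$orf_breakdown)) {
    ob <- as.data.frame.matrix(bundle$orf_breakdown)
    ob <- cbind(clade = rownames(ob), ob)
    wt(ob, "orf_breakdown.tsv")
  }
  wt(bundle$triage, "triage.tsv")
  wt(bundle$gap_scan_new, "gap_scan_new.tsv")
  wt(bundle$gap_scan_control, "gap_scan_control.tsv")
  wt(bundle$chromosome_enrichment, "chromosome_enrichment.tsv")
  wt(bundle$band_hotspots, "band_hotspots.tsv")
  wt(bundle$viral, "viral_screen.tsv")

  pct <- function(x, n) if (n > 0) round_half_up(100 * x / n, 1) else NA
  tri_counts <- as.list(table(bundle$triage$category))
  summary <- list(
    n_orfs = bundle$n_orfs,
    n_protein_groups = bundle$n_groups,
    n_protein_groups_2pep = bundle$n_groups_2pep,
    partition = bundle$partition_all,
    partition_2pep = bundle$partition_2pep,
    n_te_calls = nrow(bundle$te_calls_qc),
    n_te_calls_exact = sum(bundle$te_calls_qc$tier == "EXACT"),
    n_te_calls_background = nrow(bundle$te_calls_background),
    selected_coverage_cutoff = bundle$selected_coverage_cutoff,
    triage_counts = tri_counts,
    pct_new_with_gap = if (!is.null(bundle$gap_scan_new))
      pct(sum(bundle$gap_scan_new$has_gap), nrow(bundle$gap_scan_new))
      else NA,
    pct_control_with_gap = if (!is.null(bundle$gap_scan_control))
      pct(sum(bundle$gap_scan_control$has_gap),
          nrow(bundle$gap_scan_control)) else NA,
    enriched_bands = bundle$band_hotspots$band[bundle$band_hotspots$enriched],
    concordance = bundle$concordance,
    length_test = bundle$length_test)
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, na = "null")
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(dir)
}
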