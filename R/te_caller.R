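TE_ORDERS <- c("LTR", "NON_LTR", "PLE", "DNA_TIR", "HELITRON", "MITE", "SINE")
TE_ORF_TYPES <- c("GAG", "POL", "ENV", "ORF1", "ORF2", "TRANSPOSASE",
                  "REP_HELICASE", "OTHER")

# which ORF types each order may encode (besides OTHER)
.ORDER_ORFS <- list(
  LTR = c("GAG", "POL", "ENV", "OTHER"),
  NON_LTR = c("ORF1", "ORF2", "OTHER"),
  DNA_TIR = c("TRANSPOSASE", "OTHER"),
  HELITRON = c("REP_HELICASE", "OTHER"),
  PLE = c("OTHER"),
  MITE = c("OTHER"),
  SINE = c("OTHER"))

#' Build a transposable-element protein database
#'
#' @param te_id,source_db,te_class,order,clade,orf_type,protein parallel
#'   vectors of entry metadata; `order` in
#'   LTR/NON_LTR/PLE/DNA_TIR/HELITRON/MITE/SINE, `orf_type` consistent with
#'   the order's architecture (LTR elements encode gag/pol/env, non-LTR
#'   elements ORF1/ORF2, cut-and-paste DNA transposons a transposase)
#' @return data.frame of class `te_db`
#' @export
te_db <- function(te_id, source_db, te_class, order, clade, orf_type,
                  protein) {
  n <- length(te_id)
  source_db <- rep_len(source_db, n); te_class <- rep_len(te_class, n)
  order <- rep_len(toupper(order), n)
  clade <- rep_len(clade, n)
  orf_type <- rep_len(toupper(orf_type), n)
  bad <- setdiff(unique(order), TE_ORDERS)
  if (length(bad)) abort("unknown TE order '%s'", bad[1L])
  bad <- setdiff(unique(orf_type), TE_ORF_TYPES)
  if (length(bad)) abort("unknown TE ORF type '%s'", bad[1L])
  for (i in seq_along(te_id)) {
    if (!orf_type[i] %in% .ORDER_ORFS[[order[i]]])
      abort("entry %s: order %s cannot encode ORF type %s",
            te_id[i], order[i], orf_type[i])
  }
  db <- data.frame(te_id = te_id, source_db = source_db, te_class = te_class,
                   order = order, clade = clade, orf_type = orf_type,
                   protein = normalize_aa(protein, "TE protein"),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(db$te_id)) abort("duplicated te_id in TE database")
  class(db) <- c("te_db", "data.frame")
  db
}

#' Read a TE database from metadata-tagged FASTA
#'
#' Headers encode the entry metadata as pipe-separated key=value pairs:
#' `>Ele7_pol|source=TEFAM|class=I|order=LTR|clade=Ty3/gypsy|orf=pol`
#'
#' @param path FASTA file
#' @return `te_db` data.frame
#' @export
read_te_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(aa), "|", fixed = TRUE)
  get_kv <- function(p, key) {
    hit <- grep(paste0("^", key, "="), p, value = TRUE)
    if (!length(hit)) abort("TE FASTA header lacks '%s=' field: %s",
                            key, paste(p, collapse = "|"))
    sub(paste0("^", key, "="), "", hit[1L])
  }
  te_db(
    te_id = vapply(parts, `[`, "", 1L),
    source_db = vapply(parts, get_kv, "", key = "source"),
    te_class = vapply(parts, get_kv, "", key = "class"),
    order = vapply(parts, get_kv, "", key = "order"),
    clade = vapply(parts, get_kv, "", key = "clade"),
    orf_type = vapply(parts, get_kv, "", key = "orf"),
    protein = unname(as.character(aa)))
}

#' Write a TE database as metadata-tagged FASTA
#' @param db `te_db` data.frame
#' @param path output path
#' @return invisibly, `path`
#' @export
write_te_fasta <- function(db, path) {
  headers <- sprintf("%s|source=%s|class=%s|order=%s|clade=%s|orf=%s",
                     db$te_id, db$source_db, db$te_class, db$order, db$clade,
                     tolower(db$orf_type))
  aa <- Biostrings::AAStringSet(db$protein)
  names(aa) <- headers
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' TE-calling thresholds
#'
#' The standard thresholds (E-value < 1e-5, identity > 30%, query coverage
#' > 45%; all strict) are the empirically calibrated criteria for confident
#' TE-protein identification; matches above 95% identity and 95% coverage
#' are additionally tiered as exact matches to a known element.
#'
#' @param evalue_max E-value bound (strict `<`)
#' @param identity_min_pct,coverage_min_pct standard thresholds (strict `>`)
#' @param exact_identity_pct,exact_coverage_pct exact-match tier thresholds
#'   (strict `>`); must not be below the standard thresholds
#' @return list of class `te_call_params`
#' @export
te_call_params <- function(evalue_max = 1e-5, identity_min_pct = 30,
                           coverage_min_pct = 45, exact_identity_pct = 95,
                           exact_coverage_pct = 95) {
  if (exact_identity_pct < identity_min_pct ||
      exact_coverage_pct < coverage_min_pct)
    abort("exact-match thresholds must be >= standard thresholds")
  structure(list(evalue_max = evalue_max, identity_min_pct = identity_min_pct,
                 coverage_min_pct = coverage_min_pct,
                 exact_identity_pct = exact_identity_pct,
                 exact_coverage_pct = exact_coverage_pct),
            class = "te_call_params")
}

# best TE hit per query with full details (identity/coverage), no thresholds
.te_top_hits <- function(queries, db, scheme) {
  proteins <- stats::setNames(db$protein, db$te_id)
  m <- search_homologs(queries, proteins, scheme = scheme, db_tag = "TE",
                       details = "top")
  top_hits(m)
}

.annotate_calls <- function(best, db, params) {
  ok <- best$evalue < params$evalue_max &
    best$pct_identity > params$identity_min_pct &
    best$query_coverage_pct > params$coverage_min_pct
  calls <- best[ok, , drop = FALSE]
  idx <- match(calls$subject_id, db$te_id)
  calls$te_id <- calls$subject_id
  calls$source_db <- db$source_db[idx]
  calls$te_class <- db$te_class[idx]
  calls$order <- db$order[idx]
  calls$clade <- db$clade[idx]
  calls$orf_type <- db$orf_type[idx]
  calls$tier <- ifelse(
    calls$pct_identity > params$exact_identity_pct &
      calls$query_coverage_pct > params$exact_coverage_pct,
    "EXACT", "STANDARD")
  rownames(calls) <- NULL
  class(calls) <- c("te_calls", "data.frame")
  calls
}

#' Call TE proteins
#'
#' Searches each query against a TE protein database and calls at most one
#' TE identity per query: the top hit by raw score, retained only if it
#' passes all thresholds strictly (E-value below, identity and coverage
#' above). Calls whose top hit exceeds the exact-match thresholds are tiered
#' `EXACT`, the rest `STANDARD`; exact matches are a subset of all calls,
#' not a separate pool.
#'
#' @param queries named character vector or AAStringSet of proteins
#' @param db a [te_db()]
#' @param params [te_call_params()]
#' @param scheme [scoring_scheme()]
#' @return data.frame of class `te_calls`: `query_id`, `te_id`, `source_db`,
#'   `te_class`, `order`, `clade`, `orf_type`, match statistics and `tier`
#' @export
call_tes <- function(queries, db, params = te_call_params(),
                     scheme = scoring_scheme()) {
  if (!nrow(db)) abort("empty TE database")
  best <- .te_top_hits(queries, db, scheme)
  .annotate_calls(best, db, params)
}

# proportion of a query set whose best TE hit passes the fixed filters and a
# sliding cutoff on one axis
.calibration_curve <- function(best, n_queries, grid, axis,
                               fixed_identity, fixed_coverage, evalue_max) {
  ok <- best$evalue < evalue_max
  if (axis == "COVERAGE") {
    ok <- ok & best$pct_identity > fixed_identity
    val <- best$query_coverage_pct
  } else {
    ok <- ok & best$query_coverage_pct > fixed_coverage
    val <- best$pct_identity
  }
  val <- val[ok]
  vapply(grid, function(c) sum(val > c) / n_queries, 0)
}

#' Coverage calibration curves for TE identification
#'
#' For a target query set (expected to contain TE proteins) and a background
#' set (expected to contain none), computes the proportion of each set whose
#' best TE hit passes the E-value and identity filters at increasing query
#' coverage cutoffs. The background set acts as an empirical false-positive
#' calibrator: the coverage cutoff is chosen where the background proportion
#' collapses while the target proportion persists.
#'
#' @param target_queries,background_queries named character vectors of
#'   proteins
#' @param db a [te_db()]
#' @param grid ascending coverage cutoffs (percent); default 0 to 100 by 5
#' @param identity_min_pct fixed identity filter (default 30, strict `>`)
#' @param evalue_max fixed E-value filter (strict `<`)
#' @param scheme [scoring_scheme()]
#' @return data.frame of class `calibration_curves`: `cutoff`, `target`,
#'   `background` (proportions in [0,1], monotone non-increasing); attribute
#'   `axis`
#' @export
coverage_calibration <- function(target_queries, background_queries, db,
                                 grid = seq(0, 100, by = 5),
                                 identity_min_pct = 30, evalue_max = 1e-5,
                                 scheme = scoring_scheme()) {
  .calibrate(target_queries, background_queries, db, grid, "COVERAGE",
             identity_min_pct, NA_real_, evalue_max, scheme)
}

#' Identity calibration curves for TE identification
#'
#' As [coverage_calibration()] with the axes swapped: coverage is held fixed
#' and the identity cutoff slides along the grid.
#'
#' @inheritParams coverage_calibration
#' @param coverage_min_pct fixed coverage filter (default 45, strict `>`)
#' @return `calibration_curves` data.frame (attribute `axis = "IDENTITY"`)
#' @export
identity_calibration <- function(target_queries, background_queries, db,
                                 grid = seq(0, 100, by = 5),
                                 coverage_min_pct = 45, evalue_max = 1e-5,
                                 scheme = scoring_scheme()) {
  .calibrate(target_queries, background_queries, db, grid, "IDENTITY",
             NA_real_, coverage_min_pct, evalue_max, scheme)
}

.calibrate <- function(target_queries, background_queries, db, grid, axis,
                       identity_min_pct, coverage_min_pct, evalue_max,
                       scheme) {
  if (!length(grid)) abort("empty calibration grid")
  if (is.unsorted(grid, strictly = TRUE)) abort("grid must be ascending")
  target_queries <- as_named_chr(target_queries)
  background_queries <- as_named_chr(background_queries)
  if (!length(target_queries) || !length(background_queries))
    abort("both query sets must be non-empty")
  bt <- .te_top_hits(target_queries, db, scheme)
  bb <- .te_top_hits(background_queries, db, scheme)
  out <- data.frame(
    cutoff = grid,
    target = .calibration_curve(bt, length(target_queries), grid, axis,
                                identity_min_pct, coverage_min_pct,
                                evalue_max),
    background = .calibration_curve(bb, length(background_queries), grid,
                                    axis, identity_min_pct, coverage_min_pct,
                                    evalue_max))
  attr(out, "axis") <- axis
  class(out) <- c("calibration_curves", "data.frame")
  out
}

#' Select a coverage threshold from calibration curves
#'
#' Formalises the visual knee-picking of a coverage cutoff: returns the
#' smallest grid cutoff at which the background proportion has fallen to at
#' most `background_tolerance` times its value at cutoff 0, provided the
#' target proportion still retains at least `target_retention` of its value
#' at cutoff 0. If no cutoff qualifies, falls back to the grid point
#' maximising the target-background difference (first such point on ties).
#' The selection is advisory; it is not applied automatically to any call
#' set.
#'
#' @param curves `calibration_curves` from [coverage_calibration()] (or a
#'   data.frame with `cutoff`, `target`, `background` on a shared grid)
#' @param background_tolerance fraction of the baseline background proportion
#'   considered collapsed (default 0.2)
#' @param target_retention minimum retained fraction of the baseline target
#'   proportion (default 0.8)
#' @return selected cutoff (scalar)
#' @export
select_coverage_threshold <- function(curves, background_tolerance = 0.2,
                                      target_retention = 0.8) {
  bg0 <- curves$background[1L]
  tg0 <- curves$target[1L]
  ok <- curves$background <= background_tolerance * bg0 &
    curves$target >= target_retention * tg0
  if (any(ok)) return(curves$cutoff[which(ok)[1L]])
  curves$cutoff[which.max(curves$target - curves$background)]
}

#' Single-peptide quality control of TE calls
#'
#' Removes calls supported by exactly one distinct peptide when that peptide
#' also matches ORFs carrying a conflicting identity: an ORF with no TE call
#' (a putative non-TE gene), a call to an unrelated element, or a
#' non-concordant ORF type within the same clade. A peptide shared only
#' among ORFs of the same element, or among same-clade ORFs of the same
#' type, is considered concordant. Calls supported by two or more peptides
#' are retained regardless of sharing.
#'
#' @param calls `te_calls` data.frame (queries keyed by group id)
#' @param groups [group_peptides()] output
#' @param evidence peptide evidence data.frame (list-column `orf_ids`)
#' @return filtered `te_calls`; attribute `removed` lists the dropped
#'   query ids
#' @export
qc_single_peptide <- function(calls, groups, evidence) {
  if (!nrow(calls)) return(calls)
  rownames(groups) <- groups$group_id
  missing <- setdiff(calls$query_id, groups$group_id)
  if (length(missing))
    abort("call query '%s' has no protein group", missing[1L])
  # ORF -> owning group
  orf_sets <- strsplit(groups$orf_ids, ",", fixed = TRUE)
  orf2group <- stats::setNames(rep(groups$group_id, lengths(orf_sets)),
                               unlist(orf_sets))
  # group -> call row
  call_idx <- stats::setNames(seq_len(nrow(calls)), calls$query_id)

  concordant <- function(i, j) {
    if (calls$te_id[i] == calls$te_id[j]) return(TRUE)
    calls$clade[i] == calls$clade[j] & calls$orf_type[i] == calls$orf_type[j]
  }
  drop <- logical(nrow(calls))
  pep <- !duplicated(evidence$peptide)
  ev_sets <- evidence$orf_ids[pep]
  ev_groups <- lapply(ev_sets, function(ids)
    unique(orf2group[intersect(ids, names(orf2group))]))
  for (i in seq_len(nrow(calls))) {
    g <- calls$query_id[i]
    if (groups[g, "n_peptides"] != 1L) next
    hits <- which(vapply(ev_groups, function(gs) g %in% gs, TRUE))
    if (!length(hits)) next
    others <- setdiff(unlist(ev_groups[hits]), g)
    for (og in others) {
      j <- call_idx[og]
      if (is.na(j) || !concordant(i, j)) {   # non-TE group or conflicting call
        drop[i] <- TRUE
        break
      }
    }
  }
  out <- calls[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- calls$query_id[drop]
  out
}

#' Concordance between two call sets
#'
#' Compares TE calls made against two reference databases for the queries
#' called in both: agreement at the order level (LTR retrotransposon versus
#' cut-and-paste DNA transposon, etc.) and at the clade/superfamily level.
#'
#' @param calls_primary,calls_secondary `te_calls` data.frames keyed by
#'   `query_id`
#' @return list: `n_both`, `n_only_primary`, `n_only_secondary`,
#'   `order_agreement`, `clade_agreement` (fractions in [0,1]; `NA` when no
#'   shared queries)
#' @export
db_concordance <- function(calls_primary, calls_secondary) {
  shared <- intersect(calls_primary$query_id, calls_secondary$query_id)
  i <- match(shared, calls_primary$query_id)
  j <- match(shared, calls_secondary$query_id)
  n <- length(shared)
  list(
    n_both = n,
    n_only_primary = nrow(calls_primary) - n,
    n_only_secondary = nrow(calls_secondary) - n,
    order_agreement = if (n) mean(calls_primary$order[i] ==
                                    calls_secondary$order[j]) else NA_real_,
    clade_agreement = if (n) mean(calls_primary$clade[i] ==
                                    calls_secondary$clade[j]) else NA_real_)
}
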