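CASCADE_TIERS <- c("AEDES", "CULEX", "DROSOPHILA", "FALLBACK")
CASCADE_CATEGORIES <- c("AEDES", "NON_AEDES_INSECT", "NON_INSECT")

#' Build an ordered list of reference tiers
#'
#' The tiered homology cascade searches reference proteomes in a fixed order
#' (conspecific mosquito, then a related mosquito, then a distant dipteran,
#' then an optional fallback database) and stops at the first tier with a
#' convincing hit.
#'
#' @param ... named arguments `AEDES = <db>`, `CULEX = <db>`, ... where each
#'   db is a named character vector or AAStringSet of proteins; order is the
#'   search order
#' @return list of tiers, each `list(tag =, db =)`
#' @export
reference_tiers <- function(...) {
  dbs <- list(...)
  tags <- names(dbs)
  if (is.null(tags) || any(!nzchar(tags))) abort("tiers must be named")
  if (anyDuplicated(tags)) abort("tier tags must be unique")
  bad <- setdiff(tags, CASCADE_TIERS)
  if (length(bad)) abort("unknown tier tag '%s' (use %s)", bad[1L],
                         paste(CASCADE_TIERS, collapse = ", "))
  lapply(tags, function(t) {
    db <- as_named_chr(dbs[[t]])
    if (length(db) == 0L) abort("tier %s has an empty database", t)
    list(tag = t, db = db)
  })
}

#' Cascade stopping parameters
#'
#' @param identity_stop_pct percent identity of a tier's best hit at or above
#'   which the cascade stops at that tier (default 60)
#' @param evalue_max maximum E-value for a hit to be able to stop the cascade
#'   (default 1e-5); this guards against short spurious alignments with high
#'   identity stopping the search
#' @return list of class `cascade_params`
#' @export
cascade_params <- function(identity_stop_pct = 60, evalue_max = 1e-5) {
  if (identity_stop_pct <= 0 || identity_stop_pct > 100)
    abort("identity_stop_pct must be in (0, 100]")
  structure(list(identity_stop_pct = identity_stop_pct,
                 evalue_max = evalue_max), class = "cascade_params")
}

.category_for_tier <- function(tag) {
  ifelse(is.na(tag), "NON_INSECT",
         ifelse(tag == "AEDES", "AEDES",
                ifelse(tag %in% c("CULEX", "DROSOPHILA"),
                       "NON_AEDES_INSECT", "NON_INSECT")))
}

#' Tiered homology classification of proteins
#'
#' Each query is searched against the reference tiers in order. The search
#' stops at the first tier whose best hit reaches
#' `identity_stop_pct` identity with E-value at most `evalue_max`; queries
#' stopping in the first tier are classified `AEDES`, in the two other
#' dipteran tiers `NON_AEDES_INSECT`, and everything else (fallback-tier stop
#' or no convincing hit anywhere) `NON_INSECT`.
#'
#' @param queries named character vector or AAStringSet of proteins
#' @param tiers output of [reference_tiers()]
#' @param params [cascade_params()]
#' @param scheme [scoring_scheme()]
#' @return data.frame of class `cascade_results`: `query_id`, `category`,
#'   `stopping_tier` (`NA` if none); attribute `tier_matches` holds the best
#'   hit per query per searched tier (long data.frame)
#' @export
classify_proteins <- function(queries, tiers, params = cascade_params(),
                              scheme = scoring_scheme()) {
  queries <- normalize_aa(as_named_chr(queries), "query")
  if (length(tiers) == 0L) abort("at least one reference tier is required")
  remaining <- names(queries)
  stopping <- stats::setNames(rep(NA_character_, length(queries)),
                              names(queries))
  tier_matches <- list()
  for (tier in tiers) {
    if (!length(remaining)) break
    m <- search_homologs(queries[remaining], tier$db, scheme = scheme,
                         db_tag = tier$tag, details = "top")
    best <- top_hits(m)
    tier_matches[[tier$tag]] <- best
    ok <- best$pct_identity >= params$identity_stop_pct &
      best$evalue <= params$evalue_max
    stopped <- best$query_id[ok]
    stopping[stopped] <- tier$tag
    remaining <- setdiff(remaining, stopped)
  }
  res <- data.frame(query_id = names(queries),
                    category = .category_for_tier(unname(stopping)),
                    stopping_tier = unname(stopping),
                    stringsAsFactors = FALSE)
  res$category <- factor(res$category, levels = CASCADE_CATEGORIES)
  attr(res, "tier_matches") <- do.call(rbind, tier_matches)
  class(res) <- c("cascade_results", "data.frame")
  res
}

#' Percentages from category counts
#'
#' Turns a vector of category counts into the partition summary convention
#' used throughout: integer percentages rounded half-up, plus one-decimal
#' percentages.
#'
#' @param counts named integer vector of category counts
#' @return data.frame `category`, `count`, `pct_int`, `pct_1dp`
#' @examples
#' # 5457 + 215 + 899 proteins -> 83% / 3% / 14%
#' percentage_summary(c(AEDES = 5457, NON_AEDES_INSECT = 215,
#'                      NON_INSECT = 899))
#' @export
percentage_summary <- function(counts) {
  n <- sum(counts)
  if (n == 0) abort("no observations to summarise")
  pct <- 100 * counts / n
  data.frame(category = names(counts), count = as.integer(counts),
             pct_int = round_half_up(pct, 0),
             pct_1dp = round_half_up(pct, 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Partition summary of cascade results
#'
#' Counts and percentages per category, over either the full proteome or
#' the subset of protein groups supported by at least `min_peptides`
#' peptides.
#'
#' @param results [classify_proteins()] output (queries keyed by group id
#'   when `groups` is supplied)
#' @param min_peptides 1 (all groups) or 2 (two-peptide subset)
#' @param groups [group_peptides()] output, required when `min_peptides > 1`
#' @return data.frame as [percentage_summary()], with counts summing to the
#'   number of summarised results
#' @export
partition_summary <- function(results, min_peptides = 1L, groups = NULL) {
  if (nrow(results) == 0L) abort("no cascade results to summarise")
  keep <- results$query_id
  if (min_peptides > 1L) {
    if (is.null(groups))
      abort("groups are required to filter on peptide support")
    keep <- intersect(keep, groups$group_id[groups$n_peptides >= min_peptides])
  }
  sub <- results[results$query_id %in% keep, , drop = FALSE]
  counts <- table(sub$category)
  percentage_summary(stats::setNames(as.integer(counts), names(counts)))
}

#' Screen unclassified proteins against a viral database
#'
#' Queries whose best viral hit has a raw score above `min_raw_score` are
#' reported as candidate viral proteins, unless a transposable-element or
#' host protein matches the query with a higher score than the viral hit
#' (such hits are more plausibly TE- or host-derived).
#'
#' @param queries named character vector of proteins (typically the
#'   non-insect set)
#' @param viral_db named character vector of viral proteins
#' @param te_db,host_db optional exclusion databases (named character vectors)
#' @param min_raw_score raw-score floor (default 50)
#' @param scheme [scoring_scheme()]
#' @return data.frame `query_id`, `subject_id`, `raw_score`, `excluded_by`
#'   (`NA` for reported hits) with one row per query whose viral score passed
#'   the floor; reported viral hits are the rows with `excluded_by` NA
#' @export
screen_viral <- function(queries, viral_db, te_db = NULL, host_db = NULL,
                         min_raw_score = 50L, scheme = scoring_scheme()) {
  queries <- normalize_aa(as_named_chr(queries), "query")
  if (length(viral_db) == 0L) abort("empty viral database")
  vm <- top_hits(search_homologs(queries, viral_db, scheme = scheme,
                                 db_tag = "VIRAL", details = "top"))
  vm <- vm[vm$raw_score > min_raw_score, , drop = FALSE]
  if (nrow(vm) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      raw_score = integer(), excluded_by = character(),
                      stringsAsFactors = FALSE))
  }
  excl_score <- function(db) {
    if (is.null(db) || length(db) == 0L)
      return(stats::setNames(rep(0L, nrow(vm)), vm$query_id))
    sc <- sw_score_matrix(queries[vm$query_id], db, scheme)
    apply(sc, 1L, max)
  }
  te_s <- excl_score(te_db)
  host_s <- excl_score(host_db)
  excluded_by <- rep(NA_character_, nrow(vm))
  excluded_by[te_s > vm$raw_score] <- "TE"
  excluded_by[is.na(excluded_by) & host_s > vm$raw_score] <- "HOST"
  data.frame(query_id = vm$query_id, subject_id = vm$subject_id,
             raw_score = vm$raw_score, excluded_by = excluded_by,
             stringsAsFactors = FALSE)
}
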