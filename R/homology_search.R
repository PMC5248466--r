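#' Protein alignment scoring scheme
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul statistical parameters used to convert raw local-alignment
#' scores to bit scores and E-values. The defaults (BLOSUM62, gap open 11,
#' gap extend 1, lambda = 0.267, K = 0.041) are the standard gapped protein
#' search parameterisation; all are configurable.
#'
#' @param matrix substitution matrix name (a matrix bundled with Biostrings,
#'   e.g. "BLOSUM62") or a named square integer matrix
#' @param gap_open,gap_extend positive gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`
#' @param lambda,K positive Karlin-Altschul parameters
#' @return an object of class `scoring_scheme`
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11L,
                           gap_extend = 1L, lambda = 0.267, K = 0.041) {
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  stopifnot(is.matrix(matrix), identical(rownames(matrix), colnames(matrix)))
  if (gap_open < gap_extend || gap_extend < 1)
    abort("require gap_open >= gap_extend >= 1")
  if (lambda <= 0 || K <= 0) abort("lambda and K must be positive")
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring scheme: %dx%d matrix, gap %d/%d, lambda=%g K=%g\n",
              nrow(x$matrix), ncol(x$matrix), x$gap_open, x$gap_extend,
              x$lambda, x$K))
  invisible(x)
}

# raw local-alignment scores for all query x subject pairs (integer matrix)
sw_score_matrix <- function(queries, subjects, scheme = scoring_scheme()) {
  queries <- normalize_aa(as_named_chr(queries), "query")
  subjects <- normalize_aa(as_named_chr(subjects), "subject")
  m <- sw_score_matrix_cpp(unname(queries), unname(subjects),
                           scheme$matrix, rownames(scheme$matrix),
                           scheme$gap_open, scheme$gap_extend)
  dimnames(m) <- list(names(queries), names(subjects))
  m
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman local alignment under affine gap penalties (Gotoh
#' recurrences); opening a gap is charged `gap_open + gap_extend` on its
#' first residue. The traceback is deterministic: the first maximal cell in
#' row-major order is used, and ties between moves are resolved preferring
#' the diagonal, then a gap in the subject, then a gap in the query, so
#' results are reproducible across platforms.
#'
#' @param query,subject protein strings (20 amino acids + X)
#' @param scheme a [scoring_scheme()]
#' @return list of class `alignment_result`: `raw_score`, `identities`,
#'   `aln_length` (alignment columns including gaps), `query_span` and
#'   `subject_span` (0-based half-open), `query_aligned`, `subject_aligned`.
#'   When no cell scores above zero, `raw_score` is 0 and the spans are `NULL`
#'   (no alignment reported).
#' @export
smith_waterman <- function(query, subject, scheme = scoring_scheme()) {
  query <- normalize_aa(query, "query")
  subject <- normalize_aa(subject, "subject")
  r <- sw_align_pairs_cpp(query, subject, scheme$matrix,
                          rownames(scheme$matrix), scheme$gap_open,
                          scheme$gap_extend, TRUE)
  if (r$score[1L] <= 0L) {
    return(structure(list(raw_score = 0L, identities = 0L, aln_length = 0L,
                          query_span = NULL, subject_span = NULL,
                          query_aligned = "", subject_aligned = ""),
                     class = "alignment_result"))
  }
  structure(list(
    raw_score = r$score[1L],
    identities = r$identities[1L],
    aln_length = r$aln_length[1L],
    query_span = c(r$query_start[1L] - 1L, r$query_end[1L]),
    subject_span = c(r$subject_start[1L] - 1L, r$subject_end[1L]),
    query_aligned = r$query_aligned[1L],
    subject_aligned = r$subject_aligned[1L]),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  if (x$raw_score == 0L) {
    cat("local alignment: no positive-scoring alignment\n")
  } else {
    cat(sprintf(
      "local alignment: score %d, %d/%d identities, query %d-%d, subject %d-%d\n",
      x$raw_score, x$identities, x$aln_length,
      x$query_span[1L] + 1L, x$query_span[2L],
      x$subject_span[1L] + 1L, x$subject_span[2L]))
  }
  invisible(x)
}

#' Karlin-Altschul E-value
#'
#' Expected number of chance local alignments with score at least `raw_score`
#' in a search space of `query_len * db_len` residues:
#' `E = K * m * n * exp(-lambda * S)`.
#'
#' @param raw_score integer raw alignment score
#' @param query_len query length in residues
#' @param db_len summed residue length of the database searched
#' @param scheme a [scoring_scheme()] supplying lambda and K
#' @return E-value (vectorised over `raw_score`)
#' @export
evalue <- function(raw_score, query_len, db_len, scheme = scoring_scheme()) {
  if (any(query_len <= 0) || any(db_len <= 0)) abort("lengths must be positive")
  scheme$K * as.numeric(query_len) * as.numeric(db_len) *
    exp(-scheme$lambda * raw_score)
}

#' Bit score of a raw alignment score
#'
#' `bits = (lambda * S - ln K) / ln 2`, so that
#' `E = m * n * 2^(-bits)`.
#'
#' @inheritParams evalue
#' @return bit score (vectorised)
#' @export
bit_score <- function(raw_score, scheme = scoring_scheme()) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

# alignment details (identity, coverage, spans) for specific query/subject
# pairs, recomputed with the traceback engine in one vectorised call
.alignment_details <- function(pairs, queries, subjects, scheme) {
  r <- sw_align_pairs_cpp(unname(queries[pairs$query_id]),
                          unname(subjects[pairs$subject_id]),
                          scheme$matrix, rownames(scheme$matrix),
                          scheme$gap_open, scheme$gap_extend, FALSE)
  data.frame(identities = r$identities, aln_length = r$aln_length,
             query_start = r$query_start - 1L, query_end = r$query_end,
             subject_start = r$subject_start - 1L,
             subject_end = r$subject_end)
}

#' Ranked homology search of a protein database
#'
#' Aligns every query against every database entry (exhaustive local
#' alignment; no heuristic seeding) and returns matches ranked per query by
#' raw score (descending), with ties broken by E-value (ascending) and then
#' subject id (lexicographic). E-values use the summed residue length of the
#' database as the search-space size. Matches with raw score below
#' `min_raw_score` are omitted.
#'
#' @param queries named character vector or AAStringSet
#' @param db named character vector or AAStringSet (the database)
#' @param scheme a [scoring_scheme()]
#' @param min_raw_score raw-score floor; default 1 drops empty alignments
#' @param db_tag label recorded in the `db_tag` column
#' @param details `"top"` computes identity/coverage for each query's top hit
#'   only (the quantities downstream filters use); `"all"` computes them for
#'   every reported match
#' @return data.frame of class `homology_matches`: `query_id`, `subject_id`,
#'   `db_tag`, `raw_score`, `bit_score`, `evalue`, `pct_identity`,
#'   `query_coverage_pct`, spans (0-based half-open), `query_length`,
#'   `rank` (per query). Identity/coverage are `NA` for rows whose details
#'   were not requested.
#' @export
search_homologs <- function(queries, db, scheme = scoring_scheme(),
                            min_raw_score = 1L, db_tag = "db",
                            details = c("top", "all")) {
  details <- match.arg(details)
  queries <- normalize_aa(as_named_chr(queries), "query")
  db <- normalize_aa(as_named_chr(db), "database")
  if (length(db) == 0L) abort("empty database")
  if (anyDuplicated(names(db))) abort("duplicated database ids")
  sc <- sw_score_matrix(queries, db, scheme)
  db_len <- sum(nchar(db))
  hit <- which(sc >= min_raw_score, arr.ind = TRUE)
  m <- data.frame(
    query_id = names(queries)[hit[, 1L]],
    subject_id = names(db)[hit[, 2L]],
    db_tag = db_tag,
    raw_score = sc[hit],
    stringsAsFactors = FALSE)
  m$query_length <- nchar(queries)[hit[, 1L]]
  m$bit_score <- bit_score(m$raw_score, scheme)
  m$evalue <- evalue(m$raw_score, m$query_length, db_len, scheme)
  # rank: raw score desc, then evalue asc, then subject id
  o <- order(m$query_id, -m$raw_score, m$evalue, m$subject_id)
  m <- m[o, , drop = FALSE]
  m$rank <- stats::ave(m$raw_score, m$query_id,
                       FUN = function(x) seq_along(x))
  need <- if (details == "all") seq_len(nrow(m)) else which(m$rank == 1)
  m$identities <- NA_integer_; m$aln_length <- NA_integer_
  m$query_start <- NA_integer_; m$query_end <- NA_integer_
  m$subject_start <- NA_integer_; m$subject_end <- NA_integer_
  if (length(need)) {
    det <- .alignment_details(m[need, , drop = FALSE], queries, db, scheme)
    for (col in names(det)) m[[col]][need] <- det[[col]]
  }
  m$pct_identity <- 100 * m$identities / m$aln_length
  m$query_coverage_pct <- 100 * (m$query_end - m$query_start) / m$query_length
  rownames(m) <- NULL
  class(m) <- c("homology_matches", "data.frame")
  m
}

#' Best hit per query
#'
#' The top-ranked match for each query (the "top hit by score" rule used for
#' all downstream analyses).
#'
#' @param matches output of [search_homologs()]
#' @return data.frame with one row per query that had any match
#' @export
top_hits <- function(matches) {
  out <- matches[matches$rank == 1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read tabular homology search results
#'
#' Parses the 12-column tabular search dialect (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`), with an
#' optional 13th query-coverage column; rows of either width may be mixed.
#' Input coordinates are 1-based inclusive and are converted to the internal
#' 0-based half-open convention. When the coverage column is absent, query
#' coverage is computed from `qstart`/`qend` and `query_lengths`.
#'
#' @param path file path (or connection) of the tabular results
#' @param query_lengths named integer vector of query lengths; required to
#'   compute coverage for 12-column rows
#' @param db_tag label recorded in the `db_tag` column
#' @return `homology_matches` data.frame (raw scores are not carried by the
#'   tabular dialect and are reported as `NA`; ranking uses E-value)
#' @export
read_tabular_matches <- function(path, query_lengths = NULL, db_tag = "db") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L & nf != 13L)
  if (length(bad))
    abort("malformed tabular row %d: %d columns (expected 12 or 13)",
          bad[1L], nf[bad[1L]])
  num <- function(i) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[`, "", i)))
    if (anyNA(v)) abort("malformed tabular row %d: non-numeric field %d",
                        which(is.na(v))[1L], i)
    v
  }
  m <- data.frame(
    query_id = vapply(fields, `[`, "", 1L),
    subject_id = vapply(fields, `[`, "", 2L),
    db_tag = db_tag,
    pct_identity = num(3L),
    aln_length = as.integer(num(4L)),
    mismatch = as.integer(num(5L)),
    gapopen = as.integer(num(6L)),
    query_start = as.integer(num(7L)) - 1L,
    query_end = as.integer(num(8L)),
    subject_start = as.integer(num(9L)) - 1L,
    subject_end = as.integer(num(10L)),
    evalue = num(11L),
    bit_score = num(12L),
    stringsAsFactors = FALSE)
  cov13 <- rep(NA_real_, nrow(m))
  if (any(nf == 13L))
    cov13[nf == 13L] <- suppressWarnings(as.numeric(
      vapply(fields[nf == 13L], `[`, "", 13L)))
  need_len <- is.na(cov13)
  if (any(need_len)) {
    if (is.null(query_lengths))
      abort("query_lengths needed to compute coverage for 12-column rows")
    unknown <- setdiff(unique(m$query_id[need_len]), names(query_lengths))
    if (length(unknown))
      abort("unknown query id '%s' when computing coverage", unknown[1L])
    qlen <- query_lengths[m$query_id[need_len]]
    cov13[need_len] <- 100 * (m$query_end[need_len] - m$query_start[need_len]) /
      qlen
  }
  m$query_coverage_pct <- cov13
  m$query_length <- if (is.null(query_lengths)) NA_integer_ else
    as.integer(query_lengths[m$query_id])
  m$raw_score <- NA_integer_
  m$identities <- as.integer(round(m$pct_identity * m$aln_length / 100))
  o <- order(m$query_id, m$evalue, -m$bit_score, m$subject_id)
  m <- m[o, , drop = FALSE]
  m$rank <- stats::ave(m$evalue, m$query_id, FUN = function(x) seq_along(x))
  rownames(m) <- NULL
  class(m) <- c("homology_matches", "data.frame")
  m
}

#' Write matches in the 12/13-column tabular dialect
#'
#' Coordinates are converted back to 1-based inclusive. The 13th column
#' carries query coverage so that a round-trip through
#' [read_tabular_matches()] preserves it.
#'
#' @param matches `homology_matches` data.frame
#' @param path output path
#' @param coverage_column write the 13th (query coverage) column
#' @return invisibly, `path`
#' @export
write_tabular_matches <- function(matches, path, coverage_column = TRUE) {
  mm <- matches
  mismatch <- if ("mismatch" %in% names(mm)) mm$mismatch else
    mm$aln_length - mm$identities
  gapopen <- if ("gapopen" %in% names(mm)) mm$gapopen else 0L
  out <- data.frame(
    mm$query_id, mm$subject_id,
    sprintf("%.3f", mm$pct_identity), mm$aln_length, mismatch, gapopen,
    mm$query_start + 1L, mm$query_end,
    mm$subject_start + 1L, mm$subject_end,
    sprintf("%.3g", mm$evalue), sprintf("%.1f", mm$bit_score))
  if (coverage_column) out$cov <- sprintf("%.3f", mm$query_coverage_pct)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a protein FASTA into a named character vector
#' @param path FASTA file
#' @return named character vector
#' @export
read_protein_fasta <- function(path) {
  as_named_chr(Biostrings::readAAStringSet(path))
}

#' Read a nucleotide FASTA into a named character vector
#' @param path FASTA file
#' @return named character vector
#' @export
read_dna_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as_named_chr(x)
  # FASTA headers may carry descriptions; keep the first word as the id
  names(out) <- vapply(strsplit(names(out), "\\s+"), `[`, "", 1L)
  out
}

#' Write a named character vector of sequences as FASTA
#' @param x named character vector (nucleotide or protein)
#' @param path output path
#' @param type `"AA"` or `"DNA"`
#' @return invisibly, `path`
#' @export
write_fasta <- function(x, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  ss <- if (type == "AA") Biostrings::AAStringSet(x) else
    Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
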