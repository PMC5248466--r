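#' Read per-category genome TE statistics
#'
#' TSV with columns `category`, `level` (`ORDER` or `CLADE`), `genome_pct`
#' (percent of the genome derived from the category), `copy_number`
#' (genomic copies; `NA` when unknown) and `db_entries` (entries for the
#' category in the TE database used for calling).
#'
#' @param path TSV file
#' @return data.frame of class `te_genome_stats`
#' @export
read_te_stats <- function(path) {
  df <- read_tsv_file(path)
  need <- c("category", "level", "genome_pct", "copy_number", "db_entries")
  if (!all(need %in% names(df)))
    abort("TE stats table needs columns: %s", paste(need, collapse = ", "))
  class(df) <- c("te_genome_stats", "data.frame")
  df
}

#' Count TE calls per category
#'
#' @param calls `te_calls` data.frame
#' @param level `"order"`, `"clade"` or `"orf_type"`
#' @param categories optional category universe; categories with zero calls
#'   are reported as 0 (defaults to the categories present in the calls)
#' @return named integer vector of counts (sums to `nrow(calls)` when
#'   `categories` covers all calls)
#' @export
count_calls <- function(calls, level = c("order", "clade", "orf_type"),
                        categories = NULL) {
  level <- match.arg(level)
  vals <- calls[[level]]
  if (nrow(calls) && any(is.na(vals) | !nzchar(vals)))
    abort("a call lacks %s metadata", level)
  if (is.null(categories)) categories <- sort(unique(vals))
  counts <- stats::setNames(integer(length(categories)), categories)
  tab <- table(vals)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Relative enrichment of TE-protein counts
#'
#' Normalises per-category protein counts by the category's representation
#' (genome percentage, genomic copy number, or number of database entries)
#' and expresses each normalised rate relative to a reference category:
#' `ratio_c = (count_c / norm_c) / (count_ref / norm_ref)`, so the reference
#' has ratio 1 by construction. Categories with an unknown or zero
#' normaliser get an `NA` ratio and are flagged, never dropped. Orders that
#' do not encode their own proteins (SINE, MITE) are excluded by default.
#'
#' @param counts named integer vector from [count_calls()]
#' @param stats [read_te_stats()] table (rows at the matching level)
#' @param normalizer `"GENOME_PCT"`, `"COPY_NUMBER"` or `"DB_ENTRIES"`
#' @param reference reference category (must have a positive count and a
#'   known positive normaliser)
#' @param exclude character vector of categories to drop before normalising
#'   (default the non-autonomous orders SINE and MITE)
#' @return data.frame of class `enrichment_table`: `category`, `count`,
#'   `norm`, `ratio`, `undefined`
#' @export
relative_enrichment <- function(counts, stats,
                                normalizer = c("GENOME_PCT", "COPY_NUMBER",
                                               "DB_ENTRIES"),
                                reference,
                                exclude = c("SINE", "MITE")) {
  normalizer <- match.arg(normalizer)
  col <- c(GENOME_PCT = "genome_pct", COPY_NUMBER = "copy_number",
           DB_ENTRIES = "db_entries")[[normalizer]]
  counts <- counts[!names(counts) %in% exclude]
  if (!reference %in% names(counts)) abort("reference '%s' not in counts",
                                           reference)
  norm <- stats[[col]][match(names(counts), stats$category)]
  ref_count <- counts[[reference]]
  ref_norm <- norm[match(reference, names(counts))]
  if (is.na(ref_norm) || ref_norm <= 0)
    abort("reference '%s' has unknown or zero %s", reference, col)
  if (ref_count <= 0) abort("reference '%s' has zero calls", reference)
  rate <- as.numeric(counts) / norm
  ratio <- rate / (ref_count / ref_norm)
  undefined <- is.na(norm) | norm <= 0
  ratio[undefined] <- NA_real_
  out <- data.frame(category = names(counts), count = as.integer(counts),
                    norm = norm, ratio = ratio, undefined = undefined,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "normalizer") <- normalizer
  attr(out, "reference") <- reference
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Distinct-element counts per clade and ORF type
#'
#' For TEs encoding multiple ORFs, counts for each clade and ORF type the
#' number of distinct elements for which that ORF was detected (an element
#' detected through several protein calls to the same ORF counts once).
#'
#' @param calls `te_calls` data.frame
#' @return integer matrix, clades x ORF types (empty matrix for no calls)
#' @export
orf_breakdown <- function(calls) {
  if (!nrow(calls)) {
    return(matrix(integer(), 0L, 0L))
  }
  # element id: strip a trailing ORF designation from te_id when present so
  # gag and pol entries of one element share an id; te_ids are expected as
  # "<element>_<orf>" from the database builder, otherwise used as-is
  element <- sub("_(gag|pol|env|orf1|orf2|transposase|rep_helicase)$", "",
                 tolower(calls$te_id))
  u <- unique(data.frame(clade = calls$clade, orf_type = calls$orf_type,
                         element = element, stringsAsFactors = FALSE))
  tab <- table(u$clade, u$orf_type)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}
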