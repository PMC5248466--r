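#' Translate an open reading frame
#'
#' Translates a nucleotide sequence with the standard genetic code. Any codon
#' containing an ambiguous base (N) translates to `X`. A single trailing stop
#' codon is trimmed; an internal stop codon is an error, because the input is
#' expected to be a single uninterrupted ORF.
#'
#' @param nt nucleotide string (DNA; RNA `U` and lowercase are tolerated),
#'   length divisible by 3
#' @return amino-acid string
#' @examples
#' translate_orf("ATGAAATAA")  # "MK"
#' translate_orf("ATGNNNTAA")  # "MX"
#' @export
translate_orf <- function(nt) {
  nt <- normalize_nt(nt, "ORF sequence")
  n <- nchar(nt)
  if (n %% 3L != 0L) abort("ORF length (%d) is not divisible by 3", n)
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"  # codons with N
  k <- length(aa)
  if (aa[k] == "*") aa <- aa[-k]
  if (any(aa == "*")) abort("internal stop codon at codon %d",
                            which(aa == "*")[1L])
  paste(aa, collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# ORFs in the three frames of one strand of `s` (already oriented). Returns a
# data.frame in working-strand codon coordinates.
.orfs_one_strand <- function(s, min_nt) {
  n <- nchar(s)
  out <- vector("list", 3L)
  for (off in 0:2) {
    ncod <- (n - off) %/% 3L
    if (ncod < 1L) next
    starts <- off + seq(1L, by = 3L, length.out = ncod)
    codons <- substring(s, starts, starts + 2L)
    stop_idx <- which(codons %in% STOP_CODONS)
    seg_from <- c(1L, stop_idx + 1L)
    seg_to <- c(stop_idx - 1L, ncod)
    keep <- seg_from <= seg_to
    seg_from <- seg_from[keep]; seg_to <- seg_to[keep]
    recs <- list()
    is_atg <- codons == "ATG"
    for (i in seq_along(seg_from)) {
      a <- seg_from[i]; b <- seg_to[i]
      m <- which(is_atg[a:b])
      if (length(m) == 0L) next
      m <- a + m[1L] - 1L                    # longest-per-stop: first ATG
      len_nt <- 3L * (b - m + 1L)
      if (len_nt <= min_nt) next
      aa <- unname(Biostrings::GENETIC_CODE[codons[m:b]])
      aa[is.na(aa)] <- "X"
      recs[[length(recs) + 1L]] <- data.frame(
        offset = off,
        start = off + (m - 1L) * 3L,         # 0-based in working strand
        end = off + b * 3L,
        nt_length = len_nt,
        protein = paste(aa, collapse = ""),
        stringsAsFactors = FALSE)
    }
    if (length(recs)) out[[off + 1L]] <- do.call(rbind, recs)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out)) do.call(rbind, out) else NULL
}

#' Six-frame ORF extraction
#'
#' Finds every maximal open reading frame in all six frames of a transcript:
#' a span from an ATG start codon to the last sense codon before the next
#' in-frame stop (or to the transcript edge when no stop follows; de novo
#' transcripts are frequently 3'-truncated). Nested ATGs within a retained ORF
#' are not reported separately (longest-per-stop rule). Only ORFs whose length,
#' counted from the start codon through the last sense codon and excluding the
#' stop, is strictly greater than `min_nt` are returned.
#'
#' @param sequence transcript nucleotide sequence
#' @param transcript_id identifier used to build ORF ids
#' @param min_nt minimum ORF length in nucleotides (exclusive bound; >= 3).
#'   The default 200 retains ORFs longer than 200 nt.
#' @return data.frame with columns `orf_id`, `transcript_id`, `frame`
#'   (+1,+2,+3,-1,-2,-3), `start`, `end` (0-based half-open on the forward
#'   strand of the transcript), `nt_length`, `protein`
#' @export
six_frame_orfs <- function(sequence, transcript_id = "transcript",
                           min_nt = 200L) {
  if (min_nt < 3L) abort("min_nt must be >= 3")
  s <- normalize_nt(sequence, "transcript sequence")
  L <- nchar(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

  fwd <- .orfs_one_strand(s, min_nt)
  rev <- .orfs_one_strand(rc, min_nt)
  res <- list()
  if (!is.null(fwd)) {
    fwd$frame <- fwd$offset + 1L
    res[[1L]] <- fwd
  }
  if (!is.null(rev)) {
    # map [start, end) on the reverse complement back to forward coordinates
    new_start <- L - rev$end
    rev$end <- L - rev$start
    rev$start <- new_start
    rev$frame <- -(rev$offset + 1L)
    res[[2L]] <- rev
  }
  if (!length(res)) {
    return(data.frame(orf_id = character(), transcript_id = character(),
                      frame = integer(), start = integer(), end = integer(),
                      nt_length = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, res)
  orfs$transcript_id <- transcript_id
  orfs$orf_id <- sprintf("%s|%+d|%d-%d", transcript_id, orfs$frame,
                         orfs$start + 1L, orfs$end)
  orfs <- orfs[order(orfs$frame, orfs$start), c("orf_id", "transcript_id",
               "frame", "start", "end", "nt_length", "protein")]
  rownames(orfs) <- NULL
  orfs
}

#' Six-frame ORF extraction over a transcript set
#'
#' @param transcripts named character vector or [Biostrings::DNAStringSet]
#' @param min_nt see [six_frame_orfs()]
#' @return combined ORF data.frame (see [six_frame_orfs()])
#' @export
extract_orfs <- function(transcripts, min_nt = 200L) {
  transcripts <- as_named_chr(transcripts)
  out <- lapply(names(transcripts), function(id) {
    six_frame_orfs(transcripts[[id]], id, min_nt = min_nt)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recover the nucleotide sequence of an ORF record
#'
#' Extracts the coding nucleotides of one ORF row from its transcript,
#' reverse-complementing for negative frames, so that
#' `translate_orf(orf_nt_sequence(...)) == protein`.
#'
#' @param orf one-row slice of an ORF data.frame
#' @param transcripts named character vector of transcript sequences
#' @return nucleotide string
#' @export
orf_nt_sequence <- function(orf, transcripts) {
  transcripts <- as_named_chr(transcripts)
  s <- transcripts[[orf$transcript_id]]
  if (is.null(s)) abort("unknown transcript '%s'", orf$transcript_id)
  sub <- substr(s, orf$start + 1L, orf$end)
  if (orf$frame < 0L) {
    sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  }
  sub
}

#' Write extracted ORFs
#'
#' Writes the ORF proteins as FASTA plus a TSV sidecar with the coordinate
#' metadata (coordinates reported 1-based inclusive).
#'
#' @param orfs ORF data.frame from [extract_orfs()]
#' @param fasta_path,tsv_path output paths
#' @return invisibly, a list of the two paths
#' @export
write_orfs <- function(orfs, fasta_path, tsv_path) {
  aa <- Biostrings::AAStringSet(orfs$protein)
  names(aa) <- orfs$orf_id
  Biostrings::writeXStringSet(aa, fasta_path)
  side <- orfs[, c("orf_id", "transcript_id", "frame", "start", "end",
                   "nt_length")]
  side$start <- side$start + 1L    # report 1-based inclusive
  write_tsv_file(side, tsv_path)
  invisible(list(fasta = fasta_path, tsv = tsv_path))
}

#' Read peptide evidence
#'
#' Peptide evidence is a TSV with columns `peptide` and `orf_ids`
#' (comma-separated ORF identifiers the peptide matched).
#'
#' @param path TSV file
#' @return data.frame with columns `peptide` (character) and `orf_ids`
#'   (list column of character vectors)
#' @export
read_peptide_evidence <- function(path) {
  df <- read_tsv_file(path)
  if (!all(c("peptide", "orf_ids") %in% names(df)))
    abort("peptide evidence must have columns 'peptide' and 'orf_ids'")
  df$orf_ids <- strsplit(df$orf_ids, ",", fixed = TRUE)
  validate_evidence(df)
  df
}

#' Write peptide evidence
#' @param evidence evidence data.frame (list-column `orf_ids`)
#' @param path output TSV
#' @return invisibly, `path`
#' @export
write_peptide_evidence <- function(evidence, path) {
  out <- data.frame(peptide = evidence$peptide,
                    orf_ids = vapply(evidence$orf_ids, paste, "",
                                     collapse = ","),
                    stringsAsFactors = FALSE)
  write_tsv_file(out, path)
}

validate_evidence <- function(evidence) {
  if (any(nchar(evidence$peptide) < 6L))
    abort("peptides shorter than 6 residues are not valid evidence")
  if (any(lengths(evidence$orf_ids) == 0L))
    abort("every peptide must match at least one ORF")
  invisible(evidence)
}

#' Group ORFs by shared peptide support
#'
#' ORFs supported by an identical set of peptides are indistinguishable by the
#' evidence and are merged into one protein group. `n_peptides` counts the
#' distinct peptides supporting each group. ORFs with no peptide evidence are
#' not grouped. Filtering on a minimum peptide count (1 vs 2) is left to the
#' summary stage.
#'
#' @param evidence data.frame with `peptide` and list-column `orf_ids`
#' @param orfs ORF data.frame (used to check that evidence references real
#'   ORFs)
#' @return data.frame with columns `group_id`, `orf_ids` (comma-joined),
#'   `n_orfs`, `n_peptides`
#' @export
group_peptides <- function(evidence, orfs) {
  validate_evidence(evidence)
  all_ids <- unique(unlist(evidence$orf_ids))
  dangling <- setdiff(all_ids, orfs$orf_id)
  if (length(dangling))
    abort("peptide evidence references unknown ORF id(s): %s",
          paste(utils::head(dangling, 3L), collapse = ", "))
  # distinct peptides only: identical peptide strings carry one unit of
  # evidence, and their ORF sets must be identical by construction
  pep <- !duplicated(evidence$peptide)
  peptides <- evidence$peptide[pep]
  sets <- evidence$orf_ids[pep]
  # per-ORF support signature
  orf2pep <- split(rep(seq_along(peptides), lengths(sets)), unlist(sets))
  sig <- vapply(orf2pep, function(i) paste(sort(unique(i)), collapse = ","), "")
  grp <- split(names(sig), sig)
  first_orf <- vapply(grp, function(ids) sort(ids)[1L], "")
  o <- order(first_orf)
  grp <- grp[o]
  npep <- vapply(names(grp), function(s)
    length(strsplit(s, ",", fixed = TRUE)[[1L]]), 1L)
  data.frame(
    group_id = sprintf("PG%04d", seq_along(grp)),
    orf_ids = vapply(grp, function(ids) paste(sort(ids), collapse = ","), ""),
    n_orfs = lengths(grp),
    n_peptides = unname(npep),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Pick one representative ORF per protein group
#'
#' The longest member ORF (ties broken by ORF id) represents its group in
#' downstream homology searches.
#'
#' @param groups output of [group_peptides()]
#' @param orfs ORF data.frame
#' @return data.frame `group_id`, `orf_id`, `transcript_id`, `protein`
#' @export
group_representatives <- function(groups, orfs) {
  rownames(orfs) <- orfs$orf_id
  rep_orf <- vapply(strsplit(groups$orf_ids, ",", fixed = TRUE), function(ids) {
    cand <- orfs[ids, , drop = FALSE]
    cand <- cand[order(-cand$nt_length, cand$orf_id), , drop = FALSE]
    cand$orf_id[1L]
  }, "")
  data.frame(group_id = groups$group_id,
             orf_id = rep_orf,
             transcript_id = orfs[rep_orf, "transcript_id"],
             protein = orfs[rep_orf, "protein"],
             stringsAsFactors = FALSE, row.names = NULL)
}
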