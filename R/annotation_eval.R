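# --- transcript-to-genome alignment (built-in near-exact mapper) ----------

# stop position for an extension: cut at the first run of two consecutive
# mismatches, then drop trailing mismatches
.ext_len <- function(eq) {
  if (!length(eq)) return(0L)
  bad <- which(!eq)
  if (length(bad) > 1L) {
    pair <- bad[c(diff(bad) == 1L, FALSE)]
    stop_at <- if (length(pair)) pair[1L] - 1L else length(eq)
  } else stop_at <- length(eq)
  while (stop_at > 0L && !eq[stop_at]) stop_at <- stop_at - 1L
  stop_at
}

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

#' Align transcripts to a genome assembly
#'
#' A seed-and-extend near-exact spliced mapper intended for transcripts with
#' low divergence from the assembly (a few percent substitutions): exact
#' k-mer seeds are located with an Aho-Corasick dictionary scan, grouped by
#' diagonal on each supercontig and strand, extended allowing isolated
#' substitutions (extension stops at two consecutive mismatches), and
#' diagonal groups separated by a genomic gap up to `max_intron` are joined
#' into one spliced hit whose blocks are the exons. Transcripts producing no
#' seed hits are reported as unaligned (absent from the result), not as an
#' error. Externally computed alignments can be substituted for this mapper
#' anywhere a hit table is consumed.
#'
#' @param transcripts named character vector or DNAStringSet
#' @param genome named character vector or DNAStringSet of supercontigs
#' @param k seed length (nt)
#' @param stride distance between seed start positions (nt)
#' @param max_intron maximum genomic gap joined as an intron (nt)
#' @param min_seed_hits minimum seeds supporting a diagonal group
#' @return data.frame of class `genome_hits`, one row per hit:
#'   `transcript_id`, `supercontig`, `strand`, `n_blocks`,
#'   `block_starts`/`block_ends` (comma-joined, 1-based inclusive, genome
#'   forward strand), `span_start`, `span_end`, `matches`, `aligned_nt`,
#'   `pct_identity`, `transcript_coverage_pct`, `score` (= matched bases),
#'   `transcript_length`
#' @export
align_transcripts <- function(transcripts, genome, k = 16L, stride = 25L,
                              max_intron = 20000L, min_seed_hits = 2L) {
  transcripts <- as_named_chr(transcripts)
  genome <- as_named_chr(genome)
  if (!length(genome)) abort("empty genome")
  tl <- nchar(transcripts)

  # seeds from the forward transcript (+) and its reverse complement (-),
  # both matched against the forward genome
  seed_tab <- list()
  seqs <- list()
  for (i in seq_along(transcripts)) {
    id <- names(transcripts)[i]
    if (tl[i] < k) next
    fwd <- transcripts[[i]]
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fwd)))
    pos <- unique(c(seq(1L, tl[i] - k + 1L, by = stride), tl[i] - k + 1L))
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rev
      sd <- substring(s, pos, pos + k - 1L)
      keep <- !grepl("N", sd, fixed = TRUE)
      if (!any(keep)) next
      seqs[[paste0(id, strand)]] <- s
      seed_tab[[length(seed_tab) + 1L]] <- data.frame(
        tid = id, strand = strand, tpos = pos[keep], seed = sd[keep],
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(transcript_id = character(), supercontig = character(),
                      strand = character(), n_blocks = integer(),
                      block_starts = character(), block_ends = character(),
                      span_start = integer(), span_end = integer(),
                      matches = integer(), aligned_nt = integer(),
                      pct_identity = numeric(),
                      transcript_coverage_pct = numeric(), score = integer(),
                      transcript_length = integer(), stringsAsFactors = FALSE)
  if (!length(seed_tab)) return(structure(empty, class = c("genome_hits",
                                                           "data.frame")))
  seeds <- do.call(rbind, seed_tab)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds$seed))

  hits <- list()
  for (contig in names(genome)) {
    gseq <- genome[[contig]]
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(gseq))
    starts <- Biostrings::startIndex(m)   # plain list: fast extraction
    n_hit <- lengths(starts)
    if (!sum(n_hit)) next
    idx <- rep(seq_along(n_hit), n_hit)
    df <- data.frame(tid = seeds$tid[idx], strand = seeds$strand[idx],
                     tpos = seeds$tpos[idx], gstart = unlist(starts),
                     stringsAsFactors = FALSE)
    df$diag <- df$gstart - df$tpos
    df$contig <- contig
    hits[[contig]] <- df
  }
  if (!length(hits)) return(structure(empty, class = c("genome_hits",
                                                       "data.frame")))
  allh <- do.call(rbind, hits)

  out <- list()
  grp <- split(allh, list(allh$tid, allh$strand, allh$contig), drop = TRUE)
  for (g in grp) {
    tid <- g$tid[1L]; strand <- g$strand[1L]; contig <- g$contig[1L]
    tseq <- seqs[[paste0(tid, strand)]]
    gseq <- genome[[contig]]
    glen <- nchar(gseq)
    tlen <- nchar(tseq)
    # one candidate block per diagonal
    blocks <- list()
    for (d in unique(g$diag)) {
      sub <- g[g$diag == d, , drop = FALSE]
      if (nrow(sub) < min_seed_hits && length(unique(g$diag)) > 1L) next
      t1 <- min(sub$tpos); t2 <- max(sub$tpos) + k - 1L
      # extend left (bounded by transcript and genome starts)
      nl <- min(t1 - 1L, t1 + d - 1L)
      if (nl > 0L) {
        a <- rev(.chars(substr(tseq, t1 - nl, t1 - 1L)))
        b <- rev(.chars(substr(gseq, t1 + d - nl, t1 + d - 1L)))
        e <- .ext_len(a == b)
        t1 <- t1 - e
      }
      # extend right
      nr <- min(tlen - t2, glen - (t2 + d))
      if (nr > 0L) {
        a <- .chars(substr(tseq, t2 + 1L, t2 + nr))
        b <- .chars(substr(gseq, t2 + d + 1L, t2 + d + nr))
        e <- .ext_len(a == b)
        t2 <- t2 + e
      }
      blocks[[length(blocks) + 1L]] <- c(t1 = t1, t2 = t2, d = d)
    }
    if (!length(blocks)) next
    bl <- as.data.frame(do.call(rbind, blocks))
    bl <- bl[order(bl$t1, bl$d), , drop = FALSE]
    # chain blocks into hits: transcript and genome positions must both
    # advance, genomic gap at most max_intron, little transcript overlap
    chain_id <- integer(nrow(bl))
    cur <- 1L
    chain_id[1L] <- 1L
    if (nrow(bl) > 1L) {
      for (i in 2:nrow(bl)) {
        prev <- bl[i - 1L, ]
        this <- bl[i, ]
        ovl <- prev$t2 - this$t1 + 1L
        small <- min(prev$t2 - prev$t1, this$t2 - this$t1) + 1L
        joinable <- this$d > prev$d &&
          (this$d - prev$d) <= max_intron &&
          ovl < 0.5 * small
        if (!joinable) cur <- cur + 1L
        chain_id[i] <- cur
      }
    }
    for (cid in unique(chain_id)) {
      cb <- bl[chain_id == cid, , drop = FALSE]
      # trim transcript overlaps between consecutive blocks
      if (nrow(cb) > 1L) {
        for (i in 1:(nrow(cb) - 1L)) {
          if (cb$t2[i] >= cb$t1[i + 1L]) cb$t2[i] <- cb$t1[i + 1L] - 1L
        }
        cb <- cb[cb$t2 >= cb$t1, , drop = FALSE]
      }
      matches <- 0L; aligned <- 0L
      for (i in seq_len(nrow(cb))) {
        a <- .chars(substr(tseq, cb$t1[i], cb$t2[i]))
        b <- .chars(substr(gseq, cb$t1[i] + cb$d[i], cb$t2[i] + cb$d[i]))
        matches <- matches + sum(a == b)
        aligned <- aligned + length(a)
      }
      gs <- cb$t1 + cb$d; ge <- cb$t2 + cb$d
      # map block transcript coords are in oriented space; genome coords are
      # already forward-strand
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = tid, supercontig = contig, strand = strand,
        n_blocks = nrow(cb),
        block_starts = paste(gs, collapse = ","),
        block_ends = paste(ge, collapse = ","),
        span_start = min(gs), span_end = max(ge),
        matches = matches, aligned_nt = aligned,
        pct_identity = 100 * matches / aligned,
        transcript_coverage_pct = 100 * aligned / tl[[tid]],
        score = matches, transcript_length = tl[[tid]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(structure(empty, class = c("genome_hits",
                                                      "data.frame")))
  res <- do.call(rbind, out)
  res <- res[order(res$transcript_id, -res$score), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("genome_hits", "data.frame")
  res
}

# --- triage ----------------------------------------------------------------

TRIAGE_CATEGORIES <- c("NO_MATCH", "ALREADY_ANNOTATED", "AMBIGUOUS",
                       "NEW_ANNOTATION")

#' Triage decision parameters
#'
#' @param min_identity_pct minimum alignment identity for a hit to count
#' @param min_coverage_pct minimum transcript coverage for a hit to count
#' @param ambiguity_margin a transcript is ambiguous when two or more loci
#'   score at least this fraction of its best locus score
#' @return list of class `triage_params`
#' @export
triage_params <- function(min_identity_pct = 90, min_coverage_pct = 50,
                          ambiguity_margin = 0.95) {
  if (ambiguity_margin <= 0 || ambiguity_margin > 1)
    abort("ambiguity_margin must be in (0, 1]")
  structure(list(min_identity_pct = min_identity_pct,
                 min_coverage_pct = min_coverage_pct,
                 ambiguity_margin = ambiguity_margin),
            class = "triage_params")
}

#' Read a gene annotation for triage
#'
#' Imports GFF3 (or anything rtracklayer understands) and keeps exon
#' features; when the file has no exon features, gene (or all) features are
#' used as exon spans.
#'
#' @param path annotation file
#' @return [GenomicRanges::GRanges] of exon spans
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    ex <- gr[gr$type == "exon"]
    if (!length(ex)) ex <- gr[gr$type == "gene"]
    if (length(ex)) return(ex)
  }
  gr
}

#' Triage transcripts against a genome annotation
#'
#' Partitions transcripts into four mutually exclusive categories:
#' `NO_MATCH` (no alignment passes the identity/coverage filters),
#' `AMBIGUOUS` (two or more loci within the ambiguity margin of the best
#' score; such duplicated placements are excluded from downstream analyses),
#' `ALREADY_ANNOTATED` (the best locus overlaps an annotated exon span on
#' the same strand by at least 1 bp) and `NEW_ANNOTATION` (everything else:
#' a confident, unique, unannotated locus).
#'
#' @param hits `genome_hits` from [align_transcripts()] (or imported)
#' @param transcript_ids all transcript ids under triage (so unaligned
#'   transcripts are reported as `NO_MATCH`)
#' @param annotation [GenomicRanges::GRanges] of annotated exon spans, or
#'   `NULL` for none
#' @param params [triage_params()]
#' @return data.frame of class `triage_records`: `transcript_id`,
#'   `category`, `supercontig`, `strand`, `span_start`, `span_end`,
#'   `n_loci`, `pct_identity`, `transcript_coverage_pct`
#' @export
triage <- function(hits, transcript_ids, annotation = NULL,
                   params = triage_params()) {
  ok <- hits[hits$pct_identity >= params$min_identity_pct &
               hits$transcript_coverage_pct >= params$min_coverage_pct, ,
             drop = FALSE]
  res <- data.frame(transcript_id = transcript_ids,
                    category = "NO_MATCH",
                    supercontig = NA_character_, strand = NA_character_,
                    span_start = NA_integer_, span_end = NA_integer_,
                    n_loci = 0L, pct_identity = NA_real_,
                    transcript_coverage_pct = NA_real_,
                    stringsAsFactors = FALSE)
  rownames(res) <- res$transcript_id
  ann <- NULL
  if (!is.null(annotation) && length(annotation)) ann <- annotation
  for (tid in unique(ok$transcript_id)) {
    if (!tid %in% transcript_ids) next
    h <- ok[ok$transcript_id == tid, , drop = FALSE]
    best <- h[which.max(h$score), , drop = FALSE]
    n_loci <- sum(h$score >= params$ambiguity_margin * best$score)
    res[tid, c("supercontig", "strand")] <-
      c(best$supercontig, best$strand)
    res[tid, c("span_start", "span_end")] <-
      c(best$span_start, best$span_end)
    res[tid, "n_loci"] <- n_loci
    res[tid, "pct_identity"] <- best$pct_identity
    res[tid, "transcript_coverage_pct"] <- best$transcript_coverage_pct
    if (n_loci >= 2L) {
      res[tid, "category"] <- "AMBIGUOUS"
      next
    }
    annotated <- FALSE
    if (!is.null(ann)) {
      span <- GenomicRanges::GRanges(
        best$supercontig,
        IRanges::IRanges(best$span_start, best$span_end),
        strand = best$strand)
      # a hit on a supercontig with no annotated feature simply has no
      # overlap; silence the disjoint-seqlevels notice
      annotated <- length(suppressWarnings(GenomicRanges::findOverlaps(
        span, ann, minoverlap = 1L, ignore.strand = FALSE))) > 0L
    }
    res[tid, "category"] <- if (annotated) "ALREADY_ANNOTATED" else
      "NEW_ANNOTATION"
  }
  res$category <- factor(res$category, levels = TRIAGE_CATEGORIES)
  rownames(res) <- NULL
  class(res) <- c("triage_records", "data.frame")
  res
}

# --- sequencing-gap scan ---------------------------------------------------

#' Scan genomic windows around alignments for sequencing gaps
#'
#' For each located transcript, counts N characters (sequencing gaps) in the
#' window extending `flank_nt` bases up- and down-stream of the alignment
#' span, including the span itself (intronic genomic sequence between
#' alignment blocks is inside the span and therefore scanned). Windows are
#' truncated at supercontig ends and the truncation is flagged.
#'
#' @param genome named character vector or DNAStringSet of supercontigs
#' @param located data.frame with `transcript_id`, `supercontig`,
#'   `span_start`, `span_end` (triage records or hits)
#' @param flank_nt window flank (default 5000)
#' @return data.frame of class `gap_scan_records`: `transcript_id`,
#'   `window_start`, `window_end`, `n_count_in_window`, `has_gap`,
#'   `truncated_upstream`, `truncated_downstream`
#' @export
gap_scan <- function(genome, located, flank_nt = 5000L) {
  genome <- as_named_chr(genome)
  located <- located[!is.na(located$supercontig), , drop = FALSE]
  missing <- setdiff(unique(located$supercontig), names(genome))
  if (length(missing)) abort("supercontig '%s' absent from genome",
                             missing[1L])
  n <- nrow(located)
  out <- data.frame(transcript_id = located$transcript_id,
                    supercontig = located$supercontig,
                    window_start = integer(n), window_end = integer(n),
                    n_count_in_window = integer(n), has_gap = logical(n),
                    truncated_upstream = logical(n),
                    truncated_downstream = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    clen <- nchar(genome[[located$supercontig[i]]])
    ws <- located$span_start[i] - flank_nt
    we <- located$span_end[i] + flank_nt
    out$truncated_upstream[i] <- ws < 1L
    out$truncated_downstream[i] <- we > clen
    ws <- max(1L, ws); we <- min(clen, we)
    win <- substr(genome[[located$supercontig[i]]], ws, we)
    nn <- as.integer(Biostrings::letterFrequency(Biostrings::DNAString(win),
                                                 "N"))
    out$window_start[i] <- ws; out$window_end[i] <- we
    out$n_count_in_window[i] <- nn
    out$has_gap[i] <- nn > 0L
  }
  class(out) <- c("gap_scan_records", "data.frame")
  out
}

#' Length-matched control sample
#'
#' Draws, from a pool of candidate transcripts, a control set of the same
#' size as the target set, greedily matched on transcript length without
#' replacement. Deterministic given the seed; ties in length distance are
#' broken by a seeded shuffle of the pool.
#'
#' @param new_lengths named numeric vector of target transcript lengths
#' @param pool_lengths named numeric vector of candidate control lengths
#'   (must be at least as many as targets)
#' @param seed integer seed
#' @return character vector of selected pool ids (same length as
#'   `new_lengths`)
#' @export
matched_control_sample <- function(new_lengths, pool_lengths, seed) {
  if (length(pool_lengths) < length(new_lengths))
    abort("control pool smaller than the target set")
  with_seed(seed, {
    pool <- sample(names(pool_lengths))          # tie-break order
    targets <- sample(names(new_lengths))        # processing order
    chosen <- character(length(targets))
    avail <- rep(TRUE, length(pool))
    plen <- pool_lengths[pool]
    for (i in seq_along(targets)) {
      d <- abs(plen - new_lengths[[targets[i]]])
      d[!avail] <- Inf
      j <- which.min(d)
      chosen[i] <- pool[j]
      avail[j] <- FALSE
    }
    chosen[order(match(targets, names(new_lengths)))]
  })
}

# --- chromosomal enrichment ------------------------------------------------

#' Read a supercontig-to-chromosome map
#'
#' TSV with columns `supercontig`, `chromosome` (1-3 or NA for unplaced) and
#' `band` (cytological band such as "1p3", NA for unplaced).
#'
#' @param path TSV file
#' @return data.frame of class `chromosome_map`
#' @export
read_chromosome_map <- function(path) {
  df <- read_tsv_file(path)
  need <- c("supercontig", "chromosome", "band")
  if (!all(need %in% names(df)))
    abort("chromosome map needs columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$supercontig))
    abort("each supercontig may appear only once in the map")
  class(df) <- c("chromosome_map", "data.frame")
  df
}

#' Per-chromosome enrichment of new annotations
#'
#' For each chromosome, the ratio of supercontigs containing at least one
#' `NEW_ANNOTATION` transcript to all supercontigs mapped to that
#' chromosome, normalised by the genome-wide ratio so that 1 means no
#' enrichment. Supercontigs containing several new annotations count once.
#'
#' @param triage_records [triage()] output
#' @param chr_map [read_chromosome_map()] table
#' @return data.frame: `chromosome`, `mapped_supercontigs`,
#'   `pit_supercontigs`, `raw_ratio`, `normalized_ratio`
#' @export
chromosome_enrichment <- function(triage_records, chr_map) {
  mapped <- chr_map[!is.na(chr_map$chromosome), , drop = FALSE]
  if (!nrow(mapped)) abort("no supercontigs are mapped to chromosomes")
  new_sc <- unique(triage_records$supercontig[
    triage_records$category == "NEW_ANNOTATION"])
  new_sc <- intersect(new_sc, mapped$supercontig)
  chrs <- sort(unique(mapped$chromosome))
  m <- vapply(chrs, function(c) sum(mapped$chromosome == c), 0)
  if (any(m == 0)) abort("chromosome with zero mapped supercontigs")
  p <- vapply(chrs, function(c)
    sum(mapped$supercontig[mapped$chromosome == c] %in% new_sc), 0)
  genome_rate <- sum(p) / sum(m)
  raw <- p / m
  data.frame(chromosome = chrs, mapped_supercontigs = as.integer(m),
             pit_supercontigs = as.integer(p), raw_ratio = raw,
             normalized_ratio = if (genome_rate > 0) raw / genome_rate else
               NA_real_,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Chromosomal band hotspots of new annotation
#'
#' Ranks cytological bands by their count of `NEW_ANNOTATION` transcripts
#' (ties broken by band name) over the universe of bands with at least one
#' mapped supercontig; the top 20% of bands (ceiling) are flagged enriched
#' when their count exceeds 2.
#'
#' @param triage_records [triage()] output
#' @param chr_map [read_chromosome_map()] table
#' @param top_fraction fraction of bands eligible for flagging
#' @param min_count counts must exceed this to be flagged (default 2)
#' @return data.frame: `band`, `new_annotation_count`, `rank`, `enriched`
#' @export
band_hotspots <- function(triage_records, chr_map, top_fraction = 0.2,
                          min_count = 2L) {
  mapped <- chr_map[!is.na(chr_map$band), , drop = FALSE]
  bands <- sort(unique(mapped$band))
  new_rec <- triage_records[triage_records$category == "NEW_ANNOTATION" &
                              !is.na(triage_records$supercontig), ,
                            drop = FALSE]
  band_of <- stats::setNames(mapped$band, mapped$supercontig)
  counts <- table(factor(band_of[new_rec$supercontig], levels = bands))
  out <- data.frame(band = bands,
                    new_annotation_count = as.integer(counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$new_annotation_count, out$band), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  n_top <- ceiling(top_fraction * nrow(out))
  out$enriched <- out$rank <= n_top & out$new_annotation_count > min_count
  rownames(out) <- NULL
  out
}

# --- equal-variance t-test -------------------------------------------------

#' Two-sample t-test for samples of equal variance
#'
#' Pooled-variance two-tailed Student's t-test with
#' `df = length(x) + length(y) - 2`. When the pooled variance is zero with
#' equal means the statistic is defined as 0 with p = 1; zero pooled
#' variance with unequal means is an error.
#'
#' @param x,y numeric vectors (each of length >= 2)
#' @return list: `t`, `df`, `p`
#' @export
ttest_equal_var <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    abort("both samples need at least 2 observations")
  pooled <- ((length(x) - 1) * stats::var(x) +
               (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (pooled == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, df = length(x) + length(y) - 2L, p = 1))
    abort("zero pooled variance with unequal means")
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
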