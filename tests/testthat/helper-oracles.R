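# Independent brute-force oracles used to validate the main algorithms.
# These deliberately share no code with the implementation.

# enumerate all ORFs (frame, start, end) by scanning codons directly
oracle_orfs <- function(seq, min_nt = 200L) {
  seq <- toupper(seq)
  L <- nchar(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  rc <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) seq else rc
    for (off in 0:2) {
      ncod <- (L - off) %/% 3L
      if (ncod < 1L) next
      cods <- substring(s, off + 3 * (seq_len(ncod) - 1) + 1,
                        off + 3 * seq_len(ncod))
      # every ATG start, extended to the stop (or sequence edge)
      cand <- list()
      for (i in which(cods == "ATG")) {
        j <- i
        while (j <= ncod && !(cods[j] %in% stops)) j <- j + 1L
        end_cod <- j - 1L              # last sense codon
        if (end_cod < i) next
        cand[[length(cand) + 1L]] <- c(i, end_cod)
      }
      if (!length(cand)) next
      m <- do.call(rbind, cand)
      # longest-per-stop: keep the earliest ATG for each end codon
      keep <- !duplicated(m[, 2L])
      m <- m[keep, , drop = FALSE]
      for (r in seq_len(nrow(m))) {
        i <- m[r, 1L]; e <- m[r, 2L]
        len <- 3L * (e - i + 1L)
        if (len <= min_nt) next
        s0 <- off + 3L * (i - 1L)      # 0-based on working strand
        e0 <- off + 3L * e
        if (strand == -1L) { tmp <- s0; s0 <- L - e0; e0 <- L - tmp }
        out[[length(out) + 1L]] <- data.frame(
          frame = strand * (off + 1L), start = s0, end = e0,
          nt_length = len)
      }
    }
  }
  if (!length(out)) return(data.frame(frame = integer(), start = integer(),
                                      end = integer(),
                                      nt_length = integer()))
  res <- do.call(rbind, out)
  res[order(res$frame, res$start), , drop = FALSE]
}

# exhaustive local-alignment score: enumerate substring pairs and all
# alignments with at most 2 gap columns; gap runs cost open + L * ext
oracle_sw_score <- function(a, b, sub, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  best <- 0
  layout_score <- function(cols, ai, bj) {
    sc <- 0
    runs <- rle(cols)
    for (r in seq_along(runs$values)) {
      if (runs$values[r] != "M") sc <- sc - (open + ext * runs$lengths[r])
    }
    for (cc in cols) {
      if (cc == "M") {
        sc <- sc + sub[A[ai], B[bj]]; ai <- ai + 1; bj <- bj + 1
      } else if (cc == "GA") bj <- bj + 1 else ai <- ai + 1
    }
    sc
  }
  for (i1 in 1:na) for (i2 in i1:na) for (j1 in 1:nb) for (j2 in j1:nb) {
    p <- i2 - i1 + 1; q <- j2 - j1 + 1
    if (p == q) {   # gapless diagonal alignment
      sc <- sum(sub[cbind(A[i1:i2], B[j1:j2])])
      if (sc > best) best <- sc
    }
    for (ga in 0:2) for (gb in 0:(2 - ga)) {
      if (ga + gb == 0) next
      nM <- p - gb
      if (nM != q - ga || nM < 2) next   # first and last columns must pair
      ncol <- nM + ga + gb
      types <- if (ga + gb == 1) {
        list(if (ga == 1) "GA" else "GB")
      } else if (ga == 2) list(c("GA", "GA")) else if (gb == 2)
        list(c("GB", "GB")) else list(c("GA", "GB"), c("GB", "GA"))
      pos_sets <- utils::combn(2:(ncol - 1), ga + gb, simplify = FALSE)
      for (ps in pos_sets) for (tp in types) {
        cols <- rep("M", ncol)
        cols[ps] <- tp
        sc <- layout_score(cols, i1, j1)
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# brute-force partition of ORFs by identical peptide-support sets
oracle_group <- function(evidence) {
  orfs <- unique(unlist(evidence$orf_ids))
  support <- lapply(orfs, function(o) {
    sort(unique(evidence$peptide[vapply(evidence$orf_ids,
                                        function(s) o %in% s, TRUE)]))
  })
  names(support) <- orfs
  sig <- vapply(support, paste, "", collapse = "\r")
  unname(lapply(split(orfs, sig), sort))
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

random_protein <- function(len) {
  paste(sample(rownames(blosum62)[1:20], len, replace = TRUE),
        collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

TRIAGE_CATEGORIES_LEVELS <- c("NO_MATCH", "ALREADY_ANNOTATED", "AMBIGUOUS",
                              "NEW_ANNOTATION")
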