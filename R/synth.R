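# ---- low-level sequence randomisation (all use the caller's RNG state) ----

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.rand_protein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1L, replace = TRUE), collapse = ""))
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# synonymous codon table (stops excluded), computed once
.syn_codons <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
      tab[["*"]] <<- NULL
    }
    tab
  }
})

# BLOSUM62-weighted substitution distribution: row a gives P(b | substitute a)
.subst_probs <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      b <- e$BLOSUM62[AA20, AA20]
      w <- exp(b / 2)
      diag(w) <- 0
      m <<- sweep(w, 1L, rowSums(w), "/")
    }
    m
  }
})

.mutate_protein_rng <- function(protein, divergence) {
  if (divergence == 0) return(protein)
  aa <- .chars(protein)
  hit <- stats::runif(length(aa)) < divergence
  hit[1L] <- FALSE               # keep the initiator methionine
  hit <- hit & aa %in% AA20      # leave X untouched
  if (any(hit)) {
    pm <- .subst_probs()
    aa[hit] <- vapply(aa[hit], function(a)
      sample(AA20, 1L, prob = pm[a, ]), "")
  }
  paste(aa, collapse = "")
}

#' Mutate a protein to a target divergence
#'
#' Substitutes each site independently with probability `divergence`;
#' replacement residues are drawn from a BLOSUM62-weighted neighbour
#' distribution, emulating the divergence of individual TE copies from
#' their family consensus. Expected identity to the input is
#' `100 * (1 - divergence)` percent. The initiator methionine is preserved.
#'
#' @param protein amino-acid string
#' @param divergence per-site substitution probability in [0, 1)
#' @param seed integer seed (same seed, same output)
#' @return diverged protein string
#' @export
mutate_protein <- function(protein, divergence, seed) {
  if (divergence < 0 || divergence >= 1) abort("divergence must be in [0,1)")
  with_seed(seed, .mutate_protein_rng(protein, divergence))
}

#' Reverse-translate a protein
#'
#' Picks a uniformly random synonymous codon per residue (no stop codon is
#' emitted; append one separately). Uses the caller-visible RNG only inside
#' [with_seed()] scopes in the generator; exported for fixture building.
#'
#' @param protein amino-acid string (no X)
#' @param seed integer seed
#' @return nucleotide string of length `3 * nchar(protein)`
#' @export
reverse_translate <- function(protein, seed) {
  with_seed(seed, .reverse_translate_rng(protein))
}

.reverse_translate_rng <- function(protein) {
  aa <- .chars(protein)
  syn <- .syn_codons()
  paste(vapply(aa, function(a) {
    cods <- syn[[a]]
    if (is.null(cods)) abort("cannot reverse-translate residue '%s'", a)
    cods[sample.int(length(cods), 1L)]
  }, ""), collapse = "")
}

.ztpois <- function(lambda) {
  repeat {
    x <- stats::rpois(1L, lambda)
    if (x > 0L) return(x)
  }
}

.runif_int <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# ---- configuration --------------------------------------------------------

.default_te_families <- function() {
  data.frame(
    family = c("gypsy1", "gypsy2", "bel1", "copia1",
               "jockey1", "r4_1", "l1_1", "mariner1", "mutator1"),
    order = c("LTR", "LTR", "LTR", "LTR",
              "NON_LTR", "NON_LTR", "NON_LTR", "DNA_TIR", "DNA_TIR"),
    clade = c("Ty3/gypsy", "Ty3/gypsy", "BEL", "Ty1/copia",
              "Jockey", "R4", "L1", "IS630-Tc1-mariner", "Mutator"),
    te_class = c("I", "I", "I", "I", "I", "I", "I", "II", "II"),
    orf_types = c("GAG,POL,ENV", "GAG,POL,ENV", "GAG,POL", "GAG,POL",
                  "ORF1,ORF2", "ORF1,ORF2", "ORF1,ORF2",
                  "TRANSPOSASE", "TRANSPOSASE"),
    orf_lengths = c("300,550,250", "280,500,240", "300,520", "280,480",
                    "250,600", "240,580", "250,600", "340", "330"),
    copy_number = c(30L, 18L, 20L, 12L, 25L, 10L, 12L, 40L, 8L),
    copy_number_known = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                          FALSE),
    expressed = c("GAG:5,POL:2,ENV:1", "GAG:3,POL:1", "GAG:3,POL:1",
                  "GAG:1,POL:1", "ORF1:1,ORF2:2", "ORF2:1", "ORF2:1",
                  "TRANSPOSASE:2", "TRANSPOSASE:1"),
    stringsAsFactors = FALSE)
}

#' Synthetic-fixture configuration
#'
#' Defines the study conditions the generator emulates: a partially
#' chromosome-mapped toy genome, an annotated host gene complement, a set of
#' transcripts whose triage composition mirrors the four annotation
#' categories, planted TE families with order-biased protein expression and
#' per-copy divergence, sequencing-gap runs, and peptide-count evidence.
#'
#' @param seed mandatory integer seed; every random choice derives from it
#' @param n_supercontigs number of supercontigs (first `n_mapped` carry
#'   chromosome/band assignments)
#' @param n_mapped number of chromosome-mapped supercontigs
#' @param n_host_genes annotated host genes; `n_host_expressed` of them are
#'   expressed (transcript + peptides)
#' @param n_host_expressed see above
#' @param host_protein_len inclusive range of host protein lengths (aa)
#' @param n_novel,n_annotated_new,n_ambiguous,n_no_match composition of the
#'   annotation-evaluation transcript subset: unannotated single-locus genes,
#'   annotated genes, duplicated-locus genes, and transcripts absent from the
#'   assembly
#' @param hotspot_bands,hotspot_counts bands seeded with clustered new
#'   annotations (counts must exceed 2 to be detectable)
#' @param mapped_extra_counts new-annotation counts on additional mapped
#'   bands (at most 2 each, below the hotspot rule)
#' @param intron_fraction fraction of placed genes built from two exons
#' @param intron_len inclusive intron length range (nt)
#' @param gap_fraction fraction of novel genes with an N run planted within
#'   the 5 kb scan window
#' @param control_gap_fraction as above for expressed host genes
#' @param n_gap_len inclusive N-run length range (nt)
#' @param te_families data.frame describing planted TE families (see
#'   defaults for the column contract); `expressed` counts give the planted
#'   number of protein-expressing copies per ORF
#' @param max_divergence upper bound of per-copy protein divergence
#' @param transcript_error_rate per-base substitution rate applied to
#'   emitted transcripts
#' @param utr_len inclusive UTR length range (nt)
#' @param peptides_lambda mean of the zero-truncated Poisson peptide count
#' @param peptide_len inclusive peptide length range (aa)
#' @param n_other_noninsect unclassifiable (no-homology) transcripts
#' @param n_viral_db,n_viral_expressed viral database size and expressed
#'   viral proteins (transcripts not derived from the genome)
#' @param repbase list: `enabled`, `mutate` (divergence of the mirrored
#'   entries), `relabel_order_frac`, `relabel_clade_frac`, `extra_entries` —
#'   a second, larger TE database with partially re-classified entries
#' @param spacer_len,flank_len intergenic spacer and contig flank ranges (nt)
#' @param gap_offset_len distance range between a gene and its planted N run
#' @return list of class `synth_config`
#' @export
synth_config <- function(seed,
                         n_supercontigs = 36L, n_mapped = 18L,
                         n_host_genes = 200L, n_host_expressed = 160L,
                         host_protein_len = c(120L, 350L),
                         n_novel = 145L, n_annotated_new = 21L,
                         n_ambiguous = 11L, n_no_match = 38L,
                         hotspot_bands = c("1p3", "1q4", "2p4"),
                         hotspot_counts = c(5L, 4L, 3L),
                         mapped_extra_counts = c(2L, 2L, 1L, 1L, 1L, 1L),
                         intron_fraction = 0.2, intron_len = c(200L, 800L),
                         gap_fraction = 0.36, control_gap_fraction = 0.28,
                         n_gap_len = c(60L, 250L),
                         te_families = .default_te_families(),
                         max_divergence = 0.25,
                         transcript_error_rate = 0.005,
                         utr_len = c(20L, 80L),
                         peptides_lambda = 3,
                         peptide_len = c(9L, 18L),
                         n_other_noninsect = 15L,
                         n_viral_db = 5L, n_viral_expressed = 2L,
                         repbase = list(enabled = TRUE, mutate = 0.05,
                                        relabel_order_frac = 0.4,
                                        relabel_clade_frac = 0.3,
                                        extra_entries = 10L),
                         spacer_len = c(6000L, 12000L),
                         flank_len = c(5500L, 8000L),
                         gap_offset_len = c(500L, 3000L)) {
  if (missing(seed)) abort("a seed is mandatory")
  if (length(hotspot_bands) != length(hotspot_counts))
    abort("hotspot_bands and hotspot_counts must align")
  if (n_host_expressed > n_host_genes)
    abort("cannot express more host genes than exist")
  if (n_mapped > n_supercontigs) abort("n_mapped exceeds n_supercontigs")
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

# ---- gene / item construction --------------------------------------------

.make_gene <- function(id, plen, with_intron, cfg) {
  p <- .rand_protein(plen)
  cds <- paste0(.reverse_translate_rng(p),
                sample(STOP_CODONS, 1L))
  utr5 <- .rand_dna(.runif_int(cfg$utr_len[1L], cfg$utr_len[2L]))
  utr3 <- .rand_dna(.runif_int(cfg$utr_len[1L], cfg$utr_len[2L]))
  template <- paste0(utr5, cds, utr3)
  if (with_intron) {
    ilen <- .runif_int(cfg$intron_len[1L], cfg$intron_len[2L])
    intron <- paste0("GT", .rand_dna(ilen - 4L), "AG")
    cut <- .runif_int(round(nchar(cds) * 0.3), round(nchar(cds) * 0.7))
    item <- paste0(utr5, substr(cds, 1L, cut), intron,
                   substr(cds, cut + 1L, nchar(cds)), utr3)
    e1 <- c(1L, nchar(utr5) + cut)
    e2 <- c(nchar(utr5) + cut + ilen + 1L, nchar(item))
    exons <- list(e1, e2)
  } else {
    item <- template
    exons <- list(c(1L, nchar(item)))
  }
  list(id = id, protein = p, item = item, template = template,
       exons = exons, cds_from = nchar(utr5) + 1L,
       cds_to = nchar(utr5) + nchar(cds),
       strand = sample(c("+", "-"), 1L))
}

# substitution errors on a transcript, retried until the coding region still
# yields an intact ORF (start codon, stop codon, no internal stop)
.make_transcript <- function(gene, rate) {
  template <- gene$template
  n <- nchar(template)
  for (attempt in 1:25) {
    s <- template
    if (rate > 0) {
      hit <- which(stats::runif(n) < rate)
      if (length(hit)) {
        ch <- .chars(s)
        ch[hit] <- vapply(ch[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        s <- paste(ch, collapse = "")
      }
    }
    cds <- substr(s, gene$cds_from, gene$cds_to)
    ncod <- nchar(cds) %/% 3L
    codons <- substring(cds, seq(1L, by = 3L, length.out = ncod),
                        seq(3L, by = 3L, length.out = ncod))
    if (codons[1L] != "ATG") next
    if (!codons[ncod] %in% STOP_CODONS) next
    if (any(codons[-ncod] %in% STOP_CODONS)) next
    aa <- unname(Biostrings::GENETIC_CODE[codons[-ncod]])
    return(list(seq = s, protein = paste(aa, collapse = "")))
  }
  # give up on planting errors in this transcript
  list(seq = template, protein = gene$protein)
}

# ---- main generator -------------------------------------------------------

#' Generate a synthetic fixture bundle
#'
#' Emits a complete, internally consistent set of analysis inputs: genome
#' FASTA with planted N runs, gene annotation GFF3 (with a planted subset of
#' genes deliberately absent), supercontig-to-chromosome map, transcripts
#' FASTA (host, TE-derived, novel, unmappable, viral), peptide evidence TSV,
#' one or two metadata-tagged TE protein databases, per-category genome TE
#' statistics, tiered reference proteomes for the homology cascade, a viral
#' protein database, and ground-truth tables for parameter-recovery checks.
#' Byte-identical across reruns with the same configuration.
#'
#' @param cfg a [synth_config()]
#' @param dir output directory (created if needed)
#' @return list: `paths` (named file paths), `ground_truth` (list of
#'   data.frames), `genome`, `transcripts` (named character vectors),
#'   `te_db`, `te_db_secondary`, `te_stats`, `chr_map`
#' @export
generate_fixtures <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(cfg$seed, .generate_impl(cfg, dir))
}

.generate_impl <- function(cfg, dir) {
  # -- supercontigs and chromosome map --
  sc_ids <- sprintf("SC%03d", seq_len(cfg$n_supercontigs))
  n_hot <- length(cfg$hotspot_bands)
  n_extra <- length(cfg$mapped_extra_counts)
  other_bands <- c("1p1", "1p2", "1q1", "1q2", "1q3", "2p1", "2p2", "2q1",
                   "2q2", "2q3", "3p1", "3p2", "3p3", "3q1", "3q2", "3q3")
  other_bands <- setdiff(other_bands, cfg$hotspot_bands)
  n_other <- cfg$n_mapped - n_hot
  if (n_other > length(other_bands))
    abort("not enough distinct bands for n_mapped")
  bands <- c(cfg$hotspot_bands, other_bands[seq_len(n_other)])
  chr_map <- data.frame(
    supercontig = sc_ids,
    chromosome = c(as.integer(substr(bands, 1L, 1L)),
                   rep(NA_integer_, cfg$n_supercontigs - cfg$n_mapped)),
    band = c(bands, rep(NA_character_, cfg$n_supercontigs - cfg$n_mapped)),
    stringsAsFactors = FALSE)
  hotspot_sc <- sc_ids[seq_len(n_hot)]
  extra_sc <- sc_ids[n_hot + seq_len(n_extra)]
  unmapped_sc <- sc_ids[(cfg$n_mapped + 1L):cfg$n_supercontigs]

  # -- gene construction --
  plen <- function() .runif_int(cfg$host_protein_len[1L],
                                cfg$host_protein_len[2L])
  intron <- function() stats::runif(1L) < cfg$intron_fraction
  mk <- function(prefix, n, introns = TRUE) {
    lapply(seq_len(n), function(i)
      .make_gene(sprintf("%s%03d", prefix, i), plen(),
                 if (introns) intron() else FALSE, cfg))
  }
  host <- mk("H", cfg$n_host_genes, introns = FALSE)
  novel <- mk("NV", cfg$n_novel)
  ann_new <- mk("AN", cfg$n_annotated_new)
  ambig <- mk("AM", cfg$n_ambiguous, introns = FALSE)
  no_match <- mk("NM", cfg$n_no_match, introns = FALSE)

  # -- TE families, copies, databases --
  fam <- cfg$te_families
  te_entries <- list()     # database entries (consensus)
  te_copies <- list()      # expressed copies
  for (i in seq_len(nrow(fam))) {
    types <- strsplit(fam$orf_types[i], ",", fixed = TRUE)[[1L]]
    lens <- as.integer(strsplit(fam$orf_lengths[i], ",", fixed = TRUE)[[1L]])
    cons <- stats::setNames(
      vapply(lens, function(L) .rand_protein(L), ""), types)
    for (t in seq_along(types)) {
      te_entries[[length(te_entries) + 1L]] <- data.frame(
        te_id = sprintf("%s_%s", fam$family[i], tolower(types[t])),
        source_db = "TEFAM", te_class = fam$te_class[i],
        order = fam$order[i], clade = fam$clade[i], orf_type = types[t],
        protein = cons[[t]], stringsAsFactors = FALSE)
    }
    expr <- strsplit(fam$expressed[i], ",", fixed = TRUE)[[1L]]
    expr <- expr[nzchar(expr)]
    cidx <- 0L
    for (e in expr) {
      kv <- strsplit(e, ":", fixed = TRUE)[[1L]]
      type <- kv[1L]; n_copies <- as.integer(kv[2L])
      for (cc in seq_len(n_copies)) {
        cidx <- cidx + 1L
        div <- stats::runif(1L, 0, cfg$max_divergence)
        te_copies[[length(te_copies) + 1L]] <- list(
          copy_id = sprintf("%s_%s_c%02d", fam$family[i], tolower(type),
                            cidx),
          family = fam$family[i], order = fam$order[i],
          clade = fam$clade[i], orf_type = type, divergence = div,
          protein = .mutate_protein_rng(cons[[type]], div))
      }
    }
  }
  te_database <- do.call(rbind, te_entries)
  class(te_database) <- c("te_db", "data.frame")

  # TE copies become genes (UTRs + reverse-translated CDS) placed in the
  # genome, so their transcripts are reconstructible
  te_genes <- lapply(te_copies, function(copy) {
    g <- local({
      p <- copy$protein
      cds <- paste0(.reverse_translate_rng(p), sample(STOP_CODONS, 1L))
      utr5 <- .rand_dna(.runif_int(cfg$utr_len[1L], cfg$utr_len[2L]))
      utr3 <- .rand_dna(.runif_int(cfg$utr_len[1L], cfg$utr_len[2L]))
      item <- paste0(utr5, cds, utr3)
      list(id = copy$copy_id, protein = p, item = item, template = item,
           exons = list(c(1L, nchar(item))), cds_from = nchar(utr5) + 1L,
           cds_to = nchar(utr5) + nchar(cds),
           strand = sample(c("+", "-"), 1L))
    })
    g
  })

  # -- contig assignment --
  gene_contig <- list()
  place <- function(gene_list, contigs) {
    for (g in gene_list) gene_contig[[g$id]] <<- sample(contigs, 1L)
  }
  # hotspot novel genes first, then mapped extras, then the rest on the
  # unmapped novel contigs
  novel_ids <- vapply(novel, `[[`, "", "id")
  pos <- 0L
  for (h in seq_len(n_hot)) {
    for (j in seq_len(cfg$hotspot_counts[h])) {
      pos <- pos + 1L
      gene_contig[[novel_ids[pos]]] <- hotspot_sc[h]
    }
  }
  for (h in seq_len(n_extra)) {
    for (j in seq_len(cfg$mapped_extra_counts[h])) {
      pos <- pos + 1L
      gene_contig[[novel_ids[pos]]] <- extra_sc[h]
    }
  }
  novel_unmapped_sc <- unmapped_sc[seq_len(min(15L, length(unmapped_sc)))]
  rest <- novel_ids[(pos + 1L):length(novel_ids)]
  for (j in seq_along(rest)) {
    gene_contig[[rest[j]]] <-
      novel_unmapped_sc[((j - 1L) %% length(novel_unmapped_sc)) + 1L]
  }
  place(host, sc_ids)
  place(ann_new, sc_ids)
  place(te_genes, sc_ids)
  # ambiguous genes: two placements on distinct contigs
  ambig_contigs <- lapply(ambig, function(g) sample(sc_ids, 2L))
  names(ambig_contigs) <- vapply(ambig, `[[`, "", "id")

  # -- gap planting --
  host_expressed_ids <- vapply(host[seq_len(cfg$n_host_expressed)], `[[`,
                               "", "id")
  gap_novel <- sample(novel_ids, round(cfg$gap_fraction * length(novel_ids)))
  gap_host <- sample(host_expressed_ids,
                     round(cfg$control_gap_fraction *
                             length(host_expressed_ids)))
  has_gap <- c(gap_novel, gap_host)

  # -- contig layout --
  all_genes <- c(host, novel, ann_new, te_genes)
  names(all_genes) <- vapply(all_genes, `[[`, "", "id")
  items_by_contig <- stats::setNames(
    lapply(sc_ids, function(x) list()), sc_ids)
  push <- function(contig, entry) {
    items_by_contig[[contig]][[length(items_by_contig[[contig]]) + 1L]] <<-
      entry
  }
  for (g in all_genes) push(gene_contig[[g$id]],
                            list(kind = "gene", gene = g, placement = 1L))
  for (g in ambig) {
    push(ambig_contigs[[g$id]][1L],
         list(kind = "gene", gene = g, placement = 1L))
    push(ambig_contigs[[g$id]][2L],
         list(kind = "gene", gene = g, placement = 2L))
  }

  spacer <- function() .rand_dna(.runif_int(cfg$spacer_len[1L],
                                            cfg$spacer_len[2L]))
  genome <- stats::setNames(character(length(sc_ids)), sc_ids)
  placements <- list()   # per placed gene: coords
  for (contig in sc_ids) {
    items <- items_by_contig[[contig]]
    if (length(items) > 1L) items <- items[sample.int(length(items))]
    parts <- character(0)
    cursor <- 0L
    add <- function(s) {
      parts[[length(parts) + 1L]] <<- s
      from <- cursor + 1L
      cursor <<- cursor + nchar(s)
      c(from, cursor)
    }
    add(.rand_dna(.runif_int(cfg$flank_len[1L], cfg$flank_len[2L])))
    for (it in items) {
      g <- it$gene
      oriented <- if (g$strand == "+") g$item else .revcomp(g$item)
      span <- add(oriented)
      L <- nchar(g$item)
      exons <- lapply(g$exons, function(e) {
        if (g$strand == "+") span[1L] - 1L + e
        else c(span[2L] + 1L - e[2L], span[2L] + 1L - e[1L])
      })
      exons <- exons[order(vapply(exons, `[`, 0, 1L))]
      placements[[length(placements) + 1L]] <- list(
        id = g$id, placement = it$placement, contig = contig,
        strand = g$strand, start = span[1L], end = span[2L], exons = exons)
      if (it$placement == 1L && g$id %in% has_gap) {
        add(.rand_dna(.runif_int(cfg$gap_offset_len[1L],
                                 cfg$gap_offset_len[2L])))
        add(strrep("N", .runif_int(cfg$n_gap_len[1L], cfg$n_gap_len[2L])))
      }
      add(spacer())
    }
    add(.rand_dna(.runif_int(cfg$flank_len[1L], cfg$flank_len[2L])))
    genome[[contig]] <- paste(parts, collapse = "")
  }

  # -- annotation GFF3 (hosts + the annotated-new genes only) --
  annotated_ids <- c(vapply(host, `[[`, "", "id"),
                     vapply(ann_new, `[[`, "", "id"))
  gff <- c("##gff-version 3")
  for (pl in placements) {
    if (!pl$id %in% annotated_ids || pl$placement != 1L) next
    attr_g <- sprintf("ID=gene:%s;Name=%s", pl$id, pl$id)
    gff <- c(gff,
      sprintf("%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\t%s",
              pl$contig, pl$start, pl$end, pl$strand, attr_g),
      sprintf("%s\tsynth\tmRNA\t%d\t%d\t.\t%s\t.\tID=mrna:%s;Parent=gene:%s",
              pl$contig, pl$start, pl$end, pl$strand, pl$id, pl$id))
    for (e in pl$exons) {
      gff <- c(gff, sprintf(
        "%s\tsynth\texon\t%d\t%d\t.\t%s\t.\tParent=mrna:%s",
        pl$contig, e[1L], e[2L], pl$strand, pl$id))
    }
  }

  # -- transcripts --
  expressed_host <- host[seq_len(cfg$n_host_expressed)]
  genome_derived <- c(expressed_host, novel, ann_new, ambig, te_genes)
  transcripts <- character(0)
  realized <- character(0)
  for (g in genome_derived) {
    tr <- .make_transcript(g, cfg$transcript_error_rate)
    transcripts[[g$id]] <- tr$seq
    realized[[g$id]] <- tr$protein
  }
  for (g in no_match) {   # genes absent from the assembly
    tr <- .make_transcript(g, cfg$transcript_error_rate)
    transcripts[[g$id]] <- tr$seq
    realized[[g$id]] <- tr$protein
  }
  # viral proteins: db plus expressed contaminant transcripts
  viral_db <- stats::setNames(
    vapply(seq_len(cfg$n_viral_db), function(i)
      .rand_protein(.runif_int(180L, 400L)), ""),
    sprintf("VIR%02d", seq_len(cfg$n_viral_db)))
  if (cfg$n_viral_expressed > 0L) {
    for (i in seq_len(cfg$n_viral_expressed)) {
      id <- sprintf("VT%02d", i)
      p <- viral_db[[i]]
      g <- list(template = paste0(
        .rand_dna(30L), .reverse_translate_rng(p),
        sample(STOP_CODONS, 1L), .rand_dna(30L)),
        cds_from = 31L, cds_to = 31L + 3L * nchar(p) + 2L, protein = p)
      tr <- .make_transcript(g, cfg$transcript_error_rate)
      transcripts[[id]] <- tr$seq
      realized[[id]] <- tr$protein
    }
  }
  # other non-insect transcripts: no homology anywhere
  for (i in seq_len(cfg$n_other_noninsect)) {
    id <- sprintf("ON%02d", i)
    p <- .rand_protein(.runif_int(120L, 300L))
    g <- list(template = paste0(
      .rand_dna(25L), .reverse_translate_rng(p), sample(STOP_CODONS, 1L),
      .rand_dna(25L)), cds_from = 26L, cds_to = 26L + 3L * nchar(p) + 2L,
      protein = p)
    tr <- .make_transcript(g, cfg$transcript_error_rate)
    transcripts[[id]] <- tr$seq
    realized[[id]] <- tr$protein
  }

  # -- peptide evidence --
  orfs <- extract_orfs(transcripts, min_nt = 200L)
  pep_rows <- list()
  for (id in names(realized)) {
    p <- realized[[id]]
    npep <- .ztpois(cfg$peptides_lambda)
    for (j in seq_len(npep)) {
      L <- .runif_int(cfg$peptide_len[1L],
                      min(cfg$peptide_len[2L], nchar(p)))
      at <- .runif_int(1L, nchar(p) - L + 1L)
      pep_rows[[length(pep_rows) + 1L]] <- substr(p, at, at + L - 1L)
    }
  }
  peptides <- unique(unlist(pep_rows))
  matched <- lapply(peptides, function(pep)
    orfs$orf_id[grepl(pep, orfs$protein, fixed = TRUE)])
  keep <- lengths(matched) > 0L
  evidence <- data.frame(peptide = peptides[keep], stringsAsFactors = FALSE)
  evidence$orf_ids <- matched[keep]

  # -- tier reference databases --
  tier_aedes <- stats::setNames(
    vapply(host, `[[`, "", "protein"),
    sprintf("AAEL_%s", vapply(host, `[[`, "", "id")))
  culex_src <- c(novel, ann_new, ambig, no_match,
                 host[seq_len(min(30L, length(host)))])
  tier_culex <- stats::setNames(
    vapply(culex_src, function(g) .mutate_protein_rng(g$protein, 0.2), ""),
    sprintf("CPIJ_%s", vapply(culex_src, `[[`, "", "id")))
  dros_src <- c(novel[seq_len(min(30L, length(novel)))],
                ann_new[seq_len(min(10L, length(ann_new)))])
  tier_drosophila <- stats::setNames(
    vapply(dros_src, function(g) .mutate_protein_rng(g$protein, 0.35), ""),
    sprintf("FBpp_%s", vapply(dros_src, `[[`, "", "id")))

  # -- secondary ("RepBase-like") TE database --
  te_secondary <- NULL
  if (isTRUE(cfg$repbase$enabled)) {
    sec <- te_database
    sec$te_id <- paste0("rb_", sec$te_id)
    sec$source_db <- "REPBASE"
    sec$protein <- vapply(sec$protein, function(p)
      .mutate_protein_rng(p, cfg$repbase$mutate), "", USE.NAMES = FALSE)
    n <- nrow(sec)
    reord <- sample(n, round(cfg$repbase$relabel_order_frac * n))
    cycle <- c(LTR = "DNA_TIR", DNA_TIR = "NON_LTR", NON_LTR = "LTR")
    clade_of <- c(LTR = "Ty3/gypsy", DNA_TIR = "P", NON_LTR = "Jockey")
    sec$order[reord] <- cycle[sec$order[reord]]
    sec$clade[reord] <- clade_of[sec$order[reord]]
    sec$orf_type[reord] <- "OTHER"
    reclade <- sample(setdiff(seq_len(n), reord),
                      round(cfg$repbase$relabel_clade_frac * n))
    alt_clade <- c(`Ty3/gypsy` = "BEL", BEL = "Ty1/copia",
                   `Ty1/copia` = "Ty3/gypsy", Jockey = "L1", R4 = "Jockey",
                   L1 = "Outcast", `IS630-Tc1-mariner` = "P",
                   Mutator = "piggyBac")
    hitc <- sec$clade[reclade] %in% names(alt_clade)
    sec$clade[reclade[hitc]] <- alt_clade[sec$clade[reclade[hitc]]]
    if (cfg$repbase$extra_entries > 0L) {
      extra <- data.frame(
        te_id = sprintf("rb_extra%02d", seq_len(cfg$repbase$extra_entries)),
        source_db = "REPBASE", te_class = "I", order = "LTR",
        clade = "Ty3/gypsy", orf_type = "OTHER",
        protein = vapply(seq_len(cfg$repbase$extra_entries), function(i)
          .rand_protein(.runif_int(200L, 500L)), ""),
        stringsAsFactors = FALSE)
      sec <- rbind(sec, extra)
    }
    class(sec) <- c("te_db", "data.frame")
    te_secondary <- sec
  }

  # -- genome TE statistics --
  genome_nt <- sum(nchar(genome))
  fam$element_nt <- vapply(strsplit(fam$orf_lengths, ",", fixed = TRUE),
                           function(x) 3L * sum(as.integer(x)) + 200L, 0L)
  stats_rows <- list()
  add_stat <- function(category, level, rows) {
    cn <- fam$copy_number[rows]
    known <- fam$copy_number_known[rows]
    stats_rows[[length(stats_rows) + 1L]] <<- data.frame(
      category = category, level = level,
      genome_pct = 100 * sum(cn * fam$element_nt[rows]) / genome_nt,
      copy_number = if (level == "ORDER" || all(known)) sum(cn)
        else NA_integer_,
      db_entries = NA_integer_,   # filled below from the database itself
      stringsAsFactors = FALSE)
  }
  for (o in unique(fam$order)) add_stat(o, "ORDER", which(fam$order == o))
  for (cl in unique(fam$clade)) add_stat(cl, "CLADE", which(fam$clade == cl))
  te_stats <- do.call(rbind, stats_rows)
  # db_entries more simply: count database entries per category
  te_stats$db_entries <- ifelse(
    te_stats$level == "ORDER",
    vapply(te_stats$category, function(c) sum(te_database$order == c), 0L),
    vapply(te_stats$category, function(c) sum(te_database$clade == c), 0L))
  class(te_stats) <- c("te_genome_stats", "data.frame")

  # -- ground truth --
  pl_primary <- placements[vapply(placements, function(p)
    p$placement == 1L, TRUE)]
  pl_by_id <- stats::setNames(pl_primary, vapply(pl_primary, `[[`, "", "id"))
  classes <- c(
    stats::setNames(rep("host", length(expressed_host)),
                    vapply(expressed_host, `[[`, "", "id")),
    stats::setNames(rep("novel", length(novel)), novel_ids),
    stats::setNames(rep("annotated_new", length(ann_new)),
                    vapply(ann_new, `[[`, "", "id")),
    stats::setNames(rep("ambiguous", length(ambig)),
                    vapply(ambig, `[[`, "", "id")),
    stats::setNames(rep("no_match", length(no_match)),
                    vapply(no_match, `[[`, "", "id")),
    stats::setNames(rep("te", length(te_genes)),
                    vapply(te_genes, `[[`, "", "id")),
    stats::setNames(rep("viral", cfg$n_viral_expressed),
                    if (cfg$n_viral_expressed > 0L)
                      sprintf("VT%02d", seq_len(cfg$n_viral_expressed))
                    else character(0)),
    stats::setNames(rep("other", cfg$n_other_noninsect),
                    if (cfg$n_other_noninsect > 0L)
                      sprintf("ON%02d", seq_len(cfg$n_other_noninsect))
                    else character(0)))
  gt_tr <- data.frame(
    transcript_id = names(transcripts),
    class = unname(classes[names(transcripts)]),
    stringsAsFactors = FALSE)
  gt_tr$genome_derived <- !gt_tr$class %in% c("no_match", "viral", "other")
  loc <- pl_by_id[gt_tr$transcript_id]
  gt_tr$contig <- vapply(loc, function(p)
    if (is.null(p)) NA_character_ else p$contig, "")
  gt_tr$strand <- vapply(loc, function(p)
    if (is.null(p)) NA_character_ else p$strand, "")
  gt_tr$start <- vapply(loc, function(p)
    if (is.null(p)) NA_integer_ else p$start, 0L)
  gt_tr$end <- vapply(loc, function(p)
    if (is.null(p)) NA_integer_ else p$end, 0L)
  idx <- match(gt_tr$contig, chr_map$supercontig)
  gt_tr$chromosome <- chr_map$chromosome[idx]
  gt_tr$band <- chr_map$band[idx]
  gt_tr$planted_gap <- gt_tr$transcript_id %in% has_gap
  gt_te <- do.call(rbind, lapply(te_copies, function(x)
    data.frame(transcript_id = x$copy_id, family = x$family,
               order = x$order, clade = x$clade, orf_type = x$orf_type,
               divergence = x$divergence, stringsAsFactors = FALSE)))
  gt_bands <- within(
    data.frame(band = bands, stringsAsFactors = FALSE), {
      planted_new <- vapply(band, function(b)
        sum(gt_tr$class == "novel" & !is.na(gt_tr$band) & gt_tr$band == b),
        0L)
    })[, c("band", "planted_new")]
  ground_truth <- list(transcripts = gt_tr, te_proteins = gt_te,
                       bands = gt_bands)

  # -- write files --
  p <- function(f) file.path(dir, f)
  paths <- list(
    genome = p("genome.fasta"), transcripts = p("transcripts.fasta"),
    annotation = p("annotation.gff3"),
    chromosome_map = p("chromosome_map.tsv"),
    peptides = p("peptides.tsv"), te_db = p("te_db_tefam.fasta"),
    te_db_secondary = if (!is.null(te_secondary))
      p("te_db_repbase.fasta") else NULL,
    te_stats = p("te_stats.tsv"), tier_aedes = p("tier_aedes.fasta"),
    tier_culex = p("tier_culex.fasta"),
    tier_drosophila = p("tier_drosophila.fasta"),
    viral_db = p("viral_db.fasta"),
    ground_truth_transcripts = p("ground_truth_transcripts.tsv"),
    ground_truth_te = p("ground_truth_te.tsv"),
    ground_truth_bands = p("ground_truth_bands.tsv"))
  write_fasta(genome, paths$genome, "DNA")
  write_fasta(transcripts, paths$transcripts, "DNA")
  writeLines(gff, paths$annotation)
  write_tsv_file(chr_map, paths$chromosome_map)
  write_peptide_evidence(evidence, paths$peptides)
  write_te_fasta(te_database, paths$te_db)
  if (!is.null(te_secondary)) write_te_fasta(te_secondary,
                                             paths$te_db_secondary)
  write_tsv_file(te_stats, paths$te_stats)
  write_fasta(tier_aedes, paths$tier_aedes, "AA")
  write_fasta(tier_culex, paths$tier_culex, "AA")
  write_fasta(tier_drosophila, paths$tier_drosophila, "AA")
  write_fasta(viral_db, paths$viral_db, "AA")
  write_tsv_file(gt_tr, paths$ground_truth_transcripts)
  write_tsv_file(gt_te, paths$ground_truth_te)
  write_tsv_file(gt_bands, paths$ground_truth_bands)

  list(paths = paths, ground_truth = ground_truth, genome = genome,
       transcripts = transcripts, evidence = evidence,
       te_db = te_database, te_db_secondary = te_secondary,
       te_stats = te_stats, chr_map = chr_map, viral_db = viral_db,
       tier_aedes = tier_aedes, tier_culex = tier_culex,
       tier_drosophila = tier_drosophila, config = cfg)
}

#' Synthetic query sets for threshold calibration
#'
#' Builds a target query set containing a known fraction of full-length
#' (diverged) TE proteins and a background set of unrelated proteins of
#' which a small fraction carries a short embedded TE domain, producing the
#' characteristic calibration shape: a target curve resistant to coverage
#' cutoffs and a background curve that collapses at the knee.
#'
#' @param db a [te_db()] supplying consensus TE proteins
#' @param seed integer seed
#' @param n_target,n_background set sizes
#' @param te_fraction fraction of the target set derived from TE consensus
#'   proteins (full length)
#' @param spurious_fraction fraction of the background set carrying an
#'   embedded TE domain
#' @param divergence_range per-protein divergence range for target TE
#'   proteins
#' @param domain_coverages coverage fractions (of the background query
#'   length) of the embedded domains, recycled over the spurious queries
#' @param domain_divergence divergence applied to embedded domains
#' @return list: `target`, `background` (named character vectors), `truth`
#'   (data.frame flagging planted TE/spurious queries)
#' @export
synth_calibration_sets <- function(db, seed, n_target = 100L,
                                   n_background = 120L, te_fraction = 0.8,
                                   spurious_fraction = 0.05,
                                   divergence_range = c(0.05, 0.25),
                                   domain_coverages = c(0.42, 0.30),
                                   domain_divergence = 0.1) {
  with_seed(seed, {
    n_te <- round(te_fraction * n_target)
    pick <- sample.int(nrow(db), n_te, replace = TRUE)
    target <- character(n_target)
    for (i in seq_len(n_te)) {
      d <- stats::runif(1L, divergence_range[1L], divergence_range[2L])
      target[i] <- .mutate_protein_rng(db$protein[pick[i]], d)
    }
    for (i in seq.int(n_te + 1L, length.out = n_target - n_te)) {
      target[i] <- .rand_protein(.runif_int(150L, 400L))
    }
    names(target) <- sprintf("TGT%03d", seq_len(n_target))

    n_spur <- max(1L, round(spurious_fraction * n_background))
    background <- vapply(seq_len(n_background), function(i)
      .rand_protein(.runif_int(250L, 400L)), "")
    names(background) <- sprintf("BG%03d", seq_len(n_background))
    covs <- rep_len(domain_coverages, n_spur)
    spur_idx <- sample.int(n_background, n_spur)
    for (j in seq_len(n_spur)) {
      i <- spur_idx[j]
      L <- nchar(background[[i]])
      dlen <- round(covs[j] * L)
      src <- db$protein[sample.int(nrow(db), 1L)]
      while (nchar(src) < dlen) src <- paste0(src, src)
      at <- .runif_int(1L, nchar(src) - dlen + 1L)
      dom <- .mutate_protein_rng(substr(src, at, at + dlen - 1L),
                                 domain_divergence)
      ins <- .runif_int(2L, L - dlen)
      background[i] <- paste0(substr(background[[i]], 1L, ins - 1L), dom,
                              substr(background[[i]], ins + dlen, L))
    }
    truth <- data.frame(
      query_id = c(names(target), names(background)),
      set = rep(c("target", "background"), c(n_target, n_background)),
      planted_te = c(seq_len(n_target) <= n_te,
                     seq_len(n_background) %in% spur_idx),
      stringsAsFactors = FALSE)
    list(target = target, background = background, truth = truth)
  })
}
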