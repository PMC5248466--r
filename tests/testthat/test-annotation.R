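revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

test_that("exact substrings map as single-block, full-identity hits", {
  set.seed(41)
  contig <- random_dna(20000L)
  tr <- substr(contig, 5001L, 6200L)
  hits <- align_transcripts(c(t1 = tr), c(SC1 = contig))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$supercontig, "SC1")
  expect_equal(hits$strand, "+")
  expect_equal(hits$n_blocks, 1L)
  expect_equal(hits$span_start, 5001L)
  expect_equal(hits$span_end, 6200L)
  expect_equal(hits$pct_identity, 100)
  expect_equal(hits$transcript_coverage_pct, 100)
})

test_that("reverse-complemented transcripts map on the minus strand", {
  set.seed(42)
  contig <- random_dna(15000L)
  tr <- revcomp(substr(contig, 2001L, 3000L))
  hits <- align_transcripts(c(t1 = tr), c(SC1 = contig))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$span_start, 2001L)
  expect_equal(hits$span_end, 3000L)
  expect_equal(hits$pct_identity, 100)
})

test_that("a transcript spanning two exons is reconstructed as two blocks", {
  set.seed(43)
  contig <- random_dna(30000L)
  exon1 <- substr(contig, 10001L, 10600L)
  exon2 <- substr(contig, 11101L, 11800L)   # 500 bp intron
  tr <- paste0(exon1, exon2)
  hits <- align_transcripts(c(t1 = tr), c(SC1 = contig))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$n_blocks, 2L)
  starts <- as.integer(strsplit(hits$block_starts, ",")[[1]])
  ends <- as.integer(strsplit(hits$block_ends, ",")[[1]])
  expect_equal(starts[1], 10001L)
  expect_equal(ends[2], 11800L)
  # the exon boundary may be placed within a few bases of the truth
  expect_lt(abs(ends[1] - 10600L) + abs(starts[2] - 11101L), 60L)
  expect_gt(hits$transcript_coverage_pct, 95)
  expect_gt(hits$pct_identity, 99)
})

test_that("unalignable transcripts are reported as unaligned", {
  set.seed(44)
  hits <- align_transcripts(c(t1 = random_dna(800L)),
                            c(SC1 = random_dna(10000L)))
  expect_true(nrow(hits) == 0L ||
                all(hits$transcript_coverage_pct < 20))
})

test_that("triage partitions transcripts into the four categories", {
  set.seed(45)
  contig <- random_dna(40000L)
  contig2 <- random_dna(15000L)
  gene <- substr(contig, 5001L, 6000L)      # annotated on + strand
  opp <- substr(contig, 15001L, 16000L)     # gene annotated on - strand
  dup <- substr(contig, 25001L, 26000L)
  contig2 <- paste0(substr(contig2, 1, 7000L), dup,
                    substr(contig2, 8001L, 15000L))  # duplicate locus
  novel <- substr(contig, 30001L, 31000L)
  genome <- c(SC1 = contig, SC2 = contig2)
  ann <- GenomicRanges::GRanges(
    c("SC1", "SC1"), IRanges::IRanges(c(5001L, 15001L), c(6000L, 16000L)),
    strand = c("+", "-"))
  trs <- c(annot = gene, opposite = opp, dupl = dup, new = novel,
           nomatch = random_dna(700L))
  hits <- align_transcripts(trs, genome)
  tri <- triage(hits, names(trs), ann)
  got <- setNames(as.character(tri$category), tri$transcript_id)
  expect_equal(got[["annot"]], "ALREADY_ANNOTATED")
  # same locus, opposite strand only: not annotated
  expect_equal(got[["opposite"]], "NEW_ANNOTATION")
  expect_equal(got[["dupl"]], "AMBIGUOUS")
  expect_equal(got[["new"]], "NEW_ANNOTATION")
  expect_equal(got[["nomatch"]], "NO_MATCH")
  expect_equal(sum(table(tri$category)), length(trs))
  expect_gte(tri$n_loci[tri$transcript_id == "dupl"], 2L)
  # with no annotation nothing is already annotated
  tri2 <- triage(hits, names(trs), NULL)
  expect_false(any(tri2$category == "ALREADY_ANNOTATED"))
})

test_that("gap scanning counts Ns in flanked, truncated windows", {
  set.seed(46)
  left <- random_dna(4000L)
  span <- random_dna(1000L)
  gap <- strrep("N", 100L)
  right <- paste0(random_dna(2900L), gap, random_dna(2000L))
  contig <- paste0(left, span, right)   # N run 3 kb downstream of the span
  located <- data.frame(transcript_id = "t1", supercontig = "SC1",
                        span_start = 4001L, span_end = 5000L)
  g <- gap_scan(c(SC1 = contig), located, flank_nt = 5000L)
  expect_true(g$has_gap)
  expect_gte(g$n_count_in_window, 100L)
  expect_false(g$truncated_downstream)
  expect_true(g$truncated_upstream)  # only 4 kb upstream available
  # clean window
  g2 <- gap_scan(c(SC1 = contig), data.frame(
    transcript_id = "t1", supercontig = "SC1", span_start = 500L,
    span_end = 900L), flank_nt = 200L)
  expect_false(g2$has_gap)
  expect_equal(g2$n_count_in_window, 0L)
  expect_error(gap_scan(c(SC1 = contig), data.frame(
    transcript_id = "t1", supercontig = "SCX", span_start = 1L,
    span_end = 2L)), "absent")
})

test_that("matched controls are deterministic and length-balanced", {
  set.seed(47)
  new_len <- setNames(sample(500:3000, 40), paste0("n", 1:40))
  pool_len <- setNames(sample(400:3200, 400, replace = TRUE),
                       paste0("p", 1:400))
  c1 <- matched_control_sample(new_len, pool_len, seed = 23)
  c2 <- matched_control_sample(new_len, pool_len, seed = 23)
  expect_identical(c1, c2)
  expect_equal(length(c1), 40L)
  expect_equal(anyDuplicated(c1), 0L)
  expect_lt(abs(mean(pool_len[c1]) - mean(new_len)),
            0.05 * mean(new_len))
  # exact pool: perfect matching
  pool_exact <- setNames(as.numeric(new_len), paste0("e", 1:40))
  c3 <- matched_control_sample(new_len, pool_exact, seed = 1)
  expect_equal(mean(pool_exact[c3]), mean(new_len))
  expect_error(matched_control_sample(new_len, pool_len[1:10], seed = 1),
               "smaller")
})

test_that("chromosome enrichment normalises to the genome-wide rate", {
  chr_map <- data.frame(
    supercontig = sprintf("SC%02d", 1:12),
    chromosome = rep(1:3, each = 4),
    band = rep(c("1p1", "2p1", "3p1"), each = 4))
  tri <- function(scs) {
    structure(data.frame(
      transcript_id = paste0("t", seq_along(scs)),
      category = factor(rep("NEW_ANNOTATION", length(scs)),
                        levels = TRIAGE_CATEGORIES_LEVELS),
      supercontig = scs, stringsAsFactors = FALSE),
      class = c("triage_records", "data.frame"))
  }
  # all new annotation on chromosome 1 -> ratios 3, 0, 0
  e1 <- chromosome_enrichment(tri(c("SC01", "SC02", "SC03")), chr_map)
  expect_equal(e1$normalized_ratio, c(3, 0, 0))
  # uniform over chromosomes -> all 1 (one supercontig each)
  e2 <- chromosome_enrichment(tri(c("SC01", "SC05", "SC09")), chr_map)
  expect_equal(e2$normalized_ratio, c(1, 1, 1))
  # a supercontig with several new annotations counts once
  e3 <- chromosome_enrichment(tri(c("SC01", "SC01", "SC05", "SC09")),
                              chr_map)
  expect_equal(e3$normalized_ratio, c(1, 1, 1))
})

test_that("band hotspots flag the top 20% exceeding the count floor", {
  bands <- sprintf("b%02d", 1:10)
  chr_map <- data.frame(supercontig = sprintf("SC%02d", 1:10),
                        chromosome = 1L, band = bands)
  counts <- c(6L, 5L, 4L, 1L, 1L, 0L, 0L, 0L, 0L, 0L)
  recs <- do.call(rbind, lapply(seq_along(bands), function(i) {
    if (counts[i] == 0L) return(NULL)
    data.frame(transcript_id = paste0("t", i, "_", seq_len(counts[i])),
               category = "NEW_ANNOTATION",
               supercontig = sprintf("SC%02d", i),
               stringsAsFactors = FALSE)
  }))
  recs$category <- factor(recs$category, levels = TRIAGE_CATEGORIES_LEVELS)
  h <- band_hotspots(recs, chr_map)
  # ceil(0.2 * 10) = 2 bands eligible; both exceed the floor of 2
  expect_setequal(h$band[h$enriched], c("b01", "b02"))
  # all counts at or below 2: nothing enriched
  recs2 <- recs[recs$supercontig %in% c("SC04", "SC05"), ]
  expect_false(any(band_hotspots(recs2, chr_map)$enriched))
  # a single loaded band is flagged
  recs3 <- recs[recs$supercontig == "SC01", ]
  expect_equal(band_hotspots(recs3, chr_map)$band[
    band_hotspots(recs3, chr_map)$enriched], "b01")
})

test_that("the pooled t-test matches the closed-form oracle", {
  # pinned independent computation: x = 1,2,3 vs y = 2,3,4
  r <- ttest_equal_var(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -1.22474487, tolerance = 1e-7)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.28786413, tolerance = 1e-7)
  # identical samples
  r2 <- ttest_equal_var(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r2$t, 0); expect_equal(r2$p, 1)
  # antisymmetry
  set.seed(48)
  x <- rnorm(10); y <- rnorm(12, mean = 1)
  expect_equal(ttest_equal_var(x, y)$t, -ttest_equal_var(y, x)$t)
  expect_error(ttest_equal_var(c(1, 1), c(2, 2)), "unequal means")
  expect_error(ttest_equal_var(1, c(1, 2)), "at least 2")
})
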