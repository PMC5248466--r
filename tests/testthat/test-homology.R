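sch <- scoring_scheme()

test_that("identical sequences align end to end at 100% identity", {
  a <- smith_waterman("MKWVTFISLLF", "MKWVTFISLLF", sch)
  expect_equal(a$identities, 11L)
  expect_equal(a$aln_length, 11L)
  expect_equal(a$query_span, c(0L, 11L))
  expect_equal(a$subject_span, c(0L, 11L))
})

test_that("no positive-scoring cell means no alignment", {
  a <- smith_waterman("AAAA", "GGGG", sch)
  expect_equal(a$raw_score, 0L)
  expect_null(a$query_span)
  expect_error(smith_waterman("", "MK", sch), "empty")
  expect_error(smith_waterman("MKB", "MK", sch), "residues")
})

test_that("alignment scores match the exhaustive enumeration oracle", {
  set.seed(11)
  for (i in 1:100) {
    a <- random_protein(6L)
    b <- random_protein(6L)
    want <- oracle_sw_score(a, b, blosum62)
    expect_equal(smith_waterman(a, b, sch)$raw_score, want,
                 info = paste(a, b))
    expect_equal(unname(pitmobilome:::sw_score_matrix(c(q = a), c(s = b),
                                                      sch)[1, 1]), want)
  }
})

test_that("the fast scorer agrees with the traceback engine", {
  set.seed(21)
  qs <- setNames(vapply(1:30, function(i)
    random_protein(sample(30:120, 1)), ""), paste0("q", 1:30))
  ss <- setNames(vapply(1:10, function(i)
    random_protein(sample(30:120, 1)), ""), paste0("s", 1:10))
  fast <- pitmobilome:::sw_score_matrix(qs, ss, sch)
  for (j in seq_along(ss)) {
    slow <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(qs), Biostrings::AAString(ss[[j]]),
      substitutionMatrix = sch$matrix, gapOpening = sch$gap_open,
      gapExtension = sch$gap_extend, type = "local", scoreOnly = TRUE)
    expect_equal(unname(fast[, j]), pmax(as.integer(round(slow)), 0L))
  }
})

test_that("alignment score is symmetric in its arguments", {
  set.seed(12)
  a <- setNames(vapply(1:20, function(i)
    random_protein(sample(10:60, 1)), ""), paste0("a", 1:20))
  b <- setNames(vapply(1:10, function(i)
    random_protein(sample(10:60, 1)), ""), paste0("b", 1:10))
  expect_equal(unname(pitmobilome:::sw_score_matrix(a, b, sch)),
               t(unname(pitmobilome:::sw_score_matrix(b, a, sch))))
})

test_that("E-values follow the Karlin-Altschul closed form", {
  # pinned closed-form value: E = 0.041 * 1e6 * exp(-26.7)
  expect_equal(evalue(100L, 1000L, 1000L, sch), 1.0402103961e-07,
               tolerance = 1e-9)
  expect_equal(bit_score(100L, sch), 43.12818987, tolerance = 1e-7)
  # linear in database size
  expect_equal(evalue(50L, 100L, 2000L, sch),
               2 * evalue(50L, 100L, 1000L, sch))
  # strictly decreasing in score
  s <- 10:60
  ev <- evalue(s, 500L, 5000L, sch)
  expect_true(all(diff(ev) < 0))
  expect_error(evalue(10L, 0L, 10L, sch), "positive")
})

test_that("database search ranks by score with documented tie-breaks", {
  set.seed(31)
  target <- random_protein(60L)
  db <- c(zeta = random_protein(50L), self = target,
          alpha = random_protein(50L))
  m <- search_homologs(c(q1 = target), db, sch)
  expect_equal(top_hits(m)$subject_id, "self")
  expect_equal(top_hits(m)$pct_identity, 100)
  expect_equal(top_hits(m)$query_coverage_pct, 100)
  # equal scores: lexicographically smaller subject id first
  db2 <- c(bbb = target, aaa = target)
  m2 <- search_homologs(c(q1 = target), db2, sch)
  expect_equal(m2$subject_id[m2$rank == 1], "aaa")
  expect_error(search_homologs(c(q = "MK"), character(0), sch), "empty")
})

test_that("search ranking equals brute-force all-pairs alignment", {
  set.seed(3)
  qs <- setNames(vapply(1:15, function(i)
    random_protein(sample(15:40, 1)), ""), sprintf("q%02d", 1:15))
  db <- setNames(vapply(1:15, function(i)
    random_protein(sample(15:40, 1)), ""), sprintf("s%02d", 1:15))
  m <- search_homologs(qs, db, sch, details = "all")
  db_len <- sum(nchar(db))
  for (q in names(qs)) {
    scores <- vapply(names(db), function(s)
      smith_waterman(qs[[q]], db[[s]], sch)$raw_score, 0L)
    ev <- evalue(scores, nchar(qs[[q]]), db_len, sch)
    keep <- scores >= 1L
    want <- names(db)[keep][order(-scores[keep], ev[keep],
                                  names(db)[keep])]
    got <- m$subject_id[m$query_id == q]
    expect_equal(got, want)
  }
  # search result invariant to database input order
  m_rev <- search_homologs(qs, rev(db), sch, details = "all")
  key <- function(x) x[order(x$query_id, x$rank),
                       c("query_id", "subject_id", "raw_score")]
  expect_equal(key(as.data.frame(m)), key(as.data.frame(m_rev)),
               ignore_attr = TRUE)
})

test_that("identity and coverage percentages stay within [0, 100]", {
  set.seed(41)
  qs <- setNames(vapply(1:20, function(i)
    random_protein(sample(20:80, 1)), ""), paste0("q", 1:20))
  db <- setNames(vapply(1:8, function(i)
    random_protein(sample(20:80, 1)), ""), paste0("s", 1:8))
  m <- search_homologs(qs, db, sch, details = "all")
  expect_true(all(m$pct_identity >= 0 & m$pct_identity <= 100))
  expect_true(all(m$query_coverage_pct >= 0 & m$query_coverage_pct <= 100))
})

test_that("tabular match files parse, compute coverage, and round-trip", {
  row12 <- "q1\ts1\t95.000\t100\t5\t0\t1\t100\t1\t100\t1e-30\t200.0"
  row13 <- "q2\ts2\t88.000\t50\t6\t0\t11\t60\t1\t50\t1e-10\t90.0\t25.000"
  f <- tempfile()
  writeLines(c(row12, row13), f)
  m <- read_tabular_matches(f, query_lengths = c(q1 = 200L, q2 = 200L))
  expect_equal(nrow(m), 2L)
  # 12-column row: coverage from qstart/qend over the query length
  expect_equal(m$query_coverage_pct[m$query_id == "q1"], 50)
  # 13-column row: coverage taken from the file
  expect_equal(m$query_coverage_pct[m$query_id == "q2"], 25)
  expect_equal(m$query_start[m$query_id == "q1"], 0L)

  out <- tempfile()
  write_tabular_matches(m, out)
  back <- read_tabular_matches(out)
  expect_equal(back$query_id, m$query_id)
  expect_equal(back$subject_id, m$subject_id)
  expect_equal(back$pct_identity, m$pct_identity)
  expect_equal(back$query_coverage_pct, m$query_coverage_pct)
  expect_equal(back$query_start, m$query_start)
  expect_equal(back$evalue, m$evalue)

  writeLines("q1\ts1\tbad", f)
  expect_error(read_tabular_matches(f), "malformed")
  writeLines(row12, f)
  expect_error(read_tabular_matches(f), "query_lengths")
})
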