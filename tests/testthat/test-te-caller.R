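sch <- scoring_scheme()

small_te_db <- function(seed = 101L) {
  set.seed(seed)
  te_db(
    te_id = c("gypsyA_gag", "gypsyA_pol", "belA_gag", "jockeyA_orf1",
              "jockeyA_orf2", "marinerA_transposase"),
    source_db = "TEFAM",
    te_class = c("I", "I", "I", "I", "I", "II"),
    order = c("LTR", "LTR", "LTR", "NON_LTR", "NON_LTR", "DNA_TIR"),
    clade = c("Ty3/gypsy", "Ty3/gypsy", "BEL", "Jockey", "Jockey",
              "IS630-Tc1-mariner"),
    orf_type = c("GAG", "POL", "GAG", "ORF1", "ORF2", "TRANSPOSASE"),
    protein = vapply(c(300L, 450L, 280L, 250L, 420L, 330L),
                     function(L) random_protein(L), ""))
}

test_that("TE database metadata validates and round-trips through FASTA", {
  db <- small_te_db()
  expect_error(te_db("x", "TEFAM", "I", "LTR", "Ty3/gypsy", "ORF2", "MAK"),
               "cannot encode")
  f <- tempfile(fileext = ".fasta")
  write_te_fasta(db, f)
  back <- read_te_fasta(f)
  expect_equal(back$te_id, db$te_id)
  expect_equal(back$order, db$order)
  expect_equal(back$clade, db$clade)
  expect_equal(back$orf_type, db$orf_type)
  expect_equal(back$protein, db$protein)
})

test_that("TE calling applies the strict thresholds and the exact tier", {
  db <- small_te_db()
  # identical query: one call, exact tier
  calls <- call_tes(c(q1 = db$protein[1]), db, scheme = sch)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$te_id, "gypsyA_gag")
  expect_equal(calls$tier, "EXACT")
  # diverged copy: standard call at defaults, none at a raised identity floor
  q <- mutate_protein(db$protein[2], 0.55, seed = 17)
  aln <- smith_waterman(q, db$protein[2], sch)
  ident <- 100 * aln$identities / aln$aln_length
  expect_gt(ident, 30); expect_lt(ident, 60)
  c1 <- call_tes(c(q = q), db, scheme = sch)
  expect_equal(c1$tier, "STANDARD")
  c2 <- call_tes(c(q = q), db, te_call_params(identity_min_pct = 60),
                 scheme = sch)
  expect_equal(nrow(c2), 0L)
  # strictness: a threshold equal to the observed value rejects the call
  c3 <- call_tes(c(q = q), db,
                 te_call_params(identity_min_pct = c1$pct_identity),
                 scheme = sch)
  expect_equal(nrow(c3), 0L)
  c4 <- call_tes(c(q = q), db,
                 te_call_params(coverage_min_pct = c1$query_coverage_pct,
                                exact_coverage_pct = 100),
                 scheme = sch)
  expect_equal(nrow(c4), 0L)
  # unrelated query: no call
  expect_equal(nrow(call_tes(c(q = random_protein(200L)), db,
                             scheme = sch)), 0L)
})

test_that("raising any threshold never increases the number of calls", {
  db <- small_te_db()
  set.seed(18)
  queries <- setNames(c(
    vapply(1:10, function(i) mutate_protein(
      db$protein[sample.int(6, 1)], runif(1, 0, 0.6), seed = 300 + i), ""),
    vapply(1:5, function(i) random_protein(250L), "")),
    sprintf("q%02d", 1:15))
  base <- nrow(call_tes(queries, db, scheme = sch))
  for (p in list(te_call_params(identity_min_pct = 50),
                 te_call_params(coverage_min_pct = 70),
                 te_call_params(evalue_max = 1e-20))) {
    expect_lte(nrow(call_tes(queries, db, p, sch)), base)
  }
  # EXACT calls are a subset of all calls
  calls <- call_tes(queries, db, scheme = sch)
  expect_true(all(calls$query_id[calls$tier == "EXACT"] %in%
                    calls$query_id))
  expect_true(all(calls$pct_identity[calls$tier == "EXACT"] > 95))
})

test_that("calibration curves behave on degenerate inputs", {
  db <- small_te_db()
  set.seed(19)
  bg <- setNames(vapply(1:10, function(i) random_protein(200L), ""),
                 paste0("b", 1:10))
  tg <- setNames(db$protein[1:4], paste0("t", 1:4))
  cc <- coverage_calibration(tg, bg, db, scheme = sch)
  # background with no TE homology is identically zero
  expect_true(all(cc$background == 0))
  # identical targets stay at 1.0 through cutoff 95
  expect_true(all(cc$target[cc$cutoff <= 95] == 1))
  expect_equal(cc$target[cc$cutoff == 100], 0)  # coverage > 100 impossible
  # monotone non-increasing
  expect_true(all(diff(cc$target) <= 0))
  expect_true(all(diff(cc$background) <= 0))
  ic <- identity_calibration(tg, bg, db, scheme = sch)
  expect_true(all(diff(ic$target) <= 0))
  expect_equal(ic$target[ic$cutoff == 0], 1)
  expect_error(coverage_calibration(tg, bg, db, grid = numeric(0)), "grid")
})

test_that("calibration proportions equal brute-force filtering", {
  db <- small_te_db()
  set.seed(19)
  tg <- setNames(c(vapply(1:6, function(i) mutate_protein(
    db$protein[i], runif(1, 0.05, 0.3), seed = 400 + i), ""),
    vapply(1:2, function(i) random_protein(220L), "")),
    sprintf("t%02d", 1:8))
  bg <- setNames(vapply(1:6, function(i) random_protein(220L), ""),
                 sprintf("b%02d", 1:6))
  grid <- c(30, 40, 50)
  ic <- identity_calibration(tg, bg, db, grid = grid, scheme = sch)
  # brute force: best hit per query from an exhaustive search
  proteins <- setNames(db$protein, db$te_id)
  brute <- function(queries) {
    vapply(grid, function(cut) {
      n <- 0L
      for (q in names(queries)) {
        m <- search_homologs(queries[q], proteins, sch, details = "all")
        if (!nrow(m)) next
        b <- m[m$rank == 1, ]
        if (b$evalue < 1e-5 && b$query_coverage_pct > 45 &&
            b$pct_identity > cut) n <- n + 1L
      }
      n / length(queries)
    }, 0)
  }
  expect_equal(ic$target, brute(tg))
  expect_equal(ic$background, brute(bg))
})

test_that("threshold selection finds the knee of constructed curves", {
  grid <- seq(0, 100, by = 5)
  # background drops rapidly, target resistant up to ~75
  target <- ifelse(grid <= 75, 0.155, ifelse(grid <= 95, 0.04, 0))
  background <- ifelse(grid < 40, 0.007, ifelse(grid < 45, 0.004, 0.0005))
  curves <- data.frame(cutoff = grid, target = target,
                       background = background)
  expect_equal(select_coverage_threshold(curves), 45)
  # background identically zero: grid minimum
  curves0 <- data.frame(cutoff = grid, target = target, background = 0)
  expect_equal(select_coverage_threshold(curves0), 0)
  # degenerate identical curves fall back to the max-difference rule
  same <- data.frame(cutoff = grid, target = 0.5, background = 0.5)
  expect_equal(select_coverage_threshold(same), 0)
})

test_that("single-peptide QC removes only conflicting calls", {
  db <- small_te_db()
  calls <- structure(data.frame(
    query_id = c("PG1", "PG2", "PG3", "PG4"),
    te_id = c("gypsyA_gag", "gypsyA_pol", "jockeyA_orf2", "belA_gag"),
    clade = c("Ty3/gypsy", "Ty3/gypsy", "Jockey", "BEL"),
    order = c("LTR", "LTR", "NON_LTR", "LTR"),
    orf_type = c("GAG", "POL", "ORF2", "GAG"),
    stringsAsFactors = FALSE), class = c("te_calls", "data.frame"))
  groups <- data.frame(
    group_id = c("PG1", "PG2", "PG3", "PG4", "PG5"),
    orf_ids = c("o1", "o2", "o3", "o4", "o5"),
    n_orfs = 1L, n_peptides = c(3L, 1L, 1L, 1L, 2L))
  ev <- data.frame(peptide = c("AAAAAAK", "BBBBBBK", "CCCCCCK", "DDDDDDK",
                               "EEEEEEK", "FFFFFFK"))
  # PG1: 3 peptides, one shared with a non-TE group -> retained
  # PG2: 1 peptide shared with PG3 (different order) -> removed
  # PG3: 1 peptide shared with PG2 -> removed
  # PG4: 1 peptide, uniquely mapping -> retained
  ev$orf_ids <- list("o1", c("o1", "o5"), "o1", c("o2", "o3"), "o4", "o5")
  out <- qc_single_peptide(calls, groups, ev)
  expect_setequal(out$query_id, c("PG1", "PG4"))
  expect_setequal(attr(out, "removed"), c("PG2", "PG3"))
})

test_that("QC keeps same-element and same-clade concordant sharing", {
  calls <- structure(data.frame(
    query_id = c("PG1", "PG2"),
    te_id = c("gypsyA_gag", "gypsyB_gag"),
    clade = c("Ty3/gypsy", "Ty3/gypsy"),
    order = c("LTR", "LTR"),
    orf_type = c("GAG", "GAG"),
    stringsAsFactors = FALSE), class = c("te_calls", "data.frame"))
  groups <- data.frame(group_id = c("PG1", "PG2"),
                       orf_ids = c("o1", "o2"), n_orfs = 1L,
                       n_peptides = c(1L, 1L))
  ev <- data.frame(peptide = "GAGGAGKR")
  ev$orf_ids <- list(c("o1", "o2"))  # same clade, same ORF type: concordant
  out <- qc_single_peptide(calls, groups, ev)
  expect_equal(nrow(out), 2L)
})

test_that("database concordance is summarised at order and clade level", {
  mk <- function(ids, orders, clades) {
    structure(data.frame(query_id = ids, order = orders, clade = clades,
                         stringsAsFactors = FALSE),
              class = c("te_calls", "data.frame"))
  }
  a <- mk(paste0("q", 1:8),
          c("LTR", "LTR", "LTR", "LTR", "NON_LTR", "NON_LTR", "DNA_TIR",
            "DNA_TIR"),
          c("Ty3/gypsy", "Ty3/gypsy", "BEL", "BEL", "Jockey", "Jockey",
            "P", "P"))
  # 2 order-level disagreements (q7, q8), 4 clade-level (q3, q4, q7, q8)
  b <- mk(paste0("q", 1:8),
          c("LTR", "LTR", "LTR", "LTR", "NON_LTR", "NON_LTR", "LTR",
            "NON_LTR"),
          c("Ty3/gypsy", "Ty3/gypsy", "Ty1/copia", "Ty1/copia", "Jockey",
            "Jockey", "BEL", "L1"))
  cc <- db_concordance(a, b)
  expect_equal(cc$n_both, 8L)
  expect_equal(cc$order_agreement, 0.75)
  expect_equal(cc$clade_agreement, 0.5)
  # identical sets agree fully
  cc2 <- db_concordance(a, a)
  expect_equal(cc2$order_agreement, 1)
  expect_equal(cc2$clade_agreement, 1)
  # disjoint sets share nothing
  a2 <- mk("x1", "LTR", "BEL")
  cc3 <- db_concordance(a, a2)
  expect_equal(cc3$n_both, 0L)
  expect_true(is.na(cc3$order_agreement))
})

test_that("combining databases can only widen background identification", {
  set.seed(23)
  db1 <- small_te_db()
  extra <- te_db(
    te_id = sprintf("rbX%02d", 1:6), source_db = "REPBASE",
    te_class = "I", order = "LTR", clade = "Ty3/gypsy", orf_type = "OTHER",
    protein = vapply(1:6, function(i) random_protein(300L), ""))
  combined <- db1
  combined <- rbind(combined, extra)
  class(combined) <- c("te_db", "data.frame")
  bg <- setNames(c(
    vapply(1:15, function(i) random_protein(250L), ""),
    mutate_protein(extra$protein[1], 0.2, seed = 5)),  # hits only db2
    sprintf("h%02d", 1:16))
  n1 <- nrow(call_tes(bg, db1, scheme = sch))
  n2 <- nrow(call_tes(bg, combined, scheme = sch))
  expect_gte(n2, n1)
  expect_gte(n2, 1L)
})
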