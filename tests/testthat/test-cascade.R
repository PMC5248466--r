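sch <- scoring_scheme()

make_tiers <- function(aedes, culex, dros) {
  reference_tiers(AEDES = aedes, CULEX = culex, DROSOPHILA = dros)
}

test_that("the cascade stops at the right tier and labels categories", {
  set.seed(13)
  aedes <- setNames(vapply(1:5, function(i) random_protein(150L), ""),
                    paste0("AAEL", 1:5))
  culex <- setNames(vapply(1:5, function(i) random_protein(150L), ""),
                    paste0("CPIJ", 1:5))
  dros <- setNames(vapply(1:3, function(i) random_protein(150L), ""),
                   paste0("FBpp", 1:3))
  tiers <- make_tiers(aedes, culex, dros)

  # identical to a first-tier entry
  r1 <- classify_proteins(c(q = aedes[[1]]), tiers, scheme = sch)
  expect_equal(as.character(r1$category), "AEDES")
  expect_equal(r1$stopping_tier, "AEDES")

  # no hit anywhere
  r2 <- classify_proteins(c(q = random_protein(150L)), tiers, scheme = sch)
  expect_equal(as.character(r2$category), "NON_INSECT")
  expect_true(is.na(r2$stopping_tier))

  # ~70% identical to a second-tier entry, unrelated to the first tier
  q <- mutate_protein(culex[[2]], 0.3, seed = 13)
  aln <- smith_waterman(q, culex[[2]], sch)
  expect_gt(100 * aln$identities / aln$aln_length, 60)  # oracle check
  r3 <- classify_proteins(c(q = q), tiers, scheme = sch)
  expect_equal(as.character(r3$category), "NON_AEDES_INSECT")
  expect_equal(r3$stopping_tier, "CULEX")
})

test_that("categories partition the queries and respect tier order", {
  set.seed(14)
  aedes <- setNames(vapply(1:4, function(i) random_protein(120L), ""),
                    paste0("A", 1:4))
  culex <- setNames(vapply(1:4, function(i) random_protein(120L), ""),
                    paste0("C", 1:4))
  dros <- setNames(vapply(1:4, function(i) random_protein(120L), ""),
                   paste0("D", 1:4))
  tiers <- make_tiers(aedes, culex, dros)
  queries <- c(qa = aedes[[1]], qc = culex[[1]], qd = dros[[1]],
               qn = random_protein(120L),
               qboth = aedes[[2]])   # present in tier 1, stops there
  res <- classify_proteins(queries, tiers, scheme = sch)
  expect_equal(nrow(res), length(queries))
  expect_equal(sum(table(res$category)), length(queries))
  expect_equal(as.character(res$category[res$query_id == "qd"]),
               "NON_AEDES_INSECT")
  # within-tier database order does not change the outcome
  tiers_r <- make_tiers(rev(aedes), rev(culex), rev(dros))
  res_r <- classify_proteins(queries, tiers_r, scheme = sch)
  expect_equal(as.character(res$category), as.character(res_r$category))
})

test_that("raising the identity stop threshold only demotes categories", {
  set.seed(15)
  culex <- setNames(vapply(1:6, function(i) random_protein(150L), ""),
                    paste0("C", 1:6))
  aedes <- setNames(vapply(1:6, function(i) random_protein(150L), ""),
                    paste0("A", 1:6))
  dros <- setNames(vapply(1:2, function(i) random_protein(150L), ""),
                   paste0("D", 1:2))
  tiers <- make_tiers(aedes, culex, dros)
  queries <- c(
    setNames(vapply(1:4, function(i)
      mutate_protein(aedes[[i]], runif(1, 0, 0.5), seed = 100 + i), ""),
      paste0("qa", 1:4)),
    setNames(vapply(1:4, function(i)
      mutate_protein(culex[[i]], runif(1, 0, 0.5), seed = 200 + i), ""),
      paste0("qc", 1:4)))
  rank_of <- c(AEDES = 1L, NON_AEDES_INSECT = 2L, NON_INSECT = 3L)
  prev <- classify_proteins(queries, tiers, cascade_params(40), sch)
  for (thr in c(60, 80, 95)) {
    cur <- classify_proteins(queries, tiers, cascade_params(thr), sch)
    expect_true(all(rank_of[as.character(cur$category)] >=
                      rank_of[as.character(prev$category)]))
    prev <- cur
  }
})

test_that("partition percentages reproduce the printed-count arithmetic", {
  s <- percentage_summary(c(AEDES = 5457, NON_AEDES_INSECT = 215,
                            NON_INSECT = 899))
  expect_equal(s$pct_int, c(83, 3, 14))
  # annotation-status arithmetic of the mapped proteome
  s2 <- percentage_summary(c(annotated = 3309, hypothetical = 674,
                             conserved_hypothetical = 1474))
  expect_equal(s2$pct_int, c(61, 12, 27))
  # one-decimal convention
  expect_equal(percentage_summary(c(te = 127, rest = 899 - 127))$pct_1dp[1],
               14.1)
  expect_equal(percentage_summary(c(te = 9, rest = 5457 - 9))$pct_1dp[1],
               0.2)
  # single category
  expect_equal(percentage_summary(c(x = 42))$pct_int, 100)
})

test_that("random partitions sum exactly and round consistently", {
  set.seed(5)
  for (i in 1:20) {
    counts <- rmultinom(1, sample(50:5000, 1), c(0.6, 0.3, 0.1))[, 1]
    counts <- setNames(counts, c("A", "B", "C"))
    s <- percentage_summary(counts)
    expect_equal(sum(s$count), sum(counts))
    expect_lte(abs(sum(s$pct_int) - 100), 1)     # one rounding unit
    expect_lte(abs(sum(s$pct_1dp) - 100), 0.1)
  }
})

test_that("the peptide-support filter restricts the partition", {
  res <- structure(data.frame(
    query_id = c("PG1", "PG2", "PG3"),
    category = factor(c("AEDES", "AEDES", "NON_INSECT"),
                      levels = c("AEDES", "NON_AEDES_INSECT",
                                 "NON_INSECT")),
    stopping_tier = c("AEDES", "AEDES", NA),
    stringsAsFactors = FALSE), class = c("cascade_results", "data.frame"))
  groups <- data.frame(group_id = c("PG1", "PG2", "PG3"),
                       orf_ids = c("a", "b", "c"), n_orfs = 1L,
                       n_peptides = c(3L, 1L, 2L))
  s1 <- partition_summary(res, 1L, groups)
  expect_equal(sum(s1$count), 3L)
  s2 <- partition_summary(res, 2L, groups)
  expect_equal(sum(s2$count), 2L)
  expect_equal(s2$count[s2$category == "AEDES"], 1L)
})

test_that("the viral screen applies the score floor and exclusion rule", {
  set.seed(16)
  vdb <- setNames(vapply(1:3, function(i) random_protein(200L), ""),
                  paste0("VIR", 1:3))
  tedb_prot <- setNames(vapply(1:3, function(i) random_protein(200L), ""),
                        paste0("TE", 1:3))
  # viral protein, absent from the exclusion databases
  hits <- screen_viral(c(qv = vdb[[1]]), vdb, te_db = tedb_prot,
                       scheme = sch)
  expect_equal(hits$query_id, "qv")
  expect_true(is.na(hits$excluded_by))
  # below the score floor: a random query reaches no score > 50
  none <- screen_viral(c(qr = random_protein(60L)), vdb, scheme = sch)
  expect_equal(nrow(none), 0L)
  # stronger TE homology excludes the hit: query is an exact TE protein
  # with a weaker (planted) viral relative
  q <- tedb_prot[[1]]
  vdb2 <- c(vdb, VIRX = mutate_protein(q, 0.45, seed = 99))
  both <- screen_viral(c(qx = q), vdb2, te_db = tedb_prot, scheme = sch)
  expect_equal(both$excluded_by, "TE")
})
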