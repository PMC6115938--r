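make_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    hit_table(r[[1]], r[[2]], as.numeric(r[[3]]), as.integer(r[[4]]),
              as.numeric(r[[5]]), as.numeric(r[[6]]),
              as.integer(r[[7]]), as.integer(r[[7]]))))
}

test_that("bidirectional best hits require reciprocity and thresholds", {
  ## planted reciprocal pair at 85% identity, full coverage
  ab <- make_hits(list("a1", "b1", 85, 100, 1e-40, 200, 100))
  ba <- make_hits(list("b1", "a1", 85, 100, 1e-40, 200, 100))
  got <- bidirectional_best_hits(ab, ba)
  expect_equal(got$idA, "a1")
  expect_equal(got$identityAB, 85)

  ## a -> b best but b -> a2 best: reciprocity violated, no pair for a
  ab2 <- make_hits(list("a1", "b1", 90, 100, 1e-40, 200, 100))
  ba2 <- make_hits(list("b1", "a2", 95, 100, 1e-50, 300, 100),
                   list("b1", "a1", 90, 100, 1e-40, 200, 100))
  expect_equal(nrow(bidirectional_best_hits(ab2, ba2)), 0L)

  ## reciprocal pair below the identity threshold is excluded
  ab3 <- make_hits(list("a1", "b1", 65, 100, 1e-40, 200, 100))
  ba3 <- make_hits(list("b1", "a1", 65, 100, 1e-40, 200, 100))
  expect_equal(nrow(bidirectional_best_hits(ab3, ba3, 70, 70)), 0L)
  expect_equal(nrow(bidirectional_best_hits(ab3, ba3, 60, 70)), 1L)

  ## coverage threshold: 60/100 residues = 60% < 70%
  ab4 <- make_hits(list("a1", "b1", 90, 60, 1e-40, 200, 100))
  ba4 <- make_hits(list("b1", "a1", 90, 60, 1e-40, 200, 100))
  expect_equal(nrow(bidirectional_best_hits(ab4, ba4)), 0L)
})

test_that("BBH bitscore ties break by e-value, alignment length, subject id", {
  ab <- make_hits(list("a1", "b1", 90, 100, 1e-40, 200, 100),
                  list("a1", "b2", 90, 100, 1e-50, 200, 100))
  ba <- make_hits(list("b2", "a1", 90, 100, 1e-50, 200, 100))
  got <- bidirectional_best_hits(ab, ba)
  expect_equal(got$idB, "b2")  # lower e-value wins the tie
})

test_that("BBH matches the brute-force reciprocal-maximum oracle on seeded tables", {
  for (seed in 1:8) {
    spec <- fixture_spec(seed = seed, n_orthologs = 30L, n_decoys = 3L,
                         ortholog_identity = 85, identity_jitter = 10)
    tabs <- sim_hit_tables(spec)
    got <- bidirectional_best_hits(tabs$hitsAB, tabs$hitsBA)
    want <- oracle_bbh(tabs$hitsAB, tabs$hitsBA, 70, 70)
    expect_equal(got$idA, want$idA)
    expect_equal(got$idB, want$idB)
    expect_equal(got$identityAB, want$identityAB)
  }
})

test_that("AAI is the mean of pairwise mean identities, with the e-value filter", {
  ab <- make_hits(list("a1", "b1", 50, 100, 1e-40, 200, 100),
                  list("a2", "b2", 60, 100, 1e-40, 200, 100))
  ba <- make_hits(list("b1", "a1", 50, 100, 1e-40, 200, 100),
                  list("b2", "a2", 60, 100, 1e-40, 200, 100))
  expect_equal(compute_aai(ab, ba)$aai, 55)

  ## pair failing the e-value ceiling drops out of the mean
  ab2 <- make_hits(list("a1", "b1", 50, 100, 1e-40, 200, 100),
                   list("a2", "b2", 60, 100, 1e-6, 200, 100))
  ba2 <- make_hits(list("b1", "a1", 50, 100, 1e-40, 200, 100),
                   list("b2", "a2", 60, 100, 1e-6, 200, 100))
  expect_equal(compute_aai(ab2, ba2)$aai, 50)

  ## zero qualifying pairs is an explicit error, never 0
  expect_error(compute_aai(ab2[2, ], ba2[2, ]), class = "panmetab_data_error")
})

test_that("AAI recovers the planted ortholog identities exactly", {
  spec <- fixture_spec(seed = 5)
  tabs <- sim_hit_tables(spec)
  aai <- compute_aai(tabs$hitsAB, tabs$hitsBA)
  expect_equal(aai$aai, mean(tabs$planted_orthologs$identity), tolerance = 1e-12)
  expect_equal(aai$n_orthologs, nrow(tabs$planted_orthologs))
})

test_that("species clustering joins strains passing both measures", {
  strains <- c("A", "B", "C")
  ani <- matrix(c(100, 98.5, 80, 98.5, 100, 80, 80, 80, 100), 3,
                dimnames = list(strains, strains))
  aai <- matrix(c(100, 98.9, 75, 98.9, 100, 75, 75, 75, 100), 3,
                dimnames = list(strains, strains))
  part <- cluster_species(ani, aai, threshold = 96)
  expect_equal(part$clusters, list(c("A", "B"), "C"))

  ## all pairs at 100 -> one cluster
  all100 <- matrix(100, 3, 3, dimnames = list(strains, strains))
  expect_length(cluster_species(all100, all100)$clusters, 1L)

  ## one measure failing blocks the edge under AND semantics, not under OR
  aai2 <- aai; aai2["A", "B"] <- aai2["B", "A"] <- 90
  expect_length(cluster_species(ani, aai2, threshold = 96)$clusters, 3L)
  expect_length(cluster_species(ani, aai2, threshold = 96, require_both = FALSE)$clusters, 2L)

  ## asymmetry beyond 1e-9 rejected
  bad <- ani; bad["A", "B"] <- 99
  expect_error(cluster_species(bad, aai), class = "panmetab_data_error")
})

test_that("species clustering is order-invariant and monotone in the threshold", {
  set.seed(9)
  strains <- paste0("s", 1:9)
  block <- rep(1:3, each = 3)
  ani <- matrix(80 + runif(81) * 5, 9, 9, dimnames = list(strains, strains))
  ani[block == rep(block, each = 9)] <- 97 + runif(sum(block == rep(block, each = 9)))
  ani <- (ani + t(ani)) / 2; diag(ani) <- 100
  p96 <- cluster_species(ani, threshold = 96)
  perm <- sample(9)
  p96_perm <- cluster_species(ani[perm, perm], threshold = 96)
  expect_equal(lapply(p96$clusters, sort), lapply(p96_perm$clusters, sort))
  ## lowering the threshold never increases the number of clusters
  prev <- Inf
  for (thr in c(99, 96, 94, 90, 80)) {
    k <- length(cluster_species(ani, threshold = thr)$clusters)
    expect_lte(k, prev)
    prev <- k
  }
})

test_that("shared_specific_sets applies exact in/out set algebra", {
  clusters <- list(f1 = c("A", "B", "C"), f2 = c("A", "B", "C", "D"), f3 = "A")
  expect_equal(shared_specific_sets(clusters, c("A", "B", "C"), "D"), "f1")
  expect_error(shared_specific_sets(clusters, character(), "D"),
               class = "panmetab_config_error")
  expect_error(shared_specific_sets(clusters, c("A", "Z")),
               class = "panmetab_data_error")
  ## mirrors the arsenic-oxidizer analysis: families common and specific
  ## to an in-group of three strains
  cl <- c(lapply(1:13, function(i) c("aob1", "aob2", "aob3")),
          lapply(1:5, function(i) c("aob1", "aob2", "aob3", "other1")),
          list("aob1"))
  names(cl) <- paste0("fam", seq_along(cl))
  got <- shared_specific_sets(cl, c("aob1", "aob2", "aob3"), c("other1"))
  expect_length(got, 13L)
})

test_that("hit tables round-trip through the 14-column dialect and seqlen sidecar", {
  spec <- fixture_spec(seed = 2, n_orthologs = 5L)
  tabs <- sim_hit_tables(spec)
  f <- tempfile(fileext = ".tsv")
  write_hits(tabs$hitsAB, f)
  got <- read_hits(f)
  expect_equal(got$qseqid, tabs$hitsAB$qseqid)
  expect_equal(got$bitscore, tabs$hitsAB$bitscore, tolerance = 1e-9)
  ## 12-column + sidecar
  f12 <- tempfile(fileext = ".tsv")
  utils::write.table(tabs$hitsAB[, 1:12], f12, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  expect_error(read_hits(f12), class = "panmetab_data_error")
  sl <- unique(data.frame(id = c(tabs$hitsAB$qseqid, tabs$hitsAB$sseqid),
                          len = c(tabs$hitsAB$qlen, tabs$hitsAB$slen)))
  side <- tempfile(fileext = ".tsv")
  utils::write.table(sl, side, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  got12 <- read_hits(f12, side)
  expect_equal(got12$qlen, tabs$hitsAB$qlen)
})
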