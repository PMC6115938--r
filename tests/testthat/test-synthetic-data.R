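test_that("generators are byte-identical under a fixed seed and spec", {
  spec <- fixture_spec(seed = 61, genome_length = 5000L, n_scaffolds = 3L,
                       length_range = c(500L, 2000L))
  a1 <- sim_assembly(spec); a2 <- sim_assembly(spec)
  expect_identical(as.character(a1$seq), as.character(a2$seq))
  expect_identical(a1$coverage, a2$coverage)
  p1 <- sim_divergent_pair(spec); p2 <- sim_divergent_pair(spec)
  expect_identical(as.character(p1$b), as.character(p2$b))
  h1 <- sim_hit_tables(spec); h2 <- sim_hit_tables(spec)
  expect_identical(h1$hitsAB, h2$hitsAB)
  m1 <- sim_presence_absence(spec); m2 <- sim_presence_absence(spec)
  expect_identical(unclass(m1$matrix)[, ], unclass(m2$matrix)[, ])
  ## a different seed changes the sequences
  other <- sim_assembly(fixture_spec(seed = 62, n_scaffolds = 3L,
                                     length_range = c(500L, 2000L)))
  expect_false(identical(as.character(a1$seq), as.character(other$seq)))
})

test_that("assembly generator hits its compositional targets", {
  spec <- fixture_spec(seed = 63, n_scaffolds = 40L, length_range = c(2000L, 3000L),
                       gc_target = 0.5)
  asm <- sim_assembly(spec)
  expect_equal(length(asm), 40L)
  w <- Biostrings::width(asm$seq)
  expect_true(all(w >= 2000 & w <= 3000))
  cov <- scaffold_coverage(asm)
  expect_true(all(cov >= spec$coverage_range[1] & cov <= spec$coverage_range[2]))
  ## ~1e5 nt total: binomial concentration keeps GC within half a point
  gc <- assembly_stats(asm)$gc_percent
  expect_gt(gc, 49); expect_lt(gc, 51)
  ## empty case
  expect_length(sim_assembly(fixture_spec(seed = 1, n_scaffolds = 0L)), 0L)
})

test_that("divergent pairs carry the planted substitution rate with no indels", {
  spec <- fixture_spec(seed = 64, divergence = 0.02, genome_length = 100000L)
  pair <- sim_divergent_pair(spec)
  a <- strsplit(as.character(pair$a[[1]]), "")[[1]]
  b <- strsplit(as.character(pair$b[[1]]), "")[[1]]
  expect_length(b, length(a))  # substitution-only
  mismatch <- mean(a != b)
  expect_equal(mismatch, 0.02, tolerance = 0.003 / 0.02)
  expect_equal(pair$planted_ani, 0.98)
  ## divergence 0: identical genomes
  p0 <- sim_divergent_pair(fixture_spec(seed = 64, divergence = 0,
                                        genome_length = 2000L))
  expect_identical(as.character(p0$a[[1]]), as.character(p0$b[[1]]))
  expect_equal(p0$planted_ani, 1.0)
  ## divergence 1: substitution to an alternative base forces every site to differ
  p1 <- sim_divergent_pair(fixture_spec(seed = 64, divergence = 1,
                                        genome_length = 2000L))
  a1 <- strsplit(as.character(p1$a[[1]]), "")[[1]]
  b1 <- strsplit(as.character(p1$b[[1]]), "")[[1]]
  expect_true(all(a1 != b1))
})

test_that("planted hit tables make every ortholog a recoverable BBH", {
  spec <- fixture_spec(seed = 65, n_orthologs = 5L, n_decoys = 0L)
  tabs <- sim_hit_tables(spec)
  got <- bidirectional_best_hits(tabs$hitsAB, tabs$hitsBA)
  expect_equal(got$idA, tabs$planted_orthologs$idA)
  expect_equal(got$idB, tabs$planted_orthologs$idB)
  ## identities below the threshold are not recovered
  low <- sim_hit_tables(fixture_spec(seed = 65, n_orthologs = 5L,
                                     ortholog_identity = 65, identity_jitter = 0))
  expect_equal(nrow(bidirectional_best_hits(low$hitsAB, low$hitsBA, 70, 70)), 0L)
  ## decoys are strictly dominated: recovery unchanged
  decoyed <- sim_hit_tables(fixture_spec(seed = 65, n_orthologs = 5L, n_decoys = 3L))
  got2 <- bidirectional_best_hits(decoyed$hitsAB, decoyed$hitsBA)
  expect_equal(got2$idA, decoyed$planted_orthologs$idA)
})

test_that("presence/absence generator enforces its count contracts", {
  spec <- fixture_spec(seed = 66, n_core_families = 10L, n_unique_families = 3L,
                       strains = c("M14", "A49", "OV14", "CasidaA"),
                       shared_blocks = list(), island_spec = list(),
                       genes_per_scaffold = 60L)
  pam <- sim_presence_absence(spec)
  expect_equal(length(core_families(pam$matrix)), 10L)
  expect_equal(length(unique_families(pam$matrix, "M14")), 3L)
  ## all-core matrix: zero unique
  allcore <- sim_presence_absence(fixture_spec(seed = 66, n_core_families = 6L,
                                               n_unique_families = 0L,
                                               strains = c("M14", "A49"),
                                               shared_blocks = list(),
                                               island_spec = list(),
                                               genes_per_scaffold = 30L))
  expect_length(unique_families(allcore$matrix, "M14"), 0L)
  ## overlapping island spans rejected at spec construction
  expect_error(fixture_spec(island_spec = list(list(scaffold = 2L, at = 5L, n = 10L),
                                               list(scaffold = 2L, at = 8L, n = 4L))),
               class = "panmetab_config_error")
  expect_error(fixture_spec(divergence = 1.5), class = "panmetab_config_error")
  expect_error(sim_presence_absence(fixture_spec(strains = "only_one")),
               class = "panmetab_config_error")
})

test_that("model-pair generator plants classifiable duplicates and a viable recipient", {
  spec <- fixture_spec(seed = 67)
  mod <- sim_model_pair(spec)
  validate_model(mod$recipient); validate_model(mod$donor)
  ## every planted proton variant classifies as proton_variant against its target
  for (id in mod$planted$proton_variant)
    expect_equal(classify_match(mod$donor$reactions[[id]],
                                mod$recipient$reactions$C_carbon1), "proton_variant")
  for (id in mod$planted$stoich_variant)
    expect_equal(classify_match(mod$donor$reactions[[id]],
                                mod$recipient$reactions$C_carbon1), "stoich_variant")
  ## recipient grows on a planted carbon source
  scr <- carbon_source_screen(mod$recipient,
                              medium_spec(carbon_exchange_ids =
                                            c("EX_carbon1", "EX_carbon2")),
                              panel = mod$planted$growth_sources)
  expect_equal(scr$n_growth, 1L)
  ## zero planted transfers when nothing new is planted
  bare <- sim_model_pair(fixture_spec(seed = 67, model_spec = list(
    n_identical = 1L, n_proton_variants = 0L, n_stoich_variants = 0L,
    n_transferable = 0L, n_dead_end_chains = 0L, chain_length = 3L,
    n_unmapped_genes = 0L)))
  expect_length(bare$planted$transfer_persist, 0L)
  res <- merge_pipeline(bare$recipient,
                        list(list(model = bare$donor, ortholog_map = bare$ortholog_map)))
  expect_equal(res$report$reactions_transferred, 0L)
})

test_that("fixture serialization exercises the on-disk formats the pipeline reads", {
  spec <- fixture_spec(seed = 68, n_scaffolds = 3L, length_range = c(500L, 1500L),
                       genome_length = 3000L, n_core_families = 8L,
                       n_unique_families = 4L, strains = c("M14", "A49", "OV14"),
                       shared_blocks = list(), island_spec = list(),
                       genes_per_scaffold = 30L)
  d <- tempfile()
  files <- simulate_fixtures(spec, d)
  expect_true(all(file.exists(unlist(files))))
  asm <- read_scaffolds(files$assembly, files$coverage)
  expect_equal(length(asm), 3L)
  pam <- read_presence_absence(files$presence_absence)
  expect_equal(nrow(pam), 12L)
  truth <- jsonlite::read_json(files$ground_truth, simplifyVector = TRUE)
  expect_equal(truth$pangenome$n_unique, 4L)
  ## rerunning writes byte-identical fixtures
  d2 <- tempfile()
  files2 <- simulate_fixtures(spec, d2)
  for (key in c("assembly", "hitsAB", "presence_absence", "recipient")) {
    expect_identical(readLines(files[[key]]), readLines(files2[[key]]))
  }
})
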