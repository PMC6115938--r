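#' Fixture specification for the synthetic-data generators
#'
#' Bundles every tunable of the seeded generators with defaults chosen to
#' emulate the statistical structure of a draft *Ensifer*-like assembly and
#' its comparative analysis: 45 scaffolds at ~61.5% GC and 10-230x
#' coverage; 100-kb genome pairs at 1.5% substitution divergence (planted
#' ANI 98.5%); proteome hit tables with 20 reciprocal orthologs near 98.9%
#' identity; a 46-strain presence/absence matrix with 1652 core families,
#' 656 focal-unique families and shared blocks of 243 and 812 families
#' that put 899 / 812 families into the focal four-strain Venn cells; and
#' a recipient/donor metabolic-model pair with planted identical,
#' proton-variant, stoichiometry-variant, transferable and dead-end-chain
#' reactions. Same seed + spec regenerates byte-identical fixtures.
#'
#' @param seed Integer RNG seed.
#' @param n_scaffolds Number of scaffolds for [sim_assembly()].
#' @param length_range Integer pair: scaffold length range (nt).
#' @param gc_target GC fraction in \[0, 1\].
#' @param coverage_range Real pair: fold-coverage range.
#' @param genome_length Genome length for [sim_divergent_pair()].
#' @param divergence Per-base substitution probability in \[0, 1\].
#' @param n_orthologs,ortholog_identity,identity_jitter,n_decoys,
#'   ortholog_evalue Hit-table parameters for [sim_hit_tables()].
#' @param strains Strain ids for [sim_presence_absence()]; the first is
#'   the focal strain.
#' @param n_core_families Families present in all strains.
#' @param n_unique_families Families present only in the focal strain.
#' @param shared_blocks List of `list(strains =, n =)` blocks of families
#'   present in exactly those strains.
#' @param island_spec List of `list(scaffold =, at =, n =)`: contiguous
#'   placements of unique genes (scaffold index, first gene rank, gene
#'   count) for the planted genomic islands.
#' @param genes_per_scaffold Gene ranks available per scaffold.
#' @param model_spec List of planted model-pair parameters:
#'   `n_identical`, `n_proton_variants`, `n_stoich_variants`,
#'   `n_transferable` (persisting unique-reaction units, 2 reactions each),
#'   `n_dead_end_chains`, `chain_length`, `n_unmapped_genes`.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_scaffolds = 45L,
                         length_range = c(1000L, 400000L),
                         gc_target = 0.6147,
                         coverage_range = c(10, 230),
                         genome_length = 100000L,
                         divergence = 0.015,
                         n_orthologs = 20L,
                         ortholog_identity = 98.9,
                         identity_jitter = 1,
                         n_decoys = 2L,
                         ortholog_evalue = 1e-50,
                         strains = c("M14", "A49", "OV14", "CasidaA",
                                     sprintf("S%02d", 5:46)),
                         n_core_families = 1652L,
                         n_unique_families = 656L,
                         shared_blocks = list(
                           list(strains = c("M14", "S10"), n = 243L),
                           list(strains = c("M14", "A49"), n = 812L),
                           list(strains = c("A49", "OV14", "CasidaA"), n = 300L)),
                         island_spec = list(
                           list(scaffold = 11L, at = 5L, n = 120L),
                           list(scaffold = 8L, at = 3L, n = 97L)),
                         genes_per_scaffold = 400L,
                         model_spec = list(n_identical = 2L, n_proton_variants = 2L,
                                           n_stoich_variants = 1L, n_transferable = 3L,
                                           n_dead_end_chains = 2L, chain_length = 3L,
                                           n_unmapped_genes = 1L)) {
  spec <- list(seed = pm_assert_count(seed, "seed"),
               n_scaffolds = pm_assert_count(n_scaffolds, "n_scaffolds"),
               length_range = as.integer(length_range),
               gc_target = pm_assert_scalar_number(gc_target, "gc_target", 0, 1),
               coverage_range = as.numeric(coverage_range),
               genome_length = pm_assert_count(genome_length, "genome_length"),
               divergence = pm_assert_scalar_number(divergence, "divergence", 0, 1),
               n_orthologs = pm_assert_count(n_orthologs, "n_orthologs"),
               ortholog_identity = pm_assert_scalar_number(ortholog_identity,
                                                           "ortholog_identity", 0, 100),
               identity_jitter = pm_assert_scalar_number(identity_jitter,
                                                         "identity_jitter", 0, 50),
               n_decoys = pm_assert_count(n_decoys, "n_decoys"),
               ortholog_evalue = pm_assert_scalar_number(ortholog_evalue,
                                                         "ortholog_evalue", 0),
               strains = as.character(strains),
               n_core_families = pm_assert_count(n_core_families, "n_core_families"),
               n_unique_families = pm_assert_count(n_unique_families, "n_unique_families"),
               shared_blocks = shared_blocks,
               island_spec = island_spec,
               genes_per_scaffold = pm_assert_count(genes_per_scaffold, "genes_per_scaffold"),
               model_spec = model_spec)
  if (length(spec$length_range) != 2L || spec$length_range[1] > spec$length_range[2] ||
      spec$length_range[1] < 1L)
    pm_config_error("length_range must be an increasing positive integer pair")
  if (length(spec$coverage_range) != 2L || spec$coverage_range[1] > spec$coverage_range[2] ||
      spec$coverage_range[1] < 0)
    pm_config_error("coverage_range must be an increasing non-negative pair")
  if (anyDuplicated(spec$strains)) pm_config_error("duplicate strain ids")
  for (blk in spec$shared_blocks) {
    if (!all(blk$strains %in% spec$strains))
      pm_config_error("shared block references unknown strain(s)")
    pm_assert_count(blk$n, "shared block n")
  }
  ## overlapping island placements on the same scaffold are a configuration error
  if (length(spec$island_spec) > 1L) {
    spans <- do.call(rbind, lapply(spec$island_spec, function(is)
      data.frame(scaffold = is$scaffold, from = is$at, to = is$at + is$n - 1L)))
    for (scf in unique(spans$scaffold)) {
      s <- spans[spans$scaffold == scf, , drop = FALSE]
      s <- s[order(s$from), , drop = FALSE]
      if (nrow(s) > 1L && any(s$from[-1] <= s$to[-nrow(s)]))
        pm_config_error("overlapping island spans on scaffold %s", scf)
    }
  }
  ms <- spec$model_spec
  for (f in c("n_identical", "n_proton_variants", "n_stoich_variants",
              "n_transferable", "n_dead_end_chains", "chain_length", "n_unmapped_genes"))
    ms[[f]] <- pm_assert_count(ms[[f]] %||% 0L, f)
  spec$model_spec <- ms
  structure(spec, class = "fixture_spec")
}

random_dna <- function(n, gc) {
  if (n == 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic scaffold assembly
#'
#' Scaffold lengths are uniform in `length_range`, per-base composition
#' matches `gc_target` in expectation, and coverage is uniform in
#' `coverage_range`. Deterministic under the spec seed.
#'
#' @param spec A [fixture_spec()].
#' @return A [scaffold_set] (empty when `n_scaffolds = 0`).
#' @export
sim_assembly <- function(spec) {
  if (!inherits(spec, "fixture_spec")) pm_config_error("spec must be a fixture_spec")
  with_seed(spec$seed, {
    n <- spec$n_scaffolds
    if (n == 0L) return(scaffold_set(character(0), numeric(0)))
    lens <- sample(spec$length_range[1]:spec$length_range[2], n, replace = TRUE)
    cov <- stats::runif(n, spec$coverage_range[1], spec$coverage_range[2])
    seqs <- vapply(lens, random_dna, character(1), gc = spec$gc_target)
    names(seqs) <- sprintf("scaffold_%02d", seq_len(n))
    scaffold_set(seqs, cov)
  })
}

#' Generate a genome pair with planted nucleotide divergence
#'
#' Genome B is genome A with independent per-base substitutions at rate
#' `divergence`, the substituted base drawn uniformly from the three
#' alternatives; there are no indels, so the planted ANI is exactly
#' `1 - divergence`.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `a`, `b` ([Biostrings::DNAStringSet]s) and
#'   `planted_ani` (fraction).
#' @export
sim_divergent_pair <- function(spec) {
  if (!inherits(spec, "fixture_spec")) pm_config_error("spec must be a fixture_spec")
  with_seed(spec$seed + 1L, {
    a <- random_dna(spec$genome_length, spec$gc_target)
    bases <- strsplit(a, "")[[1]]
    mut <- stats::runif(length(bases)) < spec$divergence
    if (any(mut)) {
      alt <- vapply(bases[mut], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L),
                    character(1))
      bases[mut] <- alt
    }
    b <- paste(bases, collapse = "")
    list(a = Biostrings::DNAStringSet(c(genomeA = a)),
         b = Biostrings::DNAStringSet(c(genomeB = b)),
         planted_ani = 1 - spec$divergence)
  })
}

#' Generate reciprocal hit tables with planted orthologs
#'
#' Plants `n_orthologs` reciprocal-best-hit pairs at the configured
#' identity (jittered uniformly by `identity_jitter`), full coverage and
#' e-value, with the same identity in both directions; decoy hits are
#' strictly dominated in bitscore so the ground truth is unambiguous (ties
#' are never planted).
#'
#' @param spec A [fixture_spec()].
#' @return A list with `hitsAB`, `hitsBA` (hit tables) and
#'   `planted_orthologs` (data frame `idA`, `idB`, `identity`).
#' @export
sim_hit_tables <- function(spec) {
  if (!inherits(spec, "fixture_spec")) pm_config_error("spec must be a fixture_spec")
  with_seed(spec$seed + 2L, {
    n <- spec$n_orthologs
    if (n == 0L) {
      empty <- hit_table(character(), character(), numeric(), integer(),
                         numeric(), numeric(), integer(), integer())
      return(list(hitsAB = empty, hitsBA = empty,
                  planted_orthologs = data.frame(idA = character(), idB = character(),
                                                 identity = numeric())))
    }
    idA <- sprintf("A_%04d", seq_len(n)); idB <- sprintf("B_%04d", seq_len(n))
    ident <- spec$ortholog_identity +
      stats::runif(n, -spec$identity_jitter, spec$identity_jitter)
    ident <- pmin(100, pmax(0, ident))
    plen <- sample(200:600, n, replace = TRUE)
    best_score <- 2 * plen * ident / 100
    ab <- hit_table(idA, idB, ident, plen, spec$ortholog_evalue, best_score, plen, plen)
    ba <- hit_table(idB, idA, ident, plen, spec$ortholog_evalue, best_score, plen, plen)
    if (spec$n_decoys > 0L && n > 1L) {
      mk_decoys <- function(qid, sids, plen, best_score) {
        rows <- lapply(seq_along(qid), function(i) {
          others <- sample(setdiff(seq_along(sids), i),
                           min(spec$n_decoys, length(sids) - 1L))
          d_ident <- stats::runif(length(others), 30, 60)
          d_len <- pmax(50L, as.integer(round(plen[i] * stats::runif(length(others), 0.5, 0.9))))
          d_score <- best_score[i] - stats::runif(length(others),
                                                  0.2 * best_score[i], 0.6 * best_score[i])
          hit_table(rep(qid[i], length(others)), sids[others], d_ident, d_len,
                    1e-5, d_score, rep(plen[i], length(others)), plen[others])
        })
        do.call(rbind, rows)
      }
      ab <- rbind(ab, mk_decoys(idA, idB, plen, best_score))
      ba <- rbind(ba, mk_decoys(idB, idA, plen, best_score))
    }
    list(hitsAB = ab, hitsBA = ba,
         planted_orthologs = data.frame(idA = idA, idB = idB, identity = ident,
                                        stringsAsFactors = FALSE))
  })
}

#' Generate a presence/absence matrix with planted structure
#'
#' Builds exactly `n_core_families` all-present rows, exactly
#' `n_unique_families` rows present only in the focal (first) strain, and
#' one block of rows per `shared_blocks` entry present in exactly the
#' listed strains. The focal strain's genes are laid out along scaffolds
#' (1 kb spacing), with unique families placed contiguously per
#' `island_spec` and the remainder scattered at isolated positions.
#'
#' @param spec A [fixture_spec()] with at least two strains.
#' @return A list with `matrix` (a [presence_absence]), `gene_map`
#'   (family -> focal gene id for families present in the focal strain),
#'   `locations` (gene location data frame for the focal strain), and
#'   `planted` (core/unique family ids, per-block ids, island placements).
#' @export
sim_presence_absence <- function(spec) {
  if (!inherits(spec, "fixture_spec")) pm_config_error("spec must be a fixture_spec")
  if (length(spec$strains) < 2L) pm_config_error("need at least two strains")
  with_seed(spec$seed + 3L, {
    strains <- spec$strains; focal <- strains[1]
    fam_core <- sprintf("core_%05d", seq_len(spec$n_core_families))
    fam_uniq <- sprintf("uniq_%05d", seq_len(spec$n_unique_families))
    fam_blocks <- lapply(seq_along(spec$shared_blocks), function(i)
      sprintf("blk%d_%05d", i, seq_len(spec$shared_blocks[[i]]$n)))
    families <- c(fam_core, fam_uniq, unlist(fam_blocks))
    pres <- matrix(FALSE, length(families), length(strains),
                   dimnames = list(families, strains))
    pres[fam_core, ] <- TRUE
    pres[fam_uniq, focal] <- TRUE
    for (i in seq_along(spec$shared_blocks))
      pres[fam_blocks[[i]], spec$shared_blocks[[i]]$strains] <- TRUE

    ## Focal gene layout: every rank on the core scaffolds carries a gene
    ## (1 kb spacing); genes without a family row act as spacers, emulating
    ## annotations absent from the pangenome output. Unique families are
    ## placed contiguously per island_spec; the remainder are scattered at
    ## every 10th rank, buffered away from the islands, so only the planted
    ## islands form dense runs.
    n_scf <- max(c(12L, vapply(spec$island_spec, function(is) as.integer(is$scaffold),
                               integer(1))))
    gps <- spec$genes_per_scaffold
    total_unique_in_islands <- sum(vapply(spec$island_spec, function(is) as.integer(is$n),
                                          integer(1)))
    if (total_unique_in_islands > spec$n_unique_families)
      pm_config_error("island_spec places more unique genes (%d) than exist (%d)",
                      total_unique_in_islands, spec$n_unique_families)
    slot <- function(scf, rank) sprintf("g_s%02d_%04d", scf, rank)
    gene_map <- character(0)
    uniq_left <- fam_uniq
    taken <- matrix(FALSE, n_scf, gps)  # scaffold x rank occupancy by unique genes
    blocked <- matrix(FALSE, n_scf, gps)  # buffer zone around islands
    for (is in spec$island_spec) {
      k <- as.integer(is$n); scf <- as.integer(is$scaffold); at <- as.integer(is$at)
      ranks <- at:(at + k - 1L)
      if (max(ranks) > gps)
        pm_config_error("island on scaffold %d exceeds genes_per_scaffold", scf)
      fams <- uniq_left[seq_len(k)]; uniq_left <- uniq_left[-seq_len(k)]
      gene_map[fams] <- slot(scf, ranks)
      taken[scf, ranks] <- TRUE
      blocked[scf, max(1L, at - 5L):min(gps, at + k + 4L)] <- TRUE
    }
    if (length(uniq_left)) {
      cand <- expand.grid(rank = seq(10L, gps, by = 10L), scf = seq_len(n_scf))
      ok <- !blocked[cbind(cand$scf, cand$rank)]
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) < length(uniq_left))
        pm_config_error("not enough isolated gene slots for %d scattered unique families",
                        length(uniq_left))
      cand <- cand[seq_along(uniq_left), , drop = FALSE]
      gene_map[uniq_left] <- slot(cand$scf, cand$rank)
      taken[cbind(cand$scf, cand$rank)] <- TRUE
    }
    ## non-unique focal families fill free ranks in order; leftover ranks
    ## become family-less spacer genes
    focal_other <- setdiff(families[pres[, focal]], fam_uniq)
    free_idx <- which(!t(taken))  # column-major over t() = scaffold-major by rank
    free <- vapply(free_idx, function(i) {
      scf <- (i - 1L) %/% gps + 1L; rank <- (i - 1L) %% gps + 1L
      slot(scf, rank)
    }, character(1))
    if (length(focal_other) > length(free))
      pm_config_error("not enough gene slots for focal families; raise genes_per_scaffold")
    gene_map[focal_other] <- free[seq_along(focal_other)]

    all_slots <- as.vector(vapply(seq_len(n_scf), function(s)
      vapply(seq_len(gps), function(r) slot(s, r), character(1)), character(gps)))
    scf_of <- rep(seq_len(n_scf), each = gps)
    rank_of <- rep(seq_len(gps), times = n_scf)
    locations <- data.frame(
      gene_id = all_slots,
      scaffold_id = sprintf("scaffold_%02d", scf_of),
      start = (rank_of - 1L) * 1000L + 1L,
      end = (rank_of - 1L) * 1000L + 900L,
      strand = "+", stringsAsFactors = FALSE)
    locations <- locations[order(locations$scaffold_id, locations$start), , drop = FALSE]

    rep_gene <- lapply(families, function(f) {
      strs <- strains[pres[f, ]]
      stats::setNames(ifelse(strs == focal & f %in% names(gene_map),
                             gene_map[f], paste(f, strs, sep = "|")), strs)
    })
    names(rep_gene) <- families

    planted_islands <- lapply(spec$island_spec, function(is)
      list(scaffold_id = sprintf("scaffold_%02d", as.integer(is$scaffold)),
           first_gene_index = as.integer(is$at),
           n_unique = as.integer(is$n)))
    list(matrix = presence_absence(pres, representative_gene = rep_gene),
         gene_map = gene_map,
         locations = locations,
         planted = list(core = fam_core, unique = fam_uniq,
                        blocks = stats::setNames(fam_blocks,
                                                 vapply(spec$shared_blocks, function(b)
                                                   paste(b$strains, collapse = "&"), character(1))),
                        islands = planted_islands))
  })
}

#' Generate a recipient/donor metabolic-model pair with planted merge truth
#'
#' The recipient is a minimal growth-capable chassis (carbon import ->
#' biomass) plus a second carbon exchange with no catabolic route. The
#' donor contains, relative to the recipient: exact copies (`identical`),
#' proton-variant and stoichiometry-variant duplicates, genuinely new
#' reaction units that persist after merging, dead-end chains whose
#' transfer is undone by the dead-end pass, and reactions constrained by
#' genes without orthologs (removed by pruning). The ground truth records
#' each class and the expected final model size.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `recipient`, `donor` (`metabolic_model`s),
#'   `ortholog_map`, and `planted` (ids per class and expected outcomes).
#' @export
sim_model_pair <- function(spec) {
  if (!inherits(spec, "fixture_spec")) pm_config_error("spec must be a fixture_spec")
  ms <- spec$model_spec
  rxn <- reaction
  ## ---- recipient ----
  rec_rxns <- list(
    rxn("EX_carbon1", c(carbon1_e = -1), lower_bound = -10, upper_bound = 1000,
        is_exchange = TRUE),
    rxn("EX_carbon2", c(carbon2_e = -1), lower_bound = -10, upper_bound = 1000,
        is_exchange = TRUE),
    rxn("T_carbon1", c(carbon1_e = -1, carbon1_c = 1), gpr = "gM_T1"),
    rxn("C_carbon1", c(carbon1_c = -1, bm_c = 1), gpr = "gM_C1"),
    rxn("BIOMASS", c(bm_c = -1), lower_bound = 0, upper_bound = 1000,
        is_exchange = TRUE))
  recipient <- metabolic_model("recipient_draft", genes = c("gM_T1", "gM_C1"),
                               reactions = rec_rxns, objective = "BIOMASS")
  ## ---- donor ----
  don_rxns <- list(rxn("BIOMASS", c(bm_c = -1), lower_bound = 0, upper_bound = 1000,
                       is_exchange = TRUE))
  don_genes <- character(0); map <- character(0)
  planted <- list(identical = "BIOMASS", proton_variant = character(),
                  stoich_variant = character(), transfer_persist = character(),
                  dead_end_chain = character(), pruned = character())
  add_gene <- function(g) {
    don_genes <<- c(don_genes, g)
    map[g] <<- sub("^gD", "gM", g)
  }
  for (i in seq_len(ms$n_identical)) {
    g <- sprintf("gD_ident_%d", i); add_gene(g)
    id <- sprintf("D_ident_%d", i)
    don_rxns[[length(don_rxns) + 1L]] <- rxn(id, c(carbon1_c = -1, bm_c = 1), gpr = g)
    planted$identical <- c(planted$identical, id)
  }
  for (i in seq_len(ms$n_proton_variants)) {
    g <- sprintf("gD_prot_%d", i); add_gene(g)
    id <- sprintf("D_prot_%d", i)
    don_rxns[[length(don_rxns) + 1L]] <- rxn(id, c(carbon1_c = -1, bm_c = 1, h_c = 1), gpr = g)
    planted$proton_variant <- c(planted$proton_variant, id)
  }
  for (i in seq_len(ms$n_stoich_variants)) {
    g <- sprintf("gD_stoich_%d", i); add_gene(g)
    id <- sprintf("D_stoich_%d", i)
    don_rxns[[length(don_rxns) + 1L]] <- rxn(id, c(carbon1_c = -2, bm_c = 1), gpr = g)
    planted$stoich_variant <- c(planted$stoich_variant, id)
  }
  for (i in seq_len(ms$n_transferable)) {
    g1 <- sprintf("gD_new_%d_a", i); g2 <- sprintf("gD_new_%d_b", i)
    add_gene(g1); add_gene(g2)
    id1 <- sprintf("D_new_%d", i); id2 <- sprintf("EX_newp_%d", i)
    met <- sprintf("newp_%d_e", i)
    don_rxns[[length(don_rxns) + 1L]] <-
      rxn(id1, stats::setNames(c(-1, 1), c("bm_c", met)), gpr = sprintf("%s and %s", g1, g2))
    don_rxns[[length(don_rxns) + 1L]] <-
      rxn(id2, stats::setNames(-1, met), lower_bound = 0, upper_bound = 1000,
          is_exchange = TRUE)
    planted$transfer_persist <- c(planted$transfer_persist, id1, id2)
  }
  for (i in seq_len(ms$n_dead_end_chains)) {
    prev <- "bm_c"
    for (j in seq_len(ms$chain_length)) {
      g <- sprintf("gD_chain_%d_%d", i, j); add_gene(g)
      id <- sprintf("D_chain_%d_%d", i, j)
      met <- sprintf("z_%d_%d_c", i, j)
      don_rxns[[length(don_rxns) + 1L]] <-
        rxn(id, stats::setNames(c(-1, 1), c(prev, met)), gpr = g)
      planted$dead_end_chain <- c(planted$dead_end_chain, id)
      prev <- met
    }
  }
  for (i in seq_len(ms$n_unmapped_genes)) {
    g <- sprintf("gD_unmap_%d", i)
    don_genes <- c(don_genes, g)  # deliberately not in the ortholog map
    id <- sprintf("D_prune_%d", i)
    don_rxns[[length(don_rxns) + 1L]] <-
      rxn(id, stats::setNames(c(-1, 1), c("bm_c", sprintf("q_%d_c", i))), gpr = g)
    planted$pruned <- c(planted$pruned, id)
  }
  donor <- metabolic_model("donor_curated", genes = don_genes, reactions = don_rxns,
                           objective = "BIOMASS")
  n_persist <- length(planted$transfer_persist)
  planted$expected_final <- c(
    genes = length(recipient$genes) +
      length(unique(unname(map[unlist(lapply(
        donor$reactions[c(planted$transfer_persist, planted$dead_end_chain)],
        function(r) gpr_genes(r$gpr)))]))),
    reactions = length(recipient$reactions) + n_persist,
    metabolites = nrow(recipient$metabolites) + ms$n_transferable)
  planted$growth_sources <- "EX_carbon1"
  list(recipient = recipient, donor = donor, ortholog_map = map, planted = planted)
}

#' Write a complete fixture bundle to disk
#'
#' Serializes every generator's output in the on-disk formats the pipeline
#' reads (FASTA + coverage TSV, 14-column tabular hit files,
#' presence/absence CSV, gene-location TSV, model JSON) together with a
#' ground-truth JSON sidecar, so the I/O code paths are exercised
#' end-to-end.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_fixtures <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  asm <- sim_assembly(spec)
  write_scaffolds(asm, p("assembly.fna"), p("assembly_coverage.tsv"))
  pair <- sim_divergent_pair(spec)
  Biostrings::writeXStringSet(pair$a, p("genomeA.fna"))
  Biostrings::writeXStringSet(pair$b, p("genomeB.fna"))
  hits <- sim_hit_tables(spec)
  write_hits(hits$hitsAB, p("hits_AB.tsv"))
  write_hits(hits$hitsBA, p("hits_BA.tsv"))
  pam <- sim_presence_absence(spec)
  write_presence_absence(pam$matrix, p("gene_presence_absence.csv"))
  utils::write.table(pam$locations, p("gene_locations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(family = names(pam$gene_map), gene = unname(pam$gene_map)),
                     p("focal_gene_map.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  mod <- sim_model_pair(spec)
  write_model_json(mod$recipient, p("model_recipient.json"))
  write_model_json(mod$donor, p("model_donor.json"))
  utils::write.table(data.frame(donor_gene = names(mod$ortholog_map),
                                recipient_gene = unname(mod$ortholog_map)),
                     p("ortholog_map.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(planted_ani = pair$planted_ani,
                planted_orthologs = hits$planted_orthologs,
                pangenome = list(
                  n_core = length(pam$planted$core),
                  n_unique = length(pam$planted$unique),
                  blocks = lapply(pam$planted$blocks, length),
                  islands = pam$planted$islands),
                model = utils::modifyList(mod$planted,
                                          list(expected_final = as.list(mod$planted$expected_final))))
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(assembly = p("assembly.fna"), coverage = p("assembly_coverage.tsv"),
                 genomeA = p("genomeA.fna"), genomeB = p("genomeB.fna"),
                 hitsAB = p("hits_AB.tsv"), hitsBA = p("hits_BA.tsv"),
                 presence_absence = p("gene_presence_absence.csv"),
                 locations = p("gene_locations.tsv"),
                 gene_map = p("focal_gene_map.tsv"),
                 recipient = p("model_recipient.json"), donor = p("model_donor.json"),
                 ortholog_map = p("ortholog_map.tsv"),
                 ground_truth = p("ground_truth.json")))
}
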