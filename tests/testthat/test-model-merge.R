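rx <- function(id, st, lb = 0, ub = 1000, gpr = "", ex = FALSE)
  reaction(id, st, lower_bound = lb, upper_bound = ub, gpr = gpr, is_exchange = ex)

test_that("GPR evaluation follows boolean semantics with the empty-rule convention", {
  expect_true(evaluate_gpr("g1 or g2", "g2"))
  expect_false(evaluate_gpr("g1 and g2", "g2"))
  expect_true(evaluate_gpr("", character()))
  expect_true(evaluate_gpr("g1 and (g2 or g3)", c("g1", "g3")))
  expect_false(evaluate_gpr("g1 and (g2 or g3)", "g1"))
  expect_error(evaluate_gpr("g1 and (g2", "g1"), regexp = "parse")
  expect_error(evaluate_gpr("g1 or or g2", "g1"), regexp = "parse")
})

test_that("orthology pruning removes unsatisfiable reactions and simplifies survivors", {
  m <- metabolic_model(
    "donor", genes = c("g1", "g2", "g3"),
    reactions = list(
      rx("R_gone", c(a_c = -1, b_c = 1), gpr = "g1"),
      rx("R_kept", c(b_c = -1, c_c = 1), gpr = "g1 or g2"),
      rx("R_free", c(c_c = -1, d_c = 1)),
      rx("EX_a", c(a_c = -1), lb = -10, ub = 10, ex = TRUE),
      rx("OBJ", c(d_c = -1), ex = TRUE)),
    objective = "OBJ")
  pruned <- prune_by_orthology(m, c(g2 = "gm2", g3 = "gm3"))
  expect_false("R_gone" %in% names(pruned$reactions))
  expect_equal(pruned$reactions$R_kept$gpr, "g2")
  expect_true("R_free" %in% names(pruned$reactions))  # empty GPR always retained
  expect_equal(sort(pruned$genes), c("g2", "g3"))
  ## input untouched
  expect_equal(length(m$reactions), 5L)
})

test_that("reaction signatures canonicalize order, direction and protons", {
  r1 <- rx("r1", c(a_c = -1, b_c = -1, c_c = 1))
  r2 <- rx("r2", c(b_c = -1, a_c = -1, c_c = 1))
  expect_identical(reaction_signature(r1), reaction_signature(r2))
  ## reversible direction normalization
  f <- rx("f", c(a_c = -1, b_c = 1), lb = -1000)
  b <- rx("b", c(b_c = -1, a_c = 1), lb = -1000)
  expect_identical(reaction_signature(f), reaction_signature(b))
  ## irreversible opposite directions stay distinct
  fi <- rx("fi", c(a_c = -1, b_c = 1))
  bi <- rx("bi", c(b_c = -1, a_c = 1))
  expect_false(identical(reaction_signature(fi), reaction_signature(bi)))
  ## proton dropping
  hp <- rx("hp", c(a_c = -1, h_c = -1, b_c = 1))
  hless <- rx("hl", c(a_c = -1, b_c = 1))
  expect_identical(reaction_signature(hp, ignore_protons = TRUE),
                   reaction_signature(hless, ignore_protons = TRUE))
  ## GCD normalization: doubled equation is the same reaction
  d2 <- rx("d2", c(a_c = -2, b_c = 2))
  expect_identical(reaction_signature(d2), reaction_signature(hless))
})

test_that("classify_match ranks identical > proton variant > stoich variant > distinct", {
  base <- rx("r", c(a_c = -1, b_c = -1, c_c = 1))
  expect_equal(classify_match(base, rx("x", c(b_c = -1, a_c = -1, c_c = 1))), "identical")
  expect_equal(classify_match(base, rx("x", c(a_c = -1, b_c = -1, h_c = -1, c_c = 1))),
               "proton_variant")
  expect_equal(classify_match(rx("x", c(a_c = -2, b_c = 1)), rx("y", c(a_c = -1, b_c = 1))),
               "stoich_variant")
  expect_equal(classify_match(base, rx("x", c(a_c = -1, d_c = 1))), "distinct")
  ## symmetry on generated pairs
  spec <- fixture_spec(seed = 41)
  mod <- sim_model_pair(spec)
  rxns <- c(mod$recipient$reactions, mod$donor$reactions)
  set.seed(41)
  for (i in 1:30) {
    pick <- sample(length(rxns), 2)
    expect_equal(classify_match(rxns[[pick[1]]], rxns[[pick[2]]]),
                 classify_match(rxns[[pick[2]]], rxns[[pick[1]]]))
  }
})

test_that("transfer copies only distinct reactions, rewriting genes via the map", {
  rec <- metabolic_model("rec", genes = "gm1",
                         reactions = list(rx("R1", c(a_c = -1, b_c = 1), gpr = "gm1"),
                                          rx("EX_a", c(a_c = -1), lb = -10, ex = TRUE),
                                          rx("OBJ", c(b_c = -1), ex = TRUE)),
                         objective = "OBJ")
  don <- metabolic_model("don", genes = c("gd1", "gd2", "gd3"),
                         reactions = list(
                           rx("D_same", c(a_c = -1, b_c = 1), gpr = "gd1"),
                           rx("D_prot", c(a_c = -1, b_c = 1, h_c = 1), gpr = "gd2"),
                           rx("D_new", c(b_c = -1, n_c = 1), gpr = "gd1 and gd3"),
                           rx("OBJ", c(b_c = -1), ex = TRUE)),
                         objective = "OBJ")
  map <- c(gd1 = "gm1", gd2 = "gm2", gd3 = "gm3")
  got <- transfer_unique_reactions(rec, don, map)
  expect_equal(got$report$reactions_transferred, 1L)
  expect_equal(got$report$transfers_skipped_proton, 1L)
  expect_equal(got$report$transferred_ids, "D_new")
  expect_equal(got$model$reactions$D_new$gpr, "gm1 and gm3")
  expect_true("n_c" %in% got$model$metabolites$id)
  expect_true(all(c("gm1", "gm3") %in% got$model$genes))
  ## recipient reactions never deleted; count non-decreasing
  expect_true(all(names(rec$reactions) %in% names(got$model$reactions)))
  ## unmapped gene on a transferred reaction is an error
  don2 <- metabolic_model("don2", genes = "gX",
                          reactions = list(rx("D_bad", c(a_c = -1, q_c = 1), gpr = "gX"),
                                           rx("OBJ", c(a_c = -1), ex = TRUE)),
                          objective = "OBJ")
  expect_error(transfer_unique_reactions(rec, don2, c(notgX = "gm9")),
               class = "panmetab_data_error")
})

test_that("dead-end detection respects reaction directionality", {
  m <- metabolic_model("m", genes = character(),
                       reactions = list(rx("R_ab", c(A_c = -1, B_c = 1)),
                                        rx("R_bc", c(B_c = -1, C_c = 1)),
                                        rx("EX_a", c(A_c = -1), lb = -10, ub = 10, ex = TRUE),
                                        rx("OBJ", c(B_c = -1), ex = TRUE)),
                       objective = "OBJ")
  expect_equal(find_dead_end_metabolites(m), "C_c")
  ## consuming C shifts the dead end downstream
  m2 <- metabolic_model("m2", genes = character(),
                        reactions = c(m$reactions,
                                      list(rx("R_cd", c(C_c = -1, D_c = 1)))),
                        objective = "OBJ")
  expect_equal(find_dead_end_metabolites(m2), "D_c")
  ## a lone reversible exchange both produces and consumes its metabolite
  m3 <- metabolic_model("m3", genes = character(),
                        reactions = list(rx("EX_A", c(A_c = -1), lb = -10, ub = 10,
                                            ex = TRUE)),
                        objective = "EX_A")
  expect_equal(find_dead_end_metabolites(m3), character(0))
})

test_that("iterative dead-end removal reaches the hand-traced fixpoint and is idempotent", {
  m <- metabolic_model("m", genes = character(),
                       reactions = list(rx("EX_a", c(A_c = -1), lb = -10, ub = 10, ex = TRUE),
                                        rx("R_ab", c(A_c = -1, B_c = 1)),
                                        rx("R_bc", c(B_c = -1, C_c = 1)),
                                        rx("OBJ", c(B_c = -1), ex = TRUE)),
                       objective = "OBJ")
  got <- remove_dead_ends(m)
  ## C is a dead end -> R_bc removed; B still consumed by OBJ, chain survives
  expect_equal(got$removed_reactions, "R_bc")
  expect_equal(got$removed_metabolites, "C_c")
  again <- remove_dead_ends(got$model)
  expect_length(again$removed_reactions, 0L)
  ## no-dead-end model unchanged
  clean <- remove_dead_ends(again$model)
  expect_equal(names(clean$model$reactions), names(again$model$reactions))
  ## objective protection
  bad <- metabolic_model("bad", genes = character(),
                         reactions = list(rx("OBJ", c(X_c = 1), ex = TRUE)),
                         objective = "OBJ")
  expect_error(remove_dead_ends(bad), class = "panmetab_data_error")
})

test_that("removal fixpoint is independent of processing order", {
  for (seed in 1:5) {
    spec <- fixture_spec(seed = seed)
    mod <- sim_model_pair(spec)
    merged <- transfer_unique_reactions(mod$recipient,
                                        prune_by_orthology(mod$donor, mod$ortholog_map),
                                        mod$ortholog_map)$model
    set_based <- remove_dead_ends(merged)$model
    randomized <- oracle_dead_end_removal(merged, seed = seed * 13)
    expect_equal(sort(names(set_based$reactions)), sort(names(randomized$reactions)))
    expect_equal(sort(set_based$metabolites$id), sort(randomized$metabolites$id))
  }
})

test_that("merge_pipeline reproduces the planted ground truth end to end", {
  for (seed in c(3, 14)) {
    spec <- fixture_spec(seed = seed)
    mod <- sim_model_pair(spec)
    res <- merge_pipeline(mod$recipient,
                          list(list(model = mod$donor, ortholog_map = mod$ortholog_map)))
    planted <- mod$planted
    expect_setequal(res$report$transferred_ids,
                    c(planted$transfer_persist, planted$dead_end_chain))
    expect_equal(res$report$transfers_skipped_proton, length(planted$proton_variant))
    expect_equal(res$report$transfers_skipped_stoich, length(planted$stoich_variant))
    expect_equal(res$report$transfers_skipped_identical, length(planted$identical))
    expect_setequal(res$report$dead_end_reaction_ids, planted$dead_end_chain)
    expect_equal(res$report$reactions_removed_by_pruning, length(planted$pruned))
    expect_equal(unname(res$report$final_size),
                 unname(planted$expected_final[c("genes", "reactions", "metabolites")]))
    validate_model(res$model)
  }
})

test_that("two donors sharing a reaction transfer it once; empty donor list is a no-op", {
  spec <- fixture_spec(seed = 8)
  mod <- sim_model_pair(spec)
  res2 <- merge_pipeline(mod$recipient,
                         list(list(model = mod$donor, ortholog_map = mod$ortholog_map),
                              list(model = mod$donor, ortholog_map = mod$ortholog_map)))
  res1 <- merge_pipeline(mod$recipient,
                         list(list(model = mod$donor, ortholog_map = mod$ortholog_map)))
  ## second pass of the same donor contributes nothing new
  expect_equal(length(res2$model$reactions), length(res1$model$reactions))
  expect_equal(res2$report$reactions_transferred, res1$report$reactions_transferred)
  ## empty donor list: dead-end pass only, recipient has none
  res0 <- merge_pipeline(mod$recipient, list())
  expect_equal(names(res0$model$reactions), names(mod$recipient$reactions))
})

test_that("model JSON round-trips losslessly", {
  spec <- fixture_spec(seed = 4)
  mod <- sim_model_pair(spec)
  f <- tempfile(fileext = ".json")
  write_model_json(mod$donor, f)
  got <- read_model_json(f)
  expect_equal(names(got$reactions), names(mod$donor$reactions))
  expect_equal(got$reactions$D_prot_1$stoich, mod$donor$reactions$D_prot_1$stoich)
  expect_equal(got$genes, mod$donor$genes)
  expect_equal(got$objective, mod$donor$objective)
})
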