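## Homology-guided metabolic-model expansion: donor pruning by orthology,
## signature-based reaction comparison with proton/stoichiometry-variant
## exceptions, unique-reaction transfer with gene renaming, and iterative
## dead-end removal.

DEFAULT_PROTON_IDS <- c("h", "h+", "proton")

is_proton <- function(met_ids, proton_ids = DEFAULT_PROTON_IDS) {
  stripped <- tolower(sub("_[a-zA-Z0-9]+$", "", met_ids))
  stripped %in% tolower(proton_ids)
}

#' Prune a donor model by orthology
#'
#' Deletes every donor gene without an entry in `ortholog_map` and removes
#' the reactions this constrains: a reaction is removed iff its GPR is
#' non-empty and evaluates false with the deleted genes set false and all
#' surviving genes present. Surviving reactions keep their GPRs with
#' deleted literals substituted by false and simplified. Metabolites no
#' longer referenced are dropped. The input model is not modified.
#'
#' @param donor A `metabolic_model`.
#' @param ortholog_map Named character vector: donor gene -> recipient gene.
#' @return The pruned `metabolic_model`.
#' @export
prune_by_orthology <- function(donor, ortholog_map) {
  validate_model(donor)
  deleted <- setdiff(donor$genes, names(ortholog_map))
  keep <- list()
  for (r in donor$reactions) {
    tree <- simplify_gpr_tree(parse_gpr(r$gpr), absent = deleted)
    if (isFALSE(tree)) next
    r$gpr <- render_gpr_tree(tree)
    keep[[r$id]] <- r
  }
  refd <- unique(unlist(lapply(keep, function(r) names(r$stoich))))
  out <- donor
  out$genes <- setdiff(donor$genes, deleted)
  out$reactions <- keep
  out$metabolites <- donor$metabolites[donor$metabolites$id %in% refd, , drop = FALSE]
  if (!out$objective %in% names(out$reactions))
    pm_data_error("orthology pruning removed the objective reaction '%s' of '%s'",
                  out$objective, out$id)
  out
}

#' Canonical reaction signature
#'
#' Renders a reaction equation into a canonical string so that two
#' reactions have equal signatures iff their equations are identical under
#' the chosen flags. Metabolites are sorted lexicographically per side;
#' integral coefficient vectors are normalized by their GCD; backward-only
#' reactions are flipped to forward; for reversible reactions the side
#' ordering is normalized so the lexicographically smaller side is left,
#' and the arrow (`->` vs `<=>`) is part of the signature.
#'
#' @param r A [reaction()].
#' @param ignore_protons Drop proton metabolites before rendering.
#' @param ignore_coefficients Render only the metabolite sets per side.
#' @param proton_ids Compartment-stripped metabolite ids treated as protons.
#' @return A character scalar.
#' @export
reaction_signature <- function(r, ignore_protons = FALSE,
                               ignore_coefficients = FALSE,
                               proton_ids = DEFAULT_PROTON_IDS) {
  st <- r$stoich
  if (ignore_protons && length(st)) st <- st[!is_proton(names(st), proton_ids)]
  if (!length(st)) return("<empty>")
  ## flip backward-only reactions to the forward convention
  if (r$upper_bound <= 0 && r$lower_bound < 0) st <- -st
  reversible <- r$lower_bound < 0 && r$upper_bound > 0
  ## GCD normalization for (near-)integral stoichiometries
  co <- abs(st)
  if (all(abs(co - round(co)) < 1e-9) && any(round(co) > 0)) {
    g <- Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b), round(co))
    if (g > 1) st <- st / g
  }
  side_str <- function(ids, coefs) {
    o <- order(ids)
    if (ignore_coefficients) paste(ids[o], collapse = " + ")
    else paste(sprintf("%s %s", signif(coefs[o], 10), ids[o]), collapse = " + ")
  }
  lhs <- side_str(names(st)[st < 0], -st[st < 0])
  rhs <- side_str(names(st)[st > 0], st[st > 0])
  if (reversible) {
    s1 <- paste(lhs, "<=>", rhs); s2 <- paste(rhs, "<=>", lhs)
    if (s1 <= s2) s1 else s2
  } else paste(lhs, "->", rhs)
}

#' Classify the relationship between two reactions
#'
#' Symmetric classification used during model expansion: `identical` when
#' full signatures agree; otherwise `proton_variant` when signatures agree
#' after dropping protons; otherwise `stoich_variant` when the per-side
#' metabolite sets (ignoring protons) agree but coefficients differ;
#' otherwise `distinct`.
#'
#' @param r1,r2 [reaction()] objects.
#' @param proton_ids See [reaction_signature()].
#' @return One of `"identical"`, `"proton_variant"`, `"stoich_variant"`,
#'   `"distinct"`.
#' @export
classify_match <- function(r1, r2, proton_ids = DEFAULT_PROTON_IDS) {
  if (identical(reaction_signature(r1, proton_ids = proton_ids),
                reaction_signature(r2, proton_ids = proton_ids))) return("identical")
  if (identical(reaction_signature(r1, ignore_protons = TRUE, proton_ids = proton_ids),
                reaction_signature(r2, ignore_protons = TRUE, proton_ids = proton_ids)))
    return("proton_variant")
  if (identical(reaction_signature(r1, ignore_protons = TRUE, ignore_coefficients = TRUE,
                                   proton_ids = proton_ids),
                reaction_signature(r2, ignore_protons = TRUE, ignore_coefficients = TRUE,
                                   proton_ids = proton_ids)))
    return("stoich_variant")
  "distinct"
}

#' Transfer reactions unique to a donor model into a recipient
#'
#' Every donor reaction is classified against the recipient's reactions
#' with [classify_match()]; only `distinct` reactions are copied. Copied
#' reactions keep their bounds; their GPR gene literals are rewritten to
#' recipient gene names through `ortholog_map` (an unmapped literal on a
#' transferred reaction is an error); new metabolites and mapped genes are
#' added as needed; reaction-id collisions get a deterministic `_t<k>`
#' suffix (logged).
#'
#' @param recipient,donor `metabolic_model`s; the donor should already be
#'   pruned with [prune_by_orthology()].
#' @param ortholog_map Named character vector: donor gene -> recipient gene.
#' @param proton_ids See [reaction_signature()].
#' @return A list with `model` (expanded recipient) and `report` (counts:
#'   `reactions_transferred`, `transfers_skipped_identical`,
#'   `transfers_skipped_proton`, `transfers_skipped_stoich`, plus the
#'   transferred reaction ids).
#' @export
transfer_unique_reactions <- function(recipient, donor, ortholog_map,
                                      proton_ids = DEFAULT_PROTON_IDS) {
  validate_model(recipient); validate_model(donor)
  sig_full <- vapply(recipient$reactions, reaction_signature, character(1),
                     proton_ids = proton_ids)
  sig_nop <- vapply(recipient$reactions, reaction_signature, character(1),
                    ignore_protons = TRUE, proton_ids = proton_ids)
  sig_nopc <- vapply(recipient$reactions, reaction_signature, character(1),
                     ignore_protons = TRUE, ignore_coefficients = TRUE,
                     proton_ids = proton_ids)
  counts <- c(identical = 0L, proton_variant = 0L, stoich_variant = 0L)
  transferred <- character(0)
  out <- recipient
  for (r in donor$reactions) {
    cls <- if (reaction_signature(r, proton_ids = proton_ids) %in% sig_full) "identical"
    else if (reaction_signature(r, ignore_protons = TRUE, proton_ids = proton_ids) %in% sig_nop)
      "proton_variant"
    else if (reaction_signature(r, ignore_protons = TRUE, ignore_coefficients = TRUE,
                                proton_ids = proton_ids) %in% sig_nopc) "stoich_variant"
    else "distinct"
    if (cls != "distinct") { counts[cls] <- counts[cls] + 1L; next }
    new <- r
    new$gpr <- rewrite_gpr(r$gpr, ortholog_map, context = r$id)
    if (new$id %in% names(out$reactions)) {
      k <- 1L
      while (sprintf("%s_t%d", r$id, k) %in% names(out$reactions)) k <- k + 1L
      message(sprintf("reaction id collision: '%s' transferred as '%s_t%d'", r$id, r$id, k))
      new$id <- sprintf("%s_t%d", r$id, k)
    }
    out$reactions[[new$id]] <- new
    transferred <- c(transferred, new$id)
    new_mets <- setdiff(names(new$stoich), out$metabolites$id)
    if (length(new_mets))
      out$metabolites <- rbind(out$metabolites,
                               donor$metabolites[donor$metabolites$id %in% new_mets, , drop = FALSE])
    out$genes <- union(out$genes, gpr_genes(new$gpr))
  }
  validate_model(out)
  list(model = out,
       report = list(reactions_transferred = length(transferred),
                     transfers_skipped_identical = unname(counts["identical"]),
                     transfers_skipped_proton = unname(counts["proton_variant"]),
                     transfers_skipped_stoich = unname(counts["stoich_variant"]),
                     transferred_ids = transferred))
}

#' Find dead-end metabolites
#'
#' A metabolite is a dead end iff, taking reaction directionality into
#' account, it cannot be both produced and consumed: a reversible reaction
#' (negative lower and positive upper bound) both produces and consumes
#' each participant; an irreversible reaction produces its
#' positive-coefficient and consumes its negative-coefficient participants
#' (backward-only reactions are flipped); exchange reactions follow the
#' same bound rules. Declared metabolites referenced by no reaction are
#' dead ends.
#'
#' @param m A `metabolic_model`.
#' @return Character vector of dead-end metabolite ids.
#' @export
find_dead_end_metabolites <- function(m) {
  produced <- consumed <- character(0)
  for (r in m$reactions) {
    st <- r$stoich
    if (!length(st)) next
    if (r$upper_bound <= 0 && r$lower_bound < 0) st <- -st
    reversible <- r$lower_bound < 0 && r$upper_bound > 0
    if (reversible) {
      produced <- c(produced, names(st)); consumed <- c(consumed, names(st))
    } else {
      produced <- c(produced, names(st)[st > 0])
      consumed <- c(consumed, names(st)[st < 0])
    }
  }
  ok <- intersect(unique(produced), unique(consumed))
  setdiff(m$metabolites$id, ok)
}

#' Iteratively remove reactions touching dead-end metabolites
#'
#' Fixpoint iteration: at each pass every reaction in which a current
#' dead-end metabolite participates is removed (`mode = "participant"`,
#' the default; `mode = "producer"` removes only reactions able to produce
#' it), then unreferenced metabolites are dropped; iteration stops when a
#' pass removes nothing. Removing the objective reaction is an error.
#'
#' @param m A `metabolic_model`.
#' @param mode `"participant"` or `"producer"`.
#' @return A list with `model`, `removed_reactions`, `removed_metabolites`.
#' @export
remove_dead_ends <- function(m, mode = c("participant", "producer")) {
  mode <- match.arg(mode)
  validate_model(m)
  removed_r <- removed_m <- character(0)
  repeat {
    dead <- find_dead_end_metabolites(m)
    ## unreferenced metabolites are handled by the orphan sweep below
    refd <- unique(unlist(lapply(m$reactions, function(r) names(r$stoich))))
    dead_ref <- intersect(dead, refd)
    drop <- vapply(m$reactions, function(r) {
      st <- r$stoich
      if (r$upper_bound <= 0 && r$lower_bound < 0) st <- -st
      reversible <- r$lower_bound < 0 && r$upper_bound > 0
      touch <- if (mode == "participant") names(st)
      else if (reversible) names(st) else names(st)[st > 0]
      any(touch %in% dead_ref)
    }, logical(1))
    orphans <- setdiff(m$metabolites$id, refd)
    if (!any(drop) && !length(orphans)) break
    if (any(drop)) {
      if (m$objective %in% names(m$reactions)[drop])
        pm_data_error(paste0("dead-end removal would delete the objective reaction '%s' ",
                             "(dead-end metabolite(s): %s)"), m$objective,
                      paste(intersect(names(m$reactions[[m$objective]]$stoich), dead_ref),
                            collapse = ", "))
      removed_r <- c(removed_r, names(m$reactions)[drop])
      m$reactions <- m$reactions[!drop]
    }
    refd <- unique(unlist(lapply(m$reactions, function(r) names(r$stoich))))
    orphans <- setdiff(m$metabolites$id, refd)
    if (length(orphans)) {
      removed_m <- c(removed_m, orphans)
      m$metabolites <- m$metabolites[!m$metabolites$id %in% orphans, , drop = FALSE]
    }
  }
  list(model = m, removed_reactions = removed_r, removed_metabolites = removed_m)
}

#' Full model-expansion pipeline
#'
#' For each donor in order: prune by orthology, then transfer the donor's
#' unique reactions into the running model. After all transfers, a single
#' dead-end removal pass to fixpoint (or one after each donor with
#' `dead_end_per_donor = TRUE`). Deterministic given its inputs.
#'
#' @param draft The recipient `metabolic_model`.
#' @param donors A list; each element a list with `model` and
#'   `ortholog_map` (donor gene -> recipient gene).
#' @param proton_ids See [reaction_signature()].
#' @param dead_end_per_donor Run dead-end removal after each donor instead
#'   of once at the end (default `FALSE`).
#' @return A list with `model` and `report` (class `merge_report`).
#' @export
merge_pipeline <- function(draft, donors, proton_ids = DEFAULT_PROTON_IDS,
                           dead_end_per_donor = FALSE) {
  validate_model(draft)
  per_donor <- list()
  model <- draft
  total <- list(genes_deleted = 0L, reactions_removed_by_pruning = 0L,
                reactions_transferred = 0L, transfers_skipped_identical = 0L,
                transfers_skipped_proton = 0L, transfers_skipped_stoich = 0L)
  transferred_ids <- character(0)
  for (d in donors) {
    donor <- d$model; map <- d$ortholog_map
    pruned <- prune_by_orthology(donor, map)
    tr <- transfer_unique_reactions(model, pruned, map, proton_ids = proton_ids)
    model <- tr$model
    rep_i <- c(list(donor_id = donor$id,
                    genes_deleted = length(donor$genes) - length(pruned$genes),
                    reactions_removed_by_pruning =
                      length(donor$reactions) - length(pruned$reactions)),
               tr$report)
    per_donor[[donor$id]] <- rep_i
    total$genes_deleted <- total$genes_deleted + rep_i$genes_deleted
    total$reactions_removed_by_pruning <-
      total$reactions_removed_by_pruning + rep_i$reactions_removed_by_pruning
    for (f in c("reactions_transferred", "transfers_skipped_identical",
                "transfers_skipped_proton", "transfers_skipped_stoich"))
      total[[f]] <- total[[f]] + rep_i[[f]]
    transferred_ids <- c(transferred_ids, tr$report$transferred_ids)
    if (dead_end_per_donor) {
      de <- remove_dead_ends(model)
      model <- de$model
    }
  }
  de <- remove_dead_ends(model)
  model <- de$model
  report <- structure(c(total, list(
    dead_end_reactions_removed = length(de$removed_reactions),
    dead_end_metabolites_removed = length(de$removed_metabolites),
    dead_end_reaction_ids = de$removed_reactions,
    transferred_ids = transferred_ids,
    per_donor = per_donor,
    final_size = c(genes = length(model$genes),
                   reactions = length(model$reactions),
                   metabolites = nrow(model$metabolites)))),
    class = "merge_report")
  list(model = model, report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf(paste0("merge_report: %d transferred (skipped %d identical, %d proton, ",
                     "%d stoich); pruning removed %d reactions / %d genes; ",
                     "dead-end pass removed %d reactions, %d metabolites\n",
                     "  final size: %d genes, %d reactions, %d metabolites\n"),
              x$reactions_transferred, x$transfers_skipped_identical,
              x$transfers_skipped_proton, x$transfers_skipped_stoich,
              x$reactions_removed_by_pruning, x$genes_deleted,
              x$dead_end_reactions_removed, x$dead_end_metabolites_removed,
              x$final_size["genes"], x$final_size["reactions"],
              x$final_size["metabolites"]))
  invisible(x)
}
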