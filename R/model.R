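#' Construct a reaction
#'
#' @param id Reaction id.
#' @param stoichiometry Named numeric vector: metabolite id -> signed
#'   coefficient (negative consumed, positive produced). Zero coefficients
#'   are dropped.
#' @param lower_bound,upper_bound Flux bounds (`lower_bound <= upper_bound`).
#' @param gpr Gene-protein-reaction rule: a boolean expression over gene
#'   ids using `and`/`or` and parentheses, or `""` when the reaction is not
#'   gene-constrained.
#' @param is_exchange Whether the reaction exchanges with the environment.
#' @return A list of class `reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     gpr = "", is_exchange = FALSE) {
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (!length(stoichiometry) && !is_exchange)
    pm_data_error("reaction '%s': empty stoichiometry on a non-exchange reaction", id)
  if (lower_bound > upper_bound)
    pm_data_error("reaction '%s': lower_bound > upper_bound", id)
  structure(list(id = as.character(id),
                 stoich = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gpr = if (is.null(gpr) || is.na(gpr)) "" else as.character(gpr),
                 is_exchange = isTRUE(is_exchange)),
            class = "reaction")
}

#' Construct a genome-scale metabolic model
#'
#' @param id Model id.
#' @param genes Character vector of gene ids.
#' @param reactions List of [reaction()] objects.
#' @param metabolites Data frame with columns `id`, `name`, `compartment`;
#'   built from the reactions when `NULL`.
#' @param objective Id of the objective reaction.
#' @return A validated list of class `metabolic_model`.
#' @export
metabolic_model <- function(id, genes, reactions, metabolites = NULL, objective) {
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  if (is.null(metabolites)) {
    mids <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
    metabolites <- data.frame(
      id = mids, name = mids,
      compartment = sub(".*_([a-zA-Z0-9]+)$", "\\1", mids),
      stringsAsFactors = FALSE)
  }
  m <- structure(list(id = as.character(id), genes = unique(as.character(genes)),
                      reactions = reactions, metabolites = metabolites,
                      objective = as.character(objective)),
                 class = "metabolic_model")
  validate_model(m)
}

#' Validate a metabolic model's referential integrity
#'
#' Checks that every metabolite referenced by a reaction is declared, every
#' gene appearing in a GPR is in the gene list, bounds are ordered, and the
#' objective reaction exists.
#'
#' @param m A `metabolic_model`.
#' @return `m`, invisibly usable; errors on violation.
#' @export
validate_model <- function(m) {
  if (anyDuplicated(m$metabolites$id)) pm_data_error("duplicate metabolite ids")
  if (anyDuplicated(names(m$reactions))) pm_data_error("duplicate reaction ids")
  refd <- unique(unlist(lapply(m$reactions, function(r) names(r$stoich))))
  orphan_ref <- setdiff(refd, m$metabolites$id)
  if (length(orphan_ref))
    pm_data_error("reaction references undeclared metabolite(s): %s",
                  paste(utils::head(orphan_ref, 5), collapse = ", "))
  for (r in m$reactions) {
    if (r$lower_bound > r$upper_bound)
      pm_data_error("reaction '%s': lower_bound > upper_bound", r$id)
    g <- gpr_genes(r$gpr)
    bad <- setdiff(g, m$genes)
    if (length(bad))
      pm_data_error("reaction '%s' GPR uses undeclared gene(s): %s", r$id,
                    paste(bad, collapse = ", "))
  }
  if (!m$objective %in% names(m$reactions))
    pm_data_error("objective reaction '%s' not in model", m$objective)
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model '%s': %d genes, %d reactions, %d metabolites (objective: %s)\n",
              x$id, length(x$genes), length(x$reactions), nrow(x$metabolites),
              x$objective))
  invisible(x)
}

#' Read a metabolic model from JSON
#'
#' Schema: `{id, genes: [..], metabolites: [{id, name, compartment}],
#' reactions: [{id, stoichiometry: {met: coef}, lower_bound, upper_bound,
#' gpr, is_exchange}], objective}`.
#'
#' @param path JSON path.
#' @return A `metabolic_model`.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) pm_data_error("model JSON not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  rxns <- lapply(j$reactions, function(r)
    reaction(r$id, unlist(r$stoichiometry),
             lower_bound = r$lower_bound, upper_bound = r$upper_bound,
             gpr = if (is.null(r$gpr)) "" else r$gpr,
             is_exchange = isTRUE(r$is_exchange)))
  mets <- do.call(rbind, lapply(j$metabolites, function(mt)
    data.frame(id = mt$id, name = if (is.null(mt$name)) mt$id else mt$name,
               compartment = if (is.null(mt$compartment)) "" else mt$compartment,
               stringsAsFactors = FALSE)))
  metabolic_model(j$id, genes = unlist(j$genes), reactions = rxns,
                  metabolites = mets, objective = j$objective)
}

#' Write a metabolic model to JSON
#'
#' @param m A `metabolic_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(m, path) {
  j <- list(
    id = m$id, genes = m$genes,
    metabolites = lapply(seq_len(nrow(m$metabolites)), function(i)
      as.list(m$metabolites[i, c("id", "name", "compartment")])),
    reactions = lapply(unname(m$reactions), function(r)
      list(id = r$id, stoichiometry = as.list(r$stoich),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gpr = r$gpr, is_exchange = r$is_exchange)),
    objective = m$objective)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- GPR boolean expressions ----------------------------------------------

## Recursive-descent parser for gene-protein-reaction rules.
## Grammar: expr := term ('or' term)* ; term := factor ('and' factor)* ;
## factor := '(' expr ')' | gene-literal.
## The parse tree is either a character scalar (gene), a logical scalar,
## or list(op = "and"/"or", args = list(...)).
parse_gpr <- function(gpr) {
  if (is.null(gpr) || is.na(gpr) || !nzchar(trimws(gpr))) return(NULL)
  src <- gsub("([()])", " \\1 ", gpr)
  toks <- strsplit(trimws(src), "\\s+")[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") { take(); args <- c(args, list(parse_term())) }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") { take(); args <- c(args, list(parse_factor())) }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) pm_data_error("GPR parse error: unexpected end of expression in '%s'", gpr)
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")"))
        pm_data_error("GPR parse error: missing ')' at token %d in '%s'", pos - 1L, gpr)
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      pm_data_error("GPR parse error: unexpected '%s' at token %d in '%s'", t, pos - 1L, gpr)
    t
  }
  tree <- parse_expr()
  if (!is.na(peek()))
    pm_data_error("GPR parse error: trailing token '%s' at position %d in '%s'",
                  peek(), pos, gpr)
  tree
}

gpr_tree_genes <- function(tree) {
  if (is.null(tree) || is.logical(tree)) return(character(0))
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gpr_tree_genes)))
}

## All gene literals appearing in a GPR string.
gpr_genes <- function(gpr) gpr_tree_genes(parse_gpr(gpr))

#' Evaluate a gene-protein-reaction rule
#'
#' Standard boolean semantics: a gene literal is true iff the gene is in
#' `present_genes`; an empty rule evaluates true (reaction not
#' gene-constrained).
#'
#' @param gpr GPR string (see [reaction()]).
#' @param present_genes Character vector of present genes.
#' @return Logical scalar.
#' @export
evaluate_gpr <- function(gpr, present_genes) {
  eval_tree <- function(tree) {
    if (is.null(tree)) return(TRUE)
    if (is.logical(tree)) return(tree)
    if (is.character(tree)) return(tree %in% present_genes)
    vals <- vapply(tree$args, eval_tree, logical(1))
    if (tree$op == "and") all(vals) else any(vals)
  }
  eval_tree(parse_gpr(gpr))
}

## Substitute a set of absent genes with FALSE and simplify the tree.
## and(FALSE, x) = FALSE; or(FALSE, x) = x; empty and = TRUE; empty or = FALSE.
simplify_gpr_tree <- function(tree, absent) {
  if (is.null(tree) || is.logical(tree)) return(tree)
  if (is.character(tree)) return(if (tree %in% absent) FALSE else tree)
  args <- lapply(tree$args, simplify_gpr_tree, absent = absent)
  if (tree$op == "and") {
    if (any(vapply(args, isFALSE, logical(1)))) return(FALSE)
    args <- args[!vapply(args, isTRUE, logical(1))]
    if (!length(args)) return(TRUE)
  } else {
    if (any(vapply(args, isTRUE, logical(1)))) return(TRUE)
    args <- args[!vapply(args, isFALSE, logical(1))]
    if (!length(args)) return(FALSE)
  }
  if (length(args) == 1L) args[[1]] else list(op = tree$op, args = args)
}

## Render a GPR tree back to a string (parenthesizing or-groups inside and).
render_gpr_tree <- function(tree, parent = NULL) {
  if (is.null(tree)) return("")
  if (is.logical(tree)) return(if (tree) "" else "FALSE")
  if (is.character(tree)) return(tree)
  inner <- vapply(tree$args, render_gpr_tree, character(1), parent = tree$op)
  s <- paste(inner, collapse = paste0(" ", tree$op, " "))
  if (!is.null(parent) && parent != tree$op) paste0("(", s, ")") else s
}

## Rewrite gene literals through a donor -> recipient ortholog map.
## Errors on unmapped literals (spec of the transfer step).
rewrite_gpr <- function(gpr, ortholog_map, context = "") {
  tree <- parse_gpr(gpr)
  rec <- function(t) {
    if (is.null(t) || is.logical(t)) return(t)
    if (is.character(t)) {
      if (!t %in% names(ortholog_map))
        pm_data_error("gene '%s' in GPR%s has no recipient ortholog", t,
                      if (nzchar(context)) paste0(" of ", context) else "")
      return(unname(ortholog_map[[t]]))
    }
    list(op = t$op, args = lapply(t$args, rec))
  }
  render_gpr_tree(rec(tree))
}
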