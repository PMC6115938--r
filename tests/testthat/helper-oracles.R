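## Independent oracles used across the suite. These deliberately use
## different algorithms (exhaustive enumeration, brute force) than the
## package implementations they check.

## N50/L50 by enumerating descending-order prefixes.
oracle_n50 <- function(lengths) {
  lens <- sort(lengths, decreasing = TRUE)
  total <- sum(lens)
  for (i in seq_along(lens)) {
    if (sum(lens[seq_len(i)]) >= total / 2) return(list(n50 = lens[i], l50 = i))
  }
}

## Brute-force reciprocal-maximum BBH over raw hit tables (no dedup
## subtleties: assumes unique (q, s) rows, as planted fixtures guarantee).
oracle_bbh <- function(hitsAB, hitsBA, min_identity, min_coverage_pct) {
  qual <- function(h) h[h$pident >= min_identity &
                          100 * h$length / h$qlen >= min_coverage_pct, , drop = FALSE]
  ab <- qual(hitsAB); ba <- qual(hitsBA)
  best_of <- function(h, q) {
    rows <- h[h$qseqid == q, , drop = FALSE]
    rows <- rows[order(-rows$bitscore, rows$evalue, -rows$length, rows$sseqid), , drop = FALSE]
    rows[1, , drop = FALSE]
  }
  out <- list()
  for (q in unique(ab$qseqid)) {
    b1 <- best_of(ab, q)
    if (!b1$sseqid %in% ba$qseqid) next
    b2 <- best_of(ba, b1$sseqid)
    if (b2$sseqid == q)
      out[[length(out) + 1L]] <- data.frame(idA = q, idB = b1$sseqid,
                                            identityAB = b1$pident,
                                            identityBA = b2$pident,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(idA = character(), idB = character(),
                      identityAB = numeric(), identityBA = numeric()))
  res <- do.call(rbind, out)
  res[order(res$idA), , drop = FALSE]
}

## Two-sided Fisher p by explicit binomial-coefficient enumeration.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

## Randomized-order dead-end removal: removes reactions touching dead ends
## one at a time in shuffled order, to fixpoint.
oracle_dead_end_removal <- function(m, seed) {
  set.seed(seed)
  repeat {
    dead <- find_dead_end_metabolites(m)
    refd <- unique(unlist(lapply(m$reactions, function(r) names(r$stoich))))
    dead <- intersect(dead, refd)
    touching <- names(m$reactions)[vapply(m$reactions, function(r)
      any(names(r$stoich) %in% dead), logical(1))]
    orphans <- setdiff(m$metabolites$id, refd)
    if (!length(touching) && !length(orphans)) break
    if (length(touching)) {
      victim <- sample(touching, 1)
      m$reactions <- m$reactions[names(m$reactions) != victim]
    }
    refd <- unique(unlist(lapply(m$reactions, function(r) names(r$stoich))))
    m$metabolites <- m$metabolites[m$metabolites$id %in% refd, , drop = FALSE]
  }
  m
}

## Tiny hand-built FBA toy: EX_A (uptake) -> A -> B -> objective sink.
toy_chain_model <- function(uptake_lb = -10) {
  metabolic_model(
    "toy_chain", genes = character(),
    reactions = list(
      reaction("EX_A", c(A_e = -1), lower_bound = uptake_lb, upper_bound = 1000,
               is_exchange = TRUE),
      reaction("R_AB", c(A_e = -1, B_c = 1)),
      reaction("OBJ", c(B_c = -1), lower_bound = 0, upper_bound = 1000,
               is_exchange = TRUE)),
    objective = "OBJ")
}

## Two-carbon toy for the screen: only source1 is catabolizable.
toy_screen_model <- function() {
  metabolic_model(
    "toy_screen", genes = character(),
    reactions = list(
      reaction("EX_src1", c(src1_e = -1), lower_bound = -10, upper_bound = 1000,
               is_exchange = TRUE),
      reaction("EX_src2", c(src2_e = -1), lower_bound = -10, upper_bound = 1000,
               is_exchange = TRUE),
      reaction("R_1", c(src1_e = -1, bm_c = 1)),
      reaction("OBJ", c(bm_c = -1), lower_bound = 0, upper_bound = 1000,
               is_exchange = TRUE)),
    objective = "OBJ")
}
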