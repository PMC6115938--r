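#' Bidirectional best hits
#'
#' Identifies putative orthologs between two proteomes as reciprocal best
#' hits: a pair `(a, b)` is reported iff `b` is `a`'s highest-bitscore
#' subject in `hitsAB`, `a` is `b`'s highest-bitscore subject in `hitsBA`,
#' and both direction hits pass the identity and coverage thresholds.
#' Coverage is `alignment_length / query_length * 100` of the querying
#' direction (`coverage_mode = "query"`, the default); `"both"` additionally
#' requires subject-side coverage.
#'
#' Bitscore ties are broken deterministically: lower e-value, then longer
#' alignment, then lexicographic subject id. Duplicate (query, subject) rows
#' are collapsed to the highest-bitscore row.
#'
#' @param hitsAB,hitsBA Hit tables (see [hit_table()]) for the two search
#'   directions.
#' @param min_identity Minimum percent identity (default 70).
#' @param min_coverage_pct Minimum percent query coverage (default 70).
#' @param max_evalue Optional maximum e-value applied to both directions
#'   (default `Inf`, i.e. no filter).
#' @param coverage_mode `"query"` or `"both"`.
#' @return A data frame with columns `idA`, `idB`, `identityAB`,
#'   `identityBA`, sorted by `idA`.
#' @export
bidirectional_best_hits <- function(hitsAB, hitsBA, min_identity = 70,
                                    min_coverage_pct = 70, max_evalue = Inf,
                                    coverage_mode = c("query", "both")) {
  coverage_mode <- match.arg(coverage_mode)
  pm_assert_scalar_number(min_identity, "min_identity", 0, 100)
  pm_assert_scalar_number(min_coverage_pct, "min_coverage_pct", 0, 100)
  validate_hits(hitsAB); validate_hits(hitsBA)

  qualify <- function(h) {
    cov_q <- 100 * h$length / h$qlen
    keep <- h$pident >= min_identity & cov_q >= min_coverage_pct & h$evalue <= max_evalue
    if (coverage_mode == "both") keep <- keep & (100 * h$length / h$slen >= min_coverage_pct)
    h[keep, , drop = FALSE]
  }
  bestAB <- best_hit_per_query(qualify(dedupe_hits(hitsAB)))
  bestBA <- best_hit_per_query(qualify(dedupe_hits(hitsBA)))
  if (!nrow(bestAB) || !nrow(bestBA))
    return(data.frame(idA = character(), idB = character(),
                      identityAB = numeric(), identityBA = numeric(),
                      stringsAsFactors = FALSE))
  back <- stats::setNames(bestBA$sseqid, bestBA$qseqid)
  recip <- !is.na(back[bestAB$sseqid]) & back[bestAB$sseqid] == bestAB$qseqid
  ab <- bestAB[recip, , drop = FALSE]
  iBA <- stats::setNames(bestBA$pident, bestBA$qseqid)
  out <- data.frame(idA = ab$qseqid, idB = ab$sseqid,
                    identityAB = ab$pident,
                    identityBA = unname(iBA[ab$sseqid]),
                    stringsAsFactors = FALSE)
  out[order(out$idA), , drop = FALSE]
}

#' Average amino acid identity (AAI) between two proteomes
#'
#' Orthologs are identified with [bidirectional_best_hits()] at the
#' identity/coverage thresholds plus an e-value ceiling; AAI is the mean
#' over ortholog pairs of the pairwise mean identity
#' `(identityAB + identityBA) / 2`, in percent.
#'
#' @inheritParams bidirectional_best_hits
#' @param min_identity Minimum percent identity (default 40).
#' @param max_evalue Maximum e-value (default 1e-12).
#' @return A list with `aai` (percent), `n_orthologs`, and the `orthologs`
#'   data frame.
#' @export
compute_aai <- function(hitsAB, hitsBA, min_identity = 40,
                        min_coverage_pct = 70, max_evalue = 1e-12,
                        coverage_mode = c("query", "both")) {
  pairs <- bidirectional_best_hits(hitsAB, hitsBA, min_identity = min_identity,
                                   min_coverage_pct = min_coverage_pct,
                                   max_evalue = max_evalue,
                                   coverage_mode = coverage_mode)
  if (!nrow(pairs))
    pm_data_error("no ortholog pairs pass the AAI thresholds; AAI is undefined")
  list(aai = mean((pairs$identityAB + pairs$identityBA) / 2),
       n_orthologs = nrow(pairs), orthologs = pairs)
}

## ---- fragment-based ANI (blastn engine) -----------------------------------

chop_genome <- function(genome, fragment_length) {
  if (methods::is(genome, "XStringSet")) genome <- as.character(genome)
  genome <- toupper(genome)
  frags <- character(0)
  for (i in seq_along(genome)) {
    len <- nchar(genome[i])
    n <- len %/% fragment_length
    if (n < 1L) next
    starts <- (seq_len(n) - 1L) * fragment_length + 1L
    frags <- c(frags, substring(genome[i], starts, starts + fragment_length - 1L))
  }
  if (length(frags)) names(frags) <- sprintf("frag_%06d", seq_along(frags))
  frags
}

blast_available <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

#' One-way average nucleotide identity (ANI)
#'
#' Fragment-based ANI: the query genome is chopped into consecutive
#' non-overlapping fragments of `fragment_length` nt (terminal remainders
#' discarded); each fragment is aligned to its best location in the
#' reference with blastn, and fragments whose best hit reaches
#' `min_fragment_identity` percent identity count as mapped. ANI is the
#' mean identity over mapped fragments, in percent. Absolute values may
#' differ slightly from minimizer-based ANI tools.
#'
#' @param query_genome,reference_genome Character vectors or
#'   [Biostrings::DNAStringSet]s of genome sequences (scaffolds allowed).
#' @param fragment_length Fragment size in nt (default 1000, minimum 100).
#' @param min_fragment_identity Percent identity for a fragment to count as
#'   mapped (default 70).
#' @return A list with `ani` (percent) and `n_fragments_mapped`.
#' @export
compute_one_way_ani <- function(query_genome, reference_genome,
                                fragment_length = 1000,
                                min_fragment_identity = 70) {
  pm_assert_scalar_number(fragment_length, "fragment_length", min = 100)
  pm_assert_scalar_number(min_fragment_identity, "min_fragment_identity", 0, 100)
  if (!blast_available())
    pm_data_error("blastn/makeblastdb not found on PATH; required for ANI")
  frags <- chop_genome(query_genome, fragment_length)
  if (!length(frags))
    pm_data_error("query genome yields zero fragments of length %d", fragment_length)
  ref <- if (methods::is(reference_genome, "XStringSet"))
    as.character(reference_genome) else toupper(reference_genome)
  if (!length(ref) || !any(nzchar(ref)))
    pm_data_error("reference genome is empty")
  if (is.null(names(ref))) names(ref) <- sprintf("ref_%d", seq_along(ref))

  dir <- tempfile("ani"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  qf <- file.path(dir, "query.fna"); rf <- file.path(dir, "ref.fna")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(frags), qf)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref), rf)
  out <- file.path(dir, "hits.tsv")
  st1 <- system2("makeblastdb", c("-in", rf, "-dbtype", "nucl"),
                 stdout = FALSE, stderr = FALSE)
  if (st1 != 0) pm_data_error("makeblastdb failed (exit %d)", st1)
  st2 <- system2("blastn", c("-query", qf, "-db", rf, "-outfmt", "6",
                             "-dust", "no", "-max_target_seqs", "5",
                             "-out", out), stdout = FALSE, stderr = FALSE)
  if (st2 != 0) pm_data_error("blastn failed (exit %d)", st2)
  hits <- tryCatch(utils::read.delim(out, header = FALSE, stringsAsFactors = FALSE),
                   error = function(e) NULL)
  if (is.null(hits) || !nrow(hits))
    pm_data_error("no query fragment mapped to the reference; ANI is undefined")
  names(hits) <- HIT12
  best <- best_hit_per_query(hits)
  mapped <- best[best$pident >= min_fragment_identity, , drop = FALSE]
  if (!nrow(mapped))
    pm_data_error("no fragment reached %.1f%% identity; ANI is undefined",
                  min_fragment_identity)
  list(ani = mean(mapped$pident), n_fragments_mapped = nrow(mapped))
}

#' Averaged (two-way) ANI
#'
#' Computes one-way ANI in both directions with [compute_one_way_ani()] and
#' averages the two values.
#'
#' @param a,b Genome sequence sets.
#' @inheritParams compute_one_way_ani
#' @return A list of class `ani_result` with `one_way_ab`, `one_way_ba`,
#'   `averaged`, `n_fragments_mapped` (sum of both directions).
#' @export
averaged_ani <- function(a, b, fragment_length = 1000, min_fragment_identity = 70) {
  ab <- tryCatch(compute_one_way_ani(a, b, fragment_length, min_fragment_identity),
                 error = function(e)
                   pm_data_error("ANI direction A->B failed: %s", conditionMessage(e)))
  ba <- tryCatch(compute_one_way_ani(b, a, fragment_length, min_fragment_identity),
                 error = function(e)
                   pm_data_error("ANI direction B->A failed: %s", conditionMessage(e)))
  structure(list(one_way_ab = ab$ani, one_way_ba = ba$ani,
                 averaged = (ab$ani + ba$ani) / 2,
                 n_fragments_mapped = ab$n_fragments_mapped + ba$n_fragments_mapped),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("ANI: %.2f%% (A->B %.2f%%, B->A %.2f%%; %d fragments mapped)\n",
              x$averaged, x$one_way_ab, x$one_way_ba, x$n_fragments_mapped))
  invisible(x)
}

#' Threshold-based species clustering
#'
#' Builds a graph over strains with an edge wherever both the ANI and AAI
#' values reach `threshold` percent, and reports connected components
#' (single linkage) as putative species. With `require_both = FALSE` an
#' edge needs only one of the two measures to pass. Missing AAI entries
#' (`NA`, or `aai_matrix = NULL`) are treated as passing, with a message.
#'
#' @param ani_matrix Symmetric strain-by-strain ANI matrix in percent
#'   (diagonal 100), with dimnames.
#' @param aai_matrix Optional symmetric AAI matrix over the same strains.
#' @param threshold Percent threshold for species co-membership (default 96).
#' @param require_both Require both measures to pass (default `TRUE`).
#' @return A list of class `species_partition` with `clusters` (list of
#'   strain-id character vectors, each strain in exactly one cluster) and
#'   `threshold`.
#' @export
cluster_species <- function(ani_matrix, aai_matrix = NULL, threshold = 96,
                            require_both = TRUE) {
  pm_assert_scalar_number(threshold, "threshold", 0, 100)
  check_sym <- function(m, what) {
    if (!is.matrix(m) || nrow(m) != ncol(m))
      pm_data_error("%s matrix must be square", what)
    if (is.null(rownames(m)) || is.null(colnames(m)))
      pm_data_error("%s matrix must have strain dimnames", what)
    if (max(abs(m - t(m)), na.rm = TRUE) > 1e-9)
      pm_data_error("%s matrix is asymmetric beyond tolerance 1e-9", what)
    m
  }
  ani_matrix <- check_sym(ani_matrix, "ANI")
  strains <- rownames(ani_matrix)
  if (is.null(aai_matrix)) {
    message("no AAI matrix supplied; species edges are based on ANI alone")
    aai_pass <- matrix(TRUE, length(strains), length(strains))
  } else {
    aai_matrix <- check_sym(aai_matrix, "AAI")
    if (!identical(sort(rownames(aai_matrix)), sort(strains)))
      pm_data_error("ANI and AAI matrices cover different strain sets")
    aai_matrix <- aai_matrix[strains, strains]
    if (anyNA(aai_matrix))
      message(sprintf("%d missing AAI value(s) treated as passing", sum(is.na(aai_matrix)) / 2))
    aai_pass <- is.na(aai_matrix) | aai_matrix >= threshold
  }
  ani_pass <- ani_matrix >= threshold
  adj <- if (require_both) ani_pass & aai_pass else ani_pass | aai_pass
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)
  clusters <- split(strains, comp$membership)
  clusters <- unname(clusters[order(vapply(clusters, min, character(1)))])
  structure(list(clusters = lapply(clusters, sort), threshold = threshold),
            class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cat(sprintf("species_partition: %d cluster(s) at %.0f%%\n",
              length(x$clusters), x$threshold))
  for (i in seq_along(x$clusters))
    cat(sprintf("  [%d] %s\n", i, paste(x$clusters[[i]], collapse = ", ")))
  invisible(x)
}

#' Families shared by an in-group and absent from an out-group
#'
#' Set logic over ortholog clusters: returns the families present in every
#' in-group strain and absent from every out-group strain (e.g. proteins
#' common and specific to a set of arsenic-oxidizing strains).
#'
#' @param ortholog_clusters Named list mapping family id to the character
#'   vector of strains carrying it.
#' @param in_group,out_group Disjoint, non-empty / possibly empty strain sets.
#' @return Character vector of family ids.
#' @export
shared_specific_sets <- function(ortholog_clusters, in_group, out_group = character()) {
  if (!length(in_group)) pm_config_error("in_group must be non-empty")
  if (length(intersect(in_group, out_group)))
    pm_config_error("in_group and out_group must be disjoint")
  covered <- unique(unlist(ortholog_clusters, use.names = FALSE))
  absent <- setdiff(c(in_group, out_group), covered)
  if (length(absent))
    pm_data_error("strain(s) not covered by any ortholog cluster: %s",
                  paste(absent, collapse = ", "))
  keep <- vapply(ortholog_clusters, function(strs)
    all(in_group %in% strs) && !any(out_group %in% strs), logical(1))
  names(ortholog_clusters)[keep]
}
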