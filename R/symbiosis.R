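## Two-stage HMM search bookkeeping and top-hit classification for the
## nodulation (NodA/NodB/NodC) and nitrogenase (NifH/NifD/NifK) proteins.
## The HMM searches themselves are external; this module consumes their
## tabular output.

## label -> matching TIGRFAM accessions / Pfam model names for the top hit
SYMBIOSIS_RULES <- list(
  NodA = list(accessions = "TIGR04245", names = "NodA"),
  NodB = list(accessions = "TIGR04243", names = character()),
  NodC = list(accessions = "TIGR04242", names = character()),
  NifH = list(accessions = "TIGR01287", names = "Fer4_NifH"),
  NifD = list(accessions = c("TIGR01282", "TIGR01860", "TIGR01861"), names = character()),
  NifK = list(accessions = c("TIGR02932", "TIGR02931", "TIGR01286"), names = character())
)

#' Construct an HMM hit table
#'
#' @param query_id Query protein ids.
#' @param hmm_name HMM model names (e.g. Pfam names).
#' @param hmm_accession HMM accessions (e.g. `TIGR04245`); version suffixes
#'   (`.1`) are tolerated by the classifier.
#' @param evalue Full-sequence e-values.
#' @param score Full-sequence bitscores.
#' @return A data frame of class columns `query_id`, `hmm_name`,
#'   `hmm_accession`, `evalue`, `score`.
#' @export
hmm_hits <- function(query_id, hmm_name, hmm_accession, evalue, score) {
  data.frame(query_id = as.character(query_id), hmm_name = as.character(hmm_name),
             hmm_accession = as.character(hmm_accession),
             evalue = as.numeric(evalue), score = as.numeric(score),
             stringsAsFactors = FALSE)
}

#' Read an HMMER3 tblout file
#'
#' Parses the per-sequence tabular output of `hmmsearch`/`hmmscan`
#' (`--tblout`). For `hmmsearch` the query protein is the *target* column
#' and the HMM the *query* column; for `hmmscan` the roles are swapped.
#' Only the full-sequence e-value and score are retained.
#'
#' @param path tblout path.
#' @param type `"hmmscan"` (default) or `"hmmsearch"`.
#' @return An [hmm_hits()] data frame.
#' @export
read_tblout <- function(path, type = c("hmmscan", "hmmsearch")) {
  type <- match.arg(type)
  if (!file.exists(path)) pm_data_error("tblout file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines))
    return(hmm_hits(character(), character(), character(), numeric(), numeric()))
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(parts, length, integer(1)) < 6L
  if (any(bad)) pm_data_error("malformed tblout line(s): %d", sum(bad))
  f <- function(i) vapply(parts, `[`, character(1), i)
  if (type == "hmmscan")
    hmm_hits(query_id = f(3), hmm_name = f(1), hmm_accession = f(2),
             evalue = as.numeric(f(5)), score = as.numeric(f(6)))
  else
    hmm_hits(query_id = f(1), hmm_name = f(3), hmm_accession = f(4),
             evalue = as.numeric(f(5)), score = as.numeric(f(6)))
}

#' Collect candidate proteins from a seed-HMM search
#'
#' Returns every query protein id appearing in the seed search output,
#' deliberately without any e-value filtering: the permissive first stage
#' only gathers candidates, classification happens at the scan stage.
#'
#' @param seed_search_hits An [hmm_hits()] data frame.
#' @return Character vector of unique query ids.
#' @export
collect_candidates <- function(seed_search_hits) {
  unique(seed_search_hits$query_id)
}

#' Top-scoring HMM hit per query protein
#'
#' Ties at equal score are broken by lower e-value, then lexicographic
#' accession, so the result is deterministic.
#'
#' @param scan_hits An [hmm_hits()] data frame.
#' @return The subset of `scan_hits` with one row per query, ordered by
#'   query id.
#' @export
top_hit_per_query <- function(scan_hits) {
  if (!nrow(scan_hits)) return(scan_hits)
  ord <- order(scan_hits$query_id, -scan_hits$score, scan_hits$evalue,
               scan_hits$hmm_accession)
  hits <- scan_hits[ord, , drop = FALSE]
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

strip_accession_version <- function(acc) sub("\\.[0-9]+$", "", acc)

#' Classify proteins by their top HMM hit
#'
#' Applies the symbiosis rule table: a protein is labelled NodA if its top
#' hit is TIGR04245 or the Pfam model NodA; NodB for TIGR04243; NodC for
#' TIGR04242; NifH for TIGR01287 or Fer4_NifH; NifD for TIGR01282,
#' TIGR01860 or TIGR01861; NifK for TIGR02932, TIGR02931 or TIGR01286;
#' anything else is `none`. Matching is on the TIGRFAM accession
#' (version-stripped) or the exact Pfam model name of the top hit only.
#'
#' @param top_hits Output of [top_hit_per_query()] (one row per query).
#' @return Data frame with `query_id`, `label`, `hmm_name`,
#'   `hmm_accession`, `score`.
#' @export
classify_symbiosis <- function(top_hits) {
  if (nrow(top_hits) && anyDuplicated(top_hits$query_id))
    pm_data_error("classify_symbiosis expects one (top) hit per query")
  label_one <- function(acc, nm) {
    acc <- strip_accession_version(acc)
    for (lbl in names(SYMBIOSIS_RULES)) {
      rule <- SYMBIOSIS_RULES[[lbl]]
      if (acc %in% rule$accessions || nm %in% rule$names) return(lbl)
    }
    "none"
  }
  labels <- if (nrow(top_hits))
    mapply(label_one, top_hits$hmm_accession, top_hits$hmm_name) else character()
  data.frame(query_id = top_hits$query_id, label = unname(labels),
             hmm_name = top_hits$hmm_name, hmm_accession = top_hits$hmm_accession,
             score = top_hits$score, stringsAsFactors = FALSE)
}

#' Summarize symbiosis-gene presence
#'
#' A label is present iff at least one call carries it; the composite
#' `nodABC` requires all of NodA, NodB and NodC, and `nifHDK` all of NifH,
#' NifD and NifK.
#'
#' @param calls Output of [classify_symbiosis()].
#' @return Named logical vector over NodA, NodB, NodC, NifH, NifD, NifK,
#'   nodABC, nifHDK.
#' @export
summarize_presence <- function(calls) {
  labels <- names(SYMBIOSIS_RULES)
  present <- stats::setNames(labels %in% calls$label, labels)
  c(present,
    nodABC = unname(all(present[c("NodA", "NodB", "NodC")])),
    nifHDK = unname(all(present[c("NifH", "NifD", "NifK")])))
}

#' Write symbiosis calls to TSV
#'
#' @param calls Output of [classify_symbiosis()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_symbiosis_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
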