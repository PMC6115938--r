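## Tabular similarity-hit tables (BLAST/DIAMOND outfmt-6 dialect).

HIT12 <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
           "qstart", "qend", "sstart", "send", "evalue", "bitscore")
HIT14 <- c(HIT12, "qlen", "slen")

#' Construct a similarity-hit table
#'
#' A hit table is a data frame in the 12-column tabular alignment format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`) extended with `qlen` and `slen` (query/subject protein
#' lengths), which are required for coverage filtering.
#'
#' @param qseqid,sseqid Query/subject ids.
#' @param pident Percent identity in \[0, 100\].
#' @param length Alignment length (residues).
#' @param evalue,bitscore Alignment e-value and bitscore.
#' @param qlen,slen Query and subject sequence lengths.
#' @param mismatch,gapopen,qstart,qend,sstart,send Optional positional
#'   columns; defaulted when not supplied.
#' @return A `data.frame` with the 14 canonical columns.
#' @export
hit_table <- function(qseqid, sseqid, pident, length, evalue, bitscore,
                      qlen, slen, mismatch = 0L, gapopen = 0L,
                      qstart = 1L, qend = length, sstart = 1L, send = length) {
  df <- data.frame(qseqid = as.character(qseqid), sseqid = as.character(sseqid),
                   pident = as.numeric(pident), length = as.integer(length),
                   mismatch = mismatch, gapopen = gapopen,
                   qstart = qstart, qend = qend, sstart = sstart, send = send,
                   evalue = as.numeric(evalue), bitscore = as.numeric(bitscore),
                   qlen = as.integer(qlen), slen = as.integer(slen),
                   stringsAsFactors = FALSE)
  validate_hits(df)
}

validate_hits <- function(df) {
  missing <- setdiff(HIT12, names(df))
  if (length(missing))
    pm_data_error("hit table lacks column(s): %s", paste(missing, collapse = ", "))
  if (!all(c("qlen", "slen") %in% names(df)))
    pm_data_error("hit table lacks qlen/slen; supply a qlen/slen sidecar or the 14-column dialect")
  if (nrow(df) && (any(df$qlen < 1) || any(df$slen < 1)))
    pm_data_error("qlen/slen must be >= 1")
  if (nrow(df) && (any(df$pident < 0) || any(df$pident > 100)))
    pm_data_error("pident outside [0, 100]")
  df
}

#' Read a tabular hit file
#'
#' Accepts the 12-column tabular alignment format plus either the extended
#' 14-column dialect (`... qlen slen`) or a separate two-column sequence
#' length sidecar applied to both query and subject id spaces.
#'
#' @param path Path to the (headerless, tab-separated) hit file.
#' @param seqlen Optional named integer vector or path to a two-column TSV
#'   (`id<TAB>length`) giving sequence lengths when the file has 12 columns.
#' @return A validated hit table data frame.
#' @export
read_hits <- function(path, seqlen = NULL) {
  if (!file.exists(path)) pm_data_error("hit file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) == 14L) {
    names(df) <- HIT14
  } else if (ncol(df) == 12L) {
    names(df) <- HIT12
    if (is.character(seqlen) && length(seqlen) == 1L) {
      tab <- utils::read.delim(seqlen, header = FALSE, stringsAsFactors = FALSE)
      seqlen <- stats::setNames(as.integer(tab[[2]]), as.character(tab[[1]]))
    }
    if (is.null(seqlen))
      pm_data_error("12-column hit file requires a 'seqlen' sidecar")
    df$qlen <- as.integer(seqlen[df$qseqid])
    df$slen <- as.integer(seqlen[df$sseqid])
    if (anyNA(df$qlen) || anyNA(df$slen))
      pm_data_error("seqlen sidecar is missing ids present in the hit file")
  } else {
    pm_data_error("hit file must have 12 or 14 tab-separated columns, got %d", ncol(df))
  }
  validate_hits(df)
}

#' Write a hit table in the 14-column tabular dialect
#'
#' @param hits A hit table data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits <- function(hits, path) {
  validate_hits(hits)
  utils::write.table(hits[, HIT14], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Collapse duplicate (query, subject) rows to the highest-bitscore row.
dedupe_hits <- function(hits) {
  key <- paste(hits$qseqid, hits$sseqid, sep = "\r")
  if (!anyDuplicated(key)) return(hits)
  message(sprintf("collapsing %d duplicate (query, subject) hit row(s) to best bitscore",
                  sum(duplicated(key))))
  ord <- order(key, -hits$bitscore, hits$evalue)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(paste(hits$qseqid, hits$sseqid, sep = "\r")), , drop = FALSE]
}

## Best hit per query: maximal bitscore, ties broken by lower e-value,
## then longer alignment, then lexicographic subject id.
best_hit_per_query <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, -hits$length, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$qseqid), , drop = FALSE]
}
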