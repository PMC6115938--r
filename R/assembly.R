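#' Construct a scaffold set
#'
#' A scaffold set couples named DNA sequences with per-scaffold fold-coverage
#' values, the unit on which assembly filtering and statistics operate.
#' Sequences are upper-cased and IUPAC ambiguity codes other than
#' \code{A/C/G/T/N} are normalized to \code{N}.
#'
#' @param sequences A named character vector or a
#'   [Biostrings::DNAStringSet] of scaffold sequences.
#' @param coverage Numeric vector of fold-coverage values, one per scaffold
#'   (recycled names from `sequences` if unnamed). Use `NA` when unknown.
#' @return An object of class `scaffold_set`: a list with elements `seq`
#'   (a [Biostrings::DNAStringSet]) and `coverage` (named numeric vector).
#' @export
scaffold_set <- function(sequences, coverage = NA_real_) {
  if (is.character(sequences)) {
    if (is.null(names(sequences)))
      names(sequences) <- sprintf("scaffold_%d", seq_along(sequences))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  if (!methods::is(sequences, "DNAStringSet"))
    pm_data_error("sequences must be a character vector or DNAStringSet")
  if (any(duplicated(names(sequences))))
    pm_data_error("duplicate scaffold ids")
  if (length(sequences) && any(Biostrings::width(sequences) < 1L))
    pm_data_error("zero-length scaffold sequence")
  ## normalize ambiguity codes (not N) to N
  if (length(sequences))
    sequences <- Biostrings::DNAStringSet(
      chartr("MRWSYKVHDBmrwsykvhdb", strrep("N", 20),
             as.character(sequences)))
  coverage <- rep_len(as.numeric(coverage), length(sequences))
  names(coverage) <- names(sequences)
  structure(list(seq = sequences, coverage = coverage), class = "scaffold_set")
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat(sprintf("scaffold_set: %d scaffolds, %s bp total\n",
              length(x$seq), format(sum(Biostrings::width(x$seq)), big.mark = ",")))
  invisible(x)
}

#' @export
length.scaffold_set <- function(x) length(x$seq)

#' Scaffold ids of a scaffold set
#' @param x A [scaffold_set].
#' @return Character vector of scaffold ids.
#' @export
scaffold_ids <- function(x) names(x$seq)

#' Per-scaffold coverage values of a scaffold set
#' @param x A [scaffold_set].
#' @return Named numeric vector of fold-coverage values (`NA` when unknown).
#' @export
scaffold_coverage <- function(x) {
  if (is.null(x$coverage)) rep(NA_real_, length(x$seq)) else x$coverage
}

#' Read scaffolds from FASTA with coverage metadata
#'
#' Coverage is taken from (in order of precedence) the `coverage` argument,
#' a two-column sidecar TSV (`id<TAB>coverage`, no header required), or an
#' assembler-style header suffix `_cov_<x>` (as written by SPAdes).
#'
#' @param fasta Path to a (possibly multi-record) FASTA file.
#' @param coverage Optional: path to a sidecar TSV, or a named numeric vector.
#' @return A [scaffold_set].
#' @export
read_scaffolds <- function(fasta, coverage = NULL) {
  if (!file.exists(fasta)) pm_data_error("FASTA file not found: %s", fasta)
  seqs <- Biostrings::readDNAStringSet(fasta)
  ## keep only the first whitespace-delimited token as the id
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  names(seqs) <- ids
  cov <- rep(NA_real_, length(seqs))
  names(cov) <- ids
  if (is.null(coverage)) {
    m <- regmatches(ids, regexpr("_cov_[0-9]+(\\.[0-9]+)?", ids))
    has <- grepl("_cov_[0-9]+(\\.[0-9]+)?", ids)
    cov[has] <- as.numeric(sub("_cov_", "", m))
  } else if (is.character(coverage) && length(coverage) == 1L) {
    if (!file.exists(coverage)) pm_data_error("coverage TSV not found: %s", coverage)
    tab <- utils::read.delim(coverage, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) pm_data_error("coverage TSV needs two columns (id, coverage)")
    ## tolerate a header line
    if (is.na(suppressWarnings(as.numeric(tab[1, 2])))) tab <- tab[-1, , drop = FALSE]
    cv <- as.numeric(tab[[2]]); names(cv) <- as.character(tab[[1]])
    cov[names(cv)[names(cv) %in% ids]] <- cv[names(cv) %in% ids]
  } else if (is.numeric(coverage)) {
    if (is.null(names(coverage))) pm_data_error("numeric coverage must be named by scaffold id")
    cov[names(coverage)[names(coverage) %in% ids]] <- coverage[names(coverage) %in% ids]
  } else pm_data_error("unsupported 'coverage' argument")
  scaffold_set(seqs, cov)
}

#' Write a scaffold set to FASTA (and optional coverage TSV)
#'
#' @param x A [scaffold_set].
#' @param fasta Output FASTA path.
#' @param coverage_tsv Optional output path for an `id<TAB>coverage` sidecar.
#' @return Invisibly, `fasta`.
#' @export
write_scaffolds <- function(x, fasta, coverage_tsv = NULL) {
  Biostrings::writeXStringSet(x$seq, fasta)
  if (!is.null(coverage_tsv)) {
    utils::write.table(
      data.frame(id = names(x$seq), coverage = scaffold_coverage(x)),
      coverage_tsv, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta)
}

#' Filter scaffolds by coverage and length
#'
#' Removes scaffolds with less than `min_coverage` fold-coverage or shorter
#' than `min_length` nucleotides. Both comparisons are strict removals, so a
#' scaffold at exactly the threshold is retained. Order is preserved.
#'
#' @param x A [scaffold_set].
#' @param min_coverage Minimum fold-coverage retained (default 10).
#' @param min_length Minimum length in nt retained (default 200).
#' @return The filtered [scaffold_set].
#' @export
filter_scaffolds <- function(x, min_coverage = 10, min_length = 200) {
  pm_assert_scalar_number(min_coverage, "min_coverage", min = 0)
  pm_assert_scalar_number(min_length, "min_length", min = 0)
  cov <- scaffold_coverage(x)
  if (length(x) && anyNA(cov))
    pm_data_error("cannot filter on coverage: %d scaffold(s) lack a coverage value",
                  sum(is.na(cov)))
  keep <- cov >= min_coverage & Biostrings::width(x$seq) >= min_length
  scaffold_set(x$seq[keep], cov[keep])
}

#' Assembly statistics
#'
#' Computes the standard descriptive statistics of a scaffold assembly:
#' total length, GC content (ambiguous bases excluded from both numerator
#' and denominator), N50/L50, and the count and length fraction of scaffolds
#' strictly longer than `size_threshold`.
#'
#' N50 is the length of the scaffold at which the cumulative length, taken
#' in descending length order (ties broken by id), first reaches half the
#' total length; L50 is that scaffold's rank.
#'
#' @param x A [scaffold_set] with at least one scaffold.
#' @param size_threshold Length threshold in nt for the "large scaffold"
#'   count/fraction (default 40000; comparison is strict `>`).
#' @return A list of class `assembly_stats` with fields `total_length`,
#'   `gc_percent`, `n_scaffolds`, `n50`, `l50`, `count_over_threshold`,
#'   `fraction_length_over_threshold` (percent) and `mean_coverage`
#'   (length-weighted; `NA` if coverage unknown — note that a per-scaffold
#'   unweighted mean is an equally defensible convention).
#' @export
assembly_stats <- function(x, size_threshold = 40000) {
  if (length(x) < 1L) pm_data_error("assembly_stats requires at least one scaffold")
  pm_assert_scalar_number(size_threshold, "size_threshold", min = 0)
  w <- Biostrings::width(x$seq)
  total <- sum(w)
  freq <- Biostrings::letterFrequency(x$seq, letters = c("A", "C", "G", "T"))
  acgt <- sum(freq)
  gc <- if (acgt > 0) 100 * sum(freq[, c("C", "G")]) / acgt else NA_real_
  ord <- order(-w, names(x$seq))
  cum <- cumsum(w[ord])
  l50 <- which(cum >= total / 2)[1L]
  n50 <- w[ord][l50]
  over <- w > size_threshold
  cov <- scaffold_coverage(x)
  meancov <- if (anyNA(cov)) NA_real_ else sum(cov * w) / total
  structure(list(
    total_length = as.integer(total),
    gc_percent = gc,
    n_scaffolds = length(x),
    n50 = as.integer(n50),
    l50 = as.integer(l50),
    count_over_threshold = sum(over),
    fraction_length_over_threshold = 100 * sum(w[over]) / total,
    size_threshold = as.integer(size_threshold),
    mean_coverage = meancov
  ), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(
    paste0("Assembly statistics\n",
           "  total length : %s bp\n",
           "  scaffolds    : %d\n",
           "  GC content   : %.2f%%\n",
           "  N50 (L50)    : %s (%d)\n",
           "  %-13s: %d scaffolds, %.1f%% of length\n"),
    format(x$total_length, big.mark = ","), x$n_scaffolds, x$gc_percent,
    format(x$n50, big.mark = ","), x$l50,
    paste0("> ", format(x$size_threshold, big.mark = ","), " bp"),
    x$count_over_threshold, x$fraction_length_over_threshold))
  if (!is.na(x$mean_coverage))
    cat(sprintf("  mean coverage: %.0fx (length-weighted)\n", x$mean_coverage))
  invisible(x)
}

#' Write assembly statistics to TSV or JSON
#'
#' @param stats An `assembly_stats` object.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_assembly_stats <- function(stats, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  fields <- stats[!vapply(stats, is.null, logical(1))]
  if (format == "json") {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(
      data.frame(statistic = names(fields), value = unlist(fields)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
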