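#' Construct a gene presence/absence matrix
#'
#' @param presence A logical (or 0/1) matrix, families in rows, strains in
#'   columns, with unique dimnames. Every family must be present in at
#'   least one strain.
#' @param representative_gene Optional named list mapping family id to a
#'   named character vector (strain -> representative gene id).
#' @return An object of class `presence_absence` (a logical matrix with an
#'   optional `representative_gene` attribute).
#' @export
presence_absence <- function(presence, representative_gene = NULL) {
  if (!is.matrix(presence)) pm_data_error("presence must be a matrix")
  m <- matrix(as.logical(presence), nrow(presence), ncol(presence),
              dimnames = dimnames(presence))
  if (is.null(rownames(m)) || is.null(colnames(m)))
    pm_data_error("presence matrix needs family rownames and strain colnames")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    pm_data_error("duplicate family or strain ids")
  if (nrow(m) && any(rowSums(m) == 0))
    pm_data_error("every family must be present in at least one strain")
  structure(m, representative_gene = representative_gene,
            class = c("presence_absence", "matrix"))
}

#' @export
print.presence_absence <- function(x, ...) {
  cat(sprintf("presence_absence: %d families x %d strains (%d core)\n",
              nrow(x), ncol(x), sum(rowSums(unclass(x)) == ncol(x))))
  invisible(x)
}

#' Read a pangenome gene presence/absence CSV
#'
#' Reads the pangenome CSV dialect (`gene_presence_absence.csv` as written
#' by pangenome pipelines): a `Gene` column, optional annotation columns,
#' then one column per strain holding the representative gene id (empty
#' when absent). All columns after the last of the recognized annotation
#' columns are taken as strains unless `strains` is given.
#'
#' @param path CSV path.
#' @param strains Optional character vector naming the strain columns.
#' @return A [presence_absence] matrix with representative genes attached.
#' @export
read_presence_absence <- function(path, strains = NULL) {
  if (!file.exists(path)) pm_data_error("presence/absence CSV not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"Gene" %in% names(df)) pm_data_error("CSV lacks a 'Gene' column")
  meta_cols <- c("Gene", "Non-unique Gene name", "Annotation", "No. isolates",
                 "No. sequences", "Avg sequences per isolate", "Genome Fragment",
                 "Order within Fragment", "Accessory Fragment",
                 "Accessory Order with Fragment", "QC", "Min group size nuc",
                 "Max group size nuc", "Avg group size nuc")
  if (is.null(strains)) strains <- setdiff(names(df), meta_cols)
  if (!length(strains)) pm_data_error("no strain columns identified")
  pres <- as.matrix(df[, strains, drop = FALSE]) != "" &
    !is.na(as.matrix(df[, strains, drop = FALSE]))
  rownames(pres) <- df$Gene
  rep_gene <- lapply(seq_len(nrow(df)), function(i) {
    v <- as.character(df[i, strains]); names(v) <- strains
    v[nzchar(v) & !is.na(v)]
  })
  names(rep_gene) <- df$Gene
  presence_absence(pres, representative_gene = rep_gene)
}

#' Write a presence/absence matrix in the pangenome CSV dialect
#'
#' @param m A [presence_absence] matrix.
#' @param path Output CSV path.
#' @param annotation Optional named character vector (family -> annotation).
#' @return Invisibly, `path`.
#' @export
write_presence_absence <- function(m, path, annotation = NULL) {
  rep_gene <- attr(m, "representative_gene")
  strains <- colnames(m)
  cells <- sapply(strains, function(s) {
    vapply(rownames(m), function(f) {
      if (!m[f, s]) return("")
      rg <- rep_gene[[f]]
      if (!is.null(rg) && s %in% names(rg)) rg[[s]] else paste(f, s, sep = "_")
    }, character(1))
  })
  cells <- matrix(cells, nrow = nrow(m), dimnames = list(rownames(m), strains))
  ann <- if (is.null(annotation)) rep("", nrow(m)) else
    ifelse(is.na(annotation[rownames(m)]), "", annotation[rownames(m)])
  out <- data.frame(Gene = rownames(m), Annotation = ann,
                    cells, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Core gene families
#'
#' Families present in 100% of strains.
#'
#' @param m A [presence_absence] matrix.
#' @return Character vector of family ids.
#' @export
core_families <- function(m) {
  rownames(m)[rowSums(unclass(m)) == ncol(m)]
}

#' Venn partition of gene families over focal strains
#'
#' Restricted to 2-4 focal strains, counts families for each non-empty
#' presence pattern; families absent from all focal strains are excluded.
#' Pattern names join the present strains with `&` in the order given.
#'
#' @param m A [presence_absence] matrix.
#' @param focal_strains Ordered subset of 2-4 strain ids.
#' @return Named integer vector of counts over the `2^k - 1` patterns
#'   (zero-count patterns included).
#' @export
venn_partition <- function(m, focal_strains) {
  unknown <- setdiff(focal_strains, colnames(m))
  if (length(unknown)) pm_data_error("unknown strain id(s): %s", paste(unknown, collapse = ", "))
  k <- length(focal_strains)
  if (k < 2 || k > 4) pm_config_error("venn_partition supports 2-4 focal strains, got %d", k)
  sub <- unclass(m)[, focal_strains, drop = FALSE]
  patterns <- lapply(seq_len(2^k - 1), function(code) as.logical(bitwAnd(code, 2^(seq_len(k) - 1)) > 0))
  counts <- vapply(patterns, function(p)
    sum(apply(sub, 1, function(row) all(row == p))), integer(1))
  names(counts) <- vapply(patterns, function(p)
    paste(focal_strains[p], collapse = "&"), character(1))
  counts
}

#' Families unique to a focal strain
#'
#' Families present in the focal strain and absent from every other strain
#' in the matrix.
#'
#' @param m A [presence_absence] matrix.
#' @param focal Strain id.
#' @return Character vector of family ids.
#' @export
unique_families <- function(m, focal) {
  if (!focal %in% colnames(m)) pm_data_error("unknown strain id: %s", focal)
  sub <- unclass(m)
  others <- setdiff(colnames(sub), focal)
  rownames(sub)[sub[, focal] & rowSums(sub[, others, drop = FALSE]) == 0]
}

#' Detect putative genomic islands of strain-unique genes
#'
#' Per scaffold, genes are ranked by start position; maximal runs of unique
#' genes in which consecutive unique genes are separated by at most
#' `max_gap_genes` non-unique genes form candidate islands, and candidates
#' containing at least `min_island_genes` unique genes are reported. The
#' parameters are heuristics exposed through the configuration; contiguous
#' clusters of strain-specific genes are suggestive of horizontal transfer.
#'
#' @param unique_set Character vector of unique family ids.
#' @param gene_map Named character vector mapping family id to the focal
#'   strain's gene id.
#' @param locations Data frame with columns `gene_id`, `scaffold_id`,
#'   `start`, `end` (1-based inclusive) and optionally `strand`.
#' @param min_island_genes Minimum unique genes per island (default 4).
#' @param max_gap_genes Maximum intervening non-unique genes (default 3).
#' @return Data frame with one row per island: `scaffold_id`,
#'   `first_gene_index`, `last_gene_index` (gene ranks along the scaffold),
#'   `n_unique`, `span_nt`, `start`, `end`; sorted by scaffold then start.
#' @export
detect_islands <- function(unique_set, gene_map, locations,
                           min_island_genes = 4, max_gap_genes = 3) {
  min_island_genes <- pm_assert_count(min_island_genes, "min_island_genes")
  max_gap_genes <- pm_assert_count(max_gap_genes, "max_gap_genes")
  need <- c("gene_id", "scaffold_id", "start", "end")
  if (!all(need %in% names(locations)))
    pm_data_error("locations needs columns: %s", paste(need, collapse = ", "))
  unique_genes <- unname(gene_map[unique_set])
  missing <- unique_set[!unique_set %in% names(gene_map) |
                          !gene_map[unique_set] %in% locations$gene_id]
  if (length(missing)) {
    warning(sprintf("%d unique famil(ies) without a located gene skipped: %s",
                    length(missing), paste(utils::head(missing, 5), collapse = ", ")))
    unique_genes <- unname(gene_map[setdiff(unique_set, missing)])
  }
  out <- list()
  for (scf in unique(locations$scaffold_id)) {
    loc <- locations[locations$scaffold_id == scf, , drop = FALSE]
    loc <- loc[order(loc$start, loc$gene_id), , drop = FALSE]
    is_uniq <- loc$gene_id %in% unique_genes
    idx <- which(is_uniq)
    if (!length(idx)) next
    ## group unique-gene ranks separated by <= max_gap_genes non-unique genes
    grp <- cumsum(c(1L, diff(idx) > max_gap_genes + 1L))
    for (g in split(idx, grp)) {
      if (length(g) < min_island_genes) next
      out[[length(out) + 1L]] <- data.frame(
        scaffold_id = scf,
        first_gene_index = min(g), last_gene_index = max(g),
        n_unique = length(g),
        span_nt = max(loc$end[g]) - min(loc$start[g]) + 1L,
        start = min(loc$start[g]), end = max(loc$end[g]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(scaffold_id = character(), first_gene_index = integer(),
                      last_gene_index = integer(), n_unique = integer(),
                      span_nt = integer(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$scaffold_id, res$start), , drop = FALSE]
}

#' Read gene locations from a GFF3 file
#'
#' Extracts gene/CDS features into the location table used by
#' [detect_islands()]. Uses rtracklayer when available, otherwise a plain
#' nine-column parse.
#'
#' @param path GFF3 path.
#' @param feature_types Feature types retained (default CDS and gene).
#' @return Data frame with `gene_id`, `scaffold_id`, `start`, `end`, `strand`.
#' @export
read_gene_locations <- function(path, feature_types = c("CDS", "gene")) {
  if (!file.exists(path)) pm_data_error("GFF3 file not found: %s", path)
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path)
    gr <- gr[as.character(gr$type) %in% feature_types]
    ids <- if (!is.null(gr$ID)) gr$ID else as.character(seq_along(gr))
    return(data.frame(gene_id = as.character(ids),
                      scaffold_id = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parts <- parts[vapply(parts, length, integer(1)) >= 9L]
  df <- do.call(rbind, lapply(parts, function(p) {
    data.frame(scaffold_id = p[1], type = p[3],
               start = as.integer(p[4]), end = as.integer(p[5]),
               strand = p[7], attr = p[9], stringsAsFactors = FALSE)
  }))
  df <- df[df$type %in% feature_types, , drop = FALSE]
  id <- sub(".*ID=([^;]+).*", "\\1", df$attr)
  data.frame(gene_id = id, scaffold_id = df$scaffold_id, start = df$start,
             end = df$end, strand = df$strand, stringsAsFactors = FALSE)
}

## ---- COG functional-category profiling ------------------------------------

COG_LETTERS <- strsplit("JAKLBDYVTMNZWUOXCGEFHIPQRS", "")[[1]]

#' COG functional-category profile
#'
#' Counts, per single-letter COG category, the proteins annotated with it.
#' A protein annotated with k categories increments each of the k counts
#' (`multi = "all"`, the default, so category percentages reflect the share
#' of proteins annotated with each category); `multi = "first"` assigns
#' only the first listed category. Letters outside the standard alphabet
#' are bucketed as `unknown` with a warning. Category S (function unknown)
#' can be excluded from the annotated total.
#'
#' @param annotations Named character vector: gene id -> category letters
#'   (e.g. `"P"`, `"PC"`).
#' @param multi `"all"` or `"first"`.
#' @param exclude_S Exclude category S from `total_annotated` (default
#'   `FALSE`).
#' @return A list of class `cog_profile` with `counts` (named integer over
#'   the standard alphabet plus `unknown`), `percent`, `total_annotated`.
#' @export
cog_profile <- function(annotations, multi = c("all", "first"), exclude_S = FALSE) {
  multi <- match.arg(multi)
  counts <- stats::setNames(integer(length(COG_LETTERS) + 1L), c(COG_LETTERS, "unknown"))
  annotations <- annotations[!is.na(annotations) & nzchar(annotations)]
  n_annotated <- 0L
  for (a in annotations) {
    letters_i <- strsplit(toupper(a), "")[[1]]
    letters_i <- letters_i[letters_i != "-"]
    if (multi == "first") letters_i <- letters_i[1]
    bad <- setdiff(letters_i, COG_LETTERS)
    if (length(bad)) {
      warning(sprintf("unknown COG letter(s) '%s' bucketed as unknown",
                      paste(bad, collapse = "")))
      letters_i <- c(setdiff(letters_i, bad), rep("unknown", length(bad)))
    }
    if (exclude_S && all(letters_i %in% "S")) next
    n_annotated <- n_annotated + 1L
    for (l in unique(letters_i)) counts[l] <- counts[l] + 1L
  }
  structure(list(counts = counts, total_annotated = n_annotated,
                 percent = if (n_annotated > 0) 100 * counts / n_annotated else counts * 0),
            class = "cog_profile")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration: the sum of the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (ties included within
#' relative tolerance 1e-12). The odds ratio is the sample odds ratio
#' `ad/bc` with the usual 0/Inf conventions.
#'
#' @param table A 2x2 matrix (or length-4 vector, row-major) of
#'   non-negative integers with at least one positive margin.
#' @return A list with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(table) {
  if (is.vector(table) && length(table) == 4L) table <- matrix(table, 2, byrow = TRUE)
  if (!is.matrix(table) || !all(dim(table) == c(2L, 2L)))
    pm_data_error("fisher_exact_2x2 requires a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    pm_data_error("cells must be non-negative integers")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0) pm_data_error("at least one margin must be positive")
  or <- if (b * c == 0) { if (a * d == 0) NaN else Inf } else (a * d) / (b * c)
  if (m == 0 || n == 0 || k == 0 || k == m + n)
    return(list(odds_ratio = or, p_value = 1))
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  list(odds_ratio = or, p_value = min(1, p))
}

#' Pairwise comparison of two COG profiles
#'
#' For every category, tests the 2x2 table
#' `[[count_a, total_a - count_a], [count_b, total_b - count_b]]` with
#' [fisher_exact_2x2()] and flags categories significant at `alpha`.
#' No multiple-testing correction is applied by default; set
#' `bonferroni = TRUE` to adjust by the number of categories tested.
#'
#' @param a,b [cog_profile] objects.
#' @param alpha Significance level (default 0.05).
#' @param bonferroni Apply Bonferroni correction (default `FALSE`).
#' @return Data frame with `category`, `count_a`, `count_b`, `percent_a`,
#'   `percent_b`, `odds_ratio`, `p_value`, `significant`.
#' @export
compare_cog_profiles <- function(a, b, alpha = 0.05, bonferroni = FALSE) {
  pm_assert_scalar_number(alpha, "alpha", 0, 1)
  if (a$total_annotated == 0 || b$total_annotated == 0)
    pm_data_error("both profiles must have a positive annotated total")
  cats <- union(names(a$counts)[a$counts > 0], names(b$counts)[b$counts > 0])
  if (!length(cats)) cats <- COG_LETTERS
  res <- lapply(cats, function(cat) {
    ca <- if (cat %in% names(a$counts)) a$counts[[cat]] else 0L
    cb <- if (cat %in% names(b$counts)) b$counts[[cat]] else 0L
    ft <- fisher_exact_2x2(matrix(c(ca, a$total_annotated - ca,
                                    cb, b$total_annotated - cb), 2, byrow = TRUE))
    data.frame(category = cat, count_a = ca, count_b = cb,
               percent_a = 100 * ca / a$total_annotated,
               percent_b = 100 * cb / b$total_annotated,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  thr <- if (bonferroni) alpha / nrow(res) else alpha
  res$significant <- res$p_value < thr
  res[order(res$category), , drop = FALSE]
}
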