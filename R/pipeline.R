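PIPELINE_DEFAULTS <- list(
  scaffold_min_coverage = 10, scaffold_min_length = 200L,
  bbh_min_identity = 70, bbh_min_coverage = 70,
  aai_min_identity = 40, aai_min_coverage = 70, aai_max_evalue = 1e-12,
  family_identity = 80, species_threshold = 96, species_threshold_alt = 94,
  blast_hit_max_evalue = 1e-10, fisher_alpha = 0.05,
  ani_fragment_length = 1000L, ani_min_fragment_identity = 70,
  panel_size = 163L, uptake_rate = 10, growth_epsilon = 1e-6,
  island_min_genes = 4L, island_max_gap = 3L,
  random_seed = 1L)

#' Pipeline configuration
#'
#' Houses every numeric threshold of the characterization pipeline with
#' its default: scaffold filtering (10x coverage, 200 nt), ortholog
#' detection (70% identity / 70% coverage), AAI orthologs (40% / 70% /
#' e-value 1e-12), protein-family clustering identity (80%), species
#' delineation (96%, alternative 94%), unique-gene BLAST confirmation
#' e-value (1e-10), Fisher significance (0.05), the carbon-panel size
#' (163), FBA uptake rate and growth threshold, and the genomic-island
#' heuristics. Unknown keys are a configuration error; the configuration
#' round-trips losslessly through YAML.
#'
#' @param ... Named overrides of the defaults (see
#'   `panmetab:::PIPELINE_DEFAULTS`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  overrides <- list(...)
  if (length(overrides) && (is.null(names(overrides)) || any(!nzchar(names(overrides)))))
    pm_config_error("all configuration overrides must be named")
  unknown <- setdiff(names(overrides), names(PIPELINE_DEFAULTS))
  if (length(unknown))
    pm_config_error("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, overrides)
  for (f in c("bbh_min_identity", "bbh_min_coverage", "aai_min_identity",
              "aai_min_coverage", "family_identity", "species_threshold",
              "species_threshold_alt", "ani_min_fragment_identity"))
    pm_assert_scalar_number(cfg[[f]], f, 0, 100)
  pm_assert_scalar_number(cfg$fisher_alpha, "fisher_alpha", 0, 1)
  for (f in c("scaffold_min_coverage", "scaffold_min_length", "aai_max_evalue",
              "blast_hit_max_evalue", "uptake_rate", "growth_epsilon"))
    pm_assert_scalar_number(cfg[[f]], f, min = 0)
  for (f in c("panel_size", "island_min_genes", "island_max_gap", "random_seed",
              "ani_fragment_length"))
    cfg[[f]] <- pm_assert_count(cfg[[f]], f)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @return For `read_pipeline_config`, a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) pm_config_error("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @return For `write_pipeline_config`, invisibly `path`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full characterization pipeline on a fixture bundle
#'
#' Executes every stage in dependency order on the files written by
#' [simulate_fixtures()] (or files of the same layout): assembly filtering
#' and statistics, averaged ANI of the genome pair, bidirectional best
#' hits and AAI from the hit tables, pangenome analytics (core families,
#' focal-strain Venn partition, unique families, genomic islands), model
#' expansion with dead-end removal, and the carbon-source growth screen.
#' Any stage failure aborts with an error naming the stage. Scientific
#' outputs are deterministic given the configuration and inputs.
#'
#' @param config A [pipeline_config()].
#' @param dir Directory holding the fixture bundle.
#' @param stages Character vector of stages to run (default all).
#' @return A list of class `run_report`: per-stage outputs, the parameter
#'   snapshot, and accumulated warnings.
#' @export
run_pipeline <- function(config, dir,
                         stages = c("assembly", "ani", "homology", "pangenome",
                                    "model", "screen")) {
  if (!inherits(config, "pipeline_config")) pm_config_error("config must be a pipeline_config")
  stages <- match.arg(stages, several.ok = TRUE)
  p <- function(...) {
    f <- file.path(dir, ...)
    if (!file.exists(f)) pm_data_error("missing input file: %s", f)
    f
  }
  report <- list(config = unclass(config), stages = list(), warnings = character())
  run_stage <- function(name, fn) {
    res <- withCallingHandlers(
      tryCatch(fn(), error = function(e)
        stop(errorCondition(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                            class = c("panmetab_stage_error", "panmetab_error")))),
      warning = function(w) {
        report$warnings <<- c(report$warnings, sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    report$stages[[name]] <<- res
  }

  if ("assembly" %in% stages) run_stage("assembly", function() {
    asm <- read_scaffolds(p("assembly.fna"), p("assembly_coverage.tsv"))
    kept <- filter_scaffolds(asm, config$scaffold_min_coverage, config$scaffold_min_length)
    list(n_input = length(asm), n_kept = length(kept),
         stats = assembly_stats(kept))
  })
  if ("ani" %in% stages) run_stage("ani", function() {
    a <- Biostrings::readDNAStringSet(p("genomeA.fna"))
    b <- Biostrings::readDNAStringSet(p("genomeB.fna"))
    averaged_ani(a, b, fragment_length = config$ani_fragment_length,
                 min_fragment_identity = config$ani_min_fragment_identity)
  })
  if ("homology" %in% stages) run_stage("homology", function() {
    ab <- read_hits(p("hits_AB.tsv")); ba <- read_hits(p("hits_BA.tsv"))
    pairs <- bidirectional_best_hits(ab, ba, config$bbh_min_identity,
                                     config$bbh_min_coverage)
    aai <- compute_aai(ab, ba, config$aai_min_identity, config$aai_min_coverage,
                       config$aai_max_evalue)
    list(n_orthologs = nrow(pairs), aai = aai$aai)
  })
  if ("pangenome" %in% stages) run_stage("pangenome", function() {
    pam <- read_presence_absence(p("gene_presence_absence.csv"))
    focal <- colnames(pam)[1]
    gm <- utils::read.delim(p("focal_gene_map.tsv"), stringsAsFactors = FALSE)
    gene_map <- stats::setNames(gm$gene, gm$family)
    loc <- utils::read.delim(p("gene_locations.tsv"), stringsAsFactors = FALSE)
    uniq <- unique_families(pam, focal)
    venn_strains <- colnames(pam)[seq_len(min(4L, ncol(pam)))]
    list(n_core = length(core_families(pam)),
         venn = venn_partition(pam, venn_strains),
         n_unique = length(uniq),
         islands = detect_islands(uniq, gene_map, loc,
                                  config$island_min_genes, config$island_max_gap))
  })
  model_env <- new.env()
  if ("model" %in% stages) run_stage("model", function() {
    recipient <- read_model_json(p("model_recipient.json"))
    donor <- read_model_json(p("model_donor.json"))
    om <- utils::read.delim(p("ortholog_map.tsv"), stringsAsFactors = FALSE)
    map <- stats::setNames(om$recipient_gene, om$donor_gene)
    merged <- merge_pipeline(recipient, list(list(model = donor, ortholog_map = map)))
    assign("model", merged$model, envir = model_env)
    merged$report
  })
  if ("screen" %in% stages) run_stage("screen", function() {
    m <- if (exists("model", envir = model_env)) get("model", envir = model_env)
    else read_model_json(p("model_recipient.json"))
    panel <- grep("^EX_", names(m$reactions), value = TRUE)
    carbon_source_screen(m, medium_spec(carbon_exchange_ids = panel),
                         panel = setdiff(panel, m$objective),
                         uptake_rate = config$uptake_rate,
                         growth_epsilon = config$growth_epsilon)
  })
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d stage(s) completed (%d warning(s))\n",
              length(x$stages), length(x$warnings)))
  for (s in names(x$stages)) cat("  -", s, "\n")
  invisible(x)
}
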