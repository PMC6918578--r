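# Pipeline orchestration: configuration validation and report assembly.

CONFIG_SCHEMA <- list(
  model_path = "character",        # tabular model directory or SBML file
  model_format = "character",      # "tabular" or "sbml"
  synthetic = "logical",           # use the bundled core model
  methanol_uptake_cmol = "numeric",
  objective = "character",         # "growth", "TAG" or both
  pathway = "character",           # pathway names or "all"
  temperatures_c = "numeric",
  medium = "list",                 # concentrations (named), pH
  fasta = "character",             # protein sequences for the HPS stage
  identity_threshold = "numeric",
  seed = "numeric",
  stages = "character"             # subset of thermo, compare, hps
)

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected by name; type mismatches are reported before
#' any computation runs.
#'
#' @param config a named list, or the path of a YAML file holding one.
#' @return the validated config with defaults filled in.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  assert_that(is.list(config), "config must be a list or a YAML file path")
  unknown <- setdiff(names(config), names(CONFIG_SCHEMA))
  assert_that(length(unknown) == 0, "unknown config key(s): %s",
              paste(unknown, collapse = ", "))
  for (key in names(config)) {
    want <- CONFIG_SCHEMA[[key]]
    ok <- switch(want,
                 numeric = is.numeric(config[[key]]),
                 character = is.character(config[[key]]),
                 logical = is.logical(config[[key]]),
                 list = is.list(config[[key]]))
    assert_that(ok, "config key '%s' must be of type %s", key, want)
  }
  defaults <- list(
    synthetic = TRUE, model_format = "tabular",
    methanol_uptake_cmol = 6, objective = c("growth", "TAG"),
    pathway = "all", temperatures_c = c(28, 30, 50),
    medium = list(concentrations = c(methanol = 0.5, nad_ox = 1e-3,
                                     nad_red = 1e-3), pH = 7),
    identity_threshold = 0.9, seed = 1,
    stages = c("thermo", "compare", "hps"))
  out <- utils::modifyList(defaults, config)
  bad_stage <- setdiff(out$stages, c("thermo", "compare", "hps"))
  assert_that(length(bad_stage) == 0, "unknown stage(s): %s",
              paste(bad_stage, collapse = ", "))
  if (identical(out$pathway, "all")) out$pathway <- PATHWAY_NAMES
  bad_p <- setdiff(out$pathway, PATHWAY_NAMES)
  assert_that(length(bad_p) == 0, "unknown pathway(s): %s",
              paste(bad_p, collapse = ", "))
  out
}

#' Run the full evaluation pipeline
#'
#' Executes the configured stages -- thermodynamic equilibrium report,
#' pathway comparison, HPS-candidate clustering and tree -- and writes
#' tab-separated tables (plus a Newick tree) under `out_dir`. Deterministic
#' given the config and seed.
#'
#' @param config a [pipeline_config()] list (or raw list/YAML path).
#' @param out_dir output directory, created if needed.
#' @return named list of the result tables and output file paths.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("methylopath_")) {
  config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(files = character(0))
  tsv <- function(obj, name) {
    p <- file.path(out_dir, name)
    utils::write.table(format(obj, digits = 10), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$files <<- c(results$files, p)
    p
  }

  if ("thermo" %in% config$stages) {
    thermo <- thermo_report(temperatures_c = config$temperatures_c,
                            conditions_template = config$medium)
    results$thermo <- thermo
    tsv(thermo, "thermo_report.tsv")
  }

  if ("compare" %in% config$stages) {
    model <- if (isTRUE(config$synthetic) || is.null(config$model_path)) {
      generate_core_model(core_model_params(seed = config$seed))
    } else {
      read_model(config$model_path, config$model_format,
                 biomass_reaction_id = "BIOMASS", tag_reaction_id = "TAGS")
    }
    cmp <- compare_pathways(model, uptake = config$methanol_uptake_cmol,
                            pathways = config$pathway,
                            objectives = config$objective)
    results$comparison <- cmp
    tsv(cmp, "pathway_comparison.tsv")
  }

  if ("hps" %in% config$stages) {
    seqs <- if (!is.null(config$fasta)) {
      read_fasta(config$fasta)
    } else {
      generate_protein_family(family_params(seed = config$seed))$sequences
    }
    clusters <- cluster_by_identity(seqs, threshold = config$identity_threshold)
    results$clusters <- clusters
    tsv(clusters, "hps_clusters.tsv")
    reps <- seqs[unique(clusters$representative)]
    if (length(reps) >= 2) {
      tree <- nj_tree(identity_distances(reps))
      results$tree <- tree
      p <- file.path(out_dir, "hps_tree.nwk")
      write_newick(tree, p)
      results$files <- c(results$files, p)
    }
  }
  results$out_dir <- out_dir
  results
}
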