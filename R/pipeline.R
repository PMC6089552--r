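# cli_pipeline: end-to-end orchestration (simulate -> normalize -> call
# hits -> integrate targets -> enrich -> network -> report) driven by one
# validated config, with a machine-readable run summary.

RUN_CONFIG_KEYS <- c(
  "config_version", "seed", "out_dir", "log_level",
  "inputs", "simulate", "parameters"
)
RUN_PARAM_KEYS <- c(
  "plate_format", "span", "robust_iters", "k", "fold", "fold_only",
  "affinity_max_nm", "affinity_min_confidence", "interaction_min_score",
  "q_candidates", "q_terms", "ease", "lfc_min", "fdr_max",
  "ppi_score_min", "ppi_channels", "hit_group"
)
RUN_INPUT_KEYS <- c("wells_high", "wells_low", "affinity", "interaction",
                    "expression", "chip", "ppi", "annotations", "curated")

default_parameters <- function() {
  list(plate_format = 384, span = 0.5, robust_iters = 6, k = 3, fold = 2,
       fold_only = FALSE, affinity_max_nm = 1000, affinity_min_confidence = 4,
       interaction_min_score = 0.8, q_candidates = 0.05, q_terms = 0.01,
       ease = FALSE, lfc_min = 1, fdr_max = 0.01, ppi_score_min = 0.8,
       ppi_channels = "experimental", hit_group = "HIGH_SELECTIVE")
}

#' Build a validated pipeline run configuration
#'
#' @param out_dir output directory for all stage artifacts.
#' @param inputs named list of input paths (`wells_high`, `wells_low`,
#'   `affinity`, `interaction`, `expression`, `chip`, `ppi`, optional
#'   `annotations`, `curated`); ignored when `simulate` is given.
#' @param simulate optional [simulation_config()]; when present, stage 0
#'   generates all inputs into `out_dir/inputs`.
#' @param parameters named list overriding stage parameters (see
#'   `diffscreen:::default_parameters()` for names and defaults).
#' @param seed integer master seed.
#' @param log_level `"info"`, `"quiet"` or `"verbose"`.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(out_dir, inputs = NULL, simulate = NULL,
                       parameters = list(), seed = 1L, log_level = "info") {
  unknown <- setdiff(names(parameters), RUN_PARAM_KEYS)
  if (length(unknown))
    stop_schema("unknown parameter key(s): %s", paste(unknown, collapse = ", "))
  pars <- utils::modifyList(default_parameters(), parameters)
  if (pars$span <= 0 || pars$span > 1) stop_schema("span must lie in (0, 1]")
  if (pars$k <= 0 || pars$fold < 1) stop_schema("k must be > 0 and fold >= 1")
  for (qk in c("q_candidates", "q_terms", "fdr_max"))
    if (pars[[qk]] < 0 || pars[[qk]] > 1) stop_schema("%s must lie in [0, 1]", qk)
  if (!pars$hit_group %in% c("HIGH_SELECTIVE", "LOW_SELECTIVE",
                             "NONSELECTIVE_ACTIVE", "HIT_HIGH", "HIT_LOW"))
    stop_schema("invalid hit_group: %s", pars$hit_group)
  if (is.null(simulate)) {
    if (is.null(inputs)) stop_schema("either inputs or simulate must be given")
    unknown <- setdiff(names(inputs), RUN_INPUT_KEYS)
    if (length(unknown))
      stop_schema("unknown input key(s): %s", paste(unknown, collapse = ", "))
    need <- setdiff(RUN_INPUT_KEYS, c("annotations", "curated"))
    missing <- setdiff(need, names(inputs))
    if (length(missing))
      stop_schema("missing input path(s): %s", paste(missing, collapse = ", "))
    for (k in names(inputs))
      if (!file.exists(inputs[[k]]))
        stop_schema("input %s does not exist: %s", k, inputs[[k]])
  } else {
    stopifnot(inherits(simulate, "sim_config"))
  }
  cfg <- list(config_version = 1L, seed = as.integer(seed), out_dir = out_dir,
              log_level = log_level, inputs = inputs, simulate = simulate,
              parameters = pars)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The file must carry `config_version: 1`; unknown keys are rejected so
#' typos fail fast. A `simulate:` block holds [simulation_config()]
#' arguments; an `inputs:` block holds input paths (relative paths resolve
#' against the YAML file's directory).
#'
#' @param path path to the YAML file.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop_schema("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(y$config_version) || y$config_version != 1)
    stop_schema("config_version must be 1")
  base <- dirname(normalizePath(path))
  inputs <- y$inputs
  if (!is.null(inputs))
    inputs <- lapply(inputs, function(p)
      if (startsWith(p, "/")) p else file.path(base, p))
  sim <- if (!is.null(y$simulate)) do.call(simulation_config, y$simulate)
  out_dir <- y$out_dir %||% file.path(base, "diffscreen_out")
  if (!startsWith(out_dir, "/")) out_dir <- file.path(base, out_dir)
  run_config(out_dir = out_dir, inputs = inputs, simulate = sim,
             parameters = y$parameters %||% list(),
             seed = y$seed %||% 1L, log_level = y$log_level %||% "info")
}

pipe_log <- function(cfg, stage, msg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[diffscreen:%s] %s", stage, sprintf(msg, ...)))
}

#' Run the full differential-screen pipeline
#'
#' Stages, in dependency order: (0) simulate inputs if configured;
#' (1) read wells; (2) LOESS-log normalize; (3) call hits per condition and
#' classify selective groups; (4) filter and merge drug-target evidence,
#' summarize promiscuity; (5) candidate genes (exclusive + enriched) for
#' the configured hit group, plus term enrichment when an annotation table
#' is supplied; (6) regulation annotation, PPI filtering, network build and
#' export. Every stage writes its artifact under `out_dir` before the next
#' starts; a failure halts the pipeline, leaves a `.partial` marker and
#' records the failing stage in the summary. Rerunning with an identical
#' config reproduces byte-identical outputs.
#'
#' @param cfg a `run_config` (or path to a YAML config).
#' @return the run summary (also written to `out_dir/run_summary.json`),
#'   invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  p <- cfg$parameters
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  partial <- file.path(cfg$out_dir, ".partial")
  file.create(partial)
  summary <- list(parameters = p, seed = cfg$seed, stages = list(), counts = list())
  stage <- "init"
  result <- tryCatch({
    set.seed(cfg$seed)

    stage <- "simulate"
    if (!is.null(cfg$simulate)) {
      pipe_log(cfg, stage, "generating synthetic inputs (seed %d)", cfg$simulate$seed)
      in_dir <- file.path(cfg$out_dir, "inputs")
      simulate_inputs(cfg$simulate, in_dir)
      cfg$inputs <- list(
        wells_high = file.path(in_dir, "wells_high.tsv"),
        wells_low = file.path(in_dir, "wells_low.tsv"),
        affinity = file.path(in_dir, "targets_affinity.tsv"),
        interaction = file.path(in_dir, "targets_interaction.tsv"),
        expression = file.path(in_dir, "expression.tsv"),
        chip = file.path(in_dir, "chip_genes.txt"),
        ppi = file.path(in_dir, "ppi.tsv"))
      p$plate_format <- cfg$simulate$plate_format
      summary$stages[[stage]] <- "ok"
    } else summary$stages[[stage]] <- "skipped"

    stage <- "read_wells"
    wells <- rbind(read_well_table(cfg$inputs$wells_high, p$plate_format),
                   read_well_table(cfg$inputs$wells_low, p$plate_format))
    summary$counts$wells_read <- nrow(wells)
    pipe_log(cfg, stage, "%d wells read", nrow(wells))
    summary$stages[[stage]] <- "ok"

    stage <- "normalize"
    norm <- normalize_screen(wells, span = p$span, robust_iters = p$robust_iters)
    write_delim_table(
      transform(norm, well = well_label(row, col))[
        , c("screen_id", "plate_id", "well", "compound_id", "concentration",
            "condition", "raw_signal", "surface_fit", "corrected_signal",
            "viability", "log2_viability")],
      file.path(cfg$out_dir, "normalized.tsv"))
    n_plates <- length(unique(paste(norm$screen_id, norm$condition, norm$plate_id)))
    summary$counts$plates_normalized <- n_plates
    pipe_log(cfg, stage, "%d plates normalized", n_plates)
    summary$stages[[stage]] <- "ok"

    stage <- "call_hits"
    hits_high <- call_hits(norm, "HIGH", k = p$k)
    hits_low <- call_hits(norm, "LOW", k = p$k)
    smry <- summarize_viability(norm)
    calls <- classify_differential(hits_high, hits_low, smry,
                                   fold = p$fold, fold_only = p$fold_only)
    write_delim_table(calls, file.path(cfg$out_dir, "calls.tsv"))
    summary$counts$hits <- as.list(table(calls$group))
    pipe_log(cfg, stage, "groups: %s",
             paste(names(table(calls$group)), table(calls$group),
                   sep = "=", collapse = ", "))
    summary$stages[[stage]] <- "ok"

    stage <- "targets"
    aff <- filter_affinity_records(read_affinity_table(cfg$inputs$affinity),
                                   max_nm = p$affinity_max_nm,
                                   min_confidence = p$affinity_min_confidence)
    inter <- filter_interaction_records(
      read_interaction_table(cfg$inputs$interaction),
      min_score = p$interaction_min_score)
    curated <- if (!is.null(cfg$inputs$curated))
      read_delim_table(cfg$inputs$curated, c("compound_id", "gene"))
    tmap <- merge_target_sets(aff, inter, curated)
    write_delim_table(target_map_table(aff, inter, curated),
                      file.path(cfg$out_dir, "compound_targets.tsv"))
    hit_set <- switch(p$hit_group,
                      HIT_HIGH = hit_compounds(hits_high),
                      HIT_LOW = hit_compounds(hits_low),
                      calls$compound_id[calls$group == p$hit_group])
    prom <- promiscuity_summary(tmap, hit_set)
    summary$counts$compounds_with_targets <- length(tmap)
    summary$counts$promiscuity_median_hits <- prom$median_hits
    summary$counts$promiscuity_median_nonhits <- prom$median_nonhits
    pipe_log(cfg, stage, "%d compounds with targets; median targets %s (hits) vs %s (non-hits)",
             length(tmap), format(prom$median_hits), format(prom$median_nonhits))
    summary$stages[[stage]] <- "ok"

    stage <- "enrich"
    cand <- candidate_genes(tmap, hit_set, q_threshold = p$q_candidates)
    write_delim_table(cand, file.path(cfg$out_dir, "candidates.tsv"))
    summary$counts$candidate_genes <- sum(cand$candidate)
    pipe_log(cfg, stage, "%d candidate genes (%d exclusive, %d enriched)",
             sum(cand$candidate), sum(cand$exclusive), sum(cand$enriched))
    if (!is.null(cfg$inputs$annotations)) {
      ann <- read_delim_table(cfg$inputs$annotations, c("term", "gene"))
      terms <- term_enrichment(cand$gene[cand$candidate], ann,
                               background = sort(unique(unlist(tmap))),
                               q_threshold = p$q_terms, ease = p$ease)
      write_delim_table(terms, file.path(cfg$out_dir, "term_enrichment.tsv"))
      summary$counts$enriched_terms <- nrow(terms)
    }
    summary$stages[[stage]] <- "ok"

    stage <- "network"
    expr <- read_expression_table(cfg$inputs$expression)
    chip <- read_gene_list(cfg$inputs$chip)
    ppi <- filter_ppi(read_ppi_table(cfg$inputs$ppi),
                      score_min = p$ppi_score_min, channels = p$ppi_channels)
    reg <- annotate_regulation(cand$gene, expr,
                               lfc_min = p$lfc_min, fdr_max = p$fdr_max)
    net <- suppressWarnings(
      build_network(cand, tmap, hit_set, ppi, reg, chip))
    export_network(net, file.path(cfg$out_dir, "network"))
    summary$counts$network_nodes <- nrow(net$nodes)
    summary$counts$network_edges <- nrow(net$edges)
    pipe_log(cfg, stage, "network: %d nodes, %d edges",
             nrow(net$nodes), nrow(net$edges))
    summary$stages[[stage]] <- "ok"

    summary$status <- "ok"
    file.remove(partial)
    summary
  }, error = function(e) {
    summary$stages[[stage]] <- paste("error:", conditionMessage(e))
    summary$status <- "failed"
    summary$failed_stage <- stage
    summary
  })
  jsonlite::write_json(result, file.path(cfg$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (identical(result$status, "failed"))
    warning(sprintf("pipeline failed at stage '%s': %s", result$failed_stage,
                    result$stages[[result$failed_stage]]), call. = FALSE)
  invisible(result)
}
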