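# target_integration: evidence filtering and merging of drug-target tables
# (ChEMBL-like affinity records, STITCH-like interaction records) and
# compound-promiscuity summaries.

HUMAN_ORGANISMS <- c("Homo sapiens", "human", "9606")

#' Read a drug-target affinity table (ChEMBL-like export)
#'
#' Columns: `compound_id, gene, organism, measure_type, measure_value,
#' measure_unit, confidence, reference`.
#'
#' @param path path to the table.
#' @return data.frame of affinity records (unfiltered).
#' @export
read_affinity_table <- function(path) {
  df <- read_delim_table(path,
                         c("compound_id", "gene", "organism", "measure_type",
                           "measure_value", "measure_unit", "confidence",
                           "reference"),
                         numeric_cols = c("measure_value", "confidence"))
  for (cc in c("compound_id", "gene", "organism", "measure_type",
               "measure_unit", "reference"))
    df[[cc]] <- ifelse(is.na(df[[cc]]), "", as.character(df[[cc]]))
  df
}

#' Read a chemical-protein interaction table (STITCH-like export)
#'
#' Columns: `compound_id, gene, channel, score` with scores in \[0, 1\].
#'
#' @param path path to the table.
#' @return data.frame of interaction records (unfiltered).
#' @export
read_interaction_table <- function(path) {
  df <- read_delim_table(path, c("compound_id", "gene", "channel", "score"),
                         numeric_cols = "score")
  if (any(is.na(df$score) | df$score < 0 | df$score > 1))
    stop_schema("interaction scores must lie in [0, 1]")
  df
}

# nanomolar conversion factors for supported unit tokens
UNIT_TO_NM <- c(nM = 1, uM = 1e3, "µM" = 1e3, M = 1e9)

#' Filter drug-target affinity records
#'
#' Keeps a record only if it has a supporting reference, a non-empty target
#' gene, a present measurement value with a recognized unit, a measurement
#' type of IC50 or Ki, an affinity below 1 uM (strict), a human target
#' organism, and an assay confidence score of 4 or higher. Values are
#' normalized to nanomolar before thresholding; unrecognized unit tokens
#' count as missing measurement units and drop the record.
#'
#' @param records affinity records from [read_affinity_table()].
#' @param max_nm affinity ceiling in nM (strict `<`; default 1000 = 1 uM).
#' @param min_confidence minimum confidence score (default 4).
#' @param organisms accepted organism encodings.
#' @return the surviving records with `measure_value` in nM.
#' @export
filter_affinity_records <- function(records, max_nm = 1000,
                                    min_confidence = 4,
                                    organisms = HUMAN_ORGANISMS) {
  if (nrow(records) == 0L) return(records)
  unit_f <- UNIT_TO_NM[records$measure_unit]
  value_nm <- records$measure_value * unit_f
  keep <- !is.na(records$reference) & records$reference != "" &
    !is.na(records$gene) & records$gene != "" &
    !is.na(records$measure_value) &
    !is.na(unit_f) &
    toupper(records$measure_type) %in% c("IC50", "KI") &
    !is.na(value_nm) & value_nm < max_nm &
    records$organism %in% organisms &
    !is.na(records$confidence) & records$confidence >= min_confidence
  out <- records[keep, , drop = FALSE]
  out$measure_value <- value_nm[keep]
  out$measure_unit <- rep("nM", nrow(out))
  rownames(out) <- NULL
  out
}

#' Filter chemical-protein interaction records
#'
#' Keeps records from the `experimental` and `databases` evidence channels
#' with a confidence score of at least 0.8 (inclusive).
#'
#' @param records interaction records from [read_interaction_table()].
#' @param min_score minimum confidence (inclusive; default 0.8).
#' @param channels accepted evidence channels.
#' @return the surviving records.
#' @export
filter_interaction_records <- function(records, min_score = 0.8,
                                       channels = c("experimental", "databases")) {
  if (nrow(records) == 0L) return(records)
  keep <- records$channel %in% channels & records$score >= min_score
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge filtered target evidence into a compound-to-genes map
#'
#' Union of the target gene sets per compound across both evidence sources.
#' Compounds with no surviving record are absent from the map, which keeps
#' "no target information" distinct from "empty target set". An optional
#' manually curated table (columns `compound_id, gene`) is merged after
#' filtering, bypassing the filters.
#'
#' @param affinity filtered affinity records.
#' @param interaction filtered interaction records.
#' @param curated optional data.frame of curated compound-gene pairs.
#' @return named list: compound id -> sorted character vector of genes.
#' @export
merge_target_sets <- function(affinity, interaction, curated = NULL) {
  pairs <- rbind(
    if (nrow(affinity)) data.frame(compound_id = affinity$compound_id,
                                   gene = affinity$gene),
    if (nrow(interaction)) data.frame(compound_id = interaction$compound_id,
                                      gene = interaction$gene),
    if (!is.null(curated) && nrow(curated))
      data.frame(compound_id = curated$compound_id, gene = curated$gene)
  )
  if (is.null(pairs) || nrow(pairs) == 0L) return(structure(list(), names = character()))
  lapply(split(pairs$gene, pairs$compound_id), function(g) sort(unique(g)))
}

#' Target-map long form, with provenance
#'
#' @param affinity,interaction,curated as in [merge_target_sets()].
#' @return data.frame `compound_id, gene, provenance` where provenance is a
#'   comma-separated subset of `affinity, interaction, curated`.
#' @export
target_map_table <- function(affinity, interaction, curated = NULL) {
  tag <- function(df, p) if (!is.null(df) && nrow(df))
    data.frame(compound_id = df$compound_id, gene = df$gene, provenance = p)
  pairs <- rbind(tag(affinity, "affinity"), tag(interaction, "interaction"),
                 tag(curated, "curated"))
  if (is.null(pairs))
    return(data.frame(compound_id = character(), gene = character(),
                      provenance = character()))
  agg <- stats::aggregate(provenance ~ compound_id + gene, pairs,
                          function(p) paste(sort(unique(p)), collapse = ","))
  agg <- agg[order(agg$compound_id, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Compound promiscuity summary for hit and non-hit compounds
#'
#' Median number of annotated targets among hit compounds with at least one
#' known target, and among non-hit compounds with at least one known
#' target; compounds absent from the target map are excluded from both.
#' Full target-count histograms are returned alongside the medians.
#'
#' @param target_map compound-to-genes map from [merge_target_sets()].
#' @param hit_set character vector of hit compound ids.
#' @return list with `median_hits`, `median_nonhits`, `counts_hits`,
#'   `counts_nonhits` (named integer vectors of targets per compound) and
#'   `histogram` (table of target counts by group).
#' @export
promiscuity_summary <- function(target_map, hit_set) {
  if (length(target_map) == 0L) stop_schema("empty target map")
  n_targets <- vapply(target_map, length, 1L)
  hit_counts <- n_targets[names(n_targets) %in% hit_set]
  non_counts <- n_targets[!names(n_targets) %in% hit_set]
  if (length(hit_counts) == 0L)
    warning("no hit compound has target information; hit median undefined",
            call. = FALSE)
  list(median_hits = if (length(hit_counts)) stats::median(hit_counts) else NA_real_,
       median_nonhits = if (length(non_counts)) stats::median(non_counts) else NA_real_,
       counts_hits = hit_counts,
       counts_nonhits = non_counts,
       histogram = list(hits = table(hit_counts), nonhits = table(non_counts)))
}
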