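# network_builder: annotated compound-target network (compounds, candidate
# target genes, high-confidence PPI edges, expression-regulation and
# direct-binding annotations) with SIF / GraphML / table export.

#' Annotate genes with expression-regulation flags
#'
#' A gene is `UP` when `log2fc >= lfc_min` at `fdr <= fdr_max`, `DOWN` when
#' `log2fc <= -lfc_min` at `fdr <= fdr_max`, otherwise `NONE`. Genes absent
#' from the expression table are `NONE` with a missing log2fc.
#'
#' @param genes character vector of genes to annotate.
#' @param expression expression table from [read_expression_table()].
#' @param lfc_min minimum |log2 fold change| (default 1, i.e. two-fold on
#'   the linear scale).
#' @param fdr_max maximum adjusted p (default 0.01).
#' @return data.frame `gene, log2fc, fdr, regulated`.
#' @export
annotate_regulation <- function(genes, expression, lfc_min = 1, fdr_max = 0.01) {
  i <- match(genes, expression$gene)
  lfc <- expression$log2fc[i]
  fdr <- expression$fdr[i]
  reg <- rep("NONE", length(genes))
  ok <- !is.na(lfc) & !is.na(fdr) & fdr <= fdr_max
  reg[ok & lfc >= lfc_min] <- "UP"
  reg[ok & lfc <= -lfc_min] <- "DOWN"
  data.frame(gene = genes, log2fc = lfc, fdr = fdr, regulated = reg,
             stringsAsFactors = FALSE)
}

#' Filter protein-protein interaction edges
#'
#' Keeps edges from the accepted evidence channels with confidence strictly
#' above `score_min` (default 0.8, exclusive; experimentally verified
#' interactions only by default).
#'
#' @param edges PPI edges from [read_ppi_table()].
#' @param score_min minimum score, strict `>` (default 0.8).
#' @param channels accepted channels (default `"experimental"`).
#' @return the surviving edges.
#' @export
filter_ppi <- function(edges, score_min = 0.8, channels = "experimental") {
  out <- edges[edges$channel %in% channels & edges$score > score_min, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the annotated compound-target network
#'
#' Nodes are the hit compounds that target at least one candidate gene,
#' plus the candidate genes themselves (typed `TARGET_EXCLUSIVE`,
#' `TARGET_ENRICHED` or `TARGET_BOTH`). Edges are compound-to-candidate
#' target pairs from the target map plus filtered PPI edges between
#' included genes. Gene nodes carry the expression-regulation flag and a
#' direct-binding (ChIP-derived) flag. Candidate genes targeted by no hit
#' compound are excluded with a warning.
#'
#' @param candidates candidate table from [candidate_genes()] (or any
#'   data.frame with columns `gene, exclusive, enriched` for the candidate
#'   rows).
#' @param target_map compound-to-genes map.
#' @param hit_set character vector of hit compound ids.
#' @param ppi filtered PPI edges (see [filter_ppi()]).
#' @param regulation regulation table from [annotate_regulation()]; may be
#'   `NULL`.
#' @param direct_targets character vector of direct-binding genes; may be
#'   empty.
#' @return object of class `annotated_network`: list with data.frames
#'   `nodes` (`id, type, log2fc, regulated, direct_target`) and `edges`
#'   (`from, to, type, score`), both deterministically ordered.
#' @export
build_network <- function(candidates, target_map, hit_set, ppi,
                          regulation = NULL, direct_targets = character()) {
  cand <- candidates[candidates$exclusive | candidates$enriched, , drop = FALSE]
  cand_genes <- cand$gene
  # compound -> candidate-gene edges, hits only
  ct <- do.call(rbind, lapply(intersect(names(target_map), hit_set), function(cid) {
    g <- intersect(target_map[[cid]], cand_genes)
    if (length(g)) data.frame(from = cid, to = g, stringsAsFactors = FALSE)
  }))
  linked_genes <- if (is.null(ct)) character() else unique(ct$to)
  orphan <- setdiff(cand_genes, linked_genes)
  if (length(orphan) > 0L)
    warning(sprintf("%d candidate gene(s) targeted by no hit compound excluded: %s",
                    length(orphan), paste(utils::head(orphan, 5), collapse = ", ")),
            call. = FALSE)
  cand <- cand[cand$gene %in% linked_genes, , drop = FALSE]
  compounds <- if (is.null(ct)) character() else sort(unique(ct$from))

  gene_type <- ifelse(cand$exclusive & cand$enriched, "TARGET_BOTH",
                      ifelse(cand$exclusive, "TARGET_EXCLUSIVE",
                             "TARGET_ENRICHED"))
  reg <- if (is.null(regulation)) {
    data.frame(gene = cand$gene, log2fc = rep(NA_real_, nrow(cand)),
               regulated = rep("NONE", nrow(cand)))
  } else {
    regulation[match(cand$gene, regulation$gene), c("gene", "log2fc", "regulated")]
  }
  nodes <- rbind(
    data.frame(id = compounds, type = rep("COMPOUND", length(compounds)),
               log2fc = rep(NA_real_, length(compounds)),
               regulated = rep(NA_character_, length(compounds)),
               direct_target = rep(NA, length(compounds)),
               stringsAsFactors = FALSE),
    data.frame(id = cand$gene, type = gene_type, log2fc = reg$log2fc,
               regulated = ifelse(is.na(reg$regulated), "NONE", reg$regulated),
               direct_target = cand$gene %in% direct_targets,
               stringsAsFactors = FALSE))
  nodes <- nodes[order(nodes$type != "COMPOUND", nodes$id), , drop = FALSE]

  ppi_in <- ppi[ppi$gene_a %in% cand$gene & ppi$gene_b %in% cand$gene, ,
                drop = FALSE]
  edges <- rbind(
    if (!is.null(ct)) data.frame(from = ct$from, to = ct$to, type = "COMPOUND_TARGET",
                                 score = NA_real_, stringsAsFactors = FALSE),
    if (nrow(ppi_in)) data.frame(from = ppi_in$gene_a, to = ppi_in$gene_b,
                                 type = "PPI", score = ppi_in$score,
                                 stringsAsFactors = FALSE))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        type = character(), score = numeric())
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  stopifnot(all(edges$from %in% nodes$id), all(edges$to %in% nodes$id))
  structure(list(nodes = nodes, edges = edges), class = "annotated_network")
}

#' @export
print.annotated_network <- function(x, ...) {
  cat(sprintf("annotated_network: %d nodes (%d compounds, %d genes), %d edges (%d compound-target, %d PPI)\n",
              nrow(x$nodes), sum(x$nodes$type == "COMPOUND"),
              sum(x$nodes$type != "COMPOUND"), nrow(x$edges),
              sum(x$edges$type == "COMPOUND_TARGET"),
              sum(x$edges$type == "PPI")))
  invisible(x)
}

#' Export an annotated network
#'
#' Writes Cytoscape-openable files with deterministic node and edge
#' ordering: `<prefix>.sif` (interaction types `targets` / `ppi`),
#' `<prefix>.nodes.tsv` (node attribute table) and `<prefix>.graphml`.
#'
#' @param network an `annotated_network` from [build_network()].
#' @param out_prefix path prefix for the output files.
#' @param formats any of `"sif"`, `"graphml"`, `"tables"`.
#' @return invisibly, the vector of files written.
#' @export
export_network <- function(network, out_prefix,
                           formats = c("sif", "graphml", "tables")) {
  stopifnot(inherits(network, "annotated_network"))
  bad <- setdiff(formats, c("sif", "graphml", "tables"))
  if (length(bad)) stop_schema("unknown export format(s): %s",
                               paste(bad, collapse = ", "))
  files <- character()
  if ("sif" %in% formats) {
    f <- paste0(out_prefix, ".sif")
    rel <- ifelse(network$edges$type == "COMPOUND_TARGET", "targets", "ppi")
    writeLines(if (nrow(network$edges))
      paste(network$edges$from, rel, network$edges$to, sep = "\t")
      else character(), f)
    files <- c(files, f)
  }
  if ("tables" %in% formats) {
    f <- paste0(out_prefix, ".nodes.tsv")
    write_delim_table(network$nodes, f)
    f2 <- paste0(out_prefix, ".edges.tsv")
    write_delim_table(network$edges, f2)
    files <- c(files, f, f2)
  }
  if ("graphml" %in% formats) {
    f <- paste0(out_prefix, ".graphml")
    nd <- network$nodes
    nd$log2fc[is.na(nd$log2fc)] <- NaN
    nd$regulated[is.na(nd$regulated)] <- ""
    nd$direct_target <- !is.na(nd$direct_target) & nd$direct_target
    g <- igraph::graph_from_data_frame(
      d = if (nrow(network$edges)) transform(network$edges,
                                             score = ifelse(is.na(score), NaN, score))
      else network$edges,
      directed = FALSE, vertices = nd)
    igraph::write_graph(g, f, format = "graphml")
    files <- c(files, f)
  }
  invisible(files)
}

#' Re-read an exported network from its node/edge tables
#'
#' Round-trip counterpart of the `"tables"` export.
#'
#' @param out_prefix the prefix used in [export_network()].
#' @return an `annotated_network`.
#' @export
read_network_tables <- function(out_prefix) {
  nodes <- read_delim_table(paste0(out_prefix, ".nodes.tsv"),
                            c("id", "type", "log2fc", "regulated", "direct_target"),
                            numeric_cols = "log2fc")
  nodes$id <- as.character(nodes$id)
  nodes$direct_target <- as.logical(nodes$direct_target)
  nodes$regulated <- as.character(nodes$regulated)
  edges <- read_delim_table(paste0(out_prefix, ".edges.tsv"),
                            c("from", "to", "type", "score"),
                            numeric_cols = "score")
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  structure(list(nodes = nodes, edges = edges), class = "annotated_network")
}
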