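# enrichment: exclusive targets, Fisher/BH overrepresented targets, and
# functional term enrichment of the combined candidate list.

#' Fisher's exact test for a 2x2 table
#'
#' One-sided p (enrichment direction: the probability of observing `a` or
#' more successes in the first margin under the hypergeometric null) via
#' the hypergeometric tail, or the standard two-sided p by the
#' point-probability rule via [stats::fisher.test()].
#'
#' @param a,b,c,d nonnegative integer cell counts of the table
#'   \verb{ [a b; c d] }.
#' @param sided `"greater"` (one-sided enrichment, default) or
#'   `"two.sided"`.
#' @return p-value in \[0, 1\].
#' @export
#' @examples
#' fisher_exact(2, 0, 0, 2)        # 1/6
fisher_exact <- function(a, b, c, d, sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0))
    stop_schema("cell counts must be nonnegative")
  if (sum(counts) < 1) stop_schema("empty 2x2 table")
  if (sided == "greater") {
    # P(X >= a), X ~ Hypergeometric(white = a+b, black = c+d, drawn = a+c)
    stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
  } else {
    stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                       alternative = "two.sided")$p.value
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`q_(i) = min_{j >= i} m * p_(j) / j`, clipped to
#' 1, original order restored).
#'
#' @param p vector of p-values in \[0, 1\].
#' @return vector of q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p) | p < 0 | p > 1))
    stop_schema("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Exclusive and overrepresented target genes of a hit-compound set
#'
#' For every gene targeted by at least one compound in the background (the
#' compounds with target information), a 2x2 table is built: hit compounds
#' targeting / not targeting the gene versus non-hit compounds targeting /
#' not targeting it. A gene is *exclusive* when it is targeted by at least
#' one hit and by no non-hit; it is *enriched* when its one-sided Fisher
#' q-value (BH over all tested genes) is below `q_threshold` with odds
#' ratio above 1. The candidate list is the union of the two sets.
#'
#' @param target_map compound-to-genes map from [merge_target_sets()]; its
#'   names define the background.
#' @param hit_set character vector of hit compound ids.
#' @param q_threshold FDR threshold for the enriched set (default 0.05).
#' @param sided sidedness of the Fisher test.
#' @return data.frame with one row per tested gene: counts `a, b, c, d`,
#'   `odds_ratio`, `p`, `q`, flags `exclusive`, `enriched`, `candidate`.
#'   Candidate rows first, ordered by q.
#' @export
candidate_genes <- function(target_map, hit_set, q_threshold = 0.05,
                            sided = "greater") {
  background <- names(target_map)
  hit_bg <- intersect(background, hit_set)
  non_bg <- setdiff(background, hit_set)
  if (length(hit_bg) == 0L)
    warning("no hit compound in the target-annotated background; empty candidate list",
            call. = FALSE)
  genes <- sort(unique(unlist(target_map, use.names = FALSE)))
  if (length(genes) == 0L)
    return(data.frame(gene = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), odds_ratio = numeric(),
                      p = numeric(), q = numeric(), exclusive = logical(),
                      enriched = logical(), candidate = logical()))
  targets_of <- function(cids) table(factor(
    unlist(target_map[cids], use.names = FALSE), levels = genes))
  a <- as.integer(targets_of(hit_bg))
  c_ <- as.integer(targets_of(non_bg))
  b <- length(hit_bg) - a
  d <- length(non_bg) - c_
  p <- mapply(fisher_exact, a, b, c_, d, MoreArgs = list(sided = sided))
  q <- bh_adjust(p)
  odds <- ifelse(b * c_ == 0, ifelse(a * d == 0, NaN, Inf), (a * d) / (b * c_))
  exclusive <- c_ == 0L & a >= 1L
  enriched <- q < q_threshold & (a / pmax(a + b, 1)) > (c_ / pmax(c_ + d, 1))
  out <- data.frame(gene = genes, a = a, b = b, c = c_, d = d,
                    odds_ratio = odds, p = p, q = q, exclusive = exclusive,
                    enriched = enriched, candidate = exclusive | enriched,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$candidate, out$q, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Functional term enrichment of a gene list
#'
#' One-sided Fisher's exact test of the overlap between the gene list and
#' every annotation term against the background universe, with BH
#' correction across all tested terms. The EASE variant (one subtracted
#' from the overlap cell, a conservative score used by DAVID-style tools)
#' is available via `ease = TRUE`.
#'
#' @param genes character vector, the gene list (must be a subset of
#'   `background`).
#' @param annotations data.frame with columns `term, gene` (and optionally
#'   `name`).
#' @param background character vector, the gene universe.
#' @param q_threshold report terms with q below this (default 0.01).
#' @param ease use the EASE-adjusted overlap cell.
#' @return data.frame of enriched terms sorted by q then term size:
#'   `term, name, overlap, list_size, term_size, background_size, p, q`.
#' @export
term_enrichment <- function(genes, annotations, background,
                            q_threshold = 0.01, ease = FALSE) {
  genes <- unique(genes); background <- unique(background)
  missing <- setdiff(genes, background)
  if (length(missing) > 0L)
    stop_schema("gene(s) absent from background: %s",
                paste(utils::head(missing, 5), collapse = ", "))
  if (nrow(annotations) == 0L) stop_schema("empty annotation map")
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  terms <- split(unique(ann[, c("term", "gene")])$gene,
                 unique(ann[, c("term", "gene")])$term)
  term_name <- if ("name" %in% names(annotations)) {
    nm <- annotations$name[!duplicated(annotations$term)]
    names(nm) <- annotations$term[!duplicated(annotations$term)]
    nm
  } else NULL
  N <- length(background); L <- length(genes)
  rows <- lapply(names(terms), function(tm) {
    tg <- terms[[tm]]
    ov <- length(intersect(genes, tg))
    a <- if (ease) max(ov - 1L, 0L) else ov
    p <- fisher_exact(a, L - a, length(tg) - ov,
                      N - L - (length(tg) - ov), sided = "greater")
    data.frame(term = tm,
               name = if (is.null(term_name)) tm else unname(term_name[tm]),
               overlap = ov, list_size = L, term_size = length(tg),
               background_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[out$q < q_threshold, , drop = FALSE]
  out <- out[order(out$q, out$term_size, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
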