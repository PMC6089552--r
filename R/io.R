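# screen_io: readers and writers for every tabular artifact the pipeline
# touches. Tables are UTF-8, comma- or tab-delimited by extension
# (.csv -> comma, otherwise tab), decimal point only.

#' Convert 0-based (row, col) to a display well label
#'
#' Rows are lettered (A = 0) and columns are 1-based, the usual plate-reader
#' convention: well (0, 0) is "A1", well (1, 2) is "B3".
#'
#' @param row,col 0-based integer indices.
#' @return character vector of well labels.
#' @export
#' @examples
#' well_label(0, 0)   # "A1"
#' well_label(15, 23) # "P24"
well_label <- function(row, col) {
  stopifnot(all(row >= 0), all(col >= 0), all(row < 26))
  paste0(LETTERS[row + 1L], col + 1L)
}

#' Parse a display well label into 0-based (row, col)
#'
#' @param label character vector of labels such as "B3".
#' @param plate_format 384 or 96; labels outside the format's bounds are an
#'   error.
#' @return data.frame with integer columns `row` and `col` (0-based).
#' @export
parse_well_label <- function(label, plate_format = 384) {
  dims <- plate_dims(plate_format)
  ok <- grepl("^[A-Z][0-9]+$", label)
  if (!all(ok))
    stop_schema("malformed well label(s): %s",
                paste(utils::head(label[!ok], 5), collapse = ", "))
  row <- match(substr(label, 1, 1), LETTERS) - 1L
  col <- as.integer(sub("^[A-Z]", "", label)) - 1L
  bad <- row >= dims[["rows"]] | col >= dims[["cols"]] | col < 0L
  if (any(bad))
    stop_schema("well label(s) out of range for %s-well format: %s",
                plate_format, paste(utils::head(label[bad], 5), collapse = ", "))
  data.frame(row = row, col = col)
}

WELL_COLUMNS <- c("screen_id", "plate_id", "well", "compound_id",
                  "concentration_um", "condition", "raw_signal")

validate_wells <- function(wells, plate_format = 384) {
  dims <- plate_dims(plate_format)
  need <- c("screen_id", "plate_id", "row", "col", "compound_id",
            "concentration", "condition", "raw_signal")
  missing <- setdiff(need, names(wells))
  if (length(missing) > 0L)
    stop_schema("well collection missing column(s): %s",
                paste(missing, collapse = ", "))
  if (nrow(wells) == 0L) return(invisible(wells))
  if (!all(wells$condition %in% c("HIGH", "LOW")))
    stop_schema("condition must be HIGH or LOW")
  if (any(wells$row < 0L | wells$row >= dims[["rows"]] |
          wells$col < 0L | wells$col >= dims[["cols"]]))
    stop_schema("well position out of range for %s-well format", plate_format)
  key <- paste(wells$screen_id, wells$condition, wells$plate_id,
               wells$row, wells$col)
  if (anyDuplicated(key))
    stop_schema("duplicate well(s): %s",
                paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  if (any(!is.finite(wells$raw_signal) | wells$raw_signal < 0))
    stop_schema("raw_signal must be nonnegative and finite")
  if (any(wells$concentration < 0))
    stop_schema("concentration must be nonnegative")
  ctrl <- is_control(wells$compound_id)
  if (any(ctrl & wells$concentration != 0))
    stop_schema("control (%s) wells must have concentration 0", CONTROL_TOKEN)
  if (any(!ctrl & wells$concentration == 0))
    stop_schema("non-control wells must have positive concentration")
  invisible(wells)
}

#' Read a plate-well viability table
#'
#' Expected columns: `screen_id, plate_id, well, compound_id,
#' concentration_um, condition, raw_signal`. Display well labels ("B3") are
#' converted to 0-based `row`/`col`. Rows with a missing `raw_signal` are
#' rejected (dropped with a warning), never imputed, so normalization only
#' ever sees measured wells.
#'
#' @param path path to a `.csv` or `.tsv` file.
#' @param plate_format 384 (16 x 24) or 96 (8 x 12).
#' @return data.frame of well measurements with columns `screen_id,
#'   plate_id, row, col, compound_id, concentration, condition, raw_signal`.
#' @export
read_well_table <- function(path, plate_format = 384) {
  df <- read_delim_table(path, WELL_COLUMNS,
                         numeric_cols = c("concentration_um", "raw_signal"))
  if (nrow(df) == 0L) {
    out <- data.frame(screen_id = character(), plate_id = character(),
                      row = integer(), col = integer(),
                      compound_id = character(), concentration = numeric(),
                      condition = character(), raw_signal = numeric())
    return(out)
  }
  drop <- is.na(df$raw_signal)
  if (any(drop)) {
    warning(sprintf("%d row(s) with missing raw_signal rejected", sum(drop)),
            call. = FALSE)
    df <- df[!drop, , drop = FALSE]
  }
  rc <- parse_well_label(df$well, plate_format)
  out <- data.frame(screen_id = as.character(df$screen_id),
                    plate_id = as.character(df$plate_id),
                    row = rc$row, col = rc$col,
                    compound_id = as.character(df$compound_id),
                    concentration = df$concentration_um,
                    condition = as.character(df$condition),
                    raw_signal = df$raw_signal,
                    stringsAsFactors = FALSE)
  validate_wells(out, plate_format)
  out
}

#' Write a plate-well viability table
#'
#' The inverse of [read_well_table()]: rows are sorted deterministically by
#' (screen_id, condition, plate_id, row, col) and positions rendered as
#' display labels, so identical collections always serialize identically.
#'
#' @param wells well data.frame as returned by [read_well_table()] or
#'   [generate_screen()].
#' @param path output path (`.csv` or `.tsv`).
#' @param plate_format plate format used for validation.
#' @export
write_well_table <- function(wells, path, plate_format = 384) {
  validate_wells(wells, plate_format)
  if (nrow(wells) > 0L) {
    o <- order(wells$screen_id, wells$condition, wells$plate_id,
               wells$row, wells$col)
    wells <- wells[o, , drop = FALSE]
  }
  out <- data.frame(screen_id = wells$screen_id,
                    plate_id = wells$plate_id,
                    well = if (nrow(wells)) well_label(wells$row, wells$col) else character(),
                    compound_id = wells$compound_id,
                    concentration_um = wells$concentration,
                    condition = wells$condition,
                    raw_signal = wells$raw_signal)
  write_delim_table(out, path)
}

#' Read a differential-expression table
#'
#' Columns: `gene, log2fc, fdr` (one row per gene; `fdr` is a
#' multiple-testing adjusted p-value in \[0, 1\]).
#'
#' @param path path to the table.
#' @return validated data.frame.
#' @export
read_expression_table <- function(path) {
  df <- read_delim_table(path, c("gene", "log2fc", "fdr"),
                         numeric_cols = c("log2fc", "fdr"))
  df <- df[, c("gene", "log2fc", "fdr")]
  df$gene <- as.character(df$gene)
  if (any(is.na(df$gene) | df$gene == ""))
    stop_schema("expression table has empty gene symbol(s)")
  if (anyDuplicated(df$gene))
    stop_schema("duplicate gene(s) in expression table: %s",
                paste(utils::head(unique(df$gene[duplicated(df$gene)]), 5),
                      collapse = ", "))
  if (any(is.na(df$fdr) | df$fdr < 0 | df$fdr > 1))
    stop_schema("fdr values must lie in [0, 1]")
  df
}

#' Read a protein-protein interaction edge table
#'
#' Columns: `gene_a, gene_b, channel, score` with scores in \[0, 1\].
#' Edges are undirected: endpoints are stored in lexicographic order and
#' duplicate edges are collapsed keeping the maximum score (per channel).
#'
#' @param path path to the table.
#' @return data.frame of deduplicated undirected edges.
#' @export
read_ppi_table <- function(path) {
  df <- read_delim_table(path, c("gene_a", "gene_b", "channel", "score"),
                         numeric_cols = "score")
  df <- df[, c("gene_a", "gene_b", "channel", "score")]
  df$gene_a <- as.character(df$gene_a); df$gene_b <- as.character(df$gene_b)
  if (any(is.na(df$score) | df$score < 0 | df$score > 1))
    stop_schema("PPI scores must lie in [0, 1]")
  if (any(df$gene_a == df$gene_b))
    stop_schema("self-interaction edge(s) not allowed")
  swap <- df$gene_a > df$gene_b
  tmp <- df$gene_a[swap]; df$gene_a[swap] <- df$gene_b[swap]; df$gene_b[swap] <- tmp
  key <- paste(df$gene_a, df$gene_b, df$channel, sep = "\r")
  df <- df[order(key, -df$score), , drop = FALSE]
  df <- df[!duplicated(paste(df$gene_a, df$gene_b, df$channel, sep = "\r")), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a plain gene list (one symbol per line)
#'
#' @param path path to the file.
#' @return character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_schema("file not found: %s", path)
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  unique(x[x != ""])
}
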