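# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric mean
#'
#' @param x numeric vector, strictly positive.
#' @return the geometric mean of `x`.
#' @keywords internal
geomean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

stop_schema <- function(...) stop(sprintf(...), call. = FALSE)

# Deterministic 31-bit seed derived from a base seed and a character tag.
# Keeps independent streams per screen so adding screens does not reshuffle
# existing ones.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 2654435761 + h * 97) %% 2147483647L)
}

# Delimiter from file extension: .csv -> comma, anything else (.tsv/.txt) -> tab
delim_for <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

read_delim_table <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) stop_schema("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE,
                          colClasses = NA, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop_schema("missing required column(s): %s", paste(missing, collapse = ", "))
  for (cc in intersect(numeric_cols, names(df))) {
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  }
  df
}

write_delim_table <- function(df, path) {
  utils::write.table(df, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

# Reserved negative-control compound token (DMSO carrier wells).
CONTROL_TOKEN <- "DMSO"

#' Is a compound id the negative-control token?
#' @param compound_id character vector of compound identifiers.
#' @return logical vector.
#' @export
is_control <- function(compound_id) compound_id == CONTROL_TOKEN

plate_dims <- function(plate_format) {
  plate_format <- as.integer(plate_format)
  if (plate_format == 384L) c(rows = 16L, cols = 24L)
  else if (plate_format == 96L) c(rows = 8L, cols = 12L)
  else stop_schema("unsupported plate format: %s (use 384 or 96)", plate_format)
}
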