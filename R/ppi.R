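#' @title Scored protein-protein interaction tables
#' @description
#' PPI-based drill-down consumes an undirected table of gene pairs with a
#' STRING-style combined confidence score in `[0, 1]` and one or more
#' evidence-source labels per record (`GRID`, `DIP`, `KEGG`, `MINT`,
#' `PDB`).  Pairs are stored canonically (lexicographically ordered), at
#' most one record per unordered pair.
#' @name ppi-tables
NULL

PPI_SOURCES <- c("GRID", "DIP", "KEGG", "MINT", "PDB")

#' Construct a PPI table
#'
#' Scores given in the 0-999/1000 STRING convention (detected by any
#' score exceeding 1) are divided by 1000 and the rescaling is noted in
#' the table's `scaled` field.
#'
#' @param df data.frame with columns `gene_a`, `gene_b`, `score` and
#'   `sources` (either a list column of character vectors or a
#'   comma-separated character column)
#' @return an object of class `ppi_table`
#' @export
ppi_table <- function(df) {
  need <- c("gene_a", "gene_b", "score", "sources")
  if (!all(need %in% names(df)))
    kgml_abort(paste0("PPI table needs columns: ",
                      paste(need, collapse = ", ")), "kgml_input_error")
  df$gene_a <- as.character(df$gene_a)
  df$gene_b <- as.character(df$gene_b)
  if (any(df$gene_a == df$gene_b))
    kgml_abort("self-interactions (gene_a == gene_b) are not allowed",
               "kgml_input_error")
  if (!is.list(df$sources))
    df$sources <- strsplit(as.character(df$sources), ",", fixed = TRUE)
  df$sources <- lapply(df$sources, function(s) sort(trimws(s)))
  bad <- unique(setdiff(unlist(df$sources), PPI_SOURCES))
  if (length(bad))
    kgml_abort(paste0("unknown PPI evidence sources: ",
                      paste(bad, collapse = ", "), " (expected ",
                      paste(PPI_SOURCES, collapse = "/"), ")"),
               "kgml_input_error")
  df$score <- as.numeric(df$score)
  scaled <- FALSE
  if (length(df$score) && max(df$score, na.rm = TRUE) > 1) {
    df$score <- df$score / 1000  # STRING 0-999 convention
    scaled <- TRUE
  }
  if (any(is.na(df$score) | df$score < 0 | df$score > 1))
    kgml_abort("PPI scores must lie in [0, 1]", "kgml_input_error")
  swap <- df$gene_a > df$gene_b
  tmp <- df$gene_a[swap]
  df$gene_a[swap] <- df$gene_b[swap]
  df$gene_b[swap] <- tmp
  key <- paste(df$gene_a, df$gene_b, sep = "\r")
  if (anyDuplicated(key))
    kgml_abort(paste0("duplicate records for unordered pair(s): ",
                      paste(unique(sub("\r", " - ", key[duplicated(key)])),
                            collapse = ", ")), "kgml_input_error")
  rownames(df) <- NULL
  structure(list(interactions = df[need], scaled = scaled),
            class = "ppi_table")
}

#' @export
print.ppi_table <- function(x, ...) {
  cat(sprintf("<ppi_table> %d interactions%s\n", nrow(x$interactions),
              if (x$scaled) " (scores rescaled from 0-1000)" else ""))
  invisible(x)
}

#' Read a tab-delimited PPI table
#'
#' Expected layout: header `gene_a<TAB>gene_b<TAB>score<TAB>sources`,
#' sources comma-separated from `GRID`, `DIP`, `KEGG`, `MINT`, `PDB`.
#'
#' @param path PPI file
#' @return a `ppi_table`
#' @export
read_ppi_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ppi_table(df)
}

#' Write a PPI table as tab-delimited text
#' @param ppi a `ppi_table`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_ppi_table <- function(ppi, path) {
  df <- ppi$interactions
  df$sources <- vapply(df$sources, paste, character(1), collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# TRUE when the unordered pair {a, b} has a record with score >= threshold
# and at least one evidence source in `sources`.
ppi_supported <- function(ppi, a, b, threshold, sources) {
  ga <- min(a, b); gb <- max(a, b)
  df <- ppi$interactions
  hit <- which(df$gene_a == ga & df$gene_b == gb)
  if (!length(hit)) return(FALSE)
  df$score[hit] >= threshold &&
    length(intersect(df$sources[[hit]], sources)) > 0L
}
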