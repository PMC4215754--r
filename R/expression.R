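#' @title Gene-expression tables
#' @description
#' Tissue-specific tuning consumes a genes-by-tissues table of
#' non-negative expression values (a BioGPS-style atlas export, or any
#' user-supplied table in the same shape).  Internally the table is a
#' numeric matrix with KEGG gene ids as row names and tissue names as
#' column names; missing measurements are `NA`.
#' @name expression-tables
NULL

#' Construct an expression table
#'
#' @param values numeric matrix (genes x tissues) with gene ids as row
#'   names and tissue names as column names, or a data.frame of the same
#'   shape
#' @return an object of class `expression_table`
#' @export
expression_table <- function(values) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    kgml_abort("expression values must form a numeric matrix",
               "kgml_input_error")
  if (is.null(rownames(values)) || is.null(colnames(values)) ||
      !ncol(values))
    kgml_abort("expression table needs gene row names and at least one tissue column",
               "kgml_input_error")
  if (anyDuplicated(rownames(values)))
    kgml_abort(paste0("duplicate gene rows: ",
                      paste(unique(rownames(values)[duplicated(rownames(values))]),
                            collapse = ", ")), "kgml_input_error")
  if (anyDuplicated(colnames(values)))
    kgml_abort("duplicate tissue columns", "kgml_input_error")
  structure(list(values = values), class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d genes x %d tissues (%d missing values)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Tissue names of an expression table
#' @param table an `expression_table`
#' @return character vector
#' @export
expression_tissues <- function(table) colnames(table$values)

#' Gene ids of an expression table
#' @param table an `expression_table`
#' @return character vector
#' @export
expression_genes <- function(table) rownames(table$values)

#' Read a tab-delimited expression table
#'
#' Expected layout: header row `gene<TAB>tissue1<TAB>tissue2...`, one row
#' per gene, first column the KEGG gene id (`"hsa:1234"`).  Non-numeric or
#' blank cells become missing values.  An optional two-column
#' symbol-to-id mapping file translates symbol-keyed tables into the KEGG
#' namespace.
#'
#' @param path expression file
#' @param id_map optional path to a two-column tab-delimited file
#'   (`symbol<TAB>kegg_id`, no header) applied to the gene column
#' @return an `expression_table`
#' @export
read_expression_table <- function(path, id_map = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!nrow(df) || ncol(df) < 2L)
    kgml_abort("empty expression table: need at least one gene and one tissue",
               "kgml_input_error")
  genes <- as.character(df[[1L]])
  if (!is.null(id_map)) {
    map <- utils::read.delim(id_map, header = FALSE,
                             stringsAsFactors = FALSE)
    idx <- match(genes, map[[1L]])
    genes <- ifelse(is.na(idx), genes, map[[2L]][idx])
  }
  if (anyDuplicated(genes))
    kgml_abort(paste0("duplicate gene rows: ",
                      paste(unique(genes[duplicated(genes)]), collapse = ", ")),
               "kgml_input_error")
  vals <- vapply(df[-1L], function(col) suppressWarnings(as.numeric(col)),
                 numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(genes, colnames(df)[-1L]))
  expression_table(vals)
}

#' Write an expression table as tab-delimited text
#' @param table an `expression_table`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_expression_table <- function(table, path) {
  df <- data.frame(gene = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Nearest-rank percentile: the ceiling(p/100 * n)-th smallest value.
# Deterministic, no interpolation; p = 0 gives the minimum, p = 100 the
# maximum.
nearest_rank_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  x[[max(1L, ceiling(p / 100 * n))]]
}

#' Resolve the expression threshold of a tuning configuration
#'
#' In `absolute` mode the configured value is returned as-is.  In
#' `percentile` mode the nearest-rank percentile of the reference value
#' set is computed: the chosen tissue's column when `percentile_scope` is
#' `per_tissue`, or every value in the table when it is `whole_table`.
#' Missing values are ignored.
#'
#' @param table an `expression_table`
#' @param config a [tuning_config()]
#' @return the numeric threshold
#' @export
compute_threshold <- function(table, config) {
  if (config$threshold_mode == "absolute")
    return(config$threshold_value)
  vals <- if (config$percentile_scope == "per_tissue") {
    if (!config$tissue %in% expression_tissues(table))
      kgml_abort(sprintf("tissue '%s' not in table; available: %s",
                         config$tissue,
                         paste(expression_tissues(table), collapse = ", ")),
                 "kgml_input_error")
    table$values[, config$tissue]
  } else {
    as.vector(table$values)
  }
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    kgml_abort("no non-missing expression values to take a percentile of",
               "kgml_input_error")
  nearest_rank_percentile(vals, config$threshold_value)
}
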