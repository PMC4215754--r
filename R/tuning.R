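#' @title Context-specific pathway tuning
#' @description
#' KEGG maps are context-free abstractions: every paralog is drawn, every
#' gene is assumed expressed.  Tuning specialises a pathway to a
#' biological context.  Tissue-specific tuning keeps only the member
#' genes expressed at or above a threshold in a chosen tissue and drops
#' gene nodes left empty.  PPI-based drill-down expands each paralog
#' group node into single-gene nodes and keeps only those gene-pair edges
#' witnessed by a physical-interaction record at or above a confidence
#' score from chosen evidence sources.  Both operations are pure: the
#' input pathway is cloned with fresh entry/relation identifiers and
#' never modified.
#' @name tuning
NULL

#' Tuning configuration
#'
#' @param tissue tissue name for tissue-specific tuning (must match a
#'   column of the expression table)
#' @param threshold_mode `"percentile"` (default) or `"absolute"`
#' @param threshold_value percentile in `[0, 100]` (default 25, the
#'   conventional cutoff for calling a gene silent) or an absolute
#'   expression value
#' @param percentile_scope `"per_tissue"` (default; percentile of the
#'   chosen tissue's values) or `"whole_table"` (percentile over every
#'   value in the table)
#' @param ppi_score_threshold confidence score cutoff in `[0, 1]` for
#'   drill-down (default 0.8, a high-confidence STRING-style score)
#' @param ppi_sources evidence sources accepted during drill-down; subset
#'   of `GRID`, `DIP`, `KEGG`, `MINT`, `PDB` (default: all)
#' @param keep_missing keep genes absent from the expression table
#'   instead of treating them as below threshold (default `FALSE`)
#' @return an object of class `tuning_config`
#' @export
tuning_config <- function(tissue = NULL,
                          threshold_mode = c("percentile", "absolute"),
                          threshold_value = 25,
                          percentile_scope = c("per_tissue", "whole_table"),
                          ppi_score_threshold = 0.8,
                          ppi_sources = PPI_SOURCES,
                          keep_missing = FALSE) {
  threshold_mode <- match.arg(threshold_mode)
  percentile_scope <- match.arg(percentile_scope)
  if (threshold_mode == "percentile" &&
      (threshold_value < 0 || threshold_value > 100))
    kgml_abort("percentile threshold must lie in [0, 100]",
               "kgml_input_error")
  if (ppi_score_threshold < 0 || ppi_score_threshold > 1)
    kgml_abort("PPI score threshold must lie in [0, 1]", "kgml_input_error")
  ppi_sources <- unique(as.character(ppi_sources))
  bad <- setdiff(ppi_sources, PPI_SOURCES)
  if (length(bad))
    kgml_abort(paste0("unknown PPI sources: ", paste(bad, collapse = ", ")),
               "kgml_input_error")
  structure(list(
    tissue = tissue, threshold_mode = threshold_mode,
    threshold_value = threshold_value, percentile_scope = percentile_scope,
    ppi_score_threshold = ppi_score_threshold, ppi_sources = ppi_sources,
    keep_missing = isTRUE(keep_missing)
  ), class = "tuning_config")
}

tuning_report <- function(records = list(), ...) {
  structure(c(list(records = records), list(...)), class = "tuning_report")
}

#' @export
print.tuning_report <- function(x, ...) {
  kinds <- vapply(x$records, function(r) r$kind, character(1))
  cat(sprintf("<tuning_report> %d record(s)\n", length(kinds)))
  for (k in unique(kinds))
    cat(sprintf("  %s: %d\n", k, sum(kinds == k)))
  invisible(x)
}

# Renumber entries 1..n in document order, remapping relation endpoints,
# group components and compound-subtype values (which hold entry ids).
renumber_pathway <- function(pathway) {
  old_ids <- entry_ids(pathway)
  id_map <- stats::setNames(seq_along(old_ids), as.character(old_ids))
  entries <- lapply(pathway$entries, function(e) {
    e$id <- unname(id_map[[as.character(e$id)]])
    if (length(e$components))
      e$components <- sort(unname(id_map[as.character(e$components)]))
    e
  })
  relations <- lapply(pathway$relations, function(r) {
    r$entry1 <- unname(id_map[[as.character(r$entry1)]])
    r$entry2 <- unname(id_map[[as.character(r$entry2)]])
    r$subtypes <- lapply(r$subtypes, function(s) {
      if (s$name == "compound" && s$value %in% names(id_map))
        s$value <- as.character(id_map[[s$value]])
      s
    })
    r
  })
  kegg_pathway(pathway$name, pathway$org, pathway$number, pathway$title,
               entries, relations, pathway$extra)
}

#' Tissue-specific tuning of a pathway
#'
#' Clones the pathway, then filters each gene entry's member list to the
#' genes whose expression in the chosen tissue is at or above the
#' resolved threshold (see [compute_threshold()]).  An entry with at
#' least one expressed gene stays (with its member list filtered); a gene
#' entry left without expressed members is removed together with its
#' incident relations.  Entries of other types are always preserved,
#' except that a group entry reduced below two surviving components is
#' dropped as no longer a complex.  Genes absent from the table count as
#' below threshold (each is logged) unless `config$keep_missing` is set.
#' The output gets fresh sequential entry ids.
#'
#' @param pathway a valid `kegg_pathway`
#' @param table an [expression_table()]
#' @param config a [tuning_config()] with `tissue` set
#' @return list with elements `pathway` (the tuned clone) and `report`
#'   (`tuning_report` with fields `threshold`, `removed_genes`,
#'   `removed_entries`, `missing_genes`)
#' @export
tune_tissue <- function(pathway, table, config) {
  validate_pathway(pathway)
  if (is.null(config$tissue) ||
      !config$tissue %in% expression_tissues(table))
    kgml_abort(sprintf("tissue '%s' not in table; available: %s",
                       config$tissue %||% "<unset>",
                       paste(expression_tissues(table), collapse = ", ")),
               "kgml_input_error")
  threshold <- compute_threshold(table, config)
  genes_in_table <- expression_genes(table)

  records <- list()
  removed_genes <- character(0)
  missing_genes <- character(0)
  entries <- pathway$entries
  kept <- logical(length(entries))
  names(kept) <- names(entries)

  for (key in names(entries)) {
    e <- entries[[key]]
    if (e$type != "gene") { kept[[key]] <- TRUE; next }
    vals <- rep(NA_real_, length(e$names))
    present <- e$names %in% genes_in_table
    vals[present] <- table$values[e$names[present], config$tissue]
    miss <- e$names[!present]
    if (length(miss)) {
      missing_genes <- c(missing_genes, miss)
      for (g in miss)
        records[[length(records) + 1L]] <- new_record(
          "gene_missing_from_table", c(entry = e$id, gene = g))
    }
    survive <- !is.na(vals) & vals >= threshold
    if (config$keep_missing) survive <- survive | !present
    dropped <- e$names[!survive]
    if (length(dropped)) {
      removed_genes <- c(removed_genes, dropped)
      for (g in dropped)
        records[[length(records) + 1L]] <- new_record(
          "tissue_gene_removed",
          c(entry = e$id, gene = g, tissue = config$tissue))
    }
    if (any(survive)) {
      e$names <- e$names[survive]
      entries[[key]] <- e
      kept[[key]] <- TRUE
    }
  }

  # drop group entries whose complexes fell apart (fewer than 2 surviving
  # components); repeat for nested groups
  repeat {
    changed <- FALSE
    kept_ids <- entry_ids(pathway)[kept]
    for (key in names(entries)) {
      e <- entries[[key]]
      if (!kept[[key]] || e$type != "group") next
      surv <- intersect(e$components, kept_ids)
      if (length(surv) < 2L) {
        kept[[key]] <- FALSE
        changed <- TRUE
      } else if (length(surv) < length(e$components)) {
        entries[[key]]$components <- surv
      }
    }
    if (!changed) break
  }

  for (key in names(entries)[!kept]) {
    e <- pathway$entries[[key]]
    records[[length(records) + 1L]] <- new_record("tissue_entry_removed",
      c(entry = e$id, names = paste(e$names, collapse = " "),
        tissue = config$tissue))
  }
  removed_entry_ids <- entry_ids(pathway)[!kept]

  kept_ids <- entry_ids(pathway)[kept]
  relations <- Filter(function(r)
    r$entry1 %in% kept_ids && r$entry2 %in% kept_ids, pathway$relations)

  tuned <- kegg_pathway(pathway$name, pathway$org, pathway$number,
                        pathway$title, unname(entries[kept]), relations,
                        pathway$extra, validate = FALSE)
  tuned <- renumber_pathway(tuned)
  list(pathway = tuned,
       report = tuning_report(records, threshold = threshold,
                              tissue = config$tissue,
                              removed_genes = unique(removed_genes),
                              removed_entries = removed_entry_ids,
                              missing_genes = unique(missing_genes)))
}

#' PPI-based drill-down of paralog nodes
#'
#' Expands every gene entry into one node per member gene and rebuilds
#' the edges: a parent relation between two gene entries yields the edge
#' `u -> v` (direction inherited from the pathway) for exactly those
#' member pairs whose unordered pair has a PPI record with score at or
#' above `config$ppi_score_threshold` and at least one evidence source in
#' `config$ppi_sources`; relations touching a non-gene entry are fanned
#' out to all members without PPI filtering (interaction evidence is
#' undefined for compounds and maps).  Nodes duplicated across the map --
#' the same gene appearing in several entries -- are merged into one node
#' (graphics taken from the lowest original entry id), and gene nodes
#' left without any incident relation are removed.  Group entries must be
#' expanded first (see [process_group_nodes()]).
#'
#' @param pathway a valid `kegg_pathway` without group entries
#' @param ppi a [ppi_table()]
#' @param config a [tuning_config()]
#' @return list with elements `pathway` and `report` (`tuning_report`
#'   recording expansions, merges and removals)
#' @export
drill_down_ppi <- function(pathway, ppi, config) {
  validate_pathway(pathway)
  if (!length(config$ppi_sources))
    kgml_abort("ppi_sources must not be empty", "kgml_input_error")
  if (config$ppi_score_threshold < 0 || config$ppi_score_threshold > 1)
    kgml_abort("PPI score threshold must lie in [0, 1]", "kgml_input_error")
  if (length(entries_of_type(pathway, "group")))
    kgml_abort("pathway contains group entries; run process_group_nodes() before drill-down",
               "kgml_validation_error")

  records <- list()
  thr <- config$ppi_score_threshold
  src <- config$ppi_sources

  # prospective gene nodes: gene id -> parent entry ids (document order)
  gene_parents <- list()
  for (e in pathway$entries) {
    if (e$type != "gene") next
    members <- unique(e$names)
    records[[length(records) + 1L]] <- new_record("ppi_node_expanded",
      c(entry = e$id, members = length(members)))
    for (g in members)
      gene_parents[[g]] <- c(gene_parents[[g]], e$id)
  }

  # prospective edges keyed by endpoint: gene ids for gene nodes,
  # "#<old id>" for non-gene nodes
  node_key <- function(id) {
    e <- get_entry(pathway, id)
    if (e$type == "gene") e$names else paste0("#", id)
  }
  edges <- list()
  for (r in pathway$relations) {
    e1 <- get_entry(pathway, r$entry1)
    e2 <- get_entry(pathway, r$entry2)
    both_gene <- e1$type == "gene" && e2$type == "gene"
    for (u in node_key(r$entry1)) for (v in node_key(r$entry2)) {
      if (u == v) next
      if (both_gene && !ppi_supported(ppi, u, v, thr, src)) next
      rr <- r
      if (both_gene)
        rr$extra <- c(rr$extra[setdiff(names(rr$extra), "cyk_ppi")],
                      cyk_ppi = "supported")
      edges[[length(edges) + 1L]] <- list(src = u, dst = v, rel = rr)
    }
  }
  # merging duplicated nodes can make fanned-out edges coincide: collapse
  esig <- vapply(edges, function(ed) paste(ed$src, ed$dst, ed$rel$type,
    subtype_signature(ed$rel$subtypes), sep = "|"), character(1))
  if (anyDuplicated(esig)) {
    for (d in which(duplicated(esig)))
      records[[length(records) + 1L]] <- new_record(
        "duplicate_edge_collapsed",
        c(src = edges[[d]]$src, dst = edges[[d]]$dst))
    edges <- edges[!duplicated(esig)]
  }

  touched <- unique(unlist(lapply(edges, function(ed) c(ed$src, ed$dst))))
  isolated <- setdiff(names(gene_parents), touched)
  for (g in isolated)
    records[[length(records) + 1L]] <- new_record("ppi_isolated_removed",
      c(gene = g))

  # assemble entries: document order, gene children at their first
  # occurrence, attributes from the lowest parent entry id
  entries <- list()
  new_id <- 0L
  gene_new_id <- character(0)   # gene -> new id (as names)
  nongene_new_id <- character(0)
  emitted <- character(0)
  for (e in pathway$entries) {
    if (e$type != "gene") {
      new_id <- new_id + 1L
      ne <- e
      ne$id <- new_id
      nongene_new_id[[paste0("#", e$id)]] <- new_id
      entries[[length(entries) + 1L]] <- ne
      next
    }
    for (g in unique(e$names)) {
      if (g %in% emitted || g %in% isolated) next
      emitted <- c(emitted, g)
      parents <- sort(gene_parents[[g]])
      if (length(parents) > 1L)
        records[[length(records) + 1L]] <- new_record("ppi_nodes_merged",
          c(gene = g, copies = length(parents)))
      parent <- get_entry(pathway, min(parents))
      new_id <- new_id + 1L
      g_graphics <- parent$graphics
      g_graphics$label <- g
      ann <- parent$annotations
      ann["former_entry"] <- paste(parents, collapse = ",")
      entries[[length(entries) + 1L]] <- kegg_entry(
        id = new_id, names = g, type = "gene", link = parent$link,
        graphics = g_graphics, annotations = ann, extra = parent$extra)
      gene_new_id[[g]] <- new_id
    }
  }

  key_to_id <- c(gene_new_id, nongene_new_id)
  relations <- lapply(edges, function(ed) {
    rr <- ed$rel
    rr$entry1 <- as.integer(key_to_id[[ed$src]])
    rr$entry2 <- as.integer(key_to_id[[ed$dst]])
    rr$subtypes <- lapply(rr$subtypes, function(s) {
      k <- paste0("#", s$value)
      if (s$name == "compound" && k %in% names(nongene_new_id))
        s$value <- as.character(nongene_new_id[[k]])
      s
    })
    rr
  })

  tuned <- kegg_pathway(pathway$name, pathway$org, pathway$number,
                        pathway$title, entries, relations, pathway$extra)
  list(pathway = tuned,
       report = tuning_report(records,
                              isolated_removed = isolated,
                              n_edges = length(relations)))
}

#' Fine-tuned pathway: tissue-specific tuning followed by PPI drill-down
#'
#' @param pathway a valid `kegg_pathway` without group entries
#' @param table an [expression_table()]
#' @param ppi a [ppi_table()]
#' @param config a [tuning_config()]
#' @return list with elements `pathway` and `report` (records of both
#'   stages concatenated; the per-stage reports are kept under `stages`)
#' @export
tune_full <- function(pathway, table, ppi, config) {
  ts <- tune_tissue(pathway, table, config)
  dd <- drill_down_ppi(ts$pathway, ppi, config)
  list(pathway = dd$pathway,
       report = tuning_report(c(ts$report$records, dd$report$records),
                              stages = list(tissue = ts$report,
                                            ppi = dd$report)))
}
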