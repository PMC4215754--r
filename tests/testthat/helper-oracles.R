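# Shared helpers: tiny hand-built pathways and independent brute-force
# oracles that re-derive what the detectors/tuners should find.

expect_pathway_equal <- function(a, b) {
  expect_true(kgmltune:::pathway_equal(a, b))
}

# two genes joined by one activation relation, plus optional extras
tiny_pathway <- function() {
  kegg_pathway(
    name = "path:tst00001", org = "tst", number = "00001", title = "tiny",
    entries = list(
      kegg_entry(1, "hsa:10", "gene"),
      kegg_entry(2, "hsa:20", "gene")
    ),
    relations = list(
      kegg_relation(1, 2, "PPrel", list(kegg_subtype("activation", "-->")))
    ))
}

# brute-force PCP enumeration: all ordered relation pairs through a
# compound middle, written independently of detect_pcp_motifs()
bf_pcp <- function(p) {
  out <- list()
  for (r1 in p$relations) for (r2 in p$relations) {
    if (r1$entry2 != r2$entry1) next
    mid <- p$entries[[as.character(r1$entry2)]]
    a <- p$entries[[as.character(r1$entry1)]]
    b <- p$entries[[as.character(r2$entry2)]]
    if (mid$type != "compound") next
    if (a$type != "gene" || b$type != "gene") next
    if (a$id == b$id) next
    out[[length(out) + 1L]] <- c(a$id, mid$id, b$id)
  }
  if (!length(out)) return(matrix(integer(0), ncol = 3))
  unique(do.call(rbind, out))
}

# brute-force dead-end heuristic over binding-subtyped PPrel relations
bf_suspect_bindings <- function(p) {
  idx <- integer(0)
  for (i in seq_along(p$relations)) {
    r <- p$relations[[i]]
    if (r$type != "PPrel") next
    has_binding <- FALSE
    for (s in r$subtypes) if (s$name == "binding/association")
      has_binding <- TRUE
    if (!has_binding) next
    n_in <- 0L; n_out <- 0L
    for (j in seq_along(p$relations)) {
      if (j == i) next
      if (p$relations[[j]]$entry2 == r$entry1) n_in <- n_in + 1L
      if (p$relations[[j]]$entry1 == r$entry2) n_out <- n_out + 1L
    }
    if (n_in == 0L && n_out >= 1L) idx <- c(idx, i)
  }
  idx
}

# every gene-gene relation of a drill-down result must be witnessed by a
# parent relation and a qualifying PPI record
check_drilldown_witnesses <- function(parent, tuned, ppi, config) {
  parent_pairs <- lapply(parent$relations, function(r) {
    list(src = parent$entries[[as.character(r$entry1)]],
         dst = parent$entries[[as.character(r$entry2)]])
  })
  for (r in tuned$relations) {
    e1 <- tuned$entries[[as.character(r$entry1)]]
    e2 <- tuned$entries[[as.character(r$entry2)]]
    if (e1$type != "gene" || e2$type != "gene") next
    u <- e1$names; v <- e2$names
    witnessed <- any(vapply(parent_pairs, function(pp)
      pp$src$type == "gene" && pp$dst$type == "gene" &&
        u %in% pp$src$names && v %in% pp$dst$names, logical(1)))
    if (!witnessed) return(FALSE)
    if (!kgmltune:::ppi_supported(ppi, u, v, config$ppi_score_threshold,
                                  config$ppi_sources))
      return(FALSE)
  }
  TRUE
}

gene_entry_ids <- function(p) {
  ids <- entry_ids(p)
  ids[vapply(p$entries, function(e) e$type == "gene", logical(1))]
}

# unordered/ordered gene-level edge signatures of a pathway
gene_edge_signatures <- function(p) {
  sigs <- character(0)
  for (r in p$relations) {
    e1 <- p$entries[[as.character(r$entry1)]]
    e2 <- p$entries[[as.character(r$entry2)]]
    if (e1$type == "gene" && e2$type == "gene")
      sigs <- c(sigs, paste(paste(e1$names, collapse = ","),
                            paste(e2$names, collapse = ","), sep = "->"))
  }
  sigs
}
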