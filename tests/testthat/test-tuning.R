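test_that("expression tables read from delimited text, blanks become missing", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tliver\tbrain",
               "hsa:1\t5\t1",
               "hsa:2\t\t7"), f)
  tab <- read_expression_table(f)
  expect_equal(expression_tissues(tab), c("liver", "brain"))
  expect_equal(expression_genes(tab), c("hsa:1", "hsa:2"))
  expect_equal(tab$values["hsa:1", "liver"], 5)
  expect_true(is.na(tab$values["hsa:2", "liver"]))
  expect_equal(tab$values["hsa:2", "brain"], 7)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tliver", "hsa:1\t5", "hsa:1\t6"), dup)
  err <- tryCatch(read_expression_table(dup), error = function(e) e)
  expect_s3_class(err, "kgml_input_error")
  expect_match(conditionMessage(err), "hsa:1")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\tliver", empty)
  expect_error(read_expression_table(empty), class = "kgml_input_error")
})

test_that("generated expression tables round-trip through write/read", {
  ex <- make_expression_table(sprintf("hsa:%d", 1:12), c("T1", "T2"),
                              0.1, seed = 7)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(ex$table, f)
  back <- read_expression_table(f)
  expect_equal(back$values, ex$table$values)
})

test_that("nearest-rank percentile thresholds match hand computation", {
  tab <- expression_table(matrix(c(1, 2, 3, 4), 4, 1,
                                 dimnames = list(sprintf("g%d", 1:4), "t")))
  cfg <- function(p, scope = "per_tissue")
    tuning_config(tissue = "t", threshold_value = p,
                  percentile_scope = scope)
  expect_equal(compute_threshold(tab, cfg(25)), 1)   # ceiling(.25*4) = 1st
  expect_equal(compute_threshold(tab, cfg(50)), 2)
  expect_equal(compute_threshold(tab, cfg(0)), 1)    # minimum
  expect_equal(compute_threshold(tab, cfg(100)), 4)  # maximum
  expect_equal(compute_threshold(tab, cfg(25, "whole_table")), 1)
  abs_cfg <- tuning_config(tissue = "t", threshold_mode = "absolute",
                           threshold_value = 2.5)
  expect_equal(compute_threshold(tab, abs_cfg), 2.5)
})

mixed_entry_pathway <- function() {
  kegg_pathway(
    name = "path:tst00006", org = "tst", number = "00006", title = "mix",
    entries = list(
      kegg_entry(1, c("hsa:1", "hsa:2"), "gene"),   # g1 expressed, g2 silent
      kegg_entry(2, "hsa:3", "gene"),
      kegg_entry(3, "cpd:C00001", "compound")
    ),
    relations = list(
      kegg_relation(1, 2, "PPrel", list(kegg_subtype("activation", "-->"))),
      kegg_relation(2, 3, "PCrel", list(kegg_subtype("activation", "-->")))
    ))
}

test_that("tissue tuning filters member genes and drops emptied entries", {
  p <- mixed_entry_pathway()
  tab <- expression_table(matrix(c(10, 2, 1), 3, 1,
    dimnames = list(c("hsa:1", "hsa:2", "hsa:3"), "t")))
  cfg <- tuning_config(tissue = "t", threshold_mode = "absolute",
                       threshold_value = 5)
  res <- tune_tissue(p, tab, cfg)
  q <- res$pathway
  # entry 1 keeps only the expressed paralog; entry 2 is gone with its edges
  genes_left <- pathway_gene_ids(q)
  expect_equal(genes_left, "hsa:1")
  expect_equal(length(q$entries), 2)  # hsa:1 node + compound survives
  expect_length(q$relations, 0)
  expect_setequal(res$report$removed_genes, c("hsa:2", "hsa:3"))
  expect_equal(res$report$removed_entries, 2L)
  # the input pathway was not touched
  expect_pathway_equal(p, mixed_entry_pathway())
  # threshold at the column minimum removes nothing
  cfg0 <- tuning_config(tissue = "t", threshold_mode = "absolute",
                        threshold_value = 1)
  expect_setequal(pathway_gene_ids(tune_tissue(p, tab, cfg0)$pathway),
                  pathway_gene_ids(p))
  # unknown tissue names the available ones
  err <- tryCatch(tune_tissue(p, tab, tuning_config(tissue = "nope")),
                  error = function(e) e)
  expect_s3_class(err, "kgml_input_error")
  expect_match(conditionMessage(err), "t")
})

test_that("genes absent from the table are removed unless keep_missing", {
  p <- mixed_entry_pathway()
  tab <- expression_table(matrix(c(10, 10), 2, 1,
    dimnames = list(c("hsa:1", "hsa:2"), "t")))  # hsa:3 not measured
  cfg <- tuning_config(tissue = "t", threshold_mode = "absolute",
                       threshold_value = 5)
  res <- tune_tissue(p, tab, cfg)
  expect_false("hsa:3" %in% pathway_gene_ids(res$pathway))
  expect_equal(res$report$missing_genes, "hsa:3")
  kinds <- vapply(res$report$records, function(r) r$kind, character(1))
  expect_true("gene_missing_from_table" %in% kinds)
  keep <- tuning_config(tissue = "t", threshold_mode = "absolute",
                        threshold_value = 5, keep_missing = TRUE)
  expect_true("hsa:3" %in% pathway_gene_ids(tune_tissue(p, tab, keep)$pathway))
})

test_that("tissue-tuned gene sets shrink monotonically with the threshold", {
  fx <- make_synthetic_pathway(fixture_spec(
    n_gene_entries = 15, n_relations = 16, seed = 21))
  genes <- pathway_gene_ids(fx$pathway)
  ex <- make_expression_table(genes, "T1", 0.15, seed = 22)
  sets <- lapply(c(0, 25, 50, 75, 100), function(p) {
    cfg <- tuning_config(tissue = "T1", threshold_value = p)
    pathway_gene_ids(tune_tissue(fx$pathway, ex$table, cfg)$pathway)
  })
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  expect_true(all(sets[[1]] %in% genes))
})

drill_demo <- function() {
  # N1 = {a, b} -> N2 = {c}; PPI supports (a, c) at 0.9, (b, c) at 0.5
  p <- kegg_pathway(
    name = "path:tst00007", org = "tst", number = "00007", title = "dd",
    entries = list(
      kegg_entry(1, c("hsa:a", "hsa:b"), "gene"),
      kegg_entry(2, "hsa:c", "gene")
    ),
    relations = list(
      kegg_relation(1, 2, "PPrel", list(kegg_subtype("activation", "-->")))
    ))
  ppi <- ppi_table(data.frame(
    gene_a = c("hsa:a", "hsa:b"), gene_b = c("hsa:c", "hsa:c"),
    score = c(0.9, 0.5), sources = c("GRID,KEGG", "MINT"),
    stringsAsFactors = FALSE))
  list(p = p, ppi = ppi)
}

test_that("drill-down keeps only PPI-supported member pairs and prunes isolates", {
  d <- drill_demo()
  cfg <- tuning_config(ppi_score_threshold = 0.8)
  res <- drill_down_ppi(d$p, d$ppi, cfg)
  q <- res$pathway
  expect_setequal(pathway_gene_ids(q), c("hsa:a", "hsa:c"))  # b isolated
  expect_length(q$relations, 1)
  r <- q$relations[[1]]
  expect_equal(q$entries[[as.character(r$entry1)]]$names, "hsa:a")
  expect_equal(q$entries[[as.character(r$entry2)]]$names, "hsa:c")
  expect_equal(r$type, "PPrel")
  expect_equal(r$subtypes[[1]]$name, "activation")  # inherited
  expect_true("hsa:b" %in% res$report$isolated_removed)
  # lowering the threshold admits the 0.5-score pair as well
  res2 <- drill_down_ppi(d$p, d$ppi, tuning_config(ppi_score_threshold = 0.4))
  expect_setequal(pathway_gene_ids(res2$pathway),
                  c("hsa:a", "hsa:b", "hsa:c"))
  # source filtering: only MINT evidence supports (b, c)
  res3 <- drill_down_ppi(d$p, d$ppi,
    tuning_config(ppi_score_threshold = 0.4, ppi_sources = "MINT"))
  expect_setequal(pathway_gene_ids(res3$pathway), c("hsa:b", "hsa:c"))
  expect_error(drill_down_ppi(d$p, d$ppi,
    tuning_config(ppi_sources = character(0))), class = "kgml_input_error")
})

test_that("with permissive support the drill-down edge count is sum |N1|*|N2|", {
  fx <- make_synthetic_pathway(fixture_spec(
    n_gene_entries = 10, n_relations = 12, seed = 31))
  p <- fx$pathway
  ppi <- make_ppi_table(pathway_gene_ids(p), 1, score_tiers = 1, seed = 32)
  cfg <- tuning_config(ppi_score_threshold = 0)
  res <- drill_down_ppi(p, ppi$ppi, cfg)
  expected <- sum(vapply(p$relations, function(r) {
    length(p$entries[[as.character(r$entry1)]]$names) *
      length(p$entries[[as.character(r$entry2)]]$names)
  }, numeric(1)))
  expect_equal(length(res$pathway$relations), expected)
  expect_true(check_drilldown_witnesses(p, res$pathway, ppi$ppi, cfg))
})

test_that("every drill-down edge is witnessed and no gene node is isolated", {
  for (seed in c(5, 13)) {
    fx <- make_synthetic_pathway(fixture_spec(
      n_gene_entries = 14, n_relations = 16, seed = seed))
    genes <- pathway_gene_ids(fx$pathway)
    ppi <- make_ppi_table(genes, 0.5, score_tiers = c(0.5, 0.9),
                          seed = seed + 1)
    cfg <- tuning_config(ppi_score_threshold = 0.8)
    res <- drill_down_ppi(fx$pathway, ppi$ppi, cfg)
    expect_true(check_drilldown_witnesses(fx$pathway, res$pathway,
                                          ppi$ppi, cfg))
    touched <- unlist(lapply(res$pathway$relations,
                             function(r) c(r$entry1, r$entry2)))
    expect_true(all(gene_entry_ids(res$pathway) %in% touched))
  }
})

test_that("drill-down edge sets shrink with score and grow with sources", {
  fx <- make_synthetic_pathway(fixture_spec(
    n_gene_entries = 12, n_relations = 14, seed = 41))
  genes <- pathway_gene_ids(fx$pathway)
  ppi <- make_ppi_table(genes, 0.6, score_tiers = c(0.2, 0.5, 0.9),
                        seed = 42)
  esets <- lapply(c(0, 0.25, 0.5, 0.75, 1), function(s) {
    gene_edge_signatures(drill_down_ppi(fx$pathway, ppi$ppi,
      tuning_config(ppi_score_threshold = s))$pathway)
  })
  for (i in seq_len(length(esets) - 1))
    expect_true(all(esets[[i + 1]] %in% esets[[i]]))
  src_sets <- lapply(list("GRID", c("GRID", "DIP", "KEGG"),
                          kgmltune:::PPI_SOURCES), function(src) {
    gene_edge_signatures(drill_down_ppi(fx$pathway, ppi$ppi,
      tuning_config(ppi_score_threshold = 0.5, ppi_sources = src))$pathway)
  })
  expect_true(all(src_sets[[1]] %in% src_sets[[2]]))
  expect_true(all(src_sets[[2]] %in% src_sets[[3]]))
})

test_that("fine tuning composes the two stages; silent paralogs stay out", {
  # silent paralog b would be PPI-supported, but tissue tuning removes it
  d <- drill_demo()
  tab <- expression_table(matrix(c(10, 1, 10), 3, 1,
    dimnames = list(c("hsa:a", "hsa:b", "hsa:c"), "t")))
  cfg <- tuning_config(tissue = "t", threshold_mode = "absolute",
                       threshold_value = 5, ppi_score_threshold = 0.4)
  res <- tune_full(d$p, tab, d$ppi, cfg)
  expect_false("hsa:b" %in% pathway_gene_ids(res$pathway))
  expect_setequal(pathway_gene_ids(res$pathway), c("hsa:a", "hsa:c"))
  # equals manual composition
  manual <- drill_down_ppi(tune_tissue(d$p, tab, cfg)$pathway, d$ppi, cfg)
  expect_pathway_equal(res$pathway, manual$pathway)
  # fully permissive settings preserve the gene set
  fx <- make_synthetic_pathway(fixture_spec(
    n_gene_entries = 10, n_relations = 12, seed = 51))
  genes <- pathway_gene_ids(fx$pathway)
  ex <- make_expression_table(genes, "T1", 0, seed = 52)
  ppi <- make_ppi_table(genes, 1, score_tiers = 1, seed = 53)
  perm <- tuning_config(tissue = "T1", threshold_value = 0,
                        ppi_score_threshold = 0)
  res2 <- tune_full(fx$pathway, ex$table, ppi$ppi, perm)
  expect_setequal(pathway_gene_ids(res2$pathway), genes)
})

test_that("PPI tables normalise STRING-style scores and reject bad input", {
  df <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                   score = c(900, 450), sources = c("GRID", "PDB"),
                   stringsAsFactors = FALSE)
  ppi <- ppi_table(df)
  expect_true(ppi$scaled)
  expect_equal(sort(ppi$interactions$score), c(0.45, 0.9))
  expect_error(ppi_table(data.frame(gene_a = "a", gene_b = "a",
    score = 0.5, sources = "GRID")), class = "kgml_input_error")
  expect_error(ppi_table(data.frame(gene_a = c("a", "b"),
    gene_b = c("b", "a"), score = c(0.5, 0.6),
    sources = c("GRID", "GRID"))), class = "kgml_input_error")
  expect_error(ppi_table(data.frame(gene_a = "a", gene_b = "b",
    score = 0.5, sources = "WRONG")), class = "kgml_input_error")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ppi_table(ppi, f)
  back <- read_ppi_table(f)
  expect_equal(back$interactions$score, ppi$interactions$score)
  expect_equal(back$interactions$sources, ppi$interactions$sources)
})
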