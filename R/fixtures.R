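#' @title Synthetic fixture generators
#' @description
#' Deterministic generators for pathways, expression tables and PPI
#' tables with planted, counted motifs, so that every detector and tuner
#' has an exact ground truth without touching any external database.
#' Each generator runs one seeded pseudo-random stream local to the call
#' (the caller's RNG state is saved and restored) and returns both the
#' artifact and a `truth` list describing exactly what was planted.
#' Planted motifs are disjoint -- a relation participates in at most one
#' planted inconsistency -- so recovered counts are unambiguous.
#' @name fixtures
NULL

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification for a synthetic pathway fixture
#'
#' Counts are validated for feasibility: the gene entries are partitioned
#' into a signaling backbone (a chain plus random extra edges), one
#' dedicated terminal node per planted reversed binding, and the members
#' of planted group nodes, so every planted motif can be constructed
#' disjointly.
#'
#' @param n_gene_entries number of gene entries (backbone + terminals +
#'   group members)
#' @param genes_per_entry_range integer range for paralog count per entry
#' @param n_compound_entries number of compound entries (>=
#'   `n_pcp_motifs`)
#' @param n_relations number of backbone gene-gene relations (including
#'   the chain)
#' @param n_pcp_motifs planted protein-compound-protein motifs
#' @param n_reversed_bindings planted mis-directed binding relations
#' @param n_groups planted group (complex) nodes
#' @param group_size_range integer range for group component counts
#' @param n_duplicated_entries planted duplicated paralog entries (each
#'   adds two copies of a 3-gene entry plus two single-gene neighbours)
#' @param seed integer seed for the generator's local random stream
#' @return an object of class `fixture_spec`
#' @export
fixture_spec <- function(n_gene_entries = 20, genes_per_entry_range = c(1, 3),
                         n_compound_entries = 3, n_relations = 25,
                         n_pcp_motifs = 0, n_reversed_bindings = 0,
                         n_groups = 0, group_size_range = c(2, 3),
                         n_duplicated_entries = 0, seed = 1) {
  s <- structure(list(
    n_gene_entries = as.integer(n_gene_entries),
    genes_per_entry_range = as.integer(genes_per_entry_range),
    n_compound_entries = as.integer(n_compound_entries),
    n_relations = as.integer(n_relations),
    n_pcp_motifs = as.integer(n_pcp_motifs),
    n_reversed_bindings = as.integer(n_reversed_bindings),
    n_groups = as.integer(n_groups),
    group_size_range = as.integer(group_size_range),
    n_duplicated_entries = as.integer(n_duplicated_entries),
    seed = as.integer(seed)
  ), class = "fixture_spec")
  counts <- unlist(s[!names(s) %in% "seed"])
  if (any(counts < 0))
    kgml_abort("fixture counts must be non-negative", "kgml_input_error")
  if (s$n_compound_entries < s$n_pcp_motifs)
    kgml_abort(sprintf(
      "infeasible: %d PCP motifs need at least that many compound entries (have %d)",
      s$n_pcp_motifs, s$n_compound_entries), "kgml_input_error")
  max_members <- s$n_groups * max(s$group_size_range)
  n_chain_min <- s$n_gene_entries - s$n_reversed_bindings - max_members
  if (n_chain_min < max(2L, if (s$n_reversed_bindings > 0)
        s$n_reversed_bindings + 2L else 2L,
        if (s$n_pcp_motifs > 0) 2L else 0L))
    kgml_abort(sprintf(
      "infeasible: n_gene_entries=%d leaves too small a backbone after %d terminals and up to %d group members",
      s$n_gene_entries, s$n_reversed_bindings, max_members),
      "kgml_input_error")
  if (s$n_relations < n_chain_min - 1L + s$n_groups * 0L)
    kgml_abort(sprintf(
      "infeasible: n_relations=%d below the backbone chain length %d",
      s$n_relations, n_chain_min - 1L), "kgml_input_error")
  s
}

gene_pool_ids <- function(n) sprintf("hsa:%d", 1000L + seq_len(n))

#' Generate a synthetic KGML pathway with planted motifs
#'
#' Builds a signaling-style pathway: a chain backbone of gene entries
#' with activation/inhibition/phosphorylation relations, plus (per the
#' spec) planted PCP motifs (each through its own compound entry, with
#' exactly one upstream and one downstream protein), planted reversed
#' binding relations constructed to satisfy the dead-end heuristic
#' (terminal source with no other incoming edge, target inside the
#' cascade with another outgoing and another incoming edge), planted
#' group nodes with one incoming and one outgoing relation, and
#' duplicated paralog entries (two map positions sharing one 3-gene name
#' list, each wired to its own single-gene neighbour).  Backbone
#' relations never carry a binding/association subtype, so the planted
#' reversed bindings are exactly the detector's candidate set.
#'
#' @param spec a [fixture_spec()]
#' @return list with elements `pathway` and `truth`; `truth` records the
#'   planted PCP triples, reversed-binding endpoints, group ids and
#'   components, duplicated-entry details, per-entry gene lists, and
#'   total entry/relation counts
#' @export
make_synthetic_pathway <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, {
    group_sizes <- if (spec$n_groups > 0)
      sample(seq(spec$group_size_range[1L], spec$group_size_range[2L]),
             spec$n_groups, replace = TRUE) else integer(0)
    n_members <- sum(group_sizes)
    n_terminals <- spec$n_reversed_bindings
    n_chain <- spec$n_gene_entries - n_terminals - n_members
    if (n_chain < 2L)
      kgml_abort("infeasible: sampled group sizes leave no backbone",
                 "kgml_input_error")

    chain_ids <- seq_len(n_chain)
    member_ids <- if (n_members) n_chain + seq_len(n_members) else integer(0)
    terminal_ids <- if (n_terminals)
      n_chain + n_members + seq_len(n_terminals) else integer(0)
    compound_ids <- spec$n_gene_entries + seq_len(spec$n_compound_entries)
    group_ids <- if (spec$n_groups)
      spec$n_gene_entries + spec$n_compound_entries + seq_len(spec$n_groups)
      else integer(0)
    next_id <- spec$n_gene_entries + spec$n_compound_entries +
      spec$n_groups

    gene_counts <- sample(seq(spec$genes_per_entry_range[1L],
                              spec$genes_per_entry_range[2L]),
                          spec$n_gene_entries, replace = TRUE)
    pool <- gene_pool_ids(sum(gene_counts))
    genes_of <- split(pool, rep(seq_len(spec$n_gene_entries), gene_counts))

    place <- function(i) kegg_graphics(
      x = ((i - 1L) %% 12L) * 90L + 60L,
      y = ((i - 1L) %/% 12L) * 60L + 40L)
    entries <- list()
    for (i in seq_len(spec$n_gene_entries))
      entries[[length(entries) + 1L]] <- kegg_entry(
        i, genes_of[[i]], "gene", graphics = place(i))
    for (j in seq_along(compound_ids))
      entries[[length(entries) + 1L]] <- kegg_entry(
        compound_ids[j], sprintf("cpd:C%05d", j), "compound",
        graphics = kegg_graphics(x = j * 70L, y = 700L, shape = "circle",
                                 width = 8L, height = 8L))

    relations <- list()
    add_rel <- function(e1, e2, type, subtype_name, value = "-->") {
      relations[[length(relations) + 1L]] <<- kegg_relation(
        e1, e2, type, list(kegg_subtype(subtype_name, value)))
    }

    # backbone: chain plus random extra edges, never binding-subtyped
    backbone_subtypes <- c("activation", "inhibition", "phosphorylation")
    for (i in seq_len(n_chain - 1L))
      add_rel(chain_ids[i], chain_ids[i + 1L], "PPrel", "activation")
    existing <- paste(seq_len(n_chain - 1L), seq_len(n_chain - 1L) + 1L)
    n_extra <- spec$n_relations - (n_chain - 1L)
    guard <- 0L
    while (n_extra > 0L && guard < 10000L) {
      guard <- guard + 1L
      ab <- sample(chain_ids, 2L)
      key <- paste(ab[1L], ab[2L])
      if (key %in% existing) next
      existing <- c(existing, key)
      add_rel(ab[1L], ab[2L], "PPrel", sample(backbone_subtypes, 1L))
      n_extra <- n_extra - 1L
    }

    # PCP motifs: one compound each, one upstream and one downstream gene
    pcp <- data.frame(upstream = integer(0), compound = integer(0),
                      downstream = integer(0))
    for (k in seq_len(spec$n_pcp_motifs)) {
      ab <- sample(chain_ids, 2L)
      cmp <- compound_ids[k]
      add_rel(ab[1L], cmp, "PCrel", "activation")
      add_rel(cmp, ab[2L], "PCrel", "activation")
      pcp <- rbind(pcp, data.frame(upstream = ab[1L], compound = cmp,
                                   downstream = ab[2L]))
    }

    # reversed bindings: terminal -> mid-chain hub (hub has another
    # incoming and another outgoing edge by chain construction)
    reversed <- data.frame(entry1 = integer(0), entry2 = integer(0))
    if (n_terminals) {
      hubs <- sample(chain_ids[-c(1L, n_chain)], n_terminals)
      for (k in seq_len(n_terminals)) {
        add_rel(terminal_ids[k], hubs[k], "PPrel", "binding/association",
                "---")
        reversed <- rbind(reversed, data.frame(entry1 = terminal_ids[k],
                                               entry2 = hubs[k]))
      }
    }

    # groups: dedicated member entries; one incoming and one outgoing
    # relation so expanded members keep an incoming edge
    groups <- list()
    mcursor <- 0L
    for (k in seq_len(spec$n_groups)) {
      comps <- member_ids[mcursor + seq_len(group_sizes[k])]
      mcursor <- mcursor + group_sizes[k]
      gid <- group_ids[k]
      entries[[length(entries) + 1L]] <- kegg_entry(
        gid, "undefined", "group", graphics = place(gid),
        components = comps)
      xy <- sample(chain_ids, 2L)
      add_rel(xy[1L], gid, "PPrel", "activation")
      add_rel(gid, xy[2L], "PPrel", "phosphorylation")
      groups[[k]] <- list(id = gid, components = comps, incident = 2L)
    }

    # duplicated paralog entries: two copies of one 3-gene entry, each
    # fed by its own single-gene neighbour
    duplicated_entries <- list()
    for (k in seq_len(spec$n_duplicated_entries)) {
      vgenes <- sprintf("hsa:%d", 9000L + (k - 1L) * 3L + 1:3)
      ngenes <- sprintf("hsa:%d", 9500L + (k - 1L) * 2L + 1:2)
      copy1 <- next_id + 1L; copy2 <- next_id + 2L
      na <- next_id + 3L; nb <- next_id + 4L
      next_id <- next_id + 4L
      entries[[length(entries) + 1L]] <- kegg_entry(
        copy1, vgenes, "gene", graphics = place(copy1))
      entries[[length(entries) + 1L]] <- kegg_entry(
        copy2, vgenes, "gene", graphics = place(copy2))
      entries[[length(entries) + 1L]] <- kegg_entry(
        na, ngenes[1L], "gene", graphics = place(na))
      entries[[length(entries) + 1L]] <- kegg_entry(
        nb, ngenes[2L], "gene", graphics = place(nb))
      add_rel(na, copy1, "PPrel", "activation")
      add_rel(nb, copy2, "PPrel", "activation")
      duplicated_entries[[k]] <- list(
        genes = vgenes, entry_ids = c(copy1, copy2),
        neighbor_genes = ngenes, neighbor_ids = c(na, nb))
    }

    pathway <- kegg_pathway(
      name = sprintf("path:syn%05d", spec$seed), org = "syn",
      number = sprintf("%05d", spec$seed),
      title = "Synthetic signaling pathway fixture",
      entries = entries, relations = relations)

    truth <- list(
      pcp_motifs = pcp, reversed_bindings = reversed, groups = groups,
      duplicated_entries = duplicated_entries,
      genes_of = genes_of,
      chain_ids = chain_ids, terminal_ids = terminal_ids,
      compound_ids = compound_ids, group_ids = group_ids,
      n_entries = length(entries), n_relations = length(relations))
    list(pathway = pathway, truth = truth)
  })
}

#' Generate a synthetic expression table with controlled silent genes
#'
#' Per tissue, a chosen fraction of genes (optionally forced via
#' `silent_genes`) is silent.  Values are constructed so the 25th
#' nearest-rank percentile cleanly separates the classes: silent genes
#' score strictly below it and expressed genes at or above it, both per
#' tissue and over the whole table -- provided each tissue's silent
#' fraction stays below 0.25 (validated).  Expressed values sit on a
#' plateau at 10 up to the percentile rank, with the remainder drawn
#' uniformly above it.
#'
#' @param genes character vector of KEGG gene ids
#' @param tissues character vector of tissue names
#' @param silent_fraction_per_tissue single fraction or named vector (one
#'   entry per tissue) in `[0, 0.25)`
#' @param seed integer seed
#' @param silent_genes optional named list (tissue -> character vector)
#'   of genes forced silent, counted inside the silent fraction
#' @return list with elements `table` (an [expression_table()]) and
#'   `truth` (field `silent`: named list of per-tissue silent gene sets)
#' @export
make_expression_table <- function(genes, tissues,
                                  silent_fraction_per_tissue = 0.1,
                                  seed = 1, silent_genes = NULL) {
  if (any(silent_fraction_per_tissue < 0 | silent_fraction_per_tissue > 1))
    kgml_abort("silent fractions must lie in [0, 1]", "kgml_input_error")
  frac <- silent_fraction_per_tissue
  if (length(frac) == 1L)
    frac <- stats::setNames(rep(frac, length(tissues)), tissues)
  if (any(frac >= 0.25))
    kgml_abort("silent fractions must stay below 0.25 so the 25th percentile separates silent from expressed genes",
               "kgml_input_error")
  n <- length(genes)
  with_local_seed(seed, {
    vals <- matrix(NA_real_, n, length(tissues),
                   dimnames = list(genes, tissues))
    silent <- list()
    rank25 <- ceiling(0.25 * n)
    for (t in tissues) {
      forced <- intersect(silent_genes[[t]] %||% character(0), genes)
      n_silent <- max(round(frac[[t]] * n), length(forced))
      extra <- sample(setdiff(genes, forced),
                      max(0L, n_silent - length(forced)))
      sil <- sort(c(forced, extra))
      silent[[t]] <- sil
      expressed <- setdiff(genes, sil)
      # plateau at 10 through the percentile rank, tail above it
      n_floor <- min(length(expressed), max(1L, rank25 - length(sil)))
      v <- stats::setNames(rep(NA_real_, n), genes)
      v[sil] <- stats::runif(length(sil), 0.01, 0.9)
      if (length(expressed)) {
        floor_genes <- expressed[seq_len(n_floor)]
        v[floor_genes] <- 10
        rest <- setdiff(expressed, floor_genes)
        v[rest] <- stats::runif(length(rest), 10.5, 100)
      }
      vals[, t] <- v
    }
    list(table = expression_table(vals), truth = list(silent = silent))
  })
}

#' Generate a synthetic scored PPI table
#'
#' A chosen fraction of all unordered gene pairs is supported; each
#' supported pair gets one of the configured score tiers and a random
#' non-empty subset of the evidence sources.
#'
#' @param genes character vector of gene ids (length >= 2)
#' @param supported_pair_fraction fraction of all unordered pairs that
#'   receive a record, in `[0, 1]`
#' @param score_tiers numeric vector of tier scores in `[0, 1]`
#' @param sources evidence source labels to draw from
#' @param seed integer seed
#' @return list with elements `ppi` (a [ppi_table()]) and `truth` (field
#'   `pairs_at_or_above`: per tier, the data.frame of supported pairs
#'   with score at or above that tier)
#' @export
make_ppi_table <- function(genes, supported_pair_fraction = 0.5,
                           score_tiers = c(0.5, 0.9),
                           sources = PPI_SOURCES, seed = 1) {
  if (length(genes) < 2L)
    kgml_abort("need at least two genes for a PPI table",
               "kgml_input_error")
  if (supported_pair_fraction < 0 || supported_pair_fraction > 1)
    kgml_abort("supported_pair_fraction must lie in [0, 1]",
               "kgml_input_error")
  if (any(score_tiers < 0 | score_tiers > 1))
    kgml_abort("score tiers must lie in [0, 1]", "kgml_input_error")
  with_local_seed(seed, {
    pairs <- t(utils::combn(sort(genes), 2L))
    n_sup <- round(supported_pair_fraction * nrow(pairs))
    idx <- sort(sample(nrow(pairs), n_sup))
    df <- data.frame(gene_a = pairs[idx, 1L], gene_b = pairs[idx, 2L],
                     score = if (n_sup) sample(score_tiers, n_sup,
                                               replace = TRUE) else numeric(0),
                     stringsAsFactors = FALSE)
    df$sources <- lapply(seq_len(n_sup), function(i)
      sort(sample(sources, sample(length(sources), 1L))))
    ppi <- ppi_table(df)
    truth <- list(pairs_at_or_above = lapply(
      stats::setNames(score_tiers, as.character(score_tiers)),
      function(tier) ppi$interactions[ppi$interactions$score >= tier,
                                      c("gene_a", "gene_b")]))
    list(ppi = ppi, truth = truth)
  })
}
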