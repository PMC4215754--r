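#' @title Inconsistency detection and correction
#' @description
#' KEGG signaling maps carry recurrent KGML inconsistencies that break
#' automated network analysis: protein interactions drawn through an
#' intermediate compound node (PCP motifs) so the protein-protein edge is
#' absent; binding/association edges pointing against the signal flow; and
#' protein-complex `group` nodes whose members are invisible to edge-level
#' algorithms.  This module detects each case and applies a correction,
#' emitting exactly one log record per mutation so every change to the
#' pathway is accounted for.  Detection and mutation are separated
#' (computer-assisted rather than blindly automatic): the `detect_*`
#' functions return candidates, the `apply_*` functions accept only
#' candidates from that set, and [correct_all()] offers a `report-only`
#' mode that mutates nothing.
#' @name corrections
NULL

CORRECTION_KINDS <- c("pcp_edge_added", "binding_reversed",
                      "group_processed", "duplicate_relation_collapsed")

new_record <- function(kind, details) {
  list(kind = kind, details = details, timestamp = Sys.time())
}

#' Bundle correction records into a report
#' @param records list of internal record objects
#' @return an object of class `correction_report`
#' @keywords internal
correction_report <- function(records = list()) {
  structure(list(records = records), class = "correction_report")
}

merge_reports <- function(...) {
  correction_report(do.call(c, lapply(list(...), function(r) r$records)))
}

#' Per-kind counts of a correction report
#' @param report a `correction_report`
#' @return named integer vector over the four correction kinds
#' @export
report_counts <- function(report) {
  kinds <- vapply(report$records, function(r) r$kind, character(1))
  vapply(stats::setNames(CORRECTION_KINDS, CORRECTION_KINDS),
         function(k) sum(kinds == k), integer(1))
}

#' @export
print.correction_report <- function(x, ...) {
  counts <- report_counts(x)
  cat(sprintf("<correction_report> %d record(s)\n", length(x$records)))
  for (k in names(counts))
    if (counts[[k]] > 0) cat(sprintf("  %s: %d\n", k, counts[[k]]))
  invisible(x)
}

#' Detect protein-compound-protein (PCP) motifs
#'
#' A PCP motif is a length-2 path gene -> compound -> gene: a protein
#' interaction that KGML draws through the mediating compound, leaving the
#' direct protein-protein edge absent.  Enumeration is exhaustive: every
#' triple `(A, c, B)` with `c` a compound entry, relations `A -> c` and
#' `c -> B` present, `A != B`, and both `A` and `B` gene entries.
#'
#' @param pathway a valid `kegg_pathway`
#' @return data.frame with integer columns `upstream`, `compound`,
#'   `downstream`, ordered by compound, upstream, downstream id
#' @export
detect_pcp_motifs <- function(pathway) {
  validate_pathway(pathway)
  out <- list()
  type_of <- function(id) get_entry(pathway, id)$type
  for (ce in entries_of_type(pathway, "compound")) {
    ups <- unique(vapply(Filter(function(r) r$entry2 == ce$id,
                                pathway$relations),
                         function(r) r$entry1, integer(1)))
    downs <- unique(vapply(Filter(function(r) r$entry1 == ce$id,
                                  pathway$relations),
                           function(r) r$entry2, integer(1)))
    ups <- sort(Filter(function(id) type_of(id) == "gene", ups))
    downs <- sort(Filter(function(id) type_of(id) == "gene", downs))
    for (a in ups) for (b in downs) if (a != b)
      out[[length(out) + 1L]] <- c(upstream = a, compound = ce$id,
                                   downstream = b)
  }
  if (!length(out))
    return(data.frame(upstream = integer(0), compound = integer(0),
                      downstream = integer(0)))
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$compound, df$upstream, df$downstream), , drop = FALSE]
}

motif_key <- function(df) paste(df$upstream, df$compound, df$downstream)

# first relation a -> b, or NULL
find_relation <- function(pathway, a, b) {
  for (r in pathway$relations)
    if (r$entry1 == a && r$entry2 == b) return(r)
  NULL
}

#' Add direct protein-protein edges for PCP motifs
#'
#' For each motif `(A, c, B)` a new `PPrel` relation `A -> B` is added
#' carrying a `compound` subtype whose value is the mediating compound's
#' entry id, plus any other subtypes of the original `A -> c` relation.
#' The original protein-compound relations and the compound entry are
#' retained -- the correction overlays the missing edge on the intact map.
#' Idempotent: a motif whose direct edge already exists adds nothing.
#'
#' @param pathway a valid `kegg_pathway`
#' @param motifs subset of [detect_pcp_motifs()] output (default: all
#'   detected motifs); rows not in the detected set raise a precondition
#'   error
#' @return list with elements `pathway` (corrected) and `report`
#'   (`correction_report`, one `pcp_edge_added` record per added edge)
#' @export
apply_pcp_correction <- function(pathway, motifs = NULL) {
  detected <- detect_pcp_motifs(pathway)
  if (is.null(motifs)) motifs <- detected
  if (nrow(motifs)) {
    bad <- !(motif_key(motifs) %in% motif_key(detected))
    if (any(bad))
      kgml_abort(paste0("motifs not present in pathway: ",
                        paste(motif_key(motifs)[bad], collapse = "; ")),
                 "kgml_precondition_error")
  }
  records <- list()
  if (nrow(motifs)) {
    motifs <- motifs[order(motifs$compound, motifs$upstream,
                           motifs$downstream), , drop = FALSE]
    sigs <- vapply(pathway$relations, relation_signature, character(1))
    for (i in seq_len(nrow(motifs))) {
      a <- motifs$upstream[i]; cmp <- motifs$compound[i]
      b <- motifs$downstream[i]
      inherited <- Filter(function(s) s$name != "compound",
                          find_relation(pathway, a, cmp)$subtypes)
      rel <- kegg_relation(a, b, "PPrel",
        subtypes = c(list(kegg_subtype("compound", as.character(cmp))),
                     inherited),
        extra = c(cyk_added_by = "pcp_correction"))
      # already present (e.g. a previous run): skip, keeping idempotence
      if (relation_signature(rel) %in% sigs) next
      pathway$relations[[length(pathway$relations) + 1L]] <- rel
      sigs <- c(sigs, relation_signature(rel))
      records[[length(records) + 1L]] <- new_record("pcp_edge_added",
        c(upstream = a, compound = cmp, downstream = b))
    }
  }
  list(pathway = pathway, report = correction_report(records))
}

#' Detect binding relations that point against the signal flow
#'
#' KGML occasionally stores binding/association edges with reversed
#' direction.  Candidates are flagged with a dead-end heuristic: a `PPrel`
#' relation with a `binding/association` subtype whose source has no other
#' incoming relation while its target has at least one other outgoing
#' relation -- i.e. the edge runs from a source-less terminal node into
#' the cascade, the opposite of how a ligand/adapter binding feeds signal
#' flow.  The heuristic is deliberately an isolated predicate so that a
#' different detection rule can be swapped in.
#'
#' @param pathway a valid `kegg_pathway`
#' @return data.frame with columns `index` (position in
#'   `pathway$relations`), `entry1`, `entry2`
#' @export
detect_suspect_bindings <- function(pathway) {
  validate_pathway(pathway)
  rels <- pathway$relations
  out <- list()
  for (i in seq_along(rels)) {
    r <- rels[[i]]
    if (r$type != "PPrel") next
    if (!any(vapply(r$subtypes, function(s)
      s$name == "binding/association", logical(1)))) next
    if (suspect_binding_predicate(rels, i))
      out[[length(out) + 1L]] <- c(index = i, entry1 = r$entry1,
                                   entry2 = r$entry2)
  }
  if (!length(out))
    return(data.frame(index = integer(0), entry1 = integer(0),
                      entry2 = integer(0)))
  as.data.frame(do.call(rbind, out))
}

# The swappable dead-end predicate: TRUE when relation i looks reversed.
suspect_binding_predicate <- function(rels, i) {
  r <- rels[[i]]
  others <- rels[-i]
  incoming1 <- sum(vapply(others, function(o) o$entry2 == r$entry1,
                          logical(1)))
  outgoing2 <- sum(vapply(others, function(o) o$entry1 == r$entry2,
                          logical(1)))
  incoming1 == 0L && outgoing2 >= 1L
}

#' Reverse the direction of flagged binding relations
#'
#' Only relations flagged by [detect_suspect_bindings()] may be reversed
#' (the semi-automatic contract); endpoints are swapped, subtypes left
#' untouched, and the relation is marked with a `cyk_reversed` tracking
#' attribute.  Relation count is unchanged.
#'
#' @param pathway a valid `kegg_pathway`
#' @param candidates subset of [detect_suspect_bindings()] output
#'   (default: all flagged relations)
#' @return list with elements `pathway` and `report` (one
#'   `binding_reversed` record per reversed relation)
#' @export
apply_binding_reversal <- function(pathway, candidates = NULL) {
  detected <- detect_suspect_bindings(pathway)
  if (is.null(candidates)) candidates <- detected
  if (nrow(candidates)) {
    bad <- !(candidates$index %in% detected$index)
    if (any(bad))
      kgml_abort(paste0("relations not flagged as suspect bindings: index ",
                        paste(candidates$index[bad], collapse = ", ")),
                 "kgml_precondition_error")
  }
  records <- list()
  for (i in candidates$index) {
    r <- pathway$relations[[i]]
    pathway$relations[[i]]$entry1 <- r$entry2
    pathway$relations[[i]]$entry2 <- r$entry1
    pathway$relations[[i]]$extra <- c(
      r$extra[setdiff(names(r$extra), "cyk_reversed")],
      cyk_reversed = "true")
    records[[length(records) + 1L]] <- new_record("binding_reversed",
      c(entry1 = r$entry1, entry2 = r$entry2))
  }
  list(pathway = pathway, report = correction_report(records))
}

#' Expand protein-complex group nodes
#'
#' Each `group` entry `G` with components `e1..ek` is dissolved: (a) one
#' `PPrel` binding/association relation is added per unordered component
#' pair (`k(k-1)/2` relations, complex members are physically bound);
#' (b) every relation `X -> G` is replaced by `X -> ei` for all `i` (and
#' symmetrically for `G -> X`), inheriting type and subtypes; (c) `G` is
#' removed; (d) each member gains a `former_group` annotation recording
#' its provenance.  Nested groups are processed innermost-first, with an
#' outer group inheriting the members of a dissolved inner component;
#' cyclic component references raise a validation error.  Ties everywhere
#' are broken by ascending entry id.
#'
#' @param pathway a valid `kegg_pathway`
#' @return list with elements `pathway` and `report` (one
#'   `group_processed` record per group)
#' @export
process_group_nodes <- function(pathway) {
  validate_pathway(pathway)
  records <- list()
  repeat {
    gids <- sort(vapply(entries_of_type(pathway, "group"),
                        function(e) e$id, integer(1)))
    if (!length(gids)) break
    innermost <- Filter(function(g)
      !any(get_entry(pathway, g)$components %in% gids), gids)
    if (!length(innermost))
      kgml_abort(paste0("cyclic group component references among entries: ",
                        paste(gids, collapse = ", ")),
                 "kgml_validation_error")
    g <- min(innermost)
    comps <- sort(get_entry(pathway, g)$components)

    new_rels <- list()
    m_incident <- 0L
    for (r in pathway$relations) {
      touches1 <- r$entry1 == g
      touches2 <- r$entry2 == g
      if (!touches1 && !touches2) {
        new_rels[[length(new_rels) + 1L]] <- r
        next
      }
      m_incident <- m_incident + 1L
      if (touches1 && touches2) next  # degenerate self-relation: drop
      for (ei in comps) {
        rr <- r
        if (touches1) rr$entry1 <- ei else rr$entry2 <- ei
        rr$extra <- c(rr$extra[setdiff(names(rr$extra), "cyk_former_group")],
                      cyk_former_group = as.character(g))
        new_rels[[length(new_rels) + 1L]] <- rr
      }
    }
    pairs <- if (length(comps) >= 2L) utils::combn(comps, 2L) else NULL
    if (!is.null(pairs)) for (j in seq_len(ncol(pairs)))
      new_rels[[length(new_rels) + 1L]] <- kegg_relation(
        pairs[1L, j], pairs[2L, j], "PPrel",
        subtypes = list(kegg_subtype("binding/association")),
        extra = c(cyk_added_by = "group_expansion",
                  cyk_former_group = as.character(g)))

    # rewiring can duplicate an authored relation (X->G next to X->ei);
    # collapse such duplicates, logging each
    sigs <- vapply(new_rels, relation_signature, character(1))
    if (anyDuplicated(sigs)) {
      for (d in which(duplicated(sigs))) {
        rd <- new_rels[[d]]
        records[[length(records) + 1L]] <- new_record(
          "duplicate_relation_collapsed",
          c(entry1 = rd$entry1, entry2 = rd$entry2, type = rd$type))
      }
      new_rels <- new_rels[!duplicated(sigs)]
    }
    pathway$relations <- new_rels
    pathway$entries[[as.character(g)]] <- NULL
    for (ei in comps) {
      key <- as.character(ei)
      ann <- pathway$entries[[key]]$annotations
      prev <- ann["former_group"]
      ann["former_group"] <- if (is.na(prev)) as.character(g)
                             else paste(prev, g, sep = ",")
      pathway$entries[[key]]$annotations <- ann
    }
    # an outer group that listed g as a component inherits g's members
    for (e in entries_of_type(pathway, "group")) {
      if (g %in% e$components)
        pathway$entries[[as.character(e$id)]]$components <-
          sort(unique(c(setdiff(e$components, g), comps)))
    }
    records[[length(records) + 1L]] <- new_record("group_processed",
      c(group = g, components = paste(comps, collapse = ","),
        incident_relations = m_incident))
  }
  validate_pathway(pathway)
  list(pathway = pathway, report = correction_report(records))
}

#' Run all corrections in the fixed order PCP, binding reversal, groups
#'
#' In `auto` mode every detected candidate is corrected; the order
#' (PCP edges first, then binding reversal, then group expansion) is fixed
#' so reports are reproducible and the first two steps operate on the
#' authored topology.  In `report-only` mode nothing is mutated and the
#' report lists every candidate each detector found -- the programmatic
#' form of semi-automatic review.
#'
#' @param pathway a valid `kegg_pathway`
#' @param mode `"auto"` or `"report-only"`
#' @return list with elements `pathway` and `report`
#' @export
correct_all <- function(pathway, mode = c("auto", "report-only")) {
  mode <- match.arg(mode)
  if (mode == "report-only") {
    pcp <- detect_pcp_motifs(pathway)
    bnd <- detect_suspect_bindings(pathway)
    grp <- sort(vapply(entries_of_type(pathway, "group"),
                       function(e) e$id, integer(1)))
    records <- c(
      lapply(seq_len(nrow(pcp)), function(i) new_record("pcp_edge_added",
        c(upstream = pcp$upstream[i], compound = pcp$compound[i],
          downstream = pcp$downstream[i]))),
      lapply(seq_len(nrow(bnd)), function(i) new_record("binding_reversed",
        c(entry1 = bnd$entry1[i], entry2 = bnd$entry2[i]))),
      lapply(grp, function(g) new_record("group_processed",
        c(group = g,
          components = paste(get_entry(pathway, g)$components,
                             collapse = ","))))
    )
    return(list(pathway = pathway, report = correction_report(records)))
  }
  s1 <- apply_pcp_correction(pathway)
  s2 <- apply_binding_reversal(s1$pathway)
  s3 <- process_group_nodes(s2$pathway)
  list(pathway = s3$pathway,
       report = merge_reports(s1$report, s2$report, s3$report))
}
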