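#' @title KGML reading and writing
#' @description
#' Reading and writing of KGML v0.7.x documents through xml2.  Parsing is
#' strict about the model invariants (see [validate_pathway()]) but
#' forgiving about vocabulary drift: unknown attributes are preserved as
#' opaque annotations, unknown subtype names are kept verbatim and flagged
#' in the parse log, and duplicate relations are collapsed (and logged)
#' rather than rejected, all of which occur in real KEGG files.
#' `<reaction>` elements -- the compound-interaction markup of metabolic
#' maps -- are outside the protein-interaction scope of this package and
#' are skipped with a logged warning.
#' @name kgml-io
NULL

# entry/graphics/relation attributes that map to model fields; everything
# else is carried in `extra` (or `annotations` for the cyk_ tracking keys)
PATHWAY_CORE_ATTRS <- c("name", "org", "number", "title")
ENTRY_CORE_ATTRS <- c("id", "name", "type", "link")
GRAPHICS_CORE_ATTRS <- c("name", "fgcolor", "bgcolor", "type", "x", "y",
                         "width", "height")
RELATION_CORE_ATTRS <- c("entry1", "entry2", "type")

ANNOTATION_PREFIX <- "cyk_"

split_annotations <- function(attrs) {
  is_ann <- startsWith(names(attrs), ANNOTATION_PREFIX)
  ann <- attrs[is_ann]
  names(ann) <- substring(names(ann), nchar(ANNOTATION_PREFIX) + 1L)
  list(annotations = ann, extra = attrs[!is_ann])
}

#' Parse a KGML document into a pathway object
#'
#' @param x path to a KGML file, or a length-one character string holding
#'   the XML text itself
#' @return a validated [kegg_pathway()] object.  Messages produced while
#'   parsing (skipped `<reaction>` elements, collapsed duplicate relations,
#'   out-of-vocabulary subtype names) are attached as the parse log,
#'   retrievable with [parse_log()].
#' @seealso [write_kgml()], [parse_log()]
#' @export
parse_kgml <- function(x) {
  doc <- tryCatch(
    xml2::read_xml(x, encoding = "UTF-8"),
    error = function(e) kgml_abort(
      paste0("malformed KGML document: ", conditionMessage(e)),
      "kgml_parse_error")
  )
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "pathway")
    kgml_abort(sprintf("expected <pathway> root element, found <%s>",
                       xml2::xml_name(root)), "kgml_parse_error")

  log <- character(0)
  pattrs <- xml2::xml_attrs(root)
  pextra <- pattrs[setdiff(names(pattrs), PATHWAY_CORE_ATTRS)]

  entries <- list()
  for (node in xml2::xml_find_all(root, "./entry")) {
    attrs <- xml2::xml_attrs(node)
    for (must in c("id", "name", "type"))
      if (!must %in% names(attrs))
        kgml_abort(sprintf("<entry> missing mandatory attribute '%s'", must),
                   "kgml_validation_error")
    gnodes <- xml2::xml_find_all(node, "./graphics")
    graphics <- if (length(gnodes)) {
      ga <- xml2::xml_attrs(gnodes[[1L]])
      if (length(gnodes) > 1L)
        log <- c(log, sprintf(
          "entry %s: %d extra <graphics> elements ignored",
          attrs[["id"]], length(gnodes) - 1L))
      kegg_graphics(
        label = ga["name"] %||% "",
        x = ga["x"] %||% 0, y = ga["y"] %||% 0,
        width = ga["width"] %||% 46, height = ga["height"] %||% 17,
        shape = ga["type"] %||% "rectangle",
        fgcolor = ga["fgcolor"] %||% "#000000",
        bgcolor = ga["bgcolor"] %||% "#BFFFBF",
        extra = ga[setdiff(names(ga), GRAPHICS_CORE_ATTRS)]
      )
    } else NULL
    comps <- as.integer(xml2::xml_attr(
      xml2::xml_find_all(node, "./component"), "id"))
    ae <- split_annotations(attrs[setdiff(names(attrs), ENTRY_CORE_ATTRS)])
    entries[[length(entries) + 1L]] <- kegg_entry(
      id = attrs[["id"]],
      names = strsplit(attrs[["name"]], " +")[[1L]],
      type = attrs[["type"]],
      link = attrs["link"] %||% NA_character_,
      graphics = graphics,
      components = comps,
      annotations = ae$annotations,
      extra = ae$extra
    )
  }

  relations <- list()
  seen <- character(0)
  for (node in xml2::xml_find_all(root, "./relation")) {
    attrs <- xml2::xml_attrs(node)
    for (must in RELATION_CORE_ATTRS)
      if (!must %in% names(attrs))
        kgml_abort(sprintf("<relation> missing mandatory attribute '%s'",
                           must), "kgml_validation_error")
    subtypes <- lapply(xml2::xml_find_all(node, "./subtype"), function(s) {
      sa <- xml2::xml_attrs(s)
      kegg_subtype(sa["name"] %||% "", sa["value"] %||% "---")
    })
    unknown <- setdiff(vapply(subtypes, function(s) s$name, character(1)),
                       KGML_SUBTYPE_NAMES)
    if (length(unknown))
      log <- c(log, sprintf(
        "relation %s->%s: subtype name(s) outside KGML vocabulary kept verbatim: %s",
        attrs[["entry1"]], attrs[["entry2"]],
        paste(unknown, collapse = ", ")))
    # relations keep cyk_* tracking attributes directly in extra
    rel <- kegg_relation(attrs[["entry1"]], attrs[["entry2"]],
                         attrs[["type"]], subtypes,
                         extra = attrs[setdiff(names(attrs),
                                               RELATION_CORE_ATTRS)])
    sig <- relation_signature(rel)
    if (sig %in% seen) {
      log <- c(log, sprintf("duplicate relation collapsed: %d -> %d (%s)",
                            rel$entry1, rel$entry2, rel$type))
      next
    }
    seen <- c(seen, sig)
    relations[[length(relations) + 1L]] <- rel
  }

  n_reactions <- length(xml2::xml_find_all(root, "./reaction"))
  if (n_reactions)
    log <- c(log, sprintf(
      "%d <reaction> element(s) skipped: compound reactions of metabolic maps are outside the protein-interaction scope",
      n_reactions))

  pathway <- kegg_pathway(
    name = pattrs["name"] %||% "", org = pattrs["org"] %||% "",
    number = pattrs["number"] %||% "", title = pattrs["title"] %||% "",
    entries = entries, relations = relations, extra = pextra
  )
  attr(pathway, "parse_log") <- log
  pathway
}

#' Messages recorded while parsing a KGML document
#' @param pathway a pathway returned by [parse_kgml()]
#' @return character vector (empty when parsing was silent)
#' @export
parse_log <- function(pathway) attr(pathway, "parse_log") %||% character(0)

set_attrs_sorted <- function(node, extra) {
  for (nm in sort(names(extra)))
    xml2::xml_set_attr(node, nm, extra[[nm]])
}

#' Serialise a pathway back to KGML
#'
#' The output is deterministic: for a given pathway object two calls
#' produce byte-identical text (fixed element order following the model,
#' fixed attribute order, extra attributes sorted by name).  All
#' modification-tracking annotations are written as `cyk_*` attributes and
#' survive a round-trip through [parse_kgml()].
#'
#' @param pathway a valid `kegg_pathway`
#' @param path optional output file; written UTF-8
#' @return the KGML text, invisibly when `path` is given
#' @export
write_kgml <- function(pathway, path = NULL) {
  validate_pathway(pathway)
  doc <- xml2::xml_new_root("pathway",
    name = pathway$name, org = pathway$org, number = pathway$number,
    title = pathway$title)
  set_attrs_sorted(doc, pathway$extra)

  for (e in pathway$entries) {
    en <- xml2::xml_add_child(doc, "entry",
      id = as.character(e$id),
      name = paste(e$names, collapse = " "),
      type = e$type)
    if (!is.na(e$link %||% NA_character_) && nzchar(e$link %||% ""))
      xml2::xml_set_attr(en, "link", e$link)
    if (length(e$annotations)) {
      ann <- e$annotations
      names(ann) <- paste0(ANNOTATION_PREFIX, names(ann))
      set_attrs_sorted(en, ann)
    }
    set_attrs_sorted(en, e$extra)
    g <- e$graphics
    gn <- xml2::xml_add_child(en, "graphics",
      name = g$label, fgcolor = g$fgcolor, bgcolor = g$bgcolor,
      type = g$shape, x = as.character(g$x), y = as.character(g$y),
      width = as.character(g$width), height = as.character(g$height))
    set_attrs_sorted(gn, g$extra)
    for (cid in e$components)
      xml2::xml_add_child(en, "component", id = as.character(cid))
  }

  for (r in pathway$relations) {
    rn <- xml2::xml_add_child(doc, "relation",
      entry1 = as.character(r$entry1), entry2 = as.character(r$entry2),
      type = r$type)
    set_attrs_sorted(rn, r$extra)
    for (s in r$subtypes)
      xml2::xml_add_child(rn, "subtype", name = s$name, value = s$value)
  }

  text <- as.character(doc)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(text), con)
    return(invisible(text))
  }
  text
}

#' Fetch one pathway's KGML from the KEGG REST API
#'
#' Downloads a single pathway (`<base_url>/<org><number>/kgml`).  The KEGG
#' REST API permits individual downloads for academic use only; bulk
#' download requires a KEGG FTP subscription.  A pathway that does not
#' exist in the database yields a classed `kgml_not_found` error (the
#' programmatic equivalent of the interactive warning message); any other
#' network failure yields `kgml_transport_error`.
#'
#' @param org organism code (e.g. `"hsa"`)
#' @param number pathway number (e.g. `"04662"`)
#' @param base_url REST endpoint; override (e.g. with a `file://` URL) for
#'   offline testing
#' @return KGML text as a single string
#' @export
fetch_kgml <- function(org, number, base_url = "https://rest.kegg.jp/get") {
  u <- sprintf("%s/%s%s/kgml", base_url, org, number)
  classify <- function(e) {
    msg <- conditionMessage(e)
    if (grepl("404|400|Not Found|Bad Request", msg) ||
        (startsWith(u, "file://") && grepl("cannot open", msg)))
      kgml_abort(sprintf(
        "pathway %s%s does not exist in the database (%s)",
        org, number, msg), "kgml_not_found")
    kgml_abort(sprintf("could not reach %s: %s", u, msg),
               "kgml_transport_error")
  }
  text <- withCallingHandlers(
    tryCatch(paste(readLines(url(u), warn = FALSE), collapse = "\n"),
             error = classify),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (!nzchar(trimws(text)))
    kgml_abort(sprintf("pathway %s%s does not exist in the database (empty response)",
                       org, number), "kgml_not_found")
  text
}

#' Export the relations of a pathway as a SIF-style edge list
#'
#' One row per relation: source entry names, an interaction label of the
#' form `type:subtype1,subtype2`, and target entry names.  Multiple KEGG
#' ids within one entry are joined with `|` so rows stay three columns.
#'
#' @param pathway a valid `kegg_pathway`
#' @return a data.frame with columns `source`, `interaction`, `target`
#' @export
export_edge_list <- function(pathway) {
  validate_pathway(pathway)
  rows <- lapply(pathway$relations, function(r) {
    st <- vapply(r$subtypes, function(s) s$name, character(1))
    data.frame(
      source = paste(get_entry(pathway, r$entry1)$names, collapse = "|"),
      interaction = if (length(st)) paste0(r$type, ":", paste(st, collapse = ","))
                    else r$type,
      target = paste(get_entry(pathway, r$entry2)$names, collapse = "|"),
      stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(source = character(0), interaction = character(0),
                      target = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write the edge list of a pathway as tab-delimited SIF-style text
#' @param pathway a valid `kegg_pathway`
#' @param path output file
#' @return the edge-list data.frame, invisibly
#' @export
write_edge_list <- function(pathway, path) {
  df <- export_edge_list(pathway)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(df)
}
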