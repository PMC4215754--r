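#' @title KGML pathway domain model
#' @description
#' A KEGG pathway is represented as a plain-list graph: a `kegg_pathway`
#' holds ordered `kegg_entry` nodes (keyed by their integer entry id) and
#' ordered `kegg_relation` edges.  The model mirrors the KGML v0.7.x
#' element set (`<pathway>`, `<entry>`, `<graphics>`, `<relation>`,
#' `<subtype>`); attributes outside that set are preserved verbatim as
#' opaque key--value annotations so that unknown markup survives a
#' read--modify--write cycle.
#' @name kgml-model
NULL

KGML_ENTRY_TYPES <- c("gene", "compound", "map", "group", "ortholog",
                      "enzyme", "other")

KGML_RELATION_TYPES <- c("PPrel", "ECrel", "GErel", "PCrel", "maplink")

# Controlled vocabulary for <subtype name="...">; unknown names are kept
# but flagged in the parse log.
KGML_SUBTYPE_NAMES <- c(
  "compound", "hidden compound", "activation", "inhibition", "expression",
  "repression", "indirect effect", "state change", "binding/association",
  "dissociation", "missing interaction", "phosphorylation",
  "dephosphorylation", "glycosylation", "ubiquitination", "methylation"
)

#' Graphics block of a KGML entry
#'
#' Coordinates follow the KGML convention: `x`/`y` are the node centre in
#' pixels, integer valued, with the origin at the top-left corner and y
#' increasing downward.
#'
#' @param label display label (`name` attribute of `<graphics>`)
#' @param x,y centre coordinates in pixels
#' @param width,height node box size in pixels; must be positive
#' @param shape KGML graphics type (`rectangle`, `circle`, `roundrectangle`,
#'   `line`)
#' @param fgcolor,bgcolor hex colour strings
#' @param extra named character vector of attributes outside the KGML core
#'   set, re-emitted verbatim on write
#' @return an object of class `kegg_graphics`
#' @export
kegg_graphics <- function(label = "", x = 0L, y = 0L, width = 46L,
                          height = 17L, shape = "rectangle",
                          fgcolor = "#000000", bgcolor = "#BFFFBF",
                          extra = character(0)) {
  width <- as.integer(round(as.numeric(width)))
  height <- as.integer(round(as.numeric(height)))
  if (is.na(width) || is.na(height) || width <= 0L || height <= 0L)
    kgml_abort("graphics width and height must be positive",
               "kgml_validation_error")
  structure(list(
    label = as.character(label),
    x = as.integer(round(as.numeric(x))),
    y = as.integer(round(as.numeric(y))),
    width = width, height = height,
    shape = as.character(shape),
    fgcolor = as.character(fgcolor), bgcolor = as.character(bgcolor),
    extra = as_attr_map(extra)
  ), class = "kegg_graphics")
}

#' A single KGML entry (pathway node)
#'
#' An entry is a pathway node: a paralog gene group, a compound, a link to
#' another map, or a `group` container bundling component entries (a
#' protein complex).  The KGML `name` attribute is a space-separated list
#' of KEGG identifiers; it is held here as a character vector.
#'
#' @param id positive integer entry identifier, unique within a pathway
#' @param names non-empty character vector of KEGG ids (e.g. `"hsa:3932"`),
#'   all sharing one namespace prefix
#' @param type one of `gene`, `compound`, `map`, `group`, `ortholog`,
#'   `enzyme`, `other`
#' @param link optional URL
#' @param graphics a [kegg_graphics()] object
#' @param components integer vector of component entry ids; required (>= 2
#'   members) iff `type == "group"`, empty otherwise
#' @param annotations named character vector of modification-tracking
#'   annotations (serialised as `cyk_*` attributes in KGML output)
#' @param extra named character vector of unrecognised KGML attributes,
#'   preserved verbatim
#' @return an object of class `kegg_entry`
#' @export
kegg_entry <- function(id, names, type, link = NA_character_,
                       graphics = NULL, components = integer(0),
                       annotations = character(0), extra = character(0)) {
  id <- as.integer(id)
  if (length(id) != 1L || is.na(id) || id < 1L)
    kgml_abort("entry id must be a single positive integer",
               "kgml_validation_error")
  names <- as.character(names)
  if (!length(names) || anyNA(names) || any(!nzchar(names)))
    kgml_abort(sprintf("entry %d must have a non-empty name list", id),
               "kgml_validation_error")
  type <- match.arg(type, KGML_ENTRY_TYPES)
  components <- sort(unique(as.integer(components)))
  if (type == "group" && length(components) < 2L)
    kgml_abort(sprintf("group entry %d must have at least 2 components", id),
               "kgml_validation_error")
  if (type != "group" && length(components))
    kgml_abort(sprintf("non-group entry %d cannot have components", id),
               "kgml_validation_error")
  if (is.null(graphics)) graphics <- kegg_graphics(label = names[[1L]])
  structure(list(
    id = id, names = names, type = type, link = as.character(link),
    graphics = graphics, components = components,
    annotations = as_attr_map(annotations), extra = as_attr_map(extra)
  ), class = "kegg_entry")
}

#' A relation subtype
#'
#' @param name subtype name from the KGML controlled vocabulary
#'   (e.g. `activation`, `inhibition`, `binding/association`, `compound`);
#'   unknown names are accepted and preserved
#' @param value subtype value; for `name = "compound"` this is the entry id
#'   of the mediating compound, for most others KGML uses an arrow glyph
#'   such as `"-->"`
#' @return a list of class `kegg_subtype`
#' @export
kegg_subtype <- function(name, value = "---") {
  structure(list(name = as.character(name), value = as.character(value)),
            class = "kegg_subtype")
}

#' A single KGML relation (pathway edge)
#'
#' @param entry1 source entry id
#' @param entry2 target entry id
#' @param type relation type: `PPrel` (protein-protein), `ECrel`
#'   (enzyme-enzyme), `GErel` (gene expression), `PCrel`
#'   (protein-compound), or `maplink`
#' @param subtypes list of [kegg_subtype()] objects
#' @param extra named character vector of extra attributes (including the
#'   `cyk_*` modification-tracking attributes written by the correction and
#'   tuning operations)
#' @return an object of class `kegg_relation`
#' @export
kegg_relation <- function(entry1, entry2, type, subtypes = list(),
                          extra = character(0)) {
  entry1 <- as.integer(entry1)
  entry2 <- as.integer(entry2)
  if (anyNA(c(entry1, entry2)))
    kgml_abort("relation endpoints must be integer entry ids",
               "kgml_validation_error")
  type <- match.arg(type, KGML_RELATION_TYPES)
  subtypes <- lapply(subtypes, function(s) {
    if (inherits(s, "kegg_subtype")) s else kegg_subtype(s$name, s$value)
  })
  structure(list(entry1 = entry1, entry2 = entry2, type = type,
                 subtypes = subtypes, extra = as_attr_map(extra)),
            class = "kegg_relation")
}

subtype_signature <- function(subtypes) {
  if (!length(subtypes)) return("")
  paste(sort(vapply(subtypes, function(s)
    paste0(s$name, "=", s$value %||% ""), character(1))), collapse = ";")
}

relation_signature <- function(rel) {
  paste(rel$entry1, rel$entry2, rel$type,
        subtype_signature(rel$subtypes), sep = "|")
}

#' Construct a KEGG pathway object
#'
#' @param name KEGG pathway identifier (e.g. `"path:hsa04662"`)
#' @param org organism code (e.g. `"hsa"`)
#' @param number pathway number string (e.g. `"04662"`)
#' @param title human-readable pathway title
#' @param entries list of [kegg_entry()] objects; stored keyed by entry id,
#'   document order preserved
#' @param relations list of [kegg_relation()] objects
#' @param extra named character vector of extra `<pathway>` attributes
#'   (image URL, link, ...)
#' @param validate run [validate_pathway()] on the result (default `TRUE`)
#' @return an object of class `kegg_pathway`
#' @export
kegg_pathway <- function(name = "", org = "", number = "", title = "",
                         entries = list(), relations = list(),
                         extra = character(0), validate = TRUE) {
  ids <- vapply(entries, function(e) e$id, integer(1))
  names(entries) <- as.character(ids)
  p <- structure(list(
    name = as.character(name), org = as.character(org),
    number = as.character(number), title = as.character(title),
    entries = entries, relations = unname(relations),
    extra = as_attr_map(extra)
  ), class = "kegg_pathway")
  if (validate) validate_pathway(p)
  p
}

#' Entry ids of a pathway, in document order
#' @param pathway a `kegg_pathway`
#' @return integer vector
#' @export
entry_ids <- function(pathway) {
  vapply(pathway$entries, function(e) e$id, integer(1), USE.NAMES = FALSE)
}

get_entry <- function(pathway, id) pathway$entries[[as.character(id)]]

entries_of_type <- function(pathway, type) {
  Filter(function(e) e$type == type, pathway$entries)
}

#' All gene identifiers carried by gene-type entries
#' @param pathway a `kegg_pathway`
#' @return character vector of unique KEGG gene ids, in first-seen order
#' @export
pathway_gene_ids <- function(pathway) {
  unique(unlist(lapply(entries_of_type(pathway, "gene"),
                       function(e) e$names), use.names = FALSE)) %||% character(0)
}

#' Validate a pathway against the model invariants
#'
#' Checks entry-id uniqueness, referential integrity of relation endpoints
#' and group components, the group/components coupling, and the one
#' namespace-prefix-per-entry rule.  Signals a classed
#' `kgml_validation_error` listing every offending id.
#'
#' @param pathway a `kegg_pathway`
#' @return `TRUE`, invisibly
#' @export
validate_pathway <- function(pathway) {
  ids <- entry_ids(pathway)
  problems <- character(0)
  if (anyDuplicated(ids))
    problems <- c(problems, sprintf(
      "duplicate entry ids: %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  for (e in pathway$entries) {
    if (length(e$components)) {
      missing <- setdiff(e$components, ids)
      if (length(missing))
        problems <- c(problems, sprintf(
          "group entry %d references missing components: %s",
          e$id, paste(missing, collapse = ", ")))
    }
    withcolon <- grepl(":", e$names, fixed = TRUE)
    prefixes <- unique(sub(":.*$", "", e$names[withcolon]))
    if (length(prefixes) > 1L)
      problems <- c(problems, sprintf(
        "entry %d mixes name namespaces: %s",
        e$id, paste(prefixes, collapse = ", ")))
  }
  for (i in seq_along(pathway$relations)) {
    r <- pathway$relations[[i]]
    missing <- setdiff(c(r$entry1, r$entry2), ids)
    if (length(missing))
      problems <- c(problems, sprintf(
        "relation %d (%d -> %d) references missing entries: %s",
        i, r$entry1, r$entry2, paste(missing, collapse = ", ")))
  }
  if (length(problems))
    kgml_abort(paste0("invalid pathway:\n  ",
                      paste(problems, collapse = "\n  ")),
               "kgml_validation_error", list(problems = problems))
  invisible(TRUE)
}

#' @export
print.kegg_pathway <- function(x, ...) {
  types <- table(vapply(x$entries, function(e) e$type, character(1)))
  cat(sprintf("<kegg_pathway> %s  \"%s\"\n", x$name, x$title))
  cat(sprintf("  %d entries (%s), %d relations\n",
              length(x$entries),
              paste(sprintf("%s: %d", names(types), as.integer(types)),
                    collapse = ", "),
              length(x$relations)))
  invisible(x)
}

#' @export
print.kegg_entry <- function(x, ...) {
  cat(sprintf("<kegg_entry> id=%d type=%s [%s]\n",
              x$id, x$type, paste(x$names, collapse = " ")))
  invisible(x)
}

#' @export
print.kegg_relation <- function(x, ...) {
  st <- if (length(x$subtypes))
    paste(vapply(x$subtypes, function(s) s$name, character(1)),
          collapse = ",") else "-"
  cat(sprintf("<kegg_relation> %d -> %d %s (%s)\n",
              x$entry1, x$entry2, x$type, st))
  invisible(x)
}

# Structural equality on the pathway model, ignoring bookkeeping
# attributes such as the parse log.
pathway_equal <- function(a, b) {
  strip <- function(p) {
    attributes(p) <- attributes(p)["names"]
    p
  }
  identical(strip(unclass(a)), strip(unclass(b)))
}
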