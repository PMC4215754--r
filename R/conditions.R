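# Classed conditions so callers (and the CLI) can map failures to outcomes
# without string matching.

kgml_abort <- function(message, class, data = list()) {
  cond <- structure(
    class = c(class, "kgmltune_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

# canonical named-character form for attribute maps, so that empty maps
# compare identical regardless of how they were produced
as_attr_map <- function(x) {
  nm <- names(x)
  if (is.null(nm)) nm <- rep("", length(x))
  stats::setNames(as.character(x), nm)
}
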