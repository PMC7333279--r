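# Registry JSON dialect and record IO ----------------------------------------
#
# A registry travels as one JSON document with top-level keys
# "data_elements", "rules" and "dictionaries" (table descriptors naming
# their CSV source).  Saving is canonical -- keys sorted, newline
# terminated -- so saved files diff cleanly and load/save round-trips are
# byte identical.
#
# Records travel as CSV (header = CDE ids; a `__set_id` column groups rows
# of a repeated composite; `<id>__unit` columns carry entered units; column
# order is captured as the field order) or as an equivalent JSON
# array-of-objects.

REGISTRY_TOP_KEYS <- c("data_elements", "rules", "dictionaries")
ELEMENT_KEYS <- c("id", "name", "definition", "semantic_type", "subtype",
                  "kind", "value_domain", "members", "vocabulary_ref",
                  "dictionary_ref", "rule_ids", "dec")
DOMAIN_KEYS <- c("datatype", "unit", "permissible_values", "format")
RULE_KEYS <- c("id", "kind", "expr", "target", "description")
DICT_KEYS <- c("id", "source", "key_column", "unit_column", "range_column")

sort_keys <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, sort_keys)
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
  }
  x
}

check_keys <- function(obj, allowed, where, mode) {
  extra <- setdiff(names(obj), allowed)
  if (length(extra) == 0) return(invisible())
  msg <- sprintf("unknown key '%s' at %s", extra[1], where)
  if (mode == "strict") stop_cde("%s", msg) else warning(msg, call. = FALSE)
}

#' Load a registry from JSON
#'
#' @param path path to a registry JSON document
#' @param mode `strict` rejects unknown keys; `lenient` warns
#' @param base_dir directory that dictionary CSV `source` paths are
#'   resolved against (defaults to the registry file's directory)
#' @return a [cde_registry()]
#' @export
load_registry <- function(path, mode = c("strict", "lenient"),
                          base_dir = dirname(path)) {
  mode <- match.arg(mode)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  check_keys(doc, REGISTRY_TOP_KEYS, "/", mode)
  reg <- cde_registry()

  for (i in seq_along(doc$dictionaries %||% list())) {
    d <- doc$dictionaries[[i]]
    check_keys(d, DICT_KEYS, sprintf("/dictionaries/%d", i), mode)
    src <- d$source
    if (!file.exists(src)) src <- file.path(base_dir, d$source)
    dict <- load_dictionary(src, id = d$id, key_column = d$key_column,
                            unit_column = d$unit_column,
                            range_column = d$range_column)
    dict$source <- d$source  # keep the declared (relative) path
    reg$dictionaries[[d$id]] <- dict
  }

  for (i in seq_along(doc$rules %||% list())) {
    r <- doc$rules[[i]]
    check_keys(r, RULE_KEYS, sprintf("/rules/%d", i), mode)
    register_rule(reg, r$expr, id = r$id, kind = r$kind, target = r$target,
                  description = r$description %||% "")
  }

  elements <- doc$data_elements %||% list()
  # atomics first (plain/variable, then hybrid), composites last, so
  # members are always resolvable regardless of file order
  order_class <- vapply(elements, function(e) {
    if (identical(e$semantic_type, "composite")) 3L
    else if (identical(e$subtype, "hybrid")) 2L else 1L
  }, integer(1))
  for (e in elements[order(order_class)]) {
    i <- which(vapply(elements, identical, logical(1), e))[1]
    check_keys(e, ELEMENT_KEYS, sprintf("/data_elements/%d", i), mode)
    if (identical(e$semantic_type, "composite")) {
      compose_cde(reg, e$name, kind = e$kind,
                  members = unlist(e$members), id = e$id,
                  definition = e$definition %||% "",
                  rules = unlist(e$rule_ids),
                  dictionary_ref = e$dictionary_ref)
    } else {
      vd <- e$value_domain
      check_keys(vd, DOMAIN_KEYS, sprintf("/data_elements/%d/value_domain", i),
                 mode)
      pv <- vd$permissible_values
      if (!is.null(pv)) {
        pv <- data.frame(
          code = vapply(pv, function(p) p$code, character(1)),
          meaning = vapply(pv, function(p) p$meaning %||% p$code,
                           character(1)),
          stringsAsFactors = FALSE)
      }
      dom <- value_domain(vd$datatype, unit_of_measure = vd$unit,
                          permissible_values = pv, format = vd$format)
      dec <- if (!is.null(e$dec))
        data_element_concept(e$dec$object_class, e$dec$property)
      register_atomic(reg, e$name, dom, id = e$id,
                      definition = e$definition %||% "", dec = dec,
                      subtype = e$subtype %||% "plain",
                      members = unlist(e$members),
                      vocabulary_ref = e$vocabulary_ref,
                      rules = unlist(e$rule_ids))
    }
  }
  reg
}

#' Save a registry to canonical JSON
#'
#' Output is key-sorted and newline-terminated; `load_registry()` of the
#' result reproduces the registry, and re-saving is byte-identical.
#'
#' @param reg a [cde_registry()]
#' @param path output path
#' @export
save_registry <- function(reg, path) {
  stopifnot(inherits(reg, "cde_registry"))
  elements <- lapply(reg$cdes[order(names(reg$cdes))], function(cde) {
    if (cde$semantic_type == "composite") {
      e <- list(id = cde$id, name = cde$name, definition = cde$definition,
                semantic_type = "composite", kind = cde$kind,
                members = as.list(cde$members))
      if (length(cde$rules) > 0) e$rule_ids <- as.list(cde$rules)
      if (!is.null(cde$dictionary_ref)) e$dictionary_ref <- cde$dictionary_ref
      return(e)
    }
    dom <- cde$value_domain
    vd <- list(datatype = dom$datatype)
    if (!is.null(dom$unit_of_measure)) vd$unit <- dom$unit_of_measure
    if (!is.null(dom$permissible_values))
      vd$permissible_values <- lapply(seq_len(nrow(dom$permissible_values)),
        function(k) list(code = dom$permissible_values$code[k],
                         meaning = dom$permissible_values$meaning[k]))
    if (!is.null(dom$format)) vd$format <- dom$format
    e <- list(id = cde$id, name = cde$name, definition = cde$definition,
              semantic_type = "atomic", subtype = cde$subtype,
              value_domain = vd)
    if (!is.null(cde$members)) e$members <- as.list(cde$members)
    if (!is.null(cde$vocabulary_ref)) e$vocabulary_ref <- cde$vocabulary_ref
    if (!is.null(cde$dec))
      e$dec <- list(object_class = cde$dec$object_class,
                    property = cde$dec$property)
    if (length(cde$rules) > 0) e$rule_ids <- as.list(cde$rules)
    e
  })
  rules <- lapply(reg$rules[order(names(reg$rules))], function(r) {
    e <- list(id = r$id, kind = r$kind, expr = r$expr_text,
              description = r$description)
    if (!is.null(r$target)) e$target <- r$target
    e
  })
  dicts <- lapply(reg$dictionaries[order(names(reg$dictionaries))],
    function(d) {
      e <- list(id = d$id, source = d$source, key_column = d$key_column)
      if (!is.null(d$unit_column)) e$unit_column <- d$unit_column
      if (!is.null(d$range_column)) e$range_column <- d$range_column
      e
    })
  payload <- list(data_elements = unname(elements), rules = unname(rules),
                  dictionaries = unname(dicts))
  txt <- jsonlite::toJSON(sort_keys(payload), auto_unbox = TRUE,
                          digits = NA, pretty = TRUE)
  writeLines(txt, path)  # writeLines terminates with a newline
  invisible(path)
}

# -- records ------------------------------------------------------------------

#' Load data records from CSV or JSON
#'
#' CSV: header row of CDE ids; optional `__set_id` column grouping rows
#' into record sets; optional `<id>__unit` columns carrying entered units;
#' the remaining column order becomes each record's field order.  JSON: an
#' array of objects, where an explicit `null` is a null value (distinct
#' from an absent key); key order becomes the field order.
#'
#' @param path input file
#' @param format `csv` or `json` (guessed from the extension by default)
#' @return a list of [data_record()]s, or of [record_set()]s when set ids
#'   are present
#' @export
load_records <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  if (format == "json") return(load_records_json(path))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        stringsAsFactors = FALSE)
  cols <- names(df)
  unit_cols <- grep("__unit$", cols, value = TRUE)
  value_cols <- setdiff(cols, c("__set_id", unit_cols))
  make_record <- function(i) {
    # keep explicit nulls as named NULL entries
    vals <- stats::setNames(
      lapply(value_cols, function(cc) {
        cell <- df[[cc]][i]
        if (nzchar(trimws(cell))) cell else NULL
      }), value_cols)
    units <- list()
    for (uc in unit_cols) {
      cell <- df[[uc]][i]
      if (nzchar(trimws(cell)))
        units[[sub("__unit$", "", uc)]] <- trimws(cell)
    }
    data_record(vals, units = units, field_order = value_cols)
  }
  records <- lapply(seq_len(nrow(df)), make_record)
  if ("__set_id" %in% cols) {
    sets <- split(seq_len(nrow(df)), df[["__set_id"]])
    return(lapply(names(sets), function(sid)
      record_set(sid, records[sets[[sid]]])))
  }
  records
}

load_records_json <- function(path) {
  arr <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(arr, function(obj) {
    units <- list()
    vals <- list()
    order <- character(0)
    for (key in names(obj)) {
      if (grepl("__unit$", key)) {
        units[[sub("__unit$", "", key)]] <- obj[[key]]
      } else {
        order <- c(order, key)
        vals[key] <- list(obj[[key]])  # preserves explicit NULL
      }
    }
    data_record(vals, units = units, field_order = order)
  })
}
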