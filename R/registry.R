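# Metadata registry: atomic and composite common data elements ---------------
#
# The registry follows the ISO/IEC 11179 split of a data element into a data
# element concept (object class + property) and a value domain (datatype,
# unit, permissible values, format), and extends it with semantic subtypes:
# atomic CDEs may be plain, variable (vocabulary/dictionary-keyed) or hybrid
# (union of member domains with distinct datatypes); composite CDEs group
# atomic CDEs as general, repeated (tabular) or dictionary kinds and carry
# constraint rules.  Nesting stops at two levels: composites hold atomics,
# hybrids hold plain atomics.

DATATYPES <- c("numeric", "text", "enumerated", "time", "date", "datetime",
               "boolean")
ACDE_SUBTYPES <- c("plain", "variable", "hybrid")
CCDE_KINDS <- c("general", "repeated", "dictionary")
RULE_KINDS <- c("Operated", "Required", "Dependent", "Ordered", "Dictionary")

#' Describe a value domain
#'
#' @param datatype one of `numeric`, `text`, `enumerated`, `time`, `date`,
#'   `datetime`, `boolean`
#' @param unit_of_measure optional unit label for numeric domains
#' @param permissible_values for enumerated domains: a data.frame with
#'   columns `code` and `meaning`, or a character vector of codes
#' @param format text pattern for time/date entry; defaults to ISO 8601
#'   dates and `"HH:MM"` times
#' @return a `cde_value_domain`
#' @export
#' @examples
#' value_domain("numeric", unit_of_measure = "kg")
#' value_domain("enumerated", permissible_values = c("Start", "Finish"))
value_domain <- function(datatype, unit_of_measure = NULL,
                         permissible_values = NULL, format = NULL) {
  if (!datatype %in% DATATYPES)
    stop_cde("unknown datatype '%s'", datatype)
  if (datatype == "enumerated") {
    if (is.null(permissible_values) || length(permissible_values) == 0)
      stop_cde("enumerated domain requires non-empty permissible_values")
    if (is.character(permissible_values))
      permissible_values <- data.frame(code = permissible_values,
                                       meaning = permissible_values,
                                       stringsAsFactors = FALSE)
    if (anyDuplicated(permissible_values$code))
      stop_cde("permissible value codes must be unique")
  } else if (!is.null(permissible_values)) {
    stop_cde("permissible_values only apply to enumerated domains")
  }
  if (!is.null(unit_of_measure) && !nzchar(trimws(unit_of_measure)))
    stop_cde("unit_of_measure must be a non-empty token when present")
  if (is.null(format)) {
    format <- switch(datatype, time = "HH:MM", date = "YYYY-MM-DD",
                     datetime = "YYYY-MM-DDTHH:MM", NULL)
  }
  structure(list(datatype = datatype, unit_of_measure = unit_of_measure,
                 permissible_values = permissible_values, format = format),
            class = "cde_value_domain")
}

#' Describe a data element concept
#'
#' The semantic half of a data element: an object class (the set of entities
#' described) and a property common to that class, optionally annotated with
#' terminology codes.
#'
#' @param object_class non-empty text
#' @param property non-empty text
#' @param concept_codes optional list of `(system, code)` pairs
#' @return a `cde_dec`
#' @export
data_element_concept <- function(object_class, property,
                                 concept_codes = NULL) {
  if (!nzchar(trimws(object_class)) || !nzchar(trimws(property)))
    stop_cde("object_class and property must be non-empty")
  structure(list(object_class = object_class, property = property,
                 concept_codes = concept_codes), class = "cde_dec")
}

#' Create an empty metadata registry
#'
#' The registry is an environment-backed container, so registration
#' operations mutate it in place and return the identifier of the item they
#' created.
#'
#' @return a `cde_registry`
#' @export
#' @examples
#' reg <- cde_registry()
#' register_atomic(reg, "Body Weight Value",
#'                 value_domain("numeric", unit_of_measure = "kg"))
cde_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$cdes <- list()
  reg$rules <- list()
  reg$dictionaries <- list()
  reg$auto <- 0L
  class(reg) <- "cde_registry"
  reg
}

#' @export
print.cde_registry <- function(x, ...) {
  kinds <- vapply(x$cdes, function(c) c$semantic_type, character(1))
  cat(sprintf(
    "<cde_registry: %d atomic, %d composite, %d rules, %d dictionaries>\n",
    sum(kinds == "atomic"), sum(kinds == "composite"),
    length(x$rules), length(x$dictionaries)))
  invisible(x)
}

next_auto_id <- function(reg) {
  repeat {
    reg$auto <- reg$auto + 1L
    id <- sprintf("DE:9%04d", reg$auto)
    if (is.null(reg$cdes[[id]]) && is.null(reg$rules[[id]])) return(id)
  }
}

assert_fresh_id <- function(reg, id) {
  if (!is_valid_id(id)) stop_cde("invalid identifier '%s'", id)
  if (!is.null(reg$cdes[[id]]) || !is.null(reg$rules[[id]]) ||
      !is.null(reg$dictionaries[[id]]))
    stop_cde("duplicate id '%s'", id)
  id
}

#' Register an atomic CDE
#'
#' @param reg a [cde_registry()]
#' @param name element name
#' @param value_domain a [value_domain()]
#' @param id identifier; autogenerated when `NULL`.  Identifiers are opaque
#'   tokens; both `"CDE30"` and `"DE:47616"` styles are accepted
#' @param definition free-text definition
#' @param dec optional [data_element_concept()]
#' @param subtype `plain`, `variable` or `hybrid` (use [make_hybrid()] for
#'   hybrids)
#' @param members hybrid subtype only: ordered ids of plain members
#' @param vocabulary_ref variable subtype only: `list(table =, key_column =)`
#'   naming the dictionary table and key column supplying the vocabulary
#' @param rules ids of attached constraint rules (never `Ordered`: ordering
#'   only makes sense inside a composite)
#' @return the id of the new element
#' @export
register_atomic <- function(reg, name, value_domain, id = NULL,
                            definition = "", dec = NULL, subtype = "plain",
                            members = NULL, vocabulary_ref = NULL,
                            rules = NULL) {
  stopifnot(inherits(reg, "cde_registry"))
  if (!subtype %in% ACDE_SUBTYPES) stop_cde("unknown subtype '%s'", subtype)
  id <- assert_fresh_id(reg, id %||% next_auto_id(reg))
  if (!nzchar(trimws(name))) stop_cde("name must be non-empty")
  if (subtype == "variable" && is.null(vocabulary_ref))
    stop_cde("variable aCDE '%s' requires a vocabulary_ref", id)
  if (subtype != "variable" && !is.null(vocabulary_ref))
    stop_cde("vocabulary_ref only applies to variable aCDEs")
  if (subtype == "hybrid") {
    validate_hybrid_members(reg, members)
  } else if (!is.null(members)) {
    stop_cde("members only apply to hybrid aCDEs")
  }
  for (rid in rules) {
    rule <- reg$rules[[rid]] %||% stop_cde("unresolved rule '%s'", rid)
    if (rule$kind == "Ordered")
      stop_cde("Ordered rule '%s' cannot be attached to aCDE '%s'", rid, id)
  }
  reg$cdes[[id]] <- structure(list(
    id = id, name = name, definition = definition, dec = dec,
    value_domain = value_domain, semantic_type = "atomic",
    subtype = subtype, members = members, vocabulary_ref = vocabulary_ref,
    rules = rules), class = "cde_atomic")
  id
}

validate_hybrid_members <- function(reg, members) {
  if (length(members) < 2) stop_cde("a hybrid aCDE needs >= 2 members")
  dts <- character(0)
  for (m in members) {
    cde <- reg$cdes[[m]] %||% stop_cde("unresolved hybrid member '%s'", m)
    if (cde$semantic_type != "atomic" || cde$subtype != "plain")
      stop_cde("hybrid member '%s' must be a plain aCDE", m)
    dts <- c(dts, cde$value_domain$datatype)
  }
  if (anyDuplicated(dts))
    stop_cde("hybrid members must have pairwise distinct datatypes")
  invisible(TRUE)
}

#' Create a hybrid atomic CDE
#'
#' A hybrid aCDE unifies two or more plain aCDEs sharing one concept but
#' holding different datatypes (e.g. a dialysis-session Time that accepts
#' either an `HH:MM` time or the enumerated strings `Start`/`Finish`).  Its
#' effective value domain is the ordered union of the member domains;
#' members are tried in declared order during validation and the first
#' successful parse wins.
#'
#' @inheritParams register_atomic
#' @param members ordered ids of >= 2 existing plain aCDEs with pairwise
#'   distinct datatypes
#' @return the id of the new hybrid element
#' @export
make_hybrid <- function(reg, name, members, id = NULL, definition = "",
                        dec = NULL, rules = NULL) {
  validate_hybrid_members(reg, members)
  # the hybrid's own domain is nominal; per-member domains drive validation
  first <- reg$cdes[[members[[1]]]]
  register_atomic(reg, name, first$value_domain, id = id,
                  definition = definition, dec = dec, subtype = "hybrid",
                  members = as.character(members), rules = rules)
}

#' Register a composite CDE
#'
#' A composite CDE (cCDE) is an identified, reusable group of >= 2 atomic
#' CDEs.  Kinds: `general` (plain grouping), `repeated` (the member set is
#' entered multiple times as table rows), `dictionary` (a variable member is
#' the foreign key into a reference table that supplies units and normal
#' ranges).  The declared member order is the default Ordered sequence.
#'
#' @inheritParams register_atomic
#' @param kind `general`, `repeated` or `dictionary`
#' @param members ordered ids of member aCDEs (may include hybrids)
#' @param dictionary_ref dictionary kind only: a list with at least
#'   `table` (dictionary table id) and `key` (the variable foreign-key
#'   member).  Optional role fields `result`, `unit`, `flag`,
#'   `significance` name the members holding the measured value, its unit,
#'   the abnormal flag and the clinical-significance field, enabling the
#'   dictionary range/flag checks
#' @return the id of the new composite
#' @export
compose_cde <- function(reg, name, kind, members, id = NULL,
                        definition = "", rules = NULL,
                        dictionary_ref = NULL) {
  stopifnot(inherits(reg, "cde_registry"))
  if (!kind %in% CCDE_KINDS) stop_cde("unknown composite kind '%s'", kind)
  id <- assert_fresh_id(reg, id %||% next_auto_id(reg))
  members <- as.character(members)
  if (length(members) < 2) stop_cde("a cCDE needs >= 2 members")
  if (anyDuplicated(members)) stop_cde("duplicate members in cCDE '%s'", id)
  for (m in members) {
    cde <- reg$cdes[[m]] %||% stop_cde("unresolved member '%s'", m)
    if (cde$semantic_type != "atomic")
      stop_cde("cCDE member '%s' must be atomic (no nested composites)", m)
  }
  if (kind == "dictionary") {
    if (is.null(dictionary_ref) || is.null(dictionary_ref$table) ||
        is.null(dictionary_ref$key))
      stop_cde("dictionary cCDE '%s' requires dictionary_ref$table and $key",
               id)
    fk <- reg$cdes[[dictionary_ref$key]]
    if (is.null(fk) || !(dictionary_ref$key %in% members) ||
        fk$subtype != "variable")
      stop_cde("dictionary cCDE '%s': foreign key must be a variable member",
               id)
  } else if (!is.null(dictionary_ref)) {
    stop_cde("dictionary_ref only applies to dictionary cCDEs")
  }
  for (rid in rules) {
    if (is.null(reg$rules[[rid]])) stop_cde("unresolved rule '%s'", rid)
  }
  reg$cdes[[id]] <- structure(list(
    id = id, name = name, definition = definition, kind = kind,
    semantic_type = "composite", members = members, rules = rules,
    dictionary_ref = dictionary_ref), class = "cde_composite")
  id
}

#' Register a constraint rule
#'
#' The rule text is parsed on registration; the declared kind, when given,
#' is checked against the structural classification (a mismatch is stored
#' but reported by [lint_registry()]).  Dependent rules derive their target
#' from the expression.
#'
#' @inheritParams register_atomic
#' @param expr rule text in prefix notation, e.g.
#'   `"(Required CDE40 CDE41)"`
#' @param kind optional declared kind (`Operated`, `Required`, `Dependent`,
#'   `Ordered`, `Dictionary`)
#' @param target optional target aCDE id (Operated derivations)
#' @param description free text
#' @return the rule id
#' @export
register_rule <- function(reg, expr, id = NULL, kind = NULL, target = NULL,
                          description = "") {
  stopifnot(inherits(reg, "cde_registry"))
  id <- assert_fresh_id(reg, id %||% sprintf("RULE:%04d", length(reg$rules) + 1L))
  parsed <- parse_rule(expr)
  inferred <- classify_rule(parsed)
  kind <- kind %||% inferred
  if (!kind %in% RULE_KINDS) stop_cde("unknown rule kind '%s'", kind)
  if (kind == "Dependent" || inferred == "Dependent")
    target <- target %||% dependent_target(parsed)
  reg$rules[[id]] <- structure(list(
    id = id, kind = kind, expression = parsed, expr_text = unparse_rule(parsed),
    target = target, description = description), class = "cde_rule")
  id
}

#' Attach a dictionary table to a registry
#'
#' @inheritParams register_atomic
#' @param dict a `cde_dictionary` from [load_dictionary()]
#' @return the dictionary id
#' @export
register_dictionary <- function(reg, dict) {
  stopifnot(inherits(reg, "cde_registry"), inherits(dict, "cde_dictionary"))
  assert_fresh_id(reg, dict$id)
  reg$dictionaries[[dict$id]] <- dict
  dict$id
}

#' Retrieve registry items
#'
#' @inheritParams register_atomic
#' @param id item identifier
#' @return `get_cde()`/`get_rule()` return the stored object;
#'   `lookup_name()` returns the ids whose name matches exactly.
#' @export
get_cde <- function(reg, id) {
  reg$cdes[[id]] %||% stop_cde("unknown CDE id '%s'", id)
}

#' @rdname get_cde
#' @export
get_rule <- function(reg, id) {
  reg$rules[[id]] %||% stop_cde("unknown rule id '%s'", id)
}

#' @rdname get_cde
#' @param name exact element name
#' @export
lookup_name <- function(reg, name) {
  hits <- vapply(reg$cdes, function(c) identical(c$name, name), logical(1))
  names(reg$cdes)[hits]
}

#' Canonical identity signature of an atomic CDE
#'
#' Two aCDEs are treated as "the same element" for integration counting when
#' their signatures agree: the name is case-folded, trimmed and internal
#' whitespace collapsed, then combined with the datatype and unit.
#'
#' @param cde a `cde_atomic`, or a name when `datatype` is supplied
#' @param datatype,unit used when `cde` is a bare name
#' @return a single character signature
#' @export
#' @examples
#' sig1 <- cde_signature("Body  Weight value", "numeric", "kg")
#' sig2 <- cde_signature("body weight value ", "numeric", "kg")
#' identical(sig1, sig2)
cde_signature <- function(cde, datatype = NULL, unit = NULL) {
  if (inherits(cde, "cde_atomic")) {
    name <- cde$name
    datatype <- cde$value_domain$datatype
    unit <- cde$value_domain$unit_of_measure
  } else {
    name <- cde
    if (is.null(datatype)) stop_cde("datatype required with a bare name")
  }
  paste(tolower(trim_squish(name)), datatype, unit %||% "", sep = "|")
}

# Lint ------------------------------------------------------------------------

lint_finding <- function(item, check, message) {
  data.frame(item = item, check = check, message = message,
             stringsAsFactors = FALSE)
}

#' Audit a registry for structural faults
#'
#' Walks every element and rule, reporting (rather than raising) invariant
#' violations: unresolved references, hybrid/variable/dictionary subtype
#' faults, rules referencing non-member CDEs, Ordered rules attached to an
#' atomic CDE, and declared rule kinds that disagree with the expression's
#' structural classification.
#'
#' @inheritParams register_atomic
#' @return data.frame with columns `item`, `check`, `message`; zero rows on
#'   a clean registry
#' @export
lint_registry <- function(reg) {
  out <- list()
  add <- function(f) out[[length(out) + 1]] <<- f
  for (id in names(reg$cdes)) {
    cde <- reg$cdes[[id]]
    if (cde$semantic_type == "atomic") {
      if (cde$subtype == "hybrid") {
        if (length(cde$members) < 2)
          add(lint_finding(id, "hybrid_arity", "hybrid has < 2 members"))
        dts <- character(0)
        for (m in cde$members) {
          mem <- reg$cdes[[m]]
          if (is.null(mem)) {
            add(lint_finding(id, "unresolved_member",
                             sprintf("member '%s' not found", m)))
          } else if (mem$semantic_type != "atomic" || mem$subtype != "plain") {
            add(lint_finding(id, "hybrid_member_subtype",
                             sprintf("member '%s' is not a plain aCDE", m)))
          } else dts <- c(dts, mem$value_domain$datatype)
        }
        if (anyDuplicated(dts))
          add(lint_finding(id, "hybrid_datatypes",
                           "hybrid members share a datatype"))
      }
      if (cde$subtype == "variable" && is.null(cde$vocabulary_ref))
        add(lint_finding(id, "variable_vocabulary",
                         "variable aCDE without vocabulary_ref"))
      if (cde$subtype == "variable" &&
          !is.null(cde$vocabulary_ref$table) &&
          is.null(reg$dictionaries[[cde$vocabulary_ref$table]]))
        add(lint_finding(id, "unresolved_dictionary",
                         sprintf("vocabulary table '%s' not found",
                                 cde$vocabulary_ref$table)))
      for (rid in cde$rules) {
        rule <- reg$rules[[rid]]
        if (is.null(rule)) {
          add(lint_finding(id, "unresolved_rule",
                           sprintf("rule '%s' not found", rid)))
        } else if (rule$kind == "Ordered") {
          add(lint_finding(id, "ordered_on_acde",
                           sprintf("Ordered rule '%s' attached to aCDE", rid)))
        }
      }
    } else {
      if (length(cde$members) < 2)
        add(lint_finding(id, "composite_arity", "cCDE has < 2 members"))
      if (anyDuplicated(cde$members))
        add(lint_finding(id, "duplicate_members", "duplicate member ids"))
      for (m in cde$members) {
        mem <- reg$cdes[[m]]
        if (is.null(mem))
          add(lint_finding(id, "unresolved_member",
                           sprintf("member '%s' not found", m)))
        else if (mem$semantic_type != "atomic")
          add(lint_finding(id, "nested_composite",
                           sprintf("member '%s' is itself composite", m)))
      }
      if (cde$kind == "dictionary") {
        dr <- cde$dictionary_ref
        if (is.null(dr) || is.null(dr$table) || is.null(dr$key)) {
          add(lint_finding(id, "dictionary_ref",
                           "dictionary cCDE without dictionary_ref"))
        } else {
          if (is.null(reg$dictionaries[[dr$table]]))
            add(lint_finding(id, "unresolved_dictionary",
                             sprintf("dictionary table '%s' not found",
                                     dr$table)))
          fk <- reg$cdes[[dr$key]]
          if (is.null(fk) || !(dr$key %in% cde$members) ||
              fk$subtype != "variable")
            add(lint_finding(id, "dictionary_foreign_key",
                             "foreign key is not a variable member"))
        }
      }
      for (rid in cde$rules) {
        rule <- reg$rules[[rid]]
        if (is.null(rule)) {
          add(lint_finding(id, "unresolved_rule",
                           sprintf("rule '%s' not found", rid)))
          next
        }
        refs <- collect_refs(rule$expression)
        outside <- setdiff(unique(refs$id), cde$members)
        for (ref in outside)
          add(lint_finding(id, "rule_ref_outside_members",
                           sprintf("rule '%s' references non-member '%s'",
                                   rid, ref)))
      }
    }
  }
  for (rid in names(reg$rules)) {
    rule <- reg$rules[[rid]]
    inferred <- classify_rule(rule$expression)
    declared <- rule$kind
    # Dictionary rules are declared, not inferrable from the expression
    if (declared != "Dictionary" && declared != inferred)
      add(lint_finding(rid, "kind_mismatch",
                       sprintf("declared %s but classifies as %s",
                               declared, inferred)))
    if (!is.null(rule$target) && is.null(reg$cdes[[rule$target]]))
      add(lint_finding(rid, "unresolved_target",
                       sprintf("target '%s' not found", rule$target)))
  }
  if (length(out) == 0)
    return(data.frame(item = character(), check = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
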