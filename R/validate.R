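# Record validation ----------------------------------------------------------
#
# A record supplies raw values for the members of a composite (or for a
# standalone atomic CDE plus whatever its rules reference).  Validation runs
# value checks first (datatype / permissible / hybrid resolution), then the
# attached constraint rules in a fixed kind order -- Required, Dependent,
# Operated, Ordered, Dictionary -- and by rule id within a kind, so reports
# are deterministic.  Conditions that cannot be decided because a referenced
# value is null downgrade to `info` findings: flagging nullness itself is
# the Required constraint's job.

FINDING_KINDS <- c("datatype", "permissible", "hybrid", "required",
                   "dependent", "operated", "ordered", "dictionary_range",
                   "dictionary_flag", "indeterminate")

new_finding <- function(kind, severity, cde, rule = NA_character_,
                        row = NA_integer_, code = "", message = "") {
  data.frame(kind = kind, severity = severity, cde = cde,
             rule = if (is.null(rule)) NA_character_ else rule,
             row = if (is.null(row)) NA_integer_ else as.integer(row),
             code = code, message = message, stringsAsFactors = FALSE)
}

empty_findings <- function() {
  data.frame(kind = character(), severity = character(), cde = character(),
             rule = character(), row = integer(), code = character(),
             message = character(), stringsAsFactors = FALSE)
}

bind_findings <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
  if (length(lst) == 0) return(empty_findings())
  do.call(rbind, lst)
}

#' Construct a data record
#'
#' @param values named list mapping member CDE ids to raw values; an
#'   element that is `NULL` or `""` is an explicit null
#' @param units optional named list/character of entered units, keyed by
#'   CDE id
#' @param field_order ordered character vector of member ids as the fields
#'   were presented or collected (used by the Ordered check); defaults to
#'   the order of `values`
#' @return a `cde_record`
#' @export
data_record <- function(values, units = NULL, field_order = names(values)) {
  stopifnot(is.list(values), !is.null(names(values)))
  units <- as.list(units %||% list())
  structure(list(values = values, units = units,
                 field_order = field_order),
            class = "cde_record")
}

#' @rdname data_record
#' @param set_id identifier of the record set
#' @param rows list of `cde_record`s entered against the same repeated cCDE
#' @export
record_set <- function(set_id, rows) {
  stopifnot(is.list(rows))
  structure(list(set_id = set_id, rows = rows), class = "cde_record_set")
}

# Raw value accessor: NULL when absent or blank.
record_raw <- function(record, id) {
  if (!id %in% names(record$values)) return(NULL)
  v <- record$values[[id]]
  if (is.null(v) || length(v) == 0) return(NULL)
  v <- as.character(v)
  if (is.na(v) || !nzchar(trimws(v))) return(NULL)
  v
}

record_has_value <- function(record, id) !is.null(record_raw(record, id))

# -- value checks -------------------------------------------------------------

#' Check a raw value against an atomic CDE's value domain
#'
#' Plain aCDEs parse against their own domain; variable aCDEs pass as text
#' (code membership is the dictionary link's business); hybrid aCDEs try
#' their members in declared order and the first successful parse wins.
#'
#' @param reg a [cde_registry()] (needed to resolve hybrid members; may be
#'   `NULL` for plain aCDEs)
#' @param cde a `cde_atomic` or its id
#' @param raw the raw value
#' @param entered_unit optional entered unit of measure
#' @return list with `value` (a `cde_value`), `finding` (data.frame, zero
#'   rows when clean) and `member` (matched member id for hybrids, else
#'   `NA`)
#' @export
check_value <- function(reg, cde, raw, entered_unit = NULL) {
  if (is.character(cde)) cde <- get_cde(reg, cde)
  stopifnot(inherits(cde, "cde_atomic"))
  if (is.null(raw) || length(raw) == 0 || is.na(raw) ||
      !nzchar(trimws(as.character(raw))))
    return(list(value = v_null(), finding = empty_findings(),
                member = NA_character_))
  raw <- as.character(raw)
  if (cde$subtype == "hybrid") {
    for (m in cde$members) {
      mem <- get_cde(reg, m)
      res <- parse_raw(raw, mem$value_domain, entered_unit)
      if (res$ok)
        return(list(value = res$value, finding = empty_findings(),
                    member = m))
    }
    return(list(
      value = v_null(),
      finding = new_finding("hybrid", "error", cde$id,
                            code = "no_member_match",
                            message = sprintf(
                              "'%s' matches none of the member domains (%s)",
                              raw, paste(cde$members, collapse = ", "))),
      member = NA_character_))
  }
  if (cde$subtype == "variable") {
    # vocabulary membership is deferred to the dictionary checks
    return(list(value = v_text(trimws(raw)), finding = empty_findings(),
                member = NA_character_))
  }
  res <- parse_raw(raw, cde$value_domain, entered_unit)
  if (res$ok)
    return(list(value = res$value, finding = empty_findings(),
                member = NA_character_))
  list(value = v_null(),
       finding = new_finding(res$code, "error", cde$id, code = res$code,
                             message = res$message),
       member = NA_character_)
}

# Best-effort typed context when no registry/domain information is at hand
# (standalone rule checks): numbers, ISO dates, HH:MM times, else text.
context_from_record <- function(record, units = NULL) {
  bindings <- list()
  for (id in names(record$values)) {
    raw <- record_raw(record, id)
    bindings[[id]] <- guess_value(raw)
  }
  eval_context(bindings,
               units = unlist(units %||% record$units) %||% character(),
               mode = "lenient")
}

guess_value <- function(raw) {
  if (is.null(raw)) return(v_null())
  raw <- trimws(as.character(raw))
  if (grepl(NUMBER_RE, raw)) return(v_number(as.numeric(raw)))
  if (grepl(DATE_RE, raw)) {
    d <- as.Date(raw, format = "%Y-%m-%d")
    if (!is.na(d)) return(v_date(d))
  }
  if (grepl(HHMM_RE, raw)) return(v_time(raw))
  v_text(raw)
}

resolve_rule <- function(rule) {
  stopifnot(inherits(rule, "cde_rule"))
  rule
}

# -- per-kind checks ----------------------------------------------------------

#' Check a Required rule
#'
#' One error finding per listed reference whose value is null or absent;
#' a zero is a value (zero is not null).
#'
#' @param rule a `cde_rule` of kind Required
#' @param record a [data_record()]
#' @param row optional row index recorded in findings
#' @return data.frame of findings
#' @export
check_required <- function(rule, record, row = NA_integer_) {
  rule <- resolve_rule(rule)
  refs <- unique(collect_refs(rule$expression)$id)
  out <- list()
  for (id in refs) {
    if (!record_has_value(record, id))
      out[[length(out) + 1]] <- new_finding(
        "required", "error", id, rule = rule$id, row = row,
        code = "missing_required",
        message = sprintf("'%s' is required but null", id))
  }
  bind_findings(out)
}

#' Check a Dependent rule
#'
#' For the form `(IF cond target NULL)`: when `cond` is true the target
#' must be null (error otherwise); when false the target is unconstrained;
#' when indeterminate an info finding is recorded.
#'
#' @inheritParams check_required
#' @param ctx optional [eval_context()]; derived from the record with
#'   guessed types when omitted
#' @return data.frame of findings
#' @export
check_dependent <- function(rule, record, ctx = NULL, row = NA_integer_) {
  rule <- resolve_rule(rule)
  if (!is_dependent_form(rule$expression))
    stop_cde("rule '%s' is not a Dependent form", rule$id)
  ctx <- ctx %||% context_from_record(record)
  target <- dependent_target(rule$expression)
  cond <- value_truth(eval_rule(rule$expression$args[[1]], ctx))
  if (cond == "indet")
    return(new_finding("indeterminate", "info", target, rule = rule$id,
                       row = row, code = "indeterminate_condition",
                       message = "dependency condition involves NULL"))
  if (cond == "true" && record_has_value(record, target))
    return(new_finding("dependent", "error", target, rule = rule$id,
                       row = row, code = "target_must_be_null",
                       message = sprintf(
                         "'%s' must be null when the condition holds",
                         target)))
  empty_findings()
}

#' Check an Operated rule
#'
#' Boolean-valued expressions are assertions (error when false, info when
#' indeterminate).  Numeric-valued expressions with a target are
#' derivations: when the target carries a value it is compared to the
#' computed value within tolerance, and when absent the derived value is
#' returned for fill mode.
#'
#' @inheritParams check_dependent
#' @param rel_tol,abs_tol numeric comparison tolerances for derivations
#' @return list with `findings` (data.frame) and `derived` (a `cde_value`
#'   or `NULL`)
#' @export
check_operated <- function(rule, record, ctx = NULL, row = NA_integer_,
                           rel_tol = 1e-6, abs_tol = 1e-9) {
  rule <- resolve_rule(rule)
  ctx <- ctx %||% context_from_record(record)
  val <- eval_rule(rule$expression, ctx)
  findings <- empty_findings()
  derived <- NULL
  refs <- unique(collect_refs(rule$expression)$id)
  site <- rule$target %||% refs[1] %||% NA_character_
  if (val$tag == "boolean") {
    if (!isTRUE(val$payload))
      findings <- new_finding("operated", "error", site, rule = rule$id,
                              row = row, code = "assertion_failed",
                              message = sprintf("assertion %s is false",
                                                rule$expr_text))
  } else if (val$tag %in% c("null", "indeterminate")) {
    findings <- new_finding("indeterminate", "info", site, rule = rule$id,
                            row = row, code = "indeterminate_expression",
                            message = "expression involves NULL")
  } else if (val$tag == "number" && !is.null(rule$target)) {
    derived <- val
    entered <- record_raw(record, rule$target)
    if (!is.null(entered)) {
      if (!grepl(NUMBER_RE, trimws(entered))) {
        findings <- new_finding("operated", "error", rule$target,
                                rule = rule$id, row = row,
                                code = "target_not_numeric",
                                message = sprintf(
                                  "target '%s' is not numeric", entered))
      } else {
        x <- as.numeric(entered)
        tol <- max(abs_tol, rel_tol * abs(val$payload))
        if (abs(x - val$payload) > tol)
          findings <- new_finding("operated", "error", rule$target,
                                  rule = rule$id, row = row,
                                  code = "derivation_mismatch",
                                  message = sprintf(
                                    "entered %s differs from derived %s",
                                    entered, format(val$payload)))
      }
    }
  }
  list(findings = findings, derived = derived)
}

#' Check an Ordered rule
#'
#' Passes when the rule's references occur in the record's `field_order` as
#' a subsequence in the same relative order.  References missing from the
#' field order are skipped with an info finding; a record without a field
#' order yields a single info finding (unverifiable).
#'
#' @inheritParams check_required
#' @return data.frame of findings
#' @export
check_ordered <- function(rule, record, row = NA_integer_) {
  rule <- resolve_rule(rule)
  refs <- collect_refs(rule$expression)$id
  fo <- record$field_order
  if (is.null(fo) || length(fo) == 0)
    return(new_finding("ordered", "info", refs[1], rule = rule$id, row = row,
                       code = "no_field_order",
                       message = "record has no field order; unverifiable"))
  out <- list()
  for (id in setdiff(refs, fo))
    out[[length(out) + 1]] <- new_finding(
      "ordered", "info", id, rule = rule$id, row = row,
      code = "ref_not_in_field_order",
      message = sprintf("'%s' absent from field order; skipped", id))
  present <- refs[refs %in% fo]
  pos <- match(present, fo)
  if (length(pos) >= 2 && any(diff(pos) <= 0))
    out[[length(out) + 1]] <- new_finding(
      "ordered", "error", present[which(diff(pos) <= 0)[1] + 1],
      rule = rule$id, row = row, code = "out_of_order",
      message = sprintf("fields do not follow the declared order (%s)",
                        paste(refs, collapse = " ")))
  bind_findings(out)
}

# -- reports ------------------------------------------------------------------

new_report <- function(findings, hybrid = character(), derived = list()) {
  tallies <- table(factor(findings$kind, levels = FINDING_KINDS))
  structure(list(findings = findings,
                 tallies = as.list(tallies),
                 hybrid_resolutions = hybrid,
                 derived = derived),
            class = "cde_report")
}

#' @export
print.cde_report <- function(x, ...) {
  err <- sum(x$findings$severity == "error")
  warn <- sum(x$findings$severity == "warning")
  info <- sum(x$findings$severity == "info")
  cat(sprintf("<cde_report: %d errors, %d warnings, %d info>\n",
              err, warn, info))
  if (nrow(x$findings) > 0) print(x$findings)
  invisible(x)
}

#' @export
as.data.frame.cde_report <- function(x, ...) x$findings

#' Count error-severity findings in a report
#'
#' @param report a `cde_report`
#' @return integer count
#' @export
report_errors <- function(report) sum(report$findings$severity == "error")

#' Serialize a validation report to JSON
#'
#' @param report a `cde_report`
#' @param path optional file to write; when omitted the JSON text is
#'   returned
#' @return JSON text (invisibly when written to file)
#' @export
report_to_json <- function(report, path = NULL) {
  payload <- list(findings = report$findings,
                  tallies = report$tallies,
                  hybrid_resolutions = as.list(report$hybrid_resolutions),
                  derived = lapply(report$derived, format_value))
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                          pretty = TRUE, na = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# -- record / table validation ------------------------------------------------

rule_kind_order <- c(Required = 1L, Dependent = 2L, Operated = 3L,
                     Ordered = 4L, Dictionary = 5L)

#' Validate a record against a CDE and its constraint rules
#'
#' Runs [check_value()] on every supplied value, then the attached rules in
#' the fixed kind order Required, Dependent, Operated, Ordered, Dictionary
#' (by id within a kind).  For a dictionary composite the reference-table
#' checks run against the registry's dictionary table.
#'
#' @param reg a [cde_registry()]
#' @param cde a composite or atomic CDE, or its id
#' @param record a [data_record()]
#' @param mode `strict` (unknown record keys are an error) or `lenient`
#' @param row optional row index stamped on findings
#' @return a `cde_report`
#' @export
validate_record <- function(reg, cde, record, mode = c("strict", "lenient"),
                            row = NA_integer_) {
  mode <- match.arg(mode)
  if (is.character(cde)) cde <- get_cde(reg, cde)
  stopifnot(inherits(record, "cde_record"))
  is_composite <- inherits(cde, "cde_composite")
  members <- if (is_composite) cde$members else cde$id
  keys <- names(record$values)
  unknown <- keys[!vapply(keys, function(k) !is.null(reg$cdes[[k]]),
                          logical(1))]
  if (mode == "strict" && length(unknown) > 0)
    stop_cde("unknown CDE id '%s' in record", unknown[1])
  if (mode == "strict" && is_composite) {
    outside <- setdiff(keys, members)
    outside <- setdiff(outside, unknown)
    if (length(outside) > 0)
      stop_cde("record key '%s' is not a member of '%s'",
               outside[1], cde$id)
  }

  findings <- list()
  hybrid <- character()
  derived <- list()
  bindings <- list()
  units <- character()

  ordered_keys <- c(intersect(members, keys), setdiff(keys, members))
  for (id in ordered_keys) {
    if (is.null(reg$cdes[[id]])) next
    member <- get_cde(reg, id)
    if (member$semantic_type != "atomic") next
    entered_unit <- record$units[[id]] %||% NULL
    res <- check_value(reg, member, record$values[[id]], entered_unit)
    findings[[length(findings) + 1]] <- transform_row(res$finding, row)
    if (!is.na(res$member)) hybrid[[id]] <- res$member
    bindings[[id]] <- res$value
    units[[id]] <- entered_unit %||% member$value_domain$unit_of_measure %||%
      NA_character_
  }
  # unreferenced members default to null so rules can see them
  for (id in setdiff(members, names(bindings))) {
    member <- reg$cdes[[id]]
    if (is.null(member) || member$semantic_type != "atomic") next
    bindings[[id]] <- v_null()
    units[[id]] <- member$value_domain$unit_of_measure %||% NA_character_
  }
  units <- units[!is.na(units)]
  ctx <- eval_context(bindings, units = units, mode = "lenient")

  rule_ids <- cde$rules %||% character(0)
  if (length(rule_ids) > 0) {
    kinds <- vapply(rule_ids, function(r) get_rule(reg, r)$kind, character(1))
    rule_ids <- rule_ids[order(rule_kind_order[kinds], rule_ids)]
    for (rid in rule_ids) {
      rule <- get_rule(reg, rid)
      f <- switch(rule$kind,
        Required = check_required(rule, record, row = row),
        Dependent = check_dependent(rule, record, ctx = ctx, row = row),
        Operated = {
          res <- check_operated(rule, record, ctx = ctx, row = row)
          if (!is.null(res$derived) && !is.null(rule$target))
            derived[[rule$target]] <- res$derived
          res$findings
        },
        Ordered = check_ordered(rule, record, row = row),
        Dictionary = empty_findings()  # handled with the table below
      )
      findings[[length(findings) + 1]] <- f
    }
  }

  if (is_composite && identical(cde$kind, "dictionary")) {
    table <- reg$dictionaries[[cde$dictionary_ref$table]]
    if (is.null(table)) {
      findings[[length(findings) + 1]] <- new_finding(
        "dictionary_range", "error", cde$id, row = row,
        code = "missing_dictionary",
        message = sprintf("dictionary table '%s' is not registered",
                          cde$dictionary_ref$table))
    } else {
      findings[[length(findings) + 1]] <-
        check_dictionary_rule(cde, table, record, row = row)
    }
  }

  new_report(bind_findings(findings), hybrid = hybrid, derived = derived)
}

transform_row <- function(findings, row) {
  if (nrow(findings) > 0 && !is.na(row)) findings$row <- as.integer(row)
  findings
}

#' Validate a repeated record set row by row
#'
#' Each row is validated independently with [validate_record()]; findings
#' carry their row index and the merged report's counts are the sum of the
#' per-row counts.
#'
#' @inheritParams validate_record
#' @param recordset a [record_set()]
#' @return a `cde_report`
#' @export
validate_table <- function(reg, cde, recordset,
                           mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (is.character(cde)) cde <- get_cde(reg, cde)
  stopifnot(inherits(recordset, "cde_record_set"))
  findings <- list()
  hybrid <- character()
  derived <- list()
  for (i in seq_along(recordset$rows)) {
    rep <- validate_record(reg, cde, recordset$rows[[i]], mode = mode,
                           row = i)
    findings[[length(findings) + 1]] <- rep$findings
    for (id in names(rep$hybrid_resolutions))
      hybrid[[paste0(id, "@", i)]] <- rep$hybrid_resolutions[[id]]
    for (id in names(rep$derived))
      derived[[paste0(id, "@", i)]] <- rep$derived[[id]]
  }
  new_report(bind_findings(findings), hybrid = hybrid, derived = derived)
}
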