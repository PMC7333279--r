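# Dictionary tables and dictionary-cCDE validation ----------------------------
#
# A dictionary cCDE links a composite to a keyed reference table through a
# variable foreign-key member.  The table supplies, per key, a '^'-delimited
# list of permitted units and a JSON cell mapping each unit to an inclusive
# normal range written "lo ~ hi".  Validation then checks (a) the foreign
# key is a table key, (b) the entered unit is offered for that key, (c) the
# numeric result falls inside/outside the unit's normal range consistently
# with the entered abnormal flag, and (d) the clinical-significance field is
# non-null exactly when the flag is 'Abnormal' (the reverse direction -- a
# significance value on a 'Normal' row -- is only a warning).

#' Split a '^'-delimited unit list
#'
#' @param cell a non-empty cell such as `"mEq/L^mmol/L"`
#' @return character vector of units, order preserved, each trimmed
#' @export
parse_units <- function(cell) {
  if (is.null(cell) || is.na(cell) || !nzchar(cell))
    stop_cde("empty unit cell")
  parts <- trimws(strsplit(cell, "^", fixed = TRUE)[[1]])
  if (length(parts) == 0 || any(!nzchar(parts)))
    stop_cde("empty segment in unit list '%s'", cell)
  parts
}

#' Parse a normal-range specification
#'
#' @param spec text of the form `"135 ~ 145"`; bounds are inclusive and a
#'   point interval (`"135~135"`) is allowed
#' @return named numeric vector `c(lo =, hi =)`
#' @export
parse_range <- function(spec) {
  m <- regmatches(spec, regexec(
    "^\\s*([+-]?[0-9.eE+-]+)\\s*~\\s*([+-]?[0-9.eE+-]+)\\s*$", spec))[[1]]
  if (length(m) != 3 || !grepl(NUMBER_RE, m[2]) || !grepl(NUMBER_RE, m[3]))
    stop_cde("malformed range spec '%s'", spec)
  lo <- as.numeric(m[2]); hi <- as.numeric(m[3])
  if (lo > hi) stop_cde("range '%s' has lo > hi", spec)
  c(lo = lo, hi = hi)
}

#' Load a dictionary table from CSV
#'
#' The CSV must have a header naming the key column; the declared unit
#' column holds '^'-delimited unit lists and the declared range column holds
#' a strict-JSON object per row mapping each unit to a `"lo ~ hi"` range.
#' Every range unit must appear in the row's unit list.
#'
#' @param path CSV file path
#' @param id dictionary table id used by `vocabulary_ref`/`dictionary_ref`
#' @param key_column name of the primary-key column
#' @param unit_column optional name of the unit-list column
#' @param range_column optional name of the range-map column
#' @return a `cde_dictionary`
#' @export
load_dictionary <- function(path, id, key_column, unit_column = NULL,
                            range_column = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (!key_column %in% names(df))
    stop_cde("key column '%s' missing from %s", key_column, path)
  keys <- trimws(df[[key_column]])
  if (any(!nzchar(keys))) stop_cde("empty key in row %d",
                                   which(!nzchar(keys))[1])
  if (anyDuplicated(keys))
    stop_cde("duplicate key '%s'", keys[duplicated(keys)][1])
  units <- list(); ranges <- list()
  for (i in seq_along(keys)) {
    key <- keys[i]
    row_units <- character(0)
    if (!is.null(unit_column)) {
      row_units <- tryCatch(parse_units(df[[unit_column]][i]),
        error = function(e) stop_cde("row %d (%s): %s", i, key,
                                     conditionMessage(e)))
    }
    units[[key]] <- row_units
    row_ranges <- list()
    if (!is.null(range_column)) {
      cell <- df[[range_column]][i]
      map <- tryCatch(jsonlite::fromJSON(cell, simplifyVector = FALSE),
        error = function(e) stop_cde(
          "row %d (%s): unparseable range JSON: %s", i, key, cell))
      for (u in names(map)) {
        if (!u %in% row_units)
          stop_cde("row %d (%s): range unit '%s' not in unit list", i, key, u)
        row_ranges[[u]] <- tryCatch(parse_range(map[[u]]),
          error = function(e) stop_cde("row %d (%s): %s", i, key,
                                       conditionMessage(e)))
      }
    }
    ranges[[key]] <- row_ranges
  }
  structure(list(id = id, key_column = key_column,
                 unit_column = unit_column, range_column = range_column,
                 source = path, data = df, keys = keys,
                 units = units, ranges = ranges),
            class = "cde_dictionary")
}

#' @export
print.cde_dictionary <- function(x, ...) {
  cat(sprintf("<cde_dictionary '%s': %d keys on '%s'>\n",
              x$id, length(x$keys), x$key_column))
  invisible(x)
}

#' Look up the normal range for a key and unit
#'
#' @param table a `cde_dictionary`
#' @param key primary-key value (exact match after trimming)
#' @param unit measurement unit; must be one of the units offered for `key`
#' @return named numeric vector `c(lo =, hi =)` (inclusive bounds)
#' @export
lookup_normal_range <- function(table, key, unit) {
  key <- trimws(key)
  if (!key %in% table$keys)
    stop_cde("unknown dictionary key '%s'", key, class = "cdemdr_key_error")
  r <- table$ranges[[key]][[trimws(unit)]]
  if (is.null(r))
    stop_cde("unit '%s' not offered for key '%s'", unit, key,
             class = "cdemdr_unit_error")
  r
}

#' Validate a record against a dictionary cCDE's reference table
#'
#' Runs the dictionary checks described above.  Member roles (which members
#' hold the result value, unit, abnormal flag and significance field) come
#' from the composite's `dictionary_ref`; the unit falls back to the
#' record's entered unit for the result member when no unit member is
#' declared.
#'
#' @param ccde a dictionary-kind `cde_composite`
#' @param table the `cde_dictionary` it references
#' @param record a [data_record()]
#' @param flag_values expected-flag vocabulary, `c(normal, abnormal)`
#' @param row optional row index recorded in findings
#' @return data.frame of findings (zero rows when clean)
#' @export
check_dictionary_rule <- function(ccde, table, record,
                                  flag_values = c("Normal", "Abnormal"),
                                  row = NA_integer_) {
  stopifnot(inherits(ccde, "cde_composite"))
  dr <- ccde$dictionary_ref
  out <- list()
  add <- function(kind, cde, code, msg, severity = "error")
    out[[length(out) + 1]] <<- new_finding(kind, severity, cde, rule = NA,
                                           row = row, code = code,
                                           message = msg)
  raw <- function(id) record_raw(record, id)
  key <- raw(dr$key)
  if (is.null(key)) {
    add("dictionary_range", dr$key, "missing_key",
        "dictionary foreign-key value is missing")
    return(bind_findings(out))
  }
  key <- trimws(key)
  if (!key %in% table$keys) {
    add("dictionary_range", dr$key, "unknown_key",
        sprintf("'%s' is not a key of dictionary '%s'", key, table$id))
    return(bind_findings(out))
  }
  unit <- if (!is.null(dr$unit)) raw(dr$unit)
          else record$units[[dr$result %||% ""]]
  if (!is.null(unit)) {
    unit <- trimws(unit)
    if (!unit %in% table$units[[key]]) {
      add("dictionary_range", dr$unit %||% dr$result, "unknown_unit",
          sprintf("unit '%s' is not offered for '%s'", unit, key))
      unit <- NULL
    }
  }
  flag <- if (!is.null(dr$flag)) raw(dr$flag) else NULL
  result <- if (!is.null(dr$result)) raw(dr$result) else NULL
  if (!is.null(result) && !is.null(unit)) {
    if (!grepl(NUMBER_RE, trimws(result))) {
      add("datatype", dr$result, "nonnumeric_result",
          sprintf("result '%s' is not numeric", result))
    } else {
      rng <- table$ranges[[key]][[unit]]
      if (!is.null(rng)) {
        x <- as.numeric(result)
        expected <- if (x >= rng[["lo"]] && x <= rng[["hi"]])
          flag_values[1] else flag_values[2]
        if (!is.null(flag) && trimws(flag) != expected)
          add("dictionary_flag", dr$flag, "flag_mismatch",
              sprintf("result %s %s is %s for range %s ~ %s; flag says '%s'",
                      result, unit, expected, rng[["lo"]], rng[["hi"]], flag))
      }
    }
  }
  if (!is.null(dr$significance) && !is.null(flag)) {
    sig <- raw(dr$significance)
    if (trimws(flag) == flag_values[2] && is.null(sig))
      add("dictionary_flag", dr$significance, "significance_required",
          sprintf("flag is '%s': significance must be non-null",
                  flag_values[2]))
    if (trimws(flag) == flag_values[1] && !is.null(sig))
      add("dictionary_flag", dr$significance, "significance_unexpected",
          sprintf("flag is '%s': significance should be null",
                  flag_values[1]),
          severity = "warning")
  }
  bind_findings(out)
}
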