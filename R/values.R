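# Runtime values and three-valued (Kleene) logic ------------------------------
#
# Every quantity that flows through rule evaluation or record validation is a
# tagged value.  Comparisons never silently coerce across tags, and any
# comparison touching a null yields `indeterminate` rather than TRUE/FALSE:
# nullness is the Required constraint's business, not the comparison's.

new_value <- function(tag, payload = NULL, unit = NULL) {
  structure(list(tag = tag, payload = payload, unit = unit),
            class = "cde_value")
}

#' Construct runtime values
#'
#' Tagged runtime values used by the rule evaluator and the validation
#' engine.  Tags are one of `number`, `text`, `boolean`, `date`, `time`,
#' `datetime`, `null`, `indeterminate`.
#'
#' @param x payload (numeric, character, logical, `Date`, minutes-since-
#'   midnight, or `POSIXct` depending on the constructor)
#' @param unit optional unit-of-measure label (numbers only)
#' @return a `cde_value`
#' @export
v_number <- function(x, unit = NULL) new_value("number", as.numeric(x), unit)

#' @rdname v_number
#' @export
v_text <- function(x) new_value("text", as.character(x))

#' @rdname v_number
#' @export
v_boolean <- function(x) new_value("boolean", isTRUE(x))

#' @rdname v_number
#' @export
v_date <- function(x) new_value("date", as.Date(x))

#' @rdname v_number
#' @export
v_time <- function(x) {
  # minutes since midnight, or an "HH:MM" string
  if (is.character(x)) x <- parse_hhmm(x)
  new_value("time", as.numeric(x))
}

#' @rdname v_number
#' @export
v_datetime <- function(x) {
  if (is.character(x)) x <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M")
  new_value("datetime", x)
}

#' @rdname v_number
#' @export
v_null <- function() new_value("null")

#' @rdname v_number
#' @export
v_indeterminate <- function() new_value("indeterminate")

#' @export
print.cde_value <- function(x, ...) {
  cat(format_value(x), "\n")
  invisible(x)
}

format_value <- function(v) {
  switch(v$tag,
    null = "NULL",
    indeterminate = "<indeterminate>",
    boolean = if (isTRUE(v$payload)) "true" else "false",
    number = paste0(format(v$payload, scientific = FALSE, trim = TRUE),
                    if (!is.null(v$unit)) paste0(" ", v$unit) else ""),
    text = sprintf("'%s'", v$payload),
    time = sprintf("%02d:%02d", v$payload %/% 60, round(v$payload %% 60)),
    date = format(v$payload, "%Y-%m-%d"),
    datetime = format(v$payload, "%Y-%m-%dT%H:%M", tz = "UTC")
  )
}

#' @rdname v_number
#' @param v a `cde_value`
#' @export
is_null_value <- function(v) {
  inherits(v, "cde_value") && v$tag %in% c("null", "indeterminate")
}

# -- truth codes --------------------------------------------------------------
# Logical results are carried internally as "true"/"false"/"indet".

value_truth <- function(v) {
  switch(v$tag,
    boolean = if (isTRUE(v$payload)) "true" else "false",
    null = ,
    indeterminate = "indet",
    stop_cde("type mismatch: expected a boolean value, got tag '%s'", v$tag)
  )
}

truth_value <- function(code) {
  switch(code,
    true = v_boolean(TRUE),
    false = v_boolean(FALSE),
    indet = v_indeterminate()
  )
}

k_not <- function(a) switch(a, true = "false", false = "true", indet = "indet")

k_and <- function(codes) {
  if (any(codes == "false")) "false"
  else if (any(codes == "indet")) "indet"
  else "true"
}

k_or <- function(codes) {
  if (any(codes == "true")) "true"
  else if (any(codes == "indet")) "indet"
  else "false"
}

# -- comparison ---------------------------------------------------------------

ORDERABLE_TAGS <- c("number", "date", "time", "datetime")

value_rank <- function(v) {
  switch(v$tag,
    number = v$payload,
    time = v$payload,
    date = as.numeric(v$payload),
    datetime = as.numeric(v$payload),
    stop_cde("type mismatch: values of tag '%s' have no ordering", v$tag)
  )
}

# Pairwise comparison under one relational operator; returns a truth code.
compare_values <- function(a, b, op) {
  if (is_null_value(a) || is_null_value(b)) return("indet")
  if (op %in% c("=", "!=")) {
    eq <- if (a$tag != b$tag) {
      FALSE
    } else if (a$tag %in% ORDERABLE_TAGS) {
      isTRUE(value_rank(a) == value_rank(b))
    } else if (a$tag == "text") {
      identical(a$payload, b$payload)
    } else if (a$tag == "boolean") {
      identical(a$payload, b$payload)
    } else {
      stop_cde("cannot test equality on tag '%s'", a$tag)
    }
    if (op == "!=") eq <- !eq
    return(if (eq) "true" else "false")
  }
  if (!(a$tag %in% ORDERABLE_TAGS) || a$tag != b$tag) {
    stop_cde("type mismatch: cannot apply '%s' to tags '%s' and '%s'",
             op, a$tag, b$tag)
  }
  ra <- value_rank(a); rb <- value_rank(b)
  ok <- switch(op,
    "<" = ra < rb, ">" = ra > rb, "<=" = ra <= rb, ">=" = ra >= rb)
  if (isTRUE(ok)) "true" else "false"
}

# -- raw-text parsing against a value domain ---------------------------------

NUMBER_RE <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"
HHMM_RE <- "^([01][0-9]|2[0-3]):[0-5][0-9]$"
DATE_RE <- "^[0-9]{4}-[0-9]{2}-[0-9]{2}$"
DATETIME_RE <- "^[0-9]{4}-[0-9]{2}-[0-9]{2}[T ][0-9]{2}:[0-9]{2}([0-9:]{3})?$"

parse_hhmm <- function(x) {
  if (!grepl(HHMM_RE, x)) stop_cde("not an HH:MM time: '%s'", x)
  p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  p[1] * 60 + p[2]
}

parse_ok <- function(value) list(ok = TRUE, value = value, code = NULL,
                                 message = NULL)
parse_fail <- function(code, fmt, ...) {
  list(ok = FALSE, value = v_null(), code = code,
       message = sprintf(fmt, ...))
}

#' Parse raw text against a value domain
#'
#' Applies the domain's datatype rules: numeric syntax, enumerated code
#' membership, ISO 8601 date/datetime and `HH:MM` time formats, boolean
#' tokens.  An empty or missing raw value parses to null without a finding.
#'
#' @param raw a single raw value (character, or anything coercible)
#' @param domain a [value_domain()]
#' @param entered_unit optional unit of measure supplied with the value
#' @return list with elements `ok`, `value` (a `cde_value`), and on failure
#'   `code` and `message`
#' @export
parse_raw <- function(raw, domain, entered_unit = NULL) {
  if (is.null(raw) || length(raw) == 0) return(parse_ok(v_null()))
  raw <- as.character(raw)
  if (is.na(raw) || !nzchar(trimws(raw))) return(parse_ok(v_null()))
  raw <- trimws(raw)
  switch(domain$datatype,
    numeric = {
      if (!grepl(NUMBER_RE, raw))
        return(parse_fail("datatype", "'%s' is not numeric", raw))
      parse_ok(v_number(as.numeric(raw),
                        unit = entered_unit %||% domain$unit_of_measure))
    },
    text = parse_ok(v_text(raw)),
    enumerated = {
      codes <- domain$permissible_values$code
      if (!(raw %in% codes))
        return(parse_fail("permissible",
                          "'%s' is not among the permissible values (%s)",
                          raw, paste(codes, collapse = ", ")))
      parse_ok(v_text(raw))
    },
    time = {
      if (!grepl(HHMM_RE, raw))
        return(parse_fail("datatype", "'%s' is not an HH:MM time", raw))
      parse_ok(v_time(raw))
    },
    date = {
      d <- if (grepl(DATE_RE, raw)) as.Date(raw, format = "%Y-%m-%d") else NA
      if (is.na(d))
        return(parse_fail("datatype", "'%s' is not an ISO 8601 date", raw))
      parse_ok(v_date(d))
    },
    datetime = {
      dt <- if (grepl(DATETIME_RE, raw))
        as.POSIXct(sub(" ", "T", raw), tz = "UTC", format = "%Y-%m-%dT%H:%M")
      else NA
      if (is.na(dt[1]))
        return(parse_fail("datatype", "'%s' is not an ISO 8601 datetime", raw))
      parse_ok(new_value("datetime", dt))
    },
    boolean = {
      low <- tolower(raw)
      if (!(low %in% c("true", "false")))
        return(parse_fail("datatype", "'%s' is not a boolean", raw))
      parse_ok(v_boolean(low == "true"))
    },
    stop_cde("unknown datatype '%s'", domain$datatype)
  )
}
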