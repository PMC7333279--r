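# Prefix-notation constraint language ----------------------------------------
#
# Constraint rules are written operator-first in parentheses, e.g.
#   (Required CDE40 CDE41)
#   (IF (or (!= CDE20 'Yes') (!= CDE21 'Yes')) CDE22 NULL)
#   (< DE:47618 DE:47619)
# Commas are whitespace, string literals use single quotes, `!=` may be
# printed with an internal space (`! =`), and the NULL keyword is uppercase.
# Element references may carry a single attribute path, `.unit_of_measure`.
#
# Arithmetic operators fold left over two or more numeric arguments
# ((/ a b c) = (a/b)/c); relational operators other than the binary `!=`
# assert a pairwise chain over their arguments (all mutually equal for `=`,
# strictly increasing for `<`, ...).  Comparisons touching NULL are
# indeterminate, and indeterminacy propagates through the logical operators
# (Kleene three-valued logic).

OP_TABLE <- list(
  "+"  = list(class = "arithmetic", min = 2L, max = Inf),
  "-"  = list(class = "arithmetic", min = 2L, max = Inf),
  "*"  = list(class = "arithmetic", min = 2L, max = Inf),
  "/"  = list(class = "arithmetic", min = 2L, max = Inf),
  "="  = list(class = "relational", min = 2L, max = Inf),
  "<"  = list(class = "relational", min = 2L, max = Inf),
  ">"  = list(class = "relational", min = 2L, max = Inf),
  "<=" = list(class = "relational", min = 2L, max = Inf),
  ">=" = list(class = "relational", min = 2L, max = Inf),
  "!=" = list(class = "relational", min = 2L, max = 2L),
  "and" = list(class = "logical", min = 2L, max = Inf),
  "or"  = list(class = "logical", min = 2L, max = Inf),
  "not" = list(class = "logical", min = 1L, max = 1L),
  "IF"  = list(class = "form", min = 3L, max = 3L),
  "Required" = list(class = "form", min = 1L, max = Inf),
  "Ordered"  = list(class = "form", min = 2L, max = Inf)
)

expr_lit <- function(value) {
  structure(list(node = "literal", value = value), class = "cde_expr")
}
expr_ref <- function(id, attr = NULL) {
  structure(list(node = "cde_ref", id = id, attr = attr), class = "cde_expr")
}
expr_apply <- function(op, args) {
  structure(list(node = "apply", op = op, args = args), class = "cde_expr")
}

# -- tokenizer ----------------------------------------------------------------

tokenize_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  src <- chartr(",", " ", text)
  src <- chartr("\u2018\u2019", "''", src)  # typographic quotes
  chars <- strsplit(src, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  push <- function(type, text) toks[[length(toks) + 1]] <<- list(type = type,
                                                                 text = text)
  i <- 1
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1; next }
    if (ch %in% c("(", ")")) { push("paren", ch); i <- i + 1; next }
    if (ch == "'") {
      j <- i + 1
      while (j <= n && chars[j] != "'") j <- j + 1
      if (j > n) stop_cde("unterminated string literal")
      push("string", paste(chars[seq(i + 1, length.out = j - i - 1)],
                           collapse = ""))
      i <- j + 1
      next
    }
    j <- i
    while (j <= n && !grepl("^[\\s()']$", chars[j], perl = TRUE)) j <- j + 1
    push("symbol", paste(chars[i:(j - 1)], collapse = ""))
    i <- j
  }
  # the printed rules sometimes typeset `!=` as `! =`
  merged <- list()
  k <- 1
  while (k <= length(toks)) {
    t <- toks[[k]]
    if (t$type == "symbol" && t$text == "!" && k < length(toks) &&
        toks[[k + 1]]$type == "symbol" && toks[[k + 1]]$text == "=") {
      merged[[length(merged) + 1]] <- list(type = "symbol", text = "!=")
      k <- k + 2
    } else {
      merged[[length(merged) + 1]] <- t
      k <- k + 1
    }
  }
  merged
}

# -- parser -------------------------------------------------------------------

#' Parse a prefix-notation constraint rule
#'
#' @param text a single parenthesized form, e.g. `"(Required CDE40 CDE41)"`
#' @return a `cde_expr` tree with nodes `literal`, `cde_ref` and `apply`
#' @export
#' @examples
#' parse_rule("(IF (or (!= CDE20 'Yes') (!= CDE21 'Yes')) CDE22 NULL)")
parse_rule <- function(text) {
  toks <- tokenize_rule(text)
  if (length(toks) == 0) stop_cde("empty rule text")
  res <- parse_one(toks, 1L)
  if (res$pos <= length(toks))
    stop_cde("trailing tokens after rule: '%s'", toks[[res$pos]]$text)
  if (res$expr$node != "apply")
    stop_cde("a rule must be a single parenthesized form")
  res$expr
}

parse_one <- function(toks, pos) {
  if (pos > length(toks)) stop_cde("unbalanced parentheses: unexpected end")
  t <- toks[[pos]]
  if (t$type == "paren" && t$text == "(") return(parse_form(toks, pos))
  if (t$type == "paren") stop_cde("unexpected ')'")
  list(expr = parse_atom(t), pos = pos + 1L)
}

parse_form <- function(toks, pos) {
  pos <- pos + 1L  # consume '('
  if (pos > length(toks)) stop_cde("unbalanced parentheses: unexpected end")
  head <- toks[[pos]]
  if (head$type != "symbol" || is.null(OP_TABLE[[head$text]]))
    stop_cde("unknown operator '%s'", head$text)
  op <- head$text
  pos <- pos + 1L
  args <- list()
  repeat {
    if (pos > length(toks)) stop_cde("unbalanced parentheses: unexpected end")
    t <- toks[[pos]]
    if (t$type == "paren" && t$text == ")") { pos <- pos + 1L; break }
    res <- parse_one(toks, pos)
    args[[length(args) + 1]] <- res$expr
    pos <- res$pos
  }
  spec <- OP_TABLE[[op]]
  if (length(args) < spec$min || length(args) > spec$max)
    stop_cde("operator '%s' takes %s arguments, got %d", op,
             if (is.infinite(spec$max)) paste0(">= ", spec$min)
             else paste(spec$min, "to", spec$max),
             length(args))
  if (op %in% c("Required", "Ordered")) {
    for (a in args)
      if (a$node != "cde_ref" || !is.null(a$attr))
        stop_cde("'%s' arguments must all be CDE references", op)
  }
  list(expr = expr_apply(op, args), pos = pos)
}

parse_atom <- function(tok) {
  if (tok$type == "string") return(expr_lit(v_text(tok$text)))
  s <- tok$text
  if (s == "NULL") return(expr_lit(v_null()))
  if (grepl(NUMBER_RE, s)) return(expr_lit(v_number(as.numeric(s))))
  if (grepl("\\.unit_of_measure$", s)) {
    id <- sub("\\.unit_of_measure$", "", s)
    if (!is_valid_id(id)) stop_cde("malformed reference '%s'", s)
    return(expr_ref(id, attr = "unit_of_measure"))
  }
  if (is_valid_id(s)) return(expr_ref(s))
  stop_cde("malformed token '%s'", s)
}

# -- canonical text -----------------------------------------------------------

#' Canonical text of an expression
#'
#' Emits the single-space-separated canonical form; `parse_rule(unparse_rule(e))`
#' is structurally identical to `e`.
#'
#' @param expr a `cde_expr`
#' @return a character scalar
#' @export
unparse_rule <- function(expr) {
  stopifnot(inherits(expr, "cde_expr"))
  switch(expr$node,
    literal = unparse_literal(expr$value),
    cde_ref = paste0(expr$id,
                     if (!is.null(expr$attr)) paste0(".", expr$attr) else ""),
    apply = paste0("(", paste(c(expr$op,
                                vapply(expr$args, unparse_rule, character(1))),
                              collapse = " "), ")")
  )
}

unparse_literal <- function(v) {
  switch(v$tag,
    null = "NULL",
    text = sprintf("'%s'", v$payload),
    number = format(v$payload, scientific = FALSE, trim = TRUE, digits = 15),
    boolean = if (isTRUE(v$payload)) "true" else "false",
    stop_cde("literal of tag '%s' has no printed form", v$tag)
  )
}

#' @export
print.cde_expr <- function(x, ...) {
  cat(unparse_rule(x), "\n")
  invisible(x)
}

# -- evaluation ---------------------------------------------------------------

#' Evaluation context for rule expressions
#'
#' @param bindings named list of `cde_value`s, one per referenced CDE id
#'   (an explicit [v_null()] counts as bound)
#' @param units named character vector mapping CDE id to its
#'   `unit_of_measure` attribute value
#' @param mode `strict` (unbound reference is an error) or `lenient`
#'   (unbound maps to NULL with a warning)
#' @return a `cde_context`
#' @export
eval_context <- function(bindings = list(), units = character(),
                         mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  structure(list(bindings = bindings, units = units, mode = mode),
            class = "cde_context")
}

#' Evaluate a constraint expression
#'
#' @param expr a `cde_expr` from [parse_rule()]
#' @param ctx an [eval_context()]
#' @return a `cde_value`; relational and logical results are boolean or
#'   indeterminate, arithmetic results are numbers (null if any operand is
#'   null)
#' @export
#' @examples
#' eval_rule(parse_rule("(/ 70 1.75 1.75)"), eval_context())
eval_rule <- function(expr, ctx = eval_context()) {
  stopifnot(inherits(expr, "cde_expr"))
  switch(expr$node,
    literal = expr$value,
    cde_ref = eval_ref(expr, ctx),
    apply = eval_apply(expr, ctx)
  )
}

eval_ref <- function(expr, ctx) {
  if (!is.null(expr$attr)) {
    u <- ctx$units[[expr$id]] %||% NA_character_
    if (is.na(u)) {
      if (ctx$mode == "strict")
        stop_cde("unbound attribute reference '%s.%s'", expr$id, expr$attr)
      warning(sprintf("unbound attribute '%s.%s' treated as NULL",
                      expr$id, expr$attr), call. = FALSE)
      return(v_null())
    }
    return(v_text(u))
  }
  if (!expr$id %in% names(ctx$bindings)) {
    if (ctx$mode == "strict")
      stop_cde("unbound reference '%s'", expr$id)
    warning(sprintf("unbound reference '%s' treated as NULL", expr$id),
            call. = FALSE)
    return(v_null())
  }
  ctx$bindings[[expr$id]]
}

eval_apply <- function(expr, ctx) {
  op <- expr$op
  spec <- OP_TABLE[[op]]
  switch(spec$class,
    arithmetic = eval_arithmetic(op, expr$args, ctx),
    relational = eval_relational(op, expr$args, ctx),
    logical = eval_logical(op, expr$args, ctx),
    form = eval_form(op, expr$args, ctx)
  )
}

eval_arithmetic <- function(op, args, ctx) {
  vals <- lapply(args, eval_rule, ctx = ctx)
  if (any(vapply(vals, is_null_value, logical(1)))) return(v_null())
  for (v in vals)
    if (v$tag != "number")
      stop_cde("type mismatch: arithmetic '%s' on tag '%s'", op, v$tag)
  nums <- vapply(vals, function(v) v$payload, numeric(1))
  f <- switch(op,
    "+" = `+`, "-" = `-`, "*" = `*`,
    "/" = function(a, b) {
      if (b == 0) stop_cde("division by zero")
      a / b
    })
  v_number(Reduce(f, nums))
}

eval_relational <- function(op, args, ctx) {
  vals <- lapply(args, eval_rule, ctx = ctx)
  codes <- character(0)
  for (k in seq_len(length(vals) - 1))
    codes <- c(codes, compare_values(vals[[k]], vals[[k + 1]], op))
  truth_value(k_and(codes))
}

eval_logical <- function(op, args, ctx) {
  if (op == "not")
    return(truth_value(k_not(value_truth(eval_rule(args[[1]], ctx)))))
  # short-circuit: stop as soon as the outcome is decided
  codes <- character(0)
  for (a in args) {
    code <- value_truth(eval_rule(a, ctx))
    if (op == "and" && code == "false") return(v_boolean(FALSE))
    if (op == "or" && code == "true") return(v_boolean(TRUE))
    codes <- c(codes, code)
  }
  truth_value(if (op == "and") k_and(codes) else k_or(codes))
}

eval_form <- function(op, args, ctx) {
  if (op == "IF") {
    cond <- value_truth(eval_rule(args[[1]], ctx))
    return(switch(cond,
      true = eval_rule(args[[2]], ctx),
      false = eval_rule(args[[3]], ctx),
      indet = v_indeterminate()))
  }
  stop_cde("'%s' forms are checked by the validation engine, not evaluated",
           op)
}

# -- structural queries -------------------------------------------------------

#' Collect CDE references from an expression
#'
#' Depth-first, left-to-right walk; duplicates preserved.
#'
#' @param expr a `cde_expr`
#' @return data.frame with columns `id` and `attr` (`NA` for plain value
#'   references, `"unit_of_measure"` for attribute access)
#' @export
collect_refs <- function(expr) {
  acc <- list()
  walk <- function(e) {
    if (e$node == "cde_ref") {
      acc[[length(acc) + 1]] <<- data.frame(
        id = e$id, attr = e$attr %||% NA_character_,
        stringsAsFactors = FALSE)
    } else if (e$node == "apply") {
      for (a in e$args) walk(a)
    }
  }
  walk(expr)
  if (length(acc) == 0)
    return(data.frame(id = character(), attr = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, acc)
}

#' Classify a rule expression by constraint kind
#'
#' `Required` and `Ordered` classify by head symbol; a form
#' `(IF <boolean-expr> <ref> NULL)` is `Dependent`; everything else is
#' `Operated` (boolean-valued expressions act as assertions, numeric-valued
#' ones as derivations).
#'
#' @param expr a `cde_expr`
#' @return one of `"Required"`, `"Ordered"`, `"Dependent"`, `"Operated"`
#' @export
classify_rule <- function(expr) {
  if (expr$node != "apply") return("Operated")
  if (expr$op %in% c("Required", "Ordered")) return(expr$op)
  if (is_dependent_form(expr)) return("Dependent")
  "Operated"
}

is_dependent_form <- function(expr) {
  expr$node == "apply" && expr$op == "IF" &&
    length(expr$args) == 3 &&
    expr$args[[1]]$node == "apply" &&
    OP_TABLE[[expr$args[[1]]$op]]$class %in% c("relational", "logical") &&
    expr$args[[2]]$node == "cde_ref" && is.null(expr$args[[2]]$attr) &&
    expr$args[[3]]$node == "literal" && expr$args[[3]]$value$tag == "null"
}

#' @rdname classify_rule
#' @return `dependent_target()` returns the governed CDE id, or `NULL` when
#'   the expression is not a Dependent form.
#' @export
dependent_target <- function(expr) {
  if (!is_dependent_form(expr)) return(NULL)
  expr$args[[2]]$id
}
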