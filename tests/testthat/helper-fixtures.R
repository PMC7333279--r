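# Shared fixtures and independent oracles used across the suite.

demo_reg <- function() demo_registry()

# A valid medical-history row (ongoing, end date open).
mh_valid_record <- function() {
  data_record(list(
    "DE:37059" = "Cardiovascular", "DE:47621" = "hypertension",
    "DE:31106" = "Mild", "DE:47618" = "2020-01-01",
    "DE:44078" = "Yes", "DE:47619" = NULL))
}

# A valid sodium laboratory row for the dictionary composite.
sodium_record <- function(result = "138", flag = "Normal",
                          significance = NULL) {
  data_record(list(
    "DE:43938" = "Sodium (Na+)", "DE:43940" = result,
    "DE:43942" = "mEq/L", "DE:43944" = "2020-01-01",
    "DE:47566" = flag, "DE:44135" = significance))
}

errors_of <- function(report) {
  report$findings[report$findings$severity == "error", , drop = FALSE]
}

# -- independent oracles ------------------------------------------------------

# Brute-force recursive evaluator for arithmetic expressions: left fold,
# written independently of the package's evaluator.
oracle_arith <- function(expr) {
  if (expr$node == "literal") return(expr$value$payload)
  vals <- vapply(expr$args, oracle_arith, numeric(1))
  out <- vals[1]
  for (v in vals[-1]) {
    out <- switch(expr$op,
      "+" = out + v, "-" = out - v, "*" = out * v,
      "/" = { if (v == 0) stop("div0"); out / v })
  }
  out
}

# Literal pool whose decimal text round-trips exactly through format/parse.
rand_number <- function() {
  sample(c(0:20, 0.5, 1.5, 2.25, 3.75, 10.5, 0.125), 1)
}

# Random arithmetic expression of bounded depth.
gen_arith_expr <- function(depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.35)
    return(parse_rule(sprintf("(+ %s 0)", format(rand_number()))) $ args[[1]])
  op <- sample(c("+", "-", "*", "/"), 1)
  n_args <- sample(2:3, 1)
  args <- lapply(seq_len(n_args), function(i) gen_arith_expr(depth - 1))
  txt <- paste0("(", op, " ",
                paste(vapply(args, unparse_rule, character(1)),
                      collapse = " "), ")")
  parse_rule(txt)
}

# Random full-language expression (relational/logical/IF/refs/literals)
# that is valid by construction; used for parse/unparse identities.
gen_any_expr <- function(depth = 4) {
  atom <- function() {
    switch(sample(3, 1),
      sprintf("'%s'", sample(c("Yes", "No", "a b", "x"), 1)),
      format(rand_number()),
      sample(c("CDE20", "CDE21", "DE:47618", "ref_1"), 1))
  }
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.3) return(atom())
    op <- sample(c("+", "-", "*", "/", "=", "<", ">", "<=", ">=", "!=",
                   "and", "or", "not", "IF", "Required", "Ordered"), 1)
    n <- switch(op, "not" = 1, "!=" = 2, "IF" = 3, sample(2:3, 1))
    args <- if (op %in% c("Required", "Ordered")) {
      sample(c("CDE20", "CDE21", "CDE22", "DE:47618"), n)
    } else if (op %in% c("and", "or", "not")) {
      vapply(seq_len(n), function(i)
        if (stats::runif(1) < 0.5) build(0) else
          sprintf("(= %s %s)", atom(), atom()), character(1))
    } else {
      vapply(seq_len(n), function(i) build(d - 1), character(1))
    }
    paste0("(", op, " ", paste(args, collapse = " "), ")")
  }
  # top level must be a form
  txt <- build(depth)
  if (!startsWith(txt, "(")) txt <- sprintf("(= %s %s)", txt, atom())
  parse_rule(txt)
}
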