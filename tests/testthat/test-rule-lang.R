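# Prefix-notation parser, canonical text, and three-valued evaluator.

test_that("printed constraint rules parse to the expected structure", {
  e <- parse_rule("(Required CDE40 CDE41)")
  expect_identical(e$op, "Required")
  expect_identical(vapply(e$args, function(a) a$id, character(1)),
                   c("CDE40", "CDE41"))

  e <- parse_rule("(IF (or (!= CDE20 'Yes') (!= CDE21 'Yes')) CDE22 NULL)")
  expect_identical(e$op, "IF")
  expect_identical(e$args[[1]]$op, "or")
  expect_identical(e$args[[2]]$id, "CDE22")
  expect_identical(e$args[[3]]$value$tag, "null")

  # '!=' typeset with an internal space parses identically
  e2 <- parse_rule("(IF (or (! = CDE20 'Yes') (! = CDE21 'Yes')) CDE22 NULL)")
  expect_identical(unparse_rule(e2), unparse_rule(e))

  # namespaced ids keep their colon
  e <- parse_rule("(< DE:47618 DE:47619)")
  expect_identical(e$args[[1]]$id, "DE:47618")

  # attribute access
  e <- parse_rule("(= CDE31.unit_of_measure 'm')")
  expect_identical(e$args[[1]]$attr, "unit_of_measure")

  # commas are whitespace: the trailing token reads as two number literals
  e <- parse_rule("(/ CDE30 CDE31 CDE31 100,100)")
  expect_length(e$args, 5)
  expect_identical(e$args[[4]]$value$payload, 100)
  expect_identical(e$args[[5]]$value$payload, 100)
})

test_that("malformed rules are rejected at parse time", {
  expect_error(parse_rule("(= CDE20"), "unbalanced")
  expect_error(parse_rule("(frobnicate CDE20 CDE21)"), "unknown operator")
  expect_error(parse_rule("(not CDE20 CDE21)"), "arguments")
  expect_error(parse_rule("(!= CDE20 CDE21 CDE22)"), "arguments")
  expect_error(parse_rule("(IF (= 1 1) 2)"), "arguments")
  expect_error(parse_rule("(Required 'Yes')"), "references")
  expect_error(parse_rule("CDE20"), "parenthesized")
  expect_error(parse_rule("(= 'unterminated CDE20)"), "unterminated")
})

test_that("unparse produces canonical text and round-trips", {
  expect_identical(unparse_rule(parse_rule("(Required  CDE40,CDE41)")),
                   "(Required CDE40 CDE41)")
  txt <- "(IF (= CDE31.unit_of_measure 'm') (/ CDE30 CDE31 CDE31) (/ CDE30 CDE31 CDE31 100 100))"
  expect_identical(unparse_rule(parse_rule(txt)), txt)
  # string literals keep their single quotes
  expect_match(unparse_rule(parse_rule("(= CDE20 'Yes')")), "'Yes'",
               fixed = TRUE)
})

test_that("parse/unparse identities hold on random expressions", {
  set.seed(42)
  for (i in 1:100) {
    e <- gen_any_expr(depth = sample(1:5, 1))
    txt <- unparse_rule(e)
    expect_identical(parse_rule(txt), e)
    expect_identical(unparse_rule(parse_rule(txt)), txt)
  }
})

test_that("arithmetic evaluation matches a brute-force left-fold oracle", {
  expect_equal(eval_rule(parse_rule("(/ 70 1.75 1.75)"))$payload,
               70 / 1.75 / 1.75, tolerance = 1e-12)
  set.seed(7)
  n_checked <- 0
  while (n_checked < 1000) {
    e <- gen_arith_expr(depth = sample(1:4, 1))
    expected <- tryCatch(oracle_arith(e), error = function(err) NULL)
    if (is.null(expected)) next  # division by zero: both sides reject
    got <- eval_rule(e)
    expect_identical(got$tag, "number")
    if (expected == 0) {
      expect_lt(abs(got$payload), 1e-12)
    } else {
      expect_lt(abs(got$payload - expected) / abs(expected), 1e-12)
    }
    n_checked <- n_checked + 1
  }
  expect_error(eval_rule(parse_rule("(/ 1 0)")), "division by zero")
  expect_error(eval_rule(parse_rule("(+ 1 'a')")), "type mismatch")
})

test_that("relational chains, IF, and chronology evaluate correctly", {
  expect_true(eval_rule(parse_rule("(= 'No' 'No' 'No')"))$payload)
  expect_false(eval_rule(parse_rule("(= 'No' 'No' 'Yes')"))$payload)
  expect_true(eval_rule(parse_rule("(< 1 2 3)"))$payload)
  expect_false(eval_rule(parse_rule("(< 1 3 2)"))$payload)
  expect_identical(eval_rule(parse_rule("(IF (= 'm' 'm') 1 2)"))$payload, 1)
  expect_identical(eval_rule(parse_rule("(IF (= 'm' 'cm') 1 2)"))$payload, 2)
  ctx <- eval_context(list(a = v_date("2020-01-01"),
                           b = v_date("2019-01-01")))
  expect_false(eval_rule(parse_rule("(< a b)"), ctx)$payload)
  expect_true(eval_rule(parse_rule("(> a b)"), ctx)$payload)
  # equality across different tags is false, not an error
  ctx2 <- eval_context(list(a = v_number(5), b = v_text("5")))
  expect_false(eval_rule(parse_rule("(= a b)"), ctx2)$payload)
})

test_that("chained relational equals the pairwise-and oracle on triples", {
  set.seed(11)
  ops <- c("=", "<", ">", "<=", ">=")
  for (i in 1:200) {
    trip <- sample(c(1:4, NA), 3, replace = TRUE)
    op <- sample(ops, 1)
    bind <- lapply(trip, function(x) if (is.na(x)) v_null() else v_number(x))
    names(bind) <- c("a", "b", "c")
    ctx <- eval_context(bind)
    chained <- eval_rule(parse_rule(sprintf("(%s a b c)", op)), ctx)
    pairwise <- eval_rule(
      parse_rule(sprintf("(and (%s a b) (%s b c))", op, op)), ctx)
    expect_identical(chained$tag, pairwise$tag)
    if (chained$tag == "boolean")
      expect_identical(chained$payload, pairwise$payload)
  }
})

test_that("comparisons involving NULL are indeterminate, never boolean", {
  expect_identical(eval_rule(parse_rule("(< 5 NULL)"))$tag, "indeterminate")
  expect_identical(eval_rule(parse_rule("(= NULL NULL)"))$tag,
                   "indeterminate")
  # property: any relational node containing a NULL-bound ref evaluates
  # indeterminate, and indeterminacy propagates through logical operators
  set.seed(23)
  ids <- c("r1", "r2", "r3")
  for (i in 1:200) {
    null_id <- sample(ids, 1)
    bind <- lapply(ids, function(id)
      if (id == null_id) v_null() else v_number(sample(1:9, 1)))
    names(bind) <- ids
    ctx <- eval_context(bind)
    op <- sample(c("=", "<", ">", "<=", ">=", "!="), 1)
    pair <- sample(ids, 2)
    node <- parse_rule(sprintf("(%s %s %s)", op, pair[1], pair[2]))
    res <- eval_rule(node, ctx)
    if (null_id %in% pair) {
      expect_identical(res$tag, "indeterminate")
      # Kleene: false and indet = false; true or indet = true; else indet
      wrapped <- eval_rule(parse_rule(
        sprintf("(and (= 1 1) (%s %s %s))", op, pair[1], pair[2])), ctx)
      expect_identical(wrapped$tag, "indeterminate")
    } else {
      expect_identical(res$tag, "boolean")
    }
  }
  # short-circuit dominance
  expect_false(eval_rule(parse_rule("(and (= 1 2) (< 5 NULL))"))$payload)
  expect_true(eval_rule(parse_rule("(or (= 1 1) (< 5 NULL))"))$payload)
})

test_that("strict contexts reject unbound references, lenient maps to NULL", {
  e <- parse_rule("(= missing_ref 1)")
  expect_error(eval_rule(e, eval_context(mode = "strict")), "unbound")
  expect_warning(res <- eval_rule(e, eval_context(mode = "lenient")),
                 "unbound")
  expect_identical(res$tag, "indeterminate")
})

test_that("collect_refs walks depth-first with duplicates preserved", {
  refs <- collect_refs(parse_rule(
    "(IF (or (!= CDE20 'Yes') (!= CDE21 'Yes')) CDE22 NULL)"))
  expect_identical(refs$id, c("CDE20", "CDE21", "CDE22"))
  refs <- collect_refs(parse_rule(
    "(IF (= CDE31.unit_of_measure 'm') (/ CDE30 CDE31 CDE31) CDE32)"))
  expect_true(any(refs$id == "CDE31" & refs$attr == "unit_of_measure"))
  expect_identical(sum(refs$id == "CDE31"), 3L)
  expect_identical(nrow(collect_refs(parse_rule("(+ 1 2)"))), 0L)
})

test_that("classify_rule recognizes the four constraint kinds", {
  expect_identical(classify_rule(parse_rule("(Ordered CDE20 CDE21 CDE22)")),
                   "Ordered")
  expect_identical(classify_rule(parse_rule("(Required CDE40)")),
                   "Required")
  dep <- parse_rule("(IF (! = DE:44078 'Yes') DE:47619 NULL)")
  expect_identical(classify_rule(dep), "Dependent")
  expect_identical(dependent_target(dep), "DE:47619")
  expect_identical(classify_rule(parse_rule("(< DE:47618 DE:47619)")),
                   "Operated")
  # IF with a non-NULL alternative is a derivation, not a dependency
  expect_identical(classify_rule(parse_rule("(IF (= a 1) b 2)")),
                   "Operated")
})
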