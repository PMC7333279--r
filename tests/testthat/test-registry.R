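# Registry: registration invariants, signatures, lint.

test_that("register/lookup round-trips all atomic fields", {
  reg <- cde_registry()
  id <- register_atomic(reg, "Body Weight Value",
                        value_domain("numeric", unit_of_measure = "kg"),
                        definition = "measured weight",
                        dec = data_element_concept("Patient", "body weight"))
  cde <- get_cde(reg, id)
  expect_identical(cde$name, "Body Weight Value")
  expect_identical(cde$value_domain$datatype, "numeric")
  expect_identical(cde$value_domain$unit_of_measure, "kg")
  expect_identical(cde$definition, "measured weight")
  expect_identical(cde$dec$object_class, "Patient")
  expect_identical(cde$subtype, "plain")
  expect_identical(lookup_name(reg, "Body Weight Value"), id)
})

test_that("atomic registration enforces subtype invariants", {
  reg <- cde_registry()
  expect_error(register_atomic(reg, "x", value_domain("text"),
                               subtype = "variable"),
               "vocabulary_ref")
  register_atomic(reg, "a", value_domain("numeric"), id = "A1")
  expect_error(register_atomic(reg, "b", value_domain("text"), id = "A1"),
               "duplicate")
  # variable keyed to a dictionary is accepted
  id <- register_atomic(reg, "Laboratory Finding Test Name",
                        value_domain("text"), subtype = "variable",
                        vocabulary_ref = list(table = "DICT:ELECTROLYTE",
                                              key_column = "Lab Test Name"))
  expect_identical(get_cde(reg, id)$subtype, "variable")
  # Ordered rules cannot hang off an atomic element
  register_rule(reg, "(Ordered A1 A1)", id = "R:ORD")
  expect_error(register_atomic(reg, "c", value_domain("text"),
                               rules = "R:ORD"),
               "Ordered")
})

test_that("make_hybrid requires >= 2 plain members with distinct datatypes", {
  reg <- cde_registry()
  t1 <- register_atomic(reg, "Hemodialysis Time", value_domain("time"),
                        id = "DE:43239")
  t2 <- register_atomic(reg, "Hemodialysis Time String",
                        value_domain("enumerated",
                                     permissible_values = c("Start", "Finish")),
                        id = "DE:47614")
  n1 <- register_atomic(reg, "n1", value_domain("numeric"))
  n2 <- register_atomic(reg, "n2", value_domain("numeric"))
  hy <- make_hybrid(reg, "Time", c(t1, t2), id = "DE:47616")
  cde <- get_cde(reg, hy)
  expect_identical(cde$subtype, "hybrid")
  expect_identical(cde$members, c("DE:43239", "DE:47614"))
  expect_error(make_hybrid(reg, "bad", c(n1, n2)), "distinct datatypes")
  expect_error(make_hybrid(reg, "bad", t1), ">= 2")
  expect_error(make_hybrid(reg, "bad", c(t1, hy)), "plain")
})

test_that("compose_cde enforces kind-specific invariants", {
  reg <- demo_reg()
  # repeated composite of the eight dialysis-session members exists
  hemo <- get_cde(reg, "DE:47575")
  expect_identical(hemo$kind, "repeated")
  expect_length(hemo$members, 8)
  expect_identical(hemo$members[1], "DE:47616")  # hybrid member allowed
  lab <- get_cde(reg, "DE:47571")
  expect_identical(lab$kind, "dictionary")
  expect_length(lab$members, 6)
  expect_identical(lab$dictionary_ref$key, "DE:43938")
  # dictionary kind without a variable foreign key is rejected
  expect_error(
    compose_cde(reg, "bad", "dictionary", c("CDE30", "CDE31"),
                dictionary_ref = list(table = "DICT:ELECTROLYTE",
                                      key = "CDE30")),
    "variable")
  expect_error(compose_cde(reg, "bad", "general", "CDE30"), ">= 2")
  expect_error(compose_cde(reg, "bad", "general", c("CDE30", "CDE30")),
               "duplicate")
  expect_error(compose_cde(reg, "bad", "general",
                           c("CDE30", "CDE:SMOKE")), "atomic")
})

test_that("signatures are invariant under whitespace and case", {
  expect_identical(cde_signature("Body  Weight value", "numeric", "kg"),
                   cde_signature("body weight value", "numeric", "kg"))
  expect_identical(cde_signature("name  ", "text"),
                   cde_signature("name", "text"))
  expect_false(identical(cde_signature("x", "numeric"),
                         cde_signature("x", "text")))
  set.seed(5)
  for (i in 1:50) {
    base <- paste(sample(letters, 8), collapse = "")
    name <- paste(base, "value")
    perturbed <- paste0("  ", toupper(base), "   VALUE ")
    s <- cde_signature(name, "numeric", "kg")
    expect_identical(cde_signature(perturbed, "numeric", "kg"), s)
    expect_identical(cde_signature(s_name <- trim_squish(perturbed),
                                   "numeric", "kg"), s)
  }
})

test_that("lint is empty on a sound registry and localizes planted faults", {
  reg <- demo_reg()
  expect_identical(nrow(lint_registry(reg)), 0L)

  mutations <- list(
    list(site = "DE:47616", apply = function(r) {
      r$cdes[["DE:47616"]]$members <- "DE:43239"  # hybrid arity
    }),
    list(site = "DE:47616", apply = function(r) {
      r$cdes[["DE:47616"]]$members <- c("DE:43239", "GONE")
    }),
    list(site = "DE:47575", apply = function(r) {
      r$cdes[["DE:47575"]]$members[1] <- "GONE"
    }),
    list(site = "DE:47575", apply = function(r) {
      r$cdes[["DE:47575"]]$members[2] <- "CDE:SMOKE"  # nested composite
    }),
    list(site = "DE:47574", apply = function(r) {
      # retarget a rule to reference a CDE outside the members
      r$rules[["RULE:MH-1"]]$expression <-
        parse_rule("(< DE:47618 CDE30)")
    }),
    list(site = "CDE32", apply = function(r) {
      # attach an Ordered rule to an atomic element
      r$cdes[["CDE32"]]$rules <- c(r$cdes[["CDE32"]]$rules, "RULE:MH-4")
    }),
    list(site = "DE:43938", apply = function(r) {
      r$cdes[["DE:43938"]]$vocabulary_ref <- NULL
    }),
    list(site = "DE:47571", apply = function(r) {
      r$cdes[["DE:47571"]]$dictionary_ref$table <- "GONE"
    }),
    list(site = "DE:47571", apply = function(r) {
      r$cdes[["DE:47571"]]$dictionary_ref$key <- "DE:43940"  # not variable
    }),
    list(site = "RULE:SMOKE-DEP", apply = function(r) {
      r$rules[["RULE:SMOKE-DEP"]]$kind <- "Required"  # kind mismatch
    })
  )
  for (m in mutations) {
    r <- demo_reg()
    m$apply(r)
    findings <- lint_registry(r)
    expect_gt(nrow(findings), 0)
    expect_true(m$site %in% findings$item,
                info = paste("fault site", m$site, "not named"))
  }
})
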