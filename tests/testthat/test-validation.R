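# Validation engine: value checks, the four constraint kinds, records and
# tables.

test_that("hybrid value checking tries members in order, first match wins", {
  reg <- demo_reg()
  res <- check_value(reg, "DE:47616", "08:00")
  expect_identical(res$member, "DE:43239")
  expect_identical(res$value$tag, "time")
  res <- check_value(reg, "DE:47616", "Finish")
  expect_identical(res$member, "DE:47614")
  expect_identical(res$value$tag, "text")
  res <- check_value(reg, "DE:47616", "banana")
  expect_identical(res$finding$kind, "hybrid")
  # enumerated membership on a plain element
  expect_identical(nrow(check_value(reg, "CDE41", "Female")$finding), 0L)
  expect_identical(check_value(reg, "CDE41", "Elsewhere")$finding$kind,
                   "permissible")
})

test_that("hybrid matching equals exhaustive member trial", {
  reg <- demo_reg()
  hybrid <- get_cde(reg, "DE:47616")
  raws <- c("08:00", "23:59", "24:00", "Start", "Finish", "start", "",
            "banana", "7:30", "12:345", "00:00")
  for (raw in raws) {
    # oracle: try every member domain independently
    matches <- vapply(hybrid$members, function(m)
      parse_raw(raw, get_cde(reg, m)$value_domain)$ok, logical(1))
    res <- check_value(reg, hybrid, raw)
    if (!nzchar(raw)) {
      expect_identical(res$value$tag, "null")
    } else if (any(matches)) {
      expect_identical(res$member, hybrid$members[which(matches)[1]])
      expect_identical(nrow(res$finding), 0L)
    } else {
      expect_identical(res$finding$kind, "hybrid")
    }
  }
})

test_that("required checks flag nulls but never zeros or unlisted fields", {
  reg <- demo_reg()
  rule <- get_rule(reg, "RULE:DEMO-REQ")
  rec <- data_record(list(CDE40 = "63", CDE41 = "Female", CDE42 = NULL))
  expect_identical(nrow(check_required(rule, rec)), 0L)
  rec2 <- data_record(list(CDE40 = NULL, CDE41 = "Female"))
  f <- check_required(rule, rec2)
  expect_identical(nrow(f), 1L)
  expect_identical(f$cde, "CDE40")
  rec3 <- data_record(list(CDE40 = "0", CDE41 = "Female"))
  expect_identical(nrow(check_required(rule, rec3)), 0L)
})

test_that("dependent rules force the target null when the condition holds", {
  reg <- demo_reg()
  rule <- get_rule(reg, "RULE:SMOKE-DEP")
  # nonsmoker with a start age: exactly one error on the target
  f <- check_dependent(rule, data_record(
    list(CDE20 = "No", CDE21 = "No", CDE22 = "35")))
  expect_identical(f$kind, "dependent")
  expect_identical(f$cde, "CDE22")
  # both smokers: condition false, value allowed
  expect_identical(nrow(check_dependent(rule, data_record(
    list(CDE20 = "Yes", CDE21 = "Yes", CDE22 = "35")))), 0L)
  # one indicator null, the other 'No': the second disjunct is decidedly
  # true, so Kleene-or makes the whole condition true and the error fires
  f <- check_dependent(rule, data_record(
    list(CDE20 = NULL, CDE21 = "No", CDE22 = "35")))
  expect_identical(f$kind, "dependent")
  # condition genuinely indeterminate (null or-ed with false): info only
  f <- check_dependent(rule, data_record(
    list(CDE20 = NULL, CDE21 = "Yes", CDE22 = "35")))
  expect_identical(f$kind, "indeterminate")
  expect_identical(f$severity, "info")
  # ongoing/end-date rule
  mh <- get_rule(reg, "RULE:MH-3")
  f <- check_dependent(mh, data_record(
    list("DE:44078" = "No", "DE:47619" = "2020-02-01")))
  expect_identical(f$kind, "dependent")
  expect_identical(f$cde, "DE:47619")
})

test_that("operated rules derive, verify within tolerance, and assert", {
  reg <- demo_reg()
  bmi <- get_rule(reg, "RULE:BMI")
  rec <- data_record(list(CDE30 = "70", CDE31 = "175"))
  ctx <- eval_context(list(CDE30 = v_number(70), CDE31 = v_number(175)),
                      units = c(CDE31 = "cm"))
  res <- check_operated(bmi, rec, ctx = ctx)
  expect_equal(res$derived$payload, 70 * 1e4 / 175^2, tolerance = 1e-9)
  expect_identical(nrow(res$findings), 0L)
  # metre branch via the unit_of_measure attribute
  ctx_m <- eval_context(list(CDE30 = v_number(70), CDE31 = v_number(1.75)),
                        units = c(CDE31 = "m"))
  res <- check_operated(bmi, rec, ctx = ctx_m)
  expect_equal(res$derived$payload, 70 / 1.75^2, tolerance = 1e-9)
  # entered target within tolerance passes, a wrong one is flagged
  rec_ok <- data_record(list(CDE30 = "70", CDE31 = "175",
                             CDE32 = "22.857142857142858"))
  expect_identical(nrow(check_operated(bmi, rec_ok, ctx = ctx)$findings), 0L)
  rec_bad <- data_record(list(CDE30 = "70", CDE31 = "175", CDE32 = "25"))
  f <- check_operated(bmi, rec_bad, ctx = ctx)$findings
  expect_identical(f$code, "derivation_mismatch")
  # date assertion
  lt <- get_rule(reg, "RULE:MH-1")
  ctx_d <- eval_context(list("DE:47618" = v_date("2021-05-01"),
                             "DE:47619" = v_date("2020-01-01")))
  f <- check_operated(lt, data_record(list("DE:47618" = "2021-05-01",
                                           "DE:47619" = "2020-01-01")),
                      ctx = ctx_d)$findings
  expect_identical(f$kind, "operated")
  ctx_n <- eval_context(list("DE:47618" = v_date("2021-05-01"),
                             "DE:47619" = v_null()))
  f <- check_operated(lt, data_record(list("DE:47618" = "2021-05-01")),
                      ctx = ctx_n)$findings
  expect_identical(f$kind, "indeterminate")
  expect_identical(f$severity, "info")
})

test_that("ordered rules check subsequence order of the field layout", {
  reg <- demo_reg()
  rule <- get_rule(reg, "RULE:SMOKE-ORD")
  rec <- function(fo) data_record(
    list(CDE20 = "Yes", CDE21 = "Yes", CDE22 = "35"), field_order = fo)
  expect_identical(nrow(check_ordered(rule, rec(c("CDE20", "CDE21",
                                                  "CDE22")))), 0L)
  f <- check_ordered(rule, rec(c("CDE20", "CDE22", "CDE21")))
  expect_identical(f$severity, "error")
  f <- check_ordered(rule, rec(NULL))
  expect_identical(f$severity, "info")
  # refs missing from the order are skipped with info findings
  f <- check_ordered(rule, rec(c("CDE20", "CDE22")))
  expect_identical(sort(unique(f$severity)), "info")
})

test_that("a fully valid repeated-composite row yields zero errors", {
  reg <- demo_reg()
  rep <- validate_record(reg, "DE:47574", mh_valid_record())
  expect_identical(report_errors(rep), 0L)
  # closed history: not ongoing, end date absent
  closed <- data_record(list(
    "DE:37059" = "Respiratory", "DE:47621" = "asthma",
    "DE:31106" = "Moderate", "DE:47618" = "2019-03-01",
    "DE:44078" = "No", "DE:47619" = NULL))
  expect_identical(report_errors(validate_record(reg, "DE:47574", closed)),
                   0L)
})

test_that("single-fault injections produce errors only at the fault site", {
  reg <- demo_reg()
  base <- list(
    "DE:37059" = "Cardiovascular", "DE:47621" = "hypertension",
    "DE:31106" = "Mild", "DE:47618" = "2020-01-01",
    "DE:44078" = "Yes", "DE:47619" = "2020-06-01")
  faults <- list(
    required = list(site = "DE:37059",
                    mut = function(v) { v["DE:37059"] <- list(NULL); v }),
    dependent = list(site = "DE:47619", mut = function(v) {
      v[["DE:44078"]] <- "No"; v }),
    operated = list(site = "DE:47618", mut = function(v) {
      v[["DE:47619"]] <- "2019-01-01"; v }),
    datatype = list(site = "DE:47618", mut = function(v) {
      v[["DE:47618"]] <- "not-a-date"; v }),
    permissible = list(site = "DE:31106", mut = function(v) {
      v[["DE:31106"]] <- "Catastrophic"; v })
  )
  expect_identical(report_errors(
    validate_record(reg, "DE:47574", data_record(base))), 0L)
  for (kind in names(faults)) {
    f <- faults[[kind]]
    rec <- data_record(f$mut(base))
    errs <- errors_of(validate_record(reg, "DE:47574", rec))
    expect_gt(nrow(errs), 0)
    expect_true(all(errs$cde == f$site),
                info = paste("fault kind", kind))
  }
  # field order violation localizes to the swapped fields
  rec <- data_record(base, field_order = c(
    "DE:37059", "DE:47621", "DE:47618", "DE:31106", "DE:44078", "DE:47619"))
  errs <- errors_of(validate_record(reg, "DE:47574", rec))
  expect_identical(errs$kind, "ordered")
})

test_that("adding a Required reference never decreases the finding count", {
  reg <- demo_reg()
  rec <- data_record(list(CDE40 = NULL, CDE41 = NULL, CDE42 = NULL))
  r1 <- register_rule(reg, "(Required CDE40)")
  r2 <- register_rule(reg, "(Required CDE40 CDE41)")
  r3 <- register_rule(reg, "(Required CDE40 CDE41 CDE42)")
  counts <- vapply(c(r1, r2, r3), function(rid)
    nrow(check_required(get_rule(reg, rid), rec)), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("tables validate row-wise and row order only permutes findings", {
  reg <- demo_reg()
  good <- mh_valid_record()
  bad <- data_record(modifyList(good$values,
                                list("DE:47618" = "never"),
                                keep.null = TRUE))
  rs <- record_set("s1", list(good, bad, good))
  rep <- validate_table(reg, "DE:47574", rs)
  errs <- errors_of(rep)
  expect_identical(nrow(errs), 1L)
  expect_identical(errs$row, 2L)
  expect_identical(errs$kind, "datatype")
  # permuting rows permutes row indices and nothing else
  rs2 <- record_set("s1", list(bad, good, good))
  errs2 <- errors_of(validate_table(reg, "DE:47574", rs2))
  expect_identical(errs2$row, 1L)
  expect_identical(errs2$code, errs$code)
  # empty record set is a valid, empty report
  empty <- validate_table(reg, "DE:47574", record_set("s0", list()))
  expect_identical(nrow(empty$findings), 0L)
  # hemodialysis rows with a hybrid Time member
  hrow <- function(time) data_record(list(
    "DE:47616" = time, "DE:43340" = "120", "DE:43197" = "80",
    "DE:43195" = "72", "DE:43155" = "250", "DE:43092" = "1500",
    "DE:43372" = "90", "DE:43166" = "ok"))
  hs <- record_set("h1", list(hrow("Start"), hrow("08:00"), hrow("x9")))
  hrep <- validate_table(reg, "DE:47575", hs)
  herr <- errors_of(hrep)
  expect_identical(nrow(herr), 1L)
  expect_identical(herr$row, 3L)
  expect_identical(hrep$hybrid_resolutions[["DE:47616@1"]], "DE:47614")
  expect_identical(hrep$hybrid_resolutions[["DE:47616@2"]], "DE:43239")
})

test_that("filling a derived target and re-validating is consistent", {
  reg <- demo_reg()
  rec <- data_record(list(CDE30 = "70", CDE31 = "175"))
  rep <- validate_record(reg, "CDE32", rec)
  derived <- rep$derived[["CDE32"]]
  expect_false(is.null(derived))
  filled <- data_record(list(CDE30 = "70", CDE31 = "175",
                             CDE32 = format(derived$payload, digits = 15)))
  rep2 <- validate_record(reg, "CDE32", filled)
  expect_identical(sum(rep2$findings$kind == "operated"), 0L)
  expect_identical(report_errors(rep2), 0L)
})

test_that("strict mode rejects unknown record keys", {
  reg <- demo_reg()
  rec <- data_record(list(NOPE = "1"))
  expect_error(validate_record(reg, "DE:47574", rec, mode = "strict"),
               "unknown CDE")
})
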