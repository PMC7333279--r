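# Demo registry and deterministic fixture generation --------------------------

#' Demo registry of the worked clinical examples
#'
#' Builds, in code, a registry holding the package's worked examples:
#'
#' * the BMI trio (`CDE30` weight in kg, `CDE31` height in cm, `CDE32`
#'   BMI) with a unit-branching Operated derivation,
#' * the demographics trio (`CDE40` age, `CDE41` gender, `CDE42`
#'   ethnicity) with `(Required CDE40 CDE41)`,
#' * the smoking-history trio (`CDE20`, `CDE21`, `CDE22`) with the
#'   skip-if-nonsmoker Dependent rule and an Ordered rule,
#' * the hemodialysis hybrid Time (`DE:47616` = time `DE:43239` |
#'   enumerated `DE:47614`) inside a repeated composite (`DE:47575`),
#' * the medical-history repeated composite (`DE:47574`) with its four
#'   constraint rules (date order, required fields, ongoing/end-date
#'   dependency, field order),
#' * the electrolyte dictionary composite (`DE:47571`) keyed by the
#'   variable test-name element (`DE:43938`) into the electrolyte
#'   reference table.
#'
#' @param dictionary_csv path of the electrolyte dictionary CSV; defaults
#'   to the copy shipped under `inst/extdata`
#' @return a [cde_registry()]
#' @export
demo_registry <- function(dictionary_csv = system.file(
    "extdata", "electrolyte_dictionary.csv", package = "cdemdr")) {
  reg <- cde_registry()

  # --- BMI: operated derivation with unit branching (kg/cm^2 -> kg/m^2)
  register_atomic(reg, "Body Weight Value",
                  value_domain("numeric", unit_of_measure = "kg"),
                  id = "CDE30")
  register_atomic(reg, "Body Height Value",
                  value_domain("numeric", unit_of_measure = "cm"),
                  id = "CDE31")
  register_rule(reg,
    paste0("(IF (= CDE31.unit_of_measure 'm') (/ CDE30 CDE31 CDE31) ",
           "(* (/ CDE30 CDE31 CDE31) 10000))"),
    id = "RULE:BMI", target = "CDE32",
    description = "BMI = weight / height^2, height in m or cm")
  register_atomic(reg, "Body Mass Index Value",
                  value_domain("numeric", unit_of_measure = "kg/m2"),
                  id = "CDE32", rules = "RULE:BMI")

  # --- demographics: required constraint (ethnicity deliberately optional)
  register_atomic(reg, "Patient Age", value_domain("numeric",
                  unit_of_measure = "years"), id = "CDE40")
  register_atomic(reg, "Patient Gender",
                  value_domain("enumerated", permissible_values = c(
                    "Female", "Male", "Unknown", "Unspecified",
                    "Not reported")), id = "CDE41")
  register_atomic(reg, "Patient Ethnicity",
                  value_domain("enumerated", permissible_values = c(
                    "Hispanic or Latino", "Not Hispanic or Latino",
                    "Unknown", "Not reported")), id = "CDE42")
  register_rule(reg, "(Required CDE40 CDE41)", id = "RULE:DEMO-REQ",
                description = "age and gender are mandatory")
  compose_cde(reg, "Demographics", "general", c("CDE40", "CDE41", "CDE42"),
              id = "CDE:DEMO", rules = "RULE:DEMO-REQ")

  # --- smoking history: dependent skip rule + ordering
  yn <- value_domain("enumerated",
                     permissible_values = c("Yes", "No", "Unknown"))
  register_atomic(reg, "Current Smoking Indicator", yn, id = "CDE20")
  register_atomic(reg, "Past Smoking Indicator", yn, id = "CDE21")
  register_atomic(reg, "Age When Tobacco Use Started",
                  value_domain("numeric", unit_of_measure = "years"),
                  id = "CDE22")
  register_rule(reg,
    "(IF (or (!= CDE20 'Yes') (!= CDE21 'Yes')) CDE22 NULL)",
    id = "RULE:SMOKE-DEP",
    description = "skip start age unless both indicators are 'Yes'")
  register_rule(reg, "(Ordered CDE20 CDE21 CDE22)", id = "RULE:SMOKE-ORD")
  compose_cde(reg, "Smoking History", "general",
              c("CDE20", "CDE21", "CDE22"), id = "CDE:SMOKE",
              rules = c("RULE:SMOKE-DEP", "RULE:SMOKE-ORD"))

  # --- hemodialysis session: hybrid Time inside a repeated composite
  register_atomic(reg, "Hemodialysis Time",
                  value_domain("time"), id = "DE:43239")
  register_atomic(reg, "Hemodialysis Time String",
                  value_domain("enumerated",
                               permissible_values = c("Start", "Finish")),
                  id = "DE:47614")
  make_hybrid(reg, "Time", c("DE:43239", "DE:47614"), id = "DE:47616")
  register_atomic(reg, "Blood Pressure Systolic",
                  value_domain("numeric", unit_of_measure = "mmHg"),
                  id = "DE:43340")
  register_atomic(reg, "Blood Pressure Diastolic",
                  value_domain("numeric", unit_of_measure = "mmHg"),
                  id = "DE:43197")
  register_atomic(reg, "Pulse Rate",
                  value_domain("numeric", unit_of_measure = "beats/min"),
                  id = "DE:43195")
  register_atomic(reg, "Blood Flow Rate",
                  value_domain("numeric", unit_of_measure = "mL/min"),
                  id = "DE:43155")
  register_atomic(reg, "Ultrafiltration Volume",
                  value_domain("numeric", unit_of_measure = "mL"),
                  id = "DE:43092")
  register_atomic(reg, "Venous Pressure",
                  value_domain("numeric", unit_of_measure = "mmHg"),
                  id = "DE:43372")
  register_atomic(reg, "Session Note", value_domain("text"),
                  id = "DE:43166")
  register_rule(reg,
    "(Required DE:47616 DE:43340 DE:43197)", id = "RULE:HEMO-REQ")
  compose_cde(reg, "Hemodialysis Session", "repeated",
              c("DE:47616", "DE:43340", "DE:43197", "DE:43195", "DE:43155",
                "DE:43092", "DE:43372", "DE:43166"),
              id = "DE:47575", rules = "RULE:HEMO-REQ")

  # --- medical history: repeated composite with all four constraint kinds
  register_atomic(reg, "Medical History Body System",
                  value_domain("enumerated", permissible_values = c(
                    "Cardiovascular", "Respiratory", "Neurologic",
                    "Gastrointestinal", "Endocrine", "Other")),
                  id = "DE:37059")
  register_atomic(reg, "Medical History Specify", value_domain("text"),
                  id = "DE:47621")
  register_atomic(reg, "Medical History Severity",
                  value_domain("enumerated", permissible_values = c(
                    "Mild", "Moderate", "Severe")), id = "DE:31106")
  register_atomic(reg, "Medical History Start Date",
                  value_domain("date"), id = "DE:47618")
  register_atomic(reg, "Medical History Ongoing Indicator", yn,
                  id = "DE:44078")
  register_atomic(reg, "Medical History End Date",
                  value_domain("date"), id = "DE:47619")
  register_rule(reg, "(< DE:47618 DE:47619)", id = "RULE:MH-1",
                description = "start date precedes end date")
  register_rule(reg,
    "(Required DE:37059 DE:47621 DE:31106 DE:47618 DE:44078)",
    id = "RULE:MH-2", description = "all fields except end date required")
  register_rule(reg, "(IF (! = DE:44078 'Yes') DE:47619 NULL)",
                id = "RULE:MH-3",
                description = "no end date unless history is ongoing")
  register_rule(reg,
    "(Ordered DE:37059 DE:47621 DE:31106 DE:47618 DE:44078 DE:47619)",
    id = "RULE:MH-4")
  compose_cde(reg, "Medical History", "repeated",
              c("DE:37059", "DE:47621", "DE:31106", "DE:47618", "DE:44078",
                "DE:47619"),
              id = "DE:47574",
              rules = c("RULE:MH-1", "RULE:MH-2", "RULE:MH-3", "RULE:MH-4"))

  # --- electrolyte labs: dictionary composite
  dict <- load_dictionary(dictionary_csv, id = "DICT:ELECTROLYTE",
                          key_column = "Lab Test Name",
                          unit_column = "Unit of Result",
                          range_column = "Normal Range")
  register_dictionary(reg, dict)
  register_atomic(reg, "Laboratory Finding Test Name",
                  value_domain("text"), id = "DE:43938",
                  subtype = "variable",
                  vocabulary_ref = list(table = "DICT:ELECTROLYTE",
                                        key_column = "Lab Test Name"))
  register_atomic(reg, "Laboratory Test Result Value",
                  value_domain("numeric"), id = "DE:43940")
  register_atomic(reg, "Laboratory Test Result Unit",
                  value_domain("text"), id = "DE:43942")
  register_atomic(reg, "Laboratory Test Date", value_domain("date"),
                  id = "DE:43944")
  register_atomic(reg, "Test Result Abnormal Indicator",
                  value_domain("enumerated",
                               permissible_values = c("Normal", "Abnormal")),
                  id = "DE:47566")
  register_atomic(reg, "Clinically Significant Indicator", yn,
                  id = "DE:44135")
  register_rule(reg, "(Required DE:43938 DE:43940 DE:43942)",
                id = "RULE:LAB-REQ")
  compose_cde(reg, "Electrolyte Laboratory Tests", "dictionary",
              c("DE:43938", "DE:43940", "DE:43942", "DE:43944", "DE:47566",
                "DE:44135"),
              id = "DE:47571", rules = "RULE:LAB-REQ",
              dictionary_ref = list(table = "DICT:ELECTROLYTE",
                                    key = "DE:43938", result = "DE:43940",
                                    unit = "DE:43942", flag = "DE:47566",
                                    significance = "DE:44135"))
  reg
}

#' Fixture specification
#'
#' Parameters of the deterministic synthetic-fixture generator.  The
#' defaults mirror the evaluated study layout: five groups (hospitals) of
#' five clinical documents drawing elements from a shared pool, about a
#' third of the unique elements gathered into composites, and a dozen
#' medical-history rows with a planted violation plan.
#'
#' @param seed integer RNG seed; identical seeds give identical fixtures
#' @param n_groups number of groups (hospitals)
#' @param n_documents documents per group
#' @param pool_size size of the shared element pool documents draw from
#' @param reuse_probability chance that a document slot re-draws an element
#'   already used in its group (drives the reuse rate)
#' @param composite_fraction fraction of each group's unique elements
#'   gathered into composites of three
#' @param doc_size_range inclusive range of occurrences per document
#' @param n_rows medical-history rows generated
#' @param violation_plan named integer vector of planted single-fault
#'   violations per check kind; supported kinds: `required`, `dependent`,
#'   `operated`, `datatype`
#' @return a `cde_fixture_spec`
#' @export
fixture_spec <- function(seed = 1L, n_groups = 5L, n_documents = 5L,
                         pool_size = 60L, reuse_probability = 0.35,
                         composite_fraction = 0.3,
                         doc_size_range = c(8L, 20L), n_rows = 12L,
                         violation_plan = c(required = 2L, dependent = 2L,
                                            operated = 1L, datatype = 1L)) {
  stopifnot(reuse_probability >= 0, reuse_probability <= 1,
            composite_fraction >= 0, composite_fraction <= 1,
            all(violation_plan >= 0), n_rows >= 0)
  if (sum(violation_plan) > n_rows)
    stop_cde("infeasible plan: %d violations for %d rows",
             sum(violation_plan), n_rows)
  structure(list(seed = as.integer(seed), n_groups = n_groups,
                 n_documents = n_documents, pool_size = pool_size,
                 reuse_probability = reuse_probability,
                 composite_fraction = composite_fraction,
                 doc_size_range = doc_size_range, n_rows = n_rows,
                 violation_plan = violation_plan),
            class = "cde_fixture_spec")
}

#' Generate a synthetic fixture with planted ground truth
#'
#' Writes four artifacts to `outdir`: `registry.json` (the demo registry
#' plus its dictionary CSV), `corpus.json` (a synthetic extraction corpus
#' over a shared element pool), `records.csv` (medical-history rows with
#' planted violations) and `answer_key.json` (the planted per-group corpus
#' counts and per-kind expected error counts, recorded by the generator
#' from its own draws).  Identical seeds give byte-identical outputs.
#'
#' @param spec a [fixture_spec()]
#' @param outdir output directory (created if missing)
#' @return invisibly, a list with the artifact paths and the answer key
#' @export
generate_fixture <- function(spec, outdir) {
  stopifnot(inherits(spec, "cde_fixture_spec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  with_preserved_seed(spec$seed, {
    paths <- list(
      registry = file.path(outdir, "registry.json"),
      dictionary = file.path(outdir, "electrolyte_dictionary.csv"),
      corpus = file.path(outdir, "corpus.json"),
      records = file.path(outdir, "records.csv"),
      answer_key = file.path(outdir, "answer_key.json"))

    file.copy(system.file("extdata", "electrolyte_dictionary.csv",
                          package = "cdemdr"),
              paths$dictionary, overwrite = TRUE)
    reg <- demo_registry(paths$dictionary)
    for (d in names(reg$dictionaries)) reg$dictionaries[[d]]$source <-
      "electrolyte_dictionary.csv"
    save_registry(reg, paths$registry)

    corpus_truth <- generate_corpus(spec, paths$corpus)
    record_truth <- generate_records(spec, reg, paths$records)

    key <- list(seed = spec$seed, corpus = corpus_truth,
                violations = as.list(record_truth))
    writeLines(jsonlite::toJSON(sort_keys(key), auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
               paths$answer_key)
    invisible(c(paths, list(answer_key_data = key)))
  })
}

generate_corpus <- function(spec, path) {
  pool <- sprintf("elem_%03d", seq_len(spec$pool_size))
  groups <- list()
  truth <- list()
  all_occs <- character(0)
  all_doc_sets <- list()
  all_comp_ids <- character(0)
  all_members <- character(0)
  for (g in seq_len(spec$n_groups)) {
    gname <- sprintf("group_%02d", g)
    used <- character(0)
    docs <- list()
    for (d in seq_len(spec$n_documents)) {
      size <- sample(seq(spec$doc_size_range[1], spec$doc_size_range[2]), 1)
      occ <- character(size)
      for (k in seq_len(size)) {
        reuse <- length(used) > 0 &&
          stats::runif(1) < spec$reuse_probability
        occ[k] <- if (reuse) sample(used, 1) else sample(pool, 1)
        used <- union(used, occ[k])
      }
      docs[[d]] <- list(name = sprintf("doc_%02d", d),
                        occurrences = unique_preserve(occ))
    }
    doc_occs <- lapply(docs, function(d) d$occurrences)
    occs <- unlist(doc_occs)
    uniq <- unique(occs)
    n_comp_members <- floor(length(uniq) * spec$composite_fraction)
    n_comp <- n_comp_members %/% 3L
    comp <- list()
    captured <- character(0)
    if (n_comp > 0) {
      chosen <- uniq[seq_len(n_comp * 3L)]
      for (c_ in seq_len(n_comp)) {
        mem <- chosen[(3L * (c_ - 1L) + 1L):(3L * c_)]
        comp[[c_]] <- list(id = sprintf("%s_ccde_%02d", gname, c_),
                           members = mem)
        captured <- c(captured, mem)
      }
    }
    groups[[g]] <- list(name = gname, documents = docs, composites = comp)
    # answer key for this group, from the generator's own draws
    doc_tab <- table(unlist(lapply(doc_occs, unique)))
    truth[[gname]] <- list(
      n_total = length(occs), n_unique = length(uniq),
      n_ccde = length(comp), captured_unique = length(unique(captured)),
      n_reused = sum(doc_tab >= 2))
    all_occs <- c(all_occs, occs)
    all_doc_sets <- c(all_doc_sets, lapply(doc_occs, unique))
    all_comp_ids <- c(all_comp_ids,
                      vapply(comp, function(cc) cc$id, character(1)))
    all_members <- c(all_members, captured)
  }
  overall_tab <- table(unlist(all_doc_sets))
  truth$overall <- list(
    n_total = length(all_occs), n_unique = length(unique(all_occs)),
    n_ccde = length(unique(all_comp_ids)),
    captured_unique = length(intersect(unique(all_members),
                                       unique(all_occs))),
    n_reused = sum(overall_tab >= 2))
  save_corpus(new_corpus(groups), path)
  truth
}

# De-duplicate per document while keeping first-seen order: a document
# lists each element once, as on a real form.
unique_preserve <- function(x) x[!duplicated(x)]

generate_records <- function(spec, reg, path) {
  members <- c("DE:37059", "DE:47621", "DE:31106", "DE:47618", "DE:44078",
               "DE:47619")
  systems <- get_cde(reg, "DE:37059")$value_domain$permissible_values$code
  severities <- get_cde(reg, "DE:31106")$value_domain$permissible_values$code
  n <- spec$n_rows
  plan <- spec$violation_plan
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    start <- as.Date("2018-01-01") + sample(0:1000, 1)
    ongoing <- sample(c("Yes", "No"), 1)
    end <- if (ongoing == "Yes" && stats::runif(1) < 0.5)
      format(start + sample(1:400, 1)) else ""
    rows[[i]] <- c(sample(systems, 1),
                   sprintf("condition %02d", sample(1:99, 1)),
                   sample(severities, 1), format(start), ongoing, end)
  }
  # plant single-fault violations, one per row, in the leading rows
  kinds <- rep(names(plan), times = plan)
  for (j in seq_along(kinds)) {
    r <- rows[[j]]
    start <- as.Date(r[4])
    r <- switch(kinds[j],
      required = { r[1] <- ""; r },
      dependent = { r[5] <- "No"; r[6] <- format(start + 30); r },
      operated = { r[5] <- "Yes"; r[6] <- format(start - 30); r },
      datatype = { r[4] <- "not-a-date"; r })
    rows[[j]] <- r
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- members
  df <- cbind(`__set_id` = "medical_history", df)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  plan
}
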