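# Integration and reuse metrics ----------------------------------------------
#
# An extraction corpus lists, per group (a hospital or resource collection)
# and per document, the CDE occurrences extracted from that document
# (identified by registry id or by signature), together with the composite
# groupings assigned to each group.  The metrics reduce those occurrence
# lists to the reported counts and percentages:
#
#   n_total            occurrences extracted (with multiplicity)
#   n_unique           distinct signatures
#   n_ccde             distinct composites
#   captured_total     occurrences whose signature sits inside a composite
#   captured_unique    distinct signatures inside composites
#   n_free             n_unique - captured_unique
#   representation     n_ccde + n_free  (elements needed to represent all)
#
#   reuse_rate               = (n_total - n_unique) / n_total x 100
#   capture_share            = captured / denominator x 100
#   representation_efficiency = representation / n_total x 100
#   integration_reuse_ratio  = (n_total - n_ccde - n_unique) / n_total x 100
#
# All percentages are rounded half-up to one decimal.

#' Build or load an extraction corpus
#'
#' @param groups list of groups; each group is
#'   `list(name =, documents = list(list(name =, occurrences = chr)),
#'   composites = list(list(id =, members = chr)))`
#' @return a `cde_corpus`
#' @export
new_corpus <- function(groups) {
  structure(list(groups = groups), class = "cde_corpus")
}

#' @rdname new_corpus
#' @param path JSON file in the corpus dialect (either the full
#'   occurrence-list form or the counts-only form `{"counts": {...}}`)
#' @export
load_corpus <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(raw$counts))
    return(structure(list(counts = lapply(raw$counts, as.numeric)),
                     class = "cde_corpus"))
  groups <- lapply(raw$groups, function(g) {
    list(name = g$name,
         documents = lapply(g$documents, function(d)
           list(name = d$name,
                occurrences = vapply(d$occurrences, as.character,
                                     character(1)))),
         composites = lapply(g$composites %||% list(), function(cc)
           list(id = cc$id,
                members = vapply(cc$members, as.character, character(1)))))
  })
  new_corpus(groups)
}

#' Save a corpus to canonical JSON
#'
#' @param corpus a `cde_corpus`
#' @param path output file
#' @export
save_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "cde_corpus"))
  payload <- if (!is.null(corpus$counts)) list(counts = corpus$counts)
             else list(groups = corpus$groups)
  txt <- jsonlite::toJSON(sort_keys(payload), auto_unbox = TRUE, digits = NA,
                          pretty = TRUE)
  writeLines(txt, path)
  invisible(path)
}

corpus_documents <- function(corpus, scope = NULL) {
  groups <- corpus$groups
  if (!is.null(scope)) {
    names_ <- vapply(groups, function(g) g$name, character(1))
    if (!scope %in% names_) stop_cde("unknown group '%s'", scope)
    groups <- groups[names_ == scope]
  }
  docs <- list()
  for (g in groups) for (d in g$documents) docs[[length(docs) + 1]] <- d
  docs
}

corpus_composites <- function(corpus, scope = NULL) {
  groups <- corpus$groups
  if (!is.null(scope)) {
    names_ <- vapply(groups, function(g) g$name, character(1))
    groups <- groups[names_ == scope]
  }
  comps <- list()
  for (g in groups) for (cc in g$composites %||% list())
    comps[[length(comps) + 1]] <- cc
  comps
}

#' Deduplicate CDE occurrences
#'
#' @param corpus a `cde_corpus` with occurrence lists
#' @param scope a group name, or `NULL` for the pooled corpus
#' @return list with `n_total`, `n_unique`, `unique_signatures`, and
#'   `reused` (the signatures occurring in at least two documents of the
#'   scope)
#' @export
deduplicate_corpus <- function(corpus, scope = NULL) {
  stopifnot(inherits(corpus, "cde_corpus"))
  if (!is.null(corpus$counts)) stop_cde("counts-only corpus has no occurrences")
  docs <- corpus_documents(corpus, scope)
  if (length(docs) == 0) stop_cde("empty corpus")
  occs <- unlist(lapply(docs, function(d) d$occurrences))
  if (length(occs) == 0) stop_cde("empty corpus")
  if (any(!nzchar(occs))) stop_cde("empty occurrence signature")
  per_doc <- lapply(docs, function(d) unique(d$occurrences))
  doc_counts <- table(unlist(per_doc))
  list(n_total = length(occs),
       n_unique = length(unique(occs)),
       unique_signatures = sort(unique(occs)),
       reused = sort(names(doc_counts)[doc_counts >= 2]))
}

check_pct_inputs <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_cde("counts must be finite and non-negative")
}

#' Reuse, capture and integration percentages
#'
#' `reuse_rate(n_total, n_unique)` is the share of extracted occurrences
#' that were repeats of an already-seen element,
#' `(n_total - n_unique) / n_total x 100`.
#'
#' @param n_total occurrences extracted
#' @param n_unique distinct elements among them
#' @return percentage rounded half-up to one decimal
#' @export
#' @examples
#' reuse_rate(322, 227)   # 29.5
#' reuse_rate(1142, 586)  # 48.7
reuse_rate <- function(n_total, n_unique) {
  check_pct_inputs(n_total, n_unique)
  if (n_total <= 0) stop_cde("n_total must be positive")
  if (n_unique > n_total || n_unique <= 0)
    stop_cde("need 0 < n_unique <= n_total")
  round_half_up((n_total - n_unique) / n_total * 100, 1)
}

#' @rdname reuse_rate
#' @param n_ccde_unique distinct composites created during integration
#' @details `integration_reuse_ratio(n_total, n_ccde_unique, n_unique)` is
#'   the reduction achieved when `n_ccde_unique` composites plus the
#'   remaining free atomics replace the original occurrence list:
#'   `(n_total - n_ccde_unique - n_unique) / n_total x 100`.
#' @export
#' @examples
#' integration_reuse_ratio(1142, 20, 586)  # 46.9
integration_reuse_ratio <- function(n_total, n_ccde_unique, n_unique) {
  check_pct_inputs(n_total, n_ccde_unique, n_unique)
  if (n_total <= 0) stop_cde("n_total must be positive")
  if (n_ccde_unique + n_unique > n_total)
    stop_cde("need n_ccde_unique + n_unique <= n_total")
  round_half_up((n_total - n_ccde_unique - n_unique) / n_total * 100, 1)
}

#' @rdname reuse_rate
#' @param n_captured elements captured inside composites
#' @param denominator the base the share is taken over (unique elements or
#'   total extracted; both denominators are in reported use, so the choice
#'   is explicit)
#' @export
#' @examples
#' capture_share(110, 227)  # 48.5
capture_share <- function(n_captured, denominator) {
  check_pct_inputs(n_captured, denominator)
  if (denominator <= 0) stop_cde("denominator must be positive")
  if (n_captured > denominator) stop_cde("need n_captured <= denominator")
  round_half_up(n_captured / denominator * 100, 1)
}

#' @rdname reuse_rate
#' @param n_ccde composites
#' @param n_free atomics left outside every composite
#' @return `representation_count()` returns the integer `n_ccde + n_free`.
#' @export
#' @examples
#' representation_count(16, 117)  # 133
representation_count <- function(n_ccde, n_free) {
  check_pct_inputs(n_ccde, n_free)
  as.integer(n_ccde + n_free)
}

metrics_row <- function(group, n_total, n_unique, n_ccde, captured_total,
                        captured_unique) {
  n_free <- n_unique - captured_unique
  rep_count <- representation_count(n_ccde, n_free)
  data.frame(
    group = group, n_total = n_total, n_unique = n_unique, n_ccde = n_ccde,
    captured_total = captured_total, captured_unique = captured_unique,
    n_free = n_free, representation_count = rep_count,
    reuse_rate = reuse_rate(n_total, n_unique),
    capture_share = if (n_unique > 0) capture_share(captured_unique, n_unique)
                    else 0,
    representation_efficiency = capture_share(rep_count, n_total),
    integration_reuse_ratio = integration_reuse_ratio(n_total, n_ccde,
                                                      n_unique),
    stringsAsFactors = FALSE)
}

#' Integration report over a corpus
#'
#' Computes all counts and the four percentages per group plus an overall
#' row; the overall deduplication runs over the pooled corpus, so the
#' overall `n_unique` can be smaller than the sum of the per-group uniques.
#' A counts-only corpus computes the percentages directly from the supplied
#' counts.
#'
#' @param corpus a `cde_corpus`
#' @return a data.frame of class `cde_metrics` (one row per group +
#'   `overall`)
#' @export
metrics_report <- function(corpus) {
  stopifnot(inherits(corpus, "cde_corpus"))
  if (!is.null(corpus$counts)) {
    ct <- corpus$counts
    row <- metrics_row("overall", ct$n_total, ct$n_unique,
                       ct$n_ccde_unique %||% 0,
                       ct$n_captured_total %||% ct$n_captured %||% 0,
                       ct$n_captured %||% 0)
    class(row) <- c("cde_metrics", class(row))
    return(row)
  }
  rows <- list()
  scopes <- c(vapply(corpus$groups, function(g) g$name, character(1)),
              NA_character_)
  for (scope in scopes) {
    sc <- if (is.na(scope)) NULL else scope
    dd <- deduplicate_corpus(corpus, sc)
    comps <- corpus_composites(corpus, sc)
    comp_ids <- unique(vapply(comps, function(cc) cc$id, character(1)))
    captured_sigs <- unique(unlist(lapply(comps, function(cc) cc$members)))
    captured_sigs <- intersect(captured_sigs, dd$unique_signatures)
    occs <- unlist(lapply(corpus_documents(corpus, sc),
                          function(d) d$occurrences))
    rows[[length(rows) + 1]] <- metrics_row(
      if (is.na(scope)) "overall" else scope,
      dd$n_total, dd$n_unique, length(comp_ids),
      sum(occs %in% captured_sigs), length(captured_sigs))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cde_metrics", class(out))
  out
}

#' Write an integration report as CSV
#'
#' @param report a `cde_metrics` data.frame from [metrics_report()]
#' @param path output CSV path
#' @export
write_metrics_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
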