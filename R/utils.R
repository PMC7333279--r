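`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
trim_squish <- function(x) {
  gsub("\\s+", " ", trimws(x))
}

#' Round half away from zero
#'
#' Percentages are rounded half-up to a fixed number of decimals (so 37.85
#' prints as 37.9), the convention used throughout the reported statistics.
#' Base R's `round()` uses banker's rounding and would disagree on ties.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Identifier tokens: both plain ("CDE30") and namespaced ("DE:47616") forms.
ID_PATTERN <- "^[A-Za-z_][A-Za-z0-9_:.-]*$"

is_valid_id <- function(x) {
  is.character(x) && length(x) == 1 && !is.na(x) && grepl(ID_PATTERN, x)
}

stop_cde <- function(fmt, ..., class = "cdemdr_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
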