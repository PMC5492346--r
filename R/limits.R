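#' ISO metabolic-rate classes
#'
#' The closed set of workload categories used by occupational WBGT limit
#' tables, from resting through very high metabolic rate. "Heavy physical
#' work" — intense arm and trunk work, carrying heavy material, pushing or
#' pulling loaded carts — corresponds to `"high"`.
#'
#' @return Character vector of the five class labels, ordered from lightest
#'   to heaviest workload.
#' @export
metabolic_classes <- function() {
  c("rest", "low", "moderate", "high", "very_high")
}

#' Map the heavy-exertion case flag to a metabolic-rate class
#'
#' Cases recorded as heavy physical work are classed `"high"`; the remaining
#' outdoor manual work is classed `"moderate"` (outdoor compensated work is
#' at least moderate, never resting or light).
#'
#' @param heavy_exertion Logical vector.
#' @return Character vector of class labels.
#' @export
metabolic_class <- function(heavy_exertion) {
  ifelse(heavy_exertion, "high", "moderate")
}

#' Default occupational WBGT exposure-limit table
#'
#' Reference screening limits (degrees C WBGT) for continuous work in light
#' work clothing, stratified by acclimatization status and metabolic-rate
#' class, following the ISO 7243-style reference values:
#' acclimatized rest 33, low 30, moderate 28, high 25, very high 23;
#' unacclimatized rest 32, low 29, moderate 26, high 22, very high 18.
#' The table is data, not code — any complete, monotone table can replace it
#' (see [read_limit_table()]).
#'
#' @return A validated limit table: tibble with columns `acclimatized`
#'   (logical), `mclass` (one of [metabolic_classes()]) and `limit_c`.
#' @export
default_limit_table <- function() {
  read_limit_table(system.file("extdata", "iso_limits.yaml",
                               package = "heatstrain", mustWork = TRUE))
}

#' Build a limit table from a named structure
#'
#' @param limits A list with elements `acclimatized` and `unacclimatized`,
#'   each a named list/vector giving a WBGT limit (degrees C) for every
#'   metabolic class.
#' @return A validated limit-table tibble.
#' @export
limit_table <- function(limits) {
  if (!all(c("acclimatized", "unacclimatized") %in% names(limits))) {
    abort("limit table needs 'acclimatized' and 'unacclimatized' blocks",
          class = "heatstrain_config_error")
  }
  one <- function(status, acc) {
    vals <- unlist(limits[[status]])
    tibble::tibble(
      acclimatized = acc,
      mclass = names(vals),
      limit_c = as.numeric(vals)
    )
  }
  validate_limit_table(dplyr::bind_rows(
    one("acclimatized", TRUE), one("unacclimatized", FALSE)
  ))
}

#' Read a limit table from YAML or JSON
#'
#' Accepts a file with a top-level `limits:` block holding `acclimatized`
#' and `unacclimatized` maps over the five metabolic classes, and validates
#' it (see [validate_limit_table()]).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated limit-table tibble.
#' @export
read_limit_table <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  limit_table(raw$limits %||% raw)
}

#' Validate a WBGT limit table
#'
#' Enforces the structural invariants a usable table must satisfy: all 10
#' (acclimatization x class) combinations present exactly once; for every
#' class the unacclimatized limit does not exceed the acclimatized one; and
#' within each acclimatization status limits strictly decrease as the
#' metabolic class rises.
#'
#' @param table Data frame with columns `acclimatized`, `mclass`, `limit_c`.
#' @return The table as a tibble, rows ordered by status and class.
#' @export
validate_limit_table <- function(table) {
  assert_columns(table, c("acclimatized", "mclass", "limit_c"), "limit table")
  classes <- metabolic_classes()
  bad <- setdiff(unique(table$mclass), classes)
  if (length(bad) > 0) {
    abort(sprintf("unknown metabolic class(es): %s", paste(bad, collapse = ", ")),
          class = "heatstrain_config_error")
  }
  key <- paste(table$acclimatized, table$mclass)
  want <- paste(rep(c(TRUE, FALSE), each = length(classes)), classes)
  if (anyDuplicated(key) || !setequal(key, want)) {
    abort("limit table must cover all 10 (acclimatization x class) combinations exactly once",
          class = "heatstrain_config_error")
  }
  if (any(!is.finite(table$limit_c))) {
    abort("limits must be finite degrees C", class = "heatstrain_config_error")
  }
  tab <- table |>
    dplyr::mutate(mclass = factor(.data$mclass, levels = classes)) |>
    dplyr::arrange(dplyr::desc(.data$acclimatized), .data$mclass) |>
    dplyr::mutate(mclass = as.character(.data$mclass))
  acc <- tab$limit_c[tab$acclimatized]
  una <- tab$limit_c[!tab$acclimatized]
  if (any(una > acc)) {
    abort("unacclimatized limits must not exceed acclimatized limits",
          class = "heatstrain_config_error")
  }
  if (any(diff(acc) >= 0) || any(diff(una) >= 0)) {
    abort("limits must strictly decrease with increasing metabolic class",
          class = "heatstrain_config_error")
  }
  tibble::as_tibble(tab)
}

#' Look up the WBGT limit for a worker profile
#'
#' @param acclimatized Logical vector: acclimatized to heat?
#' @param mclass Metabolic-rate class label(s), see [metabolic_classes()].
#' @param table A validated limit table; defaults to [default_limit_table()].
#' @return WBGT limit(s) in degrees C.
#' @examples
#' get_limit(FALSE, "high") # 22 under the default table
#' @export
get_limit <- function(acclimatized, mclass, table = default_limit_table()) {
  table <- validate_limit_table(table)
  idx <- match(paste(acclimatized, mclass),
               paste(table$acclimatized, table$mclass))
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    abort(sprintf("no limit configured for acclimatized=%s, class '%s'",
                  acclimatized[miss], mclass[miss]),
          class = "heatstrain_config_error")
  }
  table$limit_c[idx]
}

#' Does a WBGT exposure reach the applicable limit?
#'
#' Inclusive comparison: an exposure exactly at the limit counts as reaching
#' it ("equal to or greater than").
#'
#' @param wbgt_max Maximum estimated WBGT of the exposure, degrees C.
#' @inheritParams get_limit
#' @return Logical vector.
#' @export
exceeds_limit <- function(wbgt_max, acclimatized, mclass,
                          table = default_limit_table()) {
  if (any(!is.finite(wbgt_max))) {
    abort("wbgt_max must be finite", class = "heatstrain_domain_error")
  }
  wbgt_max >= get_limit(acclimatized, mclass, table)
}
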