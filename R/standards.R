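#' Parameter standards tables
#'
#' A standards table holds, for each water-quality parameter, the values that
#' drive both the exceedance analysis and the weighted arithmetic WQI:
#'
#' * `ideal` — the value at which water is considered unpolluted for that
#'   parameter (`v_io`): 0 for most constituents, 7 for pH, 14.6 mg/l for
#'   dissolved oxygen;
#' * `standard` — the standard permissible value (`s_i`) used in the quality
#'   rating denominator and in the inverse-standard unit weights;
#' * `low`/`high` — the permissible limit(s); `limit_kind` is `"range"` when a
#'   two-sided band applies (pH, dissolved oxygen) and `"upper_only"` otherwise.
#'
#' Units are carried as labels only; measurements are assumed to already be in
#' the tabulated units (mg/l except pH and conductivity in uS/cm).
#'
#' @name standards
NULL

STATUS_LEVELS <- c("excellent", "good", "poor", "very_poor", "unsuitable")

STANDARDS_COLS <- c("parameter", "unit", "ideal", "standard",
                    "low", "high", "limit_kind")

#' Built-in IS 10500 (2012) standards table
#'
#' The ten physicochemical parameters of the Indian drinking-water standard
#' IS 10500 as used for supply-water WQI assessment: pH, dissolved oxygen,
#' electrical conductivity, alkalinity, hardness, chloride, total dissolved
#' solids, biochemical oxygen demand, sulphate and nitrate.
#'
#' pH and dissolved oxygen carry two-sided permissible ranges (6.5--8.5 and
#' 6.5--8 mg/l); their standard values default to the upper bound of the range,
#' so the quality rating is 0 at the ideal value and 100 at the permissible
#' bound. All other parameters have upper-only limits with `standard == high`
#' and `ideal == 0`.
#'
#' @return A validated standards tibble (see [standards]) with 10 rows.
#' @examples
#' is10500_standards()
#' @seealso [read_standards()] to load a custom table, [unit_weights()].
#' @export
is10500_standards <- function() {
  tbl <- tibble::tibble(
    parameter = c("ph", "do", "ec", "alkalinity", "hardness",
                  "chloride", "tds", "bod", "sulphate", "nitrate"),
    unit      = c("pH units", "mg/l", "uS/cm", "mg/l", "mg/l",
                  "mg/l", "mg/l", "mg/l", "mg/l", "mg/l"),
    ideal     = c(7, 14.6, 0, 0, 0, 0, 0, 0, 0, 0),
    standard  = c(8.5, 8, 300, 200, 200, 250, 500, 5, 200, 45),
    low       = c(6.5, 6.5, NA, NA, NA, NA, NA, NA, NA, NA),
    high      = c(8.5, 8, 300, 200, 200, 250, 500, 5, 200, 45),
    limit_kind = c("range", "range", rep("upper_only", 8))
  )
  validate_standards(tbl)
}

#' Validate a standards table
#'
#' Checks the structural invariants every standards table must satisfy:
#' non-empty, unique non-empty parameter names, non-empty units, finite
#' `standard != ideal` (the quality-rating denominator), `high` present, and
#' `low < high` for `"range"` parameters. Errors name the offending parameter.
#'
#' @param tbl A data frame with the columns described in [standards].
#' @return `tbl` as a tibble, invisibly unchanged, for chaining.
#' @export
validate_standards <- function(tbl) {
  if (!is.data.frame(tbl) || nrow(tbl) == 0)
    abort_fmt("standards table must be a non-empty data frame")
  missing_cols <- setdiff(STANDARDS_COLS, names(tbl))
  if (length(missing_cols) > 0)
    abort_fmt("standards table lacks column(s): %s",
              paste(missing_cols, collapse = ", "))
  tbl <- tibble::as_tibble(tbl)[STANDARDS_COLS]
  if (anyNA(tbl$parameter) || any(!nzchar(tbl$parameter)))
    abort_fmt("standards table has an empty parameter name")
  dup <- tbl$parameter[duplicated(tbl$parameter)]
  if (length(dup) > 0)
    abort_fmt("duplicate parameter name(s): %s", paste(unique(dup), collapse = ", "))
  if (anyNA(tbl$unit) || any(!nzchar(tbl$unit)))
    abort_fmt("empty unit for parameter(s): %s",
              paste(tbl$parameter[is.na(tbl$unit) | !nzchar(tbl$unit)], collapse = ", "))
  if (!all(tbl$limit_kind %in% c("upper_only", "range")))
    abort_fmt("limit_kind must be 'upper_only' or 'range' (parameter %s)",
              tbl$parameter[!tbl$limit_kind %in% c("upper_only", "range")][1])
  bad <- !is.finite(tbl$ideal) | !is.finite(tbl$standard) | !is.finite(tbl$high)
  if (any(bad))
    abort_fmt("non-finite ideal/standard/high for parameter: %s",
              tbl$parameter[bad][1])
  eq <- tbl$standard == tbl$ideal
  if (any(eq))
    abort_fmt("standard value equals ideal value for parameter: %s (rating denominator would be zero)",
              tbl$parameter[eq][1])
  rng <- tbl$limit_kind == "range"
  if (any(rng & !is.finite(tbl$low)))
    abort_fmt("range parameter without a lower limit: %s",
              tbl$parameter[rng & !is.finite(tbl$low)][1])
  inv <- rng & is.finite(tbl$low) & tbl$low >= tbl$high
  if (any(inv))
    abort_fmt("inverted permissible range (low >= high) for parameter: %s",
              tbl$parameter[inv][1])
  tbl
}

# one-row lookup; errors if absent
standards_row <- function(standards, parameter) {
  i <- match(parameter, standards$parameter)
  if (is.na(i))
    abort_fmt("unknown parameter '%s'; known: %s", parameter,
              paste(standards$parameter, collapse = ", "))
  standards[i, ]
}

#' Read a standards table from a YAML config file
#'
#' The config is a mapping `parameters:` whose entries are one block per
#' parameter with keys `unit`, `ideal`, `standard`, optional `low`, and `high`.
#' Omitting `low` declares an upper-only limit. Unknown keys are rejected so
#' typos do not silently alter a limit.
#'
#' @param path Path to the YAML file.
#' @return A validated standards tibble.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_standards(is10500_standards(), f)
#' identical(read_standards(f), is10500_standards())
#' @export
read_standards <- function(path) {
  if (!file.exists(path)) abort_fmt("standards file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  pars <- cfg$parameters
  if (is.null(pars) || length(pars) == 0)
    abort_fmt("standards file has no 'parameters' block: %s", path)
  allowed <- c("unit", "ideal", "standard", "low", "high")
  rows <- lapply(names(pars), function(nm) {
    p <- pars[[nm]]
    extra <- setdiff(names(p), allowed)
    if (length(extra) > 0)
      abort_fmt("unknown field(s) %s for parameter '%s'",
                paste(extra, collapse = ", "), nm)
    req <- setdiff(c("unit", "ideal", "standard", "high"), names(p))
    if (length(req) > 0)
      abort_fmt("parameter '%s' is missing field(s): %s", nm,
                paste(req, collapse = ", "))
    tibble::tibble(
      parameter = nm, unit = as.character(p$unit),
      ideal = as.numeric(p$ideal), standard = as.numeric(p$standard),
      low = if (is.null(p$low)) NA_real_ else as.numeric(p$low),
      high = as.numeric(p$high),
      limit_kind = if (is.null(p$low)) "upper_only" else "range"
    )
  })
  validate_standards(do.call(rbind, rows))
}

#' Write a standards table to a YAML config file
#'
#' Inverse of [read_standards()]: a round trip reproduces the table exactly.
#'
#' @param standards A validated standards tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_standards <- function(standards, path) {
  standards <- validate_standards(standards)
  pars <- lapply(seq_len(nrow(standards)), function(i) {
    r <- standards[i, ]
    block <- list(unit = r$unit, ideal = r$ideal, standard = r$standard)
    if (r$limit_kind == "range") block$low <- r$low
    block$high <- r$high
    block
  })
  names(pars) <- standards$parameter
  yaml::write_yaml(list(parameters = pars), path)
  invisible(path)
}
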