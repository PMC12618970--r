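#' Permissible-limit exceedance test
#'
#' A value exceeds its limit when it lies outside the permissible band:
#' above `high` for upper-only parameters, or outside `[low, high]` for range
#' parameters (deviation in either direction counts — acidic pH and depressed
#' dissolved oxygen are deviations just as elevated values are). Bounds are
#' inclusive-pass: a value exactly at the limit does not exceed.
#'
#' @param value Numeric vector of measured values; `NA` propagates.
#' @param spec A single standards-table row (see [is10500_standards()]), or a
#'   standards table plus `parameter` to select the row.
#' @param parameter Parameter name used to pick the row when `spec` has more
#'   than one.
#' @return Logical vector: `TRUE` where the value exceeds the limit.
#' @examples
#' std <- is10500_standards()
#' exceeds_limit(5.56, std, "ph")    # TRUE: below the 6.5-8.5 band
#' exceeds_limit(30, std, "nitrate") # FALSE: within the 45 mg/l limit
#' @export
exceeds_limit <- function(value, spec, parameter = NULL) {
  if (!is.null(parameter)) spec <- standards_row(spec, parameter)
  if (nrow(spec) != 1)
    abort_fmt("spec must be a single standards row (or give `parameter`)")
  if (spec$limit_kind == "range")
    value < spec$low | value > spec$high
  else
    value > spec$high
}

#' Zone- or ward-wise parameter summaries with exceedance rates
#'
#' For every group and parameter, computes n, min, max, arithmetic mean,
#' sample standard deviation (n-1 denominator), the count of values exceeding
#' the permissible limit ([exceeds_limit()]) and the corresponding percentage.
#' Values missing in a sample are skipped for that sample, reducing n. A group
#' with no non-missing values for a parameter yields a row flagged `empty`
#' rather than an error.
#'
#' @param samples A sample tibble (see [read_samples()]).
#' @param standards A standards table.
#' @param group `"zone"` (default) or `"ward"`.
#' @return A tibble with one row per (group, parameter): `group`, `parameter`,
#'   `n`, `minimum`, `maximum`, `mean`, `sd`, `n_exceed`, `pct_exceed` (rounded
#'   half-up to 2 decimals for display), `pct_exceed_raw` (full precision) and
#'   `empty`.
#' @examples
#' std <- is10500_standards()
#' s <- generate_samples(seed = 1)
#' summarize_samples(s, std)
#' @export
summarize_samples <- function(samples, standards, group = c("zone", "ward")) {
  group <- match.arg(group)
  standards <- validate_standards(standards)
  samples <- validate_samples(samples, standards)
  if (nrow(samples) == 0) abort_fmt("no samples to summarize")
  keys <- as.character(samples[[group]])
  if (anyNA(keys)) abort_fmt("missing %s label on some samples", group)
  pars <- intersect(standards$parameter, names(samples))
  rows <- list()
  for (g in unique(keys)) {
    sub <- samples[keys == g, ]
    for (p in pars) {
      v <- sub[[p]]
      v <- v[!is.na(v)]
      spec <- standards_row(standards, p)
      if (length(v) == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          group = g, parameter = p, n = 0L,
          minimum = NA_real_, maximum = NA_real_, mean = NA_real_,
          sd = NA_real_, n_exceed = NA_integer_,
          pct_exceed = NA_real_, pct_exceed_raw = NA_real_, empty = TRUE)
        next
      }
      ne <- sum(exceeds_limit(v, spec))
      pct <- 100 * ne / length(v)
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = g, parameter = p, n = length(v),
        minimum = min(v), maximum = max(v), mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        n_exceed = as.integer(ne),
        pct_exceed = round_half_up(pct, 2), pct_exceed_raw = pct,
        empty = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- group
  out
}

#' WQI grade distribution by zone
#'
#' Tabulates, per zone, the percentage of entities (wards or samples) falling
#' in each of the five quality grades. All five grades are always reported,
#' absent ones as 0, so zone columns line up across studies.
#'
#' @param results A tibble with columns `entity_id`, `status` and (unless
#'   `zone_of` is given) `zone` — e.g. the output of [ward_wqi()] or
#'   [sample_wqi()].
#' @param zone_of Optional named character vector mapping `entity_id` to zone,
#'   overriding/standing in for a `zone` column. Every entity must be mapped.
#' @return A tibble with one row per (zone, status): `zone`, `status`, `n`,
#'   `pct` (rounded half-up to 2 decimals) and `pct_raw`. Within a zone the
#'   raw percentages sum to 100.
#' @examples
#' res <- tibble::tibble(entity_id = as.character(1:4), zone = "north",
#'                       status = c("excellent", "good", "good", "good"))
#' status_distribution(res)
#' @export
status_distribution <- function(results, zone_of = NULL) {
  if (nrow(results) == 0) abort_fmt("no WQI results supplied")
  if (!is.null(zone_of)) {
    unmapped <- setdiff(as.character(results$entity_id), names(zone_of))
    if (length(unmapped) > 0)
      abort_fmt("entity not mapped to a zone: %s", paste(unmapped, collapse = ", "))
    zones <- unname(zone_of[as.character(results$entity_id)])
  } else {
    if (!"zone" %in% names(results))
      abort_fmt("results lack a zone column and no zone_of given")
    zones <- as.character(results$zone)
    if (anyNA(zones)) abort_fmt("entity not mapped to a zone")
  }
  bad <- setdiff(unique(results$status), STATUS_LEVELS)
  if (length(bad) > 0)
    abort_fmt("unknown status value(s): %s", paste(bad, collapse = ", "))
  rows <- lapply(unique(zones), function(z) {
    st <- results$status[zones == z]
    counts <- table(factor(st, levels = STATUS_LEVELS))
    raw <- 100 * as.numeric(counts) / length(st)
    tibble::tibble(zone = z, status = STATUS_LEVELS,
                   n = as.integer(counts),
                   pct = round_half_up(raw, 2), pct_raw = raw)
  })
  do.call(rbind, rows)
}
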