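#' Study bounding box
#'
#' The extent of the monitored city: 20°12'–20°25' N latitude and
#' 85°44'–85°55' E longitude, in decimal degrees (WGS84, x = longitude).
#'
#' @return Named numeric `c(xmin, ymin, xmax, ymax)`.
#' @export
study_bbox <- function() {
  c(xmin = 85 + 44 / 60, ymin = 20 + 12 / 60,
    xmax = 85 + 55 / 60, ymax = 20 + 25 / 60)
}

#' Built-in zone profiles
#'
#' The sampling design and per-zone, per-parameter summary statistics of the
#' study: three municipal zones (north and south-west with 21 wards each,
#' south-east with 25), five sampled locations per ward (335 samples in all),
#' and for each of the ten parameters the min, max, mean and SD observed in
#' each zone. These profiles drive [generate_samples()].
#'
#' @return A tibble with one row per (zone, parameter): `zone`, `n_wards`,
#'   `samples_per_ward`, `parameter`, `mean`, `sd`, `minimum`, `maximum`.
#' @examples
#' p <- zone_profiles()
#' sum(unique(p[c("zone", "n_wards", "samples_per_ward")])$n_wards * 5) # 335
#' @export
zone_profiles <- function() {
  # columns: parameter, zone, min, max, mean, sd
  raw <- rbind(
    c("ph",        "north",      5.56,   8.61,   7.66,     0.70),
    c("ph",        "south_west", 5.56,   8.61,   7.73,     0.69),
    c("ph",        "south_east", 6.23,   8.59,   7.56,     0.48),
    c("do",        "north",      5.91,   8.38,   7.50,     0.52),
    c("do",        "south_west", 5.91,   8.95,   7.54,     0.54),
    c("do",        "south_east", 5.91,   8.20,   7.43,     0.49),
    c("ec",        "north",      58.25,  480.30, 255.42,   90.63),
    c("ec",        "south_west", 67.70,  519.90, 251.01,   85.78),
    c("ec",        "south_east", 173.16, 581.47, 342.97,   73.69),
    c("alkalinity","north",      16.00,  128.00, 58.83,    21.85),
    c("alkalinity","south_west", 16.00,  128.00, 59.64,    21.97),
    c("alkalinity","south_east", 22.00,  78.00,  46.05,    13.75),
    c("hardness",  "north",      13.12,  262.40, 118.45,   60.24),
    c("hardness",  "south_west", 13.12,  229.60, 116.96,   57.98),
    c("hardness",  "south_east", 98.40,  268.96, 186.09,   40.78),
    c("chloride",  "north",      18.46,  87.03,  33.86,    11.65),
    c("chloride",  "south_west", 18.46,  87.03,  34.29,    10.76),
    c("chloride",  "south_east", 21.30,  64.61,  38.84,    7.61),
    c("tds",       "north",      37.86,  312.20, 166.02,   58.91),
    c("tds",       "south_west", 44.01,  337.94, 163.16,   55.75),
    c("tds",       "south_east", 112.56, 377.96, 222.93,   47.90),
    c("bod",       "north",      0.58,   4.98,   2.54,     1.32),
    c("bod",       "south_west", 0.58,   4.98,   2.75,     1.26),
    c("bod",       "south_east", 0.55,   4.60,   2.39,     1.00),
    c("sulphate",  "north",      3,      30,     15.57282, 8.307334),
    c("sulphate",  "south_west", 3,      30,     17.14286, 8.105588),
    c("sulphate",  "south_east", 3,      30,     16.88,    8.048843),
    c("nitrate",   "north",      0.2,    24.9,   11.80777, 7.346517),
    c("nitrate",   "south_west", 3,      30,     16.41905, 7.595268),
    c("nitrate",   "south_east", 3,      30,     16.88,    8.062858)
  )
  n_wards <- c(north = 21L, south_west = 21L, south_east = 25L)
  tibble::tibble(
    zone = raw[, 2],
    n_wards = unname(n_wards[raw[, 2]]),
    samples_per_ward = 5L,
    parameter = raw[, 1],
    mean = as.numeric(raw[, 5]),
    sd = as.numeric(raw[, 6]),
    minimum = as.numeric(raw[, 3]),
    maximum = as.numeric(raw[, 4])
  )
}

#' Truncated normal sampling and moments
#'
#' `rtruncnorm()` draws from a normal(mean, sd) restricted to
#' `[lower, upper]`, by inverse-CDF: a uniform between the CDF values at the
#' bounds is pushed through `qnorm`. Every draw respects the bounds exactly
#' and a fixed RNG state gives identical output. With `sd = 0` all draws are
#' the (clamped) mean.
#'
#' `truncnorm_moments()` returns the distribution's true mean and SD in closed
#' form. Truncation shifts both relative to the untruncated parameters, so
#' recovery checks on generated data must compare against these, not the
#' inputs.
#'
#' @param n Number of draws.
#' @param mean,sd Parameters of the parent normal (`sd >= 0`).
#' @param lower,upper Truncation bounds, `lower <= upper`.
#' @return `rtruncnorm()`: numeric vector of length `n` within
#'   `[lower, upper]`. `truncnorm_moments()`: list with `mean` and `sd`.
#' @examples
#' truncnorm_moments(186.09, 40.78, 98.40, 268.96)
#' @export
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (lower > upper) abort_fmt("lower must be <= upper")
  if (sd < 0) abort_fmt("sd must be >= 0")
  if (lower == upper) return(rep(lower, n))
  if (sd == 0) {
    message("sd = 0 with a non-degenerate range: drawing the clamped mean")
    return(rep(min(max(mean, lower), upper), n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  x <- stats::qnorm(stats::runif(n, plo, phi), mean, sd)
  pmin(pmax(x, lower), upper)  # guard qnorm round-off at the edges
}

#' @rdname rtruncnorm
#' @export
truncnorm_moments <- function(mean, sd, lower, upper) {
  if (sd <= 0 || lower >= upper)
    return(list(mean = min(max(mean, lower), upper), sd = 0))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / Z
  v <- sd^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

#' Generate a synthetic ward-sample table
#'
#' Emulates the study's monitoring design from zone profiles: for each zone,
#' `n_wards * samples_per_ward` samples, each parameter drawn independently
#' from a truncated normal with that zone's mean/SD/bounds. Ward centroids are
#' placed uniformly in the bounding box and the samples of a ward are jittered
#' around the centroid (normal jitter, clamped to the box). The same seed
#' always produces the same table.
#'
#' `calibrate` post-adjusts selected zone/parameter draws so that an exact
#' number of values exceeds the permissible limit (rank-preserving remap; see
#' [calibrate_exceedance()]) — useful for reconstructing published exceedance
#' counts that the marginal statistics alone do not pin down.
#'
#' @param profiles Zone profiles as from [zone_profiles()] (the default).
#' @param seed Integer seed; required for reproducibility.
#' @param bbox Bounding box `c(xmin, ymin, xmax, ymax)`; default [study_bbox()].
#' @param standards Standards table used only when `calibrate` is given.
#' @param calibrate Optional nested list `zone -> parameter -> n_exceed`.
#' @param jitter_sd SD (degrees) of the within-ward location jitter
#'   (default 0.004, ~400 m).
#' @return A sample tibble: `sample_id`, `ward`, `zone`, `x`, `y`, then one
#'   column per parameter.
#' @examples
#' s <- generate_samples(seed = 42)
#' nrow(s) # 335
#' @export
generate_samples <- function(profiles = zone_profiles(), seed,
                             bbox = study_bbox(),
                             standards = is10500_standards(),
                             calibrate = NULL, jitter_sd = 0.004) {
  if (missing(seed) || !is.numeric(seed))
    abort_fmt("an integer seed is required")
  stopifnot(all(c("zone", "n_wards", "samples_per_ward", "parameter",
                  "mean", "sd", "minimum", "maximum") %in% names(profiles)))
  bad <- profiles$minimum > profiles$mean | profiles$mean > profiles$maximum |
    profiles$sd < 0
  if (any(bad))
    abort_fmt("invalid profile row (need minimum <= mean <= maximum, sd >= 0): %s/%s",
              profiles$zone[bad][1], profiles$parameter[bad][1])

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  zones <- unique(profiles$zone)
  prefix <- c(north = "N", south_west = "SW", south_east = "SE")
  out <- list()
  for (z in zones) {
    prof <- profiles[profiles$zone == z, ]
    nw <- prof$n_wards[1]; spw <- prof$samples_per_ward[1]
    n <- nw * spw
    pz <- if (z %in% names(prefix)) prefix[[z]] else toupper(substr(z, 1, 2))
    ward <- rep(sprintf("%s%02d", pz, seq_len(nw)), each = spw)
    cx <- stats::runif(nw, bbox[1], bbox[3])
    cy <- stats::runif(nw, bbox[2], bbox[4])
    x <- pmin(pmax(rep(cx, each = spw) + stats::rnorm(n, 0, jitter_sd), bbox[1]), bbox[3])
    y <- pmin(pmax(rep(cy, each = spw) + stats::rnorm(n, 0, jitter_sd), bbox[2]), bbox[4])
    tab <- tibble::tibble(
      sample_id = sprintf("%s-%03d", pz, seq_len(n)),
      ward = ward, zone = z, x = x, y = y)
    for (j in seq_len(nrow(prof))) {
      p <- prof[j, ]
      v <- rtruncnorm(n, p$mean, p$sd, p$minimum, p$maximum)
      cal <- calibrate[[z]][[p$parameter]]
      if (!is.null(cal)) {
        spec <- standards_row(standards, p$parameter)
        v <- calibrate_exceedance(v, spec, n_exceed = cal,
                                  lower = p$minimum, upper = p$maximum)
      }
      tab[[p$parameter]] <- v
    }
    out[[z]] <- tab
  }
  do.call(rbind, unname(out))
}

#' Force an exact exceedance count onto a draw vector
#'
#' Rank-preserving remap: the `n_exceed` largest draws (smallest, for
#' `side = "low"`) are spaced evenly in the open interval beyond the limit,
#' the remaining draws are rescaled back inside the permissible side only if
#' any of them strayed past the limit. All outputs stay within
#' `[lower, upper]` and the ordering of the input draws is preserved.
#'
#' @param values Numeric draw vector.
#' @param spec A single standards-table row supplying the limit.
#' @param n_exceed Required number of exceeding values (0..length(values)).
#' @param lower,upper Bounds the remapped values must respect.
#' @param side For range limits: which bound the exceeders cross, `"high"`
#'   (default) or `"low"`. Upper-only limits always use `"high"`.
#' @return Numeric vector, same length, with exactly `n_exceed` values
#'   exceeding the limit per [exceeds_limit()].
#' @export
calibrate_exceedance <- function(values, spec, n_exceed, lower, upper,
                                 side = c("high", "low")) {
  side <- match.arg(side)
  if (spec$limit_kind == "upper_only") side <- "high"
  N <- length(values)
  if (n_exceed < 0 || n_exceed > N)
    abort_fmt("n_exceed must be in 0..%d", N)
  limit <- if (side == "high") spec$high else spec$low
  if (side == "high" && (limit >= upper || limit < lower))
    abort_fmt("limit %.4g not inside (%.4g, %.4g): cannot calibrate", limit, lower, upper)
  if (side == "low" && (limit <= lower || limit > upper))
    abort_fmt("limit %.4g not inside (%.4g, %.4g): cannot calibrate", limit, lower, upper)

  # the permissible interval the non-exceeders must occupy: for range limits
  # both bounds bind (a draw pushed below `low` would still exceed)
  ok_lo <- if (spec$limit_kind == "range") max(lower, spec$low) else lower
  ok_hi <- if (spec$limit_kind == "range") min(upper, spec$high) else min(upper, spec$high)

  ord <- order(values)
  out <- values
  if (side == "high") {
    exc_idx <- if (n_exceed > 0) ord[(N - n_exceed + 1):N] else integer(0)
    ok_idx <- if (n_exceed < N) ord[seq_len(N - n_exceed)] else integer(0)
    if (n_exceed > 0)
      out[exc_idx] <- limit + seq_len(n_exceed) / n_exceed * (upper - limit)
    if (length(ok_idx) > 0 &&
        any(values[ok_idx] > ok_hi | values[ok_idx] < ok_lo))
      out[ok_idx] <- ok_lo + rank(values[ok_idx], ties.method = "first") /
        length(ok_idx) * (ok_hi - ok_lo)
  } else {
    exc_idx <- if (n_exceed > 0) ord[seq_len(n_exceed)] else integer(0)
    ok_idx <- if (n_exceed < N) ord[(n_exceed + 1):N] else integer(0)
    if (n_exceed > 0)
      out[exc_idx] <- limit - seq_len(n_exceed) / n_exceed * (limit - lower)
    if (length(ok_idx) > 0 &&
        any(values[ok_idx] > ok_hi | values[ok_idx] < ok_lo))
      out[ok_idx] <- ok_hi - rank(-values[ok_idx], ties.method = "first") /
        length(ok_idx) * (ok_hi - ok_lo)
  }
  out
}
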