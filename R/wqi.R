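#' Inverse-standard unit weights
#'
#' Computes the weighted arithmetic WQI unit weights, which are inversely
#' proportional to the standard permissible values:
#' `w_i = k / s_i` with the normalizing constant `k = 1 / sum_i(1 / s_i)`.
#' Parameters with stricter limits therefore carry more weight, and the
#' weights sum to exactly 1 by construction.
#'
#' @param standards A standards table (see [is10500_standards()]).
#' @param subset Optional character vector of parameter names to restrict the
#'   weight computation to (weights are renormalized over the subset). Default:
#'   all parameters in `standards`.
#' @return A list of class `"wqi_weights"` with elements `weights` (named
#'   numeric, summing to 1) and `k` (the normalizing constant).
#' @examples
#' w <- unit_weights(is10500_standards())
#' sum(w$weights) # 1
#' @export
unit_weights <- function(standards, subset = NULL) {
  standards <- validate_standards(standards)
  if (is.null(subset)) subset <- standards$parameter
  if (length(subset) == 0) abort_fmt("parameter subset is empty")
  unknown <- setdiff(subset, standards$parameter)
  if (length(unknown) > 0)
    abort_fmt("unknown parameter(s): %s", paste(unknown, collapse = ", "))
  s <- standards$standard[match(subset, standards$parameter)]
  if (any(s <= 0))
    abort_fmt("standard value must be > 0 for weighting (parameter %s)",
              subset[s <= 0][1])
  k <- 1 / sum(1 / s)
  w <- k / s
  names(w) <- subset
  structure(list(weights = w, k = k), class = "wqi_weights")
}

#' Per-parameter quality rating
#'
#' The quality rating relates a measured value to the standard permissible
#' value, scaled so the ideal value rates 0 and the standard rates 100:
#' `q_i = 100 * (v_i - v_io) / (s_i - v_io)`.
#'
#' In `"signed"` mode (the literal formula) a value on the far side of the
#' ideal from the standard gives a negative rating — e.g. acidic pH below the
#' ideal 7 lowers the WQI. `"absolute"` mode takes absolute deviations instead,
#' so departure in either direction raises the rating.
#'
#' @param value Numeric vector of measured values (`v_i`).
#' @param ideal The parameter's ideal value (`v_io`).
#' @param standard The standard permissible value (`s_i`); must differ from
#'   `ideal`.
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return Numeric vector of ratings, same length as `value`.
#' @examples
#' quality_rating(22.5, ideal = 0, standard = 45)    # 50
#' quality_rating(14.6, ideal = 14.6, standard = 8)  # 0
#' @export
quality_rating <- function(value, ideal, standard, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (standard == ideal) abort_fmt("standard equals ideal: rating undefined")
  if (mode == "signed") 100 * (value - ideal) / (standard - ideal)
  else                  100 * abs(value - ideal) / abs(standard - ideal)
}

#' Weighted arithmetic Water Quality Index for one set of values
#'
#' Aggregates per-parameter quality ratings into a single score:
#' `WQI = sum(q_i * w_i) / sum(w_i)`, with ratings from [quality_rating()] and
#' weights from [unit_weights()]. A score of 0 corresponds to all parameters at
#' their ideal values and 100 to all at their standard permissible values.
#'
#' @param values Named numeric vector or single-element-per-parameter list:
#'   parameter name -> measured value. `NA` values count as missing.
#' @param standards A standards table.
#' @param mode Rating mode, `"signed"` (default) or `"absolute"`; see
#'   [quality_rating()].
#' @param missing_policy `"strict"` (default): every parameter in `standards`
#'   must be present, otherwise an error names the missing one. `"renormalize"`:
#'   weights are recomputed over the present parameters only (not rescaled from
#'   the full-set weights).
#' @param entity_id Optional identifier stored on the result.
#' @return An object of class `"wqi_result"`: a list with `entity_id`, `score`,
#'   `status` (see [classify_wqi()]), `ratings` (named q_i), `weights` (a
#'   `"wqi_weights"` object), `mode` and `missing_policy`.
#' @examples
#' std <- is10500_standards()
#' at_standard <- setNames(std$standard, std$parameter)
#' compute_wqi(at_standard, std)$score # 100
#' @export
compute_wqi <- function(values, standards,
                        mode = c("signed", "absolute"),
                        missing_policy = c("strict", "renormalize"),
                        entity_id = NA_character_) {
  mode <- match.arg(mode)
  missing_policy <- match.arg(missing_policy)
  standards <- validate_standards(standards)
  values <- unlist(values)
  values <- values[!is.na(values)]
  if (length(values) == 0) abort_fmt("no parameter values supplied")
  if (is.null(names(values)) || any(!nzchar(names(values))))
    abort_fmt("values must be named by parameter")
  unknown <- setdiff(names(values), standards$parameter)
  if (length(unknown) > 0)
    abort_fmt("unknown parameter(s): %s", paste(unknown, collapse = ", "))

  present <- intersect(standards$parameter, names(values))
  if (missing_policy == "strict") {
    absent <- setdiff(standards$parameter, present)
    if (length(absent) > 0)
      abort_fmt("missing parameter(s) under strict policy: %s",
                paste(absent, collapse = ", "))
  }
  wv <- unit_weights(standards, subset = present)
  idx <- match(present, standards$parameter)
  q <- vapply(seq_along(present), function(j) {
    quality_rating(values[[present[j]]],
                   ideal = standards$ideal[idx[j]],
                   standard = standards$standard[idx[j]],
                   mode = mode)
  }, numeric(1))
  names(q) <- present
  score <- sum(q * wv$weights) / sum(wv$weights)
  structure(list(entity_id = entity_id, score = score,
                 status = classify_wqi(score),
                 ratings = q, weights = wv,
                 mode = mode, missing_policy = missing_policy),
            class = "wqi_result")
}

#' @export
print.wqi_result <- function(x, ...) {
  cat(sprintf("WQI %s: %.2f (%s) over %d parameters [%s, %s]\n",
              if (is.na(x$entity_id)) "" else x$entity_id,
              x$score, x$status, length(x$ratings), x$mode, x$missing_policy))
  invisible(x)
}

#' Classify a WQI score into a quality grade
#'
#' Grade bands: up to 25 excellent; (25, 50] good; (50, 75] poor;
#' (75, 100] very poor; above 100 unsuitable for drinking. The published bands
#' are printed as integer ranges (0-25, 26-50, ...); half-open intervals with
#' inclusive upper bounds are used so that every real-valued score receives
#' exactly one grade. Negative scores (possible under signed ratings) classify
#' as excellent with a warning.
#'
#' @param score Numeric vector of WQI scores; must be finite.
#' @return Character vector with values among `"excellent"`, `"good"`,
#'   `"poor"`, `"very_poor"`, `"unsuitable"`.
#' @examples
#' classify_wqi(c(23, 51, 101)) # excellent, poor, unsuitable
#' @export
classify_wqi <- function(score) {
  if (any(!is.finite(score))) abort_fmt("WQI score must be finite")
  if (any(score < 0))
    warning("negative WQI score(s) classified as excellent", call. = FALSE)
  out <- character(length(score))
  out[score <= 25] <- "excellent"
  out[score > 25 & score <= 50] <- "good"
  out[score > 50 & score <= 75] <- "poor"
  out[score > 75 & score <= 100] <- "very_poor"
  out[score > 100] <- "unsuitable"
  out
}

#' Per-sample WQI over a sample table
#'
#' Applies [compute_wqi()] to every row of a sample table.
#'
#' @param samples A sample tibble (see [read_samples()] for the layout:
#'   `sample_id`, `ward`, `zone`, `x`, `y`, then one column per parameter).
#' @param standards A standards table.
#' @inheritParams compute_wqi
#' @return A tibble with one row per sample: `entity_id`, `ward`, `zone`,
#'   `wqi`, `status`.
#' @export
sample_wqi <- function(samples, standards,
                       mode = c("signed", "absolute"),
                       missing_policy = c("strict", "renormalize")) {
  mode <- match.arg(mode); missing_policy <- match.arg(missing_policy)
  samples <- validate_samples(samples, standards)
  pars <- intersect(names(samples), standards$parameter)
  res <- lapply(seq_len(nrow(samples)), function(i) {
    vals <- unlist(samples[i, pars])
    compute_wqi(vals, standards, mode = mode,
                missing_policy = missing_policy,
                entity_id = as.character(samples$sample_id[i]))
  })
  tibble::tibble(
    entity_id = vapply(res, `[[`, character(1), "entity_id"),
    ward = as.character(samples$ward),
    zone = as.character(samples$zone),
    wqi = vapply(res, `[[`, numeric(1), "score"),
    status = vapply(res, `[[`, character(1), "status")
  )
}

#' Ward-level WQI from parameter means
#'
#' For each ward, forms the arithmetic mean of every parameter over that
#' ward's samples and applies [compute_wqi()] to the mean vector — the index is
#' calculated on the average value of each parameter, not averaged over
#' per-sample indices.
#'
#' @inheritParams sample_wqi
#' @return A tibble with one row per ward: `entity_id` (the ward id), `zone`,
#'   `n_samples`, `wqi`, `status`.
#' @examples
#' std <- is10500_standards()
#' s <- generate_samples(seed = 1)
#' head(ward_wqi(s, std))
#' @export
ward_wqi <- function(samples, standards,
                     mode = c("signed", "absolute"),
                     missing_policy = c("strict", "renormalize")) {
  mode <- match.arg(mode); missing_policy <- match.arg(missing_policy)
  samples <- validate_samples(samples, standards)
  if (anyNA(samples$ward)) abort_fmt("every sample must carry a ward id")
  pars <- intersect(names(samples), standards$parameter)
  wards <- unique(as.character(samples$ward))
  rows <- lapply(wards, function(w) {
    sub <- samples[samples$ward == w, ]
    means <- vapply(pars, function(p) mean(sub[[p]], na.rm = TRUE), numeric(1))
    means[is.nan(means)] <- NA_real_
    r <- compute_wqi(means, standards, mode = mode,
                     missing_policy = missing_policy, entity_id = w)
    tibble::tibble(entity_id = w,
                   zone = as.character(sub$zone[1]),
                   n_samples = nrow(sub),
                   wqi = r$score, status = r$status)
  })
  do.call(rbind, rows)
}
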