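# Shared in-code fixtures: tiny standards tables and sample builders.

# two upper-only parameters with simple standards (hand-checkable weights)
toy_standards <- function() {
  validate_standards(tibble::tibble(
    parameter = c("A", "B"),
    unit = c("mg/l", "mg/l"),
    ideal = c(0, 0),
    standard = c(100, 200),
    low = c(NA_real_, NA_real_),
    high = c(100, 200),
    limit_kind = c("upper_only", "upper_only")
  ))
}

single_standard <- function(s = 45) {
  validate_standards(tibble::tibble(
    parameter = "A", unit = "mg/l", ideal = 0, standard = s,
    low = NA_real_, high = s, limit_kind = "upper_only"
  ))
}

# random valid standards table (upper-only, positive standards != ideal 0)
random_standards <- function(n_par = 5) {
  validate_standards(tibble::tibble(
    parameter = paste0("p", seq_len(n_par)),
    unit = "mg/l",
    ideal = 0,
    standard = stats::runif(n_par, 0.5, 500),
    low = NA_real_,
    high = stats::runif(n_par, 0.5, 500),
    limit_kind = "upper_only"
  ))
}

# minimal sample table over `standards`, one row per entry of `values` list
make_samples <- function(values_list, ward = NULL, zone = "north") {
  n <- length(values_list)
  ward <- ward %||% paste0("W", seq_len(n))
  tab <- tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    ward = ward,
    zone = rep_len(zone, n),
    x = stats::runif(n, 85.75, 85.9),
    y = stats::runif(n, 20.2, 20.4)
  )
  pars <- unique(unlist(lapply(values_list, names)))
  for (p in pars)
    tab[[p]] <- vapply(values_list, function(v) v[[p]] %||% NA_real_, numeric(1))
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force evaluation of the three WQI formulas, composed
# naively from the definitions (oracle; no shared code with compute_wqi)
brute_force_wqi <- function(values, standards, mode = "signed") {
  s <- standards$standard[match(names(values), standards$parameter)]
  v0 <- standards$ideal[match(names(values), standards$parameter)]
  k <- 1 / sum(1 / s)
  w <- k / s
  q <- if (mode == "signed") 100 * (values - v0) / (s - v0)
       else 100 * abs(values - v0) / abs(s - v0)
  sum(q * w) / sum(w)
}

# naive full-formula IDW (all points, no neighbour cap) — oracle for idw_predict
brute_force_idw <- function(points, tx, ty, power) {
  d <- sqrt((points$x - tx)^2 + (points$y - ty)^2)
  if (any(d == 0)) return(mean(points$value[d == 0]))
  w <- d^(-power) / sum(d^(-power))
  sum(w * points$value)
}
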