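#' Sample table I/O and validation
#'
#' The canonical sample table is a CSV with header columns `sample_id`,
#' `ward`, `zone`, `x`, `y` (WGS84 decimal degrees, x = longitude; may be
#' empty for non-spatial workflows) followed by one numeric column per
#' parameter. Decimal point, UTF-8; blank cells are missing values; lines
#' starting with `#` are provenance comments.
#'
#' @name sample_io
NULL

ID_COLS <- c("sample_id", "ward", "zone", "x", "y")

# case-insensitive normalization of the three study zones; unknown labels
# pass through untouched for user-defined studies
normalize_zone <- function(zone) {
  key <- gsub("[^a-z]+", "_", tolower(trimws(as.character(zone))))
  map <- c(north = "north", n = "north",
           south_west = "south_west", sw = "south_west", southwest = "south_west",
           south_east = "south_east", se = "south_east", southeast = "south_east")
  out <- unname(map[key])
  ifelse(is.na(out), as.character(zone), out)
}

#' Validate a sample table
#'
#' Enforces the sample invariants: required id columns present, parameter
#' columns numeric and known to the standards table, finite coordinates where
#' given, pH inside (0, 14) and concentrations non-negative.
#'
#' @param samples A data frame in the layout of [sample_io].
#' @param standards A standards table; parameter columns must be among its
#'   parameters.
#' @return The validated tibble (zones normalized).
#' @export
validate_samples <- function(samples, standards = is10500_standards()) {
  if (!is.data.frame(samples) || nrow(samples) == 0)
    abort_fmt("samples must be a non-empty data frame")
  samples <- tibble::as_tibble(samples)
  need <- setdiff(c("sample_id", "ward", "zone"), names(samples))
  if (length(need) > 0)
    abort_fmt("samples lack column(s): %s", paste(need, collapse = ", "))
  samples$zone <- normalize_zone(samples$zone)
  pars <- setdiff(names(samples), ID_COLS)
  unknown <- setdiff(pars, standards$parameter)
  if (length(unknown) > 0)
    abort_fmt("unknown parameter column(s): %s; known: %s",
              paste(unknown, collapse = ", "),
              paste(standards$parameter, collapse = ", "))
  for (p in pars) {
    v <- samples[[p]]
    if (!is.numeric(v))
      abort_fmt("parameter column '%s' is not numeric", p)
    if (any(is.infinite(v)))
      abort_fmt("non-finite value in parameter column '%s'", p)
    if (p == "ph" && any(v <= 0 | v >= 14, na.rm = TRUE))
      abort_fmt("pH value outside (0, 14)")
    if (p != "ph" && any(v < 0, na.rm = TRUE))
      abort_fmt("negative concentration in column '%s'", p)
  }
  for (cc in intersect(c("x", "y"), names(samples))) {
    if (!is.numeric(samples[[cc]]) || any(is.infinite(samples[[cc]])))
      abort_fmt("coordinate column '%s' must be numeric and finite where present", cc)
  }
  samples
}

#' Read a sample table from CSV
#'
#' Cells are converted with precise diagnostics: a non-numeric entry in a
#' parameter column (e.g. a locale-style `"8,5"`) raises an error naming the
#' data row and column rather than silently becoming `NA`.
#'
#' @param path CSV path (layout in [sample_io]).
#' @param standards Standards table used to validate parameter columns.
#' @return A validated sample tibble.
#' @export
read_samples <- function(path, standards = is10500_standards()) {
  if (!file.exists(path)) abort_fmt("sample file not found: %s", path)
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- setdiff(c("sample_id", "ward", "zone"), names(raw))
  if (length(need) > 0)
    abort_fmt("samples lack column(s): %s", paste(need, collapse = ", "))
  num_cols <- setdiff(names(raw), c("sample_id", "ward", "zone"))
  for (cc in num_cols) {
    v <- trimws(raw[[cc]])
    v[!nzchar(v) | is.na(v)] <- NA_character_
    conv <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(conv))
    if (length(bad) > 0)
      abort_fmt("non-numeric value '%s' at data row %d, column '%s'",
                v[bad[1]], bad[1], cc)
    raw[[cc]] <- conv
  }
  message(sprintf("read %d samples x %d columns from %s",
                  nrow(raw), ncol(raw), path))
  validate_samples(raw, standards)
}

#' Write a sample table to CSV
#'
#' @param samples A sample tibble.
#' @param path Output path.
#' @param comment Optional provenance comment written as a leading `#` line.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path, comment = NULL) {
  write_csv_commented(samples, path, comment)
}

write_csv_commented <- function(x, path, comment = NULL) {
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_csv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  } else {
    readr::write_csv(x, path, progress = FALSE)
  }
  invisible(path)
}

#' Read spatial points from GeoJSON Point features
#'
#' Accepts a FeatureCollection of Point features; the interpolated quantity is
#' taken from the property named by `value`.
#'
#' @param path GeoJSON file path.
#' @param value Name of the feature property holding the value.
#' @return A tibble with columns `x`, `y`, `value` suitable for [idw_predict()].
#' @export
read_points_geojson <- function(path, value = "value") {
  if (!file.exists(path)) abort_fmt("file not found: %s", path)
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (is.null(feats)) abort_fmt("not a GeoJSON FeatureCollection: %s", path)
  rows <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "Point"))
      abort_fmt("non-Point feature in %s", path)
    val <- f$properties[[value]]
    if (is.null(val)) abort_fmt("feature lacks property '%s'", value)
    tibble::tibble(x = as.numeric(f$geometry$coordinates[[1]]),
                   y = as.numeric(f$geometry$coordinates[[2]]),
                   value = as.numeric(val))
  })
  do.call(rbind, rows)
}

# short stable hash of the effective configuration for provenance lines;
# the output location is not part of the analysis identity
config_hash <- function(config) {
  config <- config[setdiff(names(config), "out_dir")]
  s <- paste(deparse(config), collapse = "")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the end-to-end assessment pipeline
#'
#' Chains the stages of a supply-water assessment: obtain samples (read a CSV
#' or simulate from zone profiles), score the WQI per sample or per ward,
#' classify grades, tabulate zone summaries with exceedance rates and the
#' grade distribution, optionally interpolate parameter surfaces, and write a
#' report. All outputs are plain text, carry a version/config provenance
#' comment, and contain no timestamps, so a rerun with the same configuration
#' and seed is byte-identical.
#'
#' @param config A named list (or path to a YAML file holding one) with:
#'   * `samples`: path to a sample CSV, or `NULL` to simulate;
#'   * `seed`: integer, required when simulating;
#'   * `standards`: `"builtin"` (default) or a path for [read_standards()];
#'   * `wqi`: list of `mode`, `missing_policy`, `per` (`"sample"` default, or
#'     `"ward"`);
#'   * `idw`: `NULL` (skip surfaces) or list of `parameters` (character),
#'     `power`, `max_neighbors`, `ncols`, `nrows`;
#'   * `out_dir`: output directory (created if needed).
#' @return Invisibly, a list with the output paths and the in-memory results
#'   (`samples`, `wqi`, `summary`, `status`).
#' @examples
#' \donttest{
#' out <- run_pipeline(list(seed = 1, out_dir = tempfile()))
#' nrow(out$wqi) # 335
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort_fmt("config must be a list or a YAML path")
  out_dir <- config$out_dir %||% abort_fmt("config$out_dir is required")
  wqi_cfg <- config$wqi %||% list()
  mode <- wqi_cfg$mode %||% "signed"
  policy <- wqi_cfg$missing_policy %||% "strict"
  per <- wqi_cfg$per %||% "sample"
  if (!per %in% c("sample", "ward")) abort_fmt("wqi$per must be 'sample' or 'ward'")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    abort_fmt("pipeline failed (partial outputs removed): %s", conditionMessage(e))
  }
  tryCatch({
    std_src <- config$standards %||% "builtin"
    standards <- if (identical(std_src, "builtin")) is10500_standards()
                 else read_standards(std_src)
    prov <- sprintf("aquaindex %s | config %s",
                    as.character(utils::packageVersion("aquaindex")),
                    config_hash(config))

    if (!is.null(config$samples)) {
      samples <- read_samples(config$samples, standards)
    } else {
      seed <- config$seed %||% abort_fmt("config$seed is required to simulate")
      samples <- generate_samples(seed = seed, standards = standards)
      p <- file.path(out_dir, "samples.csv")
      write_samples(samples, p, comment = prov); written <- c(written, p)
    }

    res <- if (per == "ward") ward_wqi(samples, standards, mode, policy)
           else sample_wqi(samples, standards, mode, policy)
    res$wqi_rounded <- round_half_up(res$wqi, 2)
    p <- file.path(out_dir, "wqi.csv")
    write_csv_commented(res, p, comment = prov); written <- c(written, p)

    summ <- summarize_samples(samples, standards, group = "zone")
    p <- file.path(out_dir, "summary.csv")
    write_csv_commented(summ, p, comment = prov); written <- c(written, p)

    status <- status_distribution(res)
    p <- file.path(out_dir, "status.csv")
    write_csv_commented(status, p, comment = prov); written <- c(written, p)

    surfaces <- character(0)
    if (!is.null(config$idw)) {
      ic <- config$idw
      cfg <- idw_config(power = ic$power %||% 2,
                        max_neighbors = ic$max_neighbors %||% 12,
                        metric = ic$metric %||% "planar")
      bbox <- if (!is.null(ic$bbox)) unlist(ic$bbox) else
        c(min(samples$x), min(samples$y), max(samples$x), max(samples$y))
      for (param in (ic$parameters %||% character(0))) {
        if (!param %in% names(samples))
          abort_fmt("cannot interpolate '%s': no such parameter column", param)
        pts <- tibble::tibble(x = samples$x, y = samples$y, value = samples[[param]])
        pts <- pts[stats::complete.cases(pts), ]
        surf <- idw_grid(pts, bbox, ic$ncols %||% 50, ic$nrows %||% 50, cfg)
        p <- file.path(out_dir, sprintf("surface_%s.asc", param))
        write_asc(surf, p); written <- c(written, p); surfaces <- c(surfaces, p)
      }
    }

    report <- c(
      "# Supply-water quality assessment report", "",
      paste0("Tool: ", prov),
      paste0("Standards: ", if (identical(std_src, "builtin")) "built-in IS 10500 (2012)" else std_src),
      paste0("Samples: ", if (is.null(config$samples)) sprintf("simulated (seed %d)", as.integer(config$seed)) else config$samples),
      sprintf("WQI: %s ratings, %s missing policy, per-%s", mode, policy, per),
      "", sprintf("Rows: %d samples, %d WQI results", nrow(samples), nrow(res)),
      sprintf("Grade range: %.2f to %.2f", min(res$wqi), max(res$wqi)),
      "", "## Outputs", paste0("- ", basename(written)))
    p <- file.path(out_dir, "report.md")
    writeLines(report, p); written <- c(written, p)

    invisible(list(paths = written, samples = samples, wqi = res,
                   summary = summ, status = status, surfaces = surfaces))
  }, error = on_fail)
}
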