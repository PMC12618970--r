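#' Inverse distance weighting (IDW) interpolation
#'
#' Deterministic spatial interpolation: the value at an unsampled location is
#' a weighted average of the values at the `m` nearest sampled points (or of
#' all points within a cut-off distance), with weights inversely proportional
#' to a power of distance: `lambda_i = D_i^-a / sum_j D_j^-a`. The prediction
#' is a convex combination of neighbour values, so it never extrapolates
#' beyond their range.
#'
#' @name idw
NULL

#' IDW configuration
#'
#' @param power Exponent `a` on distance (>= 0). 0 degenerates to the
#'   arithmetic mean of the neighbours; large values converge to
#'   nearest-neighbour assignment. Default 2, the customary choice.
#' @param max_neighbors Number `m` of closest points used (>= 1); published
#'   guidance is typically 10 to 30. Points tied with the m-th neighbour's
#'   distance are all included, so selection is order-independent. Default 12.
#' @param cutoff Optional cut-off distance (same units as the metric: degrees
#'   for planar, meters for haversine); locations with no point within it get
#'   the no-data value `NA`.
#' @param metric `"planar"` (Euclidean on the raw coordinates — adequate for
#'   study extents of a fraction of a degree) or `"haversine"` (great-circle
#'   meters on longitude/latitude, via \pkg{geosphere}).
#' @return A list of class `"idw_config"`.
#' @export
idw_config <- function(power = 2, max_neighbors = 12, cutoff = NULL,
                       metric = c("planar", "haversine")) {
  metric <- match.arg(metric)
  if (!is.finite(power) || power < 0) abort_fmt("power must be >= 0")
  if (max_neighbors < 1) abort_fmt("max_neighbors must be >= 1")
  if (!is.null(cutoff) && (!is.finite(cutoff) || cutoff <= 0))
    abort_fmt("cutoff must be > 0 when given")
  structure(list(power = power, max_neighbors = as.integer(max_neighbors),
                 cutoff = cutoff, metric = metric),
            class = "idw_config")
}

#' Normalized inverse-distance weights
#'
#' `lambda_i = D_i^-a / sum_j D_j^-a`. If any distance is zero the formula is
#' undefined; weight then concentrates uniformly on the zero-distance entries
#' (the exact-interpolation limit).
#'
#' @param distances Non-empty numeric vector of distances, all >= 0.
#' @param power Exponent on distance, >= 0.
#' @return Numeric weights, same length, summing to 1.
#' @examples
#' idw_weights(c(1, 2), power = 2) # 0.8, 0.2
#' @export
idw_weights <- function(distances, power) {
  if (length(distances) == 0) abort_fmt("distances must be non-empty")
  if (any(!is.finite(distances) | distances < 0))
    abort_fmt("distances must be finite and >= 0")
  zero <- distances == 0
  if (any(zero)) {
    w <- as.numeric(zero) / sum(zero)
  } else {
    inv <- distances^(-power)
    w <- inv / sum(inv)
  }
  w
}

# pairwise distances from targets (n x 2) to points (m x 2)
idw_distances <- function(tx, ty, px, py, metric) {
  if (metric == "haversine")
    geosphere::distHaversine(cbind(tx, ty), cbind(px, py))
  else
    sqrt((tx - px)^2 + (ty - py)^2)
}

#' IDW prediction at target locations
#'
#' Selects, per target, the points within the cut-off (if configured), keeps
#' the `max_neighbors` nearest (including distance ties), and returns the
#' inverse-distance weighted average of their values. A target coinciding with
#' one or more data points returns the mean of the coincident values exactly
#' (with a warning if those values differ). A target with no point inside the
#' cut-off returns `NA` (no-data), not an error.
#'
#' @param points A data frame with columns `x`, `y`, `value`, all finite.
#' @param x,y Target coordinates (vectors of equal length).
#' @param config An [idw_config()].
#' @return Numeric vector of predictions, one per target.
#' @examples
#' pts <- tibble::tibble(x = c(0, 1, 0), y = c(0, 0, 2), value = c(10, 20, 30))
#' # distances 1, sqrt(2), 1 -> (10*1 + 20*0.5 + 30*1) / 2.5
#' idw_predict(pts, 0, 1, idw_config(power = 2)) # 20
#' @export
idw_predict <- function(points, x, y, config = idw_config()) {
  if (nrow(points) == 0) abort_fmt("points must be non-empty")
  if (any(!is.finite(points$x) | !is.finite(points$y) | !is.finite(points$value)))
    abort_fmt("point coordinates and values must be finite")
  if (length(x) != length(y)) abort_fmt("x and y must have equal length")
  vapply(seq_along(x), function(i) {
    d <- idw_distances(x[i], y[i], points$x, points$y, config$metric)
    keep <- if (is.null(config$cutoff)) rep(TRUE, length(d)) else d <= config$cutoff
    if (!any(keep)) return(NA_real_)
    d <- d[keep]; v <- points$value[keep]
    if (any(d == 0)) {
      v0 <- v[d == 0]
      if (length(unique(v0)) > 1)
        warning("coincident data points with differing values at target; returning their mean",
                call. = FALSE)
      return(mean(v0))
    }
    m <- min(config$max_neighbors, length(d))
    thr <- sort(d, partial = m)[m]
    sel <- d <= thr  # include all ties with the m-th neighbour
    w <- idw_weights(d[sel], config$power)
    sum(w * v[sel])
  }, numeric(1))
}

#' IDW surface on a regular grid
#'
#' Evaluates [idw_predict()] at every cell centre of a regular grid spanning a
#' bounding box. The result is deterministic for fixed inputs; cells failing
#' the cut-off are no-data (`NA`).
#'
#' @param points A data frame with columns `x`, `y`, `value`.
#' @param bbox Numeric `c(xmin, ymin, xmax, ymax)` with `xmin < xmax`,
#'   `ymin < ymax`.
#' @param ncols,nrows Grid dimensions, both >= 1.
#' @param config An [idw_config()].
#' @return An object of class `"idw_surface"`: list with `bbox`, `ncols`,
#'   `nrows`, `cellsize_x`, `cellsize_y`, and `values`, an `nrows x ncols`
#'   matrix whose first row is the northernmost (top) row of cells.
#' @seealso [write_asc()] to export as an ESRI ASCII grid.
#' @export
idw_grid <- function(points, bbox, ncols, nrows, config = idw_config()) {
  if (length(bbox) != 4 || bbox[1] >= bbox[3] || bbox[2] >= bbox[4])
    abort_fmt("bbox must be c(xmin, ymin, xmax, ymax) with xmin < xmax, ymin < ymax")
  if (ncols < 1 || nrows < 1) abort_fmt("ncols and nrows must be >= 1")
  dx <- (bbox[3] - bbox[1]) / ncols
  dy <- (bbox[4] - bbox[2]) / nrows
  xc <- bbox[1] + (seq_len(ncols) - 0.5) * dx
  yc <- bbox[4] - (seq_len(nrows) - 0.5) * dy  # top row first
  tx <- rep(xc, times = nrows)
  ty <- rep(yc, each = ncols)
  vals <- idw_predict(points, tx, ty, config)
  structure(list(bbox = unname(bbox), ncols = as.integer(ncols),
                 nrows = as.integer(nrows),
                 cellsize_x = dx, cellsize_y = dy,
                 values = matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)),
            class = "idw_surface")
}

#' @export
print.idw_surface <- function(x, ...) {
  cat(sprintf("IDW surface: %d x %d cells over [%g, %g] x [%g, %g] (%d no-data)\n",
              x$nrows, x$ncols, x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4],
              sum(is.na(x$values))))
  invisible(x)
}

#' Write a surface as an ESRI ASCII grid (.asc)
#'
#' Emits the standard header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by row-major values, top row first.
#' The format supports square cells only, so `cellsize_x` and `cellsize_y`
#' must agree to within a small relative tolerance.
#'
#' @param surface An [idw_grid()] result.
#' @param path Output path (conventionally `.asc`).
#' @param nodata Sentinel written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_asc <- function(surface, path, nodata = -9999) {
  if (!inherits(surface, "idw_surface")) abort_fmt("not an idw_surface")
  if (abs(surface$cellsize_x - surface$cellsize_y) >
      1e-9 * max(surface$cellsize_x, surface$cellsize_y))
    abort_fmt("ESRI ASCII grids require square cells; choose ncols/nrows matching the bbox aspect ratio")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", surface$ncols),
    sprintf("nrows %d", surface$nrows),
    sprintf("xllcorner %.10g", surface$bbox[1]),
    sprintf("yllcorner %.10g", surface$bbox[2]),
    sprintf("cellsize %.10g", surface$cellsize_x),
    sprintf("NODATA_value %g", nodata)), con)
  vals <- surface$values
  vals[is.na(vals)] <- nodata
  writeLines(apply(vals, 1, function(r) paste(sprintf("%.10g", r), collapse = " ")), con)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_asc()]
#'
#' @param path Path to a `.asc` file.
#' @return An `"idw_surface"` object; no-data cells become `NA`.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) abort_fmt("file not found: %s", path)
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[[`, character(1), 1))
  vals <- as.numeric(vapply(hdr, `[[`, character(1), 2))
  names(vals) <- keys
  ncols <- as.integer(vals[["ncols"]]); nrows <- as.integer(vals[["nrows"]])
  cs <- vals[["cellsize"]]; nodata <- vals[["nodata_value"]]
  m <- matrix(as.numeric(unlist(strsplit(trimws(lines[-(1:6)]), "\\s+"))),
              nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  bbox <- c(vals[["xllcorner"]], vals[["yllcorner"]],
            vals[["xllcorner"]] + ncols * cs, vals[["yllcorner"]] + nrows * cs)
  structure(list(bbox = unname(bbox), ncols = ncols, nrows = nrows,
                 cellsize_x = cs, cellsize_y = cs, values = m),
            class = "idw_surface")
}
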