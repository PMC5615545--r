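# File formats: transect CSV, clean-point CSV, scene GeoJSON, ESRI ASCII
# surfaces, JSON run configuration.  All coordinates are projected metres.

#' Read a transect CSV
#'
#' Required columns: `time_iso`, `x`, `y`, `pm25_raw`, `pm10_raw`, `temp_c`,
#' `rh_frac` (an `rh` or `rh_percent` column is also accepted).  RH given in
#' percent (values > 1.5) is converted to a fraction with a message.  Rows
#' with missing PM are dropped and counted in the `n_dropped` attribute.
#'
#' @param path CSV file path.
#' @return data.frame of transect records (`time`, `x`, `y`, `pm25_raw`,
#'   `pm10_raw`, `temp`, `rh`).
#' @export
read_transect_csv <- function(path) {
  if (!file.exists(path)) mk_stop("no such file: ", path)
  df <- as.data.frame(data.table::fread(path))
  rh_col <- intersect(c("rh_frac", "rh", "rh_percent"), names(df))[1]
  need <- c("x", "y", "pm25_raw", "pm10_raw")
  miss <- setdiff(need, names(df))
  if (length(miss) || is.na(rh_col))
    mk_stop("transect CSV is missing required column(s): ",
            paste(c(miss, if (is.na(rh_col)) "rh_frac"), collapse = ", "))
  time_col <- intersect(c("time_iso", "time"), names(df))[1]
  out <- data.frame(
    time = if (!is.na(time_col))
      as.POSIXct(df[[time_col]], tz = "UTC",
                 tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                                "%Y-%m-%d %H:%M:%S"))
      else as.POSIXct(NA),
    x = as.numeric(df$x), y = as.numeric(df$y),
    pm25_raw = as.numeric(df$pm25_raw), pm10_raw = as.numeric(df$pm10_raw),
    temp = if ("temp_c" %in% names(df)) as.numeric(df$temp_c) else NA_real_,
    rh = as.numeric(df[[rh_col]]))
  if (any(out$rh > 1.5, na.rm = TRUE)) {
    message("RH column looks like percent; dividing by 100")
    out$rh <- out$rh / 100
  }
  drop <- !is.finite(out$pm25_raw) | !is.finite(out$pm10_raw) |
    !is.finite(out$x) | !is.finite(out$y)
  if (any(drop)) message("dropping ", sum(drop), " row(s) with missing PM/coords")
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Write a transect CSV
#'
#' Columns: `time_iso, x, y, pm25_raw, pm10_raw, temp_c, rh_frac`.
#'
#' @param records transect records (as from [simulate_walk()]).
#' @param path output path.
#' @export
write_transect_csv <- function(records, path) {
  out <- data.frame(
    time_iso = format(records$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    x = records$x, y = records$y,
    pm25_raw = records$pm25_raw, pm10_raw = records$pm10_raw,
    temp_c = records$temp, rh_frac = records$rh)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Write / read clean points
#'
#' @param points clean points from [merge_passes()].
#' @param path CSV path.
#' @export
write_clean_csv <- function(points, path) {
  data.table::fwrite(points[, c("x", "y", "pm25", "pm10", "n_merged")], path)
  invisible(path)
}

#' @rdname write_clean_csv
#' @export
read_clean_csv <- function(path) {
  if (!file.exists(path)) mk_stop("no such file: ", path)
  df <- as.data.frame(data.table::fread(path))
  need <- c("x", "y", "pm25", "pm10")
  miss <- setdiff(need, names(df))
  if (length(miss)) mk_stop("clean-point CSV is missing column(s): ",
                            paste(miss, collapse = ", "))
  if (is.null(df$n_merged)) df$n_merged <- 1L
  df
}

# ---- GeoJSON scenes -------------------------------------------------------

poly_to_ring <- function(p) {
  ring <- rbind(p, p[1, , drop = FALSE])
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

#' Write a scene as GeoJSON
#'
#' Buildings carry `kind = "building"` and a `height` property; roads carry
#' `kind = "road"`.  Coordinates are projected metres (no CRS member is
#' written; the reader refuses lon/lat-looking input).
#'
#' @param scene an [mk_scene()].
#' @param path output path.
#' @export
write_scene_geojson <- function(scene, path) {
  feats <- c(
    lapply(scene$buildings, function(b) list(
      type = "Feature",
      properties = list(kind = "building", height = b$height),
      geometry = list(type = "Polygon",
                      coordinates = list(poly_to_ring(b$poly))))),
    lapply(scene$roads, function(r) list(
      type = "Feature",
      properties = list(kind = "road"),
      geometry = list(type = "Polygon",
                      coordinates = list(poly_to_ring(r))))))
  gj <- list(type = "FeatureCollection",
             properties = list(extent = scene$extent,
                               layout_kind = scene$layout_kind),
             features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 10), path)
  invisible(path)
}

#' Read a scene from GeoJSON
#'
#' Expects the layout written by [write_scene_geojson()]: polygon features
#' with a `kind` property; buildings must carry a positive `height`.  Rings
#' are normalised (closing vertex dropped, orientation ignored).  Input that
#' looks like geographic degrees (all coordinates within lon/lat bounds and
#' spanning less than one unit) is refused: a projected CRS in metres is
#' required.
#'
#' @param path GeoJSON path.
#' @return An [mk_scene()].
#' @export
read_scene_geojson <- function(path) {
  if (!file.exists(path)) mk_stop("no such file: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    mk_stop("expected a GeoJSON FeatureCollection")
  buildings <- list(); roads <- list()
  allx <- c(); ally <- c()
  for (f in gj$features) {
    if (!identical(f$geometry$type, "Polygon")) next
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ]))
      m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y")
    allx <- c(allx, m[, 1]); ally <- c(ally, m[, 2])
    kind <- f$properties$kind %||% "building"
    if (identical(kind, "road")) {
      roads[[length(roads) + 1L]] <- m
    } else {
      h <- f$properties$height
      if (is.null(h) || !is.numeric(h) || h <= 0)
        mk_stop("building feature without a positive 'height' property")
      buildings[[length(buildings) + 1L]] <- list(poly = m, height = h)
    }
  }
  if (!length(allx)) mk_stop("no polygon features found")
  span <- c(diff(range(allx)), diff(range(ally)))
  if (all(abs(allx) <= 180) && all(abs(ally) <= 90) && all(span < 1))
    mk_stop("coordinates look like geographic degrees; ",
            "a projected CRS in metres is required")
  ext <- unlist(gj$properties$extent) %||%
    c(min(allx), max(allx), min(ally), max(ally))
  mk_scene(as.numeric(ext), buildings, roads,
           layout_kind = gj$properties$layout_kind %||% "custom")
}

# ---- ESRI ASCII surfaces --------------------------------------------------

#' Write a prediction surface
#'
#' ESRI ASCII grid (`format = "asc"`): cell-registered, rows from the north,
#' `NODATA_value -9999` for masked cells, cell size recorded in the header.
#' The round trip through [read_surface_asc()] is value-exact at the printed
#' precision (15 significant digits).  GeoTIFF is not supported in this
#' build (no GDAL-backed dependency); requesting `"tif"` is an error.
#'
#' @param surface an [mk_surface()] (or a bare matrix plus `grid`).
#' @param path output path.
#' @param format `"asc"`.
#' @param layer which layer to write: `"values"`, `"values_raw"` or
#'   `"variance"`.
#' @export
write_surface <- function(surface, path, format = c("asc", "tif"),
                          layer = "values") {
  format <- match.arg(format)
  if (format == "tif")
    mk_stop("GeoTIFF output is not available in this build; use 'asc'")
  g <- surface$grid
  vals <- surface[[layer]]
  if (is.null(vals)) mk_stop("surface has no '", layer, "' layer")
  hdr <- c(sprintf("ncols %d", g$ncol), sprintf("nrows %d", g$nrow),
           sprintf("xllcorner %.10g", g$xmin),
           sprintf("yllcorner %.10g", g$ymin),
           sprintf("cellsize %.10g", g$cell),
           "NODATA_value -9999")
  body <- apply(vals, 1, function(r) {
    r[!is.finite(r)] <- -9999
    paste(formatC(r, format = "g", digits = 15), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid surface
#'
#' @param path `.asc` path.
#' @return An [mk_surface()] (masked where NODATA).
#' @export
read_surface_asc <- function(path) {
  if (!file.exists(path)) mk_stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    mk_stop("malformed ASC header; missing ",
            paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- hdr$nodata_value %||% -9999
  vals <- matrix(scan(text = lines[i:length(lines)], quiet = TRUE),
                 nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  vals[vals == nodata] <- NA_real_
  g <- mk_grid(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
               hdr$nrows, hdr$ncols)
  mk_surface(g, vals, mask = is.finite(vals), method = "file")
}

# ---- run configuration ----------------------------------------------------

#' Read and validate a run configuration (JSON)
#'
#' Schema (all optional unless noted): `seed`; `simulate` (logical) or
#' `transect_csv` + `scene_geojson` paths (required when not simulating);
#' `layout`, `merge_radius`, `grid_cell` (prediction resolution, m),
#' `cov_cell`, `kib_res`, `bandwidth`, `k`, `methods` (subset of the 13),
#' `variables`, `variogram_kind`, `thin` (keep every i-th record).
#' Referenced paths must exist at read time.
#'
#' @param path JSON file path.
#' @return A validated config list (class `mk_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) mk_stop("no such config file: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_config(cfg, dir = dirname(path))
}

validate_config <- function(cfg, dir = ".") {
  defaults <- list(seed = 1L, simulate = TRUE, layout = "orthogonal",
                   merge_radius = 2.0, grid_cell = NULL, cov_cell = 20,
                   kib_res = NULL, bandwidth = 50, k = 2,
                   methods = METHOD_NAMES,
                   variables = c("pm25", "pm10"),
                   variogram_kind = "stable", thin = 1L)
  cfg <- modifyList(defaults, as.list(cfg))
  bad <- setdiff(cfg$methods, METHOD_NAMES)
  if (length(bad)) mk_stop("unknown method(s) in config: ",
                           paste(bad, collapse = ", "))
  if (!isTRUE(cfg$simulate)) {
    for (key in c("transect_csv", "scene_geojson")) {
      if (is.null(cfg[[key]]))
        mk_stop("config without simulate=true must set '", key, "'")
      p <- cfg[[key]]
      if (!file.exists(p) && !file.exists(file.path(dir, p)))
        mk_stop("config path does not exist: ", p)
      if (!file.exists(p)) cfg[[key]] <- file.path(dir, p)
    }
  }
  structure(cfg, class = c("mk_config", "list"))
}
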