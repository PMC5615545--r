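#' Regular raster grid definition
#'
#' Cell-registered grid in projected metre coordinates.  Values attached to a
#' grid are stored as an `nrow x ncol` matrix whose first row is the
#' *northern* edge (row-major from the north-west origin, the convention of
#' ESRI ASCII grids); `values[i, j]` sits at centre
#' `(xmin + (j - 0.5) cell, ymax - (i - 0.5) cell)`.
#'
#' @param xmin,ymin lower-left corner (m).
#' @param cell cell size (m), > 0.
#' @param nrow,ncol grid dimensions.
#' @return An object of class `mk_grid`.
#' @export
mk_grid <- function(xmin, ymin, cell, nrow, ncol) {
  stopifnot(cell > 0, nrow >= 1, ncol >= 1)
  structure(list(xmin = xmin, ymin = ymin, cell = cell,
                 nrow = as.integer(nrow), ncol = as.integer(ncol)),
            class = "mk_grid")
}

#' @export
print.mk_grid <- function(x, ...) {
  cat(sprintf("<mk_grid %d x %d cells of %.4g m, origin (%.4g, %.4g)>\n",
              x$nrow, x$ncol, x$cell, x$xmin, x$ymin))
  invisible(x)
}

grid_xmax <- function(g) g$xmin + g$ncol * g$cell
grid_ymax <- function(g) g$ymin + g$nrow * g$cell
grid_ncell <- function(g) g$nrow * g$ncol

# Cell-centre coordinates in the row-major (north-west first) cell order,
# matching `as.vector(t(values))`.
grid_center_coords <- function(g) {
  xs <- g$xmin + (seq_len(g$ncol) - 0.5) * g$cell
  ys <- grid_ymax(g) - (seq_len(g$nrow) - 0.5) * g$cell
  cbind(x = rep(xs, times = g$nrow), y = rep(ys, each = g$ncol))
}

# Reshape a row-major cell vector back into the value matrix.
grid_matrix <- function(g, v) matrix(v, nrow = g$nrow, ncol = g$ncol, byrow = TRUE)

#' Default prediction grid for an extent
#'
#' Cell size defaults to the short extent side divided by 330 (about 1.5 m on
#' a 500 m site, within the 1.4--1.7 m resolution range typical of
#' fine-scale PM prediction surfaces).
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)`.
#' @param cell optional cell size override (m).
#' @return An [mk_grid()].
#' @export
mk_grid_for_extent <- function(extent, cell = NULL) {
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  stopifnot(w > 0, h > 0)
  if (is.null(cell)) cell <- min(w, h) / 330
  mk_grid(extent[1], extent[3], cell,
          nrow = max(1L, floor(h / cell)), ncol = max(1L, floor(w / cell)))
}

# Row/col of the cell containing points (clamped to the grid).
grid_rowcol <- function(g, xy) {
  col <- pmin(pmax(ceiling((xy[, 1] - g$xmin) / g$cell), 1L), g$ncol)
  row <- pmin(pmax(ceiling((grid_ymax(g) - xy[, 2]) / g$cell), 1L), g$nrow)
  cbind(row = as.integer(row), col = as.integer(col))
}

# Bilinear interpolation of a value matrix at arbitrary points.  Points
# outside the ring of cell centres are clamped to the edge.
grid_bilinear <- function(g, values, xy) {
  stopifnot(is.matrix(values), nrow(values) == g$nrow, ncol(values) == g$ncol)
  fx <- (xy[, 1] - g$xmin) / g$cell - 0.5          # 0 at first col centre
  fy <- (grid_ymax(g) - xy[, 2]) / g$cell - 0.5    # 0 at first row centre
  fx <- pmin(pmax(fx, 0), g$ncol - 1)
  fy <- pmin(pmax(fy, 0), g$nrow - 1)
  j0 <- pmin(floor(fx), g$ncol - 2 + (g$ncol == 1)); j0 <- pmax(j0, 0)
  i0 <- pmin(floor(fy), g$nrow - 2 + (g$nrow == 1)); i0 <- pmax(i0, 0)
  tx <- fx - j0; ty <- fy - i0
  i1 <- pmin(i0 + 1, g$nrow - 1); j1 <- pmin(j0 + 1, g$ncol - 1)
  idx <- function(i, j) values[cbind(i + 1L, j + 1L)]
  (1 - tx) * (1 - ty) * idx(i0, j0) + tx * (1 - ty) * idx(i0, j1) +
    (1 - tx) * ty * idx(i1, j0) + tx * ty * idx(i1, j1)
}

#' Prediction surface container
#'
#' @param grid an [mk_grid()].
#' @param values matrix of predictions (north-west origin, row-major); values
#'   are floor-clamped at zero for concentration output, the unclamped raw
#'   prediction is retained in `values_raw`.
#' @param variance optional matrix of prediction variance (kriging only).
#' @param mask logical matrix, `TRUE` where a prediction is defined.
#' @param method method name (e.g. `"OCK_SVF"`).
#' @return An object of class `mk_surface`.
#' @export
mk_surface <- function(grid, values, variance = NULL, mask = NULL,
                       method = "unknown") {
  raw <- values
  values <- pmax(values, 0)
  if (is.null(mask)) mask <- is.finite(raw)
  values[!mask] <- NA_real_
  raw[!mask] <- NA_real_
  if (!is.null(variance)) {
    variance <- pmax(variance, 0)
    variance[!mask] <- NA_real_
  }
  structure(list(grid = grid, values = values, values_raw = raw,
                 variance = variance, mask = mask, method = method),
            class = "mk_surface")
}

#' @export
print.mk_surface <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<mk_surface %s: %d x %d @ %.3g m, range [%.3g, %.3g], %d masked>\n",
              x$method, x$grid$nrow, x$grid$ncol, x$grid$cell,
              rng[1], rng[2], sum(!x$mask)))
  invisible(x)
}
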