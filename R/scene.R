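#' Urban scene container
#'
#' A rectangular site (projected metres) holding building footprints with
#' heights and road polygons.  Scenes are either generated
#' ([make_street_grid()]) or read from GeoJSON ([read_scene_geojson()]).
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in metres.
#' @param buildings list of `list(poly = <2-col matrix>, height = <m>)`.
#' @param roads list of 2-column polygon matrices.
#' @param layout_kind `"orthogonal"`, `"irregular"` or `"custom"`.
#' @param meta optional list of generator metadata.
#' @return An object of class `mk_scene`.
#' @export
mk_scene <- function(extent, buildings, roads, layout_kind = "custom",
                     meta = list()) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  for (b in buildings) {
    stopifnot(is.matrix(b$poly), ncol(b$poly) == 2, is.numeric(b$height))
    if (b$height <= 0) mk_stop("building heights must be > 0")
  }
  structure(list(extent = extent, buildings = buildings, roads = roads,
                 layout_kind = layout_kind, meta = meta),
            class = "mk_scene")
}

#' @export
print.mk_scene <- function(x, ...) {
  cat(sprintf("<mk_scene [%s] %g x %g m, %d buildings, %d road polygons>\n",
              x$layout_kind, x$extent[2] - x$extent[1],
              x$extent[4] - x$extent[3],
              length(x$buildings), length(x$roads)))
  invisible(x)
}

building_polys <- function(scene) lapply(scene$buildings, `[[`, "poly")
building_heights <- function(scene) vapply(scene$buildings, `[[`, 0, "height")

#' Generate a synthetic street-grid scene
#'
#' Builds a block-and-street urban layout: road strips of constant width on a
#' regular lattice, one building per block inset by a margin.  The
#' `"orthogonal"` layout is a classical rectangular grid; the
#' `"irregular"` layout jitters the street positions and randomly merges
#' adjacent blocks (removing the street segment between them), emulating a
#' less regular road network.
#'
#' @param layout_kind `"orthogonal"` or `"irregular"`.
#' @param extent site size in metres, `c(width, height)` (origin at 0) or a
#'   full `c(xmin, xmax, ymin, ymax)`.  Default 500 x 500 m.
#' @param block_size block pitch minus road width (m).
#' @param road_width street width (m); must satisfy `block_size > road_width > 0`.
#' @param height_law `c(mean, sd)` of the Gaussian building-height law (m);
#'   draws are floored at 3 m.
#' @param seed RNG seed; the scene is deterministic for a fixed seed.
#' @return An [mk_scene()].
#' @examples
#' sc <- make_street_grid("orthogonal", c(500, 500), 80, 20, c(40, 15), seed = 1)
#' length(sc$buildings) # 25
#' @export
make_street_grid <- function(layout_kind = c("orthogonal", "irregular"),
                             extent = c(500, 500), block_size = 80,
                             road_width = 20, height_law = c(40, 15),
                             seed = NULL) {
  layout_kind <- match.arg(layout_kind)
  if (length(extent) == 2) extent <- c(0, extent[1], 0, extent[2])
  W <- extent[2] - extent[1]; H <- extent[4] - extent[3]
  if (W <= 0 || H <= 0) mk_stop("extent dimensions must be positive")
  if (!(block_size > road_width && road_width > 0))
    mk_stop("need block_size > road_width > 0")
  p <- block_size + road_width
  nx <- floor(W / p); ny <- floor(H / p)
  if (nx < 1 || ny < 1) mk_stop("extent too small for one block")

  with_seed(seed, {
    vx <- extent[1] + (0:(nx - 1)) * p      # left edges of vertical streets
    hy <- extent[3] + (0:(ny - 1)) * p      # bottom edges of horizontal streets
    if (layout_kind == "irregular" && nx > 1)
      vx[-1] <- vx[-1] + runif(nx - 1, -0.15, 0.15) * block_size
    if (layout_kind == "irregular" && ny > 1)
      hy[-1] <- hy[-1] + runif(ny - 1, -0.15, 0.15) * block_size
    vx_next <- c(vx[-1], extent[1] + W)     # block right edge = next street
    hy_next <- c(hy[-1], extent[3] + H)

    # blocks indexed (row r = 1..ny bottom-up, col c = 1..nx)
    merged_with_right <- matrix(FALSE, ny, nx)
    if (layout_kind == "irregular" && nx >= 4) {
      n_merge <- max(1L, round(0.15 * nx * ny))
      for (m in seq_len(n_merge)) {
        r <- sample.int(ny, 1)
        c <- sample(seq(2L, nx - 2L), 1)    # keep outer streets intact
        if (!merged_with_right[r, c] && !merged_with_right[r, c - 1] &&
            !merged_with_right[r, min(c + 1, nx)])
          merged_with_right[r, c] <- TRUE
      }
    }

    margin <- max(2, block_size / 8)
    buildings <- list()
    heights_pool <- pmax(3, rnorm(nx * ny, height_law[1], height_law[2]))
    hidx <- 0L
    skip <- matrix(FALSE, ny, nx)           # absorbed into a left neighbour
    for (r in seq_len(ny)) for (c in seq_len(nx)) {
      if (skip[r, c]) next
      x0 <- vx[c] + road_width; y0 <- hy[r] + road_width
      if (merged_with_right[r, c]) {
        x1 <- vx_next[c + 1]; skip[r, c + 1] <- TRUE
      } else x1 <- vx_next[c]
      y1 <- hy_next[r]
      hidx <- hidx + 1L
      buildings[[length(buildings) + 1L]] <- list(
        poly = rect_poly(x0 + margin, y0 + margin, x1 - margin, y1 - margin),
        height = heights_pool[hidx])
    }

    roads <- list()
    for (r in seq_len(ny))                  # horizontal strips, full width
      roads[[length(roads) + 1L]] <-
        rect_poly(extent[1], hy[r], extent[1] + W, hy[r] + road_width)
    for (c in seq_len(nx)) for (r in seq_len(ny)) {
      if (c >= 2 && merged_with_right[r, c - 1]) next  # removed by a merge
      roads[[length(roads) + 1L]] <-
        rect_poly(vx[c], hy[r] + road_width, vx[c] + road_width, hy_next[r])
    }

    mk_scene(extent, buildings, roads, layout_kind,
             meta = list(block_size = block_size, road_width = road_width,
                         pitch = p, nx = nx, ny = ny, vx = vx, hy = hy,
                         seed = seed))
  })
}

#' Walking route along the streets of a generated scene
#'
#' Boustrophedon route along the centrelines of the horizontal streets,
#' connected through the outermost vertical streets, emulating a pedestrian
#' survey that covers the whole site.
#'
#' @param scene a scene from [make_street_grid()].
#' @param speed walking speed (m/s), default 0.8 (3 km/h).
#' @param interval sampling interval (s), default 1.
#' @param directions `"forward"` or `"both"` (forward plus backward pass).
#' @return An object of class `mk_route`: vertices, speed, interval, directions.
#' @export
route_from_scene <- function(scene, speed = 0.8, interval = 1,
                             directions = c("both", "forward")) {
  directions <- match.arg(directions)
  m <- scene$meta
  if (is.null(m$vx)) mk_stop("route_from_scene needs a generated street grid")
  rw <- m$road_width
  ycenters <- m$hy + rw / 2
  xleft <- m$vx[1] + rw / 2
  xright <- m$vx[length(m$vx)] + rw / 2
  verts <- matrix(numeric(0), 0, 2)
  for (r in seq_along(ycenters)) {
    xs <- if (r %% 2 == 1) c(xleft, xright) else c(xright, xleft)
    verts <- rbind(verts, cbind(xs, ycenters[r]))
  }
  mk_route(verts, speed = speed, interval = interval, directions = directions)
}

#' Walking route constructor
#'
#' @param vertices 2-column matrix of polyline vertices (m).
#' @param speed walking speed (m/s), > 0.
#' @param interval sampling interval (s), > 0.
#' @param directions `"forward"` or `"both"`.
#' @export
mk_route <- function(vertices, speed = 0.8, interval = 1,
                     directions = c("forward", "both")) {
  directions <- match.arg(directions)
  stopifnot(is.matrix(vertices), ncol(vertices) == 2, nrow(vertices) >= 2)
  if (speed <= 0) mk_stop("walking speed must be > 0")
  if (interval <= 0) mk_stop("sampling interval must be > 0")
  structure(list(vertices = unname(vertices), speed = speed,
                 interval = interval, directions = directions),
            class = "mk_route")
}

#' @export
print.mk_route <- function(x, ...) {
  cat(sprintf("<mk_route %.0f m at %.2g m/s, %s>\n",
              polyline_length(x$vertices), x$speed, x$directions))
  invisible(x)
}
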