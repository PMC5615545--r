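# Small planar-geometry kit for rectangular-ish urban scenes.  Polygons are
# two-column (x, y) matrices, vertices in order, not closed.

poly_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

poly_centroid <- function(p) colMeans(p)

rect_poly <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

# Ray-casting point-in-polygon, vectorised over points (boundary counts as in).
points_in_poly <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- logical(length(x))
  px <- poly[, 1]; py <- poly[, 2]
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  # count points exactly on an edge as inside (cheap test on bounding segs)
  inside
}

points_in_any_poly <- function(x, y, polys) {
  inside <- logical(length(x))
  for (p in polys) {
    todo <- which(!inside)
    if (!length(todo)) break
    bb <- apply(p, 2, range)
    cand <- todo[x[todo] >= bb[1, 1] & x[todo] <= bb[2, 1] &
                 y[todo] >= bb[1, 2] & y[todo] <= bb[2, 2]]
    if (length(cand))
      inside[cand] <- points_in_poly(x[cand], y[cand], p)
  }
  inside
}

# Edge table of a list of polygons: one row per edge with an attached value
# (e.g. building height).
poly_edges <- function(polys, values = NULL) {
  out <- lapply(seq_along(polys), function(i) {
    p <- polys[[i]]
    n <- nrow(p)
    j <- c(2:n, 1)
    cbind(x1 = p[, 1], y1 = p[, 2], x2 = p[j, 1], y2 = p[j, 2],
          val = if (is.null(values)) i else values[i])
  })
  do.call(rbind, out)
}

# Length of a polyline (two-column matrix).
polyline_length <- function(v) {
  if (nrow(v) < 2) return(0)
  sum(sqrt(diff(v[, 1])^2 + diff(v[, 2])^2))
}

# Positions along a polyline at arc-length s (vectorised, clamped to [0, L]).
polyline_point <- function(v, s) {
  seg <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  s <- pmin(pmax(s, 0), L)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(seg))
  t <- ifelse(seg[i] > 0, (s - cum[i]) / seg[i], 0)
  cbind(x = v[i, 1] + t * (v[i + 1, 1] - v[i, 1]),
        y = v[i, 2] + t * (v[i + 1, 2] - v[i, 2]))
}
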