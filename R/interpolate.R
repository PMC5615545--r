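# The four interpolation engines (LPI, OK, OCK, KIB) over a common
# "predict at arbitrary targets" core, plus the 13-configuration dispatcher.

# Min-max scale a covariate into [0.1, 1] for use as an LPI/KIB weight
# factor; a constant covariate contributes nothing (all weights 1).
scale_weight_factor <- function(v) {
  rng <- range(v)
  if (!is.finite(rng[1]) || diff(rng) < 1e-12) return(rep(1, length(v)))
  0.1 + 0.9 * (v - rng[1]) / diff(rng)
}

# ---- local polynomial interpolation ---------------------------------------

n_poly_terms <- function(order) (order + 1) * (order + 2) / 2

poly_design <- function(dx, dy, order) {
  switch(as.character(order),
         "0" = matrix(1, length(dx), 1),
         "1" = cbind(rep(1, length(dx)), dx, dy, deparse.level = 0),
         "2" = cbind(rep(1, length(dx)), dx, dy, dx^2, dx * dy, dy^2,
                     deparse.level = 0),
         mk_stop("polynomial order must be 0, 1 or 2"))
}

# Kernel-weighted local polynomial prediction at arbitrary targets.
# `exclude` removes one sample index from every neighbourhood (LOOCV).
predict_lpi_at <- function(coords, values, targets, kernel, order = 1,
                           cvals = NULL, exclude = NULL) {
  coords <- as.matrix(coords); targets <- as.matrix(targets)
  n <- nrow(coords)
  if (is.null(cvals)) cvals <- rep(1, n)
  cutoff <- kernel_cutoff(kernel)
  m <- nrow(targets)
  pred <- rep(NA_real_, m)
  flag <- integer(m)                      # 0 ok, >0 order reduced, -1 empty
  keep0 <- rep(TRUE, n)
  if (!is.null(exclude)) keep0[exclude] <- FALSE
  for (t in seq_len(m)) {
    d <- sqrt((coords[, 1] - targets[t, 1])^2 +
              (coords[, 2] - targets[t, 2])^2)
    nb <- which(keep0 & d <= cutoff)
    if (!length(nb)) { flag[t] <- -1L; next }
    w <- kernel_value(kernel, d[nb]) * cvals[nb]
    pos <- w > 1e-14
    nb <- nb[pos]; w <- w[pos]
    if (!length(nb)) { flag[t] <- -1L; next }
    o <- order
    repeat {
      if (length(nb) < n_poly_terms(o)) { o <- o - 1L; next }
      X <- poly_design(coords[nb, 1] - targets[t, 1],
                       coords[nb, 2] - targets[t, 2], o)
      sw <- sqrt(w)
      qrx <- qr(X * sw)
      if (qrx$rank < ncol(X) && o > 0) { o <- o - 1L; next }
      beta <- qr.coef(qrx, values[nb] * sw)
      pred[t] <- beta[1]
      if (o < order) flag[t] <- order - o
      break
    }
  }
  list(pred = pred, flag = flag)
}

#' Local polynomial interpolation surface
#'
#' Per cell, a kernel-weighted least-squares polynomial in `(x, y)` is fitted
#' to the samples within the kernel support (infinite-support kernels are cut
#' at `3h`), with weights `K(r) * c_i` where `c_i` is 1 or a covariate weight
#' factor min-max scaled into `[0.1, 1]`; the prediction is the polynomial at
#' the cell centre.  Rank-deficient local fits fall back to a lower order
#' (flagged in the `flag` attribute); cells with no neighbours are masked.
#'
#' @param points clean points (data.frame with `x`, `y`).
#' @param values response at the points.
#' @param kernel a [kernel_spec()].
#' @param grid an [mk_grid()] prediction grid.
#' @param order polynomial order (0--2, default 1).
#' @param weight_factor_values optional covariate values at the points used
#'   as multiplicative weight factors.
#' @return An [mk_surface()].
#' @export
lpi_predict <- function(points, values, kernel, grid, order = 1,
                        weight_factor_values = NULL) {
  coords <- as.matrix(points[, c("x", "y")])
  cvals <- if (is.null(weight_factor_values)) NULL else
    scale_weight_factor(weight_factor_values)
  res <- predict_lpi_at(coords, values, grid_center_coords(grid), kernel,
                        order, cvals)
  sf <- mk_surface(grid, grid_matrix(grid, res$pred), method = "LPI")
  attr(sf, "flag") <- grid_matrix(grid, res$flag)
  sf
}

# ---- ordinary kriging -----------------------------------------------------

check_no_duplicates <- function(coords) {
  D <- as.matrix(dist(coords))
  diag(D) <- Inf
  dup <- which(D < 1e-9, arr.ind = TRUE)
  if (nrow(dup)) {
    i <- dup[1, 1]
    mk_stop("duplicate sample coordinates at (",
            signif(coords[i, 1], 8), ", ", signif(coords[i, 2], 8),
            "); merge duplicates before kriging")
  }
  invisible(D)
}

# Ordinary kriging at arbitrary targets: solve the augmented system
# [Gamma 1; 1' 0] [lambda; mu] = [gamma0; 1] per target (multi-RHS solve).
predict_ok_at <- function(coords, values, model, targets, chunk = 4000L) {
  coords <- as.matrix(coords); targets <- as.matrix(targets)
  n <- nrow(coords)
  if (n < 2) mk_stop("ordinary kriging needs at least 2 points")
  D <- as.matrix(dist(coords)); diag(D) <- Inf
  if (any(D < 1e-9)) check_no_duplicates(coords)
  diag(D) <- 0
  G <- model_gamma(model, D); dim(G) <- dim(D)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  m <- nrow(targets)
  pred <- numeric(m); vr <- numeric(m); werr <- 0
  for (s in seq(1, m, by = chunk)) {
    idx <- s:min(s + chunk - 1L, m)
    d0 <- sqrt(outer(coords[, 1], targets[idx, 1], "-")^2 +
               outer(coords[, 2], targets[idx, 2], "-")^2)
    g0 <- model_gamma(model, d0); dim(g0) <- dim(d0)
    rhs <- rbind(g0, 1)
    sol <- tryCatch(solve(A, rhs), error = function(e)
      mk_stop("singular kriging system: ", conditionMessage(e)))
    lam <- sol[1:n, , drop = FALSE]
    mu <- sol[n + 1, ]
    pred[idx] <- as.vector(crossprod(lam, values))
    vr[idx] <- colSums(lam * g0) + mu
    werr <- max(werr, max(abs(colSums(lam) - 1)))
  }
  list(pred = pred, variance = vr, weight_sum_err = werr)
}

#' Ordinary kriging surface
#'
#' Exact interpolator: the prediction at a sample coordinate equals the
#' observation with zero kriging variance.  Weights obey the sum-to-one
#' unbiasedness constraint (the attained maximum deviation is stored in the
#' `weight_sum_err` attribute).  The global neighbourhood (all points) is
#' used; merge duplicate coordinates first ([merge_passes()]).
#'
#' @param points clean points (data.frame with `x`, `y`).
#' @param values response at the points.
#' @param model a fitted [mk_vgm()].
#' @param grid an [mk_grid()] prediction grid.
#' @return An [mk_surface()] with a prediction `variance` layer.
#' @export
ok_predict <- function(points, values, model, grid) {
  coords <- as.matrix(points[, c("x", "y")])
  res <- predict_ok_at(coords, values, model, grid_center_coords(grid))
  sf <- mk_surface(grid, grid_matrix(grid, res$pred),
                   variance = grid_matrix(grid, res$variance), method = "OK")
  attr(sf, "weight_sum_err") <- res$weight_sum_err
  sf
}

# ---- ordinary cokriging ---------------------------------------------------

# Augmented ordinary-cokriging matrix: one unbiasedness constraint per
# variable (primary weights sum to 1, each covariate's weights sum to 0).
ock_system <- function(coords, coreg, nv) {
  check_no_duplicates(coords)
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  unit <- mk_vgm(coreg$kind, nugget = 0, psill = 1, range = coreg$range,
                 shape = coreg$shape)
  Gs <- model_gamma(unit, D)
  Pos <- (D > 0) * 1
  Atop <- kronecker(coreg$B_nugget, Pos) + kronecker(coreg$B_psill, Gs)
  Cmat <- matrix(0, n * nv, nv)
  for (u in seq_len(nv)) Cmat[(u - 1) * n + seq_len(n), u] <- 1
  rbind(cbind(Atop, Cmat), cbind(t(Cmat), matrix(0, nv, nv)))
}

# Ordinary cokriging of the primary variable at arbitrary targets under a
# linear model of coregionalization.
predict_ock_at <- function(coords, values, covmat, coreg, targets,
                           chunk = 2000L) {
  coords <- as.matrix(coords); targets <- as.matrix(targets)
  covmat <- as.matrix(covmat)
  n <- nrow(coords); p <- ncol(covmat)
  stopifnot(nrow(covmat) == n, length(values) == n)
  if (p + 1 != length(coreg$vars))
    mk_stop("covariate table does not match the coregionalization (",
            p, " vs ", length(coreg$vars) - 1, " secondaries)")
  nv <- p + 1
  unit <- mk_vgm(coreg$kind, nugget = 0, psill = 1, range = coreg$range,
                 shape = coreg$shape)
  A <- ock_system(coords, coreg, nv)
  allv <- as.vector(cbind(values, covmat))
  m <- nrow(targets)
  pred <- numeric(m); vr <- numeric(m); werr <- 0
  for (s in seq(1, m, by = chunk)) {
    idx <- s:min(s + chunk - 1L, m)
    d0 <- sqrt(outer(coords[, 1], targets[idx, 1], "-")^2 +
               outer(coords[, 2], targets[idx, 2], "-")^2)
    g0u <- model_gamma(unit, d0); dim(g0u) <- dim(d0)
    p0 <- (d0 > 0) * 1
    rhs_top <- do.call(rbind, lapply(seq_len(nv), function(u)
      coreg$B_nugget[u, 1] * p0 + coreg$B_psill[u, 1] * g0u))
    rhs <- rbind(rhs_top, matrix(0, nv, length(idx)))
    rhs[n * nv + 1, ] <- 1
    sol <- tryCatch(solve(A, rhs), error = function(e)
      mk_stop("singular cokriging system: ", conditionMessage(e)))
    lam <- sol[seq_len(n * nv), , drop = FALSE]
    mu1 <- sol[n * nv + 1, ]
    pred[idx] <- as.vector(crossprod(lam, allv))
    vr[idx] <- colSums(lam * rhs_top) + mu1
    werr <- max(werr, max(abs(colSums(lam[seq_len(n), , drop = FALSE]) - 1)))
  }
  list(pred = pred, variance = vr, weight_sum_err = werr)
}

#' Ordinary cokriging surface
#'
#' Kriging of the primary variable assisted by building-geometry covariates
#' observed at the sample points, under a positive-semidefinite linear model
#' of coregionalization ([fit_coregionalization()]).  With all cross sills
#' zero the system decouples and reproduces [ok_predict()].
#'
#' @param points clean points (data.frame with `x`, `y`).
#' @param values primary variable at the points.
#' @param covariates data.frame of secondary variables at the points, in the
#'   order of `coreg$vars[-1]`.
#' @param coreg an `mk_coreg` from [fit_coregionalization()].
#' @param grid an [mk_grid()] prediction grid.
#' @return An [mk_surface()] with a prediction `variance` layer.
#' @export
ock_predict <- function(points, values, covariates, coreg, grid) {
  coords <- as.matrix(points[, c("x", "y")])
  res <- predict_ock_at(coords, values, as.matrix(covariates), coreg,
                        grid_center_coords(grid))
  sf <- mk_surface(grid, grid_matrix(grid, res$pred),
                   variance = grid_matrix(grid, res$variance), method = "OCK")
  attr(sf, "weight_sum_err") <- res$weight_sum_err
  sf
}

# ---- kernel interpolation with barriers -----------------------------------

# Lattice graph over the scene at resolution `res`; cells whose centre lies
# inside a building are impassable.  8-connected, diagonal steps cost
# sqrt(2) * res.
barrier_graph <- function(scene, res) {
  ext <- scene$extent
  g <- mk_grid(ext[1], ext[3], res,
               nrow = max(2, round((ext[4] - ext[3]) / res)),
               ncol = max(2, round((ext[2] - ext[1]) / res)))
  ctr <- grid_center_coords(g)
  passable <- !points_in_any_poly(ctr[, 1], ctr[, 2], building_polys(scene))
  nr <- g$nrow; nc <- g$ncol
  id <- function(r, c) (r - 1L) * nc + c
  edges <- list(); weights <- list()
  dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (k in seq_along(dirs)) {
    dr <- dirs[[k]][1]; dc <- dirs[[k]][2]
    rs <- seq_len(nr - dr)
    cs <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    from <- as.vector(outer(cs, rs, function(c, r) id(r, c)))
    to <- as.vector(outer(cs, rs, function(c, r) id(r + dr, c + dc)))
    ok <- passable[from] & passable[to]
    edges[[k]] <- rbind(from[ok], to[ok])
    weights[[k]] <- rep(res * sqrt(dr^2 + dc^2), sum(ok))
  }
  graph <- igraph::make_graph(edges = as.vector(do.call(cbind, edges)),
                              n = nr * nc, directed = FALSE)
  igraph::E(graph)$weight <- unlist(weights)
  list(graph = graph, grid = g, passable = passable)
}

cell_id_of <- function(g, xy) {
  rc <- grid_rowcol(g, as.matrix(xy))
  (rc[, 1] - 1L) * g$ncol + rc[, 2]
}

#' Shortest around-building walking distance between two points
#'
#' Length of the shortest 8-connected grid path (diagonal steps cost
#' `sqrt(2) * res`) with building-interior cells impassable.  Symmetric;
#' equals the straight-line distance (up to the octile-metric discretisation)
#' when no building blocks the segment; `Inf` when a point is enclosed.
#'
#' @param scene an [mk_scene()].
#' @param from,to numeric `c(x, y)`; must not lie inside a building.
#' @param res grid resolution (m); default short extent side / 100.
#' @return Distance in metres (possibly `Inf`).
#' @export
barrier_distance <- function(scene, from, to, res = NULL) {
  if (is.null(res))
    res <- min(scene$extent[2] - scene$extent[1],
               scene$extent[4] - scene$extent[3]) / 100
  polys <- building_polys(scene)
  if (any(points_in_any_poly(c(from[1], to[1]), c(from[2], to[2]), polys)))
    mk_stop("both endpoints must lie outside buildings")
  eu <- sqrt(sum((from - to)^2))
  if (!length(polys)) return(eu)
  # line-of-sight: exact Euclidean distance when no building blocks the path
  ns <- max(2L, ceiling(eu / (res / 2)))
  tt <- seq(0, 1, length.out = ns)
  sx <- from[1] + tt * (to[1] - from[1]); sy <- from[2] + tt * (to[2] - from[2])
  if (!any(points_in_any_poly(sx, sy, polys))) return(eu)
  bg <- barrier_graph(scene, res)
  ids <- cell_id_of(bg$grid, rbind(from, to))
  if (!all(bg$passable[ids]))
    mk_stop("both endpoints must lie outside buildings")
  as.numeric(igraph::distances(bg$graph, v = ids[1], to = ids[2]))
}

# Nadaraya-Watson smoothing with barrier distances at arbitrary target cells.
predict_kib_at <- function(coords, values, kernel, scene, targets, res,
                           cvals = NULL, exclude = NULL, bg = NULL,
                           loo = FALSE) {
  coords <- as.matrix(coords); targets <- as.matrix(targets)
  n <- nrow(coords)
  if (is.null(cvals)) cvals <- rep(1, n)
  n_unusable <- 0L
  if (!length(scene$buildings)) {
    # barrier-free limit: exact Euclidean distances (the grid-path octile
    # metric would overestimate off-axis distances by up to 8 %)
    Dm <- sqrt(outer(coords[, 1], targets[, 1], "-")^2 +
               outer(coords[, 2], targets[, 2], "-")^2)
  } else {
  if (is.null(bg)) bg <- barrier_graph(scene, res)
  src <- cell_id_of(bg$grid, coords)
  dst <- cell_id_of(bg$grid, targets)
  usable <- bg$passable[src]
  if (!any(usable)) mk_stop("every sample point falls inside a building")
  n_unusable <- sum(!usable)
  Dm <- matrix(Inf, n, nrow(targets))
  dst_pass <- bg$passable[dst]
  dst_u <- unique(dst[dst_pass])
  if (length(dst_u)) {
    dd <- igraph::distances(bg$graph, v = src[usable], to = dst_u)
    cols <- which(dst_pass)
    Dm[usable, cols] <- dd[, match(dst[cols], dst_u), drop = FALSE]
  }
  }
  keep <- rep(TRUE, n)
  if (!is.null(exclude)) keep[exclude] <- FALSE
  W <- kernel_value(kernel, Dm) * cvals * keep
  if (loo) diag(W) <- 0   # targets are the samples: hold each one out
  sw <- colSums(W)
  pred <- ifelse(sw > 1e-12, colSums(W * values) / sw, NA_real_)
  list(pred = pred, sumw = sw, n_unusable_sources = n_unusable)
}

#' Kernel interpolation with barriers (KIB) surface
#'
#' Nadaraya-Watson kernel smoother whose distances are shortest walking
#' paths around the building footprints ([barrier_distance()]) computed on
#' the prediction grid's resolution.  Weights are `K(d) * c_i` with the same
#' optional covariate weight factor as LPI.  Cells with total weight below
#' `1e-12` (or unreachable) are masked; an entirely masked surface raises an
#' error advising a larger bandwidth.
#'
#' @param points clean points (data.frame with `x`, `y`).
#' @param values response at the points.
#' @param kernel a [kernel_spec()].
#' @param scene an [mk_scene()] supplying the barrier (building) layer.
#' @param grid an [mk_grid()] prediction grid (also the path grid).
#' @param weight_factor_values optional covariate weight factor at the points.
#' @return An [mk_surface()].
#' @export
kib_predict <- function(points, values, kernel, scene, grid,
                        weight_factor_values = NULL) {
  coords <- as.matrix(points[, c("x", "y")])
  cvals <- if (is.null(weight_factor_values)) NULL else
    scale_weight_factor(weight_factor_values)
  res <- predict_kib_at(coords, values, kernel, scene,
                        grid_center_coords(grid), res = grid$cell,
                        cvals = cvals)
  if (all(!is.finite(res$pred)))
    mk_stop("all cells masked (total kernel weight < 1e-12 everywhere); ",
            "use a larger bandwidth")
  sf <- mk_surface(grid, grid_matrix(grid, res$pred), method = "KIB")
  attr(sf, "n_unusable_sources") <- res$n_unusable_sources
  sf
}

# ---- the 13 configurations ------------------------------------------------

METHOD_NAMES <- c("LPI", "LPI_SVF", "LPI_FAI", "LPI_RDA",
                  "OK", "OCK_SVF", "OCK_FAI", "OCK_RDA", "OCK_ALL",
                  "KIB", "KIB_SVF", "KIB_FAI", "KIB_RDA")

#' One of the 13 interpolation configurations
#'
#' @param name method name: `LPI[_SVF|_FAI|_RDA]`, `OK`,
#'   `OCK_[SVF|FAI|RDA|ALL]`, `KIB[_SVF|_FAI|_RDA]`.
#' @param kernel a [kernel_spec()] for LPI/KIB (default exponential, h = 50 m).
#' @param order LPI polynomial order (default 1).
#' @param variogram_kind family for the OK/OCK variogram fit.
#' @return Object of class `mk_method`.
#' @export
method_config <- function(name, kernel = kernel_spec("exponential", 50),
                          order = 1, variogram_kind = "stable") {
  if (!name %in% METHOD_NAMES)
    mk_stop("unknown method '", name, "'; expected one of: ",
            paste(METHOD_NAMES, collapse = ", "))
  algorithm <- sub("_.*$", "", name)
  suffix <- if (grepl("_", name)) sub("^[^_]*_", "", name) else NA_character_
  covmap <- c(SVF = "svf50", FAI = "fai50", RDA = "rda50")
  weight_factor <- if (algorithm %in% c("LPI", "KIB") && !is.na(suffix))
    covmap[[suffix]] else NULL
  covariate_set <- if (algorithm == "OCK") {
    if (identical(suffix, "ALL")) unname(covmap) else unname(covmap[[suffix]])
  } else NULL
  structure(list(name = name, algorithm = algorithm,
                 weight_factor = weight_factor,
                 covariate_set = covariate_set,
                 kernel = kernel, order = order,
                 variogram_kind = variogram_kind),
            class = "mk_method")
}

#' All 13 method configurations
#'
#' @inheritParams method_config
#' @return Named list of 13 [method_config()] objects.
#' @export
all_method_configs <- function(kernel = kernel_spec("exponential", 50),
                               order = 1, variogram_kind = "stable") {
  setNames(lapply(METHOD_NAMES, method_config, kernel = kernel,
                  order = order, variogram_kind = variogram_kind),
           METHOD_NAMES)
}

#' Run one interpolation configuration on a prediction grid
#'
#' Dispatches to [lpi_predict()], [ok_predict()], [ock_predict()] or
#' [kib_predict()] with the configuration's covariate choices; fits the
#' variogram / coregionalization from the data when not supplied.
#'
#' @param config an [method_config()].
#' @param points clean points with `x`, `y` and the response column.
#' @param scene an [mk_scene()] (needed for KIB and for covariates).
#' @param grid an [mk_grid()] prediction grid.
#' @param variable response column name (`"pm25"` or `"pm10"`).
#' @param covariates optional covariate data.frame at the points
#'   (`svf50`, `fai50`, `rda50`); computed from the scene when missing.
#' @param variogram optional pre-fitted [mk_vgm()] for OK.
#' @param coreg optional pre-fitted coregionalization for OCK.
#' @return An [mk_surface()] whose `method` is the configuration name.
#' @export
run_method <- function(config, points, scene, grid, variable = "pm25",
                       covariates = NULL, variogram = NULL, coreg = NULL) {
  stopifnot(inherits(config, "mk_method"))
  values <- points[[variable]]
  if (is.null(values)) mk_stop("no '", variable, "' column in points")
  needs_cov <- !is.null(config$weight_factor) || !is.null(config$covariate_set)
  if (needs_cov && is.null(covariates))
    covariates <- extract_covariates(scene, points)
  wf <- if (!is.null(config$weight_factor)) covariates[[config$weight_factor]]
  sf <- switch(config$algorithm,
    LPI = lpi_predict(points, values, config$kernel, grid,
                      order = config$order, weight_factor_values = wf),
    KIB = kib_predict(points, values, config$kernel, scene, grid,
                      weight_factor_values = wf),
    OK = {
      if (is.null(variogram)) {
        emp <- empirical_semivariogram(as.matrix(points[, c("x", "y")]), values)
        variogram <- fit_variogram(emp, config$variogram_kind)
      }
      ok_predict(points, values, variogram, grid)
    },
    OCK = {
      covs <- covariates[, config$covariate_set, drop = FALSE]
      if (is.null(coreg))
        coreg <- fit_coregionalization(as.matrix(points[, c("x", "y")]),
                                       values, covs,
                                       kind = config$variogram_kind)
      ock_predict(points, values, covs, coreg, grid)
    },
    mk_stop("unknown algorithm tag '", config$algorithm, "'"))
  sf$method <- config$name
  sf
}
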