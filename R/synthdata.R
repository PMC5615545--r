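# Synthetic data: Gaussian random fields, PM truth rasters and walking
# transects with the statistical structure the downstream analysis assumes.

#' Prepare a dense Gaussian-random-field factor for a grid
#'
#' Builds and Cholesky-factorises the covariance matrix implied by a
#' semivariogram model on the cell centres of a grid.  Exactness is preferred
#' over scalability: the grid is capped at 8000 cells (dense factorisation);
#' ask for a coarser simulation grid beyond that.  The factor can be reused
#' across seeds (it depends only on the grid and the model).
#'
#' @param grid an [mk_grid()].
#' @param model an [mk_vgm()]; the nugget becomes independent cell-level noise.
#' @return Object of class `mk_grf` holding the upper Cholesky factor.
#' @export
grf_prepare <- function(grid, model) {
  n <- grid_ncell(grid)
  if (n > 8000)
    mk_stop("grid has ", n, " cells; dense GRF factorisation is capped at ",
            "8000 cells -- use a coarser simulation grid")
  ctr <- grid_center_coords(grid)
  if (model$psill <= 0) {
    return(structure(list(grid = grid, model = model, R = NULL, n = n),
                     class = "mk_grf"))
  }
  D <- as.matrix(dist(ctr))
  C <- model$psill + model$nugget - model_gamma(model, D)
  diag(C) <- model$psill + model$nugget
  # structured part only; the nugget is added as iid noise at draw time
  C <- C - diag(model$nugget, n)
  diag(C) <- diag(C) + 1e-8 * model$psill
  structure(list(grid = grid, model = model, R = chol(C), n = n),
            class = "mk_grf")
}

# One zero-mean realisation (vector in row-major cell order).
grf_draw <- function(grf, seed = NULL) {
  with_seed(seed, {
    z <- if (is.null(grf$R)) numeric(grf$n) else
      as.vector(crossprod(grf$R, rnorm(grf$n)))
    if (grf$model$nugget > 0) z <- z + rnorm(grf$n, 0, sqrt(grf$model$nugget))
    z
  })
}

#' Simulate a ground-truth PM field over a scene
#'
#' The PM2.5 field is `mean_level` plus a centred linear term in the
#' building-geometry covariates, a zero-mean Gaussian random field with the
#' requested semivariogram, and a sum of exponential hotspot kernels
#' `amplitude * exp(-d / decay)`; negatives are clamped at 0.  PM10 is
#' `ratio * PM2.5` plus an independent GRF component, then cell-wise
#' `max(PM10, PM2.5)` so the size-fraction ordering always holds.
#'
#' @param scene an [mk_scene()].
#' @param true_variogram an [mk_vgm()] for the PM2.5 field.
#' @param hotspots data.frame with columns `x`, `y`, `amplitude` (ug/m3),
#'   `decay` (m, > 0); may have zero rows.
#' @param covariate_betas named numeric `c(svf50=, fai50=, rda50=)` linking
#'   the covariate rasters to the mean field (0 = no covariate structure).
#' @param mean_level background PM2.5 mean (ug/m3), > 0.
#' @param seed RNG seed (bit-identical rasters for a fixed seed).
#' @param grid_cell simulation raster cell size (m, default 10).
#' @param pm10_ratio PM10:PM2.5 coupling ratio (default 1.6).
#' @param pm10_extra_frac partial sill of the independent PM10 component as a
#'   fraction of the PM2.5 partial sill (default 0.3).
#' @param grf optional pre-built [grf_prepare()] factor (reused across seeds).
#' @param cov_cell cell size of the covariate evaluation grid (m, default 20);
#'   covariates are bilinearly resampled onto the simulation grid.
#' @return Object of class `mk_truth`: `grid`, `pm25`, `pm10` (matrices),
#'   `true_variogram`, `hotspots`, `covariate_betas`, `covariates` (rasters),
#'   `mean_level`.
#' @export
simulate_pm_field <- function(scene, true_variogram = mk_vgm("stable",
                                nugget = 1.5, psill = 20, range = 25,
                                shape = 1.5),
                              hotspots = NULL, covariate_betas = c(
                                svf50 = 0, fai50 = 0, rda50 = 0),
                              mean_level = 30, seed = NULL, grid_cell = 10,
                              pm10_ratio = 1.6, pm10_extra_frac = 0.3,
                              grf = NULL, cov_cell = 20) {
  if (mean_level <= 0) mk_stop("mean_level must be > 0")
  ext <- scene$extent
  grid <- mk_grid(ext[1], ext[3], grid_cell,
                  nrow = max(1, round((ext[4] - ext[3]) / grid_cell)),
                  ncol = max(1, round((ext[2] - ext[1]) / grid_cell)))
  if (is.null(grf)) grf <- grf_prepare(grid, true_variogram)
  else if (!identical(grf$grid[c("xmin", "ymin", "cell", "nrow", "ncol")],
                      grid[c("xmin", "ymin", "cell", "nrow", "ncol")]))
    mk_stop("supplied GRF factor was prepared for a different grid")
  if (!is.null(hotspots)) {
    hotspots <- as.data.frame(hotspots)
    if (nrow(hotspots) && any(hotspots$decay <= 0))
      mk_stop("hotspot decay lengths must be > 0")
  }

  ctr <- grid_center_coords(grid)
  betas <- covariate_betas
  covs <- NULL
  mean_term <- rep(mean_level, grid_ncell(grid))
  if (any(betas != 0)) {
    cgrid <- mk_grid(ext[1], ext[3], cov_cell,
                     nrow = max(2, round((ext[4] - ext[3]) / cov_cell)),
                     ncol = max(2, round((ext[2] - ext[1]) / cov_cell)))
    covs <- covariate_rasters(scene, cgrid)
    for (nm in names(betas)) {
      if (betas[[nm]] == 0) next
      v <- grid_bilinear(cgrid, covs[[nm]], ctr)
      mean_term <- mean_term + betas[[nm]] * (v - mean(v))
    }
  }

  hot_term <- numeric(grid_ncell(grid))
  if (!is.null(hotspots) && nrow(hotspots)) {
    for (i in seq_len(nrow(hotspots))) {
      d <- sqrt((ctr[, 1] - hotspots$x[i])^2 + (ctr[, 2] - hotspots$y[i])^2)
      hot_term <- hot_term + hotspots$amplitude[i] * exp(-d / hotspots$decay[i])
    }
  }

  with_seed(seed, {
    z25 <- grf_draw(grf)
    pm25 <- pmax(mean_term + z25 + hot_term, 0)
    extra_model <- mk_vgm(true_variogram$kind,
                          nugget = true_variogram$nugget * pm10_extra_frac,
                          psill = max(true_variogram$psill * pm10_extra_frac,
                                      1e-12),
                          range = true_variogram$range,
                          shape = if (true_variogram$kind == "stable")
                            true_variogram$shape else 1)
    zx <- if (pm10_extra_frac > 0) {
      grf10 <- if (is.null(grf$R)) grf_prepare(grid, extra_model) else
        structure(list(grid = grid, model = extra_model,
                       R = grf$R * sqrt(pm10_extra_frac), n = grf$n),
                  class = "mk_grf")
      grf_draw(grf10)
    } else numeric(grid_ncell(grid))
    pm10 <- pmax(pm25 * pm10_ratio + zx, pm25)
    structure(list(grid = grid, pm25 = grid_matrix(grid, pm25),
                   pm10 = grid_matrix(grid, pm10),
                   true_variogram = true_variogram,
                   hotspots = hotspots, covariate_betas = betas,
                   covariates = covs, mean_level = mean_level,
                   pm10_ratio = pm10_ratio),
              class = "mk_truth")
  })
}

#' @export
print.mk_truth <- function(x, ...) {
  cat(sprintf("<mk_truth %d x %d @ %g m: PM2.5 [%.3g, %.3g], PM10 [%.3g, %.3g]>\n",
              x$grid$nrow, x$grid$ncol, x$grid$cell,
              min(x$pm25), max(x$pm25), min(x$pm10), max(x$pm10)))
  invisible(x)
}

#' Simulate a walking transect over a truth field
#'
#' Applies the forward observation model that preprocessing inverts: one
#' record per sampling tick; raw PM is the bilinear field value at the *true*
#' position, inflated by the hygroscopic-growth factor `CF(RH)` and a
#' multiplicative instrument noise; reported positions carry isotropic
#' Gaussian GPS noise.  `"both"` directions append the backward pass and
#' exactly double the record count.
#'
#' @param route an [mk_route()].
#' @param truth an `mk_truth` from [simulate_pm_field()].
#' @param rh_mean mean relative humidity as a fraction in (0, 1), default 0.85.
#' @param rh_ar1 `c(rho, sigma)` of the per-tick AR(1) RH excursions.
#' @param gps_sigma GPS noise sd per axis (m, default 2.0, putting ~95 % of
#'   reported positions within a 4 m receiver accuracy).
#' @param instrument_noise_cv coefficient of variation of the multiplicative
#'   instrument noise (default 0.03).
#' @param seed RNG seed.
#' @param start_time first tick (UTC), within a summer afternoon window.
#' @return data.frame of transect records: `time`, `x`, `y`, `pm25_raw`,
#'   `pm10_raw`, `temp`, `rh` (fraction).
#' @export
simulate_walk <- function(route, truth, rh_mean = 0.85,
                          rh_ar1 = c(rho = 0.995, sigma = 0.005),
                          gps_sigma = 2.0, instrument_noise_cv = 0.03,
                          seed = NULL,
                          start_time = as.POSIXct("2015-06-15 14:00:00",
                                                  tz = "UTC")) {
  stopifnot(inherits(route, "mk_route"))
  if (rh_mean <= 0 || rh_mean >= 1) mk_stop("rh_mean must be in (0, 1)")
  L <- polyline_length(route$vertices)
  if (L <= 0) mk_stop("route length must be > 0")
  step <- route$speed * route$interval
  s_fwd <- seq(0, L, by = step)
  s_all <- if (route$directions == "both") c(s_fwd, L - s_fwd) else s_fwd
  n <- length(s_all)
  pos <- polyline_point(route$vertices, s_all)

  with_seed(seed, {
    rho <- rh_ar1[[1]]; sig <- rh_ar1[[2]]
    rh <- numeric(n)
    sd0 <- if (abs(rho) < 1) sig / sqrt(1 - rho^2) else sig
    rh[1] <- rh_mean + rnorm(1, 0, sd0)
    if (n > 1) {
      eps <- rnorm(n - 1, 0, sig)
      for (t in 2:n) rh[t] <- rh_mean + rho * (rh[t - 1] - rh_mean) + eps[t - 1]
    }
    n_clip <- sum(rh >= 1 | rh < 0)
    if (n_clip > 0)
      message("clipped ", n_clip, " RH excursions into [0, 0.99]")
    rh <- pmin(pmax(rh, 0), 0.99)

    f25 <- grid_bilinear(truth$grid, truth$pm25, pos)
    f10 <- grid_bilinear(truth$grid, truth$pm10, pos)
    cf <- correction_factor(rh)
    noise25 <- pmax(1 + rnorm(n, 0, instrument_noise_cv), 0.01)
    noise10 <- pmax(1 + rnorm(n, 0, instrument_noise_cv), 0.01)
    gx <- rnorm(n, 0, gps_sigma); gy <- rnorm(n, 0, gps_sigma)
    data.frame(
      time = start_time + (seq_len(n) - 1) * route$interval,
      x = pos[, 1] + gx, y = pos[, 2] + gy,
      pm25_raw = f25 * cf * noise25,
      pm10_raw = f10 * cf * noise10,
      temp = 30.5 + rnorm(n, 0, 0.3),
      rh = rh)
  })
}

#' Assemble a complete default synthetic scenario
#'
#' One call producing the stated world of the synthetic module: a 500 x 500 m
#' street-grid scene, a stable-variogram PM field (range 25 m) with three
#' roadside hotspots, and a forward+backward walking transect sampled at 1 s
#' and 0.8 m/s with RH ~ 0.85, 2 m GPS noise and 3 % instrument noise.
#'
#' @param seed RNG seed driving scene, field and walk.
#' @param layout `"orthogonal"` or `"irregular"`.
#' @param n_hotspots number of roadside hotspots (default 3, amplitude 30,
#'   decay 10 m).
#' @param covariate_betas covariate coefficients of the mean field; the small
#'   defaults keep the covariate share of field variance under ~10 %.
#' @param grf optional reusable GRF factor for the 10 m simulation grid.
#' @param ... further arguments passed to [simulate_walk()].
#' @return list with `scene`, `truth`, `route`, `records`.
#' @export
synth_scenario <- function(seed = 1, layout = "orthogonal", n_hotspots = 3,
                           covariate_betas = c(svf50 = -2, fai50 = 3,
                                               rda50 = 2),
                           grf = NULL, ...) {
  scene <- make_street_grid(layout, seed = seed)
  route <- route_from_scene(scene)
  hotspots <- with_seed(seed + 1000L, {
    if (n_hotspots > 0) {
      s <- runif(n_hotspots, 0.05, 0.95) * polyline_length(route$vertices)
      p <- polyline_point(route$vertices, s)
      data.frame(x = p[, 1], y = p[, 2], amplitude = 30, decay = 10)
    } else NULL
  })
  truth <- simulate_pm_field(scene, hotspots = hotspots,
                             covariate_betas = covariate_betas,
                             seed = seed + 2000L, grf = grf)
  records <- simulate_walk(route, truth, seed = seed + 3000L, ...)
  list(scene = scene, truth = truth, route = route, records = records)
}
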