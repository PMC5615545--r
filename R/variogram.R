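#' Parametric semivariogram model
#'
#' The stable family is parameterised so that `range_param` is directly the
#' practical (95 % of partial sill) range for the exponential member:
#' `gamma(d) = nugget * 1{d>0} + psill * (1 - exp(-(3 d / range)^shape))`.
#' `shape = 1` is the exponential model, `shape = 2` the Gaussian; the
#' spherical model is the usual polynomial with a hard plateau at `range`.
#'
#' @param kind one of `"stable"`, `"spherical"`, `"exponential"`, `"gaussian"`.
#' @param nugget nugget variance, `>= 0`.
#' @param psill partial sill, `>= 0`.
#' @param range range parameter (m), `> 0`.
#' @param shape stable shape in `(0, 2]`; forced to 1 / 2 for the
#'   exponential / Gaussian kinds and ignored for spherical.
#' @return An object of class `mk_vgm`.
#' @export
mk_vgm <- function(kind = c("stable", "spherical", "exponential", "gaussian"),
                   nugget = 0, psill = 1, range = 30, shape = 1) {
  kind <- match.arg(kind)
  if (nugget < 0 || psill < 0) mk_stop("nugget and partial sill must be >= 0")
  if (range <= 0) mk_stop("range parameter must be > 0")
  shape <- switch(kind, exponential = 1, gaussian = 2, stable = shape, spherical = NA_real_)
  if (kind == "stable" && (shape <= 0 || shape > 2))
    mk_stop("stable shape must be in (0, 2]")
  structure(list(kind = kind, nugget = nugget, psill = psill,
                 range = range, shape = shape),
            class = "mk_vgm")
}

#' @export
print.mk_vgm <- function(x, ...) {
  cat(sprintf("<mk_vgm %s: nugget %.4g, psill %.4g, range %.4g m%s>\n",
              x$kind, x$nugget, x$psill, x$range,
              if (x$kind == "stable") sprintf(", shape %.3g", x$shape) else ""))
  invisible(x)
}

#' Evaluate a semivariogram model
#'
#' `gamma(0) = 0` by convention; the nugget applies for any `d > 0`.
#'
#' @param model an [mk_vgm()].
#' @param d distances (m), `>= 0` (vectorised).
#' @return Semivariance values (same units as the data variance).
#' @export
model_gamma <- function(model, d) {
  stopifnot(inherits(model, "mk_vgm"))
  if (any(d < 0)) mk_stop("distances must be >= 0")
  pos <- d > 0
  g <- numeric(length(d))
  if (model$kind == "spherical") {
    u <- pmin(d / model$range, 1)
    g[pos] <- model$nugget +
      model$psill * (1.5 * u[pos] - 0.5 * u[pos]^3)
  } else {
    g[pos] <- model$nugget +
      model$psill * (1 - exp(-(3 * d[pos] / model$range)^model$shape))
  }
  if (is.matrix(d)) dim(g) <- dim(d)
  g
}

# Stationary covariance implied by the model (sill - gamma), used by the
# Gaussian-random-field generator and kriging oracles.
model_cov <- function(model, d) {
  (model$nugget + model$psill) * (d == 0) +
    (model$nugget + model$psill - model_gamma(model, d)) * (d > 0)
}

#' Empirical (cross-)semivariogram
#'
#' Method-of-moments estimator on half-open distance bins
#' `[lower, upper)`: for each bin,
#' `gamma = (1 / (2 n)) * sum over pairs of (z_i - z_j) (w_i - w_j)`
#' with `w = z` for the direct semivariogram.
#'
#' @param coords 2-column matrix of point coordinates (m).
#' @param values numeric vector of the variable at `coords`.
#' @param bin_width bin width (m); default `max_lag / 12`.
#' @param max_lag largest lag considered (m); default half the maximum
#'   pairwise distance.
#' @param cross_values optional second variable for a cross-semivariogram.
#' @return Object of class `mk_empvario`: a data.frame with columns `lag`
#'   (bin centre), `gamma` (`NaN` for empty bins) and `n_pairs`, plus
#'   `max_lag` / `bin_width` attributes.
#' @export
empirical_semivariogram <- function(coords, values, bin_width = NULL,
                                    max_lag = NULL, cross_values = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) mk_stop("need at least 2 points")
  stopifnot(length(values) == n)
  d <- as.vector(dist(coords))
  if (is.null(max_lag)) max_lag <- max(d) / 2
  if (is.null(bin_width)) bin_width <- max_lag / 12
  if (bin_width <= 0 || max_lag <= 0) mk_stop("bin_width and max_lag must be > 0")
  dz <- as.vector(dist_outer_diff(values))
  dw <- if (is.null(cross_values)) dz else as.vector(dist_outer_diff(cross_values))
  keep <- d < max_lag
  bin <- floor(d[keep] / bin_width) + 1L
  nb <- as.integer(ceiling(max_lag / bin_width))
  cnt <- tabulate(bin, nbins = nb)
  prod <- dz[keep] * dw[keep]
  ssum <- as.vector(rowsum(prod, bin, reorder = TRUE))
  present <- sort(unique(bin))   # rowsum drops empty bins; realign
  full <- numeric(nb); full[present] <- ssum
  gamma <- ifelse(cnt > 0, full / (2 * cnt), NaN)
  out <- data.frame(lag = (seq_len(nb) - 0.5) * bin_width,
                    gamma = gamma, n_pairs = cnt)
  attr(out, "max_lag") <- max_lag
  attr(out, "bin_width") <- bin_width
  class(out) <- c("mk_empvario", "data.frame")
  out
}

# Pairwise differences in dist() ordering (lower triangle, column-major):
# for column j, rows j+1..n.
dist_outer_diff <- function(v) {
  n <- length(v)
  j <- rep.int(seq_len(n - 1), times = (n - 1):1)
  i <- sequence((n - 1):1) + j
  v[i] - v[j]
}

#' Fit a semivariogram model by Cressie-weighted least squares
#'
#' Minimises `sum n(d) * (gamma_emp - gamma_model)^2 / gamma_model^2` over the
#' non-empty bins, with non-negativity constraints and (for the stable family)
#' a multi-start over the shape `{0.5, 1, 1.5, 2}`.
#'
#' @param emp an [empirical_semivariogram()].
#' @param kind model family to fit.
#' @return An [mk_vgm()]; attribute `"converged"` is `FALSE` when every start
#'   hit the iteration limit (the best candidate is still returned).
#' @export
fit_variogram <- function(emp, kind = c("stable", "spherical", "exponential",
                                        "gaussian")) {
  kind <- match.arg(kind)
  ok <- is.finite(emp$gamma) & emp$n_pairs > 0
  if (sum(ok) < 4) mk_stop("need at least 4 non-empty bins to fit")
  lag <- emp$lag[ok]; g <- emp$gamma[ok]; w <- emp$n_pairs[ok]
  max_lag <- max(lag)
  gmax <- max(g)
  eps <- 1e-9 * max(gmax, 1e-12)

  obj <- function(par, shape) {
    m <- list(kind = if (kind == "spherical") "spherical" else "stable",
              nugget = par[1], psill = par[2], range = par[3],
              shape = if (kind == "spherical") NA_real_ else shape)
    class(m) <- "mk_vgm"
    gm <- pmax(model_gamma(m, lag), eps)
    sum(w * (g - gm)^2 / gm^2)
  }

  shapes <- switch(kind, stable = c(0.5, 1, 1.5, 2), exponential = 1,
                   gaussian = 2, spherical = NA_real_)
  # initial values: nugget from the first bin, sill from the top bins
  nug0 <- max(0, min(g[1], 0.5 * gmax))
  ps0 <- max(gmax - nug0, 0.1 * gmax, eps)
  r95 <- lag[which(g >= nug0 + 0.95 * ps0)[1]]
  range_starts <- unique(c(if (is.finite(r95)) r95, max_lag / 3, max_lag))
  best <- NULL
  for (sh in shapes) for (r0 in range_starts) {
    fit <- tryCatch(
      optim(c(nug0, ps0, r0), obj, shape = sh, method = "L-BFGS-B",
            lower = c(0, eps, 1e-3 * max_lag),
            upper = c(Inf, Inf, 20 * max_lag),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12) {
      best <- fit; best$shape <- sh
    }
  }
  if (is.null(best)) mk_stop("variogram fit failed for every start")
  m <- mk_vgm(kind, nugget = best$par[1], psill = best$par[2],
              range = best$par[3],
              shape = if (kind == "stable") best$shape else 1)
  if (kind == "stable") {
    # polish the shape jointly once the structural parameters are close
    obj4 <- function(p) obj(p[1:3], p[4])
    fit4 <- tryCatch(
      optim(c(best$par, best$shape), obj4, method = "L-BFGS-B",
            lower = c(0, eps, 1e-3 * max_lag, 0.1),
            upper = c(Inf, Inf, 20 * max_lag, 2),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit4) && fit4$value <= best$value) {
      best <- fit4
      m <- mk_vgm(kind, nugget = fit4$par[1], psill = fit4$par[2],
                  range = fit4$par[3], shape = fit4$par[4])
    }
  }
  attr(m, "converged") <- isTRUE(best$convergence == 0)
  attr(m, "wsse") <- best$value
  m
}

#' Select the best-fitting semivariogram family
#'
#' Fits every candidate family and keeps the one with the smallest
#' Cressie-weighted SSE; ties are broken by the order
#' stable, spherical, exponential, gaussian.
#'
#' @param emp an [empirical_semivariogram()].
#' @param candidate_kinds character vector of families to try.
#' @return `list(model = <mk_vgm>, scores = <data.frame kind/wsse/converged>)`.
#' @export
select_model <- function(emp, candidate_kinds = c("stable", "spherical",
                                                  "exponential", "gaussian")) {
  order_ref <- c("stable", "spherical", "exponential", "gaussian")
  candidate_kinds <- order_ref[order_ref %in% candidate_kinds]
  if (!length(candidate_kinds)) mk_stop("no valid candidate kinds")
  fits <- lapply(candidate_kinds, function(k)
    tryCatch(fit_variogram(emp, k), error = function(e) NULL))
  wsse <- vapply(fits, function(f) if (is.null(f)) Inf else attr(f, "wsse"), 0)
  scores <- data.frame(kind = candidate_kinds, wsse = wsse,
                       converged = vapply(fits, function(f)
                         isTRUE(attr(f, "converged")), NA))
  best <- which(wsse <= min(wsse) + 1e-10)[1]  # tie-break by listed order
  if (!is.finite(wsse[best])) mk_stop("every candidate fit failed")
  list(model = fits[[best]], scores = scores)
}

#' Practical ("major") range of a fitted model
#'
#' Distance at which the structured part of the semivariogram reaches 95 % of
#' the partial sill; for the spherical family this is the range parameter
#' itself.  Comparable to the "major range" reported by geostatistical
#' software.
#'
#' @param model an [mk_vgm()].
#' @return Distance in metres (0 with a warning when `psill = 0`).
#' @export
major_range <- function(model) {
  stopifnot(inherits(model, "mk_vgm"))
  if (model$psill <= 0) {
    warning("partial sill is 0; major range undefined, returning 0")
    return(0)
  }
  if (model$kind == "spherical") return(model$range)
  model$range * log(20)^(1 / model$shape) / 3
}

#' Linear model of coregionalization for ordinary cokriging
#'
#' Fits the primary variable's variogram (structure and range), then refits
#' the nugget / partial-sill amplitudes of every direct and cross
#' (co)variogram with the structure held fixed.  The two coregionalization
#' matrices (nugget and structured sill) are projected onto the positive
#' semidefinite cone by eigenvalue clipping so every kriging system is valid;
#' in particular `b_uv^2 <= b_uu * b_vv` holds for every pair and structure.
#'
#' @param coords 2-column matrix of sample coordinates.
#' @param values primary variable (e.g. PM2.5).
#' @param covariates data.frame / matrix of secondary variables at `coords`.
#' @param kind family for the primary fit (default `"stable"`).
#' @param bin_width,max_lag binning as in [empirical_semivariogram()].
#' @return Object of class `mk_coreg`: `vars`, `kind`, `range`, `shape`,
#'   `B_nugget`, `B_psill` (matrices with the primary first).
#' @export
fit_coregionalization <- function(coords, values, covariates,
                                  kind = "stable", bin_width = NULL,
                                  max_lag = NULL) {
  covariates <- as.data.frame(covariates)
  keep <- vapply(covariates, function(v) isTRUE(sd(v) > 1e-12), NA)
  if (any(!keep)) {
    message("dropping zero-variance covariate(s): ",
            paste(names(covariates)[!keep], collapse = ", "))
    covariates <- covariates[, keep, drop = FALSE]
  }
  p <- ncol(covariates)
  if (p < 1) mk_stop("no usable covariates for cokriging")
  emp1 <- empirical_semivariogram(coords, values, bin_width, max_lag)
  if (sum(is.finite(emp1$gamma)) < 4)
    mk_stop("need at least 4 non-empty bins in the primary variogram")
  primary <- fit_variogram(emp1, kind)
  bw <- attr(emp1, "bin_width"); ml <- attr(emp1, "max_lag")

  allv <- cbind(z = values, covariates)
  nv <- p + 1
  # unit structure g(d) of the primary fit, evaluated at the bin centres
  unit <- mk_vgm(primary$kind, nugget = 0, psill = 1,
                 range = primary$range,
                 shape = if (primary$kind == "stable") primary$shape else 1)
  B_nug <- matrix(0, nv, nv); B_ps <- matrix(0, nv, nv)
  for (u in seq_len(nv)) for (v in u:nv) {
    emp <- empirical_semivariogram(coords, allv[, u], bw, ml,
                                   cross_values = allv[, v])
    ok <- is.finite(emp$gamma) & emp$n_pairs > 0
    gs <- model_gamma(unit, emp$lag[ok])
    X <- cbind(nug = 1, str = gs)
    wls <- lm.wfit(X, emp$gamma[ok], w = emp$n_pairs[ok])
    b <- coef(wls)
    if (u == v) b <- pmax(b, 0)              # direct variograms are >= 0
    B_nug[u, v] <- B_nug[v, u] <- b[1]
    B_ps[u, v] <- B_ps[v, u] <- b[2]
  }
  structure(list(vars = c("z", names(covariates)), kind = primary$kind,
                 range = primary$range,
                 shape = if (primary$kind == "stable") primary$shape else 1,
                 B_nugget = psd_project(B_nug), B_psill = psd_project(B_ps),
                 primary = primary),
            class = "mk_coreg")
}

# Nearest-PSD projection by eigenvalue clipping.
psd_project <- function(B) {
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  out <- e$vectors %*% (lam * t(e$vectors))
  (out + t(out)) / 2
}

# Cross-semivariogram between variables u and v under a coregionalization.
coreg_gamma <- function(coreg, u, v, d) {
  unit <- mk_vgm(coreg$kind, nugget = 0, psill = 1, range = coreg$range,
                 shape = coreg$shape)
  coreg$B_nugget[u, v] * (d > 0) + coreg$B_psill[u, v] * model_gamma(unit, d)
}

#' @export
print.mk_coreg <- function(x, ...) {
  cat(sprintf("<mk_coreg %s range %.4g m over {%s}>\n", x$kind, x$range,
              paste(x$vars, collapse = ", ")))
  invisible(x)
}
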