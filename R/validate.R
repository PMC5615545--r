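# Cross-validation harness: LOOCV RMSE and k-fold R^2 for any of the 13
# interpolation configurations, plus the kernel and method comparison tables.

#' Root-mean-square error
#'
#' `RMSE = sqrt(mean((pred - obs)^2))` over the pairs where both are finite.
#'
#' @param pred,obs numeric vectors.
#' @return RMSE (>= 0).
#' @export
rmse <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  sqrt(mean((pred[ok] - obs[ok])^2))
}

#' Squared Pearson correlation of the prediction--observation regression
#'
#' The R^2 of the simple linear regression of predictions on observations,
#' i.e. the squared Pearson correlation of the pooled pairs.  `NaN` with a
#' warning when either side has zero variance.
#'
#' @param pred,obs numeric vectors.
#' @return R^2 in `[0, 1]` (or `NaN`).
#' @export
slr_r2 <- function(pred, obs) {
  ok <- is.finite(pred) & is.finite(obs)
  if (sum(ok) < 3 || sd(obs[ok]) < 1e-14 || sd(pred[ok]) < 1e-14) {
    warning("R^2 undefined (zero variance or too few pairs); returning NaN")
    return(NaN)
  }
  cor(pred[ok], obs[ok])^2
}

# Shared per-dataset context (fitted once, held fixed across CV folds, which
# is what desktop geostatistics packages do): covariates at the sample
# points, the variogram fit, the coregionalization, and the barrier graph.
cv_context <- function(config, points, scene, variable,
                       covariates = NULL, variogram = NULL, coreg = NULL,
                       kib_res = NULL) {
  coords <- as.matrix(points[, c("x", "y")])
  values <- points[[variable]]
  needs_cov <- !is.null(config$weight_factor) || !is.null(config$covariate_set)
  if (needs_cov && is.null(covariates))
    covariates <- extract_covariates(scene, points)
  if (config$algorithm == "OK" && is.null(variogram)) {
    emp <- empirical_semivariogram(coords, values)
    variogram <- fit_variogram(emp, config$variogram_kind)
  }
  if (config$algorithm == "OCK" && is.null(coreg))
    coreg <- fit_coregionalization(coords, values,
                                   covariates[, config$covariate_set,
                                              drop = FALSE],
                                   kind = config$variogram_kind)
  bg <- NULL
  if (config$algorithm == "KIB") {
    if (is.null(kib_res))
      kib_res <- min(scene$extent[2] - scene$extent[1],
                     scene$extent[4] - scene$extent[3]) / 100
    bg <- barrier_graph(scene, kib_res)
  }
  list(config = config, coords = coords, values = values, scene = scene,
       covariates = covariates, variogram = variogram, coreg = coreg,
       bg = bg)
}

# Predict at targets from a training subset, under a fixed context.
cv_predict <- function(ctx, train, targets) {
  cf <- ctx$config
  coords <- ctx$coords[train, , drop = FALSE]
  values <- ctx$values[train]
  wf <- if (!is.null(cf$weight_factor))
    scale_weight_factor(ctx$covariates[[cf$weight_factor]])[train]
  switch(cf$algorithm,
    LPI = predict_lpi_at(coords, values, targets, cf$kernel, cf$order,
                         cvals = wf)$pred,
    OK = predict_ok_at(coords, values, ctx$variogram, targets)$pred,
    OCK = predict_ock_at(coords, values,
                         as.matrix(ctx$covariates[train, cf$covariate_set,
                                                  drop = FALSE]),
                         ctx$coreg, targets)$pred,
    KIB = predict_kib_at(coords, values, cf$kernel, ctx$scene, targets,
                         res = ctx$bg$grid$cell, cvals = wf,
                         bg = ctx$bg)$pred,
    mk_stop("unknown algorithm tag '", cf$algorithm, "'"))
}

#' Leave-one-out cross-validation of one configuration
#'
#' For each sample the method is re-solved on the other `n - 1` points (the
#' variogram / coregionalization fitted on the full data is held fixed; the
#' local fits are recomputed) and predicts at the held-out location; the
#' RMSE of the held-out errors is reported.  OK uses the exact
#' leave-one-out identity on the inverse kriging matrix
#' (`fast = FALSE` forces the brute-force per-fold solve -- identical to
#' numerical precision).
#'
#' @param points clean points with `x`, `y` and the response.
#' @param config an [method_config()].
#' @param scene an [mk_scene()] (KIB / covariates).
#' @param variable response column name.
#' @param covariates,variogram,coreg optional precomputed pieces.
#' @param kib_res barrier-grid resolution for KIB (m).
#' @param fast use the closed-form OK identity (default `TRUE`).
#' @return `list(pred, rmse, n_excluded)`; unpredictable points (empty
#'   neighbourhood) are excluded from the RMSE and counted.
#' @export
loocv <- function(points, config, scene = NULL, variable = "pm25",
                  covariates = NULL, variogram = NULL, coreg = NULL,
                  kib_res = NULL, fast = TRUE) {
  n <- nrow(points)
  if (n < 3) mk_stop("LOOCV needs at least 3 points")
  ctx <- cv_context(config, points, scene, variable, covariates, variogram,
                    coreg, kib_res)
  pred <- rep(NA_real_, n)
  if (ctx$config$algorithm == "OK" && fast) {
    D <- as.matrix(dist(ctx$coords))
    check_no_duplicates(ctx$coords)
    G <- model_gamma(ctx$variogram, D); dim(G) <- dim(D); diag(G) <- 0
    A <- rbind(cbind(G, 1), c(rep(1, n), 0))
    B <- solve(A)
    e <- (B %*% c(ctx$values, 0))[seq_len(n)] / diag(B)[seq_len(n)]
    pred <- ctx$values - e
  } else if (ctx$config$algorithm == "OCK" && fast) {
    # block leave-one-out identity on the inverse cokriging matrix: with
    # B = A^-1 and S_i the rows of sample i in every variable block, the
    # held-out errors solve B[S,S] e_S = (B zt)[S]; the first component is
    # the primary error.  Algebraically identical to the brute per-fold
    # solve (tested), at one factorisation instead of n.
    covmat <- as.matrix(ctx$covariates[, ctx$config$covariate_set,
                                       drop = FALSE])
    nv <- ncol(covmat) + 1
    A <- ock_system(ctx$coords, ctx$coreg, nv)
    B <- solve(A)
    zt <- c(as.vector(cbind(ctx$values, covmat)), rep(0, nv))
    Bz <- as.vector(B %*% zt)
    for (i in seq_len(n)) {
      S <- i + (seq_len(nv) - 1) * n
      eS <- solve(B[S, S, drop = FALSE], Bz[S])
      pred[i] <- ctx$values[i] - eS[1]
    }
  } else if (ctx$config$algorithm == "KIB") {
    # all pairwise barrier distances once, then drop one column at a time
    wf <- if (!is.null(ctx$config$weight_factor))
      scale_weight_factor(ctx$covariates[[ctx$config$weight_factor]])
    full <- predict_kib_at(ctx$coords, ctx$values, ctx$config$kernel,
                           ctx$scene, ctx$coords, res = ctx$bg$grid$cell,
                           cvals = wf, bg = ctx$bg, loo = TRUE)
    pred <- full$pred
  } else {
    for (i in seq_len(n)) {
      pred[i] <- cv_predict(ctx, setdiff(seq_len(n), i),
                            ctx$coords[i, , drop = FALSE])
    }
  }
  list(pred = pred, rmse = rmse(pred, ctx$values),
       n_excluded = sum(!is.finite(pred)))
}

#' k-fold cross-validated R^2 of one configuration
#'
#' Seeded random split into `k` folds (default `k = 2`); each fold is
#' predicted from the remaining folds (model parameters held fixed from the
#' full fit), the out-of-fold predictions are pooled, and the R^2 is the
#' squared Pearson correlation of the simple linear regression of pooled
#' predictions on observations.
#'
#' @inheritParams loocv
#' @param k number of folds (default 2).
#' @param seed fold-split seed (identical seed, identical split and R^2).
#' @return `list(r2, rmse, pred, folds)`.
#' @export
kfold_r2 <- function(points, config, scene = NULL, variable = "pm25",
                     k = 2, seed = 1, covariates = NULL, variogram = NULL,
                     coreg = NULL, kib_res = NULL) {
  n <- nrow(points)
  if (n < 2 * k) mk_stop("k-fold CV needs at least 2k points")
  ctx <- cv_context(config, points, scene, variable, covariates, variogram,
                    coreg, kib_res)
  # assign folds in a canonical coordinate order so the split (hence the
  # report) is invariant under permutations of the input rows
  canon <- order(ctx$coords[, 1], ctx$coords[, 2])
  folds <- integer(n)
  folds[canon] <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  pred <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- folds == f
    pred[test] <- cv_predict(ctx, which(!test),
                             ctx$coords[test, , drop = FALSE])
  }
  list(r2 = slr_r2(pred, ctx$values), rmse = rmse(pred, ctx$values),
       pred = pred, folds = folds)
}

#' Compare the six smoothing kernels under LPI
#'
#' LOOCV RMSE and k-fold RMSE / R^2 of local polynomial interpolation with
#' each kernel, per variable; the per-variable winner (minimum LOOCV RMSE)
#' is flagged.  Both the LOOCV and the k-fold RMSE are reported because
#' either may be used to pick the kernel.
#'
#' @param points clean points.
#' @param scene an [mk_scene()] (unused by plain LPI but kept for signature
#'   uniformity).
#' @param variables response columns to evaluate.
#' @param bandwidth kernel bandwidth (m).
#' @param order LPI order.
#' @param k,seed fold settings for the R^2.
#' @return data.frame rows kernel x variable with `rmse_loocv`,
#'   `rmse_kfold`, `r2_kfold`, `winner`.
#' @export
compare_kernels <- function(points, scene = NULL,
                            variables = c("pm25", "pm10"), bandwidth = 50,
                            order = 1, k = 2, seed = 1) {
  rows <- list()
  for (v in variables) for (kk in KERNEL_KINDS) {
    cfg <- method_config("LPI", kernel = kernel_spec(kk, bandwidth),
                         order = order)
    lo <- loocv(points, cfg, scene, v)
    kf <- kfold_r2(points, cfg, scene, v, k = k, seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      kernel = kk, variable = v, rmse_loocv = lo$rmse, rmse_kfold = kf$rmse,
      r2_kfold = kf$r2, n_excluded = lo$n_excluded)
  }
  out <- do.call(rbind, rows)
  out$winner <- FALSE
  for (v in variables) {
    i <- which(out$variable == v)
    out$winner[i[which.min(out$rmse_loocv[i])]] <- TRUE
  }
  attr(out, "k") <- k; attr(out, "seed") <- seed
  out
}

#' Compare interpolation configurations
#'
#' LOOCV RMSE and k-fold R^2 for every requested configuration and variable,
#' plus the two summary groupings used to rank methods: by base algorithm
#' (averaging over the weight-factor / covariate variants) and by covariate
#' choice (none / SVF / FAI / RDA, averaging over the algorithms; the
#' all-covariate cokriging configuration belongs to no single-covariate group
#' and is excluded there).
#'
#' @param points clean points.
#' @param scene an [mk_scene()].
#' @param configs list of [method_config()]s (default all 13).
#' @param variables response columns.
#' @param k,seed fold settings.
#' @param kib_res barrier-grid resolution (m).
#' @return Object of class `mk_cvreport`: `full`, `by_algorithm`,
#'   `by_covariate` data.frames and the run settings.
#' @export
compare_methods <- function(points, scene, configs = all_method_configs(),
                            variables = c("pm25", "pm10"), k = 2, seed = 1,
                            kib_res = NULL) {
  covariates <- extract_covariates(scene, points)
  coords <- as.matrix(points[, c("x", "y")])
  rows <- list()
  for (v in variables) {
    emp <- empirical_semivariogram(coords, points[[v]])
    vg <- fit_variogram(emp, "stable")
    for (cfg in configs) {
      lo <- loocv(points, cfg, scene, v, covariates = covariates,
                  variogram = vg, kib_res = kib_res)
      kf <- kfold_r2(points, cfg, scene, v, k = k, seed = seed,
                     covariates = covariates, variogram = vg,
                     kib_res = kib_res)
      rows[[length(rows) + 1L]] <- data.frame(
        method = cfg$name, algorithm = cfg$algorithm, variable = v,
        rmse_loocv = lo$rmse, r2_kfold = kf$r2, n = nrow(points), k = k,
        seed = seed, n_excluded = lo$n_excluded)
    }
  }
  full <- do.call(rbind, rows)
  agg <- function(df, key) {
    out <- aggregate(df[, c("rmse_loocv", "r2_kfold")],
                     by = list(group = df[[key]], variable = df$variable),
                     FUN = mean)
    out[order(out$variable, out$group), ]
  }
  by_alg <- agg(full, "algorithm")
  covgrp <- c(LPI = "none", OK = "none", KIB = "none",
              LPI_SVF = "SVF", OCK_SVF = "SVF", KIB_SVF = "SVF",
              LPI_FAI = "FAI", OCK_FAI = "FAI", KIB_FAI = "FAI",
              LPI_RDA = "RDA", OCK_RDA = "RDA", KIB_RDA = "RDA")
  sub <- full[full$method %in% names(covgrp), ]
  sub$covgroup <- covgrp[sub$method]
  by_cov <- agg(sub, "covgroup")
  structure(list(full = full, by_algorithm = by_alg, by_covariate = by_cov,
                 k = k, seed = seed, n = nrow(points)),
            class = "mk_cvreport")
}

#' @export
print.mk_cvreport <- function(x, ...) {
  cat("Cross-validation report (n =", x$n, ", k =", x$k, ", seed =",
      x$seed, ")\n\nPer method:\n")
  print(x$full[, c("method", "variable", "rmse_loocv", "r2_kfold")],
        row.names = FALSE)
  cat("\nBy algorithm:\n"); print(x$by_algorithm, row.names = FALSE)
  cat("\nBy covariate:\n"); print(x$by_covariate, row.names = FALSE)
  invisible(x)
}
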