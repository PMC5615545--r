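test_that("empirical semivariogram reproduces the collinear worked example", {
  emp <- empirical_semivariogram(cbind(c(0, 1, 2), 0), c(0, 1, 2),
                                 bin_width = 1, max_lag = 2.5)
  expect_equal(emp$gamma[2], 0.5)       # two lag-1 pairs
  expect_identical(emp$n_pairs[2], 2L)
  expect_equal(emp$gamma[3], 2.0)       # one lag-2 pair
  expect_identical(emp$n_pairs[3], 1L)
  expect_true(is.nan(emp$gamma[1]))

  const <- empirical_semivariogram(cbind(runif(10), runif(10)), rep(3, 10),
                                   bin_width = 0.2, max_lag = 1)
  expect_true(all(const$gamma[const$n_pairs > 0] == 0))
  expect_error(empirical_semivariogram(cbind(1, 1), 1), "2 points")
})

test_that("binned estimator agrees with the all-pairs oracle (incl. duplicates)", {
  set.seed(11)
  for (case in 1:3) {
    n <- sample(10:50, 1)
    coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    vals <- rnorm(n)
    if (case == 3) { coords <- rbind(coords, coords); vals <- c(vals, vals) }
    emp <- empirical_semivariogram(coords, vals, bin_width = 8, max_lag = 64)
    ora <- emp_oracle(coords, vals, bin_width = 8, max_lag = 64)
    expect_equal(emp$gamma, ora$gamma, tolerance = 1e-12)
    expect_identical(emp$n_pairs, ora$n_pairs)
  }
})

test_that("model_gamma closed forms and monotonicity", {
  kinds <- list(mk_vgm("exponential", 0.2, 1, 30),
                mk_vgm("gaussian", 0, 2, 40),
                mk_vgm("stable", 0.1, 1.5, 25, shape = 0.7),
                mk_vgm("spherical", 0.3, 1, 50))
  for (m in kinds) {
    expect_identical(model_gamma(m, 0), 0)          # gamma(0) = 0 convention
    d <- seq(0.01, 200, length.out = 400)
    expect_true(all(diff(model_gamma(m, d)) >= -1e-12))
  }
  expect_equal(model_gamma(mk_vgm("exponential", 0, 1, 30), 30),
               1 - exp(-3), tolerance = 1e-12)
  sph <- mk_vgm("spherical", 0.3, 1.2, 50)
  expect_equal(model_gamma(sph, c(50, 80, 1000)), rep(1.5, 3))
  expect_error(model_gamma(sph, -1), ">= 0")
  expect_error(mk_vgm("stable", range = -5), "range")
  expect_error(mk_vgm("stable", nugget = -1), "nugget")
})

test_that("WLS fit recovers exact model parameters to < 1 %", {
  for (kind in c("spherical", "stable")) {
    truem <- if (kind == "spherical") mk_vgm("spherical", 0.2, 2, 40)
             else mk_vgm("stable", 0.1, 1.8, 35, shape = 1.5)
    lag <- seq(2.5, 75, by = 5)
    emp <- data.frame(lag = lag, gamma = model_gamma(truem, lag),
                      n_pairs = 60L)
    class(emp) <- c("mk_empvario", "data.frame")
    f <- fit_variogram(emp, kind)
    expect_equal(f$psill, truem$psill, tolerance = 0.01)
    expect_equal(f$range, truem$range, tolerance = 0.01)
    expect_equal(f$nugget, truem$nugget, tolerance = 0.05)
  }
  allnan <- data.frame(lag = 1:6, gamma = NaN, n_pairs = 0L)
  class(allnan) <- c("mk_empvario", "data.frame")
  expect_error(fit_variogram(allnan), "4 non-empty bins")
})

test_that("select_model picks the generating family and reports scores", {
  truem <- mk_vgm("spherical", 0.1, 2, 40)
  lag <- seq(2.5, 75, by = 5)
  emp <- data.frame(lag = lag, gamma = model_gamma(truem, lag), n_pairs = 60L)
  class(emp) <- c("mk_empvario", "data.frame")
  sel <- select_model(emp)
  expect_identical(nrow(sel$scores), 4L)
  expect_identical(sel$model$kind, "spherical")
  one <- select_model(emp, "gaussian")
  expect_identical(one$model$kind, "gaussian")
  expect_identical(nrow(one$scores), 1L)
})

test_that("major range follows the 95 %-of-sill definition", {
  expect_equal(major_range(mk_vgm("exponential", 0, 1, 30)), 30,
               tolerance = 0.005)
  expect_identical(major_range(mk_vgm("spherical", 0, 1, 58)), 58)
  m <- mk_vgm("stable", 0, 1, 30, shape = 1.5)
  expect_equal(model_gamma(m, major_range(m)), 0.95, tolerance = 1e-9)
  expect_warning(r0 <- major_range(mk_vgm("exponential", 1, 0, 30)), "sill")
  expect_identical(r0, 0)
})

test_that("coregionalization: bounds, degenerate covariates, identity case", {
  set.seed(21)
  n <- 200
  coords <- cbind(runif(n, 0, 300), runif(n, 0, 300))
  g <- mk_grid(0, 0, 15, 20, 20)
  gp <- grf_prepare(g, mk_vgm("exponential", 0.1, 2, 60))
  z <- microkrige:::grid_bilinear(g, microkrige:::grid_matrix(
    g, microkrige:::grf_draw(gp, seed = 1)), coords)

  # covariate identical to the primary: cross structure hits the
  # correlation-1 bound
  cr <- fit_coregionalization(coords, z, data.frame(svf50 = z),
                              kind = "exponential")
  expect_equal(cr$B_psill[1, 2], cr$B_psill[1, 1], tolerance = 1e-6)
  for (B in list(cr$B_nugget, cr$B_psill)) {
    expect_true(all(eigen(B, symmetric = TRUE)$values > -1e-8))
    expect_lte(B[1, 2]^2, B[1, 1] * B[2, 2] + 1e-10)
  }
  expect_message(
    expect_error(fit_coregionalization(coords, z,
                                       data.frame(flat = rep(1, n))),
                 "no usable covariates"),
    "zero-variance")
})

test_that("independent covariate yields a small fitted cross sill", {
  g <- mk_grid(0, 0, 15, 20, 20)
  gp <- grf_prepare(g, mk_vgm("exponential", 0.1, 2, 60))
  ratio <- vapply(1:20, function(s) {
    with_seed_local(s, {
      n <- 400
      coords <- cbind(runif(n, 0, 300), runif(n, 0, 300))
      z1 <- microkrige:::grid_bilinear(g, microkrige:::grid_matrix(
        g, microkrige:::grf_draw(gp, seed = 100 + s)), coords)
      z2 <- microkrige:::grid_bilinear(g, microkrige:::grid_matrix(
        g, microkrige:::grf_draw(gp, seed = 900 + s)), coords)
      cr <- fit_coregionalization(coords, z1, data.frame(c1 = z2),
                                  kind = "exponential")
      abs(cr$B_psill[1, 2]) /
        sqrt(max(cr$B_psill[1, 1] * cr$B_psill[2, 2], 1e-12))
    })
  }, 0)
  expect_lt(median(ratio), 0.2)
})
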