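test_that("LPI reproduces constants and planes; order-0 is the local mean", {
  set.seed(3)
  pts <- data.frame(x = runif(25, 0, 100), y = runif(25, 0, 100))
  g <- mk_grid(0, 0, 20, 5, 5)
  for (kk in c("exponential", "quartic")) {
    sf <- lpi_predict(pts, rep(7.5, 25), kernel_spec(kk, 60), g)
    expect_equal(sf$values[sf$mask], rep(7.5, sum(sf$mask)),
                 tolerance = 1e-10)
  }
  plane <- 2 * pts$x + 3 * pts$y
  sf <- lpi_predict(pts, plane, kernel_spec("gaussian", 80), g, order = 1)
  ctr <- microkrige:::grid_center_coords(g)
  expect_equal(as.vector(t(sf$values_raw)), 2 * ctr[, 1] + 3 * ctr[, 2],
               tolerance = 1e-8)

  # order 0 with the constant kernel = arithmetic mean of in-bandwidth points
  p5 <- data.frame(x = c(0, 10, 20, 60, 80), y = rep(0, 5))
  v5 <- c(1, 2, 3, 10, 20)
  res <- microkrige:::predict_lpi_at(as.matrix(p5), v5, cbind(5, 0),
                                     kernel_spec("constant", 25), order = 0)
  expect_equal(res$pred, mean(c(1, 2, 3)))   # points within 25 m of (5, 0)
})

test_that("ordinary kriging: exactness, nugget limit, dense-solve oracle", {
  set.seed(7)
  n <- 20
  pts <- data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100))
  z <- sin(pts$x / 20) + cos(pts$y / 25) + rnorm(n, 0, 0.1)
  m <- mk_vgm("exponential", nugget = 0.05, psill = 1, range = 30)
  r <- microkrige:::predict_ok_at(as.matrix(pts), z, m, as.matrix(pts))
  expect_equal(r$pred, z, tolerance = 1e-8)          # exact interpolator
  expect_equal(r$variance, rep(0, n), tolerance = 1e-8)
  expect_lt(r$weight_sum_err, 1e-10)

  # two points, pure nugget: weights 1/2 each, prediction = mean
  mn <- mk_vgm("exponential", nugget = 1, psill = 1e-12, range = 30)
  two <- microkrige:::predict_ok_at(cbind(c(0, 10), 0), c(4, 8), mn,
                                    cbind(55, 40))
  expect_equal(two$pred, 6, tolerance = 1e-6)

  # independent dense solve at random targets
  for (t in 1:5) {
    tgt <- runif(2, 0, 100)
    got <- microkrige:::predict_ok_at(as.matrix(pts), z, m,
                                      matrix(tgt, 1))$pred
    expect_equal(got, brute_ok(as.matrix(pts), z, m, tgt)$pred,
                 tolerance = 1e-8)
  }
  dup <- rbind(pts, pts[1, ])
  expect_error(microkrige:::predict_ok_at(as.matrix(dup), c(z, z[1]), m,
                                          cbind(1, 1)), "duplicate")
})

test_that("ordinary cokriging: oracle, decoupling, exactness", {
  set.seed(12)
  n <- 15
  pts <- data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100))
  z <- sin(pts$x / 15) + 0.02 * pts$y + rnorm(n, 0, 0.2)
  covs <- data.frame(svf50 = 0.5 * z + rnorm(n, 0, 0.4))
  coreg <- fit_coregionalization(as.matrix(pts), z, covs,
                                 kind = "exponential")
  for (t in 1:4) {
    tgt <- runif(2, 0, 100)
    got <- microkrige:::predict_ock_at(as.matrix(pts), z, as.matrix(covs),
                                       coreg, matrix(tgt, 1))$pred
    expect_equal(got, brute_ock(as.matrix(pts), z, as.matrix(covs), coreg,
                                tgt), tolerance = 1e-8)
  }
  rs <- microkrige:::predict_ock_at(as.matrix(pts), z, as.matrix(covs),
                                    coreg, as.matrix(pts))
  expect_equal(rs$pred, z, tolerance = 1e-8)         # exactness preserved
  expect_lt(rs$weight_sum_err, 1e-10)

  # all cross sills zero -> identical to OK
  c0 <- coreg
  c0$B_psill[1, 2] <- c0$B_psill[2, 1] <- 0
  c0$B_nugget[1, 2] <- c0$B_nugget[2, 1] <- 0
  g <- mk_grid(0, 0, 25, 4, 4)
  m1 <- mk_vgm(coreg$kind, nugget = coreg$B_nugget[1, 1],
               psill = coreg$B_psill[1, 1], range = coreg$range)
  a <- ock_predict(pts, z, covs, c0, g)
  b <- ok_predict(pts, z, m1, g)
  expect_equal(a$values_raw, b$values_raw, tolerance = 1e-8)
})

test_that("barrier distances: open scene, wall detour, symmetry", {
  open_sc <- open_scene(200, 200)
  expect_equal(barrier_distance(open_sc, c(10, 100), c(110, 100), res = 2),
               100)
  wall <- mk_scene(c(0, 100, 0, 100),
                   list(list(poly = rect_poly_t(48, 20, 52, 80),
                             height = 30)), list(), "custom")
  d <- barrier_distance(wall, c(38, 50), c(62, 50), res = 1)
  around <- 2 * sqrt(12^2 + 30^2)      # via the nearer wall end
  expect_gte(d, around - 2)            # detour, up to grid discretisation
  expect_gt(d, 24)                     # strictly above the Euclidean 24 m
  d2 <- barrier_distance(wall, c(62, 50), c(38, 50), res = 1)
  expect_equal(d, d2)
  expect_error(barrier_distance(wall, c(50, 50), c(10, 10), res = 1),
               "outside buildings")
})

test_that("KIB: barrier-free limit, constants, sealing wall", {
  set.seed(5)
  pts <- data.frame(x = runif(30, 0, 200), y = runif(30, 0, 200))
  z <- sin(pts$x / 30) + cos(pts$y / 40)
  k <- kernel_spec("gaussian", 60)
  g <- mk_grid(0, 0, 20, 10, 10)
  open_sc <- open_scene(200, 200)
  sf <- kib_predict(pts, z, k, open_sc, g)
  ctr <- microkrige:::grid_center_coords(g)
  # Euclidean Nadaraya-Watson oracle
  ora <- vapply(seq_len(nrow(ctr)), function(i) {
    w <- kernel_value(k, sqrt((pts$x - ctr[i, 1])^2 + (pts$y - ctr[i, 2])^2))
    sum(w * z) / sum(w)
  }, 0)
  expect_equal(as.vector(t(sf$values_raw)), ora, tolerance = 1e-10)

  sfc <- kib_predict(pts, rep(4, 30), k, open_sc, g)
  expect_equal(sfc$values[sfc$mask], rep(4, sum(sfc$mask)),
               tolerance = 1e-12)

  # full-width sealing wall: a northern sample cannot influence the south
  seal <- mk_scene(c(0, 100, 0, 100),
                   list(list(poly = rect_poly_t(0, 42, 100, 58),
                             height = 30)), list(), "custom")
  spts <- data.frame(x = c(20, 80, 50), y = c(20, 20, 90))
  sv <- c(1, 1, 100)
  gk <- mk_grid(0, 0, 10, 10, 10)
  sk <- kib_predict(spts, sv, kernel_spec("quartic", 80), seal, gk)
  south <- sk$values[8:10, ]           # rows south of the wall
  expect_true(all(abs(south[is.finite(south)] - 1) < 1e-9))
  # compact support far smaller than the site leaves distant cells masked
  sk3 <- kib_predict(spts, sv, kernel_spec("quartic", 12), seal, gk)
  expect_gt(sum(!sk3$mask), 0)
})

test_that("the 13-method dispatcher builds each configuration", {
  cfgs <- all_method_configs()
  expect_identical(names(cfgs), microkrige:::METHOD_NAMES)
  expect_identical(length(cfgs), 13L)
  expect_identical(cfgs$OCK_ALL$covariate_set, c("svf50", "fai50", "rda50"))
  expect_identical(cfgs$LPI_FAI$weight_factor, "fai50")
  expect_null(cfgs$OK$covariate_set)
  expect_error(method_config("IDW"), "unknown method")
  bad <- cfgs$OK; bad$algorithm <- "XXX"
  expect_error(run_method(bad, data.frame(x = 1:5, y = 1:5, pm25 = 1:5),
                          open_scene(), mk_grid(0, 0, 1, 2, 2)),
               "unknown algorithm")
})
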