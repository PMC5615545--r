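rotate_scene <- function(scene, angle, about) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  rot <- function(p) sweep(sweep(p, 2, about) %*% t(R), 2, about, "+")
  mk_scene(scene$extent,
           lapply(scene$buildings, function(b)
             list(poly = rot(b$poly), height = b$height)),
           lapply(scene$roads, rot), "custom")
}

test_that("open scene gives SVF 1, FAI 0, RDA 0", {
  sc <- open_scene()
  expect_identical(compute_svf(sc, c(100, 100)), 1)
  expect_identical(compute_fai(sc, c(100, 100)), 0)
  expect_identical(compute_rda(sc, c(100, 100)), 0)
  tr <- extract_covariates(sc, cbind(x = c(50, 150), y = c(50, 150)))
  expect_equal(tr$svf50, c(1, 1))
  expect_equal(tr$fai50, c(0, 0))
  expect_equal(tr$rda50, c(0, 0))
  expect_identical(nrow(extract_covariates(sc, cbind(x = numeric(0),
                                                     y = numeric(0)))), 0L)
})

test_that("SVF for a long wall matches the numerical quadrature oracle", {
  # wall 2 m thick at perpendicular distance 10 m, height 10 m
  sc <- mk_scene(c(0, 400, 0, 400),
                 list(list(poly = rect_poly_t(210, 0, 212, 400), height = 10)),
                 list(), "custom")
  v <- compute_svf(sc, c(200, 200), n_azimuths = 720, max_radius = 50)
  # oracle: mean of cos^2(beta(theta)) with beta = atan(h cos(theta) / d)
  # where the wall is visible (within the 50 m horizon)
  th <- seq(0, 2 * pi, length.out = 200001)[-1]
  dd <- ifelse(cos(th) > 0, 10 / cos(th), Inf)
  tb <- ifelse(dd <= 50, 10 / dd, 0)
  oracle <- mean(1 / (1 + tb^2))
  expect_equal(v, oracle, tolerance = 2e-3)
  # doubling the azimuth count moves the standard-scene SVF by < 0.01
  grid_sc <- make_street_grid(seed = 1)
  p <- c(50, 10)  # on a road
  expect_lt(abs(compute_svf(grid_sc, p, 72) - compute_svf(grid_sc, p, 144)),
            0.01)
  expect_warning(compute_svf(grid_sc, c(60, 60)), "inside a building")
})

test_that("FAI broadside geometry and direction-set rotation invariance", {
  sc <- mk_scene(c(0, 200, 0, 200),
                 list(list(poly = rect_poly_t(120, 90, 124, 110),
                           height = 40)), list(), "custom")
  expect_equal(compute_fai(sc, c(100, 100), buffer = 50, n_directions = 1),
               20 * 40 / (pi * 50^2), tolerance = 1e-9)
  p <- c(100, 100)
  rot <- rotate_scene(sc, 2 * pi / 16, p)
  expect_equal(compute_fai(sc, p, 50, 16), compute_fai(rot, p, 50, 16),
               tolerance = 1e-9)
  expect_error(compute_fai(sc, p, buffer = -1), "buffer")
})

test_that("RDA quadrature: half-plane, saturation, growth monotonicity", {
  hp <- mk_scene(c(0, 200, 0, 200), list(),
                 list(rect_poly_t(100, 0, 200, 200)), "custom")
  expect_equal(compute_rda(hp, c(100, 100)), 0.5, tolerance = 0.02)
  expect_identical(compute_rda(hp, c(150, 100), buffer = 20), 1)
  # widening the road weakly increases RDA
  narrow <- mk_scene(c(0, 200, 0, 200), list(),
                     list(rect_poly_t(90, 0, 110, 200)), "custom")
  wide <- mk_scene(c(0, 200, 0, 200), list(),
                   list(rect_poly_t(80, 0, 120, 200)), "custom")
  expect_gte(compute_rda(wide, c(100, 50)), compute_rda(narrow, c(100, 50)))
})

test_that("SVF decreases with height; covariates are translation invariant", {
  lo <- mk_scene(c(0, 200, 0, 200),
                 list(list(poly = rect_poly_t(110, 80, 130, 120),
                           height = 20)), list(), "custom")
  hi <- mk_scene(c(0, 200, 0, 200),
                 list(list(poly = rect_poly_t(110, 80, 130, 120),
                           height = 60)), list(), "custom")
  expect_lte(compute_svf(hi, c(100, 100)), compute_svf(lo, c(100, 100)))

  shift <- c(37, -21)
  sc <- mk_scene(c(0, 300, 0, 300),
                 list(list(poly = rect_poly_t(140, 120, 160, 180),
                           height = 35)),
                 list(rect_poly_t(100, 0, 120, 300)), "custom")
  moved <- mk_scene(c(0, 300, 0, 300) + rep(shift, each = 2),
                    list(list(poly = sweep(sc$buildings[[1]]$poly, 2, shift,
                                           "+"), height = 35)),
                    list(sweep(sc$roads[[1]], 2, shift, "+")), "custom")
  a <- extract_covariates(sc, cbind(x = 130, y = 150))
  b <- extract_covariates(moved, cbind(x = 130 + shift[1],
                                       y = 150 + shift[2]))
  expect_equal(unlist(a), unlist(b), tolerance = 1e-9)
})

test_that("points with identical 50 m neighbourhoods get identical triples", {
  b1 <- rect_poly_t(70, 95, 90, 115)
  b2 <- sweep(b1, 2, c(200, 150), "+")
  road1 <- rect_poly_t(40, 60, 140, 80)
  road2 <- sweep(road1, 2, c(200, 150), "+")
  sc <- mk_scene(c(0, 500, 0, 500),
                 list(list(poly = b1, height = 30),
                      list(poly = b2, height = 30)),
                 list(road1, road2), "custom")
  tr <- extract_covariates(sc, cbind(x = c(100, 300), y = c(100, 250)))
  expect_equal(unlist(tr[1, ]), unlist(tr[2, ]), tolerance = 1e-9)
})
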