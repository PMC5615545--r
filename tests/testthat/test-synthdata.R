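test_that("street grid generator honours block counts, determinism, errors", {
  sc <- make_street_grid("orthogonal", c(500, 500), 80, 20, c(40, 15), seed = 1)
  expect_identical(length(sc$buildings), 25L)   # floor(500/100)^2 blocks
  sc2 <- make_street_grid("orthogonal", c(500, 500), 80, 20, c(40, 15), seed = 1)
  expect_identical(lapply(sc$buildings, `[[`, "poly"),
                   lapply(sc2$buildings, `[[`, "poly"))
  expect_identical(microkrige:::building_heights(sc),
                   microkrige:::building_heights(sc2))
  expect_error(make_street_grid("orthogonal", c(100, 100), 100, 0), "road_width")
  expect_error(make_street_grid("orthogonal", c(-10, 100), 80, 20), "positive")
  expect_error(make_street_grid("orthogonal", c(50, 50), 80, 20), "too small")

  irr <- make_street_grid("irregular", c(500, 500), 80, 20, c(40, 15), seed = 7)
  irr2 <- make_street_grid("irregular", c(500, 500), 80, 20, c(40, 15), seed = 7)
  expect_identical(lapply(irr$buildings, `[[`, "poly"),
                   lapply(irr2$buildings, `[[`, "poly"))
  for (s in list(sc, irr)) {
    for (b in s$buildings) {
      expect_true(all(b$poly[, 1] >= s$extent[1] & b$poly[, 1] <= s$extent[2]))
      expect_true(all(b$poly[, 2] >= s$extent[3] & b$poly[, 2] <= s$extent[4]))
      expect_gt(b$height, 0)
      # building corners and centroid must not fall on a road
      px <- c(b$poly[, 1], mean(b$poly[, 1]))
      py <- c(b$poly[, 2], mean(b$poly[, 2]))
      for (r in s$roads)
        expect_false(any(px > min(r[, 1]) & px < max(r[, 1]) &
                         py > min(r[, 2]) & py < max(r[, 2])))
    }
  }
})

test_that("simulated field: flat limit, hotspot kernel, determinism, caps", {
  scene <- open_scene(200, 200)
  flat <- simulate_pm_field(scene, mk_vgm("exponential", 0, 0, 30),
                            mean_level = 30, seed = 1, grid_cell = 10)
  expect_true(all(flat$pm25 == 30))

  hot <- simulate_pm_field(scene, mk_vgm("exponential", 0, 0, 30),
                           hotspots = data.frame(x = 95, y = 95,
                                                 amplitude = 30, decay = 10),
                           mean_level = 30, seed = 1, grid_cell = 10)
  at <- function(tr, x, y) {
    rc <- microkrige:::grid_rowcol(tr$grid, cbind(x, y))
    tr$pm25[rc]
  }
  # (95, 95) is a cell centre; 30 m along the row: value drop 30 (1 - e^-3)
  expect_equal(at(hot, 95, 95) - at(hot, 125, 95), 30 * (1 - exp(-3)),
               tolerance = 1e-9)

  g1 <- simulate_pm_field(scene, seed = 9, grid_cell = 10)
  g2 <- simulate_pm_field(scene, seed = 9, grid_cell = 10)
  expect_identical(g1$pm25, g2$pm25)   # bit-identical for a fixed seed
  expect_identical(g1$pm10, g2$pm10)

  expect_error(simulate_pm_field(open_scene(500, 500), grid_cell = 2),
               "coarser")
  expect_error(simulate_pm_field(scene, mean_level = 0), "mean_level")
  expect_error(simulate_pm_field(scene,
      hotspots = data.frame(x = 1, y = 1, amplitude = 5, decay = 0)),
      "decay")
})

test_that("pm10 >= pm25 cell-wise across seeds and in walk records", {
  scene <- open_scene(200, 200)
  for (s in 1:3) {
    tr <- simulate_pm_field(scene, seed = s, grid_cell = 10)
    expect_true(all(tr$pm10 >= tr$pm25))
    rec <- simulate_walk(mk_route(rbind(c(5, 100), c(195, 100))), tr,
                         seed = s)
    expect_true(all(rec$pm10_raw >= rec$pm25_raw * 0.999))
  }
})

test_that("walk sampling counts follow route length and directions", {
  scene <- open_scene(1000, 40)
  tr <- simulate_pm_field(scene, mk_vgm("exponential", 0, 0, 30),
                          mean_level = 30, seed = 1, grid_cell = 20)
  rt <- mk_route(rbind(c(20, 20), c(980, 20)), speed = 0.8, interval = 1,
                 directions = "forward")
  rec <- simulate_walk(rt, tr, seed = 1)
  expect_identical(nrow(rec), 1201L)            # floor(960 / 0.8) + 1
  rt2 <- mk_route(rbind(c(20, 20), c(980, 20)), directions = "both")
  expect_identical(nrow(simulate_walk(rt2, tr, seed = 1)), 2402L)
  expect_error(mk_route(rbind(c(0, 0), c(1, 0)), speed = 0), "speed")
  expect_error(simulate_walk(rt, tr, rh_mean = 1), "rh_mean")
})

test_that("noiseless walk round-trips the field through the RH correction", {
  scene <- open_scene(200, 200)
  tr <- simulate_pm_field(scene,
                          hotspots = data.frame(x = 100, y = 100,
                                                amplitude = 25, decay = 12),
                          seed = 2, grid_cell = 10)
  rt <- mk_route(rbind(c(15, 100), c(185, 100)), directions = "forward")
  rec <- simulate_walk(rt, tr, rh_ar1 = c(0.9, 0.002), gps_sigma = 0,
                       instrument_noise_cv = 0, seed = 5)
  corr <- rh_correction(rec)
  truth_at <- microkrige:::grid_bilinear(tr$grid, tr$pm25,
                                         cbind(rec$x, rec$y))
  expect_equal(corr$pm25, truth_at, tolerance = 1e-9)
  expect_true(all(rec$pm25_raw >= truth_at))    # CF >= 1 inflates raw
})

test_that("GRF realisations reproduce the semivariogram sill at the range", {
  g <- mk_grid(0, 0, 10, 50, 50)
  m <- mk_vgm("exponential", nugget = 0, psill = 4, range = 30)
  gp <- grf_prepare(g, m)
  ctr <- microkrige:::grid_center_coords(g)
  sill <- m$nugget + m$psill
  gam_at_range <- vapply(1:20, function(s) {
    z <- microkrige:::grf_draw(gp, seed = s)
    emp <- empirical_semivariogram(ctr, z, bin_width = 10, max_lag = 100)
    emp$gamma[emp$lag == 35]  # bin [30, 40) containing the range distance
  }, 0)
  expect_lt(abs(mean(gam_at_range) - sill) / sill, 0.25)
})
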