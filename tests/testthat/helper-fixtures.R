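# Shared fixtures, built in code (no stored data) and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

open_scene <- function(w = 200, h = 200)
  mk_scene(c(0, w, 0, h), list(), list(), "custom")

rect_poly_t <- function(x0, y0, x1, y1)
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))

# default stable-model GRF factor on the 500 m / 10 m simulation grid
shared_grf <- function() cached("grf", {
  grf_prepare(mk_grid(0, 0, 10, 50, 50),
              mk_vgm("stable", nugget = 1.5, psill = 20, range = 25,
                     shape = 1.5))
})

# one default scenario with thinned, preprocessed points (~320 clean points)
shared_scenario <- function() cached("scenario", {
  sc <- synth_scenario(seed = 1, grf = shared_grf())
  rec <- sc$records[seq(1, nrow(sc$records), by = 15), ]
  clean <- preprocess_transect(rec, merge_radius = 3)
  c(sc, list(clean = clean))
})

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

# brute-force empirical semivariogram: double loop over all pairs
emp_oracle <- function(coords, values, bin_width, max_lag) {
  n <- nrow(coords)
  nb <- ceiling(max_lag / bin_width)
  ssum <- numeric(nb); cnt <- integer(nb)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d >= max_lag) next
    b <- floor(d / bin_width) + 1
    ssum[b] <- ssum[b] + (values[i] - values[j])^2
    cnt[b] <- cnt[b] + 1L
  }
  list(gamma = ifelse(cnt > 0, ssum / (2 * cnt), NaN), n_pairs = cnt)
}

# independent dense ordinary-kriging solve at one target
brute_ok <- function(coords, values, model, target) {
  n <- nrow(coords)
  G <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    G[i, j] <- model_gamma(model, sqrt(sum((coords[i, ] - coords[j, ])^2)))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  g0 <- vapply(1:n, function(i)
    model_gamma(model, sqrt(sum((coords[i, ] - target)^2))), 0)
  sol <- solve(A, c(g0, 1))
  list(pred = sum(sol[1:n] * values), lambda = sol[1:n])
}

# independent dense ordinary-cokriging solve at one target (primary + p
# secondaries, one unbiasedness constraint per variable), built with
# explicit loops from the coregionalization definition
brute_ock <- function(coords, values, covmat, coreg, target) {
  n <- nrow(coords); p <- ncol(covmat); nv <- p + 1
  unit <- mk_vgm(coreg$kind, nugget = 0, psill = 1, range = coreg$range,
                 shape = coreg$shape)
  gam <- function(u, v, d)
    coreg$B_nugget[u, v] * (d > 0) + coreg$B_psill[u, v] * model_gamma(unit, d)
  N <- n * nv
  A <- matrix(0, N + nv, N + nv)
  for (u in 1:nv) for (v in 1:nv) for (i in 1:n) for (j in 1:n)
    A[(u - 1) * n + i, (v - 1) * n + j] <-
      gam(u, v, sqrt(sum((coords[i, ] - coords[j, ])^2)))
  for (u in 1:nv) {
    A[(u - 1) * n + (1:n), N + u] <- 1
    A[N + u, (u - 1) * n + (1:n)] <- 1
  }
  b <- numeric(N + nv)
  for (u in 1:nv) for (i in 1:n)
    b[(u - 1) * n + i] <- gam(u, 1, sqrt(sum((coords[i, ] - target)^2)))
  b[N + 1] <- 1
  sol <- solve(A, b)
  sum(sol[1:N] * as.vector(cbind(values, covmat)))
}
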