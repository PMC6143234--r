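test_that("lattice generation masks the requested cell count", {
  expect_equal(nrow(gen_lattice(4, 4)), 16)
  g <- gen_lattice(10, 10, mask_fraction = 0.05, seed = 1)
  expect_equal(nrow(g), 95)
  expect_identical(g, gen_lattice(10, 10, mask_fraction = 0.05, seed = 1))
  expect_false(identical(g$cell_id,
                         gen_lattice(10, 10, mask_fraction = 0.05,
                                     seed = 2)$cell_id))
  # round(1296 * 0.048) = 62 removed leaves 1234 cells
  expect_equal(nrow(gen_lattice(36, 36, mask_fraction = 0.048, seed = 3)), 1234)
  expect_error(gen_lattice(3, 3, mask_fraction = 0.5), "fewer than 9")
})

test_that("lattice accepts a user-supplied mask", {
  g <- gen_lattice(4, 4, mask = c(1, 16))
  expect_equal(nrow(g), 14)
  expect_false(any(c(1, 16) %in% g$cell_id))
})

test_that("environmental fields honour the standardization contract", {
  sc <- fixture_scaffold(10, 10)
  X <- gen_env_fields(sc$grid, sc$basis, k = 6, spatial_mix = 0.5,
                      seed = 4, n_fields = 5)
  expect_equal(unname(colMeans(X)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(X, 2, sd)), rep(1, 5), tolerance = 1e-12)
  expect_error(gen_env_fields(sc$grid, sc$basis, k = 1000, spatial_mix = 0.5),
               "exceeds")
})

test_that("pure-eigenvector field attains the Moran-eigenvalue identity", {
  sc <- fixture_scaffold(10, 10)
  f <- gen_env_fields(sc$grid, sc$basis, k = 1, spatial_mix = 1, seed = 5)
  expect_equal(moran_i(f[, 1], sc$W)$I,
               (nrow(sc$grid) / sc$W$S0) * sc$basis$values[1],
               tolerance = 1e-10)
})

test_that("pure-noise fields show no spatial autocorrelation", {
  sc <- fixture_scaffold(10, 10)
  z <- vapply(1:20, function(s) {
    f <- gen_env_fields(sc$grid, sc$basis, k = 6, spatial_mix = 0, seed = s)
    moran_i(f[, 1], sc$W)$z
  }, numeric(1))
  expect_gte(sum(abs(z) < 3), 19)
})

test_that("Moran's I of generated fields increases with the spatial mix", {
  sc <- fixture_scaffold(10, 10)
  mean_i <- vapply(c(0, 0.5, 1), function(mix) {
    mean(vapply(1:20, function(s) {
      moran_i(gen_env_fields(sc$grid, sc$basis, k = 6, spatial_mix = mix,
                             seed = s)[, 1], sc$W)$I
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_i) >= 0))
})

test_that("richness surface is Poisson around its intercept", {
  sc <- fixture_scaffold(15, 15)
  y <- gen_richness_surface(sc$grid, beta0 = log(36), seed = 6)
  expect_true(all(y == round(y)))
  expect_lt(abs(mean(y) - 36), 3 * sqrt(36 / length(y)))
  expect_error(gen_richness_surface(sc$grid, beta0 = 20), "1e6")
})

test_that("richness surface without eigenvector effects leaves clean residuals", {
  sc <- fixture_scaffold(12, 12)
  X <- gen_env_fields(sc$grid, sc$basis, k = 5, spatial_mix = 0.5,
                      seed = 7, n_fields = 2)
  ok <- vapply(1:20, function(s) {
    y <- gen_richness_surface(sc$grid, X, beta = c(0.3, -0.2), seed = s)
    f <- fit_glm(X, y)
    abs(moran_i(std_pearson_residuals(f, type = "pearson"), sc$W)$z) < 3
  }, logical(1))
  expect_gte(sum(ok), 18)
})

test_that("planted eigenvector effects confound a plain GLM", {
  sc <- fixture_scaffold(12, 12)
  X <- gen_env_fields(sc$grid, sc$basis, k = 5, spatial_mix = 0.5,
                      seed = 8, n_fields = 2)
  gam <- 0.35 * sqrt(nrow(sc$grid)) * c(1, 1, 1)
  ok <- vapply(1:20, function(s) {
    y <- gen_richness_surface(sc$grid, X, beta = c(0.3, -0.2), gamma = gam,
                              basis = sc$basis, gamma_idx = c(2, 5, 9),
                              seed = 100 + s)
    f <- fit_glm(X, y)
    moran_i(std_pearson_residuals(f), sc$W)$z > 2
  }, logical(1))
  expect_gte(sum(ok), 18)
})

test_that("plot occupancy extremes behave deterministically", {
  sc <- fixture_scaffold(4, 4)
  pool <- make_species_pool(5, seed = 1)
  P1 <- matrix(1, nrow(sc$grid), 5)
  full <- gen_plot_data(sc$grid, pool, P1, plots_per_grid = c(2, 2), seed = 2)
  expect_true(all(full$species == paste(pool$species, collapse = ";")))
  P0 <- matrix(0, nrow(sc$grid), 5)
  none <- gen_plot_data(sc$grid, pool, P0, plots_per_grid = c(2, 2), seed = 2)
  expect_true(all(none$species == ""))
  expect_error(gen_plot_data(sc$grid, pool, P1, plots_per_grid = c(0, 2)),
               "within")
})

test_that("expected grid richness follows the union-probability closed form", {
  # 500 single-cell grids, m plots each, fixed occupancy vector
  g <- gen_lattice(25, 20)
  p_s <- c(0.9, 0.5, 0.2, 0.05, 0.02)
  m <- 6
  pool <- make_species_pool(5, seed = 3, score_skew = 0)
  P <- matrix(p_s, nrow(g), 5, byrow = TRUE)
  plots <- gen_plot_data(g, pool, P, plots_per_grid = c(m, m), seed = 4)
  sets <- strsplit(plots$species, ";", fixed = TRUE)
  rich <- vapply(split(sets, plots$grid_id),
                 function(s) length(unique(unlist(s))), numeric(1))
  expected <- sum(1 - (1 - p_s)^m)
  se <- sd(rich) / sqrt(length(rich))
  expect_lt(abs(mean(rich) - expected), 3 * se)
})

test_that("identical seeds reproduce plot data byte-for-byte", {
  sc <- fixture_scaffold(4, 4)
  pool <- make_species_pool(10, seed = 1)
  P <- occupancy_probs(pool, X = NULL, basis = sc$basis)
  a <- gen_plot_data(sc$grid, pool, P, plots_per_grid = c(3, 8), seed = 9)
  b <- gen_plot_data(sc$grid, pool, P, plots_per_grid = c(3, 8), seed = 9)
  d <- gen_plot_data(sc$grid, pool, P, plots_per_grid = c(3, 8), seed = 10)
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("synthetic fine climate supports full predictor derivation", {
  sc <- fixture_scaffold(5, 5)
  fine <- gen_climate_fine(sc$grid, sc$basis, cells_per_grid = 3, seed = 11)
  expect_equal(nrow(fine), 3 * nrow(sc$grid))
  pred <- derive_predictors(fine)
  expect_setequal(setdiff(names(pred), "grid_id"),
                  c("FA", "WA", "ART", "PSN", "TSN", "MAT", "MTWQ", "PET",
                    "EW", "RA", "RMAP", "RMAT", "MFDF", "MPDQ", "MTCQ",
                    "AET", "AI", "MAP"))
  expect_equal(nrow(pred), nrow(sc$grid))
  expect_true(all(is.finite(as.matrix(pred[-1]))))
})
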