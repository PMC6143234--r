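test_that("Moran's I matches a hand-expanded double sum on a 2x2 lattice", {
  # rook adjacency on a 2x2 grid, cells row-major: 1-2, 1-3, 2-4, 3-4
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- W[1, 3] <- W[3, 1] <- 1
  W[2, 4] <- W[4, 2] <- W[3, 4] <- W[4, 3] <- 1
  x <- c(1, 2, 3, 4)
  got <- moran_i(x, W)$I
  # hand expansion: cross-products over the eight directed links
  xc <- x - mean(x)
  num <- 2 * (xc[1] * xc[2] + xc[1] * xc[3] + xc[2] * xc[4] + xc[3] * xc[4])
  expect_equal(got, (4 / 8) * num / sum(xc^2), tolerance = 1e-12)
  expect_equal(got, moran_bruteforce(x, W), tolerance = 1e-12)
})

test_that("Moran's I agrees with brute force on random instances", {
  set.seed(21)
  for (case in 1:8) {
    nr <- sample(4:10, 1); nc <- sample(4:10, 1)
    sc <- fixture_scaffold(nr, nc)
    x <- rnorm(nrow(sc$grid))
    expect_equal(moran_i(x, sc$W)$I, moran_bruteforce(x, sc$W$W),
                 tolerance = 1e-10)
  }
})

test_that("the permutation mean of I is the null expectation", {
  sc <- fixture_scaffold(7, 7)
  set.seed(22)
  x <- rnorm(nrow(sc$grid))
  n <- length(x)
  Is <- vapply(1:2000, function(i) moran_i(sample(x), sc$W)$I, numeric(1))
  mc_se <- sd(Is) / sqrt(length(Is))
  expect_lt(abs(mean(Is) - (-1 / (n - 1))), 3 * mc_se)
})

test_that("Moran's I agrees with an independent implementation", {
  skip_if_not_installed("ape")
  sc <- fixture_scaffold(6, 6)
  set.seed(23)
  x <- rnorm(nrow(sc$grid))
  # ape row-standardizes the supplied weights, so hand it (and ours)
  # the identical row-normalized matrix
  Wr <- as.matrix(sc$W$W) / Matrix::rowSums(sc$W$W)
  got <- moran_i(x, Wr)
  ref <- ape::Moran.I(x, Wr, scaled = FALSE)
  expect_equal(got$I, ref$observed, tolerance = 1e-10)
  expect_equal(got$expected, ref$expected, tolerance = 1e-12)
})

test_that("Moran z-scores on pure noise are standard-normal-like", {
  sc <- fixture_scaffold(15, 15)
  set.seed(24)
  z <- vapply(1:500, function(i) moran_i(rnorm(225), sc$W)$z, numeric(1))
  expect_lt(abs(mean(z)), 0.1)
  expect_gt(sd(z), 0.85)
  expect_lt(sd(z), 1.15)
})

test_that("moran_i rejects degenerate input", {
  sc <- fixture_scaffold(4, 4)
  expect_error(moran_i(rep(2, nrow(sc$grid)), sc$W), "constant")
})

test_that("signed-rank test matches the worked case and symmetries", {
  w <- wilcoxon_signed_rank(c(0, 0, 0), c(1, -2, 3))
  expect_equal(w$W, 4)
  expect_equal(w$p, 0.75)
  # constant positive shift: W = n(n+1)/2
  obs <- rnorm(8)
  all_pos <- wilcoxon_signed_rank(obs, obs + 2)
  expect_equal(all_pos$W, 8 * 9 / 2)
  # swapping arguments reflects W about n(n+1)/2
  set.seed(25)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(wilcoxon_signed_rank(a, b)$W + wilcoxon_signed_rank(b, a)$W,
               10 * 11 / 2)
  expect_error(wilcoxon_signed_rank(a, a), "zero")
})

test_that("exact signed-rank p agrees with sign-pattern enumeration", {
  set.seed(26)
  for (n in c(4, 6, 9, 12)) {
    for (rep in 1:3) {
      d <- round(rnorm(n), 3)
      while (any(duplicated(abs(d))) || any(d == 0)) d <- round(rnorm(n), 3)
      got <- wilcoxon_signed_rank(rep(0, n), d)
      ref <- wilcoxon_enumerate(d)
      expect_equal(got$W, ref$W)
      expect_equal(got$p, ref$p, tolerance = 1e-12)
      base <- wilcox.test(d)
      expect_equal(got$W, unname(base$statistic))
      expect_equal(got$p, base$p.value, tolerance = 1e-12)
    }
  }
})

test_that("large or tied samples fall back to the corrected normal", {
  set.seed(27)
  d <- c(1, 1, 2, -2, 3, 4, -4, 5, 6, 7)  # ties in |d|
  got <- wilcoxon_signed_rank(rep(0, 10), d)
  ref <- suppressWarnings(wilcox.test(d, correct = TRUE))
  expect_equal(got$method, "normal")
  expect_equal(got$W, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("regional splits validate disjoint exhaustive coverage", {
  ids <- paste0("g", 1:10)
  labels <- rep(c("south", "inland"), c(3, 7))
  parts <- regional_split(ids, labels)
  expect_equal(lengths(parts)[c("south", "inland")], c(south = 3, inland = 7))
  expect_length(intersect(parts$south, parts$inland), 0)
  one <- regional_split(ids, rep("all", 10))
  expect_equal(lengths(one), c(all = 10))
  expect_error(regional_split(ids, list(a = ids[1:5], b = ids[4:10])),
               "overlap")
  expect_error(regional_split(ids, c(labels[-1], NA)), "unlabelled")
})

test_that("model comparison rows are internally consistent", {
  sc <- fixture_scaffold(10, 10)
  X <- gen_env_fields(sc$grid, sc$basis, k = 4, spatial_mix = 0.5,
                      seed = 28, n_fields = 2, names = c("x1", "x2"))
  gam <- 0.4 * sqrt(nrow(sc$grid)) * c(1, 1)
  y <- gen_richness_surface(sc$grid, X, beta = c(0.4, -0.3), gamma = gam,
                            basis = sc$basis, gamma_idx = c(2, 6), seed = 29)
  glm_fit <- fit_glm(X, y)
  esf <- stepwise_esf(X, y, sc$basis)
  rep_tab <- compare_models(list(glm = glm_fit, glm2 = glm_fit, esf = esf),
                            W = sc$W)
  expect_equal(rep_tab[rep_tab$model == "glm", -1],
               rep_tab[rep_tab$model == "glm2", -1],
               ignore_attr = TRUE)
  expect_equal(rep_tab$pct_explained,
               pct_deviance_explained(rep_tab$null_deviance,
                                      rep_tab$residual_deviance),
               tolerance = 1e-6)
  # spatially confounded data: ESF beats the GLM on AIC and fit
  expect_lt(rep_tab$aic[rep_tab$model == "esf"],
            rep_tab$aic[rep_tab$model == "glm"])
  expect_gt(rep_tab$pct_explained[rep_tab$model == "esf"],
            rep_tab$pct_explained[rep_tab$model == "glm"])
  expect_named(attr(rep_tab, "vif"), c("glm", "glm2", "esf"))
})
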