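test_that("closed-form Poisson MLEs are recovered", {
  f <- fit_glm(NULL, c(1, 2, 3))
  expect_equal(unname(f$coefficients), log(2), tolerance = 1e-10)
  # two groups with means 2 and 6: slope log(3)
  x <- matrix(rep(c(0, 1), each = 4), ncol = 1)
  y <- c(1, 3, 2, 2, 5, 7, 6, 6)
  f2 <- fit_glm(x, y)
  expect_equal(unname(f2$coefficients), c(log(2), log(3)), tolerance = 1e-8)
})

test_that("IRLS agrees with an independent direct optimizer", {
  set.seed(11)
  for (case in 1:5) {
    X <- matrix(rnorm(50 * 3), 50)
    y <- rpois(50, exp(0.8 + X %*% c(0.4, -0.3, 0.2)))
    f <- fit_glm(X, y)
    nll <- function(b) {
      eta <- b[1] + X %*% b[-1]
      sum(exp(eta)) - sum(y * eta)
    }
    gr <- function(b) {
      mu <- exp(b[1] + X %*% b[-1])
      c(sum(mu - y), crossprod(X, mu - y))
    }
    o <- optim(rep(0, 4), nll, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
    expect_lt(max(abs(f$coefficients - o$par) / pmax(abs(o$par), 1e-6)), 1e-6)
  }
})

test_that("real-valued outcomes are accepted and match stats::glm", {
  set.seed(12)
  X <- matrix(rnorm(40 * 2), 40, dimnames = list(NULL, c("a", "b")))
  y <- rpois(40, exp(3 + 0.2 * X[, 1])) + runif(40)
  f <- fit_glm(X, y)
  ref <- suppressWarnings(glm(y ~ X, family = poisson()))
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(f$deviance, deviance(ref), tolerance = 1e-8)
  expect_equal(f$null_deviance, ref$null.deviance, tolerance = 1e-8)
  expect_equal(unname(f$standard_errors),
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-5)
})

test_that("fit_glm rejects degenerate inputs", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  expect_error(fit_glm(X, c(1, 2, 3, 4)), "rank deficient")
  expect_error(fit_glm(NULL, c(-1, 2)), "non-negative")
})

test_that("deviance follows the saturated-model formula with the 0 convention", {
  expect_equal(poisson_deviance(c(3, 1), c(3, 1)), 0)
  expect_equal(poisson_deviance(2, 1), 2 * (2 * log(2) - 1), tolerance = 1e-12)
  expect_equal(poisson_deviance(0, 1), 2)
  expect_error(poisson_deviance(1, 0), "positive")
  # identity with twice the saturated log-likelihood gap (integer y)
  set.seed(13)
  y <- rpois(30, 5); u <- runif(30, 2, 8)
  gap <- 2 * (sum(dpois(y, y, log = TRUE)) - sum(dpois(y, u, log = TRUE)))
  expect_equal(poisson_deviance(y, u), gap, tolerance = 1e-8)
})

test_that("null deviance equals the deviance at the mean fit", {
  set.seed(14)
  y <- rpois(25, 7)
  f <- fit_glm(matrix(rnorm(25)), y)
  expect_equal(f$null_deviance, poisson_deviance(y, rep(mean(y), 25)),
               tolerance = 1e-10)
})

test_that("percent deviance explained reconciles null and residual", {
  expect_equal(pct_deviance_explained(100, 100), 0)
  expect_equal(pct_deviance_explained(200, 50), 75)
  expect_error(pct_deviance_explained(0, 1), "positive")
})

test_that("AIC uses the full likelihood and nesting identities hold", {
  # saturated two-point fit, checked against the log-pmf sum
  y <- c(1, 1)
  f <- fit_glm(NULL, y)
  expect_equal(f$aic, -2 * sum(dpois(y, 1, log = TRUE)) + 2, tolerance = 1e-10)
  set.seed(15)
  X <- matrix(rnorm(60 * 2), 60, dimnames = list(NULL, c("a", "b")))
  y <- rpois(60, exp(2 + 0.3 * X[, 1]))
  f1 <- fit_glm(X[, 1, drop = FALSE], y)
  f2 <- fit_glm(X, y)
  # nested AIC difference = deviance difference + 2 * parameter difference
  expect_equal(f2$aic - f1$aic, (f2$deviance - f1$deviance) + 2,
               tolerance = 1e-8)
  # a nuisance column never increases deviance; AIC rises by <= 2 - drop
  expect_lte(f2$deviance, f1$deviance + 1e-8)
  expect_lte(f2$aic - f1$aic, 2 + 1e-8)
})

test_that("fitted quantities are invariant to predictor standardization", {
  set.seed(16)
  X <- matrix(rnorm(50 * 2, mean = 3, sd = 4), 50)
  y <- rpois(50, exp(1 + 0.1 * X[, 1] - 0.05 * X[, 2]))
  f_raw <- fit_glm(X, y)
  f_std <- fit_glm(scale(X), y)
  expect_equal(f_raw$fitted, f_std$fitted, tolerance = 1e-8)
  expect_equal(f_raw$deviance, f_std$deviance, tolerance = 1e-8)
  expect_equal(f_raw$aic, f_std$aic, tolerance = 1e-8)
  expect_false(isTRUE(all.equal(f_raw$coefficients, f_std$coefficients)))
})

test_that("scaled residuals have unit SD and localize a lone misfit", {
  set.seed(17)
  y <- rpois(30, 10)
  f <- fit_glm(matrix(rnorm(30)), y)
  expect_equal(sd(std_pearson_residuals(f)), 1, tolerance = 1e-12)
  # textbook Pearson residuals on a hand-computed 3-point example
  fake <- structure(list(fitted = c(4, 9, 16), y = c(6, 6, 20)),
                    class = "glm_fit")
  expect_equal(std_pearson_residuals(fake, type = "pearson"),
               c(2 / 2, -3 / 3, 4 / 4))
})

test_that("VIFs match the closed form and flag collinearity", {
  set.seed(18)
  # mutually orthogonal, mean-zero columns
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(40 * 3), 40))))[, 2:4]
  colnames(Q) <- c("a", "b", "c")
  expect_equal(unname(vif(Q)), rep(1, 3), tolerance = 1e-10)
  # exact correlation 0.8: VIF = 1/(1 - 0.64)
  z1 <- rnorm(200); z2 <- rnorm(200)
  e1 <- (z1 - mean(z1)) / sd(z1)
  r <- resid(lm(z2 ~ e1)); e2 <- r / sd(r) * sqrt(1 - 0.64)
  x2 <- 0.8 * e1 + e2 * sd(e1)
  X <- cbind(a = e1, b = 0.8 * e1 + sqrt(1 - 0.64) * scale(resid(lm(z2 ~ e1)))[, 1])
  expect_equal(unname(vif(X)), rep(1 / (1 - 0.64), 2), tolerance = 1e-8)
  expect_warning(v <- vif(cbind(a = z1, b = z1)), "collinearity")
  expect_true(all(is.infinite(v)))
})
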