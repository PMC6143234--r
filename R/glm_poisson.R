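#' Poisson log-link GLM by iteratively reweighted least squares
#'
#' Maximizes the Poisson log-likelihood with a logarithmic link. The
#' outcome may be real-valued and non-negative (e.g. a bootstrap mean
#' richness): the likelihood uses `lgamma(y + 1)`, which reduces to the
#' exact Poisson case for integer counts.
#'
#' @param X design matrix or data frame of predictors (no intercept
#'   column; one is added unless `intercept = FALSE`).
#' @param y non-negative outcome vector.
#' @param intercept add an intercept column (default `TRUE`).
#' @param start optional starting coefficient vector (length
#'   `ncol(design)`), used to warm-start IRLS.
#' @param tol relative deviance-change convergence tolerance.
#' @param maxit maximum IRLS iterations.
#' @return An object of class `glm_fit`: list with `coefficients`,
#'   `standard_errors`, `fitted` (positive means), `linear_predictor`,
#'   `null_deviance`, `deviance`, `loglik`, `aic`, `n_params`,
#'   `converged`, `iter`, `y`, and `design_labels`.
#' @examples
#' fit <- fit_glm(matrix(rnorm(60), 30), rpois(30, 5))
#' fit$coefficients
#' @export
fit_glm <- function(X, y, intercept = TRUE, start = NULL,
                    tol = 1e-10, maxit = 100L) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(X)) X <- matrix(numeric(0), nrow = length(y), ncol = 0)
  if (is.vector(X)) X <- matrix(X, ncol = 1L)
  X <- assert_finite_matrix(X)
  y <- as.numeric(y)
  if (any(!is.finite(y)) || any(y < 0)) stop("y must be finite and non-negative")
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)")
  labs <- colnames(X) %||% if (ncol(X)) paste0("x", seq_len(ncol(X))) else character(0)
  Xd <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  if (intercept) colnames(Xd) <- c("(Intercept)", labs) else colnames(Xd) <- labs
  if (ncol(Xd) == 0L) stop("empty design: need an intercept or predictors")
  if (qr(Xd)$rank < ncol(Xd)) stop("design matrix is rank deficient")

  core <- irls_poisson(Xd, y, start = start, tol = tol, maxit = maxit)

  # expected (= observed for canonical link) information
  W <- core$mu
  XtWX <- crossprod(Xd * sqrt(W))
  se <- sqrt(diag(solve(XtWX)))
  names(se) <- colnames(Xd)

  null_dev <- if (intercept) poisson_deviance(y, rep(mean(y), length(y))) else {
    poisson_deviance(y, rep(1, length(y)))  # no natural null without intercept
  }
  ll <- poisson_loglik(y, core$mu)
  p <- ncol(Xd)
  out <- list(
    coefficients = core$beta,
    standard_errors = se,
    fitted = core$mu,
    linear_predictor = core$eta,
    null_deviance = null_dev,
    deviance = core$deviance,
    loglik = ll,
    aic = -2 * ll + 2 * p,
    n_params = p,
    converged = core$converged,
    iter = core$iter,
    y = y,
    intercept = intercept,
    design = Xd,
    design_labels = colnames(Xd)
  )
  class(out) <- "glm_fit"
  out
}

# Minimal IRLS core on a prebuilt design (used heavily by stepwise ESF).
irls_poisson <- function(Xd, y, start = NULL, tol = 1e-10, maxit = 100L) {
  n <- length(y)
  p <- ncol(Xd)
  if (is.null(start)) {
    mu <- y + 0.1
    eta <- log(mu)
  } else {
    beta <- start
    eta <- drop(Xd %*% beta)
    eta <- pmin(eta, 30)
    mu <- exp(eta)
  }
  dev <- poisson_deviance(y, mu)
  converged <- FALSE
  beta <- start %||% rep(0, p)
  for (it in seq_len(maxit)) {
    w <- mu
    z <- eta + (y - mu) / mu
    fit <- .lm.fit(Xd * sqrt(w), z * sqrt(w))
    beta_new <- fit$coefficients
    eta_new <- drop(Xd %*% beta_new)
    # step-halving guard against overflow/divergence of the log link only
    step <- 1
    repeat {
      eta_try <- eta + step * (eta_new - eta)
      if (max(eta_try) < 300) {
        dev_try <- poisson_deviance(y, exp(eta_try))
        if (is.finite(dev_try)) break
      }
      step <- step / 2
      if (step < 1e-10) stop("IRLS diverged")
    }
    eta <- eta_try
    mu <- exp(eta)
    beta <- beta + step * (beta_new - beta)
    dev_new <- dev_try
    if (abs(dev - dev_new) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  if (!converged) warning("IRLS did not converge in ", maxit, " iterations")
  names(beta) <- colnames(Xd)
  list(beta = beta, mu = mu, eta = eta, deviance = dev,
       converged = converged, iter = it)
}

#' Poisson deviance against the saturated model
#'
#' `2 * sum(y*log(y/u) - (y - u))` with the convention that the
#' `y*log(y/u)` term is zero when `y = 0`.
#'
#' @param y observed non-negative values.
#' @param u fitted means, strictly positive.
#' @return Scalar deviance.
#' @export
poisson_deviance <- function(y, u) {
  if (any(u <= 0)) stop("fitted means must be strictly positive")
  if (any(y < 0)) stop("y must be non-negative")
  r <- ifelse(y > 0, y * log(y / u), 0) - (y - u)
  2 * sum(r)
}

poisson_loglik <- function(y, mu) {
  sum(y * log(mu) - mu - lgamma(y + 1))
}

#' Percent deviance explained
#'
#' `(1 - residual/null) * 100`, the share of the null deviance removed by
#' the fitted model.
#'
#' @param null_dev null (intercept-only) deviance, positive.
#' @param resid_dev residual deviance, non-negative.
#' @return Percentage in (-Inf, 100].
#' @examples
#' pct_deviance_explained(6113, 2275)  # 62.78
#' @export
pct_deviance_explained <- function(null_dev, resid_dev) {
  if (any(null_dev <= 0)) stop("null deviance must be positive")
  if (any(resid_dev < 0)) stop("residual deviance must be non-negative")
  (1 - resid_dev / null_dev) * 100
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("Poisson GLM (log link), n =", length(x$y),
      ", params =", x$n_params, "\n")
  cat(sprintf("  deviance %.4g (null %.4g, %.2f%% explained), AIC %.4g\n",
              x$deviance, x$null_deviance,
              pct_deviance_explained(x$null_deviance, x$deviance), x$aic))
  ct <- cbind(Estimate = x$coefficients, `Std.Error` = x$standard_errors)
  print(round(ct, 5))
  invisible(x)
}

#' Standardized residuals of a Poisson fit
#'
#' The default (`type = "scaled"`) divides each raw residual by the
#' sample standard deviation of all raw residuals, so the output has SD
#' exactly 1. `type = "pearson"` gives the textbook Pearson residual
#' `(y - u)/sqrt(u)`.
#'
#' @param fit a `glm_fit` (or `esf_fit`) object.
#' @param y outcome; defaults to the outcome stored in the fit.
#' @param type `"scaled"` (raw residual / SD of raw residuals) or
#'   `"pearson"`.
#' @return Numeric residual vector.
#' @export
std_pearson_residuals <- function(fit, y = NULL, type = c("scaled", "pearson")) {
  type <- match.arg(type)
  if (inherits(fit, "esf_fit")) fit <- fit$fit
  y <- y %||% fit$y
  raw <- y - fit$fitted
  if (type == "pearson") return(raw / sqrt(fit$fitted))
  s <- stats::sd(raw)
  if (s == 0) stop("all residuals identical; cannot scale")
  raw / s
}

#' Variance inflation factors
#'
#' `VIF_j = 1/(1 - R^2_j)` where `R^2_j` comes from an OLS regression of
#' column `j` on all remaining columns of the supplied design (plus an
#' intercept). For spatial-filter fits pass the design including selected
#' eigenvectors and name the predictors of interest in `report_for`.
#'
#' @param X design matrix (no intercept column).
#' @param report_for column names to report; default all columns.
#' @return Named vector of VIFs; perfectly collinear columns give `Inf`
#'   with a warning.
#' @export
vif <- function(X, report_for = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  X <- assert_finite_matrix(X)
  if (ncol(X) < 2) stop("need at least two columns to compute VIFs")
  cols <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  colnames(X) <- cols
  report_for <- report_for %||% cols
  if (!all(report_for %in% cols)) stop("report_for names not in design")
  out <- vapply(report_for, function(j) {
    yj <- X[, j]
    Z <- cbind(1, X[, setdiff(cols, j), drop = FALSE])
    f <- stats::lm.fit(Z, yj)
    rss <- sum(f$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(!is.finite(out))) warning("perfect collinearity: infinite VIF")
  out
}
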