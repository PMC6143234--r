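#' Poisson LASSO regularization path
#'
#' Minimizes `(1/n) * Poisson negative log-likelihood + lambda * sum|b_j|`
#' (log link, unpenalized intercept) by cyclic coordinate descent on the
#' IRLS quadratic approximation, with warm starts along a decreasing
#' log-spaced lambda grid. `lambda_max`, the smallest penalty at which
#' every slope is zero, is computed from the score at the null model:
#' `max_j |(1/n) sum_i x_ij (y_i - ybar)|`.
#'
#' Columns of `X` must already be standardized (mean 0, sample SD 1);
#' this is verified, not silently redone, so that penalized coefficients
#' are comparable across variables.
#'
#' @param X standardized predictor matrix with column names.
#' @param y non-negative outcome.
#' @param n_lambdas grid size (default 100).
#' @param lambda_min_ratio `lambda_min/lambda_max` (default 1e-4).
#' @param lambdas optional explicit decreasing lambda vector (overrides
#'   the grid; may include 0 for the unpenalized limit). Explicit grids
#'   are fitted in full, with no early termination.
#' @param tol coordinate-descent convergence tolerance.
#' @param kkt_tol stationarity tolerance of the penalized objective at
#'   each lambda.
#' @param dev_stop with the automatic grid, the path stops early once
#'   the fraction of null deviance explained gains less than this
#'   between consecutive lambdas, or exceeds 0.999 — the remaining
#'   segment is numerically ill-conditioned and never selected by
#'   cross-validation (set to 0 to disable).
#' @return `lasso_path`: list with `lambdas`, `beta` (p x n_lambda
#'   matrix), `intercepts`, and bookkeeping fields.
#' @export
fit_lasso_path <- function(X, y, n_lambdas = 100L, lambda_min_ratio = 1e-4,
                           lambdas = NULL, tol = 1e-8, kkt_tol = 1e-7,
                           dev_stop = 1e-5) {
  if (is.data.frame(X)) X <- as.matrix(X)
  X <- assert_finite_matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("X and y sizes differ")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  mns <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (max(abs(mns)) > 1e-6 || max(abs(sds - 1)) > 1e-6)
    stop("X must be standardized (mean 0, SD 1) before the LASSO")

  ybar <- mean(y)
  # minute inflation so the soft threshold kills every slope exactly at
  # the grid's first point despite floating-point summation order
  lambda_max <- max(abs(crossprod(X, y - ybar)) / n) * (1 + 1e-12)
  auto_grid <- is.null(lambdas)
  if (auto_grid) {
    lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                       length.out = n_lambdas))
  } else {
    lambdas <- sort(as.numeric(lambdas), decreasing = TRUE)
  }

  beta <- rep(0, p)
  b0 <- log(ybar)
  B <- matrix(NA_real_, p, length(lambdas), dimnames = list(colnames(X), NULL))
  b0s <- numeric(length(lambdas))
  null_dev <- poisson_deviance(y, rep(ybar, n))
  ratio_prev <- 0
  n_fit <- length(lambdas)
  for (l in seq_along(lambdas)) {
    sol <- cd_poisson_lasso(X, y, lambdas[l], beta, b0, tol = tol,
                            kkt_tol = kkt_tol)
    beta <- sol$beta; b0 <- sol$b0
    if (auto_grid && l > 1 && sol$viol > max(10 * kkt_tol, 5e-7)) {
      # the solver cannot certify stationarity here (ill-conditioned or
      # quasi-separated tail); everything beyond is unreliable
      warning(sprintf(
        "path truncated at lambda = %.3g (%d of %d): coordinate descent no longer converges",
        lambdas[l], l, length(lambdas)))
      n_fit <- l - 1L
      break
    }
    B[, l] <- beta
    b0s[l] <- b0
    if (auto_grid && dev_stop > 0) {
      mu <- exp(pmin(b0 + drop(X %*% beta), 30))
      ratio <- 1 - poisson_deviance(y, mu) / null_dev
      if (l > 1 && (ratio - ratio_prev < dev_stop || ratio > 0.999)) {
        n_fit <- l
        break
      }
      ratio_prev <- ratio
    }
  }
  out <- list(lambdas = lambdas[seq_len(n_fit)],
              beta = B[, seq_len(n_fit), drop = FALSE],
              intercepts = b0s[seq_len(n_fit)],
              lambda_max = lambda_max, n = n, var_names = colnames(X))
  class(out) <- "lasso_path"
  out
}

# One penalized fit at a fixed lambda: outer IRLS loop, inner cyclic
# coordinate descent with soft thresholding on the weighted quadratic.
# The quadratic subproblem is solved through its Gram matrix
# (covariance updates), so a coordinate sweep costs O(p^2) rather than
# O(n p); convergence is judged on the stationarity (KKT) conditions of
# the true penalized Poisson objective, not the working approximation.
cd_poisson_lasso <- function(X, y, lambda, beta, b0, tol = 1e-9,
                             kkt_tol = 1e-7, max_outer = 30L,
                             max_inner = 150L) {
  n <- length(y)
  p <- length(beta)
  eta <- pmin(b0 + drop(X %*% beta), 30)
  obj_old <- Inf
  for (outer in seq_len(max_outer)) {
    mu <- exp(eta)
    w <- mu
    z <- eta + (y - mu) / mu
    wX <- X * w
    G <- crossprod(X, wX) / n          # p x p weighted Gram
    gx <- colSums(wX) / n              # X'W1/n (intercept cross terms)
    q <- drop(crossprod(X, w * z)) / n
    q0 <- sum(w * z) / n
    w0 <- sum(w) / n
    diagG <- diag(G)
    inner <- 0L
    repeat {
      delta <- 0
      for (j in seq_len(p)) {
        rho <- q[j] - gx[j] * b0 - sum(G[, j] * beta) + diagG[j] * beta[j]
        bj <- soft_threshold(rho, lambda) / diagG[j]
        if (bj != beta[j]) {
          delta <- max(delta, abs(bj - beta[j]) * sqrt(diagG[j]))
          beta[j] <- bj
        }
      }
      b0_new <- (q0 - sum(gx * beta)) / w0
      delta <- max(delta, abs(b0_new - b0) * sqrt(w0))
      b0 <- b0_new
      inner <- inner + 1L
      if (delta < tol || inner >= max_inner) break
    }
    eta <- pmin(b0 + drop(X %*% beta), 30)
    mu <- exp(eta)
    obj <- sum(mu - y * eta) / n + lambda * sum(abs(beta))
    g <- drop(crossprod(X, mu - y)) / n
    active <- beta != 0
    viol <- max(abs(sum(mu - y)) / n,
                if (any(active)) max(abs(g[active] + lambda * sign(beta[active]))) else 0,
                if (any(!active)) max(pmax(abs(g[!active]) - lambda, 0)) else 0)
    if (viol < kkt_tol) break
    if (is.finite(obj_old) && abs(obj_old - obj) < 1e-15 * (abs(obj) + 1)) break
    obj_old <- obj
  }
  list(beta = beta, b0 = b0, viol = viol)
}

soft_threshold <- function(x, t) sign(x) * max(abs(x) - t, 0)

#' Karush-Kuhn-Tucker residuals along a LASSO path
#'
#' For each lambda, returns the largest violation of the stationarity
#' conditions of the penalized objective: zero coefficients require
#' `|grad_j| <= lambda`, active ones `grad_j + lambda*sign(b_j) = 0`,
#' with `grad_j = (1/n) sum_i x_ij (mu_i - y_i)`.
#'
#' @param path a `lasso_path`.
#' @param X,y the data the path was fitted on.
#' @return Numeric vector of max violations, one per lambda.
#' @export
kkt_violation <- function(path, X, y) {
  if (is.data.frame(X)) X <- as.matrix(X)
  vapply(seq_along(path$lambdas), function(l) {
    b <- path$beta[, l]
    mu <- exp(pmin(path$intercepts[l] + drop(X %*% b), 30))
    g <- drop(crossprod(X, mu - y)) / length(y)
    lam <- path$lambdas[l]
    active <- b != 0
    v_zero <- if (any(!active)) max(pmax(abs(g[!active]) - lam, 0)) else 0
    v_act <- if (any(active)) max(abs(g[active] + lam * sign(b[active]))) else 0
    v0 <- abs(sum(mu - y) / length(y))  # unpenalized intercept score
    max(v_zero, v_act, v0)
  }, numeric(1))
}

#' Cross-validated penalty selection with the 1-SE rule
#'
#' Ten-fold (by default) cross-validation of the held-out mean Poisson
#' deviance over the path's lambda grid. Folds are a seeded uniform
#' random permutation. `lambda_min` minimizes the CV mean;
#' `lambda_1se` is the largest lambda whose CV mean is within one
#' standard error (at `lambda_min`) of the minimum. The selection is the
#' nonzero-coefficient set at the chosen lambda, ordered by decreasing
#' absolute penalized coefficient.
#'
#' @param path `lasso_path` fitted on the full data.
#' @param X,y the full data.
#' @param folds number of CV folds (default 10).
#' @param rule `"1se"` (default) or `"min"`.
#' @param seed integer seed for the fold permutation.
#' @return List with `selected` (ordered names), `coefficients`
#'   (penalized, at the chosen lambda), `intercept`, `lambda`,
#'   `lambda_min`, `lambda_1se`, `cv_mean`, `cv_se`.
#' @export
cv_select <- function(path, X, y, folds = 10L, rule = c("1se", "min"),
                      seed = 1L) {
  rule <- match.arg(rule)
  if (is.data.frame(X)) X <- as.matrix(X)
  n <- length(y)
  if (folds < 2) stop("need at least 2 folds")
  if (n < folds) stop("n < folds")
  if (length(path$lambdas) < 2) stop("need at least 2 lambdas")
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  dev_fold <- matrix(NA_real_, folds, length(path$lambdas))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    # standardize the training slice so the contract holds within folds
    Xtr <- scale(X[tr, , drop = FALSE])
    ctr <- attr(Xtr, "scaled:center"); sc <- attr(Xtr, "scaled:scale")
    if (any(sc == 0)) stop("zero-variance column within a CV fold")
    # held-out deviance curves only need a few significant digits, so the
    # fold fits run at a relaxed stationarity tolerance
    sub <- fit_lasso_path(Xtr, y[tr], lambdas = path$lambdas, tol = 1e-6,
                          kkt_tol = 1e-4)
    Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, ctr), 2, sc, "/")
    for (l in seq_along(path$lambdas)) {
      mu <- exp(pmin(sub$intercepts[l] + drop(Xte %*% sub$beta[, l]), 30))
      dev_fold[f, l] <- poisson_deviance(y[!tr], mu) / sum(!tr)
    }
  }
  cv_mean <- colMeans(dev_fold)
  cv_se <- apply(dev_fold, 2, stats::sd) / sqrt(folds)
  i_min <- which.min(cv_mean)
  lambda_min <- path$lambdas[i_min]
  thr <- cv_mean[i_min] + cv_se[i_min]
  i_1se <- min(which(cv_mean <= thr))  # lambdas are decreasing: first = largest
  lambda_1se <- path$lambdas[i_1se]
  i_sel <- if (rule == "1se") i_1se else i_min
  b <- path$beta[, i_sel]
  nz <- b[b != 0]
  ord <- order(abs(nz), decreasing = TRUE)
  list(selected = names(nz)[ord], coefficients = nz[ord],
       intercept = path$intercepts[i_sel],
       lambda = path$lambdas[i_sel], lambda_min = lambda_min,
       lambda_1se = lambda_1se, rule = rule,
       cv_mean = cv_mean, cv_se = cv_se, fold_id = fold_id)
}

#' LASSO selection on the full and reduced predictor sets
#'
#' Runs path fitting plus cross-validated selection twice: once on every
#' predictor column ("full"), and once excluding the named columns
#' (default `MFDF` and `FA`; "reduced"). Each selection is refit
#' unpenalized by [fit_glm()] on its selected columns, since the LASSO
#' is used for variable choice only, not for prediction.
#'
#' @param X standardized predictor table with named columns including
#'   the `drop_vars`.
#' @param y outcome.
#' @param drop_vars columns excluded from the reduced set (default
#'   `c("MFDF", "FA")`).
#' @param folds,rule,seed passed to [cv_select()].
#' @return List with elements `full` and `reduced`, each containing the
#'   `cv_select()` output plus `refit` (unpenalized `glm_fit`, or `NULL`
#'   for an empty selection).
#' @export
run_full_and_reduced <- function(X, y, drop_vars = c("MFDF", "FA"),
                                 folds = 10L, rule = "1se", seed = 1L) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!all(drop_vars %in% colnames(X)))
    stop("X must contain columns: ", paste(drop_vars, collapse = ", "))
  run_one <- function(Xs) {
    path <- fit_lasso_path(Xs, y)
    sel <- cv_select(path, Xs, y, folds = folds, rule = rule, seed = seed)
    refit <- if (length(sel$selected)) {
      fit_glm(Xs[, sel$selected, drop = FALSE], y)
    } else NULL
    c(sel, list(path = path, refit = refit))
  }
  list(full = run_one(X),
       reduced = run_one(X[, setdiff(colnames(X), drop_vars), drop = FALSE]))
}
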