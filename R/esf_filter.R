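#' Binary contiguity weights on a masked lattice
#'
#' Queen contiguity joins cells sharing an edge or a corner; rook joins
#' edge-sharing cells only. Masked (absent) cells simply have no row.
#'
#' @param grid a `grid_table` (or data frame with `cell_id`, `row`,
#'   `col`).
#' @param scheme `"queen"` (default) or `"rook"`.
#' @return `spatial_weights`: list with `ids`, sparse symmetric binary
#'   `W`, `scheme`, `S0` (total weight), `n_components`, `isolated`
#'   (ids of neighbourless cells).
#' @export
build_weights <- function(grid, scheme = c("queen", "rook")) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("cell_id", "row", "col") %in% names(grid)))
  n <- nrow(grid)
  key <- paste(grid$row, grid$col)
  idx <- seq_len(n)
  names(idx) <- key
  offs <- if (scheme == "queen") {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  ii <- integer(0); jj <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- idx[paste(grid$row + offs[k, 1], grid$col + offs[k, 2])]
    ok <- !is.na(nb)
    ii <- c(ii, which(ok)); jj <- c(jj, unname(nb[ok]))
  }
  if (length(ii) == 0) stop("fully disconnected lattice: no contiguity links")
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(g)
  iso <- grid$cell_id[Matrix::rowSums(W) == 0]
  if (length(iso)) warning(length(iso), " isolated cell(s) with no neighbours")
  out <- list(ids = grid$cell_id, W = W, scheme = scheme, S0 = sum(W),
              n_components = comp$no, isolated = iso)
  class(out) <- "spatial_weights"
  out
}

weights_matrix <- function(W) {
  if (inherits(W, "spatial_weights")) return(W$W)
  if (is.matrix(W) || inherits(W, "Matrix")) return(W)
  stop("W must be a spatial_weights object or a matrix")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d cells, %s contiguity, S0 = %g, %d component(s)\n",
              length(x$ids), x$scheme, x$S0, x$n_components))
  invisible(x)
}

#' Moran eigenvector basis of a spatial weight matrix
#'
#' Eigendecomposition of `M W M` with the centering projector
#' `M = I - 11'/n`. Each eigenvector's Moran's I is `(n/S0)` times its
#' eigenvalue, so high-eigenvalue vectors are smooth, large-scale map
#' patterns and negative-eigenvalue vectors are fine-grained alternating
#' ones. Eigenvalues numerically indistinguishable from zero are dropped
#' (their vectors carry no spatial pattern).
#'
#' @param W `spatial_weights` or symmetric zero-diagonal matrix.
#' @param drop_tol relative tolerance below which |eigenvalue| counts as
#'   zero (default `1e-10`).
#' @return `eigen_basis`: list with orthonormal `vectors` (n x kept),
#'   `values` (descending), `n`, `S0`.
#' @export
eigen_basis <- function(W, drop_tol = 1e-10) {
  Wm <- as.matrix(weights_matrix(W))
  if (max(abs(Wm - t(Wm))) > 1e-10) stop("weight matrix is not symmetric")
  n <- nrow(Wm)
  C <- Wm - outer(rowMeans(Wm), rep(1, n)) -
    outer(rep(1, n), colMeans(Wm)) + mean(Wm)
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  keep <- abs(e$values) > drop_tol * max(abs(e$values))
  vec <- e$vectors[, keep, drop = FALSE]
  colnames(vec) <- paste0("EV", seq_len(ncol(vec)))
  out <- list(vectors = vec, values = e$values[keep], n = n,
              S0 = if (inherits(W, "spatial_weights")) W$S0 else sum(Wm))
  class(out) <- "eigen_basis"
  out
}

#' @export
print.eigen_basis <- function(x, ...) {
  cat(sprintf("eigen_basis: %d eigenvectors on %d cells; eigenvalues [%.3f, %.3f]\n",
              ncol(x$vectors), x$n, min(x$values), max(x$values)))
  invisible(x)
}

#' Eigenvector spatial filtering by stepwise AIC
#'
#' Fits the Poisson model `log mu = X b + E_k g` where `E_k` is a subset
#' of Moran eigenvectors chosen by forward selection: each step adds the
#' candidate giving the largest AIC decrease (full IRLS refit), then a
#' backward pass drops any selected eigenvector whose coefficient
#' p-value exceeds `alpha` if dropping lowers AIC. Ties break toward the
#' lower eigenvector index. Stops when no addition lowers AIC.
#'
#' Because the candidate pool holds on the order of `n` eigenvectors, an
#' unguarded AIC comparison admits dozens of noise eigenvectors (the
#' best of `K` null chi-square statistics is far above 2). Entry is
#' therefore additionally gated on the significance of the entering
#' coefficient at a Bonferroni-adjusted level `alpha / K`
#' (`enter_rule = "bonferroni"`, default), which calibrates the
#' selection so that a model with no residual spatial signal admits no
#' eigenvectors in about `1 - alpha` of realizations.
#' `enter_rule = "aic"` disables the gate and reproduces the unguarded
#' AIC-greedy walk.
#'
#' @param X predictor matrix (standardized columns recommended), or
#'   `NULL` for an intercept-only base model.
#' @param y non-negative outcome.
#' @param basis `eigen_basis` over the same cells.
#' @param candidate_rule `"all"` (every kept eigenvector, both signs;
#'   default) or `"band"` (classical filter: eigenvalue within 25% of the
#'   extreme on its own sign side, for speed).
#' @param alpha backward-pass significance threshold (default 0.05).
#' @param max_steps cap on forward steps (default no cap).
#' @param enter_rule `"bonferroni"` (default) requires the entering
#'   eigenvector's Wald p-value to clear `alpha / K` over the `K`-strong
#'   candidate pool in addition to lowering AIC; `"aic"` admits on AIC
#'   decrease alone.
#' @param screen_top candidates are first ranked by their Rao score
#'   statistic (the quadratic approximation of the deviance drop at the
#'   current fit, computable for all candidates in one matrix product);
#'   only the top `screen_top` are refit exactly for the AIC comparison
#'   (default 15). Set to `Inf` to refit every candidate.
#' @return `esf_fit`: list with `fit` (the `glm_fit` on `[X, E_sel]`),
#'   `selected` (eigenvector indices, in selection order), `gamma`
#'   (their coefficients), `glm_base` (the predictor-only fit), and
#'   `steps_log` (data frame with one row per accepted step).
#' @export
stepwise_esf <- function(X, y, basis, candidate_rule = c("all", "band"),
                         alpha = 0.05, max_steps = Inf, screen_top = 15L,
                         enter_rule = c("bonferroni", "aic")) {
  candidate_rule <- match.arg(candidate_rule)
  enter_rule <- match.arg(enter_rule)
  if (!inherits(basis, "eigen_basis")) stop("basis must be an eigen_basis")
  if (!is.null(X)) {
    if (is.data.frame(X)) X <- as.matrix(X)
    if (is.vector(X)) X <- matrix(X, ncol = 1)
    if (nrow(X) != length(y)) stop("X and y sizes differ")
  }
  if (nrow(basis$vectors) != length(y)) stop("basis and y sizes differ")

  lam <- basis$values
  cand <- if (candidate_rule == "band") {
    pos <- which(lam > 0 & lam / max(lam) >= 0.25)
    neg <- if (min(lam) < 0) which(lam < 0 & lam / min(lam) >= 0.25) else integer(0)
    sort(c(pos, neg))
  } else {
    seq_along(lam)
  }
  if (length(cand) == 0) stop("empty candidate eigenvector set")

  base_fit <- fit_glm(X, y)
  cur <- base_fit
  selected <- integer(0)
  log_rows <- list()
  p_base <- ncol(base_fit$design)

  build_design <- function(sel) {
    E <- basis$vectors[, sel, drop = FALSE]
    colnames(E) <- paste0("EV", sel)
    if (is.null(X)) E else cbind(X, E)
  }

  step_i <- 0L
  while (step_i < max_steps) {
    remaining <- setdiff(cand, selected)
    if (length(remaining) == 0) break
    start0 <- c(cur$coefficients, 0)
    best <- list(aic = cur$aic, j = NA_integer_)
    Xd_cur <- cur$design
    if (is.finite(screen_top) && length(remaining) > screen_top) {
      # Rao score statistic of each candidate at the current fit:
      # [e'(y-mu)]^2 / (e'We - e'WX (X'WX)^-1 X'We); candidates are
      # scanned in one BLAS pass and only the leaders refit exactly.
      E <- basis$vectors[, remaining, drop = FALSE]
      w <- cur$fitted
      r <- y - w
      s <- drop(crossprod(E, r))
      WX <- Xd_cur * w
      A <- crossprod(WX, E)
      dn <- colSums(E^2 * w) - colSums(A * solve(crossprod(Xd_cur, WX), A))
      sc <- s^2 / pmax(dn, 1e-12)
      remaining <- remaining[order(sc, decreasing = TRUE)[seq_len(screen_top)]]
      remaining <- sort(remaining)  # keep the lower-index tie-break
    }
    for (j in remaining) {
      Xd_try <- cbind(Xd_cur, basis$vectors[, j])
      ft <- tryCatch(
        suppressWarnings(irls_poisson(Xd_try, y, start = start0, maxit = 50L)),
        error = function(e) NULL)
      if (is.null(ft) || !is.finite(ft$deviance)) next
      aic_try <- -2 * poisson_loglik(y, ft$mu) + 2 * ncol(Xd_try)
      # strict improvement; ties go to the lower index (first seen wins)
      if (aic_try < best$aic - 1e-9) best <- list(aic = aic_try, j = j)
    }
    if (is.na(best$j)) break
    fit_new <- fit_glm(build_design(c(selected, best$j)), y)
    if (enter_rule == "bonferroni") {
      nm <- paste0("EV", best$j)
      z_new <- fit_new$coefficients[nm] / fit_new$standard_errors[nm]
      p_new <- 2 * stats::pnorm(-abs(z_new))
      if (p_new > alpha / length(cand)) break
    }
    selected <- c(selected, best$j)
    cur <- fit_new
    step_i <- step_i + 1L
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      step = step_i, action = "add", eigenvector = best$j, aic = cur$aic)

    # backward pass: drop non-significant eigenvectors if that lowers AIC
    repeat {
      if (length(selected) == 0) break
      ev_names <- paste0("EV", selected)
      zz <- cur$coefficients[ev_names] / cur$standard_errors[ev_names]
      pvals <- 2 * stats::pnorm(-abs(zz))
      weak <- selected[pvals > alpha]
      dropped <- FALSE
      for (j in weak) {
        sel_try <- setdiff(selected, j)
        fit_try <- fit_glm(build_design(sel_try), y)
        if (fit_try$aic < cur$aic - 1e-9) {
          selected <- sel_try
          cur <- fit_try
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            step = step_i, action = "drop", eigenvector = j, aic = cur$aic)
          dropped <- TRUE
          break
        }
      }
      if (!dropped) break
    }
  }

  gamma <- if (length(selected)) cur$coefficients[paste0("EV", selected)] else numeric(0)
  out <- list(
    fit = cur,
    selected = selected,
    gamma = gamma,
    glm_base = base_fit,
    steps_log = if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(step = integer(0), action = character(0),
                 eigenvector = integer(0), aic = numeric(0)),
    alpha = alpha,
    candidate_rule = candidate_rule
  )
  class(out) <- "esf_fit"
  out
}

#' @export
print.esf_fit <- function(x, ...) {
  cat(sprintf("ESF Poisson fit: %d eigenvector(s) selected; AIC %.4g (base GLM %.4g)\n",
              length(x$selected), x$fit$aic, x$glm_base$aic))
  if (length(x$selected)) {
    cat("  eigenvectors:", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}
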