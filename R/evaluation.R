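#' Global Moran's I with z-score
#'
#' `I = (n/S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' over a binary symmetric weight matrix. The z-score uses the null
#' expectation `-1/(n-1)` and, by default, the variance under the
#' normality assumption; `assumption = "randomization"` switches to the
#' permutation-based variance formula.
#'
#' @param values numeric vector over the weight matrix's cells, not
#'   constant.
#' @param W a `spatial_weights` object (see [build_weights()]) or a
#'   symmetric zero-diagonal matrix.
#' @param assumption `"normality"` (default) or `"randomization"` for the
#'   variance of I under the null.
#' @return List with `I`, `expected`, `sd`, `z`, `p` (two-tailed normal).
#' @export
moran_i <- function(values, W, assumption = c("normality", "randomization")) {
  assumption <- match.arg(assumption)
  Wm <- weights_matrix(W)
  n <- nrow(Wm)
  x <- as.numeric(values)
  if (length(x) != n) stop("values length does not match weight matrix")
  if (any(!is.finite(x))) stop("non-finite values")
  xc <- x - mean(x)
  den <- sum(xc^2)
  if (den == 0) stop("constant vector: Moran's I undefined")
  S0 <- sum(Wm)
  num <- sum(xc * as.numeric(Wm %*% xc))
  I <- (n / S0) * num / den

  # standard S1/S2 sums
  S1 <- sum((Wm + Matrix::t(Wm))^2) / 2
  rs <- Matrix::rowSums(Wm)
  cs <- Matrix::colSums(Wm)
  S2 <- sum((rs + cs)^2)
  EI <- -1 / (n - 1)
  if (assumption == "normality") {
    VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  } else {
    b2 <- n * sum(xc^4) / (sum(xc^2)^2)
    VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  }
  z <- (I - EI) / sqrt(VI)
  list(I = I, expected = EI, sd = sqrt(VI), z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Paired Wilcoxon signed-rank test
#'
#' Differences are `predicted - observed`; zero differences are dropped;
#' absolute differences are ranked with midranks for ties. `W` is the sum
#' of ranks of positive differences. The two-tailed p-value is exact (by
#' the signed-rank distribution, equivalent to enumerating all sign
#' patterns) when `n <= 25` with no ties, and otherwise uses the normal
#' approximation with continuity and tie corrections.
#'
#' @param observed,predicted paired numeric vectors of equal length.
#' @return List with `W`, `p`, `n_used` (pairs after zero removal),
#'   `median_predicted`, and `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_signed_rank(c(0, 0, 0), c(1, -2, 3))  # W = 4, p = 0.75
#' @export
wilcoxon_signed_rank <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("unequal lengths")
  d <- as.numeric(predicted) - as.numeric(observed)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (n <= 25 && !ties) {
    m <- n * (n + 1) / 4
    p1 <- if (W > m) 1 - stats::psignrank(W - 1, n) else stats::psignrank(W, n)
    p <- min(1, 2 * p1)
    method <- "exact"
  } else {
    tab <- table(r)
    tiecor <- sum(tab^3 - tab) / 48
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tiecor)
    zraw <- W - n * (n + 1) / 4
    z <- (zraw - sign(zraw) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(W = W, p = p, n_used = n,
       median_predicted = stats::median(as.numeric(predicted)),
       method = method)
}

#' Partition grids into named regions
#'
#' Accepts either a label vector aligned with `grid_ids` or a named list
#' of grid-id sets; validates that the partition is disjoint and
#' exhaustive.
#'
#' @param grid_ids vector of grid identifiers.
#' @param region_labels label vector (same length as `grid_ids`) or named
#'   list of id vectors.
#' @return Named list of integer index vectors into `grid_ids`.
#' @export
regional_split <- function(grid_ids, region_labels) {
  if (is.list(region_labels)) {
    all_ids <- unlist(region_labels, use.names = FALSE)
    if (anyDuplicated(all_ids)) stop("regions overlap")
    if (!setequal(all_ids, grid_ids)) stop("regions must cover every grid exactly once")
    out <- lapply(region_labels, function(ids) which(grid_ids %in% ids))
  } else {
    if (length(region_labels) != length(grid_ids)) stop("label length mismatch")
    if (any(is.na(region_labels))) stop("unlabelled grids")
    out <- split(seq_along(grid_ids), region_labels)
  }
  out
}

#' Side-by-side diagnostic table for fitted richness models
#'
#' One row per model: AIC, null and residual deviance, percent deviance
#' explained, Moran's I and z-score of the scaled residuals, and number
#' of selected eigenvectors (for spatial-filter fits). VIFs for the named
#' predictors are attached as an attribute.
#'
#' @param fits named list of `glm_fit` / `esf_fit` objects on the same
#'   outcome.
#' @param W `spatial_weights` over the fitted cells.
#' @param predictors character vector of predictor names for VIF
#'   reporting; default: non-intercept, non-eigenvector design columns.
#' @return A data frame of class `evaluation_report` with one row per
#'   model and a `"vif"` attribute (named list).
#' @export
compare_models <- function(fits, W, predictors = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  y0 <- NULL
  rows <- list()
  vifs <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    base <- if (inherits(f, "esf_fit")) f$fit else f
    if (is.null(y0)) y0 <- base$y
    if (length(base$y) != length(y0) || max(abs(base$y - y0)) > 0)
      stop("all fits must share the same outcome")
    res <- std_pearson_residuals(base)
    mi <- moran_i(res, W)
    n_ev <- if (inherits(f, "esf_fit")) length(f$selected) else NA_integer_
    Xd <- base$design[, setdiff(colnames(base$design), "(Intercept)"), drop = FALSE]
    pr <- predictors %||% grep("^EV", colnames(Xd), invert = TRUE, value = TRUE)
    vifs[[nm]] <- if (length(pr) >= 1 && ncol(Xd) >= 2) vif(Xd, report_for = pr) else NULL
    rows[[nm]] <- data.frame(
      model = nm,
      aic = base$aic,
      null_deviance = base$null_deviance,
      residual_deviance = base$deviance,
      pct_explained = pct_deviance_explained(base$null_deviance, base$deviance),
      moran_i = mi$I,
      moran_z = mi$z,
      n_eigenvectors = n_ev,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "vif") <- vifs
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Model comparison\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, 3))
  print(df, row.names = FALSE)
  invisible(x)
}
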