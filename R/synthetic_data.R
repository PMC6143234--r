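#' Generate a masked lattice of grid cells
#'
#' Builds an `n_rows x n_cols` lattice of square cells and removes
#' `round(n_rows * n_cols * mask_fraction)` cells uniformly at random
#' (emulating coastline and data gaps). Cell ids are the row-major
#' positions in the full lattice, so the retained set is stable across
#' mask draws.
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param cell_size cell edge length in km (default 50).
#' @param mask_fraction proportion of cells removed, in `[0, 1)`.
#' @param seed integer seed for the mask draw.
#' @param mask optional user-supplied vector of cell ids to remove
#'   instead of the random mask.
#' @return `grid_table`: data frame with `cell_id`, `row`, `col` and
#'   attributes `cell_size`, `n_rows`, `n_cols`, `seed`.
#' @examples
#' nrow(gen_lattice(36, 36, mask_fraction = 0.048, seed = 1))  # 1234
#' @export
gen_lattice <- function(n_rows, n_cols, cell_size = 50, mask_fraction = 0,
                        seed = 1L, mask = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1, mask_fraction >= 0, mask_fraction < 1)
  n <- n_rows * n_cols
  df <- data.frame(cell_id = seq_len(n),
                   row = rep(seq_len(n_rows), each = n_cols),
                   col = rep(seq_len(n_cols), times = n_rows))
  drop_ids <- if (!is.null(mask)) {
    as.integer(mask)
  } else {
    n_drop <- round(n * mask_fraction)
    if (n_drop > 0) with_seed(seed, sample.int(n, n_drop)) else integer(0)
  }
  df <- df[!df$cell_id %in% drop_ids, , drop = FALSE]
  if (nrow(df) < 9) stop("fewer than 9 cells after masking; lattice too small")
  rownames(df) <- NULL
  attr(df, "cell_size") <- cell_size
  attr(df, "n_rows") <- n_rows
  attr(df, "n_cols") <- n_cols
  attr(df, "seed") <- seed
  class(df) <- c("grid_table", "data.frame")
  df
}

#' Spatially autocorrelated standardized environmental fields
#'
#' Each field is `spatial_mix` times a random combination of the first
#' `k` high-eigenvalue Moran eigenvectors plus `1 - spatial_mix` times
#' white noise (both components pre-standardized), finally standardized
#' to mean 0 and sample SD 1. `spatial_mix = 0` gives pure noise;
#' `spatial_mix = 1` with `k = 1` reproduces eigenvector 1 up to sign
#' and scale.
#'
#' @param grid `grid_table` the basis was computed on.
#' @param basis `eigen_basis` over the same cells.
#' @param k number of leading eigenvectors in the spatial component.
#' @param spatial_mix proportion in `[0, 1]`, recycled over fields.
#' @param seed integer seed.
#' @param n_fields number of fields (columns) to generate.
#' @param names optional column names.
#' @return Numeric matrix, `nrow(grid)` x `n_fields`, each column
#'   standardized.
#' @export
gen_env_fields <- function(grid, basis, k, spatial_mix, seed = 1L,
                           n_fields = 1L, names = NULL) {
  n <- nrow(grid)
  if (nrow(basis$vectors) != n) stop("basis does not match grid")
  if (k > ncol(basis$vectors)) stop("k exceeds the basis size")
  if (any(spatial_mix < 0 | spatial_mix > 1)) stop("spatial_mix must be in [0, 1]")
  mix <- rep_len(spatial_mix, n_fields)
  std1 <- function(v) (v - mean(v)) / stats::sd(v)
  out <- with_seed(seed, {
    sapply(seq_len(n_fields), function(f) {
      sp <- if (k > 0 && mix[f] > 0) {
        std1(drop(basis$vectors[, seq_len(k), drop = FALSE] %*% stats::rnorm(k)))
      } else rep(0, n)
      wn <- std1(stats::rnorm(n))
      std1(mix[f] * sp + (1 - mix[f]) * wn)
    })
  })
  out <- matrix(out, nrow = n)
  colnames(out) <- names %||% paste0("V", seq_len(n_fields))
  out
}

#' Poisson richness surface from a linear predictor
#'
#' Direct generator for the spatial-filter regression model:
#' `count_i ~ Poisson(exp(b0 + X_i b + E_i g))`, with `E` the Moran
#' eigenvectors named by `gamma_idx`. Used for parameter- and
#' signal-recovery testing of the model fitters.
#'
#' @param grid `grid_table`.
#' @param X predictor matrix (or `NULL`).
#' @param beta slope vector for `X`.
#' @param gamma eigenvector effect sizes.
#' @param basis `eigen_basis`; required when `gamma` is non-empty.
#' @param gamma_idx eigenvector indices carrying `gamma` (default
#'   `seq_along(gamma)`).
#' @param beta0 intercept on the log scale (default `log(36)`, a typical
#'   mid-thirties mean richness).
#' @param seed integer seed.
#' @return Integer vector of counts, one per cell.
#' @export
gen_richness_surface <- function(grid, X = NULL, beta = numeric(0),
                                 gamma = numeric(0), basis = NULL,
                                 gamma_idx = seq_along(gamma),
                                 beta0 = log(36), seed = 1L) {
  n <- nrow(grid)
  eta <- rep(beta0, n)
  if (length(beta)) {
    X <- as.matrix(X)
    if (ncol(X) != length(beta)) stop("beta does not match X")
    eta <- eta + drop(X %*% beta)
  }
  if (length(gamma)) {
    if (is.null(basis)) stop("basis required when gamma is non-empty")
    if (length(gamma_idx) != length(gamma)) stop("gamma_idx does not match gamma")
    eta <- eta + drop(basis$vectors[, gamma_idx, drop = FALSE] %*% gamma)
  }
  if (any(exp(eta) > 1e6)) stop("linear predictor implies mean > 1e6")
  with_seed(seed, stats::rpois(n, exp(eta)))
}

#' Synthetic species pool
#'
#' Species occupancy is governed by a per-species baseline logit and a
#' shared environmental/spatial gradient: species `s` occupies a plot in
#' cell `i` with probability `plogis(b_s + l_s * t(score_i))`, where
#' `score_i = w'X_i + v'E_i` is a unit-SD combination of standardized
#' predictors and eigenvectors and `t(z) = (1 - exp(-a z))/a` is a
#' saturating transform (`a = score_skew`) that caps richness under
#' favourable conditions while letting it collapse under poor ones —
#' the left-skewed shape real gridded richness shows. The default
#' baseline (`N(-6.1, 1.6)`), loading (`N(0.4, 0.12)`) and skew
#' (`0.55`) give 31-plot grid richness spanning roughly 5-55 with a
#' high-30s centre and median above the mean for a 254-species pool.
#'
#' @param n_species pool size (default 254).
#' @param env_weights named weights `w` over predictor columns (the
#'   gradient direction); may be zero/empty.
#' @param spatial_weights weights `v` over eigenvector indices (names
#'   are indices); may be empty.
#' @param baseline_mean,baseline_sd baseline logit distribution.
#' @param loading_mean,loading_sd shared-gradient loading distribution.
#' @param score_skew saturation rate `a` of the score transform; `0`
#'   means identity (no skew).
#' @param seed integer seed.
#' @return `species_pool`: list with `species` (codes), `baseline_logit`,
#'   `loading`, `env_weights`, `spatial_weights`, `score_skew`.
#' @export
make_species_pool <- function(n_species = 254L, env_weights = numeric(0),
                              spatial_weights = numeric(0),
                              baseline_mean = -6.1, baseline_sd = 1.6,
                              loading_mean = 0.4, loading_sd = 0.12,
                              score_skew = 0.55,
                              seed = 1L) {
  if (n_species < 1) stop("empty species pool")
  pool <- with_seed(seed, list(
    species = sprintf("sp%03d", seq_len(n_species)),
    baseline_logit = stats::rnorm(n_species, baseline_mean, baseline_sd),
    loading = stats::rnorm(n_species, loading_mean, loading_sd)
  ))
  pool$env_weights <- env_weights
  pool$spatial_weights <- spatial_weights
  pool$score_skew <- score_skew
  class(pool) <- "species_pool"
  pool
}

#' Per-cell, per-species plot occupancy probabilities
#'
#' @param pool `species_pool`.
#' @param X standardized predictor matrix (columns named as in
#'   `pool$env_weights`), or `NULL`.
#' @param basis `eigen_basis`, needed when the pool has spatial weights.
#' @return Matrix `n_cells x n_species` of probabilities in `[0, 1]`.
#' @export
occupancy_probs <- function(pool, X = NULL, basis = NULL) {
  n <- if (!is.null(X)) nrow(X) else nrow(basis$vectors)
  score <- rep(0, n)
  if (length(pool$env_weights)) {
    w <- pool$env_weights
    score <- score + drop(as.matrix(X[, names(w), drop = FALSE]) %*% w)
  }
  if (length(pool$spatial_weights)) {
    v <- pool$spatial_weights
    idx <- as.integer(names(v))
    score <- score + drop(basis$vectors[, idx, drop = FALSE] %*% v)
  }
  if (stats::sd(score) > 0) score <- (score - mean(score)) / stats::sd(score)
  a <- pool$score_skew %||% 0
  if (a > 0) score <- (1 - exp(-a * score)) / a
  lin <- outer(score, pool$loading) +
    matrix(pool$baseline_logit, n, length(pool$species), byrow = TRUE)
  P <- stats::plogis(lin)
  pmin(pmax(P, 0), 1)
}

#' Plot-level species occurrence data
#'
#' Each grid cell receives an independently drawn plot count from
#' `plots_per_grid`; each plot's species set is drawn by independent
#' Bernoulli trials per species at the cell's occupancy probability
#' (no within-grid plot correlation).
#'
#' @param grid `grid_table`.
#' @param pool `species_pool`.
#' @param P occupancy probability matrix from [occupancy_probs()] (or a
#'   user matrix, `n_cells x n_species`).
#' @param plots_per_grid inclusive integer range `c(lo, hi)`, within
#'   `[1, 100]` (default `c(31, 100)`).
#' @param seed integer seed.
#' @return Data frame with `plot_id`, `grid_id`, `species`
#'   (semicolon-delimited codes; empty string for an empty plot).
#' @export
gen_plot_data <- function(grid, pool, P, plots_per_grid = c(31L, 100L),
                          seed = 1L) {
  if (length(pool$species) == 0) stop("empty species pool")
  if (plots_per_grid[1] < 1 || plots_per_grid[2] > 100)
    stop("plots_per_grid must lie within [1, 100]")
  n <- nrow(grid)
  if (nrow(P) != n) stop("P does not match grid")
  S <- length(pool$species)
  with_seed(seed, {
    rng <- seq.int(plots_per_grid[1], plots_per_grid[2])
    m <- if (length(rng) == 1L) rep.int(rng, n) else sample(rng, n, replace = TRUE)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      occ <- matrix(stats::runif(m[i] * S) < rep(P[i, ], each = m[i]), m[i], S)
      sp <- apply(occ, 1, function(z) paste(pool$species[z], collapse = ";"))
      rows[[i]] <- data.frame(
        plot_id = sprintf("p%d_%d", grid$cell_id[i], seq_len(m[i])),
        grid_id = grid$cell_id[i],
        species = sp,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Naive frost-day frequency from monthly minimum temperature
#'
#' Mean days per month with minimum temperature below 0 degrees C,
#' approximated as 30.44 times the fraction of months whose monthly
#' minimum is below zero. This is a synthetic-data helper only, not the
#' downscaled frost climatology used with real rasters.
#'
#' @param tmin 12 monthly minimum temperatures (degrees C).
#' @return Days per month, in `[0, 30.44]`.
#' @export
mfdf_naive <- function(tmin) {
  if (length(tmin) != 12) stop("need 12 monthly values")
  30.44 * mean(tmin < 0)
}

#' Synthetic fine-cell monthly climate table
#'
#' Emulates the fine-resolution climatology the predictor derivation
#' consumes: per grid cell, a handful of fine cells sharing
#' spatially autocorrelated latent fields (annual temperature level and
#' amplitude, log-precipitation level and seasonality, elevation,
#' forest and water fractions, PET/AET/AI) plus fine-scale noise, with
#' a sinusoidal annual cycle peaking in July for temperature and a
#' precipitation cycle modulated by the seasonality field.
#'
#' @param grid `grid_table`.
#' @param basis `eigen_basis` over the grid.
#' @param cells_per_grid fine cells per grid cell (default 4).
#' @param seed integer seed.
#' @return Data frame with `cell_id`, `grid_id`, `tmean1..12`,
#'   `prec1..12`, `pet`, `aet`, `ai`, `elev`, `fa`, `wa`, `mfdf`.
#' @export
gen_climate_fine <- function(grid, basis, cells_per_grid = 4L, seed = 1L) {
  n <- nrow(grid)
  k <- min(12L, ncol(basis$vectors))
  L <- gen_env_fields(grid, basis, k = k, spatial_mix = 0.85,
                      seed = derive_seed(seed, "latent"), n_fields = 8,
                      names = c("tlev", "tamp", "plev", "pseas",
                                "elev", "fa", "wa", "pet"))
  month <- 1:12
  cyc <- cos(2 * pi * (month - 7) / 12)  # +1 in July, -1 in January
  with_seed(derive_seed(seed, "fine"), {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      m <- cells_per_grid
      tlev <- 12 + 6 * L[i, "tlev"] + stats::rnorm(m, 0, 0.5)
      tamp <- 11 + 2 * L[i, "tamp"] + stats::rnorm(m, 0, 0.3)
      plev <- log(80) + 0.35 * L[i, "plev"] + stats::rnorm(m, 0, 0.05)
      pseas <- 0.45 + 0.15 * L[i, "pseas"] + stats::rnorm(m, 0, 0.03)
      Tm <- outer(tlev, rep(1, 12)) + outer(tamp, cyc) +
        matrix(stats::rnorm(m * 12, 0, 0.4), m, 12)
      Pm <- exp(outer(plev, rep(1, 12)) + outer(pmax(pseas, 0.05), -cyc)) *
        matrix(stats::rlnorm(m * 12, 0, 0.08), m, 12)
      tmin <- Tm - 5
      pet <- 900 + 180 * L[i, "pet"] + 25 * (tlev - 12) + stats::rnorm(m, 0, 30)
      aet <- pmin(pet, 0.75 * rowSums(Pm)) + stats::rnorm(m, 0, 20)
      out <- data.frame(
        cell_id = sprintf("f%d_%d", grid$cell_id[i], seq_len(m)),
        grid_id = grid$cell_id[i])
      out[paste0("tmean", 1:12)] <- as.data.frame(Tm)
      out[paste0("prec", 1:12)] <- as.data.frame(Pm)
      out$pet <- pet
      out$aet <- aet
      out$ai <- rowSums(Pm) / pmax(pet, 1)
      out$elev <- 300 + 250 * L[i, "elev"] + stats::rnorm(m, 0, 60)
      out$fa <- stats::plogis(0.4 + 0.9 * L[i, "fa"] + stats::rnorm(m, 0, 0.2))
      out$wa <- stats::plogis(-2 + 0.8 * L[i, "wa"] + stats::rnorm(m, 0, 0.2))
      out$mfdf <- apply(tmin, 1, mfdf_naive)
      rows[[i]] <- out
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
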