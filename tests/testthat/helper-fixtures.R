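# Shared fixtures: small lattices and their spatial scaffolding, built once
# per test run.

fixture_scaffold <- local({
  cache <- list()
  function(n_rows, n_cols, scheme = "queen", mask_fraction = 0, seed = 1) {
    key <- paste(n_rows, n_cols, scheme, mask_fraction, seed)
    if (is.null(cache[[key]])) {
      grid <- gen_lattice(n_rows, n_cols, mask_fraction = mask_fraction,
                          seed = seed)
      W <- build_weights(grid, scheme = scheme)
      cache[[key]] <<- list(grid = grid, W = W, basis = eigen_basis(W))
    }
    cache[[key]]
  }
})

# Exact expected bootstrap richness by exhaustive subset enumeration.
enumerate_expected_tsr <- function(species_sets, m) {
  idx <- utils::combn(length(species_sets), m)
  mean(apply(idx, 2, function(i)
    length(unique(unlist(species_sets[i], use.names = FALSE)))))
}

# Brute-force Moran's I by the expanded double sum.
moran_bruteforce <- function(x, Wm) {
  Wm <- as.matrix(Wm)
  n <- length(x)
  xc <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + Wm[i, j] * xc[i] * xc[j]
  }
  (n / sum(Wm)) * num / sum(xc^2)
}

# Exact signed-rank test by enumerating all 2^n sign patterns (tie-free d).
wilcoxon_enumerate <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  Ws <- apply(grid, 1, function(pos) sum(r[as.logical(pos)]))
  m <- n * (n + 1) / 4
  p <- if (W_obs > m) mean(Ws >= W_obs) else mean(Ws <= W_obs)
  list(W = W_obs, p = min(1, 2 * p))
}
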