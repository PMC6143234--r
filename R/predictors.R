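#' Climatic seasonality of a monthly series
#'
#' Precipitation seasonality is the coefficient of variation of the 12
#' monthly totals (sample SD / mean, unitless even though often quoted
#' in mm); temperature seasonality is the sample SD of the 12 monthly
#' means (degrees C).
#'
#' @param x 12 monthly values (Jan..Dec).
#' @param kind `"precipitation"` (CV) or `"temperature"` (SD).
#' @return Scalar seasonality.
#' @examples
#' seasonality(rep(c(0, 200), each = 6), "precipitation")  # 1.04447
#' @export
seasonality <- function(x, kind = c("precipitation", "temperature")) {
  kind <- match.arg(kind)
  if (length(x) != 12 || any(!is.finite(x))) stop("need 12 finite monthly values")
  s <- stats::sd(x)
  if (kind == "temperature") return(s)
  m <- mean(x)
  if (m <= 0) stop("mean monthly precipitation must be positive for PSN")
  s / m
}

# fixed climatological quarters, DJF wrapping within the single year
.quarters <- list(DJF = c(12L, 1L, 2L), MAM = 3:5, JJA = 6:8, SON = 9:11)

#' Fixed-quarter climate statistics
#'
#' Quarters are the fixed three-month groupings DJF, MAM, JJA, SON, with
#' December joined to the January/February of the same climatological
#' year. Modes: `"warmest"` / `"coldest"` return the max / min quarterly
#' mean of `series`; `"driest"` locates the quarter with the lowest
#' total of `series` (precipitation) and returns its monthly mean
#' (`driest_stat = "mean"`, default) or total.
#'
#' @param series 12 monthly values driving the statistic.
#' @param mode `"warmest"`, `"coldest"`, or `"driest"`.
#' @param driest_stat `"mean"` or `"total"` for the driest quarter.
#' @return Scalar quarterly statistic.
#' @export
quarter_stat <- function(series, mode = c("warmest", "coldest", "driest"),
                         driest_stat = c("mean", "total")) {
  mode <- match.arg(mode)
  driest_stat <- match.arg(driest_stat)
  if (length(series) != 12 || any(!is.finite(series)))
    stop("need 12 finite monthly values")
  qmeans <- vapply(.quarters, function(m) mean(series[m]), numeric(1))
  qtotals <- vapply(.quarters, function(m) sum(series[m]), numeric(1))
  switch(mode,
    warmest = max(qmeans),
    coldest = min(qmeans),
    driest = {
      q <- which.min(qtotals)
      unname(if (driest_stat == "mean") qmeans[q] else qtotals[q])
    })
}

#' Energy-water dynamic predictor
#'
#' The quadratic energy-water balance `PET - PET^2 + MAP`.
#'
#' @param pet potential evapotranspiration (mm).
#' @param map_ mean annual precipitation (mm).
#' @return `pet - pet^2 + map_`.
#' @export
energy_water <- function(pet, map_) {
  stopifnot(is.finite(pet), is.finite(map_))
  pet - pet^2 + map_
}

#' Aggregate fine-cell values to a grid mean
#'
#' NA and sentinel-coded values are always removed; an optional robust
#' rule also drops values more than `mad_k` MADs from the median before
#' averaging.
#'
#' @param x fine-resolution values within one grid cell.
#' @param outlier_rule `"none"` (default: NA removal only) or `"mad"`.
#' @param mad_k MAD multiplier for the robust rule (default 3).
#' @param sentinel values treated as missing (default none).
#' @return Mean of the retained values; error if none remain.
#' @export
aggregate_mean <- function(x, outlier_rule = c("none", "mad"), mad_k = 3,
                           sentinel = NULL) {
  outlier_rule <- match.arg(outlier_rule)
  x <- x[!is.na(x)]
  if (!is.null(sentinel)) x <- x[!x %in% sentinel]
  if (outlier_rule == "mad" && length(x) > 2) {
    m <- stats::median(x)
    s <- stats::mad(x)
    if (s > 0) x <- x[abs(x - m) <= mad_k * s]
  }
  if (length(x) == 0) stop("no values left after outlier/NA removal")
  mean(x)
}

#' Aggregate fine-cell values to a grid range
#'
#' Difference between the absolute maximum and minimum finite values.
#'
#' @param x fine-resolution values within one grid cell.
#' @return `max(x) - min(x)`.
#' @export
aggregate_range <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no finite values")
  max(x) - min(x)
}

#' Standardize predictor columns to mean 0, SD 1
#'
#' Column-wise `(x - mean)/SD` with the sample SD. The means and SDs are
#' stored in the `"scaling"` attribute for back-transformation; applying
#' the function twice is idempotent.
#'
#' @param table data frame or matrix of predictors; non-numeric columns
#'   (e.g. `grid_id`) are passed through untouched.
#' @param cols columns to standardize; default all numeric columns
#'   except `grid_id`.
#' @return The table with standardized columns, a `"scaling"` attribute
#'   (data frame of column, mean, sd) and `"standardized" = TRUE`.
#' @export
standardize_predictors <- function(table, cols = NULL) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  cols <- cols %||% setdiff(names(df)[num], "grid_id")
  sc <- data.frame(column = cols, mean = NA_real_, sd = NA_real_)
  for (i in seq_along(cols)) {
    v <- df[[cols[i]]]
    m <- mean(v); s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("zero-variance column: ", cols[i])
    df[[cols[i]]] <- (v - m) / s
    sc$mean[i] <- m; sc$sd[i] <- s
  }
  attr(df, "scaling") <- sc
  attr(df, "standardized") <- TRUE
  df
}

#' Derive the standard predictor table from fine-cell climate data
#'
#' Computes, per fine cell, the bioclimatic summaries (MAT, ART, TSN,
#' PSN, MAP, MTWQ, MTCQ, MPDQ, energy-water EW) from 12 monthly mean
#' temperatures and precipitation totals, then aggregates to the
#' analysis grid: means for level variables, max-minus-min ranges for
#' RA (elevation), RMAP and RMAT. PET, AET, AI, FA, WA and MFDF are
#' consumed as supplied fine-cell fields and aggregated as means.
#'
#' @param fine data frame with `cell_id`, `grid_id`, monthly columns
#'   `tmean1..tmean12` and `prec1..prec12`, plus fields `pet`, `aet`,
#'   `ai`, `elev`, `fa`, `wa`, `mfdf`.
#' @param outlier_rule passed to [aggregate_mean()].
#' @return Data frame with one row per grid and the 18 predictor
#'   columns `FA, WA, ART, PSN, TSN, MAT, MTWQ, PET, EW, RA, RMAP,
#'   RMAT, MFDF, MPDQ, MTCQ, AET, AI, MAP` (unstandardized).
#' @export
derive_predictors <- function(fine, outlier_rule = "none") {
  tcols <- paste0("tmean", 1:12)
  pcols <- paste0("prec", 1:12)
  need <- c("cell_id", "grid_id", tcols, pcols,
            "pet", "aet", "ai", "elev", "fa", "wa", "mfdf")
  miss <- setdiff(need, names(fine))
  if (length(miss)) stop("missing fine-cell columns: ", paste(miss, collapse = ", "))
  Tm <- as.matrix(fine[, tcols])
  Pm <- as.matrix(fine[, pcols])
  cellstats <- data.frame(
    grid_id = fine$grid_id,
    mat = rowMeans(Tm),
    art = apply(Tm, 1, function(v) max(v) - min(v)),
    tsn = apply(Tm, 1, stats::sd),
    psn = apply(Pm, 1, seasonality, kind = "precipitation"),
    map = rowSums(Pm),
    mtwq = apply(Tm, 1, quarter_stat, mode = "warmest"),
    mtcq = apply(Tm, 1, quarter_stat, mode = "coldest"),
    mpdq = apply(Pm, 1, quarter_stat, mode = "driest"),
    pet = fine$pet, aet = fine$aet, ai = fine$ai,
    elev = fine$elev, fa = fine$fa, wa = fine$wa, mfdf = fine$mfdf
  )
  cellstats$ew <- cellstats$pet - cellstats$pet^2 + cellstats$map
  sp <- split(cellstats, cellstats$grid_id)
  agg <- lapply(sp, function(g) {
    data.frame(
      grid_id = g$grid_id[1],
      FA = aggregate_mean(g$fa, outlier_rule),
      WA = aggregate_mean(g$wa, outlier_rule),
      ART = aggregate_mean(g$art, outlier_rule),
      PSN = aggregate_mean(g$psn, outlier_rule),
      TSN = aggregate_mean(g$tsn, outlier_rule),
      MAT = aggregate_mean(g$mat, outlier_rule),
      MTWQ = aggregate_mean(g$mtwq, outlier_rule),
      PET = aggregate_mean(g$pet, outlier_rule),
      EW = aggregate_mean(g$ew, outlier_rule),
      RA = aggregate_range(g$elev),
      RMAP = aggregate_range(g$map),
      RMAT = aggregate_range(g$mat),
      MFDF = aggregate_mean(g$mfdf, outlier_rule),
      MPDQ = aggregate_mean(g$mpdq, outlier_rule),
      MTCQ = aggregate_mean(g$mtcq, outlier_rule),
      AET = aggregate_mean(g$aet, outlier_rule),
      AI = aggregate_mean(g$ai, outlier_rule),
      MAP = aggregate_mean(g$map, outlier_rule)
    )
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$grid_id), , drop = FALSE]
}
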