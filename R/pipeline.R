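#' Configuration for the end-to-end synthetic analysis
#'
#' Defaults reproduce the study conditions the package emulates: a
#' 36 x 36 lattice of 50-km cells with 4.8% masked (1234 cells), 31-100
#' plots per grid from a 254-species pool, richness bootstrapped as 31
#' plots x 1000 replicates over grids with at least 31 plots, ten-fold
#' cross-validated LASSO with the one-standard-error rule, queen
#' contiguity, and stepwise eigenvector selection. The occupancy
#' gradient loads on PSN (-), MFDF (-), MPDQ (+) and FA (+), plus three
#' low-order Moran eigenvectors, so both environmental signal and
#' spatial confounding are present.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param n_rows,n_cols,cell_size,mask_fraction lattice geometry.
#' @param n_species species-pool size.
#' @param plots_per_grid inclusive plot-count range per grid.
#' @param m_plots,B bootstrap draw size and replicate count.
#' @param min_plots grid retention threshold.
#' @param folds,rule LASSO cross-validation settings.
#' @param scheme contiguity scheme for the weights.
#' @param candidate_rule stepwise eigenvector candidate pool; the
#'   full-scale default `"band"` restricts to eigenvalues within 25% of
#'   the extremes (both signs) for tractability on 1000+ cells.
#' @param alpha backward-pass significance threshold.
#' @param cells_per_grid fine climate cells per grid cell.
#' @param env_weights,spatial_weights gradient direction of the species
#'   pool (see [make_species_pool()]).
#' @param n_region_south size of the synthetic southern coastal region
#'   used for the paired comparison (default 52 grids).
#' @return A `run_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_rows = 36L, n_cols = 36L,
                            cell_size = 50, mask_fraction = 0.048,
                            n_species = 254L,
                            plots_per_grid = c(31L, 100L),
                            m_plots = 31L, B = 1000L, min_plots = 31L,
                            folds = 10L, rule = "1se",
                            scheme = "queen", candidate_rule = "band",
                            alpha = 0.05, cells_per_grid = 4L,
                            env_weights = c(PSN = -0.5, MFDF = -0.45,
                                            MPDQ = 0.4, FA = 0.35),
                            spatial_weights = c("15" = 0.45, "25" = 0.4,
                                                "40" = 0.35),
                            n_region_south = 52L) {
  cfg <- list(seed = as.integer(seed), n_rows = n_rows, n_cols = n_cols,
              cell_size = cell_size, mask_fraction = mask_fraction,
              n_species = n_species, plots_per_grid = plots_per_grid,
              m_plots = m_plots, B = B, min_plots = min_plots,
              folds = folds, rule = rule, scheme = scheme,
              candidate_rule = candidate_rule, alpha = alpha,
              cells_per_grid = cells_per_grid,
              env_weights = env_weights, spatial_weights = spatial_weights,
              n_region_south = n_region_south)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

write_csv_plain <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
}

stage_log <- function(stage, t0, seed = NULL, quiet = FALSE) {
  if (quiet) return(invisible())
  el <- round(as.numeric(Sys.time()) - t0, 2)
  message(sprintf("[%s] done in %.2fs%s", stage, el,
                  if (!is.null(seed)) paste0(" (seed ", seed, ")") else ""))
}

# Rebuild the deterministic spatial scaffolding (lattice, weights, basis)
# from a config; shared by all stages so cached re-runs are exact.
pipeline_scaffold <- function(config) {
  grid <- gen_lattice(config$n_rows, config$n_cols, config$cell_size,
                      config$mask_fraction,
                      seed = derive_seed(config$seed, "mask"))
  W <- build_weights(grid, scheme = config$scheme)
  basis <- eigen_basis(W)
  list(grid = grid, W = W, basis = basis)
}

#' Run the full synthetic richness-modelling pipeline
#'
#' Stages, in order: `simulate` (lattice, fine climate, plot data),
#' `richness` (filter + bootstrap), `predictors` (derive, aggregate,
#' standardize), `select` (LASSO full/reduced), `fit` (GLM and ESF on
#' each selection), `evaluate` (comparison table, residual Moran's I,
#' paired regional Wilcoxon tests). All artifacts are flat CSV/JSON
#' files under `out_dir`, stamped with the config hash via
#' `run_manifest.json`; identical configs reproduce byte-identical
#' artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of stages to run (default all, in order);
#'   later stages read earlier stages' files from `out_dir`.
#' @param quiet suppress per-stage log messages.
#' @return Invisibly, a list with `out_dir`, `config_hash`, and (when
#'   the relevant stages ran) `comparison` and `wilcoxon` tables.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "richness", "predictors",
                                    "select", "fit", "evaluate"),
                         quiet = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "config.json"))
  manifest <- list(config_hash = hash, seed = config$seed, stages = list())
  result <- list(out_dir = out_dir, config_hash = hash)

  run_stage <- function(name, fun) {
    t0 <- as.numeric(Sys.time())
    out <- tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stage_log(name, t0, seed = config$seed, quiet = quiet)
    manifest$stages[[name]] <<- list(
      elapsed_s = round(as.numeric(Sys.time()) - t0, 3))
    out
  }

  scaf <- pipeline_scaffold(config)

  if ("simulate" %in% stages) run_stage("simulate", function() {
    fine <- gen_climate_fine(scaf$grid, scaf$basis, config$cells_per_grid,
                             seed = derive_seed(config$seed, "climate"))
    pred <- derive_predictors(fine)
    Xs <- standardize_predictors(pred)
    pool <- make_species_pool(config$n_species,
                              env_weights = config$env_weights,
                              spatial_weights = config$spatial_weights,
                              seed = derive_seed(config$seed, "pool"))
    P <- occupancy_probs(pool, X = Xs[, names(config$env_weights)],
                         basis = scaf$basis)
    plots <- gen_plot_data(scaf$grid, pool, P, config$plots_per_grid,
                           seed = derive_seed(config$seed, "plots"))
    write_csv_plain(scaf$grid, file.path(out_dir, "grid.csv"))
    write_csv_plain(fine, file.path(out_dir, "fine_climate.csv"))
    write_csv_plain(plots, file.path(out_dir, "plots.csv"))
    NULL
  })

  if ("richness" %in% stages) run_stage("richness", function() {
    plots <- utils::read.csv(file.path(out_dir, "plots.csv"),
                             colClasses = c(species = "character"))
    rich <- grid_richness_table(plots, m = config$m_plots, B = config$B,
                                min_plots = config$min_plots,
                                seed = derive_seed(config$seed, "bootstrap"))
    write_csv_plain(rich, file.path(out_dir, "richness.csv"))
    NULL
  })

  if ("predictors" %in% stages) run_stage("predictors", function() {
    fine <- utils::read.csv(file.path(out_dir, "fine_climate.csv"))
    rich <- utils::read.csv(file.path(out_dir, "richness.csv"))
    pred <- derive_predictors(fine)
    pred <- pred[pred$grid_id %in% rich$grid_id, , drop = FALSE]
    Xs <- standardize_predictors(pred)
    write_csv_plain(Xs, file.path(out_dir, "predictors.csv"))
    writeLines(jsonlite::toJSON(attr(Xs, "scaling"), digits = NA,
                                dataframe = "rows"),
               file.path(out_dir, "predictor_scaling.json"))
    NULL
  })

  read_xy <- function() {
    Xs <- utils::read.csv(file.path(out_dir, "predictors.csv"))
    rich <- utils::read.csv(file.path(out_dir, "richness.csv"))
    stopifnot(identical(Xs$grid_id, rich$grid_id))
    list(X = as.matrix(Xs[, setdiff(names(Xs), "grid_id")]),
         y = rich$tsr_mean, grid_id = rich$grid_id)
  }

  if ("select" %in% stages) run_stage("select", function() {
    d <- read_xy()
    sel <- run_full_and_reduced(d$X, d$y, folds = config$folds,
                                rule = config$rule,
                                seed = derive_seed(config$seed, "cv"))
    tab <- rbind(
      data.frame(model = "full", variable = sel$full$selected,
                 penalized_coefficient = unname(sel$full$coefficients)),
      data.frame(model = "reduced", variable = sel$reduced$selected,
                 penalized_coefficient = unname(sel$reduced$coefficients)))
    write_csv_plain(tab, file.path(out_dir, "selection.csv"))
    writeLines(jsonlite::toJSON(list(
      full = list(selected = sel$full$selected,
                  lambda = sel$full$lambda,
                  lambda_min = sel$full$lambda_min,
                  lambda_1se = sel$full$lambda_1se),
      reduced = list(selected = sel$reduced$selected,
                     lambda = sel$reduced$lambda,
                     lambda_min = sel$reduced$lambda_min,
                     lambda_1se = sel$reduced$lambda_1se),
      config_hash = hash), auto_unbox = TRUE, digits = NA),
      file.path(out_dir, "selection.json"))
    NULL
  })

  fit_four <- function() {
    d <- read_xy()
    sel <- utils::read.csv(file.path(out_dir, "selection.csv"))
    vars_full <- sel$variable[sel$model == "full"]
    vars_red <- sel$variable[sel$model == "reduced"]
    live <- match(d$grid_id, scaf$grid$cell_id)
    grid_live <- scaf$grid[live, , drop = FALSE]
    W_live <- build_weights(grid_live, scheme = config$scheme)
    basis_live <- eigen_basis(W_live)
    fit_pair <- function(vars) {
      Xm <- d$X[, vars, drop = FALSE]
      glm_fit <- fit_glm(Xm, d$y)
      esf <- stepwise_esf(Xm, d$y, basis_live,
                          candidate_rule = config$candidate_rule,
                          alpha = config$alpha)
      list(glm = glm_fit, esf = esf)
    }
    list(full = fit_pair(vars_full), reduced = fit_pair(vars_red),
         W = W_live, grid = grid_live, y = d$y, grid_id = d$grid_id)
  }

  if ("fit" %in% stages || "evaluate" %in% stages) {
    fits <- run_stage("fit", fit_four)
    if ("fit" %in% stages) {
      summ <- function(f, which) {
        base <- if (inherits(f, "esf_fit")) f$fit else f
        list(model = which,
             coefficients = as.list(base$coefficients[
               !grepl("^EV", names(base$coefficients))]),
             aic = base$aic, null_deviance = base$null_deviance,
             residual_deviance = base$deviance,
             pct_explained = pct_deviance_explained(base$null_deviance,
                                                    base$deviance),
             n_eigenvectors = if (inherits(f, "esf_fit"))
               length(f$selected) else 0,
             config_hash = hash)
      }
      writeLines(jsonlite::toJSON(list(
        glm_full = summ(fits$full$glm, "glm_full"),
        esf_full = summ(fits$full$esf, "esf_full"),
        glm_reduced = summ(fits$reduced$glm, "glm_reduced"),
        esf_reduced = summ(fits$reduced$esf, "esf_reduced")),
        auto_unbox = TRUE, digits = NA),
        file.path(out_dir, "fits.json"))
    }
  }

  if ("evaluate" %in% stages) run_stage("evaluate", function() {
    cmp <- compare_models(list(glm_full = fits$full$glm,
                               esf_full = fits$full$esf,
                               glm_reduced = fits$reduced$glm,
                               esf_reduced = fits$reduced$esf),
                          W = fits$W)
    write_csv_plain(cmp, file.path(out_dir, "comparison.csv"))
    # synthetic coastal region: the n_region_south retained grids with the
    # lowest row (then column) order, mirroring a compact southern block
    ord <- order(fits$grid$row, fits$grid$col)
    south <- fits$grid$cell_id[ord[seq_len(min(config$n_region_south,
                                               nrow(fits$grid)))]]
    labels <- ifelse(fits$grid_id %in% south, "south", "inland")
    regions <- regional_split(fits$grid_id, labels)
    wil_rows <- list()
    for (m in c("glm_full", "esf_full", "glm_reduced", "esf_reduced")) {
      f <- switch(m, glm_full = fits$full$glm, esf_full = fits$full$esf,
                  glm_reduced = fits$reduced$glm,
                  esf_reduced = fits$reduced$esf)
      base <- if (inherits(f, "esf_fit")) f$fit else f
      for (r in names(regions)) {
        i <- regions[[r]]
        w <- wilcoxon_signed_rank(fits$y[i], base$fitted[i])
        wil_rows[[paste(m, r)]] <- data.frame(
          model = m, region = r, n = length(i),
          median_predicted = w$median_predicted, W = w$W, p = w$p)
      }
    }
    wil <- do.call(rbind, wil_rows)
    rownames(wil) <- NULL
    write_csv_plain(wil, file.path(out_dir, "wilcoxon.csv"))
    result$comparison <<- cmp
    result$wilcoxon <<- wil
    NULL
  })

  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "run_manifest.json"))
  invisible(result)
}
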