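#' Configuration for a full synthesis run
#'
#' Validates all parameters up front (every problem is reported at once)
#' and records the seeds used by each stochastic stage.
#'
#' @param output_dir Directory for stage outputs and the run manifest.
#' @param seed Master seed; stage seeds derive from it.
#' @param input_csv Optional CSV of real paired observations; when `NULL`
#'   a synthetic dataset is generated.
#' @param generator [generator_config()] used when `input_csv` is `NULL`.
#' @param outcomes Outcomes to meta-analyze.
#' @param boot_iter Bootstrap iterations for subgroup confidence intervals
#'   (0 = Wald intervals).
#' @param bin_w,bin_n Input bin widths for optimum finding.
#' @param min_leaf,max_depth,cv_folds Tree stage parameters.
#' @param factor_matrix_csv,emission_coefs_csv LCA configuration; defaults
#'   to the synthetic fixtures shipped with the package.
#' @param econ_water,econ_nitrogen Economic parameter tibbles (regions,
#'   prices, areas); default to the published regional values.
#' @return A validated list of class `ws_run_config`.
#' @export
run_config <- function(output_dir,
                       seed = 1L,
                       input_csv = NULL,
                       generator = generator_config(seed = seed),
                       outcomes = c("yield", "wp", "nue"),
                       boot_iter = 999L,
                       bin_w = 50, bin_n = 30,
                       min_leaf = 5L, max_depth = 12L, cv_folds = 10L,
                       factor_matrix_csv = system.file(
                         "extdata", "lca_factors_synthetic.csv",
                         package = "wheatsynth"),
                       emission_coefs_csv = system.file(
                         "extdata", "emission_coefs_synthetic.csv",
                         package = "wheatsynth"),
                       econ_water = reference_econ_water(),
                       econ_nitrogen = reference_econ_nitrogen()) {
  problems <- character(0)
  if (!is.null(input_csv) && !file.exists(input_csv)) {
    problems <- c(problems, paste0("input_csv does not exist: ", input_csv))
  }
  if (!all(outcomes %in% c("yield", "wp", "nue"))) {
    problems <- c(problems, "outcomes must be among yield, wp, nue")
  }
  for (f in c(factor_matrix_csv = factor_matrix_csv,
              emission_coefs_csv = emission_coefs_csv)) {
    if (!nzchar(f) || !file.exists(f)) {
      problems <- c(problems, paste0("LCA config file missing: ",
                                     if (nzchar(f)) f else "(empty path)"))
    }
  }
  for (nm in c("econ_water", "econ_nitrogen")) {
    tbl <- get(nm)
    need <- c("region", "p_carbon_yuan_t", "gwp_save_kg_ha", "area_ha",
              if (nm == "econ_water") c("ws_mm", "p_water_yuan_m3") else
                c("ns_kg_ha", "p_n_yuan_kg"))
    miss <- setdiff(need, names(tbl))
    if (length(miss) > 0L) {
      problems <- c(problems, paste0(nm, " lacks column(s): ",
                                     paste(miss, collapse = ", ")))
    }
  }
  if (bin_w <= 0 || bin_n <= 0) problems <- c(problems,
                                              "bin widths must be > 0")
  if (length(problems) > 0L) {
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(list(
    output_dir = output_dir, seed = as.integer(seed),
    input_csv = input_csv, generator = generator, outcomes = outcomes,
    boot_iter = as.integer(boot_iter), bin_w = bin_w, bin_n = bin_n,
    min_leaf = as.integer(min_leaf), max_depth = as.integer(max_depth),
    cv_folds = as.integer(cv_folds),
    factor_matrix_csv = factor_matrix_csv,
    emission_coefs_csv = emission_coefs_csv,
    econ_water = econ_water, econ_nitrogen = econ_nitrogen
  ), class = "ws_run_config")
}

write_stage_csv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  path
}

#' Run the full synthesis pipeline
#'
#' Executes, in dependency order: data acquisition (synthetic generation or
#' CSV read), input-level classification and regional optima, subgroup
#' meta-analysis, saving potentials, input-level regressions, path models,
#' tree-based feature ranking with cross-validation, life-cycle impact
#' characterization and economic valuation. Each stage writes a CSV; a
#' JSON manifest records parameters, seeds and output files. A failing
#' stage stops all downstream stages and reports its name.
#'
#' @param config A [run_config()].
#' @return Invisible list with the manifest and all stage results.
#' @export
run_synthesis_pipeline <- function(config) {
  stopifnot(inherits(config, "ws_run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- NULL
  dataset_stage <- stage("data", {
    if (is.null(config$input_csv)) {
      gen <- generate_dataset(config$generator)
      truth <- gen$truth
      gen$dataset
    } else {
      read_dataset(config$input_csv)
    }
  })
  results$dataset <- dataset_stage
  results$truth <- truth
  outputs <- c(outputs, write_stage_csv(results$dataset,
                                        config$output_dir, "dataset"))

  results$optima <- stage("optima", find_optima_all(
    results$dataset, bin_w = config$bin_w, bin_n = config$bin_n))
  outputs <- c(outputs, write_stage_csv(results$optima,
                                        config$output_dir, "optima"))

  results$meta <- stage("meta", {
    dplyr::bind_rows(lapply(config$outcomes, function(oc) {
      dplyr::bind_rows(lapply(
        c("overall", "region", "water_level", "n_level"),
        function(g) {
          res <- subgroup_summary(results$dataset, oc, g,
                                  optima = results$optima,
                                  boot_iter = config$boot_iter,
                                  seed = config$seed)
          res$outcome <- oc
          res$grouping <- g
          res
        }))
    }))
  })
  outputs <- c(outputs, write_stage_csv(results$meta,
                                        config$output_dir,
                                        "meta_results"))

  results$saving <- stage("saving", dplyr::bind_rows(
    saving_potential(results$dataset, results$optima, "water"),
    saving_potential(results$dataset, results$optima, "nitrogen")
  ))
  outputs <- c(outputs, write_stage_csv(results$saving,
                                        config$output_dir,
                                        "saving_potential"))

  results$level_regressions <- stage("level_regressions",
    level_regressions(results$dataset, results$optima))
  outputs <- c(outputs, write_stage_csv(results$level_regressions,
                                        config$output_dir,
                                        "level_regressions"))

  results$paths <- stage("paths", path_analysis(results$dataset,
                                                results$optima))
  path_tbl <- dplyr::bind_rows(lapply(names(results$paths), function(s) {
    f <- results$paths[[s]]
    if (!f$converged) {
      return(tibble::tibble(stratum = s, from = NA_character_,
                            to = NA_character_, coef = NA_real_,
                            chi_square = NA_real_, df = NA_integer_,
                            n = f$n, converged = FALSE))
    }
    cc <- f$coefficients
    cc$stratum <- s
    cc$chi_square <- f$chi_square
    cc$df <- f$df
    cc$n <- f$n
    cc$converged <- TRUE
    cc
  }))
  outputs <- c(outputs, write_stage_csv(path_tbl, config$output_dir,
                                        "path_coefficients"))

  results$cart <- stage("tree", {
    feats <- c("study_id", "region", "year", "mat", "map_mm", "soc", "an",
               "ap", "ak", "water_mm", "n_kg_ha", "wheat_type",
               "split_n_stages", "irrigation_events")
    feats <- intersect(feats, names(results$dataset))
    eff <- compute_rr(results$dataset, "yield")
    ii <- match(eff$obs_id, results$dataset$obs_id)
    X <- as.data.frame(results$dataset[ii, feats])
    y <- eff$rr
    tree <- grow_tree(X, y, min_leaf = config$min_leaf,
                      max_depth = config$max_depth)
    cv <- cross_validate(X, y, k = config$cv_folds, seed = config$seed,
                         min_leaf = config$min_leaf,
                         max_depth = config$max_depth)
    list(tree = tree, cv = cv, ranking = rank_features(tree))
  })
  outputs <- c(outputs, write_stage_csv(results$cart$ranking,
                                        config$output_dir,
                                        "cart_importance"))

  results$lca <- stage("lca", {
    coefs <- read_emission_coefs(config$emission_coefs_csv)
    fm <- read_factor_matrix(config$factor_matrix_csv)
    ds <- results$dataset
    inputs <- dplyr::bind_rows(lapply(results$optima$region, function(r) {
      sel <- ds$region == r
      tibble::tibble(
        region = r,
        n_kg_ha = mean(ds$n_kg_ha[sel], na.rm = TRUE),
        irrigation_m3_ha = 10 * mean(ds$water_mm[sel], na.rm = TRUE),
        yield_t_ha = mean(ds$y_t[sel], na.rm = TRUE) / 1000
      )
    }))
    impact_table(inputs, coefs, fm)
  })
  outputs <- c(outputs, write_stage_csv(results$lca, config$output_dir,
                                        "lca_impacts"))

  results$econ <- stage("econ", {
    coefs <- read_emission_coefs(config$emission_coefs_csv)
    fm <- read_factor_matrix(config$factor_matrix_csv)
    gwp_per_kg_n <- characterize(
      build_inventory("unit", 1, 0, coefs), fm)[["GWP"]]
    gwp_per_m3 <- characterize(
      build_inventory("unit", 0, 1, coefs), fm)[["GWP"]]
    sav <- results$saving
    ws <- sav[sav$kind == "water", ]
    ns <- sav[sav$kind == "nitrogen", ]
    pw <- config$econ_water
    pn <- config$econ_nitrogen
    wtab <- tibble::tibble(
      region = ws$region,
      ws_mm = ws$mean_abs,
      p_water_yuan_m3 = pw$p_water_yuan_m3[match(ws$region, pw$region)],
      p_carbon_yuan_t = pw$p_carbon_yuan_t[match(ws$region, pw$region)],
      gwp_save_kg_ha = ws$mean_abs * 10 * gwp_per_m3,
      area_ha = pw$area_ha[match(ws$region, pw$region)]
    )
    ntab <- tibble::tibble(
      region = ns$region,
      ns_kg_ha = ns$mean_abs,
      p_n_yuan_kg = pn$p_n_yuan_kg[match(ns$region, pn$region)],
      p_carbon_yuan_t = pn$p_carbon_yuan_t[match(ns$region, pn$region)],
      gwp_save_kg_ha = ns$mean_abs * gwp_per_kg_n,
      area_ha = pn$area_ha[match(ns$region, pn$region)]
    )
    dplyr::bind_rows(
      econ_table(wtab, "water"),
      econ_table(ntab, "nitrogen")
    )
  })
  outputs <- c(outputs, write_stage_csv(results$econ, config$output_dir,
                                        "econ_valuation"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("wheatsynth")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    parameters = list(
      boot_iter = config$boot_iter, bin_w = config$bin_w,
      bin_n = config$bin_n, min_leaf = config$min_leaf,
      max_depth = config$max_depth, cv_folds = config$cv_folds,
      outcomes = config$outcomes,
      input = if (is.null(config$input_csv)) "synthetic" else
        config$input_csv
    ),
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(results, list(manifest = manifest, outputs = outputs)))
}
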