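#' Per-site diversity table with bootstrap-corrected columns
#'
#' One row per population: sample size, uncorrected multilocus `A`, `I`,
#' `He`, `Ho`, `Fis` (with across-locus sd), and the bootstrap-corrected
#' values (mean over subsamples of the minimum sample size; sd over
#' bootstrap replicates). Populations at the minimum sample size have
#' identical corrected and uncorrected values by construction.
#'
#' @param G a [genotype_matrix()].
#' @param n_boot bootstrap replicates.
#' @param subsample subsample size (default: the minimum population size,
#'   floored at 3).
#' @param seed RNG seed.
#' @param unbiased small-sample `He` correction flag (see [site_stats()]).
#' @return data.frame with one row per population.
#' @export
diversity_table <- function(G, n_boot = 1000, subsample = NULL, seed = 1L,
                            unbiased = FALSE) {
  pops <- levels(G$pops)
  if (is.null(subsample)) subsample <- max(3, min(table(G$pops)))
  stats_names <- c("A", "I", "He", "Ho", "Fis")
  rows <- lapply(pops, function(p) {
    idx <- which(G$pops == p)
    s <- suppressMessages(site_stats(G, p, unbiased = unbiased))
    row <- data.frame(pop = p, n = s$n, A = s$A, I = s$I, He = s$He,
                      Ho = s$Ho, Fis = s$Fis,
                      sd_A = s$sd["A"], sd_I = s$sd["I"], sd_He = s$sd["He"],
                      sd_Ho = s$sd["Ho"])
    for (st in stats_names) {
      bc <- bootstrap_corrected_stat(G, idx, subset_stat_fun(st),
                                     n_boot = n_boot, subsample = subsample,
                                     seed = seed)
      row[[paste0(st, "_corr")]] <- bc$mean
      row[[paste0("sd_", st, "_corr")]] <- bc$sd
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default pipeline configuration
#'
#' All defaults are the framework's reference values: 30 arc-second cells,
#' 10 arc-minute neighborhoods, 1,000 bootstraps of minimum size 3, LCA
#' thresholds 25% occupancy / 5% frequency, K = 1-8 with 10 repetitions,
#' VIF threshold 5, at most 10,000 background points, 20 null-model
#' iterations, 999 permutations, and a single global seed.
#'
#' @param seed global RNG seed.
#' @param ... overrides for any default block (partial lists are merged).
#' @return nested list of parameter blocks.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    stats = list(n_boot = 1000, subsample = 3, unbiased = FALSE),
    perm = list(n_perm = 999),
    map = list(cell_size = 1 / 120, diameter = 1 / 6, n_boot = 1000,
               min_n = 3, statistics = c("A", "I", "He", "Ho", "Fis", "LCA"),
               lca_occupancy = 0.25, lca_freq = 0.05),
    admixture = list(K_values = 1:8, restarts = 10, max_iter = 500,
                     tol = 1e-6, alpha = 0.01),
    sdm = list(models = c("envelope", "logistic"), anchor = "logistic",
               background_max = 10000, vif_threshold = 5, k_folds = 4,
               null_iterations = 20, retain_alpha = 0.05)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on one genotype dataset (and
#' optionally a landscape): per-site diversity table with bootstrap
#' correction, pairwise/global F_ST, AMOVA, diversity rasters, admixture
#' over a K range with Evanno delta-K, and (when a landscape is given) the
#' calibrated-AUC ensemble suitability workflow through retention, anchored
#' search, thresholding and consensus. Every artifact is written under
#' `out_dir` and listed in a JSON manifest stamped with the config hash and
#' seed; a re-run with the same config and inputs reproduces identical CSV
#' outputs.
#'
#' @param G a [genotype_matrix()].
#' @param out_dir output directory (created).
#' @param config a [pipeline_config()].
#' @param landscape optional list with `stack` and `presences` (e.g. from
#'   [simulate_landscape()]); `NULL` skips the suitability stage.
#' @param config_path optional YAML file to load the config from (overrides
#'   `config`).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(G, out_dir, config = pipeline_config(),
                         landscape = NULL, config_path = NULL) {
  if (!is.null(config_path)) {
    if (!file.exists(config_path)) stop("missing input: ", config_path)
    config <- utils::modifyList(pipeline_config(), yaml::read_yaml(config_path))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list(config = config, config_hash = config_hash(config),
                   seed = seed, stages = list())
  out <- function(...) file.path(out_dir, ...)
  artifacts <- character()

  stage <- function(name, expr) {
    message("[", name, "] running")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  stage("stats", {
    tab <- diversity_table(G, n_boot = config$stats$n_boot,
                           subsample = config$stats$subsample, seed = seed,
                           unbiased = config$stats$unbiased)
    utils::write.csv(tab, out("diversity_table.csv"), row.names = FALSE)
    artifacts <- c(artifacts, "diversity_table.csv")
  })

  stage("fst", {
    fst <- pairwise_fst(G)
    utils::write.csv(data.frame(pop = rownames(fst$fst), fst$fst,
                                mean_fst = fst$pop_mean),
                     out("pairwise_fst.csv"), row.names = FALSE)
    artifacts <- c(artifacts, "pairwise_fst.csv")
  })

  amv <- stage("amova", {
    a <- amova(G, n_perm = config$perm$n_perm, seed = seed)
    utils::write.csv(data.frame(level = c("among", "within"),
                                sigma2 = as.numeric(a$sigma),
                                pct = as.numeric(a$pct),
                                phi_st = c(a$phi_st, NA),
                                p_value = c(a$p_value, NA)),
                     out("amova.csv"), row.names = FALSE)
    artifacts <- c(artifacts, "amova.csv")
    a
  })

  stage("map", {
    mp <- config$map
    grid <- build_neighborhood_grid(G, mp$cell_size, mp$diameter)
    lca <- classify_lca(G, mp$lca_occupancy, mp$lca_freq)
    for (st in mp$statistics) {
      dr <- map_statistic(G, st, grid = grid, n_boot = mp$n_boot,
                          subsample = mp$min_n, seed = seed, lca = lca)
      write_raster(dr$raster, out(paste0("map_", st, ".asc")))
      cells <- dr$cells; cells$trees <- NULL
      utils::write.csv(cells, out(paste0("map_", st, ".csv")),
                       row.names = FALSE)
      artifacts <- c(artifacts, paste0("map_", st, c(".asc", ".csv")))
    }
  })

  evanno <- stage("admixture", {
    ad <- config$admixture
    run <- run_admixture(G, ad$K_values, restarts = ad$restarts, seed = seed,
                         max_iter = ad$max_iter, tol = ad$tol,
                         alpha = ad$alpha)
    utils::write.csv(run$logliks, out("admixture_logliks.csv"),
                     row.names = FALSE)
    ev <- evanno_delta_k(run$logliks)
    utils::write.csv(ev$table, out("evanno.csv"), row.names = FALSE)
    for (K in names(run$best)) {
      q <- data.frame(id = rownames(run$best[[K]]$Q), run$best[[K]]$Q)
      utils::write.csv(q, out(paste0("q_matrix_K", K, ".csv")),
                       row.names = FALSE)
    }
    artifacts <- c(artifacts, "admixture_logliks.csv", "evanno.csv",
                   paste0("q_matrix_K", names(run$best), ".csv"))
    ev
  })
  manifest$stages$evanno_best_k <- evanno$best_k
  manifest$stages$amova_pct_among <- as.numeric(amv$pct["among"])

  if (!is.null(landscape)) {
    stage("sdm", {
      sd_cfg <- config$sdm
      stack <- landscape$stack
      pres <- dedup_occurrences(landscape$presences,
                                stack$layers[[1]]$cell_size)
      keep <- vif_prune(stack_cells(stack)[names(stack$layers)],
                        sd_cfg$vif_threshold)$retained
      stack <- env_stack(stack$layers[keep])
      bg <- sample_background(pres, stack, max_n = sd_cfg$background_max,
                              seed = seed)
      fit_funs <- lapply(sd_cfg$models, function(nm) {
        force(nm)
        function(p, b, s, sd2) fit_base_model(nm, p, b, s, sd2)
      })
      names(fit_funs) <- sd_cfg$models
      caucs <- lapply(fit_funs, function(ff)
        cauc_iterations(ff, pres, bg, stack,
                        iterations = sd_cfg$null_iterations,
                        k_folds = sd_cfg$k_folds, seed = seed))
      null_cauc <- cauc_iterations(NULL, pres, bg, stack,
                                   iterations = sd_cfg$null_iterations,
                                   k_folds = sd_cfg$k_folds, seed = seed)
      ret <- retain_models(caucs, null_cauc, alpha = sd_cfg$retain_alpha)
      utils::write.csv(ret, out("model_retention.csv"), row.names = FALSE)
      kept <- ret$model[ret$retained]
      anchor <- sd_cfg$anchor
      if (!anchor %in% kept) kept <- unique(c(anchor, kept))
      ens <- ensemble_search(fit_funs[kept], anchor, pres, bg, stack,
                             k_folds = sd_cfg$k_folds, seed = seed)
      cells <- stack_cells(stack)
      thr <- threshold_max_sens_spec(
        predict(ens, cbind(stack_extract(stack, pres$lon, pres$lat),
                           pres[, c("lon", "lat")])),
        predict(ens, cbind(stack_extract(stack, bg$lon, bg$lat),
                           bg[, c("lon", "lat")])))
      suit <- project_model(ens, stack)
      binm <- project_model(ens, stack, threshold = thr)
      write_raster(suit, out("suitability.asc"))
      write_raster(binm, out("suitability_binary.asc"))
      utils::write.csv(ens$table, out("ensemble_search.csv"),
                       row.names = FALSE)
      manifest$stages$ensemble <- list(members = ens$members,
                                        weights = as.numeric(ens$weights),
                                        cauc = ens$cauc, threshold = thr)
      artifacts <- c(artifacts, "model_retention.csv", "ensemble_search.csv",
                     "suitability.asc", "suitability_binary.asc")
    })
  }

  manifest$artifacts <- lapply(setNames(nm = artifacts), function(a)
    list(path = a, md5 = unname(tools::md5sum(out(a)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
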