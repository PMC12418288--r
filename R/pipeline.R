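#' Default pipeline configuration
#'
#' A single human-readable list (serialisable to YAML) holding every
#' run-level switch: the grid, the global seed, the simulation sizes, the
#' richness options (criterion variant, signal variant, permutations), the
#' sharing options (eligibility threshold, bootstrap iterations, resampling
#' rule) and the PCA retention rule. Per-stage RNG substreams are derived
#' from the global seed so stages can be rerun in isolation reproducibly.
#'
#' @param outdir output directory.
#' @param seed global integer seed.
#' @param n_hosts,n_parasites simulated community sizes.
#' @param mode generator mode, `"sharing"` or `"richness"`.
#' @return nested list understood by [run_pipeline()].
#' @export
default_config <- function(outdir = "results/pipeline", seed = 1L,
                           n_hosts = 60, n_parasites = 30,
                           mode = "sharing") {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    simulate = TRUE,
    grid = list(lon_min = -10, lon_max = 10, lat_min = -10, lat_max = 10,
                resolution = 1),
    world = list(n_hosts = n_hosts, n_parasites = n_parasites, mode = mode,
                 richness_betas = c(-2, -0.3, 0.4, 0, 0), nb_theta = 2,
                 sharing_coefs = c(2, -6), sharing_distance = "trait",
                 range_median_cells = 40, range_sdlog = 0.7),
    inputs = list(tree = NULL, traits = NULL, pam = NULL, env = NULL,
                  incidence = NULL),
    richness = list(aicc = FALSE, signal_variant = "K*", n_perm = 499),
    sharing = list(min_hosts = 6, n_iter = 200, replace = TRUE),
    pca = list(n_components = NULL, min_variance = 0.75),
    buffer_km = 100)
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  merge_lists(base, config)
}

pipeline_inputs <- function(cfg, paths) {
  g <- do.call(grid_spec, cfg$grid)
  if (isTRUE(cfg$simulate)) {
    wcfg <- world_config(n_hosts = cfg$world$n_hosts,
                         n_parasites = cfg$world$n_parasites, grid = g,
                         seed = cfg$seed, mode = cfg$world$mode,
                         richness_betas = cfg$world$richness_betas,
                         nb_theta = cfg$world$nb_theta,
                         sharing_coefs = cfg$world$sharing_coefs,
                         sharing_distance = cfg$world$sharing_distance,
                         range_median_cells = cfg$world$range_median_cells,
                         range_sdlog = cfg$world$range_sdlog)
    world <- simulate_world(wcfg)
    ape::write.tree(world$tree, file.path(paths$sim, "tree.nwk"))
    write_traits_csv(world$traits, file.path(paths$sim, "traits.csv"))
    write_matrix_csv(world$pam, file.path(paths$sim, "presence_absence.csv"))
    write_matrix_csv(world$env, file.path(paths$sim, "environment.csv"),
                     label = "cell_id")
    write_matrix_csv(world$incidence, file.path(paths$sim, "incidence.csv"),
                     label = "parasite_id")
    write_world_sidecar(wcfg, file.path(paths$sim, "world_config.json"))
    list(grid = g, tree = world$tree, traits = world$traits, pam = world$pam,
         env = world$env, incidence = world$incidence)
  } else {
    need <- c("tree", "traits", "pam", "incidence", "env")
    missing <- need[vapply(need, function(k) is.null(cfg$inputs[[k]]),
                           logical(1))]
    if (length(missing))
      stop("analyze mode needs input paths for: ",
           paste(missing, collapse = ", "))
    list(grid = g,
         tree = ape::read.tree(cfg$inputs$tree),
         traits = read_traits_csv(cfg$inputs$traits),
         pam = read_matrix_csv(cfg$inputs$pam),
         env = read_matrix_csv(cfg$inputs$env),
         incidence = read_matrix_csv(cfg$inputs$incidence))
  }
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (optional) realm simulation, gridded range metrics,
#' the four normalized distance matrices, the phylogenetic-signal gate plus
#' all-subsets negative-binomial richness model selection, and the
#' parasite-sharing bootstrap for each distance type. All declared CSV/JSON
#' artifacts are written under `outdir`; identical config and seed give
#' identical outputs. A stage failure stops with the stage named and leaves
#' a `MANIFEST` marking the run incomplete.
#'
#' @param config a config list as from [default_config()], or the path of a
#'   YAML file with the same structure.
#' @return (invisibly) the run report list, also written as
#'   `run_report.json`.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- read_config(config)
  paths <- list(out = cfg$outdir, sim = file.path(cfg$outdir, "sim"))
  for (p in paths) dir.create(p, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed, package_version =
                   as.character(utils::packageVersion("ectofauna")),
                 stages = list(), warnings = character(0))
  log_warn <- function(w) {
    report$warnings <<- c(report$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, expr) {
    res <- tryCatch(withCallingHandlers(expr, warning = log_warn),
                    error = function(e) {
      writeLines(c("INCOMPLETE", paste("failed stage:", name),
                   conditionMessage(e)), file.path(paths$out, "MANIFEST"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    report$stages[[name]] <<- TRUE
    res
  }

  inp <- stage("inputs", pipeline_inputs(cfg, paths))

  ranges <- stage("ranges", {
    rs <- range_summary(inp$pam, inp$grid)
    utils::write.csv(rs, file.path(paths$out, "range_summary.csv"),
                     row.names = FALSE)
    rs
  })

  dists <- stage("distances", {
    d <- host_distances(inp$tree, inp$traits, inp$pam, inp$grid, inp$env,
                        n_components = cfg$pca$n_components,
                        min_variance = cfg$pca$min_variance,
                        buffer_km = cfg$buffer_km, seed = cfg$seed + 10L)
    for (k in c("PD", "TD", "GD", "ED"))
      write_dist_csv(d[[k]], file.path(paths$out, paste0("distance_", k, ".csv")))
    jsonlite::write_json(
      c(d$pca, list(norm_constants = lapply(
        d[c("PD", "TD", "GD", "ED")],
        function(m) attr(m, "norm_constant")))),
      file.path(paths$out, "pca_report.json"), auto_unbox = TRUE, digits = NA)
    d
  })

  richness <- stage("richness", {
    pred <- richness_predictors(inp$traits, ranges)
    dat <- build_richness_dataset(inp$incidence, pred)
    sig <- signal_gate(inp$tree,
                       stats::setNames(dat$richness, dat$host_id),
                       variant = cfg$richness$signal_variant,
                       n_perm = cfg$richness$n_perm, seed = cfg$seed + 20L)
    sel <- all_subsets_select(dat, aicc = cfg$richness$aicc)
    utils::write.csv(sel$table, file.path(paths$out, "model_selection.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(coefficients = as.list(sel$best$coefficients),
           theta = sel$best$theta,
           explained_deviance_percent =
             sel$best$summaries$explained_deviance_percent,
           nagelkerke_r2 = sel$best$summaries$nagelkerke_r2,
           signal = sig[c("statistic", "variant", "p_value")]),
      file.path(paths$out, "best_model.json"), auto_unbox = TRUE, digits = NA)
    list(dataset = dat, selection = sel, signal = sig)
  })

  sharing <- stage("sharing", {
    fits <- list()
    pooled_rows <- list()
    for (k in c("PD", "TD", "GD", "ED")) {
      fit <- pooled_coefficients(inp$incidence, dists[[k]],
                                 n_iter = cfg$sharing$n_iter,
                                 min_hosts = cfg$sharing$min_hosts,
                                 seed = cfg$seed + 30L,
                                 replace = cfg$sharing$replace)
      utils::write.csv(fit$per_parasite,
                       file.path(paths$out, paste0("per_parasite_", k, ".csv")),
                       row.names = FALSE)
      utils::write.csv(data.frame(iteration = seq_len(fit$n_iter),
                                  mean_a = fit$boot_a, mean_b = fit$boot_b),
                       file.path(paths$out, paste0("bootstrap_", k, ".csv")),
                       row.names = FALSE)
      utils::write.csv(sharing_probability(fit$a, fit$b),
                       file.path(paths$out, paste0("curve_", k, ".csv")),
                       row.names = FALSE)
      pooled_rows[[k]] <- data.frame(distance = k, mean_intercept = fit$a,
                                     mean_slope = fit$b, pns = fit$pns)
      fits[[k]] <- fit
    }
    utils::write.csv(do.call(rbind, pooled_rows),
                     file.path(paths$out, "pooled_sharing.csv"),
                     row.names = FALSE)
    fits
  })

  report$n_hosts <- nrow(inp$pam)
  report$n_parasites <- nrow(inp$incidence)
  report$n_eligible <- nrow(sharing$TD$per_parasite)
  jsonlite::write_json(report, file.path(paths$out, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines("COMPLETE", file.path(paths$out, "MANIFEST"))
  invisible(list(report = report, ranges = ranges, distances = dists,
                 richness = richness, sharing = sharing))
}
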