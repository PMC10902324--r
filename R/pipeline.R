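# Configuration-driven pipeline driver and synthetic-workspace writer.
#
# A single plain-text YAML configuration names the inputs (layer edge lists,
# causal-gene list, cohort, optional catalog), the resolution grid, the
# persistence threshold, the randomization counts and the seed. Every report
# is stamped with the configuration hash and seed; rerunning the same
# configuration is byte-identical (no timestamps are written).

.resolve_path <- function(p, base) {
  if (is.null(p) || grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
}

.config_hash <- function(config) {
  config <- config[order(names(config))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full multilayer persistence-module pipeline
#'
#' Loads the layers, sweeps the resolution grid, builds the severity-group
#' gene sets, tallies co-membership, extracts persistence modules and their
#' persistent cores, runs the label-shuffle module-size significance test and
#' (when a catalog is configured) the balanced-randomization catalog
#' validation, and writes all reports into the output directory. Any stage
#' error aborts with the stage name and cause.
#'
#' Configuration fields (YAML file or list): `layers` (named map of edge-list
#' paths), `causal_genes`, `cohort`, optional `catalog` (GMT), `output_dir`,
#' `seed` (default 1), `grid` (either `values` or `n` + `gamma_max`; default
#' 8 values on `(0, 4]`), `threshold` (persistence threshold `n`; default the
#' grid length), `randomizations` (default 1000), `alpha` (default 0.05).
#' Relative paths are resolved against the configuration file's directory.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param quiet Suppress progress messages.
#' @return (Invisibly) a list with the sweep, gene sets, modules, significance
#'   and catalog-validation objects plus the report written to
#'   `output_dir/report.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  base <- "."
  if (is.character(config)) {
    base <- dirname(normalizePath(config, mustWork = TRUE))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  seed <- as.integer(config$seed %||% 1L)
  Rperm <- as.integer(config$randomizations %||% 1000L)
  alpha <- as.numeric(config$alpha %||% 0.05)
  grid <- if (is.null(config$grid)) resolution_grid()
          else if (!is.null(config$grid$values)) resolution_grid(values = unlist(config$grid$values))
          else resolution_grid(n = config$grid$n %||% 8L,
                               gamma_max = config$grid$gamma_max %||% 4)
  out_dir <- .resolve_path(config$output_dir %||% "mlmod_output", base)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)

  net <- stage("load layers", {
    if (is.null(config$layers) || length(config$layers) == 0L)
      stop("no layers configured")
    layers <- lapply(names(config$layers), function(nm) {
      path <- .resolve_path(config$layers[[nm]], base)
      say("loading layer '%s' from %s", nm, path)
      read_layer(path, name = nm)
    })
    ml_network(layers)
  })
  causal <- stage("load causal genes",
                  read_gene_list(.resolve_path(config$causal_genes, base)))
  cohort <- stage("load cohort",
                  read_cohort(.resolve_path(config$cohort, base)))
  say("sweep: %d resolutions, seed %d", length(grid), seed)
  sweep <- stage("resolution sweep", sweep_resolutions(net, grid, seed = seed))
  write_sweep(sweep, file.path(out_dir, "sweep"))
  n_thr <- as.integer(config$threshold %||% length(grid))

  gs <- stage("group gene sets", build_group_gene_sets(cohort, causal))
  jsonlite::write_json(
    list(causal = as.list(gs$causal),
         severe_private = as.list(gs$severe_private),
         not_severe_private = as.list(gs$not_severe_private),
         linked = as.list(gs$linked),
         counts = gs$counts),
    file.path(out_dir, "group_sets.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  modules <- stage("persistence modules", {
    out <- list()
    for (grp in c("severe", "not_severe")) {
      cm <- suppressWarnings(co_membership(sweep, gs[[paste0(grp, "_interest")]]))
      mods <- extract_modules(cm, n = n_thr, anchors = causal)
      cores <- vapply(mods, function(m) {
        if (m$threshold == length(grid) && m$anchored)
          tryCatch(length(persistent_core(sweep, m)), error = function(e) NA_integer_)
        else NA_integer_
      }, integer(1L))
      write_module_report(mods, file.path(out_dir, sprintf("modules_%s.json", grp)),
                          core_sizes = cores)
      out[[grp]] <- list(modules = mods, core_sizes = cores)
    }
    out
  })

  say("label-shuffle significance: %d randomizations", Rperm)
  signif_res <- stage("module-size significance",
                      module_size_significance(sweep, cohort, causal, n = n_thr,
                                               R = Rperm, alpha = alpha,
                                               seed = seed))
  jsonlite::write_json(
    list(severe = list(observed_size = signif_res$severe$observed_size,
                       p = signif_res$severe$p,
                       k_min = signif_res$severe$min_size$k_min %||% NA),
         not_severe = list(observed_size = signif_res$not_severe$observed_size,
                           p = signif_res$not_severe$p,
                           k_min = signif_res$not_severe$min_size$k_min %||% NA),
         threshold = n_thr, randomizations = Rperm, alpha = alpha),
    file.path(out_dir, "significance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  catval <- NULL
  if (!is.null(config$catalog)) {
    catval <- stage("catalog validation", {
      cat0 <- read_gmt(.resolve_path(config$catalog, base))
      prep <- preprocess_catalog(cat0, net$nodes)
      cv <- catalog_validation(sweep, prep$catalog, R = Rperm, seed = seed)
      jsonlite::write_json(list(filter_report = prep$report,
                                per_gamma = cv$per_gamma,
                                stratum = cv$stratum),
                           file.path(out_dir, "catalog_validation.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      cv
    })
  }

  report <- list(
    config_hash = hash, seed = seed,
    n_nodes = length(net$nodes),
    layers = lapply(net$layers, function(l)
      list(nodes = length(l$nodes), edges = nrow(l$edges))),
    grid = unclass(grid), threshold = n_thr,
    Q = sweep$Q, n_communities = sweep$n_communities,
    severe = list(observed_size = signif_res$severe$observed_size,
                  p = signif_res$severe$p),
    not_severe = list(observed_size = signif_res$not_severe$observed_size,
                      p = signif_res$not_severe$p),
    catalog_min_p = if (!is.null(catval)) min(catval$per_gamma$p_rank_sum) else NULL
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: %s", out_dir)
  invisible(list(network = net, sweep = sweep, gene_sets = gs,
                 modules = modules, significance = signif_res,
                 catalog_validation = catval, report = report,
                 output_dir = out_dir))
}

#' Write a ready-to-run synthetic workspace
#'
#' Generates a planted multilayer network, cohort and catalog with
#' [simulate_multilayer()], [simulate_cohort()] and [simulate_catalog()], and
#' writes layer TSVs, the cohort TSV, the causal-gene list, the catalog GMT,
#' the ground-truth partition, a manifest with all parameters, and a
#' `config.yaml` that [run_pipeline()] can execute directly.
#'
#' @param dir Workspace directory (created).
#' @param sizes,n_layers,p_in,p_out,coverage Passed to [simulate_multilayer()].
#' @param signal_community,k_signal,k_background Passed to [simulate_cohort()].
#' @param n_sets,coherent_fraction Passed to [simulate_catalog()].
#' @param randomizations Randomization count written into the configuration.
#' @param seed Integer seed (drives all three generators).
#' @return (Invisibly) the workspace directory.
#' @export
simulate_workspace <- function(dir, sizes = c(30L, 30L, 30L), n_layers = 3L,
                               p_in = 0.3, p_out = 0.01, coverage = 1,
                               signal_community = 1L, k_signal = 5L,
                               k_background = 10L, n_sets = 40L,
                               coherent_fraction = 0.5,
                               randomizations = 200L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_multilayer(sizes, n_layers, p_in, p_out, coverage, seed = seed)
  coh <- simulate_cohort(sim$truth, signal_community = signal_community,
                         k_signal = k_signal, k_background = k_background,
                         seed = seed + 1L)
  cat <- simulate_catalog(sim$truth, n_sets = n_sets,
                          coherent_fraction = coherent_fraction, seed = seed + 2L)
  layer_files <- list()
  for (l in sim$network$layers) {
    f <- sprintf("layer_%s.tsv", l$name)
    write_layer(l, file.path(dir, f), nodes_path = file.path(dir, sprintf("nodes_%s.txt", l$name)))
    layer_files[[l$name]] <- f
  }
  write_cohort(coh$cohort, file.path(dir, "cohort.tsv"))
  writeLines(coh$causal, file.path(dir, "causal_genes.txt"))
  write_gmt(cat, file.path(dir, "catalog.gmt"))
  write_partition(sim$truth$partition, file.path(dir, "truth_partition.tsv"))
  jsonlite::write_json(c(sim$truth$params,
                         list(signal_community = signal_community,
                              k_signal = k_signal, k_background = k_background,
                              n_sets = n_sets, coherent_fraction = coherent_fraction,
                              seed = seed)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  yaml::write_yaml(list(layers = layer_files,
                        causal_genes = "causal_genes.txt",
                        cohort = "cohort.tsv",
                        catalog = "catalog.gmt",
                        output_dir = "output",
                        seed = as.integer(seed),
                        randomizations = as.integer(randomizations)),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
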