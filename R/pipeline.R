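#' Run configuration for the pipeline commands
#'
#' Reads a YAML configuration with blocks `founder`, `trait`, `scheme`,
#' `optimizer`, `experiment`, `output` and a top-level `master_seed`, filling
#' unspecified fields with the package defaults. `preset: tiny` selects a
#' small world (2 chromosomes x 50 loci, pool 200, panel 30) that runs in
#' seconds.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param preset optional preset name (`"default"` or `"tiny"`), overridden
#'   by a `preset` field in the file.
#' @param seed overrides the configuration's `master_seed` when non-`NULL`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(path = NULL, preset = "default", seed = NULL) {
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  preset <- user$preset %||% preset
  base <- list(
    founder = list(n_chromosomes = 10, markers_per_chromosome = 500,
                   length_cM = 1000, n_haplotypes = 4000,
                   maf_min = 0.01, n_founders = 2000, n_panel = 250),
    trait = list(qtl_per_chromosome = 2),
    scheme = list(n_pop = 250, n_sel = 15, n_top = 5, n_generations = 4,
                  selection_criterion = "WBV", standardize_features = TRUE),
    optimizer = list(budget = 20000, n_rep = 50),
    experiment = list(n_schemes = 10000, strategies = c("TBVGVP", "EQ"),
                      threshold = 1.15),
    master_seed = 1L)
  if (identical(preset, "tiny")) {
    base$founder <- list(n_chromosomes = 2, markers_per_chromosome = 50,
                         length_cM = 1000, n_haplotypes = 200,
                         maf_min = 0.01, n_founders = 200, n_panel = 30)
    base$trait$qtl_per_chromosome <- 5
    base$scheme$n_pop <- 60
    base$scheme$n_sel <- 8
    base$optimizer <- list(budget = 100, n_rep = 5)
    base$experiment$n_schemes <- 200
  }
  cfg <- utils::modifyList(base, user[setdiff(names(user), "preset")])
  if (!is.null(seed)) cfg$master_seed <- as.integer(seed)
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scheme_config_from <- function(cfg, feature_set = c("BV", "WBV", "GVP")) {
  s <- cfg$scheme
  scheme_config(n_pop = s$n_pop, n_sel = s$n_sel, n_top = s$n_top,
                n_generations = s$n_generations,
                selection_criterion = s$selection_criterion,
                feature_set = feature_set,
                standardize_features = s$standardize_features)
}

#' Build the simulated world described by a run configuration
#'
#' @param cfg a [run_config()].
#' @return A [sim_world()] object.
#' @export
world_from_config <- function(cfg) {
  f <- cfg$founder
  sim_world(n_chromosomes = f$n_chromosomes,
            markers_per_chromosome = f$markers_per_chromosome,
            length_cM = f$length_cM, n_haplotypes = f$n_haplotypes,
            maf_min = f$maf_min, n_founders = f$n_founders,
            n_panel = f$n_panel,
            qtl_per_chromosome = cfg$trait$qtl_per_chromosome,
            seed = cfg$master_seed)
}

#' Pipeline: simulate founders and write the world to files
#'
#' Writes the kept linkage map (`map.csv`), the founder haplotype pool
#' (`haplotypes.csv`), the parent panel (`panel.csv`), and the trait
#' architecture (`trait.json`) into `out_dir`, and logs a MAF summary.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress log lines.
#' @return The [sim_world()] object, invisibly.
#' @export
pipeline_simulate_founders <- function(cfg = run_config(), out_dir = ".",
                                       quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  world <- world_from_config(cfg)
  write_linkage_map(world$map, file.path(out_dir, "map.csv"))
  write_haplotypes(world$pool, file.path(out_dir, "haplotypes.csv"))
  write_population(world$panel, file.path(out_dir, "panel.csv"))
  write_trait_arch(world$arch, file.path(out_dir, "trait.json"))
  if (!quiet) {
    maf <- pool_maf(world$pool)
    message(sprintf(
      "seed %d | panel %d | kept %d loci | MAF min/median/max %.3f/%.3f/%.3f | %.1fs",
      cfg$master_seed, pop_size(world$panel), nrow(world$map),
      min(maf), stats::median(maf), max(maf),
      proc.time()[["elapsed"]] - t0))
  }
  invisible(world)
}

#' Pipeline: optimize a strategy's weight schedule
#'
#' @param cfg a [run_config()].
#' @param strategy strategy name (see [strategy_features()]); `"EQ"` is
#'   rejected since equal allocation has nothing to optimize.
#' @param out_dir output directory for `weights_<strategy>.json` and
#'   `trace_<strategy>.csv`.
#' @param world optional pre-built world (rebuilt from `cfg` when missing).
#' @param quiet suppress log lines.
#' @return The [optimize_allocation()] fit, invisibly.
#' @export
pipeline_optimize <- function(cfg = run_config(), strategy = "TBVGVP",
                              out_dir = ".", world = NULL, quiet = FALSE) {
  features <- strategy_features(strategy)
  if (is.null(features)) {
    stop("strategy 'EQ' is the non-optimized baseline; nothing to optimize")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(world)) world <- world_from_config(cfg)
  sc <- scheme_config_from(cfg, features)
  fit <- optimize_allocation(world, sc, budget = cfg$optimizer$budget,
                             n_rep = cfg$optimizer$n_rep,
                             seed = cfg$master_seed)
  write_weight_schedule(fit$weights, features,
                        file.path(out_dir, sprintf("weights_%s.json", strategy)))
  utils::write.csv(fit$fit$trace,
                   file.path(out_dir, sprintf("trace_%s.csv", strategy)),
                   row.names = FALSE)
  if (!quiet) {
    message(sprintf("seed %d | %s | %d evals | best mean gain %.4f",
                    cfg$master_seed, strategy, fit$fit$n_eval, fit$value))
  }
  invisible(fit)
}

#' Pipeline: run one breeding scheme and write crossing tables
#'
#' @param cfg a [run_config()].
#' @param strategy strategy name; `"EQ"` for equal allocation, otherwise
#'   `weights` must be supplied (e.g. from [pipeline_optimize()] or
#'   [read_weight_schedule()]).
#' @param weights T x Q weight schedule for optimized strategies.
#' @param out_dir output directory for `crossing_table_t<t>.csv`.
#' @param world optional pre-built world.
#' @return The [run_scheme()] trajectory, invisibly.
#' @export
pipeline_run_scheme <- function(cfg = run_config(), strategy = "EQ",
                                weights = NULL, out_dir = ".", world = NULL) {
  features <- strategy_features(strategy)
  if (!is.null(features) && is.null(weights)) {
    stop("optimized strategy '", strategy, "' needs a weight schedule")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(world)) world <- world_from_config(cfg)
  sc <- scheme_config_from(cfg, features %||% c("BV", "WBV", "GVP"))
  traj <- run_scheme(world$panel, world$arch, world$map, sc,
                     weights = if (is.null(features)) NULL else weights,
                     seed = cfg$master_seed, keep_tables = TRUE)
  for (t in seq_along(traj$tables)) {
    write_crossing_table(traj$tables[[t]],
                         file.path(out_dir,
                                   sprintf("crossing_table_t%d.csv", t - 1L)))
  }
  invisible(traj)
}

#' Pipeline: compare strategies and write the report
#'
#' Writes `gain_by_generation.csv`, `variance_by_generation.csv`,
#' `gains.csv` (per-replicate final gains, the CDF samples) and
#' `report.json` (mean gains, fractions above the configured threshold).
#'
#' @param cfg a [run_config()].
#' @param weights named list of weight schedules for the optimized
#'   strategies in `cfg$experiment$strategies`.
#' @param out_dir output directory.
#' @param world optional pre-built world.
#' @return The [run_comparison()] report, invisibly.
#' @export
pipeline_evaluate <- function(cfg = run_config(), weights = list(),
                              out_dir = ".", world = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(world)) world <- world_from_config(cfg)
  strategies <- lapply(cfg$experiment$strategies, function(nm) {
    if (is.null(strategy_features(nm))) NULL else weights[[nm]]
  })
  names(strategies) <- cfg$experiment$strategies
  sc <- scheme_config_from(cfg)
  report <- run_comparison(world$panel, world$arch, world$map, strategies,
                           sc, n_schemes = cfg$experiment$n_schemes,
                           seed = cfg$master_seed)
  utils::write.csv(data.frame(generation = seq_len(nrow(report$mean_gain_by_gen)) - 1L,
                              report$mean_gain_by_gen),
                   file.path(out_dir, "gain_by_generation.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(generation = seq_len(nrow(report$mean_variance_by_gen)) - 1L,
                              report$mean_variance_by_gen),
                   file.path(out_dir, "variance_by_generation.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$gains),
                   file.path(out_dir, "gains.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_schemes = report$n_schemes,
         mean_gain = as.list(colMeans(report$gains)),
         fraction_above_threshold =
           as.list(fraction_above(report, cfg$experiment$threshold)),
         threshold = cfg$experiment$threshold),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}
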