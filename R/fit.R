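#' Simulate a complete breeding world
#'
#' Convenience wrapper over the founder pipeline: simulate founder
#' haplotypes with LD, filter loci on minor allele frequency, sample diploid
#' founders, random-mate them for one generation of pre-breeding material,
#' pick the parent panel by k-medoids, and draw a trait architecture.
#'
#' @param n_chromosomes,markers_per_chromosome,length_cM genome shape (see
#'   [sim_linkage_map()]); defaults 10 chromosomes x 500 kept loci of a
#'   1000 cM map.
#' @param n_haplotypes founder haplotype pool size (default 4000).
#' @param candidate_loci simulated loci per chromosome before the MAF filter
#'   (default `2 * markers_per_chromosome`).
#' @param maf_min minor-allele-frequency floor for kept loci (default 0.01).
#' @param n_founders diploid founders sampled from the pool (default 2000).
#' @param n_panel parent-panel size selected by k-medoids (default 250).
#' @param qtl_per_chromosome QTLs per chromosome (default 2).
#' @param seed master seed; stage seeds are derived from it.
#' @return List of class `breeding_world` with elements `panel`
#'   ([population()]), `arch` ([trait_arch()]), `map` ([linkage_map()]), and
#'   `pool`.
#' @export
sim_world <- function(n_chromosomes = 10, markers_per_chromosome = 500,
                      length_cM = 1000, n_haplotypes = 4000,
                      candidate_loci = 2 * markers_per_chromosome,
                      maf_min = 0.01, n_founders = 2000, n_panel = 250,
                      qtl_per_chromosome = 2, seed = 1L) {
  map0 <- sim_linkage_map(n_chromosomes, candidate_loci, length_cM,
                          seed = child_seed(seed, 1))
  pool0 <- sim_founder_haplotypes(n_haplotypes, map0,
                                  seed = child_seed(seed, 2))
  fl <- filter_and_select_loci(pool0, map0, maf_min, markers_per_chromosome,
                               seed = child_seed(seed, 3))
  founders <- sample_founders(fl$pool, n_founders, seed = child_seed(seed, 4))
  prebreeding <- random_mate(founders, n_founders, fl$map,
                             seed = child_seed(seed, 5))
  panel <- select_parent_panel(prebreeding, n_panel,
                               seed = child_seed(seed, 6))
  arch <- sample_qtl_effects(assign_qtls(fl$map, qtl_per_chromosome,
                                         seed = child_seed(seed, 7)),
                             seed = child_seed(seed, 8))
  structure(list(panel = panel, arch = arch, map = fl$map, pool = fl$pool),
            class = "breeding_world")
}

#' @export
print.breeding_world <- function(x, ...) {
  cat(sprintf(
    "breeding world: panel of %d genotypes, %d markers on %d chromosomes, %d QTLs\n",
    pop_size(x$panel), nrow(x$map), length(unique(x$map$chromosome)),
    length(x$arch$qtl_indices)))
  invisible(x)
}

#' Optimize the progeny-allocation weight schedule of a breeding scheme
#'
#' The model-fitting front end of the package. Given a parent panel, trait
#' architecture and linkage map, it tunes the per-generation feature weights
#' `h(tau)` of the softmax progeny allocation (one weight per feature in
#' `config$feature_set`, per generation, each on `[0, 2]`) to maximize the
#' expected final genetic gain `g(T)`, estimated as the mean over `n_rep`
#' forward simulations of the scheme per candidate schedule. The noisy
#' black-box search is StoSOO ([stosoo_maximize()]), started from the
#' all-ones schedule (the domain center).
#'
#' @param world a [sim_world()] result, or any list with elements `panel`,
#'   `arch`, `map`.
#' @param config a [scheme_config()]; its `feature_set` defines the
#'   schedule's columns.
#' @param budget total objective evaluations (default 2000; the full-scale
#'   protocol uses 20000).
#' @param n_rep simulations per evaluation (default 50).
#' @param seed master seed.
#' @param trace_thin record every `trace_thin`-th incumbent.
#' @return Object of class `alloc_opt` with components `weights` (the fitted
#'   T x Q schedule), `value` (mean final gain at the recommendation),
#'   `fit` (the underlying [stosoo_maximize()] result), plus the world and
#'   config. Methods: `print`, `summary`, `coef`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' w <- sim_world(n_chromosomes = 2, markers_per_chromosome = 50,
#'                n_haplotypes = 200, n_founders = 200, n_panel = 30,
#'                seed = 7)
#' cfg <- scheme_config(n_pop = 60, n_sel = 8, feature_set = c("WBV", "GVP"))
#' fit <- optimize_allocation(w, cfg, budget = 100, n_rep = 5, seed = 7)
#' coef(fit)
#' }
#' @export
optimize_allocation <- function(world, config = scheme_config(),
                                budget = 2000, n_rep = 50, seed = 1L,
                                trace_thin = 1L) {
  stopifnot(all(c("panel", "arch", "map") %in% names(world)))
  if (length(config$feature_set) < 1) {
    stop("config$feature_set must name at least one allocation feature")
  }
  d <- config$n_generations * length(config$feature_set)
  obj <- make_gain_objective(world$panel, world$arch, world$map, config,
                             n_rep = n_rep, master_seed = child_seed(seed, 1))
  fit <- stosoo_maximize(obj, lower = rep(0, d), upper = rep(2, d),
                         budget = budget, seed = child_seed(seed, 2),
                         trace_thin = trace_thin)
  weights <- matrix(fit$par, nrow = config$n_generations,
                    ncol = length(config$feature_set), byrow = TRUE,
                    dimnames = list(
                      sprintf("tau%d", seq_len(config$n_generations) - 1L),
                      config$feature_set))
  structure(list(weights = weights, value = fit$value, fit = fit,
                 world = world, config = config, n_rep = n_rep,
                 budget = budget, seed = seed),
            class = "alloc_opt")
}

#' @export
print.alloc_opt <- function(x, ...) {
  cat("Optimized progeny-allocation weight schedule\n")
  cat(sprintf("  features: %s | generations: %d | %d evaluations x %d sims\n",
              paste(x$config$feature_set, collapse = ", "),
              x$config$n_generations, x$budget, x$n_rep))
  cat(sprintf("  expected final gain at optimum: %.4f\n", x$value))
  print(round(x$weights, 3))
  invisible(x)
}

#' @export
coef.alloc_opt <- function(object, ...) object$weights

#' @export
summary.alloc_opt <- function(object, n_schemes = 200, seed = 1L, ...) {
  strategies <- list(optimized = object$weights, EQ = NULL)
  rep <- run_comparison(object$world$panel, object$world$arch,
                        object$world$map, strategies, object$config,
                        n_schemes = n_schemes, seed = child_seed(seed, 99))
  out <- list(object = object, report = rep,
              mean_gain = colMeans(rep$gains),
              improvement_pct = 100 * (mean(rep$gains[, "optimized"]) -
                                       mean(rep$gains[, "EQ"])) /
                                mean(rep$gains[, "EQ"]))
  class(out) <- "summary.alloc_opt"
  out
}

#' @export
print.summary.alloc_opt <- function(x, ...) {
  print(x$object)
  cat(sprintf("\nEvaluation over %d paired schemes:\n", x$report$n_schemes))
  cat(sprintf("  mean final gain optimized: %.4f | equal allocation: %.4f\n",
              x$mean_gain["optimized"], x$mean_gain["EQ"]))
  cat(sprintf("  improvement over equal allocation: %.2f%%\n",
              x$improvement_pct))
  invisible(x)
}

#' @export
plot.alloc_opt <- function(x, ...) {
  graphics::plot(x$fit$trace$step, x$fit$trace$value, type = "s",
                 xlab = "objective evaluation",
                 ylab = "incumbent mean final gain",
                 main = "StoSOO convergence", ...)
  invisible(x)
}

#' Simulate breeding schemes under the fitted allocation policy
#'
#' @param object an [optimize_allocation()] fit.
#' @param nsim number of replicate schemes.
#' @param seed integer seed.
#' @param ... unused.
#' @return Data frame with one row per replicate: `gain` plus the top-mean
#'   genotypic value at each generation.
#' @export
simulate.alloc_opt <- function(object, nsim = 100, seed = 1L, ...) {
  tmax <- object$config$n_generations
  out <- matrix(NA_real_, nsim, tmax + 2L)
  for (r in seq_len(nsim)) {
    traj <- run_scheme(object$world$panel, object$world$arch,
                       object$world$map, object$config,
                       weights = object$weights,
                       seed = child_seed(seed, r))
    out[r, ] <- c(traj$gain, traj$u_top)
  }
  out <- as.data.frame(out)
  names(out) <- c("gain", sprintf("u_top_t%d", 0:tmax))
  out
}
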