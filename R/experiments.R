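#' Feature sets of the named allocation strategies
#'
#' Seven strategies are compared throughout: softmax allocation driven by
#' `BV` (breeding value), `WBV` (rare-allele-weighted breeding value), `TBV`
#' (both), each optionally with `GVP` (expected genetic variance of progeny),
#' plus the non-optimized equal allocation `EQ`.
#'
#' @param name one of `"BV"`, `"WBV"`, `"TBV"`, `"BVGVP"`, `"WBVGVP"`,
#'   `"TBVGVP"`, `"EQ"`.
#' @return Character vector of feature names, or `NULL` for `"EQ"`.
#' @export
strategy_features <- function(name) {
  sets <- list(BV = "BV", WBV = "WBV", TBV = c("BV", "WBV"),
               BVGVP = c("BV", "GVP"), WBVGVP = c("WBV", "GVP"),
               TBVGVP = c("BV", "WBV", "GVP"), EQ = NULL)
  if (!name %in% names(sets)) {
    stop("unknown strategy '", name, "'; valid: ",
         paste(names(sets), collapse = ", "))
  }
  sets[[name]]
}

#' Compare allocation strategies on a common world
#'
#' Runs `n_schemes` replicate breeding schemes per strategy with paired
#' seeds: replicate i uses the same derived seed for every strategy, so all
#' strategies face the same meiosis randomness up to the point where their
#' allocations diverge, isolating the allocation effect.
#'
#' @param panel,arch,map the world (see [run_scheme()]).
#' @param strategies named list: strategy name -> weight schedule matrix
#'   (T x Q in that strategy's feature order), or `NULL` for `"EQ"`.
#' @param config a [scheme_config()] (its `feature_set` is overridden per
#'   strategy).
#' @param n_schemes replicate schemes per strategy.
#' @param seed master seed for the paired replicate streams.
#' @return A list of class `strategy_report`: `gains` (n_schemes x strategy
#'   matrix of final gains), `mean_gain_by_gen` and `mean_variance_by_gen`
#'   ((T+1) x strategy matrices), `n_schemes`.
#' @export
run_comparison <- function(panel, arch, map, strategies,
                           config = scheme_config(), n_schemes = 100,
                           seed = 1L) {
  stopifnot(length(strategies) >= 1, !is.null(names(strategies)))
  tmax <- config$n_generations
  ns <- length(strategies)
  gains <- matrix(NA_real_, n_schemes, ns,
                  dimnames = list(NULL, names(strategies)))
  gen_gain <- gen_var <- matrix(0, tmax + 1L, ns,
                                dimnames = list(NULL, names(strategies)))
  for (s in seq_len(ns)) {
    nm <- names(strategies)[s]
    w <- strategies[[s]]
    cfg <- config
    if (!is.null(w)) {
      cfg$feature_set <- if (!is.null(colnames(w))) colnames(w)
                         else strategy_features(nm)
      if (ncol(w) != length(cfg$feature_set)) {
        stop("strategy '", nm, "': weight columns do not match its features")
      }
    } else if (nm != "EQ") {
      stop("optimized strategy '", nm, "' needs a weight schedule")
    }
    for (r in seq_len(n_schemes)) {
      traj <- run_scheme(panel, arch, map, cfg, weights = w,
                         seed = child_seed(seed, r))
      gains[r, s] <- traj$gain
      gen_gain[, s] <- gen_gain[, s] + (traj$u_top - traj$u_top[1L])
      gen_var[, s] <- gen_var[, s] + traj$variance
    }
  }
  structure(list(gains = gains,
                 mean_gain_by_gen = gen_gain / n_schemes,
                 mean_variance_by_gen = gen_var / n_schemes,
                 n_schemes = n_schemes),
            class = "strategy_report")
}

#' @export
print.strategy_report <- function(x, ...) {
  cat(sprintf("strategy comparison over %d replicate schemes\n", x$n_schemes))
  print(round(colMeans(x$gains), 4))
  invisible(x)
}

#' Empirical CDF of the final gain of a strategy
#'
#' @param report a [run_comparison()] result.
#' @param strategy strategy name.
#' @return A step function (`stats::ecdf`).
#' @export
gain_cdf <- function(report, strategy) {
  stats::ecdf(report$gains[, strategy])
}

#' Fraction of replicate schemes with final gain above a threshold
#'
#' @param report a [run_comparison()] result.
#' @param threshold gain threshold.
#' @return Named numeric vector, one fraction per strategy.
#' @export
fraction_above <- function(report, threshold) {
  colMeans(report$gains > threshold)
}

#' Improvement-rate table across trait replicates
#'
#' For each trait replicate and strategy, the improvement of the mean final
#' gain over the baseline, `100 * (mean_g - mean_g_base) / mean_g_base`,
#' summarized as min / mean / max across replicates.
#'
#' @param reports list of [run_comparison()] results, one per trait
#'   replicate, each containing the baseline strategy.
#' @param baseline baseline strategy name (default `"EQ"`).
#' @return Data frame with columns `strategy`, `min`, `mean`, `max`
#'   (percent). Replicates with zero baseline mean gain are dropped with a
#'   warning.
#' @export
improvement_table <- function(reports, baseline = "EQ") {
  stopifnot(length(reports) >= 1)
  strategies <- setdiff(colnames(reports[[1L]]$gains), baseline)
  rates <- sapply(reports, function(rep) {
    g <- colMeans(rep$gains)
    if (!baseline %in% names(g)) stop("baseline '", baseline, "' missing")
    if (g[baseline] == 0) return(rep(NA_real_, length(strategies)))
    100 * (g[strategies] - g[baseline]) / g[baseline]
  })
  rates <- matrix(rates, nrow = length(strategies),
                  dimnames = list(strategies, NULL))
  if (anyNA(rates)) {
    warning("replicate(s) with zero baseline mean gain dropped")
  }
  safe <- function(f) function(x) if (all(is.na(x))) NA_real_ else f(x, na.rm = TRUE)
  data.frame(strategy = strategies,
             min = apply(rates, 1L, safe(min)),
             mean = apply(rates, 1L, safe(mean)),
             max = apply(rates, 1L, safe(max)),
             row.names = NULL)
}
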