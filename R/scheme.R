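#' Breeding-scheme configuration
#'
#' Defaults describe a small recurrent genomic-selection program: 250
#' progenies per generation, 15 selected parents (hence 120 diallel pairs
#' including selfings), evaluation on the best 5 genotypes, and 4 generations.
#'
#' @param n_pop progenies per generation (default 250).
#' @param n_sel selected parent candidates per generation (default 15).
#' @param n_top genotypes averaged for the outcome evaluation (default 5).
#' @param n_generations final generation T (default 4).
#' @param selection_criterion criterion for the selection step, `"WBV"`
#'   (default, maintains diversity) or `"BV"`.
#' @param feature_set allocation features, a subset of `c("BV","WBV","GVP")`.
#' @param standardize_features z-score the feature columns across pairs
#'   (default `TRUE`; the three features live on incommensurate scales).
#' @return A list of class `scheme_config`.
#' @export
scheme_config <- function(n_pop = 250, n_sel = 15, n_top = 5,
                          n_generations = 4,
                          selection_criterion = c("WBV", "BV"),
                          feature_set = c("BV", "WBV", "GVP"),
                          standardize_features = TRUE) {
  selection_criterion <- match.arg(selection_criterion)
  if (n_top > n_pop) stop("n_top must not exceed n_pop")
  if (n_sel > n_pop) stop("n_sel must not exceed n_pop")
  if (n_generations < 1) stop("n_generations must be at least 1")
  bad <- setdiff(feature_set, c("BV", "WBV", "GVP"))
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  structure(list(n_pop = as.integer(n_pop), n_sel = as.integer(n_sel),
                 n_top = as.integer(n_top),
                 n_generations = as.integer(n_generations),
                 selection_criterion = selection_criterion,
                 feature_set = feature_set,
                 standardize_features = isTRUE(standardize_features)),
            class = "scheme_config")
}

#' Truncation selection of parent candidates
#'
#' Keeps the `n_sel` individuals with the highest criterion values; ties are
#' broken by position in the population (deterministic).
#'
#' @param pop a [population()].
#' @param criterion numeric vector, one value per individual.
#' @param n_sel number of candidates to keep.
#' @return A [population()] of the selected candidates, in rank order.
#' @export
select_parents <- function(pop, criterion, n_sel) {
  if (n_sel > pop_size(pop)) stop("n_sel exceeds population size")
  if (length(criterion) != pop_size(pop)) {
    stop("criterion must have one value per individual")
  }
  keep <- order(-criterion, seq_along(criterion))[seq_len(n_sel)]
  subset_population(pop, keep)
}

#' Diallel mating pairs, selfings included
#'
#' All unordered pairs of candidates, `n (n + 1) / 2` in total, each annotated
#' with the mean parental criterion value (the expected progeny value under
#' additivity).
#'
#' @param candidates a [population()] of parent candidates.
#' @param criterion numeric vector per candidate used for
#'   `expected_pair_wbv`; defaults to zeros when not supplied.
#' @return A `data.frame` of class `cross_plan` with columns `mother`,
#'   `father` (indices into `candidates`), `mother_id`, `father_id`,
#'   `expected_pair_wbv`.
#' @export
make_diallel_pairs <- function(candidates, criterion = NULL) {
  n <- pop_size(candidates)
  if (n < 1) stop("no candidates")
  if (is.null(criterion)) criterion <- numeric(n)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  plan <- data.frame(mother = idx[, 1L], father = idx[, 2L])
  plan$mother_id <- candidates$ids[plan$mother]
  plan$father_id <- candidates$ids[plan$father]
  plan$expected_pair_wbv <- (criterion[plan$mother] + criterion[plan$father]) / 2
  class(plan) <- c("cross_plan", "data.frame")
  plan
}

#' Feature matrix of mating pairs
#'
#' One row per mating pair, one column per requested feature: `BV` and `WBV`
#' columns are the means of the two parents' values (equal to the expected
#' progeny value under additive effects), and `GVP` is the expected genetic
#' variance of progeny of the cross ([expected_gvp()]). Columns are z-scored
#' across pairs when `standardize` is `TRUE`; a zero-variance column becomes
#' all zeros.
#'
#' @param plan a [make_diallel_pairs()] plan over `candidates`.
#' @param candidates the candidate [population()].
#' @param arch a [trait_arch()] with effects set.
#' @param map the [linkage_map()].
#' @param feature_set subset of `c("BV", "WBV", "GVP")`.
#' @param standardize z-score columns (default `TRUE`).
#' @param freqs optional QTL allele frequencies for the WBV column (from the
#'   population the candidates were selected out of).
#' @param kernel optional precomputed [gvp_kernel()].
#' @return Numeric matrix `n_pairs` x `length(feature_set)` with named
#'   columns.
#' @export
build_feature_matrix <- function(plan, candidates, arch, map,
                                 feature_set = c("BV", "WBV", "GVP"),
                                 standardize = TRUE, freqs = NULL,
                                 kernel = NULL) {
  bad <- setdiff(feature_set, c("BV", "WBV", "GVP"))
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))
  cols <- lapply(feature_set, function(f) {
    if (f == "BV") {
      u <- breeding_values(candidates, arch)
      (u[plan$mother] + u[plan$father]) / 2
    } else if (f == "WBV") {
      u <- weighted_breeding_values(candidates, arch, freqs)
      (u[plan$mother] + u[plan$father]) / 2
    } else {
      s <- segregation_variances(candidates, arch, map, kernel)
      s[plan$mother] + s[plan$father]
    }
  })
  omega <- do.call(cbind, cols)
  colnames(omega) <- feature_set
  rownames(omega) <- NULL
  if (standardize) {
    omega <- apply(omega, 2L, function(x) {
      s <- stats::sd(x)
      if (s > 0) (x - mean(x)) / s else rep(0, length(x))
    })
    colnames(omega) <- feature_set
  }
  if (any(!is.finite(omega))) stop("non-finite feature values")
  omega
}

#' Softmax allocation of progenies to mating pairs
#'
#' Pair scores are the weighted feature sums `s = omega %*% h`; progeny
#' counts are `b = floor(n_pop * softmax(s))`, and the deficit
#' `n_pop - sum(b)` (at most `n_pairs - 1`) is distributed one progeny each
#' to the pairs with the largest fractional parts, ties broken by descending
#' expected pair WBV and then pair order. With `h = 0` this reproduces
#' [allocate_equal()] exactly.
#'
#' @param plan a `cross_plan`.
#' @param omega feature matrix from [build_feature_matrix()].
#' @param h weight vector, one non-negative entry per feature column.
#' @param n_pop total progeny budget.
#' @return A `crossing_table`: the plan plus columns `softmax_probability`
#'   and `n_progeny` (summing exactly to `n_pop`).
#' @export
allocate_softmax <- function(plan, omega, h, n_pop) {
  if (length(h) != ncol(omega)) stop("h must have one entry per feature")
  s <- drop(omega %*% h)
  if (any(!is.finite(s))) stop("non-finite allocation scores")
  e <- exp(s - max(s))
  prob <- e / sum(e)
  finish_allocation(plan, prob, n_pop)
}

#' Equal allocation of progenies to mating pairs
#'
#' Every pair receives `floor(n_pop / n_pairs)` progenies; the remainder goes
#' one each to the pairs with the highest expected pair WBV. With the default
#' scheme (250 progenies over 120 pairs) this allocates 3 progenies to each
#' of the 10 best pairs and 2 to the remaining 110.
#'
#' @param plan a `cross_plan`.
#' @param n_pop total progeny budget.
#' @return A `crossing_table` (see [allocate_softmax()]).
#' @export
allocate_equal <- function(plan, n_pop) {
  finish_allocation(plan, rep(1 / nrow(plan), nrow(plan)), n_pop)
}

# Shared floor + largest-fractional-part remainder rule. Ties on the
# fractional part fall to higher expected pair WBV, then pair order, which
# makes softmax with h = 0 coincide with equal allocation bit for bit.
finish_allocation <- function(plan, prob, n_pop) {
  x <- n_pop * prob
  b <- floor(x)
  deficit <- n_pop - sum(b)
  if (deficit > 0) {
    frac <- x - b
    pick <- order(-frac, -plan$expected_pair_wbv,
                  seq_len(nrow(plan)))[seq_len(deficit)]
    b[pick] <- b[pick] + 1
  }
  out <- plan
  out$softmax_probability <- prob
  out$n_progeny <- as.integer(b)
  class(out) <- c("crossing_table", class(plan))
  out
}

#' Simulate one gamete by Kosambi-map meiosis
#'
#' Per chromosome, the source haplotype starts uniform and switches between
#' adjacent markers with their Kosambi recombination fraction; chromosomes
#' segregate independently. Uses the ambient RNG stream.
#'
#' @param pop a [population()].
#' @param parent index of the parent in `pop`.
#' @param map the [linkage_map()], or a precomputed [recomb_fractions()]
#'   vector.
#' @param n number of gametes.
#' @return Binary matrix `n` x M of gamete haplotypes.
#' @export
make_gametes <- function(pop, parent, map, n = 1L) {
  rec <- if (inherits(map, "linkage_map")) recomb_fractions(map) else map
  cpp_gametes(pop$hap_a, pop$hap_b, rep_len(as.integer(parent) - 1L, n), rec)
}

#' Advance one generation from a crossing table
#'
#' Each progeny of a pair receives one gamete from each parent by
#' [make_gametes()] meiosis. Uses the ambient RNG stream.
#'
#' @param pop a [population()] containing all listed parents.
#' @param table a `crossing_table` whose `mother_id` / `father_id` resolve in
#'   `pop`.
#' @param map the [linkage_map()].
#' @return A [population()] of `sum(table$n_progeny)` progenies with the
#'   generation index incremented.
#' @export
advance_generation <- function(pop, table, map) {
  mothers <- match(table$mother_id, pop$ids)
  fathers <- match(table$father_id, pop$ids)
  if (anyNA(mothers) || anyNA(fathers)) {
    stop("crossing table refers to parents absent from the population")
  }
  rec <- if (inherits(map, "linkage_map")) recomb_fractions(map) else map
  mvec <- rep(mothers, table$n_progeny)
  fvec <- rep(fathers, table$n_progeny)
  ha <- cpp_gametes(pop$hap_a, pop$hap_b, mvec - 1L, rec)
  hb <- cpp_gametes(pop$hap_a, pop$hap_b, fvec - 1L, rec)
  population(ha, hb, generation = pop$generation + 1L)
}

#' Mean true genotypic value of the top genotypes
#'
#' @param pop a [population()].
#' @param arch a [trait_arch()] with effects set.
#' @param n_top number of top genotypes averaged (default 5).
#' @return Mean of the `n_top` highest true genotypic values.
#' @export
top_mean_tgv <- function(pop, arch, n_top = 5) {
  u <- breeding_values(pop, arch)
  mean(sort(u, decreasing = TRUE)[seq_len(min(n_top, length(u)))])
}

#' Run one breeding scheme
#'
#' Executes `n_generations` rounds of: WBV truncation selection of `n_sel`
#' parents, diallel pairing with selfings, progeny allocation (softmax with
#' the generation's weight vector, or equal allocation), and meiosis to the
#' next generation of `n_pop` progenies. Records, for each generation
#' 0..T, the top-`n_top` mean true genotypic value and the population
#' genetic variance, and the final gain
#' `g(T) = u_top(T) - u_top(0)`.
#'
#' @param panel the generation-0 parent panel ([population()]).
#' @param arch a [trait_arch()] with effects set.
#' @param map the [linkage_map()].
#' @param config a [scheme_config()].
#' @param weights `NULL` for equal allocation, else a T x Q matrix of
#'   per-generation feature weights (rows `tau = 0..T-1`, columns in
#'   `config$feature_set` order) with entries in `[0, 2]`.
#' @param seed optional integer seed; when `NULL` the ambient RNG stream is
#'   used.
#' @param keep_tables record the per-generation crossing tables (default
#'   `FALSE`).
#' @return A list of class `trajectory`: `u_top`, `variance` (length T+1),
#'   `qtl_freq` ((T+1) x n_QTL), `gain`, and optionally `tables`.
#' @export
run_scheme <- function(panel, arch, map, config = scheme_config(),
                       weights = NULL, seed = NULL, keep_tables = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (nrow(weights) != config$n_generations ||
        ncol(weights) != length(config$feature_set)) {
      stop("weights must be n_generations x length(feature_set)")
    }
  }
  rec <- recomb_fractions(map)
  kernel <- gvp_kernel(map, arch)
  tmax <- config$n_generations
  u_top <- variance <- numeric(tmax + 1L)
  qtl_freq <- matrix(NA_real_, tmax + 1L, length(arch$qtl_indices))
  tables <- if (keep_tables) vector("list", tmax) else NULL
  pop <- panel
  for (t in 0:tmax) {
    u_top[t + 1L] <- top_mean_tgv(pop, arch, config$n_top)
    variance[t + 1L] <- genetic_variance(pop, arch)
    qtl_freq[t + 1L, ] <- allele_frequencies(pop, arch$qtl_indices)
    if (t == tmax) break
    freqs <- qtl_freq[t + 1L, ]
    crit <- if (config$selection_criterion == "WBV") {
      weighted_breeding_values(pop, arch, freqs)
    } else {
      breeding_values(pop, arch)
    }
    cand <- select_parents(pop, crit, config$n_sel)
    cand_wbv <- weighted_breeding_values(cand, arch, freqs)
    plan <- make_diallel_pairs(cand, cand_wbv)
    table <- if (is.null(weights)) {
      allocate_equal(plan, config$n_pop)
    } else {
      omega <- build_feature_matrix(plan, cand, arch, map,
                                    config$feature_set,
                                    config$standardize_features,
                                    freqs = freqs, kernel = kernel)
      allocate_softmax(plan, omega, weights[t + 1L, ], config$n_pop)
    }
    if (keep_tables) tables[[t + 1L]] <- table
    pop <- advance_generation(cand, table, rec)
  }
  structure(list(u_top = u_top, variance = variance, qtl_freq = qtl_freq,
                 gain = u_top[tmax + 1L] - u_top[1L], tables = tables),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("breeding trajectory over %d generations: final gain %.4f\n",
              length(x$u_top) - 1L, x$gain))
  invisible(x)
}

#' Read / write a crossing table as CSV
#'
#' Columns: `mother_id`, `father_id`, `n_progeny`, `expected_pair_wbv`,
#' `softmax_probability` — the continuous allocation information a breeder
#' can act on beyond the integer counts.
#'
#' @param table a `crossing_table`.
#' @param path file path.
#' @return `read_crossing_table` returns a `crossing_table`; the writer
#'   returns `path` invisibly.
#' @export
write_crossing_table <- function(table, path) {
  utils::write.csv(table[, c("mother_id", "father_id", "n_progeny",
                             "expected_pair_wbv", "softmax_probability")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_crossing_table
#' @export
read_crossing_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mother_id", "father_id", "n_progeny", "expected_pair_wbv",
            "softmax_probability")
  if (!all(need %in% names(df))) {
    stop("crossing-table CSV is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  class(df) <- c("crossing_table", "cross_plan", "data.frame")
  df
}
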