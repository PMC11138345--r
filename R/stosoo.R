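#' StoSOO: stochastic simultaneous optimistic optimization
#'
#' Budgeted global maximization of a noisy black-box function on a
#' hyper-rectangle by optimistic tree search. The domain is recursively
#' trisected along the longest side; each cell is represented by its center,
#' whose noisy function value is averaged over repeated samples, and cells
#' are selected optimistically by an upper confidence bound
#' `b = mean + sqrt(log(n * k / delta) / (2 * count))`. Per sweep over
#' depths, the leaf with the highest b-value at each depth is re-sampled
#' while its count is below `k`, or expanded into 3 children otherwise;
#' children start unevaluated (the middle child keeps the parent's center
#' but is sampled afresh). Defaults follow
#' the standard StoSOO analysis: `k = max(1, floor(n / log(n)^3))`,
#' `delta = 1 / sqrt(n)`, `h_max = floor(sqrt(n / k))`.
#'
#' @param objective function of a numeric vector returning one noisy value.
#' @param lower,upper domain bounds (recycled to a common dimension).
#' @param budget total number of objective evaluations `n`.
#' @param k maximum samples per node.
#' @param delta confidence parameter.
#' @param h_max maximum tree depth.
#' @param seed optional seed set before the first evaluation.
#' @param trace_thin record every `trace_thin`-th incumbent (default 1 =
#'   every evaluation).
#' @param return_tree also return the partition tree (cell bounds, centers,
#'   depths, counts, means) for inspection.
#' @return A list of class `stosoo` with elements `par` (recommended point:
#'   the deepest fully-sampled node, ties by count then mean), `value` (its
#'   empirical mean), `n_eval`, and `trace` (data frame of evaluation step,
#'   incumbent value, and incumbent coordinates).
#' @examples
#' f <- function(x) -(x - 0.5)^2 + rnorm(1, 0, 0.01)
#' fit <- stosoo_maximize(f, 0, 2, budget = 500, seed = 1)
#' fit$par
#' @export
stosoo_maximize <- function(objective, lower = 0, upper = 2, budget = 1000,
                            k = NULL, delta = NULL, h_max = NULL,
                            seed = NULL, trace_thin = 1L,
                            return_tree = FALSE) {
  if (budget < 1) stop("budget must be at least 1")
  d <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), d)
  upper <- rep_len(as.numeric(upper), d)
  if (any(upper <= lower)) stop("upper must exceed lower")
  if (is.null(k)) k <- max(1L, floor(budget / log(budget)^3))
  if (is.null(delta)) delta <- 1 / sqrt(budget)
  if (is.null(h_max)) h_max <- max(1L, floor(sqrt(budget / k)))
  if (!is.null(seed)) set.seed(seed)
  conf_num <- log(budget * k / delta)

  cap <- 1024L
  lo <- matrix(NA_real_, cap, d); hi <- matrix(NA_real_, cap, d)
  ctr <- matrix(NA_real_, cap, d)
  depth <- integer(cap); count <- integer(cap); total <- numeric(cap)
  leaf <- logical(cap)
  n_nodes <- 1L
  lo[1L, ] <- lower; hi[1L, ] <- upper; ctr[1L, ] <- (lower + upper) / 2
  depth[1L] <- 0L; count[1L] <- 0L; total[1L] <- 0; leaf[1L] <- TRUE

  grow <- function() {
    if (n_nodes + 3L > cap) {
      newcap <- cap * 2L
      lo <<- rbind(lo, matrix(NA_real_, cap, d))
      hi <<- rbind(hi, matrix(NA_real_, cap, d))
      ctr <<- rbind(ctr, matrix(NA_real_, cap, d))
      depth <<- c(depth, integer(cap)); count <<- c(count, integer(cap))
      total <<- c(total, numeric(cap)); leaf <<- c(leaf, logical(cap))
      cap <<- newcap
    }
  }

  n_eval <- 0L
  tr_step <- integer(0); tr_value <- numeric(0)
  tr_par <- matrix(numeric(0), 0L, d)
  best_node <- 1L

  # Deepest fully-sampled node (count >= k, i.e. nodes whose statistics
  # were validated before expansion is allowed), ties by count then mean.
  recommend <- function() {
    act <- which(count[seq_len(n_nodes)] > 0L)
    if (!length(act)) return(1L)
    thr <- min(k, max(count[act]))
    act <- act[count[act] >= thr]
    means <- total[act] / count[act]
    o <- order(-depth[act], -count[act], -means, act)
    act[o[1L]]
  }

  sample_node <- function(i) {
    v <- objective(ctr[i, ])
    count[i] <<- count[i] + 1L; total[i] <<- total[i] + v
    n_eval <<- n_eval + 1L
    best_node <<- recommend()
    if (n_eval %% trace_thin == 0L || n_eval == budget) {
      tr_step <<- c(tr_step, n_eval)
      tr_value <<- c(tr_value, total[best_node] / count[best_node])
      tr_par <<- rbind(tr_par, ctr[best_node, ])
    }
  }

  expand_node <- function(i) {
    grow()
    span <- hi[i, ] - lo[i, ]
    j <- which.max(span)          # longest side, lowest index on ties
    third <- span[j] / 3
    for (c3 in 0:2) {
      nn <- n_nodes + 1L
      lo[nn, ] <<- lo[i, ]; hi[nn, ] <<- hi[i, ]
      lo[nn, j] <<- lo[i, j] + c3 * third
      hi[nn, j] <<- lo[i, j] + (c3 + 1) * third
      ctr[nn, ] <<- (lo[nn, ] + hi[nn, ]) / 2
      depth[nn] <<- depth[i] + 1L; leaf[nn] <<- TRUE
      if (c3 == 1L) ctr[nn, ] <<- ctr[i, ]  # middle child keeps the center
      # children start unevaluated: fresh samples at every depth keep a
      # noise-favored branch from cascading on stale statistics
      count[nn] <<- 0L; total[nn] <<- 0
      n_nodes <<- nn
    }
    leaf[i] <<- FALSE
  }

  b_value <- function(idx) {
    ifelse(count[idx] == 0L, Inf,
           total[idx] / count[idx] + sqrt(conf_num / (2 * count[idx])))
  }

  while (n_eval < budget) {
    v_max <- -Inf
    acted <- FALSE
    for (h in 0:min(max(depth[seq_len(n_nodes)]), h_max)) {
      if (n_eval >= budget) break
      at <- which(leaf[seq_len(n_nodes)] & depth[seq_len(n_nodes)] == h)
      if (!length(at)) next
      b <- b_value(at)
      i <- at[order(-b, at)[1L]]
      if (b[order(-b, at)[1L]] >= v_max) {
        if (count[i] < k) {
          sample_node(i)
          acted <- TRUE
        } else if (h < h_max) {
          v_max <- b_value(i)
          expand_node(i)
          acted <- TRUE
        }
      }
    }
    if (!acted) {
      # every selectable leaf saturated at h_max: keep sampling the best one
      at <- which(leaf[seq_len(n_nodes)])
      b <- b_value(at)
      sample_node(at[order(-b, at)[1L]])
    }
  }

  rec <- recommend()
  trace <- data.frame(step = tr_step, value = tr_value)
  colnames(tr_par) <- sprintf("x%d", seq_len(d))
  trace <- cbind(trace, as.data.frame(tr_par))
  out <- list(par = ctr[rec, ], value = total[rec] / count[rec],
              n_eval = n_eval, trace = trace,
              settings = list(budget = budget, k = k, delta = delta,
                              h_max = h_max, lower = lower, upper = upper))
  if (return_tree) {
    keep <- seq_len(n_nodes)
    out$tree <- list(lo = lo[keep, , drop = FALSE],
                     hi = hi[keep, , drop = FALSE],
                     ctr = ctr[keep, , drop = FALSE],
                     depth = depth[keep], count = count[keep],
                     mean = ifelse(count[keep] > 0,
                                   total[keep] / pmax(count[keep], 1L), NA),
                     leaf = leaf[keep])
  }
  structure(out, class = "stosoo")
}

#' @export
print.stosoo <- function(x, ...) {
  cat(sprintf("StoSOO: %d evaluations, recommended mean %.4f at\n  (%s)\n",
              x$n_eval, x$value, paste(signif(x$par, 4), collapse = ", ")))
  invisible(x)
}

#' Noisy mean-final-gain objective for a breeding scheme
#'
#' Builds the black-box objective StoSOO maximizes: a flattened weight
#' schedule (length `T x Q`, rows of the schedule concatenated by
#' generation) is scored by the empirical mean final gain over `n_rep`
#' independent breeding-scheme simulations. Each evaluation consumes a child
#' seed derived deterministically from `master_seed` and an internal
#' evaluation counter, so a given evaluation index is reproducible
#' regardless of optimizer state.
#'
#' @param panel,arch,map,config the scheme world (see [run_scheme()]).
#' @param n_rep simulations averaged per evaluation (default 50).
#' @param master_seed integer master seed.
#' @return Function mapping a weight vector to a mean final gain; the
#'   attribute `"counter_env"` exposes the evaluation counter.
#' @export
make_gain_objective <- function(panel, arch, map, config = scheme_config(),
                                n_rep = 50, master_seed = 1L) {
  tmax <- config$n_generations
  q <- length(config$feature_set)
  env <- new.env(parent = emptyenv())
  env$counter <- 0L
  f <- function(h) {
    if (length(h) != tmax * q) stop("weight vector has wrong length")
    env$counter <- env$counter + 1L
    w <- matrix(h, nrow = tmax, ncol = q, byrow = TRUE)
    gains <- vapply(seq_len(n_rep), function(r) {
      set.seed(child_seed(master_seed, env$counter, r))
      run_scheme(panel, arch, map, config, weights = w)$gain
    }, numeric(1))
    mean(gains)
  }
  attr(f, "counter_env") <- env
  f
}

#' Re-evaluate the incumbents of an optimization trace
#'
#' Independently re-scores each recorded incumbent with a fresh objective
#' (typically [make_gain_objective()] with a different master seed),
#' producing the convergence curve of the optimization.
#'
#' @param fit a [stosoo_maximize()] result.
#' @param objective function of a parameter vector.
#' @param thin re-evaluate every `thin`-th trace row (default 1).
#' @return Data frame with columns `step` and `value`.
#' @export
reevaluate_trace <- function(fit, objective, thin = 1L) {
  if (nrow(fit$trace) < 1) stop("empty trace")
  rows <- unique(c(seq(1L, nrow(fit$trace), by = thin), nrow(fit$trace)))
  pars <- as.matrix(fit$trace[rows, -(1:2), drop = FALSE])
  data.frame(step = fit$trace$step[rows],
             value = apply(pars, 1L, objective))
}

#' Read / write a weight schedule as JSON
#'
#' Format: `{T, Q, feature_names, h}` with `h` a T x Q matrix (rows are
#' generations).
#'
#' @param weights T x Q matrix of feature weights.
#' @param feature_names column labels.
#' @param path file path.
#' @return `read_weight_schedule` returns the matrix (features as column
#'   names); the writer returns `path` invisibly.
#' @export
write_weight_schedule <- function(weights, feature_names, path) {
  weights <- as.matrix(weights)
  jsonlite::write_json(list(T = nrow(weights), Q = ncol(weights),
                            feature_names = feature_names,
                            h = weights),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_weight_schedule
#' @export
read_weight_schedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- matrix(as.numeric(x$h), nrow = x$T, ncol = x$Q)
  colnames(h) <- x$feature_names
  h
}

# Deterministic child seeds below 2^31 from a master seed and indices.
child_seed <- function(master, ...) {
  s <- as.double(master) %% 2147483647
  for (i in c(...)) {
    s <- (s * 69069 + as.double(i) * 104729 + 1) %% 2147483647
  }
  as.integer(s)
}
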