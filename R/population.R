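#' Construct a diploid population of phased genotypes
#'
#' A population stores the two phased haplotypes of each individual as binary
#' (0/1) allele matrices of dimension N x M, a generation index, and unique
#' individual ids. The marker dosage used throughout is
#' `hap_a + hap_b - 1` with values in \{-1, 0, 1\}.
#'
#' @param hap_a,hap_b integer 0/1 matrices (individuals x markers).
#' @param generation non-negative integer generation index.
#' @param ids unique character labels, one per individual.
#' @return An object of class `population`.
#' @export
population <- function(hap_a, hap_b, generation = 0L, ids = NULL) {
  hap_a <- as.matrix(hap_a); hap_b <- as.matrix(hap_b)
  storage.mode(hap_a) <- "integer"; storage.mode(hap_b) <- "integer"
  if (!identical(dim(hap_a), dim(hap_b))) {
    stop("hap_a and hap_b must have identical dimensions")
  }
  if (!all(hap_a %in% c(0L, 1L)) || !all(hap_b %in% c(0L, 1L))) {
    stop("haplotype alleles must be coded 0/1")
  }
  if (generation < 0) stop("generation must be non-negative")
  if (is.null(ids)) ids <- sprintf("g%d_i%d", generation, seq_len(nrow(hap_a)))
  if (length(ids) != nrow(hap_a) || anyDuplicated(ids)) {
    stop("ids must be unique, one per individual")
  }
  structure(list(hap_a = hap_a, hap_b = hap_b,
                 generation = as.integer(generation),
                 ids = as.character(ids)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("population: %d individuals x %d markers (generation %d)\n",
              nrow(x$hap_a), ncol(x$hap_a), x$generation))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a [population()].
#' @return Integer count.
#' @export
pop_size <- function(pop) nrow(pop$hap_a)

#' Marker dosage matrix of a population
#'
#' @param pop a [population()].
#' @param at optional marker indices to restrict to.
#' @return Integer matrix with entries in \{-1, 0, 1\}.
#' @export
dosage <- function(pop, at = NULL) {
  w <- pop$hap_a + pop$hap_b - 1L
  rownames(w) <- pop$ids
  if (!is.null(at)) w <- w[, at, drop = FALSE]
  w
}

#' Extract a subset of individuals
#' @param pop a [population()].
#' @param idx integer or logical index of individuals.
#' @param generation optional new generation tag (defaults to `pop`'s).
#' @return A [population()].
#' @export
subset_population <- function(pop, idx, generation = pop$generation) {
  population(pop$hap_a[idx, , drop = FALSE], pop$hap_b[idx, , drop = FALSE],
             generation = generation, ids = pop$ids[idx])
}

#' Read / write populations and haplotype pools as CSV
#'
#' One row per haplotype with 0/1 allele columns; populations are written as
#' paired rows per individual (`<id>_a`, `<id>_b` in the `haplotype` column).
#'
#' @param pop a [population()].
#' @param path file path.
#' @return `read_population` returns a [population()]; writers return `path`
#'   invisibly.
#' @export
write_population <- function(pop, path) {
  n <- pop_size(pop)
  m <- ncol(pop$hap_a)
  x <- matrix(0L, 2L * n, m)
  x[seq(1L, 2L * n, by = 2L), ] <- pop$hap_a
  x[seq(2L, 2L * n, by = 2L), ] <- pop$hap_b
  df <- data.frame(haplotype = paste0(rep(pop$ids, each = 2L), c("_a", "_b")),
                   x)
  names(df)[-1L] <- sprintf("m%d", seq_len(m))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @param generation generation tag for the population read back.
#' @export
read_population <- function(path, generation = 0L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(x) <- NULL
  if (nrow(x) %% 2L != 0L) stop("population CSV must contain paired rows")
  a <- seq(1L, nrow(x), by = 2L)
  ids <- sub("_a$", "", df$haplotype[a])
  population(x[a, , drop = FALSE], x[a + 1L, , drop = FALSE],
             generation = generation, ids = ids)
}

#' @rdname write_population
#' @param pool binary haplotype matrix (haplotypes x markers).
#' @export
write_haplotypes <- function(pool, path) {
  df <- data.frame(haplotype = sprintf("h%d", seq_len(nrow(pool))), pool)
  names(df)[-1L] <- sprintf("m%d", seq_len(ncol(pool)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_haplotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(x) <- "integer"
  if (!all(x %in% c(0L, 1L))) stop("haplotype CSV entries must be 0/1")
  dimnames(x) <- NULL
  x
}
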