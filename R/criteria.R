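#' Breeding values (true genotypic values)
#'
#' The breeding value of individual i is the dot product of its marker dosage
#' (-1/0/1) at the QTLs with the additive effects:
#' `u_i = sum_m w_im * alpha_m`. With true effects, as used throughout this
#' package, the breeding value equals the true genotypic value.
#'
#' @param pop a [population()].
#' @param arch a [trait_arch()] with effects set.
#' @return Named numeric vector, one value per individual.
#' @export
breeding_values <- function(pop, arch) {
  stopifnot(inherits(arch, "trait_arch"))
  if (is.null(arch$effects)) stop("trait effects are unset")
  if (max(arch$qtl_indices) > ncol(pop$hap_a)) {
    stop("trait architecture refers to markers outside the population")
  }
  drop(dosage(pop, arch$qtl_indices) %*% arch$effects)
}

#' Frequency of the 1-coded allele at each marker
#'
#' @param pop a [population()].
#' @param at optional marker indices.
#' @return Numeric vector of allele frequencies in `[0, 1]`.
#' @export
allele_frequencies <- function(pop, at = NULL) {
  if (pop_size(pop) < 1) stop("population is empty")
  (colMeans(dosage(pop, at)) + 1) / 2
}

#' Weighted breeding values
#'
#' Breeding values with each QTL effect scaled by the inverse square root of
#' the frequency of its favorable allele (the allele whose addition increases
#' the trait): `u_i = sum_m w_im * alpha_m * p_m^(-1/2)`. Rare favorable
#' alleles are up-weighted, which maintains diversity when the criterion
#' drives selection. A favorable allele that is absent (`p = 0`) contributes
#' 0: its term is constant across individuals and cannot affect ranking.
#'
#' @param pop a [population()].
#' @param arch a [trait_arch()] with effects set.
#' @param freqs optional 1-allele frequencies at the QTLs (as from
#'   [allele_frequencies()] on the same population); computed when missing.
#' @return Named numeric vector, one value per individual.
#' @export
weighted_breeding_values <- function(pop, arch, freqs = NULL) {
  stopifnot(inherits(arch, "trait_arch"))
  if (is.null(arch$effects)) stop("trait effects are unset")
  if (is.null(freqs)) freqs <- allele_frequencies(pop, arch$qtl_indices)
  if (length(freqs) != length(arch$qtl_indices)) {
    stop("freqs must have one entry per QTL")
  }
  p_fav <- ifelse(arch$effects >= 0, freqs, 1 - freqs)
  wt <- ifelse(p_fav > 0, 1 / sqrt(pmax(p_fav, .Machine$double.eps)), 0)
  drop(dosage(pop, arch$qtl_indices) %*% (arch$effects * wt))
}

#' Population genetic variance of true genotypic values
#'
#' @param pop a [population()].
#' @param arch a [trait_arch()] with effects set.
#' @return Population variance (denominator N) of the true genotypic values.
#' @export
genetic_variance <- function(pop, arch) {
  u <- breeding_values(pop, arch)
  mean((u - mean(u))^2)
}

#' Linkage kernel for progeny-variance computations
#'
#' Precomputes the QTL-by-QTL matrix of linkage factors `1 - 2 r`, where `r`
#' is the recombination fraction between two QTLs realized by map-based
#' meiosis, and the factor is 0 across chromosomes (independent
#' segregation). Meiosis walks the marker sequence, switching the source
#' haplotype between adjacent markers with the Kosambi fraction of their
#' distance; under this Markov walk the linkage factor between any two
#' markers is the product of the adjacent-interval factors separating them,
#' so the kernel is built from the cumulative log-linkage along each
#' chromosome. For adjacent markers it reduces to the Kosambi fraction of
#' their map distance.
#'
#' @param map a [linkage_map()].
#' @param arch a [trait_arch()].
#' @return Symmetric matrix of dimension `n_QTL` with unit diagonal.
#' @export
gvp_kernel <- function(map, arch) {
  idx <- arch$qtl_indices
  cumlog <- numeric(nrow(map))
  for (ch in unique(map$chromosome)) {
    at <- which(map$chromosome == ch)
    if (length(at) > 1L) {
      lam <- 1 - 2 * kosambi_r(diff(map$position[at]))
      cumlog[at] <- c(0, cumsum(log(lam)))
    }
  }
  chr <- map$chromosome[idx]
  same <- outer(chr, chr, "==")
  k <- matrix(0, length(idx), length(idx))
  d <- abs(outer(cumlog[idx], cumlog[idx], "-"))
  k[same] <- exp(-d[same])
  k
}

#' Per-parent segregation variances
#'
#' For each individual, the variance among its gametes of the gametic
#' breeding-value contribution:
#' `s = (alpha * y)' K (alpha * y) / 4`, where `y = hap_a - hap_b` at the
#' QTLs and `K` is the [gvp_kernel()]. The expected genetic variance of
#' progeny of a cross is the sum of the two parents' values.
#'
#' @param pop a [population()].
#' @param arch a [trait_arch()] with effects set.
#' @param map the [linkage_map()].
#' @param kernel optional precomputed [gvp_kernel()].
#' @return Numeric vector, one non-negative variance per individual.
#' @export
segregation_variances <- function(pop, arch, map, kernel = NULL) {
  if (is.null(kernel)) kernel <- gvp_kernel(map, arch)
  idx <- arch$qtl_indices
  y <- pop$hap_a[, idx, drop = FALSE] - pop$hap_b[, idx, drop = FALSE]
  d <- sweep(y, 2L, arch$effects, "*")
  pmax(rowSums((d %*% kernel) * d) / 4, 0)
}

#' Expected genetic variance of progeny of a cross
#'
#' For a mating pair, the expected variance of progeny breeding values
#' `v = (alpha' C_M alpha + alpha' C_P alpha) / 4`, where for each parent
#' `C[m1, m2] = (x1_m1 - x2_m1) (x1_m2 - x2_m2) (1 - 2 r_m1m2)` is built
#' from the phased haplotype difference: diagonal entries are 1 at
#' heterozygous and 0 at homozygous QTLs, off-diagonal entries are
#' `+(1 - 2r)` for QTL pairs heterozygous in coupling phase and `-(1 - 2r)`
#' in repulsion phase. Fully homozygous parents contribute nothing; the
#' result is non-negative and symmetric in parent order.
#'
#' @param mother,father row indices (or ids) of the two parents in `pop`;
#'   selfing is allowed (`mother == father`).
#' @param pop a [population()] holding the phased parents.
#' @param arch a [trait_arch()] with effects set.
#' @param map the [linkage_map()].
#' @param kernel optional precomputed [gvp_kernel()].
#' @return Single non-negative variance.
#' @export
expected_gvp <- function(mother, father, pop, arch, map, kernel = NULL) {
  if (is.character(mother)) mother <- match(mother, pop$ids)
  if (is.character(father)) father <- match(father, pop$ids)
  if (anyNA(c(mother, father))) stop("parent not found in population")
  idx <- unique(c(mother, father))
  s <- segregation_variances(subset_population(pop, idx), arch, map, kernel)
  s[match(mother, idx)] + s[match(father, idx)]
}
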