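#' Simulate founder haplotypes with linkage disequilibrium
#'
#' Generates a pool of binary founder haplotypes as recombination mosaics of a
#' small set of ancestral haplotypes: every locus of an ancestral haplotype
#' carries the 1-allele with a Beta-distributed frequency, and each founder
#' haplotype is assembled by walking the map and switching to a uniformly
#' chosen ancestor with probability `1 - (1 - r)^g`, where `r` is the
#' adjacent-marker Kosambi recombination fraction and `g` the number of
#' generations since the ancestral bottleneck. Nearby markers therefore share
#' ancestry (high LD) while distant markers are nearly independent, and the
#' allele-frequency spectrum contains rare minor alleles.
#'
#' @param n_haplotypes number of haplotypes to generate (default 4000).
#' @param map a [linkage_map()].
#' @param n_ancestors size of the ancestral bottleneck (default 40).
#' @param generations generations of random mating since the bottleneck
#'   (default 10).
#' @param beta_shape shape parameter of the symmetric Beta distribution of
#'   ancestral allele frequencies (default 0.4; small values pile frequency
#'   mass near 0 and 1, mimicking a neutral site-frequency spectrum).
#' @param seed integer seed.
#' @return Binary matrix `n_haplotypes` x `nrow(map)`.
#' @export
sim_founder_haplotypes <- function(n_haplotypes = 4000, map,
                                   n_ancestors = 40, generations = 10,
                                   beta_shape = 0.4, seed = 1L) {
  if (n_haplotypes < 2) stop("n_haplotypes must be at least 2")
  if (n_ancestors < 2) stop("n_ancestors must be at least 2")
  stopifnot(inherits(map, "linkage_map"))
  set.seed(seed)
  m <- nrow(map)
  p <- stats::rbeta(m, beta_shape, beta_shape)
  anc <- matrix(stats::rbinom(n_ancestors * m, 1L, rep(p, each = n_ancestors)),
                n_ancestors, m)
  storage.mode(anc) <- "integer"
  rec <- recomb_fractions(map)
  sw <- 1 - (1 - rec)^generations
  sw[rec == 0.5] <- 1       # chromosome starts: fresh ancestor draw
  cpp_mosaic(anc, as.integer(n_haplotypes), sw)
}

#' Minor allele frequency of each locus in a haplotype pool
#' @param pool binary haplotype matrix.
#' @return Numeric vector of MAFs in `[0, 0.5]`.
#' @export
pool_maf <- function(pool) {
  p <- colMeans(pool)
  pmin(p, 1 - p)
}

#' Filter loci on minor allele frequency and subsample the map
#'
#' Keeps, per chromosome, a random subset of `n_keep_per_chromosome` loci among
#' those whose minor allele frequency in the pool is at least `maf_min`.
#'
#' @param pool binary haplotype matrix (haplotypes x markers).
#' @param map a [linkage_map()] describing the pool's markers.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param n_keep_per_chromosome loci retained per chromosome (default 500).
#' @param seed integer seed for the random subsample.
#' @return A list with elements `pool` (restricted haplotype matrix) and `map`
#'   (restricted [linkage_map()]).
#' @export
filter_and_select_loci <- function(pool, map, maf_min = 0.01,
                                   n_keep_per_chromosome = 500, seed = 1L) {
  stopifnot(inherits(map, "linkage_map"), ncol(pool) == nrow(map))
  set.seed(seed)
  maf <- pool_maf(pool)
  keep <- integer(0)
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch & maf >= maf_min)
    if (length(idx) < n_keep_per_chromosome) {
      stop(sprintf(
        "chromosome %d: only %d loci pass MAF >= %g, need %d",
        ch, length(idx), maf_min, n_keep_per_chromosome))
    }
    keep <- c(keep, sort(sample(idx, n_keep_per_chromosome)))
  }
  list(pool = pool[, keep, drop = FALSE],
       map = linkage_map(map$chromosome[keep], map$position[keep],
                         map$marker[keep]))
}

#' Sample diploid founders from a haplotype pool
#'
#' Each founder receives two haplotypes drawn independently and uniformly with
#' replacement from the pool.
#'
#' @param pool binary haplotype matrix.
#' @param n_founders number of diploid founders (default 2000).
#' @param seed integer seed.
#' @return A [population()] at generation 0.
#' @export
sample_founders <- function(pool, n_founders = 2000, seed = 1L) {
  if (nrow(pool) < 1) stop("haplotype pool is empty")
  if (n_founders < 1) stop("n_founders must be positive")
  set.seed(seed)
  a <- sample.int(nrow(pool), n_founders, replace = TRUE)
  b <- sample.int(nrow(pool), n_founders, replace = TRUE)
  population(pool[a, , drop = FALSE], pool[b, , drop = FALSE])
}

#' Random mating for one generation
#'
#' Parents of each progeny are drawn uniformly at random (selfing possible);
#' gametes are produced by Kosambi-map meiosis.
#'
#' @param pop a [population()] of size at least 2.
#' @param n_progeny number of progenies.
#' @param map the [linkage_map()].
#' @param seed integer seed.
#' @return A [population()] with generation incremented.
#' @export
random_mate <- function(pop, n_progeny, map, seed = 1L) {
  if (pop_size(pop) < 2) stop("random mating needs at least 2 individuals")
  set.seed(seed)
  rec <- recomb_fractions(map)
  mothers <- sample.int(pop_size(pop), n_progeny, replace = TRUE)
  fathers <- sample.int(pop_size(pop), n_progeny, replace = TRUE)
  ha <- cpp_gametes(pop$hap_a, pop$hap_b, mothers - 1L, rec)
  hb <- cpp_gametes(pop$hap_a, pop$hap_b, fathers - 1L, rec)
  population(ha, hb, generation = pop$generation + 1L)
}

#' Select a representative parent panel by k-medoids
#'
#' Clusters the population's dosage matrix into `k` groups by PAM
#' (Euclidean distance) and returns the medoid of each group, i.e. `k`
#' actual members of the population, re-tagged as generation 0.
#'
#' @param pop a [population()].
#' @param k panel size (default 250).
#' @param seed integer seed (PAM is deterministic; kept for interface
#'   symmetry).
#' @return A [population()] of the `k` medoids at generation 0.
#' @export
select_parent_panel <- function(pop, k = 250, seed = 1L) {
  n <- pop_size(pop)
  if (k > n) stop("panel size k exceeds population size")
  if (k == n) return(subset_population(pop, seq_len(n), generation = 0L))
  set.seed(seed)
  w <- dosage(pop)
  fit <- cluster::pam(w, k = k, metric = "euclidean", pamonce = 5)
  subset_population(pop, sort(fit$id.med), generation = 0L)
}
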