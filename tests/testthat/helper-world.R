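# Small fixtures built in code, shared across test files.

tiny_map <- function(n_chr = 2, m = 50, len = 100, seed = 11) {
  sim_linkage_map(n_chr, m, len, seed = seed)
}

tiny_world <- function(seed = 7) {
  sim_world(n_chromosomes = 2, markers_per_chromosome = 50,
            n_haplotypes = 200, n_founders = 200, n_panel = 30,
            qtl_per_chromosome = 5, seed = seed)
}

tiny_config <- function(...) {
  scheme_config(n_pop = 60, n_sel = 8, ...)
}

# Population with explicitly given haplotypes (lists of 0/1 vectors).
pop_from_haps <- function(hap_a, hap_b, generation = 0L) {
  population(do.call(rbind, hap_a), do.call(rbind, hap_b),
             generation = generation)
}

# Independent brute-force PAM: enumerate all medoid sets of size k and
# minimize the total Euclidean distance of points to their nearest medoid.
brute_force_pam <- function(x, k) {
  dmat <- as.matrix(stats::dist(x))
  combs <- utils::combn(nrow(x), k)
  costs <- apply(combs, 2L, function(med) {
    sum(apply(dmat[, med, drop = FALSE], 1L, min))
  })
  sort(combs[, which.min(costs)])
}

# Monte-Carlo oracle for the expected progeny variance of a cross: simulate
# progenies by meiosis and take the variance of their breeding values.
mc_progeny_variance <- function(pop, mother, father, map, arch, n = 200000) {
  rec <- recomb_fractions(map)
  ha <- make_gametes(pop, mother, rec, n)
  hb <- make_gametes(pop, father, rec, n)
  prog <- population(ha, hb)
  u <- breeding_values(prog, arch)
  mean((u - mean(u))^2)
}
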