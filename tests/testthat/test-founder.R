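test_that("founder haplotypes are binary, sized as requested, and reproducible", {
  map <- tiny_map(1, 30, 100)
  pool <- sim_founder_haplotypes(4, map, seed = 5)
  expect_equal(dim(pool), c(4L, 30L))
  expect_true(all(pool %in% c(0L, 1L)))
  expect_identical(pool, sim_founder_haplotypes(4, map, seed = 5))
  expect_false(identical(pool, sim_founder_haplotypes(4, map, seed = 6)))
  expect_error(sim_founder_haplotypes(1, map), "at least 2")
})

test_that("linkage disequilibrium decays with map distance in generated pools", {
  map <- sim_linkage_map(2, 120, 200, seed = 3)
  pool <- sim_founder_haplotypes(400, map, seed = 3)
  maf <- pool_maf(pool)
  poly <- maf > 0.05
  r2_pair <- function(i, j) suppressWarnings(stats::cor(pool[, i], pool[, j]))^2
  adj <- long <- c()
  for (ch in 1:2) {
    idx <- which(map$chromosome == ch & poly)
    pos <- map$position[idx]
    adj <- c(adj, vapply(seq_len(length(idx) - 1L),
                         function(k) r2_pair(idx[k], idx[k + 1L]), numeric(1)))
    far <- which(outer(pos, pos, function(a, b) abs(a - b)) > 50, arr.ind = TRUE)
    far <- far[far[, 1] < far[, 2], , drop = FALSE]
    far <- far[seq(1, nrow(far), length.out = min(500, nrow(far))), , drop = FALSE]
    long <- c(long, vapply(seq_len(nrow(far)),
                           function(k) r2_pair(idx[far[k, 1]], idx[far[k, 2]]),
                           numeric(1)))
  }
  expect_gt(mean(adj, na.rm = TRUE), mean(long, na.rm = TRUE))
  # minor alleles are present across the frequency range
  expect_gt(mean(maf >= 0.01 & maf < 0.1), 0)
  expect_gt(mean(maf >= 0.1), 0)
})

test_that("MAF filtering keeps exactly the qualifying loci", {
  # 200 haplotypes over 10 loci on one chromosome: one fixed locus, one at
  # MAF 0.005, eight at MAF 0.02
  n <- 200
  counts <- c(0, 1, rep(4, 8))
  pool <- sapply(counts, function(k) c(rep(1L, k), rep(0L, n - k)))
  map <- linkage_map(rep(1, 10), seq(0, 90, by = 10))
  expect_equal(pool_maf(pool), counts / n)
  got <- filter_and_select_loci(pool, map, maf_min = 0.01,
                                n_keep_per_chromosome = 8, seed = 1)
  expect_equal(got$map$marker, map$marker[3:10])
  expect_true(all(pool_maf(got$pool) >= 0.01))
  expect_error(
    filter_and_select_loci(pool, map, maf_min = 0.01,
                           n_keep_per_chromosome = 9),
    "chromosome 1")
})

test_that("a fixed locus is never selected and kept loci satisfy the MAF floor", {
  map <- tiny_map(2, 40, 100)
  pool <- sim_founder_haplotypes(120, map, seed = 9)
  pool[, 7] <- 0L  # force one fixed locus
  got <- filter_and_select_loci(pool, map, maf_min = 0.01,
                                n_keep_per_chromosome = 25, seed = 2)
  expect_false(map$marker[7] %in% got$map$marker)
  expect_gte(min(pool_maf(got$pool)), 0.01)
  expect_equal(nrow(got$map), 50)
})

test_that("founder sampling draws haplotype pairs with replacement", {
  map <- tiny_map(1, 20, 50)
  pool <- sim_founder_haplotypes(50, map, seed = 2)
  founders <- sample_founders(pool, 200, seed = 3)
  expect_equal(pop_size(founders), 200)
  expect_identical(founders, sample_founders(pool, 200, seed = 3))
  # single-haplotype pool: every founder fully homozygous
  one <- pool[1, , drop = FALSE]
  homo <- sample_founders(one, 10, seed = 1)
  expect_true(all(dosage(homo) %in% c(-1L, 1L)))
})

test_that("random mating preserves allele frequencies within sampling error", {
  map <- tiny_map(2, 30, 80)
  pool <- sim_founder_haplotypes(100, map, seed = 4)
  founders <- sample_founders(pool, 500, seed = 4)
  progeny <- random_mate(founders, 2000, map, seed = 5)
  expect_equal(pop_size(progeny), 2000)
  expect_equal(progeny$generation, founders$generation + 1L)
  p0 <- allele_frequencies(founders)
  p1 <- allele_frequencies(progeny)
  # 2000 diploids = 4000 allele draws; 5 binomial sd of the parental frequency
  tol <- 5 * sqrt(p0 * (1 - p0) / 4000) + 1e-9
  expect_true(all(abs(p1 - p0) <= tol))
  expect_error(random_mate(sample_founders(pool, 1, seed = 1), 5, map),
               "at least 2")
})

test_that("k-medoids panel members are verbatim members of the population", {
  w <- tiny_world(3)
  pre <- random_mate(sample_founders(w$pool, 100, seed = 2), 100, w$map,
                     seed = 3)
  panel <- select_parent_panel(pre, 20, seed = 1)
  expect_equal(pop_size(panel), 20)
  expect_equal(panel$generation, 0L)
  pre_geno <- paste(apply(pre$hap_a, 1, paste, collapse = ""),
                    apply(pre$hap_b, 1, paste, collapse = ""))
  panel_geno <- paste(apply(panel$hap_a, 1, paste, collapse = ""),
                      apply(panel$hap_b, 1, paste, collapse = ""))
  expect_true(all(panel_geno %in% pre_geno))
  expect_error(select_parent_panel(pre, 101), "exceeds")
})

test_that("k = population size returns the whole population", {
  map <- tiny_map(1, 10, 40)
  pop <- sample_founders(sim_founder_haplotypes(20, map, seed = 1), 8,
                         seed = 2)
  panel <- select_parent_panel(pop, 8)
  expect_equal(dosage(panel), dosage(pop), ignore_attr = TRUE)
})

test_that("PAM matches brute-force medoids on well-separated dosage clusters", {
  # two tight clusters of 3 genotypes each
  a <- rbind(c(1, 1, 1, 1, 0, 0), c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 1, 0, 0))
  b <- rbind(c(1, 1, 1, 1, 0, 0), c(1, 1, 1, 1, 0, 0), c(0, 1, 1, 1, 0, 0))
  hap_a <- rbind(a, 1 - a)
  hap_b <- rbind(b, 1 - b)
  pop <- population(hap_a, hap_b)
  panel <- select_parent_panel(pop, 2, seed = 1)
  oracle <- brute_force_pam(dosage(pop), 2)
  expect_equal(sort(match(panel$ids, pop$ids)), oracle)
  # one medoid per cluster
  expect_equal(sum(oracle <= 3), 1L)
})
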