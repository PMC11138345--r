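test_that("truncation selection keeps the highest-criterion genotypes", {
  w <- tiny_world(2)
  pop <- subset_population(w$panel, 1:20)
  crit <- seq_len(20)  # distinct values 1..20
  sel <- select_parents(pop, crit, 5)
  expect_equal(sort(match(sel$ids, pop$ids)), 16:20)
  # ties broken by position: first n_sel by id
  sel2 <- select_parents(pop, rep(1, 20), 5)
  expect_equal(match(sel2$ids, pop$ids), 1:5)
  expect_error(select_parents(pop, crit, 21), "exceeds")
  expect_error(select_parents(pop, 1:3, 2), "one value per")
})

test_that("diallel pairing enumerates all unordered pairs including selfings", {
  w <- tiny_world(2)
  c15 <- subset_population(w$panel, 1:15)
  plan <- make_diallel_pairs(c15)
  expect_equal(nrow(plan), 120)
  expect_equal(nrow(unique(plan[, c("mother", "father")])), 120)
  expect_true(all(plan$mother <= plan$father))

  one <- make_diallel_pairs(subset_population(w$panel, 1))
  expect_equal(nrow(one), 1)
  expect_equal(one$mother_id, one$father_id)

  c3 <- subset_population(w$panel, 1:3)
  p3 <- make_diallel_pairs(c3, criterion = c(1, 2, 4))
  got <- p3[order(p3$mother, p3$father), c("mother", "father")]
  expect_equal(unname(as.matrix(got)),
               rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3)))
  expect_equal(sort(p3$expected_pair_wbv), sort(c(1, 1.5, 2.5, 2, 3, 4)))
})

test_that("feature matrix columns are parent means and cross variances", {
  map <- linkage_map(c(1, 1), c(0, 30))
  arch <- trait_arch(1:2, c(0.3, 0.1))
  pop <- pop_from_haps(list(c(1, 1), c(1, 1), c(1, 0)),
                       list(c(1, 1), c(0, 1), c(1, 0)))
  u <- breeding_values(pop, arch)
  expect_equal(unname(u), c(0.4, 0.1, 0.2))
  plan <- make_diallel_pairs(pop, u)
  omega <- build_feature_matrix(plan, pop, arch, map,
                                feature_set = c("BV", "GVP"),
                                standardize = FALSE)
  i12 <- which(plan$mother == 1 & plan$father == 2)
  i23 <- which(plan$mother == 2 & plan$father == 3)
  expect_equal(omega[i12, "BV"], mean(u[c(1, 2)]), ignore_attr = TRUE)
  expect_equal(omega[i23, "BV"], mean(u[c(2, 3)]), ignore_attr = TRUE)
  # selfing of the fully homozygous genotype 1 has zero progeny variance
  i11 <- which(plan$mother == 1 & plan$father == 1)
  expect_equal(omega[i11, "GVP"], 0, ignore_attr = TRUE)
  expect_error(build_feature_matrix(plan, pop, arch, map, "XYZ"), "unknown")
})

test_that("feature standardization z-scores columns and zeroes degenerate ones", {
  w <- tiny_world(4)
  cand <- subset_population(w$panel, 1:6)
  u <- weighted_breeding_values(cand, w$arch)
  plan <- make_diallel_pairs(cand, u)
  omega <- build_feature_matrix(plan, cand, w$arch, w$map,
                                feature_set = c("BV", "WBV", "GVP"))
  expect_equal(colMeans(omega), c(BV = 0, WBV = 0, GVP = 0), tolerance = 1e-12)
  expect_equal(apply(omega, 2, sd), c(BV = 1, WBV = 1, GVP = 1),
               tolerance = 1e-12)
  # a population of identical genotypes gives a zero-variance column -> zeros
  same <- population(w$panel$hap_a[rep(1, 3), ], w$panel$hap_b[rep(1, 3), ],
                     ids = c("a", "b", "c"))
  plan0 <- make_diallel_pairs(same)
  om0 <- build_feature_matrix(plan0, same, w$arch, w$map, "BV")
  expect_true(all(om0 == 0))
})

test_that("softmax allocation floors, then fills the deficit by fractional part", {
  # scores log(5), log(3), log(2) give softmax probabilities (.5, .3, .2)
  plan <- data.frame(mother = 1:3, father = 1:3,
                     mother_id = letters[1:3], father_id = letters[1:3],
                     expected_pair_wbv = c(3, 2, 1))
  class(plan) <- c("cross_plan", "data.frame")
  omega <- matrix(log(c(5, 3, 2)), ncol = 1)
  tab <- allocate_softmax(plan, omega, h = 1, n_pop = 10)
  expect_equal(tab$softmax_probability, c(0.5, 0.3, 0.2))
  expect_equal(tab$n_progeny, c(5L, 3L, 2L))

  # saturation: one score dominating takes the whole budget
  omega2 <- matrix(c(50, 0, 0), ncol = 1)
  tab2 <- allocate_softmax(plan, omega2, h = 1, n_pop = 10)
  expect_equal(tab2$n_progeny, c(10L, 0L, 0L))
  expect_error(allocate_softmax(plan, matrix(c(Inf, 0, 0), ncol = 1), 1, 10),
               "non-finite")
  expect_error(allocate_softmax(plan, omega, h = c(1, 2), n_pop = 10),
               "one entry per feature")
})

test_that("equal allocation spreads the budget with remainder to the best pairs", {
  w <- tiny_world(2)
  c15 <- subset_population(w$panel, 1:15)
  wbv <- weighted_breeding_values(c15, w$arch)
  plan <- make_diallel_pairs(c15, wbv)
  tab <- allocate_equal(plan, 250)
  expect_equal(sum(tab$n_progeny), 250L)
  expect_equal(sort(unique(tab$n_progeny)), c(2L, 3L))
  expect_equal(sum(tab$n_progeny == 3L), 10L)
  # the ten pairs receiving 3 are the ten highest expected pair WBV
  top10 <- order(-plan$expected_pair_wbv, seq_len(120))[1:10]
  expect_equal(sort(which(tab$n_progeny == 3L)), sort(top10))

  # exact division leaves no remainder
  plan5 <- make_diallel_pairs(subset_population(w$panel, 1:2),
                              criterion = c(2, 1))  # 3 pairs
  tab5 <- allocate_equal(plan5, 9)
  expect_equal(tab5$n_progeny, c(3L, 3L, 3L))

  # 4 pairs, 7 progenies: (2,2,2,1) with the +1s on the top-3 WBV pairs
  plan4 <- data.frame(mother = 1:4, father = 1:4,
                      mother_id = letters[1:4], father_id = letters[1:4],
                      expected_pair_wbv = c(0.1, 0.9, 0.5, 0.7))
  class(plan4) <- c("cross_plan", "data.frame")
  tab4 <- allocate_equal(plan4, 7)
  expect_equal(tab4$n_progeny, c(1L, 2L, 2L, 2L))
})

test_that("softmax allocation with zero weights reproduces equal allocation", {
  set.seed(99)
  for (rep in 1:50) {
    n_pairs <- sample(3:40, 1)
    n_pop <- sample(n_pairs:200, 1)
    plan <- data.frame(mother = seq_len(n_pairs), father = seq_len(n_pairs),
                       mother_id = as.character(seq_len(n_pairs)),
                       father_id = as.character(seq_len(n_pairs)),
                       expected_pair_wbv = rnorm(n_pairs))
    class(plan) <- c("cross_plan", "data.frame")
    omega <- matrix(rnorm(n_pairs * 2), n_pairs, 2)
    a <- allocate_softmax(plan, omega, h = c(0, 0), n_pop = n_pop)
    b <- allocate_equal(plan, n_pop)
    expect_identical(a$n_progeny, b$n_progeny)
    expect_equal(sum(a$n_progeny), n_pop)
    expect_true(all(a$n_progeny >= 0))
  }
})

test_that("softmax allocation is monotone in a single feature", {
  plan <- data.frame(mother = 1:8, father = 1:8,
                     mother_id = as.character(1:8),
                     father_id = as.character(1:8),
                     expected_pair_wbv = rep(0, 8))
  class(plan) <- c("cross_plan", "data.frame")
  omega <- matrix(seq(-1, 1, length.out = 8), ncol = 1)
  for (h in c(0.3, 1, 2)) {
    tab <- allocate_softmax(plan, omega, h = h, n_pop = 100)
    expect_true(all(diff(tab$n_progeny) >= -1e-9))
  }
})

test_that("meiosis respects the map: intact at r = 0, free at large distance", {
  pop <- pop_from_haps(list(rep(1L, 10)), list(rep(0L, 10)))
  rec0 <- c(0.5, rep(0, 9))  # one chromosome, no recombination
  set.seed(1)
  g <- make_gametes(pop, 1, rec0, n = 200)
  expect_true(all(rowSums(g) %in% c(0L, 10L)))  # intact parental haplotypes
  expect_gt(mean(rowSums(g) == 10L), 0.3)       # both haplotypes transmitted

  # two distant markers: switch rate ~ 0.5
  map2 <- linkage_map(c(1, 1), c(0, 5000))
  set.seed(2)
  g2 <- make_gametes(pop_from_haps(list(c(1L, 1L)), list(c(0L, 0L))), 1,
                     map2, n = 50000)
  expect_lt(abs(mean(g2[, 1] != g2[, 2]) - 0.5), 0.01)

  # single-marker chromosome: Mendelian sampling of the two alleles
  map1 <- linkage_map(1, 0)
  set.seed(3)
  g1 <- make_gametes(pop_from_haps(list(c(1L)), list(c(0L))), 1, map1,
                     n = 50000)
  expect_lt(abs(mean(g1) - 0.5), 0.01)
})

test_that("advancing a generation draws each progeny from its designated parents", {
  w <- tiny_world(5)
  cand <- subset_population(w$panel, 1:4)
  plan <- make_diallel_pairs(cand, criterion = 4:1)
  tab <- allocate_equal(plan, 30)
  set.seed(7)
  nxt <- advance_generation(cand, tab, w$map)
  expect_equal(pop_size(nxt), 30)
  expect_equal(nxt$generation, cand$generation + 1L)
  # identity-by-descent audit: every progeny allele exists in its parents
  k <- 0
  for (i in seq_len(nrow(tab))) {
    m <- tab$mother[i]; f <- tab$father[i]
    for (j in seq_len(tab$n_progeny[i])) {
      k <- k + 1
      ok_a <- nxt$hap_a[k, ] == cand$hap_a[m, ] |
              nxt$hap_a[k, ] == cand$hap_b[m, ]
      ok_b <- nxt$hap_b[k, ] == cand$hap_a[f, ] |
              nxt$hap_b[k, ] == cand$hap_b[f, ]
      expect_true(all(ok_a) && all(ok_b))
    }
  }
  bad <- tab
  bad$mother_id[1] <- "nope"
  expect_error(advance_generation(cand, bad, w$map), "absent")
})

test_that("a single selfing pair with the whole budget fills the generation", {
  w <- tiny_world(5)
  cand <- subset_population(w$panel, 1)
  tab <- allocate_equal(make_diallel_pairs(cand), 250)
  set.seed(1)
  nxt <- advance_generation(cand, tab, w$map)
  expect_equal(pop_size(nxt), 250)
})

test_that("breeding schemes are reproducible and respond to selection", {
  w <- tiny_world(6)
  cfg <- tiny_config()
  t1 <- run_scheme(w$panel, w$arch, w$map, cfg, seed = 11)
  t2 <- run_scheme(w$panel, w$arch, w$map, cfg, seed = 11)
  expect_identical(t1, t2)
  expect_length(t1$u_top, cfg$n_generations + 1L)
  expect_equal(t1$gain, t1$u_top[5] - t1$u_top[1])
  # top-subset mean dominates the population mean at every generation
  t3 <- run_scheme(w$panel, w$arch, w$map, cfg, seed = 3, keep_tables = TRUE)
  expect_true(all(vapply(t3$tables, function(tb) sum(tb$n_progeny), numeric(1)) ==
                  cfg$n_pop))
  # positive expected response under variation
  gains <- vapply(1:40, function(s) {
    run_scheme(w$panel, w$arch, w$map, cfg, seed = 100 + s)$gain
  }, numeric(1))
  expect_gt(mean(gains), 0)
})

test_that("a panel without genetic variation yields zero gain and variance", {
  w <- tiny_world(6)
  # clones of one fully inbred genotype: no segregation anywhere
  flat <- population(w$panel$hap_a[rep(3, 12), ], w$panel$hap_a[rep(3, 12), ],
                     ids = sprintf("c%d", 1:12))
  cfg <- scheme_config(n_pop = 20, n_sel = 4, n_top = 3, n_generations = 2)
  traj <- run_scheme(flat, w$arch, w$map, cfg, seed = 2)
  expect_equal(traj$gain, 0)
  expect_equal(traj$variance, rep(0, 3))
})

test_that("the top-mean genotypic value dominates the population mean", {
  w <- tiny_world(8)
  u <- breeding_values(w$panel, w$arch)
  expect_gte(top_mean_tgv(w$panel, w$arch, 5), mean(u))
  expect_equal(top_mean_tgv(w$panel, w$arch, pop_size(w$panel)), mean(u))
})
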