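test_that("random union of gametes preserves allele frequency in expectation", {
  # 2 diploid founders fixed for alternate homozygotes at one locus:
  # one generation of random mating keeps p = 0.5 only in expectation;
  # the mean over many seeds must be close to 0.5 (binomial sampling).
  cfg <- tiny_config(hist_n0 = 2, hist_n1 = 2, hist_gens1 = 1, hist_gens2 = 0,
                     n_loci_pool = 2, n_snps = 1, n_qtl = 1,
                     mutation_rate = 0)
  set.seed(99)
  map <- genome_map(2, n_chr = 1, total_cM = 100, len_min = 40, len_max = 146,
                    mutation_rate = 0)
  init <- matrix(as.raw(c(1, 1, 0, 0,  1, 1, 0, 0)), nrow = 2, byrow = TRUE)
  freqs <- vapply(1:1000, function(s) {
    pool <- simulate_historical(cfg, map, init_haplo = init, seed = s)
    mean(as.integer(pool$haplo[1, ]))
  }, 0)
  expect_gte(mean(freqs), 0.45)
  expect_lte(mean(freqs), 0.55)
})

test_that("fixed loci stay fixed without mutation", {
  cfg <- tiny_config(hist_n0 = 10, hist_n1 = 8, hist_gens1 = 5, hist_gens2 = 0,
                     mutation_rate = 0)
  map <- genome_map(50, n_chr = 2, chr_length_cM = c(55, 45),
                    mutation_rate = 0)
  init <- matrix(as.raw(1), nrow = 50, ncol = 20)
  pool <- simulate_historical(cfg, map, init_haplo = init, seed = 3)
  expect_true(all(as.integer(pool$haplo) == 1L))
})

test_that("heterozygosity decays at the Wright-Fisher rate", {
  # constant N = 20 for 60 generations: E[H_t] = H_0 (1 - 1/(2N))^t
  N <- 20L; t <- 60L
  cfg <- tiny_config(hist_n0 = N, hist_n1 = N, hist_gens1 = t, hist_gens2 = 0,
                     mutation_rate = 0)
  map <- genome_map(400, n_chr = 20, total_cM = 4000, len_min = 150,
                    len_max = 250, mutation_rate = 0)
  het <- vapply(1:8, function(s) {
    pool <- simulate_historical(cfg, map, seed = 100 + s)
    p <- rowMeans(matrix(as.integer(pool$haplo), nrow = 400))
    mean(2 * p * (1 - p))
  }, 0)
  expected <- 0.5 * (1 - 1 / (2 * N))^t
  se <- sd(het) / sqrt(length(het))
  expect_lt(abs(mean(het) - expected), 3 * se + 0.01)
  # drift must leave some loci segregating and fix others en route
  expect_gt(mean(het), 0)
  expect_lt(mean(het), 0.5)
})

test_that("founding draws the configured numbers of each sex", {
  cfg <- tiny_config(n_sires = 5, n_dams = 100)
  pool <- simulate_historical(cfg, seed = 7)
  pool <- select_panel(pool, cfg, seed = 8)
  founders <- expand_and_found(cfg, pool, seed = 9)
  expect_equal(founders$n_animals, 105L)
  expect_equal(sum(founders$ped$sex == "M"), 5L)
  expect_equal(sum(founders$ped$sex == "F"), 100L)
  expect_true(all(founders$ped$sire == 0 & founders$ped$dam == 0))
})

test_that("founding is deterministic under a fixed seed and fails when the pool is too small", {
  cfg <- tiny_config()
  pool <- select_panel(simulate_historical(cfg, seed = 21), cfg, seed = 22)
  f1 <- expand_and_found(cfg, pool, seed = 23)
  f2 <- expand_and_found(cfg, pool, seed = 23)
  expect_identical(f1$haplo, f2$haplo)
  expect_identical(f1$founder_freqs, f2$founder_freqs)
  big <- cfg; big$n_dams <- 10000L; big$expand_gens <- 0L
  expect_error(expand_and_found(big, pool), "too small")
})

test_that("genotype codes equal the sum of the two inherited gametes", {
  pop <- get_tiny_pop()
  ids <- c(1L, 50L, pop$n_animals)
  g <- pop_genotypes(pop, ids)
  for (i in seq_along(ids)) {
    h <- matrix(as.integer(pop$haplo[, c(2 * ids[i] - 1, 2 * ids[i])]),
                ncol = 2)
    expect_equal(unname(g[i, ]), (h[, 1] + h[, 2])[pop$map$snp_idx])
  }
  expect_true(all(g %in% 0:2))
})

test_that("selection on BLUP EBV produces a monotone genetic trend", {
  pop <- get_tiny_pop()
  gm <- tapply(pop$tbv, pop$ped$generation, mean)
  gen <- as.numeric(names(gm))
  expect_gt(cor(gen, gm, method = "spearman"), 0.9)
  expect_gt(gm[length(gm)], gm[1])
})

test_that("pedigree structure is valid: parents precede offspring, sexes consistent", {
  pop <- get_tiny_pop()
  ped <- pop$ped
  off <- ped[ped$sire > 0, ]
  expect_true(all(ped$sex[off$sire] == "M"))
  expect_true(all(ped$sex[off$dam] == "F"))
  expect_true(all(off$sire < off$id & off$dam < off$id))
  expect_true(all(ped$generation[off$sire] < ped$generation[off$id]))
})

test_that("generation sizes follow the growth and litter arithmetic exactly", {
  pop <- get_tiny_pop()
  cfg <- pop$config
  r <- ipgblup:::dam_growth_rate(cfg)
  dams_sched <- floor(cfg$n_dams * (1 + r)^(seq_len(cfg$n_generations) - 1))
  sizes <- tabulate(pop$ped$generation + 1L)[-1]   # generations 1..G
  expect_equal(sizes, cfg$offspring_per_dam * dams_sched)
})

test_that("zero replacement and zero growth keep the breeding set fixed", {
  cfg <- tiny_config(sire_replacement = 0, dam_replacement = 0,
                     growth_total = 0, n_generations = 4)
  pop <- simulate_population(cfg, seed = 77)
  ped <- pop$ped
  for (g in seq_len(4)) {
    par <- unique(c(ped$sire[ped$generation == g],
                    ped$dam[ped$generation == g]))
    expect_true(all(ped$generation[par] == 0L))
  }
})

test_that("without selection the mean TBV shows no systematic trend", {
  trends <- vapply(1:20, function(s) {
    cfg <- tiny_config(selection = "random", mutation_rate = 0,
                       n_generations = 4, n_dams = 16, n_sires = 4,
                       offspring_per_dam = 4, n_snps = 120, n_qtl = 20,
                       n_loci_pool = 1200)
    pop <- simulate_population(cfg, seed = 1000 + s)
    gm <- tapply(pop$tbv, pop$ped$generation, mean)
    unname(coef(lm(gm ~ seq_along(gm)))[2])
  }, 0)
  se <- sd(trends) / sqrt(length(trends))
  expect_lt(abs(mean(trends)), 3 * se)
})

test_that("expected crossover count per gamete equals the map length in Morgans", {
  set.seed(5)
  L <- 400L
  map <- genome_map(L, n_chr = 1, total_cM = 100, len_min = 40, len_max = 146,
                    mutation_rate = 0)
  lay <- ipgblup:::map_cpp_layout(map)
  # one parent heterozygous at every locus with known phase: allele switches
  # along a gamete count the crossovers realized between adjacent loci
  haplo <- matrix(as.raw(c(rep(0L, L), rep(1L, L))), nrow = L)
  n_off <- 5000L
  gam <- ipgblup:::cpp_make_offspring(haplo, rep(1L, n_off), rep(1L, n_off),
                                      lay$posM, lay$chr_start, lay$chr_end, 0)
  switches <- colSums(abs(apply(matrix(as.integer(gam), nrow = L), 2, diff)))
  m <- mean(switches)                       # 2 * n_off gametes
  se <- sd(switches) / sqrt(length(switches))
  expect_lt(abs(m - 1.0), 3 * se)
})

test_that("degenerate configurations are rejected", {
  expect_error(tiny_config(n_generations = 0))
  expect_error(tiny_config(hist_n0 = 0))
  expect_error(tiny_config(mutation_rate = 1))
  cfg <- tiny_config()
  expect_error(simulate_selection(cfg, list(), NULL))
})
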