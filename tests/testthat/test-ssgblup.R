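test_that("single-record MME shrinks to the mean", {
  ped <- data.frame(id = 1, sire = 0, dam = 0)
  fit <- ssgblup(data.frame(id = 1, phenotype = 4), ped, solver = "dense")
  expect_equal(unname(coef(fit, "fixed")), 4)
  expect_equal(unname(coef(fit, "animal")), 0, tolerance = 1e-10)
})

test_that("infinite shrinkage drives all breeding values to zero", {
  ped <- random_pedigree(30, n_founders = 10, seed = 1)
  set.seed(1)
  phen <- data.frame(id = 1:30, phenotype = rnorm(30, 5))
  fit <- ssgblup(phen, ped, lambda = 1e8, solver = "dense")
  expect_lt(max(abs(fit$gebv)), 1e-4)
})

test_that("MME solution equals the closed-form GLS/BLUP oracle", {
  ped <- random_pedigree(10, n_founders = 4, seed = 2)
  A <- pedigree_A(ped)
  set.seed(2)
  obs <- sort(sample(10, 7))
  y <- rnorm(7, 2)
  fit <- ssgblup(data.frame(id = obs, phenotype = y), ped, lambda = 3,
                 solver = "dense")
  Zinc <- matrix(0, 7, 10); Zinc[cbind(1:7, obs)] <- 1
  oracle <- blup_oracle(y, matrix(1, 7, 1), Zinc, A, s2a = 0.25, s2e = 0.75)
  expect_lt(max(abs(fit$gebv - oracle$u)), 1e-8)
  expect_equal(unname(coef(fit, "fixed")), oracle$b, tolerance = 1e-8)
})

test_that("dense and PCG solver paths agree on a genomic system", {
  ped <- random_pedigree(100, n_founders = 25, seed = 3)
  gid <- 61:100
  g <- random_genotypes(40, 300, seed = 3)
  rownames(g) <- as.character(gid)
  set.seed(3)
  phen <- data.frame(id = 1:80, phenotype = rnorm(80, 1))
  fd <- ssgblup(phen, ped, g, solver = "dense")
  fp <- ssgblup(phen, ped, g, solver = "pcg", tol = 1e-12)
  expect_lt(max(abs(fd$gebv - fp$gebv)), 1e-6)
  expect_true(fp$converged)
  expect_lt(fd$residual, 1e-10)
})

test_that("solution is invariant to the order of phenotype records", {
  ped <- random_pedigree(40, n_founders = 10, seed = 4)
  set.seed(4)
  phen <- data.frame(id = 1:40, phenotype = rnorm(40, 3))
  f1 <- ssgblup(phen, ped, solver = "dense")
  f2 <- ssgblup(phen[sample(40), ], ped, solver = "dense")
  expect_equal(f1$gebv, f2$gebv, tolerance = 1e-10)
  expect_equal(f1$mu, f2$mu, tolerance = 1e-10)
})

test_that("a zero genotyped-block correction reduces ssGBLUP to pedigree BLUP", {
  ped <- random_pedigree(50, n_founders = 15, seed = 5)
  set.seed(5)
  phen <- data.frame(id = 1:50, phenotype = rnorm(50, 2))
  Ainv <- A_inverse(ped)
  sys0 <- assemble_mme(phen$phenotype, phen$id, Ainv, 3)
  sysd <- assemble_mme(phen$phenotype, phen$id, Ainv, 3,
                       delta = matrix(0, 20, 20), geno_idx = 21:40)
  s0 <- solve_mme(sys0, method = "dense")
  sd_ <- solve_mme(sysd, method = "dense")
  expect_equal(s0$u, sd_$u, tolerance = 1e-10)
})

test_that("unphenotyped terminal animals get the parent-average breeding value", {
  ped <- data.frame(id = 1:6, sire = c(0, 0, 0, 0, 1, 1),
                    dam = c(0, 0, 0, 0, 2, 4))
  set.seed(6)
  phen <- data.frame(id = 1:4, phenotype = rnorm(4, 1))
  fit <- ssgblup(phen, ped, solver = "dense")
  u <- fit$gebv
  expect_equal(unname(u["5"]), unname((u["1"] + u["2"]) / 2), tolerance = 1e-9)
  expect_equal(unname(u["6"]), unname((u["1"] + u["4"]) / 2), tolerance = 1e-9)
})

test_that("sparse and dense pedigree-BLUP paths agree; sparse refuses genomic blocks", {
  ped <- random_pedigree(60, n_founders = 20, seed = 7)
  set.seed(7)
  phen <- data.frame(id = 1:60, phenotype = rnorm(60))
  sys <- assemble_mme(phen$phenotype, phen$id, A_inverse(ped), 3)
  expect_equal(solve_mme(sys, "sparse")$u, solve_mme(sys, "dense")$u,
               tolerance = 1e-9)
  sysg <- assemble_mme(phen$phenotype, phen$id, A_inverse(ped), 3,
                       delta = diag(5), geno_idx = 1:5)
  expect_error(solve_mme(sysg, "sparse"), "pedigree-only")
})

test_that("benchmark run predicts candidates through the genomic block only", {
  pop <- get_tiny_pop()
  bench <- run_benchmark(pop, solver = "dense")
  vg <- attr(bench, "validation_gebv")
  expect_length(vg, length(validation_ids(pop)))
  expect_gt(var(vg), 0)
  expect_gt(cor(vg, pop$tbv[validation_ids(pop)]), 0.5)
  # validation animals carry no phenotypes in the benchmark fit
  expect_false(any(validation_ids(pop) %in% bench$phenotypes$id))
})

test_that("reduced-run GEBV of training animals track the benchmark closely", {
  pop <- get_tiny_pop()
  bench <- run_benchmark(pop, solver = "dense")
  red <- run_reduced(pop, solver = "dense")
  tid <- as.character(training_ids(pop))
  expect_gt(cor(bench$gebv[tid], red$gebv[tid]), 0.95)
})

test_that("GEBV are shrunken relative to true breeding values", {
  pop <- get_tiny_pop()
  bench <- run_benchmark(pop, solver = "dense")
  expect_lte(var(bench$gebv), var(pop$tbv) * 1.05)
})

test_that("fits are deterministic and error cleanly on bad input", {
  pop <- get_tiny_pop()
  r1 <- run_reduced(pop, solver = "dense")
  r2 <- run_reduced(pop, solver = "dense")
  expect_identical(r1$gebv, r2$gebv)
  ped <- random_pedigree(10, n_founders = 5, seed = 8)
  expect_error(ssgblup(data.frame(id = 99, phenotype = 1), ped),
               "missing from pedigree")
  expect_error(ssgblup(data.frame(id = integer(), phenotype = numeric()), ped),
               "no phenotypes")
  bad <- ped; bad$id <- bad$id + 1
  expect_error(ssgblup(data.frame(id = 2, phenotype = 1), bad), "dense")
})
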