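test_that("back-solved effects are linear in the GEBV and zero at zero", {
  g <- random_genotypes(20, 80, seed = 1)
  p <- colMeans(g) / 2
  Gi <- solve(tune_and_blend(build_G(g, p), diag(20) + 0.2)$G_star)
  blend <- list(alpha = 0.05, d = 0.98)
  a0 <- backsolve_snp_effects(rep(0, 20), g, Gi, blend, p)
  expect_equal(unclass(a0), rep(0, 80), ignore_attr = TRUE)
  u <- rnorm(20)
  a1 <- backsolve_snp_effects(u, g, Gi, blend, p)
  a2 <- backsolve_snp_effects(2 * u, g, Gi, blend, p)
  expect_equal(unclass(a2), 2 * unclass(a1), tolerance = 1e-12)
})

test_that("at alpha = 0, c = 0, d = 1 training direct genomic values recover the GEBV", {
  # with G* = G full rank, Z a = G G^-1 u = u exactly; the centering
  # frequencies must not be the observed ones (1'Z = 0 makes G singular)
  set.seed(2)
  p <- runif(200, 0.2, 0.8)
  g <- random_genotypes(15, 200, seed = 2, freq = p)
  G <- build_G(g, p)$G
  set.seed(2)
  u <- rnorm(15)
  a <- backsolve_snp_effects(u, g, solve(G), list(alpha = 0, d = 1), p)
  dgv <- compute_ip(g, a)
  expect_lt(max(abs(dgv - u)), 1e-8)
})

test_that("effects scale by (1-alpha) d relative to the unblended solve", {
  g <- random_genotypes(15, 100, seed = 3)
  p <- colMeans(g) / 2
  Gi <- solve(build_G(g, p)$G + diag(0.01, 15))
  set.seed(3)
  u <- rnorm(15)
  a_ref <- backsolve_snp_effects(u, g, Gi, list(alpha = 0, d = 1), p)
  a_bl <- backsolve_snp_effects(u, g, Gi, list(alpha = 0.05, d = 0.9), p)
  expect_equal(unclass(a_bl), 0.95 * 0.9 * unclass(a_ref),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("indirect predictions obey the centering and linearity identities", {
  g <- random_genotypes(15, 100, seed = 4)
  p <- colMeans(g) / 2
  Gi <- solve(build_G(g, p)$G + diag(0.01, 15))
  set.seed(4)
  a <- backsolve_snp_effects(rnorm(15), g, Gi, list(alpha = 0.05, d = 1), p)
  # the hypothetical mean animal (genotype = 2 * freqs) predicts exactly 0
  gv <- matrix(as.integer(round(2 * p)), 1)
  # use an exactly-centered animal instead: codes equal 2p only when 2p integer
  pint <- round(2 * p) / 2
  aint <- backsolve_snp_effects(rnorm(15), g, Gi, list(alpha = 0.05, d = 1),
                                pint)
  expect_equal(unname(compute_ip(gv, aint)), 0, tolerance = 1e-12)
  # zero effects give zero IP; doubling effects doubles IP
  a0 <- a; a0[] <- 0; attributes(a0) <- attributes(a)
  gv2 <- random_genotypes(6, 100, seed = 5)
  expect_equal(unname(compute_ip(gv2, a0)), rep(0, 6))
  a2 <- a * 2; attributes(a2) <- attributes(a)
  expect_equal(compute_ip(gv2, a2), 2 * compute_ip(gv2, a), tolerance = 1e-12)
  expect_error(compute_ip(gv2[, 1:50], a), "locus count mismatch")
})

test_that("error injection perturbs exactly round(rate * n) loci per animal", {
  g <- random_genotypes(30, 200, seed = 6)
  for (rate in c(0.05, 0.10, 0.20)) {
    ge <- inject_errors(g, rate, seed = 6)
    diffs <- rowSums(ge != g)
    expect_true(all(diffs == round(rate * 200)))
    expect_true(all(ge %in% 0:2))
  }
  # every perturbed entry differs from its original
  ge <- inject_errors(g, 1, seed = 7)
  expect_true(all(ge != g))
  expect_true(all(ge %in% 0:2))
  # rate zero is the identity; invalid rates are rejected
  expect_identical(inject_errors(g, 0), g)
  expect_error(inject_errors(g, 1.2), "rate")
})

test_that("shared-loci mode perturbs the same positions in every animal", {
  g <- random_genotypes(10, 100, seed = 8)
  ge <- inject_errors(g, 0.1, seed = 8, shared_loci = TRUE)
  changed <- apply(ge != g, 1, which)
  expect_true(all(apply(changed, 2, function(x) identical(x, changed[, 1]))))
  expect_equal(nrow(changed), 10)
})

test_that("scenario runner is deterministic and spans all requested rates", {
  g <- random_genotypes(15, 100, seed = 9)
  p <- colMeans(g) / 2
  Gi <- solve(build_G(g, p)$G + diag(0.01, 15))
  set.seed(9)
  a <- backsolve_snp_effects(rnorm(15), g, Gi, list(alpha = 0.05, d = 1), p)
  gv <- random_genotypes(8, 100, seed = 10)
  r1 <- run_scenarios(a, gv, c(0, 0.05, 0.10, 0.20), seed = 11)
  r2 <- run_scenarios(a, gv, c(0, 0.05, 0.10, 0.20), seed = 11)
  expect_identical(r1, r2)
  expect_named(r1, c("correct", "E05", "E10", "E20"))
  expect_true(all(lengths(r1) == 8))
  expect_equal(r1$correct, compute_ip(gv, a))
})
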