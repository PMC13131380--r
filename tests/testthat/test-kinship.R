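test_that("A-inverse of a parent-offspring trio matches the hand-derived matrix", {
  ped <- data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
  Ai <- as.matrix(A_inverse(ped))
  expect_equal(unname(Ai),
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3, 3),
               tolerance = 1e-12)
  expect_equal(unname(as.matrix(A_inverse(data.frame(id = 1, sire = 0, dam = 0)))),
               matrix(1, 1, 1))
})

test_that("A-inverse from Henderson's rules equals the inverse of tabular A", {
  for (s in 1:3) {
    ped <- random_pedigree(200, n_founders = 30, seed = s)
    A <- pedigree_A(ped)
    Ai <- as.matrix(A_inverse(ped))
    expect_lt(max(abs(Ai %*% A - diag(200))), 1e-8)
  }
})

test_that("Meuwissen-Luo inbreeding agrees with tabular A diagonals", {
  ped <- random_pedigree(300, n_founders = 25, seed = 9)
  F <- inbreeding(ped)
  A <- pedigree_A(ped)
  expect_equal(F, diag(A) - 1, tolerance = 1e-10)
  # full sibs mated: offspring F = 0.25
  trio <- data.frame(id = 1:5, sire = c(0, 0, 1, 1, 3), dam = c(0, 0, 2, 2, 4))
  expect_equal(inbreeding(trio)[5], 0.25)
})

test_that("A22 equals the corresponding submatrix of tabular A", {
  ped <- random_pedigree(200, n_founders = 30, seed = 4)
  A <- pedigree_A(ped)
  expect_equal(pedigree_A22(ped, 1:200), A, tolerance = 1e-10)
  set.seed(5)
  ids <- sort(sample(200, 50))
  expect_lt(max(abs(pedigree_A22(ped, ids) - A[ids, ids])), 1e-10)
  # trio with only the offspring genotyped
  trio <- data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
  expect_equal(unname(pedigree_A22(trio, 3)), matrix(1, 1, 1))
  expect_error(pedigree_A22(trio, 7), "unknown id")
})

test_that("VanRaden G matches the 2x2 hand example and is symmetric", {
  codes <- matrix(c(0L, 2L, 2L, 0L), 2, 2)
  rownames(codes) <- c("1", "2")
  grm <- build_G(codes, freqs = c(0.5, 0.5))
  expect_equal(grm$k, 1)
  expect_equal(unname(grm$G), matrix(c(2, -2, -2, 2), 2, 2))
  # identical genotype rows give identical G rows and equal diagonals
  g2 <- random_genotypes(4, 50, seed = 2)
  g2[2, ] <- g2[1, ]
  G <- build_G(g2)$G
  expect_equal(G[1, ], G[2, ])
  expect_equal(G[1, 1], G[2, 2])
  expect_equal(G, t(G))
  expect_error(build_G(matrix(0L, 3, 4)), "monomorphic")
})

test_that("centered gene contents have zero column sums at observed frequencies", {
  g <- random_genotypes(60, 120, seed = 3)
  p <- colMeans(g) / 2
  Z <- gene_content_Z(g, p)
  expect_lt(max(abs(colSums(Z))), 1e-9)
  # monomorphic columns are zeroed even for non-matching codes
  Z2 <- gene_content_Z(g, replace(p, 1:2, c(0, 1)))
  expect_true(all(Z2[, 1:2] == 0))
})

test_that("mean diagonal of G tracks 1 + mean inbreeding on HWE genotypes", {
  # genotypes drawn at known base frequencies with per-animal inbreeding F:
  # an allele pair is IBD with probability F, so var(g) = 2pq(1+F) and the
  # G diagonal averages 1 + mean(F)
  set.seed(20)
  n <- 150; m <- 2000
  p <- runif(m, 0.1, 0.9)
  Fi <- runif(n, 0, 0.3)
  g <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    ibd <- rbinom(m, 1, Fi[i])
    a1 <- rbinom(m, 1, p)
    a2 <- ifelse(ibd == 1, a1, rbinom(m, 1, p))
    g[i, ] <- as.integer(a1 + a2)
  }
  G <- build_G(g, freqs = p)$G
  expect_lt(abs(mean(diag(G)) - (1 + mean(Fi))), 0.05)
})

test_that("tuning and blending satisfy their algebraic identities", {
  g <- random_genotypes(40, 300, seed = 6)
  G <- build_G(g)$G
  ped <- random_pedigree(80, n_founders = 20, seed = 6)
  A22 <- pedigree_A22(ped, 41:80)
  tb <- tune_and_blend(G, A22, alpha = 0.05)
  expect_equal(tb$blend$c, mean(A22) - mean(G))
  expect_equal(tb$blend$d, 1 - tb$blend$c / 2)
  expect_equal(mean(tb$G_star),
               (1 - 0.05) * (tb$blend$c + tb$blend$d * mean(G)) +
                 0.05 * mean(A22), tolerance = 1e-12)
  # mean(A22) = mean(G): c = 0, d = 1, G* = (1-a) G + a A22
  Gs <- G - mean(G) + mean(A22)
  tb0 <- tune_and_blend(Gs, A22, alpha = 0.05)
  expect_equal(tb0$blend$c, 0, tolerance = 1e-12)
  expect_equal(tb0$blend$d, 1)
  expect_equal(tb0$G_star, 0.95 * Gs + 0.05 * A22, tolerance = 1e-12)
  # alpha = 0, c = 0: G* = G
  expect_equal(tune_and_blend(Gs, A22, alpha = 0)$G_star, Gs,
               tolerance = 1e-12)
  # applying to G already equal to A22 with alpha = 1 returns A22 exactly
  expect_equal(tune_and_blend(A22, A22, alpha = 1)$G_star, A22,
               tolerance = 1e-12)
  # two-equation variant matches both summary statistics
  tb2 <- tune_and_blend(G, A22, alpha = 0, method = "two_eq")
  expect_equal(mean(tb2$G_star), mean(A22), tolerance = 1e-10)
  expect_equal(mean(diag(tb2$G_star)), mean(diag(A22)), tolerance = 1e-10)
})

test_that("APY inverse with a full core equals the dense inverse", {
  g <- random_genotypes(60, 400, seed = 7)
  ped <- random_pedigree(120, n_founders = 30, seed = 7)
  Gs <- tune_and_blend(build_G(g), pedigree_A22(ped, 61:120))$G_star
  expect_lt(max(abs(apy_inverse(Gs, 1:60) - solve(Gs))), 1e-8)
})

test_that("APY inverse with a partial core approximates the dense inverse action", {
  g <- random_genotypes(100, 600, seed = 8)
  ped <- random_pedigree(200, n_founders = 40, seed = 8)
  Gs <- tune_and_blend(build_G(g), pedigree_A22(ped, 101:200))$G_star
  set.seed(8)
  core <- sort(sample(100, 80))
  Ainv_apy <- apy_inverse(Gs, core)
  u <- rnorm(100)
  direct <- solve(Gs, u)
  apy <- Ainv_apy %*% u
  expect_gt(cor(direct, as.vector(apy)), 0.99)
  # single-animal core on an identity matrix is exact
  expect_equal(apy_inverse(diag(5), 3), diag(5))
  expect_error(apy_inverse(matrix(0, 3, 3), 1), "singular")
})

test_that("H-inverse genotyped-block correction reproduces the textbook H", {
  ped <- random_pedigree(50, n_founders = 12, seed = 10)
  gid <- 26:50
  g <- random_genotypes(25, 300, seed = 10)
  rownames(g) <- as.character(gid)
  A <- pedigree_A(ped)
  A22 <- A[gid, gid]
  Gs <- tune_and_blend(build_G(g), A22)$G_star
  delta <- H_inverse_delta(solve(Gs), solve(A22))
  expect_equal(delta, t(delta))
  # textbook H from its block formula
  nid <- setdiff(1:50, gid)
  A12 <- A[nid, gid]; A11 <- A[nid, nid]
  A22i <- solve(A22)
  H <- matrix(0, 50, 50)
  H[nid, nid] <- A11 + A12 %*% A22i %*% (Gs - A22) %*% A22i %*% t(A12)
  H[nid, gid] <- A12 %*% A22i %*% Gs
  H[gid, nid] <- t(H[nid, gid])
  H[gid, gid] <- Gs
  Hinv <- as.matrix(A_inverse(ped))
  Hinv[gid, gid] <- Hinv[gid, gid] + delta
  expect_lt(max(abs(Hinv %*% H - diag(50))), 1e-6)
  # G* = A22 collapses the correction to zero
  expect_equal(H_inverse_delta(solve(A22), solve(A22)),
               matrix(0, 25, 25), tolerance = 1e-12)
})

test_that("relationship matrices round-trip through the three-column text dump", {
  M <- pedigree_A(random_pedigree(20, n_founders = 6, seed = 11))
  f <- tempfile()
  write_relmat(M, f, ids = 1:20)
  d <- read.table(f)
  M2 <- matrix(0, 20, 20)
  M2[cbind(d$V1, d$V2)] <- d$V3
  M2[upper.tri(M2)] <- t(M2)[upper.tri(M2)]
  expect_equal(M2, M, tolerance = 1e-6)
  unlink(f)
})
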