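# Shared fixtures: everything is generated in code at test time.

.cache <- new.env(parent = emptyenv())

# A configuration small enough for seconds-scale end-to-end runs.
tiny_config <- function(...) {
  args <- list(n_sires = 4, n_dams = 24, n_generations = 6,
               training_generations = 3:5, validation_generation = 6,
               hist_n0 = 40, hist_n1 = 24, hist_n2 = 16,
               hist_gens1 = 15, hist_gens2 = 15, offspring_per_dam = 4,
               n_snps = 500, n_qtl = 25, n_loci_pool = 4000,
               genome_cM = 80, n_replicates = 2)
  over <- list(...)
  args[names(over)] <- over
  if (!is.null(over$n_generations) && is.null(over$validation_generation)) {
    args$validation_generation <- args$n_generations
    args$training_generations <-
      max(1, args$n_generations - 3):(args$n_generations - 1)
  }
  do.call(sim_config, args)
}

get_tiny_pop <- function() {
  if (is.null(.cache$tiny_pop))
    .cache$tiny_pop <- simulate_population(tiny_config(), seed = 42)
  .cache$tiny_pop
}

# Random valid pedigree: founders then offspring of random earlier parents.
random_pedigree <- function(n, n_founders = 20, seed = 1) {
  set.seed(seed)
  sire <- dam <- integer(n)
  sex <- c(rep(c("M", "F"), length.out = n_founders),
           sample(c("M", "F"), n - n_founders, replace = TRUE))
  for (i in (n_founders + 1):n) {
    males <- which(sex[1:(i - 1)] == "M")
    females <- which(sex[1:(i - 1)] == "F")
    sire[i] <- sample(males, 1)
    dam[i] <- sample(females, 1)
  }
  data.frame(id = 1:n, sire = sire, dam = dam, sex = sex,
             generation = 0L)
}

# Closed-form GLS/BLUP oracle for y = X b + u + e with var(u) = s2a * K.
blup_oracle <- function(y, X, Zinc, K, s2a, s2e) {
  V <- Zinc %*% K %*% t(Zinc) * s2a + diag(s2e, length(y))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- s2a * K %*% t(Zinc) %*% Vi %*% (y - X %*% b)
  list(b = as.vector(b), u = as.vector(u))
}

# Random genotype matrix with all codes represented.
random_genotypes <- function(n, m, seed = 1, freq = NULL) {
  set.seed(seed)
  if (is.null(freq)) freq <- runif(m, 0.1, 0.9)
  g <- sapply(freq, function(p) rbinom(n, 2, p))
  storage.mode(g) <- "integer"
  rownames(g) <- as.character(seq_len(n))
  g
}
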