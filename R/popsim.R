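#' Simulate the bottlenecked historical population
#'
#' Random union of gametes, no selection, equal sex ratio, discrete
#' generations. Census size declines linearly `hist_n0 -> hist_n1` over
#' `hist_gens1` generations, then `hist_n1 -> hist_n2` over `hist_gens2`
#' (two bottlenecks), so that drift generates linkage disequilibrium while
#' not all loci fix. Recurrent mutation flips allele states at
#' `map$mutation_rate` per locus per gamete.
#'
#' @param config a [sim_config()].
#' @param map a [genome_map()] for the locus pool; created from the config
#'   if `NULL` (consumes RNG state).
#' @param init_haplo optional initial haplotypes, an `n_loci x (2*hist_n0)`
#'   raw 0/1 matrix (loci in rows, gametes in columns). Defaults to
#'   independent Bernoulli(0.5) alleles.
#' @param seed optional RNG seed.
#' @return object of class `founder_pool`: list with `haplo` (raw matrix,
#'   loci x gametes, final historical generation) and `map`.
#' @export
simulate_historical <- function(config, map = NULL, init_haplo = NULL, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(map)) map <- config_genome_map(config)
  L <- nrow(map$loci)
  if (is.null(init_haplo)) {
    init_haplo <- matrix(as.raw(stats::rbinom(L * 2L * config$hist_n0, 1L, 0.5)),
                         nrow = L)
  }
  stopifnot(is.raw(init_haplo), nrow(init_haplo) == L)
  sizes1 <- round(seq(config$hist_n0, config$hist_n1,
                      length.out = config$hist_gens1 + 1L))[-1L]
  sizes2 <- if (config$hist_gens2 > 0)
    round(seq(config$hist_n1, config$hist_n2,
              length.out = config$hist_gens2 + 1L))[-1L] else integer(0)
  lay <- map_cpp_layout(map)
  haplo <- cpp_random_mating_phase(init_haplo, as.integer(c(sizes1, sizes2)),
                                   lay$posM, lay$chr_start, lay$chr_end,
                                   map$mutation_rate)
  structure(list(haplo = haplo, map = map), class = "founder_pool")
}

#' Select the SNP panel and QTL from the segregating locus pool
#'
#' After the historical phase, loci with minor-allele frequency at least
#' `config$maf_min` are eligible; `n_snps + n_qtl` of them are sampled at
#' random (preserving map order) and split at random into the SNP panel and
#' the QTL set, which are therefore position-disjoint. If too few loci pass
#' the MAF filter, the shortfall is filled with the highest-MAF remaining
#' segregating loci; an error is raised only if not enough loci segregate
#' at all.
#'
#' @param pool a `founder_pool` from [simulate_historical()].
#' @param config a [sim_config()].
#' @param seed optional RNG seed.
#' @return a `founder_pool` whose `haplo` holds only the panel + QTL loci
#'   and whose `map` carries `snp_idx`/`qtl_idx` (indices into `map$loci`).
#' @export
select_panel <- function(pool, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  haplo <- pool$haplo
  map <- pool$map
  need <- config$n_snps + config$n_qtl
  freq <- rowMeans(matrix(as.integer(haplo), nrow = nrow(haplo)))
  maf <- pmin(freq, 1 - freq)
  eligible <- which(maf >= config$maf_min)
  if (length(eligible) < need) {
    seg <- setdiff(which(maf > 0), eligible)
    seg <- seg[order(maf[seg], decreasing = TRUE)]
    eligible <- c(eligible, seg[seq_len(min(length(seg), need - length(eligible)))])
    if (length(eligible) < need)
      stop("fewer than n_snps + n_qtl segregating loci survive the historical phase")
  }
  keep <- sort(sample(eligible, need))
  qtl <- sort(sample(seq_len(need), config$n_qtl))
  map$loci <- map$loci[keep, , drop = FALSE]
  rownames(map$loci) <- NULL
  map$qtl_idx <- qtl
  map$snp_idx <- setdiff(seq_len(need), qtl)
  pool$haplo <- haplo[keep, , drop = FALSE]
  pool$map <- map
  pool
}

#' Expand the historical population and sample current-population founders
#'
#' Random mating for `config$expand_gens` generations with exponential
#' growth of the census until at least `founder_buffer * (n_sires + n_dams)`
#' animals are available, then `n_sires` males and `n_dams` females are
#' sampled without replacement as generation-0 founders of the current
#' population.
#'
#' @param config a [sim_config()].
#' @param pool a `founder_pool`, normally after [select_panel()].
#' @param seed optional RNG seed.
#' @return object of class `population` holding generation 0.
#' @export
expand_and_found <- function(config, pool, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  haplo <- pool$haplo
  map <- pool$map
  if (ncol(haplo) < 4L) stop("historical pool too small")
  n_last <- ncol(haplo) %/% 2L
  target <- ceiling(config$founder_buffer * 2 * max(config$n_sires, config$n_dams))
  lay <- map_cpp_layout(map)
  if (config$expand_gens > 0L) {
    rate <- max((target / n_last)^(1 / config$expand_gens), 1)
    sizes <- ceiling(n_last * rate^(seq_len(config$expand_gens)))
    sizes[config$expand_gens] <- max(sizes[config$expand_gens], target)
    haplo <- cpp_random_mating_phase(haplo, as.integer(sizes),
                                     lay$posM, lay$chr_start, lay$chr_end,
                                     map$mutation_rate)
  }
  n_exp <- ncol(haplo) %/% 2L
  males <- seq(1L, n_exp, by = 2L)    # even 0-based index = odd 1-based
  females <- seq(2L, n_exp, by = 2L)
  if (length(males) < config$n_sires || length(females) < config$n_dams)
    stop("expanded pool too small to supply the requested founders")
  sires <- sample(males, config$n_sires)
  dams <- sample(females, config$n_dams)
  founders <- c(sires, dams)
  n0 <- length(founders)

  # preallocate the haplotype store for the whole current population
  r <- dam_growth_rate(config)
  dams_sched <- floor(config$n_dams * (1 + r)^(seq_len(config$n_generations) - 1L))
  n_max <- n0 + config$offspring_per_dam * sum(dams_sched)
  store <- matrix(as.raw(0L), nrow = nrow(haplo), ncol = 2L * n_max)
  gam <- haplo[, as.vector(rbind(2L * founders - 1L, 2L * founders)), drop = FALSE]
  cpp_fill_cols(store, 1L, gam)

  ped <- data.frame(id = seq_len(n0), sire = 0L, dam = 0L,
                    sex = rep(c("M", "F"), c(config$n_sires, config$n_dams)),
                    generation = 0L, stringsAsFactors = FALSE)
  founder_freqs <- colMeans(cpp_genotypes(store, seq_len(n0),
                                          as.integer(map$snp_idx))) / 2
  structure(list(ped = ped, F = numeric(n0), founder_freqs = founder_freqs,
                 tbv = rep(NA_real_, n0), u_pg = rep(NA_real_, n0),
                 phenotype = rep(NA_real_, n0), ebv = rep(NA_real_, n0),
                 haplo = store, n_animals = n0, n_max = n_max,
                 map = map, trait = NULL, config = config),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("Simulated population:", x$n_animals, "animals,",
      max(x$ped$generation), "generations\n")
  cat("  panel:", length(x$map$snp_idx), "SNPs;", length(x$map$qtl_idx), "QTL\n")
  if (!is.null(x$trait))
    cat(sprintf("  trait: h2 = %.2f, mean TBV last generation = %.3f\n",
                x$trait$h2,
                mean(x$tbv[x$ped$generation == max(x$ped$generation)])))
  invisible(x)
}

# True breeding values and phenotypes for a block of animals.
# TBV = centered QTL content x effects + residual polygenic deviation.
simulate_records <- function(pop, ids) {
  trait <- pop$trait
  geno_q <- cpp_genotypes(pop$haplo, as.integer(ids),
                          as.integer(pop$map$qtl_idx))
  qtl_val <- as.vector(geno_q %*% trait$qtl_effects) -
    sum(2 * trait$qtl_freqs * trait$qtl_effects)
  s2pg <- trait$rpg_fraction * trait$sigma2_p
  s <- pop$ped$sire[ids]; d <- pop$ped$dam[ids]
  founder <- s == 0L & d == 0L
  u_pg <- numeric(length(ids))
  u_pg[founder] <- stats::rnorm(sum(founder), 0, sqrt(s2pg))
  if (any(!founder)) {
    i <- which(!founder)
    fbar <- 0.5 * (pop$F[s[i]] + pop$F[d[i]])
    u_pg[i] <- 0.5 * (pop$u_pg[s[i]] + pop$u_pg[d[i]]) +
      stats::rnorm(length(i), 0, sqrt(0.5 * s2pg * (1 - fbar)))
  }
  tbv <- qtl_val + u_pg
  s2e <- (1 - trait$h2) * trait$sigma2_p
  phen <- tbv + stats::rnorm(length(ids), 0, sqrt(s2e))
  list(tbv = tbv, u_pg = u_pg, phenotype = phen)
}

# Selection scores for the current state of the population.
selection_scores <- function(pop, lambda) {
  switch(pop$config$selection,
         blup = pedigree_ebv(pop$ped, pop$phenotype, lambda),
         phenotype = pop$phenotype,
         random = stats::rnorm(pop$n_animals))
}

# Rank-matched assortative mating: sires and dams sorted by score, dams cut
# into contiguous rank blocks assigned to sires in rank order.
mate_assortative <- function(sires, dams, score, litter) {
  so <- sires[order(score[sires], decreasing = TRUE)]
  do <- dams[order(score[dams], decreasing = TRUE)]
  ns <- length(so); nd <- length(do)
  base <- nd %/% ns; extra <- nd %% ns
  block <- rep(c(base + 1L, base), c(extra, ns - extra))
  dam_sire <- rep(so, block)
  list(sire = rep(dam_sire, each = litter), dam = rep(do, each = litter))
}

#' Simulate the selected current population
#'
#' Starting from generation-0 founders, runs `config$n_generations` of
#' truncation selection: each generation all breeding dams produce
#' `offspring_per_dam` offspring under rank-matched assortative mating,
#' records (TBV, residual polygenic deviation, phenotype on both sexes) are
#' simulated, EBV are re-estimated (pedigree BLUP on all phenotypes to
#' date, with the true variance ratio), and the breeding sets are updated:
#' the stated fractions of sires and dams are culled from the bottom of the
#' EBV ranking and replaced by the top-ranked young candidates, with the
#' dam count growing per [sim_config()]'s `growth_total`.
#'
#' @param config a [sim_config()].
#' @param founders a `population` from [expand_and_found()].
#' @param trait a [trait_model()] with QTL effects assigned
#'   ([assign_qtl_effects()]); if `NULL`, effects are drawn and scaled to the
#'   founder QTL allele frequencies.
#' @param seed optional RNG seed.
#' @return the completed `population`.
#' @export
simulate_selection <- function(config, founders, trait = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- founders
  stopifnot(inherits(pop, "population"), max(pop$ped$generation) == 0L)
  pop$config <- config
  n0 <- pop$n_animals
  if (is.null(trait)) {
    trait <- trait_model(config$h2, config$rpg_fraction, config$sigma2_p)
  }
  if (is.null(trait$qtl_effects)) {
    gq <- cpp_genotypes(pop$haplo, seq_len(n0), as.integer(pop$map$qtl_idx))
    trait <- assign_qtl_effects(pop$map, trait, colMeans(gq) / 2)
  }
  pop$trait <- trait
  lambda <- (1 - trait$h2) / trait$h2

  if (anyNA(pop$phenotype[seq_len(n0)])) {
    rec <- simulate_records(pop, seq_len(n0))
    pop$tbv[seq_len(n0)] <- rec$tbv
    pop$u_pg[seq_len(n0)] <- rec$u_pg
    pop$phenotype[seq_len(n0)] <- rec$phenotype
  }
  score <- selection_scores(pop, lambda)
  pop$ebv[seq_len(n0)] <- score

  sires <- which(pop$ped$sex == "M" & pop$ped$generation == 0L)
  dams <- which(pop$ped$sex == "F" & pop$ped$generation == 0L)
  r <- dam_growth_rate(config)
  lay <- map_cpp_layout(pop$map)
  litter <- config$offspring_per_dam

  for (g in seq_len(config$n_generations)) {
    m <- mate_assortative(sires, dams, score, litter)
    n_off <- length(m$sire)
    ids <- pop$n_animals + seq_len(n_off)
    if (max(ids) > pop$n_max) stop("haplotype store overflow")
    gam <- cpp_make_offspring(pop$haplo, as.integer(m$sire), as.integer(m$dam),
                              lay$posM, lay$chr_start, lay$chr_end,
                              pop$map$mutation_rate)
    cpp_fill_cols(pop$haplo, 2L * pop$n_animals + 1L, gam)
    pop$ped <- rbind(pop$ped, data.frame(
      id = ids, sire = m$sire, dam = m$dam,
      sex = sample(c("M", "F"), n_off, replace = TRUE),
      generation = g, stringsAsFactors = FALSE))
    pop$n_animals <- pop$n_animals + n_off
    pop$F <- cpp_inbreeding(as.integer(pop$ped$sire), as.integer(pop$ped$dam))
    rec <- simulate_records(pop, ids)
    pop$tbv <- c(pop$tbv, rec$tbv)
    pop$u_pg <- c(pop$u_pg, rec$u_pg)
    pop$phenotype <- c(pop$phenotype, rec$phenotype)
    pop$ebv <- c(pop$ebv, rep(NA_real_, n_off))

    if (g == config$n_generations) break
    score <- selection_scores(pop, lambda)
    pop$ebv <- score
    young <- pop$ped$id[pop$ped$generation == g]
    young_m <- young[pop$ped$sex[young] == "M"]
    young_f <- young[pop$ped$sex[young] == "F"]

    n_keep_s <- round((1 - config$sire_replacement) * length(sires))
    keep_s <- sires[order(score[sires], decreasing = TRUE)][seq_len(n_keep_s)]
    n_new_s <- config$n_sires - n_keep_s
    if (n_new_s > length(young_m))
      stop("not enough young males to meet the sire replacement quota")
    new_s <- young_m[order(score[young_m], decreasing = TRUE)][seq_len(n_new_s)]
    sires <- c(keep_s, new_s)

    target_d <- floor(config$n_dams * (1 + r)^g)
    n_keep_d <- min(round((1 - config$dam_replacement) * length(dams)), target_d)
    keep_d <- dams[order(score[dams], decreasing = TRUE)][seq_len(n_keep_d)]
    n_new_d <- target_d - n_keep_d
    if (n_new_d > length(young_f))
      stop("not enough young females to meet the dam replacement quota")
    new_d <- if (n_new_d > 0)
      young_f[order(score[young_f], decreasing = TRUE)][seq_len(n_new_d)]
    else integer(0)
    dams <- c(keep_d, new_d)
  }
  pop
}

#' Simulate a complete population for one replicate
#'
#' Runs the whole generator: genome map, historical bottlenecks, panel/QTL
#' selection, expansion and founding, QTL effect scaling, and the selected
#' current population. Each stage draws from a named sub-seed derived from
#' `seed`, so stages are independently reproducible.
#'
#' @param config a [sim_config()].
#' @param seed master seed for the replicate.
#' @return a `population`.
#' @export
simulate_population <- function(config, seed = 1L) {
  ss <- stage_seeds(seed, c("map", "historical", "panel", "expansion",
                            "qtl", "selection"))
  set.seed(ss[["map"]])
  map <- config_genome_map(config)
  pool <- simulate_historical(config, map, seed = ss[["historical"]])
  pool <- select_panel(pool, config, seed = ss[["panel"]])
  founders <- expand_and_found(config, pool, seed = ss[["expansion"]])
  gq <- cpp_genotypes(founders$haplo, seq_len(founders$n_animals),
                      as.integer(founders$map$qtl_idx))
  set.seed(ss[["qtl"]])
  trait <- assign_qtl_effects(founders$map,
                              trait_model(config$h2, config$rpg_fraction,
                                          config$sigma2_p),
                              colMeans(gq) / 2)
  simulate_selection(config, founders, trait, seed = ss[["selection"]])
}

#' SNP-panel genotypes of a set of animals
#'
#' @param pop a `population`.
#' @param ids animal ids; defaults to every animal.
#' @return integer matrix (animals x SNPs) of 0/1/2 codes with ids as
#'   rownames.
#' @export
pop_genotypes <- function(pop, ids = NULL) {
  if (is.null(ids)) ids <- pop$ped$id
  g <- cpp_genotypes(pop$haplo, as.integer(ids), as.integer(pop$map$snp_idx))
  rownames(g) <- as.character(ids)
  g
}

#' @rdname pop_genotypes
#' @export
training_ids <- function(pop) {
  pop$ped$id[pop$ped$generation %in% pop$config$training_generations]
}

#' @rdname pop_genotypes
#' @export
validation_ids <- function(pop) {
  pop$ped$id[pop$ped$generation == pop$config$validation_generation]
}
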