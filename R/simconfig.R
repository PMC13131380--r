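#' Simulation configuration
#'
#' Collects every knob of the breeding-program simulator: the bottlenecked
#' historical phase, the random-mating expansion, and the selected current
#' population. See [full_scale_config()] for the published full-scale
#' settings and [desk_profile()] for the reduced configuration that runs on
#' one CPU in minutes.
#'
#' The historical phase starts `hist_gens1` generations at sizes declining
#' linearly `hist_n0 -> hist_n1`, then `hist_gens2` generations declining
#' `hist_n1 -> hist_n2` (two bottlenecks). Afterwards the population is
#' randomly mated for `expand_gens` generations with exponential growth of
#' the census until enough animals of each sex are available, from which
#' the current-population founders are sampled.
#'
#' `growth_total` is the cumulative growth of the breeding-female count
#' across the current phase: dams increase by rate
#' `(1 + growth_total)^(1/(n_generations - 1)) - 1` per generation, rounded
#' down to whole animals.
#'
#' @param n_sires,n_dams breeding males/females founding the current
#'   population.
#' @param n_generations generations of selection in the current population.
#' @param growth_total cumulative growth of the number of breeding females
#'   over the current phase (0.30 = +30 percent).
#' @param sire_replacement,dam_replacement fraction of breeding sires/dams
#'   replaced each generation (lowest-EBV culled, highest-EBV young recruited).
#' @param offspring_per_dam litter size per mated dam (sexes equally likely).
#' @param selection `"blup"` (pedigree-BLUP EBV, the default), `"phenotype"`
#'   (mass selection), or `"random"` (no selection; drift-only control).
#' @param training_generations,validation_generation generation numbers used
#'   as the genotyped training and validation sets.
#' @param hist_n0,hist_n1,hist_n2,hist_gens1,hist_gens2 historical schedule.
#' @param expand_gens random-mating expansion generations.
#' @param founder_buffer safety multiple on the expansion's final census
#'   (`2 * max(n_sires, n_dams)` animals, each sex being half the census)
#'   so founders can be sampled without replacement.
#' @param n_chr,n_snps,n_qtl,n_loci_pool genome settings; the pool must be
#'   large enough that `n_snps + n_qtl` loci still segregate after the
#'   historical phase.
#' @param genome_cM total genetic map length in cM. When scaling the study
#'   down, map length should shrink with the marker count so that the
#'   per-marker linkage disequilibrium (the quantity driving how genotyping
#'   errors attenuate indirect predictions) stays comparable.
#' @param mutation_rate recurrent per-locus mutation rate.
#' @param maf_min minimum minor-allele frequency for panel eligibility.
#' @param h2,rpg_fraction,sigma2_p trait model, see [trait_model()].
#' @param n_replicates replicates of the whole experiment.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_sires = 25, n_dams = 2500, n_generations = 15,
                       growth_total = 0.30,
                       sire_replacement = 0.60, dam_replacement = 0.20,
                       offspring_per_dam = 5, selection = "blup",
                       training_generations = 11:14, validation_generation = 15,
                       hist_n0 = 1000, hist_n1 = 200, hist_n2 = 100,
                       hist_gens1 = 1020, hist_gens2 = 1000, expand_gens = 8,
                       founder_buffer = 1.15,
                       n_chr = 29, n_snps = 70000, n_qtl = 1000,
                       n_loci_pool = NULL, genome_cM = 2333,
                       mutation_rate = 1e-4, maf_min = 0.05,
                       h2 = 0.25, rpg_fraction = 0.05, sigma2_p = 1,
                       n_replicates = 5) {
  if (is.null(n_loci_pool)) n_loci_pool <- 5L * (n_snps + n_qtl)
  cfg <- list(n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
              n_generations = as.integer(n_generations),
              growth_total = growth_total,
              sire_replacement = sire_replacement,
              dam_replacement = dam_replacement,
              offspring_per_dam = as.integer(offspring_per_dam),
              selection = match.arg(selection, c("blup", "phenotype", "random")),
              training_generations = as.integer(training_generations),
              validation_generation = as.integer(validation_generation),
              hist_n0 = as.integer(hist_n0), hist_n1 = as.integer(hist_n1),
              hist_n2 = as.integer(hist_n2),
              hist_gens1 = as.integer(hist_gens1),
              hist_gens2 = as.integer(hist_gens2),
              expand_gens = as.integer(expand_gens),
              founder_buffer = founder_buffer,
              n_chr = as.integer(n_chr), n_snps = as.integer(n_snps),
              n_qtl = as.integer(n_qtl), n_loci_pool = as.integer(n_loci_pool),
              genome_cM = genome_cM,
              mutation_rate = mutation_rate, maf_min = maf_min,
              h2 = h2, rpg_fraction = rpg_fraction, sigma2_p = sigma2_p,
              n_replicates = as.integer(n_replicates))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_sires >= 1, n_dams >= 1, n_generations >= 1,
              growth_total >= 0, offspring_per_dam >= 1,
              sire_replacement >= 0, sire_replacement <= 1,
              dam_replacement >= 0, dam_replacement <= 1,
              hist_n0 >= 2, hist_n1 >= 2, hist_n2 >= 2,
              hist_gens1 >= 1, hist_gens2 >= 0, expand_gens >= 0,
              n_loci_pool >= n_snps + n_qtl, genome_cM > 0,
              mutation_rate >= 0, mutation_rate < 1,
              maf_min >= 0, maf_min < 0.5, n_replicates >= 1,
              all(training_generations >= 1),
              all(training_generations < validation_generation),
              validation_generation <= n_generations)
  })
  invisible(cfg)
}

#' Full-scale configuration
#'
#' The published simulation design: two historical bottlenecks
#' (1,000 to 200 over 1,020 generations, then 200 to 100 over 1,000
#' generations), 8 generations of random-mating expansion, 25 sires and
#' 2,500 dams founding a current population selected for 15 generations
#' (60%/20% sire/dam replacement, 30% growth of the breeding females),
#' a 29-chromosome 23.33 Morgan genome with 70,000 panel SNPs and 1,000
#' QTL, h2 = 0.25 with a 5% residual polygenic fraction, 5 replicates.
#' This configuration is far beyond desk scale; see [desk_profile()].
#'
#' @param ... overrides passed to [sim_config()].
#' @export
full_scale_config <- function(...) sim_config(...)

#' Desk-scale profile
#'
#' A reduced configuration preserving the design's structure while running
#' on one CPU: about 3,000 genotyped training animals (generations 11-14),
#' about 800 validation candidates (generation 15), the full complement of
#' 25 breeding sires (the sire count pins the effective population size,
#' which the full-scale design fixes near 100; with 120 dams the desk
#' profile sits at about 83) with 120 base dams, 5,000 panel SNPs and 200
#' QTL on a 29-chromosome map scaled to 2 Morgans, and a shortened
#' historical phase (100 + 100 generations at sizes 500 -> 100 -> 50) that
#' preserves enough segregating loci while keeping the bottleneck/drift
#' structure. All other rates match the full-scale design.
#'
#' @param ... overrides passed to [sim_config()].
#' @export
desk_profile <- function(...) {
  args <- list(n_sires = 25L, n_dams = 120L,
               hist_n0 = 500L, hist_n1 = 100L, hist_n2 = 50L,
               hist_gens1 = 100L, hist_gens2 = 100L,
               n_snps = 5000L, n_qtl = 200L, genome_cM = 200)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' Scale a configuration
#'
#' Proportionally reduces animal counts, marker/QTL counts and historical
#' generations by `scale_factor` while preserving rates and ratios.
#'
#' @param config a [sim_config()].
#' @param scale_factor multiplier in (0, 1].
#' @export
scale_config <- function(config, scale_factor) {
  stopifnot(inherits(config, "sim_config"), scale_factor > 0, scale_factor <= 1)
  sc <- function(x, lo) max(lo, as.integer(floor(x * scale_factor)))
  config$n_sires <- sc(config$n_sires, 2L)
  config$n_dams <- sc(config$n_dams, 4L)
  config$hist_n0 <- sc(config$hist_n0, 8L)
  config$hist_n1 <- sc(config$hist_n1, 6L)
  config$hist_n2 <- sc(config$hist_n2, 4L)
  config$hist_gens1 <- sc(config$hist_gens1, 2L)
  config$hist_gens2 <- sc(config$hist_gens2, 1L)
  config$n_snps <- sc(config$n_snps, 10L)
  config$n_qtl <- sc(config$n_qtl, 2L)
  config$n_loci_pool <- 5L * (config$n_snps + config$n_qtl)
  config$genome_cM <- config$genome_cM * scale_factor
  validate_sim_config(config)
  config
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Breeding-program simulation config\n")
  cat(sprintf("  historical: %d -> %d over %d gens, %d -> %d over %d gens\n",
              x$hist_n0, x$hist_n1, x$hist_gens1, x$hist_n1, x$hist_n2, x$hist_gens2))
  cat(sprintf("  expansion: %d generations; founders: %d sires + %d dams\n",
              x$expand_gens, x$n_sires, x$n_dams))
  cat(sprintf("  current: %d generations, %s selection, %.0f%%/%.0f%% replacement, +%.0f%% total growth\n",
              x$n_generations, x$selection, 100 * x$sire_replacement,
              100 * x$dam_replacement, 100 * x$growth_total))
  cat(sprintf("  genome: %d chr, %d SNPs + %d QTL from a %d-locus pool\n",
              x$n_chr, x$n_snps, x$n_qtl, x$n_loci_pool))
  cat(sprintf("  trait: h2 = %.2f (polygenic %.2f), sigma2_p = %g\n",
              x$h2, x$rpg_fraction, x$sigma2_p))
  cat(sprintf("  training gens %s; validation gen %d; %d replicates\n",
              paste(range(x$training_generations), collapse = "-"),
              x$validation_generation, x$n_replicates))
  invisible(x)
}

# Per-generation dam growth rate implied by the cumulative growth_total.
dam_growth_rate <- function(config) {
  if (config$n_generations <= 1) return(0)
  (1 + config$growth_total)^(1 / (config$n_generations - 1)) - 1
}

# Named, reproducible sub-seeds for the simulation stages of one replicate.
stage_seeds <- function(master_seed, stages) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  names(s) <- stages
  s
}
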