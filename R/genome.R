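#' Build a genome map
#'
#' Defines a multi-chromosome genetic map with a pool of biallelic loci at
#' random map positions. Chromosome lengths default to a deterministic
#' decreasing schedule from `len_max` to `len_min` cM whose total equals
#' `total_cM`, emulating a cattle-like genome (29 autosomes, 23.33 Morgans).
#' Loci are allocated to chromosomes in proportion to map length and placed
#' uniformly at random; positions are drawn with the current RNG state.
#'
#' At this stage the map describes the simulated locus *pool*; which loci end
#' up as the SNP panel and which as QTL is decided after the historical phase
#' by [select_panel()], once it is known which loci still segregate.
#'
#' @param n_loci total number of loci in the pool.
#' @param n_chr number of chromosomes.
#' @param chr_length_cM optional explicit per-chromosome lengths in cM;
#'   overrides the default schedule.
#' @param total_cM,len_min,len_max parameters of the default length schedule.
#' @param mutation_rate per-locus, per-gamete probability of an allele flip.
#' @return an object of class `genome_map`: a list with `n_chr`,
#'   `chr_len_cM`, `loci` (data.frame `chr`, `pos_cM`, ordered), and
#'   `mutation_rate`. `snp_idx`/`qtl_idx` are filled by [select_panel()].
#' @export
genome_map <- function(n_loci, n_chr = 29, chr_length_cM = NULL,
                       total_cM = 2333, len_min = 40, len_max = 146,
                       mutation_rate = 1e-4) {
  stopifnot(n_loci >= 1, n_chr >= 1, mutation_rate >= 0, mutation_rate < 1)
  if (is.null(chr_length_cM)) {
    chr_length_cM <- default_chr_lengths(n_chr, total_cM, len_min, len_max)
  }
  stopifnot(length(chr_length_cM) == n_chr, all(chr_length_cM > 0))
  # allocate loci proportionally to length, remainders to longest chromosomes
  frac <- chr_length_cM / sum(chr_length_cM)
  cnt <- floor(frac * n_loci)
  rem <- n_loci - sum(cnt)
  if (rem > 0) {
    ord <- order(chr_length_cM, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1L
  }
  chr <- rep.int(seq_len(n_chr), cnt)
  pos <- unlist(lapply(seq_len(n_chr), function(c) {
    p <- sort(stats::runif(cnt[c], 0, chr_length_cM[c]))
    while (anyDuplicated(p)) p <- sort(stats::runif(cnt[c], 0, chr_length_cM[c]))
    p
  }))
  structure(list(n_chr = n_chr, chr_len_cM = as.numeric(chr_length_cM),
                 loci = data.frame(chr = chr, pos_cM = pos),
                 snp_idx = integer(0), qtl_idx = integer(0),
                 mutation_rate = mutation_rate),
            class = "genome_map")
}

# Genome map implied by a sim_config: cattle-like length schedule scaled to
# the configured total map length.
config_genome_map <- function(config) {
  sc <- config$genome_cM / 2333
  genome_map(config$n_loci_pool, n_chr = config$n_chr,
             total_cM = config$genome_cM,
             len_min = 40 * sc, len_max = 146 * sc,
             mutation_rate = config$mutation_rate)
}

# Deterministic decreasing chromosome lengths: len_min + (len_max-len_min)*u^g
# over u = 1..0, with the exponent g chosen so the total equals total_cM.
default_chr_lengths <- function(n_chr, total_cM, len_min, len_max) {
  if (n_chr == 1) return(total_cM)
  u <- seq(1, 0, length.out = n_chr)
  need <- (total_cM - n_chr * len_min) / (len_max - len_min)
  if (need <= 1 || need >= n_chr)
    stop("total_cM incompatible with len_min/len_max bounds")
  g <- stats::uniroot(function(g) sum(u^g) - need, c(1e-3, 50),
                      tol = 1e-12)$root
  len_min + (len_max - len_min) * u^g
}

#' @export
print.genome_map <- function(x, ...) {
  cat("Genome map:", x$n_chr, "chromosomes,",
      sprintf("%.2f Morgans total,", sum(x$chr_len_cM) / 100),
      nrow(x$loci), "loci\n")
  if (length(x$snp_idx))
    cat("  panel:", length(x$snp_idx), "SNPs,", length(x$qtl_idx), "QTL\n")
  invisible(x)
}

# Locus positions in absolute Morgans within chromosome plus [start, end)
# index ranges per chromosome, in the layout the C++ meiosis kernel expects.
map_cpp_layout <- function(map, idx = NULL) {
  loci <- map$loci
  if (!is.null(idx)) loci <- loci[idx, , drop = FALSE]
  stopifnot(!is.unsorted(loci$chr))
  ends <- cumsum(tabulate(loci$chr, nbins = map$n_chr))
  starts <- c(0L, ends[-length(ends)])
  keep <- ends > starts
  list(posM = loci$pos_cM / 100,
       chr_start = as.integer(starts[keep]), chr_end = as.integer(ends[keep]))
}

#' Trait model
#'
#' A single additive trait: narrow-sense heritability `h2` of which
#' `rpg_fraction` of phenotypic variance is residual polygenic (not captured
#' by the simulated QTL). QTL-explained variance is therefore
#' `(h2 - rpg_fraction) * sigma2_p` after [assign_qtl_effects()] scaling.
#'
#' @param h2 narrow-sense heritability.
#' @param rpg_fraction fraction of phenotypic variance due to the residual
#'   polygenic effect; must satisfy `0 <= rpg_fraction < h2 < 1`.
#' @param sigma2_p phenotypic variance (dimensionless; default 1).
#' @return object of class `trait_model`.
#' @export
trait_model <- function(h2 = 0.25, rpg_fraction = 0.05, sigma2_p = 1) {
  stopifnot(h2 > 0, h2 < 1, rpg_fraction >= 0, rpg_fraction < h2, sigma2_p > 0)
  structure(list(h2 = h2, rpg_fraction = rpg_fraction, sigma2_p = sigma2_p,
                 qtl_effects = NULL, qtl_freqs = NULL),
            class = "trait_model")
}

#' Draw and scale QTL allele-substitution effects
#'
#' Raw effects are drawn from a standard normal (a symmetric choice; the
#' rescaling below makes the raw distribution second-order) and rescaled so
#' that, under linkage equilibrium at the supplied founder allele
#' frequencies, the QTL-explained additive variance
#' \eqn{\sum_l 2 p_l (1-p_l) a_l^2} equals
#' `(h2 - rpg_fraction) * sigma2_p`. Monomorphic QTL get effect zero and
#' contribute nothing to the variance; rescaling an already-scaled effect
#' vector is a fixed point.
#'
#' @param map a `genome_map` with `qtl_idx` set (see [select_panel()]).
#' @param trait a [trait_model()].
#' @param founder_freqs allele frequencies of the QTL in the founder
#'   population, in `map$qtl_idx` order.
#' @param effects optional pre-drawn raw effects (used for rescaling).
#' @return the trait with `qtl_effects` and `qtl_freqs` filled in.
#' @export
assign_qtl_effects <- function(map, trait, founder_freqs, effects = NULL) {
  nq <- length(map$qtl_idx)
  stopifnot(nq >= 1, length(founder_freqs) == nq,
            all(founder_freqs >= 0), all(founder_freqs <= 1))
  if (is.null(effects)) effects <- stats::rnorm(nq)
  stopifnot(length(effects) == nq)
  w <- 2 * founder_freqs * (1 - founder_freqs)
  effects[w == 0] <- 0
  target <- (trait$h2 - trait$rpg_fraction) * trait$sigma2_p
  if (target == 0) {
    effects[] <- 0
  } else {
    va <- sum(w * effects^2)
    if (va == 0) stop("all QTL monomorphic in the founders; cannot scale effects")
    effects <- effects * sqrt(target / va)
  }
  trait$qtl_effects <- effects
  trait$qtl_freqs <- founder_freqs
  trait
}
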