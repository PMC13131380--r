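#' Back-solve SNP effects from GEBV
#'
#' Converts the GEBV of the genotyped training animals into per-locus SNP
#' effects,
#' \deqn{\hat a = (1-\alpha)\, d \, \frac{1}{2\sum_l p_l (1-p_l)}
#'   Z_t' G^{*-1}_{tt} \hat u_t,}
#' the linear back-solution from the tuned/blended genomic relationship
#' matrix. Loci monomorphic at the centering frequencies get effect zero.
#'
#' @param u_hat GEBV of the genotyped training animals (in genotype row
#'   order).
#' @param genotypes training genotype matrix (0/1/2 codes).
#' @param Gstar_inv inverse of the tuned/blended genomic matrix of the same
#'   animals.
#' @param blend list with `alpha` and `d` (see [tune_and_blend()]).
#' @param freqs centering allele frequencies.
#' @param k scaling constant `2 sum p(1-p)`; recomputed from `freqs` if
#'   missing.
#' @return numeric vector of class `snp_effects` with attributes `alpha`,
#'   `d`, `k`, `freqs`.
#' @export
backsolve_snp_effects <- function(u_hat, genotypes, Gstar_inv, blend, freqs,
                                  k = NULL) {
  stopifnot(length(u_hat) == nrow(genotypes),
            all(dim(Gstar_inv) == length(u_hat)),
            length(freqs) == ncol(genotypes))
  if (is.null(k)) k <- 2 * sum(freqs * (1 - freqs))
  if (k <= 0) stop("scaling constant k must be positive")
  Z <- gene_content_Z(genotypes, freqs)
  a <- (1 - blend$alpha) * blend$d / k *
    as.vector(crossprod(Z, Gstar_inv %*% u_hat))
  structure(a, class = "snp_effects",
            alpha = blend$alpha, d = blend$d, k = k, freqs = freqs)
}

#' @export
print.snp_effects <- function(x, ...) {
  cat(sprintf("Back-solved SNP effects: %d loci, sd = %.3e, (1-alpha)d = %.4f\n",
              length(x), stats::sd(unclass(x)),
              (1 - attr(x, "alpha")) * attr(x, "d")))
  invisible(x)
}

#' SNP effects of a fitted ssGBLUP model
#'
#' Back-solves the fit's own genotyped-animal GEBV through its
#' tuned/blended genomic matrix; for the published pipeline this is applied
#' to the reduced (training-only) run.
#'
#' @param fit an [ssgblup()] fit with genotypes.
#' @export
snp_effects <- function(fit) {
  stopifnot(inherits(fit, "ssgblup"))
  if (is.null(fit$geno_ids)) stop("fit has no genotypes to back-solve from")
  backsolve_snp_effects(fit$gebv[as.character(fit$geno_ids)],
                        fit$genotypes, fit$Gstar_inv, fit$blend, fit$freqs,
                        fit$k)
}

#' Indirect predictions from SNP effects
#'
#' `IP = Z_v a_hat`, with the new animals' gene contents centered by the
#' *training* allele frequencies carried in the effect vector.
#'
#' @param genotypes validation genotype matrix (0/1/2 codes, same locus
#'   order as the effects).
#' @param effects a `snp_effects` vector.
#' @return named numeric vector of indirect predictions.
#' @export
compute_ip <- function(genotypes, effects) {
  stopifnot(inherits(effects, "snp_effects"))
  if (ncol(genotypes) != length(effects)) stop("locus count mismatch")
  Z <- gene_content_Z(genotypes, attr(effects, "freqs"))
  ip <- as.vector(Z %*% unclass(effects))
  names(ip) <- rownames(genotypes)
  ip
}

#' Inject genotyping errors
#'
#' For each animal, `round(rate * n_loci)` loci are chosen uniformly at
#' random (independently per animal by default) and each chosen genotype is
#' replaced by one of its two alternative codes with probability 1/2:
#' a 0 becomes 1 or 2, a 1 becomes 0 or 2, a 2 becomes 0 or 1. Every
#' perturbed entry therefore differs from its original, and the perturbed
#' count per animal is exact.
#'
#' @param codes genotype matrix of 0/1/2 codes (animals x loci).
#' @param rate fraction of loci perturbed per animal, in `[0, 1]`.
#' @param seed optional RNG seed.
#' @param shared_loci if `TRUE`, one locus subset is drawn once and
#'   perturbed in every animal (a platform/imputation-artifact mode) rather
#'   than independently per animal.
#' @return matrix of the same shape with perturbed codes.
#' @export
inject_errors <- function(codes, rate, seed = NULL, shared_loci = FALSE) {
  if (rate < 0 || rate > 1) stop("error rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n_loci <- ncol(codes)
  m <- round(rate * n_loci)
  if (m == 0L) return(codes)
  out <- codes
  if (shared_loci) {
    loci <- sample.int(n_loci, m)
    for (i in seq_len(nrow(codes))) {
      shift <- 1L + stats::rbinom(m, 1L, 0.5)
      out[i, loci] <- (codes[i, loci] + shift) %% 3L
    }
  } else {
    for (i in seq_len(nrow(codes))) {
      loci <- sample.int(n_loci, m)
      shift <- 1L + stats::rbinom(m, 1L, 0.5)
      out[i, loci] <- (codes[i, loci] + shift) %% 3L
    }
  }
  out
}

scenario_label <- function(rate) {
  if (rate == 0) "correct" else sprintf("E%02d", round(100 * rate))
}

#' Indirect predictions under a ladder of genotyping-error rates
#'
#' For each error rate, perturbs the raw validation genotype codes with
#' [inject_errors()] and recomputes the indirect predictions; the centering
#' frequencies stay those of the training set (errors never leak into the
#' centering constants). Rate 0 is the error-free `"correct"` scenario.
#'
#' @param effects back-solved `snp_effects` from the reduced run.
#' @param geno_val validation genotype matrix (raw 0/1/2 codes).
#' @param rates error rates, e.g. `c(0, 0.05, 0.10, 0.20)`.
#' @param seed seed for the error draws (one independent substream per
#'   scenario).
#' @param shared_loci see [inject_errors()].
#' @return named list of IP vectors, one per scenario
#'   (`correct`, `E05`, ...).
#' @export
run_scenarios <- function(effects, geno_val, rates = c(0, 0.05, 0.10, 0.20),
                          seed = NULL, shared_loci = FALSE) {
  rates <- sort(rates)
  out <- vector("list", length(rates))
  names(out) <- vapply(rates, scenario_label, "")
  for (i in seq_along(rates)) {
    g <- if (rates[i] == 0) geno_val
         else inject_errors(geno_val, rates[i],
                            seed = if (is.null(seed)) NULL else seed + i,
                            shared_loci = shared_loci)
    out[[i]] <- compute_ip(g, effects)
  }
  out
}
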