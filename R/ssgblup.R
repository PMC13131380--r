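#' Assemble the mixed-model equations
#'
#' Single-trait animal model `y = 1 mu + u + e` with `var(u)` proportional
#' to A (pedigree BLUP) or H (single-step). The coefficient matrix is
#' `[[n_obs, 1'W], [W'1, W'W + lambda K]]` where W scatters records onto
#' animals and `K` is `A^-1` plus, for genotyped animals, the block
#' correction `G*^-1 - A22^-1`. Animals without phenotypes are carried with
#' zero incidence. The system is kept in parts (sparse pedigree component,
#' dense genotyped-block correction) so the solver can pick a dense
#' factorization, a sparse Cholesky, or preconditioned conjugate gradients.
#'
#' @param y phenotype vector, one entry per record.
#' @param obs_ids animal id of each record.
#' @param Ainv sparse A-inverse over all `n` animals (see [A_inverse()]).
#' @param lambda variance ratio sigma2_e / sigma2_a.
#' @param delta optional dense genotyped-block correction
#'   (see [H_inverse_delta()]).
#' @param geno_idx animal ids of the rows of `delta`.
#' @return object of class `mme_system`.
#' @export
assemble_mme <- function(y, obs_ids, Ainv, lambda, delta = NULL,
                         geno_idx = NULL) {
  n <- nrow(Ainv)
  stopifnot(length(y) >= 1, length(obs_ids) == length(y),
            all(obs_ids >= 1), all(obs_ids <= n), lambda > 0)
  if (!is.null(delta)) {
    stopifnot(!is.null(geno_idx), nrow(delta) == length(geno_idx),
              all(geno_idx >= 1), all(geno_idx <= n))
  }
  cnt <- tabulate(obs_ids, nbins = n)           # records per animal
  ysum <- numeric(n)
  tt <- tapply(y, obs_ids, sum)
  ysum[as.integer(names(tt))] <- tt
  structure(list(n = n, cnt = cnt, ysum = ysum, n_obs = length(y),
                 y_total = sum(y), Ainv = Ainv, lambda = lambda,
                 delta = delta, geno_idx = as.integer(geno_idx)),
            class = "mme_system")
}

mme_matvec <- function(sys, x) {
  xm <- x[1]; xu <- x[-1]
  r1 <- sys$n_obs * xm + sum(sys$cnt * xu)
  ru <- sys$cnt * (xm + xu) + sys$lambda * as.vector(sys$Ainv %*% xu)
  if (!is.null(sys$delta)) {
    gi <- sys$geno_idx
    ru[gi] <- ru[gi] + sys$lambda * as.vector(sys$delta %*% xu[gi])
  }
  c(r1, ru)
}

mme_rhs <- function(sys) c(sys$y_total, sys$ysum)

mme_dense <- function(sys) {
  n <- sys$n
  M <- matrix(0, n + 1L, n + 1L)
  M[1, 1] <- sys$n_obs
  M[1, -1] <- sys$cnt
  M[-1, 1] <- sys$cnt
  K <- sys$lambda * as.matrix(sys$Ainv)
  if (!is.null(sys$delta)) {
    gi <- sys$geno_idx
    K[gi, gi] <- K[gi, gi] + sys$lambda * sys$delta
  }
  diag(K) <- diag(K) + sys$cnt
  M[-1, -1] <- K
  M
}

#' Solve the mixed-model equations
#'
#' `method = "dense"` factorizes the full coefficient matrix (exact, for
#' desk-scale systems); `"sparse"` uses a sparse Cholesky and requires a
#' purely pedigree-based system (no dense genotyped block); `"pcg"` runs
#' Jacobi-preconditioned conjugate gradients on the parts, the path used
#' for the larger single-step systems. `"auto"` picks dense for small
#' systems, sparse when there is no genomic block, and PCG otherwise.
#'
#' @param sys an `mme_system` from [assemble_mme()].
#' @param method solver path.
#' @param tol relative residual tolerance (PCG).
#' @param max_iter PCG iteration cap.
#' @return list of class `mme_solution`: `mu`, `u`, `converged`,
#'   `iterations`, `residual` (relative residual norm of the full system).
#' @export
solve_mme <- function(sys, method = c("auto", "dense", "sparse", "pcg"),
                      tol = 1e-10, max_iter = 20000L) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (is.null(sys$delta)) "sparse"
              else if (sys$n <= 2500L) "dense" else "pcg"
  }
  b <- mme_rhs(sys)
  iterations <- 0L
  if (method == "dense") {
    x <- solve(mme_dense(sys), b)
  } else if (method == "sparse") {
    if (!is.null(sys$delta)) stop("sparse path requires a pedigree-only system")
    n <- sys$n
    K <- sys$lambda * sys$Ainv + Matrix::Diagonal(n, x = sys$cnt)
    M <- rbind(cbind(Matrix::Matrix(sys$n_obs, 1, 1, sparse = TRUE),
                     Matrix::Matrix(sys$cnt, 1, n, sparse = TRUE)),
               cbind(Matrix::Matrix(sys$cnt, n, 1, sparse = TRUE), K))
    x <- as.vector(Matrix::solve(methods::as(M, "CsparseMatrix"), b))
  } else {
    pre <- c(sys$n_obs,
             sys$cnt + sys$lambda * Matrix::diag(sys$Ainv))
    if (!is.null(sys$delta))
      pre[1L + sys$geno_idx] <- pre[1L + sys$geno_idx] +
        sys$lambda * diag(sys$delta)
    x <- numeric(sys$n + 1L)
    r <- b
    z <- r / pre
    p <- z
    rz <- sum(r * z)
    bnorm <- sqrt(sum(b^2))
    for (it in seq_len(max_iter)) {
      Ap <- mme_matvec(sys, p)
      a <- rz / sum(p * Ap)
      x <- x + a * p
      r <- r - a * Ap
      if (sqrt(sum(r^2)) <= tol * bnorm) break
      z <- r / pre
      rz_new <- sum(r * z)
      p <- z + (rz_new / rz) * p
      rz <- rz_new
    }
    iterations <- it
  }
  res <- sqrt(sum((mme_matvec(sys, x) - b)^2)) / sqrt(sum(b^2))
  structure(list(mu = x[1], u = x[-1],
                 converged = res <= max(tol, 1e-6),
                 iterations = iterations, residual = res,
                 method = method),
            class = "mme_solution")
}

# Pedigree-BLUP EBV used inside the simulator's selection step.
pedigree_ebv <- function(ped, phenotype, lambda) {
  obs <- which(!is.na(phenotype))
  Ainv <- A_inverse(ped)
  sys <- assemble_mme(phenotype[obs], obs, Ainv, lambda)
  solve_mme(sys, method = "sparse")$u
}

#' Fit a single-step GBLUP (or pedigree BLUP) animal model
#'
#' The central fitting function. Combines phenotypes, the pedigree and
#' (optionally) SNP genotypes in Henderson's mixed-model equations with the
#' inverse realized relationship matrix
#' \deqn{H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{*-1} - A_{22}^{-1}
#' \end{bmatrix}}
#' where `G* = (1 - alpha)(11'c + d G) + alpha A22` is the tuned and blended
#' VanRaden genomic matrix. Variance components are taken as known through
#' `lambda = sigma2_e / sigma2_a` (3 for a trait with h2 = 0.25).
#'
#' @param phenotypes data.frame with columns `id` and `phenotype`
#'   (or a vector named by id). Records with `NA` are dropped.
#' @param pedigree pedigree data.frame (see [kinship]).
#' @param genotypes optional integer matrix of 0/1/2 codes, animals in rows
#'   with ids as rownames; `NULL` fits pedigree BLUP.
#' @param lambda variance ratio `sigma2_e / sigma2_a`.
#' @param alpha blending weight for `G*`.
#' @param tune_method see [tune_and_blend()].
#' @param tune optional list with fixed tuning constants `c` and `d`,
#'   bypassing their re-estimation — the way production pipelines keep the
#'   constants calibrated on a reference run.
#' @param freqs centering allele frequencies; default observed in
#'   `genotypes`.
#' @param apy use the APY inverse of `G*` instead of the direct inverse.
#' @param core_size,core_seed APY core: number of core animals, drawn at
#'   random with `core_seed`.
#' @param solver,tol,max_iter passed to [solve_mme()].
#' @return an object of class `ssgblup` with components `mu`, `gebv`
#'   (named by animal id), `blend`, `k`, `freqs`, `geno_ids`, `Gstar_inv`,
#'   solver diagnostics, and (for [coef()]/[predict()]) the genotypes.
#' @seealso [coef.ssgblup()], [predict.ssgblup()], [snp_effects()]
#' @export
ssgblup <- function(phenotypes, pedigree, genotypes = NULL, lambda = 3,
                    alpha = 0.05, tune_method = "mean", tune = NULL,
                    freqs = NULL,
                    apy = FALSE, core_size = NULL, core_seed = NULL,
                    solver = "auto", tol = 1e-10, max_iter = 20000L) {
  cl <- match.call()
  n <- check_pedigree(pedigree)
  if (!is.data.frame(phenotypes)) {
    phenotypes <- data.frame(id = as.integer(names(phenotypes)),
                             phenotype = as.numeric(phenotypes))
  }
  stopifnot(all(c("id", "phenotype") %in% names(phenotypes)))
  obs <- phenotypes[!is.na(phenotypes$phenotype), , drop = FALSE]
  if (nrow(obs) == 0L) stop("no phenotypes")
  if (any(!(obs$id %in% pedigree$id))) stop("phenotyped animal missing from pedigree")

  Ainv <- A_inverse(pedigree)
  delta <- NULL; geno_idx <- NULL; blend <- NULL; Gstar_inv <- NULL; k <- NULL
  if (!is.null(genotypes)) {
    geno_idx <- as.integer(rownames(genotypes))
    if (anyNA(geno_idx) || any(!(geno_idx %in% pedigree$id)))
      stop("genotype rownames must be animal ids present in the pedigree")
    if (is.null(freqs)) freqs <- colMeans(genotypes) / 2
    grm <- build_G(genotypes, freqs)
    k <- grm$k
    A22 <- pedigree_A22(pedigree, geno_idx)
    if (is.null(tune)) {
      tb <- tune_and_blend(grm, A22, alpha = alpha, method = tune_method)
    } else {
      G_star <- (1 - alpha) * (tune$c + tune$d * grm$G) + alpha * A22
      tb <- list(G_star = (G_star + t(G_star)) / 2,
                 blend = list(alpha = alpha, c = tune$c, d = tune$d))
    }
    blend <- tb$blend
    if (apy) {
      ng <- length(geno_idx)
      if (is.null(core_size)) core_size <- ceiling(0.5 * ng)
      if (!is.null(core_seed)) set.seed(core_seed)
      core <- sample.int(ng, min(core_size, ng))
      Gstar_inv <- apy_inverse(tb$G_star, core)
    } else {
      Gstar_inv <- pd_inverse(tb$G_star)
    }
    A22_inv <- pd_inverse(A22)
    delta <- H_inverse_delta(Gstar_inv, A22_inv)
  }
  sys <- assemble_mme(obs$phenotype, obs$id, Ainv, lambda,
                      delta = delta, geno_idx = geno_idx)
  sol <- solve_mme(sys, method = solver, tol = tol, max_iter = max_iter)
  gebv <- sol$u
  names(gebv) <- as.character(pedigree$id)
  structure(list(call = cl, mu = sol$mu, gebv = gebv,
                 converged = sol$converged, iterations = sol$iterations,
                 residual = sol$residual, solver = sol$method,
                 lambda = lambda, blend = blend, k = k, freqs = freqs,
                 geno_ids = geno_idx, Gstar_inv = Gstar_inv,
                 genotypes = genotypes,
                 phenotypes = obs, n = n),
            class = "ssgblup")
}

#' @export
print.ssgblup <- function(x, ...) {
  kind <- if (is.null(x$geno_ids)) "Pedigree BLUP" else "Single-step GBLUP"
  cat(kind, "fit:", x$n, "animals,", nrow(x$phenotypes), "records")
  if (!is.null(x$geno_ids)) cat(",", length(x$geno_ids), "genotyped")
  cat("\n")
  cat(sprintf("  mu = %.4f; lambda = %g; solver %s (rel. residual %.2e)\n",
              x$mu, x$lambda, x$solver, x$residual))
  if (!is.null(x$blend))
    cat(sprintf("  blending alpha = %.2f; tuning c = %.4f, d = %.4f\n",
                x$blend$alpha, x$blend$c, x$blend$d))
  invisible(x)
}

#' @export
summary.ssgblup <- function(object, ...) {
  g <- object$gebv
  out <- list(fit = object,
              gebv_summary = c(mean = mean(g), sd = stats::sd(g),
                               min = min(g), max = max(g)))
  class(out) <- "summary.ssgblup"
  out
}

#' @export
print.summary.ssgblup <- function(x, ...) {
  print(x$fit)
  cat("  GEBV: ")
  print(round(x$gebv_summary, 4))
  invisible(x)
}

#' Coefficients of a ssGBLUP fit
#'
#' @param object an `ssgblup` fit.
#' @param type `"animal"` for GEBV, `"fixed"` for the overall mean,
#'   `"snp"` for back-solved SNP effects (see [snp_effects()]).
#' @param ... unused.
#' @export
coef.ssgblup <- function(object, type = c("animal", "fixed", "snp"), ...) {
  type <- match.arg(type)
  switch(type,
         animal = object$gebv,
         fixed = c(mu = object$mu),
         snp = snp_effects(object))
}

#' Residuals of a ssGBLUP fit
#'
#' `y - mu - u` for the phenotyped animals.
#' @param object an `ssgblup` fit.
#' @param ... unused.
#' @export
residuals.ssgblup <- function(object, ...) {
  obs <- object$phenotypes
  obs$phenotype - object$mu - object$gebv[as.character(obs$id)]
}

#' Predict from a ssGBLUP fit
#'
#' With `newgenotypes = NULL`, returns the GEBV of the animals in the fit.
#' Given the genotypes of new (e.g. young, unphenotyped) animals, returns
#' their indirect predictions `IP = Z_v a_hat`, centering the new gene
#' contents with the fit's own allele frequencies and using its back-solved
#' SNP effects.
#'
#' @param object an `ssgblup` fit with genotypes.
#' @param newgenotypes optional matrix of 0/1/2 codes (animals x loci, same
#'   locus order as the fit).
#' @param ... unused.
#' @export
predict.ssgblup <- function(object, newgenotypes = NULL, ...) {
  if (is.null(newgenotypes)) return(object$gebv)
  compute_ip(newgenotypes, snp_effects(object))
}

#' Benchmark and reduced evaluations of a simulated population
#'
#' `run_benchmark()` fits the full ssGBLUP on all phenotypes up to (and
#' excluding) the validation generation, with genotypes for both the
#' training generations and the validation candidates: the candidates enter
#' through the relationship matrix only, and their GEBV form the benchmark.
#' `run_reduced()` removes the validation generation entirely (pedigree,
#' genotypes) and refits on the training generations; its solution is the
#' input to SNP-effect back-solving.
#'
#' Centering allele frequencies default to the *base-population*
#' frequencies, which in this simulation are known exactly: every locus
#' starts the historical phase at frequency 0.5, so the base-frequency
#' centering of VanRaden's original formulation is simply 0.5 per locus.
#' Centering at the base keeps the direct genomic values -- and hence the
#' indirect predictions -- carrying the genetic trend on a fixed reference,
#' and it makes the genotyping-error substitution (whose fixed point is the
#' heterozygote) purely multiplicative around the centering origin.
#' Alternatives: `freq_source = "founder"` uses frequencies observed in the
#' current-population founders (a drifted, noisy estimate of the base,
#' which leaks extra locus-level offsets into the error scenarios), and
#' `"training"` uses the observed training frequencies, which zero the row
#' sums of G so the direct genomic values lose the trend entirely.
#'
#' @param pop a `population` from [simulate_population()].
#' @param training_genotypes optional override of the training genotype
#'   matrix (e.g. after [inject_errors()]); rownames must be training ids.
#' @param freq_source `"base"` (default), `"founder"`, or `"training"`.
#' @param freqs explicit centering frequencies, overriding `freq_source`.
#' @param lambda,alpha,... passed to [ssgblup()].
#' @return an `ssgblup` fit; `run_benchmark()` attaches the benchmark GEBV
#'   of the candidates as attribute `"validation_gebv"`.
#' @export
run_benchmark <- function(pop, lambda = NULL, alpha = 0.05,
                          freq_source = c("base", "founder", "training"),
                          freqs = NULL, ...) {
  if (is.null(lambda)) lambda <- (1 - pop$trait$h2) / pop$trait$h2
  freq_source <- match.arg(freq_source)
  tid <- training_ids(pop); vid <- validation_ids(pop)
  phen <- data.frame(id = pop$ped$id, phenotype = pop$phenotype)
  phen$phenotype[phen$id %in% vid] <- NA      # candidates are unphenotyped
  geno_t <- pop_genotypes(pop, tid)
  geno_v <- pop_genotypes(pop, vid)
  if (is.null(freqs))
    freqs <- switch(freq_source,
                    base = rep(0.5, ncol(geno_t)),
                    founder = pop$founder_freqs,
                    training = colMeans(geno_t) / 2)
  fit <- ssgblup(phen, pop$ped, rbind(geno_t, geno_v),
                 lambda = lambda, alpha = alpha, freqs = freqs, ...)
  attr(fit, "validation_gebv") <- fit$gebv[as.character(vid)]
  fit
}

#' @rdname run_benchmark
#' @export
run_reduced <- function(pop, training_genotypes = NULL, lambda = NULL,
                        alpha = 0.05,
                        freq_source = c("base", "founder", "training"),
                        freqs = NULL, ...) {
  if (is.null(lambda)) lambda <- (1 - pop$trait$h2) / pop$trait$h2
  freq_source <- match.arg(freq_source)
  tid <- training_ids(pop)
  if (length(tid) == 0L) stop("empty training set")
  keep <- pop$ped$generation < pop$config$validation_generation
  ped <- pop$ped[keep, , drop = FALSE]
  phen <- data.frame(id = ped$id, phenotype = pop$phenotype[keep])
  geno_t <- if (is.null(training_genotypes)) pop_genotypes(pop, tid)
            else training_genotypes
  stopifnot(identical(as.integer(rownames(geno_t)), as.integer(tid)))
  if (is.null(freqs))
    freqs <- switch(freq_source,
                    base = rep(0.5, ncol(geno_t)),
                    founder = pop$founder_freqs,
                    training = colMeans(geno_t) / 2)
  ssgblup(phen, ped, geno_t, lambda = lambda, alpha = alpha, freqs = freqs,
          ...)
}
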