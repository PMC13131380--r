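#' Pedigree utilities and relationship matrices
#'
#' The pedigree convention throughout the package: a data.frame with columns
#' `id`, `sire`, `dam` (0 = unknown parent), ids dense positive integers in
#' birth order so parents always precede offspring.
#'
#' @name kinship
NULL

check_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("id", "sire", "dam") %in% names(ped)))
  n <- nrow(ped)
  if (!identical(as.integer(ped$id), seq_len(n)))
    stop("pedigree ids must be dense 1..n in birth order")
  if (any(ped$sire >= ped$id & ped$sire > 0) || any(ped$dam >= ped$id & ped$dam > 0))
    stop("parents must precede offspring (no animal may be its own ancestor)")
  if (any(ped$sire < 0) || any(ped$dam < 0)) stop("negative parent code")
  invisible(n)
}

#' Inbreeding coefficients (Meuwissen-Luo)
#'
#' @param ped pedigree data.frame (see [kinship]).
#' @return numeric vector of inbreeding coefficients F.
#' @export
inbreeding <- function(ped) {
  check_pedigree(ped)
  cpp_inbreeding(as.integer(ped$sire), as.integer(ped$dam))
}

# Mendelian-sampling variances D_i given parent knowledge and inbreeding.
mendelian_D <- function(ped, F = NULL) {
  if (is.null(F)) F <- inbreeding(ped)
  s <- ped$sire; d <- ped$dam
  Fs <- ifelse(s > 0, F[pmax(s, 1)], -1)
  Fd <- ifelse(d > 0, F[pmax(d, 1)], -1)
  0.5 - 0.25 * (Fs + Fd)
}

#' Tabular (recursive) numerator relationship matrix A
#'
#' Brute-force construction, intended for modest pedigrees and as the oracle
#' for the sparse-inverse builder.
#'
#' @param ped pedigree data.frame.
#' @return dense symmetric matrix A.
#' @export
pedigree_A <- function(ped) {
  n <- check_pedigree(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
    if (i > 1) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (s > 0) A[j, s] else 0) + (if (d > 0) A[j, d] else 0))
      A[i, j] <- A[j, i] <- aij
    }
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding from the Meuwissen-Luo algorithm.
#'
#' @param ped pedigree data.frame.
#' @param sparse return a `Matrix::dsCMatrix` (default) or a dense matrix.
#' @return A-inverse.
#' @export
A_inverse <- function(ped, sparse = TRUE) {
  n <- check_pedigree(ped)
  F <- inbreeding(ped)
  alpha <- 1 / mendelian_D(ped, F)
  s <- ped$sire; d <- ped$dam
  i0 <- seq_len(n)
  ii <- i0; jj <- i0; xx <- alpha
  hs <- s > 0; hd <- d > 0
  add <- function(a, b, v) {
    ii <<- c(ii, a, b); jj <<- c(jj, b, a); xx <<- c(xx, v, v)
  }
  if (any(hs)) {
    add(i0[hs], s[hs], -alpha[hs] / 2)
    ii <- c(ii, s[hs]); jj <- c(jj, s[hs]); xx <- c(xx, alpha[hs] / 4)
  }
  if (any(hd)) {
    add(i0[hd], d[hd], -alpha[hd] / 2)
    ii <- c(ii, d[hd]); jj <- c(jj, d[hd]); xx <- c(xx, alpha[hd] / 4)
  }
  hb <- hs & hd
  if (any(hb)) add(s[hb], d[hb], alpha[hb] / 4)
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  M <- Matrix::forceSymmetric((M + Matrix::t(M)) / 2)
  if (sparse) M else as.matrix(M)
}

#' Pedigree relationships among a subset (A22)
#'
#' Relationship submatrix for the genotyped animals, computed without
#' forming the full A: columns of A are obtained by Colleau's indirect
#' method (gene-flow recursions), then restricted to the subset.
#'
#' @param ped pedigree data.frame.
#' @param ids animals defining the subset, in the order wanted.
#' @return dense symmetric matrix `length(ids) x length(ids)`.
#' @export
pedigree_A22 <- function(ped, ids) {
  n <- check_pedigree(ped)
  ids <- as.integer(ids)
  if (any(ids < 1 | ids > n)) stop("unknown id in genotyped subset")
  D <- mendelian_D(ped)
  E <- matrix(0, n, length(ids))
  E[cbind(ids, seq_along(ids))] <- 1
  AX <- cpp_A_times(as.integer(ped$sire), as.integer(ped$dam), D, E)
  A22 <- AX[ids, , drop = FALSE]
  (A22 + t(A22)) / 2
}

#' Centered gene-content matrix Z
#'
#' @param codes animals x loci genotype matrix with 0/1/2 allele counts.
#' @param freqs per-locus reference allele frequencies used for centering;
#'   loci monomorphic at these frequencies (p = 0 or 1) get a zeroed column
#'   so they contribute neither to relationships nor to back-solved effects.
#' @return dense numeric matrix `codes - 2 * freqs` (monomorphic columns 0).
#' @export
gene_content_Z <- function(codes, freqs) {
  stopifnot(ncol(codes) == length(freqs), all(codes %in% 0:2),
            all(freqs >= 0), all(freqs <= 1))
  Z <- sweep(codes + 0.0, 2L, 2 * freqs, `-`)
  mono <- freqs <= 0 | freqs >= 1
  if (any(mono)) Z[, mono] <- 0
  Z
}

#' Genomic relationship matrix (VanRaden)
#'
#' `G = Z Z' / k` with `Z` the centered gene contents and
#' `k = 2 * sum(p (1 - p))` over the non-monomorphic loci.
#'
#' @param codes animals x loci 0/1/2 genotype matrix.
#' @param freqs centering allele frequencies; defaults to the observed
#'   frequencies in `codes`.
#' @return list with `G` (dense symmetric), `freqs`, and `k`, of class
#'   `grm`.
#' @export
build_G <- function(codes, freqs = NULL) {
  if (is.null(freqs)) freqs <- colMeans(codes) / 2
  k <- 2 * sum(freqs * (1 - freqs))
  if (k <= 0) stop("all loci monomorphic: scaling constant k = 0")
  Z <- gene_content_Z(codes, freqs)
  G <- tcrossprod(Z) / k
  structure(list(G = (G + t(G)) / 2, freqs = freqs, k = k), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("Genomic relationship matrix: %d animals, k = %.2f, mean diag = %.3f\n",
              nrow(x$G), x$k, mean(diag(x$G))))
  invisible(x)
}

#' Tune and blend G against the pedigree relationships
#'
#' Tuning puts the genomic relationships on the pedigree base:
#' `c = mean(A22) - mean(G)` and `d = 1 - c/2` (single mean-based equation,
#' the default), or `method = "two_eq"` solving the pair of equations that
#' match both the overall mean and the diagonal mean. Blending with weight
#' `alpha` guarantees a positive-definite result:
#' `G* = (1 - alpha) (11' c + d G) + alpha A22`.
#'
#' @param G dense genomic relationship matrix (or a `grm`).
#' @param A22 pedigree relationships of the same animals.
#' @param alpha blending weight (default 0.05).
#' @param method `"mean"` or `"two_eq"`.
#' @return list with `G_star` and `blend` (list `alpha`, `c`, `d`), class
#'   `blended_grm`.
#' @export
tune_and_blend <- function(G, A22, alpha = 0.05, method = c("mean", "two_eq")) {
  if (inherits(G, "grm")) G <- G$G
  method <- match.arg(method)
  stopifnot(nrow(G) == ncol(G), all(dim(G) == dim(A22)),
            alpha >= 0, alpha <= 1)
  if (method == "mean") {
    cc <- mean(A22) - mean(G)
    d <- 1 - cc / 2
  } else {
    # match mean(diag) and mean(all): A = c + d G on both summaries
    md_A <- mean(diag(A22)); md_G <- mean(diag(G))
    m_A <- mean(A22); m_G <- mean(G)
    d <- (md_A - m_A) / (md_G - m_G)
    cc <- m_A - d * m_G
  }
  G_star <- (1 - alpha) * (cc + d * G) + alpha * A22
  G_star <- (G_star + t(G_star)) / 2
  structure(list(G_star = G_star,
                 blend = list(alpha = alpha, c = cc, d = d)),
            class = "blended_grm")
}

#' APY inverse of a genomic relationship matrix
#'
#' Algorithm-for-proven-and-young sparse inverse: the core block is inverted
#' directly and noncore animals are expressed through their genomic
#' recursion on the core, with independent Mendelian-sampling-like residuals
#' on the noncore diagonal. With all animals in the core the result equals
#' the direct dense inverse.
#'
#' @param G_star blended genomic relationship matrix (dense) or a
#'   `blended_grm`.
#' @param core indices of the core animals.
#' @return dense matrix: the APY approximation of `solve(G_star)` in the
#'   original animal order.
#' @export
apy_inverse <- function(G_star, core) {
  if (inherits(G_star, "blended_grm")) G_star <- G_star$G_star
  n <- nrow(G_star)
  core <- sort(unique(as.integer(core)))
  stopifnot(length(core) >= 1, all(core >= 1), all(core <= n))
  noncore <- setdiff(seq_len(n), core)
  Gcc_inv <- tryCatch(chol2inv(chol(G_star[core, core, drop = FALSE])),
                      error = function(e) stop("singular core block"))
  if (length(noncore) == 0L) return((Gcc_inv + t(Gcc_inv)) / 2)
  Gcn <- G_star[core, noncore, drop = FALSE]
  P <- Gcc_inv %*% Gcn                              # core -> noncore recursion
  m <- diag(G_star)[noncore] - colSums(Gcn * P)     # noncore residual variances
  if (any(m <= 0)) stop("nonpositive noncore residual variance; core too small")
  Inv <- matrix(0, n, n)
  Pm <- sweep(P, 2L, m, `/`)
  Inv[core, core] <- Gcc_inv + Pm %*% t(P)
  Inv[core, noncore] <- -Pm
  Inv[noncore, core] <- -t(Pm)
  Inv[cbind(noncore, noncore)] <- 1 / m
  (Inv + t(Inv)) / 2
}

# Inverse of a nominally positive-definite relationship matrix. Cholesky
# when possible; in degenerate small-sample cases (rank-deficient G plus a
# negative tuning shift can leave G* indefinite) the spectrum is floored at
# a small fraction of the mean diagonal, which shrinks the offending
# directions to near-zero variance instead of aborting.
pd_inverse <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch)) return(chol2inv(ch))
  e <- eigen(M, symmetric = TRUE)
  if (max(e$values) <= 0) stop("matrix is not positive definite")
  floor_ev <- 1e-4 * mean(diag(M))
  warning("matrix not positive definite; eigenvalues floored at ",
          signif(floor_ev, 3), call. = FALSE)
  vals <- pmax(e$values, floor_ev)
  inv <- e$vectors %*% (t(e$vectors) / vals)
  (inv + t(inv)) / 2
}

#' Genotyped-block correction for the single-step H-inverse
#'
#' `H^-1 = A^-1 + [0 0; 0 G*^-1 - A22^-1]`; this returns the genotyped-block
#' correction `G*^-1 - A22^-1`.
#'
#' @param G_star_inv inverse of the blended genomic matrix.
#' @param A22_inv inverse of the pedigree relationships among the genotyped
#'   animals.
#' @return dense symmetric correction matrix.
#' @export
H_inverse_delta <- function(G_star_inv, A22_inv) {
  stopifnot(all(dim(G_star_inv) == dim(A22_inv)))
  d <- G_star_inv - A22_inv
  (d + t(d)) / 2
}

#' Write a relationship matrix as three-column text
#'
#' Lower triangle only, `row_id col_id value`, the plain-text exchange
#' format common in quantitative-genetics tooling.
#'
#' @param M symmetric matrix.
#' @param file output path.
#' @param ids animal ids labelling rows/columns.
#' @export
write_relmat <- function(M, file, ids = seq_len(nrow(M))) {
  idx <- which(lower.tri(M, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(row = ids[idx[, 1]], col = ids[idx[, 2]],
                   value = M[idx])
  utils::write.table(df, file, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}
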