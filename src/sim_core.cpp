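#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Haplotypes are stored as an L x (2N) raw matrix: column 2i / 2i+1 are the
// two gametes of individual i (0-based), so a gamete is contiguous memory.
//
// Gamete formation follows the Haldane model: Poisson(len_Morgan) crossovers
// placed uniformly, no interference, random start phase per chromosome.
// Recurrent mutation flips the allele state at rate mu per locus; sampled by
// geometric skips so small mu costs next to nothing. Positions are absolute
// Morgans within chromosome; chr_start/chr_end delimit [start, end) locus
// index ranges.

static void make_gamete(const Rbyte* h0, const Rbyte* h1, Rbyte* out,
                        const int* chr_start, const int* chr_end, int n_chr,
                        const double* posM, double mu, int L) {
  for (int c = 0; c < n_chr; ++c) {
    int s = chr_start[c], e = chr_end[c];
    double p0 = posM[s];
    double len = posM[e - 1] - p0;
    int ncx = (len > 0) ? (int) R::rpois(len) : 0;
    int phase = (unif_rand() < 0.5) ? 0 : 1;
    if (ncx == 0) {
      const Rbyte* src = phase ? h1 : h0;
      std::copy(src + s, src + e, out + s);
      continue;
    }
    std::vector<double> cx((size_t) ncx);
    for (int i = 0; i < ncx; ++i) cx[i] = p0 + len * unif_rand();
    std::sort(cx.begin(), cx.end());
    int ic = 0;
    for (int l = s; l < e; ++l) {
      while (ic < ncx && cx[ic] < posM[l]) { phase ^= 1; ++ic; }
      out[l] = phase ? h1[l] : h0[l];
    }
  }
  if (mu > 0) {
    double log1m = log1p(-mu);
    int i = (int) floor(log(unif_rand()) / log1m);
    while (i < L && i >= 0) {
      out[i] ^= 1;
      i += 1 + (int) floor(log(unif_rand()) / log1m);
    }
  }
}

// Random union of gametes for length(sizes) generations (sizes[g] = number of
// individuals born in generation g). Sex alternates with individual index
// (even = male), giving an equal sex ratio; sires and dams drawn uniformly.
// Returns the haplotypes of the final generation.
// [[Rcpp::export]]
RawMatrix cpp_random_mating_phase(RawMatrix haplo, IntegerVector sizes,
                                  NumericVector posM, IntegerVector chr_start,
                                  IntegerVector chr_end, double mu) {
  int L = haplo.nrow();
  int n_chr = chr_start.size();
  RawMatrix cur = haplo;
  for (int g = 0; g < sizes.size(); ++g) {
    int ncur = cur.ncol() / 2;
    int nmal = (ncur + 1) / 2;
    int nfem = ncur - nmal;
    if (nmal < 1 || nfem < 1) stop("population too small to mate");
    int N = sizes[g];
    if (N < 1) stop("generation size must be positive");
    RawMatrix nxt(L, 2 * N);
    for (int i = 0; i < N; ++i) {
      int f = (int) floor(nmal * unif_rand()); if (f >= nmal) f = nmal - 1;
      int m = (int) floor(nfem * unif_rand()); if (m >= nfem) m = nfem - 1;
      int fi = 2 * f;          // even individual index = male
      int mi = 2 * m + 1;      // odd individual index = female
      make_gamete(&cur(0, 2 * fi), &cur(0, 2 * fi + 1), &nxt(0, 2 * i),
                  chr_start.begin(), chr_end.begin(), n_chr, posM.begin(), mu, L);
      make_gamete(&cur(0, 2 * mi), &cur(0, 2 * mi + 1), &nxt(0, 2 * i + 1),
                  chr_start.begin(), chr_end.begin(), n_chr, posM.begin(), mu, L);
    }
    cur = nxt;
  }
  return cur;
}

// Gametes for a mating list: offspring i receives a paternal gamete from
// individual sire[i] and a maternal gamete from dam[i] (1-based individual
// indices into `haplo`). Returns L x (2 n_off), columns 2i = paternal.
// [[Rcpp::export]]
RawMatrix cpp_make_offspring(RawMatrix haplo, IntegerVector sire,
                             IntegerVector dam, NumericVector posM,
                             IntegerVector chr_start, IntegerVector chr_end,
                             double mu) {
  int L = haplo.nrow();
  int n_chr = chr_start.size();
  int n = sire.size();
  if (dam.size() != n) stop("sire/dam length mismatch");
  RawMatrix out(L, 2 * n);
  for (int i = 0; i < n; ++i) {
    int si = sire[i] - 1, di = dam[i] - 1;
    if (si < 0 || di < 0 || 2 * si + 1 >= haplo.ncol() || 2 * di + 1 >= haplo.ncol())
      stop("parent index out of range");
    make_gamete(&haplo(0, 2 * si), &haplo(0, 2 * si + 1), &out(0, 2 * i),
                chr_start.begin(), chr_end.begin(), n_chr, posM.begin(), mu, L);
    make_gamete(&haplo(0, 2 * di), &haplo(0, 2 * di + 1), &out(0, 2 * i + 1),
                chr_start.begin(), chr_end.begin(), n_chr, posM.begin(), mu, L);
  }
  return out;
}

// In-place write of gamete columns into a preallocated store, starting at
// 1-based column col0. Avoids R-level copies of the full haplotype store.
// [[Rcpp::export]]
void cpp_fill_cols(RawMatrix store, int col0, RawMatrix gametes) {
  int L = store.nrow();
  if (gametes.nrow() != L) stop("locus count mismatch");
  if (col0 < 1 || col0 - 1 + gametes.ncol() > store.ncol()) stop("column range out of bounds");
  std::copy(gametes.begin(), gametes.end(), store.begin() + (size_t)(col0 - 1) * L);
}

// Genotype codes (0/1/2) for the requested individuals (1-based) at the
// requested loci (1-based): returns animals x loci integer matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_genotypes(RawMatrix haplo, IntegerVector ind, IntegerVector loci) {
  int n = ind.size(), m = loci.size();
  IntegerMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    int c0 = 2 * (ind[i] - 1);
    if (c0 < 0 || c0 + 1 >= haplo.ncol()) stop("individual index out of range");
    const Rbyte* h0 = &haplo(0, c0);
    const Rbyte* h1 = &haplo(0, c0 + 1);
    for (int j = 0; j < m; ++j) {
      int l = loci[j] - 1;
      out(i, j) = (int) h0[l] + (int) h1[l];
    }
  }
  return out;
}

// Meuwissen & Luo (1992) inbreeding coefficients for a pedigree sorted
// parents-before-offspring; sire/dam are 1-based ids, 0 = unknown.
// [[Rcpp::export]]
NumericVector cpp_inbreeding(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> L(n + 1, 0.0);
  std::vector<int> point(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    int is = sire[i - 1], id = dam[i - 1];
    if (is >= i || id >= i) stop("pedigree not sorted parents-before-offspring");
    if (is == 0 || id == 0) { F[i - 1] = 0.0; continue; }
    if (i > 1 && is == sire[i - 2] && id == dam[i - 2]) { F[i - 1] = F[i - 2]; continue; }
    double fi = -1.0;
    L[i] = 1.0;
    point[i] = 0;
    int j = i;
    while (j != 0) {
      int k = j;
      double r = 0.5 * L[k];
      // process the older parent first so list insertion stays descending
      int ks = std::max(sire[k - 1], dam[k - 1]);
      int kd = std::min(sire[k - 1], dam[k - 1]);
      if (ks > 0) {
        while (point[k] > ks) k = point[k];
        L[ks] += r;
        if (ks != point[k]) { point[ks] = point[k]; point[k] = ks; }
        if (kd > 0) {
          if (kd == ks) {
            L[ks] += r;                      // selfing: both gametes
          } else {
            while (point[k] > kd) k = point[k];
            L[kd] += r;
            if (kd != point[k]) { point[kd] = point[k]; point[k] = kd; }
          }
        }
      }
      double fs = (ks > 0) ? F[ks - 1] : -1.0;
      double fd = (kd > 0) ? F[kd - 1] : -1.0;
      double D = 0.5 - 0.25 * (fs + fd);
      fi += L[j] * L[j] * D;
      L[j] = 0.0;
      int nextj = point[j];
      point[j] = 0;
      j = nextj;
    }
    F[i - 1] = fi;
  }
  return F;
}

// Colleau (2002) indirect method: computes A %*% X without forming A, using
// A = (I - P)^-1 D (I - P)^-T with P the parent-average gene-flow matrix and
// D the Mendelian-sampling variances.
// [[Rcpp::export]]
NumericMatrix cpp_A_times(IntegerVector sire, IntegerVector dam,
                          NumericVector D, NumericMatrix X) {
  int n = sire.size(), m = X.ncol();
  if (X.nrow() != n || D.size() != n) stop("dimension mismatch");
  NumericMatrix out(n, m);
  std::vector<double> w((size_t) n);
  for (int col = 0; col < m; ++col) {
    for (int i = 0; i < n; ++i) w[i] = X(i, col);
    for (int i = n - 1; i >= 0; --i) {           // w = (I - P)^-T x
      double wi = w[i];
      if (wi != 0.0) {
        if (sire[i] > 0) w[sire[i] - 1] += 0.5 * wi;
        if (dam[i] > 0) w[dam[i] - 1] += 0.5 * wi;
      }
    }
    for (int i = 0; i < n; ++i) w[i] *= D[i];    // w = D w
    for (int i = 0; i < n; ++i) {                // out = (I - P)^-1 w
      double v = w[i];
      if (sire[i] > 0) v += 0.5 * out(sire[i] - 1, col);
      if (dam[i] > 0) v += 0.5 * out(dam[i] - 1, col);
      out(i, col) = v;
    }
  }
  return out;
}
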