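#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sequences are integer vectors over {0,1,2,3}; a diploid genome is a pair of
// columns (maternal, paternal) of an (n*L) x N matrix. Peak targets are L x n
// matrices (one column per gene). All stochastic draws use R's RNG so that
// set.seed() at the R level makes every routine reproducible. The draw order
// inside a tournament is fixed and documented in tournament_core().

static inline int hamming_ptr(const int* a, const int* b, int L) {
  int d = 0;
  for (int i = 0; i < L; ++i)
    if (a[i] != b[i]) ++d;
  return d;
}

// true iff Hamming distance is strictly below r (early exit at r)
static inline bool within_radius(const int* a, const int* b, int L, double r) {
  int d = 0;
  for (int i = 0; i < L; ++i) {
    if (a[i] != b[i]) {
      ++d;
      if ((double)d >= r) return false;
    }
  }
  return (double)d < r;
}

// linear decay from the peak apex: h at d = 0, zero at d >= r
static inline double decay(double h, double d, double r) {
  if (d >= r) return 0.0;
  return h * (1.0 - d / r);
}

// best-of-two-peaks fitness for one strand's gene segment
static double strand_fit(const int* seg, const int* t0, const int* t1,
                         double h0, double h1, double r0, double r1, int L) {
  double f0 = decay(h0, (double)hamming_ptr(seg, t0, L), r0);
  double f1 = decay(h1, (double)hamming_ptr(seg, t1, L), r1);
  return f0 >= f1 ? f0 : f1;
}

// diploid fitness: per gene lambda*f_max + (1-lambda)*f_min over the two
// strands, then the minimum over genes (essential-gene epistasis)
static double indiv_fit(const int* m, const int* p,
                        const IntegerMatrix& t0, const IntegerMatrix& t1,
                        double h0, double h1, double r0, double r1,
                        double lambda, int n, int L) {
  double fmin_gene = R_PosInf;
  for (int g = 0; g < n; ++g) {
    const int* tg0 = &t0(0, g);
    const int* tg1 = &t1(0, g);
    double fm = strand_fit(m + g * L, tg0, tg1, h0, h1, r0, r1, L);
    double fp = strand_fit(p + g * L, tg0, tg1, h0, h1, r0, r1, L);
    double fmax = fm >= fp ? fm : fp;
    double fmn = fm >= fp ? fp : fm;
    double f = lambda * fmax + (1.0 - lambda) * fmn;
    if (f < fmin_gene) fmin_gene = f;
  }
  return fmin_gene;
}

// [[Rcpp::export]]
double cpp_individual_fitness(IntegerVector m, IntegerVector p,
                              IntegerMatrix t0, IntegerMatrix t1,
                              double h0, double h1, double r0, double r1,
                              double lambda) {
  int L = t0.nrow(), n = t0.ncol();
  return indiv_fit(m.begin(), p.begin(), t0, t1, h0, h1, r0, r1, lambda, n, L);
}

// [[Rcpp::export]]
NumericVector cpp_population_fitness(IntegerMatrix mat, IntegerMatrix pat,
                                     IntegerMatrix t0, IntegerMatrix t1,
                                     double h0, double h1, double r0, double r1,
                                     double lambda) {
  int N = mat.ncol();
  int L = t0.nrow(), n = t0.ncol();
  NumericVector out(N);
  for (int i = 0; i < N; ++i)
    out[i] = indiv_fit(&mat(0, i), &pat(0, i), t0, t1, h0, h1, r0, r1,
                       lambda, n, L);
  return out;
}

// K ~ Binomial(L, M); K distinct positions; each set to one of the 3 other
// symbols with equal probability
static void mutate_seg(int* seg, int L, double M) {
  int K = (int)R::rbinom((double)L, M);
  if (K <= 0) return;
  IntegerVector pos = Rcpp::sample(L, K, false); // 1-based, distinct
  for (int j = 0; j < K; ++j) {
    int idx = pos[j] - 1;
    int shift = 1 + (int)(unif_rand() * 3.0);
    if (shift > 3) shift = 3;
    seg[idx] = (seg[idx] + shift) % 4;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_mutate(IntegerVector seq, double M) {
  IntegerVector out = clone(seq);
  mutate_seg(out.begin(), out.size(), M);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_mutate_genome(IntegerVector seq, double M, int n, int L) {
  IntegerVector out = clone(seq);
  for (int g = 0; g < n; ++g)
    mutate_seg(out.begin() + g * L, L, M);
  return out;
}

// one gene's contribution to a gamete: c contiguous chromosome blocks
// (last block absorbs the length remainder); per block a uniform starting
// strand and k distinct crossover points among the internal boundaries
// 1..len-1 (half-open convention: the switch applies from the cut onwards)
static void gamete_gene(const int* m, const int* p, int* out, int L, int c,
                        int k) {
  int base = L / c;
  int start = 0;
  for (int b = 0; b < c; ++b) {
    int len = (b == c - 1) ? (L - base * (c - 1)) : base;
    bool useM = unif_rand() < 0.5;
    std::vector<int> cuts;
    if (k > 0 && len >= 2) {
      IntegerVector cv = Rcpp::sample(len - 1, k, false); // values 1..len-1
      cuts.assign(cv.begin(), cv.end());
      std::sort(cuts.begin(), cuts.end());
    }
    int ci = 0;
    for (int i = 0; i < len; ++i) {
      if (ci < (int)cuts.size() && i == cuts[ci]) {
        useM = !useM;
        ++ci;
      }
      out[start + i] = useM ? m[start + i] : p[start + i];
    }
    start += len;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_make_gamete(IntegerVector m, IntegerVector p, int n, int L,
                              int c, int k) {
  IntegerVector out(m.size());
  for (int g = 0; g < n; ++g)
    gamete_gene(m.begin() + g * L, p.begin() + g * L, out.begin() + g * L, L,
                c, k);
  return out;
}

// Triple tournament. RNG draw order (fixed contract): 3 rank tie-break
// uniforms, 1 replacement-slot uniform, then gamete + per-gene mutation for
// the child's maternal strand (from the fitter surviving parent), then the
// paternal strand (from the other survivor). Returns the replaced column
// (0-based); mat/pat/fit are updated in place.
static int tournament_core(IntegerMatrix& mat, IntegerMatrix& pat,
                           NumericVector& fit, int i0, int i1, int i2,
                           const IntegerMatrix& t0, const IntegerMatrix& t1,
                           double h0, double h1, double r0, double r1,
                           double lambda, double M, int k, int c) {
  int idx[3] = {i0, i1, i2};
  double tb[3];
  for (int j = 0; j < 3; ++j) tb[j] = unif_rand(); // always drawn: fixed order
  int ord[3] = {0, 1, 2}; // ord[0] = fittest after sort
  std::sort(ord, ord + 3, [&](int a, int b) {
    double fa = fit[idx[a]], fb = fit[idx[b]];
    if (fa != fb) return fa > fb;
    return tb[a] < tb[b];
  });
  double u = unif_rand();
  int rrank = (u < 0.25) ? 0 : (u < 0.5 ? 1 : 2); // 25/25/50 by rank
  int replaced = idx[ord[rrank]];
  int pa = -1, pb = -1; // survivors, fitter first
  for (int r = 0; r < 3; ++r) {
    if (r == rrank) continue;
    if (pa < 0) pa = idx[ord[r]]; else pb = idx[ord[r]];
  }
  int n = t0.ncol(), L = t0.nrow(), G = n * L;
  std::vector<int> childM(G), childP(G);
  {
    const int* m = &mat(0, pa);
    const int* p = &pat(0, pa);
    for (int g = 0; g < n; ++g)
      gamete_gene(m + g * L, p + g * L, childM.data() + g * L, L, c, k);
    for (int g = 0; g < n; ++g) mutate_seg(childM.data() + g * L, L, M);
  }
  {
    const int* m = &mat(0, pb);
    const int* p = &pat(0, pb);
    for (int g = 0; g < n; ++g)
      gamete_gene(m + g * L, p + g * L, childP.data() + g * L, L, c, k);
    for (int g = 0; g < n; ++g) mutate_seg(childP.data() + g * L, L, M);
  }
  int* mcol = &mat(0, replaced);
  int* pcol = &pat(0, replaced);
  for (int t = 0; t < G; ++t) {
    mcol[t] = childM[t];
    pcol[t] = childP[t];
  }
  fit[replaced] =
      indiv_fit(childM.data(), childP.data(), t0, t1, h0, h1, r0, r1, lambda,
                n, L);
  return replaced;
}

// [[Rcpp::export]]
int cpp_tournament(IntegerMatrix mat, IntegerMatrix pat, NumericVector fit,
                   IntegerVector idx, IntegerMatrix t0, IntegerMatrix t1,
                   double h0, double h1, double r0, double r1, double lambda,
                   double M, int k, int c) {
  return tournament_core(mat, pat, fit, idx[0] - 1, idx[1] - 1, idx[2] - 1,
                         t0, t1, h0, h1, r0, r1, lambda, M, k, c) + 1;
}

static void generation_core(IntegerMatrix& mat, IntegerMatrix& pat,
                            NumericVector& fit, const IntegerMatrix& t0,
                            const IntegerMatrix& t1, double h0, double h1,
                            double r0, double r1, double lambda, double M,
                            int k, int c) {
  int N = mat.ncol();
  IntegerVector perm = Rcpp::sample(N, N, false); // 1-based permutation
  int ntrio = N / 3;                              // N mod 3 leftovers skipped
  for (int t = 0; t < ntrio; ++t)
    tournament_core(mat, pat, fit, perm[3 * t] - 1, perm[3 * t + 1] - 1,
                    perm[3 * t + 2] - 1, t0, t1, h0, h1, r0, r1, lambda, M, k,
                    c);
}

// [[Rcpp::export]]
void cpp_run_generation(IntegerMatrix mat, IntegerMatrix pat,
                        NumericVector fit, IntegerMatrix t0, IntegerMatrix t1,
                        double h0, double h1, double r0, double r1,
                        double lambda, double M, int k, int c) {
  generation_core(mat, pat, fit, t0, t1, h0, h1, r0, r1, lambda, M, k, c);
}

// smallest gene index (1-based) with no strand within the peak-0 radius,
// or 0 if every gene still has a carrier
static int first_lost_gene(const IntegerMatrix& mat, const IntegerMatrix& pat,
                           const IntegerMatrix& t0, double r0) {
  int L = t0.nrow(), n = t0.ncol(), N = mat.ncol();
  for (int g = 0; g < n; ++g) {
    const int* tg = &t0(0, g);
    bool carrier = false;
    for (int i = 0; i < N && !carrier; ++i) {
      if (within_radius(&mat(0, i) + g * L, tg, L, r0) ||
          within_radius(&pat(0, i) + g * L, tg, L, r0))
        carrier = true;
    }
    if (!carrier) return g + 1;
  }
  return 0;
}

// [[Rcpp::export]]
int cpp_first_lost_gene(IntegerMatrix mat, IntegerMatrix pat,
                        IntegerMatrix t0, double r0) {
  return first_lost_gene(mat, pat, t0, r0);
}

// full run loop: one generation then a peak-0 loss check, repeated up to
// maxgen; identical draw order to calling cpp_run_generation repeatedly
// [[Rcpp::export]]
List cpp_run_simulation(IntegerMatrix mat, IntegerMatrix pat,
                        NumericVector fit, IntegerMatrix t0, IntegerMatrix t1,
                        double h0, double h1, double r0, double r1,
                        double lambda, double M, int k, int c, int maxgen) {
  for (int gen = 1; gen <= maxgen; ++gen) {
    generation_core(mat, pat, fit, t0, t1, h0, h1, r0, r1, lambda, M, k, c);
    int lost = first_lost_gene(mat, pat, t0, r0);
    if (lost > 0)
      return List::create(_["lost"] = true, _["generation"] = gen,
                          _["gene"] = lost);
    if ((gen & 0xFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["lost"] = false, _["generation"] = maxgen,
                      _["gene"] = NA_INTEGER);
}
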