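#include <Rcpp.h>
#include <vector>
#include "rng.h"

using namespace Rcpp;

// Genotype-frequency-class Gibbs sampler (NewHybrids-type model) over five
// classes: PW, PD, F1, F2, BC1W. Each class z has a vector
// g_z(w), w in {0,1,2} = number of domestic-origin allele copies at a locus:
//   PW  = (1, 0, 0)      PD = (0, 0, 1)     F1 = (0, 1, 0)
//   F2  = (1/4, 1/2, 1/4) BC1W = (1/2, 1/2, 0)
// Latent state: class z_i, per-locus origin count w_il (and, for w = 1
// heterozygotes, which copy came from which pool), wild/domestic allele
// frequencies p0/p1 (Dirichlet prior, concentration freq_prior per locus),
// and class mixing proportions pi (Dirichlet, concentration pi_prior).
//
// geno: n x (2L), alleles recoded to 0..(J_l - 1), missing = -1.
// z_init: starting class per individual (0..4); anchors PW/PD orientation.
// Returns posterior class frequencies (n x 5) from thinned post-burn-in
// sweeps, plus pi samples.
// [[Rcpp::export(name = ".genoclass_gibbs_cpp")]]
List genoclass_gibbs_cpp(IntegerMatrix geno, IntegerVector n_alleles,
                         IntegerVector z_init,
                         int burnin, int n_iter, int thin,
                         double pi_prior, NumericVector freq_prior,
                         double seed) {
  const int n = geno.nrow();
  const int L = n_alleles.size();
  const int C = 5;
  if (geno.ncol() != 2 * L) stop("genotype matrix does not match panel size");
  if (n < 2) stop("at least 2 individuals are required");
  if (z_init.size() != n) stop("z_init length mismatch");
  if (freq_prior.size() != L) stop("freq_prior length mismatch");

  static const double g[5][3] = {
      {1.0, 0.0, 0.0},    // PW
      {0.0, 0.0, 1.0},    // PD
      {0.0, 1.0, 0.0},    // F1
      {0.25, 0.5, 0.25},  // F2
      {0.5, 0.5, 0.0}};   // BC1W

  std::vector<int> off(L + 1, 0);
  for (int l = 0; l < L; ++l) off[l + 1] = off[l] + n_alleles[l];
  const int A = off[L];

  std::vector<int> a(static_cast<size_t>(n) * L * 2);
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l)
      for (int c = 0; c < 2; ++c) {
        int v = geno(i, 2 * l + c);
        if (v == NA_INTEGER || v < 0) v = -1;
        else if (v >= n_alleles[l]) stop("allele code out of range");
        a[(static_cast<size_t>(i) * L + l) * 2 + c] = v;
      }

  Xoshiro rng(static_cast<uint64_t>(seed));

  std::vector<int> z(z_init.begin(), z_init.end());
  for (int i = 0; i < n; ++i)
    if (z[i] < 0 || z[i] >= C) stop("z_init out of range");
  std::vector<double> p(2 * A);
  for (int k = 0; k < 2; ++k)
    for (int l = 0; l < L; ++l)
      for (int j = 0; j < n_alleles[l]; ++j)
        p[k * A + off[l] + j] = 1.0 / n_alleles[l];
  std::vector<double> pi(C, 1.0 / C);
  std::vector<double> cnt(2 * A);
  std::vector<double> zcnt(C);

  const int total = burnin + n_iter;
  NumericMatrix post(n, C);
  const int kept = n_iter / thin;
  NumericMatrix pi_samples(kept, C);
  int rec = 0, n_rec = 0;

  for (int sweep = 0; sweep < total; ++sweep) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    const double *p0 = &p[0], *p1 = &p[A];

    // w_il, allele origins | z, p  -> origin-specific allele counts
    for (int i = 0; i < n; ++i) {
      const int *ai = &a[static_cast<size_t>(i) * L * 2];
      const double *gz = g[z[i]];
      for (int l = 0; l < L; ++l) {
        const int a1 = ai[2 * l], a2 = ai[2 * l + 1];
        if (a1 < 0) continue;
        const int base = off[l];
        double P0, P1, P2;
        if (a1 == a2) {
          P0 = p0[base + a1] * p0[base + a1];
          P1 = p0[base + a1] * p1[base + a1];
          P2 = p1[base + a1] * p1[base + a1];
        } else {
          P0 = 2.0 * p0[base + a1] * p0[base + a2];
          P1 = p0[base + a1] * p1[base + a2] + p0[base + a2] * p1[base + a1];
          P2 = 2.0 * p1[base + a1] * p1[base + a2];
        }
        const double w0 = gz[0] * P0, w1 = gz[1] * P1, w2 = gz[2] * P2;
        const double u = rng.unif() * (w0 + w1 + w2);
        int w = (u < w0) ? 0 : ((u < w0 + w1) ? 1 : 2);
        if (w == 0) {
          cnt[base + a1] += 1.0;
          cnt[base + a2] += 1.0;
        } else if (w == 2) {
          cnt[A + base + a1] += 1.0;
          cnt[A + base + a2] += 1.0;
        } else {
          if (a1 == a2) {
            cnt[base + a1] += 1.0;
            cnt[A + base + a1] += 1.0;
          } else {
            // which copy came from the wild pool
            const double pa = p0[base + a1] * p1[base + a2];
            const double pb = p0[base + a2] * p1[base + a1];
            if (rng.unif() * (pa + pb) < pa) {
              cnt[base + a1] += 1.0;
              cnt[A + base + a2] += 1.0;
            } else {
              cnt[base + a2] += 1.0;
              cnt[A + base + a1] += 1.0;
            }
          }
        }
      }
    }

    // p | origins (gamma draws clamped away from exact zero: Jeffreys-like
    // concentrations below 1 can underflow and a hard-zero frequency would
    // permanently kill states that carry that allele)
    for (int k = 0; k < 2; ++k)
      for (int l = 0; l < L; ++l) {
        const int base = k * A + off[l];
        double s = 0.0;
        for (int j = 0; j < n_alleles[l]; ++j) {
          double gdraw = rng.rgamma(freq_prior[l] + cnt[base + j]);
          if (gdraw < 1e-12) gdraw = 1e-12;
          p[base + j] = gdraw;
          s += gdraw;
        }
        for (int j = 0; j < n_alleles[l]; ++j) p[base + j] /= s;
      }

    // pi | z, same guard
    std::fill(zcnt.begin(), zcnt.end(), 0.0);
    for (int i = 0; i < n; ++i) zcnt[z[i]] += 1.0;
    {
      double s = 0.0;
      for (int cc = 0; cc < C; ++cc) {
        double gdraw = rng.rgamma(pi_prior + zcnt[cc]);
        if (gdraw < 1e-12) gdraw = 1e-12;
        pi[cc] = gdraw;
        s += gdraw;
      }
      for (int cc = 0; cc < C; ++cc) pi[cc] /= s;
    }

    // z | pi, p (w marginalized per locus)
    {
      const double *q0 = &p[0], *q1 = &p[A];
      for (int i = 0; i < n; ++i) {
        const int *ai = &a[static_cast<size_t>(i) * L * 2];
        double ll[5] = {0, 0, 0, 0, 0};
        for (int l = 0; l < L; ++l) {
          const int a1 = ai[2 * l], a2 = ai[2 * l + 1];
          if (a1 < 0) continue;
          const int base = off[l];
          double P0, P1, P2;
          if (a1 == a2) {
            P0 = q0[base + a1] * q0[base + a1];
            P1 = q0[base + a1] * q1[base + a1];
            P2 = q1[base + a1] * q1[base + a1];
          } else {
            P0 = 2.0 * q0[base + a1] * q0[base + a2];
            P1 = q0[base + a1] * q1[base + a2] + q0[base + a2] * q1[base + a1];
            P2 = 2.0 * q1[base + a1] * q1[base + a2];
          }
          for (int cc = 0; cc < C; ++cc) {
            double lik = g[cc][0] * P0 + g[cc][1] * P1 + g[cc][2] * P2;
            ll[cc] += std::log(lik > 1e-300 ? lik : 1e-300);
          }
        }
        double mx = ll[0];
        for (int cc = 1; cc < C; ++cc) if (ll[cc] > mx) mx = ll[cc];
        double wsum = 0.0, wz[5];
        for (int cc = 0; cc < C; ++cc) {
          wz[cc] = pi[cc] * std::exp(ll[cc] - mx);
          wsum += wz[cc];
        }
        double u = rng.unif() * wsum;
        int zi = 0;
        double acc = wz[0];
        while (zi < C - 1 && u >= acc) acc += wz[++zi];
        z[i] = zi;
      }
    }

    if (sweep >= burnin && ((sweep - burnin) % thin) == (thin - 1)) {
      for (int i = 0; i < n; ++i) post(i, z[i]) += 1.0;
      if (rec < kept) {
        for (int cc = 0; cc < C; ++cc) pi_samples(rec, cc) = pi[cc];
        ++rec;
      }
      ++n_rec;
    }
  }

  if (n_rec > 0)
    for (int i = 0; i < n; ++i)
      for (int cc = 0; cc < C; ++cc) post(i, cc) /= n_rec;

  return List::create(_["post"] = post, _["pi"] = pi_samples);
}
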