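#include <Rcpp.h>
#include <vector>
#include "rng.h"

using namespace Rcpp;

// K = 2 admixture-model Gibbs sampler with independent allele frequencies
// (the Structure A + I configuration).
//
// Model: each allele copy x_{ila} has a latent cluster of origin
// Z_{ila} ~ Categorical(q_i); x_{ila} | Z = k ~ p_{k,l,.};
// p_{k,l,.} ~ Dirichlet(lambda); q_i ~ Dirichlet(alpha, alpha);
// alpha ~ Uniform(0, alpha_max], updated by random-walk Metropolis.
// Missing copies (coded -1) contribute nothing.
//
// geno:      n x (2L) integer matrix, alleles recoded to 0..(J_l - 1),
//            missing = -1, columns (locus1 copy1, locus1 copy2, locus2 ...).
// n_alleles: J_l per locus.
// Returns thinned post-burn-in samples of q_i (cluster 1) and alpha.
// [[Rcpp::export(name = ".admix_gibbs_cpp")]]
List admix_gibbs_cpp(IntegerMatrix geno, IntegerVector n_alleles,
                     int burnin, int n_iter, int thin,
                     double lambda, double alpha_init, double alpha_max,
                     double alpha_sd, bool update_alpha, double seed) {
  const int n = geno.nrow();
  const int L = n_alleles.size();
  if (geno.ncol() != 2 * L) stop("genotype matrix does not match panel size");
  if (n < 2) stop("at least 2 individuals are required");

  // per-locus offsets into flattened allele arrays
  std::vector<int> off(L + 1, 0);
  for (int l = 0; l < L; ++l) off[l + 1] = off[l] + n_alleles[l];
  const int A = off[L];

  // flatten genotypes: a[(i*L + l)*2 + c], -1 = missing
  std::vector<int> a(static_cast<size_t>(n) * L * 2);
  int n_obs_total = 0;
  for (int i = 0; i < n; ++i) {
    int n_obs_i = 0;
    for (int l = 0; l < L; ++l) {
      for (int c = 0; c < 2; ++c) {
        int v = geno(i, 2 * l + c);
        if (v != NA_INTEGER && v >= 0) {
          if (v >= n_alleles[l]) stop("allele code out of range");
          n_obs_i++;
        } else {
          v = -1;
        }
        a[(static_cast<size_t>(i) * L + l) * 2 + c] = v;
      }
    }
    if (n_obs_i == 0) stop("individual with all loci missing");
    n_obs_total += n_obs_i;
  }
  (void)n_obs_total;

  Xoshiro rng(static_cast<uint64_t>(seed));

  // state
  std::vector<double> p(2 * A);          // p[k*A + off[l] + j]
  std::vector<double> q(2 * n, 0.5);     // q[2*i + k]
  std::vector<double> cnt(2 * A);        // allele counts by cluster
  std::vector<double> m(2 * n);          // copy counts by cluster
  double alpha = alpha_init;

  // init p uniform per locus
  for (int k = 0; k < 2; ++k)
    for (int l = 0; l < L; ++l)
      for (int j = 0; j < n_alleles[l]; ++j)
        p[k * A + off[l] + j] = 1.0 / n_alleles[l];

  const int total = burnin + n_iter;
  const int kept = n_iter / thin;
  NumericMatrix q_samples(kept, n);
  NumericVector alpha_samples(kept);
  int rec = 0;

  for (int sweep = 0; sweep < total; ++sweep) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    std::fill(m.begin(), m.end(), 0.0);

    // Z | q, p  (counts accumulated, Z itself not stored)
    const double *p0 = &p[0], *p1 = &p[A];
    for (int i = 0; i < n; ++i) {
      const double qi0 = q[2 * i], qi1 = q[2 * i + 1];
      double m0 = 0.0, m1 = 0.0;
      const int *ai = &a[static_cast<size_t>(i) * L * 2];
      for (int l = 0; l < L; ++l) {
        const int base = off[l];
        for (int c = 0; c < 2; ++c) {
          const int al = ai[2 * l + c];
          if (al < 0) continue;
          const double w0 = qi0 * p0[base + al];
          const double w1 = qi1 * p1[base + al];
          if (rng.unif() * (w0 + w1) < w0) {
            cnt[base + al] += 1.0;
            m0 += 1.0;
          } else {
            cnt[A + base + al] += 1.0;
            m1 += 1.0;
          }
        }
      }
      m[2 * i] = m0;
      m[2 * i + 1] = m1;
    }

    // q_i | Z ~ Dirichlet(alpha + m), clamped away from exact 0/1: when the
    // learned alpha is small, gamma draws for shape ~alpha can underflow to
    // exactly zero, which would make log(q) = -Inf in the alpha update (a
    // runaway toward alpha = 0) and freeze copy assignments permanently.
    const double QEPS = 1e-9;
    for (int i = 0; i < n; ++i) {
      double g0 = rng.rgamma(alpha + m[2 * i]);
      double g1 = rng.rgamma(alpha + m[2 * i + 1]);
      double s = g0 + g1;
      double q0 = (s > 0.0) ? g0 / s : 0.5;
      if (q0 < QEPS) q0 = QEPS;
      if (q0 > 1.0 - QEPS) q0 = 1.0 - QEPS;
      q[2 * i] = q0;
      q[2 * i + 1] = 1.0 - q0;
    }

    // p | Z ~ Dirichlet(lambda + counts); same underflow guard as for q
    for (int k = 0; k < 2; ++k) {
      for (int l = 0; l < L; ++l) {
        double s = 0.0;
        const int base = k * A + off[l];
        for (int j = 0; j < n_alleles[l]; ++j) {
          double g = rng.rgamma(lambda + cnt[base + j]);
          if (g < 1e-12) g = 1e-12;
          p[base + j] = g;
          s += g;
        }
        for (int j = 0; j < n_alleles[l]; ++j) p[base + j] /= s;
      }
    }

    // alpha | q : random-walk Metropolis, flat prior on (0, alpha_max]
    if (update_alpha) {
      double prop = alpha + alpha_sd * rng.norm();
      if (prop > 0.0 && prop <= alpha_max) {
        double slq = 0.0;
        for (int i = 0; i < n; ++i)
          slq += std::log(q[2 * i]) + std::log(q[2 * i + 1]);
        double logr = n * (std::lgamma(2.0 * prop) - 2.0 * std::lgamma(prop)
                         - std::lgamma(2.0 * alpha) + 2.0 * std::lgamma(alpha))
                    + (prop - alpha) * slq;
        if (logr >= 0.0 || std::log(rng.unif()) < logr) alpha = prop;
      }
    }

    if (sweep >= burnin && ((sweep - burnin) % thin) == (thin - 1) && rec < kept) {
      for (int i = 0; i < n; ++i) q_samples(rec, i) = q[2 * i];
      alpha_samples[rec] = alpha;
      ++rec;
    }
  }

  return List::create(_["q"] = q_samples, _["alpha"] = alpha_samples);
}
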