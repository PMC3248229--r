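// Gibbs sampler for the haploid admixture model.
//
// Data: one allele call per accession per locus (0 = missing, else
// 1..n_alleles[l]). Latent state: per-call population of origin z,
// population allele frequencies P (independent Dirichlet(lambda)
// priors per population x locus), per-accession membership rows q
// (symmetric Dirichlet(alpha) prior), and the admixture parameter
// alpha itself (uniform prior on (0, alpha_max), Metropolis update
// with a reflecting normal proposal).
//
// All randomness comes from R's RNG so set.seed() in R makes runs
// bit-reproducible.

#include <Rcpp.h>
using namespace Rcpp;

static inline double rgamma_pos(double shape) {
  // shape > 0; R::rgamma can underflow to 0 for tiny shapes, which is
  // handled by the callers (zero-sum rows renormalized to a vertex).
  return R::rgamma(shape, 1.0);
}

// [[Rcpp::export]]
List gibbs_cpp(IntegerMatrix calls, IntegerVector n_alleles, int k,
               int burnin, int iters, int thin, double lambda,
               double alpha_init, double alpha_sd, double alpha_max) {
  const int n = calls.nrow();
  const int L = calls.ncol();
  int amax = 0;
  for (int l = 0; l < L; ++l) if (n_alleles[l] > amax) amax = n_alleles[l];

  // P indexed [kk + k*(a + amax*l)]
  std::vector<double> P((size_t)k * amax * L, 0.0);
  std::vector<double> q((size_t)n * k, 1.0 / k);   // q[i + n*kk]
  std::vector<int> z((size_t)n * L, 0);            // z[i + n*l], 1..k
  std::vector<double> counts((size_t)k * amax * L, 0.0);
  std::vector<double> mcount((size_t)n * k, 0.0);

  // init P from the prior
  for (int l = 0; l < L; ++l) {
    for (int kk = 0; kk < k; ++kk) {
      double s = 0.0;
      for (int a = 0; a < n_alleles[l]; ++a) {
        double g = rgamma_pos(lambda);
        P[kk + k * (a + (size_t)amax * l)] = g;
        s += g;
      }
      if (s <= 0.0) {
        for (int a = 0; a < n_alleles[l]; ++a)
          P[kk + k * (a + (size_t)amax * l)] = 1.0 / n_alleles[l];
      } else {
        for (int a = 0; a < n_alleles[l]; ++a)
          P[kk + k * (a + (size_t)amax * l)] /= s;
      }
    }
  }

  double alpha = alpha_init;
  const int total = burnin + iters;
  const int n_rec = iters / thin;
  NumericVector loglik_trace(n_rec);
  NumericVector alpha_trace(n_rec);
  std::vector<double> Qsum((size_t)n * k, 0.0);
  std::vector<double> Psum((size_t)k * amax * L, 0.0);
  long long n_acc_alpha = 0, n_try_alpha = 0;
  double max_simplex_dev = 0.0;
  int rec = 0;
  std::vector<double> probs(k);

  for (int t = 1; t <= total; ++t) {
    // (i) sample origins z for non-missing calls
    std::fill(counts.begin(), counts.end(), 0.0);
    std::fill(mcount.begin(), mcount.end(), 0.0);
    for (int l = 0; l < L; ++l) {
      const size_t poff = (size_t)k * amax * l;
      for (int i = 0; i < n; ++i) {
        const int a = calls(i, l);
        if (a == 0) continue;
        double s = 0.0;
        const size_t pa = poff + (size_t)k * (a - 1);
        for (int kk = 0; kk < k; ++kk) {
          probs[kk] = q[i + (size_t)n * kk] * P[kk + pa];
          s += probs[kk];
        }
        int pick = 0;
        if (s <= 0.0) {
          pick = (int)(unif_rand() * k);
          if (pick >= k) pick = k - 1;
        } else {
          double u = unif_rand() * s, c = 0.0;
          for (int kk = 0; kk < k; ++kk) {
            c += probs[kk];
            if (u <= c) { pick = kk; break; }
            pick = kk;
          }
        }
        z[i + (size_t)n * l] = pick + 1;
        counts[pick + pa] += 1.0;
        mcount[i + (size_t)n * pick] += 1.0;
      }
    }

    // (ii) P | z  ~ Dirichlet(lambda + allele counts)
    for (int l = 0; l < L; ++l) {
      const size_t poff = (size_t)k * amax * l;
      for (int kk = 0; kk < k; ++kk) {
        double s = 0.0;
        for (int a = 0; a < n_alleles[l]; ++a) {
          double g = rgamma_pos(lambda + counts[kk + poff + (size_t)k * a]);
          P[kk + poff + (size_t)k * a] = g;
          s += g;
        }
        if (s <= 0.0) {
          for (int a = 0; a < n_alleles[l]; ++a)
            P[kk + poff + (size_t)k * a] = 1.0 / n_alleles[l];
        } else {
          for (int a = 0; a < n_alleles[l]; ++a)
            P[kk + poff + (size_t)k * a] /= s;
        }
      }
    }

    // (iii) q_i | z ~ Dirichlet(alpha + per-population counts)
    double sum_log_q = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int kk = 0; kk < k; ++kk) {
        double g = rgamma_pos(alpha + mcount[i + (size_t)n * kk]);
        q[i + (size_t)n * kk] = g;
        s += g;
      }
      if (s <= 0.0) {
        int pick = (int)(unif_rand() * k);
        if (pick >= k) pick = k - 1;
        for (int kk = 0; kk < k; ++kk) q[i + (size_t)n * kk] = (kk == pick) ? 1.0 : 0.0;
        s = 1.0;
      } else {
        for (int kk = 0; kk < k; ++kk) q[i + (size_t)n * kk] /= s;
      }
      for (int kk = 0; kk < k; ++kk) {
        double qi = q[i + (size_t)n * kk];
        sum_log_q += std::log(qi > 1e-300 ? qi : 1e-300);
      }
    }

    // (iv) Metropolis update of the symmetric alpha
    if (k > 1) {
      double prop = alpha + norm_rand() * alpha_sd;
      for (int guard = 0; guard < 64; ++guard) {
        if (prop < 0.0) prop = -prop;
        else if (prop > alpha_max) prop = 2.0 * alpha_max - prop;
        else break;
      }
      if (prop > 0.0 && prop < alpha_max) {
        double cur = n * (R::lgammafn(k * alpha) - k * R::lgammafn(alpha)) +
                     (alpha - 1.0) * sum_log_q;
        double cand = n * (R::lgammafn(k * prop) - k * R::lgammafn(prop)) +
                      (prop - 1.0) * sum_log_q;
        ++n_try_alpha;
        if (std::log(unif_rand()) < cand - cur) {
          alpha = prop;
          ++n_acc_alpha;
        }
      }
    }

    // record thinned post-burn-in samples
    if (t > burnin && (t - burnin) % thin == 0 && rec < n_rec) {
      double ll = 0.0;
      for (int l = 0; l < L; ++l) {
        const size_t poff = (size_t)k * amax * l;
        for (int i = 0; i < n; ++i) {
          const int a = calls(i, l);
          if (a == 0) continue;
          double mix = 0.0;
          const size_t pa = poff + (size_t)k * (a - 1);
          for (int kk = 0; kk < k; ++kk)
            mix += q[i + (size_t)n * kk] * P[kk + pa];
          ll += std::log(mix > 0.0 ? mix : 1e-300);
        }
      }
      loglik_trace[rec] = ll;
      alpha_trace[rec] = alpha;
      for (size_t j = 0; j < Qsum.size(); ++j) Qsum[j] += q[j];
      for (size_t j = 0; j < Psum.size(); ++j) Psum[j] += P[j];
      // simplex diagnostics on the recorded sample
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int kk = 0; kk < k; ++kk) s += q[i + (size_t)n * kk];
        double d = std::fabs(s - 1.0);
        if (d > max_simplex_dev) max_simplex_dev = d;
      }
      ++rec;
    }
  }

  if (rec == 0) stop("no samples recorded; increase iters or lower thin");
  NumericMatrix Qmean(n, k);
  for (int kk = 0; kk < k; ++kk)
    for (int i = 0; i < n; ++i)
      Qmean(i, kk) = Qsum[i + (size_t)n * kk] / rec;
  // renormalize posterior-mean rows (sum of simplex samples is simplex
  // up to fp error; this pins row sums at 1 exactly)
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int kk = 0; kk < k; ++kk) s += Qmean(i, kk);
    for (int kk = 0; kk < k; ++kk) Qmean(i, kk) /= s;
  }
  NumericVector Pmean((size_t)k * amax * L);
  for (size_t j = 0; j < Psum.size(); ++j) Pmean[j] = Psum[j] / rec;
  Pmean.attr("dim") = IntegerVector::create(k, amax, L);

  return List::create(
    _["Q"] = Qmean,
    _["P"] = Pmean,
    _["loglik_trace"] = loglik_trace,
    _["alpha_trace"] = alpha_trace,
    _["alpha_accept"] = n_try_alpha > 0 ? (double)n_acc_alpha / n_try_alpha : NA_REAL,
    _["max_simplex_dev"] = max_simplex_dev
  );
}
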