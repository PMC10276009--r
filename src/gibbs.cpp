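#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// log(sum(exp(v))) guarded against empty input
static double logsumexp(const std::vector<double>& v) {
  if (v.empty()) return R_NegInf;
  double m = v[0];
  for (double x : v) if (x > m) m = x;
  if (!R_finite(m)) return m;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// Log normalizing constant of the q-neighbour-set probability for a point
// whose cluster has size m (point included), among n points in total:
//   Z(m) = sum_a C(m-1, a) C(n-m, q-a) zeta^a (1-zeta)^(q-a),
// the sum running over feasible numbers a of same-cluster neighbours.
// Constant in m when zeta = 0.5 (it collapses to 0.5^q C(n-1, q)), which
// is what makes the neighbourhood term cancel from the label conditionals.
// [[Rcpp::export]]
NumericVector logz_table_cpp(int n, int q, double zeta) {
  NumericVector lz(n);
  double lzeta = std::log(zeta), l1m = std::log1p(-zeta);
  for (int m = 1; m <= n; ++m) {
    std::vector<double> terms;
    for (int a = 0; a <= q; ++a) {
      if (a > m - 1 || q - a > n - m) continue;
      terms.push_back(Rf_lchoose(m - 1, a) + Rf_lchoose(n - m, q - a) +
                      a * lzeta + (q - a) * l1m);
    }
    lz[m - 1] = logsumexp(terms);
  }
  return lz;
}

// Unnormalized log full-conditional of label c_i over l = 1..L.
// counts = cluster sizes with point i removed; cnt[l] = number of
// neighbour links touching i (rows i and columns i of N) whose other
// endpoint currently has label l; S = sum_k counts[k] * logz(counts[k]).
static void label_logprob(double logmu_i,
                          const std::vector<int>& counts,
                          const std::vector<int>& cnt,
                          const NumericVector& d,
                          const NumericVector& logpi,
                          const NumericVector& logz,
                          double llr, double S,
                          std::vector<double>& lp) {
  int L = d.size();
  for (int l = 0; l < L; ++l) {
    double zterm = S + logz[counts[l]];  // m = counts[l] + 1 -> index counts[l]
    if (counts[l] > 0) zterm += counts[l] * (logz[counts[l]] - logz[counts[l] - 1]);
    lp[l] = logpi[l] + std::log(d[l]) - (d[l] + 1.0) * logmu_i +
            llr * cnt[l] - zterm;
  }
}

// Exposed for diagnostics/testing: unnormalized log conditional for one
// observation given the current state.  i1 and labels are 1-based.
// [[Rcpp::export]]
NumericVector label_logprob_cpp(int i1, IntegerVector labels,
                                NumericVector logmu, IntegerMatrix outn1,
                                NumericVector d, NumericVector pi,
                                double zeta) {
  int n = logmu.size(), L = d.size(), q = outn1.ncol();
  int i = i1 - 1;
  std::vector<int> counts(L, 0), cnt(L, 0);
  for (int j = 0; j < n; ++j) if (j != i) counts[labels[j] - 1]++;
  for (int k = 0; k < q; ++k) cnt[labels[outn1(i, k) - 1] - 1]++;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    for (int k = 0; k < q; ++k)
      if (outn1(j, k) - 1 == i) cnt[labels[j] - 1]++;
  }
  NumericVector logz = logz_table_cpp(n, q, zeta);
  NumericVector logpi(L);
  for (int l = 0; l < L; ++l) logpi[l] = std::log(pi[l]);
  double S = 0.0;
  for (int l = 0; l < L; ++l)
    if (counts[l] > 0) S += counts[l] * logz[counts[l] - 1];
  double llr = std::log(zeta) - std::log1p(-zeta);
  std::vector<double> lp(L);
  label_logprob(logmu[i], counts, cnt, d, logpi, logz, llr, S, lp);
  return NumericVector(lp.begin(), lp.end());
}

// Gibbs sampler for the neighbourhood-augmented Pareto mixture.
// All randomness flows through R's RNG (set.seed on the R side).
// [[Rcpp::export]]
List hidalgo_gibbs_cpp(NumericVector logmu, IntegerMatrix outn1,
                       int L, double a_d, double b_d, NumericVector alpha,
                       double zeta0, bool sample_zeta,
                       double zeta_a, double zeta_b, double zeta_prop_sd,
                       int n_iter, int burn_in) {
  int n = logmu.size();
  int q = (n > 0) ? outn1.ncol() : 0;
  int kept = n_iter - burn_in;
  RNGScope scope;

  // in-neighbour lists: j such that i is among j's q nearest neighbours
  std::vector<std::vector<int>> inn(n);
  for (int j = 0; j < n; ++j)
    for (int k = 0; k < q; ++k)
      inn[outn1(j, k) - 1].push_back(j);

  // state
  std::vector<int> c(n);
  NumericVector d(L), pi(L), logpi(L);
  std::vector<int> counts(L, 0);
  std::vector<double> slog(L, 0.0);
  for (int l = 0; l < L; ++l) d[l] = R::rgamma(a_d, 1.0 / b_d);
  {
    double tot = 0.0;
    for (int l = 0; l < L; ++l) { pi[l] = R::rgamma(alpha[l], 1.0); tot += pi[l]; }
    for (int l = 0; l < L; ++l) {
      pi[l] = std::max(pi[l] / tot, 1e-300);
      logpi[l] = std::log(pi[l]);
    }
  }
  for (int i = 0; i < n; ++i) {
    int l = std::min((int)(unif_rand() * L), L - 1);
    c[i] = l; counts[l]++; slog[l] += logmu[i];
  }

  double zeta = zeta0;
  NumericVector logz = (n > 0) ? logz_table_cpp(n, q, zeta) : NumericVector(0);
  double llr = std::log(zeta) - std::log1p(-zeta);

  IntegerMatrix labs(kept, n);
  NumericMatrix Wm(kept, L), Dm(kept, L);
  NumericVector zchain(sample_zeta ? kept : 0);

  std::vector<double> lp(L);
  std::vector<int> cnt(L);

  for (int t = 0; t < n_iter; ++t) {
    // --- labels, random scan order
    if (n > 0) {
      IntegerVector perm = Rcpp::sample(n, n);  // 1-based permutation
      for (int s = 0; s < n; ++s) {
        int i = perm[s] - 1;
        counts[c[i]]--; slog[c[i]] -= logmu[i];
        double S = 0.0;
        for (int l = 0; l < L; ++l)
          if (counts[l] > 0) S += counts[l] * logz[counts[l] - 1];
        std::fill(cnt.begin(), cnt.end(), 0);
        for (int k = 0; k < q; ++k) cnt[c[outn1(i, k) - 1]]++;
        for (int j : inn[i]) cnt[c[j]]++;
        label_logprob(logmu[i], counts, cnt, d, logpi, logz, llr, S, lp);
        // Gumbel-max categorical draw
        int best = 0; double bestv = R_NegInf;
        for (int l = 0; l < L; ++l) {
          double g = lp[l] - std::log(exp_rand());
          if (g > bestv) { bestv = g; best = l; }
        }
        c[i] = best; counts[best]++; slog[best] += logmu[i];
      }
    }

    // --- intrinsic dimensions: conjugate Gamma update
    for (int l = 0; l < L; ++l) {
      d[l] = R::rgamma(a_d + counts[l], 1.0 / (b_d + slog[l]));
      if (!R_finite(d[l]) || d[l] <= 0.0)
        stop("Gibbs sweep %d: non-finite d[%d] (counts=%d, sumlog=%f)",
             t + 1, l + 1, counts[l], slog[l]);
    }

    // --- mixing weights: Dirichlet update
    {
      double tot = 0.0;
      for (int l = 0; l < L; ++l) { pi[l] = R::rgamma(alpha[l] + counts[l], 1.0); tot += pi[l]; }
      if (!R_finite(tot) || tot <= 0.0) stop("Gibbs sweep %d: degenerate weight draw", t + 1);
      for (int l = 0; l < L; ++l) {
        pi[l] = std::max(pi[l] / tot, 1e-300);
        logpi[l] = std::log(pi[l]);
      }
    }

    // --- optional zeta update: random-walk Metropolis on logit(zeta)
    if (sample_zeta && n > 0) {
      double A = 0.0;  // same-cluster out-neighbour links
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < q; ++k)
          if (c[outn1(i, k) - 1] == c[i]) A += 1.0;
      double lo = std::log(zeta) - std::log1p(-zeta);
      double lprop = lo + norm_rand() * zeta_prop_sd;
      double zprop = 1.0 / (1.0 + std::exp(-lprop));
      NumericVector lzp = logz_table_cpp(n, q, zprop);
      auto ltarget = [&](double z, const NumericVector& lzt) {
        double v = (A + zeta_a - 1.0 + 1.0) * std::log(z) +
                   (n * q - A + zeta_b - 1.0 + 1.0) * std::log1p(-z);
        for (int l = 0; l < L; ++l)
          if (counts[l] > 0) v -= counts[l] * lzt[counts[l] - 1];
        return v;  // includes logit-RW Jacobian via the +1 exponents
      };
      if (std::log(unif_rand()) < ltarget(zprop, lzp) - ltarget(zeta, logz)) {
        zeta = zprop; logz = lzp;
        llr = std::log(zeta) - std::log1p(-zeta);
      }
    }

    // --- store
    if (t >= burn_in) {
      int r = t - burn_in;
      for (int i = 0; i < n; ++i) labs(r, i) = c[i] + 1;
      for (int l = 0; l < L; ++l) { Wm(r, l) = pi[l]; Dm(r, l) = d[l]; }
      if (sample_zeta) zchain[r] = zeta;
    }
  }

  List out = List::create(_["labels"] = labs, _["weights"] = Wm, _["dims"] = Dm);
  if (sample_zeta) out["zeta"] = zchain;
  return out;
}
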