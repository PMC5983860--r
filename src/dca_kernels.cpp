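#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-sequence redundancy counts m_a = |{b : identity(a,b) >= threshold}|,
// self always counted. Identity = fraction of columns with identical encoded
// symbols (gaps compared as ordinary symbols). O(M^2 L), the hot loop of
// sequence reweighting.
// [[Rcpp::export]]
IntegerVector cpp_redundancy_counts(const IntegerMatrix& X, double threshold) {
  const int M = X.nrow(), L = X.ncol();
  IntegerVector m(M, 1);
  for (int a = 0; a < M; ++a) {
    for (int b = a + 1; b < M; ++b) {
      int same = 0;
      for (int k = 0; k < L; ++k)
        if (X(a, k) == X(b, k)) ++same;
      if (static_cast<double>(same) / L >= threshold) {
        ++m[a];
        ++m[b];
      }
    }
  }
  return m;
}

// Direct Information for all column pairs of a mean-field Potts model.
// e: (L*q) x (L*q) coupling matrix (gauged state rows/cols zero-padded),
// fi: q x L single-site marginals. For each pair the auxiliary single-site
// fields of the two-site model are fixed by multiplicative fixed-point
// iteration until the model marginals match fi to `tol` (sup norm), then
// DI = sum P log(P / (fi fj)).
// [[Rcpp::export]]
List cpp_direct_information(const NumericMatrix& e, const NumericMatrix& fi,
                            double tol, int max_iter) {
  const int q = fi.nrow(), L = fi.ncol();
  NumericMatrix di(L, L);
  IntegerMatrix iters(L, L);
  LogicalMatrix conv(L, L);
  std::vector<double> W(q * q), mu1(q), mu2(q), n1(q), n2(q);

  for (int i = 0; i < L - 1; ++i) {
    for (int j = i + 1; j < L; ++j) {
      for (int a = 0; a < q; ++a)
        for (int b = 0; b < q; ++b)
          W[a * q + b] = std::exp(e(i * q + a, j * q + b));
      std::fill(mu1.begin(), mu1.end(), 1.0 / q);
      std::fill(mu2.begin(), mu2.end(), 1.0 / q);
      int it = 0;
      double diff = R_PosInf;
      while (diff > tol && it < max_iter) {
        double s1 = 0.0, s2 = 0.0;
        for (int a = 0; a < q; ++a) {
          double scra = 0.0;
          for (int b = 0; b < q; ++b) scra += W[a * q + b] * mu2[b];
          n1[a] = (scra > 0.0) ? fi(a, i) / scra : 0.0;
          s1 += n1[a];
        }
        for (int a = 0; a < q; ++a) n1[a] /= s1;
        for (int b = 0; b < q; ++b) {
          double scra = 0.0;
          for (int a = 0; a < q; ++a) scra += W[a * q + b] * n1[a];
          n2[b] = (scra > 0.0) ? fi(b, j) / scra : 0.0;
          s2 += n2[b];
        }
        for (int b = 0; b < q; ++b) n2[b] /= s2;
        diff = 0.0;
        for (int a = 0; a < q; ++a) {
          diff = std::max(diff, std::fabs(n1[a] - mu1[a]));
          diff = std::max(diff, std::fabs(n2[a] - mu2[a]));
          mu1[a] = n1[a];
          mu2[a] = n2[a];
        }
        ++it;
      }
      // two-site model P(a,b) = W(a,b) mu1(a) mu2(b) / Z
      double Z = 0.0;
      for (int a = 0; a < q; ++a)
        for (int b = 0; b < q; ++b) Z += W[a * q + b] * mu1[a] * mu2[b];
      double d = 0.0;
      for (int a = 0; a < q; ++a) {
        for (int b = 0; b < q; ++b) {
          double p = W[a * q + b] * mu1[a] * mu2[b] / Z;
          double ref = fi(a, i) * fi(b, j);
          if (p > 0.0 && ref > 0.0) d += p * std::log(p / ref);
        }
      }
      if (d < 0.0) d = 0.0;  // numerical round-off only
      di(i, j) = di(j, i) = d;
      iters(i, j) = iters(j, i) = it;
      conv(i, j) = conv(j, i) = (diff <= tol);
    }
  }
  return List::create(_["di"] = di, _["iterations"] = iters,
                      _["converged"] = conv);
}

// Gibbs sampler for a pairwise Potts model with zero fields and planted
// couplings. pair_i/pair_j are 1-based column indices; J is a list of q x q
// coupling matrices, one per planted pair. Uses R's RNG so set.seed()
// governs reproducibility. Returns N x L matrix of 1-based states.
// [[Rcpp::export]]
IntegerMatrix cpp_gibbs_potts(int L, int q, const IntegerVector& pair_i,
                              const IntegerVector& pair_j, const List& J,
                              int N, int burn_in, int thinning) {
  const int npair = pair_i.size();
  std::vector<std::vector<std::pair<int, int> > > nb(L);  // (pair idx, side)
  std::vector<NumericMatrix> Jm;
  for (int p = 0; p < npair; ++p) {
    Jm.push_back(as<NumericMatrix>(J[p]));
    nb[pair_i[p] - 1].push_back(std::make_pair(p, 0));
    nb[pair_j[p] - 1].push_back(std::make_pair(p, 1));
  }
  std::vector<int> s(L);
  for (int k = 0; k < L; ++k)
    s[k] = static_cast<int>(unif_rand() * q) % q;
  IntegerMatrix out(N, L);
  std::vector<double> w(q);
  int stored = 0;
  const long total_sweeps = static_cast<long>(burn_in) +
                            static_cast<long>(N) * thinning;
  for (long sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int k = 0; k < L; ++k) {
      double wmax = R_NegInf;
      for (int x = 0; x < q; ++x) {
        double en = 0.0;
        for (size_t t = 0; t < nb[k].size(); ++t) {
          const int p = nb[k][t].first;
          const NumericMatrix& Jp = Jm[p];
          if (nb[k][t].second == 0)
            en += Jp(x, s[pair_j[p] - 1]);
          else
            en += Jp(s[pair_i[p] - 1], x);
        }
        w[x] = en;
        if (en > wmax) wmax = en;
      }
      double z = 0.0;
      for (int x = 0; x < q; ++x) {
        w[x] = std::exp(w[x] - wmax);
        z += w[x];
      }
      double u = unif_rand() * z, acc = 0.0;
      int pick = q - 1;
      for (int x = 0; x < q; ++x) {
        acc += w[x];
        if (u <= acc) { pick = x; break; }
      }
      s[k] = pick;
    }
    if (sweep >= burn_in && (sweep - burn_in) % thinning == thinning - 1) {
      for (int k = 0; k < L; ++k) out(stored, k) = s[k] + 1;
      if (++stored == N) break;
    }
  }
  return out;
}

// Permutation null for the weighted KS enrichment score. wpow holds
// |value|^exponent in ranking order; each permutation draws n_hits hit ranks
// uniformly without replacement (partial Fisher-Yates on R's RNG) and
// returns the max positive running-sum deviation.
// [[Rcpp::export]]
NumericVector cpp_ks_perm_es(const NumericVector& wpow, int n_hits,
                             int n_perm) {
  const int n = wpow.size();
  NumericVector es(n_perm);
  std::vector<int> idx(n);
  std::vector<bool> hit(n);
  const double miss_dec = 1.0 / (n - n_hits);
  for (int p = 0; p < n_perm; ++p) {
    for (int k = 0; k < n; ++k) idx[k] = k;
    std::fill(hit.begin(), hit.end(), false);
    double wsum = 0.0;
    for (int t = 0; t < n_hits; ++t) {
      int j = t + static_cast<int>(unif_rand() * (n - t));
      if (j >= n) j = n - 1;
      std::swap(idx[t], idx[j]);
      hit[idx[t]] = true;
      wsum += wpow[idx[t]];
    }
    double run = 0.0, best = 0.0;
    if (wsum > 0.0) {
      for (int k = 0; k < n; ++k) {
        run += hit[k] ? wpow[k] / wsum : -miss_dec;
        if (run > best) best = run;
      }
    } else {  // all hit weights zero: fall back to unweighted increments
      const double hit_inc = 1.0 / n_hits;
      for (int k = 0; k < n; ++k) {
        run += hit[k] ? hit_inc : -miss_dec;
        if (run > best) best = run;
      }
    }
    es[p] = best;
  }
  return es;
}
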