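#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Neumaier compensated addition on long double accumulators.
static inline void neum_add(long double& s, long double& c, long double x) {
  long double t = s + x;
  if (fabsl(s) >= fabsl(x))
    c += (s - t) + x;
  else
    c += (x - t) + s;
  s = t;
}

// Power sum Z = sum_{r=1}^{W} (r+q)^(-lambda) and its lambda-derivative
// Z' = -sum (r+q)^(-lambda) * log(r+q), accumulated in long double.
// [[Rcpp::export]]
List cpp_power_sum(double W, double lambda, double q) {
  long double z = 0.0L, zc = 0.0L, zp = 0.0L, zpc = 0.0L;
  // small terms first to limit rounding
  for (double r = W; r >= 1.0; r -= 1.0) {
    long double lr = logl((long double)(r + q));
    long double term = expl(-(long double)lambda * lr);
    neum_add(z, zc, term);
    neum_add(zp, zpc, -term * lr);
  }
  return List::create(_["Z"] = (double)(z + zc), _["Zprime"] = (double)(zp + zpc));
}

// Inverse-CDF sampler for a bounded (finite-W) Zipf / Zipf-Mandelbrot
// distribution: p(r) proportional to (r+q)^(-lambda), r = 1..W.
// [[Rcpp::export]]
IntegerVector cpp_sample_finite(int n, double lambda, double q, int W) {
  std::vector<double> cum(W);
  double acc = 0.0;
  for (int r = 1; r <= W; ++r) {
    acc += std::pow((double)r + q, -lambda);
    cum[r - 1] = acc;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double u = unif_rand() * acc;
    out[i] = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin()) + 1;
  }
  return out;
}

// One draw from the tail-truncated zeta distribution
// p(m) = m^(-a) / sum_{k >= k0} k^(-a),  m in {k0, k0+1, ...}, a > 1,
// by rejection from the dominating envelope floor(Y), Y Pareto on
// [k0, inf) (Devroye 1986, ch. X.6; k0 = 1 is his zeta sampler).
// The ratio target/envelope, T / (m (T - 1)) with T = (1 + 1/m)^(a-1),
// is decreasing in m, so its value at k0 is the rejection constant and
// the expected number of iterations is uniformly bounded.
static inline double draw_zeta_tail(double a, double k0) {
  const double am1 = a - 1.0;
  const double t0 = std::pow(1.0 + 1.0 / k0, am1);
  for (;;) {
    double u = unif_rand();
    double v = unif_rand();
    double x = std::floor(k0 * std::pow(u, -1.0 / am1));
    if (!R_finite(x) || x < k0) continue;
    double t = std::pow(1.0 + 1.0 / x, am1);
    if (v * x * (t - 1.0) / (k0 * (t0 - 1.0)) <= t / t0) return x;
  }
}

static inline double draw_zeta(double a) { return draw_zeta_tail(a, 1.0); }

// [[Rcpp::export]]
NumericVector cpp_sample_zeta(int n, double lambda) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = draw_zeta(lambda);
  return out;
}

// Unbounded Zipf-Mandelbrot p(r) proportional to (r+q)^(-lambda), r >= 1:
// equivalently m = r + q follows the zeta distribution truncated to
// m >= q + 1, drawn with the shifted envelope above. q = 0 consumes
// exactly the same uniforms as cpp_sample_zeta, so outputs coincide per
// seed.
// [[Rcpp::export]]
NumericVector cpp_sample_zm(int n, double lambda, double q) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = draw_zeta_tail(lambda, q + 1.0) - q;
  return out;
}

// Tabulate sampled probability ranks into rank-frequency form.
// Returns counts sorted non-increasing plus the probability rank of the
// event occupying each empirical rank (ties: smaller probability rank
// gets the smaller empirical rank).
// [[Rcpp::export]]
List cpp_rank_counts(NumericVector x) {
  int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  std::sort(v.begin(), v.end());
  std::vector<std::pair<int, double>> ev; // (count, prob rank)
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && v[j] == v[i]) ++j;
    ev.push_back(std::make_pair(j - i, v[i]));
    i = j;
  }
  std::sort(ev.begin(), ev.end(), [](const std::pair<int, double>& a,
                                     const std::pair<int, double>& b) {
    if (a.first != b.first) return a.first > b.first;
    return a.second < b.second;
  });
  int W = ev.size();
  IntegerVector counts(W);
  NumericVector pr(W);
  for (int k = 0; k < W; ++k) { counts[k] = ev[k].first; pr[k] = ev[k].second; }
  return List::create(_["counts"] = counts, _["prob_rank"] = pr);
}

// Counts only (fast path for ABC simulation).
// [[Rcpp::export]]
IntegerVector cpp_counts_sorted(NumericVector x) {
  int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  std::sort(v.begin(), v.end());
  std::vector<int> cts;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && v[j] == v[i]) ++j;
    cts.push_back(j - i);
    i = j;
  }
  std::sort(cts.begin(), cts.end(), std::greater<int>());
  return IntegerVector(cts.begin(), cts.end());
}

// Cancellation-free log-permanent: the column-subset dynamic programme
// perm_k(S) = sum_{j in S} a_{k,j} perm_{k-1}(S \ {j}), all terms
// positive, O(W * 2^W) time and O(2^W) memory, with per-level
// renormalization so no under/overflow can occur. Also propagates a
// dual (first-order) accumulator for the likelihood derivative:
// D_k(S) = sum_j a_{kj} (B_{kj} V_{k-1} + D_{k-1}), yielding
// sum_sigma (sum_i B[i,sigma(i)]) prod_i a[i,sigma(i)] / perm.
static void perm_dp_run(int W, const std::vector<double>& A,
                        const NumericMatrix& B, bool want_grad,
                        double& log_perm_scaled, double& grad_ratio) {
  size_t nsub = 1ULL << W;
  std::vector<double> V(nsub, 0.0);
  std::vector<double> D;
  if (want_grad) D.assign(nsub, 0.0);
  V[0] = 1.0;
  double log_rescale = 0.0;
  double prev_inv = 1.0;
  for (int k = 1; k <= W; ++k) {
    const double* arow = &A[(size_t)(k - 1) * W];
    double mx = 0.0;
    uint64_t S = (1ULL << k) - 1;
    for (;;) {
      double v = 0.0, d = 0.0;
      uint64_t rem = S;
      while (rem) {
        int j = __builtin_ctzll(rem);
        rem &= rem - 1;
        uint64_t Sp = S ^ (1ULL << j);
        double a = arow[j] * prev_inv;
        v += a * V[Sp];
        if (want_grad) d += a * (B(k - 1, j) * V[Sp] + D[Sp]);
      }
      V[S] = v;
      if (want_grad) D[S] = d;
      if (v > mx) mx = v;
      uint64_t c = S & (~S + 1ULL);
      uint64_t rr = S + c;
      if (rr >= nsub) break;            // largest subset of this size done
      S = (((rr ^ S) >> 2) / c) | rr;   // Gosper: next subset of same size
    }
    if (mx <= 0.0) {
      log_perm_scaled = R_NegInf;
      grad_ratio = NA_REAL;
      return;
    }
    if (k < W) {
      log_rescale += std::log(mx);
      prev_inv = 1.0 / mx;
    }
  }
  log_perm_scaled = std::log(V[nsub - 1]) + log_rescale;
  grad_ratio = want_grad ? D[nsub - 1] / V[nsub - 1] : NA_REAL;
}

// Log-permanent of a positive matrix given as log-entries. Primary
// engine: Ryser inclusion-exclusion with Gray-code subset updates,
// O(W * 2^W), rows scaled by their max log-entry, alternating sum
// accumulated with Neumaier compensation in long double; optionally a
// dual accumulator for the likelihood derivative. When the alternating
// sum cancels more than 6 significant digits, the computation is redone
// with the positive-term subset dynamic programme above, which cannot
// cancel. digits_lost reports log10(sum |terms| / result) of the pass
// that produced the answer (0 for the DP).
// [[Rcpp::export]]
List cpp_ryser(NumericMatrix logA, NumericMatrix B, bool want_grad) {
  int W = logA.nrow();
  if (logA.ncol() != W) stop("matrix must be square");
  if (W > 25) stop("permanent computation capped at W = 25");
  std::vector<double> A((size_t)W * W);
  std::vector<double> scale(W);
  for (int i = 0; i < W; ++i) {
    double m = logA(i, 0);
    for (int j = 1; j < W; ++j) m = std::max(m, logA(i, j));
    scale[i] = m;
    for (int j = 0; j < W; ++j)
      A[(size_t)i * W + j] = std::exp(logA(i, j) - m);
  }
  std::vector<long double> r(W, 0.0L), dr(W, 0.0L);
  long double acc = 0.0L, accc = 0.0L, accabs = 0.0L, accabsc = 0.0L;
  long double gacc = 0.0L, gaccc = 0.0L;
  uint64_t nsub = 1ULL << W;
  uint32_t gray = 0;
  for (uint64_t k = 1; k < nsub; ++k) {
    uint32_t newgray = (uint32_t)(k ^ (k >> 1));
    uint32_t bit = gray ^ newgray;
    int j = __builtin_ctz(bit);
    bool added = (newgray & bit) != 0;
    gray = newgray;
    for (int i = 0; i < W; ++i) {
      long double a = A[(size_t)i * W + j];
      if (added) {
        r[i] += a;
        if (want_grad) dr[i] += a * (long double)B(i, j);
      } else {
        r[i] -= a;
        if (want_grad) dr[i] -= a * (long double)B(i, j);
      }
    }
    long double prod = 1.0L, dsum = 0.0L;
    for (int i = 0; i < W; ++i) prod *= r[i];
    if (want_grad && prod != 0.0L)
      for (int i = 0; i < W; ++i) dsum += dr[i] / r[i];
    int pc = __builtin_popcount(gray);
    long double sgn = ((W - pc) % 2 == 0) ? 1.0L : -1.0L;
    neum_add(acc, accc, sgn * prod);
    neum_add(accabs, accabsc, fabsl(prod));
    if (want_grad) neum_add(gacc, gaccc, sgn * prod * dsum);
  }
  long double perm = acc + accc;
  long double permabs = accabs + accabsc;
  double log_scale = 0.0;
  for (int i = 0; i < W; ++i) log_scale += scale[i];
  double digits_lost =
      (perm > 0.0L) ? (double)log10l(permabs / perm) : 99.0;
  bool escalated = false;
  double log_perm, grad_ratio;
  if (digits_lost > 6.0) {
    escalated = true;
    perm_dp_run(W, A, B, want_grad, log_perm, grad_ratio);
    if (!R_finite(log_perm) && log_perm != R_NegInf)
      stop("permanent evaluation failed");
    if (log_perm == R_NegInf)
      stop("permanent underflows to zero after scaling");
    log_perm += log_scale;
    digits_lost = 0.0;
  } else {
    log_perm = (double)logl(perm) + log_scale;
    grad_ratio = want_grad ? (double)((gacc + gaccc) / perm) : NA_REAL;
  }
  if (!want_grad) grad_ratio = NA_REAL;
  return List::create(_["log_perm"] = log_perm,
                      _["grad_ratio"] = grad_ratio,
                      _["digits_lost"] = digits_lost,
                      _["escalated"] = escalated);
}
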