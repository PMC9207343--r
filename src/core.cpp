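#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the coupled phase-oscillator network
//   dtheta_i/dt = omega_i + k * sum_j a_ij * sin(theta_j - theta_i)
// Phases are returned unwrapped, one row per retained sample (after burn-in).
// `noise`, when non-empty, holds per-step additive phase increments
// (n_samples x n rows) applied after the deterministic update.
// [[Rcpp::export(name = ".kuramoto_euler_cpp")]]
NumericMatrix kuramoto_euler_cpp(NumericMatrix a, NumericVector omega,
                                 NumericVector theta0, double k, double h,
                                 int n_samples, int burn_in,
                                 NumericMatrix noise) {
  const int n = a.nrow();
  const bool has_noise = noise.nrow() > 0;
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> dth(n);
  NumericMatrix out(n_samples - burn_in, n);

  for (int t = 0; t < n_samples; ++t) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      const double thi = th[i];
      for (int j = 0; j < n; ++j) {
        s += a(j, i) * std::sin(th[j] - thi);  // a symmetric: a(j,i)=a(i,j)
      }
      dth[i] = omega[i] + k * s;
    }
    for (int i = 0; i < n; ++i) {
      th[i] += h * dth[i];
      if (has_noise) th[i] += noise(t, i);
      if (!std::isfinite(th[i])) {
        stop("non-finite phase for oscillator %d at integration step %d",
             i + 1, t + 1);
      }
    }
    if (t >= burn_in) {
      for (int i = 0; i < n; ++i) out(t - burn_in, i) = th[i];
    }
  }
  return out;
}

// Lempel-Ziv (1976) exhaustive production count of a binary sequence.
// Each word is the shortest prefix of the remainder that is not a
// substring of the text preceding its last character (self-overlap
// allowed); the final incomplete word counts as one production.
// Equivalently, the word starting at l has length
// 1 + max_{i < l} matchlen(i, l). Matches are extended 64 positions at a
// time on a bit-packed copy of the sequence.
// [[Rcpp::export(name = ".lz76_count_cpp")]]
int lz76_count_cpp(IntegerVector s) {
  const int n = s.size();
  if (n == 0) stop("empty sequence");
  const int nw = (n + 63) / 64 + 1;
  std::vector<uint64_t> bits(nw, 0ULL);
  for (int t = 0; t < n; ++t) {
    if (s[t]) bits[t >> 6] |= (1ULL << (t & 63));
  }
  // 64 bits of the sequence starting at position p (zero-padded past n)
  auto get64 = [&](int p) -> uint64_t {
    const int w = p >> 6, o = p & 63;
    uint64_t v = bits[w] >> o;
    if (o) v |= bits[w + 1] << (64 - o);
    return v;
  };
  // length of the common prefix of s[i..] and s[l..], at most `cap`
  auto matchlen = [&](int i, int l, int cap) -> int {
    int j = 0;
    while (j < cap) {
      uint64_t diff = get64(i + j) ^ get64(l + j);
      if (diff) {
        int m = j + __builtin_ctzll(diff);
        return m < cap ? m : cap;
      }
      j += 64;
    }
    return cap;
  };
  int c = 0, l = 0;
  while (l < n) {
    const int cap = n - l;
    int maxlen = 0;
    for (int i = 0; i < l && maxlen < cap; ++i) {
      const int m = matchlen(i, l, cap);
      if (m > maxlen) maxlen = m;
    }
    ++c;
    if (l + maxlen + 1 > n) break;  // reproducible tail: one final word
    l += maxlen + 1;
  }
  return c;
}
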