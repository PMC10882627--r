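// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Multichannel eigenvalue-weighted multitaper power.
//
// X: samples x channels (real), tapers: samples x K (orthonormal),
// weights: K non-negative weights summing to 1.
// Returns (n/2 + 1) x channels one-sided raw power, i.e. the weighted
// average over tapers of |FFT(taper .* x)|^2 at non-negative frequencies.
// Density scaling (1/fs, one-sided doubling) is applied by the R caller.
// Channels are processed in complex-packed pairs: for real u, v the FFT of
// u + i v separates by Hermitian symmetry, halving the FFT count.
// [[Rcpp::export]]
arma::mat mtm_power_cpp(const arma::mat& X, const arma::mat& tapers,
                        const arma::vec& weights) {
  const uword n = X.n_rows, nch = X.n_cols, K = tapers.n_cols;
  const uword nf = n / 2 + 1;
  mat P(nf, nch, fill::zeros);
  cx_mat Z(n, K);
  for (uword c = 0; c < nch; c += 2) {
    const bool pair = (c + 1 < nch);
    if (pair) {
      cx_vec z(n);
      for (uword t = 0; t < n; ++t) z[t] = cx_double(X(t, c), X(t, c + 1));
      for (uword k = 0; k < K; ++k) Z.col(k) = tapers.col(k) % z;
    } else {
      for (uword k = 0; k < K; ++k)
        Z.col(k) = conv_to<cx_vec>::from(tapers.col(k) % X.col(c));
    }
    cx_mat F = fft(Z);
    for (uword k = 0; k < K; ++k) {
      const double w = weights[k];
      for (uword r = 0; r < nf; ++r) {
        const uword rr = (r == 0) ? 0 : n - r;
        const cx_double a = F(r, k), b = std::conj(F(rr, k));
        const cx_double Xa = 0.5 * (a + b);
        P(r, c) += w * std::norm(Xa);
        if (pair) {
          const cx_double Xb = cx_double(0, -0.5) * (a - b);
          P(r, c + 1) += w * std::norm(Xb);
        }
      }
    }
  }
  return P;
}

// Zero-phase FIR filtering by linear convolution with a symmetric kernel g
// (length 2L + 1, centre at index L), equivalent to one forward and one
// backward pass with the underlying order-2L linear-phase FIR pair.
// Output has the same length as the input (edge transients retained; the
// caller is responsible for discarding them). Channel pairs are packed into
// complex FFTs; since g is real, Re/Im parts stay independent.
// [[Rcpp::export]]
arma::mat fir_filt_cpp(const arma::mat& X, const arma::vec& g) {
  const uword n = X.n_rows, nch = X.n_cols;
  const uword L = (g.n_elem - 1) / 2;
  uword nfft = 1;
  while (nfft < n + g.n_elem) nfft <<= 1;
  cx_vec G = fft(join_cols(g, zeros<vec>(nfft - g.n_elem)));
  mat Y(n, nch);
  for (uword c = 0; c < nch; c += 2) {
    const bool pair = (c + 1 < nch);
    cx_vec z(nfft, fill::zeros);
    if (pair)
      for (uword t = 0; t < n; ++t) z[t] = cx_double(X(t, c), X(t, c + 1));
    else
      for (uword t = 0; t < n; ++t) z[t] = cx_double(X(t, c), 0.0);
    cx_vec y = ifft(cx_vec(fft(z) % G));
    for (uword t = 0; t < n; ++t) {
      Y(t, c) = y[t + L].real();
      if (pair) Y(t, c + 1) = y[t + L].imag();
    }
  }
  return Y;
}

static int sturm_count(const vec& d, const vec& e2, double x) {
  // number of eigenvalues of the symmetric tridiagonal (d, e) strictly < x
  int count = 0;
  double q = d[0] - x;
  if (q < 0) ++count;
  for (uword i = 1; i < d.n_elem; ++i) {
    const double denom =
        (std::abs(q) < 1e-300) ? ((q < 0) ? -1e-300 : 1e-300) : q;
    q = d[i] - x - e2[i - 1] / denom;
    if (q < 0) ++count;
  }
  return count;
}

// Discrete prolate spheroidal sequences (Slepian tapers).
//
// Computes the K most concentrated length-n tapers for half-bandwidth
// W = nw/n via the standard tridiagonal eigenproblem: bisection on Sturm
// sequence counts for the K largest eigenvalues, then inverse iteration
// with a partially pivoted tridiagonal LU solve. Columns are orthonormal,
// ordered by decreasing spectral concentration, with the usual sign
// convention (symmetric tapers have positive mean, antisymmetric tapers a
// positive leading slope).
// [[Rcpp::export]]
arma::mat dpss_cpp(int n, double nw, int K) {
  const double W = nw / n;
  vec d(n), e(n - 1), e2(n - 1);
  const double c = std::cos(2.0 * M_PI * W);
  for (int i = 0; i < n; ++i) {
    const double h = 0.5 * (n - 1 - 2.0 * i);
    d[i] = h * h * c;
  }
  for (int i = 1; i < n; ++i) {
    e[i - 1] = 0.5 * i * (n - i);
    e2[i - 1] = e[i - 1] * e[i - 1];
  }
  double lo = datum::inf, hi = -datum::inf;
  for (int i = 0; i < n; ++i) {
    const double r = (i > 0 ? std::abs(e[i - 1]) : 0.0) +
                     (i < n - 1 ? std::abs(e[i]) : 0.0);
    lo = std::min(lo, d[i] - r);
    hi = std::max(hi, d[i] + r);
  }
  mat V(n, K);
  for (int k = 0; k < K; ++k) {
    const int target = n - 1 - k;  // k-th largest = index n-1-k ascending
    double a = lo, b = hi;
    for (int it = 0;
         it < 120 && (b - a) > 1e-11 * std::max(1.0, std::abs(b)); ++it) {
      const double m = 0.5 * (a + b);
      if (sturm_count(d, e2, m) > target) b = m; else a = m;
    }
    const double lambda = 0.5 * (a + b);
    vec v(n);
    // deterministic, non-degenerate start vector
    for (int i = 0; i < n; ++i)
      v[i] = std::sin((k + 1) * M_PI * (i + 1.0) / (n + 1.0));
    v /= norm(v);
    for (int it = 0; it < 8; ++it) {
      // solve (T - lambda I) w = v, tridiagonal LU with partial pivoting
      std::vector<double> D(n), U(n, 0.0), U2(n, 0.0), Lw(n, 0.0);
      vec x = v;
      for (int i = 0; i < n; ++i) D[i] = d[i] - lambda;
      for (int i = 0; i < n - 1; ++i) { U[i] = e[i]; Lw[i] = e[i]; }
      for (int i = 0; i < n - 1; ++i) {
        if (std::abs(Lw[i]) > std::abs(D[i])) {
          std::swap(D[i], Lw[i]);
          const double tmp = U[i]; U[i] = D[i + 1]; D[i + 1] = tmp;
          if (i < n - 2) { U2[i] = U[i + 1]; U[i + 1] = 0.0; }
          const double tx = x[i]; x[i] = x[i + 1]; x[i + 1] = tx;
        }
        const double piv = (std::abs(D[i]) < 1e-300) ? 1e-300 : D[i];
        const double m = Lw[i] / piv;
        D[i + 1] -= m * U[i];
        if (i < n - 2) U[i + 1] -= m * U2[i];
        x[i + 1] -= m * x[i];
      }
      vec w(n);
      double dn = (std::abs(D[n - 1]) < 1e-300) ? 1e-300 : D[n - 1];
      w[n - 1] = x[n - 1] / dn;
      if (n >= 2) {
        dn = (std::abs(D[n - 2]) < 1e-300) ? 1e-300 : D[n - 2];
        w[n - 2] = (x[n - 2] - U[n - 2] * w[n - 1]) / dn;
      }
      for (int i = n - 3; i >= 0; --i) {
        dn = (std::abs(D[i]) < 1e-300) ? 1e-300 : D[i];
        w[i] = (x[i] - U[i] * w[i + 1] - U2[i] * w[i + 2]) / dn;
      }
      v = w / norm(w);
    }
    for (int j = 0; j < k; ++j) v -= dot(V.col(j), v) * V.col(j);
    v /= norm(v);
    V.col(k) = v;
  }
  for (int k = 0; k < K; ++k) {
    if (k % 2 == 0) {
      if (accu(V.col(k)) < 0) V.col(k) *= -1.0;
    } else {
      double sl = 0;
      for (int i = 0; i < n / 2; ++i) sl += (n - 1 - 2.0 * i) * V(i, k);
      if (sl < 0) V.col(k) *= -1.0;
    }
  }
  return V;
}

// Maximum cluster-mass statistic per permutation.
//
// T: n_perm x n_channel t-values; thresh: cluster-forming threshold (> 0);
// adj: adjacency as a list of integer vectors (1-based neighbour indices).
// For each row, channels with t > thresh are clustered by adjacency, as are
// channels with t < -thresh; the return value is the largest absolute
// within-cluster sum of t over both signs (0 when nothing is supra-threshold).
// [[Rcpp::export]]
arma::vec max_cluster_mass_cpp(const arma::mat& T, double thresh,
                               const Rcpp::List& adj) {
  const uword nperm = T.n_rows, nch = T.n_cols;
  std::vector<std::vector<int>> nb(nch);
  for (uword i = 0; i < nch; ++i) {
    Rcpp::IntegerVector v = adj[i];
    for (int j : v) nb[i].push_back(j - 1);
  }
  vec out(nperm, fill::zeros);
  std::vector<int> stack;
  std::vector<char> mask(nch), seen(nch);
  for (uword p = 0; p < nperm; ++p) {
    double best = 0.0;
    for (int sign = 0; sign < 2; ++sign) {
      for (uword i = 0; i < nch; ++i) {
        const double t = T(p, i);
        mask[i] = sign == 0 ? (t > thresh) : (t < -thresh);
        seen[i] = 0;
      }
      for (uword i = 0; i < nch; ++i) {
        if (!mask[i] || seen[i]) continue;
        double mass = 0.0;
        stack.clear();
        stack.push_back(i);
        seen[i] = 1;
        while (!stack.empty()) {
          const int u = stack.back();
          stack.pop_back();
          mass += T(p, u);
          for (int vtx : nb[u])
            if (mask[vtx] && !seen[vtx]) { seen[vtx] = 1; stack.push_back(vtx); }
        }
        best = std::max(best, std::abs(mass));
      }
    }
    out[p] = best;
  }
  return out;
}
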