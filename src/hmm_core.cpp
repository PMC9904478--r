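// Scaled forward-backward and Baum-Welch for the discrete-symbol
// spike-train HMM. Symbols are 1..N+1 (N neurons + a null symbol); the
// initial state distribution is fixed uniform and is not a fitted
// parameter. All likelihoods are accumulated in log space via per-bin
// scaling, so sessions of arbitrary length stay finite.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double TINY = 1e-300;

// Forward pass with scaling for one sequence. Returns log-likelihood;
// if alpha != nullptr, stores the scaled alphas (M x B) and the scales.
static double forward_scaled(const std::vector<double>& T,
                             const std::vector<double>& E,
                             int M, int S,
                             const int* obs, int B,
                             std::vector<double>* alpha,
                             std::vector<double>* scale) {
  std::vector<double> a(M), a2(M);
  double ll = 0.0;
  const double pi = 1.0 / M;
  for (int t = 0; t < B; ++t) {
    int o = obs[t] - 1;  // 0-based symbol
    double norm = 0.0;
    if (t == 0) {
      for (int i = 0; i < M; ++i) { a2[i] = pi * E[i * S + o]; norm += a2[i]; }
    } else {
      for (int j = 0; j < M; ++j) {
        double s = 0.0;
        for (int i = 0; i < M; ++i) s += a[i] * T[i * M + j];
        a2[j] = s * E[j * S + o];
        norm += a2[j];
      }
    }
    if (norm <= 0.0) {
      for (int j = 0; j < M; ++j) a2[j] = TINY;
      norm = M * TINY;
    }
    for (int j = 0; j < M; ++j) a2[j] /= norm;
    ll += std::log(norm);
    if (alpha) {
      for (int j = 0; j < M; ++j) (*alpha)[(size_t)t * M + j] = a2[j];
      (*scale)[t] = norm;
    }
    std::swap(a, a2);
  }
  return ll;
}

// Backward pass using the forward scales; beta is stored scaled.
static void backward_scaled(const std::vector<double>& T,
                            const std::vector<double>& E,
                            int M, int S,
                            const int* obs, int B,
                            const std::vector<double>& scale,
                            std::vector<double>& beta) {
  for (int j = 0; j < M; ++j) beta[(size_t)(B - 1) * M + j] = 1.0;
  for (int t = B - 2; t >= 0; --t) {
    int o = obs[t + 1] - 1;
    double c = scale[t + 1];
    for (int i = 0; i < M; ++i) {
      double s = 0.0;
      for (int j = 0; j < M; ++j)
        s += T[i * M + j] * E[j * S + o] * beta[(size_t)(t + 1) * M + j];
      beta[(size_t)t * M + i] = s / c;
    }
  }
}

// [[Rcpp::export]]
double cpp_hmm_loglik(NumericMatrix Tmat, NumericMatrix Emat, List seqs) {
  int M = Tmat.nrow(), S = Emat.ncol();
  std::vector<double> T(M * M), E(M * S);
  for (int i = 0; i < M; ++i) {
    for (int j = 0; j < M; ++j) T[i * M + j] = Tmat(i, j);
    for (int s = 0; s < S; ++s) E[i * S + s] = Emat(i, s);
  }
  double ll = 0.0;
  for (int q = 0; q < seqs.size(); ++q) {
    IntegerVector o = seqs[q];
    ll += forward_scaled(T, E, M, S, INTEGER(o), o.size(), nullptr, nullptr);
  }
  return ll;
}

// [[Rcpp::export]]
List cpp_baum_welch(List seqs, NumericMatrix T0, NumericMatrix E0,
                    int max_iter, double tol) {
  int M = T0.nrow(), S = E0.ncol();
  std::vector<double> T(M * M), E(M * S);
  for (int i = 0; i < M; ++i) {
    for (int j = 0; j < M; ++j) T[i * M + j] = T0(i, j);
    for (int s = 0; s < S; ++s) E[i * S + s] = E0(i, s);
  }
  int nseq = seqs.size();
  std::vector<const int*> obs(nseq);
  std::vector<int> len(nseq);
  int Bmax = 0;
  for (int q = 0; q < nseq; ++q) {
    IntegerVector o = seqs[q];
    obs[q] = INTEGER(o);
    len[q] = o.size();
    if (len[q] > Bmax) Bmax = len[q];
  }
  std::vector<double> alpha((size_t)Bmax * M), beta((size_t)Bmax * M),
      scale(Bmax);
  std::vector<double> Tnum(M * M), Enum(M * S), gsum(M);
  std::vector<double> ll_trace;
  double ll_prev = R_NegInf;
  double ll = R_NegInf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    std::fill(Tnum.begin(), Tnum.end(), 0.0);
    std::fill(Enum.begin(), Enum.end(), 0.0);
    ll = 0.0;
    for (int q = 0; q < nseq; ++q) {
      int B = len[q];
      const int* o = obs[q];
      ll += forward_scaled(T, E, M, S, o, B, &alpha, &scale);
      backward_scaled(T, E, M, S, o, B, scale, beta);
      // gamma accumulation into emission counts
      for (int t = 0; t < B; ++t) {
        int ot = o[t] - 1;
        for (int i = 0; i < M; ++i) {
          double g = alpha[(size_t)t * M + i] * beta[(size_t)t * M + i];
          Enum[i * S + ot] += g;
        }
      }
      // xi accumulation into transition counts
      std::vector<double> eb(M);
      for (int t = 0; t < B - 1; ++t) {
        int o1 = o[t + 1] - 1;
        double inv_c1 = 1.0 / scale[t + 1];
        for (int j = 0; j < M; ++j)
          eb[j] = E[j * S + o1] * beta[(size_t)(t + 1) * M + j] * inv_c1;
        for (int i = 0; i < M; ++i) {
          double ai = alpha[(size_t)t * M + i];
          if (ai <= 0) continue;
          const double* Ti = &T[i * M];
          double* Tn = &Tnum[i * M];
          for (int j = 0; j < M; ++j) Tn[j] += ai * Ti[j] * eb[j];
        }
      }
    }
    ll_trace.push_back(ll);
    // M-step
    double dT = 0.0, dE = 0.0;
    for (int i = 0; i < M; ++i) {
      double rs = 0.0;
      for (int j = 0; j < M; ++j) rs += Tnum[i * M + j];
      if (rs > 0)
        for (int j = 0; j < M; ++j) {
          double v = Tnum[i * M + j] / rs;
          dT = std::max(dT, std::fabs(v - T[i * M + j]));
          T[i * M + j] = v;
        }
      double es = 0.0;
      for (int s = 0; s < S; ++s) es += Enum[i * S + s];
      if (es > 0)
        for (int s = 0; s < S; ++s) {
          double v = Enum[i * S + s] / es;
          dE = std::max(dE, std::fabs(v - E[i * S + s]));
          E[i * S + s] = v;
        }
    }
    if (it > 0 && std::fabs(ll - ll_prev) < tol && dT < tol && dE < tol) {
      ++it;
      break;
    }
    ll_prev = ll;
  }
  // Log-likelihood of the final parameters.
  double ll_final = 0.0;
  for (int q = 0; q < nseq; ++q)
    ll_final += forward_scaled(T, E, M, S, obs[q], len[q], nullptr, nullptr);

  NumericMatrix Tout(M, M), Eout(M, S);
  for (int i = 0; i < M; ++i) {
    for (int j = 0; j < M; ++j) Tout(i, j) = T[i * M + j];
    for (int s = 0; s < S; ++s) Eout(i, s) = E[i * S + s];
  }
  return List::create(_["T"] = Tout, _["E"] = Eout,
                      _["log_likelihood"] = ll_final,
                      _["n_iter"] = it,
                      _["ll_trace"] = NumericVector(ll_trace.begin(),
                                                    ll_trace.end()));
}

// [[Rcpp::export]]
NumericMatrix cpp_posterior(NumericMatrix Tmat, NumericMatrix Emat,
                            IntegerVector seq) {
  int M = Tmat.nrow(), S = Emat.ncol(), B = seq.size();
  std::vector<double> T(M * M), E(M * S);
  for (int i = 0; i < M; ++i) {
    for (int j = 0; j < M; ++j) T[i * M + j] = Tmat(i, j);
    for (int s = 0; s < S; ++s) E[i * S + s] = Emat(i, s);
  }
  std::vector<double> alpha((size_t)B * M), beta((size_t)B * M), scale(B);
  forward_scaled(T, E, M, S, INTEGER(seq), B, &alpha, &scale);
  backward_scaled(T, E, M, S, INTEGER(seq), B, scale, beta);
  NumericMatrix G(M, B);
  for (int t = 0; t < B; ++t) {
    double norm = 0.0;
    for (int i = 0; i < M; ++i) {
      double g = alpha[(size_t)t * M + i] * beta[(size_t)t * M + i];
      G(i, t) = g;
      norm += g;
    }
    if (norm > 0) for (int i = 0; i < M; ++i) G(i, t) /= norm;
  }
  return G;
}
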