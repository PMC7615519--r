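// Per-step recursions for the online testing policies. Each routine walks the
// p-value stream once, maintaining the rejection times and the candidate /
// selection counts that shift the spending-sequence indices, and returns the
// emitted level for every step plus the level that would apply to a further
// (T+1)-th hypothesis.
//
// `gamma` holds normalized weights: gamma[i-1] = gamma_i for sequences
// indexed from 1, gamma0[k] = gamma_k for the ADDIS sequence indexed from 0.
// Bounded sequences arrive with zeros past the bound, so no bounds logic is
// needed here beyond array range checks.

#include <Rcpp.h>
using namespace Rcpp;

static inline double g1(const NumericVector& g, R_xlen_t i) {
  // weight at 1-based sequence index i; 0 outside the materialized range
  return (i >= 1 && i <= g.size()) ? g[i - 1] : 0.0;
}

static inline double g0(const NumericVector& g, R_xlen_t i) {
  // weight at 0-based sequence index i
  return (i >= 0 && i < g.size()) ? g[i] : 0.0;
}

// [[Rcpp::export]]
List run_lord_cpp(NumericVector p, NumericVector gamma, double alpha,
                  double w0, double b0) {
  R_xlen_t T = p.size();
  NumericVector levels(T + 1);
  IntegerVector reject(T);
  std::vector<R_xlen_t> tau;
  for (R_xlen_t t = 1; t <= T + 1; ++t) {
    double rew = 0.0;
    for (size_t j = 0; j < tau.size(); ++j) rew += g1(gamma, t - tau[j]);
    double a = w0 * g1(gamma, t) + b0 * rew;
    levels[t - 1] = a;
    if (t <= T && p[t - 1] <= a) {
      reject[t - 1] = 1;
      tau.push_back(t);
    }
  }
  return List::create(_["levels"] = levels, _["reject"] = reject);
}

// [[Rcpp::export]]
List run_lordpp_cpp(NumericVector p, NumericVector gamma, double alpha,
                    double w0) {
  R_xlen_t T = p.size();
  NumericVector levels(T + 1);
  IntegerVector reject(T);
  std::vector<R_xlen_t> tau;
  for (R_xlen_t t = 1; t <= T + 1; ++t) {
    double a = w0 * g1(gamma, t);
    if (!tau.empty()) a += (alpha - w0) * g1(gamma, t - tau[0]);
    double rew = 0.0;
    for (size_t j = 1; j < tau.size(); ++j) rew += g1(gamma, t - tau[j]);
    a += alpha * rew;
    levels[t - 1] = a;
    if (t <= T && p[t - 1] <= a) {
      reject[t - 1] = 1;
      tau.push_back(t);
    }
  }
  return List::create(_["levels"] = levels, _["reject"] = reject);
}

// [[Rcpp::export]]
List run_saffron_cpp(NumericVector p, NumericVector gamma, double alpha,
                     double w0, double lambda) {
  R_xlen_t T = p.size();
  NumericVector levels(T + 1);
  IntegerVector reject(T), candidate(T);
  std::vector<R_xlen_t> tau;       // rejection times
  std::vector<R_xlen_t> candAfter; // candidates strictly after tau_j so far
  R_xlen_t C0 = 0;                 // candidates among indices < t
  for (R_xlen_t t = 1; t <= T + 1; ++t) {
    double b = w0 * g1(gamma, t - C0);
    if (!tau.empty()) b += (alpha - w0) * g1(gamma, t - tau[0] - candAfter[0]);
    double rew = 0.0;
    for (size_t j = 1; j < tau.size(); ++j)
      rew += g1(gamma, t - tau[j] - candAfter[j]);
    b += alpha * rew;
    double a = std::min(lambda, (1.0 - lambda) * b);
    levels[t - 1] = a;
    if (t <= T) {
      bool rej = p[t - 1] <= a;
      reject[t - 1] = rej ? 1 : 0;
      if (p[t - 1] <= lambda) {
        candidate[t - 1] = 1;
        ++C0;
        for (size_t j = 0; j < candAfter.size(); ++j) ++candAfter[j];
      }
      if (rej) {
        tau.push_back(t);
        candAfter.push_back(0);
      }
    }
  }
  return List::create(_["levels"] = levels, _["reject"] = reject,
                      _["candidate"] = candidate);
}

// [[Rcpp::export]]
List run_addis_cpp(NumericVector p, NumericVector gamma0, double alpha,
                   double w0, double lambda, double eta) {
  R_xlen_t T = p.size();
  NumericVector levels(T + 1);
  IntegerVector reject(T), candidate(T), selected(T);
  std::vector<R_xlen_t> tau;
  std::vector<R_xlen_t> candAfter; // candidates strictly after tau_j (selected ones)
  std::vector<R_xlen_t> selAtTau;  // S^{tau_j + 1} = selected among indices <= tau_j
  R_xlen_t S = 0;                  // selected among indices < t
  R_xlen_t C0 = 0;                 // candidates among (selected) indices < t
  for (R_xlen_t t = 1; t <= T + 1; ++t) {
    double b = w0 * g0(gamma0, S - C0);
    if (!tau.empty())
      b += (alpha - w0) * g0(gamma0, S - selAtTau[0] - candAfter[0]);
    double rew = 0.0;
    for (size_t j = 1; j < tau.size(); ++j)
      rew += g0(gamma0, S - selAtTau[j] - candAfter[j]);
    b += alpha * rew;
    double a = std::min(lambda, (eta - lambda) * b);
    levels[t - 1] = a;
    if (t <= T) {
      bool rej = p[t - 1] <= a;
      reject[t - 1] = rej ? 1 : 0;
      if (p[t - 1] <= eta) {
        selected[t - 1] = 1;
        ++S;
      }
      if (p[t - 1] <= lambda) {
        candidate[t - 1] = 1;
        ++C0;
        for (size_t j = 0; j < candAfter.size(); ++j) ++candAfter[j];
      }
      if (rej) { // a rejection is always selected and a candidate (a <= lambda < eta)
        tau.push_back(t);
        candAfter.push_back(0);
        selAtTau.push_back(S);
      }
    }
  }
  return List::create(_["levels"] = levels, _["reject"] = reject,
                      _["candidate"] = candidate, _["selected"] = selected);
}

// Monotone alpha-investing: the SAFFRON recursion with per-step
// self-candidacy C_j = 1{P_j <= alpha_j} and the (1 - alpha_t) discount, so
// the level solves alpha_t = (1 - alpha_t) * b_t, i.e. alpha_t = b/(1+b).
// [[Rcpp::export]]
List run_ai_cpp(NumericVector p, NumericVector gamma, double alpha,
                double w0) {
  R_xlen_t T = p.size();
  NumericVector levels(T + 1);
  IntegerVector reject(T), candidate(T);
  std::vector<R_xlen_t> tau;
  std::vector<R_xlen_t> candAfter;
  R_xlen_t C0 = 0;
  for (R_xlen_t t = 1; t <= T + 1; ++t) {
    double b = w0 * g1(gamma, t - C0);
    if (!tau.empty()) b += (alpha - w0) * g1(gamma, t - tau[0] - candAfter[0]);
    double rew = 0.0;
    for (size_t j = 1; j < tau.size(); ++j)
      rew += g1(gamma, t - tau[j] - candAfter[j]);
    b += alpha * rew;
    double a = b / (1.0 + b);
    levels[t - 1] = a;
    if (t <= T) {
      bool rej = p[t - 1] <= a;
      reject[t - 1] = rej ? 1 : 0;
      if (p[t - 1] <= a) { // self-candidacy: candidate iff rejected
        candidate[t - 1] = 1;
        ++C0;
        for (size_t j = 0; j < candAfter.size(); ++j) ++candAfter[j];
      }
      if (rej) {
        tau.push_back(t);
        candAfter.push_back(0);
      }
    }
  }
  return List::create(_["levels"] = levels, _["reject"] = reject,
                      _["candidate"] = candidate);
}
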