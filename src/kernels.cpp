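#include <Rcpp.h>
using namespace Rcpp;

// Dominant cause index per observable for a set of latent states.
// M: D x (H+1) mean dictionary; S: U x (H+1) binary states (column 0 is the
// always-active background).  Returns U x D matrix of 0-based cause indices,
// ties broken by the lowest index.
// [[Rcpp::export]]
IntegerMatrix dominant_idx_cpp(NumericMatrix M, IntegerMatrix S) {
  const int D = M.nrow(), Hp1 = M.ncol(), U = S.nrow();
  IntegerMatrix out(U, D);
  for (int u = 0; u < U; ++u) {
    for (int d = 0; d < D; ++d) {
      int best = 0;
      double bestv = R_NegInf;
      for (int h = 0; h < Hp1; ++h) {
        if (S(u, h) == 1 && M(d, h) > bestv) {
          bestv = M(d, h);
          best = h;
        }
      }
      out(u, d) = best;
    }
  }
  return out;
}

// Beta log-likelihood term of the joint for (data point, state) pairs.
// LY, L1Y: N x D matrices of log(y) and log(1-y).  E1, E2: U x D matrices of
// (etabar - 1) for the dominant cause per observable; cLB: U vector of
// sum_d log B(etabar1, etabar2).  nIdx, uIdx: 1-based pair indices.
// [[Rcpp::export]]
NumericVector pair_loglik_cpp(NumericMatrix LY, NumericMatrix L1Y,
                              NumericMatrix E1, NumericMatrix E2,
                              NumericVector cLB,
                              IntegerVector nIdx, IntegerVector uIdx) {
  const int P = nIdx.size(), D = LY.ncol();
  NumericVector out(P);
  for (int p = 0; p < P; ++p) {
    const int n = nIdx[p] - 1, u = uIdx[p] - 1;
    double acc = -cLB[u];
    for (int d = 0; d < D; ++d) {
      acc += E1(u, d) * LY(n, d) + E2(u, d) * L1Y(n, d);
    }
    out[p] = acc;
  }
  return out;
}

// Responsibility-weighted sufficient-statistic sums for the M-step.
// Accumulates, per (observable d, cause h):
//   Wnum[d,h] = sum_p q_p * 1{Dom(u_p,d)=h} * log(y[n_p,d])
//   Vnum[d,h] = sum_p q_p * 1{Dom(u_p,d)=h} * log(1-y[n_p,d])
//   den[d,h]  = sum_p q_p * 1{Dom(u_p,d)=h}
// [[Rcpp::export]]
List mstep_sums_cpp(NumericMatrix LY, NumericMatrix L1Y, IntegerMatrix Dom,
                    IntegerVector nIdx, IntegerVector uIdx,
                    NumericVector q, int Hp1) {
  const int P = nIdx.size(), D = LY.ncol();
  NumericMatrix Wnum(D, Hp1), Vnum(D, Hp1), den(D, Hp1);
  for (int p = 0; p < P; ++p) {
    const int n = nIdx[p] - 1, u = uIdx[p] - 1;
    const double qp = q[p];
    if (qp == 0.0) continue;
    for (int d = 0; d < D; ++d) {
      const int h = Dom(u, d);
      Wnum(d, h) += qp * LY(n, d);
      Vnum(d, h) += qp * L1Y(n, d);
      den(d, h) += qp;
    }
  }
  return List::create(_["Wnum"] = Wnum, _["Vnum"] = Vnum, _["den"] = den);
}

// Per-group softmax over log-weights for groups given by a sorted 1-based
// index vector (one group per data point).  Returns normalized weights and
// the per-group log-sum-exp.
// [[Rcpp::export]]
List group_softmax_cpp(NumericVector lj, IntegerVector grp, int ngroups) {
  const int P = lj.size();
  NumericVector w(P), lse(ngroups, R_NegInf);
  NumericVector mx(ngroups, R_NegInf);
  for (int p = 0; p < P; ++p) {
    const int g = grp[p] - 1;
    if (lj[p] > mx[g]) mx[g] = lj[p];
  }
  NumericVector sum(ngroups, 0.0);
  for (int p = 0; p < P; ++p) {
    const int g = grp[p] - 1;
    w[p] = std::exp(lj[p] - mx[g]);
    sum[g] += w[p];
  }
  for (int p = 0; p < P; ++p) {
    w[p] /= sum[grp[p] - 1];
  }
  for (int g = 0; g < ngroups; ++g) {
    lse[g] = mx[g] + std::log(sum[g]);
  }
  return List::create(_["weights"] = w, _["logsumexp"] = lse);
}
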