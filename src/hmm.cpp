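// Plan7-like local profile-HMM dynamic programming.
//
// Model: match states M1..Mm with log-odds emissions (vs background),
// insert states I1..I(m-1) (background emissions, log-odds `ilo`),
// delete states D1..Dm. Local entry B->Mj carries log weight entry[j]
// (HMMER-style 2(m-j+1)/(m(m+1)) distribution); local exit Mj->E is
// free (uniform local exit). All scores are natural-log odds against an
// i.i.d. background null; bit conversion happens in R.
//
// Residue codes: 0..19 over the standard alphabet, -1 for X/unknown
// (scored 0 in log-odds in every emitting state).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -1e300;

static inline double lse(double a, double b) {
  if (a <= NEG_INF) return b;
  if (b <= NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static inline double emit(const NumericMatrix& mlo, int j, int x) {
  return x < 0 ? 0.0 : mlo(j, x);
}

struct Trans {
  NumericVector MM, MI, MD, IM, II, DM, DD;
  Trans(const List& tr)
    : MM(tr["MM"]), MI(tr["MI"]), MD(tr["MD"]), IM(tr["IM"]),
      II(tr["II"]), DM(tr["DM"]), DD(tr["DD"]) {}
};

// Viterbi over the local graph; if `traceback`, also recover the best
// path's span and per-match-state alignment.
static List viterbi_core(const IntegerVector& seq, const NumericMatrix& mlo,
                         const NumericVector& ilo, const Trans& tr,
                         const NumericVector& entry, bool traceback) {
  const int L = seq.size(), M = mlo.nrow();
  // DP matrices over (i in 1..L, j in 1..M); index [i*(M)+j-1] with i>=1
  std::vector<double> VM((L + 1) * M, NEG_INF), VI((L + 1) * M, NEG_INF),
      VD((L + 1) * M, NEG_INF);
  // traceback codes: 0 entry, 1 from M, 2 from I, 3 from D
  std::vector<signed char> PM, PI, PD;
  if (traceback) {
    PM.assign((L + 1) * M, -1);
    PI.assign((L + 1) * M, -1);
    PD.assign((L + 1) * M, -1);
  }
  double best = NEG_INF;
  int bi = -1, bj = -1;
  for (int i = 1; i <= L; ++i) {
    const int x = seq[i - 1];
    const double ie = (x < 0) ? 0.0 : ilo[x];
    for (int j = 1; j <= M; ++j) {
      const int idx = i * M + (j - 1);
      // match
      double v = entry[j - 1];
      int arg = 0;
      if (j > 1) {
        const int pidx = (i - 1) * M + (j - 2);
        double c = VM[pidx] + tr.MM[j - 2];
        if (c > v) { v = c; arg = 1; }
        c = VI[pidx] + tr.IM[j - 2];
        if (c > v) { v = c; arg = 2; }
        // D consumes no residue: D_{j-1} at residue index i-1 -> M_j at i
        c = VD[(i - 1) * M + (j - 2)] + tr.DM[j - 2];
        if (c > v) { v = c; arg = 3; }
      }
      VM[idx] = v + emit(mlo, j - 1, x);
      if (traceback) PM[idx] = (signed char)arg;
      if (VM[idx] > best) { best = VM[idx]; bi = i; bj = j; }
      // insert (only for j < M)
      if (j < M) {
        const int pidx = (i - 1) * M + (j - 1);
        double vi = VM[pidx] + tr.MI[j - 1];
        int ai = 1;
        double c = VI[pidx] + tr.II[j - 1];
        if (c > vi) { vi = c; ai = 2; }
        VI[idx] = (vi <= NEG_INF) ? NEG_INF : vi + ie;
        if (traceback) PI[idx] = (signed char)ai;
      }
      // delete (consumes no residue): D_j from M_{j-1} or D_{j-1} at same i
      if (j > 1) {
        const int midx = i * M + (j - 2);
        double vd = VM[midx] + tr.MD[j - 2];
        int ad = 1;
        double c = VD[midx] + tr.DD[j - 2];
        if (c > vd) { vd = c; ad = 3; }
        VD[idx] = vd;
        if (traceback) PD[idx] = (signed char)ad;
      }
    }
  }
  if (!traceback)
    return List::create(_["score"] = best);
  if (bi < 0)
    return List::create(_["score"] = best);
  // trace back from (bi, bj) in M
  std::vector<int> stateCol, resIdx; // match columns visited + residue (0 for D)
  int i = bi, j = bj;
  char st = 'M';
  while (true) {
    const int idx = i * M + (j - 1);
    if (st == 'M') {
      stateCol.push_back(j);
      resIdx.push_back(i);
      int p = PM[idx];
      if (p == 0) break;            // entry
      if (p == 1) { --i; --j; st = 'M'; }
      else if (p == 2) { --i; --j; st = 'I'; }
      else { --i; --j; st = 'D'; }  // D_{j-1} at residue index i-1
    } else if (st == 'I') {
      int p = PI[idx];
      if (p == 1) { --i; st = 'M'; }
      else { --i; st = 'I'; }
    } else { // D: consumes no residue
      stateCol.push_back(j);
      resIdx.push_back(0);
      int p = PD[idx];
      if (p == 1) { --j; st = 'M'; }
      else { --j; st = 'D'; }
    }
  }
  const int np = stateCol.size();
  IntegerVector cols(np), res(np);
  for (int k = 0; k < np; ++k) {
    cols[k] = stateCol[np - 1 - k];
    res[k] = resIdx[np - 1 - k];
  }
  int tstart = L + 1, tend = 0;
  for (int k = 0; k < np; ++k)
    if (res[k] > 0) { if (res[k] < tstart) tstart = res[k];
                      if (res[k] > tend) tend = res[k]; }
  return List::create(_["score"] = best,
                      _["profile_start"] = cols[0],
                      _["profile_end"] = cols[np - 1],
                      _["target_start"] = tstart,
                      _["target_end"] = tend,
                      _["match_cols"] = cols,
                      _["match_res"] = res);
}

// [[Rcpp::export(name = ".hmm_viterbi")]]
List hmm_viterbi(IntegerVector seq, NumericMatrix mlo, NumericVector ilo,
                 List tr, NumericVector entry, bool traceback = false) {
  Trans t(tr);
  return viterbi_core(seq, mlo, ilo, t, entry, traceback);
}

// [[Rcpp::export(name = ".hmm_viterbi_scores")]]
NumericVector hmm_viterbi_scores(List seqs, NumericMatrix mlo,
                                 NumericVector ilo, List tr,
                                 NumericVector entry) {
  Trans t(tr);
  const int n = seqs.size();
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    IntegerVector seq = seqs[s];
    List r = viterbi_core(seq, mlo, ilo, t, entry, false);
    out[s] = as<double>(r["score"]);
  }
  return out;
}

// Forward/backward over the same local graph. Returns log of the summed
// odds over all single-hit local alignments, and per-match-state
// posterior usage probabilities.
// [[Rcpp::export(name = ".hmm_forward_backward")]]
List hmm_forward_backward(IntegerVector seq, NumericMatrix mlo,
                          NumericVector ilo, List tr, NumericVector entry) {
  Trans t(tr);
  const int L = seq.size(), M = mlo.nrow();
  std::vector<double> FM((L + 2) * M, NEG_INF), FI((L + 2) * M, NEG_INF),
      FD((L + 2) * M, NEG_INF);
  double Zf = NEG_INF;
  for (int i = 1; i <= L; ++i) {
    const int x = seq[i - 1];
    const double ie = (x < 0) ? 0.0 : ilo[x];
    for (int j = 1; j <= M; ++j) {
      const int idx = i * M + (j - 1);
      double v = entry[j - 1];
      if (j > 1) {
        const int pidx = (i - 1) * M + (j - 2);
        v = lse(v, FM[pidx] + t.MM[j - 2]);
        v = lse(v, FI[pidx] + t.IM[j - 2]);
        v = lse(v, FD[(i - 1) * M + (j - 2)] + t.DM[j - 2]);
      }
      FM[idx] = v + emit(mlo, j - 1, x);
      Zf = lse(Zf, FM[idx]);   // free exit from any match state
      if (j < M) {
        const int pidx = (i - 1) * M + (j - 1);
        double vi = lse(FM[pidx] + t.MI[j - 1], FI[pidx] + t.II[j - 1]);
        FI[idx] = (vi <= NEG_INF) ? NEG_INF : vi + ie;
      }
      if (j > 1) {
        const int midx = i * M + (j - 2);
        FD[idx] = lse(FM[midx] + t.MD[j - 2], FD[midx] + t.DD[j - 2]);
      }
    }
  }
  // backward
  std::vector<double> BM((L + 2) * M, NEG_INF), BI((L + 2) * M, NEG_INF),
      BD((L + 2) * M, NEG_INF);
  for (int i = L; i >= 1; --i) {
    for (int j = M; j >= 1; --j) {
      const int idx = i * M + (j - 1);
      double bm = 0.0;   // free exit
      if (j < M) {
        // M_j -> D_{j+1} (same residue index)
        bm = lse(bm, t.MD[j - 1] + BD[i * M + j]);
        if (i < L) {
          const int x1 = seq[i];
          bm = lse(bm, t.MM[j - 1] + emit(mlo, j, x1) + BM[(i + 1) * M + j]);
          const double ie1 = (x1 < 0) ? 0.0 : ilo[x1];
          bm = lse(bm, t.MI[j - 1] + ie1 + BI[(i + 1) * M + (j - 1)]);
        }
        double bd = t.DD[j - 1] + BD[i * M + j];
        double bi_ = NEG_INF;
        if (i < L) {
          const int x1 = seq[i];
          const double e1 = emit(mlo, j, x1);
          bd = lse(bd, t.DM[j - 1] + e1 + BM[(i + 1) * M + j]);
          const double ie1 = (x1 < 0) ? 0.0 : ilo[x1];
          bi_ = lse(t.IM[j - 1] + e1 + BM[(i + 1) * M + j],
                    t.II[j - 1] + ie1 + BI[(i + 1) * M + (j - 1)]);
        }
        BD[idx] = bd;
        BI[idx] = bi_;
      } else {
        BD[idx] = NEG_INF; // D_M cannot reach an exit-from-match
        BI[idx] = NEG_INF;
      }
      BM[idx] = bm;
    }
  }
  double Zb = NEG_INF;
  for (int i = 1; i <= L; ++i) {
    const int x = seq[i - 1];
    for (int j = 1; j <= M; ++j)
      Zb = lse(Zb, entry[j - 1] + emit(mlo, j - 1, x) + BM[i * M + (j - 1)]);
  }
  NumericVector post(M);
  for (int j = 1; j <= M; ++j) {
    double p = NEG_INF;
    for (int i = 1; i <= L; ++i)
      p = lse(p, FM[i * M + (j - 1)] + BM[i * M + (j - 1)]);
    post[j - 1] = (p <= NEG_INF) ? 0.0 : std::exp(p - Zf);
    if (post[j - 1] > 1.0) post[j - 1] = 1.0;
  }
  return List::create(_["logZ_forward"] = Zf, _["logZ_backward"] = Zb,
                      _["posteriors"] = post);
}

// Order-k Markov chain sampler over an integer alphabet of size a,
// using R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".sample_markov")]]
IntegerVector sample_markov(int n, int k, int a, NumericMatrix trans,
                            NumericVector init) {
  IntegerVector out(n);
  if (n == 0) return out;
  // initial k-mer from init distribution over a^k states
  double u = R::runif(0, 1), acc = 0;
  int state = 0;
  for (int s = 0; s < init.size(); ++s) {
    acc += init[s];
    if (u <= acc) { state = s; break; }
    if (s == init.size() - 1) state = s;
  }
  // decode k-mer (most-significant first)
  std::vector<int> ctx(k);
  int tmp = state;
  for (int p = k - 1; p >= 0; --p) { ctx[p] = tmp % a; tmp /= a; }
  for (int p = 0; p < k && p < n; ++p) out[p] = ctx[p];
  for (int i = k; i < n; ++i) {
    // context index
    int s = 0;
    for (int p = 0; p < k; ++p) s = s * a + out[i - k + p];
    double u2 = R::runif(0, 1), a2 = 0;
    int nxt = a - 1;
    for (int c = 0; c < a; ++c) {
      a2 += trans(s, c);
      if (u2 <= a2) { nxt = c; break; }
    }
    out[i] = nxt;
  }
  return out;
}
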