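#include <Rcpp.h>
using namespace Rcpp;

// Residue coding shared with R: 0 = gap, 1..20 = amino acids in the order
// "ACDEFGHIKLMNPQRSTVWY", 21 = X (unknown; scored at background, log-odds 0).

// Transition type order shared with R:
// 0 MM, 1 MI, 2 MD, 3 IM, 4 II, 5 ID, 6 DM, 7 DD, 8 DI
// Row k of the transition matrix holds the outgoing transitions of M_k, I_k,
// D_k; row 0 is the begin state (B = M_0).

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + log1p(exp(-fabs(a - b)));
}

static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

// Position-based (Henikoff) sequence weights plus weighted emission and
// transition counts for one row subset of an alignment, over a fixed
// match-column mask. X residues occupy states but add no emission counts.
// [[Rcpp::export]]
List cpp_hmm_counts(IntegerMatrix sub, LogicalVector match_mask) {
  int n = sub.nrow(), C = sub.ncol();
  int K = 0;
  for (int j = 0; j < C; ++j) if (match_mask[j]) ++K;

  // Henikoff weights over all columns, gap/X cells contribute nothing
  NumericVector w(n, 0.0);
  std::vector<int> colcount(21);
  for (int j = 0; j < C; ++j) {
    std::fill(colcount.begin(), colcount.end(), 0);
    int ndistinct = 0;
    for (int i = 0; i < n; ++i) {
      int a = sub(i, j);
      if (a >= 1 && a <= 20) {
        if (colcount[a] == 0) ++ndistinct;
        ++colcount[a];
      }
    }
    if (ndistinct == 0) continue;
    for (int i = 0; i < n; ++i) {
      int a = sub(i, j);
      if (a >= 1 && a <= 20)
        w[i] += 1.0 / ((double)ndistinct * (double)colcount[a]);
    }
  }
  double tot = 0.0;
  for (int i = 0; i < n; ++i) tot += w[i];
  if (tot <= 0) { for (int i = 0; i < n; ++i) w[i] = 1.0 / n; }
  else          { for (int i = 0; i < n; ++i) w[i] /= tot; }

  NumericMatrix em(K, 20);          // weighted residue counts per match state
  NumericMatrix tr(K + 1, 9);       // weighted transition counts

  for (int i = 0; i < n; ++i) {
    int prev_state = 0;             // 0 = M (begin), 1 = I, 2 = D
    int prev_k = 0;
    int k = 0;
    for (int j = 0; j < C; ++j) {
      int a = sub(i, j);
      if (match_mask[j]) {
        ++k;
        int st = (a >= 1) ? 0 : 2;  // residue -> M, gap -> D
        if (a >= 1 && a <= 20) em(k - 1, a - 1) += w[i];
        tr(prev_k, prev_state * 3 + st) += w[i];
        prev_state = st; prev_k = k;
      } else if (a >= 1) {          // residue in insert column -> I_k
        if (prev_state == 1 && prev_k == k) {
          tr(prev_k, 4) += w[i];    // I -> I
        } else {
          tr(prev_k, prev_state * 3 + 1) += w[i];
        }
        prev_state = 1; prev_k = k;
      }
    }
    // exit to end state, recorded as *->M at row K
    tr(K, prev_state * 3 + 0) += w[i];
  }

  return List::create(_["weights"] = w, _["em_counts"] = em,
                      _["trans_counts"] = tr);
}

// Forward + Viterbi over a Plan7-style match/insert/delete chain in log-odds
// space (natural log). em: K x 21 match emission log-odds (column 21, for X,
// must be 0). ltr: (K+1) x 9 log transition probabilities. Insert emissions
// are the background (log-odds 0). mode 0 = glocal (model-global, free query
// flanks), mode 1 = local (uniform entry/exit over match states).
// Insert states I_0 and I_K are folded into the free flanks and not scored.
// [[Rcpp::export]]
List cpp_hmm_score(NumericMatrix em, NumericMatrix ltr, IntegerVector seq,
                   int mode) {
  int K = em.nrow();
  int L = seq.size();
  const double NEG = R_NegInf;
  double lent = -log((double)K);    // local entry/exit log prob

  NumericMatrix VM(K + 1, L + 1), VI(K + 1, L + 1), VD(K + 1, L + 1);
  NumericMatrix WM(K + 1, L + 1), WI(K + 1, L + 1), WD(K + 1, L + 1);
  IntegerMatrix PM(K + 1, L + 1), PI(K + 1, L + 1), PD(K + 1, L + 1);
  // pointer codes: 0 from M, 1 from I, 2 from D, 3 entry (B/local start)

  for (int i = 0; i <= L; ++i) {
    VM(0, i) = (mode == 0) ? 0.0 : NEG;  // row 0 is B in glocal mode
    WM(0, i) = VM(0, i);
    VI(0, i) = NEG; WI(0, i) = NEG;
    VD(0, i) = NEG; WD(0, i) = NEG;
  }

  for (int k = 1; k <= K; ++k) {
    for (int i = 0; i <= L; ++i) {
      // match
      if (i >= 1) {
        double e = em(k - 1, seq[i - 1] - 1);
        double aM = VM(k - 1, i - 1) + ltr(k - 1, 0);
        double aI = VI(k - 1, i - 1) + ltr(k - 1, 3);
        double aD = VD(k - 1, i - 1) + ltr(k - 1, 6);
        double f = lse3(aM, aI, aD);
        double bM = WM(k - 1, i - 1) + ltr(k - 1, 0);
        double bI = WI(k - 1, i - 1) + ltr(k - 1, 3);
        double bD = WD(k - 1, i - 1) + ltr(k - 1, 6);
        double v = bM; int p = 0;
        if (bI > v) { v = bI; p = 1; }
        if (bD > v) { v = bD; p = 2; }
        if (mode == 1) {            // fresh local entry
          f = lse2(f, lent);
          if (lent >= v) { v = lent; p = 3; }
        }
        VM(k, i) = e + f; WM(k, i) = e + v; PM(k, i) = p;
      } else { VM(k, i) = NEG; WM(k, i) = NEG; }
      // delete
      {
        double aM = VM(k - 1, i) + ltr(k - 1, 2);
        double aI = VI(k - 1, i) + ltr(k - 1, 5);
        double aD = VD(k - 1, i) + ltr(k - 1, 7);
        VD(k, i) = lse3(aM, aI, aD);
        double bM = WM(k - 1, i) + ltr(k - 1, 2);
        double bI = WI(k - 1, i) + ltr(k - 1, 5);
        double bD = WD(k - 1, i) + ltr(k - 1, 7);
        double v = bM; int p = 0;
        if (bI > v) { v = bI; p = 1; }
        if (bD > v) { v = bD; p = 2; }
        WD(k, i) = v; PD(k, i) = p;
      }
      // insert (internal only)
      if (k >= 1 && k <= K - 1 && i >= 1) {
        double aM = VM(k, i - 1) + ltr(k, 1);
        double aI = VI(k, i - 1) + ltr(k, 4);
        double aD = VD(k, i - 1) + ltr(k, 8);
        VI(k, i) = lse3(aM, aI, aD);
        double bM = WM(k, i - 1) + ltr(k, 1);
        double bI = WI(k, i - 1) + ltr(k, 4);
        double bD = WD(k, i - 1) + ltr(k, 8);
        double v = bM; int p = 0;
        if (bI > v) { v = bI; p = 1; }
        if (bD > v) { v = bD; p = 2; }
        WI(k, i) = v; PI(k, i) = p;
      } else { VI(k, i) = NEG; WI(k, i) = NEG; }
    }
  }

  double fwd = NEG, vit = NEG;
  int end_k = -1, end_i = -1, end_state = 0;
  if (mode == 0) {
    for (int i = 0; i <= L; ++i) {
      fwd = lse2(fwd, VM(K, i) + ltr(K, 0));
      fwd = lse2(fwd, VD(K, i) + ltr(K, 6));
      double m = WM(K, i) + ltr(K, 0);
      double d = WD(K, i) + ltr(K, 6);
      if (m > vit) { vit = m; end_k = K; end_i = i; end_state = 0; }
      if (d > vit) { vit = d; end_k = K; end_i = i; end_state = 2; }
    }
  } else {
    for (int k = 1; k <= K; ++k)
      for (int i = 1; i <= L; ++i) {
        fwd = lse2(fwd, VM(k, i) + lent);
        double m = WM(k, i) + lent;
        if (m > vit) { vit = m; end_k = k; end_i = i; end_state = 0; }
      }
  }

  // Viterbi traceback for query/model spans over match states; also collect
  // the (query position, match state) pairs of the optimal path.
  int qs = 0, qe = 0, ks = 0, ke = 0;
  std::vector<int> path_q, path_k;
  if (vit != R_NegInf && end_k > 0) {
    int k = end_k, i = end_i, st = end_state;
    while (k > 0) {
      int p;
      if (st == 0) {
        if (i < 1) break;
        if (qe == 0) { qe = i; ke = k; }
        qs = i; ks = k;
        path_q.push_back(i); path_k.push_back(k);
        p = PM(k, i);
        if (p == 3) break;          // local entry
        --k; --i;
      } else if (st == 1) {
        p = PI(k, i);
        --i;
      } else {
        p = PD(k, i);
        --k;
      }
      st = p;
      if (k == 0) break;
    }
  }
  std::reverse(path_q.begin(), path_q.end());
  std::reverse(path_k.begin(), path_k.end());

  return List::create(_["fwd"] = fwd, _["vit"] = vit,
                      _["qstart"] = qs, _["qend"] = qe,
                      _["kstart"] = ks, _["kend"] = ke,
                      _["match_q"] = wrap(path_q), _["match_k"] = wrap(path_k));
}

// Forward log-odds only (no Viterbi, no traceback); same path semantics as
// cpp_hmm_score. Used for the exhaustive node scans and E-value calibration.
// [[Rcpp::export]]
double cpp_forward_only(NumericMatrix em, NumericMatrix ltr, IntegerVector seq,
                        int mode) {
  int K = em.nrow();
  int L = seq.size();
  const double NEG = R_NegInf;
  double lent = -log((double)K);

  std::vector<double> M0(L + 1), I0(L + 1), D0(L + 1);
  std::vector<double> M1(L + 1), I1(L + 1), D1(L + 1);
  for (int i = 0; i <= L; ++i) {
    M0[i] = (mode == 0) ? 0.0 : NEG;
    I0[i] = NEG; D0[i] = NEG;
  }
  double fwd = NEG;
  for (int k = 1; k <= K; ++k) {
    const double tMM = ltr(k - 1, 0), tMI = ltr(k - 1, 1), tMD = ltr(k - 1, 2);
    const double tIM = ltr(k - 1, 3), tID = ltr(k - 1, 5);
    const double tDM = ltr(k - 1, 6), tDD = ltr(k - 1, 7);
    const double uMI = ltr(k, 1), uII = ltr(k, 4), uDI = ltr(k, 8);
    bool has_insert = (k >= 1 && k <= K - 1);
    M1[0] = NEG; I1[0] = NEG;
    D1[0] = lse3(M0[0] + tMD, I0[0] + tID, D0[0] + tDD);
    for (int i = 1; i <= L; ++i) {
      double e = em(k - 1, seq[i - 1] - 1);
      double f = lse3(M0[i - 1] + tMM, I0[i - 1] + tIM, D0[i - 1] + tDM);
      if (mode == 1) f = lse2(f, lent);
      M1[i] = e + f;
      D1[i] = lse3(M0[i] + tMD, I0[i] + tID, D0[i] + tDD);
      I1[i] = has_insert ?
        lse3(M1[i - 1] + uMI, I1[i - 1] + uII, D1[i - 1] + uDI) : NEG;
    }
    if (mode == 1) {
      for (int i = 1; i <= L; ++i) fwd = lse2(fwd, M1[i] + lent);
    }
    std::swap(M0, M1); std::swap(I0, I1); std::swap(D0, D1);
    (void)tMI;
  }
  if (mode == 0) {
    const double tME = ltr(K, 0), tDE = ltr(K, 6);
    for (int i = 0; i <= L; ++i) {
      fwd = lse2(fwd, M0[i] + tME);
      fwd = lse2(fwd, D0[i] + tDE);
    }
  }
  return fwd;
}

// Batch forward bit scores for calibration: seqs is a list of integer vectors.
// [[Rcpp::export]]
NumericVector cpp_forward_batch(NumericMatrix em, NumericMatrix ltr, List seqs,
                                int mode) {
  int n = seqs.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i];
    out[i] = cpp_forward_only(em, ltr, s, mode);
  }
  return out;
}
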