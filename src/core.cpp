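#include <Rcpp.h>
using namespace Rcpp;

// Window log-odds scores for an integer-encoded sequence (0..3; negative = N).
// lodds is 4 x w. Windows containing N get NA.
// [[Rcpp::export]]
NumericVector cpp_scan_scores(IntegerVector seq, NumericMatrix lodds) {
  int L = seq.size(), w = lodds.ncol();
  int n = L - w + 1;
  if (n < 1) return NumericVector(0);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    bool bad = false;
    for (int j = 0; j < w; ++j) {
      int b = seq[i + j];
      if (b < 0 || b > 3) { bad = true; break; }
      s += lodds(b, j);
    }
    out[i] = bad ? NA_REAL : s;
  }
  return out;
}

static double best_overlap_stat(const NumericMatrix& C, int min_ov,
                                int* best_off, bool* any) {
  int wa = C.nrow(), wb = C.ncol();
  double best = R_NegInf;
  *any = false;
  for (int o = -(wb - min_ov); o <= wa - min_ov; ++o) {
    int i0 = std::max(0, o), i1 = std::min(wa - 1, wb - 1 + o);
    int len = i1 - i0 + 1;
    if (len < min_ov) continue;
    double s = 0.0;
    for (int i = i0; i <= i1; ++i) s += C(i, i - o);
    s /= len;
    if (s > best) { best = s; *best_off = o; *any = true; }
  }
  return best;
}

// Best ungapped-overlap statistic over offsets for one orientation.
// C[i,j] = per-column Pearson correlation between column i of a and column j of b.
// [[Rcpp::export]]
List cpp_best_overlap(NumericMatrix C, int min_ov) {
  int off = 0; bool any = false;
  double s = best_overlap_stat(C, min_ov, &off, &any);
  return List::create(_["stat"] = any ? s : NA_REAL, _["offset"] = off);
}

// Column-shuffle null for the PSSM comparison statistic. perms is n x wb
// (1-based permutations of b's columns). Cf/Cr are the forward and
// reverse-complement column-correlation matrices. Shuffling b's columns
// permutes Cf's columns directly; Cr's columns are remapped because
// revcomp(b) column j corresponds to b column wb-1-j.
// [[Rcpp::export]]
NumericVector cpp_pair_null(NumericMatrix Cf, NumericMatrix Cr,
                            IntegerMatrix perms, int min_ov) {
  int n = perms.nrow(), wa = Cf.nrow(), wb = Cf.ncol();
  NumericVector out(n);
  NumericMatrix Sf(wa, wb), Sr(wa, wb);
  for (int t = 0; t < n; ++t) {
    for (int j = 0; j < wb; ++j) {
      int pj = perms(t, j) - 1;            // shuffled b col j = original col pj
      for (int i = 0; i < wa; ++i) Sf(i, j) = Cf(i, pj);
    }
    for (int j = 0; j < wb; ++j) {
      int m = perms(t, wb - 1 - j) - 1;    // original col aligned at revcomp pos j
      int k = wb - 1 - m;                  // its column index within Cr
      for (int i = 0; i < wa; ++i) Sr(i, j) = Cr(i, k);
    }
    int off; bool anyf = false, anyr = false;
    double sf = best_overlap_stat(Sf, min_ov, &off, &anyf);
    double sr = best_overlap_stat(Sr, min_ov, &off, &anyr);
    double s = R_NegInf;
    if (anyf) s = sf;
    if (anyr && sr > s) s = sr;
    out[t] = s;
  }
  return out;
}

struct BicState {
  int k, m;
  std::vector<char> g, c;       // active flags
  std::vector<double> s, ss;    // per-gene sums over active conditions
  std::vector<double> sp;       // per-pair cross sums (upper triangle)
  int ng, nc;
};

static inline int pidx(int i, int j, int k) { // i<j
  return i * k - i * (i + 1) / 2 + (j - i - 1);
}

static double bic_score(const BicState& st) {
  if (st.ng < 2 || st.nc < 2) return NA_REAL;
  double tot = 0.0; int np = 0;
  for (int i = 0; i < st.k; ++i) {
    if (!st.g[i]) continue;
    for (int j = i + 1; j < st.k; ++j) {
      if (!st.g[j]) continue;
      double n = st.nc;
      double num = n * st.sp[pidx(i, j, st.k)] - st.s[i] * st.s[j];
      double di = n * st.ss[i] - st.s[i] * st.s[i];
      double dj = n * st.ss[j] - st.s[j] * st.s[j];
      double den = std::sqrt(di * dj);
      double r = (den > 1e-12) ? num / den : 0.0;
      tot += std::fabs(r); ++np;
    }
  }
  return np > 0 ? tot / np : NA_REAL;
}

static void bic_init(BicState& st, const NumericMatrix& X,
                     const std::vector<char>& g, const std::vector<char>& c) {
  st.k = X.nrow(); st.m = X.ncol(); st.g = g; st.c = c;
  st.ng = 0; st.nc = 0;
  for (int i = 0; i < st.k; ++i) if (g[i]) ++st.ng;
  for (int t = 0; t < st.m; ++t) if (c[t]) ++st.nc;
  st.s.assign(st.k, 0.0); st.ss.assign(st.k, 0.0);
  st.sp.assign(st.k * (st.k - 1) / 2, 0.0);
  for (int t = 0; t < st.m; ++t) {
    if (!c[t]) continue;
    for (int i = 0; i < st.k; ++i) {
      double xi = X(i, t);
      st.s[i] += xi; st.ss[i] += xi * xi;
      for (int j = i + 1; j < st.k; ++j) st.sp[pidx(i, j, st.k)] += xi * X(j, t);
    }
  }
}

static void bic_drop_cond(BicState& st, const NumericMatrix& X, int t) {
  for (int i = 0; i < st.k; ++i) {
    if (!st.g[i]) continue;
    double xi = X(i, t);
    st.s[i] -= xi; st.ss[i] -= xi * xi;
    for (int j = i + 1; j < st.k; ++j)
      if (st.g[j]) st.sp[pidx(i, j, st.k)] -= xi * X(j, t);
  }
  st.c[t] = 0; --st.nc;
}

static void bic_drop_gene(BicState& st, int i) {
  st.g[i] = 0; --st.ng;
  // pair sums involving i become irrelevant (score loops skip inactive genes)
}

// Greedy alternating bicluster refinement of a gene x condition matrix
// (rows standardized and sign-aligned upstream). Starting from all
// rows/columns, alternately drops the gene least correlated with the others
// (when that improves the mean pairwise |correlation| by > 10 * min_gain)
// and, among conditions whose variance contribution is at least var_protect
// times the average (low-variance conditions carry weak but genuine signal
// and are protected), the condition whose exclusion most improves the score
// (when the gain exceeds min_gain).
// [[Rcpp::export]]
List cpp_refine_bicluster(NumericMatrix X, int min_genes, int min_conds,
                          double min_gain, double var_protect) {
  int k = X.nrow(), m = X.ncol();
  std::vector<char> g(k, 1), c(m, 1);
  BicState st;
  bic_init(st, X, g, c);
  double cur = bic_score(st);
  bool improved = true;
  while (improved) {
    improved = false;
    // gene step: prune the least coherent gene when its mean |cor| to the
    // others falls clearly below the set's level (unrelated genes sit near
    // zero; genuine members track the set) and pruning improves the score
    if (st.ng > min_genes && st.ng > 2) {
      int worst = -1; double worstv = R_PosInf;
      double sumv = 0.0; int nv = 0;
      for (int i = 0; i < k; ++i) {
        if (!st.g[i]) continue;
        double tot = 0.0; int np = 0;
        for (int j = 0; j < k; ++j) {
          if (j == i || !st.g[j]) continue;
          int a = std::min(i, j), b = std::max(i, j);
          double n = st.nc;
          double num = n * st.sp[pidx(a, b, k)] - st.s[a] * st.s[b];
          double da = n * st.ss[a] - st.s[a] * st.s[a];
          double db = n * st.ss[b] - st.s[b] * st.s[b];
          double den = std::sqrt(da * db);
          tot += std::fabs(den > 1e-12 ? num / den : 0.0); ++np;
        }
        double v = np > 0 ? tot / np : 0.0;
        sumv += v; ++nv;
        if (v < worstv) { worstv = v; worst = i; }
      }
      if (worst >= 0 && nv > 1) {
        double mbar = (sumv - worstv) / (nv - 1);
        if (worstv < 0.5 * mbar) {
          BicState trial = st;
          bic_drop_gene(trial, worst);
          double snew = bic_score(trial);
          if (!ISNA(snew) && snew > cur) {
            st = trial; cur = snew; improved = true;
          }
        }
      }
    }
    // condition step: exact leave-one-out over removable conditions
    if (st.nc > min_conds) {
      // variance contribution per active condition
      double vbar = 0.0;
      std::vector<double> vc(m, 0.0);
      for (int t = 0; t < m; ++t) {
        if (!st.c[t]) continue;
        double v = 0.0;
        for (int i = 0; i < k; ++i)
          if (st.g[i]) v += X(i, t) * X(i, t);
        vc[t] = v; vbar += v;
      }
      vbar /= st.nc;
      int best_t = -1; double best_s = cur;
      for (int t = 0; t < m; ++t) {
        if (!st.c[t] || vc[t] < var_protect * vbar) continue;
        BicState trial = st;   // copy of sums; drop is O(k^2)
        bic_drop_cond(trial, X, t);
        double snew = bic_score(trial);
        if (!ISNA(snew) && snew > best_s) { best_s = snew; best_t = t; }
      }
      if (best_t >= 0 && best_s - cur > min_gain) {
        bic_drop_cond(st, X, best_t);
        cur = best_s; improved = true;
      }
    }
  }
  LogicalVector gk(k), ck(m);
  for (int i = 0; i < k; ++i) gk[i] = st.g[i] != 0;
  for (int t = 0; t < m; ++t) ck[t] = st.c[t] != 0;
  return List::create(_["genes"] = gk, _["conditions"] = ck, _["score"] = cur);
}

// Mean pairwise |Pearson correlation| of rows of X over all columns.
// [[Rcpp::export]]
double cpp_mean_abs_cor(NumericMatrix X) {
  int k = X.nrow(), m = X.ncol();
  if (k < 2 || m < 2) return NA_REAL;
  std::vector<double> s(k, 0.0), ss(k, 0.0);
  for (int i = 0; i < k; ++i)
    for (int t = 0; t < m; ++t) { s[i] += X(i, t); ss[i] += X(i, t) * X(i, t); }
  double tot = 0.0; int np = 0;
  for (int i = 0; i < k; ++i) {
    for (int j = i + 1; j < k; ++j) {
      double sp = 0.0;
      for (int t = 0; t < m; ++t) sp += X(i, t) * X(j, t);
      double num = m * sp - s[i] * s[j];
      double di = m * ss[i] - s[i] * s[i];
      double dj = m * ss[j] - s[j] * s[j];
      double den = std::sqrt(di * dj);
      tot += std::fabs(den > 1e-12 ? num / den : 0.0); ++np;
    }
  }
  return tot / np;
}

// Mismatch-tolerant seed support: for each candidate k-mer (rows of cand,
// values 0..3), counts in how many sequences it occurs within max_mismatch
// mismatches on either strand, plus the total number of matching windows.
// [[Rcpp::export]]
IntegerMatrix cpp_seed_support(IntegerMatrix cand, List seqs,
                               int max_mismatch) {
  int nc = cand.nrow(), w = cand.ncol(), ns = seqs.size();
  IntegerMatrix out(nc, 2);  // columns: n_sequences, n_windows
  std::vector<std::vector<int> > fwd(ns), rev(ns);
  for (int s = 0; s < ns; ++s) {
    IntegerVector v = seqs[s];
    fwd[s].assign(v.begin(), v.end());
    rev[s].resize(v.size());
    for (int i = 0; i < (int)v.size(); ++i) {
      int b = v[v.size() - 1 - i];
      rev[s][i] = (b >= 0 && b <= 3) ? 3 - b : -1;
    }
  }
  for (int c = 0; c < nc; ++c) {
    int nseq = 0, nwin = 0;
    for (int s = 0; s < ns; ++s) {
      bool found = false;
      for (int strand = 0; strand < 2; ++strand) {
        const std::vector<int>& v = strand == 0 ? fwd[s] : rev[s];
        int L = v.size() - w + 1;
        for (int i = 0; i < L; ++i) {
          int mm = 0;
          for (int j = 0; j < w; ++j) {
            if (v[i + j] != cand(c, j)) {
              if (++mm > max_mismatch) break;
            }
          }
          if (mm <= max_mismatch) { ++nwin; found = true; }
        }
      }
      if (found) ++nseq;
    }
    out(c, 0) = nseq; out(c, 1) = nwin;
  }
  return out;
}

// Pairwise mutual information between rows of an integer bin matrix
// (entries 0..nbins-1), in nats.
// [[Rcpp::export]]
NumericMatrix cpp_mi_matrix(IntegerMatrix B, int nbins) {
  int k = B.nrow(), m = B.ncol();
  NumericMatrix out(k, k);
  std::vector<int> joint(nbins * nbins);
  std::vector<int> mi_(nbins), mj_(nbins);
  for (int i = 0; i < k; ++i) {
    for (int j = i + 1; j < k; ++j) {
      std::fill(joint.begin(), joint.end(), 0);
      std::fill(mi_.begin(), mi_.end(), 0);
      std::fill(mj_.begin(), mj_.end(), 0);
      for (int t = 0; t < m; ++t) {
        int a = B(i, t), b = B(j, t);
        ++joint[a * nbins + b]; ++mi_[a]; ++mj_[b];
      }
      double mi = 0.0;
      for (int a = 0; a < nbins; ++a) {
        if (mi_[a] == 0) continue;
        for (int b = 0; b < nbins; ++b) {
          int c = joint[a * nbins + b];
          if (c == 0 || mj_[b] == 0) continue;
          double p = (double)c / m;
          mi += p * std::log(p * m * (double)m / ((double)mi_[a] * mj_[b]));
        }
      }
      out(i, j) = mi; out(j, i) = mi;
    }
  }
  return out;
}
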