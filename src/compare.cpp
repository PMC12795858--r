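#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pearson correlation of two base-frequency 4-vectors; 0 when either
// column has zero variance (an uninformative column carries no evidence).
static inline double col_pearson(const double* p, const double* q) {
  double mp = 0.0, mq = 0.0;
  for (int i = 0; i < 4; ++i) { mp += p[i]; mq += q[i]; }
  mp *= 0.25; mq *= 0.25;
  double sxy = 0.0, sxx = 0.0, syy = 0.0;
  for (int i = 0; i < 4; ++i) {
    double a = p[i] - mp, b = q[i] - mq;
    sxy += a * b; sxx += a * a; syy += b * b;
  }
  if (sxx <= 0.0 || syy <= 0.0) return 0.0;
  return sxy / std::sqrt(sxx * syy);
}

// reverse complement of a 4xL matrix: reverse columns, swap A<->T, C<->G
static NumericMatrix revcomp_mat(const NumericMatrix& M) {
  int L = M.ncol();
  NumericMatrix R(4, L);
  static const int rc[4] = {3, 2, 1, 0};
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < 4; ++i)
      R(rc[i], L - 1 - j) = M(i, j);
  return R;
}

// [[Rcpp::export]]
double cpp_col_pearson(NumericVector p, NumericVector q) {
  if (p.size() != 4 || q.size() != 4) stop("column vectors must have length 4");
  return col_pearson(p.begin(), q.begin());
}

// [[Rcpp::export]]
NumericMatrix cpp_score_matrix(NumericMatrix Q, NumericMatrix T) {
  int L1 = Q.ncol(), L2 = T.ncol();
  NumericMatrix S(L1, L2);
  for (int j = 0; j < L2; ++j) {
    const double* qc = &T(0, j);
    for (int i = 0; i < L1; ++i)
      S(i, j) = col_pearson(&Q(0, i), qc);
  }
  return S;
}

// Best gapless offset for one strand given the L1 x L2 column-score matrix.
// Offset d means query column i aligns with target column i - d.
static void best_offset(const NumericMatrix& S, int mo,
                        double& best, int& best_d) {
  int L1 = S.nrow(), L2 = S.ncol();
  for (int d = -(L2 - mo); d <= L1 - mo; ++d) {
    int i0 = d > 0 ? d : 0;
    int i1 = (L1 - 1 < L2 - 1 + d) ? L1 - 1 : L2 - 1 + d;
    double s = 0.0;
    for (int i = i0; i <= i1; ++i) s += S(i, i - d);
    if (s > best + 1e-12) { best = s; best_d = d; }
  }
}

// [[Rcpp::export]]
List cpp_best_alignment(NumericMatrix Q, NumericMatrix T,
                        int min_overlap, bool both_strands) {
  int L1 = Q.ncol(), L2 = T.ncol();
  if (L1 < min_overlap || L2 < min_overlap) stop("motifs too short");
  int per_strand = L1 + L2 - 2 * min_overlap + 1;
  int n_off = per_strand * (both_strands ? 2 : 1);

  double best = -1e300; int best_d = 0; int strand = 1;
  NumericMatrix Sp = cpp_score_matrix(Q, T);
  best_offset(Sp, min_overlap, best, best_d);
  if (both_strands) {
    NumericMatrix Sm = cpp_score_matrix(Q, revcomp_mat(T));
    double bm = -1e300; int dm = 0;
    best_offset(Sm, min_overlap, bm, dm);
    if (bm > best + 1e-12) { best = bm; best_d = dm; strand = -1; }
  }
  return List::create(_["raw"] = best, _["offset"] = best_d,
                      _["strand"] = strand, _["n_offsets"] = n_off);
}

// best raw over offsets of a decoy whose score rows are looked up in a
// precomputed query-column x pool-column score matrix
static double decoy_best(const NumericMatrix& CS, const NumericMatrix& CSrc,
                         const std::vector<int>& idx, int mo,
                         bool both_strands) {
  int L1 = CS.nrow(), L2 = (int)idx.size();
  double best = -1e300;
  for (int s = 0; s < (both_strands ? 2 : 1); ++s) {
    const NumericMatrix& M = (s == 0) ? CS : CSrc;
    for (int d = -(L2 - mo); d <= L1 - mo; ++d) {
      int i0 = d > 0 ? d : 0;
      int i1 = (L1 - 1 < L2 - 1 + d) ? L1 - 1 : L2 - 1 + d;
      double sum = 0.0;
      for (int i = i0; i <= i1; ++i) {
        int j = i - d;                 // decoy column position
        int c = (s == 0) ? idx[j] : idx[L2 - 1 - j];
        sum += M(i, c);
      }
      if (sum > best) best = sum;
    }
  }
  return best;
}

// Null distribution of the best-alignment raw score: n_null decoy targets of
// length target_len with columns drawn iid from the pool (R RNG).
// [[Rcpp::export]]
NumericVector cpp_null_best_raws(NumericMatrix Q, int target_len,
                                 NumericMatrix pool, int n_null,
                                 int min_overlap, bool both_strands) {
  int L1 = Q.ncol(), P = pool.ncol();
  if (P < 1) stop("empty column pool");
  if (L1 < min_overlap || target_len < min_overlap) stop("motifs too short");
  // scores of each query column against each pool column and its complement
  NumericMatrix CS(L1, P), CSrc(L1, P);
  static const int rc[4] = {3, 2, 1, 0};
  for (int c = 0; c < P; ++c) {
    double col[4], colrc[4];
    for (int i = 0; i < 4; ++i) { col[i] = pool(i, c); colrc[rc[i]] = pool(i, c); }
    for (int i = 0; i < L1; ++i) {
      CS(i, c) = col_pearson(&Q(0, i), col);
      CSrc(i, c) = col_pearson(&Q(0, i), colrc);
    }
  }
  RNGScope scope;
  NumericVector out(n_null);
  std::vector<int> idx(target_len);
  for (int r = 0; r < n_null; ++r) {
    for (int j = 0; j < target_len; ++j) {
      int k = (int)(unif_rand() * P);
      idx[j] = k >= P ? P - 1 : k;
    }
    out[r] = decoy_best(CS, CSrc, idx, min_overlap, both_strands);
  }
  return out;
}

static inline int score_bin(double s, int n_bins) {
  int b = (int)std::floor((s + 1.0) * 0.5 * n_bins);
  if (b < 0) b = 0;
  if (b >= n_bins) b = n_bins - 1;
  return b;
}

// Exact (discretized) null: per offset, the distribution of the summed
// column score when target columns are iid uniform over the pool, computed
// by convolution of per-query-column score histograms; per-offset tail
// probability at the (identically binned) observed sum; offsets combined by
// independence, p = 1 - (1 - p_min)^n_offsets.
// [[Rcpp::export]]
List cpp_dp_pvalue(NumericMatrix Q, NumericMatrix T, NumericMatrix pool,
                   int min_overlap, bool both_strands, int n_bins) {
  int L1 = Q.ncol(), L2 = T.ncol(), P = pool.ncol();
  if (P < 1) stop("empty column pool");
  if (L1 < min_overlap || L2 < min_overlap) stop("motifs too short");

  // binned score histogram of each query column against the pool
  std::vector< std::vector<double> > pmf(L1, std::vector<double>(n_bins, 0.0));
  for (int i = 0; i < L1; ++i) {
    for (int c = 0; c < P; ++c)
      pmf[i][score_bin(col_pearson(&Q(0, i), &pool(0, c)), n_bins)] += 1.0;
    for (int b = 0; b < n_bins; ++b) pmf[i][b] /= (double)P;
  }

  NumericMatrix Tm[2];
  Tm[0] = T;
  if (both_strands) Tm[1] = revcomp_mat(T);

  int per_strand = L1 + L2 - 2 * min_overlap + 1;
  int n_off = per_strand * (both_strands ? 2 : 1);
  double p_min = 1.0, best_raw = -1e300;
  int best_d = 0, best_strand = 1;

  for (int s = 0; s < (both_strands ? 2 : 1); ++s) {
    for (int d = -(L2 - min_overlap); d <= L1 - min_overlap; ++d) {
      int i0 = d > 0 ? d : 0;
      int i1 = (L1 - 1 < L2 - 1 + d) ? L1 - 1 : L2 - 1 + d;
      // observed: continuous raw for reporting, binned sum for the tail
      double raw = 0.0; long obs_bins = 0;
      for (int i = i0; i <= i1; ++i) {
        double sc = col_pearson(&Q(0, i), &Tm[s](0, i - d));
        raw += sc;
        obs_bins += score_bin(sc, n_bins);
      }
      if (raw > best_raw + 1e-12) {
        best_raw = raw; best_d = d; best_strand = (s == 0) ? 1 : -1;
      }
      // convolve the histograms of the overlapping query columns
      std::vector<double> cur(1, 1.0);
      for (int i = i0; i <= i1; ++i) {
        std::vector<double> nxt(cur.size() + n_bins - 1, 0.0);
        for (size_t k = 0; k < cur.size(); ++k) {
          if (cur[k] == 0.0) continue;
          for (int b = 0; b < n_bins; ++b)
            nxt[k + b] += cur[k] * pmf[i][b];
        }
        cur.swap(nxt);
      }
      double tail = 0.0;
      for (size_t k = (obs_bins < 0 ? 0 : (size_t)obs_bins); k < cur.size(); ++k)
        tail += cur[k];
      if (tail < p_min) p_min = tail;
    }
  }
  double p;
  if (p_min <= 0.0) p = 0.0;
  else p = -std::expm1((double)n_off * std::log1p(-p_min));
  if (p < 1e-300) p = 1e-300;
  if (p > 1.0) p = 1.0;
  return List::create(_["p_value"] = p, _["p_min"] = p_min,
                      _["n_offsets"] = n_off, _["raw"] = best_raw,
                      _["offset"] = best_d, _["strand"] = best_strand);
}
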