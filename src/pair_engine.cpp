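// Permutation engine for the ensemble co-occurrence network.
//
// For every OTU pair it evaluates the five association measures on the
// observed data and on a shared set of sample-order permutations, returning
// observed scores, permutation p-values (two-sided around the null mean),
// null means, and the empirical covariance of the -2*log pseudo p-value
// statistics needed by Brown's combination. All randomness (the permutation
// matrix) is generated in R, so results are reproducible from R seeds.
//
// Measure definitions mirror the R functions pair_pearson/pair_spearman/
// pair_bray_curtis/pair_kl/pair_mutual_info exactly (tested for agreement).

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int NM = 5; // pearson, spearman, bray, kl, mi

// equal-frequency bin codes with tie-collapsing quantile breaks: break
// points at sorted positions t*n/bins, and equal values always share a bin
// (all zeros of a count vector fall in one bin; a constant vector
// collapses to a single bin)
static void ef_codes(const double* x, int n, int bins, int* code) {
  std::vector<double> s(x, x + n);
  std::sort(s.begin(), s.end());
  std::vector<double> brk;
  for (int t = 1; t < bins; ++t)
    brk.push_back(s[(int)(((long long)t * n) / bins)]);
  for (int k = 0; k < n; ++k) {
    int c = 0;
    for (size_t t = 0; t < brk.size(); ++t) if (x[k] >= brk[t]) ++c;
    code[k] = c;
  }
}

// mid-ranks
static void mid_ranks(const double* x, int n, double* r) {
  std::vector<int> idx(n);
  for (int k = 0; k < n; ++k) idx[k] = k;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  int k = 0;
  while (k < n) {
    int j = k;
    while (j + 1 < n && x[idx[j + 1]] == x[idx[k]]) ++j;
    double avg = 0.5 * (k + j) + 1.0;
    for (int t = k; t <= j; ++t) r[idx[t]] = avg;
    k = j + 1;
  }
}

// center and scale to unit sum of squares; returns false if constant
static bool center_norm(const double* x, int n, double* out) {
  double m = 0;
  for (int k = 0; k < n; ++k) m += x[k];
  m /= n;
  double ss = 0;
  for (int k = 0; k < n; ++k) { out[k] = x[k] - m; ss += out[k] * out[k]; }
  if (ss <= 0) return false;
  double s = std::sqrt(ss);
  for (int k = 0; k < n; ++k) out[k] /= s;
  return true;
}

struct RowPre {
  std::vector<double> xs, rs, q, lq, raw;
  std::vector<int> code;
  double rowsum;
  bool cst;
};

static void prep_row(const double* x, int n, int bins, double pc, RowPre& R) {
  R.raw.assign(x, x + n);
  R.xs.resize(n); R.rs.resize(n); R.q.resize(n); R.lq.resize(n);
  R.code.resize(n);
  R.cst = !center_norm(x, n, R.xs.data());
  std::vector<double> rk(n);
  mid_ranks(x, n, rk.data());
  center_norm(rk.data(), n, R.rs.data()); // constant iff x constant
  R.rowsum = 0;
  double qs = 0;
  for (int k = 0; k < n; ++k) { R.rowsum += x[k]; qs += x[k] + pc; }
  for (int k = 0; k < n; ++k) {
    R.q[k] = (x[k] + pc) / qs;
    R.lq[k] = std::log(R.q[k]);
  }
  ef_codes(x, n, bins, R.code.data());
}

// the five measures for pair (a, b) with b's samples reordered by idx
// (idx = NULL means identity); NA for undefined correlations
static void measures5(const RowPre& A, const RowPre& B, const int* idx,
                      int n, int bins, double* out,
                      std::vector<int>& joint) {
  double pe = 0, sp = 0, bcn = 0, kl = 0;
  std::fill(joint.begin(), joint.end(), 0);
  for (int k = 0; k < n; ++k) {
    int kk = idx ? idx[k] : k;
    pe += A.xs[k] * B.xs[kk];
    sp += A.rs[k] * B.rs[kk];
    bcn += std::fabs(A.raw[k] - B.raw[kk]);
    kl += (A.q[k] - B.q[kk]) * (A.lq[k] - B.lq[kk]);
    joint[A.code[k] * bins + B.code[kk]]++;
  }
  bool cst = A.cst || B.cst;
  out[0] = cst ? NA_REAL : pe;
  out[1] = cst ? NA_REAL : sp;
  out[2] = bcn / (A.rowsum + B.rowsum);
  out[3] = kl;
  // MI from the joint table
  std::vector<double> rm(bins, 0.0), cm(bins, 0.0);
  for (int a = 0; a < bins; ++a)
    for (int b = 0; b < bins; ++b) {
      rm[a] += joint[a * bins + b];
      cm[b] += joint[a * bins + b];
    }
  double mi = 0;
  for (int a = 0; a < bins; ++a)
    for (int b = 0; b < bins; ++b) {
      double c = joint[a * bins + b];
      if (c > 0) mi += (c / n) * std::log(c * n / (rm[a] * cm[b]));
    }
  out[4] = mi;
}

// [[Rcpp::export]]
List cpp_pair_engine(NumericMatrix X, IntegerMatrix perms, int bins,
                     double pseudocount) {
  const int p = X.nrow(), n = X.ncol(), B = perms.nrow();
  if (p < 2) stop("need at least two OTUs");
  if (perms.ncol() != n) stop("permutation matrix has wrong width");
  std::vector<RowPre> pre(p);
  std::vector<double> row(n);
  for (int i = 0; i < p; ++i) {
    for (int k = 0; k < n; ++k) row[k] = X(i, k);
    prep_row(row.data(), n, bins, pseudocount, pre[i]);
  }
  // 0-based permutation indices, row-major
  std::vector<int> P((size_t)B * n);
  for (int b = 0; b < B; ++b)
    for (int k = 0; k < n; ++k) P[(size_t)b * n + k] = perms(b, k) - 1;

  const int npairs = p * (p - 1) / 2;
  IntegerVector ia(npairs), ib(npairs);
  NumericMatrix obs(npairs, NM), pval(npairs, NM), nullmean(npairs, NM);
  NumericMatrix nullsd(npairs, NM);
  NumericMatrix cov15(npairs, NM * (NM + 1) / 2);
  // pooled standardized-null histogram per measure (z = |s - mean|/sd in
  // bins of 0.01 up to 20, final bin = overflow) for the pooled p-values
  const int NZ = 2001;
  const double ZW = 0.01;
  NumericMatrix zhist(NZ, NM);

  std::vector<int> joint((size_t)bins * bins);
  std::vector<double> nul((size_t)B * NM), ob(NM), e(B), es(B), tstat((size_t)B * NM);
  int pair = 0;
  for (int i = 0; i < p - 1; ++i) {
    for (int j = i + 1; j < p; ++j, ++pair) {
      if ((pair & 255) == 0) Rcpp::checkUserInterrupt();
      ia[pair] = i + 1; ib[pair] = j + 1;
      measures5(pre[i], pre[j], nullptr, n, bins, ob.data(), joint);
      for (int b = 0; b < B; ++b)
        measures5(pre[i], pre[j], &P[(size_t)b * n], n, bins,
                  &nul[(size_t)b * NM], joint);
      bool defm[NM];
      for (int m = 0; m < NM; ++m) {
        defm[m] = !ISNA(ob[m]);
        obs(pair, m) = ob[m];
        if (!defm[m]) {
          pval(pair, m) = NA_REAL; nullmean(pair, m) = NA_REAL;
          nullsd(pair, m) = NA_REAL;
          for (int b = 0; b < B; ++b) tstat[(size_t)b * NM + m] = NA_REAL;
          continue;
        }
        double nm = 0;
        for (int b = 0; b < B; ++b) nm += nul[(size_t)b * NM + m];
        nm /= B;
        nullmean(pair, m) = nm;
        double eobs = std::fabs(ob[m] - nm);
        int cnt = 0;
        double ss = 0;
        for (int b = 0; b < B; ++b) {
          e[b] = std::fabs(nul[(size_t)b * NM + m] - nm);
          ss += e[b] * e[b];
          if (e[b] >= eobs) ++cnt;
        }
        nullsd(pair, m) = (B > 1) ? std::sqrt(ss / (B - 1)) : NA_REAL;
        pval(pair, m) = (1.0 + cnt) / (B + 1.0);
        if (nullsd(pair, m) > 0) {
          for (int b = 0; b < B; ++b) {
            int zb = (int)(e[b] / nullsd(pair, m) / ZW);
            if (zb >= NZ) zb = NZ - 1;
            zhist(zb, m) += 1.0;
          }
        }
        // pseudo p of each replicate: descending-rank of its extremeness
        std::copy(e.begin(), e.end(), es.begin());
        std::sort(es.begin(), es.end());
        for (int b = 0; b < B; ++b) {
          int nless = (int)(std::lower_bound(es.begin(), es.end(), e[b]) -
                            es.begin());
          double pb = (double)(B - nless) / B;
          tstat[(size_t)b * NM + m] = -2.0 * std::log(pb);
        }
      }
      // covariance of the -2 log pseudo-p statistics, diagonal scaled to 4
      double mean_t[NM], var_t[NM];
      for (int m = 0; m < NM; ++m) {
        if (!defm[m]) continue;
        double s = 0;
        for (int b = 0; b < B; ++b) s += tstat[(size_t)b * NM + m];
        mean_t[m] = s / B;
        double v = 0;
        for (int b = 0; b < B; ++b) {
          double d = tstat[(size_t)b * NM + m] - mean_t[m];
          v += d * d;
        }
        var_t[m] = v / (B - 1);
      }
      int c = 0;
      for (int m1 = 0; m1 < NM; ++m1)
        for (int m2 = m1; m2 < NM; ++m2, ++c) {
          if (!defm[m1] || !defm[m2]) { cov15(pair, c) = NA_REAL; continue; }
          if (m1 == m2) { cov15(pair, c) = 4.0; continue; }
          if (var_t[m1] <= 0 || var_t[m2] <= 0) { cov15(pair, c) = 0.0; continue; }
          double cv = 0;
          for (int b = 0; b < B; ++b)
            cv += (tstat[(size_t)b * NM + m1] - mean_t[m1]) *
                  (tstat[(size_t)b * NM + m2] - mean_t[m2]);
          cv /= (B - 1);
          cov15(pair, c) = 4.0 * cv / std::sqrt(var_t[m1] * var_t[m2]);
        }
    }
  }
  return List::create(_["i"] = ia, _["j"] = ib, _["obs"] = obs,
                      _["pval"] = pval, _["null_mean"] = nullmean,
                      _["null_sd"] = nullsd, _["cov"] = cov15,
                      _["zhist"] = zhist, _["zhist_width"] = ZW);
}

// [[Rcpp::export]]
NumericMatrix cpp_null_scores(NumericVector x, NumericVector y,
                              IntegerMatrix perms, int bins,
                              double pseudocount) {
  const int n = x.size(), B = perms.nrow();
  if (y.size() != n || perms.ncol() != n) stop("length mismatch");
  RowPre A, Bp;
  prep_row(REAL(x), n, bins, pseudocount, A);
  prep_row(REAL(y), n, bins, pseudocount, Bp);
  NumericMatrix out(B, NM);
  std::vector<double> ob(NM);
  std::vector<int> joint((size_t)bins * bins), idx(n);
  for (int b = 0; b < B; ++b) {
    for (int k = 0; k < n; ++k) idx[k] = perms(b, k) - 1;
    measures5(A, Bp, idx.data(), n, bins, ob.data(), joint);
    for (int m = 0; m < NM; ++m) out(b, m) = ob[m];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_boot_scores(NumericVector x, NumericVector y,
                              IntegerMatrix boots, int bins,
                              double pseudocount) {
  const int n = x.size(), R = boots.nrow();
  if (y.size() != n || boots.ncol() != n) stop("length mismatch");
  NumericMatrix out(R, NM);
  std::vector<double> xb(n), yb(n), ob(NM);
  std::vector<int> joint((size_t)bins * bins);
  RowPre A, Bp;
  for (int r = 0; r < R; ++r) {
    for (int k = 0; k < n; ++k) {
      int kk = boots(r, k) - 1;
      xb[k] = x[kk]; yb[k] = y[kk];
    }
    prep_row(xb.data(), n, bins, pseudocount, A);
    prep_row(yb.data(), n, bins, pseudocount, Bp);
    measures5(A, Bp, nullptr, n, bins, ob.data(), joint);
    for (int m = 0; m < NM; ++m) out(r, m) = ob[m];
  }
  return out;
}
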