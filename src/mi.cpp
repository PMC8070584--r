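#include <Rcpp.h>
using namespace Rcpp;

// Plug-in mutual information (nats) between two pre-discretised variables.
// Bins are 1..B; marginal counts are passed in so they are computed once per
// feature, and a log table over 0..n avoids repeated log() calls.
static double mi_pair(const int* a, const int* b, const int* perm, int n,
                      int B, const int* ma, const int* mb,
                      const double* logtab, int* joint) {
  const int B2 = B * B;
  std::fill(joint, joint + B2, 0);
  if (perm) {
    for (int i = 0; i < n; ++i) ++joint[(a[i] - 1) * B + (b[perm[i]] - 1)];
  } else {
    for (int i = 0; i < n; ++i) ++joint[(a[i] - 1) * B + (b[i] - 1)];
  }
  const double log_n = logtab[n];
  double mi = 0.0;
  for (int i = 0; i < B; ++i) {
    if (ma[i] == 0) continue;
    const double la = logtab[ma[i]];
    const int* row = joint + i * B;
    for (int j = 0; j < B; ++j) {
      const int c = row[j];
      if (c > 0) mi += c * (logtab[c] + log_n - la - logtab[mb[j]]);
    }
  }
  mi /= n;
  return mi > 0.0 ? mi : 0.0;  // clamp tiny negative rounding error
}

static void marginals(const IntegerMatrix& bins, int B,
                      std::vector<int>& out) {
  const int n = bins.nrow(), m = bins.ncol();
  out.assign((size_t)m * B, 0);
  for (int j = 0; j < m; ++j) {
    const int* col = &bins(0, j);
    int* mj = &out[(size_t)j * B];
    for (int i = 0; i < n; ++i) ++mj[col[i] - 1];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_mi_all(IntegerMatrix tf_bins, IntegerMatrix tg_bins,
                         int n_bins) {
  const int n = tf_bins.nrow(), ntf = tf_bins.ncol(), ntg = tg_bins.ncol();
  if (tg_bins.nrow() != n) stop("sample counts differ between bin matrices");
  std::vector<double> logtab(n + 1, 0.0);
  for (int i = 1; i <= n; ++i) logtab[i] = std::log((double)i);
  std::vector<int> mtf, mtg, joint(n_bins * n_bins);
  marginals(tf_bins, n_bins, mtf);
  marginals(tg_bins, n_bins, mtg);
  NumericMatrix out(ntf, ntg);
  for (int g = 0; g < ntg; ++g) {
    const int* bg = &tg_bins(0, g);
    const int* mg = &mtg[(size_t)g * n_bins];
    for (int t = 0; t < ntf; ++t) {
      out(t, g) = mi_pair(&tf_bins(0, t), bg, nullptr, n, n_bins,
                          &mtf[(size_t)t * n_bins], mg, logtab.data(),
                          joint.data());
    }
  }
  return out;
}

// Pooled permutation null: for each permutation (column of `perms`, 1-based
// sample indices) the MI of every (tf, target) pair is computed with the
// target's samples permuted. All draws are returned in one pool.
// [[Rcpp::export]]
NumericVector cpp_mi_null(IntegerMatrix tf_bins, IntegerMatrix tg_bins,
                          int n_bins, IntegerMatrix perms) {
  const int n = tf_bins.nrow(), ntf = tf_bins.ncol(), ntg = tg_bins.ncol();
  const int n_perm = perms.ncol();
  if (perms.nrow() != n) stop("permutation length must equal sample count");
  std::vector<double> logtab(n + 1, 0.0);
  for (int i = 1; i <= n; ++i) logtab[i] = std::log((double)i);
  std::vector<int> mtf, mtg, joint(n_bins * n_bins), pm(n);
  marginals(tf_bins, n_bins, mtf);
  marginals(tg_bins, n_bins, mtg);
  NumericVector out((R_xlen_t)n_perm * ntf * ntg);
  R_xlen_t k = 0;
  for (int p = 0; p < n_perm; ++p) {
    for (int i = 0; i < n; ++i) pm[i] = perms(i, p) - 1;
    for (int g = 0; g < ntg; ++g) {
      const int* bg = &tg_bins(0, g);
      const int* mg = &mtg[(size_t)g * n_bins];
      for (int t = 0; t < ntf; ++t) {
        out[k++] = mi_pair(&tf_bins(0, t), bg, pm.data(), n, n_bins,
                           &mtf[(size_t)t * n_bins], mg, logtab.data(),
                           joint.data());
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
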