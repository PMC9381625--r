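#include <Rcpp.h>
using namespace Rcpp;

// Plug-in mutual information in bits from two 1-based integer code vectors.
static double mi_from_codes(const int* a, const int* b, int n, int na, int nb) {
  std::vector<double> joint((size_t)na * nb, 0.0);
  std::vector<double> pa(na, 0.0), pb(nb, 0.0);
  for (int i = 0; i < n; i++) {
    joint[(size_t)(a[i] - 1) * nb + (b[i] - 1)] += 1.0;
  }
  double nn = (double)n;
  for (int i = 0; i < na; i++)
    for (int j = 0; j < nb; j++) {
      double c = joint[(size_t)i * nb + j];
      if (c > 0) { pa[i] += c; pb[j] += c; }
    }
  double mi = 0.0;
  for (int i = 0; i < na; i++) {
    if (pa[i] == 0) continue;
    for (int j = 0; j < nb; j++) {
      double c = joint[(size_t)i * nb + j];
      if (c > 0) mi += (c / nn) * std::log2((c * nn) / (pa[i] * pb[j]));
    }
  }
  return mi < 0 ? 0.0 : mi;
}

// [[Rcpp::export]]
double cpp_mi(IntegerVector a, IntegerVector b, int na, int nb) {
  if (a.size() != b.size()) stop("length mismatch");
  return mi_from_codes(a.begin(), b.begin(), a.size(), na, nb);
}

// I((X_f, X_s); Y) for every column f of X, with X_s fixed.
// X, s, y are 1-based integer codes; nlev gives levels per column of X.
// [[Rcpp::export]]
NumericVector cpp_joint_mi_all(IntegerMatrix X, IntegerVector s, IntegerVector y,
                               IntegerVector nlev, int ns, int ny) {
  int n = X.nrow(), F = X.ncol();
  if (s.size() != n || y.size() != n) stop("length mismatch");
  NumericVector out(F);
  std::vector<int> pair(n);
  for (int f = 0; f < F; f++) {
    int nf = nlev[f];
    for (int i = 0; i < n; i++) {
      pair[i] = (X(i, f) - 1) * ns + s[i];  // 1-based combined code
    }
    out[f] = mi_from_codes(pair.data(), y.begin(), n, nf * ns, ny);
  }
  return out;
}

// I(X_f; Y) for every column of X.
// [[Rcpp::export]]
NumericVector cpp_mi_all(IntegerMatrix X, IntegerVector y, IntegerVector nlev, int ny) {
  int n = X.nrow(), F = X.ncol();
  NumericVector out(F);
  std::vector<int> col(n);
  for (int f = 0; f < F; f++) {
    for (int i = 0; i < n; i++) col[i] = X(i, f);
    out[f] = mi_from_codes(col.data(), y.begin(), n, nlev[f], ny);
  }
  return out;
}
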