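#include <Rcpp.h>
using namespace Rcpp;

// Column-wise cumulative product (group Kaplan-Meier factors).
// [[Rcpp::export(name = ".col_cumprod")]]
NumericMatrix col_cumprod(NumericMatrix x) {
  int k = x.nrow(), B = x.ncol();
  NumericMatrix out(k, B);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int b = 0; b < B; ++b) {
    const double* xc = xp + (size_t)b * k;
    double* oc = op + (size_t)b * k;
    double acc = 1.0;
    for (int i = 0; i < k; ++i) {
      acc *= xc[i];
      oc[i] = acc;
    }
  }
  return out;
}

// Column-wise cumulative sum (running log-rank score increments).
// [[Rcpp::export(name = ".col_cumsum")]]
NumericMatrix col_cumsum(NumericMatrix x) {
  int k = x.nrow(), B = x.ncol();
  NumericMatrix out(k, B);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int b = 0; b < B; ++b) {
    const double* xc = xp + (size_t)b * k;
    double* oc = op + (size_t)b * k;
    double acc = 0.0;
    for (int i = 0; i < k; ++i) {
      acc += xc[i];
      oc[i] = acc;
    }
  }
  return out;
}

// Per-column group-1 at-risk (N1) and event (D1) counts at the pooled
// event times.  Subjects must be sorted by time with events first at
// ties; below[i] counts subjects strictly before event time i and
// ev_hi[i] the end of its tied-event block.
// [[Rcpp::export(name = ".group_counts")]]
List group_counts(IntegerVector below, IntegerVector ev_hi,
                  NumericMatrix G) {
  int n = G.nrow(), B = G.ncol(), k = below.size();
  NumericMatrix N1(k, B), D1(k, B);
  std::vector<double> cs(n + 1);
  const double* gp = G.begin();
  double* n1p = N1.begin();
  double* d1p = D1.begin();
  const int* bl = below.begin();
  const int* eh = ev_hi.begin();
  for (int b = 0; b < B; ++b) {
    const double* gc = gp + (size_t)b * n;
    double* n1c = n1p + (size_t)b * k;
    double* d1c = d1p + (size_t)b * k;
    cs[0] = 0.0;
    for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + gc[i];
    double tot = cs[n];
    for (int i = 0; i < k; ++i) {
      n1c[i] = tot - cs[bl[i]];
      d1c[i] = cs[eh[i]] - cs[bl[i]];
    }
  }
  return List::create(_["N1"] = N1, _["D1"] = D1);
}

// Observed labels in column 1 plus n_perm uniformly random label
// permutations (Fisher-Yates on R's RNG, so results are reproducible
// from set.seed).
// [[Rcpp::export(name = ".perm_columns")]]
NumericMatrix perm_columns(NumericVector g, int n_perm) {
  int n = g.size();
  NumericMatrix P(n, n_perm + 1);
  std::vector<double> gv(g.begin(), g.end());
  std::vector<double> work(gv);
  double* pp = P.begin();
  for (int i = 0; i < n; ++i) pp[i] = gv[i];
  for (int b = 1; b <= n_perm; ++b) {
    double* pc = pp + (size_t)b * n;
    std::copy(gv.begin(), gv.end(), work.begin());
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(work[i], work[j]);
    }
    std::copy(work.begin(), work.end(), pc);
  }
  return P;
}
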