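#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter; a[0] is assumed non-zero.
// [[Rcpp::export]]
NumericVector cpp_iir(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nw = std::max(nb, na);
  std::vector<double> bz(nw, 0.0), az(nw, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bz[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) az[i] = a[i] / a0;
  NumericVector y(n);
  const double* xp = x.begin();
  double* yp = y.begin();
  if (nw <= 16) {
    double w[16] = {0.0};
    const double* bp = bz.data();
    const double* ap = az.data();
    for (int k = 0; k < n; ++k) {
      double xi = xp[k];
      double yi = bp[0] * xi + w[0];
      for (int i = 1; i < nw; ++i) {
        w[i - 1] = bp[i] * xi - ap[i] * yi + w[i];
      }
      yp[k] = yi;
    }
  } else {
    std::vector<double> w(nw, 0.0);
    for (int k = 0; k < n; ++k) {
      double xi = xp[k];
      double yi = bz[0] * xi + w[0];
      for (int i = 1; i < nw; ++i) {
        w[i - 1] = bz[i] * xi - az[i] * yi + w[i];
      }
      yp[k] = yi;
    }
  }
  return y;
}

// Centered FIR filtering evaluated only at decimated sample positions
// 1, 1+q, 1+2q, ... ; samples outside the input are treated as zero.
// Equivalent to filtering with the (odd-length) kernel at zero phase and
// subsampling.
// [[Rcpp::export]]
NumericVector cpp_fir_decim(NumericVector h, NumericVector x, int q) {
  int nh = h.size(), n = x.size();
  int half = nh / 2;
  int m = (n + q - 1) / q;
  NumericVector y(m);
  const double* xp = x.begin();
  const double* hp = h.begin();
  for (int j = 0; j < m; ++j) {
    int k = j * q;               // output anchored at input sample k
    double acc = 0.0;
    int lo = std::max(0, k + half - (nh - 1));
    int hi = std::min(n - 1, k + half);
    for (int t = lo; t <= hi; ++t) {
      acc += hp[k + half - t] * xp[t];
    }
    y[j] = acc;
  }
  return y;
}
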