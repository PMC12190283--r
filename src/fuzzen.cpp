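#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Fuzzy entropy of a univariate series.
//
// Templates of length m and m+1 both start at i = 0..N-m-1 (N-m vectors of
// each length), each centred on its own mean. Pairwise similarity uses the
// Chebyshev distance d between centred templates and a fuzzy membership:
//   form 1: mu = exp(-d^n / r)
//   form 2: mu = exp(-(d/r)^n)
// phi^m is the mean over i of the mean over j != i of mu; FuzzEn is
// ln(phi^m) - ln(phi^{m+1}), in nats.
//
// Memberships with an exponent argument beyond `cut` contribute less than
// exp(-45) ~ 3e-20 each and are skipped; the resulting error in phi is far
// below the accumulation error of the sums themselves.
// [[Rcpp::export(name = ".fuzzen_cpp")]]
double fuzzen_cpp(NumericVector x, int m, double n, double r, int form) {
  const int N = x.size();
  const int Nm = N - m;
  if (Nm < 2 || r <= 0.0) return NA_REAL;

  std::vector<double> Tm((size_t)Nm * m), Tm1((size_t)Nm * (m + 1));
  for (int i = 0; i < Nm; ++i) {
    double mu = 0.0, mu1 = 0.0;
    for (int k = 0; k < m; ++k) mu += x[i + k];
    for (int k = 0; k <= m; ++k) mu1 += x[i + k];
    mu /= m;
    mu1 /= (m + 1);
    for (int k = 0; k < m; ++k) Tm[(size_t)i * m + k] = x[i + k] - mu;
    for (int k = 0; k <= m; ++k) Tm1[(size_t)i * (m + 1) + k] = x[i + k] - mu1;
  }

  const double cut = 45.0;
  const bool sq = (n == 2.0);
  long double sm = 0.0L, sm1 = 0.0L;
  for (int i = 0; i < Nm; ++i) {
    const double *ti = &Tm[(size_t)i * m];
    const double *ti1 = &Tm1[(size_t)i * (m + 1)];
    for (int j = i + 1; j < Nm; ++j) {
      const double *tj = &Tm[(size_t)j * m];
      const double *tj1 = &Tm1[(size_t)j * (m + 1)];
      double dm = 0.0, dm1 = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(ti[k] - tj[k]);
        if (d > dm) dm = d;
      }
      for (int k = 0; k <= m; ++k) {
        double d = std::fabs(ti1[k] - tj1[k]);
        if (d > dm1) dm1 = d;
      }
      double em, em1;
      if (form == 1) {  // exp(-d^n / r)
        em = (sq ? dm * dm : std::pow(dm, n)) / r;
        em1 = (sq ? dm1 * dm1 : std::pow(dm1, n)) / r;
      } else {          // exp(-(d/r)^n)
        em = sq ? (dm / r) * (dm / r) : std::pow(dm / r, n);
        em1 = sq ? (dm1 / r) * (dm1 / r) : std::pow(dm1 / r, n);
      }
      if (em < cut) sm += std::exp(-em);
      if (em1 < cut) sm1 += std::exp(-em1);
    }
  }

  const double pairs = (double)Nm * (Nm - 1) / 2.0;
  const double phim = (double)(sm / pairs);
  const double phim1 = (double)(sm1 / pairs);
  if (phim <= 0.0 || phim1 <= 0.0) return NA_REAL;
  return std::log(phim) - std::log(phim1);
}
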