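#include <Rcpp.h>
using namespace Rcpp;

// Kendall tau-a by direct pair counting: ties count as neither concordant
// nor discordant; denominator is always n (n - 1) / 2.
// [[Rcpp::export]]
double tau_a_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  long long num = 0;
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < i; ++j) {
      const double dx = x[i] - x[j];
      const double dy = y[i] - y[j];
      if (dx != 0.0 && dy != 0.0) {
        num += ((dx > 0) == (dy > 0)) ? 1 : -1;
      }
    }
  }
  return 2.0 * static_cast<double>(num) / (static_cast<double>(n) * (n - 1));
}

// 1-D TFCE: integrate extent^E * h^H * dh over height levels; negative
// values are enhanced on the negated map and re-negated.
static void tfce_one_sign(const std::vector<double>& m, double E, double H,
                          double dh, std::vector<double>& out) {
  const int n = m.size();
  double peak = 0.0;
  for (int i = 0; i < n; ++i) peak = std::max(peak, m[i]);
  if (peak <= 0.0) return;
  const int n_steps = static_cast<int>(std::floor(peak / dh + 1e-9));
  for (int s = 1; s <= n_steps; ++s) {
    const double h = s * dh;
    const double hh = std::pow(h, H) * dh;
    int i = 0;
    while (i < n) {
      if (m[i] >= h - 1e-12) {
        int j = i;
        while (j < n && m[j] >= h - 1e-12) ++j;
        const double add = std::pow(static_cast<double>(j - i), E) * hh;
        for (int k = i; k < j; ++k) out[k] += add;
        i = j;
      } else {
        ++i;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat_map, double E, double H,
                       double dh) {
  const int n = stat_map.size();
  std::vector<double> pos(n), neg(n), out_pos(n, 0.0), out_neg(n, 0.0);
  for (int i = 0; i < n; ++i) {
    pos[i] = stat_map[i] > 0 ? stat_map[i] : 0.0;
    neg[i] = stat_map[i] < 0 ? -stat_map[i] : 0.0;
  }
  tfce_one_sign(pos, E, H, dh, out_pos);
  tfce_one_sign(neg, E, H, dh, out_neg);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = out_pos[i] - out_neg[i];
  return out;
}
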