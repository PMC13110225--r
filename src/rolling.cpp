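#include <Rcpp.h>
using namespace Rcpp;

// Rolling Pearson correlation over a regular grid with gaps.
// x, y: series on a common grid (NA = absent sample). Windows of `width`
// slots advance by `step` slots; a window yields a value iff at least
// `min_valid` slots have both series present and both windowed variances
// are positive. Two-pass (mean first, then centred sums) so results agree
// with the textbook Pearson formula to machine precision.
// Returns start index (0-based), r and the number of valid pairs.
// [[Rcpp::export]]
List rolling_pearson_cpp(NumericVector x, NumericVector y,
                         int width, int step, int min_valid) {
  int n = x.size();
  std::vector<int> starts;
  std::vector<double> rs;
  std::vector<int> ms;
  for (int s = 0; s + width <= n; s += step) {
    int m = 0;
    double sx = 0.0, sy = 0.0;
    for (int j = s; j < s + width; ++j) {
      if (!ISNAN(x[j]) && !ISNAN(y[j])) {
        ++m;
        sx += x[j];
        sy += y[j];
      }
    }
    if (m < min_valid) continue;
    double mx = sx / m, my = sy / m;
    double vx = 0.0, vy = 0.0, vxy = 0.0;
    for (int j = s; j < s + width; ++j) {
      if (!ISNAN(x[j]) && !ISNAN(y[j])) {
        double dx = x[j] - mx, dy = y[j] - my;
        vx += dx * dx;
        vy += dy * dy;
        vxy += dx * dy;
      }
    }
    if (vx <= 0.0 || vy <= 0.0) continue; // degenerate window: no value
    double r = vxy / std::sqrt(vx * vy);
    if (r > 1.0) r = 1.0;
    if (r < -1.0) r = -1.0;
    starts.push_back(s);
    rs.push_back(r);
    ms.push_back(m);
  }
  return List::create(_["start"] = wrap(starts), _["r"] = wrap(rs),
                      _["n_valid"] = wrap(ms));
}
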