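#include <Rcpp.h>
using namespace Rcpp;

// Biased correlated random walk over a gridded scene with reflecting barrier
// cells (the emergent reef crest). Each step combines directional
// persistence, Gaussian noise scaled by the per-step step_sd (diel activity
// already folded in), and attraction toward a per-step home centre (which
// moves during inter-atoll excursions). Proposals landing on a barrier cell
// or off-grid leave the animal in place and damp its velocity. Uses R's RNG
// so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix bcrw_walk(double x0, double y0,
                        NumericVector home_x, NumericVector home_y,
                        NumericVector step_sd,
                        double attraction, double persistence,
                        double max_pull,
                        IntegerMatrix barrier,
                        double cell_size, double origin_x, double origin_y) {
  int n = home_x.size();
  int nr = barrier.nrow(), nc = barrier.ncol();
  NumericMatrix out(n, 2);
  double x = x0, y = y0, vx = 0.0, vy = 0.0;
  double xmin = origin_x - 0.5 * cell_size;
  double ymin = origin_y - 0.5 * cell_size;
  double xmax = origin_x + (nc - 0.5) * cell_size;
  double ymax = origin_y + (nr - 0.5) * cell_size;
  for (int t = 0; t < n; ++t) {
    double sx = persistence * vx + R::rnorm(0.0, step_sd[t]);
    double sy = persistence * vy + R::rnorm(0.0, step_sd[t]);
    double px = attraction * (home_x[t] - x);
    double py = attraction * (home_y[t] - y);
    double pmag = std::sqrt(px * px + py * py);
    if (pmag > max_pull) { px *= max_pull / pmag; py *= max_pull / pmag; }
    double nx = x + sx + px;
    double ny = y + sy + py;
    if (nx < xmin) nx = xmin; if (nx > xmax) nx = xmax;
    if (ny < ymin) ny = ymin; if (ny > ymax) ny = ymax;
    int j = (int)std::lround((nx - origin_x) / cell_size);
    int i = (int)std::lround((ny - origin_y) / cell_size);
    if (i < 0) i = 0; if (i >= nr) i = nr - 1;
    if (j < 0) j = 0; if (j >= nc) j = nc - 1;
    if (barrier(i, j) == 1) {
      // blocked: stay put, kill momentum
      vx = 0.0; vy = 0.0;
    } else {
      vx = nx - x; vy = ny - y;
      x = nx; y = ny;
    }
    out(t, 0) = x;
    out(t, 1) = y;
  }
  return out;
}
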