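#include <Rcpp.h>
using namespace Rcpp;

// Fraction of the circle of radius r centred at (px, py) lying inside the
// rectangle [0,W] x [0,H] (Ripley isotropic edge correction). Exterior arcs
// are accumulated per edge, with the overlap of adjacent edges' arcs removed
// when the corner lies inside the circle. Valid for r <= min(W, H) / 2 plus
// the margin where at most adjacent-edge arcs overlap, which covers radius
// grids bounded by half the shorter window side.
static double circle_frac_inside(double px, double py, double W, double H,
                                 double r) {
  double d[4] = {px, W - px, py, H - py};  // left, right, bottom, top
  double a[4];
  double ext = 0.0;
  for (int k = 0; k < 4; k++) {
    if (d[k] < r) {
      a[k] = std::acos(std::min(1.0, std::max(-1.0, d[k] / r)));
      ext += 2.0 * a[k];
    } else a[k] = 0.0;
  }
  // adjacent pairs: (left,bottom), (bottom,right), (right,top), (top,left)
  const int pairs[4][2] = {{0, 2}, {2, 1}, {1, 3}, {3, 0}};
  for (int k = 0; k < 4; k++) {
    double ov = a[pairs[k][0]] + a[pairs[k][1]] - M_PI_2;
    if (ov > 0.0) ext -= ov;
  }
  double frac = 1.0 - ext / (2.0 * M_PI);
  return frac > 1e-12 ? frac : 1e-12;
}

// [[Rcpp::export]]
double ripley_weight_cpp(double px, double py, double W, double H, double r) {
  return 1.0 / circle_frac_inside(px, py, W, H, r);
}

// Weighted kernel sums of the pair-correlation estimator:
//   acc[k] = sum_{i != j} w_ij * k_b(r_k - d_ij)
// correction: 0 = none, 1 = Ripley isotropic, 2 = translation
// kernel: 0 = box (k = 1/(2b) on |u| <= b), 1 = Epanechnikov
// [[Rcpp::export]]
NumericVector pcf_pairs_cpp(NumericVector x, NumericVector y,
                            double W, double H, NumericVector r,
                            double bw, int correction, int kernel) {
  int n = x.size(), nr = r.size();
  NumericVector acc(nr);
  double rmax = r[nr - 1] + bw;
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 > rmax * rmax) continue;
      double d = std::sqrt(d2);
      // radii are sorted, so only those in [d - bw, d + bw] can match
      int k0 = int(std::lower_bound(r.begin(), r.end(), d - bw) - r.begin());
      if (k0 >= nr || r[k0] > d + bw) continue;
      double wsum;
      if (correction == 1) {
        wsum = 1.0 / circle_frac_inside(x[i], y[i], W, H, d) +
               1.0 / circle_frac_inside(x[j], y[j], W, H, d);
      } else if (correction == 2) {
        wsum = 2.0 * (W * H) /
               ((W - std::fabs(dx)) * (H - std::fabs(dy)));
      } else {
        wsum = 2.0;
      }
      for (int k = k0; k < nr && r[k] <= d + bw; k++) {
        double u = r[k] - d;
        double kb = (kernel == 1)
          ? 0.75 / bw * (1.0 - (u / bw) * (u / bw))
          : 0.5 / bw;
        acc[k] += wsum * kb;
      }
    }
  }
  return acc;
}
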