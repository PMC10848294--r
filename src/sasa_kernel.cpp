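#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Deterministic Fibonacci-sphere directions: near-uniform unit vectors.
// z_k = 1 - (2k+1)/n, phi_k = k * golden angle. For even n no point sits
// exactly on the equator, which keeps plane-classification ties away from
// the generic case.
static void fibonacci_directions(int n, std::vector<double> &dirs) {
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  dirs.resize(3 * (size_t)n);
  for (int k = 0; k < n; ++k) {
    double z = 1.0 - (2.0 * k + 1.0) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    dirs[3 * (size_t)k] = r * std::cos(phi);
    dirs[3 * (size_t)k + 1] = r * std::sin(phi);
    dirs[3 * (size_t)k + 2] = z;
  }
}

// Neighbour prune: atom j can only occlude points on atom i's expanded
// sphere if |xi-xj| < (ri+probe)+(rj+probe).
static void neighbours_of(int i, const NumericMatrix &xyz,
                          const std::vector<double> &rexp,
                          std::vector<int> &nbr) {
  nbr.clear();
  const int n = xyz.nrow();
  const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi, dz = xyz(j, 2) - zi;
    double cut = rexp[i] + rexp[j];
    if (dx * dx + dy * dy + dz * dz < cut * cut) nbr.push_back(j);
  }
}

// A surface point is buried if it lies inside or exactly on any other
// atom's expanded sphere (tie-break toward burial).
static inline bool buried(double px, double py, double pz,
                          const NumericMatrix &xyz,
                          const std::vector<double> &rexp,
                          const std::vector<int> &nbr) {
  for (size_t m = 0; m < nbr.size(); ++m) {
    int j = nbr[m];
    double dx = px - xyz(j, 0), dy = py - xyz(j, 1), dz = pz - xyz(j, 2);
    if (dx * dx + dy * dy + dz * dz <= rexp[j] * rexp[j]) return true;
  }
  return false;
}

// [[Rcpp::export(name = ".cpp_surface_points")]]
List cpp_surface_points(NumericMatrix xyz, NumericVector radii, double probe,
                        int n_points, bool keep_points) {
  const int n = xyz.nrow();
  std::vector<double> rexp(n);
  for (int i = 0; i < n; ++i) rexp[i] = radii[i] + probe;

  std::vector<double> dirs;
  fibonacci_directions(n_points, dirs);

  IntegerVector counts(n);
  NumericVector areas(n);
  std::vector<int> owner;
  std::vector<double> px_, py_, pz_, wt_;
  std::vector<int> nbr;
  nbr.reserve(64);

  for (int i = 0; i < n; ++i) {
    neighbours_of(i, xyz, rexp, nbr);
    const double R = rexp[i];
    const double w = 4.0 * M_PI * R * R / n_points;
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    int cnt = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = xi + R * dirs[3 * (size_t)k];
      double py = yi + R * dirs[3 * (size_t)k + 1];
      double pz = zi + R * dirs[3 * (size_t)k + 2];
      if (!buried(px, py, pz, xyz, rexp, nbr)) {
        ++cnt;
        if (keep_points) {
          owner.push_back(i + 1);
          px_.push_back(px);
          py_.push_back(py);
          pz_.push_back(pz);
          wt_.push_back(w);
        }
      }
    }
    counts[i] = cnt;
    areas[i] = cnt * w;
  }

  List out = List::create(_["counts"] = counts, _["area"] = areas);
  if (keep_points) {
    const size_t np = owner.size();
    NumericMatrix pts(np, 3);
    NumericVector wts(np);
    IntegerVector own(np);
    for (size_t p = 0; p < np; ++p) {
      pts(p, 0) = px_[p];
      pts(p, 1) = py_[p];
      pts(p, 2) = pz_[p];
      wts[p] = wt_[p];
      own[p] = owner[p];
    }
    out["points"] = pts;
    out["weights"] = wts;
    out["owner"] = own;
  }
  return out;
}

// Monte-Carlo SASA estimate, independent of the quadrature path: uniform
// random directions (normalised Gaussian triples from R's RNG, so results
// are reproducible via set.seed()).
// [[Rcpp::export(name = ".cpp_mc_sasa")]]
NumericVector cpp_mc_sasa(NumericMatrix xyz, NumericVector radii, double probe,
                          int n_samples) {
  const int n = xyz.nrow();
  std::vector<double> rexp(n);
  for (int i = 0; i < n; ++i) rexp[i] = radii[i] + probe;
  NumericVector areas(n);
  std::vector<int> nbr;
  RNGScope scope;

  for (int i = 0; i < n; ++i) {
    neighbours_of(i, xyz, rexp, nbr);
    const double R = rexp[i];
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    int acc = 0;
    for (int s = 0; s < n_samples; ++s) {
      double gx = norm_rand(), gy = norm_rand(), gz = norm_rand();
      double nrm = std::sqrt(gx * gx + gy * gy + gz * gz);
      if (nrm < 1e-12) { --s; continue; }
      double px = xi + R * gx / nrm;
      double py = yi + R * gy / nrm;
      double pz = zi + R * gz / nrm;
      if (!buried(px, py, pz, xyz, rexp, nbr)) ++acc;
    }
    areas[i] = 4.0 * M_PI * R * R * (double)acc / n_samples;
  }
  return areas;
}
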