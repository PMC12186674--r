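// 2-D Pareto / hypervolume / EHVI kernels.
// Objective orientation throughout: maximize yield (y), minimize cost (c).
// The reference point (yref, cref) is worse than every point of interest:
// yref below all yields, cref above all costs.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Nondominated mask. Equal points dominate neither (duplicates kept).
// [[Rcpp::export]]
LogicalVector cpp_pareto_mask(NumericVector y, NumericVector c) {
  int n = y.size();
  LogicalVector keep(n, true);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  // sort by cost ascending, yield descending
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (c[a] != c[b]) return c[a] < c[b];
    return y[a] > y[b];
  });
  double maxy_strict = R_NegInf;  // best yield among strictly cheaper points
  int i = 0;
  while (i < n) {
    int j = i;
    double cc = c[idx[i]];
    double maxy_eq = R_NegInf;    // best yield at this exact cost
    while (j < n && c[idx[j]] == cc) {
      int p = idx[j];
      if (maxy_strict >= y[p] || maxy_eq > y[p]) keep[p] = false;
      if (y[p] > maxy_eq) maxy_eq = y[p];
      ++j;
    }
    if (maxy_eq > maxy_strict) maxy_strict = maxy_eq;
    i = j;
  }
  return keep;
}

static double hv2d_sorted(const std::vector<std::pair<double,double>> &pts,
                          double yref, double cref) {
  // pts sorted by cost ascending; points outside the box already removed
  double hv = 0.0, cur = yref;
  for (size_t i = 0; i < pts.size(); ++i) {
    double cc = pts[i].first, yy = pts[i].second;
    if (yy > cur) {
      hv += (cref - cc) * (yy - cur);
      cur = yy;
    }
  }
  return hv;
}

static double hv2d_raw(const NumericVector &y, const NumericVector &c,
                       double yref, double cref) {
  std::vector<std::pair<double,double>> pts;
  pts.reserve(y.size());
  for (int i = 0; i < y.size(); ++i)
    if (y[i] > yref && c[i] < cref) pts.push_back({c[i], y[i]});
  std::sort(pts.begin(), pts.end());
  return hv2d_sorted(pts, yref, cref);
}

// Exact 2-D hypervolume by a sorted sweep.
// [[Rcpp::export]]
double cpp_hv2d(NumericVector y, NumericVector c, double yref, double cref) {
  return hv2d_raw(y, c, yref, cref);
}

struct Envelope {
  // nondominated front clipped to the box, sorted by cost ascending
  std::vector<double> fc, fy;
  double yref, cref;
  Envelope(const NumericVector &y, const NumericVector &c,
           double yref_, double cref_) : yref(yref_), cref(cref_) {
    LogicalVector keep = cpp_pareto_mask(y, c);
    std::vector<std::pair<double,double>> pts;
    for (int i = 0; i < y.size(); ++i)
      if (keep[i] && y[i] > yref && c[i] < cref)
        pts.push_back({c[i], y[i]});
    std::sort(pts.begin(), pts.end());
    for (auto &p : pts) { fc.push_back(p.first); fy.push_back(p.second); }
  }
  // hypervolume gained by adding the single point (ystar, cstar)
  double gain(double ystar, double cstar) const {
    if (ystar <= yref || cstar >= cref) return 0.0;
    double area = 0.0;
    double start = cstar;
    // env value just left of `start`
    double env = yref;
    size_t j = 0;
    while (j < fc.size() && fc[j] <= start) { env = fy[j]; ++j; }
    while (start < cref) {
      double stop = (j < fc.size()) ? std::min(fc[j], cref) : cref;
      if (ystar > env) area += (stop - start) * (ystar - env);
      if (j < fc.size() && fc[j] == stop) { env = fy[j]; ++j; }
      start = stop;
      if (env >= ystar) break;
    }
    return area;
  }
};

// Per-candidate Monte-Carlo EHVI at q = 1, common random numbers across
// candidates: z is the shared vector of standard-normal draws.
// [[Rcpp::export]]
NumericVector cpp_individual_ehvi(NumericVector front_y, NumericVector front_c,
                                  NumericVector mu, NumericVector sd,
                                  NumericVector cost,
                                  double yref, double cref, NumericVector z) {
  Envelope env(front_y, front_c, yref, cref);
  int m = mu.size(), d = z.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double acc = 0.0;
    for (int k = 0; k < d; ++k)
      acc += env.gain(mu[i] + sd[i] * z[k], cost[i]);
    out[i] = acc / d;
  }
  return out;
}

// Joint Monte-Carlo EHVI of a batch. Z is ndraws x q, yields sampled
// independently per candidate, costs deterministic.
// [[Rcpp::export]]
double cpp_joint_ehvi(NumericVector front_y, NumericVector front_c,
                      NumericVector mu, NumericVector sd, NumericVector cost,
                      double yref, double cref, NumericMatrix Z) {
  int q = mu.size();
  if (Z.ncol() < q) stop("Z needs at least q columns");
  double base = hv2d_raw(front_y, front_c, yref, cref);
  std::vector<std::pair<double,double>> fr;
  for (int i = 0; i < front_y.size(); ++i)
    if (front_y[i] > yref && front_c[i] < cref)
      fr.push_back({front_c[i], front_y[i]});
  std::sort(fr.begin(), fr.end());
  int nd = Z.nrow();
  double acc = 0.0;
  std::vector<std::pair<double,double>> pts;
  for (int k = 0; k < nd; ++k) {
    pts = fr;
    for (int j = 0; j < q; ++j) {
      double yy = mu[j] + sd[j] * Z(k, j);
      if (yy > yref && cost[j] < cref) pts.push_back({cost[j], yy});
    }
    std::sort(pts.begin(), pts.end());
    acc += hv2d_sorted(pts, yref, cref) - base;
  }
  return acc / nd;
}
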