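#include <Rcpp.h>
using namespace Rcpp;

// Hit-and-run chain on the polytope {x : sum(x) = p, lower <= x <= upper}.
// Directions are isotropic within the sum-zero hyperplane (Gaussian draws,
// mean-subtracted); chord endpoints come from the box constraints. Records
// the chain state every `thin` iterations for `n_iter` total iterations.
// [[Rcpp::export(name = ".har_chain")]]
NumericMatrix har_chain(NumericVector x0, NumericVector lower,
                        NumericVector upper, double n_iter, int thin) {
  const int n = x0.size();
  const R_xlen_t iters = (R_xlen_t) n_iter;
  const R_xlen_t n_out = iters / thin;
  NumericMatrix out(n_out, n);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> d(n);
  R_xlen_t rec = 0;

  // Marsaglia polar normals driven by R's unif_rand (cheaper than the
  // inversion method; the chain stays reproducible under set.seed)
  double spare = 0.0;
  bool has_spare = false;
  auto rnorm1 = [&]() -> double {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif_rand() - 1.0;
      v = 2.0 * unif_rand() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    has_spare = true;
    return u * f;
  };

  for (R_xlen_t it = 1; it <= iters; ++it) {
    double mean = 0.0;
    for (int i = 0; i < n; ++i) { d[i] = rnorm1(); mean += d[i]; }
    mean /= n;
    double nrm = 0.0;
    for (int i = 0; i < n; ++i) { d[i] -= mean; nrm += d[i] * d[i]; }
    if (nrm < 1e-300) { --it; continue; }

    double tmin = -std::numeric_limits<double>::infinity();
    double tmax = std::numeric_limits<double>::infinity();
    for (int i = 0; i < n; ++i) {
      if (std::fabs(d[i]) < 1e-14) continue;
      double lo = (lower[i] - x[i]) / d[i];
      double hi = (upper[i] - x[i]) / d[i];
      if (d[i] < 0) std::swap(lo, hi);
      if (lo > tmin) tmin = lo;
      if (hi < tmax) tmax = hi;
    }
    if (!(tmax > tmin)) continue;  // degenerate chord: stay put
    double t = tmin + unif_rand() * (tmax - tmin);
    for (int i = 0; i < n; ++i) x[i] += t * d[i];

    if (it % thin == 0 && rec < n_out) {
      for (int i = 0; i < n; ++i) out(rec, i) = x[i];
      ++rec;
    }
  }
  return out;
}
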