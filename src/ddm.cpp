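#include <Rcpp.h>
using namespace Rcpp;

// Two-boundary diffusion first-passage simulation (Euler-Maruyama).
//
// Evidence starts at a/2 and accumulates as dX = v dt + s dW until it hits
// 0 (error boundary) or a (correct boundary). dt defaults to 1 ms and the
// diffusion coefficient s to 0.1, the conventional DDM scaling. Uses R's RNG
// so results are reproducible under set.seed().
//
// [[Rcpp::export]]
List ddm_first_passage_cpp(NumericVector v, double a, double ter,
                           double s, double dt, double max_time) {
  if (a <= 0) stop("boundary separation 'a' must be positive");
  if (ter < 0) stop("non-decision time must be non-negative");
  if (dt <= 0 || s <= 0) stop("dt and s must be positive");
  const int n = v.size();
  NumericVector rt(n);
  LogicalVector upper(n);
  const double sq = s * std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = a / 2.0, t = 0.0;
    const double vi = v[i];
    while (x > 0.0 && x < a && t < max_time) {
      x += vi * dt + sq * norm_rand();
      t += dt;
    }
    // censored paths (never at sensible parameters) resolve to the nearer boundary
    upper[i] = (x >= a / 2.0);
    if (x >= a) upper[i] = true;
    else if (x <= 0.0) upper[i] = false;
    rt[i] = t + ter;
  }
  return List::create(_["rt"] = rt, _["upper"] = upper);
}
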