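#include <Rcpp.h>
using namespace Rcpp;

// Value iteration over a deterministic clamped grid kernel with
// reward-probability termination: V(x) = max_A [ R(x') + gamma * (1 - R(x'))
// * (1 - terminal(x')) * V(x') ]. R is the estimated probability of reward
// (and hence of trial termination) on entering each cell; `terminal` marks
// cells known to end the episode regardless of reward (e.g. doors in the
// rooms task). succ is 1-based (n x 4).
// [[Rcpp::export(name = ".vi_cpp")]]
List vi_cpp(NumericVector reward, IntegerMatrix succ, double gamma,
            double tol, int max_iter, NumericVector v0,
            NumericVector terminal) {
  const int n = reward.size();
  if (succ.nrow() != n) stop("successor table does not match reward length");
  NumericVector V = clone(v0);
  NumericMatrix Q(n, 4);
  double resid = R_PosInf;
  int iter = 0;
  while (iter < max_iter) {
    ++iter;
    resid = 0.0;
    for (int x = 0; x < n; ++x) {
      double best = R_NegInf;
      for (int a = 0; a < 4; ++a) {
        int xp = succ(x, a) - 1;
        double r = reward[xp];
        double q = r + gamma * (1.0 - r) * (1.0 - terminal[xp]) * V[xp];
        Q(x, a) = q;
        if (q > best) best = q;
      }
      double d = best - V[x];
      if (d < 0) d = -d;
      if (d > resid) resid = d;
      V[x] = best;  // in-place (Gauss-Seidel) sweep
    }
    if (resid < tol) break;
  }
  return List::create(_["V"] = V, _["Q"] = Q, _["iterations"] = iter,
                      _["residual"] = resid, _["converged"] = resid < tol);
}
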