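#include <Rcpp.h>
using namespace Rcpp;

// Saturation of a chemical effect: c / (c + kappa), kappa > 0.
static inline double hill(double c, double k) { return c / (c + k); }

// Euler-Maruyama integration of the community models.
//
// model: 0 = M (per-species logistic, chemical-mediated)
//        1 = M' (shared logistic, chemical-mediated)
//        2 = D (per-species logistic, direct gLV interactions)
//        3 = D' (shared logistic, direct gLV interactions)
//
// rho is the net chemical effect matrix (rho_plus - rho_minus), n x m.
// alpha/beta are m x n.  A (n x n) is used only by D/D'.
// noise_form: 0 = sigma*sqrt(dt)*N(0,1), 1 = sigma*dt*N(0,1),
//             2 = sigma*x*sqrt(dt)*N(0,1).
// Noise uses R's RNG, so trajectories are reproducible via set.seed().
// States are floored at 0 after every step; the microbe influx eps is
// added every step, chemicals get no influx.
//
// Returns ok/bad_step/bad_var diagnostics, post-transient time averages
// xhat/chat over steps t_burn+1..t_max, and (optionally) the full state
// matrix with t_max+1 rows.
// [[Rcpp::export]]
List em_integrate_cpp(int model, NumericVector r, double K, double delta,
                      NumericMatrix rho, NumericMatrix kappa,
                      NumericMatrix alpha, NumericMatrix beta,
                      NumericMatrix A,
                      NumericVector x0, NumericVector c0,
                      double dt, int t_max, int t_burn,
                      double sigma, double eps,
                      bool noise_on_chem, int noise_form,
                      bool return_states) {
  const int n = r.size();
  const bool mediated = (model == 0 || model == 1);
  const int m = mediated ? c0.size() : 0;
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> c(m);
  for (int k = 0; k < m; ++k) c[k] = c0[k];
  // Flat copies of the parameter matrices: column-major like R, indexed
  // manually to avoid per-element accessor overhead in the time loop.
  std::vector<double> rr(r.begin(), r.end());
  std::vector<double> Rho(rho.begin(), rho.end());       // n x m
  std::vector<double> Kap(kappa.begin(), kappa.end());   // n x m
  std::vector<double> Alp(alpha.begin(), alpha.end());   // m x n
  std::vector<double> Bet(beta.begin(), beta.end());     // m x n
  std::vector<double> Amat(A.begin(), A.end());          // n x n
  NumericMatrix states;
  if (return_states) states = NumericMatrix(t_max + 1, n + m);
  NumericVector xhat(n), chat(m);
  const double sdt = std::sqrt(dt);
  std::vector<double> fx(n), gc(m);
  int bad_step = -1, bad_var = -1;

  if (return_states) {
    for (int i = 0; i < n; ++i) states(0, i) = x[i];
    for (int k = 0; k < m; ++k) states(0, n + k) = c[k];
  }

  for (int t = 0; t < t_max; ++t) {
    double xs = 0.0;
    for (int i = 0; i < n; ++i) xs += x[i];
    for (int i = 0; i < n; ++i) {
      double grow = (model == 0 || model == 2)
                        ? rr[i] * (1.0 - x[i] / K)
                        : rr[i] * (1.0 - xs / (n * K));
      double inter = 0.0;
      if (mediated) {
        for (int k = 0; k < m; ++k)
          inter += Rho[i + k * n] * hill(c[k], Kap[i + k * n]);
      } else {
        for (int j = 0; j < n; ++j) inter += Amat[i + j * n] * x[j];
      }
      fx[i] = grow * x[i] + inter * x[i] - delta * x[i];
    }
    if (mediated) {
      for (int k = 0; k < m; ++k) {
        double s = 0.0;
        for (int i = 0; i < n; ++i)
          s += Bet[k + i * m] * x[i] -
               Alp[k + i * m] * x[i] * hill(c[k], Kap[i + k * n]);
        gc[k] = s - delta * c[k];
      }
    }
    for (int i = 0; i < n; ++i) {
      double noise = 0.0;
      if (sigma > 0.0) {
        double z = norm_rand();
        if (noise_form == 0) noise = sigma * sdt * z;
        else if (noise_form == 1) noise = sigma * dt * z;
        else noise = sigma * x[i] * sdt * z;
      }
      x[i] += fx[i] * dt + noise + eps;
      if (x[i] < 0.0) x[i] = 0.0;
    }
    for (int k = 0; k < m; ++k) {
      double noise = 0.0;
      if (sigma > 0.0 && noise_on_chem) {
        double z = norm_rand();
        if (noise_form == 0) noise = sigma * sdt * z;
        else if (noise_form == 1) noise = sigma * dt * z;
        else noise = sigma * c[k] * sdt * z;
      }
      c[k] += gc[k] * dt + noise;
      if (c[k] < 0.0) c[k] = 0.0;
    }
    for (int i = 0; i < n && bad_step < 0; ++i)
      if (!R_finite(x[i]) || x[i] > 1e12) { bad_step = t + 1; bad_var = i + 1; }
    for (int k = 0; k < m && bad_step < 0; ++k)
      if (!R_finite(c[k]) || c[k] > 1e12) { bad_step = t + 1; bad_var = n + k + 1; }
    if (bad_step >= 0) break;
    if (return_states) {
      for (int i = 0; i < n; ++i) states(t + 1, i) = x[i];
      for (int k = 0; k < m; ++k) states(t + 1, n + k) = c[k];
    }
    if (t + 1 > t_burn) {
      for (int i = 0; i < n; ++i) xhat[i] += x[i];
      for (int k = 0; k < m; ++k) chat[k] += c[k];
    }
  }
  const int navg = t_max - t_burn;
  if (bad_step < 0 && navg > 0) {
    for (int i = 0; i < n; ++i) xhat[i] /= navg;
    for (int k = 0; k < m; ++k) chat[k] /= navg;
  }
  return List::create(_["ok"] = (bad_step < 0),
                      _["bad_step"] = bad_step, _["bad_var"] = bad_var,
                      _["xhat"] = xhat, _["chat"] = chat,
                      _["states"] = return_states ? (SEXP)states : R_NilValue);
}
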