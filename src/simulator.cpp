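#include <Rcpp.h>
using namespace Rcpp;

// Synchronous fixed-point evaluation of a probabilistic logic network.
//
// Compiled network encoding (built by compile_network() in R, all 0-based):
//   n_nodes    int
//   ia_target  int[n_ia]            target node of each interaction
//   ia_gate    int[n_ia]            0 = single, 1 = AND, 2 = OR
//   ia_sign    int[n_ia]            1 = activation, 0 = inhibition
//   ia_param   int[n_ia]            index into the parameter vector
//   src        int[sum sources]     concatenated source node indices
//   src_ptr    int[n_ia + 1]        CSR offsets into src
//   has_in     int[n_nodes]         1 if the node has >= 1 incoming interaction
//
// Gate value g_i of interaction i given the current state x:
//   single: x[s]; AND: prod x[s]; OR: 1 - prod(1 - x[s])   (probabilistic union)
// Node update: a = sum_{activators} k_i g_i, then a * prod_{inhibitors}(1 - h_j g_j),
// clipped to [0,1]. Clamped nodes keep their clamp; nodes with no incoming
// interactions and no clamp keep their initial value.

static inline double clip01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

static void sweep_state(const IntegerVector& ia_target,
                        const IntegerVector& ia_gate,
                        const IntegerVector& ia_sign,
                        const IntegerVector& ia_param,
                        const IntegerVector& src,
                        const IntegerVector& src_ptr,
                        const IntegerVector& has_in,
                        const double* k,
                        const std::vector<char>& clamped,
                        const std::vector<double>& clampv,
                        const std::vector<double>& xold,
                        std::vector<double>& xnew,
                        std::vector<double>& act,
                        std::vector<double>& inh) {
  const int n_nodes = has_in.size();
  const int n_ia = ia_target.size();
  std::fill(act.begin(), act.end(), 0.0);
  std::fill(inh.begin(), inh.end(), 1.0);
  for (int i = 0; i < n_ia; ++i) {
    double g;
    int a = src_ptr[i], b = src_ptr[i + 1];
    if (ia_gate[i] == 0) {
      g = xold[src[a]];
    } else if (ia_gate[i] == 1) {           // AND
      g = 1.0;
      for (int s = a; s < b; ++s) g *= xold[src[s]];
    } else {                                 // OR
      double q = 1.0;
      for (int s = a; s < b; ++s) q *= (1.0 - xold[src[s]]);
      g = 1.0 - q;
    }
    double kg = k[ia_param[i]] * g;
    int t = ia_target[i];
    if (ia_sign[i] == 1) act[t] += kg;
    else inh[t] *= (1.0 - clip01(kg));
  }
  for (int n = 0; n < n_nodes; ++n) {
    if (clamped[n]) xnew[n] = clampv[n];
    else if (has_in[n]) xnew[n] = clip01(act[n] * inh[n]);
    else xnew[n] = xold[n];
  }
}

// [[Rcpp::export]]
NumericVector cpp_steady_state(List net, NumericVector k,
                               IntegerVector clamp_idx, NumericVector clamp_val,
                               double tol, int max_sweeps, double init) {
  const IntegerVector ia_target = net["ia_target"], ia_gate = net["ia_gate"],
    ia_sign = net["ia_sign"], ia_param = net["ia_param"],
    src = net["src"], src_ptr = net["src_ptr"], has_in = net["has_in"];
  const int n_nodes = as<int>(net["n_nodes"]);

  std::vector<char> clamped(n_nodes, 0);
  std::vector<double> clampv(n_nodes, 0.0);
  for (int j = 0; j < clamp_idx.size(); ++j) {
    clamped[clamp_idx[j]] = 1;
    clampv[clamp_idx[j]] = clamp_val[j];
  }
  std::vector<double> x(n_nodes, init), xn(n_nodes), act(n_nodes), inh(n_nodes);
  for (int n = 0; n < n_nodes; ++n) if (clamped[n]) x[n] = clampv[n];

  bool converged = false;
  int used = 0;
  for (int s = 0; s < max_sweeps; ++s) {
    sweep_state(ia_target, ia_gate, ia_sign, ia_param, src, src_ptr, has_in,
                REAL(k), clamped, clampv, x, xn, act, inh);
    double d = 0.0;
    for (int n = 0; n < n_nodes; ++n) {
      double e = std::fabs(xn[n] - x[n]);
      if (e > d) d = e;
      if (!R_finite(xn[n])) stop("numerical error: non-finite activity in update");
    }
    x.swap(xn);
    used = s + 1;
    if (d < tol) { converged = true; break; }
  }
  NumericVector out(x.begin(), x.end());
  out.attr("converged") = converged;
  out.attr("sweeps") = used;
  return out;
}

// Steady states for a batch of experiments sharing one clamp index set.
// K: parameter matrix (P x n_contexts); exp_ctx: 0-based context per
// experiment; clamp_vals: (n_clamp x n_exp). Returns n_nodes x n_exp matrix
// with a logical "converged" attribute per experiment.
// [[Rcpp::export]]
NumericMatrix cpp_simulate_batch(List net, NumericMatrix K,
                                 IntegerVector exp_ctx,
                                 IntegerVector clamp_idx, NumericMatrix clamp_vals,
                                 double tol, int max_sweeps, double init) {
  const IntegerVector ia_target = net["ia_target"], ia_gate = net["ia_gate"],
    ia_sign = net["ia_sign"], ia_param = net["ia_param"],
    src = net["src"], src_ptr = net["src_ptr"], has_in = net["has_in"];
  const int n_nodes = as<int>(net["n_nodes"]);
  const int n_exp = exp_ctx.size();

  NumericMatrix out(n_nodes, n_exp);
  LogicalVector conv(n_exp);
  std::vector<char> clamped(n_nodes, 0);
  for (int j = 0; j < clamp_idx.size(); ++j) clamped[clamp_idx[j]] = 1;
  std::vector<double> clampv(n_nodes, 0.0), x(n_nodes), xn(n_nodes),
    act(n_nodes), inh(n_nodes);

  for (int e = 0; e < n_exp; ++e) {
    for (int j = 0; j < clamp_idx.size(); ++j)
      clampv[clamp_idx[j]] = clamp_vals(j, e);
    for (int n = 0; n < n_nodes; ++n) x[n] = clamped[n] ? clampv[n] : init;
    const double* k = &K(0, exp_ctx[e]);
    bool ok = false;
    for (int s = 0; s < max_sweeps; ++s) {
      sweep_state(ia_target, ia_gate, ia_sign, ia_param, src, src_ptr, has_in,
                  k, clamped, clampv, x, xn, act, inh);
      double d = 0.0;
      for (int n = 0; n < n_nodes; ++n) {
        double err = std::fabs(xn[n] - x[n]);
        if (err > d) d = err;
      }
      x.swap(xn);
      if (d < tol) { ok = true; break; }
    }
    conv[e] = ok;
    for (int n = 0; n < n_nodes; ++n) out(n, e) = x[n];
  }
  out.attr("converged") = conv;
  return out;
}

// ---------------------------------------------------------------------------
// Full objective in C++: theta -> clip to [0,1] -> renormalize competition
// groups (sum-to-one per context) -> batch steady states -> MSE over the
// measurement rows + smoothed L1/2 and grouped-L1 penalties. Used by the
// optimizer; exact (unsmoothed) values are recomputed in R for reporting.

struct ObjCtx {
  IntegerVector ia_target, ia_gate, ia_sign, ia_param, src, src_ptr, has_in;
  int n_nodes, P, C, n_exp;
  IntegerVector exp_ctx, clamp_idx, row_node, row_exp;
  NumericMatrix clamp_vals;
  NumericVector obs;
  List groups;
  double lambda1, lambda2, eps, tol, init;
  int max_sweeps;
};

static ObjCtx make_ctx(List net, List spec) {
  ObjCtx c;
  c.ia_target = net["ia_target"]; c.ia_gate = net["ia_gate"];
  c.ia_sign = net["ia_sign"]; c.ia_param = net["ia_param"];
  c.src = net["src"]; c.src_ptr = net["src_ptr"]; c.has_in = net["has_in"];
  c.n_nodes = as<int>(net["n_nodes"]);
  c.P = as<int>(spec["P"]); c.C = as<int>(spec["C"]);
  c.exp_ctx = spec["exp_ctx"]; c.clamp_idx = spec["clamp_idx"];
  c.clamp_vals = as<NumericMatrix>(spec["clamp_vals"]);
  c.row_node = spec["row_node"]; c.row_exp = spec["row_exp"];
  c.obs = spec["obs"]; c.groups = spec["groups"];
  c.n_exp = c.exp_ctx.size();
  c.lambda1 = as<double>(spec["lambda1"]);
  c.lambda2 = as<double>(spec["lambda2"]);
  c.eps = as<double>(spec["eps"]);
  c.tol = as<double>(spec["tol"]);
  c.init = as<double>(spec["init"]);
  c.max_sweeps = as<int>(spec["max_sweeps"]);
  return c;
}

static double eval_objective(const ObjCtx& c, const double* theta,
                             std::vector<double>& K,
                             std::vector<double>& work) {
  const int P = c.P, C = c.C;
  for (int i = 0; i < P * C; ++i) {
    double v = theta[i];
    K[i] = v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
  }
  for (int g = 0; g < c.groups.size(); ++g) {
    IntegerVector gi = c.groups[g];
    for (int ctx = 0; ctx < C; ++ctx) {
      double s = 0.0;
      for (int j = 0; j < gi.size(); ++j) s += K[ctx * P + gi[j]];
      if (s < 1e-12) {
        for (int j = 0; j < gi.size(); ++j)
          K[ctx * P + gi[j]] = 1.0 / gi.size();
      } else {
        for (int j = 0; j < gi.size(); ++j) K[ctx * P + gi[j]] /= s;
      }
    }
  }
  // simulate experiments, accumulate squared error on measurement rows
  const int n_nodes = c.n_nodes;
  std::vector<double> x(n_nodes), xn(n_nodes), act(n_nodes), inh(n_nodes);
  std::vector<char> clamped(n_nodes, 0);
  std::vector<double> clampv(n_nodes, 0.0);
  for (int j = 0; j < c.clamp_idx.size(); ++j) clamped[c.clamp_idx[j]] = 1;
  // work holds the simulated node activities for all experiments
  if ((int)work.size() < n_nodes * c.n_exp) work.resize(n_nodes * c.n_exp);
  for (int e = 0; e < c.n_exp; ++e) {
    for (int j = 0; j < c.clamp_idx.size(); ++j)
      clampv[c.clamp_idx[j]] = c.clamp_vals(j, e);
    for (int n = 0; n < n_nodes; ++n) x[n] = clamped[n] ? clampv[n] : c.init;
    const double* k = &K[c.exp_ctx[e] * P];
    for (int s = 0; s < c.max_sweeps; ++s) {
      sweep_state(c.ia_target, c.ia_gate, c.ia_sign, c.ia_param, c.src,
                  c.src_ptr, c.has_in, k, clamped, clampv, x, xn, act, inh);
      double d = 0.0;
      for (int n = 0; n < n_nodes; ++n) {
        double err = std::fabs(xn[n] - x[n]);
        if (err > d) d = err;
      }
      x.swap(xn);
      if (d < c.tol) break;
    }
    std::copy(x.begin(), x.end(), work.begin() + (size_t)e * n_nodes);
  }
  double sse = 0.0;
  const int N = c.obs.size();
  for (int r = 0; r < N; ++r) {
    double diff = c.obs[r] - work[(size_t)c.row_exp[r] * n_nodes + c.row_node[r]];
    sse += diff * diff;
  }
  double val = sse / N;
  if (c.lambda1 > 0) {
    double p1 = 0.0;
    for (int i = 0; i < P * C; ++i) p1 += std::sqrt(K[i] + c.eps);
    val += c.lambda1 * p1;
  }
  if (c.lambda2 > 0 && C > 1) {
    double p2 = 0.0;
    for (int p = 0; p < P; ++p) {
      double m = 0.0;
      for (int ctx = 0; ctx < C; ++ctx) m += K[ctx * P + p];
      m /= C;
      for (int ctx = 0; ctx < C; ++ctx) {
        double d = K[ctx * P + p] - m;
        p2 += std::sqrt(d * d + c.eps);
      }
    }
    val += c.lambda2 * p2;
  }
  return val;
}

// [[Rcpp::export]]
double cpp_objective(NumericVector theta, List net, List spec) {
  ObjCtx c = make_ctx(net, spec);
  std::vector<double> K(c.P * c.C), work;
  return eval_objective(c, REAL(theta), K, work);
}

// Central-difference gradient of cpp_objective in theta.
// [[Rcpp::export]]
NumericVector cpp_objective_grad(NumericVector theta, List net, List spec,
                                 double h) {
  ObjCtx c = make_ctx(net, spec);
  const int d = theta.size();
  std::vector<double> th(REAL(theta), REAL(theta) + d);
  std::vector<double> K(c.P * c.C), work;
  NumericVector grad(d);
  for (int i = 0; i < d; ++i) {
    double orig = th[i];
    th[i] = orig + h;
    double fp = eval_objective(c, th.data(), K, work);
    th[i] = orig - h;
    double fm = eval_objective(c, th.data(), K, work);
    th[i] = orig;
    grad[i] = (fp - fm) / (2.0 * h);
  }
  return grad;
}
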