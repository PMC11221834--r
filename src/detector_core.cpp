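#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with explicit carry state so that a
// signal filtered in arbitrary chunks is bit-identical to one filtered whole.
// b, a: coefficients with a[0] == 1 (normalized by caller); zi: length
// max(len(a),len(b)) - 1.
// [[Rcpp::export(name = ".iir_filter_cpp")]]
List iir_filter_cpp(NumericVector x, NumericVector b, NumericVector a,
                    NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nz = std::max(na, nb) - 1;
  if (zi.size() != nz) stop("filter state has wrong length");
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(zi.begin(), zi.end());
  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    if (nz > 0) z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
    y[i] = yi;
  }
  return List::create(_["y"] = y, _["zf"] = NumericVector(z.begin(), z.end()));
}

// One-pass iterative baseline estimator over a vector of (already
// ripple-filtered) samples.  Recursions, applied to |x|:
//   mu'    = mu * (N-1)/N + |x|/N
//   sigma' = (||x| - mu| - sigma)/N + sigma      (mu = previous estimate)
// [[Rcpp::export(name = ".baseline_run_cpp")]]
List baseline_run_cpp(NumericVector x, double mu0, double sigma0,
                      double nsmooth, bool keep_path) {
  int n = x.size();
  double mu = mu0, sigma = sigma0;
  NumericVector mu_path, sigma_path;
  if (keep_path) { mu_path = NumericVector(n); sigma_path = NumericVector(n); }
  for (int i = 0; i < n; ++i) {
    double ax = std::fabs(x[i]);
    double mu_prev = mu;
    mu = mu_prev * (nsmooth - 1.0) / nsmooth + ax / nsmooth;
    sigma = (std::fabs(ax - mu_prev) - sigma) / nsmooth + sigma;
    if (keep_path) { mu_path[i] = mu; sigma_path[i] = sigma; }
  }
  List out = List::create(_["mu"] = mu, _["sigma"] = sigma);
  if (keep_path) { out["mu_path"] = mu_path; out["sigma_path"] = sigma_path; }
  return out;
}

struct EnvState {
  double v;
  std::vector<double> ghist;  // ring buffer, capacity 19
  int gpos;
  double glast;
  bool started;
};

static inline double env_step(EnvState &s, double ax, bool literal_gain) {
  if (!s.started) {            // first sample seeds the envelope
    s.v = ax;
    s.started = true;
    return s.v;
  }
  double g;
  if (ax <= s.v) {
    g = 0.2;
  } else {
    double sum = 1.2;
    for (size_t k = 0; k < s.ghist.size(); ++k) sum += s.ghist[k];
    g = sum / (1.0 + s.ghist.size());
  }
  double g_used = literal_gain ? s.glast : g;
  s.v = s.v + g_used * (ax - s.v);
  if (s.ghist.size() < 19) {
    s.ghist.push_back(g);
  } else {
    s.ghist[s.gpos] = g;
    s.gpos = (s.gpos + 1) % 19;
  }
  s.glast = g;
  return s.v;
}

static EnvState unpack_state(List st, int t) {
  EnvState s;
  NumericVector v = st["v"];
  NumericMatrix gh = st["ghist"];
  IntegerVector gn = st["gn"], gp = st["gpos"];
  NumericVector gl = st["glast"];
  LogicalVector started = st["started"];
  s.v = v[t];
  s.ghist.assign(gn[t], 0.0);
  for (int k = 0; k < gn[t]; ++k) s.ghist[k] = gh(k, t);
  s.gpos = gp[t];
  s.glast = gl[t];
  s.started = started[t];
  return s;
}

static void pack_state(List st, int t, const EnvState &s) {
  NumericVector v = st["v"];
  NumericMatrix gh = st["ghist"];
  IntegerVector gn = st["gn"], gp = st["gpos"];
  NumericVector gl = st["glast"];
  LogicalVector started = st["started"];
  v[t] = s.v;
  gn[t] = (int)s.ghist.size();
  for (size_t k = 0; k < s.ghist.size(); ++k) gh(k, t) = s.ghist[k];
  gp[t] = s.gpos;
  gl[t] = s.glast;
  started[t] = s.started;
}

// Streaming coincidence detector over a block of filtered samples.
// xf: n x ntet matrix of ripple-filtered LFP; state: envelope state list
// (modified copy returned); thr: absolute envelope threshold per tetrode;
// since_last: samples since last trigger (large => free).  Returns 1-based
// trigger sample indices within this block, the envelope traces, and the
// updated state, so chunked calls are bit-identical to a single call.
// [[Rcpp::export(name = ".detector_run_cpp")]]
List detector_run_cpp(NumericMatrix xf, List state, NumericVector thr,
                      int min_coincident, double lockout_samples,
                      double since_last, bool literal_gain, bool stop_at_first,
                      bool keep_env) {
  int n = xf.nrow(), ntet = xf.ncol();
  if (thr.size() != ntet) stop("threshold/tetrode count mismatch");
  std::vector<EnvState> st(ntet);
  List state2 = clone(state);
  for (int t = 0; t < ntet; ++t) st[t] = unpack_state(state2, t);
  std::vector<int> triggers;
  NumericMatrix env;
  if (keep_env) env = NumericMatrix(n, ntet);
  int i_stop = n;
  for (int i = 0; i < n; ++i) {
    int above = 0;
    for (int t = 0; t < ntet; ++t) {
      double v = env_step(st[t], std::fabs(xf(i, t)), literal_gain);
      if (keep_env) env(i, t) = v;
      if (v > thr[t]) ++above;
    }
    since_last += 1.0;
    if (above >= min_coincident && since_last > lockout_samples) {
      triggers.push_back(i + 1);
      since_last = 0.0;
      if (stop_at_first) { i_stop = i + 1; break; }
    }
  }
  for (int t = 0; t < ntet; ++t) pack_state(state2, t, st[t]);
  List out = List::create(
    _["triggers"] = IntegerVector(triggers.begin(), triggers.end()),
    _["state"] = state2, _["since_last"] = since_last,
    _["n_processed"] = i_stop);
  if (keep_env) out["env"] = env;
  return out;
}
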