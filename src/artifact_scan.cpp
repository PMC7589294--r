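#include <Rcpp.h>
using namespace Rcpp;

// Sequential validity scan: a sample is invalid when outside the plausibility
// limits or when it jumps by more than max_step relative to the previous
// *valid* sample AND to the immediately preceding raw sample.  The second
// reference stops a single borderline level shift from cascading: once the
// signal settles at a new level its samples agree with their raw
// predecessor and are accepted again.  The previous-valid reference makes
// the rule order-dependent, so it is kept as a tight loop here (10 Hz
// channels reach ~2e4 samples/run).
// [[Rcpp::export]]
LogicalVector artifact_scan_cpp(NumericVector value, double lo, double hi,
                                double max_step) {
  int n = value.size();
  LogicalVector valid(n);
  double prev_valid = 0.0;
  bool has_prev = false;
  bool use_step = R_finite(max_step);
  for (int i = 0; i < n; ++i) {
    double v = value[i];
    bool ok = R_finite(v) && v >= lo && v <= hi;
    if (ok && use_step && has_prev && std::abs(v - prev_valid) > max_step) {
      bool near_raw = i > 0 && R_finite(value[i - 1]) &&
        std::abs(v - value[i - 1]) <= max_step;
      if (!near_raw) ok = false;
    }
    valid[i] = ok;
    if (ok) { prev_valid = v; has_prev = true; }
  }
  return valid;
}
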