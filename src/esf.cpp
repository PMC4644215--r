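#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// log(exp(a) + exp(b)) with -Inf as the additive identity
static inline double logadd(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  return (a > b) ? a + log1p(exp(b - a)) : b + log1p(exp(a - b));
}

// log elementary symmetric functions of exp(logb), one item at a time.
// Working in logs is the rescaling: no intermediate can overflow.
void esf_log_into(const std::vector<double>& logb, std::vector<double>& lg) {
  int n = (int)logb.size();
  lg.assign(n + 1, R_NegInf);
  lg[0] = 0.0;
  for (int i = 0; i < n; ++i) {
    int top = (i + 1 < n) ? i + 1 : n;
    for (int s = top; s >= 1; --s)
      lg[s] = logadd(lg[s], lg[s - 1] + logb[i]);
  }
}

// [[Rcpp::export]]
NumericVector esf_log_cpp(NumericVector logb) {
  std::vector<double> in(logb.begin(), logb.end()), lg;
  esf_log_into(in, lg);
  return NumericVector(lg.begin(), lg.end());
}

// logsumexp over s of lg[s + shift] + loglam[s], s = 0..nlam-1; entries with
// s + shift outside [0, nlg) contribute gamma = 0.  'skip' (if >= 0) omits s.
double esf_weighted_lse(const std::vector<double>& lg,
                        const std::vector<double>& loglam,
                        int shift, int skip) {
  double acc = R_NegInf;
  int nlam = (int)loglam.size(), nlg = (int)lg.size();
  for (int s = 0; s < nlam; ++s) {
    if (s == skip) continue;
    int u = s + shift;
    if (u < 0 || u >= nlg) continue;
    acc = logadd(acc, lg[u] + loglam[s]);
  }
  return acc;
}

// log of the scale constant c in the item full conditional:
// c = sum_s gamma_{s-1}(b^{(i)}) lambda_s / sum_s gamma_s(b^{(i)}) lambda_s
// [[Rcpp::export]]
double item_fc_scale_cpp(NumericVector logb, NumericVector loglam, int i) {
  int n = logb.size();
  std::vector<double> red, lg;
  red.reserve(n - 1);
  for (int j = 0; j < n; ++j) if (j != i - 1) red.push_back(logb[j]);
  esf_log_into(red, lg);
  std::vector<double> ll(loglam.begin(), loglam.end());
  return esf_weighted_lse(lg, ll, -1, -1) - esf_weighted_lse(lg, ll, 0, -1);
}

// log of c = gamma_t(b) / sum_{s != t} gamma_s(b) lambda_s
// [[Rcpp::export]]
double lambda_fc_scale_cpp(NumericVector logb, NumericVector loglam, int t) {
  std::vector<double> in(logb.begin(), logb.end()), lg;
  esf_log_into(in, lg);
  std::vector<double> ll(loglam.begin(), loglam.end());
  return lg[t] - esf_weighted_lse(lg, ll, 0, t);
}
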