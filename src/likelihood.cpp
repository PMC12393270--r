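#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Model codes used across the package:
//   1 = standard delta-rule RL (alpha, beta)
//   2 = avgRPE RL             (alpha, beta, hW)
//   3 = global-reward-state   (alpha, beta, alphaR, wR)
//   4 = asymmetric 5-param    (alpha_pos, alpha_neg, gamma_pos, gamma_neg, beta)

static const double PROB_FLOOR = 1e-9;

inline double softmax_p1(double v1, double v2, double beta) {
  // probability of action 1; max-subtraction for overflow safety
  double m = std::max(v1, v2) * beta;
  double e1 = std::exp(v1 * beta - m);
  double e2 = std::exp(v2 * beta - m);
  return e1 / (e1 + e2);
}

// Negative log-likelihood of one or more sessions under one model.
// `session` marks session membership; values, avgRPE and Rtrace reset
// whenever it changes. Trials must be chronological within session.
// [[Rcpp::export]]
List cpp_rl_filter(IntegerVector choice, IntegerVector outcome,
                   IntegerVector session, int model, NumericVector params,
                   bool with_trace) {
  int n = choice.size();
  if (n == 0) stop("empty trial sequence");

  double alpha = 0, beta = 0, hW = 0, alphaR = 0, wR = 0;
  double a_pos = 0, a_neg = 0, g_pos = 0, g_neg = 0;
  switch (model) {
  case 1: alpha = params[0]; beta = params[1]; break;
  case 2: alpha = params[0]; beta = params[1]; hW = params[2]; break;
  case 3: alpha = params[0]; beta = params[1]; alphaR = params[2]; wR = params[3]; break;
  case 4: a_pos = params[0]; a_neg = params[1]; g_pos = params[2];
          g_neg = params[3]; beta = params[4]; break;
  default: stop("unknown model code");
  }

  NumericMatrix trace;
  if (with_trace) trace = NumericMatrix(n, 6);  // V1 V2 rpe avgrpe rtrace p_choice

  double nll = 0.0;
  double V1 = 0, V2 = 0, avg = 0, rtrace = 0;
  int prevR = 0;
  int cur_session = NA_INTEGER;

  for (int t = 0; t < n; ++t) {
    if (session[t] != cur_session) {            // session start: reset latents
      cur_session = session[t];
      V1 = 0; V2 = 0; avg = 0; rtrace = 0; prevR = 0;
      // first trial of a session leaves Rtrace at its initial value
    } else if (model == 3) {
      rtrace += (prevR - rtrace) * alphaR;
    }

    int c = choice[t];                          // 1 or 2
    int R = outcome[t];                         // 0 or 1
    double p1 = softmax_p1(V1, V2, beta);
    double p = (c == 1) ? p1 : (1.0 - p1);
    nll -= std::log(std::max(p, PROB_FLOOR));

    double Vc = (c == 1) ? V1 : V2;
    double rpe = 0;
    switch (model) {
    case 1:
      rpe = R - Vc;
      Vc += alpha * rpe;
      break;
    case 2:
      rpe = R - Vc;
      avg = alpha * rpe + hW * avg;
      Vc += avg;
      break;
    case 3:
      rpe = R + wR * rtrace - Vc;
      Vc += alpha * rpe;
      break;
    case 4: {
      rpe = R - Vc;
      double *Vu = (c == 1) ? &V2 : &V1;
      if (R == 1) { Vc += a_pos * rpe; *Vu *= g_pos; }
      else        { Vc += a_neg * rpe; *Vu *= g_neg; }
      break;
    }
    }
    if (c == 1) V1 = Vc; else V2 = Vc;
    prevR = R;

    if (with_trace) {
      trace(t, 0) = V1; trace(t, 1) = V2; trace(t, 2) = rpe;
      trace(t, 3) = avg; trace(t, 4) = rtrace; trace(t, 5) = p;
    }
  }

  if (with_trace)
    return List::create(_["nll"] = nll, _["trace"] = trace);
  return List::create(_["nll"] = nll);
}

// Plain nll entry point used by the optimizer (avoids List overhead).
// [[Rcpp::export]]
double cpp_rl_nll(IntegerVector choice, IntegerVector outcome,
                  IntegerVector session, int model, NumericVector params) {
  List out = cpp_rl_filter(choice, outcome, session, model, params, false);
  return as<double>(out["nll"]);
}
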