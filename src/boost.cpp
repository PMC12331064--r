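#include <RcppArmadillo.h>

using namespace arma;

// sum_t r[t] * x[t - tau], zero-padded outside [0, T)
static double shifted_dot(const rowvec& x, const vec& r, int tau) {
  const int T = r.n_elem;
  if (tau >= 0) {
    if (tau >= T) return 0.0;
    return dot(r.subvec(tau, T - 1), x.subvec(0, T - 1 - tau).t());
  }
  const int k = -tau;
  if (k >= T) return 0.0;
  return dot(r.subvec(0, T - 1 - k), x.subvec(k, T - 1).t());
}

// r += a * x shifted by tau
static void shifted_axpy(vec& r, const rowvec& x, int tau, double a) {
  const int T = r.n_elem;
  if (tau >= 0) {
    if (tau < T) r.subvec(tau, T - 1) += a * x.subvec(0, T - 1 - tau).t();
  } else {
    const int k = -tau;
    if (k < T) r.subvec(0, T - 1 - k) += a * x.subvec(k, T - 1).t();
  }
}

// sum over valid range of x[i, t - tau]^2 (per segment, aggregated by caller)
static double shifted_ss(const rowvec& x, int tau, int T) {
  if (tau >= 0) {
    if (tau >= T) return 0.0;
    rowvec s = x.subvec(0, T - 1 - tau);
    return dot(s, s);
  }
  const int k = -tau;
  if (k >= T) return 0.0;
  rowvec s = x.subvec(k, T - 1);
  return dot(s, s);
}

// Boosting coordinate descent for multivariate TRFs, fit jointly for all
// channels of a response matrix (channels share predictors, so the predictor
// auto-/cross-correlation tables are computed once).
//
// Xtr / Ytr: lists of P x Tk predictor and C x Tk response segments (already
// centered/scaled by the caller); Xval / Yval: the validation segment.
// Delays are tau_min .. tau_min + n_delays - 1 (in samples).
//
// Each step finds the single kernel element h[i, d] whose change by +/-delta
// minimizes the training sum of squared errors (ties: lowest predictor, then
// lowest delay, then +delta). If the accepted change increases validation SSE,
// it is reverted and predictor i's whole kernel is frozen. Fitting stops when
// all predictors are frozen, no candidate strictly improves training error, or
// max_steps is reached.
// [[Rcpp::export]]
Rcpp::List cpp_boost_multi(const Rcpp::List& Xtr, const Rcpp::List& Ytr,
                           const arma::mat& Xval, const arma::mat& Yval,
                           int tau_min, int n_delays, double delta,
                           int max_steps, bool record)
{
  const int nseg = Xtr.size();
  std::vector<mat> Xs(nseg);
  std::vector<mat> Ys(nseg);
  for (int s = 0; s < nseg; ++s) {
    Xs[s] = Rcpp::as<mat>(Xtr[s]);
    Ys[s] = Rcpp::as<mat>(Ytr[s]);
  }
  const int P = Xs[0].n_rows;
  const int D = n_delays;
  const int Cn = Ys[0].n_rows;

  // S[i,d]: training sum of squares of the shifted predictor; Sval likewise
  mat S(P, D, fill::zeros), Sval(P, D);
  for (int i = 0; i < P; ++i)
    for (int d = 0; d < D; ++d) {
      const int tau = tau_min + d;
      for (int s = 0; s < nseg; ++s)
        S(i, d) += shifted_ss(Xs[s].row(i), tau, Xs[s].n_cols);
      Sval(i, d) = shifted_ss(Xval.row(i), tau, Xval.n_cols);
    }

  // XX(j, i, g + D - 1) = sum_seg sum_u x_j[u] * x_i[u - g]  over the
  // edge-clipped overlap; this is the exact change in the residual/predictor
  // cross-correlation when a step is applied at lag difference g.
  cube XX(P, P, 2 * D - 1, fill::zeros);
  for (int g = 0; g < D; ++g) {
    for (int s = 0; s < nseg; ++s) {
      const int T = Xs[s].n_cols;
      if (g >= T) continue;
      for (int j = 0; j < P; ++j) {
        rowvec xj = Xs[s].row(j).subvec(g, T - 1);
        for (int i = 0; i < P; ++i) {
          const double v = dot(xj, Xs[s].row(i).subvec(0, T - 1 - g));
          XX(j, i, g + D - 1) += v;
          if (g > 0) XX(i, j, D - 1 - g) += v;
        }
      }
    }
  }

  cube Hout(P, D, Cn, fill::zeros);
  Rcpp::List steps_out(Cn), sse_out(Cn);

  for (int ch = 0; ch < Cn; ++ch) {
    std::vector<vec> r(nseg);
    double sse_tr = 0.0;
    for (int s = 0; s < nseg; ++s) {
      r[s] = Ys[s].row(ch).t();
      sse_tr += dot(r[s], r[s]);
    }
    vec rval = Yval.row(ch).t();
    double sse_val = dot(rval, rval);

    mat C(P, D);
    for (int i = 0; i < P; ++i)
      for (int d = 0; d < D; ++d) {
        double v = 0.0;
        for (int s = 0; s < nseg; ++s)
          v += shifted_dot(Xs[s].row(i), r[s], tau_min + d);
        C(i, d) = v;
      }

    std::vector<bool> frozen(P, false);
    int n_frozen = 0;
    mat h(P, D, fill::zeros);
    std::vector<double> sse_trace;
    std::vector<int> step_i, step_d, step_s;   // s = +1/-1 applied, 0 = freeze

    for (int step = 0; step < max_steps && n_frozen < P; ++step) {
      double bestd = 0.0;
      int bi = -1, bd = -1, bs = 0;
      for (int i = 0; i < P; ++i) {
        if (frozen[i]) continue;
        for (int d = 0; d < D; ++d) {
          const double dd = delta * delta * S(i, d);
          const double dp = -2.0 * delta * C(i, d) + dd;
          const double dm =  2.0 * delta * C(i, d) + dd;
          double cand; int sg;
          if (dp <= dm) { cand = dp; sg = 1; } else { cand = dm; sg = -1; }
          if (cand < bestd) { bestd = cand; bi = i; bd = d; bs = sg; }
        }
      }
      if (bi < 0) break;   // no candidate strictly improves training error

      const int tau = tau_min + bd;
      const double cval = shifted_dot(Xval.row(bi), rval, tau);
      const double dval = -2.0 * delta * bs * cval +
                          delta * delta * Sval(bi, bd);
      if (dval > 0.0) {    // validation error would increase: freeze predictor
        frozen[bi] = true;
        ++n_frozen;
        if (record) { step_i.push_back(bi); step_d.push_back(bd); step_s.push_back(0); }
        continue;
      }

      h(bi, bd) += bs * delta;
      for (int s = 0; s < nseg; ++s)
        shifted_axpy(r[s], Xs[s].row(bi), tau, -bs * delta);
      sse_tr += bestd;
      // Exact cross-correlation update. The full-range table XX covers
      // u with u in [1, T] and u - g in [1, T] (0-based: [0, T) each); the
      // residual change is additionally confined to frames t = u + tau2 in
      // [1, T], which excludes up to |tau2| edge terms that are corrected
      // here per segment.
      for (int j = 0; j < P; ++j)
        for (int d2 = 0; d2 < D; ++d2) {
          const int tau2 = tau_min + d2;
          const int g = bd - d2;           // tau - tau2
          double upd = XX(j, bi, g + D - 1);
          for (int s = 0; s < nseg; ++s) {
            const int T = Xs[s].n_cols;    // 0-based u range below
            const int u_lo = std::max(0, g);
            const int u_hi = std::min(T - 1, T - 1 + g);
            const int t_lo = std::max(u_lo, -tau2);
            const int t_hi = std::min(u_hi, T - 1 - tau2);
            for (int u = u_lo; u < t_lo && u <= u_hi; ++u)
              upd -= Xs[s](j, u) * Xs[s](bi, u - g);
            for (int u = std::max(t_hi + 1, u_lo); u <= u_hi; ++u)
              upd -= Xs[s](j, u) * Xs[s](bi, u - g);
          }
          C(j, d2) -= bs * delta * upd;
        }
      shifted_axpy(rval, Xval.row(bi), tau, -bs * delta);
      sse_val += dval;
      if (record) {
        step_i.push_back(bi); step_d.push_back(bd); step_s.push_back(bs);
        sse_trace.push_back(sse_tr);
      }
    }

    Hout.slice(ch) = h;
    if (record) {
      const int ns = step_i.size();
      imat st(ns, 3);
      for (int k = 0; k < ns; ++k) {
        st(k, 0) = step_i[k]; st(k, 1) = step_d[k]; st(k, 2) = step_s[k];
      }
      steps_out[ch] = st;
      sse_out[ch] = vec(sse_trace);
    }
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("h") = Hout);
  if (record) {
    out["steps"] = steps_out;
    out["sse"] = sse_out;
  }
  return out;
}

// yhat[t] = sum_i sum_d h[i, d] * x[i, t - (tau_min + d)], zero-padded
// [[Rcpp::export]]
arma::vec cpp_convolve(const arma::mat& h, const arma::mat& X, int tau_min) {
  const int P = X.n_rows, T = X.n_cols, D = h.n_cols;
  vec yhat(T, fill::zeros);
  for (int i = 0; i < P; ++i)
    for (int d = 0; d < D; ++d)
      if (h(i, d) != 0.0)
        shifted_axpy(yhat, X.row(i), tau_min + d, h(i, d));
  return yhat;
}
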