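#include <RcppArmadillo.h>

using namespace arma;

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// Run a stacked LSTM over one segment of B parallel streams, optionally with
// loss + full BPTT gradients.
//
// X: input_dim x (B*T), time-major blocks of B columns (column (t-1)*B + b is
//    stream b at frame t). Y, W: targets and per-element loss weights with the
//    same layout as the output (D x B*T); ignored when loss_type < 0.
// loss_type: 0 = weighted binary cross-entropy (sigmoid head),
//            1 = mean squared error (linear head), -1 = inference only.
// h0, c0: lists of h_l x B initial states (carried over from previous segment).
// Gate order within the stacked weight matrices is [input; forget; cell; output].
// [[Rcpp::export]]
Rcpp::List cpp_lstm_run(const Rcpp::List& weights, const arma::mat& X,
                        const arma::mat& Y, const arma::mat& W,
                        int B, int loss_type, bool out_sigmoid,
                        const Rcpp::List& h0, const Rcpp::List& c0,
                        bool grad, bool want_hidden, bool want_output)
{
  Rcpp::List layers = weights["layers"];
  mat Wy = Rcpp::as<mat>(weights["Wy"]);
  vec by = Rcpp::as<vec>(weights["by"]);
  const int L  = layers.size();
  const int BT = X.n_cols;
  const int T  = BT / B;

  std::vector<mat> Wxs(L), Whs(L);
  std::vector<vec> bs(L);
  for (int l = 0; l < L; ++l) {
    Rcpp::List lay = layers[l];
    Wxs[l] = Rcpp::as<mat>(lay["Wx"]);
    Whs[l] = Rcpp::as<mat>(lay["Wh"]);
    bs[l]  = Rcpp::as<vec>(lay["b"]);
  }

  std::vector<mat> I(L), F(L), G(L), O(L), C(L), TC(L), H(L), h0m(L), c0m(L);
  for (int l = 0; l < L; ++l) {
    h0m[l] = Rcpp::as<mat>(h0[l]);
    c0m[l] = Rcpp::as<mat>(c0[l]);
  }

  // ---- forward ----
  const mat* inp = &X;
  for (int l = 0; l < L; ++l) {
    const int hu = Whs[l].n_cols;
    mat Zx = Wxs[l] * (*inp);          // 4h x BT
    Zx.each_col() += bs[l];
    I[l].set_size(hu, BT); F[l].set_size(hu, BT); G[l].set_size(hu, BT);
    O[l].set_size(hu, BT); C[l].set_size(hu, BT); TC[l].set_size(hu, BT);
    H[l].set_size(hu, BT);
    mat h = h0m[l], c = c0m[l];        // hu x B
    for (int t = 0; t < T; ++t) {
      const span cols(t * B, t * B + B - 1);
      mat z  = Zx.cols(cols) + Whs[l] * h;
      mat i_ = sigm(z.rows(0, hu - 1));
      mat f_ = sigm(z.rows(hu, 2 * hu - 1));
      mat g_ = tanh(z.rows(2 * hu, 3 * hu - 1));
      mat o_ = sigm(z.rows(3 * hu, 4 * hu - 1));
      c = f_ % c + i_ % g_;
      mat tc = tanh(c);
      h = o_ % tc;
      I[l].cols(cols) = i_; F[l].cols(cols) = f_; G[l].cols(cols) = g_;
      O[l].cols(cols) = o_; C[l].cols(cols) = c; TC[l].cols(cols) = tc;
      H[l].cols(cols) = h;
    }
    inp = &H[l];
  }

  mat Z = Wy * H[L - 1];
  Z.each_col() += by;
  const double eps = 1e-7;
  mat P, dZ;
  double loss = NA_REAL;
  if (loss_type == 0) {
    P = sigm(Z);
    mat Pc = clamp(P, eps, 1.0 - eps);
    const double norm = (double)Z.n_rows * BT;
    loss = -accu(W % (Y % log(Pc) + (1.0 - Y) % log(1.0 - Pc))) / norm;
    if (grad) dZ = (W % (P - Y)) / norm;
  } else if (loss_type == 1) {
    P = Z;
    const double norm = (double)Z.n_rows * BT;
    loss = accu(square(P - Y)) / norm;
    if (grad) dZ = 2.0 * (P - Y) / norm;
  } else {
    P = out_sigmoid ? sigm(Z) : Z;
  }

  Rcpp::List hfin(L), cfin(L);
  for (int l = 0; l < L; ++l) {
    hfin[l] = H[l].cols((T - 1) * B, BT - 1);
    cfin[l] = C[l].cols((T - 1) * B, BT - 1);
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("h_final") = hfin,
    Rcpp::Named("c_final") = cfin);

  // ---- backward ----
  if (grad) {
    mat dWy = dZ * H[L - 1].t();
    vec dby = sum(dZ, 1);
    mat dH  = Wy.t() * dZ;             // flows into top layer's h
    Rcpp::List glayers(L);
    for (int l = L - 1; l >= 0; --l) {
      const int hu = Whs[l].n_cols;
      mat dZall(4 * hu, BT);
      mat dh_next(hu, B, fill::zeros), dc_next(hu, B, fill::zeros);
      for (int t = T - 1; t >= 0; --t) {
        const span cols(t * B, t * B + B - 1);
        mat dh = dH.cols(cols) + dh_next;
        mat o_ = O[l].cols(cols), tc = TC[l].cols(cols);
        mat i_ = I[l].cols(cols), f_ = F[l].cols(cols), g_ = G[l].cols(cols);
        mat da_o = (dh % tc) % o_ % (1.0 - o_);
        mat dc   = dh % o_ % (1.0 - tc % tc) + dc_next;
        mat c_prev = (t == 0) ? c0m[l] : mat(C[l].cols((t - 1) * B, t * B - 1));
        mat da_f = (dc % c_prev) % f_ % (1.0 - f_);
        mat da_i = (dc % g_) % i_ % (1.0 - i_);
        mat da_g = (dc % i_) % (1.0 - g_ % g_);
        dc_next  = dc % f_;
        mat da = join_cols(join_cols(da_i, da_f), join_cols(da_g, da_o));
        dZall.cols(cols) = da;
        dh_next = Whs[l].t() * da;
      }
      mat Hm1(hu, BT);                 // h_{t-1}, time-shifted hidden states
      Hm1.cols(0, B - 1) = h0m[l];
      if (T > 1) Hm1.cols(B, BT - 1) = H[l].cols(0, BT - B - 1);
      const mat& inl = (l == 0) ? X : H[l - 1];
      glayers[l] = Rcpp::List::create(
        Rcpp::Named("Wx") = mat(dZall * inl.t()),
        Rcpp::Named("Wh") = mat(dZall * Hm1.t()),
        Rcpp::Named("b")  = vec(sum(dZall, 1)));
      if (l > 0) dH = Wxs[l].t() * dZall;
    }
    out["grads"] = Rcpp::List::create(
      Rcpp::Named("layers") = glayers,
      Rcpp::Named("Wy") = dWy, Rcpp::Named("by") = dby);
  }

  if (want_output) out["outputs"] = P;
  if (want_hidden) {
    Rcpp::List hl(L);
    for (int l = 0; l < L; ++l) hl[l] = H[l];
    out["hidden"] = hl;
  }
  return out;
}
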