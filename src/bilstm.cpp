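// Bidirectional LSTM sequence regressor: batched forward pass and
// backpropagation through time. Parameters are plain R matrices so the
// training loop (Adam, early stopping, checkpointing) stays in R.
//
// Layout
//   X      : cube (N, F, L)  -- batch, features, timesteps
//   gates  : rows of Wx/Wh packed [input; forget; cell; output], 4H x *
//   flatten: per timestep t the forward then backward hidden state,
//            giving N x (L*2H); optional demographics appended
//   head   : FC1 (ReLU) then FC2 (linear, 2 outputs: SBP, DBP)
//   loss   : mean squared error over all N*2 outputs
//
// Dropout masks (variational: fixed across timesteps) are supplied by the
// caller, already inverted-scaled; pass matrices of ones for inference.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::cube;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct DirState {
  cube gi, gf, gg, go, tc, cprev, hm, xm; // per processing step k
  mat hout_at_t;                          // not used; outputs stored in Z
};

// [[Rcpp::export]]
List cpp_bilstm_pass(const List& params, const arma::cube& X,
                     const arma::mat& demo, const arma::mat& y,
                     const arma::mat& mask_x_f, const arma::mat& mask_h_f,
                     const arma::mat& mask_x_b, const arma::mat& mask_h_b,
                     bool compute_grad) {
  const mat Wxf = params["Wx_f"], Whf = params["Wh_f"];
  const mat Wxb = params["Wx_b"], Whb = params["Wh_b"];
  const arma::vec bf = params["b_f"], bb = params["b_b"];
  const mat W1 = params["W1"], W2 = params["W2"];
  const arma::vec b1 = params["b1"], b2 = params["b2"];

  const arma::uword N = X.n_rows, F = X.n_cols, L = X.n_slices;
  const arma::uword H = Whf.n_cols;
  const bool use_demo = demo.n_cols > 0;
  const arma::uword D = L * 2 * H + demo.n_cols;
  if (W1.n_cols != D) stop("FC1 width mismatch: expected %d", (int)D);

  mat Z(N, L * 2 * H, arma::fill::zeros);
  DirState st[2];
  for (int dir = 0; dir < 2; ++dir) {
    const bool fwd = dir == 0;
    const mat& Wx = fwd ? Wxf : Wxb;
    const mat& Wh = fwd ? Whf : Whb;
    const arma::vec& b = fwd ? bf : bb;
    const mat& mx = fwd ? mask_x_f : mask_x_b;
    const mat& mh = fwd ? mask_h_f : mask_h_b;
    DirState& s = st[dir];
    if (compute_grad) {
      s.gi.set_size(N, H, L); s.gf.set_size(N, H, L);
      s.gg.set_size(N, H, L); s.go.set_size(N, H, L);
      s.tc.set_size(N, H, L); s.cprev.set_size(N, H, L);
      s.hm.set_size(N, H, L); s.xm.set_size(N, F, L);
    }
    mat h(N, H, arma::fill::zeros), c(N, H, arma::fill::zeros);
    for (arma::uword k = 0; k < L; ++k) {
      const arma::uword t = fwd ? k : (L - 1 - k);
      mat xm = X.slice(t) % mx;
      mat hm = h % mh;
      mat a = xm * Wx.t() + hm * Wh.t();
      a.each_row() += b.t();
      mat gi = sigm(a.cols(0, H - 1));
      mat gf = sigm(a.cols(H, 2 * H - 1));
      mat gg = arma::tanh(a.cols(2 * H, 3 * H - 1));
      mat go = sigm(a.cols(3 * H, 4 * H - 1));
      if (compute_grad) {
        s.cprev.slice(k) = c;
        s.hm.slice(k) = hm;
        s.xm.slice(k) = xm;
        s.gi.slice(k) = gi; s.gf.slice(k) = gf;
        s.gg.slice(k) = gg; s.go.slice(k) = go;
      }
      c = gf % c + gi % gg;
      mat tc = arma::tanh(c);
      h = go % tc;
      if (compute_grad) s.tc.slice(k) = tc;
      const arma::uword off = t * 2 * H + (fwd ? 0 : H);
      Z.cols(off, off + H - 1) = h;
    }
  }

  mat Zd = use_demo ? arma::join_rows(Z, demo) : Z;
  mat A1 = Zd * W1.t();
  A1.each_row() += b1.t();
  mat R1 = arma::clamp(A1, 0.0, arma::datum::inf);
  mat out = R1 * W2.t();
  out.each_row() += b2.t();

  if (y.n_rows == 0)
    return List::create(_["pred"] = out);

  mat err = out - y;
  double loss = arma::accu(arma::square(err)) / (double)(N * 2);
  if (!compute_grad)
    return List::create(_["pred"] = out, _["loss"] = loss);

  mat dOut = 2.0 * err / (double)(N * 2);
  mat gW2 = dOut.t() * R1;
  arma::vec gb2 = arma::sum(dOut, 0).t();
  mat dR1 = dOut * W2;
  mat dA1 = dR1 % (A1 > 0);
  mat gW1 = dA1.t() * Zd;
  arma::vec gb1 = arma::sum(dA1, 0).t();
  mat dZd = dA1 * W1;
  mat dZ = dZd.cols(0, L * 2 * H - 1);

  mat gWx[2], gWh[2];
  arma::vec gb[2];
  for (int dir = 0; dir < 2; ++dir) {
    const bool fwd = dir == 0;
    const mat& Wx = fwd ? Wxf : Wxb;
    const mat& Wh = fwd ? Whf : Whb;
    const mat& mh = fwd ? mask_h_f : mask_h_b;
    DirState& s = st[dir];
    gWx[dir].zeros(4 * H, F);
    gWh[dir].zeros(4 * H, H);
    gb[dir].zeros(4 * H);
    mat dh_next(N, H, arma::fill::zeros), dc_next(N, H, arma::fill::zeros);
    for (arma::uword kk = L; kk-- > 0;) {
      const arma::uword t = fwd ? kk : (L - 1 - kk);
      const arma::uword off = t * 2 * H + (fwd ? 0 : H);
      mat dh = dZ.cols(off, off + H - 1) + dh_next;
      const mat& gi = s.gi.slice(kk); const mat& gf = s.gf.slice(kk);
      const mat& gg = s.gg.slice(kk); const mat& go = s.go.slice(kk);
      const mat& tc = s.tc.slice(kk);
      mat dc = dh % go % (1.0 - arma::square(tc)) + dc_next;
      mat da(N, 4 * H);
      da.cols(0, H - 1) = dc % gg % gi % (1.0 - gi);
      da.cols(H, 2 * H - 1) = dc % s.cprev.slice(kk) % gf % (1.0 - gf);
      da.cols(2 * H, 3 * H - 1) = dc % gi % (1.0 - arma::square(gg));
      da.cols(3 * H, 4 * H - 1) = dh % tc % go % (1.0 - go);
      gWx[dir] += da.t() * s.xm.slice(kk);
      gWh[dir] += da.t() * s.hm.slice(kk);
      gb[dir] += arma::sum(da, 0).t();
      dh_next = (da * Wh) % mh;
      dc_next = dc % gf;
    }
  }

  return List::create(
    _["pred"] = out, _["loss"] = loss,
    _["grads"] = List::create(
      _["Wx_f"] = gWx[0], _["Wh_f"] = gWh[0], _["b_f"] = gb[0],
      _["Wx_b"] = gWx[1], _["Wh_b"] = gWh[1], _["b_b"] = gb[1],
      _["W1"] = gW1, _["b1"] = gb1, _["W2"] = gW2, _["b2"] = gb2));
}
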