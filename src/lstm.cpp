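#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;

// Stacked LSTM with a linear head for scalar input sequences, in single
// precision (the conventional arithmetic for this model class).
//
// Parameter list layout (numeric matrices on the R side):
//   W[l]: in_l x 4u  input projection (in_0 = 1, in_l = u for l > 0)
//   U[l]: u x 4u     recurrent projection
//   b[l]: 1 x 4u     gate bias
//   Wd:   u x n_out  dense head weights
//   bd:   1 x n_out  dense head bias
// Gate column blocks in order: input i, forget f, candidate g, output o.
//
// Sequences are stored time-stacked: an (B*T x k) matrix whose row block
// [t*B, (t+1)*B) holds step t, so the input projection of a whole sequence
// is a single GEMM; only the recurrent products stay inside the time loop.

#if defined(__SSE2__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif

// Vanishing gradients decay below single-precision normal range within a few
// dozen time steps; subnormal arithmetic stalls the backward pass badly, so
// flush-to-zero is enabled for the numeric kernels.
static inline void enable_ftz() {
#if defined(__SSE2__)
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
}

struct Net {
  std::vector<fmat> W, U;
  std::vector<frowvec> b;
  fmat Wd;
  frowvec bd;
  uword L;
  std::vector<uword> u;
};

static Net unpack(const List &params) {
  Net net;
  List W = params["W"], U = params["U"], b = params["b"];
  net.L = W.size();
  for (uword l = 0; l < net.L; ++l) {
    net.W.push_back(conv_to<fmat>::from(Rcpp::as<mat>(W[l])));
    net.U.push_back(conv_to<fmat>::from(Rcpp::as<mat>(U[l])));
    net.b.push_back(conv_to<fmat>::from(Rcpp::as<mat>(b[l])).row(0));
  }
  net.Wd = conv_to<fmat>::from(Rcpp::as<mat>(params["Wd"]));
  net.bd = conv_to<fmat>::from(Rcpp::as<mat>(params["bd"])).row(0);
  for (uword l = 0; l < net.L; ++l) net.u.push_back(net.U[l].n_rows);
  return net;
}

static inline fmat sigm(const fmat &x) { return 1.0f / (1.0f + exp(-x)); }

// X arrives as (B x T); stack it to (B*T x 1).
static fmat stack_input(const mat &X) {
  fmat Xf = conv_to<fmat>::from(X);
  fmat st(Xf.n_rows * Xf.n_cols, 1);
  for (uword t = 0; t < Xf.n_cols; ++t)
    st.submat(t * Xf.n_rows, 0, (t + 1) * Xf.n_rows - 1, 0) = Xf.col(t);
  return st;
}

struct Cache {
  // per layer, time-stacked (B*T x u)
  std::vector<fmat> I, F, G, O, C, H;
};

static fmat forward(const Net &net, const fmat &Xst, uword B, uword T,
                    Cache *cache) {
  fmat in = Xst;
  fmat hT;
  for (uword l = 0; l < net.L; ++l) {
    const uword u = net.u[l];
    fmat P = in * net.W[l];
    P.each_row() += net.b[l];
    fmat Hst(B * T, u), Ist, Fst, Gst, Ost, Cst;
    if (cache) {
      Ist.set_size(B * T, u); Fst.set_size(B * T, u);
      Gst.set_size(B * T, u); Ost.set_size(B * T, u);
      Cst.set_size(B * T, u);
    }
    fmat h(B, u, fill::zeros), c(B, u, fill::zeros);
    for (uword t = 0; t < T; ++t) {
      const uword r0 = t * B, r1 = (t + 1) * B - 1;
      fmat A = P.rows(r0, r1) + h * net.U[l];
      fmat gi = sigm(A.cols(0, u - 1));
      fmat gf = sigm(A.cols(u, 2 * u - 1));
      fmat gg = tanh(A.cols(2 * u, 3 * u - 1));
      fmat go = sigm(A.cols(3 * u, 4 * u - 1));
      c = gf % c + gi % gg;
      h = go % tanh(c);
      Hst.rows(r0, r1) = h;
      if (cache) {
        Ist.rows(r0, r1) = gi; Fst.rows(r0, r1) = gf;
        Gst.rows(r0, r1) = gg; Ost.rows(r0, r1) = go;
        Cst.rows(r0, r1) = c;
      }
    }
    if (cache) {
      cache->I.push_back(std::move(Ist)); cache->F.push_back(std::move(Fst));
      cache->G.push_back(std::move(Gst)); cache->O.push_back(std::move(Ost));
      cache->C.push_back(std::move(Cst)); cache->H.push_back(Hst);
    }
    if (l + 1 == net.L) hT = Hst.rows((T - 1) * B, T * B - 1);
    in = std::move(Hst);
  }
  fmat yhat = hT * net.Wd;
  yhat.each_row() += net.bd;
  return yhat;
}

//' @noRd
// [[Rcpp::export(name = ".bc_lstm_forward")]]
arma::mat bc_lstm_forward(const Rcpp::List &params, const arma::mat &X) {
  enable_ftz();
  Net net = unpack(params);
  const uword B = X.n_rows, T = X.n_cols;
  fmat Xst = stack_input(X);
  fmat yhat = forward(net, Xst, B, T, nullptr);
  return conv_to<mat>::from(yhat);
}

//' @noRd
// [[Rcpp::export(name = ".bc_lstm_grad")]]
Rcpp::List bc_lstm_grad(const Rcpp::List &params, const arma::mat &X,
                        const arma::mat &Y) {
  enable_ftz();
  Net net = unpack(params);
  const uword B = X.n_rows, T = X.n_cols, L = net.L;
  fmat Xst = stack_input(X);
  Cache cache;
  fmat yhat = forward(net, Xst, B, T, &cache);

  fmat Yf = conv_to<fmat>::from(Y);
  const uword n_out = net.Wd.n_cols;
  fmat E = yhat - Yf;
  const double loss = accu(conv_to<mat>::from(E % E)) / (double)(B * n_out);
  fmat dY = 2.0f * E / (float)(B * n_out);

  fmat hT = cache.H[L - 1].rows((T - 1) * B, T * B - 1);
  fmat gWd = hT.t() * dY;
  fmat gbd = sum(dY, 0);

  std::vector<fmat> gW(L), gU(L), gb(L);
  fmat dAbove; // time-stacked gradient arriving from the layer above
  for (uword li = L; li-- > 0;) {
    const uword u = net.u[li];
    const fmat &I = cache.I[li], &F = cache.F[li], &G = cache.G[li],
               &O = cache.O[li], &C = cache.C[li], &H = cache.H[li];
    fmat dAst(B * T, 4 * u);
    fmat gUl(u, 4 * u, fill::zeros);
    fmat dh_rec(B, u, fill::zeros), dc_rec(B, u, fill::zeros);
    for (uword t = T; t-- > 0;) {
      const uword r0 = t * B, r1 = (t + 1) * B - 1;
      fmat dh = dh_rec;
      if (li == L - 1) {
        if (t == T - 1) dh += dY * net.Wd.t();
      } else {
        dh += dAbove.rows(r0, r1);
      }
      fmat It = I.rows(r0, r1), Ft = F.rows(r0, r1), Gt = G.rows(r0, r1),
           Ot = O.rows(r0, r1);
      fmat tc = tanh(C.rows(r0, r1));
      fmat dc = dc_rec + dh % Ot % (1.0f - tc % tc);
      fmat cprev = (t > 0) ? fmat(C.rows(r0 - B, r0 - 1))
                           : fmat(B, u, fill::zeros);
      dAst.submat(r0, 0, r1, u - 1) = dc % Gt % It % (1.0f - It);
      dAst.submat(r0, u, r1, 2 * u - 1) = dc % cprev % Ft % (1.0f - Ft);
      dAst.submat(r0, 2 * u, r1, 3 * u - 1) = dc % It % (1.0f - Gt % Gt);
      dAst.submat(r0, 3 * u, r1, 4 * u - 1) = dh % tc % Ot % (1.0f - Ot);
      fmat dA = dAst.rows(r0, r1);
      fmat hprev = (t > 0) ? fmat(H.rows(r0 - B, r0 - 1))
                           : fmat(B, u, fill::zeros);
      gUl += hprev.t() * dA;
      dh_rec = dA * net.U[li].t();
      dc_rec = dc % Ft;
    }
    const fmat &Xin = (li == 0) ? Xst : cache.H[li - 1];
    gW[li] = Xin.t() * dAst;
    gU[li] = gUl;
    gb[li] = sum(dAst, 0);
    if (li > 0) dAbove = dAst * net.W[li].t();
  }

  List lW(L), lU(L), lb(L);
  for (uword l = 0; l < L; ++l) {
    lW[l] = conv_to<mat>::from(gW[l]);
    lU[l] = conv_to<mat>::from(gU[l]);
    lb[l] = conv_to<mat>::from(gb[l]);
  }
  return List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("grads") = List::create(
          Rcpp::Named("W") = lW, Rcpp::Named("U") = lU, Rcpp::Named("b") = lb,
          Rcpp::Named("Wd") = conv_to<mat>::from(gWd),
          Rcpp::Named("bd") = conv_to<mat>::from(gbd)));
}
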