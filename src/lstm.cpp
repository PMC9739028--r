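// Per-timestep LSTM sequence classifier: forward pass, full-sequence BPTT,
// Adam updates.  Parameters travel as a named R list of dense matrices so the
// whole model state is serialisable from R without extra machinery.
//
// Gate layout in the stacked pre-activation vector (rows of Wx/Wh/b):
//   [0,H)   input gate  i   (sigmoid)
//   [H,2H)  forget gate f   (sigmoid)
//   [2H,3H) candidate   g   (tanh)
//   [3H,4H) output gate o   (sigmoid)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Params {
  mat Wx, Wh, Wy;
  vec b, by;
};

Params unpack(const Rcpp::List& p) {
  Params P;
  P.Wx = Rcpp::as<mat>(p["Wx"]);
  P.Wh = Rcpp::as<mat>(p["Wh"]);
  P.Wy = Rcpp::as<mat>(p["Wy"]);
  P.b  = Rcpp::as<vec>(p["b"]);
  P.by = Rcpp::as<vec>(p["by"]);
  return P;
}

Rcpp::List pack(const Params& P) {
  return Rcpp::List::create(Rcpp::Named("Wx") = P.Wx,
                            Rcpp::Named("Wh") = P.Wh,
                            Rcpp::Named("b")  = P.b,
                            Rcpp::Named("Wy") = P.Wy,
                            Rcpp::Named("by") = P.by);
}

struct Cache {
  mat I, F, G, O, C, Th, H, Prob;
};

inline vec sigm(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

// X is n_features x T.  Fills the cache with gate activations, cell and
// hidden states and per-timestep class probabilities.
void forward(const Params& P, const mat& X, Cache& K) {
  const uword T = X.n_cols;
  const uword H = P.Wh.n_cols;
  mat A = P.Wx * X;
  A.each_col() += P.b;
  K.I.set_size(H, T);  K.F.set_size(H, T);  K.G.set_size(H, T);
  K.O.set_size(H, T);  K.C.set_size(H, T);  K.Th.set_size(H, T);
  K.H.set_size(H, T);
  vec h(H, fill::zeros), c(H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    vec a = A.col(t) + P.Wh * h;
    vec i = sigm(a.subvec(0, H - 1));
    vec f = sigm(a.subvec(H, 2 * H - 1));
    vec g = tanh(a.subvec(2 * H, 3 * H - 1));
    vec o = sigm(a.subvec(3 * H, 4 * H - 1));
    c = f % c + i % g;
    vec th = tanh(c);
    h = o % th;
    K.I.col(t) = i;  K.F.col(t) = f;  K.G.col(t) = g;  K.O.col(t) = o;
    K.C.col(t) = c;  K.Th.col(t) = th;  K.H.col(t) = h;
  }
  mat Z = P.Wy * K.H;
  Z.each_col() += P.by;
  Z.each_row() -= max(Z, 0);  // stabilised softmax
  K.Prob = exp(Z);
  K.Prob.each_row() /= sum(K.Prob, 0);
}

// Mean per-timestep cross-entropy for integer labels y in {0, .., C-1}.
double ce_loss(const mat& Prob, const uvec& y) {
  const uword T = Prob.n_cols;
  double s = 0.0;
  for (uword t = 0; t < T; ++t)
    s -= std::log(std::max(Prob(y[t], t), 1e-12));
  return s / static_cast<double>(T);
}

// Gradients of the mean cross-entropy w.r.t. all parameters.
void backward(const Params& P, const mat& X, const uvec& y, const Cache& K,
              Params& G) {
  const uword T = X.n_cols;
  const uword H = P.Wh.n_cols;
  mat dZ = K.Prob;  // C x T
  for (uword t = 0; t < T; ++t) dZ(y[t], t) -= 1.0;
  dZ /= static_cast<double>(T);

  G.Wy = dZ * K.H.t();
  G.by = sum(dZ, 1);

  mat dHout = P.Wy.t() * dZ;  // H x T, contribution through the dense layer
  mat dA(4 * H, T);
  vec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    vec dh = dHout.col(tt) + dh_next;
    vec i = K.I.col(tt), f = K.F.col(tt), g = K.G.col(tt), o = K.O.col(tt);
    vec th = K.Th.col(tt);
    vec dc = dh % o % (1.0 - th % th) + dc_next;
    vec cprev = (tt == 0) ? vec(H, fill::zeros) : vec(K.C.col(tt - 1));
    vec da(4 * H);
    da.subvec(0, H - 1)         = (dc % g) % i % (1.0 - i);
    da.subvec(H, 2 * H - 1)     = (dc % cprev) % f % (1.0 - f);
    da.subvec(2 * H, 3 * H - 1) = (dc % i) % (1.0 - g % g);
    da.subvec(3 * H, 4 * H - 1) = (dh % th) % o % (1.0 - o);
    dA.col(tt) = da;
    dh_next = P.Wh.t() * da;
    dc_next = dc % f;
  }
  G.Wx = dA * X.t();
  G.b  = sum(dA, 1);
  if (T > 1)
    G.Wh = dA.cols(1, T - 1) * K.H.cols(0, T - 2).t();
  else
    G.Wh = zeros<mat>(4 * H, H);
}

struct Adam {
  Params m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  explicit Adam(const Params& P) {
    m.Wx = zeros<mat>(size(P.Wx));  v.Wx = zeros<mat>(size(P.Wx));
    m.Wh = zeros<mat>(size(P.Wh));  v.Wh = zeros<mat>(size(P.Wh));
    m.Wy = zeros<mat>(size(P.Wy));  v.Wy = zeros<mat>(size(P.Wy));
    m.b  = zeros<vec>(P.b.n_elem);  v.b  = zeros<vec>(P.b.n_elem);
    m.by = zeros<vec>(P.by.n_elem); v.by = zeros<vec>(P.by.n_elem);
  }

  template <typename M>
  void upd1(M& p, const M& g, M& mm, M& vv, double lr) {
    mm = b1 * mm + (1.0 - b1) * g;
    vv = b2 * vv + (1.0 - b2) * (g % g);
    M mh = mm / (1.0 - std::pow(b1, (double)step));
    M vh = vv / (1.0 - std::pow(b2, (double)step));
    p -= lr * mh / (sqrt(vh) + eps);
  }

  void update(Params& P, const Params& G, double lr) {
    ++step;
    upd1(P.Wx, G.Wx, m.Wx, v.Wx, lr);
    upd1(P.Wh, G.Wh, m.Wh, v.Wh, lr);
    upd1(P.Wy, G.Wy, m.Wy, v.Wy, lr);
    upd1(P.b,  G.b,  m.b,  v.b,  lr);
    upd1(P.by, G.by, m.by, v.by, lr);
  }
};

double grad_norm(const Params& G) {
  double s = accu(square(G.Wx)) + accu(square(G.Wh)) + accu(square(G.Wy)) +
             accu(square(G.b)) + accu(square(G.by));
  return std::sqrt(s);
}

void scale_grads(Params& G, double f) {
  G.Wx *= f;  G.Wh *= f;  G.Wy *= f;  G.b *= f;  G.by *= f;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_lstm_forward(Rcpp::List params, Rcpp::NumericMatrix x) {
  Params P = unpack(params);
  mat X = Rcpp::as<mat>(x);
  if (X.n_rows != P.Wx.n_cols)
    Rcpp::stop("input has %d channels; model expects %d", (int)X.n_rows,
               (int)P.Wx.n_cols);
  Cache K;
  forward(P, X, K);
  return Rcpp::wrap(K.Prob);
}

// Trains on a list of sequences (each n_features x T) with integer label
// vectors; one Adam update per sequence, sequences visited in the given
// order every epoch (deterministic given the initial parameters).
// [[Rcpp::export]]
Rcpp::List cpp_lstm_train(Rcpp::List params, Rcpp::List xs, Rcpp::List ys,
                          int epochs, double lr, double grad_clip) {
  Params P = unpack(params);
  const int n_seq = xs.size();
  if (n_seq == 0) Rcpp::stop("no training sequences");
  std::vector<mat> X(n_seq);
  std::vector<uvec> Y(n_seq);
  for (int s = 0; s < n_seq; ++s) {
    X[s] = Rcpp::as<mat>(xs[s]);
    Y[s] = Rcpp::as<uvec>(ys[s]);
    if (X[s].n_cols != Y[s].n_elem)
      Rcpp::stop("sequence %d: %d timesteps but %d labels", s + 1,
                 (int)X[s].n_cols, (int)Y[s].n_elem);
  }
  Adam opt(P);
  Cache K;
  Params G;
  Rcpp::NumericVector epoch_loss(epochs);
  for (int e = 0; e < epochs; ++e) {
    double tot = 0.0;
    for (int s = 0; s < n_seq; ++s) {
      forward(P, X[s], K);
      double loss = ce_loss(K.Prob, Y[s]);
      if (!std::isfinite(loss))
        Rcpp::stop("non-finite loss at epoch %d, sequence %d", e + 1, s + 1);
      tot += loss;
      backward(P, X[s], Y[s], K, G);
      if (grad_clip > 0) {
        double nrm = grad_norm(G);
        if (nrm > grad_clip) scale_grads(G, grad_clip / nrm);
      }
      opt.update(P, G, lr);
    }
    epoch_loss[e] = tot / n_seq;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = pack(P),
                            Rcpp::Named("epoch_loss") = epoch_loss);
}
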