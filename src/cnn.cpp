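// Convolutional motor-state classifier: 1-D temporal conv blocks
// (convolution + batch normalization + ReLU, valid padding) followed by a
// fully-connected head, soft-label cross-entropy loss, Adam updates.
//
// Data layout: a batch is a matrix X of shape (C0 * L0, N); each column is
// one window with the channel index fastest, i.e. element (c + C0*l, n).
// Conv weights W are (Cout, Cin * k) with column index (c + Cin*tap), which
// matches arma::vectorise of the (Cin, k) input patch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;
using arma::uword;

namespace {

const double BN_EPS = 1e-5;

struct ConvParams {
  mat W; vec b, gamma, beta, rmean, rvar;
  int k, s, Cin, Cout;
};

struct FcParams { mat W; vec b; };

struct Net {
  std::vector<ConvParams> blocks;
  std::vector<FcParams> fcs;
  int C0, L0;
};

Net load_net(const List& params, const List& spec) {
  Net net;
  net.C0 = as<int>(spec["input_channels"]);
  net.L0 = as<int>(spec["input_len"]);
  IntegerVector kk = spec["kernels"], ss = spec["strides"];
  List blocks = params["blocks"];
  int Cin = net.C0;
  for (int i = 0; i < blocks.size(); ++i) {
    List b = blocks[i];
    ConvParams cp;
    cp.W = as<mat>(b["W"]); cp.b = as<vec>(b["b"]);
    cp.gamma = as<vec>(b["gamma"]); cp.beta = as<vec>(b["beta"]);
    cp.rmean = as<vec>(b["rmean"]); cp.rvar = as<vec>(b["rvar"]);
    cp.k = kk[i]; cp.s = ss[i];
    cp.Cin = Cin; cp.Cout = cp.W.n_rows;
    if ((int)cp.W.n_cols != cp.Cin * cp.k)
      stop("conv block %d: weight shape (%d x %d) does not match Cin*k = %d",
           i + 1, (int)cp.W.n_rows, (int)cp.W.n_cols, cp.Cin * cp.k);
    Cin = cp.Cout;
    net.blocks.push_back(cp);
  }
  List fcs = params["fc"];
  for (int j = 0; j < fcs.size(); ++j) {
    List f = fcs[j];
    FcParams fp; fp.W = as<mat>(f["W"]); fp.b = as<vec>(f["b"]);
    net.fcs.push_back(fp);
  }
  return net;
}

List dump_net(const Net& net) {
  List blocks(net.blocks.size());
  for (size_t i = 0; i < net.blocks.size(); ++i) {
    const ConvParams& cp = net.blocks[i];
    blocks[i] = List::create(_["W"] = cp.W, _["b"] = cp.b,
                             _["gamma"] = cp.gamma, _["beta"] = cp.beta,
                             _["rmean"] = cp.rmean, _["rvar"] = cp.rvar);
  }
  List fcs(net.fcs.size());
  for (size_t j = 0; j < net.fcs.size(); ++j)
    fcs[j] = List::create(_["W"] = net.fcs[j].W, _["b"] = net.fcs[j].b);
  return List::create(_["blocks"] = blocks, _["fc"] = fcs);
}

int out_len(int L, int k, int s) { return (L - k) / s + 1; }

// Build im2col matrix (Cin*k, Lout*N) from activations (Cin, Lin, N).
mat im2col(const cube& A, int k, int s, int Lout) {
  const int Cin = A.n_rows, N = A.n_slices;
  mat M(Cin * k, (uword)Lout * N);
  for (int n = 0; n < N; ++n) {
    const mat& sl = A.slice(n);
    for (int t = 0; t < Lout; ++t)
      M.col((uword)n * Lout + t) = arma::vectorise(sl.cols(t * s, t * s + k - 1));
  }
  return M;
}

void col2im_add(cube& dA, const mat& dM, int k, int s, int Lout) {
  const int Cin = dA.n_rows, N = dA.n_slices;
  for (int n = 0; n < N; ++n) {
    mat& sl = dA.slice(n);
    for (int t = 0; t < Lout; ++t)
      sl.cols(t * s, t * s + k - 1) +=
        arma::reshape(dM.col((uword)n * Lout + t), Cin, k);
  }
}

// flat is (C, L*N) with column index n*L + t; regroup into (C, L, N).
cube regroup(const mat& flat, int C, int L) {
  const int N = flat.n_cols / L;
  cube A(C, L, N);
  for (int n = 0; n < N; ++n)
    A.slice(n) = flat.cols((uword)n * L, (uword)n * L + L - 1);
  return A;
}

cube to_cube(const mat& X, int C, int L) {
  cube A(C, L, X.n_cols);
  for (uword n = 0; n < X.n_cols; ++n)
    A.slice(n) = arma::reshape(X.col(n), C, L);
  return A;
}

struct BlockCache {
  mat M;        // im2col of the block input
  mat xhat;     // normalized pre-activation (Cout, Lout*N)
  mat out;      // post-ReLU output (Cout, Lout*N)
  vec invstd;
  int Lout, N;
};

struct FcCache { mat in, out; };

struct ForwardCache {
  std::vector<BlockCache> blocks;
  std::vector<FcCache> fcs;
  mat probs;   // (3, N)
};

// Forward through one conv block. Training mode uses batch statistics
// (optionally folded into the running statistics); eval mode uses the
// running statistics.
mat block_forward(ConvParams& cp, const cube& A, bool training,
                  bool update_running, double momentum, BlockCache& cache) {
  const int Lin = A.n_cols, N = A.n_slices;
  const int Lout = out_len(Lin, cp.k, cp.s);
  if (Lout < 1) stop("conv block input too short (Lin=%d, k=%d)", Lin, cp.k);
  cache.Lout = Lout; cache.N = N;
  cache.M = im2col(A, cp.k, cp.s, Lout);
  mat Z = cp.W * cache.M;
  Z.each_col() += cp.b;
  const double m = (double)Z.n_cols;
  if (training) {
    vec mu = arma::mean(Z, 1);
    mat centered = Z.each_col() - mu;
    vec var = arma::mean(arma::square(centered), 1);
    cache.invstd = 1.0 / arma::sqrt(var + BN_EPS);
    cache.xhat = centered.each_col() % cache.invstd;
    if (update_running) {
      cp.rmean = (1 - momentum) * cp.rmean + momentum * mu;
      double corr = m > 1 ? m / (m - 1) : 1.0;  // unbiased for running var
      cp.rvar = (1 - momentum) * cp.rvar + momentum * (var * corr);
    }
  } else {
    cache.invstd = 1.0 / arma::sqrt(cp.rvar + BN_EPS);
    cache.xhat = (Z.each_col() - cp.rmean).each_col() % cache.invstd;
  }
  mat Y = cache.xhat.each_col() % cp.gamma;
  Y.each_col() += cp.beta;
  cache.out = arma::clamp(Y, 0.0, arma::datum::inf);  // ReLU
  return cache.out;
}

mat softmax_cols(mat logits) {
  logits.each_row() -= arma::max(logits, 0);
  mat e = arma::exp(logits);
  e.each_row() /= arma::sum(e, 0);
  return e;
}

// Full forward pass; returns softmax probabilities (3, N).
mat net_forward(Net& net, const mat& X, bool training, bool update_running,
                double momentum, ForwardCache& cache) {
  cube A = to_cube(X, net.C0, net.L0);
  cache.blocks.resize(net.blocks.size());
  for (size_t i = 0; i < net.blocks.size(); ++i) {
    mat out = block_forward(net.blocks[i], A, training, update_running,
                            momentum, cache.blocks[i]);
    A = regroup(out, net.blocks[i].Cout, cache.blocks[i].Lout);
  }
  const int N = X.n_cols;
  mat F(A.n_rows * A.n_cols, N);
  for (int n = 0; n < N; ++n) F.col(n) = arma::vectorise(A.slice(n));
  cache.fcs.resize(net.fcs.size());
  mat H = F;
  for (size_t j = 0; j < net.fcs.size(); ++j) {
    cache.fcs[j].in = H;
    mat Z = net.fcs[j].W * H;
    Z.each_col() += net.fcs[j].b;
    if (j + 1 < net.fcs.size()) Z = arma::clamp(Z, 0.0, arma::datum::inf);
    cache.fcs[j].out = Z;
    H = Z;
  }
  cache.probs = softmax_cols(H);
  return cache.probs;
}

struct Grads {
  std::vector<mat> dW; std::vector<vec> db, dgamma, dbeta;
  std::vector<mat> dWfc; std::vector<vec> dbfc;
};

double net_backward(Net& net, const mat& X, const mat& Y,
                    ForwardCache& cache, Grads& g) {
  const int N = X.n_cols;
  const mat& P = cache.probs;
  double loss = -arma::accu(Y % arma::log(P + 1e-12)) / N;

  mat dZ = (P - Y) / N;  // gradient at final logits
  g.dWfc.resize(net.fcs.size()); g.dbfc.resize(net.fcs.size());
  for (int j = (int)net.fcs.size() - 1; j >= 0; --j) {
    g.dWfc[j] = dZ * cache.fcs[j].in.t();
    g.dbfc[j] = arma::sum(dZ, 1);
    mat dIn = net.fcs[j].W.t() * dZ;
    if (j > 0) dIn %= arma::conv_to<mat>::from(cache.fcs[j - 1].out > 0);
    dZ = dIn;
  }
  size_t nb = net.blocks.size();
  g.dW.resize(nb); g.db.resize(nb); g.dgamma.resize(nb); g.dbeta.resize(nb);

  // reshape flatten-gradient into block-output layout (Cout, Llast*N)
  const ConvParams& last = net.blocks[nb - 1];
  const int Llast = cache.blocks[nb - 1].Lout;
  mat dOut(last.Cout, (uword)Llast * N);
  for (int n = 0; n < N; ++n)
    dOut.cols((uword)n * Llast, (uword)n * Llast + Llast - 1) =
      arma::reshape(dZ.col(n), last.Cout, Llast);

  for (int i = (int)nb - 1; i >= 0; --i) {
    ConvParams& cp = net.blocks[i];
    BlockCache& c = cache.blocks[i];
    const double m = (double)c.out.n_cols;
    mat dY = dOut % arma::conv_to<mat>::from(c.out > 0);  // ReLU
    g.dgamma[i] = arma::sum(dY % c.xhat, 1);
    g.dbeta[i] = arma::sum(dY, 1);
    mat dxhat = dY.each_col() % cp.gamma;
    vec sum_dxhat = arma::sum(dxhat, 1);
    vec sum_dxhat_xhat = arma::sum(dxhat % c.xhat, 1);
    mat dZc = dxhat * m;
    dZc.each_col() -= sum_dxhat;
    dZc -= c.xhat.each_col() % sum_dxhat_xhat;
    dZc.each_col() %= (c.invstd / m);
    g.dW[i] = dZc * c.M.t();
    g.db[i] = arma::sum(dZc, 1);
    if (i > 0) {
      mat dM = cp.W.t() * dZc;
      const int Lin = cache.blocks[i - 1].Lout;
      cube dA(cp.Cin, Lin, N, arma::fill::zeros);
      col2im_add(dA, dM, cp.k, cp.s, c.Lout);
      dOut.set_size(cp.Cin, (uword)Lin * N);
      for (int n = 0; n < N; ++n)
        dOut.cols((uword)n * Lin, (uword)n * Lin + Lin - 1) = dA.slice(n);
    }
  }
  return loss;
}

}  // namespace

// [[Rcpp::export]]
List cnn_train_cpp(List params, const arma::mat& X, const arma::mat& Y,
                   List spec, int epochs, int batch_size, double lr,
                   double bn_momentum, const arma::umat& shuffle,
                   bool verbose) {
  Net net = load_net(params, spec);
  const int N = X.n_cols;
  if ((int)Y.n_cols != N) stop("X and Y disagree on sample count");
  if ((int)shuffle.n_rows != N || (int)shuffle.n_cols < epochs)
    stop("shuffle index matrix must be N x epochs");

  // Adam state over every trainable tensor, in a fixed slot order:
  // per block W, b, gamma, beta; then per fc layer W, b.
  struct Slot { mat* pm; vec* pv; };
  std::vector<Slot> slots;
  for (auto& b : net.blocks) {
    slots.push_back({&b.W, nullptr});
    slots.push_back({nullptr, &b.b});
    slots.push_back({nullptr, &b.gamma});
    slots.push_back({nullptr, &b.beta});
  }
  for (auto& f : net.fcs) {
    slots.push_back({&f.W, nullptr});
    slots.push_back({nullptr, &f.b});
  }
  std::vector<mat> am(slots.size()), av(slots.size());
  for (size_t i = 0; i < slots.size(); ++i) {
    if (slots[i].pm) { am[i].zeros(slots[i].pm->n_rows, slots[i].pm->n_cols);
                       av[i].zeros(slots[i].pm->n_rows, slots[i].pm->n_cols); }
    else { am[i].zeros(slots[i].pv->n_elem, 1);
           av[i].zeros(slots[i].pv->n_elem, 1); }
  }
  const double b1 = 0.9, b2 = 0.999, aeps = 1e-8;
  long tstep = 0;

  std::vector<double> history;
  history.reserve(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0; int n_batches = 0;
    for (int start = 0; start < N; start += batch_size) {
      int end = std::min(start + batch_size, N);
      int nbatch = end - start;
      if (nbatch < 2) continue;  // batch norm needs at least 2 samples
      arma::uvec idx(nbatch);
      for (int i = 0; i < nbatch; ++i) idx[i] = shuffle(start + i, ep);
      mat Xb = X.cols(idx), Yb = Y.cols(idx);
      ForwardCache cache;
      net_forward(net, Xb, true, true, bn_momentum, cache);
      Grads g;
      double loss = net_backward(net, Xb, Yb, cache, g);
      ep_loss += loss; ++n_batches;

      std::vector<mat> gs; gs.reserve(slots.size());
      for (size_t i = 0; i < net.blocks.size(); ++i) {
        gs.push_back(g.dW[i]);
        gs.push_back(mat(g.db[i]));
        gs.push_back(mat(g.dgamma[i]));
        gs.push_back(mat(g.dbeta[i]));
      }
      for (size_t j = 0; j < net.fcs.size(); ++j) {
        gs.push_back(g.dWfc[j]);
        gs.push_back(mat(g.dbfc[j]));
      }
      ++tstep;
      double c1 = 1 - std::pow(b1, (double)tstep);
      double c2 = 1 - std::pow(b2, (double)tstep);
      for (size_t i = 0; i < slots.size(); ++i) {
        am[i] = b1 * am[i] + (1 - b1) * gs[i];
        av[i] = b2 * av[i] + (1 - b2) * arma::square(gs[i]);
        mat upd = lr * (am[i] / c1) / (arma::sqrt(av[i] / c2) + aeps);
        if (slots[i].pm) *slots[i].pm -= upd;
        else *slots[i].pv -= vec(upd.col(0));
      }
    }
    history.push_back(n_batches ? ep_loss / n_batches : NA_REAL);
    if (verbose) Rcout << "epoch " << ep + 1 << " loss "
                       << history.back() << "\n";
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = dump_net(net),
                      _["history"] = NumericVector(history.begin(),
                                                   history.end()));
}

// [[Rcpp::export]]
arma::mat cnn_forward_cpp(List params, const arma::mat& X, List spec,
                          bool training) {
  Net net = load_net(params, spec);
  ForwardCache cache;
  return net_forward(net, X, training, false, 0.0, cache);
}

// [[Rcpp::export]]
List cnn_loss_grad_cpp(List params, const arma::mat& X, const arma::mat& Y,
                       List spec) {
  Net net = load_net(params, spec);
  ForwardCache cache;
  net_forward(net, X, true, false, 0.0, cache);
  Grads g;
  double loss = net_backward(net, X, Y, cache, g);
  List blocks(net.blocks.size());
  for (size_t i = 0; i < net.blocks.size(); ++i)
    blocks[i] = List::create(_["W"] = g.dW[i], _["b"] = g.db[i],
                             _["gamma"] = g.dgamma[i], _["beta"] = g.dbeta[i]);
  List fcs(net.fcs.size());
  for (size_t j = 0; j < net.fcs.size(); ++j)
    fcs[j] = List::create(_["W"] = g.dWfc[j], _["b"] = g.dbfc[j]);
  return List::create(_["loss"] = loss, _["blocks"] = blocks, _["fc"] = fcs);
}
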