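// Weight-clipped Wasserstein GAN core: two 3-layer MLPs (generator
// noise->256 LeakyReLU(0.2)->tanh output; critic input->256 LeakyReLU(0.2)
// ->1 linear) trained with RMSProp and critic weight clipping. All
// randomness comes from R's RNG (RNGScope), so seeded runs are exactly
// reproducible from R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// A private mt19937_64 stream, seeded from R's RNG on entry to each
// exported routine, supplies the high-volume noise draws: it is much
// faster than calling back into R's RNG per draw and remains fully
// deterministic under set.seed() at the R level.
#include <random>
static std::mt19937_64 g_rng;

static void seed_rng_from_r() {
  uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
  g_rng.seed((hi << 32) ^ lo);
}

static arma::mat rnorm_mat(int r, int c) {
  static std::normal_distribution<double> nd(0.0, 1.0);
  arma::mat M(r, c);
  double* p = M.memptr();
  for (int i = 0; i < r * c; ++i) p[i] = nd(g_rng);
  return M;
}

static arma::uvec rand_index(int B, int n) {
  std::uniform_int_distribution<int> ui(0, n - 1);
  arma::uvec idx(B);
  for (int i = 0; i < B; ++i) idx(i) = (arma::uword)ui(g_rng);
  return idx;
}

static inline arma::mat lrelu(const arma::mat& X, double a) {
  return arma::max(X, a * X);
}
static inline arma::mat lrelu_grad(const arma::mat& X, double a) {
  arma::mat G(X.n_rows, X.n_cols);
  G.fill(a);
  G.elem(arma::find(X > 0)).fill(1.0);
  return G;
}

struct Nets {
  arma::mat gW1, gb1, gW2, gb2; // generator
  arma::mat dW1, db1, dW2, db2; // critic
  double alpha;                  // leaky slope
};

static Nets unpack(const List& params) {
  Nets n;
  n.gW1 = as<arma::mat>(params["gW1"]); n.gb1 = as<arma::mat>(params["gb1"]);
  n.gW2 = as<arma::mat>(params["gW2"]); n.gb2 = as<arma::mat>(params["gb2"]);
  n.dW1 = as<arma::mat>(params["dW1"]); n.db1 = as<arma::mat>(params["db1"]);
  n.dW2 = as<arma::mat>(params["dW2"]); n.db2 = as<arma::mat>(params["db2"]);
  n.alpha = as<double>(params["alpha"]);
  return n;
}

static List pack(const Nets& n, double alpha) {
  return List::create(_["gW1"] = n.gW1, _["gb1"] = n.gb1, _["gW2"] = n.gW2,
                      _["gb2"] = n.gb2, _["dW1"] = n.dW1, _["db1"] = n.db1,
                      _["dW2"] = n.dW2, _["db2"] = n.db2, _["alpha"] = alpha);
}

static void rms_step(arma::mat& W, arma::mat& C, const arma::mat& G, double lr) {
  C = 0.9 * C + 0.1 * (G % G);
  W -= lr * G / (arma::sqrt(C) + 1e-8);
}

// generator forward; returns X in (-1,1); optionally keeps intermediates
static arma::mat g_forward(const Nets& n, const arma::mat& Z,
                           arma::mat* H1 = nullptr, arma::mat* A1 = nullptr) {
  arma::mat h1 = Z * n.gW1;
  h1.each_row() += n.gb1.row(0);
  arma::mat a1 = lrelu(h1, n.alpha);
  arma::mat o = a1 * n.gW2;
  o.each_row() += n.gb2.row(0);
  if (H1) *H1 = h1;
  if (A1) *A1 = a1;
  return arma::tanh(o);
}

static arma::vec d_forward(const Nets& n, const arma::mat& X,
                           arma::mat* H = nullptr, arma::mat* A = nullptr) {
  arma::mat h = X * n.dW1;
  h.each_row() += n.db1.row(0);
  arma::mat a = lrelu(h, n.alpha);
  arma::vec out = a * n.dW2.col(0) + n.db2(0, 0);
  if (H) *H = h;
  if (A) *A = a;
  return out;
}

// critic backward: given dloss/dout, accumulate grads; returns dloss/dX
static arma::mat d_backward(const Nets& n, const arma::mat& X,
                            const arma::mat& H, const arma::mat& A,
                            const arma::vec& dout,
                            arma::mat& gdW1, arma::mat& gdb1,
                            arma::mat& gdW2, arma::mat& gdb2) {
  gdW2 = A.t() * dout;
  gdb2 = arma::mat(1, 1, arma::fill::value(arma::accu(dout)));
  arma::mat dA = dout * n.dW2.col(0).t();
  arma::mat dH = dA % lrelu_grad(H, n.alpha);
  gdW1 = X.t() * dH;
  gdb1 = arma::sum(dH, 0);
  return dH * n.dW1.t();
}

static void clip_critic(Nets& n, double clip) {
  n.dW1 = arma::clamp(n.dW1, -clip, clip);
  n.db1 = arma::clamp(n.db1, -clip, clip);
  n.dW2 = arma::clamp(n.dW2, -clip, clip);
  n.db2 = arma::clamp(n.db2, -clip, clip);
}

// [[Rcpp::export]]
List wgan_run_cpp(List params, List cache, const arma::mat& real,
                  int epochs, int batch_size, int n_critic,
                  double lr, double clip, int noise_dim) {
  seed_rng_from_r();
  Nets net = unpack(params);
  Nets cch = unpack(cache);
  const int n = real.n_rows;
  const int B = std::min(batch_size, n);
  const int steps = (n + B - 1) / B;
  arma::vec critic_obj(epochs, arma::fill::zeros);
  arma::vec gen_loss(epochs, arma::fill::zeros);
  bool finite = true;
  int fail_epoch = -1;

  for (int ep = 0; ep < epochs && finite; ++ep) {
    double cobj = 0.0, gls = 0.0;
    for (int st = 0; st < steps; ++st) {
      for (int c = 0; c < n_critic; ++c) {
        // real batch
        arma::uvec idx = rand_index(B, n);
        arma::mat Xr = real.rows(idx);
        arma::mat Z = rnorm_mat(B, noise_dim);
        arma::mat Xf = g_forward(net, Z);
        arma::mat X = arma::join_cols(Xr, Xf);
        arma::mat H, A;
        arma::vec out = d_forward(net, X, &H, &A);
        double obj = arma::mean(out.head(B)) - arma::mean(out.tail(B));
        cobj = obj; // last critic batch objective
        // minimize mean(fake) - mean(real)
        arma::vec dout(2 * B);
        dout.head(B).fill(-1.0 / B);
        dout.tail(B).fill(1.0 / B);
        arma::mat gdW1, gdb1, gdW2, gdb2;
        d_backward(net, X, H, A, dout, gdW1, gdb1, gdW2, gdb2);
        rms_step(net.dW1, cch.dW1, gdW1, lr);
        rms_step(net.db1, cch.db1, gdb1, lr);
        rms_step(net.dW2, cch.dW2, gdW2, lr);
        rms_step(net.db2, cch.db2, gdb2, lr);
        clip_critic(net, clip);
      }
      // generator step: minimize -mean(D(G(z)))
      arma::mat Z = rnorm_mat(B, noise_dim);
      arma::mat H1, A1;
      arma::mat Xf = g_forward(net, Z, &H1, &A1);
      arma::mat H, A;
      arma::vec out = d_forward(net, Xf, &H, &A);
      gls = -arma::mean(out);
      arma::vec dout(B);
      dout.fill(-1.0 / B);
      arma::mat gdW1, gdb1, gdW2, gdb2;
      arma::mat dX = d_backward(net, Xf, H, A, dout, gdW1, gdb1, gdW2, gdb2);
      arma::mat dO = dX % (1.0 - Xf % Xf);
      arma::mat gGW2 = A1.t() * dO;
      arma::mat gGb2 = arma::sum(dO, 0);
      arma::mat dA1 = dO * net.gW2.t();
      arma::mat dH1 = dA1 % lrelu_grad(H1, net.alpha);
      arma::mat gGW1 = Z.t() * dH1;
      arma::mat gGb1 = arma::sum(dH1, 0);
      rms_step(net.gW1, cch.gW1, gGW1, lr);
      rms_step(net.gb1, cch.gb1, gGb1, lr);
      rms_step(net.gW2, cch.gW2, gGW2, lr);
      rms_step(net.gb2, cch.gb2, gGb2, lr);
      if (!std::isfinite(gls) || !std::isfinite(cobj)) {
        finite = false;
        fail_epoch = ep + 1;
        break;
      }
    }
    critic_obj(ep) = cobj;
    gen_loss(ep) = gls;
  }
  return List::create(_["params"] = pack(net, net.alpha),
                      _["cache"] = pack(cch, net.alpha),
                      _["critic_obj"] = critic_obj,
                      _["gen_loss"] = gen_loss,
                      _["finite"] = finite,
                      _["fail_epoch"] = fail_epoch);
}

// [[Rcpp::export]]
arma::mat wgan_generate_cpp(List params, int n, int noise_dim) {
  seed_rng_from_r();
  Nets net = unpack(params);
  arma::mat Z = rnorm_mat(n, noise_dim);
  return g_forward(net, Z);
}

// [[Rcpp::export]]
arma::vec wgan_critic_value_cpp(List params, const arma::mat& x) {
  Nets net = unpack(params);
  return d_forward(net, x);
}

// Critic-only training on fixed real/fake batches; returns the trace of
// E[D(real)] - E[D(fake)] after each step (used to test that the critic
// learns to separate the two clusters).
// [[Rcpp::export]]
List wgan_critic_only_cpp(List params, List cache, const arma::mat& real,
                          const arma::mat& fake, int steps,
                          double lr, double clip) {
  Nets net = unpack(params);
  Nets cch = unpack(cache);
  const int Br = real.n_rows, Bf = fake.n_rows;
  arma::mat X = arma::join_cols(real, fake);
  arma::vec trace(steps);
  for (int st = 0; st < steps; ++st) {
    arma::mat H, A;
    arma::vec out = d_forward(net, X, &H, &A);
    arma::vec dout(Br + Bf);
    dout.head(Br).fill(-1.0 / Br);
    dout.tail(Bf).fill(1.0 / Bf);
    arma::mat gdW1, gdb1, gdW2, gdb2;
    d_backward(net, X, H, A, dout, gdW1, gdb1, gdW2, gdb2);
    rms_step(net.dW1, cch.dW1, gdW1, lr);
    rms_step(net.db1, cch.db1, gdb1, lr);
    rms_step(net.dW2, cch.dW2, gdW2, lr);
    rms_step(net.db2, cch.db2, gdb2, lr);
    clip_critic(net, clip);
    arma::vec out2 = d_forward(net, X);
    trace(st) = arma::mean(out2.head(Br)) - arma::mean(out2.tail(Bf));
  }
  return List::create(_["params"] = pack(net, net.alpha),
                      _["cache"] = pack(cch, net.alpha),
                      _["trace"] = trace);
}
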