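// Single-hidden-layer softmax network trained with Adam and early stopping.
// Kept in C++ because the streaming evaluation protocol retrains the whole
// classifier bank every two trials; everything else in the package is R.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat softmax_rows(const arma::mat& z) {
  arma::vec m = arma::max(z, 1);
  arma::mat e = arma::exp(z.each_col() - m);
  arma::vec s = arma::sum(e, 1);
  return e.each_col() / s;
}

static arma::uvec argmax_rows(const arma::mat& p) {
  arma::uvec out(p.n_rows);
  for (arma::uword i = 0; i < p.n_rows; ++i) out(i) = p.row(i).index_max();
  return out;
}

struct AdamState {
  arma::mat m, v;
  AdamState(arma::uword r, arma::uword c) : m(r, c, arma::fill::zeros),
                                            v(r, c, arma::fill::zeros) {}
  void step(arma::mat& w, const arma::mat& g, double lr, long t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1.0 - b1) * g;
    v = b2 * v + (1.0 - b2) * (g % g);
    arma::mat mh = m / (1.0 - std::pow(b1, (double)t));
    arma::mat vh = v / (1.0 - std::pow(b2, (double)t));
    w -= lr * (mh / (arma::sqrt(vh) + eps));
  }
};

// Deterministic given `seed`: weight init, validation split and batch
// shuffling all come from one mt19937 stream, independent of R's RNG.
// y is 0-based class index; returns the weights at the best validation epoch.
// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& X, const arma::ivec& y, int n_class,
                   int hidden, double lr, int max_epochs, int patience,
                   double val_frac, int batch_size, int seed) {
  const arma::uword n = X.n_rows, d = X.n_cols;
  const arma::uword K = (arma::uword)n_class, H = (arma::uword)hidden;
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<arma::uword> perm(n);
  for (arma::uword i = 0; i < n; ++i) perm[i] = i;
  std::shuffle(perm.begin(), perm.end(), rng);

  arma::uword n_val = (arma::uword)std::floor(val_frac * (double)n);
  if (n_val < 1) n_val = 1;
  if (n_val >= n) n_val = n - 1;
  arma::uword n_tr = n - n_val;

  arma::uvec vidx(n_val), tidx(n_tr);
  for (arma::uword i = 0; i < n_val; ++i) vidx(i) = perm[i];
  for (arma::uword i = 0; i < n_tr; ++i) tidx(i) = perm[n_val + i];

  arma::mat Xtr = X.rows(tidx), Xval = X.rows(vidx);
  arma::ivec ytr(n_tr); arma::uvec yval(n_val);
  for (arma::uword i = 0; i < n_tr; ++i) ytr(i) = y(tidx(i));
  for (arma::uword i = 0; i < n_val; ++i) yval(i) = (arma::uword)y(vidx(i));

  arma::mat Ytr(n_tr, K, arma::fill::zeros);
  for (arma::uword i = 0; i < n_tr; ++i) Ytr(i, (arma::uword)ytr(i)) = 1.0;

  // He initialisation for the rectifier layer, small-variance output layer
  arma::mat W1(d, H), W2(H, K);
  arma::rowvec b1(H, arma::fill::zeros), b2(K, arma::fill::zeros);
  double s1 = std::sqrt(2.0 / (double)d), s2 = std::sqrt(2.0 / (double)H);
  for (auto& w : W1) w = gauss(rng) * s1;
  for (auto& w : W2) w = gauss(rng) * s2;

  AdamState aW1(d, H), ab1(1, H), aW2(H, K), ab2(1, K);
  long t = 0;

  arma::mat bW1 = W1, bW2 = W2;
  arma::rowvec bb1 = b1, bb2 = b2;
  double best_err = std::numeric_limits<double>::infinity();
  int best_epoch = 0, since_best = 0, epochs_run = 0;

  std::vector<arma::uword> order(n_tr);
  for (arma::uword i = 0; i < n_tr; ++i) order[i] = i;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    epochs_run = epoch;
    std::shuffle(order.begin(), order.end(), rng);
    for (arma::uword start = 0; start < n_tr; start += (arma::uword)batch_size) {
      arma::uword stop = std::min(start + (arma::uword)batch_size, n_tr);
      arma::uvec bi(stop - start);
      for (arma::uword i = start; i < stop; ++i) bi(i - start) = order[i];
      arma::mat Xb = Xtr.rows(bi), Yb = Ytr.rows(bi);
      double nb = (double)Xb.n_rows;

      arma::mat A = Xb * W1;
      A.each_row() += b1;
      arma::mat R = arma::clamp(A, 0.0, arma::datum::inf);
      arma::mat Z = R * W2;
      Z.each_row() += b2;
      arma::mat P = softmax_rows(Z);

      arma::mat G = (P - Yb) / nb;
      arma::mat gW2 = R.t() * G;
      arma::rowvec gb2 = arma::sum(G, 0);
      arma::mat GR = G * W2.t();
      GR.elem(arma::find(A <= 0.0)).zeros();
      arma::mat gW1 = Xb.t() * GR;
      arma::rowvec gb1 = arma::sum(GR, 0);

      ++t;
      aW2.step(W2, gW2, lr, t);
      aW1.step(W1, gW1, lr, t);
      arma::mat b1m(b1), b2m(b2), g1m(gb1), g2m(gb2);
      ab1.step(b1m, g1m, lr, t);
      ab2.step(b2m, g2m, lr, t);
      b1 = b1m.row(0); b2 = b2m.row(0);
    }

    arma::mat Av = Xval * W1;
    Av.each_row() += b1;
    arma::mat Zv = arma::clamp(Av, 0.0, arma::datum::inf) * W2;
    Zv.each_row() += b2;
    arma::uvec pv = argmax_rows(Zv);
    double err = 0.0;
    for (arma::uword i = 0; i < n_val; ++i) if (pv(i) != yval(i)) err += 1.0;
    err /= (double)n_val;

    // Early stopping on sustained validation degradation: epochs at or below
    // the best error refresh the snapshot; `patience` consecutive epochs
    // strictly above it end training, returning the last snapshot.
    if (err <= best_err) {
      best_err = err; best_epoch = epoch; since_best = 0;
      bW1 = W1; bb1 = b1; bW2 = W2; bb2 = b2;
    } else {
      ++since_best;
      if (since_best >= patience) break;
    }
  }

  return List::create(_["w1"] = bW1, _["b1"] = arma::vec(bb1.t()),
                      _["w2"] = bW2, _["b2"] = arma::vec(bb2.t()),
                      _["val_error"] = best_err,
                      _["epochs"] = epochs_run,
                      _["best_epoch"] = best_epoch);
}
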