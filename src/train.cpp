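// Feed-forward network training core: one hidden layer of logistic
// units, logistic output, cross-entropy loss.  Alternating rounds of
// offline (full-batch) and online (per-example) training with early
// stopping on validation loss.  All randomness comes from a seeded
// mt19937 so training is bitwise reproducible for a given seed.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat sigmoid(const arma::mat& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

static arma::vec forward_scores(const arma::mat& X, const arma::mat& W1,
                                const arma::rowvec& b1, const arma::vec& w2,
                                double b2) {
  arma::mat H = sigmoid(X * W1 + arma::repmat(b1, X.n_rows, 1));
  return arma::vectorise(sigmoid(H * w2 + b2));
}

static double xent(const arma::vec& yhat, const arma::vec& y) {
  const double eps = 1e-12;
  return -arma::mean(y % arma::log(yhat + eps) +
                     (1.0 - y) % arma::log(1.0 - yhat + eps));
}

// [[Rcpp::export(name = ".nn_forward_cpp")]]
NumericVector nn_forward_cpp(const arma::mat& X, const arma::mat& W1,
                             const arma::rowvec& b1, const arma::vec& w2,
                             double b2) {
  return wrap(forward_scores(X, W1, b1, w2, b2));
}

// [[Rcpp::export(name = ".nn_train_cpp")]]
List nn_train_cpp(const arma::mat& X, const arma::vec& y,
                  const arma::uvec& train_idx0, const arma::uvec& valid_idx0,
                  int nhid, double lr_offline, double lr_online,
                  int max_rounds, int patience, unsigned int seed) {
  const arma::uword p = X.n_cols;
  std::mt19937 rng(seed);
  auto runif = [&rng](double lo, double hi) {
    // fixed-algorithm uniform: 53-bit mantissa from two draws
    double u = ((rng() >> 5) * 67108864.0 + (rng() >> 6)) / 9007199254740992.0;
    return lo + u * (hi - lo);
  };

  arma::mat W1(p, (arma::uword)nhid);
  arma::rowvec b1((arma::uword)nhid, arma::fill::zeros);
  arma::vec w2((arma::uword)nhid);
  double b2 = 0.0;
  const double r1 = 1.0 / std::sqrt((double)p);
  const double r2 = 1.0 / std::sqrt((double)nhid);
  for (arma::uword k = 0; k < W1.n_cols; ++k)
    for (arma::uword i = 0; i < W1.n_rows; ++i) W1(i, k) = runif(-r1, r1);
  for (int k = 0; k < nhid; ++k) w2(k) = runif(-r2, r2);

  const arma::mat Xtr = X.rows(train_idx0);
  const arma::vec ytr = y.elem(train_idx0);
  const arma::mat Xva = X.rows(valid_idx0);
  const arma::vec yva = y.elem(valid_idx0);
  const arma::uword n = Xtr.n_rows;

  arma::mat bW1 = W1; arma::rowvec bb1 = b1; arma::vec bw2 = w2; double bb2 = b2;
  double best = xent(forward_scores(Xva, W1, b1, w2, b2), yva);
  int since_best = 0;
  std::vector<double> history;
  history.push_back(best);
  std::vector<arma::uword> perm(n);
  for (arma::uword i = 0; i < n; ++i) perm[i] = i;

  for (int round = 0; round < max_rounds; ++round) {
    // offline: one full-batch gradient step on the mean cross-entropy
    {
      arma::mat H = sigmoid(Xtr * W1 + arma::repmat(b1, n, 1));
      arma::vec yhat = arma::vectorise(sigmoid(H * w2 + b2));
      arma::vec delta = (yhat - ytr) / (double)n;   // d loss / d preact(out)
      arma::vec g_w2 = H.t() * delta;
      double g_b2 = arma::accu(delta);
      arma::mat dH = (delta * w2.t()) % H % (1.0 - H);
      W1 -= lr_offline * (Xtr.t() * dH);
      b1 -= lr_offline * arma::sum(dH, 0);
      w2 -= lr_offline * g_w2;
      b2 -= lr_offline * g_b2;
    }
    // online: one stochastic pass, per-example updates, seeded shuffle
    for (arma::uword i = n; i > 1; --i) {
      arma::uword jswap = (arma::uword)(rng() % i);
      std::swap(perm[i - 1], perm[jswap]);
    }
    arma::rowvec h((arma::uword)nhid), dh((arma::uword)nhid);
    arma::vec xbuf(p);
    for (arma::uword t = 0; t < n; ++t) {
      // gather the example once into a contiguous buffer
      for (arma::uword i = 0; i < p; ++i) xbuf(i) = Xtr(perm[t], i);
      const double yt = ytr(perm[t]);
      for (int k = 0; k < nhid; ++k) {
        double z = b1(k) + arma::dot(xbuf, W1.unsafe_col(k));
        h(k) = 1.0 / (1.0 + std::exp(-z));
      }
      double yhat = 1.0 / (1.0 + std::exp(-(arma::dot(h, w2.t()) + b2)));
      double delta = yhat - yt;
      for (int k = 0; k < nhid; ++k) {
        dh(k) = delta * w2(k) * h(k) * (1.0 - h(k));
      }
      // in-place rank-1 update, no temporaries
      for (int k = 0; k < nhid; ++k) {
        w2(k) -= lr_online * delta * h(k);
        const double d = lr_online * dh(k);
        if (d == 0.0) continue;
        b1(k) -= d;
        double* col = W1.colptr(k);
        const double* xp = xbuf.memptr();
        for (arma::uword i = 0; i < p; ++i) col[i] -= d * xp[i];
      }
      b2 -= lr_online * delta;
    }
    double vloss = xent(forward_scores(Xva, W1, b1, w2, b2), yva);
    history.push_back(vloss);
    if (vloss < best - 1e-9) {
      best = vloss; bW1 = W1; bb1 = b1; bw2 = w2; bb2 = b2;
      since_best = 0;
    } else if (++since_best >= patience) break;
  }

  return List::create(_["W1"] = bW1, _["b1"] = wrap(arma::vec(bb1.t())),
                      _["w2"] = bw2, _["b2"] = bb2,
                      _["valid_loss"] = best,
                      _["history"] = wrap(history));
}
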