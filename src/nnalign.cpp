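// Feedforward core for pan-specific binding prediction.
//
// One hidden layer, logistic activations throughout, one output unit.
// Training is classic online (per-example) gradient descent on
// E = 1/2 (o - t)^2, with the NNAlign twist: each training peptide owns a
// small block of candidate binding-core encodings, the current network
// scores all of them, and back-propagation runs on the argmax candidate
// only.  All randomness (weight init, per-epoch shuffling) flows from one
// std::mt19937 seed so training trajectories are bit-reproducible.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }
static inline vec sigv(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

// first index of the strict maximum (ties -> lowest candidate offset)
static uword argmax_first(const vec& s) {
  uword best = 0;
  for (uword i = 1; i < s.n_elem; ++i) if (s[i] > s[best]) best = i;
  return best;
}

// [[Rcpp::export]]
arma::vec cppForward(const arma::mat& W1, const arma::vec& b1,
                     const arma::vec& W2, double b2, const arma::mat& X) {
  mat H = sigm(X * W1 + repmat(b1.t(), X.n_rows, 1));
  return vectorise(sigm(H * W2 + b2));
}

// [[Rcpp::export]]
Rcpp::List cppInitNet(int D, int H, int seed) {
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> unif(-0.05, 0.05);
  mat W1(D, H); vec b1(H); vec W2(H);
  for (uword j = 0; j < W1.n_cols; ++j)
    for (uword i = 0; i < W1.n_rows; ++i) W1(i, j) = unif(rng);
  for (uword i = 0; i < b1.n_elem; ++i) b1[i] = unif(rng);
  for (uword i = 0; i < W2.n_elem; ++i) W2[i] = unif(rng);
  double b2 = unif(rng);
  return Rcpp::List::create(Rcpp::Named("W1") = W1, Rcpp::Named("b1") = b1,
                            Rcpp::Named("W2") = W2, Rcpp::Named("b2") = b2);
}

// Gradient of the mean over the batch of 1/2 (o - t)^2.
// [[Rcpp::export]]
Rcpp::List cppGradBatch(const arma::mat& W1, const arma::vec& b1,
                        const arma::vec& W2, double b2,
                        const arma::mat& X, const arma::vec& y) {
  const double n = static_cast<double>(X.n_rows);
  mat H = sigm(X * W1 + repmat(b1.t(), X.n_rows, 1));
  vec o = sigv(H * W2 + b2);
  vec d_o = (o - y) % o % (1.0 - o) / n;          // n x 1
  mat d_h = (d_o * W2.t()) % H % (1.0 - H);       // n x H
  mat gW1 = X.t() * d_h;                          // D x H
  vec gb1 = sum(d_h, 0).t();
  vec gW2 = H.t() * d_o;
  double gb2 = accu(d_o);
  if (!gW1.is_finite() || !gb1.is_finite() || !gW2.is_finite() ||
      !std::isfinite(gb2))
    Rcpp::stop("non-finite gradient encountered");
  return Rcpp::List::create(Rcpp::Named("W1") = gW1, Rcpp::Named("b1") = gb1,
                            Rcpp::Named("W2") = gW2, Rcpp::Named("b2") = gb2);
}

// one online update on a single encoded example; modifies the nets in place
static inline void online_update(mat& W1, vec& b1, vec& W2, double& b2,
                                 const rowvec& x, double y, double lr) {
  vec h = sigv(W1.t() * x.t() + b1);
  double o = 1.0 / (1.0 + std::exp(-(dot(h, W2) + b2)));
  double d_o = (o - y) * o * (1.0 - o);
  vec d_h = (d_o * W2) % h % (1.0 - h);
  W2 -= lr * d_o * h;
  b2 -= lr * d_o;
  W1 -= lr * (x.t() * d_h.t());
  b1 -= lr * d_h;
}

// mean squared error over records, scoring each record by its best candidate
static double block_error(const mat& W1, const vec& b1, const vec& W2,
                          double b2, const mat& X,
                          const Rcpp::IntegerVector& candStart,
                          const Rcpp::IntegerVector& candCount,
                          const Rcpp::NumericVector& target,
                          const Rcpp::IntegerVector& idx) {
  double err = 0.0;
  for (int k = 0; k < idx.size(); ++k) {
    int r = idx[k];
    mat Xc = X.rows(candStart[r], candStart[r] + candCount[r] - 1);
    vec s = cppForward(W1, b1, W2, b2, Xc);
    double d = s[argmax_first(s)] - target[r];
    err += d * d;
  }
  return err / idx.size();
}

// NNAlign training loop with early stopping on a held-out stop set.
// X holds the candidate-core encodings of *all* records, stacked; record r
// owns rows candStart[r] .. candStart[r]+candCount[r]-1 (0-based).
// Plain fixed-encoding training is the special case candCount == 1.
// [[Rcpp::export]]
Rcpp::List cppTrainNNAlign(const arma::mat& X,
                           const Rcpp::IntegerVector& candStart,
                           const Rcpp::IntegerVector& candCount,
                           const Rcpp::NumericVector& target,
                           const Rcpp::IntegerVector& trainIdx,
                           const Rcpp::IntegerVector& stopIdx,
                           int H, double lr, int maxEpochs, int patience,
                           int seed) {
  const int D = X.n_cols;
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> unif(-0.05, 0.05);
  mat W1(D, H); vec b1(H); vec W2(H); double b2;
  for (uword j = 0; j < W1.n_cols; ++j)
    for (uword i = 0; i < W1.n_rows; ++i) W1(i, j) = unif(rng);
  for (uword i = 0; i < b1.n_elem; ++i) b1[i] = unif(rng);
  for (uword i = 0; i < W2.n_elem; ++i) W2[i] = unif(rng);
  b2 = unif(rng);

  mat bW1 = W1; vec bb1 = b1; vec bW2 = W2; double bb2 = b2;
  int bestEpoch = 0;
  double bestErr = (maxEpochs > 0)
    ? block_error(W1, b1, W2, b2, X, candStart, candCount, target, stopIdx)
    : datum::inf;

  std::vector<int> order(trainIdx.begin(), trainIdx.end());
  std::vector<double> trainLog, stopLog;
  int sincBest = 0, epochsRun = 0;

  for (int e = 1; e <= maxEpochs; ++e) {
    std::shuffle(order.begin(), order.end(), rng);
    double terr = 0.0;
    for (size_t k = 0; k < order.size(); ++k) {
      int r = order[k];
      mat Xc = X.rows(candStart[r], candStart[r] + candCount[r] - 1);
      vec s = cppForward(W1, b1, W2, b2, Xc);
      uword j = argmax_first(s);
      double d = s[j] - target[r];
      terr += d * d;
      online_update(W1, b1, W2, b2, Xc.row(j), target[r], lr);
      if (!std::isfinite(b2))
        Rcpp::stop("training diverged: non-finite parameters at epoch %d", e);
    }
    trainLog.push_back(terr / order.size());
    double serr = block_error(W1, b1, W2, b2, X, candStart, candCount,
                              target, stopIdx);
    stopLog.push_back(serr);
    epochsRun = e;
    if (serr < bestErr) {
      bestErr = serr; bestEpoch = e; sincBest = 0;
      bW1 = W1; bb1 = b1; bW2 = W2; bb2 = b2;
    } else if (++sincBest >= patience) break;
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("W1") = bW1, Rcpp::Named("b1") = bb1,
    Rcpp::Named("W2") = bW2, Rcpp::Named("b2") = bb2,
    Rcpp::Named("bestEpoch") = bestEpoch,
    Rcpp::Named("bestStopErr") = bestErr,
    Rcpp::Named("trainErr") = trainLog,
    Rcpp::Named("stopErr") = stopLog,
    Rcpp::Named("epochsRun") = epochsRun);
}
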