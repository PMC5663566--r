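// Multilayer perceptron with symmetric-sigmoid (tanh) units, trained by
// full-batch iRPROP- under early stopping on a validation set.  The weight
// layout mirrors the R side: weights[l] is (n_l x n_{l+1}), biases[l] is
// length n_{l+1}; tanh is applied in every layer including the output.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static std::vector<arma::mat> as_mats(const List& weights) {
  std::vector<arma::mat> W;
  for (R_xlen_t l = 0; l < weights.size(); ++l)
    W.push_back(as<arma::mat>(weights[l]));
  return W;
}

static std::vector<arma::rowvec> as_rows(const List& biases) {
  std::vector<arma::rowvec> B;
  for (R_xlen_t l = 0; l < biases.size(); ++l)
    B.push_back(as<arma::rowvec>(biases[l]));
  return B;
}

static arma::mat forward(const std::vector<arma::mat>& W,
                         const std::vector<arma::rowvec>& B,
                         const arma::mat& X,
                         std::vector<arma::mat>* acts = nullptr) {
  arma::mat A = X;
  if (acts) acts->push_back(A);
  for (size_t l = 0; l < W.size(); ++l) {
    A = arma::tanh(A * W[l] + arma::repmat(B[l], A.n_rows, 1));
    if (acts) acts->push_back(A);
  }
  return A;
}

static double mse(const arma::mat& out, const arma::vec& y) {
  arma::vec d = out.col(0) - y;
  return arma::dot(d, d) / d.n_elem;
}

// [[Rcpp::export]]
NumericVector mlp_forward_cpp(List weights, List biases, NumericMatrix X) {
  std::vector<arma::mat> W = as_mats(weights);
  std::vector<arma::rowvec> B = as_rows(biases);
  arma::mat out = forward(W, B, as<arma::mat>(X));
  return wrap(arma::vec(out.col(0)));
}

// Backpropagated gradient of the mean squared error (targets +/-1).
static void gradient(const std::vector<arma::mat>& W,
                     const std::vector<arma::rowvec>& B,
                     const arma::mat& X, const arma::vec& y,
                     std::vector<arma::mat>& gW,
                     std::vector<arma::rowvec>& gB,
                     double* err = nullptr) {
  std::vector<arma::mat> acts;
  arma::mat out = forward(W, B, X, &acts);
  const size_t L = W.size();
  const double n = X.n_rows;
  if (err) *err = mse(out, y);
  // dE/dout for E = mean((out - y)^2); tanh'(z) = 1 - a^2
  arma::mat delta = (out.col(0) - y) * (2.0 / n);
  delta %= (1.0 - arma::square(acts[L]));
  gW.assign(L, arma::mat());
  gB.assign(L, arma::rowvec());
  for (size_t l = L; l-- > 0;) {
    gW[l] = acts[l].t() * delta;
    gB[l] = arma::sum(delta, 0);
    if (l > 0) {
      delta = delta * W[l].t();
      delta %= (1.0 - arma::square(acts[l]));
    }
  }
}

// [[Rcpp::export]]
List mlp_gradient_cpp(List weights, List biases, NumericMatrix X,
                      NumericVector y) {
  std::vector<arma::mat> W = as_mats(weights);
  std::vector<arma::rowvec> B = as_rows(biases);
  std::vector<arma::mat> gW;
  std::vector<arma::rowvec> gB;
  double err = 0.0;
  gradient(W, B, as<arma::mat>(X), as<arma::vec>(y), gW, gB, &err);
  List lW(gW.size()), lB(gB.size());
  for (size_t l = 0; l < gW.size(); ++l) {
    lW[l] = wrap(gW[l]);
    lB[l] = wrap(arma::vec(gB[l].t()));
  }
  return List::create(_["grad_weights"] = lW, _["grad_biases"] = lB,
                      _["error"] = err);
}

// iRPROP- update for one parameter array, in place.
static void rprop_apply(arma::mat& w, const arma::mat& g, arma::mat& step,
                        arma::mat& prev, double eta_plus, double eta_minus,
                        double step_min, double step_max) {
  for (arma::uword i = 0; i < w.n_elem; ++i) {
    double prod = g(i) * prev(i);
    if (prod > 0) {
      step(i) = std::min(step(i) * eta_plus, step_max);
      w(i) -= ((g(i) > 0) - (g(i) < 0)) * step(i);
      prev(i) = g(i);
    } else if (prod < 0) {
      step(i) = std::max(step(i) * eta_minus, step_min);
      prev(i) = 0.0;  // gradient treated as 0: no move this epoch
    } else {
      w(i) -= ((g(i) > 0) - (g(i) < 0)) * step(i);
      prev(i) = g(i);
    }
  }
}

// Full training loop: full-batch iRPROP- with best-so-far retention on
// validation error.  Epoch 0 is the initialization; training stops at
// max_epochs or once the validation error has not improved for `patience`
// epochs.  Returns the best-validation weights and the error traces.
// [[Rcpp::export]]
List mlp_train_cpp(List weights, List biases, NumericMatrix X_train,
                   NumericVector y_train, NumericMatrix X_val,
                   NumericVector y_val, int max_epochs, int patience,
                   double eta_plus, double eta_minus, double step0,
                   double step_min, double step_max) {
  std::vector<arma::mat> W = as_mats(weights);
  std::vector<arma::rowvec> B = as_rows(biases);
  arma::mat Xt = as<arma::mat>(X_train), Xv = as<arma::mat>(X_val);
  arma::vec yt = as<arma::vec>(y_train), yv = as<arma::vec>(y_val);
  const size_t L = W.size();

  std::vector<arma::mat> stepW(L), prevW(L), bestW = W;
  std::vector<arma::mat> stepB(L), prevB(L), bestB_m(L);
  for (size_t l = 0; l < L; ++l) {
    stepW[l] = arma::mat(W[l].n_rows, W[l].n_cols, arma::fill::value(step0));
    prevW[l] = arma::mat(W[l].n_rows, W[l].n_cols, arma::fill::zeros);
    stepB[l] = arma::mat(1, B[l].n_elem, arma::fill::value(step0));
    prevB[l] = arma::mat(1, B[l].n_elem, arma::fill::zeros);
    bestB_m[l] = arma::mat(B[l]);
  }

  double best_val = mse(forward(W, B, Xv), yv);
  int best_epoch = 0, since_improve = 0, epoch = 0;
  std::vector<double> train_trace, val_trace;
  train_trace.push_back(mse(forward(W, B, Xt), yt));
  val_trace.push_back(best_val);

  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    if (since_improve >= patience) break;
    std::vector<arma::mat> gW;
    std::vector<arma::rowvec> gB;
    double train_err = 0.0;
    gradient(W, B, Xt, yt, gW, gB, &train_err);
    for (size_t l = 0; l < L; ++l) {
      rprop_apply(W[l], gW[l], stepW[l], prevW[l],
                  eta_plus, eta_minus, step_min, step_max);
      arma::mat b(B[l]), g(gB[l]);
      rprop_apply(b, g, stepB[l], prevB[l],
                  eta_plus, eta_minus, step_min, step_max);
      B[l] = arma::rowvec(b);
    }
    double val_err = mse(forward(W, B, Xv), yv);
    train_trace.push_back(mse(forward(W, B, Xt), yt));
    val_trace.push_back(val_err);
    if (val_err < best_val) {
      best_val = val_err;
      best_epoch = epoch;
      bestW = W;
      for (size_t l = 0; l < L; ++l) bestB_m[l] = arma::mat(B[l]);
      since_improve = 0;
    } else {
      ++since_improve;
    }
  }

  List outW(L), outB(L);
  for (size_t l = 0; l < L; ++l) {
    outW[l] = wrap(bestW[l]);
    outB[l] = wrap(arma::vec(bestB_m[l].row(0).t()));
  }
  return List::create(_["weights"] = outW, _["biases"] = outB,
                      _["val_error"] = best_val, _["best_epoch"] = best_epoch,
                      _["epochs_run"] = epoch - 1,
                      _["train_trace"] = train_trace,
                      _["val_trace"] = val_trace);
}
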