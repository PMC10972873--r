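// Hot loops: synchronous Heaviside state update and full-batch ADAM.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Run the synchronous update x(t) = theta(u(t) + W x(t-1)) for `steps` steps.
// W(i, j) is the weight from neuron j to neuron i; theta(z) = 1 iff z > 0,
// so the all-zero state is absorbing in a free run.
// input: one external value per step (all zero for a free run); neurons in
// input_idx (0-based) receive input_scale * input[t], all others receive 0.
// Returns the mean-activity trace A(1..steps) and, when record = true, the
// states restricted to record_idx for steps record_from+1 .. steps
// (row t of the matrix is the state after consuming input t of that window).
// [[Rcpp::export]]
List cpp_run_network(const arma::sp_mat& W,
                     const arma::vec& init,
                     const arma::vec& input,
                     const arma::uvec& input_idx,
                     double input_scale,
                     const arma::uvec& record_idx,
                     int record_from,
                     bool record) {
  const arma::uword n = W.n_rows;
  const arma::uword steps = input.n_elem;
  arma::vec x = init;
  arma::vec trace(steps);
  arma::mat states;
  arma::uword n_rec = 0;
  if (record) {
    n_rec = steps - static_cast<arma::uword>(record_from);
    states.set_size(n_rec, record_idx.n_elem);
  }
  arma::vec u(n);
  for (arma::uword t = 0; t < steps; ++t) {
    u.zeros();
    if (input[t] != 0.0) {
      u.elem(input_idx).fill(input_scale * input[t]);
    }
    arma::vec field = u + W * x;
    x = arma::conv_to<arma::vec>::from(field > 0.0);
    trace[t] = arma::mean(x);
    if (record && t >= static_cast<arma::uword>(record_from)) {
      states.row(t - record_from) = x.elem(record_idx).t();
    }
  }
  List out = List::create(_["trace"] = trace);
  if (record) out["states"] = states;
  return out;
}

// Full-batch ADAM on a sigmoid readout with MSE loss.
// Model: yhat = 1 / (1 + exp(-(X w + c))); loss = mean((yhat - y)^2).
// Bias-corrected first/second moments, one full-batch update per epoch.
// [[Rcpp::export]]
List cpp_adam_sigmoid(const arma::mat& X,
                      const arma::vec& y,
                      arma::vec w,
                      double c,
                      int epochs,
                      double lr,
                      double beta1,
                      double beta2,
                      double eps) {
  const double n = static_cast<double>(X.n_rows);
  arma::vec m_w(w.n_elem, arma::fill::zeros), v_w(w.n_elem, arma::fill::zeros);
  double m_c = 0.0, v_c = 0.0;
  arma::vec loss(epochs);
  for (int e = 0; e < epochs; ++e) {
    arma::vec z = X * w + c;
    arma::vec yhat = 1.0 / (1.0 + arma::exp(-z));
    arma::vec err = yhat - y;
    loss[e] = arma::dot(err, err) / n;
    arma::vec g = (2.0 / n) * (err % yhat % (1.0 - yhat));
    arma::vec g_w = X.t() * g;
    double g_c = arma::accu(g);
    m_w = beta1 * m_w + (1.0 - beta1) * g_w;
    v_w = beta2 * v_w + (1.0 - beta2) * arma::square(g_w);
    m_c = beta1 * m_c + (1.0 - beta1) * g_c;
    v_c = beta2 * v_c + (1.0 - beta2) * g_c * g_c;
    const double bc1 = 1.0 - std::pow(beta1, e + 1);
    const double bc2 = 1.0 - std::pow(beta2, e + 1);
    w -= lr * (m_w / bc1) / (arma::sqrt(v_w / bc2) + eps);
    c -= lr * (m_c / bc1) / (std::sqrt(v_c / bc2) + eps);
  }
  return List::create(_["weights"] = w, _["bias"] = c, _["loss"] = loss);
}
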