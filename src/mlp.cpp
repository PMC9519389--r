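// Multilayer perceptron with ReLU hidden layers, logistic output, Adam
// optimiser and L2 penalty — the per-motif classifier architecture
// (default hidden sizes 250/125/100). Implemented here because training
// must be deterministic under a seed and fast on a single CPU.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;

namespace {

struct Net {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;
};

Net net_from_list(const List& weights) {
  Net net;
  for (int l = 0; l < weights.size(); ++l) {
    List layer = weights[l];
    net.W.push_back(as<arma::mat>(layer["W"]));
    net.b.push_back(as<arma::vec>(layer["b"]));
  }
  return net;
}

List net_to_list(const Net& net) {
  List out(net.W.size());
  for (size_t l = 0; l < net.W.size(); ++l)
    out[l] = List::create(_["W"] = net.W[l], _["b"] = net.b[l]);
  return out;
}

arma::vec forward(const Net& net, const arma::mat& X,
                  std::vector<arma::mat>* acts = nullptr) {
  arma::mat a = X;
  if (acts) acts->push_back(a);
  size_t L = net.W.size();
  for (size_t l = 0; l + 1 < L; ++l) {
    a = a * net.W[l];
    a.each_row() += net.b[l].t();
    a.transform([](double v) { return v > 0.0 ? v : 0.0; });
    if (acts) acts->push_back(a);
  }
  arma::vec z = a * net.W[L - 1] + net.b[L - 1](0);
  // numerically safe logistic
  arma::vec p = 1.0 / (1.0 + arma::exp(-arma::clamp(z, -35.0, 35.0)));
  return p;
}

double bce(const arma::vec& p, const arma::vec& y) {
  const double eps = 1e-12;
  return -arma::mean(y % arma::log(p + eps) +
                     (1.0 - y) % arma::log(1.0 - p + eps));
}

// Backprop on one batch; returns gradients (same shapes as net) and loss
// including the L2 penalty alpha/(2*n) * sum ||W||^2.
double backward(const Net& net, const arma::mat& X, const arma::vec& y,
                double alpha, Net& grad) {
  std::vector<arma::mat> acts;
  arma::vec p = forward(net, X, &acts);
  size_t L = net.W.size();
  double n = (double)X.n_rows;
  double loss = bce(p, y);
  for (size_t l = 0; l < L; ++l)
    loss += alpha / (2.0 * n) * arma::accu(net.W[l] % net.W[l]);
  arma::mat delta = (p - y) / n;  // d(meanBCE)/dz for logistic output
  grad.W.assign(L, arma::mat());
  grad.b.assign(L, arma::vec());
  for (int l = (int)L - 1; l >= 0; --l) {
    grad.W[l] = acts[l].t() * delta + (alpha / n) * net.W[l];
    grad.b[l] = arma::sum(delta, 0).t();
    if (l > 0) {
      delta = delta * net.W[l].t();
      delta %= arma::conv_to<arma::mat>::from(acts[l] > 0.0);
    }
  }
  return loss;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_mlp_train")]]
List cpp_mlp_train(const arma::mat& X, const arma::vec& y,
                   const arma::mat& Xval, const arma::vec& yval,
                   IntegerVector hidden, double lr, double alpha,
                   int batchSize, int maxEpochs, int patience, double tol,
                   int seed) {
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  size_t n = X.n_rows, d = X.n_cols;
  std::vector<size_t> sizes;
  sizes.push_back(d);
  for (int h : hidden) sizes.push_back((size_t)h);
  sizes.push_back(1);
  Net net;
  for (size_t l = 0; l + 1 < sizes.size(); ++l) {
    double sd = std::sqrt(2.0 / (double)sizes[l]);  // He initialisation
    arma::mat W(sizes[l], sizes[l + 1]);
    for (arma::uword j = 0; j < W.n_elem; ++j) W(j) = sd * norm(rng);
    net.W.push_back(W);
    net.b.push_back(arma::vec(sizes[l + 1], arma::fill::zeros));
  }
  // Adam state
  Net m, v;
  for (size_t l = 0; l < net.W.size(); ++l) {
    m.W.push_back(arma::mat(arma::size(net.W[l]), arma::fill::zeros));
    m.b.push_back(arma::vec(net.b[l].n_elem, arma::fill::zeros));
    v.W.push_back(arma::mat(arma::size(net.W[l]), arma::fill::zeros));
    v.b.push_back(arma::vec(net.b[l].n_elem, arma::fill::zeros));
  }
  const double b1 = 0.9, b2 = 0.999, adamEps = 1e-8;
  long t = 0;
  std::vector<size_t> order(n);
  for (size_t i = 0; i < n; ++i) order[i] = i;
  bool haveVal = Xval.n_rows > 0;
  double bestLoss = std::numeric_limits<double>::infinity();
  Net best = net;
  int bestEpoch = 0, wait = 0, epochsRun = 0;
  std::vector<double> history;
  for (int epoch = 1; epoch <= maxEpochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    for (size_t start = 0; start < n; start += (size_t)batchSize) {
      size_t end = std::min(n, start + (size_t)batchSize);
      arma::uvec idx(end - start);
      for (size_t i = start; i < end; ++i) idx[i - start] = order[i];
      arma::mat Xb = X.rows(idx);
      arma::vec yb = y.elem(idx);
      Net grad;
      backward(net, Xb, yb, alpha, grad);
      ++t;
      double corr = lr * std::sqrt(1.0 - std::pow(b2, (double)t)) /
                    (1.0 - std::pow(b1, (double)t));
      for (size_t l = 0; l < net.W.size(); ++l) {
        m.W[l] = b1 * m.W[l] + (1.0 - b1) * grad.W[l];
        v.W[l] = b2 * v.W[l] + (1.0 - b2) * (grad.W[l] % grad.W[l]);
        net.W[l] -= corr * m.W[l] / (arma::sqrt(v.W[l]) + adamEps);
        m.b[l] = b1 * m.b[l] + (1.0 - b1) * grad.b[l];
        v.b[l] = b2 * v.b[l] + (1.0 - b2) * (grad.b[l] % grad.b[l]);
        net.b[l] -= corr * m.b[l] / (arma::sqrt(v.b[l]) + adamEps);
      }
    }
    epochsRun = epoch;
    double vloss;
    if (haveVal) {
      vloss = bce(forward(net, Xval), yval);
    } else {
      vloss = bce(forward(net, X), y);
    }
    history.push_back(vloss);
    if (vloss < bestLoss - tol) {
      bestLoss = vloss;
      best = net;
      bestEpoch = epoch;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
  }
  return List::create(_["weights"] = net_to_list(best),
                      _["valHistory"] = history,
                      _["bestEpoch"] = bestEpoch,
                      _["epochsRun"] = epochsRun,
                      _["bestValLoss"] = bestLoss);
}

// [[Rcpp::export(name = ".cpp_mlp_predict")]]
arma::vec cpp_mlp_predict(List weights, const arma::mat& X) {
  Net net = net_from_list(weights);
  return forward(net, X);
}

// [[Rcpp::export(name = ".cpp_mlp_loss_grad")]]
List cpp_mlp_loss_grad(List weights, const arma::mat& X, const arma::vec& y,
                       double alpha) {
  Net net = net_from_list(weights);
  Net grad;
  double loss = backward(net, X, y, alpha, grad);
  return List::create(_["loss"] = loss, _["grad"] = net_to_list(grad));
}
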