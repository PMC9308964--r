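// Multi-task quantile MLP: shared ReLU trunk, one linear unit per percentile
// head, summed mean pinball loss, Adam updates. Self-contained mt19937 RNG so
// a given seed reproduces the fit bit-for-bit on a given platform.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Net {
  std::vector<mat> W;   // trunk weights, layer l: (units_{l-1} x units_l)
  std::vector<rowvec> b;
  mat Wo;               // heads: (units_L x K)
  rowvec bo;
};

Net init_net(int p, const std::vector<int>& hidden, int K, std::mt19937& rng) {
  Net net;
  std::normal_distribution<double> norm(0.0, 1.0);
  int fan = p;
  for (int h : hidden) {
    mat W(fan, h);
    for (uword j = 0; j < W.n_elem; ++j) W(j) = norm(rng) * std::sqrt(2.0 / fan);
    net.W.push_back(W);
    net.b.push_back(rowvec(h, fill::zeros));
    fan = h;
  }
  net.Wo.set_size(fan, K);
  for (uword j = 0; j < net.Wo.n_elem; ++j) net.Wo(j) = norm(rng) * std::sqrt(1.0 / fan);
  net.bo = rowvec(K, fill::zeros);
  return net;
}

// forward pass keeping hidden activations for backprop
mat forward(const Net& net, const mat& X, std::vector<mat>* acts) {
  mat A = X;
  if (acts) acts->clear();
  for (size_t l = 0; l < net.W.size(); ++l) {
    A = A * net.W[l];
    A.each_row() += net.b[l];
    A = clamp(A, 0.0, datum::inf);  // ReLU
    if (acts) acts->push_back(A);
  }
  mat out = A * net.Wo;
  out.each_row() += net.bo;
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".qmlp_train")]]
Rcpp::List qmlp_train(const arma::mat& X, const arma::vec& y,
                      const std::vector<int>& hidden, const arma::vec& taus,
                      int epochs, int batch_size, double lr, int seed) {
  const int n = X.n_rows, p = X.n_cols, K = taus.n_elem;
  std::mt19937 rng(static_cast<unsigned>(seed));
  Net net = init_net(p, hidden, K, rng);
  const size_t L = net.W.size();

  // Adam state (one slot per parameter tensor; heads last two)
  std::vector<mat> mW(L), vW(L);
  std::vector<rowvec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l] = zeros(size(net.W[l])); vW[l] = mW[l];
    mb[l] = zeros<rowvec>(net.b[l].n_elem); vb[l] = mb[l];
  }
  mat mWo = zeros(size(net.Wo)), vWo = mWo;
  rowvec mbo = zeros<rowvec>(K), vbo = mbo;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> history(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0; long ep_count = 0;
    for (int start = 0; start < n; start += batch_size) {
      int m = std::min(batch_size, n - start);
      uvec rows(m);
      for (int i = 0; i < m; ++i) rows(i) = idx[start + i];
      mat Xb = X.rows(rows);
      vec yb = y(rows);

      std::vector<mat> acts;
      mat out = forward(net, Xb, &acts);  // m x K

      // pinball loss and its gradient wrt the head outputs
      mat G(m, K);
      double loss = 0.0;
      for (int k = 0; k < K; ++k) {
        double tau = taus(k);
        for (int i = 0; i < m; ++i) {
          double r = yb(i) - out(i, k);
          loss += std::max(tau * r, (tau - 1.0) * r);
          G(i, k) = (r > 0) ? -tau : (r < 0 ? (1.0 - tau) : 0.0);
        }
      }
      ep_loss += loss / m; ep_count++;
      G /= m;  // batch-mean pinball per head, summed over heads

      // backprop
      const mat& Alast = acts.empty() ? Xb : acts.back();
      mat gWo = Alast.t() * G;
      rowvec gbo = sum(G, 0);
      mat delta = G * net.Wo.t();
      std::vector<mat> gW(L); std::vector<rowvec> gb(L);
      for (int l = static_cast<int>(L) - 1; l >= 0; --l) {
        delta %= conv_to<mat>::from(acts[l] > 0.0);  // ReLU gate
        const mat& Aprev = (l == 0) ? Xb : acts[l - 1];
        gW[l] = Aprev.t() * delta;
        gb[l] = sum(delta, 0);
        if (l > 0) delta = delta * net.W[l].t();
      }

      // Adam
      ++step;
      double c1 = 1.0 - std::pow(b1, step), c2 = 1.0 - std::pow(b2, step);
      auto adam = [&](mat& theta, const mat& g, mat& mm, mat& vv) {
        mm = b1 * mm + (1 - b1) * g;
        vv = b2 * vv + (1 - b2) * square(g);
        theta -= lr * (mm / c1) / (sqrt(vv / c2) + eps);
      };
      auto adam_r = [&](rowvec& theta, const rowvec& g, rowvec& mm, rowvec& vv) {
        mm = b1 * mm + (1 - b1) * g;
        vv = b2 * vv + (1 - b2) * square(g);
        theta -= lr * (mm / c1) / (sqrt(vv / c2) + eps);
      };
      for (size_t l = 0; l < L; ++l) {
        adam(net.W[l], gW[l], mW[l], vW[l]);
        adam_r(net.b[l], gb[l], mb[l], vb[l]);
      }
      adam(net.Wo, gWo, mWo, vWo);
      adam_r(net.bo, gbo, mbo, vbo);
    }
    history[ep] = ep_loss / ep_count;
  }

  Rcpp::List Wl(L), bl(L);
  for (size_t l = 0; l < L; ++l) { Wl[l] = net.W[l]; bl[l] = net.b[l]; }
  return Rcpp::List::create(Rcpp::Named("W") = Wl, Rcpp::Named("b") = bl,
                            Rcpp::Named("Wo") = net.Wo, Rcpp::Named("bo") = net.bo,
                            Rcpp::Named("history") = history);
}

// [[Rcpp::export(name = ".qmlp_predict")]]
arma::mat qmlp_predict(const Rcpp::List& weights, const arma::mat& X) {
  Net net;
  Rcpp::List Wl = weights["W"], bl = weights["b"];
  for (int l = 0; l < Wl.size(); ++l) {
    net.W.push_back(Rcpp::as<mat>(Wl[l]));
    net.b.push_back(Rcpp::as<rowvec>(bl[l]));
  }
  net.Wo = Rcpp::as<mat>(weights["Wo"]);
  net.bo = Rcpp::as<rowvec>(weights["bo"]);
  return forward(net, X, nullptr);
}
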