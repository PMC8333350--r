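// Compiled training loop of the conditioned adversarial autoencoder.
// The R level owns initialisation, preprocessing and all inference-time
// forward passes; this file only runs the minibatch optimisation (three
// sequential Adam phases per batch: reconstruction, discriminator,
// generator) where R-level overhead would dominate. All randomness
// (shuffling, prior samples) is drawn from R's RNG so training stays
// deterministic under set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::mat;
using arma::rowvec;

namespace {

struct Net {
  std::vector<mat> W;
  std::vector<rowvec> b;
  size_t L() const { return W.size(); }
};

Net netFromList(const List &layers) {
  Net net;
  for (R_xlen_t l = 0; l < layers.size(); ++l) {
    List layer = layers[l];
    net.W.push_back(as<mat>(layer["W"]));
    net.b.push_back(as<rowvec>(layer["b"]));
  }
  return net;
}

List netToList(const Net &net) {
  List out(net.L());
  for (size_t l = 0; l < net.L(); ++l)
    out[l] = List::create(Named("W") = net.W[l], Named("b") = net.b[l]);
  return out;
}

struct Cache {
  std::vector<mat> act;  // act[0] = input, act[l] = post-activation
  std::vector<mat> pre;  // pre-activation per layer
};

// forward pass; hidden layers leaky ReLU, output layer linear
mat forward(const Net &net, const mat &X, double slope, Cache &cache) {
  cache.act.assign(net.L() + 1, mat());
  cache.pre.assign(net.L(), mat());
  cache.act[0] = X;
  for (size_t l = 0; l < net.L(); ++l) {
    mat A = cache.act[l] * net.W[l];
    A.each_row() += net.b[l];
    cache.pre[l] = A;
    if (l + 1 < net.L())
      cache.act[l + 1] = arma::max(A, A * slope);  // leaky ReLU
    else
      cache.act[l + 1] = A;
  }
  return cache.act[net.L()];
}

struct Grads {
  std::vector<mat> gW;
  std::vector<rowvec> gb;
  mat dX;
};

// backward pass from dOut (gradient w.r.t. the linear output layer)
void backward(const Net &net, const Cache &cache, const mat &dOut,
              double slope, bool needInput, bool needParams, Grads &g) {
  size_t L = net.L();
  g.gW.assign(needParams ? L : 0, mat());
  g.gb.assign(needParams ? L : 0, rowvec());
  mat dA = dOut;
  for (size_t l = L; l-- > 0;) {
    if (needParams) {
      g.gW[l] = cache.act[l].t() * dA;
      g.gb[l] = arma::sum(dA, 0);
    }
    if (l > 0 || needInput) {
      mat dZ = dA * net.W[l].t();
      if (l > 0) {
        // derivative of leaky ReLU at the previous layer's preactivation
        dA = dZ % (arma::conv_to<mat>::from(cache.pre[l - 1] >= 0) *
                       (1.0 - slope) +
                   slope);
      } else {
        g.dX = dZ;
      }
    }
  }
}

struct Adam {
  std::vector<mat> mW, vW;
  std::vector<rowvec> mb, vb;
  long t = 0;
  explicit Adam(const Net &net) {
    for (size_t l = 0; l < net.L(); ++l) {
      mW.push_back(arma::zeros<mat>(arma::size(net.W[l])));
      vW.push_back(arma::zeros<mat>(arma::size(net.W[l])));
      mb.push_back(arma::zeros<rowvec>(net.b[l].n_elem));
      vb.push_back(arma::zeros<rowvec>(net.b[l].n_elem));
    }
  }
  void step(Net &net, const Grads &g, double lr, double beta1 = 0.9,
            double beta2 = 0.999, double eps = 1e-8) {
    ++t;
    const double c1 = 1.0 - std::pow(beta1, (double)t);
    const double c2 = 1.0 - std::pow(beta2, (double)t);
    for (size_t l = 0; l < net.L(); ++l) {
      mW[l] = beta1 * mW[l] + (1 - beta1) * g.gW[l];
      vW[l] = beta2 * vW[l] + (1 - beta2) * arma::square(g.gW[l]);
      net.W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
      mb[l] = beta1 * mb[l] + (1 - beta1) * g.gb[l];
      vb[l] = beta2 * vb[l] + (1 - beta2) * arma::square(g.gb[l]);
      net.b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
    }
  }
};

inline mat sigmoidM(const mat &a) { return 1.0 / (1.0 + arma::exp(-a)); }

// numerically safe log(sigmoid(a))
inline mat logSigmoidM(const mat &a) {
  mat out(arma::size(a));
  for (arma::uword i = 0; i < a.n_elem; ++i) {
    double v = a(i);
    out(i) = v > -30.0 ? -std::log1p(std::exp(-v)) : v;
  }
  return out;
}

double triangularLr(long step, double baseLr, double maxLr, double gamma,
                    long stepSize) {
  long cycle = step / (2 * stepSize);
  double pos = (double)step / stepSize - 2.0 * cycle;
  double tri = 1.0 - std::fabs(pos - 1.0);
  return baseLr + (maxLr - baseLr) * std::pow(gamma, (double)cycle) * tri;
}

}  // namespace

// [[Rcpp::export(name = ".aaeTrainLoop")]]
List aaeTrainLoop(NumericMatrix X_, NumericMatrix C_, List encoder0,
                  List decoder0, List discriminator0, int epochs,
                  int batchSize, double baseLr, double maxLr, double lrGamma,
                  int cycleStepSize, double slope, double advWeight,
                  double advLrScale, int discSteps, int latentDim) {
  mat X(X_.begin(), X_.nrow(), X_.ncol(), false);
  mat C(C_.begin(), C_.nrow(), C_.ncol(), false);
  Net enc = netFromList(encoder0);
  Net dec = netFromList(decoder0);
  Net dis = netFromList(discriminator0);
  Adam optE(enc), optD(dec), optDis(dis), optG(enc);

  const int n = X.n_rows;
  const int bs = std::min(batchSize, n);
  const int nbatch = std::max(1, n / bs);
  const long stepSize =
      cycleStepSize > 0 ? cycleStepSize : 4L * nbatch;  // 4 epochs default

  NumericVector reconLog(epochs), disLog(epochs), genLog(epochs),
      lrLog(epochs);
  long globalStep = 0;
  Grads gE, gD, gDis, gThrough;
  Cache cE, cD, cDis;

  for (int epoch = 0; epoch < epochs; ++epoch) {
    IntegerVector perm = Rcpp::sample(n, n, false);  // R RNG, 1-based
    double eRec = 0, eDis = 0, eGen = 0;
    for (int bi = 0; bi < nbatch; ++bi) {
      arma::uvec idx(bs);
      for (int k = 0; k < bs; ++k) idx[k] = perm[bi * bs + k] - 1;
      mat xb = X.rows(idx);
      mat cb = C.rows(idx);
      double lr = triangularLr(globalStep, baseLr, maxLr, lrGamma, stepSize);
      double lrAdv = lr * advLrScale;

      // (1) reconstruction: update encoder + decoder
      mat h = forward(enc, xb, slope, cE);
      mat xhat = forward(dec, arma::join_rows(h, cb), slope, cD);
      mat err = xhat - xb;
      eRec += arma::accu(arma::square(err)) / err.n_elem;
      mat dOut = 2.0 * err / err.n_elem;
      backward(dec, cD, dOut, slope, true, true, gD);
      mat dH = gD.dX.cols(0, latentDim - 1);
      backward(enc, cE, dH, slope, false, true, gE);
      optE.step(enc, gE, lr);
      optD.step(dec, gD, lr);

      // (2) discriminator: prior samples (label 1) vs fresh codes (label 0)
      mat zFake = forward(enc, xb, slope, cE);
      arma::vec y = arma::join_cols(arma::ones(bs), arma::zeros(bs));
      for (int ds = 0; ds < discSteps; ++ds) {
        NumericVector pr = Rcpp::rnorm(bs * latentDim);
        mat zReal(pr.begin(), bs, latentDim, false);
        mat zAll = arma::join_cols(zReal, zFake);
        mat a = forward(dis, zAll, slope, cDis);
        eDis += -arma::accu(y % logSigmoidM(a) +
                            (1.0 - y) % logSigmoidM(-a)) /
                (2.0 * bs * discSteps);
        mat dA = (sigmoidM(a) - mat(y)) / (2.0 * bs);
        backward(dis, cDis, dA, slope, false, true, gDis);
        optDis.step(dis, gDis, lrAdv);
      }

      // (3) generator: encoder updated to fool the discriminator
      mat h2 = forward(enc, xb, slope, cE);
      mat a2 = forward(dis, h2, slope, cDis);
      eGen += -arma::accu(logSigmoidM(a2)) / bs;
      mat dA2 = advWeight * (sigmoidM(a2) - 1.0) / bs;
      backward(dis, cDis, dA2, slope, true, false, gThrough);
      backward(enc, cE, gThrough.dX, slope, false, true, gE);
      optG.step(enc, gE, lrAdv);

      ++globalStep;
    }
    reconLog[epoch] = eRec / nbatch;
    disLog[epoch] = eDis / nbatch;
    genLog[epoch] = eGen / nbatch;
    lrLog[epoch] =
        triangularLr(globalStep - 1, baseLr, maxLr, lrGamma, stepSize);
    Rcpp::checkUserInterrupt();
  }

  return List::create(
      Named("encoder") = netToList(enc), Named("decoder") = netToList(dec),
      Named("discriminator") = netToList(dis),
      Named("recon_loss") = reconLog, Named("disc_loss") = disLog,
      Named("gen_loss") = genLog, Named("lr") = lrLog);
}
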