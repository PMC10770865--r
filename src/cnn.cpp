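// Small residual denoising CNN (DnCNN-style): a stack of 3x3 convolutions
// with ReLU nonlinearities whose final layer predicts the noise residual;
// the denoised plane is input - residual. Convolutions use edge-replication
// padding and are realized as im2col + GEMM; training is mini-batch Adam on
// the mean-squared error of (input - residual) against the target plane.
// All randomness (initial weights, batch order) is generated on the R side,
// so training is bit-deterministic given a seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Flat (column-major, y + x*H) source indices of the 9 replicate-padded
// 3x3 neighbours for every pixel.
static arma::umat neighbour_index(int H, int W) {
  arma::umat idx(H * W, 9);
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy, ++k) {
      for (int x = 0; x < W; ++x) {
        int xs = std::min(std::max(x + dx, 0), W - 1);
        for (int y = 0; y < H; ++y) {
          int ys = std::min(std::max(y + dy, 0), H - 1);
          idx(y + x * H, k) = ys + xs * H;
        }
      }
    }
  }
  return idx;
}

// (HW x C) activations -> (HW x 9C) patch matrix.
static arma::mat im2col(const arma::mat& act, const arma::umat& idx) {
  const arma::uword C = act.n_cols;
  arma::mat cols(act.n_rows, 9 * C);
  for (int k = 0; k < 9; ++k)
    cols.cols(k * C, (k + 1) * C - 1) = act.rows(idx.col(k));
  return cols;
}

// Scatter-add transpose of im2col: (HW x 9C) gradient -> (HW x C).
static arma::mat col2im(const arma::mat& dcols, const arma::umat& idx,
                        arma::uword C) {
  arma::mat dact(dcols.n_rows, C, arma::fill::zeros);
  for (int k = 0; k < 9; ++k) {
    const arma::mat part = dcols.cols(k * C, (k + 1) * C - 1);
    const arma::uvec tgt = idx.col(k);
    for (arma::uword r = 0; r < part.n_rows; ++r)
      dact.row(tgt(r)) += part.row(r);
  }
  return dact;
}

struct Layer { arma::mat W; arma::rowvec b; };

static std::vector<Layer> unpack(const List& weights) {
  std::vector<Layer> L(weights.size());
  for (int i = 0; i < weights.size(); ++i) {
    List li = weights[i];
    L[i].W = as<arma::mat>(li["W"]);
    L[i].b = as<arma::rowvec>(li["b"]);
  }
  return L;
}

// Forward pass; optionally records pre-activations and im2col inputs for
// backprop. Returns the residual column (HW x 1).
static arma::mat forward(const arma::mat& x, const std::vector<Layer>& L,
                         const arma::umat& idx,
                         std::vector<arma::mat>* cols_out,
                         std::vector<arma::mat>* relu_mask) {
  arma::mat act = x;  // (HW x 1)
  const int D = (int)L.size();
  for (int l = 0; l < D; ++l) {
    arma::mat cols = im2col(act, idx);
    arma::mat z = cols * L[l].W;
    z.each_row() += L[l].b;
    if (cols_out) cols_out->push_back(std::move(cols));
    if (l < D - 1) {
      if (relu_mask) relu_mask->push_back(arma::conv_to<arma::mat>::from(z > 0));
      act = arma::clamp(z, 0.0, arma::datum::inf);
    } else {
      act = z;
    }
  }
  return act;
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(const arma::mat& img, const List& weights) {
  const int H = img.n_rows, W = img.n_cols;
  arma::umat idx = neighbour_index(H, W);
  std::vector<Layer> L = unpack(weights);
  arma::mat x = arma::vectorise(img);
  arma::mat res = forward(x, L, idx, nullptr, nullptr);
  arma::mat out = x - res;          // residual learning
  out.reshape(H, W);
  return out;
}

// [[Rcpp::export]]
List cnn_train_cpp(const arma::cube& inputs, const arma::cube& targets,
                   const List& weights0, int epochs, int batch, double lr,
                   const arma::imat& order) {
  const int H = inputs.n_rows, W = inputs.n_cols, P = inputs.n_slices;
  arma::umat idx = neighbour_index(H, W);
  std::vector<Layer> L = unpack(weights0);
  const int D = (int)L.size();

  std::vector<arma::mat> mW(D), vW(D);
  std::vector<arma::rowvec> mb(D), vb(D);
  for (int l = 0; l < D; ++l) {
    mW[l].zeros(L[l].W.n_rows, L[l].W.n_cols); vW[l] = mW[l];
    mb[l].zeros(L[l].b.n_elem); vb[l] = mb[l];
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  arma::vec loss_hist(epochs, arma::fill::zeros);

  std::vector<arma::mat> dW(D);
  std::vector<arma::rowvec> db(D);

  for (int e = 0; e < epochs; ++e) {
    double eloss = 0.0;
    for (int start = 0; start < P; start += batch) {
      int bsz = std::min(batch, P - start);
      for (int l = 0; l < D; ++l) {
        dW[l].zeros(L[l].W.n_rows, L[l].W.n_cols);
        db[l].zeros(L[l].b.n_elem);
      }
      for (int bi = 0; bi < bsz; ++bi) {
        int p = (int)order(start + bi, e) - 1;  // 1-based from R
        arma::mat x = arma::vectorise(inputs.slice(p));
        arma::mat t = arma::vectorise(targets.slice(p));
        std::vector<arma::mat> cols, mask;
        arma::mat res = forward(x, L, idx, &cols, &mask);
        arma::mat diff = (x - res) - t;           // denoised - target
        eloss += arma::accu(arma::square(diff)) / diff.n_rows;
        // dL/dres = -2 * diff / N
        arma::mat dz = (-2.0 / diff.n_rows) * diff;
        for (int l = D - 1; l >= 0; --l) {
          dW[l] += cols[l].t() * dz;
          db[l] += arma::sum(dz, 0);
          if (l > 0) {
            arma::mat dcols = dz * L[l].W.t();
            arma::mat dact = col2im(dcols, idx, L[l - 1].W.n_cols);
            dz = dact % mask[l - 1];
          }
        }
      }
      ++step;
      double c1 = 1.0 - std::pow(b1, (double)step);
      double c2 = 1.0 - std::pow(b2, (double)step);
      for (int l = 0; l < D; ++l) {
        arma::mat gW = dW[l] / bsz;
        arma::rowvec gb = db[l] / bsz;
        mW[l] = b1 * mW[l] + (1 - b1) * gW;
        vW[l] = b2 * vW[l] + (1 - b2) * arma::square(gW);
        mb[l] = b1 * mb[l] + (1 - b1) * gb;
        vb[l] = b2 * vb[l] + (1 - b2) * arma::square(gb);
        L[l].W -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
        L[l].b -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
      }
    }
    loss_hist(e) = eloss / P;
  }

  List out(D);
  for (int l = 0; l < D; ++l)
    out[l] = List::create(Named("W") = L[l].W, Named("b") = L[l].b);
  return List::create(Named("weights") = out,
                      Named("loss") = loss_hist);
}
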