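// Fully convolutional autoencoder: 3x3 conv/deconv layers with 'same'
// padding, per-layer batch normalization and ELU activation, sigmoid output,
// MSE loss, Adam optimizer. Convolutions are evaluated as im2col + one GEMM
// per layer per minibatch; transposed convolutions as zero-stuffed stride-1
// convolutions, which makes the decoder exactly double spatial dimensions
// per stride-2 layer. Arithmetic is single precision: the network is a
// feature extractor trained by stochastic gradient steps, where float noise
// is far below the optimization noise floor.
//
// Memory layout: activations and unfolded patch matrices are position-major
// (rows = batch * spatial positions, columns = channels / patch entries), so
// per-channel batch-norm statistics, activations and im2col reads/writes all
// touch contiguous memory.

#include <RcppArmadillo.h>
#include <random>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::fcube;
using arma::fmat;
using arma::fvec;

static const int K = 3;    // kernel size (3x3 everywhere)
static const int PAD = 1;  // 'same' padding
static const float BN_EPS = 1e-5f;

struct Layer {
  int type;        // 0 = conv, 1 = deconv (transposed conv)
  int stride;
  int in_ch, out_ch;
  fmat W;          // out_ch x (in_ch * 9)
  fvec b;
  bool bn;
  fvec gamma, beta, rmean, rvar;
  int act;         // 0 = ELU, 1 = sigmoid
};

static int out_size(int H, int stride) {
  return (H + 2 * PAD - K) / stride + 1;
}

// Unfold an (H, W, C) cube into rows [row0, row0 + Ho*Wo) of the
// position-major patch matrix `cols` (n_rows = B * Ho*Wo, n_cols = C*9).
// Patch row index within the image = j * Ho + i.
static void im2col_into(const fcube& X, int stride, fmat& cols, int row0) {
  const int H = X.n_rows, Wd = X.n_cols, C = X.n_slices;
  const int Ho = out_size(H, stride), Wo = out_size(Wd, stride);
  for (int c = 0; c < C; ++c) {
    const fmat& plane = X.slice(c);
    for (int dr = 0; dr < K; ++dr) {
      for (int dc = 0; dc < K; ++dc) {
        float* dst = cols.colptr(c * K * K + dr * K + dc) + row0;
        for (int j = 0; j < Wo; ++j) {
          const int src_c = j * stride - PAD + dc;
          if (src_c < 0 || src_c >= Wd) continue;
          const float* src = plane.colptr(src_c);
          const int base = j * Ho;
          for (int i = 0; i < Ho; ++i) {
            const int src_r = i * stride - PAD + dr;
            if (src_r < 0 || src_r >= H) continue;
            dst[base + i] = src[src_r];
          }
        }
      }
    }
  }
}

// Adjoint of im2col: fold rows [row0, row0 + Ho*Wo) of a position-major
// gradient matrix back onto an (H, W, C) cube.
static fcube col2im(const fmat& cols, int row0, int H, int Wd, int C,
                    int stride) {
  const int Ho = out_size(H, stride), Wo = out_size(Wd, stride);
  fcube X(H, Wd, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    fmat& plane = X.slice(c);
    for (int dr = 0; dr < K; ++dr) {
      for (int dc = 0; dc < K; ++dc) {
        const float* src = cols.colptr(c * K * K + dr * K + dc) + row0;
        for (int j = 0; j < Wo; ++j) {
          const int dst_c = j * stride - PAD + dc;
          if (dst_c < 0 || dst_c >= Wd) continue;
          float* dst = plane.colptr(dst_c);
          const int base = j * Ho;
          for (int i = 0; i < Ho; ++i) {
            const int dst_r = i * stride - PAD + dr;
            if (dst_r < 0 || dst_r >= H) continue;
            dst[dst_r] += src[base + i];
          }
        }
      }
    }
  }
  return X;
}

// Insert stride-1 zeros between samples: value (i, j) moves to (s*i, s*j) in
// an (s*H, s*W) grid. A stride-1 'same' convolution of the stuffed input is
// the transposed convolution that exactly doubles H and W for s = 2.
static fcube zero_stuff(const fcube& X, int s) {
  fcube Xs(X.n_rows * s, X.n_cols * s, X.n_slices, arma::fill::zeros);
  for (arma::uword c = 0; c < X.n_slices; ++c)
    for (arma::uword j = 0; j < X.n_cols; ++j)
      for (arma::uword i = 0; i < X.n_rows; ++i)
        Xs(i * s, j * s, c) = X(i, j, c);
  return Xs;
}

static fcube unstuff(const fcube& G, int s, int H, int Wd) {
  fcube X(H, Wd, G.n_slices);
  for (arma::uword c = 0; c < G.n_slices; ++c)
    for (int j = 0; j < Wd; ++j)
      for (int i = 0; i < H; ++i)
        X(i, j, c) = G(i * s, j * s, c);
  return X;
}

// Position-major flat layout: F is (B*npos x channels); the block of image
// `img` occupies rows [img*npos, (img+1)*npos) with row index j*Ho + i.
static fcube flat_to_cube(const fmat& F, int img, int npos, int Ho, int Wo) {
  fcube Y(Ho, Wo, F.n_cols);
  for (arma::uword c = 0; c < F.n_cols; ++c) {
    Y.slice(c) = arma::reshape(
      F.col(c).subvec(img * npos, (img + 1) * npos - 1), Ho, Wo);
  }
  return Y;
}

static void cube_to_flat(const fcube& Y, fmat& F, int img, int npos) {
  for (arma::uword c = 0; c < Y.n_slices; ++c)
    F.col(c).subvec(img * npos, (img + 1) * npos - 1) =
      arma::vectorise(Y.slice(c));
}

static std::vector<Layer> parse_layers(const Rcpp::List& layers) {
  std::vector<Layer> out;
  for (int l = 0; l < layers.size(); ++l) {
    Rcpp::List li = layers[l];
    Layer L;
    std::string ty = Rcpp::as<std::string>(li["type"]);
    L.type = (ty == "deconv") ? 1 : 0;
    L.stride = Rcpp::as<int>(li["stride"]);
    L.in_ch = Rcpp::as<int>(li["in_ch"]);
    L.out_ch = Rcpp::as<int>(li["out_ch"]);
    L.W = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(li["W"]));
    L.b = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(li["b"]));
    L.bn = Rcpp::as<bool>(li["bn"]);
    if (L.bn) {
      L.gamma = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(li["gamma"]));
      L.beta = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(li["beta"]));
      L.rmean = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(li["run_mean"]));
      L.rvar = arma::conv_to<fvec>::from(Rcpp::as<arma::vec>(li["run_var"]));
    }
    std::string act = Rcpp::as<std::string>(li["activation"]);
    L.act = (act == "sigmoid") ? 1 : 0;
    out.push_back(L);
  }
  return out;
}

static Rcpp::List layers_to_r(const std::vector<Layer>& layers,
                              const Rcpp::List& tmpl) {
  Rcpp::List out(layers.size());
  for (size_t l = 0; l < layers.size(); ++l) {
    Rcpp::List li = Rcpp::clone(Rcpp::as<Rcpp::List>(tmpl[l]));
    li["W"] = arma::conv_to<arma::mat>::from(layers[l].W);
    li["b"] = arma::conv_to<arma::vec>::from(layers[l].b);
    if (layers[l].bn) {
      li["gamma"] = arma::conv_to<arma::vec>::from(layers[l].gamma);
      li["beta"] = arma::conv_to<arma::vec>::from(layers[l].beta);
      li["run_mean"] = arma::conv_to<arma::vec>::from(layers[l].rmean);
      li["run_var"] = arma::conv_to<arma::vec>::from(layers[l].rvar);
    }
    out[l] = li;
  }
  return out;
}

// Geometry of one layer for a given (square) input spatial size.
struct LayerGeom {
  int Hin, Hout;
  int npos;        // Hout * Hout
  int Hstuff;      // stuffed size for deconv (= Hin * stride)
};

static std::vector<LayerGeom> geometry(const std::vector<Layer>& layers,
                                       int input_size) {
  std::vector<LayerGeom> g(layers.size());
  int H = input_size;
  for (size_t l = 0; l < layers.size(); ++l) {
    g[l].Hin = H;
    if (layers[l].type == 0) {
      g[l].Hstuff = H;
      H = out_size(H, layers[l].stride);
    } else {
      g[l].Hstuff = H * layers[l].stride;
      H = out_size(g[l].Hstuff, 1);
    }
    g[l].Hout = H;
    g[l].npos = H * H;
  }
  return g;
}

// Build the unfolded input matrix of layer l for the whole batch.
static fmat unfold_batch(const Layer& L, const LayerGeom& G,
                         const std::vector<fcube>& input) {
  const int B = (int)input.size();
  fmat cols((size_t)B * G.npos, L.in_ch * K * K, arma::fill::zeros);
  for (int i = 0; i < B; ++i) {
    if (L.type == 0) {
      im2col_into(input[i], L.stride, cols, i * G.npos);
    } else {
      fcube Xs = (L.stride > 1) ? zero_stuff(input[i], L.stride) : input[i];
      im2col_into(Xs, 1, cols, i * G.npos);
    }
  }
  return cols;
}

struct BatchCache {
  std::vector<fmat> z;                    // pre-BN conv output, flat
  std::vector<fmat> y;                    // post-activation output, flat
  std::vector<std::vector<fcube>> ycube;  // same data as cubes (conv input)
  std::vector<fvec> mu, var;              // batch statistics
};

// Forward a batch (as cubes); returns the flat output of the last layer.
// When training, BN uses batch statistics recorded in the cache; otherwise
// the stored running statistics. Cache may be null for inference.
static fmat forward_batch(const std::vector<Layer>& layers,
                          const std::vector<LayerGeom>& geom,
                          const std::vector<fcube>& batch,
                          bool training, BatchCache* cache) {
  const int B = (int)batch.size();
  const std::vector<fcube>* cur = &batch;
  std::vector<fcube> cur_own;
  if (cache) {
    cache->z.resize(layers.size());
    cache->y.resize(layers.size());
    cache->ycube.resize(layers.size());
    cache->mu.resize(layers.size());
    cache->var.resize(layers.size());
  }
  fmat Yf;
  for (size_t l = 0; l < layers.size(); ++l) {
    const Layer& L = layers[l];
    const LayerGeom& G = geom[l];
    fmat cols = unfold_batch(L, G, *cur);
    fmat Z = cols * L.W.t();               // (B*npos) x out_ch
    for (int c = 0; c < L.out_ch; ++c) Z.col(c) += L.b(c);

    fvec mu, var;
    fmat A = Z;
    if (L.bn) {
      if (training) {
        mu.set_size(L.out_ch);
        var.set_size(L.out_ch);
        for (int c = 0; c < L.out_ch; ++c) {
          mu(c) = arma::mean(Z.col(c));
          var(c) = arma::mean(arma::square(Z.col(c))) - mu(c) * mu(c);
          if (var(c) < 0) var(c) = 0;
        }
      } else {
        mu = L.rmean;
        var = L.rvar;
      }
      for (int c = 0; c < L.out_ch; ++c) {
        const float inv_sd = 1.0f / std::sqrt(var(c) + BN_EPS);
        A.col(c) = L.gamma(c) * inv_sd * (Z.col(c) - mu(c)) + L.beta(c);
      }
    }
    if (L.act == 1) {
      Yf = 1.0f / (1.0f + arma::exp(-A));
    } else {
      Yf = A;
      Yf.for_each([](float& v) { if (v <= 0.0f) v = std::exp(v) - 1.0f; });
    }

    cur_own.resize(B);
    for (int i = 0; i < B; ++i)
      cur_own[i] = flat_to_cube(Yf, i, G.npos, G.Hout, G.Hout);
    if (cache) {
      cache->z[l] = std::move(Z);
      cache->y[l] = Yf;
      cache->ycube[l] = cur_own;
      if (L.bn) { cache->mu[l] = mu; cache->var[l] = var; }
    }
    cur = cache ? &cache->ycube[l] : &cur_own;
  }
  return Yf;
}

struct AdamState {
  fmat mW, vW;
  fvec mb, vb, mg, vg, mbe, vbe;
};

template <typename T>
static void adam_step(T& p, T& m, T& v, const T& g, float lr, double t) {
  m = 0.9f * m + 0.1f * g;
  v = 0.999f * v + 0.001f * (g % g);
  const float c1 = (float)(1.0 - std::pow(0.9, t));
  const float c2 = (float)(1.0 - std::pow(0.999, t));
  p -= lr * (m / c1) / (arma::sqrt(v / c2) + 1e-8f);
}

// [[Rcpp::export]]
Rcpp::List ae_train_cpp(Rcpp::List r_layers, Rcpp::List images, int epochs,
                        int batch_size, double lr, int seed) {
  std::vector<Layer> layers = parse_layers(r_layers);
  const int n = images.size();
  std::vector<fcube> data(n);
  for (int i = 0; i < n; ++i)
    data[i] = arma::conv_to<fcube>::from(Rcpp::as<arma::cube>(images[i]));
  const int input_size = (int)data[0].n_rows;
  std::vector<LayerGeom> geom = geometry(layers, input_size);
  const float flr = (float)lr;
  const size_t n_layers = layers.size();
  const int L_last = (int)n_layers - 1;

  std::vector<AdamState> adam(n_layers);
  for (size_t l = 0; l < n_layers; ++l) {
    adam[l].mW.zeros(arma::size(layers[l].W));
    adam[l].vW.zeros(arma::size(layers[l].W));
    adam[l].mb.zeros(layers[l].b.n_elem);
    adam[l].vb.zeros(layers[l].b.n_elem);
    if (layers[l].bn) {
      adam[l].mg.zeros(layers[l].gamma.n_elem);
      adam[l].vg.zeros(layers[l].gamma.n_elem);
      adam[l].mbe.zeros(layers[l].beta.n_elem);
      adam[l].vbe.zeros(layers[l].beta.n_elem);
    }
  }

  std::mt19937 rng((unsigned int)seed);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  arma::vec loss_trace(epochs, arma::fill::zeros);
  double adam_t = 0.0;

  // BN statistics of the final epoch, averaged over its batches, become the
  // inference (running) statistics.
  std::vector<fvec> sum_mu(n_layers), sum_var(n_layers);
  int n_batches_final = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    const bool last_epoch = (ep == epochs - 1);
    if (last_epoch) {
      for (size_t l = 0; l < n_layers; ++l) {
        if (layers[l].bn) {
          sum_mu[l].zeros(layers[l].out_ch);
          sum_var[l].zeros(layers[l].out_ch);
        }
      }
    }
    double ep_loss = 0.0;
    int n_seen = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int end = std::min(n, start + batch_size);
      const int B = end - start;
      std::vector<fcube> batch(B);
      for (int i = 0; i < B; ++i) batch[i] = data[idx[start + i]];

      BatchCache cache;
      fmat out = forward_batch(layers, geom, batch, true, &cache);

      const int npos_out = geom[L_last].npos;
      const double denom = (double)layers[L_last].out_ch * npos_out;
      fmat Xflat((size_t)B * npos_out, layers[L_last].out_ch);
      for (int i = 0; i < B; ++i) cube_to_flat(batch[i], Xflat, i, npos_out);
      fmat diff = out - Xflat;
      ep_loss += arma::accu(arma::square(diff)) / denom;
      n_seen += B;
      fmat dY = (float)(2.0 / denom / (double)B) * diff;

      if (last_epoch) {
        for (size_t l = 0; l < n_layers; ++l) {
          if (layers[l].bn) {
            sum_mu[l] += cache.mu[l];
            sum_var[l] += cache.var[l];
          }
        }
        ++n_batches_final;
      }

      adam_t += 1.0;
      for (int l = L_last; l >= 0; --l) {
        Layer& L = layers[l];
        const LayerGeom& G = geom[l];
        const fmat& Y = cache.y[l];
        const fmat& Z = cache.z[l];

        // activation backward
        fmat da;
        if (L.act == 1) {
          da = dY % Y % (1.0f - Y);
        } else {
          da = dY;
          // ELU'(a) = 1 for a > 0, exp(a) = y + 1 otherwise; the sign of a
          // is recoverable from y since ELU is monotone with y > 0 iff a > 0.
          const float* yp = Y.memptr();
          float* dp = da.memptr();
          for (arma::uword u = 0; u < da.n_elem; ++u)
            if (yp[u] <= 0.0f) dp[u] *= (yp[u] + 1.0f);
        }

        // batch-norm backward, one contiguous column per channel
        fmat dz;
        fvec dgamma, dbeta;
        if (L.bn) {
          dz.set_size(arma::size(da));
          dgamma.set_size(L.out_ch);
          dbeta.set_size(L.out_ch);
          const float cnt = (float)da.n_rows;
          for (int c = 0; c < L.out_ch; ++c) {
            const float inv_sd = 1.0f / std::sqrt(cache.var[l](c) + BN_EPS);
            fvec xhat = (Z.col(c) - cache.mu[l](c)) * inv_sd;
            fvec dxhat = da.col(c) * L.gamma(c);
            dgamma(c) = arma::dot(da.col(c), xhat);
            dbeta(c) = arma::accu(da.col(c));
            const float s1 = arma::accu(dxhat) / cnt;
            const float s2 = arma::dot(dxhat, xhat) / cnt;
            dz.col(c) = inv_sd * (dxhat - s1 - xhat * s2);
          }
        } else {
          dz = da;
        }

        // convolution backward: rebuild the unfolded input, one GEMM each
        // for the weight gradient and the input gradient.
        const std::vector<fcube>& input =
          (l == 0) ? batch : cache.ycube[l - 1];
        fmat cols = unfold_batch(L, G, input);
        fmat dW = (cols.t() * dz).t();   // out_ch x (in_ch*9), matches W
        fvec db = arma::sum(dz, 0).t();
        if (l > 0) {
          fmat dcols = dz * L.W;          // (B*npos) x (in_ch*9)
          fmat dY_prev((size_t)B * geom[l - 1].npos, L.in_ch);
          for (int i = 0; i < B; ++i) {
            fcube dX;
            if (L.type == 0) {
              dX = col2im(dcols, i * G.npos, G.Hin, G.Hin, L.in_ch, L.stride);
            } else {
              fcube dXs = col2im(dcols, i * G.npos, G.Hstuff, G.Hstuff,
                                 L.in_ch, 1);
              dX = (L.stride > 1) ? unstuff(dXs, L.stride, G.Hin, G.Hin)
                                  : std::move(dXs);
            }
            cube_to_flat(dX, dY_prev, i, geom[l - 1].npos);
          }
          dY = std::move(dY_prev);
        }

        adam_step(L.W, adam[l].mW, adam[l].vW, dW, flr, adam_t);
        adam_step(L.b, adam[l].mb, adam[l].vb, db, flr, adam_t);
        if (L.bn) {
          adam_step(L.gamma, adam[l].mg, adam[l].vg, dgamma, flr, adam_t);
          adam_step(L.beta, adam[l].mbe, adam[l].vbe, dbeta, flr, adam_t);
        }
      }
      Rcpp::checkUserInterrupt();
    }
    loss_trace(ep) = ep_loss / (double)n_seen;
  }

  if (n_batches_final > 0) {
    for (size_t l = 0; l < n_layers; ++l) {
      if (layers[l].bn) {
        layers[l].rmean = sum_mu[l] / (float)n_batches_final;
        layers[l].rvar = sum_var[l] / (float)n_batches_final;
      }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("layers") = layers_to_r(layers, r_layers),
    Rcpp::Named("loss_trace") = loss_trace);
}

// Reconstruct a batch of images in inference mode (BN running statistics).
// [[Rcpp::export]]
Rcpp::List ae_reconstruct_cpp(Rcpp::List r_layers, Rcpp::List images) {
  std::vector<Layer> layers = parse_layers(r_layers);
  const int n = images.size();
  std::vector<fcube> data(n);
  for (int i = 0; i < n; ++i)
    data[i] = arma::conv_to<fcube>::from(Rcpp::as<arma::cube>(images[i]));
  std::vector<LayerGeom> geom = geometry(layers, (int)data[0].n_rows);
  const int L_last = (int)layers.size() - 1;

  Rcpp::List res(n);
  const int chunk = 32;  // bound memory during inference
  for (int start = 0; start < n; start += chunk) {
    const int end = std::min(n, start + chunk);
    std::vector<fcube> batch(data.begin() + start, data.begin() + end);
    fmat out = forward_batch(layers, geom, batch, false, nullptr);
    for (int i = 0; i < end - start; ++i) {
      fcube Y = flat_to_cube(out, i, geom[L_last].npos, geom[L_last].Hout,
                             geom[L_last].Hout);
      res[start + i] = arma::conv_to<arma::cube>::from(Y);
    }
  }
  return res;
}

// Per-layer output spatial sizes for a given input size (shape conformance).
// [[Rcpp::export]]
Rcpp::IntegerVector ae_layer_sizes_cpp(Rcpp::List r_layers, int input_size) {
  std::vector<Layer> layers = parse_layers(r_layers);
  std::vector<LayerGeom> geom = geometry(layers, input_size);
  Rcpp::IntegerVector sizes(layers.size());
  for (size_t l = 0; l < layers.size(); ++l) sizes[l] = geom[l].Hout;
  return sizes;
}
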