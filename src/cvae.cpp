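// Convolutional variational autoencoder on contact maps.
//
// Encoder: L stride-1 "same"-padded convolutions (ReLU) -> 2x2 mean-pool
// (single stride-2 downsample) -> dense (ReLU) -> linear (mu, log sigma^2)
// heads. Decoder mirrors the encoder: dense -> dense -> unflatten ->
// nearest-neighbour x2 upsample -> L convolutions, the last mapping to one
// channel through a sigmoid. Losses: per-map summed binary cross entropy
// averaged over the batch, plus the closed-form KL(N(mu, sigma^2) || N(0,1))
// averaged over the batch. All randomness (init, shuffling, reparameterized
// eps) is drawn from a std::mt19937_64 seeded from R, so runs are exactly
// reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Dims {
  int M;   // input side (padded map size, even)
  int L;   // number of conv layers in encoder (and decoder)
  int F;   // filters per conv layer
  int k;   // kernel side
  int nd;  // dense width
  int d;   // latent width
  int P;   // pooled side = M/2
  int Pf;  // flattened pooled size = P*P*F
};

Dims make_dims(const Rcpp::List& hp) {
  Dims dm;
  dm.M = Rcpp::as<int>(hp["input_dim"]);
  dm.L = Rcpp::as<int>(hp["n_conv_layers"]);
  dm.F = Rcpp::as<int>(hp["n_filters"]);
  dm.k = Rcpp::as<int>(hp["kernel"]);
  dm.nd = Rcpp::as<int>(hp["n_dense"]);
  dm.d = Rcpp::as<int>(hp["latent_dim"]);
  if (dm.M < 2 || dm.M % 2 != 0)
    Rcpp::stop("input_dim must be an even integer >= 2");
  dm.P = dm.M / 2;
  dm.Pf = dm.P * dm.P * dm.F;
  return dm;
}

// Parameter vector layout:
//   [0 .. 2L-1]        encoder conv W/b pairs
//   [2L .. 2L+9]       Wd1, bd1, Wmu, bmu, Wlv, blv, Wd2, bd2, Wd3, bd3
//   [2L+10 .. 4L+9]    decoder conv W/b pairs
// Conv weights are (k*k*Cin) x Cout; biases are 1 x Cout row vectors.
int n_params(const Dims& dm) { return 4 * dm.L + 10; }

std::vector<mat> init_params(const Dims& dm, std::mt19937_64& rng) {
  std::vector<mat> P;
  P.reserve(n_params(dm));
  auto glorot = [&](int nr, int nc, int fan_in, int fan_out) {
    double lim = std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<double> U(-lim, lim);
    mat W(nr, nc);
    for (uword j = 0; j < W.n_cols; ++j)
      for (uword i = 0; i < W.n_rows; ++i) W(i, j) = U(rng);
    return W;
  };
  int kk = dm.k * dm.k;
  for (int l = 0; l < dm.L; ++l) {           // encoder convs
    int cin = (l == 0) ? 1 : dm.F;
    P.push_back(glorot(kk * cin, dm.F, kk * cin, kk * dm.F));
    P.push_back(mat(1, dm.F, fill::zeros));
  }
  P.push_back(glorot(dm.Pf, dm.nd, dm.Pf, dm.nd));   // Wd1
  P.push_back(mat(1, dm.nd, fill::zeros));
  P.push_back(glorot(dm.nd, dm.d, dm.nd, dm.d));     // Wmu
  P.push_back(mat(1, dm.d, fill::zeros));
  P.push_back(glorot(dm.nd, dm.d, dm.nd, dm.d));     // Wlv
  P.push_back(mat(1, dm.d, fill::zeros));
  P.push_back(glorot(dm.d, dm.nd, dm.d, dm.nd));     // Wd2
  P.push_back(mat(1, dm.nd, fill::zeros));
  P.push_back(glorot(dm.nd, dm.Pf, dm.nd, dm.Pf));   // Wd3
  P.push_back(mat(1, dm.Pf, fill::zeros));
  for (int l = 0; l < dm.L; ++l) {           // decoder convs
    int cout = (l == dm.L - 1) ? 1 : dm.F;
    P.push_back(glorot(kk * dm.F, cout, kk * dm.F, kk * cout));
    P.push_back(mat(1, cout, fill::zeros));
  }
  return P;
}

// im2col for a zero-padded stride-1 "same" convolution. Rows index output
// pixels (column-major i + j*H), columns index (channel, kj, ki).
mat im2col(const cube& X, int k) {
  int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  int lo = (k - 1) / 2;
  mat out(H * W, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* Xc = X.slice_memptr(c);
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        double* oc = out.colptr(c * k * k + kj * k + ki);
        int i0 = std::max(0, lo - ki), i1 = std::min(H - 1, H - 1 + lo - ki);
        int len = i1 - i0 + 1;
        if (len <= 0) continue;
        for (int j = 0; j < W; ++j) {
          int sj = j + kj - lo;
          if (sj < 0 || sj >= W) continue;
          // contiguous run: out rows i0..i1 of pixel column j <- X column sj
          std::copy(Xc + sj * H + i0 + ki - lo,
                    Xc + sj * H + i0 + ki - lo + len, oc + j * H + i0);
        }
      }
  }
  return out;
}

// Adjoint of im2col: scatter-add a (H*W) x (k*k*C) gradient back to H x W x C.
cube col2im(const mat& G, int H, int W, int C, int k) {
  int lo = (k - 1) / 2;
  cube out(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* Oc = out.slice_memptr(c);
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const double* gc = G.colptr(c * k * k + kj * k + ki);
        int i0 = std::max(0, lo - ki), i1 = std::min(H - 1, H - 1 + lo - ki);
        int len = i1 - i0 + 1;
        if (len <= 0) continue;
        for (int j = 0; j < W; ++j) {
          int sj = j + kj - lo;
          if (sj < 0 || sj >= W) continue;
          double* dst = Oc + sj * H + i0 + ki - lo;
          const double* src = gc + j * H + i0;
          for (int t = 0; t < len; ++t) dst[t] += src[t];
        }
      }
  }
  return out;
}

cube mat_to_cube(const mat& Z, int H, int W) {
  cube out(H, W, Z.n_cols);
  for (uword c = 0; c < Z.n_cols; ++c)
    out.slice(c) = reshape(Z.col(c), H, W);
  return out;
}

mat cube_to_mat(const cube& X) {
  mat out(X.n_rows * X.n_cols, X.n_slices);
  for (uword c = 0; c < X.n_slices; ++c)
    out.col(c) = vectorise(X.slice(c));
  return out;
}

cube meanpool2(const cube& X) {
  int P = X.n_rows / 2;
  cube out(P, P, X.n_slices);
  for (uword c = 0; c < X.n_slices; ++c)
    for (int j = 0; j < P; ++j)
      for (int i = 0; i < P; ++i)
        out(i, j, c) = 0.25 * (X(2 * i, 2 * j, c) + X(2 * i + 1, 2 * j, c) +
                               X(2 * i, 2 * j + 1, c) + X(2 * i + 1, 2 * j + 1, c));
  return out;
}

cube meanpool2_back(const cube& G, int H) {
  cube out(H, H, G.n_slices);
  for (uword c = 0; c < G.n_slices; ++c)
    for (uword j = 0; j < G.n_cols; ++j)
      for (uword i = 0; i < G.n_rows; ++i) {
        double g = 0.25 * G(i, j, c);
        out(2 * i, 2 * j, c) = g;
        out(2 * i + 1, 2 * j, c) = g;
        out(2 * i, 2 * j + 1, c) = g;
        out(2 * i + 1, 2 * j + 1, c) = g;
      }
  return out;
}

cube upsample2(const cube& X) {
  int H = X.n_rows;
  cube out(2 * H, 2 * H, X.n_slices);
  for (uword c = 0; c < X.n_slices; ++c)
    for (int j = 0; j < H; ++j)
      for (int i = 0; i < H; ++i) {
        double v = X(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

cube upsample2_back(const cube& G) {
  int P = G.n_rows / 2;
  cube out(P, P, G.n_slices);
  for (uword c = 0; c < G.n_slices; ++c)
    for (int j = 0; j < P; ++j)
      for (int i = 0; i < P; ++i)
        out(i, j, c) = G(2 * i, 2 * j, c) + G(2 * i + 1, 2 * j, c) +
                       G(2 * i, 2 * j + 1, c) + G(2 * i + 1, 2 * j + 1, c);
  return out;
}

struct Cache {
  std::vector<mat> enc_cols;    // im2col inputs per encoder conv
  std::vector<cube> enc_pre;    // pre-activation conv outputs
  cube pooled;
  rowvec flat, h1_pre, h1, mu, lv, eps, z;
  rowvec h2_pre, h2, g_pre, g;
  std::vector<mat> dec_cols;
  std::vector<cube> dec_pre;
  cube fhat;                    // sigmoid output, M x M x 1
};

// Forward pass for one map. If eps is empty, z = mu (deterministic).
void forward(const std::vector<mat>& P, const Dims& dm, const mat& Xmap,
             const rowvec& eps, Cache& C) {
  int L = dm.L;
  cube a(dm.M, dm.M, 1);
  a.slice(0) = Xmap;
  C.enc_cols.resize(L);
  C.enc_pre.resize(L);
  for (int l = 0; l < L; ++l) {
    C.enc_cols[l] = im2col(a, dm.k);
    mat Z = C.enc_cols[l] * P[2 * l];
    Z.each_row() += P[2 * l + 1];
    C.enc_pre[l] = mat_to_cube(Z, dm.M, dm.M);
    a = clamp(C.enc_pre[l], 0.0, datum::inf);  // ReLU
  }
  C.pooled = meanpool2(a);
  C.flat = vectorise(C.pooled).t();
  int o = 2 * L;
  C.h1_pre = C.flat * P[o] + P[o + 1];
  C.h1 = clamp(C.h1_pre, 0.0, datum::inf);
  C.mu = C.h1 * P[o + 2] + P[o + 3];
  C.lv = C.h1 * P[o + 4] + P[o + 5];
  if (eps.n_elem == 0) {
    C.eps.reset();
    C.z = C.mu;
  } else {
    C.eps = eps;
    C.z = C.mu + exp(0.5 * C.lv) % eps;
  }
  C.h2_pre = C.z * P[o + 6] + P[o + 7];
  C.h2 = clamp(C.h2_pre, 0.0, datum::inf);
  C.g_pre = C.h2 * P[o + 8] + P[o + 9];
  C.g = clamp(C.g_pre, 0.0, datum::inf);
  cube gc(const_cast<double*>(C.g.memptr()), dm.P, dm.P, dm.F, false, true);
  cube u = upsample2(gc);
  C.dec_cols.resize(L);
  C.dec_pre.resize(L);
  for (int l = 0; l < L; ++l) {
    C.dec_cols[l] = im2col(u, dm.k);
    mat Z = C.dec_cols[l] * P[o + 10 + 2 * l];
    Z.each_row() += P[o + 10 + 2 * l + 1];
    int cout = (l == L - 1) ? 1 : dm.F;
    C.dec_pre[l] = mat_to_cube(Z, dm.M, dm.M);
    if (l < L - 1)
      u = clamp(C.dec_pre[l], 0.0, datum::inf);
  }
  C.fhat = 1.0 / (1.0 + exp(-C.dec_pre[L - 1]));
}

// Per-sample losses given a completed forward pass.
void losses(const Dims& dm, const mat& Xmap, const Cache& C,
            double& Er, double& El) {
  cube f = clamp(C.fhat, 1e-7, 1.0 - 1e-7);
  Er = -accu(Xmap % log(f.slice(0)) + (1.0 - Xmap) % log(1.0 - f.slice(0)));
  El = -0.5 * accu(1.0 + C.lv - square(C.mu) - exp(C.lv));
}

// Backward pass; adds this sample's parameter gradients into G.
void backward(const std::vector<mat>& P, const Dims& dm, const mat& Xmap,
              const Cache& C, std::vector<mat>& G) {
  int L = dm.L, o = 2 * L;
  // output: dE_r/dlogit = fhat - X
  cube dpre = C.fhat;
  dpre.slice(0) -= Xmap;
  // decoder convs, last to first
  cube dinput;
  for (int l = L - 1; l >= 0; --l) {
    if (l < L - 1)
      dpre %= conv_to<cube>::from(C.dec_pre[l] > 0);  // ReLU mask
    mat dmatZ = cube_to_mat(dpre);
    G[o + 10 + 2 * l] += C.dec_cols[l].t() * dmatZ;
    G[o + 10 + 2 * l + 1] += sum(dmatZ, 0);
    dinput = col2im(dmatZ * P[o + 10 + 2 * l].t(), dm.M, dm.M,
                    P[o + 10 + 2 * l].n_rows / (dm.k * dm.k), dm.k);
    dpre = dinput;
  }
  cube dg_c = upsample2_back(dinput);
  rowvec dg = vectorise(dg_c).t();
  dg %= conv_to<rowvec>::from(C.g_pre > 0);
  G[o + 8] += C.h2.t() * dg;
  G[o + 9] += dg;
  rowvec dh2 = dg * P[o + 8].t();
  dh2 %= conv_to<rowvec>::from(C.h2_pre > 0);
  G[o + 6] += C.z.t() * dh2;
  G[o + 7] += dh2;
  rowvec dz = dh2 * P[o + 6].t();
  // reparameterization + KL terms
  rowvec dmu = dz + C.mu;
  rowvec dlv = 0.5 * (exp(C.lv) - 1.0);
  if (C.eps.n_elem > 0)
    dlv += dz % (0.5 * exp(0.5 * C.lv) % C.eps);
  G[o + 2] += C.h1.t() * dmu;
  G[o + 3] += dmu;
  G[o + 4] += C.h1.t() * dlv;
  G[o + 5] += dlv;
  rowvec dh1 = dmu * P[o + 2].t() + dlv * P[o + 4].t();
  dh1 %= conv_to<rowvec>::from(C.h1_pre > 0);
  G[o] += C.flat.t() * dh1;
  G[o + 1] += dh1;
  rowvec dflat = dh1 * P[o].t();
  cube dpool(const_cast<double*>(dflat.memptr()), dm.P, dm.P, dm.F, false, true);
  cube da = meanpool2_back(dpool, dm.M);
  for (int l = L - 1; l >= 0; --l) {
    da %= conv_to<cube>::from(C.enc_pre[l] > 0);
    mat dmatZ = cube_to_mat(da);
    G[2 * l] += C.enc_cols[l].t() * dmatZ;
    G[2 * l + 1] += sum(dmatZ, 0);
    if (l > 0)
      da = col2im(dmatZ * P[2 * l].t(), dm.M, dm.M, dm.F, dm.k);
  }
}

enum OptKind { RMSPROP, ADAM, ADAMAX, ADAGRAD };

OptKind opt_kind(const std::string& s) {
  std::string t;
  for (char c : s) t.push_back(std::tolower(c));
  if (t == "rmsprop") return RMSPROP;
  if (t == "adam") return ADAM;
  if (t == "adamax") return ADAMAX;
  if (t == "adagrad") return ADAGRAD;
  Rcpp::stop("unknown optimizer '%s'", s);
}

struct Optimizer {
  OptKind kind;
  double lr;
  long t = 0;
  std::vector<mat> s1, s2;
  Optimizer(OptKind k, double lr_, const std::vector<mat>& P) : kind(k), lr(lr_) {
    for (const mat& p : P) {
      s1.push_back(mat(p.n_rows, p.n_cols, fill::zeros));
      s2.push_back(mat(p.n_rows, p.n_cols, fill::zeros));
    }
  }
  void step(std::vector<mat>& P, const std::vector<mat>& G) {
    ++t;
    const double eps = 1e-8;
    for (size_t i = 0; i < P.size(); ++i) {
      switch (kind) {
      case RMSPROP:
        s1[i] = 0.9 * s1[i] + 0.1 * square(G[i]);
        P[i] -= lr * G[i] / (sqrt(s1[i]) + eps);
        break;
      case ADAM: {
        s1[i] = 0.9 * s1[i] + 0.1 * G[i];
        s2[i] = 0.999 * s2[i] + 0.001 * square(G[i]);
        double c1 = 1.0 - std::pow(0.9, (double)t);
        double c2 = 1.0 - std::pow(0.999, (double)t);
        P[i] -= lr * (s1[i] / c1) / (sqrt(s2[i] / c2) + eps);
        break;
      }
      case ADAMAX: {
        s1[i] = 0.9 * s1[i] + 0.1 * G[i];
        s2[i] = max(0.999 * s2[i], abs(G[i]));
        double c1 = 1.0 - std::pow(0.9, (double)t);
        P[i] -= (lr / c1) * s1[i] / (s2[i] + eps);
        break;
      }
      case ADAGRAD:
        s1[i] += square(G[i]);
        P[i] -= lr * G[i] / (sqrt(s1[i]) + eps);
        break;
      }
    }
  }
};

std::vector<mat> list_to_params(const Rcpp::List& W) {
  std::vector<mat> P;
  P.reserve(W.size());
  for (int i = 0; i < W.size(); ++i)
    P.push_back(Rcpp::as<mat>(W[i]));
  return P;
}

Rcpp::List params_to_list(const std::vector<mat>& P) {
  Rcpp::List out(P.size());
  for (size_t i = 0; i < P.size(); ++i)
    out[i] = P[i];
  return out;
}

// Mean per-sample (Er, El) over an index set with deterministic z = mu.
void eval_set(const std::vector<mat>& P, const Dims& dm, const cube& X,
              const uvec& idx, double& Er, double& El) {
  Er = 0.0;
  El = 0.0;
  if (idx.n_elem == 0) return;
  Cache C;
  rowvec no_eps;
  double er, el;
  for (uword i = 0; i < idx.n_elem; ++i) {
    forward(P, dm, X.slice(idx[i]), no_eps, C);
    losses(dm, X.slice(idx[i]), C, er, el);
    Er += er;
    El += el;
  }
  Er /= idx.n_elem;
  El /= idx.n_elem;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cvae_init_cpp(Rcpp::List hp, int seed) {
  Dims dm = make_dims(hp);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  return params_to_list(init_params(dm, rng));
}

// [[Rcpp::export]]
Rcpp::List cvae_train_cpp(Rcpp::List weights, Rcpp::List hp, const arma::cube& X,
                          const arma::uvec& train_idx, const arma::uvec& val_idx,
                          int epochs, int batch_size, std::string optimizer,
                          double lr, int seed, int patience = 0,
                          double tol = 1e-3) {
  Dims dm = make_dims(hp);
  std::vector<mat> P = list_to_params(weights);
  if ((int)P.size() != n_params(dm))
    Rcpp::stop("weight list does not match the hyperparameter layout");
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  std::normal_distribution<double> N01(0.0, 1.0);
  Optimizer opt(opt_kind(optimizer), lr, P);
  int n_train = train_idx.n_elem;
  if (epochs > 0 && n_train == 0)
    Rcpp::stop("empty training set");
  std::vector<mat> G;
  for (const mat& p : P) G.push_back(mat(p.n_rows, p.n_cols, fill::zeros));
  mat trace(epochs, 7);
  std::vector<uword> order(train_idx.begin(), train_idx.end());
  Cache C;
  double best_val = datum::inf;
  int stall = 0, done = 0;
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(order.begin(), order.end(), rng);
    double sumEr = 0.0, sumEl = 0.0;
    for (int b0 = 0; b0 < n_train; b0 += batch_size) {
      int b1 = std::min(b0 + batch_size, n_train);
      int nb = b1 - b0;
      for (auto& g : G) g.zeros();
      for (int s = b0; s < b1; ++s) {
        const mat& Xmap = X.slice(order[s]);
        rowvec eps(dm.d);
        for (int j = 0; j < dm.d; ++j) eps[j] = N01(rng);
        forward(P, dm, Xmap, eps, C);
        double er, el;
        losses(dm, Xmap, C, er, el);
        sumEr += er;
        sumEl += el;
        backward(P, dm, Xmap, C, G);
      }
      for (auto& g : G) g /= nb;
      opt.step(P, G);
    }
    double trEr = sumEr / n_train, trEl = sumEl / n_train;
    if (!std::isfinite(trEr) || !std::isfinite(trEl))
      Rcpp::stop("training diverged (non-finite loss) at epoch %d", e + 1);
    double vEr, vEl;
    eval_set(P, dm, X, val_idx, vEr, vEl);
    trace(e, 0) = e + 1;
    trace(e, 1) = trEr + trEl;
    trace(e, 2) = trEr;
    trace(e, 3) = trEl;
    trace(e, 4) = vEr + vEl;
    trace(e, 5) = vEr;
    trace(e, 6) = vEl;
    done = e + 1;
    if (patience > 0 && val_idx.n_elem > 0) {
      double vL = vEr + vEl;
      if (vL < best_val - tol) {
        best_val = vL;
        stall = 0;
      } else if (++stall >= patience) {
        break;  // validation loss plateaued
      }
    }
    Rcpp::checkUserInterrupt();
  }
  if (done < epochs)
    trace = trace.rows(0, done > 0 ? done - 1 : 0);
  if (done == 0)
    trace.set_size(0, 7);
  return Rcpp::List::create(Rcpp::Named("weights") = params_to_list(P),
                            Rcpp::Named("trace") = trace);
}

// [[Rcpp::export]]
Rcpp::List cvae_encode_cpp(Rcpp::List weights, Rcpp::List hp, const arma::cube& X,
                           int seed, bool sample) {
  Dims dm = make_dims(hp);
  std::vector<mat> P = list_to_params(weights);
  int n = X.n_slices;
  mat mu(n, dm.d), lv(n, dm.d), z(n, dm.d);
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 7ULL);
  std::normal_distribution<double> N01(0.0, 1.0);
  Cache C;
  rowvec no_eps;
  for (int i = 0; i < n; ++i) {
    rowvec eps;
    if (sample) {
      eps.set_size(dm.d);
      for (int j = 0; j < dm.d; ++j) eps[j] = N01(rng);
    }
    forward(P, dm, X.slice(i), sample ? eps : no_eps, C);
    mu.row(i) = C.mu;
    lv.row(i) = C.lv;
    z.row(i) = C.z;
  }
  return Rcpp::List::create(Rcpp::Named("mu") = mu, Rcpp::Named("log_var") = lv,
                            Rcpp::Named("z") = z);
}

// [[Rcpp::export]]
arma::cube cvae_decode_cpp(Rcpp::List weights, Rcpp::List hp, const arma::mat& Z) {
  Dims dm = make_dims(hp);
  std::vector<mat> P = list_to_params(weights);
  if ((int)Z.n_cols != dm.d)
    Rcpp::stop("latent matrix has %d columns; model expects %d", Z.n_cols, dm.d);
  int L = dm.L, o = 2 * L;
  cube out(dm.M, dm.M, Z.n_rows);
  for (uword i = 0; i < Z.n_rows; ++i) {
    rowvec z = Z.row(i);
    rowvec h2 = clamp(z * P[o + 6] + P[o + 7], 0.0, datum::inf);
    rowvec g = clamp(h2 * P[o + 8] + P[o + 9], 0.0, datum::inf);
    cube gc(const_cast<double*>(g.memptr()), dm.P, dm.P, dm.F, false, true);
    cube u = upsample2(gc);
    for (int l = 0; l < L; ++l) {
      mat Zm = im2col(u, dm.k) * P[o + 10 + 2 * l];
      Zm.each_row() += P[o + 10 + 2 * l + 1];
      cube pre = mat_to_cube(Zm, dm.M, dm.M);
      if (l < L - 1)
        u = clamp(pre, 0.0, datum::inf);
      else
        out.slice(i) = 1.0 / (1.0 + exp(-pre.slice(0)));
    }
  }
  // keep strictly inside (0,1) as a numeric guarantee for downstream logs
  out = clamp(out, 1e-12, 1.0 - 1e-12);
  return out;
}

// Single-sample loss and analytic parameter gradients (fixed eps), used to
// validate the backward pass against numerical differentiation.
// [[Rcpp::export]]
Rcpp::List cvae_loss_grad_cpp(Rcpp::List weights, Rcpp::List hp,
                              const arma::mat& Xmap, const arma::rowvec& eps) {
  Dims dm = make_dims(hp);
  std::vector<mat> P = list_to_params(weights);
  std::vector<mat> G;
  for (const mat& p : P) G.push_back(mat(p.n_rows, p.n_cols, fill::zeros));
  Cache C;
  forward(P, dm, Xmap, eps, C);
  double er, el;
  losses(dm, Xmap, C, er, el);
  backward(P, dm, Xmap, C, G);
  return Rcpp::List::create(Rcpp::Named("loss") = er + el,
                            Rcpp::Named("E_r") = er, Rcpp::Named("E_l") = el,
                            Rcpp::Named("grads") = params_to_list(G));
}

// [[Rcpp::export]]
double cvae_bce_cpp(const arma::cube& X, const arma::cube& F) {
  if (X.n_rows != F.n_rows || X.n_cols != F.n_cols || X.n_slices != F.n_slices)
    Rcpp::stop("shape mismatch between maps and reconstructions");
  cube f = clamp(F, 1e-7, 1.0 - 1e-7);
  double tot = 0.0;
  for (uword s = 0; s < X.n_slices; ++s)
    tot += -accu(X.slice(s) % log(f.slice(s)) +
                 (1.0 - X.slice(s)) % log(1.0 - f.slice(s)));
  return tot / X.n_slices;
}

// [[Rcpp::export]]
double cvae_kl_cpp(const arma::mat& mu, const arma::mat& lv) {
  if (mu.n_rows != lv.n_rows || mu.n_cols != lv.n_cols)
    Rcpp::stop("mu and log_var shapes differ");
  double tot = -0.5 * accu(1.0 + lv - square(mu) - exp(lv));
  return tot / mu.n_rows;
}
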