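// Compact 3D dense-block convolutional network: hand-rolled forward and
// backward passes (conv3x3x3, conv1x1x1, batch norm, ReLU, 2x average
// pooling, global average pooling, fully connected, softmax cross-entropy)
// plus Grad-CAM on the final feature maps. Tensors are column-major with
// dims (D, H, W, C, N), matching R arrays with z fastest.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include <string>
using namespace Rcpp;

namespace {

struct Ten {
  std::vector<double> v;
  int D, H, W, C, N;
  Ten() : D(0), H(0), W(0), C(0), N(0) {}
  Ten(int D_, int H_, int W_, int C_, int N_)
      : v((size_t)D_ * H_ * W_ * C_ * N_, 0.0), D(D_), H(H_), W(W_), C(C_), N(N_) {}
  inline size_t idx(int z, int y, int x, int c, int n) const {
    return (size_t)z + (size_t)D * ((size_t)y + (size_t)H * ((size_t)x + (size_t)W * ((size_t)c + (size_t)C * (size_t)n)));
  }
  inline double at(int z, int y, int x, int c, int n) const { return v[idx(z, y, x, c, n)]; }
  inline double& at(int z, int y, int x, int c, int n) { return v[idx(z, y, x, c, n)]; }
  size_t spatial() const { return (size_t)D * H * W; }
  size_t size() const { return v.size(); }
};

// weight layout for 3x3x3 conv: (kz, ky, kx, cin, cout), column-major
inline size_t w3idx(int kz, int ky, int kx, int ci, int co, int Cin) {
  return (size_t)kz + 3 * ((size_t)ky + 3 * ((size_t)kx + 3 * ((size_t)ci + (size_t)Cin * (size_t)co)));
}

void conv3_fwd(const Ten& in, const double* Wt, int Cout, Ten& out) {
  out = Ten(in.D, in.H, in.W, Cout, in.N);
  const int D = in.D, H = in.H, Wd = in.W, Cin = in.C, N = in.N;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        for (int kx = 0; kx < 3; ++kx)
          for (int ky = 0; ky < 3; ++ky)
            for (int kz = 0; kz < 3; ++kz) {
              const double w = Wt[w3idx(kz, ky, kx, ci, co, Cin)];
              if (w == 0.0) continue;
              const int dz = kz - 1, dy = ky - 1, dx = kx - 1;
              const int x0 = std::max(0, -dx), x1 = std::min(Wd, Wd - dx);
              const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
              const int z0 = std::max(0, -dz), z1 = std::min(D, D - dz);
              for (int x = x0; x < x1; ++x)
                for (int y = y0; y < y1; ++y) {
                  const double* src = &in.v[in.idx(z0 + dz, y + dy, x + dx, ci, n)];
                  double* dst = &out.v[out.idx(z0, y, x, co, n)];
                  for (int z = z0; z < z1; ++z) *dst++ += w * *src++;
                }
            }
}

void conv3_bwd(const Ten& in, const double* Wt, const Ten& gout,
               Ten& gin, double* gW) {
  const int D = in.D, H = in.H, Wd = in.W, Cin = in.C, Cout = gout.C, N = in.N;
  gin = Ten(D, H, Wd, Cin, N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        for (int kx = 0; kx < 3; ++kx)
          for (int ky = 0; ky < 3; ++ky)
            for (int kz = 0; kz < 3; ++kz) {
              const double w = Wt[w3idx(kz, ky, kx, ci, co, Cin)];
              double acc = 0.0;
              const int dz = kz - 1, dy = ky - 1, dx = kx - 1;
              const int x0 = std::max(0, -dx), x1 = std::min(Wd, Wd - dx);
              const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
              const int z0 = std::max(0, -dz), z1 = std::min(D, D - dz);
              for (int x = x0; x < x1; ++x)
                for (int y = y0; y < y1; ++y) {
                  const double* gsrc = &gout.v[gout.idx(z0, y, x, co, n)];
                  const double* isrc = &in.v[in.idx(z0 + dz, y + dy, x + dx, ci, n)];
                  double* gdst = &gin.v[gin.idx(z0 + dz, y + dy, x + dx, ci, n)];
                  for (int z = z0; z < z1; ++z) {
                    acc += gsrc[z - z0] * isrc[z - z0];
                    gdst[z - z0] += w * gsrc[z - z0];
                  }
                }
              gW[w3idx(kz, ky, kx, ci, co, Cin)] += acc;
            }
}

void conv1_fwd(const Ten& in, const double* Wt, int Cout, Ten& out) {
  out = Ten(in.D, in.H, in.W, Cout, in.N);
  const size_t S = in.spatial();
  const int Cin = in.C, N = in.N;
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci) {
        const double w = Wt[(size_t)ci + (size_t)Cin * co];
        const double* src = &in.v[S * ((size_t)ci + (size_t)Cin * n)];
        double* dst = &out.v[S * ((size_t)co + (size_t)Cout * n)];
        for (size_t p = 0; p < S; ++p) dst[p] += w * src[p];
      }
}

void conv1_bwd(const Ten& in, const double* Wt, const Ten& gout,
               Ten& gin, double* gW) {
  const size_t S = in.spatial();
  const int Cin = in.C, Cout = gout.C, N = in.N;
  gin = Ten(in.D, in.H, in.W, Cin, N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci) {
        const double w = Wt[(size_t)ci + (size_t)Cin * co];
        const double* gsrc = &gout.v[S * ((size_t)co + (size_t)Cout * n)];
        const double* isrc = &in.v[S * ((size_t)ci + (size_t)Cin * n)];
        double* gdst = &gin.v[S * ((size_t)ci + (size_t)Cin * n)];
        double acc = 0.0;
        for (size_t p = 0; p < S; ++p) {
          acc += gsrc[p] * isrc[p];
          gdst[p] += w * gsrc[p];
        }
        gW[(size_t)ci + (size_t)Cin * co] += acc;
      }
}

struct BNCache {
  Ten xhat;
  std::vector<double> invstd;
};

const double BN_EPS = 1e-5;
const double BN_MOMENTUM = 0.1;

void bn_fwd(const Ten& in, const double* gamma, const double* beta,
            bool training, double* run_m, double* run_v,
            Ten& out, BNCache& cache) {
  const int C = in.C, N = in.N;
  const size_t S = in.spatial();
  const double M = (double)S * N;
  out = Ten(in.D, in.H, in.W, C, N);
  cache.xhat = Ten(in.D, in.H, in.W, C, N);
  cache.invstd.assign(C, 0.0);
  for (int c = 0; c < C; ++c) {
    double mu, var;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* src = &in.v[S * ((size_t)c + (size_t)C * n)];
        for (size_t p = 0; p < S; ++p) { s += src[p]; s2 += src[p] * src[p]; }
      }
      mu = s / M;
      var = s2 / M - mu * mu;
      if (var < 0) var = 0;
      run_m[c] = (1.0 - BN_MOMENTUM) * run_m[c] + BN_MOMENTUM * mu;
      run_v[c] = (1.0 - BN_MOMENTUM) * run_v[c] + BN_MOMENTUM * var;
    } else {
      mu = run_m[c];
      var = run_v[c];
    }
    const double is = 1.0 / std::sqrt(var + BN_EPS);
    cache.invstd[c] = is;
    for (int n = 0; n < N; ++n) {
      const double* src = &in.v[S * ((size_t)c + (size_t)C * n)];
      double* xh = &cache.xhat.v[S * ((size_t)c + (size_t)C * n)];
      double* dst = &out.v[S * ((size_t)c + (size_t)C * n)];
      for (size_t p = 0; p < S; ++p) {
        xh[p] = (src[p] - mu) * is;
        dst[p] = gamma[c] * xh[p] + beta[c];
      }
    }
  }
}

void bn_bwd(const BNCache& cache, const double* gamma, const Ten& gout,
            Ten& gin, double* dgamma, double* dbeta) {
  const int C = gout.C, N = gout.N;
  const size_t S = gout.spatial();
  const double M = (double)S * N;
  gin = Ten(gout.D, gout.H, gout.W, C, N);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* g = &gout.v[S * ((size_t)c + (size_t)C * n)];
      const double* xh = &cache.xhat.v[S * ((size_t)c + (size_t)C * n)];
      for (size_t p = 0; p < S; ++p) { sg += g[p]; sgx += g[p] * xh[p]; }
    }
    dgamma[c] += sgx;
    dbeta[c] += sg;
    const double is = cache.invstd[c];
    for (int n = 0; n < N; ++n) {
      const double* g = &gout.v[S * ((size_t)c + (size_t)C * n)];
      const double* xh = &cache.xhat.v[S * ((size_t)c + (size_t)C * n)];
      double* gi = &gin.v[S * ((size_t)c + (size_t)C * n)];
      for (size_t p = 0; p < S; ++p)
        gi[p] = gamma[c] * is / M * (M * g[p] - sg - xh[p] * sgx);
    }
  }
}

void relu_fwd(const Ten& in, Ten& out) {
  out = in;
  for (size_t i = 0; i < out.size(); ++i) if (out.v[i] < 0) out.v[i] = 0;
}

void relu_bwd(const Ten& in, const Ten& gout, Ten& gin) {
  gin = gout;
  for (size_t i = 0; i < gin.size(); ++i) if (in.v[i] <= 0) gin.v[i] = 0;
}

void pool2_fwd(const Ten& in, Ten& out) {
  const int D = in.D / 2, H = in.H / 2, Wd = in.W / 2;
  out = Ten(D, H, Wd, in.C, in.N);
  for (int n = 0; n < in.N; ++n)
    for (int c = 0; c < in.C; ++c)
      for (int x = 0; x < Wd; ++x)
        for (int y = 0; y < H; ++y)
          for (int z = 0; z < D; ++z) {
            double s = 0.0;
            for (int dx = 0; dx < 2; ++dx)
              for (int dy = 0; dy < 2; ++dy)
                for (int dz = 0; dz < 2; ++dz)
                  s += in.at(2 * z + dz, 2 * y + dy, 2 * x + dx, c, n);
            out.at(z, y, x, c, n) = s / 8.0;
          }
}

void pool2_bwd(const Ten& in, const Ten& gout, Ten& gin) {
  gin = Ten(in.D, in.H, in.W, in.C, in.N);
  for (int n = 0; n < in.N; ++n)
    for (int c = 0; c < in.C; ++c)
      for (int x = 0; x < gout.W; ++x)
        for (int y = 0; y < gout.H; ++y)
          for (int z = 0; z < gout.D; ++z) {
            const double g = gout.at(z, y, x, c, n) / 8.0;
            for (int dx = 0; dx < 2; ++dx)
              for (int dy = 0; dy < 2; ++dy)
                for (int dz = 0; dz < 2; ++dz)
                  gin.at(2 * z + dz, 2 * y + dy, 2 * x + dx, c, n) = g;
          }
}

void concat_channels(const Ten& a, const Ten& b, Ten& out) {
  out = Ten(a.D, a.H, a.W, a.C + b.C, a.N);
  const size_t S = a.spatial();
  for (int n = 0; n < a.N; ++n) {
    std::memcpy(&out.v[S * (size_t)(a.C + b.C) * n],
                &a.v[S * (size_t)a.C * n], S * a.C * sizeof(double));
    std::memcpy(&out.v[S * ((size_t)(a.C + b.C) * n + a.C)],
                &b.v[S * (size_t)b.C * n], S * b.C * sizeof(double));
  }
}

void split_grad(const Ten& gcat, int Ca, Ten& ga_add, Ten& gb) {
  // first Ca channels accumulate into ga_add, the rest become gb
  const size_t S = gcat.spatial();
  const int Cb = gcat.C - Ca;
  gb = Ten(gcat.D, gcat.H, gcat.W, Cb, gcat.N);
  for (int n = 0; n < gcat.N; ++n) {
    const double* src = &gcat.v[S * (size_t)gcat.C * n];
    double* da = &ga_add.v[S * (size_t)Ca * n];
    for (size_t p = 0; p < S * (size_t)Ca; ++p) da[p] += src[p];
    std::memcpy(&gb.v[S * (size_t)Cb * n], src + S * (size_t)Ca, S * Cb * sizeof(double));
  }
}

struct Cfg {
  int C0, growth, layers, blocks, classes;
  double compression;
};

Cfg read_cfg(const List& cfg) {
  Cfg c;
  c.C0 = as<int>(cfg["init_channels"]);
  c.growth = as<int>(cfg["growth"]);
  c.layers = as<int>(cfg["layers_per_block"]);
  c.blocks = as<int>(cfg["n_blocks"]);
  c.classes = as<int>(cfg["n_classes"]);
  c.compression = as<double>(cfg["compression"]);
  return c;
}

std::string key(const std::string& s) { return s; }

NumericVector getp(const List& L, const std::string& nm) {
  if (!L.containsElementNamed(nm.c_str()))
    stop("missing parameter/state element '%s'", nm.c_str());
  return L[nm];
}

// all caches for one full forward pass
struct FwdCache {
  Ten x;               // input
  Ten conv0_out; BNCache bn0; Ten bn0_out; Ten relu0_out; Ten pool0_out;
  // per dense layer: bn input is the running feats
  std::vector<Ten> feats_in;        // feats entering each dense layer (for bn bwd via cache)
  std::vector<BNCache> dl_bn;       // per dense layer (blocks*layers)
  std::vector<Ten> dl_bn_out, dl_relu_out, dl_conv_out;
  std::vector<Ten> tr_in;           // feats entering each transition
  std::vector<BNCache> tr_bn;
  std::vector<Ten> tr_bn_out, tr_relu_out, tr_conv_out, tr_pool_out;
  Ten final_feats;                  // input of bnF (Grad-CAM target)
  BNCache bnF; Ten bnF_out; Ten reluF_out;
  std::vector<double> gap;          // Cf x N
  std::vector<double> logits;       // classes x N
  std::vector<double> probs;
  int Cf;
};

void forward(const Cfg& cfg, const List& params, List& state, const Ten& x,
             bool training, FwdCache& fc) {
  fc.x = x;
  NumericVector W0 = getp(params, "conv0.W");
  conv3_fwd(x, REAL(W0), cfg.C0, fc.conv0_out);
  {
    NumericVector g = getp(params, "bn0.g"), b = getp(params, "bn0.b");
    NumericVector m = getp(state, "bn0.m"), v = getp(state, "bn0.v");
    bn_fwd(fc.conv0_out, REAL(g), REAL(b), training, REAL(m), REAL(v), fc.bn0_out, fc.bn0);
  }
  relu_fwd(fc.bn0_out, fc.relu0_out);
  pool2_fwd(fc.relu0_out, fc.pool0_out);

  Ten feats = fc.pool0_out;
  const int BL = cfg.blocks * cfg.layers;
  fc.feats_in.resize(BL); fc.dl_bn.resize(BL);
  fc.dl_bn_out.resize(BL); fc.dl_relu_out.resize(BL); fc.dl_conv_out.resize(BL);
  const int T = cfg.blocks - 1;
  fc.tr_in.resize(T); fc.tr_bn.resize(T); fc.tr_bn_out.resize(T);
  fc.tr_relu_out.resize(T); fc.tr_conv_out.resize(T); fc.tr_pool_out.resize(T);

  for (int b = 0; b < cfg.blocks; ++b) {
    for (int l = 0; l < cfg.layers; ++l) {
      const int i = b * cfg.layers + l;
      char nm[64];
      fc.feats_in[i] = feats;
      std::snprintf(nm, 64, "db%d.l%d.bn.g", b, l); NumericVector g = getp(params, nm);
      std::snprintf(nm, 64, "db%d.l%d.bn.b", b, l); NumericVector be = getp(params, nm);
      std::snprintf(nm, 64, "db%d.l%d.bn.m", b, l); NumericVector m = getp(state, nm);
      std::snprintf(nm, 64, "db%d.l%d.bn.v", b, l); NumericVector v = getp(state, nm);
      bn_fwd(feats, REAL(g), REAL(be), training, REAL(m), REAL(v), fc.dl_bn_out[i], fc.dl_bn[i]);
      relu_fwd(fc.dl_bn_out[i], fc.dl_relu_out[i]);
      std::snprintf(nm, 64, "db%d.l%d.W", b, l); NumericVector Wc = getp(params, nm);
      conv3_fwd(fc.dl_relu_out[i], REAL(Wc), cfg.growth, fc.dl_conv_out[i]);
      Ten nf;
      concat_channels(feats, fc.dl_conv_out[i], nf);
      feats = nf;
    }
    if (b < cfg.blocks - 1) {
      char nm[64];
      fc.tr_in[b] = feats;
      std::snprintf(nm, 64, "tr%d.bn.g", b); NumericVector g = getp(params, nm);
      std::snprintf(nm, 64, "tr%d.bn.b", b); NumericVector be = getp(params, nm);
      std::snprintf(nm, 64, "tr%d.bn.m", b); NumericVector m = getp(state, nm);
      std::snprintf(nm, 64, "tr%d.bn.v", b); NumericVector v = getp(state, nm);
      bn_fwd(feats, REAL(g), REAL(be), training, REAL(m), REAL(v), fc.tr_bn_out[b], fc.tr_bn[b]);
      relu_fwd(fc.tr_bn_out[b], fc.tr_relu_out[b]);
      std::snprintf(nm, 64, "tr%d.W", b); NumericVector Wt = getp(params, nm);
      const int Cout = (int)std::floor(cfg.compression * feats.C);
      conv1_fwd(fc.tr_relu_out[b], REAL(Wt), Cout, fc.tr_conv_out[b]);
      pool2_fwd(fc.tr_conv_out[b], fc.tr_pool_out[b]);
      feats = fc.tr_pool_out[b];
    }
  }
  fc.final_feats = feats;
  {
    NumericVector g = getp(params, "bnF.g"), b = getp(params, "bnF.b");
    NumericVector m = getp(state, "bnF.m"), v = getp(state, "bnF.v");
    bn_fwd(feats, REAL(g), REAL(b), training, REAL(m), REAL(v), fc.bnF_out, fc.bnF);
  }
  relu_fwd(fc.bnF_out, fc.reluF_out);
  const int Cf = fc.reluF_out.C, N = fc.reluF_out.N;
  fc.Cf = Cf;
  const size_t S = fc.reluF_out.spatial();
  fc.gap.assign((size_t)Cf * N, 0.0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cf; ++c) {
      const double* src = &fc.reluF_out.v[S * ((size_t)c + (size_t)Cf * n)];
      double s = 0.0;
      for (size_t p = 0; p < S; ++p) s += src[p];
      fc.gap[(size_t)c + (size_t)Cf * n] = s / (double)S;
    }
  NumericVector Wf = getp(params, "fc.W"), bf = getp(params, "fc.b");
  const int K = cfg.classes;
  fc.logits.assign((size_t)K * N, 0.0);
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < K; ++k) {
      double s = REAL(bf)[k];
      for (int c = 0; c < Cf; ++c)
        s += REAL(Wf)[(size_t)c + (size_t)Cf * k] * fc.gap[(size_t)c + (size_t)Cf * n];
      fc.logits[(size_t)k + (size_t)K * n] = s;
    }
  fc.probs.assign((size_t)K * N, 0.0);
  for (int n = 0; n < N; ++n) {
    double mx = fc.logits[(size_t)K * n];
    for (int k = 1; k < K; ++k) mx = std::max(mx, fc.logits[(size_t)k + (size_t)K * n]);
    double Z = 0.0;
    for (int k = 0; k < K; ++k) {
      double e = std::exp(fc.logits[(size_t)k + (size_t)K * n] - mx);
      fc.probs[(size_t)k + (size_t)K * n] = e;
      Z += e;
    }
    for (int k = 0; k < K; ++k) fc.probs[(size_t)k + (size_t)K * n] /= Z;
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_net_forward(List params, List state, NumericVector x, List cfg_, bool training) {
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 5) stop("input must be a 5-d array (D,H,W,C,N)");
  Ten X(dims[0], dims[1], dims[2], dims[3], dims[4]);
  std::copy(x.begin(), x.end(), X.v.begin());
  Cfg cfg = read_cfg(cfg_);
  FwdCache fc;
  forward(cfg, params, state, X, training, fc);
  NumericMatrix probs(cfg.classes, dims[4]);
  std::copy(fc.probs.begin(), fc.probs.end(), probs.begin());
  NumericMatrix logits(cfg.classes, dims[4]);
  std::copy(fc.logits.begin(), fc.logits.end(), logits.begin());
  return List::create(_["probs"] = probs, _["logits"] = logits);
}

// [[Rcpp::export]]
List cpp_net_train_batch(List params, List state, NumericVector x,
                         IntegerVector y, List cfg_) {
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 5) stop("input must be a 5-d array (D,H,W,C,N)");
  const int N = dims[4];
  if (y.size() != N) stop("label length must match batch size");
  Ten X(dims[0], dims[1], dims[2], dims[3], dims[4]);
  std::copy(x.begin(), x.end(), X.v.begin());
  Cfg cfg = read_cfg(cfg_);
  FwdCache fc;
  forward(cfg, params, state, X, true, fc);  // updates running stats in-place

  const int K = cfg.classes;
  double loss = 0.0;
  std::vector<double> dlogits((size_t)K * N, 0.0);
  for (int n = 0; n < N; ++n) {
    const int yi = y[n];
    if (yi < 0 || yi >= K) stop("label out of range");
    const double p = fc.probs[(size_t)yi + (size_t)K * n];
    loss += -std::log(std::max(p, 1e-300));
    for (int k = 0; k < K; ++k)
      dlogits[(size_t)k + (size_t)K * n] =
          (fc.probs[(size_t)k + (size_t)K * n] - (k == yi ? 1.0 : 0.0)) / N;
  }
  loss /= N;
  if (!std::isfinite(loss)) stop("non-finite training loss");

  // gradient containers
  List grads = clone(params);
  CharacterVector nms = grads.names();
  for (int i = 0; i < grads.size(); ++i) {
    NumericVector g = grads[i];
    std::fill(g.begin(), g.end(), 0.0);
  }

  const int Cf = fc.Cf;
  NumericVector Wf = getp(params, "fc.W");
  NumericVector gWf = getp(grads, "fc.W"), gbf = getp(grads, "fc.b");
  std::vector<double> dgap((size_t)Cf * N, 0.0);
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < K; ++k) {
      const double dl = dlogits[(size_t)k + (size_t)K * n];
      REAL(gbf)[k] += dl;
      for (int c = 0; c < Cf; ++c) {
        REAL(gWf)[(size_t)c + (size_t)Cf * k] += dl * fc.gap[(size_t)c + (size_t)Cf * n];
        dgap[(size_t)c + (size_t)Cf * n] += dl * REAL(Wf)[(size_t)c + (size_t)Cf * k];
      }
    }
  const size_t S = fc.reluF_out.spatial();
  Ten dreluF(fc.reluF_out.D, fc.reluF_out.H, fc.reluF_out.W, Cf, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cf; ++c) {
      const double g = dgap[(size_t)c + (size_t)Cf * n] / (double)S;
      double* dst = &dreluF.v[S * ((size_t)c + (size_t)Cf * n)];
      for (size_t p = 0; p < S; ++p) dst[p] = g;
    }
  Ten dbnF_out;
  relu_bwd(fc.bnF_out, dreluF, dbnF_out);
  Ten dfeats;
  {
    NumericVector g = getp(params, "bnF.g");
    NumericVector dg = getp(grads, "bnF.g"), db = getp(grads, "bnF.b");
    bn_bwd(fc.bnF, REAL(g), dbnF_out, dfeats, REAL(dg), REAL(db));
  }

  // walk blocks in reverse
  for (int b = cfg.blocks - 1; b >= 0; --b) {
    if (b < cfg.blocks - 1) {
      // dfeats is gradient wrt tr_pool_out[b]
      Ten dconv, dreluT, dbnT, dtrin;
      pool2_bwd(fc.tr_conv_out[b], dfeats, dconv);
      char nm[64];
      std::snprintf(nm, 64, "tr%d.W", b);
      NumericVector Wt = getp(params, nm), gWt = getp(grads, nm);
      conv1_bwd(fc.tr_relu_out[b], REAL(Wt), dconv, dreluT, REAL(gWt));
      relu_bwd(fc.tr_bn_out[b], dreluT, dbnT);
      std::snprintf(nm, 64, "tr%d.bn.g", b);
      NumericVector g = getp(params, nm), dg = getp(grads, nm);
      std::snprintf(nm, 64, "tr%d.bn.b", b);
      NumericVector db = getp(grads, nm);
      bn_bwd(fc.tr_bn[b], REAL(g), dbnT, dtrin, REAL(dg), REAL(db));
      dfeats = dtrin;
    }
    for (int l = cfg.layers - 1; l >= 0; --l) {
      const int i = b * cfg.layers + l;
      const int Cprev = fc.feats_in[i].C;
      // dfeats: gradient wrt concat(feats_in, conv_out)
      Ten dprev(fc.feats_in[i].D, fc.feats_in[i].H, fc.feats_in[i].W, Cprev, N);
      Ten dconv;
      split_grad(dfeats, Cprev, dprev, dconv);
      char nm[64];
      std::snprintf(nm, 64, "db%d.l%d.W", b, l);
      NumericVector Wc = getp(params, nm), gWc = getp(grads, nm);
      Ten drelu, dbn, din;
      conv3_bwd(fc.dl_relu_out[i], REAL(Wc), dconv, drelu, REAL(gWc));
      relu_bwd(fc.dl_bn_out[i], drelu, dbn);
      std::snprintf(nm, 64, "db%d.l%d.bn.g", b, l);
      NumericVector g = getp(params, nm), dg = getp(grads, nm);
      std::snprintf(nm, 64, "db%d.l%d.bn.b", b, l);
      NumericVector db = getp(grads, nm);
      bn_bwd(fc.dl_bn[i], REAL(g), dbn, din, REAL(dg), REAL(db));
      for (size_t p = 0; p < din.size(); ++p) dprev.v[p] += din.v[p];
      dfeats = dprev;
    }
  }
  // dfeats is gradient wrt pool0_out
  Ten drelu0, dbn0, dconv0, dx;
  pool2_bwd(fc.relu0_out, dfeats, drelu0);
  relu_bwd(fc.bn0_out, drelu0, dbn0);
  {
    NumericVector g = getp(params, "bn0.g");
    NumericVector dg = getp(grads, "bn0.g"), db = getp(grads, "bn0.b");
    bn_bwd(fc.bn0, REAL(g), dbn0, dconv0, REAL(dg), REAL(db));
  }
  {
    NumericVector W0 = getp(params, "conv0.W"), gW0 = getp(grads, "conv0.W");
    conv3_bwd(fc.x, REAL(W0), dconv0, dx, REAL(gW0));
  }

  NumericMatrix probs(K, N);
  std::copy(fc.probs.begin(), fc.probs.end(), probs.begin());
  return List::create(_["loss"] = loss, _["grads"] = grads, _["probs"] = probs);
}

namespace {

// inference-mode batch norm is an affine map per channel, so its backward
// is elementwise gamma / sqrt(running_var + eps)
void bn_bwd_inference(const List& params, const List& state,
                      const std::string& nm, const Ten& gout, Ten& gin) {
  NumericVector g = getp(const_cast<List&>(params), nm + ".g");
  NumericVector rv = getp(const_cast<List&>(state), nm + ".v");
  gin = gout;
  const size_t S = gout.spatial();
  for (int n = 0; n < gout.N; ++n)
    for (int c = 0; c < gout.C; ++c) {
      const double s = REAL(g)[c] / std::sqrt(REAL(rv)[c] + BN_EPS);
      double* dst = &gin.v[S * ((size_t)c + (size_t)gout.C * n)];
      for (size_t p = 0; p < S; ++p) dst[p] *= s;
    }
}

} // namespace

// Gradient of the target-class logit with respect to the feature maps
// produced by dense block `target_block` (0-based), at inference.
// [[Rcpp::export]]
List cpp_net_gradcam(List params, List state, NumericVector x, int target,
                     int target_block, List cfg_) {
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 5 || dims[4] != 1) stop("Grad-CAM expects a single volume (N = 1)");
  Ten X(dims[0], dims[1], dims[2], dims[3], dims[4]);
  std::copy(x.begin(), x.end(), X.v.begin());
  Cfg cfg = read_cfg(cfg_);
  if (target_block < 0 || target_block >= cfg.blocks) stop("target block out of range");
  FwdCache fc;
  forward(cfg, params, state, X, false, fc);
  const int K = cfg.classes, Cf = fc.Cf;
  if (target < 0 || target >= K) stop("target class out of range");

  // seed: gradient of the target logit wrt the post-activation features
  NumericVector Wf = getp(params, "fc.W");
  const size_t S = fc.reluF_out.spatial();
  Ten dreluF(fc.reluF_out.D, fc.reluF_out.H, fc.reluF_out.W, Cf, 1);
  for (int c = 0; c < Cf; ++c) {
    const double g = REAL(Wf)[(size_t)c + (size_t)Cf * target] / (double)S;
    double* dst = &dreluF.v[S * (size_t)c];
    for (size_t p = 0; p < S; ++p) dst[p] = g;
  }
  Ten dbnF_out, dfeats;
  relu_bwd(fc.bnF_out, dreluF, dbnF_out);
  bn_bwd_inference(params, state, "bnF", dbnF_out, dfeats);

  const Ten* amap = &fc.final_feats;
  bool found = (target_block == cfg.blocks - 1);
  for (int b = cfg.blocks - 1; b >= 0 && !found; --b) {
    for (int l = cfg.layers - 1; l >= 0; --l) {
      const int i = b * cfg.layers + l;
      const int Cprev = fc.feats_in[i].C;
      Ten dprev(fc.feats_in[i].D, fc.feats_in[i].H, fc.feats_in[i].W, Cprev, 1);
      Ten dconv;
      split_grad(dfeats, Cprev, dprev, dconv);
      char nm[64];
      std::snprintf(nm, 64, "db%d.l%d.W", b, l);
      NumericVector Wc = getp(params, nm);
      std::vector<double> scratch(Wc.size(), 0.0);
      Ten drelu, dbn, din;
      conv3_bwd(fc.dl_relu_out[i], REAL(Wc), dconv, drelu, scratch.data());
      relu_bwd(fc.dl_bn_out[i], drelu, dbn);
      std::snprintf(nm, 64, "db%d.l%d.bn", b, l);
      bn_bwd_inference(params, state, nm, dbn, din);
      for (size_t p = 0; p < din.size(); ++p) dprev.v[p] += din.v[p];
      dfeats = dprev;
    }
    // dfeats is now the gradient wrt the input of block b, i.e. the pooled
    // transition output of block b-1
    if (b - 1 == target_block) {
      const int t = b - 1;
      Ten dconv, dreluT, dbnT, dtrin;
      pool2_bwd(fc.tr_conv_out[t], dfeats, dconv);
      char nm[64];
      std::snprintf(nm, 64, "tr%d.W", t);
      NumericVector Wt = getp(params, nm);
      std::vector<double> scratch(Wt.size(), 0.0);
      conv1_bwd(fc.tr_relu_out[t], REAL(Wt), dconv, dreluT, scratch.data());
      relu_bwd(fc.tr_bn_out[t], dreluT, dbnT);
      std::snprintf(nm, 64, "tr%d.bn", t);
      bn_bwd_inference(params, state, nm, dbnT, dfeats);
      amap = &fc.tr_in[t];
      found = true;
    } else if (b > 0) {
      const int t = b - 1;
      Ten dconv, dreluT, dbnT;
      pool2_bwd(fc.tr_conv_out[t], dfeats, dconv);
      char nm[64];
      std::snprintf(nm, 64, "tr%d.W", t);
      NumericVector Wt = getp(params, nm);
      std::vector<double> scratch(Wt.size(), 0.0);
      conv1_bwd(fc.tr_relu_out[t], REAL(Wt), dconv, dreluT, scratch.data());
      relu_bwd(fc.tr_bn_out[t], dreluT, dbnT);
      std::snprintf(nm, 64, "tr%d.bn", t);
      bn_bwd_inference(params, state, nm, dbnT, dfeats);
    }
  }

  IntegerVector fd = IntegerVector::create(amap->D, amap->H, amap->W, amap->C);
  NumericVector fmap(amap->v.begin(), amap->v.end());
  fmap.attr("dim") = fd;
  NumericVector grad(dfeats.v.begin(), dfeats.v.end());
  grad.attr("dim") = fd;
  NumericMatrix probs(K, 1);
  std::copy(fc.probs.begin(), fc.probs.end(), probs.begin());
  return List::create(_["fmap"] = fmap, _["grad"] = grad, _["probs"] = probs);
}
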