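// 2.5D U-Net used for neurite masking: the 7 context slices of a chunk enter
// as input channels of a 2D encoder-decoder and the center slice is
// predicted. Forward, backward and the IoU + cross-entropy loss are
// implemented here; the optimizer loop lives in R.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct ConvSpec {
  std::string name;
  int cin, cout, k;  // k = 3 (padded 3x3) or 1 (1x1)
  bool relu;
};

std::vector<ConvSpec> build_specs(int L, int base, int in_ch) {
  std::vector<ConvSpec> sp;
  for (int i = 0; i <= L - 2; ++i) {
    int ci = base << i;
    int prev = (i == 0) ? in_ch : (base << (i - 1));
    sp.push_back({"enc" + std::to_string(i) + "_c1", prev, ci, 3, true});
    sp.push_back({"enc" + std::to_string(i) + "_c2", ci, ci, 3, true});
  }
  int cb = base << (L - 1);
  sp.push_back({"bot_c1", base << (L - 2), cb, 3, true});
  sp.push_back({"bot_c2", cb, cb, 3, true});
  for (int i = L - 2; i >= 0; --i) {
    int ci = base << i;
    sp.push_back({"up" + std::to_string(i), ci * 2, ci, 3, true});
    sp.push_back({"dec" + std::to_string(i) + "_c1", ci * 2, ci, 3, true});
    sp.push_back({"dec" + std::to_string(i) + "_c2", ci, ci, 3, true});
  }
  sp.push_back({"out", base, 1, 1, false});
  return sp;
}

// Spatial index convention: s = y + H * x (column-major over the slice).
arma::mat im2col(const arma::mat& A, int H, int W) {
  int C = A.n_rows, S = H * W;
  arma::mat cols(C * 9, S, arma::fill::zeros);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int s = y + H * x;
      for (int ky = -1; ky <= 1; ++ky) {
        int yy = y + ky;
        if (yy < 0 || yy >= H) continue;
        for (int kx = -1; kx <= 1; ++kx) {
          int xx = x + kx;
          if (xx < 0 || xx >= W) continue;
          int off = (ky + 1) * 3 + (kx + 1);
          int src = yy + H * xx;
          for (int c = 0; c < C; ++c) cols(c * 9 + off, s) = A(c, src);
        }
      }
    }
  return cols;
}

arma::mat col2im(const arma::mat& dcols, int C, int H, int W) {
  arma::mat dX(C, H * W, arma::fill::zeros);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int s = y + H * x;
      for (int ky = -1; ky <= 1; ++ky) {
        int yy = y + ky;
        if (yy < 0 || yy >= H) continue;
        for (int kx = -1; kx <= 1; ++kx) {
          int xx = x + kx;
          if (xx < 0 || xx >= W) continue;
          int off = (ky + 1) * 3 + (kx + 1);
          int src = yy + H * xx;
          for (int c = 0; c < C; ++c) dX(c, src) += dcols(c * 9 + off, s);
        }
      }
    }
  return dX;
}

arma::mat maxpool(const arma::mat& A, int H, int W, arma::umat& idx) {
  int C = A.n_rows, H2 = H / 2, W2 = W / 2;
  arma::mat out(C, H2 * W2);
  idx.set_size(C, H2 * W2);
  for (int x2 = 0; x2 < W2; ++x2)
    for (int y2 = 0; y2 < H2; ++y2) {
      int s2 = y2 + H2 * x2;
      int s00 = 2 * y2 + H * (2 * x2);
      int cand[4] = {s00, s00 + 1, s00 + H, s00 + H + 1};
      for (int c = 0; c < C; ++c) {
        double best = A(c, cand[0]);
        int bi = cand[0];
        for (int q = 1; q < 4; ++q)
          if (A(c, cand[q]) > best) { best = A(c, cand[q]); bi = cand[q]; }
        out(c, s2) = best;
        idx(c, s2) = (arma::uword)bi;
      }
    }
  return out;
}

arma::mat unpool(const arma::mat& dOut, const arma::umat& idx, int H, int W) {
  int C = dOut.n_rows;
  arma::mat dIn(C, H * W, arma::fill::zeros);
  for (arma::uword s2 = 0; s2 < dOut.n_cols; ++s2)
    for (int c = 0; c < C; ++c) dIn(c, idx(c, s2)) += dOut(c, s2);
  return dIn;
}

arma::mat upsample2(const arma::mat& A, int H2, int W2) {
  int C = A.n_rows, H = H2 * 2, W = W2 * 2;
  arma::mat out(C, H * W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int s = y + H * x, s2 = (y / 2) + H2 * (x / 2);
      for (int c = 0; c < C; ++c) out(c, s) = A(c, s2);
    }
  return out;
}

arma::mat downsum2(const arma::mat& dOut, int H2, int W2) {
  int C = dOut.n_rows, H = H2 * 2;
  arma::mat dIn(C, H2 * W2, arma::fill::zeros);
  for (arma::uword s = 0; s < dOut.n_cols; ++s) {
    int y = (int)(s % H), x = (int)(s / H);
    int s2 = (y / 2) + H2 * (x / 2);
    for (int c = 0; c < C; ++c) dIn(c, s2) += dOut(c, s);
  }
  return dIn;
}

struct WStore {
  std::map<std::string, arma::mat> W;
  std::map<std::string, arma::vec> b;
};

WStore load_weights(const List& weights, const std::vector<ConvSpec>& sp) {
  WStore ws;
  for (const auto& c : sp) {
    ws.W[c.name] = as<arma::mat>(weights[c.name + "_W"]);
    ws.b[c.name] = as<arma::vec>(weights[c.name + "_b"]);
  }
  return ws;
}

struct Caches {
  std::map<std::string, arma::mat> cols;  // conv input in im2col form
  std::map<std::string, arma::mat> act;   // conv output (post-ReLU)
  std::vector<arma::umat> poolidx;
};

// Runs the network on one chunk; fills caches when wanted.
arma::rowvec forward_pass(const WStore& ws, const std::vector<ConvSpec>& sp,
                          int L, const arma::mat& X, int H, int W,
                          Caches* cache) {
  auto conv = [&](const std::string& name, const arma::mat& A, int h, int w,
                  bool relu, int k) {
    arma::mat cols = (k == 3) ? im2col(A, h, w) : A;
    arma::mat Y = ws.W.at(name) * cols;
    Y.each_col() += ws.b.at(name);
    if (relu) Y.transform([](double v) { return v > 0 ? v : 0.0; });
    if (cache) { cache->cols[name] = std::move(cols); cache->act[name] = Y; }
    return Y;
  };
  arma::mat a = X;
  std::vector<arma::mat> skips(L - 1);
  for (int i = 0; i <= L - 2; ++i) {
    int h = H >> i, w = W >> i;
    std::string p = "enc" + std::to_string(i);
    a = conv(p + "_c1", a, h, w, true, 3);
    a = conv(p + "_c2", a, h, w, true, 3);
    skips[i] = a;
    arma::umat idx;
    a = maxpool(a, h, w, idx);
    if (cache) cache->poolidx.push_back(std::move(idx));
  }
  {
    int h = H >> (L - 1), w = W >> (L - 1);
    a = conv("bot_c1", a, h, w, true, 3);
    a = conv("bot_c2", a, h, w, true, 3);
  }
  for (int i = L - 2; i >= 0; --i) {
    int h = H >> i, w = W >> i;
    a = upsample2(a, h / 2, w / 2);
    a = conv("up" + std::to_string(i), a, h, w, true, 3);
    a = arma::join_cols(skips[i], a);
    std::string p = "dec" + std::to_string(i);
    a = conv(p + "_c1", a, h, w, true, 3);
    a = conv(p + "_c2", a, h, w, true, 3);
  }
  arma::mat z = conv("out", a, H, W, false, 1);
  arma::rowvec p = 1.0 / (1.0 + arma::exp(-z.row(0)));
  return p;
}

// Loss pieces on probabilities p vs binary target t.
void loss_and_dz(const arma::rowvec& p, const arma::rowvec& t, double eps,
                 double& lce, double& liou, arma::rowvec& dz) {
  int S = p.n_elem;
  arma::rowvec pc = arma::clamp(p, 1e-7, 1.0 - 1e-7);
  lce = -arma::mean(t % arma::log(pc) + (1.0 - t) % arma::log(1.0 - pc));
  double I = arma::dot(p, t);
  double U = arma::accu(p) + arma::accu(t) - I;
  liou = 1.0 - (I + eps) / (U + eps);
  arma::rowvec dce = (p - t) / (double)S;
  arma::rowvec dliou_dp =
      -((t * (U + eps)) - (I + eps) * (1.0 - t)) / ((U + eps) * (U + eps));
  dz = dce + dliou_dp % (p % (1.0 - p));
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_unet_forward(List weights, List cfg, NumericVector x) {
  int L = as<int>(cfg["levels"]), base = as<int>(cfg["base"]),
      in_ch = as<int>(cfg["in_ch"]);
  IntegerVector d = x.attr("dim");
  int H = d[1], W = d[2];
  std::vector<ConvSpec> sp = build_specs(L, base, in_ch);
  WStore ws = load_weights(weights, sp);
  arma::mat X(x.begin(), in_ch, H * W);  // (c, y + H*x) layout matches R array
  arma::rowvec p = forward_pass(ws, sp, L, X, H, W, nullptr);
  NumericMatrix out(H, W);
  std::copy(p.begin(), p.end(), out.begin());
  return out;
}

// Accumulated gradients and mean loss over a batch of chunks.
// [[Rcpp::export]]
List cpp_unet_grad_batch(List weights, List cfg, List xs, List ys) {
  int L = as<int>(cfg["levels"]), base = as<int>(cfg["base"]),
      in_ch = as<int>(cfg["in_ch"]);
  double eps = cfg.containsElementNamed("iou_eps") ? as<double>(cfg["iou_eps"]) : 1e-6;
  std::vector<ConvSpec> sp = build_specs(L, base, in_ch);
  WStore ws = load_weights(weights, sp);
  int n = xs.size();
  std::map<std::string, arma::mat> gW;
  std::map<std::string, arma::vec> gb;
  for (const auto& c : sp) {
    gW[c.name] = arma::mat(arma::size(ws.W[c.name]), arma::fill::zeros);
    gb[c.name] = arma::vec(arma::size(ws.b[c.name]), arma::fill::zeros);
  }
  double tot_ce = 0.0, tot_iou = 0.0;

  for (int bi = 0; bi < n; ++bi) {
    NumericVector x = xs[bi];
    NumericMatrix yR = ys[bi];
    IntegerVector d = x.attr("dim");
    int H = d[1], W = d[2];
    arma::mat X(x.begin(), in_ch, H * W);
    arma::rowvec t(yR.begin(), H * W);
    Caches cache;
    arma::rowvec p = forward_pass(ws, sp, L, X, H, W, &cache);
    double lce, liou;
    arma::rowvec dz;
    loss_and_dz(p, t, eps, lce, liou, dz);
    tot_ce += lce; tot_iou += liou;

    // Backward through a conv (+ReLU); returns gradient wrt its input.
    auto conv_bwd = [&](const std::string& name, arma::mat dY, int h, int w,
                        bool relu, int k, int cin) {
      if (relu) dY %= arma::conv_to<arma::mat>::from(cache.act[name] > 0);
      gW[name] += dY * cache.cols[name].t();
      gb[name] += arma::sum(dY, 1);
      arma::mat dcols = ws.W[name].t() * dY;
      return (k == 3) ? col2im(dcols, cin, h, w) : dcols;
    };

    // output 1x1 conv
    arma::mat dz_m(1, H * W);
    dz_m.row(0) = dz;
    arma::mat da = conv_bwd("out", dz_m, H, W, false, 1, base);

    std::vector<arma::mat> skipgrad(L - 1);
    for (int i = 0; i <= L - 2; ++i) {
      int ci = base << i;
      int h = H >> i, w = W >> i;
      std::string p2 = "dec" + std::to_string(i);
      da = conv_bwd(p2 + "_c2", da, h, w, true, 3, ci);
      da = conv_bwd(p2 + "_c1", da, h, w, true, 3, ci * 2);
      skipgrad[i] = da.rows(0, ci - 1);
      arma::mat dup = da.rows(ci, 2 * ci - 1);
      dup = conv_bwd("up" + std::to_string(i), dup, h, w, true, 3, ci * 2);
      da = downsum2(dup, h / 2, w / 2);
    }
    {
      int cb2 = base << (L - 2);
      int h = H >> (L - 1), w = W >> (L - 1);
      da = conv_bwd("bot_c2", da, h, w, true, 3, base << (L - 1));
      da = conv_bwd("bot_c1", da, h, w, true, 3, cb2);
    }
    for (int i = L - 2; i >= 0; --i) {
      int ci = base << i;
      int h = H >> i, w = W >> i;
      da = unpool(da, cache.poolidx[i], h, w);
      da += skipgrad[i];
      std::string p2 = "enc" + std::to_string(i);
      da = conv_bwd(p2 + "_c2", da, h, w, true, 3, ci);
      int prev = (i == 0) ? in_ch : (base << (i - 1));
      da = conv_bwd(p2 + "_c1", da, h, w, true, 3, prev);
    }
  }

  List grads;
  for (const auto& c : sp) {
    grads[c.name + "_W"] = wrap(gW[c.name] / (double)n);
    grads[c.name + "_b"] = wrap(gb[c.name] / (double)n);
  }
  return List::create(_["loss"] = (tot_ce + tot_iou) / n,
                      _["loss_ce"] = tot_ce / n, _["loss_iou"] = tot_iou / n,
                      _["grads"] = grads);
}
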