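// Encoder-decoder semantic segmentation network: five residual encoder stages
// (max-pooling after the first three only, so spatial resolution is capped at
// one eighth of the input), an atrous spatial pyramid pooling block at the
// bottleneck, and a symmetric decoder with skip connections.  Implemented as
// shifted-matmul convolutions on Armadillo cubes (H, W, C); weights live in a
// named R list so the optimizer can stay in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uword;

struct ConvW {
  int kh, kw, cin, cout, dil;
  std::vector<mat> W;   // one (cin x cout) matrix per kernel tap
  vec b;
  std::vector<mat> gW;  // gradient accumulators (only allocated when training)
  vec gb;
  std::string wname, bname;
};

static ConvW parse_conv(const List &weights, const std::string &base, int dil, bool train) {
  ConvW cw;
  cw.wname = base + "_w";
  cw.bname = base + "_b";
  NumericVector w = weights[cw.wname];
  NumericVector b = weights[cw.bname];
  IntegerVector d = w.attr("dim");
  cw.kh = d[0]; cw.kw = d[1]; cw.cin = d[2]; cw.cout = d[3];
  cw.dil = dil;
  cw.W.resize(cw.kh * cw.kw);
  for (int kj = 0; kj < cw.kw; ++kj)
    for (int ki = 0; ki < cw.kh; ++ki) {
      mat m(cw.cin, cw.cout);
      for (int o = 0; o < cw.cout; ++o)
        for (int c = 0; c < cw.cin; ++c)
          m(c, o) = w[ki + cw.kh * (kj + cw.kw * (c + (long)cw.cin * o))];
      cw.W[ki + cw.kh * kj] = m;
    }
  cw.b = vec(b.begin(), cw.cout);
  if (train) {
    cw.gW.assign(cw.kh * cw.kw, mat(cw.cin, cw.cout, arma::fill::zeros));
    cw.gb = vec(cw.cout, arma::fill::zeros);
  }
  return cw;
}

static cube conv_fw(const cube &X, const ConvW &cw) {
  const int H = X.n_rows, W = X.n_cols;
  cube Y(H, W, cw.cout, arma::fill::zeros);
  const int cy = (cw.kh - 1) / 2, cx = (cw.kw - 1) / 2;
  for (int kj = 0; kj < cw.kw; ++kj)
    for (int ki = 0; ki < cw.kh; ++ki) {
      int dy = (ki - cy) * cw.dil, dx = (kj - cx) * cw.dil;
      int y0 = std::max(0, -dy), y1 = std::min(H - 1, H - 1 - dy);
      int x0 = std::max(0, -dx), x1 = std::min(W - 1, W - 1 - dx);
      if (y0 > y1 || x0 > x1) continue;
      int ny = y1 - y0 + 1, nx = x1 - x0 + 1;
      cube sub = X.subcube(y0 + dy, x0 + dx, 0, y1 + dy, x1 + dx, cw.cin - 1);
      mat M(sub.memptr(), (uword)ny * nx, cw.cin, false, true);
      mat R = M * cw.W[ki + cw.kh * kj];
      cube Rc(R.memptr(), ny, nx, cw.cout, false, true);
      Y.subcube(y0, x0, 0, y1, x1, cw.cout - 1) += Rc;
    }
  for (int c = 0; c < cw.cout; ++c) Y.slice(c) += cw.b(c);
  return Y;
}

// accumulates weight gradients into cw, returns dX
static cube conv_bw(const cube &X, const cube &dY, ConvW &cw) {
  const int H = X.n_rows, W = X.n_cols;
  cube dX(H, W, cw.cin, arma::fill::zeros);
  const int cy = (cw.kh - 1) / 2, cx = (cw.kw - 1) / 2;
  for (int kj = 0; kj < cw.kw; ++kj)
    for (int ki = 0; ki < cw.kh; ++ki) {
      int dy = (ki - cy) * cw.dil, dx = (kj - cx) * cw.dil;
      int y0 = std::max(0, -dy), y1 = std::min(H - 1, H - 1 - dy);
      int x0 = std::max(0, -dx), x1 = std::min(W - 1, W - 1 - dx);
      if (y0 > y1 || x0 > x1) continue;
      int ny = y1 - y0 + 1, nx = x1 - x0 + 1;
      cube dsub = dY.subcube(y0, x0, 0, y1, x1, cw.cout - 1);
      mat dM(dsub.memptr(), (uword)ny * nx, cw.cout, false, true);
      cube xsub = X.subcube(y0 + dy, x0 + dx, 0, y1 + dy, x1 + dx, cw.cin - 1);
      mat xM(xsub.memptr(), (uword)ny * nx, cw.cin, false, true);
      cw.gW[ki + cw.kh * kj] += xM.t() * dM;
      mat dXm = dM * cw.W[ki + cw.kh * kj].t();
      cube dXc(dXm.memptr(), ny, nx, cw.cin, false, true);
      dX.subcube(y0 + dy, x0 + dx, 0, y1 + dy, x1 + dx, cw.cin - 1) += dXc;
    }
  for (int c = 0; c < cw.cout; ++c) cw.gb(c) += arma::accu(dY.slice(c));
  return dX;
}

static cube lrelu_fw(const cube &X, double s) {
  cube Y = X;
  Y.transform([s](double v) { return v > 0 ? v : s * v; });
  return Y;
}

static cube lrelu_bw(const cube &X, const cube &dY, double s) {
  cube dX = dY;
  const double *x = X.memptr();
  double *d = dX.memptr();
  for (uword i = 0; i < dX.n_elem; ++i)
    if (x[i] <= 0) d[i] *= s;
  return dX;
}

static cube pool_fw(const cube &X, arma::ucube &idx) {
  const int H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  cube Y(H, W, C);
  idx.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        double best = X(2 * y, 2 * x, c);
        uword bi = 0;
        // scan order fixes the tie-break
        const int oy[4] = {0, 1, 0, 1}, ox[4] = {0, 0, 1, 1};
        for (uword t = 1; t < 4; ++t) {
          double v = X(2 * y + oy[t], 2 * x + ox[t], c);
          if (v > best) { best = v; bi = t; }
        }
        Y(y, x, c) = best;
        idx(y, x, c) = bi;
      }
  return Y;
}

static cube pool_bw(const cube &dY, const arma::ucube &idx) {
  const int H = dY.n_rows, W = dY.n_cols, C = dY.n_slices;
  cube dX(2 * H, 2 * W, C, arma::fill::zeros);
  const int oy[4] = {0, 1, 0, 1}, ox[4] = {0, 0, 1, 1};
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        uword t = idx(y, x, c);
        dX(2 * y + oy[t], 2 * x + ox[t], c) = dY(y, x, c);
      }
  return dX;
}

static cube up_fw(const cube &X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  cube Y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        double v = X(y, x, c);
        Y(2 * y, 2 * x, c) = v;
        Y(2 * y + 1, 2 * x, c) = v;
        Y(2 * y, 2 * x + 1, c) = v;
        Y(2 * y + 1, 2 * x + 1, c) = v;
      }
  return Y;
}

static cube up_bw(const cube &dY) {
  const int H = dY.n_rows / 2, W = dY.n_cols / 2, C = dY.n_slices;
  cube dX(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y)
        dX(y, x, c) = dY(2 * y, 2 * x, c) + dY(2 * y + 1, 2 * x, c) +
                      dY(2 * y, 2 * x + 1, c) + dY(2 * y + 1, 2 * x + 1, c);
  return dX;
}

static cube concat_c(const cube &A, const cube &B) {
  cube Y(A.n_rows, A.n_cols, A.n_slices + B.n_slices);
  Y.slices(0, A.n_slices - 1) = A;
  Y.slices(A.n_slices, Y.n_slices - 1) = B;
  return Y;
}

struct Net {
  std::vector<ConvW> encA, encB, encS;
  std::vector<ConvW> aspp;
  std::vector<ConvW> dc1, dc2;
  ConvW out;
  double slope;
};

static Net parse_net(const List &weights, const IntegerVector &aspp_rates,
                     double slope, bool train) {
  Net net;
  net.slope = slope;
  for (int i = 1; i <= 5; ++i) {
    std::string b = "enc" + std::to_string(i);
    net.encA.push_back(parse_conv(weights, b + "_a", 1, train));
    net.encB.push_back(parse_conv(weights, b + "_b", 1, train));
    net.encS.push_back(parse_conv(weights, b + "_s", 1, train));
  }
  for (int k = 0; k < aspp_rates.size(); ++k)
    net.aspp.push_back(parse_conv(weights, "aspp" + std::to_string(k + 1),
                                  aspp_rates[k], train));
  for (int j = 1; j <= 3; ++j) {
    std::string b = "dec" + std::to_string(j);
    net.dc1.push_back(parse_conv(weights, b + "_c1", 1, train));
    net.dc2.push_back(parse_conv(weights, b + "_c2", 1, train));
  }
  net.out = parse_conv(weights, "out", 1, train);
  return net;
}

// residual stage forward; caches only filled when provided
static cube stage_fw(const cube &Xin, ConvW &a, ConvW &b, ConvW &s, double slope,
                     cube *cA, cube *cAr, cube *cP) {
  cube A = conv_fw(Xin, a);
  cube Ar = lrelu_fw(A, slope);
  cube B = conv_fw(Ar, b);
  cube S = conv_fw(Xin, s);
  cube P = B + S;
  if (cA) { *cA = A; *cAr = Ar; *cP = P; }
  return lrelu_fw(P, slope);
}

// Inference forward.  Returns logits plus the spatial side of every encoder
// feature map (for the architecture contract).
// [[Rcpp::export]]
List unet_forward_cpp(List weights, NumericMatrix x, IntegerVector aspp_rates,
                      double slope) {
  Net net = parse_net(weights, aspp_rates, slope, false);
  const int H = x.nrow(), W = x.ncol();
  cube X(H, W, 1);
  std::copy(x.begin(), x.end(), X.memptr());

  std::vector<cube> skips;
  IntegerMatrix fdims(7, 2);
  cube cur = X;
  for (int i = 0; i < 5; ++i) {
    cur = stage_fw(cur, net.encA[i], net.encB[i], net.encS[i], net.slope,
                   nullptr, nullptr, nullptr);
    fdims(i, 0) = cur.n_rows; fdims(i, 1) = cur.n_cols;
    if (i < 3) {
      skips.push_back(cur);
      arma::ucube idx;
      cur = pool_fw(cur, idx);
    }
  }
  cube Z(cur.n_rows, cur.n_cols, cur.n_slices, arma::fill::zeros);
  for (auto &ac : net.aspp) Z += conv_fw(cur, ac);
  cur = lrelu_fw(Z, net.slope);
  fdims(5, 0) = cur.n_rows; fdims(5, 1) = cur.n_cols;

  for (int j = 0; j < 3; ++j) {
    cube U = up_fw(cur);
    cube C = concat_c(U, skips[2 - j]);
    cube C1 = lrelu_fw(conv_fw(C, net.dc1[j]), net.slope);
    cur = lrelu_fw(conv_fw(C1, net.dc2[j]), net.slope);
  }
  cube logits = conv_fw(cur, net.out);
  fdims(6, 0) = logits.n_rows; fdims(6, 1) = logits.n_cols;

  NumericVector out(logits.memptr(), logits.memptr() + logits.n_elem);
  out.attr("dim") = IntegerVector::create(logits.n_rows, logits.n_cols, logits.n_slices);
  rownames(fdims) = CharacterVector::create("enc1", "enc2", "enc3", "enc4",
                                            "enc5", "aspp", "logits");
  return List::create(_["logits"] = out, _["feature_dims"] = fdims);
}

// Training pass: forward with caching, softmax cross-entropy against integer
// labels (0-based), full backward; returns loss and named gradient list.
// [[Rcpp::export]]
List unet_loss_grad_cpp(List weights, NumericMatrix x, IntegerMatrix y,
                        IntegerVector aspp_rates, double slope) {
  Net net = parse_net(weights, aspp_rates, slope, true);
  const int H = x.nrow(), W = x.ncol();
  cube X(H, W, 1);
  std::copy(x.begin(), x.end(), X.memptr());

  // ---- forward with caches ----
  std::vector<cube> inA(5), cA(5), cAr(5), cP(5), stageOut(5);
  std::vector<arma::ucube> poolIdx(3);
  cube cur = X;
  for (int i = 0; i < 5; ++i) {
    inA[i] = cur;
    stageOut[i] = stage_fw(cur, net.encA[i], net.encB[i], net.encS[i], net.slope,
                           &cA[i], &cAr[i], &cP[i]);
    cur = stageOut[i];
    if (i < 3) cur = pool_fw(cur, poolIdx[i]);
  }
  cube asppIn = cur;
  cube Z(cur.n_rows, cur.n_cols, cur.n_slices, arma::fill::zeros);
  for (auto &ac : net.aspp) Z += conv_fw(asppIn, ac);
  cube asppOut = lrelu_fw(Z, net.slope);

  std::vector<cube> dC(3), dC1pre(3), dC1r(3), dC2pre(3), dOut(3);
  cur = asppOut;
  for (int j = 0; j < 3; ++j) {
    cube U = up_fw(cur);
    dC[j] = concat_c(U, stageOut[2 - j]);
    dC1pre[j] = conv_fw(dC[j], net.dc1[j]);
    dC1r[j] = lrelu_fw(dC1pre[j], net.slope);
    dC2pre[j] = conv_fw(dC1r[j], net.dc2[j]);
    dOut[j] = lrelu_fw(dC2pre[j], net.slope);
    cur = dOut[j];
  }
  cube logits = conv_fw(cur, net.out);
  const int K = logits.n_slices;

  // ---- loss + dlogits ----
  double loss = 0.0;
  cube dlog(H, W, K);
  const double npix = (double)H * W;
  for (int xx = 0; xx < W; ++xx)
    for (int yy = 0; yy < H; ++yy) {
      double mx = logits(yy, xx, 0);
      for (int c = 1; c < K; ++c) mx = std::max(mx, logits(yy, xx, c));
      double se = 0.0;
      for (int c = 0; c < K; ++c) se += std::exp(logits(yy, xx, c) - mx);
      int lab = y(yy, xx);
      loss += -(logits(yy, xx, lab) - mx - std::log(se)) / npix;
      for (int c = 0; c < K; ++c) {
        double p = std::exp(logits(yy, xx, c) - mx) / se;
        dlog(yy, xx, c) = (p - (c == lab ? 1.0 : 0.0)) / npix;
      }
    }

  // ---- backward ----
  cube d = conv_bw(dOut[2], dlog, net.out);
  for (int j = 2; j >= 0; --j) {
    d = lrelu_bw(dC2pre[j], d, net.slope);
    d = conv_bw(dC1r[j], d, net.dc2[j]);
    d = lrelu_bw(dC1pre[j], d, net.slope);
    d = conv_bw(dC[j], d, net.dc1[j]);
    // split concat: first channels -> upsample path, rest -> skip
    int cu = d.n_slices - stageOut[2 - j].n_slices;
    cube dU = d.slices(0, cu - 1);
    cube dSkip = d.slices(cu, d.n_slices - 1);
    // stash skip grad for later (added when unwinding encoder)
    dC[j] = dSkip;                    // reuse slot
    d = up_bw(dU);
  }
  // d is now gradient at asppOut
  d = lrelu_bw(Z, d, net.slope);
  cube dAsppIn(asppIn.n_rows, asppIn.n_cols, asppIn.n_slices, arma::fill::zeros);
  for (auto &ac : net.aspp) dAsppIn += conv_bw(asppIn, d, ac);
  d = dAsppIn;

  for (int i = 4; i >= 0; --i) {
    // incoming d: gradient at pooled output (i<3) or stage output (i>=3)
    cube dO;
    if (i < 3) {
      dO = pool_bw(d, poolIdx[i]);
      dO += dC[2 - i];                // skip-connection gradient
    } else {
      dO = d;
    }
    cube dP = lrelu_bw(cP[i], dO, net.slope);
    cube dAr = conv_bw(cAr[i], dP, net.encB[i]);
    cube dA = lrelu_bw(cA[i], dAr, net.slope);
    cube dIn = conv_bw(inA[i], dA, net.encA[i]);
    dIn += conv_bw(inA[i], dP, net.encS[i]);
    d = dIn;
  }

  // ---- serialize gradients ----
  std::vector<ConvW*> all;
  for (int i = 0; i < 5; ++i) { all.push_back(&net.encA[i]); all.push_back(&net.encB[i]); all.push_back(&net.encS[i]); }
  for (auto &ac : net.aspp) all.push_back(&ac);
  for (int j = 0; j < 3; ++j) { all.push_back(&net.dc1[j]); all.push_back(&net.dc2[j]); }
  all.push_back(&net.out);
  List grads(2 * all.size());
  CharacterVector gnames(2 * all.size());
  int gi = 0;
  for (ConvW *cw : all) {
    NumericVector gw((long)cw->kh * cw->kw * cw->cin * cw->cout);
    for (int kj = 0; kj < cw->kw; ++kj)
      for (int ki = 0; ki < cw->kh; ++ki) {
        const mat &m = cw->gW[ki + cw->kh * kj];
        for (int o = 0; o < cw->cout; ++o)
          for (int c = 0; c < cw->cin; ++c)
            gw[ki + cw->kh * (kj + cw->kw * (c + (long)cw->cin * o))] = m(c, o);
      }
    gw.attr("dim") = IntegerVector::create(cw->kh, cw->kw, cw->cin, cw->cout);
    gnames[gi] = cw->wname; grads[gi++] = gw;
    gnames[gi] = cw->bname; grads[gi++] = NumericVector(cw->gb.begin(), cw->gb.end());
  }
  grads.attr("names") = gnames;
  return List::create(_["loss"] = loss, _["grads"] = grads);
}
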