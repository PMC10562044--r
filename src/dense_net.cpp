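// Convolutional engine for the dense-skip denoiser.
//
// All feature maps of the network live in one channel-planar matrix
// `Fall` (Pt x Ctot): each sample occupies a zero-padded (H+2) x (W+2)
// plane (pixel index h fastest, then w, then sample), and every layer
// appends its output channels as new columns.  Dense connectivity makes
// each layer's input a contiguous column range of `Fall`, and in the
// padded layout each 3x3 kernel offset is a constant row shift, so both
// the forward convolution and the full backward pass reduce to direct
// SGEMM calls on shifted views (lda/ldc = Pt) with no im2col copies.
// Padding rows are re-zeroed after every layer so out-of-image
// neighbours read 0.

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

extern "C" void sgemm_(const char* transa, const char* transb, const int* m,
                       const int* n, const int* k, const float* alpha,
                       const float* a, const int* lda, const float* b,
                       const int* ldb, const float* beta, float* c,
                       const int* ldc);

namespace {

// Large scratch matrices are allocated and freed once per call; keep
// them on the heap instead of mmap so pages are reused between calls.
struct AllocTuning {
  AllocTuning() {
#ifdef __GLIBC__
    mallopt(M_MMAP_THRESHOLD, 1 << 30);
    mallopt(M_TRIM_THRESHOLD, 1 << 30);
#endif
  }
};
static AllocTuning alloc_tuning;

inline void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* a, int lda, const float* b, int ldb,
                  float beta, float* c, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c, &ldc);
}

struct Geom {
  int H, W, N, Hp, Wp;
  arma::uword Pp, Pt, Npix;
  std::vector<arma::uword> interior;  // padded row of each real pixel
  std::vector<arma::uword> padrows;
};

Geom make_geom(int H, int W, int N) {
  Geom g;
  g.H = H; g.W = W; g.N = N; g.Hp = H + 2; g.Wp = W + 2;
  g.Pp = (arma::uword)g.Hp * g.Wp;
  g.Pt = g.Pp * N;
  g.Npix = (arma::uword)H * W * N;
  g.interior.reserve(g.Npix);
  std::vector<char> real(g.Pt, 0);
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        arma::uword r = (arma::uword)n * g.Pp + (arma::uword)(w + 1) * g.Hp + (h + 1);
        g.interior.push_back(r);
        real[r] = 1;
      }
  for (arma::uword r = 0; r < g.Pt; ++r)
    if (!real[r]) g.padrows.push_back(r);
  return g;
}

inline void zero_pad_cols(arma::fmat& F, const Geom& g, arma::uword c0,
                          arma::uword c1) {
  for (arma::uword c = c0; c <= c1; ++c) {
    float* p = F.colptr(c);
    for (arma::uword r : g.padrows) p[r] = 0.0f;
  }
}

struct Layer {
  int k, cout;
  bool relu;
  arma::uword in0, in1;    // input column range in Fall
  arma::uword out0, out1;  // output column range in Fall
};

struct Plan {
  std::vector<Layer> layers;
  arma::uword ctot;
};

// The R-side plan lists 0-based source block ids; blocks are appended
// in order (block 0 = input image), so valid dense plans always have
// contiguous ascending src ranges.
Plan parse_plan(List plan) {
  Plan pl;
  std::vector<arma::uword> bcol(1, 0), bch(1, 1);  // block -> first col, channels
  arma::uword next = 1;
  for (R_xlen_t i = 0; i < plan.size(); ++i) {
    List li = plan[i];
    Layer lay;
    IntegerVector s = li["src"];
    for (int j = 1; j < s.size(); ++j)
      if (s[j] != s[j - 1] + 1) stop("non-contiguous dense source range");
    lay.k = as<int>(li["k"]);
    lay.cout = as<int>(li["cout"]);
    lay.relu = as<bool>(li["relu"]);
    const int sfirst = s[0], slast = s[s.size() - 1];
    lay.in0 = bcol[sfirst];
    lay.in1 = bcol[slast] + bch[slast] - 1;
    lay.out0 = next;
    lay.out1 = next + lay.cout - 1;
    bcol.push_back(next);
    bch.push_back(lay.cout);
    next += lay.cout;
    pl.layers.push_back(lay);
  }
  pl.ctot = next;
  return pl;
}

// (cout x k2*cin) R weight (columns grouped kk-outer, channel-inner)
// -> per-offset (cin x cout) float blocks
std::vector<arma::fmat> split_weight(const NumericMatrix& W, int k2, int cin) {
  std::vector<arma::fmat> out(k2);
  for (int kk = 0; kk < k2; ++kk) {
    arma::fmat w(cin, W.nrow());
    for (int i = 0; i < W.nrow(); ++i)
      for (int c = 0; c < cin; ++c) w(c, i) = (float)W(i, kk * cin + c);
    out[kk] = w;
  }
  return out;
}

// row shift of kernel offset kk (kk = (dw+1)*3 + (dh+1) for 3x3)
inline long kk_offset(int kk, const Geom& g) {
  const int dw = kk / 3 - 1, dh = kk % 3 - 1;
  return (long)dw * g.Hp + dh;
}

arma::fmat forward(const Plan& pl, const std::vector<std::vector<arma::fmat>>& W,
                   const List& biases, const arma::fvec& x, const Geom& g) {
  const int Pt = (int)g.Pt;
  arma::fmat Fall(g.Pt, pl.ctot, arma::fill::zeros);
  {
    float* p = Fall.colptr(0);
    for (arma::uword i = 0; i < g.Npix; ++i) p[g.interior[i]] = x[i];
  }
  for (size_t l = 0; l < pl.layers.size(); ++l) {
    const Layer& lay = pl.layers[l];
    const int cin = (int)(lay.in1 - lay.in0 + 1);
    const float* F0 = Fall.colptr(lay.in0);
    float* Y0 = Fall.colptr(lay.out0);
    if (lay.k == 1) {
      sgemm('N', 'N', Pt, lay.cout, cin, 1.0f, F0, Pt,
            W[l][0].memptr(), cin, 0.0f, Y0, Pt);
    } else {
      // output columns start zeroed (Fall is zero-initialised and each
      // output range is written exactly once), so accumulate with beta=1
      for (int kk = 0; kk < 9; ++kk) {
        const long off = kk_offset(kk, g);
        const arma::uword lo = off < 0 ? (arma::uword)(-off) : 0;
        const arma::uword hi = off > 0 ? g.Pt - 1 - (arma::uword)off : g.Pt - 1;
        sgemm('N', 'N', (int)(hi - lo + 1), lay.cout, cin, 1.0f,
              F0 + lo + off, Pt, W[l][kk].memptr(), cin,
              1.0f, Y0 + lo, Pt);
      }
    }
    NumericVector bR = biases[l];
    for (int c = 0; c < lay.cout; ++c) {
      float* p = Y0 + (arma::uword)c * g.Pt;
      const float b = (float)bR[c];
      if (lay.relu)
        for (arma::uword r = 0; r < g.Pt; ++r)
          p[r] = p[r] + b > 0.0f ? p[r] + b : 0.0f;
      else
        for (arma::uword r = 0; r < g.Pt; ++r) p[r] += b;
    }
    zero_pad_cols(Fall, g, lay.out0, lay.out1);
  }
  return Fall;
}

std::vector<std::vector<arma::fmat>> prep_weights(const Plan& pl,
                                                  const List& weights) {
  std::vector<std::vector<arma::fmat>> W(pl.layers.size());
  for (size_t l = 0; l < pl.layers.size(); ++l) {
    const Layer& lay = pl.layers[l];
    const int cin = (int)(lay.in1 - lay.in0 + 1);
    W[l] = split_weight(weights[l], lay.k * lay.k, cin);
  }
  return W;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_net_forward(List plan, List weights, List biases,
                              NumericVector x, int H, int W, int N) {
  Plan pl = parse_plan(plan);
  Geom g = make_geom(H, W, N);
  arma::fvec xin(g.Npix);
  for (arma::uword i = 0; i < g.Npix; ++i) xin[i] = (float)x[i];
  std::vector<std::vector<arma::fmat>> Ws = prep_weights(pl, weights);
  arma::fmat Fall = forward(pl, Ws, biases, xin, g);
  const float* p = Fall.colptr(pl.layers.back().out0);
  NumericVector res(g.Npix);
  for (arma::uword i = 0; i < g.Npix; ++i) res[i] = p[g.interior[i]];
  return res;
}

// [[Rcpp::export]]
List cpp_net_loss_grad(List plan, List weights, List biases,
                       NumericVector x, NumericVector y, int H, int W, int N) {
  Plan pl = parse_plan(plan);
  Geom g = make_geom(H, W, N);
  const int Pt = (int)g.Pt;
  arma::fvec xin(g.Npix);
  for (arma::uword i = 0; i < g.Npix; ++i) xin[i] = (float)x[i];
  std::vector<std::vector<arma::fmat>> Ws = prep_weights(pl, weights);
  arma::fmat Fall = forward(pl, Ws, biases, xin, g);
  const size_t L = pl.layers.size();

  arma::fmat dAll(g.Pt, pl.ctot, arma::fill::zeros);

  // RMSE loss over the real pixels
  double sse = 0.0;
  {
    const float* p = Fall.colptr(pl.layers.back().out0);
    float* d = dAll.colptr(pl.layers.back().out0);
    for (arma::uword i = 0; i < g.Npix; ++i) {
      const double r = (double)p[g.interior[i]] - (double)y[i];
      sse += r * r;
      d[g.interior[i]] = (float)r;
    }
  }
  const double rmse = std::sqrt(sse / (double)g.Npix);
  {
    const float s = (float)(1.0 / ((double)g.Npix * std::max(rmse, 1e-12)));
    float* d = dAll.colptr(pl.layers.back().out0);
    for (arma::uword r = 0; r < g.Pt; ++r) d[r] *= s;
  }

  List dW(L), db(L);
  for (size_t li = L; li-- > 0;) {
    const Layer& lay = pl.layers[li];
    const int cin = (int)(lay.in1 - lay.in0 + 1);
    float* dY0 = dAll.colptr(lay.out0);
    // ReLU mask (also keeps pad rows at zero, since activations there are 0)
    if (lay.relu) {
      for (int c = 0; c < lay.cout; ++c) {
        const float* pp = Fall.colptr(lay.out0 + c);
        float* dp = dY0 + (arma::uword)c * g.Pt;
        for (arma::uword r = 0; r < g.Pt; ++r)
          if (pp[r] <= 0.0f) dp[r] = 0.0f;
      }
    }
    const float* F0 = Fall.colptr(lay.in0);
    float* dF0 = dAll.colptr(lay.in0);
    const int k2 = lay.k * lay.k;
    arma::fmat dw(cin, lay.cout);
    NumericMatrix dWout(lay.cout, k2 * cin);
    if (lay.k == 1) {
      sgemm('T', 'N', cin, lay.cout, Pt, 1.0f, F0, Pt, dY0, Pt, 0.0f,
            dw.memptr(), cin);
      for (int i = 0; i < lay.cout; ++i)
        for (int c = 0; c < cin; ++c) dWout(i, c) = dw(c, i);
      sgemm('N', 'T', Pt, cin, lay.cout, 1.0f, dY0, Pt,
            Ws[li][0].memptr(), cin, 1.0f, dF0, Pt);
    } else {
      for (int kk = 0; kk < 9; ++kk) {
        const long off = kk_offset(kk, g);
        const arma::uword lo = off < 0 ? (arma::uword)(-off) : 0;
        const arma::uword hi = off > 0 ? g.Pt - 1 - (arma::uword)off : g.Pt - 1;
        const int m = (int)(hi - lo + 1);
        sgemm('T', 'N', cin, lay.cout, m, 1.0f, F0 + lo + off, Pt,
              dY0 + lo, Pt, 0.0f, dw.memptr(), cin);
        for (int i = 0; i < lay.cout; ++i)
          for (int c = 0; c < cin; ++c) dWout(i, kk * cin + c) = dw(c, i);
        sgemm('N', 'T', m, cin, lay.cout, 1.0f, dY0 + lo, Pt,
              Ws[li][kk].memptr(), cin, 1.0f,
              dF0 + lo + off, Pt);
      }
      // drop gradients accumulated onto structural-zero pad rows
      zero_pad_cols(dAll, g, lay.in0, lay.in1);
      // the input image (column 0) carries no gradient; harmless if it does
    }
    NumericVector dbout(lay.cout);
    for (int c = 0; c < lay.cout; ++c) {
      const float* dp = dY0 + (arma::uword)c * g.Pt;
      double s = 0.0;
      for (arma::uword r = 0; r < g.Pt; ++r) s += dp[r];
      dbout[c] = s;
    }
    dW[li] = dWout;
    db[li] = dbout;
  }
  return List::create(_["loss"] = rmse, _["dW"] = dW, _["db"] = db);
}
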