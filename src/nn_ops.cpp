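// Low-level kernels for the convolutional network engine.
// Tensor layout: column-major R arrays, dim = c(H, W, C, N)
// (rows, cols, channels, batch). Convolutions use "same" zero padding:
// out = floor((in - 1)/stride) + 1, pad_top = total_pad / 2.

#include <Rcpp.h>
using namespace Rcpp;

static inline int out_dim(int in, int stride) {
  return (in - 1) / stride + 1;
}
static inline int pad_before(int in, int out, int k, int stride) {
  int total = (out - 1) * stride + k - in;
  if (total < 0) total = 0;
  return total / 2;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int sh, int sw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int Ho = out_dim(H, sh), Wo = out_dim(W, sw);
  const int ph = pad_before(H, Ho, kh, sh), pw = pad_before(W, Wo, kw, sw);
  NumericVector y(Ho * Wo * F * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  const double *px = x.begin(), *pw_ = w.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = b[f];
          const int h0 = ho * sh - ph, w0 = wo * sw - pw;
          for (int c = 0; c < C; ++c)
            for (int j = 0; j < kw; ++j) {
              const int wi = w0 + j;
              if (wi < 0 || wi >= W) continue;
              for (int i = 0; i < kh; ++i) {
                const int hi = h0 + i;
                if (hi < 0 || hi >= H) continue;
                acc += px[hi + H * (wi + W * (c + C * n))] *
                       pw_[i + kh * (j + kw * (c + C * f))];
              }
            }
          py[ho + Ho * (wo + Wo * (f + F * n))] = acc;
        }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int sh, int sw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], F = wd[3];
  const int Ho = out_dim(H, sh), Wo = out_dim(W, sw);
  const int ph = pad_before(H, Ho, kh, sh), pw = pad_before(W, Wo, kw, sw);
  NumericVector dx(x.size()), dw(w.size()), db(F);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  const double *px = x.begin(), *pw_ = w.begin(), *pdy = dy.begin();
  double *pdx = dx.begin(), *pdw = dw.begin();
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = pdy[ho + Ho * (wo + Wo * (f + F * n))];
          if (g == 0.0) continue;
          db[f] += g;
          const int h0 = ho * sh - ph, w0 = wo * sw - pw;
          for (int c = 0; c < C; ++c)
            for (int j = 0; j < kw; ++j) {
              const int wi = w0 + j;
              if (wi < 0 || wi >= W) continue;
              for (int i = 0; i < kh; ++i) {
                const int hi = h0 + i;
                if (hi < 0 || hi >= H) continue;
                const int xi = hi + H * (wi + W * (c + C * n));
                const int ki = i + kh * (j + kw * (c + C * f));
                pdw[ki] += g * px[xi];
                pdx[xi] += g * pw_[ki];
              }
            }
        }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector cpp_depthwise_fwd(NumericVector x, NumericVector w,
                                int sh, int sw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = out_dim(H, sh), Wo = out_dim(W, sw);
  const int ph = pad_before(H, Ho, kh, sh), pw = pad_before(W, Wo, kw, sw);
  NumericVector y(Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *px = x.begin(), *pw_ = w.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = 0.0;
          const int h0 = ho * sh - ph, w0 = wo * sw - pw;
          for (int j = 0; j < kw; ++j) {
            const int wi = w0 + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = h0 + i;
              if (hi < 0 || hi >= H) continue;
              acc += px[hi + H * (wi + W * (c + C * n))] *
                     pw_[i + kh * (j + kw * c)];
            }
          }
          py[ho + Ho * (wo + Wo * (c + C * n))] = acc;
        }
  return y;
}

// [[Rcpp::export]]
List cpp_depthwise_bwd(NumericVector x, NumericVector w, NumericVector dy,
                       int sh, int sw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int Ho = out_dim(H, sh), Wo = out_dim(W, sw);
  const int ph = pad_before(H, Ho, kh, sh), pw = pad_before(W, Wo, kw, sw);
  NumericVector dx(x.size()), dw(w.size());
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  const double *px = x.begin(), *pw_ = w.begin(), *pdy = dy.begin();
  double *pdx = dx.begin(), *pdw = dw.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = pdy[ho + Ho * (wo + Wo * (c + C * n))];
          if (g == 0.0) continue;
          const int h0 = ho * sh - ph, w0 = wo * sw - pw;
          for (int j = 0; j < kw; ++j) {
            const int wi = w0 + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = h0 + i;
              if (hi < 0 || hi >= H) continue;
              const int xi = hi + H * (wi + W * (c + C * n));
              const int ki = i + kh * (j + kw * c);
              pdw[ki] += g * px[xi];
              pdx[xi] += g * pw_[ki];
            }
          }
        }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Max pooling, window ph x pw, stride equal to the window, floor division
// (trailing rows/cols that do not fill a window are dropped). Returns the
// pooled tensor and the 1-based linear argmax index into x for backprop.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int ph, int pw) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / ph, Wo = W / pw;
  NumericVector y(Ho * Wo * C * N);
  IntegerVector amax(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  amax.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *px = x.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = R_NegInf;
          int besti = -1;
          for (int j = 0; j < pw; ++j)
            for (int i = 0; i < ph; ++i) {
              const int xi = (ho * ph + i) + H * ((wo * pw + j) + W * (c + C * n));
              if (px[xi] > best) { best = px[xi]; besti = xi; }
            }
          const int yi = ho + Ho * (wo + Wo * (c + C * n));
          py[yi] = best;
          amax[yi] = besti + 1;
        }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector xdim, IntegerVector amax,
                              NumericVector dy) {
  NumericVector dx(xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  double *pdx = dx.begin();
  const double *pdy = dy.begin();
  for (int i = 0; i < amax.size(); ++i) pdx[amax[i] - 1] += pdy[i];
  return dx;
}
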