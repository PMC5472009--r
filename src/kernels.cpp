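#include <Rcpp.h>
using namespace Rcpp;

// Dense 3D cross-correlation ("convolution" in CNN usage), stride 1, no
// padding.  Tensors are stored channel-first in R's column-major order:
// x[c + C*(i + S1*(j + S2*k))].  Filter bank w has dim (C, F, F, F, L).
// Output has dim (L, O1, O2, O3) with O = S - F + 1.  The linear response is
// returned; the nonlinearity is applied by the caller (which needs the
// pre-activation for backprop anyway).

// [[Rcpp::export]]
NumericVector cpp_conv3d_forward(NumericVector x, IntegerVector xd,
                                 NumericVector w, IntegerVector wd,
                                 NumericVector b) {
  const int C = xd[0], S1 = xd[1], S2 = xd[2], S3 = xd[3];
  const int F = wd[1], L = wd[4];
  if (wd[0] != C) stop("channel mismatch between input and filters");
  if (S1 < F || S2 < F || S3 < F) stop("input smaller than filter");
  const int O1 = S1 - F + 1, O2 = S2 - F + 1, O3 = S3 - F + 1;
  NumericVector out(L * O1 * O2 * O3);
  out.attr("dim") = IntegerVector::create(L, O1, O2, O3);
  const double *px = x.begin(), *pw = w.begin();
  double *po = out.begin();
  const int fsz = C * F * F * F;
  for (int ok = 0; ok < O3; ++ok)
    for (int oj = 0; oj < O2; ++oj)
      for (int oi = 0; oi < O1; ++oi)
        for (int l = 0; l < L; ++l) {
          double acc = b[l];
          const double *wl = pw + (size_t)l * fsz;
          for (int d = 0; d < F; ++d)
            for (int n = 0; n < F; ++n)
              for (int m = 0; m < F; ++m) {
                const double *xs = px + (size_t)C *
                  ((oi + m) + (size_t)S1 * ((oj + n) + (size_t)S2 * (ok + d)));
                const double *ws = wl + (size_t)C * (m + F * (n + F * d));
                for (int c = 0; c < C; ++c) acc += ws[c] * xs[c];
              }
          po[l + (size_t)L * (oi + (size_t)O1 * (oj + (size_t)O2 * ok))] = acc;
        }
  return out;
}

// Gradients of the conv layer w.r.t. input, weights and bias given the
// gradient at the (pre-activation) output.

// [[Rcpp::export]]
List cpp_conv3d_backward(NumericVector x, IntegerVector xd,
                         NumericVector w, IntegerVector wd,
                         NumericVector gout) {
  const int C = xd[0], S1 = xd[1], S2 = xd[2], S3 = xd[3];
  const int F = wd[1], L = wd[4];
  const int O1 = S1 - F + 1, O2 = S2 - F + 1, O3 = S3 - F + 1;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(L);
  const double *px = x.begin(), *pw = w.begin(), *pg = gout.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();
  const int fsz = C * F * F * F;
  for (int ok = 0; ok < O3; ++ok)
    for (int oj = 0; oj < O2; ++oj)
      for (int oi = 0; oi < O1; ++oi)
        for (int l = 0; l < L; ++l) {
          const double g =
            pg[l + (size_t)L * (oi + (size_t)O1 * (oj + (size_t)O2 * ok))];
          if (g == 0.0) continue;
          gb[l] += g;
          const double *wl = pw + (size_t)l * fsz;
          double *gwl = pgw + (size_t)l * fsz;
          for (int d = 0; d < F; ++d)
            for (int n = 0; n < F; ++n)
              for (int m = 0; m < F; ++m) {
                const size_t xoff = (size_t)C *
                  ((oi + m) + (size_t)S1 * ((oj + n) + (size_t)S2 * (ok + d)));
                const size_t woff = (size_t)C * (m + F * (n + F * d));
                for (int c = 0; c < C; ++c) {
                  gwl[woff + c] += g * px[xoff + c];
                  pgx[xoff + c] += g * wl[woff + c];
                }
              }
        }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling with stride 2; spatial sides must be even.  Returns the
// pooled tensor and the 1-based flat index (into the input) of each maximum,
// lowest index winning ties, for exact gradient routing.

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x, IntegerVector xd) {
  const int C = xd[0], S1 = xd[1], S2 = xd[2], S3 = xd[3];
  if (S1 % 2 || S2 % 2 || S3 % 2) stop("max pooling requires even spatial sides");
  const int O1 = S1 / 2, O2 = S2 / 2, O3 = S3 / 2;
  NumericVector out(C * O1 * O2 * O3);
  out.attr("dim") = IntegerVector::create(C, O1, O2, O3);
  IntegerVector arg(out.size());
  const double *px = x.begin();
  double *po = out.begin();
  for (int ok = 0; ok < O3; ++ok)
    for (int oj = 0; oj < O2; ++oj)
      for (int oi = 0; oi < O1; ++oi)
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          size_t bestIdx = 0;
          for (int d = 0; d < 2; ++d)
            for (int n = 0; n < 2; ++n)
              for (int m = 0; m < 2; ++m) {
                const size_t idx = c + (size_t)C *
                  ((2 * oi + m) +
                   (size_t)S1 * ((2 * oj + n) + (size_t)S2 * (2 * ok + d)));
                if (px[idx] > best) { best = px[idx]; bestIdx = idx; }
              }
          const size_t oidx =
            c + (size_t)C * (oi + (size_t)O1 * (oj + (size_t)O2 * ok));
          po[oidx] = best;
          arg[oidx] = (int)bestIdx + 1;
        }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector gout, IntegerVector argmax,
                                   IntegerVector xd) {
  NumericVector gx((size_t)xd[0] * xd[1] * xd[2] * xd[3]);
  gx.attr("dim") = xd;
  for (R_xlen_t i = 0; i < gout.size(); ++i)
    gx[argmax[i] - 1] += gout[i];
  return gx;
}
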