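// Batched 1D valid convolution and max-pooling kernels for the CNN engine.
// Layout: signals are cubes (length, channels, batch); conv weights are
// matrices (kernel * in_channels, filters) with tap index fastest within a
// channel block, i.e. row (c * k + j) holds tap j of input channel c.
// Samples are stacked into chunked im2col matrices so each BLAS call works
// on a tall patch matrix rather than one small matrix per sample, and the
// GEMMs run in single precision (the customary precision for CNN training;
// parameters and results stay double on the R side).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// rows [s_local * Lout, (s_local + 1) * Lout) of P hold sample s's patches
static inline void im2col_chunk(const cube& X, int s0, int ns, int k,
                                fmat& P) {
  const int Lout = X.n_rows - k + 1;
  const int Cin = X.n_cols;
  for (int s = 0; s < ns; ++s)
    for (int c = 0; c < Cin; ++c) {
      const double* src = X.slice(s0 + s).colptr(c);
      for (int j = 0; j < k; ++j) {
        float* dst = P.colptr(c * k + j) + (size_t)s * Lout;
        const double* sj = src + j;
        for (int t = 0; t < Lout; ++t) dst[t] = (float)sj[t];
      }
    }
}

static inline int chunk_size(int Lout, int B) {
  int ns = std::max(1, 16384 / std::max(Lout, 1));
  return std::min(ns, B);
}

// [[Rcpp::export(name = ".conv1d_forward")]]
arma::cube conv1d_forward(const arma::cube& X, const arma::mat& W,
                          const arma::vec& b, int kernel) {
  const int L = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const int F = W.n_cols;
  const int Lout = L - kernel + 1;
  if (Lout < 1) Rcpp::stop("input length %d too short for kernel %d", L, kernel);
  if ((int)W.n_rows != kernel * Cin)
    Rcpp::stop("weight rows (%d) != kernel * in_channels (%d)",
               (int)W.n_rows, kernel * Cin);
  fmat Wf = conv_to<fmat>::from(W);
  frowvec bf = conv_to<frowvec>::from(b.t());
  cube Y(Lout, F, B);
  const int ns = chunk_size(Lout, B);
  fmat P((size_t)ns * Lout, kernel * Cin);
  for (int s0 = 0; s0 < B; s0 += ns) {
    const int m = std::min(ns, B - s0);
    if (m < ns) P.set_size((size_t)m * Lout, kernel * Cin);
    im2col_chunk(X, s0, m, kernel, P);
    fmat Yc = P * Wf;
    Yc.each_row() += bf;
    for (int s = 0; s < m; ++s) {
      double* dst = Y.slice_memptr(s0 + s);
      const float* src = Yc.memptr() + (size_t)s * Lout;
      for (int f = 0; f < F; ++f)
        for (int t = 0; t < Lout; ++t)
          dst[(size_t)f * Lout + t] = src[(size_t)f * m * Lout + t];
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".conv1d_backward")]]
Rcpp::List conv1d_backward(const arma::cube& X, const arma::mat& W,
                           const arma::cube& dY, int kernel,
                           bool need_dx) {
  const int L = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const int Lout = dY.n_rows, F = dY.n_cols;
  fmat Wf = conv_to<fmat>::from(W);
  fmat dWf(W.n_rows, W.n_cols, fill::zeros);
  fvec dbf(W.n_cols, fill::zeros);
  cube dX;
  if (need_dx) dX.zeros(L, Cin, B);
  const int ns = chunk_size(Lout, B);
  fmat P((size_t)ns * Lout, kernel * Cin);
  fmat dYc((size_t)ns * Lout, F);
  for (int s0 = 0; s0 < B; s0 += ns) {
    const int m = std::min(ns, B - s0);
    if (m < ns) {
      P.set_size((size_t)m * Lout, kernel * Cin);
      dYc.set_size((size_t)m * Lout, F);
    }
    im2col_chunk(X, s0, m, kernel, P);
    for (int s = 0; s < m; ++s) {
      const double* src = dY.slice_memptr(s0 + s);
      float* dst = dYc.memptr() + (size_t)s * Lout;
      for (int f = 0; f < F; ++f)
        for (int t = 0; t < Lout; ++t)
          dst[(size_t)f * m * Lout + t] = (float)src[(size_t)f * Lout + t];
    }
    dWf += P.t() * dYc;
    dbf += sum(dYc, 0).t();
    if (need_dx) {
      fmat dP = dYc * Wf.t();
      for (int s = 0; s < m; ++s) {
        const size_t r0 = (size_t)s * Lout;
        for (int c = 0; c < Cin; ++c) {
          double* dst = dX.slice(s0 + s).colptr(c);
          for (int j = 0; j < kernel; ++j) {
            const float* src = dP.colptr(c * kernel + j) + r0;
            for (int t = 0; t < Lout; ++t) dst[t + j] += (double)src[t];
          }
        }
      }
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("dW") = conv_to<mat>::from(dWf),
    Rcpp::Named("db") = conv_to<vec>::from(dbf),
    Rcpp::Named("dX") = dX);
}

// [[Rcpp::export(name = ".maxpool_forward")]]
Rcpp::List maxpool_forward(const arma::cube& X, int pool) {
  const int L = X.n_rows, C = X.n_cols, B = X.n_slices;
  const int Lp = L / pool;  // trailing remainder dropped
  if (Lp < 1) Rcpp::stop("input length %d shorter than pool size %d", L, pool);
  cube Y(Lp, C, B);
  icube amax(Lp, C, B);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* x = X.slice(s).colptr(c);
      for (int t = 0; t < Lp; ++t) {
        int base = t * pool, best = base;
        double v = x[base];
        for (int j = 1; j < pool; ++j)
          if (x[base + j] > v) { v = x[base + j]; best = base + j; }
        Y(t, c, s) = v;
        amax(t, c, s) = best;
      }
    }
  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("argmax") = amax);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
arma::cube maxpool_backward(const arma::icube& amax, const arma::cube& dY,
                            int L) {
  const int Lp = dY.n_rows, C = dY.n_cols, B = dY.n_slices;
  cube dX(L, C, B, fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < Lp; ++t)
        dX(amax(t, c, s), c, s) += dY(t, c, s);
  return dX;
}

// [[Rcpp::export(name = ".leaky_relu_forward")]]
arma::cube leaky_relu_forward(const arma::cube& X, double slope) {
  cube Y = X;
  Y.for_each([slope](double& v) { if (v < 0) v *= slope; });
  return Y;
}

// [[Rcpp::export(name = ".leaky_relu_backward")]]
arma::cube leaky_relu_backward(const arma::cube& X, const arma::cube& dY,
                               double slope) {
  cube dX(size(X));
  const size_t n = X.n_elem;
  const double* x = X.memptr();
  const double* g = dY.memptr();
  double* d = dX.memptr();
  for (size_t i = 0; i < n; ++i) d[i] = x[i] >= 0 ? g[i] : g[i] * slope;
  return dX;
}
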