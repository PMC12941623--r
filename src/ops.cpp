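// Low-level image-tensor kernels backing the autodiff tape.
// Feature maps are stored as (H*W) x C matrices, column-major pixel index
// p = r + (c)*H (0-based row r, column c), matching R's matrix layout when an
// H x W image plane is flattened with dim<-.

#include <Rcpp.h>
#include <cstring>

using namespace Rcpp;

// im2col for a 3x3 kernel with zero padding 1 and stride 1 or 2.
// Output: (Ho*Wo) x (C*9); column (ch*9 + k) holds channel ch at offset k,
// offsets enumerated k = (dy+1) + 3*(dx+1), dy/dx in {-1,0,1}.
// Input sample for output pixel (ho,wo): (ho*stride + dy, wo*stride + dx).
// [[Rcpp::export(name = ".c_im2col3")]]
NumericMatrix c_im2col3(const NumericMatrix& X, int H, int W, int stride) {
  const int C = X.ncol();
  const int Ho = (H - 1) / stride + 1;
  const int Wo = (W - 1) / stride + 1;
  NumericMatrix out(Ho * Wo, C * 9);
  const double* xp = REAL(X);
  double* op = REAL(out);
  std::memset(op, 0, sizeof(double) * (size_t)Ho * Wo * C * 9);
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = xp + (size_t)ch * H * W;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const int k = (dy + 1) + 3 * (dx + 1);
        double* oc = op + ((size_t)ch * 9 + k) * Ho * Wo;
        if (stride == 1) {
          const int w0 = dx < 0 ? 1 : 0, w1 = dx > 0 ? W - 1 : W;
          const int h0 = dy < 0 ? 1 : 0, h1 = dy > 0 ? H - 1 : H;
          const int len = h1 - h0;
          for (int wo = w0; wo < w1; ++wo)
            std::memcpy(oc + (size_t)wo * H + h0,
                        xc + (size_t)(wo + dx) * H + h0 + dy,
                        sizeof(double) * len);
        } else {
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + dx;
            if (wi < 0 || wi >= W) continue;
            const double* src = xc + (size_t)wi * H;
            double* dst = oc + (size_t)wo * Ho;
            const int hA = dy < 0 ? (1 + stride - 1) / stride : 0;
            int hB = (H - 1 - dy) / stride; if (hB > Ho - 1) hB = Ho - 1;
            for (int ho = hA; ho <= hB; ++ho)
              dst[ho] = src[ho * stride + dy];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add column gradients back onto the input grid.
// [[Rcpp::export(name = ".c_col2im3")]]
NumericMatrix c_col2im3(const NumericMatrix& dCols, int H, int W, int stride,
                        int C) {
  const int Ho = (H - 1) / stride + 1;
  const int Wo = (W - 1) / stride + 1;
  NumericMatrix dX(H * W, C);
  const double* gp = REAL(dCols);
  double* xp = REAL(dX);
  for (int ch = 0; ch < C; ++ch) {
    double* xc = xp + (size_t)ch * H * W;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        const int k = (dy + 1) + 3 * (dx + 1);
        const double* oc = gp + ((size_t)ch * 9 + k) * Ho * Wo;
        if (stride == 1) {
          const int w0 = dx < 0 ? 1 : 0, w1 = dx > 0 ? W - 1 : W;
          const int h0 = dy < 0 ? 1 : 0, h1 = dy > 0 ? H - 1 : H;
          for (int wo = w0; wo < w1; ++wo) {
            double* dst = xc + (size_t)(wo + dx) * H + dy;
            const double* src = oc + (size_t)wo * H;
            for (int ho = h0; ho < h1; ++ho) dst[ho] += src[ho];
          }
        } else {
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride + dx;
            if (wi < 0 || wi >= W) continue;
            double* dst = xc + (size_t)wi * H;
            const double* src = oc + (size_t)wo * Ho;
            const int hA = dy < 0 ? (1 + stride - 1) / stride : 0;
            int hB = (H - 1 - dy) / stride; if (hB > Ho - 1) hB = Ho - 1;
            for (int ho = hA; ho <= hB; ++ho)
              dst[ho * stride + dy] += src[ho];
          }
        }
      }
    }
  }
  return dX;
}

// 3x3 box blur (mean over the 9-neighborhood, zero padding). Self-adjoint.
// [[Rcpp::export(name = ".c_blur3")]]
NumericMatrix c_blur3(const NumericMatrix& X, int H, int W) {
  const int C = X.ncol();
  NumericMatrix out(H * W, C);
  const double w9 = 1.0 / 9.0;
  const double* xp = REAL(X);
  double* op = REAL(out);
  std::vector<double> colsum((size_t)H);
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = xp + (size_t)ch * H * W;
    double* oc = op + (size_t)ch * H * W;
    for (int c = 0; c < W; ++c) {
      // vertical 3-tap sum of columns c-1..c+1, then horizontal 3-tap
      std::fill(colsum.begin(), colsum.end(), 0.0);
      for (int cc = c - 1; cc <= c + 1; ++cc) {
        if (cc < 0 || cc >= W) continue;
        const double* col = xc + (size_t)cc * H;
        for (int r = 0; r < H; ++r) colsum[r] += col[r];
      }
      double* dst = oc + (size_t)c * H;
      for (int r = 0; r < H; ++r) {
        double s = colsum[r];
        if (r > 0) s += colsum[r - 1];
        if (r < H - 1) s += colsum[r + 1];
        dst[r] = s * w9;
      }
    }
  }
  return out;
}

// Nearest-neighbour 2x upsampling: (H*W) x C -> (2H*2W) x C.
// [[Rcpp::export(name = ".c_upsample2")]]
NumericMatrix c_upsample2(const NumericMatrix& X, int H, int W) {
  const int C = X.ncol(), H2 = 2 * H;
  NumericMatrix out(4 * H * W, C);
  const double* xp = REAL(X);
  double* op = REAL(out);
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = xp + (size_t)ch * H * W;
    double* oc = op + (size_t)ch * 4 * H * W;
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        const double v = xc[r + (size_t)c * H];
        const size_t r2 = 2 * (size_t)r, c2 = 2 * (size_t)c;
        oc[r2     + c2       * H2] = v;
        oc[r2 + 1 + c2       * H2] = v;
        oc[r2     + (c2 + 1) * H2] = v;
        oc[r2 + 1 + (c2 + 1) * H2] = v;
      }
    }
  }
  return out;
}

// Adjoint of nearest 2x upsampling: sum each 2x2 block. H,W refer to the
// UPSAMPLED grid (must be even).
// [[Rcpp::export(name = ".c_downsum2")]]
NumericMatrix c_downsum2(const NumericMatrix& X, int H, int W) {
  const int C = X.ncol(), Ho = H / 2, Wo = W / 2;
  NumericMatrix out(Ho * Wo, C);
  const double* xp = REAL(X);
  double* op = REAL(out);
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = xp + (size_t)ch * H * W;
    double* oc = op + (size_t)ch * Ho * Wo;
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const size_t r2 = 2 * (size_t)r, c2 = 2 * (size_t)c;
        oc[r + (size_t)c * Ho] =
          xc[r2     + c2       * (size_t)H] +
          xc[r2 + 1 + c2       * (size_t)H] +
          xc[r2     + (c2 + 1) * (size_t)H] +
          xc[r2 + 1 + (c2 + 1) * (size_t)H];
      }
    }
  }
  return out;
}

#ifdef __GLIBC__
#include <malloc.h>
#endif
#ifdef __unix__
#include <dlfcn.h>
#endif

// Large tensors are allocated and freed once per training sample; with
// glibc's default thresholds every one becomes an mmap/munmap pair and the
// process spends most of its time faulting pages back in. Raising the
// thresholds keeps the arena in the heap and recycles it.
// [[Rcpp::export(name = ".c_tune_malloc")]]
void c_tune_malloc() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
#ifdef __unix__
  // The package issues many small BLAS products; multithreaded OpenBLAS
  // thrashes on them (measured slower than one thread even on idle hosts).
  typedef void (*setthreads_t)(int);
  void* sym = dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (sym) ((setthreads_t)sym)(1);
#endif
}
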