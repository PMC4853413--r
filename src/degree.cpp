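// Blockwise thresholded-correlation degree.
//
// Input Z is the masked time-series matrix (T x N), each column already
// centred and scaled to unit L2 norm, so crossprod(Z) is the Pearson
// correlation matrix. The full N x N matrix is never materialized: one
// N x block_size panel is computed per dgemm call and reduced to per-voxel
// counts immediately. Each correlation is the plain dot product of two
// standardized columns, so the counts are identical for any block size and
// match an exhaustive pairwise loop.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif

#ifdef __GLIBC__
#include <malloc.h>
#endif

#include <vector>
#include <algorithm>

using namespace Rcpp;

// The degree kernel and the simulator allocate multi-megabyte temporaries
// in a tight per-subject loop; keep such blocks on the glibc heap instead
// of mmap so freed pages are reused rather than returned to (and
// re-faulted from) the OS on every iteration. Called once at package load.
// [[Rcpp::export(name = ".tune_allocator")]]
void tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 128 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}

// [[Rcpp::export(name = ".fcd_degree_blockwise")]]
List fcd_degree_blockwise(NumericMatrix Z, IntegerVector hemi,
                          double threshold, int block_size) {
  const int T = Z.nrow();
  const int N = Z.ncol();
  if (hemi.size() != N)
    stop("hemisphere label vector length must equal the number of columns");
  if (block_size < 1) block_size = 1;
  if (block_size > N) block_size = N;

  IntegerVector g(N), c(N);
  std::vector<double> S(static_cast<size_t>(N) * block_size);
  const double one = 1.0, zero = 0.0;
  const double *z = REAL(Z);
  const int *h = INTEGER(hemi);

  for (int j0 = 0; j0 < N; j0 += block_size) {
    const int bs = std::min(block_size, N - j0);
    // S[, b] = t(Z) %*% Z[, j0 + b]: all correlations of one panel of voxels
    F77_CALL(dgemm)("T", "N", &N, &bs, &T, &one,
                    z, &T, z + static_cast<size_t>(j0) * T, &T,
                    &zero, S.data(), &N FCONE FCONE);
    for (int b = 0; b < bs; ++b) {
      const int j = j0 + b;
      const int hj = h[j];
      const double *col = S.data() + static_cast<size_t>(b) * N;
      int gj = 0, cj = 0;
      for (int i = 0; i < N; ++i) {
        if (i != j && col[i] > threshold) {
          ++gj;
          // contralateral only for strictly opposite {L,R} labels;
          // midline voxels (0) never contribute
          if (hj * h[i] == -1) ++cj;
        }
      }
      g[j] = gj;
      c[j] = cj;
    }
  }
  return List::create(_["g_raw"] = g, _["c_raw"] = c);
}
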