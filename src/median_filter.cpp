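#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Masked 3x3x3 median filter of one 3D volume. Only masked voxels are
// filtered, the kernel is restricted to masked (and finite) neighbours, and
// the median of an even count is the midpoint of the two central values.
// Unmasked voxels pass through unchanged.
// [[Rcpp::export(name = "median_filter3_masked")]]
NumericVector median_filter3_masked(NumericVector vol, LogicalVector mask) {
  IntegerVector d = vol.attr("dim");
  if (d.size() != 3) stop("vol must be a 3D array");
  const int nx = d[0], ny = d[1], nz = d[2];
  NumericVector out = clone(vol);
  std::vector<double> buf;
  buf.reserve(27);

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t c = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[c]) continue;
        buf.clear();
        for (int dk = -1; dk <= 1; ++dk) {
          const int kk = k + dk;
          if (kk < 0 || kk >= nz) continue;
          for (int dj = -1; dj <= 1; ++dj) {
            const int jj = j + dj;
            if (jj < 0 || jj >= ny) continue;
            for (int di = -1; di <= 1; ++di) {
              const int ii = i + di;
              if (ii < 0 || ii >= nx) continue;
              const R_xlen_t n = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
              if (mask[n] && R_finite(vol[n])) buf.push_back(vol[n]);
            }
          }
        }
        const size_t m = buf.size();
        if (m == 0) { out[c] = NA_REAL; continue; }
        std::sort(buf.begin(), buf.end());
        out[c] = (m % 2 == 1) ? buf[m / 2]
                              : 0.5 * (buf[m / 2 - 1] + buf[m / 2]);
      }
    }
  }
  out.attr("dim") = d;
  return out;
}

// Jacobi diffusion fill of background (unmasked) voxels from fixed masked
// values: `iters` sweeps of the 6-neighbour average, zero initial state.
// [[Rcpp::export(name = "jacobi_fill3")]]
NumericVector jacobi_fill3(NumericVector vol, LogicalVector mask, int iters) {
  IntegerVector d = vol.attr("dim");
  if (d.size() != 3) stop("vol must be a 3D array");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> cur(n), nxt(n);
  for (R_xlen_t i = 0; i < n; ++i) cur[i] = mask[i] ? vol[i] : 0.0;
  for (int it = 0; it < iters; ++it) {
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const R_xlen_t c = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
          if (mask[c]) { nxt[c] = cur[c]; continue; }
          double s = 0.0;
          if (i > 0)      s += cur[c - 1];
          if (i < nx - 1) s += cur[c + 1];
          if (j > 0)      s += cur[c - nx];
          if (j < ny - 1) s += cur[c + nx];
          if (k > 0)      s += cur[c - (R_xlen_t)nx * ny];
          if (k < nz - 1) s += cur[c + (R_xlen_t)nx * ny];
          nxt[c] = s / 6.0;
        }
      }
    }
    cur.swap(nxt);
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = cur[i];
  out.attr("dim") = d;
  return out;
}
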