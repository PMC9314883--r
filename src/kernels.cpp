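// Hot numerical kernels: batch-normalization forward/backward for the
// segmentation network, and the mass-based region-growing averager used
// for 10 g SAR / Q-matrix averaging.

#include <Rcpp.h>
using namespace Rcpp;

// Batch-normalization forward on the (rows x channels) activation matrix.
// Returns the normalized activations and the cached xhat.
// [[Rcpp::export(name = ".bn_fwd_cpp")]]
List bn_fwd_cpp(const NumericMatrix& M, const NumericVector& gamma,
                const NumericVector& beta, const NumericVector& mu,
                const NumericVector& istd) {
  const int m = M.nrow(), C = M.ncol();
  NumericMatrix Y(m, C), xhat(m, C);
  for (int c = 0; c < C; ++c) {
    const double g = gamma[c], b = beta[c], mc = mu[c], is = istd[c];
    const double* x = &M(0, c);
    double* xh = &xhat(0, c);
    double* y = &Y(0, c);
    for (int i = 0; i < m; ++i) {
      const double v = (x[i] - mc) * is;
      xh[i] = v;
      y[i] = g * v + b;
    }
  }
  return List::create(_["Y"] = Y, _["xhat"] = xhat);
}

// Batch-normalization backward; single pass per channel.
// [[Rcpp::export(name = ".bn_bwd_cpp")]]
List bn_bwd_cpp(const NumericMatrix& dY, const NumericMatrix& xhat,
                const NumericVector& gamma, const NumericVector& istd,
                const bool train_stats) {
  const int m = dY.nrow(), C = dY.ncol();
  NumericMatrix dM(m, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dy = &dY(0, c);
    const double* xh = &xhat(0, c);
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < m; ++i) {
      sg += dy[i] * xh[i];
      sb += dy[i];
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double g = gamma[c], is = istd[c];
    double* out = &dM(0, c);
    if (train_stats) {
      const double t1 = g * sb / m, t2 = g * sg / m;
      for (int i = 0; i < m; ++i)
        out[i] = (g * dy[i] - t1 - xh[i] * t2) * is;
    } else {
      // inference-mode statistics are constants: no mean terms
      for (int i = 0; i < m; ++i) out[i] = g * dy[i] * is;
    }
  }
  return List::create(_["dM"] = dM, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Mass-based region-growing average. For each tissue voxel, neighbouring
// tissue voxels are accumulated in order of increasing Euclidean
// voxel-center distance (ties by lexicographic (i,j,k) offset, which
// equals lexicographic absolute index order) until the accumulated mass
// reaches target_mass; the final voxel contributes fractionally so that
// the region mass equals target_mass exactly. values has one row per
// voxel (column-major linear index) and K columns averaged jointly over
// identical regions. Voxels whose region cannot be completed within the
// supplied offsets get complete = FALSE and must be retried with a larger
// offset set (or fall back to a whole-body average).
// [[Rcpp::export(name = ".avg10g_cpp")]]
List avg10g_cpp(const IntegerVector& dims, const LogicalVector& tissue,
                const NumericVector& mass, const NumericMatrix& values,
                const double target_mass, const IntegerMatrix& offsets,
                const LogicalVector& todo) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz, K = values.ncol(), noff = offsets.nrow();
  NumericMatrix avg(nvox, K);
  LogicalVector complete(nvox);
  std::vector<double> acc(K);
  std::vector<int> region;
  std::vector<double> wts;
  region.reserve(4096);
  wts.reserve(4096);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int v = i + nx * (j + ny * k);
        if (!tissue[v] || !todo[v]) continue;
        double acc_mass = 0.0;
        bool done = false;
        region.clear();
        wts.clear();
        for (int o = 0; o < noff; ++o) {
          const int ii = i + offsets(o, 0);
          if (ii < 0 || ii >= nx) continue;
          const int jj = j + offsets(o, 1);
          if (jj < 0 || jj >= ny) continue;
          const int kk = k + offsets(o, 2);
          if (kk < 0 || kk >= nz) continue;
          const int w = ii + nx * (jj + ny * kk);
          if (!tissue[w]) continue;
          const double mw = mass[w];
          if (acc_mass + mw >= target_mass) {
            region.push_back(w);
            wts.push_back(target_mass - acc_mass);
            acc_mass = target_mass;
            done = true;
            break;
          }
          region.push_back(w);
          wts.push_back(mw);
          acc_mass += mw;
        }
        if (!done) { complete[v] = false; continue; }
        complete[v] = true;
        std::fill(acc.begin(), acc.end(), 0.0);
        for (size_t r = 0; r < region.size(); ++r) {
          const double wt = wts[r];
          const int w = region[r];
          for (int c = 0; c < K; ++c) acc[c] += wt * values(w, c);
        }
        for (int c = 0; c < K; ++c) avg(v, c) = acc[c] / target_mass;
      }
  return List::create(_["avg"] = avg, _["complete"] = complete);
}
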