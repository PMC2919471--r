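#include <Rcpp.h>
using namespace Rcpp;

// Explicit reaction-diffusion steps on a compacted list of interior voxels.
//
// Tt      : total concentration per interior voxel (modified copy returned)
// nbr     : n x 6 matrix of 1-based neighbour indices into the compacted
//           list; 0 marks a face on the embryo surface (zero flux)
// r       : local bound-to-free ratio per voxel; free = T / (1 + r)
// ddt_h2  : D * dt / h^2
// omega_dt: omega * dt
// src     : 1-based compacted indices of source voxels
// src_add : concentration added per source voxel per step
// [[Rcpp::export]]
NumericVector rd_steps_cpp(NumericVector Tt, IntegerMatrix nbr,
                           NumericVector r, double ddt_h2, double omega_dt,
                           IntegerVector src, double src_add, int nsteps) {
  const int n = Tt.size();
  NumericVector T = clone(Tt);
  std::vector<double> Bf(n);
  const int *nb = INTEGER(nbr);
  for (int step = 0; step < nsteps; ++step) {
    for (int i = 0; i < n; ++i) Bf[i] = T[i] / (1.0 + r[i]);
    for (int i = 0; i < n; ++i) {
      double lap = 0.0;
      for (int k = 0; k < 6; ++k) {
        int j = nb[i + (std::size_t)k * n];
        if (j > 0) lap += Bf[j - 1] - Bf[i];
      }
      T[i] += ddt_h2 * lap - omega_dt * T[i];
    }
    for (int s = 0; s < src.size(); ++s) T[src[s] - 1] += src_add;
  }
  return T;
}
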