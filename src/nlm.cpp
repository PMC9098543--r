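#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rician-adapted non-local means on one 3D volume.
// For voxel i, weights over the search window j:
//   w_ij = exp(-msd(patch_i, patch_j) / h^2)
// with msd the mean squared intensity difference over the patch (patches
// clipped at the volume border are compared over their valid overlap).
// Output: sqrt(max(sum_j w_ij x_j^2 / sum_j w_ij - 2 sigma^2, 0)).
// [[Rcpp::export]]
NumericVector nlm_denoise_vol(NumericVector vol, IntegerVector dims,
                              int patch_radius, int search_radius,
                              double h, double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(vol.size());
  const double h2 = h * h;
  auto at = [&](int x, int y, int z) -> double {
    return vol[x + nx * (y + ny * z)];
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double wsum = 0.0, acc = 0.0;
        for (int dz = -search_radius; dz <= search_radius; ++dz)
          for (int dy = -search_radius; dy <= search_radius; ++dy)
            for (int dx = -search_radius; dx <= search_radius; ++dx) {
              const int qx = x + dx, qy = y + dy, qz = z + dz;
              if (qx < 0 || qx >= nx || qy < 0 || qy >= ny ||
                  qz < 0 || qz >= nz) continue;
              double ssd = 0.0; int np = 0;
              for (int pz = -patch_radius; pz <= patch_radius; ++pz)
                for (int py = -patch_radius; py <= patch_radius; ++py)
                  for (int px = -patch_radius; px <= patch_radius; ++px) {
                    const int ax = x + px, ay = y + py, az = z + pz;
                    const int bx = qx + px, by = qy + py, bz = qz + pz;
                    if (ax < 0 || ax >= nx || ay < 0 || ay >= ny ||
                        az < 0 || az >= nz) continue;
                    if (bx < 0 || bx >= nx || by < 0 || by >= ny ||
                        bz < 0 || bz >= nz) continue;
                    const double d = at(ax, ay, az) - at(bx, by, bz);
                    ssd += d * d; ++np;
                  }
              const double msd = np > 0 ? ssd / np : 0.0;
              const double w = (h2 > 0.0) ? std::exp(-msd / h2)
                                          : (msd == 0.0 ? 1.0 : 0.0);
              const double q = at(qx, qy, qz);
              wsum += w; acc += w * q * q;
            }
        const double ex2 = acc / wsum;
        const double v = ex2 - 2.0 * sigma * sigma;
        out[x + nx * (y + ny * z)] = v > 0.0 ? std::sqrt(v) : 0.0;
      }
  return out;
}
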