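#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Field {
  const double *sh, *gfa;
  const int *mask;
  int nx, ny, nz, nc;
  double vs;

  bool in_mask_mm(double x, double y, double z) const {
    int i = (int)std::floor(x / vs), j = (int)std::floor(y / vs),
        k = (int)std::floor(z / vs);
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return false;
    return mask[i + nx * (j + (size_t)ny * k)] != 0;
  }

  // trilinear interpolation on the voxel-center grid; border-clamped
  void interp_coef(double x, double y, double z, double *out) const {
    double cx = x / vs - 0.5, cy = y / vs - 0.5, cz = z / vs - 0.5;
    int i0 = (int)std::floor(cx), j0 = (int)std::floor(cy),
        k0 = (int)std::floor(cz);
    double fx = cx - i0, fy = cy - j0, fz = cz - k0;
    for (int c = 0; c < nc; ++c) out[c] = 0.0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          int i = std::min(std::max(i0 + di, 0), nx - 1);
          int j = std::min(std::max(j0 + dj, 0), ny - 1);
          int k = std::min(std::max(k0 + dk, 0), nz - 1);
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                     (dk ? fz : 1 - fz);
          if (w <= 0) continue;
          size_t base = i + nx * (j + (size_t)ny * k);
          size_t vol = (size_t)nx * ny * nz;
          for (int c = 0; c < nc; ++c) out[c] += w * sh[base + vol * c];
        }
  }

  double interp_gfa(double x, double y, double z) const {
    double cx = x / vs - 0.5, cy = y / vs - 0.5, cz = z / vs - 0.5;
    int i0 = (int)std::floor(cx), j0 = (int)std::floor(cy),
        k0 = (int)std::floor(cz);
    double fx = cx - i0, fy = cy - j0, fz = cz - k0, acc = 0.0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          int i = std::min(std::max(i0 + di, 0), nx - 1);
          int j = std::min(std::max(j0 + dj, 0), ny - 1);
          int k = std::min(std::max(k0 + dk, 0), nz - 1);
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                     (dk ? fz : 1 - fz);
          acc += w * gfa[i + nx * (j + (size_t)ny * k)];
        }
    return acc;
  }
};

struct Peaks {
  const double *tess, *B;          // nt x 3, nt x nc (column-major)
  const int *nb_idx, *nb_start;    // CSR neighbor lists, 0-based
  int nt, nc;
  double rel_thr;
  std::vector<double> odf;

  void eval(const double *coef) {
    double mn = 0.0;
    for (int t = 0; t < nt; ++t) {
      double v = 0.0;
      for (int c = 0; c < nc; ++c) v += B[t + (size_t)nt * c] * coef[c];
      odf[t] = v;
      if (v < mn) mn = v;
    }
    if (mn < 0)
      for (int t = 0; t < nt; ++t) odf[t] -= mn;
  }

  // global maximum direction
  void global_max(double *dir) const {
    int best = 0;
    for (int t = 1; t < nt; ++t)
      if (odf[t] > odf[best]) best = t;
    dir[0] = tess[best]; dir[1] = tess[best + nt]; dir[2] = tess[best + 2 * nt];
  }

  // among NMS peaks within the aperture cone of d, the one closest in
  // angle; ties broken by larger ODF then lexicographically smaller
  // direction. Returns false if no in-cone peak exists.
  bool nearest_peak(const double *d, double cos_ap, double *out) const {
    double gmax = 0.0;
    for (int t = 0; t < nt; ++t) if (odf[t] > gmax) gmax = odf[t];
    if (gmax <= 0.0) return false;
    int best = -1; double best_dot = -2.0;
    for (int t = 0; t < nt; ++t) {
      double dot = d[0] * tess[t] + d[1] * tess[t + nt] + d[2] * tess[t + 2 * nt];
      if (dot < cos_ap) continue;
      if (odf[t] < rel_thr * gmax) continue;
      bool is_peak = true;
      for (int q = nb_start[t]; q < nb_start[t + 1]; ++q)
        if (odf[nb_idx[q]] > odf[t]) { is_peak = false; break; }
      if (!is_peak) continue;
      bool take = false;
      if (dot > best_dot + 1e-12) take = true;
      else if (dot > best_dot - 1e-12 && best >= 0) {
        if (odf[t] > odf[best] + 1e-12) take = true;
        else if (std::abs(odf[t] - odf[best]) <= 1e-12) {
          for (int a = 0; a < 3; ++a) {
            double u = tess[t + a * nt], v = tess[best + a * nt];
            if (u < v - 1e-12) { take = true; break; }
            if (u > v + 1e-12) break;
          }
        }
      }
      if (take) { best = t; best_dot = dot; }
    }
    if (best < 0) return false;
    out[0] = tess[best]; out[1] = tess[best + nt]; out[2] = tess[best + 2 * nt];
    return true;
  }
};

// one half-streamline: starts at seed, first direction d0 given, walks
// until mask exit, no in-cone peak, or max step count
void walk(const Field &F, Peaks &P, const double *seed, const double *d0,
          double step, double cos_ap, double theta, int max_steps,
          std::vector<double> &pts, std::vector<double> &coef_buf) {
  double x[3] = {seed[0], seed[1], seed[2]};
  double d[3] = {d0[0], d0[1], d0[2]};
  // first step: along d0 (the global ODF maximum at the seed)
  for (int s = 0; s < max_steps; ++s) {
    double dn[3];
    if (s == 0) {
      dn[0] = d[0]; dn[1] = d[1]; dn[2] = d[2];
    } else {
      F.interp_coef(x[0], x[1], x[2], coef_buf.data());
      P.eval(coef_buf.data());
      double dodf[3];
      if (!P.nearest_peak(d, cos_ap, dodf)) break;
      double g = F.interp_gfa(x[0], x[1], x[2]);
      double w = 1.0 - g / theta;
      if (w < 0) w = 0; if (w > 1) w = 1;
      double nrm = 0.0;
      for (int a = 0; a < 3; ++a) {
        dn[a] = (1 - w) * dodf[a] + w * d[a];
        nrm += dn[a] * dn[a];
      }
      nrm = std::sqrt(nrm);
      if (nrm < 1e-12) break;
      for (int a = 0; a < 3; ++a) dn[a] /= nrm;
    }
    double xn[3] = {x[0] + step * dn[0], x[1] + step * dn[1],
                    x[2] + step * dn[2]};
    if (!F.in_mask_mm(xn[0], xn[1], xn[2])) break;
    pts.push_back(xn[0]); pts.push_back(xn[1]); pts.push_back(xn[2]);
    x[0] = xn[0]; x[1] = xn[1]; x[2] = xn[2];
    d[0] = dn[0]; d[1] = dn[1]; d[2] = dn[2];
  }
}

}  // namespace

// [[Rcpp::export]]
List track_srd_cpp(NumericVector sh, IntegerVector dims_sh, NumericVector gfa,
                   IntegerVector mask, NumericMatrix seeds,
                   NumericMatrix tess, NumericMatrix Btess,
                   IntegerVector nb_idx, IntegerVector nb_start,
                   double voxel_size, double step, double aperture_deg,
                   double theta, double min_len, double max_len,
                   double rel_peak_thr) {
  Field F;
  F.sh = sh.begin(); F.gfa = gfa.begin(); F.mask = mask.begin();
  F.nx = dims_sh[0]; F.ny = dims_sh[1]; F.nz = dims_sh[2]; F.nc = dims_sh[3];
  F.vs = voxel_size;
  Peaks P;
  P.tess = tess.begin(); P.B = Btess.begin();
  P.nb_idx = nb_idx.begin(); P.nb_start = nb_start.begin();
  P.nt = tess.nrow(); P.nc = F.nc; P.rel_thr = rel_peak_thr;
  P.odf.resize(P.nt);
  const double cos_ap = std::cos(aperture_deg * M_PI / 180.0);
  const int max_steps = (int)std::ceil(max_len / step) + 2;

  std::vector<double> coef_buf(F.nc);
  List out;
  std::vector<int> seed_id;
  int dropped = 0;
  for (int si = 0; si < seeds.nrow(); ++si) {
    double seed[3] = {seeds(si, 0), seeds(si, 1), seeds(si, 2)};
    if (!F.in_mask_mm(seed[0], seed[1], seed[2])) { ++dropped; continue; }
    F.interp_coef(seed[0], seed[1], seed[2], coef_buf.data());
    P.eval(coef_buf.data());
    double d0[3];
    P.global_max(d0);
    std::vector<double> fwd, bwd;
    walk(F, P, seed, d0, step, cos_ap, theta, max_steps, fwd, coef_buf);
    double d0n[3] = {-d0[0], -d0[1], -d0[2]};
    walk(F, P, seed, d0n, step, cos_ap, theta, max_steps, bwd, coef_buf);
    const int nf = fwd.size() / 3, nb = bwd.size() / 3;
    const int npts = nf + nb + 1;
    const double len = step * (nf + nb);
    if (npts < 2 || len < min_len || len > max_len) { ++dropped; continue; }
    NumericMatrix sl(npts, 3);
    int r = 0;
    for (int i = nb - 1; i >= 0; --i, ++r)
      for (int a = 0; a < 3; ++a) sl(r, a) = bwd[3 * i + a];
    for (int a = 0; a < 3; ++a) sl(r, a) = seed[a];
    ++r;
    for (int i = 0; i < nf; ++i, ++r)
      for (int a = 0; a < 3; ++a) sl(r, a) = fwd[3 * i + a];
    out.push_back(sl);
    seed_id.push_back(si + 1);
  }
  return List::create(_["streamlines"] = out,
                      _["seed_index"] = wrap(seed_id),
                      _["n_dropped"] = dropped);
}
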