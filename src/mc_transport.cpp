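#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Weighted photon random walk in a layered semi-infinite medium.
//
// Physics conventions (documented on the R side):
//  * similarity relation: isotropic scattering with step rate mu_s' (no g),
//  * continuous absorption: weight *= exp(-mu_a * l) per segment,
//  * index-matched boundaries (no Fresnel reflection / refraction); the
//    per-layer refractive index enters only through the speed c/n,
//  * z increases downward, surface at z = 0; lengths mm, time ns,
//  * any upward crossing of z = 0 exits; exits inside the detector rectangle
//    are tallied per photon, others only contribute to the escaped weight,
//  * Russian roulette below w_min with survival probability rr_p; the
//    realised net weight change is tallied so the energy balance closes
//    exactly (launched = detected + escaped + absorbed + capped + roulette).

static inline double clip_overlap(double lo, double hi, double a, double b) {
  double l = lo > a ? lo : a;
  double h = hi < b ? hi : b;
  return h > l ? h - l : 0.0;
}

// path length of the segment p + t*v, t in [0, d], inside an axis-aligned
// cylinder (axis 0=x, 1=y, 2=z) of radius r and half-length hl about centre c
static double cylinder_path(double px, double py, double pz,
                            double vx, double vy, double vz, double d,
                            int axis, double cx, double cy, double cz,
                            double r, double hl) {
  double p1, p2, pa, v1, v2, va;
  if (axis == 2) {        // axis along z: radial plane is (x, y)
    p1 = px - cx; p2 = py - cy; pa = pz - cz;
    v1 = vx; v2 = vy; va = vz;
  } else if (axis == 1) { // axis along y
    p1 = px - cx; p2 = pz - cz; pa = py - cy;
    v1 = vx; v2 = vz; va = vy;
  } else {                // axis along x
    p1 = py - cy; p2 = pz - cz; pa = px - cx;
    v1 = vy; v2 = vz; va = vx;
  }
  double A = v1 * v1 + v2 * v2;
  double tlo, thi;
  if (A < 1e-14) {
    if (p1 * p1 + p2 * p2 > r * r) return 0.0;
    tlo = 0.0; thi = d;
  } else {
    double B = 2.0 * (p1 * v1 + p2 * v2);
    double C = p1 * p1 + p2 * p2 - r * r;
    double disc = B * B - 4.0 * A * C;
    if (disc <= 0.0) return 0.0;
    double sq = std::sqrt(disc);
    tlo = (-B - sq) / (2.0 * A);
    thi = (-B + sq) / (2.0 * A);
  }
  // axial extent
  double alo = -INFINITY, ahi = INFINITY;
  if (R_finite(hl)) {
    if (std::fabs(va) < 1e-14) {
      if (std::fabs(pa) > hl) return 0.0;
    } else {
      double t1 = (-hl - pa) / va, t2 = (hl - pa) / va;
      alo = t1 < t2 ? t1 : t2;
      ahi = t1 < t2 ? t2 : t1;
    }
  }
  double lo = tlo > alo ? tlo : alo;
  double hi = thi < ahi ? thi : ahi;
  return clip_overlap(lo, hi, 0.0, d);
}

// [[Rcpp::export(name = ".mc_transport_cpp")]]
List mc_transport_cpp(NumericVector thickness, NumericVector mus,
                      NumericVector mua, NumericVector nrefr,
                      NumericVector src_rect, NumericVector det_rect,
                      bool has_slab, double slab_z0, double slab_z1,
                      bool has_incl, int incl_axis,
                      double incl_cx, double incl_cy, double incl_cz,
                      double incl_r, double incl_hl, double incl_dmua,
                      bool incl_apply,
                      double n_photons, double max_path,
                      double w_min, double rr_p,
                      bool keep_layer_paths, double c_mm_ns) {
  const int nl = thickness.size();
  std::vector<double> ztop(nl), zbot(nl);
  double zc = 0.0;
  for (int i = 0; i < nl; ++i) {
    ztop[i] = zc;
    zc = R_finite(thickness[i]) ? zc + thickness[i] : R_PosInf;
    zbot[i] = zc;
  }
  const double sx0 = src_rect[0], sx1 = src_rect[1];
  const double sy0 = src_rect[2], sy1 = src_rect[3];
  const double dx0 = det_rect[0], dx1 = det_rect[1];
  const double dy0 = det_rect[2], dy1 = det_rect[3];

  std::vector<double> o_time, o_x, o_y, o_w, o_ptot, o_pslab, o_pincl;
  std::vector<double> o_play; // row-major n_det x nl
  double det_w = 0.0, esc_w = 0.0, abs_w = 0.0, cap_w = 0.0, rr_net = 0.0;
  long long n_det = 0;
  const long long N = (long long)n_photons;
  std::vector<double> play(nl);

  RNGScope scope;
  for (long long ip = 0; ip < N; ++ip) {
    double x = sx0 + unif_rand() * (sx1 - sx0);
    double y = sy0 + unif_rand() * (sy1 - sy0);
    double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0, t = 0.0, ptot = 0.0, pslab = 0.0, pincl = 0.0;
    int layer = 0;
    std::fill(play.begin(), play.end(), 0.0);
    bool alive = true;

    while (alive) {
      double u = unif_rand();
      double tau = -std::log(u > 1e-300 ? u : 1e-300);
      // propagate one scattering free path, possibly across boundaries
      while (true) {
        const double musl = mus[layer];
        const double d_sc = musl > 0.0 ? tau / musl : R_PosInf;
        double d_b = R_PosInf;
        int nlayer = layer;
        if (uz > 0.0) {
          if (R_finite(zbot[layer])) d_b = (zbot[layer] - z) / uz;
          nlayer = layer + 1;
        } else if (uz < 0.0) {
          d_b = (ztop[layer] - z) / uz; // >= 0 since z >= ztop
          nlayer = layer - 1;
        }
        const double d_cap = max_path - ptot;
        double d = d_sc < d_b ? d_sc : d_b;
        bool hit_cap = false;
        if (d_cap <= d) { d = d_cap; hit_cap = true; }
        if (d < 0.0) d = 0.0;

        // segment tallies
        double linc = 0.0;
        if (has_incl && d > 0.0)
          linc = cylinder_path(x, y, z, ux, uy, uz, d, incl_axis,
                               incl_cx, incl_cy, incl_cz, incl_r, incl_hl);
        double od = mua[layer] * d;
        if (incl_apply) od += incl_dmua * linc;
        const double f = std::exp(-od);
        abs_w += w * (1.0 - f);
        w *= f;
        play[layer] += d;
        ptot += d;
        pincl += linc;
        t += d * nrefr[layer] / c_mm_ns;
        if (has_slab && d > 0.0) {
          if (uz != 0.0) {
            const double t0 = (slab_z0 - z) / uz, t1 = (slab_z1 - z) / uz;
            pslab += clip_overlap(t0 < t1 ? t0 : t1, t0 < t1 ? t1 : t0, 0.0, d);
          } else if (z >= slab_z0 && z <= slab_z1) {
            pslab += d;
          }
        }
        x += ux * d; y += uy * d; z += uz * d;

        if (hit_cap) { cap_w += w; alive = false; break; }
        if (d_b <= d_sc) { // boundary crossing
          tau -= d * musl;
          if (nlayer < 0) { // upward exit through the surface
            z = 0.0;
            if (x >= dx0 && x <= dx1 && y >= dy0 && y <= dy1) {
              det_w += w; ++n_det;
              o_time.push_back(t); o_x.push_back(x); o_y.push_back(y);
              o_w.push_back(w); o_ptot.push_back(ptot);
              o_pslab.push_back(pslab); o_pincl.push_back(pincl);
              if (keep_layer_paths)
                for (int l = 0; l < nl; ++l) o_play.push_back(play[l]);
            } else {
              esc_w += w;
            }
            alive = false;
            break;
          }
          if (nlayer >= nl) { // transmitted through a finite bottom layer
            esc_w += w;
            alive = false;
            break;
          }
          z = (nlayer > layer) ? zbot[layer] : ztop[layer];
          layer = nlayer;
        } else { // scattering event
          const double czen = 2.0 * unif_rand() - 1.0;
          const double szen = std::sqrt(1.0 - czen * czen);
          const double phi = 2.0 * M_PI * unif_rand();
          ux = szen * std::cos(phi);
          uy = szen * std::sin(phi);
          uz = czen;
          break;
        }
      }
      if (alive && w < w_min) { // Russian roulette
        if (unif_rand() < rr_p) {
          rr_net -= w * (1.0 / rr_p - 1.0);
          w /= rr_p;
        } else {
          rr_net += w;
          alive = false;
        }
      }
    }
    if (ip % 65536 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["exit_time"] = NumericVector(o_time.begin(), o_time.end()),
    _["exit_x"] = NumericVector(o_x.begin(), o_x.end()),
    _["exit_y"] = NumericVector(o_y.begin(), o_y.end()),
    _["weight"] = NumericVector(o_w.begin(), o_w.end()),
    _["path_total"] = NumericVector(o_ptot.begin(), o_ptot.end()),
    _["path_slab"] = NumericVector(o_pslab.begin(), o_pslab.end()),
    _["path_inclusion"] = NumericVector(o_pincl.begin(), o_pincl.end()));
  if (keep_layer_paths) {
    NumericMatrix pm(nl, (int)n_det); // filled column-wise, transpose in R
    std::copy(o_play.begin(), o_play.end(), pm.begin());
    out["path_layers"] = pm;
  } else {
    out["path_layers"] = R_NilValue;
  }
  out["totals"] = List::create(
    _["launched"] = (double)N, _["detected"] = det_w,
    _["escaped"] = esc_w, _["absorbed"] = abs_w,
    _["capped"] = cap_w, _["roulette_net"] = rr_net,
    _["n_detected"] = (double)n_det);
  return out;
}
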