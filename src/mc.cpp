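// Time-resolved weighted Monte Carlo photon transport on a labeled voxel grid.
//
// Physics: exponential free-path sampling against the local total interaction
// coefficient mu_t = mu_a + mu_s, absorption by albedo weighting at each
// interaction, isotropic scattering (reduced-scattering / g = 0 convention),
// Fresnel reflection/refraction at refractive-index steps across voxel faces,
// Russian roulette below a weight threshold, and a hard time cutoff at the
// end of the recorded window. Fluence is accumulated with the path-length
// estimator per voxel and 40 ps-class time bin; boundary exits crossing the
// detector plane are binned into a fixed rectangular detector array.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

const double C_MM_NS = 299.792458; // speed of light in vacuum, mm/ns

// --- xoshiro256+ RNG, seeded via splitmix64: fast, reproducible across
// platforms, independent of R's RNG stream (seed is an explicit argument).
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double u01() { // in (0,1]: safe for log()
    return ((next() >> 11) + 1.0) * 0x1.0p-53;
  }
};

struct Detector {
  bool active = false;
  double x_plane = 0.0;   // grid-frame x of the detector plane (exit side)
  double y0 = 0.0, z0 = 0.0; // center of first patch
  double pitch = 2.48;
  int ny = 0, nz = 0;
};

inline void isotropic_dir(Rng& rng, double* d) {
  double ct = 2.0 * rng.u01() - 1.0;
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 6.283185307179586 * rng.u01();
  d[0] = st * std::cos(phi);
  d[1] = st * std::sin(phi);
  d[2] = ct;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(IntegerVector labels, IntegerVector dims, double voxel_mm,
                NumericMatrix props,      // nlabel x 3: mu_a (1/mm), mu_s (1/mm), n
                List source,              // type "rect" or "point"
                double dt_ns, int nt,
                List detector,            // may be empty list
                IntegerVector tissue_row, // per voxel: 0-based fluence row or -1
                int n_tissue,
                double n_photons_d, double seed_d,
                double roulette_threshold, double roulette_p,
                bool record_fluence) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double vx = voxel_mm;
  const double gx = nx * vx, gy = ny * vx, gz = nz * vx;
  const double tmax = nt * dt_ns;
  const long long n_photons = (long long)n_photons_d;
  if (n_photons < 1) stop("n_photons must be positive");

  const int nlab = props.nrow();
  std::vector<double> mua(nlab), mus(nlab), mut(nlab), nref(nlab), albedo(nlab);
  for (int l = 0; l < nlab; ++l) {
    mua[l] = props(l, 0); mus[l] = props(l, 1); nref[l] = props(l, 2);
    mut[l] = mua[l] + mus[l];
    albedo[l] = mut[l] > 0 ? mus[l] / mut[l] : 0.0;
  }

  // source
  std::string stype = as<std::string>(source["type"]);
  double sy0 = 0, sy1 = 0, sz0 = 0, sz1 = 0, sdir = 1.0;
  double spx = 0, spy = 0, spz = 0;
  bool is_rect = (stype == "rect");
  if (is_rect) {
    sy0 = as<double>(source["y0"]); sy1 = as<double>(source["y1"]);
    sz0 = as<double>(source["z0"]); sz1 = as<double>(source["z1"]);
    sdir = as<double>(source["dir"]); // +1: launch at x=0 plane, -1: at x=gx
  } else if (stype == "point") {
    NumericVector pos = source["pos"];
    spx = pos[0]; spy = pos[1]; spz = pos[2];
  } else stop("unknown source type");

  Detector det;
  if (detector.size() > 0) {
    det.active = true;
    det.x_plane = as<double>(detector["x_plane"]);
    det.y0 = as<double>(detector["y0"]);
    det.z0 = as<double>(detector["z0"]);
    det.pitch = as<double>(detector["pitch"]);
    det.ny = as<int>(detector["ny"]);
    det.nz = as<int>(detector["nz"]);
  }

  arma::mat flu;
  if (record_fluence) flu.zeros(n_tissue, nt);
  arma::mat dtpsf;
  if (det.active) dtpsf.zeros((size_t)det.ny * det.nz, nt);

  double absorbed = 0.0, exited = 0.0, cutoff = 0.0, roulette_net = 0.0,
         detected = 0.0;

  Rng rng((uint64_t)seed_d);
  const int* lab = INTEGER(labels);
  const int* trow = INTEGER(tissue_row);

  const double inv_dt = 1.0 / dt_ns;
  const double inv_c = 1.0 / C_MM_NS;

  for (long long ph = 0; ph < n_photons; ++ph) {
    double p[3], d[3], invd[3];
    if (is_rect) {
      p[0] = sdir > 0 ? 1e-9 : gx - 1e-9;
      p[1] = sy0 + (sy1 - sy0) * rng.u01();
      p[2] = sz0 + (sz1 - sz0) * rng.u01();
      d[0] = sdir; d[1] = 0.0; d[2] = 0.0;
    } else {
      p[0] = spx; p[1] = spy; p[2] = spz;
      isotropic_dir(rng, d);
    }
    for (int a = 0; a < 3; ++a)
      invd[a] = std::fabs(d[a]) > 1e-12 ? 1.0 / d[a] : 0.0;
    int iv[3] = { (int)std::floor(p[0] / vx), (int)std::floor(p[1] / vx),
                  (int)std::floor(p[2] / vx) };
    for (int a = 0; a < 3; ++a) {
      int n = a == 0 ? nx : (a == 1 ? ny : nz);
      if (iv[a] < 0) iv[a] = 0;
      if (iv[a] >= n) iv[a] = n - 1;
    }
    double w = 1.0, t = 0.0;
    double tau = -std::log(rng.u01());
    bool entered_tissue = false;
    bool alive = true;
    long long steps = 0;

    while (alive) {
      if (++steps > 100000000LL) { cutoff += w; break; } // safety, unreachable
      const int lin = iv[0] + nx * (iv[1] + ny * iv[2]);
      const int L = lab[lin];
      const double mt = mut[L], n1 = nref[L];
      if (mt > 0) entered_tissue = true;

      // distance to the nearest voxel face along the travel direction
      double dface = std::numeric_limits<double>::infinity();
      int kmin = -1;
      for (int a = 0; a < 3; ++a) {
        if (invd[a] > 0) {
          double dd = ((iv[a] + 1) * vx - p[a]) * invd[a];
          if (dd < dface) { dface = dd; kmin = a; }
        } else if (invd[a] < 0) {
          double dd = (iv[a] * vx - p[a]) * invd[a];
          if (dd < dface) { dface = dd; kmin = a; }
        }
      }
      if (kmin < 0) { cutoff += w; break; } // degenerate direction
      if (dface < 0) dface = 0;

      if (mt > 0 && tau < mt * dface) {
        // interaction inside this voxel
        double s = tau / mt;
        if (record_fluence && trow[lin] >= 0) {
          int bin = (int)((t + 0.5 * s * n1 * inv_c) * inv_dt);
          if (bin >= 0 && bin < nt) flu(trow[lin], bin) += w * s;
        }
        for (int a = 0; a < 3; ++a) p[a] += s * d[a];
        t += s * n1 * inv_c;
        if (t > tmax) { cutoff += w; break; }
        absorbed += w * (1.0 - albedo[L]);
        w *= albedo[L];
        if (w <= 0) { break; }
        isotropic_dir(rng, d);
        for (int a = 0; a < 3; ++a)
          invd[a] = std::fabs(d[a]) > 1e-12 ? 1.0 / d[a] : 0.0;
        tau = -std::log(rng.u01());
        if (w < roulette_threshold) {
          if (rng.u01() < roulette_p) {
            roulette_net += w - w / roulette_p;
            w /= roulette_p;
          } else { roulette_net += w; break; }
        }
      } else {
        // traverse to the voxel face
        double s = dface;
        if (mt > 0) {
          if (record_fluence && trow[lin] >= 0) {
            int bin = (int)((t + 0.5 * s * n1 * inv_c) * inv_dt);
            if (bin >= 0 && bin < nt) flu(trow[lin], bin) += w * s;
          }
          tau -= mt * s;
          if (tau < 0) tau = 0;
        }
        for (int a = 0; a < 3; ++a) p[a] += s * d[a];
        t += s * n1 * inv_c;
        if (t > tmax) { cutoff += w; break; }
        // snap exactly onto the face
        int stepdir = d[kmin] > 0 ? 1 : -1;
        p[kmin] = (iv[kmin] + (stepdir > 0 ? 1 : 0)) * vx;
        int jn = iv[kmin] + stepdir;
        int nax = kmin == 0 ? nx : (kmin == 1 ? ny : nz);
        if (jn < 0 || jn >= nax) {
          // leaves the grid bounding box
          exited += w;
          if (det.active && entered_tissue && d[0] > 1e-12) {
            double tx = (det.x_plane - p[0]) / d[0];
            if (tx > -1e-9) {
              double yy = p[1] + tx * d[1];
              double zz = p[2] + tx * d[2];
              int jy = (int)std::floor((yy - det.y0) / det.pitch + 0.5);
              int jz = (int)std::floor((zz - det.z0) / det.pitch + 0.5);
              if (jy >= 0 && jy < det.ny && jz >= 0 && jz < det.nz) {
                double ta = t + std::max(0.0, tx) / C_MM_NS; // air, n = 1
                int bin = (int)(ta / dt_ns);
                if (bin >= 0 && bin < nt) {
                  dtpsf((size_t)jz * det.ny + jy, bin) += w;
                  detected += w;
                }
              }
            }
          }
          break;
        }
        int lin2 = lin + (kmin == 0 ? stepdir
                          : (kmin == 1 ? stepdir * nx : stepdir * nx * ny));
        double n2 = nref[lab[lin2]];
        if (n2 != n1) {
          // Fresnel at the axis-aligned face
          double ci = std::fabs(d[kmin]);
          double ratio = n1 / n2;
          double st2 = ratio * ratio * (1.0 - ci * ci);
          double R = 1.0, ct = 0.0;
          if (st2 < 1.0) {
            ct = std::sqrt(1.0 - st2);
            double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
            double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
            R = 0.5 * (rs * rs + rp * rp);
          }
          if (rng.u01() < R) {
            d[kmin] = -d[kmin]; // specular reflection, stay in current voxel
            invd[kmin] = -invd[kmin];
          } else {
            for (int a = 0; a < 3; ++a)
              if (a != kmin) d[a] *= ratio;
            d[kmin] = (d[kmin] > 0 ? 1.0 : -1.0) * ct;
            for (int a = 0; a < 3; ++a)
              invd[a] = std::fabs(d[a]) > 1e-12 ? 1.0 / d[a] : 0.0;
            iv[kmin] = jn;
          }
        } else {
          iv[kmin] = jn;
        }
      }
    }
  }

  const double nl = (double)n_photons;
  if (record_fluence) flu /= (nl * vx * vx * vx); // fluence per launched photon
  if (det.active) dtpsf /= nl;

  return List::create(
    _["fluence"] = record_fluence ? wrap(flu) : R_NilValue,
    _["det_tpsf"] = det.active ? wrap(dtpsf) : R_NilValue,
    _["tallies"] = NumericVector::create(
      _["launched"] = 1.0, _["absorbed"] = absorbed / nl,
      _["exited"] = exited / nl, _["cutoff"] = cutoff / nl,
      _["roulette_net"] = roulette_net / nl, _["detected"] = detected / nl));
}
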