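// Voxel Monte Carlo photon transport in a homogeneous slab.
//
// Weighted photon packets propagate by sampled free paths -ln(U)/mu_t,
// deposit fluence by the track-length estimator on a regular scoring grid,
// lose weight to absorption by implicit capture (w *= mu_s/mu_t per
// collision), scatter isotropically or by Henyey-Greenstein, and are
// terminated by Russian roulette below a weight threshold. Boundaries are
// refractive-index matched by default; an optional Fresnel mismatch applies
// unpolarized specular reflection at the six axis-aligned faces.
//
// Uses R's RNG stream (unif_rand) so runs are reproducible via set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tallies {
  double absorbed = 0.0;    // implicit-capture deposition
  double escaped = 0.0;     // weight leaving through any face
  double roulette_net = 0.0; // killed minus created weight
};

inline double runif_pos() {
  // avoid log(0)
  double u;
  do { u = unif_rand(); } while (u <= 0.0);
  return u;
}

// unpolarized Fresnel reflectance for cosine of incidence ci, indices ni->nt
inline double fresnel_R(double ci, double ni, double nt) {
  double si2 = 1.0 - ci * ci;
  double st2 = (ni / nt) * (ni / nt) * si2;
  if (st2 >= 1.0) return 1.0; // total internal reflection
  double ct = std::sqrt(1.0 - st2);
  double rs = (ni * ci - nt * ct) / (ni * ci + nt * ct);
  double rp = (ni * ct - nt * ci) / (ni * ct + nt * ci);
  return 0.5 * (rs * rs + rp * rp);
}

} // namespace

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(int n_packets,
                double lx, double ly, double lz,    // box dims (cm)
                int nx, int ny, int nz,             // scoring grid
                double mu_a, double mu_s, double g, // optical props (1/cm)
                double beam_radius,                 // cm
                int gaussian_profile,               // 0 flat, 1 gaussian
                double beam_sigma,                  // cm (gaussian width)
                double beam_trunc,                  // cm (gaussian cutoff)
                double n_rel,                       // tissue/ambient index
                double w_min, double p_survive) {
  const double mu_t = mu_a + mu_s;
  if (mu_t <= 0.0) stop("mu_a + mu_s must be positive");
  const double albedo = mu_s / mu_t;
  const double hx = lx / nx, hy = ly / ny, hz = lz / nz;
  const bool fresnel = n_rel != 1.0;

  std::vector<double> fluence((size_t)nx * ny * nz, 0.0);
  Tallies tal;

  RNGScope scope;

  const double sigma = beam_sigma;
  const double r_trunc = beam_trunc;

  for (int ip = 0; ip < n_packets; ++ip) {
    // launch position on the front face (z = 0), beam centred on axis
    double x, y;
    if (gaussian_profile) {
      do {
        x = norm_rand() * sigma;
        y = norm_rand() * sigma;
      } while (x * x + y * y > r_trunc * r_trunc);
    } else {
      double r2;
      do {
        x = (2.0 * unif_rand() - 1.0) * beam_radius;
        y = (2.0 * unif_rand() - 1.0) * beam_radius;
        r2 = x * x + y * y;
      } while (r2 > beam_radius * beam_radius);
    }
    double z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;

    if (fresnel) { // specular reflection entering at normal incidence
      double rsp = fresnel_R(1.0, 1.0, n_rel);
      tal.escaped += w * rsp;
      w *= (1.0 - rsp);
    }

    bool alive = true;
    while (alive) {
      double s = -std::log(runif_pos()) / mu_t; // free path (cm)

      // ray-march the step through the voxel grid (track-length estimator)
      while (s > 0.0) {
        int ix = (int)std::floor((x + lx / 2.0) / hx);
        int iy = (int)std::floor((y + ly / 2.0) / hy);
        int iz = (int)std::floor(z / hz);
        if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
        if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
        if (iz < 0) iz = 0; if (iz >= nz) iz = nz - 1;

        // distance to the next voxel boundary along the direction
        double dt = s;
        int face = -1; // 0:x 1:y 2:z, sign from direction
        if (ux > 0) {
          double b = -lx / 2.0 + (ix + 1) * hx;
          double d = (b - x) / ux;
          if (d < dt) { dt = d; face = 0; }
        } else if (ux < 0) {
          double b = -lx / 2.0 + ix * hx;
          double d = (b - x) / ux;
          if (d < dt) { dt = d; face = 0; }
        }
        if (uy > 0) {
          double b = -ly / 2.0 + (iy + 1) * hy;
          double d = (b - y) / uy;
          if (d < dt) { dt = d; face = 1; }
        } else if (uy < 0) {
          double b = -ly / 2.0 + iy * hy;
          double d = (b - y) / uy;
          if (d < dt) { dt = d; face = 1; }
        }
        if (uz > 0) {
          double b = (iz + 1) * hz;
          double d = (b - z) / uz;
          if (d < dt) { dt = d; face = 2; }
        } else if (uz < 0) {
          double b = iz * hz;
          double d = (b - z) / uz;
          if (d < dt) { dt = d; face = 2; }
        }
        if (dt < 0.0) dt = 0.0;

        fluence[(size_t)iz * nx * ny + (size_t)iy * nx + ix] += w * dt;

        x += ux * dt; y += uy * dt; z += uz * dt;
        s -= dt;
        if (face < 0) break; // interaction inside this voxel

        // nudge across the boundary so the next voxel lookup is unambiguous
        const double eps = 1e-9;
        x += ux * eps; y += uy * eps; z += uz * eps;

        if (x < -lx / 2.0 || x > lx / 2.0 || y < -ly / 2.0 ||
            y > ly / 2.0 || z < 0.0 || z > lz) {
          if (fresnel) {
            double ci = (face == 0) ? std::fabs(ux)
                      : (face == 1) ? std::fabs(uy) : std::fabs(uz);
            if (unif_rand() < fresnel_R(ci, n_rel, 1.0)) {
              // internally reflected: flip the normal component and
              // step back inside the box
              if (face == 0) ux = -ux;
              else if (face == 1) uy = -uy;
              else uz = -uz;
              x += ux * 2.0 * eps; y += uy * 2.0 * eps; z += uz * 2.0 * eps;
              continue;
            }
          }
          tal.escaped += w;
          alive = false;
          break;
        }
      }
      if (!alive) break;

      // interaction: implicit capture then scatter
      tal.absorbed += w * (mu_a / mu_t);
      w *= albedo;

      double ct; // cos of scattering angle
      if (g == 0.0) {
        ct = 2.0 * unif_rand() - 1.0;
      } else {
        double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
        ct = (1.0 + g * g - f * f) / (2.0 * g);
        if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
      }
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * unif_rand();
      double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = ct * (uz > 0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nuz = -st * cp * den + uz * ct;
        ux = nux; uy = nuy; uz = nuz;
      }
      // renormalize against drift
      double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
      ux /= norm; uy /= norm; uz /= norm;

      if (w < w_min) { // Russian roulette
        if (unif_rand() < p_survive) {
          tal.roulette_net -= w * (1.0 / p_survive - 1.0); // created
          w /= p_survive;
        } else {
          tal.roulette_net += w; // killed
          alive = false;
        }
      }
    }
  }

  NumericVector flu(fluence.begin(), fluence.end());
  flu.attr("dim") = IntegerVector::create(nx, ny, nz);
  return List::create(
    _["fluence_track_cm"] = flu,
    _["launched"] = (double)n_packets,
    _["absorbed"] = tal.absorbed,
    _["escaped"] = tal.escaped,
    _["roulette_net"] = tal.roulette_net);
}
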