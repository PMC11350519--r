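// Weighted-photon Monte Carlo transport in a layered semi-infinite medium.
// Geometry: planar layers stacked along +z (z = 0 is the top surface, z grows
// downward); pencil beam enters at the origin along +z. Diffuse reflectance is
// scored by exit radius into half-open annular bins [rho_i, rho_i + d_rho).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

inline std::uint64_t splitmix64(std::uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  std::uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xoshiro256+ — fast, well-tested generator; seeded via splitmix64 so that
// any 64-bit seed yields a well-mixed state.
struct Xoshiro256 {
  std::uint64_t s[4];
  explicit Xoshiro256(std::uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static inline std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline std::uint64_t next() {
    const std::uint64_t result = s[0] + s[3];
    const std::uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform on (0, 1] — safe argument for log()
  inline double unif_pos() { return 1.0 - unif(); }
};

// Unpolarized Fresnel reflectance for a photon hitting the top surface from
// inside (index n_in) with |cos| of the incidence angle ca, exiting into n_out.
inline double fresnel_reflectance(double ca, double n_in, double n_out) {
  if (n_in == n_out) return 0.0;
  double si = std::sqrt(std::max(0.0, 1.0 - ca * ca));
  double st = n_in / n_out * si;
  if (st >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (n_in * ca - n_out * ct) / (n_in * ca + n_out * ct);
  double rp = (n_in * ct - n_out * ca) / (n_in * ct + n_out * ca);
  return 0.5 * (rs * rs + rp * rp);
}

}  // namespace

// [[Rcpp::export(name = ".mc_transport")]]
List mc_transport(NumericVector mu_a, NumericVector mu_s, NumericVector g,
                  NumericVector n_layer, NumericVector thickness,
                  double ambient_n, double rho_min, double rho_max,
                  double d_rho, double n_photons, double seed,
                  double weight_threshold, double roulette_survival,
                  double max_interactions, bool matched_boundary,
                  double beam_radius) {
  const int L = mu_a.size();
  std::vector<double> mut(L), albedo(L), inv_mut(L), z_top(L), z_bot(L), gv(L);
  double z = 0.0;
  for (int l = 0; l < L; ++l) {
    mut[l] = mu_a[l] + mu_s[l];
    inv_mut[l] = 1.0 / mut[l];
    albedo[l] = mu_s[l] / mut[l];
    gv[l] = g[l];
    z_top[l] = z;
    z += thickness[l];
    z_bot[l] = (l == L - 1) ? R_PosInf : z;
  }

  const int nbins = (int)std::lround((rho_max - rho_min) / d_rho);
  std::vector<double> sumw(nbins, 0.0), sumw2(nbins, 0.0);
  std::vector<double> hits(nbins, 0.0);

  const double n0 = n_layer[0];
  const double specular = matched_boundary
      ? 0.0
      : std::pow((n0 - ambient_n) / (n0 + ambient_n), 2);

  double absorbed = 0.0, roulette_lost = 0.0, cap_lost = 0.0;
  double outside = 0.0, escaped = 0.0, total_interactions = 0.0;

  Xoshiro256 rng((std::uint64_t)(long long)seed);
  const long long N = (long long)n_photons;

  for (long long ph = 0; ph < N; ++ph) {
    double x = 0.0, y = 0.0, pz = 0.0;
    if (beam_radius > 0.0) {
      // flat-top beam: uniform over the disk of radius beam_radius
      double r = beam_radius * std::sqrt(rng.unif());
      double phi = 6.283185307179586476925287 * rng.unif();
      x = r * std::cos(phi);
      y = r * std::sin(phi);
    }
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - specular;
    int layer = 0;
    long long n_int = 0;
    bool alive = true;

    double step = -std::log(rng.unif_pos()) * inv_mut[layer];

    while (alive) {
      // propagate, handling layer/surface crossings
      for (;;) {
        double db;
        if (uz > 0.0)      db = (z_bot[layer] - pz) / uz;
        else if (uz < 0.0) db = (z_top[layer] - pz) / uz;  // positive
        else               db = R_PosInf;
        if (step <= db) {
          x += step * ux; y += step * uy; pz += step * uz;
          break;  // interaction inside current layer
        }
        x += db * ux; y += db * uy;
        step -= db;
        if (uz < 0.0) {
          pz = z_top[layer];
          if (layer == 0) {
            // top surface: probabilistic Fresnel reflect-or-escape
            double R = matched_boundary ? 0.0
                                        : fresnel_reflectance(-uz, n0, ambient_n);
            if (R > 0.0 && rng.unif() < R) {
              uz = -uz;  // specularly reflected back inside
            } else {
              double r = std::sqrt(x * x + y * y);
              escaped += w;
              double b = (r - rho_min) / d_rho;
              if (b >= 0.0 && b < (double)nbins) {
                int bi = (int)b;
                sumw[bi] += w; sumw2[bi] += w * w; hits[bi] += 1.0;
              } else {
                outside += w;
              }
              alive = false;
              break;
            }
          } else {
            // internal interface, index-matched: rescale remaining optical depth
            step *= mut[layer] * inv_mut[layer - 1];
            --layer;
          }
        } else {
          pz = z_bot[layer];
          step *= mut[layer] * inv_mut[layer + 1];
          ++layer;
        }
      }
      if (!alive) break;

      // interaction: deposit weight, then scatter
      absorbed += w * (1.0 - albedo[layer]);
      w *= albedo[layer];
      ++n_int;

      if (n_int >= (long long)max_interactions) {
        cap_lost += w;
        break;
      }
      if (w < weight_threshold) {
        if (rng.unif() < roulette_survival) {
          // injected weight is booked against the roulette ledger so that
          // the energy audit closes exactly, not just in expectation
          double w_new = w / roulette_survival;
          roulette_lost -= (w_new - w);
          w = w_new;
        } else {
          roulette_lost += w;
          break;
        }
      }

      // Henyey-Greenstein deflection
      const double gl = gv[layer];
      double cost;
      if (gl == 0.0) {
        cost = 2.0 * rng.unif() - 1.0;
      } else {
        double t = (1.0 - gl * gl) / (1.0 - gl + 2.0 * gl * rng.unif());
        cost = (1.0 + gl * gl - t * t) / (2.0 * gl);
        if (cost > 1.0) cost = 1.0; else if (cost < -1.0) cost = -1.0;
      }
      double sint = std::sqrt(1.0 - cost * cost);
      // azimuth via Marsaglia rejection: uniform angle without trig calls
      double cosp, sinp;
      for (;;) {
        double a = 2.0 * rng.unif() - 1.0;
        double b = 2.0 * rng.unif() - 1.0;
        double s2 = a * a + b * b;
        if (s2 > 0.0 && s2 < 1.0) {
          double inv = 1.0 / s2;
          cosp = (a * a - b * b) * inv;
          sinp = 2.0 * a * b * inv;
          break;
        }
      }

      if (std::fabs(uz) > 0.99999) {
        ux = sint * cosp;
        uy = sint * sinp;
        uz = cost * (uz >= 0.0 ? 1.0 : -1.0);
      } else {
        double tmp = std::sqrt(1.0 - uz * uz);
        double nux = sint * (ux * uz * cosp - uy * sinp) / tmp + ux * cost;
        double nuy = sint * (uy * uz * cosp + ux * sinp) / tmp + uy * cost;
        double nuz = -sint * cosp * tmp + uz * cost;
        ux = nux; uy = nuy; uz = nuz;
      }

      step = -std::log(rng.unif_pos()) * inv_mut[layer];
      total_interactions += 1.0;
    }
  }

  return List::create(
      _["sum_w"] = NumericVector(sumw.begin(), sumw.end()),
      _["sum_w2"] = NumericVector(sumw2.begin(), sumw2.end()),
      _["hits"] = NumericVector(hits.begin(), hits.end()),
      _["specular"] = specular * (double)N,
      _["absorbed"] = absorbed,
      _["roulette_lost"] = roulette_lost,
      _["cap_lost"] = cap_lost,
      _["outside"] = outside,
      _["escaped"] = escaped,
      _["interactions"] = total_interactions);
}
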