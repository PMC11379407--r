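#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// speed of light, mm/ns
static const double C_MM_NS = 299.792458;

// --- xoshiro256++ PRNG (deterministic across platforms, independent of R's stream) ---
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0,1)
  inline double unif_pos() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
};

// Scattering deflection sampler: closed-form Henyey-Greenstein or a tabulated
// inverse CDF on a regular CDF grid dc, 2*dc, ..., n*dc (user-defined SPF).
struct SpfSampler {
  int mode;  // 0 = stHG closed form, 1 = inverse-CDF table
  double g;
  const double *tab;
  int ntab;
  double dc;
  inline double sample(Xoshiro &rng) const {
    double u = rng.unif();
    double ct;
    if (mode == 0) {
      if (std::fabs(g) < 1e-12) {
        ct = 2.0 * u - 1.0;
      } else {
        double s = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
        ct = (1.0 + g * g - s * s) / (2.0 * g);
      }
    } else {
      double k = u / dc;  // fractional index into CDF grid (1-based)
      if (k <= 1.0) {
        ct = tab[0];
      } else if (k >= (double)ntab) {
        ct = tab[ntab - 1];
      } else {
        int k0 = (int)k;
        double f = k - k0;
        ct = tab[k0 - 1] * (1.0 - f) + tab[k0] * f;
      }
    }
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    return ct;
  }
};

// Unpolarized Fresnel reflection coefficient, incidence from n1 into n2.
static inline double fresnel_R(double n1, double n2, double cosi) {
  if (std::fabs(n1 - n2) < 1e-12) return 0.0;
  double sini2 = 1.0 - cosi * cosi;
  if (sini2 < 0.0) sini2 = 0.0;
  double sint = n1 / n2 * std::sqrt(sini2);
  if (sint >= 1.0) return 1.0;  // total internal reflection
  double cost = std::sqrt(1.0 - sint * sint);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

// Rotate direction (ux,uy,uz) by deflection cos(theta)=ct and azimuth phi.
static inline void spin(double &ux, double &uy, double &uz, double ct, double phi) {
  double st2 = 1.0 - ct * ct;
  double st = st2 > 0.0 ? std::sqrt(st2) : 0.0;
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = (uz >= 0.0 ? ct : -ct);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    double nz = -den * st * cp + uz * ct;
    double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
    ux = nx / nrm;
    uy = ny / nrm;
    uz = nz / nrm;
  }
}

static inline double wrap(double x, double period) {
  x -= std::floor(x / period) * period;
  if (x >= period) x -= period;  // guard against rounding at the edge
  return x;
}

// Core transport loop. Medium occupies 0 <= z <= thickness (thickness <= 0 means
// a semi-infinite half-space). Photons launched at z = 0 travelling +z.
//
// source: 0 pencil at origin; 1 uniform disc of diameter `beam`; 2 sinusoid
//         0.5*(1 + cos(2*pi*fx*x + phase)) over x in [0, lx).
// Lateral boundaries cyclic with periods lx, ly when > 0.
// Absorption handled by survival-weight deposition at scattering events.
//
// [[Rcpp::export]]
List cpp_transport(double mua, double mus, double n_med, double n_out,
                   double t_max, double thickness, int n_photons, double seed,
                   int spf_mode, double g, NumericVector spf_table, double spf_dc,
                   int source, double beam, double fx, double phase,
                   double lx, double ly, int profile_bins, bool keep_records,
                   double roulette_s0) {
  Xoshiro rng((uint64_t)seed);
  SpfSampler spf{spf_mode, g, spf_table.begin(), (int)spf_table.size(), spf_dc};

  const double mut = mua + mus;
  const double albedo = mut > 0.0 ? mus / mut : 0.0;
  const double frac_abs = mut > 0.0 ? mua / mut : 0.0;
  const double path_max = t_max * C_MM_NS / n_med;
  const bool semi_inf = thickness <= 0.0;
  const double rsp = fresnel_R(n_out, n_med, 1.0);  // specular at normal entry

  double w_specular = 0.0, w_top = 0.0, w_bottom = 0.0, w_abs = 0.0, w_inflight = 0.0;
  // Path-stretching roulette: past a path of roulette_s0 (mm), photons pass
  // survival checkpoints at s0*2^k with p = 1/2 and doubled weight. Unbiased;
  // the net killed-minus-gained weight is tracked so the ledger stays exact.
  double w_killed = 0.0, w_gained = 0.0;
  long n_dropped = 0;

  std::vector<double> rec_r, rec_t, rec_w;
  if (keep_records) {
    rec_r.reserve(n_photons);
    rec_t.reserve(n_photons);
    rec_w.reserve(n_photons);
  }
  NumericVector profile(profile_bins > 0 ? profile_bins : 1);

  for (int i = 0; i < n_photons; ++i) {
    double x = 0.0, y = 0.0, z = 0.0;
    if (source == 1) {  // uniform disc
      double r = 0.5 * beam * std::sqrt(rng.unif());
      double a = 2.0 * M_PI * rng.unif();
      x = r * std::cos(a);
      y = r * std::sin(a);
      if (lx > 0.0) x = wrap(x, lx);
      if (ly > 0.0) y = wrap(y, ly);
    } else if (source == 2) {  // sinusoidal pattern, rejection from envelope 1
      for (;;) {
        double xc = rng.unif() * lx;
        double acc = 0.5 * (1.0 + std::cos(2.0 * M_PI * fx * xc + phase));
        if (rng.unif() < acc) { x = xc; break; }
      }
      y = rng.unif() * ly;
    }
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - rsp;
    w_specular += rsp;
    double path = 0.0;
    double next_roulette = roulette_s0 > 0.0 ? roulette_s0 : 1e300;
    bool alive = true;

    while (alive) {
      double step = mut > 0.0 ? -std::log(rng.unif_pos()) / mut : 1e30;
      // propagate `step`, handling z-boundary crossings
      while (step > 0.0 && alive) {
        double db = 1e30;
        bool to_top = false;
        if (uz < 0.0) {
          db = -z / uz;
          to_top = true;
        } else if (uz > 0.0 && !semi_inf) {
          db = (thickness - z) / uz;
        }
        double d = step < db ? step : db;
        if (path + d > path_max) {  // time cap reached mid-flight
          w_inflight += w;
          ++n_dropped;
          alive = false;
          break;
        }
        x += ux * d;
        y += uy * d;
        z += uz * d;
        path += d;
        if (lx > 0.0) x = wrap(x, lx);
        if (ly > 0.0) y = wrap(y, ly);
        if (step < db) {  // interaction point inside medium
          step = 0.0;
          if (mut <= 0.0) {  // clear medium, no boundary reachable
            w_inflight += w;
            ++n_dropped;
            alive = false;
          }
        } else {  // at a z boundary
          step -= db;
          double cosi = std::fabs(uz);
          double R = fresnel_R(n_med, n_out, cosi);
          if (rng.unif() >= R) {  // escape
            if (to_top) {
              w_top += w;
              if (keep_records) {
                rec_r.push_back(std::sqrt(x * x + y * y));
                rec_t.push_back(path * n_med / C_MM_NS);
                rec_w.push_back(w);
              }
              if (profile_bins > 0) {
                int b = (int)(x / lx * profile_bins);
                if (b < 0) b = 0;
                if (b >= profile_bins) b = profile_bins - 1;
                profile[b] += w;
              }
            } else {
              w_bottom += w;
            }
            alive = false;
          } else {  // internal reflection
            uz = -uz;
            z = to_top ? 0.0 : thickness;
          }
        }
      }
      if (!alive) break;
      while (path > next_roulette) {  // survival checkpoint
        if (rng.unif() < 0.5) {
          w_gained += w;
          w *= 2.0;
        } else {
          w_killed += w;
          alive = false;
        }
        next_roulette *= 2.0;
        if (!alive) break;
      }
      if (!alive) break;
      // scattering event: deposit absorbed weight, then spin
      if (frac_abs > 0.0) {
        w_abs += w * frac_abs;
        w *= albedo;
        if (w < 1e-12) {  // exhausted weight stays in the absorbed ledger
          w_abs += w;
          break;
        }
      }
      double ct = spf.sample(rng);
      double phi = 2.0 * M_PI * rng.unif();
      spin(ux, uy, uz, ct, phi);
    }
  }

  List out = List::create(
      _["specular"] = w_specular / n_photons, _["refl_top"] = w_top / n_photons,
      _["trans_bottom"] = w_bottom / n_photons, _["absorbed"] = w_abs / n_photons,
      _["inflight"] = w_inflight / n_photons, _["n_dropped"] = n_dropped,
      _["roulette_net"] = (w_killed - w_gained) / n_photons,
      _["n_photons"] = n_photons);
  if (keep_records) {
    out["radius"] = NumericVector(rec_r.begin(), rec_r.end());
    out["time_of_flight"] = NumericVector(rec_t.begin(), rec_t.end());
    out["weight"] = NumericVector(rec_w.begin(), rec_w.end());
  }
  if (profile_bins > 0) out["profile"] = profile;
  return out;
}
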