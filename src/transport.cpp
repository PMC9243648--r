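#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

// Uniform doubles in [0, 1) from the top 53 bits of a Mersenne 64-bit stream;
// independent of R's RNG so results are bit-reproducible for a given seed.
class Rng64 {
  std::mt19937_64 gen;
public:
  explicit Rng64(uint64_t seed) : gen(seed) {}
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  double unif_open() { return 1.0 - unif(); }  // (0, 1], safe for log()
};

struct Layer {
  double z0, z1, mua, mus, mut, g, n;
};

static inline double fresnel_unpolarized(double ni, double nt, double ci,
                                         double &ct) {
  if (ni == nt) { ct = ci; return 0.0; }
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = ni / nt * si;
  if (st >= 1.0) return 1.0;  // total internal reflection
  ct = std::sqrt(1.0 - st * st);
  double rs = (ni * ci - nt * ct) / (ni * ci + nt * ct);
  double rp = (ni * ct - nt * ci) / (ni * ct + nt * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Weighted-packet transport through a layered slab with cylindrical symmetry.
// layers: matrix with columns d, mua, mus, g, n (top to bottom; last d may be Inf).
// Returns totals per incident packet plus raw exit radii/weights at the top
// surface so detection annuli can be formed without binning loss.
// [[Rcpp::export(name = ".mc_transport")]]
List mc_transport(NumericMatrix layers, double n_above, double n_below,
                  int n_packets, double seed, double roulette_threshold,
                  int roulette_m) {
  const int nl = layers.nrow();
  std::vector<Layer> lay(nl);
  double z = 0.0;
  for (int i = 0; i < nl; ++i) {
    lay[i].z0 = z;
    double d = layers(i, 0);
    lay[i].z1 = std::isfinite(d) ? z + d : std::numeric_limits<double>::infinity();
    z = lay[i].z1;
    lay[i].mua = layers(i, 1);
    lay[i].mus = layers(i, 2);
    lay[i].mut = lay[i].mua + lay[i].mus;
    lay[i].g = layers(i, 3);
    lay[i].n = layers(i, 4);
  }

  Rng64 rng(static_cast<uint64_t>(seed));

  const double n1 = lay[0].n;
  double rsp = 0.0;
  if (n_above != n1) {
    double t = (n_above - n1) / (n_above + n1);
    rsp = t * t;
  }

  double rd = 0.0, tt = 0.0, aa = 0.0, rnet = 0.0;
  std::vector<double> exit_r, exit_w;
  exit_r.reserve(n_packets / 4 + 16);
  exit_w.reserve(n_packets / 4 + 16);
  const double inv_m = 1.0 / roulette_m;

  for (int ip = 0; ip < n_packets; ++ip) {
    if ((ip & 0xFFF) == 0) Rcpp::checkUserInterrupt();
    double x = 0.0, y = 0.0, zz = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - rsp;
    int L = 0;
    double sleft = 0.0;
    bool alive = true;

    while (alive) {
      const Layer &la = lay[L];
      if (sleft <= 0.0) sleft = -std::log(rng.unif_open());
      double s = (la.mut > 0.0) ? sleft / la.mut
                                : std::numeric_limits<double>::infinity();
      double db;
      if (uz > 0.0)      db = (la.z1 - zz) / uz;
      else if (uz < 0.0) db = (la.z0 - zz) / uz;
      else               db = std::numeric_limits<double>::infinity();

      if (db <= s) {
        // hit a layer boundary before the next interaction
        x += ux * db; y += uy * db; zz += uz * db;
        sleft -= db * la.mut;
        if (sleft < 0.0) sleft = 0.0;
        bool up = uz < 0.0;
        double ni = la.n;
        double nt;
        if (up)  nt = (L == 0) ? n_above : lay[L - 1].n;
        else     nt = (L == nl - 1) ? n_below : lay[L + 1].n;
        double ci = std::fabs(uz), ct = 0.0;
        double R = fresnel_unpolarized(ni, nt, ci, ct);
        if (rng.unif() < R) {
          uz = -uz;  // internally reflected
          zz = up ? la.z0 : la.z1;
        } else if (up && L == 0) {
          double r = std::sqrt(x * x + y * y);
          exit_r.push_back(r);
          exit_w.push_back(w);
          rd += w;
          alive = false;
        } else if (!up && L == nl - 1) {
          tt += w;  // transmitted through a finite bottom layer
          alive = false;
        } else {
          double f = ni / nt;
          ux *= f; uy *= f;
          uz = up ? -ct : ct;
          L += up ? -1 : 1;
        }
      } else {
        // interaction site: deposit, then scatter
        x += ux * s; y += uy * s; zz += uz * s;
        sleft = 0.0;
        double dw = w * la.mua / la.mut;
        aa += dw;
        w -= dw;
        if (w <= 0.0) { alive = false; continue; }

        double cth;
        if (la.g != 0.0) {
          double t = (1.0 - la.g * la.g) / (1.0 - la.g + 2.0 * la.g * rng.unif());
          cth = (1.0 + la.g * la.g - t * t) / (2.0 * la.g);
          if (cth > 1.0) cth = 1.0;
          if (cth < -1.0) cth = -1.0;
        } else {
          cth = 2.0 * rng.unif() - 1.0;
        }
        double sth = std::sqrt(1.0 - cth * cth);
        double phi = 2.0 * M_PI * rng.unif();
        double cp = std::cos(phi), sp = std::sin(phi);
        if (std::fabs(uz) > 0.99999) {
          ux = sth * cp;
          uy = sth * sp;
          uz = (uz >= 0.0) ? cth : -cth;
        } else {
          double tmp = std::sqrt(1.0 - uz * uz);
          double nux = sth * (ux * uz * cp - uy * sp) / tmp + ux * cth;
          double nuy = sth * (uy * uz * cp + ux * sp) / tmp + uy * cth;
          double nuz = -sth * cp * tmp + uz * cth;
          ux = nux; uy = nuy; uz = nuz;
        }

        if (w < roulette_threshold) {
          if (rng.unif() < inv_m) {
            rnet -= (roulette_m - 1.0) * w;  // weight created on survival
            w *= roulette_m;
          } else {
            rnet += w;  // weight destroyed on termination
            alive = false;
          }
        }
      }
    }
  }

  double N = static_cast<double>(n_packets);
  return List::create(
      _["rsp"] = rsp,
      _["rd"] = rd / N,
      _["tt"] = tt / N,
      _["aa"] = aa / N,
      _["roulette_net"] = rnet / N,
      _["exit_r"] = NumericVector(exit_r.begin(), exit_r.end()),
      _["exit_w"] = NumericVector(exit_w.begin(), exit_w.end()));
}
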