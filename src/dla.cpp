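#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// On-lattice diffusion-limited aggregation.
//
// Walkers are launched on a circle (2D) or sphere (3D) of radius
// R_cluster + 5, take unit lattice steps near the cluster and long radial
// jumps when far from it (which cannot skip a sticking event, since
// sticking requires lattice adjacency), stick on first lattice-neighbor
// contact, and are relaunched when they wander past 3x the launch radius.
// Randomness comes from the R RNG, so results are reproducible under
// set.seed().

static inline double runifd() { return unif_rand(); }

// [[Rcpp::export(name = ".dla2d")]]
IntegerMatrix dla2d(int n) {
  if (n < 1) stop("n must be positive");
  int half = (int)std::ceil(std::pow((double)n, 1.0 / 1.6)) + 10;
  int G = 2 * half + 1;
  std::vector<unsigned char> occ((size_t)G * G, 0);
  IntegerMatrix out(n, 2);
  auto at = [&](int x, int y) -> unsigned char& {
    return occ[(size_t)(y + half) * G + (x + half)];
  };
  auto nearCluster = [&](int x, int y) {
    return at(x + 1, y) || at(x - 1, y) || at(x, y + 1) || at(x, y - 1);
  };
  at(0, 0) = 1; out(0, 0) = 0; out(0, 1) = 0;
  double rc = 0.0;  // current cluster radius
  for (int i = 1; i < n; ++i) {
    bool placed = false;
    while (!placed) {
      double rl = rc + 5.0, rkill = 3.0 * rl;
      double th = 2.0 * M_PI * runifd();
      double xd = rl * std::cos(th), yd = rl * std::sin(th);
      int x = (int)std::lround(xd), y = (int)std::lround(yd);
      while (true) {
        double r = std::sqrt((double)x * x + (double)y * y);
        if (r > rkill) break;  // killed; relaunch
        if (std::abs(x) >= half - 1 || std::abs(y) >= half - 1) break;
        if (nearCluster(x, y)) {
          at(x, y) = 1;
          out(i, 0) = x; out(i, 1) = y;
          double rr = std::sqrt((double)x * x + (double)y * y);
          if (rr > rc) rc = rr;
          placed = true;
          break;
        }
        if (r > rc + 7.0) {  // long jump towards the action zone
          double jump = r - rc - 5.0;
          double ph = 2.0 * M_PI * runifd();
          x = (int)std::lround(x + jump * std::cos(ph));
          y = (int)std::lround(y + jump * std::sin(ph));
        } else {
          double u = runifd();
          if (u < 0.25) ++x; else if (u < 0.5) --x;
          else if (u < 0.75) ++y; else --y;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".dla3d")]]
IntegerMatrix dla3d(int n) {
  if (n < 1) stop("n must be positive");
  int half = (int)std::ceil(std::pow((double)n, 1.0 / 2.2)) + 10;
  int G = 2 * half + 1;
  std::vector<unsigned char> occ((size_t)G * G * G, 0);
  IntegerMatrix out(n, 3);
  auto at = [&](int x, int y, int z) -> unsigned char& {
    return occ[((size_t)(z + half) * G + (y + half)) * G + (x + half)];
  };
  auto nearCluster = [&](int x, int y, int z) {
    return at(x + 1, y, z) || at(x - 1, y, z) || at(x, y + 1, z) ||
           at(x, y - 1, z) || at(x, y, z + 1) || at(x, y, z - 1);
  };
  at(0, 0, 0) = 1;
  double rc = 0.0;
  for (int i = 1; i < n; ++i) {
    bool placed = false;
    while (!placed) {
      double rl = rc + 5.0, rkill = 3.0 * rl;
      // uniform direction on the sphere
      double z0 = 2.0 * runifd() - 1.0;
      double ph0 = 2.0 * M_PI * runifd();
      double s0 = std::sqrt(1.0 - z0 * z0);
      int x = (int)std::lround(rl * s0 * std::cos(ph0));
      int y = (int)std::lround(rl * s0 * std::sin(ph0));
      int z = (int)std::lround(rl * z0);
      while (true) {
        double r = std::sqrt((double)x * x + (double)y * y + (double)z * z);
        if (r > rkill) break;
        if (std::abs(x) >= half - 1 || std::abs(y) >= half - 1 ||
            std::abs(z) >= half - 1) break;
        if (nearCluster(x, y, z)) {
          at(x, y, z) = 1;
          out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
          double rr = std::sqrt((double)x * x + (double)y * y +
                                (double)z * z);
          if (rr > rc) rc = rr;
          placed = true;
          break;
        }
        if (r > rc + 7.0) {
          double jump = r - rc - 5.0;
          double zj = 2.0 * runifd() - 1.0;
          double pj = 2.0 * M_PI * runifd();
          double sj = std::sqrt(1.0 - zj * zj);
          x = (int)std::lround(x + jump * sj * std::cos(pj));
          y = (int)std::lround(y + jump * sj * std::sin(pj));
          z = (int)std::lround(z + jump * zj);
        } else {
          double u = runifd();
          if (u < 1.0 / 6) ++x; else if (u < 2.0 / 6) --x;
          else if (u < 3.0 / 6) ++y; else if (u < 4.0 / 6) --y;
          else if (u < 5.0 / 6) ++z; else --z;
        }
      }
    }
  }
  return out;
}
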