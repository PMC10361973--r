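// Core stepper of the stochastic discrete mesoscopic tumor simulator.
//
// State: two integer fields (cells of the less aggressive and the more
// aggressive clonal population) on an L^3 voxel lattice with per-voxel
// carrying capacity K. Per step and voxel, division / death / migration
// outcomes for each whole clonal population are drawn from binomial
// distributions (one Bernoulli trial per cell), all probabilities computed
// from the pre-step state; updates land in staging buffers and are swapped in
// synchronously. Boundaries are closed (no-flux): migrants headed off-lattice
// stay in their source voxel, and migrants whose destination is at capacity
// are returned to the source, so migration conserves cell number exactly and
// no voxel ever exceeds K.

#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <cmath>
using namespace Rcpp;

static inline int rbin(int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  return static_cast<int>(R::rbinom(static_cast<double>(n), p));
}

struct Migrant {
  int dest;
  int src;
  int pop;
  int cnt;
};

// [[Rcpp::export]]
List meso_advance(IntegerVector pop1, IntegerVector pop2, int L, double K,
                  int nsteps, double pdiv1, double pdiv2, double pdeath,
                  double pmig1, double pmig2, IntegerVector bbox,
                  bool track_max) {
  const int n = L * L * L;
  if (pop1.size() != n || pop2.size() != n)
    stop("population arrays do not match lattice size");
  std::vector<int> cur1(pop1.begin(), pop1.end());
  std::vector<int> cur2(pop2.begin(), pop2.end());
  std::vector<int> new1(n, 0), new2(n, 0);

  int x0 = bbox[0], x1 = bbox[1], y0 = bbox[2], y1 = bbox[3],
      z0 = bbox[4], z1 = bbox[5];

  NumericVector tot1(nsteps), tot2(nsteps), maxvox(nsteps);
  std::vector<Migrant> queue;
  queue.reserve(4096);

  const int Ki = static_cast<int>(K);
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};

  for (int step = 0; step < nsteps; ++step) {
    std::memset(new1.data(), 0, sizeof(int) * n);
    std::memset(new2.data(), 0, sizeof(int) * n);
    queue.clear();
    double s1 = 0.0, s2 = 0.0;
    int nx0 = x0, nx1 = x1, ny0 = y0, ny1 = y1, nz0 = z0, nz1 = z1;

    for (int z = z0; z <= z1; ++z) {
      for (int y = y0; y <= y1; ++y) {
        const int rowbase = L * (y + L * z);
        for (int x = x0; x <= x1; ++x) {
          const int idx = x + rowbase;
          const int n1 = cur1[idx], n2 = cur2[idx];
          const int ntot = n1 + n2;
          if (ntot == 0) continue;

          double f = 1.0 - ntot / K;  // free-space brake on division
          if (f < 0.0) f = 0.0;
          double pd = pdeath * ntot / K;  // crowding-driven death
          if (pd > 1.0) pd = 1.0;

          int a1 = 0, a2 = 0;
          if (n1 > 0) {
            a1 = n1 + rbin(n1, pdiv1 * f) - rbin(n1, pd);
            if (a1 < 0) a1 = 0;
          }
          if (n2 > 0) {
            a2 = n2 + rbin(n2, pdiv2 * f) - rbin(n2, pd);
            if (a2 < 0) a2 = 0;
          }
          // division cannot push a voxel beyond capacity: trim the overshoot
          // proportionally between the populations
          if (a1 + a2 > Ki) {
            int excess = a1 + a2 - Ki;
            int r1 = static_cast<int>(
                std::lround(static_cast<double>(excess) * a1 / (a1 + a2)));
            if (r1 > a1) r1 = a1;
            int r2 = excess - r1;
            if (r2 > a2) { r1 += r2 - a2; r2 = a2; }
            a1 -= r1;
            a2 -= r2;
          }

          for (int pop = 0; pop < 2; ++pop) {
            const int a = (pop == 0) ? a1 : a2;
            if (a == 0) continue;
            const double pm = (pop == 0) ? pmig1 : pmig2;
            std::vector<int>& dst = (pop == 0) ? new1 : new2;
            int M = rbin(a, pm);
            dst[idx] += a - M;
            // split the migrants uniformly over the 6 face neighbors
            // (conditional binomials for large M, per-migrant uniform
            // directions for small M; both are the exact multinomial)
            int md[6] = {0, 0, 0, 0, 0, 0};
            if (M > 8) {
              int rem = M;
              for (int d = 0; d < 5 && rem > 0; ++d) {
                md[d] = rbin(rem, 1.0 / (6 - d));
                rem -= md[d];
              }
              md[5] = rem;
            } else {
              for (int k = 0; k < M; ++k) {
                int d = static_cast<int>(unif_rand() * 6.0);
                if (d > 5) d = 5;
                ++md[d];
              }
            }
            for (int d = 0; d < 6; ++d) {
              const int m = md[d];
              if (m == 0) continue;
              const int wx = x + dx[d], wy = y + dy[d], wz = z + dz[d];
              if (wx < 0 || wx >= L || wy < 0 || wy >= L ||
                  wz < 0 || wz >= L) {
                dst[idx] += m;  // no-flux boundary: stay put
              } else {
                queue.push_back({wx + L * (wy + L * wz), idx, pop, m});
              }
            }
          }
        }
      }
    }

    // place migrants against staged occupancy; overflow returns to source
    for (const Migrant& q : queue) {
      int room = Ki - new1[q.dest] - new2[q.dest];
      if (room < 0) room = 0;
      int acc = (q.cnt < room) ? q.cnt : room;
      std::vector<int>& dst = (q.pop == 0) ? new1 : new2;
      dst[q.dest] += acc;
      dst[q.src] += q.cnt - acc;
      if (acc > 0) {
        const int wz = q.dest / (L * L);
        const int wy = (q.dest / L) % L;
        const int wx = q.dest % L;
        if (wx < nx0) nx0 = wx;
        if (wx > nx1) nx1 = wx;
        if (wy < ny0) ny0 = wy;
        if (wy > ny1) ny1 = wy;
        if (wz < nz0) nz0 = wz;
        if (wz > nz1) nz1 = wz;
      }
    }

    x0 = nx0; x1 = nx1; y0 = ny0; y1 = ny1; z0 = nz0; z1 = nz1;
    cur1.swap(new1);
    cur2.swap(new2);

    int mx = 0;
    for (int z = z0; z <= z1; ++z) {
      for (int y = y0; y <= y1; ++y) {
        const int rowbase = L * (y + L * z);
        for (int x = x0; x <= x1; ++x) {
          const int idx = x + rowbase;
          s1 += cur1[idx];
          s2 += cur2[idx];
          if (track_max) {
            const int tot = cur1[idx] + cur2[idx];
            if (tot > mx) mx = tot;
          }
        }
      }
    }
    tot1[step] = s1;
    tot2[step] = s2;
    maxvox[step] = mx;
  }

  IntegerVector out1(cur1.begin(), cur1.end());
  IntegerVector out2(cur2.begin(), cur2.end());
  IntegerVector obox = IntegerVector::create(x0, x1, y0, y1, z0, z1);
  return List::create(_["pop1"] = out1, _["pop2"] = out2, _["tot1"] = tot1,
                      _["tot2"] = tot2, _["maxvox"] = maxvox,
                      _["bbox"] = obox);
}
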