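// Volume-exclusion bead-chain sampler for the Rabl-like orientation.
//
// Chromosomes are chains of impenetrable beads confined to a spherical
// nucleus; centromere beads are tethered to a capture sphere at the spindle
// pole body, telomere beads to a peripheral shell, and rDNA beads to a
// nucleolar spherical cap opposite the SPB (non-rDNA beads are excluded
// from it). Structures are generated by randomized chain growth from the
// centromere outward followed by iterative constraint projection
// (position-based dynamics): bond clamping, tether projection, pairwise
// overlap resolution on a cell grid, repeated until no violation remains.
// All randomness comes from a self-contained 64-bit generator, so a given
// seed yields bitwise-identical coordinates on any platform.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  void sphere_dir(double* d) { // uniform direction
    double u = 2.0 * unif() - 1.0, phi = 2.0 * M_PI * unif();
    double r = std::sqrt(std::max(0.0, 1.0 - u * u));
    d[0] = r * std::cos(phi); d[1] = r * std::sin(phi); d[2] = u;
  }
};

struct Params {
  double R;            // nuclear radius (scaled)
  double cap_cx;       // centromere capture sphere center on +x axis
  double cap_r;        // capture sphere radius
  double shell;        // telomere shell thickness
  double nuc_plane;    // nucleolar cap plane: cap = { x <= nuc_plane }
  bool has_nucleolus;
  double diam;         // bead diameter
  double bond_min, bond_max;
  double overlap_tol, region_tol;
  double anchor_sigma_scale;
  int max_iter;
};

Params read_params(List p) {
  Params q;
  q.R = p["nuclear_radius"];
  q.cap_cx = p["cap_cx"];
  q.cap_r = p["cap_radius"];
  q.shell = p["shell_thickness"];
  q.nuc_plane = p["nucleolus_plane"];
  q.has_nucleolus = p["has_nucleolus"];
  q.diam = p["bead_diameter"];
  q.bond_min = p["bond_min"];
  q.bond_max = p["bond_max"];
  q.overlap_tol = p["overlap_tolerance"];
  q.region_tol = p["region_tolerance"];
  q.anchor_sigma_scale = p["anchor_sigma_scale"];
  q.max_iter = p["max_iterations"];
  return q;
}

inline double dist3(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// uniform grid for neighbour queries
struct Grid {
  double cell, R;
  int n;                       // cells per axis
  std::vector<int> head, nxt;
  Grid(double cell_, double R_, int nbeads) : cell(cell_), R(R_) {
    n = (int)std::ceil(2.0 * R / cell) + 2;
    head.assign((size_t)n * n * n, -1);
    nxt.assign(nbeads, -1);
  }
  inline int cidx(double v) const {
    int i = (int)std::floor((v + R) / cell) + 1;
    if (i < 0) i = 0; if (i >= n) i = n - 1;
    return i;
  }
  inline size_t cell_of(const double* x) const {
    return ((size_t)cidx(x[0]) * n + cidx(x[1])) * n + cidx(x[2]);
  }
  void insert(const double* x, int i) {
    size_t c = cell_of(x);
    nxt[i] = head[c];
    head[c] = i;
  }
  // any already-inserted bead closer than dmin to x (excluding bead `skip`)?
  bool crowded(const std::vector<double>& pos, const double* x, double dmin,
               int skip) const {
    int cx = cidx(x[0]), cy = cidx(x[1]), cz = cidx(x[2]);
    for (int ox = -1; ox <= 1; ++ox)
      for (int oy = -1; oy <= 1; ++oy)
        for (int oz = -1; oz <= 1; ++oz) {
          int nx = cx + ox, ny = cy + oy, nz = cz + oz;
          if (nx < 0 || ny < 0 || nz < 0 || nx >= n || ny >= n || nz >= n)
            continue;
          for (int j = head[((size_t)nx * n + ny) * n + nz]; j != -1;
               j = nxt[j]) {
            if (j == skip) continue;
            double dx = pos[3 * j] - x[0], dy = pos[3 * j + 1] - x[1],
                   dz = pos[3 * j + 2] - x[2];
            if (dx * dx + dy * dy + dz * dz < dmin * dmin) return true;
          }
        }
    return false;
  }
  void build(const std::vector<double>& pos, int nbeads) {
    std::fill(head.begin(), head.end(), -1);
    for (int i = 0; i < nbeads; ++i) {
      size_t c = cell_of(&pos[3 * i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

struct ChainLayout {
  std::vector<int> len, offset, cen;       // per chain
  std::vector<int> rdna_a, rdna_b;         // bead range [a,b) within chain, -1 none
  int nbeads;
  std::vector<int> chain_of;               // per bead
  std::vector<bool> is_rdna;
  ChainLayout(IntegerVector l, IntegerVector c, IntegerVector ra, IntegerVector rb) {
    int nc = l.size();
    len.assign(l.begin(), l.end());
    cen.assign(c.begin(), c.end());
    rdna_a.assign(ra.begin(), ra.end());
    rdna_b.assign(rb.begin(), rb.end());
    offset.resize(nc);
    nbeads = 0;
    for (int k = 0; k < nc; ++k) { offset[k] = nbeads; nbeads += len[k]; }
    chain_of.assign(nbeads, 0);
    is_rdna.assign(nbeads, false);
    for (int k = 0; k < nc; ++k) {
      for (int j = 0; j < len[k]; ++j) {
        chain_of[offset[k] + j] = k;
        if (rdna_a[k] >= 0 && j >= rdna_a[k] && j < rdna_b[k])
          is_rdna[offset[k] + j] = true;
      }
    }
  }
};

inline bool bonded(const ChainLayout& L, int i, int j) {
  return L.chain_of[i] == L.chain_of[j] && std::abs(i - j) == 1;
}

void clamp_nucleus(double* x, double R) {
  double r = std::sqrt(x[0] * x[0] + x[1] * x[1] + x[2] * x[2]);
  if (r > R) { double f = R / r; x[0] *= f; x[1] *= f; x[2] *= f; }
}

int project_tethers(std::vector<double>& pos, const ChainLayout& L, const Params& P,
                    Rng& rng) {
  int fixes = 0;
  const double tol = 0.5 * P.region_tol;
  for (size_t k = 0; k < L.len.size(); ++k) {
    // centromere bead into the capture sphere
    double* c = &pos[3 * (L.offset[k] + L.cen[k])];
    double dx = c[0] - P.cap_cx, dy = c[1], dz = c[2];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d > P.cap_r + tol) {
      ++fixes;
      double f = P.cap_r / d;
      c[0] = P.cap_cx + dx * f; c[1] = dy * f; c[2] = dz * f;
    }
    // telomere beads into the peripheral shell
    for (int e = 0; e < 2; ++e) {
      double* t = &pos[3 * (L.offset[k] + (e == 0 ? 0 : L.len[k] - 1))];
      double r = std::sqrt(t[0] * t[0] + t[1] * t[1] + t[2] * t[2]);
      double lo = P.R - P.shell;
      if (r < lo - tol) {
        ++fixes;
        if (r < 1e-9) { rng.sphere_dir(t); r = 1.0; }
        double f = lo / r;
        t[0] *= f; t[1] *= f; t[2] *= f;
      }
    }
  }
  for (int i = 0; i < L.nbeads; ++i) {
    double* x = &pos[3 * i];
    if (P.has_nucleolus) {
      if (L.is_rdna[i]) {
        if (x[0] > P.nuc_plane + tol) { ++fixes; x[0] = P.nuc_plane; }
      } else if (x[0] < P.nuc_plane - tol) { ++fixes; x[0] = P.nuc_plane; }
    }
    double r = std::sqrt(x[0] * x[0] + x[1] * x[1] + x[2] * x[2]);
    if (r > P.R + tol) ++fixes;
    clamp_nucleus(x, P.R);
  }
  return fixes;
}

int project_bonds(std::vector<double>& pos, const ChainLayout& L, const Params& P,
                  bool forward) {
  int fixes = 0;
  const double tol = 0.5 * P.region_tol;
  for (size_t k = 0; k < L.len.size(); ++k) {
    int n = L.len[k], o = L.offset[k];
    for (int s = 0; s < n - 1; ++s) {
      int i = forward ? s : n - 2 - s;
      double* a = &pos[3 * (o + i)];
      double* b = &pos[3 * (o + i + 1)];
      double d = dist3(a, b);
      double target = d;
      if (d > P.bond_max + tol) target = P.bond_max;
      else if (d < P.bond_min - tol) target = P.bond_min;
      if (target != d) {
        ++fixes;
        if (d < 1e-9) { b[0] += P.bond_min; d = P.bond_min; target = P.bond_min; }
        double f = 0.5 * (target - d) / d;
        double dx = b[0] - a[0], dy = b[1] - a[1], dz = b[2] - a[2];
        a[0] -= f * dx; a[1] -= f * dy; a[2] -= f * dz;
        b[0] += f * dx; b[1] += f * dy; b[2] += f * dz;
      }
    }
  }
  return fixes;
}


// forward half of the 26-cell neighbourhood: each unordered cross-cell pair is
// visited exactly once; same-cell pairs are handled with an index comparison
static const int kFwd[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1}, {1, 1, 0}, {1, -1, 0}, {1, 0, 1},
    {1, 0, -1}, {0, 1, 1}, {0, 1, -1}, {1, 1, 1}, {1, 1, -1}, {1, -1, 1},
    {1, -1, -1}};

// push overlapping non-bonded bead pairs apart; returns number of pushes
int project_overlaps(std::vector<double>& pos, const ChainLayout& L, const Params& P,
                     Grid& g, Rng& rng) {
  g.build(pos, L.nbeads);
  int pushes = 0;
  for (int i = 0; i < L.nbeads; ++i) {
    double* a = &pos[3 * i];
    int cx = g.cidx(a[0]), cy = g.cidx(a[1]), cz = g.cidx(a[2]);
    for (int nb = -1; nb < 13; ++nb) {
      int nx = cx, ny = cy, nz = cz;
      if (nb >= 0) { nx += kFwd[nb][0]; ny += kFwd[nb][1]; nz += kFwd[nb][2]; }
      if (nx < 0 || ny < 0 || nz < 0 || nx >= g.n || ny >= g.n || nz >= g.n) continue;
      for (int j = g.head[((size_t)nx * g.n + ny) * g.n + nz]; j != -1; j = g.nxt[j]) {
            if (nb < 0 && j <= i) continue;
            if (j == i) continue;
            double* b = &pos[3 * j];
            double d = dist3(a, b);
            if (d < P.diam - 0.5 * P.overlap_tol && !bonded(L, i, j)) {
              ++pushes;
              double dx, dy, dz2;
              if (d < 1e-9) {
                double dir[3]; rng.sphere_dir(dir);
                dx = dir[0]; dy = dir[1]; dz2 = dir[2]; d = 1.0;
                double f = 0.5 * P.diam;
                a[0] -= f * dx; a[1] -= f * dy; a[2] -= f * dz2;
                b[0] += f * dx; b[1] += f * dy; b[2] += f * dz2;
              } else {
                double f = 0.5 * (P.diam * 1.05 - d) / d;
                dx = b[0] - a[0]; dy = b[1] - a[1]; dz2 = b[2] - a[2];
                a[0] -= f * dx; a[1] -= f * dy; a[2] -= f * dz2;
                b[0] += f * dx; b[1] += f * dy; b[2] += f * dz2;
              }
            }
          }
        }
  }
  return pushes;
}

IntegerVector count_violations(const std::vector<double>& pos, const ChainLayout& L,
                               const Params& P, Grid& g) {
  int bond = 0, overlap = 0, cen = 0, telo = 0, rdna_out = 0, non_rdna_in = 0,
      outside = 0;
  double tol = P.region_tol;
  for (size_t k = 0; k < L.len.size(); ++k) {
    int n = L.len[k], o = L.offset[k];
    for (int i = 0; i < n - 1; ++i) {
      double d = dist3(&pos[3 * (o + i)], &pos[3 * (o + i + 1)]);
      if (d < P.bond_min - tol || d > P.bond_max + tol) ++bond;
    }
    const double* c = &pos[3 * (o + L.cen[k])];
    double dx = c[0] - P.cap_cx;
    if (std::sqrt(dx * dx + c[1] * c[1] + c[2] * c[2]) > P.cap_r + tol) ++cen;
    for (int e = 0; e < 2; ++e) {
      const double* t = &pos[3 * (o + (e == 0 ? 0 : n - 1))];
      double r = std::sqrt(t[0] * t[0] + t[1] * t[1] + t[2] * t[2]);
      if (r < P.R - P.shell - tol) ++telo;
    }
  }
  for (int i = 0; i < L.nbeads; ++i) {
    const double* x = &pos[3 * i];
    double r = std::sqrt(x[0] * x[0] + x[1] * x[1] + x[2] * x[2]);
    if (r > P.R + tol) ++outside;
    if (P.has_nucleolus) {
      if (L.is_rdna[i]) { if (x[0] > P.nuc_plane + tol) ++rdna_out; }
      else if (x[0] < P.nuc_plane - tol) ++non_rdna_in;
    }
  }
  g.build(pos, L.nbeads);
  for (int i = 0; i < L.nbeads; ++i) {
    const double* a = &pos[3 * i];
    int cx = g.cidx(a[0]), cy = g.cidx(a[1]), cz = g.cidx(a[2]);
    for (int nb = -1; nb < 13; ++nb) {
      int nx = cx, ny = cy, nz = cz;
      if (nb >= 0) { nx += kFwd[nb][0]; ny += kFwd[nb][1]; nz += kFwd[nb][2]; }
      if (nx < 0 || ny < 0 || nz < 0 || nx >= g.n || ny >= g.n || nz >= g.n) continue;
      for (int j = g.head[((size_t)nx * g.n + ny) * g.n + nz]; j != -1; j = g.nxt[j]) {
        if (j == i || (nb < 0 && j < i) || bonded(L, i, j)) continue;
        if (dist3(a, &pos[3 * j]) < P.diam - P.overlap_tol) ++overlap;
      }
    }
  }
  return IntegerVector::create(
      _["bond"] = bond, _["overlap"] = overlap, _["centromere_tether"] = cen,
      _["telomere_tether"] = telo, _["rdna_outside_nucleolus"] = rdna_out,
      _["non_rdna_in_nucleolus"] = non_rdna_in, _["outside_nucleus"] = outside);
}

void grow_chains(std::vector<double>& pos, const ChainLayout& L, const Params& P,
                 Rng& rng, Grid& g) {
  std::fill(g.head.begin(), g.head.end(), -1);
  for (size_t k = 0; k < L.len.size(); ++k) {
    int o = L.offset[k], n = L.len[k], cenb = L.cen[k];
    double* c = &pos[3 * (o + cenb)];
    // centromere bead uniform in the capture sphere, avoiding placed beads
    for (int t = 0; t < 2000; ++t) {
      double x = (2 * rng.unif() - 1), y = (2 * rng.unif() - 1), z = (2 * rng.unif() - 1);
      if (x * x + y * y + z * z <= 1.0) {
        c[0] = P.cap_cx + P.cap_r * x; c[1] = P.cap_r * y; c[2] = P.cap_r * z;
        if (!g.crowded(pos, c, P.diam, -1) || t > 1900) break;
      }
    }
    clamp_nucleus(c, P.R);
    g.insert(c, o + cenb);
    for (int arm = 0; arm < 2; ++arm) {
      int narm = arm == 0 ? cenb : n - 1 - cenb;
      if (narm == 0) continue;
      // telomere anchor on the shell: reachable by the arm and weighted by
      // the random-walk end-to-end density (sigma = sqrt(n) * mean bond), so
      // short arms anchor near the SPB as chain entropy dictates rather than
      // being stretched to the farthest reachable point
      double anchor[3];
      double reach = 0.92 * narm * P.bond_max;
      double sigma = P.anchor_sigma_scale * std::sqrt((double)narm) *
                         0.5 * (P.bond_min + P.bond_max);
      double ar = P.R - 0.5 * P.shell;
      bool found = false;
      for (int t = 0; t < 400 && !found; ++t) {
        double d[3]; rng.sphere_dir(d);
        anchor[0] = ar * d[0]; anchor[1] = ar * d[1]; anchor[2] = ar * d[2];
        if (P.has_nucleolus && anchor[0] < P.nuc_plane) continue;
        double da = dist3(anchor, c);
        if (da > reach) continue;
        if (rng.unif() < std::exp(-da * da / (2.0 * sigma * sigma))) found = true;
      }
      if (!found) { // nearest shell point to the centromere bead
        double r = std::sqrt(c[0] * c[0] + c[1] * c[1] + c[2] * c[2]);
        if (r < 1e-9) { anchor[0] = ar; anchor[1] = 0; anchor[2] = 0; }
        else { double f = ar / r; anchor[0] = c[0] * f; anchor[1] = c[1] * f; anchor[2] = c[2] * f; }
      }
      // if this arm carries the rDNA segment, route the walk through a
      // waypoint inside the nucleolar cap so the tethered beads do not have
      // to be dragged across the nucleus during relaxation
      int seg_from = -1, seg_to = -1;
      if (P.has_nucleolus && L.rdna_a[k] >= 0) {
        if (arm == 1 && L.rdna_a[k] > cenb) {
          seg_from = L.rdna_a[k] - cenb;
          seg_to = L.rdna_b[k] - 1 - cenb;
        } else if (arm == 0 && L.rdna_b[k] - 1 < cenb) {
          seg_from = cenb - (L.rdna_b[k] - 1);
          seg_to = cenb - L.rdna_a[k];
        }
      }
      double wp[3] = {0, 0, 0};
      if (seg_from >= 0) {
        double depth = P.nuc_plane + P.R;
        wp[0] = P.nuc_plane - rng.unif() * 0.5 * depth;
        double disc = 0.7 * std::sqrt(std::max(0.0, P.R * P.R - wp[0] * wp[0]));
        double u1 = 2 * rng.unif() - 1, u2 = 2 * rng.unif() - 1;
        wp[1] = disc * u1; wp[2] = disc * u2;
      }
      double prev[3] = {c[0], c[1], c[2]};
      for (int s = 1; s <= narm; ++s) {
        int bead = arm == 0 ? cenb - s : cenb + s;
        double* x = &pos[3 * (o + bead)];
        const double* tgt = anchor;
        int remaining = narm - s + 1;
        if (seg_from >= 0 && s <= seg_to) {
          tgt = wp;
          remaining = s < seg_from ? seg_from - s + 1 : 1;
        }
        double to_a[3] = {tgt[0] - prev[0], tgt[1] - prev[1], tgt[2] - prev[2]};
        double da = std::sqrt(to_a[0] * to_a[0] + to_a[1] * to_a[1] + to_a[2] * to_a[2]);
        double urgency = da / (remaining * P.bond_max);
        if (urgency > 1) urgency = 1;
        double rd[3]; rng.sphere_dir(rd);
        double dir[3];
        if (da < 1e-9) { dir[0] = rd[0]; dir[1] = rd[1]; dir[2] = rd[2]; }
        else {
          for (int q = 0; q < 3; ++q)
            dir[q] = urgency * to_a[q] / da + (1 - urgency) * rd[q];
          double dn = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
          if (dn < 1e-9) { dir[0] = rd[0]; dir[1] = rd[1]; dir[2] = rd[2]; }
          else for (int q = 0; q < 3; ++q) dir[q] /= dn;
        }
        double step = urgency > 0.8 ? P.bond_max
                                    : P.bond_min + rng.unif() * (P.bond_max - P.bond_min);
        // try a few directions, keeping the first uncrowded placement
        for (int attempt = 0; attempt < 12; ++attempt) {
          for (int q = 0; q < 3; ++q) x[q] = prev[q] + step * dir[q];
          if (P.has_nucleolus) {
            if (L.is_rdna[o + bead]) {
              if (x[0] > P.nuc_plane) x[0] = P.nuc_plane - rng.unif() * 0.05 * P.R;
            } else if (x[0] < P.nuc_plane) {
              // keep non-rDNA beads out of the nucleolar cap from the start
              x[0] = P.nuc_plane + rng.unif() * 0.05 * P.R;
            }
          }
          clamp_nucleus(x, P.R);
          if (urgency > 0.8 || !g.crowded(pos, x, P.diam, -1)) break;
          // re-blend a fresh random component and retry
          rng.sphere_dir(rd);
          if (da >= 1e-9) {
            for (int q = 0; q < 3; ++q)
              dir[q] = urgency * to_a[q] / da + (1 - urgency) * rd[q];
            double dn = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
            if (dn >= 1e-9) for (int q = 0; q < 3; ++q) dir[q] /= dn;
          } else {
            dir[0] = rd[0]; dir[1] = rd[1]; dir[2] = rd[2];
          }
        }
        g.insert(x, o + bead);
        prev[0] = x[0]; prev[1] = x[1]; prev[2] = x[2];
      }
      // place the telomere bead into the shell
      double* t = &pos[3 * (o + (arm == 0 ? 0 : n - 1))];
      double r = std::sqrt(t[0] * t[0] + t[1] * t[1] + t[2] * t[2]);
      double lo = P.R - P.shell;
      if (r < lo && r > 1e-9) {
        double f = lo / r; t[0] *= f; t[1] *= f; t[2] *= f;
      }
    }
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_sample_structure(IntegerVector chain_len, IntegerVector cen_bead,
                          IntegerVector rdna_from, IntegerVector rdna_to,
                          List params, double seed) {
  ChainLayout L(chain_len, cen_bead, rdna_from, rdna_to);
  Params P = read_params(params);
  Rng rng((uint64_t)seed);
  std::vector<double> pos(3 * L.nbeads, 0.0);
  Grid g(std::max(P.diam, P.bond_max), P.R + P.bond_max, L.nbeads);
  grow_chains(pos, L, P, rng, g);
  int it = 0;
  bool ok = false;
  for (; it < P.max_iter; ++it) {
    int fixes = 0;
    fixes += project_bonds(pos, L, P, true);
    fixes += project_bonds(pos, L, P, false);
    fixes += project_tethers(pos, L, P, rng);
    fixes += project_overlaps(pos, L, P, g, rng);
    if (fixes == 0) { ok = true; break; }
  }
  if (ok) { // postcondition: the relaxed structure passes the strict check
    IntegerVector v = count_violations(pos, L, P, g);
    for (int q = 0; q < v.size(); ++q) if (v[q] > 0) { ok = false; break; }
  }
  NumericMatrix out(L.nbeads, 3);
  for (int i = 0; i < L.nbeads; ++i)
    for (int q = 0; q < 3; ++q) out(i, q) = pos[3 * i + q];
  return List::create(_["coords"] = out, _["converged"] = ok,
                      _["iterations"] = it + 1);
}

// [[Rcpp::export]]
IntegerVector cpp_check_constraints(NumericMatrix coords, IntegerVector chain_len,
                                    IntegerVector cen_bead, IntegerVector rdna_from,
                                    IntegerVector rdna_to, List params) {
  ChainLayout L(chain_len, cen_bead, rdna_from, rdna_to);
  Params P = read_params(params);
  if (coords.nrow() != L.nbeads) stop("coordinate count does not match chain beads");
  std::vector<double> pos(3 * L.nbeads);
  double maxr = P.R;
  for (int i = 0; i < L.nbeads; ++i) {
    for (int q = 0; q < 3; ++q) pos[3 * i + q] = coords(i, q);
    double r = std::sqrt(pos[3 * i] * pos[3 * i] + pos[3 * i + 1] * pos[3 * i + 1] +
                         pos[3 * i + 2] * pos[3 * i + 2]);
    if (r > maxr) maxr = r;
  }
  Grid g(std::max(P.diam, P.bond_max), maxr + P.bond_max, L.nbeads);
  return count_violations(pos, L, P, g);
}

// [[Rcpp::export]]
NumericMatrix cpp_population_contacts(List structures, IntegerVector bead_bin,
                                      double threshold, int nbins) {
  int nb = bead_bin.size();
  NumericMatrix mat(nbins, nbins);
  for (int s = 0; s < structures.size(); ++s) {
    NumericMatrix coords = structures[s];
    if (coords.nrow() != nb) stop("bead/bin assignment does not match structure");
    std::vector<double> pos(3 * nb);
    double maxr = 1.0;
    for (int i = 0; i < nb; ++i) {
      for (int q = 0; q < 3; ++q) pos[3 * i + q] = coords(i, q);
      double r = std::abs(pos[3 * i]) + std::abs(pos[3 * i + 1]) + std::abs(pos[3 * i + 2]);
      if (r > maxr) maxr = r;
    }
    Grid g(threshold, maxr + threshold, nb);
    g.build(pos, nb);
    for (int i = 0; i < nb; ++i) {
      const double* a = &pos[3 * i];
      int cx = g.cidx(a[0]), cy = g.cidx(a[1]), cz = g.cidx(a[2]);
      for (int ox = -1; ox <= 1; ++ox)
        for (int oy = -1; oy <= 1; ++oy)
          for (int oz = -1; oz <= 1; ++oz) {
            int nx = cx + ox, ny = cy + oy, nz = cz + oz;
            if (nx < 0 || ny < 0 || nz < 0 || nx >= g.n || ny >= g.n || nz >= g.n)
              continue;
            for (int j = g.head[((size_t)nx * g.n + ny) * g.n + nz]; j != -1;
                 j = g.nxt[j]) {
              if (j <= i) continue;
              if (dist3(a, &pos[3 * j]) <= threshold) {
                int b1 = bead_bin[i], b2 = bead_bin[j];
                mat(b1, b2) += 1.0;
                if (b1 != b2) mat(b2, b1) += 1.0;
              }
            }
          }
    }
  }
  return mat;
}

// [[Rcpp::export]]
double cpp_mix_seed(double seed, double index) {
  Rng r(((uint64_t)seed << 20) ^ (uint64_t)index);
  uint64_t h = r.next();
  return (double)(h & ((1ULL << 52) - 1));
}
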