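#include <Rcpp.h>
#include <array>
#include <vector>
#include <cmath>
#include <climits>
using namespace Rcpp;

// Uniform integer in [0, n) from R's RNG stream.
static inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Lattice world shared by the growth engine and the push test harness.
// Coordinates are 0-based internal lattice positions; cell ids are 1-based.
struct World {
  int dim;
  int side;   // extent along x and y (and z when dim == 3)
  int zdim;   // side when 3D, 1 when 2D
  std::vector<int> grid;              // linear index -> cell id (0 = empty)
  std::vector<int> cx, cy, cz;        // cell id - 1 -> coordinates
  std::vector<std::array<int, 3> > dirs;  // Moore directions, lexicographic

  void init(int dim_, int side_) {
    dim = dim_;
    side = side_;
    zdim = (dim == 3) ? side : 1;
    grid.assign((size_t)side * side * zdim, 0);
    dirs.clear();
    int zlo = (dim == 3) ? -1 : 0, zhi = (dim == 3) ? 1 : 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = zlo; dz <= zhi; ++dz) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          std::array<int, 3> d = {{dx, dy, dz}};
          dirs.push_back(d);
        }
  }

  inline bool in_bounds(int x, int y, int z) const {
    return x >= 0 && x < side && y >= 0 && y < side &&
           z >= 0 && z < zdim;
  }
  inline size_t at(int x, int y, int z) const {
    return ((size_t)x * side + y) * zdim + z;
  }
  inline int occupant(int x, int y, int z) const { return grid[at(x, y, z)]; }

  void place(int id, int x, int y, int z) {
    grid[at(x, y, z)] = id;
    if ((int)cx.size() < id) { cx.resize(id); cy.resize(id); cz.resize(id); }
    cx[id - 1] = x; cy[id - 1] = y; cz[id - 1] = z;
  }

  void move_cell(int x0, int y0, int z0, int x1, int y1, int z1) {
    int id = grid[at(x0, y0, z0)];
    grid[at(x0, y0, z0)] = 0;
    grid[at(x1, y1, z1)] = id;
    cx[id - 1] = x1; cy[id - 1] = y1; cz[id - 1] = z1;
  }

  // Push along the discrete ray origin + t * dirs[di] until the first empty
  // site; every occupied ray site shifts outward one step.  Returns the
  // linear index of the freed site adjacent to the origin.
  size_t push_random(int id, int di) {
    int x = cx[id - 1], y = cy[id - 1], z = cz[id - 1];
    const std::array<int, 3>& d = dirs[di];
    int t = 1;
    while (true) {
      int px = x + t * d[0], py = y + t * d[1], pz = z + t * d[2];
      if (!in_bounds(px, py, pz))
        stop("push reached the lattice boundary; increase the lattice size");
      if (occupant(px, py, pz) == 0) break;
      ++t;
    }
    // shift from the outermost occupied ray site inward
    for (int s = t - 1; s >= 1; --s)
      move_cell(x + s * d[0], y + s * d[1], z + s * d[2],
                x + (s + 1) * d[0], y + (s + 1) * d[1], z + (s + 1) * d[2]);
    return at(x + d[0], y + d[1], z + d[2]);
  }

  // Visit one site of the Chebyshev ring scan; update the running set of
  // nearest empty sites (squared Euclidean distance, ties collected).
  inline void ring_visit(int x, int y, int z, long& best_d2,
                         std::vector<std::array<int, 3> >& cand,
                         int ox, int oy, int oz) {
    if (!in_bounds(x, y, z) || occupant(x, y, z) != 0) return;
    long ddx = x - ox, ddy = y - oy, ddz = z - oz;
    long d2 = ddx * ddx + ddy * ddy + ddz * ddz;
    if (d2 < best_d2) {
      best_d2 = d2;
      cand.clear();
    }
    if (d2 == best_d2) {
      std::array<int, 3> s = {{x, y, z}};
      cand.push_back(s);
    }
  }

  // Nearest empty lattice site by Euclidean distance (Chebyshev ring scan;
  // ties broken uniformly at random), then shift cells one step along the
  // rounded straight-line (Moore-step) path toward it.  Returns the linear
  // index of the freed site adjacent to the origin.
  size_t push_shortest(int id) {
    int ox = cx[id - 1], oy = cy[id - 1], oz = cz[id - 1];
    long best_d2 = LONG_MAX;
    std::vector<std::array<int, 3> > cand;
    for (int r = 1; r <= side; ++r) {
      if ((long)r * r > best_d2) break;
      if (dim == 2) {
        for (int dx = -r; dx <= r; ++dx) {
          if (dx == -r || dx == r) {
            for (int dy = -r; dy <= r; ++dy)
              ring_visit(ox + dx, oy + dy, oz, best_d2, cand, ox, oy, oz);
          } else {
            ring_visit(ox + dx, oy - r, oz, best_d2, cand, ox, oy, oz);
            ring_visit(ox + dx, oy + r, oz, best_d2, cand, ox, oy, oz);
          }
        }
      } else {
        for (int dx = -r; dx <= r; ++dx)
          for (int dy = -r; dy <= r; ++dy) {
            if (std::max(std::abs(dx), std::abs(dy)) == r) {
              for (int dz = -r; dz <= r; ++dz)
                ring_visit(ox + dx, oy + dy, oz + dz, best_d2, cand,
                           ox, oy, oz);
            } else {
              ring_visit(ox + dx, oy + dy, oz - r, best_d2, cand, ox, oy, oz);
              ring_visit(ox + dx, oy + dy, oz + r, best_d2, cand, ox, oy, oz);
            }
          }
      }
    }
    if (cand.empty())
      stop("no empty lattice site found; increase the lattice size");
    std::array<int, 3> tgt =
        cand.size() > 1 ? cand[rand_int((int)cand.size())] : cand[0];

    // rounded parametric segment from origin to target: consecutive points
    // differ by at most one per axis, so every step is a Moore step
    long dx = tgt[0] - ox, dy = tgt[1] - oy, dz = tgt[2] - oz;
    int steps = (int)std::max(std::labs(dx),
                              std::max(std::labs(dy), std::labs(dz)));
    std::vector<std::array<int, 3> > path(steps);
    for (int i = 1; i <= steps; ++i) {
      double f = (double)i / steps;
      std::array<int, 3> q = {{(int)std::lround(ox + dx * f),
                               (int)std::lround(oy + dy * f),
                               (int)std::lround(oz + dz * f)}};
      path[i - 1] = q;
    }
    // shift cells up to the first empty site on the path (the target at
    // the latest); the path site adjacent to the origin is freed
    int j = 0;
    while (j < steps && occupant(path[j][0], path[j][1], path[j][2]) != 0)
      ++j;
    for (int s = j; s >= 1; --s)
      move_cell(path[s - 1][0], path[s - 1][1], path[s - 1][2],
                path[s][0], path[s][1], path[s][2]);
    return at(path[0][0], path[0][1], path[0][2]);
  }
};

// Growth engine: synchronous generations from a single seeded cell.
// RNG draws come from R's stream in a fixed order per division:
// empty-neighbour choice OR (push-gate uniform, then direction / tie
// choice), then one Poisson draw per daughter (in-place daughter first).
// [[Rcpp::export(name = ".grow_engine")]]
List grow_engine(double push_rate, double mutation_rate, int dimension,
                 int target_size, int max_generations, int algorithm,
                 int side) {
  World w;
  w.init(dimension, side);
  int c0 = side / 2;
  int z0 = (dimension == 3) ? c0 : 0;

  std::vector<int> parent(1, 0), birth_gen(1, 0);
  std::vector<int> mut_start(1, 1), mut_n(1, 0);
  std::vector<char> alive(1, 1);
  w.place(1, c0, c0, z0);
  int n_cells = 1, n_alive = 1;
  long next_mut = 1;
  int ndirs = (int)w.dirs.size();

  int g = 0;
  std::vector<int> snapshot;
  while (g < max_generations && n_alive < target_size) {
    snapshot.clear();
    for (int i = 0; i < n_cells; ++i)
      if (alive[i]) snapshot.push_back(i + 1);
    // uniform shuffle (Fisher-Yates) of the within-generation order
    for (int i = (int)snapshot.size() - 1; i >= 1; --i) {
      int j = rand_int(i + 1);
      std::swap(snapshot[i], snapshot[j]);
    }
    for (size_t s = 0; s < snapshot.size(); ++s) {
      int id = snapshot[s];
      int x = w.cx[id - 1], y = w.cy[id - 1], z = w.cz[id - 1];
      // collect empty Moore neighbours
      int n_empty = 0;
      int empty_idx[26];
      for (int di = 0; di < ndirs; ++di) {
        int nx = x + w.dirs[di][0], ny = y + w.dirs[di][1],
            nz = z + w.dirs[di][2];
        if (w.in_bounds(nx, ny, nz) && w.occupant(nx, ny, nz) == 0)
          empty_idx[n_empty++] = di;
      }
      size_t new_site;
      if (n_empty > 0) {
        int di = empty_idx[rand_int(n_empty)];
        new_site = w.at(x + w.dirs[di][0], y + w.dirs[di][1],
                        z + w.dirs[di][2]);
      } else {
        if (push_rate <= 0.0) continue;
        if (unif_rand() >= push_rate) continue;
        if (algorithm == 0)
          new_site = w.push_random(id, rand_int(ndirs));
        else
          new_site = w.push_shortest(id);
      }
      // the parent retires; two daughters are created, each with an
      // independent Poisson(lambda) number of new private mutations
      alive[id - 1] = 0;
      for (int dgt = 0; dgt < 2; ++dgt) {
        ++n_cells;
        parent.push_back(id);
        birth_gen.push_back(g + 1);
        alive.push_back(1);
        int k = (int)R::rpois(mutation_rate);
        mut_start.push_back((int)next_mut);
        mut_n.push_back(k);
        next_mut += k;
        if (dgt == 0) {
          w.place(n_cells, x, y, z);   // in-place daughter at L_p
        } else {
          int sx = (int)(new_site / ((size_t)w.side * w.zdim));
          int sy = (int)((new_site / w.zdim) % w.side);
          int sz = (int)(new_site % w.zdim);
          w.place(n_cells, sx, sy, sz);
        }
      }
      ++n_alive;  // one net birth per division
      if (next_mut > INT_MAX - 64)
        stop("mutation id overflow; reduce lambda or tumour size");
    }
    ++g;
  }

  IntegerVector X(n_cells), Y(n_cells), Z(n_cells);
  for (int i = 0; i < n_cells; ++i) {
    X[i] = w.cx[i] - c0;
    Y[i] = w.cy[i] - c0;
    Z[i] = (dimension == 3) ? (w.cz[i] - z0) : 0;
  }
  LogicalVector alv(n_cells);
  for (int i = 0; i < n_cells; ++i) alv[i] = (bool)alive[i];
  return List::create(
      _["parent_id"] = IntegerVector(parent.begin(), parent.end()),
      _["birth_generation"] = IntegerVector(birth_gen.begin(),
                                            birth_gen.end()),
      _["x"] = X, _["y"] = Y, _["z"] = Z, _["alive"] = alv,
      _["mut_start"] = IntegerVector(mut_start.begin(), mut_start.end()),
      _["mut_n"] = IntegerVector(mut_n.begin(), mut_n.end()),
      _["generations"] = g, _["n_alive"] = n_alive,
      _["n_mutations"] = (double)(next_mut - 1));
}

// Test harness: build a lattice from explicit occupied coordinates, perform
// one push from the origin cell, and report the rearranged coordinates plus
// the freed site.  `direction` is a 1-based index into the lexicographic
// Moore direction list (0 = draw at random); ignored by shortest_path.
// [[Rcpp::export(name = ".push_harness")]]
List push_harness(IntegerMatrix coords, int origin, int algorithm,
                  int direction, int pad) {
  int n = coords.nrow(), dimension = coords.ncol();
  if (dimension != 2 && dimension != 3) stop("coords must have 2 or 3 columns");
  int lo = INT_MAX, hi = INT_MIN;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < dimension; ++j) {
      lo = std::min(lo, coords(i, j));
      hi = std::max(hi, coords(i, j));
    }
  int side = (hi - lo + 1) + 2 * pad;
  World w;
  w.init(dimension, side);
  int off = pad - lo;
  for (int i = 0; i < n; ++i) {
    int x = coords(i, 0) + off, y = coords(i, 1) + off;
    int z = (dimension == 3) ? coords(i, 2) + off : 0;
    if (w.occupant(x, y, z) != 0) stop("duplicate occupied site");
    w.place(i + 1, x, y, z);
  }
  size_t freed;
  if (algorithm == 0) {
    int di = (direction >= 1) ? direction - 1 : rand_int((int)w.dirs.size());
    freed = w.push_random(origin, di);
  } else {
    freed = w.push_shortest(origin);
  }
  IntegerMatrix out(n, dimension);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = w.cx[i] - off;
    out(i, 1) = w.cy[i] - off;
    if (dimension == 3) out(i, 2) = w.cz[i] - off;
  }
  IntegerVector fr(dimension);
  int fx = (int)(freed / ((size_t)w.side * w.zdim));
  int fy = (int)((freed / w.zdim) % w.side);
  int fz = (int)(freed % w.zdim);
  fr[0] = fx - off; fr[1] = fy - off;
  if (dimension == 3) fr[2] = fz - off;
  return List::create(_["coords"] = out, _["freed"] = fr);
}
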