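// Batched forward kinematics + pose scoring for the stochastic engine.
// Semantics mirror the R-level apply_genome() / score_pose() exactly
// (a unit test pins the two within 1e-9): torsions are deltas from the
// reference geometry applied in rank order, then a rigid-body rotation
// about the reference centroid and a centroid translation.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static void axis_rotation(const double *p1, const double *p2, double angle,
                          double R[3][3]) {
  double ax = p2[0] - p1[0], ay = p2[1] - p1[1], az = p2[2] - p1[2];
  double n = std::sqrt(ax * ax + ay * ay + az * az);
  ax /= n; ay /= n; az /= n;
  double c = std::cos(angle), s = std::sin(angle), t = 1.0 - c;
  R[0][0] = t * ax * ax + c;      R[0][1] = t * ax * ay - s * az; R[0][2] = t * ax * az + s * ay;
  R[1][0] = t * ax * ay + s * az; R[1][1] = t * ay * ay + c;      R[1][2] = t * ay * az - s * ax;
  R[2][0] = t * ax * az - s * ay; R[2][1] = t * ay * az + s * ax; R[2][2] = t * az * az + c;
}

static void quat_rotation(double w, double x, double y, double z,
                          double R[3][3]) {
  double n = std::sqrt(w * w + x * x + y * y + z * z);
  w /= n; x /= n; y /= n; z /= n;
  R[0][0] = 1 - 2 * (y * y + z * z); R[0][1] = 2 * (x * y - w * z); R[0][2] = 2 * (x * z + w * y);
  R[1][0] = 2 * (x * y + w * z); R[1][1] = 1 - 2 * (x * x + z * z); R[1][2] = 2 * (y * z - w * x);
  R[2][0] = 2 * (x * z - w * y); R[2][1] = 2 * (y * z + w * x); R[2][2] = 1 - 2 * (x * x + y * y);
}

// coordinates of one genome; out is n x 3 (row-major triples)
static void genome_coords(const NumericMatrix &ref, const NumericVector &centroid,
                          const IntegerVector &edge_a, const IntegerVector &edge_b,
                          const List &edge_moving, const IntegerVector &edge_slot,
                          const NumericVector &edge_fixed,
                          const double *genome, int n_active,
                          std::vector<double> &out) {
  int n = ref.nrow();
  out.resize(3 * n);
  for (int i = 0; i < n; ++i) {
    out[3 * i] = ref(i, 0); out[3 * i + 1] = ref(i, 1); out[3 * i + 2] = ref(i, 2);
  }
  int m = edge_a.size();
  double R[3][3];
  for (int e = 0; e < m; ++e) {
    double ang = edge_slot[e] >= 0 ? genome[7 + edge_slot[e]] : edge_fixed[e];
    if (ang == 0.0) continue;
    // child->parent axis: positive delta increases the measured dihedral
    // (mirrors R-level apply_genome)
    const double *p1 = &out[3 * (edge_b[e] - 1)];
    const double *p2 = &out[3 * (edge_a[e] - 1)];
    double a0 = p1[0], a1 = p1[1], a2 = p1[2];
    axis_rotation(p1, p2, ang, R);
    IntegerVector mv = edge_moving[e];
    for (int k = 0; k < mv.size(); ++k) {
      double *p = &out[3 * (mv[k] - 1)];
      double vx = p[0] - a0, vy = p[1] - a1, vz = p[2] - a2;
      p[0] = a0 + R[0][0] * vx + R[0][1] * vy + R[0][2] * vz;
      p[1] = a1 + R[1][0] * vx + R[1][1] * vy + R[1][2] * vz;
      p[2] = a2 + R[2][0] * vx + R[2][1] * vy + R[2][2] * vz;
    }
  }
  quat_rotation(genome[3], genome[4], genome[5], genome[6], R);
  double cx = centroid[0], cy = centroid[1], cz = centroid[2];
  double tx = genome[0] + cx, ty = genome[1] + cy, tz = genome[2] + cz;
  for (int i = 0; i < n; ++i) {
    double vx = out[3 * i] - cx, vy = out[3 * i + 1] - cy, vz = out[3 * i + 2] - cz;
    out[3 * i]     = tx + R[0][0] * vx + R[0][1] * vy + R[0][2] * vz;
    out[3 * i + 1] = ty + R[1][0] * vx + R[1][1] * vy + R[1][2] * vz;
    out[3 * i + 2] = tz + R[2][0] * vx + R[2][1] * vy + R[2][2] * vz;
  }
  (void)n_active;
}

static double trilinear_one(const NumericVector &map, const IntegerVector &npts,
                            double fx, double fy, double fz) {
  int nx = npts[0], ny = npts[1];
  int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
  if (i0 > npts[0] - 2) i0 = npts[0] - 2; if (i0 < 0) i0 = 0;
  if (j0 > npts[1] - 2) j0 = npts[1] - 2; if (j0 < 0) j0 = 0;
  if (k0 > npts[2] - 2) k0 = npts[2] - 2; if (k0 < 0) k0 = 0;
  double ux = fx - i0, uy = fy - j0, uz = fz - k0;
  #define M(i, j, k) map[(i) + nx * ((j) + ny * (size_t)(k))]
  double c00 = M(i0, j0, k0) * (1 - ux) + M(i0 + 1, j0, k0) * ux;
  double c10 = M(i0, j0 + 1, k0) * (1 - ux) + M(i0 + 1, j0 + 1, k0) * ux;
  double c01 = M(i0, j0, k0 + 1) * (1 - ux) + M(i0 + 1, j0, k0 + 1) * ux;
  double c11 = M(i0, j0 + 1, k0 + 1) * (1 - ux) + M(i0 + 1, j0 + 1, k0 + 1) * ux;
  #undef M
  return (c00 * (1 - uy) + c10 * uy) * (1 - uz) + (c01 * (1 - uy) + c11 * uy) * uz;
}

static double score_coords(const std::vector<double> &xyz, int n, const List &field) {
  std::string kind = as<std::string>(field["kind"]);
  if (kind == "funnel") {
    NumericMatrix targets = field["targets"];
    double k = as<double>(field["k"]);
    double amp = as<double>(field["noise_amp"]);
    double period = as<double>(field["noise_period"]);
    double e = 0.0;
    const double two_pi = 6.283185307179586;
    for (int i = 0; i < n; ++i) {
      double dx = xyz[3 * i] - targets(i, 0);
      double dy = xyz[3 * i + 1] - targets(i, 1);
      double dz = xyz[3 * i + 2] - targets(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      e += k * d2;
      if (amp > 0) e += amp * (1.0 - std::cos(two_pi * std::sqrt(d2) / period));
    }
    return e;
  }
  // grid field
  List maps = field["maps"];
  IntegerVector atom_map = field["atom_map"];     // 0-based map index per atom
  NumericVector charges = field["charges"];
  NumericVector elec = field["elec"];
  NumericVector origin = field["origin"];
  IntegerVector npts = field["npts"];
  double spacing = as<double>(field["spacing"]);
  double penalty = as<double>(field["oob_penalty"]);
  double hx = (npts[0] - 1), hy = (npts[1] - 1), hz = (npts[2] - 1);
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    double fx = (xyz[3 * i] - origin[0]) / spacing;
    double fy = (xyz[3 * i + 1] - origin[1]) / spacing;
    double fz = (xyz[3 * i + 2] - origin[2]) / spacing;
    if (fx < 0 || fx > hx || fy < 0 || fy > hy || fz < 0 || fz > hz) {
      e += penalty;
      continue;
    }
    NumericVector tm = maps[atom_map[i]];
    e += trilinear_one(tm, npts, fx, fy, fz);
    e += charges[i] * trilinear_one(elec, npts, fx, fy, fz);
  }
  return e;
}

// [[Rcpp::export]]
NumericVector cpp_eval_genomes(NumericMatrix ref, NumericVector centroid,
                               IntegerVector edge_a, IntegerVector edge_b,
                               List edge_moving, IntegerVector edge_slot,
                               NumericVector edge_fixed,
                               NumericMatrix genomes, List field) {
  int npop = genomes.nrow();
  int n = ref.nrow();
  int n_active = genomes.ncol() - 7;
  NumericVector scores(npop);
  std::vector<double> xyz;
  std::vector<double> g(genomes.ncol());
  for (int p = 0; p < npop; ++p) {
    for (int j = 0; j < genomes.ncol(); ++j) g[j] = genomes(p, j);
    genome_coords(ref, centroid, edge_a, edge_b, edge_moving, edge_slot,
                  edge_fixed, g.data(), n_active, xyz);
    scores[p] = score_coords(xyz, n, field);
  }
  return scores;
}

// [[Rcpp::export]]
NumericMatrix cpp_genome_coords(NumericMatrix ref, NumericVector centroid,
                                IntegerVector edge_a, IntegerVector edge_b,
                                List edge_moving, IntegerVector edge_slot,
                                NumericVector edge_fixed, NumericVector genome) {
  int n = ref.nrow();
  std::vector<double> xyz;
  std::vector<double> g(genome.size());
  for (int j = 0; j < genome.size(); ++j) g[j] = genome[j];
  genome_coords(ref, centroid, edge_a, edge_b, edge_moving, edge_slot,
                edge_fixed, g.data(), genome.size() - 7, xyz);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = xyz[3 * i]; out(i, 1) = xyz[3 * i + 1]; out(i, 2) = xyz[3 * i + 2];
  }
  return out;
}

// ---- full GA run in C++ --------------------------------------------------
// Draws exclusively from R's RNG stream (unif_rand / norm_rand), so results
// are reproducible under set.seed() on the R side and independent of
// execution order across runs.

static void rnd_quat(double *q) {
  double u1 = unif_rand(), u2 = unif_rand(), u3 = unif_rand();
  const double two_pi = 6.283185307179586;
  q[0] = std::sqrt(1 - u1) * std::sin(two_pi * u2);
  q[1] = std::sqrt(1 - u1) * std::cos(two_pi * u2);
  q[2] = std::sqrt(u1) * std::sin(two_pi * u3);
  q[3] = std::sqrt(u1) * std::cos(two_pi * u3);
}

static void quat_compose_axis(double *q, double angle) {
  // small rotation about a random axis composed onto q, then renormalised
  double ax = norm_rand(), ay = norm_rand(), az = norm_rand();
  double n = std::sqrt(ax * ax + ay * ay + az * az);
  if (n < 1e-12) { ax = 1; ay = az = 0; n = 1; }
  double s = std::sin(angle / 2) / n, w1 = std::cos(angle / 2);
  double x1 = s * ax, y1 = s * ay, z1 = s * az;
  double w2 = q[0], x2 = q[1], y2 = q[2], z2 = q[3];
  double w = w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2;
  double x = w1 * x2 + w2 * x1 + y1 * z2 - z1 * y2;
  double y = w1 * y2 + w2 * y1 + z1 * x2 - x1 * z2;
  double z = w1 * z2 + w2 * z1 + x1 * y2 - y1 * x2;
  n = std::sqrt(w * w + x * x + y * y + z * z);
  q[0] = w / n; q[1] = x / n; q[2] = y / n; q[3] = z / n;
}

static void norm_quat_part(double *g) {
  double n = std::sqrt(g[3] * g[3] + g[4] * g[4] + g[5] * g[5] + g[6] * g[6]);
  for (int j = 3; j < 7; ++j) g[j] /= n;
}

static void random_genome_cpp(double *g, int L, int n_active,
                              const double *bc, const double *bh,
                              const double *centroid) {
  const double pi_ = 3.141592653589793;
  for (int k = 0; k < 3; ++k)
    g[k] = bc[k] + (2 * unif_rand() - 1) * bh[k] - centroid[k];
  rnd_quat(g + 3);
  for (int k = 0; k < n_active; ++k) g[7 + k] = (2 * unif_rand() - 1) * pi_;
  (void)L;
}

static void perturb_genome_cpp(double *g, int L, double st, double sr) {
  for (int k = 0; k < 3; ++k) g[k] += norm_rand() * st;
  quat_compose_axis(g + 3, norm_rand() * sr);
  for (int k = 7; k < L; ++k) g[k] += norm_rand() * sr;
}

static void mutate_genome_cpp(double *g, int L, double rate,
                              double st, double sr) {
  for (int k = 0; k < 3; ++k)
    if (unif_rand() < rate) g[k] += norm_rand() * st;
  if (unif_rand() < rate) quat_compose_axis(g + 3, norm_rand() * sr);
  for (int k = 7; k < L; ++k)
    if (unif_rand() < rate) g[k] += norm_rand() * sr;
  norm_quat_part(g);
}

// [[Rcpp::export]]
List cpp_ga_run(NumericMatrix ref, NumericVector centroid,
                IntegerVector edge_a, IntegerVector edge_b, List edge_moving,
                IntegerVector edge_slot, NumericVector edge_fixed,
                List field, List cfg, Nullable<NumericVector> parent_genome,
                NumericVector box_center, NumericVector box_half,
                int n_active) {
  int pop_n = as<int>(cfg["population_size"]);
  int budget = as<int>(cfg["ga_num_evals"]);
  double mut = as<double>(cfg["mutation_rate"]);
  double cx = as<double>(cfg["crossover_rate"]);
  int ls_steps = as<int>(cfg["local_search_steps"]);
  int L = 7 + n_active;
  int natoms = ref.nrow();
  std::vector<double> pop((size_t)pop_n * L), npop((size_t)pop_n * L);
  std::vector<double> scores(pop_n), nscores(pop_n), xyz;

  if (parent_genome.isNotNull()) {
    NumericVector pg(parent_genome);
    for (int j = 0; j < L; ++j) pop[j] = pg[j];
    for (int i = 1; i < pop_n; ++i) {
      for (int j = 0; j < L; ++j) pop[(size_t)i * L + j] = pg[j];
      perturb_genome_cpp(&pop[(size_t)i * L], L, 1.0, 0.1);
    }
  } else {
    for (int i = 0; i < pop_n; ++i)
      random_genome_cpp(&pop[(size_t)i * L], L, n_active,
                        &box_center[0], &box_half[0], &centroid[0]);
  }
  long evals = 0;
  std::vector<double> history;
  for (int i = 0; i < pop_n; ++i) {
    genome_coords(ref, centroid, edge_a, edge_b, edge_moving, edge_slot,
                  edge_fixed, &pop[(size_t)i * L], n_active, xyz);
    scores[i] = score_coords(xyz, natoms, field);
  }
  evals += pop_n;
  int bi = 0;
  for (int i = 1; i < pop_n; ++i) if (scores[i] < scores[bi]) bi = i;
  std::vector<double> best_g(pop.begin() + (size_t)bi * L,
                             pop.begin() + (size_t)bi * L + L);
  double best_s = scores[bi];
  history.push_back(best_s);
  int ls_n = ls_steps > 0 ? std::max(1, pop_n / 10) : 0;
  std::vector<int> ord(pop_n);
  std::vector<double> cand(L);
  // reserve ~10% of the budget for an annealed polish of the overall best
  int polish = budget / 10;
  int ga_budget = budget - polish;

  while (evals + pop_n <= ga_budget) {
    // elitism
    for (int j = 0; j < L; ++j) npop[j] = best_g[j];
    int i = 1;
    while (i < pop_n) {
      int a1 = (int)(unif_rand() * pop_n), a2 = (int)(unif_rand() * pop_n);
      if (a1 >= pop_n) a1 = pop_n - 1; if (a2 >= pop_n) a2 = pop_n - 1;
      int p1 = scores[a1] <= scores[a2] ? a1 : a2;
      a1 = (int)(unif_rand() * pop_n); a2 = (int)(unif_rand() * pop_n);
      if (a1 >= pop_n) a1 = pop_n - 1; if (a2 >= pop_n) a2 = pop_n - 1;
      int p2 = scores[a1] <= scores[a2] ? a1 : a2;
      double *g1 = &npop[(size_t)i * L];
      double *g2 = (i + 1 < pop_n) ? &npop[(size_t)(i + 1) * L] : cand.data();
      for (int j = 0; j < L; ++j) g1[j] = pop[(size_t)p1 * L + j];
      for (int j = 0; j < L; ++j) g2[j] = pop[(size_t)p2 * L + j];
      if (unif_rand() < cx) {
        // two-point crossover on distinct sorted cut points
        int c1 = 1 + (int)(unif_rand() * L), c2 = 1 + (int)(unif_rand() * L);
        while (c2 == c1) c2 = 1 + (int)(unif_rand() * L);
        if (c1 > c2) std::swap(c1, c2);
        for (int j = c1; j < c2; ++j) std::swap(g1[j], g2[j]);
        norm_quat_part(g1); norm_quat_part(g2);
      }
      mutate_genome_cpp(g1, L, mut, 1.0, 0.1);
      if (i + 1 < pop_n) mutate_genome_cpp(g2, L, mut, 1.0, 0.1);
      i += 2;
    }
    for (int k = 0; k < pop_n; ++k) {
      genome_coords(ref, centroid, edge_a, edge_b, edge_moving, edge_slot,
                    edge_fixed, &npop[(size_t)k * L], n_active, xyz);
      nscores[k] = score_coords(xyz, natoms, field);
    }
    evals += pop_n;
    if (ls_n > 0) {
      for (int k = 0; k < pop_n; ++k) ord[k] = k;
      std::partial_sort(ord.begin(), ord.begin() + ls_n, ord.end(),
                        [&](int x, int y) { return nscores[x] < nscores[y]; });
      for (int t = 0; t < ls_n; ++t) {
        int j = ord[t];
        for (int s = 0; s < ls_steps; ++s) {
          if (evals + 1 > budget) break;
          for (int jj = 0; jj < L; ++jj) cand[jj] = npop[(size_t)j * L + jj];
          perturb_genome_cpp(cand.data(), L, 0.3, 0.03);
          genome_coords(ref, centroid, edge_a, edge_b, edge_moving, edge_slot,
                        edge_fixed, cand.data(), n_active, xyz);
          double cs = score_coords(xyz, natoms, field);
          ++evals;
          if (cs < nscores[j]) {
            for (int jj = 0; jj < L; ++jj) npop[(size_t)j * L + jj] = cand[jj];
            nscores[j] = cs;
          }
        }
      }
    }
    pop.swap(npop); scores.swap(nscores);
    bi = 0;
    for (int k = 1; k < pop_n; ++k) if (scores[k] < scores[bi]) bi = k;
    if (scores[bi] < best_s) {
      best_s = scores[bi];
      std::copy(pop.begin() + (size_t)bi * L,
                pop.begin() + (size_t)bi * L + L, best_g.begin());
    }
    history.push_back(best_s);
  }
  // polish: greedy hill-climb on the best genome with shrinking step sizes
  {
    double sig_t = 0.5, sig_r = 0.05;
    int stage = std::max(1, polish / 5), in_stage = 0;
    while (evals + 1 <= budget) {
      for (int j = 0; j < L; ++j) cand[j] = best_g[j];
      // coordinate-wise move: translation block, orientation, or one torsion
      int pick = (int)(unif_rand() * (2 + n_active));
      if (pick <= 0) {
        for (int k = 0; k < 3; ++k) cand[k] += norm_rand() * sig_t;
      } else if (pick == 1 || pick >= 2 + n_active) {
        quat_compose_axis(cand.data() + 3, norm_rand() * sig_r);
      } else {
        cand[7 + (pick - 2)] += norm_rand() * sig_r;
      }
      genome_coords(ref, centroid, edge_a, edge_b, edge_moving, edge_slot,
                    edge_fixed, cand.data(), n_active, xyz);
      double cs = score_coords(xyz, natoms, field);
      ++evals;
      if (cs < best_s) { best_s = cs; std::copy(cand.begin(), cand.end(),
                                                best_g.begin()); }
      if (++in_stage >= stage) { in_stage = 0; sig_t *= 0.4; sig_r *= 0.4; }
    }
    history.push_back(best_s);
  }
  return List::create(_["genome"] = NumericVector(best_g.begin(), best_g.end()),
                      _["score"] = best_s,
                      _["evals"] = (double)evals,
                      _["history"] = NumericVector(history.begin(), history.end()));
}
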