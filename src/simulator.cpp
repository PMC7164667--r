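// Core of the lattice-free cellular-particle spheroid simulator.
// Positions are in micrometres, time in minutes. Diffusion lengths are
// interpreted in millimetres where alpha/D (per mm^2) enters.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <random>
#include <cmath>
using namespace Rcpp;

static inline double sq(double v) { return v * v; }

// ---- radial growth-source profile -----------------------------------------
// Steady state of dR/dt = D d2R/dx2 - alpha on depth nodes x_i = i*dx
// (x = depth below the spheroid surface), Dirichlet R_s at the surface node,
// zero-flux at the innermost node, consumption only in occupied shells,
// profile clamped at 0 (projected Gauss-Seidel; the clamp realizes the free
// boundary where the source runs out).
static std::vector<double> shell_profile(double Rs, int m, double dx_um,
                                         double alpha_over_D_mm2,
                                         const std::vector<int>& occ) {
  std::vector<double> N(m, 0.0);
  if (m < 1) return N;
  N[0] = Rs;
  if (m == 1) return N;
  double dx_mm = dx_um / 1000.0;
  double c = alpha_over_D_mm2 * dx_mm * dx_mm; // consumption per node
  for (int sweep = 0; sweep < 100000; ++sweep) {
    double delta = 0.0;
    for (int i = 1; i < m; ++i) {
      double nb = (i < m - 1) ? 0.5 * (N[i - 1] + N[i + 1])
                              : N[i - 1]; // mirror ghost: zero flux
      double v = nb - 0.5 * c * (occ[i] ? 1.0 : 0.0);
      if (v < 0.0) v = 0.0;
      delta = std::max(delta, std::fabs(v - N[i]));
      N[i] = v;
    }
    if (delta < 1e-12 * std::max(1.0, Rs)) break;
  }
  return N;
}

// [[Rcpp::export]]
NumericVector cpp_shell_profile(double Rs, int n_shells, double shell_width_um,
                                double alpha_over_D, LogicalVector occupied) {
  std::vector<int> occ(n_shells, 1);
  if (occupied.size() == n_shells)
    for (int i = 0; i < n_shells; ++i) occ[i] = occupied[i] ? 1 : 0;
  std::vector<double> N = shell_profile(Rs, n_shells, shell_width_um,
                                        alpha_over_D, occ);
  return wrap(N);
}

// ---- neighbour grid --------------------------------------------------------
struct Grid {
  double cell;
  std::unordered_map<long long, std::vector<int> > cells;
  static long long key(int ix, int iy, int iz) {
    return (static_cast<long long>(ix + 1048576) << 42) ^
           (static_cast<long long>(iy + 1048576) << 21) ^
           static_cast<long long>(iz + 1048576);
  }
  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, double cell_size) {
    cell = cell_size;
    cells.clear();
    for (size_t i = 0; i < x.size(); ++i) {
      int ix = (int)std::floor(x[i] / cell), iy = (int)std::floor(y[i] / cell),
          iz = (int)std::floor(z[i] / cell);
      cells[key(ix, iy, iz)].push_back((int)i);
    }
  }
  template <class F>
  void for_neighbours(const std::vector<double>& x, const std::vector<double>& y,
                      const std::vector<double>& z, int i, F fun) const {
    int ix = (int)std::floor(x[i] / cell), iy = (int)std::floor(y[i] / cell),
        iz = (int)std::floor(z[i] / cell);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(key(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (int j : it->second)
            if (j != i) fun(j);
        }
  }
};

// [[Rcpp::export]]
IntegerVector cpp_density_bruteforce(NumericMatrix pos, double cutoff) {
  int n = pos.nrow();
  IntegerVector dens(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double r2 = sq(pos(i, 0) - pos(j, 0)) + sq(pos(i, 1) - pos(j, 1)) +
                  sq(pos(i, 2) - pos(j, 2));
      if (r2 < cutoff * cutoff) {
        dens[i]++;
        dens[j]++;
      }
    }
  return dens;
}

// [[Rcpp::export]]
IntegerVector cpp_density_grid(NumericMatrix pos, double cutoff) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0);
    y[i] = pos(i, 1);
    z[i] = pos(i, 2);
  }
  Grid g;
  g.build(x, y, z, cutoff);
  IntegerVector dens(n, 0);
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    int d = 0;
    g.for_neighbours(x, y, z, i, [&](int j) {
      double r2 = sq(x[i] - x[j]) + sq(y[i] - y[j]) + sq(z[i] - z[j]);
      if (r2 < c2) ++d;
    });
    dens[i] = d;
  }
  return dens;
}

// ---- pair force ------------------------------------------------------------
static inline double pair_force_val(double r, double k, double R, double G,
                                    double r0) {
  if (r >= G * r0) return 0.0;
  return k * (1.0 - r / (R * r0)) * (1.0 - r / (G * r0));
}

// ---- full simulation -------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_simulation(NumericMatrix init_pos, IntegerVector init_gen,
                        NumericVector init_age, List par) {
  const double dt = as<double>(par["dt_min"]);
  const double total_min = as<double>(par["total_min"]);
  const double k = as<double>(par["k"]);
  const double Rrep = as<double>(par["R"]);
  const double Gatt = as<double>(par["G"]);
  const double r0 = as<double>(par["cell_diameter_um"]);
  const double eta = as<double>(par["eta"]);
  const double max_disp = as<double>(par["max_step_frac"]) * r0;
  const double capacity = as<double>(par["capacity"]);
  const double aD = as<double>(par["alpha_over_D"]);
  const double max_depth = as<double>(par["max_depth_um"]);
  const double shell_w = as<double>(par["shell_width_um"]);
  const double Tmin = as<double>(par["min_cycle_h"]) * 60.0;
  const double Kc = as<double>(par["Kc"]);
  const double Ke = as<double>(par["Ke"]);
  const double eps_mob = as<double>(par["eps_mobility"]);
  const double max_particles = as<double>(par["max_particles"]);
  const int seed = as<int>(par["seed"]);
  const double snap_every = as<double>(par["snapshot_every_min"]);
  const double cutoff = Gatt * r0;

  int n = init_pos.nrow();
  std::vector<double> x(n), y(n), z(n), age(n);
  std::vector<int> gen(n);
  for (int i = 0; i < n; ++i) {
    x[i] = init_pos(i, 0);
    y[i] = init_pos(i, 1);
    z[i] = init_pos(i, 2);
    gen[i] = init_gen[i];
    age[i] = init_age[i];
  }

  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  auto unit_vec = [&](double& ux, double& uy, double& uz) {
    double nrm = 0.0;
    do {
      ux = gauss(rng);
      uy = gauss(rng);
      uz = gauss(rng);
      nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
    } while (nrm < 1e-12);
    ux /= nrm;
    uy /= nrm;
    uz /= nrm;
  };

  double consumed = 0.0;
  Grid grid;
  std::vector<double> dens, Nz, mob, Tz, fx, fy, fz, dist;

  List snapshots;
  std::vector<double> idx_day, idx_n, idx_diam, idx_Rt;

  int n_steps = (int)std::round(total_min / dt);
  double next_snap = 0.0;

  for (int step_i = 0; step_i <= n_steps; ++step_i) {
    double t_min = step_i * dt;
    n = (int)x.size();

    // residual source index (Eq 2 style budget)
    double Rt = capacity > 0.0
                    ? std::max(0.0, 1.0 - consumed / capacity)
                    : 0.0;
    if (!R_finite(capacity)) Rt = 1.0;

    // geometry
    double cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < n; ++i) {
      cx += x[i];
      cy += y[i];
      cz += z[i];
    }
    cx /= n;
    cy /= n;
    cz /= n;
    dist.assign(n, 0.0);
    double rmax = 0.0;
    for (int i = 0; i < n; ++i) {
      dist[i] = std::sqrt(sq(x[i] - cx) + sq(y[i] - cy) + sq(z[i] - cz));
      rmax = std::max(rmax, dist[i]);
    }
    double radius = rmax + r0 / 2.0;

    // density (neighbour count within the attraction range)
    grid.build(x, y, z, cutoff);
    dens.assign(n, 0.0);
    double c2 = cutoff * cutoff;
    for (int i = 0; i < n; ++i) {
      int d = 0;
      grid.for_neighbours(x, y, z, i, [&](int j) {
        double r2 = sq(x[i] - x[j]) + sq(y[i] - y[j]) + sq(z[i] - z[j]);
        if (r2 < c2) ++d;
      });
      dens[i] = d;
    }

    // radial growth-source profile and per-particle supply
    double span = std::min(radius, max_depth);
    int m = std::max(1, (int)std::ceil(span / shell_w));
    std::vector<int> occ(m, 0);
    std::vector<int> shell_of(n);
    for (int i = 0; i < n; ++i) {
      double depth = radius - dist[i];
      int s = std::min(m - 1, (int)std::floor(depth / shell_w));
      shell_of[i] = (depth > max_depth) ? -1 : s;
      if (shell_of[i] >= 0) occ[s] = 1;
    }
    std::vector<double> prof = shell_profile(Rt, m, shell_w, aD, occ);
    Nz.assign(n, 0.0);
    for (int i = 0; i < n; ++i)
      Nz[i] = (shell_of[i] >= 0) ? prof[shell_of[i]] : 0.0;

    // mobility (normalized by the outermost particle's centre distance, so
    // the outermost particle has mobility 1) and cycle time
    mob.assign(n, eps_mob);
    Tz.assign(n, R_PosInf);
    for (int i = 0; i < n; ++i) {
      mob[i] = rmax > 0.0 ? std::max(eps_mob, dist[i] / rmax) : eps_mob;
      if (Nz[i] > 0.0) {
        double supply = (1.0 + sq(Kc / Nz[i])) / (1.0 + sq(Kc));
        double env = 1.0 + Ke * dens[i] / mob[i];
        Tz[i] = Tmin * supply * env;
      }
    }

    // snapshot before state advances (records the state at t_min)
    if (t_min >= next_snap - 1e-9 || step_i == n_steps) {
      snapshots.push_back(List::create(
          _["time_min"] = t_min, _["x_um"] = wrap(x), _["y_um"] = wrap(y),
          _["z_um"] = wrap(z), _["generation"] = wrap(gen),
          _["cycle_age_min"] = wrap(age), _["N"] = wrap(Nz),
          _["density"] = wrap(dens), _["mobility"] = wrap(mob),
          _["R_t"] = Rt, _["diameter_um"] = 2.0 * radius));
      idx_day.push_back(t_min / 1440.0);
      idx_n.push_back(n);
      idx_diam.push_back(2.0 * radius);
      idx_Rt.push_back(Rt);
      while (next_snap <= t_min + 1e-9) next_snap += snap_every;
    }
    if (step_i == n_steps) break;

    // consumption accrues for supplied particles (1 unit per particle-minute)
    int n_supplied = 0;
    for (int i = 0; i < n; ++i)
      if (Nz[i] > 0.0) ++n_supplied;
    consumed += (double)n_supplied * dt;

    // aging and division (suspended at the carrying-capacity guard)
    std::vector<int> dividing;
    for (int i = 0; i < n; ++i) {
      age[i] += dt;
      if (Nz[i] > 0.0 && age[i] >= Tz[i] &&
          (double)(n + (int)dividing.size()) < max_particles)
        dividing.push_back(i);
    }
    for (int idx : dividing) {
      double ux, uy, uz;
      unit_vec(ux, uy, uz);
      double off = r0 / 4.0;
      double px = x[idx], py = y[idx], pz = z[idx];
      // parent replaced by daughter 1; daughter 2 appended
      x[idx] = px - off * ux;
      y[idx] = py - off * uy;
      z[idx] = pz - off * uz;
      gen[idx] += 1;
      age[idx] = 0.0;
      x.push_back(px + off * ux);
      y.push_back(py + off * uy);
      z.push_back(pz + off * uz);
      gen.push_back(gen[idx]);
      age.push_back(0.0);
    }
    n = (int)x.size();

    // overdamped relaxation under pairwise forces
    grid.build(x, y, z, cutoff);
    fx.assign(n, 0.0);
    fy.assign(n, 0.0);
    fz.assign(n, 0.0);
    for (int i = 0; i < n; ++i) {
      grid.for_neighbours(x, y, z, i, [&](int j) {
        double dxp = x[i] - x[j], dyp = y[i] - y[j], dzp = z[i] - z[j];
        double r = std::sqrt(dxp * dxp + dyp * dyp + dzp * dzp);
        if (r < 1e-9) { // coincident particles: deterministic-seeded jitter
          double ux, uy, uz;
          unit_vec(ux, uy, uz);
          dxp = ux * 1e-3 * r0;
          dyp = uy * 1e-3 * r0;
          dzp = uz * 1e-3 * r0;
          r = 1e-3 * r0;
        }
        double F = pair_force_val(r, k, Rrep, Gatt, r0);
        if (F != 0.0) {
          fx[i] += F * dxp / r;
          fy[i] += F * dyp / r;
          fz[i] += F * dzp / r;
        }
      });
    }
    for (int i = 0; i < n; ++i) {
      double mx = eta * fx[i], my = eta * fy[i], mz = eta * fz[i];
      double nrm = std::sqrt(mx * mx + my * my + mz * mz);
      if (nrm > max_disp) {
        mx *= max_disp / nrm;
        my *= max_disp / nrm;
        mz *= max_disp / nrm;
      }
      x[i] += mx;
      y[i] += my;
      z[i] += mz;
    }
  }

  return List::create(
      _["snapshots"] = snapshots,
      _["index"] = DataFrame::create(_["day"] = wrap(idx_day),
                                     _["n_particles"] = wrap(idx_n),
                                     _["diameter_um"] = wrap(idx_diam),
                                     _["R_t"] = wrap(idx_Rt)),
      _["consumed"] = consumed);
}

// ---- Monte-Carlo random close packing --------------------------------------
// Overlap relaxation with culling: start from an FCC-density worth of random
// centres, repeatedly push overlapping pairs apart and project back into the
// container; if overlaps persist, remove the worst offender. The surviving
// count estimates a random close packing of the container.
// [[Rcpp::export]]
int cpp_random_packing(double container_diameter, double sphere_diameter,
                       int seed, int relax_iter) {
  double Rc = container_diameter / 2.0, rs = sphere_diameter / 2.0;
  double rmax = Rc - rs; // centre confinement
  double d = sphere_diameter;
  int n0 = (int)std::floor(std::pow(container_diameter / sphere_diameter, 3.0) *
                           M_PI / (3.0 * std::sqrt(2.0)));
  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  std::vector<double> x, y, z;
  while ((int)x.size() < n0) {
    double px = unif(rng) * rmax, py = unif(rng) * rmax, pz = unif(rng) * rmax;
    if (px * px + py * py + pz * pz <= rmax * rmax) {
      x.push_back(px);
      y.push_back(py);
      z.push_back(pz);
    }
  }
  double tol = 1e-3 * d;
  Grid grid;
  int sweeps_per_round = 20;
  int rounds = std::max(1, relax_iter); // at most one cull per round
  for (int round = 0; round < rounds; ++round) {
    int n = (int)x.size();
    double worst = 0.0;
    int worst_i = -1;
    for (int sweep = 0; sweep < sweeps_per_round; ++sweep) {
      grid.build(x, y, z, d);
      worst = 0.0;
      worst_i = -1;
      std::vector<double> ox(n, 0.0), oy(n, 0.0), oz(n, 0.0), osum(n, 0.0);
      for (int i = 0; i < n; ++i) {
        grid.for_neighbours(x, y, z, i, [&](int j) {
          if (j <= i) return;
          double dxp = x[i] - x[j], dyp = y[i] - y[j], dzp = z[i] - z[j];
          double r = std::sqrt(dxp * dxp + dyp * dyp + dzp * dzp);
          if (r < d) {
            double push;
            if (r < 1e-9) {
              double ux = unif(rng), uy = unif(rng), uz = unif(rng);
              double nn = std::sqrt(ux * ux + uy * uy + uz * uz) + 1e-12;
              dxp = ux / nn;
              dyp = uy / nn;
              dzp = uz / nn;
              r = 1.0;
              push = d / 2.0;
            } else {
              push = 0.55 * (d - r); // slight over-relaxation
            }
            ox[i] += push * dxp / r;
            oy[i] += push * dyp / r;
            oz[i] += push * dzp / r;
            ox[j] -= push * dxp / r;
            oy[j] -= push * dyp / r;
            oz[j] -= push * dzp / r;
            osum[i] += d - r;
            osum[j] += d - r;
          }
        });
      }
      for (int i = 0; i < n; ++i) {
        x[i] += ox[i];
        y[i] += oy[i];
        z[i] += oz[i];
        double rr = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);
        if (rr > rmax) {
          x[i] *= rmax / rr;
          y[i] *= rmax / rr;
          z[i] *= rmax / rr;
        }
        if (osum[i] > worst) {
          worst = osum[i];
          worst_i = i;
        }
      }
      if (worst <= tol) break;
    }
    if (worst <= tol) break;
    // cull the particle with the largest cumulative overlap
    if (worst_i >= 0) {
      x.erase(x.begin() + worst_i);
      y.erase(y.begin() + worst_i);
      z.erase(z.begin() + worst_i);
    }
  }
  return (int)x.size();
}
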