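#include <Rcpp.h>
#include "rng.h"
#include <vector>
#include <numeric>
using namespace Rcpp;

// Particle-based stochastic simulator of the GABA_B -> Gbetagamma -> GIRK
// cascade.  GABA molecules diffuse in 3D inside a reflecting box (effective
// diffusion already includes extracellular tortuosity) and are removed by a
// first-order sink; surface species live in a 2D parameterization of the
// dendritic membrane (axial u in [0, len], circumferential v periodic).
// Bimolecular events fire with probability k_micro * dt for pairs inside a
// reaction radius; k_micro is precomputed in R so that the well-mixed limit
// reproduces mass action exactly.

struct Gaba { double x, y, z; bool alive; };
struct Surf2 { double u, v; bool alive; };

static inline double wrap_v(double v, double circ) {
  double w = v / circ;
  return (w - std::floor(w)) * circ;
}

static inline double dv_wrap(double a, double b, double circ) {
  double d = std::fabs(a - b);
  return d > circ / 2 ? circ - d : d;
}

static inline double reflect01(double x, double lo, double hi) {
  // single reflection is enough for small steps
  if (x < lo) x = 2 * lo - x;
  if (x > hi) x = 2 * hi - x;
  if (x < lo) x = lo;
  if (x > hi) x = hi;
  return x;
}

// [[Rcpp::export]]
List sim_cascade_cpp(List geom, NumericMatrix release, List surf,
                     List rates, double dt, double t_end,
                     double report_every, int seed) {
  // geometry
  NumericVector box = geom["box"];           // lx, ly, lz (um)
  double dend_r = as<double>(geom["dend_radius"]);
  double dend_y0 = as<double>(geom["dend_y0"]);
  double dend_z0 = as<double>(geom["dend_z0"]);
  double surf_len = as<double>(geom["surf_len"]);
  double surf_circ = as<double>(geom["surf_circ"]);
  bool excl_dend = as<bool>(geom["exclude_dendrite"]);

  // surface molecules
  NumericMatrix gm = surf["gabab"];   // u, v, size, mobile, compartment
  NumericMatrix km = surf["girk"];    // u, v, compartment (one row per channel)
  NumericMatrix tm = surf["trimer"];  // u, v

  int nG = gm.nrow(), nK = km.nrow(), nT0 = tm.nrow();
  std::vector<double> g_u(nG), g_v(nG);
  std::vector<int> g_size(nG), g_active(nG, 0), g_virgin(nG);
  std::vector<bool> g_mobile(nG);
  std::vector<int> g_comp(nG);
  for (int i = 0; i < nG; ++i) {
    g_u[i] = gm(i, 0); g_v[i] = gm(i, 1);
    g_size[i] = (int)gm(i, 2); g_virgin[i] = g_size[i];
    g_mobile[i] = gm(i, 3) > 0.5; g_comp[i] = (int)gm(i, 4);
  }
  std::vector<double> k_u(nK), k_v(nK);
  std::vector<int> k_bound(nK, 0), k_comp(nK);
  std::vector<bool> k_opened(nK, false);
  for (int i = 0; i < nK; ++i) {
    k_u[i] = km(i, 0); k_v[i] = km(i, 1); k_comp[i] = (int)km(i, 2);
  }
  std::vector<Surf2> trimer(nT0);
  for (int i = 0; i < nT0; ++i)
    trimer[i] = Surf2{tm(i, 0), tm(i, 1), true};
  std::vector<Surf2> gbg;

  // rates (all precomputed to per-ms microscopic constants in R)
  double D_gaba = as<double>(rates["D_gaba"]);
  double D_rec = as<double>(rates["D_rec"]);
  double D_gbg = as<double>(rates["D_gbg"]);
  double k_clear = as<double>(rates["k_clear"]);
  double p_bind = as<double>(rates["k_on_micro"]) * dt;   // per free receptor
  double rho_bind = as<double>(rates["rho_bind"]);
  double k_off = as<double>(rates["k_off"]);
  double p_cat1 = as<double>(rates["k_cat_micro"]) * dt;  // per active rec.
  double rho_cat = as<double>(rates["rho_cat"]);
  double p_gb = as<double>(rates["k_gb_micro"]) * dt;     // per channel
  double rho_girk = as<double>(rates["rho_girk"]);
  double k_gu = as<double>(rates["k_gu"]);
  double k_re = as<double>(rates["k_re"]);

  double p_clear = 1.0 - std::exp(-k_clear * dt);
  double p_off = 1.0 - std::exp(-k_off * dt);
  double p_unb = 1.0 - std::exp(-k_gu * dt);
  double p_reass = 1.0 - std::exp(-k_re * dt);
  double sg_g = std::sqrt(2.0 * D_gaba * dt);
  double sg_r = std::sqrt(2.0 * D_rec * dt);
  double sg_b = std::sqrt(2.0 * D_gbg * dt);

  // stability: largest per-step event probability must stay below 0.2
  double pmax = std::max(std::max(p_bind * 8, p_cat1 * 8),
                         std::max(p_gb, std::max(p_clear, p_off)));
  if (pmax > 0.2)
    stop("time step too large for the fastest rate (p_event = %f > 0.2)",
         pmax);

  XRng rng((uint64_t)seed);
  std::vector<Gaba> gaba;
  gaba.reserve(100000);

  int n_steps = (int)std::ceil(t_end / dt);
  int rep_stride = std::max(1, (int)std::round(report_every / dt));
  int n_rep = n_steps / rep_stride + 1;

  std::vector<double> r_time; r_time.reserve(n_rep);
  std::vector<int> r_gaba, r_act_sh, r_act_sp, r_cum_sh, r_cum_sp,
      r_gbg_free, r_gbg_cum, r_trimer, r_open_sh, r_open_sp,
      r_cumopen_sh, r_cumopen_sp, r_gbg_bound;

  int cum_act[2] = {0, 0};     // shaft, spine
  int cum_open[2] = {0, 0};
  long cum_gbg = 0;
  int next_rel = 0;

  auto report = [&](double t) {
    int ngab = 0;
    for (auto &g : gaba) if (g.alive) ++ngab;
    int act[2] = {0, 0};
    for (int i = 0; i < nG; ++i) act[g_comp[i]] += g_active[i];
    int nbg = 0;
    for (auto &b : gbg) if (b.alive) ++nbg;
    int ntr = 0;
    for (auto &x : trimer) if (x.alive) ++ntr;
    int open[2] = {0, 0}; int nbound = 0;
    for (int i = 0; i < nK; ++i) {
      nbound += k_bound[i];
      if (k_bound[i] == 4) open[k_comp[i]]++;
    }
    r_time.push_back(t);
    r_gaba.push_back(ngab);
    r_act_sh.push_back(act[0]); r_act_sp.push_back(act[1]);
    r_cum_sh.push_back(cum_act[0]); r_cum_sp.push_back(cum_act[1]);
    r_gbg_free.push_back(nbg); r_gbg_cum.push_back((int)cum_gbg);
    r_trimer.push_back(ntr);
    r_open_sh.push_back(open[0]); r_open_sp.push_back(open[1]);
    r_cumopen_sh.push_back(cum_open[0]); r_cumopen_sp.push_back(cum_open[1]);
    r_gbg_bound.push_back(nbound);
  };
  report(0.0);

  for (int s = 1; s <= n_steps; ++s) {
    double t = s * dt;
    // 1. releases in (t - dt, t]
    while (next_rel < release.nrow() && release(next_rel, 0) <= t) {
      int n_mol = (int)release(next_rel, 4);
      for (int m = 0; m < n_mol; ++m)
        gaba.push_back(Gaba{release(next_rel, 1), release(next_rel, 2),
                            release(next_rel, 3), true});
      ++next_rel;
    }
    // 2. GABA diffusion + clearance
    for (auto &g : gaba) {
      if (!g.alive) continue;
      if (rng.unif() < p_clear) { g.alive = false; continue; }
      double nx = reflect01(g.x + sg_g * rng.norm(), 0, box[0]);
      double ny = reflect01(g.y + sg_g * rng.norm(), 0, box[1]);
      double nz = reflect01(g.z + sg_g * rng.norm(), 0, box[2]);
      if (excl_dend) {
        double dy = ny - dend_y0, dz = nz - dend_z0;
        if (dy * dy + dz * dz < dend_r * dend_r) continue;  // reject
      }
      g.x = nx; g.y = ny; g.z = nz;
    }
    // 3. mobile receptor clusters diffuse
    if (sg_r > 0) {
      for (int i = 0; i < nG; ++i) {
        if (!g_mobile[i]) continue;
        g_u[i] = reflect01(g_u[i] + sg_r * rng.norm(), 0, surf_len);
        g_v[i] = wrap_v(g_v[i] + sg_r * rng.norm(), surf_circ);
      }
    }
    // receptor cluster 3D positions
    std::vector<double> cx(nG), cy(nG), cz(nG);
    for (int i = 0; i < nG; ++i) {
      double th = g_v[i] / (surf_circ / (2 * M_PI)) ;
      cx[i] = g_u[i];
      cy[i] = dend_y0 + dend_r * std::cos(th);
      cz[i] = dend_z0 + dend_r * std::sin(th);
    }
    // 4. GABA-receptor binding
    double rb2 = rho_bind * rho_bind;
    for (auto &g : gaba) {
      if (!g.alive) continue;
      if (excl_dend) {
        double dy = g.y - dend_y0, dz = g.z - dend_z0;
        double rr = std::sqrt(dy * dy + dz * dz);
        if (std::fabs(rr - dend_r) > rho_bind) continue;
      }
      for (int i = 0; i < nG; ++i) {
        int nfree = g_size[i] - g_active[i];
        if (nfree <= 0) continue;
        double dx = g.x - cx[i], dy = g.y - cy[i], dz = g.z - cz[i];
        if (dx * dx + dy * dy + dz * dz > rb2) continue;
        if (rng.unif() < p_bind * nfree) {
          g_active[i]++;
          if (rng.unif() * nfree < g_virgin[i]) {
            g_virgin[i]--; cum_act[g_comp[i]]++;
          }
          g.alive = false;
          break;
        }
      }
    }
    // 5. receptor deactivation
    for (int i = 0; i < nG; ++i) {
      int a = g_active[i];
      for (int j = 0; j < a; ++j)
        if (rng.unif() < p_off) g_active[i]--;
    }
    // 6. catalysis: active receptor clusters convert nearby trimers
    for (int i = 0; i < nG; ++i) {
      if (g_active[i] == 0) continue;
      double pc = p_cat1 * g_active[i];
      for (auto &tr : trimer) {
        if (!tr.alive) continue;
        double du = tr.u - g_u[i];
        double dv = dv_wrap(tr.v, g_v[i], surf_circ);
        if (du * du + dv * dv > rho_cat * rho_cat) continue;
        if (rng.unif() < pc) {
          tr.alive = false;
          gbg.push_back(Surf2{tr.u, tr.v, true});
          ++cum_gbg;
        }
      }
    }
    // 7.-8. Gbg diffusion and GIRK binding
    for (auto &b : gbg) {
      if (!b.alive) continue;
      b.u = reflect01(b.u + sg_b * rng.norm(), 0, surf_len);
      b.v = wrap_v(b.v + sg_b * rng.norm(), surf_circ);
      for (int i = 0; i < nK; ++i) {
        if (k_bound[i] >= 4) continue;
        double du = b.u - k_u[i];
        double dv = dv_wrap(b.v, k_v[i], surf_circ);
        if (du * du + dv * dv > rho_girk * rho_girk) continue;
        if (rng.unif() < p_gb) {
          k_bound[i]++;
          if (k_bound[i] == 4 && !k_opened[i]) {
            k_opened[i] = true; cum_open[k_comp[i]]++;
          }
          b.alive = false;
          break;
        }
      }
      if (!b.alive) continue;
      // 10. reassociation into a heterotrimer
      if (rng.unif() < p_reass) {
        b.alive = false;
        trimer.push_back(Surf2{b.u, b.v, true});
      }
    }
    // 9. Gbg unbinding from GIRK
    for (int i = 0; i < nK; ++i) {
      int bnd = k_bound[i];
      for (int j = 0; j < bnd; ++j) {
        if (rng.unif() < p_unb) {
          k_bound[i]--;
          gbg.push_back(Surf2{k_u[i], k_v[i], true});
        }
      }
    }
    if (s % rep_stride == 0) report(t);
  }

  return List::create(
    _["time"] = wrap(r_time), _["gaba_free"] = wrap(r_gaba),
    _["gabab_active_shaft"] = wrap(r_act_sh),
    _["gabab_active_spine"] = wrap(r_act_sp),
    _["gabab_cum_shaft"] = wrap(r_cum_sh),
    _["gabab_cum_spine"] = wrap(r_cum_sp),
    _["gbg_free"] = wrap(r_gbg_free), _["gbg_cum"] = wrap(r_gbg_cum),
    _["trimer"] = wrap(r_trimer), _["gbg_bound"] = wrap(r_gbg_bound),
    _["girk_open_shaft"] = wrap(r_open_sh),
    _["girk_open_spine"] = wrap(r_open_sp),
    _["girk_cum_shaft"] = wrap(r_cumopen_sh),
    _["girk_cum_spine"] = wrap(r_cumopen_sp),
    _["total_receptors"] = wrap(std::accumulate(g_size.begin(),
                                                g_size.end(), 0)),
    _["total_channels"] = wrap(nK));
}
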