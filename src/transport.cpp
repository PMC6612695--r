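// Condensed-history proton transport through the collimated scanning
// nozzle and water phantom, with per-channel (collimator-scattered vs
// unscattered) voxel tallies of deposited energy and energy * LET.
//
// Conventions: cm, MeV; +z is the beam direction with z = 0 at the water
// surface.  One counter-based random stream per primary index, so results
// depend only on (seed, primary index) and never on execution order.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

const double PROTON_M = 938.272;
const double E_CUT = 1.0;       // MeV: stop and deposit locally below this

// ---------------------------------------------------------------- RNG --
struct Rng {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;

  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t run_seed, uint64_t primary) {
    uint64_t x = run_seed ^ (primary * 0xD1B54A32D192ED03ULL + 0x9E3779B9ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
    has_spare = false;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u1;
    do { u1 = unif(); } while (u1 <= 1e-300);
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double a = 6.283185307179586 * unif();
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// ------------------------------------------------------- physics tables --
// material ids: 0 air, 1 absorber plastic, 2 brass, 3 water
struct Phys {
  int n;
  double le0, dle;
  std::vector<double> s_tab[4], r_tab[4];
  double strag_c[4], x0_cm[4], lambda_cm[4];

  // grid coordinate of an energy (tables are uniform in log E)
  inline double uof(double e) const {
    return (std::log(e) - le0) / dle;
  }
  inline double interp(const std::vector<double> &y, double u) const {
    if (u <= 0.0) return y[0];
    if (u >= n - 1) return y[n - 1];
    const int i = static_cast<int>(u);
    const double f = u - i;
    return y[i] * (1.0 - f) + y[i + 1] * f;
  }
  inline double S(int m, double u) const { return interp(s_tab[m], u); }
  inline double R(int m, double u) const { return interp(r_tab[m], u); }
};

inline double pv(double e) {
  const double etot = e + PROTON_M;
  return (etot * etot - PROTON_M * PROTON_M) / etot;
}

// --------------------------------------------------------------- scene --
struct Scn {
  double zb[7];
  double ap_x, ap_y;
  int region_mat[6];            // 0-based material id per region
  double region_corr[6], aperture_corr;
  int nx, ny, nz;
  double h, x0, y0;
  double max_step[4];
  double r_kill;
};

// ---------------------------------------------------------------- tally --
struct Tally {
  int nx, ny, nz, nb;
  std::vector<double> eps, epsl;
  void init(int nx_, int ny_, int nz_, int nb_) {
    nx = nx_; ny = ny_; nz = nz_; nb = nb_;
    eps.assign(static_cast<size_t>(nx) * ny * nz * 2 * nb, 0.0);
    epsl.assign(eps.size(), 0.0);
  }
  inline size_t idx(int ix, int iy, int iz, int ch, int b) const {
    return ix + static_cast<size_t>(nx) *
           (iy + static_cast<size_t>(ny) *
           (iz + static_cast<size_t>(nz) * (ch + 2 * static_cast<size_t>(b))));
  }
};

struct StepLog {
  bool enabled = false;
  std::vector<double> ix, iy, iz, eps, L, ch;
};

// deposit a (possibly clipped) segment into the voxel grid by exact
// slab-crossing traversal; energy shared by path-length fraction
void score_segment(const Scn &sc, Tally &tl, StepLog &lg,
                   double px, double py, double pz,
                   double dx, double dy, double dz,
                   double len, double edep, double L, int ch, int b) {
  if (edep <= 0.0 || len <= 0.0) return;
  const double gx1 = sc.x0 + sc.nx * sc.h;
  const double gy1 = sc.y0 + sc.ny * sc.h;
  const double gz1 = sc.nz * sc.h;
  double tmin = 0.0, tmax = len;
  const double p0[3] = {px, py, pz};
  const double dd[3] = {dx, dy, dz};
  const double lo[3] = {sc.x0, sc.y0, 0.0};
  const double hi[3] = {gx1, gy1, gz1};
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dd[a]) < 1e-12) {
      if (p0[a] < lo[a] || p0[a] >= hi[a]) return;
    } else {
      double t1 = (lo[a] - p0[a]) / dd[a];
      double t2 = (hi[a] - p0[a]) / dd[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    }
  }
  if (tmax <= tmin) return;
  // voxel walk (Amanatides-Woo)
  const double eps_t = 1e-10;
  double t = tmin + eps_t;
  int iv[3];
  double tnext[3], tdelta[3];
  int istep[3];
  for (int a = 0; a < 3; ++a) {
    double c = p0[a] + dd[a] * t;
    int i = static_cast<int>(std::floor((c - lo[a]) / sc.h));
    const int nmax = (a == 0 ? sc.nx : (a == 1 ? sc.ny : sc.nz));
    if (i < 0) i = 0;
    if (i >= nmax) i = nmax - 1;
    iv[a] = i;
    if (dd[a] > 1e-12) {
      istep[a] = 1;
      tnext[a] = (lo[a] + (i + 1) * sc.h - p0[a]) / dd[a];
      tdelta[a] = sc.h / dd[a];
    } else if (dd[a] < -1e-12) {
      istep[a] = -1;
      tnext[a] = (lo[a] + i * sc.h - p0[a]) / dd[a];
      tdelta[a] = -sc.h / dd[a];
    } else {
      istep[a] = 0;
      tnext[a] = 1e30;
      tdelta[a] = 1e30;
    }
  }
  double tcur = tmin;
  const double per_len = edep / len;
  while (tcur < tmax - eps_t) {
    int amin = 0;
    if (tnext[1] < tnext[amin]) amin = 1;
    if (tnext[2] < tnext[amin]) amin = 2;
    double tstop = std::min(tnext[amin], tmax);
    const double seg = tstop - tcur;
    if (seg > 0.0 &&
        iv[0] >= 0 && iv[0] < sc.nx &&
        iv[1] >= 0 && iv[1] < sc.ny &&
        iv[2] >= 0 && iv[2] < sc.nz) {
      const double share = per_len * seg;
      const size_t k = tl.idx(iv[0], iv[1], iv[2], ch, b);
      tl.eps[k] += share;
      tl.epsl[k] += share * L;
      if (lg.enabled) {
        lg.ix.push_back(iv[0]); lg.iy.push_back(iv[1]); lg.iz.push_back(iv[2]);
        lg.eps.push_back(share); lg.L.push_back(L); lg.ch.push_back(ch);
      }
    }
    tcur = tstop;
    if (tnext[amin] >= tmax) break;
    iv[amin] += istep[amin];
    tnext[amin] += tdelta[amin];
    if (iv[amin] < 0 || iv[amin] >= (amin == 0 ? sc.nx :
                                     (amin == 1 ? sc.ny : sc.nz))) break;
  }
}

struct Opts {
  bool no_scatter = false, no_straggle = false, no_nuclear = false;
  bool do_tally = true, do_log = false, do_ledger = false, do_zprof = false;
  double plane_z = NA_REAL;
  bool do_plane = false;
  double sad_x = 200.0, sad_y = 240.0, z_src = 0.0, dispersion = 0.006;
  int max_steps = 100000;
};

}  // namespace

// [[Rcpp::export(name = ".mc_engine")]]
List mc_engine(List phys_in, List scn_in, DataFrame spots, double seed,
               double weight_per_primary, int nbatch, List opts_in) {
  // ---- unpack physics ----
  Phys ph;
  NumericVector log_e = phys_in["log_e"];
  NumericMatrix log_s = phys_in["log_s"], log_r = phys_in["log_r"];
  NumericVector dens = phys_in["density"], za = phys_in["z_over_a"];
  NumericVector x0 = phys_in["x0_cm"], lam = phys_in["lambda_cm"];
  ph.n = log_e.size();
  ph.le0 = log_e[0];
  ph.dle = (log_e[ph.n - 1] - log_e[0]) / (ph.n - 1);
  for (int m = 0; m < 4; ++m) {
    ph.s_tab[m].assign(ph.n, 0.0);
    ph.r_tab[m].assign(ph.n, 0.0);
    for (int i = 0; i < ph.n; ++i) {
      ph.s_tab[m][i] = std::exp(log_s(i, m));
      ph.r_tab[m][i] = std::exp(log_r(i, m));
    }
    ph.strag_c[m] = 0.1569 * dens[m] * za[m];
    ph.x0_cm[m] = x0[m];
    ph.lambda_cm[m] = lam[m];
  }

  // ---- unpack scene ----
  Scn sc;
  NumericVector zb = scn_in["z_bounds"];
  for (int i = 0; i < 7; ++i) sc.zb[i] = zb[i];
  sc.ap_x = scn_in["ap_x"];
  sc.ap_y = scn_in["ap_y"];
  IntegerVector rm = scn_in["region_mat"];
  NumericVector rc = scn_in["region_corr"];
  for (int i = 0; i < 6; ++i) {
    sc.region_mat[i] = rm[i] - 1;
    sc.region_corr[i] = rc[i];
  }
  sc.aperture_corr = scn_in["aperture_corr"];
  sc.nx = scn_in["nx"]; sc.ny = scn_in["ny"]; sc.nz = scn_in["nz"];
  sc.h = scn_in["h"]; sc.x0 = scn_in["x0"]; sc.y0 = scn_in["y0"];
  NumericVector ms = scn_in["max_step"];
  for (int i = 0; i < 4; ++i) sc.max_step[i] = ms[i];
  sc.r_kill = scn_in["r_kill"];

  // ---- options ----
  Opts op;
  op.no_scatter = as<bool>(opts_in["no_scatter"]);
  op.no_straggle = as<bool>(opts_in["no_straggle"]);
  op.no_nuclear = as<bool>(opts_in["no_nuclear"]);
  op.do_tally = as<bool>(opts_in["do_tally"]);
  op.do_log = as<bool>(opts_in["do_log"]);
  op.do_ledger = as<bool>(opts_in["do_ledger"]);
  op.do_zprof = as<bool>(opts_in["do_zprof"]);
  op.sad_x = as<double>(opts_in["sad_x"]);
  op.sad_y = as<double>(opts_in["sad_y"]);
  op.z_src = as<double>(opts_in["z_src"]);
  op.dispersion = as<double>(opts_in["dispersion"]);
  NumericVector pz = opts_in["plane_z"];
  op.do_plane = R_finite(pz[0]);
  op.plane_z = pz[0];

  // ---- spots ----
  NumericVector sx = spots["x_iso"], sy = spots["y_iso"], se = spots["energy"];
  NumericVector spos = spots["sigma_pos"], sang = spots["sigma_ang"];
  IntegerVector sn = spots["n_primaries"];
  const int nspot = sx.size();
  long n_tot = 0;
  for (int i = 0; i < nspot; ++i) n_tot += sn[i];

  Tally tl;
  if (op.do_tally) tl.init(sc.nx, sc.ny, sc.nz, nbatch);
  StepLog lg;
  lg.enabled = op.do_log;
  std::vector<double> zprof_eps, zprof_r2, zprof_in;
  std::vector<double> zwx, zwy;
  bool has_window = false;
  if (op.do_zprof) {
    zprof_eps.assign(sc.nz, 0.0);
    zprof_r2.assign(sc.nz, 0.0);
    zprof_in.assign(sc.nz, 0.0);
    if (opts_in.containsElementNamed("zprof_wx")) {
      NumericVector wx = opts_in["zprof_wx"], wy = opts_in["zprof_wy"];
      if (wx.size() == sc.nz) {
        has_window = true;
        zwx.assign(wx.begin(), wx.end());
        zwy.assign(wy.begin(), wy.end());
      }
    }
  }
  std::vector<double> led_ein, led_edep, led_eesc, led_erem, led_scat;
  std::vector<double> led_x, led_y, led_z, led_e;
  std::vector<double> plane_x, plane_y, plane_e, plane_scat;

  double tot_ein = 0.0, tot_edep = 0.0, tot_eesc = 0.0, tot_erem = 0.0;
  const uint64_t useed = static_cast<uint64_t>(seed);
  const double inv_sadx = R_finite(op.sad_x) ? 1.0 / op.sad_x : 0.0;
  const double inv_sady = R_finite(op.sad_y) ? 1.0 / op.sad_y : 0.0;
  const double z_iso = 3.0;
  const double fx = 1.0 - (z_iso - op.z_src) * inv_sadx;
  const double fy = 1.0 - (z_iso - op.z_src) * inv_sady;

  Rng rng;
  long g = -1;
  for (int isp = 0; isp < nspot; ++isp) {
    for (int k = 0; k < sn[isp]; ++k) {
      ++g;
      rng.seed(useed, static_cast<uint64_t>(g));
      const int batch = static_cast<int>(g % nbatch);

      // --- sample the primary from the calibrated source model ---
      double tx = sx[isp] * inv_sadx + sang[isp] * rng.normal();
      double ty = sy[isp] * inv_sady + sang[isp] * rng.normal();
      double x = sx[isp] * fx + spos[isp] * rng.normal();
      double y = sy[isp] * fy + spos[isp] * rng.normal();
      double z = op.z_src;
      double nrm = std::sqrt(1.0 + tx * tx + ty * ty);
      double dx = tx / nrm, dy = ty / nrm, dz = 1.0 / nrm;
      double E = se[isp] * (1.0 + op.dispersion * rng.normal());
      if (E < 2.0) E = 2.0;
      if (E > 295.0) E = 295.0;
      double w = weight_per_primary;
      bool scattered = false;

      const double e_in = w * E;
      double e_dep = 0.0, e_rem = 0.0, e_esc = 0.0;
      bool alive = true;
      bool plane_done = !op.do_plane;
      int nstep = 0;

      while (alive) {
        if (++nstep > op.max_steps) stop("runaway history (> max_steps)");
        // region
        int reg = -1;
        if (z >= sc.zb[0] && z < sc.zb[6]) {
          for (int r = 5; r >= 0; --r) {
            if (z >= sc.zb[r]) { reg = r; break; }
          }
        }
        if (reg < 0 || x * x + y * y > sc.r_kill * sc.r_kill) {
          e_esc = w * E;
          break;
        }
        int mat = sc.region_mat[reg];
        double corr = sc.region_corr[reg];
        bool in_aperture_air = false;
        if (reg == 3) {  // collimator slab: brass outside the opening
          if (std::fabs(x) < sc.ap_x && std::fabs(y) < sc.ap_y) {
            mat = 0;
            corr = sc.aperture_corr;
            in_aperture_air = true;
          }
        }

        // step length: material cap, 5% of residual range, boundary
        const double uE = ph.uof(std::max(E, 0.11));
        const double rr = ph.R(mat, uE);
        double l = std::min(sc.max_step[mat], std::max(0.05 * rr, 0.01));
        double t_bound = 1e30;
        if (dz > 1e-12) t_bound = (sc.zb[reg + 1] - z) / dz;
        else if (dz < -1e-12) t_bound = (sc.zb[reg] - z) / dz;
        if (reg == 3) {  // lateral aperture walls
          const double pl[4] = {sc.ap_x, -sc.ap_x, sc.ap_y, -sc.ap_y};
          const double cc[4] = {x, x, y, y};
          const double di[4] = {dx, dx, dy, dy};
          for (int q = 0; q < 4; ++q) {
            if (std::fabs(di[q]) > 1e-12) {
              const double t = (pl[q] - cc[q]) / di[q];
              if (t > 1e-9 && t < t_bound) t_bound = t;
            }
          }
        }
        bool crossing = false;
        if (t_bound < l) { l = std::max(t_bound, 1e-6); crossing = true; }

        // energy loss with Bohr straggling at mid-step energy
        const double s0 = ph.S(mat, uE);
        double emid = E - 0.5 * s0 * l;
        double de;
        double uMid;
        if (emid <= 0.15) {
          de = E;
          emid = std::max(0.5 * E, 0.11);
          uMid = ph.uof(emid);
        } else {
          uMid = ph.uof(emid);
          de = ph.S(mat, uMid) * l;
          if (!op.no_straggle) {
            de += std::sqrt(ph.strag_c[mat] * l) * rng.normal();
          }
          if (de < 0.0) de = 0.0;
          if (de > E) de = E;
        }

        // score within the phantom grid
        const bool in_phantom = (reg == 5);
        const double L_let = 0.1 * ph.S(3, uMid);  // keV/um, water
        if (in_phantom && (op.do_tally || op.do_zprof) && w * de > 0.0) {
          if (op.do_tally) {
            score_segment(sc, tl, lg, x, y, z, dx, dy, dz, l, w * de, L_let,
                          scattered ? 0 : 1, batch);
          }
          if (op.do_zprof) {
            const double zmid = z + 0.5 * l * dz;
            int iz = static_cast<int>(std::floor(zmid / sc.h));
            if (iz >= 0 && iz < sc.nz) {
              zprof_eps[iz] += w * de;
              const double xm = x + 0.5 * l * dx, ym = y + 0.5 * l * dy;
              zprof_r2[iz] += w * de * (xm * xm + ym * ym);
              if (has_window && std::fabs(xm) < zwx[iz] &&
                  std::fabs(ym) < zwy[iz]) {
                zprof_in[iz] += w * de;
              }
            }
          }
        }
        e_dep += w * de;

        // advance along the pre-deflection direction
        const double zold = z;
        x += l * dx; y += l * dy; z += l * dz;
        E -= de;
        if (crossing) {  // nudge across the boundary (half-open regions)
          x += 1e-7 * dx; y += 1e-7 * dy; z += 1e-7 * dz;
        }
        if (!plane_done && zold < op.plane_z && z >= op.plane_z) {
          const double tt = (op.plane_z - zold) / (z - zold);
          plane_x.push_back(x - l * dx + tt * l * dx);
          plane_y.push_back(y - l * dy + tt * l * dy);
          plane_e.push_back(E);
          plane_scat.push_back(scattered ? 1.0 : 0.0);
          plane_done = true;
        }

        if (mat == 2) scattered = true;  // stepped through brass

        if (E < E_CUT) {  // terminal local deposit
          const double e_left = w * E;
          if (in_phantom && op.do_tally && e_left > 0.0) {
            score_segment(sc, tl, lg, x, y, z, 0.0, 0.0, 1.0, 1e-6, e_left,
                          0.1 * ph.S(3, ph.uof(std::max(E, 0.11))),
                          scattered ? 0 : 1, batch);
          }
          if (in_phantom && op.do_zprof && e_left > 0.0) {
            int iz = static_cast<int>(std::floor(z / sc.h));
            if (iz >= 0 && iz < sc.nz) {
              zprof_eps[iz] += e_left;
              zprof_r2[iz] += e_left * (x * x + y * y);
              if (has_window && std::fabs(x) < zwx[iz] &&
                  std::fabs(y) < zwy[iz]) {
                zprof_in[iz] += e_left;
              }
            }
          }
          e_dep += e_left;
          E = 0.0;
          break;
        }

        // multiple Coulomb scattering, deflection after the advance
        if (!op.no_scatter) {
          const double th0 = 14.1 / pv(emid) *
            std::sqrt(l / ph.x0_cm[mat]) * corr;
          const double t1 = th0 * rng.normal();
          const double t2 = th0 * rng.normal();
          // orthonormal basis perpendicular to d
          double ux, uy, uz;
          if (std::fabs(dz) < 0.99) { ux = -dy; uy = dx; uz = 0.0; }
          else { ux = 1.0; uy = 0.0; uz = 0.0; }
          double un = std::sqrt(ux * ux + uy * uy + uz * uz);
          ux /= un; uy /= un; uz /= un;
          const double vx = dy * uz - dz * uy;
          const double vy = dz * ux - dx * uz;
          const double vz = dx * uy - dy * ux;
          dx += t1 * ux + t2 * vx;
          dy += t1 * uy + t2 * vy;
          dz += t1 * uz + t2 * vz;
          const double dn = std::sqrt(dx * dx + dy * dy + dz * dz);
          dx /= dn; dy /= dn; dz /= dn;
        }

        // nuclear removal as fluence attenuation
        if (!op.no_nuclear) {
          const double wnew = w * std::exp(-l / ph.lambda_cm[mat]);
          e_rem += (w - wnew) * E;
          w = wnew;
          if (w < 1e-12 * weight_per_primary) { e_esc = w * E; break; }
        }
        (void)in_aperture_air;
      }

      tot_ein += e_in;
      tot_edep += e_dep;
      tot_eesc += e_esc;
      tot_erem += e_rem;
      if (op.do_ledger) {
        led_ein.push_back(e_in);
        led_edep.push_back(e_dep);
        led_eesc.push_back(e_esc);
        led_erem.push_back(e_rem);
        led_scat.push_back(scattered ? 1.0 : 0.0);
        led_x.push_back(x); led_y.push_back(y); led_z.push_back(z);
        led_e.push_back(E);
      }
    }
  }

  List out = List::create(
      _["n_primaries"] = static_cast<double>(n_tot),
      _["e_in"] = tot_ein, _["e_dep"] = tot_edep,
      _["e_escaped"] = tot_eesc, _["e_removed"] = tot_erem);
  if (op.do_tally) {
    NumericVector eps(tl.eps.begin(), tl.eps.end());
    NumericVector epsl(tl.epsl.begin(), tl.epsl.end());
    IntegerVector dims = IntegerVector::create(sc.nx, sc.ny, sc.nz, 2, nbatch);
    eps.attr("dim") = dims;
    epsl.attr("dim") = dims;
    out["eps"] = eps;
    out["epsL"] = epsl;
  }
  if (op.do_zprof) {
    out["zprof_eps"] = NumericVector(zprof_eps.begin(), zprof_eps.end());
    out["zprof_r2"] = NumericVector(zprof_r2.begin(), zprof_r2.end());
    out["zprof_in"] = NumericVector(zprof_in.begin(), zprof_in.end());
  }
  if (op.do_log) {
    out["step_log"] = DataFrame::create(
        _["ix"] = lg.ix, _["iy"] = lg.iy, _["iz"] = lg.iz,
        _["eps"] = lg.eps, _["L"] = lg.L, _["channel"] = lg.ch);
  }
  if (op.do_ledger) {
    out["ledger"] = DataFrame::create(
        _["e_in"] = led_ein, _["e_dep"] = led_edep,
        _["e_escaped"] = led_eesc, _["e_removed"] = led_erem,
        _["scattered"] = led_scat,
        _["x"] = led_x, _["y"] = led_y, _["z"] = led_z,
        _["energy"] = led_e);
  }
  if (op.do_plane) {
    out["plane"] = DataFrame::create(
        _["x"] = plane_x, _["y"] = plane_y, _["energy"] = plane_e,
        _["scattered"] = plane_scat);
  }
  return out;
}
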