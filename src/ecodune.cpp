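#include <Rcpp.h>
using namespace Rcpp;

// Downwind unit step for a 16-bin compass direction (degrees from north,
// direction of origin). Rows increase southwards, columns eastwards. The
// step is normalised so the dominant axis advances one cell per step;
// step_len is the physical length of one step.
static void dir_step(int dirbin, double cell, double &sr, double &sc,
                     double &step_len) {
  double brg = (dirbin * 22.5 + 180.0) * M_PI / 180.0;  // blowing toward
  double east = std::sin(brg), north = std::cos(brg);
  double dr = -north, dc = east;
  double m = std::max(std::fabs(dr), std::fabs(dc));
  if (m < 1e-12) { sr = 0.0; sc = 0.0; step_len = cell; return; }
  sr = dr / m; sc = dc / m;
  step_len = std::sqrt(sr * sr + sc * sc) * cell;
}

static inline int wrap(int i, int n) {
  i %= n; if (i < 0) i += n; return i;
}

// [[Rcpp::export]]
double cpp_max_slope(NumericMatrix surface, double cell, bool periodic) {
  int nr = surface.nrow(), nc = surface.ncol();
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  double maxs = 0.0;
  for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j) {
    for (int k = 0; k < 8; ++k) {
      int ni = i + dr[k], nj = j + dc[k];
      if (periodic) { ni = wrap(ni, nr); nj = wrap(nj, nc); }
      else if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      double dist = cell * ((dr[k] != 0 && dc[k] != 0) ? M_SQRT2 : 1.0);
      double s = std::fabs(surface(i, j) - surface(ni, nj)) / dist;
      if (s > maxs) maxs = s;
    }
  }
  return std::atan(maxs);
}

// [[Rcpp::export]]
NumericMatrix cpp_velocity_field(NumericMatrix surface, IntegerMatrix species,
                                 NumericMatrix height, NumericMatrix porosity,
                                 double u, int dirbin, double cell,
                                 double rec_coef, double decay_rate,
                                 double tree_mid, double tree_rate,
                                 double alpha, double cap, bool periodic) {
  int nr = surface.nrow(), nc = surface.ncol();
  double sr, sc, step_len;
  dir_step(dirbin, cell, sr, sc, step_len);
  NumericMatrix factor(nr, nc);
  std::fill(factor.begin(), factor.end(), 1.0);

  double exp_norm = 1.0 - std::exp(-decay_rate);
  double log_lo = 1.0 / (1.0 + std::exp(tree_rate * tree_mid));
  double log_hi = 1.0 / (1.0 + std::exp(-tree_rate * (1.0 - tree_mid)));

  for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j) {
    int sp = species(i, j);
    if (sp == 0) continue;
    double h = height(i, j);
    double por = porosity(i, j);
    double L = rec_coef * h * (1.0 - por);
    if (L <= 0.0) continue;
    double r0 = por;  // residual velocity fraction behind the element
    if (r0 < factor(i, j)) factor(i, j) = r0;
    int maxt = (int)std::ceil(L / step_len);
    for (int t = 1; t <= maxt; ++t) {
      double dist = t * step_len;
      double frac = dist / L;
      if (frac >= 1.0) break;
      int ci = i + (int)std::lround(t * sr);
      int cj = j + (int)std::lround(t * sc);
      if (periodic) { ci = wrap(ci, nr); cj = wrap(cj, nc); }
      else if (ci < 0 || ci >= nr || cj < 0 || cj >= nc) break;
      double f;
      if (sp == 3) {
        double lg = 1.0 / (1.0 + std::exp(-tree_rate * (frac - tree_mid)));
        f = (lg - log_lo) / (log_hi - log_lo);
      } else {
        f = (1.0 - std::exp(-decay_rate * frac)) / exp_norm;
      }
      f = r0 + (1.0 - r0) * f;
      if (f < factor(ci, cj)) factor(ci, cj) = f;
    }
  }

  // topographic compression on upwind-facing slopes
  int ur = (int)std::lround(sr), uc = (int)std::lround(sc);
  double uw_len = std::sqrt((double)(ur * ur + uc * uc)) * cell;
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j) {
    double comp = 1.0;
    if (uw_len > 0.0) {
      int pi = i - ur, pj = j - uc;
      bool ok = true;
      if (periodic) { pi = wrap(pi, nr); pj = wrap(pj, nc); }
      else if (pi < 0 || pi >= nr || pj < 0 || pj >= nc) ok = false;
      if (ok) {
        double slope = (surface(i, j) - surface(pi, pj)) / uw_len;
        if (slope > 0.0) comp = std::min(cap, 1.0 + alpha * slope);
      }
    }
    out(i, j) = u * factor(i, j) * comp;
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_shadow_mask(NumericMatrix surface, int dirbin, double cell,
                              double tan_angle, bool periodic) {
  int nr = surface.nrow(), nc = surface.ncol();
  double sr, sc, step_len;
  dir_step(dirbin, cell, sr, sc, step_len);
  IntegerMatrix mask(nr, nc);
  double hmax = *std::max_element(surface.begin(), surface.end());
  double hmin = *std::min_element(surface.begin(), surface.end());
  int maxt = (int)std::ceil((hmax - hmin) / (tan_angle * step_len));
  int tcap = periodic ? (nr + nc) : std::max(nr, nc);
  if (maxt > tcap) maxt = tcap;
  for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j) {
    double h0 = surface(i, j);
    for (int t = 1; t <= maxt; ++t) {
      int pi = i - (int)std::lround(t * sr);
      int pj = j - (int)std::lround(t * sc);
      if (periodic) { pi = wrap(pi, nr); pj = wrap(pj, nc); }
      else if (pi < 0 || pi >= nr || pj < 0 || pj >= nc) break;
      double line = surface(pi, pj) - tan_angle * (t * step_len);
      if (line - h0 > 1e-9) { mask(i, j) = 1; break; }
    }
  }
  return mask;
}

// [[Rcpp::export]]
List cpp_transport_iteration(IntegerMatrix sand, NumericMatrix base,
                             IntegerMatrix species, NumericMatrix vel,
                             IntegerMatrix shadow, IntegerVector order,
                             int dirbin, double cell, double slab_h,
                             double u_t, double flux_coef,
                             double pe_bare, double pe_veg,
                             double pd_bare, double pd_veg, bool periodic) {
  int nr = sand.nrow(), nc = sand.ncol();
  IntegerMatrix snd = clone(sand);
  double sr, sc, step_len;
  dir_step(dirbin, cell, sr, sc, step_len);
  long eroded = 0, deposited = 0, lost = 0;
  int max_hop = 4 * (nr + nc);

  for (int idx = 0; idx < order.size(); ++idx) {
    int lin = order[idx];
    int j = lin / nr, i = lin % nr;   // column-major linear index
    if (shadow(i, j)) continue;
    double u = vel(i, j);
    if (u <= u_t) continue;
    int avail = snd(i, j);
    if (avail <= 0) continue;
    double pe = species(i, j) > 0 ? pe_veg : pe_bare;
    if (R::unif_rand() > pe) continue;
    double q = flux_coef * (u - u_t) * u * u;
    if (q > avail) q = avail;
    int n = (int)std::floor(q);
    double frac = q - n;
    if (frac > 0.0 && R::unif_rand() < frac) n += 1;
    if (n > avail) n = avail;
    if (n <= 0) continue;
    snd(i, j) -= n;
    eroded += n;
    // hop downwind, depositing along the pathway
    double pr = i, pc = j;
    int ci = i, cj = j;
    for (int hop = 1; n > 0 && hop <= max_hop; ++hop) {
      pr += sr; pc += sc;
      ci = (int)std::lround(pr); cj = (int)std::lround(pc);
      if (periodic) {
        if (ci < 0 || ci >= nr) { ci = wrap(ci, nr); pr = ci; }
        if (cj < 0 || cj >= nc) { cj = wrap(cj, nc); pc = cj; }
      } else if (ci < 0 || ci >= nr || cj < 0 || cj >= nc) {
        lost += n; n = 0; break;
      }
      double pd = shadow(ci, cj) ? 1.0
                  : (species(ci, cj) > 0 ? pd_veg : pd_bare);
      int k = (pd >= 1.0) ? n : (int)R::rbinom((double)n, pd);
      if (k > 0) { snd(ci, cj) += k; deposited += k; n -= k; }
    }
    if (n > 0) {  // pathway guard: settle the remainder where it is
      snd(ci, cj) += n; deposited += n; n = 0;
    }
  }
  return List::create(_["sand"] = snd,
                      _["eroded"] = (double)eroded,
                      _["deposited"] = (double)deposited,
                      _["lost"] = (double)lost);
}

// [[Rcpp::export]]
List cpp_avalanche(IntegerMatrix sand, NumericMatrix base, IntegerMatrix veg,
                   double cell, double slab_h, double tan_bare,
                   double tan_veg, bool periodic, int max_sweeps) {
  int nr = sand.nrow(), nc = sand.ncol();
  IntegerMatrix snd = clone(sand);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  double dist[8];
  for (int k = 0; k < 8; ++k)
    dist[k] = cell * ((dr[k] != 0 && dc[k] != 0) ? M_SQRT2 : 1.0);

  bool changed = true;
  int sweep = 0;
  while (changed && sweep < max_sweeps) {
    changed = false;
    ++sweep;
    for (int i = 0; i < nr; ++i) for (int j = 0; j < nc; ++j) {
      if (snd(i, j) <= 0) continue;
      double h = base(i, j) + snd(i, j) * slab_h;
      double crit = veg(i, j) ? tan_veg : tan_bare;
      double best = crit * (1.0 + 1e-12) + 1e-12;
      int nbest = 0;
      int bi[8], bj[8];
      for (int k = 0; k < 8; ++k) {
        int ni = i + dr[k], nj = j + dc[k];
        if (periodic) { ni = wrap(ni, nr); nj = wrap(nj, nc); }
        else if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        double hn = base(ni, nj) + snd(ni, nj) * slab_h;
        double s = (h - hn) / dist[k];
        if (s > best + 1e-12) {
          best = s; nbest = 0; bi[nbest] = ni; bj[nbest] = nj; nbest = 1;
        } else if (nbest > 0 && std::fabs(s - best) <= 1e-12) {
          bi[nbest] = ni; bj[nbest] = nj; ++nbest;
        }
      }
      if (nbest > 0) {
        int pick = (nbest == 1) ? 0
                   : (int)std::floor(R::unif_rand() * nbest);
        if (pick >= nbest) pick = nbest - 1;
        snd(i, j) -= 1;
        snd(bi[pick], bj[pick]) += 1;
        changed = true;
      }
    }
  }
  return List::create(_["sand"] = snd,
                      _["converged"] = changed ? 0 : 1,
                      _["sweeps"] = sweep);
}
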