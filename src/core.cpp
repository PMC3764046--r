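#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact circle-rectangle geometry.
//
// quarter_area(a, b, rho): area of [0,a] x [0,b] intersected with the disk of
// radius rho centred at the origin (a, b >= 0).  Assembled four ways this
// gives the disk-rectangle intersection for a centre INSIDE the rectangle,
// which is all the estimators need (points live in the window).
// ---------------------------------------------------------------------------

static inline double seg_int(double rho, double x) {
  // integral_0^x sqrt(rho^2 - t^2) dt for 0 <= x <= rho
  double q = std::max(0.0, rho * rho - x * x);
  double s = std::min(1.0, std::max(-1.0, x / rho));
  return 0.5 * (x * std::sqrt(q) + rho * rho * std::asin(s));
}

static double quarter_area(double a, double b, double rho) {
  if (rho <= 0.0 || a <= 0.0 || b <= 0.0) return 0.0;
  double A = std::min(a, rho);
  double x1 = (b >= rho) ? 0.0 : std::sqrt(rho * rho - b * b);
  if (A <= x1) return A * b;
  return x1 * b + (seg_int(rho, A) - seg_int(rho, x1));
}

static double disk_rect(double cx, double cy, double rho,
                        double xmin, double ymin, double xmax, double ymax) {
  return quarter_area(xmax - cx, ymax - cy, rho)
       + quarter_area(xmax - cx, cy - ymin, rho)
       + quarter_area(cx - xmin, ymax - cy, rho)
       + quarter_area(cx - xmin, cy - ymin, rho);
}

static inline double ring_area_one(double cx, double cy, double r, double w,
                                   double xmin, double ymin, double xmax,
                                   double ymax) {
  double ro = r + 0.5 * w;
  double ri = std::max(0.0, r - 0.5 * w);
  return disk_rect(cx, cy, ro, xmin, ymin, xmax, ymax) -
         disk_rect(cx, cy, ri, xmin, ymin, xmax, ymax);
}

// [[Rcpp::export]]
NumericVector cpp_disk_rect_area(NumericVector cx, NumericVector cy,
                                 NumericVector rho, double xmin, double ymin,
                                 double xmax, double ymax) {
  int n = cx.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = disk_rect(cx[i], cy[i], rho[i], xmin, ymin, xmax, ymax);
  return out;
}

// Per-point ring areas: matrix n x nr
// [[Rcpp::export]]
NumericMatrix cpp_ring_area_mat(NumericVector x, NumericVector y,
                                NumericVector rvals, double w, double xmin,
                                double ymin, double xmax, double ymax) {
  int n = x.size(), nr = rvals.size();
  NumericMatrix out(n, nr);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < nr; ++k)
      out(i, k) = ring_area_one(x[i], y[i], rvals[k], w, xmin, ymin, xmax, ymax);
  return out;
}

// Ordered-pair ring counts from pattern 1 to pattern 2.  Ring k holds
// distances d with max(0, r_k - w/2) <= d < r_k + w/2, i.e. bins with
// d - w/2 < r_k <= d + w/2.  `self` marks p2 == p1 (skip i == j).
// [[Rcpp::export]]
NumericVector cpp_ring_counts(NumericVector x1, NumericVector y1,
                              NumericVector x2, NumericVector y2,
                              NumericVector rvals, double w, bool self) {
  int n1 = x1.size(), n2 = x2.size(), nr = rvals.size();
  NumericVector cnt(nr);
  const double* rv = rvals.begin();
  double rmax = rvals[nr - 1] + 0.5 * w;
  double rmax2 = rmax * rmax;
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n2; ++j) {
      if (self && i == j) continue;
      double dx = x1[i] - x2[j], dy = y1[i] - y2[j];
      double d2 = dx * dx + dy * dy;
      if (d2 >= rmax2) continue;
      double d = std::sqrt(d2);
      int k0 = std::upper_bound(rv, rv + nr, d - 0.5 * w) - rv;
      int k1 = int(std::upper_bound(rv, rv + nr, d + 0.5 * w) - rv) - 1;
      for (int k = k0; k <= k1; ++k) cnt[k] += 1.0;
    }
  }
  return cnt;
}

// k nearest-neighbour distances of each point within one pattern (k small).
// [[Rcpp::export]]
NumericMatrix cpp_knn_dist(NumericVector x, NumericVector y, int k) {
  int n = x.size();
  NumericMatrix out(n, k);
  std::vector<double> best(k);
  for (int i = 0; i < n; ++i) {
    for (int m = 0; m < k; ++m) best[m] = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < best[k - 1]) {
        int m = k - 1;
        while (m > 0 && best[m - 1] > d) { best[m] = best[m - 1]; --m; }
        best[m] = d;
      }
    }
    for (int m = 0; m < k; ++m) out(i, m) = best[m];
  }
  return out;
}

// Nearest distance from each query location to the pattern.
// [[Rcpp::export]]
NumericVector cpp_nndist_to(NumericVector xq, NumericVector yq,
                            NumericVector xp, NumericVector yp) {
  int nq = xq.size(), np = xp.size();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < np; ++j) {
      double dx = xq[i] - xp[j], dy = yq[i] - yp[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Number of neighbours within radius for each point (self excluded).
// [[Rcpp::export]]
IntegerVector cpp_count_within(NumericVector x, NumericVector y, double radius) {
  int n = x.size();
  IntegerVector out(n);
  double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    int c = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy <= r2) ++c;
    }
    out[i] = c;
  }
  return out;
}

// Epanechnikov kernel intensity surface on a raster, with per-point edge
// renormalisation: lambda(c) = sum_j e_R(|c - x_j|) / m_j where m_j is the
// (raster-approximated) kernel mass of point j inside the window.
// [[Rcpp::export]]
NumericMatrix cpp_epanechnikov_surface(NumericVector x, NumericVector y,
                                       NumericVector cxs, NumericVector cys,
                                       double R, double cell) {
  int n = x.size(), nx = cxs.size(), ny = cys.size();
  NumericMatrix z(ny, nx);
  double R2 = R * R;
  double k0 = 2.0 / (M_PI * R2);
  double ca = cell * cell;
  for (int j = 0; j < n; ++j) {
    // raster cells within reach of point j
    int ix0 = std::max(0, int(std::floor((x[j] - R - cxs[0]) / cell)));
    int ix1 = std::min(nx - 1, int(std::ceil((x[j] + R - cxs[0]) / cell)));
    int iy0 = std::max(0, int(std::floor((y[j] - R - cys[0]) / cell)));
    int iy1 = std::min(ny - 1, int(std::ceil((y[j] + R - cys[0]) / cell)));
    double mass = 0.0;
    for (int ix = ix0; ix <= ix1; ++ix) {
      double dx = cxs[ix] - x[j];
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dy = cys[iy] - y[j];
        double d2 = dx * dx + dy * dy;
        if (d2 < R2) mass += k0 * (1.0 - d2 / R2) * ca;
      }
    }
    if (mass <= 0.0) continue;
    for (int ix = ix0; ix <= ix1; ++ix) {
      double dx = cxs[ix] - x[j];
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dy = cys[iy] - y[j];
        double d2 = dx * dx + dy * dy;
        if (d2 < R2) z(iy, ix) += k0 * (1.0 - d2 / R2) / mass;
      }
    }
  }
  return z;
}

// ---------------------------------------------------------------------------
// Pattern reconstruction by improvement-only simulated annealing.
//
// State keeps, incrementally: the pairwise distance matrix; overlapping ring
// pair counts for g; contiguous ring pair counts for K/L; per-point ring-area
// matrices and their column sums; nearest distances (and provider index) of a
// fixed test lattice for Hs; first and second nearest-neighbour distances for
// D1/D2.  A step relocates one uniformly chosen point to a uniform location
// and is accepted iff the energy does not increase.
// ---------------------------------------------------------------------------

struct ReconStat {
  NumericVector rvals;   // grid
  double w;              // ring width (overlapping for g, = step for K)
  std::vector<double> target;
  double norm;
  double weight;
};

static void bins_for(double d, const double* rv, int nr, double w, int& k0,
                     int& k1) {
  k0 = std::upper_bound(rv, rv + nr, d - 0.5 * w) - rv;
  k1 = int(std::upper_bound(rv, rv + nr, d + 0.5 * w) - rv) - 1;
}

// [[Rcpp::export]]
List cpp_reconstruct(NumericVector x0, NumericVector y0, double xmin,
                     double ymin, double xmax, double ymax,
                     NumericVector rg, double wg, NumericVector g_obs,
                     double g_norm, double g_wt,
                     NumericVector rl, double stepl, NumericVector l_obs,
                     double l_norm, double l_wt,
                     NumericVector rh, NumericVector hs_obs, double hs_norm,
                     double hs_wt, NumericVector latx, NumericVector laty,
                     NumericVector rd, NumericVector d1_obs, double d1_norm,
                     double d1_wt, NumericVector d2_obs, double d2_norm,
                     double d2_wt,
                     int max_steps, int stall_limit, int trace_every) {
  int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  double area = (xmax - xmin) * (ymax - ymin);
  double lambda = n / area;

  int nrg = rg.size(), nrl = rl.size(), nrh = rh.size(), nrd = rd.size();
  int T = latx.size();
  bool use_g = g_wt > 0.0, use_l = l_wt > 0.0, use_h = hs_wt > 0.0 && T > 0;
  bool use_d1 = d1_wt > 0.0, use_d2 = d2_wt > 0.0 && n > 2;

  // pairwise distances
  std::vector<double> D(size_t(n) * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d = std::sqrt(dx * dx + dy * dy);
      D[size_t(i) * n + j] = d;
      D[size_t(j) * n + i] = d;
    }

  // ring pair counts (ordered pairs) and per-point ring areas
  std::vector<double> cg(nrg, 0.0), cl(nrl, 0.0);
  std::vector<double> ag(size_t(n) * nrg), al(size_t(n) * nrl);
  std::vector<double> agsum(nrg, 0.0), alsum(nrl, 0.0);
  const double* rgp = rg.begin();
  const double* rlp = rl.begin();
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < nrg; ++k) {
      double a = ring_area_one(x[i], y[i], rg[k], wg, xmin, ymin, xmax, ymax);
      ag[size_t(i) * nrg + k] = a;
      agsum[k] += a;
    }
    for (int k = 0; k < nrl; ++k) {
      double a = ring_area_one(x[i], y[i], rl[k], stepl, xmin, ymin, xmax, ymax);
      al[size_t(i) * nrl + k] = a;
      alsum[k] += a;
    }
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d = D[size_t(i) * n + j];
      int k0, k1;
      bins_for(d, rgp, nrg, wg, k0, k1);
      for (int k = k0; k <= k1; ++k) cg[k] += 1.0;
      bins_for(d, rlp, nrl, stepl, k0, k1);
      for (int k = k0; k <= k1; ++k) cl[k] += 1.0;
    }
  }

  // full annulus areas for K cumulation
  std::vector<double> fullann(nrl);
  for (int k = 0; k < nrl; ++k) {
    double ro = rl[k] + 0.5 * stepl, ri = std::max(0.0, rl[k] - 0.5 * stepl);
    fullann[k] = M_PI * (ro * ro - ri * ri);
  }

  // Hs lattice nearest distances
  std::vector<double> hd(T);
  std::vector<int> hi(T);
  std::vector<int> hbin(T);                 // first rh index with rh >= hd
  std::vector<double> hcnt(nrh + 1, 0.0);   // histogram over bins (last = beyond)
  const double* rhp = rh.begin();
  if (use_h) {
    for (int t = 0; t < T; ++t) {
      double best = R_PosInf; int bi = -1;
      for (int j = 0; j < n; ++j) {
        double dx = latx[t] - x[j], dy = laty[t] - y[j];
        double d2 = dx * dx + dy * dy;
        if (d2 < best) { best = d2; bi = j; }
      }
      hd[t] = std::sqrt(best);
      hi[t] = bi;
      hbin[t] = std::lower_bound(rhp, rhp + nrh, hd[t]) - rhp;
      hcnt[hbin[t]] += 1.0;
    }
  }

  // nearest and second-nearest neighbour distances
  std::vector<double> nd1(n, R_PosInf), nd2(n, R_PosInf);
  std::vector<int> ni1(n, -1), ni2(n, -1);
  if (use_d1 || use_d2) {
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double d = D[size_t(i) * n + j];
        if (d < nd1[i]) {
          nd2[i] = nd1[i]; ni2[i] = ni1[i];
          nd1[i] = d; ni1[i] = j;
        } else if (d < nd2[i]) {
          nd2[i] = d; ni2[i] = j;
        }
      }
    }
  }

  const double* rdp = rd.begin();

  // energy from current state (d-histogram buffers hoisted out of the loop)
  std::vector<double> c1buf(nrd + 1), c2buf(nrd + 1);
  auto energy = [&]() -> double {
    double E = 0.0;
    if (use_g) {
      for (int k = 0; k < nrg; ++k) {
        double ghat = (agsum[k] > 0.0) ? cg[k] / agsum[k] / lambda : 0.0;
        double dlt = ghat - g_obs[k];
        E += g_wt * dlt * dlt / g_norm;
      }
    }
    if (use_l) {
      double K = 0.0;
      for (int k = 0; k < nrl; ++k) {
        double dens = (alsum[k] > 0.0) ? cl[k] / alsum[k] : 0.0;
        K += dens * fullann[k] / lambda;
        double Lh = std::sqrt(K / M_PI);
        double dlt = Lh - l_obs[k];
        E += l_wt * dlt * dlt / l_norm;
      }
    }
    if (use_h) {
      double run = 0.0;
      for (int k = 0; k < nrh; ++k) {
        run += hcnt[k];
        double dlt = run / T - hs_obs[k];
        E += hs_wt * dlt * dlt / hs_norm;
      }
    }
    if (use_d1 || use_d2) {
      std::vector<double>& c1 = c1buf;
      std::vector<double>& c2 = c2buf;
      std::fill(c1.begin(), c1.end(), 0.0);
      std::fill(c2.begin(), c2.end(), 0.0);
      for (int i = 0; i < n; ++i) {
        c1[std::lower_bound(rdp, rdp + nrd, nd1[i]) - rdp] += 1.0;
        if (use_d2)
          c2[std::lower_bound(rdp, rdp + nrd, nd2[i]) - rdp] += 1.0;
      }
      double r1 = 0.0, r2 = 0.0;
      for (int k = 0; k < nrd; ++k) {
        r1 += c1[k]; r2 += c2[k];
        if (use_d1) {
          double dlt = r1 / n - d1_obs[k];
          E += d1_wt * dlt * dlt / d1_norm;
        }
        if (use_d2) {
          double dlt = r2 / n - d2_obs[k];
          E += d2_wt * dlt * dlt / d2_norm;
        }
      }
    }
    return E;
  };

  double E_cur = energy();
  double E_init = E_cur;

  std::vector<double> trace;
  if (trace_every > 0) trace.push_back(E_cur);

  // scratch for rollback
  std::vector<double> cg_save(nrg), cl_save(nrl);
  std::vector<double> agrow_save(nrg), alrow_save(nrl);
  std::vector<double> drow_save(n);
  std::vector<double> nd1_save, nd2_save;
  std::vector<int> ni1_save, ni2_save;
  struct HChange { int t; double d; int idx; int bin; };
  std::vector<HChange> hch;

  int steps = 0, accepted = 0, stall = 0;

  while (steps < max_steps && stall < stall_limit) {
    ++steps;
    int j = std::min(n - 1, int(std::floor(unif_rand() * n)));
    double nx_ = xmin + unif_rand() * (xmax - xmin);
    double ny_ = ymin + unif_rand() * (ymax - ymin);
    double ox = x[j], oy = y[j];

    // save state touched by this step
    std::copy(cg.begin(), cg.end(), cg_save.begin());
    std::copy(cl.begin(), cl.end(), cl_save.begin());
    std::copy(ag.begin() + size_t(j) * nrg, ag.begin() + size_t(j + 1) * nrg,
              agrow_save.begin());
    std::copy(al.begin() + size_t(j) * nrl, al.begin() + size_t(j + 1) * nrl,
              alrow_save.begin());
    for (int i = 0; i < n; ++i) drow_save[i] = D[size_t(j) * n + i];
    if (use_d1 || use_d2) {
      nd1_save = nd1; nd2_save = nd2; ni1_save = ni1; ni2_save = ni2;
    }
    hch.clear();

    // apply move
    x[j] = nx_; y[j] = ny_;
    for (int i = 0; i < n; ++i) {
      if (i == j) continue;
      double dold = drow_save[i];
      double dx = x[i] - nx_, dy = y[i] - ny_;
      double dnew = std::sqrt(dx * dx + dy * dy);
      D[size_t(j) * n + i] = dnew;
      D[size_t(i) * n + j] = dnew;
      int k0, k1;
      bins_for(dold, rgp, nrg, wg, k0, k1);
      for (int k = k0; k <= k1; ++k) cg[k] -= 2.0;
      bins_for(dnew, rgp, nrg, wg, k0, k1);
      for (int k = k0; k <= k1; ++k) cg[k] += 2.0;
      bins_for(dold, rlp, nrl, stepl, k0, k1);
      for (int k = k0; k <= k1; ++k) cl[k] -= 2.0;
      bins_for(dnew, rlp, nrl, stepl, k0, k1);
      for (int k = k0; k <= k1; ++k) cl[k] += 2.0;
    }
    for (int k = 0; k < nrg; ++k) {
      double a = ring_area_one(nx_, ny_, rg[k], wg, xmin, ymin, xmax, ymax);
      agsum[k] += a - agrow_save[k];
      ag[size_t(j) * nrg + k] = a;
    }
    for (int k = 0; k < nrl; ++k) {
      double a = ring_area_one(nx_, ny_, rl[k], stepl, xmin, ymin, xmax, ymax);
      alsum[k] += a - alrow_save[k];
      al[size_t(j) * nrl + k] = a;
    }

    if (use_h) {
      for (int t = 0; t < T; ++t) {
        double dx = latx[t] - nx_, dy = laty[t] - ny_;
        double dnew = std::sqrt(dx * dx + dy * dy);
        if (hi[t] == j) {
          // previous provider moved: rescan
          double best = dnew; int bi = j;
          for (int m = 0; m < n; ++m) {
            if (m == j) continue;
            double ddx = latx[t] - x[m], ddy = laty[t] - y[m];
            double d2 = ddx * ddx + ddy * ddy;
            if (d2 < best * best) { best = std::sqrt(d2); bi = m; }
          }
          if (best != hd[t] || bi != hi[t]) {
            hch.push_back({t, hd[t], hi[t], hbin[t]});
            hcnt[hbin[t]] -= 1.0;
            hd[t] = best; hi[t] = bi;
            hbin[t] = std::lower_bound(rhp, rhp + nrh, best) - rhp;
            hcnt[hbin[t]] += 1.0;
          }
        } else if (dnew < hd[t]) {
          hch.push_back({t, hd[t], hi[t], hbin[t]});
          hcnt[hbin[t]] -= 1.0;
          hd[t] = dnew; hi[t] = j;
          hbin[t] = std::lower_bound(rhp, rhp + nrh, dnew) - rhp;
          hcnt[hbin[t]] += 1.0;
        }
      }
    }

    if (use_d1 || use_d2) {
      // moved point: full rescan
      nd1[j] = R_PosInf; nd2[j] = R_PosInf; ni1[j] = -1; ni2[j] = -1;
      for (int m = 0; m < n; ++m) {
        if (m == j) continue;
        double d = D[size_t(j) * n + m];
        if (d < nd1[j]) {
          nd2[j] = nd1[j]; ni2[j] = ni1[j]; nd1[j] = d; ni1[j] = m;
        } else if (d < nd2[j]) {
          nd2[j] = d; ni2[j] = m;
        }
      }
      for (int i = 0; i < n; ++i) {
        if (i == j) continue;
        double d = D[size_t(i) * n + j];
        if (ni1[i] == j || ni2[i] == j) {
          nd1[i] = R_PosInf; nd2[i] = R_PosInf; ni1[i] = -1; ni2[i] = -1;
          for (int m = 0; m < n; ++m) {
            if (m == i) continue;
            double dm = D[size_t(i) * n + m];
            if (dm < nd1[i]) {
              nd2[i] = nd1[i]; ni2[i] = ni1[i]; nd1[i] = dm; ni1[i] = m;
            } else if (dm < nd2[i]) {
              nd2[i] = dm; ni2[i] = m;
            }
          }
        } else if (d < nd1[i]) {
          nd2[i] = nd1[i]; ni2[i] = ni1[i]; nd1[i] = d; ni1[i] = j;
        } else if (d < nd2[i]) {
          nd2[i] = d; ni2[i] = j;
        }
      }
    }

    double E_new = energy();
    if (E_new <= E_cur) {
      E_cur = E_new;
      ++accepted;
      stall = 0;
    } else {
      // rollback
      x[j] = ox; y[j] = oy;
      for (int i = 0; i < n; ++i) {
        D[size_t(j) * n + i] = drow_save[i];
        D[size_t(i) * n + j] = drow_save[i];
      }
      std::copy(cg_save.begin(), cg_save.end(), cg.begin());
      std::copy(cl_save.begin(), cl_save.end(), cl.begin());
      for (int k = 0; k < nrg; ++k) {
        agsum[k] += agrow_save[k] - ag[size_t(j) * nrg + k];
        ag[size_t(j) * nrg + k] = agrow_save[k];
      }
      for (int k = 0; k < nrl; ++k) {
        alsum[k] += alrow_save[k] - al[size_t(j) * nrl + k];
        al[size_t(j) * nrl + k] = alrow_save[k];
      }
      for (int m = int(hch.size()) - 1; m >= 0; --m) {
        const HChange& c = hch[m];
        hcnt[hbin[c.t]] -= 1.0;
        hd[c.t] = c.d; hi[c.t] = c.idx; hbin[c.t] = c.bin;
        hcnt[c.bin] += 1.0;
      }
      if (use_d1 || use_d2) {
        nd1 = nd1_save; nd2 = nd2_save; ni1 = ni1_save; ni2 = ni2_save;
      }
      ++stall;
    }
    if (trace_every > 0 && steps % trace_every == 0) trace.push_back(E_cur);
  }

  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["y"] = NumericVector(y.begin(), y.end()),
                      _["energy_init"] = E_init, _["energy_final"] = E_cur,
                      _["steps"] = steps, _["accepted"] = accepted,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
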