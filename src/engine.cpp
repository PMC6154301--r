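// IMEX Euler engine for the 2D membrane/nucleus node system.
//
// Mirrors the reference R integrator (advance()) step for step: rotation
// fit, linear-implicit membrane update with the old/new split of the
// chemotactic gradient, nucleus update against the already-advanced
// membrane, tangential contact projection plus boundary clamping, nucleus
// centroid refresh, and source-consumption bookkeeping. Noise is drawn
// from R's RNG (R::rnorm) in the same per-node x,y order as the R path,
// so both engines agree for a fixed seed.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Eval {
  double sdist;      // > 0 inside the obstacle (penetration depth)
  double nx, ny;     // outward obstacle normal at nearest feature
  double bx, by;     // nearest boundary point
};

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static Eval eval_disc(const double* d, double px, double py) {
  double vx = px - d[0], vy = py - d[1];
  double r = std::sqrt(vx * vx + vy * vy);
  Eval e;
  if (r > 0) { e.nx = vx / r; e.ny = vy / r; } else { e.nx = 1; e.ny = 0; }
  e.sdist = d[2] - r;
  e.bx = d[0] + d[2] * e.nx;
  e.by = d[1] + d[2] * e.ny;
  return e;
}

// band columns: x0 x1 ylo0 yhi0 eps_lo eps_hi omega faces
// faces == 0: only the sinusoidal surfaces constrain (channel walls);
// nodes beyond the x-extent are unconstrained.
static Eval eval_band(const double* b, double px, double py) {
  const double x0 = b[0], x1 = b[1], ylo0 = b[2], yhi0 = b[3];
  const double el = b[4], eh = b[5], om = b[6];
  const bool faces = b[7] > 0;
  Eval e;
  if (px > x0 && px < x1) {
    double s = std::sin(om * px), c = std::cos(om * px);
    double ylo = ylo0 + el * s, yhi = yhi0 + eh * s;
    if (py > ylo && py < yhi) {  // interior
      double d0 = faces ? px - x0 : 1e18, d1 = faces ? x1 - px : 1e18;
      double d2 = py - ylo, d3 = yhi - py;
      double dmin = d0; int k = 0;
      if (d1 < dmin) { dmin = d1; k = 1; }
      if (d2 < dmin) { dmin = d2; k = 2; }
      if (d3 < dmin) { dmin = d3; k = 3; }
      e.sdist = dmin;
      if (k == 0) { e.nx = -1; e.ny = 0; e.bx = x0; e.by = py; }
      else if (k == 1) { e.nx = 1; e.ny = 0; e.bx = x1; e.by = py; }
      else if (k == 2) {
        double gx = el * om * c, gy = -1, gn = std::sqrt(gx * gx + gy * gy);
        e.nx = gx / gn; e.ny = gy / gn; e.bx = px; e.by = ylo;
      } else {
        double gx = -eh * om * c, gy = 1, gn = std::sqrt(gx * gx + gy * gy);
        e.nx = gx / gn; e.ny = gy / gn; e.bx = px; e.by = yhi;
      }
      return e;
    }
    if (py <= ylo) {
      double gx = el * om * c, gy = -1, gn = std::sqrt(gx * gx + gy * gy);
      e.sdist = -(ylo - py); e.nx = gx / gn; e.ny = gy / gn;
      e.bx = px; e.by = ylo;
      return e;
    }
    double gx = -eh * om * c, gy = 1, gn = std::sqrt(gx * gx + gy * gy);
    e.sdist = -(py - yhi); e.nx = gx / gn; e.ny = gy / gn;
    e.bx = px; e.by = yhi;
    return e;
  }
  if (!faces) {   // beyond the wall's x-extent: unconstrained
    e.sdist = -1e6; e.nx = -1; e.ny = 0; e.bx = px; e.by = py;
    return e;
  }
  double qx = clampd(px, x0, x1);
  double s = std::sin(om * qx);
  double ylo = ylo0 + el * s, yhi = yhi0 + eh * s;
  if (py >= ylo && py <= yhi) {
    e.sdist = -std::fabs(px - qx);
    e.nx = (px <= x0) ? -1 : 1; e.ny = 0;
    e.bx = qx; e.by = py;
    return e;
  }
  double cy = clampd(py, ylo, yhi);
  double vx = px - qx, vy = py - cy;
  double d = std::sqrt(vx * vx + vy * vy);
  e.sdist = -d;
  if (d > 0) { e.nx = vx / d; e.ny = vy / d; }
  else { e.nx = (px <= x0) ? -1 : 1; e.ny = 0; }
  e.bx = qx; e.by = cy;
  return e;
}

// tangential projection at contact, then clamp residual interior points
static void resolve_contact(double x, double y, double& dx, double& dy,
                            const NumericMatrix& discs,
                            const NumericMatrix& bands,
                            double tol, double& outx, double& outy) {
  const int nd = discs.nrow(), nb = bands.nrow();
  std::vector<double> row(8);
  for (int k = 0; k < nd + nb; ++k) {
    Eval e;
    if (k < nd) {
      double d[3] = { discs(k, 0), discs(k, 1), discs(k, 2) };
      e = eval_disc(d, x, y);
    } else {
      for (int j = 0; j < 8; ++j) row[j] = bands(k - nd, j);
      e = eval_band(row.data(), x, y);
    }
    if (e.sdist >= -tol) {
      double dot = dx * e.nx + dy * e.ny;
      if (dot < 0) { dx -= dot * e.nx; dy -= dot * e.ny; }
    }
  }
  double cx = x + dx, cy = y + dy;
  for (int k = 0; k < nd + nb; ++k) {
    Eval e;
    if (k < nd) {
      double d[3] = { discs(k, 0), discs(k, 1), discs(k, 2) };
      e = eval_disc(d, cx, cy);
    } else {
      for (int j = 0; j < 8; ++j) row[j] = bands(k - nd, j);
      e = eval_band(row.data(), cx, cy);
    }
    if (e.sdist > 0) { cx = e.bx; cy = e.by; }
  }
  outx = cx; outy = cy;
}

static bool point_in_poly(double px, double py,
                          const std::vector<double>& xs,
                          const std::vector<double>& ys, double tol) {
  const int n = (int) xs.size();
  bool inside = false;
  int j = n - 1;
  for (int i = 0; i < n; ++i) {
    double xi = xs[i], yi = ys[i], xj = xs[j], yj = ys[j];
    // boundary tie-break: distance from p to segment
    double abx = xj - xi, aby = yj - yi;
    double len2 = abx * abx + aby * aby;
    double tt = len2 > 0 ? clampd(((px - xi) * abx + (py - yi) * aby) / len2, 0.0, 1.0) : 0.0;
    double ex = xi + tt * abx - px, ey = yi + tt * aby - py;
    if (std::sqrt(ex * ex + ey * ey) <= tol) return true;
    if ((yi > py) != (yj > py)) {
      double xc = xi + (py - yi) / (yj - yi) * (xj - xi);
      if (px < xc) inside = !inside;
    }
    j = i;
  }
  return inside;
}

// [[Rcpp::export]]
List engine_run_2d(NumericMatrix mem0, NumericMatrix nuc0,
                   NumericMatrix xhat, NumericMatrix xhatn,
                   NumericMatrix xref, NumericVector xc0,
                   List par, NumericMatrix sources,
                   NumericMatrix discs, NumericMatrix bands,
                   double dt, int max_steps, double tol,
                   int record_every, bool stop_after_exit,
                   double relax_tail, NumericVector channel,
                   bool explicit_grad) {
  const int N = mem0.nrow();
  const double alpha = as<double>(par["alpha"]);
  const double alpha_n = as<double>(par["alpha_n"]);
  const double beta = as<double>(par["beta"]);
  const double eta = as<double>(par["eta"]);
  const double Rcell = as<double>(par["R"]);
  const double D = as<double>(par["D"]);
  const double sq_dt = std::sqrt(dt);

  std::vector<double> mx(N), my(N), nx_(N), ny_(N);
  for (int i = 0; i < N; ++i) {
    mx[i] = mem0(i, 0); my[i] = mem0(i, 1);
    nx_[i] = nuc0(i, 0); ny_[i] = nuc0(i, 1);
  }
  double xcx = xc0[0], xcy = xc0[1];

  const int ns = sources.nrow();
  std::vector<int> src_active(ns);
  std::vector<double> consumed(ns, NA_REAL);
  for (int s = 0; s < ns; ++s) src_active[s] = sources(s, 5) > 0 ? 1 : 0;

  const bool has_channel = channel.size() == 2;
  const double ch_in = has_channel ? channel[0] : 0.0;
  const double ch_out = has_channel ? channel[1] : 0.0;
  double entry_t = NA_REAL, exit_t = NA_REAL;
  double last_consumed = NA_REAL;

  const int rec = record_every > 0 ? record_every : max_steps + 1;
  const int max_frames = max_steps / rec + 3;
  NumericMatrix mem_fr(max_frames, 2 * N), nuc_fr(max_frames, 2 * N);
  NumericVector fr_t(max_frames);
  IntegerVector fr_contacts(max_frames);
  int nf = 0;
  int contacts_this_step = 0;

  // record initial frame
  for (int i = 0; i < N; ++i) {
    mem_fr(nf, i) = mx[i]; mem_fr(nf, N + i) = my[i];
    nuc_fr(nf, i) = nx_[i]; nuc_fr(nf, N + i) = ny_[i];
  }
  fr_t[nf] = 0.0; fr_contacts[nf] = 0; ++nf;

  int status = 0;  // 0 ok, 1 singular source, 2 unstable
  double t = 0.0;
  int step = 0;
  std::vector<double> nmx(N), nmy(N), nnx(N), nny(N);

  for (step = 0; step < max_steps; ++step) {
    const double t_new = t + dt;
    contacts_this_step = 0;

    // (1) rotation fit about the membrane node centroid
    double cmx = 0, cmy = 0;
    for (int i = 0; i < N; ++i) { cmx += mx[i]; cmy += my[i]; }
    cmx /= N; cmy /= N;
    double sdot = 0, scross = 0;
    for (int i = 0; i < N; ++i) {
      double dx = mx[i] - cmx, dy = my[i] - cmy;
      sdot += xref(i, 0) * dx + xref(i, 1) * dy;
      scross += xref(i, 0) * dy - xref(i, 1) * dx;
    }
    const double phi = std::atan2(scross, sdot);
    const double cph = std::cos(phi), sph = std::sin(phi);

    // (2) membrane IMEX step + contact projection
    for (int i = 0; i < N; ++i) {
      double G = 0, sxs = 0, sys = 0, ex = 0, ey = 0;
      for (int s = 0; s < ns; ++s) {
        if (!src_active[s]) continue;
        if (t < sources(s, 3) || t >= sources(s, 4)) continue;
        double rx = sources(s, 0) - mx[i], ry = sources(s, 1) - my[i];
        double r2 = rx * rx + ry * ry;
        if (r2 == 0) { status = 1; break; }
        double coef = sources(s, 2) / (M_PI * D * r2);
        G += coef;
        sxs += coef * sources(s, 0);
        sys += coef * sources(s, 1);
        ex += coef * rx;            // explicit form: coef * (x_S - x_old)
        ey += coef * ry;
      }
      if (status) break;
      double wx = 0, wy = 0;
      if (eta > 0) { wx = eta * sq_dt * R::rnorm(0.0, 1.0);
                     wy = eta * sq_dt * R::rnorm(0.0, 1.0); }
      const double bx = cph * xhat(i, 0) - sph * xhat(i, 1);
      const double by = sph * xhat(i, 0) + cph * xhat(i, 1);
      double newx, newy;
      if (explicit_grad) {
        const double den = 1.0 + dt * alpha;
        newx = (mx[i] + dt * (beta * ex + alpha * (nx_[i] + bx)) + wx) / den;
        newy = (my[i] + dt * (beta * ey + alpha * (ny_[i] + by)) + wy) / den;
      } else {
        const double den = 1.0 + dt * alpha + dt * beta * G;
        newx = (mx[i] + dt * (beta * sxs + alpha * (nx_[i] + bx)) + wx) / den;
        newy = (my[i] + dt * (beta * sys + alpha * (ny_[i] + by)) + wy) / den;
      }
      double dx = newx - mx[i], dy = newy - my[i];
      if (std::sqrt(dx * dx + dy * dy) > Rcell) { status = 2; break; }
      double fx, fy;
      double dx0 = dx, dy0 = dy;
      resolve_contact(mx[i], my[i], dx, dy, discs, bands, tol, fx, fy);
      if (dx != dx0 || dy != dy0 || fx != mx[i] + dx0 || fy != my[i] + dy0)
        ++contacts_this_step;
      nmx[i] = fx; nmy[i] = fy;
    }
    if (status) break;

    // (3) nucleus IMEX step (uses the advanced membrane) + contacts
    for (int i = 0; i < N; ++i) {
      double wx = 0, wy = 0;
      if (eta > 0) { wx = eta * sq_dt * R::rnorm(0.0, 1.0);
                     wy = eta * sq_dt * R::rnorm(0.0, 1.0); }
      const double bx = cph * xhat(i, 0) - sph * xhat(i, 1);
      const double by = sph * xhat(i, 0) + cph * xhat(i, 1);
      const double bnx = cph * xhatn(i, 0) - sph * xhatn(i, 1);
      const double bny = sph * xhatn(i, 0) + cph * xhatn(i, 1);
      const double den = 1.0 + dt * alpha_n;
      double newx = (nx_[i] + dt * (-alpha * (nx_[i] + bx - nmx[i])
                                    + alpha_n * (xcx + bnx)) + wx) / den;
      double newy = (ny_[i] + dt * (-alpha * (ny_[i] + by - nmy[i])
                                    + alpha_n * (xcy + bny)) + wy) / den;
      double dx = newx - nx_[i], dy = newy - ny_[i];
      double fx, fy;
      resolve_contact(nx_[i], ny_[i], dx, dy, discs, bands, tol, fx, fy);
      nnx[i] = fx; nny[i] = fy;
    }

    for (int i = 0; i < N; ++i) {
      mx[i] = nmx[i]; my[i] = nmy[i];
      nx_[i] = nnx[i]; ny_[i] = nny[i];
    }

    // (4) nucleus centre = area centroid of the nucleus polygon
    {
      double A2 = 0, cx = 0, cy = 0;
      for (int i = 0; i < N; ++i) {
        int j = (i + 1) % N;
        double cr = nx_[i] * ny_[j] - nx_[j] * ny_[i];
        A2 += cr;
        cx += (nx_[i] + nx_[j]) * cr;
        cy += (ny_[i] + ny_[j]) * cr;
      }
      if (std::fabs(A2) > 1e-12) {
        xcx = cx / (3.0 * A2); xcy = cy / (3.0 * A2);
      } else {
        double sx = 0, sy = 0;
        for (int i = 0; i < N; ++i) { sx += nx_[i]; sy += ny_[i]; }
        xcx = sx / N; xcy = sy / N;
      }
    }

    // (5) source consumption: engulfed sources deactivate permanently
    for (int s = 0; s < ns; ++s) {
      if (!src_active[s]) continue;
      if (point_in_poly(sources(s, 0), sources(s, 1), mx, my, 1e-9)) {
        src_active[s] = 0;
        consumed[s] = t_new;
        last_consumed = t_new;
      }
    }

    t = t_new;

    // (6) channel entry/exit bookkeeping
    if (has_channel) {
      if (ISNA(entry_t)) {
        for (int i = 0; i < N; ++i) {
          if (mx[i] > ch_in) { entry_t = t; break; }
        }
      }
      if (!ISNA(entry_t) && ISNA(exit_t)) {
        bool all_out = true;
        for (int i = 0; i < N; ++i) {
          if (mx[i] <= ch_out) { all_out = false; break; }
        }
        if (all_out) exit_t = t;
      }
    }

    // (7) record frame
    if (((step + 1) % rec == 0) && nf < max_frames) {
      for (int i = 0; i < N; ++i) {
        mem_fr(nf, i) = mx[i]; mem_fr(nf, N + i) = my[i];
        nuc_fr(nf, i) = nx_[i]; nuc_fr(nf, N + i) = ny_[i];
      }
      fr_t[nf] = t; fr_contacts[nf] = contacts_this_step; ++nf;
    }

    // (8) stopping conditions
    if (stop_after_exit && !ISNA(exit_t)) { ++step; break; }
    bool any_active = false;
    for (int s = 0; s < ns; ++s) if (src_active[s]) any_active = true;
    if (!any_active && !ISNA(last_consumed) && t - last_consumed >= relax_tail) {
      ++step; break;
    }
  }

  // record final state as last frame if not already recorded
  if (nf == 0 || fr_t[nf - 1] != t) {
    if (nf < max_frames) {
      for (int i = 0; i < N; ++i) {
        mem_fr(nf, i) = mx[i]; mem_fr(nf, N + i) = my[i];
        nuc_fr(nf, i) = nx_[i]; nuc_fr(nf, N + i) = ny_[i];
      }
      fr_t[nf] = t; fr_contacts[nf] = contacts_this_step; ++nf;
    }
  }

  NumericMatrix mem_out(nf, 2 * N), nuc_out(nf, 2 * N);
  NumericVector t_out(nf);
  IntegerVector c_out(nf);
  for (int f = 0; f < nf; ++f) {
    t_out[f] = fr_t[f]; c_out[f] = fr_contacts[f];
    for (int j = 0; j < 2 * N; ++j) {
      mem_out(f, j) = mem_fr(f, j);
      nuc_out(f, j) = nuc_fr(f, j);
    }
  }

  NumericMatrix mem_fin(N, 2), nuc_fin(N, 2);
  for (int i = 0; i < N; ++i) {
    mem_fin(i, 0) = mx[i]; mem_fin(i, 1) = my[i];
    nuc_fin(i, 0) = nx_[i]; nuc_fin(i, 1) = ny_[i];
  }

  return List::create(
    _["times"] = t_out, _["mem"] = mem_out, _["nuc"] = nuc_out,
    _["contacts"] = c_out,
    _["mem_final"] = mem_fin, _["nuc_final"] = nuc_fin,
    _["x_c"] = NumericVector::create(xcx, xcy),
    _["entry_time"] = entry_t, _["exit_time"] = exit_t,
    _["consumed"] = NumericVector(consumed.begin(), consumed.end()),
    _["t_final"] = t, _["steps"] = step, _["status"] = status,
    _["source_active"] = IntegerVector(src_active.begin(), src_active.end()));
}
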