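// Y-maze geometry and agent-based locomotion core.
//
// Geometry: three rectangular arms of length L (center to cap start) and
// width w, separated by 120 degrees, each closed by a semicircular
// cul-de-sac cap of radius w/2. The bottom arm points along -y. A sample
// belongs to an arm iff it lies in that arm's rectangle (or cap) at depth
// greater than w/sqrt(3), the on-axis depth at which adjacent arm
// rectangles stop overlapping; shallower in-maze samples are "intersection".

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double SQRT3 = 1.7320508075688772;

// Local arm frame: depth d >= 0 grows away from the center along the arm
// axis, lat is the signed lateral offset. Arm 0 = bottom (-y axis),
// arm 1 = left (up-left), arm 2 = right (up-right).
static inline void to_arm(int a, double x, double y, double &d, double &lat) {
  if (a == 0) {
    lat = x;
    d = -y;
  } else if (a == 1) {
    // rotate by +120 deg into local frame
    lat = -0.5 * x - (SQRT3 / 2.0) * y;
    d = -((SQRT3 / 2.0) * x - 0.5 * y);
  } else {
    // rotate by -120 deg into local frame
    lat = -0.5 * x + (SQRT3 / 2.0) * y;
    d = -(-(SQRT3 / 2.0) * x - 0.5 * y);
  }
}

// Map a local-frame vector back to global coordinates.
static inline void from_arm(int a, double lat, double yloc, double &x, double &y) {
  if (a == 0) {
    x = lat;
    y = yloc;
  } else if (a == 1) {
    // rotate by -120 deg back to global
    x = -0.5 * lat + (SQRT3 / 2.0) * yloc;
    y = -(SQRT3 / 2.0) * lat - 0.5 * yloc;
  } else {
    x = -0.5 * lat - (SQRT3 / 2.0) * yloc;
    y = (SQRT3 / 2.0) * lat - 0.5 * yloc;
  }
}

static inline bool in_arm_region(double d, double lat, double L, double w) {
  double capr = w / 2.0;
  if (d >= 0.0 && d <= L && std::fabs(lat) <= capr) return true;
  if (d > L) {
    double dx = lat, dy = d - L;
    return dx * dx + dy * dy <= capr * capr;
  }
  return false;
}

static inline bool contains_pt(double x, double y, double L, double w) {
  for (int a = 0; a < 3; ++a) {
    double d, lat;
    to_arm(a, x, y, d, lat);
    if (in_arm_region(d, lat, L, w)) return true;
  }
  return false;
}

// 0 bottom, 1 left, 2 right, 3 intersection, NA_INTEGER outside.
static inline int arm_label_pt(double x, double y, double L, double w) {
  double yint = w / SQRT3;
  int best = -1;
  double bestd = yint;
  bool inside = false;
  for (int a = 0; a < 3; ++a) {
    double d, lat;
    to_arm(a, x, y, d, lat);
    if (in_arm_region(d, lat, L, w)) {
      inside = true;
      if (d > bestd) {
        bestd = d;
        best = a;
      }
    }
  }
  if (!inside) return NA_INTEGER;
  return best >= 0 ? best : 3;
}

// Distance to the nearest wall and the inward (into-maze) unit normal.
// Points in the intersection get a large distance and a zero normal.
static inline void wall_info_pt(double x, double y, double L, double w,
                                double &dist, double &nx, double &ny) {
  int a = arm_label_pt(x, y, L, w);
  double capr = w / 2.0;
  if (a == NA_INTEGER || a == 3) {
    dist = 1e6;
    nx = 0.0;
    ny = 0.0;
    return;
  }
  double d, lat;
  to_arm(a, x, y, d, lat);
  double lnx, lny; // inward normal in the local frame (local y = -d)
  if (d <= L) {
    dist = capr - std::fabs(lat);
    lnx = (lat > 0) ? -1.0 : 1.0;
    lny = 0.0;
  } else {
    double rx = lat, ry = -(d - L); // radial vector from cap center, local frame
    double r = std::sqrt(rx * rx + ry * ry);
    if (r < 1e-12) {
      dist = capr;
      lnx = 0.0;
      lny = 1.0;
    } else {
      dist = capr - r;
      lnx = -rx / r;
      lny = -ry / r;
    }
  }
  from_arm(a, lnx, lny, nx, ny);
}

// [[Rcpp::export]]
LogicalVector maze_contains_cpp(NumericVector x, NumericVector y,
                                double arm_length, double arm_width) {
  R_xlen_t n = x.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = contains_pt(x[i], y[i], arm_length, arm_width);
  return out;
}

// [[Rcpp::export]]
IntegerVector maze_arm_cpp(NumericVector x, NumericVector y,
                           double arm_length, double arm_width) {
  R_xlen_t n = x.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = arm_label_pt(x[i], y[i], arm_length, arm_width);
  return out;
}

// [[Rcpp::export]]
NumericMatrix maze_wall_cpp(NumericVector x, NumericVector y,
                            double arm_length, double arm_width) {
  R_xlen_t n = x.size();
  NumericMatrix out(n, 3);
  for (R_xlen_t i = 0; i < n; ++i) {
    double dist, nx, ny;
    wall_info_pt(x[i], y[i], arm_length, arm_width, dist, nx, ny);
    out(i, 0) = dist;
    out(i, 1) = nx;
    out(i, 2) = ny;
  }
  return out;
}

static inline double wrap_pi(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a < -M_PI) a += 2.0 * M_PI;
  return a;
}

// Specular reflection of a proposed out-of-maze step off the wall of arm a.
// Returns true if a valid in-maze position was produced.
static inline bool reflect_in_arm(int a, double L, double w,
                                  double &px, double &py, double &theta) {
  double capr = w / 2.0;
  double d, lat;
  to_arm(a, px, py, d, lat);
  double vx = std::cos(theta), vy = std::sin(theta);
  // velocity in local frame (local axes: lat, yloc = -d)
  double lvx, lvy;
  {
    double gx = vx, gy = vy;
    double dd, ll;
    // rotate velocity like a point: reuse to_arm on the vector
    to_arm(a, gx, gy, dd, ll);
    lvx = ll;
    lvy = -dd;
  }
  bool changed = false;
  if (d <= L) {
    if (std::fabs(lat) > capr) {
      double s = (lat > 0) ? 1.0 : -1.0;
      double over = std::fabs(lat) - capr;
      lat = s * (capr - over);
      lvx = -lvx;
      changed = true;
    }
  } else {
    double rx = lat, ry = -(d - L);
    double r = std::sqrt(rx * rx + ry * ry);
    if (r > capr && r > 1e-12) {
      double rn = 2.0 * capr - r;
      if (rn < 0) rn = 0.5 * capr;
      lat = rx / r * rn;
      double dnew = L + (-(ry / r * rn));
      d = dnew;
      // reflect local velocity about the tangent (negate radial component)
      double ux = rx / r, uy = ry / r;
      double vr = lvx * ux + lvy * uy;
      lvx -= 2.0 * vr * ux;
      lvy -= 2.0 * vr * uy;
      changed = true;
    }
  }
  if (!changed) return false;
  double gx, gy, gvx, gvy;
  from_arm(a, lat, -d, gx, gy);
  from_arm(a, lvx, lvy, gvx, gvy);
  if (!contains_pt(gx, gy, L, w)) return false;
  px = gx;
  py = gy;
  theta = std::atan2(gvy, gvx);
  return true;
}

// Agent-based locomotion. model: 0 = brownian (heading redrawn uniformly
// each step), 1 = heading random walk, 2 = heading random walk plus
// wall-following steering. Returns an (n_steps + 1) x 2 matrix of positions.
// Uses R's RNG so set.seed() governs determinism.
// [[Rcpp::export]]
NumericMatrix abm_simulate_cpp(int n_steps, double x0, double y0, double theta0,
                               int model, double speed, double heading_noise,
                               double wall_attraction, double sensing_range,
                               double dt, double arm_length, double arm_width) {
  NumericMatrix out(n_steps + 1, 2);
  double px = x0, py = y0, theta = theta0;
  const double L = arm_length, w = arm_width;
  if (!contains_pt(px, py, L, w))
    stop("agent initial state lies outside the maze");
  out(0, 0) = px;
  out(0, 1) = py;
  const double sq_dt = std::sqrt(dt);
  const double blend0 = M_PI / 4.0; // toward-wall blend angle at full range
  for (int i = 1; i <= n_steps; ++i) {
    if (model == 0) {
      theta = R::runif(-M_PI, M_PI);
    } else {
      theta += heading_noise * sq_dt * R::norm_rand();
      theta = wrap_pi(theta);
    }
    if (model == 2 && wall_attraction > 0) {
      double dist, nx, ny;
      wall_info_pt(px, py, L, w, dist, nx, ny);
      if (dist < sensing_range && (nx != 0.0 || ny != 0.0)) {
        // tangent closest to current heading
        double t1x = -ny, t1y = nx;
        double hx = std::cos(theta), hy = std::sin(theta);
        if (t1x * hx + t1y * hy < 0) {
          t1x = -t1x;
          t1y = -t1y;
        }
        // blend slightly toward the wall, vanishing as the wall is reached
        double del = blend0 * (dist / sensing_range);
        double cx = std::cos(del) * t1x + std::sin(del) * (-nx);
        double cy = std::cos(del) * t1y + std::sin(del) * (-ny);
        double target = std::atan2(cy, cx);
        double gain = wall_attraction * dt;
        if (gain > 1.0) gain = 1.0;
        theta = wrap_pi(theta + gain * wrap_pi(target - theta));
      }
    }
    double qx = px + speed * dt * std::cos(theta);
    double qy = py + speed * dt * std::sin(theta);
    if (contains_pt(qx, qy, L, w)) {
      px = qx;
      py = qy;
    } else {
      // reflect off the wall of the arm the agent currently occupies
      int a = arm_label_pt(px, py, L, w);
      bool ok = false;
      if (a >= 0 && a <= 2) {
        double rx = qx, ry = qy, th = theta;
        ok = reflect_in_arm(a, L, w, rx, ry, th);
        if (ok) {
          px = rx;
          py = ry;
          theta = th;
        }
      }
      if (!ok) {
        // try the arm frames of the proposed point, deepest first (a fixed
        // order would resolve escapes near the central notches into one
        // arm preferentially and break left/right symmetry)
        double dep[3], lat_;
        int ord[3] = {0, 1, 2};
        for (int b = 0; b < 3; ++b) to_arm(b, qx, qy, dep[b], lat_);
        for (int u = 0; u < 2; ++u)
          for (int v = u + 1; v < 3; ++v)
            if (dep[ord[v]] > dep[ord[u]]) std::swap(ord[u], ord[v]);
        for (int u = 0; u < 3 && !ok; ++u) {
          double rx = qx, ry = qy, th = theta;
          ok = reflect_in_arm(ord[u], L, w, rx, ry, th);
          if (ok) {
            px = rx;
            py = ry;
            theta = th;
          }
        }
        if (!ok) theta = wrap_pi(theta + M_PI); // stay put, turn around
      }
    }
    out(i, 0) = px;
    out(i, 1) = py;
  }
  return out;
}
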