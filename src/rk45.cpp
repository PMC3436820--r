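#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Natural cubic spline evaluation from knots, values and second derivatives
// at the knots (M, with M[0] = M[N-1] = 0 for natural boundary conditions).
// Outside [t_1, t_N] the spline is continued as a constant at the boundary
// value, so that ODE solvers may step marginally outside the data window.
static double natspline_eval(const double* kn, const double* v,
                             const double* m2, int n, double t) {
  if (t <= kn[0]) return v[0];
  if (t >= kn[n - 1]) return v[n - 1];
  // locate interval by binary search
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (kn[mid] <= t) lo = mid; else hi = mid;
  }
  double h = kn[lo + 1] - kn[lo];
  double a = (kn[lo + 1] - t) / h;
  double b = (t - kn[lo]) / h;
  return a * v[lo] + b * v[lo + 1] +
         ((a * a * a - a) * m2[lo] + (b * b * b - b) * m2[lo + 1]) *
             (h * h) / 6.0;
}

// input types: 0 = Gaussian bell (height, centre, width),
//              1 = natural cubic spline of log10-input (u = 10^S(t)),
//              2 = natural cubic spline on linear scale (u = S(t))
struct InputFn {
  int type;
  double height, centre, width;
  const double* kn;
  const double* v;
  const double* m2;
  int n;
  double eval(double t) const {
    if (type == 0) {
      double z = (t - centre) / width;
      return height * std::exp(-0.5 * z * z);
    }
    double s = natspline_eval(kn, v, m2, n, t);
    return (type == 1) ? std::pow(10.0, s) : s;
  }
};

// Three-state interconversion chain X1 <-> X2 <-> X3, first forward flux
// catalysed by the input u(t): v1 = k1*u*x1, v-1 = km1*x2, v2 = k2*x2,
// v-2 = km2*x3.
static inline void toy_rhs(double t, const double* x, double* dx,
                           const double* k, const InputFn& in) {
  double u = in.eval(t);
  double v1 = k[0] * u * x[0];
  double vm1 = k[1] * x[1];
  double v2 = k[2] * x[1];
  double vm2 = k[3] * x[2];
  dx[0] = -v1 + vm1;
  dx[1] = v1 - vm1 - v2 + vm2;
  dx[2] = v2 - vm2;
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                    e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                    e6 = 187.0 / 2100, e7 = 1.0 / 40;

#define NS 3

// [[Rcpp::export(name = ".rk45_toy")]]
List rk45_toy(NumericVector x0, NumericVector times, NumericVector k,
              List input, double rtol, double atol) {
  InputFn in;
  in.type = as<int>(input["type"]);
  NumericVector ikn, iv, im2;
  if (in.type == 0) {
    in.height = as<double>(input["height"]);
    in.centre = as<double>(input["centre"]);
    in.width = as<double>(input["width"]);
    in.kn = in.v = in.m2 = nullptr;
    in.n = 0;
  } else {
    ikn = as<NumericVector>(input["knots"]);
    iv = as<NumericVector>(input["values"]);
    im2 = as<NumericVector>(input["m2"]);
    in.kn = ikn.begin();
    in.v = iv.begin();
    in.m2 = im2.begin();
    in.n = ikn.size();
  }

  int nt = times.size();
  NumericMatrix out(nt, NS);
  NumericVector uout(nt);

  double x[NS], k1v[NS], k2v[NS], k3v[NS], k4v[NS], k5v[NS], k6v[NS],
      k7v[NS], xt[NS], x5[NS];
  for (int i = 0; i < NS; ++i) x[i] = x0[i];

  double t = times[0];
  int status = 0;
  double tfail = NA_REAL;
  int iout = 0;
  // first output time equals start
  for (int i = 0; i < NS; ++i) out(0, i) = x[i];
  uout[0] = in.eval(t);
  iout = 1;

  double h = (times[nt - 1] - times[0]) / 100.0;
  if (h <= 0) h = 1e-3;
  const double hmin = 1e-12;
  long maxsteps = 100000;

  toy_rhs(t, x, k1v, k.begin(), in);  // FSAL seed

  while (iout < nt && status == 0) {
    double ttarget = times[iout];
    long nstep = 0;
    while (t < ttarget) {
      if (++nstep > maxsteps) { status = 1; tfail = t; break; }
      bool hit = false;
      double hs = h;
      if (t + hs >= ttarget) { hs = ttarget - t; hit = true; }

      for (int i = 0; i < NS; ++i) xt[i] = x[i] + hs * a21 * k1v[i];
      toy_rhs(t + c2 * hs, xt, k2v, k.begin(), in);
      for (int i = 0; i < NS; ++i)
        xt[i] = x[i] + hs * (a31 * k1v[i] + a32 * k2v[i]);
      toy_rhs(t + c3 * hs, xt, k3v, k.begin(), in);
      for (int i = 0; i < NS; ++i)
        xt[i] = x[i] + hs * (a41 * k1v[i] + a42 * k2v[i] + a43 * k3v[i]);
      toy_rhs(t + c4 * hs, xt, k4v, k.begin(), in);
      for (int i = 0; i < NS; ++i)
        xt[i] = x[i] + hs * (a51 * k1v[i] + a52 * k2v[i] + a53 * k3v[i] +
                             a54 * k4v[i]);
      toy_rhs(t + c5 * hs, xt, k5v, k.begin(), in);
      for (int i = 0; i < NS; ++i)
        xt[i] = x[i] + hs * (a61 * k1v[i] + a62 * k2v[i] + a63 * k3v[i] +
                             a64 * k4v[i] + a65 * k5v[i]);
      toy_rhs(t + hs, xt, k6v, k.begin(), in);
      for (int i = 0; i < NS; ++i)
        x5[i] = x[i] + hs * (b1 * k1v[i] + b3 * k3v[i] + b4 * k4v[i] +
                             b5 * k5v[i] + b6 * k6v[i]);
      toy_rhs(t + hs, x5, k7v, k.begin(), in);

      double err = 0.0;
      for (int i = 0; i < NS; ++i) {
        double x4 = x[i] + hs * (e1 * k1v[i] + e3 * k3v[i] + e4 * k4v[i] +
                                 e5 * k5v[i] + e6 * k6v[i] + e7 * k7v[i]);
        double sc = atol + rtol * std::max(std::fabs(x[i]), std::fabs(x5[i]));
        double d = (x5[i] - x4) / sc;
        err += d * d;
      }
      err = std::sqrt(err / NS);

      if (!std::isfinite(err)) { status = 1; tfail = t; break; }

      if (err <= 1.0) {
        t += hs;
        for (int i = 0; i < NS; ++i) { x[i] = x5[i]; k1v[i] = k7v[i]; }
        double fac = (err == 0.0) ? 5.0
                                  : std::min(5.0, std::max(0.2, 0.9 * std::pow(err, -0.2)));
        if (!hit) h = hs * fac; else h = std::max(h, hs * fac);
      } else {
        double fac = std::max(0.2, 0.9 * std::pow(err, -0.2));
        h = hs * fac;
        if (h < hmin) { status = 1; tfail = t; break; }
      }
    }
    if (status != 0) break;
    for (int i = 0; i < NS; ++i) out(iout, i) = x[i];
    uout[iout] = in.eval(t);
    ++iout;
  }

  return List::create(_["states"] = out, _["u"] = uout,
                      _["status"] = status, _["tfail"] = tfail);
}

// [[Rcpp::export(name = ".natspline_eval_cpp")]]
NumericVector natspline_eval_vec(NumericVector knots, NumericVector values,
                                 NumericVector m2, NumericVector t) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = natspline_eval(knots.begin(), values.begin(), m2.begin(),
                            knots.size(), t[i]);
  return out;
}
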