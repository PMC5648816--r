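// Compiled inner loop of the soft-annealing engine: total restraint energy
// and its analytic gradient. Mirrors the R reference implementation
// (anneal_energy / anneal_gradient), which the test suite uses as an
// independent oracle for this code.

#include <Rcpp.h>
using namespace Rcpp;

// Flat-bottom RDC term for one medium, accumulating energy and gradient.
static double rdc_term(const NumericMatrix &X,
                       const IntegerVector &iN, const IntegerVector &iH,
                       const NumericVector &obs, const LogicalVector &act,
                       const NumericMatrix &A, double k, double tol,
                       NumericMatrix *G) {
  double e = 0.0;
  const int n = iN.size();
  for (int r = 0; r < n; ++r) {
    if (!act[r]) continue;
    const int hi = iH[r] - 1, ni = iN[r] - 1;
    double v0 = X(hi, 0) - X(ni, 0);
    double v1 = X(hi, 1) - X(ni, 1);
    double v2 = X(hi, 2) - X(ni, 2);
    double nv = std::sqrt(v0 * v0 + v1 * v1 + v2 * v2);
    double u0 = v0 / nv, u1 = v1 / nv, u2 = v2 / nv;
    double au0 = A(0, 0) * u0 + A(0, 1) * u1 + A(0, 2) * u2;
    double au1 = A(1, 0) * u0 + A(1, 1) * u1 + A(1, 2) * u2;
    double au2 = A(2, 0) * u0 + A(2, 1) * u1 + A(2, 2) * u2;
    double D = u0 * au0 + u1 * au1 + u2 * au2;
    double delta = obs[r] - D;
    double viol = std::fabs(delta) - tol;
    if (viol > 0) {
      e += k * viol;
      if (G) {
        double dEdD = (delta > 0) ? -k : k;
        double g0 = dEdD / nv * (2.0 * au0 - 2.0 * D * u0);
        double g1 = dEdD / nv * (2.0 * au1 - 2.0 * D * u1);
        double g2 = dEdD / nv * (2.0 * au2 - 2.0 * D * u2);
        (*G)(hi, 0) += g0; (*G)(hi, 1) += g1; (*G)(hi, 2) += g2;
        (*G)(ni, 0) -= g0; (*G)(ni, 1) -= g1; (*G)(ni, 2) -= g2;
      }
    }
  }
  return e;
}

static double eval_all(const NumericMatrix &X,
                       const IntegerVector &pi, const IntegerVector &pj,
                       const NumericVector &w, const NumericVector &dref,
                       const IntegerMatrix &quad, double w_plane,
                       const List &media, double k, double tol,
                       NumericMatrix *G) {
  double e = 0.0;
  const int np = pi.size();
  for (int p = 0; p < np; ++p) {
    const int i = pi[p] - 1, j = pj[p] - 1;
    double d0 = X(i, 0) - X(j, 0);
    double d1 = X(i, 1) - X(j, 1);
    double d2 = X(i, 2) - X(j, 2);
    double dd = std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
    double diff = dd - dref[p];
    e += w[p] * diff * diff;
    if (G) {
      double c = 2.0 * w[p] * diff / std::max(dd, 1e-12);
      (*G)(i, 0) += c * d0; (*G)(i, 1) += c * d1; (*G)(i, 2) += c * d2;
      (*G)(j, 0) -= c * d0; (*G)(j, 1) -= c * d1; (*G)(j, 2) -= c * d2;
    }
  }
  const int nq = quad.nrow();
  for (int q = 0; q < nq; ++q) {
    const int p = quad(q, 0) - 1, a = quad(q, 1) - 1;
    const int b = quad(q, 2) - 1, c = quad(q, 3) - 1;
    double ep0 = X(p, 0) - X(a, 0), ep1 = X(p, 1) - X(a, 1), ep2 = X(p, 2) - X(a, 2);
    double eb0 = X(b, 0) - X(a, 0), eb1 = X(b, 1) - X(a, 1), eb2 = X(b, 2) - X(a, 2);
    double ec0 = X(c, 0) - X(a, 0), ec1 = X(c, 1) - X(a, 1), ec2 = X(c, 2) - X(a, 2);
    // V = ep . (eb x ec)
    double cx0 = eb1 * ec2 - eb2 * ec1;
    double cx1 = eb2 * ec0 - eb0 * ec2;
    double cx2 = eb0 * ec1 - eb1 * ec0;
    double V = ep0 * cx0 + ep1 * cx1 + ep2 * cx2;
    e += w_plane * V * V;
    if (G) {
      double f = 2.0 * w_plane * V;
      // dV/dp = eb x ec ; dV/db = ec x ep ; dV/dc = ep x eb
      double gb0 = ec1 * ep2 - ec2 * ep1;
      double gb1 = ec2 * ep0 - ec0 * ep2;
      double gb2 = ec0 * ep1 - ec1 * ep0;
      double gc0 = ep1 * eb2 - ep2 * eb1;
      double gc1 = ep2 * eb0 - ep0 * eb2;
      double gc2 = ep0 * eb1 - ep1 * eb0;
      (*G)(p, 0) += f * cx0; (*G)(p, 1) += f * cx1; (*G)(p, 2) += f * cx2;
      (*G)(b, 0) += f * gb0; (*G)(b, 1) += f * gb1; (*G)(b, 2) += f * gb2;
      (*G)(c, 0) += f * gc0; (*G)(c, 1) += f * gc1; (*G)(c, 2) += f * gc2;
      (*G)(a, 0) -= f * (cx0 + gb0 + gc0);
      (*G)(a, 1) -= f * (cx1 + gb1 + gc1);
      (*G)(a, 2) -= f * (cx2 + gb2 + gc2);
    }
  }
  for (int m = 0; m < media.size(); ++m) {
    List med = media[m];
    e += rdc_term(X, med["iN"], med["iH"], med["obs"], med["act"],
                  med["A"], k, tol, G);
  }
  return e;
}

// [[Rcpp::export(name = ".anneal_energy_cpp")]]
double anneal_energy_cpp(NumericMatrix X, IntegerVector pi, IntegerVector pj,
                         NumericVector w, NumericVector dref,
                         IntegerMatrix quad, double w_plane, List media,
                         double k, double tol) {
  return eval_all(X, pi, pj, w, dref, quad, w_plane, media, k, tol, nullptr);
}

// [[Rcpp::export(name = ".anneal_gradient_cpp")]]
NumericMatrix anneal_gradient_cpp(NumericMatrix X, IntegerVector pi,
                                  IntegerVector pj, NumericVector w,
                                  NumericVector dref, IntegerMatrix quad,
                                  double w_plane, List media, double k,
                                  double tol) {
  NumericMatrix G(X.nrow(), 3);
  eval_all(X, pi, pj, w, dref, quad, w_plane, media, k, tol, &G);
  return G;
}
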