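#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Degeneracy threshold for collinear / coplanar segment configurations:
// below it the signed crossing probability is returned as exactly 0.
static const double DEG_EPS = 1e-12;

static inline void sub3(const double* a, const double* b, double* o) {
  o[0] = a[0] - b[0]; o[1] = a[1] - b[1]; o[2] = a[2] - b[2];
}
static inline void cross3(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }
static inline double clamp1(double x) {
  return x > 1.0 ? 1.0 : (x < -1.0 ? -1.0 : x);
}

// Signed crossing probability of two line segments averaged over all
// projection directions on the sphere (sign by the right-hand rule).
// Closed form: signed area of the spherical quadrilateral spanned by the
// four inter-endpoint directions (Klenin & Langowski method 1a), divided
// by 2*pi because crossings occur for both antipodal direction regions.
static double seg_writhe_core(const double* p1, const double* p2,
                              const double* p3, const double* p4) {
  double r12[3], r34[3], r13[3], r14[3], r23[3], r24[3];
  sub3(p2, p1, r12); sub3(p4, p3, r34);
  sub3(p3, p1, r13); sub3(p4, p1, r14);
  sub3(p3, p2, r23); sub3(p4, p2, r24);

  double n1[3], n2[3], n3[3], n4[3];
  cross3(r13, r14, n1); cross3(r14, r24, n2);
  cross3(r24, r23, n3); cross3(r23, r13, n4);

  double l1 = norm3(n1), l2 = norm3(n2), l3 = norm3(n3), l4 = norm3(n4);
  if (l1 < DEG_EPS || l2 < DEG_EPS || l3 < DEG_EPS || l4 < DEG_EPS)
    return 0.0;  // shared endpoint or (near-)degenerate quadrilateral
  for (int k = 0; k < 3; ++k) {
    n1[k] /= l1; n2[k] /= l2; n3[k] /= l3; n4[k] /= l4;
  }

  double area = std::asin(clamp1(dot3(n1, n2))) +
                std::asin(clamp1(dot3(n2, n3))) +
                std::asin(clamp1(dot3(n3, n4))) +
                std::asin(clamp1(dot3(n4, n1)));

  double sgnv[3];
  cross3(r34, r12, sgnv);
  double s = dot3(sgnv, r13);
  if (std::fabs(s) < DEG_EPS || std::fabs(area) < DEG_EPS)
    return 0.0;  // coplanar configuration
  return (s > 0 ? area : -area) / (2.0 * M_PI);
}

//' @noRd
// [[Rcpp::export]]
double cpp_segment_writhe(NumericVector a_start, NumericVector a_end,
                          NumericVector b_start, NumericVector b_end) {
  if (a_start.size() != 3 || a_end.size() != 3 ||
      b_start.size() != 3 || b_end.size() != 3)
    stop("segment endpoints must be 3-vectors");
  double p1[3], p2[3], p3[3], p4[3];
  for (int k = 0; k < 3; ++k) {
    p1[k] = a_start[k]; p2[k] = a_end[k];
    p3[k] = b_start[k]; p4[k] = b_end[k];
    if (!R_finite(p1[k]) || !R_finite(p2[k]) ||
        !R_finite(p3[k]) || !R_finite(p4[k]))
      stop("non-finite coordinates");
  }
  double ra[3], rb[3];
  sub3(p2, p1, ra); sub3(p4, p3, rb);
  if (norm3(ra) < DEG_EPS || norm3(rb) < DEG_EPS)
    stop("zero-length segment");
  return seg_writhe_core(p1, p2, p3, p4);
}

// Pairwise segment-writhe matrix of a polygonal curve.  Row/column i is
// the segment from point i to point i+1; entries with |i-j| <= 1 are zero
// (a shared endpoint makes the average signed crossing vanish).
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_writhe_matrix(NumericMatrix pts) {
  int npt = pts.nrow();
  if (pts.ncol() != 3) stop("points must be an n x 3 matrix");
  if (npt < 2) stop("need at least two points");
  int n = npt - 1;  // number of segments
  NumericMatrix W(n, n);
  std::vector<double> P(3 * npt);
  for (int i = 0; i < npt; ++i)
    for (int k = 0; k < 3; ++k) {
      double v = pts(i, k);
      if (!R_finite(v)) stop("non-finite coordinates");
      P[3 * i + k] = v;
    }
  for (int i = 0; i < n; ++i) {
    double d[3];
    sub3(&P[3 * (i + 1)], &P[3 * i], d);
    if (norm3(d) < DEG_EPS) stop("zero-length segment in curve");
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double w = seg_writhe_core(&P[3 * i], &P[3 * (i + 1)],
                                 &P[3 * j], &P[3 * (j + 1)]);
      W(i, j) = w;
      W(j, i) = w;
    }
  }
  return W;
}

// ---------------------------------------------------------------------------
// Gauss integrals of orders 1-3 from the writhe matrix.
//
// Every invariant is a sum over strictly increasing segment-index tuples
// i1 < i2 < ... < i2k of a product of one W (or |W|) factor per chord of a
// perfect matching of the 2k tuple positions.  Each matching is evaluated
// by sequential elimination of tuple variables against prefix-sum tables,
// giving O(n^2) or O(n^3) time and O(n^2) memory per invariant.
//
// All tables are 1-based over segments 1..n with a guard row/column 0.
// ---------------------------------------------------------------------------

struct PrefTab {
  int n;
  int n1;                      // stride = n + 1
  std::vector<double> W;       // symmetric matrix, 1-based
  std::vector<double> cw;      // cw[a][y]  = sum_{d<=y} W(a,d)
  std::vector<double> cw2;     // cw2[x][y] = sum_{a<=x} cw[a][y]
  std::vector<double> dsum;    // dsum[p]   = sum_{d<=p} cw[d][d]

  double w(int i, int j) const { return W[i * n1 + j]; }
  double CW(int a, int y) const { return cw[a * n1 + y]; }
  double CW2(int x, int y) const { return cw2[x * n1 + y]; }
  // F(j) = sum_{i<j} W(i,j); G(i) = sum_{j>i} W(i,j)
  double F(int j) const { return CW(j, j - 1); }
  double G(int i) const { return CW(i, n) - CW(i, i); }
  // box sum over c < d < e < f of W(d,e)
  double Phi(int c, int f) const {
    if (f - c < 3) return 0.0;
    double u_hi = CW2(f - 1, f - 1) - dsum[f - 1];
    double u_lo = CW2(c, f - 1) - dsum[c];
    return u_hi - u_lo;
  }
};

static void build_tab(PrefTab& t, const double* Wsrc, int n, bool absval) {
  t.n = n;
  t.n1 = n + 1;
  int n1 = t.n1;
  t.W.assign((size_t)n1 * n1, 0.0);
  t.cw.assign((size_t)n1 * n1, 0.0);
  t.cw2.assign((size_t)n1 * n1, 0.0);
  t.dsum.assign(n1, 0.0);
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= n; ++j) {
      double v = Wsrc[(i - 1) + (size_t)(j - 1) * n];
      t.W[i * n1 + j] = absval ? std::fabs(v) : v;
    }
  for (int a = 1; a <= n; ++a)
    for (int y = 1; y <= n; ++y)
      t.cw[a * n1 + y] = t.cw[a * n1 + y - 1] + t.W[a * n1 + y];
  for (int x = 1; x <= n; ++x)
    for (int y = 0; y <= n; ++y)
      t.cw2[x * n1 + y] = t.cw2[(x - 1) * n1 + y] + t.cw[x * n1 + y];
  for (int p = 1; p <= n; ++p)
    t.dsum[p] = t.dsum[p - 1] + t.cw[p * n1 + p];
}

// -------- order 1:  sum_{i<j} A(i,j) --------
static double ord1(const PrefTab& A) {
  double s = 0.0;
  for (int j = 2; j <= A.n; ++j) s += A.F(j);
  return s;
}

// -------- order 2 --------
// (12)(34): sum_{a<b<c<d} A(a,b) B(c,d)
static double ord2_1234(const PrefTab& A, const PrefTab& B) {
  int n = A.n;
  double s = 0.0, cumFA = 0.0;
  for (int c = 1; c <= n; ++c) {
    s += B.G(c) * cumFA;          // cumFA = sum_{b<c} F_A(b)
    cumFA += A.F(c);
  }
  return s;
}

// (13)(24): sum_{a<b<c<d} A(a,c) B(b,d)
static double ord2_1324(const PrefTab& A, const PrefTab& B) {
  int n = A.n;
  double s = 0.0;
  for (int b = 1; b <= n; ++b)
    for (int c = b + 1; c <= n; ++c)
      s += A.CW(c, b - 1) * (B.CW(b, n) - B.CW(b, c));
  return s;
}

// (14)(23): sum_{a<b<c<d} A(a,d) B(b,c)
static double ord2_1423(const PrefTab& A, const PrefTab& B) {
  int n = A.n;
  double s = 0.0;
  for (int b = 1; b <= n; ++b)
    for (int c = b + 1; c <= n; ++c)
      s += B.w(b, c) * (A.CW2(b - 1, n) - A.CW2(b - 1, c));
  return s;
}

// -------- order 3 (plain W only) --------
// Shared auxiliaries: S[d] = sum_{d<e<f} W(e,f)
static void suffix_S(const PrefTab& t, std::vector<double>& S) {
  int n = t.n;
  S.assign(n + 2, 0.0);
  for (int d = n - 1; d >= 1; --d) S[d] = S[d + 1] + t.G(d + 1);
}

// (12)(34)(56)
static double m01(const PrefTab& t, const std::vector<double>& S) {
  int n = t.n;
  std::vector<double> Q(n + 2, 0.0);     // Q[c] = sum_{d>c} W(c,d) S[d]
  for (int c = 1; c <= n; ++c) {
    double q = 0.0;
    for (int d = c + 1; d <= n; ++d) q += t.w(c, d) * S[d];
    Q[c] = q;
  }
  double qq = 0.0, s = 0.0;              // qq = sum_{c>b} Q[c]
  for (int b = n; b >= 1; --b) {
    s += t.F(b) * qq;
    qq += Q[b];
  }
  return s;
}

// (12)(35)(46)
static double m02(const PrefTab& t) {
  int n = t.n;
  double s = 0.0;
  for (int b = 1; b <= n - 4; ++b) {
    double X = 0.0;
    for (int d = b + 2; d <= n; ++d)
      for (int e = d + 1; e <= n; ++e)
        X += (t.CW(e, d - 1) - t.CW(e, b)) * (t.CW(d, n) - t.CW(d, e));
    s += t.F(b) * X;
  }
  return s;
}

// (12)(36)(45)
static double m03(const PrefTab& t) {
  int n = t.n;
  double s = 0.0;
  for (int b = 1; b <= n - 4; ++b) {
    double X = 0.0;
    for (int d = b + 2; d <= n; ++d)
      for (int e = d + 1; e <= n; ++e)
        X += t.w(d, e) * ((t.CW2(d - 1, n) - t.CW2(d - 1, e)) -
                          (t.CW2(b, n) - t.CW2(b, e)));
    s += t.F(b) * X;
  }
  return s;
}

// (13)(24)(56)
static double m04(const PrefTab& t, const std::vector<double>& S) {
  int n = t.n;
  double s = 0.0;
  std::vector<double> V(n + 2, 0.0);
  for (int b = 1; b <= n; ++b) {
    V[n] = 0.0; V[n + 1] = 0.0;
    for (int c = n - 1; c >= b; --c)
      V[c] = V[c + 1] + t.w(b, c + 1) * S[c + 1];
    for (int c = b + 1; c <= n; ++c)
      s += t.CW(c, b - 1) * V[c];
  }
  return s;
}

// (13)(25)(46)
static double m05(const PrefTab& t) {
  int n = t.n;
  double s = 0.0;
  for (int b = 1; b <= n; ++b)
    for (int e = b + 3; e <= n; ++e) {
      double wbe = t.w(b, e);
      if (wbe == 0.0) continue;
      double K = 0.0;
      for (int d = b + 2; d <= e - 1; ++d)
        K += (t.CW(d, n) - t.CW(d, e)) *
             (t.CW2(d - 1, b - 1) - t.CW2(b, b - 1));
      s += wbe * K;
    }
  return s;
}

// (13)(26)(45)
static double m06(const PrefTab& t) {
  int n = t.n;
  double s = 0.0;
  for (int b = 1; b <= n; ++b)
    for (int f = b + 4; f <= n; ++f) {
      double wbf = t.w(b, f);
      if (wbf == 0.0) continue;
      double inner = 0.0;
      for (int c = b + 1; c <= f - 1; ++c)
        inner += t.CW(c, b - 1) * t.Phi(c, f);
      s += wbf * inner;
    }
  return s;
}

// (14)(23)(56)
static double m07(const PrefTab& t, const std::vector<double>& S) {
  int n = t.n;
  int n1 = n + 1;
  // prefix tables of W'(a,d) = W(a,d) * S[d]
  std::vector<double> cwp((size_t)n1 * n1, 0.0), cwp2((size_t)n1 * n1, 0.0);
  for (int a = 1; a <= n; ++a)
    for (int y = 1; y <= n; ++y)
      cwp[a * n1 + y] = cwp[a * n1 + y - 1] + t.w(a, y) * S[y];
  for (int x = 1; x <= n; ++x)
    for (int y = 0; y <= n; ++y)
      cwp2[x * n1 + y] = cwp2[(x - 1) * n1 + y] + cwp[x * n1 + y];
  double s = 0.0;
  for (int b = 1; b <= n; ++b)
    for (int c = b + 1; c <= n; ++c)
      s += t.w(b, c) * (cwp2[(b - 1) * n1 + n] - cwp2[(b - 1) * n1 + c]);
  return s;
}

// (14)(25)(36)
static double m08(const PrefTab& t) {
  int n = t.n;
  double s = 0.0;
  for (int c = 1; c <= n; ++c)
    for (int e = c + 2; e <= n; ++e) {
      double rce = t.CW(c, n) - t.CW(c, e);   // sum_{f>e} W(c,f)
      if (rce == 0.0) continue;
      double Z = 0.0;
      for (int b = 1; b <= c - 1; ++b)
        Z += t.w(b, e) * (t.CW2(e - 1, b - 1) - t.CW2(c, b - 1));
      s += Z * rce;
    }
  return s;
}

// (14)(26)(35)
static double m09(const PrefTab& t) {
  int n = t.n;
  double s = 0.0;
  for (int c = 1; c <= n; ++c)
    for (int e = c + 2; e <= n; ++e) {
      double wce = t.w(c, e);
      if (wce == 0.0) continue;
      double Y = 0.0;
      for (int b = 1; b <= c - 1; ++b)
        Y += (t.CW(b, n) - t.CW(b, e)) *
             (t.CW2(b - 1, e - 1) - t.CW2(b - 1, c));
      s += wce * Y;
    }
  return s;
}

// (15)(23)(46)
static double m10(const PrefTab& t) {
  int n = t.n;
  int n1 = n + 1;
  // rho[a][c] = sum_{e>c+1} W(a,e) * sum_{c<d<e} (sum_{f>e} W(d,f))
  std::vector<double> sig((size_t)n1 * n1, 0.0);  // prefix over a of rho
  for (int a = 1; a <= n; ++a)
    for (int c = 1; c <= n; ++c) {
      double rho = 0.0;
      for (int e = c + 2; e <= n; ++e) {
        double sr = (t.CW2(e - 1, n) - t.CW2(e - 1, e)) -
                    (t.CW2(c, n) - t.CW2(c, e));
        rho += t.w(a, e) * sr;
      }
      sig[a * n1 + c] = sig[(a - 1) * n1 + c] + rho;
    }
  double s = 0.0;
  for (int b = 1; b <= n; ++b)
    for (int c = b + 1; c <= n; ++c)
      s += t.w(b, c) * sig[(b - 1) * n1 + c];
  return s;
}

// (15)(24)(36)
static double m11(const PrefTab& t) {
  int n = t.n;
  int n1 = n + 1;
  // xi[b][y] = sum_{d<=y} W(b,d) * CW2(d, b-1)
  std::vector<double> xi((size_t)n1 * n1, 0.0);
  for (int b = 1; b <= n; ++b)
    for (int y = 1; y <= n; ++y)
      xi[b * n1 + y] = xi[b * n1 + y - 1] + t.w(b, y) * t.CW2(y, b - 1);
  double s = 0.0;
  for (int c = 1; c <= n; ++c)
    for (int f = c + 3; f <= n; ++f) {
      double wcf = t.w(c, f);
      if (wcf == 0.0) continue;
      double inner = 0.0;
      for (int b = 1; b <= c - 1; ++b)
        inner += t.CW2(f - 1, b - 1) * (t.CW(b, f - 1) - t.CW(b, c)) -
                 (xi[b * n1 + f - 1] - xi[b * n1 + c]);
      s += wcf * inner;
    }
  return s;
}

// (15)(26)(34)
static double m12(const PrefTab& t) {
  int n = t.n;
  int n1 = n + 1;
  // kap[c][e] = sum_{b<c} (sum_{a<b} W(a,e)) (sum_{f>e} W(b,f))
  std::vector<double> kap((size_t)n1 * n1, 0.0);
  for (int c = 2; c <= n; ++c)
    for (int e = 1; e <= n; ++e)
      kap[c * n1 + e] = kap[(c - 1) * n1 + e] +
        t.CW(e, c - 2) * (t.CW(c - 1, n) - t.CW(c - 1, e));
  double s = 0.0;
  for (int c = 1; c <= n; ++c) {
    double kbar = 0.0;  // sum_{e>d} kap[c][e], built as suffix in d
    for (int d = n; d >= c + 1; --d) {
      if (d + 1 <= n) kbar += kap[c * n1 + d + 1];
      s += t.w(c, d) * kbar;
    }
  }
  return s;
}

// (16)(23)(45)
static double m13(const PrefTab& t) {
  int n = t.n;
  double s = 0.0;
  for (int b = 1; b <= n; ++b)
    for (int c = b + 1; c <= n; ++c) {
      double wbc = t.w(b, c);
      if (wbc == 0.0) continue;
      double om = 0.0;
      for (int e = c + 2; e <= n; ++e)
        om += (t.CW2(b - 1, n) - t.CW2(b - 1, e)) *
              (t.F(e) - t.CW(e, c));
      s += wbc * om;
    }
  return s;
}

// (16)(24)(35)
static double m14(const PrefTab& t) {
  int n = t.n;
  double s = 0.0;
  for (int c = 1; c <= n; ++c)
    for (int e = c + 2; e <= n; ++e) {
      double wce = t.w(c, e);
      if (wce == 0.0) continue;
      double inner = 0.0;
      for (int b = 1; b <= c - 1; ++b)
        inner += (t.CW2(b - 1, n) - t.CW2(b - 1, e)) *
                 (t.CW(b, e - 1) - t.CW(b, c));
      s += wce * inner;
    }
  return s;
}

// (16)(25)(34)
static double m15(const PrefTab& t) {
  int n = t.n;
  int n1 = n + 1;
  // nu[b][d] = sum_{e>d} W(b,e) * T(b-1, e+1), then prefix over b
  std::vector<double> nubar((size_t)n1 * n1, 0.0);
  std::vector<double> nu(n + 2, 0.0);
  for (int b = 1; b <= n; ++b) {
    nu[n] = 0.0; nu[n + 1] = 0.0;
    for (int d = n - 1; d >= 1; --d)
      nu[d] = nu[d + 1] +
        t.w(b, d + 1) * (t.CW2(b - 1, n) - t.CW2(b - 1, d + 1));
    for (int d = 1; d <= n; ++d)
      nubar[b * n1 + d] = nubar[(b - 1) * n1 + d] + nu[d];
  }
  double s = 0.0;
  for (int c = 2; c <= n; ++c)
    for (int d = c + 1; d <= n; ++d)
      s += t.w(c, d) * nubar[(c - 1) * n1 + d];
  return s;
}

// All 29 Gauss integrals in the fixed pattern order (see chord_patterns()
// on the R side): order 1 {plain, abs}; order 2 {3 matchings x 4 abs
// variants}; order 3 {15 matchings, plain}.
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_gauss_invariants(NumericMatrix W) {
  int n = W.nrow();
  if (W.ncol() != n) stop("writhe matrix must be square");
  PrefTab P, A;                 // plain and absolute-value tables
  build_tab(P, W.begin(), n, false);
  build_tab(A, W.begin(), n, true);
  std::vector<double> S;
  suffix_S(P, S);

  NumericVector out(29);
  int k = 0;
  // order 1
  out[k++] = ord1(P);
  out[k++] = ord1(A);
  // order 2: matchings (12)(34), (13)(24), (14)(23);
  // abs variants per matching: none, first chord, second chord, both
  double (*fns[3])(const PrefTab&, const PrefTab&) =
    {ord2_1234, ord2_1324, ord2_1423};
  for (int m = 0; m < 3; ++m) {
    out[k++] = fns[m](P, P);
    out[k++] = fns[m](A, P);
    out[k++] = fns[m](P, A);
    out[k++] = fns[m](A, A);
  }
  // order 3: all 15 perfect matchings of six positions, lexicographic
  out[k++] = m01(P, S);
  out[k++] = m02(P);
  out[k++] = m03(P);
  out[k++] = m04(P, S);
  out[k++] = m05(P);
  out[k++] = m06(P);
  out[k++] = m07(P, S);
  out[k++] = m08(P);
  out[k++] = m09(P);
  out[k++] = m10(P);
  out[k++] = m11(P);
  out[k++] = m12(P);
  out[k++] = m13(P);
  out[k++] = m14(P);
  out[k++] = m15(P);
  return out;
}
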