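// Exact polyhedral-geometry kernel.
//
// Everything here works over exact rationals (see bigint.h).  The central
// routine is double-description ray enumeration for cones of the form
// {z >= 0, M z = 0}; all other cone/polyhedron enumerations in the R layer
// are reduced to this form by variable splitting, slack variables and
// homogenization.  Rational values cross the R boundary as "p/q" strings so
// that no precision is lost.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include "bigint.h"

using namespace Rcpp;
using eg::BI;
using eg::Rat;

typedef std::vector<Rat> RatVec;
typedef std::vector<RatVec> RatMat;
typedef std::vector<BI> BIVec;

// ---------------------------------------------------------------------------
// conversions
// ---------------------------------------------------------------------------

static RatMat mat_from_R(const CharacterMatrix& M) {
  RatMat out(M.nrow(), RatVec(M.ncol()));
  for (int i = 0; i < M.nrow(); ++i)
    for (int j = 0; j < M.ncol(); ++j)
      out[i][j] = eg::rat_from_string(as<std::string>(M(i, j)));
  return out;
}

static RatVec vec_from_R(const CharacterVector& v) {
  RatVec out(v.size());
  for (int i = 0; i < v.size(); ++i)
    out[i] = eg::rat_from_string(as<std::string>(v[i]));
  return out;
}

static CharacterMatrix mat_to_R(const RatMat& M, int ncol_hint = 0) {
  int nr = (int)M.size();
  int nc = nr ? (int)M[0].size() : ncol_hint;
  CharacterMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      out(i, j) = eg::rat_to_string(M[i][j]);
  return out;
}

static CharacterVector vec_to_R(const RatVec& v) {
  CharacterVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = eg::rat_to_string(v[i]);
  return out;
}

// clear denominators of a rational row -> coprime integer row
static BIVec int_row(const RatVec& row) {
  BI l(1);
  for (const Rat& r : row)
    if (!r.is_zero()) l = eg::divexact(eg::mul(l, r.den), eg::gcd(l, r.den));
  BIVec out(row.size());
  for (size_t j = 0; j < row.size(); ++j)
    out[j] = eg::mul(row[j].num, eg::divexact(l, row[j].den));
  BI g;
  for (const BI& b : out) g = eg::gcd(g, b);
  if (g.sign != 0 && !(g.d.size() == 1 && g.d[0] == 1))
    for (BI& b : out) b = eg::divexact(b, g);
  return out;
}

static void canon_ray(BIVec& r) {
  BI g;
  for (const BI& b : r) g = eg::gcd(g, b);
  if (g.sign != 0 && !(g.d.size() == 1 && g.d[0] == 1))
    for (BI& b : r) b = eg::divexact(b, g);
}

// ---------------------------------------------------------------------------
// double description for {z in R^n : z >= 0, M z = 0}
// ---------------------------------------------------------------------------

struct ZSet {  // zero set over coordinates, as dynamic bitset
  std::vector<uint64_t> w;
  void init(size_t n) { w.assign((n + 63) / 64, 0); }
  void set(size_t i) { w[i / 64] |= (uint64_t)1 << (i % 64); }
};

static bool zs_subset(const ZSet& a, const ZSet& b) {  // a subseteq b ?
  for (size_t i = 0; i < a.w.size(); ++i)
    if (a.w[i] & ~b.w[i]) return false;
  return true;
}

static ZSet zs_and(const ZSet& a, const ZSet& b) {
  ZSet r;
  r.w.resize(a.w.size());
  for (size_t i = 0; i < a.w.size(); ++i) r.w[i] = a.w[i] & b.w[i];
  return r;
}

static ZSet zero_set(const BIVec& ray) {
  ZSet z;
  z.init(ray.size());
  for (size_t i = 0; i < ray.size(); ++i)
    if (ray[i].sign == 0) z.set(i);
  return z;
}

// extreme rays of the pointed cone {z >= 0, M z = 0}; rays returned as
// canonical (coprime, nonnegative integer) rows
static std::vector<BIVec> dd_rays(const RatMat& Mrat, int n) {
  std::vector<BIVec> rays;
  for (int i = 0; i < n; ++i) {
    BIVec u(n);
    u[i] = BI(1);
    rays.push_back(u);
  }
  for (const RatVec& rrow : Mrat) {
    BIVec row = int_row(rrow);
    std::vector<BI> dot(rays.size());
    for (size_t r = 0; r < rays.size(); ++r) {
      BI s;
      for (int j = 0; j < n; ++j)
        if (row[j].sign != 0 && rays[r][j].sign != 0)
          s = eg::add(s, eg::mul(row[j], rays[r][j]));
      dot[r] = s;
    }
    std::vector<size_t> P, Z, N;
    for (size_t r = 0; r < rays.size(); ++r) {
      if (dot[r].sign > 0) P.push_back(r);
      else if (dot[r].sign < 0) N.push_back(r);
      else Z.push_back(r);
    }
    if (P.empty() && N.empty()) continue;  // row redundant
    std::vector<ZSet> zs(rays.size());
    for (size_t r = 0; r < rays.size(); ++r) zs[r] = zero_set(rays[r]);
    std::vector<BIVec> next;
    for (size_t r : Z) next.push_back(rays[r]);
    for (size_t p : P) {
      for (size_t q : N) {
        // combinatorial adjacency: no third ray's zero set contains the pair's
        ZSet common = zs_and(zs[p], zs[q]);
        bool adjacent = true;
        for (size_t t = 0; t < rays.size(); ++t) {
          if (t == p || t == q) continue;
          if (zs_subset(common, zs[t])) { adjacent = false; break; }
        }
        if (!adjacent) continue;
        BIVec nr(n);
        BI a = dot[p];          // > 0
        BI b = eg::neg(dot[q]); // > 0
        for (int j = 0; j < n; ++j)
          nr[j] = eg::add(eg::mul(b, rays[p][j]), eg::mul(a, rays[q][j]));
        canon_ray(nr);
        next.push_back(std::move(nr));
      }
    }
    rays.swap(next);
    if (rays.empty()) break;  // cone is {0}
  }
  return rays;
}

// [[Rcpp::export]]
CharacterMatrix cxx_dd_rays(CharacterMatrix M, int n) {
  RatMat Mr = mat_from_R(M);
  std::vector<BIVec> rays = dd_rays(Mr, n);
  CharacterMatrix out((int)rays.size(), n);
  for (size_t i = 0; i < rays.size(); ++i)
    for (int j = 0; j < n; ++j)
      out((int)i, j) = eg::bi_to_string(rays[i][j]);
  return out;
}

// ---------------------------------------------------------------------------
// exact linear algebra: rank, nullspace, solve
// ---------------------------------------------------------------------------

// row echelon in place; returns pivot columns
static std::vector<int> echelon(RatMat& A) {
  std::vector<int> piv;
  size_t m = A.size();
  if (m == 0) return piv;
  size_t n = A[0].size();
  size_t r = 0;
  for (size_t c = 0; c < n && r < m; ++c) {
    size_t sel = m;
    for (size_t i = r; i < m; ++i)
      if (!A[i][c].is_zero()) { sel = i; break; }
    if (sel == m) continue;
    std::swap(A[r], A[sel]);
    Rat p = A[r][c];
    for (size_t j = c; j < n; ++j) A[r][j] = eg::rdiv(A[r][j], p);
    for (size_t i = 0; i < m; ++i) {
      if (i == r || A[i][c].is_zero()) continue;
      Rat f = A[i][c];
      for (size_t j = c; j < n; ++j)
        A[i][j] = eg::rsub(A[i][j], eg::rmul(f, A[r][j]));
    }
    piv.push_back((int)c);
    ++r;
  }
  return piv;
}

// [[Rcpp::export]]
int cxx_rank(CharacterMatrix M) {
  RatMat A = mat_from_R(M);
  return (int)echelon(A).size();
}

// basis of {x : M x = 0}, rows of the returned matrix
// [[Rcpp::export]]
CharacterMatrix cxx_nullspace(CharacterMatrix M) {
  RatMat A = mat_from_R(M);
  int n = M.ncol();
  std::vector<int> piv = echelon(A);
  std::vector<bool> is_piv(n, false);
  for (int c : piv) is_piv[c] = true;
  RatMat basis;
  for (int c = 0; c < n; ++c) {
    if (is_piv[c]) continue;
    RatVec v(n);
    v[c] = Rat(1);
    for (size_t r = 0; r < piv.size(); ++r)
      v[piv[r]] = eg::rneg(A[r][c]);
    basis.push_back(v);
  }
  return mat_to_R(basis, n);
}

// solve M x = b; status 0 = unique, 1 = underdetermined (particular solution
// returned with free coordinates zero), 2 = inconsistent
// [[Rcpp::export]]
List cxx_solve(CharacterMatrix M, CharacterVector b) {
  RatMat A = mat_from_R(M);
  RatVec rhs = vec_from_R(b);
  int n = M.ncol();
  for (size_t i = 0; i < A.size(); ++i) A[i].push_back(rhs[i]);
  std::vector<int> piv = echelon(A);
  bool inconsistent = false;
  for (int c : piv)
    if (c == n) inconsistent = true;
  if (inconsistent)
    return List::create(_["status"] = 2, _["x"] = CharacterVector(0));
  RatVec x(n);
  for (size_t r = 0; r < piv.size(); ++r) x[piv[r]] = A[r][n];
  int status = ((int)piv.size() == n) ? 0 : 1;
  return List::create(_["status"] = status, _["x"] = vec_to_R(x));
}

// ---------------------------------------------------------------------------
// exact simplex: min c^T z  s.t.  M z = f, z >= 0   (Bland's rule)
// ---------------------------------------------------------------------------

struct Tableau {
  RatMat T;                 // m x (n+1), last column rhs
  std::vector<int> basis;   // basic variable per row
  int n;
};

static void pivot(Tableau& tb, int row, int col) {
  RatVec& pr = tb.T[row];
  Rat p = pr[col];
  for (size_t j = 0; j < pr.size(); ++j) pr[j] = eg::rdiv(pr[j], p);
  for (size_t i = 0; i < tb.T.size(); ++i) {
    if ((int)i == row || tb.T[i][col].is_zero()) continue;
    Rat f = tb.T[i][col];
    for (size_t j = 0; j < pr.size(); ++j)
      tb.T[i][j] = eg::rsub(tb.T[i][j], eg::rmul(f, pr[j]));
  }
  tb.basis[row] = col;
}

// minimize reduced costs; returns 0 optimal, 2 unbounded
static int simplex_core(Tableau& tb, RatVec& cost, Rat& obj) {
  int m = (int)tb.T.size();
  for (;;) {
    // reduced costs: c_j - c_B^T B^{-1} A_j (tableau already reduced, so
    // compute cbar_j = cost_j - sum_i cost[basis[i]] * T[i][j])
    int enter = -1;
    for (int j = 0; j < tb.n; ++j) {
      Rat cb = cost[j];
      for (int i = 0; i < m; ++i)
        if (!cost[tb.basis[i]].is_zero() && !tb.T[i][j].is_zero())
          cb = eg::rsub(cb, eg::rmul(cost[tb.basis[i]], tb.T[i][j]));
      if (cb.sgn() < 0) { enter = j; break; }  // Bland: first improving index
    }
    if (enter < 0) {
      obj = Rat(0);
      for (int i = 0; i < m; ++i)
        if (!cost[tb.basis[i]].is_zero())
          obj = eg::radd(obj, eg::rmul(cost[tb.basis[i]], tb.T[i][tb.n]));
      return 0;
    }
    int leave = -1;
    Rat best;
    for (int i = 0; i < m; ++i) {
      if (tb.T[i][enter].sgn() <= 0) continue;
      Rat ratio = eg::rdiv(tb.T[i][tb.n], tb.T[i][enter]);
      if (leave < 0 || eg::rcmp(ratio, best) < 0 ||
          (eg::rcmp(ratio, best) == 0 && tb.basis[i] < tb.basis[leave])) {
        leave = i;
        best = ratio;
      }
    }
    if (leave < 0) return 2;
    pivot(tb, leave, enter);
  }
}

// [[Rcpp::export]]
List cxx_simplex(CharacterMatrix M, CharacterVector f, CharacterVector c) {
  RatMat A = mat_from_R(M);
  RatVec rhs = vec_from_R(f);
  RatVec cost = vec_from_R(c);
  int m = (int)A.size(), n = M.ncol();
  // phase 1 with artificial variables
  Tableau tb;
  tb.n = n + m;
  tb.T.assign(m, RatVec(n + m + 1));
  tb.basis.resize(m);
  for (int i = 0; i < m; ++i) {
    int sg = rhs[i].sgn() < 0 ? -1 : 1;
    for (int j = 0; j < n; ++j)
      tb.T[i][j] = sg < 0 ? eg::rneg(A[i][j]) : A[i][j];
    tb.T[i][n + i] = Rat(1);
    tb.T[i][n + m] = sg < 0 ? eg::rneg(rhs[i]) : rhs[i];
    tb.basis[i] = n + i;
  }
  RatVec cost1(n + m);
  for (int j = 0; j < m; ++j) cost1[n + j] = Rat(1);
  Rat obj;
  simplex_core(tb, cost1, obj);
  if (obj.sgn() != 0)
    return List::create(_["status"] = 1, _["z"] = CharacterVector(0),
                        _["obj"] = "0");
  // drive remaining artificials out of the basis where possible
  for (int i = 0; i < m; ++i) {
    if (tb.basis[i] < n) continue;
    int col = -1;
    for (int j = 0; j < n; ++j)
      if (!tb.T[i][j].is_zero()) { col = j; break; }
    if (col >= 0) pivot(tb, i, col);
    // else: redundant row, artificial stays basic at value 0
  }
  // phase 2
  RatVec cost2(n + m);
  for (int j = 0; j < n; ++j) cost2[j] = cost[j];
  // forbid artificials from re-entering: set n (original) as tableau width
  // by zeroing their columns
  for (size_t i = 0; i < tb.T.size(); ++i)
    for (int j = n; j < n + m; ++j) tb.T[i][j] = Rat(0);
  // keep artificial basics (value 0) pinned by marking their cost zero
  int st = simplex_core(tb, cost2, obj);
  if (st == 2)
    return List::create(_["status"] = 2, _["z"] = CharacterVector(0),
                        _["obj"] = "0");
  RatVec z(n);
  for (int i = 0; i < m; ++i)
    if (tb.basis[i] < n) z[tb.basis[i]] = tb.T[i][n + m];
  return List::create(_["status"] = 0, _["z"] = vec_to_R(z),
                      _["obj"] = eg::rat_to_string(obj));
}

// ---------------------------------------------------------------------------
// residual signs: sign(A x - b) for columns x of X
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cxx_residual_signs(CharacterMatrix A, CharacterVector b,
                                 CharacterMatrix X) {
  RatMat Ar = mat_from_R(A);
  RatVec br = vec_from_R(b);
  RatMat Xr = mat_from_R(X);  // n x k
  int m = A.nrow(), n = A.ncol(), k = X.ncol();
  IntegerMatrix out(m, k);
  for (int col = 0; col < k; ++col) {
    for (int i = 0; i < m; ++i) {
      Rat s = eg::rneg(br[i]);
      for (int j = 0; j < n; ++j)
        if (!Ar[i][j].is_zero() && !Xr[j][col].is_zero())
          s = eg::radd(s, eg::rmul(Ar[i][j], Xr[j][col]));
      out(i, col) = s.sgn();
    }
  }
  return out;
}

// exact matrix product (A %*% B) on "p/q" strings
// [[Rcpp::export]]
CharacterMatrix cxx_matmul(CharacterMatrix A, CharacterMatrix B) {
  RatMat Ar = mat_from_R(A), Br = mat_from_R(B);
  int m = A.nrow(), n = A.ncol(), k = B.ncol();
  RatMat out(m, RatVec(k));
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < k; ++j) {
      Rat s;
      for (int l = 0; l < n; ++l)
        if (!Ar[i][l].is_zero() && !Br[l][j].is_zero())
          s = eg::radd(s, eg::rmul(Ar[i][l], Br[l][j]));
      out[i][j] = s;
    }
  return mat_to_R(out, k);
}

// elementwise a op b with op in {"+","-","*","/"} (vectors, recycled scalar b)
// [[Rcpp::export]]
CharacterVector cxx_elementwise(CharacterVector a, CharacterVector b,
                                std::string op) {
  RatVec ar = vec_from_R(a), br = vec_from_R(b);
  size_t n = std::max(ar.size(), br.size());
  RatVec out(n);
  for (size_t i = 0; i < n; ++i) {
    const Rat& x = ar[i % ar.size()];
    const Rat& y = br[i % br.size()];
    if (op == "+") out[i] = eg::radd(x, y);
    else if (op == "-") out[i] = eg::rsub(x, y);
    else if (op == "*") out[i] = eg::rmul(x, y);
    else if (op == "/") out[i] = eg::rdiv(x, y);
    else stop("unknown op");
  }
  return vec_to_R(out);
}

// [[Rcpp::export]]
NumericVector cxx_rat_to_num(CharacterVector a) {
  NumericVector out(a.size());
  for (int i = 0; i < a.size(); ++i)
    out[i] = eg::rat_to_double(eg::rat_from_string(as<std::string>(a[i])));
  return out;
}

// canonical form: validates and reduces "p/q" strings
// [[Rcpp::export]]
CharacterVector cxx_rat_canon(CharacterVector a) {
  CharacterVector out(a.size());
  for (int i = 0; i < a.size(); ++i)
    out[i] = eg::rat_to_string(eg::rat_from_string(as<std::string>(a[i])));
  return out;
}

// scale rows of X so each is a coprime integer vector (positive scaling only)
// [[Rcpp::export]]
CharacterMatrix cxx_canon_rows(CharacterMatrix X) {
  RatMat Xr = mat_from_R(X);
  int nc = X.ncol();
  CharacterMatrix out(X.nrow(), nc);
  for (int i = 0; i < X.nrow(); ++i) {
    BIVec row = int_row(Xr[i]);
    for (int j = 0; j < nc; ++j) out(i, j) = eg::bi_to_string(row[j]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// greedy conformal decomposition inside a cone {x : A x >= 0, G x = 0,
// x_nonneg >= 0}.  EVs in rows of E; target assumed to be a member.
// Each step subtracts the largest sign-compatible multiple of an EV that
// keeps the remainder in the cone; this zeroes at least one coordinate of x
// or of Ax per step (the constructive argument behind the conformal-sum
// theorems), so the term count is bounded by |supp(x)| + |supp(Ax)|.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cxx_decompose(CharacterMatrix A, CharacterMatrix E, CharacterVector x) {
  RatMat Ar = mat_from_R(A);       // inequality rows only
  RatMat Er = mat_from_R(E);       // EVs as rows
  RatVec rem = vec_from_R(x);
  int n = (int)rem.size(), m = (int)Ar.size(), K = (int)Er.size();
  RatVec coef(K);

  // pre-compute A e for every EV
  RatMat Ae(K, RatVec(m));
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < m; ++i) {
      Rat s;
      for (int j = 0; j < n; ++j)
        if (!Ar[i][j].is_zero() && !Er[k][j].is_zero())
          s = eg::radd(s, eg::rmul(Ar[i][j], Er[k][j]));
      Ae[k][i] = s;
    }

  RatVec Arem(m);
  for (int i = 0; i < m; ++i) {
    Rat s;
    for (int j = 0; j < n; ++j)
      if (!Ar[i][j].is_zero() && !rem[j].is_zero())
        s = eg::radd(s, eg::rmul(Ar[i][j], rem[j]));
    Arem[i] = s;
  }

  int guard = 2 * (n + m) + 4;
  while (guard-- > 0) {
    bool zero = true;
    for (int j = 0; j < n; ++j)
      if (!rem[j].is_zero()) { zero = false; break; }
    if (zero) break;
    int pick = -1;
    Rat lam;
    for (int k = 0; k < K; ++k) {
      // sign compatibility with remainder
      bool ok = true;
      for (int j = 0; j < n && ok; ++j) {
        int se = Er[k][j].sgn();
        if (se != 0 && se != rem[j].sgn()) ok = false;
      }
      if (!ok) continue;
      // lambda* = largest step keeping remainder in cone and sign-compatible
      bool has = false, positive = true;
      Rat lmin;
      for (int j = 0; j < n; ++j) {
        int se = Er[k][j].sgn();
        if (se == 0) continue;
        Rat ratio = eg::rdiv(rem[j], Er[k][j]);
        if (!has || eg::rcmp(ratio, lmin) < 0) { lmin = ratio; has = true; }
      }
      for (int i = 0; i < m; ++i) {
        if (Ae[k][i].sgn() <= 0) continue;
        Rat ratio = eg::rdiv(Arem[i], Ae[k][i]);
        if (ratio.sgn() <= 0) { positive = false; break; }
        if (!has || eg::rcmp(ratio, lmin) < 0) { lmin = ratio; has = true; }
      }
      if (!has || !positive || lmin.sgn() <= 0) continue;
      pick = k;
      lam = lmin;
      break;
    }
    if (pick < 0)
      return List::create(_["ok"] = false, _["coef"] = CharacterVector(0));
    coef[pick] = eg::radd(coef[pick], lam);
    for (int j = 0; j < n; ++j)
      if (!Er[pick][j].is_zero())
        rem[j] = eg::rsub(rem[j], eg::rmul(lam, Er[pick][j]));
    for (int i = 0; i < m; ++i)
      if (!Ae[pick][i].is_zero())
        Arem[i] = eg::rsub(Arem[i], eg::rmul(lam, Ae[pick][i]));
  }
  bool done = true;
  for (int j = 0; j < n; ++j)
    if (!rem[j].is_zero()) { done = false; break; }
  return List::create(_["ok"] = done, _["coef"] = vec_to_R(coef));
}

// ---------------------------------------------------------------------------
// float-mode double description (tolerance-based), for large models where
// exact arithmetic is too slow.  Same cone form {z >= 0, M z = 0}.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cxx_dd_rays_float(NumericMatrix M, int n, double tol) {
  std::vector<std::vector<double> > rays;
  for (int i = 0; i < n; ++i) {
    std::vector<double> u(n, 0.0);
    u[i] = 1.0;
    rays.push_back(u);
  }
  for (int r = 0; r < M.nrow(); ++r) {
    std::vector<double> row(n);
    for (int j = 0; j < n; ++j) row[j] = M(r, j);
    std::vector<double> dot(rays.size());
    for (size_t k = 0; k < rays.size(); ++k) {
      double s = 0;
      for (int j = 0; j < n; ++j) s += row[j] * rays[k][j];
      dot[k] = s;
    }
    std::vector<size_t> P, Z, N;
    for (size_t k = 0; k < rays.size(); ++k) {
      if (dot[k] > tol) P.push_back(k);
      else if (dot[k] < -tol) N.push_back(k);
      else Z.push_back(k);
    }
    if (P.empty() && N.empty()) continue;
    std::vector<std::vector<bool> > zs(rays.size(), std::vector<bool>(n));
    for (size_t k = 0; k < rays.size(); ++k)
      for (int j = 0; j < n; ++j) zs[k][j] = std::fabs(rays[k][j]) <= tol;
    std::vector<std::vector<double> > next;
    for (size_t k : Z) next.push_back(rays[k]);
    for (size_t p : P)
      for (size_t q : N) {
        bool adjacent = true;
        for (size_t t = 0; t < rays.size() && adjacent; ++t) {
          if (t == p || t == q) continue;
          bool contains = true;
          for (int j = 0; j < n; ++j)
            if (zs[p][j] && zs[q][j] && !zs[t][j]) { contains = false; break; }
          if (contains) adjacent = false;
        }
        if (!adjacent) continue;
        std::vector<double> nr(n);
        double norm = 0;
        for (int j = 0; j < n; ++j) {
          nr[j] = (-dot[q]) * rays[p][j] + dot[p] * rays[q][j];
          norm += nr[j] * nr[j];
        }
        norm = std::sqrt(norm);
        for (int j = 0; j < n; ++j) {
          nr[j] /= norm;
          if (std::fabs(nr[j]) <= tol) nr[j] = 0;
        }
        next.push_back(nr);
      }
    rays.swap(next);
    if (rays.empty()) break;
  }
  NumericMatrix out((int)rays.size(), n);
  for (size_t i = 0; i < rays.size(); ++i)
    for (int j = 0; j < n; ++j) out((int)i, j) = rays[i][j];
  return out;
}
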