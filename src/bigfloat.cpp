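// Arbitrary-precision floating-point core and the Gauss-diffusion-quadrature
// moment machinery built on top of it.
//
// The moments -> recurrence-coefficient map for the diffusion weight function
// is catastrophically ill-conditioned (it loses O(2N log10 R) digits), so the
// moment recurrences and the orthogonal-polynomial inner products must run at
// ~100+ decimal digits.  Numbers are sign/exponent/limb triples with 6 decimal
// digits per limb; schoolbook arithmetic is ample at these sizes (<= ~100
// limbs, polynomial degrees <= ~40).

#include <Rcpp.h>
#include <vector>
#include <map>
#include <string>
#include <cmath>
#include <cstdint>
#include <cstdio>
#include <algorithm>

using namespace Rcpp;

namespace bf {

typedef long long ll;
static const ll B = 1000000LL; // limb base: 6 decimal digits
static const int LD = 6;

static int g_prec = 30; // working precision, in limbs

struct Num {
  int sign;          // -1, 0, +1
  ll e;              // value = sign * sum_i m[i] * B^(e - i)
  std::vector<ll> m; // m[0] != 0 when sign != 0
  Num() : sign(0), e(0) {}
};

struct PrecGuard {
  int saved;
  explicit PrecGuard(int limbs) : saved(g_prec) { g_prec = limbs; }
  ~PrecGuard() { g_prec = saved; }
};

static void trim(Num &x) {
  size_t i = 0;
  while (i < x.m.size() && x.m[i] == 0) ++i;
  if (i == x.m.size()) { x.sign = 0; x.e = 0; x.m.clear(); return; }
  if (i > 0) {
    x.m.erase(x.m.begin(), x.m.begin() + i);
    x.e -= (ll)i;
  }
  if ((int)x.m.size() > g_prec) x.m.resize(g_prec);
  while (!x.m.empty() && x.m.back() == 0) x.m.pop_back();
  if (x.m.empty()) { x.sign = 0; x.e = 0; }
}

static bool is_zero(const Num &x) { return x.sign == 0; }

static Num from_ll(ll v) {
  Num x;
  if (v == 0) return x;
  x.sign = v < 0 ? -1 : 1;
  ll a = v < 0 ? -v : v;
  std::vector<ll> rev;
  while (a > 0) { rev.push_back(a % B); a /= B; }
  x.m.assign(rev.rbegin(), rev.rend());
  x.e = (ll)x.m.size() - 1;
  return x;
}

static Num neg(const Num &a) { Num r = a; r.sign = -r.sign; return r; }

// compare |a| vs |b|: -1, 0, 1
static int cmp_abs(const Num &a, const Num &b) {
  if (is_zero(a) && is_zero(b)) return 0;
  if (is_zero(a)) return -1;
  if (is_zero(b)) return 1;
  if (a.e != b.e) return a.e < b.e ? -1 : 1;
  size_t n = std::max(a.m.size(), b.m.size());
  for (size_t i = 0; i < n; ++i) {
    ll ai = i < a.m.size() ? a.m[i] : 0;
    ll bi = i < b.m.size() ? b.m[i] : 0;
    if (ai != bi) return ai < bi ? -1 : 1;
  }
  return 0;
}

// |a| + |b|, both nonzero
static Num add_abs(const Num &a, const Num &b) {
  ll hi = std::max(a.e, b.e);
  ll loa = a.e - (ll)a.m.size() + 1;
  ll lob = b.e - (ll)b.m.size() + 1;
  ll lo = std::min(loa, lob);
  if (lo < hi - (ll)(g_prec + 2)) lo = hi - (ll)(g_prec + 2);
  std::vector<ll> v((size_t)(hi - lo + 1), 0);
  for (size_t i = 0; i < a.m.size(); ++i) {
    ll pos = a.e - (ll)i;
    if (pos >= lo) v[(size_t)(hi - pos)] += a.m[i];
  }
  for (size_t i = 0; i < b.m.size(); ++i) {
    ll pos = b.e - (ll)i;
    if (pos >= lo) v[(size_t)(hi - pos)] += b.m[i];
  }
  for (size_t idx = v.size() - 1; idx > 0; --idx) {
    if (v[idx] >= B) { v[idx - 1] += v[idx] / B; v[idx] %= B; }
  }
  Num r;
  r.e = hi;
  while (v[0] >= B) {
    ll c = v[0] / B;
    v[0] %= B;
    v.insert(v.begin(), c);
    r.e += 1;
  }
  r.m = v;
  r.sign = 1;
  trim(r);
  return r;
}

// |a| - |b|, requires |a| >= |b|, both nonzero
static Num sub_abs(const Num &a, const Num &b) {
  ll hi = a.e;
  ll loa = a.e - (ll)a.m.size() + 1;
  ll lob = b.e - (ll)b.m.size() + 1;
  ll lo = std::min(loa, lob);
  if (lo < hi - (ll)(g_prec + 4)) lo = hi - (ll)(g_prec + 4);
  std::vector<ll> v((size_t)(hi - lo + 1), 0);
  for (size_t i = 0; i < a.m.size(); ++i) {
    ll pos = a.e - (ll)i;
    if (pos >= lo) v[(size_t)(hi - pos)] += a.m[i];
  }
  for (size_t i = 0; i < b.m.size(); ++i) {
    ll pos = b.e - (ll)i;
    if (pos >= lo) v[(size_t)(hi - pos)] -= b.m[i];
  }
  for (size_t idx = v.size() - 1; idx > 0; --idx) {
    while (v[idx] < 0) { v[idx] += B; v[idx - 1] -= 1; }
  }
  Num r;
  r.e = hi;
  r.m = v;
  r.sign = 1;
  trim(r);
  return r;
}

static Num add(const Num &a, const Num &b) {
  if (is_zero(a)) return b;
  if (is_zero(b)) return a;
  if (a.sign == b.sign) {
    Num r = add_abs(a, b);
    r.sign = is_zero(r) ? 0 : a.sign;
    return r;
  }
  int c = cmp_abs(a, b);
  if (c == 0) return Num();
  Num r = c > 0 ? sub_abs(a, b) : sub_abs(b, a);
  if (!is_zero(r)) r.sign = c > 0 ? a.sign : b.sign;
  return r;
}

static Num sub(const Num &a, const Num &b) { return add(a, neg(b)); }

static Num mul(const Num &a, const Num &b) {
  if (is_zero(a) || is_zero(b)) return Num();
  size_t la = a.m.size(), lb = b.m.size();
  std::vector<ll> v(la + lb - 1, 0);
  for (size_t i = 0; i < la; ++i) {
    ll ai = a.m[i];
    for (size_t j = 0; j < lb; ++j) v[i + j] += ai * b.m[j];
  }
  for (size_t idx = v.size() - 1; idx > 0; --idx) {
    if (v[idx] >= B) { v[idx - 1] += v[idx] / B; v[idx] %= B; }
  }
  Num r;
  r.e = a.e + b.e;
  while (v[0] >= B) {
    ll c = v[0] / B;
    v[0] %= B;
    v.insert(v.begin(), c);
    r.e += 1;
  }
  r.m = v;
  r.sign = a.sign * b.sign;
  trim(r);
  return r;
}

// |k| must stay below ~1e12 so limb*k fits in int64
static Num mul_small(const Num &a, ll k) {
  if (is_zero(a) || k == 0) return Num();
  int ks = k < 0 ? -1 : 1;
  ll ka = k < 0 ? -k : k;
  std::vector<ll> v(a.m.size(), 0);
  for (size_t i = 0; i < a.m.size(); ++i) v[i] = a.m[i] * ka;
  for (size_t idx = v.size() - 1; idx > 0; --idx) {
    if (v[idx] >= B) { v[idx - 1] += v[idx] / B; v[idx] %= B; }
  }
  Num r;
  r.e = a.e;
  while (v[0] >= B) {
    ll c = v[0] / B;
    v[0] %= B;
    v.insert(v.begin(), c);
    r.e += 1;
  }
  r.m = v;
  r.sign = a.sign * ks;
  trim(r);
  return r;
}

// |k| must stay below ~9e11 so r*B + limb fits in int64
static Num div_small(const Num &a, ll k) {
  if (is_zero(a)) return Num();
  int ks = k < 0 ? -1 : 1;
  ll ka = k < 0 ? -k : k;
  Num r;
  r.e = a.e;
  r.sign = a.sign * ks;
  ll rem = 0;
  int len = g_prec + 3;
  r.m.reserve(len);
  for (int i = 0; i < len; ++i) {
    ll cur = rem * B + (i < (int)a.m.size() ? a.m[i] : 0);
    r.m.push_back(cur / ka);
    rem = cur % ka;
  }
  trim(r);
  return r;
}

static double to_double(const Num &a) {
  if (is_zero(a)) return 0.0;
  double md = 0.0;
  for (size_t i = 0; i < std::min<size_t>(4, a.m.size()); ++i)
    md += (double)a.m[i] * std::pow((double)B, -(double)i);
  double de = (double)a.e * LD;
  if (de > 305) return a.sign > 0 ? R_PosInf : R_NegInf;
  if (de < -305) return 0.0;
  return a.sign * md * std::pow(10.0, de);
}

static Num from_double(double d) {
  if (d == 0.0 || !std::isfinite(d)) return Num();
  int be;
  double mant = std::frexp(std::fabs(d), &be); // in [0.5, 1)
  ll mi = (ll)std::llround(mant * 9007199254740992.0); // * 2^53
  be -= 53;
  Num x = from_ll(mi);
  if (d < 0) x.sign = -x.sign;
  while (be > 0) {
    int ch = std::min(be, 30);
    x = mul_small(x, (ll)1 << ch);
    be -= ch;
  }
  while (be < 0) {
    int ch = std::min(-be, 30);
    x = div_small(x, (ll)1 << ch);
    be += ch;
  }
  return x;
}

static std::string to_string(const Num &a, int sig) {
  if (is_zero(a)) return "0";
  std::string s;
  if (a.sign < 0) s += "-";
  char buf[32];
  std::snprintf(buf, sizeof(buf), "%lld", a.m[0]);
  std::string lead(buf);
  std::string digits = lead;
  for (size_t i = 1; i < a.m.size(); ++i) {
    std::snprintf(buf, sizeof(buf), "%06lld", a.m[i]);
    digits += buf;
  }
  if ((int)digits.size() > sig) digits.resize(sig);
  ll dec_exp = a.e * LD + (ll)lead.size() - 1;
  s += digits.substr(0, 1);
  if (digits.size() > 1) { s += "."; s += digits.substr(1); }
  s += "e";
  std::snprintf(buf, sizeof(buf), "%lld", dec_exp);
  s += buf;
  return s;
}

// ---- reciprocal, division, sqrt ------------------------------------------

static Num recip(const Num &b) {
  if (is_zero(b)) Rcpp::stop("division by zero in high-precision arithmetic");
  double md = 0.0;
  for (size_t i = 0; i < std::min<size_t>(3, b.m.size()); ++i)
    md += (double)b.m[i] * std::pow((double)B, -(double)i); // in [1, B)
  Num r = from_double(1.0 / md);
  r.e -= b.e;
  if (b.sign < 0) r.sign = -r.sign;
  Num one = from_ll(1);
  int iters = 3;
  for (double digs = 15.0; digs < 6.0 * (g_prec + 2); digs *= 2.0) ++iters;
  for (int it = 0; it < iters; ++it) {
    Num err = sub(one, mul(b, r));
    r = add(r, mul(r, err));
  }
  return r;
}

static Num div(const Num &a, const Num &b) { return mul(a, recip(b)); }

static Num sqrt_num(const Num &a) {
  if (is_zero(a)) return Num();
  if (a.sign < 0) Rcpp::stop("sqrt of negative value in high-precision arithmetic");
  double md = 0.0;
  for (size_t i = 0; i < std::min<size_t>(3, a.m.size()); ++i)
    md += (double)a.m[i] * std::pow((double)B, -(double)i);
  ll ee = a.e;
  if (((ee % 2) + 2) % 2 != 0) { md *= (double)B; ee -= 1; }
  Num r = from_double(1.0 / std::sqrt(md));
  r.e -= ee / 2;
  Num three = from_ll(3);
  int iters = 3;
  for (double digs = 15.0; digs < 6.0 * (g_prec + 2); digs *= 2.0) ++iters;
  for (int it = 0; it < iters; ++it) {
    Num t = mul(a, mul(r, r));
    t = sub(three, t);
    r = div_small(mul(r, t), 2);
  }
  return mul(a, r);
}

// ---- pi, exp, erf ---------------------------------------------------------

static Num atan_inv(ll x) {
  Num t = div_small(from_ll(1), x);
  Num s = t;
  ll x2 = x * x;
  for (int k = 1; k < 100000; ++k) {
    t = div_small(t, x2);
    Num term = div_small(t, 2 * k + 1);
    if (is_zero(term) || (!is_zero(s) && term.e < s.e - (ll)(g_prec + 2))) break;
    s = (k % 2 == 1) ? sub(s, term) : add(s, term);
  }
  return s;
}

static Num pi_num() {
  static std::map<int, Num> cache;
  std::map<int, Num>::iterator it = cache.find(g_prec);
  if (it != cache.end()) return it->second;
  // Machin: pi = 16 atan(1/5) - 4 atan(1/239)
  Num p = sub(mul_small(atan_inv(5), 16), mul_small(atan_inv(239), 4));
  cache[g_prec] = p;
  return p;
}

static Num exp_num(const Num &a) {
  Num one = from_ll(1);
  if (is_zero(a)) return one;
  double ad = std::fabs(to_double(a));
  int k = 0;
  if (ad > 0.5) k = (int)std::ceil(std::log2(ad / 0.5)) + 1;
  PrecGuard pg(g_prec + 3 + k / 3);
  Num y = a;
  for (int i = 0; i < k; ++i) y = div_small(y, 2);
  Num s = one, t = one;
  for (int n = 1; n < 100000; ++n) {
    t = div_small(mul(t, y), n);
    if (is_zero(t) || (!is_zero(s) && t.e < s.e - (ll)(g_prec + 2))) break;
    s = add(s, t);
  }
  for (int i = 0; i < k; ++i) s = mul(s, s);
  return s;
}

// erf(x) for x >= 0.  Relative accuracy ~ the ambient precision; once
// erfc(x) < 10^-(digits+12) the result is exactly 1 at that precision.
static Num erf_num(const Num &x) {
  if (is_zero(x)) return Num();
  int digits = g_prec * LD;
  double xd = to_double(x);
  if (xd * xd >= (digits + 12) * 2.302585092994046) return from_ll(1);
  int guard = (int)(xd * xd * 0.4342944819032518) + 12;
  PrecGuard pg(g_prec + guard / LD + 2);
  Num u = mul(x, x);
  Num t = x, s = x;
  double kmin = xd * xd;
  for (int k = 1; k < 200000; ++k) {
    t = div_small(mul(t, u), k);
    t.sign = -t.sign;
    Num term = div_small(t, 2 * k + 1);
    if ((double)k > kmin &&
        (is_zero(term) || (!is_zero(s) && term.e < s.e - (ll)g_prec - 2)))
      break;
    s = add(s, term);
  }
  Num c = div_small(recip(sqrt_num(pi_num())), 1); // 1/sqrt(pi)
  s = mul_small(mul(s, c), 2);
  trim(s);
  return s;
}

// ---- moments of the diffusion weight function -----------------------------
//
// W(R,x) = (1/sqrt(pi)) [exp(-(R-x)^2) - exp(-(R+x)^2)] on (0, inf).
// M_0 = erf(R), M_1 = R,
// M_2 = (R^2 + 1/2) erf(R) + R exp(-R^2)/sqrt(pi),
// M_3 = R (2 R^2 + 3) / 2,
// M_{2k}   = (R^2 + 2k - 3/2) M_{2k-2} + (k-1)(3/2-k) M_{2k-4},   k >= 2
// M_{2l+1} = (R^2 + 2l - 1/2) M_{2l-1} - (l-1/2)(l-1) M_{2l-3},   l >= 2
// (confluent-hypergeometric recurrences split by parity).

static std::vector<Num> moments_vec(const Num &Rb, int n_max) {
  std::vector<Num> M(n_max + 1);
  Num R2 = mul(Rb, Rb);
  Num erfR = erf_num(Rb);
  Num expm = exp_num(neg(R2));
  Num spi = sqrt_num(pi_num());
  Num s = div(mul(Rb, expm), spi);
  Num half = div_small(from_ll(1), 2);
  M[0] = erfR;
  if (n_max >= 1) M[1] = Rb;
  if (n_max >= 2) M[2] = add(mul(add(R2, half), erfR), s);
  if (n_max >= 3)
    M[3] = div_small(mul(Rb, add(mul_small(R2, 2), from_ll(3))), 2);
  for (int n = 4; n <= n_max; ++n) {
    if (n % 2 == 0) {
      ll k = n / 2;
      Num c1 = add(R2, div_small(from_ll(4 * k - 3), 2));
      Num c2 = div_small(from_ll(-(k - 1) * (2 * k - 3)), 2); // (k-1)(3/2-k)
      M[n] = add(mul(c1, M[n - 2]), mul(c2, M[n - 4]));
    } else {
      ll l = (n - 1) / 2;
      Num c1 = add(R2, div_small(from_ll(4 * l - 1), 2));
      Num c2 = div_small(from_ll(-(2 * l - 1) * (l - 1)), 2); // -(l-1/2)(l-1)
      M[n] = add(mul(c1, M[n - 2]), mul(c2, M[n - 4]));
    }
  }
  return M;
}

// dot product of polynomial-square coefficients with the moment vector;
// tracks the worst cancellation (limb exponent of the largest term vs the sum)
static Num dot_moments(const std::vector<Num> &coef, const std::vector<Num> &M,
                       int offset, ll *max_term_e) {
  Num s;
  ll mte = -((ll)1 << 60);
  for (size_t n = 0; n < coef.size(); ++n) {
    if (is_zero(coef[n])) continue;
    Num t = mul(coef[n], M[n + offset]);
    if (!is_zero(t) && t.e > mte) mte = t.e;
    s = add(s, t);
  }
  *max_term_e = mte;
  return s;
}

static std::vector<Num> conv(const std::vector<Num> &p, const std::vector<Num> &q) {
  std::vector<Num> r(p.size() + q.size() - 1);
  for (size_t i = 0; i < p.size(); ++i)
    for (size_t j = 0; j < q.size(); ++j)
      r[i + j] = add(r[i + j], mul(p[i], q[j]));
  return r;
}

struct CoefOut {
  std::vector<double> a, b;
  int status; // 0 ok, 1 precision exhausted
};

// Monic three-term recurrence p_{j+1} = (x - a_j) p_j - b_j p_{j-1} for the
// polynomials orthogonal under <f> = int f(x) W(R,x) dx, via moment dot
// products (list convolution of coefficient vectors).
static CoefOut recurrence_coefficients(const Num &Rb, int N) {
  CoefOut out;
  out.status = 0;
  std::vector<Num> M = moments_vec(Rb, 2 * N);
  std::vector<Num> pprev;            // p_{-1} = 0
  std::vector<Num> pcur(1, from_ll(1)); // p_0 = 1
  Num den_prev;
  std::vector<Num> aN, bN;
  for (int j = 0; j < N; ++j) {
    std::vector<Num> sq = conv(pcur, pcur);
    ll mte_d = 0, mte_n = 0;
    Num den = dot_moments(sq, M, 0, &mte_d);
    Num num = dot_moments(sq, M, 1, &mte_n);
    if (den.sign <= 0) { out.status = 1; return out; }
    // cancellation headroom: need ~30 clean digits after the losses
    ll lost_limbs = mte_d - den.e;
    if (lost_limbs * LD > (ll)(g_prec * LD - 30)) { out.status = 1; return out; }
    Num aj = div(num, den);
    aN.push_back(aj);
    if (j > 0) {
      Num bj = div(den, den_prev);
      if (bj.sign <= 0) { out.status = 1; return out; }
      bN.push_back(bj);
    }
    den_prev = den;
    if (j < N - 1) {
      // p_{j+1} = x p_j - a_j p_j - b_j p_{j-1}
      std::vector<Num> pnext(pcur.size() + 1);
      for (size_t i = 0; i < pcur.size(); ++i)
        pnext[i + 1] = add(pnext[i + 1], pcur[i]); // x * p_j
      for (size_t i = 0; i < pcur.size(); ++i)
        pnext[i] = sub(pnext[i], mul(aj, pcur[i]));
      if (j > 0) {
        const Num &bj = bN.back();
        for (size_t i = 0; i < pprev.size(); ++i)
          pnext[i] = sub(pnext[i], mul(bj, pprev[i]));
      }
      pprev = pcur;
      pcur = pnext;
    }
  }
  for (size_t i = 0; i < aN.size(); ++i) out.a.push_back(to_double(aN[i]));
  for (size_t i = 0; i < bN.size(); ++i) out.b.push_back(to_double(bN[i]));
  return out;
}

} // namespace bf

// ---------------------------------------------------------------------------
// Exported interface
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_gdq_coeffs(double R, int N, int prec_digits) {
  if (!(R > 0)) stop("R must be > 0");
  bf::PrecGuard pg(prec_digits / bf::LD + 5);
  bf::Num Rb = bf::from_double(R);
  bf::CoefOut out = bf::recurrence_coefficients(Rb, N);
  return List::create(_["a"] = NumericVector(out.a.begin(), out.a.end()),
                      _["b"] = NumericVector(out.b.begin(), out.b.end()),
                      _["status"] = out.status);
}

// [[Rcpp::export]]
List cpp_moments(double R, int n_max, int prec_digits) {
  if (!(R > 0)) stop("R must be > 0");
  bf::PrecGuard pg(prec_digits / bf::LD + 5);
  bf::Num Rb = bf::from_double(R);
  std::vector<bf::Num> M = bf::moments_vec(Rb, n_max);
  NumericVector vals(n_max + 1);
  CharacterVector strs(n_max + 1);
  int sig = std::min(prec_digits, 50);
  for (int n = 0; n <= n_max; ++n) {
    vals[n] = bf::to_double(M[n]);
    strs[n] = bf::to_string(M[n], sig);
  }
  return List::create(_["values"] = vals, _["strings"] = strs);
}

// High-precision erf, for cross-checks of the moment seeds.
// [[Rcpp::export]]
List cpp_erf_hp(double x, int prec_digits) {
  bf::PrecGuard pg(prec_digits / bf::LD + 5);
  bf::Num r = bf::erf_num(bf::from_double(std::fabs(x)));
  if (x < 0) r.sign = -r.sign;
  return List::create(_["value"] = bf::to_double(r),
                      _["string"] = bf::to_string(r, std::min(prec_digits, 50)));
}

// Brute-force oracle for the moments, independent of the recurrences.
//
// Splitting the weight into its two Gaussian pieces and reflecting the image
// term gives, with G_n = int_{-inf}^{inf} x^n e^{-(x-R)^2} dx and
// T_n = int_0^{inf} x^n e^{-(x+R)^2} dx:
//   sqrt(pi) M_n = G_n            (n odd)
//   sqrt(pi) M_n = G_n - 2 T_n    (n even)
// G_n is a full-line integral of an analytic function with Gaussian decay,
// where the plain trapezoidal rule is spectrally accurate
// (error ~ exp(-(pi/h)^2)).  T_n lives on a short interval near the origin
// and is integrated by fine-step tanh-sinh (double-exponential) quadrature,
// which is endpoint-robust and spectrally accurate for analytic integrands.
// Returns |relative difference| against the recurrence-based moments.
// [[Rcpp::export]]
NumericVector cpp_moment_check(double R, int n_max, int prec_digits) {
  if (!(R > 0)) stop("R must be > 0");
  bf::PrecGuard pg(prec_digits / bf::LD + 8);
  bf::Num Rb = bf::from_double(R);
  std::vector<bf::Num> Mrec = bf::moments_vec(Rb, n_max);
  bf::Num pi = bf::pi_num();
  bf::Num spi = bf::sqrt_num(pi);
  bf::Num one = bf::from_ll(1);

  // G_n: trapezoid, x = R + j/8, |j/8| <= 32 + sqrt(n_max)
  std::vector<bf::Num> G(n_max + 1);
  {
    const int den = 8;
    int jmax = (int)std::ceil((32.0 + std::sqrt((double)std::max(n_max, 1))) * den);
    for (int j = -jmax; j <= jmax; ++j) {
      bf::Num u = bf::div_small(bf::from_ll(j), den);
      bf::Num x = bf::add(Rb, u);
      bf::Num e1 = bf::exp_num(bf::neg(bf::mul(u, u)));
      bf::Num pw = e1;
      G[0] = bf::add(G[0], pw);
      for (int n = 1; n <= n_max; ++n) {
        pw = bf::mul(pw, x);
        G[n] = bf::add(G[n], pw);
      }
    }
    for (int n = 0; n <= n_max; ++n) G[n] = bf::div_small(G[n], den);
  }

  // T_n: tanh-sinh on [0, U], U sized so the integrand tail is negligible
  std::vector<bf::Num> T(n_max + 1);
  {
    double Ud = std::sqrt((prec_digits + 25) * 2.302585 +
                          (double)n_max * std::log(4.0 + R)) ;
    Ud = std::max(4.0, Ud - R + 2.0);
    bf::Num Uh = bf::div_small(bf::from_double(Ud), 2);
    const int hden = 128;
    const int K = (9 * hden) / 2; // |t| <= 4.5
    for (int k = -K; k <= K; ++k) {
      bf::Num t = bf::div_small(bf::from_ll(k), hden);
      bf::Num et = bf::exp_num(t);
      bf::Num iet = bf::recip(et);
      bf::Num sinh_t = bf::div_small(bf::sub(et, iet), 2);
      bf::Num cosh_t = bf::div_small(bf::add(et, iet), 2);
      bf::Num u = bf::div_small(bf::mul(pi, sinh_t), 2);
      bf::Num au = u;
      if (au.sign < 0) au.sign = 1;
      bf::Num em = bf::exp_num(bf::mul_small(au, -2)); // e^{-2|u|}
      bf::Num den1 = bf::add(one, em);
      bf::Num th = bf::div(bf::sub(one, em), den1);
      if (u.sign < 0) th.sign = -th.sign;
      bf::Num sech2 = bf::div(bf::mul_small(em, 4), bf::mul(den1, den1));
      bf::Num x = bf::mul(Uh, bf::add(one, th));
      if (bf::is_zero(x)) continue;
      bf::Num w = bf::mul(Uh, bf::div_small(bf::mul(pi, bf::mul(cosh_t, sech2)),
                                            2 * (bf::ll)hden));
      bf::Num d2 = bf::add(x, Rb);
      bf::Num e2 = bf::exp_num(bf::neg(bf::mul(d2, d2)));
      bf::Num pw = bf::mul(e2, w);
      T[0] = bf::add(T[0], pw);
      for (int n = 1; n <= n_max; ++n) {
        pw = bf::mul(pw, x);
        T[n] = bf::add(T[n], pw);
      }
    }
  }

  NumericVector rel(n_max + 1);
  for (int n = 0; n <= n_max; ++n) {
    bf::Num Mn = G[n];
    if (n % 2 == 0) Mn = bf::sub(Mn, bf::mul_small(T[n], 2));
    Mn = bf::div(Mn, spi);
    rel[n] = std::fabs(bf::to_double(bf::div(bf::sub(Mrec[n], Mn), Mrec[n])));
  }
  return rel;
}
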