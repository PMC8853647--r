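// Arbitrary-precision signed integers and rationals.
//
// Vertex/ray enumeration is numerically brittle: active-set signatures and
// generator counts must be decided exactly.  All enumeration, rank and LP
// routines in this package therefore run over exact rationals built on the
// little bignum below (base 2^32 limbs, schoolbook arithmetic).  Problem
// sizes are desk scale (tens of dimensions), so asymptotics are irrelevant.

#ifndef EGROWTH_BIGINT_H
#define EGROWTH_BIGINT_H

#include <cmath>
#include <cstdint>
#include <cstdio>
#include <cstdlib>
#include <string>
#include <vector>
#include <stdexcept>

namespace eg {

struct BI {
  // sign in {-1,0,1}; d = limbs, little endian, no leading zeros; empty iff sign==0
  int sign = 0;
  std::vector<uint32_t> d;

  BI() = default;
  explicit BI(long long v) {
    if (v == 0) return;
    sign = v < 0 ? -1 : 1;
    unsigned long long a = v < 0 ? -(unsigned long long)v : (unsigned long long)v;
    while (a) { d.push_back((uint32_t)(a & 0xffffffffu)); a >>= 32; }
  }
  bool is_zero() const { return sign == 0; }
  void trim() {
    while (!d.empty() && d.back() == 0) d.pop_back();
    if (d.empty()) sign = 0;
  }
};

// |a| vs |b|
inline int cmp_abs(const BI& a, const BI& b) {
  if (a.d.size() != b.d.size()) return a.d.size() < b.d.size() ? -1 : 1;
  for (size_t i = a.d.size(); i-- > 0;)
    if (a.d[i] != b.d[i]) return a.d[i] < b.d[i] ? -1 : 1;
  return 0;
}

inline std::vector<uint32_t> add_abs(const std::vector<uint32_t>& a,
                                     const std::vector<uint32_t>& b) {
  std::vector<uint32_t> r;
  r.reserve(std::max(a.size(), b.size()) + 1);
  uint64_t carry = 0;
  for (size_t i = 0; i < std::max(a.size(), b.size()); ++i) {
    uint64_t s = carry;
    if (i < a.size()) s += a[i];
    if (i < b.size()) s += b[i];
    r.push_back((uint32_t)(s & 0xffffffffu));
    carry = s >> 32;
  }
  if (carry) r.push_back((uint32_t)carry);
  return r;
}

// requires |a| >= |b|
inline std::vector<uint32_t> sub_abs(const std::vector<uint32_t>& a,
                                     const std::vector<uint32_t>& b) {
  std::vector<uint32_t> r(a.size());
  int64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int64_t s = (int64_t)a[i] - borrow - (i < b.size() ? (int64_t)b[i] : 0);
    if (s < 0) { s += ((int64_t)1 << 32); borrow = 1; } else borrow = 0;
    r[i] = (uint32_t)s;
  }
  while (!r.empty() && r.back() == 0) r.pop_back();
  return r;
}

inline BI add(const BI& a, const BI& b) {
  if (a.sign == 0) return b;
  if (b.sign == 0) return a;
  BI r;
  if (a.sign == b.sign) {
    r.sign = a.sign;
    r.d = add_abs(a.d, b.d);
  } else {
    int c = cmp_abs(a, b);
    if (c == 0) return BI();
    if (c > 0) { r.sign = a.sign; r.d = sub_abs(a.d, b.d); }
    else       { r.sign = b.sign; r.d = sub_abs(b.d, a.d); }
  }
  return r;
}

inline BI neg(const BI& a) { BI r = a; r.sign = -r.sign; return r; }
inline BI sub(const BI& a, const BI& b) { return add(a, neg(b)); }

inline BI mul(const BI& a, const BI& b) {
  if (a.sign == 0 || b.sign == 0) return BI();
  BI r;
  r.sign = a.sign * b.sign;
  r.d.assign(a.d.size() + b.d.size(), 0);
  for (size_t i = 0; i < a.d.size(); ++i) {
    uint64_t carry = 0;
    for (size_t j = 0; j < b.d.size(); ++j) {
      uint64_t cur = r.d[i + j] + (uint64_t)a.d[i] * b.d[j] + carry;
      r.d[i + j] = (uint32_t)(cur & 0xffffffffu);
      carry = cur >> 32;
    }
    size_t k = i + b.d.size();
    while (carry) {
      uint64_t cur = r.d[k] + carry;
      r.d[k] = (uint32_t)(cur & 0xffffffffu);
      carry = cur >> 32;
      ++k;
    }
  }
  r.trim();
  return r;
}

inline int cmp(const BI& a, const BI& b) {
  if (a.sign != b.sign) return a.sign < b.sign ? -1 : 1;
  if (a.sign == 0) return 0;
  return a.sign > 0 ? cmp_abs(a, b) : -cmp_abs(a, b);
}

inline size_t bitlen(const BI& a) {
  if (a.sign == 0) return 0;
  uint32_t hi = a.d.back();
  size_t n = (a.d.size() - 1) * 32;
  while (hi) { ++n; hi >>= 1; }
  return n;
}

inline BI shl(const BI& a, size_t k) {
  if (a.sign == 0 || k == 0) return a;
  BI r;
  r.sign = a.sign;
  size_t words = k / 32, bits = k % 32;
  r.d.assign(a.d.size() + words + 1, 0);
  for (size_t i = 0; i < a.d.size(); ++i) {
    uint64_t v = (uint64_t)a.d[i] << bits;
    r.d[i + words] |= (uint32_t)(v & 0xffffffffu);
    r.d[i + words + 1] |= (uint32_t)(v >> 32);
  }
  r.trim();
  return r;
}

inline bool bit_at(const BI& a, size_t k) {
  size_t w = k / 32, b = k % 32;
  if (w >= a.d.size()) return false;
  return (a.d[w] >> b) & 1u;
}

#ifdef __SIZEOF_INT128__
// fast-path helpers for values fitting in 128 bits
inline bool fits_u128(const BI& a) { return a.d.size() <= 4; }
inline unsigned __int128 to_u128(const BI& a) {
  unsigned __int128 v = 0;
  for (size_t i = a.d.size(); i-- > 0;) v = (v << 32) | a.d[i];
  return v;
}
inline BI from_u128(unsigned __int128 v, int sign) {
  BI r;
  if (v == 0) return r;
  r.sign = sign;
  while (v) { r.d.push_back((uint32_t)(v & 0xffffffffu)); v >>= 32; }
  return r;
}
#endif

// long division of |a| by |b| (b nonzero): returns (q, r), both nonnegative
inline void divmod_abs(const BI& a, const BI& b, BI& q, BI& r) {
  q = BI(); r = BI();
  if (a.sign == 0) return;
#ifdef __SIZEOF_INT128__
  if (fits_u128(a) && fits_u128(b)) {
    unsigned __int128 ua = to_u128(a), ub = to_u128(b);
    q = from_u128(ua / ub, 1);
    r = from_u128(ua % ub, 1);
    return;
  }
#endif
  if (b.d.size() == 1) {  // single-limb divisor: O(limbs) schoolbook
    uint64_t div = b.d[0], rem = 0;
    q.d.assign(a.d.size(), 0);
    for (size_t i = a.d.size(); i-- > 0;) {
      uint64_t cur = (rem << 32) | a.d[i];
      q.d[i] = (uint32_t)(cur / div);
      rem = cur % div;
    }
    q.sign = 1; q.trim();
    r = BI((long long)rem);
    return;
  }
  size_t n = bitlen(a);
  std::vector<uint32_t> qd((n + 31) / 32, 0);
  for (size_t i = n; i-- > 0;) {
    // r = 2r + bit_i(a)
    r = shl(r, 1);
    if (bit_at(a, i)) {
      if (r.sign == 0) { r.sign = 1; r.d.assign(1, 1); }
      else {
        uint64_t carry = 1;
        for (size_t w = 0; w < r.d.size() && carry; ++w) {
          uint64_t cur = (uint64_t)r.d[w] + carry;
          r.d[w] = (uint32_t)(cur & 0xffffffffu);
          carry = cur >> 32;
        }
        if (carry) r.d.push_back(1);
      }
    }
    if (r.sign != 0 && cmp_abs(r, b) >= 0) {
      r.d = sub_abs(r.d, b.d);
      r.trim();
      qd[i / 32] |= (1u << (i % 32));
    }
  }
  q.d = qd;
  q.sign = 1;
  q.trim();
}

// exact division (caller guarantees divisibility), sign-aware
inline BI divexact(const BI& a, const BI& b) {
  if (a.sign == 0) return BI();
  BI q, r;
  divmod_abs(a, b, q, r);
  q.sign = a.sign * b.sign;
  q.trim();
  return q;
}

inline BI gcd(BI a, BI b) {
  a.sign = a.sign ? 1 : 0;
  b.sign = b.sign ? 1 : 0;
#ifdef __SIZEOF_INT128__
  if (fits_u128(a) && fits_u128(b)) {
    unsigned __int128 x = to_u128(a), y = to_u128(b);
    while (y) { unsigned __int128 t = x % y; x = y; y = t; }
    return from_u128(x, x ? 1 : 0);
  }
#endif
  while (b.sign != 0) {
    BI q, r;
    divmod_abs(a, b, q, r);
    a = b;
    b = r;
  }
  return a;
}

inline BI bi_from_string(const std::string& s) {
  BI r;
  size_t i = 0;
  int sg = 1;
  if (i < s.size() && (s[i] == '-' || s[i] == '+')) { if (s[i] == '-') sg = -1; ++i; }
  if (i >= s.size()) throw std::invalid_argument("empty integer string");
  BI ten(10);
  for (; i < s.size(); ++i) {
    if (s[i] < '0' || s[i] > '9') throw std::invalid_argument("bad integer string: " + s);
    r = add(mul(r, ten), BI(s[i] - '0'));
  }
  if (r.sign != 0) r.sign = sg;
  return r;
}

inline std::string bi_to_string(BI a) {
  if (a.sign == 0) return "0";
  std::string out;
  int sg = a.sign;
  a.sign = 1;
  BI base(1000000000);
  std::vector<uint32_t> chunks;
  while (a.sign != 0) {
    BI q, r;
    divmod_abs(a, base, q, r);
    uint64_t v = 0;
    for (size_t i = r.d.size(); i-- > 0;) v = (v << 32) | r.d[i];
    chunks.push_back((uint32_t)v);
    a = q;
  }
  char buf[16];
  snprintf(buf, sizeof(buf), "%u", chunks.back());
  out += buf;
  for (size_t i = chunks.size() - 1; i-- > 0;) {
    snprintf(buf, sizeof(buf), "%09u", chunks[i]);
    out += buf;
  }
  if (sg < 0) out = "-" + out;
  return out;
}

inline double bi_to_double(const BI& a) {
  double v = 0;
  for (size_t i = a.d.size(); i-- > 0;) v = v * 4294967296.0 + a.d[i];
  return a.sign < 0 ? -v : v;
}

// ---------------------------------------------------------------------------
// Rationals
// ---------------------------------------------------------------------------

struct Rat {
  BI num, den;  // den > 0; canonical: gcd(num,den)=1; zero stored as 0/1
  Rat() : num(), den(BI(1)) {}
  explicit Rat(long long v) : num(v), den(BI(1)) {}
  Rat(BI n, BI d) : num(std::move(n)), den(std::move(d)) { reduce(); }
  void reduce() {
    if (den.sign == 0) throw std::invalid_argument("zero denominator");
    if (den.sign < 0) { den.sign = 1; num.sign = -num.sign; }
    if (num.sign == 0) { den = BI(1); return; }
    BI g = gcd(num, den);
    if (!(g.d.size() == 1 && g.d[0] == 1)) {
      num = divexact(num, g);
      den = divexact(den, g);
    }
  }
  bool is_zero() const { return num.sign == 0; }
  int sgn() const { return num.sign; }
};

inline Rat radd(const Rat& a, const Rat& b) {
  return Rat(add(mul(a.num, b.den), mul(b.num, a.den)), mul(a.den, b.den));
}
inline Rat rsub(const Rat& a, const Rat& b) {
  return Rat(sub(mul(a.num, b.den), mul(b.num, a.den)), mul(a.den, b.den));
}
inline Rat rmul(const Rat& a, const Rat& b) {
  return Rat(mul(a.num, b.num), mul(a.den, b.den));
}
inline Rat rdiv(const Rat& a, const Rat& b) {
  if (b.is_zero()) throw std::invalid_argument("division by zero");
  return Rat(mul(a.num, b.den), mul(a.den, b.num));
}
inline Rat rneg(const Rat& a) { Rat r = a; r.num.sign = -r.num.sign; return r; }
inline int rcmp(const Rat& a, const Rat& b) {
  return cmp(mul(a.num, b.den), mul(b.num, a.den));
}

inline Rat rat_from_string(const std::string& s) {
  size_t pos = s.find('/');
  if (pos == std::string::npos) return Rat(bi_from_string(s), BI(1));
  return Rat(bi_from_string(s.substr(0, pos)), bi_from_string(s.substr(pos + 1)));
}

inline std::string rat_to_string(const Rat& a) {
  if (a.den.d.size() == 1 && a.den.d[0] == 1) return bi_to_string(a.num);
  return bi_to_string(a.num) + "/" + bi_to_string(a.den);
}

inline double rat_to_double(const Rat& a) {
  // exact enough for reporting: long division to double precision
  double n = bi_to_double(a.num), d = bi_to_double(a.den);
  if (std::isfinite(n) && std::isfinite(d) && d != 0) return n / d;
  return NAN;
}

}  // namespace eg

#endif
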