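// Reptation Monte Carlo kernel for the chiral worm-like chain.
//
// The chain lives in a circular vertex buffer so a reptation move (delete
// the terminal segment at one end, append a fresh segment at the other) is
// O(1) in memory traffic. Energy bookkeeping is incremental; stored frames
// carry the incrementally tracked energies so drift can be audited against
// a from-scratch recomputation on the R side.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 operator-(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 operator+(const Vec3 &a, const Vec3 &b) {
  return {a.x + b.x, a.y + b.y, a.z + b.z};
}
inline Vec3 operator*(double s, const Vec3 &a) {
  return {s * a.x, s * a.y, s * a.z};
}
inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

// chiral pair kernel for ordered pair (i, j): (t_i x t_j) . rhat_ij
inline double pair_term(const Vec3 &ti, const Vec3 &tj, const Vec3 &ci,
                        const Vec3 &cj) {
  Vec3 r = cj - ci;
  double n = norm(r);
  if (n <= 0.0) return 0.0;
  return dot(cross(ti, tj), r) / n;
}

inline Vec3 random_unit() {
  double z = 2.0 * unif_rand() - 1.0;
  double phi = 2.0 * M_PI * unif_rand();
  double s = std::sqrt(std::max(0.0, 1.0 - z * z));
  return {s * std::cos(phi), s * std::sin(phi), z};
}

class Chain {
public:
  Chain(const NumericMatrix &init, double b)
      : m_(init.nrow()), start_(0), b_(b), buf_(init.nrow()) {
    for (int i = 0; i < m_; ++i)
      buf_[i] = {init(i, 0), init(i, 1), init(i, 2)};
  }
  int n_vertices() const { return m_; }
  int n_segments() const { return m_ - 1; }
  const Vec3 &vertex(int i) const { return buf_[(start_ + i) % m_]; }
  Vec3 tangent(int s) const {  // segment s in 1..N
    return (1.0 / b_) * (vertex(s) - vertex(s - 1));
  }
  Vec3 center(int s) const { return 0.5 * (vertex(s - 1) + vertex(s)); }
  // drop vertex 0, append w after vertex N
  void grow_head(const Vec3 &w) {
    buf_[start_] = w;
    start_ = (start_ + 1) % m_;
  }
  // drop vertex N, prepend w before vertex 0
  void grow_tail(const Vec3 &w) {
    start_ = (start_ + m_ - 1) % m_;
    buf_[start_] = w;
  }
  // true if any segment center in q_lo..q_hi lies within sqrt(rlim2) of c;
  // linear buffer walk (no per-access modulo) — the sampler's hot loop
  bool center_within(const Vec3 &c, double rlim2, int q_lo, int q_hi) const {
    int idx = (start_ + q_lo - 1) % m_;
    Vec3 prev = buf_[idx];
    for (int q = q_lo; q <= q_hi; ++q) {
      if (++idx == m_) idx = 0;
      const Vec3 &cur = buf_[idx];
      double dx = c.x - 0.5 * (prev.x + cur.x);
      double dy = c.y - 0.5 * (prev.y + cur.y);
      double dz = c.z - 0.5 * (prev.z + cur.z);
      if (dx * dx + dy * dy + dz * dz <= rlim2) return true;
      prev = cur;
    }
    return false;
  }

private:
  int m_, start_;
  double b_;
  std::vector<Vec3> buf_;
};

double full_bending(const Chain &c, double eps_b) {
  double acc = 0.0;
  int n = c.n_segments();
  Vec3 prev = c.tangent(1);
  for (int s = 2; s <= n; ++s) {
    Vec3 t = c.tangent(s);
    acc += dot(prev, t);
    prev = t;
  }
  return -eps_b * acc;
}

double full_chiral(const Chain &c, double u, int d) {
  if (u == 0.0 || d == 0) return 0.0;
  int n = c.n_segments();
  double acc = 0.0;
  for (int i = 1; i <= n; ++i) {
    Vec3 ti = c.tangent(i), ci = c.center(i);
    int jmax = std::min(n, i + d);
    for (int j = i + 1; j <= jmax; ++j)
      acc += pair_term(ti, c.tangent(j), ci, c.center(j));
  }
  return u * acc;
}

} // namespace

// [[Rcpp::export(name = "cpp_run_reptation")]]
List cpp_run_reptation(NumericMatrix init, double eps_b, double u, int d,
                       double R, double b, int n_samples, double equil_moves,
                       double moves_per_sample, double head_prob) {
  Chain chain(init, b);
  const int N = chain.n_segments();
  const int w_excl = (int)std::floor(4.0 * R / b);
  const int w_eff = w_excl < 1 ? 1 : w_excl;
  const double rlim2 = 4.0 * R * R;
  const bool has_chiral = (u != 0.0 && d > 0);
  const bool has_core = (R > 0.0);

  double e_bend = full_bending(chain, eps_b);
  double e_chir = full_chiral(chain, u, d);

  List frames(n_samples);
  NumericVector out_eb(n_samples), out_ec(n_samples);
  double accepted = 0.0, total_moves = 0.0;

  auto do_move = [&]() {
    total_moves += 1.0;
    bool head = unif_rand() < head_prob;
    Vec3 omega = random_unit();
    double d_bend = 0.0, d_chir = 0.0;

    if (head) {
      // new vertex w = v_N + b*omega; segment 1 removed
      Vec3 w = chain.vertex(N) + b * omega;
      Vec3 c_new = 0.5 * (chain.vertex(N) + w);
      d_bend = -eps_b * (dot(chain.tangent(N), omega) -
                         dot(chain.tangent(1), chain.tangent(2)));
      if (has_chiral) {
        double rem = 0.0, add = 0.0;
        Vec3 t1 = chain.tangent(1), c1 = chain.center(1);
        int jmax = std::min(N, 1 + d);
        for (int j = 2; j <= jmax; ++j)
          rem += pair_term(t1, chain.tangent(j), c1, chain.center(j));
        int qmin = std::max(2, N - d + 1);
        for (int q = qmin; q <= N; ++q)
          add += pair_term(chain.tangent(q), omega, chain.center(q), c_new);
        d_chir = u * (add - rem);
      }
      if (has_core && N - w_eff + 1 >= 2 &&
          chain.center_within(c_new, rlim2, 2, N - w_eff + 1)) {
        return; // reject
      }
      double dH = d_bend + d_chir;
      if (dH <= 0.0 || unif_rand() < std::exp(-dH)) {
        chain.grow_head(w);
        e_bend += d_bend;
        e_chir += d_chir;
        accepted += 1.0;
      }
    } else {
      // new vertex w = v_0 - b*omega; segment N removed; new tangent = omega
      Vec3 w = chain.vertex(0) - b * omega;
      Vec3 c_new = 0.5 * (w + chain.vertex(0));
      d_bend = -eps_b * (dot(omega, chain.tangent(1)) -
                         dot(chain.tangent(N - 1), chain.tangent(N)));
      if (has_chiral) {
        double rem = 0.0, add = 0.0;
        Vec3 tN = chain.tangent(N), cN = chain.center(N);
        int imin = std::max(1, N - d);
        for (int i = imin; i <= N - 1; ++i)
          rem += pair_term(chain.tangent(i), tN, chain.center(i), cN);
        int qmax = std::min(d, N - 1);
        for (int q = 1; q <= qmax; ++q)
          add += pair_term(omega, chain.tangent(q), c_new, chain.center(q));
        d_chir = u * (add - rem);
      }
      if (has_core && N - 1 >= w_eff &&
          chain.center_within(c_new, rlim2, w_eff, N - 1)) {
        return; // reject
      }
      double dH = d_bend + d_chir;
      if (dH <= 0.0 || unif_rand() < std::exp(-dH)) {
        chain.grow_tail(w);
        e_bend += d_bend;
        e_chir += d_chir;
        accepted += 1.0;
      }
    }
  };

  for (double m = 0; m < equil_moves; m += 1.0) do_move();

  for (int s = 0; s < n_samples; ++s) {
    for (double m = 0; m < moves_per_sample; m += 1.0) do_move();
    NumericMatrix fr(N + 1, 3);
    for (int i = 0; i <= N; ++i) {
      const Vec3 &v = chain.vertex(i);
      fr(i, 0) = v.x;
      fr(i, 1) = v.y;
      fr(i, 2) = v.z;
    }
    frames[s] = fr;
    out_eb[s] = e_bend;
    out_ec[s] = e_chir;
    if (s % 64 == 63) Rcpp::checkUserInterrupt();
  }

  double acc_rate = total_moves > 0 ? accepted / total_moves : NA_REAL;
  return List::create(_["frames"] = frames, _["E_bend"] = out_eb,
                      _["E_chiral"] = out_ec,
                      _["acceptance_rate"] = acc_rate,
                      _["total_moves"] = total_moves);
}
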