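// Dynamic programs for the copy-number triplet (median) problem.
//
// State: L[i, m, du, au, dv, av] = minimum summed cost of sorted event
// sequences from a median prefix (m_1..m_i, with m_i = m) to the prefixes
// u^i and v^i, where du/au (dv/av) are the deletion/amplification costs
// covering position i on the path to u (v). Budgets range over 0..B with
// B the maximum input copy number; the median entries are capped at
// min(B, e).
//
// cnp_cn3_full: fills the complete table, returns the optimum plus a
//   traceback (median profile and per-position coverage tracks).
// cnp_cn3_fast: cost only, using the pruned predecessor enumeration
//   (when u[i-1] > 0 the amplification budget au' is determined by
//   au' = u[i-1] - m' + du'; when u[i-1] == 0 one may fix
//   du' = max(du, m') and au' = au; symmetrically for v).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

static const int INFC = INT_MAX / 4;

// Base-case feasibility / value at position i (0-based into u, v).
// Returns -1 for infeasible, otherwise the base value when i == 0,
// or -2 meaning "use the recursion".
static inline int base_case(int ui, int vi, int m, int du, int au,
                            int dv, int av, bool first) {
  if (ui > 0 && (du >= m || ui != m - du + au)) return -1;
  if (vi > 0 && (dv >= m || vi != m - dv + av)) return -1;
  if (ui == 0 && du < m) return -1;
  if (vi == 0 && dv < m) return -1;
  if (first) return du + au + dv + av;
  return -2;
}

// Lower envelope along one budget axis: out[x] = min_x' in[x'] + max(x-x',0).
static void axis_transform(std::vector<int>& t, int B1, int stride, int base,
                           int count_outer, int outer_stride) {
  for (int o = 0; o < count_outer; ++o) {
    int off = base + o * outer_stride;
    // free decrease: min over x' >= x
    for (int x = B1 - 2; x >= 0; --x) {
      int a = t[off + x * stride], b = t[off + (x + 1) * stride];
      if (b < a) t[off + x * stride] = b;
    }
    // paid increase: +1 per unit
    for (int x = 1; x < B1; ++x) {
      int a = t[off + x * stride];
      int b = t[off + (x - 1) * stride];
      if (b < INFC && b + 1 < a) t[off + x * stride] = b + 1;
    }
  }
}

// [[Rcpp::export]]
List cnp_cn3_full(IntegerVector u, IntegerVector v, int emax_in) {
  int n = u.size();
  if (n != (int)v.size()) stop("profiles differ in length");
  int B = 0;
  for (int i = 0; i < n; ++i) B = std::max(B, std::max(u[i], v[i]));
  int B1 = B + 1;
  int emax = std::min(B, emax_in < 0 ? B : emax_in);
  size_t S4 = (size_t)B1 * B1 * B1 * B1;      // (du, au, dv, av)
  size_t S5 = S4 * B1;                         // (m, du, au, dv, av)
  // index: ((((m)*B1 + du)*B1 + au)*B1 + dv)*B1 + av
  std::vector<int> L((size_t)n * S5, INFC);
  std::vector<int> env(S4);

  for (int i = 0; i < n; ++i) {
    int* cur = L.data() + (size_t)i * S5;
    if (i > 0) {
      // envelope over m' <= emax of the previous level, then the four
      // axis transforms implementing max(x - x', 0) increments
      const int* prev = L.data() + (size_t)(i - 1) * S5;
      std::fill(env.begin(), env.end(), INFC);
      for (int m = 0; m <= emax; ++m) {
        const int* pm = prev + (size_t)m * S4;
        for (size_t j = 0; j < S4; ++j) env[j] = std::min(env[j], pm[j]);
      }
      // axes from innermost (av, stride 1) outward (du, stride B1^3)
      int s3 = B1 * B1 * B1;
      // av axis
      axis_transform(env, B1, 1, 0, (int)(S4 / B1), B1);
      // dv axis: stride B1; outer iterates (du,au) blocks x av offsets
      for (int blk = 0; blk < B1 * B1; ++blk)
        axis_transform(env, B1, B1, blk * B1 * B1, B1, 1);
      // au axis: stride B1^2
      for (int blk = 0; blk < B1; ++blk)
        axis_transform(env, B1, B1 * B1, blk * s3, B1 * B1, 1);
      // du axis: stride B1^3
      axis_transform(env, B1, s3, 0, B1 * B1 * B1, 1);
    }
    for (int m = 0; m <= B; ++m) {
      size_t off_m = (size_t)m * S4;
      for (int du = 0; du <= B; ++du)
        for (int au = 0; au <= B; ++au)
          for (int dv = 0; dv <= B; ++dv)
            for (int av = 0; av <= B; ++av) {
              int bc = base_case(u[i], v[i], m, du, au, dv, av, i == 0);
              size_t id = off_m +
                ((size_t)du * B1 + au) * B1 * B1 + (size_t)dv * B1 + av;
              if (bc == -1) cur[id] = INFC;
              else if (bc >= 0) cur[id] = bc;
              else cur[id] = env[id - off_m];
            }
    }
  }

  // optimum and lexicographically smallest argmin at level n
  const int* last = L.data() + (size_t)(n - 1) * S5;
  int best = INFC;
  int bm = -1, bdu = 0, bau = 0, bdv = 0, bav = 0;
  for (int m = 0; m <= emax; ++m)
    for (int du = 0; du <= B; ++du)
      for (int au = 0; au <= B; ++au)
        for (int dv = 0; dv <= B; ++dv)
          for (int av = 0; av <= B; ++av) {
            size_t id = (((size_t)m * B1 + du) * B1 + au) * B1 * B1 +
              (size_t)dv * B1 + av;
            if (last[id] < best) {
              best = last[id];
              bm = m; bdu = du; bau = au; bdv = dv; bav = av;
            }
          }
  if (best >= INFC) stop("triplet DP found no feasible median");

  IntegerVector med(n), tdu(n), tau(n), tdv(n), tav(n);
  med[n - 1] = bm; tdu[n - 1] = bdu; tau[n - 1] = bau;
  tdv[n - 1] = bdv; tav[n - 1] = bav;
  for (int i = n - 1; i >= 1; --i) {
    const int* prev = L.data() + (size_t)(i - 1) * S5;
    int target = L[(size_t)i * S5 +
      (((size_t)bm * B1 + bdu) * B1 + bau) * B1 * B1 + (size_t)bdv * B1 + bav];
    bool found = false;
    for (int m = 0; m <= emax && !found; ++m)
      for (int du = 0; du <= B && !found; ++du)
        for (int au = 0; au <= B && !found; ++au)
          for (int dv = 0; dv <= B && !found; ++dv)
            for (int av = 0; av <= B && !found; ++av) {
              size_t id = (((size_t)m * B1 + du) * B1 + au) * B1 * B1 +
                (size_t)dv * B1 + av;
              if (prev[id] >= INFC) continue;
              int val = prev[id] +
                std::max(bdu - du, 0) + std::max(bau - au, 0) +
                std::max(bdv - dv, 0) + std::max(bav - av, 0);
              if (val == target) {
                bm = m; bdu = du; bau = au; bdv = dv; bav = av;
                found = true;
              }
            }
    if (!found) stop("traceback failed: no predecessor attains table value");
    med[i - 1] = bm; tdu[i - 1] = bdu; tau[i - 1] = bau;
    tdv[i - 1] = bdv; tav[i - 1] = bav;
  }

  return List::create(_["cost"] = best, _["median"] = med,
                      _["du"] = tdu, _["au"] = tau,
                      _["dv"] = tdv, _["av"] = tav,
                      _["B"] = B);
}

// [[Rcpp::export]]
int cnp_cn3_fast(IntegerVector u, IntegerVector v, int emax_in) {
  int n = u.size();
  if (n != (int)v.size()) stop("profiles differ in length");
  int B = 0;
  for (int i = 0; i < n; ++i) {
    if (u[i] == 0 && v[i] == 0)
      stop("apply the common-zero reduction before the DP");
    B = std::max(B, std::max(u[i], v[i]));
  }
  int B1 = B + 1;
  int emax = std::min(B, emax_in < 0 ? B : emax_in);
  size_t S4 = (size_t)B1 * B1 * B1 * B1;
  size_t S5 = S4 * B1;
  std::vector<int> prev(S5, INFC), cur(S5, INFC);

  for (int i = 0; i < n; ++i) {
    std::fill(cur.begin(), cur.end(), INFC);
    int ui = u[i], vi = v[i];
    int uprev = (i > 0) ? u[i - 1] : -1, vprev = (i > 0) ? v[i - 1] : -1;
    for (int m = 0; m <= B; ++m) {
      for (int du = 0; du <= B; ++du) {
        int au_lo = 0, au_hi = B;
        if (ui > 0) { au_lo = au_hi = ui - m + du; }
        if (au_lo < 0 || au_lo > B) continue;
        for (int au = au_lo; au <= au_hi; ++au) {
          for (int dv = 0; dv <= B; ++dv) {
            int av_lo = 0, av_hi = B;
            if (vi > 0) { av_lo = av_hi = vi - m + dv; }
            if (av_lo < 0 || av_lo > B) continue;
            for (int av = av_lo; av <= av_hi; ++av) {
              int bc = base_case(ui, vi, m, du, au, dv, av, i == 0);
              if (bc == -1) continue;
              size_t id = (((size_t)m * B1 + du) * B1 + au) * B1 * B1 +
                (size_t)dv * B1 + av;
              if (bc >= 0) { cur[id] = bc; continue; }
              int best = INFC;
              if (uprev > 0 && vprev > 0) {
                for (int mp = 0; mp <= emax; ++mp)
                  for (int dup = 0; dup <= B; ++dup) {
                    int aup = uprev - mp + dup;
                    if (aup < 0 || aup > B) continue;
                    for (int dvp = 0; dvp <= B; ++dvp) {
                      int avp = vprev - mp + dvp;
                      if (avp < 0 || avp > B) continue;
                      size_t pid = (((size_t)mp * B1 + dup) * B1 + aup)
                        * B1 * B1 + (size_t)dvp * B1 + avp;
                      if (prev[pid] >= INFC) continue;
                      int val = prev[pid] +
                        std::max(du - dup, 0) + std::max(au - aup, 0) +
                        std::max(dv - dvp, 0) + std::max(av - avp, 0);
                      if (val < best) best = val;
                    }
                  }
              } else if (uprev == 0) {
                // v[i-1] > 0 after the reduction; fix du' = max(du, m'),
                // au' = au, av' = vprev - m' + dv'
                for (int mp = 0; mp <= emax; ++mp) {
                  int dup = std::max(du, mp);
                  if (dup > B) continue;
                  int aup = au;
                  for (int dvp = 0; dvp <= B; ++dvp) {
                    int avp = vprev - mp + dvp;
                    if (avp < 0 || avp > B) continue;
                    size_t pid = (((size_t)mp * B1 + dup) * B1 + aup)
                      * B1 * B1 + (size_t)dvp * B1 + avp;
                    if (prev[pid] >= INFC) continue;
                    int val = prev[pid] +
                      std::max(du - dup, 0) + std::max(au - aup, 0) +
                      std::max(dv - dvp, 0) + std::max(av - avp, 0);
                    if (val < best) best = val;
                  }
                }
              } else { // vprev == 0, uprev > 0
                for (int mp = 0; mp <= emax; ++mp) {
                  int dvp = std::max(dv, mp);
                  if (dvp > B) continue;
                  int avp = av;
                  for (int dup = 0; dup <= B; ++dup) {
                    int aup = uprev - mp + dup;
                    if (aup < 0 || aup > B) continue;
                    size_t pid = (((size_t)mp * B1 + dup) * B1 + aup)
                      * B1 * B1 + (size_t)dvp * B1 + avp;
                    if (prev[pid] >= INFC) continue;
                    int val = prev[pid] +
                      std::max(du - dup, 0) + std::max(au - aup, 0) +
                      std::max(dv - dvp, 0) + std::max(av - avp, 0);
                    if (val < best) best = val;
                  }
                }
              }
              cur[id] = best;
            }
          }
        }
      }
    }
    std::swap(prev, cur);
  }

  int best = INFC;
  for (int m = 0; m <= emax; ++m)
    for (size_t j = 0; j < S4; ++j)
      best = std::min(best, prev[(size_t)m * S4 + j]);
  if (best >= INFC) stop("triplet DP found no feasible median");
  return best;
}
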