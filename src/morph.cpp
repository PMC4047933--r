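#include <Rcpp.h>
using namespace Rcpp;

// 8-neighbourhood of (r, c) in the Guo-Hall ordering:
// p2 = N, p3 = NE, p4 = E, p5 = SE, p6 = S, p7 = SW, p8 = W, p9 = NW
static inline void neighbours(const IntegerMatrix &m, int r, int c, int p[10]) {
  int nr = m.nrow(), nc = m.ncol();
  auto at = [&](int rr, int cc) -> int {
    if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) return 0;
    return m(rr, cc) != 0;
  };
  p[2] = at(r - 1, c);
  p[3] = at(r - 1, c + 1);
  p[4] = at(r, c + 1);
  p[5] = at(r + 1, c + 1);
  p[6] = at(r + 1, c);
  p[7] = at(r + 1, c - 1);
  p[8] = at(r, c - 1);
  p[9] = at(r - 1, c - 1);
}

// Yokoi-style crossing count used by Guo-Hall
static inline int gh_C(const int p[10]) {
  return ((!p[2]) && (p[3] || p[4])) + ((!p[4]) && (p[5] || p[6])) +
         ((!p[6]) && (p[7] || p[8])) + ((!p[8]) && (p[9] || p[2]));
}

// exact number of 8-connected components among the foreground cells of the
// 8-neighbourhood ring; deleting the centre preserves foreground
// connectivity iff this is 1 (1-px background holes are tolerated — the
// skeleton contract is about foreground component counts)
static inline int n8_components(const int p[10]) {
  static const int rc[8][2] = {{-1, 0}, {-1, 1}, {0, 1}, {1, 1},
                               {1, 0},  {1, -1}, {0, -1}, {-1, -1}};
  int idx[8];
  int n = 0;
  for (int k = 0; k < 8; ++k)
    if (p[k + 2]) idx[n++] = k;
  if (n == 0) return 0;
  int parent[8];
  for (int i = 0; i < n; ++i) parent[i] = i;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int dr = rc[idx[i]][0] - rc[idx[j]][0];
      int dc = rc[idx[i]][1] - rc[idx[j]][1];
      if (dr >= -1 && dr <= 1 && dc >= -1 && dc <= 1) {
        int a = i, b = j;
        while (parent[a] != a) a = parent[a];
        while (parent[b] != b) b = parent[b];
        if (a != b) parent[b] = a;
      }
    }
  int c = 0;
  for (int i = 0; i < n; ++i) {
    int a = i;
    while (parent[a] != a) a = parent[a];
    if (a == i) ++c;
  }
  return c;
}

// [[Rcpp::export(name = ".thin_gh_cpp")]]
IntegerMatrix thin_gh_cpp(IntegerMatrix mask) {
  IntegerMatrix m = clone(mask);
  int nr = m.nrow(), nc = m.ncol();
  int p[10];
  std::vector<std::pair<int, int> > del;
  // alternate Guo-Hall passes and the 2x2 cleanup until a joint fixed
  // point: the cleanup may expose pixels the subiterations can then
  // remove, and idempotence requires global stability
  bool outer_changed = true;
  while (outer_changed) {
  outer_changed = false;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      del.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!m(r, c)) continue;
          neighbours(m, r, c, p);
          int C = gh_C(p);
          if (C != 1) continue;
          int n1 = (p[9] || p[2]) + (p[3] || p[4]) + (p[5] || p[6]) + (p[7] || p[8]);
          int n2 = (p[2] || p[3]) + (p[4] || p[5]) + (p[6] || p[7]) + (p[8] || p[9]);
          int N = n1 < n2 ? n1 : n2;
          if (N < 2 || N > 3) continue;
          int cond;
          if (iter == 0)
            cond = (p[2] || p[3] || (!p[5])) && p[4];
          else
            cond = (p[6] || p[7] || (!p[9])) && p[8];
          if (cond) continue;
          del.push_back(std::make_pair(r, c));
        }
      }
      if (!del.empty()) {
        changed = true;
        outer_changed = true;
        for (size_t i = 0; i < del.size(); ++i) m(del[i].first, del[i].second) = 0;
      }
    }
  }
  // sequential cleanup: remove simple, non-end pixels still sitting in a
  // fully-foreground 2x2 block (Guo-Hall can leave these in rare tilings)
  bool again = true;
  while (again) {
    again = false;
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        if (!m(r, c)) continue;
        bool in22 = false;
        for (int dr = -1; dr <= 0 && !in22; ++dr)
          for (int dc = -1; dc <= 0 && !in22; ++dc) {
            int r0 = r + dr, c0 = c + dc;
            if (r0 < 0 || c0 < 0 || r0 + 1 >= nr || c0 + 1 >= nc) continue;
            if (m(r0, c0) && m(r0, c0 + 1) && m(r0 + 1, c0) && m(r0 + 1, c0 + 1))
              in22 = true;
          }
        if (!in22) continue;
        neighbours(m, r, c, p);
        int b = 0;
        for (int k = 2; k <= 9; ++k) b += p[k];
        if (b <= 1) continue;            // never delete endpoints
        if (n8_components(p) != 1) continue;  // keep topology
        m(r, c) = 0;
        again = true;
        outer_changed = true;
      }
    }
  }
  }
  return m;
}

// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  auto findp = [&](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = findp(a);
    b = findp(b);
    if (a != b) parent[b < a ? a : b] = (a < b ? a : b);
  };
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      // previously-scanned 8-neighbours in column-major order:
      // (r-1, c), (r-1, c-1), (r, c-1), (r+1, c-1)
      int best = 0;
      int cand[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      for (int k = 0; k < 4; ++k) {
        int rr = cand[k][0], cc = cand[k][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        best = ++next;
        parent.push_back(best);
      }
      lab(r, c) = best;
    }
  }
  // flatten labels to 1..k
  std::vector<int> remap(next + 1, 0);
  int k = 0;
  for (int i = 1; i <= next; ++i)
    if (findp(i) == i) remap[i] = ++k;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) lab(r, c) = remap[findp(lab(r, c))];
  return lab;
}
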