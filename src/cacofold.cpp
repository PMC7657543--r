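#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double NEG = -1e30;

// ---------------------------------------------------------------------------
// G-test scores for all column pairs from the 4L x 4L cross-product of the
// fractional residue-weight matrix. C(4(i-1)+x, 4(j-1)+y) is the joint count
// n_xy for columns i,j. G = 2 * sum n_xy log(n_xy / e_xy), e_xy from the
// table margins; empty tables score 0.
// [[Rcpp::export]]
NumericMatrix gtest_from_crossprod(NumericMatrix C, int L) {
  NumericMatrix G(L, L);
  for (int i = 0; i < L; ++i) {
    for (int j = i + 1; j < L; ++j) {
      double n[4][4], rowm[4] = {0, 0, 0, 0}, colm[4] = {0, 0, 0, 0}, tot = 0;
      for (int x = 0; x < 4; ++x)
        for (int y = 0; y < 4; ++y) {
          double v = C(4 * i + x, 4 * j + y);
          n[x][y] = v; rowm[x] += v; colm[y] += v; tot += v;
        }
      double g = 0.0;
      if (tot > 0) {
        for (int x = 0; x < 4; ++x)
          for (int y = 0; y < 4; ++y) {
            if (n[x][y] > 0) {
              double e = rowm[x] * colm[y] / tot;
              g += n[x][y] * std::log(n[x][y] / e);
            }
          }
        g *= 2.0;
        if (g < 0 && g > -1e-9) g = 0.0;  // fp noise
      }
      G(i, j) = g; G(j, i) = g;
    }
  }
  return G;
}

// ---------------------------------------------------------------------------
// Shared helpers for the CYK engines.

struct Mat {
  int n;
  std::vector<double> v;
  Mat(int L) : n(L + 2), v((L + 2) * (L + 2), NEG) {}
  double& at(int i, int j) { return v[i * n + j]; }
};
struct IMat {
  int n;
  std::vector<int> v;
  IMat(int L) : n(L + 2), v((L + 2) * (L + 2), -1) {}
  int& at(int i, int j) { return v[i * n + j]; }
};

// ---------------------------------------------------------------------------
// RBG grammar CYK.
//
// S  -> a S | F0 S | eps
// F0 -> a F5 a' | a P a'          (F0 emits a non-stacked basepair)
// F5 -> a F5 a' | a P a'          (F5 emits a basepair stacked on (i-1,j+1))
// P  -> m..m | m..m F0 | F0 m..m | m..m F0 m..m | M1 M
// M  -> M1 M | R
// M1 -> a M1 | F0
// R  -> R a | M1
//
// s1: unpaired emission score per position (NEG for positions in forced
//     pairs); ep/est: (non-stacked / stacked) pair emission scores with
//     constraint masking applied (NEG = pair cannot form); forced: partner
//     index (1-based) or 0. Hairpin loops shorter than min_hairpin are only
//     admitted under a forced closing pair.
// [[Rcpp::export]]
List cyk_rbg_cpp(NumericVector s1, NumericMatrix ep, NumericMatrix est,
                 IntegerVector forced, List par, int min_hairpin,
                 int max_intloop_side) {
  const int L = s1.size();
  NumericVector tS = par["tS"], tF0 = par["tF0"], tF5 = par["tF5"],
                tP = par["tP"], tM = par["tM"], tM1 = par["tM1"],
                tR = par["tR"], lh = par["lh"], lb = par["lb"],
                li = par["li"];
  // prefix sums of s1 (1-based); positions that may not be unpaired (score
  // at the NEG sentinel) are tracked separately to keep the sums exact
  std::vector<double> cs(L + 1, 0.0);
  std::vector<int> nblk(L + 1, 0);
  for (int k = 1; k <= L; ++k) {
    bool blocked = s1[k - 1] < NEG / 2;
    cs[k] = cs[k - 1] + (blocked ? 0.0 : s1[k - 1]);
    nblk[k] = nblk[k - 1] + (blocked ? 1 : 0);
  }
  auto run = [&](int i, int j) {  // sum of unpaired scores over i..j
    if (j < i) return 0.0;
    if (nblk[j] - nblk[i - 1] > 0) return NEG;
    return cs[j] - cs[i - 1];
  };
  auto LH = [&](int len) { return len < lh.size() ? lh[len] : NEG; };
  auto LB = [&](int l) { return l >= 1 && l <= lb.size() ? lb[l - 1] : NEG; };
  auto LI = [&](int l) { return l >= 1 && l <= li.size() ? li[l - 1] : NEG; };

  Mat S(L), F0(L), F5(L), P(L), M(L), M1(L), R(L);
  IMat cS(L), cF0(L), cF5(L), cP(L), cM(L), cM1(L), cR(L);
  IMat aS(L), aP(L), aP2(L), aM(L);

  for (int len = 0; len <= L; ++len) {
    for (int i = 1; i + len - 1 <= L; ++i) {
      int j = i + len - 1;  // empty interval when len == 0 (j = i-1)
      // ---- P: loop content of closing pair (i-1, j+1)
      {
        bool closing_forced =
            (i - 1 >= 1 && j + 1 <= L && forced[i - 2] == j + 1);
        int minh = closing_forced ? 0 : min_hairpin;
        double best = NEG; int ch = -1, a1 = -1, a2 = -1;
        if (len >= minh) {
          double v = tP[0] + LH(len) + run(i, j);
          if (v > best) { best = v; ch = 0; }
        }
        if (len >= 3) {  // bulges need run >= 1 plus a pair (>= 2 positions)
          for (int l = 1; l <= len - 2; ++l) {
            double v = tP[1] + LB(l) + run(i, i + l - 1) + F0.at(i + l, j);
            if (v > best) { best = v; ch = 1; a1 = l; }
          }
          for (int l = 1; l <= len - 2; ++l) {
            double v = tP[2] + LB(l) + run(j - l + 1, j) + F0.at(i, j - l);
            if (v > best) { best = v; ch = 2; a1 = l; }
          }
        }
        if (len >= 4) {
          int cap = max_intloop_side;
          for (int l1 = 1; l1 <= std::min(cap, len - 3); ++l1) {
            for (int l2 = 1; l2 <= std::min(cap, len - 2 - l1); ++l2) {
              double v = tP[3] + LI(l1) + LI(l2) + run(i, i + l1 - 1) +
                         run(j - l2 + 1, j) + F0.at(i + l1, j - l2);
              if (v > best) { best = v; ch = 3; a1 = l1; a2 = l2; }
            }
          }
        }
        if (len >= 4) {  // multiloop: at least two helices
          for (int k = i + 1; k < j; ++k) {
            double v = tP[4] + M1.at(i, k) + M.at(k + 1, j);
            if (v > best) { best = v; ch = 4; a1 = k; }
          }
        }
        P.at(i, j) = best; cP.at(i, j) = ch; aP.at(i, j) = a1; aP2.at(i, j) = a2;
      }
      if (len >= 2) {
        // ---- F5 (stacked pair i:j, outer pair is (i-1, j+1))
        if (i >= 2 && j <= L - 1 && est(i - 1, j - 1) > NEG / 2) {
          double e = est(i - 1, j - 1);
          double v0 = e + tF5[0] + F5.at(i + 1, j - 1);
          double v1 = e + tF5[1] + P.at(i + 1, j - 1);
          if (v0 >= v1) { F5.at(i, j) = v0; cF5.at(i, j) = 0; }
          else { F5.at(i, j) = v1; cF5.at(i, j) = 1; }
        }
        // ---- F0 (non-stacked pair i:j)
        if (ep(i - 1, j - 1) > NEG / 2) {
          double e = ep(i - 1, j - 1);
          double v0 = e + tF0[0] + F5.at(i + 1, j - 1);
          double v1 = e + tF0[1] + P.at(i + 1, j - 1);
          if (v0 >= v1) { F0.at(i, j) = v0; cF0.at(i, j) = 0; }
          else { F0.at(i, j) = v1; cF0.at(i, j) = 1; }
        }
      }
      if (len >= 1) {
        // ---- M1 -> a M1 | F0
        {
          double v0 = s1[i - 1] + tM1[0] + M1.at(i + 1, j);
          double v1 = tM1[1] + F0.at(i, j);
          if (v1 >= v0) { M1.at(i, j) = v1; cM1.at(i, j) = 1; }
          else { M1.at(i, j) = v0; cM1.at(i, j) = 0; }
        }
        // ---- R -> R a | M1
        {
          double v0 = R.at(i, j - 1) + tR[0] + s1[j - 1];
          double v1 = tR[1] + M1.at(i, j);
          if (v1 >= v0) { R.at(i, j) = v1; cR.at(i, j) = 1; }
          else { R.at(i, j) = v0; cR.at(i, j) = 0; }
        }
        // ---- M -> M1 M | R
        {
          double best = tM[1] + R.at(i, j); int ch = 1, a1 = -1;
          for (int k = i; k < j; ++k) {
            double v = tM[0] + M1.at(i, k) + M.at(k + 1, j);
            if (v > best) { best = v; ch = 0; a1 = k; }
          }
          M.at(i, j) = best; cM.at(i, j) = ch; aM.at(i, j) = a1;
        }
      }
      // ---- S -> a S | F0 S | eps
      {
        double best; int ch, a1 = -1;
        if (len == 0) { best = tS[2]; ch = 2; }
        else {
          best = s1[i - 1] + tS[0] + S.at(i + 1, j); ch = 0;
          for (int k = i + 1; k <= j; ++k) {
            double v = tS[1] + F0.at(i, k) + S.at(k + 1, j);
            if (v > best) { best = v; ch = 1; a1 = k; }
          }
        }
        S.at(i, j) = best; cS.at(i, j) = ch; aS.at(i, j) = a1;
      }
    }
  }

  // traceback
  std::vector<int> pi, pj, pstk;
  struct Frame { int st, i, j; };
  std::vector<Frame> stack;
  stack.push_back({0, 1, L});
  while (!stack.empty()) {
    Frame f = stack.back(); stack.pop_back();
    int i = f.i, j = f.j;
    switch (f.st) {
      case 0: {  // S
        int ch = cS.at(i, j);
        if (ch == 0) stack.push_back({0, i + 1, j});
        else if (ch == 1) {
          int k = aS.at(i, j);
          stack.push_back({1, i, k});
          stack.push_back({0, k + 1, j});
        }
        break;
      }
      case 1: case 2: {  // F0 / F5: pair (i,j)
        pi.push_back(i); pj.push_back(j); pstk.push_back(f.st == 2 ? 1 : 0);
        int ch = (f.st == 1) ? cF0.at(i, j) : cF5.at(i, j);
        if (ch == 0) stack.push_back({2, i + 1, j - 1});
        else stack.push_back({3, i + 1, j - 1});
        break;
      }
      case 3: {  // P
        int ch = cP.at(i, j);
        if (ch == 1) stack.push_back({1, i + aP.at(i, j), j});
        else if (ch == 2) stack.push_back({1, i, j - aP.at(i, j)});
        else if (ch == 3)
          stack.push_back({1, i + aP.at(i, j), j - aP2.at(i, j)});
        else if (ch == 4) {
          int k = aP.at(i, j);
          stack.push_back({5, i, k});
          stack.push_back({4, k + 1, j});
        }
        break;
      }
      case 4: {  // M
        int ch = cM.at(i, j);
        if (ch == 0) {
          int k = aM.at(i, j);
          stack.push_back({5, i, k});
          stack.push_back({4, k + 1, j});
        } else stack.push_back({6, i, j});
        break;
      }
      case 5: {  // M1
        if (cM1.at(i, j) == 0) stack.push_back({5, i + 1, j});
        else stack.push_back({1, i, j});
        break;
      }
      case 6: {  // R
        if (cR.at(i, j) == 0) stack.push_back({6, i, j - 1});
        else stack.push_back({5, i, j});
        break;
      }
    }
  }
  IntegerMatrix pairs(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    pairs(k, 0) = pi[k]; pairs(k, 1) = pj[k];
  }
  return List::create(_["pairs"] = pairs, _["logp"] = S.at(1, L));
}

// ---------------------------------------------------------------------------
// G6X grammar CYK.
//
// S -> L S | eps
// L -> a F a' | a
// F -> a F a' | L S | eps      (F emits a pair stacked on (i-1, j+1);
//                               F -> eps admits zero-length hairpin loops)
//
// To keep the grammar unambiguous, F -> L S may not consist of a single
// full-span paired L: a pair spanning the whole of F is by construction
// stacked on the enclosing pair and must use F -> a F a'.
// [[Rcpp::export]]
List cyk_g6x_cpp(NumericVector s1, NumericMatrix ep, NumericMatrix est,
                 List par) {
  const int L = s1.size();
  NumericVector tS = par["tS"], tL = par["tL"], tF = par["tF"];

  Mat S(L), Lm(L), F(L);
  IMat cS(L), aS(L), cL(L), cF(L), aF(L);

  for (int len = 0; len <= L; ++len) {
    for (int i = 1; i + len - 1 <= L; ++i) {
      int j = i + len - 1;
      // ---- L
      if (len == 1) {
        Lm.at(i, j) = tL[1] + s1[i - 1]; cL.at(i, j) = 1;
      } else if (len >= 2) {
        if (ep(i - 1, j - 1) > NEG / 2) {
          Lm.at(i, j) = tL[0] + ep(i - 1, j - 1) + F.at(i + 1, j - 1);
          cL.at(i, j) = 0;
        }
      }
      // ---- F (content of pair (i-1, j+1))
      {
        double best = NEG; int ch = -1, a1 = -1;
        if (len == 0) { best = tF[2]; ch = 2; }
        else {
          if (len >= 2 && i >= 2 && j <= L - 1 && est(i - 1, j - 1) > NEG / 2) {
            double v = tF[0] + est(i - 1, j - 1) + F.at(i + 1, j - 1);
            if (v > best) { best = v; ch = 0; }
          }
          for (int k = i; k <= j; ++k) {
            if (k == j && len >= 2) continue;  // full-span pair must stack
            double v = tF[1] + Lm.at(i, k) + S.at(k + 1, j);
            if (v > best) { best = v; ch = 1; a1 = k; }
          }
        }
        F.at(i, j) = best; cF.at(i, j) = ch; aF.at(i, j) = a1;
      }
      // ---- S
      {
        double best; int ch, a1 = -1;
        if (len == 0) { best = tS[1]; ch = 1; }
        else {
          best = NEG; ch = -1;
          for (int k = i; k <= j; ++k) {
            double v = tS[0] + Lm.at(i, k) + S.at(k + 1, j);
            if (v > best) { best = v; ch = 0; a1 = k; }
          }
        }
        S.at(i, j) = best; cS.at(i, j) = ch; aS.at(i, j) = a1;
      }
    }
  }

  std::vector<int> pi, pj;
  struct Frame { int st, i, j; };
  std::vector<Frame> stack;
  stack.push_back({0, 1, L});
  while (!stack.empty()) {
    Frame f = stack.back(); stack.pop_back();
    int i = f.i, j = f.j;
    if (f.st == 0) {  // S
      if (cS.at(i, j) == 0) {
        int k = aS.at(i, j);
        stack.push_back({1, i, k});
        stack.push_back({0, k + 1, j});
      }
    } else if (f.st == 1) {  // L
      if (cL.at(i, j) == 0) {
        pi.push_back(i); pj.push_back(j);
        stack.push_back({2, i + 1, j - 1});
      }
    } else {  // F
      int ch = cF.at(i, j);
      if (ch == 0) {
        pi.push_back(i); pj.push_back(j);
        stack.push_back({2, i + 1, j - 1});
      } else if (ch == 1) {
        int k = aF.at(i, j);
        stack.push_back({1, i, k});
        stack.push_back({0, k + 1, j});
      }
    }
  }
  IntegerMatrix pairs(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    pairs(k, 0) = pi[k]; pairs(k, 1) = pj[k];
  }
  return List::create(_["pairs"] = pairs, _["logp"] = S.at(1, L));
}
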