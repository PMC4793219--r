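// Local alignment kernels for realignment-based artifact removal.
//
// Three modes are computed for a (query, window) pair:
//   * ungapped : best gap-free local alignment (single diagonal run)
//   * gapped   : affine-gap Smith-Waterman (Gotoh)
//   * spliced  : affine-gap local alignment allowing exactly one
//                reference-only "intron" jump of length >= 1 and
//                <= max_intron, at a flat intron penalty
//
// Coordinates in the returned blocks are 0-based half-open, relative to the
// window (reference) and to the query as passed in.  Blocks are pure
// diagonal runs: the reference span of each block equals its query span;
// substitutions live inside blocks, gaps/introns between blocks.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Piece {
  double score;
  std::vector<std::array<int, 4>> blocks; // ref0, ref1, q0, q1
  bool gapped;
  int matches;
  int cols; // aligned columns: diagonal columns + gap characters
};

inline double sc(char a, char b, double match, double mismatch) {
  return (a == b && a != 'N' && b != 'N') ? match : mismatch;
}

// Gotoh local alignment; fills H (best ending at cell), E (gap consuming
// reference), F (gap consuming query) and pointer matrices for traceback.
struct Gotoh {
  int n, m;
  std::vector<double> H, E, F;
  // pointers: for H: 0 stop, 1 diag, 2 from E, 3 from F
  //           for E: 0 open (from H), 1 extend; for F likewise
  std::vector<signed char> PH, PE, PF;
  double best;
  int bi, bj;

  inline int id(int i, int j) const { return i * (m + 1) + j; }

  Gotoh(const std::string& q, const std::string& r,
        double match, double mismatch, double gopen, double gext)
      : n((int)q.size()), m((int)r.size()),
        H((n + 1) * (m + 1), 0.0), E((n + 1) * (m + 1), -1e18),
        F((n + 1) * (m + 1), -1e18),
        PH((n + 1) * (m + 1), 0), PE((n + 1) * (m + 1), 0),
        PF((n + 1) * (m + 1), 0), best(0.0), bi(0), bj(0) {
    for (int i = 1; i <= n; ++i) {
      for (int j = 1; j <= m; ++j) {
        double eo = H[id(i, j - 1)] + gopen;
        double ee = E[id(i, j - 1)] + gext;
        if (eo >= ee) { E[id(i, j)] = eo; PE[id(i, j)] = 0; }
        else          { E[id(i, j)] = ee; PE[id(i, j)] = 1; }
        double fo = H[id(i - 1, j)] + gopen;
        double fe = F[id(i - 1, j)] + gext;
        if (fo >= fe) { F[id(i, j)] = fo; PF[id(i, j)] = 0; }
        else          { F[id(i, j)] = fe; PF[id(i, j)] = 1; }
        double d = H[id(i - 1, j - 1)] + sc(q[i - 1], r[j - 1], match, mismatch);
        double h = 0.0; signed char p = 0;
        if (d > h) { h = d; p = 1; }
        if (E[id(i, j)] > h) { h = E[id(i, j)]; p = 2; }
        if (F[id(i, j)] > h) { h = F[id(i, j)]; p = 3; }
        H[id(i, j)] = h; PH[id(i, j)] = p;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
  }

  // Trace back from (i, j) assuming an alignment *ends* at that cell
  // (H-state).  Returns the piece; block coordinates are 0-based half-open.
  Piece trace(int i, int j, const std::string& q, const std::string& r) const {
    Piece p; p.score = H[id(i, j)]; p.gapped = false; p.matches = 0; p.cols = 0;
    int state = 0; // 0 = H, 1 = E, 2 = F
    int di = i, dj = j;            // current cell
    int runEndI = i, runEndJ = j;  // end (exclusive) of current diagonal run
    bool inRun = false;
    while (di > 0 && dj > 0) {
      if (state == 0) {
        signed char p0 = PH[id(di, dj)];
        if (p0 == 0) break;
        if (p0 == 1) {
          if (!inRun) { runEndI = di; runEndJ = dj; inRun = true; }
          p.cols += 1;
          if (q[di - 1] == r[dj - 1]) p.matches += 1;
          --di; --dj;
        } else {
          if (inRun) {
            p.blocks.push_back({dj, runEndJ, di, runEndI});
            inRun = false;
          }
          state = (p0 == 2) ? 1 : 2;
        }
      } else if (state == 1) { // E: gap consuming reference
        p.gapped = true; p.cols += 1;
        signed char p1 = PE[id(di, dj)];
        --dj;
        if (p1 == 0) state = 0;
      } else { // F: gap consuming query
        p.gapped = true; p.cols += 1;
        signed char p1 = PF[id(di, dj)];
        --di;
        if (p1 == 0) state = 0;
      }
    }
    if (inRun) p.blocks.push_back({dj, runEndJ, di, runEndI});
    std::reverse(p.blocks.begin(), p.blocks.end());
    return p;
  }
};

List piece_to_list(const Piece& p) {
  IntegerMatrix b(p.blocks.size(), 4);
  for (size_t k = 0; k < p.blocks.size(); ++k)
    for (int c = 0; c < 4; ++c) b(k, c) = p.blocks[k][c];
  colnames(b) = CharacterVector::create("ref0", "ref1", "q0", "q1");
  return List::create(_["score"] = p.score, _["blocks"] = b,
                      _["gapped"] = p.gapped, _["matches"] = p.matches,
                      _["cols"] = p.cols);
}

} // namespace

// [[Rcpp::export(name = ".cpp_align_modes")]]
List cpp_align_modes(std::string query, std::string window,
                     double match, double mismatch,
                     double gap_open, double gap_extend,
                     double intron_gap, double max_intron,
                     double min_intron) {
  const int n = (int)query.size(), m = (int)window.size();

  // --- ungapped -----------------------------------------------------------
  Piece ug; ug.score = 0; ug.gapped = false; ug.matches = 0; ug.cols = 0;
  if (n > 0 && m > 0) {
    std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
    double best = 0; int bi = 0, bj = 0;
    std::vector<double> Hall((n + 1) * (m + 1), 0.0);
    for (int i = 1; i <= n; ++i) {
      for (int j = 1; j <= m; ++j) {
        double v = prev[j - 1] + sc(query[i - 1], window[j - 1], match, mismatch);
        cur[j] = v > 0 ? v : 0;
        Hall[i * (m + 1) + j] = cur[j];
        if (cur[j] > best) { best = cur[j]; bi = i; bj = j; }
      }
      std::swap(prev, cur);
    }
    if (best > 0) {
      int i = bi, j = bj, len = 0;
      while (i > 0 && j > 0 && Hall[i * (m + 1) + j] > 0) {
        if (query[i - 1] == window[j - 1]) ug.matches += 1;
        --i; --j; ++len;
      }
      ug.score = best; ug.cols = len;
      ug.blocks.push_back({j, j + len, i, i + len});
    }
  }

  // --- gapped (Gotoh) -----------------------------------------------------
  Piece gp; gp.score = 0; gp.gapped = false; gp.matches = 0; gp.cols = 0;
  Piece sp; sp.score = 0; sp.gapped = false; sp.matches = 0; sp.cols = 0;
  bool sp_found = false;
  if (n > 0 && m > 0) {
    Gotoh fwd(query, window, match, mismatch, gap_open, gap_extend);
    if (fwd.best > 0) gp = fwd.trace(fwd.bi, fwd.bj, query, window);
    gp.score = fwd.best;

    // --- spliced ----------------------------------------------------------
    // Compose a forward piece ending at (i, j) with a backward piece
    // starting at (i + 1, k); the intron length k - j - 1 must lie in
    // [min_intron, max_intron].
    const int imin = std::max(1, (int)min_intron);
    std::string qr(query.rbegin(), query.rend());
    std::string wr(window.rbegin(), window.rend());
    Gotoh rev(qr, wr, match, mismatch, gap_open, gap_extend);
    // Hb(i, k) = best alignment starting exactly at query i, ref k (1-based)
    //          = rev.H at (n - i + 1, m - k + 1)
    double bestS = 0; int si = 0, sj = 0, sk = 0;
    const bool bounded = (double)m > max_intron + 1.0 + imin;
    std::vector<double> suf(m + 2, 0.0);
    std::vector<int> sufArg(m + 2, 0);
    for (int i = 1; i <= n - 1; ++i) {
      // suffix maxima of Hb(i + 1, k) over k
      suf[m + 1] = -1e18; sufArg[m + 1] = 0;
      for (int k = m; k >= 1; --k) {
        double hb = rev.H[rev.id(n - i, m - k + 1)];
        if (hb >= suf[k + 1]) { suf[k] = hb; sufArg[k] = k; }
        else { suf[k] = suf[k + 1]; sufArg[k] = sufArg[k + 1]; }
      }
      for (int j = 1; j <= m - 1 - imin; ++j) {
        double hf = fwd.H[fwd.id(i, j)];
        if (hf <= 0) continue;
        double hb; int karg;
        if (!bounded) {
          hb = suf[j + 1 + imin]; karg = sufArg[j + 1 + imin];
        } else {
          hb = -1e18; karg = 0;
          int kmax = std::min(m, j + 1 + (int)max_intron);
          for (int k = j + 1 + imin; k <= kmax; ++k) {
            double v = rev.H[rev.id(n - i, m - k + 1)];
            if (v > hb) { hb = v; karg = k; }
          }
        }
        if (hb <= 0) continue;
        double tot = hf + hb + intron_gap;
        if (tot > bestS) { bestS = tot; si = i; sj = j; sk = karg; }
      }
    }
    if (bestS > 0) {
      sp_found = true;
      Piece left = fwd.trace(si, sj, query, window);
      Piece rightRev = rev.trace(n - si, m - sk + 1, qr, wr);
      // map reversed-coordinate blocks back to the original frame
      Piece right; right.score = rightRev.score; right.gapped = rightRev.gapped;
      right.matches = rightRev.matches; right.cols = rightRev.cols;
      for (auto it = rightRev.blocks.rbegin(); it != rightRev.blocks.rend(); ++it)
        right.blocks.push_back({m - (*it)[1], m - (*it)[0],
                                n - (*it)[3], n - (*it)[2]});
      sp.score = bestS;
      sp.gapped = left.gapped || right.gapped;
      sp.matches = left.matches + right.matches;
      sp.cols = left.cols + right.cols;
      sp.blocks = left.blocks;
      sp.blocks.insert(sp.blocks.end(), right.blocks.begin(), right.blocks.end());
    }
  }

  List out = List::create(_["ungapped"] = piece_to_list(ug),
                          _["gapped"] = piece_to_list(gp),
                          _["spliced"] = piece_to_list(sp));
  out.attr("spliced_found") = sp_found;
  return out;
}
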