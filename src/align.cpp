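#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). Coordinates returned 1-based inclusive.
// Gap of length L costs gap_open + (L-1) * gap_ext (both supplied negative).
// Tie-break among equal-scoring maxima: smallest query_start, then ref_start,
// then query_end, then ref_end. Traceback preference: diagonal, vertical
// (query gapped base, 'I'), horizontal ('D').

struct Aln {
  int score, qs, qe, rs, re, nmatch, nmism, ngap;
  std::string edit;
};

static void traceback(const std::string &q, const std::string &r,
                      const std::vector<int> &H, const std::vector<int> &E,
                      const std::vector<int> &F, int m1, int i0, int j0,
                      int match, int mismatch, int gap_open, int gap_ext,
                      Aln &out) {
  int i = i0, j = j0;
  std::string ops;
  int nm = 0, nx = 0, ng = 0;
  int state = 0; // 0 = H, 1 = F (vertical), 2 = E (horizontal)
  while (true) {
    if (state == 0) {
      int h = H[i * m1 + j];
      if (h == 0) break;
      int sub = (q[i - 1] == r[j - 1]) ? match : mismatch;
      if (i > 0 && j > 0 && h == H[(i - 1) * m1 + (j - 1)] + sub) {
        if (q[i - 1] == r[j - 1]) { ops.push_back('M'); ++nm; }
        else { ops.push_back('X'); ++nx; }
        --i; --j;
      } else if (h == F[i * m1 + j]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ops.push_back('I'); ++ng;
      int f = F[i * m1 + j];
      if (i > 1 && f == F[(i - 1) * m1 + j] + gap_ext) { --i; }
      else { --i; state = 0; }
    } else {
      ops.push_back('D'); ++ng;
      int e = E[i * m1 + j];
      if (j > 1 && e == E[i * m1 + (j - 1)] + gap_ext) { --j; }
      else { --j; state = 0; }
    }
  }
  out.qs = i + 1; out.rs = j + 1; out.qe = i0; out.re = j0;
  out.nmatch = nm; out.nmism = nx; out.ngap = ng;
  std::reverse(ops.begin(), ops.end());
  out.edit = ops;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string ref, int match, int mismatch,
                  int gap_open, int gap_ext) {
  const int n = (int)query.size(), m = (int)ref.size();
  const int m1 = m + 1;
  const int NEG = -1000000000;
  std::vector<int> H((n + 1) * m1, 0), E((n + 1) * m1, NEG), F((n + 1) * m1, NEG);
  int best = 0;
  std::vector<std::pair<int,int> > maxima;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int e = std::max(H[i * m1 + (j - 1)] + gap_open, E[i * m1 + (j - 1)] + gap_ext);
      int f = std::max(H[(i - 1) * m1 + j] + gap_open, F[(i - 1) * m1 + j] + gap_ext);
      int sub = (query[i - 1] == ref[j - 1]) ? match : mismatch;
      int h = H[(i - 1) * m1 + (j - 1)] + sub;
      h = std::max(h, std::max(e, f));
      if (h < 0) h = 0;
      E[i * m1 + j] = e; F[i * m1 + j] = f; H[i * m1 + j] = h;
      if (h > best) { best = h; maxima.clear(); maxima.push_back(std::make_pair(i, j)); }
      else if (h == best && best > 0 && maxima.size() < 256)
        maxima.push_back(std::make_pair(i, j));
    }
  }
  if (best == 0) {
    return List::create(_["score"] = 0, _["query_start"] = NA_INTEGER,
                        _["query_end"] = NA_INTEGER, _["ref_start"] = NA_INTEGER,
                        _["ref_end"] = NA_INTEGER, _["n_match"] = 0,
                        _["n_mismatch"] = 0, _["n_gap"] = 0, _["edit"] = "");
  }
  Aln bestAln; bool have = false;
  for (size_t k = 0; k < maxima.size(); ++k) {
    Aln a; a.score = best;
    traceback(query, ref, H, E, F, m1, maxima[k].first, maxima[k].second,
              match, mismatch, gap_open, gap_ext, a);
    if (!have ||
        a.qs < bestAln.qs ||
        (a.qs == bestAln.qs && (a.rs < bestAln.rs ||
         (a.rs == bestAln.rs && (a.qe < bestAln.qe ||
          (a.qe == bestAln.qe && a.re < bestAln.re)))))) {
      bestAln = a; have = true;
    }
  }
  return List::create(_["score"] = bestAln.score,
                      _["query_start"] = bestAln.qs, _["query_end"] = bestAln.qe,
                      _["ref_start"] = bestAln.rs, _["ref_end"] = bestAln.re,
                      _["n_match"] = bestAln.nmatch, _["n_mismatch"] = bestAln.nmism,
                      _["n_gap"] = bestAln.ngap, _["edit"] = bestAln.edit);
}

// Longest common substring of a and b (exact, contiguous). Ties broken by
// earliest start in a, then earliest start in b. 1-based starts; length 0
// when no character is shared.
// [[Rcpp::export(name = ".lcs_substring_cpp")]]
List lcs_substring_cpp(std::string a, std::string b) {
  const int n = (int)a.size(), m = (int)b.size();
  int best = 0, ba = 0, bb = 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      cur[j] = (a[i - 1] == b[j - 1]) ? prev[j - 1] + 1 : 0;
      if (cur[j] > best) { best = cur[j]; ba = i - cur[j] + 1; bb = j - cur[j] + 1; }
    }
    std::swap(prev, cur);
  }
  return List::create(_["length"] = best, _["a_start"] = ba, _["b_start"] = bb);
}

// Gap-free end-overlap scan between a forward read and the reverse-complement
// of its mate. Shift s places rc[1] at forward position s + 1 (s may be
// negative). Score = matches - mismatches; best by score, then larger
// overlap, then smaller |s|, then smaller s.
// [[Rcpp::export(name = ".overlap_scan_cpp")]]
List overlap_scan_cpp(std::string fwd, std::string rc) {
  const int nf = (int)fwd.size(), nr = (int)rc.size();
  int bestScore = -1000000000, bestOv = 0, bestS = 0, bestMm = 0;
  bool have = false;
  for (int s = -(nr - 1); s <= nf - 1; ++s) {
    int lo = std::max(0, s);            // fwd index (0-based) where overlap starts
    int hi = std::min(nf, s + nr);      // one past end
    int ov = hi - lo;
    if (ov <= 0) continue;
    int mm = 0;
    for (int t = lo; t < hi; ++t)
      if (fwd[t] != rc[t - s]) ++mm;
    int sc = (ov - mm) - mm;
    bool better = false;
    if (!have || sc > bestScore) better = true;
    else if (sc == bestScore) {
      if (ov > bestOv) better = true;
      else if (ov == bestOv) {
        if (std::abs(s) < std::abs(bestS)) better = true;
        else if (std::abs(s) == std::abs(bestS) && s < bestS) better = true;
      }
    }
    if (better) { bestScore = sc; bestOv = ov; bestS = s; bestMm = mm; have = true; }
  }
  return List::create(_["score"] = bestScore, _["shift"] = bestS,
                      _["overlap"] = bestOv, _["n_mismatch"] = bestMm);
}
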