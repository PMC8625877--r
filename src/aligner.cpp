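// Seed-and-extend local nucleotide aligner.
//
// Exact word seeding on a 2-bit rolling hash, ungapped X-drop extension
// with per-diagonal skip, then banded affine-gap extension (Gotoh) with
// X-drop termination and full traceback so that match/column counts are
// available for identity computation.  N is never a match and never seeds.
// Coordinates are 0-based half-open throughout.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static const int NEG_INF = -(1 << 29);

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;  // N / anything else: never matches, never seeds
  }
}

struct ExtResult {
  int di;       // query letters consumed by the best extension
  int dj;       // subject letters consumed
  int score;    // best extension score (>= 0; 0 = extend nothing)
  int matches;  // identical aligned pairs on the traceback path
  int cols;     // alignment columns (substitution + gap columns)
};

// Banded affine-gap extension from an anchor cell known to be a match.
// Alignment path starts adjacent to the anchor (offset (0,0)) and may end at
// any substitution cell; negative prefixes are allowed so the extension can
// climb through diverged patches.  dir = +1 extends toward larger
// coordinates, dir = -1 toward smaller ones.
static ExtResult extend_banded(const std::vector<int8_t>& q,
                               const std::vector<int8_t>& s,
                               int q0, int s0, int dir,
                               int match, int mismatch,
                               int gap_open, int gap_extend,
                               int band, int xdrop) {
  ExtResult best{0, 0, 0, 0, 0};
  const int qlen = (int)q.size(), slen = (int)s.size();
  const int max_i = dir > 0 ? (qlen - 1 - q0) : q0;
  const int max_j = dir > 0 ? (slen - 1 - s0) : s0;
  if (max_i <= 0 || max_j <= 0) return best;
  const int W = 2 * band + 1;
  const int gape = gap_extend, gapo = gap_open + gap_extend;  // first gap col

  std::vector<int> Mp(W, NEG_INF), Ixp(W, NEG_INF), Iyp(W, NEG_INF);
  std::vector<int> Mc(W), Ixc(W), Iyc(W);
  // virtual row i = 0: origin at k = band (j = 0); leading-gap chain in Ix.
  Mp[band] = 0;
  for (int k = band + 1; k < W; ++k) {
    int j = k - band;
    if (j > max_j) break;
    Ixp[k] = -(gap_open + j * gap_extend);
  }

  std::vector<uint8_t> tb;  // per-cell packed traceback, rows appended
  int best_i = 0, best_k = band, n_rows = 0;

  for (int i = 1; i <= max_i; ++i) {
    int klo = band - i + 1; if (klo < 0) klo = 0;
    int khi = band + max_j - i; if (khi > W - 1) khi = W - 1;
    if (klo > khi) break;
    std::fill(Mc.begin(), Mc.end(), NEG_INF);
    std::fill(Ixc.begin(), Ixc.end(), NEG_INF);
    std::fill(Iyc.begin(), Iyc.end(), NEG_INF);
    tb.resize((size_t)(n_rows + 1) * W, 0);
    uint8_t* tbr = &tb[(size_t)n_rows * W];
    int row_max = NEG_INF;
    const int qi = q[q0 + dir * i];
    for (int k = klo; k <= khi; ++k) {
      const int j = i + k - band;
      // M: diagonal predecessor (i-1, same k)
      int m = Mp[k], pm = 1;
      if (Ixp[k] > m) { m = Ixp[k]; pm = 2; }
      if (Iyp[k] > m) { m = Iyp[k]; pm = 3; }
      if (m > NEG_INF) {
        const int sj = s[s0 + dir * j];
        const bool is_match = (qi >= 0 && qi == sj);
        Mc[k] = m + (is_match ? match : mismatch);
      } else {
        pm = 0;
      }
      // Iy: gap in subject, consumes query letter; predecessor (i-1, k+1)
      int py = 0;
      if (k + 1 < W) {
        const int fromM = (Mp[k + 1] > NEG_INF) ? Mp[k + 1] - gapo : NEG_INF;
        const int fromY = (Iyp[k + 1] > NEG_INF) ? Iyp[k + 1] - gape : NEG_INF;
        if (fromM >= fromY) { Iyc[k] = fromM; py = fromM > NEG_INF ? 1 : 0; }
        else                { Iyc[k] = fromY; py = 2; }
      }
      // Ix: gap in query, consumes subject letter; predecessor (i, k-1)
      int px = 0;
      if (k - 1 >= 0) {
        const int fromM = (Mc[k - 1] > NEG_INF) ? Mc[k - 1] - gapo : NEG_INF;
        const int fromX = (Ixc[k - 1] > NEG_INF) ? Ixc[k - 1] - gape : NEG_INF;
        if (fromM >= fromX) { Ixc[k] = fromM; px = fromM > NEG_INF ? 1 : 0; }
        else                { Ixc[k] = fromX; px = 2; }
      }
      tbr[k] = (uint8_t)(pm | (px << 2) | (py << 4));
      if (Mc[k] > best.score) {  // strict: ties keep the shorter extension
        best.score = Mc[k];
        best_i = i; best_k = k;
      }
      if (Mc[k] > row_max) row_max = Mc[k];
      if (Ixc[k] > row_max) row_max = Ixc[k];
      if (Iyc[k] > row_max) row_max = Iyc[k];
    }
    ++n_rows;
    if (row_max < best.score - xdrop) break;
    Mp.swap(Mc); Ixp.swap(Ixc); Iyp.swap(Iyc);
  }

  if (best_i == 0) return best;  // nothing beat the empty extension
  best.di = best_i;
  best.dj = best_i + best_k - band;

  // traceback from (best_i, best_k), state M
  int i = best_i, k = best_k, state = 1;
  while (i > 0) {
    const uint8_t code = tb[(size_t)(i - 1) * W + k];
    if (state == 1) {  // M consumed (q_i, s_j)
      const int j = i + k - band;
      ++best.cols;
      const int qi2 = q[q0 + dir * i], sj2 = s[s0 + dir * j];
      if (qi2 >= 0 && qi2 == sj2) ++best.matches;
      state = code & 3;  // 0 handled below: i becomes 0 via origin
      --i;
      if (state == 0) state = 1;  // origin reached after this step
    } else if (state == 2) {  // Ix: gap column consuming subject
      ++best.cols;
      const int p = (code >> 2) & 3;
      --k;
      if (p == 2) { state = 2; }
      else if (p == 1) { state = 1; }
      else {  // came from the virtual row-0 boundary chain
        // remaining leading-gap columns: j letters of subject before i rows
        state = 4; break;
      }
    } else {  // state == 3, Iy: gap column consuming query
      ++best.cols;
      const int p = (code >> 4) & 3;
      ++k; --i;
      state = (p == 2) ? 3 : 1;
    }
  }
  if (state == 4 || (i == 0 && k > band)) {
    best.cols += k - band;  // leading gap columns along row 0
  }
  return best;
}

struct Candidate {
  int qpos, spos;      // seed word start
  int qs, qe, ss, se;  // ungapped HSP extent, half-open
  int score;           // ungapped score
};

struct GappedHit {
  int qs, qe, ss, se, score, matches, cols, diag;
};

// Scan one subject sequence with one query orientation.
// [[Rcpp::export(name = ".scan_hits_cpp")]]
DataFrame scan_hits_cpp(std::string query, std::string subject,
                        int match, int mismatch,
                        int gap_open, int gap_extend,
                        int word_size, int xdrop_ungapped,
                        int gap_trigger, int band, int xdrop_gapped) {
  const int qlen = (int)query.size(), slen = (int)subject.size();
  if (qlen < word_size)
    stop("query shorter than word_size (%d < %d)", qlen, word_size);

  std::vector<int8_t> q(qlen), s(slen);
  for (int i = 0; i < qlen; ++i) q[i] = (int8_t)base_code(query[i]);
  for (int i = 0; i < slen; ++i) s[i] = (int8_t)base_code(subject[i]);

  // query word index: head[word] -> last qpos, nxt chains
  const uint32_t nwords = 1u << (2 * word_size);
  const uint32_t wmask = nwords - 1;
  std::vector<int> head(nwords, -1), nxt(qlen, -1);
  {
    uint32_t w = 0; int run = 0;
    for (int i = 0; i < qlen; ++i) {
      if (q[i] < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint32_t)q[i]) & wmask;
      if (++run >= word_size) {
        const int pos = i - word_size + 1;
        nxt[pos] = head[w];
        head[w] = pos;
      }
    }
  }

  std::vector<int> last_ext((size_t)qlen + slen + 1, -1);
  std::vector<Candidate> cands;

  uint32_t w = 0; int run = 0;
  for (int sp = 0; sp < slen; ++sp) {
    if (s[sp] < 0) { run = 0; w = 0; continue; }
    w = ((w << 2) | (uint32_t)s[sp]) & wmask;
    if (++run < word_size) continue;
    const int spos = sp - word_size + 1;
    for (int qpos = head[w]; qpos >= 0; qpos = nxt[qpos]) {
      const size_t d = (size_t)(spos - qpos + qlen);
      if (last_ext[d] >= spos) continue;
      // ungapped X-drop extension
      int sc = word_size * match, best_sc = sc;
      int qi = qpos + word_size, sj = spos + word_size;
      int best_r = 0, step = 0;
      while (qi < qlen && sj < slen) {
        ++step;
        sc += (q[qi] >= 0 && q[qi] == s[sj]) ? match : mismatch;
        if (sc > best_sc) { best_sc = sc; best_r = step; }
        if (sc <= best_sc - xdrop_ungapped) break;
        ++qi; ++sj;
      }
      const int reached = spos + word_size + step;
      int sc2 = best_sc, best_l = 0;
      qi = qpos - 1; sj = spos - 1; step = 0;
      while (qi >= 0 && sj >= 0) {
        ++step;
        sc2 += (q[qi] >= 0 && q[qi] == s[sj]) ? match : mismatch;
        if (sc2 > best_sc) { best_sc = sc2; best_l = step; }
        if (sc2 <= best_sc - xdrop_ungapped) break;
        --qi; --sj;
      }
      last_ext[d] = reached;
      if (best_sc >= gap_trigger) {
        Candidate c;
        c.qpos = qpos; c.spos = spos;
        c.qs = qpos - best_l; c.qe = qpos + word_size + best_r;
        c.ss = spos - best_l; c.se = spos + word_size + best_r;
        c.score = best_sc;
        cands.push_back(c);
      }
    }
  }

  // strongest candidates first so containment skipping is well-defined
  std::sort(cands.begin(), cands.end(), [](const Candidate& a, const Candidate& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.ss != b.ss) return a.ss < b.ss;
    return a.qs < b.qs;
  });

  std::vector<GappedHit> hits;
  const int half_band = band / 2;
  for (const Candidate& c : cands) {
    bool covered = false;
    const int cd = c.spos - c.qpos;
    for (const GappedHit& h : hits) {
      if (c.qs >= h.qs && c.qe <= h.qe && c.ss >= h.ss && c.se <= h.se &&
          cd - h.diag <= half_band && h.diag - cd <= half_band) {
        covered = true; break;
      }
    }
    if (covered) continue;
    const int aq = c.qpos + word_size / 2;
    const int as = c.spos + word_size / 2;
    ExtResult right = extend_banded(q, s, aq, as, +1, match, mismatch,
                                    gap_open, gap_extend, band, xdrop_gapped);
    ExtResult left = extend_banded(q, s, aq, as, -1, match, mismatch,
                                   gap_open, gap_extend, band, xdrop_gapped);
    GappedHit h;
    h.qs = aq - left.di; h.qe = aq + 1 + right.di;
    h.ss = as - left.dj; h.se = as + 1 + right.dj;
    h.score = match + left.score + right.score;
    h.matches = 1 + left.matches + right.matches;
    h.cols = 1 + left.cols + right.cols;
    h.diag = as - aq;
    hits.push_back(h);
  }

  const int n = (int)hits.size();
  IntegerVector qs(n), qe(n), ss(n), se(n), score(n), matches(n), cols(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = hits[i].qs; qe[i] = hits[i].qe;
    ss[i] = hits[i].ss; se[i] = hits[i].se;
    score[i] = hits[i].score; matches[i] = hits[i].matches;
    cols[i] = hits[i].cols;
  }
  return DataFrame::create(
      Named("query_start") = qs, Named("query_end") = qe,
      Named("subject_start") = ss, Named("subject_end") = se,
      Named("score") = score, Named("matches") = matches,
      Named("aligned_cols") = cols);
}
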