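// Seed-and-extend local alignment engine.
//
// One engine serves both the nucleotide liftover aligner and the six-frame
// translated protein search: exact k-mer seeding on a sorted index, ungapped
// X-drop extension along the seed diagonal, then a full affine-gap
// Smith-Waterman with traceback restricted to a target window around the
// extended seed.  Windows are merged per target before DP so each reported
// hit is the single best local alignment in its window; distinct windows give
// distinct hits (that is what makes multi-placement ambiguity observable).
//
// Gap cost convention matches BLAST/Biostrings: a gap of length L costs
// gap_open + L * gap_ext.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct AlnResult {
  int score = 0;
  int qstart = 0, qend = 0, tstart = 0, tend = 0;   // 0-based half-open
  int matches = 0, mismatches = 0, gap_opens = 0, aligned_cols = 0, positives = 0;
  std::string cigar;
  bool valid = false;
};

struct RawHit {
  int qid, tid;
  int qstart, qend, tstart, tend;
  char strand;
  int matches, mismatches, gap_opens, aligned_cols, positives, score;
  std::string cigar;
};

// ---- scoring ---------------------------------------------------------------

// Generic residue scorer over small integer alphabets.
struct Scorer {
  std::vector<int> mat;  // n x n
  int n;
  inline int s(uint8_t a, uint8_t b) const { return mat[(size_t)a * n + b]; }
};

// ---- Smith-Waterman with affine gaps and traceback -------------------------

// Trace codes per cell for H: 0 stop, 1 diag, 2 from E (gap in query: consumes
// target, cigar D), 3 from F (consumes query, cigar I).  E/F each carry one
// extension bit.
AlnResult sw_window(const std::vector<uint8_t>& q,
                    const std::vector<uint8_t>& t, int t_lo, int t_hi,
                    const Scorer& sc, int gap_open, int gap_ext,
                    int min_score) {
  AlnResult res;
  const int m = (int)q.size();
  const int w = t_hi - t_lo;
  if (m <= 0 || w <= 0) return res;
  if ((double)m * (double)w > 1.6e8) return res;  // window guard

  const int NEG = -1000000;
  std::vector<int> H(w + 1, 0), E(w + 1, NEG);
  std::vector<uint8_t> trH((size_t)(m + 1) * (w + 1), 0);
  std::vector<uint8_t> trE((size_t)(m + 1) * (w + 1), 0);
  std::vector<uint8_t> trF((size_t)(m + 1) * (w + 1), 0);

  int best = 0, bi = 0, bj = 0;
  std::vector<int> Hprev(w + 1, 0);
  std::vector<int> Fcol(w + 1, NEG);

  for (int i = 1; i <= m; ++i) {
    std::swap(Hprev, H);
    H[0] = 0;
    int Ei = NEG;
    for (int j = 1; j <= w; ++j) {
      // E: gap consuming target (horizontal)
      int e_open = H[j - 1] - gap_open - gap_ext;
      int e_ext  = Ei - gap_ext;
      uint8_t te = 0;
      if (e_ext > e_open) { Ei = e_ext; te = 1; } else { Ei = e_open; }
      trE[(size_t)i * (w + 1) + j] = te;
      // F: gap consuming query (vertical)
      int f_open = Hprev[j] - gap_open - gap_ext;
      int f_ext  = Fcol[j] - gap_ext;
      uint8_t tf = 0;
      if (f_ext > f_open) { Fcol[j] = f_ext; tf = 1; } else { Fcol[j] = f_open; }
      trF[(size_t)i * (w + 1) + j] = tf;

      int diag = Hprev[j - 1] + sc.s(q[i - 1], t[t_lo + j - 1]);
      int h = 0; uint8_t th = 0;
      if (diag > h) { h = diag; th = 1; }
      if (Ei > h)   { h = Ei;   th = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; th = 3; }
      H[j] = h;
      trH[(size_t)i * (w + 1) + j] = th;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best < min_score) return res;

  // traceback
  std::vector<char> ops;
  int i = bi, j = bj;
  int state = 0;  // 0 = in H, 2 = in E, 3 = in F
  while (i > 0 && j > 0) {
    if (state == 0) {
      uint8_t th = trH[(size_t)i * (w + 1) + j];
      if (th == 0) break;
      if (th == 1) { ops.push_back('M'); --i; --j; }
      else state = th;
    } else if (state == 2) {
      uint8_t te = trE[(size_t)i * (w + 1) + j];
      ops.push_back('D'); --j;
      if (!te) state = 0;
    } else {
      uint8_t tf = trF[(size_t)i * (w + 1) + j];
      ops.push_back('I'); --i;
      if (!tf) state = 0;
    }
  }
  std::reverse(ops.begin(), ops.end());

  res.valid = true;
  res.score = best;
  res.qstart = i; res.qend = bi;
  res.tstart = t_lo + j; res.tend = t_lo + bj;
  // stats + run-length cigar
  int qi = i, tj = t_lo + j;
  char prev = 0; int run = 0;
  std::string cig;
  for (char op : ops) {
    if (op == 'M') {
      int scv = sc.s(q[qi], t[tj]);
      if (q[qi] == t[tj]) res.matches++; else res.mismatches++;
      if (scv > 0) res.positives++;
      ++qi; ++tj;
    } else if (op == 'D') { ++tj; }
    else { ++qi; }
    if (op == prev) { ++run; }
    else {
      if (prev) { cig += std::to_string(run); cig += prev; }
      prev = op; run = 1;
    }
    res.aligned_cols++;
  }
  if (prev) { cig += std::to_string(run); cig += prev; }
  res.cigar = cig;
  // gap opens = runs of I or D
  {
    int opens = 0; char p = 0;
    for (char op : ops) { if ((op == 'I' || op == 'D') && op != p) ++opens; p = op; }
    res.gap_opens = opens;
  }
  return res;
}

// ---- k-mer index -----------------------------------------------------------

struct SeedIndex {
  int k;
  uint64_t mask;
  std::vector<std::pair<uint64_t, uint64_t>> entries;  // (key, tid<<32|pos)

  void build(const std::vector<std::vector<uint8_t>>& targets, int k_, int alpha_bits,
             uint8_t max_code) {
    k = k_;
    const int shift = alpha_bits * (k - 1);
    mask = (alpha_bits * k >= 64) ? ~0ULL : ((1ULL << (alpha_bits * k)) - 1ULL);
    entries.clear();
    for (size_t tid = 0; tid < targets.size(); ++tid) {
      const auto& t = targets[tid];
      if ((int)t.size() < k) continue;
      uint64_t key = 0; int valid = 0;
      for (size_t p = 0; p < t.size(); ++p) {
        uint8_t c = t[p];
        if (c >= max_code) { valid = 0; key = 0; continue; }
        key = ((key << alpha_bits) | c) & mask;
        if (++valid >= k) {
          entries.emplace_back(key, ((uint64_t)tid << 32) | (uint64_t)(p - k + 1));
        }
      }
      (void)shift;
    }
    std::sort(entries.begin(), entries.end());
  }
};

struct Cluster {
  int tid;
  long diag;
  int tmin, tmax;   // seed span on target (inclusive start of first / last seed)
  int ungapped = 0;
  int ext_lo = 0, ext_hi = 0;  // target extent after ungapped extension
};

// ungapped X-drop extension along the cluster diagonal
void extend_cluster(const std::vector<uint8_t>& q, const std::vector<uint8_t>& t,
                    const Scorer& sc, int k, int xdrop, Cluster& cl) {
  long d = cl.diag;
  int qs = (int)(cl.tmin - d);
  int qe = (int)(cl.tmax - d) + k;  // exclusive
  int score = 0;
  for (int qi = qs; qi < qe; ++qi) score += sc.s(q[qi], t[qi + d]);
  // right
  int cur = score, bestr = score; int qhi = qe;
  for (int qi = qe; qi < (int)q.size() && qi + d < (long)t.size(); ++qi) {
    cur += sc.s(q[qi], t[qi + d]);
    if (cur > bestr) { bestr = cur; qhi = qi + 1; }
    if (cur < bestr - xdrop) break;
  }
  // left
  cur = bestr; int bestl = bestr; int qlo = qs;
  for (int qi = qs - 1; qi >= 0 && qi + d >= 0; --qi) {
    cur += sc.s(q[qi], t[qi + d]);
    if (cur > bestl) { bestl = cur; qlo = qi; }
    if (cur < bestl - xdrop) break;
  }
  cl.ungapped = bestl;
  cl.ext_lo = (int)(qlo + d);
  cl.ext_hi = (int)(qhi + d);
}

// Seeds -> diagonal clusters -> merged windows -> SW hits (one strand).
void align_one(const std::vector<uint8_t>& q, int qid,
               const std::vector<std::vector<uint8_t>>& targets,
               const SeedIndex& idx, const Scorer& sc,
               int gap_open, int gap_ext, int xdrop, int min_ungapped,
               int min_score, int max_occ, int max_windows, int alpha_bits,
               uint8_t max_code, char strand, int orig_qlen,
               std::vector<RawHit>& out) {
  const int k = idx.k;
  const int m = (int)q.size();
  if (m < k) return;

  // collect seeds
  std::vector<std::pair<uint64_t, int>> seeds;  // (tid<<32|tpos, qpos) flat
  struct Seed { int tid; long diag; int tpos; };
  std::vector<Seed> sv;
  uint64_t key = 0; int valid = 0;
  for (int p = 0; p < m; ++p) {
    uint8_t c = q[p];
    if (c >= max_code) { valid = 0; key = 0; continue; }
    key = ((key << alpha_bits) | c) & idx.mask;
    if (++valid < k) continue;
    int qpos = p - k + 1;
    auto lo = std::lower_bound(idx.entries.begin(), idx.entries.end(),
                               std::pair<uint64_t, uint64_t>(key, 0ULL));
    auto hi = std::upper_bound(idx.entries.begin(), idx.entries.end(),
                               std::pair<uint64_t, uint64_t>(key, ~0ULL));
    if (hi - lo > max_occ) continue;
    for (auto it = lo; it != hi; ++it) {
      int tid = (int)(it->second >> 32);
      int tpos = (int)(it->second & 0xffffffffULL);
      sv.push_back({tid, (long)tpos - qpos, tpos});
    }
  }
  if (sv.empty()) return;
  std::sort(sv.begin(), sv.end(), [](const Seed& a, const Seed& b) {
    if (a.tid != b.tid) return a.tid < b.tid;
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.tpos < b.tpos;
  });

  // cluster per (tid, diag) with tpos gaps <= 64
  std::vector<Cluster> clusters;
  size_t i = 0;
  while (i < sv.size()) {
    Cluster cl; cl.tid = sv[i].tid; cl.diag = sv[i].diag;
    cl.tmin = sv[i].tpos; cl.tmax = sv[i].tpos;
    size_t j = i + 1;
    while (j < sv.size() && sv[j].tid == cl.tid && sv[j].diag == cl.diag &&
           sv[j].tpos - cl.tmax <= 64) {
      cl.tmax = sv[j].tpos; ++j;
    }
    clusters.push_back(cl);
    i = j;
  }
  for (auto& cl : clusters)
    extend_cluster(q, targets[cl.tid], sc, k, xdrop, cl);

  clusters.erase(std::remove_if(clusters.begin(), clusters.end(),
                                [&](const Cluster& c) { return c.ungapped < min_ungapped; }),
                 clusters.end());
  if (clusters.empty()) return;
  std::sort(clusters.begin(), clusters.end(),
            [](const Cluster& a, const Cluster& b) { return a.ungapped > b.ungapped; });
  // near-equal placements must all be examined (ambiguity detection), but
  // clusters far below the best ungapped score can only yield hits that the
  // identity/coverage filters discard; skip their DP
  const int floor_score = clusters.front().ungapped / 2;
  clusters.erase(std::remove_if(clusters.begin(), clusters.end(),
                                [&](const Cluster& c) { return c.ungapped < floor_score; }),
                 clusters.end());
  if ((int)clusters.size() > max_windows) clusters.resize(max_windows);

  // One DP window per cluster (windows are NOT merged: nearby but distinct
  // placements, e.g. tandem paralogs, must each surface their own best
  // alignment).  Identical windows are deduplicated before DP; hits whose
  // target spans substantially overlap a better hit are deduplicated after.
  struct Win { int tid, lo, hi; };
  std::vector<Win> wins;
  const int pad = m + 64;
  for (const auto& cl : clusters) {
    int tlen = (int)targets[cl.tid].size();
    Win w{cl.tid, std::max(0, cl.ext_lo - pad), std::min(tlen, cl.ext_hi + pad)};
    bool dup = false;
    for (const auto& o : wins)
      if (o.tid == w.tid && std::abs(o.lo - w.lo) < 32 &&
          std::abs(o.hi - w.hi) < 32) { dup = true; break; }
    if (!dup) wins.push_back(w);
  }

  std::vector<RawHit> local;
  for (const auto& w : wins) {
    AlnResult r = sw_window(q, targets[w.tid], w.lo, w.hi, sc, gap_open, gap_ext,
                            min_score);
    if (!r.valid) continue;
    RawHit h;
    h.qid = qid; h.tid = w.tid; h.strand = strand;
    if (strand == '+') { h.qstart = r.qstart; h.qend = r.qend; }
    else { h.qstart = orig_qlen - r.qend; h.qend = orig_qlen - r.qstart; }
    h.tstart = r.tstart; h.tend = r.tend;
    h.matches = r.matches; h.mismatches = r.mismatches;
    h.gap_opens = r.gap_opens; h.aligned_cols = r.aligned_cols;
    h.positives = r.positives; h.score = r.score; h.cigar = r.cigar;
    local.push_back(std::move(h));
  }
  std::sort(local.begin(), local.end(),
            [](const RawHit& a, const RawHit& b) { return a.score > b.score; });
  std::vector<RawHit> kept;
  for (auto& h : local) {
    bool shadowed = false;
    for (const auto& k : kept) {
      if (k.tid != h.tid) continue;
      int ov = std::min(k.tend, h.tend) - std::max(k.tstart, h.tstart);
      int shorter = std::min(k.tend - k.tstart, h.tend - h.tstart);
      if (ov > 0 && shorter > 0 && 2 * ov > shorter) { shadowed = true; break; }
    }
    if (!shadowed) kept.push_back(std::move(h));
  }
  for (auto& h : kept) out.push_back(std::move(h));
}

DataFrame hits_to_df(const std::vector<RawHit>& hits) {
  int n = (int)hits.size();
  IntegerVector qid(n), tid(n), qstart(n), qend(n), tstart(n), tend(n),
      matches(n), mismatches(n), gap_opens(n), aligned_cols(n), positives(n),
      score(n);
  CharacterVector strand(n), cigar(n);
  for (int i = 0; i < n; ++i) {
    const RawHit& h = hits[i];
    qid[i] = h.qid + 1; tid[i] = h.tid + 1;
    qstart[i] = h.qstart; qend[i] = h.qend;
    tstart[i] = h.tstart; tend[i] = h.tend;
    strand[i] = std::string(1, h.strand);
    matches[i] = h.matches; mismatches[i] = h.mismatches;
    gap_opens[i] = h.gap_opens; aligned_cols[i] = h.aligned_cols;
    positives[i] = h.positives; score[i] = h.score; cigar[i] = h.cigar;
  }
  return DataFrame::create(
      _["qid"] = qid, _["tid"] = tid, _["qstart"] = qstart, _["qend"] = qend,
      _["tstart"] = tstart, _["tend"] = tend, _["strand"] = strand,
      _["matches"] = matches, _["mismatches"] = mismatches,
      _["gap_opens"] = gap_opens, _["aligned_cols"] = aligned_cols,
      _["positives"] = positives, _["score"] = score, _["cigar"] = cigar,
      _["stringsAsFactors"] = false);
}

// ---- nucleotide specifics --------------------------------------------------

inline uint8_t nt_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return 4;  // N and anything else
  }
}

std::vector<uint8_t> encode_nt(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = nt_code(s[i]);
  return v;
}

std::vector<uint8_t> revcomp_codes(const std::vector<uint8_t>& v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t c = v[v.size() - 1 - i];
    r[i] = (c < 4) ? (uint8_t)(3 - c) : (uint8_t)4;
  }
  return r;
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_align_nt(CharacterVector queries, CharacterVector targets,
                       int k, int match, int mismatch, int gap_open, int gap_ext,
                       int xdrop, int min_ungapped, int min_score, int max_occ,
                       int max_windows, bool both_strands) {
  std::vector<std::vector<uint8_t>> tg(targets.size());
  for (int i = 0; i < targets.size(); ++i)
    tg[i] = encode_nt(as<std::string>(targets[i]));

  Scorer sc; sc.n = 5; sc.mat.assign(25, mismatch);
  for (int i = 0; i < 4; ++i) sc.mat[i * 5 + i] = match;
  // N scores as mismatch against everything, including N

  SeedIndex idx; idx.build(tg, k, 2, 4);

  std::vector<RawHit> hits;
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::vector<uint8_t> q = encode_nt(as<std::string>(queries[qi]));
    int qlen = (int)q.size();
    align_one(q, qi, tg, idx, sc, -gap_open, -gap_ext, xdrop, min_ungapped,
              min_score, max_occ, max_windows, 2, 4, '+', qlen, hits);
    if (both_strands) {
      std::vector<uint8_t> rq = revcomp_codes(q);
      align_one(rq, qi, tg, idx, sc, -gap_open, -gap_ext, xdrop, min_ungapped,
                min_score, max_occ, max_windows, 2, 4, '-', qlen, hits);
    }
  }
  return hits_to_df(hits);
}

// [[Rcpp::export]]
DataFrame cpp_align_prot(CharacterVector queries, CharacterVector targets,
                         CharacterVector alphabet, IntegerMatrix score_mat,
                         int k, int gap_open, int gap_ext, int xdrop,
                         int min_ungapped, int min_score, int max_occ,
                         int max_windows) {
  // char -> code lookup from alphabet (row order of score_mat)
  std::string alpha = as<std::string>(alphabet[0]);
  int n = (int)alpha.size();
  std::vector<int> lut(128, -1);
  for (int i = 0; i < n; ++i) lut[(unsigned char)alpha[i]] = i;
  int xcode = lut['X'] >= 0 ? lut['X'] : 0;

  Scorer sc; sc.n = n; sc.mat.resize((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) sc.mat[(size_t)i * n + j] = score_mat(i, j);

  auto encode = [&](const std::string& s) {
    std::vector<uint8_t> v(s.size());
    for (size_t i = 0; i < s.size(); ++i) {
      int c = lut[(unsigned char)s[i]];
      v[i] = (uint8_t)(c < 0 ? xcode : c);
    }
    return v;
  };

  std::vector<std::vector<uint8_t>> tg(targets.size());
  for (int i = 0; i < targets.size(); ++i)
    tg[i] = encode(as<std::string>(targets[i]));

  // Alphabet must list X and '*' last (Biostrings BLOSUM order); codes at or
  // above `cap` are excluded from seeds but still scored in the DP.
  int star = lut['*'];
  uint8_t cap = (uint8_t)n;
  if (xcode >= 0 && (uint8_t)xcode < cap) cap = (uint8_t)xcode;
  if (star >= 0 && (uint8_t)star < cap) cap = (uint8_t)star;

  SeedIndex idx; idx.build(tg, k, 5, cap);

  std::vector<RawHit> hits;
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::vector<uint8_t> q = encode(as<std::string>(queries[qi]));
    int qlen = (int)q.size();
    align_one(q, qi, tg, idx, sc, gap_open, gap_ext, xdrop, min_ungapped,
              min_score, max_occ, max_windows, 5, cap, '+', qlen, hits);
  }
  return hits_to_df(hits);
}
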