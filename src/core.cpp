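#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <array>
#include <string>
#include <cstdint>
#include <cctype>
#include <tuple>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Shared helpers
// ---------------------------------------------------------------------------

// 2-bit encode A/C/G/T; -1 for anything else (incl. N: never matches a k-mer)
static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char complement(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = complement(c);
  return r;
}

// enumerate valid (no ambiguous base) k-mers of s as 2k-bit codes; cb(code, pos)
template <typename F>
static void for_each_kmer(const std::string& s, int k, F cb) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t code = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) cb(code, i - k + 1);
  }
}

// ---------------------------------------------------------------------------
// Host subtraction: count read k-mers present in the host k-mer set
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_host_kmer_counts(CharacterVector reads, std::string host,
                                   int k) {
  std::unordered_set<uint64_t> hostset;
  hostset.reserve(2 * host.size());
  for_each_kmer(host, k, [&](uint64_t c, int) { hostset.insert(c); });
  std::string hrc = revcomp_str(host);
  for_each_kmer(hrc, k, [&](uint64_t c, int) { hostset.insert(c); });

  int n = reads.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    int cnt = 0;
    for_each_kmer(s, k, [&](uint64_t c, int) {
      if (hostset.count(c)) ++cnt;
    });
    out[i] = cnt;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Smith-Waterman (affine gaps). Generic alphabet: a 256-entry lookup maps
// characters to row indices of the scoring matrix; a gap of length g costs
// gap_open + g * gap_ext (BLAST convention).
// ---------------------------------------------------------------------------

struct CharMap {
  int idx[256];
  CharMap(const IntegerMatrix& mat, const CharacterVector& letters) {
    for (int i = 0; i < 256; ++i) idx[i] = -1;
    for (int i = 0; i < letters.size(); ++i) {
      std::string l = as<std::string>(letters[i]);
      if (!l.empty()) {
        idx[(unsigned char)l[0]] = i;
        idx[(unsigned char)std::tolower(l[0])] = i;
      }
    }
  }
};

// flat copy of the scoring matrix with an extra "unknown" row/column
// holding the fallback score, so the inner loop needs no branches
struct FlatMat {
  std::vector<int> v;
  int R;
  FlatMat(const IntegerMatrix& mat, int fallback) : R(mat.nrow() + 1) {
    v.assign((size_t)R * R, fallback);
    for (int i = 0; i < mat.nrow(); ++i)
      for (int j = 0; j < mat.ncol(); ++j)
        v[(size_t)i * R + j] = mat(i, j);
  }
};

// score-only local alignment
static int sw_score(const std::string& a, const std::string& b,
                    const FlatMat& fm, const CharMap& cm,
                    int gap_open, int gap_ext) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return 0;
  const int unk = fm.R - 1;
  std::vector<int> H(n + 1, 0), E(n + 1, 0);
  std::vector<int> bj(n);
  for (int j = 0; j < n; ++j) {
    int r = cm.idx[(unsigned char)b[j]];
    bj[j] = (r >= 0) ? r : unk;
  }
  const int go = gap_open + gap_ext;  // cost of first gap position
  int best = 0;
  int* Hp = H.data();
  int* Ep = E.data();
  const int* bjp = bj.data();
  for (int i = 1; i <= m; ++i) {
    int ai = cm.idx[(unsigned char)a[i - 1]];
    if (ai < 0) ai = unk;
    const int* row = fm.v.data() + (size_t)ai * fm.R;
    int diag = 0, F = 0;
    for (int j = 1; j <= n; ++j) {
      int h = diag + row[bjp[j - 1]];
      int e = Ep[j] - gap_ext, e2 = Hp[j] - go;
      e = e > e2 ? e : e2;
      Ep[j] = e;
      int f2 = Hp[j - 1] - go;
      F = (F - gap_ext > f2) ? F - gap_ext : f2;
      if (e > h) h = e;
      if (F > h) h = F;
      if (h < 0) h = 0;
      diag = Hp[j];
      Hp[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
int cpp_sw_score(std::string a, std::string b, IntegerMatrix mat,
                 CharacterVector letters, int gap_open, int gap_ext,
                 int fallback = -4) {
  CharMap cm(mat, letters);
  FlatMat fm(mat, fallback);
  return sw_score(a, b, fm, cm, gap_open, gap_ext);
}

// full local alignment with traceback; returns score, matches, alignment
// length (columns), and 1-based spans on both sequences
// [[Rcpp::export]]
List cpp_sw_align(std::string a, std::string b, IntegerMatrix mat,
                  CharacterVector letters, int gap_open, int gap_ext,
                  int fallback = -4) {
  const int m = (int)a.size(), n = (int)b.size();
  if ((double)m * (double)n > 4e8)
    stop("alignment problem too large (%d x %d)", m, n);
  CharMap cm(mat, letters);
  const int go = gap_open + gap_ext;
  std::vector<int> H((size_t)(n + 1), 0), E((size_t)(n + 1), 0);
  // traceback codes: 0 stop, 1 diag, 2 up (gap in b), 3 left (gap in a)
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbE((size_t)(m + 1) * (n + 1), 0); // 1: E extended
  std::vector<uint8_t> tbF((size_t)(m + 1) * (n + 1), 0); // 1: F extended
  int best = 0, bi_ = 0, bj_ = 0;
  for (int i = 1; i <= m; ++i) {
    int diag = 0, F = 0;
    int ai = cm.idx[(unsigned char)a[i - 1]];
    for (int j = 1; j <= n; ++j) {
      int bj2 = cm.idx[(unsigned char)b[j - 1]];
      int sub = (ai >= 0 && bj2 >= 0) ? mat(ai, bj2) : fallback;
      int eNew = H[j] - go, eExt = E[j] - gap_ext;
      if (eExt > eNew) { E[j] = eExt; tbE[(size_t)i * (n + 1) + j] = 1; }
      else E[j] = eNew;
      int fNew = H[j - 1] - go, fExt = F - gap_ext;
      if (fExt > fNew) { F = fExt; tbF[(size_t)i * (n + 1) + j] = 1; }
      else F = fNew;
      int h = diag + sub;
      uint8_t t = 1;
      if (E[j] > h) { h = E[j]; t = 2; }
      if (F > h) { h = F; t = 3; }
      if (h <= 0) { h = 0; t = 0; }
      diag = H[j];
      H[j] = h;
      tb[(size_t)i * (n + 1) + j] = t;
      if (h > best) { best = h; bi_ = i; bj_ = j; }
    }
  }
  int i = bi_, j = bj_, matches = 0, cols = 0;
  int aend = bi_, bend = bj_;
  // walk back; gap runs follow the extension flags
  while (i > 0 && j > 0) {
    uint8_t t = tb[(size_t)i * (n + 1) + j];
    if (t == 0) break;
    if (t == 1) {
      ++cols;
      if (std::toupper(a[i - 1]) == std::toupper(b[j - 1])) ++matches;
      --i; --j;
    } else if (t == 2) {
      while (i > 0 && tbE[(size_t)i * (n + 1) + j]) { ++cols; --i; }
      if (i > 0) { ++cols; --i; }
    } else {
      while (j > 0 && tbF[(size_t)i * (n + 1) + j]) { ++cols; --j; }
      if (j > 0) { ++cols; --j; }
    }
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["length"] = cols,
                      _["astart"] = i + 1, _["aend"] = aend,
                      _["bstart"] = j + 1, _["bend"] = bend);
}

// ---------------------------------------------------------------------------
// Seeded translated search. Queries arrive pre-translated (6 frames per
// read, done in R); a subject is aligned only if it shares at least one
// exact word of length w with the frame (word positions with unmapped or
// non-seedable residues are skipped). Returns every seeded (query, frame,
// subject) candidate with its local alignment score; E-values, tie-breaks
// and identities are computed in R.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_seeded_search(List frames_per_query, CharacterVector db,
                            IntegerMatrix mat, CharacterVector letters,
                            LogicalVector seedable, int word_size,
                            int gap_open, int gap_ext, int min_score) {
  CharMap cm(mat, letters);
  FlatMat fm(mat, -4);
  const int R = letters.size();
  const int nsub = db.size();
  std::vector<std::string> subs(nsub);
  for (int s = 0; s < nsub; ++s) subs[s] = as<std::string>(db[s]);

  // word index over the database
  std::unordered_map<uint64_t, std::vector<int>> index; // word -> subjects
  for (int s = 0; s < nsub; ++s) {
    const std::string& ss = subs[s];
    int L = (int)ss.size();
    for (int p = 0; p + word_size <= L; ++p) {
      uint64_t code = 0; bool ok = true;
      for (int q = 0; q < word_size; ++q) {
        int r = cm.idx[(unsigned char)ss[p + q]];
        if (r < 0 || !seedable[r]) { ok = false; break; }
        code = code * (uint64_t)R + (uint64_t)r;
      }
      if (!ok) continue;
      auto& v = index[code];
      if (v.empty() || v.back() != s) v.push_back(s);
    }
  }

  std::vector<int> out_q, out_f, out_s, out_sc;
  int nq = frames_per_query.size();
  std::vector<char> gated(nsub, 0);
  std::vector<int> gated_list;
  for (int q = 0; q < nq; ++q) {
    CharacterVector fr = frames_per_query[q];
    for (int f = 0; f < fr.size(); ++f) {
      std::string qs = as<std::string>(fr[f]);
      int L = (int)qs.size();
      if (L < word_size) continue;
      gated_list.clear();
      for (int p = 0; p + word_size <= L; ++p) {
        uint64_t code = 0; bool ok = true;
        for (int w = 0; w < word_size; ++w) {
          int r = cm.idx[(unsigned char)qs[p + w]];
          if (r < 0 || !seedable[r]) { ok = false; break; }
          code = code * (uint64_t)R + (uint64_t)r;
        }
        if (!ok) continue;
        auto it = index.find(code);
        if (it == index.end()) continue;
        for (int s : it->second) {
          if (!gated[s]) { gated[s] = 1; gated_list.push_back(s); }
        }
      }
      for (int s : gated_list) {
        gated[s] = 0;
        int sc = sw_score(qs, subs[s], fm, cm, gap_open, gap_ext);
        if (sc >= min_score) {
          out_q.push_back(q + 1); out_f.push_back(f + 1);
          out_s.push_back(s + 1); out_sc.push_back(sc);
        }
      }
    }
  }
  return DataFrame::create(_["query"] = out_q, _["frame_idx"] = out_f,
                           _["subject"] = out_s, _["score"] = out_sc);
}

// ---------------------------------------------------------------------------
// Overlap detection for OLC assembly. Gap-free suffix-prefix overlaps (the
// generator's error model is substitution-only); candidate diagonals come
// from shared exact k-mers, in both relative orientations. For each
// (i, j, orientation) the best-scoring diagonal meeting the length and
// identity thresholds is reported once, with i < j.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_find_overlaps(CharacterVector seqs, int k, int min_len,
                            double min_identity) {
  const int n = seqs.size();
  std::vector<std::string> fwd(n), rev(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(seqs[i]);
    rev[i] = revcomp_str(fwd[i]);
  }
  // index forward and reverse-complement k-mers of every read
  // value packs (seq << 1 | strand), position kept separately
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> idxF, idxR;
  for (int j = 0; j < n; ++j) {
    for_each_kmer(fwd[j], k, [&](uint64_t c, int p) {
      idxF[c].push_back({j, p});
    });
    for_each_kmer(rev[j], k, [&](uint64_t c, int p) {
      idxR[c].push_back({j, p});
    });
  }

  std::vector<int> o_i, o_j, o_orient, o_off, o_len, o_match;
  std::vector<double> o_ident, o_score;

  // per-read-i: distinct (j, orient, diag) candidates
  std::unordered_set<uint64_t> seen;
  for (int i = 0; i < n; ++i) {
    seen.clear();
    const std::string& a = fwd[i];
    const int La = (int)a.size();
    // best per (j, orient): evaluated lazily keyed by diag dedup
    std::unordered_map<uint64_t, std::tuple<double, int, int, int>> best;
    auto consider = [&](int j, int orient, int diag) {
      if (j <= i) return;  // unordered pairs once
      uint64_t key = (((uint64_t)(2 * j + orient)) << 32) ^
                     (uint64_t)(uint32_t)(diag + 1073741824);
      if (!seen.insert(key).second) return;
      const std::string& b = (orient == 0) ? fwd[j] : rev[j];
      const int Lb = (int)b.size();
      int p0 = std::max(0, diag), p1 = std::min(La, Lb + diag);
      int len = p1 - p0;
      if (len < min_len) return;
      int matches = 0;
      for (int p = p0; p < p1; ++p) {
        char ca = a[p], cb = b[p - diag];
        if (base2bit(ca) >= 0 && ca == cb) ++matches;
      }
      double ident = 100.0 * matches / len;
      if (ident < min_identity) return;
      double score = len * ident / 100.0;
      uint64_t bk = ((uint64_t)j << 1) | (uint64_t)orient;
      auto it = best.find(bk);
      if (it == best.end() ||
          score > std::get<0>(it->second) ||
          (score == std::get<0>(it->second) && len > std::get<2>(it->second)))
        best[bk] = std::make_tuple(score, diag, len, matches);
    };
    for_each_kmer(a, k, [&](uint64_t c, int p) {
      auto itF = idxF.find(c);
      if (itF != idxF.end())
        for (auto& h : itF->second) consider(h.first, 0, p - h.second);
      auto itR = idxR.find(c);
      if (itR != idxR.end())
        for (auto& h : itR->second) consider(h.first, 1, p - h.second);
    });
    for (auto& kv : best) {
      int j = (int)(kv.first >> 1), orient = (int)(kv.first & 1);
      double score = std::get<0>(kv.second);
      int diag = std::get<1>(kv.second), len = std::get<2>(kv.second),
          matches = std::get<3>(kv.second);
      o_i.push_back(i + 1); o_j.push_back(j + 1); o_orient.push_back(orient);
      o_off.push_back(diag); o_len.push_back(len); o_match.push_back(matches);
      o_ident.push_back(100.0 * matches / len); o_score.push_back(score);
    }
  }
  return DataFrame::create(_["i"] = o_i, _["j"] = o_j, _["orient"] = o_orient,
                           _["offset"] = o_off, _["length"] = o_len,
                           _["matches"] = o_match, _["identity"] = o_ident,
                           _["score"] = o_score);
}

// ---------------------------------------------------------------------------
// Greedy layout: process overlaps in the order given (R pre-sorts by score),
// merging reads into growing contigs with a union-find that tracks each
// read's offset and orientation relative to its contig root. Overlaps whose
// two reads already share a contig are skipped (first placement wins).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_greedy_layout(IntegerVector lens, IntegerVector oi, IntegerVector oj,
                       IntegerVector orient, IntegerVector offset) {
  const int n = lens.size();
  std::vector<int> parent(n), off(n, 0), flip(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;

  // find with full path compression; after the call, off/flip of x are
  // relative to the root. Iterative: collect the chain, then compose the
  // placement transforms top-down.
  std::vector<int> chain;
  auto find = [&](int x) -> int {
    chain.clear();
    int r = x;
    while (parent[r] != r) { chain.push_back(r); r = parent[r]; }
    for (int c = (int)chain.size() - 1; c >= 0; --c) {
      int node = chain[c], p = parent[node];
      // p's off/flip are already root-relative here
      if (flip[p] == 0) {
        off[node] = off[p] + off[node];
      } else {
        off[node] = off[p] + lens[p] - off[node] - lens[node];
        flip[node] = 1 - flip[node];
      }
      parent[node] = r;
    }
    return r;
  };

  const int m = oi.size();
  for (int e = 0; e < m; ++e) {
    int i = oi[e] - 1, j = oj[e] - 1;
    int ri = find(i), rj = find(j);
    if (ri == rj) continue;
    // target placement of j in ri's frame
    int Fj_t = flip[i] ^ orient[e];
    int Oj_t;
    if (flip[i] == 0) Oj_t = off[i] + offset[e];
    else Oj_t = off[i] + lens[i] - offset[e] - lens[j];
    // attach rj under ri so that j lands on its target
    int Fr = flip[j] ^ Fj_t;
    int Or;
    if (Fr == 0) Or = Oj_t - off[j];
    else Or = Oj_t + off[j] + lens[j] - lens[rj];
    parent[rj] = ri; off[rj] = Or; flip[rj] = Fr;
  }
  IntegerVector contig(n), out_off(n), out_flip(n);
  for (int i = 0; i < n; ++i) {
    contig[i] = find(i) + 1;
    out_off[i] = off[i];
    out_flip[i] = flip[i];
  }
  return List::create(_["contig"] = contig, _["offset"] = out_off,
                      _["flip"] = out_flip);
}

// ---------------------------------------------------------------------------
// Majority-vote consensus over pre-oriented reads placed at given offsets
// (0-based). Ties break by fixed base order A < C < G < T; uncovered
// columns (should not occur inside a contig) emit N.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
std::string cpp_consensus(CharacterVector seqs, IntegerVector offsets,
                          int total_len) {
  std::vector<std::array<int, 4>> counts((size_t)total_len, {0, 0, 0, 0});
  for (int r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    int o = offsets[r];
    for (int p = 0; p < (int)s.size(); ++p) {
      int pos = o + p;
      if (pos < 0 || pos >= total_len) continue;
      int b = base2bit(s[p]);
      if (b >= 0) counts[pos][b]++;
    }
  }
  static const char bases[] = "ACGT";
  std::string cons(total_len, 'N');
  for (int p = 0; p < total_len; ++p) {
    int bi = -1, bc = 0;
    for (int b = 0; b < 4; ++b) {
      if (counts[p][b] > bc) { bc = counts[p][b]; bi = b; }
    }
    if (bi >= 0) cons[p] = bases[bi];
  }
  return cons;
}
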