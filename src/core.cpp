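// Ungapped seed-and-extend mapper and pileup extraction for toy genomes.
// Genomes here are a few hundred kb, reads 75-150 bp, SNP-only: mismatch
// counting over full read length is the alignment score, and a k-mer
// positional index supplies candidate placements on both strands.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

static inline uint8_t base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // N or anything else: mismatches everything
  }
}

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Cand {
  int chrom;
  int pos;      // 0-based start on chrom
  bool rev;
  bool operator<(const Cand& o) const {
    if (chrom != o.chrom) return chrom < o.chrom;
    if (pos != o.pos) return pos < o.pos;
    return rev < o.rev;
  }
  bool operator==(const Cand& o) const {
    return chrom == o.chrom && pos == o.pos && rev == o.rev;
  }
};

// [[Rcpp::export(name = ".map_reads_cpp")]]
DataFrame map_reads_cpp(CharacterVector ref_seqs, CharacterVector read_seqs,
                        int k, int stride, int max_mm, double seed) {
  int nchrom = ref_seqs.size();
  std::vector<std::vector<uint8_t>> ref(nchrom);
  for (int c = 0; c < nchrom; ++c) {
    const char* s = CHAR(STRING_ELT(ref_seqs, c));
    size_t L = strlen(s);
    ref[c].resize(L);
    for (size_t i = 0; i < L; ++i) ref[c][i] = base_code(s[i]);
  }
  // k-mer index over all chromosomes
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> index;
  index.reserve(1 << 20);
  for (int c = 0; c < nchrom; ++c) {
    const std::vector<uint8_t>& s = ref[c];
    if ((int)s.size() < k) continue;
    uint64_t km = 0; int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      if (s[i] > 3) { valid = 0; km = 0; continue; }
      km = ((km << 2) | s[i]) & mask;
      if (++valid >= k)
        index[km].push_back(std::make_pair(c, (int)(i - k + 1)));
    }
  }
  uint64_t seed64 = (uint64_t)seed;
  int nread = read_seqs.size();
  IntegerVector out_chrom(nread, NA_INTEGER), out_pos(nread, NA_INTEGER),
    out_nm(nread, NA_INTEGER), out_mapq(nread, NA_INTEGER),
    out_nbest(nread, NA_INTEGER);
  CharacterVector out_strand(nread, NA_STRING);

  std::vector<Cand> cands;
  for (int r = 0; r < nread; ++r) {
    const char* rs = CHAR(STRING_ELT(read_seqs, r));
    int L = (int)strlen(rs);
    if (L < k) continue;
    std::vector<uint8_t> fwd(L), rc(L);
    bool anyN = false;
    for (int i = 0; i < L; ++i) {
      fwd[i] = base_code(rs[i]);
      if (fwd[i] > 3) anyN = true;
    }
    for (int i = 0; i < L; ++i)
      rc[i] = fwd[L - 1 - i] > 3 ? 4 : 3 - fwd[L - 1 - i];
    cands.clear();
    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<uint8_t>& q = strand ? rc : fwd;
      for (int off = 0; off + k <= L; off += stride) {
        uint64_t km = 0; bool ok = true;
        for (int i = 0; i < k; ++i) {
          if (q[off + i] > 3) { ok = false; break; }
          km = (km << 2) | q[off + i];
        }
        if (!ok) continue;
        auto it = index.find(km);
        if (it == index.end()) continue;
        for (auto& hit : it->second) {
          int pos = hit.second - off;
          if (pos >= 0 && pos + L <= (int)ref[hit.first].size())
            cands.push_back({hit.first, pos, strand == 1});
        }
      }
    }
    if (anyN || cands.empty()) continue;
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
    int best = max_mm + 1, second = max_mm + 1;
    std::vector<int> best_idx;
    for (size_t ci = 0; ci < cands.size(); ++ci) {
      const std::vector<uint8_t>& q = cands[ci].rev ? rc : fwd;
      const std::vector<uint8_t>& s = ref[cands[ci].chrom];
      int p = cands[ci].pos, mm = 0;
      for (int i = 0; i < L && mm <= max_mm; ++i)
        if (s[p + i] > 3 || s[p + i] != q[i]) ++mm;
      if (mm > max_mm) continue;
      if (mm < best) {
        second = best; best = mm;
        best_idx.clear(); best_idx.push_back((int)ci);
      } else if (mm == best) {
        best_idx.push_back((int)ci);
      } else if (mm < second) {
        second = mm;
      }
    }
    if (best > max_mm) continue;
    int pick;
    int nbest = (int)best_idx.size();
    if (nbest >= 2) {
      pick = best_idx[(int)(splitmix64(seed64 ^ (uint64_t)(r + 1)) %
                            (uint64_t)nbest)];
      out_mapq[r] = 0;
    } else {
      pick = best_idx[0];
      // co-optimals count as second-best distance 0 is impossible here;
      // absent any scored second candidate the placement is unique
      int delta = (second <= max_mm) ? (second - best) : (max_mm + 1);
      out_mapq[r] = std::min(60, 6 * delta + 20);
      if (second > max_mm) out_mapq[r] = 60;
    }
    out_chrom[r] = cands[pick].chrom + 1;
    out_pos[r] = cands[pick].pos;
    out_strand[r] = cands[pick].rev ? "-" : "+";
    out_nm[r] = best;
    out_nbest[r] = nbest;
  }
  return DataFrame::create(
    _["chrom_idx"] = out_chrom, _["start0"] = out_pos,
    _["strand"] = out_strand, _["nm"] = out_nm,
    _["mapq"] = out_mapq, _["n_best"] = out_nbest,
    _["stringsAsFactors"] = false);
}

// base counts per reference position from ungapped alignments
// [[Rcpp::export(name = ".pileup_counts_cpp")]]
List pileup_counts_cpp(IntegerVector chrom_idx, IntegerVector start0,
                       IntegerVector rev, IntegerVector read_row,
                       IntegerVector mapq, CharacterVector read_seqs,
                       IntegerVector ref_lens, int min_mapq,
                       bool drop_mapq0) {
  int nchrom = ref_lens.size();
  List out(nchrom);
  std::vector<IntegerMatrix> mats;
  for (int c = 0; c < nchrom; ++c) {
    IntegerMatrix m(4, ref_lens[c]);
    mats.push_back(m);
    out[c] = m;
  }
  int n = chrom_idx.size();
  for (int i = 0; i < n; ++i) {
    if (chrom_idx[i] == NA_INTEGER) continue;
    if (mapq[i] < min_mapq || (drop_mapq0 && mapq[i] == 0)) continue;
    const char* s = CHAR(STRING_ELT(read_seqs, read_row[i] - 1));
    int L = (int)strlen(s);
    bool rv = rev[i] == 1;
    int c = chrom_idx[i] - 1, p = start0[i];
    for (int j = 0; j < L; ++j) {
      uint8_t b = rv ? (base_code(s[L - 1 - j]) > 3 ? 4
                        : 3 - base_code(s[L - 1 - j]))
                     : base_code(s[j]);
      if (b > 3) continue;
      mats[c](b, p + j)++;
    }
  }
  return out;
}

// full per-read columns at requested positions
// [[Rcpp::export(name = ".extract_columns_cpp")]]
DataFrame extract_columns_cpp(IntegerVector chrom_idx, IntegerVector start0,
                              IntegerVector rev, IntegerVector read_row,
                              IntegerVector mapq, CharacterVector read_seqs,
                              CharacterVector read_quals,
                              List positions,  // per chrom: 0-based sorted
                              IntegerVector ref_lens, int min_mapq,
                              bool drop_mapq0) {
  int nchrom = ref_lens.size();
  std::vector<std::vector<int>> want(nchrom);
  for (int c = 0; c < nchrom; ++c) {
    IntegerVector p = positions[c];
    want[c].assign(ref_lens[c], -1);
    for (int i = 0; i < p.size(); ++i) want[c][p[i]] = i;
  }
  std::vector<int> o_chrom, o_pos, o_qual, o_mapq, o_end, o_row;
  std::vector<char> o_base, o_strand;
  int n = chrom_idx.size();
  for (int i = 0; i < n; ++i) {
    if (chrom_idx[i] == NA_INTEGER) continue;
    if (mapq[i] < min_mapq || (drop_mapq0 && mapq[i] == 0)) continue;
    const char* s = CHAR(STRING_ELT(read_seqs, read_row[i] - 1));
    const char* q = CHAR(STRING_ELT(read_quals, read_row[i] - 1));
    int L = (int)strlen(s);
    bool rv = rev[i] == 1;
    int c = chrom_idx[i] - 1, p = start0[i];
    for (int j = 0; j < L; ++j) {
      if (want[c][p + j] < 0) continue;
      int jr = rv ? (L - 1 - j) : j;  // index in sequencing orientation
      uint8_t b = base_code(s[jr]);
      if (rv && b <= 3) b = 3 - b;
      if (b > 3) continue;
      o_chrom.push_back(c + 1);
      o_pos.push_back(p + j + 1);  // 1-based
      o_base.push_back("ACGT"[b]);
      o_qual.push_back((int)q[jr] - 33);
      o_mapq.push_back(mapq[i]);
      o_strand.push_back(rv ? '-' : '+');
      o_end.push_back(std::min(jr, L - 1 - jr));
      o_row.push_back(read_row[i]);
    }
  }
  int m = (int)o_chrom.size();
  CharacterVector base_out(m), strand_out(m);
  for (int i = 0; i < m; ++i) {
    base_out[i] = std::string(1, o_base[i]);
    strand_out[i] = std::string(1, o_strand[i]);
  }
  return DataFrame::create(
    _["chrom_idx"] = wrap(o_chrom), _["pos"] = wrap(o_pos),
    _["base"] = base_out, _["qual"] = wrap(o_qual),
    _["mapq"] = wrap(o_mapq), _["strand"] = strand_out,
    _["enddist"] = wrap(o_end), _["read_row"] = wrap(o_row),
    _["stringsAsFactors"] = false);
}
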