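#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit nucleotide codes; 4 = N/other (never matches, invalidates windows).
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

struct Candidate {
  int64_t pos;   // global start
  int strand;    // 0 = forward, 1 = reverse
  bool operator<(const Candidate& o) const {
    if (pos != o.pos) return pos < o.pos;
    return strand < o.strand;
  }
  bool operator==(const Candidate& o) const {
    return pos == o.pos && strand == o.strand;
  }
};

// Unique-placement short-read mapper.
//
// A read is reported only when it has a single strictly best placement
// (fewest mismatches, both strands) over fully unmasked sequence; ties at the
// best mismatch count discard the read. Masked bases must be 'N' in `contigs`;
// a placement window containing any N is invalid.
//
// Uses a pigeonhole seed index (max_mm + 1 non-overlapping exact seeds) when
// reads are long enough, which enumerates every placement with <= max_mm
// mismatches; falls back to a full sliding-window scan otherwise.
//
// [[Rcpp::export(name = ".map_reads_cpp")]]
List map_reads_cpp(CharacterVector reads, CharacterVector contigs, int max_mm) {
  const int n_contig = contigs.size();
  const int n_reads = reads.size();

  // concatenate genome
  std::vector<int64_t> offset(n_contig + 1, 0);
  for (int i = 0; i < n_contig; ++i)
    offset[i + 1] = offset[i] + LENGTH(STRING_ELT(contigs, i));
  const int64_t G = offset[n_contig];
  std::vector<uint8_t> g(G);
  for (int i = 0; i < n_contig; ++i) {
    const char* s = CHAR(STRING_ELT(contigs, i));
    int64_t len = offset[i + 1] - offset[i];
    for (int64_t j = 0; j < len; ++j) g[offset[i] + j] = (uint8_t)base_code(s[j]);
  }

  // run[p]: length of the maximal N-free stretch starting at p, truncated at
  // the end of p's contig. A window of width w starting at p is valid iff
  // run[p] >= w.
  std::vector<int32_t> run(G, 0);
  for (int i = 0; i < n_contig; ++i) {
    for (int64_t p = offset[i + 1] - 1; p >= offset[i]; --p) {
      if (g[p] == 4) run[p] = 0;
      else run[p] = 1 + (p + 1 < offset[i + 1] ? run[p + 1] : 0);
    }
  }

  if (n_reads == 0) {
    return List::create(_["read"] = IntegerVector(0), _["contig"] = IntegerVector(0),
                        _["start"] = IntegerVector(0), _["strand"] = IntegerVector(0),
                        _["mismatches"] = IntegerVector(0),
                        _["n_placed"] = 0, _["n_ambiguous"] = 0, _["n_unplaced"] = 0);
  }

  const int r = LENGTH(STRING_ELT(reads, 0));
  for (int i = 0; i < n_reads; ++i)
    if (LENGTH(STRING_ELT(reads, i)) != r)
      stop("all reads must have the same length");

  const int n_seeds = max_mm + 1;
  int s = r / n_seeds;
  if (s > 12) s = 12;
  const bool use_seeds = (s >= 8) && ((int64_t)s * n_seeds <= r);

  // seed index (counting sort of seed keys over valid windows)
  std::vector<uint32_t> bucket_start;
  std::vector<int64_t> bucket_pos;
  uint32_t n_keys = 0;
  if (use_seeds) {
    n_keys = 1u << (2 * s);
    std::vector<uint32_t> counts(n_keys + 1, 0);
    // first pass: count
    for (int64_t p = 0; p + s <= G; ++p) {
      if (run[p] < s) continue;
      uint32_t key = 0;
      for (int j = 0; j < s; ++j) key = (key << 2) | g[p + j];
      counts[key + 1]++;
    }
    bucket_start.resize(n_keys + 1, 0);
    for (uint32_t k = 0; k < n_keys; ++k) bucket_start[k + 1] = bucket_start[k] + counts[k + 1];
    bucket_pos.resize(bucket_start[n_keys]);
    std::vector<uint32_t> fill(bucket_start.begin(), bucket_start.end() - 1);
    for (int64_t p = 0; p + s <= G; ++p) {
      if (run[p] < s) continue;
      uint32_t key = 0;
      for (int j = 0; j < s; ++j) key = (key << 2) | g[p + j];
      bucket_pos[fill[key]++] = p;
    }
  }

  std::vector<int> out_read, out_contig, out_start, out_strand, out_mm;
  int n_placed = 0, n_ambiguous = 0, n_unplaced = 0;

  std::vector<uint8_t> rc_f(r), rc_r(r);
  std::vector<Candidate> cand;

  for (int i = 0; i < n_reads; ++i) {
    const char* rs = CHAR(STRING_ELT(reads, i));
    for (int j = 0; j < r; ++j) rc_f[j] = (uint8_t)base_code(rs[j]);
    for (int j = 0; j < r; ++j) {
      uint8_t c = rc_f[r - 1 - j];
      rc_r[j] = (c <= 3) ? (uint8_t)(3 - c) : (uint8_t)4;
    }

    cand.clear();
    if (use_seeds) {
      for (int strand = 0; strand < 2; ++strand) {
        const std::vector<uint8_t>& rc = (strand == 0) ? rc_f : rc_r;
        for (int sd = 0; sd < n_seeds; ++sd) {
          const int off = sd * s;
          uint32_t key = 0;
          bool ok = true;
          for (int j = 0; j < s; ++j) {
            if (rc[off + j] > 3) { ok = false; break; }
            key = (key << 2) | rc[off + j];
          }
          if (!ok) continue;
          for (uint32_t b = bucket_start[key]; b < bucket_start[key + 1]; ++b) {
            int64_t start = bucket_pos[b] - off;
            if (start < 0) continue;
            if (run[start] < r) continue;  // N-free and within one contig
            cand.push_back({start, strand});
          }
        }
      }
    } else {
      for (int64_t p = 0; p + r <= G; ++p) {
        if (run[p] < r) continue;
        cand.push_back({p, 0});
        cand.push_back({p, 1});
      }
    }

    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

    // per candidate position (collapsing strands), minimal mismatch count
    int best = max_mm + 1;
    int64_t best_pos = -1;
    int best_strand = 0, n_best = 0;
    int64_t cur_pos = -1;
    int cur_mm = max_mm + 1, cur_strand = 0;
    size_t nc = cand.size();
    for (size_t ci = 0; ci <= nc; ++ci) {
      if (ci == nc || cand[ci].pos != cur_pos) {
        if (cur_pos >= 0 && cur_mm <= max_mm) {
          if (cur_mm < best) { best = cur_mm; best_pos = cur_pos; best_strand = cur_strand; n_best = 1; }
          else if (cur_mm == best) { n_best++; }
        }
        if (ci == nc) break;
        cur_pos = cand[ci].pos;
        cur_mm = max_mm + 1;
        cur_strand = 0;
      }
      const std::vector<uint8_t>& rc = (cand[ci].strand == 0) ? rc_f : rc_r;
      int mm = 0;
      const int64_t p = cand[ci].pos;
      for (int j = 0; j < r; ++j) {
        if (g[p + j] != rc[j]) { if (++mm > max_mm) break; }
      }
      if (mm < cur_mm) { cur_mm = mm; cur_strand = cand[ci].strand; }
    }

    if (n_best == 1) {
      // locate contig by binary search
      int lo = 0, hi = n_contig;
      while (hi - lo > 1) {
        int mid = (lo + hi) / 2;
        if (offset[mid] <= best_pos) lo = mid; else hi = mid;
      }
      out_read.push_back(i + 1);
      out_contig.push_back(lo + 1);
      out_start.push_back((int)(best_pos - offset[lo]));
      out_strand.push_back(best_strand);
      out_mm.push_back(best);
      n_placed++;
    } else if (n_best > 1) {
      n_ambiguous++;
    } else {
      n_unplaced++;
    }
  }

  return List::create(
    _["read"] = wrap(out_read), _["contig"] = wrap(out_contig),
    _["start"] = wrap(out_start), _["strand"] = wrap(out_strand),
    _["mismatches"] = wrap(out_mm),
    _["n_placed"] = n_placed, _["n_ambiguous"] = n_ambiguous,
    _["n_unplaced"] = n_unplaced);
}
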