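#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static inline char complement(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

// encode an ACGT string to 2 bits/base; returns false on non-ACGT
static bool encode_string(const std::string& s, uint64_t& out) {
  uint64_t code = 0;
  for (char c : s) {
    int b = base_code(c);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  out = code;
  return true;
}

// Scan reads against a set of shards.
//
// Each shard is given by its integer prefix code, its suffix strings and,
// parallel to those, the 1-based species-id sets stored under each suffix.
// A shard answers (a) exact windows whose prefix equals its own and (b), in
// permuted mode, any 1-substitution variant whose (possibly mutated) prefix
// equals its own — so variants whose substitution falls inside the prefix
// are answered by the shard owning the new prefix, and a map step over all
// shards is exactly equivalent to a global 1-edit search.
//
// Matches are reported one row per (read, offset, strand, species); a
// species hit by both the exact window and a variant is reported once with
// permuted = false.
// [[Rcpp::export]]
List cpp_search(CharacterVector read_seqs, int k, int prefix_len,
                IntegerVector shard_codes, List shard_suffixes,
                List shard_species, bool permuted) {
  if (k < 2 || k > 32) stop("k must be in [2, 32]");
  if (prefix_len <= 0 || prefix_len >= k) stop("invalid prefix_len");
  const int suffix_bits = 2 * (k - prefix_len);
  const uint64_t kmer_mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const uint64_t suffix_mask = (1ULL << suffix_bits) - 1;
  const int n_shards_total = 1 << (2 * prefix_len);

  // position of each shard code in the payload (-1 = not active here)
  std::vector<int> shard_pos(n_shards_total, -1);
  const int n_payload = shard_codes.size();
  std::vector<std::unordered_map<uint64_t, int> > tables(n_payload);
  for (int s = 0; s < n_payload; ++s) {
    int code = shard_codes[s];
    if (code < 0 || code >= n_shards_total) stop("shard code out of range");
    shard_pos[code] = s;
    CharacterVector sufs = shard_suffixes[s];
    tables[s].reserve(sufs.size() * 2 + 1);
    for (int j = 0; j < sufs.size(); ++j) {
      uint64_t sc;
      std::string suf = as<std::string>(sufs[j]);
      if ((int)suf.size() != k - prefix_len)
        stop("suffix length mismatch in shard payload");
      if (!encode_string(suf, sc)) stop("non-ACGT suffix in shard payload");
      tables[s][sc] = j;
    }
  }

  std::vector<int> out_read, out_offset, out_strand, out_species;
  std::vector<int> out_permuted;
  const int n_reads = read_seqs.size();
  IntegerVector windows_scanned(n_reads, 0);

  std::vector<int> exact_sp, perm_sp;
  for (int r = 0; r < n_reads; ++r) {
    std::string fwd = as<std::string>(read_seqs[r]);
    for (int strand = 0; strand < 2; ++strand) {
      std::string seq;
      if (strand == 0) {
        seq = fwd;
      } else {
        seq.resize(fwd.size());
        for (size_t i = 0; i < fwd.size(); ++i)
          seq[i] = complement(fwd[fwd.size() - 1 - i]);
      }
      const int L = (int)seq.size();
      uint64_t code = 0;
      int valid = 0;
      for (int i = 0; i < L; ++i) {
        int b = base_code(seq[i]);
        if (b < 0) {
          valid = 0;
          code = 0;
          continue;
        }
        code = ((code << 2) | (uint64_t)b) & kmer_mask;
        if (++valid < k) continue;
        // window ending at i, starting at offset
        const int offset = i - k + 1;
        windows_scanned[r] += 1;

        exact_sp.clear();
        perm_sp.clear();

        const int pc = (int)(code >> suffix_bits);
        int pos = shard_pos[pc];
        if (pos >= 0) {
          std::unordered_map<uint64_t, int>::const_iterator it =
            tables[pos].find(code & suffix_mask);
          if (it != tables[pos].end()) {
            List sets = shard_species[pos];
            IntegerVector sp = sets[it->second];
            for (int v = 0; v < sp.size(); ++v) exact_sp.push_back(sp[v]);
          }
        }

        if (permuted) {
          for (int j = 0; j < k; ++j) {
            const int shift = 2 * (k - 1 - j);
            const uint64_t orig = (code >> shift) & 3ULL;
            const uint64_t cleared = code & ~(3ULL << shift);
            for (uint64_t d = 1; d <= 3; ++d) {
              const uint64_t nb = (orig + d) & 3ULL;
              const uint64_t vcode = cleared | (nb << shift);
              const int vpc = (int)(vcode >> suffix_bits);
              const int vpos = shard_pos[vpc];
              if (vpos < 0) continue;
              std::unordered_map<uint64_t, int>::const_iterator it =
                tables[vpos].find(vcode & suffix_mask);
              if (it == tables[vpos].end()) continue;
              List sets = shard_species[vpos];
              IntegerVector sp = sets[it->second];
              for (int v = 0; v < sp.size(); ++v) perm_sp.push_back(sp[v]);
            }
          }
        }

        for (size_t v = 0; v < exact_sp.size(); ++v) {
          out_read.push_back(r + 1);
          out_offset.push_back(offset);
          out_strand.push_back(strand);
          out_permuted.push_back(0);
          out_species.push_back(exact_sp[v]);
        }
        if (!perm_sp.empty()) {
          std::sort(perm_sp.begin(), perm_sp.end());
          perm_sp.erase(std::unique(perm_sp.begin(), perm_sp.end()),
                        perm_sp.end());
          for (size_t v = 0; v < perm_sp.size(); ++v) {
            if (std::find(exact_sp.begin(), exact_sp.end(), perm_sp[v]) !=
                exact_sp.end()) continue;  // exact evidence wins
            out_read.push_back(r + 1);
            out_offset.push_back(offset);
            out_strand.push_back(strand);
            out_permuted.push_back(1);
            out_species.push_back(perm_sp[v]);
          }
        }
      }
    }
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["read"] = wrap(out_read), _["offset"] = wrap(out_offset),
    _["strand"] = wrap(out_strand),
    _["permuted"] = LogicalVector(out_permuted.begin(), out_permuted.end()),
    _["species"] = wrap(out_species),
    _["windows_scanned"] = windows_scanned);
}
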