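#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Ungapped end-to-end placement of short reads on reference sequences:
// every offset on both strands is scanned, substitutions only, and hits
// are reported up to max_mm mismatches. Best-stratum filtering (keep only
// hits at the minimum observed mismatch count per read) happens here so
// the R side never sees suboptimal placements.

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// [[Rcpp::export(name = ".align_scan_cpp")]]
List align_scan_cpp(CharacterVector reads, CharacterVector refs, int max_mm) {
  int n_reads = reads.size(), n_refs = refs.size();
  std::vector<std::string> ref_str(n_refs);
  for (int j = 0; j < n_refs; ++j) ref_str[j] = as<std::string>(refs[j]);

  std::vector<int> out_read, out_ref, out_start, out_mm;
  std::vector<int> out_sense;

  std::vector<int> hit_ref, hit_start, hit_mm, hit_sense;

  for (int i = 0; i < n_reads; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int L = (int) rd.size();
    std::string rc(L, 'N');
    for (int k = 0; k < L; ++k) rc[L - 1 - k] = comp(rd[k]);

    hit_ref.clear(); hit_start.clear(); hit_mm.clear(); hit_sense.clear();
    int best = max_mm + 1;

    for (int j = 0; j < n_refs; ++j) {
      const std::string& rf = ref_str[j];
      int n_off = (int) rf.size() - L;
      if (n_off < 0) continue;
      for (int strand = 0; strand < 2; ++strand) {
        const std::string& q = strand == 0 ? rd : rc;
        const char* qc = q.c_str();
        const char* fc = rf.c_str();
        for (int s = 0; s <= n_off; ++s) {
          int mm = 0;
          const char* rp = fc + s;
          for (int k = 0; k < L; ++k) {
            if (qc[k] != rp[k] && ++mm > max_mm) break;
          }
          if (mm <= max_mm) {
            hit_ref.push_back(j + 1);
            hit_start.push_back(s);
            hit_mm.push_back(mm);
            hit_sense.push_back(strand == 0 ? 1 : 0);
            if (mm < best) best = mm;
          }
        }
      }
    }
    for (size_t h = 0; h < hit_mm.size(); ++h) {
      if (hit_mm[h] == best) {
        out_read.push_back(i + 1);
        out_ref.push_back(hit_ref[h]);
        out_start.push_back(hit_start[h]);
        out_mm.push_back(hit_mm[h]);
        out_sense.push_back(hit_sense[h]);
      }
    }
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["read"] = wrap(out_read),
    _["ref"] = wrap(out_ref),
    _["start"] = wrap(out_start),
    _["mismatches"] = wrap(out_mm),
    _["sense"] = wrap(out_sense));
}

// Depletion scan: for each read report the index (1-based) of the first
// reference, in input order, containing an end-to-end hit on either strand
// with <= max_mm substitutions, or 0 if none. References are expected in
// priority order (e.g. rRNA before miRNA hairpins).

// [[Rcpp::export(name = ".deplete_scan_cpp")]]
IntegerVector deplete_scan_cpp(CharacterVector reads, CharacterVector refs, int max_mm) {
  int n_reads = reads.size(), n_refs = refs.size();
  std::vector<std::string> ref_str(n_refs);
  for (int j = 0; j < n_refs; ++j) ref_str[j] = as<std::string>(refs[j]);
  IntegerVector out(n_reads, 0);

  for (int i = 0; i < n_reads; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int L = (int) rd.size();
    std::string rc(L, 'N');
    for (int k = 0; k < L; ++k) rc[L - 1 - k] = comp(rd[k]);
    int found = 0;
    for (int j = 0; j < n_refs && !found; ++j) {
      const std::string& rf = ref_str[j];
      int n_off = (int) rf.size() - L;
      if (n_off < 0) continue;
      for (int strand = 0; strand < 2 && !found; ++strand) {
        const std::string& q = strand == 0 ? rd : rc;
        const char* qc = q.c_str();
        const char* fc = rf.c_str();
        for (int s = 0; s <= n_off; ++s) {
          int mm = 0;
          const char* rp = fc + s;
          for (int k = 0; k < L; ++k) {
            if (qc[k] != rp[k] && ++mm > max_mm) break;
          }
          if (mm <= max_mm) { found = j + 1; break; }
        }
      }
    }
    out[i] = found;
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
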