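#include <Rcpp.h>
using namespace Rcpp;

// Quality-aware ungapped overlap merge of read pairs.
//
// r2 must already be reverse-complemented (and its quality string reversed)
// so both mates are on the read-1 strand. Candidate overlaps o in
// [min_overlap, min(L1, L2)] are scored with +1 (match) / -1 (mismatch) per
// position, each weighted by the mean of the two Phred qualities; an N never
// counts as a match. The best-scoring overlap wins; two candidates tying on
// the top score make the junction ambiguous and the pair fails. A winning
// overlap still fails if its mismatch fraction exceeds max_mismatch_frac.
//
// Consensus within the overlap: equal bases keep the base with the max
// quality; N against a base yields the base with its own quality; otherwise
// the higher-quality base wins (quality tie -> read-1 base, quality = max).

// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector r1, CharacterVector q1,
                     CharacterVector r2rc, CharacterVector q2r,
                     int min_overlap, double max_mismatch_frac) {
  int n = r1.size();
  CharacterVector mseq(n), mqual(n), status(n);
  IntegerVector olen(n), omis(n);

  for (int k = 0; k < n; ++k) {
    std::string a = as<std::string>(r1[k]);
    std::string qa = as<std::string>(q1[k]);
    std::string b = as<std::string>(r2rc[k]);
    std::string qb = as<std::string>(q2r[k]);
    int L1 = a.size(), L2 = b.size();
    int omax = std::min(L1, L2);

    double best = R_NegInf;
    int best_o = -1, ties = 0;
    for (int o = min_overlap; o <= omax; ++o) {
      double score = 0.0;
      for (int i = 0; i < o; ++i) {
        char ca = a[L1 - o + i], cb = b[i];
        double w = ((qa[L1 - o + i] - 33) + (qb[i] - 33)) / 2.0;
        bool match = (ca == cb) && ca != 'N' && cb != 'N';
        score += match ? w : -w;
      }
      if (score > best) {
        best = score; best_o = o; ties = 0;
      } else if (score == best) {
        ++ties;
      }
    }

    if (best_o < 0) {
      status[k] = "no_overlap";
      mseq[k] = ""; mqual[k] = ""; olen[k] = 0; omis[k] = NA_INTEGER;
      continue;
    }
    if (ties > 0) {
      status[k] = "ambiguous";
      mseq[k] = ""; mqual[k] = ""; olen[k] = best_o; omis[k] = NA_INTEGER;
      continue;
    }

    int o = best_o, mism = 0;
    std::string cons(o, 'N'), consq(o, '!');
    for (int i = 0; i < o; ++i) {
      char ca = a[L1 - o + i], cb = b[i];
      char pa = qa[L1 - o + i], pb = qb[i];
      bool match = (ca == cb) && ca != 'N' && cb != 'N';
      if (!match) ++mism;
      if (ca == cb) {
        cons[i] = ca; consq[i] = std::max(pa, pb);
      } else if (ca == 'N') {
        cons[i] = cb; consq[i] = pb;
      } else if (cb == 'N') {
        cons[i] = ca; consq[i] = pa;
      } else if (pa >= pb) {
        cons[i] = ca; consq[i] = (pa == pb) ? std::max(pa, pb) : pa;
      } else {
        cons[i] = cb; consq[i] = pb;
      }
    }
    if ((double)mism / o > max_mismatch_frac) {
      status[k] = "mismatch";
      mseq[k] = ""; mqual[k] = ""; olen[k] = o; omis[k] = mism;
      continue;
    }
    status[k] = "ok";
    mseq[k] = a.substr(0, L1 - o) + cons + b.substr(o);
    mqual[k] = qa.substr(0, L1 - o) + consq + qb.substr(o);
    olen[k] = o;
    omis[k] = mism;
  }

  return List::create(_["sequence"] = mseq, _["quality"] = mqual,
                      _["status"] = status, _["overlap_length"] = olen,
                      _["overlap_mismatches"] = omis);
}
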