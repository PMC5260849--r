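#include <Rcpp.h>
using namespace Rcpp;

// Per-pixel, per-bin clear-sky level: the integer count value whose
// surrounding window of `window_w` consecutive count values contains the
// most samples (the steepest section of the sample ECDF), ties broken by
// the smallest value. Samples are 10-bit digital counts (0..1023); NA
// samples are skipped. Bins with fewer than `min_samples` valid samples are
// returned as NA.
//
// counts:      npix x nt integer matrix (column = slot), NA = missing
// bin_of_slot: length-nt 1-based bin index per slot
// n_bins:      number of bins
// [[Rcpp::export]]
List clim_steepest_cpp(IntegerMatrix counts, IntegerVector bin_of_slot,
                       int n_bins, int window_w, int min_samples) {
  const int npix = counts.nrow();
  const int nt = counts.ncol();
  if (bin_of_slot.size() != nt) stop("bin index length mismatch");
  if (window_w < 1) stop("window_w must be >= 1");

  // group slots by bin
  std::vector< std::vector<int> > slots(n_bins);
  for (int t = 0; t < nt; ++t) {
    int b = bin_of_slot[t];
    if (b < 1 || b > n_bins) stop("bin index out of range");
    slots[b - 1].push_back(t);
  }

  IntegerMatrix values(npix, n_bins);
  IntegerMatrix nsamp(npix, n_bins);
  std::vector<int> hist(1024, 0);

  for (int b = 0; b < n_bins; ++b) {
    const std::vector<int>& sl = slots[b];
    for (int p = 0; p < npix; ++p) {
      int n = 0, minv = 1024, maxv = -1;
      for (size_t k = 0; k < sl.size(); ++k) {
        int v = counts(p, sl[k]);
        if (v == NA_INTEGER) continue;
        if (v < 0 || v > 1023) stop("counts must be 10-bit (0..1023)");
        ++hist[v];
        ++n;
        if (v < minv) minv = v;
        if (v > maxv) maxv = v;
      }
      nsamp(p, b) = n;
      if (n < min_samples) {
        values(p, b) = NA_INTEGER;
      } else {
        // window of window_w consecutive integers ending at v + floor(w/2)
        int best_v = minv, best_score = -1;
        for (int v = minv; v <= maxv; ++v) {
          int hi = v + window_w / 2;
          int lo = hi - window_w + 1;
          if (lo < minv) lo = minv;
          if (hi > maxv) hi = maxv;
          int score = 0;
          for (int u = lo; u <= hi; ++u) score += hist[u];
          if (score > best_score) { best_score = score; best_v = v; }
        }
        values(p, b) = best_v;
      }
      if (maxv >= 0)
        for (int u = minv; u <= maxv; ++u) hist[u] = 0;
    }
  }
  return List::create(_["values"] = values, _["n"] = nsamp);
}
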