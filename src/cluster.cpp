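#include <Rcpp.h>
using namespace Rcpp;

// Greedy first-fit clustering of multi-site (pseudo-)genotypes with missing data.
//
// Rows are individuals, columns are SNPs of one analysis window; NA encodes a
// missing call.  An individual joins the first existing open cluster whose
// founding row matches it at every position where both are non-missing.
// Individuals whose missing fraction exceeds `m` (or that are entirely missing)
// never merge and never found a joinable cluster: they stay singletons.
//
// Returns cluster sizes in creation order, the 1-based assignment of each row,
// and a flag marking clusters created as forced singletons.
// [[Rcpp::export]]
List cluster_window_cpp(IntegerMatrix calls, double m) {
  const int n = calls.nrow();
  const int S = calls.ncol();
  if (S == 0) stop("analysis window has zero SNPs");
  if (n == 0) stop("analysis window has zero individuals");

  std::vector<int> rep_row;           // founding row of each cluster
  std::vector<int> csize;
  std::vector<bool> open;             // joinable?
  IntegerVector assign(n);
  LogicalVector forced(n);            // per-row: treated as forced singleton

  for (int i = 0; i < n; ++i) {
    int miss = 0;
    for (int j = 0; j < S; ++j)
      if (calls(i, j) == NA_INTEGER) ++miss;
    const double mf = (double)miss / (double)S;
    const bool singleton = (mf > m) || (miss == S);
    forced[i] = singleton;

    int found = -1;
    if (!singleton) {
      for (size_t c = 0; c < rep_row.size(); ++c) {
        if (!open[c]) continue;
        const int r = rep_row[c];
        bool match = true;
        for (int j = 0; j < S; ++j) {
          const int a = calls(i, j), b = calls(r, j);
          if (a == NA_INTEGER || b == NA_INTEGER) continue;
          if (a != b) { match = false; break; }
        }
        if (match) { found = (int)c; break; }
      }
    }
    if (found >= 0) {
      csize[found] += 1;
      assign[i] = found + 1;
    } else {
      rep_row.push_back(i);
      csize.push_back(1);
      open.push_back(!singleton);
      assign[i] = (int)rep_row.size();
    }
  }

  return List::create(_["sizes"] = wrap(csize),
                      _["assignment"] = assign,
                      _["forced_singleton"] = forced);
}
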