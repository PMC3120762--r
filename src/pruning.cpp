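#include <Rcpp.h>
#include "prune.h"
using namespace Rcpp;

// R-facing wrapper of the pruning kernel in prune.h. Nodes are 1..nnode
// with tips 1..ntip; parent[v]==0 marks the root. The substitution model is
// passed as the spectral decomposition of its (reversible, normalised) rate
// matrix: P(t) = right diag(exp(vals t)) left.

// [[Rcpp::export(name = ".prunedLoglikCpp")]]
double prunedLoglikCpp(IntegerVector parent, NumericVector time,
                       IntegerMatrix patterns, NumericVector weights,
                       NumericMatrix right, NumericVector vals,
                       NumericMatrix left, NumericVector freqs,
                       NumericVector rates, NumericVector probs,
                       double rateScale) {
  static PruneScratch sc;
  return pruneLoglik(parent.begin(), time.begin(), parent.size(),
                     patterns.begin(), patterns.nrow(), patterns.ncol(),
                     weights.begin(), right.begin(), vals.begin(),
                     left.begin(), freqs.begin(), rates.begin(),
                     probs.begin(), rates.size(), rateScale, sc);
}
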