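#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Standard persistence column reduction over Z2.
//
// `columns` is the boundary matrix in filtration order: columns[j] holds the
// sorted 1-based filtration indices of the facets of simplex j+1 (empty for
// vertices). Columns are reduced left to right: while a column shares its
// lowest entry with an earlier reduced column, add (symmetric difference,
// i.e. Z2 addition) that column into it. The return value is low(j): 0 if
// the column reduced to zero (simplex j+1 is positive, it creates a class),
// otherwise the 1-based index of the simplex whose class simplex j+1 kills.
// [[Rcpp::export]]
IntegerVector reduce_boundary(const List& columns) {
  const int n = columns.size();
  std::vector<std::vector<int> > cols(n);
  std::vector<int> pivot_owner(n + 1, -1); // low value -> column index
  IntegerVector lows(n);

  std::vector<int> tmp;
  for (int j = 0; j < n; ++j) {
    IntegerVector cj = columns[j];
    cols[j].assign(cj.begin(), cj.end());
    std::sort(cols[j].begin(), cols[j].end());
    while (!cols[j].empty()) {
      int low = cols[j].back();
      int owner = pivot_owner[low];
      if (owner < 0) {
        pivot_owner[low] = j;
        break;
      }
      tmp.clear();
      std::set_symmetric_difference(cols[j].begin(), cols[j].end(),
                                    cols[owner].begin(), cols[owner].end(),
                                    std::back_inserter(tmp));
      cols[j].swap(tmp);
    }
    lows[j] = cols[j].empty() ? 0 : cols[j].back();
  }
  return lows;
}
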