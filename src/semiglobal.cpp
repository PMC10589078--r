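#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Semi-global (free end gap) pairwise alignment.
//
// Gaps at either terminus of either sequence cost zero; internal gaps and
// mismatches are penalised. Among equal-score alignments the optimum is made
// unique (up to reported statistics) by a lexicographic objective:
//   score desc, matched columns desc, alignment columns asc,
//   query-consuming columns desc, target-consuming columns desc.
// All five quantities are additive along a DP path, so the lexicographic
// optimum is itself computable by DP. Identity and coverage are then
// well-defined: identity = matches / columns (terminal-gap columns are
// outside the path and never counted), coverage = query-consuming columns /
// query length.

struct Cell {
  int score, matches, cols, qcols, tcols;
};

static inline bool better(const Cell &a, const Cell &b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.matches != b.matches) return a.matches > b.matches;
  if (a.cols != b.cols) return a.cols < b.cols;
  if (a.qcols != b.qcols) return a.qcols > b.qcols;
  return a.tcols > b.tcols;
}

// With query_global = true the query must align end to end (usearch_global
// / blastn semantics): leading and trailing query positions can no longer
// sit in free terminal gaps, only the target's overhangs are free. Used for
// the relaxed reference-cleaning search, where identity ranking is only
// meaningful over alignments spanning the whole barcode.

// [[Rcpp::export]]
List semiglobal_align_cpp(std::string q, std::string t,
                          int match, int mismatch, int gap,
                          bool query_global = false) {
  const int n = (int)q.size(), m = (int)t.size();
  if (n < 1 || m < 1) stop("sequences must be non-empty");

  std::vector<Cell> prev(m + 1), cur(m + 1);
  // last-column cells (j = m) for every row, needed for the endpoint scan
  std::vector<Cell> lastcol(n + 1);

  for (int j = 0; j <= m; ++j) prev[j] = Cell{0, 0, 0, 0, 0};
  lastcol[0] = prev[m];

  for (int i = 1; i <= n; ++i) {
    if (query_global) {
      // consuming query bases against nothing is an internal gap
      cur[0] = Cell{prev[0].score + gap, 0, prev[0].cols + 1,
                    prev[0].qcols + 1, 0};
    } else {
      cur[0] = Cell{0, 0, 0, 0, 0};  // free leading gap in target
    }
    const char qc = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char tc = t[j - 1];
      const bool is_match = (qc == tc) && qc != 'N';
      Cell diag = prev[j - 1];
      diag.score += is_match ? match : mismatch;
      diag.matches += is_match ? 1 : 0;
      diag.cols += 1; diag.qcols += 1; diag.tcols += 1;
      Cell up = prev[j];          // consume query base, gap in target
      up.score += gap; up.cols += 1; up.qcols += 1;
      Cell left = cur[j - 1];     // consume target base, gap in query
      left.score += gap; left.cols += 1; left.tcols += 1;
      Cell best = diag;
      if (better(up, best)) best = up;
      if (better(left, best)) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
    lastcol[i] = prev[m];
  }
  // prev now holds row n

  // endpoint: best cell over the last row and last column; ties on the full
  // tuple are broken by larger i, then larger j (reported statistics are
  // identical for tied tuples, only the span can differ)
  Cell best = prev[0];
  int bi = n, bj = 0;
  for (int j = 0; j <= m; ++j) {
    if (better(prev[j], best)) { best = prev[j]; bi = n; bj = j; }
  }
  if (!query_global) {
    for (int i = n; i >= 0; --i) {
      if (better(lastcol[i], best)) { best = lastcol[i]; bi = i; bj = m; }
    }
  }

  const double identity = best.cols > 0 ? (double)best.matches / best.cols : 0.0;
  const double coverage = (double)best.qcols / n;

  return List::create(
    _["score"] = best.score,
    _["matches"] = best.matches,
    _["columns"] = best.cols,
    _["identity"] = identity,
    _["coverage"] = coverage,
    _["qstart"] = bi - best.qcols, _["qend"] = bi,
    _["tstart"] = bj - best.tcols, _["tend"] = bj);
}

// Batch variant: one query against many targets; returns a numeric matrix
// with one row per target (score, matches, columns, identity, coverage,
// qstart, qend, tstart, tend). Avoids per-pair R call overhead during
// read classification.
// [[Rcpp::export]]
NumericMatrix semiglobal_align_many_cpp(std::string q, CharacterVector targets,
                                        int match, int mismatch, int gap,
                                        bool query_global = false) {
  const int nt = targets.size();
  NumericMatrix out(nt, 9);
  for (int k = 0; k < nt; ++k) {
    std::string t = as<std::string>(targets[k]);
    List hit = semiglobal_align_cpp(q, t, match, mismatch, gap, query_global);
    out(k, 0) = as<int>(hit["score"]);
    out(k, 1) = as<int>(hit["matches"]);
    out(k, 2) = as<int>(hit["columns"]);
    out(k, 3) = as<double>(hit["identity"]);
    out(k, 4) = as<double>(hit["coverage"]);
    out(k, 5) = as<int>(hit["qstart"]);
    out(k, 6) = as<int>(hit["qend"]);
    out(k, 7) = as<int>(hit["tstart"]);
    out(k, 8) = as<int>(hit["tend"]);
  }
  colnames(out) = CharacterVector::create("score", "matches", "columns",
    "identity", "coverage", "qstart", "qend", "tstart", "tend");
  return out;
}
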