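#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>

using namespace Rcpp;

// Gotoh affine-gap global alignment with full traceback.
//
// A gap of length L costs gap_open + L * gap_extend (both parameters are
// negative). Three states: M (match/mismatch), X (gap in the query: a
// reference base is skipped, i.e. a deletion in the molecule), Y (gap in the
// reference: an insertion in the molecule). Traceback tie-break prefers
// M over X over Y, and gap extension over gap opening, so the alignment is
// deterministic. Indel events are reported in 0-based reference coordinates
// and left-normalised (shifted to their leftmost equivalent placement), the
// convention the lesion classifier relies on when attributing events to cut
// junctions.

static const int NEG_INF = INT_MIN / 4;

// [[Rcpp::export]]
List align_global_cpp(std::string query, std::string ref,
                      int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int) query.size();
  const int m = (int) ref.size();
  if (n == 0 || m == 0)
    stop("align_global: sequences must be non-empty");
  if ((double) n * (double) m > 4e7)
    stop("align_global: sequences too long for full dynamic programming");

  const size_t W = (size_t) m + 1;
  std::vector<int> M((size_t)(n + 1) * W, NEG_INF);
  std::vector<int> X((size_t)(n + 1) * W, NEG_INF);
  std::vector<int> Y((size_t)(n + 1) * W, NEG_INF);

  M[0] = 0;
  for (int j = 1; j <= m; ++j) X[(size_t) j] = gap_open + j * gap_extend;
  for (int i = 1; i <= n; ++i) Y[(size_t) i * W] = gap_open + i * gap_extend;

  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t) i * W, prev = (size_t)(i - 1) * W;
    const char qc = query[(size_t) i - 1];
    for (int j = 1; j <= m; ++j) {
      const int s = (qc == ref[(size_t) j - 1]) ? match : mismatch;
      int d = M[prev + j - 1];
      if (X[prev + j - 1] > d) d = X[prev + j - 1];
      if (Y[prev + j - 1] > d) d = Y[prev + j - 1];
      M[row + j] = d + s;

      int xo = M[row + j - 1] > Y[row + j - 1] ? M[row + j - 1] : Y[row + j - 1];
      xo += gap_open + gap_extend;
      int xe = X[row + j - 1] + gap_extend;
      X[row + j] = xe > xo ? xe : xo;

      int yo = M[prev + j] > X[prev + j] ? M[prev + j] : X[prev + j];
      yo += gap_open + gap_extend;
      int ye = Y[prev + j] + gap_extend;
      Y[row + j] = ye > yo ? ye : yo;
    }
  }

  const size_t end = (size_t) n * W + m;
  int state; // 0 = M, 1 = X, 2 = Y; prefer M, then X, then Y
  int score;
  if (M[end] >= X[end] && M[end] >= Y[end]) { state = 0; score = M[end]; }
  else if (X[end] >= Y[end])                { state = 1; score = X[end]; }
  else                                      { state = 2; score = Y[end]; }

  // Traceback: emit steps in reverse, recording per-column operations.
  int i = n, j = m;
  int n_match = 0, n_mismatch = 0;
  // steps recorded reversed; op: 0 = diag, 1 = del (consume ref), 2 = ins
  std::vector<signed char> ops;
  ops.reserve((size_t) n + m);
  // The NEG_INF sentinels guarantee that exactly the true predecessors
  // satisfy the equality checks below; ties are resolved M > X > Y, with
  // gap extension preferred over a fresh gap opening.
  while (i > 0 || j > 0) {
    const size_t row = (size_t) i * W;
    const size_t prev = (i > 0) ? (size_t)(i - 1) * W : 0;
    if (state == 0) {
      const int s = (query[(size_t) i - 1] == ref[(size_t) j - 1]) ? match : mismatch;
      if (s == match) ++n_match; else ++n_mismatch;
      ops.push_back(0);
      const int need = M[row + j] - s;
      if (M[prev + j - 1] == need)      state = 0;
      else if (X[prev + j - 1] == need) state = 1;
      else                              state = 2;
      --i; --j;
    } else if (state == 1) {
      ops.push_back(1);
      const int need = X[row + j];
      if (X[row + j - 1] + gap_extend == need)               state = 1;
      else if (M[row + j - 1] + gap_open + gap_extend == need) state = 0;
      else                                                   state = 2;
      --j;
    } else {
      ops.push_back(2);
      const int need = Y[row + j];
      if (Y[prev + j] + gap_extend == need)                  state = 2;
      else if (M[prev + j] + gap_open + gap_extend == need)    state = 0;
      else                                                   state = 1;
      --i;
    }
  }

  // Walk forward, grouping runs of ops into events.
  std::vector<int> ev_pos, ev_len;
  std::vector<std::string> ev_type, ev_seq;
  int qi = 0, rj = 0;
  const int L = (int) ops.size();
  for (int k = L - 1; k >= 0; ) {
    const signed char op = ops[(size_t) k];
    if (op == 0) { ++qi; ++rj; --k; continue; }
    int len = 0;
    const int start_r = rj, start_q = qi;
    while (k >= 0 && ops[(size_t) k] == op) {
      ++len;
      if (op == 1) ++rj; else ++qi;
      --k;
    }
    if (op == 1) {
      // deletion of ref[start_r, start_r + len)
      int pos = start_r;
      while (pos > 0 && ref[(size_t) pos - 1] == ref[(size_t) pos + len - 1]) --pos;
      ev_type.push_back("deletion");
      ev_pos.push_back(pos);
      ev_len.push_back(len);
      ev_seq.push_back(ref.substr((size_t) pos, (size_t) len));
    } else {
      // insertion of query[start_q, start_q + len) before ref position start_r
      int pos = start_r;
      std::string ins = query.substr((size_t) start_q, (size_t) len);
      while (pos > 0 && ins[(size_t) len - 1] == ref[(size_t) pos - 1]) {
        ins = std::string(1, ref[(size_t) pos - 1]) + ins.substr(0, (size_t) len - 1);
        --pos;
      }
      ev_type.push_back("insertion");
      ev_pos.push_back(pos);
      ev_len.push_back(len);
      ev_seq.push_back(ins);
    }
  }

  return List::create(
    _["score"] = score,
    _["n_match"] = n_match,
    _["n_mismatch"] = n_mismatch,
    _["events"] = DataFrame::create(
      _["type"] = ev_type,
      _["ref_pos"] = ev_pos,
      _["length"] = ev_len,
      _["seq"] = ev_seq,
      _["stringsAsFactors"] = false)
  );
}
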