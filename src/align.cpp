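#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Banded local alignment (Gotoh affine gaps) of short reads against
// reference windows.  A gap of length k costs gap_open + k * gap_ext,
// matching the gapOpening/gapExtension convention of classic DP tools.
//
// Band: cell (i, j) (i = 1..m read base, j = 1..n window base) is reachable
// only when |j - i - diag| <= band.  With band >= max(m, n) the full matrix
// is computed and the result equals unbanded Smith-Waterman.

static const int NEG = -100000000;

struct Cell { int i, j; };

// When `extend` is true the best local alignment is extended gaplessly
// towards both read ends (as far as window bases remain), counting the
// extra mismatches and adjusting the score: a mismatch on the terminal
// base then appears as a mismatch instead of being soft-clipped.

// [[Rcpp::export(name = ".sw_banded_batch")]]
List sw_banded_batch(CharacterVector reads, CharacterVector windows,
                     IntegerVector diag, int band,
                     int match, int mismatch, int gap_open, int gap_ext,
                     bool extend = false) {
  const int np = reads.size();
  if (windows.size() != np || diag.size() != np)
    stop("reads, windows and diag must have equal length");

  IntegerVector score(np), rstart(np), rend(np), wstart(np), wend(np),
      nmm(np), gap_total(np), gap_max(np), ngap(np);

  std::vector<int> seg_pair, seg_len, seg_rs, seg_ws;
  std::vector<char> seg_op;
  std::vector<int> mm_pair, mm_rpos, mm_wpos;

  std::vector<int> H, E, F;

  for (int p = 0; p < np; ++p) {
    std::string r = as<std::string>(reads[p]);
    std::string w = as<std::string>(windows[p]);
    const int m = (int)r.size(), n = (int)w.size();
    const int d = diag[p];
    const size_t sz = (size_t)(m + 1) * (n + 1);
    if (H.size() < sz) { H.resize(sz); E.resize(sz); F.resize(sz); }
    // index helper
    #define IX(i, j) ((size_t)(i) * (n + 1) + (j))

    for (int j = 0; j <= n; ++j) { H[IX(0, j)] = 0; E[IX(0, j)] = NEG; F[IX(0, j)] = NEG; }
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= m; ++i) {
      int lo = i + d - band, hi = i + d + band;
      if (lo < 0) lo = 0;
      if (hi > n) hi = n;
      // initialise full row to NEG so out-of-band neighbours never win
      for (int j = 0; j <= n; ++j) { H[IX(i, j)] = NEG; E[IX(i, j)] = NEG; F[IX(i, j)] = NEG; }
      if (lo == 0) { H[IX(i, 0)] = 0; lo = 1; }
      for (int j = lo; j <= hi; ++j) {
        if (j < 1) continue;
        const char rb = r[i - 1], wb = w[j - 1];
        const int s = (rb == wb && rb != 'N' && wb != 'N') ? match : mismatch;
        int hd = H[IX(i - 1, j - 1)];
        int sub = (hd <= NEG / 2) ? NEG : hd + s;
        int e1 = (H[IX(i, j - 1)] <= NEG / 2) ? NEG : H[IX(i, j - 1)] - gap_open - gap_ext;
        int e2 = (E[IX(i, j - 1)] <= NEG / 2) ? NEG : E[IX(i, j - 1)] - gap_ext;
        E[IX(i, j)] = e1 > e2 ? e1 : e2;
        int f1 = (H[IX(i - 1, j)] <= NEG / 2) ? NEG : H[IX(i - 1, j)] - gap_open - gap_ext;
        int f2 = (F[IX(i - 1, j)] <= NEG / 2) ? NEG : F[IX(i - 1, j)] - gap_ext;
        F[IX(i, j)] = f1 > f2 ? f1 : f2;
        int h = 0;
        if (sub > h) h = sub;
        if (E[IX(i, j)] > h) h = E[IX(i, j)];
        if (F[IX(i, j)] > h) h = F[IX(i, j)];
        H[IX(i, j)] = h;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }

    score[p] = best;
    if (best <= 0) {
      rstart[p] = rend[p] = wstart[p] = wend[p] = 0;
      nmm[p] = gap_total[p] = gap_max[p] = ngap[p] = 0;
      continue;
    }

    // traceback: prefer diagonal, then window-gap (D), then read-gap (I)
    std::vector<char> ops;           // reversed order
    std::vector<Cell> mmcells;       // mismatch cells (i, j), 1-based
    int i = bi, j = bj;
    while (i > 0 && j > 0 && H[IX(i, j)] > 0) {
      const char rb = r[i - 1], wb = w[j - 1];
      const int s = (rb == wb && rb != 'N' && wb != 'N') ? match : mismatch;
      const int h = H[IX(i, j)];
      if (H[IX(i - 1, j - 1)] > NEG / 2 && h == H[IX(i - 1, j - 1)] + s) {
        ops.push_back('M');
        if (!(rb == wb && rb != 'N' && wb != 'N')) { Cell c = {i, j}; mmcells.push_back(c); }
        --i; --j;
      } else if (h == E[IX(i, j)]) {
        // gap consuming window bases only (deletion from the read)
        while (true) {
          ops.push_back('D');
          const bool ext = (E[IX(i, j)] == E[IX(i, j - 1)] - gap_ext) &&
                           E[IX(i, j - 1)] > NEG / 2;
          const bool open = (H[IX(i, j - 1)] > NEG / 2) &&
                            (E[IX(i, j)] == H[IX(i, j - 1)] - gap_open - gap_ext);
          --j;
          if (open) break;          // prefer closing the gap as early as possible
          if (!ext) break;
        }
      } else if (h == F[IX(i, j)]) {
        while (true) {
          ops.push_back('I');
          const bool ext = (F[IX(i, j)] == F[IX(i - 1, j)] - gap_ext) &&
                           F[IX(i - 1, j)] > NEG / 2;
          const bool open = (H[IX(i - 1, j)] > NEG / 2) &&
                            (F[IX(i, j)] == H[IX(i - 1, j)] - gap_open - gap_ext);
          --i;
          if (open) break;
          if (!ext) break;
        }
      } else {
        break;  // h == 0 handled by loop condition; defensive
      }
    }
    int sc = best;
    if (extend) {
      while (i > 0 && j > 0) {                    // towards the read start
        --i; --j;
        ops.push_back('M');
        const char rb = r[i], wb = w[j];
        if (rb == wb && rb != 'N' && wb != 'N') sc += match;
        else { sc += mismatch; Cell c = {i + 1, j + 1}; mmcells.push_back(c); }
      }
      int fwd = 0;
      while (bi < m && bj < n) {                  // towards the read end
        const char rb = r[bi], wb = w[bj];
        ++bi; ++bj; ++fwd;
        if (rb == wb && rb != 'N' && wb != 'N') sc += match;
        else { sc += mismatch; Cell c = {bi, bj}; mmcells.push_back(c); }
      }
      if (fwd > 0) ops.insert(ops.begin(), (size_t)fwd, 'M');
    }
    score[p] = sc;
    rstart[p] = i; rend[p] = bi;       // 0-based half-open on the read
    wstart[p] = j; wend[p] = bj;       // 0-based half-open on the window
    nmm[p] = (int)mmcells.size();

    // emit run-length segments in forward order with 0-based starts
    int gt = 0, gm = 0, ng = 0;
    int ri = i, wi = j;                // current 0-based positions
    int k = (int)ops.size() - 1;
    while (k >= 0) {
      const char op = ops[k];
      int len = 0, k2 = k;
      while (k2 >= 0 && ops[k2] == op) { ++len; --k2; }
      seg_pair.push_back(p); seg_op.push_back(op); seg_len.push_back(len);
      seg_rs.push_back(ri); seg_ws.push_back(wi);
      if (op == 'M') { ri += len; wi += len; }
      else if (op == 'I') { ri += len; gt += len; ++ng; if (len > gm) gm = len; }
      else { wi += len; gt += len; ++ng; if (len > gm) gm = len; }
      k = k2;
    }
    gap_total[p] = gt; gap_max[p] = gm; ngap[p] = ng;
    for (size_t q = 0; q < mmcells.size(); ++q) {
      mm_pair.push_back(p);
      mm_rpos.push_back(mmcells[q].i - 1);
      mm_wpos.push_back(mmcells[q].j - 1);
    }
    #undef IX
  }

  CharacterVector seg_op_r(seg_op.size());
  for (size_t q = 0; q < seg_op.size(); ++q) seg_op_r[q] = std::string(1, seg_op[q]);

  return List::create(
    _["score"] = score, _["read_start"] = rstart, _["read_end"] = rend,
    _["win_start"] = wstart, _["win_end"] = wend,
    _["n_mismatch"] = nmm, _["gap_total"] = gap_total,
    _["gap_max"] = gap_max, _["n_gap"] = ngap,
    _["seg_pair"] = wrap(seg_pair), _["seg_op"] = seg_op_r,
    _["seg_len"] = wrap(seg_len), _["seg_read_start"] = wrap(seg_rs),
    _["seg_win_start"] = wrap(seg_ws),
    _["mm_pair"] = wrap(mm_pair), _["mm_read_pos"] = wrap(mm_rpos),
    _["mm_win_pos"] = wrap(mm_wpos));
}
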