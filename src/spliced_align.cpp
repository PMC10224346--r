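#include <Rcpp.h>
#include <deque>

#include <cfloat>
using namespace Rcpp;

// Semi-global spliced alignment: the reference CDS must be consumed in full
// (gaps at its ends are penalized), the window is free at both ends.  A
// contig-only gap may be scored as an intron at a flat penalty when it
// begins with the donor dinucleotide GT (optionally GC at an extra penalty)
// and ends with the acceptor AG, with its length inside [min_intron,
// max_intron].  Ties are broken deterministically: diagonal > ref-gap >
// contig-gap > intron, and the earliest window end among equal maxima.

struct Donor { int d; double score; };

static inline void push_donor(std::deque<Donor> &dq, int d, double s) {
  while (!dq.empty() && dq.back().score < s) dq.pop_back();
  dq.push_back({d, s});
}

// [[Rcpp::export(name = ".splice_align_core")]]
List splice_align_core(std::string ref, std::string win,
                       double match, double mismatch, double gap,
                       double intron_pen, int min_intron, int max_intron,
                       bool gc_ag, double gc_pen) {
  const int m = (int)ref.size(), n = (int)win.size();
  if (m < 3 || n < 3) stop("sequences too short for spliced alignment");
  std::vector<double> prev(n + 1), cur(n + 1);
  // move codes: 0 start, 1 diag, 2 up (ref base vs gap), 3 left, 4 intron
  std::vector<unsigned char> move((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> intron_donor((size_t)(m + 1) * (n + 1), -1);

  for (int j = 0; j <= n; ++j) prev[j] = 0.0;

  for (int i = 1; i <= m; ++i) {
    std::deque<Donor> dq_gt, dq_gc;
    const char ri = ref[i - 1];
    cur[0] = i * gap;
    move[(size_t)i * (n + 1)] = 2;
    for (int j = 1; j <= n; ++j) {
      // donor at position d (0-based prefix length d) becomes eligible for
      // acceptors at j once j - d >= min_intron
      int d = j - min_intron;
      if (d >= 0 && d + 1 < n) {
        if (win[d] == 'G' && win[d + 1] == 'T') push_donor(dq_gt, d, cur[d]);
        else if (gc_ag && win[d] == 'G' && win[d + 1] == 'C')
          push_donor(dq_gc, d, cur[d]);
      }
      while (!dq_gt.empty() && dq_gt.front().d < j - max_intron) dq_gt.pop_front();
      while (!dq_gc.empty() && dq_gc.front().d < j - max_intron) dq_gc.pop_front();

      double best = prev[j - 1] + (ri == win[j - 1] ? match : mismatch);
      unsigned char mv = 1;
      double alt = prev[j] + gap;           // consume ref base against gap
      if (alt > best) { best = alt; mv = 2; }
      alt = cur[j - 1] + gap;               // consume window base against gap
      if (alt > best) { best = alt; mv = 3; }
      int don = -1;
      if (j >= 2 && win[j - 2] == 'A' && win[j - 1] == 'G') {
        if (!dq_gt.empty()) {
          alt = dq_gt.front().score + intron_pen;
          if (alt > best) { best = alt; mv = 4; don = dq_gt.front().d; }
        }
        if (!dq_gc.empty()) {
          alt = dq_gc.front().score + intron_pen + gc_pen;
          if (alt > best) { best = alt; mv = 4; don = dq_gc.front().d; }
        }
      }
      cur[j] = best;
      move[(size_t)i * (n + 1) + j] = mv;
      if (mv == 4) intron_donor[(size_t)i * (n + 1) + j] = don;
    }
    std::swap(prev, cur);
  }
  // prev now holds row m
  double best = -DBL_MAX; int endj = 0;
  for (int j = 0; j <= n; ++j) if (prev[j] > best) { best = prev[j]; endj = j; }

  // traceback
  int i = m, j = endj;
  std::vector<int> op_type;      // forward-reversed later; 1 diag 2 up 3 left
  std::vector<int> op_i, op_j;   // 1-based ref / window positions consumed
  std::vector<int> intr_start, intr_end;  // 1-based window coords
  int matches = 0, cols = 0, diag_cols = 0;
  while (i > 0) {
    unsigned char mv = move[(size_t)i * (n + 1) + j];
    if (mv == 1) {
      op_type.push_back(1); op_i.push_back(i); op_j.push_back(j);
      if (ref[i - 1] == win[j - 1]) ++matches;
      ++cols; ++diag_cols; --i; --j;
    } else if (mv == 2) {
      op_type.push_back(2); op_i.push_back(i); op_j.push_back(0);
      ++cols; --i;
    } else if (mv == 3) {
      op_type.push_back(3); op_i.push_back(0); op_j.push_back(j);
      ++cols; --j;
    } else if (mv == 4) {
      int d = intron_donor[(size_t)i * (n + 1) + j];
      intr_start.push_back(d + 1);   // 1-based first intron base
      intr_end.push_back(j);         // 1-based last intron base (the G of AG)
      op_type.push_back(4); op_i.push_back(0); op_j.push_back(-(int)intr_start.size());
      j = d;
    } else {
      break;  // start state
    }
  }
  std::reverse(op_type.begin(), op_type.end());
  std::reverse(op_i.begin(), op_i.end());
  std::reverse(op_j.begin(), op_j.end());
  std::reverse(intr_start.begin(), intr_start.end());
  std::reverse(intr_end.begin(), intr_end.end());

  // assemble blocks between introns
  std::vector<int> brs, bre, bcs, bce;
  int cur_rs = 0, cur_re = -1, cur_cs = 0, cur_ce = -1;
  bool open = false;
  for (size_t t = 0; t < op_type.size(); ++t) {
    if (op_type[t] == 4) {
      if (open) { brs.push_back(cur_rs); bre.push_back(cur_re);
                  bcs.push_back(cur_cs); bce.push_back(cur_ce); open = false; }
      continue;
    }
    int ri_ = op_i[t], cj = op_j[t];
    if (!open) { cur_rs = m + 1; cur_re = 0; cur_cs = n + 1; cur_ce = 0; open = true; }
    if (ri_ > 0) { if (ri_ < cur_rs) cur_rs = ri_; if (ri_ > cur_re) cur_re = ri_; }
    if (cj > 0) { if (cj < cur_cs) cur_cs = cj; if (cj > cur_ce) cur_ce = cj; }
  }
  if (open) { brs.push_back(cur_rs); bre.push_back(cur_re);
              bcs.push_back(cur_cs); bce.push_back(cur_ce); }

  IntegerMatrix blocks(brs.size(), 4);
  for (size_t b = 0; b < brs.size(); ++b) {
    blocks(b, 0) = brs[b]; blocks(b, 1) = bre[b];
    blocks(b, 2) = bcs[b]; blocks(b, 3) = bce[b];
  }
  IntegerMatrix introns(intr_start.size(), 2);
  CharacterVector donors(intr_start.size()), acceptors(intr_start.size());
  for (size_t t = 0; t < intr_start.size(); ++t) {
    introns(t, 0) = intr_start[t]; introns(t, 1) = intr_end[t];
    donors[t] = win.substr(intr_start[t] - 1, 2);
    acceptors[t] = win.substr(intr_end[t] - 2, 2);
  }
  double identity = cols > 0 ? (double)matches / cols : 0.0;
  return List::create(_["score"] = best, _["blocks"] = blocks,
                      _["introns"] = introns, _["donors"] = donors,
                      _["acceptors"] = acceptors, _["identity"] = identity,
                      _["matches"] = matches, _["columns"] = cols,
                      _["aligned_ref"] = diag_cols);
}
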