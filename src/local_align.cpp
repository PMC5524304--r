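#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

// Smith-Waterman local alignment with gap cost open + k * extend for a gap
// of length k (the first gap column costs open + extend). N mismatches
// everything, including N. Deterministic tie-break on equal score: smaller
// query start, then smaller subject start, then shorter alignment.

static const double NEG = -1e18;  // sentinel: no valid alignment in state

// per-state rolling row: score plus (qstart, sstart, len) tie-break metadata
struct Row {
  std::vector<double> sc;
  std::vector<int> qs, ss, len;
  explicit Row(int m) : sc(m + 1, NEG), qs(m + 1), ss(m + 1), len(m + 1) {}
  void reset() { std::fill(sc.begin(), sc.end(), NEG); }
};

static inline bool meta_better(int q1, int s1, int l1,
                               int q2, int s2, int l2) {
  if (q1 != q2) return q1 < q2;
  if (s1 != s2) return s1 < s2;
  return l1 < l2;
}

// [[Rcpp::export(name = ".cpp_local_align")]]
List cpp_local_align(std::string q, std::string s,
                     double match, double mismatch,
                     double gap_open, double gap_extend) {
  const int n = q.size(), m = s.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if ((double)(n + 1) * (double)(m + 1) > 2.5e8)
    stop("sequences too long for full DP; window the inputs");

  // direction matrices for traceback
  // H: 0 = fresh start, 1 = from H diag, 2 = from E diag, 3 = from F diag
  // E (gap in query, consumes subject): 1 = open from H, 2 = extend E
  // F (gap in subject, consumes query): 1 = open from H, 2 = extend F
  std::vector<uint8_t> Hdir((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> Edir((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> Fdir((size_t)(n + 1) * (m + 1), 0);

  Row Hp(m), Hc(m), Ep(m), Ec(m), Fp(m), Fc(m);
  const double first_gap = gap_open + gap_extend;

  double best_sc = 0;
  int best_qs = 0, best_ss = 0, best_len = 0, best_i = 0, best_j = 0;
  bool found = false;

  for (int i = 1; i <= n; ++i) {
    Hc.sc[0] = Ec.sc[0] = Fc.sc[0] = NEG;
    const char qc = q[i - 1];
    const size_t rowoff = (size_t)i * (m + 1);
    for (int j = 1; j <= m; ++j) {
      const char sc_ = s[j - 1];
      const double sub =
          (qc == sc_ && qc != 'N' && sc_ != 'N') ? match : mismatch;

      // ---- H: end on a match/mismatch column
      double hs = sub;              // fresh start at (i, j)
      int hq = i, hss = j, hl = 1;
      uint8_t hd = 0;
      // continuations from the three diagonal states (zero-score prefixes
      // allowed: the qstart tie-break prefers the longer-reaching one)
      if (Hp.sc[j - 1] >= 0) {
        double v = Hp.sc[j - 1] + sub;
        if (v > hs || (v == hs && meta_better(Hp.qs[j - 1], Hp.ss[j - 1],
                                              Hp.len[j - 1] + 1, hq, hss, hl))) {
          hs = v; hq = Hp.qs[j - 1]; hss = Hp.ss[j - 1];
          hl = Hp.len[j - 1] + 1; hd = 1;
        }
      }
      if (Ep.sc[j - 1] >= 0) {
        double v = Ep.sc[j - 1] + sub;
        if (v > hs || (v == hs && meta_better(Ep.qs[j - 1], Ep.ss[j - 1],
                                              Ep.len[j - 1] + 1, hq, hss, hl))) {
          hs = v; hq = Ep.qs[j - 1]; hss = Ep.ss[j - 1];
          hl = Ep.len[j - 1] + 1; hd = 2;
        }
      }
      if (Fp.sc[j - 1] >= 0) {
        double v = Fp.sc[j - 1] + sub;
        if (v > hs || (v == hs && meta_better(Fp.qs[j - 1], Fp.ss[j - 1],
                                              Fp.len[j - 1] + 1, hq, hss, hl))) {
          hs = v; hq = Fp.qs[j - 1]; hss = Fp.ss[j - 1];
          hl = Fp.len[j - 1] + 1; hd = 3;
        }
      }
      Hc.sc[j] = hs; Hc.qs[j] = hq; Hc.ss[j] = hss; Hc.len[j] = hl;
      Hdir[rowoff + j] = hd;

      // ---- E: gap in query (subject base j unmatched)
      double es = NEG; int eq = 0, ess = 0, el = 0; uint8_t ed = 0;
      if (Hc.sc[j - 1] > NEG / 2) {
        es = Hc.sc[j - 1] - first_gap;
        eq = Hc.qs[j - 1]; ess = Hc.ss[j - 1]; el = Hc.len[j - 1] + 1;
        ed = 1;
      }
      if (Ec.sc[j - 1] > NEG / 2) {
        double v = Ec.sc[j - 1] - gap_extend;
        if (v > es || (v == es && meta_better(Ec.qs[j - 1], Ec.ss[j - 1],
                                              Ec.len[j - 1] + 1, eq, ess, el))) {
          es = v; eq = Ec.qs[j - 1]; ess = Ec.ss[j - 1];
          el = Ec.len[j - 1] + 1; ed = 2;
        }
      }
      if (es < 0) { es = NEG; ed = 0; }  // gapped prefixes below 0 never help
      Ec.sc[j] = es; Ec.qs[j] = eq; Ec.ss[j] = ess; Ec.len[j] = el;
      Edir[rowoff + j] = ed;

      // ---- F: gap in subject (query base i unmatched)
      double fs = NEG; int fq = 0, fss = 0, fl = 0; uint8_t fd = 0;
      if (Hp.sc[j] > NEG / 2) {
        fs = Hp.sc[j] - first_gap;
        fq = Hp.qs[j]; fss = Hp.ss[j]; fl = Hp.len[j] + 1;
        fd = 1;
      }
      if (Fp.sc[j] > NEG / 2) {
        double v = Fp.sc[j] - gap_extend;
        if (v > fs || (v == fs && meta_better(Fp.qs[j], Fp.ss[j],
                                              Fp.len[j] + 1, fq, fss, fl))) {
          fs = v; fq = Fp.qs[j]; fss = Fp.ss[j]; fl = Fp.len[j] + 1; fd = 2;
        }
      }
      if (fs < 0) { fs = NEG; fd = 0; }
      Fc.sc[j] = fs; Fc.qs[j] = fq; Fc.ss[j] = fss; Fc.len[j] = fl;
      Fdir[rowoff + j] = fd;

      if (hs > 0 &&
          (!found || hs > best_sc ||
           (hs == best_sc && meta_better(hq, hss, hl,
                                         best_qs, best_ss, best_len)))) {
        best_sc = hs; best_qs = hq; best_ss = hss; best_len = hl;
        best_i = i; best_j = j;
        found = true;
      }
    }
    std::swap(Hp, Hc);
    std::swap(Ep, Ec);
    std::swap(Fp, Fc);
  }

  if (!found) {
    return List::create(_["score"] = 0.0, _["found"] = false);
  }

  // traceback
  std::string path;
  int i = best_i, j = best_j;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  int n_match = 0, n_mismatch = 0, n_gap = 0;
  while (true) {
    size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      bool is_match =
          (q[i - 1] == s[j - 1]) && q[i - 1] != 'N' && s[j - 1] != 'N';
      path.push_back('M');
      if (is_match) ++n_match; else ++n_mismatch;
      uint8_t d = Hdir[idx];
      --i; --j;
      if (d == 0) break;
      state = (d == 1) ? 0 : (d == 2 ? 1 : 2);
    } else if (state == 1) {
      path.push_back('D');  // gap in query, subject consumed
      ++n_gap;
      uint8_t d = Edir[idx];
      --j;
      state = (d == 1) ? 0 : 1;
    } else {
      path.push_back('I');  // gap in subject, query consumed
      ++n_gap;
      uint8_t d = Fdir[idx];
      --i;
      state = (d == 1) ? 0 : 2;
    }
  }
  std::reverse(path.begin(), path.end());

  return List::create(
      _["score"] = best_sc, _["found"] = true,
      _["q_start"] = i, _["q_end"] = best_i,  // 0-based half-open
      _["s_start"] = j, _["s_end"] = best_j,
      _["n_match"] = n_match, _["n_mismatch"] = n_mismatch,
      _["n_gap"] = n_gap, _["path"] = path);
}
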