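#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment of a target protein against a PSSM.
//
// States: M (target residue matched to a profile column), D (profile column
// deleted, gap in target), I (target residue inserted between columns).
// A gap run of length L costs open + (L-1) * extend. Local: paths may start
// and end only in M; flanking gaps are free.
//
// Tie-break: among equal-score alignments prefer the earliest target start,
// then the earliest profile start (tracked through the DP), then the
// earliest end cell in (i, j) scan order.

struct Cell { double s; int si; int sj; int ptr; };

static inline bool better(double s, int si, int sj, const Cell &c) {
  if (s > c.s + 1e-12) return true;
  if (s < c.s - 1e-12) return false;
  if (si != c.si) return si < c.si;
  return sj < c.sj;
}

// [[Rcpp::export(name = ".local_align_cpp")]]
List local_align_cpp(NumericMatrix emis, IntegerVector target,
                     double gap_open, double gap_extend) {
  const int P = emis.nrow();   // profile columns; emis is P x 20
  const int T = target.size();
  const double NEG = -1e100;

  std::vector<Cell> M((T + 1) * (P + 1)), D((T + 1) * (P + 1)),
      I((T + 1) * (P + 1));
  auto at = [P](int i, int j) { return i * (P + 1) + j; };
  for (int i = 0; i <= T; ++i)
    for (int j = 0; j <= P; ++j) {
      M[at(i, j)] = {NEG, 0, 0, 0};
      D[at(i, j)] = {NEG, 0, 0, 0};
      I[at(i, j)] = {NEG, 0, 0, 0};
    }

  Cell best = {0.0, 0, 0, 0};
  int bi = -1, bj = -1;

  for (int i = 1; i <= T; ++i) {
    for (int j = 1; j <= P; ++j) {
      int aa = target[i - 1];           // 1..20, 0 = unknown residue
      double e = (aa >= 1) ? emis(j - 1, aa - 1) : 0.0;
      // M: from M/D/I at (i-1, j-1) or a fresh local start
      Cell c = {e, i, j, 0};            // ptr 0 = start
      const Cell &md = M[at(i - 1, j - 1)];
      if (md.s > NEG / 2 && better(md.s + e, md.si, md.sj, c))
        c = {md.s + e, md.si, md.sj, 1};
      const Cell &dd = D[at(i - 1, j - 1)];
      if (dd.s > NEG / 2 && better(dd.s + e, dd.si, dd.sj, c))
        c = {dd.s + e, dd.si, dd.sj, 2};
      const Cell &id = I[at(i - 1, j - 1)];
      if (id.s > NEG / 2 && better(id.s + e, id.si, id.sj, c))
        c = {id.s + e, id.si, id.sj, 3};
      M[at(i, j)] = c;
      if (better(c.s, c.si, c.sj, best) && c.s > 0) { best = c; bi = i; bj = j; }

      // D: gap in target, consume profile column j
      Cell d = {NEG, 0, 0, 0};
      const Cell &mo = M[at(i, j - 1)];
      if (mo.s > NEG / 2 && better(mo.s - gap_open, mo.si, mo.sj, d))
        d = {mo.s - gap_open, mo.si, mo.sj, 1};
      const Cell &dopen = D[at(i, j - 1)];
      if (dopen.s > NEG / 2 && better(dopen.s - gap_extend, dopen.si, dopen.sj, d))
        d = {dopen.s - gap_extend, dopen.si, dopen.sj, 2};
      D[at(i, j)] = d;

      // I: insertion in target, consume target residue i
      Cell in = {NEG, 0, 0, 0};
      const Cell &mu = M[at(i - 1, j)];
      if (mu.s > NEG / 2 && better(mu.s - gap_open, mu.si, mu.sj, in))
        in = {mu.s - gap_open, mu.si, mu.sj, 1};
      const Cell &iu = I[at(i - 1, j)];
      if (iu.s > NEG / 2 && better(iu.s - gap_extend, iu.si, iu.sj, in))
        in = {iu.s - gap_extend, iu.si, iu.sj, 3};
      I[at(i, j)] = in;
    }
  }

  IntegerVector colmap(P, -1);       // -1 outside alignment, 0 deleted, else 1-based target pos
  IntegerVector ins(P + 1, 0);       // insertions after profile column j (0..P)
  double score = 0.0;
  int t_start = 0, t_end = 0, p_start = 0, p_end = 0;

  if (bi >= 1) {
    score = best.s;
    int i = bi, j = bj, state = 0;   // 0 = M
    t_end = bi; p_end = bj;
    while (true) {
      if (state == 0) {
        const Cell &c = M[at(i, j)];
        colmap[j - 1] = i;
        if (c.ptr == 0) { t_start = i; p_start = j; break; }
        state = c.ptr - 1;           // 0=M,1=D,2=I at (i-1,j-1)
        --i; --j;
      } else if (state == 1) {
        const Cell &c = D[at(i, j)];
        colmap[j - 1] = 0;
        state = c.ptr - 1;
        --j;
      } else {
        const Cell &c = I[at(i, j)];
        ins[j] += 1;
        state = c.ptr - 1;
        --i;
      }
    }
  }

  return List::create(_["score"] = score, _["t_start"] = t_start,
                      _["t_end"] = t_end, _["p_start"] = p_start,
                      _["p_end"] = p_end, _["colmap"] = colmap,
                      _["ins"] = ins);
}
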