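// Search kernel for MDL grammar induction.
//
// Forms are integer phoneme-id vectors (0-based); feature matrices are
// 64-bit sign masks (or a literal phoneme id); rules are fixed-width integer
// encodings built on the R side. Candidate-theory evaluation inverts the
// rule pipeline: for each observed cell we enumerate preimage strings under
// the theory (candidate generation per change kind, each forward-verified),
// then factor preimages as prefix + stem + suffix against the per-column
// affix candidates. This makes rejecting an inconsistent theory cheap, which
// is what dominates exhaustive search.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <set>
#include <map>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<int> Form;

struct FMx {
  uint64_t plus, minus;
  int phlit; // -1 unless a literal-phoneme matrix
};

struct TrigElem { int fm; bool star; };

struct RuleC {
  int focus;                // fm index, -1 for insertion (empty focus)
  int change_kind;          // 0 feature, 1 delete, 2 insert
  int change_fm;            // fm index for feature change
  Form insert_seq;          // for insert
  std::vector<TrigElem> left, right;
  bool lbound, rbound;
  // precomputed for feature changes:
  std::vector<int> fwd;                  // phoneme -> result (-1 = gap)
  std::vector<std::vector<int> > srcs;   // result phoneme -> possible sources
};

struct Kernel {
  int nphon;
  std::vector<uint64_t> pplus, pminus;
  std::vector<FMx> fms;
  std::vector<RuleC> rules;
  std::vector<double> rule_bits;

  bool fm_match(int fm, int p) const {
    const FMx &f = fms[fm];
    if (f.phlit >= 0) return p == f.phlit;
    return ((pplus[p] & f.plus) == f.plus) && ((pminus[p] & f.minus) == f.minus);
  }
};

// ---------------------------------------------------------------------------
// forward application

static bool side_match(const Kernel &K, const std::vector<TrigElem> &elems,
                       bool bound, const Form &ph, int from, int dir,
                       int k) {
  int n = (int)ph.size();
  if (k >= (int)elems.size()) {
    if (bound) return from < 0 || from >= n;
    return true;
  }
  // elements are stored focus-outward already (see build_rule)
  const TrigElem &e = elems[k];
  if (e.star) {
    if (side_match(K, elems, bound, ph, from, dir, k + 1)) return true;
    if (from >= 0 && from < n && K.fm_match(e.fm, ph[from]))
      return side_match(K, elems, bound, ph, from + dir, dir, k);
    return false;
  }
  if (from < 0 || from >= n) return false;
  if (!K.fm_match(e.fm, ph[from])) return false;
  return side_match(K, elems, bound, ph, from + dir, dir, k + 1);
}

static Form apply_rule_c(const Kernel &K, const RuleC &r, const Form &ph) {
  int n = (int)ph.size();
  if (r.focus < 0) { // insertion at gaps
    std::vector<int> gaps;
    for (int g = 0; g <= n; ++g) {
      if (side_match(K, r.left, r.lbound, ph, g - 1, -1, 0) &&
          side_match(K, r.right, r.rbound, ph, g, +1, 0))
        gaps.push_back(g);
    }
    if (gaps.empty()) return ph;
    Form out;
    size_t gi = 0;
    for (int i = 0; i <= n; ++i) {
      if (gi < gaps.size() && gaps[gi] == i) {
        out.insert(out.end(), r.insert_seq.begin(), r.insert_seq.end());
        ++gi;
      }
      if (i < n) out.push_back(ph[i]);
    }
    return out;
  }
  std::vector<char> site(n, 0);
  bool any = false;
  for (int i = 0; i < n; ++i) {
    if (K.fm_match(r.focus, ph[i]) &&
        side_match(K, r.left, r.lbound, ph, i - 1, -1, 0) &&
        side_match(K, r.right, r.rbound, ph, i + 1, +1, 0)) {
      site[i] = 1; any = true;
    }
  }
  if (!any) return ph;
  Form out;
  out.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (!site[i]) { out.push_back(ph[i]); continue; }
    if (r.change_kind == 1) continue; // delete
    if (r.change_kind == 0) {
      int q = r.fwd[ph[i]];
      out.push_back(q < 0 ? ph[i] : q); // inventory gap: unchanged
    } else {
      out.push_back(ph[i]); // insert with non-empty focus never happens
    }
  }
  return out;
}

static Form apply_theory(const Kernel &K, const std::vector<int> &th,
                         const Form &ph) {
  Form cur = ph;
  for (size_t k = 0; k < th.size(); ++k)
    cur = apply_rule_c(K, K.rules[th[k]], cur);
  return cur;
}

// ---------------------------------------------------------------------------
// preimages

struct PreCtx {
  int max_len;
  int cap;        // candidate-generation cap per call
  bool truncated;
};

// all x with apply_rule(r, x) == y, |x| <= max_len (sound by forward check;
// completeness within the generation caps)
static void preimage_rule(const Kernel &K, const RuleC &r, const Form &y,
                          PreCtx &ctx, std::set<Form> &out) {
  int n = (int)y.size();
  std::vector<Form> cands;
  cands.push_back(y); // non-firing case always considered

  if (r.focus >= 0 && r.change_kind == 0) {
    // overwrite: choose changed positions and their sources
    std::vector<int> pos;
    for (int i = 0; i < n; ++i)
      if (!r.srcs[y[i]].empty()) pos.push_back(i);
    if ((int)pos.size() > 12) { ctx.truncated = true; pos.resize(12); }
    int nsub = 1 << (int)pos.size();
    for (int mask = 1; mask < nsub; ++mask) {
      // bounded rewrite fan-in: at most 6 changed sites per application
      if (__builtin_popcount((unsigned)mask) > 6) continue;
      // cartesian product of sources over the chosen positions
      std::vector<Form> part;
      part.push_back(y);
      for (size_t b = 0; b < pos.size(); ++b) {
        if (!(mask & (1 << b))) continue;
        std::vector<Form> next;
        for (size_t ci = 0; ci < part.size(); ++ci) {
          const std::vector<int> &ss = r.srcs[y[pos[b]]];
          for (size_t si = 0; si < ss.size(); ++si) {
            Form f = part[ci];
            f[pos[b]] = ss[si];
            next.push_back(f);
            if ((int)next.size() > ctx.cap) { ctx.truncated = true; break; }
          }
          if ((int)next.size() > ctx.cap) break;
        }
        part.swap(next);
      }
      for (size_t ci = 0; ci < part.size(); ++ci) cands.push_back(part[ci]);
      if ((int)cands.size() > ctx.cap) { ctx.truncated = true; break; }
    }
  } else if (r.focus >= 0 && r.change_kind == 1) {
    // delete: reinsert focus-matching phonemes
    std::vector<int> focus_ph;
    for (int p = 0; p < K.nphon; ++p)
      if (K.fm_match(r.focus, p)) focus_ph.push_back(p);
    int budget = ctx.max_len - n;
    if (budget > 2) budget = 2; // deletions per application rarely exceed this
    // recursively insert j phonemes at nondecreasing positions
    std::vector<Form> layer;
    layer.push_back(y);
    for (int j = 0; j < budget; ++j) {
      std::vector<Form> next;
      for (size_t ci = 0; ci < layer.size(); ++ci) {
        const Form &f = layer[ci];
        for (int ins = 0; ins <= (int)f.size(); ++ins) {
          for (size_t pi = 0; pi < focus_ph.size(); ++pi) {
            Form g = f;
            g.insert(g.begin() + ins, focus_ph[pi]);
            next.push_back(g);
            if ((int)next.size() > ctx.cap) { ctx.truncated = true; break; }
          }
          if ((int)next.size() > ctx.cap) break;
        }
        if ((int)next.size() > ctx.cap) break;
      }
      for (size_t ci = 0; ci < next.size(); ++ci) cands.push_back(next[ci]);
      layer.swap(next);
      if ((int)cands.size() > 4 * ctx.cap) { ctx.truncated = true; break; }
    }
  } else if (r.focus < 0 && r.change_kind == 2) {
    // insertion: remove subsets of occurrences of the inserted sequence
    const Form &q = r.insert_seq;
    int m = (int)q.size();
    std::vector<int> occ;
    for (int i = 0; i + m <= n; ++i) {
      bool hit = true;
      for (int j = 0; j < m; ++j) if (y[i + j] != q[j]) { hit = false; break; }
      if (hit) occ.push_back(i);
    }
    if ((int)occ.size() > 14) { ctx.truncated = true; occ.resize(14); }
    int nsub = 1 << (int)occ.size();
    for (int mask = 1; mask < nsub; ++mask) {
      // skip overlapping selections
      bool ok = true;
      int last_end = -1;
      Form f;
      int prev = 0;
      for (size_t b = 0; b < occ.size() && ok; ++b) {
        if (!(mask & (1 << b))) continue;
        if (occ[b] < last_end) { ok = false; break; }
        for (int i = prev; i < occ[b]; ++i) f.push_back(y[i]);
        prev = occ[b] + m;
        last_end = prev;
      }
      if (!ok) continue;
      for (int i = prev; i < n; ++i) f.push_back(y[i]);
      cands.push_back(f);
      if ((int)cands.size() > ctx.cap) { ctx.truncated = true; break; }
    }
  }

  for (size_t ci = 0; ci < cands.size(); ++ci) {
    if ((int)cands[ci].size() > ctx.max_len) continue;
    if (apply_rule_c(K, r, cands[ci]) == y) out.insert(cands[ci]);
  }
}

// invert `th` (in reverse order) starting from an initial candidate set
static std::vector<Form> theory_preimages_from(const Kernel &K,
                                               const std::vector<int> &th,
                                               const std::vector<Form> &init,
                                               PreCtx &ctx) {
  std::set<Form> cur(init.begin(), init.end());
  for (int k = (int)th.size() - 1; k >= 0; --k) {
    std::set<Form> next;
    for (std::set<Form>::const_iterator it = cur.begin(); it != cur.end(); ++it)
      preimage_rule(K, K.rules[th[k]], *it, ctx, next);
    if ((int)next.size() > 4 * ctx.cap) ctx.truncated = true;
    cur.swap(next);
    if (cur.empty()) break;
  }
  return std::vector<Form>(cur.begin(), cur.end());
}

// ---------------------------------------------------------------------------
// problem data and evaluation

struct AffixCand { Form pfx, sfx; double bits; };

struct Problem {
  int nrows, ncols;
  std::vector<std::vector<Form> > cell;       // [r][c]
  std::vector<std::vector<char> > has;        // [r][c]
  std::vector<std::vector<AffixCand> > cands; // [c]
  std::vector<char> stem_ok;                  // phoneme id -> allowed in stem
  int max_stem_len;
  double unit_bits;
  bool fixed_stems;
  std::vector<Form> stems_fixed;              // [r] when fixed_stems
};

struct EvalResult {
  bool consistent;
  double affix_bits, stem_bits, total; // total excludes rule bits
  std::vector<int> affix_choice;       // per column candidate index
  std::vector<Form> stems;             // per row
  bool truncated;
};

static bool stem_less(const Form &a, const Form &b) {
  if (a.size() != b.size()) return a.size() < b.size();
  return a < b;
}

static int affix_slack(const Problem &P) {
  int max_affix = 0;
  for (int c = 0; c < P.ncols; ++c)
    for (size_t a = 0; a < P.cands[c].size(); ++a) {
      int l = (int)(P.cands[c][a].pfx.size() + P.cands[c][a].sfx.size());
      if (l > max_affix) max_affix = l;
    }
  return max_affix;
}

// `full_th` is the whole theory (used for forward checks); `prefix_th` are
// the rules not yet inverted in `stage`, which holds per-cell candidate sets
// (preimages of each cell under the already-inverted suffix of the theory).
static bool eval_theory(const Kernel &K, const Problem &P,
                        const std::vector<int> &full_th,
                        const std::vector<int> &prefix_th,
                        const std::vector<std::vector<Form> > &stage,
                        EvalResult &res) {
  const std::vector<int> &th = full_th;
  res.truncated = false;

  if (P.fixed_stems) {
    // lexicon fully determined: forward derivation check only
    double sb = 0;
    for (int r = 0; r < P.nrows; ++r) {
      for (int c = 0; c < P.ncols; ++c) {
        if (!P.has[r][c]) continue;
        Form u = P.cands[c][0].pfx;
        u.insert(u.end(), P.stems_fixed[r].begin(), P.stems_fixed[r].end());
        u.insert(u.end(), P.cands[c][0].sfx.begin(), P.cands[c][0].sfx.end());
        if (apply_theory(K, th, u) != P.cell[r][c]) return false;
      }
      sb += P.stems_fixed[r].size() * P.unit_bits;
    }
    res.consistent = true;
    res.affix_bits = 0;
    for (int c = 0; c < P.ncols; ++c) res.affix_bits += P.cands[c][0].bits;
    res.stem_bits = sb;
    res.total = res.affix_bits + res.stem_bits;
    res.affix_choice.assign(P.ncols, 0);
    res.stems = P.stems_fixed;
    return true;
  }

  PreCtx ctx;
  // slack: intermediates may transiently exceed the underlying-form bound
  ctx.max_len = P.max_stem_len + affix_slack(P) + 4;
  ctx.cap = 2048;
  ctx.truncated = false;

  // stems[r][c][a]: candidate stems (sorted, unique)
  std::vector<std::vector<std::vector<std::vector<Form> > > > stems(P.nrows);
  for (int r = 0; r < P.nrows; ++r) {
    stems[r].resize(P.ncols);
    for (int c = 0; c < P.ncols; ++c) {
      if (!P.has[r][c]) { stems[r][c].resize(P.cands[c].size()); continue; }
      std::vector<Form> pre = theory_preimages_from(
        K, prefix_th, stage[r * P.ncols + c], ctx);
      stems[r][c].resize(P.cands[c].size());
      bool row_any = false;
      for (size_t a = 0; a < P.cands[c].size(); ++a) {
        const AffixCand &ac = P.cands[c][a];
        std::set<Form> got;
        for (size_t u = 0; u < pre.size(); ++u) {
          const Form &f = pre[u];
          int np = (int)ac.pfx.size(), ns = (int)ac.sfx.size();
          int len = (int)f.size() - np - ns;
          if (len < 0 || len > P.max_stem_len) continue;
          bool ok = true;
          for (int i = 0; i < np && ok; ++i) if (f[i] != ac.pfx[i]) ok = false;
          for (int i = 0; i < ns && ok; ++i)
            if (f[np + len + i] != ac.sfx[i]) ok = false;
          if (!ok) continue;
          Form s(f.begin() + np, f.begin() + np + len);
          for (int i = 0; i < len && ok; ++i) if (!P.stem_ok[s[i]]) ok = false;
          if (ok) got.insert(s);
        }
        stems[r][c][a].assign(got.begin(), got.end());
        std::sort(stems[r][c][a].begin(), stems[r][c][a].end(), stem_less);
        if (!got.empty()) row_any = true;
      }
      if (!row_any) { res.truncated = ctx.truncated; return false; }
    }
  }
  res.truncated = ctx.truncated;

  // per-column candidates valid for every row
  std::vector<std::vector<int> > valid(P.ncols);
  for (int c = 0; c < P.ncols; ++c) {
    for (size_t a = 0; a < P.cands[c].size(); ++a) {
      bool ok = true;
      for (int r = 0; r < P.nrows && ok; ++r)
        if (P.has[r][c] && stems[r][c][a].empty()) ok = false;
      if (ok) valid[c].push_back((int)a);
    }
    if (valid[c].empty()) return false;
  }

  // cartesian product over columns of valid affix choices
  std::vector<size_t> idx(P.ncols, 0);
  bool found = false;
  double best_total = 0;
  std::vector<int> best_choice;
  std::vector<Form> best_stems;
  while (true) {
    double ab = 0;
    std::vector<int> choice(P.ncols);
    for (int c = 0; c < P.ncols; ++c) {
      choice[c] = valid[c][idx[c]];
      ab += P.cands[c][choice[c]].bits;
    }
    double sb = 0;
    std::vector<Form> rstems(P.nrows);
    bool ok = true;
    for (int r = 0; r < P.nrows && ok; ++r) {
      // intersect stem sets across observed columns; pick the cheapest
      int first_c = -1;
      for (int c = 0; c < P.ncols; ++c) if (P.has[r][c]) { first_c = c; break; }
      if (first_c < 0) { rstems[r] = Form(); continue; }
      const std::vector<Form> &base = stems[r][first_c][choice[first_c]];
      bool got = false;
      Form pick;
      for (size_t i = 0; i < base.size(); ++i) {
        bool everywhere = true;
        for (int c = 0; c < P.ncols && everywhere; ++c) {
          if (!P.has[r][c] || c == first_c) continue;
          const std::vector<Form> &other = stems[r][c][choice[c]];
          if (!std::binary_search(other.begin(), other.end(), base[i],
                                  stem_less)) everywhere = false;
        }
        if (everywhere) { pick = base[i]; got = true; break; }
      }
      if (!got) { ok = false; break; }
      rstems[r] = pick;
      sb += pick.size() * P.unit_bits;
    }
    if (ok) {
      double tot = ab + sb;
      if (!found || tot < best_total - 1e-12) {
        found = true;
        best_total = tot;
        best_choice = choice;
        best_stems = rstems;
        res.affix_bits = ab;
        res.stem_bits = sb;
      }
    }
    // advance
    int c = P.ncols - 1;
    while (c >= 0) {
      if (++idx[c] < valid[c].size()) break;
      idx[c] = 0; --c;
    }
    if (c < 0) break;
  }
  if (!found) return false;
  res.consistent = true;
  res.total = best_total;
  res.affix_choice = best_choice;
  res.stems = best_stems;
  return true;
}

// ---------------------------------------------------------------------------
// construction from R objects

static Kernel build_kernel(int nphon, NumericVector pplus, NumericVector pminus,
                           NumericVector fm_plus, NumericVector fm_minus,
                           IntegerVector fm_phlit, IntegerMatrix rules_enc,
                           NumericVector rule_bits) {
  Kernel K;
  K.nphon = nphon;
  K.pplus.resize(nphon); K.pminus.resize(nphon);
  for (int i = 0; i < nphon; ++i) {
    K.pplus[i] = (uint64_t)pplus[i];
    K.pminus[i] = (uint64_t)pminus[i];
  }
  int nfm = fm_plus.size();
  K.fms.resize(nfm);
  for (int i = 0; i < nfm; ++i) {
    K.fms[i].plus = (uint64_t)fm_plus[i];
    K.fms[i].minus = (uint64_t)fm_minus[i];
    K.fms[i].phlit = fm_phlit[i];
  }
  int nr = rules_enc.nrow();
  K.rules.resize(nr);
  K.rule_bits.assign(rule_bits.begin(), rule_bits.end());
  for (int i = 0; i < nr; ++i) {
    RuleC &r = K.rules[i];
    r.focus = rules_enc(i, 0);
    r.change_kind = rules_enc(i, 1);
    r.change_fm = rules_enc(i, 2);
    r.insert_seq.clear();
    if (rules_enc(i, 3) >= 0) r.insert_seq.push_back(rules_enc(i, 3));
    if (rules_enc(i, 4) >= 0) r.insert_seq.push_back(rules_enc(i, 4));
    // triggers: elements arrive in surface order; store focus-outward
    r.left.clear();
    for (int e = 1; e >= 0; --e) { // left: reverse surface order
      int fm = rules_enc(i, 5 + 2 * e);
      if (fm >= 0) {
        TrigElem t; t.fm = fm; t.star = rules_enc(i, 6 + 2 * e) != 0;
        r.left.push_back(t);
      }
    }
    r.lbound = rules_enc(i, 9) != 0;
    r.right.clear();
    for (int e = 0; e < 2; ++e) {
      int fm = rules_enc(i, 10 + 2 * e);
      if (fm >= 0) {
        TrigElem t; t.fm = fm; t.star = rules_enc(i, 11 + 2 * e) != 0;
        r.right.push_back(t);
      }
    }
    r.rbound = rules_enc(i, 14) != 0;
    if (r.change_kind == 0 && r.focus >= 0) {
      r.fwd.assign(nphon, -1);
      r.srcs.assign(nphon, std::vector<int>());
      const FMx &ch = K.fms[r.change_fm];
      for (int p = 0; p < nphon; ++p) {
        int q = -1;
        if (ch.phlit >= 0) q = ch.phlit;
        else {
          uint64_t tp = (K.pplus[p] & ~ch.minus) | ch.plus;
          uint64_t tm = (K.pminus[p] & ~ch.plus) | ch.minus;
          int hit = -1, nhit = 0;
          for (int t = 0; t < nphon; ++t)
            if (K.pplus[t] == tp && K.pminus[t] == tm) { hit = t; ++nhit; }
          q = (nhit == 1) ? hit : -1;
        }
        r.fwd[p] = q;
        if (q >= 0 && q != p) r.srcs[q].push_back(p);
      }
    }
  }
  return K;
}

static Problem build_problem(const List &data) {
  Problem P;
  P.nrows = as<int>(data["nrows"]);
  P.ncols = as<int>(data["ncols"]);
  List cells = data["cells"];
  P.cell.assign(P.nrows, std::vector<Form>(P.ncols));
  P.has.assign(P.nrows, std::vector<char>(P.ncols, 0));
  for (int r = 0; r < P.nrows; ++r)
    for (int c = 0; c < P.ncols; ++c) {
      RObject cl = cells[r * P.ncols + c];
      if (!cl.isNULL()) {
        IntegerVector v(cl);
        P.cell[r][c].assign(v.begin(), v.end());
        P.has[r][c] = 1;
      }
    }
  List cands = data["affix_cands"];
  P.cands.resize(P.ncols);
  for (int c = 0; c < P.ncols; ++c) {
    List cc = cands[c];
    List pf = cc["pfx"], sf = cc["sfx"];
    NumericVector bits = cc["bits"];
    int na = pf.size();
    P.cands[c].resize(na);
    for (int a = 0; a < na; ++a) {
      IntegerVector p = pf[a], s = sf[a];
      P.cands[c][a].pfx.assign(p.begin(), p.end());
      P.cands[c][a].sfx.assign(s.begin(), s.end());
      P.cands[c][a].bits = bits[a];
    }
  }
  int nphon = as<int>(data["nphon"]);
  IntegerVector alpha = data["stem_alphabet"];
  P.stem_ok.assign(nphon, 0);
  for (int i = 0; i < alpha.size(); ++i) P.stem_ok[alpha[i]] = 1;
  P.max_stem_len = as<int>(data["max_stem_len"]);
  P.unit_bits = as<double>(data["unit_bits"]);
  P.fixed_stems = as<bool>(data["fixed_stems"]);
  if (P.fixed_stems) {
    List fstems = data["stems_fixed"];
    P.stems_fixed.resize(P.nrows);
    for (int r = 0; r < P.nrows; ++r) {
      IntegerVector v = fstems[r];
      P.stems_fixed[r].assign(v.begin(), v.end());
    }
  }
  return P;
}

// ---------------------------------------------------------------------------
// exports

// [[Rcpp::export(name = ".kernel_apply")]]
IntegerVector kernel_apply(IntegerVector form, IntegerVector theory,
                           int nphon, NumericVector pplus, NumericVector pminus,
                           NumericVector fm_plus, NumericVector fm_minus,
                           IntegerVector fm_phlit, IntegerMatrix rules_enc,
                           NumericVector rule_bits) {
  Kernel K = build_kernel(nphon, pplus, pminus, fm_plus, fm_minus, fm_phlit,
                          rules_enc, rule_bits);
  std::vector<int> th(theory.begin(), theory.end());
  Form ph(form.begin(), form.end());
  Form out = apply_theory(K, th, ph);
  return IntegerVector(out.begin(), out.end());
}

static List result_to_list(const Kernel &K, const std::vector<int> &th,
                           const EvalResult &res) {
  double rb = 0;
  for (size_t k = 0; k < th.size(); ++k) rb += K.rule_bits[th[k]];
  List stems(res.stems.size());
  for (size_t r = 0; r < res.stems.size(); ++r)
    stems[r] = IntegerVector(res.stems[r].begin(), res.stems[r].end());
  return List::create(
    _["theory"] = IntegerVector(th.begin(), th.end()),
    _["rule_bits"] = rb,
    _["affix_bits"] = res.affix_bits,
    _["stem_bits"] = res.stem_bits,
    _["total_bits"] = rb + res.total,
    _["affix_choice"] = IntegerVector(res.affix_choice.begin(),
                                      res.affix_choice.end()),
    _["stems"] = stems,
    _["truncated"] = res.truncated);
}

// Enumerate theories (all ordered sequences of 0..K rules, or an explicit
// list) and evaluate each. Returns the best by total bits (tie: fewer
// parsimony bits, then enumeration order), plus optionally every consistent
// theory's summary.
// [[Rcpp::export(name = ".kernel_search")]]
List kernel_search(int nphon, NumericVector pplus, NumericVector pminus,
                   NumericVector fm_plus, NumericVector fm_minus,
                   IntegerVector fm_phlit, IntegerMatrix rules_enc,
                   NumericVector rule_bits, List data, int K_max,
                   bool collect_all, Nullable<List> theories_in,
                   bool prune) {
  Kernel K = build_kernel(nphon, pplus, pminus, fm_plus, fm_minus, fm_phlit,
                          rules_enc, rule_bits);
  Problem P = build_problem(data);
  int nr = rules_enc.nrow();

  if (K_max >= 3 && theories_in.isNull())
    stop("kernel enumerates at most 2 rules");

  // identity stage: each cell's candidate set is the cell itself
  std::vector<std::vector<Form> > id_stage(P.nrows * P.ncols);
  for (int r = 0; r < P.nrows; ++r)
    for (int c = 0; c < P.ncols; ++c)
      if (P.has[r][c]) id_stage[r * P.ncols + c].push_back(P.cell[r][c]);

  bool found = false, any_trunc = false;
  double best_total = 0, best_pars = 0;
  EvalResult best_res;
  std::vector<int> best_th;
  std::vector<std::vector<int> > all_th;
  std::vector<double> all_rule, all_affix, all_stem;
  std::vector<std::string> all_sig;
  long n_eval = 0, n_theories = 0;

  // returns false when the theory was pruned without evaluation
  auto process = [&](const std::vector<int> &full_th,
                     const std::vector<int> &prefix_th,
                     const std::vector<std::vector<Form> > &stage) {
    ++n_theories;
    double rb = 0;
    for (size_t k = 0; k < full_th.size(); ++k) rb += K.rule_bits[full_th[k]];
    if (prune && !collect_all && found && rb >= best_total - 1e-12) return;
    EvalResult res;
    ++n_eval;
    if (!eval_theory(K, P, full_th, prefix_th, stage, res)) {
      if (res.truncated) any_trunc = true;
      return;
    }
    if (res.truncated) any_trunc = true;
    double tot = rb + res.total;
    double pars = rb + res.affix_bits;
    if (collect_all) {
      all_th.push_back(full_th);
      all_rule.push_back(rb);
      all_affix.push_back(res.affix_bits);
      all_stem.push_back(res.stem_bits);
      // analysis signature: stems and affix choice determine behavior on X
      std::string sig;
      char buf[16];
      for (size_t r = 0; r < res.stems.size(); ++r) {
        for (size_t i = 0; i < res.stems[r].size(); ++i) {
          snprintf(buf, sizeof(buf), "%d.", res.stems[r][i]);
          sig += buf;
        }
        sig += "|";
      }
      for (size_t c = 0; c < res.affix_choice.size(); ++c) {
        snprintf(buf, sizeof(buf), "%d,", res.affix_choice[c]);
        sig += buf;
      }
      all_sig.push_back(sig);
    }
    bool better = false;
    if (!found || tot < best_total - 1e-12) better = true;
    else if (std::abs(tot - best_total) <= 1e-12) {
      if (pars < best_pars - 1e-12) better = true;
      else if (std::abs(pars - best_pars) <= 1e-12 && full_th < best_th)
        better = true; // canonical rule order breaks exact ties
    }
    if (better) {
      found = true;
      best_total = tot;
      best_pars = pars;
      best_res = res;
      best_th = full_th;
    }
  };

  if (theories_in.isNotNull()) {
    List tl(theories_in);
    for (int i = 0; i < tl.size(); ++i) {
      IntegerVector v = tl[i];
      std::vector<int> th(v.begin(), v.end());
      process(th, th, id_stage);
      if (i % 512 == 0) Rcpp::checkUserInterrupt();
    }
  } else {
    std::vector<int> empty_th;
    process(empty_th, empty_th, id_stage);
    if (K_max >= 1) {
      for (int i = 0; i < nr; ++i) {
        std::vector<int> th(1, i);
        process(th, th, id_stage);
        if (i % 512 == 0) Rcpp::checkUserInterrupt();
      }
    }
    if (K_max >= 2) {
      // memoize per second rule: invert it once over every cell
      for (int j = 0; j < nr; ++j) {
        Rcpp::checkUserInterrupt();
        PreCtx sctx;
        sctx.max_len = P.max_stem_len + affix_slack(P) + 4;
        sctx.cap = 2048;
        sctx.truncated = false;
        std::vector<std::vector<Form> > stage_j(P.nrows * P.ncols);
        std::vector<int> rj(1, j);
        bool feasible = true;
        for (int r = 0; r < P.nrows && feasible; ++r)
          for (int c = 0; c < P.ncols; ++c) {
            if (!P.has[r][c]) continue;
            stage_j[r * P.ncols + c] = theory_preimages_from(
              K, rj, id_stage[r * P.ncols + c], sctx);
            if (stage_j[r * P.ncols + c].empty()) { feasible = false; break; }
          }
        if (sctx.truncated) any_trunc = true;
        if (!feasible) { n_theories += nr; continue; }
        for (int i = 0; i < nr; ++i) {
          std::vector<int> th;
          th.push_back(i); th.push_back(j);
          std::vector<int> prefix(1, i);
          process(th, prefix, stage_j);
        }
      }
    }
  }

  List out = List::create(
    _["found"] = found,
    _["n_theories"] = (double)n_theories,
    _["n_evaluated"] = (double)n_eval,
    _["truncated"] = any_trunc);
  if (found) out["best"] = result_to_list(K, best_th, best_res);
  if (collect_all) {
    List ths(all_th.size());
    for (size_t i = 0; i < all_th.size(); ++i)
      ths[i] = IntegerVector(all_th[i].begin(), all_th[i].end());
    out["all_theories"] = ths;
    out["all_rule_bits"] = NumericVector(all_rule.begin(), all_rule.end());
    out["all_affix_bits"] = NumericVector(all_affix.begin(), all_affix.end());
    out["all_stem_bits"] = NumericVector(all_stem.begin(), all_stem.end());
    out["all_sig"] = CharacterVector(all_sig.begin(), all_sig.end());
  }
  return out;
}

// Evaluate one explicit theory in full detail (used by repair search and for
// scoring a known grammar against data).
// [[Rcpp::export(name = ".kernel_eval")]]
List kernel_eval(int nphon, NumericVector pplus, NumericVector pminus,
                 NumericVector fm_plus, NumericVector fm_minus,
                 IntegerVector fm_phlit, IntegerMatrix rules_enc,
                 NumericVector rule_bits, List data, IntegerVector theory) {
  Kernel K = build_kernel(nphon, pplus, pminus, fm_plus, fm_minus, fm_phlit,
                          rules_enc, rule_bits);
  Problem P = build_problem(data);
  std::vector<int> th(theory.begin(), theory.end());
  std::vector<std::vector<Form> > id_stage(P.nrows * P.ncols);
  for (int r = 0; r < P.nrows; ++r)
    for (int c = 0; c < P.ncols; ++c)
      if (P.has[r][c]) id_stage[r * P.ncols + c].push_back(P.cell[r][c]);
  EvalResult res;
  if (!eval_theory(K, P, th, th, id_stage, res)) {
    return List::create(_["found"] = false, _["truncated"] = res.truncated);
  }
  List out = result_to_list(K, th, res);
  out["found"] = true;
  return out;
}
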