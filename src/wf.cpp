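#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <set>
using namespace Rcpp;

// Two Wright-Fisher engines share this file:
//
//  * coalescent_sample_cpp -- an exact discrete-generation backward WF
//    coalescent with recombination and infinite-sites mutation, used to draw
//    equilibrium samples / initial populations under piecewise demography.
//    Each generation every lineage picks a uniform parent chromosome among the
//    2N of that generation; lineages sharing a parent coalesce (simultaneous
//    and multiple mergers arise naturally, as in the true WF genealogy).
//
//  * forward_sim_cpp -- forward WF with additive selection (fitness 1,
//    1 + s/2, 1 + s), per-gamete Poisson crossovers and mutations, and the
//    sweep modes (hard de novo, recurrent de novo, standing variation) with
//    conditioning by snapshot-restart.
//
// Both use R's RNG so set.seed() governs all randomness.

namespace {

typedef std::vector<uint64_t> Bits;

inline int popcnt(const Bits& b) {
  int s = 0;
  for (uint64_t w : b) s += __builtin_popcountll(w);
  return s;
}

struct Seg {
  double l, r;   // half-open [l, r)
  Bits desc;     // descendant sample chromosomes
  int cnt;
};

typedef std::vector<Seg> Lineage;  // sorted by l, non-overlapping

// Merge two coalescing lineages; overlapping ancestral material unions its
// descendant sets, segments reaching the full sample (MRCA) are dropped.
Lineage merge_lineages(Lineage A, Lineage B, int n) {
  Lineage out;
  out.reserve(A.size() + B.size());
  size_t ia = 0, ib = 0;
  while (ia < A.size() || ib < B.size()) {
    if (ia == A.size()) { out.push_back(std::move(B[ib++])); continue; }
    if (ib == B.size()) { out.push_back(std::move(A[ia++])); continue; }
    Seg& a = A[ia];
    Seg& b = B[ib];
    if (a.r <= b.l) { out.push_back(std::move(a)); ++ia; continue; }
    if (b.r <= a.l) { out.push_back(std::move(b)); ++ib; continue; }
    // overlap
    double ol = std::max(a.l, b.l);
    if (a.l < ol) { out.push_back(Seg{a.l, ol, a.desc, a.cnt}); a.l = ol; }
    if (b.l < ol) { out.push_back(Seg{b.l, ol, b.desc, b.cnt}); b.l = ol; }
    double orr = std::min(a.r, b.r);
    Bits u(a.desc.size());
    for (size_t w = 0; w < u.size(); ++w) u[w] = a.desc[w] | b.desc[w];
    int c = popcnt(u);
    if (c < n) out.push_back(Seg{ol, orr, std::move(u), c});
    if (a.r > orr) a.l = orr; else ++ia;
    if (b.r > orr) b.l = orr; else ++ib;
  }
  return out;
}

inline double lineage_length(const Lineage& lin) {
  double len = 0;
  for (const Seg& s : lin) len += s.r - s.l;
  return len;
}

}  // namespace

// Draw n sample chromosomes at generation 0 under a demography given as the
// chromosome count 2N at each generation back in time (n2_back[g] = 2N at g
// generations before the sampling/initialization time; beyond the end of the
// vector the ancestral value n2_anc applies).  Returns segregating sites as a
// 0/1 matrix (rows = chromosomes) with positions in [0, L).
// [[Rcpp::export]]
List coalescent_sample_cpp(int n, IntegerVector n2_back, int n2_anc,
                           double mu_bp, double r_bp, double L,
                           double max_gen) {
  if (n < 2) stop("need at least 2 sample chromosomes");
  const int words = (n + 63) / 64;

  std::vector<Lineage> lins;
  lins.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    Bits b(words, 0);
    b[i / 64] |= (uint64_t)1 << (i % 64);
    lins.push_back(Lineage{Seg{0.0, L, std::move(b), 1}});
  }

  std::vector<double> mpos;
  std::vector<Bits> mdesc;
  std::vector<double> brk;
  double gen = 0;

  while (!lins.empty()) {
    if (++gen > max_gen) stop("coalescent did not complete within %g generations", max_gen);
    long g = (long)gen;
    long N2 = (g < (long)n2_back.size()) ? n2_back[g] : n2_anc;
    if (N2 < 1) stop("demography gives non-positive population size");

    // mutation and recombination on the branch each lineage spans this generation
    size_t nl = lins.size();
    for (size_t k = 0; k < nl; ++k) {
      double len = lineage_length(lins[k]);
      int nm = (int)R::rpois(mu_bp * len);
      for (int m = 0; m < nm; ++m) {
        double u = unif_rand() * len, acc = 0;
        for (const Seg& sg : lins[k]) {
          double w = sg.r - sg.l;
          if (u < acc + w) {
            mpos.push_back(sg.l + (u - acc));
            mdesc.push_back(sg.desc);
            break;
          }
          acc += w;
        }
      }
      double lo = lins[k].front().l, hi = lins[k].back().r;
      int nc = (int)R::rpois(r_bp * (hi - lo));
      if (nc > 0) {
        brk.clear();
        for (int c = 0; c < nc; ++c) brk.push_back(lo + unif_rand() * (hi - lo));
        std::sort(brk.begin(), brk.end());
        Lineage cur = std::move(lins[k]);
        lins[k].clear();
        bool first = true;
        for (double bp : brk) {
          Lineage left;
          Lineage right;
          for (Seg& sg : cur) {
            if (sg.r <= bp) left.push_back(std::move(sg));
            else if (sg.l >= bp) right.push_back(std::move(sg));
            else {
              left.push_back(Seg{sg.l, bp, sg.desc, sg.cnt});
              right.push_back(Seg{bp, sg.r, std::move(sg.desc), sg.cnt});
            }
          }
          if (!left.empty()) {
            if (first) { lins[k] = std::move(left); first = false; }
            else lins.push_back(std::move(left));
          }
          cur = std::move(right);
        }
        if (!cur.empty()) {
          if (first) lins[k] = std::move(cur);
          else lins.push_back(std::move(cur));
        }
      }
    }

    // parent assignment; shared parents coalesce
    std::vector<std::pair<long, size_t> > par;
    par.reserve(lins.size());
    std::vector<Lineage> nxt;
    nxt.reserve(lins.size());
    for (size_t k = 0; k < lins.size(); ++k) {
      long p = (long)(unif_rand() * (double)N2);
      if (p >= N2) p = N2 - 1;
      size_t hit = nxt.size();
      for (size_t q = 0; q < par.size(); ++q)
        if (par[q].first == p) { hit = par[q].second; break; }
      if (hit == nxt.size()) {
        par.push_back(std::make_pair(p, nxt.size()));
        nxt.push_back(std::move(lins[k]));
      } else {
        nxt[hit] = merge_lineages(std::move(nxt[hit]), std::move(lins[k]), n);
      }
    }
    lins.clear();
    for (size_t k = 0; k < nxt.size(); ++k)
      if (!nxt[k].empty()) lins.push_back(std::move(nxt[k]));
  }

  const int S = (int)mpos.size();
  IntegerMatrix geno(n, S);
  NumericVector pos(S);
  for (int j = 0; j < S; ++j) {
    pos[j] = mpos[j];
    const Bits& d = mdesc[j];
    for (int i = 0; i < n; ++i)
      if (d[i / 64] & ((uint64_t)1 << (i % 64))) geno(i, j) = 1;
  }
  return List::create(_["positions"] = pos, _["haplotypes"] = geno);
}

// ---------------------------------------------------------------------------
// Forward engine
// ---------------------------------------------------------------------------

namespace {

struct MutTab {
  std::vector<double> pos;
  std::vector<int> origin;  // -1 neutral, >= 0 adaptive origin label
};

typedef std::vector<int> Chrom;  // mutation ids sorted by position (ties by id)

struct PosLess {
  const MutTab* tab;
  bool operator()(int a, int b) const {
    if (tab->pos[a] != tab->pos[b]) return tab->pos[a] < tab->pos[b];
    return a < b;
  }
};

inline bool is_carrier(const Chrom& c, const MutTab& tab, double lhalf) {
  // adaptive mutations sit exactly at lhalf; neutral positions are continuous
  for (int id : c) {
    if (tab.pos[id] == lhalf && tab.origin[id] >= 0) return true;
    if (tab.pos[id] > lhalf) break;
  }
  return false;
}

inline int carrier_origin(const Chrom& c, const MutTab& tab, double lhalf) {
  for (int id : c) {
    if (tab.pos[id] == lhalf && tab.origin[id] >= 0) return tab.origin[id];
    if (tab.pos[id] > lhalf) break;
  }
  return -1;
}

void make_gamete(const Chrom& A, const Chrom& B, double r_bp, double mu_bp,
                 double L, MutTab& tab, Chrom& out, std::vector<double>& brk) {
  int nc = (int)R::rpois(r_bp * L);
  if (nc == 0) {
    out = (unif_rand() < 0.5) ? A : B;
  } else {
    brk.clear();
    for (int c = 0; c < nc; ++c) brk.push_back(unif_rand() * L);
    std::sort(brk.begin(), brk.end());
    brk.push_back(L + 1.0);
    const Chrom* src[2] = {&A, &B};
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    size_t ix[2] = {0, 0};
    out.clear();
    out.reserve(std::max(A.size(), B.size()) + 4);
    for (double bp : brk) {
      const Chrom& S = *src[cur];
      while (ix[cur] < S.size() && tab.pos[S[ix[cur]]] < bp) {
        out.push_back(S[ix[cur]]);
        ++ix[cur];
      }
      const Chrom& O = *src[1 - cur];
      while (ix[1 - cur] < O.size() && tab.pos[O[ix[1 - cur]]] < bp) ++ix[1 - cur];
      cur = 1 - cur;
    }
  }
  int nm = (int)R::rpois(mu_bp * L);
  for (int m = 0; m < nm; ++m) {
    int id = (int)tab.pos.size();
    tab.pos.push_back(unif_rand() * L);
    tab.origin.push_back(-1);
    PosLess cmp{&tab};
    out.insert(std::upper_bound(out.begin(), out.end(), id, cmp), id);
  }
}

void prune_fixed(std::vector<Chrom>& pop, MutTab& tab) {
  const size_t M = tab.pos.size();
  std::vector<int> cnt(M, 0);
  for (const Chrom& c : pop)
    for (int id : c) ++cnt[id];
  const int N2 = (int)pop.size();
  std::vector<char> drop(M, 0);
  bool any = false;
  for (size_t i = 0; i < M; ++i)
    if (cnt[i] == N2 && tab.origin[i] < 0) { drop[i] = 1; any = true; }
  if (!any) return;
  for (Chrom& c : pop) {
    size_t w = 0;
    for (size_t i = 0; i < c.size(); ++i)
      if (!drop[c[i]]) c[w++] = c[i];
    c.resize(w);
  }
}

}  // namespace

// Forward WF simulation from an initial population (list of integer vectors of
// 0-based mutation ids into init_pos/init_origin) through the per-generation
// chromosome counts n2_fwd (n2_fwd[0] must equal the initial population size;
// the final entry is the sampling generation).  mode: 0 neutral, 1 hard de
// novo, 2 recurrent de novo, 3 standing variation.  s, mu_bp, r_bp are the
// (already rescaled) per-generation parameters.
// [[Rcpp::export]]
List forward_sim_cpp(List init, NumericVector init_pos, IntegerVector init_origin,
                     IntegerVector n2_fwd, double mu_bp, double r_bp, double L,
                     int mode, double s, double thetaA, double f_init,
                     int sample_dip, int max_restarts) {
  const int G = n2_fwd.size() - 1;
  const double lhalf = 0.5 * L;
  const int n2_0 = n2_fwd[0];
  if ((int)init.size() != n2_0) stop("initial population size does not match n2_fwd[0]");
  for (int t = 0; t <= G; ++t) {
    if (n2_fwd[t] < 2 || n2_fwd[t] % 2 != 0)
      stop("population chromosome counts must be even and >= 2");
  }
  if (2 * sample_dip > n2_fwd[G]) stop("sample larger than final population");

  MutTab tab;
  tab.pos.assign(init_pos.begin(), init_pos.end());
  tab.origin.assign(init_origin.begin(), init_origin.end());
  const size_t base_mut = tab.pos.size();

  std::vector<Chrom> snap(n2_0);
  {
    PosLess cmp{&tab};
    for (int i = 0; i < n2_0; ++i) {
      IntegerVector v = init[i];
      snap[i].assign(v.begin(), v.end());
      std::sort(snap[i].begin(), snap[i].end(), cmp);
    }
  }

  std::vector<Chrom> pop;
  std::vector<Chrom> off;
  std::vector<double> brk;
  std::vector<double> cumw;

  int attempts = 0;
  int onset_gen = -1, carriers_at_onset = 0, distinct_at_onset = 0;
  int next_origin = 0;
  bool done = false;

  while (!done) {
    if (attempts > max_restarts)
      stop("adaptive mutation failed to establish after %d attempts", attempts);
    ++attempts;
    pop = snap;
    tab.pos.resize(base_mut);
    tab.origin.resize(base_mut);
    next_origin = 0;
    onset_gen = -1;
    carriers_at_onset = 0;
    distinct_at_onset = 0;
    bool onset = (mode == 1 || mode == 2);  // selection live from introduction
    bool lost = false;

    PosLess cmp{&tab};
    // introductions into the standing (generation-0) population
    if (mode == 1 || mode == 3) {
      int id = (int)tab.pos.size();
      tab.pos.push_back(lhalf);
      tab.origin.push_back(next_origin++);
      Chrom& c = pop[(int)(unif_rand() * n2_0) % n2_0];
      c.insert(std::upper_bound(c.begin(), c.end(), id, cmp), id);
    } else if (mode == 2) {
      int nnew = (int)R::rpois(thetaA / 2.0);
      for (int k = 0; k < nnew; ++k) {
        Chrom& c = pop[(int)(unif_rand() * n2_0) % n2_0];
        if (is_carrier(c, tab, lhalf)) continue;
        int id = (int)tab.pos.size();
        tab.pos.push_back(lhalf);
        tab.origin.push_back(next_origin++);
        c.insert(std::upper_bound(c.begin(), c.end(), id, cmp), id);
      }
    }
    if (mode == 3) {
      // onset may trigger immediately if f_init <= 1/2N
      if (1.0 / (double)n2_0 >= f_init) {
        onset = true;
        onset_gen = 0;
        carriers_at_onset = 1;
        distinct_at_onset = 1;
      }
    }

    for (int t = 1; t <= G; ++t) {
      const int n2_prev = (int)pop.size();
      const int Nprev = n2_prev / 2;
      const int n2_next = n2_fwd[t];
      const int Nnext = n2_next / 2;

      bool select = false;
      if (mode != 0 && s > 0 && onset) {
        cumw.assign(Nprev, 0.0);
        double acc = 0;
        bool any = false;
        for (int i = 0; i < Nprev; ++i) {
          int d = (is_carrier(pop[2 * i], tab, lhalf) ? 1 : 0) +
                  (is_carrier(pop[2 * i + 1], tab, lhalf) ? 1 : 0);
          if (d > 0) any = true;
          acc += 1.0 + s * 0.5 * (double)d;
          cumw[i] = acc;
        }
        select = any;
      }

      off.assign(n2_next, Chrom());
      for (int k = 0; k < Nnext; ++k) {
        int p1, p2;
        if (select) {
          double tot = cumw.back();
          p1 = (int)(std::lower_bound(cumw.begin(), cumw.end(), unif_rand() * tot) - cumw.begin());
          p2 = (int)(std::lower_bound(cumw.begin(), cumw.end(), unif_rand() * tot) - cumw.begin());
        } else {
          p1 = (int)(unif_rand() * Nprev) % Nprev;
          p2 = (int)(unif_rand() * Nprev) % Nprev;
        }
        make_gamete(pop[2 * p1], pop[2 * p1 + 1], r_bp, mu_bp, L, tab, off[2 * k], brk);
        make_gamete(pop[2 * p2], pop[2 * p2 + 1], r_bp, mu_bp, L, tab, off[2 * k + 1], brk);
      }
      pop.swap(off);

      if (mode == 2) {
        PosLess cmp2{&tab};
        int nnew = (int)R::rpois(thetaA / 2.0);
        for (int k = 0; k < nnew; ++k) {
          Chrom& c = pop[(int)(unif_rand() * n2_next) % n2_next];
          if (is_carrier(c, tab, lhalf)) continue;
          int id = (int)tab.pos.size();
          tab.pos.push_back(lhalf);
          tab.origin.push_back(next_origin++);
          c.insert(std::upper_bound(c.begin(), c.end(), id, cmp2), id);
        }
      }

      if (mode != 0) {
        int carriers = 0;
        for (const Chrom& c : pop)
          if (is_carrier(c, tab, lhalf)) ++carriers;
        if (mode == 3 && !onset && carriers > 0 &&
            (double)carriers / (double)n2_next >= f_init) {
          onset = true;
          onset_gen = t;
          carriers_at_onset = carriers;
          std::set<Chrom> uniq;
          for (const Chrom& c : pop)
            if (is_carrier(c, tab, lhalf)) uniq.insert(c);
          distinct_at_onset = (int)uniq.size();
        }
        if (carriers == 0) {
          if (mode == 1 || mode == 3) { lost = true; break; }
          if (mode == 2 && t == G) { lost = true; break; }
        }
        if (mode == 3 && !onset && t == G) { lost = true; break; }
      }

      if (t % 32 == 0) prune_fixed(pop, tab);
    }
    if (!lost) done = true;
  }

  // sample diploids without replacement, keeping chromosome pairing
  const int Nfin = (int)pop.size() / 2;
  std::vector<int> idx(Nfin);
  for (int i = 0; i < Nfin; ++i) idx[i] = i;
  for (int i = 0; i < sample_dip; ++i) {
    int j = i + (int)(unif_rand() * (Nfin - i));
    if (j >= Nfin) j = Nfin - 1;
    std::swap(idx[i], idx[j]);
  }
  const int ns = 2 * sample_dip;
  std::vector<const Chrom*> samp(ns);
  for (int i = 0; i < sample_dip; ++i) {
    samp[2 * i] = &pop[2 * idx[i]];
    samp[2 * i + 1] = &pop[2 * idx[i] + 1];
  }

  // segregating sites in the sample; adaptive origins collapse to one site
  std::vector<int> cnt(tab.pos.size(), 0);
  for (int i = 0; i < ns; ++i)
    for (int id : *samp[i]) ++cnt[id];
  int adap_carriers_sample = 0;
  std::set<int> samp_origins;
  for (int i = 0; i < ns; ++i) {
    int og = carrier_origin(*samp[i], tab, lhalf);
    if (og >= 0) { ++adap_carriers_sample; samp_origins.insert(og); }
  }
  std::vector<int> keep;  // neutral segregating site ids
  for (size_t id = 0; id < tab.pos.size(); ++id)
    if (tab.origin[id] < 0 && cnt[id] > 0 && cnt[id] < ns) keep.push_back((int)id);
  bool adap_col = (mode != 0 && adap_carriers_sample > 0 && adap_carriers_sample < ns);

  struct ColRef { double pos; int id; };  // id = -1 for the adaptive column
  std::vector<ColRef> cols;
  cols.reserve(keep.size() + 1);
  for (int id : keep) cols.push_back(ColRef{tab.pos[id], id});
  if (adap_col) cols.push_back(ColRef{lhalf, -1});
  std::sort(cols.begin(), cols.end(),
            [](const ColRef& a, const ColRef& b) { return a.pos < b.pos; });

  const int S = (int)cols.size();
  IntegerMatrix hap(ns, S);
  NumericVector pos(S);
  int adaptive_index = 0;
  std::vector<int> colof(tab.pos.size(), -1);
  for (int j = 0; j < S; ++j) {
    pos[j] = cols[j].pos;
    if (cols[j].id < 0) adaptive_index = j + 1;
    else colof[cols[j].id] = j;
  }
  for (int i = 0; i < ns; ++i) {
    for (int id : *samp[i]) {
      if (tab.origin[id] >= 0) {
        if (adaptive_index > 0) hap(i, adaptive_index - 1) = 1;
      } else if (colof[id] >= 0) {
        hap(i, colof[id]) = 1;
      }
    }
  }

  // population-level adaptive summary at sampling
  int pop_carriers = 0;
  std::set<int> pop_origins;
  for (const Chrom& c : pop) {
    int og = carrier_origin(c, tab, lhalf);
    if (og >= 0) { ++pop_carriers; pop_origins.insert(og); }
  }

  return List::create(
      _["positions"] = pos, _["haplotypes"] = hap,
      _["adaptive_index"] = adaptive_index,
      _["adaptive_pos"] = lhalf,
      _["sampled_origins"] = IntegerVector(samp_origins.begin(), samp_origins.end()),
      _["pop_origins"] = IntegerVector(pop_origins.begin(), pop_origins.end()),
      _["pop_adaptive_freq"] = (double)pop_carriers / (double)pop.size(),
      _["onset_gen"] = onset_gen,
      _["carriers_at_onset"] = carriers_at_onset,
      _["distinct_at_onset"] = distinct_at_onset,
      _["attempts"] = attempts);
}
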