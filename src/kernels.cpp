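#include <Rcpp.h>
#include <array>
using namespace Rcpp;

// A founder-labelled haplotype in merged form: segment i covers
// [ends[i-1], ends[i]) with ends[-1] := 0 and ends.back() == chromosome length.
struct Hap {
  std::vector<double> ends;
  std::vector<int> fdr;
};

static inline int hap_at(const Hap& h, double pos) {
  size_t i = std::upper_bound(h.ends.begin(), h.ends.end(), pos) - h.ends.begin();
  if (i >= h.fdr.size()) i = h.fdr.size() - 1;  // position == L clamps to last segment
  return h.fdr[i];
}

// One meiotic product under the Haldane model: crossover count ~ Poisson(L/100),
// positions iid uniform on (0, L), starting homolog a fair coin, homolog
// alternates at each crossover.  Uses R's RNG so set.seed() governs everything.
static Hap gamete(const Hap& a, const Hap& b, double L) {
  int k = (int) R::rpois(L / 100.0);
  std::vector<double> x(k);
  for (int i = 0; i < k; ++i) x[i] = unif_rand() * L;
  std::sort(x.begin(), x.end());
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  const Hap* src[2] = { &a, &b };
  Hap out;
  out.ends.reserve(8); out.fdr.reserve(8);
  double start = 0.0;
  for (int i = 0; i <= k; ++i) {
    double end = (i == k) ? L : x[i];
    if (end > start) {
      const Hap& s = *src[cur];
      size_t j = std::upper_bound(s.ends.begin(), s.ends.end(), start) - s.ends.begin();
      double seg_start = start;
      for (; j < s.ends.size() && seg_start < end; ++j) {
        double seg_end = std::min(s.ends[j], end);
        if (!out.fdr.empty() && out.fdr.back() == s.fdr[j]) {
          out.ends.back() = seg_end;
        } else {
          out.ends.push_back(seg_end);
          out.fdr.push_back(s.fdr[j]);
        }
        seg_start = seg_end;
      }
    }
    cur = 1 - cur;
    start = end;
  }
  out.ends.back() = L;
  return out;
}

static Hap hap_from_r(List h) {
  Hap out;
  NumericVector e = h["ends"];
  IntegerVector f = h["founder"];
  out.ends.assign(e.begin(), e.end());
  out.fdr.assign(f.begin(), f.end());
  return out;
}

static List hap_to_r(const Hap& h) {
  return List::create(_["ends"] = NumericVector(h.ends.begin(), h.ends.end()),
                      _["founder"] = IntegerVector(h.fdr.begin(), h.fdr.end()));
}

// [[Rcpp::export]]
List gamete_cpp(List hap1, List hap2, double len) {
  Hap a = hap_from_r(hap1), b = hap_from_r(hap2);
  return hap_to_r(gamete(a, b, len));
}

// Simulate every row of a pedigree (topologically ordered) and return the
// segment haplotypes of the terminal individuals.  p1/p2 are 1-based row
// indices of the parents (0 for founders); founder gives the founder label of
// founder rows.  Gametes are drawn in fixed row/chromosome order, so results
// are fully determined by the RNG state.
// [[Rcpp::export]]
List sim_pedigree_cpp(IntegerVector p1, IntegerVector p2, IntegerVector founder,
                      NumericVector chrlen, IntegerVector terminal) {
  int n = p1.size(), nc = chrlen.size(), nt = terminal.size();
  std::vector<std::vector<std::array<Hap, 2> > > pop(
      n, std::vector<std::array<Hap, 2> >(nc));
  for (int i = 0; i < n; ++i) {
    if (p1[i] == 0) {
      for (int c = 0; c < nc; ++c)
        for (int h = 0; h < 2; ++h) {
          pop[i][c][h].ends.assign(1, chrlen[c]);
          pop[i][c][h].fdr.assign(1, founder[i]);
        }
    } else {
      int a = p1[i] - 1, b = p2[i] - 1;
      for (int c = 0; c < nc; ++c) {
        pop[i][c][0] = gamete(pop[a][c][0], pop[a][c][1], chrlen[c]);
        pop[i][c][1] = gamete(pop[b][c][0], pop[b][c][1], chrlen[c]);
      }
    }
  }
  // Compact export: per chromosome, per homolog, concatenated segments with
  // 0-based offsets (length nt + 1).
  List chroms(nc);
  for (int c = 0; c < nc; ++c) {
    List homs(2);
    for (int h = 0; h < 2; ++h) {
      int total = 0;
      for (int t = 0; t < nt; ++t) total += pop[terminal[t] - 1][c][h].ends.size();
      NumericVector ends(total);
      IntegerVector fdr(total);
      IntegerVector off(nt + 1);
      int k = 0;
      for (int t = 0; t < nt; ++t) {
        const Hap& hp = pop[terminal[t] - 1][c][h];
        off[t] = k - 0;
        for (size_t j = 0; j < hp.ends.size(); ++j, ++k) {
          ends[k] = hp.ends[j];
          fdr[k] = hp.fdr[j];
        }
      }
      off[nt] = k;
      homs[h] = List::create(_["ends"] = ends, _["founder"] = fdr,
                             _["offsets"] = off);
    }
    chroms[c] = homs;
  }
  return chroms;
}

// Founder labels of many haplotypes at a common marker grid.
// ends/founder/offsets describe n_ind concatenated haplotypes (offsets is
// 0-based, length n_ind + 1); returns an n_ind x n_marker matrix.
// [[Rcpp::export]]
IntegerMatrix marker_labels_cpp(NumericVector ends, IntegerVector founder,
                                IntegerVector offsets, NumericVector markers) {
  int ni = offsets.size() - 1, nm = markers.size();
  IntegerMatrix out(ni, nm);
  for (int i = 0; i < ni; ++i) {
    int lo = offsets[i], hi = offsets[i + 1];
    int j = lo;
    for (int m = 0; m < nm; ++m) {
      while (j < hi - 1 && ends[j] <= markers[m]) ++j;
      out(i, m) = founder[j];
    }
  }
  return out;
}

// ---- Balanced funnel-set enumeration for 8 founders -------------------------
//
// A minimal balanced set is seven funnels whose two-way founder pairs form a
// 1-factorization of K8 (every pair exactly once) and whose four-way pair
// counts are all exactly 2 (the eight-way counts of 4 then follow because each
// founder pair meets exactly once per funnel).  Exact-cover backtracking on the
// two-way pairs: always branch on the smallest uncovered pair, so every set is
// produced exactly once.

static int pair_id(int i, int j) {  // i < j, 0-based founders
  return i * (15 - i) / 2 + (j - i - 1) - 0;  // index into the 28 pairs of 8
}

// [[Rcpp::export]]
IntegerMatrix balanced_sets8_cpp(IntegerMatrix funnels) {
  int nf = funnels.nrow();
  if (funnels.ncol() != 8) stop("funnels must have 8 columns");
  std::vector<uint32_t> two_mask(nf);
  std::vector<std::array<int, 8> > four(nf);
  for (int f = 0; f < nf; ++f) {
    uint32_t m = 0;
    for (int b = 0; b < 4; ++b) {
      int i = funnels(f, 2 * b) - 1, j = funnels(f, 2 * b + 1) - 1;
      if (i > j) std::swap(i, j);
      m |= (1u << pair_id(i, j));
    }
    two_mask[f] = m;
    int k = 0;
    for (int blk = 0; blk < 2; ++blk) {          // two four-way crosses
      for (int u = 0; u < 2; ++u)                // left two-way of the block
        for (int v = 2; v < 4; ++v) {            // right two-way of the block
          int i = funnels(f, 4 * blk + u) - 1, j = funnels(f, 4 * blk + v) - 1;
          if (i > j) std::swap(i, j);
          four[f][k++] = pair_id(i, j);
        }
    }
  }
  std::vector<std::array<int, 7> > sols;
  std::array<int, 28> cnt4{};
  std::array<int, 7> cur{};
  uint32_t full = (1u << 28) - 1;

  struct Rec {
    std::vector<uint32_t>& two_mask;
    std::vector<std::array<int, 8> >& four;
    std::vector<std::array<int, 7> >& sols;
    std::array<int, 28>& cnt4;
    std::array<int, 7>& cur;
    uint32_t full;
    int nf;
    void go(uint32_t used, int depth) {
      if (used == full) {
        sols.push_back(cur);
        return;
      }
      int p = 0;
      while (used & (1u << p)) ++p;  // smallest uncovered two-way pair
      for (int f = 0; f < nf; ++f) {
        if (!(two_mask[f] & (1u << p))) continue;
        if (two_mask[f] & used) continue;
        bool ok = true;
        for (int k = 0; k < 8; ++k)
          if (cnt4[four[f][k]] >= 2) { ok = false; break; }
        if (!ok) continue;
        for (int k = 0; k < 8; ++k) ++cnt4[four[f][k]];
        cur[depth] = f;
        go(used | two_mask[f], depth + 1);
        for (int k = 0; k < 8; ++k) --cnt4[four[f][k]];
      }
    }
  } rec{two_mask, four, sols, cnt4, cur, full, nf};
  rec.go(0u, 0);

  IntegerMatrix out(sols.size(), 7);
  for (size_t s = 0; s < sols.size(); ++s)
    for (int k = 0; k < 7; ++k) out(s, k) = sols[s][k] + 1;
  return out;
}
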