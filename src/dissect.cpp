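// Dynamic-programming dissection of a tableau against a concept dictionary.
//
// The R side precomputes, per tableau, the position-wise null costs (adaptive
// KT costs for SSE symbols and contact cells, plus the uniform angle cost for
// contacting pairs folded into `cellbase`).  Those per-position costs are
// constants of the tableau because the adaptive models condition on all
// previously transmitted or concept-implied symbols, so the objective
// decomposes additively over regions and the DP below is exact.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LOG2E = 1.4426950408889634;

struct PackedConcept {
  int n;
  IntegerVector sse;
  LogicalMatrix contact;
  NumericMatrix angle;
  double kappa;
  double const_bits;   // log2(2 pi I0(kappa) e^-kappa) - log2(eps_rad)
};

struct PackedTableau {
  int n;
  IntegerVector sse;
  LogicalMatrix contact;
  NumericMatrix angle;
  NumericVector kt_sse;
  NumericMatrix cellbase;  // KT cell cost + uniform angle cost if contacting
  double base_total;       // gamma(n+1) + sum of upper-triangle cellbase
};

static PackedConcept unpack_concept(const List& c) {
  PackedConcept pc;
  pc.n = as<int>(c["n"]);
  pc.sse = c["sse"];
  pc.contact = as<LogicalMatrix>(c["contact"]);
  pc.angle = as<NumericMatrix>(c["angle"]);
  pc.kappa = as<double>(c["kappa"]);
  pc.const_bits = as<double>(c["const_bits"]);
  return pc;
}

static PackedTableau unpack_tableau(const List& t) {
  PackedTableau pt;
  pt.n = as<int>(t["n"]);
  pt.sse = t["sse"];
  pt.contact = as<LogicalMatrix>(t["contact"]);
  pt.angle = as<NumericMatrix>(t["angle"]);
  pt.kt_sse = t["kt_sse"];
  pt.cellbase = as<NumericMatrix>(t["cellbase"]);
  pt.base_total = as<double>(t["base_total"]);
  return pt;
}

static inline double vm_bits(double delta_deg, double kappa, double const_bits) {
  double d = delta_deg * M_PI / 180.0;
  double bits = kappa * (1.0 - std::cos(d)) * LOG2E + const_bits;
  return bits > 0.0 ? bits : 0.0;
}

// Region cost of assigning concept c to 0-based span [a, a+m), minus the
// null base cost of the same cells.  Returns NA when the validity gate
// (identical SSE string; every archetype contact present) fails.
// When match_bits is non-null it receives the raw match cost.
static double concept_delta(const PackedTableau& t, const PackedConcept& c,
                            int a, double uniform_bits,
                            double flip_match, double flip_mis,
                            double* match_bits) {
  int m = c.n;
  for (int p = 0; p < m; ++p) {
    if (t.sse[a + p] != c.sse[p]) return NA_REAL;
  }
  for (int p = 0; p < m - 1; ++p) {
    for (int q = p + 1; q < m; ++q) {
      if (c.contact(p, q) && !t.contact(a + p, a + q)) return NA_REAL;
    }
  }
  double delta = 0.0, match = 0.0;
  for (int p = 0; p < m - 1; ++p) {
    for (int q = p + 1; q < m; ++q) {
      bool tc = t.contact(a + p, a + q);
      bool ac = c.contact(p, q);
      double bits = (tc == ac) ? flip_match : flip_mis;
      if (tc) {
        bits += ac ? vm_bits(t.angle(a + p, a + q) - c.angle(p, q),
                             c.kappa, c.const_bits)
                   : uniform_bits;
      }
      match += bits;
      delta += bits - t.cellbase(a + p, a + q);
    }
  }
  if (match_bits) *match_bits = match;
  return delta;
}

struct DPResult {
  double total;
  std::vector<int> choice;  // per end position j (1..n): -1 null, else concept
};

static DPResult dp_dissect(const PackedTableau& t,
                           const std::vector<PackedConcept>& concepts,
                           double label_bits, double uniform_bits,
                           double flip_match, double flip_mis) {
  int n = t.n;
  std::vector<double> best(n + 1, 0.0);
  std::vector<int> nreg(n + 1, 0), choice(n + 1, -1);
  const double tol = 1e-12;
  for (int j = 1; j <= n; ++j) {
    // null step: one SSE, adaptive symbol cost
    double bcost = best[j - 1] + label_bits + t.kt_sse[j - 1];
    int bnr = nreg[j - 1] + 1;
    int bchoice = -1;
    for (size_t ci = 0; ci < concepts.size(); ++ci) {
      const PackedConcept& c = concepts[ci];
      if (c.n > j) continue;
      int a = j - c.n;
      double delta = concept_delta(t, c, a, uniform_bits,
                                   flip_match, flip_mis, nullptr);
      if (ISNA(delta)) continue;
      double cost = best[a] + label_bits + delta;
      int nr = nreg[a] + 1;
      // tie-break: fewer regions, then earlier concept id (null first)
      bool take = cost < bcost - tol ||
        (cost <= bcost + tol && (nr < bnr));
      if (take) { bcost = cost; bnr = nr; bchoice = (int)ci; }
    }
    best[j] = bcost;
    nreg[j] = bnr;
    choice[j] = bchoice;
  }
  DPResult r;
  r.total = t.base_total + best[n];
  r.choice = choice;
  return r;
}

// Persistent packed collection so the annealing loop pays the R-to-C++
// conversion once, not per proposal.
typedef std::vector<PackedTableau> PackedCollection;

// [[Rcpp::export]]
SEXP cpp_pack_collection(List tabs) {
  XPtr<PackedCollection> ptr(new PackedCollection(), true);
  for (int i = 0; i < tabs.size(); ++i) {
    ptr->push_back(unpack_tableau(tabs[i]));
  }
  return ptr;
}

// [[Rcpp::export]]
double cpp_collection_total(SEXP collection, List concepts, double label_bits,
                            double uniform_bits, double flip_match,
                            double flip_mis) {
  XPtr<PackedCollection> tabs(collection);
  std::vector<PackedConcept> cs;
  for (int i = 0; i < concepts.size(); ++i) {
    cs.push_back(unpack_concept(concepts[i]));
  }
  double total = 0.0;
  for (size_t i = 0; i < tabs->size(); ++i) {
    total += dp_dissect((*tabs)[i], cs, label_bits, uniform_bits,
                        flip_match, flip_mis).total;
  }
  return total;
}

// Spans (tableau index, start, end) currently encoded by concept `target`
// (1-based) in the optimal dissections of the whole collection.
// [[Rcpp::export]]
IntegerMatrix cpp_collection_usages(SEXP collection, List concepts,
                                    double label_bits, double uniform_bits,
                                    double flip_match, double flip_mis,
                                    int target) {
  XPtr<PackedCollection> tabs(collection);
  std::vector<PackedConcept> cs;
  for (int i = 0; i < concepts.size(); ++i) {
    cs.push_back(unpack_concept(concepts[i]));
  }
  std::vector<int> out_tab, out_start, out_end;
  for (size_t ti = 0; ti < tabs->size(); ++ti) {
    const PackedTableau& t = (*tabs)[ti];
    DPResult r = dp_dissect(t, cs, label_bits, uniform_bits,
                            flip_match, flip_mis);
    int j = t.n;
    while (j > 0) {
      int ch = r.choice[j];
      if (ch < 0) { j -= 1; continue; }
      int a = j - cs[ch].n;
      if (ch + 1 == target) {
        out_tab.push_back((int)ti + 1);
        out_start.push_back(a + 1);
        out_end.push_back(j);
      }
      j = a;
    }
  }
  IntegerMatrix out(out_tab.size(), 3);
  for (size_t k = 0; k < out_tab.size(); ++k) {
    out(k, 0) = out_tab[k];
    out(k, 1) = out_start[k];
    out(k, 2) = out_end[k];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dissect(List tab, List concepts, double label_bits,
                 double uniform_bits, double flip_match, double flip_mis) {
  PackedTableau t = unpack_tableau(tab);
  std::vector<PackedConcept> cs;
  for (int i = 0; i < concepts.size(); ++i) {
    cs.push_back(unpack_concept(concepts[i]));
  }
  DPResult r = dp_dissect(t, cs, label_bits, uniform_bits,
                          flip_match, flip_mis);
  // traceback
  std::vector<int> starts, ends, cids;
  std::vector<double> bits;
  int j = t.n;
  while (j > 0) {
    int ch = r.choice[j];
    if (ch < 0) {
      starts.push_back(j); ends.push_back(j); cids.push_back(0);
      bits.push_back(t.kt_sse[j - 1]);
      j -= 1;
    } else {
      const PackedConcept& c = cs[ch];
      int a = j - c.n;
      double match = 0.0;
      concept_delta(t, c, a, uniform_bits, flip_match, flip_mis, &match);
      starts.push_back(a + 1); ends.push_back(j); cids.push_back(ch + 1);
      bits.push_back(match);
      j = a;
    }
  }
  int k = (int)starts.size();
  IntegerVector start(k), end(k), cid(k);
  NumericVector rbits(k);
  for (int i = 0; i < k; ++i) {        // reverse into left-to-right order
    start[i] = starts[k - 1 - i];
    end[i] = ends[k - 1 - i];
    cid[i] = cids[k - 1 - i];
    rbits[i] = bits[k - 1 - i];
  }
  return List::create(_["total"] = r.total,
                      _["start"] = start, _["end"] = end,
                      _["concept"] = cid, _["region_bits"] = rbits);
}
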