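#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <functional>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Sequential stochastic end-matching and aberration classification.
//
// All randomness goes through R's RNG (unif_rand / R::rpois) so that a single
// set.seed() on the R side makes every simulation reproducible.
// ---------------------------------------------------------------------------

namespace {

struct Junction {
  int a, b;  // 0-based end indices
};

// Fisher-Yates shuffle of 0..n-1 using R's RNG.
static std::vector<int> random_order(int n) {
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = static_cast<int>(std::floor(unif_rand() * (i + 1)));
    if (j > i) j = i;
    std::swap(ord[i], ord[j]);
  }
  return ord;
}

// Visit free ends in random order; each undecided end either pairs with an
// undecided non-sibling end (weight exp(-d/r0)) or stays permanently free
// (weight c_free).  Sibling ends (born at the same critical lesion) may never
// rejoin with each other: a CL produces two independent fragments.
static void rejoin_core(const std::vector<double>& ex,
                        const std::vector<double>& ey,
                        const std::vector<double>& ez,
                        const std::vector<int>& cl,
                        double r0, double c_free,
                        std::vector<Junction>& junc,
                        std::vector<int>& free_ends) {
  const int n = static_cast<int>(ex.size());
  std::vector<int> state(n, 0);  // 0 undecided, 1 paired, 2 permanently free
  std::vector<int> ord = random_order(n);
  // precompute pairwise weights once (each pair would otherwise be
  // evaluated up to twice during the visit scans)
  const double inv_r0 = 1.0 / r0;
  std::vector<double> W(static_cast<size_t>(n) * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = ex[j] - ex[i], dy = ey[j] - ey[i], dz = ez[j] - ez[i];
      double w2 = std::exp(-std::sqrt(dx * dx + dy * dy + dz * dz) * inv_r0);
      W[static_cast<size_t>(i) * n + j] = w2;
      W[static_cast<size_t>(j) * n + i] = w2;
    }
  }
  std::vector<int> cand;
  std::vector<double> w;
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    if (state[i] != 0) continue;
    cand.clear();
    w.clear();
    double wsum = 0.0;
    const double* Wi = &W[static_cast<size_t>(i) * n];
    for (int j = 0; j < n; ++j) {
      if (j == i || state[j] != 0 || cl[j] == cl[i]) continue;
      double wj = Wi[j];
      cand.push_back(j);
      w.push_back(wj);
      wsum += wj;
    }
    double total = wsum + c_free;
    if (cand.empty() || total <= 0.0) {
      // no eligible partner (only the sibling is left) -> permanently free,
      // regardless of c_free; likewise if every weight underflows to zero.
      state[i] = 2;
      free_ends.push_back(i);
      continue;
    }
    double u = unif_rand() * total;
    int chosen = -1;
    double acc = 0.0;
    for (size_t k = 0; k < cand.size(); ++k) {
      acc += w[k];
      if (u < acc) { chosen = cand[k]; break; }
    }
    if (chosen < 0) {
      state[i] = 2;
      free_ends.push_back(i);
    } else {
      state[i] = 1;
      state[chosen] = 1;
      Junction J;
      J.a = i;
      J.b = chosen;
      junc.push_back(J);
    }
  }
}

// Classify the junction graph over fragments into aberration categories.
// Components are paths or cycles (every end sits in at most one junction and
// every fragment has at most two free ends).  Conventions:
//   * linear or cyclic element with c >= 2 centromeres counts c - 1 dicentrics
//   * cyclic element with exactly 1 centromere is a centric ring
//   * acentric element with total length >= visibility_mbp is a deletion
struct Tally {
  int dic, rings, dels;
};

static Tally classify_core(int n_frag,
                           const std::vector<int>& end_frag,  // 0-based frag per end
                           const std::vector<char>& centric,
                           const std::vector<double>& frag_len,
                           const std::vector<Junction>& junc,
                           double visibility) {
  std::vector<int> parent(n_frag);
  for (int i = 0; i < n_frag; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (const Junction& J : junc) {
    int ra = find(end_frag[J.a]), rb = find(end_frag[J.b]);
    if (ra != rb) parent[ra] = rb;
  }
  std::vector<int> nodes(n_frag, 0), edges(n_frag, 0), cens(n_frag, 0);
  std::vector<double> len(n_frag, 0.0);
  for (int i = 0; i < n_frag; ++i) {
    int r = find(i);
    nodes[r] += 1;
    if (centric[i]) cens[r] += 1;
    len[r] += frag_len[i];
  }
  for (const Junction& J : junc) edges[find(end_frag[J.a])] += 1;
  Tally t;
  t.dic = t.rings = t.dels = 0;
  for (int r = 0; r < n_frag; ++r) {
    if (nodes[r] == 0 || find(r) != r) continue;
    bool cyclic = (edges[r] == nodes[r]);
    if (cens[r] == 0) {
      if (len[r] >= visibility) t.dels += 1;
    } else if (cens[r] == 1) {
      if (cyclic) t.rings += 1;
    } else {
      t.dic += cens[r] - 1;
    }
  }
  return t;
}

// One lesion: spatial position + chromosome + genomic coordinate.
struct Lesion {
  double x, y, z;
  int chrom;     // 0-based
  double coord;  // Mbp
};

// Build fragments and free ends from a lesion list, then rejoin + classify.
static Tally damage_cell(const std::vector<Lesion>& les,
                         const std::vector<double>& chrom_len,
                         const std::vector<double>& chrom_cen,
                         double r0, double c_free, double visibility) {
  const int n_chrom = static_cast<int>(chrom_len.size());
  // group lesion indices by chromosome
  std::vector<std::vector<int>> by_chrom(n_chrom);
  for (size_t i = 0; i < les.size(); ++i) by_chrom[les[i].chrom].push_back(static_cast<int>(i));

  std::vector<char> centric;
  std::vector<double> frag_len;
  std::vector<int> end_frag, end_cl;
  std::vector<double> ex, ey, ez;

  for (int c = 0; c < n_chrom; ++c) {
    std::vector<int>& idx = by_chrom[c];
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      return les[a].coord < les[b].coord;
    });
    double prev = 0.0;
    int frag_id = static_cast<int>(frag_len.size());
    // k lesions -> k+1 fragments covering (0, L)
    for (size_t j = 0; j <= idx.size(); ++j) {
      double hi = (j == idx.size()) ? chrom_len[c] : les[idx[j]].coord;
      frag_len.push_back(hi - prev);
      centric.push_back(prev < chrom_cen[c] && chrom_cen[c] < hi ? 1 : 0);
      prev = hi;
    }
    for (size_t j = 0; j < idx.size(); ++j) {
      const Lesion& L = les[idx[j]];
      // right end of fragment j, left end of fragment j+1; sibling pair
      for (int side = 0; side < 2; ++side) {
        end_frag.push_back(frag_id + static_cast<int>(j) + side);
        end_cl.push_back(idx[j]);
        ex.push_back(L.x);
        ey.push_back(L.y);
        ez.push_back(L.z);
      }
    }
  }

  std::vector<Junction> junc;
  std::vector<int> free_ends;
  rejoin_core(ex, ey, ez, end_cl, r0, c_free, junc, free_ends);
  return classify_core(static_cast<int>(frag_len.size()), end_frag, centric,
                       frag_len, junc, visibility);
}

// content-weighted chromosome draw from cumulative probabilities
static int draw_chrom(const std::vector<double>& cum) {
  double u = unif_rand();
  return static_cast<int>(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
}

static int nearest_seed(const NumericMatrix& seeds, double x, double y, double z) {
  int best = 0;
  double bd = R_PosInf;
  for (int k = 0; k < seeds.nrow(); ++k) {
    double dx = seeds(k, 0) - x, dy = seeds(k, 1) - y, dz = seeds(k, 2) - z;
    double d = dx * dx + dy * dy + dz * dz;
    if (d < bd) { bd = d; best = k; }
  }
  return best;
}

}  // namespace

// [[Rcpp::export]]
List cpp_rejoin(NumericMatrix pos, IntegerVector cl_id, double r0, double c_free) {
  int n = pos.nrow();
  std::vector<double> ex(n), ey(n), ez(n);
  std::vector<int> cl(n);
  for (int i = 0; i < n; ++i) {
    ex[i] = pos(i, 0);
    ey[i] = pos(i, 1);
    ez[i] = pos(i, 2);
    cl[i] = cl_id[i];
  }
  std::vector<Junction> junc;
  std::vector<int> free_ends;
  rejoin_core(ex, ey, ez, cl, r0, c_free, junc, free_ends);
  IntegerMatrix jm(static_cast<int>(junc.size()), 2);
  for (size_t k = 0; k < junc.size(); ++k) {
    jm(static_cast<int>(k), 0) = junc[k].a + 1;
    jm(static_cast<int>(k), 1) = junc[k].b + 1;
  }
  IntegerVector fv(free_ends.begin(), free_ends.end());
  for (int i = 0; i < fv.size(); ++i) fv[i] += 1;
  return List::create(_["junctions"] = jm, _["free"] = fv);
}

// [[Rcpp::export]]
IntegerVector cpp_classify(IntegerMatrix junctions, IntegerVector end_frag,
                           LogicalVector frag_centric, NumericVector frag_len,
                           double visibility) {
  int n_frag = frag_len.size();
  std::vector<int> ef(end_frag.size());
  for (int i = 0; i < end_frag.size(); ++i) ef[i] = end_frag[i] - 1;
  std::vector<char> cen(n_frag);
  std::vector<double> fl(n_frag);
  for (int i = 0; i < n_frag; ++i) {
    cen[i] = frag_centric[i] ? 1 : 0;
    fl[i] = frag_len[i];
  }
  std::vector<Junction> junc(junctions.nrow());
  for (int k = 0; k < junctions.nrow(); ++k) {
    junc[k].a = junctions(k, 0) - 1;
    junc[k].b = junctions(k, 1) - 1;
  }
  Tally t = classify_core(n_frag, ef, cen, fl, junc, visibility);
  return IntegerVector::create(_["dicentrics"] = t.dic,
                               _["centric_rings"] = t.rings,
                               _["deletions"] = t.dels,
                               _["dicentrics_plus_rings"] = t.dic + t.rings);
}

// Fused per-cell simulator: track sampling, CL placement, fragmentation,
// rejoining and classification for n_cells independent nuclei at one dose.
// field_type: 0 = photon (cl_yield in CL Gy^-1 cell^-1, CLs uniform in the
// nuclear volume), 1 = ion (cl_yield in CL um^-1 along straight parallel
// tracks; fluence Phi = dose / (0.1602 * LET)).
// mode: 0 = content_weighted, 1 = voronoi_territories (seeds: 46 x 3).
// [[Rcpp::export]]
IntegerMatrix cpp_simulate_cells(int n_cells, int field_type, double dose,
                                 double let, double cl_yield, double radius,
                                 NumericVector chrom_len, NumericVector chrom_cen,
                                 int mode, NumericMatrix seeds,
                                 double r0, double c_free, double visibility) {
  const int n_chrom = chrom_len.size();
  std::vector<double> len(n_chrom), cen(n_chrom), cum(n_chrom);
  double tot = 0.0;
  for (int i = 0; i < n_chrom; ++i) {
    len[i] = chrom_len[i];
    cen[i] = chrom_cen[i];
    tot += len[i];
  }
  double acc = 0.0;
  for (int i = 0; i < n_chrom; ++i) {
    acc += len[i] / tot;
    cum[i] = acc;
  }
  cum[n_chrom - 1] = 1.0;

  const double area = M_PI * radius * radius;
  IntegerMatrix out(n_cells, 4);
  colnames(out) = CharacterVector::create("dicentrics", "centric_rings",
                                          "deletions", "dicentrics_plus_rings");
  std::vector<Lesion> les;
  for (int cell = 0; cell < n_cells; ++cell) {
    les.clear();
    if (field_type == 1) {
      double phi = dose / (0.1602 * let);
      int n_tracks = static_cast<int>(R::rpois(phi * area));
      for (int tnum = 0; tnum < n_tracks; ++tnum) {
        double b = radius * std::sqrt(unif_rand());  // uniform over disc
        double theta = 2.0 * M_PI * unif_rand();
        double cx = b * std::cos(theta), cy = b * std::sin(theta);
        double half = std::sqrt(std::max(0.0, radius * radius - b * b));
        double chord = 2.0 * half;
        int n_cl = static_cast<int>(R::rpois(cl_yield * chord));
        for (int k = 0; k < n_cl; ++k) {
          Lesion L;
          L.x = cx;
          L.y = cy;
          L.z = -half + unif_rand() * chord;
          L.chrom = (mode == 1) ? nearest_seed(seeds, L.x, L.y, L.z)
                                : draw_chrom(cum);
          L.coord = unif_rand() * len[L.chrom];
          les.push_back(L);
        }
      }
    } else {
      int n_cl = static_cast<int>(R::rpois(dose * cl_yield));
      for (int k = 0; k < n_cl; ++k) {
        // uniform in sphere
        double r = radius * std::cbrt(unif_rand());
        double zc = 2.0 * unif_rand() - 1.0;
        double phi2 = 2.0 * M_PI * unif_rand();
        double s = std::sqrt(std::max(0.0, 1.0 - zc * zc));
        Lesion L;
        L.x = r * s * std::cos(phi2);
        L.y = r * s * std::sin(phi2);
        L.z = r * zc;
        L.chrom = draw_chrom(cum);
        L.coord = unif_rand() * len[L.chrom];
        les.push_back(L);
      }
    }
    Tally t = damage_cell(les, len, cen, r0, c_free, visibility);
    out(cell, 0) = t.dic;
    out(cell, 1) = t.rings;
    out(cell, 2) = t.dels;
    out(cell, 3) = t.dic + t.rings;
  }
  return out;
}
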