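// Core of the forward simulator: haplotypes as sparse change-point lists,
// single-crossover meiosis on a genetic map, X/0 sex determination,
// fitness-weighted mating, paternal-toxin/zygotic-antidote lethality,
// and marker-frequency queries. All randomness goes through R's RNG so
// set.seed() at the R level makes every simulation reproducible.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

// A haplotype over one chromosome: parental origin of the first segment
// (0 = allele-A parent, 1 = allele-B parent) plus strictly increasing
// change-points in bp. origin(bp) = start XOR parity(#cuts < bp).
// start == -1 marks an absent haplotype (male X second slot, nullo-X gamete).
struct Hap {
  int start = 0;
  std::vector<double> cuts;
};

static inline int origin_at(const Hap &h, double bp) {
  size_t k = std::lower_bound(h.cuts.begin(), h.cuts.end(), bp) - h.cuts.begin();
  return h.start ^ (int)(k & 1u);
}

struct Chrom {
  std::vector<double> mbp, mcm; // map anchors
  double cmlen = 0.0;
  bool is_x = false;
};

struct Genome {
  std::vector<Chrom> chr;
  int x_idx = -1; // -1 when no X flagged
};

static Genome parse_genome(List g) {
  Genome gen;
  int nc = g.size();
  gen.chr.resize(nc);
  for (int c = 0; c < nc; ++c) {
    List ch = g[c];
    NumericVector bp = ch["bp"], cm = ch["cm"];
    gen.chr[c].mbp.assign(bp.begin(), bp.end());
    gen.chr[c].mcm.assign(cm.begin(), cm.end());
    gen.chr[c].cmlen = gen.chr[c].mcm.back() - gen.chr[c].mcm.front();
    gen.chr[c].is_x = as<bool>(ch["is_x"]);
    if (gen.chr[c].is_x) gen.x_idx = c;
  }
  return gen;
}

// cM -> bp, piecewise linear between anchors (cm measured from first anchor)
static inline double cm_to_bp_c(const Chrom &ch, double cm) {
  double target = ch.mcm.front() + cm;
  size_t k = std::upper_bound(ch.mcm.begin(), ch.mcm.end(), target) - ch.mcm.begin();
  if (k == 0) return ch.mbp.front();
  if (k >= ch.mcm.size()) return ch.mbp.back();
  double f = (target - ch.mcm[k - 1]) / (ch.mcm[k] - ch.mcm[k - 1]);
  return ch.mbp[k - 1] + f * (ch.mbp[k] - ch.mbp[k - 1]);
}

struct Pop {
  int n = 0;
  std::vector<int> sex;                              // 0 female, 1 male
  std::vector<std::array<std::vector<Hap>, 2>> hap;  // [chrom][slot][ind]
};

static Pop unpack_pop(List p) {
  Pop pop;
  pop.n = as<int>(p["n"]);
  IntegerVector sex = p["sex"];
  pop.sex.assign(sex.begin(), sex.end());
  List chrom = p["chrom"];
  int nc = chrom.size();
  pop.hap.resize(nc);
  for (int c = 0; c < nc; ++c) {
    List ch = chrom[c];
    for (int s = 0; s < 2; ++s) {
      IntegerVector start = ch[s == 0 ? "start1" : "start2"];
      IntegerVector off = ch[s == 0 ? "off1" : "off2"];
      NumericVector cuts = ch[s == 0 ? "cuts1" : "cuts2"];
      pop.hap[c][s].resize(pop.n);
      for (int i = 0; i < pop.n; ++i) {
        Hap &h = pop.hap[c][s][i];
        h.start = (start[i] == NA_INTEGER) ? -1 : start[i];
        if (h.start >= 0)
          h.cuts.assign(cuts.begin() + off[i], cuts.begin() + off[i + 1]);
      }
    }
  }
  return pop;
}

static List pack_pop(const Pop &pop) {
  int nc = pop.hap.size();
  List chrom(nc);
  for (int c = 0; c < nc; ++c) {
    List ch;
    for (int s = 0; s < 2; ++s) {
      IntegerVector start(pop.n), off(pop.n + 1);
      size_t tot = 0;
      for (int i = 0; i < pop.n; ++i) tot += pop.hap[c][s][i].cuts.size();
      NumericVector cuts(tot);
      size_t k = 0;
      off[0] = 0;
      for (int i = 0; i < pop.n; ++i) {
        const Hap &h = pop.hap[c][s][i];
        start[i] = (h.start < 0) ? NA_INTEGER : h.start;
        for (double x : h.cuts) cuts[k++] = x;
        off[i + 1] = (int)k;
      }
      ch[s == 0 ? "start1" : "start2"] = start;
      ch[s == 0 ? "off1" : "off2"] = off;
      ch[s == 0 ? "cuts1" : "cuts2"] = cuts;
    }
    chrom[c] = ch;
  }
  return List::create(_["n"] = pop.n,
                      _["sex"] = IntegerVector(pop.sex.begin(), pop.sex.end()),
                      _["chrom"] = chrom);
}

// Join two haplotypes at breakpoint x: A for bp <= x, B for bp > x.
static Hap cross_haps(const Hap &A, const Hap &B, double x) {
  Hap g;
  g.start = A.start;
  size_t ka = std::lower_bound(A.cuts.begin(), A.cuts.end(), x) - A.cuts.begin();
  g.cuts.assign(A.cuts.begin(), A.cuts.begin() + ka);
  int oA = A.start ^ (int)(ka & 1u);
  size_t kb = std::lower_bound(B.cuts.begin(), B.cuts.end(), x) - B.cuts.begin();
  int oB = B.start ^ (int)(kb & 1u);
  if (oA != oB) g.cuts.push_back(x);
  g.cuts.insert(g.cuts.end(), B.cuts.begin() + kb, B.cuts.end());
  return g;
}

// One gamete for one chromosome from a diploid parent. With probability
// p_xo a single crossover is placed uniformly in cM and one of the two
// reciprocal products is returned; otherwise one parental haplotype is
// copied unchanged.
static Hap gamete_chrom(const Hap &h1, const Hap &h2, const Chrom &ch, double p_xo) {
  if (unif_rand() < p_xo) {
    double x = cm_to_bp_c(ch, unif_rand() * ch.cmlen);
    return (unif_rand() < 0.5) ? cross_haps(h1, h2, x) : cross_haps(h2, h1, x);
  }
  return (unif_rand() < 0.5) ? h1 : h2;
}

static inline int dosage_at(const Pop &pop, int c, int i, double bp, int &ploidy) {
  const Hap &h1 = pop.hap[c][0][i], &h2 = pop.hap[c][1][i];
  int d = 0;
  ploidy = 0;
  if (h1.start >= 0) { d += origin_at(h1, bp); ++ploidy; }
  if (h2.start >= 0) { d += origin_at(h2, bp); ++ploidy; }
  return d; // dosage of the B (origin 1) allele
}

struct DriveSpec {
  bool active = false;
  int chrom = 0;      // 0-based
  double bp = 0;
  int allele = 0;     // origin code of the element-bearing allele (0 = A)
  double s = 0;       // penetrance
};

static DriveSpec parse_drive(RObject drive) {
  DriveSpec d;
  if (drive.isNULL()) return d;
  List dl(drive);
  d.active = true;
  d.chrom = as<int>(dl["chrom"]) - 1;
  d.bp = as<double>(dl["bp"]);
  d.allele = as<int>(dl["allele"]);
  d.s = as<double>(dl["s"]);
  return d;
}

struct FitLocus {
  int chrom;
  double bp;
  double w[3]; // weight by genotype (0,1,2 copies of B); hemizygous uses w[0]/w[2]
};

static std::vector<FitLocus> parse_fitness(RObject fit) {
  std::vector<FitLocus> out;
  if (fit.isNULL()) return out;
  List fl(fit);
  for (int k = 0; k < fl.size(); ++k) {
    List l = fl[k];
    FitLocus f;
    f.chrom = as<int>(l["chrom"]) - 1;
    f.bp = as<double>(l["bp"]);
    NumericVector w = l["w"];
    f.w[0] = w[0]; f.w[1] = w[1]; f.w[2] = w[2];
    out.push_back(f);
  }
  return out;
}

static double fitness_weight(const Pop &pop, int i, const std::vector<FitLocus> &loci) {
  double w = 1.0;
  for (const FitLocus &f : loci) {
    int ploidy;
    int d = dosage_at(pop, f.chrom, i, f.bp, ploidy);
    w *= (ploidy == 2) ? f.w[d] : f.w[2 * d];
  }
  return w;
}

// Make one zygote from mother mi and father fi; returns survival.
static bool make_offspring(const Pop &pop, const Genome &gen, int mi, int fi,
                           double p_xo, const DriveSpec &drive,
                           std::vector<Hap> *mat, std::vector<Hap> *pat, int &sex) {
  int nc = gen.chr.size();
  // sex decided by the paternal X/0 gamete
  bool x_bearing_sperm = (unif_rand() < 0.5);
  sex = (gen.x_idx >= 0) ? (x_bearing_sperm ? 0 : 1) : ((unif_rand() < 0.5) ? 0 : 1);
  for (int c = 0; c < nc; ++c) {
    const Chrom &ch = gen.chr[c];
    if (ch.is_x) {
      mat[c][0] = gamete_chrom(pop.hap[c][0][mi], pop.hap[c][1][mi], ch, p_xo);
      if (sex == 0) pat[c][0] = pop.hap[c][0][fi]; // father's single X, unrecombined
      else pat[c][0].start = -1, pat[c][0].cuts.clear();
    } else {
      mat[c][0] = gamete_chrom(pop.hap[c][0][mi], pop.hap[c][1][mi], ch, p_xo);
      pat[c][0] = gamete_chrom(pop.hap[c][0][fi], pop.hap[c][1][fi], ch, p_xo);
    }
  }
  if (drive.active) {
    int ploidy;
    int fd = dosage_at(pop, drive.chrom, fi, drive.bp, ploidy);
    int father_elem = (drive.allele == 1) ? fd : ploidy - fd;
    if (father_elem > 0) {
      int zb = origin_at(mat[drive.chrom][0], drive.bp) +
               origin_at(pat[drive.chrom][0], drive.bp);
      int zygote_elem = (drive.allele == 1) ? zb : 2 - zb;
      if (zygote_elem == 0 && unif_rand() < drive.s) return false;
    }
  }
  return true;
}

// Weighted father index sampler (with replacement).
struct FatherSampler {
  std::vector<int> males;
  std::vector<double> cum;
  double tot = 0;
  bool uniform = true;
  int draw() const {
    if (uniform) {
      int k = (int)(unif_rand() * males.size());
      if (k >= (int)males.size()) k = males.size() - 1;
      return males[k];
    }
    double u = unif_rand() * tot;
    size_t k = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
    if (k >= males.size()) k = males.size() - 1;
    return males[k];
  }
};

static FatherSampler father_sampler(const Pop &pop, const std::vector<FitLocus> &loci) {
  FatherSampler fs;
  for (int i = 0; i < pop.n; ++i)
    if (pop.sex[i] == 1) fs.males.push_back(i);
  if (!loci.empty()) {
    fs.uniform = false;
    fs.cum.resize(fs.males.size());
    for (size_t k = 0; k < fs.males.size(); ++k) {
      fs.tot += fitness_weight(pop, fs.males[k], loci);
      fs.cum[k] = fs.tot;
    }
  }
  return fs;
}

// [[Rcpp::export]]
List cpp_propagate(List pop_r, List genome_r, double p_xo, int progeny, int cap,
                   RObject fitness_r, RObject drive_r) {
  Pop pop = unpack_pop(pop_r);
  Genome gen = parse_genome(genome_r);
  DriveSpec drive = parse_drive(drive_r);
  std::vector<FitLocus> loci = parse_fitness(fitness_r);
  int nc = gen.chr.size();

  std::vector<int> females;
  for (int i = 0; i < pop.n; ++i)
    if (pop.sex[i] == 0) females.push_back(i);
  FatherSampler fs = father_sampler(pop, loci);
  if (females.empty() || fs.males.empty())
    stop("population lacks one sex; cannot mate");

  Pop off;
  off.hap.resize(nc);
  // scratch gamete buffers (one chromosome slot each)
  std::vector<std::vector<Hap>> mat(nc), pat(nc);
  for (int c = 0; c < nc; ++c) { mat[c].resize(1); pat[c].resize(1); }

  for (int mi : females) {
    int fi = fs.draw();
    for (int k = 0; k < progeny; ++k) {
      int sex;
      if (!make_offspring(pop, gen, mi, fi, p_xo, drive,
                          mat.data(), pat.data(), sex)) continue;
      off.sex.push_back(sex);
      for (int c = 0; c < nc; ++c) {
        off.hap[c][0].push_back(std::move(mat[c][0]));
        off.hap[c][1].push_back(std::move(pat[c][0]));
      }
      ++off.n;
    }
  }
  if (off.n == 0) stop("extinction: no offspring survived");

  if (off.n > cap) {
    // partial Fisher-Yates without replacement
    std::vector<int> idx(off.n);
    for (int i = 0; i < off.n; ++i) idx[i] = i;
    for (int i = 0; i < cap; ++i) {
      int j = i + (int)(unif_rand() * (off.n - i));
      if (j >= off.n) j = off.n - 1;
      std::swap(idx[i], idx[j]);
    }
    Pop kept;
    kept.n = cap;
    kept.hap.resize(nc);
    kept.sex.resize(cap);
    for (int c = 0; c < nc; ++c) {
      kept.hap[c][0].resize(cap);
      kept.hap[c][1].resize(cap);
    }
    for (int i = 0; i < cap; ++i) {
      kept.sex[i] = off.sex[idx[i]];
      for (int c = 0; c < nc; ++c) {
        kept.hap[c][0][i] = std::move(off.hap[c][0][idx[i]]);
        kept.hap[c][1][i] = std::move(off.hap[c][1][idx[i]]);
      }
    }
    return pack_pop(kept);
  }
  return pack_pop(off);
}

// Progeny of a single mother x father pairing (drive lethality applied).
// [[Rcpp::export]]
List cpp_mate(List pop_r, List genome_r, int mother, int father, int n_progeny,
              double p_xo, RObject drive_r) {
  Pop pop = unpack_pop(pop_r);
  Genome gen = parse_genome(genome_r);
  DriveSpec drive = parse_drive(drive_r);
  int nc = gen.chr.size();
  int mi = mother - 1, fi = father - 1;
  if (pop.sex[mi] != 0 || pop.sex[fi] != 1)
    stop("mate() requires a female mother and a male father");
  Pop off;
  off.hap.resize(nc);
  std::vector<std::vector<Hap>> mat(nc), pat(nc);
  for (int c = 0; c < nc; ++c) { mat[c].resize(1); pat[c].resize(1); }
  for (int k = 0; k < n_progeny; ++k) {
    int sex;
    if (!make_offspring(pop, gen, mi, fi, p_xo, drive,
                        mat.data(), pat.data(), sex)) continue;
    off.sex.push_back(sex);
    for (int c = 0; c < nc; ++c) {
      off.hap[c][0].push_back(std::move(mat[c][0]));
      off.hap[c][1].push_back(std::move(pat[c][0]));
    }
    ++off.n;
  }
  return pack_pop(off);
}

// n gametes from one parent, as a packed haplotype set per chromosome.
// Male X gametes return the father's X (the mate() step decides X/0 sperm).
// [[Rcpp::export]]
List cpp_gametes(List pop_r, List genome_r, int parent, int n, double p_xo) {
  Pop pop = unpack_pop(pop_r);
  Genome gen = parse_genome(genome_r);
  int i = parent - 1, nc = gen.chr.size();
  List out(nc);
  for (int c = 0; c < nc; ++c) {
    const Chrom &ch = gen.chr[c];
    const Hap &h1 = pop.hap[c][0][i], &h2 = pop.hap[c][1][i];
    IntegerVector start(n), off(n + 1);
    std::vector<double> cuts;
    off[0] = 0;
    for (int k = 0; k < n; ++k) {
      Hap g = (h2.start < 0) ? h1 : gamete_chrom(h1, h2, ch, p_xo);
      start[k] = g.start;
      cuts.insert(cuts.end(), g.cuts.begin(), g.cuts.end());
      off[k + 1] = (int)cuts.size();
    }
    out[c] = List::create(_["start"] = start, _["off"] = off,
                          _["cuts"] = NumericVector(cuts.begin(), cuts.end()));
  }
  return out;
}

// B-allele count and total allele count per marker. Markers must be sorted
// by (chrom, bp); chrom is the 0-based chromosome index per marker.
// [[Rcpp::export]]
List cpp_marker_counts(List pop_r, List genome_r, IntegerVector chrom0,
                       NumericVector bp) {
  Pop pop = unpack_pop(pop_r);
  Genome gen = parse_genome(genome_r);
  int m = bp.size();
  NumericVector nB(m), tot(m);
  int lo = 0;
  while (lo < m) {
    int c = chrom0[lo];
    int hi = lo;
    while (hi < m && chrom0[hi] == c) ++hi;
    int mc = hi - lo;
    const double *mbp = &bp[lo];
    std::vector<double> diff(mc + 1, 0.0);
    double nhap = 0;
    for (int s = 0; s < 2; ++s) {
      for (int i = 0; i < pop.n; ++i) {
        const Hap &h = pop.hap[c][s][i];
        if (h.start < 0) continue;
        nhap += 1;
        // haplotype segments (c_{j-1}, c_j] carry origin start^(j&1);
        // add +1 over the marker-index range of each B-origin segment
        int k = (int)h.cuts.size();
        for (int j = 0; j <= k; ++j) {
          if ((h.start ^ (j & 1)) != 1) continue;
          double a = (j == 0) ? -1.0 : h.cuts[j - 1];
          double b = (j == k) ? HUGE_VAL : h.cuts[j];
          int i0 = std::upper_bound(mbp, mbp + mc, a) - mbp;
          int i1 = std::upper_bound(mbp, mbp + mc, b) - mbp;
          if (i1 > i0) { diff[i0] += 1; diff[i1] -= 1; }
        }
      }
    }
    double acc = 0;
    for (int k = 0; k < mc; ++k) {
      acc += diff[k];
      nB[lo + k] = acc;
      tot[lo + k] = nhap;
    }
    lo = hi;
  }
  return List::create(_["nB"] = nB, _["tot"] = tot);
}

// Per-individual B-allele dosage at one locus (0/1 for hemizygous males on X).
// [[Rcpp::export]]
IntegerVector cpp_dosage(List pop_r, List genome_r, int chrom, double bp) {
  Pop pop = unpack_pop(pop_r);
  Genome gen = parse_genome(genome_r);
  IntegerVector out(pop.n);
  for (int i = 0; i < pop.n; ++i) {
    int ploidy;
    out[i] = dosage_at(pop, chrom - 1, i, bp, ploidy);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_subset_pop(List pop_r, IntegerVector idx) {
  Pop pop = unpack_pop(pop_r);
  Pop out;
  int nc = pop.hap.size();
  out.n = idx.size();
  out.sex.resize(out.n);
  out.hap.resize(nc);
  for (int c = 0; c < nc; ++c) {
    out.hap[c][0].resize(out.n);
    out.hap[c][1].resize(out.n);
  }
  for (int k = 0; k < out.n; ++k) {
    int i = idx[k] - 1;
    out.sex[k] = pop.sex[i];
    for (int c = 0; c < nc; ++c) {
      out.hap[c][0][k] = pop.hap[c][0][i];
      out.hap[c][1][k] = pop.hap[c][1][i];
    }
  }
  return pack_pop(out);
}

// Tri-cube kernel smoothing of g over genetic distance, per chromosome.
// Markers must be sorted by (chrom, cm). Weights (1 - D^3)^3 with
// D = |cm_j - cm_s| / half_width, normalised to sum to one in the window.
// [[Rcpp::export]]
NumericVector cpp_tricube(NumericVector g, NumericVector cm, IntegerVector chrom,
                          double half_width) {
  int m = g.size();
  NumericVector out(m);
  int lo = 0, hi = 0;
  for (int s = 0; s < m; ++s) {
    if (lo < s && chrom[lo] != chrom[s]) lo = s;
    while (lo < s && cm[lo] < cm[s] - half_width) ++lo;
    if (hi < s) hi = s;
    while (hi + 1 < m && chrom[hi + 1] == chrom[s] && cm[hi + 1] <= cm[s] + half_width)
      ++hi;
    // hi may overshoot from a previous, wider window on the same chromosome
    while (hi > s && (chrom[hi] != chrom[s] || cm[hi] > cm[s] + half_width)) --hi;
    double sw = 0, acc = 0;
    for (int j = lo; j <= hi; ++j) {
      double D = std::abs(cm[j] - cm[s]) / half_width;
      double w = 1.0 - D * D * D;
      w = w * w * w;
      sw += w;
      acc += w * g[j];
    }
    out[s] = acc / sw;
  }
  return out;
}
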