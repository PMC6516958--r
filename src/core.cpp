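#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <vector>
#include <queue>
using namespace Rcpp;

// 2-bit encode; -1 for anything that is not A/C/G/T
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline uint64_t rc_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

// Canonical k-mer occurrence counts at every start position of every
// sequence.  The count attached to a k-mer is its occurrence count over BOTH
// strands of the whole genome (a palindromic k-mer therefore counts twice per
// genomic site).  Positions whose window contains a non-ACGT base get NA.
// [[Rcpp::export]]
List cpp_kmer_position_counts(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  int nseq = seqs.size();
  std::unordered_map<uint64_t, int> counts;
  std::vector<std::vector<int64_t>> codes_per_seq(nseq);

  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int s = 0; s < nseq; ++s) {
    std::string seq = as<std::string>(seqs[s]);
    int n = seq.size();
    int nwin = n - k + 1;
    std::vector<int64_t>& codes = codes_per_seq[s];
    if (nwin <= 0) { continue; }
    codes.assign(nwin, -1);
    uint64_t code = 0;
    int valid = 0; // length of current run of ACGT ending at i
    for (int i = 0; i < n; ++i) {
      int b = base_code(seq[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        int start = i - k + 1;
        uint64_t rc = rc_code(code, k);
        uint64_t canon = code < rc ? code : rc;
        counts[canon] += (code == rc) ? 2 : 1;
        codes[start] = (int64_t)canon;
      }
    }
  }

  List out(nseq);
  for (int s = 0; s < nseq; ++s) {
    std::vector<int64_t>& codes = codes_per_seq[s];
    IntegerVector v(codes.size(), NA_INTEGER);
    for (size_t i = 0; i < codes.size(); ++i)
      if (codes[i] >= 0) v[i] = counts[(uint64_t)codes[i]];
    out[s] = v;
  }
  return out;
}

// Both-strand occurrence count of one k-mer across all sequences.
// [[Rcpp::export]]
int cpp_kmer_count_query(CharacterVector seqs, std::string kmer) {
  int k = kmer.size();
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  uint64_t q = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(kmer[i]);
    if (b < 0) stop("query k-mer contains a non-ACGT character");
    q = (q << 2) | (uint64_t)b;
  }
  uint64_t qrc = rc_code(q, k);
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  long total = 0;
  for (int s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    uint64_t code = 0;
    int valid = 0;
    for (size_t i = 0; i < seq.size(); ++i) {
      int b = base_code(seq[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        if (code == q) ++total;
        if (code == qrc) ++total; // palindrome counts twice, one per strand
      }
    }
  }
  return (int)total;
}

// Longest self-complementary stem: substrings A = seq[a..a+s), B = seq[b..b+s)
// with B == revcomp(A) and loop b - (a + s) >= min_loop.  DP over pairings
// (i, j): run[i][j] = run of complementary pairs ending with i paired to j.
// [[Rcpp::export]]
int cpp_longest_stem(std::string seq, int min_loop) {
  int n = seq.size();
  if (n < 2) return 0;
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);
  int best = 0;
  // prev[j]: run length for (i-1, j+1); updated row by row over i
  std::vector<int> prev(n, 0), cur(n, 0);
  for (int i = 0; i < n; ++i) {
    for (int j = n - 1; j > i; --j) {
      bool comp = code[i] >= 0 && code[j] >= 0 && code[i] + code[j] == 3;
      int run = 0;
      if (comp) run = ((j + 1 < n) ? prev[j + 1] : 0) + 1;
      cur[j] = run;
      // pairing (i, j) closes the stem innermost; loop is seq(i+1 .. j-1)
      if (run > 0 && (j - i - 1) >= min_loop && run > best) best = run;
    }
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), 0);
  }
  return best;
}

struct NN { double dh, ds; };

// Unified nearest-neighbor parameters (kcal/mol, cal/mol/K), indexed by
// 4*first+second with symmetric dinucleotides folded onto their canonical
// representative.
static void nn_tables(double* dh, double* ds) {
  auto set = [&](const char* d, double h, double s) {
    int a = base_code(d[0]), b = base_code(d[1]);
    dh[4 * a + b] = h; ds[4 * a + b] = s;
  };
  set("AA", -7.6, -21.3); set("TT", -7.6, -21.3);
  set("AT", -7.2, -20.4);
  set("TA", -7.2, -21.3);
  set("CA", -8.5, -22.7); set("TG", -8.5, -22.7);
  set("GT", -8.4, -22.4); set("AC", -8.4, -22.4);
  set("CT", -7.8, -21.0); set("AG", -7.8, -21.0);
  set("GA", -8.2, -22.2); set("TC", -8.2, -22.2);
  set("CG", -10.6, -27.2);
  set("GC", -9.8, -24.4);
  set("GG", -8.0, -19.9); set("CC", -8.0, -19.9);
}

// Nearest-neighbor melting temperature in degrees C.  Entropic salt
// correction 0.368 * (N-1) * ln[Na+]; formamide depresses Tm linearly.
// [[Rcpp::export]]
double cpp_tm_nn(std::string seq, double na_conc, double oligo_conc,
                 double formamide_pct, double formamide_coef) {
  int n = seq.size();
  if (n < 8) stop("sequence must be at least 8 nt for nearest-neighbor Tm");
  double dh_tab[16], ds_tab[16];
  nn_tables(dh_tab, ds_tab);
  double dh = 0.2, ds = -5.7; // duplex initiation
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) {
    code[i] = base_code(seq[i]);
    if (code[i] < 0) stop("sequence contains a non-ACGT character");
  }
  for (int i = 0; i + 1 < n; ++i) {
    dh += dh_tab[4 * code[i] + code[i + 1]];
    ds += ds_tab[4 * code[i] + code[i + 1]];
  }
  // terminal A/T penalties
  if (code[0] == 0 || code[0] == 3) { dh += 2.2; ds += 6.9; }
  if (code[n - 1] == 0 || code[n - 1] == 3) { dh += 2.2; ds += 6.9; }
  ds += 0.368 * (n - 1) * std::log(na_conc);
  const double R = 1.987;
  double tm = 1000.0 * dh / (ds + R * std::log(oligo_conc / 4.0)) - 273.15;
  tm -= formamide_coef * formamide_pct;
  return tm;
}

// Full candidate-window scan used by probe mining.  poscnt holds the
// both-strand canonical count for the k-mer starting at each position
// (NA where the k-mer window contains N).  A window of length L starting at s
// passes uniqueness iff every constituent k-mer count is <= max_hits.
// Returns passing windows with their Tm and GC.
// [[Rcpp::export]]
DataFrame cpp_scan_windows(std::string seq, IntegerVector poscnt, int L, int k,
                           double gc_min, double gc_max,
                           double tm_min, double tm_max,
                           double na_conc, double oligo_conc,
                           int max_hits, int max_homopolymer,
                           int max_dinuc_units, int max_stem, int min_loop) {
  int n = seq.size();
  int nwin = n - L + 1;
  std::vector<int> starts;
  std::vector<double> tms, gcs;
  if (nwin <= 0)
    return DataFrame::create(_["start"] = IntegerVector(0),
                             _["tm"] = NumericVector(0),
                             _["gc"] = NumericVector(0));

  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);

  // prefix sums: GC, NN dH/dS, uniqueness violations, repeat marks
  double dh_tab[16], ds_tab[16];
  nn_tables(dh_tab, ds_tab);
  std::vector<double> gc_ps(n + 1, 0.0), dh_ps(n, 0.0), ds_ps(n, 0.0);
  std::vector<int> badk_ps(n + 1, 0);   // k-mer windows violating uniqueness
  std::vector<int> hp_ps(n + 1, 0);     // starts of (max_homopolymer+1)-runs
  std::vector<int> di_ps(n + 1, 0);     // starts of (max_dinuc_units+1)-unit period-2 repeats
  for (int i = 0; i < n; ++i)
    gc_ps[i + 1] = gc_ps[i] + ((code[i] == 1 || code[i] == 2) ? 1 : 0);
  for (int i = 0; i + 1 < n; ++i) {
    double h = 0, s2 = 0;
    if (code[i] >= 0 && code[i + 1] >= 0) {
      h = dh_tab[4 * code[i] + code[i + 1]];
      s2 = ds_tab[4 * code[i] + code[i + 1]];
    }
    dh_ps[i + 1] = dh_ps[i] + h;
    ds_ps[i + 1] = ds_ps[i] + s2;
  }
  int nk = poscnt.size();
  for (int i = 0; i < n; ++i) {
    int bad = 0;
    if (i < nk) {
      int c = poscnt[i];
      if (c == NA_INTEGER || c > max_hits) bad = 1;
    }
    badk_ps[i + 1] = badk_ps[i] + bad;
  }
  int hp_len = max_homopolymer + 1;
  for (int i = 0; i <= n; ++i) hp_ps[i] = 0;
  for (int i = 0; i + hp_len <= n; ++i) {
    bool run = code[i] >= 0;
    for (int j = 1; run && j < hp_len; ++j) run = code[i + j] == code[i];
    hp_ps[i + 1] = run ? 1 : 0;
  }
  for (int i = 0; i < n; ++i) hp_ps[i + 1] += hp_ps[i];
  int di_len = 2 * (max_dinuc_units + 1);
  std::vector<int> dimark(n + 1, 0);
  for (int i = 0; i + di_len <= n; ++i) {
    bool rep = code[i] >= 0 && code[i + 1] >= 0;
    for (int j = 2; rep && j < di_len; ++j) rep = code[i + j] == code[i + j - 2];
    dimark[i + 1] = rep ? 1 : 0;
  }
  for (int i = 0; i < n; ++i) dimark[i + 1] += dimark[i];

  const double R = 1.987;
  double conc_term = R * std::log(oligo_conc / 4.0);
  double salt_ds = 0.368 * (L - 1) * std::log(na_conc);

  for (int s = 0; s < nwin; ++s) {
    // uniqueness: k-mer starts s .. s+L-k must all be clean
    if (badk_ps[s + L - k + 1] - badk_ps[s] > 0) continue;
    double gc = (gc_ps[s + L] - gc_ps[s]) / (double)L;
    if (gc < gc_min || gc > gc_max) continue;
    // repeats
    if (s + L - hp_len >= s) {
      if (hp_ps[s + L - hp_len + 1] - hp_ps[s] > 0) continue;
    }
    if (L >= di_len) {
      if (dimark[s + L - di_len + 1] - dimark[s] > 0) continue;
    }
    // Tm
    double dh = 0.2 + dh_ps[s + L - 1] - dh_ps[s];
    double ds = -5.7 + ds_ps[s + L - 1] - ds_ps[s];
    if (code[s] == 0 || code[s] == 3) { dh += 2.2; ds += 6.9; }
    if (code[s + L - 1] == 0 || code[s + L - 1] == 3) { dh += 2.2; ds += 6.9; }
    double tm = 1000.0 * dh / (ds + salt_ds + conc_term) - 273.15;
    if (tm < tm_min || tm > tm_max) continue;
    // secondary structure (most expensive; evaluated last)
    if (cpp_longest_stem(seq.substr(s, L), min_loop) > max_stem) continue;
    starts.push_back(s);
    tms.push_back(tm);
    gcs.push_back(gc);
  }
  return DataFrame::create(_["start"] = wrap(starts), _["tm"] = wrap(tms),
                           _["gc"] = wrap(gcs));
}

// 3D connected-component labeling (breadth-first flood fill) of a binary
// mask laid out as an array with dims (nz, ny, nx), column-major as in R.
// connectivity: 6 (faces) or 26 (faces + edges + corners).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dz, dy, dx});
      }

  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next;
    labels[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z = cur % nz;
      int y = (cur / nz) % ny;
      int x = cur / ((R_xlen_t)nz * ny);
      for (auto& o : offs) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = (R_xlen_t)xx * nz * ny + (R_xlen_t)yy * nz + zz;
        if (mask[j] && labels[j] == 0) {
          labels[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Separable 3D Gaussian blur, reflective boundaries; sigma in voxels.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(NumericVector img, IntegerVector dims,
                                  double sigma) {
  if (dims.size() != 3) stop("dims must have length 3");
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (img.size() != n) stop("image length does not match dims");
  if (sigma <= 0) {
    NumericVector out = clone(img);
    out.attr("dim") = dims;
    return out;
  }
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * radius + 1);
  double ksum = 0;
  for (int i = -radius; i <= radius; ++i) {
    kern[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    ksum += kern[i + radius];
  }
  for (auto& v : kern) v /= ksum;

  std::vector<double> a(img.begin(), img.end()), b(n);
  auto idx = [&](int z, int y, int x) {
    return (R_xlen_t)x * nz * ny + (R_xlen_t)y * nz + z;
  };
  auto reflect = [](int i, int m) {
    while (i < 0 || i >= m) { if (i < 0) i = -i - 1; if (i >= m) i = 2 * m - i - 1; }
    return i;
  };
  // z axis
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double acc = 0;
        for (int d = -radius; d <= radius; ++d)
          acc += kern[d + radius] * a[idx(reflect(z + d, nz), y, x)];
        b[idx(z, y, x)] = acc;
      }
  std::swap(a, b);
  // y axis
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double acc = 0;
        for (int d = -radius; d <= radius; ++d)
          acc += kern[d + radius] * a[idx(z, reflect(y + d, ny), x)];
        b[idx(z, y, x)] = acc;
      }
  std::swap(a, b);
  // x axis
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double acc = 0;
        for (int d = -radius; d <= radius; ++d)
          acc += kern[d + radius] * a[idx(z, y, reflect(x + d, nx))];
        b[idx(z, y, x)] = acc;
      }
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dims;
  return out;
}
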