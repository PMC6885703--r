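// Core numeric engine: binding-core enumeration, input encoding, and the
// per-example SGD training loop of the one-hidden-layer two-output network.
// Layout of one encoded input vector (length n_in):
//   [ core block: core_len * 20 | aux block: n_aux | pseudo block: pseudo_len * 20 ]
// Aux block: length one-hot over [len_min, len_max], scaled insertion length,
// scaled deletion length, 3 indel gross-position flags (N-term/middle/C-term);
// class II additionally mean-encoded PFRs (2 x 20) and 2 scaled PFR lengths.
#include <Rcpp.h>
#include <cstring>
#include <string>
#include <vector>
#include <unordered_set>
using namespace Rcpp;

static const char AA_ORDER[] = "ACDEFGHIKLMNPQRSTVWYX"; // 20 standard + wildcard
static const int N_AA = 20;
static const int X_IDX = 20;
static const double INDEL_CAP = 4.0;   // indel lengths scaled as min(len,4)/4
static const int TERM_WINDOW = 3;      // indel within 3 positions of a terminus
static const int PFR_WINDOW = 3;       // class II flanking window

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static int aa_index(char c) {
  const char* p = std::strchr(AA_ORDER, c);
  if (p == nullptr || c == '\0') return -1;
  return (int)(p - AA_ORDER);
}

struct Core {
  std::vector<int> res;   // core_len residue indices (0-based, 20 = X)
  int del_len, del_start, ins_len, ins_start;
};

// Enumerate candidate binding cores of a peptide (residue indices, 0-based).
// L == core_len: identity. L > core_len: one contiguous deletion block of
// d = L - core_len residues at every start position (including termini),
// deduplicated. L < core_len: a wildcard block of core_len - L inserted at
// every interior position, deduplicated. First occurrence kept.
static std::vector<Core> enum_cores(const std::vector<int>& pep, int core_len) {
  const int L = (int)pep.size();
  std::vector<Core> out;
  std::unordered_set<std::string> seen;
  auto push = [&](std::vector<int> res, int dl, int ds, int il, int is) {
    std::string key(res.begin(), res.end());
    if (seen.insert(key).second) {
      Core c; c.res = std::move(res);
      c.del_len = dl; c.del_start = ds; c.ins_len = il; c.ins_start = is;
      out.push_back(std::move(c));
    }
  };
  if (L == core_len) {
    push(pep, 0, 0, 0, 0);
  } else if (L > core_len) {
    const int d = L - core_len;
    for (int s = 0; s <= L - d; ++s) {
      std::vector<int> res;
      res.reserve(core_len);
      for (int i = 0; i < s; ++i) res.push_back(pep[i]);
      for (int i = s + d; i < L; ++i) res.push_back(pep[i]);
      push(std::move(res), d, s, 0, 0);
    }
  } else {
    const int d = core_len - L;
    for (int s = 1; s <= L - 1; ++s) { // interior insertion points only
      std::vector<int> res;
      res.reserve(core_len);
      for (int i = 0; i < s; ++i) res.push_back(pep[i]);
      for (int i = 0; i < d; ++i) res.push_back(X_IDX);
      for (int i = s; i < L; ++i) res.push_back(pep[i]);
      push(std::move(res), 0, 0, d, s);
    }
  }
  return out;
}

static std::vector<int> pep_to_idx(const std::string& p) {
  std::vector<int> v(p.size());
  for (size_t i = 0; i < p.size(); ++i) {
    int k = aa_index(p[i]);
    if (k < 0) stop("illegal symbol '%s' in peptide '%s'",
                    std::string(1, p[i]).c_str(), p.c_str());
    v[i] = k;
  }
  return v;
}

// [[Rcpp::export]]
List cpp_enumerate_cores(std::string peptide, int core_len) {
  std::vector<int> pep = pep_to_idx(peptide);
  std::vector<Core> cs = enum_cores(pep, core_len);
  int n = (int)cs.size();
  CharacterVector core(n);
  IntegerVector dl(n), ds(n), il(n), is(n);
  for (int i = 0; i < n; ++i) {
    std::string s(core_len, ' ');
    for (int j = 0; j < core_len; ++j) s[j] = AA_ORDER[cs[i].res[j]];
    core[i] = s;
    dl[i] = cs[i].del_len; ds[i] = cs[i].del_start;
    il[i] = cs[i].ins_len; is[i] = cs[i].ins_start;
  }
  return List::create(_["core"] = core, _["deletion_length"] = dl,
                      _["deletion_start"] = ds, _["insertion_length"] = il,
                      _["insertion_start"] = is);
}

// Aux features for one core. aux must be zero-initialized, length n_aux.
static void core_aux_features(const Core& c, int L, int len_min, int len_max,
                              bool class2, const double* encT, double* aux) {
  const int n_len = len_max - len_min + 1;
  int li = L - len_min;
  if (li < 0) li = 0;
  if (li >= n_len) li = n_len - 1;
  aux[li] = 1.0;
  int pos = n_len;
  aux[pos++] = std::min((double)c.ins_len, INDEL_CAP) / INDEL_CAP;
  aux[pos++] = std::min((double)c.del_len, INDEL_CAP) / INDEL_CAP;
  // gross indel position flags: N-term / middle / C-term
  if (c.del_len > 0 || c.ins_len > 0) {
    int s = c.del_len > 0 ? c.del_start : c.ins_start;
    int e = c.del_len > 0 ? c.del_start + c.del_len : c.ins_start;
    if (s <= TERM_WINDOW - 1) aux[pos + 0] = 1.0;
    else if (e >= L - (TERM_WINDOW - 1)) aux[pos + 2] = 1.0;
    else aux[pos + 1] = 1.0;
  }
  pos += 3;
  if (class2) {
    // PFRs exist only when the deletion block touches a terminus; mean-encode
    // up to PFR_WINDOW flanking residues on each side.
    // left flank: deleted prefix (block start 0); right flank: deleted suffix.
    // (pfp = pointer into peptide indices provided via c.res? need peptide) --
    // handled by caller via pfr residue lists below.
    (void)encT; // filled by caller
  }
}

// Encode a set of peptides into the flat core/aux arrays used by the trainer.
// encT: 20 x 21 matrix (column r = encoding row of residue r).
// [[Rcpp::export]]
List cpp_encode_dataset(CharacterVector peptides, int core_len, int len_min,
                        int len_max, bool class2, NumericMatrix encT) {
  const int n_rec = peptides.size();
  const int n_len = len_max - len_min + 1;
  const int n_aux = n_len + 2 + 3 + (class2 ? 2 * N_AA + 2 : 0);
  const double* et = REAL(encT);
  std::vector<int> core_res;
  std::vector<double> core_aux;
  IntegerVector core_off(n_rec + 1);
  core_off[0] = 0;
  int total = 0;
  for (int r = 0; r < n_rec; ++r) {
    std::string p = as<std::string>(peptides[r]);
    const int L = (int)p.size();
    if (L < len_min || L > len_max)
      stop("peptide '%s' outside length bounds [%d, %d]", p.c_str(), len_min, len_max);
    std::vector<int> pep = pep_to_idx(p);
    std::vector<Core> cs = enum_cores(pep, core_len);
    for (const Core& c : cs) {
      for (int j = 0; j < core_len; ++j) core_res.push_back(c.res[j]);
      std::vector<double> aux(n_aux, 0.0);
      core_aux_features(c, L, len_min, len_max, class2, et, aux.data());
      if (class2) {
        int base = n_len + 5;
        // flanking residues from a terminal deletion block
        std::vector<int> left, right;
        if (c.del_len > 0 && c.del_start == 0) {
          int from = std::max(0, c.del_len - PFR_WINDOW);
          for (int i = from; i < c.del_len; ++i) left.push_back(pep[i]);
        }
        if (c.del_len > 0 && c.del_start + c.del_len == L) {
          int to = std::min(L, c.del_start + PFR_WINDOW);
          for (int i = c.del_start; i < to; ++i) right.push_back(pep[i]);
        }
        if (!left.empty())
          for (int d = 0; d < N_AA; ++d) {
            double s = 0; for (int k : left) s += et[d + N_AA * k];
            aux[base + d] = s / left.size();
          }
        if (!right.empty())
          for (int d = 0; d < N_AA; ++d) {
            double s = 0; for (int k : right) s += et[d + N_AA * k];
            aux[base + N_AA + d] = s / right.size();
          }
        aux[base + 2 * N_AA] = std::min((double)left.size(), (double)PFR_WINDOW) / PFR_WINDOW;
        aux[base + 2 * N_AA + 1] = std::min((double)right.size(), (double)PFR_WINDOW) / PFR_WINDOW;
      }
      core_aux.insert(core_aux.end(), aux.begin(), aux.end());
      ++total;
    }
    core_off[r + 1] = total;
  }
  return List::create(_["core_res"] = IntegerVector(core_res.begin(), core_res.end()),
                      _["core_aux"] = NumericVector(core_aux.begin(), core_aux.end()),
                      _["core_off"] = core_off, _["n_aux"] = n_aux,
                      _["core_len"] = core_len);
}

struct Net {
  double *W1, *b1, *W2, *b2;
  int nin, nh;
};

struct Data {
  const int* core_res;
  const double* core_aux;
  const int* core_off;
  const double* enT;        // 20 x 21
  const double* allele_enc; // pseudo_dim x n_alleles
  const double* target;
  const int* out;           // 0 = BA, 1 = EL
  int core_len, n_aux, pseudo_dim, off_aux, off_pseudo;
};

static Data unpack_data(List data) {
  Data d;
  d.core_res = INTEGER(as<IntegerVector>(data["core_res"]));
  d.core_aux = REAL(as<NumericVector>(data["core_aux"]));
  d.core_off = INTEGER(as<IntegerVector>(data["core_off"]));
  d.enT = REAL(as<NumericMatrix>(data["enc_t"]));
  d.allele_enc = REAL(as<NumericMatrix>(data["allele_enc"]));
  d.target = REAL(as<NumericVector>(data["target"]));
  d.out = INTEGER(as<IntegerVector>(data["out"]));
  d.core_len = as<int>(data["core_len"]);
  d.n_aux = as<int>(data["n_aux"]);
  d.pseudo_dim = as<NumericMatrix>(data["allele_enc"]).nrow();
  d.off_aux = d.core_len * N_AA;
  d.off_pseudo = d.off_aux + d.n_aux;
  return d;
}

static inline double ddot(const double* __restrict a,
                          const double* __restrict b, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += a[i] * b[i];
  return s;
}

// two dot products sharing the same x (halves x bandwidth)
static inline void ddot2(const double* __restrict x,
                         const double* __restrict w0,
                         const double* __restrict w1, int n,
                         double* s0, double* s1) {
  double a = 0.0, b = 0.0;
  for (int i = 0; i < n; ++i) {
    a += x[i] * w0[i];
    b += x[i] * w1[i];
  }
  *s0 = a; *s1 = b;
}

static inline void daxpy(double* __restrict y, const double* __restrict x,
                         double a, int n) {
  for (int i = 0; i < n; ++i) y[i] -= a * x[i];
}

// materialize the dense [core | aux] block of core c into xc (length off_pseudo)
static inline void fill_core_input(const Data& d, int c, double* __restrict xc) {
  const int* res = d.core_res + (size_t)d.core_len * c;
  for (int p = 0; p < d.core_len; ++p)
    std::memcpy(xc + (size_t)N_AA * p, d.enT + (size_t)N_AA * res[p],
                N_AA * sizeof(double));
  std::memcpy(xc + d.off_aux, d.core_aux + (size_t)d.n_aux * c,
              d.n_aux * sizeof(double));
}

// hidden pre-activations contributed by the pseudo-sequence block (+ bias)
static void pseudo_preact(const Net& net, const Data& d, int a, double* hp) {
  const int nh = net.nh, nin = net.nin;
  const double* pe = d.allele_enc + (size_t)d.pseudo_dim * a;
  int j = 0;
  for (; j + 1 < nh; j += 2)
    ddot2(pe, net.W1 + (size_t)nin * j + d.off_pseudo,
          net.W1 + (size_t)nin * (j + 1) + d.off_pseudo, d.pseudo_dim,
          &hp[j], &hp[j + 1]);
  for (; j < nh; ++j)
    hp[j] = ddot(pe, net.W1 + (size_t)nin * j + d.off_pseudo, d.pseudo_dim);
  for (j = 0; j < nh; ++j) hp[j] += net.b1[j];
}

// forward pass for record r against allele a; returns best score on output k,
// stores best core (global index) and its hidden activations.
// scratch must hold >= 2*nh + off_pseudo doubles. If hp_cached, scratch[0..nh)
// already holds the pseudo pre-activations for allele a.
static double fwd_record(const Net& net, const Data& d, int r, int a, int k,
                         int* best_core, double* hbest, double* scratch,
                         bool hp_cached = false) {
  const int nh = net.nh, nin = net.nin;
  double* hp = scratch;
  double* h = scratch + nh;
  double* xc = scratch + 2 * nh;
  if (!hp_cached) pseudo_preact(net, d, a, hp);
  double best = -1.0;
  int bc = -1;
  for (int c = d.core_off[r]; c < d.core_off[r + 1]; ++c) {
    fill_core_input(d, c, xc);
    int j = 0;
    for (; j + 1 < nh; j += 2) {
      double s0, s1;
      ddot2(xc, net.W1 + (size_t)nin * j, net.W1 + (size_t)nin * (j + 1),
            d.off_pseudo, &s0, &s1);
      h[j] = sigm(hp[j] + s0);
      h[j + 1] = sigm(hp[j + 1] + s1);
    }
    for (; j < nh; ++j)
      h[j] = sigm(hp[j] + ddot(xc, net.W1 + (size_t)nin * j, d.off_pseudo));
    double o = sigm(net.b2[k] + ddot(h, net.W2 + (size_t)nh * k, nh));
    if (o > best) {
      best = o; bc = c;
      std::memcpy(hbest, h, nh * sizeof(double));
    }
  }
  *best_core = bc;
  return best;
}

// One epoch of per-example SGD over `order` (0-based record indices).
// Squared-error gradient of the relevant output neuron only, backpropagated
// through the argmax core (hard max). Weights updated in place on copies.
// [[Rcpp::export]]
List cpp_epoch(NumericMatrix W1, NumericVector b1, NumericMatrix W2,
               NumericVector b2, List data, IntegerVector order,
               IntegerVector rec_allele, double lr) {
  NumericMatrix W1c = clone(W1); NumericVector b1c = clone(b1);
  NumericMatrix W2c = clone(W2); NumericVector b2c = clone(b2);
  Net net; net.W1 = REAL(W1c); net.b1 = REAL(b1c);
  net.W2 = REAL(W2c); net.b2 = REAL(b2c);
  net.nin = W1c.nrow(); net.nh = W1c.ncol();
  Data d = unpack_data(data);
  const int* ra = INTEGER(rec_allele);
  const int nh = net.nh, nin = net.nin;
  std::vector<double> h(nh), dh(nh), scratch(2 * nh + d.off_pseudo),
    x(nin);
  for (int oi = 0; oi < order.size(); ++oi) {
    const int r = order[oi];
    const int a = ra[r];
    if (a < 0) stop("record %d has no allele annotation", r + 1);
    const int k = d.out[r];
    int bc;
    double o = fwd_record(net, d, r, a, k, &bc, h.data(), scratch.data());
    const double e = o - d.target[r];
    if (e == 0.0) continue;
    const double dout = e * o * (1.0 - o);
    double* w2 = net.W2 + (size_t)nh * k;
    for (int j = 0; j < nh; ++j) {
      dh[j] = dout * w2[j] * h[j] * (1.0 - h[j]);
      w2[j] -= lr * dout * h[j];
    }
    net.b2[k] -= lr * dout;
    // dense input of the argmax core: [core | aux | pseudo]
    fill_core_input(d, bc, x.data());
    std::memcpy(x.data() + d.off_pseudo, d.allele_enc + (size_t)d.pseudo_dim * a,
                d.pseudo_dim * sizeof(double));
    {
      const double* __restrict xp = x.data();
      int j = 0;
      for (; j + 1 < nh; j += 2) {
        const double c0 = lr * dh[j], c1 = lr * dh[j + 1];
        double* __restrict w0 = net.W1 + (size_t)nin * j;
        double* __restrict w1 = net.W1 + (size_t)nin * (j + 1);
        for (int i = 0; i < nin; ++i) {
          const double xi = xp[i];
          w0[i] -= c0 * xi;
          w1[i] -= c1 * xi;
        }
        net.b1[j] -= c0;
        net.b1[j + 1] -= c1;
      }
      for (; j < nh; ++j) {
        const double coef = lr * dh[j];
        daxpy(net.W1 + (size_t)nin * j, xp, coef, nin);
        net.b1[j] -= coef;
      }
    }
  }
  return List::create(_["W1"] = W1c, _["b1"] = b1c, _["W2"] = W2c, _["b2"] = b2c);
}

// Max-core prediction for a subset of records. rec_idx, allele_idx 0-based.
// [[Rcpp::export]]
List cpp_predict(NumericMatrix W1, NumericVector b1, NumericMatrix W2,
                 NumericVector b2, List data, IntegerVector rec_idx,
                 IntegerVector allele_idx, int out_idx) {
  Net net; net.W1 = REAL(W1); net.b1 = REAL(b1);
  net.W2 = REAL(W2); net.b2 = REAL(b2);
  net.nin = W1.nrow(); net.nh = W1.ncol();
  Data d = unpack_data(data);
  const int n = rec_idx.size();
  NumericVector score(n);
  IntegerVector core(n);
  std::vector<double> h(net.nh), scratch(2 * net.nh + d.off_pseudo);
  int prev_a = -1;
  for (int i = 0; i < n; ++i) {
    int bc;
    const int a = allele_idx[i];
    score[i] = fwd_record(net, d, rec_idx[i], a, out_idx, &bc,
                          h.data(), scratch.data(), a == prev_a);
    prev_a = a;
    core[i] = bc;
  }
  return List::create(_["score"] = score, _["core"] = core);
}

// Scores of every candidate core of each requested record (flat, in core order).
// [[Rcpp::export]]
NumericVector cpp_predict_cores(NumericMatrix W1, NumericVector b1,
                                NumericMatrix W2, NumericVector b2, List data,
                                IntegerVector rec_idx, IntegerVector allele_idx,
                                int out_idx) {
  Net net; net.W1 = REAL(W1); net.b1 = REAL(b1);
  net.W2 = REAL(W2); net.b2 = REAL(b2);
  net.nin = W1.nrow(); net.nh = W1.ncol();
  Data d = unpack_data(data);
  const int nh = net.nh, nin = net.nin;
  std::vector<double> out;
  std::vector<double> hp(nh), h(nh), xc(d.off_pseudo);
  int prev_a = -1;
  for (int i = 0; i < rec_idx.size(); ++i) {
    const int r = rec_idx[i], a = allele_idx[i];
    if (a != prev_a) pseudo_preact(net, d, a, hp.data());
    prev_a = a;
    for (int c = d.core_off[r]; c < d.core_off[r + 1]; ++c) {
      fill_core_input(d, c, xc.data());
      int j = 0;
      for (; j + 1 < nh; j += 2) {
        double s0, s1;
        ddot2(xc.data(), net.W1 + (size_t)nin * j,
              net.W1 + (size_t)nin * (j + 1), d.off_pseudo, &s0, &s1);
        h[j] = sigm(hp[j] + s0);
        h[j + 1] = sigm(hp[j + 1] + s1);
      }
      for (; j < nh; ++j)
        h[j] = sigm(hp[j] + ddot(xc.data(), net.W1 + (size_t)nin * j,
                                 d.off_pseudo));
      out.push_back(sigm(net.b2[out_idx] +
                         ddot(h.data(), net.W2 + (size_t)nh * out_idx, nh)));
    }
  }
  return NumericVector(out.begin(), out.end());
}

// Per-output sum of squared errors over a record subset (each record scored on
// its own output neuron against its own allele). Returns c(ss_BA, n_BA, ss_EL, n_EL).
// [[Rcpp::export]]
NumericVector cpp_sse(NumericMatrix W1, NumericVector b1, NumericMatrix W2,
                      NumericVector b2, List data, IntegerVector rec_idx,
                      IntegerVector allele_idx) {
  Net net; net.W1 = REAL(W1); net.b1 = REAL(b1);
  net.W2 = REAL(W2); net.b2 = REAL(b2);
  net.nin = W1.nrow(); net.nh = W1.ncol();
  Data d = unpack_data(data);
  double ss[2] = {0, 0};
  double nn[2] = {0, 0};
  std::vector<double> h(net.nh), scratch(2 * net.nh + d.off_pseudo);
  for (int i = 0; i < rec_idx.size(); ++i) {
    const int r = rec_idx[i];
    const int k = d.out[r];
    int bc;
    double o = fwd_record(net, d, r, allele_idx[i], k, &bc, h.data(),
                          scratch.data());
    double e = o - d.target[r];
    ss[k] += e * e;
    nn[k] += 1.0;
  }
  return NumericVector::create(ss[0], nn[0], ss[1], nn[1]);
}
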