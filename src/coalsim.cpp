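#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-population isolation coalescent with Jukes-Cantor mutations.
//
// Time is measured in expected substitutions per site per lineage, so a
// sister pair whose populations separated tau pairwise-substitution units
// apart split tau/2 lineage-units in the past.  theta is the population
// mutation parameter 4*N*mu per site; with k active lineages the
// coalescence rate is k*(k-1)/theta, which gives E[pi] = theta within a
// panmictic population.
//
// All randomness goes through R's RNG so set.seed() in R controls every
// replicate.

struct GNode {
  int left, right;   // child node ids, -1 for tips
  double time;       // age (0 at tips)
};

// Coalesce `active` lineages at rate k(k-1)/theta until one lineage remains
// or `t_end` is reached.  Advances *t; fills internal nodes.
static void coalesce_phase(std::vector<int> &active, double theta,
                           double *t, double t_end,
                           std::vector<GNode> &nodes, int *next_id) {
  while (active.size() >= 2) {
    double k = (double)active.size();
    double rate = k * (k - 1.0) / theta;
    double wait = R::exp_rand() / rate;
    if (*t + wait >= t_end) { *t = t_end; return; }
    *t += wait;
    int i = (int)(unif_rand() * active.size());
    if (i >= (int)active.size()) i = active.size() - 1;
    int a = active[i];
    active.erase(active.begin() + i);
    int j = (int)(unif_rand() * active.size());
    if (j >= (int)active.size()) j = active.size() - 1;
    int b = active[j];
    active.erase(active.begin() + j);
    GNode nd; nd.left = a; nd.right = b; nd.time = *t;
    int id = (*next_id)++;
    nodes[id] = nd;
    active.push_back(id);
  }
  if (*t < t_end) *t = t_end;
}

// Genealogy of n_a + n_b samples (n_b may be 0 for a single population).
// Tips 0..n_a-1 are population A, n_a..n-1 population B.  Root is node
// 2n-2.
static void sim_genealogy(double theta_a, double theta_b, double theta_anc,
                          double tau, int n_a, int n_b,
                          std::vector<GNode> &nodes) {
  int n = n_a + n_b;
  nodes.resize(2 * n - 1);
  for (int i = 0; i < n; ++i) { nodes[i].left = -1; nodes[i].right = -1; nodes[i].time = 0.0; }
  int next_id = n;
  double t_split = tau / 2.0;

  std::vector<int> act_a, act_b;
  act_a.reserve(n_a); act_b.reserve(n_b);
  for (int i = 0; i < n_a; ++i) act_a.push_back(i);
  for (int i = 0; i < n_b; ++i) act_b.push_back(n_a + i);

  double ta = 0.0, tb = 0.0;
  if (t_split > 0.0) {
    coalesce_phase(act_a, theta_a, &ta, t_split, nodes, &next_id);
    coalesce_phase(act_b, theta_b, &tb, t_split, nodes, &next_id);
  }
  std::vector<int> act(act_a);
  act.insert(act.end(), act_b.begin(), act_b.end());
  double t = t_split;
  coalesce_phase(act, theta_anc, &t, R_PosInf, nodes, &next_id);
}

static void apply_mutations(unsigned char *seq, double blen, int L) {
  if (blen <= 0.0) return;
  int nmut = (int)R::rpois(blen * (double)L);
  for (int m = 0; m < nmut; ++m) {
    int site = (int)(unif_rand() * L);
    if (site >= L) site = L - 1;
    int step = 1 + (int)(unif_rand() * 3.0);
    if (step > 3) step = 3;
    seq[site] = (unsigned char)((seq[site] + step) & 3);
  }
}

// Drop mutations on the genealogy and write all 2n-1 node sequences into
// `buf` (row-contiguous, node id * L).  If root_depth >= the root age and
// a root sequence is supplied, the tree root hangs from that sequence by
// a stem of length root_depth - root_age; otherwise the root sequence is
// uniform random.
static void seqs_from_genealogy(const std::vector<GNode> &nodes, int n,
                                int L, double root_depth,
                                const unsigned char *root_seq,
                                unsigned char *buf) {
  int nn = 2 * n - 1;
  unsigned char *root = buf + (size_t)(nn - 1) * L;
  if (root_seq != NULL) {
    std::copy(root_seq, root_seq + L, root);
    double stem = root_depth - nodes[nn - 1].time;
    apply_mutations(root, stem > 0.0 ? stem : 0.0, L);
  } else {
    for (int s = 0; s < L; ++s) {
      int b = (int)(unif_rand() * 4.0);
      root[s] = (unsigned char)(b > 3 ? 3 : b);
    }
  }
  // internal nodes were created in increasing age order, so walking ids
  // downward always visits a parent before its children
  for (int id = nn - 1; id >= n; --id) {
    const GNode &nd = nodes[id];
    int ch[2] = { nd.left, nd.right };
    for (int c = 0; c < 2; ++c) {
      unsigned char *dst = buf + (size_t)ch[c] * L;
      std::copy(buf + (size_t)id * L, buf + (size_t)id * L + L, dst);
      apply_mutations(dst, nd.time - nodes[ch[c]].time, L);
    }
  }
}

// [[Rcpp::export(name = ".sim_isolation_pair_cpp")]]
IntegerMatrix sim_isolation_pair_cpp(double theta_a, double theta_b,
                                     double theta_anc, double tau,
                                     int n_a, int n_b, int L,
                                     double root_depth,
                                     Nullable<IntegerVector> root_seq) {
  int n = n_a + n_b;
  std::vector<GNode> nodes;
  sim_genealogy(theta_a, theta_b, theta_anc, tau, n_a, n_b, nodes);
  std::vector<unsigned char> buf((size_t)(2 * n - 1) * L);
  if (root_seq.isNotNull()) {
    IntegerVector rs(root_seq.get());
    std::vector<unsigned char> root(L);
    for (int s = 0; s < L; ++s) root[s] = (unsigned char)(rs[s] & 3);
    seqs_from_genealogy(nodes, n, L, root_depth, root.data(), buf.data());
  } else {
    seqs_from_genealogy(nodes, n, L, -1.0, NULL, buf.data());
  }
  IntegerMatrix out(n, L);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < L; ++s) out(i, s) = buf[(size_t)i * L + s];
  return out;
}

static double harmonic(int n) {
  double a = 0.0;
  for (int i = 1; i < n; ++i) a += 1.0 / (double)i;
  return a;
}

// Summary statistics for one pair sample laid out row-contiguously in
// `buf`: pi_between, pi_within each side, Watterson's theta each side,
// and net divergence pi_b - mean(pi_w).
static void pair_stats(const unsigned char *buf, int n_a, int n_b, int L,
                       double *out) {
  double pib = 0.0, piwa = 0.0, piwb = 0.0;
  int n = n_a + n_b;
  for (int i = 0; i < n; ++i) {
    const unsigned char *si = buf + (size_t)i * L;
    for (int j = i + 1; j < n; ++j) {
      const unsigned char *sj = buf + (size_t)j * L;
      int diff = 0;
      for (int s = 0; s < L; ++s) diff += (si[s] != sj[s]);
      double d = (double)diff / (double)L;
      if (i < n_a && j < n_a) piwa += d;
      else if (i >= n_a && j >= n_a) piwb += d;
      else pib += d;
    }
  }
  if (n_a >= 2) piwa /= (double)n_a * (n_a - 1) / 2.0;
  if (n_b >= 2) piwb /= (double)n_b * (n_b - 1) / 2.0;
  pib /= (double)n_a * (double)n_b;
  int S_a = 0, S_b = 0;
  for (int s = 0; s < L; ++s) {
    unsigned char ref = buf[s];
    for (int i = 1; i < n_a; ++i)
      if (buf[(size_t)i * L + s] != ref) { ++S_a; break; }
    ref = buf[(size_t)n_a * L + s];
    for (int i = n_a + 1; i < n; ++i)
      if (buf[(size_t)i * L + s] != ref) { ++S_b; break; }
  }
  double thwa = n_a >= 2 ? (double)S_a / (harmonic(n_a) * (double)L) : 0.0;
  double thwb = n_b >= 2 ? (double)S_b / (harmonic(n_b) * (double)L) : 0.0;
  out[0] = pib;
  out[1] = piwa;
  out[2] = piwb;
  out[3] = thwa;
  out[4] = thwb;
  out[5] = pib - 0.5 * (piwa + piwb);
}

// [[Rcpp::export(name = ".pair_stats_cpp")]]
NumericVector pair_stats_cpp(IntegerMatrix seq, int n_a, int n_b) {
  int n = seq.nrow(), L = seq.ncol();
  std::vector<unsigned char> buf((size_t)n * L);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < L; ++s)
      buf[(size_t)i * L + s] = (unsigned char)(seq(i, s) & 3);
  NumericVector out(6);
  double res[6];
  pair_stats(buf.data(), n_a, n_b, L, res);
  for (int i = 0; i < 6; ++i) out[i] = res[i];
  return out;
}

// Simulate every prior draw through the isolation coalescent and return
// the 6-statistic vector per pair, draws in rows.  Parameter matrices are
// n_sims x n_pairs.
// [[Rcpp::export(name = ".habc_sim_stats_cpp")]]
NumericMatrix habc_sim_stats_cpp(NumericMatrix tau_pair,
                                 NumericMatrix theta_a, NumericMatrix theta_b,
                                 NumericMatrix theta_anc,
                                 IntegerVector n_a, IntegerVector n_b, int L) {
  int n_sims = tau_pair.nrow(), n_pairs = tau_pair.ncol();
  NumericMatrix out(n_sims, 6 * n_pairs);
  int n_max = 0;
  for (int p = 0; p < n_pairs; ++p)
    if (n_a[p] + n_b[p] > n_max) n_max = n_a[p] + n_b[p];
  std::vector<unsigned char> buf((size_t)(2 * n_max - 1) * L);
  std::vector<GNode> nodes;
  double res[6];
  for (int d = 0; d < n_sims; ++d) {
    for (int p = 0; p < n_pairs; ++p) {
      int n = n_a[p] + n_b[p];
      sim_genealogy(theta_a(d, p), theta_b(d, p), theta_anc(d, p),
                    tau_pair(d, p), n_a[p], n_b[p], nodes);
      seqs_from_genealogy(nodes, n, L, -1.0, NULL, buf.data());
      pair_stats(buf.data(), n_a[p], n_b[p], L, res);
      for (int k = 0; k < 6; ++k) out(d, 6 * p + k) = res[k];
    }
    if ((d & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
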