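// Compiled kernels: k-mer counting, de Bruijn graph construction and
// cleaning, unitig extraction, ungapped read placement, spectrum-based read
// correction, and seeded exact-match block alignment for evaluation.
//
// Graph representation: nodes are canonical k-mers, edges canonical
// (k+1)-mers.  All traversal happens in oriented k-mer space; lookups go
// through canonicalization, which keeps the graph strand-symmetric by
// construction.  k is odd everywhere a graph is built, so no k-mer is its
// own reverse complement.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

static inline bool acgt_only(const std::string& s) {
  for (char c : s)
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
  return true;
}

// lexicographically smaller of s and revcomp(s)
static std::string canon(const std::string& s) {
  std::string r = revcomp(s);
  return (r < s) ? r : s;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

// [[Rcpp::export]]
CharacterVector canonical_cpp(CharacterVector kmers) {
  CharacterVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if (!acgt_only(s)) { out[i] = NA_STRING; continue; }
    out[i] = canon(s);
  }
  return out;
}

// ---------------------------------------------------------------------------
// k-mer counting

static void count_into(std::unordered_map<std::string, long long>& tab,
                       const std::string& s, int k) {
  if ((int)s.size() < k) return;
  // track rightmost non-ACGT inside the current window
  int last_bad = -1;
  for (int i = 0; i < (int)s.size(); ++i) {
    char c = s[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') last_bad = i;
    int start = i - k + 1;
    if (start >= 0 && last_bad < start)
      ++tab[canon(s.substr(start, k))];
  }
}

static List tab_to_list(const std::unordered_map<std::string, long long>& tab) {
  std::vector<std::string> keys;
  keys.reserve(tab.size());
  for (auto& kv : tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector km(keys.size());
  NumericVector ct(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    km[i] = keys[i];
    ct[i] = (double)tab.at(keys[i]);
  }
  return List::create(_["kmer"] = km, _["count"] = ct);
}

// [[Rcpp::export]]
List count_kmers_cpp(CharacterVector seqs, int k) {
  std::unordered_map<std::string, long long> tab;
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    count_into(tab, as<std::string>(seqs[i]), k);
  return tab_to_list(tab);
}

// Nodes (canonical k-mers) and edges (canonical (k+1)-mers) in one pass.
// [[Rcpp::export]]
List build_dbg_cpp(CharacterVector seqs, int k) {
  std::unordered_map<std::string, long long> nodes, edges;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    count_into(nodes, s, k);
    count_into(edges, s, k + 1);
  }
  List nl = tab_to_list(nodes), el = tab_to_list(edges);
  return List::create(_["node_kmer"] = nl["kmer"], _["node_count"] = nl["count"],
                      _["edge_kmer"] = el["kmer"], _["edge_count"] = el["count"]);
}

// canonical prefix/suffix k-mer of each (k+1)-mer edge
// [[Rcpp::export]]
List edge_endpoints_cpp(CharacterVector edge_kmers, int k) {
  R_xlen_t n = edge_kmers.size();
  CharacterVector from(n), to(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string e = as<std::string>(edge_kmers[i]);
    from[i] = canon(e.substr(0, k));
    to[i]   = canon(e.substr(1, k));
  }
  return List::create(_["from"] = from, _["to"] = to);
}

// ---------------------------------------------------------------------------
// In-memory graph used by cleaning / unitig kernels

struct Graph {
  int k;
  std::unordered_map<std::string, long long> edges;   // canonical (k+1)-mer
  std::unordered_set<std::string> eprot;              // protected edges
  std::unordered_map<std::string, long long> nodes;   // canonical k-mer

  bool has_node(const std::string& canon_km) const {
    return nodes.count(canon_km) > 0;
  }
  // oriented successors of oriented k-mer X
  void succ(const std::string& X, std::vector<char>& bases,
            std::vector<std::string>& ekeys) const {
    bases.clear(); ekeys.clear();
    static const char B[4] = {'A', 'C', 'G', 'T'};
    for (char b : B) {
      std::string e = X + b;
      std::string ce = canon(e);
      if (!edges.count(ce)) continue;
      if (!has_node(canon(e.substr(1, k)))) continue;
      bases.push_back(b);
      ekeys.push_back(ce);
    }
  }
  void pred(const std::string& X, std::vector<char>& bases,
            std::vector<std::string>& ekeys) const {
    bases.clear(); ekeys.clear();
    static const char B[4] = {'A', 'C', 'G', 'T'};
    for (char b : B) {
      std::string e = b + X;
      std::string ce = canon(e);
      if (!edges.count(ce)) continue;
      if (!has_node(canon(e.substr(0, k)))) continue;
      bases.push_back(b);
      ekeys.push_back(ce);
    }
  }
  int outdeg(const std::string& X) const {
    std::vector<char> b; std::vector<std::string> e; succ(X, b, e);
    return (int)b.size();
  }
  int indeg(const std::string& X) const {
    std::vector<char> b; std::vector<std::string> e; pred(X, b, e);
    return (int)b.size();
  }
};

static Graph make_graph(CharacterVector node_kmer, NumericVector node_count,
                        CharacterVector edge_kmer, NumericVector edge_count,
                        LogicalVector edge_protected, int k) {
  Graph g; g.k = k;
  for (R_xlen_t i = 0; i < node_kmer.size(); ++i)
    g.nodes[as<std::string>(node_kmer[i])] = (long long)node_count[i];
  for (R_xlen_t i = 0; i < edge_kmer.size(); ++i) {
    std::string e = as<std::string>(edge_kmer[i]);
    g.edges[e] = (long long)edge_count[i];
    if (edge_protected.size() == edge_kmer.size() && edge_protected[i])
      g.eprot.insert(e);
  }
  return g;
}

static List graph_to_list(const Graph& g) {
  std::vector<std::string> nk, ek;
  for (auto& kv : g.nodes) nk.push_back(kv.first);
  for (auto& kv : g.edges) ek.push_back(kv.first);
  std::sort(nk.begin(), nk.end());
  std::sort(ek.begin(), ek.end());
  CharacterVector NK(nk.size()), EK(ek.size());
  NumericVector NC(nk.size()), EC(ek.size());
  LogicalVector EP(ek.size());
  for (size_t i = 0; i < nk.size(); ++i) { NK[i] = nk[i]; NC[i] = (double)g.nodes.at(nk[i]); }
  for (size_t i = 0; i < ek.size(); ++i) {
    EK[i] = ek[i]; EC[i] = (double)g.edges.at(ek[i]);
    EP[i] = g.eprot.count(ek[i]) > 0;
  }
  return List::create(_["node_kmer"] = NK, _["node_count"] = NC,
                      _["edge_kmer"] = EK, _["edge_count"] = EC,
                      _["edge_protected"] = EP);
}

// ---------------------------------------------------------------------------
// Unitig extraction: maximal unbranched paths, canonical orientation,
// deterministic (length desc, seq asc) ordering.

struct Walk {
  std::string seq;
  double mean_cov;
  int in_start, out_end;
  size_t n_edges;
};

static Walk walk_from(const Graph& g, const std::string& X0,
                      std::unordered_set<std::string>& visited) {
  int k = g.k;
  std::string seq = X0;
  std::string X = X0;
  visited.insert(canon(X0));
  double covsum = 0; size_t nedge = 0;
  std::vector<char> b; std::vector<std::string> e;
  for (;;) {
    g.succ(X, b, e);
    if (b.size() != 1) break;
    std::string Y = X.substr(1) + b[0];
    if (g.indeg(Y) != 1) break;
    if (visited.count(canon(Y))) break;
    covsum += (double)g.edges.at(e[0]);
    ++nedge;
    seq += b[0];
    X = Y;
    visited.insert(canon(Y));
  }
  Walk w;
  w.n_edges = nedge;
  w.mean_cov = nedge ? covsum / nedge
                     : (double)(g.nodes.count(canon(X0)) ? g.nodes.at(canon(X0)) : 0);
  // canonical orientation
  std::string rcseq = revcomp(seq);
  if (rcseq < seq) seq = rcseq;
  w.seq = seq;
  std::string F = seq.substr(0, k), L = seq.substr(seq.size() - k);
  w.in_start = g.indeg(F);
  w.out_end = g.outdeg(L);
  return w;
}

static bool is_start(const Graph& g, const std::string& X) {
  // can this oriented k-mer begin a maximal unbranched path?
  std::vector<char> b; std::vector<std::string> e;
  g.pred(X, b, e);
  if (b.size() != 1) return true;
  std::string P = b[0] + X.substr(0, g.k - 1);
  if (g.outdeg(P) != 1) return true;
  if (canon(P) == canon(X)) return true;  // tight self-loop
  return false;
}

// [[Rcpp::export]]
List extract_unitigs_cpp(CharacterVector node_kmer, NumericVector node_count,
                         CharacterVector edge_kmer, NumericVector edge_count,
                         int k) {
  Graph g = make_graph(node_kmer, node_count, edge_kmer, edge_count,
                       LogicalVector(0), k);
  std::vector<std::string> order;
  order.reserve(g.nodes.size());
  for (auto& kv : g.nodes) order.push_back(kv.first);
  std::sort(order.begin(), order.end());

  std::unordered_set<std::string> visited;
  std::vector<Walk> out;

  for (auto& K : order) {
    if (visited.count(K)) continue;
    std::string R = revcomp(K);
    if (is_start(g, K)) out.push_back(walk_from(g, K, visited));
    else if (is_start(g, R)) out.push_back(walk_from(g, R, visited));
  }
  // leftovers: perfect cycles; start at smallest canonical k-mer
  for (auto& K : order) {
    if (visited.count(K)) continue;
    out.push_back(walk_from(g, K, visited));
  }

  std::vector<size_t> idx(out.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](size_t a, size_t bb) {
    if (out[a].seq.size() != out[bb].seq.size())
      return out[a].seq.size() > out[bb].seq.size();
    return out[a].seq < out[bb].seq;
  });

  CharacterVector seqs(out.size());
  NumericVector cov(out.size());
  IntegerVector din(out.size()), dout(out.size());
  for (size_t i = 0; i < idx.size(); ++i) {
    const Walk& w = out[idx[i]];
    seqs[i] = w.seq; cov[i] = w.mean_cov;
    din[i] = w.in_start; dout[i] = w.out_end;
  }
  return List::create(_["seq"] = seqs, _["mean_coverage"] = cov,
                      _["in_degree_start"] = din, _["out_degree_end"] = dout);
}

// ---------------------------------------------------------------------------
// Tip clipping: dead-end chain shorter than max_tip_len attached to a
// junction, with mean coverage below its best sibling, removed; iterated to
// fixpoint.  Protected edges block removal of the whole tip.

// [[Rcpp::export]]
List clip_tips_cpp(CharacterVector node_kmer, NumericVector node_count,
                   CharacterVector edge_kmer, NumericVector edge_count,
                   LogicalVector edge_protected, int k, int max_tip_len) {
  Graph g = make_graph(node_kmer, node_count, edge_kmer, edge_count,
                       edge_protected, k);
  bool changed = true;
  int guard = 0;
  while (changed && ++guard <= 1000) {
    changed = false;
    std::vector<std::string> order;
    for (auto& kv : g.nodes) order.push_back(kv.first);
    std::sort(order.begin(), order.end());
    for (auto& K : order) {
      if (!g.nodes.count(K)) continue;  // removed earlier this round
      for (int ori = 0; ori < 2; ++ori) {
        std::string X = ori ? revcomp(K) : K;
        if (g.indeg(X) != 0) continue;
        // walk the dead-end chain forward
        std::vector<std::string> chain_nodes;   // canonical
        std::vector<std::string> chain_edges;   // canonical keys
        std::string cur = X;
        chain_nodes.push_back(canon(cur));
        bool attached = false;
        std::string junction;
        std::string attach_edge;
        std::vector<char> b; std::vector<std::string> e;
        for (;;) {
          g.succ(cur, b, e);
          if (b.size() != 1) break;  // dead end or forward fork: not a simple tip
          std::string Y = cur.substr(1) + b[0];
          if (g.indeg(Y) >= 2) { attached = true; junction = Y; attach_edge = e[0]; break; }
          if (std::find(chain_nodes.begin(), chain_nodes.end(), canon(Y))
              != chain_nodes.end()) break;
          chain_edges.push_back(e[0]);
          chain_nodes.push_back(canon(Y));
          cur = Y;
          if ((int)chain_nodes.size() > max_tip_len) break;
        }
        if (!attached) continue;
        int tip_len = k + (int)chain_nodes.size() - 1;  // spelled bp
        if (tip_len >= max_tip_len) continue;
        // protected edges anywhere in the tip?
        bool prot = g.eprot.count(attach_edge) > 0;
        for (auto& ce : chain_edges) if (g.eprot.count(ce)) prot = true;
        if (prot) continue;
        // coverage vs best sibling entering the junction
        double covsum = (double)g.edges.at(attach_edge);
        for (auto& ce : chain_edges) covsum += (double)g.edges.at(ce);
        double tip_cov = covsum / (1.0 + chain_edges.size());
        g.pred(junction, b, e);
        double sib = -1;
        for (size_t j = 0; j < e.size(); ++j)
          if (e[j] != attach_edge) sib = std::max(sib, (double)g.edges.at(e[j]));
        if (sib < 0 || tip_cov >= sib) continue;
        // delete tip
        g.edges.erase(attach_edge);
        for (auto& ce : chain_edges) g.edges.erase(ce);
        for (auto& cn : chain_nodes) g.nodes.erase(cn);
        changed = true;
        break;  // orientation loop; node gone
      }
    }
  }
  return graph_to_list(g);
}

// ---------------------------------------------------------------------------
// Bubble popping

static int edit_distance(const std::string& a, const std::string& bstr) {
  size_t n = a.size(), m = bstr.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i;
    for (size_t j = 1; j <= m; ++j) {
      int c = (a[i - 1] == bstr[j - 1]) ? 0 : 1;
      cur[j] = std::min({prev[j] + 1, cur[j - 1] + 1, prev[j - 1] + c});
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

struct BranchWalk {
  bool ok = false;
  std::string sink;                  // oriented k-mer where the branch converges
  std::string spelled;               // bases after the source k-mer
  std::vector<std::string> edges;    // canonical edge keys along the branch
  std::vector<std::string> nodes;    // canonical interior nodes (excl. sink)
};

static BranchWalk walk_branch(const Graph& g, const std::string& X, char b0,
                              int max_path_len) {
  BranchWalk w;
  std::string e0 = X + b0;
  w.edges.push_back(canon(e0));
  w.spelled += b0;
  std::string cur = X.substr(1) + b0;
  std::unordered_set<std::string> seen;
  for (;;) {
    if (g.indeg(cur) >= 2) { w.ok = true; w.sink = cur; return w; }
    std::vector<char> b; std::vector<std::string> e;
    g.succ(cur, b, e);
    if (b.size() != 1) return w;                 // dead end or fork: not a bubble path
    std::string cn = canon(cur);
    if (seen.count(cn)) return w;
    seen.insert(cn);
    w.nodes.push_back(cn);
    if ((int)w.spelled.size() > max_path_len) return w;
    w.edges.push_back(e[0]);
    w.spelled += b[0];
    cur = cur.substr(1) + b[0];
  }
}

static double path_mean_cov(const Graph& g, const std::vector<std::string>& edges) {
  double s = 0;
  for (auto& e : edges) s += (double)g.edges.at(e);
  return edges.empty() ? 0 : s / edges.size();
}

// [[Rcpp::export]]
List pop_bubbles_cpp(CharacterVector node_kmer, NumericVector node_count,
                     CharacterVector edge_kmer, NumericVector edge_count,
                     LogicalVector edge_protected, int k,
                     double max_divergence, int max_path_len) {
  Graph g = make_graph(node_kmer, node_count, edge_kmer, edge_count,
                       edge_protected, k);
  bool changed = true;
  int guard = 0;
  while (changed && ++guard <= 1000) {
    changed = false;
    std::vector<std::string> order;
    for (auto& kv : g.nodes) order.push_back(kv.first);
    std::sort(order.begin(), order.end());
    for (auto& K : order) {
      if (!g.nodes.count(K)) continue;
      for (int ori = 0; ori < 2 && !changed; ++ori) {
        std::string X = ori ? revcomp(K) : K;
        std::vector<char> b; std::vector<std::string> e;
        g.succ(X, b, e);
        if (b.size() < 2) continue;
        for (size_t i = 0; i < b.size() && !changed; ++i) {
          for (size_t j = i + 1; j < b.size() && !changed; ++j) {
            BranchWalk w1 = walk_branch(g, X, b[i], max_path_len);
            BranchWalk w2 = walk_branch(g, X, b[j], max_path_len);
            if (!w1.ok || !w2.ok || w1.sink != w2.sink) continue;
            // interior node sets must be disjoint
            std::unordered_set<std::string> s1(w1.nodes.begin(), w1.nodes.end());
            bool overlap = false;
            for (auto& n2 : w2.nodes) if (s1.count(n2)) overlap = true;
            if (overlap) continue;
            size_t mx = std::max(w1.spelled.size(), w2.spelled.size());
            if (mx == 0) continue;
            double div = (double)edit_distance(w1.spelled, w2.spelled) / (double)mx;
            if (div > max_divergence) continue;
            double c1 = path_mean_cov(g, w1.edges);
            double c2 = path_mean_cov(g, w2.edges);
            const BranchWalk* win;
            const BranchWalk* lose;
            if (c1 > c2) { win = &w1; lose = &w2; }
            else if (c2 > c1) { win = &w2; lose = &w1; }
            else { // tie: lexicographically smaller spelled sequence survives
              if (w1.spelled <= w2.spelled) { win = &w1; lose = &w2; }
              else { win = &w2; lose = &w1; }
            }
            bool prot = false;
            for (auto& ce : lose->edges) if (g.eprot.count(ce)) prot = true;
            if (prot) continue;
            long long add = (long long)std::llround(path_mean_cov(g, lose->edges));
            for (auto& ce : lose->edges) g.edges.erase(ce);
            for (auto& cn : lose->nodes) g.nodes.erase(cn);
            for (auto& ce : win->edges)
              if (g.edges.count(ce)) g.edges[ce] += add;
            changed = true;
          }
        }
      }
      if (changed) break;  // rescan with fresh order
    }
  }
  return graph_to_list(g);
}

// ---------------------------------------------------------------------------
// Full-length ungapped read placement on contigs

// [[Rcpp::export]]
List map_reads_cpp(CharacterVector reads, CharacterVector contigs,
                   int max_mismatch, int seed_len) {
  // index every contig position's seed
  std::unordered_map<std::string, std::vector<std::pair<int, int>>> idx;
  std::vector<std::string> cs(contigs.size());
  for (R_xlen_t c = 0; c < contigs.size(); ++c) {
    cs[c] = as<std::string>(contigs[c]);
    const std::string& s = cs[c];
    if ((int)s.size() < seed_len) continue;
    for (int p = 0; p + seed_len <= (int)s.size(); ++p) {
      std::string sd = s.substr(p, seed_len);
      if (!acgt_only(sd)) continue;
      auto& v = idx[sd];
      if (v.size() < 200) v.emplace_back((int)c, p);
    }
  }
  std::vector<int> o_read, o_contig, o_off, o_mm;
  std::vector<int> o_strand;  // 1 = +, -1 = -
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string rs = as<std::string>(reads[r]);
    int L = (int)rs.size();
    if (L < seed_len) continue;
    int best_mm = max_mismatch + 1, best_c = -1, best_off = -1, best_st = 0;
    for (int st = 0; st < 2; ++st) {
      std::string q = st ? revcomp(rs) : rs;
      std::vector<int> soffs = {0, (L - seed_len) / 2, L - seed_len};
      std::sort(soffs.begin(), soffs.end());
      soffs.erase(std::unique(soffs.begin(), soffs.end()), soffs.end());
      std::unordered_set<long long> tried;
      for (int so : soffs) {
        std::string sd = q.substr(so, seed_len);
        auto it = idx.find(sd);
        if (it == idx.end()) continue;
        for (auto& hit : it->second) {
          int c = hit.first, off = hit.second - so;
          if (off < 0 || off + L > (int)cs[c].size()) continue;
          long long key = ((long long)c << 32) ^ (long long)(off + 1);
          if (tried.count(key)) continue;
          tried.insert(key);
          const std::string& t = cs[c];
          int mm = 0;
          for (int i = 0; i < L && mm <= max_mismatch; ++i)
            if (q[i] != t[off + i]) ++mm;
          if (mm > max_mismatch) continue;
          int stv = st ? -1 : 1;
          bool better = false;
          if (mm < best_mm) better = true;
          else if (mm == best_mm) {
            if (c < best_c) better = true;
            else if (c == best_c) {
              if (off < best_off) better = true;
              else if (off == best_off && stv > best_st) better = true;
            }
          }
          if (better) { best_mm = mm; best_c = c; best_off = off; best_st = stv; }
        }
      }
    }
    if (best_c >= 0) {
      o_read.push_back((int)r + 1);
      o_contig.push_back(best_c + 1);
      o_off.push_back(best_off);
      o_strand.push_back(best_st);
      o_mm.push_back(best_mm);
    }
  }
  return List::create(_["read_idx"] = wrap(o_read), _["contig_idx"] = wrap(o_contig),
                      _["offset"] = wrap(o_off), _["strand"] = wrap(o_strand),
                      _["mismatches"] = wrap(o_mm));
}

// ---------------------------------------------------------------------------
// Spectrum-based read correction

struct Spectrum {
  std::unordered_map<std::string, long long> tab;
  int k;
  long long cutoff;
  long long count(const std::string& w) const {
    if (!acgt_only(w)) return 0;
    auto it = tab.find(canon(w));
    return it == tab.end() ? 0 : it->second;
  }
  bool trusted(const std::string& w) const { return count(w) >= cutoff; }
};

static std::vector<bool> window_flags(const Spectrum& sp, const std::string& s) {
  int W = (int)s.size() - sp.k + 1;
  std::vector<bool> tr(std::max(W, 0));
  for (int i = 0; i < W; ++i) tr[i] = sp.trusted(s.substr(i, sp.k));
  return tr;
}

static int n_untrusted(const std::vector<bool>& tr) {
  int n = 0;
  for (bool t : tr) if (!t) ++n;
  return n;
}

// candidate positions for the first untrusted run: positions covered only by
// untrusted windows, ordered by distance from the last base of the first
// untrusted window
static std::vector<int> candidate_positions(const std::vector<bool>& tr, int k, int L) {
  int W = (int)tr.size();
  int i0 = -1;
  for (int i = 0; i < W; ++i) if (!tr[i]) { i0 = i; break; }
  if (i0 < 0) return {};
  int i1 = i0;
  while (i1 + 1 < W && !tr[i1 + 1]) ++i1;
  int lo = i0, hi = std::min(i1 + k - 1, L - 1);
  std::vector<int> cand;
  for (int p = lo; p <= hi; ++p) {
    bool only_untr = true;
    int wlo = std::max(0, p - k + 1), whi = std::min(p, W - 1);
    for (int w = wlo; w <= whi; ++w) if (tr[w]) { only_untr = false; break; }
    if (only_untr) cand.push_back(p);
  }
  int pp = i0 + k - 1;
  std::sort(cand.begin(), cand.end(), [&](int a, int bb) {
    int da = std::abs(a - pp), db = std::abs(bb - pp);
    if (da != db) return da < db;
    return a < bb;
  });
  return cand;
}

// do all windows covering p become trusted after the substitution already
// applied to s?
static bool position_cleared(const Spectrum& sp, const std::string& s, int p) {
  int k = sp.k, W = (int)s.size() - k + 1;
  int wlo = std::max(0, p - k + 1), whi = std::min(p, W - 1);
  for (int w = wlo; w <= whi; ++w)
    if (!sp.trusted(s.substr(w, k))) return false;
  return true;
}

// status codes: 0 unchanged, 1 corrected, 2 uncorrectable, 3 ambiguous
struct CorrOut {
  int status;
  std::string seq;
  std::vector<int> pos;
  std::vector<char> oldb, newb;
  int before, after;
};

static CorrOut correct_fast(const Spectrum& sp, const std::string& seq0,
                            int max_edits) {
  CorrOut out;
  out.seq = seq0;
  int k = sp.k, L = (int)seq0.size();
  std::vector<bool> tr = window_flags(sp, out.seq);
  out.before = n_untrusted(tr);
  out.after = out.before;
  if (out.before == 0) { out.status = 0; return out; }
  std::string work = seq0;
  std::vector<int> ep; std::vector<char> eo, en;
  bool saw_ambig = false;
  int edits = 0;
  static const char B[4] = {'A', 'C', 'G', 'T'};
  while (edits < max_edits) {
    tr = window_flags(sp, work);
    if (n_untrusted(tr) == 0) break;
    std::vector<int> cand = candidate_positions(tr, k, L);
    bool applied = false;
    for (int p : cand) {
      char orig = work[p];
      std::vector<char> clearing;
      for (char b : B) {
        if (b == orig) continue;
        work[p] = b;
        if (position_cleared(sp, work, p)) clearing.push_back(b);
        work[p] = orig;
      }
      if (clearing.size() == 1) {
        ep.push_back(p); eo.push_back(orig); en.push_back(clearing[0]);
        work[p] = clearing[0];
        ++edits;
        applied = true;
        break;
      }
      if (clearing.size() > 1) saw_ambig = true;
    }
    if (!applied) break;
  }
  tr = window_flags(sp, work);
  if (n_untrusted(tr) == 0 && !ep.empty()) {
    out.status = 1; out.seq = work;
    out.pos = ep; out.oldb = eo; out.newb = en;
    out.after = 0;
  } else {
    out.status = saw_ambig && ep.empty() ? 3 : 2;  // revert
  }
  return out;
}

struct DeepCand {
  std::string seq;
  std::vector<int> pos;
  std::vector<char> oldb, newb;
  double total;
};

static void deep_dfs(const Spectrum& sp, std::string& work, const std::string& orig,
                     int max_edits, int& budget,
                     std::vector<int>& ep, std::vector<char>& eo, std::vector<char>& en,
                     std::vector<DeepCand>& found,
                     std::unordered_set<std::string>& seen) {
  std::vector<bool> tr = window_flags(sp, work);
  if (n_untrusted(tr) == 0) {
    if (!seen.count(work)) {
      seen.insert(work);
      DeepCand c;
      c.seq = work; c.pos = ep; c.oldb = eo; c.newb = en;
      c.total = 0;
      for (size_t w = 0; w + sp.k <= work.size(); ++w)
        c.total += (double)sp.count(work.substr(w, sp.k));
      found.push_back(c);
    }
    return;
  }
  if ((int)ep.size() >= max_edits) return;
  std::vector<int> cand = candidate_positions(tr, sp.k, (int)work.size());
  static const char B[4] = {'A', 'C', 'G', 'T'};
  for (int p : cand) {
    char ob = work[p];
    for (char b : B) {
      if (b == ob) continue;
      if (budget <= 0) return;
      --budget;
      work[p] = b;
      ep.push_back(p); eo.push_back(ob); en.push_back(b);
      deep_dfs(sp, work, orig, max_edits, budget, ep, eo, en, found, seen);
      ep.pop_back(); eo.pop_back(); en.pop_back();
      work[p] = ob;
    }
  }
}

static CorrOut correct_deep(const Spectrum& sp, const std::string& seq0,
                            int max_edits, int budget) {
  CorrOut out;
  out.seq = seq0;
  std::vector<bool> tr = window_flags(sp, seq0);
  out.before = n_untrusted(tr);
  out.after = out.before;
  if (out.before == 0) { out.status = 0; return out; }
  std::string work = seq0;
  std::vector<int> ep; std::vector<char> eo, en;
  std::vector<DeepCand> found;
  std::unordered_set<std::string> seen;
  int bud = budget;
  deep_dfs(sp, work, seq0, max_edits, bud, ep, eo, en, found, seen);
  if (found.empty()) { out.status = 2; return out; }
  // best by (0 untrusted already) then total window count, descending
  size_t best = 0;
  bool tie = false;
  for (size_t i = 1; i < found.size(); ++i) {
    if (found[i].total > found[best].total) { best = i; tie = false; }
    else if (found[i].total == found[best].total) tie = true;
  }
  if (tie) { out.status = 3; return out; }
  out.status = 1;
  out.seq = found[best].seq;
  out.pos = found[best].pos; out.oldb = found[best].oldb; out.newb = found[best].newb;
  out.after = 0;
  return out;
}

// mode: 0 fast, 1 deep, 2 fast_then_deep
// [[Rcpp::export]]
List correct_reads_cpp(CharacterVector seqs, int k,
                       CharacterVector spec_kmers, NumericVector spec_counts,
                       double cutoff, int max_edits, int mode, int budget) {
  Spectrum sp;
  sp.k = k;
  sp.cutoff = (long long)cutoff;
  for (R_xlen_t i = 0; i < spec_kmers.size(); ++i)
    sp.tab[as<std::string>(spec_kmers[i])] = (long long)spec_counts[i];

  R_xlen_t n = seqs.size();
  IntegerVector status(n), nbef(n), naft(n);
  CharacterVector corrected(n);
  List edits(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    CorrOut o;
    if ((int)s.size() < k) {
      o.status = 0; o.seq = s; o.before = 0; o.after = 0;
    } else if (mode == 0) {
      o = correct_fast(sp, s, max_edits);
    } else if (mode == 1) {
      o = correct_deep(sp, s, max_edits, budget);
    } else {
      o = correct_fast(sp, s, max_edits);
      if (o.status == 2 || o.status == 3)
        o = correct_deep(sp, s, max_edits, budget);
    }
    status[i] = o.status;
    corrected[i] = o.seq;
    nbef[i] = o.before;
    naft[i] = o.after;
    IntegerVector P(o.pos.size());
    CharacterVector OB(o.pos.size()), NB(o.pos.size());
    for (size_t j = 0; j < o.pos.size(); ++j) {
      P[j] = o.pos[j];
      OB[j] = std::string(1, o.oldb[j]);
      NB[j] = std::string(1, o.newb[j]);
    }
    edits[i] = List::create(_["position"] = P, _["old_base"] = OB, _["new_base"] = NB);
  }
  return List::create(_["status"] = status, _["seq"] = corrected,
                      _["edits"] = edits, _["n_untrusted_before"] = nbef,
                      _["n_untrusted_after"] = naft);
}

// ---------------------------------------------------------------------------
// Seeded exact-match block alignment (evaluation)

// Returns, for each query, a matrix of blocks:
// columns q_start, q_end (0-based half-open), r_start, r_end, strand (1/-1)
// [[Rcpp::export]]
List align_blocks_cpp(CharacterVector queries, std::string ref, int seed_len) {
  std::unordered_map<std::string, std::vector<int>> idx;
  int RL = (int)ref.size();
  for (int p = 0; p + seed_len <= RL; ++p) {
    std::string sd = ref.substr(p, seed_len);
    if (!acgt_only(sd)) continue;
    auto& v = idx[sd];
    if (v.size() < 100) v.push_back(p);
  }
  List out(queries.size());
  for (R_xlen_t qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    int L = (int)q.size();
    std::vector<std::array<int, 5>> blocks;
    int pos = 0;
    int prev_strand = 0;
    long long prev_diag = 0;   // r_start - q_start for +, r_end + q_start for -
    while (pos + seed_len <= L) {
      std::string sd = q.substr(pos, seed_len);
      if (!acgt_only(sd)) { ++pos; continue; }
      // forward hits
      int chosen_r = -1, chosen_st = 0;
      auto pick = [&](const std::vector<int>& hits, int st) {
        for (int r : hits) {
          long long diag = (st == 1) ? (long long)r - pos : (long long)r + pos;
          if (prev_strand == st && std::llabs(diag - prev_diag) < 5) {
            chosen_r = r; chosen_st = st; return true;
          }
        }
        return false;
      };
      auto itf = idx.find(sd);
      std::string rsd = revcomp(sd);
      auto itr = idx.find(rsd);
      bool got = false;
      if (itf != idx.end()) got = pick(itf->second, 1);
      if (!got && itr != idx.end()) got = pick(itr->second, -1);
      if (!got) {
        if (itf != idx.end()) { chosen_r = itf->second[0]; chosen_st = 1; }
        else if (itr != idx.end()) { chosen_r = itr->second[0]; chosen_st = -1; }
      }
      if (chosen_st == 0) { ++pos; continue; }
      int qs = pos, qe = pos + seed_len, rs, re;
      if (chosen_st == 1) {
        rs = chosen_r; re = chosen_r + seed_len;
        while (qs > 0 && rs > 0 && q[qs - 1] == ref[rs - 1]) { --qs; --rs; }
        while (qe < L && re < RL && q[qe] == ref[re]) { ++qe; ++re; }
      } else {
        // q[qs..qe) matches revcomp of ref[rs..re)
        rs = chosen_r; re = chosen_r + seed_len;
        while (qs > 0 && re < RL && q[qs - 1] == comp_base(ref[re])) { --qs; ++re; }
        while (qe < L && rs > 0 && q[qe] == comp_base(ref[rs - 1])) { ++qe; --rs; }
      }
      blocks.push_back({qs, qe, rs, re, chosen_st});
      prev_strand = chosen_st;
      prev_diag = (chosen_st == 1) ? (long long)rs - qs : (long long)re + qs;
      pos = qe;
    }
    IntegerMatrix M((int)blocks.size(), 5);
    for (size_t i = 0; i < blocks.size(); ++i)
      for (int j = 0; j < 5; ++j) M((int)i, j) = blocks[i][j];
    colnames(M) = CharacterVector::create("q_start", "q_end", "r_start",
                                          "r_end", "strand");
    out[qi] = M;
  }
  return out;
}
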