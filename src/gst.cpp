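// Generalized suffix tree over a set of DNA sequences.
//
// Two construction modes share one node layout and one query surface:
//  * full tree: Ukkonen's online algorithm over the concatenation of all
//    sequences, each terminated by its own unique sentinel symbol;
//  * depth-truncated tree: compressed-trie insertion of every suffix cut at
//    string depth k (O(total length * k)), for word queries with |w| <= k.
//
// Edge labels are (start, end) references into the concatenated integer
// text, never copied strings.  Residues are coded A=0 C=1 G=2 T=3, other
// IUPAC ambiguity letters 4..14, and the sentinel of sequence i gets code
// 16+i, so sentinels can never collide with residue symbols.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <string>
#include <utility>

using namespace Rcpp;

static const std::string IUPAC = "ACGTRYSWKMBDHVN";
static const int SENTINEL_BASE = 16;

struct GstNode {
  int start;                               // edge label [start, end) in text
  int end;                                 // -1 while an open Ukkonen leaf
  int link;                                // suffix link (Ukkonen only)
  std::map<int, int> next;                 // first symbol -> child node id
  std::vector<std::pair<int, int> > ann;   // (seq index, suffix start), 0-based
};

struct Gst {
  std::vector<int> text;
  std::vector<GstNode> nodes;
  int n_seq;
  std::vector<int> seq_begin;   // residue span of sequence i: [begin, sent)
  std::vector<int> seq_sent;    // text position of sentinel i
  int max_depth;                // 0 = full tree

  // Ukkonen state
  int active_node, active_edge, active_len, remainder;

  Gst() : n_seq(0), max_depth(0), active_node(0), active_edge(0),
          active_len(0), remainder(0) {}

  int new_node(int start, int end) {
    GstNode nd;
    nd.start = start; nd.end = end; nd.link = 0;
    nodes.push_back(nd);
    return (int)nodes.size() - 1;
  }

  int edge_length(int v, int pos) const {
    return (nodes[v].end == -1 ? pos + 1 : nodes[v].end) - nodes[v].start;
  }

  void extend(int pos) {
    ++remainder;
    int need_link = 0;
    while (remainder > 0) {
      if (active_len == 0) active_edge = pos;
      std::map<int, int>::iterator it =
        nodes[active_node].next.find(text[active_edge]);
      if (it == nodes[active_node].next.end()) {
        int leaf = new_node(pos, -1);
        nodes[active_node].next[text[active_edge]] = leaf;
        if (need_link) nodes[need_link].link = active_node;
        need_link = active_node;
      } else {
        int nxt = it->second;
        int len = edge_length(nxt, pos);
        if (active_len >= len) {
          active_node = nxt;
          active_edge += len;
          active_len -= len;
          continue;
        }
        if (text[nodes[nxt].start + active_len] == text[pos]) {
          ++active_len;
          if (need_link) nodes[need_link].link = active_node;
          break;
        }
        int split = new_node(nodes[nxt].start, nodes[nxt].start + active_len);
        nodes[active_node].next[text[active_edge]] = split;
        int leaf = new_node(pos, -1);
        nodes[split].next[text[pos]] = leaf;
        nodes[nxt].start += active_len;
        nodes[split].next[text[nodes[nxt].start]] = nxt;
        if (need_link) nodes[need_link].link = split;
        need_link = split;
      }
      --remainder;
      if (active_node == 0 && active_len > 0) {
        --active_len;
        active_edge = pos - remainder + 1;
      } else {
        active_node = nodes[active_node].link;
      }
    }
  }

  int seq_of_pos(int p) const {
    // binary search: sequence i spans [seq_begin[i], seq_sent[i]]
    int lo = 0, hi = n_seq - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (p <= seq_sent[mid]) hi = mid; else lo = mid + 1;
    }
    return lo;
  }

  // After Ukkonen: close leaves, compute suffix starts, trim each leaf edge
  // at its sequence's sentinel, and attach the (seq, pos) annotation.
  void finalize_full() {
    int tlen = (int)text.size();
    // iterative DFS tracking string depth at node entry
    std::vector<std::pair<int, int> > stack;  // (node, depth before its edge)
    for (std::map<int, int>::reverse_iterator it = nodes[0].next.rbegin();
         it != nodes[0].next.rend(); ++it)
      stack.push_back(std::make_pair(it->second, 0));
    while (!stack.empty()) {
      int v = stack.back().first;
      int d0 = stack.back().second;
      stack.pop_back();
      if (nodes[v].end == -1) nodes[v].end = tlen;
      int d1 = d0 + (nodes[v].end - nodes[v].start);
      if (nodes[v].next.empty()) {
        int suf = tlen - d1;
        int s = seq_of_pos(suf);
        int sent = seq_sent[s];
        nodes[v].end = sent + 1;       // trim past-sentinel tail
        nodes[v].ann.push_back(std::make_pair(s, suf - seq_begin[s]));
      } else {
        for (std::map<int, int>::reverse_iterator it = nodes[v].next.rbegin();
             it != nodes[v].next.rend(); ++it)
          stack.push_back(std::make_pair(it->second, d1));
      }
    }
  }

  // Depth-truncated construction: insert text[tstart, tstart+len) for the
  // suffix (seq, pos), splitting edges at mismatches.
  void insert_truncated(int tstart, int len, int seq, int pos) {
    int v = 0, i = 0;
    while (i < len) {
      std::map<int, int>::iterator it = nodes[v].next.find(text[tstart + i]);
      if (it == nodes[v].next.end()) {
        int leaf = new_node(tstart + i, tstart + len);
        nodes[v].next[text[tstart + i]] = leaf;
        v = leaf; i = len;
        break;
      }
      int u = it->second;
      int estart = nodes[u].start, elen = nodes[u].end - nodes[u].start;
      int j = 0;
      while (j < elen && i < len && text[estart + j] == text[tstart + i]) {
        ++j; ++i;
      }
      if (j == elen) { v = u; continue; }
      // mismatch (or, defensively, exhausted insertion) inside the edge
      int split = new_node(estart, estart + j);
      nodes[v].next[text[estart]] = split;
      nodes[u].start += j;
      nodes[split].next[text[nodes[u].start]] = u;
      if (i < len) {
        int leaf = new_node(tstart + i, tstart + len);
        nodes[split].next[text[tstart + i]] = leaf;
        v = leaf;
      } else {
        v = split;
      }
      i = len;
    }
    nodes[v].ann.push_back(std::make_pair(seq, pos));
  }

  // Sum annotations over the subtree rooted at v into counts (length n_seq).
  void tally_subtree(int v, std::vector<int>& counts) const {
    std::vector<int> stack;
    stack.push_back(v);
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      for (size_t a = 0; a < nodes[u].ann.size(); ++a)
        ++counts[nodes[u].ann[a].first];
      for (std::map<int, int>::const_iterator it = nodes[u].next.begin();
           it != nodes[u].next.end(); ++it)
        stack.push_back(it->second);
    }
  }
};

static int code_of(char c) {
  size_t p = IUPAC.find(c);
  if (p == std::string::npos) return -1;
  return (int)p;
}

// [[Rcpp::export]]
SEXP gst_build_cpp(CharacterVector seqs, int max_depth) {
  int n = seqs.size();
  if (n < 1) stop("need at least one sequence");
  Gst* g = new Gst();
  g->n_seq = n;
  g->max_depth = max_depth;
  size_t total = 0;
  for (int i = 0; i < n; ++i) total += std::string(seqs[i]).size() + 1;
  g->text.reserve(total);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (s.empty()) { delete g; stop("sequence %d is empty", i + 1); }
    g->seq_begin.push_back((int)g->text.size());
    for (size_t j = 0; j < s.size(); ++j) {
      int c = code_of(s[j]);
      if (c < 0) {
        delete g;
        stop("sequence %d contains non-IUPAC character '%c'", i + 1, s[j]);
      }
      g->text.push_back(c);
    }
    g->seq_sent.push_back((int)g->text.size());
    g->text.push_back(SENTINEL_BASE + i);
  }

  g->new_node(-1, -1);  // root
  if (max_depth <= 0) {
    for (int pos = 0; pos < (int)g->text.size(); ++pos) g->extend(pos);
    g->finalize_full();
  } else {
    for (int i = 0; i < n; ++i) {
      int b = g->seq_begin[i], sent = g->seq_sent[i];
      for (int p = b; p <= sent; ++p) {
        int len = sent + 1 - p;             // up to and including sentinel
        if (len > max_depth) len = max_depth;
        g->insert_truncated(p, len, i, p - b);
      }
    }
  }
  XPtr<Gst> ptr(g, true);
  return ptr;
}

// [[Rcpp::export]]
IntegerVector gst_count_word_cpp(SEXP tree, std::string w) {
  XPtr<Gst> g(tree);
  int n = g->n_seq;
  std::vector<int> counts(n, 0);
  std::vector<int> code(w.size());
  for (size_t i = 0; i < w.size(); ++i) {
    int c = code_of(w[i]);
    if (c < 0 || c > 3) stop("query word must be over {A,C,G,T}");
    code[i] = c;
  }
  int v = 0;
  size_t matched = 0;
  bool found = true;
  while (matched < code.size()) {
    std::map<int, int>::const_iterator it =
      g->nodes[v].next.find(code[matched]);
    if (it == g->nodes[v].next.end()) { found = false; break; }
    int u = it->second;
    int elen = g->nodes[u].end - g->nodes[u].start;
    for (int j = 0; j < elen && matched < code.size(); ++j, ++matched) {
      if (g->text[g->nodes[u].start + j] != code[matched]) {
        found = false;
        break;
      }
    }
    if (!found) break;
    v = u;
  }
  if (found) g->tally_subtree(v, counts);
  return wrap(counts);
}

// Bulk collection of all ACGT words at string depth exactly L.  The
// recursion only descends while depth < L, so its depth is bounded by L;
// subtree tallies below the depth-L frontier are iterative.
static void words_dfs(const Gst* g, int v, int depth, std::string& buf,
                      std::vector<std::string>& words,
                      std::vector<std::vector<int> >& mats, int L) {
  for (std::map<int, int>::const_iterator it = g->nodes[v].next.begin();
       it != g->nodes[v].next.end(); ++it) {
    int u = it->second;
    int elen = g->nodes[u].end - g->nodes[u].start;
    int take = L - depth < elen ? L - depth : elen;
    bool ok = true;
    for (int j = 0; j < take; ++j) {
      int c = g->text[g->nodes[u].start + j];
      if (c > 3) { ok = false; break; }      // ambiguity letter or sentinel
      buf[depth + j] = IUPAC[c];
    }
    if (!ok) continue;
    if (depth + take == L) {
      std::vector<int> counts(g->n_seq, 0);
      g->tally_subtree(u, counts);
      words.push_back(buf);
      mats.push_back(counts);
    } else {
      words_dfs(g, u, depth + elen, buf, words, mats, L);
    }
  }
}

// [[Rcpp::export]]
List gst_words_at_depth_cpp(SEXP tree, int L) {
  XPtr<Gst> g(tree);
  if (L < 1) stop("L must be >= 1");
  std::string buf(L, 'A');
  std::vector<std::string> words;
  std::vector<std::vector<int> > mats;
  words_dfs(g, 0, 0, buf, words, mats, L);
  IntegerMatrix counts(g->n_seq, (int)words.size());
  for (size_t k = 0; k < mats.size(); ++k)
    for (int i = 0; i < g->n_seq; ++i)
      counts(i, (int)k) = mats[k][i];
  return List::create(_["words"] = wrap(words), _["counts"] = counts);
}

// [[Rcpp::export]]
List gst_stats_cpp(SEXP tree) {
  XPtr<Gst> g(tree);
  int leaves = 0, internal = 0;
  size_t anns = 0;
  for (size_t v = 1; v < g->nodes.size(); ++v) {
    if (g->nodes[v].next.empty()) ++leaves; else ++internal;
    anns += g->nodes[v].ann.size();
  }
  return List::create(
    _["n_nodes"] = (int)g->nodes.size(),
    _["n_leaves"] = leaves,
    _["n_internal"] = internal + 1,  // incl. root
    _["n_annotations"] = (double)anns,
    _["text_length"] = (int)g->text.size(),
    _["max_depth"] = g->max_depth);
}

// One row per leaf annotation: sequence (1-based), suffix start (1-based),
// and the spelled root-to-node path with the sentinel rendered as '$'.
// [[Rcpp::export]]
DataFrame gst_annotations_cpp(SEXP tree) {
  XPtr<Gst> g(tree);
  std::vector<int> seq_out, pos_out;
  std::vector<std::string> path_out;
  // iterative DFS carrying the spelled path length per node
  std::vector<std::pair<int, int> > stack;  // (node, parent depth)
  std::string buf;
  for (std::map<int, int>::const_reverse_iterator it = g->nodes[0].next.rbegin();
       it != g->nodes[0].next.rend(); ++it)
    stack.push_back(std::make_pair(it->second, 0));
  while (!stack.empty()) {
    int v = stack.back().first;
    int d0 = stack.back().second;
    stack.pop_back();
    buf.resize(d0);
    int elen = g->nodes[v].end - g->nodes[v].start;
    for (int j = 0; j < elen; ++j) {
      int c = g->text[g->nodes[v].start + j];
      buf.push_back(c >= SENTINEL_BASE ? '$' : IUPAC[c]);
    }
    for (size_t a = 0; a < g->nodes[v].ann.size(); ++a) {
      seq_out.push_back(g->nodes[v].ann[a].first + 1);
      pos_out.push_back(g->nodes[v].ann[a].second + 1);
      path_out.push_back(buf);
    }
    for (std::map<int, int>::const_reverse_iterator it = g->nodes[v].next.rbegin();
         it != g->nodes[v].next.rend(); ++it)
      stack.push_back(std::make_pair(it->second, d0 + elen));
  }
  return DataFrame::create(_["seq"] = wrap(seq_out), _["pos"] = wrap(pos_out),
                           _["path"] = wrap(path_out),
                           _["stringsAsFactors"] = false);
}

// Structural audit: path compression (every internal non-root node has >= 2
// children), non-empty edges, distinct first symbols (by construction of the
// child map, verified via edge starts), and annotation placement.
// [[Rcpp::export]]
List gst_check_cpp(SEXP tree) {
  XPtr<Gst> g(tree);
  int single_child = 0, empty_edge = 0, bad_first = 0, ann_on_branching = 0;
  for (size_t v = 1; v < g->nodes.size(); ++v) {
    const GstNode& nd = g->nodes[v];
    if (nd.end - nd.start < 1) ++empty_edge;
    if (!nd.next.empty() && nd.next.size() < 2) ++single_child;
    if (!nd.next.empty() && !nd.ann.empty() && g->max_depth <= 0)
      ++ann_on_branching;
    for (std::map<int, int>::const_iterator it = nd.next.begin();
         it != nd.next.end(); ++it)
      if (g->text[g->nodes[it->second].start] != it->first) ++bad_first;
  }
  for (std::map<int, int>::const_iterator it = g->nodes[0].next.begin();
       it != g->nodes[0].next.end(); ++it)
    if (g->text[g->nodes[it->second].start] != it->first) ++bad_first;
  bool ok = single_child == 0 && empty_edge == 0 && bad_first == 0 &&
            ann_on_branching == 0;
  return List::create(_["ok"] = ok, _["single_child_internal"] = single_child,
                      _["empty_edge"] = empty_edge,
                      _["first_symbol_mismatch"] = bad_first,
                      _["annotation_on_branching_node"] = ann_on_branching);
}
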