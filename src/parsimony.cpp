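// Parsimony engine: Fitch / Sankoff scoring, exact tree enumeration,
// branch-and-bound, stepwise addition and SPR neighborhoods.
//
// Conventions shared with the R side:
//  * character states are bitmasks (bit s set <=> state s allowed at the tip);
//    missing tips carry the full alphabet, polymorphic tips a multi-bit mask;
//  * rooted trees use ape's encoding (tips 1..nTip, edge matrix parent/child);
//  * unrooted trees in the search engine are plain edge lists with tips
//    0..nTip-1 and internal nodes nTip..2*nTip-3 (0-based internally,
//    exported 1-based).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ------------------------------------------------------------------
// rooted-tree utilities (ape edge matrices)
// ------------------------------------------------------------------

struct Rooted {
  int nNode;                           // max node id
  int root;
  std::vector<std::vector<int> > kids; // kids[v]
  std::vector<int> post;               // postorder (children before parents)
};

static Rooted build_rooted(const IntegerMatrix& edge, int nTip) {
  Rooted t;
  int m = edge.nrow();
  t.nNode = nTip;
  for (int i = 0; i < m; ++i) {
    if (edge(i, 0) > t.nNode) t.nNode = edge(i, 0);
    if (edge(i, 1) > t.nNode) t.nNode = edge(i, 1);
  }
  t.kids.assign(t.nNode + 1, std::vector<int>());
  std::vector<char> isChild(t.nNode + 1, 0);
  for (int i = 0; i < m; ++i) {
    t.kids[edge(i, 0)].push_back(edge(i, 1));
    isChild[edge(i, 1)] = 1;
  }
  t.root = -1;
  for (int v = 1; v <= t.nNode; ++v)
    if (!isChild[v] && !t.kids[v].empty()) { t.root = v; break; }
  if (t.root < 0) stop("edge matrix has no root");
  // iterative postorder
  std::vector<int> stack1, stack2;
  stack1.push_back(t.root);
  while (!stack1.empty()) {
    int v = stack1.back(); stack1.pop_back();
    stack2.push_back(v);
    for (size_t j = 0; j < t.kids[v].size(); ++j) stack1.push_back(t.kids[v][j]);
  }
  t.post.assign(stack2.rbegin(), stack2.rend());
  return t;
}

// Fitch pass for one character on a rooted tree whose internal nodes have at
// most two children (pass-through nodes of one child are tolerated, as is a
// tip used as root). Returns the minimum number of state changes.
// [[Rcpp::export]]
int fitch_steps_cpp(IntegerMatrix edge, int nTip, IntegerVector tipSets) {
  Rooted t = build_rooted(edge, nTip);
  std::vector<uint32_t> S(t.nNode + 1, 0u);
  int steps = 0;
  for (size_t i = 0; i < t.post.size(); ++i) {
    int v = t.post[i];
    const std::vector<int>& k = t.kids[v];
    if (k.empty()) { S[v] = (uint32_t) tipSets[v - 1]; continue; }
    if (k.size() > 2) stop("fitch_steps: tree is not binary");
    uint32_t s;
    if (k.size() == 1) {
      s = S[k[0]];
    } else {
      uint32_t a = S[k[0]], b = S[k[1]];
      uint32_t inter = a & b;
      if (inter) s = inter; else { s = a | b; ++steps; }
    }
    if (v <= nTip) {               // root placed on a tip
      uint32_t own = (uint32_t) tipSets[v - 1];
      if (s & own) s &= own; else ++steps;
    }
    S[v] = s;
  }
  return steps;
}

// Generalized (Sankoff) parsimony for one character under an arbitrary cost
// matrix; handles multifurcations and polymorphic/missing tips.
// [[Rcpp::export]]
double sankoff_steps_cpp(IntegerMatrix edge, int nTip, IntegerVector tipSets,
                         NumericMatrix cost) {
  int ns = cost.nrow();
  if (cost.ncol() != ns) stop("cost matrix must be square");
  Rooted t = build_rooted(edge, nTip);
  std::vector<double> D((t.nNode + 1) * ns, 0.0);
  for (size_t i = 0; i < t.post.size(); ++i) {
    int v = t.post[i];
    double* dv = &D[v * ns];
    uint32_t own = (v <= nTip) ? (uint32_t) tipSets[v - 1] : ~0u;
    for (int s = 0; s < ns; ++s)
      dv[s] = (own & (1u << s)) ? 0.0 : INF;
    const std::vector<int>& k = t.kids[v];
    for (size_t j = 0; j < k.size(); ++j) {
      double* dc = &D[k[j] * ns];
      for (int s = 0; s < ns; ++s) {
        if (dv[s] == INF) continue;
        double best = INF;
        for (int u = 0; u < ns; ++u) {
          double c = cost(s, u) + dc[u];
          if (c < best) best = c;
        }
        dv[s] += best;
      }
    }
  }
  double best = INF;
  double* dr = &D[t.root * ns];
  for (int s = 0; s < ns; ++s) if (dr[s] < best) best = dr[s];
  return best;
}

// Per-character step counts for a whole matrix on a rooted tree.
// tipStates: nTip x nChar bitmask matrix. ordered chars use linear step
// costs |i-j|; unordered use Fitch when the tree is binary, unit-cost
// Sankoff otherwise (correct on polytomies).
// [[Rcpp::export]]
NumericVector matrix_steps_cpp(IntegerMatrix edge, int nTip,
                               IntegerMatrix tipStates,
                               LogicalVector ordered, IntegerVector nstates) {
  int nChar = tipStates.ncol();
  Rooted t = build_rooted(edge, nTip);
  bool binary = true;
  for (int v = 1; v <= t.nNode; ++v)
    if (t.kids[v].size() > 2) { binary = false; break; }

  NumericVector out(nChar);
  std::vector<uint32_t> S(t.nNode + 1);
  std::vector<double> D;
  for (int c = 0; c < nChar; ++c) {
    int ns = nstates[c];
    if (!ordered[c] && binary) {
      int steps = 0;
      for (size_t i = 0; i < t.post.size(); ++i) {
        int v = t.post[i];
        const std::vector<int>& k = t.kids[v];
        if (k.empty()) { S[v] = (uint32_t) tipStates(v - 1, c); continue; }
        uint32_t s;
        if (k.size() == 1) s = S[k[0]];
        else {
          uint32_t inter = S[k[0]] & S[k[1]];
          if (inter) s = inter; else { s = S[k[0]] | S[k[1]]; ++steps; }
        }
        if (v <= nTip) {
          uint32_t own = (uint32_t) tipStates(v - 1, c);
          if (s & own) s &= own; else ++steps;
        }
        S[v] = s;
      }
      out[c] = steps;
    } else {
      D.assign((size_t)(t.nNode + 1) * ns, 0.0);
      for (size_t i = 0; i < t.post.size(); ++i) {
        int v = t.post[i];
        double* dv = &D[(size_t) v * ns];
        uint32_t own = (v <= nTip) ? (uint32_t) tipStates(v - 1, c) : ~0u;
        for (int s = 0; s < ns; ++s) dv[s] = (own & (1u << s)) ? 0.0 : INF;
        const std::vector<int>& k = t.kids[v];
        for (size_t j = 0; j < k.size(); ++j) {
          double* dc = &D[(size_t) k[j] * ns];
          for (int s = 0; s < ns; ++s) {
            if (dv[s] == INF) continue;
            double best = INF;
            for (int u = 0; u < ns; ++u) {
              double step = ordered[c] ? std::abs(s - u) : (s == u ? 0.0 : 1.0);
              double v2 = step + dc[u];
              if (v2 < best) best = v2;
            }
            dv[s] += best;
          }
        }
      }
      double best = INF;
      double* dr = &D[(size_t) t.root * ns];
      for (int s = 0; s < ns; ++s) if (dr[s] < best) best = dr[s];
      out[c] = best;
    }
  }
  return out;
}

// ------------------------------------------------------------------
// search engine on unrooted edge lists
// ------------------------------------------------------------------

struct Engine {
  int nTip, nChar;
  std::vector<uint32_t> st;      // tip-major bitmasks: st[tip*nChar + c]
  std::vector<char> ord;
  std::vector<int> ns;
  std::vector<double> w;         // per-character weights
  std::vector<double> mref;      // per-character min steps on the FULL taxon
                                 // set (admissible es lower bound for IW)
  double K;
  bool implied;

  // current unrooted tree
  std::vector<int> eu, ev;       // edge endpoints, 0-based node ids
  int nEdges;

  // scratch for scoring
  int maxNodes;
  std::vector<int> head, nxt, to;        // adjacency as linked lists
  std::vector<int> post, parent;         // postorder over nodes
  std::vector<uint32_t> inA, unA; std::vector<int> cntA;
  std::vector<uint32_t> setA;
  std::vector<double> dp, acc;

  void init(int nTip_, const IntegerMatrix& tipStates,
            const LogicalVector& ordered, const IntegerVector& nstates,
            const NumericVector& weights, const NumericVector& minref,
            double K_, bool implied_) {
    nTip = nTip_; nChar = tipStates.ncol();
    st.resize((size_t) nTip * nChar);
    for (int i = 0; i < nTip; ++i)
      for (int c = 0; c < nChar; ++c)
        st[(size_t) i * nChar + c] = (uint32_t) tipStates(i, c);
    ord.assign(nChar, 0); ns.resize(nChar); w.resize(nChar); mref.resize(nChar);
    for (int c = 0; c < nChar; ++c) {
      ord[c] = ordered[c] ? 1 : 0;
      ns[c] = nstates[c];
      w[c] = weights[c];
      mref[c] = minref[c];
    }
    K = K_; implied = implied_;
    maxNodes = 2 * nTip - 2;
    eu.assign(2 * nTip - 3, -1); ev.assign(2 * nTip - 3, -1); nEdges = 0;
    head.assign(maxNodes, -1);
    nxt.assign(2 * (2 * nTip - 3), -1);
    to.assign(2 * (2 * nTip - 3), -1);
    post.resize(maxNodes); parent.resize(maxNodes);
    inA.resize(maxNodes); unA.resize(maxNodes); cntA.resize(maxNodes);
    setA.resize(maxNodes);
    int maxNs = 2;
    for (int c = 0; c < nChar; ++c) if (ns[c] > maxNs) maxNs = ns[c];
    dp.resize((size_t) maxNodes * maxNs);
    acc.resize((size_t) maxNodes * maxNs);
  }

  // score the current (possibly partial) unrooted tree rooted at tip `r`;
  // `extra` (optional, per character) adds an admissible completion bound
  // for the taxa not yet on the tree
  double score(int r, const int* extra = 0) {
    // adjacency
    std::fill(head.begin(), head.end(), -1);
    int slot = 0;
    for (int i = 0; i < nEdges; ++i) {
      int a = eu[i], b = ev[i];
      to[slot] = b; nxt[slot] = head[a]; head[a] = slot; ++slot;
      to[slot] = a; nxt[slot] = head[b]; head[b] = slot; ++slot;
    }
    // DFS postorder from r
    int nPost = 0;
    std::vector<int>& stk = cntA;  // reuse as stack storage is unsafe; use local
    (void) stk;
    {
      static thread_local std::vector<int> stack1, stack2;
      stack1.clear(); stack2.clear();
      stack1.push_back(r); parent[r] = -1;
      while (!stack1.empty()) {
        int v = stack1.back(); stack1.pop_back();
        stack2.push_back(v);
        for (int e = head[v]; e != -1; e = nxt[e]) {
          int u = to[e];
          if (u != parent[v]) { parent[u] = v; stack1.push_back(u); }
        }
      }
      nPost = (int) stack2.size();
      for (int i = 0; i < nPost; ++i) post[i] = stack2[nPost - 1 - i];
    }

    double total = 0.0;
    for (int c = 0; c < nChar; ++c) {
      if (w[c] == 0.0) continue;
      double steps;
      if (!ord[c]) {
        // Fitch (rooted at tip r; all internals have exactly 2 children here)
        int stp = 0;
        for (int i = 0; i < nPost; ++i) { inA[post[i]] = ~0u; unA[post[i]] = 0u; cntA[post[i]] = 0; }
        for (int i = 0; i < nPost; ++i) {
          int v = post[i];
          uint32_t s;
          if (v < nTip && v != r) {
            s = st[(size_t) v * nChar + c];
          } else if (cntA[v] == 1) {
            s = inA[v];
          } else {
            uint32_t inter = inA[v];
            if (inter) s = inter; else { s = unA[v]; ++stp; }
          }
          if (v == r) {           // root tip: reconcile with own states
            uint32_t own = st[(size_t) r * nChar + c];
            if (s & own) s &= own; else ++stp;
            setA[v] = s;
            break;
          }
          setA[v] = s;
          int p = parent[v];
          if (cntA[p] == 0) { inA[p] = s; unA[p] = s; }
          else { inA[p] &= s; unA[p] |= s; }
          ++cntA[p];
        }
        steps = stp;
      } else {
        int nsc = ns[c];
        for (int i = 0; i < nPost; ++i) {
          int v = post[i];
          double* dv = &dp[(size_t) v * nsc];
          uint32_t own = (v < nTip) ? st[(size_t) v * nChar + c] : ~0u;
          for (int s = 0; s < nsc; ++s) dv[s] = (own & (1u << s)) ? 0.0 : INF;
        }
        for (int i = 0; i < nPost; ++i) {
          int v = post[i];
          if (v == r) break;
          int p = parent[v];
          double* dv = &dp[(size_t) v * nsc];
          double* dpv = &dp[(size_t) p * nsc];
          for (int s = 0; s < nsc; ++s) {
            if (dpv[s] == INF) continue;
            double best = INF;
            for (int u = 0; u < nsc; ++u) {
              double v2 = std::abs(s - u) + dv[u];
              if (v2 < best) best = v2;
            }
            dpv[s] += best;
          }
        }
        double best = INF;
        double* dr = &dp[(size_t) r * nsc];
        for (int s = 0; s < nsc; ++s) if (dr[s] < best) best = dr[s];
        steps = best;
      }
      if (extra) steps += extra[c];
      if (implied) {
        double es = steps - mref[c];
        if (es < 0) es = 0;
        total += w[c] * es / (K + es);
      } else {
        total += w[c] * steps;
      }
    }
    return total;
  }
};

static IntegerMatrix edges_out(const Engine& E) {
  IntegerMatrix m(E.nEdges, 2);
  for (int i = 0; i < E.nEdges; ++i) { m(i, 0) = E.eu[i] + 1; m(i, 1) = E.ev[i] + 1; }
  return m;
}

struct SearchState {
  Engine E;
  std::vector<int> order;      // tip addition order, 0-based
  bool useBound;
  double best;
  double eps;
  long nodesVisited;
  long maxTrees;
  std::vector<int> extras;     // (nTip+1) x nChar, level-major completion bounds
  std::vector<std::vector<int> > optU, optV;

  void start3() {
    int hub = E.nTip;  // first internal node
    E.nEdges = 0;
    for (int j = 0; j < 3; ++j) {
      E.eu[E.nEdges] = hub; E.ev[E.nEdges] = order[j]; ++E.nEdges;
    }
  }

  void recurse(int k) {
    if (k == (int) order.size()) {
      double sc = E.score(order[0]);
      ++nodesVisited;
      if (sc < best - eps) {
        best = sc;
        optU.clear(); optV.clear();
      }
      if (sc < best) best = sc;   // keep the exact optimum (the initial
                                  // upper bound may sit eps above it)
      if (sc <= best + eps && (long) optU.size() < maxTrees) {
        optU.push_back(std::vector<int>(E.eu.begin(), E.eu.begin() + E.nEdges));
        optV.push_back(std::vector<int>(E.ev.begin(), E.ev.begin() + E.nEdges));
      }
      return;
    }
    if ((nodesVisited & 1023) == 0) Rcpp::checkUserInterrupt();
    int tip = order[k];
    int newNode = E.nTip + (k - 2);
    int m = E.nEdges;
    for (int i = 0; i < m; ++i) {
      int ou = E.eu[i], ov = E.ev[i];
      // split edge i with newNode, hang tip
      E.ev[i] = newNode;
      E.eu[E.nEdges] = newNode; E.ev[E.nEdges] = ov; ++E.nEdges;
      E.eu[E.nEdges] = newNode; E.ev[E.nEdges] = tip; ++E.nEdges;
      bool ok = true;
      if (useBound) {
        ++nodesVisited;
        const int* ex = extras.empty() ? 0 : &extras[(size_t)(k + 1) * E.nChar];
        double lb = E.score(order[0], ex);   // admissible lower bound
        if (lb > best + eps) ok = false;
      }
      if (ok) recurse(k + 1);
      E.nEdges -= 2;
      E.ev[i] = ov; (void) ou;
    }
  }
};

static List run_search(IntegerMatrix tipStates, LogicalVector ordered,
                       IntegerVector nstates, NumericVector weights,
                       NumericVector minref, double K, bool implied,
                       IntegerVector order, bool useBound, double upper,
                       int maxTrees, Nullable<IntegerMatrix> extras = R_NilValue) {
  int nTip = tipStates.nrow();
  if (nTip < 3) stop("need at least 3 taxa");
  SearchState S;
  S.E.init(nTip, tipStates, ordered, nstates, weights, minref, K, implied);
  S.order.resize(nTip);
  for (int i = 0; i < nTip; ++i) S.order[i] = order[i] - 1;
  S.useBound = useBound;
  if (extras.isNotNull()) {
    IntegerMatrix ex(extras);
    if (ex.nrow() != nTip + 1 || ex.ncol() != S.E.nChar)
      stop("extras must be (nTip+1) x nChar");
    S.extras.resize((size_t)(nTip + 1) * S.E.nChar);
    for (int l = 0; l <= nTip; ++l)
      for (int c = 0; c < S.E.nChar; ++c)
        S.extras[(size_t) l * S.E.nChar + c] = ex(l, c);
  }
  S.best = upper;
  S.eps = 1e-9;
  S.nodesVisited = 0;
  S.maxTrees = maxTrees;
  S.start3();
  S.recurse(3);
  List trees(S.optU.size());
  for (size_t t = 0; t < S.optU.size(); ++t) {
    IntegerMatrix m(S.optU[t].size(), 2);
    for (size_t i = 0; i < S.optU[t].size(); ++i) {
      m(i, 0) = S.optU[t][i] + 1; m(i, 1) = S.optV[t][i] + 1;
    }
    trees[t] = m;
  }
  return List::create(_["score"] = S.best, _["trees"] = trees,
                      _["nodes_visited"] = (double) S.nodesVisited);
}

// Exhaustive enumeration of all unrooted topologies (no pruning).
// [[Rcpp::export]]
List exhaustive_cpp(IntegerMatrix tipStates, LogicalVector ordered,
                    IntegerVector nstates, NumericVector weights,
                    NumericVector minref, double K, bool implied,
                    IntegerVector order, int maxTrees) {
  return run_search(tipStates, ordered, nstates, weights, minref, K, implied,
                    order, false, INF, maxTrees);
}

// Branch and bound: prunes insertion branches whose partial score already
// exceeds the best complete score seen (partial scores are admissible lower
// bounds: adding taxa can only increase each character's length, and the
// implied-weighting penalty uses es >= steps(partial) - min_steps(full)).
// [[Rcpp::export]]
List branch_and_bound_cpp(IntegerMatrix tipStates, LogicalVector ordered,
                          IntegerVector nstates, NumericVector weights,
                          NumericVector minref, double K, bool implied,
                          IntegerVector order, double upper, int maxTrees,
                          Nullable<IntegerMatrix> extras) {
  return run_search(tipStates, ordered, nstates, weights, minref, K, implied,
                    order, true, upper, maxTrees, extras);
}

// Greedy stepwise addition following `order`; ties broken uniformly at
// random using R's RNG (reproducible under set.seed on the R side).
// [[Rcpp::export]]
List stepwise_addition_cpp(IntegerMatrix tipStates, LogicalVector ordered,
                           IntegerVector nstates, NumericVector weights,
                           NumericVector minref, double K, bool implied,
                           IntegerVector order) {
  int nTip = tipStates.nrow();
  if (nTip < 3) stop("need at least 3 taxa");
  Engine E;
  E.init(nTip, tipStates, ordered, nstates, weights, minref, K, implied);
  std::vector<int> ord(nTip);
  for (int i = 0; i < nTip; ++i) ord[i] = order[i] - 1;
  int hub = nTip;
  E.nEdges = 0;
  for (int j = 0; j < 3; ++j) { E.eu[E.nEdges] = hub; E.ev[E.nEdges] = ord[j]; ++E.nEdges; }
  RNGScope rng;
  for (int k = 3; k < nTip; ++k) {
    int tip = ord[k], newNode = nTip + (k - 2);
    int m = E.nEdges;
    double bestSc = INF; int bestEdge = -1; int nBest = 0;
    for (int i = 0; i < m; ++i) {
      int ov = E.ev[i];
      E.ev[i] = newNode;
      E.eu[E.nEdges] = newNode; E.ev[E.nEdges] = ov; ++E.nEdges;
      E.eu[E.nEdges] = newNode; E.ev[E.nEdges] = tip; ++E.nEdges;
      double sc = E.score(ord[0]);
      E.nEdges -= 2;
      E.ev[i] = ov;
      if (sc < bestSc - 1e-12) { bestSc = sc; bestEdge = i; nBest = 1; }
      else if (sc <= bestSc + 1e-12) {
        ++nBest;
        if (R::unif_rand() < 1.0 / nBest) bestEdge = i;
      }
    }
    int ov = E.ev[bestEdge];
    E.ev[bestEdge] = newNode;
    E.eu[E.nEdges] = newNode; E.ev[E.nEdges] = ov; ++E.nEdges;
    E.eu[E.nEdges] = newNode; E.ev[E.nEdges] = tip; ++E.nEdges;
  }
  double sc = E.score(ord[0]);
  return List::create(_["score"] = sc, _["edges"] = edges_out(E));
}

// Score one unrooted tree given as a 1-based edge list (tips 1..nTip).
// [[Rcpp::export]]
double score_unrooted_cpp(IntegerMatrix edges, IntegerMatrix tipStates,
                          LogicalVector ordered, IntegerVector nstates,
                          NumericVector weights, NumericVector minref,
                          double K, bool implied) {
  int nTip = tipStates.nrow();
  Engine E;
  E.init(nTip, tipStates, ordered, nstates, weights, minref, K, implied);
  E.nEdges = edges.nrow();
  for (int i = 0; i < E.nEdges; ++i) { E.eu[i] = edges(i, 0) - 1; E.ev[i] = edges(i, 1) - 1; }
  return E.score(0);
}

// All SPR neighbors of an unrooted tree; returns the best neighbor score and
// every neighbor edge list attaining it (up to maxKeep).
// [[Rcpp::export]]
List spr_neighbors_cpp(IntegerMatrix edges, IntegerMatrix tipStates,
                       LogicalVector ordered, IntegerVector nstates,
                       NumericVector weights, NumericVector minref,
                       double K, bool implied, int maxKeep) {
  int nTip = tipStates.nrow();
  int nE = edges.nrow();
  Engine E;
  E.init(nTip, tipStates, ordered, nstates, weights, minref, K, implied);

  std::vector<int> baseU(nE), baseV(nE);
  for (int i = 0; i < nE; ++i) { baseU[i] = edges(i, 0) - 1; baseV[i] = edges(i, 1) - 1; }
  int nNodes = 2 * nTip - 2;

  double bestSc = INF;
  std::vector<std::vector<int> > keepU, keepV;
  long nScored = 0;

  std::vector<std::vector<int> > adj(nNodes);
  std::vector<char> inPruned(nNodes);
  std::vector<int> stack1;

  for (int e = 0; e < nE; ++e) {
    for (int dir = 0; dir < 2; ++dir) {
      int u = dir == 0 ? baseU[e] : baseV[e];
      int v = dir == 0 ? baseV[e] : baseU[e];
      // prune the v-side component; u must be internal (degree 3)
      if (u < nTip) continue;
      // adjacency of the base tree
      for (int i = 0; i < nNodes; ++i) adj[i].clear();
      for (int i = 0; i < nE; ++i) {
        adj[baseU[i]].push_back(baseV[i]);
        adj[baseV[i]].push_back(baseU[i]);
      }
      // mark pruned component (v side, excluding edge e)
      std::fill(inPruned.begin(), inPruned.end(), 0);
      stack1.clear(); stack1.push_back(v); inPruned[v] = 1;
      while (!stack1.empty()) {
        int x = stack1.back(); stack1.pop_back();
        for (size_t j = 0; j < adj[x].size(); ++j) {
          int y = adj[x][j];
          if ((x == v && y == u)) continue;
          if (!inPruned[y]) { inPruned[y] = 1; stack1.push_back(y); }
        }
      }
      if (inPruned[u]) continue;        // shouldn't happen on a tree
      // u's two other neighbors a, b
      int a = -1, b = -1;
      for (size_t j = 0; j < adj[u].size(); ++j) {
        int y = adj[u][j];
        if (y == v) continue;
        if (a < 0) a = y; else b = y;
      }
      if (a < 0 || b < 0) continue;
      // remaining component's edges: all base edges not incident to u and
      // not inside the pruned component, plus the merged edge (a, b)
      for (int t = 0; t < nE; ++t) {
        int x = baseU[t], y = baseV[t];
        if (x == u || y == u) continue;         // replaced by (a,b) / removed
        if (inPruned[x] || inPruned[y]) continue;
        // reattach on edge (x, y): new tree edges =
        //   all kept edges except (x,y), plus (a,b), (x,u), (u,y), (u,v)
        E.nEdges = 0;
        for (int q = 0; q < nE; ++q) {
          int qx = baseU[q], qy = baseV[q];
          if (q == t) continue;
          if (qx == u || qy == u) continue;
          if (q != e && (inPruned[qx] || inPruned[qy])) {
            // pruned-side edge: kept verbatim
            E.eu[E.nEdges] = qx; E.ev[E.nEdges] = qy; ++E.nEdges;
            continue;
          }
          if (q == e) continue;
          E.eu[E.nEdges] = qx; E.ev[E.nEdges] = qy; ++E.nEdges;
        }
        E.eu[E.nEdges] = a; E.ev[E.nEdges] = b; ++E.nEdges;
        E.eu[E.nEdges] = x; E.ev[E.nEdges] = u; ++E.nEdges;
        E.eu[E.nEdges] = u; E.ev[E.nEdges] = y; ++E.nEdges;
        E.eu[E.nEdges] = u; E.ev[E.nEdges] = v; ++E.nEdges;
        if (E.nEdges != nE) continue;  // defensive
        double sc = E.score(0);
        ++nScored;
        if (sc < bestSc - 1e-9) {
          bestSc = sc; keepU.clear(); keepV.clear();
        }
        if (sc <= bestSc + 1e-9 && (int) keepU.size() < maxKeep) {
          keepU.push_back(std::vector<int>(E.eu.begin(), E.eu.begin() + E.nEdges));
          keepV.push_back(std::vector<int>(E.ev.begin(), E.ev.begin() + E.nEdges));
        }
      }
    }
    if ((e & 7) == 0) Rcpp::checkUserInterrupt();
  }
  List trees(keepU.size());
  for (size_t t = 0; t < keepU.size(); ++t) {
    IntegerMatrix m(keepU[t].size(), 2);
    for (size_t i = 0; i < keepU[t].size(); ++i) {
      m(i, 0) = keepU[t][i] + 1; m(i, 1) = keepV[t][i] + 1;
    }
    trees[t] = m;
  }
  return List::create(_["best_score"] = bestSc, _["trees"] = trees,
                      _["n_scored"] = (double) nScored);
}

// ------------------------------------------------------------------
// minimum branch lengths (for the PAUP "amb-" style collapse rule)
// ------------------------------------------------------------------

// For each edge of a rooted binary tree, report whether EVERY character
// admits an optimal reconstruction with zero changes on that edge
// (=> minimum branch length 0). Uses in/out Sankoff cost vectors.
// [[Rcpp::export]]
LogicalVector zero_length_edges_cpp(IntegerMatrix edge, int nTip,
                                    IntegerMatrix tipStates,
                                    LogicalVector ordered,
                                    IntegerVector nstates) {
  int nChar = tipStates.ncol();
  Rooted t = build_rooted(edge, nTip);
  int m = edge.nrow();
  LogicalVector canZero(m);
  for (int i = 0; i < m; ++i) canZero[i] = true;

  std::vector<int> parentOf(t.nNode + 1, 0);
  for (int i = 0; i < m; ++i) parentOf[edge(i, 1)] = edge(i, 0);

  for (int c = 0; c < nChar; ++c) {
    int ns = nstates[c];
    bool isOrd = ordered[c];
    std::vector<double> D((size_t)(t.nNode + 1) * ns);
    // postorder D
    for (size_t ii = 0; ii < t.post.size(); ++ii) {
      int v = t.post[ii];
      double* dv = &D[(size_t) v * ns];
      uint32_t own = (v <= nTip) ? (uint32_t) tipStates(v - 1, c) : ~0u;
      for (int s = 0; s < ns; ++s) dv[s] = (own & (1u << s)) ? 0.0 : INF;
      const std::vector<int>& k = t.kids[v];
      for (size_t j = 0; j < k.size(); ++j) {
        double* dc = &D[(size_t) k[j] * ns];
        for (int s = 0; s < ns; ++s) {
          if (dv[s] == INF) continue;
          double best = INF;
          for (int u = 0; u < ns; ++u) {
            double step = isOrd ? std::abs(s - u) : (s == u ? 0.0 : 1.0);
            double v2 = step + dc[u];
            if (v2 < best) best = v2;
          }
          dv[s] += best;
        }
      }
    }
    double opt = INF;
    double* drt = &D[(size_t) t.root * ns];
    for (int s = 0; s < ns; ++s) if (drt[s] < opt) opt = drt[s];

    // OUT[v][s]: cost of the tree outside subtree(v) given parent(v) = s.
    std::vector<double> OUT((size_t)(t.nNode + 1) * ns, 0.0);
    // preorder = reverse postorder
    for (int ii = (int) t.post.size() - 1; ii >= 0; --ii) {
      int v = t.post[ii];
      const std::vector<int>& k = t.kids[v];
      for (size_t j = 0; j < k.size(); ++j) {
        int x = k[j];
        double* ox = &OUT[(size_t) x * ns];
        // v's own-state admissibility (root may be a tip; internal full)
        uint32_t ownV = (v <= nTip) ? (uint32_t) tipStates(v - 1, c) : ~0u;
        for (int s = 0; s < ns; ++s) {
          if (!(ownV & (1u << s))) { ox[s] = INF; continue; }
          double tot = 0.0;
          // siblings' subtree costs given v = s
          for (size_t j2 = 0; j2 < k.size(); ++j2) {
            if (j2 == j) continue;
            double* dy = &D[(size_t) k[j2] * ns];
            double best = INF;
            for (int u = 0; u < ns; ++u) {
              double step = isOrd ? std::abs(s - u) : (s == u ? 0.0 : 1.0);
              double v2 = step + dy[u];
              if (v2 < best) best = v2;
            }
            tot += best;
          }
          // contribution from above v
          if (v != t.root) {
            double* ov = &OUT[(size_t) v * ns];
            double best = INF;
            for (int u = 0; u < ns; ++u) {
              if (ov[u] == INF) continue;
              double step = isOrd ? std::abs(s - u) : (s == u ? 0.0 : 1.0);
              double v2 = step + ov[u];
              if (v2 < best) best = v2;
            }
            tot += best;
          }
          ox[s] = tot;
        }
      }
    }
    for (int i = 0; i < m; ++i) {
      if (!canZero[i]) continue;
      int x = edge(i, 1);
      double* dx = &D[(size_t) x * ns];
      double* ox = &OUT[(size_t) x * ns];
      double best = INF;
      for (int s = 0; s < ns; ++s) {
        if (ox[s] == INF || dx[s] == INF) continue;
        double v2 = dx[s] + ox[s];
        if (v2 < best) best = v2;
      }
      if (best > opt + 1e-9) canZero[i] = false;
    }
  }
  return canZero;
}
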