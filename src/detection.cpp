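// Local-search kernels for network detection.
//
// Both kernels are deterministic given their inputs: clique extraction
// seeds at the heaviest edges (ties broken lexicographically) and the
// k-partite relabeling takes its random initial labelings from R, so all
// randomness stays under R's set.seed control.

#include <Rcpp.h>
#include <algorithm>
#include <tuple>
#include <vector>
using namespace Rcpp;

static const double EPS = 1e-9;  // minimum gain counted as an improvement

// Greedy seed-and-grow extraction of node-disjoint clique-topology
// networks maximizing sum_{edges within S} (W_e - lambda).
//
// For each extraction round: seed at each of the top nRestarts heaviest
// active edges; alternately add the node with the largest score gain and
// remove the node whose removal gains most, until no single move improves
// the score (every accepted move strictly increases the score, so the
// search terminates). The best result with size >= minSize and score > 0
// is extracted and its nodes removed; rounds repeat until nothing positive
// remains or maxNetworks is reached.
// [[Rcpp::export]]
List cpp_detect_cliques(NumericMatrix W, double lambda, int minSize,
                        int maxNetworks, int nRestarts) {
  const int n = W.nrow();
  std::vector<char> active(n, 1);
  List outNodes;
  std::vector<double> outScores;

  while ((int)outNodes.size() < maxNetworks) {
    std::vector<std::tuple<double, int, int>> edges;
    for (int j = 1; j < n; ++j)
      for (int i = 0; i < j; ++i)
        if (active[i] && active[j]) edges.emplace_back(W(i, j), i, j);
    if (edges.empty()) break;
    const int R = std::min((int)edges.size(), nRestarts);
    std::partial_sort(
        edges.begin(), edges.begin() + R, edges.end(),
        [](const std::tuple<double, int, int>& a,
           const std::tuple<double, int, int>& b) {
          if (std::get<0>(a) != std::get<0>(b))
            return std::get<0>(a) > std::get<0>(b);
          if (std::get<1>(a) != std::get<1>(b))
            return std::get<1>(a) < std::get<1>(b);
          return std::get<2>(a) < std::get<2>(b);
        });

    double bestScore = EPS;
    std::vector<int> bestSet;
    std::vector<char> inSet(n);
    std::vector<double> deg(n);  // sum of W to current set members

    for (int r = 0; r < R; ++r) {
      std::fill(inSet.begin(), inSet.end(), 0);
      std::fill(deg.begin(), deg.end(), 0.0);
      int m = 0;
      double score = 0.0;

      auto addNode = [&](int v) {
        for (int u = 0; u < n; ++u)
          if (active[u] && u != v) deg[u] += W(u, v);
        inSet[v] = 1;
        ++m;
      };
      auto rmNode = [&](int v) {
        inSet[v] = 0;
        --m;
        for (int u = 0; u < n; ++u)
          if (active[u] && u != v) deg[u] -= W(u, v);
      };

      const int si = std::get<1>(edges[r]), sj = std::get<2>(edges[r]);
      score = W(si, sj) - lambda;
      addNode(si);
      addNode(sj);

      for (;;) {
        bool moved = false;
        // best single-node addition (ties -> smaller node index)
        int bv = -1;
        double bg = EPS;
        for (int v = 0; v < n; ++v) {
          if (!active[v] || inSet[v]) continue;
          const double g = deg[v] - lambda * m;
          if (g > bg) { bg = g; bv = v; }
        }
        if (bv >= 0) { score += bg; addNode(bv); moved = true; }
        // best single-node removal (never below a pair)
        if (m > 2) {
          int rv = -1;
          double rg = EPS;
          for (int v = 0; v < n; ++v) {
            if (!inSet[v]) continue;
            const double g = lambda * (m - 1) - deg[v];
            if (g > rg) { rg = g; rv = v; }
          }
          if (rv >= 0) { score += rg; rmNode(rv); moved = true; }
        }
        // swap neighborhood: exchange an outside node for a member
        // (lambda cancels: gain = deg[v] - deg[u] - W(u, v)); escapes
        // local optima that no single move can leave
        if (!moved) {
          int sv = -1, su = -1;
          double sg = EPS;
          for (int v = 0; v < n; ++v) {
            if (!active[v] || inSet[v]) continue;
            for (int u = 0; u < n; ++u) {
              if (!inSet[u]) continue;
              const double g = deg[v] - deg[u] - W(u, v);
              if (g > sg) { sg = g; sv = v; su = u; }
            }
          }
          if (sv >= 0) {
            score += sg;
            addNode(sv);
            rmNode(su);
            moved = true;
          }
        }
        // pair addition: two nodes whose joint inclusion pays even though
        // each alone does not (gain = deg[v] + deg[w] + W(v,w) - lambda(2m+1))
        if (!moved) {
          int av = -1, aw = -1;
          double ag = EPS;
          for (int v = 0; v < n; ++v) {
            if (!active[v] || inSet[v]) continue;
            for (int w = v + 1; w < n; ++w) {
              if (!active[w] || inSet[w]) continue;
              const double g =
                  deg[v] + deg[w] + W(v, w) - lambda * (2 * m + 1);
              if (g > ag) { ag = g; av = v; aw = w; }
            }
          }
          if (av >= 0) {
            score += ag;
            addNode(av);
            addNode(aw);
            moved = true;
          }
        }
        // pair removal (kept above the seed pair)
        if (!moved && m > 3) {
          int ru = -1, rw = -1;
          double rg = EPS;
          for (int u = 0; u < n; ++u) {
            if (!inSet[u]) continue;
            for (int w = u + 1; w < n; ++w) {
              if (!inSet[w]) continue;
              const double g =
                  lambda * (2 * m - 3) - deg[u] - deg[w] + W(u, w);
              if (g > rg) { rg = g; ru = u; rw = w; }
            }
          }
          if (ru >= 0) {
            score += rg;
            rmNode(ru);
            rmNode(rw);
            moved = true;
          }
        }
        if (!moved) break;
      }

      if (m >= minSize && score > bestScore) {
        bestScore = score;
        bestSet.clear();
        for (int v = 0; v < n; ++v)
          if (inSet[v]) bestSet.push_back(v + 1);
      }
    }

    if (bestSet.empty()) break;
    for (int v : bestSet) active[v - 1] = 0;
    outNodes.push_back(IntegerVector(bestSet.begin(), bestSet.end()));
    outScores.push_back(bestScore);
  }

  return List::create(_["nodes"] = outNodes,
                      _["scores"] = NumericVector(outScores.begin(),
                                                  outScores.end()));
}

// Kernighan-Lin style single-node relabeling maximizing the between-set
// score sum_{between-set pairs} (W_e - lambda) over partitions into k
// nonempty sets. `inits` is an n x R matrix of initial labels in 1..k
// (each column must use every label at least once). Returns the best
// labeling over all initializations.
// [[Rcpp::export]]
List cpp_kl_partition(NumericMatrix W, double lambda, IntegerMatrix inits) {
  const int n = W.nrow(), R = inits.ncol();
  int k = 0;
  for (int r = 0; r < R; ++r)
    for (int i = 0; i < n; ++i) k = std::max(k, inits(i, r));

  double totalC = 0.0;
  for (int j = 1; j < n; ++j)
    for (int i = 0; i < j; ++i) totalC += W(i, j) - lambda;

  std::vector<int> bestLab;
  double bestScore = -std::numeric_limits<double>::infinity();

  std::vector<int> lab(n), cnt(k);
  std::vector<double> setW(n * k);  // setW[v*k + c] = sum of W(v, u), lab[u]=c

  for (int r = 0; r < R; ++r) {
    for (int i = 0; i < n; ++i) lab[i] = inits(i, r) - 1;
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) ++cnt[lab[i]];
    std::fill(setW.begin(), setW.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (i != j) setW[i * k + lab[j]] += W(i, j);

    double within = 0.0;
    for (int j = 1; j < n; ++j)
      for (int i = 0; i < j; ++i)
        if (lab[i] == lab[j]) within += W(i, j) - lambda;

    bool moved = true;
    int pass = 0;
    while (moved && pass < 200) {
      moved = false;
      ++pass;
      for (int v = 0; v < n; ++v) {
        const int a = lab[v];
        if (cnt[a] <= 1) continue;  // sets must stay nonempty
        const double wa = setW[v * k + a] - lambda * (cnt[a] - 1);
        int bb = -1;
        double bg = EPS;
        for (int b = 0; b < k; ++b) {
          if (b == a) continue;
          const double wb = setW[v * k + b] - lambda * cnt[b];
          const double gain = wa - wb;  // between-score gain of moving v
          if (gain > bg) { bg = gain; bb = b; }
        }
        if (bb >= 0) {
          within -= bg;
          lab[v] = bb;
          --cnt[a];
          ++cnt[bb];
          for (int u = 0; u < n; ++u) {
            if (u == v) continue;
            setW[u * k + a] -= W(u, v);
            setW[u * k + bb] += W(u, v);
          }
          moved = true;
        }
      }
    }

    const double score = totalC - within;
    if (score > bestScore) {
      bestScore = score;
      bestLab = lab;
    }
  }

  IntegerVector outLab(n);
  for (int i = 0; i < n; ++i) outLab[i] = bestLab[i] + 1;
  return List::create(_["labels"] = outLab, _["score"] = bestScore);
}
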