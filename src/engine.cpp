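// Attractor search engine.
//
// States are integer level-index vectors (0..h-1 per node). Update rules
// arrive as postfix stack programs compiled in R (see compile_variant):
//   opcode 0: push state[arg]        opcode 1: push constant arg
//   opcode 2: complement (h-1-x)     opcode 3: binary min   4: binary max
// min/max/complement on level indices are the Zadeh connectives expressed
// on the exact integer grid, so no floating point enters the dynamics.

#include <Rcpp.h>
#include <map>
#include <set>
#include <string>
#include <vector>
#include <queue>
using namespace Rcpp;

typedef std::vector<int> State;

struct Engine {
  int n;
  int h;
  std::vector< std::vector<int> > code; // one program per node

  Engine(List programs, int h_) : h(h_) {
    n = programs.size();
    code.resize(n);
    for (int i = 0; i < n; ++i) {
      IntegerVector p = programs[i];
      code[i] = std::vector<int>(p.begin(), p.end());
    }
  }

  int eval(int node, const State &s) const {
    const std::vector<int> &c = code[node];
    static thread_local std::vector<int> stack;
    stack.clear();
    for (size_t k = 0; k < c.size(); k += 2) {
      int op = c[k], arg = c[k + 1];
      switch (op) {
      case 0: stack.push_back(s[arg]); break;
      case 1: stack.push_back(arg); break;
      case 2: stack.back() = (h - 1) - stack.back(); break;
      case 3: { int b = stack.back(); stack.pop_back();
                if (b < stack.back()) stack.back() = b; break; }
      case 4: { int b = stack.back(); stack.pop_back();
                if (b > stack.back()) stack.back() = b; break; }
      default: stop("corrupt update program");
      }
    }
    return stack.back();
  }

  // successor when only `node` is updated
  State succ(const State &s, int node) const {
    State t = s;
    t[node] = eval(node, s);
    return t;
  }

  State sync_succ(const State &s) const {
    State t(n);
    for (int i = 0; i < n; ++i) t[i] = eval(i, s);
    return t;
  }
};

static inline std::string key_of(const State &s) {
  return std::string(s.begin(), s.end()); // raw-byte key, exact for h < 128
}

static State state_from_row(const IntegerMatrix &m, int row) {
  State s(m.ncol());
  for (int j = 0; j < m.ncol(); ++j) s[j] = m(row, j);
  return s;
}

static IntegerMatrix states_to_matrix(const std::vector<State> &states) {
  int n = states.empty() ? 0 : (int)states[0].size();
  IntegerMatrix m(states.size(), n);
  for (size_t i = 0; i < states.size(); ++i)
    for (int j = 0; j < n; ++j) m(i, j) = states[i][j];
  return m;
}

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Breadth-first closure of `start` under all single-node asynchronous
// successors; includes `start`. Returns false when the closure exceeds `cap`
// (candidate too large: the walk is still in a transient).
static bool forward_closure(const Engine &eng, const State &start, size_t cap,
                            std::vector<State> &out) {
  std::set<std::string> seen;
  std::queue<State> todo;
  out.clear();
  seen.insert(key_of(start));
  todo.push(start);
  out.push_back(start);
  while (!todo.empty()) {
    State s = todo.front();
    todo.pop();
    for (int i = 0; i < eng.n; ++i) {
      State t = eng.succ(s, i);
      std::string k = key_of(t);
      if (seen.insert(k).second) {
        if (out.size() + 1 > cap) return false;
        out.push_back(t);
        todo.push(t);
      }
    }
  }
  return true;
}

// A candidate set is an attractor (terminal SCC) iff it is (i) closed under
// every single-node update and (ii) strongly connected. For a candidate
// produced as a forward-reachable set, closure holds by construction and the
// set is an attractor iff every member can reach the walk's end state back —
// i.e. the closed set contains no smaller escape-free subset. We check both
// conditions explicitly so the predicate is meaningful for arbitrary sets.
static bool is_terminal_scc(const Engine &eng, const std::vector<State> &cand) {
  if (cand.empty()) return false;
  std::map<std::string, int> index;
  for (size_t i = 0; i < cand.size(); ++i) index[key_of(cand[i])] = (int)i;
  std::vector< std::vector<int> > fwd(cand.size()), rev(cand.size());
  for (size_t i = 0; i < cand.size(); ++i) {
    for (int nd = 0; nd < eng.n; ++nd) {
      State t = eng.succ(cand[i], nd);
      std::map<std::string, int>::iterator it = index.find(key_of(t));
      if (it == index.end()) return false; // escape: not closed
      fwd[i].push_back(it->second);
      rev[it->second].push_back((int)i);
    }
  }
  // strong connectivity: node 0 reaches all and is reached by all
  for (int dir = 0; dir < 2; ++dir) {
    const std::vector< std::vector<int> > &adj = dir ? rev : fwd;
    std::vector<char> vis(cand.size(), 0);
    std::queue<int> q;
    q.push(0);
    vis[0] = 1;
    size_t count = 1;
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (size_t k = 0; k < adj[u].size(); ++k)
        if (!vis[adj[u][k]]) { vis[adj[u][k]] = 1; ++count; q.push(adj[u][k]); }
    }
    if (count != cand.size()) return false;
  }
  return true;
}

static void sort_states(std::vector<State> &states) {
  std::sort(states.begin(), states.end());
}

// [[Rcpp::export]]
IntegerMatrix cpp_forward_set(List programs, IntegerVector state, int h,
                              double cap) {
  Engine eng(programs, h);
  State s(state.begin(), state.end());
  std::vector<State> out;
  if (!forward_closure(eng, s, (size_t)cap, out))
    stop("forward set exceeds the %d-state cap; the walk has not reached an attractor (increase maxk)",
         (int)cap);
  sort_states(out);
  return states_to_matrix(out);
}

// [[Rcpp::export]]
bool cpp_validate_tscc(List programs, IntegerMatrix states, int h) {
  Engine eng(programs, h);
  std::vector<State> cand;
  for (int i = 0; i < states.nrow(); ++i) cand.push_back(state_from_row(states, i));
  return is_terminal_scc(eng, cand);
}

// [[Rcpp::export]]
IntegerVector cpp_random_walk(List programs, IntegerVector state, int h,
                              int maxk, Nullable<List> stop_sets) {
  Engine eng(programs, h);
  std::set<std::string> stops;
  if (stop_sets.isNotNull()) {
    List ss(stop_sets);
    for (int a = 0; a < ss.size(); ++a) {
      IntegerMatrix m = ss[a];
      for (int i = 0; i < m.nrow(); ++i) stops.insert(key_of(state_from_row(m, i)));
    }
  }
  State s(state.begin(), state.end());
  for (int k = 0; k < maxk; ++k) {
    if (!stops.empty() && stops.count(key_of(s))) break;
    int nd = runif_int(eng.n);
    s[nd] = eng.eval(nd, s);
  }
  return IntegerVector(s.begin(), s.end());
}

// [[Rcpp::export]]
IntegerVector cpp_sync_step(List programs, IntegerVector state, int h) {
  Engine eng(programs, h);
  State s(state.begin(), state.end());
  State t = eng.sync_succ(s);
  return IntegerVector(t.begin(), t.end());
}

// [[Rcpp::export]]
IntegerVector cpp_async_step(List programs, IntegerVector state, int h) {
  Engine eng(programs, h);
  State s(state.begin(), state.end());
  int nd = runif_int(eng.n);
  s[nd] = eng.eval(nd, s);
  return IntegerVector(s.begin(), s.end());
}

// Asynchronous attractor search: from each start perform a long random walk
// (early exit on entering an already-validated attractor), take the forward
// reachable set of the final state as candidate attractor and validate it as
// a terminal SCC; on failure retry the walk with fresh randomness, then give
// the start up as unresolved.
// [[Rcpp::export]]
List cpp_find_attractors_async(List programs, IntegerMatrix starts, int h,
                               int maxk, int retries, double fwd_cap) {
  Engine eng(programs, h);
  std::vector< std::vector<State> > attractors; // canonical (sorted) states
  std::map<std::string, int> member; // state key -> attractor index
  std::map<std::string, int> att_by_key; // canonical set key -> index
  IntegerVector credits(starts.nrow());

  for (int r = 0; r < starts.nrow(); ++r) {
    State start = state_from_row(starts, r);
    int credited = 0; // 0 = unresolved
    for (int attempt = 0; attempt <= retries && !credited; ++attempt) {
      State s = start;
      bool hit = false;
      std::map<std::string, int>::iterator it = member.find(key_of(s));
      for (int k = 0; k < maxk; ++k) {
        if (it != member.end()) { hit = true; break; }
        int nd = runif_int(eng.n);
        s[nd] = eng.eval(nd, s);
        it = member.find(key_of(s));
      }
      if (!hit && it != member.end()) hit = true;
      if (hit) {
        credited = it->second + 1;
        break;
      }
      std::vector<State> cand;
      if (!forward_closure(eng, s, (size_t)fwd_cap, cand)) continue;
      if (!is_terminal_scc(eng, cand)) continue;
      sort_states(cand);
      std::string setkey;
      for (size_t i = 0; i < cand.size(); ++i) setkey += key_of(cand[i]) + '\x01';
      std::map<std::string, int>::iterator found = att_by_key.find(setkey);
      int idx;
      if (found == att_by_key.end()) {
        idx = (int)attractors.size();
        attractors.push_back(cand);
        att_by_key[setkey] = idx;
        for (size_t i = 0; i < cand.size(); ++i) member[key_of(cand[i])] = idx;
      } else idx = found->second;
      credited = idx + 1;
    }
    credits[r] = credited;
    if ((r & 0x3f) == 0) Rcpp::checkUserInterrupt();
  }

  List atts(attractors.size());
  for (size_t a = 0; a < attractors.size(); ++a)
    atts[a] = states_to_matrix(attractors[a]);
  return List::create(_["attractors"] = atts, _["credits"] = credits);
}

// Synchronous attractor search: iterate the deterministic map from each
// start, recording visited states; the cycle from the first recurrence is
// the attractor. Cycles are canonicalized by rotating so the
// lexicographically smallest state comes first.
// [[Rcpp::export]]
List cpp_find_attractors_sync(List programs, IntegerMatrix starts, int h) {
  Engine eng(programs, h);
  std::vector< std::vector<State> > attractors; // canonical cycle order
  std::map<std::string, int> member; // any state on a known cycle -> index
  std::map<std::string, int> att_by_key;
  IntegerVector credits(starts.nrow());

  for (int r = 0; r < starts.nrow(); ++r) {
    State s = state_from_row(starts, r);
    std::map<std::string, int> visited; // key -> step
    std::vector<State> path;
    int idx = -1;
    while (true) {
      std::string k = key_of(s);
      std::map<std::string, int>::iterator hit = member.find(k);
      if (hit != member.end()) { idx = hit->second; break; }
      std::map<std::string, int>::iterator seen = visited.find(k);
      if (seen != visited.end()) {
        // new cycle: path[seen->second .. end]
        std::vector<State> cycle(path.begin() + seen->second, path.end());
        size_t best = 0;
        for (size_t i = 1; i < cycle.size(); ++i)
          if (cycle[i] < cycle[best]) best = i;
        std::rotate(cycle.begin(), cycle.begin() + best, cycle.end());
        std::string setkey;
        for (size_t i = 0; i < cycle.size(); ++i) setkey += key_of(cycle[i]) + '\x01';
        std::map<std::string, int>::iterator found = att_by_key.find(setkey);
        if (found == att_by_key.end()) {
          idx = (int)attractors.size();
          attractors.push_back(cycle);
          att_by_key[setkey] = idx;
          for (size_t i = 0; i < cycle.size(); ++i) member[key_of(cycle[i])] = idx;
        } else idx = found->second;
        break;
      }
      visited[k] = (int)path.size();
      path.push_back(s);
      s = eng.sync_succ(s);
    }
    credits[r] = idx + 1;
    if ((r & 0x3f) == 0) Rcpp::checkUserInterrupt();
  }

  List atts(attractors.size());
  for (size_t a = 0; a < attractors.size(); ++a)
    atts[a] = states_to_matrix(attractors[a]);
  return List::create(_["attractors"] = atts, _["credits"] = credits);
}
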