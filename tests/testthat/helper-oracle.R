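# Independent oracles the engine is checked against. They share no code with
# the search path: successors are computed with the R expression evaluator
# and attractors come from an explicit state-transition graph condensed with
# igraph, or from brute-force iteration.

state_key_of <- function(state) paste(state, collapse = "")

# single-node asynchronous successor computed with the R evaluator
r_async_succ <- function(variant, state, node_idx) {
  h <- variant$model$domain$h
  rules <- effective_rules_of(variant)
  nodes <- variant$model$nodes
  vals <- stats::setNames(state / (h - 1), nodes)
  nxt <- eval_expr(rules[[nodes[node_idx]]], vals)
  state[node_idx] <- as.integer(round(nxt * (h - 1)))
  state
}

effective_rules_of <- function(variant) {
  rules <- variant$model$update
  for (nm in names(variant$forcings))
    rules[[nm]] <- parse_expression(bnscreen:::format_level(variant$forcings[[nm]]))
  rules
}

# Exhaustive asynchronous attractors: full transition graph over h^n states,
# strongly connected components via igraph, keep the terminal ones.
# Returns a sorted character vector of canonical attractor keys
# (lexicographically sorted member state keys joined by "|").
oracle_async_attractors <- function(x) {
  v <- as_variant(x)
  states <- enumerate_states(v)
  n <- ncol(states)
  keys <- apply(states, 1, paste, collapse = "")
  idx <- stats::setNames(seq_len(nrow(states)), keys)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(nrow(states))) {
    for (j in seq_len(n)) {
      succ <- r_async_succ(v, states[i, ], j)
      from <- c(from, i)
      to <- c(to, idx[[state_key_of(succ)]])
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  comp <- igraph::components(g, mode = "strong")$membership
  terminal <- setdiff(unique(comp), unique(comp[from][comp[from] != comp[to]]))
  sort(vapply(terminal, function(cc)
    paste(sort(keys[comp == cc]), collapse = "|"), character(1)))
}

# Brute-force synchronous attractors from every state (pure R iteration).
oracle_sync_attractors <- function(x) {
  v <- as_variant(x)
  states <- enumerate_states(v)
  found <- character(0)
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    seen <- list()
    repeat {
      k <- state_key_of(s)
      if (!is.null(seen[[k]])) {
        cycle_keys <- names(seen)[seq(seen[[k]], length(seen))]
        found <- c(found, paste(sort(cycle_keys), collapse = "|"))
        break
      }
      seen[[k]] <- length(seen) + 1L
      s <- sync_update(v, s)
    }
  }
  sort(unique(found))
}

# Canonical keys of an attractor_set, as state sets (order-insensitive).
aset_keys <- function(aset) {
  sort(vapply(aset$attractors, function(a)
    paste(sort(apply(a$states, 1, paste, collapse = "")), collapse = "|"),
    character(1)))
}

# The example network's printed attractor projections onto
# (do, factory, energy, locker, task).
EXAMPLE_PROJ <- c("do", "factory", "energy", "locker", "task")
EXAMPLE_PHYSIO_PROJ <- c("00010", "00100", "01100", "10010", "11101")
EXAMPLE_PATHO_PROJ <- c("00000", "00100", "01100", "10001", "11101")

example_search <- function(seed) {
  search_config("async", max_states = 512, max_walk = 1000, seed = seed)
}

bladder_search <- function(seed) {
  search_config("async", max_states = 1000, max_walk = 10000, seed = seed)
}

# Exact expected basin percentages under general asynchronous updating with
# one-walk-per-start crediting: absorption probabilities of the uniform
# single-node-update Markov chain, solved as a sparse linear system and
# averaged over all starts. Returns percentages named by canonical attractor
# key.
exact_absorption_basins <- function(x) {
  v <- as_variant(x)
  st <- enumerate_states(v)
  n <- ncol(st)
  N <- nrow(st)
  keys <- apply(st, 1, paste, collapse = "")
  idx <- stats::setNames(seq_len(N), keys)
  from <- rep(seq_len(N), n)
  to <- integer(N * n)
  k <- 0L
  for (j in seq_len(n)) for (i in seq_len(N)) {
    k <- k + 1L
    to[k] <- idx[[state_key_of(r_async_succ(v, st[i, ], j))]]
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  comp <- igraph::components(g, mode = "strong")$membership
  term <- setdiff(unique(comp), unique(comp[from][comp[from] != comp[to]]))
  A <- Matrix::sparseMatrix(i = from, j = to, x = 1 / n, dims = c(N, N))
  trans <- which(!comp %in% term)
  pct <- vapply(term, function(a) {
    b <- numeric(N)
    b[comp == a] <- 1
    if (length(trans)) {
      M <- Matrix::Diagonal(length(trans)) - A[trans, trans, drop = FALSE]
      b[trans] <- as.vector(Matrix::solve(M, (A[trans, , drop = FALSE] %*% b)[, 1]))
    }
    mean(b) * 100
  }, numeric(1))
  names(pct) <- vapply(term, function(a)
    paste(sort(keys[comp == a]), collapse = "|"), character(1))
  pct
}
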