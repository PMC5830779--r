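# Attractor discovery and basin-size estimation.
#
# Synchronous updating: deterministic cycle detection from each start.
# Asynchronous updating: long random walk to reach a candidate attractor with
# high probability, forward-reachable-set computation, terminal-SCC
# validation, with retries; each start is credited to the attractor its own
# walk lands in, so basin sizes are reachability estimations.

#' Search configuration for attractor discovery
#'
#' @param mode `"async"` (general asynchronous updating: one uniformly chosen
#'   node updated per iteration) or `"sync"` (all nodes updated at once).
#' @param max_states Maximum number of initial states (`maxS`). When it is at
#'   least `h^n` the full state space is enumerated and every start used
#'   exactly once; otherwise `max_states` distinct starts are sampled
#'   uniformly.
#' @param max_walk Length of the asynchronous random walks (`maxk`).
#' @param seed Optional integer seed; when given, `set.seed(seed)` is called
#'   before the search.
#' @param retries How many times a failed walk (one whose forward set is not
#'   a terminal SCC) is retried with fresh randomness before the start is
#'   counted as unresolved.
#' @param forward_cap Abort a forward-set computation beyond this many states
#'   (fail fast on walks stranded in a huge transient instead of exhausting
#'   memory; signals that `max_walk` is too small).
#' @return A list of class `search_config`.
#' @export
search_config <- function(mode = c("async", "sync"), max_states = 1000L,
                          max_walk = 10000L, seed = NULL, retries = 3L,
                          forward_cap = 1e6) {
  mode <- match.arg(mode)
  stopifnot(max_states >= 1, max_walk >= 0, retries >= 0)
  structure(list(mode = mode, max_states = as.integer(max_states),
                 max_walk = as.integer(max_walk), seed = seed,
                 retries = as.integer(retries), forward_cap = forward_cap),
            class = "search_config")
}

# Starts for a search: enumerate the whole space when maxS covers it,
# otherwise sample maxS distinct states. Initial states range over the FULL
# state space, including values contradicting forcings (a forced node relaxes
# to its forced value when it is updated).
search_starts <- function(variant, config) {
  n <- length(variant$model$nodes)
  h <- variant$model$domain$h
  if (config$max_states >= h^n) enumerate_states(variant)
  else sample_states(variant, config$max_states)
}

#' Perform an asynchronous random walk
#'
#' Applies `maxk` single-node asynchronous updates to `start` and returns the
#' final state. When `stop_at` (a list of attractor state matrices) is given,
#' the walk exits early upon entering one of them — a pure optimization,
#' since attractors are escape-free.
#'
#' @param x A `variant` or `logical_model`.
#' @param start Integer level-index state (named vector).
#' @param maxk Number of steps.
#' @param stop_at Optional list of state matrices to stop inside.
#' @return The final state (integer level indices, named).
#' @export
random_walk <- function(x, start, maxk, stop_at = NULL) {
  v <- as_variant(x)
  cm <- compile_variant(v)
  out <- cpp_random_walk(cm$programs, as.integer(start), cm$h, as.integer(maxk),
                         stop_at)
  stats::setNames(out, cm$nodes)
}

#' Forward reachable set of a state
#'
#' Breadth-first closure of `state` under all single-node asynchronous
#' successors (n successors per state, duplicates collapsed); includes the
#' state itself. This is the candidate attractor examined after a random
#' walk.
#'
#' @inheritParams random_walk
#' @param state Integer level-index state.
#' @param cap Error out when the closure exceeds this many states.
#' @return Integer matrix of states (rows sorted lexicographically).
#' @export
forward_set <- function(x, state, cap = 1e6) {
  v <- as_variant(x)
  cm <- compile_variant(v)
  m <- cpp_forward_set(cm$programs, as.integer(state), cm$h, cap)
  colnames(m) <- cm$nodes
  m
}

#' Check whether a state set is a terminal strongly connected component
#'
#' True iff every single-node successor of every member is itself a member
#' (the system cannot escape the set) and the members are mutually reachable.
#' A forward reachable set is closed by construction, so for candidates
#' produced by [forward_set()] the decisive test is strong connectivity:
#' it rejects closed sets that still contain smaller escape-free subsets.
#'
#' @inheritParams random_walk
#' @param states Integer matrix of states (one per row).
#' @return Logical scalar.
#' @export
validate_terminal_scc <- function(x, states) {
  v <- as_variant(x)
  cm <- compile_variant(v)
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  if (nrow(states) == 0L) stop("candidate attractor is empty", call. = FALSE)
  storage.mode(states) <- "integer"
  cpp_validate_tscc(cm$programs, states, cm$h)
}

#' Find the attractors of a variant and estimate their basins
#'
#' In synchronous mode each start is iterated deterministically until a state
#' repeats; the cycle from the first recurrence is the attractor. In
#' asynchronous mode each start performs a long random walk, the forward
#' reachable set of the final state is validated as a terminal SCC, failures
#' are retried with fresh randomness, and starts whose every attempt fails
#' are counted as unresolved (excluded from basin percentages, with a
#' warning). Each start is credited to exactly one attractor; attractors are
#' deduplicated by canonical (lexicographically sorted) state-set equality.
#'
#' @param x A `variant` or `logical_model`.
#' @param config A [search_config()].
#' @return An object of class `attractor_set`: fields `attractors` (list of
#'   `attractor` objects with `states`, `kind`, `label`, `key`), `counts`,
#'   `total`, `unresolved`, `mode`, `nodes`, `h`.
#' @examples
#' m <- parse_model(c("a = b", "b = a"))
#' find_attractors(m, search_config("async", max_states = 4, max_walk = 50,
#'                                  seed = 1))
#' @export
find_attractors <- function(x, config = search_config()) {
  v <- as_variant(x)
  cm <- compile_variant(v)
  if (!is.null(config$seed)) set.seed(config$seed)
  starts <- search_starts(v, config)
  if (config$mode == "sync") {
    res <- cpp_find_attractors_sync(cm$programs, starts, cm$h)
    kind <- "sync-cycle"
  } else {
    res <- cpp_find_attractors_async(cm$programs, starts, cm$h,
                                     config$max_walk, config$retries,
                                     config$forward_cap)
    kind <- "async-tscc"
  }
  credits <- res$credits
  unresolved <- sum(credits == 0L)
  if (unresolved == nrow(starts))
    stop("no start state resolved to an attractor; max_walk is far too small",
         call. = FALSE)
  if (unresolved > 0L)
    warning(sprintf("%d of %d start states unresolved after %d retries; excluded from basin percentages",
                    unresolved, nrow(starts), config$retries), call. = FALSE)
  atts <- res$attractors
  counts <- tabulate(credits, nbins = length(atts))
  # canonical presentation order: attractor-set key (independent of the order
  # of discovery, hence of the seed)
  keys <- vapply(atts, function(m) paste(apply(m, 1, paste, collapse = ""),
                                         collapse = "|"), character(1))
  ord <- order(keys)
  attractors <- vector("list", length(atts))
  for (i in seq_along(ord)) {
    m <- atts[[ord[i]]]
    colnames(m) <- cm$nodes
    attractors[[i]] <- structure(
      list(states = m, kind = kind, label = sprintf("A%d", i), key = keys[ord[i]]),
      class = "attractor")
  }
  structure(list(attractors = attractors, counts = counts[ord],
                 total = nrow(starts), unresolved = unresolved,
                 mode = config$mode, nodes = cm$nodes, h = cm$h),
            class = "attractor_set")
}

#' Basin percentages of an attractor set
#'
#' Percentages are taken over resolved starts and sum to 100 up to rounding;
#' display rounding is one decimal, but all downstream comparisons use the
#' unrounded values.
#'
#' @param aset An `attractor_set`.
#' @return Named numeric vector of percentages (names = attractor labels).
#' @export
basin_percentages <- function(aset) {
  resolved <- aset$total - aset$unresolved
  if (resolved <= 0) stop("no resolved starts", call. = FALSE)
  stats::setNames(100 * aset$counts / resolved,
                  vapply(aset$attractors, `[[`, character(1), "label"))
}

#' Project attractors onto a subset of nodes
#'
#' @param aset An `attractor_set`.
#' @param nodes Character vector of node names.
#' @return Character vector (one per attractor) of `/`-separated projected
#'   state digit strings (single-state attractors give a single digit
#'   string), level indices in node order.
#' @export
project_attractors <- function(aset, nodes) {
  missing <- setdiff(nodes, aset$nodes)
  if (length(missing))
    stop(sprintf("unknown projection node(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  vapply(aset$attractors, function(a) {
    rows <- unique(apply(a$states[, nodes, drop = FALSE], 1, paste, collapse = ""))
    paste(sort(rows), collapse = "/")
  }, character(1))
}

#' @export
print.attractor_set <- function(x, ...) {
  pct <- basin_percentages(x)
  cat(sprintf("<attractor_set> mode = %s, %d attractor(s), %d starts (%d unresolved)\n",
              x$mode, length(x$attractors), x$total, x$unresolved))
  for (i in seq_along(x$attractors)) {
    a <- x$attractors[[i]]
    cat(sprintf("  %s: %d state(s), basin %.1f%%\n", a$label, nrow(a$states), pct[i]))
  }
  invisible(x)
}

#' @export
print.attractor <- function(x, ...) {
  cat(sprintf("<attractor> %s (%s), %d state(s)\n",
              x$label, x$kind, nrow(x$states)))
  print(x$states)
  invisible(x)
}
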