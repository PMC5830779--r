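# Logical models, variants under constant forcings, the state space, and
# one-step update semantics (synchronous and general asynchronous).
#
# States are handled as integer level-index vectors (0 .. h-1 per node) so
# that state equality, basin bookkeeping and attractor deduplication are
# exact; values in [0,1] appear only at evaluation/display boundaries.

#' Construct a logical model
#'
#' A logical model is an ordered set of named nodes, one update expression per
#' node, over an h-level domain. Input nodes are ordinary nodes with
#' self-equations (e.g. `do = do`); they get no special treatment — their
#' constancy partitions the state space naturally.
#'
#' @param exprs Named list of expression trees (see [parse_expression()]),
#'   one per node; names give the node order.
#' @param h Number of logic levels (default 2, Boolean).
#' @return An object of class `logical_model` with fields `nodes`, `update`,
#'   `domain`.
#' @export
logical_model <- function(exprs, h = 2L) {
  domain <- make_domain(h)
  nodes <- names(exprs)
  if (is.null(nodes) || any(!nzchar(nodes)))
    stop("update rules must be a named list", call. = FALSE)
  if (anyDuplicated(nodes))
    stop(sprintf("duplicate node definition: %s",
                 paste(unique(nodes[duplicated(nodes)]), collapse = ", ")),
         call. = FALSE)
  for (nm in nodes) {
    refs <- expression_vars(exprs[[nm]])
    missing <- setdiff(refs, nodes)
    if (length(missing))
      stop(sprintf("rule for '%s' references undeclared variable(s): %s",
                   nm, paste(missing, collapse = ", ")), call. = FALSE)
    check_constants(exprs[[nm]], domain$h, context = sprintf("rule for '%s'", nm))
  }
  structure(list(nodes = nodes, update = exprs, domain = domain),
            class = "logical_model")
}

#' Parse a logical model from equation text
#'
#' One `name = expression` per line; `#` starts a comment; blank lines are
#' ignored. Node order is the first-appearance order of left-hand sides.
#'
#' @param text Character vector of lines, or a single string with embedded
#'   newlines.
#' @param h Number of logic levels.
#' @return A `logical_model`.
#' @examples
#' parse_model(c("a = a", "b = a & !b"))
#' @export
parse_model <- function(text, h = 2L) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  exprs <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    eq <- regmatches(line, regexec("^([A-Za-z_][A-Za-z0-9_]*)[ \t]*=(.*)$", line))[[1]]
    if (length(eq) != 3L)
      stop(sprintf("line %d: expected 'name = expression', got '%s'", i, line),
           call. = FALSE)
    nm <- eq[2]
    if (nm %in% names(exprs))
      stop(sprintf("line %d: duplicate definition of '%s'", i, nm), call. = FALSE)
    exprs[[nm]] <- parse_expression(eq[3], line = i)
  }
  if (!length(exprs)) stop("model text contains no equations", call. = FALSE)
  logical_model(exprs, h = h)
}

#' Read a logical model from a file
#' @param path Path to an equation file.
#' @param h Number of logic levels.
#' @return A `logical_model`.
#' @export
read_model <- function(path, h = 2L) {
  if (!file.exists(path))
    stop(sprintf("model file '%s' does not exist", path), call. = FALSE)
  parse_model(readLines(path, warn = FALSE, encoding = "UTF-8"), h = h)
}

#' Serialize a logical model to equation text
#' @param model A `logical_model`.
#' @return Character vector of `name = expression` lines in node order.
#' @export
format_model <- function(model) {
  vapply(model$nodes, function(nm)
    paste(nm, "=", format_expression(model$update[[nm]])), character(1),
    USE.NAMES = FALSE)
}

#' @export
print.logical_model <- function(x, ...) {
  cat(sprintf("<logical_model> %d nodes, h = %d (|S| = %s)\n",
              length(x$nodes), x$domain$h,
              format(x$domain$h^length(x$nodes), big.mark = ",", scientific = FALSE)))
  cat(paste0("  ", format_model(x), collapse = "\n"), "\n")
  invisible(x)
}

## ------------------------------------------------------------------------
## Forcings and variants

#' Parse node forcings
#'
#' Forcings are constant assignments `name=value`, the representation of both
#' pathological disturbances (e.g. `locker=0`) and therapeutic bullets.
#'
#' @param spec Character vector of `name=value` strings (or a single string
#'   with comma/newline separators), or a named numeric vector.
#' @return Named numeric vector of forced values.
#' @export
parse_forcings <- function(spec) {
  if (is.numeric(spec)) {
    if (length(spec) && is.null(names(spec)))
      stop("numeric forcings must be named", call. = FALSE)
    return(spec)
  }
  lines <- sub("#.*$", "", unlist(strsplit(spec, "\n", fixed = TRUE)))
  parts <- trimws(unlist(strsplit(lines, ",", fixed = TRUE)))
  parts <- parts[nzchar(parts)]
  out <- numeric(0)
  for (p in parts) {
    m <- regmatches(p, regexec("^([A-Za-z_][A-Za-z0-9_]*)[ \t]*=[ \t]*([0-9.]+)$", p))[[1]]
    if (length(m) != 3L)
      stop(sprintf("invalid forcing '%s' (expected name=value)", p), call. = FALSE)
    out[m[2]] <- as.numeric(m[3])
  }
  out
}

#' Create a model variant under constant forcings
#'
#' The effective update rule of a forced node is the constant expression of
#' its forced value; unforced nodes keep the base rules. Forcings applied
#' later override earlier ones for the same node, so a bullet may override a
#' pathological forcing (reversal bullets are legal to test).
#'
#' @param x A `logical_model` or an existing `variant`.
#' @param forcings Named numeric vector (or `name=value` strings, see
#'   [parse_forcings()]); may be empty.
#' @param label Optional label, conventionally one of `"physiological"`,
#'   `"pathological"`, `"testing"`.
#' @return An object of class `variant` with fields `model`, `forcings`,
#'   `label`.
#' @export
apply_forcings <- function(x, forcings = numeric(0), label = NULL) {
  if (inherits(x, "variant")) {
    base <- x$model
    eff <- x$forcings
    if (is.null(label)) label <- x$label
  } else if (inherits(x, "logical_model")) {
    base <- x
    eff <- numeric(0)
  } else stop("'x' must be a logical_model or a variant", call. = FALSE)
  forcings <- parse_forcings(forcings)
  for (nm in names(forcings)) {
    if (!nm %in% base$nodes)
      stop(sprintf("cannot force unknown node '%s'", nm), call. = FALSE)
    if (is.na(level_index(forcings[[nm]], base$domain$h)))
      stop(sprintf("forced value %s for '%s' is not a level of the %d-valued domain",
                   format_level(forcings[[nm]]), nm, base$domain$h), call. = FALSE)
    eff[nm] <- forcings[[nm]]
  }
  structure(list(model = base, forcings = eff,
                 label = if (is.null(label)) "variant" else label),
            class = "variant")
}

#' Coerce to a variant (a bare model becomes its unforced variant)
#' @param x A `logical_model` or `variant`.
#' @return A `variant`.
#' @export
as_variant <- function(x) {
  if (inherits(x, "variant")) x else apply_forcings(x)
}

# Effective update expressions of a variant (forced nodes become constants).
effective_rules <- function(variant) {
  exprs <- variant$model$update
  for (nm in names(variant$forcings))
    exprs[[nm]] <- e_const(variant$forcings[[nm]])
  exprs
}

#' @export
print.variant <- function(x, ...) {
  cat(sprintf("<variant> label = %s, %d nodes, h = %d\n", x$label,
              length(x$model$nodes), x$model$domain$h))
  if (length(x$forcings))
    cat("  forcings:", paste(sprintf("%s=%s", names(x$forcings),
                                     format_level(x$forcings)), collapse = " "), "\n")
  invisible(x)
}

#' Substitute input values into a model, removing the input nodes
#'
#' Unlike [apply_forcings()], which keeps forced nodes in the state space,
#' this injects constant input values directly into the concerned equations
#' and drops the input nodes from the model, reducing the state space (the
#' treatment applied to the case-study input parameters). Expressions are
#' constant-folded where the substitution makes sub-expressions trivial.
#'
#' @param model A `logical_model`.
#' @param forcings Named numeric vector of input values.
#' @return A smaller `logical_model` over the remaining nodes.
#' @export
substitute_inputs <- function(model, forcings = numeric(0)) {
  stopifnot(inherits(model, "logical_model"))
  forcings <- parse_forcings(forcings)
  unknown <- setdiff(names(forcings), model$nodes)
  if (length(unknown))
    stop(sprintf("cannot substitute unknown node(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (!length(forcings)) return(model)
  keep <- setdiff(model$nodes, names(forcings))
  if (!length(keep)) stop("substitution would remove every node", call. = FALSE)
  exprs <- lapply(model$update[keep], function(e)
    fold_constants(substitute_vars(e, forcings)))
  for (nm in keep) {
    left <- intersect(expression_vars(exprs[[nm]]), names(forcings))
    if (length(left)) stop("internal error: substitution left input references")
  }
  logical_model(exprs, h = model$domain$h)
}

substitute_vars <- function(expr, values) {
  switch(expr$op,
    var = if (expr$name %in% names(values)) e_const(values[[expr$name]]) else expr,
    const = expr,
    not = e_not(substitute_vars(expr$arg, values)),
    { expr$args <- lapply(expr$args, substitute_vars, values = values); expr }
  )
}

# Algebraic constant folding under Zadeh semantics. 1 absorbs disjunction and
# is neutral for conjunction; dually for 0. Partial constants are combined.
fold_constants <- function(expr) {
  switch(expr$op,
    var = ,
    const = expr,
    not = {
      a <- fold_constants(expr$arg)
      if (a$op == "const") e_const(1 - a$value) else e_not(a)
    },
    {
      args <- lapply(expr$args, fold_constants)
      is_const <- vapply(args, function(a) a$op == "const", logical(1))
      cvals <- vapply(args[is_const], function(a) a$value, numeric(1))
      if (expr$op == "and") {
        if (any(cvals == 0)) return(e_const(0))
        cv <- if (length(cvals)) min(cvals) else NULL
        rest <- args[!is_const]
        if (!is.null(cv) && cv < 1) rest <- c(rest, list(e_const(cv)))
      } else {
        if (any(cvals == 1)) return(e_const(1))
        cv <- if (length(cvals)) max(cvals) else NULL
        rest <- args[!is_const]
        if (!is.null(cv) && cv > 0) rest <- c(rest, list(e_const(cv)))
      }
      if (!length(rest)) return(e_const(if (expr$op == "and") 1 else 0))
      if (length(rest) == 1L) return(rest[[1L]])
      list(op = expr$op, args = rest)
    }
  )
}

## ------------------------------------------------------------------------
## States

# A state is an integer vector of level indices (0..h-1), named by node.
# Compact digit-string serialization follows node declaration order.

state_key <- function(state) paste(state, collapse = "")

state_values <- function(state, h) state / (h - 1)

state_from_values <- function(values, h) {
  idx <- level_index(values, h)
  if (anyNA(idx)) stop("state contains values outside the domain", call. = FALSE)
  stats::setNames(idx, names(values))
}

#' Enumerate the full state space of a variant
#'
#' States are produced in lexicographic order of the level indices, the first
#' declared node being the most significant digit. Refuses (with guidance to
#' sample) when `h^n` exceeds `cap`.
#'
#' @param x A `variant` or `logical_model`.
#' @param cap Maximum number of states to enumerate (default `2^20`).
#' @return Integer matrix, one row per state, columns named by node.
#' @export
enumerate_states <- function(x, cap = 2^20) {
  v <- as_variant(x)
  n <- length(v$model$nodes)
  h <- v$model$domain$h
  total <- h^n
  if (total > cap)
    stop(sprintf(paste("state space has %s states, above the enumeration cap (%s);",
                       "use sample_states() instead"),
                 format(total, scientific = FALSE), format(cap, scientific = FALSE)),
         call. = FALSE)
  grid <- as.matrix(rev(expand.grid(rev(lapply(seq_len(n), function(i) 0:(h - 1L))),
                                    KEEP.OUT.ATTRS = FALSE)))
  colnames(grid) <- v$model$nodes
  storage.mode(grid) <- "integer"
  grid
}

#' Sample distinct states uniformly from the state space
#'
#' Uniform without replacement: each level of each node is drawn uniformly and
#' duplicate states are redrawn, so every state of the (possibly astronomically
#' large) space is equally likely and each appears at most once. Uses R's RNG;
#' call `set.seed()` for reproducibility.
#'
#' @param x A `variant` or `logical_model`.
#' @param count Number of distinct states to draw; must not exceed `h^n`.
#' @return Integer matrix, one row per state, columns named by node.
#' @export
sample_states <- function(x, count) {
  v <- as_variant(x)
  n <- length(v$model$nodes)
  h <- v$model$domain$h
  if (count < 1) stop("'count' must be >= 1", call. = FALSE)
  if (count > h^n)
    stop(sprintf("cannot draw %d distinct states from a space of %s",
                 count, format(h^n, scientific = FALSE)), call. = FALSE)
  draw <- function(k) matrix(sample.int(h, k * n, replace = TRUE) - 1L, nrow = k)
  out <- draw(count)
  keys <- apply(out, 1, paste, collapse = "")
  while (anyDuplicated(keys)) {
    dup <- which(duplicated(keys))
    out[dup, ] <- draw(length(dup))
    keys <- apply(out, 1, paste, collapse = "")
  }
  colnames(out) <- v$model$nodes
  out
}

## ------------------------------------------------------------------------
## One-step updates (R reference semantics; the search engine uses the
## compiled equivalents and is tested against these).

#' Synchronous one-step update
#'
#' Every node's next value is computed from the same input state;
#' deterministic. Initial states may contradict forcings: a forced node
#' relaxes to its forced value when updated, which under synchronous updating
#' means after one step.
#'
#' @param x A `variant` or `logical_model`.
#' @param state Integer level-index vector named by node (see
#'   [enumerate_states()]).
#' @return The successor state (integer level indices).
#' @export
sync_update <- function(x, state) {
  v <- as_variant(x)
  h <- v$model$domain$h
  rules <- effective_rules(v)
  vals <- stats::setNames(state_values(state, h), v$model$nodes)
  nxt <- vapply(v$model$nodes, function(nm) eval_expr(rules[[nm]], vals), numeric(1))
  stats::setNames(level_index(nxt, h), v$model$nodes)
}

#' General asynchronous one-step update
#'
#' Exactly one node, chosen uniformly at random, is recomputed; all others are
#' unchanged (Hamming distance to the input state is at most 1). Uses R's RNG.
#'
#' @inheritParams sync_update
#' @return The successor state.
#' @export
async_update <- function(x, state) {
  v <- as_variant(x)
  h <- v$model$domain$h
  rules <- effective_rules(v)
  i <- sample.int(length(v$model$nodes), 1L)
  nm <- v$model$nodes[i]
  vals <- stats::setNames(state_values(state, h), v$model$nodes)
  state[i] <- level_index(eval_expr(rules[[nm]], vals), h)
  state
}

## ------------------------------------------------------------------------
## Compilation to stack programs for the C++ engine
##
## Each effective rule is flattened to postfix opcode pairs:
##   0 arg: push level index of variable arg (0-based node index)
##   1 arg: push constant level index arg
##   2 .  : complement (h-1 - x)
##   3 .  : binary min      4 . : binary max

compile_variant <- function(x) {
  v <- as_variant(x)
  h <- v$model$domain$h
  nodes <- v$model$nodes
  rules <- effective_rules(v)
  emit <- function(e) {
    switch(e$op,
      var = c(0L, match(e$name, nodes) - 1L),
      const = c(1L, level_index(e$value, h)),
      not = c(emit(e$arg), 2L, 0L),
      and = ,
      or = {
        code <- emit(e$args[[1L]])
        opc <- if (e$op == "and") 3L else 4L
        for (a in e$args[-1L]) code <- c(code, emit(a), opc, 0L)
        code
      }
    )
  }
  list(nodes = nodes, h = h, programs = lapply(rules[nodes], emit))
}
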