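# Phenotype readouts: named output expressions kept out of the dynamical
# model (so they influence neither attractor discovery nor basins) and
# evaluated on the returned attractors once a run has terminated.

#' Parse a readout set
#'
#' Readouts use the same `name = expression` syntax as models but may only
#' reference model nodes, never each other.
#'
#' @param text Character vector of equation lines.
#' @param model The `logical_model` the readouts are evaluated against.
#' @return An object of class `readout_set` (ordered named list of
#'   expressions).
#' @export
parse_readouts <- function(text, model) {
  stopifnot(inherits(model, "logical_model"))
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  out <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    eq <- regmatches(line, regexec("^([A-Za-z_][A-Za-z0-9_]*)[ \t]*=(.*)$", line))[[1]]
    if (length(eq) != 3L)
      stop(sprintf("line %d: expected 'name = expression'", i), call. = FALSE)
    expr <- parse_expression(eq[3], line = i)
    missing <- setdiff(expression_vars(expr), model$nodes)
    if (length(missing))
      stop(sprintf("readout '%s' references unknown node(s): %s",
                   eq[2], paste(missing, collapse = ", ")), call. = FALSE)
    check_constants(expr, model$domain$h, context = sprintf("readout '%s'", eq[2]))
    out[[eq[2]]] <- expr
  }
  structure(out, class = "readout_set")
}

#' Read a readout set from a file
#' @param path Path to a readout equation file.
#' @param model The `logical_model` the readouts are evaluated against.
#' @return A `readout_set`.
#' @export
read_readouts <- function(path, model) {
  parse_readouts(readLines(path, warn = FALSE, encoding = "UTF-8"), model)
}

#' Evaluate readouts on an attractor
#'
#' Each readout is evaluated on every state of the attractor. The reported
#' level is the maximum over states — on single-state attractors this is the
#' plain evaluation — and the per-state breakdown is retained so that
#' disagreement across a cyclic attractor stays visible.
#'
#' @param att An `attractor`.
#' @param readouts A `readout_set`.
#' @param h Number of logic levels of the model the attractor came from.
#' @return Named numeric vector of levels (one per readout), with the
#'   per-state matrix as attribute `"per_state"`.
#' @export
evaluate_readouts <- function(att, readouts, h = 2L) {
  states <- att$states
  per_state <- matrix(NA_real_, nrow = nrow(states), ncol = length(readouts),
                      dimnames = list(NULL, names(readouts)))
  for (i in seq_len(nrow(states))) {
    vals <- stats::setNames(states[i, ] / (h - 1), colnames(states))
    for (nm in names(readouts))
      per_state[i, nm] <- eval_expr(readouts[[nm]], vals)
  }
  structure(apply(per_state, 2, max), per_state = per_state)
}
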