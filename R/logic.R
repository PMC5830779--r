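# Multivalued logic core: evenly spaced h-level domains, Zadeh connectives
# (min / max / 1-x), and the expression language update rules are written in.

#' Create an h-level logic domain
#'
#' An h-valued logic uses the evenly spaced levels \eqn{\{0, 1/(h-1), \ldots, 1\}}.
#' `h = 2` is ordinary Boolean logic; `h = 3` gives the three-valued domain
#' \{0, 0.5, 1\}. Internally all machinery works on integer level *indices*
#' `0..h-1` so that state equality and closure are exact; values are produced
#' only for display and evaluation.
#'
#' @param h Integer number of levels, at least 2.
#' @return An object of class `logic_domain` with fields `h` and `levels`.
#' @examples
#' make_domain(3)$levels # 0 0.5 1
#' @export
make_domain <- function(h) {
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h != as.integer(h) || h < 2)
    stop("invalid logic domain: 'h' must be a single integer >= 2", call. = FALSE)
  h <- as.integer(h)
  structure(list(h = h, levels = (0:(h - 1L)) / (h - 1L)), class = "logic_domain")
}

#' @export
print.logic_domain <- function(x, ...) {
  cat(sprintf("<logic_domain> h = %d, levels = {%s}\n", x$h,
              paste(format_level(x$levels), collapse = ", ")))
  invisible(x)
}

# Map a numeric value in [0,1] to its level index in an h-domain, or NA if the
# value does not sit (within 1e-9) on the grid. Non-domain constants are
# rejected downstream, never snapped.
level_index <- function(value, h) {
  idx <- value * (h - 1)
  r <- round(idx)
  ifelse(abs(idx - r) <= 1e-9 & r >= 0 & r <= (h - 1), as.integer(r), NA_integer_)
}

format_level <- function(value) {
  out <- format(value, trim = TRUE, drop0trailing = TRUE)
  out[value == 0] <- "0"
  out[value == 1] <- "1"
  out
}

## ------------------------------------------------------------------------
## Expression AST
##
## An expression is a plain nested list:
##   list(op = "var",   name  = <chr>)
##   list(op = "const", value = <num in [0,1]>)
##   list(op = "not",   arg   = <expr>)
##   list(op = "and",   args  = list(<expr>, ...))   # n-ary, n >= 2
##   list(op = "or",    args  = list(<expr>, ...))

e_var   <- function(name)  list(op = "var", name = name)
e_const <- function(value) list(op = "const", value = value)
e_not   <- function(arg)   list(op = "not", arg = arg)
e_and   <- function(...)   list(op = "and", args = list(...))
e_or    <- function(...)   list(op = "or",  args = list(...))

#' Evaluate a logic expression under the Zadeh operators
#'
#' Conjunction is the minimum of its operands, disjunction the maximum, and
#' negation the complement `1 - x`. On the Boolean domain these coincide with
#' the classical truth tables; on any evenly spaced h-level domain they are
#' closed (min, max and `1 - x` preserve the grid).
#'
#' @param expr Expression as returned by [parse_expression()].
#' @param state Named numeric vector of levels, one entry per variable the
#'   expression references.
#' @return A single numeric level in `[0, 1]`.
#' @examples
#' eval_expr(parse_expression("a | (b & !c)"), c(a = 0, b = 1, c = 0.5))
#' @export
eval_expr <- function(expr, state) {
  switch(expr$op,
    var = {
      if (!expr$name %in% names(state) || is.na(state[[expr$name]]))
        stop(sprintf("unbound variable '%s' in expression", expr$name), call. = FALSE)
      state[[expr$name]]
    },
    const = expr$value,
    not = 1 - eval_expr(expr$arg, state),
    and = min(vapply(expr$args, eval_expr, numeric(1), state = state)),
    or  = max(vapply(expr$args, eval_expr, numeric(1), state = state)),
    stop(sprintf("unknown expression node '%s'", expr$op), call. = FALSE)
  )
}

# All variable names referenced by an expression (unique, in first-use order).
expression_vars <- function(expr) {
  switch(expr$op,
    var = expr$name,
    const = character(0),
    not = expression_vars(expr$arg),
    unique(unlist(lapply(expr$args, expression_vars)))
  )
}

## ------------------------------------------------------------------------
## Tokenizer / parser
##
## Grammar (NOT > AND > OR, parentheses override):
##   expr := or
##   or   := and (("|"|"or"|"OR"|"∨") and)*
##   and  := not (("&"|"and"|"∧") not)*
##   not  := ("!"|"not"|"¬") not | atom
##   atom := IDENT | NUMBER | "(" expr ")"
## IDENT = [A-Za-z_][A-Za-z0-9_]* ; NUMBER = decimal in [0,1].
## Keywords are case-insensitive; canonical serialization uses ! & |.

tokenize_expression <- function(text, line = 1L) {
  tokens <- list()
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  i <- 1L
  n <- length(chars)
  push <- function(type, value, col) tokens[[length(tokens) + 1L]] <<- list(
    type = type, value = value, line = line, col = col)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^[ \t\r]$", ch)) { i <- i + 1L; next }
    if (ch %in% c("!", "¬")) { push("not", "!", i); i <- i + 1L; next }
    if (ch %in% c("&", "∧")) { push("and", "&", i); i <- i + 1L; next }
    if (ch %in% c("|", "∨")) { push("or", "|", i); i <- i + 1L; next }
    if (ch == "(") { push("lpar", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("rpar", ")", i); i <- i + 1L; next }
    if (grepl("^[A-Za-z_]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_]$", chars[j])) j <- j + 1L
      word <- paste(chars[i:(j - 1L)], collapse = "")
      lw <- tolower(word)
      if (lw == "not") push("not", "!", i)
      else if (lw == "and") push("and", "&", i)
      else if (lw == "or") push("or", "|", i)
      else push("ident", word, i)
      i <- j
      next
    }
    if (grepl("^[0-9.]$", ch)) {
      j <- i
      while (j <= n && grepl("^[0-9.]$", chars[j])) j <- j + 1L
      num <- paste(chars[i:(j - 1L)], collapse = "")
      value <- suppressWarnings(as.numeric(num))
      if (is.na(value) || value < 0 || value > 1)
        stop(sprintf("line %d, col %d: invalid constant '%s' (must be a decimal in [0,1])",
                     line, i, num), call. = FALSE)
      push("number", value, i)
      i <- j
      next
    }
    stop(sprintf("line %d, col %d: unknown token '%s'", line, i, ch), call. = FALSE)
  }
  tokens
}

#' Parse a logic expression
#'
#' Accepts `!`/`not`/`¬` for negation, `&`/`and`/`∧` for conjunction and
#' `|`/`or`/`∨` for disjunction (keywords case-insensitive), identifiers
#' `[A-Za-z_][A-Za-z0-9_]*`, decimal constants in `[0, 1]` and parentheses.
#' Precedence is NOT > AND > OR. Parsing, serializing with
#' [format_expression()] and re-parsing is the identity on the tree.
#'
#' @param text A single character string.
#' @param line Line number used in error messages (for file parsers).
#' @return An expression tree (nested list).
#' @examples
#' parse_expression("factory | (energy & !task)")
#' @export
parse_expression <- function(text, line = 1L) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- tokenize_expression(text, line = line)
  if (length(tokens) == 0L)
    stop(sprintf("line %d: empty expression", line), call. = FALSE)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() { tok <- tokens[[pos]]; pos <<- pos + 1L; tok }
  expect <- function(type) {
    tok <- peek()
    if (is.null(tok) || tok$type != type)
      stop(sprintf("line %d, col %s: expected %s%s", line,
                   if (is.null(tok)) "end" else tok$col, type,
                   if (is.null(tok)) " but input ended" else sprintf(" but found '%s'", tok$value)),
           call. = FALSE)
    advance()
  }
  parse_or <- function() {
    parts <- list(parse_and())
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      parts[[length(parts) + 1L]] <- parse_and()
    }
    if (length(parts) == 1L) parts[[1L]] else list(op = "or", args = parts)
  }
  parse_and <- function() {
    parts <- list(parse_not())
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      parts[[length(parts) + 1L]] <- parse_not()
    }
    if (length(parts) == 1L) parts[[1L]] else list(op = "and", args = parts)
  }
  parse_not <- function() {
    tok <- peek()
    if (!is.null(tok) && tok$type == "not") {
      advance()
      return(e_not(parse_not()))
    }
    parse_atom()
  }
  parse_atom <- function() {
    tok <- peek()
    if (is.null(tok))
      stop(sprintf("line %d: unexpected end of expression", line), call. = FALSE)
    if (tok$type == "ident") { advance(); return(e_var(tok$value)) }
    if (tok$type == "number") { advance(); return(e_const(tok$value)) }
    if (tok$type == "lpar") {
      advance()
      inner <- parse_or()
      expect("rpar")
      return(inner)
    }
    stop(sprintf("line %d, col %d: unexpected '%s'", line, tok$col, tok$value),
         call. = FALSE)
  }
  out <- parse_or()
  if (!is.null(peek())) {
    tok <- peek()
    stop(sprintf("line %d, col %d: trailing input starting at '%s'", line, tok$col,
                 tok$value), call. = FALSE)
  }
  out
}

#' Serialize an expression to canonical ASCII syntax
#'
#' @param expr An expression tree.
#' @return A single string using `!`, `&`, `|` with minimal parentheses
#'   (precedence NOT > AND > OR).
#' @export
format_expression <- function(expr) {
  prec <- function(e) switch(e$op, or = 1L, and = 2L, not = 3L, 4L)
  fmt <- function(e, parent_prec) {
    txt <- switch(e$op,
      var = e$name,
      const = format_level(e$value),
      not = paste0("!", fmt(e$arg, prec(e))),
      and = paste(vapply(e$args, fmt, character(1), parent_prec = prec(e)), collapse = " & "),
      or  = paste(vapply(e$args, fmt, character(1), parent_prec = prec(e)), collapse = " | ")
    )
    if (prec(e) < parent_prec) paste0("(", txt, ")") else txt
  }
  fmt(expr, 0L)
}

# Check that all constants in an expression sit on the h-level grid;
# returns invisibly or stops naming the offending constant.
check_constants <- function(expr, h, context = "expression") {
  walk <- function(e) {
    switch(e$op,
      const = if (is.na(level_index(e$value, h)))
        stop(sprintf("constant %s in %s is not a level of the %d-valued domain",
                     format_level(e$value), context, h), call. = FALSE),
      not = walk(e$arg),
      and = ,
      or = for (a in e$args) walk(a),
      invisible(NULL)
    )
    invisible(NULL)
  }
  walk(expr)
  invisible(expr)
}
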