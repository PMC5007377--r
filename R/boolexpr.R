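bool_leaf <- function(name) {
  structure(list(op = "leaf", name = name), class = "bool_expr")
}

bool_node <- function(op, children) {
  stopifnot(op %in% c("and", "or"), length(children) >= 1L)
  if (length(children) == 1L) return(children[[1L]])
  structure(list(op = op, children = children), class = "bool_expr")
}

# Tokenize into NAME / AND / OR / parentheses, keeping 1-based character
# positions for error reporting. Anything not matched (other than whitespace)
# is a lexical error.
tokenize_expression <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("expression must be a single character string")
  m <- gregexpr("\\(|\\)|[A-Za-z_][A-Za-z0-9_.]*", text)[[1L]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  covered <- rep(FALSE, nchar(text))
  toks <- character(0)
  if (starts[1L] != -1L) {
    toks <- substring(text, starts, starts + lens - 1L)
    for (i in seq_along(starts))
      covered[seq.int(starts[i], length.out = lens[i])] <- TRUE
  } else {
    starts <- integer(0)
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  stray <- which(!covered & !grepl("^[[:space:]]$", chars))
  if (length(stray))
    stop(sprintf("parse error: unexpected character '%s' at position %d",
                 chars[stray[1L]], stray[1L]))
  type <- ifelse(toks == "(", "lparen",
          ifelse(toks == ")", "rparen",
          ifelse(toupper(toks) == "AND", "and",
          ifelse(toupper(toks) == "OR", "or", "name"))))
  list(value = toks, type = type, pos = starts)
}

#' Parse a Boolean combination expression
#'
#' Grammar: `NAME | '(' expr ')' | expr 'AND' expr | expr 'OR' expr`, with
#' `AND` binding tighter than `OR` and case-insensitive keywords. The
#' canonical form (fully parenthesized) is recovered with `format()`.
#'
#' @param text Expression text, e.g. `"(C1 AND (C2 OR C3)) AND C4 AND (C5 OR C6)"`.
#' @return An abstract syntax tree of class `bool_expr`.
#' @export
parse_expression <- function(text) {
  tk <- tokenize_expression(text)
  n <- length(tk$value)
  if (n == 0L) stop("parse error: empty expression")
  i <- 1L

  peek <- function() if (i <= n) tk$type[i] else "eof"
  take <- function() { v <- i; i <<- i + 1L; v }
  fail <- function(what, at) {
    pos <- if (at <= n) tk$pos[at] else nchar(text) + 1L
    tok <- if (at <= n) tk$value[at] else "end of input"
    stop(sprintf("parse error: expected %s but found '%s' at position %d",
                 what, tok, pos))
  }

  parse_atom <- function() {
    t <- peek()
    if (t == "name") {
      return(bool_leaf(tk$value[take()]))
    }
    if (t == "lparen") {
      open <- take()
      node <- parse_or()
      if (peek() != "rparen")
        stop(sprintf("parse error: unbalanced parenthesis opened at position %d",
                     tk$pos[open]))
      take()
      return(node)
    }
    fail("a comparison name or '('", i)
  }
  parse_and <- function() {
    kids <- list(parse_atom())
    while (peek() == "and") {
      take()
      kids <- c(kids, list(parse_atom()))
    }
    bool_node("and", kids)
  }
  parse_or <- function() {
    kids <- list(parse_and())
    while (peek() == "or") {
      take()
      kids <- c(kids, list(parse_and()))
    }
    bool_node("or", kids)
  }

  node <- parse_or()
  if (i <= n) fail("end of expression", i)
  node
}

#' @export
format.bool_expr <- function(x, ...) {
  if (x$op == "leaf") return(x$name)
  inner <- vapply(x$children, format, character(1))
  paste0("(", paste(inner, collapse = if (x$op == "and") " AND " else " OR "), ")")
}

#' @export
print.bool_expr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Comparison names referenced by an expression
#'
#' @param expr A `bool_expr`.
#' @return Character vector of unique leaf names, in first-appearance order.
#' @export
expr_leaves <- function(expr) {
  stopifnot(inherits(expr, "bool_expr"))
  if (expr$op == "leaf") return(expr$name)
  unique(unlist(lapply(expr$children, expr_leaves)))
}

#' Evaluate an expression for one gene's comparison calls
#'
#' A leaf is true iff the gene's call in that comparison equals `direction`;
#' the same expression therefore serves the enriched and the depleted set
#' (sign-consistent combination).
#'
#' @param expr A `bool_expr`.
#' @param calls Named character vector or list mapping comparison names to
#'   calls in `{"enriched", "depleted", "ns"}`.
#' @param direction `"enriched"` or `"depleted"`.
#' @return Logical scalar.
#' @export
evaluate_gene <- function(expr, calls, direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  calls <- unlist(calls)
  missing <- setdiff(expr_leaves(expr), names(calls))
  if (length(missing))
    stop("no call for comparison(s): ", paste(missing, collapse = ", "))
  eval_node <- function(node) {
    if (node$op == "leaf") return(identical(unname(calls[[node$name]]), direction))
    vals <- vapply(node$children, eval_node, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  eval_node(expr)
}

# Vectorized evaluation over a genes x comparisons call matrix.
eval_expr_matrix <- function(expr, call_matrix, direction) {
  missing <- setdiff(expr_leaves(expr), colnames(call_matrix))
  if (length(missing))
    stop("call matrix lacks comparison(s): ", paste(missing, collapse = ", "))
  eval_node <- function(node) {
    if (node$op == "leaf") return(call_matrix[, node$name] == direction)
    vals <- lapply(node$children, eval_node)
    Reduce(if (node$op == "and") `&` else `|`, vals)
  }
  eval_node(expr)
}
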