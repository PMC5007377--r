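# Shared fixtures and independent oracles used across test files.

# Tiny two-group expression matrix built in code.
toy_matrix <- function(values_a = c(5.0, 5.2, 5.4), values_b = c(3.0, 3.1, 3.2),
                       n_genes = 3L) {
  sheet <- data.frame(
    sample_id = c(paste0("A", seq_along(values_a)), paste0("B", seq_along(values_b))),
    group = rep(c("GA", "GB"), c(length(values_a), length(values_b))),
    replicate = c(seq_along(values_a), seq_along(values_b)),
    stringsAsFactors = FALSE
  )
  vals <- matrix(rep(c(values_a, values_b), each = n_genes),
                 nrow = n_genes,
                 dimnames = list(sprintf("gene%02d", seq_len(n_genes)),
                                 sheet$sample_id))
  expression_matrix(vals, sheet)
}

toy_comparison <- function() list(name = "T1", group_a = "GA", group_b = "GB")

# Brute-force truth-table evaluator, structurally independent of the package
# evaluator: expands the AST into an R logical expression and eval()s it.
brute_eval <- function(expr, calls, direction) {
  to_r <- function(node) {
    if (node$op == "leaf")
      return(sprintf('(calls[["%s"]] == "%s")', node$name, direction))
    glue <- if (node$op == "and") " & " else " | "
    paste0("(", paste(vapply(node$children, to_r, character(1)),
                      collapse = glue), ")")
  }
  eval(parse(text = to_r(expr)))
}

# All 3^k call vectors over comparison names.
all_call_vectors <- function(names) {
  grid <- expand.grid(rep(list(c("enriched", "depleted", "ns")), length(names)),
                      stringsAsFactors = FALSE)
  colnames(grid) <- names
  grid
}

# Random AST over given comparison names (for property tests).
random_ast <- function(names, depth = 3L) {
  if (depth == 0L || stats::runif(1) < 0.3)
    return(orgscreen::parse_expression(sample(names, 1L)))
  op <- sample(c("and", "or"), 1L)
  k <- sample(2:3, 1L)
  kids <- replicate(k, random_ast(names, depth - 1L), simplify = FALSE)
  txt <- paste0("(", paste(vapply(kids, format, character(1)),
                           collapse = if (op == "and") " AND " else " OR "), ")")
  orgscreen::parse_expression(txt)
}

# Exhaustive hypergeometric enumeration oracle for the two-sided Fisher test,
# built on stats::dhyper (independent of the package's lchoose route).
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  if (min(r1, r2, c1, sum(tab[, 2])) == 0) return(1)
  x <- max(0, c1 - r2):min(r1, c1)
  d <- stats::dhyper(x, r1, r2, c1)
  sum(d[d <= d[x == a] * (1 + 1e-7)])
}
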