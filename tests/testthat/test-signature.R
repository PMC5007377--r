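test_that("parser handles atoms, precedence and the default expression", {
  expect_equal(format(parse_expression("C1")), "C1")
  # AND binds tighter than OR
  expect_equal(format(parse_expression("C1 AND C2 OR C3")),
               "((C1 AND C2) OR C3)")
  expect_equal(format(parse_expression("c1 and c2 or c3")),
               "((c1 AND c2) OR c3)")
  ast <- parse_expression(default_expression_text())
  expect_equal(format(ast), "((C1 AND (C2 OR C3)) AND C4 AND (C5 OR C6))")
  # canonical re-serialization is a fixed point
  expect_equal(format(parse_expression(format(ast))), format(ast))
})

test_that("parser reports errors with positions", {
  expect_error(parse_expression("(C1 AND C2"), "unbalanced.*position 1")
  expect_error(parse_expression("C1 AND"), "end of input")
  expect_error(parse_expression("C1 ? C2"), "'\\?' at position 4")
  expect_error(parse_expression("C1 C2"), "position")
  expect_error(parse_expression(""), "empty")
})

test_that("precedence agrees with exhaustive parenthesization on 3 atoms", {
  calls_grid <- all_call_vectors(c("A", "B", "C"))
  e_flat <- parse_expression("A AND B OR C")
  e_paren <- parse_expression("(A AND B) OR C")
  e_wrong <- parse_expression("A AND (B OR C)")
  for (i in seq_len(nrow(calls_grid))) {
    calls <- unlist(calls_grid[i, ])
    expect_equal(evaluate_gene(e_flat, calls, "enriched"),
                 evaluate_gene(e_paren, calls, "enriched"))
  }
  # the two parenthesizations genuinely differ somewhere
  diffs <- vapply(seq_len(nrow(calls_grid)), function(i) {
    calls <- unlist(calls_grid[i, ])
    evaluate_gene(e_paren, calls, "enriched") !=
      evaluate_gene(e_wrong, calls, "enriched")
  }, logical(1))
  expect_true(any(diffs))
})

test_that("evaluator matches the truth-table oracle on all 729 call vectors", {
  cmp_names <- paste0("C", 1:6)
  grid <- all_call_vectors(cmp_names)
  exprs <- c(list(parse_expression(default_expression_text())),
             { set.seed(99); replicate(25, random_ast(cmp_names), simplify = FALSE) })
  grid_mat <- as.matrix(grid)
  rownames(grid_mat) <- sprintf("v%03d", seq_len(nrow(grid_mat)))
  for (ex in exprs) {
    for (dir in c("enriched", "depleted")) {
      got <- unname(orgscreen:::eval_expr_matrix(ex, grid_mat, dir))
      want <- vapply(seq_len(nrow(grid)), function(i)
        brute_eval(ex, as.list(grid[i, ]), dir), logical(1))
      expect_identical(got, want)
    }
  }
})

test_that("evaluation examples: vacuous calls, the worked call vector, errors", {
  expr <- parse_expression(default_expression_text())
  ns_calls <- setNames(rep("ns", 6), paste0("C", 1:6))
  expect_false(evaluate_gene(expr, ns_calls, "enriched"))
  expect_false(evaluate_gene(expr, ns_calls, "depleted"))
  # enriched in early node vs streak, persisting early-vs-late, VNT and HH20 limb
  calls <- setNames(c("enriched", "ns", "enriched", "enriched", "enriched", "ns"),
                    paste0("C", 1:6))
  expect_true(evaluate_gene(expr, calls, "enriched"))
  expect_false(evaluate_gene(expr, calls, "depleted"))
  expect_error(evaluate_gene(expr, calls[1:5], "enriched"), "C6")
})

test_that("derive_signature handles empty input, disjointness and table lists", {
  expr <- parse_expression(default_expression_text())
  ns_mat <- matrix("ns", nrow = 4, ncol = 6,
                   dimnames = list(paste0("g", 1:4), paste0("C", 1:6)))
  sig <- derive_signature(ns_mat, expr)
  expect_length(sig$enriched, 0)
  expect_length(sig$depleted, 0)

  # under the default expression enriched and depleted sets cannot overlap
  set.seed(12)
  rand <- matrix(sample(c("enriched", "depleted", "ns"), 6 * 2000, replace = TRUE),
                 ncol = 6, dimnames = list(sprintf("g%04d", 1:2000), paste0("C", 1:6)))
  sig2 <- derive_signature(rand, expr)
  expect_length(intersect(sig2$enriched, sig2$depleted), 0)

  # list-of-tables input equals matrix input; inconsistent gene sets error
  tbls <- lapply(paste0("C", 1:6), function(nm)
    data.frame(gene_id = rownames(rand), call = rand[, nm]))
  names(tbls) <- paste0("C", 1:6)
  sig3 <- derive_signature(tbls, expr)
  expect_identical(sig3$enriched, sig2$enriched)
  tbls$C6 <- tbls$C6[-1, ]
  expect_error(derive_signature(tbls, expr), "consistency error")
})

test_that("adding OR-branches grows and AND-conjuncts shrinks the signature", {
  set.seed(22)
  cmp_names <- paste0("C", 1:6)
  rand <- matrix(sample(c("enriched", "depleted", "ns"), 6 * 1000, replace = TRUE),
                 ncol = 6, dimnames = list(sprintf("g%04d", 1:1000), cmp_names))
  base_txt <- "(C1 AND (C2 OR C3)) AND C4"
  wider <- parse_expression(paste(base_txt, "OR C5"))
  narrower <- parse_expression(paste(base_txt, "AND C5"))
  base <- parse_expression(base_txt)
  s_base <- derive_signature(rand, base)
  # the widened expression can legitimately place a gene in both sets
  # (enriched via one OR-branch, depleted via the other), which warns
  s_wide <- suppressWarnings(derive_signature(rand, wider))
  s_narrow <- derive_signature(rand, narrower)
  expect_true(all(s_base$enriched %in% s_wide$enriched))
  expect_true(all(s_narrow$enriched %in% s_base$enriched))
})

test_that("flipping every call maps the enriched set onto the depleted set", {
  set.seed(33)
  cmp_names <- paste0("C", 1:6)
  rand <- matrix(sample(c("enriched", "depleted", "ns"), 6 * 500, replace = TRUE),
                 ncol = 6, dimnames = list(sprintf("g%03d", 1:500), cmp_names))
  flipped <- rand
  flipped[rand == "enriched"] <- "depleted"
  flipped[rand == "depleted"] <- "enriched"
  expr <- parse_expression(default_expression_text())
  a <- derive_signature(rand, expr)
  b <- derive_signature(flipped, expr)
  expect_identical(a$enriched, b$depleted)
  expect_identical(a$depleted, b$enriched)
})

test_that("recovery metrics: perfect, degenerate and random-signature cases", {
  truth <- data.frame(
    gene_id = sprintf("g%05d", 1:10000),
    class = c(rep("planted_enriched", 31), rep("planted_depleted", 17),
              rep("null", 10000 - 48)),
    stringsAsFactors = FALSE
  )
  perfect <- signature_set(truth$gene_id[1:31], truth$gene_id[32:48])
  r <- recovery_metrics(perfect, truth)
  expect_equal(r$sensitivity_enriched, 1.0)
  expect_equal(r$sensitivity_depleted, 1.0)
  expect_equal(r$set_fdr, 0.0)

  empty <- signature_set(character(0), character(0))
  r0 <- recovery_metrics(empty, truth)
  expect_equal(r0$sensitivity_enriched, 0.0)
  expect_true(is.na(r0$set_fdr))

  # random 31+17 signature: expected per-direction sensitivity is
  # hypergeometric, 31/10000 and 17/10000
  set.seed(55)
  sens_e <- sens_d <- numeric(300)
  for (i in 1:300) {
    pick <- sample(truth$gene_id, 48)
    rr <- recovery_metrics(signature_set(pick[1:31], pick[32:48]), truth)
    sens_e[i] <- rr$sensitivity_enriched
    sens_d[i] <- rr$sensitivity_depleted
  }
  expect_lt(abs(mean(sens_e) - 31 / 10000), 3 * sd(sens_e) / sqrt(300) + 1e-12)
  expect_lt(abs(mean(sens_d) - 17 / 10000), 3 * sd(sens_d) / sqrt(300) + 1e-12)
})

test_that("signature JSON round-trips through write and read", {
  sig <- signature_set(c("a", "b"), c("c"), expression_text = "C1 AND C4")
  f <- tempfile(fileext = ".json")
  write_signature(sig, f, thresholds = list(lfc = 1.2, fdr = 0.05))
  back <- read_signature(f)
  expect_identical(back$enriched, sig$enriched)
  expect_identical(back$depleted, sig$depleted)
  expect_identical(back$expression_text, sig$expression_text)
})
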