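test_that("group_stats matches the hand-computed pooled-variance oracle", {
  x <- toy_matrix(c(5.0, 5.2, 5.4), c(3.0, 3.1, 3.2))
  gs <- group_stats(x, toy_comparison())
  expect_equal(unname(gs$log2fc), rep(2.1, 3))
  # var(5.0,5.2,5.4) = 0.04, var(3.0,3.1,3.2) = 0.01 -> pooled (2*.04+2*.01)/4
  expect_equal(unname(gs$s_sq), rep(0.025, 3))
  expect_equal(gs$df, 4L)

  # degenerate: identical constant in both groups
  xc <- toy_matrix(c(7, 7, 7), c(7, 7, 7))
  gsc <- group_stats(xc, toy_comparison())
  expect_equal(unname(gsc$log2fc), rep(0, 3))
  expect_equal(unname(gsc$s_sq), rep(0, 3))

  # antisymmetry under group swap
  swapped <- list(name = "T1r", group_a = "GB", group_b = "GA")
  gsr <- group_stats(x, swapped)
  expect_equal(gsr$log2fc, -gs$log2fc)
  expect_equal(gsr$s_sq, gs$s_sq)

  # comparison naming a group outside the design is an error
  expect_error(group_stats(x, list(name = "T2", group_a = "GA", group_b = "GX")),
               "GX")
})

test_that("variance prior fit: degenerate spread and parameter recovery", {
  # all variances identical -> infinitely strong prior at the common value
  pr <- estimate_variance_prior(rep(0.3, 100), df = 4)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 0.3)

  expect_error(estimate_variance_prior(rep(0.2, 20), df = 4), ">= 50")
  expect_error(estimate_variance_prior(rep(0, 100), df = 4), "zero")

  # recovery from the generative model: s^2 = s0^2 * F(df, d0)
  set.seed(101)
  d0 <- 4; s0 <- 1; df <- 4; n <- 10000
  sigma2 <- d0 * s0 / rchisq(n, d0)
  s_sq <- sigma2 * rchisq(n, df) / df
  fit <- estimate_variance_prior(s_sq, df)
  expect_lt(abs(fit$d0 - d0) / d0, 0.20)
  expect_lt(abs(fit$s0_sq - s0) / s0, 0.10)
})

test_that("variance prior agrees with limma's empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(7)
  s_sq <- 0.1 * rf(5000, 6, 5)
  mine <- estimate_variance_prior(s_sq, df = 6)
  lim <- limma::fitFDist(s_sq, df1 = 6)
  expect_equal(mine$d0, lim$df2, tolerance = 1e-6)
  expect_equal(mine$s0_sq, lim$scale, tolerance = 1e-6)
})

test_that("moderated test: null center, classical limit, common-variance limit", {
  x <- toy_matrix(c(5.0, 5.2, 5.4), c(3.0, 3.1, 3.2))
  gs <- group_stats(x, toy_comparison())

  # null center
  gs0 <- gs; gs0$log2fc <- rep(0, 3)
  mt0 <- moderated_test(gs0, moderation_params(4, 0.05))
  expect_equal(unname(mt0$t_mod), rep(0, 3))
  expect_equal(unname(mt0$p), rep(1, 3))

  # d0 = 0 reproduces the classical pooled two-sample t exactly
  mt <- moderated_test(gs, moderation_params(0, 1))
  t_hand <- 2.1 / sqrt(0.025 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(unname(mt$t_mod), rep(t_hand, 3), tolerance = 1e-9)
  expect_equal(unname(mt$p), rep(p_hand, 3), tolerance = 1e-9)

  # d0 = Inf tests every gene at s0^2: |t| ranking equals |log2fc| ranking
  set.seed(3)
  gsr <- list(log2fc = rnorm(50), s_sq = rf(50, 4, 4), df = 4, n_a = 3, n_b = 3)
  mti <- moderated_test(gsr, moderation_params(Inf, 0.2))
  expect_equal(order(abs(mti$t_mod)), order(abs(gsr$log2fc)))

  # moderation shrinks: posterior variance lies between s^2 and s0^2
  pr <- moderation_params(4, 0.2)
  mtm <- moderated_test(gsr, pr)
  s_post <- (pr$d0 * pr$s0_sq + gsr$df * gsr$s_sq) / (pr$d0 + gsr$df)
  expect_true(all(s_post >= pmin(gsr$s_sq, pr$s0_sq) - 1e-12))
  expect_true(all(s_post <= pmax(gsr$s_sq, pr$s0_sq) + 1e-12))

  # zero variance with nonzero effect needs a prior
  gsz <- list(log2fc = c(1, 0), s_sq = c(0, 0), df = 4, n_a = 3, n_b = 3)
  expect_error(moderated_test(gsz, moderation_params(0, 1)), "d0 > 0")
  mtz <- moderated_test(gsz, moderation_params(4, 0.05))
  expect_true(is.finite(mtz$t_mod[1]) && mtz$t_mod[1] > 0)
})

test_that("moderated t matches limma's eBayes on simulated data", {
  skip_if_not_installed("limma")
  sim <- simulate_expression(params = planted_params(n_genes = 300, n_decoy = 10),
                             seed = 15)
  cmp <- default_comparisons()[4, ]
  gs <- group_stats(sim$matrix, cmp)
  pr <- estimate_variance_prior(gs$s_sq, gs$df)
  mt <- moderated_test(gs, pr)
  sel <- sim$matrix$sheet$group %in% c(cmp$group_a, cmp$group_b)
  grp <- factor(sim$matrix$sheet$group[sel], levels = c(cmp$group_b, cmp$group_a))
  fit <- limma::eBayes(limma::lmFit(sim$matrix$values[, sel],
                                    stats::model.matrix(~grp)))
  expect_equal(unname(mt$t_mod), unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(mt$p), unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("BH adjustment follows the step-up formula and its properties", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(adjust_bh(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(adjust_bh(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(8)
  for (i in 1:5) {
    p <- runif(200)
    q <- adjust_bh(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    # monotone: sorting p sorts q identically
    expect_true(all(diff(q[order(p)]) >= 0))
  }
})

test_that("calls apply the fold-change and FDR thresholds inclusively", {
  tbl <- data.frame(log2fc = c(1.3, 1.3, -1.5, 1.2, -1.2, 0.5),
                    q = c(0.01, 0.06, 0.04, 0.05, 0.05, 0.001))
  out <- call_genes(tbl, tau = 1.2, alpha = 0.05)
  expect_equal(out$call,
               c("enriched", "ns", "depleted", "enriched", "depleted", "ns"))
})

test_that("swapping comparison groups swaps enriched and depleted calls", {
  sim <- simulate_expression(params = planted_params(n_genes = 500, n_decoy = 20),
                             seed = 31)
  fwd <- orgscreen:::differential_table(sim$matrix, default_comparisons()[4, ],
                                        tau = 1.2, alpha = 0.05)
  rev_cmp <- list(name = "C4r", group_a = "DNT", group_b = "VNT")
  bwd <- orgscreen:::differential_table(sim$matrix, rev_cmp,
                                        tau = 1.2, alpha = 0.05)
  expect_equal(bwd$call[fwd$call == "enriched"],
               rep("depleted", sum(fwd$call == "enriched")))
  expect_equal(bwd$call[fwd$call == "depleted"],
               rep("enriched", sum(fwd$call == "depleted")))
})

test_that("all-null simulations keep the per-comparison call rate below alpha", {
  frac <- vapply(1:10, function(s) {
    sim <- simulate_expression(
      params = planted_params(n_genes = 2000, n_enriched = 0, n_depleted = 0,
                              n_decoy = 0),
      seed = 400 + s)
    tbl <- orgscreen:::differential_table(sim$matrix, default_comparisons()[4, ],
                                          tau = 0, alpha = 0.05)
    mean(tbl$call != "ns")
  }, numeric(1))
  n_total <- 10 * 2000
  se <- sqrt(0.05 * 0.95 / n_total)
  expect_lte(mean(frac), 0.05 + 3 * se)
})
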