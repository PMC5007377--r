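#' Variance-moderation prior parameters
#'
#' The gene-level variance prior is a scaled inverse-chi-square distribution
#' with `d0` prior degrees of freedom and prior value `s0_sq`. `d0 = 0` means
#' no moderation (classical pooled t); `d0 = Inf` means every gene is tested
#' against the common variance `s0_sq`.
#'
#' @param d0 Prior degrees of freedom, in `[0, Inf]`.
#' @param s0_sq Prior variance; must be positive whenever `d0 > 0`.
#' @return An object of class `moderation_params`.
#' @export
moderation_params <- function(d0, s0_sq) {
  if (!is.numeric(d0) || length(d0) != 1L || is.na(d0) || d0 < 0)
    stop("d0 must be a single number >= 0 (Inf allowed)")
  if (!is.numeric(s0_sq) || length(s0_sq) != 1L || is.na(s0_sq))
    stop("s0_sq must be a single number")
  if (d0 > 0 && s0_sq <= 0)
    stop("s0_sq must be positive when d0 > 0")
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderation_params")
}

#' @export
print.moderation_params <- function(x, ...) {
  cat(sprintf("Variance prior: d0 = %s, s0^2 = %.6g\n",
              format(x$d0), x$s0_sq))
  invisible(x)
}

#' Per-gene two-group statistics for one comparison
#'
#' For every gene computes the log2 fold change (mean of `group_a` minus mean
#' of `group_b`), the pooled within-group variance, and its degrees of
#' freedom `n_a + n_b - 2`.
#'
#' @param x An [expression_matrix()].
#' @param comparison A one-row data frame or list with `name`, `group_a`,
#'   `group_b`.
#' @return List with `gene_id`, `log2fc`, `s_sq`, `df`, `n_a`, `n_b`.
#' @export
group_stats <- function(x, comparison) {
  stopifnot(inherits(x, "expr_matrix"))
  comparison <- as.list(comparison)
  ia <- which(x$sheet$group == comparison$group_a)
  ib <- which(x$sheet$group == comparison$group_b)
  if (length(ia) == 0L) stop("group not in sheet: ", comparison$group_a)
  if (length(ib) == 0L) stop("group not in sheet: ", comparison$group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("both groups need >= 2 replicates (variance undefined otherwise)")
  va <- x$values[, ia, drop = FALSE]
  vb <- x$values[, ib, drop = FALSE]
  ma <- rowMeans(va)
  mb <- rowMeans(vb)
  ssa <- rowSums((va - ma)^2)
  ssb <- rowSums((vb - mb)^2)
  df <- length(ia) + length(ib) - 2L
  list(gene_id = rownames(x$values),
       log2fc = ma - mb,
       s_sq = (ssa + ssb) / df,
       df = df,
       n_a = length(ia), n_b = length(ib))
}

# Newton solve of trigamma(x) = y, vector-safe for scalar use.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Fit the variance prior by method of moments on the log scale
#'
#' Under the hierarchical model `s^2 = s0^2 * F(df, d0)`, the log sample
#' variances satisfy `Var(log s^2) = trigamma(df/2) + trigamma(d0/2)`.
#' The prior degrees of freedom solve
#' `trigamma(d0/2) = var(log s^2) - trigamma(df/2)`; when the observed spread
#' does not exceed the pure sampling contribution the prior is degenerate
#' (`d0 = Inf`) and `s0_sq` is the geometric mean of the positive variances.
#' Otherwise `s0_sq` follows from the mean relation
#' `E[log s^2] = log s0^2 + digamma(df/2) - log(df/2) - digamma(d0/2) + log(d0/2)`.
#'
#' @param s_sq Per-gene sample variances (>= 50 positive values required).
#' @param df Residual degrees of freedom shared by all genes.
#' @return A [moderation_params()] object.
#' @export
estimate_variance_prior <- function(s_sq, df) {
  if (!is.numeric(df) || length(df) != 1L || df < 1)
    stop("df must be a positive scalar")
  if (any(is.na(s_sq)) || any(s_sq < 0))
    stop("variances must be non-negative and non-missing")
  pos <- s_sq[s_sq > 0]
  if (all(s_sq == 0))
    stop("all variances are zero; the prior is not estimable")
  if (length(pos) < 50L)
    stop("need >= 50 genes with positive variance to fit the prior (got ",
         length(pos), ")")
  z <- log(pos)
  evar <- stats::var(z) - trigamma(df / 2)
  if (evar <= 0) {
    return(moderation_params(d0 = Inf, s0_sq = exp(mean(z))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  moderation_params(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-test for two-group contrasts
#'
#' Shrinks each gene's pooled variance towards the prior,
#' `s~^2 = (d0 * s0^2 + df * s^2) / (d0 + df)`, and tests
#' `t = log2fc / (s~ * sqrt(1/n_a + 1/n_b))` against a Student t with
#' `d0 + df` degrees of freedom (standard normal when `d0 = Inf`). With
#' `d0 = 0` this is the classical pooled two-sample t-test.
#'
#' @param stats Output of [group_stats()] (or any list with `log2fc`, `s_sq`,
#'   `df`).
#' @param prior A [moderation_params()] object.
#' @param n_a,n_b Group sample sizes (defaulting to those in `stats`).
#' @return List with `t_mod` and two-sided `p`.
#' @export
moderated_test <- function(stats, prior, n_a = stats$n_a, n_b = stats$n_b) {
  stopifnot(inherits(prior, "moderation_params"))
  lfc <- stats$log2fc
  s_sq <- stats$s_sq
  df <- stats$df
  d0 <- prior$d0
  if (d0 + df <= 0)
    stop("d0 + df must be positive")
  if (d0 == 0 && any(s_sq == 0 & lfc != 0))
    stop("zero residual variance with nonzero log2fc requires d0 > 0")
  s_post <- if (is.infinite(d0)) rep(prior$s0_sq, length(s_sq))
            else (d0 * prior$s0_sq + df * s_sq) / (d0 + df)
  se <- sqrt(s_post * (1 / n_a + 1 / n_b))
  t_mod <- ifelse(se == 0, 0, lfc / se)
  p <- if (is.infinite(d0)) 2 * stats::pnorm(-abs(t_mod))
       else 2 * stats::pt(-abs(t_mod), df = d0 + df)
  p <- pmax(p, .Machine$double.xmin)
  p <- pmin(p, 1)
  list(t_mod = t_mod, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_(j>=i) m * p_(j) / j` on the sorted
#' p-values, capped at 1 and mapped back to input order.
#'
#' @param p P-values, all in (0, 1].
#' @return Adjusted q-values in the input order.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify genes as enriched, depleted or not significant
#'
#' A gene is `enriched` iff `log2fc >= tau` and `q <= alpha`, `depleted` iff
#' `log2fc <= -tau` and `q <= alpha`, otherwise `ns`.
#'
#' @param table Data frame with columns `log2fc` and `q`.
#' @param tau Absolute log2 fold-change threshold.
#' @param alpha FDR threshold.
#' @return `table` with a `call` column added (or replaced).
#' @export
call_genes <- function(table, tau = 1.2, alpha = 0.05) {
  stopifnot(is.data.frame(table), all(c("log2fc", "q") %in% names(table)))
  call <- rep("ns", nrow(table))
  sig <- table$q <= alpha
  call[sig & table$log2fc >= tau] <- "enriched"
  call[sig & table$log2fc <= -tau] <- "depleted"
  table$call <- call
  table
}

#' Residual variance pooled across the whole design
#'
#' Per-gene within-group variance pooled over every group in the sample
#' sheet, with `df = n_samples - n_groups` residual degrees of freedom. This
#' is the residual variance of the one-way layout over all tissues, shared by
#' every pairwise contrast (as in a joint linear-model fit).
#'
#' @param x An [expression_matrix()].
#' @return List with `s_sq` (per-gene pooled variance) and `df`.
#' @export
design_residual_variance <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  groups <- unique(x$sheet$group)
  ss <- numeric(nrow(x$values))
  for (g in groups) {
    v <- x$values[, x$sheet$group == g, drop = FALSE]
    ss <- ss + rowSums((v - rowMeans(v))^2)
  }
  df <- ncol(x$values) - length(groups)
  if (df < 1L) stop("design leaves no residual degrees of freedom")
  list(s_sq = ss / df, df = df)
}

# Full single-comparison table: stats -> prior -> moderated t -> BH -> calls.
differential_table <- function(x, comparison, tau, alpha, prior = NULL,
                               var_pool = c("design", "pair")) {
  var_pool <- match.arg(var_pool)
  gs <- group_stats(x, comparison)
  if (var_pool == "design") {
    rv <- design_residual_variance(x)
    gs$s_sq <- rv$s_sq
    gs$df <- rv$df
  }
  if (is.null(prior)) prior <- estimate_variance_prior(gs$s_sq, gs$df)
  mt <- moderated_test(gs, prior)
  tbl <- data.frame(gene_id = gs$gene_id,
                    log2fc = gs$log2fc,
                    s_sq = gs$s_sq,
                    df = gs$df,
                    t_mod = mt$t_mod,
                    p = mt$p,
                    q = adjust_bh(mt$p),
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  tbl <- call_genes(tbl, tau = tau, alpha = alpha)
  attr(tbl, "prior") <- prior
  tbl
}
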