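#' Fit the organizer synexpression screen
#'
#' The central model fit of the package. For each configured pairwise
#' comparison (organizer tissue vs its most similar non-organizer neighbour)
#' it computes per-gene log2 fold changes and pooled variances, fits a scaled
#' inverse-chi-square variance prior by method of moments, tests each gene
#' with the empirical-Bayes moderated t-statistic, controls the FDR per
#' comparison with Benjamini-Hochberg, and classifies genes as enriched /
#' depleted / ns at the configured fold-change and FDR thresholds. The
#' per-comparison calls are then combined with the configured Boolean algebra
#' (significance as the indicator, not absolute expression level) to derive
#' the enriched and depleted synexpression sets.
#'
#' @param x An [expression_matrix()]. Values are assumed log2; if
#'   `config$already_log2` is `FALSE` they are log2-transformed (with a +1
#'   offset) first.
#' @param config An [orgscreen_config()].
#' @param prior Optional [moderation_params()] applied to every comparison
#'   instead of the per-comparison empirical-Bayes fit. `moderation_params(0, 1)`
#'   yields the classical pooled two-sample t-test.
#' @param var_pool Residual-variance pooling: `"design"` (default) pools
#'   within-group variance across all tissues of the design
#'   (`df = n_samples - n_groups`, as in a joint linear-model fit of the
#'   whole array set); `"pair"` uses only the two groups of each comparison
#'   (`df = n_a + n_b - 2`).
#' @return An object of class `organizer_screen` with elements
#'   `tables` (named list of per-comparison data frames: `gene_id`, `log2fc`,
#'   `s_sq`, `df`, `t_mod`, `p`, `q`, `call`), `calls` (genes x comparisons
#'   character matrix), `priors` (per-comparison data frame of `d0`, `s0_sq`),
#'   `signature` (a [signature_set()]), and `config`.
#' @seealso [derive_signature()], [score_candidate()], [simulate_expression()]
#' @examples
#' sim <- simulate_expression(params = planted_params(n_genes = 500,
#'                                                    n_decoy = 20), seed = 7)
#' fit <- organizer_screen(sim$matrix)
#' summary(fit)
#' recovery_metrics(fit$signature, sim$truth)
#' @export
organizer_screen <- function(x, config = orgscreen_config(), prior = NULL,
                             var_pool = c("design", "pair")) {
  stopifnot(inherits(x, "expr_matrix"), inherits(config, "orgscreen_config"))
  var_pool <- match.arg(var_pool)
  if (!is.null(prior)) stopifnot(inherits(prior, "moderation_params"))
  comparisons <- validate_comparisons(config$comparisons, x$sheet)
  if (!config$already_log2) {
    if (any(x$values < 0))
      stop("negative values are incompatible with already_log2 = FALSE")
    x$values <- log2(x$values + 1)
  }
  tau <- lfc_cutoff(config)
  alpha <- config$fdr_threshold
  tables <- vector("list", nrow(comparisons))
  names(tables) <- comparisons$name
  for (i in seq_len(nrow(comparisons))) {
    tables[[i]] <- differential_table(x, comparisons[i, ], tau = tau,
                                      alpha = alpha, prior = prior,
                                      var_pool = var_pool)
  }
  gid <- rownames(x$values)
  calls <- vapply(tables, function(tbl) tbl$call, character(length(gid)))
  calls <- matrix(calls, nrow = length(gid),
                  dimnames = list(gid, comparisons$name))
  priors <- do.call(rbind, lapply(names(tables), function(nm) {
    pr <- attr(tables[[nm]], "prior")
    data.frame(comparison = nm, d0 = pr$d0, s0_sq = pr$s0_sq,
               stringsAsFactors = FALSE)
  }))
  signature <- derive_signature(calls, config$expression)
  structure(list(tables = tables, calls = calls, priors = priors,
                 signature = signature, config = config,
                 n_genes = length(gid)),
            class = "organizer_screen")
}

#' @export
print.organizer_screen <- function(x, ...) {
  cat(sprintf("Organizer screen: %d genes, %d comparisons\n",
              x$n_genes, length(x$tables)))
  cat("  expression:", x$config$expression_text, "\n")
  cat(sprintf("  signature: %d enriched, %d depleted\n",
              length(x$signature$enriched), length(x$signature$depleted)))
  invisible(x)
}

#' Summarize an organizer screen fit
#'
#' @param object An `organizer_screen` fit.
#' @param ... Unused.
#' @return A data frame of per-comparison enriched/depleted counts and prior
#'   parameters, invisibly, after printing it with the signature summary.
#' @export
summary.organizer_screen <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$tables), function(nm) {
    tbl <- object$tables[[nm]]
    data.frame(comparison = nm,
               enriched = sum(tbl$call == "enriched"),
               depleted = sum(tbl$call == "depleted"),
               d0 = attr(tbl, "prior")$d0,
               s0_sq = attr(tbl, "prior")$s0_sq,
               stringsAsFactors = FALSE)
  }))
  print(object)
  cat("\nPer-comparison calls:\n")
  print(tab, row.names = FALSE, digits = 4)
  invisible(tab)
}

#' Log2 fold-change matrix of a screen fit
#'
#' @param object An `organizer_screen` fit.
#' @param ... Unused.
#' @return Genes x comparisons numeric matrix of log2 fold changes.
#' @export
coef.organizer_screen <- function(object, ...) {
  lfc <- vapply(object$tables, function(tbl) tbl$log2fc,
                numeric(object$n_genes))
  matrix(lfc, nrow = object$n_genes,
         dimnames = list(object$tables[[1L]]$gene_id, names(object$tables)))
}

#' Volcano plot for one comparison of a screen fit
#'
#' @param x An `organizer_screen` fit.
#' @param comparison Comparison name or index (default first).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.organizer_screen <- function(x, comparison = 1L, ...) {
  tbl <- x$tables[[comparison]]
  nm <- if (is.character(comparison)) comparison else names(x$tables)[comparison]
  col <- ifelse(tbl$call == "enriched", "firebrick",
         ifelse(tbl$call == "depleted", "steelblue", "grey60"))
  graphics::plot(tbl$log2fc, -log10(tbl$p), col = col, pch = 20,
                 xlab = expression(log[2] ~ "fold change"),
                 ylab = expression(-log[10] ~ p),
                 main = paste("Comparison", nm), ...)
  tau <- lfc_cutoff(x$config)
  graphics::abline(v = c(-tau, tau), lty = 2, col = "grey40")
  invisible(x)
}
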