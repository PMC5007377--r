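#' Read explant scoring records from TSV
#'
#' Expects columns `experiment_id`, `condition`, `marker`, `category` with
#' categories in `{positive, patchy, negative, excluded}`.
#'
#' @param path Path to the TSV file.
#' @return Data frame of validated records.
#' @export
read_explant_records <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("experiment_id", "condition", "marker", "category")
  miss <- setdiff(need, names(tbl))
  if (length(miss))
    stop("records file is missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(tbl$category),
                 c("positive", "patchy", "negative", "excluded"))
  if (length(bad))
    stop("invalid category value(s): ", paste(bad, collapse = ", "))
  tbl
}

#' Tabulate explant outcomes into a 2x2 contingency table
#'
#' Positive column = `positive` scores (plus `patchy` when
#' `patchy_as_positive`); negative column = `negative` scores. Explants
#' scored `excluded` (high-level expression confined to a small patch) are
#' dropped unless `include_excluded`, in which case they count as negative.
#' Patchy explants are dropped when not counted positive.
#'
#' @param records Data frame of explant records (see
#'   [read_explant_records()]).
#' @param condition_pair Length-2 character vector of conditions to compare;
#'   rows of the table follow this order.
#' @param marker Marker gene to tabulate.
#' @param patchy_as_positive Count patchy as positive (default `FALSE`).
#' @param include_excluded Count excluded as negative (default `FALSE`).
#' @return 2x2 integer matrix, rows = conditions, columns = positive/negative.
#' @export
tabulate_explants <- function(records, condition_pair, marker,
                              patchy_as_positive = FALSE,
                              include_excluded = FALSE) {
  stopifnot(is.data.frame(records), length(condition_pair) == 2L)
  sub <- records[records$marker == marker, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no records for marker '", marker, "'")
  absent <- setdiff(condition_pair, unique(sub$condition))
  if (length(absent))
    stop("condition(s) absent from the records for marker '", marker, "': ",
         paste(absent, collapse = ", "))
  count <- function(cond, cats)
    sum(sub$condition == cond & sub$category %in% cats)
  pos_cats <- c("positive", if (isTRUE(patchy_as_positive)) "patchy")
  neg_cats <- c("negative", if (isTRUE(include_excluded)) "excluded")
  tab <- matrix(
    c(count(condition_pair[1L], pos_cats), count(condition_pair[1L], neg_cats),
      count(condition_pair[2L], pos_cats), count(condition_pair[2L], neg_cats)),
    nrow = 2L, byrow = TRUE,
    dimnames = list(condition = condition_pair,
                    result = c("positive", "negative"))
  )
  storage.mode(tab) <- "integer"
  tab
}

#' Exact two-tailed Fisher test for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric point probabilities
#' of every table at least as extreme as the observed one, where "as extreme"
#' means point probability no greater than the observed probability times
#' `1 + 1e-7` (a relative tie tolerance). Probabilities are accumulated via
#' log-binomial coefficients, exact to ~1e-12 for totals up to 1000. A table
#' with any zero margin has p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("table must be 2x2")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers")
  a <- tab[1L, 1L]
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L]); c2 <- sum(tab[, 2L])
  n <- r1 + r2
  if (min(r1, r2, c1, c2) == 0) return(1)
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  x <- lo:hi
  logp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  obs <- logp[x == a]
  p <- sum(exp(logp[logp <= obs + log1p(1e-7)]))
  min(p, 1)
}

#' Star label for a Fisher p-value
#'
#' `"***"` for p <= 0.0005, `"**"` for p <= 0.005, `"*"` for p <= 0.05
#' (the significance cutoff), `"ns"` otherwise. Boundaries are inclusive.
#'
#' @param p P-value(s) in (0, 1].
#' @return Character vector of labels.
#' @export
significance_label <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p must lie in (0, 1]")
  ifelse(p <= 0.0005, "***",
  ifelse(p <= 0.005, "**",
  ifelse(p <= 0.05, "*", "ns")))
}

#' Tabulate and test one explant comparison
#'
#' Convenience wrapper: builds the 2x2 table, runs the exact two-tailed
#' Fisher test and attaches the significance label.
#'
#' @inheritParams tabulate_explants
#' @return List with `table`, `p` and `label`.
#' @export
assay_test <- function(records, condition_pair, marker,
                       patchy_as_positive = FALSE,
                       include_excluded = FALSE) {
  tab <- tabulate_explants(records, condition_pair, marker,
                           patchy_as_positive = patchy_as_positive,
                           include_excluded = include_excluded)
  p <- fisher_exact_two_sided(tab)
  list(table = tab, p = p, label = significance_label(p))
}
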