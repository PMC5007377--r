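# Run code under a given seed without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Parameters of the planted-signature simulation
#'
#' Defaults emulate the scale and design of the organizer screen: 10,000
#' probe-level genes (use `n_genes = 32773` for full array scale), a planted
#' set of 31 enriched and 17 depleted signature genes, 200 decoy genes
#' differential in only a subset of comparisons, and the remainder null.
#' Gene variances follow a scaled inverse-chi-square prior.
#'
#' @param n_genes Total genes (default 10000).
#' @param n_enriched,n_depleted Planted signature genes per direction
#'   (defaults 31 and 17).
#' @param effect Planted shift in log2 units (default 2.0).
#' @param baseline_range Range of per-gene baseline means, log2 (default 4..12).
#' @param var_prior_df,var_prior_scale Scaled inverse-chi-square variance
#'   prior: degrees of freedom d0 (default 4) and scale s0^2 (default 0.0625).
#' @param n_decoy Number of decoy genes (default 200).
#' @param decoy_pattern Comparisons each decoy perturbs (default `"C1"`).
#'   Because comparisons share tissue groups, a decoy's shift can induce
#'   significance in algebraically linked comparisons as well; the pattern is
#'   validated to leave the Boolean expression unsatisfied.
#' @param planted_pattern Comparisons the planted genes satisfy (default
#'   `NULL`: all configured comparisons, the strongest concordant pattern).
#' @return An object of class `planted_params`.
#' @export
planted_params <- function(n_genes = 10000L,
                           n_enriched = 31L,
                           n_depleted = 17L,
                           effect = 2.0,
                           baseline_range = c(4, 12),
                           var_prior_df = 4,
                           var_prior_scale = 0.0625,
                           n_decoy = 200L,
                           decoy_pattern = "C1",
                           planted_pattern = NULL) {
  n_genes <- as.integer(n_genes)
  n_enriched <- as.integer(n_enriched)
  n_depleted <- as.integer(n_depleted)
  n_decoy <- as.integer(n_decoy)
  if (any(c(n_genes, n_enriched, n_depleted, n_decoy) < 0L))
    stop("gene counts must be non-negative")
  if (n_enriched + n_depleted + n_decoy > n_genes)
    stop("n_enriched + n_depleted + n_decoy must not exceed n_genes")
  if (!is.numeric(effect) || effect < 0)
    stop("effect must be non-negative")
  if (length(baseline_range) != 2L || baseline_range[1] > baseline_range[2])
    stop("baseline_range must be (low, high) with low <= high")
  if (var_prior_df <= 0) stop("var_prior_df must be positive")
  if (var_prior_scale < 0) stop("var_prior_scale must be non-negative")
  structure(list(n_genes = n_genes, n_enriched = n_enriched,
                 n_depleted = n_depleted, effect = effect,
                 baseline_range = baseline_range,
                 var_prior_df = var_prior_df,
                 var_prior_scale = var_prior_scale,
                 n_decoy = n_decoy, decoy_pattern = decoy_pattern,
                 planted_pattern = planted_pattern),
            class = "planted_params")
}

# Resolve a set of directed comparison constraints to group-level offsets.
# For sign +1 each comparison in `pattern` must end with
# offset[group_a] - offset[group_b] >= effect (<= -effect for sign -1).
# Solved by longest-path relaxation; a cyclic (group-inconsistent) pattern
# fails to converge and is an error.
resolve_offsets <- function(comparisons, pattern, sign, effect, groups) {
  offsets <- stats::setNames(numeric(length(groups)), groups)
  if (effect == 0 || length(pattern) == 0L) return(offsets)
  rows <- comparisons[match(pattern, comparisons$name), , drop = FALSE]
  if (any(is.na(rows$name)))
    stop("pattern names not among the configured comparisons: ",
         paste(setdiff(pattern, comparisons$name), collapse = ", "))
  for (pass in seq_len(length(groups) + 1L)) {
    changed <- FALSE
    for (i in seq_len(nrow(rows))) {
      a <- rows$group_a[i]; b <- rows$group_b[i]
      target <- offsets[b] + sign * effect
      if (sign > 0 && offsets[a] < target - 1e-12) {
        offsets[a] <- target; changed <- TRUE
      } else if (sign < 0 && offsets[a] > target + 1e-12) {
        offsets[a] <- target; changed <- TRUE
      }
    }
    if (!changed) return(offsets)
  }
  stop("generation error: pattern ", paste(pattern, collapse = ","),
       " is group-inconsistent (cyclic constraints over shared tissue groups)")
}

# Calls induced by exact (noise-free) group offsets at threshold `effect`.
induced_calls <- function(comparisons, offsets, effect) {
  d <- offsets[comparisons$group_a] - offsets[comparisons$group_b]
  tol <- effect * (1 - 1e-9)
  calls <- ifelse(d >= tol, "enriched", ifelse(d <= -tol, "depleted", "ns"))
  stats::setNames(calls, comparisons$name)
}

calls_to_pattern <- function(calls) {
  paste(ifelse(calls == "enriched", "+", ifelse(calls == "depleted", "-", "0")),
        collapse = "")
}

#' Simulate an expression matrix with a planted organizer signature
#'
#' Per gene g: baseline `mu_g ~ Uniform(baseline_range)`, variance
#' `sigma_g^2 ~ scaled-inv-chi-square(var_prior_df, var_prior_scale)`, and
#' each replicate is `mu_g + group offset + N(0, sigma_g^2)`. Planted
#' enriched genes are shifted up on the organizer side of every comparison in
#' the planted pattern (resolved to tissue-group offsets, so each comparison's
#' mean difference is at least `effect`); planted depleted genes are shifted
#' down analogously; decoys are shifted only on their `decoy_pattern`
#' (validated to fail the Boolean expression); nulls are untouched.
#'
#' @param config An [orgscreen_config()] supplying comparisons and the
#'   Boolean expression.
#' @param params A [planted_params()] object.
#' @param sheet Sample sheet (default [default_sample_sheet()]).
#' @param seed Integer seed; the output is a deterministic function of
#'   `(sheet, params, config, seed)`.
#' @return List with `matrix` (an [expression_matrix()]) and `truth`
#'   (data frame `gene_id`, `class`, `pattern`, where `pattern` is the
#'   noise-free call per comparison coded `+`/`-`/`0`).
#' @export
simulate_expression <- function(config = orgscreen_config(),
                                params = planted_params(),
                                sheet = default_sample_sheet(),
                                seed = 1L) {
  stopifnot(inherits(config, "orgscreen_config"),
            inherits(params, "planted_params"))
  sheet <- validate_sample_sheet(sheet)
  comparisons <- validate_comparisons(config$comparisons, sheet)
  expr <- config$expression
  groups <- unique(sheet$group)
  planted_pattern <- params$planted_pattern
  if (is.null(planted_pattern)) planted_pattern <- comparisons$name

  off_e <- resolve_offsets(comparisons, planted_pattern, +1, params$effect, groups)
  off_d <- resolve_offsets(comparisons, planted_pattern, -1, params$effect, groups)
  off_dec_up <- resolve_offsets(comparisons, params$decoy_pattern, +1,
                                params$effect, groups)
  off_dec_dn <- resolve_offsets(comparisons, params$decoy_pattern, -1,
                                params$effect, groups)

  calls_e <- induced_calls(comparisons, off_e, params$effect)
  calls_d <- induced_calls(comparisons, off_d, params$effect)
  if (params$effect > 0) {
    if (params$n_enriched > 0 && !evaluate_gene(expr, calls_e, "enriched"))
      stop("generation error: the planted pattern does not satisfy the ",
           "Boolean expression in the enriched direction")
    if (params$n_depleted > 0 && !evaluate_gene(expr, calls_d, "depleted"))
      stop("generation error: the planted pattern does not satisfy the ",
           "Boolean expression in the depleted direction")
    if (params$n_decoy > 0) {
      for (off in list(off_dec_up, off_dec_dn)) {
        ic <- induced_calls(comparisons, off, params$effect)
        if (evaluate_gene(expr, ic, "enriched") ||
            evaluate_gene(expr, ic, "depleted"))
          stop("generation error: decoy pattern ",
               paste(params$decoy_pattern, collapse = ","),
               " satisfies the Boolean expression; decoys must fail it")
      }
    }
  }

  n <- params$n_genes
  class <- rep("null", n)
  i_e <- seq_len(params$n_enriched)
  i_d <- seq_len(params$n_depleted) + params$n_enriched
  i_dec <- seq_len(params$n_decoy) + params$n_enriched + params$n_depleted
  class[i_e] <- "planted_enriched"
  class[i_d] <- "planted_depleted"
  class[i_dec] <- "decoy"
  gene_id <- sprintf("g%05d", seq_len(n))

  # genes x groups matrix of true group offsets
  offmat <- matrix(0, nrow = n, ncol = length(groups),
                   dimnames = list(NULL, groups))
  if (params$n_enriched > 0) offmat[i_e, ] <- rep(off_e, each = params$n_enriched)
  if (params$n_depleted > 0) offmat[i_d, ] <- rep(off_d, each = params$n_depleted)
  if (params$n_decoy > 0) {
    dec_up <- i_dec[seq_along(i_dec) %% 2L == 1L]
    dec_dn <- setdiff(i_dec, dec_up)
    if (length(dec_up)) offmat[dec_up, ] <- rep(off_dec_up, each = length(dec_up))
    if (length(dec_dn)) offmat[dec_dn, ] <- rep(off_dec_dn, each = length(dec_dn))
  }

  S <- nrow(sheet)
  gi <- match(sheet$group, groups)
  sim <- with_seed(seed, {
    mu <- stats::runif(n, params$baseline_range[1], params$baseline_range[2])
    sigma2 <- if (params$var_prior_scale == 0) rep(0, n)
              else params$var_prior_df * params$var_prior_scale /
                   stats::rchisq(n, df = params$var_prior_df)
    noise <- matrix(stats::rnorm(n * S), nrow = n, ncol = S) * sqrt(sigma2)
    mu + offmat[, gi, drop = FALSE] + noise
  })
  dimnames(sim) <- list(gene_id, sheet$sample_id)

  pattern <- character(n)
  pattern[class == "null"] <- calls_to_pattern(
    induced_calls(comparisons, stats::setNames(numeric(length(groups)), groups),
                  max(params$effect, 1)))
  pattern[i_e] <- calls_to_pattern(calls_e)
  pattern[i_d] <- calls_to_pattern(calls_d)
  if (params$n_decoy > 0) {
    pat_up <- calls_to_pattern(induced_calls(comparisons, off_dec_up, params$effect))
    pat_dn <- calls_to_pattern(induced_calls(comparisons, off_dec_dn, params$effect))
    pattern[i_dec] <- ifelse(seq_along(i_dec) %% 2L == 1L, pat_up, pat_dn)
  }
  if (params$effect == 0) pattern <- strrep("0", nrow(comparisons))

  truth <- data.frame(gene_id = gene_id, class = class, pattern = pattern,
                      stringsAsFactors = FALSE)
  list(matrix = expression_matrix(sim, sheet), truth = truth)
}

#' Expand truth patterns to a noise-free call matrix
#'
#' Converts the `pattern` strings of a simulation truth table back into a
#' genes x comparisons call matrix, i.e. the calls an ideal (noise-free)
#' differential stage would make.
#'
#' @param truth Truth data frame from [simulate_expression()].
#' @param comparisons Comparison data frame (for column names and order).
#' @return Character matrix of calls.
#' @export
truth_calls <- function(truth, comparisons = default_comparisons()) {
  codes <- strsplit(truth$pattern, "", fixed = TRUE)
  if (any(lengths(codes) != nrow(comparisons)))
    stop("pattern length does not match the number of comparisons")
  mat <- t(vapply(codes, function(cc)
    ifelse(cc == "+", "enriched", ifelse(cc == "-", "depleted", "ns")),
    character(nrow(comparisons))))
  dimnames(mat) <- list(truth$gene_id, comparisons$name)
  mat
}

#' Simulate a candidate-region presence/absence profile
#'
#' Each enriched signature gene is marked `detected` with probability
#' `p_concordant_enriched` (else `absent`); each depleted gene is marked
#' `absent` with probability `p_concordant_depleted` (else `detected`).
#'
#' @param signature A [signature_set()]; must be nonempty.
#' @param p_concordant_enriched,p_concordant_depleted Concordance
#'   probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @param region_name Region label (default "synthetic").
#' @return A [candidate_profile()].
#' @export
simulate_candidate_profile <- function(signature,
                                       p_concordant_enriched,
                                       p_concordant_depleted,
                                       seed = 1L,
                                       region_name = "synthetic") {
  stopifnot(inherits(signature, "signature_set"))
  n_e <- length(signature$enriched)
  n_d <- length(signature$depleted)
  if (n_e + n_d == 0L) stop("signature is empty; nothing to profile")
  p1 <- p_concordant_enriched; p2 <- p_concordant_depleted
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1))
    stop("probabilities must lie in [0, 1]")
  status <- with_seed(seed, {
    se <- ifelse(stats::rbinom(n_e, 1L, p1) == 1L, "detected", "absent")
    sd_ <- ifelse(stats::rbinom(n_d, 1L, p2) == 1L, "absent", "detected")
    stats::setNames(c(se, sd_), c(signature$enriched, signature$depleted))
  })
  candidate_profile(region_name, status)
}

#' Simulate explant co-culture scoring records
#'
#' Draws per-explant outcomes in `{positive, patchy, negative}` for a
#' treatment and a control arm.
#'
#' @param n_treat,n_ctrl Explant counts per arm (non-negative).
#' @param p_pos_treat,p_pos_ctrl Probability of a positive score per arm.
#' @param p_patchy Probability of a patchy score (same in both arms;
#'   `p_pos + p_patchy <= 1` required).
#' @param seed Integer seed.
#' @param marker Marker gene label stored in the records (default "MYOCD").
#' @return Data frame of records: `experiment_id`, `condition`, `marker`,
#'   `category`.
#' @export
simulate_assay_records <- function(n_treat, n_ctrl,
                                   p_pos_treat, p_pos_ctrl,
                                   p_patchy = 0,
                                   seed = 1L,
                                   marker = "MYOCD") {
  n_treat <- as.integer(n_treat); n_ctrl <- as.integer(n_ctrl)
  if (is.na(n_treat) || is.na(n_ctrl) || n_treat < 0L || n_ctrl < 0L)
    stop("explant counts must be non-negative")
  for (p in c(p_pos_treat, p_pos_ctrl, p_patchy))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (p_pos_treat + p_patchy > 1 || p_pos_ctrl + p_patchy > 1)
    stop("p_pos + p_patchy must not exceed 1 in either arm")
  draw <- function(nn, p_pos) {
    if (nn == 0L) return(character(0))
    sample(c("positive", "patchy", "negative"), nn, replace = TRUE,
           prob = c(p_pos, p_patchy, 1 - p_pos - p_patchy))
  }
  cats <- with_seed(seed, c(draw(n_treat, p_pos_treat), draw(n_ctrl, p_pos_ctrl)))
  data.frame(
    experiment_id = sprintf("E%03d", seq_len(n_treat + n_ctrl)),
    condition = rep(c("treatment", "control"), c(n_treat, n_ctrl)),
    marker = rep(marker, n_treat + n_ctrl),
    category = cats,
    stringsAsFactors = FALSE
  )
}
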