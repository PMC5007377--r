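#' Construct a candidate-region expression profile
#'
#' Summarizes whether each signature gene is detected in a candidate region
#' anywhere in the stage window of interest. `unknown` marks genes whose
#' status cannot be scored (e.g. stage-restricted expression); they are
#' excluded from concordance numerators and denominators alike.
#'
#' @param region_name Region label.
#' @param status Named character vector over signature gene ids with values
#'   in `{"detected", "absent", "unknown"}`.
#' @return An object of class `candidate_profile`.
#' @export
candidate_profile <- function(region_name, status) {
  if (!is.character(region_name) || length(region_name) != 1L ||
      is.na(region_name) || region_name == "")
    stop("region_name must be a non-empty string")
  status <- unlist(status)
  if (is.null(names(status)) || any(names(status) == ""))
    stop("status must be named by gene id")
  if (anyDuplicated(names(status)))
    stop("duplicate gene id(s) in profile")
  bad <- setdiff(unique(status), c("detected", "absent", "unknown"))
  if (length(bad))
    stop("invalid status value(s): ", paste(bad, collapse = ", "))
  structure(list(region_name = region_name, status = status),
            class = "candidate_profile")
}

#' @export
print.candidate_profile <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("detected", "absent", "unknown")))
  cat(sprintf("Candidate profile '%s': %d detected, %d absent, %d unknown\n",
              x$region_name, tab[["detected"]], tab[["absent"]],
              tab[["unknown"]]))
  invisible(x)
}

#' Read candidate profiles from TSV
#'
#' Expects columns `region`, `gene_id`, `status`; one [candidate_profile()]
#' is built per region.
#'
#' @param path Path to the TSV file.
#' @return Named list of `candidate_profile` objects.
#' @export
read_candidate_profiles <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("region", "gene_id", "status")
  miss <- setdiff(need, names(tbl))
  if (length(miss))
    stop("profile file is missing column(s): ", paste(miss, collapse = ", "))
  regions <- unique(tbl$region)
  stats::setNames(lapply(regions, function(r) {
    sub <- tbl[tbl$region == r, ]
    candidate_profile(r, stats::setNames(sub$status, sub$gene_id))
  }), regions)
}

#' Score a candidate region against the signature
#'
#' A gene is concordant when it is an enriched signature gene scored
#' `detected`, or a depleted signature gene scored `absent`. Genes with
#' status `unknown` (or absent from the profile) are excluded from both the
#' numerator and the denominator.
#'
#' @param signature A [signature_set()].
#' @param profile A [candidate_profile()]; every profiled gene must belong to
#'   the signature.
#' @return An object of class `match_score` with counts
#'   `n_enriched_detected`, `n_enriched_scored`, `n_depleted_absent`,
#'   `n_depleted_scored`, `n_concordant`, `n_scored` and the concordance
#'   `fraction` (`NA` when nothing is scored).
#' @export
score_candidate <- function(signature, profile) {
  stopifnot(inherits(signature, "signature_set"),
            inherits(profile, "candidate_profile"))
  status <- profile$status
  stray <- setdiff(names(status), c(signature$enriched, signature$depleted))
  if (length(stray))
    stop("profiled gene(s) not in the signature: ",
         paste(stray, collapse = ", "))
  st_e <- status[names(status) %in% signature$enriched]
  st_d <- status[names(status) %in% signature$depleted]
  n_e_scored <- sum(st_e != "unknown")
  n_d_scored <- sum(st_d != "unknown")
  n_e_det <- sum(st_e == "detected")
  n_d_abs <- sum(st_d == "absent")
  n_scored <- n_e_scored + n_d_scored
  n_conc <- n_e_det + n_d_abs
  structure(list(
    region_name = profile$region_name,
    n_enriched_detected = n_e_det,
    n_enriched_scored = n_e_scored,
    n_depleted_absent = n_d_abs,
    n_depleted_scored = n_d_scored,
    n_concordant = n_conc,
    n_scored = n_scored,
    fraction = if (n_scored == 0L) NA_real_ else n_conc / n_scored
  ), class = "match_score")
}

#' @export
print.match_score <- function(x, ...) {
  cat(sprintf("Region '%s': %d/%d signature genes concordant", x$region_name,
              x$n_concordant, x$n_scored))
  if (!is.na(x$fraction)) cat(sprintf(" (%.1f%%)", 100 * x$fraction))
  cat(sprintf("\n  enriched detected: %d/%d; depleted absent: %d/%d\n",
              x$n_enriched_detected, x$n_enriched_scored,
              x$n_depleted_absent, x$n_depleted_scored))
  invisible(x)
}

#' Rank candidate regions by signature concordance
#'
#' Regions are ordered by descending concordance fraction; ties break by
#' `n_scored` (more evidence first), then region name; regions with an
#' undefined fraction come last.
#'
#' @param signature A [signature_set()].
#' @param profiles List of [candidate_profile()] objects with unique region
#'   names.
#' @return Data frame, one row per region, with all [score_candidate()]
#'   fields, best region first.
#' @export
rank_candidates <- function(signature, profiles) {
  if (inherits(profiles, "candidate_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("need at least one profile")
  regions <- vapply(profiles, function(p) p$region_name, character(1))
  if (anyDuplicated(regions))
    stop("duplicate region name(s): ",
         paste(unique(regions[duplicated(regions)]), collapse = ", "))
  scores <- lapply(profiles, function(p) score_candidate(signature, p))
  tbl <- do.call(rbind, lapply(scores, function(s)
    data.frame(region_name = s$region_name,
               n_enriched_detected = s$n_enriched_detected,
               n_enriched_scored = s$n_enriched_scored,
               n_depleted_absent = s$n_depleted_absent,
               n_depleted_scored = s$n_depleted_scored,
               n_concordant = s$n_concordant,
               n_scored = s$n_scored,
               fraction = s$fraction,
               stringsAsFactors = FALSE)))
  ord <- order(is.na(tbl$fraction),
               -ifelse(is.na(tbl$fraction), 0, tbl$fraction),
               -tbl$n_scored,
               tbl$region_name)
  tbl <- tbl[ord, , drop = FALSE]
  rownames(tbl) <- NULL
  tbl
}
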