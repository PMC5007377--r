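#' Default Boolean combination of the six comparisons
#'
#' Requires enrichment (or depletion) in the early node vs streak, persistence
#' in at least one of the other node comparisons, the ventral neural tube, and
#' at least one limb stage. The literal-precedence alternative reading
#' `"(C1 AND C3) OR C2"` for the node block can be supplied via
#' `expression_text` in [orgscreen_config()].
#'
#' @return The default expression text.
#' @export
default_expression_text <- function() {
  "(C1 AND (C2 OR C3)) AND C4 AND (C5 OR C6)"
}

#' Pipeline configuration
#'
#' Collects the comparisons, the Boolean combination, and the significance
#' thresholds used by the screen.
#'
#' @param comparisons Data frame with `name`, `group_a`, `group_b`
#'   (default: [default_comparisons()]).
#' @param expression_text Boolean algebra over comparison names
#'   (default: [default_expression_text()]).
#' @param lfc_threshold Fold-change threshold; on the `"log2"` scale this is
#'   the minimum |log2 fold change| (default 1.2). With `fc_scale = "linear"`
#'   it is a linear fold change and the effective cutoff is `log2(lfc_threshold)`.
#' @param fdr_threshold FDR significance level alpha in (0, 1] (default 0.05).
#' @param fc_scale Either `"log2"` (default) or `"linear"`; see `lfc_threshold`.
#' @param patchy_as_positive Whether explants scored "patchy" count as positive
#'   in assay tabulations (default `FALSE`).
#' @param already_log2 Whether expression files are already on the log2 scale
#'   (default `TRUE`); when `FALSE`, [organizer_screen()] log2-transforms.
#' @param seed Integer seed recorded in the configuration (default 1).
#' @return An object of class `orgscreen_config`.
#' @export
orgscreen_config <- function(comparisons = default_comparisons(),
                             expression_text = default_expression_text(),
                             lfc_threshold = 1.2,
                             fdr_threshold = 0.05,
                             fc_scale = c("log2", "linear"),
                             patchy_as_positive = FALSE,
                             already_log2 = TRUE,
                             seed = 1L) {
  comparisons <- validate_comparisons(comparisons)
  fc_scale <- match.arg(fc_scale)
  if (!is.numeric(lfc_threshold) || length(lfc_threshold) != 1L ||
      !is.finite(lfc_threshold) || lfc_threshold <= 0)
    stop("lfc_threshold must be a positive number")
  if (fc_scale == "linear" && lfc_threshold <= 1)
    stop("a linear fold-change threshold must exceed 1")
  if (!is.numeric(fdr_threshold) || length(fdr_threshold) != 1L ||
      !is.finite(fdr_threshold) || fdr_threshold <= 0 || fdr_threshold > 1)
    stop("fdr_threshold must lie in (0, 1]")
  expr <- parse_expression(expression_text)
  bad <- setdiff(expr_leaves(expr), comparisons$name)
  if (length(bad))
    stop("config error: unknown comparison name(s) in expression: ",
         paste(bad, collapse = ", "),
         "; valid names: ", paste(comparisons$name, collapse = ", "))
  structure(list(
    comparisons = comparisons,
    expression_text = format(expr),
    expression = expr,
    lfc_threshold = lfc_threshold,
    fdr_threshold = fdr_threshold,
    fc_scale = fc_scale,
    patchy_as_positive = isTRUE(patchy_as_positive),
    already_log2 = isTRUE(already_log2),
    seed = as.integer(seed)
  ), class = "orgscreen_config")
}

# effective |log2FC| cutoff implied by the configured scale
lfc_cutoff <- function(config) {
  if (config$fc_scale == "linear") log2(config$lfc_threshold) else config$lfc_threshold
}

#' @export
print.orgscreen_config <- function(x, ...) {
  cat("Organizer screen configuration\n")
  cat(sprintf("  %d comparisons: %s\n", nrow(x$comparisons),
              paste(x$comparisons$name, collapse = ", ")))
  cat("  expression:", x$expression_text, "\n")
  cat(sprintf("  |log2FC| >= %.4g (%s scale), FDR <= %g\n",
              lfc_cutoff(x), x$fc_scale, x$fdr_threshold))
  invisible(x)
}

#' Load a pipeline configuration from YAML
#'
#' Any key omitted from the file falls back to the default in
#' [orgscreen_config()]; an empty or absent file yields the default
#' configuration (six comparisons, the default expression, threshold 1.2 log2,
#' FDR 0.05).
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return An `orgscreen_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(orgscreen_config())
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("comparisons", "expression_text", "lfc_threshold", "fdr_threshold",
             "fc_scale", "patchy_as_positive", "already_log2", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- raw[intersect(names(raw), known)]
  if (!is.null(args$comparisons)) {
    cmp <- args$comparisons
    if (is.data.frame(cmp)) {
      args$comparisons <- cmp
    } else {
      args$comparisons <- do.call(rbind, lapply(cmp, function(ci)
        data.frame(name = ci$name, group_a = ci$group_a, group_b = ci$group_b,
                   stringsAsFactors = FALSE)))
    }
  }
  do.call(orgscreen_config, args)
}

#' Write a pipeline configuration to YAML
#'
#' The dump round-trips: loading the written file reproduces the
#' configuration field for field.
#'
#' @param config An `orgscreen_config`.
#' @param path Output path.
#' @return `config`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "orgscreen_config"))
  out <- list(
    comparisons = lapply(seq_len(nrow(config$comparisons)), function(i)
      as.list(config$comparisons[i, c("name", "group_a", "group_b")])),
    expression_text = config$expression_text,
    lfc_threshold = config$lfc_threshold,
    fdr_threshold = config$fdr_threshold,
    fc_scale = config$fc_scale,
    patchy_as_positive = config$patchy_as_positive,
    already_log2 = config$already_log2,
    seed = config$seed
  )
  yaml::write_yaml(out, path)
  invisible(config)
}
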