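#' Construct a synexpression signature set
#'
#' @param enriched,depleted Character vectors of gene ids (input order is
#'   preserved).
#' @param expression_text Optional provenance: the Boolean expression that
#'   produced the set.
#' @return An object of class `signature_set`.
#' @export
signature_set <- function(enriched, depleted, expression_text = NA_character_) {
  enriched <- as.character(enriched)
  depleted <- as.character(depleted)
  if (anyDuplicated(enriched) || anyDuplicated(depleted))
    stop("gene ids within a direction must be unique")
  overlap <- intersect(enriched, depleted)
  if (length(overlap))
    warning("gene(s) in both the enriched and depleted set: ",
            paste(overlap, collapse = ", "))
  structure(list(enriched = enriched, depleted = depleted,
                 expression_text = expression_text),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("Synexpression signature: %d enriched, %d depleted\n",
              length(x$enriched), length(x$depleted)))
  if (!is.na(x$expression_text))
    cat("  expression:", x$expression_text, "\n")
  invisible(x)
}

#' Derive the signature from per-comparison calls
#'
#' Applies the Boolean expression gene by gene, once in the enriched and once
#' in the depleted direction. Genes must carry a call in every comparison;
#' a gene present in one table but missing from another is a consistency
#' error (calls are not imputed).
#'
#' @param calls Either a character matrix (genes x comparisons, rownames =
#'   gene ids, entries in `{"enriched","depleted","ns"}`) or a named list of
#'   per-comparison data frames with columns `gene_id` and `call`.
#' @param expr A `bool_expr` (or expression text, parsed on the fly).
#' @return A [signature_set()] with provenance set to the canonical
#'   expression text.
#' @export
derive_signature <- function(calls, expr) {
  if (is.character(expr)) expr <- parse_expression(expr)
  stopifnot(inherits(expr, "bool_expr"))
  if (is.list(calls) && !is.data.frame(calls) && !is.matrix(calls)) {
    if (is.null(names(calls)) || any(names(calls) == ""))
      stop("the list of call tables must be named by comparison")
    ref <- calls[[1L]]$gene_id
    for (nm in names(calls)) {
      tbl <- calls[[nm]]
      if (!all(c("gene_id", "call") %in% names(tbl)))
        stop("call table '", nm, "' needs columns gene_id and call")
      if (!identical(sort(tbl$gene_id), sort(ref)))
        stop("consistency error: gene sets differ between call tables ('",
             names(calls)[1L], "' vs '", nm, "')")
    }
    mat <- vapply(calls, function(tbl) tbl$call[match(ref, tbl$gene_id)],
                  character(length(ref)))
    mat <- matrix(mat, nrow = length(ref),
                  dimnames = list(ref, names(calls)))
    calls <- mat
  }
  if (!is.matrix(calls) || is.null(rownames(calls)))
    stop("calls must be a genes x comparisons matrix with gene id rownames")
  enr <- eval_expr_matrix(expr, calls, "enriched")
  dep <- eval_expr_matrix(expr, calls, "depleted")
  signature_set(rownames(calls)[enr], rownames(calls)[dep],
                expression_text = format(expr))
}

#' Recovery of a planted signature
#'
#' Confusion summary of a derived signature against simulation ground truth.
#' Sensitivities are fractions of planted genes recovered in the correct
#' direction; `set_fdr` is the fraction of reported genes that were not
#' planted in the reported direction. Undefined ratios (zero denominators)
#' are `NA`, not 0.
#'
#' @param signature A [signature_set()].
#' @param truth Data frame with columns `gene_id` and `class` (values
#'   `planted_enriched`, `planted_depleted`, `decoy`, `null`), covering the
#'   same gene universe.
#' @return An object of class `recovery_report`.
#' @export
recovery_metrics <- function(signature, truth) {
  stopifnot(inherits(signature, "signature_set"),
            is.data.frame(truth),
            all(c("gene_id", "class") %in% names(truth)))
  outside <- setdiff(c(signature$enriched, signature$depleted), truth$gene_id)
  if (length(outside))
    stop("signature gene(s) not in the truth table: ",
         paste(outside, collapse = ", "))
  planted_e <- truth$gene_id[truth$class == "planted_enriched"]
  planted_d <- truth$gene_id[truth$class == "planted_depleted"]
  tp_e <- length(intersect(signature$enriched, planted_e))
  tp_d <- length(intersect(signature$depleted, planted_d))
  fp_e <- length(signature$enriched) - tp_e
  fp_d <- length(signature$depleted) - tp_d
  n_reported <- length(signature$enriched) + length(signature$depleted)
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    sensitivity_enriched = frac(tp_e, length(planted_e)),
    sensitivity_depleted = frac(tp_d, length(planted_d)),
    set_fdr = frac(fp_e + fp_d, n_reported),
    n_planted_enriched = length(planted_e),
    n_planted_depleted = length(planted_d),
    tp_enriched = tp_e, fn_enriched = length(planted_e) - tp_e, fp_enriched = fp_e,
    tp_depleted = tp_d, fn_depleted = length(planted_d) - tp_d, fp_depleted = fp_d,
    n_reported = n_reported,
    n_genes = nrow(truth)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Signature recovery\n")
  cat(sprintf("  sensitivity (enriched): %s  [%d/%d]\n",
              format(x$sensitivity_enriched), x$tp_enriched, x$n_planted_enriched))
  cat(sprintf("  sensitivity (depleted): %s  [%d/%d]\n",
              format(x$sensitivity_depleted), x$tp_depleted, x$n_planted_depleted))
  cat(sprintf("  set FDR: %s  [%d false of %d reported]\n",
              format(x$set_fdr), x$fp_enriched + x$fp_depleted, x$n_reported))
  invisible(x)
}

#' Write a signature set to JSON
#'
#' @param signature A [signature_set()].
#' @param path Output path.
#' @param thresholds Optional named list recorded alongside the gene lists.
#' @return `signature`, invisibly.
#' @export
write_signature <- function(signature, path, thresholds = NULL) {
  stopifnot(inherits(signature, "signature_set"))
  out <- list(enriched = signature$enriched,
              depleted = signature$depleted,
              expression = signature$expression_text)
  if (!is.null(thresholds)) out$thresholds <- thresholds
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(signature)
}

#' Read a signature set from JSON
#'
#' @param path Path to a JSON file written by [write_signature()].
#' @return A [signature_set()].
#' @export
read_signature <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  signature_set(raw$enriched, raw$depleted,
                expression_text = if (is.null(raw$expression)) NA_character_
                                  else raw$expression)
}
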