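#' Tissue groups of the default screen design
#'
#' The nine tissues of the three-organizer screen: early and late Hensen's
#' node and posterior primitive streak (gastrula organizer), ventral vs dorsal
#' neural tube (notochord/floor-plate organizer), and posterior vs anterior
#' limb bud at two stages (ZPA).
#'
#' @return Character vector of the nine group labels.
#' @export
organizer_groups <- function() {
  c("HH4 HN", "HH6 HN", "HH4 PS", "VNT", "DNT",
    "HH20 PL", "HH20 AL", "HH24 PL", "HH24 AL")
}

#' Default sample sheet: nine tissues in triplicate
#'
#' Builds the 27-sample design of the screen (9 tissue groups, each with
#' `n_replicates` arrays).
#'
#' @param n_replicates Replicates per tissue group (default 3).
#' @return A data frame with columns `sample_id`, `group`, `replicate`.
#' @export
default_sample_sheet <- function(n_replicates = 3L) {
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 2L)
    stop("n_replicates must be >= 2 (within-group variance must be estimable)")
  groups <- organizer_groups()
  sheet <- data.frame(
    sample_id = paste0(rep(gsub(" ", "_", groups), each = n_replicates),
                       "_r", rep(seq_len(n_replicates), times = length(groups))),
    group = rep(groups, each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = length(groups)),
    stringsAsFactors = FALSE
  )
  validate_sample_sheet(sheet)
}

#' Validate a sample sheet
#'
#' Checks the invariants of the study design: required columns, unique sample
#' identifiers, positive integer replicate numbers, and at least two samples
#' per group so that a within-group variance exists.
#'
#' @param sheet Data frame with columns `sample_id`, `group`, `replicate`.
#' @return The validated sheet (invisibly usable in pipelines).
#' @export
validate_sample_sheet <- function(sheet) {
  if (!is.data.frame(sheet))
    stop("sample sheet must be a data frame")
  need <- c("sample_id", "group", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$group <- as.character(sheet$group)
  sheet$replicate <- as.integer(sheet$replicate)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", "))
  if (any(is.na(sheet$replicate)) || any(sheet$replicate < 1L))
    stop("replicate must be a positive integer")
  tab <- table(sheet$group)
  small <- names(tab)[tab < 2L]
  if (length(small))
    stop("every group needs >= 2 samples; offending group(s): ",
         paste(small, collapse = ", "))
  sheet
}

#' The six organizer-vs-neighbour comparisons
#'
#' Each comparison lists the putative organizer tissue first (`group_a`), so
#' that "enriched" always means higher in the organizer side:
#' C1 = HH4 HN vs HH4 PS, C2 = HH6 HN vs HH4 PS, C3 = HH4 HN vs HH6 HN,
#' C4 = VNT vs DNT, C5 = HH20 PL vs HH20 AL, C6 = HH24 PL vs HH24 AL.
#'
#' @return Data frame with columns `name`, `group_a`, `group_b`.
#' @export
default_comparisons <- function() {
  data.frame(
    name    = paste0("C", 1:6),
    group_a = c("HH4 HN", "HH6 HN", "HH4 HN", "VNT", "HH20 PL", "HH24 PL"),
    group_b = c("HH4 PS", "HH4 PS", "HH6 HN", "DNT", "HH20 AL", "HH24 AL"),
    stringsAsFactors = FALSE
  )
}

validate_comparisons <- function(comparisons, sheet = NULL) {
  if (!is.data.frame(comparisons))
    stop("comparisons must be a data frame")
  need <- c("name", "group_a", "group_b")
  miss <- setdiff(need, names(comparisons))
  if (length(miss))
    stop("comparisons are missing column(s): ", paste(miss, collapse = ", "))
  comparisons[need] <- lapply(comparisons[need], as.character)
  if (anyDuplicated(comparisons$name))
    stop("comparison names must be unique")
  same <- comparisons$group_a == comparisons$group_b
  if (any(same))
    stop("group_a must differ from group_b in comparison(s): ",
         paste(comparisons$name[same], collapse = ", "))
  if (!is.null(sheet)) {
    known <- unique(sheet$group)
    bad <- setdiff(unique(c(comparisons$group_a, comparisons$group_b)), known)
    if (length(bad))
      stop("comparison group(s) absent from the sample sheet: ",
           paste(bad, collapse = ", "))
  }
  comparisons
}

#' Construct an expression matrix object
#'
#' Bundles a genes-by-samples numeric matrix (log2 scale) with its sample
#' sheet. Columns are reordered to follow the sheet. Gene identifiers are
#' opaque strings at probe-set resolution; no probe-to-gene collapsing is
#' performed.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param sheet Sample sheet data frame (see [validate_sample_sheet()]).
#' @return An object of class `expr_matrix` with elements `values` and `sheet`.
#' @export
expression_matrix <- function(values, sheet) {
  sheet <- validate_sample_sheet(sheet)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  gid <- rownames(values)
  if (is.null(gid) || any(is.na(gid)) || any(gid == ""))
    stop("values must have non-missing gene ids as rownames")
  if (anyDuplicated(gid))
    stop("duplicate gene id(s): ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  sid <- colnames(values)
  if (is.null(sid))
    stop("values must have sample ids as colnames")
  missing_in_matrix <- setdiff(sheet$sample_id, sid)
  if (length(missing_in_matrix))
    stop("design error: sample(s) in sheet absent from the matrix: ",
         paste(missing_in_matrix, collapse = ", "))
  extra <- setdiff(sid, sheet$sample_id)
  if (length(extra))
    stop("design error: matrix column(s) absent from the sheet: ",
         paste(extra, collapse = ", "))
  values <- values[, sheet$sample_id, drop = FALSE]
  structure(list(values = values, sheet = sheet), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%d groups)\n",
              nrow(x$values), ncol(x$values), length(unique(x$sheet$group))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its sample sheet from TSV
#'
#' The matrix file is tab-separated with a header row of sample ids whose
#' first cell is literally `gene_id`, and one row per gene. The sheet has
#' columns `sample_id`, `group`, `replicate`. Files use UTF-8, "." decimals
#' and no quoting.
#'
#' @param matrix_path Path to the expression TSV.
#' @param sheet_path Path to the sample sheet TSV.
#' @return An [expression_matrix()] with columns ordered as in the sheet.
#' @export
read_expression <- function(matrix_path, sheet_path) {
  sheet <- utils::read.delim(sheet_path, check.names = FALSE,
                             stringsAsFactors = FALSE, quote = "")
  sheet <- validate_sample_sheet(sheet)
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2L || names(raw)[1L] != "gene_id")
    stop("parse error: first header cell must be 'gene_id'")
  gid <- raw[[1L]]
  if (anyDuplicated(gid))
    stop("duplicate gene id(s): ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw) - 1L,
                 dimnames = list(gid, names(raw)[-1L]))
  for (j in seq_len(ncol(raw) - 1L)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("parse error: non-numeric value '%s' at row %d (gene '%s'), column '%s'",
                   col[bad[1L]], bad[1L], gid[bad[1L]], names(raw)[j + 1L]))
    vals[, j] <- num
  }
  expression_matrix(vals, sheet)
}

#' Write an expression matrix and sample sheet to TSV
#'
#' Values are serialized with 17 significant digits so that a write/read
#' round trip reproduces the doubles bit-for-bit.
#'
#' @param x An [expression_matrix()].
#' @param matrix_path,sheet_path Output paths.
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, matrix_path, sheet_path) {
  stopifnot(inherits(x, "expr_matrix"))
  vals <- x$values
  txt <- matrix(sprintf("%.17g", vals), nrow = nrow(vals))
  lines <- c(
    paste(c("gene_id", colnames(vals)), collapse = "\t"),
    vapply(seq_len(nrow(vals)),
           function(i) paste(c(rownames(vals)[i], txt[i, ]), collapse = "\t"),
           character(1))
  )
  writeLines(lines, matrix_path, useBytes = TRUE)
  utils::write.table(x$sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
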