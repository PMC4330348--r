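#' Construct a ratio matrix
#'
#' The central data container: a proteins x samples matrix of H/L
#' enrichment ratios over the pooled mixed reference, with an explicit
#' missingness mask. Present values are strictly positive; zeros only
#' appear after explicit imputation ([impute_zero()]), and the mask
#' keeps track of which entries were measured so downstream statistics
#' can ignore imputed values.
#'
#' @param values Numeric matrix (proteins x samples); `NA` marks missing.
#' @param design A [sample_design()] describing the columns.
#' @param protein_ids Optional character vector of row names (defaults
#'   to existing row names).
#' @return An object of class `ratio_matrix` with fields `values`
#'   (missing entries `NA` until imputation), `mask` (logical, TRUE =
#'   measured), `design`, and `imputed` (logical flag).
#' @export
ratio_matrix <- function(values, design, protein_ids = rownames(values)) {
  values <- as.matrix(values)
  if (ncol(values) != n_samples(design))
    stop("ratio matrix has ", ncol(values), " columns but the design ",
         "requires ", n_samples(design))
  if (is.null(protein_ids))
    protein_ids <- paste0("P", seq_len(nrow(values)))
  if (anyDuplicated(protein_ids)) stop("duplicate protein ids")
  rownames(values) <- protein_ids
  colnames(values) <- sample_names(design)
  present <- !is.na(values)
  if (any(values[present] < 0))
    stop("H/L ratios must be nonnegative")
  structure(
    list(values = values, mask = present, design = design, imputed = FALSE),
    class = "ratio_matrix"
  )
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat("ratio_matrix:", nrow(x$values), "proteins x", ncol(x$values),
      "samples;", sum(!x$mask), "missing entries",
      if (x$imputed) "(zero-imputed)" else "", "\n")
  invisible(x)
}

#' @export
dim.ratio_matrix <- function(x) dim(x$values)

n_missing_per_protein <- function(rm) rowSums(!rm$mask)

#' Replace missing ratios by zero
#'
#' Zero imputation ahead of correlation networking: every missing entry
#' becomes 0 while the missingness mask is retained, so enrichment
#' statistics can still be computed over measured values only.
#'
#' @param matrix A `ratio_matrix`.
#' @return The matrix with `NA` entries set to 0 and `imputed = TRUE`.
#' @export
impute_zero <- function(matrix) {
  stopifnot(inherits(matrix, "ratio_matrix"))
  matrix$values[!matrix$mask] <- 0
  matrix$imputed <- TRUE
  matrix
}

#' Filter proteins by missingness
#'
#' Retains proteins with at most `max_missing` missing entries; under
#' the default 18-sample design the default of 14 keeps exactly the
#' proteins quantified in at least 4 of 18 samples.
#'
#' @param matrix A `ratio_matrix`.
#' @param max_missing Maximum tolerated number of missing entries per
#'   protein (must be < number of samples).
#' @return The filtered `ratio_matrix`.
#' @export
filter_missingness <- function(matrix, max_missing = 14L) {
  stopifnot(inherits(matrix, "ratio_matrix"))
  total <- ncol(matrix$values)
  if (max_missing >= total)
    stop("'max_missing' (", max_missing, ") must be smaller than the ",
         "number of samples (", total, ")")
  keep <- n_missing_per_protein(matrix) <= max_missing
  matrix$values <- matrix$values[keep, , drop = FALSE]
  matrix$mask <- matrix$mask[keep, , drop = FALSE]
  matrix
}

#' Serialize a ratio matrix to TSV
#' @param matrix A `ratio_matrix`.
#' @param path Output file; missing entries are written as empty fields.
#' @export
write_ratio_matrix <- function(matrix, path) {
  df <- data.frame(ProteinID = rownames(matrix$values),
                   matrix$values, check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}
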