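#' Read a protein-groups ratio table
#'
#' Parses a tab-separated protein-groups table (one row per protein
#' group) with `Ratio H/L <sample>` and `Ratio H/L count <sample>`
#' columns for every sample of the design, plus `ProteinID`,
#' `GeneName`, `Contaminant` and `Reverse` flag columns. Empty, `NaN`
#' and zero ratio cells become missing (true H/L ratios are strictly
#' positive).
#'
#' @param path Path to the table.
#' @param design A [sample_design()] naming the expected samples.
#' @return An object of class `protein_groups`: list with `table`
#'   (data.frame), `ratios` and `counts` (matrices, proteins x
#'   samples), and `design`.
#' @export
read_protein_groups <- function(path, design) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- read_tsv(path)
  required <- c("ProteinID", "GeneName", "Contaminant", "Reverse")
  snames <- sample_names(design)
  ratio_cols <- paste0("Ratio H/L ", snames)
  count_cols <- paste0("Ratio H/L count ", snames)
  absent <- setdiff(c(required, ratio_cols, count_cols), names(df))
  if (length(absent))
    stop("missing required column(s): ", paste(absent, collapse = ", "))
  if (anyDuplicated(df$ProteinID))
    stop("duplicate ProteinID value(s): ",
         paste(unique(df$ProteinID[duplicated(df$ProteinID)]), collapse = ", "))
  ratios <- as.matrix(df[ratio_cols])
  mode(ratios) <- "numeric"
  ratios[!is.finite(ratios) | ratios == 0] <- NA_real_
  counts <- as.matrix(df[count_cols])
  mode(counts) <- "numeric"
  counts[is.na(counts)] <- 0
  dimnames(ratios) <- dimnames(counts) <- list(df$ProteinID, snames)
  structure(
    list(table = df[required], ratios = ratios, counts = counts,
         design = design),
    class = "protein_groups"
  )
}

#' @export
print.protein_groups <- function(x, ...) {
  cat("protein_groups:", nrow(x$ratios), "protein groups x",
      ncol(x$ratios), "samples\n")
  invisible(x)
}

flag_positive <- function(x) {
  !is.na(x) & trimws(as.character(x)) %in% c("+", "TRUE", "true", "1", "yes")
}

#' Apply contaminant/decoy and ratio-count quality filters
#'
#' Drops rows flagged as common contaminants or reverse-database
#' (decoy) identifications; masks any ratio backed by fewer than
#' `min_ratio_count` redundant peptides; then drops rows left with no
#' measured ratio at all.
#'
#' @param table A `protein_groups` object.
#' @param min_ratio_count Minimum redundant peptide count per
#'   quantified ratio (default 2).
#' @return The filtered `protein_groups` object.
#' @export
filter_quality <- function(table, min_ratio_count = 2L) {
  stopifnot(inherits(table, "protein_groups"))
  keep <- !(flag_positive(table$table$Contaminant) |
              flag_positive(table$table$Reverse))
  table$table <- table$table[keep, , drop = FALSE]
  table$ratios <- table$ratios[keep, , drop = FALSE]
  table$counts <- table$counts[keep, , drop = FALSE]
  low <- table$counts < min_ratio_count
  table$ratios[low] <- NA_real_
  nonempty <- rowSums(!is.na(table$ratios)) > 0
  table$table <- table$table[nonempty, , drop = FALSE]
  table$ratios <- table$ratios[nonempty, , drop = FALSE]
  table$counts <- table$counts[nonempty, , drop = FALSE]
  table
}

#' Convert a filtered protein-groups table to a ratio matrix
#' @param table A `protein_groups` object.
#' @return A [ratio_matrix()].
#' @export
as_ratio_matrix <- function(table) {
  stopifnot(inherits(table, "protein_groups"))
  ratio_matrix(table$ratios, table$design,
               protein_ids = rownames(table$ratios))
}
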