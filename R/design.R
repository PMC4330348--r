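#' Default pulldown conditions
#'
#' The nine capture conditions of the histone H3 tail pulldown design:
#' two unmodified peptides (residues 1-20 and 18-38), the K9/K27
#' trimethyl and S10/S28 phospho marks singly and combined, plus the
#' beads-only negative control.
#'
#' @format Character vector of length 9.
#' @export
DEFAULT_CONDITIONS <- c(
  "H3_1-20_unmod", "H3K9me3", "H3S10ph", "H3K9me3S10ph",
  "H3_18-38_unmod", "H3K27me3", "H3S28ph", "H3K27me3S28ph",
  "beads"
)

#' Describe the sample layout of a pulldown experiment
#'
#' A sample design is the ordered set of pulldown conditions, the number
#' of replicates per condition and the name of the beads-only negative
#' control. Samples are laid out condition-major within replicate
#' (`<condition>_rep<k>` for replicate k), giving
#' `length(conditions) * replicates` columns.
#'
#' @param conditions Ordered character vector of unique condition names.
#' @param replicates Positive integer, replicates per condition.
#' @param beads_condition Name of the negative-control condition; must be
#'   one of `conditions`.
#' @return An object of class `sample_design`.
#' @examples
#' d <- sample_design()
#' n_samples(d)   # 18
#' @export
sample_design <- function(conditions = DEFAULT_CONDITIONS,
                          replicates = 2L,
                          beads_condition = "beads") {
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions))
    stop("condition names must be unique")
  replicates <- as.integer(replicates)
  if (length(replicates) != 1L || is.na(replicates) || replicates < 1L)
    stop("'replicates' must be a single positive integer")
  if (!beads_condition %in% conditions)
    stop("'beads_condition' (", beads_condition, ") is not among the conditions")
  structure(
    list(conditions = conditions,
         replicates = replicates,
         beads_condition = beads_condition),
    class = "sample_design"
  )
}

#' @export
print.sample_design <- function(x, ...) {
  cat("Sample design:", length(x$conditions), "conditions x",
      x$replicates, "replicates =", n_samples(x), "samples\n")
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("  negative control:", x$beads_condition, "\n")
  invisible(x)
}

#' Number of samples in a design
#' @param design A `sample_design`.
#' @return Integer, `length(conditions) * replicates`.
#' @export
n_samples <- function(design) {
  length(design$conditions) * design$replicates
}

#' Sample (column) names of a design
#'
#' Condition-major within replicate: all conditions of replicate 1, then
#' replicate 2, and so on. This is the canonical column order used by
#' every matrix in the pipeline.
#'
#' @param design A `sample_design`.
#' @return Character vector of `n_samples(design)` names.
#' @export
sample_names <- function(design) {
  as.vector(vapply(
    seq_len(design$replicates),
    function(r) paste0(design$conditions, "_rep", r),
    character(length(design$conditions))
  ))
}

#' Map sample columns to (condition, replicate)
#' @param design A `sample_design`.
#' @return Data frame with columns `sample`, `condition`, `replicate`.
#' @export
sample_layout <- function(design) {
  data.frame(
    sample = sample_names(design),
    condition = rep(design$conditions, times = design$replicates),
    replicate = rep(seq_len(design$replicates),
                    each = length(design$conditions)),
    stringsAsFactors = FALSE
  )
}
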