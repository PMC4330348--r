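#' Replicate-mean log2 enrichment over beads
#'
#' For every protein and condition: the mean H/L ratio over the
#' replicates in which it was measured (missing values ignored; missing
#' if none), log2-transformed, minus the protein's beads-only log2
#' value. Proteins without a beads measurement get all-missing
#' enrichments. The beads condition itself is excluded from the output
#' columns.
#'
#' @param matrix An un-imputed [ratio_matrix()] (the missingness mask
#'   is required; imputed zeros would corrupt the means).
#' @return An object of class `enrichment_input`: list with `d`
#'   (proteins x specific-conditions matrix of log2 enrichments, `NA`
#'   where undefined), `conditions`, `design`.
#' @export
replicate_mean_log_enrichment <- function(matrix) {
  stopifnot(inherits(matrix, "ratio_matrix"))
  if (matrix$imputed)
    stop("enrichment means must be computed before zero imputation")
  design <- matrix$design
  layout <- sample_layout(design)
  conds <- design$conditions
  vals <- matrix$values
  means <- sapply(conds, function(cc) {
    cols <- which(layout$condition == cc)
    rowMeans(vals[, cols, drop = FALSE], na.rm = TRUE)
  })
  means[is.nan(means)] <- NA_real_
  if (any(means <= 0, na.rm = TRUE))
    stop("nonpositive replicate-mean ratio encountered")
  lg <- log2(means)
  specific <- setdiff(conds, design$beads_condition)
  d <- lg[, specific, drop = FALSE] - lg[, design$beads_condition]
  rownames(d) <- rownames(vals)
  structure(list(d = d, conditions = specific, design = design),
            class = "enrichment_input")
}

#' Module-versus-beads paired t-test
#'
#' For each module and specific pulldown condition, a classic paired
#' two-tailed t-test of whether the module members' binding exceeds the
#' beads-only control: the paired differences are the per-protein log2
#' enrichments d (specific minus beads), so `t = mean(d) / (sd(d) /
#' sqrt(n))` with `df = n - 1` and a two-tailed p from the t
#' distribution.
#'
#' @param enrich An `enrichment_input` (or a bare proteins x conditions
#'   matrix of paired differences).
#' @param assignment A `module_assignment`.
#' @return Data frame with columns `module`, `condition`,
#'   `t_statistic`, `df`, `p_value`, `n_pairs`, `flag` ("" normally;
#'   "degenerate_variance" when sd = 0 with nonzero mean, in which case
#'   p = 0; "insufficient_pairs" when n < 2, in which case the test is
#'   undefined).
#' @export
module_enrichment_ttest <- function(enrich, assignment) {
  d <- if (inherits(enrich, "enrichment_input")) enrich$d else as.matrix(enrich)
  mods <- setdiff(unique(as.character(assignment)), "grey")
  out <- list()
  for (m in mods) {
    members <- intersect(names(assignment)[as.character(assignment) == m],
                         rownames(d))
    for (cc in colnames(d)) {
      diffs <- d[members, cc]
      diffs <- diffs[!is.na(diffs)]
      n <- length(diffs)
      t_stat <- df <- p <- NA_real_
      flag <- ""
      if (n < 2L) {
        flag <- "insufficient_pairs"
      } else {
        s <- stats::sd(diffs)
        mu <- mean(diffs)
        df <- n - 1
        if (s == 0) {
          if (mu == 0) { t_stat <- 0; p <- 1 }
          else { t_stat <- sign(mu) * Inf; p <- 0; flag <- "degenerate_variance" }
        } else {
          t_stat <- mu / (s / sqrt(n))
          p <- 2 * stats::pt(-abs(t_stat), df)
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        module = m, condition = cc, t_statistic = t_stat, df = df,
        p_value = p, n_pairs = n, flag = flag, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-protein outlier z-scores
#'
#' Tests whether a protein's enrichment in a pulldown is an outlier
#' with respect to all proteins in that pulldown, under the null
#' assumption of no enrichment over beads: within each condition,
#' sigma is the sample standard deviation of all defined log2
#' enrichments d, the z-score is `d / sigma` (null mean pinned at 0,
#' i.e. the number of standard deviations above zero), and the p-value
#' is the standard-normal tail probability. The default is the
#' one-sided upper tail (enrichment direction); `two_sided = TRUE`
#' doubles the tail.
#'
#' @param enrich An `enrichment_input`.
#' @param two_sided Use a two-sided normal p-value (default FALSE).
#' @param leave_one_out Exclude each protein from the sigma used for
#'   its own z-score (default FALSE; negligible at typical cohort
#'   sizes).
#' @return List of class `outlier_result` with matrices `z` and `p`
#'   (proteins x conditions) and `sigma` (named per condition; `NA`
#'   flags a degenerate condition whose z-scores are undefined).
#' @export
outlier_zscore <- function(enrich, two_sided = FALSE, leave_one_out = FALSE) {
  stopifnot(inherits(enrich, "enrichment_input"))
  d <- enrich$d
  z <- p <- matrix(NA_real_, nrow(d), ncol(d), dimnames = dimnames(d))
  sigma <- stats::setNames(rep(NA_real_, ncol(d)), colnames(d))
  for (cc in colnames(d)) {
    x <- d[, cc]
    defined <- !is.na(x)
    if (sum(defined) < 3L) next
    s_all <- stats::sd(x[defined])
    if (s_all == 0) next
    sigma[cc] <- s_all
    if (leave_one_out) {
      n <- sum(defined); mu <- mean(x[defined]); ss <- s_all^2 * (n - 1)
      for (i in which(defined)) {
        s_i <- sqrt((ss - (x[i] - mu)^2 * n / (n - 1)) / (n - 2))
        z[i, cc] <- x[i] / s_i
      }
    } else {
      z[defined, cc] <- x[defined] / s_all
    }
    p[, cc] <- stats::pnorm(z[, cc], lower.tail = FALSE)
    if (two_sided) p[, cc] <- 2 * stats::pnorm(-abs(z[, cc]))
  }
  structure(list(z = z, p = p, sigma = sigma), class = "outlier_result")
}

#' Multiple-testing adjustment
#'
#' Default "none" (matching the published raw p-values); optional
#' Benjamini-Hochberg step-up.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param method "none" or "benjamini_hochberg".
#' @return Adjusted p-values.
#' @export
adjust_fdr <- function(p_values, method = c("none", "benjamini_hochberg")) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  switch(method,
         none = p_values,
         benjamini_hochberg = stats::p.adjust(p_values, method = "BH"))
}
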