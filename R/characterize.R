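#' Module eigenproteins
#'
#' Summarizes each non-grey module by the first principal component of
#' its members' standardized profiles across samples (the module
#' "eigenprotein"): rows are centred and scaled to unit variance, the
#' first right-singular vector over samples is returned with the
#' fraction of variance it explains. The sign is oriented so the
#' eigenprotein correlates positively with the module's mean
#' standardized profile, giving interpretable binding profiles.
#'
#' @param matrix A zero-imputed [ratio_matrix()].
#' @param assignment A `module_assignment` over its proteins.
#' @return An object of class `eigenproteins`: list with `vectors`
#'   (modules x samples matrix of eigenprotein scores, unit norm) and
#'   `variance_explained` (named numeric in \[0, 1\]).
#' @export
compute_eigenproteins <- function(matrix, assignment) {
  stopifnot(inherits(matrix, "ratio_matrix"))
  mods <- setdiff(unique(as.character(assignment)), "grey")
  mods <- names(sort(table(factor(as.character(assignment), levels = mods)),
                     decreasing = TRUE))
  vec <- matrix(NA_real_, length(mods), ncol(matrix$values),
                dimnames = list(mods, colnames(matrix$values)))
  ve <- stats::setNames(rep(NA_real_, length(mods)), mods)
  for (m in mods) {
    members <- names(assignment)[as.character(assignment) == m]
    x <- matrix$values[members, , drop = FALSE]
    sds <- apply(x, 1L, stats::sd)
    if (any(sds == 0)) {
      warning("module '", m, "': ", sum(sds == 0),
              " zero-variance protein row(s) excluded from the eigenprotein")
      x <- x[sds > 0, , drop = FALSE]
    }
    if (nrow(x) == 0L) next
    xs <- t(scale(t(x)))                     # rows: mean 0, sd 1
    sv <- svd(xs)
    e <- sv$v[, 1]
    if (stats::cor(e, colMeans(xs)) < 0) e <- -e
    vec[m, ] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(vectors = vec, variance_explained = ve),
            class = "eigenproteins")
}

#' @export
print.eigenproteins <- function(x, ...) {
  cat("eigenproteins for", nrow(x$vectors), "modules; variance explained:\n")
  print(round(x$variance_explained, 3))
  invisible(x)
}

#' Intramodular connectivity
#'
#' For every protein: `kWithin_raw`, the sum of its adjacencies to
#' proteins of the same module; `kWithin`, that sum divided by the
#' module's maximum (so each module's strongest hub scores exactly 1);
#' and `kTotal`, the sum of adjacencies to all proteins. Grey proteins
#' carry `NA` kWithin.
#'
#' @param adj Adjacency matrix over the assigned proteins.
#' @param assignment A `module_assignment`.
#' @return Data frame `connectivity_table` with columns `protein`,
#'   `module`, `kWithin_raw`, `kWithin`, `kTotal`.
#' @export
intramodular_connectivity <- function(adj, assignment) {
  ids <- rownames(adj)
  if (is.null(ids)) ids <- names(assignment)
  if (!identical(sort(ids), sort(names(assignment))))
    stop("adjacency and assignment cover different proteins")
  lab <- as.character(assignment[ids])
  k_total <- rowSums(adj)
  k_raw <- rep(NA_real_, length(ids))
  k_norm <- rep(NA_real_, length(ids))
  for (m in setdiff(unique(lab), "grey")) {
    idx <- which(lab == m)
    sub <- adj[idx, idx, drop = FALSE]
    raw <- rowSums(sub)
    k_raw[idx] <- raw
    mx <- max(raw)
    k_norm[idx] <- if (mx > 0) raw / mx else NA_real_
  }
  out <- data.frame(protein = ids, module = lab, kWithin_raw = k_raw,
                    kWithin = k_norm, kTotal = k_total,
                    stringsAsFactors = FALSE)
  class(out) <- c("connectivity_table", class(out))
  out
}

#' Identify module hub proteins
#'
#' Per module, proteins ranked by normalized intramodular connectivity
#' (ties broken by total connectivity, then protein id) with the top
#' `top_n` returned; the top hub of each module has kWithin = 1.
#'
#' @param connectivity A `connectivity_table`.
#' @param top_n Hubs per module (clipped to the module size).
#' @return Data frame with columns `module`, `rank`, `protein`,
#'   `kWithin`, `kTotal`.
#' @export
identify_hubs <- function(connectivity, top_n = 1L) {
  stopifnot(inherits(connectivity, "connectivity_table"))
  non_grey <- connectivity[connectivity$module != "grey", , drop = FALSE]
  res <- lapply(split(non_grey, non_grey$module), function(d) {
    ord <- order(-d$kWithin, -d$kTotal, d$protein)
    d <- d[ord[seq_len(min(top_n, nrow(d)))], , drop = FALSE]
    data.frame(module = d$module, rank = seq_len(nrow(d)),
               protein = d$protein, kWithin = d$kWithin,
               kTotal = d$kTotal, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
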