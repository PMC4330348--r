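# Independent brute-force oracles and small fixture builders used
# across the suite.

# O(n^3) triple-loop topological overlap, straight from the formula.
tom_oracle <- function(adj) {
  n <- nrow(adj)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
    ki <- sum(adj[i, -i])
    kj <- sum(adj[j, -j])
    out[i, j] <- (l + adj[i, j]) / (min(ki, kj) + 1 - adj[i, j])
  }
  out
}

# Two-pass covariance/variance Pearson correlation.
cor_oracle <- function(x) {
  n <- nrow(x)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- x[i, ] - mean(x[i, ])
    b <- x[j, ] - mean(x[j, ])
    out[i, j] <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  out
}

# Naive agglomerative average-linkage clustering; returns sorted merge
# heights (enough to check against hclust without matching its node
# bookkeeping).
average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_len(length(clusters) - 1L))
      for (j in seq.int(i + 1L, length(clusters))) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Random symmetric adjacency in [0, 1] with zero diagonal.
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# A block-structured TOM: within-block overlap `hi`, between `lo`.
block_tom <- function(sizes, hi = 0.95, lo = 0.02) {
  n <- sum(sizes)
  tom <- matrix(lo, n, n)
  at <- 0
  for (s in sizes) {
    idx <- at + seq_len(s)
    tom[idx, idx] <- hi
    at <- at + s
  }
  diag(tom) <- 1
  dimnames(tom) <- list(paste0("P", 1:n), paste0("P", 1:n))
  tom
}

# Ratio matrix with a given missingness mask (values strictly positive).
masked_ratio_matrix <- function(mask, design) {
  vals <- matrix(stats::runif(length(mask), 0.5, 2), nrow(mask), ncol(mask))
  vals[!mask] <- NA
  ratio_matrix(vals, design, protein_ids = paste0("P", seq_len(nrow(mask))))
}

# Small null (flat-signature) dataset for calibration checks.
null_dataset <- function(n_proteins, seed, noise_cv = 0.2) {
  specs <- list(complex_spec("flat", n_proteins, rep(1, 9)))
  cfg <- generator_config(n_background = 0, noise_cv = noise_cv,
                          apply_missingness = FALSE, seed = seed)
  simulate_dataset(specs = specs, config = cfg)
}

# Best-matching-module Jaccard overlap for one planted complex.
complex_overlap <- function(assignment, truth, complex_id) {
  members <- names(truth)[truth == complex_id]
  mods <- unclass(assignment)[members]
  mods <- mods[mods != "grey"]
  if (!length(mods)) return(0)
  best <- names(sort(table(mods), decreasing = TRUE))[1]
  modset <- names(assignment)[unclass(assignment) == best]
  length(intersect(modset, members)) / length(union(modset, members))
}

# End-to-end network + tree cut from a ratio matrix.
modules_from_ratios <- function(rm, beta = 15, ...) {
  imp <- impute_zero(filter_missingness(rm, 14))
  cor <- suppressWarnings(pairwise_correlation(imp))
  tom <- topological_overlap(signed_adjacency(cor, beta))
  dynamic_tree_cut(cluster_dendrogram(tom), tom = tom, ...)
}
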