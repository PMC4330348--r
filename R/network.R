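#' Pairwise Pearson correlation of protein profiles
#'
#' Correlation between every pair of protein rows across all samples of
#' the zero-imputed ratio matrix (imputed zeros participate, by
#' design: shared absence is signal in a pulldown panel). Constant rows
#' have undefined correlation and are removed with a warning.
#'
#' @param matrix A zero-imputed [ratio_matrix()].
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlation <- function(matrix) {
  stopifnot(inherits(matrix, "ratio_matrix"))
  if (!matrix$imputed)
    stop("pairwise_correlation expects a zero-imputed matrix; call impute_zero()")
  v <- matrix$values
  constant <- apply(v, 1L, stats::sd) == 0
  if (any(constant)) {
    warning(sum(constant), " constant protein row(s) removed ",
            "(correlation undefined): ",
            paste(utils::head(rownames(v)[constant], 5L), collapse = ", "))
    v <- v[!constant, , drop = FALSE]
  }
  cor <- stats::cor(t(v))
  diag(cor) <- 1
  cor
}

#' Signed soft-threshold adjacency
#'
#' Transforms correlations into connection strengths with the signed
#' power adjacency `a_ij = ((1 + cor_ij) / 2) ^ beta`, which maps
#' perfect anticorrelation to 0 and keeps only positive co-binding
#' relationships, as appropriate when complex members bind as a unit.
#' The diagonal is set to 0 so connectivities are sums over partners.
#'
#' @param cor Symmetric correlation matrix.
#' @param beta Soft power threshold (integer >= 1; default 15).
#' @return Adjacency matrix with entries in \[0, 1\] and zero diagonal.
#' @export
signed_adjacency <- function(cor, beta = 15L) {
  if (beta < 1) stop("'beta' must be >= 1")
  adj <- ((1 + cor) / 2)^beta
  diag(adj) <- 0
  adj
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins connectivities into `n_bins` equal-width bins, then regresses
#' log10 bin frequency on log10 mean bin connectivity. The fit index is
#' R-squared signed by the regression slope: a negative slope (the
#' scale-free expectation) gives a positive index.
#'
#' @param k Numeric vector of connectivities.
#' @param n_bins Number of bins (default 10).
#' @return List with `fit` (signed R-squared; `NA` when fewer than 3
#'   nonempty bins), `slope`, and the binned `log_k`/`log_freq` points.
#' @export
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[is.finite(k) & k > 0]
  if (length(unique(k)) < 2L)
    return(list(fit = NA_real_, slope = NA_real_,
                log_k = numeric(), log_freq = numeric()))
  bins <- cut(k, n_bins)
  mean_k <- tapply(k, bins, mean)
  freq <- tapply(k, bins, length) / length(k)
  ok <- !is.na(mean_k) & !is.na(freq)
  if (sum(ok) < 3L)
    return(list(fit = NA_real_, slope = NA_real_,
                log_k = numeric(), log_freq = numeric()))
  x <- log10(mean_k[ok]); y <- log10(freq[ok])
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[["x"]]
  list(fit = -sign(slope) * r2, slope = slope,
       log_k = unname(x), log_freq = unname(y))
}

#' Survey candidate soft powers
#'
#' For each candidate power, builds the signed adjacency, computes the
#' connectivity of every protein and summarizes the scale-free
#' topology fit and mean connectivity. The default pipeline records
#' this table and uses beta = 15.
#'
#' @param matrix A zero-imputed [ratio_matrix()].
#' @param candidates Integer vector of candidate powers.
#' @return Data frame with columns `beta`, `scale_free_fit_R2`
#'   (signed; `NA` when degenerate), `mean_connectivity`.
#' @export
pick_soft_threshold <- function(matrix, candidates = c(1:10, 12, 15, 18, 20)) {
  if (length(candidates) == 0L) stop("'candidates' must be nonempty")
  cor <- pairwise_correlation(matrix)
  out <- lapply(candidates, function(beta) {
    adj <- signed_adjacency(cor, beta)
    k <- rowSums(adj)
    data.frame(beta = beta,
               scale_free_fit_R2 = scale_free_fit(k)$fit,
               mean_connectivity = mean(k))
  })
  do.call(rbind, out)
}

#' Topological overlap matrix
#'
#' The topological overlap of proteins i and j combines their direct
#' connection with the strength of their shared neighbourhood:
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` (u != i, j) and `k_i = sum_u a_iu`.
#' The diagonal is 1.
#'
#' @param adj Adjacency matrix (entries in \[0, 1\], zero diagonal).
#' @return Symmetric TOM with entries in \[0, 1\] and unit diagonal.
#' @export
topological_overlap <- function(adj) {
  if (any(adj < 0) || any(adj > 1)) stop("adjacency entries must be in [0, 1]")
  diag(adj) <- 0
  l <- adj %*% adj          # diag(adj) = 0, so u = i and u = j drop out
  k <- rowSums(adj)
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (l + adj) / denom
  diag(tom) <- 1
  tom
}

#' Hierarchical clustering on topological overlap dissimilarity
#'
#' Average-linkage agglomerative clustering of proteins on the
#' dissimilarity `1 - TOM`.
#'
#' @param tom A topological overlap matrix.
#' @return An [stats::hclust] dendrogram.
#' @export
cluster_dendrogram <- function(tom) {
  d <- stats::as.dist(1 - tom)
  stats::hclust(d, method = "average")
}

# For each internal node of an hclust tree, the set of leaves below it
# and the heights of all merges in its subtree.
tree_tables <- function(dendro) {
  m <- dendro$merge
  n <- nrow(m) + 1L
  leaves <- vector("list", nrow(m))
  subheights <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    lv <- hv <- list()
    for (child in m[i, ]) {
      if (child < 0) {
        lv <- c(lv, list(-child))
      } else {
        lv <- c(lv, list(leaves[[child]]))
        hv <- c(hv, list(subheights[[child]]))
      }
    }
    leaves[[i]] <- unlist(lv)
    subheights[[i]] <- c(unlist(hv), dendro$height[i])
  }
  list(leaves = leaves, subheights = subheights, merge = m,
       height = dendro$height, n = n)
}

#' Cut a dendrogram into modules adaptively
#'
#' Deterministic adaptive branch decomposition. A static cut at
#' `cut_fraction` of the maximum merge height first separates the
#' top-level branches. Each branch is then decomposed recursively: a
#' branch whose merge heights span more than `max_branch_spread` times
#' the maximum tree height is heterogeneous and is split into its two
#' children; a branch whose heights are confined within that band and
#' that coheres below `max_module_height` is a candidate module.
#' When the topological overlap matrix is supplied, a final adoption
#' pass reunites stray fragments with their cluster: every candidate
#' smaller than `min_module_size` joins the candidate branch with the
#' smallest mean topological-overlap dissimilarity, provided that mean
#' lies within the target branch's own mean internal dissimilarity
#' plus the spread tolerance (and below the module height cap), so
#' diffuse background is never adopted. Remaining candidates smaller than
#' `min_module_size` are pooled into the reserved "grey" label.
#' Modules are named by decreasing size from the conventional colour
#' list.
#'
#' @param dendro An [stats::hclust] tree from [cluster_dendrogram()].
#' @param tom Optional topological overlap matrix over the same
#'   proteins (enables the fragment-adoption pass).
#' @param min_module_size Minimum module size (default 5).
#' @param cut_fraction Static cut height as a fraction of the maximum
#'   merge height (default 0.99).
#' @param max_branch_spread Maximum within-module merge-height range,
#'   as a fraction of the maximum merge height (default 0.25).
#' @param max_module_height Maximum height (as a fraction of the
#'   maximum merge height) at which a branch may still be called a
#'   module (default 0.9): homogeneous branches that only cohere near
#'   the top of the tree are diffuse background and are left grey.
#' @param static_cut_height If non-`NULL`, disables the adaptive
#'   decomposition and simply cuts the tree at this absolute height
#'   (small branches still pooled as grey).
#' @return An object of class `module_assignment`: named character
#'   vector of module colours ("grey" = unassigned) with attribute
#'   `sizes`.
#' @export
dynamic_tree_cut <- function(dendro, tom = NULL, min_module_size = 5L,
                             cut_fraction = 0.99,
                             max_branch_spread = 0.25,
                             max_module_height = 0.9,
                             static_cut_height = NULL) {
  if (min_module_size < 1L) stop("'min_module_size' must be >= 1")
  n <- length(dendro$order)
  ids <- dendro$labels %||% as.character(seq_len(n))
  if (n < 2L) {
    labels <- rep("grey", n)
    names(labels) <- ids
    return(finish_assignment(labels, min_module_size))
  }
  # average linkage is monotone, but exact ties can leave fp-level
  # inversions that cutree rejects
  if (is.unsorted(dendro$height)) {
    if (any(diff(dendro$height) < -1e-8))
      stop("dendrogram heights decrease along merges")
    dendro$height <- cummax(dendro$height)
  }
  hmax <- max(dendro$height)

  if (!is.null(static_cut_height)) {
    branch <- stats::cutree(dendro, h = static_cut_height)
    groups <- split(seq_len(n), branch)
  } else {
    info <- tree_tables(dendro)
    tol <- max_branch_spread * hmax
    # the cap never bites below the tightest merge plus the tolerance,
    # so a tree with no height variation yields one module, not grey
    cap <- max(max_module_height * hmax, min(dendro$height) + tol)
    # a tree with no height variation is a single branch: the static
    # cut would otherwise atomise it
    branch <- if (diff(range(dendro$height)) < 1e-12) rep(1L, n)
              else stats::cutree(dendro, h = cut_fraction * hmax)
    groups <- list()
    for (g in split(seq_len(n), branch)) {
      if (length(g) == 1L) { groups <- c(groups, list(g)); next }
      node <- find_subtree_node(info, g)
      groups <- c(groups, decompose_node(info, node, tol, cap))
    }
    if (!is.null(tom)) {
      tm <- if (!is.null(rownames(tom))) tom[ids, ids] else tom
      groups <- adopt_fragments(groups, tm, min_module_size, tol, cap)
    }
  }

  labels <- rep("grey", n)
  names(labels) <- ids
  good <- Filter(function(g) length(g) >= min_module_size, groups)
  if (length(good)) {
    ord <- order(vapply(good, length, integer(1)), decreasing = TRUE)
    cols <- module_color_names(length(good))
    for (i in seq_along(ord)) labels[good[[ord[i]]]] <- cols[i]
  }
  finish_assignment(labels, min_module_size)
}

finish_assignment <- function(labels, min_module_size) {
  sizes <- table(labels[labels != "grey"])
  structure(labels,
            sizes = sizes[order(-as.integer(sizes))],
            min_module_size = min_module_size,
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  sizes <- attr(x, "sizes")
  cat("module_assignment:", length(sizes), "modules over", length(x),
      "proteins (", sum(unclass(x) == "grey"), "grey )\n")
  if (length(sizes)) print(sizes)
  invisible(x)
}

# The internal node whose leaf set is exactly `members` (a cutree
# branch always corresponds to one subtree, or to a single leaf).
find_subtree_node <- function(info, members) {
  target <- sort(members)
  sizes <- vapply(info$leaves, length, integer(1))
  for (i in which(sizes == length(target)))
    if (identical(sort(info$leaves[[i]]), target)) return(i)
  stop("internal error: branch does not correspond to a subtree node")
}

# Recursive adaptive decomposition: a node whose subtree merge heights
# span more than `tol` is split into its children; a node that is
# homogeneous but only coheres above `cap` is diffuse background and
# dissolves into singletons (-> grey); otherwise its leaves form one
# candidate module.
decompose_node <- function(info, node, tol, cap) {
  if (node < 0) return(list(-node))       # single leaf
  hs <- info$subheights[[node]]
  if (max(hs) - min(hs) <= tol) {
    if (max(hs) <= cap) return(list(info$leaves[[node]]))
    return(as.list(info$leaves[[node]]))
  }
  out <- list()
  for (child in info$merge[node, ]) {
    if (child < 0) out <- c(out, list(-child))
    else out <- c(out, decompose_node(info, child, tol, cap))
  }
  out
}

# Reunite fragments smaller than the minimum module size with the
# candidate branch they are closest to in topological overlap. The
# adoption radius of a branch is its own original mean within-branch
# dissimilarity plus the spread tolerance, and is never widened by
# adopted members, so adoption cannot snowball into absorbing diffuse
# background.
adopt_fragments <- function(groups, tom, min_size, tol, cap) {
  dis <- 1 - tom
  sizes <- vapply(groups, length, integer(1))
  core_mean <- vapply(groups, function(g) {
    if (length(g) < 2L) return(0)
    d <- dis[g, g]
    mean(d[upper.tri(d)])
  }, numeric(1))
  frag <- order(sizes)                     # smallest fragments first
  frag <- frag[sizes[frag] < min_size]
  dead <- rep(FALSE, length(groups))
  for (i in frag) {
    if (length(groups[[i]]) >= min_size) next    # grew by adoption already
    adopters <- which(!dead & sizes >= 2L)       # original cores only
    adopters <- setdiff(adopters, i)
    if (!length(adopters)) next
    md <- vapply(adopters, function(j)
      mean(dis[groups[[i]], groups[[j]], drop = FALSE]), numeric(1))
    radius <- pmin(core_mean[adopters] + tol, cap)
    ok <- which(md <= radius)
    if (!length(ok)) next
    j <- adopters[ok[which.min(md[ok])]]
    groups[[j]] <- c(groups[[j]], groups[[i]])
    dead[i] <- TRUE
    groups[[i]] <- integer(0)
  }
  groups[!dead]
}

#' Module sizes of an assignment
#' @param assignment A `module_assignment`.
#' @return Named integer vector (grey excluded), decreasing.
#' @export
module_sizes <- function(assignment) {
  attr(assignment, "sizes")
}
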