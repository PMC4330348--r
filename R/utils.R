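`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index, computed from the contingency
#' table of two label vectors. 1 means identical partitions (up to label
#' names), 0 is the expectation under random agreement.
#'
#' @param a,b Label vectors of equal length (coerced to character).
#' @return A number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (length(a) == 0L) return(NA_real_)
  tab <- table(as.character(a), as.character(b))
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Ordered module colour vocabulary
#'
#' The conventional WGCNA colour sequence used to name modules by
#' decreasing size; "grey" is reserved for unassigned proteins and never
#' appears here. If more modules are found than colours listed, names
#' fall back to `module<N>`.
#' @format Character vector.
#' @export
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black",
  "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown",
  "steelblue", "paleturquoise", "violet", "darkolivegreen",
  "darkmagenta", "sienna3", "yellowgreen", "skyblue3", "plum1",
  "orangered4", "mediumpurple3", "lightsteelblue1", "lightcyan1",
  "ivory", "floralwhite", "darkslateblue"
)

module_color_names <- function(n) {
  if (n <= length(MODULE_COLORS)) return(MODULE_COLORS[seq_len(n)])
  c(MODULE_COLORS,
    paste0("module", seq.int(length(MODULE_COLORS) + 1L, n)))
}
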