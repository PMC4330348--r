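#' A reciprocal SILAC immunoprecipitation experiment
#'
#' One bait pulled down with a specific antibody (heavy label) mixed
#' 1:1 with its isotype control (light label); the prey table holds the
#' H/L enrichment of each co-immunoprecipitated protein over the
#' control.
#'
#' @param bait_id Protein id of the bait; must appear in the prey
#'   table.
#' @param preys Data frame with columns `protein_id`, `hl_ratio`
#'   (positive), `ratio_count` (nonnegative integer).
#' @return An object of class `ip_experiment`.
#' @export
ip_experiment <- function(bait_id, preys) {
  req <- c("protein_id", "hl_ratio", "ratio_count")
  if (!all(req %in% names(preys)))
    stop("prey table needs columns: ", paste(req, collapse = ", "))
  if (!bait_id %in% preys$protein_id)
    stop("bait '", bait_id, "' absent from its own prey table")
  if (any(preys$hl_ratio <= 0)) stop("hl_ratio values must be positive")
  structure(list(bait_id = bait_id, preys = preys), class = "ip_experiment")
}

#' Bait-normalize an IP experiment
#'
#' Divides every prey's H/L ratio by the H/L ratio of the bait protein
#' itself, making edge weights invariant to overall IP efficiency.
#' Preys quantified with fewer than `min_ratio_count` peptides are
#' dropped, as is the bait self-edge.
#'
#' @param exp An [ip_experiment()].
#' @param min_ratio_count Minimum ratio count (default 2).
#' @return Data frame edge list with columns `source` (bait), `target`,
#'   `weight`.
#' @export
normalize_ip <- function(exp, min_ratio_count = 2L) {
  stopifnot(inherits(exp, "ip_experiment"))
  bait_ratio <- exp$preys$hl_ratio[match(exp$bait_id, exp$preys$protein_id)]
  keep <- exp$preys$ratio_count >= min_ratio_count &
    exp$preys$protein_id != exp$bait_id
  preys <- exp$preys[keep, , drop = FALSE]
  data.frame(source = rep(exp$bait_id, nrow(preys)),
             target = preys$protein_id,
             weight = preys$hl_ratio / bait_ratio,
             stringsAsFactors = FALSE)
}

#' Merge bait-normalized IP experiments into one network
#'
#' Takes the union of bait-to-prey edges over all experiments;
#' reciprocal detections (A pulls down B and B pulls down A) are merged
#' into a single undirected edge carrying the larger of the two weights
#' and a reciprocal flag (both weights preserved). Node attributes
#' (module, kWithin) are joined from a connectivity table where
#' available.
#'
#' @param experiments List of [ip_experiment()] objects.
#' @param connectivity Optional `connectivity_table` for node
#'   attributes.
#' @param min_ratio_count Passed to [normalize_ip()].
#' @return An object of class `interaction_network`: list with `nodes`
#'   (protein, module, kWithin) and `edges` (source, target, weight,
#'   reciprocal, weight_forward, weight_reverse).
#' @export
merge_ip_networks <- function(experiments, connectivity = NULL,
                              min_ratio_count = 2L) {
  if (length(experiments) == 0L) stop("need at least one experiment")
  edges <- do.call(rbind, lapply(experiments, normalize_ip,
                                 min_ratio_count = min_ratio_count))
  if (nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), reciprocal = logical(),
                        weight_forward = numeric(),
                        weight_reverse = numeric(), stringsAsFactors = FALSE)
    proteins <- sort(unique(vapply(experiments,
                                   function(e) e$bait_id, "")))
    return(structure(
      list(nodes = data.frame(protein = proteins, module = NA_character_,
                              kWithin = NA_real_, stringsAsFactors = FALSE),
           edges = edges),
      class = "interaction_network"))
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  edges$pair <- key(edges$source, edges$target)
  merged <- lapply(split(edges, edges$pair), function(e) {
    if (nrow(e) == 1L)
      return(data.frame(source = e$source, target = e$target,
                        weight = e$weight, reciprocal = FALSE,
                        weight_forward = e$weight,
                        weight_reverse = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(source = e$source[1], target = e$target[1],
               weight = max(e$weight), reciprocal = TRUE,
               weight_forward = e$weight[1], weight_reverse = e$weight[2],
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, merged)
  rownames(edges) <- NULL
  proteins <- sort(unique(c(edges$source, edges$target,
                            vapply(experiments, function(e) e$bait_id, ""))))
  nodes <- data.frame(protein = proteins, module = NA_character_,
                      kWithin = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(connectivity)) {
    i <- match(nodes$protein, connectivity$protein)
    nodes$module <- connectivity$module[i]
    nodes$kWithin <- connectivity$kWithin[i]
  }
  structure(list(nodes = nodes, edges = edges),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (", sum(x$edges$reciprocal), "reciprocal )\n")
  invisible(x)
}

#' Export an interaction network
#'
#' Writes a TSV edge table (`source`, `target`, `weight`, `reciprocal`)
#' and a TSV node table (`protein`, `module`, `kWithin`); with
#' `format = "graphml"`, additionally writes a GraphML file carrying
#' the same attributes (weights at full precision throughout).
#'
#' @param net An `interaction_network`.
#' @param path Output path prefix; `<path>_edges.tsv`,
#'   `<path>_nodes.tsv` and optionally `<path>.graphml` are written.
#' @param format "tsv" or "graphml" (graphml implies the TSVs too).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  edge_path <- paste0(path, "_edges.tsv")
  node_path <- paste0(path, "_nodes.tsv")
  ef <- net$edges
  ef$weight <- format(ef$weight, digits = 17, trim = TRUE)
  write_tsv(ef[c("source", "target", "weight", "reciprocal")], edge_path)
  write_tsv(net$nodes, node_path)
  paths <- c(edges = edge_path, nodes = node_path)
  if (format == "graphml") {
    g <- as_igraph(net)
    gp <- paste0(path, ".graphml")
    igraph::write_graph(g, gp, format = "graphml")
    paths <- c(paths, graphml = gp)
  }
  invisible(paths)
}

#' Convert an interaction network to an igraph object
#' @param net An `interaction_network`.
#' @return An undirected [igraph::graph] with node attributes `module`,
#'   `kWithin` and edge attributes `weight`, `reciprocal`.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[c("source", "target", "weight", "reciprocal")],
    directed = FALSE, vertices = net$nodes)
  g
}

#' Read a per-bait IP prey table
#'
#' TSV with columns `protein_id`, `hl_ratio`, `ratio_count` (one file
#' per antibody pulldown).
#'
#' @param path File path.
#' @param bait_id The bait protein's id.
#' @return An [ip_experiment()].
#' @export
read_ip_table <- function(path, bait_id) {
  if (!file.exists(path)) stop("IP table not found: ", path)
  ip_experiment(bait_id, read_tsv(path))
}
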