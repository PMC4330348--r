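default_config <- function() {
  list(
    mode = "simulate",
    input = NULL,
    output_dir = "silacnet_results",
    seed = 1L,
    design = list(),
    generator = list(),
    filters = list(min_ratio_count = 2L, max_missing = 14L),
    network = list(beta = 15L, candidate_betas = NULL, min_module_size = 5L,
                   cut_fraction = 0.99, max_branch_spread = 0.25,
                   max_module_height = 0.9, static_cut_height = NULL),
    statistics = list(two_sided = FALSE, fdr_method = "none")
  )
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings over the defaults, rejecting unknown keys at
#' every level; a seed is mandatory in simulate mode, an input table in
#' table mode.
#'
#' @param ... Named top-level settings, or a single list of them (e.g.
#'   from [yaml::read_yaml()]).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  base <- default_config()
  merge_checked <- function(base, user, where) {
    unknown <- setdiff(names(user), names(base))
    if (length(unknown))
      stop("unknown configuration key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
    for (nm in names(user)) {
      if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
          nm %in% c("filters", "network", "statistics"))
        base[[nm]] <- merge_checked(base[[nm]], user[[nm]],
                                    paste0(where, "$", nm))
      else base[[nm]] <- user[[nm]]
    }
    base
  }
  cfg <- merge_checked(base, user, "config")
  if (!cfg$mode %in% c("simulate", "table"))
    stop("mode must be 'simulate' or 'table'")
  if (cfg$mode == "simulate" && is.null(cfg$seed))
    stop("simulate mode requires an explicit seed")
  if (cfg$mode == "table" && is.null(cfg$input))
    stop("table mode requires an input protein-groups table")
  total <- {
    d <- do.call(sample_design, cfg$design)
    n_samples(d)
  }
  if (cfg$filters$max_missing >= total)
    stop("filters$max_missing (", cfg$filters$max_missing,
         ") must be smaller than the number of samples (", total, ")")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  pipeline_config(yaml::read_yaml(path))
}

stage_log <- function(verbose, ...) if (verbose) message("[silacnet] ", ...)

#' Run the full analysis pipeline
#'
#' Sequences ingest -> quality filter -> missingness filter -> zero
#' imputation -> correlation network -> topological overlap ->
#' dendrogram -> adaptive tree cut -> eigenproteins/connectivity ->
#' enrichment statistics, writing every result as TSV plus a JSON run
#' manifest into the configured output directory. In simulate mode the
#' input is generated by [simulate_dataset()] under the configured
#' seed, making the whole bundle bit-reproducible.
#'
#' @param config A `pipeline_config` (or list acceptable to
#'   [pipeline_config()]).
#' @param verbose Log per-stage protein counts (default TRUE).
#' @return A `results_bundle` list: `matrix` (filtered, un-imputed),
#'   `imputed`, `assignment`, `eigenproteins`, `connectivity`, `hubs`,
#'   `soft_threshold`, `module_tests`, `outliers`, `truth` (simulate
#'   mode only), `manifest`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  design <- do.call(sample_design, config$design)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  if (config$mode == "simulate") {
    gen <- run_stage("simulate", {
      gcfg <- do.call(generator_config,
                      c(config$generator, list(seed = config$seed)))
      simulate_dataset(design = design, config = gcfg)
    })
    rm0 <- gen$ratios
    truth <- gen$truth
    stage_log(verbose, "simulate: ", nrow(rm0$values), " proteins, ",
              sum(!rm0$mask), " missing entries")
  } else {
    pg <- run_stage("ingest", read_protein_groups(config$input, design))
    counts$ingest_in <- nrow(pg$ratios)
    pg <- run_stage("quality_filter",
                    filter_quality(pg, config$filters$min_ratio_count))
    counts$quality_out <- nrow(pg$ratios)
    stage_log(verbose, "ingest: ", counts$ingest_in, " -> ",
              counts$quality_out, " after contaminant/decoy/count filter")
    rm0 <- as_ratio_matrix(pg)
  }

  counts$missingness_in <- nrow(rm0$values)
  rm_f <- run_stage("missingness_filter",
                    filter_missingness(rm0, config$filters$max_missing))
  counts$missingness_out <- nrow(rm_f$values)
  stage_log(verbose, "missingness filter: ", counts$missingness_in, " -> ",
            counts$missingness_out, " proteins (max ",
            config$filters$max_missing, " missing)")

  imp <- run_stage("impute", impute_zero(rm_f))

  soft <- NULL
  if (!is.null(config$network$candidate_betas))
    soft <- run_stage("soft_threshold",
                      pick_soft_threshold(imp, config$network$candidate_betas))

  cor <- run_stage("correlation", pairwise_correlation(imp))
  kept <- rownames(cor)
  if (length(kept) < nrow(imp$values)) {
    keep <- rownames(imp$values) %in% kept
    imp$values <- imp$values[keep, , drop = FALSE]
    imp$mask <- imp$mask[keep, , drop = FALSE]
    rm_f$values <- rm_f$values[keep, , drop = FALSE]
    rm_f$mask <- rm_f$mask[keep, , drop = FALSE]
  }
  adj <- run_stage("adjacency", signed_adjacency(cor, config$network$beta))
  tom <- run_stage("topological_overlap", topological_overlap(adj))
  dendro <- run_stage("dendrogram", cluster_dendrogram(tom))
  assignment <- run_stage("tree_cut", dynamic_tree_cut(
    dendro, tom = tom,
    min_module_size = config$network$min_module_size,
    cut_fraction = config$network$cut_fraction,
    max_branch_spread = config$network$max_branch_spread,
    max_module_height = config$network$max_module_height,
    static_cut_height = config$network$static_cut_height))
  stage_log(verbose, "modules: ", length(module_sizes(assignment)),
            " modules, ", sum(unclass(assignment) == "grey"),
            " grey proteins")

  eig <- run_stage("eigenproteins", compute_eigenproteins(imp, assignment))
  conn <- run_stage("connectivity", intramodular_connectivity(adj, assignment))
  hubs <- run_stage("hubs", identify_hubs(conn, top_n = 3L))

  enrich <- run_stage("enrichment", replicate_mean_log_enrichment(rm_f))
  mod_tests <- run_stage("module_ttest",
                         module_enrichment_ttest(enrich, assignment))
  outliers <- run_stage("outlier_zscore",
                        outlier_zscore(enrich,
                                       two_sided = config$statistics$two_sided))
  if (config$statistics$fdr_method != "none") {
    for (cc in colnames(outliers$p))
      outliers$p[, cc] <- adjust_fdr(outliers$p[, cc],
                                     config$statistics$fdr_method)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("silacnet")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = unclass(config),
    counts = counts,
    n_modules = length(module_sizes(assignment)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  write_ratio_matrix(rm_f, file.path(out_dir, "filtered_matrix.tsv"))
  write_tsv(data.frame(protein = names(assignment),
                       module = unname(unclass(assignment))),
            file.path(out_dir, "modules.tsv"))
  write_tsv(data.frame(module = rownames(eig$vectors),
                       variance_explained = unname(eig$variance_explained),
                       eig$vectors, check.names = FALSE),
            file.path(out_dir, "eigenproteins.tsv"))
  write_tsv(conn, file.path(out_dir, "connectivity.tsv"))
  write_tsv(hubs, file.path(out_dir, "hubs.tsv"))
  if (!is.null(soft))
    write_tsv(soft, file.path(out_dir, "soft_threshold.tsv"))
  write_tsv(mod_tests, file.path(out_dir, "module_enrichment.tsv"))
  write_tsv(data.frame(protein = rownames(outliers$z),
                       outliers$z, check.names = FALSE),
            file.path(out_dir, "outlier_z.tsv"))
  write_tsv(data.frame(protein = rownames(outliers$p),
                       outliers$p, check.names = FALSE),
            file.path(out_dir, "outlier_p.tsv"))
  if (!is.null(truth))
    write_tsv(data.frame(protein = names(truth), complex = unname(truth)),
              file.path(out_dir, "truth_labels.tsv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  structure(
    list(matrix = rm_f, imputed = imp, assignment = assignment,
         eigenproteins = eig, connectivity = conn, hubs = hubs,
         soft_threshold = soft, module_tests = mod_tests,
         outliers = outliers, truth = truth, manifest = manifest),
    class = "results_bundle"
  )
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("results_bundle:", nrow(x$matrix$values), "proteins,",
      length(module_sizes(x$assignment)), "modules\n")
  invisible(x)
}
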