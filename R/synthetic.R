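#' Specify a planted protein complex
#'
#' A complex is a set of proteins that binds the peptide panel as a
#' unit: every member shares the same binding signature (one
#' nonnegative affinity per condition), scaled by a per-complex
#' abundance multiplier.
#'
#' @param complex_id Character id.
#' @param member_count Integer >= 1, number of member proteins.
#' @param signature Nonnegative numeric vector, one affinity per
#'   condition (including the beads-only control, whose entry models
#'   nonspecific binding). At least one entry must be positive.
#' @param abundance_scale Positive multiplier on bound amounts.
#' @return An object of class `complex_spec`.
#' @export
complex_spec <- function(complex_id, member_count, signature,
                         abundance_scale = 1) {
  member_count <- as.integer(member_count)
  if (member_count < 1L) stop("member_count must be >= 1")
  signature <- as.numeric(signature)
  if (any(signature < 0)) stop("signature entries must be nonnegative")
  if (all(signature == 0)) stop("signature must have a positive entry")
  if (abundance_scale <= 0) stop("abundance_scale must be positive")
  structure(
    list(complex_id = as.character(complex_id),
         member_count = member_count,
         signature = signature,
         abundance_scale = abundance_scale),
    class = "complex_spec"
  )
}

#' Library of archetype binding signatures
#'
#' Named archetypes of chromatin reader complexes on the nine-condition
#' H3 tail panel, qualitatively matching well-known module classes:
#' an HP1-like K9me3 reader displaced by S10 phosphorylation, an
#' Atrx/Daxx/FACT-like reader indifferent to the phospho-switch, a
#' 14-3-3-like phospho reader strongly preferring S28ph over S10ph, a
#' NuRD-like unmodified-tail binder antagonized by K9me3 and S10ph, a
#' SWI/SNF-like binder of the unmodified and K9me3 tails displaced by
#' S10ph, a PRC2-like reader with 3-fold higher affinity for K9me3 than
#' K27me3, a PARP/B-NHEJ-like broad K9me3/K9me3S10ph binder, and a
#' generic tail binder. Affinities are in arbitrary bound-amount units.
#'
#' @param design A [sample_design()]; must use the default nine
#'   conditions (the archetypes are defined on that panel).
#' @return Named list of [complex_spec()] objects.
#' @export
make_signature_library <- function(design = sample_design()) {
  cond <- design$conditions
  req <- c("H3_1-20_unmod", "H3K9me3", "H3S10ph", "H3K9me3S10ph",
           "H3_18-38_unmod", "H3K27me3", "H3S28ph", "H3K27me3S28ph",
           "beads")
  if (!all(req %in% cond))
    stop("the signature library is defined on the default nine-condition panel")
  sig <- function(...) {
    v <- c(...)
    out <- numeric(length(cond))
    out[match(names(v), cond)] <- unname(v)
    out
  }
  specs <- list(
    # HP1-like: strong K9me3 binding nearly abolished by S10ph
    hp1_like = complex_spec(
      "hp1_like", 60,
      sig("H3_1-20_unmod" = 0.3, "H3K9me3" = 10, "H3S10ph" = 0.2,
          "H3K9me3S10ph" = 0.5, "H3_18-38_unmod" = 0.2, "H3K27me3" = 0.3,
          "H3S28ph" = 0.2, "H3K27me3S28ph" = 0.2, "beads" = 0.2),
      abundance_scale = 1.5),
    # Atrx-like: comparable K9me3 and K9me3S10ph, no S10ph alone
    atrx_like = complex_spec(
      "atrx_like", 12,
      sig("H3_1-20_unmod" = 0.3, "H3K9me3" = 8, "H3S10ph" = 0.2,
          "H3K9me3S10ph" = 7.5, "beads" = 0.2),
      abundance_scale = 1),
    # 14-3-3-like: S28ph much stronger than S10ph
    p1433_like = complex_spec(
      "p1433_like", 7,
      sig("H3_1-20_unmod" = 0.2, "H3K9me3" = 0.2, "H3S10ph" = 2,
          "H3K9me3S10ph" = 2, "H3_18-38_unmod" = 0.2, "H3K27me3" = 0.2,
          "H3S28ph" = 12, "H3K27me3S28ph" = 10, "beads" = 0.2),
      abundance_scale = 2),
    # NuRD-like: unmodified 1-20 highest, reduced by either mark,
    # lowest on the K9me3/S10ph double
    nurd_like = complex_spec(
      "nurd_like", 40,
      sig("H3_1-20_unmod" = 10, "H3K9me3" = 3, "H3S10ph" = 4,
          "H3K9me3S10ph" = 0.5, "H3_18-38_unmod" = 2, "H3K27me3" = 1,
          "H3S28ph" = 0.5, "H3K27me3S28ph" = 0.5, "beads" = 0.3),
      abundance_scale = 1.2),
    # SWI/SNF-like: unmodified ~ K9me3, displaced by S10ph
    swisnf_like = complex_spec(
      "swisnf_like", 30,
      sig("H3_1-20_unmod" = 8, "H3K9me3" = 8, "H3S10ph" = 0.5,
          "H3K9me3S10ph" = 0.5, "H3_18-38_unmod" = 1, "H3K27me3" = 0.5,
          "H3S28ph" = 0.3, "H3K27me3S28ph" = 0.3, "beads" = 0.2),
      abundance_scale = 1),
    # PRC2-like: K9me3 binding exactly 3-fold over K27me3, with
    # appreciable affinity for the unmodified 18-38 peptide
    prc2_like = complex_spec(
      "prc2_like", 6,
      sig("H3_1-20_unmod" = 0.3, "H3K9me3" = 3, "H3S10ph" = 0.2,
          "H3K9me3S10ph" = 0.5, "H3_18-38_unmod" = 5, "H3K27me3" = 1,
          "H3S28ph" = 0.3, "H3K27me3S28ph" = 2, "beads" = 0.2),
      abundance_scale = 0.8),
    # B-NHEJ-like: phospho-tolerant binder, strongest on K9me3 with
    # appreciable K9me3S10ph and S10ph binding
    bnhej_like = complex_spec(
      "bnhej_like", 5,
      sig("H3_1-20_unmod" = 0.3, "H3K9me3" = 6, "H3S10ph" = 5.5,
          "H3K9me3S10ph" = 5, "H3_18-38_unmod" = 0.5, "H3K27me3" = 1,
          "H3S28ph" = 0.5, "H3K27me3S28ph" = 4, "beads" = 0.5),
      abundance_scale = 1),
    # generic tail binder: prefers both unmodified peptides
    tailbinder = complex_spec(
      "tailbinder", 20,
      sig("H3_1-20_unmod" = 5, "H3K9me3" = 1, "H3S10ph" = 2,
          "H3K9me3S10ph" = 0.5, "H3_18-38_unmod" = 5, "H3K27me3" = 1,
          "H3S28ph" = 2, "H3K27me3S28ph" = 1.5, "beads" = 0.3),
      abundance_scale = 1)
  )
  specs
}

#' Generator configuration
#'
#' @param n_background Number of unplanted background proteins; these
#'   carry a flat signature equal to `background_binding`.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal measurement noise (0 disables noise).
#' @param background_binding Nonspecific binding added to every
#'   condition (including beads) of every protein.
#' @param detection_midpoint,detection_slope Logistic detection model on
#'   the log bound amount: an entry is retained with probability
#'   `plogis(detection_slope * (log(bound) - detection_midpoint))`.
#' @param target_missing_rate If non-`NULL`, `detection_midpoint` is
#'   calibrated at generation time so that the expected overall
#'   missingness equals this rate.
#' @param apply_missingness Logical; set `FALSE` to skip the detection
#'   model entirely (complete data).
#' @param seed Integer seed making the whole dataset bit-reproducible.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_background = 300L,
                             noise_cv = 0.2,
                             background_binding = 0.05,
                             detection_midpoint = log(0.15),
                             detection_slope = 1.5,
                             target_missing_rate = NULL,
                             apply_missingness = TRUE,
                             seed = 1L) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (detection_slope < 0) stop("detection_slope must be >= 0")
  if (background_binding < 0) stop("background_binding must be >= 0")
  if (!is.null(target_missing_rate) &&
      (target_missing_rate < 0 || target_missing_rate >= 1))
    stop("target_missing_rate must be in [0, 1)")
  structure(
    list(n_background = as.integer(n_background),
         noise_cv = noise_cv,
         background_binding = background_binding,
         detection_midpoint = detection_midpoint,
         detection_slope = detection_slope,
         target_missing_rate = target_missing_rate,
         apply_missingness = isTRUE(apply_missingness),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "generator_config"
  )
}

rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate bound protein amounts
#'
#' Forward model of the capture assay: the amount of protein i
#' (member of complex m) bound in condition c, replicate r is
#' `abundance_scale(m) * (signature(m, c) + background_binding)` times
#' independent multiplicative lognormal noise with the configured CV.
#' Background proteins use a flat signature equal to
#' `background_binding`. All members of one complex share the same
#' signature (a complex binds as a unit).
#'
#' @param specs List of [complex_spec()]; signature lengths must match
#'   the design's condition count.
#' @param design A [sample_design()].
#' @param config A [generator_config()]. If `config$seed` is non-`NULL`
#'   the RNG is seeded here; pass `seed = NULL` to draw from the
#'   current stream (as [simulate_dataset()] does).
#' @return 3-d array (protein x condition x replicate) of nonnegative
#'   bound amounts; row names are protein ids, complex members first.
#' @export
simulate_binding <- function(specs, design, config = generator_config()) {
  if (length(specs) == 0L && config$n_background < 1L)
    stop("'specs' must be nonempty when there are no background proteins")
  ncond <- length(design$conditions)
  for (s in specs) {
    if (length(s$signature) != ncond)
      stop("signature length of '", s$complex_id, "' does not match the design")
    if (any(s$signature < 0)) stop("negative signature entries")
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  ids <- c(
    unlist(lapply(unname(specs), function(s)
      paste0(s$complex_id, "_", seq_len(s$member_count)))),
    if (config$n_background > 0L)
      paste0("background_", seq_len(config$n_background))
  )
  nprot <- length(ids)
  mean_amount <- matrix(config$background_binding, nprot, ncond)
  row0 <- 0L
  for (s in specs) {
    idx <- row0 + seq_len(s$member_count)
    mean_amount[idx, ] <- s$abundance_scale *
      rep(s$signature + config$background_binding, each = s$member_count)
    row0 <- row0 + s$member_count
  }

  bound <- array(NA_real_, dim = c(nprot, ncond, design$replicates),
                 dimnames = list(ids, design$conditions,
                                 paste0("rep", seq_len(design$replicates))))
  for (r in seq_len(design$replicates)) {
    noise <- matrix(rlnorm_cv(nprot * ncond, config$noise_cv), nprot, ncond)
    bound[, , r] <- mean_amount * noise
  }
  bound
}

#' Form H/L ratios against the pooled mixed reference
#'
#' Emulates the super-SILAC mixed-reference design: per replicate, the
#' light eluates of all conditions are pooled and split into
#' `|conditions|` equal aliquots, so the reference amount for protein i
#' is the mean of its light bound amounts over the conditions. The H/L
#' ratio is the heavy amount divided by that reference. With heavy =
#' light and no noise, each protein's ratios over the nine conditions
#' sum exactly to nine.
#'
#' @param heavy,light Bound-amount arrays from [simulate_binding()]
#'   with identical dimensions.
#' @param design A [sample_design()].
#' @return A [ratio_matrix()]; entries where the reference is zero are
#'   missing.
#' @export
apply_mixed_reference <- function(heavy, light, design) {
  if (!identical(dim(heavy), dim(light)))
    stop("'heavy' and 'light' dimensions differ")
  ncond <- length(design$conditions)
  if (dim(heavy)[2] != ncond || dim(heavy)[3] != design$replicates)
    stop("bound array dimensions do not match the design")
  vals <- matrix(NA_real_, nrow = dim(heavy)[1], ncol = n_samples(design))
  for (r in seq_len(design$replicates)) {
    lr <- matrix(light[, , r], nrow = dim(light)[1])
    hr <- matrix(heavy[, , r], nrow = dim(heavy)[1])
    ref <- rowMeans(lr)
    block <- hr / ref
    block[ref == 0, ] <- NA_real_
    vals[, (r - 1L) * ncond + seq_len(ncond)] <- block
  }
  ratio_matrix(vals, design, protein_ids = dimnames(heavy)[[1]])
}

#' Apply abundance-dependent missingness
#'
#' Each ratio is retained with probability
#' `plogis(detection_slope * (log(bound) - detection_midpoint))`,
#' mirroring mass-spectrometric detection limits: low-abundance
#' captures are more likely to be dropped. Dropped entries are marked
#' missing (not zero).
#'
#' @param ratios A [ratio_matrix()].
#' @param bound Bound-amount array used for the detection model (same
#'   protein x condition x replicate layout the ratios came from).
#' @param config A [generator_config()]; if `config$seed` is non-`NULL`
#'   the RNG is seeded here.
#' @return The ratio matrix with additional entries marked missing.
#' @export
apply_missingness <- function(ratios, bound, config) {
  stopifnot(inherits(ratios, "ratio_matrix"))
  ncond <- dim(bound)[2]
  if (dim(bound)[1] != nrow(ratios$values) ||
      ncond * dim(bound)[3] != ncol(ratios$values))
    stop("'bound' dimensions do not match the ratio matrix")
  if (!is.null(config$seed)) set.seed(config$seed)
  flat <- matrix(NA_real_, nrow(ratios$values), ncol(ratios$values))
  for (r in seq_len(dim(bound)[3]))
    flat[, (r - 1L) * ncond + seq_len(ncond)] <- bound[, , r]
  p_keep <- detection_probability(flat, config)
  drop <- matrix(stats::runif(length(flat)) > p_keep,
                 nrow(flat), ncol(flat))
  ratios$values[drop] <- NA_real_
  ratios$mask[drop] <- FALSE
  ratios
}

detection_probability <- function(bound, config) {
  if (config$detection_slope == 0)
    return(array(0.5, dim = dim(bound)))
  lb <- suppressWarnings(log(bound))
  p <- stats::plogis(config$detection_slope * (lb - config$detection_midpoint))
  p[bound == 0] <- 0
  if (is.infinite(config$detection_midpoint) && config$detection_midpoint < 0)
    p[] <- 1
  p
}

#' Calibrate the detection midpoint to a target missingness rate
#'
#' Solves for the logistic midpoint such that the mean retention
#' probability over all bound amounts equals `1 - rate`. Deterministic
#' given the bound amounts.
#'
#' @param bound Numeric array of bound amounts (> 0).
#' @param rate Target overall missingness in \[0, 1).
#' @param slope Logistic slope (> 0).
#' @return The calibrated midpoint on the log bound scale.
#' @export
calibrate_detection_midpoint <- function(bound, rate, slope) {
  if (slope <= 0) stop("calibration needs a positive detection slope")
  if (rate == 0) return(-Inf)
  lb <- log(bound[bound > 0])
  f <- function(m) mean(stats::plogis(slope * (lb - m))) - (1 - rate)
  stats::uniroot(f, lower = min(lb) - 50, upper = max(lb) + 50,
                 tol = 1e-10)$root
}

#' Generate a complete synthetic dataset
#'
#' End-to-end forward model: simulates independent heavy and light
#' capture sets (shared means, independent noise), forms mixed-reference
#' H/L ratios per replicate, and optionally applies abundance-dependent
#' missingness. The configured seed makes the result bit-reproducible.
#'
#' @param specs List of [complex_spec()] (default: the archetype
#'   library).
#' @param design A [sample_design()].
#' @param config A [generator_config()].
#' @return An object of class `synthetic_dataset`: list with `ratios`
#'   (a [ratio_matrix()]), `truth` (named character vector mapping
#'   protein id to complex id or "background"), `specs`, `bound_heavy`,
#'   and `config`.
#' @export
simulate_dataset <- function(specs = make_signature_library(design),
                             design = sample_design(),
                             config = generator_config()) {
  if (is.null(config$seed)) stop("simulate mode requires an explicit seed")
  set.seed(config$seed)
  inner <- config
  inner$seed <- NULL
  heavy <- simulate_binding(specs, design, inner)
  light <- if (config$noise_cv == 0) heavy else
    simulate_binding(specs, design, inner)
  ratios <- apply_mixed_reference(heavy, light, design)
  if (config$apply_missingness) {
    if (!is.null(config$target_missing_rate)) {
      inner$detection_midpoint <- calibrate_detection_midpoint(
        heavy, config$target_missing_rate, config$detection_slope)
    }
    ratios <- apply_missingness(ratios, heavy, inner)
  }
  truth <- rep("background", nrow(ratios$values))
  names(truth) <- rownames(ratios$values)
  for (s in specs)
    truth[paste0(s$complex_id, "_", seq_len(s$member_count))] <- s$complex_id
  structure(
    list(ratios = ratios, truth = truth, specs = specs,
         bound_heavy = heavy, config = config, design = design),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$ratios$values), "proteins (",
      sum(x$truth != "background"), "in", length(x$specs),
      "planted complexes ),", sum(!x$ratios$mask), "missing entries\n")
  invisible(x)
}

#' Write a synthetic dataset as a protein-groups fixture
#'
#' Serializes the dataset as (a) a tab-separated protein-groups-style
#' table readable by [read_protein_groups()], with per-sample
#' `Ratio H/L <sample>` and `Ratio H/L count <sample>` columns and
#' contaminant/reverse flag columns, and (b) a truth-labels table.
#' Ratio counts stand in for the number of redundant peptides used for
#' quantification: a deterministic per-protein count for measured
#' entries, 0 for missing ones. Optionally spikes contaminant-flagged
#' decoy rows to exercise the quality filter.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @param n_contaminants Number of contaminant-flagged rows to spike.
#' @return Invisibly, the paths of the two files written.
#' @export
write_fixture <- function(dataset, dir, n_contaminants = 0L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rm <- dataset$ratios
  snames <- sample_names(rm$design)
  ids <- rownames(rm$values)
  counts <- matrix(0L, nrow(rm$values), ncol(rm$values))
  counts[rm$mask] <- rep(2L + seq_along(ids) %% 5L,
                         times = ncol(rm$values))[which(rm$mask)]
  df <- data.frame(ProteinID = ids, GeneName = toupper(ids),
                   Contaminant = "-", Reverse = "-",
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(snames)) {
    v <- rm$values[, j]
    df[[paste0("Ratio H/L ", snames[j])]] <-
      ifelse(is.na(v), NA_character_, format(v, digits = 17, trim = TRUE))
    df[[paste0("Ratio H/L count ", snames[j])]] <- counts[, j]
  }
  if (n_contaminants > 0L) {
    spike <- df[rep_len(seq_len(nrow(df)), n_contaminants), , drop = FALSE]
    spike$ProteinID <- paste0("CON_", seq_len(n_contaminants))
    spike$GeneName <- spike$ProteinID
    spike$Contaminant <- "+"
    df <- rbind(df, spike)
  }
  pg_path <- file.path(dir, "protein_groups.tsv")
  truth_path <- file.path(dir, "truth_labels.tsv")
  write_tsv(df, pg_path)
  write_tsv(data.frame(ProteinID = names(dataset$truth),
                       ComplexID = unname(dataset$truth)),
            truth_path)
  invisible(c(protein_groups = pg_path, truth = truth_path))
}
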