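ratio_matrix_from <- function(vals, design = sample_design()) {
  ratio_matrix(vals, design, protein_ids = paste0("P", seq_len(nrow(vals))))
}

test_that("replicate-mean log2 enrichment handles means, missingness, beads", {
  design <- sample_design()
  vals <- matrix(1, 3, 18)
  colnames(vals) <- sample_names(design)
  # P1: H3K9me3 replicates (2, 8); beads (2, 2)
  vals[1, "H3K9me3_rep1"] <- 2; vals[1, "H3K9me3_rep2"] <- 8
  vals[1, "beads_rep1"] <- 2;   vals[1, "beads_rep2"] <- 2
  # P2: one replicate missing, surviving value 4, beads 4
  vals[2, "H3S10ph_rep1"] <- NA; vals[2, "H3S10ph_rep2"] <- 4
  vals[2, "beads_rep1"] <- 4;    vals[2, "beads_rep2"] <- 4
  # P3: both replicates missing in one condition
  vals[3, "H3K27me3_rep1"] <- NA; vals[3, "H3K27me3_rep2"] <- NA
  en <- replicate_mean_log_enrichment(ratio_matrix_from(vals))
  expect_equal(en$d["P1", "H3K9me3"], log2(5) - log2(2))
  expect_equal(en$d["P2", "H3S10ph"], 0)
  expect_true(is.na(en$d["P3", "H3K27me3"]))
  expect_false("beads" %in% colnames(en$d))

  # missing beads poisons the whole protein row
  vals2 <- vals
  vals2[1, c("beads_rep1", "beads_rep2")] <- NA
  en2 <- replicate_mean_log_enrichment(ratio_matrix_from(vals2))
  expect_true(all(is.na(en2$d["P1", ])))

  # imputed matrices are refused (zeros would corrupt the means)
  expect_error(
    replicate_mean_log_enrichment(impute_zero(ratio_matrix_from(vals))),
    "before zero imputation")
})

test_that("module t-test matches the textbook oracle", {
  d <- matrix(NA_real_, 3, 1, dimnames = list(paste0("P", 1:3), "H3K9me3"))
  asg <- stats::setNames(rep("m1", 3), rownames(d))
  class(asg) <- "module_assignment"

  d[, 1] <- c(1, 2, 3)
  res <- module_enrichment_ttest(d, asg)
  expect_equal(res$t_statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(res$p_value, 0.0741799, tolerance = 1e-4)
  expect_equal(res$n_pairs, 3)

  # null case: no difference from beads
  d[, 1] <- 0
  res0 <- module_enrichment_ttest(d, asg)
  expect_equal(res0$t_statistic, 0)
  expect_equal(res0$p_value, 1)

  # two-tailed symmetry
  d[, 1] <- c(-1, -2, -3)
  resn <- module_enrichment_ttest(d, asg)
  expect_equal(resn$t_statistic, -2 * sqrt(3), tolerance = 1e-12)
  expect_equal(resn$p_value, res$p_value)

  # degenerate variance and insufficient pairs are flagged
  d[, 1] <- c(1, 1, 1)
  resd <- module_enrichment_ttest(d, asg)
  expect_equal(resd$flag, "degenerate_variance")
  expect_equal(resd$p_value, 0)
  d[, 1] <- c(1, NA, NA)
  resi <- module_enrichment_ttest(d, asg)
  expect_equal(resi$flag, "insufficient_pairs")
  expect_true(is.na(resi$p_value))
})

test_that("outlier z-scores match the hand-computed example", {
  design <- sample_design()
  d <- matrix(c(1, -1, 2, 0, -2), 5, 1,
              dimnames = list(paste0("P", 1:5), "H3K9me3"))
  en <- structure(list(d = d, conditions = "H3K9me3", design = design),
                  class = "enrichment_input")
  zz <- outlier_zscore(en)
  expect_equal(unname(zz$sigma["H3K9me3"]), sqrt(2.5), tolerance = 1e-12)
  expect_equal(unname(zz$z["P3", 1]), 2 / sqrt(2.5), tolerance = 1e-12)
  expect_equal(unname(zz$z["P3", 1]), 1.264911, tolerance = 1e-4)
  expect_equal(unname(zz$p["P3", 1]), pnorm(2 / sqrt(2.5), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(unname(zz$p["P3", 1]), 0.102952, tolerance = 1e-4)
  # null centre
  expect_equal(unname(zz$z["P4", 1]), 0)
  expect_equal(unname(zz$p["P4", 1]), 0.5)
  # scale invariance of z
  en2 <- en; en2$d <- 2 * d
  expect_equal(outlier_zscore(en2)$z, zz$z, tolerance = 1e-12)
  # two-sided option doubles the tail
  z2 <- outlier_zscore(en, two_sided = TRUE)
  expect_equal(unname(z2$p["P3", 1]),
               2 * pnorm(-2 / sqrt(2.5)), tolerance = 1e-12)
  # degenerate condition flagged via NA sigma
  en3 <- en; en3$d[, 1] <- 1
  expect_true(is.na(outlier_zscore(en3)$sigma["H3K9me3"]))
})

test_that("z-scores are invariant to a global pre-log scaling of ratios", {
  cfg <- generator_config(n_background = 0, noise_cv = 0.2,
                          apply_missingness = FALSE, seed = 8)
  ds <- simulate_dataset(list(complex_spec("flat", 40, rep(1, 9))),
                         config = cfg)
  z1 <- outlier_zscore(replicate_mean_log_enrichment(ds$ratios))
  scaled <- ds$ratios
  scaled$values <- scaled$values * 7.3
  z2 <- outlier_zscore(replicate_mean_log_enrichment(scaled))
  expect_equal(z1$z, z2$z, tolerance = 1e-10)
})

test_that("FDR adjustment is paper-faithful by default", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_identical(adjust_fdr(p), p)
  expect_equal(adjust_fdr(p, "benjamini_hochberg"), rep(0.04, 4))
  expect_equal(adjust_fdr(0.2, "benjamini_hochberg"), 0.2)
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("leave-one-out sigma option changes little at moderate n", {
  set.seed(9)
  design <- sample_design()
  d <- matrix(rnorm(200 * 8), 200, 8,
              dimnames = list(paste0("P", 1:200),
                              setdiff(design$conditions, "beads")))
  en <- structure(list(d = d, conditions = colnames(d), design = design),
                  class = "enrichment_input")
  z0 <- outlier_zscore(en)
  z1 <- outlier_zscore(en, leave_one_out = TRUE)
  expect_lt(max(abs(z0$z - z1$z)), 0.1)
  expect_false(identical(z0$z, z1$z))
})

test_that("planted enrichment is detected, null modules are calibrated", {
  # power: a strongly-bound complex is significant in its top conditions
  hits <- 0
  for (seed in 1:5) {
    specs <- make_signature_library()["hp1_like"]
    specs$hp1_like$member_count <- 20L
    cfg <- generator_config(n_background = 80, noise_cv = 0.2,
                            apply_missingness = FALSE, seed = seed)
    ds <- simulate_dataset(specs, config = cfg)
    en <- replicate_mean_log_enrichment(ds$ratios)
    asg <- stats::setNames(unname(ds$truth), names(ds$truth))
    class(asg) <- "module_assignment"
    tt <- module_enrichment_ttest(en, asg)
    row <- tt[tt$module == "hp1_like" & tt$condition == "H3K9me3", ]
    hits <- hits + (row$p_value < 0.05 & row$t_statistic > 0)
  }
  expect_equal(hits, 5)

  # calibration at nominal level under the null (few seeds; the
  # acceptance suite runs the full Monte-Carlo version)
  ds0 <- null_dataset(250, seed = 21)
  en0 <- replicate_mean_log_enrichment(ds0$ratios)
  rate <- mean(outlier_zscore(en0)$p < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / 2000))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})
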