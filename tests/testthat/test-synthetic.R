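test_that("signature library encodes the archetype contrasts", {
  design <- sample_design()
  lib <- make_signature_library(design)
  expect_gte(length(lib), 6L)
  cond <- design$conditions
  get <- function(spec, cc) spec$signature[match(cc, cond)]

  # HP1-like: K9me3 maximal, double mark < 10% of it
  hp1 <- lib$hp1_like
  expect_equal(which.max(hp1$signature), match("H3K9me3", cond))
  expect_lt(get(hp1, "H3K9me3S10ph"), 0.1 * get(hp1, "H3K9me3"))

  # Atrx-like: K9me3 and K9me3S10ph within 20%, S10ph alone near zero
  atrx <- lib$atrx_like
  expect_lt(abs(get(atrx, "H3K9me3") - get(atrx, "H3K9me3S10ph")) /
              get(atrx, "H3K9me3"), 0.2)
  expect_lt(get(atrx, "H3S10ph"), 0.1 * get(atrx, "H3K9me3"))

  # 14-3-3-like: S28ph much greater than S10ph
  expect_gt(get(lib$p1433_like, "H3S28ph"), 4 * get(lib$p1433_like, "H3S10ph"))

  # NuRD-like ordering: unmod > single marks > double mark
  nurd <- lib$nurd_like
  expect_equal(which.max(nurd$signature), match("H3_1-20_unmod", cond))
  expect_gt(get(nurd, "H3K9me3"), get(nurd, "H3K9me3S10ph"))
  expect_gt(get(nurd, "H3S10ph"), get(nurd, "H3K9me3S10ph"))

  # SWI/SNF-like: unmod ~ K9me3, displaced by S10ph
  swi <- lib$swisnf_like
  expect_equal(get(swi, "H3_1-20_unmod"), get(swi, "H3K9me3"))
  expect_lt(get(swi, "H3S10ph"), 0.1 * get(swi, "H3K9me3"))

  # PRC2-like: exactly 3-fold K9me3 over K27me3
  expect_equal(get(lib$prc2_like, "H3K9me3") / get(lib$prc2_like, "H3K27me3"),
               3)

  # every signature matches the panel and carries a nonspecific beads term
  for (s in lib) {
    expect_length(s$signature, length(cond))
    expect_gte(get(s, "beads"), 0)
  }
})

test_that("simulate_binding follows the forward model", {
  design <- sample_design()
  specs <- list(complex_spec("cx", 3, c(2, 4, 0, 1, 0, 0, 0, 0, 0),
                             abundance_scale = 2),
                complex_spec("cy", 2, c(1, 1, 1, 1, 1, 1, 1, 1, 1),
                             abundance_scale = 0.5))
  cfg <- generator_config(n_background = 2, noise_cv = 0,
                          background_binding = 0.1, seed = 1)
  b <- simulate_binding(specs, design, cfg)
  expect_equal(dim(b), c(7L, 9L, 2L))
  # noiseless determinism: exactly abundance_scale * (signature + background)
  expect_equal(unname(b["cx_1", , 1]),
               2 * (specs[[1]]$signature + 0.1))
  # complex members share the profile up to their abundance ratio
  expect_equal(b["cx_1", , 2], b["cx_2", , 2])
  expect_equal(unname(b["cy_1", , 1] / b["cx_1", , 1]),
               0.5 * (specs[[2]]$signature + 0.1) /
                 (2 * (specs[[1]]$signature + 0.1)))
  # background proteins are flat
  expect_true(all(b["background_1", , ] == 0.1))
  # seeded reproducibility with noise is bit-identical
  cfg2 <- generator_config(n_background = 2, noise_cv = 0.2, seed = 42)
  expect_identical(simulate_binding(specs, design, cfg2),
                   simulate_binding(specs, design, cfg2))
  expect_error(complex_spec("bad", 3, c(-1, rep(1, 8))), "nonnegative")
})

test_that("mixed reference pooling reproduces the sum rule", {
  design <- sample_design()
  specs <- list(complex_spec("cx", 4, c(3, 1, 0.5, 2, 0.2, 0.1, 1, 1, 0.2)))
  cfg <- generator_config(n_background = 6, noise_cv = 0,
                          background_binding = 0.05, seed = 1)
  b <- simulate_binding(specs, design, cfg)
  rm <- apply_mixed_reference(b, b, design)
  # heavy = light, no noise: each protein's nine ratios sum to exactly 9
  for (r in 1:2) {
    cols <- paste0(design$conditions, "_rep", r)
    expect_equal(unname(rowSums(rm$values[, cols])), rep(9, nrow(rm$values)),
                 tolerance = 1e-14)
  }
  # protein bound in a single condition: H/L = 9 there, 0 elsewhere
  solo <- array(0, dim = c(1, 9, 1), dimnames = list("p", design$conditions, "rep1"))
  solo[1, 3, 1] <- 5
  d1 <- sample_design(replicates = 1)
  rm_solo <- apply_mixed_reference(solo, solo, d1)
  expect_equal(unname(rm_solo$values[1, ]), c(0, 0, 9, 0, 0, 0, 0, 0, 0))
  # flat profile: every ratio 1
  flat <- array(2, dim = c(1, 9, 1), dimnames = list("p", design$conditions, "rep1"))
  expect_true(all(apply_mixed_reference(flat, flat, d1)$values == 1))
  # dimension mismatch rejected
  expect_error(apply_mixed_reference(b, b[, 1:5, , drop = FALSE], design),
               "dimensions")
})

test_that("abundance-dependent missingness behaves as specified", {
  design <- sample_design()
  specs <- list(complex_spec("cx", 10, rep(1, 9)))
  cfg <- generator_config(n_background = 0, noise_cv = 0, seed = 7)
  b <- simulate_binding(specs, design, cfg)
  rm <- apply_mixed_reference(b, b, design)
  # slope 0: retention probability exactly 1/2 everywhere
  p <- silacnet:::detection_probability(b, generator_config(detection_slope = 0))
  expect_true(all(p == 0.5))
  # midpoint -Inf: everything retained
  keep_all <- apply_missingness(rm, b,
                                generator_config(detection_midpoint = -Inf,
                                                 seed = 1))
  expect_true(all(keep_all$mask))
  # seeded mask is reproducible
  cfg_m <- generator_config(detection_midpoint = 0, detection_slope = 1.5,
                            seed = 11)
  m1 <- apply_missingness(rm, b, cfg_m)
  m2 <- apply_missingness(rm, b, cfg_m)
  expect_identical(m1$mask, m2$mask)
  expect_true(any(!m1$mask))
  # dropped entries are missing, not zero
  expect_true(all(is.na(m1$values[!m1$mask])))
})

test_that("midpoint calibration hits the requested missingness", {
  set.seed(3)
  bound <- array(rlnorm(1000, 0, 1), dim = c(100, 10))
  mid <- calibrate_detection_midpoint(bound, rate = 0.3, slope = 1.5)
  p <- plogis(1.5 * (log(bound) - mid))
  expect_equal(mean(1 - p), 0.3, tolerance = 1e-8)
})

test_that("whole datasets are reproducible and respect planted structure", {
  cfg <- generator_config(n_background = 30, noise_cv = 0.2,
                          target_missing_rate = 0.3, seed = 5)
  specs <- make_signature_library()
  ds1 <- simulate_dataset(specs, config = cfg)
  ds2 <- simulate_dataset(specs, config = cfg)
  expect_identical(ds1$ratios$values, ds2$ratios$values)
  expect_identical(ds1$truth, ds2$truth)
  expect_setequal(unique(ds1$truth),
                  c(names(specs), "background"))
  # overall missingness lands near the calibrated target
  expect_equal(mean(!ds1$ratios$mask), 0.3, tolerance = 0.05)

  # noiseless members of one complex have pairwise profile correlation 1
  cfg0 <- generator_config(n_background = 0, noise_cv = 0,
                           apply_missingness = FALSE, seed = 1)
  ds0 <- simulate_dataset(specs, config = cfg0)
  m <- names(ds0$truth)[ds0$truth == "nurd_like"][1:5]
  cors <- cor(t(ds0$ratios$values[m, ]))
  expect_equal(unname(cors), matrix(1, 5, 5), tolerance = 1e-12)
})

test_that("more noise means less within-complex coherence", {
  median_within <- function(noise_cv, seed) {
    specs <- make_signature_library()
    cfg <- generator_config(n_background = 0, noise_cv = noise_cv,
                            apply_missingness = FALSE, seed = seed)
    ds <- simulate_dataset(specs, config = cfg)
    cors <- c()
    for (cid in names(specs)) {
      m <- names(ds$truth)[ds$truth == cid]
      cc <- cor(t(ds$ratios$values[m, ]))
      cors <- c(cors, cc[upper.tri(cc)])
    }
    median(cors)
  }
  for (seed in 1:3) {
    r <- vapply(c(0.1, 0.3, 0.6), median_within, numeric(1), seed = seed)
    expect_true(all(diff(r) < 0))
  }
})

test_that("fixtures round-trip through the protein-groups dialect", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(n_background = 10, noise_cv = 0.2,
                          target_missing_rate = 0.25, seed = 9)
  specs <- make_signature_library()[c("prc2_like", "p1433_like")]
  ds <- simulate_dataset(specs, config = cfg)
  paths <- write_fixture(ds, dir, n_contaminants = 5)
  design <- sample_design()
  pg <- read_protein_groups(paths[["protein_groups"]], design)
  expect_equal(nrow(pg$ratios), nrow(ds$ratios$values) + 5)
  filtered <- filter_quality(pg)
  expect_equal(nrow(filtered$ratios), nrow(ds$ratios$values))
  rm_back <- as_ratio_matrix(filtered)
  expect_equal(rm_back$values, ds$ratios$values, tolerance = 1e-12)
  expect_identical(rm_back$mask, ds$ratios$mask)
  truth_back <- read.delim(paths[["truth"]], sep = "\t")
  expect_identical(truth_back$ComplexID,
                   unname(ds$truth[truth_back$ProteinID]))
})
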