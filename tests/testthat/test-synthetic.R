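small_config <- function(...) {
  simulation_config(n_samples = 20, n_genes = 160, seed = 101, ...)
}

test_that("simulation is bit-identical for a fixed seed", {
  a <- simulate_cohort(small_config())
  b <- simulate_cohort(small_config())
  expect_identical(unclass(a$expression$rnaseq), unclass(b$expression$rnaseq))
  expect_identical(a$volumes$S0001$t1c, b$volumes$S0001$t1c)
  expect_identical(a$truth, b$truth)
  # and the caller's RNG stream is untouched
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(simulate_cohort(small_config()))
  expect_identical(rnorm(1), before)
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(group_proportions = c(0.5, 0.5, 0, 0, 0.1)),
               "sum to 1")
  expect_error(simulation_config(image_shape = c(4, 16, 16)), ">= 8")
  expect_error(simulate_cohort(simulation_config(n_samples = 5)), ">= 10")
  expect_error(simulation_config(median_survival_by_group = c(1, 2, 3, 4, -5)))
})

test_that("degenerate proportions put every sample in G1, all states low", {
  cfg <- simulation_config(n_samples = 50,
                           group_proportions = c(1, 0, 0, 0, 0),
                           n_genes = 160, seed = 5)
  sim <- simulate_cohort(cfg, components = character(0))
  expect_true(all(sim$truth$group == "G1"))
  expect_true(all(truth_levels(sim$truth) == "low"))
})

test_that("planted groups are consistent with the labelling rules", {
  sim <- simulate_cohort(small_config(), components = character(0))
  mapped <- map_levels_to_group(truth_levels(sim$truth))
  expect_equal(mapped$group, sim$truth$group, ignore_attr = TRUE)
  expect_true(all(sim$truth$survival_days > 0))
})

test_that("group frequencies recover the configured proportions at n = 10000", {
  cfg <- simulation_config(n_samples = 10000, seed = 17)
  sim <- simulate_cohort(cfg, components = character(0))
  freq <- table(factor(sim$truth$group, paste0("G", 1:5))) / 10000
  target <- c(0.377, 0.162, 0.065, 0.130, 0.266)
  expect_true(all(abs(freq - target) < 0.02))
})

test_that("effect_size 0 plants no expression shift", {
  cfg <- simulation_config(n_samples = 60, effect_size = 0, n_genes = 160,
                           seed = 7)
  sim <- simulate_cohort(cfg, components = "expression")
  lf <- log_fpkm(sim$expression$rnaseq)
  tl <- truth_levels(sim$truth)
  # per-gene mean difference between high and low CTL samples ~ 0
  hi <- tl[, "MDSC"] == "high"
  if (any(hi) && any(!hi)) {
    d <- rowMeans(lf[, hi, drop = FALSE]) - rowMeans(lf[, !hi, drop = FALSE])
    genes <- sim$catalog$MDSC
    expect_lt(abs(mean(d[genes])), 3 * sd(d) / sqrt(length(genes)) + 0.15)
  }
})

test_that("planted expression shift appears on both platforms", {
  sim <- simulate_cohort(simulation_config(n_samples = 60, n_genes = 160,
                                           seed = 9))
  tl <- truth_levels(sim$truth)
  lf <- log_fpkm(sim$expression$rnaseq)
  ma <- unclass(sim$expression$microarray)
  for (s in c("aDC", "MDSC")) {
    hi <- tl[, s] == "high"
    g <- sim$catalog[[s]]
    d_r <- mean(rowMeans(lf[g, hi]) - rowMeans(lf[g, !hi]))
    d_a <- mean(rowMeans(ma[g, hi]) - rowMeans(ma[g, !hi]))
    expect_gt(d_r, 1)   # effect_size 2 minus attenuation/noise
    expect_gt(d_a, 1)
    expect_equal(sign(d_r), sign(d_a))
  }
})

test_that("ROI image statistics track the planted CTL and MDSC states", {
  sim <- simulate_cohort(simulation_config(n_samples = 40, n_genes = 160,
                                           seed = 11))
  tl <- truth_levels(sim$truth)
  med <- vapply(sim$volumes, function(v) {
    nv <- normalize_intensity(v$t1c, v$mask)
    median(nv[v$mask == 1])
  }, numeric(1))
  sre <- vapply(sim$volumes, function(v) {
    q <- quantize_roi(normalize_intensity(v$t1c, v$mask), v$mask, 32)
    glrlm_features(q, list(c(1, 0, 0)))["SRE"]
  }, numeric(1))
  # high CTL skews intensities: the normalized median drops
  expect_lt(mean(med[tl[, "CTL"] == "high"]), mean(med[tl[, "CTL"] == "low"]))
  # high MDSC coarsens runs: SRE drops
  expect_lt(mean(sre[tl[, "MDSC"] == "high"]), mean(sre[tl[, "MDSC"] == "low"]))
})

test_that("survival times follow the configured group medians", {
  ok <- vapply(1:5, function(k) {
    sim <- simulate_cohort(simulation_config(n_samples = 300,
                                             seed = 200 + k),
                           components = character(0))
    med <- vapply(c("G2", "G3"), function(g) {
      d <- sim$truth[sim$truth$group == g, ]
      km_estimate(d$survival_days, d$event)$median
    }, numeric(1))
    !is.na(med["G3"]) && !is.na(med["G2"]) && med["G3"] > med["G2"]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("fixtures round-trip through disk formats", {
  sim <- simulate_cohort(simulation_config(n_samples = 10, n_genes = 160,
                                           seed = 13))
  dir <- withr::local_tempdir()
  write_fixtures(sim, dir)
  back <- read_fixtures(dir)
  # expression TSVs are lossless
  expect_equal(unclass(back$expression$rnaseq),
               unclass(sim$expression$rnaseq), tolerance = 1e-12)
  # NIfTI volumes reproduce to float32 precision, masks exactly {0,1}
  expect_equal(back$volumes$S0001$t1c, sim$volumes$S0001$t1c,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_setequal(unique(as.vector(back$volumes$S0001$mask)), c(0, 1))
  # volume and mask share spacing metadata
  t1c_img <- RNifti::readNifti(file.path(dir, "nifti", "S0001_t1c.nii.gz"))
  msk_img <- RNifti::readNifti(file.path(dir, "nifti", "S0001_mask.nii.gz"))
  expect_equal(RNifti::pixdim(t1c_img), RNifti::pixdim(msk_img))
  expect_equal(RNifti::pixdim(t1c_img), sim$spacing, tolerance = 1e-6)
  expect_equal(back$clinical$survival_days, sim$clinical$survival_days,
               tolerance = 1e-9)
})
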