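test_that("resampling preserves physical extent and degenerates cleanly", {
  v <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  out <- resample_volume(v, spacing = c(1.5, 1.5, 3.0),
                         target_spacing = c(0.75, 0.75, 3.0))
  expect_equal(dim(out), c(32, 32, 8))
  # constant volume stays constant under interpolation
  cv <- array(4.2, c(8, 8, 8))
  expect_true(all(abs(resample_volume(cv, c(1, 1, 1), c(0.6, 0.8, 1.1)) -
                        4.2) < 1e-12))
  # identity when spacing already matches
  expect_identical(resample_volume(v, c(0.75, 0.75, 3), c(0.75, 0.75, 3)), v)
  expect_error(resample_volume(v, c(1, 1, 1), c(0, 1, 1)), "positive")
  # nearest-neighbour keeps a binary mask binary
  m <- array(sample(0:1, 8 * 8 * 8, TRUE), c(8, 8, 8))
  rm_ <- resample_volume(m, c(1, 1, 1), c(0.7, 0.7, 0.7), "nearest")
  expect_true(all(rm_ %in% 0:1))
})

test_that("intensity normalization maps the ROI to [0,1] around 0.5", {
  set.seed(41)
  v <- array(rnorm(8^3, 50, 10), c(8, 8, 8))
  m <- array(1L, c(8, 8, 8))
  out <- normalize_intensity(v, m)
  expect_true(all(out >= 0 & out <= 1))
  # in-mask mean maps to 0.5 (mean of clipped values stays very close)
  expect_equal(mean(out), 0.5, tolerance = 5e-3)
  # affine intensity invariance is exact
  expect_equal(normalize_intensity(3 * v + 100, m), out, tolerance = 1e-12)
  # +/-3 SD clipping
  v2 <- v
  v2[1] <- 1e6
  expect_equal(normalize_intensity(v2, m)[1], 1)
  # idempotent up to the clipping perturbation
  expect_equal(normalize_intensity(out, m), out, tolerance = 1e-2)
  expect_error(normalize_intensity(array(1, c(4, 4, 4)),
                                   array(1, c(4, 4, 4))), "variance")
  expect_error(normalize_intensity(v, array(0L, c(8, 8, 8))), "empty")
})

test_that("wavelet bands: hand-computed Haar on a 2x2x2 block", {
  v <- array(1:8, c(2, 2, 2))
  wb <- wavelet_bands(v, "haar")
  expect_equal(names(wb),
               c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  s <- sqrt(2)^3
  # x varies fastest (1,2), then y (+2), then z (+4)
  expect_equal(as.vector(wb$LLL), sum(1:8) / s)
  expect_equal(as.vector(wb$HLL), ((1 - 2) + (3 - 4) + (5 - 6) + (7 - 8)) / s)
  expect_equal(as.vector(wb$LHL), ((1 + 2) - (3 + 4) + (5 + 6) - (7 + 8)) / s)
  expect_equal(as.vector(wb$LLH), ((1 + 2 + 3 + 4) - (5 + 6 + 7 + 8)) / s)
  expect_equal(as.vector(wb$HHH), ((1 - 2) - (3 - 4) - ((5 - 6) - (7 - 8))) / s)
})

test_that("wavelet transform conserves energy and kills constants", {
  set.seed(42)
  v <- array(rnorm(8 * 6 * 4), c(8, 6, 4))
  for (fam in c("haar", "d4")) {
    wb <- wavelet_bands(v, fam)
    expect_equal(sum(vapply(wb, function(b) sum(b^2), numeric(1))),
                 sum(v^2), tolerance = 1e-10)
  }
  const <- array(3, c(4, 4, 4))
  wb <- wavelet_bands(const, "haar")
  for (b in setdiff(names(wb), "LLL"))
    expect_true(all(abs(wb[[b]]) < 1e-12))
  expect_error(wavelet_bands(array(1, c(1, 4, 4))), ">= 2")
})

test_that("first-order statistics match direct arithmetic", {
  f <- first_order_features(c(1, 2, 3, 4), n_bins = 4)
  expect_equal(unname(f["Entropy"]), 2)          # uniform over 4 bins
  expect_equal(unname(f["Uniformity"]), 0.25)
  expect_equal(unname(f["Mean"]), 2.5)
  expect_equal(unname(f["Root mean square"]), sqrt(7.5))
  expect_equal(unname(f["Third quartile"]), 3.25)
  cst <- first_order_features(rep(2, 10))
  expect_equal(unname(cst[c("Variance", "Range", "Skewness")]), c(0, 0, 0))
  expect_error(first_order_features(1), "at least 2")
  # permutation invariance of the ROI values
  set.seed(43)
  v <- rnorm(50)
  expect_equal(first_order_features(v), first_order_features(sample(v)))
  # agreement with a literal oracle
  o <- oracle_first_order(v, 32)
  f2 <- first_order_features(v, 32)
  expect_equal(f2[names(o)], o, tolerance = 1e-12)
})

test_that("GLRLM features match hand-enumerated runs", {
  # 2D slab rows (1,1,2) and (2,2,2): runs (1,2),(2,1),(2,3)
  q <- array(NA_integer_, c(3, 2, 1))
  q[, 1, 1] <- c(1L, 1L, 2L)
  q[, 2, 1] <- c(2L, 2L, 2L)
  f <- glrlm_features(q, directions = list(c(1, 0, 0)))
  expect_equal(unname(f["SRE"]), (1 / 4 + 1 + 1 / 9) / 3, tolerance = 1e-12)
  expect_equal(unname(f["LRHGLE"]), (1 * 4 + 4 * 1 + 4 * 9) / 3)
  # checkerboard: every run has length 1
  cb <- array((seq_len(64) %% 2) + 1L, c(4, 4, 4))
  expect_equal(unname(glrlm_features(cb, list(c(1, 0, 0)))["SRE"]), 1)
})

test_that("constant ROI minimizes SRE and maximizes LRHGLE over 2-level cubes", {
  vols <- all_two_level_volumes(c(2, 2, 2))
  sre <- vapply(vols, function(v)
    glrlm_features(v, list(c(1, 0, 0)))["SRE"], numeric(1))
  lrh <- vapply(vols, function(v)
    glrlm_features(v, list(c(1, 0, 0)))["LRHGLE"], numeric(1))
  const_hi <- which(vapply(vols, function(v) all(v == 2L), logical(1)))
  expect_equal(sre[const_hi], min(sre), ignore_attr = TRUE)
  expect_equal(lrh[const_hi], max(lrh), ignore_attr = TRUE)
})

test_that("texture features agree with brute-force oracles on random volumes", {
  set.seed(44)
  dirs <- directions_3d()
  for (rep in 1:10) {
    dims <- c(sample(2:4, 1), sample(2:4, 1), sample(2:3, 1))
    q <- array(sample(1:3, prod(dims), TRUE), dims)
    q[sample(length(q), round(length(q) * 0.2))] <- NA  # ragged ROI
    if (all(is.na(q))) next
    for (d in dirs[sample(13, 3)]) {
      o <- oracle_glrlm(q, d)
      if (is.null(o)) next
      f <- glrlm_features(q, list(d))
      expect_equal(f[names(o)], o, tolerance = 1e-12,
                   info = paste(dims, collapse = "x"))
      oi <- oracle_imc1(q, d)
      if (!is.null(oi) && sum(!is.na(q)) > 1 &&
          length(unique(stats::na.omit(as.vector(q)))) > 1) {
        expect_equal(suppressWarnings(glcm_imc1(q, 1, list(d))), oi,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("IMC1 hits its analytic anchors", {
  # independent pairs: sequence 1,1,2,2,1 gives the uniform joint table
  q <- array(c(1L, 1L, 2L, 2L, 1L), c(5, 1, 1))
  expect_equal(glcm_imc1(q, 1, list(c(1, 0, 0))), 0, tolerance = 1e-12)
  # perfectly dependent two-level stripes
  st <- array(NA_integer_, c(4, 4, 2))
  for (j in 1:4) st[, j, ] <- ifelse(j %% 2 == 0, 2L, 1L)
  expect_equal(glcm_imc1(st, 1, list(c(0, 1, 0))), -1)
  # constant ROI degenerates to 0 with a warning
  expect_warning(z <- glcm_imc1(array(1L, c(3, 3, 3))), "degenerate")
  expect_equal(z, 0)
})

test_that("shape features: voxel, cube and the isoperimetric bound", {
  expect_equal(unname(shape_features(array(1L, c(1, 1, 1)),
                                     c(1, 1, 1))["Volume"]), 1)
  cube <- shape_features(array(1L, c(5, 5, 5)), c(1, 1, 1))
  expect_equal(unname(cube["Sphericity"]), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)
  set.seed(45)
  for (rep in 1:5) {
    m <- array(0L, c(6, 6, 6))
    m[2:5, 2:5, 2:5] <- rbinom(64, 1, 0.7)
    if (sum(m) == 0) next
    expect_lte(unname(shape_features(m, c(1, 1, 2))["Sphericity"]), 1)
  }
  expect_error(shape_features(array(0L, c(3, 3, 3))), "empty")
})

test_that("features are invariant under voxel traversal order", {
  set.seed(46)
  v <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
  m <- array(1L, c(6, 6, 6))
  q <- quantize_roi(v, m, 8)
  f1 <- glrlm_features(q)           # all 13 directions
  perm <- c(2, 3, 1)
  f2 <- glrlm_features(aperm(q, perm))
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_equal(glcm_imc1(q), glcm_imc1(aperm(q, perm)), tolerance = 1e-12)
})

test_that("extract_all composes names, honors band toggle and restriction", {
  set.seed(47)
  v <- array(rnorm(12 * 12 * 8, 10, 2), c(12, 12, 8))
  m <- array(0L, c(12, 12, 8))
  m[3:10, 3:10, 2:7] <- 1L
  cfg_nb <- radiomics_config(bands = FALSE)
  f_nb <- extract_all(v, m, cfg_nb)
  expect_true(all(grepl("^none_none_", names(f_nb))))
  f_all <- extract_all(v, m, radiomics_config())
  expect_true("LLL_none_Median" %in% names(f_all))
  expect_true(all(is.finite(f_all)))
  expect_false(anyDuplicated(names(f_all)) > 0)
  # deterministic
  expect_identical(extract_all(v, m, radiomics_config()), f_all)
  # class proportions sum to 100
  expect_equal(sum(feature_class_summary(names(f_all))), 100)
  # restriction reproduces the full computation on the requested names
  pick <- c("none_none_Median", "HHL_none_SRE", "LLH_none_IMC1",
            "none_none_Sphericity")
  f_r <- extract_all(v, m, radiomics_config(features = pick))
  expect_equal(f_r, f_all[pick])
  expect_error(extract_all(v, array(1L, c(4, 4, 4)), radiomics_config()),
               "mismatch")
  # a named transform hook shows up in feature names
  f_t <- extract_all(v, m, radiomics_config(bands = FALSE,
                                            transform = identity,
                                            transform_name = "SIFT"))
  expect_true("none_SIFT_Median" %in% names(f_t))
})

test_that("quantization covers the ROI with the requested levels", {
  v <- array(seq(0, 1, length.out = 27), c(3, 3, 3))
  m <- array(1L, c(3, 3, 3))
  q <- quantize_roi(v, m, 4)
  expect_equal(sort(unique(as.vector(q))), 1:4)
  expect_true(all(is.na(quantize_roi(v, array(0:1, c(3, 3, 3)), 4)[
    array(0:1, c(3, 3, 3)) == 0])))
  expect_equal(unique(as.vector(quantize_roi(array(2, c(3, 3, 3)), m, 8))), 1L)
})
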