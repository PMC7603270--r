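test_that("stage 1 removes features missing/zero in more than 90% of samples", {
  set.seed(51)
  X <- matrix(rnorm(100 * 3), 100, 3,
              dimnames = list(NULL, c("f91", "f90", "clean")))
  X[1:91, "f91"] <- 0
  X[1:90, "f90"] <- 0
  s <- stage1_missing_zero(X)
  expect_false("f91" %in% s$kept)      # 91% zero: removed
  expect_true("f90" %in% s$kept)       # exactly 90%: strict inequality keeps
  expect_true("clean" %in% s$kept)
  # NA counts like zero
  X2 <- X
  X2[1:95, "clean"] <- NA
  expect_false("clean" %in% stage1_missing_zero(X2)$kept)
  # ledger conservation
  expect_setequal(s$ledger$feature, colnames(X))
  expect_error(stage1_missing_zero(X, 0), "threshold")
  expect_error(stage1_missing_zero(matrix(numeric(0), 0, 0)), "empty")
})

# Small two-platform fixture: a latent binary state drives one gene set
# and the "signal" feature on both platforms; "flipped" correlates with
# opposite signs; "noise" is independent.
make_stage2_fixture <- function(n = 120, seed = 52) {
  set.seed(seed)
  state <- rbinom(n, 1, 0.5)
  ids <- sprintf("s%03d", seq_len(n))
  genes <- sprintf("g%02d", 1:12)
  catalog <- metagene_catalog(list(CTL = genes[1:3], aDC = genes[4:6],
                                   Treg = genes[7:9], MDSC = genes[10:12]))
  base <- function() {
    e <- matrix(rnorm(12 * n), 12, n, dimnames = list(genes, ids))
    e[1:3, ] <- e[1:3, ] + 2 * rep(state, each = 3)
    e
  }
  er <- base()
  ea <- base()
  sig <- state + rnorm(n, sd = 0.5)
  feats <- cbind(signal = sig, flipped = sig, noise = rnorm(n))
  rownames(feats) <- ids
  # make "flipped" correlate negatively with the array platform only:
  # flip the array expression of the set genes around their mean
  ea_f <- ea
  ea_f[1:3, ] <- 2 * rowMeans(ea[1:3, ]) - ea[1:3, ]
  list(feats = feats, er = er, ea = ea, ea_f = ea_f, catalog = catalog)
}

test_that("stage 2 requires sign agreement across platforms", {
  fx <- make_stage2_fixture()
  s <- stage2_cross_platform_consistency(fx$feats, fx$er, fx$ea, fx$catalog)
  expect_true("signal" %in% s$kept)
  expect_false("noise" %in% s$kept)
  # same feature, but the array platform carries the anti-correlated set
  s2 <- stage2_cross_platform_consistency(
    fx$feats[, "flipped", drop = FALSE], fx$er, fx$ea_f, fx$catalog)
  expect_false("flipped" %in% s2$kept)
  # ledger covers every input feature
  expect_setequal(s$ledger$feature, colnames(fx$feats))
})

test_that("pure-noise features are removed at n = 200", {
  removed <- vapply(1:10, function(k) {
    set.seed(520 + k)
    n <- 200
    ids <- sprintf("s%03d", 1:n)
    genes <- sprintf("g%02d", 1:8)
    catalog <- metagene_catalog(list(CTL = genes[1:2], aDC = genes[3:4],
                                     Treg = genes[5:6], MDSC = genes[7:8]))
    er <- matrix(rnorm(8 * n), 8, n, dimnames = list(genes, ids))
    ea <- matrix(rnorm(8 * n), 8, n, dimnames = list(genes, ids))
    feats <- matrix(rnorm(n), n, 1, dimnames = list(ids, "noise"))
    !("noise" %in% stage2_cross_platform_consistency(feats, er, ea,
                                                     catalog)$kept)
  }, logical(1))
  expect_gte(mean(removed), 0.95)
})

test_that("information gain matches hand entropy arithmetic", {
  # split {0,0,1} vs {1}: IG = 1 - (3/4) H(1/3)
  expect_equal(information_gain(c(0, 0.1, 0.4, 1), c(0, 0, 1, 1), n_bins = 2),
               1 - (3 / 4) * (-(1 / 3) * log2(1 / 3) - (2 / 3) * log2(2 / 3)),
               tolerance = 1e-10)
  # X identical to Y: IG = H(Y) = 1 bit for balanced labels
  y <- rep(0:1, each = 10)
  expect_equal(information_gain(y, y, n_bins = 2), 1)
  # independent feature: IG near 0 for large n
  set.seed(53)
  expect_lt(information_gain(rnorm(5000), rbinom(5000, 1, 0.5)), 0.01)
  # bounds: 0 <= IG <= H(Y)
  for (k in 1:10) {
    x <- rnorm(40)
    yy <- rbinom(40, 1, 0.3)
    if (length(unique(yy)) < 2) next
    ig <- information_gain(x, yy)
    hy <- -sum(table(yy) / 40 * log2(table(yy) / 40))
    expect_gte(ig, 0)
    expect_lte(ig, hy + 1e-12)
  }
  expect_equal(information_gain(rep(1, 10), rep(0:1, 5)), 0)
})

test_that("stage 3 keeps label-aligned features and drops independent ones", {
  set.seed(54)
  n <- 200
  y <- rep(c("low", "high"), each = n / 2)
  X <- cbind(perfect = as.integer(y == "high"),
             good = as.integer(y == "high") + rnorm(n, sd = 0.8),
             junk1 = rnorm(n), junk2 = rnorm(n), junk3 = rnorm(n))
  rownames(X) <- sprintf("s%03d", 1:n)
  s <- stage3_importance(X, y, seed = 5)
  expect_equal(s$kept[1], "perfect")
  expect_false(any(c("junk1", "junk2", "junk3") %in% s$kept))
  expect_setequal(s$ledger$feature, colnames(X))
  # determinism
  s2 <- stage3_importance(X, y, seed = 5)
  expect_identical(s$kept, s2$kept)
  expect_error(stage3_importance(X, rep("low", n)), "single class")
})

test_that("the full filter keeps a conserved, non-increasing ledger", {
  fx <- make_stage2_fixture(n = 60, seed = 55)
  lv <- matrix(sample(c("low", "high"), 60 * 4, TRUE), 60, 4,
               dimnames = list(rownames(fx$feats),
                               c("CTL", "aDC", "Treg", "MDSC")))
  # ensure both classes per subset
  lv[1:2, ] <- "low"
  lv[3:4, ] <- "high"
  rep_ <- select_features(fx$feats, fx$er, fx$ea, fx$catalog, lv, seed = 9)
  cnt <- rep_$counts
  expect_true(all(diff(unname(cnt)) <= 0))
  expect_setequal(rep_$stage1$feature, colnames(fx$feats))
  expect_setequal(rep_$stage2$feature, rep_$stage1$feature[rep_$stage1$kept])
  for (s in names(rep_$stage3)) {
    expect_setequal(rep_$stage3[[s]]$feature,
                    rep_$stage2$feature[rep_$stage2$kept])
    expect_true(all(rep_$selected[[s]] %in% rep_$stage2$feature))
  }
  # determinism for a fixed seed
  rep2 <- select_features(fx$feats, fx$er, fx$ea, fx$catalog, lv, seed = 9)
  expect_identical(rep_$selected, rep2$selected)
  # report writing
  dir <- withr::local_tempdir()
  write_filter_report(rep_, dir)
  expect_true(file.exists(file.path(dir, "filter_ledger.csv")))
  expect_true(file.exists(file.path(dir, "filter_summary.json")))
})
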