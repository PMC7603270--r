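#' Three-stage radiomic feature filter
#'
#' Candidate features pass three gates: (1) removal of features missing
#' or zero in more than 90% of samples; (2) cross-platform stability of
#' the feature-to-metagene correlation (same sign and magnitude floor on
#' both expression platforms); (3) per-subset importance, requiring a
#' positive random-forest mean-decrease-in-Gini and an information gain
#' at or above the mean of positive gains (median fallback). Every stage
#' logs a kept/removed reason per feature in a ledger.
#'
#' @name feature_selection
NULL

#' Stage 1: drop features that are mostly missing or zero
#'
#' A feature is removed iff the fraction of samples in which it is
#' missing (`NA`) or exactly zero is strictly greater than `threshold`.
#'
#' @param features samples x features numeric matrix.
#' @param threshold fraction in (0, 1\], default 0.90.
#' @return list: `kept` (surviving feature names) and `ledger` (data
#'   frame feature/kept/reason).
#' @export
stage1_missing_zero <- function(features, threshold = 0.90) {
  if (length(features) == 0 || nrow(features) == 0) stop("empty feature table")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  frac <- colMeans(is.na(features) | features == 0)  # TRUE|NA is TRUE, so NA counts as missing
  removed <- frac > threshold
  ledger <- data.frame(
    feature = colnames(features), kept = !removed,
    reason = ifelse(removed,
                    sprintf("missing_or_zero_fraction=%.3f>%.2f", frac, threshold),
                    "ok"),
    stringsAsFactors = FALSE)
  list(kept = colnames(features)[!removed], ledger = ledger)
}

#' Stage 2: cross-platform consistency of feature-gene correlations
#'
#' For every feature and every catalog gene measured on both platforms,
#' the correlation between feature values and gene expression is
#' computed across the samples shared with each platform. Under the
#' default `per_set_median` strategy a feature survives iff, for at
#' least one gene set, the median per-gene correlation has the same sign
#' on both platforms and `|median| >= min_abs` on both. `per_gene_all`
#' requires every set gene to agree individually; `overall` uses the
#' median over all catalog genes.
#'
#' @param features samples x features matrix (rownames = sample ids).
#' @param expr_rnaseq,expr_array genes x samples expression matrices
#'   (log-scale recommended for rnaseq; see [log_fpkm()]).
#' @param catalog a [metagene_catalog()].
#' @param method correlation type, default `"spearman"`.
#' @param min_abs magnitude floor for the summarized correlation
#'   (default 0.2).
#' @param strategy consistency rule (see above).
#' @return list: `kept`, `ledger`, and `summary` (per feature x set the
#'   summarized correlation on each platform).
#' @export
stage2_cross_platform_consistency <- function(features, expr_rnaseq, expr_array,
                                              catalog, method = "spearman",
                                              min_abs = 0.2,
                                              strategy = c("per_set_median",
                                                           "per_gene_all",
                                                           "overall")) {
  strategy <- match.arg(strategy)
  expr_rnaseq <- as.matrix(unclass(expr_rnaseq))
  expr_array <- as.matrix(unclass(expr_array))
  genes <- intersect(rownames(expr_rnaseq), rownames(expr_array))
  catalog <- suppressWarnings(restrict_catalog(catalog, genes))
  cor_platform <- function(expr) {
    shared <- intersect(rownames(features), colnames(expr))
    if (length(shared) < 5) stop("fewer than 5 shared samples with a platform")
    gset <- unique(unlist(catalog))
    cor(features[shared, , drop = FALSE], t(expr[gset, shared, drop = FALSE]),
        method = method)  # features x genes
  }
  cr <- cor_platform(expr_rnaseq)
  ca <- cor_platform(expr_array)
  feats <- colnames(features)
  kept <- logical(length(feats))
  reason <- character(length(feats))
  summ <- list()
  for (k in seq_along(feats)) {
    ok_sets <- character(0)
    for (s in names(catalog)) {
      g <- catalog[[s]]
      if (strategy == "per_gene_all") {
        r1 <- cr[k, g]; r2 <- ca[k, g]
        ok <- all(sign(r1) == sign(r2)) && all(abs(r1) >= min_abs) &&
          all(abs(r2) >= min_abs)
        m1 <- median(r1); m2 <- median(r2)
      } else {
        gg <- if (strategy == "overall") unique(unlist(catalog)) else g
        m1 <- median(cr[k, gg]); m2 <- median(ca[k, gg])
        ok <- sign(m1) == sign(m2) && sign(m1) != 0 &&
          abs(m1) >= min_abs && abs(m2) >= min_abs
      }
      summ[[length(summ) + 1L]] <- data.frame(
        feature = feats[k], set = s, cor_rnaseq = m1, cor_array = m2,
        consistent = ok, stringsAsFactors = FALSE)
      if (ok) ok_sets <- c(ok_sets, s)
      if (strategy == "overall") break
    }
    kept[k] <- length(ok_sets) > 0
    reason[k] <- if (kept[k])
      paste0("consistent:", paste(ok_sets, collapse = "+"))
    else "no_set_with_cross_platform_sign_and_magnitude_agreement"
  }
  list(kept = feats[kept],
       ledger = data.frame(feature = feats, kept = kept, reason = reason,
                           stringsAsFactors = FALSE),
       summary = do.call(rbind, summ))
}

#' Information gain of a feature about a binary label
#'
#' `IG = H(Y) - H(Y|X)` in bits, with `X` discretized into `n_bins`
#' equal-width bins over its range (constant features give IG 0).
#'
#' @param x numeric feature values.
#' @param y binary labels (any two-valued vector).
#' @param n_bins number of equal-width bins (default 10).
#' @return non-negative information gain in bits.
#' @export
information_gain <- function(x, y, n_bins = 10) {
  if (length(x) < 2 || length(x) != length(y)) stop("need n >= 2 paired values")
  y <- as.integer(factor(y))
  hy <- entropy_bits(tabulate(y) / length(y))
  rng <- range(x)
  if (diff(rng) == 0) return(0)
  bins <- pmin(floor((x - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
  hyx <- 0
  for (b in unique(bins)) {
    idx <- bins == b
    hyx <- hyx + mean(idx) * entropy_bits(tabulate(y[idx]) / sum(idx))
  }
  max(hy - hyx, 0)
}

#' Stage 3: importance filter (random forest + information gain)
#'
#' Per subset, a feature survives iff its random-forest
#' mean-decrease-in-Gini importance is strictly positive (500 trees,
#' seeded) and its information gain is positive and at least the cutoff,
#' where the cutoff is the mean of the positive gains, falling back to
#' the median of positive gains if the mean selects none. Survivors are
#' ranked by descending gain.
#'
#' @param features samples x features matrix.
#' @param labels binary label vector (both classes present), e.g. one
#'   subset's high/low levels.
#' @param seed seed for the forest.
#' @param n_trees forest size (default 500).
#' @param n_bins discretization bins for the gain (default 10).
#' @return list: `kept` (ranked), `ledger`, `importance` (data frame
#'   feature/gini/gain).
#' @export
stage3_importance <- function(features, labels, seed = 1L, n_trees = 500,
                              n_bins = 10) {
  y <- factor(labels)
  if (nlevels(y) < 2) stop("labels contain a single class")
  rf <- with_seed(seed, randomForest::randomForest(
    x = as.data.frame(features), y = y, ntree = n_trees))
  gini <- rf$importance[, "MeanDecreaseGini"]
  gain <- apply(features, 2, information_gain, y = y, n_bins = n_bins)
  pos <- gain[gain > 0]
  cutoff <- if (length(pos)) mean(pos) else Inf
  sel <- gini > 0 & gain > 0 & gain >= cutoff
  if (!any(sel) && length(pos)) {
    cutoff <- median(pos)
    sel <- gini > 0 & gain > 0 & gain >= cutoff
  }
  reason <- ifelse(sel, "ok",
            ifelse(gini <= 0, "gini_importance<=0",
            ifelse(gain <= 0, "information_gain<=0",
                   sprintf("gain<cutoff=%.4f", cutoff))))
  kept <- names(sort(gain[sel], decreasing = TRUE))
  list(kept = kept,
       ledger = data.frame(feature = colnames(features), kept = unname(sel),
                           reason = unname(reason), stringsAsFactors = FALSE),
       importance = data.frame(feature = colnames(features),
                               gini = unname(gini), gain = unname(gain),
                               stringsAsFactors = FALSE))
}

#' Run the full three-stage filter for all four subsets
#'
#' @param features samples x features matrix.
#' @param expr_rnaseq,expr_array genes x samples expression matrices.
#' @param catalog a [metagene_catalog()].
#' @param levels samples x 4 high/low matrix ([binarize_levels()]).
#' @param seed seed for stage 3.
#' @param stage1_threshold,min_abs,strategy stage parameters.
#' @return a `feature_filter_report`: per-stage ledgers and counts plus
#'   per-subset selected (ranked) feature names.
#' @export
select_features <- function(features, expr_rnaseq, expr_array, catalog,
                            levels, seed = 1L, stage1_threshold = 0.90,
                            min_abs = 0.2, strategy = "per_set_median") {
  s1 <- stage1_missing_zero(features, stage1_threshold)
  f1 <- features[, s1$kept, drop = FALSE]
  s2 <- stage2_cross_platform_consistency(f1, expr_rnaseq, expr_array,
                                          catalog, min_abs = min_abs,
                                          strategy = strategy)
  f2 <- f1[, s2$kept, drop = FALSE]
  lv <- as.matrix(levels)[rownames(features), , drop = FALSE]
  per_subset <- list()
  s3_ledgers <- list()
  for (s in SUBSETS) {
    s3 <- stage3_importance(f2, lv[, s], seed = seed)
    per_subset[[s]] <- s3$kept
    s3_ledgers[[s]] <- s3$ledger
  }
  counts <- c(input = ncol(features), stage1 = ncol(f1), stage2 = ncol(f2))
  structure(list(stage1 = s1$ledger, stage2 = s2$ledger,
                 stage3 = s3_ledgers, selected = per_subset,
                 counts = counts, stage2_summary = s2$summary),
            class = "feature_filter_report")
}

#' @export
print.feature_filter_report <- function(x, ...) {
  cat("<feature_filter_report>\n")
  cat(sprintf("  features: %d -> stage1 %d -> stage2 %d\n",
              x$counts["input"], x$counts["stage1"], x$counts["stage2"]))
  for (s in names(x$selected))
    cat(sprintf("  %s: %d selected\n", s, length(x$selected[[s]])))
  invisible(x)
}

#' Write the filter report as a CSV ledger plus JSON count summary
#'
#' @param report a `feature_filter_report`.
#' @param dir output directory (created if needed).
#' @export
write_filter_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  led <- rbind(
    cbind(stage = "stage1_missing_zero", subset = NA, report$stage1),
    cbind(stage = "stage2_cross_platform", subset = NA, report$stage2),
    do.call(rbind, lapply(names(report$stage3), function(s)
      cbind(stage = "stage3_importance", subset = s, report$stage3[[s]]))))
  write.csv(led, file.path(dir, "filter_ledger.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(counts = as.list(report$counts),
         selected = lapply(report$selected, identity)),
    file.path(dir, "filter_summary.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
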