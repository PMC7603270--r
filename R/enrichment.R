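#' Single-sample gene-set enrichment
#'
#' Per-sample enrichment of each immune subset is scored with the classic
#' GSEA running-sum statistic computed on the sample's own expression
#' ranking, normalized against a random-gene-set permutation null (NES),
#' binarized to high/low by a cohort-median split and rescaled to
#' immunogram scores on \[0, 5\].
#'
#' @name enrichment
NULL

#' GSEA running-sum enrichment score
#'
#' Genes are ranked in descending expression order. Walking down the
#' ranking, `P_hit` accumulates `|value|^weight` over set members
#' (normalized by the members' total) and `P_miss` accumulates uniformly
#' over non-members; the score is the signed maximum-magnitude deviation
#' of `P_hit - P_miss`. With `weight = 0` the statistic is a pure
#' Kolmogorov-Smirnov deviation in \[-1, 1\].
#'
#' @param ranked_values named numeric vector, sorted in descending order
#'   (names are gene ids).
#' @param gene_set character vector of member gene ids; must intersect the
#'   ranking.
#' @param weight non-negative weighting exponent on `|value|` (default 1).
#' @return signed enrichment score. When the set covers every ranked gene
#'   the score is `+1` by convention (the miss walk is undefined).
#' @export
enrichment_score <- function(ranked_values, gene_set, weight = 1) {
  genes <- names(ranked_values)
  if (is.null(genes)) stop("ranked_values must be named by gene id")
  if (anyDuplicated(genes)) stop("duplicate genes in ranking")
  if (is.unsorted(rev(ranked_values))) stop("values must be ranked descending")
  hit <- genes %in% gene_set
  m <- sum(hit)
  n <- length(genes)
  if (m == 0L) stop("gene set does not intersect the ranking")
  if (m == n) return(1)
  es_kernel(abs(ranked_values)^weight, which(hit), n)
}

# Lean running-sum kernel: `absw` are |value|^weight in ranking order,
# `pos` the sorted hit positions. The deviation P_hit - P_miss is
# piecewise linear, so its extremes occur at hit positions (candidate
# maxima) or just before them (candidate minima).
es_kernel <- function(absw, pos, n) {
  m <- length(pos)
  w <- absw[pos]
  tw <- sum(w)
  # all-zero weights (flat tail of zeros): fall back to uniform hit steps
  cw <- if (tw > 0) cumsum(w) / tw else seq_len(m) / m
  miss <- (pos - seq_len(m)) / (n - m)
  at_hit <- cw - miss
  before_hit <- c(0, cw[-m]) - miss
  hi <- max(at_hit)
  lo <- min(before_hit, 0)
  # equal-magnitude extremes resolve to the positive deviation; the
  # tolerance absorbs floating-point ties in the running sums
  unname(if (hi >= -lo - 1e-9) hi else lo)
}

#' Rank a sample's expression vector for enrichment scoring
#'
#' @param values numeric vector named by gene id.
#' @return named vector sorted descending (ties keep input order).
#' @export
rank_sample <- function(values) {
  if (is.null(names(values))) stop("values must be named by gene id")
  sort(values, decreasing = TRUE)
}

#' Normalized enrichment score
#'
#' Divides the observed enrichment score by the mean absolute score of
#' size-matched random gene sets drawn from the same ranking, preserving
#' sign. Deterministic for a fixed seed.
#'
#' @inheritParams enrichment_score
#' @param n_permutations number of random sets (>= 100; default 1000).
#' @param seed integer seed for the permutation draw.
#' @return normalized enrichment score.
#' @export
nes <- function(ranked_values, gene_set, weight = 1, n_permutations = 1000,
                seed = 1L) {
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  if (length(unique(ranked_values)) == 1L)
    stop("constant expression vector: enrichment undefined")
  es <- enrichment_score(ranked_values, gene_set, weight)
  m <- sum(names(ranked_values) %in% gene_set)
  n <- length(ranked_values)
  if (m == n) return(sign(es) * 1)
  absw <- abs(ranked_values)^weight
  null_es <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      es_kernel(absw, sort.int(sample.int(n, m)), n)
    }, numeric(1))
  })
  denom <- mean(abs(null_es))
  if (denom == 0) stop("degenerate permutation null (all null scores zero)")
  es / denom
}

#' Score a cohort: NES matrix for the four subsets
#'
#' Computes per-sample NES for each catalog subset from a genes x samples
#' expression matrix (values are ranked per sample; FPKM data should be
#' log-transformed first, see [log_fpkm()]).
#'
#' @param values genes x samples numeric matrix with dimnames.
#' @param catalog a [metagene_catalog()]; genes absent from the matrix are
#'   dropped via [restrict_catalog()].
#' @param weight GSEA weighting exponent.
#' @param n_permutations,seed permutation-null settings (the per-sample
#'   seed is derived deterministically from `seed`).
#' @return samples x 4 NES matrix (columns CTL, aDC, Treg, MDSC).
#' @export
score_cohort <- function(values, catalog, weight = 1, n_permutations = 1000,
                         seed = 1L) {
  values <- as.matrix(unclass(values))
  catalog <- suppressWarnings(restrict_catalog(catalog, rownames(values)))
  out <- matrix(NA_real_, ncol(values), length(SUBSETS),
                dimnames = list(colnames(values), SUBSETS))
  for (j in seq_len(ncol(values))) {
    ranked <- rank_sample(values[, j])
    for (s in SUBSETS) {
      out[j, s] <- nes(ranked, catalog[[s]], weight, n_permutations,
                       seed = seed + j - 1L)
    }
  }
  out
}

#' Binarize cohort NES to high/low levels
#'
#' Per subset, samples strictly above the cohort median are "high"; ties
#' (including an all-equal column) are "low".
#'
#' @param nes_matrix samples x subsets numeric matrix.
#' @return character matrix of `"low"`/`"high"`, same dimnames.
#' @export
binarize_levels <- function(nes_matrix) {
  nes_matrix <- as.matrix(nes_matrix)
  if (nrow(nes_matrix) < 2) stop("need at least 2 samples")
  out <- nes_matrix
  out[] <- "low"
  for (j in seq_len(ncol(nes_matrix))) {
    out[nes_matrix[, j] > median(nes_matrix[, j]), j] <- "high"
  }
  out
}

#' Immunogram scores
#'
#' Per-subset min-max rescaling of NES to \[0, 5\] for radar-chart display.
#' A subset with zero NES range maps to 2.5 everywhere with a warning.
#'
#' @param nes_matrix samples x subsets numeric matrix.
#' @return numeric matrix of IGS values in \[0, 5\].
#' @export
immunogram_scores <- function(nes_matrix) {
  nes_matrix <- as.matrix(nes_matrix)
  if (nrow(nes_matrix) < 2) stop("need at least 2 samples")
  out <- nes_matrix
  for (j in seq_len(ncol(nes_matrix))) {
    rng <- range(nes_matrix[, j])
    if (diff(rng) == 0) {
      warning("zero NES range for subset ", colnames(nes_matrix)[j],
              "; IGS set to 2.5")
      out[, j] <- 2.5
    } else {
      out[, j] <- 5 * (nes_matrix[, j] - rng[1]) / diff(rng)
    }
  }
  out
}

#' Assemble per-sample enrichment profiles
#'
#' @param nes_matrix samples x 4 NES matrix from [score_cohort()].
#' @return data frame with one row per sample: NES, IGS and level per
#'   subset (`ctl_nes`, `ctl_igs`, `ctl_level`, ...).
#' @export
enrichment_profiles <- function(nes_matrix) {
  lv <- binarize_levels(nes_matrix)
  igs <- immunogram_scores(nes_matrix)
  df <- data.frame(sample_id = rownames(nes_matrix), stringsAsFactors = FALSE)
  for (s in SUBSETS) {
    p <- tolower(s)
    df[[paste0(p, "_nes")]] <- nes_matrix[, s]
    df[[paste0(p, "_igs")]] <- igs[, s]
    df[[paste0(p, "_level")]] <- lv[, s]
  }
  rownames(df) <- NULL
  df
}

#' Write the immunogram (radar-chart) table as CSV
#'
#' @param profiles output of [enrichment_profiles()].
#' @param path CSV path.
#' @export
write_igs_csv <- function(profiles, path) {
  cols <- c("sample_id",
            paste0(tolower(SUBSETS), "_igs"),
            paste0(tolower(SUBSETS), "_level"))
  write.csv(profiles[, cols], path, row.names = FALSE)
  invisible(path)
}
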