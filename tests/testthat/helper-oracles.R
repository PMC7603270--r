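# Independent brute-force oracles, written from the definitions with
# naive loops. They must never share code with the package internals.

# Full running-sum GSEA score: evaluates the deviation at every ranking
# position by explicit accumulation.
oracle_es <- function(ranked_values, gene_set, weight = 0) {
  genes <- names(ranked_values)
  hit <- genes %in% gene_set
  nh <- sum(abs(ranked_values[hit])^weight)
  if (nh == 0) nh <- sum(hit)  # uniform fallback for all-zero weights
  p_hit <- 0
  p_miss <- 0
  hi <- 0
  lo <- 0
  for (i in seq_along(genes)) {
    if (hit[i]) {
      w <- abs(ranked_values[i])^weight
      p_hit <- p_hit + (if (sum(abs(ranked_values[hit])^weight) > 0)
        w / sum(abs(ranked_values[hit])^weight) else 1 / sum(hit))
    } else {
      p_miss <- p_miss + 1 / sum(!hit)
    }
    dev <- unname(p_hit - p_miss)
    hi <- max(hi, dev)
    lo <- min(lo, dev)
  }
  # equal-magnitude extremes resolve to the positive deviation (same
  # convention as the implementation); tolerance absorbs float ties
  if (hi >= -lo - 1e-9) hi else lo
}

# Run-length features by walking every line voxel-by-voxel.
oracle_glrlm <- function(q, d) {
  dims <- dim(q)
  inb <- function(p) all(p >= 1) && all(p <= dims)
  runs <- list()
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3])) {
      p <- c(x, y, z)
      prev <- p - d
      # start of a line only if the previous voxel is outside the array
      if (inb(prev)) next
      cur_val <- NA
      cur_len <- 0
      while (inb(p)) {
        v <- q[p[1], p[2], p[3]]
        if (!is.na(v) && !is.na(cur_val) && v == cur_val) {
          cur_len <- cur_len + 1
        } else {
          if (!is.na(cur_val)) runs[[length(runs) + 1]] <- c(cur_val, cur_len)
          cur_val <- v
          cur_len <- if (is.na(v)) 0 else 1
        }
        p <- p + d
      }
      if (!is.na(cur_val)) runs[[length(runs) + 1]] <- c(cur_val, cur_len)
    }
  m <- do.call(rbind, runs)
  if (is.null(m)) return(NULL)
  i <- m[, 1]
  j <- m[, 2]
  nr <- nrow(m)
  c(SRE = sum(1 / j^2) / nr,
    LRE = sum(j^2) / nr,
    SRLGLE = sum(1 / (i^2 * j^2)) / nr,
    SRHGLE = sum(i^2 / j^2) / nr,
    LRHGLE = sum(i^2 * j^2) / nr)
}

# GLCM IMC1 by explicit pair enumeration and entropy sums.
oracle_imc1 <- function(q, d) {
  dims <- dim(q)
  pairs <- matrix(0, 0, 2)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3])) {
      p2 <- c(x, y, z) + d
      if (any(p2 < 1) || any(p2 > dims)) next
      a <- q[x, y, z]
      b <- q[p2[1], p2[2], p2[3]]
      if (is.na(a) || is.na(b)) next
      pairs <- rbind(pairs, c(a, b), c(b, a))
    }
  if (nrow(pairs) == 0) return(NULL)
  lev <- sort(unique(as.vector(pairs)))
  P <- matrix(0, length(lev), length(lev))
  for (r in seq_len(nrow(pairs))) {
    i <- match(pairs[r, 1], lev)
    j <- match(pairs[r, 2], lev)
    P[i, j] <- P[i, j] + 1
  }
  P <- P / sum(P)
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  px <- rowSums(P)
  py <- colSums(P)
  if (max(h(px), h(py)) == 0) return(0)
  hxy <- h(as.vector(P))
  hxy1 <- 0
  for (i in seq_along(lev)) for (j in seq_along(lev))
    if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(px[i] * py[j])
  (hxy - hxy1) / max(h(px), h(py))
}

# First-order statistics written out literally.
oracle_first_order <- function(v, n_bins) {
  n <- length(v)
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  rng <- max(v) - min(v)
  if (rng == 0) p <- 1 else {
    b <- floor((v - min(v)) / rng * n_bins) + 1
    b[b > n_bins] <- n_bins
    p <- as.vector(table(factor(b, levels = 1:n_bins))) / n
  }
  pp <- p[p > 0]
  c("Energy" = sum(v^2),
    "Entropy" = -sum(pp * log2(pp)),
    "Mean" = mu,
    "Median" = median(v),
    "Root mean square" = sqrt(sum(v^2) / n),
    "Skewness" = if (m2 > 0) (sum((v - mu)^3) / n) / m2^1.5 else 0,
    "Uniformity" = sum(p^2),
    "Variance" = m2)
}

# AUC by explicit concordant-pair counting.
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Adjusted Rand index for comparing partitions.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# All 2-level volumes of the given dimensions (list of integer arrays).
all_two_level_volumes <- function(dims) {
  n <- prod(dims)
  lapply(seq_len(2^n) - 1, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    array(bits + 1L, dims)
  })
}
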