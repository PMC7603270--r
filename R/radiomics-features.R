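#' Radiomic feature extractors
#'
#' First-order statistics, gray-level run-length (GLRLM) and
#' co-occurrence (GLCM) texture features and shape descriptors, computed
#' per ROI and per wavelet sub-band. Texture features use the 13 unique
#' 3D directions and are averaged over directions (feature-level
#' aggregation, not matrix merging).
#'
#' @name radiomics_features
NULL

FIRST_ORDER_NAMES <- c(
  "Energy", "Entropy", "Maximum", "Mean", "Mean absolute deviation",
  "Median", "Range", "Root mean square", "Skewness", "Standard deviation",
  "Third quartile", "Uniformity", "Variance")

GLRLM_NAMES <- c("SRE", "LRE", "GLN", "RLN", "RP", "LGLRE", "HGLRE",
                 "SRLGLE", "SRHGLE", "LRLGLE", "LRHGLE")

#' The 13 unique 3D displacement directions
#'
#' Unit-step offsets covering every 3D direction up to sign (first
#' nonzero component positive).
#'
#' @return list of 13 integer 3-vectors.
#' @export
directions_3d <- function() {
  list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
       c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
       c(0, 1, 1), c(0, 1, -1),
       c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

#' First-order statistics of ROI intensities
#'
#' Thirteen named statistics of the raw in-ROI values. Entropy and
#' uniformity use an equal-width histogram with `n_bins` bins over the
#' value range (entropy in bits); moments are population moments;
#' skewness of a constant ROI is 0 by convention; the third quartile uses
#' linear interpolation (type-7 quantile).
#'
#' @param values numeric vector of in-ROI voxel intensities (>= 2).
#' @param n_bins histogram bins for entropy/uniformity (default 32).
#' @return named numeric vector of length 13.
#' @export
first_order_features <- function(values, n_bins = 32) {
  if (length(values) < 2) stop("need at least 2 in-ROI voxels")
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  rng <- range(values)
  if (diff(rng) == 0) {
    p <- 1
  } else {
    bins <- pmin(floor((values - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
    p <- tabulate(bins, n_bins) / n
  }
  c("Energy" = sum(values^2),
    "Entropy" = entropy_bits(p),
    "Maximum" = max(values),
    "Mean" = mu,
    "Mean absolute deviation" = mean(abs(values - mu)),
    "Median" = median(values),
    "Range" = diff(rng),
    "Root mean square" = sqrt(mean(values^2)),
    "Skewness" = if (m2 > 0) m3 / m2^1.5 else 0,
    "Standard deviation" = sqrt(m2),
    "Third quartile" = unname(quantile(values, 0.75)),
    "Uniformity" = sum(p^2),
    "Variance" = m2)
}

# Geometry of voxel traversal is value-independent, so the sort order
# that groups voxels into lines along a direction (and the line-break
# flags) is computed once per (dims, direction) and cached.
.geom_cache <- new.env(parent = emptyenv())

line_geometry <- function(dims, d) {
  a <- which(d != 0)[1]
  if (d[a] < 0) d <- -d  # runs are direction-sign invariant
  key <- paste(c("line", dims, d), collapse = ",")
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  coords <- arrayInd(seq_len(prod(dims)), dims)
  t <- coords[, a]
  base <- 2 * max(dims) + 3
  lk <- (coords[, 1] - t * d[1] + base) +
    (coords[, 2] - t * d[2] + base) * (2 * base) +
    (coords[, 3] - t * d[3] + base) * (2 * base)^2
  o <- order(lk, t)
  g <- list(o = o, newline = c(TRUE, diff(lk[o]) != 0))
  .geom_cache[[key]] <- g
  g
}

# Enumerate homogeneous runs of a quantized ROI along one direction.
# `q` is an integer 3D array with NA outside the ROI; NA voxels break
# runs. Returns a list with per-run gray level and length.
runs_in_direction <- function(q, d) {
  g <- line_geometry(dim(q), d)
  v2 <- q[g$o]
  v2[is.na(v2)] <- -1L
  n <- length(v2)
  start <- g$newline
  start[-1] <- start[-1] | (v2[-1] != v2[-n])
  lens <- tabulate(cumsum(start))
  levs <- v2[start]
  ok <- levs > 0
  list(level = levs[ok], length = lens[ok])
}

glrlm_from_runs <- function(runs, n_voxels) {
  i <- runs$level
  j <- runs$length
  nr <- length(j)
  if (nr == 0) stop("no runs in ROI")
  gl_counts <- tabulate(i)
  rl_counts <- tabulate(j)
  c(SRE = sum(1 / j^2) / nr,
    LRE = sum(j^2) / nr,
    GLN = sum(gl_counts^2) / nr,
    RLN = sum(rl_counts^2) / nr,
    RP = nr / n_voxels,
    LGLRE = sum(1 / i^2) / nr,
    HGLRE = sum(i^2) / nr,
    SRLGLE = sum(1 / (i^2 * j^2)) / nr,
    SRHGLE = sum(i^2 / j^2) / nr,
    LRLGLE = sum(j^2 / i^2) / nr,
    LRHGLE = sum(i^2 * j^2) / nr)
}

#' Gray-level run-length features
#'
#' Builds the run-length inventory of a quantized ROI per direction and
#' averages the standard GLRLM features over directions. Runs are
#' maximal homogeneous voxel sequences; out-of-ROI voxels break runs.
#'
#' @param q quantized ROI from [quantize_roi()] (NA outside the ROI).
#' @param directions list of integer 3-vector offsets
#'   (default [directions_3d()]).
#' @param which optional subset of feature names to compute (all by
#'   default): SRE, LRE, GLN, RLN, RP, LGLRE, HGLRE, SRLGLE, SRHGLE,
#'   LRLGLE, LRHGLE.
#' @return named numeric vector of direction-averaged features.
#' @export
glrlm_features <- function(q, directions = directions_3d(), which = NULL) {
  n_voxels <- sum(!is.na(q))
  if (n_voxels == 0) stop("empty ROI")
  acc <- NULL
  for (d in directions) {
    f <- glrlm_from_runs(runs_in_direction(q, d), n_voxels)
    acc <- if (is.null(acc)) f else acc + f
  }
  f <- acc / length(directions)
  if (!is.null(which)) f <- f[which]
  f
}

# Co-occurring gray-level pairs along one offset (both voxels in ROI).
# The linear source/target indices are geometry-only and cached.
glcm_pairs <- function(q, d) {
  dims <- dim(q)
  key <- paste(c("pair", dims, d), collapse = ",")
  g <- .geom_cache[[key]]
  if (is.null(g)) {
    rng <- lapply(1:3, function(a) {
      if (d[a] >= 0) seq_len(max(dims[a] - d[a], 0)) else seq(1 - d[a], dims[a])
    })
    if (any(lengths(rng) == 0)) {
      g <- list(src = integer(0), tgt = integer(0))
    } else {
      lin <- array(seq_len(prod(dims)), dims)
      g <- list(src = as.vector(lin[rng[[1]], rng[[2]], rng[[3]]]),
                tgt = as.vector(lin[rng[[1]] + d[1], rng[[2]] + d[2],
                                    rng[[3]] + d[3]]))
    }
    .geom_cache[[key]] <- g
  }
  if (length(g$src) == 0) return(NULL)
  src <- q[g$src]
  tgt <- q[g$tgt]
  ok <- !is.na(src) & !is.na(tgt)
  if (!any(ok)) return(NULL)
  cbind(src[ok], tgt[ok])
}

#' GLCM informational measure of correlation 1
#'
#' For each direction a symmetric, normalized co-occurrence matrix at
#' the given voxel distance is formed and
#' `IMC1 = (HXY - HXY1) / max(HX, HY)` computed with entropies in bits,
#' where `HXY` is the joint entropy and `HXY1 = -sum p(i,j) log2(px(i)
#' py(j))`. Values are averaged over directions. An ROI whose marginal
#' entropies are zero (single gray level) returns 0 with a warning.
#'
#' @param q quantized ROI ([quantize_roi()]).
#' @param distance co-occurrence offset in voxels (default 1).
#' @inheritParams glrlm_features
#' @return direction-averaged IMC1 (scalar).
#' @export
glcm_imc1 <- function(q, distance = 1, directions = directions_3d()) {
  if (sum(!is.na(q)) == 0) stop("empty ROI")
  nlev <- max(q, na.rm = TRUE)
  vals <- numeric(0)
  degenerate <- FALSE
  for (d in directions) {
    pr <- glcm_pairs(q, d * distance)
    if (is.null(pr)) next
    idx <- c((pr[, 1] - 1L) * nlev + pr[, 2], (pr[, 2] - 1L) * nlev + pr[, 1])
    cnt <- tabulate(idx, nlev * nlev)
    p <- cnt / sum(cnt)  # p[(i-1)*L + j], symmetric in (i, j)
    px <- .colSums(p, nlev, nlev)  # marginal of the first symbol
    py <- .rowSums(p, nlev, nlev)
    hx <- entropy_bits(px)
    hy <- entropy_bits(py)
    if (max(hx, hy) == 0) {
      degenerate <- TRUE
      vals <- c(vals, 0)
      next
    }
    hxy <- entropy_bits(p)
    nz <- which(p > 0)
    li <- log2(px)[(nz - 1L) %/% nlev + 1L]
    lj <- log2(py)[(nz - 1L) %% nlev + 1L]
    hxy1 <- -sum(p[nz] * (li + lj))
    vals <- c(vals, (hxy - hxy1) / max(hx, hy))
  }
  if (degenerate)
    warning("degenerate co-occurrence marginals; IMC1 = 0 for some directions")
  if (length(vals) == 0) return(0)
  mean(vals)
}

#' Shape features of an ROI mask
#'
#' Voxel-count volume in mm^3, face-count surface area in mm^2 and
#' sphericity `pi^(1/3) (6V)^(2/3) / A` (1 in the continuum-ball limit;
#' ~0.806 for a cube under the face-count surface).
#'
#' @param mask 3D array, nonzero inside the ROI.
#' @param spacing voxel spacing in mm (length 3).
#' @return named numeric vector: Volume, Surface area, Sphericity.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  m <- mask != 0
  nv <- sum(m)
  if (nv == 0) stop("empty mask")
  vol <- nv * prod(spacing)
  area <- 0
  d <- dim(m)
  for (a in 1:3) {
    face <- prod(spacing[-a])
    perm <- c(a, setdiff(1:3, a))
    x <- aperm(m, perm)
    mm <- matrix(x, nrow = d[a])
    # boundary faces at the array edges plus interior exposed faces
    exposed <- sum(mm[1, ]) + sum(mm[d[a], ]) +
      sum(mm[-1, , drop = FALSE] != mm[-d[a], , drop = FALSE])
    area <- area + exposed * face
  }
  c("Volume" = vol, "Surface area" = area,
    "Sphericity" = pi^(1 / 3) * (6 * vol)^(2 / 3) / area)
}
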