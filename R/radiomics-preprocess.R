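#' Volume preprocessing: resampling, intensity normalization, wavelets
#'
#' Volumes are plain 3D numeric arrays with a `spacing` in mm carried
#' alongside. Preprocessing matches common radiomics practice: resample
#' to a fixed voxel size, z-normalize intensity within the ROI, then
#' decompose into eight single-level 3D wavelet sub-bands.
#'
#' @name radiomics_preprocess
NULL

#' Resample a volume to a target voxel spacing
#'
#' Trilinear interpolation for images, nearest-neighbour for masks.
#' Output dimensions are `round(dim * spacing / target)`, preserving the
#' physical extent to within one voxel. Output voxel centres are placed
#' on the physical grid `(i - 0.5) * target`.
#'
#' @param volume 3D numeric array.
#' @param spacing current voxel spacing in mm (length 3, positive).
#' @param target_spacing desired spacing, default `c(0.75, 0.75, 3.0)` mm.
#' @param method `"trilinear"` or `"nearest"`.
#' @return resampled 3D array.
#' @export
resample_volume <- function(volume, spacing,
                            target_spacing = c(0.75, 0.75, 3.0),
                            method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (any(spacing <= 0) || any(target_spacing <= 0))
    stop("spacings must be positive")
  d <- dim(volume)
  stopifnot(length(d) == 3)
  nd <- pmax(1L, as.integer(round(d * spacing / target_spacing)))
  if (all(nd == d) && all(abs(spacing - target_spacing) < 1e-12))
    return(volume)
  coord <- lapply(1:3, function(a)
    ((seq_len(nd[a]) - 0.5) * target_spacing[a]) / spacing[a] + 0.5)
  if (method == "nearest") {
    ix <- lapply(1:3, function(a) pmin(pmax(round(coord[[a]]), 1L), d[a]))
    return(volume[ix[[1]], ix[[2]], ix[[3]], drop = FALSE])
  }
  out <- volume
  for (a in 1:3) {
    x <- coord[[a]]
    lo <- pmin(pmax(floor(x), 1L), max(d[a] - 1L, 1L))
    hi <- pmin(lo + 1L, d[a])
    f <- pmin(pmax(x - lo, 0), 1)
    da <- dim(out)
    # interpolate along axis a: out = (1-f)*out[lo] + f*out[hi]
    out <- aperm(out, c(a, setdiff(1:3, a)))
    m <- matrix(out, nrow = da[a])
    m2 <- m[lo, , drop = FALSE] * (1 - f) + m[hi, , drop = FALSE] * f
    dim(m2) <- c(length(x), da[setdiff(1:3, a)])
    out <- aperm(m2, order(c(a, setdiff(1:3, a))))
  }
  out
}

#' Normalize volume intensity within an ROI
#'
#' Voxels are z-scored with the in-mask mean and standard deviation,
#' clipped at +/- 3 SD and mapped linearly to \[0, 1\] (so the in-mask
#' mean maps to 0.5). The whole volume is transformed with the in-mask
#' statistics. Invariant under affine intensity changes of the input;
#' idempotent up to the small perturbation introduced by clipping.
#'
#' @param volume 3D numeric array.
#' @param mask 3D array, nonzero inside the ROI; same shape as `volume`.
#' @return normalized volume in \[0, 1\].
#' @export
normalize_intensity <- function(volume, mask) {
  if (!all(dim(volume) == dim(mask))) stop("volume/mask shape mismatch")
  inm <- volume[mask != 0]
  if (length(inm) == 0) stop("empty mask")
  s <- sd(inm)
  if (!is.finite(s) || s == 0) stop("zero in-mask intensity variance")
  z <- (volume - mean(inm)) / s
  z[z > 3] <- 3
  z[z < -3] <- -3
  (z + 3) / 6
}

wavelet_filters <- function(family = c("haar", "d4")) {
  family <- match.arg(family)
  lo <- switch(family,
    haar = c(1, 1) / sqrt(2),
    d4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)))
  n <- seq_along(lo) - 1
  hi <- rev(lo) * (-1)^n  # quadrature mirror filter
  list(lo = lo, hi = hi)
}

# One analysis step along the first axis of a 3D array (periodic
# extension; odd lengths are edge-padded to even first).
dwt_axis1 <- function(x, filt) {
  d <- dim(x)
  n <- d[1]
  if (n %% 2 == 1) {
    x <- x[c(seq_len(n), n), , , drop = FALSE]
    n <- n + 1
    d[1] <- n
  }
  k <- n / 2
  m <- matrix(x, nrow = n)
  lo <- matrix(0, k, ncol(m))
  hi <- matrix(0, k, ncol(m))
  for (j in seq_along(filt$lo)) {
    idx <- ((2 * seq_len(k) - 2 + (j - 1)) %% n) + 1
    lo <- lo + filt$lo[j] * m[idx, , drop = FALSE]
    hi <- hi + filt$hi[j] * m[idx, , drop = FALSE]
  }
  list(L = array(lo, c(k, d[2], d[3])), H = array(hi, c(k, d[2], d[3])))
}

#' Single-level 3D separable discrete wavelet transform
#'
#' Decomposes a volume into eight sub-bands labelled `LLL` ... `HHH`,
#' where the three letters give the low-/high-pass filter applied along
#' the x, y and z axes respectively. Filters are orthonormal (Haar by
#' default, Daubechies-4 optionally) with periodic boundary extension,
#' so for even dimensions the total coefficient energy equals the input
#' energy; odd dimensions are edge-padded to even.
#'
#' @param volume 3D numeric array, every dimension >= 2.
#' @param family wavelet family: `"haar"` (default) or `"d4"`.
#' @return named list of eight sub-band arrays (each dimension halved,
#'   rounded up).
#' @export
wavelet_bands <- function(volume, family = "haar") {
  if (any(dim(volume) < 2)) stop("every dimension must be >= 2")
  filt <- wavelet_filters(family)
  step_axis <- function(arr, axis) {
    perm <- c(axis, setdiff(1:3, axis))
    r <- dwt_axis1(aperm(arr, perm), filt)
    lapply(r, function(a) aperm(a, order(perm)))
  }
  sx <- step_axis(volume, 1)
  out <- list()
  for (fx in c("L", "H")) {
    sy <- step_axis(sx[[fx]], 2)
    for (fy in c("L", "H")) {
      sz <- step_axis(sy[[fy]], 3)
      for (fz in c("L", "H")) {
        out[[paste0(fx, fy, fz)]] <- sz[[fz]]
      }
    }
  }
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

#' Quantize ROI intensities to a fixed number of gray levels
#'
#' Equal-width binning of the in-mask intensity range into `n_bins`
#' levels (1-based integers); voxels outside the mask become `NA`. A
#' constant ROI maps entirely to level 1.
#'
#' @param volume 3D numeric array.
#' @param mask 3D ROI mask, same shape.
#' @param n_bins number of gray levels (default 32).
#' @return integer 3D array with `NA` outside the ROI.
#' @export
quantize_roi <- function(volume, mask, n_bins = 32) {
  if (!all(dim(volume) == dim(mask))) stop("volume/mask shape mismatch")
  q <- array(NA_integer_, dim(volume))
  v <- volume[mask != 0]
  if (length(v) == 0) stop("empty mask")
  rng <- range(v)
  if (diff(rng) == 0) {
    q[mask != 0] <- 1L
  } else {
    lev <- pmin(floor((v - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
    q[mask != 0] <- as.integer(lev)
  }
  q
}
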