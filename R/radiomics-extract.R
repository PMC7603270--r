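#' Radiomic extraction configuration
#'
#' @param n_bins gray levels for texture quantization and first-order
#'   histograms (default 32).
#' @param wavelet wavelet family for sub-band decomposition ("haar" or
#'   "d4").
#' @param bands compute the eight wavelet sub-bands in addition to the
#'   untransformed volume (default TRUE).
#' @param directions list of displacement vectors for texture matrices
#'   (default the 13 unique 3D directions).
#' @param glcm_distance co-occurrence distance in voxels.
#' @param transform optional pre-transform hook, a function
#'   `volume -> volume` applied before normalization. The hook exists so
#'   feature inventories can carry a named transform step (e.g. "SIFT")
#'   in their feature names; the default is the identity, named "none".
#' @param transform_name label used in feature names for the hook.
#' @param glrlm_set which run-length features to extract per band; the
#'   default is the published texture inventory (SRE, SRLGLE, SRHGLE,
#'   LRHGLE); any of the full set computed by [glrlm_features()] may be
#'   requested.
#' @param features optional character vector of full feature names; when
#'   given, only the sub-bands and feature classes needed for those names
#'   are computed (used to speed up inference).
#' @param target_spacing voxel spacing volumes are resampled to before
#'   extraction, in mm.
#' @return a `radiomics_config` list.
#' @export
radiomics_config <- function(n_bins = 32, wavelet = "haar", bands = TRUE,
                             directions = directions_3d(), glcm_distance = 1,
                             transform = NULL, transform_name = "none",
                             glrlm_set = c("SRE", "SRLGLE", "SRHGLE",
                                           "LRHGLE"),
                             features = NULL,
                             target_spacing = c(0.75, 0.75, 3.0)) {
  structure(list(n_bins = n_bins, wavelet = wavelet, bands = bands,
                 directions = directions, glcm_distance = glcm_distance,
                 transform = transform, transform_name = transform_name,
                 glrlm_set = glrlm_set,
                 features = features, target_spacing = target_spacing),
            class = "radiomics_config")
}

feature_name <- function(band, transform, feature) {
  paste(band, transform, feature, sep = "_")
}

#' Class of a radiomic feature from its name
#'
#' @param names character vector of `<band>_<transform>_<feature>` names.
#' @return factor with levels first_order, glrlm, glcm, shape.
#' @export
feature_class <- function(names) {
  leaf <- sub("^[^_]+_[^_]+_", "", names)
  cls <- ifelse(leaf %in% FIRST_ORDER_NAMES, "first_order",
         ifelse(leaf %in% GLRLM_NAMES, "glrlm",
         ifelse(leaf == "IMC1", "glcm",
         ifelse(leaf %in% c("Volume", "Surface area", "Sphericity"),
                "shape", NA_character_))))
  factor(cls, levels = c("first_order", "glrlm", "glcm", "shape"))
}

#' Feature-class composition of a feature vector
#'
#' @param names feature names.
#' @return named percentages by class, summing to 100.
#' @export
feature_class_summary <- function(names) {
  tab <- table(feature_class(names))
  100 * tab / sum(tab)
}

# Nearest-neighbour downsampling of a mask to match wavelet band dims.
downsample_mask <- function(mask) {
  d <- dim(mask)
  mask[seq(1, d[1], by = 2), seq(1, d[2], by = 2), seq(1, d[3], by = 2),
       drop = FALSE]
}

#' Extract the full radiomic feature vector of one volume/mask pair
#'
#' The volume is intensity-normalized within the ROI, optionally
#' decomposed into eight wavelet sub-bands (the ROI mask is
#' nearest-neighbour downsampled to band resolution), and first-order,
#' GLRLM and GLCM-IMC1 features are computed per band. Shape features
#' are computed once from the mask. Names follow
#' `<band>_<transform>_<feature>` with band `none` for the untransformed
#' volume and transform `none` for the identity hook.
#'
#' @param volume 3D numeric array (already resampled/co-registered).
#' @param mask 3D ROI mask, same shape.
#' @param config a [radiomics_config()].
#' @param spacing voxel spacing in mm (used by shape features).
#' @return named numeric feature vector.
#' @export
extract_all <- function(volume, mask, config = radiomics_config(),
                        spacing = config$target_spacing) {
  if (!all(dim(volume) == dim(mask))) stop("volume/mask shape mismatch")
  if (!is.null(config$transform)) volume <- config$transform(volume)
  tn <- config$transform_name
  norm <- normalize_intensity(volume, mask)
  imgs <- list(none = list(v = norm, m = mask))
  if (isTRUE(config$bands)) {
    bw <- wavelet_bands(norm, config$wavelet)
    bm <- downsample_mask(mask)
    for (b in names(bw)) imgs[[b]] <- list(v = bw[[b]], m = bm)
  }
  want <- config$features
  needed <- function(nms) is.null(want) || any(nms %in% want)
  out <- numeric(0)
  for (b in names(imgs)) {
    v <- imgs[[b]]$v
    m <- imgs[[b]]$m
    if (sum(m != 0) < 2) next
    fo_names <- feature_name(b, tn, FIRST_ORDER_NAMES)
    rl_names <- feature_name(b, tn, config$glrlm_set %||% GLRLM_NAMES)
    cm_name <- feature_name(b, tn, "IMC1")
    need_fo <- needed(fo_names)
    need_rl <- needed(rl_names)
    need_cm <- needed(cm_name)
    if (need_fo) {
      fo <- first_order_features(v[m != 0], config$n_bins)
      out[fo_names] <- fo
    }
    if (need_rl || need_cm) {
      q <- quantize_roi(v, m, config$n_bins)
      if (need_rl)
        out[rl_names] <- glrlm_features(q, config$directions,
                                        which = config$glrlm_set)
      if (need_cm)
        out[cm_name] <- suppressWarnings(
          glcm_imc1(q, config$glcm_distance, config$directions))
    }
  }
  sh_names <- feature_name("none", tn, c("Volume", "Surface area", "Sphericity"))
  if (needed(sh_names)) out[sh_names] <- shape_features(mask, spacing)
  if (!is.null(want)) out <- out[intersect(want, names(out))]
  out
}

#' Extract features for a cohort of volumes
#'
#' @param volumes list per sample; each element a list with `mask` plus
#'   one array per modality (e.g. `t1c`, `adc`).
#' @param modality which modality to extract (`"t1c"` or `"adc"`).
#' @param config a [radiomics_config()].
#' @param spacing voxel spacing of the volumes.
#' @return samples x features numeric matrix.
#' @export
extract_cohort <- function(volumes, modality = "t1c",
                           config = radiomics_config(),
                           spacing = config$target_spacing) {
  rows <- lapply(volumes, function(s) {
    if (is.null(s[[modality]])) stop("modality not present: ", modality)
    extract_all(s[[modality]], s$mask, config, spacing)
  })
  nm <- names(rows[[1]])
  mat <- do.call(rbind, lapply(rows, function(r) r[nm]))
  colnames(mat) <- nm
  rownames(mat) <- names(volumes)
  mat
}

#' Write a cohort feature matrix as long-format CSV
#'
#' Columns: sample_id, modality, feature_name, value.
#'
#' @param mat samples x features matrix from [extract_cohort()].
#' @param modality modality tag recorded in the CSV.
#' @param path CSV path.
#' @export
write_features_csv <- function(mat, modality, path) {
  df <- data.frame(
    sample_id = rep(rownames(mat), times = ncol(mat)),
    modality = modality,
    feature_name = rep(colnames(mat), each = nrow(mat)),
    value = as.vector(mat))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
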