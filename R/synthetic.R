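#' Synthetic cohort generator with known immune ground truth
#'
#' Generates a fully synthetic cohort — two-platform gene expression with
#' planted gene-set enrichment, co-registered MR-like volumes whose ROI
#' statistics depend on the latent immune states, and a clinical table
#' with group-dependent exponential survival — so that every downstream
#' stage of the pipeline has a recoverable truth.
#'
#' The per-group latent state model (order CTL, aDC, Treg, MDSC):
#' G1 all low; G5 all high; G2 = (low, high, high, high); G3 = (high,
#' Bernoulli(0.7), low, low); G4 = CTL high and MDSC high with
#' (aDC, Treg) drawn from (low,low)/(low,high)/(high,low) with
#' probabilities 0.25/0.55/0.20. Free-state probabilities are chosen so
#' each subset's cohort prevalence of "high" sits as close to one half
#' as the default group proportions allow, consistent with the
#' median-split definition of enrichment levels.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' @param n_samples cohort size (>= 10; LOOCV is undefined below that).
#' @param group_proportions five non-negative reals summing to 1;
#'   default the published cluster proportions
#'   (0.377, 0.162, 0.065, 0.130, 0.266).
#' @param effect_size expression shift, in log2-expression SD units,
#'   added to a set's genes in samples where that subset is high
#'   (default 2).
#' @param image_shape volume dimensions in voxels (each >= 8).
#' @param voxel_spacing voxel size in mm (default 0.75 x 0.75 x 3.0).
#' @param platform_noise_sd SD of platform-specific expression noise.
#' @param median_survival_by_group five exponential medians in days
#'   (default 408, 266, 867, 330, 357 for G1..G5).
#' @param censor_rate independent uniform censoring probability
#'   (default 0.2).
#' @param n_genes total genes simulated (default 500; must cover the
#'   catalog).
#' @param mutant_rate probability of IDH-mutant status (default 0.1).
#' @param seed integer seed; one RNG stream drives the whole cohort.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 100,
                              group_proportions = c(0.377, 0.162, 0.065,
                                                    0.130, 0.266),
                              effect_size = 2,
                              image_shape = c(16, 16, 12),
                              voxel_spacing = c(0.75, 0.75, 3.0),
                              platform_noise_sd = 0.3,
                              median_survival_by_group = c(408, 266, 867,
                                                           330, 357),
                              censor_rate = 0.2,
                              n_genes = 500,
                              mutant_rate = 0.1,
                              seed = 1L) {
  stopifnot(length(group_proportions) == 5, all(group_proportions >= 0))
  if (abs(sum(group_proportions) - 1) > 1e-9)
    stop("group_proportions must sum to 1")
  stopifnot(length(image_shape) == 3)
  if (any(image_shape < 8)) stop("every image dimension must be >= 8")
  stopifnot(length(voxel_spacing) == 3, all(voxel_spacing > 0))
  stopifnot(length(median_survival_by_group) == 5,
            all(median_survival_by_group > 0))
  stopifnot(effect_size >= 0, platform_noise_sd >= 0,
            censor_rate >= 0, censor_rate < 1)
  structure(list(n_samples = as.integer(n_samples),
                 group_proportions = group_proportions,
                 effect_size = effect_size,
                 image_shape = as.integer(image_shape),
                 voxel_spacing = voxel_spacing,
                 platform_noise_sd = platform_noise_sd,
                 median_survival_by_group = median_survival_by_group,
                 censor_rate = censor_rate,
                 n_genes = as.integer(n_genes),
                 mutant_rate = mutant_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default metagene catalog for simulations
#'
#' Disjoint sets of 5 (CTL), 51 (aDC), 26 (Treg) and 58 (MDSC) genes —
#' the published set sizes — drawn from the simulated gene pool.
#'
#' @param n_genes size of the gene pool (>= 140).
#' @return a [metagene_catalog()].
#' @export
default_catalog <- function(n_genes = 500) {
  if (n_genes < 140) stop("need at least 140 genes for the default catalog")
  ids <- sprintf("GENE%04d", seq_len(n_genes))
  metagene_catalog(list(CTL = ids[1:5], aDC = ids[6:56],
                        Treg = ids[57:82], MDSC = ids[83:140]))
}

# Draw latent subset states consistent with a group label.
sample_states <- function(group) {
  switch(group,
    G1 = c(CTL = "low", aDC = "low", Treg = "low", MDSC = "low"),
    G5 = c(CTL = "high", aDC = "high", Treg = "high", MDSC = "high"),
    G2 = c(CTL = "low", aDC = "high", Treg = "high", MDSC = "high"),
    G3 = c(CTL = "high",
           aDC = if (runif(1) < 0.7) "high" else "low",
           Treg = "low", MDSC = "low"),
    G4 = {
      at <- sample(c("ll", "lh", "hl"), 1, prob = c(0.25, 0.55, 0.20))
      c(CTL = "high",
        aDC = if (substr(at, 1, 1) == "h") "high" else "low",
        Treg = if (substr(at, 2, 2) == "h") "high" else "low",
        MDSC = "high")
    })
}

# Blockwise-constant standard-normal field: iid draws on a coarse grid of
# cell size `b`, upsampled by replication. b = 1 gives iid voxel noise.
block_field <- function(dims, b) {
  if (all(b == 1)) return(array(rnorm(prod(dims)), dims))
  cdims <- ceiling(dims / b)
  coarse <- array(rnorm(prod(cdims)), cdims)
  coarse[ceiling(seq_len(dims[1]) / b[1]),
         ceiling(seq_len(dims[2]) / b[2]),
         ceiling(seq_len(dims[3]) / b[3]), drop = FALSE]
}

# Unit-variance ROI noise field: mixing weight block_w on a blockwise
# component (run coherence) against fine iid noise.
roi_field <- function(dims, block_w, b = c(2, 2, 2)) {
  sqrt(block_w) * block_field(dims, b) +
    sqrt(1 - block_w) * array(rnorm(prod(dims)), dims)
}

# Ellipsoid ROI mask centred in the volume.
ellipsoid_mask <- function(dims, radii) {
  c0 <- (dims + 1) / 2
  x <- ((seq_len(dims[1]) - c0[1]) / radii[1])^2
  y <- ((seq_len(dims[2]) - c0[2]) / radii[2])^2
  z <- ((seq_len(dims[3]) - c0[3]) / radii[3])^2
  d2 <- outer(outer(x, y, `+`), z, `+`)
  array(as.integer(d2 <= 1), dims)
}

#' Simulate a full synthetic cohort
#'
#' Deterministic for a fixed `config$seed`. Genes of a subset's metagene
#' set are shifted by `effect_size` (log2 scale) in samples whose state
#' for that subset is high, on both platforms (shared biological signal
#' plus platform-specific noise). In the volumes, a high CTL state
#' brightens a contiguous core subregion of the ROI, which skews the
#' in-ROI intensity distribution (the median of the normalized volume
#' shifts monotonically with CTL state, surviving the per-volume
#' z-normalization that would erase a global mean shift); a high MDSC
#' state makes the ROI texture blockwise-coherent (longer gray-level
#' runs). The T1C modality carries the stronger version of both
#' effects, ADC a weaker one.
#' Survival is exponential with the group's configured median plus
#' independent uniform censoring.
#'
#' @param config a [simulation_config()].
#' @param catalog optional [metagene_catalog()]; defaults to
#'   [default_catalog()] over the simulated gene pool.
#' @param components which data blocks to generate (`"expression"`,
#'   `"volumes"` or both). Ground truth, survival and the clinical table
#'   are always produced; dropping a block saves the bulk of the cost
#'   when only the truth is needed (e.g. sampling checks at large n).
#' @return list with elements `config`, `truth` (sample_id, group,
#'   per-subset states, survival_days, event), `catalog`, `expression`
#'   (rnaseq + microarray [expression_matrix()]s), `volumes` (per sample:
#'   `t1c`, `adc`, `mask` arrays), `spacing`, `clinical` (sample_id,
#'   survival_days, event, idh_status).
#' @export
simulate_cohort <- function(config, catalog = NULL,
                            components = c("expression", "volumes")) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_samples < 10) stop("n_samples must be >= 10 (LOOCV undefined)")
  if (is.null(catalog)) catalog <- default_catalog(config$n_genes)
  if (any(lengths(catalog) == 0)) stop("empty metagene set")
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))
  if (!all(unlist(catalog) %in% gene_ids))
    stop("catalog genes must be contained in the simulated gene pool")
  with_seed(config$seed, {
    n <- config$n_samples
    ids <- sprintf("S%04d", seq_len(n))
    groups <- PHENOTYPE_GROUPS[sample.int(5, n, replace = TRUE,
                                          prob = config$group_proportions)]
    states <- t(vapply(groups, sample_states, character(4)))
    rownames(states) <- ids

    # --- expression ------------------------------------------------------
    expr <- NULL
    if ("expression" %in% components) {
    mu <- rnorm(config$n_genes, mean = 3, sd = 1)
    shift <- matrix(0, config$n_genes, n, dimnames = list(gene_ids, ids))
    for (s in SUBSETS) {
      gi <- match(catalog[[s]], gene_ids)
      hi <- states[, s] == "high"
      shift[gi, hi] <- shift[gi, hi] + config$effect_size
    }
    z <- mu + shift + matrix(rnorm(config$n_genes * n), config$n_genes, n)
    rnaseq <- 2^(z + matrix(rnorm(config$n_genes * n,
                                  sd = config$platform_noise_sd),
                            config$n_genes, n))
    arr_offset <- rep(rnorm(n, sd = 0.5), each = config$n_genes)
    microarray <- z + arr_offset +
      matrix(rnorm(config$n_genes * n, sd = config$platform_noise_sd),
             config$n_genes, n)
    expr <- list(
      rnaseq = expression_matrix(rnaseq, gene_ids, ids, "rnaseq_fpkm"),
      microarray = expression_matrix(microarray, gene_ids, ids, "microarray"))
    }

    # --- volumes ---------------------------------------------------------
    dims <- config$image_shape
    volumes <- NULL
    if ("volumes" %in% components) {
    volumes <- vector("list", n)
    names(volumes) <- ids
    for (i in seq_len(n)) {
      radii <- dims * (0.30 + 0.10 * runif(3))
      mask <- ellipsoid_mask(dims, radii)
      core <- ellipsoid_mask(dims, 0.65 * radii)  # "enhancing core" subregion
      ctl_hi <- states[i, "CTL"] == "high"
      mdsc_hi <- states[i, "MDSC"] == "high"
      make_modality <- function(core_hi, block_hi, bg_mean) {
        vol <- array(rnorm(prod(dims), mean = bg_mean, sd = 0.02), dims)
        e <- roi_field(dims, block_w = if (mdsc_hi) block_hi else 0)
        if (ctl_hi) e <- e + core_hi * core
        vol[mask == 1] <- 1 + 0.3 * e[mask == 1]
        vol
      }
      volumes[[i]] <- list(
        t1c = make_modality(core_hi = 3.0, block_hi = 0.9995, bg_mean = 0.1),
        adc = make_modality(core_hi = 1.5, block_hi = 0.99, bg_mean = 0.2),
        mask = mask)
    }
    }

    # --- survival & clinical --------------------------------------------
    gidx <- match(groups, PHENOTYPE_GROUPS)
    rate <- log(2) / config$median_survival_by_group[gidx]
    t_true <- rexp(n, rate)
    if (config$censor_rate > 0) {
      # independent Unif(0, M) censor clock per group, M calibrated so
      # P(C < T) equals the configured rate under the exponential law:
      # (1 - exp(-x)) / x = rate with x = lambda * M
      x <- uniroot(function(x) (1 - exp(-x)) / x - config$censor_rate,
                   c(1e-8, 1e6))$root
      cens <- runif(n) * (x / rate)
      event <- as.integer(t_true <= cens)
      time <- pmax(pmin(t_true, cens), 0.5)
    } else {
      event <- rep(1L, n)
      time <- pmax(t_true, 0.5)
    }
    idh <- ifelse(runif(n) < config$mutant_rate, "mutant", "wild-type")

    truth <- data.frame(sample_id = ids, group = groups,
                        ctl_state = states[, "CTL"],
                        adc_state = states[, "aDC"],
                        treg_state = states[, "Treg"],
                        mdsc_state = states[, "MDSC"],
                        survival_days = time, event = event,
                        stringsAsFactors = FALSE, row.names = NULL)
    clinical <- data.frame(sample_id = ids, survival_days = time,
                           event = event, idh_status = idh,
                           stringsAsFactors = FALSE)
    list(config = config, truth = truth, catalog = catalog,
         expression = expr, volumes = volumes,
         spacing = config$voxel_spacing, clinical = clinical)
  })
}

#' Latent truth as a level matrix
#'
#' @param truth the `truth` data frame from [simulate_cohort()].
#' @return samples x 4 character matrix of planted states.
#' @export
truth_levels <- function(truth) {
  m <- as.matrix(truth[, c("ctl_state", "adc_state", "treg_state",
                           "mdsc_state")])
  dimnames(m) <- list(truth$sample_id, SUBSETS)
  m
}

#' Write a simulated cohort to disk as open formats
#'
#' GMT catalog, two expression TSVs, NIfTI volume + mask per sample and
#' modality (float32; volume and mask share spacing metadata), clinical
#' CSV and truth CSV. Re-reading reproduces values to float32 precision.
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_fixtures <- function(sim, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  write_gmt(sim$catalog, file.path(dir, "metagenes.gmt"))
  write_expression_tsv(sim$expression$rnaseq,
                       file.path(dir, "expression_rnaseq_fpkm.tsv"))
  write_expression_tsv(sim$expression$microarray,
                       file.path(dir, "expression_microarray.tsv"))
  write.csv(sim$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  nifti_dir <- file.path(dir, "nifti")
  dir.create(nifti_dir, showWarnings = FALSE)
  for (id in names(sim$volumes)) {
    v <- sim$volumes[[id]]
    as_img <- function(arr, dt) {
      attr(arr, "pixdim") <- sim$spacing
      RNifti::asNifti(arr, datatype = dt)
    }
    for (mod in c("t1c", "adc")) {
      RNifti::writeNifti(as_img(v[[mod]], "float"),
                         file.path(nifti_dir,
                                   sprintf("%s_%s.nii.gz", id, mod)))
    }
    RNifti::writeNifti(as_img(v$mask, "uint8"),
                       file.path(nifti_dir,
                                 sprintf("%s_mask.nii.gz", id)))
  }
  invisible(dir)
}

#' Read a fixture directory back into the simulate_cohort layout
#'
#' @param dir directory written by [write_fixtures()].
#' @return list with `catalog`, `expression`, `volumes`, `spacing`,
#'   `clinical`, `truth`.
#' @export
read_fixtures <- function(dir) {
  catalog <- read_gmt(file.path(dir, "metagenes.gmt"))
  expr <- list(
    rnaseq = read_expression_tsv(file.path(dir, "expression_rnaseq_fpkm.tsv"),
                                 "rnaseq_fpkm"),
    microarray = read_expression_tsv(
      file.path(dir, "expression_microarray.tsv"), "microarray"))
  clinical <- read.csv(file.path(dir, "clinical.csv"),
                       stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path))
    read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  nifti_dir <- file.path(dir, "nifti")
  ids <- clinical$sample_id
  spacing <- NULL
  volumes <- lapply(ids, function(id) {
    t1c <- RNifti::readNifti(file.path(nifti_dir, sprintf("%s_t1c.nii.gz", id)))
    adc <- RNifti::readNifti(file.path(nifti_dir, sprintf("%s_adc.nii.gz", id)))
    msk <- RNifti::readNifti(file.path(nifti_dir, sprintf("%s_mask.nii.gz", id)))
    spacing <<- RNifti::pixdim(t1c)
    list(t1c = unclass(t1c)[, , , drop = FALSE],
         adc = unclass(adc)[, , , drop = FALSE],
         mask = unclass(msk)[, , , drop = FALSE])
  })
  names(volumes) <- ids
  list(catalog = catalog, expression = expr, volumes = volumes,
       spacing = spacing, clinical = clinical, truth = truth)
}
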