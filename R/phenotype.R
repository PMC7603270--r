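#' Immunophenotype groups G1-G5
#'
#' Five phenotype groups are defined from the four binary enrichment
#' levels (order CTL, aDC, Treg, MDSC):
#' \itemize{
#'   \item G1 immune-cold: all subsets low
#'   \item G2: CTL low and MDSC high
#'   \item G3: CTL high with Treg and MDSC low (aDC unconstrained)
#'   \item G4: residual mixed patterns
#'   \item G5 immune-hot: all subsets high
#' }
#' Rules are applied in priority order G1, G5, G3, G2, G4 so every one of
#' the 16 level combinations maps to exactly one group.
#'
#' @name immunophenotyping
NULL

#' Map a high/low level quadruple to a phenotype group
#'
#' @param levels character vector or matrix of `"low"`/`"high"`; either a
#'   single 4-vector or a samples x 4 matrix in subset order CTL, aDC,
#'   Treg, MDSC.
#' @return for a vector input, a list with `group` and `rule_fired`; for a
#'   matrix, a data frame with one row per sample.
#' @examples
#' map_levels_to_group(c("low", "low", "low", "low"))$group   # G1
#' map_levels_to_group(c("low", "high", "low", "high"))$group # G2
#' @export
map_levels_to_group <- function(levels) {
  if (is.matrix(levels) || is.data.frame(levels)) {
    levels <- as.matrix(levels)
    res <- apply(levels, 1, function(r) unlist(map_levels_to_group(r)))
    df <- data.frame(group = res["group", ], rule_fired = res["rule_fired", ],
                     stringsAsFactors = FALSE)
    rownames(df) <- rownames(levels)
    return(df)
  }
  stopifnot(length(levels) == 4, all(levels %in% c("low", "high")))
  ctl <- levels[1]; treg <- levels[3]; mdsc <- levels[4]
  if (all(levels == "low"))
    list(group = "G1", rule_fired = "all_low")
  else if (all(levels == "high"))
    list(group = "G5", rule_fired = "all_high")
  else if (ctl == "high" && treg == "low" && mdsc == "low")
    list(group = "G3", rule_fired = "ctl_high_treg_low_mdsc_low")
  else if (ctl == "low" && mdsc == "high")
    list(group = "G2", rule_fired = "ctl_low_mdsc_high")
  else
    list(group = "G4", rule_fired = "residual")
}

#' Cluster enrichment profiles into k groups
#'
#' Hierarchical agglomerative clustering (Ward linkage, Euclidean
#' distance) of the 4-dimensional NES vectors, tree cut at `k`; or
#' seeded k-means when `method = "kmeans"`.
#'
#' @param nes_matrix samples x 4 NES matrix.
#' @param k number of clusters (default 5).
#' @param method `"ward"` (default, deterministic) or `"kmeans"`.
#' @param seed seed for k-means starts.
#' @return integer cluster index per sample (named).
#' @export
cluster_profiles <- function(nes_matrix, k = 5, method = c("ward", "kmeans"),
                             seed = 1L) {
  method <- match.arg(method)
  nes_matrix <- as.matrix(nes_matrix)
  if (k > nrow(nes_matrix)) stop("k exceeds the number of samples")
  if (method == "ward") {
    hc <- hclust(dist(nes_matrix), method = "ward.D2")
    cl <- cutree(hc, k = k)
  } else {
    cl <- with_seed(seed, kmeans(nes_matrix, centers = k, nstart = 10)$cluster)
  }
  setNames(as.integer(cl), rownames(nes_matrix))
}

#' Label clusters with phenotype groups
#'
#' Each cluster is labelled by applying the priority rules to its
#' majority level pattern (per-subset majority across cluster members;
#' exact ties resolve to "low", matching the median-split tie rule).
#' Clusters whose majority patterns coincide receive the same group.
#'
#' @param clusters integer cluster index per sample (named).
#' @param levels samples x 4 `"low"`/`"high"` matrix ([binarize_levels()]).
#' @return data frame: sample_id, group, source = `"clustered"`,
#'   rule_fired (the majority pattern rule), cluster.
#' @export
label_clusters <- function(clusters, levels) {
  levels <- as.matrix(levels)
  stopifnot(nrow(levels) == length(clusters))
  out <- data.frame(sample_id = names(clusters), group = NA_character_,
                    source = "clustered", rule_fired = NA_character_,
                    cluster = as.integer(clusters), stringsAsFactors = FALSE)
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    maj <- apply(levels[idx, , drop = FALSE], 2, function(col) {
      if (mean(col == "high") > 0.5) "high" else "low"
    })
    m <- map_levels_to_group(maj)
    out$group[idx] <- m$group
    out$rule_fired[idx] <- paste0("majority:", m$rule_fired)
  }
  out
}

#' Write phenotype labels as CSV
#'
#' @param labels data frame from [label_clusters()] or [predict_groups()].
#' @param path CSV path.
#' @export
write_labels_csv <- function(labels, path) {
  write.csv(labels, path, row.names = FALSE)
  invisible(path)
}
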