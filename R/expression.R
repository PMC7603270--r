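#' Expression containers, FPKM, LOWESS array normalization and file I/O
#'
#' Gene expression enters the pipeline as a genes-by-samples matrix tagged
#' with its platform. RNA-seq data are expected on the FPKM scale
#' (non-negative); microarray data are log-scale intensities.
#'
#' @name expression
NULL

#' Construct an expression matrix
#'
#' @param values numeric genes x samples matrix.
#' @param gene_ids,sample_ids optional character vectors; default to the
#'   dimnames of `values`.
#' @param platform `"rnaseq_fpkm"` or `"microarray"`.
#' @return an `expression_matrix` object (matrix plus platform attribute).
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              platform = c("rnaseq_fpkm", "microarray")) {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample ids are required")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions")
  if (platform == "rnaseq_fpkm" && any(values < 0, na.rm = TRUE))
    stop("FPKM values must be non-negative")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(values, platform = platform, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, platform = %s\n",
              nrow(x), ncol(x), attr(x, "platform")))
  invisible(x)
}

#' Fragments per kilobase of transcript per million mapped reads
#'
#' FPKM = total_fragments / (mapped_reads_millions * exon_length_kb).
#' Vectorized over all arguments.
#'
#' @param total_fragments non-negative fragment count(s).
#' @param mapped_reads_millions library size in millions of mapped reads.
#' @param exon_length_kb exonic length in kilobases.
#' @return non-negative FPKM value(s).
#' @examples
#' fpkm(1000, 1, 1)   # 1000
#' fpkm(50, 2, 2.5)   # 10
#' @export
fpkm <- function(total_fragments, mapped_reads_millions, exon_length_kb) {
  if (any(total_fragments < 0)) stop("total_fragments must be non-negative")
  if (any(mapped_reads_millions <= 0)) stop("mapped_reads_millions must be positive")
  if (any(exon_length_kb <= 0)) stop("exon_length_kb must be positive")
  total_fragments / (mapped_reads_millions * exon_length_kb)
}

#' LOWESS normalization of a microarray expression matrix
#'
#' Removes per-sample intensity-dependent bias: for each sample, the
#' difference to a reference profile (per-gene cohort median) is smoothed
#' against the mean intensity (sample + reference)/2 with [stats::lowess()]
#' and subtracted. With a linear bias this reduces to mean-centering; the
#' operation is idempotent up to smoother tolerance.
#'
#' @param mat an [expression_matrix()] with platform `"microarray"`.
#' @param f lowess smoother span (fraction of points), default 0.3.
#' @param iter robustifying iterations, default 3.
#' @return normalized `expression_matrix`, same shape, ids and platform.
#' @export
normalize_array <- function(mat, f = 0.3, iter = 3) {
  if (!inherits(mat, "expression_matrix") || attr(mat, "platform") != "microarray")
    stop("normalize_array expects a microarray expression_matrix")
  if (nrow(mat) < 10) stop("need at least 10 genes to fit the smoother")
  ref <- apply(mat, 1, median)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    d <- mat[, j] - ref
    a <- (mat[, j] + ref) / 2
    fit <- lowess(a, d, f = f, iter = iter)
    bias <- approx(fit$x, fit$y, xout = a, rule = 2, ties = mean)$y
    out[, j] <- mat[, j] - bias
  }
  out
}

#' Metagene catalog for the four immune subsets
#'
#' @param sets named list with exactly the elements `CTL`, `aDC`, `Treg`
#'   and `MDSC`, each a non-empty character vector of gene ids.
#' @return a `metagene_catalog` (validated named list).
#' @export
metagene_catalog <- function(sets) {
  missing <- setdiff(SUBSETS, names(sets))
  if (length(missing))
    stop("missing gene set(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(sets), SUBSETS)
  if (length(extra))
    stop("unknown gene set(s): ", paste(extra, collapse = ", "))
  sets <- sets[SUBSETS]
  for (s in SUBSETS) {
    if (length(sets[[s]]) == 0L) stop("empty gene set: ", s)
    if (anyDuplicated(sets[[s]])) stop("duplicate gene ids in set ", s)
    sets[[s]] <- as.character(sets[[s]])
  }
  structure(sets, class = "metagene_catalog")
}

#' Restrict a catalog to genes measured on a platform
#'
#' Genes absent from `gene_ids` (e.g. not covered by a microarray probe
#' set) are dropped with a warning, producing the "modified gene sets"
#' used when scoring that platform.
#'
#' @param catalog a [metagene_catalog()].
#' @param gene_ids genes available on the platform.
#' @return restricted `metagene_catalog`.
#' @export
restrict_catalog <- function(catalog, gene_ids) {
  out <- lapply(catalog, intersect, gene_ids)
  dropped <- mapply(function(a, b) length(a) - length(b), catalog, out)
  if (any(dropped > 0))
    warning("dropped genes absent from platform: ",
            paste(sprintf("%s(%d)", names(out)[dropped > 0],
                          dropped[dropped > 0]), collapse = ", "))
  metagene_catalog(out)
}

#' Read a GMT gene-set file into a metagene catalog
#'
#' Each line is tab-separated: set name, description, then gene ids. The
#' file must define exactly the four subsets CTL, aDC, Treg, MDSC.
#'
#' @param path GMT file path.
#' @return a [metagene_catalog()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(ln, 1, 40))
    sets[[parts[1]]] <- parts[-(1:2)]
  }
  metagene_catalog(sets)
}

#' Write a metagene catalog as GMT
#'
#' @param catalog a [metagene_catalog()].
#' @param path output file.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog), function(s) {
    paste(c(s, paste0(s, " metagenes"), catalog[[s]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an expression matrix as TSV
#'
#' Layout: first column `gene_id`, remaining columns one per sample.
#'
#' @param path TSV file.
#' @param platform platform tag for the result.
#' @return [expression_matrix()].
#' @export
read_expression_tsv <- function(path, platform = c("rnaseq_fpkm", "microarray")) {
  platform <- match.arg(platform)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  expression_matrix(m, genes, colnames(m), platform)
}

#' @rdname read_expression_tsv
#' @param mat an [expression_matrix()] to write.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), as.data.frame(unclass(mat)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Center expression per gene at the cohort median
#'
#' Subtracts each gene's cohort median so that per-sample rankings
#' reflect relative (between-sample) expression rather than baseline
#' abundance — the usual preparation for single-sample enrichment
#' scoring, where a small gene set's score would otherwise be dominated
#' by the set members' baseline ranks.
#'
#' @param values genes x samples numeric matrix (log scale).
#' @return matrix of the same shape, each row median-centered.
#' @export
center_expression <- function(values) {
  values <- as.matrix(unclass(values))
  values - apply(values, 1, median)
}

#' Log-transform FPKM values for rank-based analyses
#'
#' @param mat rnaseq `expression_matrix`.
#' @return matrix of `log2(x + 1)` values (plain matrix).
#' @export
log_fpkm <- function(mat) {
  if (attr(mat, "platform") != "rnaseq_fpkm")
    stop("log_fpkm expects rnaseq_fpkm data")
  log2(unclass(mat) + 1)
}
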