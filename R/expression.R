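#' Median-of-ratios size factors
#'
#' Per-sample normalization factors from the median-of-ratios estimator: each
#' sample's counts are divided by the gene-wise geometric mean (over genes
#' with nonzero counts in every sample) and the per-sample median of those
#' ratios is the size factor.  Factors are rescaled to have geometric mean 1.
#'
#' @param counts non-negative gene x sample count matrix (>= 1 gene nonzero in
#'   all samples).
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  use <- rowSums(counts > 0) == ncol(counts)
  if (!any(use)) {
    stop("no gene has nonzero counts in all samples; consider adding a pseudocount")
  }
  logc <- log(counts[use, , drop = FALSE])
  log_geo <- rowMeans(logc)
  sf <- apply(logc, 2, function(s) exp(stats::median(s - log_geo)))
  sf <- sf / exp(mean(log(sf)))  # geometric-mean-1 convention
  sf
}

#' Log-scale normalization of counts
#'
#' The variance-stabilizing transform stand-in used throughout: counts are
#' divided by their sample's size factor and shifted-log transformed,
#' `log2(count / factor + 1)`.  Downstream subtype calling is rank-based
#' (Spearman), which is invariant to any strictly monotone per-sample
#' transform, so this stand-in preserves the calls a full VST would give.
#'
#' @param counts gene x sample count matrix.
#' @param factors positive per-sample size factors (default
#'   [size_factors()]).
#' @return normalized matrix, same dimensions.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  counts <- as.matrix(counts)
  if (length(factors) != ncol(counts)) stop("one factor per sample is required")
  if (any(factors <= 0)) stop("size factors must be positive")
  log2(sweep(counts, 2, factors, "/") + 1)
}

#' Load the packaged synthetic centroid panel
#'
#' Reads the synthetic 77-gene TNBC subtype centroid table and the synthetic
#' human-to-mouse ortholog map shipped under `inst/extdata` and returns the
#' mapped panel (see [map_orthologs()]).  Both fixtures are synthetic
#' stand-ins for the published signature and a live ortholog database; the
#' ortholog table covers 60 of the 77 genes, reproducing the structure of the
#' published 60/77 = 78% mapping.
#'
#' @return a `centroid_panel` (see [map_orthologs()]).
#' @export
default_centroid_panel <- function() {
  centroids <- utils::read.delim(
    system.file("extdata", "tnbc_centroids_synthetic.tsv",
                package = "tmesubtype", mustWork = TRUE),
    row.names = 1, check.names = FALSE
  )
  orthologs <- utils::read.delim(
    system.file("extdata", "ortholog_map_synthetic.tsv",
                package = "tmesubtype", mustWork = TRUE)
  )
  map_orthologs(as.matrix(centroids), orthologs)
}

#' Map centroid signature genes across species
#'
#' Retains the centroid genes that map to a mouse symbol in the supplied
#' ortholog table, renames them to the mouse symbols, and re-z-scores each
#' gene's centroid values across subtypes after filtering.  One-to-many
#' mappings are resolved by the first listed pair (collisions produce a
#' warning).
#'
#' @param centroids numeric matrix, signature genes x subtypes (human
#'   symbols as rownames; columns typically BLIA, BLIS, LAR, MES).
#' @param ortholog_table data.frame with columns `human_symbol`,
#'   `mouse_symbol`.
#' @return object of class `centroid_panel`: list with `centroids` (mapped,
#'   re-z-scored matrix with mouse rownames), `mapped_genes` (mouse symbols),
#'   `unmapped_genes` (human symbols), `mapping_fraction`.
#' @export
map_orthologs <- function(centroids, ortholog_table) {
  centroids <- as.matrix(centroids)
  if (is.null(rownames(centroids))) stop("centroids must have gene rownames")
  check_columns(ortholog_table, c("human_symbol", "mouse_symbol"),
                "ortholog table")
  if (nrow(ortholog_table) == 0L) stop("ortholog table is empty")
  dup <- duplicated(ortholog_table$human_symbol)
  if (any(dup)) {
    warning(sprintf("%d duplicate human symbol mapping(s); keeping first listed",
                    sum(dup)))
    ortholog_table <- ortholog_table[!dup, , drop = FALSE]
  }
  hit <- match(rownames(centroids), ortholog_table$human_symbol)
  keep <- !is.na(hit)
  if (!any(keep)) stop("no centroid gene maps through the ortholog table")
  mapped <- centroids[keep, , drop = FALSE]
  rownames(mapped) <- ortholog_table$mouse_symbol[hit[keep]]
  # re-z-score each gene across subtypes on the filtered panel
  mapped <- t(scale(t(mapped)))
  mapped[is.nan(mapped)] <- 0
  structure(list(
    centroids = mapped,
    mapped_genes = rownames(mapped),
    unmapped_genes = rownames(centroids)[!keep],
    mapping_fraction = mean(keep)
  ), class = "centroid_panel")
}

#' Molecular subtype calling by centroid correlation
#'
#' z-scores the normalized expression of the shared signature genes per gene
#' across samples, computes the Spearman correlation of each sample's
#' z-vector with each subtype centroid, and calls the subtype with the
#' highest correlation.  Samples whose expression vector is constant over the
#' shared genes carry no rank information and get `NA` correlations and no
#' call; an exact tie for the top correlation also produces a no-call.
#'
#' @param norm normalized gene x sample matrix ([normalize_counts()]).
#' @param panel a `centroid_panel` ([map_orthologs()] /
#'   [default_centroid_panel()]).
#' @param min_shared minimum shared genes required (default 3).
#' @return object of class `correlation_result`: list with `rho` (sample x
#'   subtype Spearman matrix), `call` (named character, `NA` for no-call),
#'   `n_genes` (shared genes used).
#' @export
centroid_correlation <- function(norm, panel, min_shared = 3L) {
  stopifnot(inherits(panel, "centroid_panel"))
  norm <- as.matrix(norm)
  shared <- intersect(rownames(norm), rownames(panel$centroids))
  if (length(shared) < min_shared) {
    stop(sprintf("only %d gene(s) shared between matrix and panel (need >= %d)",
                 length(shared), min_shared))
  }
  x <- norm[shared, , drop = FALSE]
  cz <- panel$centroids[shared, , drop = FALSE]
  constant_sample <- apply(x, 2, function(v) stats::sd(v) == 0)
  # z-score per gene across samples (skipped for a single sample, where the
  # transform is degenerate; Spearman is unaffected by the per-gene centring
  # only through rank changes, and with one sample there is nothing to centre)
  if (ncol(x) > 1L) {
    xz <- t(scale(t(x)))
    xz[is.nan(xz)] <- 0
  } else {
    xz <- x
  }
  rho <- suppressWarnings(stats::cor(xz, cz, method = "spearman"))
  rho[constant_sample, ] <- NA_real_
  call <- apply(rho, 1, function(r) {
    if (all(is.na(r))) return(NA_character_)
    top <- which(r == max(r, na.rm = TRUE))
    if (length(top) != 1L) return(NA_character_)  # tie -> no call
    colnames(rho)[top]
  })
  structure(list(rho = rho, call = call, n_genes = length(shared)),
            class = "correlation_result")
}

#' Filter a differential-expression table by effect size and significance
#'
#' Returns the genes of `gene_list` whose records pass `log2_fold_change >
#' lfc_min` and `adjusted_p < padj_max` (both strict, matching the stated
#' "Log2FC > 1.5 and padj < 0.05" rule).  Genes missing from the records count
#' as failing.
#'
#' @param de_records data.frame with `gene`, `log2_fold_change`, `adjusted_p`.
#' @param gene_list genes to evaluate (default: all genes in the records).
#' @param lfc_min,padj_max strict cutoffs.
#' @return character vector of passing genes.
#' @export
signature_filter <- function(de_records, gene_list = de_records$gene,
                             lfc_min = 1.5, padj_max = 0.05) {
  check_columns(de_records, c("gene", "log2_fold_change", "adjusted_p"),
                "DE table")
  if (any(de_records$adjusted_p < 0 | de_records$adjusted_p > 1, na.rm = TRUE)) {
    stop("adjusted_p must lie in [0, 1]")
  }
  hit <- match(gene_list, de_records$gene)
  pass <- !is.na(hit) &
    de_records$log2_fold_change[hit] > lfc_min &
    de_records$adjusted_p[hit] < padj_max
  pass[is.na(pass)] <- FALSE
  gene_list[pass]
}

#' Variance-scaled principal-component embedding
#'
#' Selects the `n_top_genes` most variable genes, computes principal
#' components over samples, and divides each component's scores by the
#' proportion of variance that component explains.  (This scaling inflates
#' minor components; it is implemented verbatim as the stated display
#' convention.)
#'
#' @param norm normalized gene x sample matrix (>= 2 samples).
#' @param n_top_genes number of top-variance genes (capped at the gene count
#'   with a warning).
#' @return list with `embedding` (sample x PC matrix of scaled scores),
#'   `proportion_variance`, `genes_used`.
#' @export
scaled_pc_embedding <- function(norm, n_top_genes = 1000) {
  norm <- as.matrix(norm)
  if (ncol(norm) < 2L) stop("need at least 2 samples")
  v <- apply(norm, 1, stats::var)
  if (n_top_genes > nrow(norm)) {
    warning("n_top_genes exceeds the gene count; using all genes")
    n_top_genes <- nrow(norm)
  }
  genes <- rownames(norm)[order(v, decreasing = TRUE)[seq_len(n_top_genes)]]
  pc <- stats::prcomp(t(norm[genes, , drop = FALSE]), center = TRUE, scale. = FALSE)
  prop <- pc$sdev^2 / sum(pc$sdev^2)
  # dividing by a numerically-zero variance proportion amplifies rounding
  # noise without bound; drop such components
  keep <- prop > 1e-10
  emb <- sweep(pc$x[, keep, drop = FALSE], 2, prop[keep], "/")
  list(embedding = emb, proportion_variance = prop[keep], genes_used = genes)
}

#' Ward hierarchical clustering of samples
#'
#' Utility wrapper: Euclidean distance on sample columns, Ward's minimum
#' variance linkage (`ward.D2`).
#'
#' @param norm normalized gene x sample matrix.
#' @return an [stats::hclust] tree over samples.
#' @export
cluster_samples_ward <- function(norm) {
  stats::hclust(stats::dist(t(as.matrix(norm))), method = "ward.D2")
}
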