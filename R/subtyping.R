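#' Per-core lineage composition
#'
#' Collapses gated cells to one frequency vector per tissue core over
#' \{epithelial, immune, stromal\}.  Endothelial cells are rare and are merged
#' into the stromal fraction for subtyping.  Cores with zero cells are
#' excluded with a warning.
#'
#' @param cells cell table with `core_id` and `lineage` columns (output of
#'   [gate_lineages()]).
#' @return data.frame with `core_id`, `epithelial`, `immune`, `stromal`
#'   (fractions summing to 1) and `n_cells`.
#' @export
compute_frequencies <- function(cells) {
  check_columns(cells, c("core_id", "lineage"), "cell table")
  if (nrow(cells) == 0L) stop("empty cell table")
  bad <- setdiff(unique(cells$lineage),
                 c("epithelial", "immune", "endothelial", "stromal"))
  if (length(bad) > 0L) stop("unknown lineage(s): ", paste(bad, collapse = ", "))
  lin3 <- ifelse(cells$lineage == "endothelial", "stromal", cells$lineage)
  lin3 <- factor(lin3, levels = c("epithelial", "immune", "stromal"))
  tab <- table(cells$core_id, lin3)
  n_cells <- rowSums(tab)
  if (any(n_cells == 0L)) {
    warning("excluding core(s) with zero cells: ",
            paste(rownames(tab)[n_cells == 0L], collapse = ", "))
    tab <- tab[n_cells > 0L, , drop = FALSE]
    n_cells <- n_cells[n_cells > 0L]
  }
  freq <- tab / n_cells
  out <- data.frame(core_id = rownames(tab),
                    epithelial = as.numeric(freq[, "epithelial"]),
                    immune = as.numeric(freq[, "immune"]),
                    stromal = as.numeric(freq[, "stromal"]),
                    n_cells = as.integer(n_cells),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Symmetric k-nearest-neighbour graph on the rows of x (Euclidean).
knn_graph <- function(x, k) {
  n <- nrow(x)
  if (k >= n) stop("k_neighbors must be smaller than the number of observations")
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nbr <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nbr)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Graph-community clustering of observations
#'
#' Builds a k-nearest-neighbour graph on the feature rows and partitions it
#' with the Leiden algorithm using the modularity (RB-Potts-style) objective
#' at the given resolution.  The mean silhouette width of the partition is
#' computed on Euclidean distances in the input feature space (`NA` for a
#' single-cluster solution).
#'
#' @param x numeric feature matrix or data.frame (observations in rows); all
#'   values must be finite.
#' @param k_neighbors neighbours for the kNN graph (default 15, the stated
#'   single-cell setting, reused at core level).
#' @param resolution Leiden resolution parameter.
#' @param seed integer seed (community detection is stochastic).
#' @return object of class `cluster_solution`: list with `labels` (integer
#'   cluster per observation, 1-based), `n_clusters`, `resolution`,
#'   `silhouette` (mean width), `k_neighbors`, `seed`.
#' @export
cluster_observations <- function(x, k_neighbors = 15, resolution = 0.5, seed = 0) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("features must be numeric")
  if (any(!is.finite(x))) stop("features contain non-finite values")
  if (nrow(x) < k_neighbors + 1) stop("k_neighbors must be smaller than the number of observations")
  g <- knn_graph(x, k_neighbors)
  local_seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 10)
  labels <- as.integer(igraph::membership(comm))
  labels <- as.integer(factor(labels))  # contiguous 1..k
  n_clusters <- max(labels)
  sil <- if (n_clusters > 1L) {
    mean(cluster::silhouette(labels, stats::dist(x))[, "sil_width"])
  } else NA_real_
  structure(list(labels = labels, n_clusters = n_clusters,
                 resolution = resolution, silhouette = sil,
                 k_neighbors = k_neighbors, seed = seed),
            class = "cluster_solution")
}

#' Resolution selection by silhouette width
#'
#' Clusters at every resolution in the grid and returns the solution with the
#' highest mean silhouette width; ties go to the lowest resolution.  The full
#' trace (resolution, number of clusters, silhouette) is attached for
#' auditing.  If every resolution yields a single cluster the first solution
#' is returned with a warning.
#'
#' @param x feature matrix, as [cluster_observations()].
#' @param resolutions numeric grid; default `c(0.2, 0.3, 0.4, 0.5)`, the grid
#'   used for tissue-core frequency clustering.
#' @param k_neighbors,seed passed to [cluster_observations()].
#' @return the chosen `cluster_solution`, with a `trace` data.frame element.
#' @export
select_resolution <- function(x, resolutions = c(0.2, 0.3, 0.4, 0.5),
                              k_neighbors = 15, seed = 0) {
  if (length(resolutions) == 0L) stop("resolution grid is empty")
  resolutions <- sort(resolutions)
  solutions <- lapply(resolutions, function(r) {
    cluster_observations(x, k_neighbors = k_neighbors, resolution = r, seed = seed)
  })
  trace <- data.frame(
    resolution = resolutions,
    n_clusters = vapply(solutions, `[[`, integer(1), "n_clusters"),
    silhouette = vapply(solutions, `[[`, numeric(1), "silhouette")
  )
  if (all(is.na(trace$silhouette))) {
    warning("all resolutions give a single cluster; returning the first solution")
    chosen <- solutions[[1]]
  } else {
    # ascending grid + which.max => ties resolve to the lowest resolution
    chosen <- solutions[[which.max(trace$silhouette)]]
  }
  chosen$trace <- trace
  chosen
}

#' Collapse clusters by centroid correlation
#'
#' Computes the mean feature vector of each raw cluster, hierarchically
#' clusters the centroids on correlation distance (1 - Pearson, average
#' linkage) and cuts the tree at `k_target` groups.
#'
#' @param solution a `cluster_solution` (or an integer label vector).
#' @param x the feature matrix the solution was computed on.
#' @param k_target number of collapsed groups (1..n_clusters).
#' @return named integer vector: raw cluster -> collapsed group (1..k_target).
#' @export
collapse_clusters <- function(solution, x, k_target) {
  labels <- if (inherits(solution, "cluster_solution")) solution$labels else as.integer(solution)
  x <- as.matrix(x)
  if (length(labels) != nrow(x)) stop("labels and features disagree in length")
  raw <- sort(unique(labels))
  k <- length(raw)
  if (k_target < 1L || k_target > k) {
    stop(sprintf("k_target must be in 1..%d", k))
  }
  if (k_target == k) {
    return(stats::setNames(seq_len(k), raw))
  }
  if (k_target == 1L) {
    return(stats::setNames(rep(1L, k), raw))
  }
  centroids <- t(vapply(raw, function(cl) colMeans(x[labels == cl, , drop = FALSE]),
                        numeric(ncol(x))))
  cmat <- suppressWarnings(stats::cor(t(centroids)))
  if (any(is.na(cmat))) {
    warning("correlation between some centroids is undefined (constant centroid); treating as 0")
    cmat[is.na(cmat)] <- 0
    diag(cmat) <- 1
  }
  hc <- stats::hclust(stats::as.dist(1 - cmat), method = "average")
  stats::setNames(as.integer(stats::cutree(hc, k = k_target)), raw)
}

#' Annotate three collapsed groups as SP / SR-IR / SR-IP
#'
#' The collapsed group with the highest mean epithelial fraction is the
#' stromal-poor (SP) subtype; of the remaining two, the one with the higher
#' mean immune fraction is stromal-rich-immune-rich (SR-IR) and the other
#' stromal-rich-immune-poor (SR-IP).  Ties on the deciding fraction are broken
#' deterministically by group index, with a warning.  If raw cluster labels
#' are supplied, cores belonging to the SP-member raw cluster with the lowest
#' mean stromal fraction are flagged `sp_plus` (the SP+ sub-phenotype with the
#' least stroma).
#'
#' @param groups integer vector of collapsed group labels per core (exactly 3
#'   distinct groups), aligned with `composition` rows.
#' @param composition the [compute_frequencies()] data.frame.
#' @param raw_labels optional raw cluster labels per core (for the SP+ flag).
#' @return data.frame with `core_id`, `raw_cluster` (if given), `group`,
#'   `subtype` and `sp_plus`.
#' @export
annotate_subtypes <- function(groups, composition, raw_labels = NULL) {
  check_columns(composition, c("core_id", "epithelial", "immune", "stromal"),
                "composition")
  if (length(groups) != nrow(composition)) {
    stop("`groups` must have one label per composition row")
  }
  gl <- sort(unique(groups))
  if (length(gl) != 3L) stop("exactly 3 collapsed groups are required")
  mean_by <- function(col) {
    vapply(gl, function(g) mean(composition[[col]][groups == g]), numeric(1))
  }
  epi <- mean_by("epithelial")
  if (sum(epi == max(epi)) > 1) {
    warning("tie on mean epithelial fraction; breaking by group index")
  }
  sp_group <- gl[which.max(epi)]
  rest <- gl[gl != sp_group]
  imm <- vapply(rest, function(g) mean(composition$immune[groups == g]), numeric(1))
  if (imm[1] == imm[2]) warning("tie on mean immune fraction; breaking by group index")
  srir_group <- rest[which.max(imm)]
  srip_group <- rest[rest != srir_group]
  map <- stats::setNames(c("SP", "SR-IR", "SR-IP"),
                         c(sp_group, srir_group, srip_group))
  subtype <- unname(map[as.character(groups)])

  sp_plus <- rep(FALSE, length(groups))
  if (!is.null(raw_labels)) {
    sp_raw <- unique(raw_labels[groups == sp_group])
    if (length(sp_raw) > 0L) {
      strom <- vapply(sp_raw, function(cl) {
        mean(composition$stromal[raw_labels == cl & groups == sp_group])
      }, numeric(1))
      sp_plus <- groups == sp_group & raw_labels == sp_raw[which.min(strom)]
    }
  }
  out <- data.frame(core_id = composition$core_id, group = groups,
                    subtype = subtype, sp_plus = sp_plus,
                    stringsAsFactors = FALSE)
  if (!is.null(raw_labels)) out$raw_cluster <- raw_labels
  out
}

#' Consensus lineage label for a cluster
#'
#' Returns the modal label of the cluster's member annotations if its
#' frequency reaches the agreement threshold ("at least 80 percent" by
#' default, inclusive), otherwise `"mixed"`.
#'
#' @param labels character vector of member annotations (nonempty).
#' @param threshold agreement threshold in (0.5, 1].
#' @return a single label or `"mixed"`.
#' @export
consensus_label <- function(labels, threshold = 0.8) {
  if (length(labels) == 0L) stop("empty member list")
  if (threshold <= 0.5 || threshold > 1) stop("threshold must be in (0.5, 1]")
  tab <- table(labels)
  modal <- names(tab)[which.max(tab)]
  if (max(tab) / length(labels) >= threshold) modal else "mixed"
}
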