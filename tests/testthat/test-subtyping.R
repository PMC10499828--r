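make_gated <- function(lineages, core_id = "c1") {
  data.frame(core_id = core_id, lineage = lineages, stringsAsFactors = FALSE)
}

test_that("compute_frequencies merges endothelial into stromal", {
  one <- compute_frequencies(make_gated(rep("epithelial", 10)))
  expect_equal(unlist(one[1, c("epithelial", "immune", "stromal")]),
               c(epithelial = 1, immune = 0, stromal = 0))
  # 5 epi, 3 immune, 1 endothelial, 1 stromal -> (0.5, 0.3, 0.2)
  mix <- make_gated(c(rep("epithelial", 5), rep("immune", 3),
                      "endothelial", "stromal"))
  out <- compute_frequencies(mix)
  expect_equal(unlist(out[1, c("epithelial", "immune", "stromal")]),
               c(epithelial = 0.5, immune = 0.3, stromal = 0.2))
  expect_equal(out$n_cells, 10L)
  # order invariance
  set.seed(1)
  expect_identical(compute_frequencies(mix[sample.int(10), , drop = FALSE]), out)
  # fractions always sum to 1
  expect_equal(out$epithelial + out$immune + out$stromal, 1)
  expect_error(compute_frequencies(make_gated("unknown")), "unknown lineage")
})

test_that("planted blobs are recovered exactly at the core-level resolution", {
  pb <- planted_blobs(n_per = 20, k = 3)
  sol <- cluster_observations(pb$x, k_neighbors = 15, resolution = 0.5, seed = 0)
  expect_equal(sol$n_clusters, 3L)
  expect_equal(adjusted_rand_index(sol$labels, pb$labels), 1)
  expect_gt(sol$silhouette, 0.5)
  # determinism
  sol2 <- cluster_observations(pb$x, k_neighbors = 15, resolution = 0.5, seed = 0)
  expect_identical(sol$labels, sol2$labels)
  # resolution -> 0: single cluster (on a connected kNN graph; disconnected
  # components can never merge under a vanishing resolution penalty)
  set.seed(2)
  one_blob <- matrix(rnorm(120), 60, 2)
  low <- cluster_observations(one_blob, k_neighbors = 15, resolution = 1e-6, seed = 0)
  expect_equal(low$n_clusters, 1L)
  expect_true(is.na(low$silhouette))
  # duplicated dataset: duplicates land in the same cluster
  dup <- rbind(pb$x, pb$x)
  sold <- cluster_observations(dup, k_neighbors = 15, resolution = 0.5, seed = 0)
  expect_equal(adjusted_rand_index(sold$labels, rep(pb$labels, 2)), 1)
  expect_error(cluster_observations(pb$x[1:10, ], k_neighbors = 15), "k_neighbors")
  xx <- pb$x; xx[1, 1] <- NA
  expect_error(cluster_observations(xx, k_neighbors = 5), "non-finite")
})

test_that("silhouette selection picks the planted number of clusters", {
  pb <- planted_blobs(n_per = 20, k = 3)
  chosen <- select_resolution(pb$x, c(0.2, 0.3, 0.4, 0.5), k_neighbors = 15, seed = 0)
  expect_equal(chosen$n_clusters, 3L)
  # the choice maximizes silhouette over the trace (exhaustive check)
  expect_equal(chosen$silhouette, max(chosen$trace$silhouette, na.rm = TRUE))
  # singleton grid
  single <- select_resolution(pb$x, 0.4, k_neighbors = 15, seed = 0)
  expect_equal(single$resolution, 0.4)
  # identical observations: 1-cluster warning path
  same <- matrix(1, 30, 2) + 0
  expect_warning(deg <- select_resolution(same, c(0.2, 0.5), k_neighbors = 5, seed = 0),
                 "single cluster")
  expect_equal(deg$n_clusters, 1L)
  expect_error(select_resolution(pb$x, numeric(0)), "empty")
})

test_that("silhouette selection recovers planted k on >= 90% of seeds", {
  hits <- vapply(1:50, function(s) {
    pb <- planted_blobs(n_per = 20, k = 3, seed = 400 + s)
    sol <- select_resolution(pb$x, c(0.2, 0.3, 0.4, 0.5), k_neighbors = 15, seed = 0)
    sol$n_clusters == 3L
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("collapse_clusters merges correlated centroid pairs", {
  # 6 cluster centroids forming 3 highly correlated pairs; oracle: exhaustive
  # search over all ways to partition 6 items into 3 pairs, minimizing total
  # within-pair correlation distance
  set.seed(5)
  base <- list(c(5, 0, 0, 1, 2), c(0, 5, 0, 2, 1), c(0, 0, 5, 1, 1))
  centroids <- do.call(rbind, lapply(base, function(b) {
    rbind(b + rnorm(5, 0, 0.01), b * 2 + rnorm(5, 0, 0.01))
  }))
  labels <- rep(1:6, each = 4)
  x <- centroids[labels, ] + rnorm(24 * 5, 0, 1e-3)

  all_pairings <- function(items) {
    if (length(items) == 0) return(list(list()))
    a <- items[1]
    out <- list()
    for (b in items[-1]) {
      rest <- setdiff(items, c(a, b))
      for (sub in all_pairings(rest)) out <- c(out, list(c(list(c(a, b)), sub)))
    }
    out
  }
  cmat <- cor(t(centroids))
  cost <- function(pairing) sum(vapply(pairing, function(p) 1 - cmat[p[1], p[2]],
                                       numeric(1)))
  pairings <- all_pairings(1:6)
  best <- pairings[[which.min(vapply(pairings, cost, numeric(1)))]]

  cmap <- collapse_clusters(labels, x, 3)
  expect_equal(length(unique(cmap)), 3L)
  for (p in best) expect_equal(cmap[[as.character(p[1])]], cmap[[as.character(p[2])]])

  # identity and total-merge boundaries
  expect_equal(unname(collapse_clusters(labels, x, 6)), 1:6)
  expect_equal(unname(collapse_clusters(labels, x, 1)), rep(1L, 6))
  expect_error(collapse_clusters(labels, x, 0), "k_target")
  expect_error(collapse_clusters(labels, x, 7), "k_target")
})

test_that("annotate_subtypes applies the epithelial-then-immune rule", {
  comp <- data.frame(
    core_id = sprintf("c%d", 1:6),
    epithelial = c(0.9, 0.9, 0.5, 0.5, 0.5, 0.5),
    immune = c(0.05, 0.05, 0.35, 0.35, 0.05, 0.05),
    stromal = c(0.05, 0.05, 0.15, 0.15, 0.45, 0.45),
    n_cells = 100
  )
  groups <- c(1, 1, 2, 2, 3, 3)
  ann <- annotate_subtypes(groups, comp)
  expect_equal(ann$subtype, c("SP", "SP", "SR-IR", "SR-IR", "SR-IP", "SR-IP"))
  # annotation is a bijection between the 3 groups and the 3 subtype names
  expect_equal(sort(unique(ann$subtype)), c("SP", "SR-IP", "SR-IR"))
  # SP+ flag goes to the SP raw cluster with the lowest stromal fraction
  comp2 <- comp; comp2$stromal[1] <- 0.01; comp2$epithelial[1] <- 0.94
  ann2 <- annotate_subtypes(groups, comp2, raw_labels = c(11, 12, 2, 2, 3, 3))
  expect_equal(ann2$sp_plus, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  # degenerate identical means: deterministic tie-break with warning
  flat <- comp; flat$epithelial <- 0.5; flat$immune <- 0.3; flat$stromal <- 0.2
  w <- capture_warnings(tie <- annotate_subtypes(groups, flat))
  expect_match(w, "tie", all = FALSE)
  expect_equal(sort(unique(tie$subtype)), c("SP", "SR-IP", "SR-IR"))
  expect_error(annotate_subtypes(c(1, 1, 1, 2, 2, 2), comp), "exactly 3")
})

test_that("consensus_label applies the inclusive 80% agreement rule", {
  expect_equal(consensus_label(rep(c("epithelial", "other"), c(17, 3))), "epithelial")
  expect_equal(consensus_label(rep(c("epithelial", "other"), c(15, 5))), "mixed")
  expect_equal(consensus_label(rep(c("epithelial", "other"), c(16, 4))), "epithelial")
  expect_equal(consensus_label("lymphoid"), "lymphoid")
  expect_error(consensus_label(character(0)), "empty")
  expect_error(consensus_label("a", threshold = 0.4), "threshold")
})
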