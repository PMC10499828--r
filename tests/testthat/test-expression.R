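test_that("size factors implement median-of-ratios", {
  counts <- matrix(rpois(200, 50) + 1, 50, 4,
                   dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:4)))
  # identical samples: all factors equal
  same <- counts[, c(1, 1, 1)]
  expect_equal(unname(size_factors(same)), rep(1, 3))
  # sample2 = 2 x sample1 exactly: factors (1/sqrt(2), sqrt(2))
  two <- cbind(s1 = counts[, 1], s2 = 2 * counts[, 1])
  expect_equal(unname(size_factors(two)), c(1 / sqrt(2), sqrt(2)))
  # single sample: factor 1
  expect_equal(unname(size_factors(counts[, 1, drop = FALSE])), 1)
  # cross-check against the reference median-of-ratios implementation
  skip_if_not_installed("DESeq2")
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  mine <- size_factors(counts)
  # both are defined up to a common scale; compare ratios
  expect_equal(unname(mine / mine[1]), unname(ref / ref[1]), tolerance = 1e-8)
  # no all-nonzero gene -> informative error
  z <- counts; z[cbind(1:50, rep(1:4, length.out = 50))] <- 0
  expect_error(size_factors(z), "pseudocount")
})

test_that("normalize_counts is the shifted-log stand-in", {
  counts <- matrix(c(0, 3, 7, 15), 2, 2)
  norm <- normalize_counts(counts, factors = c(1, 1))
  expect_equal(norm[1, 1], 0)          # log2(0/1 + 1)
  expect_equal(norm, log2(counts + 1))
  # doubling counts and factors together leaves norm unchanged
  expect_equal(normalize_counts(2 * counts, factors = c(2, 2)), norm)
  expect_error(normalize_counts(counts, factors = c(1, -1)), "positive")
})

test_that("ortholog mapping retains mapped genes and reports the fraction", {
  centro <- matrix(rnorm(12), 3, 4,
                   dimnames = list(c("GA", "GB", "GC"),
                                   c("BLIA", "BLIS", "LAR", "MES")))
  # identity map covering all genes
  full <- map_orthologs(centro, data.frame(human_symbol = c("GA", "GB", "GC"),
                                           mouse_symbol = c("Ga", "Gb", "Gc")))
  expect_equal(full$mapping_fraction, 1)
  expect_equal(full$mapped_genes, c("Ga", "Gb", "Gc"))
  # mapped centroids are re-z-scored per gene
  expect_equal(unname(rowMeans(full$centroids)), rep(0, 3))
  expect_equal(unname(apply(full$centroids, 1, sd)), rep(1, 3))
  # partial map
  part <- map_orthologs(centro, data.frame(human_symbol = "GB", mouse_symbol = "Gb"))
  expect_equal(part$mapping_fraction, 1 / 3)
  expect_equal(part$unmapped_genes, c("GA", "GC"))
  # duplicates resolved by first listed pair, with warning
  expect_warning(dup <- map_orthologs(centro, data.frame(
    human_symbol = c("GA", "GA"), mouse_symbol = c("Ga1", "Ga2"))), "duplicate")
  expect_equal(dup$mapped_genes, "Ga1")
  expect_error(map_orthologs(centro, data.frame(human_symbol = character(0),
                                                mouse_symbol = character(0))),
               "empty")
  expect_error(map_orthologs(centro, data.frame(human_symbol = "ZZ",
                                                mouse_symbol = "Zz")), "no centroid gene")
})

test_that("the packaged synthetic panel reproduces the 60/77 mapping fraction", {
  panel <- default_centroid_panel()
  expect_equal(length(panel$mapped_genes), 60L)
  expect_equal(length(panel$unmapped_genes), 17L)
  expect_equal(panel$mapping_fraction, 60 / 77)
  expect_equal(colnames(panel$centroids), c("BLIA", "BLIS", "LAR", "MES"))
})

test_that("centroid correlation calls the matching subtype", {
  panel <- default_centroid_panel()
  cz <- panel$centroids
  # a sample equal to the MES centroid: rho(MES) = 1, call MES
  norm <- cbind(sampleA = cz[, "MES"])
  res <- centroid_correlation(norm, panel)
  expect_equal(unname(res$call["sampleA"]), "MES")
  expect_equal(unname(res$rho["sampleA", "MES"]), 1)
  # a monotone transform of the centroid gives the same rho (rank statistic)
  res2 <- centroid_correlation(cbind(sampleA = exp(cz[, "MES"])), panel)
  expect_equal(res2$rho, res$rho)
  # constant sample vector: NA correlations, no call
  res3 <- centroid_correlation(cbind(flat = rep(1, nrow(cz)),
                                     sampleA = cz[, "BLIA"]), panel)
  expect_true(is.na(res3$call["flat"]))
  expect_error(centroid_correlation(matrix(1, 2, 2,
                                           dimnames = list(c("x", "y"), NULL)),
                                    panel), "shared")
})

test_that("call accuracy rises monotonically with the centroid shift", {
  cfg0 <- sim_config()
  truth <- list(cores = data.frame(core_id = sprintf("s%03d", 1:60),
                                   subtype = rep(c("SP", "SR-IR", "SR-IP"), 20)))
  panel <- default_centroid_panel()
  acc <- vapply(c(0, 0.5, 2), function(shift) {
    cfg <- cfg0
    cfg$expression_model$centroid_shift <- shift
    expr <- simulate_expression(cfg, truth, panel = panel, seed = 77)
    cc <- centroid_correlation(normalize_counts(expr$counts), panel)
    mean(cc$call == expr$subtype, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_gt(acc[3], acc[1])
})

test_that("signature_filter applies both strict cutoffs", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log2_fold_change = c(2.0, 1.5, 2.0, 3.0),
                   adjusted_p = c(0.01, 0.01, 0.05, 0.2))
  expect_equal(signature_filter(de), "a")       # b fails strict >, c strict <
  # missing genes count as failing
  expect_equal(signature_filter(de, gene_list = c("a", "zz")), "a")
  expect_equal(signature_filter(de, lfc_min = 0.5, padj_max = 0.5),
               c("a", "b", "c", "d"))
})

test_that("scaled PC embedding divides scores by the variance proportion", {
  set.seed(8)
  norm <- matrix(rnorm(300), 30, 10,
                 dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  emb <- scaled_pc_embedding(norm, n_top_genes = 30)
  pc <- prcomp(t(norm), center = TRUE)
  prop <- (pc$sdev^2 / sum(pc$sdev^2))
  expect_equal(unname(emb$embedding[, 1]), unname(pc$x[, 1] / prop[1]))
  # stated arithmetic: score 2.0 at variance proportion 0.5 -> 4.0
  expect_equal(2.0 / 0.5, 4.0)
  # unscaled components stay orthogonal
  expect_equal(max(abs(crossprod(pc$x[, 1:3])[upper.tri(diag(3))])), 0,
               tolerance = 1e-8)
  # duplicated samples give identical embedding rows
  dup <- cbind(norm, s11 = norm[, 1])
  embd <- scaled_pc_embedding(dup, n_top_genes = 30)
  expect_equal(unname(embd$embedding["s11", ]), unname(embd$embedding["s01", ]),
               tolerance = 1e-6)
  expect_warning(scaled_pc_embedding(norm, n_top_genes = 1000), "all genes")
  expect_error(scaled_pc_embedding(norm[, 1, drop = FALSE]), "2 samples")
})

test_that("subtype calls are invariant to monotone per-sample transforms", {
  cfg <- sim_config()
  truth <- list(cores = data.frame(core_id = sprintf("s%03d", 1:60),
                                   subtype = rep(c("SP", "SR-IR", "SR-IP"), 20)))
  panel <- default_centroid_panel()
  expr <- simulate_expression(cfg, truth, panel = panel, seed = 99)
  sf <- size_factors(expr$counts)
  scaled <- sweep(expr$counts, 2, sf, "/")
  transforms <- list(log2p1 = function(x) log2(x + 1),
                     sqrt = sqrt,
                     asinh = asinh)
  calls <- lapply(transforms, function(f) centroid_correlation(f(scaled), panel)$call)
  expect_identical(calls$log2p1, calls$sqrt)
  expect_identical(calls$log2p1, calls$asinh)
})
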