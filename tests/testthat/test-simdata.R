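test_that("simulate_cohort is deterministic given the seed", {
  cfg <- sim_config(n_cores = 2, cells_per_core = 200)
  a <- simulate_cohort(cfg, seed = 11)
  b <- simulate_cohort(cfg, seed = 11)
  c <- simulate_cohort(cfg, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$cells, c$cells))
  # the generator restores the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(simulate_cohort(cfg, seed = 5)); after <- runif(3)
  expect_identical(before, after)
})

test_that("realized composition matches the configured fractions", {
  # one SP core: epithelial fraction 0.8 within the normal-approx binomial
  # 99% CI at n = 1000
  cfg <- sim_config(n_cores = 1, cells_per_core = 1000,
                    compositions = list(
                      "SP" = c(epithelial = 0.8, immune = 0.07, stromal = 0.13)))
  coh <- simulate_cohort(cfg, seed = 3)
  p_hat <- coh$truth$realized_composition[1, "epithelial"]
  half <- qnorm(0.995) * sqrt(0.8 * 0.2 / 1000)
  expect_gt(p_hat, 0.8 - half)
  expect_lt(p_hat, 0.8 + half)
  # compositional convergence: within 1% at 1e4 cells per core
  cfg2 <- sim_config(n_cores = 1, cells_per_core = 10000)
  coh2 <- simulate_cohort(cfg2, seed = 4)
  for (s in cfg2$subtypes) {
    core <- coh2$truth$cores$core_id[coh2$truth$cores$subtype == s][1]
    realized <- coh2$truth$realized_composition[core, ]
    target <- cfg2$compositions[[s]]
    expect_lt(max(abs(realized[names(target)] - target)), 0.01)
  }
  # realized composition rows sum to 1 and truth covers every cell once
  expect_equal(unname(rowSums(coh2$truth$realized_composition)),
               rep(1, nrow(coh2$truth$realized_composition)))
  expect_setequal(coh2$truth$cells$cell_id, coh2$cells$cell_id)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(compositions = list(SP = c(epithelial = 0.9, immune = 0.2))),
               "sums to")
  expect_error(sim_config(core_radius_um = -5), "strictly positive")
  expect_error(sim_config(nest_radius_um = 800, core_radius_um = 700), "smaller")
  expect_error(sim_config(survival_model = list(hazards = c("SP" = -1, "SR-IR" = 1,
                                                            "SR-IP" = 1),
                                                censor_window = 10)),
               "hazards")
})

test_that("noise-free cohorts are perfectly gateable", {
  cfg <- noise_free_config(n_cores = 2, cells_per_core = 300)
  coh <- simulate_cohort(cfg, seed = 7)
  gcfg <- gating_config()
  # positive mode exp(log 20) = 20, negative exp(log 2) = 2: threshold anywhere
  # between separates exactly
  markers <- unique(c(gcfg$endothelial_marker, gcfg$immune_marker,
                      gcfg$epithelial_markers, gcfg$stromal_gating_markers))
  gcfg$thresholds <- setNames(rep(10, length(markers)), markers)
  gated <- gate_lineages(qc_filter(coh$cells)$cells, gcfg)
  truth <- coh$truth$cells$lineage[match(gated$cell_id, coh$truth$cells$cell_id)]
  expect_equal(mean(gated$lineage == truth), 1)
})

test_that("immune infiltration is graded periphery > border > core", {
  # default SR-IR profile: realized immune density must be lowest in the core
  # and ordered core < border < periphery in >= 95% of cores
  cfg <- sim_config(n_cores = 50, cells_per_core = 1000,
                    compositions = list("SR-IR" = c(epithelial = 0.45, immune = 0.30,
                                                    endothelial = 0.02, stromal = 0.23)))
  coh <- simulate_cohort(cfg, seed = 21)
  nest <- cfg$nest_radius_um; band <- cfg$band_width_um; R <- cfg$core_radius_um
  areas <- c(core = pi * (nest - band)^2,
             border = pi * ((nest + band)^2 - (nest - band)^2),
             periphery = pi * (R^2 - (nest + band)^2)) * 1e-6
  tc <- coh$truth$cells[coh$truth$cells$lineage == "immune", ]
  ok <- vapply(split(tc$compartment, tc$core_id), function(cp) {
    d <- table(factor(cp, levels = names(areas))) / areas
    d[["core"]] < d[["border"]] && d[["border"]] < d[["periphery"]]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("expression generator hits its degenerate and shifted regimes", {
  cfg <- sim_config()
  truth <- list(cores = data.frame(core_id = sprintf("s%03d", 1:10),
                                   subtype = rep(c("SP", "SR-IR"), 5)))
  # determinism
  e1 <- simulate_expression(cfg, truth, seed = 5)
  e2 <- simulate_expression(cfg, truth, seed = 5)
  expect_identical(e1, e2)
  # dispersion -> 0, shift 0: counts equal rounded expected means (identical
  # samples)
  cfg0 <- cfg
  cfg0$expression_model$dispersion <- 0
  cfg0$expression_model$centroid_shift <- 0
  e0 <- simulate_expression(cfg0, truth, seed = 5)
  expect_true(all(e0$counts == e0$counts[, 1]))
  # negative shift is a configuration error
  cfgn <- cfg
  cfgn$expression_model$centroid_shift <- -1
  expect_error(simulate_expression(cfgn, truth, seed = 1), "centroid_shift")
  expect_error(simulate_expression(cfg, list(cores = data.frame(
    core_id = character(0), subtype = character(0))), seed = 1), "no cores")
})

test_that("survival times follow the configured exponential law", {
  # hazard 0.01/day, n = 500, no censoring: median within 10% of ln(2)/0.01
  cfg <- sim_config(
    compositions = list("SP" = c(epithelial = 0.8, immune = 0.1, stromal = 0.1)),
    survival_model = list(hazards = c("SP" = 0.01), censor_window = 1e9))
  truth <- list(cores = data.frame(core_id = sprintf("m%03d", 1:500),
                                   subtype = "SP"))
  rec <- simulate_survival(truth, cfg, seed = 8)
  expect_true(all(rec$event == 1))
  expect_lt(abs(median(rec$time) - log(2) / 0.01), 0.1 * log(2) / 0.01)
  # censoring window 0: all censored at time 0
  cfg$survival_model$censor_window <- 0
  rec0 <- simulate_survival(truth, cfg, seed = 8)
  expect_true(all(rec0$time == 0) && all(rec0$event == 0))
  expect_error(simulate_survival(list(cores = data.frame(core_id = character(0),
                                                         subtype = character(0))),
                                 cfg), "empty")
})

test_that("log-rank p-values are uniform under equal hazards", {
  # all groups share one hazard: over repetitions the log-rank p should be
  # U(0,1) (KS test not rejecting at 0.01)
  cfg <- sim_config(survival_model = list(
    hazards = c("SP" = 0.01, "SR-IR" = 0.01, "SR-IP" = 0.01),
    censor_window = 400))
  truth <- list(cores = data.frame(
    core_id = sprintf("m%03d", 1:60),
    subtype = rep(c("SP", "SR-IR", "SR-IP"), each = 20)))
  ps <- vapply(1:200, function(i) {
    rec <- simulate_survival(truth, cfg, seed = 1000 + i)
    weighted_logrank(rec, "logrank")$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
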