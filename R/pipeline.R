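#' Pipeline configuration
#'
#' Assembles the configuration driving [run_pipeline()].  Three platform
#' presets encode the parameterizations used on the different data sources:
#' `"cycif_mouse"` (tissue-core clustering at fixed resolution 0.5, grid
#' c(0.2, 0.3, 0.4, 0.5) when silhouette selection is requested),
#' `"mibi_human"` (resolution 0.1) and `"synthetic"` (simulated cohort,
#' mouse parameterization).  Presets differ only in panel/resolution
#' defaults; every field can be overridden.
#'
#' @param preset one of `"synthetic"`, `"cycif_mouse"`, `"mibi_human"`.
#' @param paths named list of input paths (`cell_table`, `counts`,
#'   `survival`), required for the non-synthetic presets.
#' @param sim a [sim_config()] for the synthetic preset.
#' @param gating a [gating_config()]; `thresholds = NULL` requests
#'   [auto_threshold()] per gating marker.
#' @param k_neighbors kNN graph size for core clustering (capped at the
#'   number of cores minus 1 at run time).
#' @param resolution fixed Leiden resolution for core clustering; `NULL`
#'   selects by silhouette over `resolution_grid`.
#' @param resolution_grid grid for [select_resolution()].
#' @param grid_size_um,band_width_um spatial mask grid and border band.
#' @param do_spatial,do_expression,do_survival stage switches.
#' @param out_dir optional output directory; when set, stage outputs (CSV)
#'   and the run report (JSON) are written there.
#' @param seed master seed for all stage randomness.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("synthetic", "cycif_mouse", "mibi_human"),
                            paths = list(),
                            sim = sim_config(),
                            gating = gating_config(),
                            k_neighbors = 15,
                            resolution = NULL,
                            resolution_grid = c(0.2, 0.3, 0.4, 0.5),
                            grid_size_um = 50,
                            band_width_um = 100,
                            do_spatial = TRUE,
                            do_expression = TRUE,
                            do_survival = TRUE,
                            out_dir = NULL,
                            seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(resolution)) {
    resolution <- switch(preset, synthetic = , cycif_mouse = 0.5, mibi_human = 0.1)
  }
  structure(list(preset = preset, paths = paths, sim = sim, gating = gating,
                 k_neighbors = k_neighbors, resolution = resolution,
                 resolution_grid = resolution_grid,
                 grid_size_um = grid_size_um, band_width_um = band_width_um,
                 do_spatial = do_spatial, do_expression = do_expression,
                 do_survival = do_survival, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Thin wrapper so runs are reproducible from a single config document;
#' fields mirror the [pipeline_config()] arguments (nested `sim` / `gating`
#' objects are rebuilt through their constructors, so their invariants are
#' re-validated).
#'
#' @param path JSON file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- doc[intersect(names(doc), setdiff(names(formals(pipeline_config)),
                                            c("sim", "gating")))]
  if (!is.null(doc$sim)) args$sim <- do.call(sim_config, doc$sim)
  if (!is.null(doc$gating)) {
    g <- doc$gating
    if (!is.null(g$thresholds)) g$thresholds <- unlist(g$thresholds)
    args$gating <- do.call(gating_config, g)
  }
  do.call(pipeline_config, args)
}

# Auto-threshold every gating marker on the pooled corrected intensities.
# Values clamped to exactly 0 by background subtraction are unambiguous
# negatives; they are excluded so the clamp spike cannot masquerade as a
# second mode.
auto_thresholds_for <- function(cells, gcfg) {
  markers <- unique(c(gcfg$endothelial_marker, gcfg$immune_marker,
                      gcfg$epithelial_markers, gcfg$stromal_gating_markers))
  thr <- vapply(markers, function(m) {
    v <- cells[[m]]
    auto_threshold(v[v > 0])
  }, numeric(1))
  stats::setNames(thr, markers)
}

#' Run the end-to-end subtyping pipeline
#'
#' Orchestrates the full analysis in the order of the underlying workflow:
#' simulate (or read) a cell table, QC filter, background-subtract, gate
#' lineages, compute per-core compositions, cluster cores and collapse to the
#' three microenvironment subtypes, profile periphery/border/core densities,
#' call molecular subtypes on bulk counts, and compute the survival and
#' association statistics.  Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report` with per-stage results:
#'   `n_cells_input`, `qc_removed_fraction`, `thresholds`, `composition`,
#'   `cluster` (resolution, n_clusters, silhouette, trace), `subtypes`
#'   (per-core assignment, plus truth columns and recovery ARI for the
#'   synthetic preset), `densities`, `flow`, `expression` (correlations and
#'   calls), `survival` (log-rank and Gehan tests), `association`
#'   (chi-squared of called vs true subtype, synthetic preset), `config`
#'   fingerprint.  When `out_dir` is set the tables and a JSON report are
#'   also written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(preset = config$preset, seed = config$seed)

  truth <- NULL
  if (config$preset == "synthetic") {
    cohort <- simulate_cohort(config$sim, seed = config$seed)
    cells <- cohort$cells
    truth <- cohort$truth
  } else {
    if (is.null(config$paths$cell_table)) {
      stop("config$paths$cell_table is required for non-synthetic presets")
    }
    cells <- read_cell_table(config$paths$cell_table)
  }
  report$n_cells_input <- nrow(cells)

  qc <- qc_filter(cells)
  cells <- qc$cells
  report$qc_removed_fraction <- qc$removed_fraction

  gcfg <- config$gating
  cells <- subtract_background(cells, gcfg)
  if (is.null(gcfg$thresholds)) {
    gcfg$thresholds <- auto_thresholds_for(cells, gcfg)
  }
  report$thresholds <- gcfg$thresholds
  cells <- gate_lineages(cells, gcfg)
  report$n_cells_gated <- nrow(cells)

  composition <- compute_frequencies(cells)
  report$composition <- composition

  feats <- as.matrix(composition[, c("epithelial", "immune", "stromal")])
  k_nb <- min(config$k_neighbors, nrow(feats) - 1L)
  if (is.null(config$resolution)) {
    sol <- select_resolution(feats, config$resolution_grid,
                             k_neighbors = k_nb, seed = config$seed)
  } else {
    sol <- cluster_observations(feats, k_neighbors = k_nb,
                                resolution = config$resolution,
                                seed = config$seed)
  }
  report$cluster <- list(resolution = sol$resolution,
                         n_clusters = sol$n_clusters,
                         silhouette = sol$silhouette,
                         trace = sol$trace)

  if (sol$n_clusters >= 3L) {
    cmap <- collapse_clusters(sol, feats, 3L)
    groups <- unname(cmap[as.character(sol$labels)])
    subtypes <- annotate_subtypes(groups, composition, raw_labels = sol$labels)
  } else {
    warning("fewer than 3 clusters found; subtype annotation skipped")
    subtypes <- data.frame(core_id = composition$core_id,
                           group = sol$labels, subtype = NA_character_,
                           sp_plus = FALSE, raw_cluster = sol$labels,
                           stringsAsFactors = FALSE)
  }
  if (!is.null(truth)) {
    subtypes$true_subtype <- truth$cores$subtype[
      match(subtypes$core_id, truth$cores$core_id)]
    if (!all(is.na(subtypes$subtype))) {
      report$recovery_ari <- adjusted_rand_index(subtypes$subtype,
                                                 subtypes$true_subtype)
    }
  }
  report$subtypes <- subtypes

  if (config$do_spatial) {
    dens <- do.call(rbind, lapply(split(cells, cells$core_id), function(sub) {
      mask <- withCallingHandlers(
        build_tumor_mask(sub, grid_size_um = config$grid_size_um),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!any(mask$mask)) return(NULL)
      cm <- assign_compartments(sub, mask, band_width_um = config$band_width_um)
      d <- compartment_densities(sub, cm)
      d$core_id <- sub$core_id[1]
      d
    }))
    rownames(dens) <- NULL
    dens <- zlog_densities(dens)
    report$densities <- dens
    report$flow <- stats::aggregate(count ~ compartment + cell_type, dens, sum)
  }

  if (config$do_expression) {
    panel <- default_centroid_panel()
    if (config$preset == "synthetic") {
      expr <- simulate_expression(config$sim, truth, panel = panel,
                                  seed = config$seed + 1L)
      counts <- expr$counts
    } else if (!is.null(config$paths$counts)) {
      if (!file.exists(config$paths$counts)) {
        stop(sprintf("counts file not found: %s", config$paths$counts))
      }
      counts <- read_counts_tsv(config$paths$counts)
      expr <- NULL
    } else {
      counts <- NULL
    }
    if (!is.null(counts)) {
      norm <- normalize_counts(counts)
      cc <- centroid_correlation(norm, panel)
      report$expression <- list(rho = cc$rho, call = cc$call,
                                n_genes = cc$n_genes,
                                mapping_fraction = panel$mapping_fraction)
      if (!is.null(expr)) {
        report$expression$true_subtype <- expr$subtype
        report$expression$call_accuracy <- mean(cc$call == expr$subtype,
                                                na.rm = TRUE)
      }
    }
  }

  if (config$do_survival) {
    surv <- if (config$preset == "synthetic") {
      simulate_survival(truth, config$sim, seed = config$seed + 2L)
    } else if (!is.null(config$paths$survival)) {
      read_survival_csv(config$paths$survival)
    } else NULL
    if (!is.null(surv)) {
      lr <- weighted_logrank(surv, "logrank")
      gw <- weighted_logrank(surv, "gehan")
      report$survival <- list(
        km = km_estimate(surv),
        logrank = list(statistic = lr$statistic, df = lr$df, p = lr$p_value),
        gehan = list(statistic = gw$statistic, df = gw$df, p = gw$p_value)
      )
    }
  }

  if (!is.null(truth) && !all(is.na(subtypes$subtype))) {
    tab <- table(subtypes$subtype, subtypes$true_subtype)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0) && all(dim(tab) > 1)) {
      report$association <- chi_squared_association(tab)
    }
  }

  report$config <- list(preset = config$preset, seed = config$seed,
                        k_neighbors = config$k_neighbors,
                        resolution = config$resolution,
                        grid_size_um = config$grid_size_um,
                        band_width_um = config$band_width_um)
  class(report) <- "run_report"

  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

# Serialize the run report: CSV tables + a JSON summary.
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$composition, file.path(out_dir, "composition.csv"),
                   row.names = FALSE)
  utils::write.csv(report$subtypes, file.path(out_dir, "subtypes.csv"),
                   row.names = FALSE)
  if (!is.null(report$densities)) {
    utils::write.csv(report$densities, file.path(out_dir, "densities.csv"),
                     row.names = FALSE)
  }
  summary <- report
  summary$composition <- NULL
  summary$densities <- NULL
  summary$flow <- NULL
  summary$subtypes <- NULL
  if (!is.null(summary$expression)) summary$expression$rho <- NULL
  if (!is.null(summary$survival)) summary$survival$km <- NULL
  jsonlite::write_json(summary, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("tmesubtype run report (preset:", x$preset, ", seed:", x$seed, ")\n")
  cat(sprintf("  cells: %d in, %.1f%% removed by QC\n",
              x$n_cells_input, 100 * x$qc_removed_fraction))
  cat(sprintf("  cores: %d; clusters: %d at resolution %.2f (silhouette %.3f)\n",
              nrow(x$composition), x$cluster$n_clusters,
              x$cluster$resolution,
              ifelse(is.na(x$cluster$silhouette), NA, x$cluster$silhouette)))
  if (!is.null(x$subtypes$subtype)) {
    print(table(subtype = x$subtypes$subtype))
  }
  if (!is.null(x$recovery_ari)) {
    cat(sprintf("  subtype recovery ARI vs truth: %.3f\n", x$recovery_ari))
  }
  if (!is.null(x$expression$call_accuracy)) {
    cat(sprintf("  molecular subtype call accuracy: %.3f\n",
                x$expression$call_accuracy))
  }
  if (!is.null(x$survival)) {
    cat(sprintf("  survival: log-rank chi2 = %.2f (p = %.3g), Gehan chi2 = %.2f (p = %.3g)\n",
                x$survival$logrank$statistic, x$survival$logrank$p,
                x$survival$gehan$statistic, x$survival$gehan$p))
  }
  invisible(x)
}
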