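#' Gating configuration
#'
#' Collects the per-marker thresholds and marker-role lists used by
#' [gate_lineages()] and [subtract_background()].  The defaults mirror the
#' mouse CyCIF panel conventions: epithelial cells are positive for one or
#' more of Ecad, EpCAM, CK5; immune cells CD45+; endothelial cells CD31+;
#' background subtraction is applied to the high-background markers present in
#' the panel.  `fallback_cores` lists cores whose tumor cells lack canonical
#' epithelial markers; in those cores any cell negative for all
#' `stromal_gating_markers` is called epithelial (negative-definition tumor
#' gating).
#'
#' @param thresholds named numeric vector of per-marker positivity thresholds
#'   (same units as the corrected intensities); positivity is strict
#'   (`intensity > threshold`). May be `NULL` at construction and filled later
#'   (e.g. from [auto_threshold()]).
#' @param epithelial_markers,immune_marker,endothelial_marker marker roles.
#' @param stromal_gating_markers markers whose joint negativity defines tumor
#'   cells in fallback cores; default CD31, CD45, Vim, aSMA, ColIV, ColVI,
#'   Gal3.
#' @param background_markers markers that receive per-core background
#'   subtraction.
#' @param fallback_cores character vector of core IDs using the
#'   negative-definition tumor rule.
#' @return object of class `gating_config`.
#' @export
gating_config <- function(thresholds = NULL,
                          epithelial_markers = c("Ecad", "EpCAM", "CK5"),
                          immune_marker = "CD45",
                          endothelial_marker = "CD31",
                          stromal_gating_markers = c("CD31", "CD45", "Vim",
                                                     "aSMA", "ColIV", "ColVI",
                                                     "Gal3"),
                          background_markers = c("CD31", "CD45", "ColIV"),
                          fallback_cores = character(0)) {
  if (!is.null(thresholds)) {
    if (is.null(names(thresholds)) || any(names(thresholds) == "")) {
      stop("`thresholds` must be a named numeric vector")
    }
    if (any(!is.finite(thresholds)) || any(thresholds < 0)) {
      stop("thresholds must be finite and >= 0")
    }
  }
  structure(list(
    thresholds = thresholds,
    epithelial_markers = epithelial_markers,
    immune_marker = immune_marker,
    endothelial_marker = endothelial_marker,
    stromal_gating_markers = stromal_gating_markers,
    background_markers = background_markers,
    fallback_cores = fallback_cores
  ), class = "gating_config")
}

#' Quality-control filter: drop DAPI-negative cells
#'
#' Cells negative for DAPI after the staining rounds have lost their nucleus
#' (tissue loss) and are removed before any downstream analysis; on real TMA
#' data this removes on the order of two percent of cells.
#'
#' @param cells a cell table containing a logical (or 0/1) `dapi_positive`
#'   column.
#' @return list with `cells` (retained rows) and `removed_fraction` in
#'   \eqn{[0, 1]}.
#' @export
qc_filter <- function(cells) {
  if (nrow(cells) == 0L) stop("empty cell table")
  check_columns(cells, "dapi_positive", "cell table")
  keep <- as.logical(cells$dapi_positive)
  if (any(is.na(keep))) stop("dapi_positive contains missing values")
  removed_fraction <- mean(!keep)
  if (all(!keep)) warning("all cells are DAPI-negative; returning empty table")
  list(cells = cells[keep, , drop = FALSE], removed_fraction = removed_fraction)
}

#' Per-core background subtraction for high-background markers
#'
#' For each flagged marker the per-core background level is estimated from the
#' marker's intensity distribution within that core and subtracted; results
#' are clamped at zero.  The published image-domain autofluorescence
#' interpolation is out of scope for a single-cell table, so the default
#' estimator is a table-level stand-in: the per-core 20th percentile of the
#' marker's intensities.
#'
#' @param cells cell table with `core_id` and marker intensity columns.
#' @param config a [gating_config()]; `background_markers` are corrected.
#' @param estimator function of a numeric vector returning one background
#'   estimate; default 20th percentile. Negative estimates are treated as 0
#'   with a warning.
#' @return the cell table with corrected intensities for flagged markers.
#' @export
subtract_background <- function(cells, config,
                                estimator = function(x) stats::quantile(x, 0.2, names = FALSE)) {
  stopifnot(inherits(config, "gating_config"))
  markers <- config$background_markers
  check_columns(cells, c("core_id", markers), "cell table")
  for (m in markers) {
    for (core in unique(cells$core_id)) {
      sel <- cells$core_id == core
      est <- estimator(cells[[m]][sel])
      if (!is.finite(est)) stop(sprintf("background estimate for %s in core %s is not finite", m, core))
      if (est < 0) {
        warning(sprintf("negative background estimate for %s in core %s; using 0", m, core))
        est <- 0
      }
      cells[[m]][sel] <- pmax(cells[[m]][sel] - est, 0)
    }
  }
  cells
}

#' Automatic intensity threshold (Otsu-style)
#'
#' Convenience default for panels without manually set thresholds: maximizes
#' the between-class variance over a histogram of the intensity distribution
#' (equivalently, minimizes the pooled intra-class variance).  By default the
#' histogram is built on the `log10(x + 1)` scale, which symmetrizes the
#' log-normal positive/negative components of fluorescence intensities and
#' keeps the cut stable when the positive class is rare; the threshold is
#' returned on the original scale.  It lies strictly between the minimum and
#' maximum observed value.
#'
#' @param values numeric vector of marker intensities (>= 10 finite values).
#' @param n_bins number of histogram bins.
#' @param log threshold on the `log10(x + 1)` scale (default; requires
#'   non-negative values).
#' @return a single threshold value.
#' @export
auto_threshold <- function(values, n_bins = 256, log = TRUE) {
  v <- values[is.finite(values)]
  if (log) {
    if (any(v < 0)) stop("log-scale thresholding requires non-negative values")
    return(10^auto_threshold(log10(v + 1), n_bins = n_bins, log = FALSE) - 1)
  }
  if (length(v) < 10L) stop("need at least 10 finite values")
  rng <- range(v)
  if (diff(rng) <= .Machine$double.eps^0.5 * max(1, abs(rng[2]))) {
    stop("constant intensity vector: no separation to threshold")
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)                       # class-0 mass below each cut
  mu_cum <- cumsum(p * mids)
  mu_total <- mu_cum[n_bins]
  # between-class variance for cuts after bin t (t = 1..n_bins-1)
  t <- seq_len(n_bins - 1)
  w0 <- omega[t]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins - 1)
  sigma_b[valid] <- (mu_total * w0[valid] - mu_cum[t][valid])^2 /
    (w0[valid] * w1[valid])
  # the optimum is a plateau when the histogram has an empty gap between the
  # components; take the middle of the plateau, as standard Otsu codes do
  plateau <- which(sigma_b >= max(sigma_b) * (1 - 1e-9))
  best <- plateau[ceiling(length(plateau) / 2)]
  threshold <- breaks[best + 1]            # upper edge of the last class-0 bin
  # contract: strictly inside the observed range
  min(max(threshold, rng[1] + diff(rng) * 1e-9), rng[2] - diff(rng) * 1e-9)
}

#' Rule-based lineage gating
#'
#' Applies the manual-gating rules as an exhaustive, mutually exclusive
#' partition in priority order: endothelial cells are CD31+; epithelial cells
#' are positive for one or more epithelial marker and CD31-; immune cells are
#' CD45+, CD31- and epithelial-marker negative; stromal cells are all
#' remaining segmented nuclei.  For cores in `fallback_cores` (tumors whose
#' epithelial cells are negative for the canonical epithelial markers), cells
#' negative for all `stromal_gating_markers` are called epithelial.
#' Positivity is strict: corrected intensity > threshold.
#'
#' @param cells cell table (background-corrected) with `core_id` and the
#'   gating marker columns.
#' @param config a [gating_config()] with `thresholds` set for every gating
#'   marker.
#' @return the cell table with added columns `lineage` (one of epithelial /
#'   immune / endothelial / stromal) and `rule_fired`.
#' @export
gate_lineages <- function(cells, config) {
  stopifnot(inherits(config, "gating_config"))
  if (is.null(config$thresholds)) stop("gating thresholds are not set")
  gating_markers <- unique(c(config$endothelial_marker, config$immune_marker,
                             config$epithelial_markers,
                             config$stromal_gating_markers))
  missing_thr <- setdiff(gating_markers, names(config$thresholds))
  if (length(missing_thr) > 0L) {
    stop("no threshold for marker(s): ", paste(missing_thr, collapse = ", "))
  }
  check_columns(cells, c("core_id", gating_markers), "cell table")

  pos <- vapply(gating_markers,
                function(m) cells[[m]] > config$thresholds[[m]],
                logical(nrow(cells)))
  if (nrow(cells) == 1L) pos <- matrix(pos, nrow = 1, dimnames = list(NULL, gating_markers))

  endo <- pos[, config$endothelial_marker]
  epi_marker_pos <- rowSums(pos[, config$epithelial_markers, drop = FALSE]) > 0
  fallback <- cells$core_id %in% config$fallback_cores &
    rowSums(pos[, config$stromal_gating_markers, drop = FALSE]) == 0
  imm <- pos[, config$immune_marker]

  lineage <- rep("stromal", nrow(cells))
  rule <- rep("default_stromal", nrow(cells))
  # priority: endothelial > epithelial (canonical or fallback) > immune > stromal
  sel <- !endo & !epi_marker_pos & !fallback & imm
  lineage[sel] <- "immune"; rule[sel] <- "CD45pos_CD31neg_epineg"
  sel <- !endo & fallback & !epi_marker_pos
  lineage[sel] <- "epithelial"; rule[sel] <- "fallback_negative_definition"
  sel <- !endo & epi_marker_pos
  lineage[sel] <- "epithelial"; rule[sel] <- "epithelial_marker_pos_CD31neg"
  lineage[endo] <- "endothelial"; rule[endo] <- "CD31pos"

  cells$lineage <- lineage
  cells$rule_fired <- rule
  cells
}
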