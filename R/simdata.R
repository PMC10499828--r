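#' Default marker model for the synthetic CyCIF-style panel
#'
#' One row per marker with the two-component log-normal intensity parameters
#' (`mu_neg`, `mu_pos` are meanlog values; `sigma` the common sdlog) and the
#' additive background model for markers flagged as high-background.  The panel
#' is the 10-marker gating subset of a mouse mammary CyCIF panel: endothelial
#' CD31, pan-immune CD45, epithelial Ecad/EpCAM/CK5, and the stromal/matrix
#' markers Vim, aSMA, ColIV, ColVI and Gal3.  Background is flagged on CD31,
#' CD45 and ColIV (members of the high-background set that are in this panel).
#'
#' @return data.frame with columns `marker`, `mu_neg`, `mu_pos`, `sigma`,
#'   `background`, `background_level`.
#' @export
default_marker_model <- function() {
  markers <- c("CD31", "CD45", "Ecad", "EpCAM", "CK5",
               "Vim", "aSMA", "ColIV", "ColVI", "Gal3")
  data.frame(
    marker = markers,
    mu_neg = log(2),
    mu_pos = log(20),
    sigma = 0.4,
    background = markers %in% c("CD31", "CD45", "ColIV"),
    background_level = ifelse(markers %in% c("CD31", "CD45", "ColIV"), 1.5, 0),
    stringsAsFactors = FALSE
  )
}

#' Default lineage -> positive-marker map for the synthetic panel
#'
#' Which markers each simulated lineage expresses above background.  Matches
#' the gating rules: endothelial cells are CD31+, epithelial cells express the
#' epithelial markers, immune cells CD45, stromal cells the matrix/mesenchymal
#' markers.
#'
#' @return named list of character vectors.
#' @export
default_lineage_markers <- function() {
  list(
    epithelial  = c("Ecad", "EpCAM", "CK5"),
    immune      = "CD45",
    endothelial = "CD31",
    stromal     = c("Vim", "aSMA", "ColIV", "ColVI", "Gal3")
  )
}

#' Simulation configuration for synthetic multiplex-imaging cohorts
#'
#' Builds and validates the stated world that the downstream modules are tested
#' against: tissue cores of three ground-truth microenvironment subtypes
#' (stromal-poor SP, stromal-rich-immune-rich SR-IR, stromal-rich-immune-poor
#' SR-IP) with subtype-specific epithelial/immune/stromal composition, a disk
#' core with a concentric tumor nest and compartment-graded immune
#' infiltration (immune density lowest in the tumor core), two-component
#' log-normal marker intensities with additive per-core background on flagged
#' markers, negative-binomial bulk counts with subtype-specific centroid
#' shifts, and exponential survival with subtype-specific hazards.
#'
#' @param n_cores cores per subtype.
#' @param cells_per_core cells simulated per core.
#' @param compositions named list (one per subtype) of lineage fraction
#'   vectors; each must sum to 1. Names must be a subset of
#'   `c("epithelial","immune","endothelial","stromal")`.
#' @param core_radius_um radius of the (disk) tissue core in micrometres;
#'   default 750 (a 1.5 mm diameter TMA core).
#' @param nest_radius_um radius of the concentric tumor nest.
#' @param band_width_um half-width of the border band around the nest edge
#'   used for the ground-truth compartment labels.
#' @param infiltration named list (one per subtype) of per-compartment immune
#'   density multipliers `c(periphery=, border=, core=)`; the default enforces
#'   periphery > border > core.
#' @param marker_model data.frame as [default_marker_model()].
#' @param lineage_markers list as [default_lineage_markers()].
#' @param dapi_negative_frac fraction of cells emitted DAPI-negative
#'   (tissue-loss artifact; default 0.02, the QC filter's stated scale).
#' @param expression_model list with `n_genes`, `dispersion` (NB dispersion,
#'   variance = mu + dispersion * mu^2), `centroid_shift` (signature-gene shift
#'   toward the sample's true centroid, in units of the gene's marginal
#'   log2-count sd), `base_mean_log`, `base_mean_sd` (log-normal baseline
#'   means).
#' @param survival_model list with `hazards` (named per-subtype event rates,
#'   1/day) and `censor_window` (days; uniform independent censoring on
#'   `[0, censor_window]`).
#' @param seed default integer seed used by the generators.
#' @return object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_expression()], [simulate_survival()]
#' @export
sim_config <- function(n_cores = 20,
                       cells_per_core = 1000,
                       compositions = list(
                         "SP"    = c(epithelial = 0.80, immune = 0.07,
                                     endothelial = 0.02, stromal = 0.11),
                         "SR-IR" = c(epithelial = 0.45, immune = 0.30,
                                     endothelial = 0.02, stromal = 0.23),
                         "SR-IP" = c(epithelial = 0.45, immune = 0.05,
                                     endothelial = 0.02, stromal = 0.48)
                       ),
                       core_radius_um = 750,
                       nest_radius_um = 500,
                       band_width_um = 100,
                       infiltration = NULL,
                       marker_model = default_marker_model(),
                       lineage_markers = default_lineage_markers(),
                       dapi_negative_frac = 0.02,
                       expression_model = list(
                         n_genes = 200, dispersion = 0.1, centroid_shift = 2,
                         base_mean_log = log(500), base_mean_sd = 1
                       ),
                       survival_model = list(
                         hazards = c("SP" = 0.02, "SR-IR" = 0.004, "SR-IP" = 0.008),
                         censor_window = 365
                       ),
                       seed = 1L) {
  subtypes <- names(compositions)
  if (is.null(subtypes) || any(subtypes == "")) {
    stop("`compositions` must be a named list (one entry per subtype)")
  }
  if (is.null(infiltration)) {
    infiltration <- stats::setNames(
      rep(list(c(periphery = 4, border = 2, core = 1)), length(subtypes)),
      subtypes
    )
  }
  cfg <- structure(list(
    n_cores = as.integer(n_cores),
    cells_per_core = as.integer(cells_per_core),
    subtypes = subtypes,
    compositions = compositions,
    core_radius_um = core_radius_um,
    nest_radius_um = nest_radius_um,
    band_width_um = band_width_um,
    infiltration = infiltration,
    marker_model = marker_model,
    lineage_markers = lineage_markers,
    dapi_negative_frac = dapi_negative_frac,
    expression_model = expression_model,
    survival_model = survival_model,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  known <- c("epithelial", "immune", "endothelial", "stromal")
  for (s in cfg$subtypes) {
    comp <- cfg$compositions[[s]]
    if (is.null(names(comp)) || !all(names(comp) %in% known)) {
      stop("composition lineages must be named from: ",
           paste(known, collapse = ", "))
    }
    if (any(comp < 0) || any(comp > 1)) {
      stop(sprintf("composition for subtype '%s' has fractions outside [0,1]", s))
    }
    if (abs(sum(comp) - 1) > 1e-9) {
      stop(sprintf("composition for subtype '%s' sums to %.6f, not 1", s, sum(comp)))
    }
    infl <- cfg$infiltration[[s]]
    if (is.null(infl) || !all(c("periphery", "border", "core") %in% names(infl))) {
      stop(sprintf("infiltration profile for subtype '%s' must name periphery/border/core", s))
    }
    if (any(infl < 0)) stop("infiltration multipliers must be >= 0")
  }
  geom <- c(cfg$core_radius_um, cfg$nest_radius_um, cfg$band_width_um)
  if (any(!is.finite(geom)) || any(geom <= 0)) {
    stop("core_radius_um, nest_radius_um and band_width_um must be strictly positive")
  }
  if (cfg$nest_radius_um >= cfg$core_radius_um) {
    stop("nest_radius_um must be smaller than core_radius_um")
  }
  if (cfg$n_cores < 1L || cfg$cells_per_core < 1L) {
    stop("n_cores and cells_per_core must be >= 1")
  }
  if (cfg$dapi_negative_frac < 0 || cfg$dapi_negative_frac >= 1) {
    stop("dapi_negative_frac must be in [0, 1)")
  }
  em <- cfg$expression_model
  if (em$dispersion < 0) stop("expression dispersion must be >= 0")
  if (em$centroid_shift < 0) stop("centroid_shift must be >= 0")
  sm <- cfg$survival_model
  if (!all(cfg$subtypes %in% names(sm$hazards))) {
    stop("survival hazards must be named for every subtype")
  }
  if (any(sm$hazards <= 0)) stop("hazards must be strictly positive")
  if (sm$censor_window < 0) stop("censor_window must be >= 0")
  mm <- cfg$marker_model
  check_columns(mm, c("marker", "mu_neg", "mu_pos", "sigma",
                      "background", "background_level"), "marker_model")
  panel <- mm$marker
  if (!all(unlist(cfg$lineage_markers) %in% panel)) {
    stop("lineage_markers refer to markers outside the panel")
  }
  cfg
}

# Compartment label of a radius relative to the nest edge.
compartment_of_radius <- function(r, nest_radius, band_width) {
  ifelse(r < nest_radius - band_width, "core",
         ifelse(r <= nest_radius + band_width, "border", "periphery"))
}

# Draw n uniform points in the annulus [r0, r1) of a disk centred at 0.
runif_annulus <- function(n, r0, r1) {
  r <- sqrt(stats::runif(n, r0^2, r1^2))
  theta <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * cos(theta), y = r * sin(theta), r = r)
}

#' Simulate a synthetic multiplex-imaging cohort with known ground truth
#'
#' Generates `n_cores` disk-shaped tissue cores per subtype.  Each cell draws a
#' lineage from the subtype's composition; epithelial cells are placed
#' uniformly in the concentric tumor nest, stromal and endothelial cells in
#' the surrounding annulus, and immune cells across the three ground-truth
#' compartments (core / border / periphery of the nest edge) with probability
#' proportional to compartment area times the subtype's infiltration
#' multiplier, which produces the graded infiltration pattern (immune density
#' lowest in the tumor core).  Marker intensities are log-normal draws from the
#' positive component for the lineage's markers and the negative component
#' otherwise; background-flagged markers get a constant-per-core additive
#' background term.  A configurable fraction of cells is emitted DAPI-negative.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`. Identical config and
#'   seed give identical output.
#' @return list of class `sim_cohort` with elements
#'   \describe{
#'     \item{cells}{data.frame, one row per cell: `cell_id`, `core_id`,
#'       `x_um`, `y_um`, `nuclear_area_um2`, `eccentricity`, `dapi_positive`
#'       and one intensity column per marker.}
#'     \item{truth}{list with `cores` (core_id, subtype), `cells` (cell_id,
#'       core_id, lineage, compartment), `realized_composition` (core x lineage
#'       fraction matrix, rows sum to 1) and `seed`.}
#'   }
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  local_seed(seed)

  nest <- config$nest_radius_um
  band <- config$band_width_um
  R <- config$core_radius_um
  # immune compartment sampling: annuli bounded by the nest edge +/- band
  r_core_hi <- max(nest - band, 0)
  r_border_hi <- min(nest + band, R)
  areas <- c(periphery = R^2 - r_border_hi^2,
             border = r_border_hi^2 - r_core_hi^2,
             core = r_core_hi^2)

  mm <- config$marker_model
  lineages_all <- c("epithelial", "immune", "endothelial", "stromal")

  cells_list <- list()
  truth_list <- list()
  core_rows <- list()
  idx <- 0L
  for (s in config$subtypes) {
    comp <- config$compositions[[s]]
    infl <- config$infiltration[[s]][c("periphery", "border", "core")]
    for (k in seq_len(config$n_cores)) {
      idx <- idx + 1L
      core_id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9+-]", "", s), k)
      n <- config$cells_per_core
      lineage <- sample(names(comp), n, replace = TRUE, prob = comp)

      xy <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "r")))
      is_epi <- lineage == "epithelial"
      is_imm <- lineage == "immune"
      is_out <- !is_epi & !is_imm  # stromal + endothelial: outside the nest
      if (any(is_epi)) xy[is_epi, ] <- runif_annulus(sum(is_epi), 0, nest)
      if (any(is_out)) xy[is_out, ] <- runif_annulus(sum(is_out), nest, R)
      if (any(is_imm)) {
        w <- infl * areas
        comp_draw <- sample(names(w), sum(is_imm), replace = TRUE, prob = w)
        lims <- list(periphery = c(r_border_hi, R),
                     border = c(r_core_hi, r_border_hi),
                     core = c(0, r_core_hi))
        pos <- matrix(NA_real_, sum(is_imm), 3)
        for (cp in names(lims)) {
          sel <- comp_draw == cp
          if (any(sel)) pos[sel, ] <- runif_annulus(sum(sel), lims[[cp]][1], lims[[cp]][2])
        }
        xy[is_imm, ] <- pos
      }
      compartment <- compartment_of_radius(xy[, "r"], nest, band)

      # marker intensities: positive component for the lineage's markers
      intens <- matrix(NA_real_, n, nrow(mm), dimnames = list(NULL, mm$marker))
      bg_core <- ifelse(mm$background,
                        mm$background_level * stats::runif(nrow(mm), 0.5, 1.5),
                        0)
      for (j in seq_len(nrow(mm))) {
        m <- mm$marker[j]
        pos_lin <- vapply(config$lineage_markers, function(v) m %in% v, logical(1))
        is_pos <- lineage %in% names(pos_lin)[pos_lin]
        meanlog <- ifelse(is_pos, mm$mu_pos[j], mm$mu_neg[j])
        intens[, j] <- stats::rlnorm(n, meanlog = meanlog, sdlog = mm$sigma[j]) + bg_core[j]
      }

      nuclear_area <- stats::rlnorm(n, meanlog = log(40), sdlog = 0.25)
      ecc_shape1 <- ifelse(lineage %in% c("stromal", "endothelial"), 6, 4)
      eccentricity <- stats::rbeta(n, ecc_shape1, 3)
      dapi_positive <- stats::runif(n) >= config$dapi_negative_frac

      cells_list[[idx]] <- data.frame(
        cell_id = sprintf("%s_c%04d", core_id, seq_len(n)),
        core_id = core_id,
        x_um = xy[, "x"], y_um = xy[, "y"],
        nuclear_area_um2 = nuclear_area,
        eccentricity = eccentricity,
        dapi_positive = dapi_positive,
        intens,
        stringsAsFactors = FALSE, check.names = FALSE
      )
      truth_list[[idx]] <- data.frame(
        cell_id = cells_list[[idx]]$cell_id,
        core_id = core_id,
        lineage = lineage,
        compartment = compartment,
        stringsAsFactors = FALSE
      )
      core_rows[[idx]] <- data.frame(core_id = core_id, subtype = s,
                                     stringsAsFactors = FALSE)
    }
  }

  cells <- do.call(rbind, cells_list)
  truth_cells <- do.call(rbind, truth_list)
  cores <- do.call(rbind, core_rows)
  rownames(cells) <- rownames(truth_cells) <- rownames(cores) <- NULL

  realized <- prop.table(table(truth_cells$core_id, truth_cells$lineage), 1)
  realized <- matrix(realized, nrow = nrow(realized),
                     dimnames = dimnames(realized))[cores$core_id, , drop = FALSE]

  structure(list(
    cells = cells,
    truth = list(cores = cores, cells = truth_cells,
                 realized_composition = realized, seed = seed)
  ), class = "sim_cohort")
}

#' Simulate paired bulk expression counts for a cohort
#'
#' One bulk RNA-seq sample per core.  Each core's tissue subtype maps to a
#' human TNBC molecular subtype via `molecular_map`; signature genes (the
#' mouse-mapped centroid panel genes) have their log2 mean shifted toward the
#' sample's true centroid by `centroid_shift` units of the gene's marginal
#' log2-count standard deviation (delta-method sd
#' \eqn{\sqrt{1/\mu + \phi}/\ln 2} under the NB model).  Counts are
#' negative-binomial with dispersion `phi` (`dispersion` in the config);
#' `dispersion = 0` degenerates to rounded means.
#'
#' @param config a [sim_config()]; the `expression_model` element is used.
#' @param truth either the `truth` element of a [simulate_cohort()] result or
#'   any list with a `cores` data.frame (`core_id`, `subtype`).
#' @param panel optional [CentroidPanel][map_orthologs()]; defaults to the
#'   packaged synthetic centroid panel mapped through the packaged synthetic
#'   ortholog table.
#' @param molecular_map named character vector mapping tissue subtypes to
#'   centroid subtypes; unmapped subtypes are assigned centroids round-robin.
#' @param seed integer seed.
#' @return list with `counts` (gene x sample integer matrix, samples named by
#'   core_id), `subtype` (named character vector: true molecular subtype per
#'   sample) and `signature_genes`.
#' @export
simulate_expression <- function(config, truth,
                                panel = NULL,
                                molecular_map = c("SP" = "BLIS",
                                                  "SR-IR" = "BLIA",
                                                  "SR-IP" = "MES"),
                                seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  cores <- truth$cores
  check_columns(cores, c("core_id", "subtype"), "truth$cores")
  if (nrow(cores) < 1L) stop("truth contains no cores")
  em <- config$expression_model
  if (em$centroid_shift < 0) stop("centroid_shift must be >= 0")
  if (is.null(panel)) panel <- default_centroid_panel()
  sig <- panel$centroids
  n_sig <- nrow(sig)
  if (em$n_genes < n_sig + 1L) stop("n_genes must exceed the signature size")
  local_seed(seed)

  subtype_cols <- colnames(sig)
  mol <- unname(molecular_map[cores$subtype])
  if (any(is.na(mol))) {
    # tissue subtypes without a stated molecular counterpart cycle the panel
    nas <- which(is.na(mol))
    mol[nas] <- subtype_cols[((seq_along(nas) - 1L) %% length(subtype_cols)) + 1L]
  }
  names(mol) <- cores$core_id

  genes <- c(rownames(sig),
             sprintf("bg%04d", seq_len(em$n_genes - n_sig)))
  base_mu <- stats::rlnorm(length(genes), em$base_mean_log, em$base_mean_sd)
  names(base_mu) <- genes

  # marginal sd of log2 counts under NB(mu, phi), delta method
  sd_log2 <- sqrt(1 / base_mu[rownames(sig)] + em$dispersion) / log(2)

  counts <- matrix(0L, length(genes), nrow(cores),
                   dimnames = list(genes, cores$core_id))
  for (i in seq_len(nrow(cores))) {
    z <- sig[, mol[i]]
    lfc <- numeric(length(genes))
    lfc[seq_len(n_sig)] <- em$centroid_shift * sd_log2 * z
    mu <- base_mu * 2^lfc
    if (em$dispersion > 0) {
      counts[, i] <- stats::rnbinom(length(mu), mu = mu, size = 1 / em$dispersion)
    } else {
      counts[, i] <- as.integer(round(mu))
    }
  }
  list(counts = counts, subtype = mol, signature_genes = rownames(sig))
}

#' Simulate survival records with subtype-specific exponential hazards
#'
#' Event times are exponential with the subtype's hazard (1/day); censoring
#' times are independent uniform on `[0, censor_window]`; the record keeps the
#' earlier of the two.  A zero-length window censors every record at time 0.
#'
#' @param truth list with a `cores` data.frame (`core_id`, `subtype`).
#' @param config a [sim_config()]; `survival_model` supplies hazards and the
#'   censoring window.
#' @param seed integer seed.
#' @return data.frame with `core_id`, `time` (days), `event` (1 event /
#'   0 censored), `group` (subtype).
#' @export
simulate_survival <- function(truth, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  cores <- truth$cores
  check_columns(cores, c("core_id", "subtype"), "truth$cores")
  if (nrow(cores) < 1L) stop("truth contains no cores (empty truth)")
  sm <- config$survival_model
  if (!all(cores$subtype %in% names(sm$hazards))) {
    stop("survival hazards missing for some subtype in truth")
  }
  if (any(sm$hazards <= 0)) stop("hazards must be strictly positive")
  local_seed(seed)
  rate <- unname(sm$hazards[cores$subtype])
  t_event <- stats::rexp(nrow(cores), rate = rate)
  if (sm$censor_window == 0) {
    t_cens <- rep(0, nrow(cores))
  } else {
    t_cens <- stats::runif(nrow(cores), 0, sm$censor_window)
  }
  data.frame(
    core_id = cores$core_id,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    group = cores$subtype,
    stringsAsFactors = FALSE
  )
}
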