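# Shared builders for small in-code fixtures.

# A minimal cell table with explicit marker intensities. `...` are named
# marker values (scalars or vectors recycled to n).
make_cells <- function(n = 1, core_id = "core1", dapi = TRUE, ...) {
  markers <- list(...)
  base <- data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    core_id = rep_len(core_id, max(n, 0)),
    x_um = seq_len(n) * 10,
    y_um = seq_len(n) * 10,
    nuclear_area_um2 = rep(40, n),
    eccentricity = rep(0.5, n),
    dapi_positive = rep_len(dapi, max(n, 0)),
    stringsAsFactors = FALSE
  )
  panel <- c("CD31", "CD45", "Ecad", "EpCAM", "CK5",
             "Vim", "aSMA", "ColIV", "ColVI", "Gal3")
  for (m in panel) base[[m]] <- rep(0, n)
  for (m in names(markers)) base[[m]] <- rep_len(markers[[m]], n)
  base
}

# Gating config with every threshold fixed at 5 (markers are set to 0 or 10
# in the fixtures, so positivity is unambiguous).
fixed_gating_config <- function(...) {
  cfg <- gating_config(...)
  markers <- unique(c(cfg$endothelial_marker, cfg$immune_marker,
                      cfg$epithelial_markers, cfg$stromal_gating_markers))
  cfg$thresholds <- stats::setNames(rep(5, length(markers)), markers)
  cfg
}

# Three well-separated planted Gaussian blobs in 2D.
planted_blobs <- function(n_per = 20, k = 3, sep = 1, sd = sep / 20, seed = 1) {
  set.seed(seed)
  centers <- cbind(seq_len(k) * sep, (seq_len(k) %% 2) * sep)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(stats::rnorm(n_per, centers[i, 1], sd),
          stats::rnorm(n_per, centers[i, 2], sd))
  }))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# A noise-free simulation config: sigma -> 0, no background, full DAPI.
noise_free_config <- function(...) {
  mm <- default_marker_model()
  mm$sigma <- 1e-12
  mm$background_level <- 0
  sim_config(marker_model = mm, dapi_negative_frac = 0, ...)
}

# Analytic disk tumor mask centred at the origin.
disk_mask <- function(radius_um = 500, grid_size_um = 50, extent_um = 1000) {
  half_cells <- ceiling(extent_um / grid_size_um)
  origin <- c(-half_cells, -half_cells) * grid_size_um
  nx <- 2L * half_cells
  cx <- origin[1] + (seq_len(nx) - 0.5) * grid_size_um
  cy <- origin[2] + (seq_len(nx) - 0.5) * grid_size_um
  m <- outer(cx, cy, function(x, y) sqrt(x^2 + y^2) < radius_um)
  tumor_mask(m, origin, grid_size_um)
}
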