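#' Construct a tumor-mask object
#'
#' Low-level constructor used by [build_tumor_mask()] and by tests that build
#' analytic masks (e.g. a disk) directly.
#'
#' @param mask logical matrix (rows index x grid cells, columns y).
#' @param origin numeric length-2: coordinates (micrometres) of the lower-left
#'   corner of grid cell `[1, 1]`.
#' @param grid_size_um grid cell edge length in micrometres.
#' @return object of class `tumor_mask`.
#' @export
tumor_mask <- function(mask, origin, grid_size_um) {
  stopifnot(is.logical(mask), is.matrix(mask), length(origin) == 2,
            grid_size_um > 0)
  structure(list(mask = mask, origin = as.numeric(origin),
                 grid_size_um = grid_size_um),
            class = "tumor_mask")
}

# 3x3 binary dilation / erosion (radius one grid cell, 8-connected).
dilate3 <- function(m) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    src_r <- max(1, 1 - dx):min(nr, nr - dx)
    src_c <- max(1, 1 - dy):min(nc, nc - dy)
    out[src_r + dx, src_c + dy] <- out[src_r + dx, src_c + dy] | m[src_r, src_c]
  }
  out
}
erode3 <- function(m) !dilate3(!m)

# Map positions to grid indices for a given mask geometry.
grid_index <- function(x, y, origin, gs, dim) {
  ix <- pmin(pmax(floor((x - origin[1]) / gs) + 1L, 1L), dim[1])
  iy <- pmin(pmax(floor((y - origin[2]) / gs) + 1L, 1L), dim[2])
  cbind(ix, iy)
}

#' Build a binary tumor mask from gated cells
#'
#' Rasterizes epithelial-cell counts on a square grid (default 50 um cells),
#' thresholds at `min_count` cells, and applies a morphological closing
#' (radius one grid cell) to fill small gaps; grid cells dominated by immune
#' cells (immune count exceeding epithelial count) are excluded from the
#' mask.  This is the table-level analogue of delineating the tumor
#' compartment from PanCK (epithelial) versus CD45 (immune) expression.
#'
#' @param cells cell table with `x_um`, `y_um` and `lineage` columns.
#' @param grid_size_um grid cell edge (micrometres).
#' @param min_count minimum epithelial cells per grid cell (before closing).
#' @param pad_cells empty grid cells added around the bounding box so the
#'   mask boundary is interior to the grid.
#' @return a [tumor_mask()]; empty (all-FALSE) with a warning when the core
#'   contains no epithelial cells.
#' @export
build_tumor_mask <- function(cells, grid_size_um = 50, min_count = 1,
                             pad_cells = 2L) {
  check_columns(cells, c("x_um", "y_um", "lineage"), "cell table")
  gs <- grid_size_um
  if (gs <= 0) stop("grid_size_um must be positive")
  if (nrow(cells) == 0L) {
    warning("no cells: returning empty mask")
    return(tumor_mask(matrix(FALSE, 1, 1), c(0, 0), gs))
  }
  origin <- c(floor(min(cells$x_um) / gs) - pad_cells,
              floor(min(cells$y_um) / gs) - pad_cells) * gs
  nx <- ceiling((max(cells$x_um) - origin[1]) / gs) + pad_cells + 1L
  ny <- ceiling((max(cells$y_um) - origin[2]) / gs) + pad_cells + 1L
  count_grid <- function(sub) {
    m <- matrix(0L, nx, ny)
    if (nrow(sub) > 0L) {
      ij <- grid_index(sub$x_um, sub$y_um, origin, gs, c(nx, ny))
      tab <- table(ij[, 1], ij[, 2])
      m[cbind(as.integer(rownames(tab))[row(tab)],
              as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)
    }
    m
  }
  epi <- count_grid(cells[cells$lineage == "epithelial", , drop = FALSE])
  imm <- count_grid(cells[cells$lineage == "immune", , drop = FALSE])
  if (sum(epi) == 0L) {
    warning("no epithelial cells: returning empty mask")
    return(tumor_mask(matrix(FALSE, nx, ny), origin, gs))
  }
  mask <- epi >= min_count
  mask <- erode3(dilate3(mask))     # closing
  mask[imm > epi] <- FALSE          # immune-dominated cells are not tumor
  tumor_mask(mask, origin, gs)
}

# Per-grid-cell distance (um) to the nearest grid cell of opposite mask state,
# approximating distance to the mask boundary to within half a grid cell.
boundary_distance <- function(mask_obj) {
  m <- mask_obj$mask
  gs <- mask_obj$grid_size_um
  nr <- nrow(m); nc <- ncol(m)
  cx <- mask_obj$origin[1] + (seq_len(nr) - 0.5) * gs
  cy <- mask_obj$origin[2] + (seq_len(nc) - 0.5) * gs
  inside <- which(m, arr.ind = TRUE)
  outside <- which(!m, arr.ind = TRUE)
  d <- matrix(Inf, nr, nc)
  if (nrow(inside) == 0L || nrow(outside) == 0L) return(d)
  pin <- cbind(cx[inside[, 1]], cy[inside[, 2]])
  pout <- cbind(cx[outside[, 1]], cy[outside[, 2]])
  # distance from every inside centre to nearest outside centre and vice versa
  cross <- function(a, b) {
    # row-wise min distances from a to b, chunked to bound memory
    n <- nrow(a)
    res <- numeric(n)
    chunk <- max(1L, floor(2e6 / nrow(b)))
    for (start in seq(1L, n, by = chunk)) {
      iv <- start:min(n, start + chunk - 1L)
      dd <- outer(a[iv, 1], b[, 1], "-")^2 + outer(a[iv, 2], b[, 2], "-")^2
      res[iv] <- sqrt(apply(dd, 1, min))
    }
    res
  }
  d[inside] <- cross(pin, pout)
  d[outside] <- cross(pout, pin)
  d
}

#' Assign cells to periphery / border / core compartments
#'
#' The border compartment is every point within `band_width_um` of the tumor
#' mask boundary (inside or outside); the core is inside the mask beyond the
#' band; the periphery is outside the mask beyond the band.  Cells inherit the
#' compartment of their grid cell, so per-compartment areas (counted in grid
#' cells) are exactly consistent with the cell assignment.
#'
#' @param cells cell table with `x_um`, `y_um`.
#' @param mask a [tumor_mask()].
#' @param band_width_um band half-width around the mask boundary (> 0).
#' @return object of class `compartment_map`: list with `compartment`
#'   (character per cell), `grid_compartment` (matrix), `areas_mm2` (named
#'   numeric, analyzed area per compartment), `mask`, `band_width_um`.
#' @export
assign_compartments <- function(cells, mask, band_width_um = 100) {
  stopifnot(inherits(mask, "tumor_mask"))
  if (band_width_um <= 0) stop("band_width_um must be positive")
  check_columns(cells, c("x_um", "y_um"), "cell table")
  d <- boundary_distance(mask)
  grid_comp <- matrix("periphery", nrow(mask$mask), ncol(mask$mask))
  grid_comp[mask$mask] <- "core"
  grid_comp[d <= band_width_um] <- "border"
  areas <- vapply(c(periphery = "periphery", border = "border", core = "core"),
                  function(cp) sum(grid_comp == cp), numeric(1)) *
    mask$grid_size_um^2 * 1e-6
  ij <- grid_index(cells$x_um, cells$y_um, mask$origin, mask$grid_size_um,
                   dim(mask$mask))
  structure(list(compartment = grid_comp[ij],
                 grid_compartment = grid_comp,
                 areas_mm2 = areas,
                 mask = mask,
                 band_width_um = band_width_um),
            class = "compartment_map")
}

#' Compartmental cell-type densities
#'
#' Counts cells of each type per spatial compartment and divides by the
#' compartment's analyzed area to give densities in cells per square
#' millimetre.
#'
#' @param cells cell table aligned with the compartment map.
#' @param cmap a [assign_compartments()] result for the same cells.
#' @param type_col name of the cell-type column (default `"lineage"`).
#' @return data.frame in long format: `compartment`, `cell_type`, `count`,
#'   `area_mm2`, `density` (cells/mm^2). All type-compartment combinations are
#'   present (zero counts included).
#' @export
compartment_densities <- function(cells, cmap, type_col = "lineage") {
  stopifnot(inherits(cmap, "compartment_map"))
  check_columns(cells, type_col, "cell table")
  if (nrow(cells) != length(cmap$compartment)) {
    stop("cells and compartment map are not aligned")
  }
  comps <- c("periphery", "border", "core")
  types <- sort(unique(cells[[type_col]]))
  tab <- table(factor(cells[[type_col]], levels = types),
               factor(cmap$compartment, levels = comps))
  out <- data.frame(
    compartment = rep(comps, each = length(types)),
    cell_type = rep(types, times = length(comps)),
    count = as.integer(tab),
    area_mm2 = rep(unname(cmap$areas_mm2[comps]), each = length(types)),
    stringsAsFactors = FALSE
  )
  if (any(out$count > 0 & out$area_mm2 <= 0)) {
    stop("compartment with cells has zero analyzed area (inconsistent map)")
  }
  out$density <- ifelse(out$area_mm2 > 0, out$count / out$area_mm2, 0)
  out
}

#' z-score of log10 density per cell type
#'
#' Adds the heatmap transform used for compartmental density profiles: per
#' cell type, `log10(density + pseudocount)` is z-scored (sample sd, n-1
#' denominator) across all rows (compartments, and cores when the table spans
#' several).  Rows whose cell type has zero spread get `zlog = 0`.
#'
#' @param density_table a [compartment_densities()] data.frame (optionally
#'   row-bound over cores).
#' @param pseudocount added before the log (default 1 cell/mm^2).
#' @return the table with a `zlog` column.
#' @export
zlog_densities <- function(density_table, pseudocount = 1) {
  check_columns(density_table, c("cell_type", "density"), "density table")
  lg <- log10(density_table$density + pseudocount)
  z <- numeric(length(lg))
  for (ct in unique(density_table$cell_type)) {
    sel <- density_table$cell_type == ct
    s <- stats::sd(lg[sel])
    z[sel] <- if (is.na(s) || s == 0) 0 else (lg[sel] - mean(lg[sel])) / s
  }
  density_table$zlog <- z
  density_table
}

#' Per-compartment cell-type composition (flow table)
#'
#' Converts a density table to the per-compartment cell-type fractions behind
#' a periphery -> border -> core flow (Sankey-style) display.  Fractions per
#' compartment sum to 1; an all-zero compartment yields `NA` fractions.
#'
#' @param density_table a [compartment_densities()] data.frame for one core.
#' @return data.frame `compartment` (ordered periphery, border, core),
#'   `cell_type`, `fraction`.
#' @export
composition_flow <- function(density_table) {
  check_columns(density_table, c("compartment", "cell_type", "count"),
                "density table")
  comps <- c("periphery", "border", "core")
  out <- do.call(rbind, lapply(comps, function(cp) {
    sub <- density_table[density_table$compartment == cp, , drop = FALSE]
    total <- sum(sub$count)
    data.frame(compartment = cp, cell_type = sub$cell_type,
               fraction = if (total > 0) sub$count / total else rep(NA_real_, nrow(sub)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$compartment <- factor(out$compartment, levels = comps)
  out
}
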