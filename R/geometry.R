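# Domain geometry and biomass rasterisation.

#' Simulation domain geometry
#'
#' A 2D domain of unit depth (1 um): `width` columns of voxels along x
#' (periodic), `height` rows along y with the inert substratum at y = 0 and
#' the well-mixed bulk liquid above. Solute concentrations are clamped to
#' their bulk values from `boundary_layer` um above the biofilm front upward.
#'
#' @param width domain width (um), an integer multiple of `h`.
#' @param height domain height (um), an integer multiple of `h`.
#' @param h grid spacing (um).
#' @param boundary_layer thickness of the diffusive boundary layer above the
#'   biofilm front (um), at least `h`.
#' @return an object of class `domain_geometry`.
#' @examples
#' domain_geometry(width = 130, height = 130)
#' @export
domain_geometry <- function(width = 258, height = 258, h = 2,
                            boundary_layer = 40) {
  stopifnot(width > 0, height > 0, h > 0)
  ncol <- width / h
  nrow <- height / h
  if (abs(ncol - round(ncol)) > 1e-9 || abs(nrow - round(nrow)) > 1e-9) {
    stop("width and height must be integer multiples of the grid spacing h",
         call. = FALSE)
  }
  if (boundary_layer < h) {
    stop("boundary_layer must be at least one grid spacing", call. = FALSE)
  }
  structure(list(width = width, height = height, h = h,
                 boundary_layer = boundary_layer,
                 ncol = as.integer(round(ncol)),
                 nrow = as.integer(round(nrow)),
                 voxel_volume = h * h * 1),
            class = "domain_geometry")
}

#' @export
print.domain_geometry <- function(x, ...) {
  cat(sprintf("Domain %g x %g um, h = %g um (%d x %d voxels), boundary layer %g um\n",
              x$width, x$height, x$h, x$ncol, x$nrow, x$boundary_layer))
  invisible(x)
}

# Voxel (row, col) of cell centres; 1-based. x == width wraps to column 1.
cell_voxels <- function(cells, geometry) {
  col <- 1L + as.integer(floor((cells$x %% geometry$width) / geometry$h))
  row <- 1L + as.integer(floor(cells$y / geometry$h))
  col[col > geometry$ncol] <- geometry$ncol
  list(row = row, col = col)
}

#' Deposit cell masses onto the solute lattice
#'
#' Each cell's whole mass is assigned to the voxel containing its centre;
#' dividing by the voxel volume (h x h x 1 um^3) gives a biomass density in
#' fg/um^3, numerically g/L. Total deposited mass equals total cell mass per
#' lineage exactly.
#'
#' @param cells a cell table (see [make_inoculum()]).
#' @param geometry a [domain_geometry()].
#' @return list with matrices `X_R` and `X_S` (nrow x ncol, g/L).
#' @export
rasterize_biomass <- function(cells, geometry) {
  g <- geometry
  X_R <- matrix(0, g$nrow, g$ncol)
  X_S <- matrix(0, g$nrow, g$ncol)
  if (nrow(cells) > 0) {
    if (any(cells$y < 0) || any(cells$y > g$height) ||
        any(cells$x < 0) || any(cells$x > g$width)) {
      stop("cell outside simulation domain", call. = FALSE)
    }
    if (any(cells$y >= g$height - g$h)) {
      stop("biofilm front reached the top of the domain; enlarge the domain height",
           call. = FALSE)
    }
    v <- cell_voxels(cells, g)
    idx <- (v$col - 1L) * g$nrow + v$row
    for (sp in c("R", "S")) {
      sel <- cells$species == sp
      if (!any(sel)) next
      acc <- rowsum(cells$mass[sel], group = idx[sel])
      tgt <- if (sp == "R") "X_R" else "X_S"
      m <- get(tgt)
      m[as.integer(rownames(acc))] <- acc[, 1] / g$voxel_volume
      assign(tgt, m)
    }
  }
  list(X_R = X_R, X_S = X_S)
}

# Index of the first clamped row: rows >= clamp_row hold the bulk value and
# are excluded from the solve. Row 1 sits on the substratum.
clamp_row_index <- function(biomass, geometry) {
  occ <- which(rowSums(biomass$X_R + biomass$X_S) > 0)
  front <- if (length(occ)) max(occ) else 0L
  n_bl <- as.integer(ceiling(geometry$boundary_layer / geometry$h))
  min(front + n_bl + 1L, geometry$nrow)
}

#' Locate the biofilm front and the clamped bulk region
#'
#' Solute fields are solved only below the boundary layer; every node from
#' `boundary_layer` um above the highest occupied voxel upward is held at the
#' solute's bulk value (a Dirichlet condition; for by-products and toxins the
#' bulk value 0 makes this an absorbing sink). The substratum row has zero
#' normal flux and the lateral edges wrap periodically.
#'
#' @param biomass output of [rasterize_biomass()].
#' @param geometry a [domain_geometry()].
#' @return list with `front_height` (um, 0 for an empty domain),
#'   `clamp_height` (um, where clamping starts) and `clamp_row` (1-based
#'   index of the first clamped row).
#' @export
locate_front_and_clamp <- function(biomass, geometry) {
  occ <- which(rowSums(biomass$X_R + biomass$X_S) > 0)
  front <- if (length(occ)) max(occ) else 0L
  row <- clamp_row_index(biomass, geometry)
  list(front_height = front * geometry$h,
       clamp_height = (row - 1L) * geometry$h,
       clamp_row = row)
}
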