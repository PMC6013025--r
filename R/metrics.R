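# Analysis metrics: census, segregation index, outcome statistics, profiles.

# pairwise distances with periodic wrap in x, plain Euclidean in y
pair_distances <- function(x1, y1, x2, y2, width) {
  dx <- abs(outer(x1, x2, "-"))
  dx <- pmin(dx, width - dx)
  dy <- outer(y1, y2, "-")
  sqrt(dx^2 + dy^2)
}

#' Proportion of like-typed neighbours of one cell
#'
#' Among all cells whose centre lies within `radius` of the focal cell
#' (periodic wrap in x, focal cell excluded), the fraction that share the
#' focal cell's lineage. `NA` when the neighbourhood is empty.
#'
#' @param cells a cell table.
#' @param focal row index of the focal cell in `cells`.
#' @param radius neighbourhood radius (um).
#' @param width domain width (um) for the periodic wrap.
#' @return a proportion in `[0, 1]`, or `NA` if the cell has no neighbours.
#' @export
local_proportion <- function(cells, focal, radius = 10, width) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  d <- pair_distances(cells$x[focal], cells$y[focal], cells$x, cells$y, width)[1, ]
  nb <- which(d <= radius)
  nb <- nb[nb != focal]
  if (length(nb) == 0) return(NA_real_)
  mean(cells$species[nb] == cells$species[focal])
}

#' Spatial segregation index of one lineage
#'
#' For the focal lineage (default R), `s = (p_local - p_global) /
#' (1 - p_global)` where `p_local` is the mean, over focal cells with at
#' least one neighbour within `radius`, of the proportion of like-typed
#' neighbours, and `p_global` is the focal lineage's share of the whole
#' population. Near 0 for random mixing, near 1 for complete segregation;
#' negative values indicate over-dispersion (unlike neighbours
#' over-represented).
#'
#' @param cells a cell table.
#' @param focal_species `"R"` or `"S"`.
#' @param radius neighbourhood radius (um).
#' @param width domain width (um) for the periodic wrap.
#' @return the segregation index, or `NA` if either lineage is absent (the
#'   index is undefined for a single-species population) or no focal cell
#'   has neighbours.
#' @export
segregation_index <- function(cells, focal_species = "R", radius = 10, width) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  n <- nrow(cells)
  is_focal <- cells$species == focal_species
  n_f <- sum(is_focal)
  if (n_f == 0 || n_f == n) return(NA_real_)
  p_global <- n_f / n
  nc <- neighbour_counts_cpp(cells$x, cells$y, as.integer(is_focal),
                             radius, width)
  n_d <- nc$n_d[is_focal]
  p_i <- nc$n_same[is_focal][n_d > 0] / n_d[n_d > 0]
  if (length(p_i) == 0) return(NA_real_)
  (mean(p_i) - p_global) / (1 - p_global)
}

#' Mean biofilm height
#'
#' Mean over all columns of the height of the highest occupied voxel
#' (0 for empty columns).
#'
#' @param biomass output of [rasterize_biomass()].
#' @param geometry a [domain_geometry()].
#' @return height in um.
#' @export
biofilm_height <- function(biomass, geometry) {
  tot <- biomass$X_R + biomass$X_S
  top <- apply(tot > 0, 2, function(col) {
    w <- which(col)
    if (length(w)) max(w) else 0L
  })
  mean(top) * geometry$h
}

# one metrics row for the current state
census <- function(state) {
  cells <- state$cells
  biomass <- rasterize_biomass(cells, state$geometry)
  data.frame(
    time_h = state$time,
    count_R = sum(cells$species == "R"),
    count_S = sum(cells$species == "S"),
    biomass_R_fg = sum(cells$mass[cells$species == "R"]),
    biomass_S_fg = sum(cells$mass[cells$species == "S"]),
    s_R = segregation_index(cells, "R", radius = 10,
                            width = state$geometry$width),
    biofilm_height_um = biofilm_height(biomass, state$geometry))
}

metric_at_time <- function(metrics, t, col) {
  i <- which.min(abs(metrics$time_h - t))
  if (abs(metrics$time_h[i] - t) > 1e-6) {
    stop("no metrics record at t = ", t, " h", call. = FALSE)
  }
  metrics[[col]][i]
}

outcome_label <- function(delta_R, delta_S) {
  if (delta_R > 0 && delta_S > 0) "mutualists"
  else if (delta_R < 0 && delta_S < 0) "competitors"
  else if (delta_R == 0 && delta_S == 0) "neutral"
  else "exploitation"
}

#' Coculture-versus-monoculture ecological outcome
#'
#' Computes, at time `t`, the number of R cells in coculture minus in R
#' monoculture and the number of S cells in coculture minus in S
#' monoculture. Both positive: the pair are mutualists; both negative:
#' competitors; mixed signs: one exploits the other.
#'
#' @param co,monoR,monoS metrics data frames (or mean series) with columns
#'   `time_h`, `count_R`, `count_S`.
#' @param t evaluation time (h).
#' @return list with `delta_R`, `delta_S` (cells) and `label`.
#' @export
ecological_outcome <- function(co, monoR, monoS, t) {
  delta_R <- metric_at_time(co, t, "count_R") - metric_at_time(monoR, t, "count_R")
  delta_S <- metric_at_time(co, t, "count_S") - metric_at_time(monoS, t, "count_S")
  list(delta_R = delta_R, delta_S = delta_S,
       label = outcome_label(delta_R, delta_S))
}

#' Antibiotic response statistics
#'
#' Competitive release / mutualistic suppression statistic
#' `R_co[A>0] - R_co[A=0]` and the cross-species phenotypic resistance
#' statistic `S_co[A>0] - S_mono[A>0]`, both at time `t`. A positive release
#' statistic is labelled `competitive_release`, a negative one
#' `mutualistic_suppression`, zero `neutral`; cross-protection is flagged
#' when the second statistic is positive.
#'
#' @param co_at_A coculture metrics under antibiotic.
#' @param co_at_zero coculture metrics without antibiotic.
#' @param monoS_at_A S monoculture metrics under the same antibiotic level.
#' @param t evaluation time (h).
#' @return list with `release_statistic`, `cross_protection_statistic`
#'   (cells), `release_label` and `cross_protection`.
#' @export
antibiotic_response <- function(co_at_A, co_at_zero, monoS_at_A, t) {
  release <- metric_at_time(co_at_A, t, "count_R") -
    metric_at_time(co_at_zero, t, "count_R")
  crossprot <- metric_at_time(co_at_A, t, "count_S") -
    metric_at_time(monoS_at_A, t, "count_S")
  list(release_statistic = release,
       cross_protection_statistic = crossprot,
       release_label = if (release > 0) "competitive_release"
       else if (release < 0) "mutualistic_suppression" else "neutral",
       cross_protection = crossprot > 0)
}

#' Height profile of a solute field
#'
#' Row-wise mean concentration as a function of height above the substratum
#' (the mean is over the full domain width, as in bulk-averaged community
#' profiles).
#'
#' @param field one solute matrix.
#' @param geometry a [domain_geometry()].
#' @return data frame with `height_um` (voxel centres) and `mean_conc`.
#' @export
solute_height_profile <- function(field, geometry) {
  data.frame(height_um = (seq_len(geometry$nrow) - 0.5) * geometry$h,
             mean_conc = rowMeans(field))
}
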