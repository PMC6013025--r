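# Reading/writing configs, cell tables, metrics and summaries.

#' Write / read a simulation configuration as YAML
#'
#' The declarative form uses the keys `medium`, `antibiotic_bulk`,
#' `antibiotic_start_time`, `cost`, `alpha`, `seed`, `duration_h`, `dt_h`,
#' `snapshot_every_h`, `domain` (`width`, `height`, `h`, `boundary_layer`)
#' and `inoculum` (`n_R`, `n_S`, `arrangement`). `cost` accepts either the
#' absolute rate reduction in h^-1 or (equivalently, since `mu_max` defaults
#' to 1 h^-1) the fractional cost.
#'
#' @param config a [simulation_config()].
#' @param path file path.
#' @return `read_config` returns a [simulation_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  x <- list(medium = config$medium,
            antibiotic_bulk = config$antibiotic_bulk,
            antibiotic_start_time = config$antibiotic_start_time,
            cost = config$cost_c,
            alpha = config$alpha_detox,
            seed = config$seed,
            duration_h = config$duration_h,
            dt_h = config$dt_h,
            snapshot_every_h = config$snapshot_every_h,
            domain = list(width = config$geometry$width,
                          height = config$geometry$height,
                          h = config$geometry$h,
                          boundary_layer = config$geometry$boundary_layer),
            inoculum = list(n_R = config$inoculum$n_R,
                            n_S = config$inoculum$n_S,
                            arrangement = config$inoculum$arrangement))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  geometry <- if (is.null(x$domain)) domain_geometry() else
    do.call(domain_geometry, x$domain)
  inoculum <- if (is.null(x$inoculum)) inoculum_spec() else
    do.call(inoculum_spec, x$inoculum)
  opt <- function(nm, default) if (is.null(x[[nm]])) default else x[[nm]]
  simulation_config(medium = opt("medium", "exploitation_competition"),
                    antibiotic_bulk = opt("antibiotic_bulk", 0),
                    antibiotic_start_time = opt("antibiotic_start_time", 0),
                    cost_c = opt("cost", 0),
                    alpha_detox = opt("alpha", 0),
                    inoculum = inoculum, geometry = geometry,
                    dt_h = opt("dt_h", 0.02),
                    duration_h = opt("duration_h", 36),
                    snapshot_every_h = opt("snapshot_every_h", 2),
                    seed = opt("seed", 1))
}

#' Write / read a cell table as CSV
#'
#' Columns: `time_h` (if present), `cell_id`, `species`, `x_um`, `y_um`,
#' `mass_fg`, `radius_um`. Inocula stored this way can be replayed.
#'
#' @param cells a cell table (optionally with a `time_h` column).
#' @param path file path.
#' @return `read_cells_csv` returns a cell table.
#' @export
write_cells_csv <- function(cells, path) {
  out <- data.frame(cell_id = cells$id, species = cells$species,
                    x_um = cells$x, y_um = cells$y, mass_fg = cells$mass,
                    radius_um = cells$radius)
  if (!is.null(cells$time_h)) out <- cbind(time_h = cells$time_h, out)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  cells <- data.frame(id = as.integer(x$cell_id), species = x$species,
                      x = x$x_um, y = x$y_um, mass = x$mass_fg,
                      radius = x$radius_um, stringsAsFactors = FALSE)
  if (!is.null(x$time_h)) cells$time_h <- x$time_h
  cells
}

#' Write replicate metrics as tidy CSV
#'
#' @param metrics a metrics data frame (e.g. `per_replicate` from
#'   [run_replicates()]).
#' @param path file path.
#' @param ... constant annotation columns prepended to every row (e.g.
#'   `medium`, `antibiotic`).
#' @export
write_metrics_csv <- function(metrics, path, ...) {
  ann <- list(...)
  if (length(ann)) metrics <- cbind(as.data.frame(ann), metrics)
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Export a solute field (or all fields) as plain-text matrices / profiles
#'
#' @param fields named list of solute matrices.
#' @param geometry a [domain_geometry()].
#' @param dir output directory, created if needed.
#' @return invisibly, the data frame of height profiles (`height_um`,
#'   `solute`, `mean_conc`) that was written to `height_profiles.csv`.
#' @export
write_fields <- function(fields, geometry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  profs <- list()
  for (s in names(fields)) {
    utils::write.csv(fields[[s]], file.path(dir, paste0("field_", s, ".csv")),
                     row.names = FALSE)
    p <- solute_height_profile(fields[[s]], geometry)
    profs[[s]] <- data.frame(height_um = p$height_um, solute = s,
                             mean_conc = p$mean_conc)
  }
  out <- do.call(rbind, profs)
  utils::write.csv(out, file.path(dir, "height_profiles.csv"),
                   row.names = FALSE)
  invisible(out)
}
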