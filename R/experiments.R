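# Pre-configured experiment suites and replicate handling.
#
# Every suite runs at one of two scales:
#   full    - 258 um domain, 120 cells per lineage, 36 h, 3 replicates
#             (the standard design)
#   reduced - 130 um domain, 40 cells per lineage, 24 h, 2 replicates
#             (same design at desk scale; preserves the sign structure of
#             the headline outcomes while running in minutes)

scale_defaults <- function(scale = c("reduced", "full", "mini")) {
  scale <- match.arg(scale)
  switch(scale,
    full = list(geometry = domain_geometry(width = 258, height = 258),
                n_per_species = 120L, duration_h = 36, replicates = 3L),
    reduced = list(geometry = domain_geometry(width = 130, height = 180),
                   n_per_species = 40L, duration_h = 24, replicates = 2L),
    # smoke-test scale: keeps the design, too small for reliable outcomes
    mini = list(geometry = domain_geometry(width = 64, height = 80,
                                           boundary_layer = 20),
                n_per_species = 16L, duration_h = 8, replicates = 1L))
}

#' Experiment configuration with replicates
#'
#' A [simulation_config()] plus a replicate count and one distinct seed per
#' replicate.
#'
#' @param config a [simulation_config()].
#' @param replicates number of independent replicate runs.
#' @param seeds integer vector of length `replicates` (distinct); defaults
#'   to `config$seed + 0:(replicates-1)`.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(config, replicates = 3, seeds = NULL) {
  stopifnot(inherits(config, "simulation_config"), replicates >= 1)
  if (is.null(seeds)) seeds <- config$seed + seq_len(replicates) - 1L
  if (length(seeds) != replicates || anyDuplicated(seeds)) {
    stop("seeds must be distinct and one per replicate", call. = FALSE)
  }
  structure(list(config = config, replicates = as.integer(replicates),
                 seeds = as.integer(seeds)),
            class = "experiment_config")
}

#' Run replicate simulations and average the metrics
#'
#' Runs one seeded simulation per replicate and returns the per-replicate
#' metrics plus the replicate-mean time series. Each replicate is exactly
#' reproducible from its seed.
#'
#' @param expt an [experiment_config()] (or a [simulation_config()], in
#'   which case `replicates`/`seeds` may be given directly).
#' @param replicates,seeds used when `expt` is a plain [simulation_config()].
#' @param keep_sims keep the full `biofilm_sim` objects (memory-heavy).
#' @return list with `per_replicate` (metrics with a `replicate` column),
#'   `mean` (metrics averaged over replicates at each time point), `seeds`,
#'   and optionally `sims`.
#' @export
run_replicates <- function(expt, replicates = 3, seeds = NULL,
                           keep_sims = FALSE) {
  if (inherits(expt, "simulation_config")) {
    expt <- experiment_config(expt, replicates = replicates, seeds = seeds)
  }
  stopifnot(inherits(expt, "experiment_config"))
  per <- vector("list", expt$replicates)
  sims <- if (keep_sims) vector("list", expt$replicates) else NULL
  for (r in seq_len(expt$replicates)) {
    cfg <- expt$config
    cfg$seed <- expt$seeds[r]
    cfg$store_cells <- keep_sims && cfg$store_cells
    sim <- run_simulation(cfg)
    per[[r]] <- cbind(replicate = r, seed = expt$seeds[r], sim$metrics)
    if (keep_sims) sims[[r]] <- sim
  }
  per_replicate <- do.call(rbind, per)
  num_cols <- c("count_R", "count_S", "biomass_R_fg", "biomass_S_fg",
                "s_R", "biofilm_height_um")
  mean_series <- stats::aggregate(per_replicate[num_cols],
                                  by = list(time_h = per_replicate$time_h),
                                  FUN = mean, na.rm = TRUE)
  out <- list(per_replicate = per_replicate, mean = mean_series,
              seeds = expt$seeds)
  if (keep_sims) out$sims <- sims
  out
}

# shared builder: coculture / monoculture config for one design cell
design_config <- function(medium, antibiotic, culture = c("co", "monoR", "monoS"),
                          sc, cost_c = 0, alpha_detox = 0, seed = 1,
                          arrangement = "random", antibiotic_start_time = 0,
                          n_per_species = NULL) {
  culture <- match.arg(culture)
  if (is.null(n_per_species)) n_per_species <- sc$n_per_species
  inoc <- switch(culture,
                 co = inoculum_spec(n_per_species, n_per_species, arrangement),
                 monoR = inoculum_spec(n_per_species, 0, arrangement),
                 monoS = inoculum_spec(0, n_per_species, arrangement))
  simulation_config(medium = medium, antibiotic_bulk = antibiotic,
                    antibiotic_start_time = antibiotic_start_time,
                    cost_c = cost_c, alpha_detox = alpha_detox,
                    inoculum = inoc, geometry = sc$geometry,
                    duration_h = sc$duration_h, seed = seed,
                    store_cells = FALSE)
}

#' Ecological outcome suite: four media, three antibiotic levels
#'
#' For every medium and bulk antibiotic level, runs coculture, R monoculture
#' and S monoculture (replicate means) and derives the
#' coculture-minus-monoculture outcome and the antibiotic-response
#' statistics (release relative to the antibiotic-free coculture of the same
#' medium).
#'
#' @param scale `"reduced"` or `"full"`.
#' @param media medium names to include.
#' @param antibiotic_levels bulk antibiotic concentrations (g/L); must
#'   include 0 for release statistics.
#' @param seed base seed; each design cell derives distinct replicate seeds.
#' @param replicates overrides the scale's replicate count.
#' @return data frame with one row per medium x antibiotic level: mean final
#'   counts, `delta_R`, `delta_S`, `outcome_label`, `release_statistic`,
#'   `cross_protection_statistic`, `release_label`.
#' @export
suite_fig1 <- function(scale = "reduced",
                       media = MEDIUM_NAMES,
                       antibiotic_levels = c(0, 0.05, 0.2),
                       seed = 1, replicates = NULL) {
  sc <- scale_defaults(scale)
  if (!is.null(replicates)) sc$replicates <- replicates
  t_end <- sc$duration_h
  runs <- list()
  key <- function(...) paste(..., sep = "|")
  cell_seed <- function(i) seed * 1000L + i
  i <- 0L
  for (med in media) {
    for (A in antibiotic_levels) {
      for (cult in c("co", "monoR", "monoS")) {
        i <- i + 100L
        cfg <- design_config(med, A, cult, sc, seed = cell_seed(i))
        runs[[key(med, A, cult)]] <-
          run_replicates(experiment_config(cfg, sc$replicates))$mean
      }
    }
  }
  out <- list()
  for (med in media) {
    for (A in antibiotic_levels) {
      co <- runs[[key(med, A, "co")]]
      eco <- ecological_outcome(co, runs[[key(med, A, "monoR")]],
                                runs[[key(med, A, "monoS")]], t_end)
      resp <- if (0 %in% antibiotic_levels) {
        antibiotic_response(co, runs[[key(med, 0, "co")]],
                            runs[[key(med, A, "monoS")]], t_end)
      } else NULL
      out[[key(med, A)]] <- data.frame(
        medium = med, antibiotic = A, time_h = t_end,
        R_co = metric_at_time(co, t_end, "count_R"),
        S_co = metric_at_time(co, t_end, "count_S"),
        R_mono = metric_at_time(runs[[key(med, A, "monoR")]], t_end, "count_R"),
        S_mono = metric_at_time(runs[[key(med, A, "monoS")]], t_end, "count_S"),
        delta_R = eco$delta_R, delta_S = eco$delta_S,
        outcome_label = eco$label,
        release_statistic = if (is.null(resp)) NA_real_ else resp$release_statistic,
        cross_protection_statistic = if (is.null(resp)) NA_real_ else
          resp$cross_protection_statistic,
        release_label = if (is.null(resp)) NA_character_ else resp$release_label,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# generic sweep runner over coculture configs
run_coculture_sweep <- function(grid, sc, seed) {
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- design_config(g$medium, g$antibiotic, "co", sc,
                         cost_c = g$cost_c, alpha_detox = g$alpha_detox,
                         seed = seed * 1000L + i * 100L,
                         arrangement = as.character(g$arrangement),
                         antibiotic_start_time = g$antibiotic_start_time,
                         n_per_species = g$n_per_species)
    m <- run_replicates(experiment_config(cfg, sc$replicates))$mean
    final <- m[nrow(m), ]
    rows[[i]] <- cbind(g, final_count_R = final$count_R,
                       final_count_S = final$count_S,
                       final_s_R = final$s_R, row.names = NULL)
  }
  do.call(rbind, rows)
}

sweep_grid <- function(sc, media, antibiotic_levels, costs = 0, alphas = 0,
                       arrangements = "random", start_times = 0,
                       n_per_species = NULL) {
  if (is.null(n_per_species)) n_per_species <- sc$n_per_species
  expand.grid(medium = media, antibiotic = antibiotic_levels, cost_c = costs,
              alpha_detox = alphas, arrangement = arrangements,
              antibiotic_start_time = start_times,
              n_per_species = n_per_species,
              stringsAsFactors = FALSE)
}

#' Cost-of-resistance sweep
#'
#' Coculture runs across media, antibiotic levels and resistance costs
#' (fractions of `mu_max`, e.g. 0.1 for a 10% cost).
#'
#' @param costs resistance costs (h^-1).
#' @param scale,media,antibiotic_levels,seed design controls.
#' @return tidy data frame of final counts per design cell.
#' @export
suite_fig2_cost <- function(costs = c(0, 0.1, 0.2, 0.3), scale = "reduced",
                            media = MEDIUM_NAMES,
                            antibiotic_levels = c(0, 0.05, 0.2), seed = 1) {
  sc <- scale_defaults(scale)
  run_coculture_sweep(sweep_grid(sc, media, antibiotic_levels, costs = costs),
                      sc, seed)
}

#' Detoxification sweep
#'
#' Coculture runs with and without growth-coupled detoxification. The
#' detoxification coefficient has no single canonical value; the default
#' 1 g antibiotic per g biomass is deliberately prominent and configurable.
#'
#' @param alphas detoxification coefficients (g/g).
#' @param scale,media,antibiotic_levels,seed design controls.
#' @return tidy data frame of final counts per design cell.
#' @export
suite_fig3_detox <- function(alphas = c(0, 1), scale = "reduced",
                             media = MEDIUM_NAMES,
                             antibiotic_levels = c(0.2), seed = 1) {
  sc <- scale_defaults(scale)
  run_coculture_sweep(sweep_grid(sc, media, antibiotic_levels, alphas = alphas),
                      sc, seed)
}

#' Seeding arrangement x detoxification suite
#'
#' Random-mixed versus segregated seeding, with and without detoxification,
#' tracking the segregation index trajectory of each design cell.
#'
#' @param arrangements seeding arrangements.
#' @param alphas detoxification coefficients (g/g).
#' @param scale,media,antibiotic,seed design controls.
#' @return list with `final` (tidy final-state table) and `series`
#'   (replicate-mean time series per design cell, including `s_R`).
#' @export
suite_fig4_spatial <- function(arrangements = c("random", "segregated"),
                               alphas = c(0, 1), scale = "reduced",
                               media = c("non_crossfeeding", "crossfeeding"),
                               antibiotic = 0.2, seed = 1) {
  sc <- scale_defaults(scale)
  grid <- sweep_grid(sc, media, antibiotic, alphas = alphas,
                     arrangements = arrangements)
  series <- list()
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- design_config(g$medium, g$antibiotic, "co", sc,
                         alpha_detox = g$alpha_detox,
                         seed = seed * 1000L + i * 100L,
                         arrangement = as.character(g$arrangement))
    m <- run_replicates(experiment_config(cfg, sc$replicates))$mean
    series[[i]] <- cbind(g, m, row.names = NULL)
    final <- m[nrow(m), ]
    rows[[i]] <- cbind(g, final_count_R = final$count_R,
                       final_count_S = final$count_S,
                       final_s_R = final$s_R, row.names = NULL)
  }
  list(final = do.call(rbind, rows), series = do.call(rbind, series))
}

#' Inoculum-size suite
#'
#' @param sizes inoculum sizes, cells per lineage.
#' @param scale,media,antibiotic_levels,seed design controls.
#' @return tidy data frame of final counts per design cell.
#' @export
suite_s3_inoculum <- function(sizes = c(60, 120, 960), scale = "reduced",
                              media = MEDIUM_NAMES,
                              antibiotic_levels = c(0, 0.2), seed = 1) {
  sc <- scale_defaults(scale)
  run_coculture_sweep(sweep_grid(sc, media, antibiotic_levels,
                                 n_per_species = sizes), sc, seed)
}

#' Initial proportion x mixing suite
#'
#' Varies the initial proportion of S cells and the seeding arrangement at a
#' fixed total inoculum.
#'
#' @param proportions_S initial S proportions in (0, 1).
#' @param arrangements seeding arrangements.
#' @param scale,media,antibiotic_levels,seed design controls.
#' @return tidy data frame of final counts per design cell.
#' @export
suite_s4_initial <- function(proportions_S = c(0.05, 0.5, 0.95),
                             arrangements = c("random", "segregated"),
                             scale = "reduced",
                             media = c("interference_competition", "crossfeeding"),
                             antibiotic_levels = c(0, 0.2), seed = 1) {
  sc <- scale_defaults(scale)
  total <- 2L * sc$n_per_species
  rows <- list()
  i <- 0L
  for (med in media) {
    for (A in antibiotic_levels) {
      for (sp in ratio_sweep_specs(total, proportions_S, arrangements)) {
        i <- i + 1L
        cfg <- simulation_config(medium = med, antibiotic_bulk = A,
                                 inoculum = sp, geometry = sc$geometry,
                                 duration_h = sc$duration_h,
                                 seed = seed * 1000L + i * 100L,
                                 store_cells = FALSE)
        m <- run_replicates(experiment_config(cfg, sc$replicates))$mean
        final <- m[nrow(m), ]
        rows[[i]] <- data.frame(medium = med, antibiotic = A,
                                proportion_S = attr(sp, "proportion_S"),
                                arrangement = attr(sp, "arrangement"),
                                n_R = sp$n_R, n_S = sp$n_S,
                                final_count_R = final$count_R,
                                final_count_S = final$count_S,
                                final_s_R = final$s_R,
                                stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Antibiotic timing suite
#'
#' The antibiotic is added at the start of the run or only after the biofilm
#' has grown for a while.
#'
#' @param start_times dosing start times (h).
#' @param scale,media,antibiotic,seed design controls.
#' @return tidy data frame of final counts per design cell.
#' @export
suite_s8_timing <- function(start_times = c(0, 4, 12, 24), scale = "reduced",
                            media = MEDIUM_NAMES, antibiotic = 0.2, seed = 1) {
  sc <- scale_defaults(scale)
  start_times <- start_times[start_times <= sc$duration_h]
  run_coculture_sweep(sweep_grid(sc, media, antibiotic,
                                 start_times = start_times), sc, seed)
}
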