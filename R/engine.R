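# Simulation engine: growth, division, shoving, and the step/run loop.

#' Simulation configuration
#'
#' Collects everything needed for one run. The defaults reproduce the
#' standard full-scale design: a 258 um wide domain, 120 cells of each
#' lineage seeded randomly 1:1, 36 h of growth with a 0.02 h biomass step.
#'
#' @param medium medium name (see [build_medium()]).
#' @param params a [parameter_set()]; its `A_bulk` is overridden by
#'   `antibiotic_bulk`.
#' @param antibiotic_bulk bulk antibiotic concentration (g/L).
#' @param antibiotic_start_time time (h) at which the antibiotic appears in
#'   the bulk; before it the bulk antibiotic is 0.
#' @param cost_c cost of resistance (h^-1).
#' @param alpha_detox detoxification coefficient (g/g).
#' @param inoculum an [inoculum_spec()].
#' @param geometry a [domain_geometry()].
#' @param dt_h biomass time step (h).
#' @param duration_h simulated time (h).
#' @param snapshot_every_h interval between recorded metrics/cell snapshots (h).
#' @param division_radius_um radius at which a cell divides (um).
#' @param density_g_per_L cytoplasm density (g/L).
#' @param seed RNG seed; every stochastic element of the run (inoculum,
#'   division fractions and directions) draws from this stream.
#' @param solver_tol,solver_omega,solver_inner,solver_max_outer settings of
#'   the pseudo-steady solver (see [solve_pseudo_steady_state()]).
#' @param sealed if `TRUE`, run the sealed well-mixed variant: no bulk
#'   exchange, spatially uniform solute pools depleted stoichiometrically by
#'   growth (used for mass-balance checks; no pseudo-steady solve).
#' @param store_cells keep a cell table per snapshot.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(medium = "exploitation_competition",
                              params = parameter_set(),
                              antibiotic_bulk = 0,
                              antibiotic_start_time = 0,
                              cost_c = 0,
                              alpha_detox = 0,
                              inoculum = inoculum_spec(),
                              geometry = domain_geometry(),
                              dt_h = 0.02,
                              duration_h = 36,
                              snapshot_every_h = 2,
                              division_radius_um = 1,
                              density_g_per_L = 200,
                              seed = 1,
                              solver_tol = 1e-6,
                              solver_omega = 1.8,
                              solver_inner = 2,
                              solver_max_outer = 20000,
                              sealed = FALSE,
                              store_cells = TRUE) {
  if (duration_h < 0) stop("duration_h must be >= 0", call. = FALSE)
  if (duration_h > 0 && dt_h <= 0) stop("dt_h must be positive", call. = FALSE)
  if (antibiotic_bulk < 0) stop("antibiotic_bulk must be >= 0", call. = FALSE)
  if (antibiotic_start_time < 0) stop("antibiotic_start_time must be >= 0", call. = FALSE)
  structure(list(medium = medium, params = params,
                 antibiotic_bulk = antibiotic_bulk,
                 antibiotic_start_time = antibiotic_start_time,
                 cost_c = cost_c, alpha_detox = alpha_detox,
                 inoculum = inoculum, geometry = geometry,
                 dt_h = dt_h, duration_h = duration_h,
                 snapshot_every_h = snapshot_every_h,
                 division_radius_um = division_radius_um,
                 density_g_per_L = density_g_per_L,
                 seed = seed,
                 solver_tol = solver_tol, solver_omega = solver_omega,
                 solver_inner = solver_inner,
                 solver_max_outer = solver_max_outer,
                 sealed = sealed, store_cells = store_cells),
            class = "simulation_config")
}

division_mass <- function(config) {
  config$density_g_per_L * pi * config$division_radius_um^2
}

# bulk antibiotic in effect at time t (delayed-dosing support)
effective_antibiotic <- function(config, t) {
  if (t + 1e-9 >= config$antibiotic_start_time) config$antibiotic_bulk else 0
}

#' Initialise a simulation state
#'
#' @param config a [simulation_config()]. The caller is responsible for the
#'   RNG seed (use [run_simulation()] for seeded end-to-end runs).
#' @return a `simulation_state` list: `time`, `cells`, `fields`, `medium`,
#'   `geometry`, `config`, `next_id`.
#' @export
init_state <- function(config) {
  medium <- build_medium(config$medium, config$params,
                         cost_c = config$cost_c,
                         alpha_detox = config$alpha_detox)
  cells <- make_inoculum(config$inoculum, config$geometry,
                         density = config$density_g_per_L,
                         division_radius = config$division_radius_um)
  A0 <- effective_antibiotic(config, 0)
  if (config$sealed) {
    b <- solute_bulk_values(medium)
    b["A"] <- A0
    fields <- b  # uniform pools (g/L)
  } else {
    fields <- init_fields(medium, config$geometry, bulk = c(A = A0))
  }
  structure(list(time = 0, cells = cells, fields = fields, medium = medium,
                 geometry = config$geometry, config = config,
                 next_id = nrow(cells) + 1L,
                 antibiotic_dosed = A0 > 0 || config$antibiotic_bulk == 0),
            class = "simulation_state")
}

# local solute concentrations at each cell (named list of vectors)
local_concentrations <- function(state) {
  if (state$config$sealed) {
    lapply(as.list(state$fields), rep, nrow(state$cells))
  } else {
    v <- cell_voxels(state$cells, state$geometry)
    lapply(state$fields, function(F) F[cbind(v$row, v$col)])
  }
}

#' Grow all cells over one time step
#'
#' Each cell's mass is multiplied by `exp(mu * dt)` where `mu` is its
#' specific growth rate at the solute concentrations of its voxel (exact for
#' constant `mu` over the step). Growth is never negative: the antibiotic is
#' bacteriostatic, so inhibited cells merely slow down or stall.
#'
#' In the sealed variant the uniform solute pools are additionally depleted
#' (or fed) by the stoichiometry of the biomass actually formed on each
#' route, then truncated at zero.
#'
#' @param state a `simulation_state`.
#' @param dt time step (h), positive.
#' @return the updated state.
#' @export
grow_cells <- function(state, dt) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  cells <- state$cells
  if (nrow(cells) == 0) return(state)
  conc <- local_concentrations(state)
  n <- nrow(cells)
  reactions <- state$medium$reactions
  route_rate <- matrix(0, n, length(reactions))
  for (k in seq_along(reactions)) {
    r <- reactions[[k]]
    sel <- cells$species == r$actor
    if (!any(sel)) next
    rate <- rep(r$max_rate, sum(sel))
    for (m in r$monod) rate <- rate * monod_factor(conc[[m$solute]][sel], m$K)
    for (i in r$inhibition) rate <- rate * inhibition_factor(conc[[i$solute]][sel], i$Ki)
    route_rate[sel, k] <- rate
  }
  mu <- rowSums(route_rate)
  gain <- cells$mass * (exp(mu * dt) - 1)
  cells$mass <- cells$mass + gain
  cells$radius <- radius_from_mass(cells$mass, state$config$density_g_per_L)
  state$cells <- cells

  if (state$config$sealed) {
    # stoichiometric pool update from the biomass formed per route
    share <- route_rate / ifelse(mu > 0, mu, 1)
    V <- state$geometry$width * state$geometry$height * 1
    pools <- state$fields
    for (k in seq_along(reactions)) {
      r <- reactions[[k]]
      dm <- sum(gain * share[, k])
      if (dm == 0) next
      pools[names(r$stoich)] <- pools[names(r$stoich)] + r$stoich * dm / V
    }
    pools[pools < 0] <- 0
    state$fields <- pools
  }
  state
}

#' Divide cells that reached the division mass
#'
#' Every cell at or above the division mass splits into two daughters of the
#' same lineage with mass fractions `f` and `1 - f`, `f ~ Uniform(0.45,
#' 0.55)` (jitter breaks symmetry); the daughters are placed at half the
#' parent radius on either side of the parent centre along a uniformly
#' random direction. Total mass is conserved exactly; daughters get fresh
#' ids.
#'
#' @param state a `simulation_state`.
#' @return the updated state.
#' @export
divide_cells <- function(state) {
  cells <- state$cells
  m_div <- division_mass(state$config)
  sel <- which(cells$mass >= m_div)
  if (length(sel) == 0) return(state)
  parents <- cells[sel, , drop = FALSE]
  nd <- length(sel)
  f <- stats::runif(nd, 0.45, 0.55)
  theta <- stats::runif(nd, 0, 2 * pi)
  off <- parents$radius / 2
  dx <- off * cos(theta)
  dy <- off * sin(theta)
  dens <- state$config$density_g_per_L
  w <- state$geometry$width
  d1 <- new_cell_table(id = state$next_id + seq_len(nd) - 1L,
                       species = parents$species,
                       x = (parents$x + dx) %% w,
                       y = parents$y + dy,
                       mass = parents$mass * f, density = dens)
  d2 <- new_cell_table(id = state$next_id + nd + seq_len(nd) - 1L,
                       species = parents$species,
                       x = (parents$x - dx) %% w,
                       y = parents$y - dy,
                       mass = parents$mass * (1 - f), density = dens)
  d1$y <- pmax(d1$y, d1$radius)
  d2$y <- pmax(d2$y, d2$radius)
  state$next_id <- state$next_id + 2L * nd
  state$cells <- rbind(cells[-sel, , drop = FALSE], d1, d2)
  state$cells <- state$cells[order(state$cells$id), , drop = FALSE]
  rownames(state$cells) <- NULL
  state
}

#' Resolve cell overlaps by shoving
#'
#' Iterative mechanical relaxation: every overlapping pair is displaced
#' apart symmetrically along the centre line by half the overlap each, with
#' periodic lateral wrap and reflection above the substratum, until the
#' largest overlap is below 0.01 um (or 5000 sweeps, in which case a warning
#' is issued and the state returned as-is).
#'
#' @param state a `simulation_state`.
#' @param tol overlap tolerance (um).
#' @param max_sweeps sweep budget.
#' @return the updated state.
#' @export
relax_overlaps <- function(state, tol = 0.01, max_sweeps = 5000) {
  cells <- state$cells
  if (nrow(cells) < 2) return(state)
  res <- shove_cpp(cells$x, cells$y, cells$radius, state$geometry$width,
                   tol = tol, max_sweeps = max_sweeps)
  if (!res$converged) {
    warning(sprintf("shoving did not fully relax (max overlap %.3g um after %d sweeps)",
                    res$max_overlap, res$sweeps), call. = FALSE)
  }
  state$cells$x <- res$x
  state$cells$y <- res$y
  state
}

#' Advance the simulation by one biomass step
#'
#' Executes the model loop: re-solve the solute fields to pseudo-steady
#' state for the current biomass, then (for `dt > 0`) grow, divide, shove,
#' and advance the clock. With `dt = 0` only the solute refresh happens.
#'
#' @param state a `simulation_state`.
#' @param dt time step (h), `>= 0`.
#' @return the updated state.
#' @export
simulation_step <- function(state, dt) {
  config <- state$config
  A_now <- effective_antibiotic(config, state$time)
  if (config$sealed) {
    # pools carry over; the antibiotic pool appears when dosing starts
    if (A_now > 0 && !state$antibiotic_dosed) {
      state$fields[["A"]] <- A_now
      state$antibiotic_dosed <- TRUE
    }
  } else {
    biomass <- rasterize_biomass(state$cells, state$geometry)
    state$fields <- solve_pseudo_steady_state(
      state$fields, biomass, state$medium, state$geometry,
      bulk = c(A = A_now),
      tol = config$solver_tol, max_outer = config$solver_max_outer,
      omega = config$solver_omega, inner_sweeps = config$solver_inner)
  }
  if (dt > 0) {
    state <- grow_cells(state, dt)
    state <- divide_cells(state)
    state <- relax_overlaps(state)
    state$time <- state$time + dt
  }
  state
}

#' Run a full seeded simulation
#'
#' Seeds the RNG, generates the inoculum, and advances the state from t = 0
#' to `duration_h`, recording a metrics row (and optionally a cell table)
#' every `snapshot_every_h` hours. With a fixed seed the run is exactly
#' reproducible.
#'
#' @param config a [simulation_config()].
#' @return an object of class `biofilm_sim` with elements `config`,
#'   `metrics` (data frame: `time_h`, `count_R`, `count_S`, `biomass_R_fg`,
#'   `biomass_S_fg`, `s_R`, `biofilm_height_um`), `snapshots` (list of cell
#'   tables, if stored), `cells` (final cell table), `fields` (final solute
#'   fields), `medium`.
#' @examples
#' \donttest{
#' cfg <- simulation_config(duration_h = 1, geometry = domain_geometry(64, 64),
#'                          inoculum = inoculum_spec(10, 10), seed = 1)
#' sim <- run_simulation(cfg)
#' sim$metrics
#' }
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  state <- init_state(config)
  n_steps <- if (config$duration_h > 0) round(config$duration_h / config$dt_h) else 0L
  snap_every <- max(1L, if (config$duration_h > 0)
    round(config$snapshot_every_h / config$dt_h) else 1L)

  metrics <- list()
  snapshots <- list()
  record <- function(state) {
    i <- length(metrics) + 1L
    metrics[[i]] <<- census(state)
    if (config$store_cells) {
      snapshots[[i]] <<- cbind(time_h = state$time, state$cells)
    }
  }
  # refresh fields once so the t = 0 snapshot is consistent
  state <- simulation_step(state, 0)
  record(state)
  if (n_steps > 0) {
    for (k in seq_len(n_steps)) {
      state <- simulation_step(state, config$dt_h)
      if (k %% snap_every == 0 || k == n_steps) record(state)
    }
    state <- simulation_step(state, 0) # final field refresh
  }

  structure(list(config = config,
                 metrics = do.call(rbind, metrics),
                 snapshots = if (config$store_cells) snapshots else NULL,
                 cells = state$cells,
                 fields = state$fields,
                 medium = state$medium),
            class = "biofilm_sim")
}
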