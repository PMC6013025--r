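# Shared fixtures: tiny geometries, quick configs, independent oracles.

tiny_geom <- function(width = 64, height = 80, h = 2, boundary_layer = 20) {
  domain_geometry(width, height, h, boundary_layer)
}

quick_config <- function(medium = "exploitation_competition",
                         antibiotic_bulk = 0, duration_h = 2,
                         n_R = 10, n_S = 10, seed = 1, ...) {
  simulation_config(medium = medium, antibiotic_bulk = antibiotic_bulk,
                    inoculum = inoculum_spec(n_R, n_S),
                    geometry = tiny_geom(), duration_h = duration_h,
                    seed = seed, store_cells = FALSE, ...)
}

# O(n^2) double-loop oracle for the segregation index (periodic wrap in x)
brute_force_segregation <- function(cells, focal_species, radius, width) {
  n <- nrow(cells)
  focal <- which(cells$species == focal_species)
  if (length(focal) == 0 || length(focal) == n) return(NA_real_)
  p_global <- length(focal) / n
  p_loc <- c()
  for (i in focal) {
    n_d <- 0; same <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      dx <- abs(cells$x[i] - cells$x[j])
      dx <- min(dx, width - dx)
      d <- sqrt(dx^2 + (cells$y[i] - cells$y[j])^2)
      if (d <= radius) {
        n_d <- n_d + 1
        if (cells$species[j] == cells$species[i]) same <- same + 1
      }
    }
    if (n_d > 0) p_loc <- c(p_loc, same / n_d)
  }
  if (length(p_loc) == 0) return(NA_real_)
  (mean(p_loc) - p_global) / (1 - p_global)
}

two_pair_cells <- function(width = 100) {
  # two near-coincident R cells and two near-coincident S cells, the pairs
  # well beyond the neighbourhood radius of each other
  data.frame(id = 1:4, species = c("R", "R", "S", "S"),
             x = c(5, 5.5, 30, 30.5), y = c(1, 1, 1, 1),
             mass = 314, radius = 0.7, stringsAsFactors = FALSE)
}

# random cell cloud for metric tests
random_cells <- function(n, width, height, seed, p_R = 0.5) {
  set.seed(seed)
  data.frame(id = seq_len(n),
             species = ifelse(stats::runif(n) < p_R, "R", "S"),
             x = stats::runif(n, 0, width),
             y = stats::runif(n, 0, height),
             mass = rep(314, n),
             radius = rep(0.7, n),
             stringsAsFactors = FALSE)
}

# analytic steady profile for a uniform first-order sink slab of thickness L
# below a purely diffusive layer with Dirichlet C0 at height yD
slab_closed_form <- function(y, L, yD, C0, k, D) {
  phi <- sqrt(k / D)
  b <- yD - L
  A <- C0 / (cosh(phi * L) + phi * b * sinh(phi * L))
  out <- ifelse(y <= L, A * cosh(phi * y),
                A * cosh(phi * L) + A * phi * sinh(phi * L) * (y - L))
  out[y >= yD] <- C0
  out
}

# slab test problem: uniform R biomass in the bottom L/h rows, linearised
# Monod sink (C0 << K)
slab_problem <- function(h = 2, width = 32, height = 128, L = 64,
                         boundary_layer = 20, X = 100, K = 0.68, C0 = 1e-4) {
  geom <- domain_geometry(width, height, h, boundary_layer)
  p <- parameter_set(N_bulk = C0, K_N = K)
  med <- build_medium("non_crossfeeding", p, 0, 0)
  biomass <- list(X_R = matrix(0, geom$nrow, geom$ncol),
                  X_S = matrix(0, geom$nrow, geom$ncol))
  biomass$X_R[seq_len(L / h), ] <- X
  list(geom = geom, params = p, medium = med, biomass = biomass,
       L = L, X = X, k = (1 / p$Y_N) * p$mu_max * X / K, C0 = C0, D = p$D_N)
}
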